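#' Build the design matrix for the nested c-Fos GLMs
#'
#' Constructs the model matrix for one of the three nested count models used
#' by the screen. All models share an intercept, a sex dummy (male = 1),
#' orthogonal linear and quadratic polynomials of the ordinal timepoint codes
#' 1--4, and block entered as a single numeric covariate 1--6 (optionally as
#' a factor). The `bonding` model adds a partner-type dummy (mate = 1) and
#' its interactions with sex and with both time polynomials; `reduced_sex`
#' is the bonding model without the partner-by-sex interaction, so comparing
#' `bonding` against it isolates the sex-by-partner interaction.
#'
#' @param design a [simulate_design()]-style table.
#' @param formula one of `"null"`, `"bonding"`, `"reduced_sex"`.
#' @param block_factor code block as a factor instead of a numeric covariate.
#' @return numeric model matrix with descriptive column names.
#' @export
design_matrix <- function(design, formula = c("null", "bonding", "reduced_sex"),
                          block_factor = FALSE) {
  formula <- match.arg(formula)
  for (f in c("sex", "partner_type", "timepoint")) {
    if (length(unique(design[[f]])) < 2L)
      stop("factor '", f, "' has a single level")
  }
  tpoly <- poly(design$timepoint, 2)   # orthogonal linear + quadratic
  sexM <- as.numeric(design$sex == "M")
  blk <- if (block_factor && length(unique(design$block)) > 1L) {
    b <- stats::model.matrix(~ factor(design$block))[, -1, drop = FALSE]
    colnames(b) <- paste0("block", sort(unique(design$block))[-1])
    b
  } else if (block_factor) {
    # single block: nothing to absorb beyond the intercept
    matrix(numeric(nrow(design)), ncol = 1, dimnames = list(NULL, "block"))
  } else matrix(design$block, ncol = 1, dimnames = list(NULL, "block"))
  X <- cbind("(Intercept)" = 1, sexM = sexM, t1 = tpoly[, 1], t2 = tpoly[, 2],
             blk)
  if (formula == "null") return(X)
  partner <- as.numeric(design$partner_type == "mate")
  Xp <- cbind(partner = partner, "partner:t1" = partner * tpoly[, 1],
              "partner:t2" = partner * tpoly[, 2])
  if (formula == "bonding")
    Xp <- cbind(partner = Xp[, "partner"], "partner:sexM" = partner * sexM,
                Xp[, c("partner:t1", "partner:t2"), drop = FALSE])
  cbind(X, Xp)
}

#' Fit a quasi-Poisson GLM to one unit's counts
#'
#' Log-link iteratively reweighted least squares (convergence when the
#' relative deviance change falls below 1e-8, at most 100 iterations), with
#' the dispersion estimated as the Pearson chi-square divided by the
#' residual degrees of freedom. An all-zero response is degenerate under the
#' log link (the intercept diverges); it is returned as a flagged
#' zero-deviance fit rather than an error so that screens over sparse units
#' keep running.
#'
#' @param X numeric design matrix (see [design_matrix()]).
#' @param y nonnegative counts, one per row of `X`.
#' @return object of class `"qp_fit"`: `coefficients`, `deviance`,
#'   `pearson_dispersion`, `df_residual`, `rank`, `fitted`, `converged`,
#'   `degenerate`.
#' @export
fit_quasipoisson <- function(X, y) {
  stopifnot(nrow(X) == length(y), all(y >= 0))
  if (all(y == 0)) {
    return(structure(list(coefficients = setNames(rep(NA_real_, ncol(X)),
                                                  colnames(X)),
                          deviance = 0, pearson_dispersion = 0,
                          df_residual = length(y) - ncol(X), rank = ncol(X),
                          fitted = rep(0, length(y)), converged = TRUE,
                          degenerate = TRUE), class = "qp_fit"))
  }
  fit <- glm.fit(X, y, family = quasipoisson(),
                 control = glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged)
    stop("IRLS did not converge in 100 iterations (deviance ",
         format(fit$deviance), ")")
  dfres <- length(y) - fit$rank
  phi <- if (dfres > 0) sum((y - fit$fitted.values)^2 / fit$fitted.values) / dfres
         else NA_real_
  structure(list(coefficients = fit$coefficients, deviance = fit$deviance,
                 pearson_dispersion = phi, df_residual = dfres,
                 rank = fit$rank, fitted = fit$fitted.values,
                 converged = TRUE, degenerate = FALSE), class = "qp_fit")
}

#' F statistic for a nested quasi-Poisson model comparison
#'
#' Quasi-likelihood ANOVA: `F = ((D_null - D_full) / df1) / phi_full`, with
#' `df1` the rank difference between the models and `phi_full` the Pearson
#' dispersion of the full fit; negative values (possible through dispersion
#' noise) are clipped at zero.
#'
#' @param fit_null,fit_full `"qp_fit"` objects for nested models fitted to
#'   the same response.
#' @return named vector `c(F, df1, df2)`.
#' @export
anova_f <- function(fit_null, fit_full) {
  df1 <- fit_full$rank - fit_null$rank
  if (df1 <= 0) stop("added columns are collinear: rank difference is 0")
  if (fit_full$degenerate || fit_null$degenerate)
    return(c(F = 0, df1 = df1, df2 = fit_full$df_residual))
  F <- ((fit_null$deviance - fit_full$deviance) / df1) /
    fit_full$pearson_dispersion
  c(F = max(0, F), df1 = df1, df2 = fit_full$df_residual)
}

#' Permutation-calibrated GLM screen over a count matrix
#'
#' For every unit (region or voxel) of the count matrix, compares two nested
#' quasi-Poisson GLMs by ANOVA F test and calibrates the F statistic against
#' a Monte Carlo permutation null, then controls the false discovery rate
#' across units. Contrasts: `"bonding"` tests the partner-type block (main
#' effect plus its interactions with sex and time) against the null model of
#' sex, time and block; `"sex_interaction"` tests the partner-by-sex
#' interaction by comparing the bonding model to the same model without that
#' term.
#'
#' The default permutation scheme (`"pair"`) shuffles partner-type labels at
#' the pair level within timepoint-by-block strata: each pair keeps its two
#' animals, sexes, timepoint and block, and only the mate/sibling assignment
#' is permuted among pairs tested at the same timepoint in the same block.
#' Stratifying on block as well as timepoint matters because block effects
#' need not be linear in the block index while the model adjusts for block
#' only linearly; relabelings that stay balanced within blocks keep the
#' residual block variation exchangeable, so the permutation null of F is
#' calibrated. `scheme = "row"`
#' instead permutes the response rows freely. One shuffle produces one
#' relabeled design applied to all units, so permutation indices are shared
#' across units. The p-value uses the add-one estimator
#' `(1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`, whose floor at 10,000
#' permutations is 1/10001, reported as 0.0001.
#'
#' @param counts animals-by-units count matrix; rows are matched to the
#'   design's `ieg_included` animals by row name.
#' @param design a [simulate_design()]-style table.
#' @param contrast `"bonding"` or `"sex_interaction"`.
#' @param n_perm number of permutations (>= 1; < 20 draws a warning since p
#'   resolution is then coarser than 0.05).
#' @param seed integer seed; results are deterministic given it.
#' @param scheme `"pair"` (stratified pair-level label shuffling, default)
#'   or `"row"` (unrestricted response-row shuffling).
#' @param alpha FDR threshold for the `significant` flag (study convention:
#'   0.1 for the brain screen).
#' @param fdr `"bh"` (Benjamini--Hochberg, default) or `"qvalue"` (Storey).
#' @param block_factor code block as a factor (default) rather than a single
#'   numeric covariate. Batch effects are categorical in nature; absorbing
#'   them fully keeps the permutation null exact, whereas a linear block
#'   term leaves residual block variation that leaks into the
#'   partner-by-sex interaction (whose balance over blocks cannot be
#'   preserved by any relabeling, since sex composition is tied to partner
#'   type). Set `FALSE` for the single-coefficient block adjustment.
#' @return object of class `"fos_screen"`: a `table` data.frame with one row
#'   per unit (`unit`, `F`, `df1`, `df2`, `p`, `q`, `significant`,
#'   `direction` — the sign of the partner main-effect coefficient), plus
#'   the call parameters and the matrix of permuted F statistics.
#' @seealso [select_exclusive()] for reducing significant units to an
#'   anatomically exclusive set.
#' @examples
#' d <- simulate_design(2)
#' y <- simulate_counts(d, paste0("u", 1:5),
#'                      sim_config(effect_units = "u1", effect_size = 1),
#'                      seed = 1)
#' sc <- fos_screen(y, d, n_perm = 99, seed = 1)
#' summary(sc)
#' @export
fos_screen <- function(counts, design, contrast = c("bonding", "sex_interaction"),
                       n_perm = 1000, seed = 1, scheme = c("pair", "row"),
                       alpha = 0.1, fdr = c("bh", "qvalue"),
                       block_factor = TRUE) {
  contrast <- match.arg(contrast)
  scheme <- match.arg(scheme)
  fdr <- match.arg(fdr)
  stopifnot(n_perm >= 1)
  if (n_perm < 20)
    warning("n_perm < 20 gives p-value resolution coarser than 0.05")
  design <- design[design$ieg_included, , drop = FALSE]
  missing_rows <- setdiff(design$animal_id, rownames(counts))
  if (length(missing_rows))
    stop("counts lack rows for included animals: ",
         paste(head(missing_rows, 5), collapse = ", "))
  counts <- counts[design$animal_id, , drop = FALSE]
  units <- colnames(counts)
  reduced <- if (contrast == "bonding") "null" else "reduced_sex"
  dm <- function(d, f) design_matrix(d, f, block_factor = block_factor)
  X0 <- dm(design, reduced)
  X1 <- dm(design, "bonding")

  # for the bonding contrast the reduced model has no partner term, so its
  # fit is invariant under partner-label shuffles and is computed once
  fits0 <- if (contrast == "bonding")
    lapply(units, function(u) fit_quasipoisson(X0, counts[, u]))
  else NULL
  screen_once <- function(d) {
    Xf <- dm(d, "bonding")
    f0 <- if (contrast == "bonding") fits0
          else { Xr <- dm(d, reduced)
                 lapply(units, function(u) fit_quasipoisson(Xr, counts[, u])) }
    t(vapply(seq_along(units), function(j)
      anova_f(f0[[j]], fit_quasipoisson(Xf, counts[, units[j]])),
      c(F = 0, df1 = 0, df2 = 0)))
  }
  obs <- screen_once(design)
  coefs <- vapply(units, function(u)
    fit_quasipoisson(X1, counts[, u])$coefficients["partner"], 0)

  set.seed(seed)
  pd <- design[!duplicated(design$pair_id),
               c("pair_id", "partner_type", "timepoint", "block")]
  # exchangeability strata: pairs sharing timepoint and block; shuffling
  # within them keeps relabeled designs balanced over both nuisance factors
  strata <- split(seq_len(nrow(pd)),
                  interaction(pd$timepoint, pd$block, drop = TRUE))
  Fperm <- matrix(NA_real_, n_perm, length(units),
                  dimnames = list(NULL, units))
  for (b in seq_len(n_perm)) {
    d <- design
    if (scheme == "pair") {
      newlab <- pd$partner_type
      for (i in strata) if (length(i) > 1)
        newlab[i] <- pd$partner_type[i][sample.int(length(i))]
      d$partner_type <- newlab[match(d$pair_id, pd$pair_id)]
      # sibling pairs relabeled as mates keep their true sexes; this only
      # permutes the tested labels, as intended
      Fperm[b, ] <- screen_once(d)[, "F"]
    } else {
      ridx <- sample.int(nrow(d))
      yperm <- counts[ridx, , drop = FALSE]
      Xr <- X0
      Fperm[b, ] <- vapply(units, function(u)
        anova_f(fit_quasipoisson(Xr, yperm[, u]),
                fit_quasipoisson(X1, yperm[, u]))["F"], 0)
    }
  }
  p <- vapply(seq_along(units), function(j)
    (1 + sum(Fperm[, j] >= obs[j, "F"])) / (1 + n_perm), 0)
  adj <- fdr_adjust(p, method = fdr, alpha = alpha)
  tab <- data.frame(unit = units, F = obs[, "F"], df1 = obs[, "df1"],
                    df2 = obs[, "df2"], p = p, q = adj$q,
                    significant = adj$significant,
                    direction = sign(coefs), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, contrast = contrast, n_perm = n_perm,
                 scheme = scheme, alpha = alpha, fdr = fdr, seed = seed,
                 n_animals = nrow(design), perm_F = Fperm),
            class = "fos_screen")
}

#' False discovery rate adjustment
#'
#' Benjamini--Hochberg step-up q-values (default) or Storey q-values (BH
#' scaled by the estimated null proportion `pi0`, computed at
#' `lambda = 0.5`). Significance flags compare q against `alpha`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"qvalue"`.
#' @param alpha threshold for the flags.
#' @return list with `q` and logical `significant`, in input order.
#' @export
fdr_adjust <- function(p, method = c("bh", "qvalue"), alpha = 0.1) {
  method <- match.arg(method)
  if (!length(p)) return(list(q = numeric(0), significant = logical(0)))
  stopifnot(all(p >= 0 & p <= 1))
  q <- p.adjust(p, method = "BH")
  if (method == "qvalue") {
    lambda <- 0.5
    pi0 <- min(1, mean(p > lambda) / (1 - lambda))
    q <- pmin(1, q * pi0)
  }
  list(q = q, significant = q < alpha)
}

#' @export
print.fos_screen <- function(x, ...) {
  cat("Permutation-calibrated GLM screen (", x$contrast, " contrast)\n",
      sep = "")
  cat("  ", nrow(x$table), " units, ", x$n_animals, " animals, ",
      x$n_perm, " permutations (", x$scheme, " scheme)\n", sep = "")
  cat("  ", sum(x$table$significant), " units significant at q < ",
      x$alpha, " (", toupper(x$fdr), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.fos_screen <- function(object, n = 10, ...) {
  print(object)
  tab <- object$table[order(-object$table$F), ]
  cat("\nTop units by F:\n")
  print(head(tab, n), row.names = FALSE, digits = 4)
  invisible(tab)
}

#' @param x a `"fos_screen"` object.
#' @param ... ignored.
#' @describeIn fos_screen histogram of the pooled permutation-null F values
#'   with observed F statistics of significant units overlaid.
#' @export
plot.fos_screen <- function(x, ...) {
  hist(x$perm_F, breaks = 50, main = "Permutation null of F",
       xlab = "F statistic", col = "grey85", border = "grey60")
  sig <- x$table$F[x$table$significant]
  if (length(sig)) {
    abline(v = sig, col = "firebrick")
    legend("topright", legend = sprintf("significant units (q < %g)", x$alpha),
           col = "firebrick", lty = 1, bty = "n")
  }
  invisible(x)
}
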