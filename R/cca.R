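#' Canonical correlation analysis of brain and behavior variables
#'
#' Finds paired linear combinations (canonical factors) of two variable
#' sets — typically chosen-region c-Fos counts (`X`) and behavioral measures
#' (`Y`) — maximizing their correlation. Both sets are centered and scaled;
#' the solution comes from the singular value decomposition of the whitened
#' cross-covariance. Rank-deficient sets lose the dimensions beyond their
#' rank, with a warning. Each factor is oriented so that its
#' largest-magnitude `Y` (behavior) loading is positive, making score signs
#' interpretable across runs.
#'
#' Animals with missing values in either set are dropped (complete-case);
#' a warning is raised when `n <= p + q`, where the solution is still
#' computed but overfits.
#'
#' @param X,Y numeric matrices with the same animals as rows (matched by row
#'   name when present, else by position).
#' @param ridge nonnegative ridge added to both within-set correlation
#'   matrices before whitening; 0 (none) by default, useful for small
#'   synthetic runs.
#' @return object of class `"cca_fit"`: `cor` (canonical correlations,
#'   non-increasing), `xweights`, `yweights` (columns are factors, on the
#'   scaled-variable scale), `xscores`, `yscores`, `xloadings`, `yloadings`
#'   (correlations of raw variables with their own set's scores), `n`,
#'   `dropped` (excluded animal ids).
#' @seealso [wilks_test()], [score_loadings()], [group_cc_scores()]
#' @export
cca_fit <- function(X, Y, ridge = 0) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    common <- intersect(rownames(X), rownames(Y))
    X <- X[common, , drop = FALSE]; Y <- Y[common, , drop = FALSE]
  }
  stopifnot(nrow(X) == nrow(Y))
  cc_ok <- complete.cases(X) & complete.cases(Y)
  dropped <- if (!is.null(rownames(X))) rownames(X)[!cc_ok] else which(!cc_ok)
  X <- X[cc_ok, , drop = FALSE]; Y <- Y[cc_ok, , drop = FALSE]
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n <= p + q)
    warning("n (", n, ") <= p + q (", p + q, "): canonical structure overfits")
  zvx <- apply(X, 2, sd) == 0
  zvy <- apply(Y, 2, sd) == 0
  if (any(zvx) || any(zvy))
    stop("zero-variance variables: ",
         paste(c(colnames(X)[zvx], colnames(Y)[zvy]), collapse = ", "))
  Xs <- scale(X); Ys <- scale(Y)
  Sxx <- crossprod(Xs) / (n - 1) + diag(ridge, p)
  Syy <- crossprod(Ys) / (n - 1) + diag(ridge, q)
  Sxy <- crossprod(Xs, Ys) / (n - 1)
  inv_sqrt <- function(S, label) {
    e <- eigen(S, symmetric = TRUE)
    tol <- max(e$values) * 1e-10
    keep <- e$values > tol
    if (!all(keep))
      warning(label, " set is rank-deficient; dropping ", sum(!keep),
              " dimension(s)")
    e$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(e$values[keep]), sum(keep)) %*%
      t(e$vectors[, keep, drop = FALSE])
  }
  Wx <- inv_sqrt(Sxx, "X"); Wy <- inv_sqrt(Syy, "Y")
  sv <- svd(Wx %*% Sxy %*% Wy)
  m <- min(qr(Xs)$rank, qr(Ys)$rank)
  rho <- pmin(1, pmax(0, sv$d[seq_len(m)]))
  A <- (Wx %*% sv$u)[, seq_len(m), drop = FALSE]
  B <- (Wy %*% sv$v)[, seq_len(m), drop = FALSE]
  xs <- Xs %*% A; ys <- Ys %*% B
  # sign convention: largest-|loading| behavior variable loads positively
  yl <- cor(Y, ys)
  for (k in seq_len(m)) {
    top <- which.max(abs(yl[, k]))
    if (yl[top, k] < 0) {
      A[, k] <- -A[, k]; B[, k] <- -B[, k]
      xs[, k] <- -xs[, k]; ys[, k] <- -ys[, k]
    }
  }
  dimnames(A) <- list(colnames(X), paste0("CC", seq_len(m)))
  dimnames(B) <- list(colnames(Y), paste0("CC", seq_len(m)))
  colnames(xs) <- colnames(ys) <- paste0("CC", seq_len(m))
  rownames(xs) <- rownames(ys) <- rownames(X)
  structure(list(cor = rho, xweights = A, yweights = B,
                 xscores = xs, yscores = ys,
                 xloadings = cor(X, xs), yloadings = cor(Y, ys),
                 n = n, p = p, q = q, dropped = dropped),
            class = "cca_fit")
}

#' @export
print.cca_fit <- function(x, ...) {
  cat("Canonical correlation analysis: n =", x$n, ", p =", x$p, ", q =",
      x$q, "\n")
  cat("  canonical correlations:",
      paste(sprintf("%.3f", x$cor), collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  dropped (incomplete):", length(x$dropped), "animals\n")
  invisible(x)
}

#' Wilks' lambda tests for canonical factors
#'
#' Sequential tests that canonical correlations `k, k+1, ...` are all zero:
#' `Lambda_k = prod_{i >= k} (1 - rho_i^2)`, converted to an F statistic by
#' Rao's approximation. A small p-value at factor `k` indicates that factor
#' `k` (and possibly later ones) carries real association.
#'
#' @param fit a [cca_fit()] object.
#' @param n number of animals; defaults to `fit$n`.
#' @return `data.frame` with one row per factor: `factor`, `lambda`,
#'   `statistic` (approximate F), `df1`, `df2`, `p`.
#' @export
wilks_test <- function(fit, n = fit$n) {
  rho <- fit$cor; p <- fit$p; q <- fit$q
  m <- length(rho)
  if (n <= p + q + 1)
    warning("n <= p + q + 1: Rao's approximation is unreliable here")
  out <- data.frame(factor = seq_len(m), lambda = NA_real_,
                    statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                    p = NA_real_)
  for (k in seq_len(m)) {
    pk <- p - k + 1; qk <- q - k + 1
    lam <- prod(1 - rho[k:m]^2)
    s2 <- (pk^2 * qk^2 - 4) / (pk^2 + qk^2 - 5)
    s <- if (is.finite(s2) && s2 > 0) sqrt(s2) else 1
    df1 <- pk * qk
    df2 <- ((n - 1) - (pk + qk + 1) / 2) * s - pk * qk / 2 + 1
    lam_s <- lam^(1 / s)
    Fstat <- if (lam_s > 0) (1 - lam_s) / lam_s * df2 / df1 else Inf
    out[k, -1] <- c(lam, Fstat, df1, df2, pf(Fstat, df1, df2, lower.tail = FALSE))
  }
  out
}

#' Correlation loadings of raw variables on canonical scores
#'
#' Pearson correlation of every raw variable with every canonical score of
#' its own set — the quantities used to interpret what each factor
#' represents. Zero-variance variables get `NA` loadings.
#'
#' @param fit a [cca_fit()] object.
#' @param xraw,yraw optional raw variable matrices over the scored animals;
#'   default to the variables used in the fit (whose loadings are already
#'   stored).
#' @return `data.frame` in long form: `set` (`"X"`/`"Y"`), `variable`,
#'   `factor`, `loading`.
#' @export
score_loadings <- function(fit, xraw = NULL, yraw = NULL) {
  align <- function(raw, scores) {
    raw <- as.matrix(raw)
    if (!is.null(rownames(scores)) && !is.null(rownames(raw)))
      raw <- raw[rownames(scores), , drop = FALSE]
    suppressWarnings(cor(raw, scores))
  }
  xl <- if (is.null(xraw)) fit$xloadings else align(xraw, fit$xscores)
  yl <- if (is.null(yraw)) fit$yloadings else align(yraw, fit$yscores)
  long <- function(l, set) {
    vars <- if (is.null(rownames(l)))
      paste0(tolower(set), seq_len(nrow(l))) else rownames(l)
    data.frame(set = set, variable = rep(vars, ncol(l)),
               factor = rep(colnames(l), each = nrow(l)),
               loading = as.vector(l), stringsAsFactors = FALSE)
  }
  rbind(long(xl, "X"), long(yl, "Y"))
}

#' Canonical score summaries by experimental group
#'
#' Mean and sd of each canonical factor score within every partner-type x
#' sex x timepoint cell, for either variable set's scores.
#'
#' @param fit a [cca_fit()] object with row-named scores.
#' @param design design table covering the scored animals.
#' @param set which scores to summarize: `"X"` (brain, default) or `"Y"`.
#' @return long `data.frame`: `factor`, `partner_type`, `sex`, `timepoint`,
#'   `mean`, `sd`, `n`; empty cells give `NA` with a warning.
#' @export
group_cc_scores <- function(fit, design, set = c("X", "Y")) {
  set <- match.arg(set)
  scores <- if (set == "X") fit$xscores else fit$yscores
  design <- design[match(rownames(scores), design$animal_id), , drop = FALSE]
  if (anyNA(design$animal_id)) stop("design does not cover all scored animals")
  cells <- expand.grid(partner_type = c("mate", "sibling"), sex = c("F", "M"),
                       timepoint = sort(unique(design$timepoint)),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(colnames(scores), function(f) {
    res <- cells
    res$factor <- f
    res$mean <- res$sd <- NA_real_
    res$n <- 0L
    for (i in seq_len(nrow(cells))) {
      sel <- design$partner_type == cells$partner_type[i] &
        design$sex == cells$sex[i] & design$timepoint == cells$timepoint[i]
      res$n[i] <- sum(sel)
      if (res$n[i] > 0) {
        res$mean[i] <- mean(scores[sel, f])
        res$sd[i] <- sd(scores[sel, f])
      }
    }
    res
  }))
  if (any(out$n == 0)) warning("empty design cells produce NA summaries")
  out[, c("factor", "partner_type", "sex", "timepoint", "mean", "sd", "n")]
}
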