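#' Welch two-sample t test
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors, each of length >= 2 with finite variance.
#' @return named list `t`, `df`, `p`, `n1`, `n2`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       n1 = length(x), n2 = length(y))
}

#' Paired t test
#'
#' Two-sided t test on within-pair differences, `df = n - 1`. A constant
#' difference vector (zero sd) leaves the statistic undefined; it is
#' returned flagged rather than raised.
#'
#' @param x,y numeric vectors of equal length >= 2 (matched members).
#' @return named list `t`, `df`, `p`, `n`, `defined`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors differ in length")
  if (length(x) < 2) stop("need n >= 2 pairs")
  d <- x - y
  if (sd(d) == 0)
    return(list(t = NA_real_, df = length(x) - 1L, p = NA_real_,
                n = length(x), defined = FALSE))
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       n = length(x), defined = TRUE)
}

#' Batch behavioral group comparisons with FDR correction
#'
#' Runs the study's behavioral contrasts over a behavior table: Welch t
#' tests of mates vs siblings for every measure (all timepoints pooled and,
#' optionally, per timepoint) and paired t tests of female vs male mates
#' for individual measures, then adjusts the whole batch of p-values by FDR
#' (threshold q < `alpha`, study convention 0.05). Dyadic measures
#' (identical within a pair) are tested at the pair level — one value per
#' dyad — while individual measures use animal-level values; paired F-vs-M
#' tests are skipped for dyadic measures, whose members are identical by
#' construction. Only `behavior_included` animals enter. Contrasts with an
#' empty group are skipped with a warning.
#'
#' @param behavior behavior table with `animal_id` column (see
#'   [simulate_behavior()]).
#' @param design design table.
#' @param measures measure columns to test; defaults to all numeric columns.
#' @param dyadic measures to treat as dyadic; defaults to
#'   `attr(behavior, "dyadic")`.
#' @param per_timepoint also run each contrast within each timepoint.
#' @param alpha FDR threshold for the `significant` flag.
#' @param fdr `"bh"` or `"qvalue"`, passed to [fdr_adjust()].
#' @return `data.frame`: `measure`, `contrast`, `timepoint` (`NA` =
#'   pooled), `n1`, `n2`, `t`, `df`, `p`, `q`, `significant`.
#' @export
batch_behavior_tests <- function(behavior, design,
                                 measures = NULL, dyadic = NULL,
                                 per_timepoint = FALSE, alpha = 0.05,
                                 fdr = "bh") {
  if (is.null(measures))
    measures <- names(behavior)[vapply(behavior, is.numeric, TRUE)]
  if (is.null(dyadic)) dyadic <- attr(behavior, "dyadic")
  d <- design[design$behavior_included, , drop = FALSE]
  d <- d[d$animal_id %in% behavior$animal_id, , drop = FALSE]
  b <- behavior[match(d$animal_id, behavior$animal_id), , drop = FALSE]
  tps <- if (per_timepoint) c(NA, sort(unique(d$timepoint))) else NA
  rows <- list()
  add <- function(measure, contrast, tp, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, contrast = contrast, timepoint = tp,
      n1 = res$n1, n2 = res$n2, t = res$t, df = res$df, p = res$p,
      stringsAsFactors = FALSE)
  }
  for (m in measures) {
    is_dy <- m %in% dyadic
    for (tp in tps) {
      sel <- if (is.na(tp)) rep(TRUE, nrow(d)) else d$timepoint == tp
      dd <- d[sel, ]; bb <- b[sel, ]
      if (is_dy) {  # one value per dyad
        keep <- !duplicated(dd$pair_id)
        dd <- dd[keep, ]; bb <- bb[keep, ]
      }
      x <- bb[[m]][dd$partner_type == "mate"]
      y <- bb[[m]][dd$partner_type == "sibling"]
      if (length(x) < 2 || length(y) < 2) {
        warning("skipping mate-vs-sibling '", m, "' at timepoint ", tp,
                ": empty or singleton group")
      } else add(m, "mate_vs_sibling", tp, welch_t(x, y))
      if (!is_dy) {  # female vs male mates, paired within dyads
        mates <- d[sel & d$partner_type == "mate", ]
        bp <- b[sel & d$partner_type == "mate", ]
        keep <- mates$pair_id %in%
          names(which(table(mates$pair_id) == 2))
        mates <- mates[keep, ]; bp <- bp[keep, ]
        if (nrow(mates) >= 4) {
          ordp <- order(mates$pair_id, mates$sex)
          mates <- mates[ordp, ]; bp <- bp[ordp, ]
          xf <- bp[[m]][mates$sex == "F"]
          xm <- bp[[m]][mates$sex == "M"]
          res <- paired_t(xf, xm)
          res$n1 <- res$n; res$n2 <- res$n
          add(m, "female_vs_male_mates", tp, res)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  adj <- fdr_adjust(ifelse(is.na(out$p), 1, out$p), method = fdr,
                    alpha = alpha)
  out$q <- ifelse(is.na(out$p), NA, adj$q)
  out$significant <- !is.na(out$p) & adj$significant
  rownames(out) <- NULL
  out
}

#' Generalized extreme studentized deviate (Rosner) outlier test
#'
#' Detects up to `max_outliers` outliers in an approximately normal sample.
#' Iteratively, the most extreme point (largest `|x - mean| / sd`) is
#' recorded as candidate `i` with statistic `R_i` and removed; the critical
#' value is
#' `lambda_i = (n - i) * t / sqrt((n - i - 1 + t^2) * (n - i + 1))` with
#' `t = qt(1 - alpha / (2 (n - i + 1)), n - i - 1)`. The flagged outliers
#' are candidates `1..i*` where `i*` is the largest `i` with
#' `R_i > lambda_i` (the prefix rule — earlier candidates are flagged even
#' if their own `R` fell short). Used here to screen whole-brain c-Fos
#' totals for aberrant samples before analysis.
#'
#' @param values numeric vector, named by animal id if available;
#'   `length(values) >= max_outliers + 5`.
#' @param max_outliers maximum number of outliers to test for (k).
#' @param alpha significance level of each sequential test.
#' @return `data.frame` of class `"rosner_esd"` with one row per candidate:
#'   `i`, `id`, `value`, `R`, `lambda`, `flagged`.
#' @export
rosner_esd <- function(values, max_outliers = 5, alpha = 0.05) {
  stopifnot(max_outliers >= 1)
  n <- length(values)
  if (n < max_outliers + 5)
    stop("need at least max_outliers + 5 observations, have ", n)
  ids <- if (is.null(names(values))) as.character(seq_len(n)) else names(values)
  if (sd(values) == 0) {
    warning("constant input: no outliers detectable")
    return(structure(data.frame(i = integer(0), id = character(0),
                                value = numeric(0), R = numeric(0),
                                lambda = numeric(0), flagged = logical(0)),
                     class = c("rosner_esd", "data.frame")))
  }
  x <- values; xi <- ids
  out <- data.frame(i = seq_len(max_outliers), id = NA_character_,
                    value = NA_real_, R = NA_real_, lambda = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(max_outliers)) {
    ni <- n - i + 1L               # sample size at step i
    s <- sd(x)
    if (s == 0) { out <- out[seq_len(i - 1L), , drop = FALSE]; break }
    dev <- abs(x - mean(x))
    j <- which.max(dev)
    out$id[i] <- xi[j]; out$value[i] <- x[j]
    out$R[i] <- dev[j] / s
    tcrit <- qt(1 - alpha / (2 * ni), ni - 2)
    out$lambda[i] <- (ni - 1) * tcrit / sqrt((ni - 2 + tcrit^2) * ni)
    x <- x[-j]; xi <- xi[-j]
  }
  istar <- which(out$R > out$lambda)
  if (length(istar)) out$flagged[seq_len(max(istar))] <- TRUE
  class(out) <- c("rosner_esd", "data.frame")
  out
}
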