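#' Paired female/male values for mated (or sibling) pairs
#'
#' Assembles one row per retained pair with the two members' values of a
#' per-animal measure, for correlation across pairs. For mate pairs the
#' female's value comes first; sibling pairs (same-sex) are ordered by
#' animal id, which leaves the correlation unchanged. Pairs with either
#' member missing from `values` or flagged `ieg_included = FALSE` are
#' dropped and reported via the `"dropped"` attribute.
#'
#' @param values named numeric vector keyed by animal id (e.g. one region's
#'   counts, or CC1 scores).
#' @param design design table.
#' @param timepoints integer subset of timepoints to retain (e.g. `2:3` for
#'   the bond-formation window, `4` for after bonding); must be non-empty.
#' @param pair_type `"mate"` (default) or `"sibling"`.
#' @return `data.frame` with `pair_id`, `timepoint`, `member1`, `member2`
#'   (female first for mate pairs).
#' @export
pair_vectors <- function(values, design, timepoints = 2:3,
                         pair_type = c("mate", "sibling")) {
  pair_type <- match.arg(pair_type)
  if (!length(timepoints)) stop("timepoints subset is empty")
  d <- design[design$partner_type == pair_type &
                design$timepoint %in% timepoints, , drop = FALSE]
  pairs <- unique(d$pair_id)
  rows <- list(); dropped <- character(0)
  for (p in pairs) {
    mem <- d[d$pair_id == p, , drop = FALSE]
    ok <- nrow(mem) == 2L && all(mem$ieg_included) &&
      all(mem$animal_id %in% names(values))
    if (!ok) { dropped <- c(dropped, p); next }
    ord <- if (pair_type == "mate") order(mem$sex) else order(mem$animal_id)
    mem <- mem[ord, ]
    rows[[p]] <- data.frame(pair_id = p, timepoint = mem$timepoint[1],
                            member1 = unname(values[mem$animal_id[1]]),
                            member2 = unname(values[mem$animal_id[2]]),
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(0), timepoint = integer(0),
               member1 = numeric(0), member2 = numeric(0))
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Pearson correlation with a t test
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return named list `r`, `df` (`n - 2`), `p` (two-sided), `n`; zero
#'   variance yields `NA` values with `defined = FALSE`.
#' @export
pearson_with_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, df = length(x) - 2L, p = NA_real_,
                n = length(x), defined = FALSE))
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value,
       n = length(x), defined = TRUE)
}

#' Partial Pearson correlation controlling one covariate
#'
#' First-order partial correlation
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' with a two-sided t test on `df = n - 3`. Used to ask whether within-pair
#' brain coordination survives once a shared behavioral driver (e.g.
#' ejaculation count) is controlled.
#'
#' @param x,y,z numeric vectors of equal length >= 4.
#' @return named list `r` (partial), `df`, `p`, `n`, `defined`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, n >= 4)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  if (anyNA(c(rxy, rxz, ryz)) || abs(rxz) >= 1 || abs(ryz) >= 1)
    return(list(r = NA_real_, df = n - 3L, p = NA_real_, n = n,
                defined = FALSE))
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- min(1, max(-1, r))
  df <- n - 3L
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * pt(-abs(tstat), df), n = n, defined = TRUE)
}

#' Within-pair coordination of regional activity
#'
#' Correlates, across mated pairs, one member's activity with the other
#' member's activity — per region (`mode = "roi"`: female vs male in the
#' same region) or across all region pairs (`mode = "cross"`: female's
#' region a vs male's region b). With `control` (a pair-level behavior such
#' as ejaculation count, keyed by pair id), partial correlations are
#' computed instead. Entries exceeding `threshold` form the coordination
#' edge list (the study drew its bonded-pair network at r > 0.75).
#'
#' @param counts animals-by-regions count matrix.
#' @param design design table.
#' @param timepoints timepoint subset defining the analysis window.
#' @param control optional named pair-level vector (by `pair_id`).
#' @param threshold edge threshold on the (partial) correlation.
#' @param mode `"roi"` or `"cross"`.
#' @param pair_type passed to [pair_vectors()].
#' @return list of class `"coordination"`: `r` (named vector in `"roi"`
#'   mode; regions-by-regions matrix, rows = member 1 / female, in
#'   `"cross"` mode), `edges` (`data.frame` of supra-threshold entries),
#'   `n_pairs`, `threshold`, `control` (name or `NA`).
#' @export
coordination_matrix <- function(counts, design, timepoints = 2:3,
                                control = NULL, threshold = 0.75,
                                mode = c("cross", "roi"),
                                pair_type = "mate") {
  mode <- match.arg(mode)
  units <- colnames(counts)
  pv0 <- pair_vectors(setNames(counts[, 1], rownames(counts)), design,
                      timepoints, pair_type)
  if (nrow(pv0) < 4)
    stop("need at least 4 retained pairs, have ", nrow(pv0))
  # per-unit member matrices aligned on the retained pairs
  ids <- lapply(pv0$pair_id, function(p) {
    mem <- design[design$pair_id == p & design$timepoint %in% timepoints, ]
    ord <- if (pair_type == "mate") order(mem$sex) else order(mem$animal_id)
    mem$animal_id[ord]
  })
  m1 <- counts[vapply(ids, `[`, "", 1L), , drop = FALSE]
  m2 <- counts[vapply(ids, `[`, "", 2L), , drop = FALSE]
  zc <- if (!is.null(control)) {
    if (is.null(names(control))) stop("control must be named by pair_id")
    unname(control[pv0$pair_id])
  } else NULL
  corr1 <- function(a, b) {
    if (is.null(zc)) {
      if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
    } else partial_correlation(a, b, zc)$r
  }
  if (mode == "roi") {
    r <- setNames(vapply(units, function(u) corr1(m1[, u], m2[, u]), 0), units)
    edges <- data.frame(unit = names(r)[!is.na(r) & r > threshold],
                        stringsAsFactors = FALSE)
    edges$r <- r[edges$unit]
  } else {
    r <- matrix(NA_real_, length(units), length(units),
                dimnames = list(units, units))
    for (a in units) for (b in units) r[a, b] <- corr1(m1[, a], m2[, b])
    idx <- which(!is.na(r) & r > threshold, arr.ind = TRUE)
    edges <- data.frame(unit1 = units[idx[, 1]], unit2 = units[idx[, 2]],
                        r = r[idx], stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(r = r, edges = edges, n_pairs = nrow(pv0),
                 threshold = threshold,
                 control = if (is.null(control)) NA_character_ else
                   deparse(substitute(control))),
            class = "coordination")
}

#' @export
print.coordination <- function(x, ...) {
  cat("Within-pair coordination over", x$n_pairs, "pairs\n")
  cat("  ", nrow(x$edges), " entries exceed r > ", x$threshold, "\n", sep = "")
  invisible(x)
}
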