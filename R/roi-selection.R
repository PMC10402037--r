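#' Ancestry relation between two atlas structures
#'
#' Determines whether structure `a` is an `"ancestor"` of `b`, a
#' `"descendant"` of `b`, `"unrelated"`, or the `"same"` node, by walking
#' parent links transitively.
#'
#' @param atlas a [simulate_atlas()]-style table (columns `id`, `acronym`,
#'   `parent_id`).
#' @param a,b structure acronyms.
#' @return one of `"ancestor"`, `"descendant"`, `"unrelated"`, `"same"`.
#' @export
atlas_relation <- function(atlas, a, b) {
  ia <- match(a, atlas$acronym); ib <- match(b, atlas$acronym)
  if (is.na(ia)) stop("unknown unit: ", a)
  if (is.na(ib)) stop("unknown unit: ", b)
  if (ia == ib) return("same")
  anc <- function(i) {   # ids of all strict ancestors of node at row i
    out <- integer(0)
    p <- atlas$parent_id[i]
    while (!is.na(p)) {
      out <- c(out, p)
      p <- atlas$parent_id[match(p, atlas$id)]
    }
    out
  }
  if (atlas$id[ia] %in% anc(ib)) return("ancestor")
  if (atlas$id[ib] %in% anc(ia)) return("descendant")
  "unrelated"
}

node_depths <- function(atlas) {
  depth <- rep(NA_integer_, nrow(atlas))
  for (i in seq_len(nrow(atlas))) {
    d <- 0L
    p <- atlas$parent_id[i]
    while (!is.na(p)) {
      d <- d + 1L
      p <- atlas$parent_id[match(p, atlas$id)]
    }
    depth[i] <- d
  }
  depth
}

#' Reduce significant regions to an anatomically exclusive set
#'
#' When significant regions overlap anatomically (one is an ancestor of the
#' other in the atlas hierarchy), the one with the higher ANOVA F statistic
#' is kept, iteratively: units are visited in decreasing F order and
#' accepted only if unrelated to every already-accepted unit. Because a
#' substructure usually carries a sharper signal than the parent that
#' contains it, this tends to retain smaller, more localized regions over
#' large composite ones. Ties on F are broken in favor of the deeper (more
#' localized) node, then by acronym.
#'
#' @param atlas a [simulate_atlas()]-style table.
#' @param units character vector of significant unit acronyms (no
#'   duplicates).
#' @param F numeric F statistics, parallel to `units`.
#' @return object of class `"roi_selection"`: a `data.frame` with `unit`,
#'   `F`, `chosen`, and `displaced_by` (the accepted relative that excluded
#'   a rejected unit), ordered by decreasing F.
#' @export
select_exclusive <- function(atlas, units, F) {
  stopifnot(length(units) == length(F), all(is.finite(F)))
  if (anyDuplicated(units)) stop("duplicate unit labels")
  missing <- setdiff(units, atlas$acronym)
  if (length(missing)) stop("units not in atlas: ", paste(missing, collapse = ", "))
  depth <- node_depths(atlas)[match(units, atlas$acronym)]
  ord <- order(-F, -depth, units)
  chosen <- character(0)
  displaced_by <- setNames(rep(NA_character_, length(units)), units)
  keep <- setNames(logical(length(units)), units)
  for (i in ord) {
    u <- units[i]
    rel <- vapply(chosen, function(cu) atlas_relation(atlas, u, cu), "")
    conflict <- rel %in% c("ancestor", "descendant")
    if (any(conflict)) {
      displaced_by[u] <- chosen[which(conflict)[1L]]
    } else {
      chosen <- c(chosen, u)
      keep[u] <- TRUE
    }
  }
  out <- data.frame(unit = units[ord], F = F[ord], chosen = keep[units[ord]],
                    displaced_by = displaced_by[units[ord]],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("roi_selection", "data.frame")
  out
}
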