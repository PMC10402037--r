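#' Z-score each unit across animals
#'
#' Centers and scales every column (unit) of a count matrix to mean 0, sd 1
#' across animals. Zero-variance units cannot be scaled and are dropped with
#' a warning. The per-unit centers and scales are kept as attributes so the
#' transform can be inverted.
#'
#' @param counts animals-by-units numeric matrix (>= 2 rows).
#' @return scaled matrix with attributes `"center"` and `"scale"`.
#' @export
zscore_units <- function(counts) {
  stopifnot(nrow(counts) >= 2)
  sds <- apply(counts, 2, sd)
  drop <- sds == 0
  if (any(drop)) {
    warning("dropping zero-variance units: ",
            paste(colnames(counts)[drop], collapse = ", "))
    counts <- counts[, !drop, drop = FALSE]
  }
  out <- scale(counts)
  structure(out[, , drop = FALSE], center = attr(out, "scaled:center"),
            scale = attr(out, "scaled:scale"))
}

#' Euclidean distances between units
#'
#' Pairwise Euclidean distance between unit profiles (columns) across
#' animals; the input is usually [zscore_units()] output so that high-count
#' regions do not dominate.
#'
#' @param scaled animals-by-units matrix with >= 2 units.
#' @return a `dist` object over units.
#' @export
unit_distance <- function(scaled) {
  stopifnot(ncol(scaled) >= 2)
  dist(t(scaled))
}

#' Ward (D2) hierarchical clustering of units
#'
#' Agglomerative clustering with the ward.D2 criterion (Lance--Williams
#' update on squared distances, merge heights reported on the distance
#' scale). Ties are broken by the implementation's stable index order, so
#' the tree is deterministic.
#'
#' @param d a `dist` object (e.g. from [unit_distance()]) over >= 2 units.
#' @return an `hclust` tree.
#' @export
ward_linkage <- function(d) {
  if (attr(d, "Size") < 2) stop("need at least 2 units to cluster")
  hclust(d, method = "ward.D2")
}

#' Cut a linkage tree into k clusters
#'
#' @param tree an `hclust` tree from [ward_linkage()].
#' @param k number of clusters, between 1 and the number of leaves; the
#'   study cut its tree of 68 regions into 8 groups.
#' @return named integer vector unit -> cluster label in `1..k`; every label
#'   is non-empty.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  cutree(tree, k = k)
}

#' Pairwise Pearson correlations between units
#'
#' @param counts animals-by-units matrix with >= 3 animals. Zero-variance
#'   units yield `NA` correlations, reported with a warning.
#' @return units-by-units correlation matrix.
#' @export
unit_correlations <- function(counts) {
  stopifnot(nrow(counts) >= 3)
  sds <- apply(counts, 2, sd)
  if (any(sds == 0))
    warning("zero-variance units have undefined correlations: ",
            paste(colnames(counts)[sds == 0], collapse = ", "))
  suppressWarnings(cor(counts))
}

#' Non-metric multidimensional scaling of unit distances
#'
#' Kruskal's non-metric MDS (isotonic regression on dissimilarity ranks),
#' initialized from the classical (Torgerson) solution, as a low-dimensional
#' map of similarity between units. Stress is Kruskal's stress-1 on the
#' 0--1 scale. Because the initialization is deterministic, so is the
#' embedding; `seed` is accepted for interface stability.
#'
#' @param d a `dist` object over units.
#' @param dims embedding dimension (>= 1), default 2.
#' @param seed ignored (deterministic initialization); kept so pipeline
#'   configs can treat every stage uniformly.
#' @param maxit maximum isotonic/gradient iterations.
#' @return list of class `"mds_embed"`: `points` (units x dims), `stress`
#'   (in `[0, 1]`), `converged`.
#' @export
mds_embed <- function(d, dims = 2, seed = NULL, maxit = 100) {
  stopifnot(dims >= 1)
  n <- attr(d, "Size")
  if (n <= dims + 1) stop("need more than dims + 1 units")
  dv <- as.vector(d)
  if (any(dv <= 0)) {
    # isoMDS rejects zero dissimilarities between distinct objects
    d[d <= 0] <- min(dv[dv > 0], 1e-8) / 2
  }
  init <- cmdscale(d, k = dims)
  if (ncol(init) < dims)
    init <- cbind(init, matrix(0, n, dims - ncol(init)))
  fit <- MASS::isoMDS(d, y = init, k = dims, maxit = maxit, trace = FALSE)
  structure(list(points = fit$points, stress = fit$stress / 100,
                 converged = TRUE), class = "mds_embed")
}

#' Scaled cluster activity time courses by experimental group
#'
#' Sums counts over the units of each cluster per animal, z-scores the
#' totals across animals, and averages within each partner-type x sex x
#' timepoint cell — the scaled group time course of each cluster's activity.
#'
#' @param counts animals-by-units matrix (IEG-included animals).
#' @param assignment named unit -> cluster vector from [cut_clusters()].
#' @param design design table covering the count rows.
#' @return long `data.frame`: `cluster`, `partner_type`, `sex`, `timepoint`,
#'   `mean` (scaled cluster activity), `n`. Empty cells give `NA` with a
#'   warning.
#' @export
cluster_time_course <- function(counts, assignment, design) {
  stopifnot(all(names(assignment) %in% colnames(counts)))
  design <- design[design$animal_id %in% rownames(counts), , drop = FALSE]
  counts <- counts[design$animal_id, , drop = FALSE]
  ks <- sort(unique(assignment))
  totals <- vapply(ks, function(k)
    rowSums(counts[, names(assignment)[assignment == k], drop = FALSE]),
    numeric(nrow(counts)))
  z <- scale(totals)
  cells <- expand.grid(partner_type = c("mate", "sibling"), sex = c("F", "M"),
                       timepoint = sort(unique(design$timepoint)),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(ks, function(k) {
    res <- cells
    res$cluster <- k
    res$mean <- NA_real_
    res$n <- 0L
    for (i in seq_len(nrow(cells))) {
      sel <- design$partner_type == cells$partner_type[i] &
        design$sex == cells$sex[i] & design$timepoint == cells$timepoint[i]
      res$n[i] <- sum(sel)
      if (res$n[i] > 0) res$mean[i] <- mean(z[sel, match(k, ks)])
    }
    res
  }))
  if (any(out$n == 0)) warning("empty design cells produce NA means")
  out[, c("cluster", "partner_type", "sex", "timepoint", "mean", "n")]
}

#' Map analysis units onto connectome labels
#'
#' A chosen region absent from the connectivity matrix (typically a
#' substructure finer than the connectome's parcellation) is represented by
#' its nearest ancestor that is present, e.g. BST standing in for BSTpr.
#' Units with no ancestor in the matrix are dropped and reported.
#'
#' @param units character vector of unit acronyms.
#' @param conn_labels row/column labels of the connectivity matrix.
#' @param atlas atlas hierarchy containing all `units`.
#' @return list with `map` (named vector unit -> connectome label) and
#'   `unresolved` (units that could not be mapped; excluded with a warning).
#' @export
map_to_connectome <- function(units, conn_labels, atlas) {
  missing <- setdiff(units, atlas$acronym)
  if (length(missing)) stop("units not in atlas: ", paste(missing, collapse = ", "))
  map <- setNames(rep(NA_character_, length(units)), units)
  for (u in units) {
    cur <- u
    repeat {
      if (cur %in% conn_labels) { map[u] <- cur; break }
      p <- atlas$parent_id[match(cur, atlas$acronym)]
      if (is.na(p)) break
      cur <- atlas$acronym[match(p, atlas$id)]
    }
  }
  unresolved <- names(map)[is.na(map)]
  if (length(unresolved))
    warning("units with no ancestor in the connectome, excluded: ",
            paste(unresolved, collapse = ", "))
  list(map = map[!is.na(map)], unresolved = unresolved)
}

#' Mean within-cluster connection density
#'
#' For each cluster, averages the normalized connection densities between
#' its member regions in both directions, excluding the matrix diagonal
#' (self-connections) to emphasize between-region connectivity; the overall
#' value is the unweighted mean of the per-cluster densities. Units mapping
#' to the same connectome label are collapsed; clusters left with fewer
#' than two distinct labels are skipped with a warning.
#'
#' @param conn square connectivity matrix with matching row/column labels.
#' @param assignment named unit -> cluster vector; unit names must be (or
#'   have been mapped to, see [map_to_connectome()]) `conn` labels.
#' @return list with `per_cluster` (named numeric) and `overall`.
#' @export
connectivity_density <- function(conn, assignment) {
  stopifnot(identical(rownames(conn), colnames(conn)))
  ks <- sort(unique(assignment))
  per <- setNames(rep(NA_real_, length(ks)), ks)
  for (k in ks) {
    members <- intersect(unique(names(assignment)[assignment == k]),
                         rownames(conn))
    if (length(members) < 2) next
    sub <- conn[members, members, drop = FALSE]
    per[as.character(k)] <- mean(sub[row(sub) != col(sub)])
  }
  if (anyNA(per))
    warning("clusters with < 2 resolvable members skipped: ",
            paste(names(per)[is.na(per)], collapse = ", "))
  list(per_cluster = per, overall = mean(per, na.rm = TRUE))
}

#' Permutation test of cluster connection density
#'
#' Tests whether the observed mean within-cluster connection density
#' exceeds chance by randomly shuffling the rows (origin regions) of the
#' connectivity matrix — row contents move wholesale while column labels
#' stay fixed — recomputing the overall density each time (diagonal cells
#' excluded after shuffling). The p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`; at 10,000 permutations a
#' density exceeding every null draw reports the floor 0.0001.
#'
#' @param conn square connectivity matrix.
#' @param assignment named unit -> cluster vector (see
#'   [connectivity_density()]); pass a subset to restrict the test to, e.g.,
#'   the major clusters.
#' @param n_perm number of row shuffles (study: 10,000).
#' @param seed integer seed.
#' @return list of class `"connectivity_test"`: `observed`, `p`, `n_perm`,
#'   `null` (the permuted densities), `per_cluster`.
#' @export
connectivity_permutation_test <- function(conn, assignment, n_perm = 10000,
                                          seed = 1) {
  stopifnot(n_perm >= 1)
  obs <- connectivity_density(conn, assignment)
  if (max(conn) == min(conn)) warning("constant connectivity matrix; p = 1")
  set.seed(seed)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    m <- conn[sample.int(nrow(conn)), , drop = FALSE]
    dimnames(m) <- dimnames(conn)
    null[b] <- suppressWarnings(connectivity_density(m, assignment)$overall)
  }
  p <- (1 + sum(null >= obs$overall)) / (1 + n_perm)
  structure(list(observed = obs$overall, p = p, n_perm = n_perm, null = null,
                 per_cluster = obs$per_cluster),
            class = "connectivity_test")
}

#' @export
print.connectivity_test <- function(x, ...) {
  cat("Cluster connectivity permutation test\n")
  cat(sprintf("  observed mean density = %.4g, p = %.4f (%d row shuffles)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}
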