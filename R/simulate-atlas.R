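#' Simulate a hierarchical brain atlas
#'
#' Generates a structure hierarchy in the style of the Allen Reference Atlas
#' structure graph: a single root, internal grouping structures, and
#' `n_leaves` leaf regions. The internal skeleton always contains a chain of
#' depth `depth` so the tree reaches the requested depth; additional internal
#' nodes and the leaf attachment points are drawn at random (reproducibly,
#' from `seed`).
#'
#' @param n_leaves number of leaf regions (>= 1).
#' @param depth maximum depth of a leaf below the root (>= 1); `depth = 1`
#'   places all leaves directly under the root.
#' @param seed integer seed; same seed, same atlas.
#' @return A `data.frame` of class `"bond_atlas"` with columns `id`,
#'   `acronym`, `name`, `parent_id` (`NA` for the root). Leaf acronyms are
#'   `R001`, `R002`, ...; internal nodes `G01`, `G02`, ...
#' @seealso [atlas_relation()], [select_exclusive()]
#' @export
simulate_atlas <- function(n_leaves, depth = 3, seed = 1) {
  stopifnot(n_leaves >= 1, depth >= 1)
  set.seed(seed)
  root_id <- 997L  # conventional root id in Allen-style graphs
  nodes <- data.frame(id = root_id, acronym = "root", name = "root",
                      parent_id = NA_integer_, depth = 0L,
                      stringsAsFactors = FALSE)
  next_id <- 1000L
  # internal skeleton: a guaranteed chain to depth-1, plus random extras
  if (depth > 1) {
    parent <- root_id
    for (d in seq_len(depth - 1L)) {
      nodes <- rbind(nodes, data.frame(
        id = next_id, acronym = sprintf("G%02d", next_id - 999L),
        name = sprintf("group %d", next_id - 999L),
        parent_id = parent, depth = d, stringsAsFactors = FALSE))
      parent <- next_id
      next_id <- next_id + 1L
    }
    n_extra <- max(0L, min(n_leaves %/% 3L, 3L * (depth - 1L)) - (depth - 1L))
    for (k in seq_len(n_extra)) {
      cand <- nodes[nodes$depth < depth - 1L, ]
      p <- cand$id[sample.int(nrow(cand), 1L)]
      nodes <- rbind(nodes, data.frame(
        id = next_id, acronym = sprintf("G%02d", next_id - 999L),
        name = sprintf("group %d", next_id - 999L),
        parent_id = p, depth = nodes$depth[match(p, nodes$id)] + 1L,
        stringsAsFactors = FALSE))
      next_id <- next_id + 1L
    }
  }
  internal <- nodes[nodes$depth < depth, ]
  # deepest skeleton node gets at least one leaf so the tree attains `depth`
  attach_to <- c(internal$id[which.max(internal$depth)],
                 internal$id[sample.int(nrow(internal), n_leaves - 1L,
                                        replace = TRUE)])[seq_len(n_leaves)]
  leaves <- data.frame(
    id = next_id + seq_len(n_leaves) - 1L,
    acronym = sprintf("R%03d", seq_len(n_leaves)),
    name = sprintf("region %d", seq_len(n_leaves)),
    parent_id = attach_to,
    depth = nodes$depth[match(attach_to, nodes$id)] + 1L,
    stringsAsFactors = FALSE)
  out <- rbind(nodes, leaves)
  rownames(out) <- NULL
  out$depth <- NULL
  class(out) <- c("bond_atlas", "data.frame")
  out
}

#' Simulate a structural connectivity matrix with planted cluster structure
#'
#' Builds a square origin-by-target matrix of normalized connection
#' densities in which region pairs sharing a cluster receive base density
#' `within_density`, pairs in different clusters receive `between_density`,
#' and Gaussian noise (sd `noise_sd`) is added and clipped at zero. The
#' diagonal is populated the same way but is excluded by downstream density
#' computations.
#'
#' @param units character vector of region labels (rows = columns).
#' @param clusters named vector/list mapping each unit to a cluster label.
#' @param within_density base density for same-cluster pairs.
#' @param between_density base density for different-cluster pairs; must not
#'   exceed `within_density`.
#' @param noise_sd standard deviation of additive noise (>= 0).
#' @param seed integer seed.
#' @return numeric matrix with `units` as row and column names, entries >= 0.
#' @seealso [connectivity_density()], [connectivity_permutation_test()]
#' @export
simulate_connectivity <- function(units, clusters, within_density = 1,
                                  between_density = 0, noise_sd = 0.01,
                                  seed = 1) {
  stopifnot(within_density >= between_density, between_density >= 0,
            noise_sd >= 0)
  cl <- unlist(clusters)[units]
  if (anyNA(cl)) stop("clusters must cover every unit")
  set.seed(seed)
  n <- length(units)
  same <- outer(cl, cl, "==")
  base <- ifelse(same, within_density, between_density)
  m <- base + matrix(rnorm(n * n, sd = noise_sd), n, n)
  m[m < 0] <- 0
  dimnames(m) <- list(units, units)
  m
}
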