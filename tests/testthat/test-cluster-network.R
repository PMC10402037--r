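test_that("z-scoring is exact, invertible, and drops degenerate units", {
  set.seed(1)
  X <- matrix(rnorm(60, 10, 3), 12, 5, dimnames = list(NULL, paste0("u", 1:5)))
  z <- zscore_units(X)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
  back <- sweep(sweep(z, 2, attr(z, "scale"), "*"), 2, attr(z, "center"), "+")
  expect_equal(unname(back[, ]), unname(X), tolerance = 1e-10)
  Xc <- cbind(X, const = 7)
  expect_warning(z2 <- zscore_units(Xc), "const")
  expect_false("const" %in% colnames(z2))
})

test_that("unit distances match a naive pairwise loop", {
  m <- matrix(c(0, 0, 3, 4), 2, 2, dimnames = list(NULL, c("u", "v")))
  expect_equal(as.matrix(unit_distance(m))["u", "v"], 5)  # 3-4-5 triangle
  set.seed(2)
  X <- matrix(rnorm(80), 8, 10, dimnames = list(NULL, paste0("u", 1:10)))
  D <- as.matrix(unit_distance(X))
  for (i in 1:10) for (j in 1:10)
    expect_equal(D[i, j], sqrt(sum((X[, i] - X[, j])^2)), tolerance = 1e-10)
  expect_equal(unname(diag(D)), rep(0, 10))
  # identical columns at zero distance
  X2 <- cbind(a = X[, 1], b = X[, 1])
  expect_equal(as.matrix(unit_distance(X2))["a", "b"], 0)
})

test_that("ward linkage matches the brute-force Lance-Williams oracle", {
  set.seed(3)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    X <- matrix(rnorm(n * 3), 3, n, dimnames = list(NULL, paste0("u", 1:n)))
    d <- dist(t(X))
    h <- ward_linkage(d)
    o <- ward_oracle(d)
    expect_equal(h$height, o$height, tolerance = 1e-8)
    expect_equal(unname(h$merge), unname(o$merge))
    expect_true(all(diff(h$height) >= -1e-10))  # monotone heights
  }
  # two-point tree merges at their distance
  d2 <- dist(t(matrix(c(0, 3), 1, 2, dimnames = list(NULL, c("a", "b")))))
  expect_equal(ward_linkage(d2)$height, 3)
  # well-separated clouds merge last, far above everything else
  set.seed(4)
  X <- cbind(matrix(rnorm(12), 3, 4), matrix(rnorm(12) + 100, 3, 4))
  colnames(X) <- paste0("u", 1:8)
  h <- ward_linkage(dist(t(X)))
  expect_gt(h$height[7], 50 * h$height[6])
})

test_that("tree cutting respects k and recovers planted blobs", {
  set.seed(5)
  centers <- c(0, 30, 60)
  X <- do.call(cbind, lapply(centers, function(cc)
    matrix(rnorm(5 * 6, cc), 5, 6)))
  colnames(X) <- paste0("u", 1:18)
  tr <- ward_linkage(dist(t(X)))
  expect_equal(unname(cut_clusters(tr, 1)), rep(1L, 18))
  expect_equal(length(unique(cut_clusters(tr, 18))), 18)
  cl <- cut_clusters(tr, 3)
  truth <- rep(1:3, each = 6)
  # agreement up to label permutation
  expect_equal(length(unique(paste(cl, truth))), 3)
  expect_error(cut_clusters(tr, 0))
  expect_error(cut_clusters(tr, 19))
})

test_that("unit correlations are exact Pearson", {
  set.seed(6)
  X <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("u", 1:5)))
  C <- unit_correlations(X)
  for (i in 1:5) for (j in 1:5) {
    num <- sum((X[, i] - mean(X[, i])) * (X[, j] - mean(X[, j])))
    den <- sqrt(sum((X[, i] - mean(X[, i]))^2) * sum((X[, j] - mean(X[, j]))^2))
    expect_equal(C[i, j], num / den, tolerance = 1e-12)
  }
  X2 <- cbind(a = X[, 1], b = X[, 1], c = -X[, 1])
  C2 <- unit_correlations(X2)
  expect_equal(C2["a", "b"], 1)
  expect_equal(C2["a", "c"], -1)
  expect_warning(unit_correlations(cbind(X, z = 0)), "zero-variance")
})

test_that("MDS embeds exact configurations and is rank-invariant", {
  set.seed(7)
  pts <- matrix(rnorm(20), 10, 2)
  rownames(pts) <- paste0("u", 1:10)
  d <- dist(pts)
  m2 <- mds_embed(d, dims = 2)
  expect_lt(m2$stress, 0.01)
  m1 <- mds_embed(d, dims = 1)
  expect_gt(m1$stress, m2$stress)
  # doubling distances leaves the (rank-based) stress unchanged
  expect_equal(mds_embed(2 * d, dims = 2)$stress, m2$stress, tolerance = 1e-6)
  # higher dims never hurt
  expect_lte(mds_embed(d, dims = 3)$stress, m2$stress + 1e-8)
})

test_that("cluster time courses center at zero and track planted effects", {
  fx <- make_fixture(n_pairs = 8, n_units = 6, effect_units = c("u01", "u02"),
                     effect_size = 1, dispersion = 1.5, seed = 23)
  fx$counts <- fx$counts  # planted on timepoints uniformly
  assign <- setNames(c(1L, 1L, 2L, 2L, 2L, 2L), fx$units)
  tc <- cluster_time_course(fx$counts, assign, fx$design)
  expect_setequal(unique(tc$cluster), 1:2)
  # z-scored totals sum to zero over animals => group means average to ~0
  w <- tapply(tc$mean * tc$n, tc$cluster, sum) / tapply(tc$n, tc$cluster, sum)
  expect_lt(max(abs(w)), 1e-10)
  # planted cluster: mates exceed siblings
  m1 <- tc[tc$cluster == 1 & tc$partner_type == "mate", "mean"]
  s1 <- tc[tc$cluster == 1 & tc$partner_type == "sibling", "mean"]
  expect_gt(mean(m1), mean(s1))
})

test_that("connectivity density matches an index-loop oracle", {
  cl <- setNames(c(1, 1, 1, 2, 2), paste0("r", 1:5))
  set.seed(8)
  conn <- matrix(runif(25), 5, 5, dimnames = list(names(cl), names(cl)))
  got <- connectivity_density(conn, cl)
  for (k in 1:2) {
    mem <- names(cl)[cl == k]
    vals <- c()
    for (a in mem) for (b in mem) if (a != b) vals <- c(vals, conn[a, b])
    expect_equal(unname(got$per_cluster[as.character(k)]), mean(vals),
                 tolerance = 1e-12)
  }
  expect_equal(got$overall, mean(got$per_cluster), tolerance = 1e-12)
  # 2-member cluster is the plain mean of its two directed entries
  expect_equal(unname(got$per_cluster["2"]),
               (conn["r4", "r5"] + conn["r5", "r4"]) / 2)
  # all-ones matrix has density 1 everywhere
  ones <- matrix(1, 5, 5, dimnames = dimnames(conn))
  expect_equal(unname(connectivity_density(ones, cl)$per_cluster), c(1, 1))
  expect_warning(connectivity_density(conn, setNames(c(1, 2, 2), paste0("r", 1:3))),
                 "skipped")
})

test_that("connectome mapping falls back to the nearest present ancestor", {
  a <- simulate_atlas(6, 3, seed = 11)
  leaves <- a$acronym[grepl("^R", a$acronym)]
  # connectome holds some leaves and some internal nodes only
  internal <- setdiff(a$acronym, c(leaves, "root"))
  conn_labels <- c(leaves[1], internal)
  got <- suppressWarnings(map_to_connectome(leaves, conn_labels, a))
  expect_identical(unname(got$map[leaves[1]]), leaves[1])  # present => identity
  for (u in names(got$map)) {
    lab <- got$map[[u]]
    expect_true(lab %in% conn_labels)
    expect_true(u == lab ||
                  atlas_relation(a, lab, u) == "ancestor")
  }
  # a leaf whose ancestors are all absent is reported unresolved
  got2 <- suppressWarnings(map_to_connectome(leaves, leaves[1], a))
  expect_true(all(setdiff(leaves, leaves[1]) %in% got2$unresolved))
})

test_that("connectivity permutation test hits the floor on planted structure", {
  cl <- setNames(rep(1:3, each = 4), sprintf("r%02d", 1:12))
  conn <- simulate_connectivity(names(cl), cl, 1, 0, noise_sd = 0.01, seed = 3)
  ct <- connectivity_permutation_test(conn, cl, n_perm = 999, seed = 1)
  expect_equal(ct$p, 1 / 1000)
  # constant off-diagonal matrix: observed equals every null value
  ones <- matrix(1, 12, 12, dimnames = dimnames(conn))
  expect_warning(ct1 <- connectivity_permutation_test(ones, cl, n_perm = 99,
                                                      seed = 1), "constant")
  expect_equal(ct1$p, 1)
})

test_that("Monte-Carlo connectivity p matches exhaustive row permutations", {
  cl <- setNames(c(1, 1, 2, 2), paste0("r", 1:4))
  set.seed(9)
  conn <- matrix(runif(16), 4, 4, dimnames = list(names(cl), names(cl)))
  perms <- expand.grid(rep(list(1:4), 4))
  perms <- perms[apply(perms, 1, function(p) all(sort(p) == 1:4)), ]
  dens <- apply(perms, 1, function(p) {
    m <- conn[unlist(p), ]
    dimnames(m) <- dimnames(conn)
    suppressWarnings(connectivity_density(m, cl)$overall)
  })
  obs <- connectivity_density(conn, cl)$overall
  p_exh <- mean(dens >= obs - 1e-12)
  ct <- connectivity_permutation_test(conn, cl, n_perm = 2000, seed = 5)
  expect_lt(abs(ct$p - p_exh), 0.05)
})

test_that("null cluster labels give uniform connectivity p-values", {
  cl0 <- setNames(rep(1:4, each = 3), sprintf("r%02d", 1:12))
  set.seed(12)
  conn <- matrix(runif(144), 12, 12,
                 dimnames = list(names(cl0), names(cl0)))
  ps <- vapply(1:200, function(b) {
    lab <- setNames(sample(cl0), names(cl0))
    connectivity_permutation_test(conn, lab, n_perm = 60, seed = b)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
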