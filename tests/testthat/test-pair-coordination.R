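test_that("pair vectors keep bookkeeping straight", {
  d <- simulate_design(12)
  v <- setNames(rnorm(nrow(d)), d$animal_id)
  pv <- pair_vectors(v, d, timepoints = 2:3)
  expect_equal(nrow(pv), 24)       # 12 mate pairs at each of 2 timepoints
  r <- pearson_with_test(pv$member1, pv$member2)
  expect_equal(r$df, 22)           # the study's df for CC1 pair correlations
  # excluding one member removes the pair
  d2 <- apply_exclusions(d, data.frame(
    animal_id = d$animal_id[d$partner_type == "mate" & d$timepoint == 2][1],
    scope = "ieg"))
  pv2 <- pair_vectors(v, d2, timepoints = 2:3)
  expect_equal(nrow(pv2), 23)
  expect_error(pair_vectors(v, d, timepoints = integer(0)), "empty")
  # mate ordering is female first
  mem <- d[d$pair_id == pv$pair_id[1], ]
  expect_equal(pv$member1[1], unname(v[mem$animal_id[mem$sex == "F"]]))
  # sibling machinery works with id ordering
  pvs <- pair_vectors(v, d, timepoints = 2:3, pair_type = "sibling")
  expect_equal(nrow(pvs), 24)
})

test_that("pearson test matches the textbook formula", {
  set.seed(71)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  got <- pearson_with_test(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r, tolerance = 1e-12)
  tstat <- r * sqrt(28 / (1 - r^2))
  expect_equal(got$p, 2 * pt(-abs(tstat), 28), tolerance = 1e-12)
  expect_equal(pearson_with_test(x, x)$r, 1)
  expect_equal(pearson_with_test(x, -x)$r, -1)
  expect_false(pearson_with_test(x, rep(1, 30))$defined)
  # symmetry
  expect_equal(pearson_with_test(y, x)$r, got$r)
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(72)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    z <- rnorm(n)
    x <- 0.7 * z + rnorm(n); y <- -0.4 * z + rnorm(n)
    got <- partial_correlation(x, y, z)
    expect_equal(got$r, partial_oracle(x, y, z), tolerance = 1e-10)
    expect_equal(got$df, n - 3)
  }
  # uncorrelated control leaves r unchanged (formula identity)
  x <- rnorm(200); y <- rnorm(200); z <- rnorm(200)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  expect_equal(partial_correlation(x, y, z)$r,
               (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
               tolerance = 1e-12)
})

test_that("controlling the shared driver abolishes the correlation", {
  set.seed(73)
  n <- 1000
  z <- rnorm(n)
  x <- z + rnorm(n); y <- z + rnorm(n)
  expect_gt(cor(x, y), 0.3)
  expect_lt(abs(partial_correlation(x, y, z)$r), 0.1)
})

test_that("coordination recovers planted coupled regions and only those", {
  res <- lapply(1:20, function(r) {
    d <- simulate_design(12)
    coupled <- c("u01", "u02", "u03")
    # block and time effects are shared within a pair and would add
    # coordination on every unit; switch them off to isolate the coupling
    cfg <- sim_config(dispersion = 1.5, coupling_units = coupled, gamma = 0.4,
                      effect_units = coupled, effect_size = 0.7,
                      block_sd = 0, beta_t1 = 0, beta_t2 = 0)
    y <- simulate_counts(d, sprintf("u%02d", 1:8), cfg, seed = 900 + r)
    cm <- coordination_matrix(y, d, timepoints = 2:3, mode = "cross",
                              threshold = 0.75)
    list(edges = cm$edges, coupled = coupled)
  })
  n_true <- vapply(res, function(x)
    sum(x$edges$unit1 %in% x$coupled & x$edges$unit2 %in% x$coupled), 0)
  n_false <- vapply(res, function(x)
    sum(!(x$edges$unit1 %in% x$coupled) | !(x$edges$unit2 %in% x$coupled)), 0)
  expect_gt(mean(n_true), 0)                 # edges found within the planted set
  expect_equal(sum(n_false), 0)              # none among uncoupled regions
  expect_true(all(n_true >= 1))
})

test_that("controlling the true latent dissolves the coordination network", {
  d <- simulate_design(12)
  coupled <- c("u01", "u02")
  cfg <- sim_config(dispersion = 1.5, coupling_units = coupled, gamma = 0.4,
                    block_sd = 0, beta_t1 = 0, beta_t2 = 0)
  y <- simulate_counts(d, sprintf("u%02d", 1:4), cfg, seed = 74)
  # the latent on the activity scale: coupled means are linear in z^gamma,
  # so partialling it out is the exact analogue of controlling the driver
  z <- attr(y, "latent")^0.4
  cm0 <- coordination_matrix(y, d, timepoints = 2:3, mode = "roi",
                             threshold = 0.75)
  cmz <- coordination_matrix(y, d, timepoints = 2:3, control = z,
                             mode = "roi", threshold = 0.75)
  expect_gt(nrow(cm0$edges), 0)
  expect_equal(nrow(cmz$edges), 0)
  n_pairs <- cm0$n_pairs
  expect_lt(mean(abs(cmz$r[coupled])), 2 / sqrt(n_pairs))
})

test_that("coordination correlations rise monotonically with coupling", {
  gammas <- c(0.05, 0.1, 0.2, 0.3, 0.45)
  trend <- vapply(1:20, function(r) {
    rs <- vapply(gammas, function(g) {
      d <- simulate_design(12)
      cfg <- sim_config(dispersion = 1.5, coupling_units = "u01", gamma = g,
                        block_sd = 0, beta_t1 = 0, beta_t2 = 0)
      y <- simulate_counts(d, c("u01", "u02"), cfg, seed = 800 + r)
      cm <- coordination_matrix(y, d, timepoints = 1:4, mode = "roi",
                                threshold = 1.01)
      cm$r[["u01"]]
    }, 0)
    cor(rs, gammas, method = "spearman")
  }, 0)
  expect_gt(mean(trend), 0.9)
})

test_that("coordination guards its preconditions", {
  d <- simulate_design(12)
  y <- simulate_counts(d, c("u01", "u02"), sim_config(dispersion = 1.5),
                       seed = 75)
  cm <- coordination_matrix(y, d, timepoints = 2:3, threshold = 1.01)
  expect_equal(nrow(cm$edges), 0)            # nothing exceeds r > 1
  d4 <- simulate_design(1)
  y4 <- simulate_counts(d4, c("u01", "u02"), sim_config(dispersion = 1.5),
                        seed = 76)
  expect_error(coordination_matrix(y4, d4, timepoints = 2), "4 retained pairs")
})
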