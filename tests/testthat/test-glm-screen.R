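test_that("design matrices have the documented columns and spans", {
  d <- simulate_design(3)
  X0 <- design_matrix(d, "null")
  X1 <- design_matrix(d, "bonding")
  X2 <- design_matrix(d, "reduced_sex")
  expect_equal(ncol(X0), 5)   # intercept, sex, t1, t2, block
  expect_equal(ncol(X1), 9)   # + partner, partner:sex, partner:t1, partner:t2
  expect_equal(ncol(X2), 8)   # bonding minus partner:sex
  expect_true(all(colnames(X0) %in% colnames(X1)))
  # orthogonal time polynomials span the same space as raw {T, T^2}
  raw <- cbind(1, d$timepoint, d$timepoint^2)
  proj <- raw - X0[, c("(Intercept)", "t1", "t2")] %*%
    solve(crossprod(X0[, c("(Intercept)", "t1", "t2")]),
          crossprod(X0[, c("(Intercept)", "t1", "t2")], raw))
  expect_lt(max(abs(proj)), 1e-8)
  d1 <- d; d1$partner_type <- "mate"
  expect_error(design_matrix(d1, "bonding"), "partner_type")
})

test_that("quasi-Poisson fits match a hand-rolled IRLS oracle", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(8:40, 1)
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    y <- rpois(n, exp(1.5 + 0.3 * X[, 2]))
    if (all(y == 0)) next
    fit <- fit_quasipoisson(X, y)
    ora <- irls_oracle(X, y)
    expect_equal(unname(fit$coefficients), unname(ora$coefficients),
                 tolerance = 1e-6)
    expect_equal(fit$deviance, ora$deviance, tolerance = 1e-6)
    expect_equal(fit$pearson_dispersion, ora$phi, tolerance = 1e-6)
  }
})

test_that("constant response gives a saturated intercept fit", {
  X <- matrix(1, 8, 1)
  fit <- fit_quasipoisson(X, rep(5, 8))
  expect_equal(unname(fit$coefficients), log(5), tolerance = 1e-8)
  expect_equal(fit$deviance, 0, tolerance = 1e-8)
  z <- fit_quasipoisson(X, rep(0, 8))
  expect_true(z$degenerate)
  expect_equal(z$deviance, 0)
})

test_that("dispersion estimate is near 1 for Poisson data", {
  set.seed(7)
  n <- 1000
  X <- cbind(1, rnorm(n))
  y <- rpois(n, exp(2 + 0.2 * X[, 2]))
  expect_lt(abs(fit_quasipoisson(X, y)$pearson_dispersion - 1), 0.15)
})

test_that("nested F behaves at its boundaries and under the null", {
  d <- simulate_design(6)
  X0 <- design_matrix(d, "null")
  X1 <- design_matrix(d, "bonding")
  set.seed(21)
  y <- rpois(nrow(d), 40)
  f0 <- fit_quasipoisson(X0, y)
  f1 <- fit_quasipoisson(X1, y)
  expect_error(anova_f(f0, f0), "collinear")
  Fv <- anova_f(f0, f1)
  expect_gte(Fv["F"], 0)
  expect_equal(unname(Fv["df1"]), 4)
  # under the null the F statistic has mean about 1
  Fs <- replicate(300, {
    yy <- rpois(nrow(d), 40)
    anova_f(fit_quasipoisson(X0, yy), fit_quasipoisson(X1, yy))["F"]
  })
  expect_lt(abs(mean(Fs) - 1), 0.25)
  # same fit twice means zero deviance drop
  expect_equal(unname(anova_f(f1, list(rank = f1$rank + 1, deviance = f1$deviance,
                                       pearson_dispersion = f1$pearson_dispersion,
                                       df_residual = f1$df_residual - 1,
                                       degenerate = FALSE))["F"]), 0)
})

test_that("F is invariant to the time-polynomial basis", {
  d <- simulate_design(4)
  set.seed(3)
  y <- rpois(nrow(d), exp(3 + 0.3 * (d$partner_type == "mate")))
  X0 <- design_matrix(d, "null"); X1 <- design_matrix(d, "bonding")
  raw0 <- X0; raw0[, "t1"] <- d$timepoint; raw0[, "t2"] <- d$timepoint^2
  raw1 <- X1
  raw1[, "t1"] <- d$timepoint; raw1[, "t2"] <- d$timepoint^2
  partner <- as.numeric(d$partner_type == "mate")
  raw1[, "partner:t1"] <- partner * d$timepoint
  raw1[, "partner:t2"] <- partner * d$timepoint^2
  F_orth <- anova_f(fit_quasipoisson(X0, y), fit_quasipoisson(X1, y))
  F_raw <- anova_f(fit_quasipoisson(raw0, y), fit_quasipoisson(raw1, y))
  expect_equal(unname(F_orth["F"]), unname(F_raw["F"]), tolerance = 1e-8)
})

test_that("planted effects clear the permutation null; screen is deterministic", {
  fx <- make_fixture(n_pairs = 12, n_units = 4, effect_units = "u01",
                     effect_size = 1, dispersion = 2)
  sc <- fos_screen(fx$counts, fx$design, n_perm = 99, seed = 5)
  tab <- sc$table
  expect_equal(tab$unit[tab$F == max(tab$F)], "u01")
  expect_equal(tab$p[tab$unit == "u01"], 1 / 100)
  expect_gt(tab$F[tab$unit == "u01"], quantile(sc$perm_F[, "u01"], 0.95))
  expect_equal(tab$direction[tab$unit == "u01"], 1)
  sc2 <- fos_screen(fx$counts, fx$design, n_perm = 99, seed = 5)
  expect_identical(sc$table, sc2$table)
  sc3 <- fos_screen(fx$counts, fx$design, n_perm = 99, seed = 6)
  expect_false(identical(sc$perm_F, sc3$perm_F))
})

test_that("Monte-Carlo p matches the exhaustive stratified relabeling oracle", {
  fx <- make_fixture(n_pairs = 1, n_units = 2, effect_units = "u01",
                     effect_size = 0.8, dispersion = 1.5, seed = 13)
  d <- fx$design
  # exhaustive: every stratified relabeling of partner type (2^4 here)
  relabs <- enumerate_relabelings(d)
  expect_length(relabs, 16)
  X0 <- design_matrix(d, "null")
  obs <- anova_f(fit_quasipoisson(X0, fx$counts[, "u01"]),
                 fit_quasipoisson(design_matrix(d, "bonding"),
                                  fx$counts[, "u01"]))["F"]
  Fs <- vapply(relabs, function(dd)
    anova_f(fit_quasipoisson(X0, fx$counts[, "u01"]),
            fit_quasipoisson(design_matrix(dd, "bonding"),
                             fx$counts[, "u01"]))["F"], 0)
  p_exh <- mean(Fs >= obs - 1e-12)
  sc <- fos_screen(fx$counts, d, n_perm = 2000, seed = 3)
  expect_lt(abs(sc$table$p[sc$table$unit == "u01"] - p_exh), 0.02)
})

test_that("row-shuffling scheme and sex-interaction contrast run and calibrate", {
  fx <- make_fixture(n_pairs = 6, n_units = 3, dispersion = 1.5, seed = 17)
  scr <- fos_screen(fx$counts, fx$design, n_perm = 60, seed = 2,
                    scheme = "row")
  expect_true(all(scr$table$p > 0.05))  # null data, no signal
  scs <- fos_screen(fx$counts, fx$design, contrast = "sex_interaction",
                    n_perm = 60, seed = 2)
  expect_equal(unique(scs$table$df1), 1)
  expect_true(all(scs$table$p >= 1 / 61 & scs$table$p <= 1))
})

test_that("fdr adjustment matches hand-stepped BH and keeps order", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  expect_equal(fdr_adjust(0.03)$q, 0.03)                 # m = 1
  expect_equal(fdr_adjust(rep(0.2, 5))$q, rep(0.2, 5))   # ties stay ties
  expect_identical(fdr_adjust(numeric(0))$q, numeric(0))
  set.seed(31)
  for (i in 1:100) {
    p <- runif(sample(2:50, 1))
    q <- fdr_adjust(p)$q
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # order-preserving
  }
  # Storey option never exceeds BH and flags against alpha
  p <- c(runif(50), runif(10, 0, 0.001))
  a <- fdr_adjust(p, "qvalue", alpha = 0.1)
  expect_true(all(a$q <= fdr_adjust(p)$q + 1e-12))
  expect_identical(a$significant, a$q < 0.1)
})

test_that("screen warns on tiny n_perm and rejects mismatched rows", {
  fx <- make_fixture(n_pairs = 1, n_units = 2)
  expect_warning(fos_screen(fx$counts, fx$design, n_perm = 5, seed = 1),
                 "resolution")
  bad <- fx$counts[-1, , drop = FALSE]
  expect_error(fos_screen(bad, fx$design, n_perm = 25, seed = 1), "lack rows")
})
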