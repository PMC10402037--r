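# Independent brute-force oracles used to cross-check the implementation.
# Each is written from first principles and shares no code with R/.

# Poisson/quasi-Poisson IRLS, hand-rolled from the normal equations.
irls_oracle <- function(X, y, tol = 1e-10, maxit = 200) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) + 0.1)
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    w <- mu                       # Poisson working weights under log link
    zz <- eta + (y - mu) / mu     # working response
    beta <- solve(crossprod(X, w * X), crossprod(X, w * zz))
    mu <- exp(drop(X %*% beta))
    dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    if (abs(dev - dev_old) / (abs(dev) + 0.1) < tol) break
    dev_old <- dev
  }
  list(coefficients = drop(beta), deviance = dev,
       phi = sum((y - mu)^2 / mu) / (length(y) - ncol(X)))
}

# O(n^3) ward.D2 agglomeration via the Lance-Williams recurrence on
# squared distances, heights reported on the distance scale.
ward_oracle <- function(d) {
  n <- attr(d, "Size")
  D2 <- as.matrix(d)^2
  sizes <- rep(1, n)
  active <- seq_len(n)
  id <- -seq_len(n)              # hclust convention: negatives are leaves
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (m in seq_len(n - 1)) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      a <- active[i]; b <- active[j]
      if (D2[a, b] < bd) { bd <- D2[a, b]; best <- c(b, a) }
    }
    a <- best[1]; b <- best[2]
    pair <- c(id[a], id[b])
    # hclust row convention: singletons (negative, by index) before
    # clusters (positive, ascending)
    merges[m, ] <- pair[order(pair >= 0, abs(pair))]
    heights[m] <- sqrt(bd)
    na <- sizes[a]; nb <- sizes[b]
    for (k in active) {
      if (k == a || k == b) next
      nk <- sizes[k]
      D2[a, k] <- D2[k, a] <-
        ((na + nk) * D2[a, k] + (nb + nk) * D2[b, k] - nk * D2[a, b]) /
        (na + nb + nk)
    }
    sizes[a] <- na + nb
    id[a] <- m
    active <- setdiff(active, b)
  }
  list(merge = merges, height = heights)
}

# Step-by-step simulation of the iterative exclusive-selection rule:
# repeatedly take the top-F remaining unit, discard its relatives.
select_oracle <- function(atlas, units, F) {
  anc_ids <- function(acr) {
    out <- integer(0)
    p <- atlas$parent_id[match(acr, atlas$acronym)]
    while (!is.na(p)) { out <- c(out, p); p <- atlas$parent_id[match(p, atlas$id)] }
    out
  }
  depth <- vapply(units, function(u) length(anc_ids(u)), 0L)
  related <- function(a, b) {
    ia <- atlas$id[match(a, atlas$acronym)]
    ib <- atlas$id[match(b, atlas$acronym)]
    ia %in% anc_ids(b) || ib %in% anc_ids(a)
  }
  remaining <- order(-F, -depth, units)
  chosen <- character(0)
  while (length(remaining)) {
    u <- units[remaining[1]]
    chosen <- c(chosen, u)
    remaining <- remaining[!vapply(remaining, function(i)
      units[i] == u || related(units[i], u), TRUE)]
  }
  chosen
}

# Textbook Benjamini-Hochberg step-up, stepped by hand.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q[order(o)]
}

# Published generalized-ESD critical value at step i of n samples.
esd_lambda_oracle <- function(n, i, alpha) {
  pcrit <- 1 - alpha / (2 * (n - i + 1))
  tq <- qt(pcrit, n - i - 1)
  (n - i) * tq / sqrt((n - i - 1 + tq^2) * (n - i + 1))
}

# Partial correlation via residual-on-residual regression.
partial_oracle <- function(x, y, z) {
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  cor(rx, ry)
}

# All stratified pair-level relabelings of partner type — strata are
# timepoint x block cells, mirroring the screen's exchangeability blocks
# (used to enumerate the exact permutation distribution on tiny designs).
enumerate_relabelings <- function(design) {
  pd <- design[!duplicated(design$pair_id),
               c("pair_id", "partner_type", "timepoint", "block")]
  key <- paste(pd$timepoint, pd$block)
  per_cell <- lapply(split(pd, key), function(s) {
    n_mate <- sum(s$partner_type == "mate")
    combn(nrow(s), n_mate, simplify = FALSE)
  })
  grids <- expand.grid(lapply(per_cell, seq_along))
  cells <- names(per_cell)
  lapply(seq_len(nrow(grids)), function(g) {
    lab <- setNames(rep("sibling", nrow(pd)), pd$pair_id)
    for (cc in cells) {
      s <- pd[key == cc, ]
      idx <- per_cell[[cc]][[grids[g, cc]]]
      lab[s$pair_id[idx]] <- "mate"
    }
    d <- design
    d$partner_type <- unname(lab[d$pair_id])
    d
  })
}

# small balanced design + counts fixture used across tests
make_fixture <- function(n_pairs = 3, n_units = 4, effect_units = character(),
                         effect_size = 0, dispersion = 1.5, gamma = 0,
                         seed = 42) {
  d <- simulate_design(n_pairs)
  units <- sprintf("u%02d", seq_len(n_units))
  cfg <- sim_config(effect_units = intersect(effect_units, units),
                    effect_size = effect_size, dispersion = dispersion,
                    coupling_units = if (gamma != 0)
                      intersect(effect_units, units) else character(),
                    gamma = gamma)
  y <- simulate_counts(d, units, cfg, seed = seed)
  list(design = d, counts = y, units = units)
}
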