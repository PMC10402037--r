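#' Simulation configuration for c-Fos count generation
#'
#' Collects the generative parameters for [simulate_counts()]. Counts are
#' drawn from a gamma--Poisson (negative binomial) mixture whose variance is
#' `dispersion` times its mean, matching the mean--variance relation the
#' quasi-Poisson screen assumes. The log-scale linear predictor contains a
#' baseline, a sex effect, linear and quadratic timepoint trends (on the
#' ordinal 1--4 coding), i.i.d. normal block effects, and — on the designated
#' `effect_units` only — a partner-type (mate vs sibling) effect of size
#' `effect_size`, optionally shaped over timepoints by `effect_profile`.
#' Units listed in `coupling_units` are additionally scaled by
#' `z_p^gamma` — log-linear in the standard-normal log-latent `log(z_p)`,
#' like every other term of the log-link model — where `z_p` is a
#' log-normal(0, 1) latent shared by both members of a pair (the same
#' latent that drives mating intensity in [simulate_behavior()]), inducing
#' within-pair coordination of the coupled units.
#'
#' @param baseline log-scale intercept; default `log(100)` (about 100
#'   c-Fos+ cells per region).
#' @param beta_sex log effect of male sex; default 0.05.
#' @param beta_t1,beta_t2 linear/quadratic log trends over timepoint codes
#'   1--4 (applied to centered codes); defaults 0.05 and -0.05.
#' @param block_sd sd of i.i.d. normal log-scale block effects; default 0.1.
#' @param dispersion variance-to-mean ratio phi (>= 1; 1 = Poisson).
#' @param effect_units character vector of units carrying a planted
#'   partner-type effect.
#' @param effect_size log-scale mate-vs-sibling effect on those units.
#' @param effect_profile optional length-4 multiplier of `effect_size` per
#'   timepoint (default constant 1).
#' @param coupling_units units whose mean is modulated by the shared pair
#'   latent.
#' @param gamma coupling strength (log-scale coefficient on the latent).
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(baseline = log(100), beta_sex = 0.05,
                       beta_t1 = 0.05, beta_t2 = -0.05, block_sd = 0.1,
                       dispersion = 2, effect_units = character(),
                       effect_size = 0.7, effect_profile = rep(1, 4),
                       coupling_units = character(), gamma = 0) {
  if (dispersion < 1) stop("underdispersion unsupported: dispersion must be >= 1")
  stopifnot(length(effect_profile) == 4L)
  structure(list(baseline = baseline, beta_sex = beta_sex, beta_t1 = beta_t1,
                 beta_t2 = beta_t2, block_sd = block_sd,
                 dispersion = dispersion, effect_units = effect_units,
                 effect_size = effect_size, effect_profile = effect_profile,
                 coupling_units = coupling_units, gamma = gamma),
            class = "sim_config")
}

#' Simulate an overdispersed c-Fos count matrix with planted effects
#'
#' Draws an animals-by-units count matrix under the generative model of
#' [sim_config()]. Deterministic given `seed`. The pair-level latent values
#' `z_p` used for coupling are attached as `attr(, "latent")` (named by
#' `pair_id`) so the behavior generator can reuse them.
#'
#' @param design a [simulate_design()] table (all animals are simulated;
#'   subset downstream by inclusion flags).
#' @param units character vector of unit (region/voxel) labels.
#' @param config a [sim_config()]; its `effect_units` and `coupling_units`
#'   must be a subset of `units`.
#' @param seed integer seed.
#' @return integer matrix, animals as rows (named by `animal_id`), units as
#'   columns, with attribute `"latent"`.
#' @examples
#' d <- simulate_design(2)
#' cfg <- sim_config(effect_units = "u1", effect_size = 0.5, dispersion = 1.5)
#' y <- simulate_counts(d, c("u1", "u2"), cfg, seed = 1)
#' dim(y)
#' @export
simulate_counts <- function(design, units, config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(config$effect_units %in% units))
    stop("effect_units must be a subset of units")
  if (!all(config$coupling_units %in% units))
    stop("coupling_units must be a subset of units")
  set.seed(seed)
  n <- nrow(design)
  tp <- design$timepoint
  tc <- tp - mean(1:4)
  pairs <- unique(design$pair_id)
  z <- stats::rlnorm(length(pairs))          # shared pair latent, log-normal(0,1)
  names(z) <- pairs
  blk_eff <- rnorm(6, sd = config$block_sd)  # one log-effect per block
  eta_base <- config$baseline + config$beta_sex * (design$sex == "M") +
    config$beta_t1 * tc + config$beta_t2 * tc^2 + blk_eff[design$block]
  is_mate <- design$partner_type == "mate"
  phi <- config$dispersion
  out <- matrix(0L, n, length(units), dimnames = list(design$animal_id, units))
  for (j in seq_along(units)) {
    eta <- eta_base
    if (units[j] %in% config$effect_units)
      eta <- eta + config$effect_size * config$effect_profile[tp] * is_mate
    if (units[j] %in% config$coupling_units && config$gamma != 0)
      eta <- eta + config$gamma * log(z[design$pair_id])
    mu <- exp(eta)
    out[, j] <- if (phi == 1) rpois(n, mu) else
      rnbinom(n, size = mu / (phi - 1), mu = mu)
  }
  attr(out, "latent") <- z
  out
}
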