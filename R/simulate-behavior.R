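#' Simulate a behavior table for the cohabitation assay
#'
#' Generates per-animal and dyadic behavioral measures for the 1 h focal
#' observation window. Individual measures (velocity, net movement toward
#' partner, anogenital investigation, self-grooming) are log-normal with
#' partner-type mean shifts. Dyadic measures (mounts, intromissions,
#' ejaculations, huddling duration, ultrasonic vocalization rate) are
#' identical for both pair members. Mating behaviors occur only in mate
#' pairs: ejaculations are Poisson with mean `lambda_ejac * z_p` (the shared
#' pair latent) at the 2.5 h and 6 h timepoints, and nearly absent by 22 h,
#' reproducing the hump-shaped mating time course; mounts and intromissions
#' scale with ejaculations. Sibling pairs score zero on all mating measures.
#' Animals at the 0 h timepoint were never in contact, so all interaction
#' measures are zero there (they remain observed values, not missing).
#'
#' @param design a [simulate_design()] table.
#' @param latent named numeric vector of pair-level latent values keyed by
#'   `pair_id` (use `attr(counts, "latent")` from [simulate_counts()] to
#'   couple behavior with brain activity); defaults to fresh log-normal(0,1)
#'   draws.
#' @param lambda_ejac base ejaculation mean per unit latent; default 3.
#' @param seed integer seed.
#' @return `data.frame` with `animal_id` plus measure columns; attribute
#'   `"dyadic"` names the dyadic measures.
#' @export
simulate_behavior <- function(design, latent = NULL, lambda_ejac = 3, seed = 1) {
  set.seed(seed)
  pairs <- unique(design$pair_id)
  if (is.null(latent)) {
    latent <- stats::rlnorm(length(pairs))
    names(latent) <- pairs
  }
  if (!all(pairs %in% names(latent))) stop("latent must be keyed by pair_id")
  n <- nrow(design)
  is_mate <- design$partner_type == "mate"
  tp <- design$timepoint
  interacting <- tp > 1L                      # 0 h animals never met
  # individual measures (log-normal; units per hour or proportion of window)
  velocity <- rlnorm(n, meanlog = log(3), sdlog = 0.3)
  net_movement <- rnorm(n, mean = ifelse(is_mate & interacting, 0.3, 0), sd = 0.5)
  anogenital_investigation <-
    rlnorm(n, log(2) + 0.6 * (is_mate & interacting), 0.4) * interacting
  self_grooming <- rlnorm(n, log(1.5), 0.3)
  # dyadic measures: draw once per pair, copy to both members
  pd <- design[!duplicated(design$pair_id), ]
  mate_p <- pd$partner_type == "mate"
  tp_p <- pd$timepoint
  # hump-shaped mating time course: none at 0 h, peak 2.5-6 h, rare by 22 h
  mate_rate <- ifelse(tp_p %in% 2:3, 1, ifelse(tp_p == 4L, 0.05, 0))
  ejac <- rpois(nrow(pd), lambda_ejac * latent[pd$pair_id] * mate_rate * mate_p)
  intro <- ejac * 3L + rpois(nrow(pd), 2 * mate_rate * mate_p)
  mounts <- intro + rpois(nrow(pd), 3 * mate_rate * mate_p)
  huddling <- pmin(1, rlnorm(nrow(pd), log(0.2) + 0.5 * (mate_p & tp_p %in% 2:3),
                             0.4)) * (tp_p > 1L)
  usv_rate <- rlnorm(nrow(pd), log(20) + 0.8 * mate_p, 0.5) * (tp_p > 1L)
  dy <- data.frame(pair_id = pd$pair_id, mounts = mounts,
                   intromissions = intro, ejaculations = ejac,
                   huddling_duration = huddling, usv_rate = usv_rate,
                   stringsAsFactors = FALSE)
  i <- match(design$pair_id, dy$pair_id)
  out <- data.frame(
    animal_id = design$animal_id,
    velocity = velocity, net_movement = net_movement,
    anogenital_investigation = anogenital_investigation,
    self_grooming = self_grooming,
    mounts = dy$mounts[i], intromissions = dy$intromissions[i],
    ejaculations = dy$ejaculations[i],
    huddling_duration = dy$huddling_duration[i], usv_rate = dy$usv_rate[i],
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$animal_id
  attr(out, "dyadic") <- c("mounts", "intromissions", "ejaculations",
                           "huddling_duration", "usv_rate")
  out
}
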