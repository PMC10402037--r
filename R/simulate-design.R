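#' Simulate the paired-cohabitation study design
#'
#' Builds a design table mirroring the pair-bonding cohabitation experiment:
#' at each of four cohabitation timepoints (0, 2.5, 6 and 22 h, coded
#' ordinally 1--4), `n_pairs_per_cell` opposite-sex mate pairs and
#' `n_pairs_per_cell` same-sex sibling pairs are generated. Sibling pairs are
#' split evenly between female--female and male--male; when
#' `n_pairs_per_cell` is odd the extra sibling pair alternates sex across
#' timepoints so the overall design stays near-balanced. Experimental blocks
#' 1--6 are assigned round-robin within each timepoint, balancing blocks
#' across timepoints and partner types.
#'
#' The design is fully deterministic given `n_pairs_per_cell`; the `seed`
#' argument is reserved for future randomized layouts and currently has no
#' effect. With the default `n_pairs_per_cell = 12` the table contains 192
#' animals (96 female, 96 male), matching the study scale.
#'
#' @param n_pairs_per_cell number of mate pairs (and of sibling pairs) per
#'   timepoint; the study used 12.
#' @param seed reserved; ignored (the layout is deterministic).
#' @return A `data.frame` of class `"bond_design"` with one row per animal:
#'   `animal_id`, `pair_id`, `sex` (`"F"`/`"M"`), `partner_type`
#'   (`"mate"`/`"sibling"`), `timepoint` (integer 1--4), `cohab_hours`
#'   (0, 2.5, 6, 22), `block` (integer 1--6), and the inclusion flags
#'   `behavior_included`, `ieg_included` (all `TRUE` initially; see
#'   [apply_exclusions()]).
#' @seealso [apply_exclusions()], [study_exclusions()], [simulate_counts()]
#' @examples
#' d <- simulate_design(12)
#' table(d$sex, d$partner_type)
#' @export
simulate_design <- function(n_pairs_per_cell = 12, seed = NULL) {
  stopifnot(n_pairs_per_cell >= 1)
  n <- n_pairs_per_cell
  hours <- c(0, 2.5, 6, 22)
  rows <- vector("list", 4L)
  pair_counter <- 0L
  animal_counter <- 0L
  for (tp in 1:4) {
    # mate pairs: one F + one M each
    n_ff <- n %/% 2L
    n_mm <- n %/% 2L
    if (n %% 2L == 1L) {
      # odd sibling split: extra pair alternates sex by timepoint
      if (tp %% 2L == 1L) n_ff <- n_ff + 1L else n_mm <- n_mm + 1L
    }
    ptype <- c(rep("mate", n), rep("sibling", n_ff + n_mm))
    sib_sex <- c(rep("F", n_ff), rep("M", n_mm))
    n_pairs_tp <- length(ptype)
    # blocks cycle within each partner type so that every block holds both
    # mate and sibling pairs whenever possible
    blocks <- c(((seq_len(n) - 1L) %% 6L) + 1L,
                ((seq_len(n_ff + n_mm) - 1L) %% 6L) + 1L)
    tp_rows <- vector("list", n_pairs_tp)
    for (j in seq_len(n_pairs_tp)) {
      pair_counter <- pair_counter + 1L
      pid <- sprintf("P%03d", pair_counter)
      sexes <- if (ptype[j] == "mate") c("F", "M") else rep(sib_sex[j - n], 2L)
      aid <- sprintf("A%03d", animal_counter + 1:2)
      animal_counter <- animal_counter + 2L
      tp_rows[[j]] <- data.frame(
        animal_id = aid, pair_id = pid, sex = sexes,
        partner_type = ptype[j], timepoint = tp, cohab_hours = hours[tp],
        block = blocks[j], behavior_included = TRUE, ieg_included = TRUE,
        stringsAsFactors = FALSE
      )
    }
    rows[[tp]] <- do.call(rbind, tp_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- out$animal_id
  class(out) <- c("bond_design", "data.frame")
  out
}

#' Mark animals as excluded from behavior or IEG analyses
#'
#' Updates the `behavior_included` / `ieg_included` flags of a design table.
#' Exclusions are scoped: `"behavior"` removes an animal from behavioral
#' analyses only, `"ieg"` from c-Fos count analyses only.
#'
#' @param design a [simulate_design()] table (or compatible `data.frame`).
#' @param exclusions `data.frame` with columns `animal_id`, `reason`, `scope`
#'   (`"behavior"` or `"ieg"`).
#' @return the design with inclusion flags updated.
#' @examples
#' d <- simulate_design(1)
#' d2 <- apply_exclusions(d, data.frame(
#'   animal_id = d$animal_id[1], reason = "perfusion failure", scope = "ieg"))
#' sum(d2$ieg_included)
#' @export
apply_exclusions <- function(design, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0L) return(design)
  stopifnot(all(c("animal_id", "scope") %in% names(exclusions)))
  unknown <- setdiff(exclusions$animal_id, design$animal_id)
  if (length(unknown))
    stop("unknown animal_id in exclusions: ", paste(unknown, collapse = ", "))
  bad_scope <- setdiff(exclusions$scope, c("behavior", "ieg"))
  if (length(bad_scope))
    stop("exclusion scope must be 'behavior' or 'ieg', got: ",
         paste(bad_scope, collapse = ", "))
  for (i in seq_len(nrow(exclusions))) {
    j <- match(exclusions$animal_id[i], design$animal_id)
    if (exclusions$scope[i] == "behavior") design$behavior_included[j] <- FALSE
    else design$ieg_included[j] <- FALSE
  }
  design
}

#' The study's documented sample exclusions
#'
#' Returns the exclusion table reproducing the published subject bookkeeping:
#' three brains dropped from IEG analyses (one male sibling at the 6 h
#' timepoint with a failed perfusion; two female mates, at 0 h and 6 h,
#' flagged as whole-brain count outliers) and one mate pair at the 0 h
#' timepoint dropped from behavioral analyses after a camera malfunction.
#' Applied to the default 192-animal design this leaves 189 animals for IEG
#' analyses and 190 for behavior.
#'
#' Concrete animal ids are picked deterministically from `design` as the
#' first animals matching each description.
#'
#' @param design a design table from [simulate_design()]; needs at least one
#'   animal matching each published description.
#' @return an exclusion `data.frame` suitable for [apply_exclusions()].
#' @examples
#' d <- simulate_design(12)
#' d <- apply_exclusions(d, study_exclusions(d))
#' c(ieg = sum(d$ieg_included), behavior = sum(d$behavior_included))
#' @export
study_exclusions <- function(design) {
  pick <- function(sex, ptype, tp, skip = character()) {
    i <- which(design$sex == sex & design$partner_type == ptype &
                 design$timepoint == tp & !(design$animal_id %in% skip))
    if (!length(i)) stop("design has no ", sex, " ", ptype, " at timepoint ", tp)
    design$animal_id[i[1L]]
  }
  sib_m_6h <- pick("M", "sibling", 3L)
  mate_f_0h <- pick("F", "mate", 1L)
  mate_f_6h <- pick("F", "mate", 3L)
  # camera-malfunction mate pair at 0 h: both members lose behavior data
  cam_pair <- design$pair_id[design$partner_type == "mate" & design$timepoint == 1L][1L]
  cam_members <- design$animal_id[design$pair_id == cam_pair]
  data.frame(
    animal_id = c(sib_m_6h, mate_f_0h, mate_f_6h, cam_members),
    reason = c("perfusion failure", "whole-brain count outlier",
               "whole-brain count outlier", "camera malfunction",
               "camera malfunction"),
    scope = c("ieg", "ieg", "ieg", "behavior", "behavior"),
    stringsAsFactors = FALSE
  )
}
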