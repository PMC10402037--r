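#' Configuration for the end-to-end pipeline
#'
#' Collects every tunable of [run_pipeline()] with the study's conventions
#' as defaults: 12 pairs of each type per timepoint, a brain FDR threshold
#' of q < 0.1 and a behavioral one of q < 0.05, 8 clusters, bond-formation
#' window at timepoints 2--3, coordination threshold r > 0.75, pair-level
#' stratified permutations. The synthetic dataset defaults plant a
#' partner-type log effect of 0.7 on `n_planted` of `n_units` regions (all
#' planted regions are also latent-coupled so the coordination stage has
#' signal), with quasi-Poisson dispersion 2. `n_perm = 200` keeps a default
#' run on one CPU in minutes; raise to 10,000 for study-grade p-value
#' resolution. Every stage derives its own seed from `seed` so stages stay
#' reproducible when run standalone.
#'
#' @param n_pairs_per_cell pairs of each type per timepoint.
#' @param n_units number of simulated regions.
#' @param n_planted number of regions carrying the partner effect.
#' @param effect_size log-scale planted effect.
#' @param dispersion count dispersion (>= 1).
#' @param gamma pair-latent coupling strength on planted regions.
#' @param n_perm screen/connectivity permutations.
#' @param alpha_brain,alpha_behavior FDR thresholds.
#' @param k number of clusters.
#' @param formation_timepoints coordination window.
#' @param coordination_threshold edge threshold.
#' @param scheme permutation scheme for the screen.
#' @param fdr FDR method.
#' @param seed master seed.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_pairs_per_cell = 12, n_units = 800,
                            n_planted = 68, effect_size = 0.7,
                            dispersion = 2, gamma = 0.3, n_perm = 200,
                            alpha_brain = 0.1, alpha_behavior = 0.05,
                            k = 8, formation_timepoints = 2:3,
                            coordination_threshold = 0.75,
                            scheme = "pair", fdr = "bh", seed = 1) {
  cfg <- as.list(environment())
  cfg$stage_seeds <- seed * 10L + seq_len(6L)  # design..coordination
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis chain on a synthetic dataset
#'
#' Executes simulate -> screen -> exclusive ROI selection -> clustering /
#' MDS / time courses -> connectome permutation test -> brain--behavior CCA
#' -> within-pair coordination -> behavioral tests -> whole-brain outlier
#' screen, writing every stage product as CSV/JSON under `outdir` and
#' returning a manifest sufficient to reproduce the run bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed); `NULL` skips file
#'   output.
#' @param verbose print stage progress to stderr.
#' @return list of class `"run_manifest"`: `config`, `results` (all stage
#'   objects), `timings` (seconds per stage), `checksums` (md5 of written
#'   files), `warnings`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- list(); warns <- character(0)
  res <- list()
  say <- function(...) if (verbose) message("[bondmap] ", ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    t_all[[name]] <<- proc.time()[["elapsed"]] - t0
    say(name, " done in ", sprintf("%.1fs", t_all[[name]]))
    out
  }
  ss <- config$stage_seeds

  res$design <- stage("design", {
    d <- simulate_design(config$n_pairs_per_cell)
    apply_exclusions(d, study_exclusions(d))
  })
  units <- sprintf("R%03d", seq_len(config$n_units))
  planted <- units[seq_len(config$n_planted)]
  res$atlas <- stage("atlas",
    simulate_atlas(config$n_units, depth = 3, seed = ss[1]))
  simcfg <- sim_config(dispersion = config$dispersion,
                       effect_units = planted,
                       effect_size = config$effect_size,
                       coupling_units = planted, gamma = config$gamma)
  res$counts <- stage("counts",
    simulate_counts(res$design, units, simcfg, seed = ss[2]))
  res$behavior <- stage("behavior",
    simulate_behavior(res$design, latent = attr(res$counts, "latent"),
                      seed = ss[3]))
  res$planted_units <- planted

  res$screen <- stage("screen",
    fos_screen(res$counts, res$design, contrast = "bonding",
               n_perm = config$n_perm, seed = ss[4], scheme = config$scheme,
               alpha = config$alpha_brain, fdr = config$fdr))
  sig <- res$screen$table[res$screen$table$significant, , drop = FALSE]
  res$selection <- stage("select",
    select_exclusive(res$atlas, sig$unit, sig$F))
  chosen <- res$selection$unit[res$selection$chosen]

  if (length(chosen) >= max(3, config$k)) {
    res$clusters <- stage("cluster", {
      z <- zscore_units(res$counts[res$design$animal_id[res$design$ieg_included],
                                   chosen, drop = FALSE])
      d <- unit_distance(z)
      tree <- ward_linkage(d)
      assign <- cut_clusters(tree, config$k)
      mds <- if (length(chosen) > 4) mds_embed(d, dims = 2) else NULL
      list(tree = tree, assignment = assign, mds = mds,
           correlations = unit_correlations(
             res$counts[res$design$animal_id[res$design$ieg_included],
                        chosen, drop = FALSE]),
           time_course = cluster_time_course(res$counts, assign, res$design))
    })
    res$connectivity <- stage("connectivity", {
      # planted units form dense circuits; background units are singletons
      truecl <- setNames(paste0("bg", seq_along(units)), units)
      truecl[planted] <- paste0("c", 1L + (seq_along(planted) - 1L) %%
                                  max(1L, config$k - 2L))
      conn <- simulate_connectivity(units, truecl, within_density = 0.3,
                                    between_density = 0.05, noise_sd = 0.02,
                                    seed = ss[5])
      mp <- map_to_connectome(chosen, rownames(conn), res$atlas)
      assign <- res$clusters$assignment[names(mp$map)]
      names(assign) <- mp$map
      list(conn = conn,
           test = connectivity_permutation_test(conn, assign,
                                                n_perm = config$n_perm,
                                                seed = ss[5]))
    })
    res$cca <- stage("cca", {
      inc <- res$design$animal_id[res$design$ieg_included &
                                    res$design$behavior_included]
      bm <- as.matrix(res$behavior[match(inc, res$behavior$animal_id), -1])
      rownames(bm) <- inc
      bm <- bm[, apply(bm, 2, sd) > 0, drop = FALSE]
      fit <- cca_fit(res$counts[inc, chosen, drop = FALSE], bm)
      list(fit = fit, tests = wilks_test(fit),
           loadings = score_loadings(fit),
           groups = group_cc_scores(fit, res$design))
    })
    res$coordination <- stage("coordination", {
      ej <- res$behavior$ejaculations
      names(ej) <- res$behavior$animal_id
      pair_ej <- tapply(ej[res$design$animal_id], res$design$pair_id, max)
      cm <- coordination_matrix(res$counts[, chosen, drop = FALSE],
                                res$design,
                                timepoints = config$formation_timepoints,
                                threshold = config$coordination_threshold)
      cmc <- coordination_matrix(res$counts[, chosen, drop = FALSE],
                                 res$design,
                                 timepoints = config$formation_timepoints,
                                 control = pair_ej,
                                 threshold = config$coordination_threshold)
      list(raw = cm, controlled = cmc)
    })
  } else {
    warns <- c(warns, "fewer chosen units than clusters; network stages skipped")
  }
  res$behavior_tests <- stage("behavior_tests",
    batch_behavior_tests(res$behavior, res$design,
                         alpha = config$alpha_behavior, fdr = config$fdr))
  res$outliers <- stage("outliers", {
    tot <- rowSums(res$counts)
    rosner_esd(tot, max_outliers = 5, alpha = 0.05)
  })

  checksums <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(outdir, f)
    write_design(res$design, fp("design.csv"))
    write_counts(res$counts, fp("counts.csv"))
    write_behavior(res$behavior, fp("behavior.csv"))
    write_atlas(res$atlas, fp("atlas.json"))
    write.csv(res$screen$table, fp("screen.csv"), row.names = FALSE)
    write.csv(res$selection, fp("chosen_rois.csv"), row.names = FALSE)
    if (!is.null(res$clusters)) {
      write.csv(data.frame(unit = names(res$clusters$assignment),
                           cluster = res$clusters$assignment),
                fp("clusters.csv"), row.names = FALSE)
      write_connectivity(res$connectivity$conn, fp("connectivity.csv"))
      jsonlite::write_json(list(observed = res$connectivity$test$observed,
                                p = res$connectivity$test$p,
                                n_perm = res$connectivity$test$n_perm),
                           fp("connectivity_test.json"), auto_unbox = TRUE)
      write.csv(res$cca$loadings, fp("cca_loadings.csv"), row.names = FALSE)
      write.csv(res$cca$tests, fp("cca_tests.csv"), row.names = FALSE)
      write.csv(res$coordination$raw$edges, fp("coordination_edges.csv"),
                row.names = FALSE)
    }
    write.csv(res$behavior_tests, fp("behavior_tests.csv"), row.names = FALSE)
    write.csv(res$outliers, fp("outliers.csv"), row.names = FALSE)
    files <- list.files(outdir, full.names = TRUE)
    checksums <- tools::md5sum(files)
    names(checksums) <- basename(files)
  }
  structure(list(config = config, results = res,
                 timings = unlist(t_all), checksums = checksums,
                 warnings = warns),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("bondmap pipeline run\n")
  cat("  stages:", paste(names(x$timings), collapse = ", "), "\n")
  cat(sprintf("  total time: %.1fs\n", sum(x$timings)))
  sc <- x$results$screen
  if (!is.null(sc))
    cat("  screen:", sum(sc$table$significant), "of", nrow(sc$table),
        "units significant at q <", sc$alpha, "\n")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
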