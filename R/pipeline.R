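#' Pipeline configuration with canonical defaults
#'
#' Collects every tunable threshold of the analysis with its default:
#' FWD censoring threshold 1.5 mm, run rejection above 50\% censored
#' frames, vcov dispersion cutoff 10, noise-ceiling validity floor 0.1,
#' 1000 bootstrap resamples, diagonal included for feature RSA and
#' excluded for DNN/maturity RSA. All defaults are overridable; the
#' config is serialized alongside outputs for provenance.
#'
#' @param ... overrides of the default fields.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fwd_threshold = 1.5,
    max_censored_fraction = 0.5,
    dispersion_max = 10,
    ceiling_floor = 0.1,
    n_boot = 1000,
    n_splits = 100,
    seed = 1L,
    diagonal_feature_rsa = TRUE,
    diagonal_dnn_rsa = FALSE,
    # synthetic cohort defaults (demo scale)
    n_subjects = 12,
    runs_per_subject = 2,
    n_voxels = 300,
    groups = c("infant2mo", "adult"),
    mixture_weights = c(category = 1, animacy_tripartite = 0.5),
    group_sd = 1, individual_sd = 0.5, session_sd = 0.25, noise_sd = 1,
    run_dnn = TRUE,
    run_mds = TRUE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Generates a synthetic cohort per configured group, builds cross-subject
#' pair RSMs and noise ceilings, constructs perceptual and categorical
#' model RSMs from rendered stimuli, runs bootstrap (partial) RSA per
#' group and model, partitions pattern variance, optionally aligns to the
#' untrained network's layer RSMs and computes hierarchically aligned
#' embeddings. Deterministic given the config seed. When \code{out_dir}
#' is supplied, result tables, the group RSMs and the config are written
#' there.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional output directory.
#' @return list with \code{cohorts}, \code{pair_sets}, \code{ceilings},
#'   \code{models}, \code{rsa} (data frame), \code{variance},
#'   \code{dnn_profiles}, \code{embeddings}, \code{config}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ss <- make_stimulus_set()
  rendered <- render_stimulus_images(ss, seed = config$seed)
  perc <- perceptual_rsms(rendered$features)
  catm <- categorical_rsms(ss)
  models <- c(perc, catm)
  weights <- config$mixture_weights
  mix_models <- lapply(names(weights), function(nm) as.matrix(models[[nm]]))
  mixture <- ground_truth_mixture(mix_models, unname(weights),
                                  group_sd = config$group_sd,
                                  individual_sd = config$individual_sd,
                                  session_sd = config$session_sd,
                                  noise_sd = config$noise_sd)
  cohorts <- list(); pair_sets <- list(); ceilings <- list()
  for (gi in seq_along(config$groups)) {
    g <- config$groups[gi]
    cohorts[[g]] <- simulate_patterns(ss, mixture,
                                      n_subjects = config$n_subjects,
                                      runs_per_subject = config$runs_per_subject,
                                      n_voxels = config$n_voxels,
                                      seed = config$seed + 1000 * gi,
                                      group = g)
    level <- if (grepl("adult", g)) "subject" else "run"
    pair_sets[[g]] <- cohort_pair_rsms(cohorts[[g]], level = level)
    ceilings[[g]] <- split_half_noise_ceiling(
      cohorts[[g]], level = level, n_splits = config$n_splits,
      seed = config$seed + gi, floor = config$ceiling_floor,
      pair_set = pair_sets[[g]])
  }
  perc_names <- names(perc)
  rsa_rows <- list()
  for (g in names(cohorts)) {
    ps <- pair_sets[[g]]
    for (mn in names(models)) {
      model_m <- as.matrix(models[[mn]])
      is_semantic <- mn %in% names(catm)
      covs <- if (is_semantic) lapply(perc, as.matrix) else list()
      stat <- function(m) partial_rsa(m, model_m, covariates = covs,
                                      include_diagonal =
                                        config$diagonal_feature_rsa)
      br <- bootstrap_statistic(ps$rsms, stat, n_boot = config$n_boot,
                                seed = config$seed + 7)
      nz <- normalize_by_ceiling(br$point, ceilings[[g]])
      rsa_rows[[length(rsa_rows) + 1]] <- data.frame(
        group = g, model = mn,
        partial = is_semantic,
        rho = br$point, rho_norm = nz$value,
        ci_lo = br$ci[1], ci_hi = br$ci[2],
        valid_ceiling = nz$normalized)
    }
  }
  rsa_df <- do.call(rbind, rsa_rows)
  variance <- lapply(cohorts, partition_variance,
                     n_boot = min(config$n_boot, 200),
                     seed = config$seed + 11)
  dnn_profiles <- NULL
  if (isTRUE(config$run_dnn)) {
    acts <- default_activation_provider(rendered$images,
                                        masks = rendered$masks,
                                        seed = config$seed)
    lrs <- layer_rsms(acts)
    dnn_profiles <- lapply(names(cohorts), function(g)
      layerwise_rsa(pair_sets[[g]]$rsms, lrs, ceiling = ceilings[[g]],
                    n_boot = min(config$n_boot, 200),
                    seed = config$seed + 13))
    names(dnn_profiles) <- names(cohorts)
  }
  embeddings <- NULL
  if (isTRUE(config$run_mds)) {
    group_rsms <- lapply(names(cohorts), function(g)
      zscore_rsm(group_rsm(pair_sets[[g]]$rsms,
                           labels = pair_sets[[g]]$labels)))
    names(group_rsms) <- paste0("vvc.", names(cohorts))
    embeddings <- hierarchical_embed(group_rsms, seed = config$seed)
  }
  out <- list(cohorts = cohorts, pair_sets = pair_sets,
              ceilings = ceilings, models = models, rsa = rsa_df,
              variance = variance, dnn_profiles = dnn_profiles,
              embeddings = embeddings, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  invisible(out)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$rsa, file.path(out_dir, "rsa_results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  vp <- do.call(rbind, lapply(names(result$variance), function(g)
    data.frame(group = g, component = names(result$variance[[g]]$components),
               value = unname(result$variance[[g]]$components))))
  utils::write.table(vp, file.path(out_dir, "variance_components.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (g in names(result$pair_sets)) {
    gr <- group_rsm(result$pair_sets[[g]]$rsms,
                    labels = result$pair_sets[[g]]$labels)
    write_rsm(gr, file.path(out_dir, paste0("group_rsm_", g, ".tsv")))
  }
  if (!is.null(result$dnn_profiles)) {
    dn <- do.call(rbind, lapply(names(result$dnn_profiles), function(g)
      cbind(group = g, result$dnn_profiles[[g]]$profile)))
    utils::write.table(dn, file.path(out_dir, "dnn_profile.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(result$embeddings)) {
    co <- do.call(rbind, lapply(names(result$embeddings$by_cell), function(k) {
      e <- result$embeddings$by_cell[[k]]
      data.frame(cell = k, condition = seq_len(nrow(e$coords)),
                 x = e$coords[, 1], y = e$coords[, 2])
    }))
    utils::write.table(co, file.path(out_dir, "mds_coords.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  cfg <- result$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
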