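# End-to-end orchestration: phantom -> preprocess -> habitat ->
# radiomics -> modeling -> evaluation -> survival, communicating through
# files under the output directory and recording a run manifest.

.stage_files <- function(dir) {
  fs <- list.files(dir, recursive = TRUE, full.names = TRUE)
  as.list(tools::md5sum(fs))
}

#' Run the whole habitat-radiomics pipeline on a synthetic cohort
#'
#' Generates the phantom cohort, windows/resamples the volumes, fits the
#' pooled habitat clustering with CH-index selection of K, extracts
#' radiomics tables for the whole tumor and each habitat, runs the
#' repeated-split modeling experiment (per-region models plus the fused
#' signature), evaluates the representative fused model (calibration,
#' Hosmer-Lemeshow, decision curve), computes the survival statistics,
#' and writes a manifest with config snapshot, seeds and output hashes.
#' Re-running with the same config reproduces identical outputs.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param out_dir output directory (created if needed).
#' @param spec a [phantom_spec()]; its seed is taken from
#'   `config$phantom$seed`.
#' @param write_volumes write per-patient NIfTI files (off by default to
#'   keep runs light).
#' @return The run manifest (named list), invisibly; written as
#'   `manifest.json`.
#' @export
run_all <- function(config = default_config(), out_dir = tempfile("habrad_run_"),
                    spec = NULL, write_volumes = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  if (is.null(spec)) spec <- phantom_spec(seed = config$phantom$seed)

  .log_msg("info", "stage phantom")
  gen <- generate_cohort(spec)
  write_cohort(gen$cohort, file.path(out_dir, "cohort.csv"))
  if (write_volumes) {
    vd <- file.path(out_dir, "volumes")
    dir.create(vd, showWarnings = FALSE)
    for (p in gen$patients) {
      write_volume(p$arterial, file.path(vd, paste0(p$mask$patient_id, "_art.nii.gz")))
      write_volume(p$venous, file.path(vd, paste0(p$mask$patient_id, "_ven.nii.gz")))
      write_mask(p$mask, file.path(vd, paste0(p$mask$patient_id, "_mask.nii.gz")))
    }
  }
  stages <- c(stages, "phantom")

  .log_msg("info", "stage preprocess")
  w <- window_spec(config$window$level, config$window$width)
  patients <- lapply(gen$patients, function(p) {
    a <- resample_isotropic(window_clip(p$arterial, w), config$resample$spacing)
    v <- resample_isotropic(window_clip(p$venous, w), config$resample$spacing)
    m <- resample_isotropic(p$mask, config$resample$spacing)
    al <- check_alignment(a, v)
    if (!al$pass) stop("stage preprocess failed: misaligned phases for ",
                       p$mask$patient_id)
    list(arterial = a, venous = v, mask = m)
  })
  stages <- c(stages, "preprocess")

  .log_msg("info", "stage habitat")
  vox <- pool_voxels(patients)
  model <- select_k(vox, config$habitat$k_min:config$habitat$k_max,
                    seed = config$habitat$seed,
                    n_init = config$habitat$n_init,
                    max_iter = config$habitat$max_iter,
                    tol = config$habitat$tol)
  write.csv(data.frame(K = as.integer(names(model$ch_scores)),
                       ch = as.numeric(model$ch_scores)),
            file.path(out_dir, "ch_scores.csv"), row.names = FALSE)
  jsonlite::write_json(list(K = model$K, centers = model$centers,
                            seed = model$seed),
                       file.path(out_dir, "habitat_model.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  maps <- lapply(patients, function(p)
    assign_habitats(model, p$arterial, p$venous, p$mask))
  stages <- c(stages, "habitat")

  .log_msg("info", "stage radiomics")
  feats <- radiomics_table(patients, maps, model$K,
                           bin_width = config$radiomics$bin_width,
                           min_voxels = config$radiomics$min_voxels,
                           w = w, log_sigma = config$radiomics$log_sigma)
  for (rg in names(feats))
    write.csv(feats[[rg]], file.path(out_dir, paste0("features_", rg, ".csv")),
              row.names = FALSE)
  stages <- c(stages, "radiomics")

  .log_msg("info", "stage modeling")
  exp <- run_experiment(feats, gen$cohort,
                        n_repeats = config$modeling$n_repeats,
                        ratio = config$modeling$split_ratio,
                        seed = config$modeling$seed,
                        rho_threshold = config$selection$rho_threshold,
                        n_lambda = config$selection$n_lambda,
                        lambda_min_ratio = config$selection$lambda_min_ratio,
                        cv_folds = config$selection$cv_folds)
  write.csv(exp$aggregate$summary, file.path(out_dir, "model_metrics.csv"),
            row.names = FALSE)
  stages <- c(stages, "modeling")

  .log_msg("info", "stage evaluation")
  rep_i <- exp$aggregate$representative[["fusion"]]
  fus <- exp$repeats[[rep_i]]$fusion
  probs_te <- stats::plogis(fus$scores$test)
  yte <- fus$scores$y_test
  hl <- tryCatch(hosmer_lemeshow(pmin(pmax(probs_te, 1e-8), 1 - 1e-8), yte,
                                 config$evaluation$hl_bins),
                 error = function(e) list(chi2 = NA, p = NA))
  eval_report <- list(
    representative_repeat = rep_i,
    fusion_test = exp$repeats[[rep_i]]$fusion$metrics$test,
    region_counts = as.list(fus$region_counts),
    hosmer_lemeshow = list(chi2 = hl$chi2, p = hl$p),
    calibration = calibration_curve(probs_te, yte, config$evaluation$hl_bins),
    decision_curve = decision_curve(probs_te, yte, config$evaluation$dca_grid))
  write_report(eval_report, file.path(out_dir, "evaluation.json"))
  stages <- c(stages, "evaluation")

  .log_msg("info", "stage survival")
  coh <- gen$cohort
  km <- lapply(split(coh, coh$lnm_status), function(d)
    km_estimate(d$survival_time, d$event))
  lr <- logrank_test(coh$survival_time, coh$event, coh$lnm_status)
  surv_report <- list(
    median_lnm_neg = km[["0"]]$median, median_lnm_pos = km[["1"]]$median,
    logrank_chi2 = lr$chi2, logrank_p = lr$p,
    table1 = table1_report(coh))
  write_report(surv_report, file.path(out_dir, "survival.json"))
  stages <- c(stages, "survival")

  manifest <- list(
    created = "run", stages = stages,
    config = unclass(config),
    phantom = list(n_patients = spec$n_patients, k_true = spec$k_true,
                   seed = spec$seed),
    selected_K = model$K,
    outputs = .stage_files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
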