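# Pipeline orchestration: a structured run configuration and the four
# stages (simulate -> extract -> evaluate, plus the cohort statistics
# report). Every stage writes into the configured output directory and a
# manifest sufficient to reproduce its outputs exactly.

#' Default run configuration
#'
#' All published analysis defaults are pre-filled: 0.5 x 0.5 x 3 mm target
#' spacing, 224 x 224 network input, 32 gray levels, top-90 chi-square
#' selection, 4 classifier types over 2 feature vectors, stratified 5-fold
#' cross-validation repeated 20 times, and the 74/64 synthetic cohort.
#'
#' @param data_dir directory holding (or receiving) the cohort.
#' @param output_dir directory for feature tables, metrics and the manifest.
#' @param base_seed master seed for every downstream source of randomness.
#' @return nested configuration list.
#' @export
default_run_config <- function(data_dir = "cohort", output_dir = "results",
                               base_seed = 1L) {
  list(
    paths = list(data_dir = data_dir, output_dir = output_dir),
    preprocessing = list(target_spacing = c(0.5, 0.5, 3), out_size = 224L,
                         crop_margin = 0L),
    features = list(n_bins = 32L),
    backbone = list(widths = c(64L, 128L, 256L, 512L, 512L),
                    conv_counts = c(2L, 2L, 4L, 4L, 4L),
                    weights = NULL, seed_offset = 91L),
    selection = list(k = 90L),
    ensemble = list(classifiers = c("lr", "svm", "knn", "nb"),
                    val_fraction = 0.2),
    cv = list(n_folds = 5L, n_repeats = 20L),
    synthetic = list(n_pcr = 74L, n_nonpcr = 64L, phantom = list()),
    base_seed = as.integer(base_seed)
  )
}

#' Read a run configuration from YAML
#'
#' Unspecified keys fall back to [default_run_config()] values.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(def, usr) {
    for (k in names(usr)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(usr[[k]]))
        merge_cfg(def[[k]], usr[[k]]) else usr[[k]]
    }
    def
  }
  merge_cfg(default_run_config(), user)
}

write_manifest <- function(config, out_dir, stage) {
  cfg_file <- file.path(out_dir, paste0(stage, "_config.yaml"))
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    stage = stage,
    config_md5 = unname(tools::md5sum(cfg_file)),
    base_seed = config$base_seed,
    package_version = as.character(utils::packageVersion("hybridpCR")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Stage 1: materialise a synthetic cohort
#'
#' @param config a run configuration (see [default_run_config()]).
#' @return invisibly, the clinical table.
#' @export
pipe_simulate <- function(config = default_run_config()) {
  spec <- do.call(phantom_spec, config$synthetic$phantom %||% list())
  clin <- simulate_cohort(config$paths$data_dir,
                          n_pcr = config$synthetic$n_pcr,
                          n_nonpcr = config$synthetic$n_nonpcr,
                          spec = spec, seed = config$base_seed)
  write_manifest(config, config$paths$data_dir, "simulate")
  message(sprintf("simulate: wrote %d patients to %s", nrow(clin),
                  config$paths$data_dir))
  invisible(clin)
}

#' Stage 2: extract domain, abstract and encoded clinical features
#'
#' For every patient: reads the NIfTI pair, resamples to the target grid
#' (trilinear image / nearest-neighbour mask), min-max normalises, extracts
#' the domain-specific feature vector on the 3D ROI, prepares the
#' largest-ROI tumor slice and extracts the multi-level pooled abstract
#' features. Writes `domain_features.csv`, `abstract_features.csv`,
#' `clinical_encoded.csv` and the catalogue JSON copy into the output
#' directory.
#'
#' @param config a run configuration.
#' @return invisibly, a list of the three feature data.frames.
#' @export
pipe_extract <- function(config = default_run_config()) {
  dd <- config$paths$data_dir
  od <- config$paths$output_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  clin <- read_clinical_csv(file.path(dd, "clinical.csv"))
  bb <- build_backbone(
    backbone_plan(config$backbone$widths, config$backbone$conv_counts,
                  in_size = config$preprocessing$out_size),
    weights = config$backbone$weights,
    seed = derive_seed(config$base_seed, config$backbone$seed_offset))
  cat_df <- feature_catalogue()

  dom_rows <- list(); abs_rows <- list()
  t0 <- Sys.time()
  for (i in seq_len(nrow(clin))) {
    pair <- load_volume_and_mask(file.path(dd, clin$volume_file[i]),
                                 file.path(dd, clin$mask_file[i]))
    vol <- resample(pair$volume, config$preprocessing$target_spacing, "linear")
    mask <- resample(pair$mask, config$preprocessing$target_spacing, "nearest")
    vol <- normalize_intensity(vol)
    dom_rows[[i]] <- extract_domain_vector(vol, mask,
                                           n_bins = config$features$n_bins,
                                           catalogue = cat_df)
    sl <- prepare_tumor_slice(vol, mask, out_size = config$preprocessing$out_size,
                              margin = config$preprocessing$crop_margin,
                              provenance = list(patient_id = clin$patient_id[i]))
    abs_rows[[i]] <- extract_multilevel(sl, bb)
  }
  message(sprintf("extract: %d patients in %.1f s", nrow(clin),
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))

  dom <- data.frame(patient_id = clin$patient_id,
                    do.call(rbind, dom_rows), check.names = FALSE)
  abs_ <- data.frame(patient_id = clin$patient_id,
                     do.call(rbind, abs_rows), check.names = FALSE)
  enc <- data.frame(patient_id = clin$patient_id,
                    encode_clinical_table(clin), check.names = FALSE)
  enc$pcr_label <- as.character(clin$pcr_label)
  utils::write.csv(dom, file.path(od, "domain_features.csv"), row.names = FALSE)
  utils::write.csv(abs_, file.path(od, "abstract_features.csv"), row.names = FALSE)
  utils::write.csv(enc, file.path(od, "clinical_encoded.csv"), row.names = FALSE)
  file.copy(system.file("extdata", "feature_catalogue.json", package = "hybridpCR"),
            file.path(od, "feature_catalogue.json"), overwrite = TRUE)
  write_manifest(config, od, "extract")
  invisible(list(domain = dom, abstract = abs_, clinical = enc))
}

# build the feature-set specification of each variant from the three blocks
variant_features <- function(variant, dom, abs_, clin) {
  switch(variant,
    A = list(features = list(clinical = clin), select_k = NULL, select_within = NULL),
    B = list(features = list(domain = dom), select_k = NULL, select_within = NULL),
    C = list(features = list(domain = cbind(dom, clin)), select_k = NULL,
             select_within = NULL),
    D = list(features = list(abstract = abs_),
             select_k = c(abstract = 90L),
             select_within = list(abstract = colnames(abs_))),
    E = list(features = list(abstract = cbind(abs_, clin)),
             select_k = c(abstract = 90L),
             select_within = list(abstract = colnames(abs_))),
    F = list(features = list(domain = cbind(dom, clin),
                             abstract = cbind(abs_, clin)),
             select_k = c(abstract = 90L),
             select_within = list(abstract = colnames(abs_))),
    stop_hybridpcr(paste("unknown variant:", variant), "hybridpcr_parameter_error")
  )
}

#' Stage 3: repeated cross-validated evaluation
#'
#' Evaluates the six feature-combination variants (A clinical only,
#' B domain, C domain + clinical, D abstract, E abstract + clinical,
#' F full hybrid) with the 4-type ensemble, plus the single-classifier
#' ablations (each base type alone, and the ensemble, on the concatenated
#' domain + clinical + selected-abstract vector). Writes
#' `variants_metrics.csv`, `classifier_ablation.csv`, `mean_roc.csv`,
#' per-patient predictions and ensemble weights of a final full-data fit,
#' and the manifest.
#'
#' @param config a run configuration.
#' @param variants subset of `LETTERS[1:6]` to run (default all six).
#' @return invisibly, a list with both metric tables and the `cv_report`
#'   of the hybrid variant.
#' @export
pipe_evaluate <- function(config = default_run_config(),
                          variants = c("A", "B", "C", "D", "E", "F")) {
  od <- config$paths$output_dir
  dom_df <- utils::read.csv(file.path(od, "domain_features.csv"), check.names = FALSE)
  abs_df <- utils::read.csv(file.path(od, "abstract_features.csv"), check.names = FALSE)
  enc_df <- utils::read.csv(file.path(od, "clinical_encoded.csv"), check.names = FALSE)
  labels <- factor(enc_df$pcr_label, levels = PCR_LEVELS)
  dom <- as.matrix(dom_df[, -1, drop = FALSE])
  abs_ <- as.matrix(abs_df[, -1, drop = FALSE])
  clin <- as.matrix(enc_df[, setdiff(names(enc_df), c("patient_id", "pcr_label")),
                           drop = FALSE])
  k <- config$selection$k
  fmt <- function(m, s) sprintf("%.3f +/- %.3f", m, s)

  rows <- list(); hybrid_report <- NULL
  for (v in variants) {
    vf <- variant_features(v, dom, abs_, clin)
    if (!is.null(vf$select_k)) vf$select_k[] <- pmin(vf$select_k, k)
    rep_ <- run_repeated_cv(vf$features, labels,
                            n_folds = config$cv$n_folds,
                            n_repeats = config$cv$n_repeats,
                            base_seed = derive_seed(config$base_seed, 7, match(v, LETTERS)),
                            classifiers = config$ensemble$classifiers,
                            select_k = vf$select_k,
                            select_within = vf$select_within)
    s <- rep_$summary
    rows[[v]] <- data.frame(classifier = v, t(stats::setNames(
      fmt(s$mean, s$sd_fold), s$metric)), check.names = FALSE)
    if (v == "F") hybrid_report <- rep_
  }
  var_tab <- do.call(rbind, rows)
  utils::write.csv(var_tab, file.path(od, "variants_metrics.csv"), row.names = FALSE)

  # single-classifier ablations on the concatenated vector
  all_feat <- cbind(dom, clin, abs_)
  abl_rows <- list()
  abl_types <- list(Bayesian = "nb", `Logistic Regression` = "lr",
                    KNN = "knn", SVC = "svm",
                    `Ensemble classifier` = config$ensemble$classifiers)
  for (nm in names(abl_types)) {
    rep_ <- run_repeated_cv(list(all = all_feat), labels,
                            n_folds = config$cv$n_folds,
                            n_repeats = config$cv$n_repeats,
                            base_seed = derive_seed(config$base_seed, 8, match(nm, names(abl_types))),
                            classifiers = abl_types[[nm]],
                            select_k = c(all = k),
                            select_within = list(all = colnames(abs_)))
    s <- rep_$summary
    abl_rows[[nm]] <- data.frame(method = nm, t(stats::setNames(
      fmt(s$mean, s$sd_fold), s$metric)), check.names = FALSE)
  }
  abl_tab <- do.call(rbind, abl_rows)
  utils::write.csv(abl_tab, file.path(od, "classifier_ablation.csv"), row.names = FALSE)

  if (!is.null(hybrid_report))
    utils::write.csv(hybrid_report$mean_roc, file.path(od, "mean_roc.csv"),
                     row.names = FALSE)

  # final fit on the full cohort: weights + per-patient predictions
  vf <- variant_features("F", dom, abs_, clin)
  fit <- hybrid_pcr(vf$features, labels, classifiers = config$ensemble$classifiers,
                    select_k = vf$select_k, select_within = vf$select_within,
                    seed = derive_seed(config$base_seed, 9))
  pr <- predict(fit, vf$features, type = "both")
  utils::write.csv(data.frame(patient_id = enc_df$patient_id,
                              p_non_pcr = pr$prob[, "non-pCR"],
                              p_pcr = pr$prob[, "pCR"],
                              predicted_label = as.character(pr$class)),
                   file.path(od, "predictions.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(members = names(coef(fit)), accuracy = unname(fit$weights$p),
         weight = unname(fit$weights$w)),
    file.path(od, "ensemble_weights.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  write_manifest(config, od, "evaluate")
  invisible(list(variants = var_tab, ablation = abl_tab, hybrid = hybrid_report))
}

#' Cohort chi-square statistics report
#'
#' @param clinical_csv path to a clinical CSV.
#' @param out optional output CSV path.
#' @return data.frame with `variable`, `statistic`, `df`, `p_value`.
#' @export
pipe_stats <- function(clinical_csv, out = NULL) {
  clin <- read_clinical_csv(clinical_csv)
  res <- clinical_cohort_stats(clin)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
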