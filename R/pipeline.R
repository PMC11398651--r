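#' Write / read feature tables as CSV
#'
#' The on-disk layout is wide: one row per (patient_id, radiologist, phase,
#' seq_index) with the 127 feature columns under their exact registry names.
#' In memory the long format (one row per feature value) is used.
#'
#' @param tbl Long feature table (`data.table`).
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` the long-format `data.table`.
#' @export
write_feature_table <- function(tbl, path) {
  wide <- data.table::dcast(data.table::as.data.table(tbl),
                            patient_id + radiologist + phase + seq_index ~ feature,
                            value.var = "value")
  ord <- intersect(c("patient_id", "radiologist", "phase", "seq_index",
                     feature_registry()$name), names(wide))
  data.table::fwrite(wide[, ord, with = FALSE], path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  wide <- data.table::fread(path)
  id_cols <- c("patient_id", "radiologist", "phase", "seq_index")
  missing <- setdiff(id_cols, names(wide))
  if (length(missing))
    stop("read_feature_table: missing identifier columns: ",
         paste(missing, collapse = ", "))
  featcols <- setdiff(names(wide), id_cols)
  for (fc in featcols) data.table::set(wide, j = fc, value = as.numeric(wide[[fc]]))
  long <- data.table::melt(wide, id.vars = id_cols, variable.name = "feature",
                           value.name = "value", variable.factor = FALSE)
  long[order(long$patient_id, long$radiologist, long$seq_index, long$feature), ]
}

# Normalise header variants ("LoG_Z_Uniformity", trailing underscores) to
# registry names.
normalize_feature_name <- function(x) {
  y <- gsub("_+$", "", x)
  y <- gsub("_", " ", y)
  trimws(gsub("\\s+", " ", y))
}

#' Ingest an external feature CSV
#'
#' Reads a third-party feature table (for example a study's supplementary
#' per-sequence feature file), maps its identifier columns through a
#' user-supplied column mapping, and matches feature columns against the
#' registry, tolerating underscore/punctuation variants of the names
#' (`"LoG_Z_MGI"` vs `"LoG Z MGI"`). Unmapped columns are reported in the
#' returned attributes.
#'
#' @param path CSV file path.
#' @param mapping Named list/character vector mapping the canonical
#'   identifier names `patient_id`, `radiologist`, `phase`, `seq_index` to
#'   the file's column names. Identity mapping by default.
#' @return Long-format feature `data.table`; attributes `unmapped`
#'   (ignored columns) and `renamed` (normalised header report).
#' @export
ingest_external_table <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("ingest_external_table: no such file: ", path)
  wide <- data.table::fread(path)
  if (!nrow(wide)) stop("ingest_external_table: file has no data rows")
  id_canon <- c("patient_id", "radiologist", "phase", "seq_index")
  mapping <- as.list(mapping %||% stats::setNames(id_canon, id_canon))
  for (k in id_canon) {
    src <- mapping[[k]] %||% k
    if (!src %in% names(wide))
      stop("ingest_external_table: mandatory column '", k, "' (mapped to '",
           src, "') not found; available: ",
           paste(utils::head(names(wide), 20), collapse = ", "))
    data.table::setnames(wide, src, k)
  }
  reg <- feature_registry()$name
  other <- setdiff(names(wide), id_canon)
  norm <- normalize_feature_name(other)
  match_idx <- match(norm, reg)
  renamed <- data.table::data.table(column = other, normalised = norm,
                                    matched = !is.na(match_idx))
  for (i in which(!is.na(match_idx) & other != reg[match_idx]))
    data.table::setnames(wide, other[i], reg[match_idx[i]])
  unmapped <- other[is.na(match_idx)]
  keep <- c(id_canon, reg[stats::na.omit(match_idx)])
  sub <- wide[, intersect(keep, names(wide)), with = FALSE]
  for (fc in setdiff(names(sub), id_canon))
    data.table::set(sub, j = fc, value = as.numeric(sub[[fc]]))
  long <- data.table::melt(sub, id.vars = id_canon, variable.name = "feature",
                           value.name = "value", variable.factor = FALSE)
  data.table::setattr(long, "unmapped", unmapped)
  data.table::setattr(long, "renamed", renamed)
  long
}

#' Write a phantom cohort to disk
#'
#' Volumes are written as NIfTI, one file per sequence
#' (`{patient}_{phase}_{seqindex}.nii.gz`), observer masks alongside, and a
#' manifest CSV (patient_id, phase, seq_index, path, grade, observer).
#'
#' @param cohort Result of [build_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest `data.table`, invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (case in cohort$cases) {
    grade <- case$grade
    for (s in seq_along(case$series)) {
      ph <- gsub("-", "", case$phases[s])
      f <- file.path(dir, sprintf("%s_%s_%02d.nii.gz", case$patient_id, ph, s))
      write_volume_nifti(case$series[[s]], f)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        patient_id = case$patient_id, phase = case$phases[s],
        seq_index = s, path = f, grade = grade, observer = NA_character_)
    }
    for (obs in c("R1", "R2")) {
      m <- if (obs == "R1") case$observer1_mask else case$observer2_mask
      f <- file.path(dir, sprintf("%s_mask_%s.nii.gz", case$patient_id, obs))
      write_mask_nifti(m, f, spacing = case$spec$spacing)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        patient_id = case$patient_id, phase = NA_character_,
        seq_index = NA_integer_, path = f, grade = grade, observer = obs)
    }
  }
  manifest <- data.table::rbindlist(rows)
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Heat-map of pairwise reproducible-feature counts
#'
#' @param counts Symmetric count matrix from [pairwise_sequence_matrix()].
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
write_pairwise_heatmap <- function(counts, path) {
  grDevices::png(path, width = 720, height = 640)
  on.exit(grDevices::dev.off(), add = TRUE)
  n <- nrow(counts)
  graphics::image(seq_len(n), seq_len(n), t(counts[n:1, ]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "sequence", ylab = "sequence",
                  main = "Reproducible features per sequence pair")
  graphics::axis(1, at = seq_len(n), labels = colnames(counts), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(counts)), las = 2, cex.axis = 0.7)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All numeric constants used by any stage, in one structure: phase labels,
#' cutoffs (CCC 0.90, Spearman 0.90, alpha 0.05, bin width 25 HU),
#' selection counts (2/7/7), split fractions (74%/26%), and per-stage seeds
#' derived from one root seed.
#'
#' @param n_patients Cohort size for the simulate stage. The demo default is
#'   8 with balanced-ish grade fractions so that the modeling stage (which
#'   needs at least two minority training patients for SMOTE) remains
#'   feasible; a clinical-scale run would use 39 patients with fractions
#'   `c(7, 32)/39`.
#' @param seed Root seed.
#' @param out_dir Output directory for artifacts.
#' @param ... Overrides for any top-level config entry.
#' @return A named list (class `run_config`).
#' @export
default_run_config <- function(n_patients = 8L, seed = 1L, out_dir = tempfile("dcerun"), ...) {
  cfg <- list(
    n_patients = n_patients,
    seed = seed,
    out_dir = out_dir,
    phases = c("NCE", "L-AP", "PVP"),
    ccc_cutoff = 0.90,
    spearman_threshold = 0.90,
    alpha = 0.05,
    bin_width = 25,
    selection_counts = c(NCE = 2L, `L-AP` = 7L, PVP = 7L),
    test_fraction = 0.26,
    grade_fractions = c(3, 5) / 8,
    classify_phase = "PVP",
    classify_radiologist = "R1",
    phantom = list())
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  bad <- function(msg) stop("run_pipeline config: ", msg, call. = FALSE)
  if (cfg$ccc_cutoff <= 0 || cfg$ccc_cutoff > 1) bad("ccc_cutoff must be in (0, 1]")
  if (cfg$spearman_threshold <= 0 || cfg$spearman_threshold > 1)
    bad("spearman_threshold must be in (0, 1]")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) bad("alpha must be in (0, 1)")
  if (cfg$bin_width <= 0) bad("bin_width must be > 0")
  if (cfg$test_fraction <= 0 || cfg$test_fraction >= 1)
    bad("test_fraction must be in (0, 1)")
  if (cfg$n_patients < 4) bad("n_patients must be >= 4")
  invisible(cfg)
}

#' Run the end-to-end phantom pipeline
#'
#' Executes simulate -> extract -> concordance (inter-observer, pairwise,
#' intra-phase) -> prune -> descriptive statistics -> classify, writing all
#' artifacts (feature CSV, concordance CSV/JSON, pairwise count CSV + PNG
#' heat maps, model report JSON, config echo and a run manifest with the
#' config hash and per-stage row counts) into `config$out_dir`. Rerunning
#' with an identical config reproduces identical outputs.
#'
#' @param config A list from [default_run_config()], or a path to a YAML
#'   file with the same entries.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    config <- do.call(default_run_config, cfg)
  }
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                             sprintf(...)))
  cfg_echo <- config; class(cfg_echo) <- NULL
  yaml::write_yaml(cfg_echo, file.path(config$out_dir, "config_echo.yaml"))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial artifacts preserved in ", config$out_dir, ")", call. = FALSE))
  }

  log_stage("simulate: %d patients", config$n_patients)
  spec <- do.call(phantom_spec, config$phantom)
  cohort <- run_stage("simulate",
    build_cohort(config$n_patients, spec, config$grade_fractions, seed = config$seed))
  data.table::fwrite(cohort$manifest, file.path(config$out_dir, "cohort_manifest.csv"))

  log_stage("extract: 16 selected sequences x 2 observers per patient")
  tbl <- run_stage("extract", extract_cohort_features(cohort$cases))
  write_feature_table(tbl, file.path(config$out_dir, "features.csv"))

  log_stage("concordance")
  inter <- list(); intra <- list(); pairwise <- list()
  concord <- run_stage("concordance", {
    for (ph in config$phases) {
      inter[[ph]] <- interobserver_reproducible(tbl, ph, config$ccc_cutoff)
      for (r in c("R1", "R2"))
        intra[[paste(r, ph)]] <- intra_phase_reproducible(tbl, r, ph, config$ccc_cutoff)
    }
    for (r in c("R1", "R2")) {
      pairwise[[r]] <- pairwise_sequence_matrix(tbl, r, config$ccc_cutoff)
      utils::write.csv(pairwise[[r]]$counts,
                       file.path(config$out_dir, paste0("pairwise_counts_", r, ".csv")))
      write_pairwise_heatmap(pairwise[[r]]$counts,
                             file.path(config$out_dir, paste0("pairwise_counts_", r, ".png")))
    }
    list(inter = inter, intra = intra, pairwise = pairwise)
  })
  jsonlite::write_json(
    list(interobserver = lapply(concord$inter, function(r)
           names(which(r$reproducible))),
         intraphase = lapply(concord$intra, as.character)),
    file.path(config$out_dir, "reproducible_features.json"),
    auto_unbox = FALSE, pretty = TRUE)

  log_stage("prune + stats + classify (%s, %s)",
            config$classify_radiologist, config$classify_phase)
  result <- run_stage("classify", {
    rsel <- concord$intra[[paste(config$classify_radiologist, config$classify_phase)]]
    if (length(rsel) < 1) stop("no intra-phase reproducible features to model")
    pm <- patient_feature_matrix(tbl, config$classify_radiologist,
                                 config$classify_phase, rsel)
    kept <- if (length(rsel) >= 2)
      prune_correlated(pm$features, config$spearman_threshold) else rsel
    stats_tbl <- grade_descriptive_stats(
      pm$features[, kept, drop = FALSE],
      cohort$manifest$grade[match(pm$patients, cohort$manifest$patient_id)])
    data.table::fwrite(stats_tbl, file.path(config$out_dir, "descriptive_stats.csv"))
    grades <- cohort$manifest$grade[match(pm$patients, cohort$manifest$patient_id)]
    report <- classify_grades(pm$features[, kept, drop = FALSE], grades,
                              seed = derive_seed(config$seed, "classify"))
    jsonlite::write_json(
      list(selected = report$selected, auc = report$auc,
           sensitivity = report$sensitivity, specificity = report$specificity,
           npv = report$npv, ppv = report$ppv,
           pre_prune = length(rsel), post_prune = length(kept)),
      file.path(config$out_dir, "model_report.json"), auto_unbox = TRUE, digits = NA)
    list(pruned = kept, stats = stats_tbl, report = report)
  })

  run_manifest <- list(
    config_hash = digest_config(cfg_echo),
    seed = config$seed,
    rows = list(features = nrow(tbl),
                patients = config$n_patients,
                reproducible_preprune = length(result$pruned)))
  jsonlite::write_json(run_manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, features = tbl, concordance = concord,
                 classification = result))
}

# Stable hash of the config echo (no external digest dependency).
digest_config <- function(cfg) {
  s <- yaml::as.yaml(cfg)
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %% 2147483647
}

#' Per-patient feature matrix for modeling
#'
#' Collapses a long feature table to one value per (patient, feature) for a
#' given radiologist and phase by averaging over the phase's selected
#' sequences.
#'
#' @inheritParams interobserver_reproducible
#' @param radiologist `"R1"` or `"R2"`.
#' @param features Character vector of feature names to keep.
#' @return List with `features` (patients x features matrix) and `patients`.
#' @export
patient_feature_matrix <- function(tbl, radiologist, phase, features) {
  t <- data.table::as.data.table(tbl)
  keep <- t$radiologist == radiologist & t$phase == phase &
    t$feature %in% features
  t <- t[keep, ]
  if (!nrow(t)) stop("patient_feature_matrix: no matching rows")
  agg <- t[, list(value = mean(value)), by = c("patient_id", "feature")]
  wide <- data.table::dcast(agg, patient_id ~ feature, value.var = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$patient_id
  list(features = m[, intersect(features, colnames(m)), drop = FALSE],
       patients = wide$patient_id)
}
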