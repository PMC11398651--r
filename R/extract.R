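#' Extract the full 127-feature radiomic vector
#'
#' Runs every feature-class extractor on one (volume, VOI) pair and returns
#' the features in the fixed registry order. Computation is on the native
#' voxel grid (no resampling); quantised-texture classes share one 25-HU
#' discretisation anchored at the in-mask minimum. A hard failure inside one
#' extractor sets that class's features to `NA` with a warning; if more than
#' 10% of features end up missing the extraction fails.
#'
#' @inheritParams first_order_features
#' @param bin_width Gray-level bin width in HU (default 25).
#' @return Named numeric vector of length 127 (registry order).
#' @seealso [feature_registry()]
#' @export
extract_feature_vector <- function(vol, mask, bin_width = 25) {
  check_geometry(vol, mask)
  reg <- feature_registry()

  # crop once: every feature depends only on the VOI neighbourhood
  bb <- mask_bbox(mask, margin = 16L)
  a <- crop_bbox(as_volume_array(vol), bb)
  m <- crop_bbox(mask, bb)
  v <- image_volume(a, spacing = vol_spacing(vol))

  q <- NULL
  safe <- function(expr) {
    tryCatch(expr, error = function(e) {
      warning("feature extractor failed: ", conditionMessage(e))
      NULL
    })
  }
  q <- safe(discretize_intensities(v, m, bin_width))

  parts <- list(
    safe(first_order_features(v, m, bin_width)),
    if (!is.null(q)) safe(glcm_features(q, m)),
    if (!is.null(q)) safe(run_length_features(q, m)),
    if (!is.null(q)) safe(gtdm_features(q, m)),
    safe(filter_response_features(v, m, "Gabor")),
    safe(filter_response_features(v, m, "Laws")),
    safe(filter_response_features(v, m, "LoG")),
    safe(filter_response_features(v, m, "DWF")),
    safe(sigmoid_boundary_features(v, m)),
    safe(misc_texture_features(v, m)))
  vals <- unlist(Filter(Negate(is.null), parts))

  out <- stats::setNames(rep(NA_real_, nrow(reg)), reg$name)
  hit <- intersect(names(vals), reg$name)
  out[hit] <- vals[hit]
  n_missing <- sum(!is.finite(out))
  if (n_missing > 0.10 * length(out))
    stop("extract_feature_vector: ", n_missing,
         " of 127 features missing (> 10%)")
  out
}

#' Build a long-format feature table from phantom cases
#'
#' Extracts the 127-feature vector for every requested (patient, observer,
#' sequence) combination of a phantom cohort and returns the long-format
#' feature table used by the concordance analyses: one row per (patient_id,
#' radiologist, phase, seq_index, feature).
#'
#' @param cases A list of `phantom_case` objects (see [build_cohort()]).
#' @param observers Character subset of `c("R1", "R2")`.
#' @param sequences Optional integer vector of global sequence indices to
#'   extract (default: the 16 sequences chosen by
#'   [select_phase_sequences()]).
#' @param verbose Print per-patient progress.
#' @return A `data.table` with columns `patient_id`, `radiologist`, `phase`,
#'   `seq_index`, `feature`, `value`.
#' @export
extract_cohort_features <- function(cases, observers = c("R1", "R2"),
                                    sequences = NULL, verbose = FALSE) {
  stopifnot(length(cases) >= 1)
  out <- vector("list", length(cases) * length(observers) * 20L)
  n <- 0L
  for (case in cases) {
    sel <- sequences %||% unlist(select_phase_sequences(case$phase_index))
    for (obs in observers) {
      msk <- if (obs == "R1") case$observer1_mask else case$observer2_mask
      for (s in sel) {
        fv <- extract_feature_vector(case$series[[s]], msk)
        n <- n + 1L
        out[[n]] <- data.table::data.table(
          patient_id = case$patient_id, radiologist = obs,
          phase = case$phases[s], seq_index = as.integer(s),
          feature = names(fv), value = unname(fv))
      }
    }
    if (verbose) message("extracted features for ", case$patient_id)
  }
  data.table::rbindlist(out[seq_len(n)])
}
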