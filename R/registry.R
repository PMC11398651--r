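#' The radiomic feature registry
#'
#' The registry is the single source of truth for the 127 feature names the
#' extractor produces, their feature class (12 classes: first-order
#' statistics, GLCM, run length, GTDM, Gabor, LAW filter, LOG feature,
#' discrete wavelet transform, sigmoid, edge frequency, fractal dimension and
#' spatial correlation) and the voxel set each is computed on (whole VOI,
#' boundary shell, or interior). Names that appear verbatim in published
#' reproducibility tables for this feature set are marked `reconstructed =
#' FALSE`; the remaining members fill each class with its conventional
#' statistics to the documented total of 127 and are flagged `reconstructed =
#' TRUE` in the manifest.
#'
#' @return A `data.frame` with columns `name`, `class`, `extractor`,
#'   `voxel_set` and `reconstructed`, with exactly 127 rows in the canonical
#'   extraction order.
#' @seealso [write_registry_manifest()], [extract_feature_vector()]
#' @export
#' @examples
#' reg <- feature_registry()
#' nrow(reg)            # 127
#' table(reg$class)
feature_registry <- function() {
  if (!is.null(.registry_cache$reg)) return(.registry_cache$reg)
  rows <- list()
  add <- function(name, class, extractor, voxel_set = "whole", reconstructed = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, class = class, extractor = extractor,
      voxel_set = voxel_set, reconstructed = reconstructed,
      stringsAsFactors = FALSE)
  }

  fo_printed <- c("Mean", "Median", "Std", "Variance", "Energy", "Entropy",
                  "Uniformity", "Mean absolute deviation", "Root mean square",
                  "25percent", "75percent", "Maximum", "PeakPosition")
  fo_extra <- c("Minimum", "Skewness", "Kurtosis", "Range",
                "Interquartile range", "10percent", "90percent", "Mode",
                "Total Energy")
  for (f in fo_printed) add(paste("Intensity", f), "First Order Statistics", "first_order")
  for (f in fo_extra)   add(paste("Intensity", f), "First Order Statistics", "first_order",
                            reconstructed = TRUE)

  glcm_printed <- c("Contrast", "Correlation", "Sum Squares", "ASM", "Entropy",
                    "Sum Entropy", "Diff Entropy", "Diff Variance", "IDM",
                    "Homogeneity", "Cluster Tendency", "IMC1", "IMC2", "MCC",
                    "Max Prob")
  glcm_extra <- c("Sum Average", "Sum Variance", "Diff Average",
                  "Autocorrelation", "Cluster Shade", "Cluster Prominence")
  for (f in glcm_printed) add(paste("GLCM", f), "GLCM", "glcm")
  for (f in glcm_extra)   add(paste("GLCM", f), "GLCM", "glcm", reconstructed = TRUE)

  rl_printed <- c("RSR Emphasis", "RLR Emphasis", "RGL Uniformity",
                  "RPL Uniformity", "RHGLR Emphasis", "RLGLR Emphasis",
                  "RSRLGL Emphasis", "RSRHGL Emphasis", "RLRHGL Emphasis",
                  "RLRLGL Emphasis")
  rl_extra <- c("Run Percentage", "Run Entropy", "Run Length Variance",
                "Gray Level Variance")
  for (f in rl_printed) add(f, "Run Length", "run_length")
  for (f in rl_extra)   add(f, "Run Length", "run_length", reconstructed = TRUE)

  add("GTDM Strength", "GTDM", "gtdm")
  add("GTDM Complexity", "GTDM", "gtdm")
  for (f in c("Coarseness", "Busyness", "Contrast"))
    add(paste("GTDM", f), "GTDM", "gtdm", reconstructed = TRUE)

  sets <- c(whole = "", boundary = " Boundary", interior = " NoBoundary")
  gabor_stats <- c("sum", "Max", "Min", "Mean", "Median", "Std")
  for (s in names(sets)) for (g in gabor_stats) {
    nm <- paste0("Gabor ", g, " Z", sets[[s]])
    add(nm, "Gabor", "gabor", voxel_set = s,
        reconstructed = (s == "interior" || g == "Std"))
  }

  for (s in names(sets)) for (k in 1:6) {
    nm <- paste0("Laws ", k, " Z", sets[[s]])
    add(nm, "LAW filter", "laws", voxel_set = s, reconstructed = (s == "whole"))
  }

  for (s in names(sets)) for (f in c("Uniformity", "Entropy", "MGI")) {
    nm <- paste0("LoG Z ", f, sets[[s]])
    add(nm, "LOG feature", "log", voxel_set = s, reconstructed = (s != "whole"))
  }

  for (s in names(sets)) for (f in c("L", "LL", "LLL")) {
    nm <- paste0("DWF Z ", f, sets[[s]])
    add(nm, "Discrete Wavelet Transform", "dwf", voxel_set = s,
        reconstructed = (s != "whole"))
  }

  for (f in c("Amplitude Mean", "Amplitude Std", "Offset Mean", "Offset Std"))
    add(paste("Sigmoid", f), "Sigmoid Feature", "sigmoid", voxel_set = "boundary")
  for (f in c("Width Mean", "Width Std"))
    add(paste("Sigmoid", f), "Sigmoid Feature", "sigmoid", voxel_set = "boundary",
        reconstructed = TRUE)

  add("Edge Frequency", "Edge Frequency", "misc", reconstructed = TRUE)
  add("Edge Frequency Boundary", "Edge Frequency", "misc", voxel_set = "boundary",
      reconstructed = TRUE)
  add("Edge Frequency NoBoundary", "Edge Frequency", "misc", voxel_set = "interior",
      reconstructed = TRUE)
  add("Fractal Dimension", "Fractal Dimension", "misc", reconstructed = TRUE)
  add("Spatial Correlation", "Spatial correlation", "misc")

  reg <- do.call(rbind, rows)
  stopifnot(nrow(reg) == 127L, !anyDuplicated(reg$name))
  .registry_cache$reg <- reg
  reg
}

.registry_cache <- new.env(parent = emptyenv())

#' Write the JSON registry manifest
#'
#' Serialises [feature_registry()] together with the fixed extraction
#' parameters (bin width, GLCM offsets, filter-bank settings, sigmoid ray
#' geometry) so that every feature's definition is documented alongside the
#' extracted values.
#'
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_registry_manifest <- function(path) {
  manifest <- list(
    n_features = 127L,
    bin_width_hu = 25,
    resampling = "none",
    slice_convention = paste(
      "Features suffixed or tagged 'Z' are computed per axial slice in 2D and",
      "aggregated across slices (mean for matrix features, pooled voxels for",
      "filter responses)."),
    glcm = list(distance = 1L, directions = c("0", "45", "90", "135"),
                symmetric = TRUE, aggregation = "feature mean over directions"),
    run_length = list(directions = c("0", "45", "90", "135"),
                      aggregation = "matrix summed over directions per slice"),
    gtdm = list(neighborhood = "3x3 in-plane"),
    gabor = list(orientations = c(0, 45, 90, 135), frequencies = c(0.1, 0.3),
                 sigma_voxels = 2, response = "mean magnitude over bank"),
    laws = list(kernels = c("L5E5", "E5L5", "L5S5", "S5L5", "E5E5", "S5S5"),
                statistic = "mean signed response"),
    log = list(sigma_mm = 2,
               mgi = "mean of the LoG-filtered gray-level intensities in the voxel set",
               histogram = "25-unit bins anchored at the in-set minimum response"),
    dwf = list(wavelet = "Haar low-pass cascade (undecimated, unnormalised)",
               levels = c("L", "LL", "LLL"),
               statistic = "sum of absolute approximation coefficients"),
    sigmoid = list(ray_samples = 11L, ray_step_voxels = 1,
                   model = "a + b / (1 + exp(-(t - c) / w))",
                   fit = "profiled linear least squares over a (c, w) grid",
                   note = "profiles sample peri-lesional voxels outside the VOI"),
    spatial_correlation = paste(
      "4 x mean in-plane lag-1 autocorrelation coefficient over in-mask",
      "neighbouring pairs; saturates at 4 for smooth images"),
    boundary = "VOI minus its one-voxel in-plane erosion; interior = the erosion",
    features = feature_registry()
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
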