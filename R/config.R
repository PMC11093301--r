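#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one validated list:
#' the analysis band (0.01-0.08 Hz, the standard resting-state BOLD band),
#' the number of frequency segments Q used for wavelet coherence, the
#' Morlet parameter, the coherence smoothing windows, the PCA variance
#' threshold, CNN training hyperparameters and the cross-validation setup.
#'
#' @param n_roi number of ROIs per subject (AAL atlas: 116)
#' @param freq_lo,freq_hi analysis band in Hz
#' @param n_bands number of frequency segments Q
#' @param band_spacing `"linear"` (default) or `"log"` segment spacing
#' @param morlet_omega0 Morlet centre frequency (dimensionless, default 6)
#' @param tr sampling interval of the time series in seconds
#' @param smooth_time_factor time boxcar half-width is
#'   `max(3, round(smooth_time_factor * scale))` samples
#' @param smooth_scale_bins boxcar width over scale bins
#' @param smooth_enabled set `FALSE` to disable coherence smoothing
#'   (useful only as a diagnostic: unsmoothed coherence is identically 1)
#' @param pca_variance_threshold fraction of variance the temporal PCA
#'   must retain (default 0.99)
#' @param learning_rate,max_epochs,dropout,leaky_slope,batch_size CNN
#'   training hyperparameters (Adam, cross-entropy head). The default
#'   batch size of 8 keeps the optimizer step count of a desk-scale
#'   cohort (~200 subjects) at the level the 50-epoch budget implies
#'   for a multi-hundred-subject study
#' @param svm_C linear-SVM cost parameter
#' @param n_folds cross-validation folds (default 10)
#' @param seed default master seed
#' @return a validated list with class `"fchybrid_config"`
#' @export
#' @examples
#' cfg <- pipeline_config(n_roi = 20)
#' cfg$n_bands
pipeline_config <- function(n_roi = 116,
                            freq_lo = 0.01,
                            freq_hi = 0.08,
                            n_bands = 40,
                            band_spacing = c("linear", "log"),
                            morlet_omega0 = 6,
                            tr = 2,
                            smooth_time_factor = 0.6,
                            smooth_scale_bins = 3,
                            smooth_enabled = TRUE,
                            pca_variance_threshold = 0.99,
                            learning_rate = 1e-4,
                            max_epochs = 50,
                            dropout = 0.5,
                            leaky_slope = 0.01,
                            batch_size = 8,
                            svm_C = 1,
                            n_folds = 10,
                            seed = 1L) {
  band_spacing <- match.arg(band_spacing)
  cfg <- list(
    n_roi = as.integer(n_roi), freq_lo = freq_lo, freq_hi = freq_hi,
    n_bands = as.integer(n_bands), band_spacing = band_spacing,
    morlet_omega0 = morlet_omega0, tr = tr,
    smooth_time_factor = smooth_time_factor,
    smooth_scale_bins = as.integer(smooth_scale_bins),
    smooth_enabled = isTRUE(smooth_enabled),
    pca_variance_threshold = pca_variance_threshold,
    learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
    dropout = dropout, leaky_slope = leaky_slope,
    batch_size = as.integer(batch_size),
    svm_C = svm_C, n_folds = as.integer(n_folds), seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "fchybrid_config")
}

validate_config <- function(cfg) {
  if (!(cfg$freq_lo > 0 && cfg$freq_lo < cfg$freq_hi)) {
    abort_validation("need 0 < freq_lo < freq_hi (got %g, %g)",
                     cfg$freq_lo, cfg$freq_hi)
  }
  if (cfg$n_bands < 2L) {
    abort_validation("n_bands must be >= 2 (got %d)", cfg$n_bands)
  }
  if (!(cfg$pca_variance_threshold > 0 && cfg$pca_variance_threshold <= 1)) {
    abort_validation("pca_variance_threshold must be in (0, 1]")
  }
  if (cfg$n_folds < 2L) abort_validation("n_folds must be >= 2")
  if (cfg$n_roi < 2L) abort_validation("n_roi must be >= 2")
  if (cfg$tr <= 0) abort_validation("tr must be positive")
  if (cfg$svm_C <= 0) abort_validation("svm_C must be positive")
  if (!(cfg$dropout >= 0 && cfg$dropout < 1)) {
    abort_validation("dropout must be in [0, 1)")
  }
  invisible(cfg)
}

#' Read a configuration file
#'
#' Reads a YAML file whose keys are [pipeline_config()] arguments and
#' merges it with the defaults; `...` overrides both (CLI-style).
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @param ... named overrides applied after the file
#' @return a `"fchybrid_config"` list
#' @export
read_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort_validation("config file not found: %s", path)
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(formals(pipeline_config)))
    if (length(unknown)) {
      abort_schema("unknown config keys: %s", paste(unknown, collapse = ", "))
    }
  }
  dots <- list(...)
  vals[names(dots)] <- dots
  do.call(pipeline_config, vals)
}

#' @export
print.fchybrid_config <- function(x, ...) {
  cat("<fchybrid pipeline config>\n")
  cat(sprintf("  ROIs %d | band %.3g-%.3g Hz in %d segments (%s) | TR %gs\n",
              x$n_roi, x$freq_lo, x$freq_hi, x$n_bands, x$band_spacing, x$tr))
  cat(sprintf("  Morlet omega0 %g | smoothing %s (time factor %g, %d scale bins)\n",
              x$morlet_omega0, if (x$smooth_enabled) "on" else "OFF",
              x$smooth_time_factor, x$smooth_scale_bins))
  cat(sprintf("  PCA threshold %g | CNN lr %g, epochs %d, batch %d, dropout %g\n",
              x$pca_variance_threshold, x$learning_rate, x$max_epochs,
              x$batch_size, x$dropout))
  cat(sprintf("  SVM C %g | %d-fold CV | seed %d\n",
              x$svm_C, x$n_folds, x$seed))
  invisible(x)
}
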