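# Synthetic two-group cohort with planted, recoverable effects:
# band-limited ROI noise, pairwise coupling through a shared narrowband
# latent at chosen ROI pairs, and SRS subscales with a chosen
# standardized group difference.

#' Describe the ground truth of a synthetic cohort
#'
#' Defaults describe the package's reference desk-scale cohort: 20 ROIs,
#' 150 time points at TR = 2 s, 100 subjects per group, one coupled ROI
#' pair whose shared narrowband component lives in 0.04-0.05 Hz, strong
#' coupling contrast (in-band coherence targets 0.9 vs 0.1), and SRS
#' subscales on a T-score-like scale (TC mean 45, SD 10) separated by a
#' standardized difference of 3 -- the separation a screening instrument
#' is designed to give.
#'
#' @param planted_pairs list of length-2 integer vectors (1-based ROI pairs)
#' @param planted_band length-2 numeric, Hz sub-band of the coupling
#' @param coupling_asd,coupling_tc in-band coherence targets in `[0, 1]`
#' @param srs_effect standardized mean difference (ASD - TC) per subscale;
#'   scalar or length 5
#' @param n_asd,n_tc group sizes
#' @param n_roi,t_len,tr cohort dimensions: ROIs, time points, sampling
#'   interval (seconds)
#' @param freq_lo,freq_hi global signal band in Hz
#' @param srs_mean_tc,srs_sd TC subscale mean and common SD
#' @return an object of class `"cohort_truth"`
#' @export
cohort_truth <- function(planted_pairs = list(c(3L, 8L)),
                         planted_band = c(0.04, 0.05),
                         coupling_asd = 0.9,
                         coupling_tc = 0.1,
                         srs_effect = 3,
                         n_asd = 100L, n_tc = 100L,
                         n_roi = 20L, t_len = 150L, tr = 2,
                         freq_lo = 0.01, freq_hi = 0.08,
                         srs_mean_tc = 45, srs_sd = 10) {
  planted_pairs <- lapply(planted_pairs, as.integer)
  for (p in planted_pairs) {
    if (length(p) != 2L || p[1] == p[2]) {
      abort_validation("planted pairs must be two distinct ROI indices")
    }
    if (any(p < 1L) || any(p > n_roi)) {
      abort_validation("planted pair (%d, %d) outside 1..%d", p[1], p[2], n_roi)
    }
  }
  if (!(planted_band[1] >= freq_lo && planted_band[2] <= freq_hi &&
        planted_band[1] < planted_band[2])) {
    abort_validation("planted band [%g, %g] must lie inside [%g, %g] Hz",
                     planted_band[1], planted_band[2], freq_lo, freq_hi)
  }
  for (g in c(coupling_asd, coupling_tc)) {
    if (g < 0 || g > 1) abort_validation("coupling targets must be in [0, 1]")
  }
  if (length(srs_effect) == 1L) srs_effect <- rep(srs_effect, 5L)
  if (length(srs_effect) != 5L) {
    abort_validation("srs_effect must have length 1 or 5")
  }
  structure(list(
    planted_pairs = planted_pairs, planted_band = as.numeric(planted_band),
    coupling_asd = coupling_asd, coupling_tc = coupling_tc,
    srs_effect = as.numeric(srs_effect),
    n_asd = as.integer(n_asd), n_tc = as.integer(n_tc),
    n_roi = as.integer(n_roi), t_len = as.integer(t_len), tr = tr,
    freq_lo = freq_lo, freq_hi = freq_hi,
    srs_mean_tc = srs_mean_tc, srs_sd = srs_sd
  ), class = "cohort_truth")
}

#' Band-limited Gaussian noise
#'
#' White Gaussian noise projected onto the Fourier modes whose frequency
#' lies in `[f_lo, f_hi]`, rescaled to unit variance. All spectral mass
#' outside the band is removed exactly (up to the frequency resolution
#' 1/(T*tr)).
#'
#' @param t_len number of samples
#' @param tr sampling interval (seconds)
#' @param f_lo,f_hi band edges in Hz
#' @return numeric vector of length `t_len` with unit sample variance
#' @export
band_limited_noise <- function(t_len, tr, f_lo, f_hi) {
  x <- stats::rnorm(t_len)
  xf <- stats::fft(x)
  f <- freq_axis(t_len, tr)
  keep <- abs(f) >= f_lo & abs(f) <= f_hi
  if (!any(keep)) {
    abort_validation("band [%g, %g] Hz contains no Fourier mode at T=%d, TR=%g",
                     f_lo, f_hi, t_len, tr)
  }
  xf[!keep] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE)) / t_len
  y / stats::sd(y)
}

freq_axis <- function(t_len, tr) {
  k <- seq_len(t_len) - 1L
  k[k > t_len / 2] <- k[k > t_len / 2] - t_len
  k / (t_len * tr)
}

# Mixing variance fraction w that yields an expected in-band coherence
# of `gamma` when a unit-variance latent confined to a band of width b_p
# is added to unit-variance noise spread over the full band b_t:
# in-band coherence ~ rho^2 with rho = (w/b_p) / (w/b_p + (1-w)/b_t).
coupling_weight <- function(gamma, b_p, b_t) {
  if (gamma <= 0) return(0)
  if (gamma >= 1) return(1)
  rho <- sqrt(gamma)
  c0 <- (rho / (1 - rho)) * (b_p / b_t)
  c0 / (1 + c0)
}

#' Simulate one subject
#'
#' Every ROI signal is unit-variance band-limited noise in the global
#' band; each planted pair additionally shares a latent narrowband
#' component restricted to the planted band, mixed with a weight chosen
#' so the expected coherence inside the band matches the group's
#' coupling target. SRS subscales are Gaussian with the group's mean.
#'
#' @param truth a [cohort_truth()]
#' @param group `"ASD"` or `"TC"`
#' @param seed integer seed; the output is fully reproducible from it
#' @param subject_id identifier (defaults to group + seed)
#' @return list with elements `ts` ([roi_timeseries()]) and `phenotype`
#'   (one-row tibble)
#' @export
simulate_subject <- function(truth, group = c("ASD", "TC"), seed,
                             subject_id = NULL) {
  group <- match.arg(group)
  if (is.null(subject_id)) subject_id <- sprintf("%s_%06d", group, seed)
  gamma <- if (group == "ASD") truth$coupling_asd else truth$coupling_tc
  b_p <- truth$planted_band[2] - truth$planted_band[1]
  b_t <- truth$freq_hi - truth$freq_lo
  w <- coupling_weight(gamma, b_p, b_t)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  sig <- matrix(0, truth$t_len, truth$n_roi)
  for (r in seq_len(truth$n_roi)) {
    sig[, r] <- band_limited_noise(truth$t_len, truth$tr,
                                   truth$freq_lo, truth$freq_hi)
  }
  # total latent variance injected into each ROI must stay below 1
  w_roi <- numeric(truth$n_roi)
  for (p in truth$planted_pairs) w_roi[p] <- w_roi[p] + w
  if (any(w_roi > 1)) {
    abort_validation("total coupling weight exceeds 1 for ROI(s) %s",
                     paste(which(w_roi > 1), collapse = ", "))
  }
  if (w > 0) {
    for (p in truth$planted_pairs) {
      latent <- band_limited_noise(truth$t_len, truth$tr,
                                   truth$planted_band[1], truth$planted_band[2])
      for (r in p) {
        sig[, r] <- sqrt(1 - w) * sig[, r] + sqrt(w) * latent
      }
    }
  }
  ts <- roi_timeseries(sig, subject_id = subject_id, tr = truth$tr)

  mu <- truth$srs_mean_tc +
    (group == "ASD") * truth$srs_effect * truth$srs_sd
  srs <- stats::rnorm(5L, mean = mu, sd = truth$srs_sd)
  phen <- tibble::tibble(subject_id = subject_id,
                         label = as.integer(group == "ASD"))
  for (i in seq_along(SRS_SUBSCALES)) {
    phen[[paste0("srs_", SRS_SUBSCALES[i])]] <- srs[i]
  }
  list(ts = ts, phenotype = phen)
}

#' Simulate a full two-group cohort
#'
#' Generates `n_asd + n_tc` subjects with disjoint per-subject seeds
#' derived from the master seed. With `out_dir` set, writes one TSV per
#' subject plus `manifest.csv`, `phenotypes.csv` and `truth.json`; the
#' in-memory cohort is returned either way.
#'
#' @param truth a [cohort_truth()]
#' @param seed master seed
#' @param out_dir optional output directory
#' @return list of class `"fc_cohort"` with elements `subjects` (list of
#'   [roi_timeseries()]), `phenotypes` (tibble), `truth`, and (when
#'   written) `manifest`
#' @export
simulate_cohort <- function(truth, seed, out_dir = NULL) {
  if (truth$n_asd < 1L || truth$n_tc < 1L) {
    abort_validation("need at least one subject per group")
  }
  groups <- c(rep("ASD", truth$n_asd), rep("TC", truth$n_tc))
  ids <- sprintf("%s_%03d", tolower(groups),
                 c(seq_len(truth$n_asd), seq_len(truth$n_tc)))
  subjects <- vector("list", length(groups))
  phen <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    s <- simulate_subject(truth, groups[i], seed = derive_seed(seed, i),
                          subject_id = ids[i])
    subjects[[i]] <- s$ts
    phen[[i]] <- s$phenotype
  }
  phenotypes <- dplyr::bind_rows(phen)
  out <- structure(list(subjects = subjects, phenotypes = phenotypes,
                        truth = truth, seed = as.integer(seed)),
                   class = "fc_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, paste0(ids, ".tsv"))
    for (i in seq_along(subjects)) {
      ok <- tryCatch({
        utils::write.table(subjects[[i]]$data, paths[i], sep = "\t",
                           row.names = FALSE, col.names = FALSE)
        TRUE
      }, error = function(e) e)
      if (!isTRUE(ok)) {
        abort_validation("failed writing %s: %s", paths[i],
                         conditionMessage(ok))
      }
    }
    manifest <- tibble::tibble(subject_id = ids, path = paths)
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    readr::write_csv(phenotypes, file.path(out_dir, "phenotypes.csv"))
    jsonlite::write_json(truth_to_list(truth),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out$manifest <- manifest
  }
  out
}

truth_to_list <- function(truth) {
  x <- unclass(truth)
  x$planted_pairs <- lapply(x$planted_pairs, as.integer)
  x
}

#' Read a planted-truth JSON back into a `cohort_truth`
#'
#' @param path `truth.json` written by [simulate_cohort()]
#' @return a [cohort_truth()]
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_truth(
    planted_pairs = if (is.matrix(x$planted_pairs)) {
      lapply(seq_len(nrow(x$planted_pairs)), function(i) x$planted_pairs[i, ])
    } else lapply(x$planted_pairs, unlist),
    planted_band = x$planted_band,
    coupling_asd = x$coupling_asd, coupling_tc = x$coupling_tc,
    srs_effect = x$srs_effect, n_asd = x$n_asd, n_tc = x$n_tc,
    n_roi = x$n_roi, t_len = x$t_len, tr = x$tr,
    freq_lo = x$freq_lo, freq_hi = x$freq_hi,
    srs_mean_tc = x$srs_mean_tc, srs_sd = x$srs_sd
  )
}

#' Read a cohort from a manifest written by [simulate_cohort()]
#'
#' @param manifest_path `manifest.csv` (columns `subject_id`, `path`)
#' @param phenotypes_path phenotype CSV
#' @param config a [pipeline_config()]
#' @return an `"fc_cohort"` list (without truth)
#' @export
read_cohort <- function(manifest_path, phenotypes_path, config) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  if (!all(c("subject_id", "path") %in% names(manifest))) {
    abort_schema("manifest must have subject_id and path columns")
  }
  phenotypes <- read_phenotypes(phenotypes_path)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(dirname(manifest_path), basename(p))
    read_roi_timeseries(p, config, subject_id = manifest$subject_id[i])
  })
  structure(list(subjects = subjects, phenotypes = phenotypes,
                 manifest = manifest),
            class = "fc_cohort")
}
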