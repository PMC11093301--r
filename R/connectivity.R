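# Static and dynamic functional connectivity.
#
# Static FC is the Pearson correlation matrix of the ROI time series.
# Dynamic FC is the Morlet wavelet coherence of every ROI pair
# (Q scales x T time points), reduced over time by PCA: the pair's
# Q-vector stored in the tensor is the leading column of the projection
# of the scale-covariance matrix onto its eigenvectors.

#' Static functional connectivity (Pearson)
#'
#' @param ts a [roi_timeseries()]
#' @return object of class `"static_fc"`: list with `matrix` (R x R,
#'   symmetric, unit diagonal) and `subject_id`
#' @export
static_fc <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  v <- apply(ts$data, 2L, stats::var)
  if (any(v == 0)) {
    abort_validation("static_fc %s: zero-variance ROI column(s) %s",
                     ts$subject_id, paste(which(v == 0), collapse = ", "))
  }
  m <- stats::cor(ts$data)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  structure(list(matrix = unname(m), subject_id = ts$subject_id),
            class = "static_fc")
}

#' Frequency grid for the wavelet analysis
#'
#' Partitions `[freq_lo, freq_hi]` into Q contiguous segments (linear by
#' default, log optional), takes segment midpoints as centre frequencies,
#' and converts centres to Morlet scales (in samples) via
#' `f = omega0 / (2 * pi * s * tr)`.
#'
#' @param config a [pipeline_config()]
#' @return object of class `"frequency_grid"`: `centers` (Hz, increasing),
#'   `edges` (Hz, length Q+1), `scales` (samples, decreasing), plus the
#'   `tr` and `omega0` they were built with
#' @export
frequency_grid <- function(config) {
  q <- config$n_bands
  if (q < 2L) abort_validation("frequency grid needs Q >= 2 (got %d)", q)
  edges <- switch(config$band_spacing,
    linear = seq(config$freq_lo, config$freq_hi, length.out = q + 1L),
    log = exp(seq(log(config$freq_lo), log(config$freq_hi),
                  length.out = q + 1L))
  )
  centers <- (edges[-1] + edges[-(q + 1L)]) / 2
  scales <- config$morlet_omega0 / (2 * pi * centers * config$tr)
  structure(list(centers = centers, edges = edges, scales = scales,
                 tr = config$tr, omega0 = config$morlet_omega0),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid: %d bands, %.4g-%.4g Hz, omega0 %g, TR %gs>\n",
              length(x$centers), x$edges[1], x$edges[length(x$edges)],
              x$omega0, x$tr))
  invisible(x)
}

#' Continuous Morlet wavelet transform
#'
#' Evaluates the CWT of one signal at the grid's Q scales and all T
#' translations by frequency-domain multiplication with the analytic
#' Morlet kernel (`pi^(-1/4) * exp(i*omega0*t) * exp(-t^2/2)`), using
#' zero padding to the next power of two.
#'
#' @param x numeric vector of length T
#' @param grid a [frequency_grid()]
#' @param config a [pipeline_config()]
#' @return complex Q x T matrix; row q corresponds to `grid$centers[q]`
#' @export
morlet_cwt <- function(x, grid, config) {
  if (anyNA(x) || any(!is.finite(x))) {
    abort_validation("morlet_cwt: input signal must be finite")
  }
  t_len <- length(x)
  max_scale <- max(grid$scales)
  if (t_len < 2 * max_scale) {
    warning(sprintf(
      "morlet_cwt: T=%d is short relative to the largest scale (%.1f samples); edge effects will be strong",
      t_len, max_scale), call. = FALSE)
  }
  n_pad <- 2^ceiling(log2(2 * t_len))
  xf <- stats::fft(c(x, rep(0, n_pad - t_len)))
  # angular frequencies in rad/sample
  k <- seq_len(n_pad) - 1L
  k[k > n_pad / 2] <- k[k > n_pad / 2] - n_pad
  om <- 2 * pi * k / n_pad
  w <- matrix(0i, length(grid$scales), t_len)
  for (q in seq_along(grid$scales)) {
    s <- grid$scales[q]                       # in samples
    psi_hat <- pi^(-0.25) * sqrt(2 * pi * s) * exp(-((s * om - grid$omega0)^2) / 2)
    psi_hat[om <= 0] <- 0                     # analytic wavelet
    wq <- stats::fft(xf * psi_hat, inverse = TRUE) / n_pad
    w[q, ] <- wq[seq_len(t_len)]
  }
  w
}

#' Cross-wavelet spectrum
#'
#' Elementwise `Wx * Conj(Wy)`; its modulus is the cross-wavelet power
#' locating common high-power regions of the two signals.
#'
#' @param wx,wy complex Q x T coefficient matrices from [morlet_cwt()]
#' @return complex Q x T matrix
#' @export
cross_wavelet <- function(wx, wy) {
  if (!all(dim(wx) == dim(wy))) {
    abort_dimension("cross_wavelet: shapes %s vs %s differ",
                    paste(dim(wx), collapse = "x"),
                    paste(dim(wy), collapse = "x"))
  }
  wx * Conj(wy)
}

# Precompute the smoothing plan for a (grid, T) combination: per-scale
# boxcar widths in time, the reflective padding index map, and the
# scale-direction averaging matrix. The same linear operator is applied
# to numerator and denominators of the coherence, which is what keeps
# the coherence in [0, 1] (Cauchy-Schwarz for positive-weight averages).
smoothing_plan <- function(grid, t_len, config) {
  widths <- pmax(3L, as.integer(round(config$smooth_time_factor * grid$scales)))
  widths <- pmin(widths, 2L * t_len - 1L)
  max_h <- max(widths %/% 2L + 1L)
  # reflective (mirror, no repeat) padding index for the longest overhang
  idx <- c(rev(seq_len(max_h) + 1L), seq_len(t_len),
           t_len - seq_len(max_h))
  idx <- pmin(pmax(idx, 1L), t_len)
  nb <- config$smooth_scale_bins
  q <- length(grid$scales)
  ms <- matrix(0, q, q)
  h1 <- (nb - 1L) %/% 2L
  h2 <- nb - 1L - h1
  for (i in seq_len(q)) {
    j <- (i - h1):(i + h2)
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > q, 2L * q - j, j)
    j <- pmin(pmax(j, 1L), q)
    for (jj in j) ms[i, jj] <- ms[i, jj] + 1 / nb
  }
  list(widths = widths, pad_idx = idx, max_h = max_h, scale_op = ms)
}

smooth_rows_time <- function(map, plan) {
  t_len <- ncol(map)
  out <- map
  for (q in seq_len(nrow(map))) {
    w <- plan$widths[q]
    h1 <- (w - 1L) %/% 2L
    h2 <- w - 1L - h1
    padded <- map[q, plan$pad_idx]
    cs <- cumsum(padded)
    # position t in original series sits at plan$max_h + t in padded
    lo <- plan$max_h + seq_len(t_len) - h1 - 1L
    hi <- plan$max_h + seq_len(t_len) + h2
    out[q, ] <- (cs[hi] - cs[lo]) / w
  }
  out
}

#' Time-frequency smoothing operator
#'
#' Separable moving average: a boxcar in time whose width grows with the
#' wavelet scale (`max(3, round(factor * scale))` samples, reflective
#' edges), followed by a boxcar over scale bins. Linear, positive, and
#' exact on constant maps. With `config$smooth_enabled = FALSE` this is
#' the identity.
#'
#' @param map real or complex Q x T matrix
#' @param grid a [frequency_grid()]
#' @param config a [pipeline_config()]
#' @return smoothed matrix of the same shape
#' @export
smooth_tf <- function(map, grid, config) {
  if (!isTRUE(config$smooth_enabled)) return(map)
  if (nrow(map) != length(grid$scales)) {
    abort_dimension("smooth_tf: map has %d rows, grid has %d scales",
                    nrow(map), length(grid$scales))
  }
  plan <- smoothing_plan(grid, ncol(map), config)
  plan$scale_op %*% smooth_rows_time(map, plan)
}

#' Wavelet coherence of two signals
#'
#' `R_xy = |S(Wx * Conj(Wy))|^2 / (S(|Wx|^2) * S(|Wy|^2))` with the
#' moving-average smoother `S` of [smooth_tf()]. Values are clipped to
#' `[0, 1]` only to absorb floating error (<= 1e-9 by construction).
#' Without smoothing the map is identically 1 for any pair -- the
#' degenerate identity that makes the smoother necessary.
#'
#' @param x,y numeric T-vectors (same length)
#' @param grid a [frequency_grid()]
#' @param config a [pipeline_config()]
#' @return real Q x T matrix in `[0, 1]`
#' @export
wavelet_coherence <- function(x, y, grid, config) {
  if (length(x) != length(y)) {
    abort_dimension("wavelet_coherence: lengths %d vs %d", length(x), length(y))
  }
  wx <- morlet_cwt(x, grid, config)
  wy <- morlet_cwt(y, grid, config)
  plan <- if (isTRUE(config$smooth_enabled)) {
    smoothing_plan(grid, length(x), config)
  } else NULL
  sxx <- smooth_power(wx, plan)
  syy <- smooth_power(wy, plan)
  coherence_from_cwt(wx, wy, sxx, syy, plan)
}

smooth_power <- function(w, plan) {
  p <- Re(w * Conj(w))
  if (is.null(plan)) return(p)
  plan$scale_op %*% smooth_rows_time(p, plan)
}

coherence_from_cwt <- function(wx, wy, sxx, syy, plan) {
  cw <- wx * Conj(wy)
  scw <- if (is.null(plan)) cw else plan$scale_op %*% smooth_rows_time(cw, plan)
  den <- sxx * syy
  if (any(den <= 0)) {
    bad <- which(den <= 0, arr.ind = TRUE)[1, ]
    abort_validation("wavelet coherence: zero power at scale %d, time %d",
                     bad[1], bad[2])
  }
  r <- Re(scw * Conj(scw)) / den
  if (any(r > 1 + 1e-9) || any(r < -1e-9)) {
    abort_validation("wavelet coherence left [0,1] beyond floating tolerance (max %.3g)",
                     max(r))
  }
  pmin(pmax(r, 0), 1)
}

#' Temporal PCA reduction of a coherence map
#'
#' Implements the eigen-reduction over time: remove the mean time column
#' from `WC` (Q x T), build `C = WChat %*% t(WChat) / T`, eigendecompose,
#' keep the smallest k whose cumulative eigenvalue fraction reaches the
#' variance threshold, and project: `XP = C %*% P = P %*% diag(lambda)`
#' (Q x k). Eigenvector signs are fixed so each component's entry sum is
#' non-negative (ties: first nonzero entry positive).
#'
#' @param wc real Q x T matrix (a [wavelet_coherence()] map)
#' @param config a [pipeline_config()]
#' @return list: `components` (Q x k projection), `vectors` (Q x k unit
#'   eigenvectors, sign-fixed), `values` (all eigenvalues), `k`,
#'   `variance_retained`
#' @export
pca_reduce_time <- function(wc, config) {
  if (anyNA(wc) || any(!is.finite(wc))) {
    abort_validation("pca_reduce_time: non-finite input")
  }
  n <- ncol(wc)
  xhat <- wc - rowMeans(wc)
  cmat <- (xhat %*% t(xhat)) / n
  ee <- eigen(cmat, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  total <- sum(lam)
  if (total <= 0) {
    # constant map: demeaning leaves nothing; projection is zero
    q <- nrow(wc)
    return(list(components = matrix(0, q, 1L),
                vectors = matrix(c(1, rep(0, q - 1L)), q, 1L),
                values = lam, k = 1L, variance_retained = 1))
  }
  frac <- cumsum(lam) / total
  k <- which(frac >= config$pca_variance_threshold)[1]
  vec <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(vec[, j])
    if (s < 0 || (s == 0 && vec[which(vec[, j] != 0)[1], j] < 0)) {
      vec[, j] <- -vec[, j]
    }
  }
  comps <- sweep(vec, 2L, lam[seq_len(k)], `*`)
  list(components = comps, vectors = vec, values = lam, k = k,
       variance_retained = frac[k])
}

#' Dynamic functional connectivity tensor
#'
#' For every unordered ROI pair, computes the wavelet coherence map and
#' its temporal PCA reduction, and stores the leading component
#' (a Q-vector) at `[i, j, ]` and `[j, i, ]`. The diagonal is zero: a
#' self-coherence map is constant 1, so its demeaned projection
#' vanishes. Per-pair minimal k and retained variance are recorded; a
#' single warning lists pairs where the variance rule needed k > 1
#' (only the first component is stored regardless, keeping the tensor
#' shape fixed at R x R x Q).
#'
#' @param ts a [roi_timeseries()]
#' @param grid a [frequency_grid()]
#' @param config a [pipeline_config()]
#' @return object of class `"dynamic_fc"`: `tensor` (R x R x Q),
#'   `k_used` and `variance_retained` (R x R matrices), `subject_id`
#' @export
dynamic_fc <- function(ts, grid, config) {
  stopifnot(inherits(ts, "roi_timeseries"))
  r <- ncol(ts$data)
  t_len <- nrow(ts$data)
  q <- length(grid$centers)
  plan <- if (isTRUE(config$smooth_enabled)) {
    smoothing_plan(grid, t_len, config)
  } else NULL
  w_list <- vector("list", r)
  s_list <- vector("list", r)
  for (i in seq_len(r)) {
    w_list[[i]] <- withCallingHandlers(
      morlet_cwt(ts$data[, i], grid, config),
      warning = function(w) if (i > 1L) invokeRestart("muffleWarning")
    )
    s_list[[i]] <- smooth_power(w_list[[i]], plan)
  }
  tensor <- array(0, dim = c(r, r, q))
  k_used <- matrix(1L, r, r)
  var_ret <- matrix(1, r, r)
  multi_k <- character(0)
  for (i in seq_len(r - 1L)) {
    for (j in (i + 1L):r) {
      wc <- tryCatch(
        coherence_from_cwt(w_list[[i]], w_list[[j]],
                           s_list[[i]], s_list[[j]], plan),
        error = function(e) {
          abort_validation("dynamic_fc %s, pair (%d, %d): %s",
                           ts$subject_id, i, j, conditionMessage(e))
        }
      )
      red <- pca_reduce_time(wc, config)
      tensor[i, j, ] <- red$components[, 1L]
      tensor[j, i, ] <- red$components[, 1L]
      k_used[i, j] <- k_used[j, i] <- red$k
      var_ret[i, j] <- var_ret[j, i] <- red$variance_retained
      if (red$k > 1L) multi_k <- c(multi_k, sprintf("(%d,%d)", i, j))
    }
  }
  if (length(multi_k)) {
    warning(sprintf(
      "dynamic_fc %s: %d pair(s) needed k > 1 to reach the variance threshold (first component stored): %s",
      ts$subject_id, length(multi_k),
      paste(utils::head(multi_k, 10L), collapse = " ")), call. = FALSE)
  }
  structure(list(tensor = tensor, k_used = k_used,
                 variance_retained = var_ret, subject_id = ts$subject_id),
            class = "dynamic_fc")
}

#' Compute both connectomes for every subject of a cohort
#'
#' @param cohort an `"fc_cohort"` (from [simulate_cohort()] or
#'   [read_cohort()])
#' @param config a [pipeline_config()]
#' @param quiet suppress per-subject progress
#' @return list of [subject_record()]s
#' @export
compute_connectivity <- function(cohort, config, quiet = TRUE) {
  grid <- frequency_grid(config)
  phen <- cohort$phenotypes
  lapply(seq_along(cohort$subjects), function(i) {
    ts <- cohort$subjects[[i]]
    if (!quiet) message(sprintf("connectivity %d/%d (%s)",
                                i, length(cohort$subjects), ts$subject_id))
    subject_record(
      phenotype = phen[phen$subject_id == ts$subject_id, , drop = FALSE],
      static_fc = static_fc(ts),
      dynamic_fc = dynamic_fc(ts, grid, config)
    )
  })
}
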