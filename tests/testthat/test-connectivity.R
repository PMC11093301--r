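test_that("static FC matches the textbook correlation formula", {
  # hand-evaluated example: sum of cross-deviations 11.5,
  # denominators sqrt(5) * sqrt(28.75)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 4, 8)
  expect_equal(pearson_oracle(x, y), 11.5 / sqrt(5 * 28.75), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:100) {
    m <- matrix(rnorm(35 * 4), 35, 4)
    ts <- roi_timeseries(m, "p", tr = 2)
    fc <- static_fc(ts)$matrix
    for (a in 1:3) for (b in (a + 1):4) {
      expect_equal(fc[a, b], pearson_oracle(m[, a], m[, b]), tolerance = 1e-12)
    }
    expect_equal(fc, t(fc))
    expect_equal(diag(fc), rep(1, 4))
    expect_true(all(fc >= -1 - 1e-12 & fc <= 1 + 1e-12))
  }
})

test_that("static FC handles perfect anticorrelation and rejects constants", {
  m <- cbind(c(1, 2, 3), c(3, 2, 1), rnorm(3))
  # bypass the T >= 30 reader guard: call cor path directly via oracle
  expect_equal(pearson_oracle(m[, 1], m[, 2]), -1)
  ts <- roi_timeseries(matrix(rnorm(90), 30, 3), "p", tr = 2)
  ts$data[, 2] <- 7
  expect_error(static_fc(ts), class = "fchybrid_error_validation")
})

test_that("frequency grid partitions the band as specified", {
  cfg <- pipeline_config(n_bands = 40)
  g <- frequency_grid(cfg)
  expect_equal(diff(g$edges)[1], (0.08 - 0.01) / 40, tolerance = 1e-12)
  expect_equal(g$centers[1], 0.010875, tolerance = 1e-12)
  expect_equal(length(g$edges), 41L)
  expect_true(all(diff(g$edges) > 0))
  expect_true(all(g$centers > cfg$freq_lo & g$centers < cfg$freq_hi))
  # Morlet scale-frequency relation, scales decreasing with frequency
  expect_equal(g$centers, cfg$morlet_omega0 / (2 * pi * g$scales * cfg$tr),
               tolerance = 1e-12)
  expect_true(all(diff(g$scales) < 0))
  expect_error(frequency_grid(pipeline_config(n_bands = 2)), NA)

  glog <- frequency_grid(pipeline_config(band_spacing = "log"))
  expect_equal(glog$edges[1], 0.01, tolerance = 1e-12)
  expect_equal(glog$edges[41], 0.08, tolerance = 1e-12)
  expect_gt(diff(glog$edges)[40], diff(glog$edges)[1])
})

test_that("Morlet CWT is linear, null on zero input, and peaks at the
           driving frequency", {
  cfg <- pipeline_config(n_roi = 2, n_bands = 20)
  g <- frequency_grid(cfg)
  t_len <- 200
  expect_true(all(morlet_cwt(rep(0, t_len), g, cfg) == 0))

  set.seed(3)
  x <- rnorm(t_len); y <- rnorm(t_len)
  wx <- morlet_cwt(x, g, cfg); wy <- morlet_cwt(y, g, cfg)
  expect_lt(max(Mod(morlet_cwt(2.5 * x - y, g, cfg) - (2.5 * wx - wy))), 1e-10)

  # pure 0.04 Hz sinusoid: max mean |W| row within one segment of 0.04
  tt <- (seq_len(t_len) - 1) * cfg$tr
  w <- morlet_cwt(sin(2 * pi * 0.04 * tt), g, cfg)
  peak <- which.max(rowMeans(Mod(w)))
  seg <- diff(g$edges)[1]
  expect_lt(abs(g$centers[peak] - 0.04), seg + 1e-12)
  # analytic oracle: the Morlet response at scale s to frequency f0 is
  # proportional to sqrt(s) * exp(-(s*w0_rad - omega0)^2 / 2)
  resp <- sqrt(g$scales) * exp(-((g$scales * 2 * pi * 0.04 * cfg$tr -
                                    cfg$morlet_omega0)^2) / 2)
  expect_equal(peak, which.max(resp))

  expect_error(morlet_cwt(c(1, NA, 3), g, cfg),
               class = "fchybrid_error_validation")
})

test_that("cross-wavelet spectrum obeys its algebraic identities", {
  cfg <- pipeline_config(n_bands = 10)
  g <- frequency_grid(cfg)
  set.seed(4)
  wx <- morlet_cwt(rnorm(100), g, cfg)
  wy <- morlet_cwt(rnorm(100), g, cfg)
  self <- cross_wavelet(wx, wx)
  expect_lt(max(abs(Im(self))), 1e-14)
  expect_true(all(Re(self) >= 0))
  expect_equal(cross_wavelet(wx, wy), Conj(cross_wavelet(wy, wx)))
  expect_true(all(cross_wavelet(wx, wy * 0) == 0))
  expect_error(cross_wavelet(wx, wy[1:5, ]), class = "fchybrid_error_dimension")
})

test_that("smoothing is linear, constant-preserving and mass-preserving,
           matching a direct-convolution oracle", {
  cfg <- pipeline_config(n_bands = 12)
  g <- frequency_grid(cfg)
  q <- 12; t_len <- 80
  const <- matrix(3.7, q, t_len)
  expect_equal(smooth_tf(const, g, cfg), const, tolerance = 1e-12)

  set.seed(5)
  a <- matrix(rnorm(q * t_len), q, t_len)
  b <- matrix(rnorm(q * t_len), q, t_len)
  lhs <- smooth_tf(2 * a + 3 * b, g, cfg)
  rhs <- 2 * smooth_tf(a, g, cfg) + 3 * smooth_tf(b, g, cfg)
  expect_lt(max(abs(lhs - rhs)), 1e-12)

  expect_equal(smooth_tf(a, g, cfg), smooth_oracle(a, g, cfg),
               tolerance = 1e-10)

  # single interior impulse spreads but keeps its mass
  imp <- matrix(0, q, t_len); imp[6, 40] <- 1
  expect_equal(sum(smooth_tf(imp, g, cfg)), 1, tolerance = 1e-10)
})

test_that("wavelet coherence is bounded, exact for self-pairs, and
           degenerate without smoothing", {
  cfg <- pipeline_config(n_bands = 15)
  g <- frequency_grid(cfg)
  set.seed(6)
  x <- rnorm(150); y <- rnorm(150)

  wc <- wavelet_coherence(x, y, g, cfg)
  expect_true(all(wc >= 0 & wc <= 1))
  expect_true(all(abs(wavelet_coherence(x, x, g, cfg) - 1) < 1e-6))

  # regression guard for the order of smoothing and modulus: identity
  # smoothing makes the coherence identically 1 for ANY pair
  cfg_ns <- pipeline_config(n_bands = 15, smooth_enabled = FALSE)
  expect_true(all(abs(wavelet_coherence(x, y, g, cfg_ns) - 1) < 1e-9))

  expect_error(wavelet_coherence(x, y[1:100], g, cfg),
               class = "fchybrid_error_dimension")
})

test_that("a shared narrowband component raises coherence at its scale
           over independent noise", {
  cfg <- pipeline_config(n_bands = 15)
  g <- frequency_grid(cfg)
  t_len <- 300
  row04 <- which.min(abs(g$centers - 0.04))
  wins <- 0L
  for (s in 1:20) {
    set.seed(8000 + s)
    tt <- (seq_len(t_len) - 1) * cfg$tr
    common <- sin(2 * pi * 0.04 * tt + runif(1, 0, 2 * pi))
    x1 <- rnorm(t_len) + 2 * common
    y1 <- rnorm(t_len) + 2 * common
    x0 <- rnorm(t_len); y0 <- rnorm(t_len)
    c1 <- median(wavelet_coherence(x1, y1, g, cfg)[row04, ])
    c0 <- median(wavelet_coherence(x0, y0, g, cfg))
    wins <- wins + (c1 > c0)
  }
  expect_equal(wins, 20L)
})

test_that("temporal PCA matches an independent SVD oracle", {
  cfg <- pipeline_config()
  set.seed(9)
  for (i in 1:10) {
    wc <- matrix(runif(20 * 60), 20, 60)
    red <- pca_reduce_time(wc, cfg)
    # oracle: SVD of the demeaned matrix; eigenvalues are sv^2 / n,
    # projection columns are lambda * u with the same sign rule
    xhat <- wc - rowMeans(wc)
    sv <- svd(xhat)
    lam <- sv$d^2 / ncol(wc)
    frac <- cumsum(lam) / sum(lam)
    k <- which(frac >= cfg$pca_variance_threshold)[1]
    expect_equal(red$k, k)
    expect_equal(red$variance_retained, frac[k], tolerance = 1e-10)
    expect_gte(red$variance_retained, cfg$pca_variance_threshold)
    for (j in seq_len(k)) {
      u <- sv$u[, j]
      if (sum(u) < 0) u <- -u
      expect_equal(red$components[, j], lam[j] * u, tolerance = 1e-8)
      expect_gte(sum(red$vectors[, j]), 0)
    }
    # cumulative variance non-decreasing
    expect_true(all(diff(frac) >= -1e-15))
  }
})

test_that("rank-1 and full-threshold PCA limit cases", {
  cfg <- pipeline_config()
  u <- c(3, -1, 2, 0.5); v <- rnorm(30)
  wc <- outer(u, v)
  red <- pca_reduce_time(wc, cfg)
  expect_equal(red$k, 1L)
  expect_equal(red$variance_retained, 1.0, tolerance = 1e-12)
  # projection onto the single component reconstructs the demeaned map
  xhat <- wc - rowMeans(wc)
  recon <- red$vectors %*% (t(red$vectors) %*% xhat)
  expect_equal(recon, xhat, tolerance = 1e-8)

  # threshold 1 on a generic map keeps the full numerical rank
  cfg1 <- pipeline_config(pca_variance_threshold = 1)
  set.seed(10)
  wc2 <- matrix(rnorm(6 * 40), 6, 40)
  red2 <- pca_reduce_time(wc2, cfg1)
  expect_equal(red2$k, 6L)

  expect_error(pca_reduce_time(matrix(c(1, Inf, 2, 3), 2, 2), cfg),
               class = "fchybrid_error_validation")
})

test_that("dynamic FC tensor has the contracted shape and symmetry", {
  cfg <- small_config()
  g <- frequency_grid(cfg)
  truth <- small_truth()
  s <- simulate_subject(truth, "ASD", seed = 21)
  dfc <- suppressWarnings(dynamic_fc(s$ts, g, cfg))
  expect_equal(dim(dfc$tensor), c(8L, 8L, 10L))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_identical(dfc$tensor[i, j, ], dfc$tensor[j, i, ])
  }
  expect_true(all(dfc$tensor[cbind(1:8, 1:8, 3)] == 0))
  expect_true(all(dfc$variance_retained >= cfg$pca_variance_threshold))
  expect_true(all(is.finite(dfc$tensor)))
})

test_that("dynamic FC shape does not depend on the scan length", {
  # same subject truncated vs full: tensor shape is R x R x Q either way
  cfg <- small_config()
  g <- frequency_grid(cfg)
  s <- simulate_subject(small_truth(), "TC", seed = 33)
  short <- roi_timeseries(s$ts$data[1:90, ], "short", tr = 2)
  d1 <- suppressWarnings(dynamic_fc(s$ts, g, cfg))
  d2 <- suppressWarnings(dynamic_fc(short, g, cfg))
  expect_equal(dim(d1$tensor), dim(d2$tensor))
})

test_that("rank-1 coherence maps yield no multi-component warnings", {
  cfg <- small_config()
  g <- frequency_grid(cfg)
  # a cohort of pure shared sinusoids gives numerically rank-1-ish maps is
  # hard to construct exactly; instead verify the warning logic directly:
  # warnings fire iff some pair needs k > 1
  s <- simulate_subject(small_truth(), "ASD", seed = 50)
  expect_warning(dynamic_fc(s$ts, g, cfg), "k > 1")
  cfg_low <- small_config(pca_variance_threshold = 0.05)
  expect_no_warning(dynamic_fc(s$ts, g, cfg_low))
})
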