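# Shared fixtures, built in code. Heavy intermediates are cached per
# test process so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_config <- function(...) {
  pipeline_config(n_roi = 8, n_bands = 10, n_folds = 3, ...)
}

# A small two-group cohort with a strongly coupled planted pair.
small_truth <- function(n_asd = 12, n_tc = 12, ...) {
  cohort_truth(n_roi = 8, n_asd = n_asd, n_tc = n_tc,
               planted_pairs = list(c(2L, 5L)), ...)
}

small_records <- function() {
  cached("small_records", {
    cfg <- small_config()
    co <- simulate_cohort(small_truth(), seed = 2024)
    suppressWarnings(compute_connectivity(co, cfg))
  })
}

small_cohort <- function() {
  cached("small_cohort", simulate_cohort(small_truth(), seed = 2024))
}

# Plain-text time-series fixture on disk
write_ts_fixture <- function(mat, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "subj.tsv")
  utils::write.table(mat, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  path
}

# Independent hand-rolled Pearson correlation (the textbook formula),
# used as an oracle against the implementation.
pearson_oracle <- function(x, y) {
  num <- sum((x - mean(x)) * (y - mean(y)))
  num / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Independent direct-convolution smoother: same reflective boxcar
# definition as the implementation but computed by explicit loops.
smooth_oracle <- function(map, grid, config) {
  q <- nrow(map); t_len <- ncol(map)
  widths <- pmax(3L, as.integer(round(config$smooth_time_factor * grid$scales)))
  widths <- pmin(widths, 2L * t_len - 1L)
  reflect <- function(i, n) {
    i <- ifelse(i < 1L, 2L - i, i)
    i <- ifelse(i > n, 2L * n - i, i)
    pmin(pmax(i, 1L), n)
  }
  tsm <- map
  for (qq in seq_len(q)) {
    w <- widths[qq]
    h1 <- (w - 1L) %/% 2L
    h2 <- w - 1L - h1
    for (tt in seq_len(t_len)) {
      idx <- reflect((tt - h1):(tt + h2), t_len)
      tsm[qq, tt] <- mean(map[qq, idx])
    }
  }
  out <- tsm
  nb <- config$smooth_scale_bins
  h1 <- (nb - 1L) %/% 2L
  h2 <- nb - 1L - h1
  for (tt in seq_len(t_len)) {
    for (qq in seq_len(q)) {
      idx <- reflect((qq - h1):(qq + h2), q)
      out[qq, tt] <- mean(tsm[idx, tt])
    }
  }
  out
}
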