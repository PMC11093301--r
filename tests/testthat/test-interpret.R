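make_static_model <- function(r = 8, seed = 1) {
  cfg <- pipeline_config(n_roi = r)
  arch <- build_branch("static", cfg, n_roi = r)
  structure(list(arch = arch, weights = fchybrid:::init_weights(arch, seed)),
            class = "trained_extractor")
}

make_dynamic_model <- function(r = 8, q = 10, seed = 1) {
  cfg <- pipeline_config(n_roi = r, n_bands = q)
  arch <- build_branch("dynamic", cfg, n_roi = r, n_bands = q)
  structure(list(arch = arch, weights = fchybrid:::init_weights(arch, seed)),
            class = "trained_extractor")
}

test_that("region importance is the column abs-sum of the 1xR kernels", {
  m <- make_static_model(r = 8)
  m$weights$W1[] <- 0
  m$weights$W1[1, 7] <- -3
  rr <- rank_regions(m)
  expect_equal(rr$importance[7], 3)
  expect_equal(sum(rr$importance), 3)
  expect_equal(rr$roi[rr$rank == 1], 7L)

  # tie rule: equal importance -> lower index first
  m$weights$W1[] <- 0
  m$weights$W1[2, 3] <- 1
  m$weights$W1[5, 6] <- -1
  rr2 <- rank_regions(m)
  expect_equal(rr2$rank[3], 1L)
  expect_equal(rr2$rank[6], 2L)

  # general case matches a direct loop oracle
  m3 <- make_static_model(r = 8, seed = 44)
  rr3 <- rank_regions(m3)
  oracle <- vapply(1:8, function(j) sum(abs(m3$weights$W1[, j])), 0)
  expect_equal(rr3$importance, oracle, tolerance = 1e-12)

  expect_error(rank_regions(42), class = "fchybrid_error_validation")
})

test_that("band importance is the magnitude of compression weights", {
  g <- frequency_grid(pipeline_config(n_roi = 8, n_bands = 10))
  m <- make_dynamic_model(r = 8, q = 10)
  m$weights$w0 <- c(rep(0, 5), 1, rep(0, 4))   # one-hot on band 6
  rb <- rank_bands(m, g)
  expect_equal(rb$band[rb$rank == 1], 6L)
  expect_equal(rb$f_lo, g$edges[1:10], tolerance = 1e-12)

  # all-equal weights -> documented ascending tie order
  m$weights$w0 <- rep(0.3, 10)
  rb2 <- rank_bands(m, g)
  expect_equal(rb2$rank, 1:10)

  sm <- make_static_model()
  expect_error(rank_bands(sm, g), class = "fchybrid_error_validation")
  expect_error(rank_bands(make_dynamic_model(q = 7), g),
               class = "fchybrid_error_dimension")
})

test_that("three-player Shapley satisfies efficiency, dummy and symmetry
           exactly and matches the linear closed form", {
  set.seed(16)
  w <- rnorm(37); b <- 0.7
  f <- function(x) as.numeric(x %*% w + b)
  baseline <- rnorm(37)
  x <- rnorm(37)
  sh <- group_shapley(f, x, baseline)
  # efficiency
  expect_equal(sum(sh$phi), f(matrix(x, 1)) - f(matrix(baseline, 1)),
               tolerance = 1e-9)
  # linear closed form: phi_block = sum_j w_j (x_j - baseline_j)
  slices <- list(srs = 1:5, static = 6:21, dynamic = 22:37)
  for (i in 1:3) {
    expect_equal(sh$phi[i],
                 sum(w[slices[[i]]] * (x - baseline)[slices[[i]]]),
                 tolerance = 1e-10)
  }
  # dummy: only one block differs from baseline
  x2 <- baseline; x2[1:5] <- x[1:5]
  sh2 <- group_shapley(f, x2, baseline)
  expect_equal(sh2$phi[1], f(matrix(x2, 1)) - f(matrix(baseline, 1)),
               tolerance = 1e-10)
  expect_equal(sh2$phi[2:3], c(0, 0), tolerance = 1e-12)
  expect_equal(sh2$phi_abs, abs(sh2$phi))

  # symmetry under a nonlinear f: two blocks with identical marginal
  # contributions in every coalition get equal phi
  g2 <- function(x) {
    a <- as.numeric(x[, 1, drop = FALSE])
    b2 <- as.numeric(x[, 6, drop = FALSE])
    c2 <- as.numeric(x[, 22, drop = FALSE])
    a + b2 + a * c2 + b2 * c2
  }
  base0 <- rep(0, 37)
  x3 <- rep(0, 37); x3[1] <- 1; x3[6] <- 1; x3[22] <- 2
  sh3 <- group_shapley(g2, x3, base0)
  expect_equal(sh3$phi[1], sh3$phi[2], tolerance = 1e-12)

  expect_error(group_shapley(f, x[1:10], baseline),
               class = "fchybrid_error_validation")
})

test_that("the nonlinear SVM decision function still gets exact
           efficiency", {
  recs <- small_records()
  cfg <- small_config(max_epochs = 5)
  cv <- cached("tiny_cv", cross_validate(recs, cfg, seed = 19))
  f <- decision_fun(cv$best_bundle)
  feats <- assemble_features(recs, cv$best_bundle$static_model,
                             cv$best_bundle$dynamic_model)
  baseline <- colMeans(cv$best_bundle$train_features$x)
  for (i in c(1, 10)) {
    sh <- group_shapley(f, feats$x[i, ], baseline)
    expect_equal(sum(sh$phi), attr(sh, "f_x") - attr(sh, "f_baseline"),
                 tolerance = 1e-9)
  }
})

test_that("explain reports are complete, deterministic and serializable", {
  recs <- small_records()
  cfg <- small_config(max_epochs = 5)
  cv <- cached("tiny_cv", cross_validate(recs, cfg, seed = 19))
  g <- frequency_grid(cfg)
  ids <- vapply(recs[1:5], function(r) r$phenotype$subject_id, "")
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "r1.json"); p2 <- file.path(dir, "r2.json")
  ex1 <- explain_report(cv, recs, g, subjects = ids, path = p1)
  ex2 <- explain_report(cv, recs, g, subjects = ids, path = p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_s3_class(ex1$regions_static, "region_ranking")
  expect_s3_class(ex1$regions_dynamic, "region_ranking")
  expect_s3_class(ex1$bands, "band_ranking")
  expect_equal(nrow(ex1$shapley), 15L)   # 5 subjects x 3 blocks
  expect_equal(length(unique(ex1$shapley$subject_id)), 5L)
  expect_error(explain_report(cv, recs, g, subjects = "nobody"),
               class = "fchybrid_error_validation")
  # node table export is plain text
  np <- file.path(dir, "nodes.tsv")
  write_node_table(ex1$regions_static, np)
  expect_equal(nrow(utils::read.table(np, header = TRUE, sep = "\t")), 8L)
  # plots build
  expect_s3_class(autoplot(ex1$regions_static), "ggplot")
  expect_s3_class(autoplot(ex1$bands), "ggplot")
})

test_that("region importance is permutation-equivariant at fixed seed", {
  # permuting ROI order of the inputs and retraining with identical
  # init/shuffle seeds permutes the importance vector accordingly
  cfg <- pipeline_config(n_roi = 8, max_epochs = 8, batch_size = 8)
  arch <- build_branch("static", cfg, n_roi = 8)
  set.seed(18)
  n <- 40
  labs <- rep(0:1, each = n / 2)
  x <- array(rnorm(8 * 8 * n, sd = 0.5), dim = c(8, 8, n))
  for (i in which(labs == 1)) x[2, 6, i] <- x[6, 2, i] <- x[2, 6, i] + 1.5
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  xp <- x[perm, perm, , drop = FALSE]

  init <- fchybrid:::init_weights(arch, 1234)
  m <- train_extractor(arch, x, labs, cfg, seed = 4, init = init)
  imp <- rank_regions(m)$importance

  # permute the init consistently with the ROI relabelling: conv1
  # kernels act on matrix columns (W1 columns), conv2 kernels on the
  # spatial position r inside each channel block of W2
  initp <- init
  initp$W1 <- init$W1[, perm]
  w2 <- init$W2
  for (ch in 1:32) {
    cols <- (ch - 1) * 8 + 1:8
    w2[, cols] <- init$W2[, cols][, perm]
  }
  initp$W2 <- w2
  mp <- train_extractor(arch, xp, labs, cfg, seed = 4, init = initp)
  impp <- rank_regions(mp)$importance
  expect_equal(impp, imp[perm], tolerance = 1e-8)
})
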