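# Feature fusion and cross-validated evaluation.
#
# Per fold: both CNN branches are trained on the training subjects only,
# deep features are extracted for everyone, every feature column is
# z-scored with training-fold statistics, and a linear-kernel SVM is fit
# on the 37-vector (5 SRS + 16 static-deep + 16 dynamic-deep). No
# validation subject touches any training step.

FEATURE_SLICES <- list(srs = 1:5, static = 6:21, dynamic = 22:37)

#' Stratified cross-validation plan
#'
#' @param phenotypes phenotype tibble (needs `subject_id`, `label`)
#' @param k number of folds
#' @param seed shuffling seed
#' @return tibble (`subject_id`, `label`, `fold`) of class `"cv_plan"`;
#'   folds are disjoint, cover all subjects, and keep the class ratio
#'   within one subject of the global ratio
#' @export
make_cv_plan <- function(phenotypes, k, seed) {
  k <- as.integer(k)
  if (k < 2L) abort_validation("make_cv_plan: k must be >= 2")
  tab <- table(phenotypes$label)
  if (any(tab < k)) {
    abort_validation("make_cv_plan: class %s has %d members, fewer than k=%d",
                     names(tab)[which.min(tab)], min(tab), k)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fold <- integer(nrow(phenotypes))
  for (cl in unique(phenotypes$label)) {
    idx <- which(phenotypes$label == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  out <- tibble::tibble(subject_id = phenotypes$subject_id,
                        label = phenotypes$label, fold = fold)
  class(out) <- c("cv_plan", class(out))
  attr(out, "k") <- k
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Confusion counts from labels and predictions
#'
#' Positive class is ASD (label 1).
#'
#' @param truth,prediction integer 0/1 vectors
#' @return list with `TP`, `FP`, `TN`, `FN`
#' @export
confusion_counts <- function(truth, prediction) {
  stopifnot(length(truth) == length(prediction))
  list(TP = sum(truth == 1L & prediction == 1L),
       FP = sum(truth == 0L & prediction == 1L),
       TN = sum(truth == 0L & prediction == 0L),
       FN = sum(truth == 1L & prediction == 0L))
}

#' Classification metrics from confusion counts
#'
#' Exact formula evaluation: ACC, SEN (= TP/(TP+FN)), SPE, FPR, FNR,
#' Precision and F1. A metric whose denominator is zero is reported as
#' `NA` (undefined), never as 0.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN`
#' @return one-row tibble of metrics plus the counts
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  if (any(c(tp, fp, tn, fn) < 0)) abort_validation("negative confusion count")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sen <- div(tp, tp + fn)
  spe <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(sen) && (prec + sen) > 0) {
    2 * prec * sen / (prec + sen)
  } else NA_real_
  tibble::tibble(
    ACC = div(tp + tn, tp + fp + tn + fn),
    SEN = sen, SPE = spe,
    FPR = div(fp, fp + tn), FNR = div(fn, fn + tp),
    Precision = prec, F1 = f1,
    TP = tp, FP = fp, TN = tn, FN = fn
  )
}

#' Assemble the fused 37-feature matrix
#'
#' Order: 5 SRS subscales, 16 static-deep, 16 dynamic-deep (slices
#' 1:5, 6:21, 22:37).
#'
#' @param records list of [subject_record()]s
#' @param static_model,dynamic_model trained extractors
#' @return list: `x` (N x 37 matrix), `subject_id`, `label`
#' @export
assemble_features <- function(records, static_model, dynamic_model) {
  phen <- dplyr::bind_rows(lapply(records, `[[`, "phenotype"))
  sfc <- stack_static(records)
  dfc <- stack_dynamic(records)
  fs <- extract_features(static_model, sfc)$features
  fd <- extract_features(dynamic_model, dfc)$features
  x <- cbind(srs_matrix(phen), fs, fd)
  colnames(x) <- c(paste0("srs_", SRS_SUBSCALES),
                   paste0("static_", 1:16), paste0("dynamic_", 1:16))
  list(x = x, subject_id = phen$subject_id, label = phen$label)
}

stack_static <- function(records) {
  r <- nrow(records[[1]]$static_fc$matrix)
  arr <- array(0, dim = c(r, r, length(records)))
  for (i in seq_along(records)) arr[, , i] <- records[[i]]$static_fc$matrix
  arr
}

stack_dynamic <- function(records) {
  d <- dim(records[[1]]$dynamic_fc$tensor)
  arr <- array(0, dim = c(d[3], d[1], d[2], length(records)))
  for (i in seq_along(records)) {
    arr[, , , i] <- aperm(records[[i]]$dynamic_fc$tensor, c(3L, 1L, 2L))
  }
  arr
}

fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$mean), 2L, scaler$sd, `/`)
}

# Decision value oriented so positive => ASD (class "1"), regardless of
# e1071's internal class ordering.
svm_decision <- function(fit, x) {
  pr <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  if (grepl("^1/", colnames(dv)[1])) as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
}

#' Run one cross-validation fold
#'
#' Trains both CNN branches on the fold's training records only,
#' extracts and z-scores features with training statistics, fits the
#' linear SVM, and scores the validation records.
#'
#' @param train_records,val_records lists of [subject_record()]s
#' @param config a [pipeline_config()]
#' @param seed fold seed (drives both extractor trainings)
#' @return list: `metrics` (one-row tibble), `predictions` (tibble),
#'   `static_model`, `dynamic_model`, `svm_fit`, `scaler`
#' @export
run_fold <- function(train_records, val_records, config, seed) {
  labs <- vapply(train_records, function(r) r$phenotype$label, integer(1))
  if (length(unique(labs)) < 2L) {
    abort_validation("run_fold: training records contain a single class")
  }
  q <- dim(train_records[[1]]$dynamic_fc$tensor)[3]
  r <- nrow(train_records[[1]]$static_fc$matrix)
  arch_s <- build_branch("static", config, n_roi = r)
  arch_d <- build_branch("dynamic", config, n_roi = r, n_bands = q)
  sm <- train_extractor(arch_s, stack_static(train_records), labs, config,
                        seed = derive_seed(seed, 11L))
  dm <- train_extractor(arch_d, stack_dynamic(train_records), labs, config,
                        seed = derive_seed(seed, 12L))
  tr <- assemble_features(train_records, sm, dm)
  va <- assemble_features(val_records, sm, dm)
  scaler <- fit_scaler(tr$x)
  xtr <- apply_scaler(tr$x, scaler)
  xva <- apply_scaler(va$x, scaler)
  fit <- e1071::svm(xtr, factor(tr$label, levels = c(0L, 1L)),
                    kernel = "linear", cost = config$svm_C, scale = FALSE)
  dv <- svm_decision(fit, xva)
  pred <- as.integer(dv > 0)
  metrics <- compute_metrics(confusion_counts(va$label, pred))
  predictions <- tibble::tibble(subject_id = va$subject_id,
                                label = va$label, prediction = pred,
                                decision_value = dv)
  list(metrics = metrics, predictions = predictions,
       static_model = sm, dynamic_model = dm, svm_fit = fit,
       scaler = scaler, train_features = tr)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Runs [run_fold()] for every fold of a stratified plan, reports
#' per-fold and mean metrics, and keeps the fold bundle with the
#' highest validation accuracy (ties: lowest fold index) as the
#' deployable model.
#'
#' @param records list of [subject_record()]s
#' @param config a [pipeline_config()]
#' @param seed master seed (plan + per-fold training)
#' @param plan optional precomputed [make_cv_plan()]
#' @param quiet suppress per-fold progress messages
#' @return object of class `"fchybrid_cv"`: `fold_metrics`,
#'   `mean_metrics`, `predictions`, `best_fold`, `best_bundle`, `plan`
#' @export
cross_validate <- function(records, config, seed = config$seed, plan = NULL,
                           quiet = TRUE) {
  phen <- dplyr::bind_rows(lapply(records, `[[`, "phenotype"))
  if (is.null(plan)) {
    plan <- make_cv_plan(phen, config$n_folds, seed = derive_seed(seed, 1L))
  }
  k <- attr(plan, "k")
  id_fold <- stats::setNames(plan$fold, plan$subject_id)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    if (!quiet) message(sprintf("fold %d/%d", f, k))
    val_idx <- which(id_fold[phen$subject_id] == f)
    res <- tryCatch(
      run_fold(records[-val_idx], records[val_idx], config,
               seed = derive_seed(seed, 100L + f)),
      error = function(e) {
        rlang::abort(sprintf("cross_validate: fold %d failed: %s",
                             f, conditionMessage(e)),
                     class = "fchybrid_error_fold")
      }
    )
    res$predictions$fold <- f
    folds[[f]] <- res
  }
  fold_metrics <- dplyr::bind_rows(lapply(folds, `[[`, "metrics"))
  fold_metrics$fold <- seq_len(k)
  mean_metrics <- dplyr::summarise(
    fold_metrics,
    dplyr::across(c("ACC", "SEN", "SPE", "FPR", "FNR", "Precision", "F1"),
                  ~ mean(.x, na.rm = TRUE)))
  best <- which.max(fold_metrics$ACC)  # ties: first (lowest index)
  structure(list(
    fold_metrics = fold_metrics,
    mean_metrics = mean_metrics,
    predictions = dplyr::bind_rows(lapply(folds, `[[`, "predictions")),
    best_fold = best,
    best_bundle = folds[[best]][c("static_model", "dynamic_model",
                                  "svm_fit", "scaler", "train_features")],
    plan = plan, config = config, seed = as.integer(seed)
  ), class = "fchybrid_cv")
}

#' @export
print.fchybrid_cv <- function(x, ...) {
  cat(sprintf("<fchybrid_cv: %d folds, mean ACC %.3f (SEN %.3f, SPE %.3f, F1 %.3f)>\n",
              nrow(x$fold_metrics), x$mean_metrics$ACC, x$mean_metrics$SEN,
              x$mean_metrics$SPE, x$mean_metrics$F1))
  invisible(x)
}

#' Baseline classifiers on the fused features
#'
#' Trains an MLP (two hidden layers of 64 and 16 units), a random
#' forest (100 trees) and a logistic regression (0.5 threshold;
#' probability exactly 0.5 classifies positive) on the same z-scored
#' 37-features as the SVM, plus the SVM itself for reference.
#'
#' @param train_x,train_y training matrix and 0/1 labels
#' @param val_x,val_y validation matrix and 0/1 labels
#' @param config a [pipeline_config()]
#' @param seed seed for the stochastic models
#' @return tibble of per-model metrics
#' @export
fit_baselines <- function(train_x, train_y, val_x, val_y, config, seed) {
  train_y <- as.integer(train_y); val_y <- as.integer(val_y)
  out <- list()

  fit <- e1071::svm(train_x, factor(train_y, levels = c(0L, 1L)),
                    kernel = "linear", cost = config$svm_C, scale = FALSE)
  pred <- as.integer(svm_decision(fit, val_x) > 0)
  out$SVM <- compute_metrics(confusion_counts(val_y, pred))

  mlp <- train_mlp(train_x, train_y, hidden = c(64L, 16L), config = config,
                   seed = derive_seed(seed, 21L))
  out$MLP <- compute_metrics(confusion_counts(val_y, predict_mlp(mlp, val_x)))

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(derive_seed(seed, 22L))
  rf <- randomForest::randomForest(train_x, factor(train_y, levels = c(0L, 1L)),
                                   ntree = 100L)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  out$RF <- compute_metrics(
    confusion_counts(val_y, as.integer(as.character(predict(rf, val_x)))))

  df_tr <- data.frame(y = train_y, train_x)
  lr <- suppressWarnings(stats::glm(y ~ ., data = df_tr, family = stats::binomial()))
  prob <- suppressWarnings(
    predict(lr, newdata = data.frame(val_x), type = "response"))
  out$LR <- compute_metrics(confusion_counts(val_y, classify_prob(prob)))

  res <- dplyr::bind_rows(out)
  res$model <- names(out)
  dplyr::relocate(res, "model")
}

# The documented LR decision rule: probability >= 0.5 (the boundary
# inclusive) classifies as ASD.
classify_prob <- function(p) as.integer(p >= 0.5)

# Minimal MLP (ReLU hidden layers, softmax cross-entropy head) trained
# with Adam under the same budget as the CNN branches.
train_mlp <- function(x, y, hidden, config, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  dims <- c(ncol(x), hidden, 2L)
  ws <- bs <- list()
  for (l in seq_len(length(dims) - 1L)) {
    ws[[l]] <- uinit(dims[l + 1L], dims[l], dims[l])
    bs[[l]] <- as.numeric(uinit(dims[l + 1L], 1L, dims[l]))
  }
  nlayer <- length(ws)
  mws <- vws <- lapply(ws, function(w) w * 0)
  mbs <- vbs <- lapply(bs, function(b) b * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(x)
  bsz <- max(2L, min(config$batch_size, n))
  step <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = bsz)) {
      idx <- ord[s:min(s + bsz - 1L, n)]
      a <- list(x[idx, , drop = FALSE])
      zs <- list()
      for (l in seq_len(nlayer)) {
        z <- sweep(a[[l]] %*% t(ws[[l]]), 2L, bs[[l]], `+`)
        zs[[l]] <- z
        a[[l + 1L]] <- if (l < nlayer) pmax(z, 0) else z
      }
      p <- softmax(a[[nlayer + 1L]])
      dz <- (p - cbind(1 - y[idx], y[idx])) / length(idx)
      step <- step + 1L
      for (l in rev(seq_len(nlayer))) {
        gw <- t(dz) %*% a[[l]]
        gb <- colSums(dz)
        if (l > 1L) dz <- (dz %*% ws[[l]]) * (zs[[l - 1L]] > 0)
        mws[[l]] <- beta1 * mws[[l]] + (1 - beta1) * gw
        vws[[l]] <- beta2 * vws[[l]] + (1 - beta2) * gw^2
        mbs[[l]] <- beta1 * mbs[[l]] + (1 - beta1) * gb
        vbs[[l]] <- beta2 * vbs[[l]] + (1 - beta2) * gb^2
        ws[[l]] <- ws[[l]] - config$learning_rate *
          (mws[[l]] / (1 - beta1^step)) / (sqrt(vws[[l]] / (1 - beta2^step)) + eps)
        bs[[l]] <- bs[[l]] - config$learning_rate *
          (mbs[[l]] / (1 - beta1^step)) / (sqrt(vbs[[l]] / (1 - beta2^step)) + eps)
      }
    }
  }
  list(ws = ws, bs = bs)
}

predict_mlp <- function(mlp, x) {
  a <- x
  nlayer <- length(mlp$ws)
  for (l in seq_len(nlayer)) {
    z <- sweep(a %*% t(mlp$ws[[l]]), 2L, mlp$bs[[l]], `+`)
    a <- if (l < nlayer) pmax(z, 0) else z
  }
  as.integer(a[, 2L] > a[, 1L])
}

#' Metrics within phenotype strata
#'
#' Recomputes the confusion metrics within each level of a grouping
#' variable (`sex`, `site`, or `age` binned into decades). Strata where
#' a metric's denominator is zero carry `NA` for that metric.
#'
#' @param predictions prediction tibble (from an `"fchybrid_cv"` object)
#' @param phenotypes phenotype tibble with the grouping metadata
#' @param by `"sex"`, `"age"` or `"site"`
#' @return tibble of per-stratum metrics
#' @export
subgroup_report <- function(predictions, phenotypes, by) {
  if (!by %in% c("sex", "age", "site")) {
    abort_validation("subgroup_report: unknown grouping '%s'", by)
  }
  if (!by %in% names(phenotypes)) {
    abort_validation("subgroup_report: phenotypes lack a '%s' column", by)
  }
  df <- dplyr::left_join(predictions,
                         phenotypes[c("subject_id", by)], by = "subject_id")
  df$stratum <- if (by == "age") {
    paste0(floor(df[[by]] / 10) * 10, "-", floor(df[[by]] / 10) * 10 + 9)
  } else as.character(df[[by]])
  groups <- split(df, df$stratum)
  res <- dplyr::bind_rows(lapply(groups, function(g) {
    compute_metrics(confusion_counts(g$label, g$prediction))
  }))
  res$stratum <- names(groups)
  res$n <- vapply(groups, nrow, integer(1))
  dplyr::relocate(res, "stratum", "n")
}
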