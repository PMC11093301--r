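# Interpretability: which ROIs, which frequency bands, and which
# feature blocks drive the classification.
#
# Region importance is the column-wise sum of absolute first-row-kernel
# convolution weights (the 32 x R kernel bank applied directly to the
# FC matrix: for the static branch its first conv layer, for the
# dynamic branch the conv after channel compression -- both are the
# 32-filter 1 x R layer). Band importance is the magnitude of the
# channel-compression weights. Block attribution is the exact Shapley
# value over the three feature blocks (SRS, static-deep, dynamic-deep)
# of the SVM decision function, with absent blocks mean-imputed from
# the training set.

#' Rank ROIs by convolution-weight importance
#'
#' @param model a [train_extractor()] result (either branch)
#' @param labels optional label table, e.g. [aal_labels()] (needs
#'   columns `roi`, `label`)
#' @param top_k how many top regions to flag (default 10, capped at R)
#' @return tibble (`roi`, `label`, `importance`, `rank`, `top`) of class
#'   `"region_ranking"`; ties rank by lower ROI index
#' @export
rank_regions <- function(model, labels = NULL, top_k = 10L) {
  if (!inherits(model, "trained_extractor")) {
    abort_validation("rank_regions: need a trained_extractor")
  }
  w1 <- model$weights$W1                      # 32 x R
  if (is.null(w1) || nrow(w1) != 32L) {
    abort_validation("rank_regions: model lacks the 32-filter 1xR conv layer")
  }
  importance <- colSums(abs(w1))
  r <- length(importance)
  ord <- order(-importance, seq_len(r))
  rank <- integer(r); rank[ord] <- seq_len(r)
  top_k <- min(as.integer(top_k), r)
  out <- tibble::tibble(roi = seq_len(r), importance = importance,
                        rank = rank, top = rank <= top_k)
  out$label <- if (!is.null(labels)) {
    labels$label[match(out$roi, labels$roi)]
  } else sprintf("ROI_%d", out$roi)
  out <- dplyr::relocate(out, "roi", "label")
  structure(out, class = c("region_ranking", class(out)),
            branch = model$arch$kind, top_k = top_k)
}

#' Rank frequency bands by channel-compression weight
#'
#' @param model a dynamic-branch [train_extractor()] result
#' @param grid the [frequency_grid()] the dynamic FC was built with
#' @param top_k how many top bands to flag (default 5)
#' @return tibble (`band`, `f_lo`, `f_hi`, `center`, `importance`,
#'   `rank`, `top`) of class `"band_ranking"`; ties rank by lower band
#'   index
#' @export
rank_bands <- function(model, grid, top_k = 5L) {
  if (!inherits(model, "trained_extractor") || model$arch$kind != "dynamic") {
    abort_validation("rank_bands: need a dynamic-branch trained_extractor")
  }
  importance <- abs(model$weights$w0)
  q <- length(importance)
  if (q != length(grid$centers)) {
    abort_dimension("rank_bands: model has %d channels, grid %d bands",
                    q, length(grid$centers))
  }
  ord <- order(-importance, seq_len(q))
  rank <- integer(q); rank[ord] <- seq_len(q)
  top_k <- min(as.integer(top_k), q)
  out <- tibble::tibble(band = seq_len(q),
                        f_lo = grid$edges[-(q + 1L)],
                        f_hi = grid$edges[-1L],
                        center = grid$centers,
                        importance = importance,
                        rank = rank, top = rank <= top_k)
  structure(out, class = c("band_ranking", class(out)), top_k = top_k)
}

#' Exact Shapley attribution over the three feature blocks
#'
#' Treats the SRS, static-deep and dynamic-deep blocks as three players
#' and enumerates all 2^3 coalitions exactly. A coalition's value is
#' the real-valued decision function applied to the subject's features
#' with blocks outside the coalition replaced by the baseline (the
#' training-set feature means). Signed values satisfy efficiency:
#' `sum(phi) = f(x) - f(baseline)`.
#'
#' @param f decision function: takes an N x 37 matrix, returns N reals
#' @param x the subject's feature vector (length 37, SVM input scale)
#' @param baseline length-37 baseline vector
#' @param slices named list of index slices (default the 5/16/16 blocks)
#' @return tibble (`block`, `phi`, `phi_abs`) with attributes `f_x`,
#'   `f_baseline`
#' @export
group_shapley <- function(f, x, baseline,
                          slices = FEATURE_SLICES) {
  p <- length(slices)
  d <- length(x)
  if (length(baseline) != d) {
    abort_validation("group_shapley: baseline length %d != feature length %d",
                     length(baseline), d)
  }
  idx_all <- as.integer(sort(unname(unlist(slices))))
  if (!identical(idx_all, seq_len(d))) {
    abort_validation("group_shapley: slices must partition 1..%d", d)
  }
  # value of every coalition, one f() call on a 2^p-row matrix
  coalitions <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  xmat <- matrix(rep(baseline, each = nrow(coalitions)),
                 nrow = nrow(coalitions))
  for (j in seq_len(p)) {
    rows <- which(coalitions[[j]])
    xmat[rows, slices[[j]]] <- matrix(rep(x[slices[[j]]], each = length(rows)),
                                      nrow = length(rows))
  }
  vals <- f(xmat)
  coal_key <- apply(as.matrix(coalitions), 1L, function(z) paste(as.integer(z), collapse = ""))
  value_of <- function(members) {
    z <- rep(0L, p); z[members] <- 1L
    vals[match(paste(z, collapse = ""), coal_key)]
  }
  phi <- numeric(p)
  others <- seq_len(p)
  for (i in seq_len(p)) {
    rest <- setdiff(others, i)
    for (tsize in 0:length(rest)) {
      subsets <- if (tsize == 0L) list(integer(0)) else
        utils::combn(rest, tsize, simplify = FALSE)
      wgt <- factorial(tsize) * factorial(p - tsize - 1L) / factorial(p)
      for (tt in subsets) {
        phi[i] <- phi[i] + wgt * (value_of(c(tt, i)) - value_of(tt))
      }
    }
  }
  out <- tibble::tibble(block = names(slices), phi = phi, phi_abs = abs(phi))
  attr(out, "f_x") <- value_of(seq_len(p))
  attr(out, "f_baseline") <- value_of(integer(0))
  out
}

#' Decision function of a fitted fold bundle
#'
#' Wraps the best-fold SVM (and its feature scaler) as a plain function
#' of raw 37-feature rows, oriented so positive means ASD.
#'
#' @param bundle `best_bundle` element of an `"fchybrid_cv"` object
#' @return function(matrix) -> numeric decision values
#' @export
decision_fun <- function(bundle) {
  force(bundle)
  function(x) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    svm_decision(bundle$svm_fit, apply_scaler(x, bundle$scaler))
  }
}

#' Full interpretability report
#'
#' Region rankings for both branches, the frequency-band ranking, and
#' per-subject Shapley triples for the requested subjects, computed
#' from a fitted cross-validation bundle. Deterministic given inputs;
#' optionally serialised to JSON.
#'
#' @param cv an `"fchybrid_cv"` object
#' @param records the records the bundle was trained on (for features)
#' @param grid the [frequency_grid()] used for dynamic FC
#' @param subjects subject ids to attribute (default: first 5)
#' @param labels optional ROI label table
#' @param path optional JSON output path
#' @return list of class `"fchybrid_explain"` with elements
#'   `regions_static`, `regions_dynamic`, `bands`, `shapley`
#' @export
explain_report <- function(cv, records, grid, subjects = NULL,
                           labels = NULL, path = NULL) {
  bundle <- cv$best_bundle
  feats <- assemble_features(records, bundle$static_model,
                             bundle$dynamic_model)
  if (is.null(subjects)) subjects <- utils::head(feats$subject_id, 5L)
  missing <- setdiff(subjects, feats$subject_id)
  if (length(missing)) {
    abort_validation("explain_report: unknown subject(s) %s",
                     paste(missing, collapse = ", "))
  }
  f <- decision_fun(bundle)
  baseline <- colMeans(bundle$train_features$x)
  shap <- dplyr::bind_rows(lapply(subjects, function(sid) {
    xrow <- feats$x[match(sid, feats$subject_id), ]
    s <- group_shapley(f, xrow, baseline)
    s$subject_id <- sid
    s$f_x <- attr(s, "f_x")
    s$f_baseline <- attr(s, "f_baseline")
    s
  }))
  out <- structure(list(
    regions_static = rank_regions(bundle$static_model, labels = labels),
    regions_dynamic = rank_regions(bundle$dynamic_model, labels = labels),
    bands = rank_bands(bundle$dynamic_model, grid),
    shapley = dplyr::relocate(shap, "subject_id")
  ), class = "fchybrid_explain")
  if (!is.null(path)) {
    jsonlite::write_json(
      lapply(unclass(out), function(x) as.data.frame(x)),
      path, digits = NA, auto_unbox = TRUE)
  }
  out
}

#' Export a plain-text node table for brain-network viewers
#'
#' @param ranking a [rank_regions()] result
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_node_table <- function(ranking, path) {
  utils::write.table(
    data.frame(label = ranking$label, importance = ranking$importance),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
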