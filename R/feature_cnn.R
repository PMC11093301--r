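# Connectome CNN feature extractors.
#
# Both branches share a conv stack whose kernels span whole rows or
# columns of the FC matrix: 32 filters of 1xR, 64 of Rx1, 16 of 1x1,
# each followed by batch normalisation and LeakyReLU(0.01), then
# dropout, a sigmoid attention block (16 -> 8 -> 16) that gates the
# 16-vector, and an auxiliary 2-class softmax head used only to train
# the parameters. The dynamic branch prepends a 1x1 channel-compression
# convolution collapsing the Q frequency channels to one map.
#
# Because every kernel spans a full row/column, each convolution is an
# exact matrix product, which is how the engine implements it.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Describe a CNN branch architecture
#'
#' @param kind `"static"` or `"dynamic"`
#' @param config a [pipeline_config()]
#' @param n_roi number of ROIs R (default from config)
#' @param n_bands input channels Q for the dynamic branch
#' @return object of class `"branch_arch"` with the conv specs
#'   (filters, kernel height, kernel width), attention dims and
#'   regularisation settings
#' @export
build_branch <- function(kind = c("static", "dynamic"), config,
                         n_roi = config$n_roi, n_bands = config$n_bands) {
  kind <- match.arg(kind)
  r <- as.integer(n_roi)
  q <- as.integer(n_bands)
  if (r < 2L) abort_dimension("build_branch: need R >= 2, got %d", r)
  if (kind == "dynamic" && q < 1L) {
    abort_dimension("build_branch: need Q >= 1, got %d", q)
  }
  convs <- list(c(filters = 32L, kh = 1L, kw = r),
                c(filters = 64L, kh = r, kw = 1L),
                c(filters = 16L, kh = 1L, kw = 1L))
  if (kind == "dynamic") {
    convs <- c(list(c(filters = 1L, kh = 1L, kw = 1L)), convs)
  }
  structure(list(kind = kind, n_roi = r,
                 in_channels = if (kind == "dynamic") q else 1L,
                 convs = convs,
                 attention = c(hidden = 8L, out = 16L),
                 dropout = config$dropout,
                 leaky_slope = config$leaky_slope),
            class = "branch_arch")
}

#' Weight shapes of a branch (filters x in-channels x kh x kw)
#'
#' @param arch a [build_branch()] architecture
#' @return named list of integer shape vectors
#' @export
weight_shapes <- function(arch) {
  r <- arch$n_roi
  shapes <- list()
  if (arch$kind == "dynamic") {
    shapes$compress <- c(1L, arch$in_channels, 1L, 1L)
  }
  shapes$conv1 <- c(32L, 1L, 1L, r)
  shapes$conv2 <- c(64L, 32L, r, 1L)
  shapes$conv3 <- c(16L, 64L, 1L, 1L)
  shapes$att1 <- c(8L, 16L)
  shapes$att2 <- c(16L, 8L)
  shapes$head <- c(2L, 16L)
  shapes
}

uinit <- function(nr, nc, fan_in) {
  b <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

bn_new <- function(n) {
  list(gamma = rep(1, n), beta = rep(0, n),
       run_mean = rep(0, n), run_var = rep(1, n))
}

# The first kernel bank of each branch (channel compression w0 and the
# 1xR conv W1) is initialised at a tenth of the fan-in scale. Batch
# normalisation directly after each of these layers makes the network
# function invariant to their overall scale, but their weight
# magnitudes are read out for interpretability (region and band
# rankings), so learned structure -- not the random draw -- should
# dominate them.
FIRST_LAYER_INIT_SCALE <- 0.1

init_weights <- function(arch, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  r <- arch$n_roi
  w <- list()
  if (arch$kind == "dynamic") {
    q <- arch$in_channels
    w$w0 <- as.numeric(uinit(1L, q, q)) * FIRST_LAYER_INIT_SCALE
    w$b0 <- as.numeric(uinit(1L, 1L, q))
    w$bn0 <- bn_new(1L)
  }
  w$W1 <- uinit(32L, r, r) * FIRST_LAYER_INIT_SCALE
  w$b1 <- as.numeric(uinit(32L, 1L, r))
  w$bn1 <- bn_new(32L)
  w$W2 <- uinit(64L, 32L * r, 32L * r)
  w$b2 <- as.numeric(uinit(64L, 1L, 32L * r))
  w$bn2 <- bn_new(64L)
  w$W3 <- uinit(16L, 64L, 64L);    w$b3 <- as.numeric(uinit(16L, 1L, 64L))
  w$bn3 <- bn_new(16L)
  w$Wa1 <- uinit(8L, 16L, 16L);    w$ba1 <- as.numeric(uinit(8L, 1L, 16L))
  w$Wa2 <- uinit(16L, 8L, 8L);     w$ba2 <- as.numeric(uinit(16L, 1L, 8L))
  w$Wh <- uinit(2L, 16L, 16L);     w$bh <- as.numeric(uinit(2L, 1L, 16L))
  w
}

leaky <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)
leaky_grad <- function(x, slope) {
  g <- x > 0
  g + slope * (1 - g)
}
sigmoid <- function(x) 1 / (1 + exp(-x))

# fast column-wise broadcast helpers (avoid sweep() overhead)
addcol <- function(m, v) m + rep(v, each = nrow(m))
mulcol <- function(m, v) m * rep(v, each = nrow(m))

# Batch-norm forward over rows (each column = one channel).
bn_forward <- function(x, bn, training) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    xhat <- mulcol(addcol(x, -mu), 1 / sqrt(v + BN_EPS))
    n <- nrow(x)
    unb <- if (n > 1L) v * n / (n - 1L) else v
    bn$run_mean <- (1 - BN_MOMENTUM) * bn$run_mean + BN_MOMENTUM * mu
    bn$run_var <- (1 - BN_MOMENTUM) * bn$run_var + BN_MOMENTUM * unb
    list(y = addcol(mulcol(xhat, bn$gamma), bn$beta),
         xhat = xhat, var = v, bn = bn)
  } else {
    xhat <- mulcol(addcol(x, -bn$run_mean), 1 / sqrt(bn$run_var + BN_EPS))
    list(y = addcol(mulcol(xhat, bn$gamma), bn$beta),
         xhat = xhat, var = bn$run_var, bn = bn)
  }
}

bn_backward <- function(dy, cache, bn) {
  n <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  inv_sd <- 1 / sqrt(cache$var + BN_EPS)
  t1 <- addcol(dy, -colMeans(dy))
  t2 <- mulcol(xhat, colMeans(dy * xhat))
  dx <- mulcol(t1 - t2, bn$gamma * inv_sd)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Forward pass. `x` is an array: static (R, R, B); dynamic (Q, R, R, B).
# Returns logits plus every intermediate needed for the backward pass.
cnn_forward <- function(arch, w, x, training = FALSE, dropout_mask = NULL) {
  r <- arch$n_roi
  slope <- arch$leaky_slope
  cache <- list()
  if (arch$kind == "dynamic") {
    q <- arch$in_channels
    if (length(dim(x)) != 4L || dim(x)[1] != q || dim(x)[2] != r) {
      abort_dimension("dynamic branch expects a Q x R x R x B array")
    }
    b <- dim(x)[4]
    m <- matrix(x, nrow = q)                     # Q x (R*R*B)
    y0 <- as.numeric(w$w0 %*% m) + w$b0          # compressed map
    bn0 <- bn_forward(matrix(y0, ncol = 1L), w$bn0, training)
    w$bn0 <- bn0$bn
    a0 <- leaky(bn0$y[, 1L], slope)
    xs <- array(a0, dim = c(r, r, b))
    cache$m <- m; cache$bn0 <- bn0; cache$y0 <- y0
  } else {
    if (length(dim(x)) != 3L || dim(x)[1] != r || dim(x)[2] != r) {
      abort_dimension("static branch expects an R x R x B array")
    }
    b <- dim(x)[3]
    xs <- x
  }
  # conv1 (1 x R kernels): rows of each sample's matrix -> 32 channels
  xstack <- matrix(aperm(xs, c(1L, 3L, 2L)), nrow = r * b)  # (r,b) x R
  h1 <- addcol(xstack %*% t(w$W1), w$b1)
  bn1 <- bn_forward(h1, w$bn1, training); w$bn1 <- bn1$bn
  l1 <- leaky(bn1$y, slope)
  # conv2 (R x 1 kernels over 32 channels) == dense over flattened maps
  v <- matrix(aperm(array(l1, dim = c(r, b, 32L)), c(2L, 1L, 3L)), nrow = b)
  h2 <- addcol(v %*% t(w$W2), w$b2)
  bn2 <- bn_forward(h2, w$bn2, training); w$bn2 <- bn2$bn
  l2 <- leaky(bn2$y, slope)
  # conv3 (1 x 1 kernels) == dense 64 -> 16
  h3 <- addcol(l2 %*% t(w$W3), w$b3)
  bn3 <- bn_forward(h3, w$bn3, training); w$bn3 <- bn3$bn
  l3 <- leaky(bn3$y, slope)
  # dropout after the flattened conv output
  if (training && arch$dropout > 0) {
    if (is.null(dropout_mask)) dropout_mask <- matrix(1, b, 16L)
    d <- l3 * dropout_mask / (1 - arch$dropout)
  } else {
    dropout_mask <- NULL
    d <- l3
  }
  # attention: 16 -> 8 (ReLU) -> 16 (sigmoid), gates the 16-vector
  z1 <- addcol(d %*% t(w$Wa1), w$ba1)
  a1 <- pmax(z1, 0)
  z2 <- addcol(a1 %*% t(w$Wa2), w$ba2)
  g <- sigmoid(z2)
  feat <- g * d
  logits <- addcol(feat %*% t(w$Wh), w$bh)
  c(cache, list(xs = xs, xstack = xstack, h1 = h1, bn1 = bn1, l1 = l1,
                v = v, h2 = h2, bn2 = bn2, l2 = l2, h3 = h3, bn3 = bn3,
                l3 = l3, d = d, mask = dropout_mask, z1 = z1, a1 = a1,
                g = g, feat = feat, logits = logits, w = w, b = b))
}

softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

cnn_backward <- function(arch, w, fw, y_onehot) {
  r <- arch$n_roi
  slope <- arch$leaky_slope
  b <- fw$b
  g <- list()
  p <- softmax(fw$logits)
  dlog <- (p - y_onehot) / b
  g$Wh <- t(dlog) %*% fw$feat; g$bh <- colSums(dlog)
  dfeat <- dlog %*% w$Wh
  dg <- dfeat * fw$d
  dd <- dfeat * fw$g
  dz2 <- dg * fw$g * (1 - fw$g)
  g$Wa2 <- t(dz2) %*% fw$a1; g$ba2 <- colSums(dz2)
  da1 <- dz2 %*% w$Wa2
  dz1 <- da1 * (fw$z1 > 0)
  g$Wa1 <- t(dz1) %*% fw$d; g$ba1 <- colSums(dz1)
  dd <- dd + dz1 %*% w$Wa1
  dl3 <- if (!is.null(fw$mask)) dd * fw$mask / (1 - arch$dropout) else dd
  dbn3y <- dl3 * leaky_grad(fw$bn3$y, slope)
  bb3 <- bn_backward(dbn3y, fw$bn3, w$bn3)
  g$bn3_gamma <- bb3$dgamma; g$bn3_beta <- bb3$dbeta
  dh3 <- bb3$dx
  g$W3 <- t(dh3) %*% fw$l2; g$b3 <- colSums(dh3)
  dl2 <- dh3 %*% w$W3
  dbn2y <- dl2 * leaky_grad(fw$bn2$y, slope)
  bb2 <- bn_backward(dbn2y, fw$bn2, w$bn2)
  g$bn2_gamma <- bb2$dgamma; g$bn2_beta <- bb2$dbeta
  dh2 <- bb2$dx
  g$W2 <- t(dh2) %*% fw$v; g$b2 <- colSums(dh2)
  dv <- dh2 %*% w$W2
  dl1 <- matrix(aperm(array(dv, dim = c(b, r, 32L)), c(2L, 1L, 3L)),
                nrow = r * b)
  dbn1y <- dl1 * leaky_grad(fw$bn1$y, slope)
  bb1 <- bn_backward(dbn1y, fw$bn1, w$bn1)
  g$bn1_gamma <- bb1$dgamma; g$bn1_beta <- bb1$dbeta
  dh1 <- bb1$dx
  g$W1 <- t(dh1) %*% fw$xstack; g$b1 <- colSums(dh1)
  if (arch$kind == "dynamic") {
    dxstack <- dh1 %*% w$W1
    dxs <- aperm(array(dxstack, dim = c(r, b, r)), c(1L, 3L, 2L))
    da0 <- as.numeric(dxs)
    dbn0y <- da0 * leaky_grad(fw$bn0$y[, 1L], slope)
    bb0 <- bn_backward(matrix(dbn0y, ncol = 1L), fw$bn0, w$bn0)
    g$bn0_gamma <- bb0$dgamma; g$bn0_beta <- bb0$dbeta
    dy0 <- bb0$dx[, 1L]
    g$w0 <- as.numeric(fw$m %*% dy0)
    g$b0 <- sum(dy0)
  }
  g
}

# Flatten trainable parameters (BN running stats excluded) for Adam.
param_names <- function(arch) {
  base <- c("W1", "b1", "bn1_gamma", "bn1_beta",
            "W2", "b2", "bn2_gamma", "bn2_beta",
            "W3", "b3", "bn3_gamma", "bn3_beta",
            "Wa1", "ba1", "Wa2", "ba2", "Wh", "bh")
  if (arch$kind == "dynamic") c("w0", "b0", "bn0_gamma", "bn0_beta", base)
  else base
}

get_param <- function(w, nm) {
  if (grepl("^bn[0-9]+_", nm)) {
    parts <- strsplit(nm, "_")[[1]]
    w[[parts[1]]][[parts[2]]]
  } else w[[nm]]
}

set_param <- function(w, nm, value) {
  if (grepl("^bn[0-9]+_", nm)) {
    parts <- strsplit(nm, "_")[[1]]
    w[[parts[1]]][[parts[2]]] <- value
  } else w[[nm]] <- value
  w
}

#' Train a CNN feature extractor
#'
#' Minimises the cross-entropy of the auxiliary 2-class head with Adam
#' (learning rate `config$learning_rate`) for up to `config$max_epochs`
#' epochs over seeded, shuffled minibatches. The head exists only to
#' give the extractor a training signal; downstream classification uses
#' [extract_features()] outputs, never the head.
#'
#' @param arch a [build_branch()] architecture
#' @param inputs array of stacked FC inputs: `R x R x N` (static) or
#'   `Q x R x R x N` (dynamic)
#' @param labels integer vector of 0/1 labels, length N
#' @param config a [pipeline_config()]
#' @param seed integer seed controlling init, shuffling and dropout
#' @param init optional explicit initial weight list (replaces the
#'   seeded init; shuffling and dropout remain governed by `seed`)
#' @return object of class `"trained_extractor"`: `arch`, `weights`,
#'   `loss_trace` (per-epoch mean loss), `seed`
#' @export
train_extractor <- function(arch, inputs, labels, config, seed, init = NULL) {
  nd <- length(dim(inputs))
  n <- dim(inputs)[nd]
  labels <- as.integer(labels)
  if (length(labels) != n) {
    abort_dimension("train_extractor: %d inputs vs %d labels", n, length(labels))
  }
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L) {
    abort_validation("train_extractor: need at least 2 subjects per class")
  }
  w <- if (is.null(init)) init_weights(arch, derive_seed(seed, 1L)) else init
  nms <- param_names(arch)
  mstate <- vstate <- lapply(nms, function(nm) get_param(w, nm) * 0)
  names(mstate) <- names(vstate) <- nms
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  bsz <- max(2L, min(config$batch_size, n))
  y1 <- cbind(1 - labels, labels)  # columns: class 0, class 1
  loss_trace <- numeric(config$max_epochs)
  step <- 0L

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(derive_seed(seed, 2L))

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = bsz)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + bsz - 1L, n)]
      if (length(idx) < 2L) next  # BN needs at least 2 samples
      xb <- if (nd == 3L) inputs[, , idx, drop = FALSE]
            else inputs[, , , idx, drop = FALSE]
      mask <- if (arch$dropout > 0) {
        matrix(stats::rbinom(length(idx) * 16L, 1L, 1 - arch$dropout),
               length(idx), 16L)
      } else NULL
      fw <- cnn_forward(arch, w, xb, training = TRUE, dropout_mask = mask)
      w <- fw$w  # BN running stats updated
      p <- softmax(fw$logits)
      ll <- -mean(log(pmax(p[cbind(seq_along(idx), labels[idx] + 1L)], 1e-300)))
      if (!is.finite(ll)) {
        rlang::abort(sprintf("train_extractor: non-finite loss at epoch %d",
                             epoch), class = "fchybrid_error_runtime")
      }
      ep_loss <- ep_loss + ll * length(idx)
      grads <- cnn_backward(arch, w, fw, y1[idx, , drop = FALSE])
      step <- step + 1L
      for (nm in nms) {
        gi <- grads[[nm]]
        if (is.null(gi)) next
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * gi
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * gi^2
        mhat <- mstate[[nm]] / (1 - beta1^step)
        vhat <- vstate[[nm]] / (1 - beta2^step)
        set_param(w, nm, get_param(w, nm) - lr * mhat / (sqrt(vhat) + eps)) -> w
      }
    }
    loss_trace[epoch] <- ep_loss / n
  }
  structure(list(arch = arch, weights = w, loss_trace = loss_trace,
                 seed = as.integer(seed)),
            class = "trained_extractor")
}

#' @export
print.trained_extractor <- function(x, ...) {
  cat(sprintf("<trained_extractor: %s branch, R=%d%s, final loss %.4f>\n",
              x$arch$kind, x$arch$n_roi,
              if (x$arch$kind == "dynamic") sprintf(", Q=%d", x$arch$in_channels) else "",
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Extract attention-weighted deep features
#'
#' Runs the branch in inference mode (dropout off, batch normalisation
#' using running statistics) and returns the sigmoid-gated 16-vector
#' per subject together with the gate weights themselves.
#'
#' @param model a [train_extractor()] result
#' @param inputs one input (`R x R` or `Q x R x R`) or a stacked batch
#'   with one extra trailing dimension
#' @return list: `features` (N x 16), `attention` (N x 16, in (0, 1)),
#'   `pre_attention` (N x 16)
#' @export
extract_features <- function(model, inputs) {
  arch <- model$arch
  nd_single <- if (arch$kind == "dynamic") 3L else 2L
  d <- dim(inputs)
  if (length(d) == nd_single) {
    inputs <- array(inputs, dim = c(d, 1L))
  } else if (length(d) != nd_single + 1L) {
    abort_dimension("extract_features: unexpected input rank %d", length(d))
  }
  fw <- cnn_forward(arch, model$weights, inputs, training = FALSE)
  list(features = fw$feat, attention = fw$g, pre_attention = fw$d)
}

#' Head predictions of a trained extractor (diagnostic)
#'
#' @param model a [train_extractor()] result
#' @param inputs stacked input array
#' @return integer vector of predicted 0/1 labels
#' @export
cnn_predict <- function(model, inputs) {
  fw <- cnn_forward(model$arch, model$weights, inputs, training = FALSE)
  as.integer(fw$logits[, 2L] > fw$logits[, 1L])
}
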