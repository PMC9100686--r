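#' Configuration of the structural (3D convolution) branch
#'
#' The branch stacks convolution blocks (3D convolution with same
#' padding and stride 1, batch normalization, ReLU, then non-overlapping
#' max pooling with floor division of the spatial extent), collapses the
#' final feature map with global average pooling, and finishes with two
#' fully-connected ReLU layers (dropout after each in training mode)
#' producing the structural embedding. With the defaults and a
#' 121 x 145 x 121 gray-matter volume the spatial chain is
#' 121x145x121 -> 60x72x60 -> 30x36x30 -> 15x18x15 -> 7x9x7 with
#' 16/32/64/128 channels, a 128-vector after pooling, and a
#' 64-dimensional embedding.
#'
#' @param convChannels output channels per block (default
#'   `c(16, 32, 64, 128)`); the number of blocks is its length.
#' @param kernelSize odd convolution kernel edge (default 3).
#' @param poolSize max-pool window and stride (default 2).
#' @param fcWidths widths of the two fully-connected layers (default
#'   `c(128, 64)`); the second is the embedding width.
#' @param dropout dropout probability after each fully-connected layer in
#'   training mode (default 0.5).
#' @param zscore if `TRUE` (default) volumes are standardized per subject
#'   (mean 0, sd 1 over voxels) before the first block.
#' @return A list of class `cnn_config`.
#' @export
cnnBranchConfig <- function(convChannels = c(16L, 32L, 64L, 128L),
                            kernelSize = 3L, poolSize = 2L,
                            fcWidths = c(128L, 64L), dropout = 0.5,
                            zscore = TRUE) {
  convChannels <- as.integer(convChannels)
  if (length(convChannels) < 1L || any(convChannels <= 0L))
    stop("convChannels must be a nonempty vector of positive integers")
  kernelSize <- as.integer(kernelSize)
  if (kernelSize < 1L || kernelSize %% 2L == 0L)
    stop("kernelSize must be a positive odd integer (same padding)")
  poolSize <- as.integer(poolSize)
  if (poolSize < 1L) stop("poolSize must be a positive integer")
  fcWidths <- as.integer(fcWidths)
  if (length(fcWidths) != 2L || any(fcWidths <= 0L))
    stop("fcWidths must be two positive integers")
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1)
    stop("dropout must lie in [0, 1)")
  structure(list(convChannels = convChannels, kernelSize = kernelSize,
                 poolSize = poolSize, fcWidths = fcWidths,
                 dropout = dropout, zscore = isTRUE(zscore)),
            class = "cnn_config")
}

#' Shape propagation through the convolution blocks
#'
#' Computes the deterministic chain of feature-map shapes for a given
#' configuration and input volume shape: same-padding stride-1
#' convolutions preserve the spatial extent, and each max-pool divides it
#' by the pool size with floor rounding (trailing voxels that do not fill
#' a window are dropped). Used to validate a configuration before any
#' weights are allocated.
#'
#' @param config a [cnnBranchConfig()].
#' @param inputShape integer triple, input volume extent.
#' @return A data.frame with columns `layer`, `h`, `w`, `d`, `channels`,
#'   one row per stage (input, each convolution and pooling layer, and
#'   the global-average-pool output).
#' @examples
#' propagateShapes(cnnBranchConfig(), c(121, 145, 121))
#' @export
propagateShapes <- function(config, inputShape) {
  stopifnot(inherits(config, "cnn_config"))
  shape <- as.integer(inputShape)
  if (length(shape) != 3L || any(shape < config$kernelSize))
    stop("inputShape must be a triple with every extent >= kernel size")
  rows <- list(data.frame(layer = "input", h = shape[1], w = shape[2],
                          d = shape[3], channels = 1L))
  for (i in seq_along(config$convChannels)) {
    ch <- config$convChannels[i]
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("C%d", i), h = shape[1], w = shape[2],
                 d = shape[3], channels = ch)
    shape <- shape %/% config$poolSize
    if (any(shape < 1L))
      stop(sprintf(
        "config error: pooling stage M%d collapses the volume to %dx%dx%d; use fewer blocks or a larger input",
        i, shape[1], shape[2], shape[3]))
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("M%d", i), h = shape[1], w = shape[2],
                 d = shape[3], channels = ch)
  }
  ch <- config$convChannels[length(config$convChannels)]
  rows[[length(rows) + 1L]] <-
    data.frame(layer = "GAP", h = 1L, w = 1L, d = 1L, channels = ch)
  do.call(rbind, rows)
}

# ---- batch normalization ----------------------------------------------

bn_state <- function(channels, eps = 1e-5, momentum = 0.1) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       runMean = rep(0, channels), runVar = rep(1, channels),
       eps = eps, momentum = momentum)
}

# x: 5-d tensor (H,W,D,B,C). Returns normalized tensor + cache; in train
# mode also the updated running moments (biased variance normalizes the
# batch, unbiased variance feeds the running estimate).
bn_forward <- function(x, bn, train) {
  d <- dim(x)
  C <- d[5]
  n <- prod(d[1:4])
  m <- matrix(x, ncol = C)
  if (train) {
    mu <- colMeans(m)
    varb <- colMeans(m^2) - mu^2
    varb[varb < 0] <- 0
    invstd <- 1 / sqrt(varb + bn$eps)
    newRun <- list(
      runMean = (1 - bn$momentum) * bn$runMean + bn$momentum * mu,
      runVar = (1 - bn$momentum) * bn$runVar +
        bn$momentum * varb * n / max(n - 1, 1))
  } else {
    mu <- bn$runMean
    invstd <- 1 / sqrt(bn$runVar + bn$eps)
    newRun <- NULL
  }
  xhat <- (m - rep(mu, each = n)) * rep(invstd, each = n)
  y <- xhat * rep(bn$gamma, each = n) + rep(bn$beta, each = n)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, dims = d),
       newRun = newRun)
}

bn_backward <- function(dy, bn, cache) {
  d <- cache$dims
  C <- d[5]
  n <- prod(d[1:4])
  dym <- matrix(dy, ncol = C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(bn$gamma, each = n)
  sx <- colSums(dxhat)
  sxx <- colSums(dxhat * cache$xhat)
  dx <- (dxhat - rep(sx / n, each = n) -
           cache$xhat * rep(sxx / n, each = n)) * rep(cache$invstd, each = n)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- weight allocation -------------------------------------------------

init_cnn_branch <- function(config, inputShape) {
  shapes <- propagateShapes(config, inputShape)
  k <- config$kernelSize
  chans <- c(1L, config$convChannels)
  blocks <- vector("list", length(config$convChannels))
  for (i in seq_along(blocks)) {
    fanIn <- k^3 * chans[i]
    fanOut <- k^3 * chans[i + 1L]
    blocks[[i]] <- list(
      W = glorot(fanIn, fanOut, dims = c(k, k, k, chans[i], chans[i + 1L])),
      b = numeric(chans[i + 1L]),
      bn = bn_state(chans[i + 1L]))
  }
  cLast <- config$convChannels[length(config$convChannels)]
  list(blocks = blocks,
       fc1W = glorot(cLast, config$fcWidths[1]),
       fc1b = numeric(config$fcWidths[1]),
       fc2W = glorot(config$fcWidths[1], config$fcWidths[2]),
       fc2b = numeric(config$fcWidths[2]),
       config = config, inputShape = as.integer(inputShape),
       shapes = shapes)
}

# ---- exported single-volume operations ---------------------------------

as_tensor5 <- function(V) {
  d <- dim(V)
  if (is.null(d) || !length(d) %in% c(3L, 4L))
    stop("expected a 3D volume or 4D (H, W, D, channels) array")
  if (length(d) == 3L) d <- c(d, 1L)
  array(V, dim = c(d[1:3], 1L, d[4]))
}

#' Forward pass of one convolution block
#'
#' Applies same-padding stride-1 3D convolution, batch normalization
#' (spatial statistics in training mode, running moments in evaluation
#' mode; skipped when the block carries `bn = FALSE`), ReLU, and
#' non-overlapping max pooling to a single feature volume.
#'
#' @param V input array, `(H, W, D)` or `(H, W, D, channels)`.
#' @param blockState list with convolution kernel `W`
#'   (`k x k x k x inChannels x outChannels`), bias `b`, optionally `bn`
#'   (a batch-norm state or `FALSE`), and `poolSize`.
#' @param mode `"eval"` (default) or `"train"`.
#' @return Array `(H/pool, W/pool, D/pool, outChannels)` (floor division).
#' @export
convBlockForward <- function(V, blockState, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  x <- as_tensor5(V)
  y <- conv3d_fw(x, blockState$W, blockState$b)
  bn <- blockState$bn
  if (!is.null(bn) && !isFALSE(bn))
    y <- bn_forward(y, bn, train = identical(mode, "train"))$y
  y <- pmax(y, 0)
  pool <- blockState$poolSize %||% 2L
  out <- maxpool3d_fw(y, as.integer(pool))$y
  d <- dim(out)
  array(out, dim = c(d[1:3], d[5]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Global average pooling
#'
#' Collapses a feature map to one value per channel by averaging over all
#' voxels: `g_j = sum_{h,w,d} v_j^{h,w,d} / (H W D)`.
#'
#' @param V array `(H, W, D, channels)` (or a 3D array, treated as one
#'   channel).
#' @return numeric vector of length `channels`.
#' @export
globalAveragePool <- function(V) {
  d <- dim(V)
  if (is.null(d) || !length(d) %in% c(3L, 4L))
    stop("expected a 3D volume or 4D (H, W, D, channels) array")
  if (length(d) == 3L) d <- c(d, 1L)
  if (any(d[1:3] < 1L)) stop("empty spatial dimensions")
  colMeans(matrix(V, ncol = d[4]))
}

#' Fully-connected head of the structural branch
#'
#' Maps the pooled channel vector through two affine + ReLU layers, with
#' dropout after each layer in training mode, producing the structural
#' embedding.
#'
#' @param gS pooled channel vector from [globalAveragePool()].
#' @param state branch state (elements `fc1W`, `fc1b`, `fc2W`, `fc2b`,
#'   and `config$dropout`).
#' @param mode `"eval"` (default, deterministic) or `"train"`.
#' @param subjectId identifier attached to the returned feature.
#' @return A [BranchFeature-class] with `modality = "structural"`.
#' @export
cnnHeadForward <- function(gS, state, mode = c("eval", "train"),
                           subjectId = "subject") {
  mode <- match.arg(mode)
  gS <- as.numeric(gS)
  if (length(gS) != nrow(state$fc1W))
    stop(sprintf("input length %d does not match first FC width %d",
                 length(gS), nrow(state$fc1W)))
  p <- if (identical(mode, "train")) state$config$dropout %||% 0 else 0
  h <- pmax(drop(gS %*% state$fc1W) + state$fc1b, 0)
  if (p > 0) h <- h * (stats::runif(length(h)) >= p) / (1 - p)
  v <- pmax(drop(h %*% state$fc2W) + state$fc2b, 0)
  if (p > 0) v <- v * (stats::runif(length(v)) >= p) / (1 - p)
  new("BranchFeature", subjectId = as.character(subjectId),
      modality = "structural", values = v)
}

# Re-estimate batch-norm population moments with frozen weights: one pass
# over the data in batches, forward with batch statistics, accumulating
# exact (not exponential) per-channel means and variances. Running
# moments estimated during optimization lag the weights they normalize;
# re-estimation makes evaluation-mode normalization consistent with the
# final weights.
cnn_recalibrate_bn <- function(state, prepared, idx, batchSize = 32L) {
  nBlocks <- length(state$blocks)
  acc <- lapply(seq_len(nBlocks), function(i) list(w = 0, m = 0, e2 = 0))
  starts <- seq(1L, length(idx), by = batchSize)
  for (s in starts) {
    bidx <- idx[s:min(s + batchSize - 1L, length(idx))]
    if (length(bidx) < 2L) next
    fw <- cnn_forward_batch(assemble_volumes(prepared, bidx), state,
                            train = TRUE)
    for (i in seq_len(nBlocks)) {
      ck <- fw$cache$blocks[[i]]
      varb <- 1 / ck$invstd^2 - state$blocks[[i]]$bn$eps
      w <- length(bidx)
      acc[[i]]$w <- acc[[i]]$w + w
      acc[[i]]$m <- acc[[i]]$m + w * ck$mu
      acc[[i]]$e2 <- acc[[i]]$e2 + w * (varb + ck$mu^2)
    }
  }
  for (i in seq_len(nBlocks)) {
    if (acc[[i]]$w == 0) next
    m <- acc[[i]]$m / acc[[i]]$w
    v <- acc[[i]]$e2 / acc[[i]]$w - m^2
    state$blocks[[i]]$bn$runMean <- m
    state$blocks[[i]]$bn$runVar <- pmax(v, 0)
  }
  state
}

# ---- batched forward/backward used by the trainer ----------------------

# x: 5-d tensor (H,W,D,B,1), already standardized. Returns embeddings
# (B x fcWidths[2]) and caches; in train mode updates running moments
# in-place via the returned newBn list and draws dropout masks from the
# current RNG stream.
cnn_forward_batch <- function(x, state, train = FALSE) {
  nBlocks <- length(state$blocks)
  caches <- vector("list", nBlocks)
  newBn <- vector("list", nBlocks)
  pool <- state$config$poolSize
  for (i in seq_len(nBlocks)) {
    blk <- state$blocks[[i]]
    convOut <- conv3d_fw(x, blk$W, blk$b)
    bn <- blk$bn
    if (train) {
      st <- bn3d_stats(convOut)
      mu <- st$mean
      n <- prod(dim(convOut)[1:4])
      invstd <- 1 / sqrt(st$var + bn$eps)
      newBn[[i]] <- list(
        runMean = (1 - bn$momentum) * bn$runMean + bn$momentum * mu,
        runVar = (1 - bn$momentum) * bn$runVar +
          bn$momentum * st$var * n / max(n - 1, 1))
    } else {
      mu <- bn$runMean
      invstd <- 1 / sqrt(bn$runVar + bn$eps)
    }
    scale <- bn$gamma * invstd
    y <- bn3d_apply(convOut, scale, bn$beta - mu * scale)
    act <- relu_fw(y)
    pooled <- maxpool3d_fw(act$y, pool)
    caches[[i]] <- list(x = x, convOut = convOut, mu = mu, invstd = invstd,
                        mask = act$mask, poolIdx = pooled$idx,
                        actDim = dim(y))
    x <- pooled$y
  }
  d <- dim(x)
  B <- d[4]; C <- d[5]
  g <- matrix(.colMeans(x, prod(d[1:3]), B * C), B, C)
  p <- if (train) state$config$dropout else 0
  pre1 <- g %*% state$fc1W + matrix(state$fc1b, B, ncol(state$fc1W), byrow = TRUE)
  h1 <- pmax(pre1, 0)
  mask1 <- if (p > 0) (matrix(stats::runif(length(h1)), B) >= p) / (1 - p) else NULL
  h1d <- if (p > 0) h1 * mask1 else h1
  pre2 <- h1d %*% state$fc2W + matrix(state$fc2b, B, ncol(state$fc2W), byrow = TRUE)
  h2 <- pmax(pre2, 0)
  mask2 <- if (p > 0) (matrix(stats::runif(length(h2)), B) >= p) / (1 - p) else NULL
  emb <- if (p > 0) h2 * mask2 else h2
  list(emb = emb,
       cache = list(blocks = caches, gapDim = d, g = g, pre1 = pre1,
                    h1d = h1d, pre2 = pre2, mask1 = mask1, mask2 = mask2),
       newBn = newBn)
}

cnn_backward_batch <- function(dEmb, state, fw) {
  cache <- fw$cache
  if (!is.null(cache$mask2)) dEmb <- dEmb * cache$mask2
  dPre2 <- dEmb * (cache$pre2 > 0)
  gFc2W <- crossprod(cache$h1d, dPre2)
  gFc2b <- colSums(dPre2)
  dH1 <- dPre2 %*% t(state$fc2W)
  if (!is.null(cache$mask1)) dH1 <- dH1 * cache$mask1
  dPre1 <- dH1 * (cache$pre1 > 0)
  gFc1W <- crossprod(cache$g, dPre1)
  gFc1b <- colSums(dPre1)
  dG <- dPre1 %*% t(state$fc1W)

  d <- cache$gapDim
  vox <- prod(d[1:3])
  dPool <- array(rep(as.numeric(dG), each = vox) / vox, dim = d)
  gBlocks <- vector("list", length(state$blocks))
  for (i in rev(seq_along(state$blocks))) {
    blk <- state$blocks[[i]]
    ck <- cache$blocks[[i]]
    dAct <- maxpool3d_bw(dPool, ck$poolIdx, as.integer(ck$actDim))
    dBnOut <- dAct * ck$mask
    dim(dBnOut) <- ck$actDim
    bnGrad <- bn3d_bw(ck$convOut, dBnOut, ck$mu, ck$invstd, blk$bn$gamma)
    convGrad <- conv3d_bw(ck$x, blk$W, bnGrad$dx)
    gBlocks[[i]] <- list(W = convGrad$gw, b = convGrad$gb,
                         gamma = bnGrad$dgamma, beta = bnGrad$dbeta)
    dPool <- convGrad$gx
  }
  list(blocks = gBlocks, fc1W = gFc1W, fc1b = gFc1b,
       fc2W = gFc2W, fc2b = gFc2b)
}
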