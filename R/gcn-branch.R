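#' Configuration of the functional (graph-convolution) branch
#'
#' The branch stacks spectral graph-convolution layers
#' `H^{l+1} = ReLU(Atilde H^l W^l)`, pools node representations with a
#' concatenated mean/max readout, and maps the pooled vector through one
#' fully-connected ReLU layer to the branch embedding used for alignment
#' and fusion.
#'
#' @param layerWidths integer vector of graph-convolution widths
#'   (default `c(64, 64)`).
#' @param headWidth width of the fully-connected head / embedding
#'   (default 64, matching the structural branch).
#' @param dropout dropout probability after the head in training mode
#'   (default 0; the convolutional layers never use dropout).
#' @return A list of class `gcn_config`.
#' @export
gcnBranchConfig <- function(layerWidths = c(64L, 64L), headWidth = 64L,
                            dropout = 0) {
  layerWidths <- as.integer(layerWidths)
  if (length(layerWidths) < 1L || any(layerWidths <= 0L))
    stop("layerWidths must be a nonempty vector of positive integers")
  headWidth <- as.integer(headWidth)
  if (headWidth <= 0L) stop("headWidth must be positive")
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1)
    stop("dropout must lie in [0, 1)")
  structure(list(layerWidths = layerWidths, headWidth = headWidth,
                 dropout = dropout), class = "gcn_config")
}

glorot <- function(fanIn, fanOut, dims = c(fanIn, fanOut)) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# Allocate branch weights. Graph-convolution layers carry no bias (the
# propagation rule has none); the head is affine. Draws from the current
# RNG stream, so callers seed once for the whole model.
init_gcn_branch <- function(config, nRois) {
  widths <- c(nRois, config$layerWidths)
  W <- vector("list", length(config$layerWidths))
  for (l in seq_along(W)) W[[l]] <- glorot(widths[l], widths[l + 1L])
  dLast <- config$layerWidths[length(config$layerWidths)]
  list(W = W,
       headW = glorot(2L * dLast, config$headWidth),
       headB = numeric(config$headWidth),
       config = config)
}

#' Single spectral graph-convolution layer
#'
#' Computes `ReLU(Atilde %*% H %*% W)`: each node's representation is
#' replaced by a degree-weighted average of its neighbourhood (including
#' itself, through the self-loop in the normalized adjacency), linearly
#' transformed and rectified.
#'
#' @param H node representation matrix, N x d_in.
#' @param Anorm a [NormalizedAdjacency-class] (or plain matrix).
#' @param W weight matrix, d_in x d_out.
#' @return N x d_out matrix of rectified node representations.
#' @export
gcnLayerForward <- function(H, Anorm, W) {
  A <- if (is(Anorm, "NormalizedAdjacency")) Anorm@values else as.matrix(Anorm)
  H <- as.matrix(H)
  if (ncol(A) != nrow(H)) stop("adjacency and node matrix sizes are incompatible")
  if (ncol(H) != nrow(W)) stop("node width does not match weight rows")
  pmax(A %*% H %*% W, 0)
}

#' Forward pass of the stacked graph-convolution layers
#'
#' Applies every configured layer to the graph's node features
#' (`X = B`, the connectivity matrix), i.e. for the default two layers
#' `Z = ReLU(Atilde ReLU(Atilde X W0) W1)`.
#'
#' @param G a [ConnectivityGraph-class].
#' @param state branch state from the model initializer (list with
#'   element `W`, a list of layer weights).
#' @return N x d_last matrix of node embeddings.
#' @export
gcnStackForward <- function(G, state) {
  stopifnot(is(G, "ConnectivityGraph"))
  A <- normalizeAdjacency(G)@values
  H <- G@nodeFeatures
  for (W in state$W) H <- gcnLayerForward(H, A, W)
  H
}

#' Mean/max graph readout
#'
#' Pools node embeddings into one graph-level vector by concatenating the
#' channel-wise mean and the channel-wise maximum over nodes:
#' `g = mean_i(z_i) || max_i(z_i)`, length `2 d`. Permutation of the
#' nodes leaves the readout unchanged.
#'
#' @param Z node embedding matrix, N x d.
#' @return numeric vector of length `2 d`.
#' @export
graphReadout <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 1L) stop("readout of an empty graph")
  c(colMeans(Z), apply(Z, 2, max))
}

#' Fully-connected head of the functional branch
#'
#' Maps the pooled readout vector (length `2 d_last`) through one affine
#' layer with ReLU to the branch embedding, so the functional and
#' structural embeddings live in spaces of equal width for the MMD
#' penalty and fusion.
#'
#' @param pooled readout vector from [graphReadout()].
#' @param state branch state (elements `headW`, `headB`).
#' @param subjectId identifier attached to the returned feature.
#' @return A [BranchFeature-class] with `modality = "functional"`.
#' @export
gcnHeadForward <- function(pooled, state, subjectId = "subject") {
  pooled <- as.numeric(pooled)
  if (length(pooled) != nrow(state$headW))
    stop(sprintf("pooled length %d does not match head input width %d",
                 length(pooled), nrow(state$headW)))
  v <- pmax(drop(pooled %*% state$headW) + state$headB, 0)
  new("BranchFeature", subjectId = as.character(subjectId),
      modality = "functional", values = v)
}

# ---- batched forward/backward used by the trainer ----------------------

# graphs: list of list(A = normalized adjacency matrix, X = node features)
# Returns embeddings (batch x headWidth) plus caches for the backward pass.
gcn_forward_batch <- function(graphs, state, train = FALSE) {
  nb <- length(graphs)
  nLayers <- length(state$W)
  caches <- vector("list", nb)
  pooledDim <- 2L * ncol(state$W[[nLayers]])
  P <- matrix(0, nb, pooledDim)
  for (s in seq_len(nb)) {
    A <- graphs[[s]]$A
    H <- graphs[[s]]$X
    Hs <- vector("list", nLayers + 1L)
    Hs[[1L]] <- H
    for (l in seq_len(nLayers)) {
      pre <- A %*% Hs[[l]] %*% state$W[[l]]
      Hs[[l + 1L]] <- pmax(pre, 0)
    }
    Z <- Hs[[nLayers + 1L]]
    am <- max.col(t(Z), ties.method = "first")  # argmax node per channel
    d <- ncol(Z)
    P[s, ] <- c(colMeans(Z), Z[cbind(am, seq_len(d))])
    caches[[s]] <- list(Hs = Hs, argmax = am)
  }
  pre <- P %*% state$headW +
    matrix(state$headB, nb, length(state$headB), byrow = TRUE)
  emb <- pmax(pre, 0)
  list(emb = emb, cache = list(P = P, pre = pre, caches = caches,
                               graphs = graphs))
}

# dEmb: batch x headWidth gradient. Returns gradient list matching state.
gcn_backward_batch <- function(dEmb, state, fw) {
  nb <- nrow(dEmb)
  nLayers <- length(state$W)
  dPre <- dEmb * (fw$cache$pre > 0)
  gHeadW <- crossprod(fw$cache$P, dPre)
  gHeadB <- colSums(dPre)
  dP <- dPre %*% t(state$headW)
  gW <- lapply(state$W, function(w) array(0, dim(w)))
  for (s in seq_len(nb)) {
    cache <- fw$cache$caches[[s]]
    A <- fw$cache$graphs[[s]]$A
    Z <- cache$Hs[[nLayers + 1L]]
    n <- nrow(Z); d <- ncol(Z)
    dZ <- matrix(dP[s, seq_len(d)] / n, n, d, byrow = TRUE)
    maxPart <- dP[s, d + seq_len(d)]
    dZ[cbind(cache$argmax, seq_len(d))] <-
      dZ[cbind(cache$argmax, seq_len(d))] + maxPart
    for (l in rev(seq_len(nLayers))) {
      dPreL <- dZ * (cache$Hs[[l + 1L]] > 0)
      AH <- A %*% cache$Hs[[l]]
      gW[[l]] <- gW[[l]] + crossprod(AH, dPreL)
      if (l > 1L) dZ <- A %*% (dPreL %*% t(state$W[[l]]))
    }
  }
  list(W = gW, headW = gHeadW, headB = gHeadB)
}
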