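#' Cross-modal maximum mean discrepancy
#'
#' Measures the discrepancy between the functional and structural
#' embedding batches. With the default linear kernel (identity feature
#' map) this is the Euclidean distance between the two batch means,
#' \deqn{L_M = \left\| \tfrac{1}{|G_F|}\sum g_F - \tfrac{1}{|G_S|}\sum g_S \right\|,}
#' the form used as the alignment penalty during training. An RBF kernel
#' with median-heuristic bandwidth is available as an option (the
#' standard biased kernel-MMD estimate). The unsquared norm is the
#' default; `squared = TRUE` returns its square.
#'
#' @param F_batch,S_batch numeric matrices (batch x width), one embedding
#'   per row; widths must match.
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param squared return the squared statistic (default `FALSE`).
#' @param bandwidth RBF bandwidth; `NULL` (default) uses the median
#'   heuristic on the pooled pairwise distances.
#' @return A single nonnegative number; 0 when the two batches coincide.
#' @export
mmdLoss <- function(F_batch, S_batch, kernel = c("linear", "rbf"),
                    squared = FALSE, bandwidth = NULL) {
  kernel <- match.arg(kernel)
  F_batch <- as.matrix(F_batch)
  S_batch <- as.matrix(S_batch)
  if (ncol(F_batch) != ncol(S_batch))
    stop("the two batches must have equal feature width")
  if (nrow(F_batch) < 1L || nrow(S_batch) < 1L)
    stop("batches must be nonempty")
  if (kernel == "linear") {
    diff <- colMeans(F_batch) - colMeans(S_batch)
    m2 <- sum(diff^2)
  } else {
    z <- rbind(F_batch, S_batch)
    d2 <- as.matrix(stats::dist(z))^2
    if (is.null(bandwidth)) {
      off <- d2[upper.tri(d2)]
      med <- stats::median(off[off > 0])
      if (!is.finite(med) || med <= 0) med <- 1
      bandwidth <- sqrt(med / 2)
    }
    kmat <- exp(-d2 / (2 * bandwidth^2))
    nf <- nrow(F_batch)
    ns <- nrow(S_batch)
    iF <- seq_len(nf)
    iS <- nf + seq_len(ns)
    m2 <- mean(kmat[iF, iF, drop = FALSE]) +
      mean(kmat[iS, iS, drop = FALSE]) -
      2 * mean(kmat[iF, iS, drop = FALSE])
    m2 <- max(m2, 0)
  }
  if (squared) m2 else sqrt(m2)
}

# Gradient of the unsquared linear-kernel MMD w.r.t. both batches.
# Returns zero gradients at the (non-differentiable) origin.
mmd_linear_grad <- function(F_batch, S_batch, eps = 1e-12) {
  diff <- colMeans(F_batch) - colMeans(S_batch)
  nrm <- sqrt(sum(diff^2))
  if (nrm < eps) {
    return(list(value = 0,
                dF = matrix(0, nrow(F_batch), ncol(F_batch)),
                dS = matrix(0, nrow(S_batch), ncol(S_batch))))
  }
  u <- diff / nrm
  list(value = nrm,
       dF = matrix(u / nrow(F_batch), nrow(F_batch), length(u), byrow = TRUE),
       dS = matrix(-u / nrow(S_batch), nrow(S_batch), length(u), byrow = TRUE))
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

init_fusion_head <- function(inputWidth, hidden = 64L, classes = 2L) {
  list(W1 = glorot(inputWidth, hidden), b1 = numeric(hidden),
       W2 = glorot(hidden, classes), b2 = numeric(classes))
}

# emb: batch x inputWidth. Returns class probabilities and cache.
fusion_forward_batch <- function(emb, state) {
  B <- nrow(emb)
  pre1 <- emb %*% state$W1 + matrix(state$b1, B, ncol(state$W1), byrow = TRUE)
  h <- pmax(pre1, 0)
  logits <- h %*% state$W2 + matrix(state$b2, B, ncol(state$W2), byrow = TRUE)
  prob <- softmax_rows(logits)
  list(prob = prob, cache = list(emb = emb, pre1 = pre1, h = h))
}

# dLogits: batch x 2 (already includes the 1/N of the mean loss).
fusion_backward_batch <- function(dLogits, state, fw) {
  cache <- fw$cache
  gW2 <- crossprod(cache$h, dLogits)
  gb2 <- colSums(dLogits)
  dH <- dLogits %*% t(state$W2)
  dPre1 <- dH * (cache$pre1 > 0)
  gW1 <- crossprod(cache$emb, dPre1)
  gb1 <- colSums(dPre1)
  dEmb <- dPre1 %*% t(state$W1)
  list(grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2), dEmb = dEmb)
}

#' Fuse two branch embeddings and classify
#'
#' Concatenates the functional and structural embeddings (functional
#' first), passes the joint vector through the fusion head (affine + ReLU
#' to 64 units, affine to 2 logits) and a softmax, and predicts the class
#' with the larger probability.
#'
#' @param f1 functional [BranchFeature-class] (or numeric vector).
#' @param f2 structural [BranchFeature-class] (or numeric vector).
#' @param state fusion head state (`W1`, `b1`, `W2`, `b2`).
#' @param subjectId identifier for the returned row.
#' @return A one-row data.frame with columns `subjectId`, `p0`, `p1`,
#'   `predicted` (0/1; class 1 is the patient class).
#' @export
fuseAndClassify <- function(f1, f2, state, subjectId = NULL) {
  v1 <- if (is(f1, "BranchFeature")) f1@values else as.numeric(f1)
  v2 <- if (is(f2, "BranchFeature")) f2@values else as.numeric(f2)
  if (is.null(subjectId))
    subjectId <- if (is(f1, "BranchFeature")) f1@subjectId else "subject"
  emb <- matrix(c(v1, v2), nrow = 1)
  if (ncol(emb) != nrow(state$W1))
    stop(sprintf("concatenated width %d does not match head input %d",
                 ncol(emb), nrow(state$W1)))
  prob <- fusion_forward_batch(emb, state)$prob
  data.frame(subjectId = as.character(subjectId), p0 = prob[1, 1],
             p1 = prob[1, 2], predicted = as.integer(prob[1, 2] >= prob[1, 1]),
             stringsAsFactors = FALSE)
}

#' Mean binary cross-entropy
#'
#' \deqn{L_C = -\tfrac{1}{N}\sum_i \big(y_i \log p_i + (1-y_i)\log(1-p_i)\big)}
#' where `p_i` is the predicted probability of class 1 (the patient
#' class). Probabilities are clipped to `[1e-7, 1 - 1e-7]` before the
#' logarithm.
#'
#' @param prob numeric vector of class-1 probabilities.
#' @param labels 0/1 truth labels, same length.
#' @return A single nonnegative number.
#' @export
crossEntropyLoss <- function(prob, labels) {
  prob <- as.numeric(prob)
  labels <- as.numeric(labels)
  if (length(prob) == 0L) stop("empty prediction set")
  if (length(prob) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Total training loss
#'
#' `L = L_C + lambda * L_M`: classification loss plus the weighted
#' cross-modal alignment penalty.
#'
#' @param lossCE classification (cross-entropy) term.
#' @param lossMMD alignment (MMD) term.
#' @param lambda nonnegative weight of the alignment term.
#' @return A single number.
#' @export
totalLoss <- function(lossCE, lossMMD, lambda) {
  stopifnot(is.finite(lossCE), is.finite(lossMMD),
            is.finite(lambda), lambda >= 0)
  lossCE + lambda * lossMMD
}

#' Decision-level fusion of two branch predictions
#'
#' Weighted sum of the two per-branch softmax outputs:
#' `p = w_f * p_functional + (1 - w_f) * p_structural`.
#'
#' @param fProb functional-branch probability pair `(p0, p1)`.
#' @param sProb structural-branch probability pair `(p0, p1)`.
#' @param wF weight of the functional branch, in \[0, 1\].
#' @return A list with `prob` (fused pair) and `predicted` (0/1).
#' @export
lateFusionForward <- function(fProb, sProb, wF = 0.5) {
  fProb <- as.numeric(fProb)
  sProb <- as.numeric(sProb)
  if (length(fProb) != 2L || length(sProb) != 2L)
    stop("probability inputs must be pairs")
  if (!is.numeric(wF) || length(wF) != 1L || wF < 0 || wF > 1)
    stop("wF must lie in [0, 1]")
  p <- wF * fProb + (1 - wF) * sProb
  list(prob = p, predicted = as.integer(p[2] >= p[1]))
}
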