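#' Construct a TimeSeriesMatrix
#'
#' @param values numeric matrix, M time points (rows) x N ROIs (columns).
#' @param subjectId subject identifier.
#' @param roiNames optional ROI names; defaults to column names of
#'   `values`, or `roi1..roiN`.
#' @return A validated [TimeSeriesMatrix-class] object.
#' @examples
#' ts <- TimeSeriesMatrix(matrix(rnorm(40), 10, 4), "s01")
#' pearsonFCN(ts)
#' @export
TimeSeriesMatrix <- function(values, subjectId = "subject",
                             roiNames = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(roiNames)) {
    roiNames <- colnames(values)
    if (is.null(roiNames)) roiNames <- paste0("roi", seq_len(ncol(values)))
  }
  colnames(values) <- roiNames
  new("TimeSeriesMatrix", subjectId = as.character(subjectId),
      values = values, roiNames = as.character(roiNames))
}

#' Construct a VolumeImage
#'
#' @param values 3D numeric array.
#' @param subjectId subject identifier.
#' @param voxelSize voxel edge lengths in mm (length-3).
#' @return A validated [VolumeImage-class] object.
#' @export
VolumeImage <- function(values, subjectId = "subject",
                        voxelSize = c(1, 1, 1)) {
  values <- as.array(values)
  storage.mode(values) <- "double"
  new("VolumeImage", subjectId = as.character(subjectId), values = values,
      voxelSize = as.numeric(voxelSize))
}

#' Pearson functional connectivity matrix
#'
#' Computes the N x N matrix of Pearson correlation coefficients between
#' the regional BOLD series: for ROIs i and j with series y_i, y_j and
#' means ybar_i, ybar_j,
#' \deqn{b_{ij} = \frac{(y_i - \bar y_i)^\top (y_j - \bar y_j)}{
#'   \sqrt{(y_i - \bar y_i)^\top (y_i - \bar y_i)}
#'   \sqrt{(y_j - \bar y_j)^\top (y_j - \bar y_j)}}.}
#' This is the static, full-scan estimator; any ROI with zero temporal
#' variance makes its correlations undefined and is reported as an error.
#'
#' @param ts a [TimeSeriesMatrix-class].
#' @return A [ConnectivityMatrix-class] with unit diagonal and entries in
#'   \[-1, 1\].
#' @export
pearsonFCN <- function(ts) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  y <- ts@values
  sds <- apply(y, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    stop(sprintf(
      "degenerate input: ROI '%s' (column %d) has zero variance; Pearson correlation is undefined",
      ts@roiNames[bad], bad))
  }
  b <- stats::cor(y)
  # guard against rounding drift outside the admissible range
  b[b > 1] <- 1
  b[b < -1] <- -1
  b <- (b + t(b)) / 2
  diag(b) <- 1
  dimnames(b) <- list(ts@roiNames, ts@roiNames)
  new("ConnectivityMatrix", values = b, kind = "pearson",
      roiNames = ts@roiNames)
}

edge_strength <- function(b, weight) {
  if (weight == "absolute") abs(b) else b
}

#' Build a k-nearest-neighbour graph from a connectivity matrix
#'
#' For each node, the k edges with the largest connectivity strength
#' (by default the absolute Pearson coefficient, so strong
#' anticorrelations count) are retained; the directed top-k relation is
#' then symmetrized by logical OR, so an edge survives if either endpoint
#' selected it. Ties at the k-th rank are broken towards the lower ROI
#' index for cross-platform determinism. Node features are the
#' connectivity matrix itself.
#'
#' @param B a [ConnectivityMatrix-class].
#' @param k neighbours per node, in `1..N-1`.
#' @param weight `"absolute"` (default) ranks edges by `|b_ij|`;
#'   `"signed"` ranks by the raw coefficient.
#' @return A binary [ConnectivityGraph-class]; every node has degree >= k.
#' @export
buildKnnGraph <- function(B, k = 10L, weight = c("absolute", "signed")) {
  stopifnot(is(B, "ConnectivityMatrix"))
  weight <- match.arg(weight)
  b <- B@values
  n <- nrow(b)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n - 1L)
    stop(sprintf("k must be an integer in [1, %d], got %s", n - 1L, k))
  s <- edge_strength(b, weight)
  dimnames(s) <- NULL
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    # order by decreasing strength, ties towards lower ROI index
    ord <- cand[order(-s[i, cand], cand)]
    a[i, ord[seq_len(k)]] <- 1
  }
  a <- pmax(a, t(a))  # logical OR symmetrization
  new("ConnectivityGraph", adjacency = a, nodeFeatures = b,
      strategy = "knn", strategyParam = as.numeric(k))
}

#' Build a threshold graph from a connectivity matrix
#'
#' Binarizes the connectivity matrix: `a_ij = 1` iff the connectivity
#' strength exceeds the threshold `q` (strictly) and `i != j`. By default
#' the strength is the absolute coefficient, consistent with the KNN
#' construction; set `weight = "signed"` to threshold raw coefficients.
#'
#' @param B a [ConnectivityMatrix-class].
#' @param q nonnegative threshold (default 0.2).
#' @param weight `"absolute"` (default) or `"signed"`.
#' @return A binary [ConnectivityGraph-class].
#' @export
buildThresholdGraph <- function(B, q = 0.2, weight = c("absolute", "signed")) {
  stopifnot(is(B, "ConnectivityMatrix"))
  weight <- match.arg(weight)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop("q must be a single nonnegative number")
  b <- B@values
  a <- (edge_strength(b, weight) > q) * 1
  dimnames(a) <- NULL
  diag(a) <- 0
  new("ConnectivityGraph", adjacency = a, nodeFeatures = b,
      strategy = "threshold", strategyParam = q)
}

#' Build a fully-connected weighted graph from a connectivity matrix
#'
#' Takes the absolute connectivity `|b_ij|` as an edge-weighted adjacency
#' (zero diagonal); no sparsification is applied.
#'
#' @param B a [ConnectivityMatrix-class].
#' @return A weighted [ConnectivityGraph-class].
#' @export
buildFullGraph <- function(B) {
  stopifnot(is(B, "ConnectivityMatrix"))
  b <- B@values
  a <- abs(b)
  dimnames(a) <- NULL
  diag(a) <- 0
  new("ConnectivityGraph", adjacency = a, nodeFeatures = b,
      strategy = "full", strategyParam = NA_real_)
}

#' Symmetric normalization of a graph adjacency with self-loops
#'
#' Computes the graph-convolution propagation operator
#' \deqn{\tilde A = \hat D^{-1/2} (A + I) \hat D^{-1/2}}
#' where \eqn{\hat D} is the diagonal degree matrix of \eqn{A + I}. The
#' self-loops guarantee strictly positive degrees, so the operator is
#' always finite, and its spectral radius is at most 1.
#'
#' @param G a [ConnectivityGraph-class] (or a plain symmetric nonnegative
#'   matrix with zero diagonal).
#' @return A [NormalizedAdjacency-class].
#' @export
normalizeAdjacency <- function(G) {
  a <- if (is(G, "ConnectivityGraph")) G@adjacency else as.matrix(G)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (max(abs(a - t(a))) > 1e-8) stop("adjacency must be symmetric")
  if (any(a < 0)) stop("adjacency must be nonnegative")
  aI <- a + diag(nrow(a))
  dInvSqrt <- 1 / sqrt(rowSums(aI))
  v <- aI * (dInvSqrt %o% dInvSqrt)
  v <- (v + t(v)) / 2
  new("NormalizedAdjacency", values = v, includesSelfLoops = TRUE)
}
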