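#' @import methods
NULL

#' Regional BOLD time series for one subject
#'
#' An M x N matrix of BOLD measurements: rows are time points, columns are
#' atlas regions of interest (ROIs). This is the raw material from which
#' Pearson functional-connectivity matrices are computed.
#'
#' @slot subjectId single subject identifier.
#' @slot values numeric matrix, M time points x N ROIs.
#' @slot roiNames character vector of N ROI names.
#'
#' @seealso [TimeSeriesMatrix()] for the validating constructor,
#'   [pearsonFCN()] for connectivity estimation.
#' @export
setClass("TimeSeriesMatrix",
  representation(subjectId = "character", values = "matrix",
                 roiNames = "character"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be numeric")
    if (nrow(v) < 3L) return("need at least 3 time points")
    if (ncol(v) < 2L) return("need at least 2 ROIs")
    if (anyNA(v) || !all(is.finite(v))) return("values must be finite, no missing entries")
    if (length(object@roiNames) != ncol(v))
      return("roiNames length must equal the number of ROI columns")
    if (anyDuplicated(object@roiNames)) return("duplicate ROI names")
    if (length(object@subjectId) != 1L) return("subjectId must be a single string")
    TRUE
  })

#' Functional connectivity matrix
#'
#' A symmetric N x N matrix of pairwise ROI association strengths with unit
#' diagonal; currently the only supported kind is the Pearson correlation
#' of the regional BOLD series.
#'
#' @slot values symmetric numeric matrix with entries in \[-1, 1\] and unit
#'   diagonal.
#' @slot kind estimator name, currently `"pearson"`.
#' @slot roiNames ROI names carried through from the time series.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", kind = "character",
                 roiNames = "character"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("matrix must be square")
    if (anyNA(v) || !all(is.finite(v))) return("entries must be finite")
    if (max(abs(v - t(v))) > 1e-8) return("matrix must be symmetric")
    if (max(abs(diag(v) - 1)) > 1e-8) return("diagonal must be 1")
    if (max(abs(v)) > 1 + 1e-8) return("entries must lie in [-1, 1]")
    if (!identical(object@kind, "pearson")) return("unsupported kind")
    if (length(object@roiNames) != ncol(v))
      return("roiNames length must equal matrix order")
    TRUE
  })

#' Graph encoding of a functional connectivity matrix
#'
#' Adjacency plus node features, ready for the spectral graph-convolution
#' branch. The adjacency is binary for the `knn` and `threshold`
#' construction strategies and weighted (`|b_ij|`) for `full`; the node
#' feature matrix is always the connectivity matrix itself (each node is
#' described by its connection profile). Self-loops are never stored here;
#' they are added during normalization.
#'
#' @slot adjacency symmetric, nonnegative N x N matrix with zero diagonal.
#' @slot nodeFeatures N x N node-feature matrix (the connectivity matrix).
#' @slot strategy one of `"knn"`, `"threshold"`, `"full"`.
#' @slot strategyParam k for knn, q for threshold, `NA` for full.
#' @export
setClass("ConnectivityGraph",
  representation(adjacency = "matrix", nodeFeatures = "matrix",
                 strategy = "character", strategyParam = "numeric"),
  validity = function(object) {
    a <- object@adjacency
    if (nrow(a) != ncol(a)) return("adjacency must be square")
    if (anyNA(a) || !all(is.finite(a))) return("adjacency must be finite")
    if (max(abs(a - t(a))) > 1e-8) return("adjacency must be symmetric")
    if (any(diag(a) != 0)) return("adjacency diagonal must be zero (no stored self-loops)")
    if (any(a < 0)) return("adjacency must be nonnegative")
    if (!object@strategy %in% c("knn", "threshold", "full"))
      return("unknown strategy")
    if (object@strategy %in% c("knn", "threshold") && !all(a %in% c(0, 1)))
      return("knn/threshold adjacency must be binary")
    if (!identical(dim(a), dim(object@nodeFeatures)))
      return("node features must be N x N, matching the adjacency")
    TRUE
  })

#' Symmetrically normalized adjacency with self-loops
#'
#' Stores D^{-1/2} (A + I) D^{-1/2}, where D is the degree matrix of
#' A + I. This is the propagation operator of each graph-convolution
#' layer.
#'
#' @slot values symmetric N x N numeric matrix.
#' @slot includesSelfLoops always `TRUE` for operators produced by
#'   [normalizeAdjacency()].
#' @export
setClass("NormalizedAdjacency",
  representation(values = "matrix", includesSelfLoops = "logical"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("matrix must be square")
    if (anyNA(v) || !all(is.finite(v))) return("entries must be finite")
    if (max(abs(v - t(v))) > 1e-8) return("matrix must be symmetric")
    TRUE
  })

#' Gray-matter volume for one subject
#'
#' A 3D intensity array (arbitrary units) as produced by upstream
#' segmentation/normalization, together with its voxel size in mm.
#'
#' @slot subjectId single subject identifier.
#' @slot values 3D numeric array H x W x D.
#' @slot voxelSize numeric triple, voxel edge lengths in mm.
#' @export
setClass("VolumeImage",
  representation(subjectId = "character", values = "array",
                 voxelSize = "numeric"),
  validity = function(object) {
    v <- object@values
    if (length(dim(v)) != 3L) return("values must be a 3D array")
    if (anyNA(v) || !all(is.finite(v))) return("values must be finite")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be three positive numbers")
    if (length(object@subjectId) != 1L) return("subjectId must be a single string")
    TRUE
  })

#' Per-subject branch embedding
#'
#' The 64-dimensional (by default) embedding a modality branch produces for
#' one subject; these are the vectors the cross-modal MMD penalty aligns
#' and the fusion head consumes.
#'
#' @slot subjectId subject identifier.
#' @slot modality `"functional"` or `"structural"`.
#' @slot values finite numeric vector.
#' @export
setClass("BranchFeature",
  representation(subjectId = "character", modality = "character",
                 values = "numeric"),
  validity = function(object) {
    if (!object@modality %in% c("functional", "structural"))
      return("modality must be 'functional' or 'structural'")
    if (anyNA(object@values) || !all(is.finite(object@values)))
      return("values must be finite")
    TRUE
  })
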