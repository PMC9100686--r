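#' Accessors for the core data classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `subjectId()` and `roiNames()` apply to most classes, `adjacency()`,
#' `nodeFeatures()`, `graphStrategy()` and `strategyParam()` to
#' [ConnectivityGraph-class] objects, `voxelSize()` to
#' [VolumeImage-class], and `as.matrix()` / `as.array()` return the
#' underlying numeric data.
#'
#' @param x an object of one of the neurofuse data classes.
#' @param ... unused.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

#' @rdname accessors
#' @export
setGeneric("graphStrategy", function(x) standardGeneric("graphStrategy"))

#' @rdname accessors
#' @export
setGeneric("strategyParam", function(x) standardGeneric("strategyParam"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setMethod("subjectId", "TimeSeriesMatrix", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("subjectId", "VolumeImage", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("subjectId", "BranchFeature", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("roiNames", "TimeSeriesMatrix", function(x) x@roiNames)

#' @rdname accessors
#' @export
setMethod("roiNames", "ConnectivityMatrix", function(x) x@roiNames)

#' @rdname accessors
#' @export
setMethod("adjacency", "ConnectivityGraph", function(x) x@adjacency)

#' @rdname accessors
#' @export
setMethod("nodeFeatures", "ConnectivityGraph", function(x) x@nodeFeatures)

#' @rdname accessors
#' @export
setMethod("graphStrategy", "ConnectivityGraph", function(x) x@strategy)

#' @rdname accessors
#' @export
setMethod("strategyParam", "ConnectivityGraph", function(x) x@strategyParam)

#' @rdname accessors
#' @export
setMethod("voxelSize", "VolumeImage", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("as.matrix", "TimeSeriesMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("as.matrix", "ConnectivityMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("as.matrix", "NormalizedAdjacency", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("as.array", "VolumeImage", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("as.numeric", "BranchFeature", function(x, ...) x@values)

setMethod("show", "TimeSeriesMatrix", function(object) {
  cat(sprintf("TimeSeriesMatrix '%s': %d time points x %d ROIs\n",
              object@subjectId, nrow(object@values), ncol(object@values)))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix (%s): %d x %d, range [%.3f, %.3f]\n",
              object@kind, nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "ConnectivityGraph", function(object) {
  nEdges <- sum(object@adjacency[upper.tri(object@adjacency)] != 0)
  param <- if (is.na(object@strategyParam)) "" else
    sprintf(" (param %.3g)", object@strategyParam)
  cat(sprintf("ConnectivityGraph [%s%s]: %d nodes, %d undirected edges\n",
              object@strategy, param, nrow(object@adjacency), nEdges))
})

setMethod("show", "NormalizedAdjacency", function(object) {
  cat(sprintf("NormalizedAdjacency: %d x %d, self-loops %s\n",
              nrow(object@values), ncol(object@values),
              if (object@includesSelfLoops) "included" else "absent"))
})

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("VolumeImage '%s': %d x %d x %d voxels (%.2f x %.2f x %.2f mm)\n",
              object@subjectId, d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
})

setMethod("show", "BranchFeature", function(object) {
  cat(sprintf("BranchFeature '%s' [%s]: length %d\n",
              object@subjectId, object@modality, length(object@values)))
})
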