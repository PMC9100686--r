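default_effect_edges <- function() {
  # cross-community pairs: zero base correlation, so the class shift is
  # the full effect size
  list(c(1L, 6L), c(2L, 7L), c(3L, 8L), c(4L, 9L), c(5L, 10L),
       c(1L, 11L), c(2L, 12L), c(3L, 13L))
}

default_effect_blobs <- function(volumeShape) {
  ctr <- function(f1, f2, f3) round(volumeShape * c(f1, f2, f3))
  list(list(center = ctr(0.35, 0.35, 0.35), radius = 3, delta = -0.5),
       list(center = ctr(0.65, 0.35, 0.6), radius = 3, delta = -0.5),
       list(center = ctr(0.35, 0.65, 0.6), radius = 3, delta = -0.5),
       list(center = ctr(0.65, 0.65, 0.35), radius = 3, delta = -0.5))
}

#' Configuration of the synthetic multimodal cohort generator
#'
#' Describes a two-class cohort with the statistical structure the
#' classifier assumes: the functional modality is a zero-mean
#' multivariate-normal time series whose inter-ROI covariance differs
#' between classes on a chosen edge subset (a community-block base
#' correlation matrix, plus `functionalEffectDelta` on the effect edges
#' for class 1, with positive definiteness enforced by shrinkage), with
#' AR(1) temporal smoothing; the structural modality is a smooth
#' ellipsoidal intensity profile plus Gaussian noise, with
#' class-1 intensity shifts inside spherical blobs (negative deltas model
#' atrophy). `modalitySignalSplit` routes a fraction of the class effects
#' exclusively to the functional modality and the rest exclusively to the
#' structural one, so at 0.5 neither single modality carries the full
#' class signal and multimodal fusion has something to gain.
#'
#' @param nClass0,nClass1 subjects per class (defaults 150/150).
#' @param nRois number of ROIs (default 20).
#' @param nTimepoints time points per series (default 120).
#' @param volumeShape volume extent (default `c(24, 28, 24)`).
#' @param functionalEffectEdges list of ROI index pairs carrying the
#'   class covariance shift.
#' @param functionalEffectDelta covariance shift on those edges
#'   (default 0.4).
#' @param structuralEffectBlobs list of `list(center, radius, delta)`
#'   spherical intensity effects; all blobs must lie inside the volume.
#' @param noiseSd voxelwise Gaussian noise sd of the volumes
#'   (default 0.3).
#' @param structuralPenetrance fraction of class-1 subjects whose volume
#'   carries the blob effects at all (default 1).
#' @param structuralSeverityRange range `c(lo, hi)` of the per-subject
#'   uniform severity multiplier applied to the blob deltas of affected
#'   class-1 subjects (default `c(0.1, 1)`). A disease-severity gradient
#'   is what real patient groups show; it keeps every affected subject
#'   informative for training while leaving mild cases close to the
#'   control distribution, so the structural modality alone cannot reach
#'   perfect accuracy. Severity is recorded per subject.
#' @param temporalArCoeff AR(1) smoothing coefficient in \[0, 1)
#'   (default 0.3); smoothing is variance-preserving, so the
#'   cross-sectional covariance is unchanged.
#' @param modalitySignalSplit fraction of class effects routed to the
#'   functional modality (default 0.5).
#' @param baseCorrelation within-community correlation of the base
#'   covariance (default 0.3, communities of 5 ROIs).
#' @param seed cohort seed.
#' @return list of class `synth_config`.
#' @export
syntheticCohortConfig <- function(nClass0 = 150L, nClass1 = 150L,
                                  nRois = 20L, nTimepoints = 120L,
                                  volumeShape = c(24L, 28L, 24L),
                                  functionalEffectEdges = default_effect_edges(),
                                  functionalEffectDelta = 0.4,
                                  structuralEffectBlobs =
                                    default_effect_blobs(volumeShape),
                                  noiseSd = 0.3,
                                  structuralPenetrance = 1,
                                  structuralSeverityRange = c(0.1, 1),
                                  temporalArCoeff = 0.3,
                                  modalitySignalSplit = 0.5,
                                  baseCorrelation = 0.3, seed = 1L) {
  nRois <- as.integer(nRois)
  nTimepoints <- as.integer(nTimepoints)
  volumeShape <- as.integer(volumeShape)
  if (nClass0 < 1L || nClass1 < 1L) stop("class counts must be positive")
  if (nRois < 2L) stop("need at least 2 ROIs")
  if (nTimepoints < 3L) stop("need at least 3 time points")
  if (length(volumeShape) != 3L || any(volumeShape < 4L))
    stop("volumeShape must be a triple of extents >= 4")
  for (e in functionalEffectEdges) {
    if (length(e) != 2L || any(e < 1L) || any(e > nRois) || e[1] == e[2])
      stop("effect edges must be pairs of distinct ROI indices in range")
  }
  for (b in structuralEffectBlobs) {
    if (any(b$center - b$radius < 1) || any(b$center + b$radius > volumeShape))
      stop("config error: a structural effect blob extends outside the volume")
  }
  if (temporalArCoeff < 0 || temporalArCoeff >= 1)
    stop("temporalArCoeff must lie in [0, 1)")
  if (modalitySignalSplit < 0 || modalitySignalSplit > 1)
    stop("modalitySignalSplit must lie in [0, 1]")
  if (structuralPenetrance < 0 || structuralPenetrance > 1)
    stop("structuralPenetrance must lie in [0, 1]")
  if (length(structuralSeverityRange) != 2L ||
      structuralSeverityRange[1] < 0 ||
      structuralSeverityRange[2] < structuralSeverityRange[1])
    stop("structuralSeverityRange must be an increasing nonnegative pair")
  structure(list(nClass0 = as.integer(nClass0), nClass1 = as.integer(nClass1),
                 nRois = nRois, nTimepoints = nTimepoints,
                 volumeShape = volumeShape,
                 functionalEffectEdges = functionalEffectEdges,
                 functionalEffectDelta = functionalEffectDelta,
                 structuralEffectBlobs = structuralEffectBlobs,
                 noiseSd = noiseSd,
                 structuralPenetrance = structuralPenetrance,
                 structuralSeverityRange = structuralSeverityRange,
                 temporalArCoeff = temporalArCoeff,
                 modalitySignalSplit = modalitySignalSplit,
                 baseCorrelation = baseCorrelation,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Full-scale acquisition constants
#'
#' The dimensions of the real acquisition the generator emulates at desk
#' scale: 112 atlas ROIs, 242 acquired volumes of which the first 10 are
#' discarded (so 232 retained time points), and 121 x 145 x 121
#' gray-matter volumes.
#'
#' @param timepointsAcquired acquired fMRI volumes (default 242).
#' @param timepointsDiscarded initial volumes discarded (default 10).
#' @return list with `nRois`, `nTimepoints`, `volumeShape`.
#' @export
studyScaleDims <- function(timepointsAcquired = 242L,
                           timepointsDiscarded = 10L) {
  list(nRois = 112L,
       nTimepoints = as.integer(timepointsAcquired - timepointsDiscarded),
       volumeShape = c(121L, 145L, 121L))
}

# Community-block base correlation matrix (unit diagonal, PD for
# within-community correlation < 1).
base_covariance <- function(cfg) {
  n <- cfg$nRois
  comm <- ((seq_len(n) - 1L) %/% 5L)
  s <- outer(comm, comm, `==`) * cfg$baseCorrelation
  diag(s) <- 1
  s
}

# Class covariance: base plus delta on the given edges, shrunk toward the
# base just enough to restore positive definiteness (bisection on the
# minimum eigenvalue).
class_covariance <- function(cfg, edges) {
  s0 <- base_covariance(cfg)
  if (length(edges) == 0L) return(s0)
  s1 <- s0
  for (e in edges) {
    s1[e[1], e[2]] <- s1[e[1], e[2]] + cfg$functionalEffectDelta
    s1[e[2], e[1]] <- s1[e[1], e[2]]
  }
  minEig <- function(m) min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  target <- 1e-8
  if (minEig(s1) >= target) return(s1)
  lo <- 0; hi <- 1
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (minEig((1 - mid) * s1 + mid * s0) >= target) hi <- mid else lo <- mid
  }
  out <- (1 - hi) * s1 + hi * s0
  if (minEig(out) < 0)
    stop("generation error: covariance not positive definite after shrinkage")
  out
}

#' Generate one synthetic BOLD time series
#'
#' Draws M multivariate-normal samples with the class covariance (base
#' community-block correlations, plus the configured effect-edge shift
#' for class 1) and applies variance-preserving AR(1) smoothing
#' `x_t = a x_{t-1} + sqrt(1 - a^2) z_t`. Draws from the current RNG
#' stream; seed before calling for reproducibility.
#'
#' @param cfg a [syntheticCohortConfig()].
#' @param label 0 or 1.
#' @return A [TimeSeriesMatrix-class].
#' @export
generateTimeSeries <- function(cfg, label, subjectId = "subject") {
  stopifnot(inherits(cfg, "synth_config"), label %in% c(0, 1))
  sigma <- if (label == 1) class_covariance(cfg, cfg$functionalEffectEdges)
           else base_covariance(cfg)
  ch <- chol(sigma)
  m <- cfg$nTimepoints
  z <- matrix(stats::rnorm(m * cfg$nRois), m) %*% ch
  a <- cfg$temporalArCoeff
  if (a > 0) {
    s <- sqrt(1 - a^2)
    for (t in 2:m) z[t, ] <- a * z[t - 1L, ] + s * z[t, ]
  }
  TimeSeriesMatrix(z, subjectId = subjectId)
}

#' @rdname generateTimeSeries
#' @param subjectId identifier for the generated subject.
#' @export
generateVolume <- function(cfg, label, subjectId = "subject",
                           severity = 1) {
  stopifnot(inherits(cfg, "synth_config"), label %in% c(0, 1))
  d <- cfg$volumeShape
  ax <- lapply(1:3, function(i) (seq_len(d[i]) - (d[i] + 1) / 2) / (0.45 * d[i]))
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  v <- exp(-1.5 * r2)
  if (label == 1) {
    for (b in cfg$structuralEffectBlobs) {
      i1 <- outer(outer((seq_len(d[1]) - b$center[1])^2,
                        (seq_len(d[2]) - b$center[2])^2, `+`),
                  (seq_len(d[3]) - b$center[3])^2, `+`) <= b$radius^2
      v[i1] <- v[i1] + severity * b$delta
    }
  }
  if (cfg$noiseSd > 0)
    v <- v + array(stats::rnorm(length(v), sd = cfg$noiseSd), dim = d)
  VolumeImage(v, subjectId = subjectId)
}

# Route the class effects across modalities: the first
# round(split * nEdges) effect edges stay functional, the first
# round((1 - split) * nBlobs) blobs stay structural.
route_effects <- function(cfg) {
  nE <- length(cfg$functionalEffectEdges)
  nB <- length(cfg$structuralEffectBlobs)
  s <- cfg$modalitySignalSplit
  list(edges = cfg$functionalEffectEdges[seq_len(round(s * nE))],
       blobs = cfg$structuralEffectBlobs[seq_len(round((1 - s) * nB))])
}

#' Generate a synthetic two-class multimodal cohort
#'
#' Generates `nClass0 + nClass1` subjects with paired time series and
#' volumes. The configured class effects are first routed across the two
#' modalities according to `modalitySignalSplit` (see
#' [syntheticCohortConfig()]); each subject's `groundTruth` records the
#' effects actually applied. The whole cohort is a pure function of the
#' configuration (including its seed).
#'
#' @param cfg a [syntheticCohortConfig()].
#' @return list of subjects: `subjectId`, `label`, `ts`, `volume`,
#'   `groundTruth`.
#' @export
generateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  routed <- route_effects(cfg)
  cfgF <- cfg
  cfgF$functionalEffectEdges <- routed$edges
  cfgS <- cfg
  cfgS$structuralEffectBlobs <- routed$blobs
  set.seed(cfg$seed)
  labels <- rep(c(0L, 1L), c(cfg$nClass0, cfg$nClass1))
  sevRange <- cfg$structuralSeverityRange
  lapply(seq_along(labels), function(i) {
    id <- sprintf("sub%03d", i)
    carrier <- labels[i] == 1L &&
      stats::runif(1) < cfg$structuralPenetrance
    severity <- if (carrier) stats::runif(1, sevRange[1], sevRange[2]) else 0
    gt <- list(functionalEdges = if (labels[i] == 1) routed$edges else list(),
               structuralBlobs = if (carrier) routed$blobs else list(),
               structuralCarrier = carrier,
               structuralSeverity = severity)
    list(subjectId = id, label = labels[i],
         ts = generateTimeSeries(cfgF, labels[i], subjectId = id),
         volume = generateVolume(cfgS, if (carrier) 1L else 0L,
                                 subjectId = id, severity = severity),
         groundTruth = gt)
  })
}

#' Write a cohort to disk in the pipeline's standard layout
#'
#' One time-series TSV and one gzipped NIfTI volume per subject, plus a
#' manifest TSV (`subjectId`, `label`, `timeseries`, `volume`) with paths
#' relative to the manifest location, so synthetic and real cohorts are
#' consumed identically.
#'
#' @param cohort output of [generateCohort()] (or the same structure).
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(subj) {
    tsFile <- paste0(subj$subjectId, "_ts.tsv")
    volFile <- paste0(subj$subjectId, "_gm.nii.gz")
    writeTimeSeries(subj$ts, file.path(dir, tsFile))
    writeVolume(subj$volume, file.path(dir, volFile))
    data.frame(subjectId = subj$subjectId, label = subj$label,
               timeseries = tsFile, volume = volFile,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
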