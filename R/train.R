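#' Training configuration
#'
#' Bundles every switch of the end-to-end optimization: the model variant,
#' the optimizer recipe (Adam with a flat learning rate, no schedule or
#' early stopping), the alignment weight lambda, and the two branch
#' configurations.
#'
#' Variants: `"multimodal"` is the full two-branch model with feature-level
#' fusion and the MMD penalty; `"no_mmd"` is the same model with
#' `lambda = 0`; `"structural"` and `"functional"` train a single branch
#' with a 64 -> 64 -> 2 classification head; `"late_fusion"` trains the
#' two single-branch classifiers independently and fuses their softmax
#' outputs with weight `lfWeight` on the functional branch.
#'
#' @param variant one of `"multimodal"`, `"structural"`, `"functional"`,
#'   `"no_mmd"`, `"late_fusion"`.
#' @param epochs training epochs (default 100).
#' @param batchSize mini-batch size (default 16). The last incomplete
#'   batch is kept, unless it contains a single subject, in which case it
#'   is merged with the previous batch (batch normalization needs at
#'   least 2 samples in training mode).
#' @param learningRate Adam learning rate (default 1e-4).
#' @param weightDecay L2 coefficient added to the gradient of every
#'   weight matrix and convolution kernel (default 0.0015); biases and
#'   batch-norm parameters are not decayed.
#' @param lambda weight of the MMD alignment term (default 0.01; forced
#'   to 0 for single-modality and `no_mmd` variants).
#' @param mmdKernel `"linear"` (default) or `"rbf"`.
#' @param lfWeight functional-branch weight for `late_fusion`, in
#'   \[0, 1\] (default 0.5).
#' @param seed integer seed controlling parameter initialization, batch
#'   shuffling and dropout masks.
#' @param gcn a [gcnBranchConfig()].
#' @param cnn a [cnnBranchConfig()].
#' @return A list of class `train_config`.
#' @export
trainConfig <- function(variant = c("multimodal", "structural", "functional",
                                    "no_mmd", "late_fusion"),
                        epochs = 100L, batchSize = 16L,
                        learningRate = 1e-4, weightDecay = 0.0015,
                        lambda = 0.01, mmdKernel = c("linear", "rbf"),
                        lfWeight = 0.5, seed = 1L,
                        gcn = gcnBranchConfig(), cnn = cnnBranchConfig()) {
  variant <- match.arg(variant)
  mmdKernel <- match.arg(mmdKernel)
  epochs <- as.integer(epochs)
  if (epochs < 0L) stop("epochs must be nonnegative")
  batchSize <- as.integer(batchSize)
  if (batchSize < 2L) stop("batchSize must be at least 2")
  if (learningRate <= 0) stop("learningRate must be positive")
  if (weightDecay < 0) stop("weightDecay must be nonnegative")
  if (lambda < 0 || !is.finite(lambda)) stop("lambda must be finite and >= 0")
  if (lfWeight < 0 || lfWeight > 1) stop("lfWeight must lie in [0, 1]")
  if (variant %in% c("structural", "functional", "no_mmd")) lambda <- 0
  structure(list(variant = variant, epochs = epochs, batchSize = batchSize,
                 learningRate = learningRate, weightDecay = weightDecay,
                 lambda = lambda, mmdKernel = mmdKernel,
                 lfWeight = lfWeight, seed = as.integer(seed),
                 gcn = gcn, cnn = cnn),
            class = "train_config")
}

#' Prepare a cohort for training
#'
#' Performs the per-subject deterministic preprocessing once: Pearson
#' connectivity, graph construction, symmetric normalization, and
#' per-subject volume standardization. The result is the input format
#' [trainModel()] and [predict.nf_model()] consume.
#'
#' @param cohort list of subjects; each subject is a list with elements
#'   `subjectId`, `label` (0/1 or `NA`), and `ts`
#'   ([TimeSeriesMatrix-class]) and/or `volume` ([VolumeImage-class]).
#' @param strategy graph construction: `"knn"` (default), `"threshold"`,
#'   or `"full"`.
#' @param k neighbours for `"knn"` (default 10).
#' @param q threshold for `"threshold"` (default 0.2).
#' @param weight `"absolute"` (default) or `"signed"` edge strength.
#' @param zscore standardize each volume to mean 0, sd 1 (default TRUE).
#' @return A list of class `nf_cohort`: per subject `subjectId`, `label`,
#'   `graph` (list with normalized adjacency `A` and node features `X`)
#'   and/or `vol` (standardized 3D array).
#' @export
prepareCohort <- function(cohort, strategy = c("knn", "threshold", "full"),
                          k = 10L, q = 0.2,
                          weight = c("absolute", "signed"), zscore = TRUE) {
  strategy <- match.arg(strategy)
  weight <- match.arg(weight)
  prep <- lapply(cohort, function(subj) {
    out <- list(subjectId = subj$subjectId,
                label = if (is.null(subj$label)) NA_integer_ else as.integer(subj$label))
    if (!is.null(subj$ts)) {
      B <- pearsonFCN(subj$ts)
      G <- switch(strategy,
                  knn = buildKnnGraph(B, k = k, weight = weight),
                  threshold = buildThresholdGraph(B, q = q, weight = weight),
                  full = buildFullGraph(B))
      out$graph <- list(A = normalizeAdjacency(G)@values, X = G@nodeFeatures)
    }
    if (!is.null(subj$volume)) {
      v <- if (is(subj$volume, "VolumeImage")) subj$volume@values else subj$volume
      if (isTRUE(zscore)) {
        s <- stats::sd(v)
        v <- if (s > 0) (v - mean(v)) / s else v - mean(v)
      }
      out$vol <- v
    }
    out
  })
  attr(prep, "prep") <- list(strategy = strategy, k = k, q = q,
                             weight = weight, zscore = zscore)
  class(prep) <- "nf_cohort"
  prep
}

# ---- parameter registry / Adam ----------------------------------------

get_path <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}

set_path <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path[[1L]]]] <- value
    return(x)
  }
  x[[path[[1L]]]] <- set_path(x[[path[[1L]]]], path[-1L], value)
  x
}

# One spec per trainable tensor: spath indexes the model state, gpath the
# gradient tree, decay says whether weight decay applies.
param_specs <- function(state) {
  specs <- list()
  add <- function(spath, gpath, decay) {
    specs[[length(specs) + 1L]] <<- list(spath = spath, gpath = gpath,
                                         decay = decay)
  }
  if (!is.null(state$gcn)) {
    for (l in seq_along(state$gcn$W))
      add(list("gcn", "W", l), list("gcn", "W", l), TRUE)
    add(list("gcn", "headW"), list("gcn", "headW"), TRUE)
    add(list("gcn", "headB"), list("gcn", "headB"), FALSE)
  }
  if (!is.null(state$cnn)) {
    for (i in seq_along(state$cnn$blocks)) {
      add(list("cnn", "blocks", i, "W"), list("cnn", "blocks", i, "W"), TRUE)
      add(list("cnn", "blocks", i, "b"), list("cnn", "blocks", i, "b"), FALSE)
      add(list("cnn", "blocks", i, "bn", "gamma"),
          list("cnn", "blocks", i, "gamma"), FALSE)
      add(list("cnn", "blocks", i, "bn", "beta"),
          list("cnn", "blocks", i, "beta"), FALSE)
    }
    add(list("cnn", "fc1W"), list("cnn", "fc1W"), TRUE)
    add(list("cnn", "fc1b"), list("cnn", "fc1b"), FALSE)
    add(list("cnn", "fc2W"), list("cnn", "fc2W"), TRUE)
    add(list("cnn", "fc2b"), list("cnn", "fc2b"), FALSE)
  }
  if (!is.null(state$fuse)) {
    add(list("fuse", "W1"), list("fuse", "W1"), TRUE)
    add(list("fuse", "b1"), list("fuse", "b1"), FALSE)
    add(list("fuse", "W2"), list("fuse", "W2"), TRUE)
    add(list("fuse", "b2"), list("fuse", "b2"), FALSE)
  }
  specs
}

adam_init <- function(state, specs) {
  list(m = lapply(specs, function(s) {
         p <- get_path(state, s$spath); array(0, dim = dim(p) %||% length(p))
       }),
       v = lapply(specs, function(s) {
         p <- get_path(state, s$spath); array(0, dim = dim(p) %||% length(p))
       }),
       t = 0L)
}

adam_step <- function(state, grads, opt, specs, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    p <- get_path(state, s$spath)
    g <- get_path(grads, s$gpath)
    if (s$decay && wd > 0) g <- g + wd * p
    opt$m[[i]] <- beta1 * opt$m[[i]] + (1 - beta1) * g
    opt$v[[i]] <- beta2 * opt$v[[i]] + (1 - beta2) * g^2
    upd <- lr * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + eps)
    state <- set_path(state, s$spath, p - upd)
  }
  list(state = state, opt = opt)
}

# ---- model assembly ----------------------------------------------------

uses_functional <- function(variant) variant %in% c("multimodal", "no_mmd", "functional")
uses_structural <- function(variant) variant %in% c("multimodal", "no_mmd", "structural")

init_model_state <- function(cfg, nRois, volShape) {
  state <- list()
  if (uses_functional(cfg$variant))
    state$gcn <- init_gcn_branch(cfg$gcn, nRois)
  if (uses_structural(cfg$variant))
    state$cnn <- init_cnn_branch(cfg$cnn, volShape)
  width <- 0L
  if (uses_functional(cfg$variant)) width <- width + cfg$gcn$headWidth
  if (uses_structural(cfg$variant)) width <- width + cfg$cnn$fcWidths[2]
  state$fuse <- init_fusion_head(width)
  state
}

cohort_dims <- function(prepared, variant) {
  nRois <- NULL
  volShape <- NULL
  if (uses_functional(variant)) {
    if (is.null(prepared[[1]]$graph))
      stop("variant requires functional data, but the cohort has no time series")
    nRois <- nrow(prepared[[1]]$graph$X)
  }
  if (uses_structural(variant)) {
    if (is.null(prepared[[1]]$vol))
      stop("variant requires structural data, but the cohort has no volumes")
    volShape <- dim(prepared[[1]]$vol)
  }
  list(nRois = nRois, volShape = volShape)
}

assemble_volumes <- function(prepared, idx) {
  d <- dim(prepared[[idx[1]]]$vol)
  x <- array(0, dim = c(d, length(idx), 1L))
  for (s in seq_along(idx)) x[, , , s, 1L] <- prepared[[idx[s]]]$vol
  x
}

check_modalities <- function(prepared, variant) {
  for (subj in prepared) {
    if (uses_functional(variant) && is.null(subj$graph))
      stop(sprintf("subject '%s' lacks functional data required by variant '%s'",
                   subj$subjectId, variant))
    if (uses_structural(variant) && is.null(subj$vol))
      stop(sprintf("subject '%s' lacks structural data required by variant '%s'",
                   subj$subjectId, variant))
  }
}

# Forward pass on a subject index set; train mode draws dropout masks and
# uses batch statistics. Returns probabilities, losses, and caches.
model_forward <- function(state, cfg, prepared, idx, train) {
  out <- list()
  emb <- NULL
  if (!is.null(state$gcn)) {
    graphs <- lapply(prepared[idx], `[[`, "graph")
    out$gcnF <- gcn_forward_batch(graphs, state$gcn, train = train)
    emb <- out$gcnF$emb
  }
  if (!is.null(state$cnn)) {
    x <- assemble_volumes(prepared, idx)
    out$cnnF <- cnn_forward_batch(x, state$cnn, train = train)
    emb <- if (is.null(emb)) out$cnnF$emb else cbind(emb, out$cnnF$emb)
  }
  out$fusion <- fusion_forward_batch(emb, state$fuse)
  out$prob <- out$fusion$prob
  out
}

#' Train a multimodal classifier
#'
#' End-to-end seeded optimization of the configured variant under the
#' joint loss `L = L_C + lambda * L_M` with Adam. Identical seeds yield
#' identical parameters and history. The per-epoch history records the
#' mean classification loss, the mean alignment loss (recorded even when
#' `lambda = 0`, so ablations can be compared), the total loss, and the
#' training accuracy.
#'
#' @param cohort a prepared cohort from [prepareCohort()]; every subject
#'   must carry the modalities the variant needs and a 0/1 label.
#' @param cfg a [trainConfig()].
#' @return An object of class `nf_model`: list with `state`, `cfg`,
#'   `history` (data.frame), and for `late_fusion` the two sub-models.
#' @export
trainModel <- function(cohort, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(cohort) == 0L) stop("empty cohort")
  labels <- vapply(cohort, function(s) as.integer(s$label), integer(1))
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("every subject needs a 0/1 label for training")

  if (cfg$variant == "late_fusion") {
    subCfg <- function(variant) {
      out <- cfg
      out$variant <- variant
      out$lambda <- 0
      out
    }
    fm <- trainModel(cohort, subCfg("functional"))
    sm <- trainModel(cohort, subCfg("structural"))
    model <- structure(list(cfg = cfg, functional = fm, structural = sm,
                            history = data.frame()),
                       class = "nf_model")
    return(model)
  }

  check_modalities(cohort, cfg$variant)
  dims <- cohort_dims(cohort, cfg$variant)

  set.seed(cfg$seed)
  state <- init_model_state(cfg, dims$nRois, dims$volShape)
  specs <- param_specs(state)
  opt <- adam_init(state, specs)

  n <- length(cohort)
  useMMD <- !is.null(state$gcn) && !is.null(state$cnn)
  history <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batchSize)
    batches <- lapply(starts, function(s) perm[s:min(s + cfg$batchSize - 1L, n)])
    nb <- length(batches)
    if (nb > 1L && length(batches[[nb]]) < 2L) {
      batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
      batches[[nb]] <- NULL
    }
    epCE <- 0; epMMD <- 0; epN <- 0L; epCorrect <- 0L; nbUsed <- 0L
    for (idx in batches) {
      B <- length(idx)
      y <- labels[idx]
      fw <- model_forward(state, cfg, cohort, idx, train = TRUE)
      if (!is.null(fw$cnnF)) {
        for (i in seq_along(fw$cnnF$newBn)) {
          state$cnn$blocks[[i]]$bn$runMean <- fw$cnnF$newBn[[i]]$runMean
          state$cnn$blocks[[i]]$bn$runVar <- fw$cnnF$newBn[[i]]$runVar
        }
      }
      prob <- fw$prob
      lossCE <- crossEntropyLoss(prob[, 2], y)
      lossMMD <- 0
      mmdGrad <- NULL
      if (useMMD) {
        if (cfg$mmdKernel == "linear") {
          mmdGrad <- mmd_linear_grad(fw$gcnF$emb, fw$cnnF$emb)
        } else {
          mmdGrad <- mmd_rbf_grad(fw$gcnF$emb, fw$cnnF$emb)
        }
        lossMMD <- mmdGrad$value
      }
      onehot <- cbind(1 - y, y)
      dLogits <- (prob - onehot) / B
      fb <- fusion_backward_batch(dLogits, state$fuse, fw$fusion)
      grads <- list(fuse = fb$grad)
      dEmb <- fb$dEmb
      colOff <- 0L
      if (!is.null(state$gcn)) {
        wF <- ncol(fw$gcnF$emb)
        dG <- dEmb[, colOff + seq_len(wF), drop = FALSE]
        if (useMMD && cfg$lambda > 0) dG <- dG + cfg$lambda * mmdGrad$dF
        grads$gcn <- gcn_backward_batch(dG, state$gcn, fw$gcnF)
        colOff <- colOff + wF
      }
      if (!is.null(state$cnn)) {
        wS <- ncol(fw$cnnF$emb)
        dS <- dEmb[, colOff + seq_len(wS), drop = FALSE]
        if (useMMD && cfg$lambda > 0) dS <- dS + cfg$lambda * mmdGrad$dS
        grads$cnn <- cnn_backward_batch(dS, state$cnn, fw$cnnF)
      }
      step <- adam_step(state, grads, opt, specs,
                        lr = cfg$learningRate, wd = cfg$weightDecay)
      state <- step$state
      opt <- step$opt
      epCE <- epCE + lossCE * B
      epMMD <- epMMD + lossMMD
      nbUsed <- nbUsed + 1L
      epN <- epN + B
      epCorrect <- epCorrect + sum((prob[, 2] >= prob[, 1]) == (y == 1L))
    }
    history[[epoch]] <- data.frame(
      epoch = epoch,
      loss_ce = epCE / epN,
      loss_mmd = if (useMMD) epMMD / nbUsed else NA_real_,
      loss_total = epCE / epN +
        cfg$lambda * (if (useMMD) epMMD / nbUsed else 0),
      train_acc = epCorrect / epN,
      lambda = cfg$lambda)
  }

  if (!is.null(state$cnn) && cfg$epochs > 0)
    state$cnn <- cnn_recalibrate_bn(state$cnn, cohort, seq_len(n))

  structure(list(state = state, cfg = cfg,
                 history = if (cfg$epochs > 0)
                   do.call(rbind, history) else data.frame()),
            class = "nf_model")
}

# RBF-kernel MMD with median-heuristic bandwidth (treated as a constant
# for differentiation, the usual practice) and its gradient.
mmd_rbf_grad <- function(F_batch, S_batch, eps = 1e-12) {
  nf <- nrow(F_batch); ns <- nrow(S_batch)
  z <- rbind(F_batch, S_batch)
  d2 <- as.matrix(stats::dist(z))^2
  off <- d2[upper.tri(d2)]
  med <- stats::median(off[off > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  sig2 <- med / 2
  kmat <- exp(-d2 / (2 * sig2))
  iF <- seq_len(nf); iS <- nf + seq_len(ns)
  m2 <- mean(kmat[iF, iF]) + mean(kmat[iS, iS]) - 2 * mean(kmat[iF, iS])
  m2 <- max(m2, 0)
  val <- sqrt(m2)
  dF <- matrix(0, nf, ncol(F_batch))
  dS <- matrix(0, ns, ncol(S_batch))
  if (val > eps) {
    # d m2 / d f_i, with dK(x,y)/dx = K(x,y) (y - x) / sig2
    for (i in seq_len(nf)) {
      diffFF <- sweep(F_batch, 2, F_batch[i, ])       # f_j - f_i
      diffFS <- sweep(S_batch, 2, F_batch[i, ])       # s_j - f_i
      dF[i, ] <- (2 / nf^2) * colSums(kmat[iF, iF][, i] * diffFF) / sig2 -
        (2 / (nf * ns)) * colSums(kmat[iF, iS][i, ] * diffFS) / sig2
    }
    for (j in seq_len(ns)) {
      diffSS <- sweep(S_batch, 2, S_batch[j, ])
      diffSF <- sweep(F_batch, 2, S_batch[j, ])
      dS[j, ] <- (2 / ns^2) * colSums(kmat[iS, iS][, j] * diffSS) / sig2 -
        (2 / (nf * ns)) * colSums(kmat[iF, iS][, j] * diffSF) / sig2
    }
    dF <- dF / (2 * val)
    dS <- dS / (2 * val)
  }
  list(value = val, dF = dF, dS = dS)
}

#' Predict with a trained model
#'
#' Deterministic evaluation-mode forward pass: dropout off, batch
#' normalization with running moments. Works on any prepared cohort
#' carrying the modalities the model's variant uses; labels, when
#' present, are copied into the output for convenience.
#'
#' @param object an `nf_model` from [trainModel()].
#' @param cohort a prepared cohort from [prepareCohort()].
#' @param batchSize evaluation batch size (default 32; results do not
#'   depend on it).
#' @param ... unused.
#' @return data.frame with `subjectId`, `truth` (may be `NA`), `p0`,
#'   `p1`, `predicted`.
#' @export
predict.nf_model <- function(object, cohort, batchSize = 32L, ...) {
  cfg <- object$cfg
  if (cfg$variant == "late_fusion") {
    pf <- predict(object$functional, cohort, batchSize = batchSize)
    ps <- predict(object$structural, cohort, batchSize = batchSize)
    w <- cfg$lfWeight
    p1 <- w * pf$p1 + (1 - w) * ps$p1
    p0 <- w * pf$p0 + (1 - w) * ps$p0
    return(data.frame(subjectId = pf$subjectId, truth = pf$truth,
                      p0 = p0, p1 = p1,
                      predicted = as.integer(p1 >= p0),
                      stringsAsFactors = FALSE))
  }
  check_modalities(cohort, cfg$variant)
  n <- length(cohort)
  starts <- seq(1L, n, by = as.integer(batchSize))
  rows <- lapply(starts, function(s) {
    idx <- s:min(s + batchSize - 1L, n)
    fw <- model_forward(object$state, cfg, cohort, idx, train = FALSE)
    data.frame(
      subjectId = vapply(cohort[idx], `[[`, character(1), "subjectId"),
      truth = vapply(cohort[idx], function(x) as.integer(x$label), integer(1)),
      p0 = fw$prob[, 1], p1 = fw$prob[, 2],
      predicted = as.integer(fw$prob[, 2] >= fw$prob[, 1]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Branch embeddings of a trained model
#'
#' Evaluation-mode embeddings of each modality branch, mainly for
#' diagnostics (alignment inspection, projection plots).
#'
#' @param model an `nf_model`.
#' @param cohort a prepared cohort.
#' @return list with elements `functional` and/or `structural`, matrices
#'   with one row per subject.
#' @export
branchEmbeddings <- function(model, cohort) {
  stopifnot(inherits(model, "nf_model"))
  if (model$cfg$variant == "late_fusion")
    return(list(
      functional = branchEmbeddings(model$functional, cohort)$functional,
      structural = branchEmbeddings(model$structural, cohort)$structural))
  check_modalities(cohort, model$cfg$variant)
  idx <- seq_along(cohort)
  out <- list()
  if (!is.null(model$state$gcn)) {
    graphs <- lapply(cohort[idx], `[[`, "graph")
    out$functional <- gcn_forward_batch(graphs, model$state$gcn)$emb
  }
  if (!is.null(model$state$cnn)) {
    x <- assemble_volumes(cohort, idx)
    out$structural <- cnn_forward_batch(x, model$state$cnn)$emb
  }
  out
}

#' @export
print.nf_model <- function(x, ...) {
  cat(sprintf("neurofuse model: variant '%s', %d epochs, seed %d\n",
              x$cfg$variant, x$cfg$epochs, x$cfg$seed))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final: loss %.4f (CE %.4f, MMD %s), train acc %.3f\n",
                last$loss_total, last$loss_ce,
                if (is.na(last$loss_mmd)) "-" else sprintf("%.4f", last$loss_mmd),
                last$train_acc))
  }
  invisible(x)
}
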