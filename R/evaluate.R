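#' Eight classification metrics
#'
#' Computes ACC, SEN, SPE, BAC, PPV, NPV, F1 and AUC from a prediction
#' table, with class 1 (the patient class) as positive: SEN = TP/(TP+FN),
#' SPE = TN/(TN+FP), BAC = (SEN+SPE)/2, PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), F1 the harmonic mean of PPV and SEN, and AUC the
#' rank-based (Mann-Whitney) statistic on the class-1 probabilities,
#' with tied scores contributing 1/2 per pair. Metrics whose denominator
#' is empty are returned as `NA` (never silently zero); if the truth
#' contains a single class this affects SEN or SPE (and AUC), and a
#' warning is raised.
#'
#' @param preds data.frame with columns `truth` (0/1), `predicted` (0/1)
#'   and `p1` (class-1 probability), as returned by
#'   [predict.nf_model()].
#' @return Named numeric vector with the eight metrics.
#' @export
computeMetrics <- function(preds) {
  truth <- as.integer(preds$truth)
  predicted <- as.integer(preds$predicted)
  p1 <- as.numeric(preds$p1)
  if (length(truth) == 0L) stop("empty prediction set")
  if (anyNA(truth) || !all(truth %in% c(0L, 1L)))
    stop("truth labels must be 0/1")
  tp <- sum(truth == 1L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  tn <- sum(truth == 0L & predicted == 0L)
  fp <- sum(truth == 0L & predicted == 1L)
  div <- function(num, den) if (den == 0L) NA_real_ else num / den
  sen <- div(tp, tp + fn)
  spe <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp)
  npv <- div(tn, tn + fn)
  f1 <- if (is.na(ppv) || is.na(sen) || (ppv + sen) == 0) NA_real_ else
    2 * ppv * sen / (ppv + sen)
  auc <- if (tp + fn == 0L || tn + fp == 0L) NA_real_ else auc_rank(p1, truth)
  if (tp + fn == 0L || tn + fp == 0L)
    warning("single-class truth: SEN or SPE (and AUC) are undefined")
  c(ACC = (tp + tn) / length(truth), SEN = sen, SPE = spe,
    BAC = (sen + spe) / 2, PPV = ppv, NPV = npv, F1 = f1, AUC = auc)
}

# Mann-Whitney AUC via midranks; ties count 1/2 per pair.
auc_rank <- function(scores, truth) {
  r <- rank(scores, ties.method = "average")
  nPos <- sum(truth == 1L)
  nNeg <- sum(truth == 0L)
  (sum(r[truth == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Repeated random holdout evaluation
#'
#' The evaluation protocol: `nRepeats` independent random partitions into
#' training (1 - testFraction) and test (testFraction) sets, a model
#' trained on each training set, the eight metrics recorded on each test
#' set, and their mean and standard deviation (n - 1 denominator)
#' reported. Splits are stratified by class by default, so small cohorts
#' cannot produce single-class test sets; repeat r uses seed
#' `baseSeed + r - 1` for both the split and the training run. All
#' per-subject test probabilities are retained for paired significance
#' testing between methods.
#'
#' @param cohort a prepared cohort (see [prepareCohort()]) with 0/1
#'   labels.
#' @param trainFun `function(trainCohort, seed)` returning an object
#'   accepted by `predictFun`.
#' @param nRepeats number of random partitions (default 10).
#' @param testFraction fraction held out for testing (default 0.2).
#' @param baseSeed integer seed of the first repeat.
#' @param stratify stratify the split by class (default TRUE).
#' @param predictFun `function(model, testCohort)` returning the
#'   prediction data.frame (default [predict.nf_model()]'s interface,
#'   `predict`).
#' @return list of class `nf_eval` with `perRepeat` (metrics x repeats),
#'   `summary` (mean/sd rows), and `testProbs` (subjectId, repeat, truth,
#'   p1 for every test-set occurrence).
#' @export
repeatedHoldout <- function(cohort, trainFun, nRepeats = 10L,
                            testFraction = 0.2, baseSeed = 1L,
                            stratify = TRUE, predictFun = predict) {
  nRepeats <- as.integer(nRepeats)
  if (nRepeats < 1L) stop("nRepeats must be at least 1")
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1")
  labels <- vapply(cohort, function(s) as.integer(s$label), integer(1))
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("cohort labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("cohort too small to split with both classes on each side")
  n <- length(cohort)

  perRepeat <- vector("list", nRepeats)
  probs <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    seed <- as.integer(baseSeed + r - 1L)
    set.seed(seed)
    if (stratify) {
      testIdx <- unlist(lapply(c(0L, 1L), function(cl) {
        ids <- which(labels == cl)
        ids[sample.int(length(ids),
                       max(1L, round(length(ids) * testFraction)))]
      }))
    } else {
      testIdx <- sample.int(n, max(1L, round(n * testFraction)))
    }
    testIdx <- sort(testIdx)
    trainIdx <- setdiff(seq_len(n), testIdx)
    if (length(unique(labels[testIdx])) < 2L ||
        length(unique(labels[trainIdx])) < 2L)
      stop("cohort too small to split with both classes on each side")
    model <- trainFun(cohort[trainIdx], seed)
    preds <- predictFun(model, cohort[testIdx])
    perRepeat[[r]] <- c(repeat_ = r, computeMetrics(preds))
    probs[[r]] <- data.frame(subjectId = preds$subjectId, repeat_ = r,
                             truth = preds$truth, p1 = preds$p1,
                             stringsAsFactors = FALSE)
  }
  perRepeat <- as.data.frame(do.call(rbind, perRepeat))
  metricCols <- setdiff(names(perRepeat), "repeat_")
  summary <- rbind(
    data.frame(stat = "mean", t(colMeans(perRepeat[metricCols]))),
    data.frame(stat = "sd", t(apply(perRepeat[metricCols], 2, stats::sd))))
  structure(list(perRepeat = perRepeat, summary = summary,
                 testProbs = do.call(rbind, probs)),
            class = "nf_eval")
}

#' @export
print.nf_eval <- function(x, ...) {
  cat("Repeated-holdout evaluation:\n")
  m <- x$summary[x$summary$stat == "mean", -1]
  s <- x$summary[x$summary$stat == "sd", -1]
  for (nm in names(m))
    cat(sprintf("  %s: %.3f (%.3f)\n", nm, m[[nm]], s[[nm]]))
  invisible(x)
}

#' Paired t-test on predicted probabilities
#'
#' Two-sided paired-sample t-test on two aligned probability vectors
#' (same subjects and repeats, two methods):
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d` the pairwise differences,
#' `sd` the n-1 sample standard deviation, and the p-value from the t
#' distribution with n-1 degrees of freedom.
#'
#' @param probsA,probsB numeric vectors of equal length n >= 2.
#' @return list with `t`, `p`, `df`, `nPairs`, `meanDiff`.
#' @export
pairedTTest <- function(probsA, probsB) {
  probsA <- as.numeric(probsA)
  probsB <- as.numeric(probsB)
  if (length(probsA) != length(probsB))
    stop("the two probability vectors must be aligned (equal length)")
  n <- length(probsA)
  if (n < 2L) stop("need at least 2 pairs")
  d <- probsA - probsB
  sdiff <- stats::sd(d)
  if (sdiff == 0)
    stop("zero variance of the paired differences: t statistic undefined")
  tstat <- mean(d) / (sdiff / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1),
       df = n - 1L, nPairs = n, meanDiff = mean(d))
}
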