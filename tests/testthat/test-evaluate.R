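preds_from_confusion <- function(tp, fn, tn, fp) {
  # class-1 probabilities consistent with the predicted labels
  data.frame(
    truth = c(rep(1, tp + fn), rep(0, tn + fp)),
    predicted = c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp)),
    p1 = c(seq(0.6, 0.9, length.out = tp), seq(0.1, 0.4, length.out = fn),
           seq(0.1, 0.4, length.out = tn), seq(0.6, 0.9, length.out = fp)))
}

test_that("computeMetrics reproduces the hand confusion-table oracle", {
  m <- computeMetrics(preds_from_confusion(3, 1, 2, 2))
  expect_equal(m[["SEN"]], 0.75)
  expect_equal(m[["SPE"]], 0.5)
  expect_equal(m[["ACC"]], 0.625)
  expect_equal(m[["BAC"]], 0.625)
  expect_equal(m[["PPV"]], 0.6)
  expect_equal(m[["NPV"]], 2 / 3, tolerance = 1e-12)
  expect_equal(m[["F1"]], 2 * 0.6 * 0.75 / (0.6 + 0.75), tolerance = 1e-12)
})

test_that("perfect predictions score 1 everywhere; flat scores give AUC 1/2", {
  perfect <- data.frame(truth = c(1, 1, 0, 0), predicted = c(1, 1, 0, 0),
                        p1 = c(0.9, 0.8, 0.1, 0.2))
  expect_equal(unname(computeMetrics(perfect)), rep(1, 8))

  flat <- data.frame(truth = c(1, 0, 1, 0), predicted = c(1, 1, 1, 1),
                     p1 = rep(0.5, 4))
  expect_equal(computeMetrics(flat)[["AUC"]], 0.5)
})

test_that("single-class truth yields undefined-metric markers, not zeros", {
  one <- data.frame(truth = c(1, 1), predicted = c(1, 0), p1 = c(0.9, 0.2))
  expect_warning(m <- computeMetrics(one), "single-class")
  expect_true(is.na(m[["SPE"]]))
  expect_true(is.na(m[["AUC"]]))
  expect_false(is.na(m[["SEN"]]))
})

test_that("AUC matches the exhaustive pairwise oracle and ignores monotone transforms", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
    p <- round(runif(n), 2)  # rounding forces ties
    preds <- data.frame(truth = truth, predicted = as.integer(p >= 0.5),
                        p1 = p)
    auc <- computeMetrics(preds)[["AUC"]]
    expect_equal(auc, oracle_auc_pairwise(p, truth), tolerance = 1e-12)
    # strictly increasing transform leaves AUC unchanged
    preds2 <- preds
    preds2$p1 <- plogis(5 * p - 2)
    expect_equal(computeMetrics(preds2)[["AUC"]], auc, tolerance = 1e-12)
  }
})

test_that("metric identities hold and prediction order is irrelevant", {
  set.seed(32)
  for (rep in 1:5) {
    n <- 40
    truth <- c(rep(1, 17), rep(0, 23))
    p <- runif(n)
    preds <- data.frame(truth = truth, predicted = as.integer(p >= 0.5),
                        p1 = p)
    m <- computeMetrics(preds)
    expect_equal(m[["BAC"]], (m[["SEN"]] + m[["SPE"]]) / 2,
                 tolerance = 1e-9)
    expect_equal(m[["ACC"]], (m[["SEN"]] * 17 + m[["SPE"]] * 23) / 40,
                 tolerance = 1e-12)
    shuffled <- preds[sample(n), ]
    expect_equal(computeMetrics(shuffled), m)
  }
})

test_that("repeatedHoldout splits, summarizes, and reproduces under a fixed seed", {
  # 10 subjects at test fraction 0.2: 8 train / 2 test
  cohort <- lapply(1:10, function(i)
    list(subjectId = sprintf("s%02d", i), label = as.integer(i > 5),
         x = i))
  trainFun <- function(train, seed) {
    list(mu1 = mean(sapply(Filter(function(s) s$label == 1, train),
                           `[[`, "x")))
  }
  predictFun <- function(model, test) {
    x <- sapply(test, `[[`, "x")
    p1 <- plogis(x - 5.5)
    data.frame(subjectId = sapply(test, `[[`, "subjectId"),
               truth = sapply(test, `[[`, "label"),
               p0 = 1 - p1, p1 = p1, predicted = as.integer(p1 >= 0.5))
  }
  sizes <- new.env()
  countingTrain <- function(train, seed) {
    sizes$n <- c(sizes$n, length(train))
    trainFun(train, seed)
  }
  ev <- repeatedHoldout(cohort, countingTrain, nRepeats = 3,
                        testFraction = 0.2, baseSeed = 5,
                        predictFun = predictFun)
  expect_equal(unique(sizes$n), 8L)
  expect_equal(nrow(ev$perRepeat), 3)
  expect_equal(nrow(ev$testProbs), 6)

  ev2 <- repeatedHoldout(cohort, trainFun, nRepeats = 3,
                         testFraction = 0.2, baseSeed = 5,
                         predictFun = predictFun)
  expect_identical(ev$perRepeat, ev2$perRepeat)
  expect_identical(ev$testProbs, ev2$testProbs)

  # summary equals the textbook mean / n-1 standard deviation
  accs <- ev$perRepeat$ACC
  expect_equal(ev$summary$ACC[ev$summary$stat == "mean"], mean(accs))
  expect_equal(ev$summary$ACC[ev$summary$stat == "sd"],
               sqrt(sum((accs - mean(accs))^2) / (length(accs) - 1)))

  expect_error(repeatedHoldout(cohort[1:3], trainFun, nRepeats = 1,
                               testFraction = 0.2,
                               predictFun = predictFun),
               "both classes")
})

test_that("pairedTTest reproduces the closed-form example and its symmetries", {
  a <- c(2, 4, 6)
  b <- c(1, 2, 3)  # differences 1, 2, 3
  r <- pairedTTest(a, b)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  # closed-form df=2 t cdf: F(t) = 1/2 + t / (2 sqrt(2) sqrt(1 + t^2/2))
  t0 <- 2 * sqrt(3)
  pRef <- 2 * (0.5 - t0 / (2 * sqrt(2) * sqrt(1 + t0^2 / 2)))
  expect_equal(r$p, pRef, tolerance = 1e-12)

  r2 <- pairedTTest(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  expect_error(pairedTTest(a, a), "zero variance")
  expect_error(pairedTTest(1:3, 1:4), "aligned")
})

test_that("pairedTTest agrees with the reference implementation on random data", {
  set.seed(35)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    a <- runif(n); b <- runif(n)
    r <- pairedTTest(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  }
})
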