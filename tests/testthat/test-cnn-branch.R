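test_that("propagateShapes reproduces the default architecture chain and validates configs", {
  shapes <- propagateShapes(cnnBranchConfig(), c(121, 145, 121))
  expect_equal(shapes$layer,
               c("input", "C1", "M1", "C2", "M2", "C3", "M3", "C4", "M4",
                 "GAP"))
  expect_equal(shapes[shapes$layer == "M1", c("h", "w", "d")],
               data.frame(h = 60L, w = 72L, d = 60L), ignore_attr = TRUE)
  expect_equal(shapes[shapes$layer == "M4", c("h", "w", "d")],
               data.frame(h = 7L, w = 9L, d = 7L), ignore_attr = TRUE)
  expect_equal(shapes$channels,
               c(1L, 16L, 16L, 32L, 32L, 64L, 64L, 128L, 128L, 128L))

  # minimal input: a single block pools (2,2,2) -> (1,1,1)
  s2 <- propagateShapes(cnnBranchConfig(convChannels = 4), c(3, 3, 3))
  expect_equal(unlist(s2[s2$layer == "M1", c("h", "w", "d")]),
               c(h = 1L, w = 1L, d = 1L))

  # scaled-down input follows repeated floor division
  s3 <- propagateShapes(cnnBranchConfig(convChannels = c(16, 32, 64)),
                        c(24, 28, 24))
  expect_equal(s3[s3$layer == "M3", c("h", "w", "d")],
               data.frame(h = 24L %/% 8L, w = 28L %/% 8L, d = 24L %/% 8L),
               ignore_attr = TRUE)

  # collapsing chain is a config error
  expect_error(propagateShapes(cnnBranchConfig(), c(8, 8, 8)),
               "config error.*collapses")
})

test_that("propagateShapes agrees with actual forward shapes on random configs", {
  set.seed(60)
  for (rep in 1:4) {
    nb <- sample(1:3, 1)
    chans <- sample(2:4, nb, replace = TRUE)
    cfg <- cnnBranchConfig(convChannels = chans, dropout = 0)
    shape <- c(sample(7:12, 1), sample(7:12, 1), sample(7:12, 1))
    if (min(shape %/% 2^nb) < 1) next
    shapes <- propagateShapes(cfg, shape)
    set.seed(rep)
    state <- neurofuse:::init_cnn_branch(cfg, shape)
    x <- array(rnorm(prod(shape) * 2), c(shape, 2, 1))
    fw <- neurofuse:::cnn_forward_batch(x, state, train = TRUE)
    last <- shapes[shapes$layer == sprintf("M%d", nb), ]
    expect_identical(as.integer(fw$cache$gapDim),
                     c(last$h, last$w, last$d, 2L, last$channels))
  }
})

test_that("convBlockForward handles the null kernel and matches the scalar-loop oracle", {
  blk <- list(W = array(0, c(3, 3, 3, 1, 1)), b = 0, bn = FALSE,
              poolSize = 2L)
  out <- convBlockForward(array(1, c(4, 4, 4)), blk)
  expect_equal(out, array(0, c(2, 2, 2, 1)))

  set.seed(12)
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4, 1))
  w <- array(rnorm(27), c(3, 3, 3, 1, 1))
  blk2 <- list(W = w, b = 0.3, bn = FALSE, poolSize = 2L)
  got <- convBlockForward(x, blk2)
  ref <- oracle_maxpool3(pmax(oracle_conv3(x, w, 0.3), 0), 2)
  expect_rel_equal(got, ref)
})

test_that("conv3d forward matches the seven-loop oracle with multiple channels", {
  set.seed(13)
  x <- array(rnorm(5 * 4 * 3 * 2), c(5, 4, 3, 2))       # H,W,D,Cin
  w <- array(rnorm(27 * 2 * 3), c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  x5 <- array(x, c(5, 4, 3, 1, 2))
  got <- neurofuse:::conv3d_fw(x5, w, b)
  expect_rel_equal(array(got, c(5, 4, 3, 3)), oracle_conv3(x, w, b))
})

test_that("conv3d and maxpool backward passes match finite differences", {
  set.seed(42)
  x <- array(rnorm(4 * 5 * 4 * 2 * 2), c(4, 5, 4, 2, 2))
  w <- array(rnorm(27 * 2 * 2), c(3, 3, 3, 2, 2))
  b <- rnorm(2)
  gy <- array(rnorm(4 * 5 * 4 * 2 * 2), c(4, 5, 4, 2, 2))
  bw <- neurofuse:::conv3d_bw(x, w, gy)
  f <- function(xx, ww, bb) sum(neurofuse:::conv3d_fw(xx, ww, bb) * gy)
  eps <- 1e-6
  check <- function(arr, grad, wrap) {
    ii <- sample(length(arr), min(12, length(arr)))
    for (i in ii) {
      a1 <- arr; a1[i] <- a1[i] + eps
      a2 <- arr; a2[i] <- a2[i] - eps
      expect_equal(grad[i], (wrap(a1) - wrap(a2)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
  check(x, bw$gx, function(a) f(a, w, b))
  check(w, bw$gw, function(a) f(x, a, b))
  check(b, bw$gb, function(a) f(x, w, a))

  mp <- neurofuse:::maxpool3d_fw(x, 2L)
  gy2 <- array(rnorm(length(mp$y)), dim(mp$y))
  gx2 <- neurofuse:::maxpool3d_bw(gy2, mp$idx, dim(x))
  check(x, gx2, function(a) sum(neurofuse:::maxpool3d_fw(a, 2L)$y * gy2))
})

test_that("batch normalization standardizes per channel and the two implementations agree", {
  set.seed(14)
  x <- array(rnorm(6 * 5 * 4 * 4 * 3, mean = 2, sd = 3), c(6, 5, 4, 4, 3))
  bn <- neurofuse:::bn_state(3)
  fwd <- neurofuse:::bn_forward(x, bn, train = TRUE)
  m <- matrix(fwd$y, ncol = 3)
  expect_lt(max(abs(colMeans(m))), 1e-4)
  expect_lt(max(abs(apply(m, 2, function(v) mean(v^2)) - 1)), 1e-3)

  # C++ path equals the R reference
  st <- neurofuse:::bn3d_stats(x)
  expect_rel_equal(st$mean, colMeans(matrix(x, ncol = 3)))
  scale <- bn$gamma / sqrt(st$var + bn$eps)
  yC <- neurofuse:::bn3d_apply(x, scale, bn$beta - st$mean * scale)
  expect_rel_equal(yC, fwd$y)

  gy <- array(rnorm(length(x)), dim(x))
  bwR <- neurofuse:::bn_backward(gy, bn, fwd$cache)
  bwC <- neurofuse:::bn3d_bw(x, gy, st$mean, 1 / sqrt(st$var + bn$eps),
                             bn$gamma)
  expect_rel_equal(bwC$dx, bwR$dx)
  expect_rel_equal(bwC$dgamma, bwR$dgamma)
  expect_rel_equal(bwC$dbeta, bwR$dbeta)
})

test_that("globalAveragePool matches direct summation and respects channel structure", {
  x <- array(2.5, c(3, 3, 3, 1))
  expect_equal(globalAveragePool(x), 2.5)

  set.seed(15)
  x2 <- array(rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2))
  expect_rel_equal(globalAveragePool(x2), oracle_gap(x2))

  # GAP commutes with channel permutation
  x3 <- array(rnorm(3 * 4 * 2 * 5), c(3, 4, 2, 5))
  perm <- c(4, 1, 5, 2, 3)
  expect_equal(globalAveragePool(x3[, , , perm]),
               globalAveragePool(x3)[perm])

  # 128-channel map collapses to a 128-vector
  x4 <- array(0, c(7, 9, 7, 128))
  expect_length(globalAveragePool(x4), 128)
})

test_that("cnnHeadForward chains two affine + ReLU layers; dropout off in eval mode", {
  state <- list(fc1W = matrix(0, 3, 2), fc1b = numeric(2),
                fc2W = matrix(0, 2, 2), fc2b = numeric(2),
                config = list(dropout = 0.5))
  expect_equal(as.numeric(cnnHeadForward(rnorm(3), state)), c(0, 0))

  set.seed(16)
  state$fc1W <- matrix(rnorm(6), 3, 2)
  state$fc1b <- rnorm(2)
  state$fc2W <- matrix(rnorm(4), 2, 2)
  state$fc2b <- rnorm(2)
  x <- rnorm(3)
  h <- oracle_affine_relu(x, state$fc1W, state$fc1b)
  ref <- oracle_affine_relu(h, state$fc2W, state$fc2b)
  got <- cnnHeadForward(x, state)
  expect_s4_class(got, "BranchFeature")
  expect_identical(got@modality, "structural")
  expect_rel_equal(as.numeric(got), ref)
  expect_error(cnnHeadForward(rnorm(4), state), "does not match")

  # default configuration produces a 64-vector from the 128-channel GAP
  set.seed(17)
  big <- neurofuse:::init_cnn_branch(cnnBranchConfig(), c(121, 145, 121))
  expect_length(as.numeric(cnnHeadForward(rnorm(128), big)), 64)
})

test_that("the branch is deterministic in eval mode", {
  set.seed(18)
  cfg <- cnnBranchConfig(convChannels = c(2, 3), fcWidths = c(4, 3))
  state <- neurofuse:::init_cnn_branch(cfg, c(8, 10, 8))
  x <- array(rnorm(8 * 10 * 8 * 2), c(8, 10, 8, 2, 1))
  e1 <- neurofuse:::cnn_forward_batch(x, state, train = FALSE)$emb
  e2 <- neurofuse:::cnn_forward_batch(x, state, train = FALSE)$emb
  expect_identical(e1, e2)
})

test_that("the full structural branch backward matches finite differences", {
  set.seed(19)
  cfg <- cnnBranchConfig(convChannels = c(2, 2), fcWidths = c(4, 3),
                         dropout = 0)
  state <- neurofuse:::init_cnn_branch(cfg, c(6, 6, 6))
  x <- array(rnorm(6 * 6 * 6 * 3), c(6, 6, 6, 3, 1))
  fw <- neurofuse:::cnn_forward_batch(x, state, train = TRUE)
  dEmb <- matrix(rnorm(length(fw$emb)), nrow(fw$emb))
  gr <- neurofuse:::cnn_backward_batch(dEmb, state, fw)
  lossOf <- function(st)
    sum(neurofuse:::cnn_forward_batch(x, st, train = TRUE)$emb * dEmb)
  eps <- 1e-6
  paths <- list(list(spath = list("blocks", 1L, "W"),
                     gpath = list("blocks", 1L, "W")),
                list(spath = list("blocks", 2L, "bn", "gamma"),
                     gpath = list("blocks", 2L, "gamma")),
                list(spath = list("fc1W"), gpath = list("fc1W")),
                list(spath = list("fc2b"), gpath = list("fc2b")))
  for (p in paths) {
    par <- neurofuse:::get_path(state, p$spath)
    g <- neurofuse:::get_path(gr, p$gpath)
    ii <- sample(length(par), min(4, length(par)))
    for (i in ii) {
      s1 <- state; pp <- par; pp[i] <- pp[i] + eps
      s1 <- neurofuse:::set_path(s1, p$spath, pp)
      s2 <- state; pp <- par; pp[i] <- pp[i] - eps
      s2 <- neurofuse:::set_path(s2, p$spath, pp)
      expect_equal(g[i], (lossOf(s1) - lossOf(s2)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})
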