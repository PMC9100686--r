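test_that("gcnLayerForward propagates identity and matches the scalar-loop oracle", {
  H <- matrix(c(1, 2, 0.5, 3, 0.1, 4), 3, 2)
  expect_equal(gcnLayerForward(H, diag(3), diag(2)), H,
               ignore_attr = TRUE)
  expect_equal(gcnLayerForward(H, diag(3), matrix(0, 2, 2)),
               matrix(0, 3, 2), ignore_attr = TRUE)

  # 3-node path graph, fixed weights
  a <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  An <- normalizeAdjacency(a)
  W <- matrix(c(0.3, -0.8, 1.2, 0.4), 2, 2)
  H2 <- matrix(c(0.2, -1, 0.7, 1.5, 0.3, -0.4), 3, 2)
  expect_rel_equal(gcnLayerForward(H2, An, W),
                   oracle_matprod3(as.matrix(An), H2, W))

  expect_error(gcnLayerForward(H2, An, matrix(0, 3, 2)), "width")
})

test_that("gcnStackForward composes layers and honours configured widths", {
  B <- fixed_fcn(5, seed = 3)
  G <- buildKnnGraph(B, 2)
  An <- as.matrix(normalizeAdjacency(G))
  set.seed(10)
  state <- neurofuse:::init_gcn_branch(
    gcnBranchConfig(layerWidths = c(3, 2), headWidth = 4), nRois = 5)

  # one-layer state equals a single layer call
  one <- list(W = state$W[1])
  expect_equal(gcnStackForward(G, one),
               gcnLayerForward(nodeFeatures(G), An, state$W[[1]]))

  # two layers equal manual chaining through the oracle
  z1 <- oracle_matprod3(An, nodeFeatures(G), state$W[[1]])
  z2 <- oracle_matprod3(An, z1, state$W[[2]])
  expect_rel_equal(gcnStackForward(G, state), z2)

  # default configuration at full scale: 112 x 64
  set.seed(2)
  big <- neurofuse:::init_gcn_branch(gcnBranchConfig(), nRois = 112)
  Xbig <- diag(112)
  z <- gcnLayerForward(gcnLayerForward(Xbig, diag(112), big$W[[1]]),
                       diag(112), big$W[[2]])
  expect_identical(dim(z), c(112L, 64L))
})

test_that("graphReadout concatenates mean and max and ignores node order", {
  v <- c(1.5, -2, 0.25)
  Z <- matrix(rep(v, each = 4), 4, 3)
  expect_equal(graphReadout(Z), c(v, v))

  Z2 <- matrix(c(1, 4, 2, 0.5, 3, -1), 3, 2)
  expect_rel_equal(graphReadout(Z2), oracle_readout(Z2))
  expect_equal(graphReadout(Z2[c(3, 1, 2), ]), graphReadout(Z2))
  expect_error(graphReadout(Z2[0, , drop = FALSE]), "empty")
})

test_that("gcnHeadForward is the affine + ReLU map to the embedding", {
  state <- list(headW = matrix(0, 4, 3), headB = numeric(3))
  f0 <- gcnHeadForward(rep(1, 4), state, "s1")
  expect_s4_class(f0, "BranchFeature")
  expect_equal(as.numeric(f0), rep(0, 3))

  set.seed(6)
  state$headW <- matrix(rnorm(12), 4, 3)
  state$headB <- rnorm(3)
  x <- rnorm(4)
  expect_rel_equal(as.numeric(gcnHeadForward(x, state)),
                   oracle_affine_relu(x, state$headW, state$headB))
  expect_error(gcnHeadForward(rnorm(5), state), "does not match")

  # default widths: readout 128 -> head 64
  set.seed(8)
  big <- neurofuse:::init_gcn_branch(gcnBranchConfig(), nRois = 112)
  expect_length(as.numeric(gcnHeadForward(rnorm(128), big)), 64)
})

test_that("the whole branch is invariant to node permutation with matching first-layer rows", {
  set.seed(33)
  for (rep in 1:3) {
    B <- fixed_fcn(6, seed = 100 + rep)
    G <- buildKnnGraph(B, 2)
    state <- neurofuse:::init_gcn_branch(
      gcnBranchConfig(layerWidths = c(4, 3), headWidth = 5), nRois = 6)
    emb <- function(G, st) {
      fw <- neurofuse:::gcn_forward_batch(
        list(list(A = as.matrix(normalizeAdjacency(G)),
                  X = nodeFeatures(G))), st)
      fw$emb[1, ]
    }
    e1 <- emb(G, state)

    perm <- sample(6)
    b <- as.matrix(B)[perm, perm]
    Gp <- methods::new("ConnectivityGraph",
                       adjacency = adjacency(G)[perm, perm],
                       nodeFeatures = b, strategy = "knn",
                       strategyParam = 2)
    statePerm <- state
    statePerm$W[[1]] <- state$W[[1]][perm, ]
    e2 <- emb(Gp, statePerm)
    expect_equal(e2, e1, tolerance = 1e-12)
  }
})

test_that("stacked tied-weight layers smooth node representations on a connected graph", {
  # motivation for keeping the stack shallow: deeper stacks contract the
  # spread between node representations
  a <- matrix(0, 6, 6)
  for (i in 1:5) { a[i, i + 1] <- 1; a[i + 1, i] <- 1 }
  An <- as.matrix(normalizeAdjacency(a))
  set.seed(4)
  H <- matrix(abs(rnorm(6 * 3)), 6, 3)
  W <- diag(3)
  spread <- function(h) mean(dist(h)^2)
  spreads <- numeric(5)
  for (l in 1:5) {
    H <- gcnLayerForward(H, An, W)
    spreads[l] <- spread(H)
  }
  expect_true(all(diff(spreads) <= 1e-12))
})

test_that("branch activations stay finite and nonnegative", {
  B <- fixed_fcn(5, seed = 55)
  G <- buildFullGraph(B)
  set.seed(5)
  state <- neurofuse:::init_gcn_branch(gcnBranchConfig(layerWidths = c(4, 4),
                                                       headWidth = 6), 5)
  z <- gcnStackForward(G, state)
  expect_true(all(is.finite(z)) && all(z >= 0))
})

test_that("gcn backward pass matches finite differences", {
  set.seed(71)
  B <- fixed_fcn(5, seed = 71)
  G <- buildKnnGraph(B, 2)
  graphs <- list(list(A = as.matrix(normalizeAdjacency(G)),
                      X = nodeFeatures(G)))
  state <- neurofuse:::init_gcn_branch(
    gcnBranchConfig(layerWidths = c(3, 3), headWidth = 4), 5)
  fw <- neurofuse:::gcn_forward_batch(graphs, state)
  dEmb <- matrix(rnorm(length(fw$emb)), nrow(fw$emb))
  gr <- neurofuse:::gcn_backward_batch(dEmb, state, fw)
  lossOf <- function(st) sum(neurofuse:::gcn_forward_batch(graphs, st)$emb * dEmb)
  eps <- 1e-6
  for (path in list(list("W", 1L), list("headW"), list("headB"))) {
    p <- neurofuse:::get_path(state, path)
    g <- neurofuse:::get_path(gr, path)
    ii <- sample(length(p), min(5, length(p)))
    for (i in ii) {
      s1 <- state; pp <- p; pp[i] <- pp[i] + eps
      s1 <- neurofuse:::set_path(s1, path, pp)
      s2 <- state; pp <- p; pp[i] <- pp[i] - eps
      s2 <- neurofuse:::set_path(s2, path, pp)
      expect_equal(g[i], (lossOf(s1) - lossOf(s2)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})
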