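# Independent brute-force oracles, written as plain scalar loops over the
# textbook formulas. They deliberately share no code with the package
# implementations they check.

oracle_pearson <- function(y) {
  n <- ncol(y)
  m <- nrow(y)
  b <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      yi <- y[, i] - sum(y[, i]) / m
      yj <- y[, j] - sum(y[, j]) / m
      num <- 0; di <- 0; dj <- 0
      for (t in seq_len(m)) {
        num <- num + yi[t] * yj[t]
        di <- di + yi[t]^2
        dj <- dj + yj[t]^2
      }
      b[i, j] <- num / (sqrt(di) * sqrt(dj))
    }
  }
  b
}

oracle_knn_adjacency <- function(b, k, absolute = TRUE) {
  n <- nrow(b)
  s <- if (absolute) abs(b) else b
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    # exhaustive sort with index tie-break
    ord <- others[order(-s[i, others], others)]
    for (j in ord[seq_len(k)]) a[i, j] <- 1
  }
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (a[i, j] == 1 || a[j, i] == 1) { a[i, j] <- 1; a[j, i] <- 1 }
  a
}

oracle_normalize <- function(a) {
  n <- nrow(a)
  ai <- a + diag(n)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sum(ai[i, ])
  out <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      out[i, j] <- ai[i, j] / sqrt(d[i] * d[j])
  out
}

oracle_matprod3 <- function(a, h, w) {
  # sigma(A H W) with scalar triple loops
  n <- nrow(a); dIn <- ncol(h); dOut <- ncol(w)
  ah <- matrix(0, n, dIn)
  for (i in seq_len(n))
    for (j in seq_len(dIn))
      for (t in seq_len(n)) ah[i, j] <- ah[i, j] + a[i, t] * h[t, j]
  out <- matrix(0, n, dOut)
  for (i in seq_len(n))
    for (j in seq_len(dOut))
      for (t in seq_len(dIn)) out[i, j] <- out[i, j] + ah[i, t] * w[t, j]
  pmax(out, 0)
}

oracle_readout <- function(z) {
  n <- nrow(z); d <- ncol(z)
  mn <- numeric(d); mx <- numeric(d)
  for (j in seq_len(d)) {
    s <- 0; m <- -Inf
    for (i in seq_len(n)) {
      s <- s + z[i, j]
      if (z[i, j] > m) m <- z[i, j]
    }
    mn[j] <- s / n
    mx[j] <- m
  }
  c(mn, mx)
}

oracle_affine_relu <- function(x, w, b) {
  out <- numeric(ncol(w))
  for (j in seq_len(ncol(w))) {
    s <- b[j]
    for (i in seq_along(x)) s <- s + x[i] * w[i, j]
    out[j] <- max(s, 0)
  }
  out
}

# Same-padding stride-1 3D convolution of a single channel/sample pair,
# seven nested loops.
oracle_conv3 <- function(x, w, bias) {
  dd <- dim(x)       # H, W, D, Cin
  k <- dim(w)[1]
  p <- (k - 1) / 2
  cout <- dim(w)[5]
  out <- array(0, c(dd[1:3], cout))
  for (co in seq_len(cout))
    for (z in seq_len(dd[3]))
      for (y in seq_len(dd[2]))
        for (xx in seq_len(dd[1])) {
          s <- bias[co]
          for (ci in seq_len(dd[4]))
            for (kz in seq_len(k))
              for (ky in seq_len(k))
                for (kx in seq_len(k)) {
                  ix <- xx + kx - 1 - p
                  iy <- y + ky - 1 - p
                  iz <- z + kz - 1 - p
                  if (ix >= 1 && ix <= dd[1] && iy >= 1 && iy <= dd[2] &&
                      iz >= 1 && iz <= dd[3])
                    s <- s + x[ix, iy, iz, ci] * w[kx, ky, kz, ci, co]
                }
          out[xx, y, z, co] <- s
        }
  out
}

oracle_maxpool3 <- function(x, pool) {
  dd <- dim(x)       # H, W, D, C
  od <- dd[1:3] %/% pool
  out <- array(-Inf, c(od, dd[4]))
  for (c in seq_len(dd[4]))
    for (z in seq_len(od[3]))
      for (y in seq_len(od[2]))
        for (xx in seq_len(od[1]))
          for (kz in seq_len(pool))
            for (ky in seq_len(pool))
              for (kx in seq_len(pool)) {
                v <- x[(xx - 1) * pool + kx, (y - 1) * pool + ky,
                       (z - 1) * pool + kz, c]
                if (v > out[xx, y, z, c]) out[xx, y, z, c] <- v
              }
  out
}

oracle_gap <- function(x) {
  dd <- dim(x)
  out <- numeric(dd[4])
  for (c in seq_len(dd[4])) {
    s <- 0
    for (z in seq_len(dd[3]))
      for (y in seq_len(dd[2]))
        for (xx in seq_len(dd[1])) s <- s + x[xx, y, z, c]
    out[c] <- s / (dd[1] * dd[2] * dd[3])
  }
  out
}

oracle_mmd_linear <- function(fb, sb) {
  d <- ncol(fb)
  mf <- numeric(d); ms <- numeric(d)
  for (j in seq_len(d)) {
    for (i in seq_len(nrow(fb))) mf[j] <- mf[j] + fb[i, j]
    for (i in seq_len(nrow(sb))) ms[j] <- ms[j] + sb[i, j]
  }
  mf <- mf / nrow(fb)
  ms <- ms / nrow(sb)
  s <- 0
  for (j in seq_len(d)) s <- s + (mf[j] - ms[j])^2
  sqrt(s)
}

oracle_auc_pairwise <- function(p, truth) {
  pos <- which(truth == 1)
  neg <- which(truth == 0)
  s <- 0
  for (i in pos)
    for (j in neg)
      s <- s + (if (p[i] > p[j]) 1 else if (p[i] == p[j]) 0.5 else 0)
  s / (length(pos) * length(neg))
}

# ---- shared fixtures ---------------------------------------------------

fixed_fcn <- function(n = 4, seed = 5) {
  set.seed(seed)
  y <- matrix(rnorm(12 * n), 12, n)
  pearsonFCN(TimeSeriesMatrix(y, "fix"))
}

# tiny multimodal cohort + matching branch configs for fast train tests
tiny_cohort <- function(n0 = 6, n1 = 6, seed = 7) {
  cfg <- syntheticCohortConfig(
    nClass0 = n0, nClass1 = n1, nRois = 8, nTimepoints = 40,
    volumeShape = c(8, 10, 8),
    functionalEffectEdges = list(c(1, 6), c(2, 7)),
    structuralEffectBlobs = list(
      list(center = c(4, 5, 4), radius = 2, delta = -0.5)),
    structuralSeverityRange = c(1, 1), seed = seed)
  prepareCohort(generateCohort(cfg), k = 3)
}

tiny_train_config <- function(variant = "multimodal", epochs = 2,
                              seed = 3, ...) {
  trainConfig(variant = variant, epochs = epochs, batchSize = 4,
              learningRate = 1e-3, seed = seed,
              gcn = gcnBranchConfig(layerWidths = c(6, 6), headWidth = 5),
              cnn = cnnBranchConfig(convChannels = c(2, 3),
                                    fcWidths = c(7, 5), dropout = 0),
              ...)
}

expect_rel_equal <- function(x, y, tol = 1e-9) {
  denom <- pmax(abs(y), 1)
  expect_lt(max(abs(x - y) / denom), tol)
}
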