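# VAE losses, reparameterization, Adam, backprop exactness, training
# reproducibility, and embedding invariances.

tinyArch <- vaeArchitecture(input = 6, latent = 2, enc1 = 4,
                            enc2 = c(3, 4), enc3 = c(3, 4), enc4 = 4,
                            dec1 = 4, dec2 = c(4, 3), dec3 = c(4, 3),
                            dec4 = 4)

test_that("encoder and decoder expose the published widths", {
  arch <- vaeArchitecture()
  expect_equal(arch$decConcat, 752)          # 384 + 192 + 48 + 128
  expect_equal(arch$encConcat, 1024)
  expect_equal(arch$latent, 16)
  p <- initVaeParams(arch, seed = 1)
  expect_equal(dim(p$mu.W), c(1024L, 16L))
  expect_equal(dim(p$lv.W), c(1024L, 16L))
  expect_equal(dim(p$out.W), c(752L, 20L))
})

test_that("encoding returns 16-dim outputs, finite and deterministic", {
  m <- untrainedVae()
  x <- runif(20)
  e1 <- encodeXic(x, m)
  expect_equal(dim(e1$mu), c(1L, 16L))
  expect_equal(dim(e1$logVar), c(1L, 16L))
  # zero input, zero biases: finite
  e0 <- encodeXic(rep(0, 20), m)
  expect_true(all(is.finite(e0$mu)), all(is.finite(e0$logVar)))
  # inference is deterministic
  e2 <- encodeXic(x, m)
  expect_identical(e1, e2)
  expect_error(encodeXic(runif(19), m), "expected 20")
})

test_that("decoding returns length-20 reconstructions", {
  m <- untrainedVae()
  z <- rnorm(16)
  out <- decodeLatent(z, m)
  expect_equal(dim(out), c(1L, 20L))
  expect_identical(out, decodeLatent(z, m))
  expect_error(decodeLatent(rnorm(15), m), "expected 16")
})

test_that("latent sampling follows both interpretation modes", {
  mu <- c(1, 2); lv <- c(0, 0)
  expect_equal(sampleLatent(mu, lv, c(0, 0)), mu)
  e <- c(0.5, -1)
  expect_equal(sampleLatent(mu, lv, e), mu + e)            # sigma = 1
  expect_equal(sampleLatent(mu, lv, e, literal = TRUE), mu + e)
  # mu = 0, sigma^2 = 4: default 2.0, literal 4.0
  expect_equal(sampleLatent(0, log(4), 1), 2)
  expect_equal(sampleLatent(0, log(4), 1, literal = TRUE), 4)
})

test_that("the VAE loss components match their closed forms", {
  l0 <- vaeLoss(rep(0.5, 20), rep(0.5, 20), rep(0, 16), rep(0, 16))
  expect_equal(l0$kl, 0); expect_equal(l0$recon, 0); expect_equal(l0$vae, 0)
  expect_equal(vaeLoss(0, 0, 1, 0)$kl, 0.5)   # -1/2 (0 - 1 - 1 + 1)
  x <- c(1, rep(0, 19))
  expect_equal(vaeLoss(x, rep(0, 20), 0, 0)$recon, 0.05)  # 1/20
  # KL nonnegativity with equality only at the standard normal
  set.seed(2)
  for (i in 1:25) {
    mu <- rnorm(16); lv <- rnorm(16)
    expect_gte(vaeLoss(rep(0, 4), rep(0, 4), mu, lv)$kl, 0)
  }
  expect_gt(vaeLoss(0, 0, 0.3, 0.2)$kl, 0)
  expect_error(vaeLoss(NaN, 0, 0, 0), "nonfinite")
  # literal printed sign flips the KL contribution
  expect_equal(vaeLoss(0, 0, 1, 0, literalEq2 = TRUE)$vae, -0.5)
})

test_that("triplet loss is a clamped batch-mean hinge", {
  mu <- rnorm(16)
  expect_equal(tripletLoss(mu, mu, mu), 1)          # the margin
  expect_equal(tripletLoss(c(0, 0), c(0, 0), c(5, 0)), 0)
  expect_equal(tripletLoss(rbind(c(0, 0), c(0, 0)),
                           rbind(c(0, 0), c(0, 0)),
                           rbind(c(0, 0), c(5, 0))), 0.5)
  # bounded by the max hinge term, nonnegative
  set.seed(3)
  for (i in 1:20) {
    A <- matrix(rnorm(8), 4); P <- matrix(rnorm(8), 4)
    N <- matrix(rnorm(8), 4)
    tl <- tripletLoss(A, P, N)
    hmax <- max(pmax(rowSums((A - P)^2) - rowSums((A - N)^2) + 1, 0))
    expect_gte(tl, 0); expect_lte(tl, hmax)
  }
  expect_error(tripletLoss(matrix(0, 2, 3), matrix(0, 2, 2),
                           matrix(0, 2, 2)))
})

test_that("the total loss decomposes into its parts", {
  params <- initVaeParams(tinyArch, seed = 8)
  set.seed(9); B <- 4
  Xa <- matrix(runif(B * 6), B); Xp <- matrix(runif(B * 6), B)
  Xn <- matrix(runif(B * 6), B)
  eA <- matrix(rnorm(B * 2), B); eP <- matrix(rnorm(B * 2), B)
  eN <- matrix(rnorm(B * 2), B)
  tl <- vaeTotalLoss(params, tinyArch, Xa, Xp, Xn, eA, eP, eN)
  expect_equal(tl$total, (tl$vaeA + tl$vaeP + tl$vaeN) / 3 + tl$triplet,
               tolerance = 1e-10)
  expect_true(is.finite(tl$total))
})

test_that("Adam matches an independent scalar reference to 1e-12", {
  p <- list(w = matrix(0, 1, 1))
  st <- adamInit(p)
  # zero gradient leaves parameters untouched
  up <- adamStep(p, list(w = matrix(0, 1, 1)), st)
  expect_equal(up$params$w[1, 1], 0)
  # first step with g = 1: theta ~ -lr
  p <- list(w = matrix(0, 1, 1))
  up <- adamStep(p, list(w = matrix(1, 1, 1)), adamInit(p))
  expect_equal(up$params$w[1, 1], -0.001 / (1 + 1e-8), tolerance = 1e-12)
  # 100 randomized steps against the scalar oracle
  set.seed(10)
  gs <- rnorm(100)
  ref <- scalarAdamRef(gs)
  p <- list(w = matrix(0, 1, 1)); st <- adamInit(p)
  for (g in gs) {
    up <- adamStep(p, list(w = matrix(g, 1, 1)), st)
    p <- up$params; st <- up$state
  }
  expect_equal(p$w[1, 1], ref, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on a tiny network", {
  params <- initVaeParams(tinyArch, seed = 42)
  set.seed(11)  # move biases off the ReLU kinks
  params <- lapply(params, function(p) p + rnorm(length(p), 0, 0.05))
  set.seed(7); B <- 3
  Xa <- matrix(runif(B * 6), B); Xp <- matrix(runif(B * 6), B)
  Xn <- matrix(runif(B * 6), B)
  eA <- matrix(rnorm(B * 2), B); eP <- matrix(rnorm(B * 2), B)
  eN <- matrix(rnorm(B * 2), B)
  gl <- DIAdeconv:::vaeTotalGrad(params, tinyArch, Xa, Xp, Xn, eA, eP, eN)
  f <- function(pp) vaeTotalLoss(pp, tinyArch, Xa, Xp, Xn,
                                 eA, eP, eN)$total
  expect_equal(gl$loss, f(params), tolerance = 1e-12)
  h <- 1e-5
  for (k in names(params)) {
    for (j in seq_len(min(4L, length(params[[k]])))) {
      pp <- params; pp[[k]][j] <- pp[[k]][j] + h; f1 <- f(pp)
      pp <- params; pp[[k]][j] <- pp[[k]][j] - h; f2 <- f(pp)
      num <- (f1 - f2) / (2 * h)
      an <- gl$grads[[k]][j]
      expect_equal(an, num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", k, j))
    }
  }
})

test_that("training is reproducible and records a loss history", {
  set.seed(21)
  base <- runif(6)
  tri <- list(
    anchor = matrix(rep(base, each = 30), 30) +
      matrix(runif(180, 0, 0.05), 30),
    positive = matrix(rep(base, each = 30), 30) +
      matrix(runif(180, 0, 0.05), 30),
    negative = matrix(runif(180), 30))
  m1 <- trainVae(tri, arch = tinyArch, epochs = 3, batchSize = 16, seed = 5)
  m2 <- trainVae(tri, arch = tinyArch, epochs = 3, batchSize = 16, seed = 5)
  expect_identical(lossHistory(m1), lossHistory(m2))
  expect_identical(modelParams(m1), modelParams(m2))
  expect_length(lossHistory(m1), 3L)
  expect_true(all(is.finite(lossHistory(m1))))
  expect_error(trainVae(list(anchor = matrix(0, 0, 6),
                             positive = matrix(0, 0, 6),
                             negative = matrix(0, 0, 6)),
                        arch = tinyArch), "no triplets")
})

test_that("embeddings are per-XIC, duplicate-stable and scale-invariant", {
  m <- untrainedVae()
  set.seed(31)
  X <- matrix(runif(5 * 20), 5)
  E <- embedXics(X, m)
  expect_equal(dim(E), c(5L, 16L))
  # duplicates embed identically
  E2 <- embedXics(rbind(X[1, ], X[1, ]), m)
  expect_equal(E2[1, ], E2[2, ])
  # min-max normalization makes scaled copies identical
  Es <- embedXics(rbind(X[3, ], 10 * X[3, ]), m)
  expect_equal(Es[1, ], Es[2, ], tolerance = 1e-12)
})
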