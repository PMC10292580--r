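# Four-branch fully connected variational autoencoder with triplet loss.
# The encoder maps a length-20 fragment XIC to a 16-dimensional latent mean
# (the embedding used for clustering) and log-variance; the mirrored decoder
# reconstructs the XIC from the sampled latent vector. Training combines the
# ELBO-style VAE loss of the anchor/positive/negative XICs with the triplet
# hinge on their latent means, optimized by a from-scratch Adam.
#
# All weights live in a flat named list of matrices/vectors so the Adam
# update and gradient checks can iterate parameters generically.

relu <- function(x) pmax(x, 0)

addBias <- function(M, b) M + rep(b, each = nrow(M))

#' Architecture of the 4-branch VAE
#'
#' Default branch widths: encoder 384 | 192-384 | 48-128 | 128 (concatenated
#' to 1024) with two 16-dimensional heads; decoder mirrored as
#' 384 | 384-192 | 128-48 | 128, concatenated to 752 = 384+192+48+128 and
#' mapped back to the 20-point XIC.
#'
#' @param input XIC length (default 20).
#' @param latent latent dimension (default 16).
#' @param enc1,enc2,enc3,enc4 encoder branch widths.
#' @param dec1,dec2,dec3,dec4 decoder branch widths.
#' @return list describing the architecture, including the derived
#'   concatenation widths `encConcat` and `decConcat`.
#' @export
vaeArchitecture <- function(input = 20, latent = 16,
                            enc1 = 384, enc2 = c(192, 384),
                            enc3 = c(48, 128), enc4 = 128,
                            dec1 = 384, dec2 = c(384, 192),
                            dec3 = c(128, 48), dec4 = 128) {
  list(input = input, latent = latent,
       enc = list(enc1, enc2, enc3, enc4),
       dec = list(dec1, dec2, dec3, dec4),
       encConcat = sum(vapply(list(enc1, enc2, enc3, enc4), function(x)
         x[length(x)], numeric(1))),
       decConcat = sum(vapply(list(dec1, dec2, dec3, dec4), function(x)
         x[length(x)], numeric(1))))
}

# Glorot-uniform weight matrix.
initW <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(runif(fin * fout, -lim, lim), fin, fout)
}

#' Initialize VAE parameters
#'
#' Scaled-uniform (Glorot) weight initialization with zero biases, seeded
#' for reproducibility.
#'
#' @param arch architecture from [vaeArchitecture()].
#' @param seed RNG seed.
#' @return flat named list of parameter arrays.
#' @export
initVaeParams <- function(arch = vaeArchitecture(), seed = 1) {
  set.seed(seed)
  p <- list()
  mkBranch <- function(name, fin, widths) {
    prev <- fin
    for (l in seq_along(widths)) {
      p[[sprintf("%s.W%d", name, l)]] <<- initW(prev, widths[l])
      p[[sprintf("%s.b%d", name, l)]] <<- numeric(widths[l])
      prev <- widths[l]
    }
  }
  for (i in 1:4) mkBranch(paste0("enc", i), arch$input, arch$enc[[i]])
  p$mu.W <- initW(arch$encConcat, arch$latent); p$mu.b <- numeric(arch$latent)
  p$lv.W <- initW(arch$encConcat, arch$latent); p$lv.b <- numeric(arch$latent)
  for (i in 1:4) mkBranch(paste0("dec", i), arch$latent, arch$dec[[i]])
  p$out.W <- initW(arch$decConcat, arch$input); p$out.b <- numeric(arch$input)
  p
}

# Forward through one branch (stack of FC+ReLU, optional dropout on output).
branchForward <- function(X, params, name, nLayers, training, dropP,
                          useDropout) {
  acts <- vector("list", nLayers)
  A <- X
  for (l in seq_len(nLayers)) {
    pre <- addBias(A %*% params[[sprintf("%s.W%d", name, l)]],
                   params[[sprintf("%s.b%d", name, l)]])
    A <- relu(pre)
    acts[[l]] <- list(input = if (l == 1L) X else acts[[l - 1L]]$out,
                      pre = pre, out = A)
    acts[[l]]$out <- A
  }
  mask <- NULL
  if (training && useDropout && dropP > 0) {
    mask <- matrix((runif(length(A)) >= dropP) / (1 - dropP),
                   nrow(A), ncol(A))
    A <- A * mask
  }
  list(out = A, acts = acts, mask = mask)
}

branchBackward <- function(dOut, X, params, name, nLayers, cache, grads) {
  if (!is.null(cache$mask)) dOut <- dOut * cache$mask
  dA <- dOut
  for (l in rev(seq_len(nLayers))) {
    pre <- cache$acts[[l]]$pre
    dPre <- dA * (pre > 0)
    inp <- if (l == 1L) X else cache$acts[[l - 1L]]$out
    wn <- sprintf("%s.W%d", name, l); bn <- sprintf("%s.b%d", name, l)
    grads[[wn]] <- grads[[wn]] + crossprod(inp, dPre)
    grads[[bn]] <- grads[[bn]] + colSums(dPre)
    dA <- tcrossprod(dPre, params[[wn]])
  }
  list(dX = dA, grads = grads)
}

# Full forward pass of one stream; returns everything needed for backward.
vaeForward <- function(params, arch, X, eps, training = FALSE, dropP = 0.2,
                       literalSampling = FALSE) {
  nb <- function(i) length(arch$enc[[i]])
  bc <- vector("list", 4)
  outs <- vector("list", 4)
  for (i in 1:4) {
    bc[[i]] <- branchForward(X, params, paste0("enc", i), nb(i), training,
                             dropP, useDropout = i < 4)
    outs[[i]] <- bc[[i]]$out
  }
  H <- do.call(cbind, outs)
  mu <- addBias(H %*% params$mu.W, params$mu.b)
  lv <- addBias(H %*% params$lv.W, params$lv.b)
  s <- if (literalSampling) exp(lv) else exp(0.5 * lv)
  Z <- mu + eps * s
  nd <- function(i) length(arch$dec[[i]])
  dc <- vector("list", 4)
  douts <- vector("list", 4)
  for (i in 1:4) {
    dc[[i]] <- branchForward(Z, params, paste0("dec", i), nd(i), training,
                             dropP, useDropout = i < 4)
    douts[[i]] <- dc[[i]]$out
  }
  G <- do.call(cbind, douts)
  Xhat <- addBias(G %*% params$out.W, params$out.b)
  list(X = X, encCache = bc, H = H, mu = mu, lv = lv, eps = eps, s = s,
       Z = Z, decCache = dc, G = G, Xhat = Xhat,
       literalSampling = literalSampling)
}

# Backward pass of one stream. dMuExtra collects the triplet-loss gradient
# on mu; vaeWeight is the 1/3 factor of the total loss.
vaeBackward <- function(params, arch, fw, grads, vaeWeight, dMuExtra = NULL) {
  B <- nrow(fw$X)
  inputDim <- ncol(fw$X)
  # reconstruction: vaeWeight * mean_b mean_d (x - xhat)^2
  dXhat <- vaeWeight * (2 / (inputDim * B)) * (fw$Xhat - fw$X)
  grads$out.W <- grads$out.W + crossprod(fw$G, dXhat)
  grads$out.b <- grads$out.b + colSums(dXhat)
  dG <- tcrossprod(dXhat, params$out.W)
  # split decoder concat
  widths <- vapply(arch$dec, function(x) x[length(x)], numeric(1))
  offs <- cumsum(c(0, widths))
  dZ <- matrix(0, B, arch$latent)
  for (i in 1:4) {
    sl <- (offs[i] + 1):offs[i + 1]
    bb <- branchBackward(dG[, sl, drop = FALSE], fw$Z, params,
                         paste0("dec", i), length(arch$dec[[i]]),
                         fw$decCache[[i]], grads)
    grads <- bb$grads
    dZ <- dZ + bb$dX
  }
  sigma2 <- exp(fw$lv)
  dMu <- dZ + vaeWeight * fw$mu / B
  if (!is.null(dMuExtra)) dMu <- dMu + dMuExtra
  dsdlv <- if (fw$literalSampling) exp(fw$lv) else 0.5 * fw$s
  dLv <- dZ * fw$eps * dsdlv + vaeWeight * 0.5 * (sigma2 - 1) / B
  grads$mu.W <- grads$mu.W + crossprod(fw$H, dMu)
  grads$mu.b <- grads$mu.b + colSums(dMu)
  grads$lv.W <- grads$lv.W + crossprod(fw$H, dLv)
  grads$lv.b <- grads$lv.b + colSums(dLv)
  dH <- tcrossprod(dMu, params$mu.W) + tcrossprod(dLv, params$lv.W)
  widths <- vapply(arch$enc, function(x) x[length(x)], numeric(1))
  offs <- cumsum(c(0, widths))
  for (i in 1:4) {
    sl <- (offs[i] + 1):offs[i + 1]
    bb <- branchBackward(dH[, sl, drop = FALSE], fw$X, params,
                         paste0("enc", i), length(arch$enc[[i]]),
                         fw$encCache[[i]], grads)
    grads <- bb$grads
  }
  grads
}

zeroGrads <- function(params) lapply(params, function(p) p * 0)

## ---- user-facing operations ----

asMatrixRow <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

#' Encode XICs to latent mean and log-variance
#'
#' Deterministic when `training = FALSE` (dropout disabled). Inputs are
#' min-max normalized to \[0, 1\] per XIC before entering the network, so
#' embeddings are invariant to overall fragment abundance.
#'
#' @param x length-20 XIC or a matrix with one XIC per row.
#' @param model a [VaeModel-class] (or a bare list with `params`/`arch`).
#' @param training logical; enables dropout.
#' @return list with matrices `mu` and `logVar` (rows = inputs, 16 columns).
#' @export
encodeXic <- function(x, model, training = FALSE) {
  params <- if (is(model, "VaeModel")) model@params else model$params
  arch <- if (is(model, "VaeModel")) model@arch else model$arch
  dropP <- if (is(model, "VaeModel")) model@config$dropP %||% 0.2
           else model$config$dropP %||% 0.2
  X <- asMatrixRow(x)
  if (ncol(X) != arch$input)
    stop("input length ", ncol(X), ", expected ", arch$input)
  X <- minMaxRows(X)
  fw <- vaeForward(params, arch, X, eps = matrix(0, nrow(X), arch$latent),
                   training = training, dropP = dropP)
  list(mu = fw$mu, logVar = fw$lv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reparameterized latent sample
#'
#' Default mode: `Z = mu + eps * exp(log_var / 2)` (standard
#' reparameterization, treating the second head as log-variance). Literal
#' mode: `Z = mu + eps * sigma^2`, the variance-scaled form, available as a
#' configuration switch.
#'
#' @param mu,logVar encoder outputs (vectors or matrices).
#' @param eps standard normal draw of the same shape (injectable for tests).
#' @param literal use the variance-scaled form.
#' @return latent sample of the same shape as `mu`.
#' @export
sampleLatent <- function(mu, logVar, eps, literal = FALSE) {
  s <- if (literal) exp(logVar) else exp(0.5 * logVar)
  mu + eps * s
}

#' Decode a latent vector to a reconstructed XIC
#'
#' @param z latent vector (length 16) or matrix of rows.
#' @param model a [VaeModel-class].
#' @param training logical; enables dropout.
#' @return matrix of reconstructed length-20 XICs.
#' @export
decodeLatent <- function(z, model, training = FALSE) {
  params <- if (is(model, "VaeModel")) model@params else model$params
  arch <- if (is(model, "VaeModel")) model@arch else model$arch
  Z <- asMatrixRow(z)
  if (ncol(Z) != arch$latent)
    stop("latent length ", ncol(Z), ", expected ", arch$latent)
  douts <- vector("list", 4)
  for (i in 1:4) {
    bf <- branchForward(Z, params, paste0("dec", i),
                        length(arch$dec[[i]]), training, 0.2,
                        useDropout = i < 4)
    douts[[i]] <- bf$out
  }
  G <- do.call(cbind, douts)
  addBias(G %*% params$out.W, params$out.b)
}

#' VAE loss components
#'
#' `lossKl = -1/2 * sum_d(log sigma^2 - mu^2 - sigma^2 + 1)` (nonnegative,
#' zero exactly for a standard-normal posterior), `lossRecon` = mean squared
#' error over the XIC points, and `lossVae = lossKl + lossRecon`. Setting
#' `literalEq2 = TRUE` flips the KL sign (`-lossKl + lossRecon`), a
#' configuration mode kept for comparison although it rewards posterior
#' divergence and is not used for training.
#'
#' @param x,xhat input and reconstruction (vectors or row-matrices).
#' @param mu,logVar encoder outputs.
#' @param literalEq2 flip the KL sign.
#' @return list with `kl`, `recon`, `vae` (batch means).
#' @export
vaeLoss <- function(x, xhat, mu, logVar, literalEq2 = FALSE) {
  x <- asMatrixRow(x); xhat <- asMatrixRow(xhat)
  mu <- asMatrixRow(mu); logVar <- asMatrixRow(logVar)
  if (any(!is.finite(x)) || any(!is.finite(xhat)) ||
      any(!is.finite(mu)) || any(!is.finite(logVar)))
    stop("nonfinite inputs to vaeLoss")
  sigma2 <- exp(logVar)
  klPer <- -0.5 * rowSums(logVar - mu^2 - sigma2 + 1)
  reconPer <- rowMeans((x - xhat)^2)
  kl <- mean(klPer); recon <- mean(reconPer)
  list(kl = kl, recon = recon,
       vae = if (literalEq2) -kl + recon else kl + recon)
}

#' Triplet loss on latent means
#'
#' Mean over the batch of
#' `max(||mu_a - mu_p||^2 - ||mu_a - mu_n||^2 + margin, 0)`.
#'
#' @param muA,muP,muN anchor/positive/negative latent means (vectors or
#'   row-matrices).
#' @param margin hinge margin (default 1).
#' @return nonnegative scalar.
#' @export
tripletLoss <- function(muA, muP, muN, margin = 1) {
  muA <- asMatrixRow(muA); muP <- asMatrixRow(muP); muN <- asMatrixRow(muN)
  stopifnot(all(dim(muA) == dim(muP)), all(dim(muA) == dim(muN)))
  hinge <- pmax(rowSums((muA - muP)^2) - rowSums((muA - muN)^2) + margin, 0)
  mean(hinge)
}

#' Total training loss of one triplet batch
#'
#' `(lossVae(a) + lossVae(p) + lossVae(n)) / 3 + tripletLoss(mu_a, mu_p,
#' mu_n)`, evaluated with injectable noise and dropout off, so the value is
#' a deterministic function of the parameters.
#'
#' @param params flat parameter list.
#' @param arch architecture list.
#' @param Xa,Xp,Xn normalized anchor/positive/negative batches (rows).
#' @param epsA,epsP,epsN standard-normal draws (same shape as the latent).
#' @param margin triplet margin.
#' @param literalSampling use the variance-scaled sampling mode.
#' @return list with `total` and the component losses.
#' @export
vaeTotalLoss <- function(params, arch, Xa, Xp, Xn, epsA, epsP, epsN,
                         margin = 1, literalSampling = FALSE) {
  fa <- vaeForward(params, arch, Xa, epsA, literalSampling = literalSampling)
  fp <- vaeForward(params, arch, Xp, epsP, literalSampling = literalSampling)
  fn <- vaeForward(params, arch, Xn, epsN, literalSampling = literalSampling)
  la <- vaeLoss(Xa, fa$Xhat, fa$mu, fa$lv)
  lp <- vaeLoss(Xp, fp$Xhat, fp$mu, fp$lv)
  ln <- vaeLoss(Xn, fn$Xhat, fn$mu, fn$lv)
  tl <- tripletLoss(fa$mu, fp$mu, fn$mu, margin)
  list(total = (la$vae + lp$vae + ln$vae) / 3 + tl,
       vaeA = la$vae, vaeP = lp$vae, vaeN = ln$vae, triplet = tl)
}

# Gradient of vaeTotalLoss wrt params (dropout off, eps fixed).
vaeTotalGrad <- function(params, arch, Xa, Xp, Xn, epsA, epsP, epsN,
                         margin = 1, training = FALSE, dropP = 0.2,
                         literalSampling = FALSE) {
  B <- nrow(Xa)
  fa <- vaeForward(params, arch, Xa, epsA, training, dropP, literalSampling)
  fp <- vaeForward(params, arch, Xp, epsP, training, dropP, literalSampling)
  fn <- vaeForward(params, arch, Xn, epsN, training, dropP, literalSampling)
  hinge <- rowSums((fa$mu - fp$mu)^2) - rowSums((fa$mu - fn$mu)^2) + margin
  act <- as.numeric(hinge > 0) / B
  dMuA <- 2 * (fn$mu - fp$mu) * act
  dMuP <- -2 * (fa$mu - fp$mu) * act
  dMuN <- 2 * (fa$mu - fn$mu) * act
  grads <- zeroGrads(params)
  grads <- vaeBackward(params, arch, fa, grads, 1 / 3, dMuA)
  grads <- vaeBackward(params, arch, fp, grads, 1 / 3, dMuP)
  grads <- vaeBackward(params, arch, fn, grads, 1 / 3, dMuN)
  loss <- (vaeLoss(Xa, fa$Xhat, fa$mu, fa$lv)$vae +
           vaeLoss(Xp, fp$Xhat, fp$mu, fp$lv)$vae +
           vaeLoss(Xn, fn$Xhat, fn$mu, fn$lv)$vae) / 3 +
    mean(pmax(hinge, 0))
  list(grads = grads, loss = loss)
}

## ---- Adam optimizer ----

#' Initialize Adam optimizer state
#'
#' @param params flat parameter list.
#' @return list with zeroed first/second moment accumulators and `t = 0`.
#' @export
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

#' One Adam update step
#'
#' `m_t = b1 m + (1-b1) g`; `v_t = b2 v + (1-b2) g^2`; bias-corrected
#' `mhat = m_t / (1 - b1^t)`, `vhat = v_t / (1 - b2^t)`; update
#' `theta <- theta - lr * mhat / (sqrt(vhat) + eps)`.
#'
#' @param params flat parameter list.
#' @param grads gradients of the same shape.
#' @param state optimizer state from [adamInit()].
#' @param lr learning rate (default 0.001).
#' @param beta1,beta2 moment decay rates (defaults 0.9, 0.999).
#' @param eps denominator stabilizer (default 1e-8).
#' @return list with updated `params` and `state`.
#' @export
adamStep <- function(params, grads, state, lr = 0.001, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- training loop and embedding ----

#' Min-max normalize the rows of a matrix to \[0, 1\]
#'
#' Constant rows map to all zeros.
#'
#' @param X numeric matrix.
#' @return matrix of the same shape.
#' @export
minMaxRows <- function(X) {
  X <- asMatrixRow(X)
  lo <- apply(X, 1, min)
  hi <- apply(X, 1, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  (X - lo) / rng
}

#' Train the triplet-loss VAE
#'
#' @param triplets list with matrices `anchor`, `positive`, `negative`
#'   (one XIC per row), e.g. from [makeTriplets()].
#' @param arch architecture from [vaeArchitecture()].
#' @param epochs training epochs (default 10).
#' @param batchSize minibatch size (default 256).
#' @param seed RNG seed controlling init, shuffling, sampling noise and
#'   dropout; fixed seed gives an identical loss history.
#' @param lr Adam learning rate.
#' @param dropP dropout rate on branch outputs (default 0.2).
#' @param margin triplet margin (default 1).
#' @param literalSampling use the variance-scaled sampling mode in training.
#' @param verbose print per-epoch losses.
#' @return a trained [VaeModel-class] with per-epoch loss history.
#' @export
trainVae <- function(triplets, arch = vaeArchitecture(), epochs = 10,
                     batchSize = 256, seed = 1, lr = 0.001, dropP = 0.2,
                     margin = 1, literalSampling = FALSE, verbose = FALSE) {
  Xa <- minMaxRows(triplets$anchor)
  Xp <- minMaxRows(triplets$positive)
  Xn <- minMaxRows(triplets$negative)
  n <- nrow(Xa)
  if (n < 1L) stop("no triplets supplied")
  stopifnot(nrow(Xp) == n, nrow(Xn) == n)
  params <- initVaeParams(arch, seed = seed)
  state <- adamInit(params)
  set.seed(seed + 1L)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric()
    for (b0 in seq(1L, n, by = batchSize)) {
      idx <- ord[b0:min(b0 + batchSize - 1L, n)]
      B <- length(idx)
      epsA <- matrix(rnorm(B * arch$latent), B)
      epsP <- matrix(rnorm(B * arch$latent), B)
      epsN <- matrix(rnorm(B * arch$latent), B)
      gl <- vaeTotalGrad(params, arch, Xa[idx, , drop = FALSE],
                         Xp[idx, , drop = FALSE], Xn[idx, , drop = FALSE],
                         epsA, epsP, epsN, margin = margin,
                         training = TRUE, dropP = dropP,
                         literalSampling = literalSampling)
      upd <- adamStep(params, gl$grads, state, lr = lr)
      params <- upd$params; state <- upd$state
      losses <- c(losses, gl$loss)
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
  }
  new("VaeModel", params = params, arch = arch,
      config = list(dropP = dropP, margin = margin,
                    literalSampling = literalSampling, seed = seed),
      history = history)
}

#' Embed fragment XICs in the latent Euclidean space
#'
#' Inference mode: dropout off, no sampling; the latent mean is the
#' embedding. XICs are min-max normalized internally, so scaled copies of
#' one XIC embed identically.
#'
#' @param xics matrix with one length-20 XIC per row (or a list of vectors).
#' @param model trained [VaeModel-class].
#' @return matrix of latent means (rows = XICs, 16 columns).
#' @export
embedXics <- function(xics, model) {
  if (is.list(xics) && !is.matrix(xics))
    xics <- do.call(rbind, xics)
  encodeXic(xics, model, training = FALSE)$mu
}
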