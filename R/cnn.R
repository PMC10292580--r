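# Inception-style convolutional classifier scoring the co-elution
# similarity of the top-6 fragment XICs matched to a candidate peptide.
# Input: 6x20 matrix (rows = min-max normalized XICs, descending apex
# intensity, zero-padded below 6). Four branches (1-2-2-1 convolutional
# layers: 1x1 | 1x1->3x3 | 1x1->5x5 | 3x3 avg-pool->1x1, 16 channels each)
# are concatenated along channels, flattened, passed through a
# 512-dimensional fully connected layer and a sigmoid score unit.
#
# Activations are arrays (batch, 6, 20, channels); convolutions use
# shift-and-add with same padding, so forward and backward are exact matrix
# operations.

CNN_H <- 6L
CNN_W <- 20L

# 2D convolution, same padding. X: (B,H,W,Cin); W: (kh,kw,Cin,Cout).
conv2dForward <- function(X, Wk, b) {
  d <- dim(X); B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  kh <- dim(Wk)[1]; kw <- dim(Wk)[2]; Cout <- dim(Wk)[4]
  ch <- (kh + 1L) %/% 2L; cw <- (kw + 1L) %/% 2L
  out <- array(0, c(B, H, Wd, Cout))
  outM <- matrix(out, B * H * Wd, Cout)
  for (di in seq_len(kh)) {
    oi <- di - ch
    hs <- intersect(seq_len(H), seq_len(H) - oi)  # dest rows with valid src
    if (!length(hs)) next
    for (dj in seq_len(kw)) {
      oj <- dj - cw
      ws <- intersect(seq_len(Wd), seq_len(Wd) - oj)
      if (!length(ws)) next
      Xs <- array(0, c(B, H, Wd, Cin))
      Xs[, hs, ws, ] <- X[, hs + oi, ws + oj, , drop = FALSE]
      outM <- outM + matrix(Xs, B * H * Wd, Cin) %*%
        matrix(Wk[di, dj, , ], Cin, Cout)
    }
  }
  out <- array(outM, c(B, H, Wd, Cout))
  sweep(out, 4, b, "+")
}

# Backward of conv2dForward: returns dX, dW, db.
conv2dBackward <- function(dOut, X, Wk) {
  d <- dim(X); B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  kh <- dim(Wk)[1]; kw <- dim(Wk)[2]; Cout <- dim(Wk)[4]
  ch <- (kh + 1L) %/% 2L; cw <- (kw + 1L) %/% 2L
  dX <- array(0, c(B, H, Wd, Cin))
  dW <- array(0, dim(Wk))
  dOutM <- matrix(dOut, B * H * Wd, Cout)
  for (di in seq_len(kh)) {
    oi <- di - ch
    hs <- intersect(seq_len(H), seq_len(H) - oi)
    if (!length(hs)) next
    for (dj in seq_len(kw)) {
      oj <- dj - cw
      ws <- intersect(seq_len(Wd), seq_len(Wd) + -oj)
      if (!length(ws)) next
      Xs <- array(0, c(B, H, Wd, Cin))
      Xs[, hs, ws, ] <- X[, hs + oi, ws + oj, , drop = FALSE]
      XsM <- matrix(Xs, B * H * Wd, Cin)
      dW[di, dj, , ] <- dW[di, dj, , ] + crossprod(XsM, dOutM)
      dXsM <- dOutM %*% t(matrix(Wk[di, dj, , ], Cin, Cout))
      dXs <- array(dXsM, c(B, H, Wd, Cin))
      dX[, hs + oi, ws + oj, ] <- dX[, hs + oi, ws + oj, , drop = FALSE] +
        dXs[, hs, ws, , drop = FALSE]
    }
  }
  db <- colSums(matrix(dOut, B * H * Wd, Cout))
  list(dX = dX, dW = dW, db = db)
}

# 3x3 average pooling with same padding (zeros outside count in the mean,
# fixed divisor 9) -- linear, so backward is the transposed stencil.
avgPool3Forward <- function(X) {
  d <- dim(X)
  out <- array(0, d)
  for (oi in -1:1) {
    hs <- intersect(seq_len(d[2]), seq_len(d[2]) - oi)
    for (oj in -1:1) {
      ws <- intersect(seq_len(d[3]), seq_len(d[3]) - oj)
      out[, hs, ws, ] <- out[, hs, ws, , drop = FALSE] +
        X[, hs + oi, ws + oj, , drop = FALSE]
    }
  }
  out / 9
}

avgPool3Backward <- function(dOut) {
  d <- dim(dOut)
  dX <- array(0, d)
  for (oi in -1:1) {
    hs <- intersect(seq_len(d[2]), seq_len(d[2]) - oi)
    for (oj in -1:1) {
      ws <- intersect(seq_len(d[3]), seq_len(d[3]) - oj)
      dX[, hs + oi, ws + oj, ] <- dX[, hs + oi, ws + oj, , drop = FALSE] +
        dOut[, hs, ws, , drop = FALSE]
    }
  }
  dX / 9
}

#' Initialize CNN classifier parameters
#'
#' @param channels channels per branch (default 16).
#' @param fcDim width of the fully connected layer (default 512).
#' @param seed RNG seed.
#' @return flat named parameter list.
#' @export
initCnnParams <- function(channels = 16, fcDim = 512, seed = 1) {
  set.seed(seed)
  ic <- function(kh, kw, cin, cout) {
    lim <- sqrt(6 / (kh * kw * cin + cout))
    array(runif(kh * kw * cin * cout, -lim, lim), c(kh, kw, cin, cout))
  }
  C <- channels
  flat <- CNN_H * CNN_W * 4L * C
  list(
    b1.W = ic(1, 1, 1, C), b1.b = numeric(C),
    b2.W1 = ic(1, 1, 1, C), b2.b1 = numeric(C),
    b2.W2 = ic(3, 3, C, C), b2.b2 = numeric(C),
    b3.W1 = ic(1, 1, 1, C), b3.b1 = numeric(C),
    b3.W2 = ic(5, 5, C, C), b3.b2 = numeric(C),
    b4.W = ic(1, 1, 1, C), b4.b = numeric(C),
    fc1.W = initW(flat, fcDim), fc1.b = numeric(fcDim),
    fc2.W = initW(fcDim, 1), fc2.b = numeric(1)
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

cnnForward <- function(params, X) {
  # X: (B, 6, 20) -> add channel dim
  if (length(dim(X)) == 3L) dim(X) <- c(dim(X), 1L)
  B <- dim(X)[1]
  a1p <- conv2dForward(X, params$b1.W, params$b1.b); a1 <- relu(a1p)
  a2ap <- conv2dForward(X, params$b2.W1, params$b2.b1); a2a <- relu(a2ap)
  a2p <- conv2dForward(a2a, params$b2.W2, params$b2.b2); a2 <- relu(a2p)
  a3ap <- conv2dForward(X, params$b3.W1, params$b3.b1); a3a <- relu(a3ap)
  a3p <- conv2dForward(a3a, params$b3.W2, params$b3.b2); a3 <- relu(a3p)
  pl <- avgPool3Forward(X)
  a4p <- conv2dForward(pl, params$b4.W, params$b4.b); a4 <- relu(a4p)
  # channel concat: branch output spatial dims must match the input grid
  stopifnot(dim(a1)[2] == CNN_H, dim(a1)[3] == CNN_W,
            all(dim(a2)[2:3] == dim(a1)[2:3]),
            all(dim(a3)[2:3] == dim(a1)[2:3]),
            all(dim(a4)[2:3] == dim(a1)[2:3]))
  cc <- array(c(a1, a2, a3, a4), c(B, CNN_H, CNN_W, 4L * dim(a1)[4]))
  flat <- matrix(cc, B, prod(dim(cc)[-1]))
  h1p <- addBias(flat %*% params$fc1.W, params$fc1.b); h1 <- relu(h1p)
  logit <- addBias(h1 %*% params$fc2.W, params$fc2.b)
  y <- sigmoid(logit)
  list(X = X, a1p = a1p, a1 = a1, a2ap = a2ap, a2a = a2a, a2p = a2p,
       a2 = a2, a3ap = a3ap, a3a = a3a, a3p = a3p, a3 = a3, pl = pl,
       a4p = a4p, a4 = a4, flat = flat, h1p = h1p, h1 = h1,
       logit = logit, y = y)
}

# Backward from dLogit (B x 1).
cnnBackward <- function(params, fw, dLogit) {
  B <- nrow(dLogit)
  grads <- list()
  grads$fc2.W <- crossprod(fw$h1, dLogit)
  grads$fc2.b <- colSums(dLogit)
  dH1 <- tcrossprod(dLogit, params$fc2.W) * (fw$h1p > 0)
  grads$fc1.W <- crossprod(fw$flat, dH1)
  grads$fc1.b <- colSums(dH1)
  dFlat <- tcrossprod(dH1, params$fc1.W)
  C <- dim(fw$a1)[4]
  dCC <- array(dFlat, c(B, CNN_H, CNN_W, 4L * C))
  dA <- lapply(1:4, function(i)
    dCC[, , , ((i - 1) * C + 1):(i * C), drop = FALSE])
  # branch 1
  d1 <- dA[[1]] * (fw$a1p > 0)
  bb <- conv2dBackward(d1, fw$X, params$b1.W)
  grads$b1.W <- bb$dW; grads$b1.b <- bb$db
  # branch 2
  d2 <- dA[[2]] * (fw$a2p > 0)
  bb2 <- conv2dBackward(d2, fw$a2a, params$b2.W2)
  grads$b2.W2 <- bb2$dW; grads$b2.b2 <- bb2$db
  d2a <- bb2$dX * (fw$a2ap > 0)
  bb2a <- conv2dBackward(d2a, fw$X, params$b2.W1)
  grads$b2.W1 <- bb2a$dW; grads$b2.b1 <- bb2a$db
  # branch 3
  d3 <- dA[[3]] * (fw$a3p > 0)
  bb3 <- conv2dBackward(d3, fw$a3a, params$b3.W2)
  grads$b3.W2 <- bb3$dW; grads$b3.b2 <- bb3$db
  d3a <- bb3$dX * (fw$a3ap > 0)
  bb3a <- conv2dBackward(d3a, fw$X, params$b3.W1)
  grads$b3.W1 <- bb3a$dW; grads$b3.b1 <- bb3a$db
  # branch 4
  d4 <- dA[[4]] * (fw$a4p > 0)
  bb4 <- conv2dBackward(d4, fw$pl, params$b4.W)
  grads$b4.W <- bb4$dW; grads$b4.b <- bb4$db
  grads[names(params)]
}

#' Build the 6x20 fragment-group matrix
#'
#' Rows are the matched fragment XICs ordered by descending apex intensity,
#' truncated to the top 6 and min-max normalized per row; groups with fewer
#' than 6 fragments are zero-padded.
#'
#' @param xics list of XIC vectors (length 20) or a matrix of rows.
#' @return 6 x 20 numeric matrix with values in \[0, 1\].
#' @export
buildGroupMatrix <- function(xics) {
  if (is.list(xics) && !is.matrix(xics)) xics <- do.call(rbind, xics)
  xics <- asMatrixRow(xics)
  stopifnot(ncol(xics) == CNN_W)
  apex <- apply(xics, 1, max)
  xics <- xics[order(-apex), , drop = FALSE]
  xics <- minMaxRows(xics[seq_len(min(6L, nrow(xics))), , drop = FALSE])
  out <- matrix(0, CNN_H, CNN_W)
  out[seq_len(nrow(xics)), ] <- xics
  out
}

#' Score the co-elution similarity of a fragment group
#'
#' Deterministic at inference; output bounded in (0, 1) by the sigmoid
#' unit.
#'
#' @param matrix a 6x20 group matrix from [buildGroupMatrix()], or an array
#'   (batch, 6, 20).
#' @param model a [CnnModel-class].
#' @return numeric vector of similarity scores in \[0, 1\].
#' @export
scoreGroup <- function(matrix, model) {
  params <- if (is(model, "CnnModel")) model@params else model$params
  X <- matrix
  if (is.matrix(X)) {
    stopifnot(nrow(X) == CNN_H, ncol(X) == CNN_W)
    X <- array(X, c(1L, CNN_H, CNN_W))
  }
  stopifnot(length(dim(X)) == 3L, dim(X)[2] == CNN_H, dim(X)[3] == CNN_W)
  as.numeric(cnnForward(params, X)$y)
}

#' Binary cross-entropy loss
#'
#' `-(1/N) sum(t log y + (1-t) log(1-y))`. Scores exactly 0 or 1 are
#' clamped at 1e-12 with a warning.
#'
#' @param scores predicted probabilities in (0, 1).
#' @param labels 0/1 labels.
#' @return nonnegative scalar.
#' @export
bceLoss <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (any(scores <= 0 | scores >= 1)) {
    warning("scores clamped away from {0, 1}")
    scores <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  }
  -mean(labels * log(scores) + (1 - labels) * log(1 - scores))
}

#' Train the CNN co-elution classifier
#'
#' Label 1 marks groups whose fragments come from one peptide, 0 marks
#' mixed groups. Optimized with [adamStep()] (Adam, default parameters) on
#' the BCE loss.
#'
#' @param groups array (n, 6, 20) of group matrices.
#' @param labels 0/1 vector of length n; both classes must be present.
#' @param channels,fcDim architecture sizes.
#' @param epochs,batchSize,seed,lr training configuration.
#' @param verbose print per-epoch losses.
#' @return a trained [CnnModel-class] with per-epoch loss history.
#' @export
trainCnn <- function(groups, labels, channels = 16, fcDim = 512,
                     epochs = 5, batchSize = 64, seed = 1, lr = 0.001,
                     verbose = FALSE) {
  stopifnot(length(dim(groups)) == 3L, dim(groups)[2] == CNN_H,
            dim(groups)[3] == CNN_W)
  n <- dim(groups)[1]
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2L)
    stop("training stream must contain both labels")
  params <- initCnnParams(channels, fcDim, seed = seed)
  state <- adamInit(params)
  set.seed(seed + 1L)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric()
    for (b0 in seq(1L, n, by = batchSize)) {
      idx <- ord[b0:min(b0 + batchSize - 1L, n)]
      X <- groups[idx, , , drop = FALSE]
      t <- labels[idx]
      fw <- cnnForward(params, X)
      y <- pmin(pmax(fw$y, 1e-12), 1 - 1e-12)
      loss <- -mean(t * log(y) + (1 - t) * log(1 - y))
      # d BCE / d logit = (y - t) / B  (sigmoid folded in)
      dLogit <- matrix((fw$y - t) / length(t), ncol = 1)
      grads <- cnnBackward(params, fw, dLogit)
      upd <- adamStep(params, grads, state, lr = lr)
      params <- upd$params; state <- upd$state
      losses <- c(losses, loss)
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("cnn epoch %d: loss %.4f", ep, history[ep]))
  }
  new("CnnModel", params = params,
      config = list(channels = channels, fcDim = fcDim, seed = seed),
      history = history)
}

#' Acceptance gate on the similarity score
#'
#' Accepts strictly when `score > theta` ("exceeds").
#'
#' @param score similarity in \[0, 1\].
#' @param theta threshold in \[0, 1\] (default 0.5).
#' @return logical.
#' @export
acceptGroup <- function(score, theta = 0.5) {
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  score > theta
}
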