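# Low-level neural-network primitives for the 1D residual backbone.
#
# Tensors are numeric arrays of dim (batch, length, channels). Convolution
# uses 'same' padding with ceil-mode output length ceil(L / stride), so the
# spatial size after a stride-s layer is independent of the kernel size.
# Batch normalization is per channel over (batch, length); training mode
# uses batch statistics and maintains exponential running averages for
# inference. Everything is plain double precision and fully deterministic.

convOutLen <- function(L, stride) as.integer(ceiling(L / stride))

# x: (n, L, Cin); W: (k, Cin, Cout); b: length Cout
convForward <- function(x, W, b, stride) {
  d <- dim(x); n <- d[1]; L <- d[2]; Cin <- d[3]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  Lout <- convOutLen(L, stride)
  pad <- max((Lout - 1L) * stride + k - L, 0L)
  pl <- pad %/% 2L
  Lp <- L + pad
  xp <- array(0, c(n, Lp, Cin))
  xp[, pl + seq_len(L), ] <- x
  starts <- (seq_len(Lout) - 1L) * stride          # 0-based window starts
  idx <- as.vector(outer(starts, seq_len(k), "+")) # Lout*k positions
  xg <- xp[, idx, , drop = FALSE]                  # (n, Lout*k, Cin)
  X2 <- matrix(xg, n * Lout, k * Cin)              # col-major: (i,l),(a,c)
  Wm <- matrix(W, k * Cin, Cout)
  Y2 <- X2 %*% Wm
  Y2 <- sweep(Y2, 2L, b, "+")
  out <- array(Y2, c(n, Lout, Cout))
  list(out = out,
       cache = list(X2 = X2, dimx = d, Wm = Wm, k = k, stride = stride,
                    starts = starts, pl = pl, Lp = Lp, Lout = Lout))
}

convBackward <- function(dout, cache) {
  d <- cache$dimx; n <- d[1]; L <- d[2]; Cin <- d[3]
  k <- cache$k; Lout <- cache$Lout
  Cout <- ncol(cache$Wm)
  dY2 <- matrix(dout, n * Lout, Cout)
  dW <- crossprod(cache$X2, dY2)                   # (k*Cin, Cout)
  db <- colSums(dY2)
  dX2 <- dY2 %*% t(cache$Wm)                       # (n*Lout, k*Cin)
  dxp <- array(0, c(n, cache$Lp, Cin))
  dim(dX2) <- c(n, Lout, k, Cin)
  for (a in seq_len(k)) {
    pos <- cache$starts + a
    dxp[, pos, ] <- dxp[, pos, ] + dX2[, , a, ]
  }
  dx <- dxp[, cache$pl + seq_len(L), , drop = FALSE]
  list(dx = dx, dW = array(dW, c(k, Cin, Cout)), db = db)
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

bnForward <- function(x, gamma, beta, running, train) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  xm <- matrix(x, n * L, C)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2L, mu)^2)             # biased variance
    running$mean <- BN_MOMENTUM * running$mean + (1 - BN_MOMENTUM) * mu
    running$var <- BN_MOMENTUM * running$var + (1 - BN_MOMENTUM) * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, inv, "*")
  ym <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = array(ym, d), running = running,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d))
}

bnBackward <- function(dout, cache) {
  d <- cache$d; m <- d[1] * d[2]
  dym <- matrix(dout, m, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, cache$gamma, "*")
  # standard batch-norm gradient (batch statistics path included)
  t1 <- sweep(dxhat, 2L, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
  dxm <- sweep(t1 - t2, 2L, cache$inv, "*")
  list(dx = array(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

reluForward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

reluBackward <- function(dout, mask) dout * mask

denseForward <- function(x, W, b) {
  out <- sweep(x %*% W, 2L, b, "+")
  list(out = out, cache = list(x = x, W = W))
}

denseBackward <- function(dout, cache) {
  list(dx = dout %*% t(cache$W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}
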