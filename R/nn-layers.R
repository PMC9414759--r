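# Neural-network layer primitives (single-sample forward/backward).
#
# The regressors train with batch size 1 on 50 x 8 windows, so every layer
# operates on one sample: matrices (time x channels) for 1D layers, arrays
# (height x width x channels) for 2D layers. Each *_fwd returns its output
# plus the cache its *_bwd needs; backward passes return parameter gradients
# and the gradient w.r.t. the layer input.

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- 1D convolution, kernel 2, stride 2, valid padding, ReLU ----

conv1d_fwd <- function(X, W, b) {
  T_in <- nrow(X)
  T_out <- (T_in - 2L) %/% 2L + 1L
  i1 <- seq.int(1L, by = 2L, length.out = T_out)
  X2 <- cbind(X[i1, , drop = FALSE], X[i1 + 1L, , drop = FALSE])
  Z <- X2 %*% W
  Z <- sweep(Z, 2L, b, "+")
  mask <- Z > 0
  list(out = Z * mask, X2 = X2, mask = mask, i1 = i1,
       T_in = T_in, C = ncol(X))
}

conv1d_bwd <- function(dA, cache, W) {
  dZ <- dA * cache$mask
  dW <- crossprod(cache$X2, dZ)
  db <- colSums(dZ)
  dX2 <- tcrossprod(dZ, W)
  C <- cache$C
  dX <- matrix(0, cache$T_in, C)
  dX[cache$i1, ] <- dX2[, seq_len(C), drop = FALSE]
  dX[cache$i1 + 1L, ] <- dX2[, C + seq_len(C), drop = FALSE]
  list(dW = dW, db = db, dX = dX)
}

## ---- 1D max pooling, size 2, stride 2, valid ----

pool1d_fwd <- function(X) {
  T_out <- nrow(X) %/% 2L
  i1 <- seq.int(1L, by = 2L, length.out = T_out)
  a <- X[i1, , drop = FALSE]
  b <- X[i1 + 1L, , drop = FALSE]
  sel <- a >= b                      # ties to the earlier sample
  list(out = pmax(a, b), sel = sel, i1 = i1, T_in = nrow(X))
}

pool1d_bwd <- function(dP, cache) {
  dX <- matrix(0, cache$T_in, ncol(dP))
  dX[cache$i1, ] <- dP * cache$sel
  dX[cache$i1 + 1L, ] <- dP * !cache$sel
  dX
}

## ---- 2D convolution, same padding, ReLU ----
# Geometry (padding offsets and the patch->column index map) depends only on
# the input dims, which are fixed per layer, so it is precomputed at model
# build time.

conv2d_geom <- function(H, W, C, kh = 4L, kw = 4L, sh = 2L, sw = 2L) {
  H2 <- as.integer(ceiling(H / sh))
  W2 <- as.integer(ceiling(W / sw))
  pad_h <- max((H2 - 1L) * sh + kh - H, 0L)
  pad_w <- max((W2 - 1L) * sw + kw - W, 0L)
  pt <- pad_h %/% 2L
  pl <- pad_w %/% 2L
  Hp <- H + pad_h
  Wp <- W + pad_w
  idx <- matrix(0L, H2 * W2, kh * kw * C)
  r <- 0L
  pos_h <- integer(H2 * W2)
  pos_w <- integer(H2 * W2)
  for (w2 in seq_len(W2)) {
    for (h2 in seq_len(H2)) {
      r <- (w2 - 1L) * H2 + h2
      pos_h[r] <- (h2 - 1L) * sh
      pos_w[r] <- (w2 - 1L) * sw
    }
  }
  col <- 0L
  for (cc in seq_len(C)) {
    for (kwo in seq_len(kw)) {
      for (kho in seq_len(kh)) {
        col <- col + 1L
        idx[, col] <- (pos_h + kho) + (pos_w + kwo - 1L) * Hp +
          (cc - 1L) * Hp * Wp
      }
    }
  }
  list(H = H, W = W, C = C, H2 = H2, W2 = W2, Hp = Hp, Wp = Wp,
       pt = pt, pl = pl, idx = idx)
}

conv2d_fwd <- function(X, W, b, g) {
  pad <- array(0, c(g$Hp, g$Wp, g$C))
  pad[g$pt + seq_len(g$H), g$pl + seq_len(g$W), ] <- X
  Pm <- matrix(as.vector(pad)[g$idx], nrow = g$H2 * g$W2)
  Z <- Pm %*% W
  Z <- sweep(Z, 2L, b, "+")
  mask <- Z > 0
  A <- Z * mask
  list(out = array(A, c(g$H2, g$W2, ncol(W))), Pm = Pm, mask = mask)
}

conv2d_bwd <- function(dA, cache, W, g) {
  F_out <- ncol(W)
  dZ <- matrix(dA, g$H2 * g$W2, F_out) * cache$mask
  dW <- crossprod(cache$Pm, dZ)
  db <- colSums(dZ)
  dPm <- tcrossprod(dZ, W)
  dv <- numeric(g$Hp * g$Wp * g$C)
  for (j in seq_len(ncol(g$idx))) {
    ii <- g$idx[, j]
    dv[ii] <- dv[ii] + dPm[, j]      # indices unique within a column
  }
  dpad <- array(dv, c(g$Hp, g$Wp, g$C))
  list(dW = dW, db = db,
       dX = dpad[g$pt + seq_len(g$H), g$pl + seq_len(g$W), , drop = FALSE])
}

## ---- 2D max pooling, size (2,2), stride (2,2) ----
# Output dims floor(dim/2), clamped to >= 1: an axis already reduced to a
# single element passes through (the pooling window is truncated at the
# border), which keeps the narrow 8-wide input poolable after two stride-2
# convolutions.

pool2d_fwd <- function(X) {
  d <- dim(X)
  H2 <- max(d[1] %/% 2L, 1L)
  W2 <- max(d[2] %/% 2L, 1L)
  C <- d[3]
  P <- array(-Inf, c(2L * H2, 2L * W2, C))
  hh <- seq_len(min(d[1], 2L * H2))
  ww <- seq_len(min(d[2], 2L * W2))
  P[hh, ww, ] <- X[hh, ww, , drop = FALSE]
  io <- seq.int(1L, by = 2L, length.out = H2)
  jo <- seq.int(1L, by = 2L, length.out = W2)
  A11 <- P[io, jo, , drop = FALSE]
  A21 <- P[io + 1L, jo, , drop = FALSE]
  A12 <- P[io, jo + 1L, , drop = FALSE]
  A22 <- P[io + 1L, jo + 1L, , drop = FALSE]
  M <- pmax(A11, A21, A12, A22)
  s1 <- A11 == M
  s2 <- (A21 == M) & !s1
  s3 <- (A12 == M) & !s1 & !s2
  s4 <- !(s1 | s2 | s3)
  list(out = M, s = list(s1, s2, s3, s4), dims = d, H2 = H2, W2 = W2,
       hh = hh, ww = ww, io = io, jo = jo)
}

pool2d_bwd <- function(dM, cache) {
  d <- cache$dims
  dP <- array(0, c(2L * cache$H2, 2L * cache$W2, d[3]))
  io <- cache$io; jo <- cache$jo
  dP[io, jo, ] <- dM * cache$s[[1]]
  dP[io + 1L, jo, ] <- dM * cache$s[[2]]
  dP[io, jo + 1L, ] <- dM * cache$s[[3]]
  dP[io + 1L, jo + 1L, ] <- dM * cache$s[[4]]
  dX <- array(0, d)
  dX[cache$hh, cache$ww, ] <- dP[cache$hh, cache$ww, , drop = FALSE]
  dX
}

## ---- LSTM (tanh cell, sigmoid gates), gate order i, f, g, o ----

lstm_fwd <- function(X, Wx, Wh, b, return_seq = TRUE) {
  T_in <- nrow(X)
  U <- ncol(Wh) %/% 4L
  iu <- seq_len(U); fu <- U + iu; gu <- 2L * U + iu; ou <- 3L * U + iu
  H <- matrix(0, T_in, U); Cs <- matrix(0, T_in, U)
  I <- matrix(0, T_in, U); Fg <- matrix(0, T_in, U)
  G <- matrix(0, T_in, U); O <- matrix(0, T_in, U); TC <- matrix(0, T_in, U)
  h <- numeric(U); cc <- numeric(U)
  ZX <- X %*% Wx                     # input contribution for all steps
  for (t in seq_len(T_in)) {
    z <- ZX[t, ] + drop(h %*% Wh) + b
    i <- sigmoid(z[iu]); f <- sigmoid(z[fu])
    g <- tanh(z[gu]); o <- sigmoid(z[ou])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    I[t, ] <- i; Fg[t, ] <- f; G[t, ] <- g; O[t, ] <- o
    Cs[t, ] <- cc; TC[t, ] <- tc; H[t, ] <- h
  }
  list(out = if (return_seq) H else H[T_in, ], H = H, Cs = Cs, I = I,
       Fg = Fg, G = G, O = O, TC = TC, X = X, U = U, return_seq = return_seq)
}

lstm_bwd <- function(dOut, cache, Wx, Wh) {
  X <- cache$X
  T_in <- nrow(X)
  U <- cache$U
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, U, 4L * U)
  db <- numeric(4L * U)
  dX <- matrix(0, T_in, ncol(X))
  dh_next <- numeric(U)
  dc_next <- numeric(U)
  dZ <- matrix(0, T_in, 4L * U)
  iu <- seq_len(U); fu <- U + iu; gu <- 2L * U + iu; ou <- 3L * U + iu
  for (t in seq.int(T_in, 1L)) {
    dh <- dh_next
    if (cache$return_seq) {
      dh <- dh + dOut[t, ]
    } else if (t == T_in) {
      dh <- dh + dOut
    }
    o <- cache$O[t, ]; tc <- cache$TC[t, ]
    i <- cache$I[t, ]; f <- cache$Fg[t, ]; g <- cache$G[t, ]
    c_prev <- if (t > 1L) cache$Cs[t - 1L, ] else numeric(U)
    do_ <- dh * tc
    dc <- dh * o * (1 - tc^2) + dc_next
    dz <- numeric(4L * U)
    dz[iu] <- dc * g * i * (1 - i)
    dz[fu] <- dc * c_prev * f * (1 - f)
    dz[gu] <- dc * i * (1 - g^2)
    dz[ou] <- do_ * o * (1 - o)
    dZ[t, ] <- dz
    h_prev <- if (t > 1L) cache$H[t - 1L, ] else numeric(U)
    dWh <- dWh + outer(h_prev, dz)
    dh_next <- drop(Wh %*% dz)
    dc_next <- dc * f
  }
  dWx <- crossprod(X, dZ)
  db <- colSums(dZ)
  dX <- tcrossprod(dZ, Wx)
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

## ---- parameter initialization ----

glorot <- function(nin, nout, nrow_ = nin, ncol_ = nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nrow_ * ncol_, -lim, lim), nrow_, ncol_)
}

lstm_init <- function(D, U) {
  b <- numeric(4L * U)
  b[U + seq_len(U)] <- 1        # forget-gate bias 1 eases gradient flow
  list(Wx = glorot(D, 4L * U), Wh = glorot(U, 4L * U), b = b)
}
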