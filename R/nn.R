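# Compact CNN engine used by the classifier: 3x3 stride-1 "same"
# convolutions via im2col + BLAS gemm, 2x2 stride-2 max-pooling, dense
# layers with inverted dropout, softmax cross-entropy, and RMSprop. Frozen
# layers take part in the forward pass but receive no gradients; training
# caches the frozen-prefix feature maps once per image, so epochs cost only
# the trainable suffix.

#' Softmax with max-subtraction
#'
#' `softmax(z)_i = exp(z_i) / sum_j exp(z_j)`, computed after subtracting
#' `max(z)` so large logits cannot overflow.
#'
#' @param z finite numeric vector of logits.
#' @return probability vector summing to 1.
#' @export
softmax <- function(z) {
  if (any(!is.finite(z))) stop("logits must be finite", call. = FALSE)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Rectified linear unit
#'
#' @param x numeric vector.
#' @return `max(0, x)`, elementwise.
#' @export
relu <- function(x) pmax(x, 0)

# --- conv -------------------------------------------------------------------

# zero padding by one pixel on each side
pad1 <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  xp
}

# im2col for a 3x3 kernel: (H*W) x (9*Cin), column block k holds the pixels
# under kernel offset k (column-major offsets), channels fastest within block
im2col3 <- function(xp, H, W, Cin) {
  cols <- matrix(0, H * W, 9L * Cin)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    slice <- xp[(1L + di):(H + di), (1L + dj):(W + dj), , drop = FALSE]
    cols[, ((k - 1L) * Cin + 1L):(k * Cin)] <- matrix(slice, H * W, Cin)
  }
  cols
}

col2im3 <- function(dcols, H, W, Cin) {
  dxp <- array(0, c(H + 2L, W + 2L, Cin))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    block <- array(dcols[, ((k - 1L) * Cin + 1L):(k * Cin)], c(H, W, Cin))
    dxp[(1L + di):(H + di), (1L + dj):(W + dj), ] <-
      dxp[(1L + di):(H + di), (1L + dj):(W + dj), , drop = FALSE] + block
  }
  dxp
}

# x: H x W x Cin in, returns activation H x W x Cout (ReLU), optional cache
conv_forward <- function(x, Wt, b, keep_cache = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  cols <- im2col3(pad1(x), H, W, Cin)
  pre <- cols %*% Wt
  pre <- sweep(pre, 2L, b, "+")
  act <- array(pmax(pre, 0), c(H, W, ncol(Wt)))
  if (keep_cache) list(out = act, cols = cols, pre = pre) else list(out = act)
}

# dout: H x W x Cout gradient on the activation
conv_backward <- function(dout, cache, Wt, need_dx = TRUE) {
  H <- dim(dout)[1]; W <- dim(dout)[2]; Cout <- dim(dout)[3]
  dpre <- matrix(dout, H * W, Cout) * (cache$pre > 0)
  dWt <- crossprod(cache$cols, dpre)
  db <- colSums(dpre)
  dx <- NULL
  if (need_dx) {
    Cin9 <- nrow(Wt)
    dcols <- tcrossprod(dpre, Wt)          # (H*W) x (9*Cin)
    dxp <- col2im3(dcols, H, W, Cin9 / 9L)
    dx <- dxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
  }
  list(dWt = dWt, db = db, dx = dx)
}

# --- max pool ---------------------------------------------------------------

pool_forward <- function(x, keep_cache = FALSE) {
  d <- dim(x); H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L; C <- d[3]
  i1 <- seq(1L, 2L * H2, by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * W2, by = 2L); j2 <- j1 + 1L
  a <- x[i1, j1, , drop = FALSE]; b <- x[i2, j1, , drop = FALSE]
  cc <- x[i1, j2, , drop = FALSE]; dd <- x[i2, j2, , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  if (!keep_cache) return(list(out = out))
  # argmax over the 2x2 window, ties to the first in (row, col) scan order
  idx <- array(4L, dim(out))
  idx[cc >= dd] <- 3L
  idx[b >= pmax(cc, dd)] <- 2L
  idx[a >= pmax(b, cc, dd)] <- 1L
  list(out = out, idx = idx, in_dim = d)
}

pool_backward <- function(dout, cache) {
  d <- cache$in_dim
  H2 <- dim(dout)[1]; W2 <- dim(dout)[2]
  i1 <- seq(1L, 2L * H2, by = 2L); j1 <- seq(1L, 2L * W2, by = 2L)
  dx <- array(0, d)
  sel <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (s in 1:4) {
    mask <- (cache$idx == s) * dout
    dx[i1 + sel[[s]][1], j1 + sel[[s]][2], ] <-
      dx[i1 + sel[[s]][1], j1 + sel[[s]][2], , drop = FALSE] + mask
  }
  dx
}

# --- dense / dropout --------------------------------------------------------

dense_forward <- function(a, W, b, activation, keep_cache = FALSE) {
  pre <- drop(W %*% a) + b
  out <- switch(activation,
                relu = pmax(pre, 0),
                softmax = softmax(pre),
                linear = pre)
  if (keep_cache) list(out = out, pre = pre, a_in = a) else list(out = out)
}

dense_backward <- function(dout, cache, W, activation) {
  dpre <- switch(activation,
                 relu = dout * (cache$pre > 0),
                 # softmax handled jointly with cross-entropy by the caller
                 linear = dout,
                 softmax = dout)
  list(dW = tcrossprod(dpre, cache$a_in), db = dpre,
       dx = drop(crossprod(W, dpre)))
}

dropout_mask <- function(n, rate) {
  if (rate <= 0) return(rep(1, n))
  (stats::runif(n) >= rate) / (1 - rate)
}

# --- RMSprop ----------------------------------------------------------------

rmsprop_update <- function(w, g, v, lr, rho = 0.9, eps = 1e-7) {
  v <- rho * v + (1 - rho) * g * g
  list(w = w - lr * g / (sqrt(v) + eps), v = v)
}
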