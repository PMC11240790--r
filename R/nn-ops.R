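# Differentiable layer primitives for 4D (x, y, z, channel) arrays.
# Convolutions run through the compiled kernels in src/ops.cpp; everything
# else is vectorized R. Each *_fwd returns what its *_bwd needs.

# convolutions are lowered to GEMM via im2col so they run on BLAS;
# conv3_fwd/conv3_bwd_* in src/ are the direct-loop reference kernels.
# want_cols=TRUE additionally returns the im2col matrix so the backward
# pass does not have to rebuild it.
nn_conv_fwd <- function(x, w, b, want_cols = FALSE) {
  d <- dim(x); dw <- dim(w); k <- dw[1]
  nvox <- prod(d[1:3])
  cols <- NULL
  if (k == 1L) {
    y <- matrix(x, nvox, d[4]) %*% matrix(w, d[4], dw[5])
  } else {
    cols <- im2col3(x, k)
    y <- cols %*% matrix(w, k^3 * dw[4], dw[5])
  }
  y <- array(y + rep(b, each = nvox), dim = c(d[1:3], dw[5]))
  if (want_cols) list(y = y, cols = cols) else y
}

nn_conv_bwd <- function(x, w, gy, cols = NULL) {
  d <- dim(x); dw <- dim(w); k <- dw[1]
  nvox <- prod(d[1:3])
  gym <- matrix(gy, nvox, dw[5])
  if (k == 1L) {
    gw <- crossprod(matrix(x, nvox, d[4]), gym)
    gx <- array(tcrossprod(gym, matrix(w, d[4], dw[5])), dim = d)
  } else {
    if (is.null(cols)) cols <- im2col3(x, k)
    gw <- crossprod(cols, gym)
    gcols <- tcrossprod(gym, matrix(w, k^3 * dw[4], dw[5]))
    gx <- col2im3(gcols, d[1], d[2], d[3], d[4], k)
  }
  list(gx = gx, gw = array(gw, dim = dw), gb = colSums(gym))
}

# instance normalization: per-channel standardization over the spatial grid,
# with learned scale/shift. eps guards all-constant channels (padded crops).
nn_inorm_fwd <- function(x, g, b, eps = 1e-5) {
  d <- dim(x); nvox <- prod(d[1:3]); nc <- d[4]
  xm <- matrix(x, nvox, nc)
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  istd <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- (xm - rep(mu, each = nvox)) * rep(istd, each = nvox)
  y <- xhat * rep(g, each = nvox) + rep(b, each = nvox)
  list(y = array(y, d), xhat = xhat, istd = istd)
}

nn_inorm_bwd <- function(cache, g, gy) {
  d <- dim(gy); nvox <- prod(d[1:3]); nc <- d[4]
  gym <- matrix(gy, nvox, nc)
  gg <- colSums(gym * cache$xhat)
  gb <- colSums(gym)
  dxhat <- gym * rep(g, each = nvox)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- (dxhat - rep(m1, each = nvox) - cache$xhat * rep(m2, each = nvox)) *
    rep(cache$istd, each = nvox)
  list(gx = array(dx, d), gg = gg, gb = gb)
}

nn_relu_fwd <- function(x) { x[x < 0] <- 0; x }
nn_relu_bwd <- function(y, gy) { gy[y <= 0] <- 0; gy }

# 2x average pooling / nearest upsampling along the three spatial axes
nn_pool2 <- function(x) {
  d <- dim(x)
  i <- seq(1L, d[1], 2L); j <- seq(1L, d[2], 2L); k <- seq(1L, d[3], 2L)
  (x[i, j, k, , drop = FALSE]     + x[i + 1, j, k, , drop = FALSE] +
   x[i, j + 1, k, , drop = FALSE] + x[i, j, k + 1, , drop = FALSE] +
   x[i + 1, j + 1, k, , drop = FALSE] + x[i + 1, j, k + 1, , drop = FALSE] +
   x[i, j + 1, k + 1, , drop = FALSE] + x[i + 1, j + 1, k + 1, , drop = FALSE]) / 8
}

nn_pool2_bwd <- function(gy, in_dim) {
  g <- gy / 8
  ri <- rep(seq_len(dim(gy)[1]), each = 2L)
  rj <- rep(seq_len(dim(gy)[2]), each = 2L)
  rk <- rep(seq_len(dim(gy)[3]), each = 2L)
  g[ri, rj, rk, , drop = FALSE]
}

nn_up2 <- function(x) {
  ri <- rep(seq_len(dim(x)[1]), each = 2L)
  rj <- rep(seq_len(dim(x)[2]), each = 2L)
  rk <- rep(seq_len(dim(x)[3]), each = 2L)
  x[ri, rj, rk, , drop = FALSE]
}

nn_up2_bwd <- function(gy) nn_pool2(gy) * 8

nn_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))

nn_softmax <- function(z) {
  nc <- dim(z)[4]
  zmax <- z[, , , 1]
  if (nc > 1) for (c in 2:nc) zmax <- pmax(zmax, z[, , , c])
  e <- z
  for (c in seq_len(nc)) e[, , , c] <- exp(z[, , , c] - zmax)
  s <- e[, , , 1]
  if (nc > 1) for (c in 2:nc) s <- s + e[, , , c]
  for (c in seq_len(nc)) e[, , , c] <- e[, , , c] / s
  e
}

# compound soft-Dice + cross-entropy objective; returns the loss and its
# gradient with respect to the logits (head folded in analytically)
nn_loss_grad <- function(logits, target, head, smooth = 1) {
  d <- dim(logits); nvox <- prod(d[1:3])
  if (head == "sigmoid") {
    p <- nn_sigmoid(logits)
    t <- target
    bce <- -mean(t * log(p + 1e-12) + (1 - t) * log(1 - p + 1e-12))
    sp <- sum(p); st <- sum(t); spt <- sum(p * t)
    dice <- (2 * spt + smooth) / (sp + st + smooth)
    dL_dp <- -(2 * t * (sp + st + smooth) - (2 * spt + smooth)) /
      (sp + st + smooth)^2
    dz <- (p - t) / length(p) + dL_dp * p * (1 - p)
    return(list(loss = bce + (1 - dice), dice = dice, dlogits = dz))
  }
  # softmax over channels; target is one-hot with matching channels
  p <- nn_softmax(logits)
  nc <- d[4]
  ce <- -sum(target * log(p + 1e-12)) / nvox
  dL_dp <- array(0, d)
  dice_sum <- 0; ndice <- 0
  for (c in seq_len(nc - 1)) {      # last channel is background, skipped in Dice
    pc <- p[, , , c]; tc <- target[, , , c]
    sp <- sum(pc); st <- sum(tc); spt <- sum(pc * tc)
    dice_sum <- dice_sum + (2 * spt + smooth) / (sp + st + smooth)
    ndice <- ndice + 1
    dL_dp[, , , c] <- -(2 * tc * (sp + st + smooth) - (2 * spt + smooth)) /
      (sp + st + smooth)^2 / (nc - 1)
  }
  dice <- dice_sum / ndice
  # softmax jacobian: dz_c = p_c * (dL/dp_c - sum_c' dL/dp_c' p_c')
  inner <- array(0, d[1:3])
  for (c in seq_len(nc)) inner <- inner + dL_dp[, , , c] * p[, , , c]
  dz <- array(0, d)
  for (c in seq_len(nc))
    dz[, , , c] <- p[, , , c] * (dL_dp[, , , c] - inner)
  dz <- dz + (p - target) / nvox    # cross-entropy part
  list(loss = ce + (1 - dice), dice = dice, dlogits = dz)
}
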