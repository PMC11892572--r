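# Minimal CPU engine for convolutional encoder-decoder networks.
#
# Feature tensors are R arrays with the channel axis LAST:
#   2D: (H, W, N, C)      3D: (D, H, W, N, C)
# where N is the batch. A tensor's matrix view is (prod(spatial)*N, C),
# which maps every convolution onto one BLAS gemm via shifted-slice
# im2col (kernel 3, stride 1, padding 1 throughout).

matv <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[-length(d)]), d[length(d)])
  x
}

add_bias <- function(y, b) y + rep(b, each = nrow(y))

# ---- 3x3 convolution, padding 1 --------------------------------------

conv2d_fwd <- function(x, W, b, keep = TRUE) {
  d <- dim(x)
  cols <- cpp_im2col_2d(x, as.integer(d))
  y <- add_bias(cols %*% W, b)
  dim(y) <- c(d[1], d[2], d[3], ncol(W))
  list(y = y, cols = if (keep) cols else NULL, xdim = d)
}

conv2d_bwd <- function(dy, cache, W) {
  dy_m <- matv(dy)
  dW <- crossprod(cache$cols, dy_m)
  db <- colSums(dy_m)
  dcols <- tcrossprod(dy_m, W)
  dx <- cpp_col2im_2d(dcols, as.integer(cache$xdim))
  list(dx = dx, dW = dW, db = db)
}

conv3d_fwd <- function(x, W, b, keep = TRUE) {
  d <- dim(x)
  cols <- cpp_im2col_3d(x, as.integer(d))
  y <- add_bias(cols %*% W, b)
  dim(y) <- c(d[1], d[2], d[3], d[4], ncol(W))
  list(y = y, cols = if (keep) cols else NULL, xdim = d)
}

conv3d_bwd <- function(dy, cache, W) {
  dy_m <- matv(dy)
  dW <- crossprod(cache$cols, dy_m)
  db <- colSums(dy_m)
  dcols <- tcrossprod(dy_m, W)
  dx <- cpp_col2im_3d(dcols, as.integer(cache$xdim))
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalization (per channel) -------------------------------

bn_fwd <- function(x, gamma, beta, run_mu, run_var, train,
                   momentum = 0.1, eps = 1e-5) {
  xm <- matv(x)
  M <- nrow(xm)
  if (train) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = M)
    v <- colMeans(xc * xc)
    run_mu <- (1 - momentum) * run_mu + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mu; v <- run_var
    xc <- xm - rep(mu, each = M)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = M)
  y <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  dim(y) <- dim(x)
  list(y = y, xhat = xhat, inv = inv, run_mu = run_mu, run_var = run_var)
}

bn_bwd <- function(dy, cache, gamma) {
  dy_m <- matv(dy)
  M <- nrow(dy_m)
  dgamma <- colSums(dy_m * cache$xhat)
  dbeta <- colSums(dy_m)
  dxhat <- dy_m * rep(gamma, each = M)
  dx <- (rep(cache$inv, each = M) / M) *
    (M * dxhat - rep(colSums(dxhat), each = M) -
       cache$xhat * rep(dgamma, each = M))
  dim(dx) <- dim(dy)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- 2x max pooling ---------------------------------------------------

pool2d_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  r1 <- seq(1L, H, 2L); r2 <- seq(2L, H, 2L)
  c1 <- seq(1L, W, 2L); c2 <- seq(2L, W, 2L)
  a11 <- x[r1, c1, , , drop = FALSE]; a21 <- x[r2, c1, , , drop = FALSE]
  a12 <- x[r1, c2, , , drop = FALSE]; a22 <- x[r2, c2, , , drop = FALSE]
  y <- pmax(a11, a21, a12, a22)
  m11 <- a11 == y
  m21 <- (a21 == y) & !m11
  m12 <- (a12 == y) & !(m11 | m21)
  m22 <- !(m11 | m21 | m12)
  list(y = y, masks = list(m11, m21, m12, m22), xdim = d)
}

pool2d_bwd <- function(dy, cache) {
  d <- cache$xdim; H <- d[1]; W <- d[2]
  r1 <- seq(1L, H, 2L); r2 <- seq(2L, H, 2L)
  c1 <- seq(1L, W, 2L); c2 <- seq(2L, W, 2L)
  m <- cache$masks
  dx <- array(0, d)
  dx[r1, c1, , ] <- dy * m[[1]]
  dx[r2, c1, , ] <- dy * m[[2]]
  dx[r1, c2, , ] <- dy * m[[3]]
  dx[r2, c2, , ] <- dy * m[[4]]
  dx
}

pool3d_fwd <- function(x) {
  d <- dim(x); D <- d[1]; H <- d[2]; W <- d[3]
  s <- function(n) list(seq(1L, n, 2L), seq(2L, n, 2L))
  sd <- s(D); sh <- s(H); sw <- s(W)
  slices <- vector("list", 8L)
  k <- 0L
  for (ow in 1:2) for (oh in 1:2) for (od in 1:2) {
    k <- k + 1L
    slices[[k]] <- x[sd[[od]], sh[[oh]], sw[[ow]], , , drop = FALSE]
  }
  y <- slices[[1]]
  for (k in 2:8) y <- pmax(y, slices[[k]])
  masks <- vector("list", 8L)
  taken <- array(FALSE, dim(y))
  for (k in 1:8) {
    masks[[k]] <- (slices[[k]] == y) & !taken
    taken <- taken | masks[[k]]
  }
  list(y = y, masks = masks, xdim = d)
}

pool3d_bwd <- function(dy, cache) {
  d <- cache$xdim; D <- d[1]; H <- d[2]; W <- d[3]
  s <- function(n) list(seq(1L, n, 2L), seq(2L, n, 2L))
  sd <- s(D); sh <- s(H); sw <- s(W)
  dx <- array(0, d)
  k <- 0L
  for (ow in 1:2) for (oh in 1:2) for (od in 1:2) {
    k <- k + 1L
    dx[sd[[od]], sh[[oh]], sw[[ow]], , ] <- dy * cache$masks[[k]]
  }
  dx
}

# ---- transposed convolution, kernel 2, stride 2 ----------------------
# Weight layout: matrix (n_offsets * Cin, Cout), offset-major rows.

upconv2d_fwd <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  Cout <- ncol(W)
  xm <- matv(x)
  y <- array(0, c(2L * H, 2L * Wd, N, Cout))
  k <- 0L
  for (dj in 0:1) for (di in 0:1) {
    yo <- add_bias(xm %*% W[k * C + seq_len(C), , drop = FALSE], b)
    dim(yo) <- c(H, Wd, N, Cout)
    y[seq(1L + di, 2L * H, 2L), seq(1L + dj, 2L * Wd, 2L), , ] <- yo
    k <- k + 1L
  }
  list(y = y, xm = xm, xdim = d)
}

upconv2d_bwd <- function(dy, cache, W) {
  d <- cache$xdim; H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(ncol(W))
  dxm <- matrix(0, nrow(cache$xm), C)
  k <- 0L
  for (dj in 0:1) for (di in 0:1) {
    dyo <- dy[seq(1L + di, 2L * H, 2L), seq(1L + dj, 2L * Wd, 2L), , ,
              drop = FALSE]
    dyo <- matv(dyo)
    rows <- k * C + seq_len(C)
    dW[rows, ] <- crossprod(cache$xm, dyo)
    db <- db + colSums(dyo)
    dxm <- dxm + tcrossprod(dyo, W[rows, , drop = FALSE])
    k <- k + 1L
  }
  dim(dxm) <- d
  list(dx = dxm, dW = dW, db = db)
}

upconv3d_fwd <- function(x, W, b) {
  d <- dim(x); D <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]; C <- d[5]
  Cout <- ncol(W)
  xm <- matv(x)
  y <- array(0, c(2L * D, 2L * H, 2L * Wd, N, Cout))
  k <- 0L
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    yo <- add_bias(xm %*% W[k * C + seq_len(C), , drop = FALSE], b)
    dim(yo) <- c(D, H, Wd, N, Cout)
    y[seq(1L + di, 2L * D, 2L), seq(1L + dj, 2L * H, 2L),
      seq(1L + dk, 2L * Wd, 2L), , ] <- yo
    k <- k + 1L
  }
  list(y = y, xm = xm, xdim = d)
}

upconv3d_bwd <- function(dy, cache, W) {
  d <- cache$xdim; D <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]; C <- d[5]
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(ncol(W))
  dxm <- matrix(0, nrow(cache$xm), C)
  k <- 0L
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    dyo <- dy[seq(1L + di, 2L * D, 2L), seq(1L + dj, 2L * H, 2L),
              seq(1L + dk, 2L * Wd, 2L), , , drop = FALSE]
    dyo <- matv(dyo)
    rows <- k * C + seq_len(C)
    dW[rows, ] <- crossprod(cache$xm, dyo)
    db <- db + colSums(dyo)
    dxm <- dxm + tcrossprod(dyo, W[rows, , drop = FALSE])
    k <- k + 1L
  }
  dim(dxm) <- d
  list(dx = dxm, dW = dW, db = db)
}

# ---- channel concatenation (channel axis is last) --------------------

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[-length(da)], da[length(da)] + db[length(db)]))
}

split_ch <- function(d, c_first) {
  dd <- dim(d); nc <- dd[length(dd)]
  n1 <- prod(dd[-length(dd)]) * c_first
  a <- d[seq_len(n1)]
  b <- d[(n1 + 1L):length(d)]
  dim(a) <- c(dd[-length(dd)], c_first)
  dim(b) <- c(dd[-length(dd)], nc - c_first)
  list(a, b)
}

# ---- softmax cross-entropy -------------------------------------------

# logits: (spatial..., N, K); labels: integer vector over the same
# spatial x batch order, values 1..K. Returns mean loss and dlogits.
softmax_ce <- function(logits, labels) {
  lm <- matv(logits)
  M <- nrow(lm); K <- ncol(lm)
  mx <- lm[cbind(seq_len(M), max.col(lm, ties.method = "first"))]
  e <- exp(lm - mx)
  s <- rowSums(e)
  p <- e / s
  idx <- cbind(seq_len(M), as.integer(labels))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  dl <- dl / M
  dim(dl) <- dim(logits)
  list(loss = loss, dlogits = dl, prob = p)
}

# ---- Adam optimizer --------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.98, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
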