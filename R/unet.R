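#' U-Net configuration
#'
#' Describes a 2D or 3D U-Net encoder-decoder: `n_stages` encoder stages
#' (each two 3-kernel convolutions with padding 1, batch normalization
#' after the first, ReLU activations, then 2x max pooling between
#' stages), a symmetric decoder with skip-connection concatenation and
#' transposed-convolution (kernel 2, stride 2) upsampling, and a final
#' 1x1 convolution to `n_classes` score channels. With defaults the
#' encoder stages generate 32, 64, 128, 256 and 512 features.
#'
#' @param dims Spatial dimensionality, 2 or 3.
#' @param n_stages Number of encoder stages (default 5; the last stage
#'   is the bottleneck).
#' @param base_features Features of the first stage (default 32,
#'   doubling per stage).
#' @param n_classes Output classes (default 5).
#' @param in_channels Input channels (default 1).
#' @param width_multiplier Real in (0, 1] scaling every stage width
#'   (rounded, floor 1 feature) for scaled-down instances.
#' @param batchnorm Use batch normalization (default TRUE).
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(dims = 2L, n_stages = 5L, base_features = 32L,
                        n_classes = 5L, in_channels = 1L,
                        width_multiplier = 1, batchnorm = TRUE) {
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3", call. = FALSE)
  if (width_multiplier <= 0 || width_multiplier > 1)
    stop("width_multiplier must be in (0, 1]", call. = FALSE)
  n_stages <- as.integer(n_stages)
  if (n_stages < 2L) stop("n_stages must be >= 2", call. = FALSE)
  structure(list(dims = dims, n_stages = n_stages,
                 base_features = as.integer(base_features),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 width_multiplier = width_multiplier,
                 batchnorm = isTRUE(batchnorm)),
            class = "unet_config")
}

#' @rdname unet_config
#' @param config A `unet_config`.
#' @return `unet_features()`: integer vector of per-stage feature counts.
#' @export
unet_features <- function(config) {
  pmax(1L, as.integer(round(config$base_features *
                              2^(seq_len(config$n_stages) - 1) *
                              config$width_multiplier)))
}

#' Construct a U-Net with randomly initialized weights
#'
#' Weights use He (fan-in) initialization; batch-norm scales start at 1
#' and running statistics at (0, 1). The same code implements the 2D
#' network (B-scan blocks) and the 3D network (all 2D operations
#' replaced by their 3D analogues).
#'
#' @param config A [unet_config()].
#' @param seed RNG seed for the weight draw.
#' @return An object of class `unet` with elements `config`, `params`
#'   (named list of weight arrays) and `bn` (running statistics).
#' @export
unet <- function(config = unet_config(), seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  set.seed(seed)
  S <- config$n_stages
  Fs <- unet_features(config)
  kk <- if (config$dims == 2L) 9L else 27L   # 3^dims conv taps
  uu <- if (config$dims == 2L) 4L else 8L    # 2^dims upsample taps
  he <- function(fan_in, n_out)
    matrix(stats::rnorm(fan_in * n_out, 0, sqrt(2 / fan_in)), fan_in, n_out)
  P <- list(); B <- list()
  for (s in seq_len(S)) {
    cin <- if (s == 1L) config$in_channels else Fs[s - 1L]
    P[[sprintf("enc%d_conv1_W", s)]] <- he(kk * cin, Fs[s])
    P[[sprintf("enc%d_conv1_b", s)]] <- numeric(Fs[s])
    P[[sprintf("enc%d_bn_gamma", s)]] <- rep(1, Fs[s])
    P[[sprintf("enc%d_bn_beta", s)]] <- numeric(Fs[s])
    P[[sprintf("enc%d_conv2_W", s)]] <- he(kk * Fs[s], Fs[s])
    P[[sprintf("enc%d_conv2_b", s)]] <- numeric(Fs[s])
    B[[sprintf("enc%d_mu", s)]] <- numeric(Fs[s])
    B[[sprintf("enc%d_var", s)]] <- rep(1, Fs[s])
  }
  for (s in seq_len(S - 1L)) {
    P[[sprintf("dec%d_up_W", s)]] <- he(uu * Fs[s + 1L], Fs[s])
    P[[sprintf("dec%d_up_b", s)]] <- numeric(Fs[s])
    P[[sprintf("dec%d_conv1_W", s)]] <- he(kk * 2L * Fs[s], Fs[s])
    P[[sprintf("dec%d_conv1_b", s)]] <- numeric(Fs[s])
    P[[sprintf("dec%d_bn_gamma", s)]] <- rep(1, Fs[s])
    P[[sprintf("dec%d_bn_beta", s)]] <- numeric(Fs[s])
    P[[sprintf("dec%d_conv2_W", s)]] <- he(kk * Fs[s], Fs[s])
    P[[sprintf("dec%d_conv2_b", s)]] <- numeric(Fs[s])
    B[[sprintf("dec%d_mu", s)]] <- numeric(Fs[s])
    B[[sprintf("dec%d_var", s)]] <- rep(1, Fs[s])
  }
  P[["final_W"]] <- he(Fs[1L], config$n_classes)
  P[["final_b"]] <- numeric(config$n_classes)
  structure(list(config = config, params = P, bn = B), class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%dD U-Net: %d stages, features %s, %d classes, %s parameters\n",
              cfg$dims, cfg$n_stages,
              paste(unet_features(cfg), collapse = "/"),
              cfg$n_classes, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param net A [unet()].
#' @return Integer count.
#' @export
n_parameters <- function(net) sum(vapply(net$params, length, numeric(1)))

# normalize user input (spatial dims only, or with batch/channel axes)
as_input_tensor <- function(x, dims) {
  d <- dim(x)
  if (is.null(d)) stop("input must be an array", call. = FALSE)
  if (length(d) == dims) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == dims + 1L) dim(x) <- c(d, 1L)
  else if (length(d) != dims + 2L)
    stop("input has wrong rank for a ", dims, "D network", call. = FALSE)
  x
}

check_divisible <- function(sdim, S) {
  f <- 2L^(S - 1L)
  if (any(sdim %% f != 0L))
    stop("input spatial dims (", paste(sdim, collapse = "x"),
         ") must be divisible by 2^(n_stages-1) = ", f, call. = FALSE)
}

#' Forward pass of a U-Net
#'
#' Computes per-voxel, per-class confidence scores (raw, un-normalized).
#' In evaluation mode (`train = FALSE`) batch normalization uses running
#' statistics and no gradient caches are kept, so repeated calls on the
#' same input are deterministic and memory-light.
#'
#' @param net A [unet()].
#' @param x Input array: spatial dims only (one block), or with trailing
#'   batch and channel axes.
#' @param train Training mode (caches activations, updates batch-norm
#'   running statistics).
#' @return `list(scores, cache, bn)`: `scores` has shape
#'   `(spatial..., N, n_classes)`; `cache` is `NULL` unless `train`.
#' @export
unet_forward <- function(net, x, train = FALSE) {
  cfg <- net$config
  dims <- cfg$dims
  x <- as_input_tensor(x, dims)
  d <- dim(x)
  check_divisible(d[seq_len(dims)], cfg$n_stages)
  if (d[length(d)] != cfg$in_channels)
    stop("input has ", d[length(d)], " channels, expected ",
         cfg$in_channels, call. = FALSE)
  cfwd <- if (dims == 2L) conv2d_fwd else conv3d_fwd
  pfwd <- if (dims == 2L) pool2d_fwd else pool3d_fwd
  ufwd <- if (dims == 2L) upconv2d_fwd else upconv3d_fwd
  P <- net$params; Bn <- net$bn
  S <- cfg$n_stages
  keep <- isTRUE(train)
  cache <- if (keep) list() else NULL
  skips <- vector("list", S - 1L)
  h <- x

  block_fwd <- function(h, pre) {
    c1 <- cfwd(h, P[[paste0(pre, "_conv1_W")]], P[[paste0(pre, "_conv1_b")]],
               keep = keep)
    h <- c1$y
    if (cfg$batchnorm) {
      bn <- bn_fwd(h, P[[paste0(pre, "_bn_gamma")]],
                   P[[paste0(pre, "_bn_beta")]],
                   Bn[[paste0(pre_state(pre), "_mu")]],
                   Bn[[paste0(pre_state(pre), "_var")]], train = keep)
      h <- bn$y
      Bn[[paste0(pre_state(pre), "_mu")]] <<- bn$run_mu
      Bn[[paste0(pre_state(pre), "_var")]] <<- bn$run_var
    } else bn <- NULL
    m1 <- h > 0
    h <- h * m1
    c2 <- cfwd(h, P[[paste0(pre, "_conv2_W")]], P[[paste0(pre, "_conv2_b")]],
               keep = keep)
    h <- c2$y
    m2 <- h > 0
    h <- h * m2
    if (keep)
      cache[[pre]] <<- list(c1 = c1, bn = bn, m1 = m1, c2 = c2, m2 = m2)
    h
  }
  pre_state <- function(pre) pre

  for (s in seq_len(S)) {
    h <- block_fwd(h, sprintf("enc%d", s))
    if (s < S) {
      skips[[s]] <- h
      pl <- pfwd(h)
      if (keep) cache[[sprintf("pool%d", s)]] <- list(masks = pl$masks,
                                                      xdim = pl$xdim)
      h <- pl$y
    }
  }
  for (s in rev(seq_len(S - 1L))) {
    up <- ufwd(h, P[[sprintf("dec%d_up_W", s)]], P[[sprintf("dec%d_up_b", s)]])
    if (keep) cache[[sprintf("up%d", s)]] <- list(xm = up$xm, xdim = up$xdim)
    h <- concat_ch(up$y, skips[[s]])
    h <- block_fwd(h, sprintf("dec%d", s))
  }
  hm <- matv(h)
  scores <- add_bias(hm %*% P[["final_W"]], P[["final_b"]])
  dd <- dim(h)
  dim(scores) <- c(dd[-length(dd)], cfg$n_classes)
  if (keep) cache[["final_h"]] <- hm
  list(scores = scores, cache = cache, bn = Bn)
}

# Backward pass: returns gradients for every parameter.
unet_backward <- function(net, cache, dscores) {
  cfg <- net$config
  dims <- cfg$dims
  cbwd <- if (dims == 2L) conv2d_bwd else conv3d_bwd
  pbwd <- if (dims == 2L) pool2d_bwd else pool3d_bwd
  ubwd <- if (dims == 2L) upconv2d_bwd else upconv3d_bwd
  P <- net$params
  S <- cfg$n_stages
  Fs <- unet_features(cfg)
  G <- list()

  dm <- matv(dscores)
  G[["final_W"]] <- crossprod(cache[["final_h"]], dm)
  G[["final_b"]] <- colSums(dm)
  dh <- tcrossprod(dm, P[["final_W"]])
  dd <- dim(dscores)
  dim(dh) <- c(dd[-length(dd)], nrow(P[["final_W"]]))

  block_bwd <- function(dh, pre) {
    cc <- cache[[pre]]
    dh <- dh * cc$m2
    b2 <- cbwd(dh, cc$c2, P[[paste0(pre, "_conv2_W")]])
    G[[paste0(pre, "_conv2_W")]] <<- b2$dW
    G[[paste0(pre, "_conv2_b")]] <<- b2$db
    dh <- b2$dx * cc$m1
    if (cfg$batchnorm) {
      bb <- bn_bwd(dh, cc$bn, P[[paste0(pre, "_bn_gamma")]])
      G[[paste0(pre, "_bn_gamma")]] <<- bb$dgamma
      G[[paste0(pre, "_bn_beta")]] <<- bb$dbeta
      dh <- bb$dx
    }
    b1 <- cbwd(dh, cc$c1, P[[paste0(pre, "_conv1_W")]])
    G[[paste0(pre, "_conv1_W")]] <<- b1$dW
    G[[paste0(pre, "_conv1_b")]] <<- b1$db
    b1$dx
  }

  dskips <- vector("list", S - 1L)
  for (s in seq_len(S - 1L)) {
    dcat <- block_bwd(dh, sprintf("dec%d", s))
    parts <- split_ch(dcat, Fs[s])
    dskips[[s]] <- parts[[2]]
    bu <- ubwd(parts[[1]], cache[[sprintf("up%d", s)]],
               P[[sprintf("dec%d_up_W", s)]])
    G[[sprintf("dec%d_up_W", s)]] <- bu$dW
    G[[sprintf("dec%d_up_b", s)]] <- bu$db
    dh <- bu$dx
  }
  for (s in rev(seq_len(S))) {
    if (s < S) dh <- pbwd(dh, cache[[sprintf("pool%d", s)]]) + dskips[[s]]
    dh <- block_bwd(dh, sprintf("enc%d", s))
  }
  G
}

#' Class labels from a confidence map
#'
#' Per-voxel argmax over the class axis, ties broken toward the lowest
#' class index; returns labels 1..n_classes.
#'
#' @param scores Array whose FIRST axis is the class axis
#'   (`(class, spatial...)`), as returned by [predict_block()].
#' @return Integer array of labels with the spatial shape of `scores`.
#' @export
classify_confidence <- function(scores) {
  d <- dim(scores)
  K <- d[1]
  m <- matrix(scores, nrow = K)
  lab <- max.col(t(m), ties.method = "first")
  lab <- as.integer(lab)
  if (length(d) > 1L) dim(lab) <- d[-1]
  lab
}

#' Per-class confidence scores for one block
#'
#' Runs the network in evaluation mode on a single intensity block and
#' returns the confidence map with the class axis first.
#'
#' @param net A [unet()].
#' @param block Numeric array with the block's spatial shape.
#' @return Array `(n_classes, spatial...)` of raw confidence scores.
#' @export
predict_block <- function(net, block) {
  dims <- net$config$dims
  if (length(dim(block)) != dims)
    stop("block must have exactly ", dims, " spatial dims", call. = FALSE)
  sc <- unet_forward(net, block, train = FALSE)$scores
  d <- dim(sc)                        # (spatial..., N = 1, K)
  dim(sc) <- c(d[seq_len(dims)], d[length(d)])
  aperm(sc, c(dims + 1L, seq_len(dims)))
}

softmax_scores <- function(scores_mat) {
  mx <- scores_mat[cbind(seq_len(nrow(scores_mat)),
                         max.col(scores_mat, ties.method = "first"))]
  e <- exp(scores_mat - mx)
  e / rowSums(e)
}
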