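# Stateless forward operations on single feature maps.
#
# A feature map is a numeric (H, W, C) array (a matrix is promoted to
# C = 1). These functions expose the building blocks of the segmentation
# network as plain array transforms with explicit weights, so each block
# can be exercised and verified in isolation; the trainable network in
# build_network() routes through the same C++ kernels.

as_feature_map <- function(x, arg = "x") {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort(sprintf("`%s` must be an (H, W, C) array", arg))
  }
  if (any(dim(x) < 1L)) {
    abort(sprintf("`%s` has a zero-sized dimension", arg))
  }
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values", arg))
  }
  x
}

fm4 <- function(x) array(x, c(dim(x), 1L))
fm3 <- function(x) array(x, dim(x)[1:3])

#' Multi-scale convolution stem
#'
#' Runs several same-padding stride-1 convolutions with different odd kernel
#' sizes over one image in parallel and concatenates their outputs along the
#' channel axis, in the order the branches are given. This widens the
#' receptive-field mix available to the first dense block: small kernels
#' favour tiny lesions, large ones suppress isolated false positives.
#'
#' @param image numeric `(H, W, C)` array (a matrix is treated as one
#'   channel).
#' @param branch_weights list of convolution kernels, each a
#'   `(k, k, C, filters)` array with odd `k`.
#' @param branch_biases optional list of per-branch bias vectors (length
#'   `filters`); zeros when omitted.
#' @return `(H, W, sum(filters))` array: the channel-wise concatenation of
#'   the branch outputs.
#' @examples
#' img <- array(rnorm(64), c(8, 8, 1))
#' w <- lapply(c(3, 5), function(k) array(0, c(k, k, 1, 2)))
#' dim(multiscale_forward(img, w))  # 8 8 4
#' @export
multiscale_forward <- function(image, branch_weights, branch_biases = NULL) {
  image <- as_feature_map(image, "image")
  stopifnot(is.list(branch_weights), length(branch_weights) >= 1)
  outs <- vector("list", length(branch_weights))
  for (i in seq_along(branch_weights)) {
    w <- branch_weights[[i]]
    if (length(dim(w)) != 4L) abort("branch weights must be (k, k, C, f)")
    k <- dim(w)[1]
    if (k %% 2L == 0L) abort("kernel sizes must be odd")
    if (dim(w)[3] != dim(image)[3]) {
      abort("branch input channels do not match the image")
    }
    b <- if (is.null(branch_biases)) numeric(dim(w)[4]) else
      branch_biases[[i]]
    outs[[i]] <- .conv2d_fw(fm4(image), w, b)
  }
  y <- do.call(function(...) abind3(...), outs)
  fm3(y)
}

# channel-axis concatenation of 4-d arrays
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(z) dim(z)[3], 0)
  y <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    y[, , at + seq_len(dim(x)[3]), ] <- x
    at <- at + dim(x)[3]
  }
  y
}

#' Dense block forward pass
#'
#' Iteratively applies composite layers (batch normalization, ELU, 3x3
#' convolution) where each layer consumes the channel concatenation of the
#' block input and every preceding layer's output, and contributes `k` new
#' feature maps (`k` = growth rate). With `include_input` the block output
#' is the full concatenation (input channels + L*k, encoder convention);
#' otherwise only the L*k new maps are returned (decoder convention).
#'
#' @param U `(H, W, C0)` feature map.
#' @param layers list of layer specs, each a list with `weights`
#'   (`(3, 3, C_in, k)` array) and optional `bias`, `bn_gamma`, `bn_beta`,
#'   `bn_mean`, `bn_var` (inference-mode normalization; identity when
#'   omitted).
#' @param include_input logical; include the block input in the output
#'   concatenation.
#' @return feature map with `C0 + L*k` (or `L*k`) channels; spatial size is
#'   preserved.
#' @export
dense_block_forward <- function(U, layers, include_input = TRUE) {
  U <- as_feature_map(U, "U")
  feats <- list(fm4(U))
  newf <- list()
  for (spec in layers) {
    x <- if (length(feats) == 1L) feats[[1]] else do.call(abind3, feats)
    cin <- dim(x)[3]
    w <- spec$weights
    if (dim(w)[3] != cin) {
      abort(sprintf(
        "layer expects %d input channels but the concatenation has %d",
        dim(w)[3], cin))
    }
    h <- bn_inference(x, spec, cin)
    h <- elu_num(h)
    b <- spec$bias %||% numeric(dim(w)[4])
    h <- .conv2d_fw(h, w, b)
    feats <- c(feats, list(h))
    newf <- c(newf, list(h))
  }
  if (length(newf) == 0L) return(U)
  out <- if (include_input) do.call(abind3, feats) else
    if (length(newf) == 1L) newf[[1]] else do.call(abind3, newf)
  fm3(out)
}

bn_inference <- function(x, spec, C, eps = 1e-5) {
  gamma <- spec$bn_gamma %||% rep(1, C)
  beta <- spec$bn_beta %||% numeric(C)
  mu <- spec$bn_mean %||% numeric(C)
  v <- spec$bn_var %||% rep(1, C)
  d <- dim(x)
  hw <- d[1] * d[2]
  ch <- rep(seq_len(C), d[4])
  xm <- matrix(x, hw, C * d[4])
  xm <- (xm - rep(mu[ch], each = hw)) /
    rep(sqrt(v[ch] + eps), each = hw) * rep(gamma[ch], each = hw) +
    rep(beta[ch], each = hw)
  array(xm, d)
}

elu_num <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}

sigmoid_num <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spatial squeeze-and-excitation (sSE)
#'
#' Projects the channels at every position through a 1x1 convolution with
#' weights `W_s`, squashes the projection through a sigmoid into a `[0, 1]`
#' spatial gate, and rescales every channel of `U` by that gate. Positions
#' the gate considers irrelevant are suppressed across all channels.
#'
#' @param U `(H, W, C)` feature map.
#' @param W_s length-`C` numeric vector (or `(1, 1, C, 1)` array): the 1x1
#'   projection kernel.
#' @param bias scalar projection bias.
#' @return recalibrated feature map, same shape as `U`.
#' @export
sse_forward <- function(U, W_s, bias = 0) {
  U <- as_feature_map(U, "U")
  W_s <- as.numeric(W_s)
  C <- dim(U)[3]
  if (length(W_s) != C) abort("`W_s` must have one weight per channel")
  q <- apply(U, c(1, 2), function(v) sum(v * W_s)) + bias
  gate <- sigmoid_num(q)
  U * array(rep(gate, C), dim(U))
}

#' Channel squeeze-and-excitation (cSE)
#'
#' Global-average-pools `U` into a channel descriptor `z`, passes it through
#' a two-layer bottleneck (`W_2`: C -> C/r, ReLU, `W_1`: C/r -> C), squashes
#' with a sigmoid into per-channel gates in `[0, 1]`, and rescales each
#' channel of `U` by its gate.
#'
#' @param U `(H, W, C)` feature map.
#' @param W_1 `(C, C/r)` matrix (excitation weights, hidden -> channels).
#' @param W_2 `(C/r, C)` matrix (squeeze weights, channels -> hidden).
#' @param b1,b2 optional bias vectors for the two layers.
#' @return recalibrated feature map, same shape as `U`.
#' @export
cse_forward <- function(U, W_1, W_2, b1 = NULL, b2 = NULL) {
  U <- as_feature_map(U, "U")
  C <- dim(U)[3]
  W_1 <- as.matrix(W_1); W_2 <- as.matrix(W_2)
  h <- nrow(W_2)
  if (h < 1L) abort("hidden size must be at least 1")
  if (ncol(W_2) != C || nrow(W_1) != C || ncol(W_1) != h) {
    abort("`W_1`/`W_2` shapes are inconsistent with C")
  }
  z <- apply(U, 3, mean)
  hid <- pmax(as.numeric(W_2 %*% z) + (b2 %||% numeric(h)), 0)
  zhat <- as.numeric(W_1 %*% hid) + (b1 %||% numeric(C))
  gate <- sigmoid_num(zhat)
  sweep(U, 3, gate, `*`)
}

#' Concurrent spatial and channel squeeze-and-excitation (scSE)
#'
#' Elementwise sum of the sSE and cSE recalibrations of `U`. With all gate
#' logits at zero both branches gate at 0.5 and the module is the identity.
#'
#' @param U `(H, W, C)` feature map.
#' @param weights list with `W_s`, `s_bias`, `W_1`, `W_2`, `b1`, `b2` (see
#'   [sse_forward()] and [cse_forward()]).
#' @return recalibrated feature map, same shape as `U`.
#' @export
scse_forward <- function(U, weights) {
  sse_forward(U, weights$W_s, weights$s_bias %||% 0) +
    cse_forward(U, weights$W_1, weights$W_2, weights$b1, weights$b2)
}

#' Transition down (spatial halving)
#'
#' The encoder join between dense blocks: batch normalization, ELU, a
#' depth-preserving 1x1 convolution, then 2x2 stride-2 max pooling (floor
#' semantics on odd sizes). When `weights` is omitted the normalization and
#' convolution default to the identity, leaving the pooling geometry.
#'
#' @param U `(H, W, C)` feature map with `H, W >= 2`.
#' @param weights optional list with `w` (`(1, 1, C, C)` kernel), `bias`,
#'   and inference-mode `bn_gamma`/`bn_beta`/`bn_mean`/`bn_var`.
#' @param identity_path logical; skip BN/ELU/conv entirely (pure pooling).
#' @return `(floor(H/2), floor(W/2), C)` feature map.
#' @export
transition_down_forward <- function(U, weights = NULL,
                                    identity_path = is.null(weights)) {
  U <- as_feature_map(U, "U")
  d <- dim(U)
  if (d[1] < 2L || d[2] < 2L) abort("spatial size must be at least 2x2")
  x <- fm4(U)
  if (!identity_path) {
    x <- bn_inference(x, weights, d[3])
    x <- elu_num(x)
    w <- weights$w %||% {
      w0 <- array(0, c(1, 1, d[3], d[3]))
      for (c in seq_len(d[3])) w0[1, 1, c, c] <- 1
      w0
    }
    x <- .conv2d_fw(x, w, weights$bias %||% numeric(d[3]))
  }
  fm3(.maxpool2_fw(x)$y)
}

#' Transition up (spatial doubling)
#'
#' The decoder join: a 3x3 stride-2 transposed convolution that exactly
#' doubles the spatial size and maps to `out_channels` feature maps.
#'
#' @param U `(H, W, C)` feature map.
#' @param weights `(3, 3, C, out_channels)` kernel.
#' @param bias optional length-`out_channels` bias.
#' @return `(2H, 2W, out_channels)` feature map.
#' @export
transition_up_forward <- function(U, weights, bias = NULL) {
  U <- as_feature_map(U, "U")
  if (length(dim(weights)) != 4L || dim(weights)[3] != dim(U)[3]) {
    abort("`weights` must be a (3, 3, C, out_channels) array")
  }
  out_channels <- dim(weights)[4]
  if (out_channels < 1L) abort("`out_channels` must be at least 1")
  fm3(.convt2d_fw(fm4(U), weights, bias %||% numeric(out_channels)))
}
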