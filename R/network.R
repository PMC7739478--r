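# Network assembly: configuration, parameter initialization, forward graph.

#' Network configuration
#'
#' Collects every architecture hyperparameter of the segmentation network.
#' `layers_per_block` gives the layer counts of the encoder dense blocks
#' followed by the bottleneck; the decoder mirrors the encoder counts in
#' reverse. The stem is either a single 3x3 convolution with
#' `initial_channels` filters or, with `multiscale = TRUE`, parallel
#' `ms_kernels` convolutions with `ms_filters_per_branch` filters each
#' (default `initial_channels / length(ms_kernels)`).
#'
#' @param growth_rate feature maps added by each dense-block layer (k).
#' @param layers_per_block integer vector: encoder dense blocks then
#'   bottleneck, e.g. `c(4, 5, 7, 10, 12, 15)`.
#' @param initial_channels stem output channels.
#' @param in_channels input image channels (3 replicates grayscale to the
#'   conventional RGB radiograph input; 1 keeps it single-channel).
#' @param multiscale use the parallel multi-kernel stem.
#' @param ms_kernels odd kernel sizes of the stem branches.
#' @param ms_filters_per_branch filters per stem branch.
#' @param dropout dropout probability in composite layers.
#' @param num_classes output classes (background, pneumothorax).
#' @param scse one of `"none"`, `"per_block"` (one recalibration of every
#'   dense-block output) or `"per_layer"` (recalibrate each layer's new
#'   feature maps).
#' @param scse_reduction channel-bottleneck divisor r of the cSE branch.
#' @return a `ptx_network_config` object (a validated list).
#' @export
network_config <- function(growth_rate = 12,
                           layers_per_block = c(4, 5, 7, 10, 12, 15),
                           initial_channels = 48,
                           in_channels = 3,
                           multiscale = TRUE,
                           ms_kernels = c(3, 5, 7),
                           ms_filters_per_branch = NULL,
                           dropout = 0.2,
                           num_classes = 2,
                           scse = c("per_block", "per_layer", "none"),
                           scse_reduction = 2) {
  scse <- match.arg(scse)
  if (growth_rate < 1) abort("`growth_rate` must be at least 1")
  if (length(layers_per_block) < 2) {
    abort("`layers_per_block` needs at least one encoder block + bottleneck")
  }
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1)")
  if (num_classes < 2) abort("`num_classes` must be at least 2")
  if (any(ms_kernels %% 2 == 0) || any(ms_kernels < 3)) {
    abort("`ms_kernels` must be odd and >= 3")
  }
  if (is.null(ms_filters_per_branch)) {
    ms_filters_per_branch <- initial_channels %/% length(ms_kernels)
  }
  if (multiscale) {
    initial_channels <- ms_filters_per_branch * length(ms_kernels)
  }
  structure(list(
    growth_rate = as.integer(growth_rate),
    down_blocks = as.integer(head(layers_per_block, -1)),
    bottleneck = as.integer(layers_per_block[length(layers_per_block)]),
    initial_channels = as.integer(initial_channels),
    in_channels = as.integer(in_channels),
    multiscale = isTRUE(multiscale),
    ms_kernels = as.integer(ms_kernels),
    ms_filters_per_branch = as.integer(ms_filters_per_branch),
    dropout = dropout,
    num_classes = as.integer(num_classes),
    scse = scse,
    scse_reduction = as.integer(scse_reduction)
  ), class = "ptx_network_config")
}

#' Reference configurations
#'
#' `reference_network_config()` is the full multi-scale scSE network: growth
#' rate 12, encoder blocks (4, 5, 7, 10, 12) with a 15-layer bottleneck,
#' a 48-channel three-branch stem and per-block scSE. `baseline_config()`
#' is the plain dense backbone: same layout, single 3x3 stem, no scSE.
#' Both take 3-channel input.
#'
#' @return a [network_config()] object.
#' @export
reference_network_config <- function() network_config()

#' @rdname reference_network_config
#' @export
baseline_config <- function() {
  network_config(multiscale = FALSE, scse = "none")
}

#' Reduced configuration for desk-scale training
#'
#' A small network (growth rate 4, two encoder blocks plus bottleneck of
#' two layers each, 24-channel stem, single-channel input) whose two
#' pooling stages accept any input with sides divisible by 4.
#'
#' @param scse scSE placement, as in [network_config()].
#' @return a [network_config()] object.
#' @export
reduced_config <- function(scse = "per_block") {
  network_config(growth_rate = 4, layers_per_block = c(2, 2, 2),
                 initial_channels = 24, in_channels = 1,
                 ms_filters_per_branch = 8, scse = scse)
}

#' @export
print.ptx_network_config <- function(x, ...) {
  cat("<ptx_network_config>\n")
  cat("  growth rate k:      ", x$growth_rate, "\n")
  cat("  encoder blocks:     ", paste(x$down_blocks, collapse = ", "),
      " | bottleneck ", x$bottleneck, "\n", sep = "")
  cat("  stem:               ",
      if (x$multiscale) {
        sprintf("multi-scale [%s] x %d filters",
                paste(x$ms_kernels, collapse = "/"),
                x$ms_filters_per_branch)
      } else sprintf("3x3 conv, %d filters", x$initial_channels), "\n")
  cat("  scSE:               ", x$scse, "\n")
  cat("  input channels:     ", x$in_channels, "\n")
  invisible(x)
}

he_uniform <- function(dim, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dim), -lim, lim), dim)
}

#' Build the segmentation network
#'
#' Allocates and initializes all trainable parameters (HeUniform for
#' convolution and fully connected weights, zeros for biases, unit/zero for
#' batch-norm scale/shift) and returns a model object whose forward pass
#' maps an `(H, W, in_channels, N)` batch to per-pixel class probabilities.
#' `H` and `W` must be divisible by `2^length(down_blocks)`.
#'
#' @param config a [network_config()].
#' @param seed optional integer seed for reproducible initialization.
#' @return a `ptx_network` object.
#' @export
build_network <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ptx_network_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  params <- new.env(parent = emptyenv())
  order <- character(0)
  put <- function(name, value) {
    params[[name]] <- value
    order <<- c(order, name)
  }
  add_conv <- function(name, k, cin, cout) {
    put(paste0(name, ".w"), he_uniform(c(k, k, cin, cout), k * k * cin))
    put(paste0(name, ".b"), numeric(cout))
  }
  add_bn <- function(name, c) {
    put(paste0(name, ".gamma"), rep(1, c))
    put(paste0(name, ".beta"), numeric(c))
  }
  add_dense <- function(name, cin, cout) {
    put(paste0(name, ".w"), he_uniform(c(cin, cout), cin))
    put(paste0(name, ".b"), numeric(cout))
  }
  add_scse <- function(name, c) {
    h <- max(1L, c %/% config$scse_reduction)
    add_conv(paste0(name, ".sse"), 1, c, 1)
    add_dense(paste0(name, ".cse.fc1"), c, h)  # squeeze C -> h
    add_dense(paste0(name, ".cse.fc2"), h, c)  # excite h -> C
  }
  add_layer <- function(name, cin, k) {
    add_bn(paste0(name, ".bn"), cin)
    add_conv(paste0(name, ".conv"), 3, cin, k)
  }
  k <- config$growth_rate
  if (config$multiscale) {
    for (i in seq_along(config$ms_kernels)) {
      add_conv(sprintf("stem.b%d", i), config$ms_kernels[i],
               config$in_channels, config$ms_filters_per_branch)
    }
  } else {
    add_conv("stem", 3, config$in_channels, config$initial_channels)
  }
  cc <- config$initial_channels
  skips <- integer(0)
  dense_block_params <- function(prefix, cin, L) {
    for (l in seq_len(L)) {
      add_layer(sprintf("%s.l%d", prefix, l), cin, k)
      if (config$scse == "per_layer") {
        add_scse(sprintf("%s.l%d.scse", prefix, l), k)
      }
      cin <- cin + k
    }
    cin
  }
  for (i in seq_along(config$down_blocks)) {
    L <- config$down_blocks[i]
    cc <- dense_block_params(sprintf("down%d", i), cc, L)
    if (config$scse == "per_block") add_scse(sprintf("down%d.scse", i), cc)
    skips <- c(skips, cc)
    add_bn(sprintf("td%d.bn", i), cc)
    add_conv(sprintf("td%d.conv", i), 1, cc, cc)
  }
  dense_block_params("bottleneck", cc, config$bottleneck)
  new <- config$bottleneck * k
  if (config$scse == "per_block") add_scse("bottleneck.scse", new)
  up_blocks <- rev(config$down_blocks)
  for (i in seq_along(up_blocks)) {
    add_conv(sprintf("tu%d", i), 3, new, new)
    cin <- new + rev(skips)[i]
    dense_block_params(sprintf("up%d", i), cin, up_blocks[i])
    new <- up_blocks[i] * k
    if (config$scse == "per_block") add_scse(sprintf("up%d.scse", i), new)
    if (i == length(up_blocks)) final_channels <- cin + new
  }
  add_conv("head", 1, final_channels, config$num_classes)
  structure(list(config = config, params = params, param_names = order,
                 state = new.env(parent = emptyenv())),
            class = "ptx_network")
}

#' Count trainable parameters
#'
#' Sums the lengths of every trainable weight, bias and batch-norm
#' scale/shift array of the model. Batch-norm running moments are state,
#' not parameters, and are excluded.
#'
#' @param model a `ptx_network`.
#' @return integer scalar.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ptx_network"))
  sum(vapply(model$param_names,
             function(nm) length(model$params[[nm]]), 0))
}

#' @export
print.ptx_network <- function(x, ...) {
  cat("<ptx_network> ")
  print(x$config)
  cat("  trainable parameters:", format(count_parameters(x), big.mark = ","),
      "\n")
  invisible(x)
}

# ---- forward graph ---------------------------------------------------------

scse_graph <- function(tape, model, prefix, x) {
  p <- function(nm) op_param(tape, model$params, paste0(prefix, ".", nm))
  # spatial branch: 1x1 conv to a single map, sigmoid gate
  q <- op_conv2d(tape, x, p("sse.w"), p("sse.b"))
  sgate <- op_sigmoid(tape, q)
  s <- op_scale_spatial(tape, x, sgate)
  # channel branch: GAP -> squeeze -> ReLU -> excite -> sigmoid gate
  z <- op_gap(tape, x)
  h <- op_relu(tape, op_dense(tape, z, p("cse.fc1.w"), p("cse.fc1.b")))
  zhat <- op_dense(tape, h, p("cse.fc2.w"), p("cse.fc2.b"))
  cgate <- op_sigmoid(tape, zhat)
  cx <- op_scale_channel(tape, x, cgate)
  op_add(tape, s, cx)
}

dense_block_graph <- function(tape, model, prefix, x, L, include_input) {
  cfg <- model$config
  p <- function(nm) op_param(tape, model$params, paste0(prefix, ".", nm))
  feats <- list(x)
  newf <- list()
  for (l in seq_len(L)) {
    inp <- if (length(feats) == 1L) feats[[1]] else op_concat(tape, feats)
    nm <- sprintf("l%d", l)
    h <- op_batchnorm(tape, inp, p(paste0(nm, ".bn.gamma")),
                      p(paste0(nm, ".bn.beta")), model$state,
                      paste0(prefix, ".", nm, ".bn"))
    h <- op_elu(tape, h)
    h <- op_conv2d(tape, h, p(paste0(nm, ".conv.w")), p(paste0(nm, ".conv.b")))
    h <- op_dropout(tape, h, cfg$dropout)
    if (cfg$scse == "per_layer") {
      h <- scse_graph(tape, model, paste0(prefix, ".", nm, ".scse"), h)
    }
    feats <- c(feats, list(h))
    newf <- c(newf, list(h))
  }
  if (L == 0L) return(x)
  full <- op_concat(tape, feats)
  new <- if (length(newf) == 1L) newf[[1]] else op_concat(tape, newf)
  list(full = full, new = new)
}

# builds the whole graph; returns the logits node
network_graph <- function(model, tape, xnode) {
  cfg <- model$config
  p <- function(nm) op_param(tape, model$params, nm)
  d <- dim(xnode$value)
  depth <- length(cfg$down_blocks)
  if (d[1] %% 2^depth != 0 || d[2] %% 2^depth != 0) {
    abort(sprintf("input size %dx%d is not divisible by 2^%d",
                  d[1], d[2], depth))
  }
  if (d[3] != cfg$in_channels) {
    abort(sprintf("input has %d channels; the network expects %d",
                  d[3], cfg$in_channels))
  }
  if (cfg$multiscale) {
    branches <- lapply(seq_along(cfg$ms_kernels), function(i) {
      op_conv2d(tape, xnode, p(sprintf("stem.b%d.w", i)),
                p(sprintf("stem.b%d.b", i)))
    })
    cur <- op_concat(tape, branches)
  } else {
    cur <- op_conv2d(tape, xnode, p("stem.w"), p("stem.b"))
  }
  skips <- list()
  for (i in seq_along(cfg$down_blocks)) {
    blk <- dense_block_graph(tape, model, sprintf("down%d", i), cur,
                             cfg$down_blocks[i], TRUE)
    cur <- blk$full
    if (cfg$scse == "per_block") {
      cur <- scse_graph(tape, model, sprintf("down%d.scse", i), cur)
    }
    skips[[i]] <- cur
    # transition down
    h <- op_batchnorm(tape, cur, p(sprintf("td%d.bn.gamma", i)),
                      p(sprintf("td%d.bn.beta", i)), model$state,
                      sprintf("td%d.bn", i))
    h <- op_elu(tape, h)
    h <- op_conv2d(tape, h, p(sprintf("td%d.conv.w", i)),
                   p(sprintf("td%d.conv.b", i)))
    h <- op_dropout(tape, h, cfg$dropout)
    cur <- op_maxpool2(tape, h)
  }
  blk <- dense_block_graph(tape, model, "bottleneck", cur, cfg$bottleneck,
                           TRUE)
  new <- blk$new
  if (cfg$scse == "per_block") {
    new <- scse_graph(tape, model, "bottleneck.scse", new)
  }
  up_blocks <- rev(cfg$down_blocks)
  for (i in seq_along(up_blocks)) {
    up <- op_convt2d(tape, new, p(sprintf("tu%d.w", i)),
                     p(sprintf("tu%d.b", i)))
    cur <- op_concat(tape, list(up, skips[[depth - i + 1L]]))
    blk <- dense_block_graph(tape, model, sprintf("up%d", i), cur,
                             up_blocks[i], TRUE)
    new <- blk$new
    if (cfg$scse == "per_block") {
      new <- scse_graph(tape, model, sprintf("up%d.scse", i), new)
    }
    if (i == length(up_blocks)) {
      cur <- op_concat(tape, list(cur, new))
    }
  }
  op_conv2d(tape, cur, p("head.w"), p("head.b"))
}

softmax_channels <- function(logits) {
  d <- dim(logits)
  m <- matrix(aperm(logits, c(1, 2, 4, 3)), prod(d[c(1, 2, 4)]), d[3])
  m <- exp(m - apply(m, 1, max))
  m <- m / rowSums(m)
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

#' Run the network forward
#'
#' @param model a `ptx_network`.
#' @param x input batch `(H, W, C, N)` array, a single `(H, W, C)` image or
#'   an `(H, W)` matrix.
#' @param training logical; enables dropout, batch statistics and
#'   running-moment updates.
#' @return per-pixel class probabilities, `(H, W, num_classes, N)` (the
#'   trailing batch axis is dropped for single-image input); probabilities
#'   at each pixel sum to 1.
#' @export
network_forward <- function(model, x, training = FALSE) {
  single <- length(dim(x)) < 4L
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  tape <- new_tape(training = training)
  logits <- network_graph(model, tape, op_input(tape, x))
  probs <- softmax_channels(logits$value)
  if (single) probs <- array(probs, dim(probs)[1:3])
  probs
}
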