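# Reverse-mode autodiff on a linear tape.
#
# Every operation appends a node to the tape; a node holds its value, the
# accumulated gradient, its parent nodes and a backward closure that pushes
# the node's gradient into the parents. Calling tape_backward() seeds the
# final node with gradient 1 and replays the tape in reverse. Tensors are
# plain R arrays laid out (H, W, C, N); vectors flowing through the channel
# excitation are (C, N) matrices.

new_tape <- function(training = FALSE) {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape$training <- training
  tape
}

node_new <- function(tape, value, parents = list(), backward = NULL,
                     param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$param <- param
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

acc_grad <- function(nd, g) {
  if (is.null(nd$grad)) {
    nd$grad <- g
  } else {
    nd$grad <- nd$grad + g
  }
  invisible(nd)
}

#' @noRd
tape_backward <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(tape)
}

# collect gradients of parameter leaves, keyed by parameter name
tape_param_grads <- function(tape) {
  out <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$param) && !is.null(nd$grad)) {
      if (is.null(out[[nd$param]])) {
        out[[nd$param]] <- nd$grad
      } else {
        out[[nd$param]] <- out[[nd$param]] + nd$grad
      }
    }
  }
  out
}

op_input <- function(tape, x) node_new(tape, x)

op_param <- function(tape, params, name) {
  node_new(tape, params[[name]], param = name)
}

op_conv2d <- function(tape, x, w, b) {
  y <- .conv2d_fw(x$value, w$value, b$value)
  node_new(tape, y, parents = list(x, w, b), backward = function(nd) {
    g <- .conv2d_bw(x$value, w$value, nd$grad)
    acc_grad(x, g$dx); acc_grad(w, g$dw); acc_grad(b, g$db)
  })
}

op_convt2d <- function(tape, x, w, b) {
  y <- .convt2d_fw(x$value, w$value, b$value)
  node_new(tape, y, parents = list(x, w, b), backward = function(nd) {
    g <- .convt2d_bw(x$value, w$value, nd$grad)
    acc_grad(x, g$dx); acc_grad(w, g$dw); acc_grad(b, g$db)
  })
}

op_maxpool2 <- function(tape, x) {
  r <- .maxpool2_fw(x$value)
  xd <- dim(x$value)
  node_new(tape, r$y, parents = list(x), backward = function(nd) {
    acc_grad(x, .maxpool2_bw(nd$grad, r$idx, xd))
  })
}

# batch normalization over (H, W, N) per channel; `state` is an environment
# holding running moments under `key` (updated only in training mode)
op_batchnorm <- function(tape, x, gamma, beta, state, key,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- hw * N
  xm <- matrix(x$value, hw, C * N)
  ch <- rep(seq_len(C), N)  # channel of each column
  csum <- function(mat) as.numeric(rowsum(colSums(mat), ch, reorder = FALSE))
  if (tape$training) {
    mu <- csum(xm) / m
    xc <- xm - rep(mu[ch], each = hw)
    v <- csum(xc * xc) / m
    rk <- paste0(key, ".mean"); vk <- paste0(key, ".var")
    if (is.null(state[[rk]])) {
      state[[rk]] <- mu
      state[[vk]] <- v
    } else {
      state[[rk]] <- (1 - momentum) * state[[rk]] + momentum * mu
      state[[vk]] <- (1 - momentum) * state[[vk]] + momentum * v
    }
  } else {
    mu <- state[[paste0(key, ".mean")]]
    v <- state[[paste0(key, ".var")]]
    if (is.null(mu)) { mu <- numeric(C); v <- rep(1, C) }
    xc <- xm - rep(mu[ch], each = hw)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd[ch], each = hw)
  ym <- xhat * rep(gamma$value[ch], each = hw) +
    rep(beta$value[ch], each = hw)
  y <- array(ym, d)
  training <- tape$training
  node_new(tape, y, parents = list(x, gamma, beta), backward = function(nd) {
    dym <- matrix(nd$grad, hw, C * N)
    dgamma <- csum(dym * xhat)
    dbeta <- csum(dym)
    dxhat <- dym * rep(gamma$value[ch], each = hw)
    if (training) {
      s1 <- csum(dxhat)
      s2 <- csum(dxhat * xhat)
      dxm <- (dxhat - rep(s1[ch], each = hw) / m -
                xhat * rep(s2[ch], each = hw) / m) *
        rep(istd[ch], each = hw)
    } else {
      dxm <- dxhat * rep(istd[ch], each = hw)
    }
    acc_grad(x, array(dxm, d))
    acc_grad(gamma, dgamma)
    acc_grad(beta, dbeta)
  })
}

op_elu <- function(tape, x) {
  v <- x$value
  neg <- v < 0
  y <- v
  y[neg] <- exp(v[neg]) - 1
  node_new(tape, y, parents = list(x), backward = function(nd) {
    d <- nd$grad
    d[neg] <- d[neg] * (y[neg] + 1)
    acc_grad(x, d)
  })
}

op_relu <- function(tape, x) {
  y <- pmax(x$value, 0)
  if (!is.null(dim(x$value))) dim(y) <- dim(x$value)
  node_new(tape, y, parents = list(x), backward = function(nd) {
    acc_grad(x, nd$grad * (x$value > 0))
  })
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  node_new(tape, y, parents = list(x), backward = function(nd) {
    acc_grad(x, nd$grad * y * (1 - y))
  })
}

# inverted dropout; identity when not training or p = 0
op_dropout <- function(tape, x, p) {
  if (!tape$training || p <= 0) return(x)
  keep <- array(runif(length(x$value)) >= p, dim(x$value))
  scale <- 1 / (1 - p)
  node_new(tape, x$value * keep * scale, parents = list(x),
           backward = function(nd) acc_grad(x, nd$grad * keep * scale))
}

op_concat <- function(tape, xs) {
  dims <- lapply(xs, function(z) dim(z$value))
  cs <- vapply(dims, function(d) d[3], 0)
  d1 <- dims[[1]]
  y <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    y[, , at + seq_len(cs[i]), ] <- xs[[i]]$value
    at <- at + cs[i]
  }
  node_new(tape, y, parents = xs, backward = function(nd) {
    at <- 0L
    for (i in seq_along(xs)) {
      g <- nd$grad[, , at + seq_len(cs[i]), , drop = FALSE]
      acc_grad(xs[[i]], g)
      at <- at + cs[i]
    }
  })
}

op_add <- function(tape, a, b) {
  node_new(tape, a$value + b$value, parents = list(a, b),
           backward = function(nd) {
             acc_grad(a, nd$grad); acc_grad(b, nd$grad)
           })
}

# global average pooling: (H, W, C, N) -> (C, N)
op_gap <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  z <- matrix(colSums(matrix(x$value, hw, d[3] * d[4])) / hw, d[3], d[4])
  node_new(tape, z, parents = list(x), backward = function(nd) {
    g <- array(rep(as.numeric(nd$grad), each = hw) / hw, d)
    acc_grad(x, g)
  })
}

# fully connected: z (Cin, N), w (Cin, Cout), b (Cout) -> (Cout, N)
op_dense <- function(tape, z, w, b) {
  y <- crossprod(w$value, z$value) + b$value
  node_new(tape, y, parents = list(z, w, b), backward = function(nd) {
    acc_grad(w, z$value %*% t(nd$grad))
    acc_grad(b, rowSums(nd$grad))
    acc_grad(z, w$value %*% nd$grad)
  })
}

# x (H,W,C,N) scaled by a per-position gate (H,W,1,N), broadcast over channels
op_scale_spatial <- function(tape, x, gate) {
  d <- dim(x$value)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  gm <- matrix(gate$value, hw, N)
  # column order of matrix(x, hw, C * N) is (c fastest, then n)
  gcols <- gm[, rep(seq_len(N), each = C), drop = FALSE]
  y <- array(matrix(x$value, hw, C * N) * gcols, d)
  node_new(tape, y, parents = list(x, gate), backward = function(nd) {
    dm <- matrix(nd$grad, hw, C * N)
    acc_grad(x, array(dm * gcols, d))
    prod <- dm * matrix(x$value, hw, C * N)
    dg <- matrix(0, hw, N)
    for (n in seq_len(N)) {
      dg[, n] <- rowSums(prod[, (n - 1) * C + seq_len(C), drop = FALSE])
    }
    acc_grad(gate, array(dg, c(d[1], d[2], 1, N)))
  })
}

# x (H,W,C,N) scaled by a per-channel gate (C, N), broadcast over positions
op_scale_channel <- function(tape, x, gate) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  gv <- rep(as.numeric(gate$value), each = hw)
  y <- array(as.numeric(x$value) * gv, d)
  node_new(tape, y, parents = list(x, gate), backward = function(nd) {
    acc_grad(x, array(as.numeric(nd$grad) * gv, d))
    prod <- matrix(as.numeric(nd$grad) * as.numeric(x$value), hw)
    acc_grad(gate, matrix(colSums(prod), d[3], d[4]))
  })
}

# fused per-pixel softmax + weighted cross-entropy.
# logits (H,W,K,N); target class indices (H,W,N) in 0..K-1; weights (H,W,N).
op_wce_softmax <- function(tape, logits, target, wmap,
                           reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  d <- dim(logits$value)
  hw <- d[1] * d[2]; K <- d[3]; N <- d[4]
  lm <- matrix(aperm(logits$value, c(1, 2, 4, 3)), hw * N, K)
  lm <- lm - apply(lm, 1, max)
  e <- exp(lm)
  p <- e / rowSums(e)
  tgt <- as.integer(target) + 1L
  pick <- p[cbind(seq_len(hw * N), tgt)]
  w <- as.numeric(wmap)
  denom <- if (reduction == "mean") hw * N else 1
  loss <- sum(w * -log(pmax(pick, 1e-12))) / denom
  node_new(tape, loss, parents = list(logits), backward = function(nd) {
    g <- p
    g[cbind(seq_len(hw * N), tgt)] <- pick - 1
    g <- g * (w / denom) * nd$grad
    garr <- aperm(array(g, c(d[1], d[2], N, K)), c(1, 2, 4, 3))
    acc_grad(logits, garr)
  })
}

# scalar helpers for regularizers
op_sum_squares <- function(tape, w) {
  node_new(tape, sum(w$value^2), parents = list(w),
           backward = function(nd) acc_grad(w, 2 * nd$grad * w$value))
}
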