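# Independent brute-force oracles: plain double loops, no shared code with
# the implementation under test.

# boundary pixels by explicit neighbour enumeration
bf_boundary <- function(mask) {
  n <- nrow(mask); p <- ncol(mask)
  out <- matrix(FALSE, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    if (mask[i, j] != 1) next
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= p && mask[ii, jj] == 0) {
        out[i, j] <- TRUE
      }
    }
  }
  out
}

# iterated cross dilation by explicit loops
bf_dilate <- function(band, iterations) {
  n <- nrow(band); p <- ncol(band)
  cur <- band
  for (it in seq_len(iterations)) {
    nxt <- cur
    for (i in seq_len(n)) for (j in seq_len(p)) {
      if (!cur[i, j]) next
      if (i > 1) nxt[i - 1, j] <- TRUE
      if (i < n) nxt[i + 1, j] <- TRUE
      if (j > 1) nxt[i, j - 1] <- TRUE
      if (j < p) nxt[i, j + 1] <- TRUE
    }
    cur <- nxt
  }
  cur
}

# per-pixel evaluation of the weight-map definition
bf_weight_map <- function(mask, iterations, mode) {
  n <- length(mask)
  if (mode == "cel") return(matrix(1, nrow(mask), ncol(mask)))
  band <- bf_dilate(bf_boundary(mask), iterations)
  w <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    for (cls in c(0, 1)) {
      tc <- sum(mask == cls)
      if (tc > 0 && mask[i, j] == cls) w[i, j] <- w[i, j] + n / tc
      if (mode == "swcel") {
        bc <- sum(band & mask == cls)
        if (bc > 0 && band[i, j] && mask[i, j] == cls) {
          w[i, j] <- w[i, j] + n / bc
        }
      }
    }
  }
  w
}

bf_hausdorff <- function(P, G) {
  h <- function(A, B) {
    worst <- 0
    for (i in seq_len(nrow(A))) {
      best <- Inf
      for (j in seq_len(nrow(B))) {
        best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
      }
      worst <- max(worst, best)
    }
    worst
  }
  max(h(P, G), h(G, P))
}

random_mask <- function(n = 8, p_one = 0.3) {
  matrix(rbinom(n * n, 1, p_one), n, n)
}

# tiny network used across tests: two pooling stages, trivial widths
tiny_config <- function(...) {
  network_config(growth_rate = 2, layers_per_block = c(1, 1),
                 initial_channels = 4, in_channels = 1,
                 ms_filters_per_branch = 2, dropout = 0, ...)
}

# central-difference gradient check of `loss_fn` wrt one entry of a param
numgrad <- function(loss_fn, model, nm, i, eps = 1e-5) {
  arr <- model$params[[nm]]
  model$params[[nm]][i] <- arr[i] + eps
  lp <- loss_fn()
  model$params[[nm]][i] <- arr[i] - eps
  lm <- loss_fn()
  model$params[[nm]][i] <- arr[i]
  (lp - lm) / (2 * eps)
}
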