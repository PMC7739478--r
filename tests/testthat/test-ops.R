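# Stateless building-block operations: multi-scale stem, dense blocks,
# squeeze-and-excitation, transitions.

test_that("multi-scale stem concatenates branch outputs with preserved size", {
  set.seed(1)
  img <- array(rnorm(64 * 64), c(64, 64, 1))
  w <- lapply(c(3, 5, 7), function(k) array(rnorm(k * k * 16) * 0.1,
                                            c(k, k, 1, 16)))
  out <- multiscale_forward(img, w)
  expect_equal(dim(out), c(64, 64, 48))

  wz <- lapply(c(3, 5, 7), function(k) array(0, c(k, k, 1, 16)))
  expect_true(all(multiscale_forward(img, wz) == 0))

  # identity-center 3x3 kernel reproduces the input on its branch
  delta <- array(0, c(5, 5, 1)); delta[3, 3, 1] <- 1
  wi <- array(0, c(3, 3, 1, 1)); wi[2, 2, 1, 1] <- 1
  out1 <- multiscale_forward(delta, list(wi))
  expect_equal(out1[, , 1], delta[, , 1])

  expect_error(multiscale_forward(img, list(array(0, c(4, 4, 1, 2)))),
               "odd")
  expect_error(multiscale_forward(array(0, c(0, 5, 1)), w), "zero-sized")
})

make_layers <- function(c0, L, k, scale = 0.1) {
  lapply(seq_len(L), function(l) {
    cin <- c0 + (l - 1) * k
    list(weights = array(rnorm(9 * cin * k) * scale, c(3, 3, cin, k)))
  })
}

test_that("dense block channel growth follows C0 + L * k", {
  set.seed(2)
  U <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  out <- dense_block_forward(U, make_layers(4, 2, 3))
  expect_equal(dim(out), c(6, 6, 4 + 2 * 3))

  expect_identical(dense_block_forward(U, list()), U)

  U2 <- array(rnorm(4 * 4 * 48), c(4, 4, 48))
  out2 <- dense_block_forward(U2, make_layers(48, 4, 12))
  expect_equal(dim(out2)[3], 96)
  # decoder convention: only the new features
  out3 <- dense_block_forward(U2, make_layers(48, 4, 12),
                              include_input = FALSE)
  expect_equal(dim(out3)[3], 48)
  # property: growth is linear for random settings
  for (trial in 1:5) {
    c0 <- sample(1:6, 1); L <- sample(0:3, 1); k <- sample(1:4, 1)
    Ur <- array(rnorm(5 * 5 * c0), c(5, 5, c0))
    o <- dense_block_forward(Ur, make_layers(c0, L, k))
    expect_equal(dim(o), c(5, 5, c0 + L * k))
  }

  bad <- make_layers(5, 1, 3)  # expects 5 input channels, gets 4
  expect_error(dense_block_forward(U, bad), "channels")
})

test_that("dense block output prefix is the input (feature reuse)", {
  set.seed(22)
  U <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  out <- dense_block_forward(U, make_layers(4, 2, 3))
  expect_equal(out[, , 1:4], U)
})

test_that("spatial squeeze-excitation gates every channel by one map", {
  set.seed(3)
  U <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  expect_equal(sse_forward(U, numeric(3)), 0.5 * U)

  U2 <- array(c(1, -1), c(1, 1, 2))
  out <- sse_forward(U2, c(1, 1))   # projection 0 -> gate 0.5
  expect_equal(as.numeric(out), c(0.5, -0.5))

  Upos <- array(runif(5 * 5 * 3, 1, 2), c(5, 5, 3))
  out_sat <- sse_forward(Upos, rep(50, 3))
  expect_equal(out_sat, Upos, tolerance = 1e-6)

  expect_error(sse_forward(U, numeric(2)), "per channel")
})

test_that("channel squeeze-excitation matches hand arithmetic", {
  U <- array(rep(c(1, 3), each = 4), c(2, 2, 2))
  out <- cse_forward(U, W_1 = matrix(c(1, -1), 2, 1),
                     W_2 = matrix(c(1, 0), 1, 2))
  # z = (1, 3); hidden = 1; zhat = (1, -1); gates (0.7311, 0.2689)
  expect_equal(out[1, 1, 1], 1 / (1 + exp(-1)), tolerance = 1e-6)
  expect_equal(out[1, 1, 2], 3 / (1 + exp(1)), tolerance = 1e-6)
  expect_equal(out[1, 1, 2], 0.8068, tolerance = 1e-3)

  set.seed(4)
  U3 <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  expect_equal(cse_forward(U3, matrix(0, 4, 2), matrix(0, 2, 4)), 0.5 * U3)

  # zero-mean channels give gates 0.5 regardless of weights
  Uz <- array(rep(c(-1, 1), 8), c(4, 4, 1))
  Uz <- sweep(Uz, 3, apply(Uz, 3, mean))
  out_z <- cse_forward(Uz, matrix(rnorm(1), 1, 1), matrix(rnorm(1), 1, 1))
  expect_equal(out_z, 0.5 * Uz)

  expect_error(cse_forward(U, matrix(0, 2, 0), matrix(0, 0, 2)), "hidden")
})

test_that("scSE is the sum of its branches, bounded, identity at zero", {
  set.seed(5)
  U <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  w <- list(W_s = rnorm(4), s_bias = 0.3,
            W_1 = matrix(rnorm(8), 4, 2), W_2 = matrix(rnorm(8), 2, 4),
            b1 = rnorm(4), b2 = rnorm(2))
  out <- scse_forward(U, w)
  expect_equal(out, sse_forward(U, w$W_s, w$s_bias) +
                 cse_forward(U, w$W_1, w$W_2, w$b1, w$b2))
  expect_true(all(abs(out) <= 2 * abs(U) + 1e-12))

  wz <- list(W_s = numeric(4), W_1 = matrix(0, 4, 2),
             W_2 = matrix(0, 2, 4))
  expect_equal(scse_forward(U, wz), U)
})

test_that("transition down halves space with floor semantics", {
  set.seed(6)
  U <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
  w <- list(w = array(rnorm(8 * 8) * 0.2, c(1, 1, 8, 8)))
  out <- transition_down_forward(U, w)
  expect_equal(dim(out), c(16, 16, 8))

  const <- array(0.7, c(6, 6, 2))
  expect_true(all(transition_down_forward(const) == 0.7))

  expect_equal(dim(transition_down_forward(array(rnorm(7 * 7 * 3),
                                                 c(7, 7, 3)))),
               c(3, 3, 3))
  expect_error(transition_down_forward(array(0, c(1, 5, 2))), "at least")
})

test_that("transition up doubles space and inverts pooling geometry", {
  set.seed(7)
  U <- array(rnorm(8 * 8 * 12), c(8, 8, 12))
  w <- array(rnorm(9 * 12 * 12) * 0.1, c(3, 3, 12, 12))
  out <- transition_up_forward(U, w)
  expect_equal(dim(out), c(16, 16, 12))

  expect_true(all(transition_up_forward(U, array(0, c(3, 3, 12, 5))) == 0))

  down_then_up <- transition_up_forward(transition_down_forward(U), w)
  expect_equal(dim(down_then_up)[1:2], dim(U)[1:2])
})
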