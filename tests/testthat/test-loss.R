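# Boundary detection, band dilation, weight maps and the weighted
# cross-entropy, pinned to hand-worked values and a brute-force oracle.

test_that("boundary detection follows the 8-neighbour rule", {
  expect_false(any(detect_boundary(matrix(0, 5, 5))))
  expect_false(any(detect_boundary(matrix(1, 5, 5))))

  m <- matrix(0, 4, 4); m[2:3, 2:3] <- 1
  b <- detect_boundary(m)
  expect_equal(which(b), which(m == 1))  # all four block pixels

  # interior pixels of a larger block are not boundary
  m2 <- matrix(0, 6, 6); m2[2:5, 2:5] <- 1
  b2 <- detect_boundary(m2)
  expect_false(b2[3, 3]); expect_true(b2[2, 2])

  expect_error(detect_boundary(matrix(2, 3, 3)), "binary")
})

test_that("border pixels with all in-bounds neighbours lesioned are interior", {
  m <- matrix(1, 4, 4); m[4, 4] <- 0
  b <- detect_boundary(m)
  expect_false(b[1, 1])   # corner: all in-bounds neighbours are 1
  expect_true(b[3, 3])    # touches the single 0
})

test_that("cross dilation expands a pixel into a clipped plus shape", {
  ct <- matrix(FALSE, 5, 5); ct[3, 3] <- TRUE
  expect_identical(dilate_band(ct, 0), ct)
  d1 <- dilate_band(ct, 1)
  expect_equal(sum(d1), 5)
  expect_true(all(d1[cbind(c(3, 2, 4, 3, 3), c(3, 3, 3, 2, 4))]))

  corner <- matrix(FALSE, 5, 5); corner[1, 1] <- TRUE
  dc <- dilate_band(corner, 1)
  expect_equal(sum(dc), 3)
  expect_true(all(dc[cbind(c(1, 1, 2), c(1, 2, 1))]))

  expect_error(dilate_band(ct, -1), "non-negative")
})

test_that("iterated dilation matches the brute-force oracle", {
  set.seed(41)
  for (trial in 1:10) {
    band <- random_mask(8, 0.2) == 1
    it <- sample(0:3, 1)
    expect_identical(dilate_band(band, it), bf_dilate(band, it))
  }
})

test_that("weight maps reproduce the worked single-pixel example", {
  m <- matrix(0, 4, 4); m[2, 2] <- 1
  w0 <- compute_weight_map(m, iterations = 0, mode = "swcel")
  expect_equal(w0[2, 2], 32)             # 16/1 + 16/1
  expect_equal(w0[1, 1], 16 / 15)
  expect_equal(sort(unique(as.numeric(w0))), c(16 / 15, 32))

  w1 <- compute_weight_map(m, iterations = 1, mode = "swcel")
  expect_equal(w1[2, 2], 32)
  band_bg <- rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2))
  expect_equal(unique(w1[band_bg]), 16 / 15 + 16 / 4)
  expect_equal(w1[4, 4], 16 / 15)

  z <- matrix(0, 4, 4)
  expect_true(all(compute_weight_map(z, mode = "swcel") == 1))
  expect_true(all(compute_weight_map(z, mode = "wcel") == 1))
})

test_that("weight maps equal the brute-force oracle on random masks", {
  set.seed(42)
  for (trial in 1:12) {
    m <- random_mask(8, runif(1, 0.1, 0.9))
    it <- sample(0:2, 1)
    mode <- sample(c("cel", "wcel", "swcel"), 1)
    expect_equal(compute_weight_map(m, it, mode), bf_weight_map(m, it, mode),
                 label = sprintf("trial %d mode %s", trial, mode))
  }
})

test_that("loss-mode collapse identities hold", {
  set.seed(43)
  # no boundary anywhere: swcel == wcel
  z <- matrix(0, 6, 6)
  expect_equal(compute_weight_map(z, 3, "swcel"),
               compute_weight_map(z, 3, "wcel"))
  o <- matrix(1, 6, 6)
  expect_equal(compute_weight_map(o, 2, "swcel"),
               compute_weight_map(o, 2, "wcel"))
  # single present class: wcel == cel (all weights |N|/|N| = 1)
  expect_equal(compute_weight_map(o, mode = "wcel"),
               compute_weight_map(o, mode = "cel"))
})

test_that("per-class weight mass without a band is |N| per present class", {
  set.seed(44)
  for (trial in 1:8) {
    m <- random_mask(8, runif(1, 0.05, 0.95))
    w <- compute_weight_map(m, mode = "wcel")
    n <- length(m)
    present <- unique(as.numeric(m))
    for (cls in present) {
      expect_equal(sum(w[m == cls]), n)
    }
    expect_equal(sum(w), length(present) * n)
  }
})

test_that("weighted cross-entropy matches hand arithmetic", {
  perfect <- matrix(1, 2, 2)
  tgt <- matrix(1, 2, 2)
  expect_equal(weighted_cross_entropy(perfect, tgt, reduction = "sum"), 0)

  half <- matrix(0.5, 2, 2)
  expect_equal(weighted_cross_entropy(half, tgt, reduction = "sum"),
               4 * log(2))

  p <- matrix(exp(-1), 1, 1)
  w <- matrix(32, 1, 1)
  expect_equal(weighted_cross_entropy(p, matrix(1, 1, 1), w,
                                      reduction = "sum"), 32)

  # zero probability clamps, never -Inf
  expect_true(is.finite(weighted_cross_entropy(matrix(0, 1, 1),
                                               matrix(1, 1, 1),
                                               reduction = "sum")))
  # unit weights equal plain cross-entropy (mean)
  set.seed(45)
  pr <- matrix(runif(16, 0.1, 0.9), 4, 4)
  tg <- random_mask(4, 0.5)
  expect_equal(weighted_cross_entropy(pr, tg),
               mean(-log(ifelse(tg == 1, pr, 1 - pr))))
})

test_that("loss strictly decreases as target probability rises", {
  tg <- matrix(c(1, 0, 1, 0), 2, 2)
  w <- compute_weight_map(tg, mode = "swcel")
  p_lo <- matrix(0.4, 2, 2)
  p_hi <- p_lo; p_hi[1, 1] <- 0.6    # better at a target=1 pixel
  expect_lt(weighted_cross_entropy(p_hi, tg, w),
            weighted_cross_entropy(p_lo, tg, w))
})
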