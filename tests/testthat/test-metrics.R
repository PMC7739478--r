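# Segmentation metrics (MPA/PA1, DSC, Hausdorff) and diagnostic rates,
# against hand counts, brute force and an independent library.

test_that("pixel accuracy reproduces the worked 4x4 example", {
  truth <- matrix(0, 4, 4); truth[1:2, 1:2] <- 1          # 4 lesion pixels
  pred <- truth; pred[2, 2] <- 0                          # recovers 3 of 4
  pred[4, 4] <- 1                                         # 11 of 12 bg ok
  r <- pixel_accuracy(pred, truth)
  expect_equal(r$pa1, 0.75)
  expect_equal(r$mpa, (0.75 + 11 / 12) / 2)

  perf <- pixel_accuracy(truth, truth)
  expect_equal(perf$mpa, 1); expect_equal(perf$pa1, 1)

  z <- matrix(0, 4, 4)
  expect_equal(pixel_accuracy(z, z)$pa1, 1)   # empty-class convention
  pred_fp <- z; pred_fp[1, 1] <- 1
  expect_equal(pixel_accuracy(pred_fp, z)$pa1, 0)

  expect_error(pixel_accuracy(matrix(0, 3, 3), matrix(0, 4, 4)),
               "mismatch")
})

test_that("Dice matches set arithmetic and conventions", {
  fx <- worked_fixtures()$dice_4_7
  expect_equal(dice(fx$pred, fx$truth)$dsc1, 4 / 7)

  m <- matrix(0, 5, 5); m[2:3, 2:3] <- 1
  expect_equal(dice(m, m)$dsc1, 1)

  a <- matrix(0, 4, 4); a[1, 1] <- 1
  b <- matrix(0, 4, 4); b[4, 4] <- 1
  expect_equal(dice(a, b)$dsc1, 0)

  # symmetry under swapping prediction and truth
  set.seed(51)
  for (trial in 1:6) {
    p <- random_mask(8); t <- random_mask(8)
    expect_equal(dice(p, t)$dsc, dice(t, p)$dsc)
  }
})

test_that("MPA and DSC agree with direct counting on random pairs", {
  set.seed(52)
  for (trial in 1:8) {
    p <- random_mask(8); t <- random_mask(8)
    r <- pixel_accuracy(p, t); d <- dice(p, t)
    ratios <- c()
    dscs <- c()
    for (cls in 0:1) {
      tc <- sum(t == cls)
      ratios <- c(ratios,
                  if (tc == 0) as.numeric(sum(p == cls) == 0)
                  else sum(p == cls & t == cls) / tc)
      ab <- sum(p == cls) + sum(t == cls)
      dscs <- c(dscs, if (ab == 0) 1 else 2 * sum(p == cls & t == cls) / ab)
    }
    expect_equal(r$mpa, mean(ratios))
    expect_equal(d$dsc, mean(dscs))
  }
})

test_that("Hausdorff distance matches examples, brute force and pracma", {
  P <- matrix(c(0, 0), 1, 2); G <- matrix(c(3, 4), 1, 2)
  expect_equal(hausdorff(P, G), 5)
  expect_equal(hausdorff(P, P), 0)
  P2 <- rbind(c(0, 0), c(10, 0)); G2 <- matrix(c(0, 0), 1, 2)
  expect_equal(hausdorff(P2, G2), 10)

  expect_true(is.na(hausdorff(matrix(0, 0, 2), G)))

  set.seed(53)
  for (trial in 1:8) {
    A <- matrix(sample(0:15, 2 * sample(2:20, 1), TRUE), ncol = 2)
    B <- matrix(sample(0:15, 2 * sample(2:20, 1), TRUE), ncol = 2)
    expect_equal(hausdorff(A, B), bf_hausdorff(A, B))
    expect_equal(hausdorff(A, B), hausdorff(B, A))   # symmetry
    expect_equal(hausdorff(A, B), pracma::hausdorff_dist(A, B))
  }
})

test_that("mask-based Hausdorff compares detected contours", {
  m <- matrix(0, 6, 6); m[2:3, 2:3] <- 1
  expect_equal(hausdorff_mask(m, m), 0)
  shifted <- matrix(0, 6, 6); shifted[4:5, 4:5] <- 1
  expect_equal(hausdorff_mask(m, shifted), sqrt(8))
  expect_true(is.na(hausdorff_mask(matrix(0, 4, 4), m)))
})

test_that("confusion tally and reconstruction from printed rates", {
  cc <- confusion(c("PTX", "PTX", "PTX", "NonPTX", "NonPTX"),
                  c("PTX", "PTX", "PTX", "NonPTX", "NonPTX"))
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 3, tn = 2, fp = 0, fn = 0))

  cc2 <- confusion(c("PTX", "NonPTX"), c("PTX", "PTX"))
  expect_equal(cc2$tp, 1); expect_equal(cc2$fp, 1)

  # test-set composition 1083 PTX / 1130 Non-PTX with sensitivity 88.55%
  # and specificity 98.14% pins the confusion matrix by rounding
  tp <- round(0.8855 * 1083); tn <- round(0.9814 * 1130)
  expect_equal(tp, 959); expect_equal(tn, 1109)
  expect_equal(1083 - tp, 124); expect_equal(1130 - tn, 21)

  expect_error(confusion("PTX", c("PTX", "PTX")), "length")
  expect_error(confusion("yes", "no"), "PTX")
})

test_that("diagnostic rates follow their definitions", {
  perfect <- list(tp = 10, fp = 0, fn = 0, tn = 10)
  expect_true(all(unlist(diagnostic_metrics(perfect)) == 100))

  even <- list(tp = 1, fp = 1, fn = 1, tn = 1)
  expect_true(all(unlist(diagnostic_metrics(even)) == 50))

  none <- diagnostic_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0))
  expect_true(all(is.na(unlist(none))))

  set.seed(54)
  for (trial in 1:6) {
    cc <- list(tp = sample(1:50, 1), fp = sample(1:50, 1),
               fn = sample(1:50, 1), tn = sample(1:50, 1))
    dm <- diagnostic_metrics(cc)
    # F1 is the harmonic mean of PPV and sensitivity
    expect_equal(dm$f1, 2 / (1 / dm$ppv + 1 / dm$sensitivity))
    # accuracy is the prevalence-weighted mix of sensitivity/specificity
    pos <- cc$tp + cc$fn; neg <- cc$tn + cc$fp
    expect_equal(dm$accuracy,
                 (dm$sensitivity * pos + dm$specificity * neg) / (pos + neg))
  }
})

test_that("t-test utility flags separated DSC distributions", {
  set.seed(55)
  a <- runif(30, 0.8, 0.9)
  b <- runif(30, 0.5, 0.6)
  r <- dsc_t_test(a, b)
  expect_true(r$significant)
  expect_gt(r$statistic, 0)
  same <- dsc_t_test(a, a)
  expect_equal(same$statistic, 0)
  expect_false(same$significant)
})

test_that("segmentation report has one row per image", {
  set.seed(56)
  preds <- replicate(5, random_mask(8), simplify = FALSE)
  truths <- replicate(5, random_mask(8), simplify = FALSE)
  rep <- segmentation_report(preds, truths, ids = letters[1:5])
  expect_equal(nrow(rep), 5)
  expect_named(rep, c("id", "pa1", "dsc1", "hd"))
})
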