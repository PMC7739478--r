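# Segmentation and diagnostic evaluation: per-class pixel accuracy (MPA,
# PA1), Dice similarity (DSC, DSC1), symmetric Hausdorff contour distance,
# the 2x2 diagnostic confusion tally and its derived rates.

as_mask_list <- function(x, arg) {
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x)) abort(sprintf("`%s` must be a matrix or list of matrices",
                                 arg))
  lapply(x, check_binary_mask, arg = arg)
}

check_pairs <- function(pred, truth) {
  pred <- as_mask_list(pred, "pred")
  truth <- as_mask_list(truth, "truth")
  if (length(pred) != length(truth)) {
    abort("`pred` and `truth` must have the same length")
  }
  for (i in seq_along(pred)) {
    if (!all(dim(pred[[i]]) == dim(truth[[i]]))) {
      abort(sprintf("mask shape mismatch in pair %d", i))
    }
  }
  list(pred = pred, truth = truth)
}

# empty-class convention shared by PA and DSC: a class absent from the truth
# scores 1 when the prediction is also empty for it, else 0
class_ratio <- function(pred, truth, cls) {
  pc <- sum(truth == cls)
  if (pc == 0) return(as.numeric(sum(pred == cls) == 0))
  sum(pred == cls & truth == cls) / pc
}

#' Per-class pixel accuracy and MPA
#'
#' For every image and class, the fraction of that class's ground-truth
#' pixels recovered by the prediction. MPA averages the ratio over images
#' and classes; PA1 averages the lesion-class ratio over images. A class
#' with no ground-truth pixels scores 1 when the prediction is also empty
#' for it, 0 otherwise.
#'
#' @param pred,truth binary mask matrices, or lists of them (paired).
#' @return list with `per_image` (tibble: image, class, accuracy), `mpa`
#'   and `pa1`.
#' @export
pixel_accuracy <- function(pred, truth) {
  pr <- check_pairs(pred, truth)
  rows <- purrr::map_dfr(seq_along(pr$pred), function(i) {
    tibble(image = i, class = c(0L, 1L),
           accuracy = c(class_ratio(pr$pred[[i]], pr$truth[[i]], 0),
                        class_ratio(pr$pred[[i]], pr$truth[[i]], 1)))
  })
  list(per_image = rows,
       mpa = mean(rows$accuracy),
       pa1 = mean(rows$accuracy[rows$class == 1L]))
}

#' Dice similarity coefficients
#'
#' Per image and class, `2 |A_c intersect B_c| / (|A_c| + |B_c|)` between
#' predicted (`A`) and ground-truth (`B`) pixel sets; two empty sets score
#' 1. `dsc` averages over images and classes; `dsc1` is the lesion-class
#' mean.
#'
#' @inheritParams pixel_accuracy
#' @return list with `per_image` (tibble: image, class, dsc), `dsc`,
#'   `dsc1`.
#' @export
dice <- function(pred, truth) {
  pr <- check_pairs(pred, truth)
  dsc_one <- function(p, t, cls) {
    a <- sum(p == cls); b <- sum(t == cls)
    if (a + b == 0) return(1)
    2 * sum(p == cls & t == cls) / (a + b)
  }
  rows <- purrr::map_dfr(seq_along(pr$pred), function(i) {
    tibble(image = i, class = c(0L, 1L),
           dsc = c(dsc_one(pr$pred[[i]], pr$truth[[i]], 0),
                   dsc_one(pr$pred[[i]], pr$truth[[i]], 1)))
  })
  list(per_image = rows,
       dsc = mean(rows$dsc),
       dsc1 = mean(rows$dsc[rows$class == 1L]))
}

directed_hausdorff <- function(P, G) {
  # max over P of the distance to the nearest point of G
  d2 <- outer(rowSums(P^2), rep(1, nrow(G))) +
    outer(rep(1, nrow(P)), rowSums(G^2)) - 2 * P %*% t(G)
  max(sqrt(pmax(apply(d2, 1, min), 0)))
}

#' Symmetric Hausdorff distance between point sets
#'
#' `max(h(P, G), h(G, P))` with `h(P, G) = max_p min_g ||p - g||`
#' (Euclidean, pixel units). Either set empty gives `NA` (undefined);
#' aggregate reports exclude such images.
#'
#' @param P,G two-column matrices of 0-based (row, col) pixel coordinates.
#' @return scalar distance, 0 iff the sets are equal, or `NA`.
#' @export
hausdorff <- function(P, G) {
  P <- as_coords(P); G <- as_coords(G)
  if (nrow(P) == 0 || nrow(G) == 0) return(NA_real_)
  max(directed_hausdorff(P, G), directed_hausdorff(G, P))
}

as_coords <- function(x) {
  if (is.null(x) || length(x) == 0) return(matrix(0, 0, 2))
  if (!is.matrix(x) || ncol(x) != 2) {
    abort("expected a two-column coordinate matrix")
  }
  x
}

#' @rdname hausdorff
#' @param pred,truth binary masks; their contours from [detect_boundary()]
#'   (0-based coordinates) are compared.
#' @export
hausdorff_mask <- function(pred, truth) {
  hausdorff(which(detect_boundary(pred), arr.ind = TRUE) - 1,
            which(detect_boundary(truth), arr.ind = TRUE) - 1)
}

#' Diagnostic confusion counts
#'
#' Tallies image-level pneumothorax calls against truth, with `"PTX"` as
#' the positive class.
#'
#' @param labels,calls character vectors in `{"PTX", "NonPTX"}`, equal
#'   length.
#' @return a `ptx_confusion` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(labels, calls) {
  if (length(labels) != length(calls)) {
    abort("`labels` and `calls` must have the same length")
  }
  ok <- c("PTX", "NonPTX")
  if (!all(labels %in% ok) || !all(calls %in% ok)) {
    abort('labels and calls must be "PTX" or "NonPTX"')
  }
  structure(list(
    tp = sum(labels == "PTX" & calls == "PTX"),
    fp = sum(labels == "NonPTX" & calls == "PTX"),
    fn = sum(labels == "PTX" & calls == "NonPTX"),
    tn = sum(labels == "NonPTX" & calls == "NonPTX")
  ), class = "ptx_confusion")
}

#' Diagnostic metrics from a confusion tally
#'
#' Accuracy, sensitivity, specificity, positive/negative predictive value
#' and F1 score, reported in percent as clinically customary. A zero
#' denominator yields `NA` for that field.
#'
#' @param cc a [confusion()] result, or a list with `tp`, `fp`, `fn`, `tn`.
#' @return named list of percentages.
#' @export
diagnostic_metrics <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; fn <- cc$fn; tn <- cc$tn
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sens <- rate(tp, tp + fn)
  ppv <- rate(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(ppv) || sens + ppv == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  list(accuracy = rate(tp + tn, tp + fp + fn + tn),
       sensitivity = sens,
       specificity = rate(tn, tn + fp),
       ppv = ppv,
       npv = rate(tn, tn + fn),
       f1 = f1)
}

#' Compare per-image Dice vectors between two models
#'
#' Two-sample Student's t-test (equal variances) on per-image DSC scores,
#' the reporting convention used to flag significant segmentation
#' differences.
#'
#' @param dsc_a,dsc_b numeric vectors of per-image DSC values.
#' @return tibble with the t statistic, degrees of freedom, p value and
#'   group means.
#' @export
dsc_t_test <- function(dsc_a, dsc_b) {
  ht <- t.test(dsc_a, dsc_b, var.equal = TRUE)
  tibble(statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = ht$p.value,
         mean_a = mean(dsc_a), mean_b = mean(dsc_b),
         significant = ht$p.value < 0.05)
}

#' Per-image segmentation report
#'
#' Computes PA1, DSC1 and the Hausdorff contour distance for each
#' prediction/truth pair, the building block of the evaluation reports.
#'
#' @inheritParams pixel_accuracy
#' @param ids optional image identifiers.
#' @return tibble with one row per image: `id`, `pa1`, `dsc1`, `hd`.
#' @export
segmentation_report <- function(pred, truth, ids = NULL) {
  pr <- check_pairs(pred, truth)
  n <- length(pr$pred)
  ids <- ids %||% seq_len(n)
  purrr::map_dfr(seq_len(n), function(i) {
    p <- pr$pred[[i]]; t <- pr$truth[[i]]
    tibble(id = ids[i],
           pa1 = class_ratio(p, t, 1),
           dsc1 = {
             a <- sum(p == 1); b <- sum(t == 1)
             if (a + b == 0) 1 else 2 * sum(p == 1 & t == 1) / (a + b)
           },
           hd = hausdorff_mask(p, t))
  })
}
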