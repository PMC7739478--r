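# Spatially weighted cross-entropy: boundary detection on the ground-truth
# mask, morphological dilation of the contour into a band, per-pixel weights
# from inverse class frequency plus a boundary bonus, and the weighted
# negative log-likelihood itself.

check_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) abort(sprintf("`%s` must be a matrix", arg))
  if (!all(mask %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (0 = background, 1 = lesion)", arg))
  }
  storage.mode(mask) <- "double"
  mask
}

shift_mat <- function(m, dr, dc, fill = NA) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  rs <- seq_len(n) - dr
  cs <- seq_len(p) - dc
  ok_r <- rs >= 1 & rs <= n
  ok_c <- cs >= 1 & cs <= p
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Detect lesion boundary pixels
#'
#' A lesion pixel (value 1) is a boundary contour pixel when at least one of
#' its eight in-bounds neighbours is background (value 0). Neighbours
#' falling outside the image are ignored, so a lesion flush against the
#' image border is not declared boundary on that side.
#'
#' @param mask binary matrix.
#' @return logical matrix marking boundary contour pixels.
#' @examples
#' m <- matrix(0, 4, 4); m[2:3, 2:3] <- 1
#' which(detect_boundary(m))  # all four lesion pixels
#' @export
detect_boundary <- function(mask) {
  mask <- check_binary_mask(mask)
  has_zero <- matrix(FALSE, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- shift_mat(mask, dr, dc, fill = NA)
    has_zero <- has_zero | (!is.na(nb) & nb == 0)
  }
  mask == 1 & has_zero
}

#' Dilate a pixel set with a 3x3 cross
#'
#' Iterated morphological dilation with a plus-shaped structuring element
#' (the pixel and its four edge neighbours), clipped at the image borders.
#'
#' @param contour logical matrix (e.g. from [detect_boundary()]).
#' @param iterations non-negative dilation count; 0 returns the input.
#' @return logical matrix of the dilated band.
#' @export
dilate_band <- function(contour, iterations = 2) {
  if (!is.matrix(contour)) abort("`contour` must be a matrix")
  if (iterations < 0) abort("`iterations` must be non-negative")
  band <- contour != 0
  for (i in seq_len(iterations)) {
    band <- band |
      shift_mat(band, 1, 0, FALSE) | shift_mat(band, -1, 0, FALSE) |
      shift_mat(band, 0, 1, FALSE) | shift_mat(band, 0, -1, FALSE)
  }
  band
}

#' Per-pixel loss weight map
#'
#' Builds the spatial weight map used by the weighted cross-entropy
#' variants. Writing `N` for all pixels of one image, `T_c` for the pixels
#' of class `c` and `B_c` for the band pixels of class `c` (the detected
#' contour dilated `iterations` times, intersected with `T_c`):
#'
#' * `"cel"`: every weight is 1 (plain cross-entropy);
#' * `"wcel"`: a pixel of class `c` weighs `|N| / |T_c|` (inverse class
#'   frequency);
#' * `"swcel"`: the `wcel` weight plus a boundary bonus `|N| / |B_c|` on
#'   band pixels of class `c`.
#'
#' Classes with no pixels (or an empty band) contribute no term.
#'
#' @param mask binary ground-truth matrix.
#' @param iterations dilation count for the boundary band.
#' @param mode `"cel"`, `"wcel"` or `"swcel"`.
#' @return numeric matrix of positive weights, same shape as `mask`.
#' @examples
#' m <- matrix(0, 4, 4); m[2, 2] <- 1
#' compute_weight_map(m, iterations = 0, mode = "swcel")[2, 2]  # 32
#' @export
compute_weight_map <- function(mask, iterations = 2,
                               mode = c("swcel", "wcel", "cel")) {
  mode <- match.arg(mode)
  mask <- check_binary_mask(mask)
  n <- length(mask)
  w <- matrix(1, nrow(mask), ncol(mask))
  if (mode == "cel") return(w)
  w[] <- 0
  for (cls in c(0, 1)) {
    tc <- mask == cls
    if (!any(tc)) next
    w[tc] <- w[tc] + n / sum(tc)
  }
  if (mode == "swcel") {
    band <- dilate_band(detect_boundary(mask), iterations)
    for (cls in c(0, 1)) {
      bc <- band & mask == cls
      if (!any(bc)) next
      w[bc] <- w[bc] + n / sum(bc)
    }
  }
  w
}

#' Weighted cross-entropy loss
#'
#' `sum_i w(x_i) * (-log p(t_i | x_i))` over the pixels of one image (or
#' its mean). With unit weights this is plain cross-entropy. Probabilities
#' are clamped at `eps` so a zero-probability target yields a large finite
#' loss, never infinity.
#'
#' @param probabilities `(H, W, num_classes)` array of per-pixel class
#'   probabilities, or an `(H, W)` matrix of lesion probabilities for the
#'   two-class case.
#' @param targets binary matrix of target labels.
#' @param weights numeric weight matrix (e.g. from [compute_weight_map()]);
#'   defaults to 1 everywhere.
#' @param reduction `"mean"` (default, stable across image sizes) or
#'   `"sum"`.
#' @param eps probability clamp.
#' @return non-negative scalar loss.
#' @export
weighted_cross_entropy <- function(probabilities, targets, weights = NULL,
                                   reduction = c("mean", "sum"),
                                   eps = 1e-7) {
  reduction <- match.arg(reduction)
  targets <- check_binary_mask(targets, "targets")
  if (is.matrix(probabilities)) {
    p1 <- probabilities
    p_target <- ifelse(targets == 1, p1, 1 - p1)
  } else {
    stopifnot(length(dim(probabilities)) == 3L)
    idx <- cbind(as.vector(row(targets)), as.vector(col(targets)),
                 as.vector(targets) + 1L)
    p_target <- matrix(probabilities[idx], nrow(targets), ncol(targets))
  }
  if (is.null(weights)) weights <- matrix(1, nrow(targets), ncol(targets))
  if (!all(dim(weights) == dim(targets))) {
    abort("`weights` shape must match `targets`")
  }
  contrib <- weights * -log(pmax(p_target, eps))
  if (reduction == "sum") sum(contrib) else mean(contrib)
}
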