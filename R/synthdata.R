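# Chest-phantom generator: stylized radiograph-like images with ground-truth
# lesion masks, so the whole pipeline is exercisable without any clinical
# data. Phantoms combine a body background, two elliptical lung fields,
# periodic rib-like stripes and Gaussian noise; lesions are darker
# crescents/ellipses with a sharp boundary at the lung periphery.

#' Phantom generation settings
#'
#' @param image_size side length in pixels (square images).
#' @param lesion_prob probability that a phantom carries a lesion (default
#'   0.504, the pneumothorax share of the emulated dataset).
#' @param lesion_area two-element range of lesion areas in pixels. The
#'   lower bound must exceed the 50-pixel diagnosis threshold unless
#'   `sub_threshold = TRUE` (used for boundary-case tests).
#' @param lesion_shape `"crescent"`, `"ellipse"` or `"mixed"` (random per
#'   phantom).
#' @param rib_period,rib_amplitude period (pixels) and amplitude of the
#'   rib-like sinusoidal stripes.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param sub_threshold allow lesion areas at or below 50 pixels.
#' @return a `ptx_phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 64,
                         lesion_prob = 0.504,
                         lesion_area = c(60, round(0.15 * image_size^2)),
                         lesion_shape = c("mixed", "crescent", "ellipse"),
                         rib_period = 9,
                         rib_amplitude = 0.08,
                         noise_sd = 0.04,
                         sub_threshold = FALSE) {
  lesion_shape <- match.arg(lesion_shape)
  if (length(lesion_area) != 2 || lesion_area[1] > lesion_area[2]) {
    abort("`lesion_area` must be an increasing range")
  }
  # the achievable lesion area is capped by the lung fields (~40% of the
  # frame); only an unreachable MINIMUM is infeasible, a generous maximum
  # is clipped by the lung support at generation time
  if (lesion_area[1] > 0.3 * image_size^2) {
    abort("`lesion_area` is infeasible for this image size")
  }
  if (!sub_threshold && lesion_area[1] <= 50) {
    abort(paste("minimum lesion area must exceed the 50-pixel diagnosis",
                "threshold (or set `sub_threshold = TRUE`)"))
  }
  structure(list(image_size = as.integer(image_size),
                 lesion_prob = lesion_prob,
                 lesion_area = round(lesion_area),
                 lesion_shape = lesion_shape,
                 rib_period = rib_period,
                 rib_amplitude = rib_amplitude,
                 noise_sd = noise_sd,
                 sub_threshold = sub_threshold),
            class = "ptx_phantom_spec")
}

lung_fields <- function(s) {
  r <- matrix(seq_len(s), s, s)
  cl <- matrix(seq_len(s), s, s, byrow = TRUE)
  inside <- function(cy, cx, a, b) {
    ((r - cy) / a)^2 + ((cl - cx) / b)^2 <= 1
  }
  left <- inside(0.52 * s, 0.30 * s, 0.38 * s, 0.17 * s)
  right <- inside(0.52 * s, 0.70 * s, 0.38 * s, 0.17 * s)
  list(left = left, right = right, either = left | right)
}

# exact-area lesion support: the `area` lowest-potential lung pixels around
# a peripheral seed. Crescent potential bends the level sets into a sliver
# between the chest wall and the (collapsed) lung.
lesion_support <- function(lungs, s, area, shape) {
  side <- if (runif(1) < 0.5) "left" else "right"
  lung <- lungs[[side]]
  cx0 <- if (side == "left") 0.30 * s else 0.70 * s
  idx <- which(lung, arr.ind = TRUE)
  # peripheral seed: lung pixel far from the lung centre, apical half
  dc <- sqrt((idx[, 1] - 0.52 * s)^2 + (idx[, 2] - cx0)^2)
  top <- idx[, 1] < 0.55 * s
  cand <- which(top & dc > stats::quantile(dc[top], 0.7))
  if (length(cand) == 0) cand <- seq_len(nrow(idx))
  seed <- idx[sample(cand, 1), ]
  r <- matrix(seq_len(s), s, s)
  cl <- matrix(seq_len(s), s, s, byrow = TRUE)
  d1 <- sqrt((r - seed[1])^2 + (cl - seed[2])^2)
  pot <- if (shape == "ellipse") {
    th <- runif(1, 0, pi)
    e <- runif(1, 0.4, 1)
    dx <- (cl - seed[2]) * cos(th) + (r - seed[1]) * sin(th)
    dy <- -(cl - seed[2]) * sin(th) + (r - seed[1]) * cos(th)
    sqrt(dx^2 + (dy / e)^2)
  } else {
    # crescent: pulled toward the boundary away from a displaced "lung" disc
    off <- 0.18 * s
    c2r <- seed[1] + off * sign(0.52 * s - seed[1] + 1e-9)
    c2c <- seed[2] + off * sign(cx0 - seed[2] + 1e-9)
    d2 <- sqrt((r - c2r)^2 + (cl - c2c)^2)
    d1 - 0.72 * d2
  }
  pool <- which(lung)
  area <- min(area, length(pool))
  sel <- pool[order(pot[pool])[seq_len(area)]]
  m <- matrix(0, s, s)
  m[sel] <- 1
  m
}

#' Generate one chest phantom
#'
#' Deterministic in `(spec, seed)`: the same pair reproduces the image,
#' mask and label bit-identically. Lesion phantoms carry a reduced-
#' intensity region (rib texture suppressed, sharp boundary) whose support
#' is the ground-truth mask and always lies inside a lung field; lesion-
#' free phantoms have an all-zero mask.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return list with `image` (matrix in `[0, 1]`), `mask` (binary matrix)
#'   and `label` (`"PTX"` or `"NonPTX"`).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1) {
  stopifnot(inherits(spec, "ptx_phantom_spec"))
  withr::local_seed(seed)
  s <- spec$image_size
  lungs <- lung_fields(s)
  r <- matrix(seq_len(s), s, s)
  img <- 0.72 - 0.08 * r / s          # body background, mild gradient
  img[lungs$either] <- 0.38
  ribs <- spec$rib_amplitude *
    (1 + sin(2 * pi * r / spec$rib_period + runif(1, 0, 2 * pi))) / 2
  img[lungs$either] <- img[lungs$either] + ribs[lungs$either]
  label <- if (runif(1) < spec$lesion_prob) "PTX" else "NonPTX"
  mask <- matrix(0, s, s)
  if (label == "PTX") {
    shape <- if (spec$lesion_shape == "mixed") {
      if (runif(1) < 0.5) "crescent" else "ellipse"
    } else spec$lesion_shape
    area <- round(runif(1, spec$lesion_area[1], spec$lesion_area[2]))
    mask <- lesion_support(lungs, s, area, shape)
    img[mask == 1] <- 0.26            # subtle lucency, no lung markings
  }
  img <- img + rnorm(s * s, 0, spec$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, label = label)
}

#' Generate a phantom set in memory
#'
#' @param n number of phantoms.
#' @param spec a [phantom_spec()].
#' @param seed integer seed; phantom `i` uses `seed * 10000 + i` so sets
#'   built from the same seed are reproducible element-wise.
#' @return tibble with `id`, `image`, `mask` (list columns) and `label`.
#' @export
generate_phantom_set <- function(n, spec = phantom_spec(), seed = 1) {
  rows <- purrr::map(seq_len(n), function(i) {
    ph <- generate_phantom(spec, seed = seed * 10000 + i)
    tibble(id = sprintf("phantom_%04d", i),
           image = list(ph$image), mask = list(ph$mask), label = ph$label)
  })
  dplyr::bind_rows(rows)
}

largest_remainder <- function(n, fractions) {
  raw <- n * fractions / sum(fractions)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

# stratified split labels for one vector of class labels
stratified_split <- function(labels, fractions) {
  n <- length(labels)
  split_names <- names(fractions) %||% paste0("s", seq_along(fractions))
  totals <- largest_remainder(n, fractions)
  out <- character(n)
  remaining <- totals
  classes <- unique(labels)
  for (ci in seq_along(classes)) {
    idx <- sample(which(labels == classes[ci]))
    take <- if (ci == length(classes)) {
      remaining
    } else {
      largest_remainder(length(idx), fractions)
    }
    take <- pmin(take, remaining)
    # distribute any shortfall caused by the cap
    while (sum(take) < length(idx)) {
      room <- which(remaining - take > 0)
      take[room[1]] <- take[room[1]] + 1
    }
    at <- 0L
    for (si in seq_along(take)) {
      if (take[si] > 0) {
        out[idx[at + seq_len(take[si])]] <- split_names[si]
        at <- at + take[si]
      }
    }
    remaining <- remaining - take
  }
  out
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask PNG pairs (8-bit grayscale; masks 0/255,
#' lesion-free phantoms get no mask file) plus a `manifest.csv` with
#' columns `image_path`, `mask_path` (empty for lesion-free images),
#' `label` and `split`. The split is stratified so each subset preserves
#' the overall class ratio to within one image.
#'
#' @inheritParams generate_phantom_set
#' @param split_fractions named fractions summing to 1, default
#'   `c(train = 0.64, val = 0.16, test = 0.20)`.
#' @param out_dir output directory (created if needed).
#' @return the manifest tibble, invisibly; written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(n, spec = phantom_spec(), seed = 1,
                             split_fractions = c(train = 0.64, val = 0.16,
                                                 test = 0.20),
                             out_dir) {
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    abort("`split_fractions` must sum to 1")
  }
  if (n < length(split_fractions)) {
    abort("`n` must be at least the number of splits")
  }
  set <- generate_phantom_set(n, spec, seed)
  withr::local_seed(seed)
  set$split <- stratified_split(set$label, split_fractions)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- purrr::map_dfr(seq_len(n), function(i) {
    img_rel <- file.path("images", paste0(set$id[i], ".png"))
    png::writePNG(set$image[[i]], file.path(out_dir, img_rel))
    mask_rel <- ""
    if (set$label[i] == "PTX") {
      mask_rel <- file.path("masks", paste0(set$id[i], ".png"))
      png::writePNG(set$mask[[i]], file.path(out_dir, mask_rel))
    }
    tibble(image_path = img_rel, mask_path = mask_rel,
           label = set$label[i], split = set$split[i])
  })
  write.csv(manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}

#' Hand-checkable fixtures
#'
#' Small masks and contour sets whose weight maps, Dice scores and
#' Hausdorff distances are known from pencil-and-paper arithmetic; used as
#' frozen oracles in the test-suite and in examples.
#'
#' @return named list of fixtures; each holds inputs and the expected
#'   values.
#' @export
worked_fixtures <- function() {
  single <- matrix(0, 4, 4); single[2, 2] <- 1
  w0 <- matrix(16 / 15, 4, 4); w0[2, 2] <- 32
  w1 <- matrix(16 / 15, 4, 4); w1[2, 2] <- 32
  band_bg <- rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2))
  w1[band_bg] <- 16 / 15 + 16 / 4
  block <- matrix(0, 4, 4); block[2:3, 2:3] <- 1
  pred47 <- matrix(0, 4, 4); pred47[cbind(c(1, 2, 2), c(2, 2, 3))] <- 1
  truth47 <- matrix(0, 4, 4); truth47[cbind(c(2, 2, 3, 3),
                                            c(2, 3, 2, 3))] <- 1
  list(
    single_pixel_4x4 = list(
      mask = single,
      weight_map_iter0 = w0,
      weight_map_iter1 = w1,
      center_weight = 32),
    block_2x2_4x4 = list(
      mask = block,
      boundary = block == 1),
    two_point_contour = list(
      P = matrix(c(0, 0), 1, 2),
      G = matrix(c(3, 4), 1, 2),
      hd = 5),
    dice_4_7 = list(
      pred = pred47, truth = truth47,
      dsc1 = 4 / 7)
  )
}
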