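# Training, inference, the pixel-count diagnosis rule and end-to-end
# evaluation.

#' Training settings
#'
#' Defaults follow the reference protocol: Adam (beta1 0.9, beta2 0.999)
#' with learning rate 1e-4 and weight decay 1e-4, up to 200 epochs,
#' early stopping on validation DSC1 with patience 20, random horizontal
#' flips with probability 0.5, and the spatially weighted cross-entropy
#' loss.
#'
#' @param loss_mode `"swcel"`, `"wcel"` or `"cel"`.
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decays.
#' @param weight_decay L2 penalty added to weight gradients (biases and
#'   batch-norm parameters are exempt).
#' @param max_epochs epoch cap.
#' @param patience consecutive non-improving epochs tolerated before
#'   stopping (monitored: validation DSC1).
#' @param batch_size images per optimization step.
#' @param flip_prob probability of flipping an image (and its mask)
#'   horizontally during training.
#' @param dilate_iterations boundary-band dilation count for the swcel
#'   weight maps.
#' @param reduction loss reduction, `"mean"` or `"sum"`.
#' @param seed integer seed controlling shuffling, flips and dropout.
#' @param verbose print one structured line per epoch.
#' @return a `ptx_training_config` list.
#' @export
training_config <- function(loss_mode = c("swcel", "wcel", "cel"),
                            learning_rate = 1e-4,
                            beta1 = 0.9, beta2 = 0.999,
                            weight_decay = 1e-4,
                            max_epochs = 200,
                            patience = 20,
                            batch_size = 4,
                            flip_prob = 0.5,
                            dilate_iterations = 2,
                            reduction = c("mean", "sum"),
                            seed = 42,
                            verbose = FALSE) {
  loss_mode <- match.arg(loss_mode)
  reduction <- match.arg(reduction)
  if (learning_rate <= 0) abort("`learning_rate` must be positive")
  if (patience > max_epochs) abort("`patience` cannot exceed `max_epochs`")
  structure(as.list(environment()), class = "ptx_training_config")
}

as_input_array <- function(img, in_channels) {
  if (is.matrix(img)) {
    img <- array(rep(img, in_channels),
                 c(nrow(img), ncol(img), in_channels))
  }
  if (dim(img)[3] != in_channels) {
    abort(sprintf("image has %d channels; the network expects %d",
                  dim(img)[3], in_channels))
  }
  img
}

flip_h <- function(m) {
  if (is.matrix(m)) m[, ncol(m):1, drop = FALSE]
  else m[, dim(m)[2]:1, , drop = FALSE]
}

# per-pixel argmax with ties broken toward the earliest class (background)
prob_to_mask <- function(prob) {
  k <- dim(prob)[3]
  best_p <- prob[, , 1]
  cls <- matrix(0, nrow(best_p), ncol(best_p))
  for (c in seq_len(k - 1)) {
    p <- prob[, , c + 1]
    take <- p > best_p           # strict: ties keep the earlier class
    cls[take] <- c
    best_p[take] <- p[take]
  }
  (cls > 0) * 1
}

adam_step <- function(model, grads, opt, config) {
  opt$t <- (opt$t %||% 0L) + 1L
  b1 <- config$beta1; b2 <- config$beta2
  lr <- config$learning_rate
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (config$weight_decay > 0 && grepl("\\.w$", nm)) {
      g <- g + config$weight_decay * model$params[[nm]]
    }
    mk <- paste0("m.", nm); vk <- paste0("v.", nm)
    m <- (opt[[mk]] %||% 0) * b1 + (1 - b1) * g
    v <- (opt[[vk]] %||% 0) * b2 + (1 - b2) * g^2
    opt[[mk]] <- m; opt[[vk]] <- v
    model$params[[nm]] <- model$params[[nm]] -
      lr * (m / bc1) / (sqrt(v / bc2) + 1e-8)
  }
}

snapshot_params <- function(model) {
  list(params = as.list(model$params), state = as.list(model$state))
}

restore_params <- function(model, snap) {
  for (nm in names(snap$params)) model$params[[nm]] <- snap$params[[nm]]
  for (nm in names(snap$state)) model$state[[nm]] <- snap$state[[nm]]
}

val_dsc1 <- function(model, data, chunk = 8L) {
  cin <- model$config$in_channels
  preds <- list()
  for (b0 in seq(1, nrow(data), by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, nrow(data))
    imgs <- lapply(data$image[idx], as_input_array, in_channels = cin)
    d1 <- dim(imgs[[1]])
    x <- array(0, c(d1[1], d1[2], cin, length(idx)))
    for (j in seq_along(idx)) x[, , , j] <- imgs[[j]]
    prob <- network_forward(model, x, training = FALSE)
    for (j in seq_along(idx)) {
      preds[[idx[j]]] <- prob_to_mask(prob[, , , j])
    }
  }
  dice(preds, data$mask)$dsc1
}

#' Train the segmentation network
#'
#' Minimizes the configured cross-entropy variant with Adam, monitors
#' DSC1 on the validation set after every epoch, stops once it has not
#' improved for `patience` consecutive epochs, and restores the weights of
#' the best epoch (earliest epoch on ties). Fully reproducible given
#' `config$seed`.
#'
#' @param model a `ptx_network` from [build_network()].
#' @param train_data,val_data tibbles with `image` and `mask` list columns
#'   (e.g. from [generate_phantom_set()] or [load_dataset()]).
#' @param config a [training_config()].
#' @return a `ptx_training` object: the trained model plus a per-epoch
#'   `history` tibble (`epoch`, `loss`, `val_dsc1`, `patience_left`,
#'   `best`). The model's parameters are updated in place as well.
#' @export
train <- function(model, train_data, val_data,
                  config = training_config()) {
  stopifnot(inherits(model, "ptx_network"),
            inherits(config, "ptx_training_config"))
  if (nrow(train_data) == 0 || nrow(val_data) == 0) {
    abort("training and validation sets must be non-empty")
  }
  withr::local_seed(config$seed)
  cin <- model$config$in_channels
  imgs <- lapply(train_data$image, as_input_array, in_channels = cin)
  masks <- lapply(train_data$mask, check_binary_mask)
  wmaps <- lapply(masks, compute_weight_map,
                  iterations = config$dilate_iterations,
                  mode = config$loss_mode)
  opt <- new.env(parent = emptyenv())
  n <- length(imgs)
  best <- -Inf
  best_epoch <- 0L
  best_snap <- snapshot_params(model)
  history <- vector("list", config$max_epochs)
  stopped <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(n)
    losses <- c()
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
      bs <- length(idx)
      d1 <- dim(imgs[[1]])
      x <- array(0, c(d1[1], d1[2], cin, bs))
      tgt <- array(0, c(d1[1], d1[2], bs))
      w <- array(0, c(d1[1], d1[2], bs))
      for (j in seq_len(bs)) {
        im <- imgs[[idx[j]]]; mk <- masks[[idx[j]]]; wm <- wmaps[[idx[j]]]
        if (runif(1) < config$flip_prob) {
          im <- flip_h(im); mk <- flip_h(mk); wm <- flip_h(wm)
        }
        x[, , , j] <- im; tgt[, , j] <- mk; w[, , j] <- wm
      }
      tape <- new_tape(training = TRUE)
      logits <- network_graph(model, tape, op_input(tape, x))
      loss <- op_wce_softmax(tape, logits, tgt, w,
                             reduction = config$reduction)
      if (!is.finite(loss$value)) {
        abort(sprintf("non-finite loss at epoch %d (value %s)",
                      epoch, format(loss$value)))
      }
      tape_backward(tape, loss)
      adam_step(model, tape_param_grads(tape), opt, config)
      losses <- c(losses, loss$value)
    }
    vd <- val_dsc1(model, val_data)
    improved <- vd > best
    if (improved) {
      best <- vd
      best_epoch <- epoch
      best_snap <- snapshot_params(model)
    }
    since <- epoch - best_epoch
    history[[epoch]] <- tibble(epoch = epoch, loss = mean(losses),
                               val_dsc1 = vd,
                               patience_left = config$patience - since,
                               best = improved)
    if (config$verbose) {
      message(sprintf("epoch %3d | loss %.4f | val DSC1 %.4f | patience %d/%d",
                      epoch, mean(losses), vd, since, config$patience))
    }
    if (since >= config$patience && epoch > best_epoch) {
      stopped <- epoch
      break
    }
    stopped <- epoch
  }
  restore_params(model, best_snap)
  structure(list(model = model,
                 history = dplyr::bind_rows(history),
                 best_epoch = best_epoch,
                 best_val_dsc1 = best,
                 stopped_epoch = stopped,
                 config = config),
            class = "ptx_training")
}

#' @export
print.ptx_training <- function(x, ...) {
  cat("<ptx_training>\n")
  cat(sprintf("  epochs run: %d (best epoch %d, val DSC1 %.4f)\n",
              x$stopped_epoch, x$best_epoch, x$best_val_dsc1))
  invisible(x)
}

#' Predict a segmentation mask
#'
#' Runs the network in inference mode and takes the per-pixel class with
#' the highest probability; exact ties break toward background, so a
#' lesion call requires its probability to strictly exceed every other
#' class.
#'
#' @param object a `ptx_network`.
#' @param image `(H, W)` matrix or `(H, W, C)` array.
#' @param ... unused.
#' @return list with `mask` (binary matrix) and `prob`
#'   (`(H, W, num_classes)` probability array).
#' @export
predict.ptx_network <- function(object, image, ...) {
  img <- as_input_array(image, object$config$in_channels)
  prob <- network_forward(object, img, training = FALSE)
  list(mask = prob_to_mask(prob), prob = prob)
}

#' Pixel-count diagnosis rule
#'
#' Calls an image pneumothorax-positive when its predicted lesion mask has
#' strictly more positive pixels than `threshold` (default 50; counts at
#' the mask's own resolution).
#'
#' @param mask binary predicted mask, or a list of them.
#' @param threshold non-negative pixel-count threshold.
#' @param ids optional image identifiers.
#' @return tibble with `id`, `positive_pixels`, `call`, `threshold`.
#' @export
diagnose <- function(mask, threshold = 50, ids = NULL) {
  if (threshold < 0) abort("`threshold` must be non-negative")
  masks <- as_mask_list(mask, "mask")
  ids <- ids %||% seq_along(masks)
  purrr::map_dfr(seq_along(masks), function(i) {
    np <- sum(masks[[i]] == 1)
    tibble(id = ids[i], positive_pixels = np,
           call = if (np > threshold) "PTX" else "NonPTX",
           threshold = threshold)
  })
}

#' End-to-end evaluation
#'
#' Predicts every image, scores the segmentations (PA1, DSC1, Hausdorff
#' contour distance per image; MPA/DSC over images and classes), applies
#' the pixel-count diagnosis rule and tallies the diagnostic metrics.
#' Hausdorff values are undefined (NA) when either contour is empty and
#' are excluded from the aggregates.
#'
#' @param model a `ptx_network`.
#' @param data tibble with `id`, `image`, `mask`, `label` columns.
#' @param threshold diagnosis pixel-count threshold.
#' @param out_dir optional; when given, writes `report.csv` (per image)
#'   and `summary.json`.
#' @return a `ptx_evaluation` list: `per_image`, `summary`, `confusion`,
#'   `diagnostics`.
#' @export
evaluate <- function(model, data, threshold = 50, out_dir = NULL) {
  if (nrow(data) == 0) abort("evaluation set must be non-empty")
  preds <- lapply(data$image, function(img) predict(model, img)$mask)
  per_image <- segmentation_report(preds, data$mask, ids = data$id)
  dg <- diagnose(preds, threshold = threshold, ids = data$id)
  per_image$positive_pixels <- dg$positive_pixels
  per_image$call <- dg$call
  per_image$label <- data$label
  pa <- pixel_accuracy(preds, data$mask)
  dc <- dice(preds, data$mask)
  cc <- confusion(data$label, dg$call)
  dm <- diagnostic_metrics(cc)
  hd_ok <- per_image$hd[!is.na(per_image$hd)]
  summary <- list(
    n = nrow(data),
    mpa = pa$mpa, pa1 = pa$pa1, pa1_sd = sd(pa$per_image$accuracy[
      pa$per_image$class == 1L]),
    dsc = dc$dsc, dsc1 = dc$dsc1, dsc1_sd = sd(dc$per_image$dsc[
      dc$per_image$class == 1L]),
    hd_mean = if (length(hd_ok)) mean(hd_ok) else NA_real_,
    hd_max = if (length(hd_ok)) max(hd_ok) else NA_real_,
    hd_defined = length(hd_ok),
    diagnostics = dm)
  out <- structure(list(per_image = per_image, summary = summary,
                        confusion = cc, diagnostics = dm),
                   class = "ptx_evaluation")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_image, file.path(out_dir, "report.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.ptx_evaluation <- function(x, ...) {
  s <- x$summary
  cat("<ptx_evaluation>", s$n, "images\n")
  cat(sprintf("  MPA %.3f | PA1 %.3f | DSC %.3f | DSC1 %.3f\n",
              s$mpa, s$pa1, s$dsc, s$dsc1))
  cat(sprintf("  HD max(mean) %.2f(%.2f) over %d images with contours\n",
              s$hd_max, s$hd_mean, s$hd_defined))
  d <- x$diagnostics
  cat(sprintf("  accuracy %.2f%% | sens %.2f%% | spec %.2f%% | F1 %.2f%%\n",
              d$accuracy, d$sensitivity, d$specificity, d$f1))
  invisible(x)
}
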