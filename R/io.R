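# Manifest and PNG I/O, checkpoints.

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `image_path`, `mask_path` (may be
#' empty for lesion-free images), `label` (`"PTX"`/`"NonPTX"`) and
#' optionally `split`.
#'
#' @param path manifest CSV path.
#' @return tibble with the manifest columns.
#' @export
read_manifest <- function(path) {
  m <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character"))
  need <- c("image_path", "mask_path", "label")
  if (!all(need %in% names(m))) {
    abort(sprintf("manifest must have columns %s",
                  paste(need, collapse = ", ")))
  }
  m
}

read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}

#' Load manifest images and masks into memory
#'
#' Reads every image (grayscale, `[0, 1]`) and mask (binarized at 0.5;
#' all-zero when `mask_path` is empty). Missing files are reported
#' together in one error.
#'
#' @param manifest tibble from [read_manifest()] or [generate_dataset()].
#' @param base_dir directory the manifest paths are relative to.
#' @param split optional split name to filter on.
#' @return tibble with `id`, `image`, `mask` (list columns) and `label`.
#' @export
load_dataset <- function(manifest, base_dir = ".", split = NULL) {
  if (!is.null(split) && "split" %in% names(manifest)) {
    manifest <- manifest[manifest$split %in% split, , drop = FALSE]
  }
  paths <- file.path(base_dir, manifest$image_path)
  mpaths <- ifelse(manifest$mask_path == "", NA,
                   file.path(base_dir, manifest$mask_path))
  missing <- c(paths[!file.exists(paths)],
               stats::na.omit(mpaths[!is.na(mpaths) & !file.exists(mpaths)]))
  if (length(missing)) {
    abort(paste0("missing files:\n", paste(" -", missing, collapse = "\n")))
  }
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    img <- read_gray_png(paths[i])
    mask <- if (is.na(mpaths[i])) {
      matrix(0, nrow(img), ncol(img))
    } else {
      (read_gray_png(mpaths[i]) > 0.5) * 1
    }
    tibble(id = sub("\\.png$", "", basename(manifest$image_path[i])),
           image = list(img), mask = list(mask),
           label = manifest$label[i])
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized file with all weights and
#' batch-norm state, plus a human-readable JSON sidecar
#' (`<path>.json`) recording the full network configuration, so parameter
#' counts and shapes are reproducible exactly.
#'
#' @param model a `ptx_network`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` the path, invisibly; `load_checkpoint` the
#'   restored `ptx_network`.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(config = unclass(model$config),
                  param_names = model$param_names,
                  params = as.list(model$params),
                  state = as.list(model$state))
  saveRDS(payload, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  cfg <- payload$config
  config <- network_config(
    growth_rate = cfg$growth_rate,
    layers_per_block = c(cfg$down_blocks, cfg$bottleneck),
    initial_channels = cfg$initial_channels,
    in_channels = cfg$in_channels,
    multiscale = cfg$multiscale,
    ms_kernels = cfg$ms_kernels,
    ms_filters_per_branch = cfg$ms_filters_per_branch,
    dropout = cfg$dropout,
    num_classes = cfg$num_classes,
    scse = cfg$scse,
    scse_reduction = cfg$scse_reduction)
  params <- new.env(parent = emptyenv())
  for (nm in names(payload$params)) params[[nm]] <- payload$params[[nm]]
  state <- new.env(parent = emptyenv())
  for (nm in names(payload$state)) state[[nm]] <- payload$state[[nm]]
  structure(list(config = config, params = params,
                 param_names = payload$param_names, state = state),
            class = "ptx_network")
}
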