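#' Read and write grayscale raster images
#'
#' Supported formats by extension: `.png` (8-bit grayscale; 16-bit PNGs are
#' read), `.tif`/`.tiff` (8- or 16-bit grayscale), and `.txt`/`.dat`
#' numeric grids (whitespace-separated rows, lossless at full double
#' precision). Color inputs are rejected explicitly rather than silently
#' converted. Images are returned as [raster_image] objects whose value
#' range matches the file's bit depth (text grids keep their values as-is).
#'
#' @param path file path.
#' @param image a [raster_image] or matrix (matrices get their range
#'   inferred).
#' @param bits bit depth for raster output: 8 or 16 (16 requires TIFF).
#' @return `load_image` returns a [raster_image]; `save_image` returns
#'   `path` invisibly.
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    depth_max <- 255  # readPNG rescales to [0,1]; keep 8-bit quantization
    if (length(dim(a)) == 3) {
      if (dim(a)[3] == 2) a <- a[, , 1] else
        stop("color PNG not supported (grayscale only): ", path, call. = FALSE)
    }
    raster_image(round(a * depth_max), c(0, depth_max))
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(a, "bits.per.sample") %||% 8
    if (length(dim(a)) == 3) {
      if (dim(a)[3] == 2) a <- a[, , 1] else
        stop("color TIFF not supported (grayscale only): ", path, call. = FALSE)
    }
    mx <- 2^bits - 1
    raster_image(matrix(round(a * mx), nrow(a), ncol(a)), c(0, mx))
  } else if (ext %in% c("txt", "dat")) {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
    raster_image(m)
  } else {
    stop("unsupported image format '", ext, "': ", path, call. = FALSE)
  }
}

#' @rdname load_image
#' @export
save_image <- function(image, path, bits = 8) {
  ext <- tolower(tools::file_ext(path))
  img <- if (inherits(image, "raster_image")) image else raster_image(image)
  vr <- img$value_range
  norm <- (img$pixels - vr[1]) / (vr[2] - vr[1])
  if (ext == "png") {
    if (bits != 8)
      stop("PNG output is 8-bit; use TIFF for 16-bit", call. = FALSE)
    png::writePNG(round(norm * 255) / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!bits %in% c(8, 16)) stop("'bits' must be 8 or 16", call. = FALSE)
    mx <- 2^bits - 1
    tiff::writeTIFF(round(norm * mx) / mx, path, bits.per.sample = bits)
  } else if (ext %in% c("txt", "dat")) {
    utils::write.table(img$pixels, path, row.names = FALSE, col.names = FALSE)
  } else {
    stop("unsupported image format '", ext, "': ", path, call. = FALSE)
  }
  invisible(path)
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys (all offenders
#' listed at once), enforces that exactly one segmenter is configured, and
#' fills defaults: EM tolerance 0.001, learning rate 0.001, batch size 32,
#' 70/15/15 split, seed 1. See the packaged example under
#' `system.file("examples", "em-run.yaml", package = "ctmixseg")`.
#'
#' @param path YAML file, or a list already in memory.
#' @return validated configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  known_top <- c("input", "synthetic", "preprocess", "segmenter",
                 "evaluation", "output_dir", "seed", "log_level")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$segmenter) || is.null(cfg$segmenter$method))
    stop("configuration must select a segmenter method", call. = FALSE)
  if (length(cfg$segmenter$method) != 1 ||
      !cfg$segmenter$method %in% c("em", "network"))
    stop("segmenter method must be exactly one of 'em' or 'network'",
         call. = FALSE)
  if (!is.null(cfg$input) && !is.null(cfg$synthetic))
    stop("give either 'input' paths or a 'synthetic' block, not both",
         call. = FALSE)
  if (!is.null(cfg$synthetic)) {
    known_syn <- c("n_samples", "size", "n_nodules", "nodule_radius",
                   "tissue", "noise_sd", "value_range")
    bad_syn <- setdiff(names(cfg$synthetic), known_syn)
    if (length(bad_syn))
      stop("unknown synthetic key(s): ", paste(bad_syn, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(cfg$input)) {
    missing_ <- cfg$input$images[!file.exists(cfg$input$images)]
    if (length(missing_))
      stop("input image(s) not found: ", paste(missing_, collapse = ", "),
           call. = FALSE)
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$log_level <- cfg$log_level %||% "info"
  if (cfg$segmenter$method == "em") {
    cfg$segmenter$tol <- cfg$segmenter$tol %||% 1e-3
    cfg$segmenter$max_iter <- cfg$segmenter$max_iter %||% 500L
    cfg$segmenter$shape <- cfg$segmenter$shape %||% 4
  } else {
    cfg$segmenter$learning_rate <- cfg$segmenter$learning_rate %||% 0.001
    cfg$segmenter$batch_size <- cfg$segmenter$batch_size %||% 32L
    cfg$segmenter$epochs <- cfg$segmenter$epochs %||% 100L
    cfg$segmenter$split <- cfg$segmenter$split %||% c(0.70, 0.15, 0.15)
    cfg$segmenter$depth <- cfg$segmenter$depth %||% 5L
    cfg$segmenter$base_filters <- cfg$segmenter$base_filters %||% 8L
  }
  cfg$evaluation$metrics <- cfg$evaluation$metrics %||%
    c("dice", "iou", "pri", "voi", "gce")
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# resolve configured samples into list(image=, mask= or NULL) pairs
gather_samples <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    sp <- do.call(phantom_spec, cfg$synthetic[setdiff(names(cfg$synthetic),
                                                      "n_samples")])
    n <- cfg$synthetic$n_samples %||% 10L
    samples <- make_dataset(sp, n, seed = cfg$seed)
    lapply(samples, function(s)
      list(image = raster_image(s$image, sp$value_range), mask = s$mask))
  } else if (!is.null(cfg$input)) {
    imgs <- lapply(cfg$input$images, load_image)
    msks <- if (!is.null(cfg$input$masks))
      lapply(cfg$input$masks, function(p) px(load_image(p)))
    else vector("list", length(imgs))
    Map(function(i, m) list(image = i, mask = m), imgs, msks)
  } else {
    stop("configuration provides neither 'input' nor 'synthetic'",
         call. = FALSE)
  }
}

#' Run the EM segmentation pipeline
#'
#' For each configured sample: preprocess, estimate the segment count from
#' the intensity histogram (unless `segmenter$k` fixes it), fit the
#' logistic-type mixture by EM, classify pixels by maximum posterior,
#' relabel to the ground truth when a mask is available, and score the
#' configured metrics. Per-sample failures are recorded and skipped; an
#' all-failed run is an error.
#'
#' @param config a `run_config` (or path/list accepted by [load_config()])
#'   with `segmenter$method == "em"`.
#' @return list of class `run_report`: `samples` (long metric data frame),
#'   `aggregate`, `segmentations`, `failures`, `provenance`.
#' @export
run_em_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  if (cfg$segmenter$method != "em")
    stop("run_em_pipeline needs segmenter method 'em'", call. = FALSE)
  samples <- gather_samples(cfg)
  rows <- list(); segs <- list(); failures <- character(0)
  for (i in seq_along(samples)) {
    res <- try({
      img <- preprocess_pipeline(samples[[i]]$image, cfg$preprocess)
      pxs <- px(img)
      k <- cfg$segmenter$k %||% estimate_k(pxs)
      fit <- ltmix(pxs, K = k, shape = cfg$segmenter$shape,
                   control = ltmix_control(tol = cfg$segmenter$tol,
                                           max_iter = cfg$segmenter$max_iter,
                                           seed = cfg$seed))
      seg <- predict(fit, type = "class")
      truth <- samples[[i]]$mask
      if (!is.null(truth)) {
        if (all(dim(seg) == dim(truth))) seg <- relabel_to_truth(seg, truth)
        mets <- evaluate_masks(seg, truth, metrics = cfg$evaluation$metrics,
                               roi = cfg$evaluation$roi)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = i, metric = names(mets), value = unname(mets))
      }
      segs[[length(segs) + 1]] <- seg
      TRUE
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      failures <- c(failures, paste0("sample ", i, ": ",
                                     conditionMessage(attr(res, "condition"))))
  }
  if (length(failures) == length(samples))
    stop("every sample failed:\n", paste(failures, collapse = "\n"),
         call. = FALSE)
  per_sample <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = integer(0), metric = character(0),
               value = numeric(0))
  structure(list(samples = per_sample,
                 aggregate = if (nrow(per_sample))
                   aggregate_report(per_sample) else NULL,
                 segmentations = segs, failures = failures,
                 provenance = run_provenance(cfg)),
            class = "run_report")
}

run_provenance <- function(cfg) {
  plain <- unclass(cfg)
  list(config_hash = config_hash(plain), seed = cfg$seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       package_version = as.character(utils::packageVersion("ctmixseg")))
}

# small stable content hash (djb2 over the serialized config text)
config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (ch in s) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Train and evaluate the network pipeline
#'
#' `run_train` splits the configured dataset per the configured fractions,
#' trains the network on the training set with validation-set
#' checkpointing, and returns the fit plus the split. `run_eval` scores a
#' fit (or its checkpoint) on the held-out test set with the configured
#' metrics.
#'
#' @param config a `run_config` with `segmenter$method == "network"`.
#' @return `run_train`: list of class `train_run` (`fit`, `split`,
#'   `samples`, `config`). `run_eval`: a `run_report`.
#' @export
run_train <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  if (cfg$segmenter$method != "network")
    stop("run_train needs segmenter method 'network'", call. = FALSE)
  samples <- gather_samples(cfg)
  prep <- lapply(samples, function(s) {
    img <- preprocess_pipeline(s$image, cfg$preprocess)
    list(image = px(normalize01(img)), mask = s$mask)
  })
  sz <- dim(prep[[1]]$image)
  tc <- train_config(learning_rate = cfg$segmenter$learning_rate,
                     batch_size = cfg$segmenter$batch_size,
                     epochs = cfg$segmenter$epochs,
                     split_fractions = cfg$segmenter$split,
                     seed = cfg$seed)
  split <- split_dataset(length(prep), tc)
  spec <- unet_spec(input_size = sz, depth = cfg$segmenter$depth,
                    base_filters = cfg$segmenter$base_filters,
                    dropout_rate = cfg$segmenter$dropout_rate %||% 0.5,
                    l2_lambda = cfg$segmenter$l2_lambda %||% 0.001)
  model <- build_unet(spec, seed = cfg$seed)
  binmask <- function(m) matrix(as.integer(m > 0), nrow(m), ncol(m))
  fit <- train_unet(model,
                    images = lapply(prep[split$train], `[[`, "image"),
                    masks = lapply(prep[split$train],
                                   function(s) binmask(s$mask)),
                    config = tc,
                    val_images = lapply(prep[split$val], `[[`, "image"),
                    val_masks = lapply(prep[split$val],
                                       function(s) binmask(s$mask)))
  structure(list(fit = fit, split = split, samples = prep, config = cfg),
            class = "train_run")
}

#' @rdname run_train
#' @param train_run the result of [run_train()].
#' @export
run_eval <- function(train_run) {
  stopifnot(inherits(train_run, "train_run"))
  cfg <- train_run$config
  rows <- list()
  binmask <- function(m) matrix(as.integer(m > 0), nrow(m), ncol(m))
  for (i in train_run$split$test) {
    s <- train_run$samples[[i]]
    pr <- predict_mask(train_run$fit, s$image,
                       threshold = train_run$fit$config$threshold)
    mets <- evaluate_masks(pr$mask, binmask(s$mask),
                           metrics = cfg$evaluation$metrics,
                           roi = cfg$evaluation$roi)
    rows[[length(rows) + 1]] <- data.frame(sample_id = i,
                                           metric = names(mets),
                                           value = unname(mets))
  }
  per_sample <- do.call(rbind, rows)
  structure(list(samples = per_sample,
                 aggregate = aggregate_report(per_sample),
                 segmentations = NULL, failures = character(0),
                 provenance = c(run_provenance(cfg),
                                list(test_indices = train_run$split$test))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report: ", length(unique(x$samples$sample_id)), " scored sample(s), ",
      length(x$failures), " failure(s)\n", sep = "")
  if (!is.null(x$aggregate)) print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Write a tidy metrics CSV
#'
#' Long per-sample rows (`sample_id`, `metric`, `value`) followed by
#' aggregate rows (`sample_id = "aggregate"`, value = mean, plus a `sd`
#' column), in a stable ordering, so the aggregate is recomputable from
#' the file.
#'
#' @param report a `run_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  ps <- report$samples
  ps <- ps[order(ps$sample_id, ps$metric), , drop = FALSE]
  out <- data.frame(sample_id = as.character(ps$sample_id),
                    metric = ps$metric, value = ps$value,
                    sd = NA_real_)
  if (!is.null(report$aggregate)) {
    ag <- report$aggregate
    out <- rbind(out, data.frame(sample_id = "aggregate", metric = ag$metric,
                                 value = ag$mean, sd = ag$sd))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
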