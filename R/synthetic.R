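#' Phantom specification
#'
#' Settings for the synthetic lung-slice generator. A phantom is a darker
#' body background carrying two ellipse "lung fields" that contain bright
#' disc nodules; the pixel intensities of each tissue class are drawn from
#' its own logistic-type distribution, plus optional additive Gaussian
#' noise, clamped to the declared value range. The default class
#' intensities place the lung interior near 60.5 and the surrounding
#' tissue near 122 (the two-component intensity regime the mixture model
#' targets), with nodules brighter still.
#'
#' @param size `c(h, w)` image size in pixels.
#' @param n_nodules integer range `c(min, max)` of nodules per phantom.
#' @param nodule_radius range `c(min, max)` of nodule radii in pixels.
#' @param tissue named list of logistic-type parameter lists
#'   (`location`, `scale`, `shape`) for `background`, `lung`, `nodule`.
#' @param noise_sd standard deviation of additive Gaussian sensor noise.
#' @param value_range intensity encoding range.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(128, 128),
                         n_nodules = c(1, 3),
                         nodule_radius = c(4, 10),
                         tissue = list(
                           background = list(location = 121.98,
                                             scale = sqrt(128.784), shape = 4),
                           lung = list(location = 60.54,
                                       scale = sqrt(94.2568), shape = 4),
                           nodule = list(location = 185,
                                         scale = 8, shape = 4)),
                         noise_sd = 2,
                         value_range = c(0, 255)) {
  stopifnot(length(size) == 2, all(size >= 16),
            length(n_nodules) == 2, n_nodules[1] <= n_nodules[2],
            n_nodules[1] >= 0,
            length(nodule_radius) == 2,
            nodule_radius[1] <= nodule_radius[2], nodule_radius[1] > 0,
            noise_sd >= 0,
            all(c("background", "lung", "nodule") %in% names(tissue)))
  structure(list(size = as.integer(size), n_nodules = as.integer(n_nodules),
                 nodule_radius = nodule_radius, tissue = tissue,
                 noise_sd = noise_sd, value_range = as.numeric(value_range)),
            class = "phantom_spec")
}

#' Draw a region-labeled mixture image
#'
#' Fills a given label layout with per-pixel draws from the mixture
#' component of each region: label `k - 1` (0-based) takes component `k` of
#' `params`. This reproduces, image-side, the modeling assumption that each
#' image sector carries its own logistic-type intensity distribution.
#'
#' @param params an [ltmix_params] object.
#' @param layout integer matrix of 0-based region labels in
#'   `0..K-1`.
#' @param seed integer seed.
#' @return list of class `labeled_sample`: `image` (matrix), `mask`
#'   (the layout), `truth_params`, `seed`.
#' @export
generate_mixture_image <- function(params, layout, seed = NULL) {
  stopifnot(inherits(params, "ltmix_params"), is.matrix(layout))
  labs <- sort(unique(as.vector(layout)))
  if (any(labs < 0) || any(labs > params$K - 1))
    stop("layout labels must lie in 0..K-1 of the mixture", call. = FALSE)
  img <- with_seed(seed, {
    out <- matrix(0, nrow(layout), ncol(layout))
    for (lb in labs) {
      idx <- which(layout == lb)
      i <- lb + 1
      out[idx] <- rltype(length(idx), params$locations[i], params$scales[i],
                         params$shape)
    }
    out
  })
  structure(list(image = img, mask = layout, truth_params = params,
                 seed = seed),
            class = "labeled_sample")
}

#' Generate a lung phantom with nodules
#'
#' Builds one synthetic slice per `spec`: two seeded-jitter ellipse lung
#' fields on a body background, `n_nodules` discs placed fully inside the
#' lung fields (100 rejection attempts per nodule before erroring), class
#' intensities drawn from the spec's logistic-type distributions, additive
#' Gaussian noise, and clamping to the value range. Mask labels: 0 =
#' background, 1 = lung field, 2 = nodule.
#'
#' @param spec a [phantom_spec].
#' @param seed integer seed; fixed seed + spec gives an identical phantom.
#' @return a `labeled_sample` (`image`, `mask`, `truth_params`, `seed`).
#' @export
generate_lung_phantom <- function(spec = phantom_spec(), seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    h <- spec$size[1]; w <- spec$size[2]
    mask <- matrix(0L, h, w)
    ii <- rep(seq_len(h), times = w)
    jj <- rep(seq_len(w), each = h)
    for (side in c(-1, 1)) {
      cy <- h * (0.52 + stats::runif(1, -0.02, 0.02))
      cx <- w * (0.5 + side * (0.24 + stats::runif(1, -0.02, 0.02)))
      ry <- h * stats::runif(1, 0.28, 0.34)
      rx <- w * stats::runif(1, 0.13, 0.17)
      th <- stats::runif(1, -0.1, 0.1)
      di <- ii - cy; dj <- jj - cx
      u <- cos(th) * dj + sin(th) * di
      v <- -sin(th) * dj + cos(th) * di
      inside <- (u / rx)^2 + (v / ry)^2 <= 1
      mask[cbind(ii[inside], jj[inside])] <- 1L
    }
    n_nod <- if (spec$n_nodules[1] == spec$n_nodules[2]) spec$n_nodules[1]
             else sample(seq(spec$n_nodules[1], spec$n_nodules[2]), 1)
    lung_idx <- which(mask == 1L)
    for (k in seq_len(n_nod)) {
      placed <- FALSE
      for (attempt in seq_len(100)) {
        r <- stats::runif(1, spec$nodule_radius[1], spec$nodule_radius[2])
        ctr <- lung_idx[sample.int(length(lung_idx), 1)]
        cy <- (ctr - 1) %% h + 1
        cx <- (ctr - 1) %/% h + 1
        disc <- (ii - cy)^2 + (jj - cx)^2 <= r^2
        if (all(mask[disc] >= 1L)) {      # fully inside a lung field
          mask[disc] <- 2L
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place a nodule of the requested radius inside a ",
             "lung field after 100 attempts", call. = FALSE)
    }
    img <- matrix(0, h, w)
    classes <- c("background", "lung", "nodule")
    for (lb in 0:2) {
      idx <- which(mask == lb)
      if (!length(idx)) next
      td <- spec$tissue[[classes[lb + 1]]]
      img[idx] <- rltype(length(idx), td$location, td$scale,
                         td$shape %||% 4)
    }
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(h * w, 0, spec$noise_sd)
    img <- pmin(pmax(img, spec$value_range[1]), spec$value_range[2])
    dim(img) <- c(h, w)
    cnt <- pmax(tabulate(as.vector(mask) + 1L, 3), 1)
    truth <- ltmix_params(
      weights = cnt / sum(cnt),
      locations = vapply(classes, function(cl) spec$tissue[[cl]]$location,
                         numeric(1)),
      scales = vapply(classes, function(cl) spec$tissue[[cl]]$scale,
                      numeric(1)),
      shape = spec$tissue$lung$shape %||% 4)
    structure(list(image = img, mask = mask, truth_params = truth,
                   seed = seed),
              class = "labeled_sample")
  })
}

#' Generate a seeded phantom dataset
#'
#' `n` phantoms with derived per-sample seeds `seed + i`, so any sample is
#' reproducible in isolation.
#'
#' @param spec a [phantom_spec].
#' @param n number of samples.
#' @param seed base integer seed.
#' @return list of `labeled_sample` objects.
#' @export
make_dataset <- function(spec = phantom_spec(), n, seed = 1) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) generate_lung_phantom(spec, seed = seed + i))
}

#' @export
print.labeled_sample <- function(x, ...) {
  cat("labeled_sample ", nrow(x$image), " x ", ncol(x$image),
      ", labels {", paste(sort(unique(as.vector(x$mask))), collapse = ", "),
      "}, seed ", x$seed %||% NA, "\n", sep = "")
  invisible(x)
}
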