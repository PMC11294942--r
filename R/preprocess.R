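#' Raster images
#'
#' Thin container for a 2-D grayscale image: a numeric matrix of pixel
#' intensities plus the declared value range of its encoding (e.g. `c(0,
#' 255)` for 8-bit, `c(0, 65535)` for 16-bit, `c(0, 1)` for normalized
#' data). Most functions in the package also accept a bare matrix, in which
#' case the range is inferred: `[0,1]` if no pixel exceeds 1, otherwise
#' `[0,255]` or `[0,65535]` by the observed maximum.
#'
#' @param pixels numeric matrix (rows = image rows).
#' @param value_range length-2 numeric, `c(min, max)` of the encoding.
#' @return an object of class `raster_image`.
#' @export
raster_image <- function(pixels, value_range = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1 || ncol(pixels) < 1)
    stop("image must be at least 1 x 1", call. = FALSE)
  if (is.null(value_range)) value_range <- infer_range(pixels)
  if (length(value_range) != 2 || value_range[2] <= value_range[1])
    stop("'value_range' must be c(min, max) with max > min", call. = FALSE)
  if (any(pixels < value_range[1] - 1e-9) || any(pixels > value_range[2] + 1e-9))
    stop("pixels fall outside the declared value_range", call. = FALSE)
  structure(list(pixels = pixels, value_range = as.numeric(value_range)),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat("raster_image ", nrow(x$pixels), " x ", ncol(x$pixels),
      ", range [", x$value_range[1], ", ", x$value_range[2], "]\n", sep = "")
  invisible(x)
}

infer_range <- function(m) {
  mn <- min(m); mx <- max(m)
  if (mn >= 0 && mx <= 1) c(0, 1)
  else if (mn >= 0 && mx <= 255) c(0, 255)
  else if (mn >= 0 && mx <= 65535) c(0, 65535)
  else if (mx > mn) c(mn, mx)               # signed / unusual data: observed range
  else c(mn, mn + 1)
}

px <- function(img) if (inherits(img, "raster_image")) img$pixels else img

vrange <- function(img, value_range = NULL) {
  if (!is.null(value_range)) return(as.numeric(value_range))
  if (inherits(img, "raster_image")) img$value_range else infer_range(px(img))
}

rewrap <- function(img, pixels, value_range = NULL) {
  if (inherits(img, "raster_image"))
    raster_image(pixels, value_range %||% img$value_range)
  else pixels
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hounsfield display windowing
#'
#' Maps a CT image in Hounsfield units linearly onto `[0, 1]`: intensities
#' at `center - width/2` and below go to 0, `center + width/2` and above to
#' 1. Presets: `"lung"` = center -600 HU, width 1500 HU; `"soft_tissue"` =
#' center 50 HU, width 400 HU (the standard lung and soft-tissue display
#' windows).
#'
#' @param image matrix or `raster_image` in Hounsfield units.
#' @param center window center in HU, or a preset name.
#' @param width window width in HU (ignored when `center` is a preset).
#' @return image in `[0, 1]` (same container as the input).
#' @examples
#' hounsfield_window(matrix(c(-1350, -600, 150), 1), "lung")
#' @export
hounsfield_window <- function(image, center = "lung", width = NULL) {
  if (is.character(center)) {
    preset <- match.arg(center, c("lung", "soft_tissue"))
    w <- switch(preset, lung = c(-600, 1500), soft_tissue = c(50, 400))
    center <- w[1]; width <- w[2]
  }
  if (is.null(width) || width <= 0) stop("'width' must be > 0", call. = FALSE)
  m <- (px(image) - (center - width / 2)) / width
  out <- pmin(pmax(m, 0), 1)
  dim(out) <- dim(px(image))
  rewrap(image, out, value_range = c(0, 1))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Classic CLAHE: the image is divided into a grid of tiles; each tile's
#' intensity histogram (over `n_bins` bins spanning the declared value
#' range) is clipped at `clip_limit` times the tile pixel count, the excess
#' is redistributed uniformly over all bins, and each pixel is remapped by
#' bilinear interpolation between the equalization mappings of the four
#' surrounding tile centers. Output stays in the declared value range.
#'
#' @param image matrix or `raster_image`.
#' @param tiles `c(rows, cols)` of the tile grid.
#' @param clip_limit histogram clip level, as a fraction of the per-tile
#'   pixel count (each bin is clipped at `clip_limit * tile_pixels`).
#' @param n_bins number of histogram bins.
#' @param value_range declared encoding range; inferred if `NULL`.
#' @return equalized image, same container as the input.
#' @export
clahe <- function(image, tiles = c(8, 8), clip_limit = 0.01, n_bins = 256,
                  value_range = NULL) {
  m <- px(image)
  vr <- vrange(image, value_range)
  if (length(tiles) != 2 || any(tiles < 1)) stop("'tiles' must be c(rows, cols)")
  if (any(tiles > dim(m)))
    stop("tile grid larger than the image", call. = FALSE)
  if (clip_limit <= 0) stop("'clip_limit' must be > 0", call. = FALSE)
  h <- nrow(m); w <- ncol(m)
  bins <- intensity_bins(m, vr, n_bins)           # 1..n_bins
  row_tile_of <- tile_index(h, tiles[1])
  col_tile_of <- tile_index(w, tiles[2])
  # per-tile clipped-histogram equalization mappings: value = vr cdf
  maps <- array(0, c(tiles[1], tiles[2], n_bins))
  for (tr in seq_len(tiles[1])) for (tc in seq_len(tiles[2])) {
    sel <- bins[row_tile_of == tr, col_tile_of == tc]
    hist_ <- tabulate(sel, nbins = n_bins)
    hist_ <- clip_histogram(hist_, clip_limit * length(sel))
    maps[tr, tc, ] <- cumsum(hist_) / sum(hist_)
  }
  # bilinear blend between the four surrounding tile-center mappings
  rw <- center_weights(h, tiles[1])
  cw <- center_weights(w, tiles[2])
  i <- rep(seq_len(h), times = w)
  j <- rep(seq_len(w), each = h)
  b <- as.vector(bins)
  val <- rw$w[i]       * cw$w[j]       * maps[cbind(rw$lo[i], cw$lo[j], b)] +
         rw$w[i]       * (1 - cw$w[j]) * maps[cbind(rw$lo[i], cw$hi[j], b)] +
         (1 - rw$w[i]) * cw$w[j]       * maps[cbind(rw$hi[i], cw$lo[j], b)] +
         (1 - rw$w[i]) * (1 - cw$w[j]) * maps[cbind(rw$hi[i], cw$hi[j], b)]
  out <- matrix(vr[1] + val * (vr[2] - vr[1]), h, w)
  rewrap(image, out)
}

intensity_bins <- function(m, vr, n_bins) {
  b <- floor((m - vr[1]) / (vr[2] - vr[1]) * n_bins) + 1
  matrix(pmin(pmax(b, 1), n_bins), nrow(m), ncol(m))
}

tile_index <- function(n, k) {
  # contiguous near-equal tiles covering 1..n
  as.integer(cut(seq_len(n), breaks = round(seq(0, n, length.out = k + 1)),
                 labels = FALSE))
}

# clip each bin at 'clip' and spread the excess uniformly (single pass;
# bins may end at clip + excess/n_bins, the documented residual)
clip_histogram <- function(counts, clip) {
  excess <- sum(pmax(counts - clip, 0))
  counts <- pmin(counts, clip)
  counts + excess / length(counts)
}

center_weights <- function(n, k) {
  # for each pixel coordinate: surrounding tile centers and blend weight.
  bounds <- round(seq(0, n, length.out = k + 1))
  centers <- (bounds[-1] + bounds[-(k + 1)] + 1) / 2
  pos <- seq_len(n)
  hi <- pmin(findInterval(pos, centers) + 1, k)
  lo <- pmax(hi - 1, 1)
  wlo <- ifelse(hi == lo, 1, (centers[hi] - pos) / (centers[hi] - centers[lo]))
  list(lo = lo, hi = hi, w = pmin(pmax(wlo, 0), 1))
}

#' Local adaptive Wiener denoising
#'
#' Pixel-wise shrinkage toward the local mean: with local mean \eqn{m} and
#' variance \eqn{v} over an odd `window`-sided neighborhood (reflective
#' borders) and noise variance \eqn{\nu},
#' \deqn{\hat x = m + \frac{\max(0, v - \nu)}{\max(v, \nu)} (x - m).}
#' With `noise = "auto"` the noise variance is estimated as the mean of the
#' local variances, the usual adaptive choice for uniform additive noise.
#'
#' @param image matrix or `raster_image`.
#' @param window odd neighborhood side length.
#' @param noise noise variance, or `"auto"`.
#' @return filtered image, same container as the input.
#' @export
wiener_filter <- function(image, window = 3, noise = "auto") {
  if (window < 1 || window %% 2 == 0) stop("'window' must be odd and >= 1")
  m <- px(image)
  mu <- box_mean(m, window)
  v <- pmax(box_mean(m^2, window) - mu^2, 0)
  nv <- if (identical(noise, "auto")) mean(v) else {
    if (!is.numeric(noise) || noise < 0) stop("'noise' must be >= 0 or \"auto\"")
    noise
  }
  gain <- ifelse(pmax(v, nv) > 0, pmax(v - nv, 0) / pmax(v, nv), 0)
  out <- mu + gain * (m - mu)
  dim(out) <- dim(m)
  rewrap(image, out)
}

# mean over a w x w window with reflective padding, via a summed-area table
box_mean <- function(m, w) {
  r <- (w - 1) / 2
  p <- pad_reflect(m, r)
  sat <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed SAT
  sat <- rbind(0, cbind(0, t(sat)))
  h <- nrow(m); wd <- ncol(m)
  i1 <- seq_len(h); i2 <- i1 + w; j1 <- seq_len(wd); j2 <- j1 + w
  (sat[i2, j2] - sat[i1, j2] - sat[i2, j1] + sat[i1, j1]) / (w * w)
}

pad_reflect <- function(m, r) {
  if (r == 0) return(m)
  h <- nrow(m); w <- ncol(m)
  ri <- reflect_idx(h, r); ci <- reflect_idx(w, r)
  m[ri, ci, drop = FALSE]
}

reflect_idx <- function(n, r) {
  idx <- c(rev(seq_len(min(r, n - 1)) + 1), seq_len(n),
           n - seq_len(min(r, n - 1)))
  # for r >= n fall back to clamping (tiny images)
  if (length(idx) < n + 2 * r) {
    idx <- c(rep(idx[1], n + 2 * r - length(idx)), idx)
  }
  idx
}

#' Bilinear image resize
#'
#' Deterministic bilinear interpolation with pixel-center alignment; the
#' identity when the target equals the source size, and constant images map
#' to the same constant at any size.
#'
#' @param image matrix or `raster_image`.
#' @param target `c(rows, cols)` output size.
#' @return resized image, same container as the input.
#' @export
resize_image <- function(image, target) {
  if (length(target) != 2 || any(target < 1)) stop("'target' must be c(h, w)")
  m <- px(image)
  h1 <- nrow(m); w1 <- ncol(m); h2 <- target[1]; w2 <- target[2]
  out <- bilinear_gather(m,
                         src = (seq_len(h2) - 0.5) * h1 / h2 + 0.5,
                         srcj = (seq_len(w2) - 0.5) * w1 / w2 + 0.5)
  rewrap(image, out)
}

# gather m at real-valued row coords 'src' x col coords 'srcj' (outer grid),
# clamped to the image
bilinear_gather <- function(m, src, srcj) {
  h <- nrow(m); w <- ncol(m)
  fi <- pmin(pmax(src, 1), h); fj <- pmin(pmax(srcj, 1), w)
  i0 <- pmin(floor(fi), h - 1L); i0 <- pmax(i0, 1L)
  j0 <- pmin(floor(fj), w - 1L); j0 <- pmax(j0, 1L)
  di <- fi - i0; dj <- fj - j0
  a <- m[i0, j0, drop = FALSE]; b <- m[i0 + 1, j0, drop = FALSE]
  c_ <- m[i0, j0 + 1, drop = FALSE]; d <- m[i0 + 1, j0 + 1, drop = FALSE]
  wa <- outer(1 - di, 1 - dj); wb <- outer(di, 1 - dj)
  wc <- outer(1 - di, dj); wd <- outer(di, dj)
  wa * a + wb * b + wc * c_ + wd * d
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant image maps to all zeros by
#' convention.
#'
#' @param image matrix or `raster_image`.
#' @return image in `[0, 1]`, same container as the input.
#' @export
normalize01 <- function(image) {
  m <- px(image)
  rng <- range(m)
  out <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1])
         else matrix(0, nrow(m), ncol(m))
  rewrap(image, out, value_range = c(0, 1))
}

#' Eight-fold rotation augmentation
#'
#' Returns the input image/mask pair rotated by 0, 45, ..., 315 degrees
#' about the image center. Axis-aligned rotations (multiples of 90) are
#' exact grid permutations; oblique angles interpolate the image
#' bilinearly and the mask by nearest neighbor, both with reflective
#' padding, so each pair stays aligned and the mask keeps its label set.
#'
#' @param image matrix or `raster_image`.
#' @param mask integer label matrix of the same shape.
#' @return list of 8 elements, each `list(image =, mask =, angle =)`.
#' @export
augment_rotations <- function(image, mask) {
  m <- px(image)
  if (!all(dim(m) == dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  lapply(seq(0, 315, by = 45), function(a) {
    list(image = rewrap(image, rotate_matrix(m, a, "bilinear")),
         mask = rotate_matrix(mask, a, "nearest"),
         angle = a)
  })
}

#' Rotate a matrix about its center
#'
#' @param m numeric matrix.
#' @param angle rotation angle in degrees, counter-clockwise.
#' @param method `"bilinear"` or `"nearest"`.
#' @return rotated matrix, same shape (reflective padding off-grid;
#'   multiples of 90 degrees are exact).
#' @export
rotate_matrix <- function(m, angle, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  a <- angle %% 360
  if (a == 0) return(m)
  if (a %% 90 == 0) {
    k <- a / 90
    out <- m
    for (. in seq_len(k)) out <- t(out)[rev(seq_len(ncol(out))), , drop = FALSE]
    return(out)
  }
  h <- nrow(m); w <- ncol(m)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- a * pi / 180
  i <- rep(seq_len(h), times = w) - cy
  j <- rep(seq_len(w), each = h) - cx
  # inverse mapping (sample the source at the back-rotated coordinate)
  si <- cos(th) * i + sin(th) * j + cy
  sj <- -sin(th) * i + cos(th) * j + cx
  si <- reflect_coord(si, h); sj <- reflect_coord(sj, w)
  out <- if (method == "nearest") {
    m[cbind(pmin(pmax(round(si), 1), h), pmin(pmax(round(sj), 1), w))]
  } else {
    i0 <- pmin(pmax(floor(si), 1), h - 1); j0 <- pmin(pmax(floor(sj), 1), w - 1)
    di <- pmin(pmax(si - i0, 0), 1); dj <- pmin(pmax(sj - j0, 0), 1)
    m[cbind(i0, j0)] * (1 - di) * (1 - dj) +
      m[cbind(i0 + 1, j0)] * di * (1 - dj) +
      m[cbind(i0, j0 + 1)] * (1 - di) * dj +
      m[cbind(i0 + 1, j0 + 1)] * di * dj
  }
  matrix(out, h, w)
}

reflect_coord <- function(x, n) {
  # reflect about the borders [1, n] (period 2(n-1))
  if (n == 1) return(rep(1, length(x)))
  p <- 2 * (n - 1)
  x <- (x - 1) %% p
  ifelse(x > n - 1, p - x, x) + 1
}

#' Apply an ordered preprocessing chain
#'
#' Runs a list of named stages over an image. Each stage is either a bare
#' name or `list(stage = name, <parameters>)`; stage names are `"window"`,
#' `"clahe"`, `"wiener"`, `"resize"`, `"normalize"`. The default chain is
#' window -> CLAHE -> Wiener -> resize -> normalize.
#'
#' @param image matrix or `raster_image`.
#' @param stages list (or character vector) of stages; `NULL` applies none.
#' @return processed image.
#' @examples
#' img <- matrix(runif(64 * 64, 0, 255), 64)
#' out <- preprocess_pipeline(img, list(
#'   list(stage = "clahe", tiles = c(4, 4)),
#'   "wiener",
#'   list(stage = "resize", target = c(32, 32)),
#'   "normalize"))
#' @export
preprocess_pipeline <- function(image, stages) {
  if (is.null(stages)) return(image)
  if (is.character(stages)) stages <- as.list(stages)
  for (st in stages) {
    if (is.character(st)) st <- list(stage = st)
    name <- st$stage
    args <- st[setdiff(names(st), "stage")]
    image <- switch(
      name %||% "<missing>",
      window = do.call(hounsfield_window, c(list(image), args)),
      clahe = do.call(clahe, c(list(image), args)),
      wiener = do.call(wiener_filter, c(list(image), args)),
      resize = do.call(resize_image, c(list(image), args)),
      normalize = do.call(normalize01, c(list(image), args)),
      stop("unknown preprocessing stage: ", name, call. = FALSE))
  }
  image
}

#' @rdname preprocess_pipeline
#' @export
default_stages <- function() {
  list("window", "clahe", "wiener",
       list(stage = "resize", target = c(128, 128)), "normalize")
}
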