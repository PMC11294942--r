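#' Mixture parameter sets
#'
#' Constructor and validator for a K-component logistic-type mixture: mixing
#' weights, component locations and scales, and the (shared) shape. Weights
#' must be a probability vector; scales are floored at `scale_floor` by the
#' EM routines to keep the likelihood bounded.
#'
#' @param weights numeric vector of K mixing proportions, summing to 1.
#' @param locations numeric vector of K component locations.
#' @param scales numeric vector of K positive component scales.
#' @param shape positive shape parameter shared by all components
#'   (4 = two-parameter family).
#' @return an object of class `ltmix_params`.
#' @examples
#' ltmix_params(c(.5, .5), c(60.54, 121.98), sqrt(c(94.2568, 128.784)))
#' @export
ltmix_params <- function(weights, locations, scales, shape = 4) {
  K <- length(weights)
  if (K < 1) stop("mixture needs at least one component", call. = FALSE)
  if (length(locations) != K || length(scales) != K)
    stop("'weights', 'locations' and 'scales' must have equal length", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0) || any(weights > 1))
    stop("weights must lie in (0, 1]", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-12)
    stop("weights must sum to 1 (within 1e-12)", call. = FALSE)
  check_ltype_params(locations, scales, shape)
  structure(list(weights = as.numeric(weights),
                 locations = as.numeric(locations),
                 scales = as.numeric(scales),
                 shape = shape, K = K),
            class = "ltmix_params")
}

#' @export
print.ltmix_params <- function(x, digits = 4, ...) {
  cat("Logistic-type mixture parameters (K = ", x$K,
      ", shape = ", x$shape, ")\n", sep = "")
  m <- rbind(weight = x$weights, location = x$locations, scale = x$scales)
  colnames(m) <- paste0("comp", seq_len(x$K))
  print(round(m, digits), ...)
  invisible(x)
}

#' Mixture density
#'
#' Density of a K-component logistic-type mixture,
#' \eqn{\sum_i \alpha_i f(y; \mu_i, \sigma_i, p)}, computed in log space.
#'
#' @param x numeric vector of intensities.
#' @param params an [ltmix_params] object.
#' @param log logical; return the log-density.
#' @return numeric vector of (log-)densities.
#' @export
dltmix <- function(x, params, log = FALSE) {
  stopifnot(inherits(params, "ltmix_params"))
  lp <- component_logdens(x, params)        # N x K
  ll <- logsumexp_rows(lp)
  if (log) ll else exp(ll)
}

# N x K matrix of log(alpha_i) + log f_i(y)
component_logdens <- function(x, params) {
  K <- params$K
  out <- matrix(0, length(x), K)
  for (i in seq_len(K)) {
    out[, i] <- log(params$weights[i]) +
      dltype(x, params$locations[i], params$scales[i], params$shape, log = TRUE)
  }
  out
}

logsumexp_rows <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), na.rm = FALSE))
  mx + log(rowSums(exp(m - mx)))
}

#' Posterior component responsibilities
#'
#' E-step quantities: the posterior probability that each pixel belongs to
#' each mixture component,
#' \eqn{P_i(y_s) = \alpha_i f_i(y_s) / \sum_j \alpha_j f_j(y_s)},
#' computed in log space so well-separated components do not underflow.
#'
#' @param x numeric vector of pixel intensities (a matrix is flattened).
#' @param params an [ltmix_params] object.
#' @return an N x K row-stochastic matrix.
#' @export
responsibilities <- function(x, params) {
  stopifnot(inherits(params, "ltmix_params"))
  x <- as.numeric(x)
  if (length(x) < 1) stop("need at least one pixel", call. = FALSE)
  lp <- component_logdens(x, params)
  lse <- logsumexp_rows(lp)
  bad <- !is.finite(lse)
  if (any(bad))
    stop("degenerate likelihood: all component densities vanish at pixel(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  r <- exp(lp - lse)
  r / rowSums(r)
}

#' Initialize mixture parameters
#'
#' Starting values for the EM fit: equal weights 1/K; locations at the
#' (i - 0.5)/K sample quantiles (`"quantile"`) or at seeded k-means centers
#' (`"kmeans"`); scales from the within-group standard deviation about the
#' assigned location, floored at `scale_floor`.
#'
#' @param x numeric vector of intensities.
#' @param K number of components.
#' @param strategy `"quantile"` or `"kmeans"`.
#' @param shape shape parameter passed through to the parameter set.
#' @param seed optional integer seed (used by the k-means strategy).
#' @param scale_floor smallest admissible scale.
#' @return an [ltmix_params] object.
#' @export
ltmix_init <- function(x, K, strategy = c("quantile", "kmeans"), shape = 4,
                       seed = NULL, scale_floor = 1e-3) {
  strategy <- match.arg(strategy)
  x <- as.numeric(x)
  if (K < 1) stop("'K' must be at least 1", call. = FALSE)
  if (length(unique(x)) < K)
    stop("'K' exceeds the number of distinct pixel values", call. = FALSE)
  if (strategy == "quantile" || K == 1) {
    locs <- unname(stats::quantile(x, probs = (seq_len(K) - 0.5) / K, type = 7))
    assign_ <- max.col(-abs(outer(x, locs, "-")), ties.method = "first")
  } else {
    km <- with_seed(seed, stats::kmeans(x, centers = K, nstart = 5))
    ord <- order(km$centers[, 1])
    locs <- sort(km$centers[, 1])
    assign_ <- match(km$cluster, ord)
  }
  # convert the within-group SD into the family's scale units: the
  # standardized variance is (p*pi^2 + 7*pi^4/5) / (3p + pi^2), about 8.04
  # at shape 4, so sd = scale * 2.84 there
  sdfac <- sqrt(ltype_moments(0, 1, shape)[["var"]])
  scales <- vapply(seq_len(K), function(i) {
    xi <- x[assign_ == i]
    if (length(xi) < 2) return(scale_floor)
    max(stats::sd(xi) / sdfac, scale_floor)
  }, numeric(1))
  ltmix_params(rep(1 / K, K), locs, scales, shape = shape)
}

#' EM configuration
#'
#' Convergence and control settings for [ltmix()]: the fit stops when the
#' largest absolute change over all weights, locations and scales drops
#' below `tol` (the model's stated estimation error, default 0.001), or
#' after `max_iter` iterations.
#'
#' @param tol positive convergence threshold on the max absolute parameter
#'   change.
#' @param max_iter maximum number of EM iterations.
#' @param init initialization strategy, `"quantile"` or `"kmeans"`.
#' @param scale_update `"score"` (default) maximizes each component's
#'   responsibility-weighted log-likelihood numerically in
#'   (location, log scale); `"fixed_point"` uses the closed ratio update of
#'   the scale score equation with a weighted-mean location update.
#' @param scale_floor smallest admissible component scale.
#' @param seed optional integer seed (k-means initialization).
#' @return a list of class `ltmix_control`.
#' @export
ltmix_control <- function(tol = 1e-3, max_iter = 500,
                          init = c("quantile", "kmeans"),
                          scale_update = c("score", "fixed_point"),
                          scale_floor = 1e-3, seed = NULL) {
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0", call. = FALSE)
  if (max_iter < 1) stop("'max_iter' must be >= 1", call. = FALSE)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 init = match.arg(init), scale_update = match.arg(scale_update),
                 scale_floor = scale_floor, seed = seed),
            class = "ltmix_control")
}

# weighted negative log-likelihood of one component and its gradient in
# (mu, log sigma); r = responsibility weights
comp_negll <- function(par, x, r, shape) {
  mu <- par[1]; sig <- exp(par[2])
  -sum(r * dltype(x, mu, sig, shape, log = TRUE))
}

comp_negll_grad <- function(par, x, r, shape) {
  mu <- par[1]; sig <- exp(par[2])
  z <- (x - mu) / sig
  A <- 2 * z / (shape + z^2) + 1 - 2 * stats::plogis(z)   # dlogf/dz
  dmu <- sum(r * A) / sig                                  # -d(negll)/dmu
  dlsig <- sum(r * (-1 - z * A))                           # dlogf/dlogsigma
  c(-dmu, -dlsig)
}

#' One EM step
#'
#' E-step: component responsibilities. M-step: weights become the mean
#' responsibility; each component's location and scale maximize the
#' responsibility-weighted log-likelihood (see [ltmix_control] for the two
#' scale-update modes). The step never decreases the observed-data
#' log-likelihood: the numerical maximizer starts from the current
#' parameters and falls back to them if no improvement is found.
#'
#' @param x numeric vector of intensities.
#' @param params current [ltmix_params].
#' @param control an [ltmix_control] list.
#' @return updated [ltmix_params].
#' @export
ltmix_em_step <- function(x, params, control = ltmix_control()) {
  r <- responsibilities(x, params)
  w <- colMeans(r)
  w <- w / sum(w)
  collapsed <- which(w < 1e-8)
  if (length(collapsed))
    stop("mixture component ", collapsed[1],
         " collapsed (effective weight < 1e-8)", call. = FALSE)
  K <- params$K
  locs <- params$locations
  scls <- params$scales
  for (i in seq_len(K)) {
    if (control$scale_update == "score") {
      par0 <- c(locs[i], log(scls[i]))
      f0 <- comp_negll(par0, x, r[, i], params$shape)
      opt <- try(stats::optim(par0, comp_negll, comp_negll_grad,
                              x = x, r = r[, i], shape = params$shape,
                              method = "BFGS",
                              control = list(maxit = 50, reltol = 1e-10)),
                 silent = TRUE)
      if (!inherits(opt, "try-error") && is.finite(opt$value) && opt$value <= f0) {
        locs[i] <- opt$par[1]
        scls[i] <- max(exp(opt$par[2]), control$scale_floor)
      }
    } else {
      # weighted-mean location, then the fixed-point rearrangement of the
      # sigma score equation sum r (1 + zA) = 0:
      #   sigma^2_new = sum r (y-mu) sigma (2 plogis(z) - 1) /
      #                 sum r (1 + 2 u / (p sigma^2 + u)),  u = (y-mu)^2
      locs[i] <- sum(r[, i] * x) / sum(r[, i])
      sig <- scls[i]
      z <- (x - locs[i]) / sig
      u <- (x - locs[i])^2
      num <- sum(r[, i] * (x - locs[i]) * sig * (2 * stats::plogis(z) - 1))
      den <- sum(r[, i] * (1 + 2 * u / (params$shape * sig^2 + u)))
      if (is.finite(num) && is.finite(den) && num > 0 && den > 0)
        scls[i] <- max(sqrt(num / den), control$scale_floor)
    }
  }
  ltmix_params(w, locs, scls, shape = params$shape)
}

#' Fit a logistic-type mixture by EM
#'
#' Fits a K-component mixture of logistic-type distributions to pixel
#' intensities by expectation-maximization and returns a fitted-model
#' object. `y` may be a numeric vector, a matrix (an image, flattened for
#' fitting; its dimensions are remembered so `predict()` can return a label
#' mask), or a `raster_image`. If `K` is omitted it is estimated from the
#' smoothed intensity histogram via [estimate_k()].
#'
#' @param y pixel intensities: numeric vector or matrix.
#' @param K number of mixture components; `NULL` to estimate from the
#'   histogram.
#' @param shape shape parameter of the family (4 = two-parameter model).
#' @param control an [ltmix_control] list.
#' @param start optional [ltmix_params] starting values (overrides the
#'   initialization strategy).
#' @return an object of class `ltmix` with components `params` (the fitted
#'   [ltmix_params]), `loglik` (per-iteration observed-data log-likelihood),
#'   `trace` (per-iteration parameter sets), `converged`, `iterations`,
#'   `n`, `K`, and the flattened data `y`.
#' @examples
#' set.seed(1)
#' y <- c(rltype(300, 60, 10), rltype(300, 122, 11))
#' fit <- ltmix(y, K = 2)
#' coef(fit)
#' head(predict(fit, type = "class"))
#' @export
ltmix <- function(y, K = NULL, shape = 4, control = ltmix_control(),
                  start = NULL) {
  dims <- dim(as_pixel_matrix_or_null(y))
  x <- as.numeric(as_pixels(y))
  if (!length(x) || any(!is.finite(x)))
    stop("'y' must be finite pixel intensities", call. = FALSE)
  if (is.null(K)) K <- estimate_k(x)
  K <- as.integer(K)
  if (length(x) < 10 * K)
    stop("need at least 10 pixels per component", call. = FALSE)
  if (length(unique(x)) == 1 && K > 1)
    stop("constant intensities cannot support K > 1 components", call. = FALSE)
  params <- if (is.null(start)) {
    ltmix_init(x, K, strategy = control$init, shape = shape,
               seed = control$seed, scale_floor = control$scale_floor)
  } else {
    stopifnot(inherits(start, "ltmix_params"), start$K == K)
    start
  }
  trace <- list(params)
  ll <- sum(dltmix(x, params, log = TRUE))
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    new <- ltmix_em_step(x, params, control)
    delta <- max(abs(c(new$weights - params$weights,
                       new$locations - params$locations,
                       new$scales - params$scales)))
    params <- new
    trace[[iter + 1L]] <- params
    ll <- c(ll, sum(dltmix(x, params, log = TRUE)))
    if (delta < control$tol) { converged <- TRUE; break }
  }
  structure(list(params = params, loglik = ll, trace = trace,
                 converged = converged, iterations = iter,
                 n = length(x), K = K, shape = shape, dims = dims,
                 control = control, y = x, call = match.call()),
            class = "ltmix")
}

as_pixels <- function(y) {
  if (inherits(y, "raster_image")) y <- y$pixels
  if (is.matrix(y) || is.numeric(y)) return(as.numeric(y))
  stop("'y' must be a numeric vector, matrix or raster_image", call. = FALSE)
}

as_pixel_matrix_or_null <- function(y) {
  if (inherits(y, "raster_image")) return(y$pixels)
  if (is.matrix(y)) return(y)
  NULL
}

#' Estimate the number of intensity segments
#'
#' Counts the modes of a kernel-smoothed histogram of pixel intensities:
#' local maxima of the density estimate whose topographic prominence
#' exceeds `min_prominence` times the tallest peak. Degenerate inputs
#' (constant images) yield 1.
#'
#' @param x numeric vector of at least 100 intensities (shorter inputs are
#'   accepted but flagged unreliable via a warning).
#' @param bw bandwidth passed to [stats::density()].
#' @param min_prominence minimum peak prominence, as a fraction of the
#'   highest peak.
#' @return integer count >= 1.
#' @export
estimate_k <- function(x, bw = "nrd0", min_prominence = 0.05) {
  x <- as.numeric(as_pixels(x))
  if (length(x) < 100)
    warning("fewer than 100 pixels; segment-count estimate is unreliable")
  if (length(unique(x)) == 1) return(1L)
  d <- stats::density(x, bw = bw)
  f <- d$y
  n <- length(f)
  is_max <- which(f > c(-Inf, f[-n]) & f >= c(f[-1], -Inf))
  if (!length(is_max)) return(1L)
  prom <- vapply(is_max, function(i) peak_prominence(f, i), numeric(1))
  max(1L, sum(prom >= min_prominence * max(f)))
}

# topographic prominence: height above the higher of the two key saddles
# (lowest point between the peak and the nearest higher ground on each side)
peak_prominence <- function(f, i) {
  h <- f[i]
  left <- f[seq_len(i - 1)]
  right <- if (i < length(f)) f[(i + 1):length(f)] else numeric(0)
  key <- function(side, rev) {
    if (!length(side)) return(0)           # edge: drops to the boundary
    if (rev) side <- rev(side)
    higher <- which(side > h)
    if (!length(higher)) return(0)         # highest ground this side
    min(side[seq_len(higher[1])])
  }
  saddle <- max(key(left, rev = TRUE), key(right, rev = FALSE))
  h - saddle
}

#' Max-posterior pixel classification
#'
#' Assigns every pixel the mixture component with the largest posterior
#' responsibility (ties broken toward the lowest component index) and
#' returns 0-based labels in `0..K-1`, shaped like the input image when it
#' had dimensions.
#'
#' @param y intensities (vector, matrix or `raster_image`).
#' @param params an [ltmix_params] object or a fitted [ltmix] model.
#' @return integer vector or matrix of labels.
#' @export
classify_pixels <- function(y, params) {
  if (inherits(params, "ltmix")) params <- params$params
  dims <- dim(as_pixel_matrix_or_null(y))
  x <- as.numeric(as_pixels(y))
  r <- responsibilities(x, params)
  lab <- max.col(r, ties.method = "first") - 1L
  if (!is.null(dims)) dim(lab) <- dims
  lab
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.ltmix <- function(x, digits = 4, ...) {
  cat("Logistic-type mixture fit (EM)\n")
  cat("  n = ", x$n, " pixels, K = ", x$K, ", shape = ", x$shape, "\n", sep = "")
  cat("  log-likelihood ", format(utils::tail(x$loglik, 1), digits = 8),
      " after ", x$iterations, " iteration(s); ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  print(x$params, digits = digits)
  invisible(x)
}

#' @export
summary.ltmix <- function(object, ...) {
  structure(list(fit = object,
                 coef = coef(object),
                 loglik = utils::tail(object$loglik, 1),
                 moments = t(vapply(seq_len(object$K), function(i)
                   ltype_moments(object$params$locations[i],
                                 object$params$scales[i], object$shape),
                   numeric(2)))),
            class = "summary.ltmix")
}

#' @export
print.summary.ltmix <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nComponent moments:\n")
  m <- cbind(x$coef, sd = sqrt(x$moments[, "var"]))
  print(round(m, digits))
  invisible(x)
}

#' @export
coef.ltmix <- function(object, ...) {
  p <- object$params
  cbind(weight = p$weights, location = p$locations, scale = p$scales)
}

#' @export
logLik.ltmix <- function(object, ...) {
  structure(utils::tail(object$loglik, 1),
            df = 3 * object$K - 1, nobs = object$n, class = "logLik")
}

#' Predict from a fitted mixture
#'
#' @param object a fitted [ltmix] model.
#' @param newdata optional intensities; defaults to the training pixels
#'   (reshaped to the original image when one was supplied).
#' @param type `"class"` for 0-based max-posterior labels,
#'   `"responsibility"` for the N x K posterior matrix, `"density"` for the
#'   mixture density at the pixels.
#' @param ... unused.
#' @return labels, matrix or densities per `type`.
#' @export
predict.ltmix <- function(object, newdata = NULL,
                          type = c("class", "responsibility", "density"), ...) {
  type <- match.arg(type)
  y <- if (is.null(newdata)) {
    if (!is.null(object$dims)) array(object$y, object$dims) else object$y
  } else newdata
  switch(type,
         class = classify_pixels(y, object$params),
         responsibility = responsibilities(as.numeric(as_pixels(y)), object$params),
         density = dltmix(as.numeric(as_pixels(y)), object$params))
}

#' @export
simulate.ltmix <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    p <- object$params
    replicate(nsim, {
      comp <- sample.int(p$K, object$n, replace = TRUE, prob = p$weights)
      rltype(object$n, p$locations[comp], p$scales[comp], p$shape)
    }, simplify = FALSE)
  })
}

#' @export
plot.ltmix <- function(x, breaks = 60, main = "Logistic-type mixture fit", ...) {
  graphics::hist(x$y, breaks = breaks, freq = FALSE, main = main,
                 xlab = "pixel intensity", border = "grey70", ...)
  xs <- seq(min(x$y), max(x$y), length.out = 512)
  for (i in seq_len(x$K)) {
    graphics::lines(xs, x$params$weights[i] *
                      dltype(xs, x$params$locations[i], x$params$scales[i],
                             x$shape), col = i + 1, lty = 2)
  }
  graphics::lines(xs, dltmix(xs, x$params), lwd = 2)
  invisible(x)
}

#' Serialize mixture parameters to a text file
#'
#' Writes/reads an [ltmix_params] object as small YAML (keys `K`, `shape`,
#' `weights`, `locations`, `scales`) so fitted segmentations round-trip
#' through the run configuration machinery.
#'
#' @param params an [ltmix_params] object.
#' @param path file path.
#' @return `write_ltmix_params` returns `path` invisibly;
#'   `read_ltmix_params` returns an [ltmix_params] object.
#' @export
write_ltmix_params <- function(params, path) {
  stopifnot(inherits(params, "ltmix_params"))
  yaml::write_yaml(list(K = params$K, shape = params$shape,
                        weights = params$weights,
                        locations = params$locations,
                        scales = params$scales), path,
                   precision = 17L)
  invisible(path)
}

#' @rdname write_ltmix_params
#' @export
read_ltmix_params <- function(path) {
  v <- yaml::read_yaml(path)
  p <- ltmix_params(v$weights, v$locations, v$scales, shape = v$shape)
  if (!is.null(v$K) && v$K != p$K)
    stop("stored K disagrees with the number of components", call. = FALSE)
  p
}
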