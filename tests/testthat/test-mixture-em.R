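test_that("mixture density reduces correctly in degenerate cases", {
  one <- ltmix_params(1, 60, 10)
  xs <- seq(0, 120, by = 5)
  expect_equal(dltmix(xs, one), dltype(xs, 60, 10), tolerance = 1e-12)
  twin <- ltmix_params(c(0.5, 0.5), c(60, 60), c(10, 10))
  expect_equal(dltmix(xs, twin), dltype(xs, 60, 10), tolerance = 1e-12)
})

test_that("mixture density is larger near the components than far away", {
  p <- table9_params()
  expect_gt(dltmix(60.54, p), dltmix(250, p))
  expect_gt(dltmix(121.98, p), 0)
})

test_that("parameter sets are validated", {
  expect_error(ltmix_params(c(0.6, 0.6), c(0, 1), c(1, 1)), "sum to 1")
  expect_error(ltmix_params(c(0.5, 0.5), c(0, 1), c(1, -1)), "scale")
  expect_error(ltmix_params(numeric(0), numeric(0), numeric(0)),
               "at least one")
  expect_error(ltmix_params(1, 0, 1, shape = -4), "shape")
})

test_that("responsibilities are row-stochastic and follow the posterior", {
  x <- seq(0, 200, by = 0.5)
  expect_true(all(responsibilities(x, ltmix_params(1, 60, 10)) == 1))
  twin <- ltmix_params(c(0.5, 0.5), c(60, 60), c(10, 10))
  expect_equal(unname(responsibilities(x, twin)),
               matrix(0.5, length(x), 2), tolerance = 1e-12)
  p <- table9_params()
  r <- responsibilities(x, p)
  expect_equal(rowSums(r), rep(1, length(x)), tolerance = 1e-9)
  expect_gt(responsibilities(60.54, p)[1, 1], 0.5)
  # far tails still well-defined thanks to log-space computation
  rr <- responsibilities(c(-1e4, 1e4), p)
  expect_true(all(is.finite(rr)))
})

test_that("an EM step keeps weights normalized and climbs the likelihood", {
  y <- draw_table9(1000, seed = 3)
  p0 <- ltmix_init(y, 2)
  p1 <- ltmix_em_step(y, p0)
  expect_equal(sum(p1$weights), 1, tolerance = 1e-12)
  ll0 <- sum(dltmix(y, p0, log = TRUE))
  ll1 <- sum(dltmix(y, p1, log = TRUE))
  expect_gte(ll1, ll0 - 1e-9)
  # K = 1 reduces to a single-distribution MLE near the sample center
  y1 <- ctmixseg:::with_seed(5, rltype(2000, 42, 3))
  m1 <- ltmix_em_step(y1, ltmix_init(y1, 1))
  expect_lt(abs(m1$locations - median(y1)), 0.5)
  expect_equal(m1$weights, 1)
})

test_that("the printed-form fixed-point scale update also climbs", {
  y <- draw_table9(1000, seed = 9)
  ctl <- ltmix_control(scale_update = "fixed_point")
  p0 <- ltmix_init(y, 2)
  ll <- sum(dltmix(y, p0, log = TRUE))
  p <- p0
  for (i in 1:15) {
    p <- ltmix_em_step(y, p, ctl)
    lln <- sum(dltmix(y, p, log = TRUE))
    expect_gte(lln, ll - 1e-6)
    ll <- lln
  }
  # and lands near the score-based optimum
  fit <- ltmix(y, K = 2)
  o <- order(p$locations)
  expect_equal(p$locations[o], sort(fit$params$locations), tolerance = 2)
})

test_that("EM fit recovers simulated two-component truth", {
  y <- draw_table9(5000, seed = 2)
  fit <- ltmix(y, K = 2)
  expect_s3_class(fit, "ltmix")
  expect_true(fit$converged)
  co <- coef(fit)
  o <- order(co[, "location"])
  expect_lt(max(abs(co[o, "location"] - c(60.54, 121.98))), 3)
  expect_lt(max(abs(co[o, "weight"] - 0.5)), 0.05)
  expect_true(all(diff(fit$loglik) >= -1e-9))
})

test_that("EM trace records every iterate and non-convergence is flagged", {
  y <- draw_table9(500, seed = 4)
  fit <- ltmix(y, K = 2, control = ltmix_control(max_iter = 1))
  expect_false(fit$converged)
  expect_equal(fit$iterations, 1L)
  expect_length(fit$trace, 2)            # init + one step
  expect_length(fit$loglik, 2)
})

test_that("degenerate inputs are handled per contract", {
  const <- rep(7, 100)
  fit <- ltmix(const, K = 1)
  expect_true(fit$converged)
  expect_equal(fit$params$locations, 7, tolerance = 1e-6)
  expect_error(ltmix(const, K = 2), "constant")
  expect_error(ltmix(rnorm(5), K = 1), "at least 10")
})

test_that("initialization honours its contracts", {
  y <- draw_table9(500, seed = 6)
  p <- ltmix_init(y, 2)
  expect_equal(p$weights, c(0.5, 0.5))
  p1 <- ltmix_init(y, 1)
  expect_equal(p1$locations, median(y), tolerance = 1e-9)
  k1 <- ltmix_init(y, 3, strategy = "kmeans", seed = 11)
  k2 <- ltmix_init(y, 3, strategy = "kmeans", seed = 11)
  expect_identical(k1, k2)
  expect_error(ltmix_init(c(1, 1, 1, 2), 3), "distinct")
})

test_that("histogram mode counting finds well-separated segments", {
  expect_identical(estimate_k(rep(3, 500)), 1L)
  sd1 <- sqrt(ltype_moments(0, 10, 4)[["var"]])  # component SD at scale 10
  y2 <- ctmixseg:::with_seed(8, c(rltype(5000, 0, 10),
                                  rltype(5000, 6 * sd1, 10)))
  expect_equal(estimate_k(y2), 2)
  y3 <- ctmixseg:::with_seed(8, c(rltype(4000, 0, 5), rltype(4000, 60, 5),
                                  rltype(4000, 120, 5)))
  expect_equal(estimate_k(y3), 3)
  expect_warning(estimate_k(rnorm(50)), "unreliable")
})

test_that("max-posterior classification emits 0-based labels", {
  img <- matrix(c(rep(60, 8), rep(122, 8)), 4, 4)
  p <- table9_params()
  lab <- classify_pixels(img, p)
  expect_true(all(lab %in% 0:1))
  expect_identical(dim(lab), dim(img))
  expect_true(all(lab[img == 60] == 0L))
  expect_true(all(lab[img == 122] == 1L))
  expect_true(all(classify_pixels(img, ltmix_params(1, 60, 10)) == 0L))
  # swapping components permutes labels consistently
  ps <- ltmix_params(p$weights[2:1], p$locations[2:1], p$scales[2:1])
  expect_identical(classify_pixels(img, ps), 1L - lab)
})

test_that("fitted-model methods behave like standard modelling objects", {
  y <- draw_table9(1000, seed = 12)
  fit <- ltmix(y, K = 2)
  expect_output(print(fit), "Logistic-type mixture fit")
  expect_output(print(summary(fit)), "Component moments")
  expect_identical(dim(coef(fit)), c(2L, 3L))
  expect_equal(attr(logLik(fit), "df"), 5)
  r <- predict(fit, type = "responsibility")
  expect_equal(dim(r), c(fit$n, 2L))       # 1000 draws per component
  expect_length(predict(fit, newdata = c(60, 120), type = "density"), 2)
  s1 <- simulate(fit, seed = 3)[[1]]
  s2 <- simulate(fit, seed = 3)[[1]]
  expect_identical(s1, s2)
  expect_length(s1, fit$n)
  # image-shaped input comes back as a label matrix
  img <- matrix(y[1:100], 10, 10)
  fim <- ltmix(img, K = 2)
  expect_identical(dim(predict(fim, type = "class")), c(10L, 10L))
})

test_that("mixture parameters round-trip through their text serialization", {
  p <- table9_params()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_ltmix_params(p, f)
  q <- read_ltmix_params(f)
  expect_equal(q$weights, p$weights, tolerance = 1e-12)
  expect_equal(q$locations, p$locations, tolerance = 1e-12)
  expect_equal(q$scales, p$scales, tolerance = 1e-12)
  expect_identical(q$K, p$K)
})
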