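test_that("network spec validates its geometry", {
  expect_error(unet_spec(input_size = c(100, 100), depth = 5), "divisible")
  expect_error(unet_spec(dropout_rate = 1), "dropout")
  expect_error(unet_spec(base_filters = 0), "base_filters")
  s <- unet_spec(input_size = c(32, 32), depth = 3)
  expect_s3_class(s, "unet_spec")
})

test_that("the constructed graph matches the declared architecture", {
  cl <- count_layers(unet_spec())
  # encoder: 5 levels x 2 convs; decoder mirrors; +1 head conv
  expect_equal(cl[["conv"]], 21)
  expect_equal(cl[["conv_transpose"]], 5)
  expect_equal(cl[["pool"]], 5)             # one pool per encoder level
  expect_equal(cl[["dropout"]], 1)
  expect_equal(cl[["conv_type_total"]], 26) # regression on the builder
  # first convolution carries base_filters (8) 3x3 filters
  model <- build_unet(unet_spec(input_size = c(32, 32), depth = 3), seed = 1)
  first_conv <- model$nodes[[which(vapply(model$nodes, `[[`, character(1),
                                          "op") == "conv")[1]]]
  expect_equal(dim(model$params[[first_conv$w]]), c(3, 3, 1, 8))
  # filter counts double per level
  specs <- vapply(model$nodes, function(nd)
    if (nd$op == "pool") nd$channels else NA_integer_, numeric(1))
  expect_equal(specs[!is.na(specs)], c(8, 16, 32))
})

test_that("encoder feature sizes halve down the depth-5 backbone", {
  model <- build_unet(unet_spec(input_size = c(128, 128), depth = 5,
                                base_filters = 1), seed = 1)
  x <- array(runif(128 * 128), c(1, 128, 128, 1))
  fwd <- ctmixseg:::unet_forward(model, x)
  pools <- which(vapply(model$nodes, `[[`, character(1), "op") == "pool")
  sizes <- vapply(pools, function(i) dim(fwd$vals[[i]])[2], numeric(1))
  expect_equal(sizes, c(64, 32, 16, 8, 4))  # after each pool
  # symmetric decoder restores the input resolution, probabilities in [0,1]
  expect_equal(dim(fwd$out), c(1, 128, 128, 1))
  expect_true(all(fwd$out >= 0 & fwd$out <= 1))
})

test_that("backpropagation matches numerical gradients in both skip modes", {
  set.seed(41)
  for (mode in c("plain", "nested")) {
    spec <- unet_spec(input_size = c(8, 8), depth = 2, base_filters = 2,
                      dropout_rate = 0, l2_lambda = 0, skip_mode = mode)
    model <- build_unet(spec, seed = 3)
    # jitter every parameter (esp. the zero-initialized biases) so no ReLU
    # preactivation sits exactly on its kink, where one-sided subgradients
    # and central differences legitimately disagree
    model$params <- lapply(model$params,
                           function(p) p + stats::rnorm(length(p), sd = 0.05))
    x <- array(runif(2 * 64), c(2, 8, 8, 1))
    t_ <- array(rbinom(2 * 64, 1, 0.4), c(2, 8, 8, 1))
    lg <- ctmixseg:::unet_loss_grads(model, x, t_, train = FALSE)
    for (pn in sample(names(model$params), 4)) {
      p <- model$params[[pn]]
      for (ix in sample(length(p), min(3, length(p)))) {
        eps <- 1e-6
        up <- model; up$params[[pn]][ix] <- p[ix] + eps
        dn <- model; dn$params[[pn]][ix] <- p[ix] - eps
        num <- (ctmixseg:::unet_loss_grads(up, x, t_, train = FALSE)$loss -
                ctmixseg:::unet_loss_grads(dn, x, t_, train = FALSE)$loss) /
               (2 * eps)
        expect_equal(lg$grads[[pn]][ix], num, tolerance = 1e-5)
      }
    }
  }
})

test_that("dice loss matches its closed form and the dice coefficient", {
  a <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(dice_loss(a, a), 0)          # eps cancels exactly
  b <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(dice_loss(a, b, eps = 1e-12), 1, tolerance = 1e-9)
  # half-overlap, equal areas: loss 0.5 in the eps-free limit
  h <- matrix(c(1, 1, 0, 0), 2); t2 <- matrix(c(1, 0, 1, 0), 2)
  expect_equal(dice_loss(h, t2, eps = 1e-12), 0.5, tolerance = 1e-9)
  set.seed(42)
  p <- matrix(rbinom(64, 1, 0.5), 8); q <- matrix(rbinom(64, 1, 0.5), 8)
  expect_equal(1 - dice_loss(p, q, eps = 1e-12), dice_coefficient(p, q),
               tolerance = 1e-9)
  expect_error(dice_loss(p, q[1:4, ]), "differ")
})

test_that("dataset splitting is seeded, disjoint and exhaustive", {
  sp <- split_dataset(100, train_config(seed = 5))
  expect_length(sp$train, 70)
  expect_length(sp$val, 15)
  expect_length(sp$test, 15)
  expect_identical(sort(c(sp$train, sp$val, sp$test)), 1:100)
  expect_identical(sp, split_dataset(100, train_config(seed = 5)))
  expect_false(identical(sp$train, split_dataset(100,
                                                 train_config(seed = 6))$train))
  expect_error(split_dataset(2, train_config()), "at least 3")
  expect_error(train_config(split_fractions = c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("a few Adam steps reduce the training loss deterministically", {
  set.seed(43)
  sp <- small_phantom_spec(16)
  ds <- make_dataset(phantom_spec(size = c(16, 16), n_nodules = c(0, 0)),
                     4, seed = 9)
  imgs <- lapply(ds, function(s) ctmixseg:::px(normalize01(s$image)))
  msks <- lapply(ds, function(s) matrix(as.integer(s$mask > 0), 16, 16))
  model <- build_unet(unet_spec(input_size = c(16, 16), depth = 2,
                                base_filters = 4), seed = 2)
  cfg <- train_config(epochs = 15, batch_size = 4, seed = 7)
  fit <- train_unet(model, imgs, msks, cfg)
  h <- fit$history
  expect_equal(nrow(h), 15)                  # one record per epoch
  expect_lt(min(h$train_loss), h$train_loss[1])
  fit2 <- train_unet(model, imgs, msks, cfg)
  expect_identical(fit$history, fit2$history)  # seeded determinism
  # prediction thresholds behave definitionally
  pr <- predict_mask(fit, imgs[[1]], threshold = 0)
  expect_true(all(pr$mask == 1))
  pr1 <- predict_mask(fit, imgs[[1]], threshold = 1 + 1e-9)
  expect_true(all(pr1$mask == 0))
  pr5 <- predict_mask(fit, imgs[[1]], threshold = 0.5)
  expect_identical(pr5$mask, matrix(as.integer(pr5$prob >= 0.5), 16, 16))
  expect_error(predict_mask(fit, matrix(0, 8, 8)), "does not match")
})

test_that("the softmax head emits channel distributions", {
  spec <- unet_spec(input_size = c(8, 8), depth = 1, base_filters = 2,
                    dropout_rate = 0, out_activation = "softmax",
                    n_classes = 3)
  model <- build_unet(spec, seed = 4)
  x <- array(runif(64), c(1, 8, 8, 1))
  out <- ctmixseg:::unet_forward(model, x)$out
  expect_equal(dim(out), c(1, 8, 8, 3))
  sums <- apply(out, c(1, 2, 3), sum)
  expect_equal(as.vector(sums), rep(1, 64), tolerance = 1e-9)
})

test_that("non-finite losses abort with a located diagnostic", {
  model <- build_unet(unet_spec(input_size = c(8, 8), depth = 1,
                                base_filters = 2), seed = 5)
  model$params[[1]][] <- NaN
  img <- list(matrix(runif(64), 8))
  msk <- list(matrix(1L, 8, 8))
  expect_error(train_unet(model, img, msk, train_config(epochs = 1)),
               "non-finite loss at epoch 1")
})
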