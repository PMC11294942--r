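#' Encoder-decoder network specification
#'
#' Declarative description of the small U-Net-style segmentation network:
#' `depth` encoder levels of two 3x3 convolutions (stride 1, padding 1,
#' ReLU) followed by 2x2 max-pooling, a dropout bottleneck, and a mirrored
#' decoder of 2x2 stride-2 transposed convolutions with skip concatenation
#' and two convolutions per level; filter counts double per level from
#' `base_filters` (8, 16, 32, ...). `skip_mode = "plain"` concatenates each
#' encoder level once; `"nested"` builds the dense nested-skip lattice in
#' which every node re-aggregates all same-resolution predecessors. The
#' head is a 3x3 convolution to one channel with a sigmoid (binary masks)
#' or to `n_classes` channels with a channel softmax.
#'
#' @param input_size `c(h, w)`; each side must be divisible by `2^depth`.
#' @param depth number of encoder levels.
#' @param base_filters filters in the first convolution.
#' @param dropout_rate bottleneck dropout rate in `[0, 1)`.
#' @param l2_lambda L2 penalty on all convolution weights.
#' @param skip_mode `"plain"` or `"nested"`.
#' @param out_activation `"sigmoid"` or `"softmax"`.
#' @param n_classes output channels for the softmax head.
#' @return a list of class `unet_spec`.
#' @export
unet_spec <- function(input_size = c(128, 128), depth = 5, base_filters = 8,
                      dropout_rate = 0.5, l2_lambda = 0.001,
                      skip_mode = c("plain", "nested"),
                      out_activation = c("sigmoid", "softmax"),
                      n_classes = 2) {
  skip_mode <- match.arg(skip_mode)
  out_activation <- match.arg(out_activation)
  if (any(input_size %% 2^depth != 0))
    stop("input sides must be divisible by 2^depth", call. = FALSE)
  if (base_filters < 1) stop("'base_filters' must be >= 1", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("'dropout_rate' must be in [0, 1)", call. = FALSE)
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 kernel = c(3L, 3L), pool = c(2L, 2L),
                 dropout_rate = dropout_rate, l2_lambda = l2_lambda,
                 skip_mode = skip_mode, out_activation = out_activation,
                 n_classes = as.integer(n_classes)),
            class = "unet_spec")
}

#' Training configuration
#'
#' Adam optimizer settings and data handling for [train_unet()]: learning
#' rate 0.001, batch size 32, Dice loss, and a 70/15/15
#' train/validation/test split by default.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param split_fractions train/validation/test fractions summing to 1.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param threshold probability cut for binarizing predicted masks.
#' @return a list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32, epochs = 100,
                         split_fractions = c(0.70, 0.15, 0.15), seed = 1,
                         threshold = 0.5) {
  if (any(split_fractions <= 0) || abs(sum(split_fractions) - 1) > 1e-9)
    stop("split fractions must be positive and sum to 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), split_fractions = split_fractions,
                 seed = seed, threshold = threshold),
            class = "train_config")
}

#' Dice loss
#'
#' Soft Dice loss between a predicted probability mask and a binary target,
#' `1 - (2 sum(p t) + eps) / (sum(p) + sum(t) + eps)` with smoothing
#' `eps = 1` so empty pairs are well-defined.
#'
#' @param pred numeric array of probabilities in `[0, 1]`.
#' @param target binary array of the same shape.
#' @param eps smoothing constant.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, eps = 1) {
  check_same_shape(pred, target)
  a <- 2 * sum(pred * target) + eps
  b <- sum(pred) + sum(target) + eps
  1 - a / b
}

dice_loss_grad <- function(pred, target, eps = 1) {
  a <- 2 * sum(pred * target) + eps
  b <- sum(pred) + sum(target) + eps
  g <- -(2 * target * b - a) / b^2
  list(loss = 1 - a / b, grad = array(g, dim(pred) %||% length(pred)))
}

#' Seeded dataset split
#'
#' Shuffles `1..n` with the configured seed and partitions it contiguously
#' into train/validation/test index sets (floor sizes for train and
#' validation, remainder to test); disjoint and exhaustive.
#'
#' @param n number of samples (or a list, whose length is used).
#' @param config a [train_config] (its `split_fractions` and `seed`).
#' @return list of integer vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, config = train_config()) {
  if (is.list(n)) n <- length(n)
  if (n < 3) stop("need at least 3 samples to split", call. = FALSE)
  fr <- config$split_fractions
  idx <- with_seed(config$seed, sample.int(n))
  n_train <- floor(fr[1] * n)
  n_val <- floor(fr[2] * n)
  if (n_train < 1 || n_val < 1 || n_train + n_val >= n)
    stop("split produced an empty partition", call. = FALSE)
  list(train = idx[seq_len(n_train)],
       val = idx[n_train + seq_len(n_val)],
       test = idx[(n_train + n_val + 1):n])
}

# ---- graph construction ----------------------------------------------------

#' Build the network
#'
#' Instantiates the computation graph and He-initialized weights for a
#' [unet_spec]. The returned model is an ordinary list (`nodes`, `params`,
#' `spec`) consumed by [train_unet()] and [predict_mask()].
#'
#' @param spec a [unet_spec].
#' @param seed integer seed for weight initialization.
#' @return a list of class `unet_model`.
#' @export
build_unet <- function(spec = unet_spec(), seed = 1) {
  stopifnot(inherits(spec, "unet_spec"))
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$params <- list()
  g$nw <- 0L
  add <- function(op, inputs, channels, ...) {
    g$nodes[[length(g$nodes) + 1L]] <- c(list(op = op, inputs = inputs,
                                              channels = channels), list(...))
    length(g$nodes)
  }
  make_w <- function(kh, kw, cin, cout) {
    g$nw <- g$nw + 1L
    wn <- paste0("w", g$nw); bn <- paste0("b", g$nw)
    g$params[[wn]] <- array(stats::rnorm(kh * kw * cin * cout,
                                         sd = sqrt(2 / (kh * kw * cin))),
                            c(kh, kw, cin, cout))
    g$params[[bn]] <- numeric(cout)
    list(w = wn, b = bn)
  }
  conv_block <- function(id, cin, cout) {
    for (. in 1:2) {
      p <- make_w(3, 3, cin, cout)
      id <- add("conv", id, cout, w = p$w, b = p$b)
      id <- add("relu", id, cout)
      cin <- cout
    }
    id
  }
  up <- function(id, cin, cout) {
    p <- make_w(2, 2, cin, cout)
    id <- add("convT", id, cout, w = p$w, b = p$b)
    add("relu", id, cout)
  }
  ch <- function(id) g$nodes[[id]]$channels

  with_seed(seed, {
    d <- spec$depth
    f <- spec$base_filters * 2^(seq_len(d) - 1)
    inp <- add("input", integer(0), 1L)
    # encoder backbone
    skips <- integer(d)
    cur <- inp
    for (l in seq_len(d)) {
      cur <- conv_block(cur, ch(cur), f[l])
      skips[l] <- cur
      cur <- add("pool", cur, f[l])
    }
    bott <- add("dropout", cur, ch(cur), rate = spec$dropout_rate)
    if (spec$skip_mode == "plain") {
      cur <- bott
      for (l in rev(seq_len(d))) {
        u <- up(cur, ch(cur), f[l])
        cat_ <- add("concat", c(u, skips[l]), f[l] + ch(skips[l]))
        cur <- conv_block(cat_, ch(cat_), f[l])
      }
    } else {
      # nested dense-skip lattice: X[l, j] re-aggregates all previous
      # same-resolution nodes plus the upsampled deeper node
      X <- vector("list", d + 1)
      for (l in seq_len(d)) X[[l]] <- skips[l]
      X[[d + 1]] <- bott
      for (j in seq_len(d)) {
        for (l in seq_len(d + 1 - j)) {
          below <- X[[l + 1]][j]          # X[l+1, j-1]
          u <- up(below, ch(below), f[l])
          prev <- X[[l]]                  # X[l, 0..j-1]
          cat_ <- add("concat", c(prev, u),
                      sum(vapply(prev, ch, numeric(1))) + f[l])
          X[[l]] <- c(prev, conv_block(cat_, ch(cat_), f[l]))
        }
      }
      cur <- X[[1]][d + 1]
    }
    cout <- if (spec$out_activation == "sigmoid") 1L else spec$n_classes
    p <- make_w(3, 3, ch(cur), cout)
    head_ <- add("conv", cur, cout, w = p$w, b = p$b)
    add(spec$out_activation, head_, cout)
  })
  structure(list(spec = spec, nodes = g$nodes, params = g$params),
            class = "unet_model")
}

#' Per-kind layer counts
#'
#' Enumerates the constructed graph: convolution, transposed-convolution,
#' pooling and dropout layers, plus the total of convolution-type layers.
#'
#' @param model a `unet_model` (or a [unet_spec], which is built first).
#' @return named integer vector.
#' @export
count_layers <- function(model) {
  if (inherits(model, "unet_spec")) model <- build_unet(model, seed = 1)
  ops <- vapply(model$nodes, `[[`, character(1), "op")
  c(conv = sum(ops == "conv"),
    conv_transpose = sum(ops == "convT"),
    pool = sum(ops == "pool"),
    dropout = sum(ops == "dropout"),
    conv_type_total = sum(ops %in% c("conv", "convT")))
}

#' @export
print.unet_model <- function(x, ...) {
  cl <- count_layers(x)
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat("unet_model: input ", paste(x$spec$input_size, collapse = "x"),
      ", depth ", x$spec$depth, ", base ", x$spec$base_filters,
      ", skips ", x$spec$skip_mode, ", head ", x$spec$out_activation, "\n",
      "  layers: ", cl["conv"], " conv + ", cl["conv_transpose"],
      " transposed, ", cl["pool"], " pool, ", cl["dropout"], " dropout; ",
      npar, " parameters\n", sep = "")
  invisible(x)
}

# ---- array ops (N, H, W, C) ------------------------------------------------

conv_fwd <- function(x, W, b) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  Cout <- dim(W)[4]
  xp <- array(0, c(N, H + 2, Wd + 2, C))
  xp[, 2:(H + 1), 2:(Wd + 1), ] <- x
  y <- matrix(rep(b, each = N * H * Wd), N * H * Wd, Cout)
  for (a in 0:2) for (bb in 0:2) {
    xs <- xp[, (1 + a):(H + a), (1 + bb):(Wd + bb), , drop = FALSE]
    y <- y + matrix(xs, N * H * Wd, C) %*% matrix(W[a + 1, bb + 1, , ], C, Cout)
  }
  array(y, c(N, H, Wd, Cout))
}

conv_bwd <- function(x, W, dy) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  Cout <- dim(W)[4]
  xp <- array(0, c(N, H + 2, Wd + 2, C))
  xp[, 2:(H + 1), 2:(Wd + 1), ] <- x
  dym <- matrix(dy, N * H * Wd, Cout)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(xp))
  for (a in 0:2) for (bb in 0:2) {
    xs <- xp[, (1 + a):(H + a), (1 + bb):(Wd + bb), , drop = FALSE]
    dW[a + 1, bb + 1, , ] <- crossprod(matrix(xs, N * H * Wd, C), dym)
    dxp[, (1 + a):(H + a), (1 + bb):(Wd + bb), ] <-
      dxp[, (1 + a):(H + a), (1 + bb):(Wd + bb), , drop = FALSE] +
      array(dym %*% t(matrix(W[a + 1, bb + 1, , ], C, Cout)), c(N, H, Wd, C))
  }
  list(dx = dxp[, 2:(H + 1), 2:(Wd + 1), , drop = FALSE],
       dW = dW, db = colSums(dym))
}

pool_fwd <- function(x) {
  d <- dim(x); H <- d[2]; Wd <- d[3]
  oi <- seq(1, H, 2); ei <- seq(2, H, 2); oj <- seq(1, Wd, 2); ej <- seq(2, Wd, 2)
  s <- list(x[, oi, oj, , drop = FALSE], x[, ei, oj, , drop = FALSE],
            x[, oi, ej, , drop = FALSE], x[, ei, ej, , drop = FALSE])
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  # deterministic tie-break: first matching quadrant wins
  taken <- array(FALSE, dim(y))
  which_ <- array(0L, dim(y))
  for (k in 1:4) {
    hit <- (s[[k]] == y) & !taken
    which_[hit] <- k
    taken <- taken | hit
  }
  list(y = y, aux = which_)
}

pool_bwd <- function(dy, aux, dimx) {
  dx <- array(0, dimx)
  H <- dimx[2]; Wd <- dimx[3]
  oi <- seq(1, H, 2); ei <- seq(2, H, 2); oj <- seq(1, Wd, 2); ej <- seq(2, Wd, 2)
  idx <- list(list(oi, oj), list(ei, oj), list(oi, ej), list(ei, ej))
  for (k in 1:4) {
    g <- dy * (aux == k)
    dx[, idx[[k]][[1]], idx[[k]][[2]], ] <-
      dx[, idx[[k]][[1]], idx[[k]][[2]], , drop = FALSE] + g
  }
  dx
}

convT_fwd <- function(x, W, b) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  Cout <- dim(W)[4]
  xm <- matrix(x, N * H * Wd, C)
  y <- array(rep(b, each = N * 2 * H * 2 * Wd), c(N, 2 * H, 2 * Wd, Cout))
  for (a in 0:1) for (bb in 0:1) {
    y[, seq(1 + a, 2 * H, 2), seq(1 + bb, 2 * Wd, 2), ] <-
      y[, seq(1 + a, 2 * H, 2), seq(1 + bb, 2 * Wd, 2), , drop = FALSE] +
      array(xm %*% matrix(W[a + 1, bb + 1, , ], C, Cout), c(N, H, Wd, Cout))
  }
  y
}

convT_bwd <- function(x, W, dy) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  Cout <- dim(W)[4]
  xm <- matrix(x, N * H * Wd, C)
  dW <- array(0, dim(W))
  dxm <- matrix(0, N * H * Wd, C)
  for (a in 0:1) for (bb in 0:1) {
    dys <- matrix(dy[, seq(1 + a, 2 * H, 2), seq(1 + bb, 2 * Wd, 2), ,
                     drop = FALSE], N * H * Wd, Cout)
    dW[a + 1, bb + 1, , ] <- crossprod(xm, dys)
    dxm <- dxm + dys %*% t(matrix(W[a + 1, bb + 1, , ], C, Cout))
  }
  list(dx = array(dxm, c(N, H, Wd, C)), dW = dW,
       db = colSums(matrix(dy, ncol = Cout)))
}

concat_fwd <- function(parts) {
  d1 <- dim(parts[[1]])
  cs <- vapply(parts, function(p) dim(p)[4], integer(1))
  y <- array(0, c(d1[1:3], sum(cs)))
  off <- 0L
  for (p in parts) {
    cp <- dim(p)[4]
    y[, , , off + seq_len(cp)] <- p
    off <- off + cp
  }
  y
}

softmax_channels <- function(x) {
  mx <- apply(x, c(1, 2, 3), max)
  e <- exp(x - as.vector(mx))
  e / as.vector(apply(e, c(1, 2, 3), sum))
}

# ---- forward / backward over the graph -------------------------------------

unet_forward <- function(model, x, train = FALSE) {
  nn <- length(model$nodes)
  vals <- vector("list", nn)
  aux <- vector("list", nn)
  for (id in seq_len(nn)) {
    nd <- model$nodes[[id]]
    v <- if (length(nd$inputs)) vals[[nd$inputs[1]]]
    vals[[id]] <- switch(nd$op,
      input = x,
      conv = conv_fwd(v, model$params[[nd$w]], model$params[[nd$b]]),
      relu = pmax(v, 0),
      pool = { r <- pool_fwd(v); aux[[id]] <- r$aux; r$y },
      convT = convT_fwd(v, model$params[[nd$w]], model$params[[nd$b]]),
      concat = concat_fwd(lapply(nd$inputs, function(i) vals[[i]])),
      dropout = if (train && nd$rate > 0) {
        mask <- (array(stats::runif(length(v)), dim(v)) >= nd$rate) /
          (1 - nd$rate)
        aux[[id]] <- mask
        v * mask
      } else v,
      sigmoid = stats::plogis(v),
      softmax = softmax_channels(v),
      stop("unknown op ", nd$op))
  }
  list(out = vals[[nn]], vals = vals, aux = aux)
}

unet_backward <- function(model, fwd, dout) {
  nn <- length(model$nodes)
  gv <- vector("list", nn)
  gv[[nn]] <- dout
  grads <- lapply(model$params, function(p) array(0, dim(p) %||% length(p)))
  for (id in rev(seq_len(nn))) {
    g <- gv[[id]]
    if (is.null(g)) next
    nd <- model$nodes[[id]]
    if (nd$op == "input") next
    inp <- nd$inputs
    addg <- function(i, d) gv[[i]] <<- if (is.null(gv[[i]])) d else gv[[i]] + d
    switch(nd$op,
      conv = {
        r <- conv_bwd(fwd$vals[[inp]], model$params[[nd$w]], g)
        grads[[nd$w]] <- grads[[nd$w]] + r$dW
        grads[[nd$b]] <- grads[[nd$b]] + r$db
        addg(inp, r$dx)
      },
      relu = addg(inp, g * (fwd$vals[[inp]] > 0)),
      pool = addg(inp, pool_bwd(g, fwd$aux[[id]], dim(fwd$vals[[inp]]))),
      convT = {
        r <- convT_bwd(fwd$vals[[inp]], model$params[[nd$w]], g)
        grads[[nd$w]] <- grads[[nd$w]] + r$dW
        grads[[nd$b]] <- grads[[nd$b]] + r$db
        addg(inp, r$dx)
      },
      concat = {
        off <- 0L
        for (i in nd$inputs) {
          ci <- dim(fwd$vals[[i]])[4]
          addg(i, fwd_slice_channels(g, off + seq_len(ci)))
          off <- off + ci
        }
      },
      dropout = addg(inp, if (is.null(fwd$aux[[id]])) g else g * fwd$aux[[id]]),
      sigmoid = {
        y <- fwd$vals[[id]]
        addg(inp, g * y * (1 - y))
      },
      softmax = {
        y <- fwd$vals[[id]]
        s <- apply(g * y, c(1, 2, 3), sum)
        addg(inp, y * (g - as.vector(s)))
      })
  }
  grads
}

fwd_slice_channels <- function(x, chans) {
  x[, , , chans, drop = FALSE]
}

# loss (+ L2) and parameter gradients on one batch
unet_loss_grads <- function(model, x, target, train = TRUE) {
  fwd <- unet_forward(model, x, train = train)
  dl <- dice_loss_grad(fwd$out, target)
  grads <- unet_backward(model, fwd, dl$grad)
  lam <- model$spec$l2_lambda
  l2 <- 0
  if (lam > 0) {
    for (wn in grep("^w", names(model$params), value = TRUE)) {
      l2 <- l2 + lam * sum(model$params[[wn]]^2)
      grads[[wn]] <- grads[[wn]] + 2 * lam * model$params[[wn]]
    }
  }
  list(loss = dl$loss + l2, dice_loss = dl$loss, grads = grads)
}

stack_batch <- function(items) {
  # list of H x W matrices -> (N, H, W, 1) array
  h <- nrow(items[[1]]); w <- ncol(items[[1]])
  x <- array(0, c(length(items), h, w, 1))
  for (i in seq_along(items)) x[i, , , 1] <- items[[i]]
  x
}

target_batch <- function(masks, out_activation, n_classes) {
  if (out_activation == "sigmoid") return(stack_batch(masks))
  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  x <- array(0, c(length(masks), h, w, n_classes))
  for (i in seq_along(masks)) for (k in seq_len(n_classes))
    x[i, , , k] <- (masks[[i]] == k - 1)
  x
}

#' Train the network with Dice loss
#'
#' Seeded single-device training loop: Adam on the Dice loss (plus the L2
#' penalty), minibatches reshuffled every epoch, per-epoch training and
#' validation loss/Dice logging, and best-validation-Dice checkpointing.
#' Identical seeds give identical runs.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param images list of H x W intensity matrices in `[0, 1]`.
#' @param masks list of binary (or 0..K-1 label) matrices, same shapes.
#' @param config a [train_config].
#' @param val_images,val_masks optional validation set; when absent the
#'   checkpoint is the final state.
#' @return list of class `unet_fit`: the trained `model` (final weights),
#'   `best_params` (checkpointed weights), `history` data frame (one row
#'   per epoch: train/val loss and Dice), `config`.
#' @export
train_unet <- function(model, images, masks, config = train_config(),
                       val_images = NULL, val_masks = NULL) {
  stopifnot(inherits(model, "unet_model"), length(images) == length(masks),
            length(images) >= 1)
  spec <- model$spec
  xs <- stack_batch(images)
  ts <- target_batch(masks, spec$out_activation, spec$n_classes)
  has_val <- !is.null(val_images) && length(val_images) > 0
  if (has_val) {
    xv <- stack_batch(val_images)
    tv <- target_batch(val_masks, spec$out_activation, spec$n_classes)
  }
  n <- length(images)
  adam <- list(m = lapply(model$params, function(p) array(0, dim(p) %||% length(p))),
               v = lapply(model$params, function(p) array(0, dim(p) %||% length(p))),
               t = 0)
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8
  hist_rows <- vector("list", config$epochs)
  best <- list(dice = -Inf, params = model$params)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1, n)]
        lg <- unet_loss_grads(model,
                              xs[bi, , , , drop = FALSE],
                              ts[bi, , , , drop = FALSE], train = TRUE)
        if (!is.finite(lg$loss))
          stop("non-finite loss at epoch ", ep, ", batch starting at sample ",
               start, call. = FALSE)
        adam$t <- adam$t + 1
        for (pn in names(model$params)) {
          gradp <- lg$grads[[pn]]
          adam$m[[pn]] <- b1 * adam$m[[pn]] + (1 - b1) * gradp
          adam$v[[pn]] <- b2 * adam$v[[pn]] + (1 - b2) * gradp^2
          mhat <- adam$m[[pn]] / (1 - b1^adam$t)
          vhat <- adam$v[[pn]] / (1 - b2^adam$t)
          model$params[[pn]] <- model$params[[pn]] -
            config$learning_rate * mhat / (sqrt(vhat) + epsa)
        }
      }
      tr <- eval_set(model, xs, ts, config$threshold)
      va <- if (has_val) eval_set(model, xv, tv, config$threshold)
            else list(loss = NA_real_, dice = NA_real_)
      hist_rows[[ep]] <- data.frame(epoch = ep,
                                    train_loss = tr$loss, train_dice = tr$dice,
                                    val_loss = va$loss, val_dice = va$dice)
      score <- if (has_val) va$dice else tr$dice
      if (is.finite(score) && score >= best$dice) {
        best$dice <- score
        best$params <- model$params
      }
    }
  })
  structure(list(model = model, best_params = best$params,
                 history = do.call(rbind, hist_rows), config = config),
            class = "unet_fit")
}

# eval-mode loss and hard Dice over a stacked set
eval_set <- function(model, x, target, threshold) {
  out <- unet_forward(model, x, train = FALSE)$out
  fg <- foreground_prob(out, model$spec)
  tfg <- if (model$spec$out_activation == "sigmoid") target
         else fwd_slice_channels(target, dim(target)[4])
  list(loss = dice_loss(out, target),
       dice = dice_coefficient(fg >= threshold, tfg >= 0.5))
}

foreground_prob <- function(out, spec) {
  if (spec$out_activation == "sigmoid") out
  else fwd_slice_channels(out, dim(out)[4])   # last class = foreground
}

#' @export
print.unet_fit <- function(x, ...) {
  h <- x$history
  cat("unet_fit: ", nrow(h), " epoch(s); final train Dice ",
      round(utils::tail(h$train_dice, 1), 4), ", best val Dice ",
      round(suppressWarnings(max(h$val_dice, na.rm = TRUE)), 4), "\n", sep = "")
  invisible(x)
}

#' Predict a segmentation mask
#'
#' Forward pass in evaluation mode (dropout off): returns the per-pixel
#' foreground probability map and its thresholded binary mask.
#'
#' @param model a `unet_model` or `unet_fit` (whose checkpointed weights
#'   are used).
#' @param image H x W matrix matching the spec's input size.
#' @param threshold probability cut in the binary mask.
#' @return list with `prob` (matrix in `[0,1]`) and `mask` (0/1 integer
#'   matrix).
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  if (inherits(model, "unet_fit")) {
    m <- model$model
    m$params <- model$best_params
    model <- m
  }
  image <- px(image)
  if (!all(dim(image) == model$spec$input_size))
    stop("image size ", paste(dim(image), collapse = "x"),
         " does not match the network input ",
         paste(model$spec$input_size, collapse = "x"), call. = FALSE)
  out <- unet_forward(model, stack_batch(list(image)), train = FALSE)$out
  fg <- foreground_prob(out, model$spec)
  prob <- matrix(fg[1, , , 1], nrow(image), ncol(image))
  list(prob = prob, mask = matrix(as.integer(prob >= threshold),
                                  nrow(image), ncol(image)))
}
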