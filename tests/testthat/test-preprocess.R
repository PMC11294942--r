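test_that("hounsfield windowing maps the window linearly onto [0,1]", {
  m <- matrix(c(-1350, -600, 150, -2000, 500, 0), 2, 3)
  out <- hounsfield_window(m, "lung")
  expect_equal(out[1, 2], 1)                 # 150 HU: at the upper edge
  expect_equal(out[2, 1], 0.5)               # -600 HU: window center
  expect_equal(out[1, 1], 0)                 # -1350 HU: at the lower edge
  expect_equal(out[2, 2], 0)                 # -2000 HU: clamped below
  expect_equal(out[1, 3], 1)                 # 500 HU: clamped above
  expect_equal(out[2, 3], (0 - (-1350)) / 1500)
  st <- hounsfield_window(matrix(50), "soft_tissue")
  expect_equal(st[1, 1], 0.5)
  expect_error(hounsfield_window(m, center = 0, width = -5), "width")
})

test_that("clahe clips tile histograms and blends mappings", {
  set.seed(21)
  m <- matrix(runif(64 * 64, 0, 255), 64)
  out <- clahe(m, tiles = c(4, 4), clip_limit = 0.02, n_bins = 64,
               value_range = c(0, 255))
  expect_identical(dim(out), dim(m))
  expect_true(all(out >= 0 & out <= 255))
  # per-tile clip contract: recompute each tile histogram and verify the
  # clipped version never exceeds clip + uniform redistribution residual
  bins <- ctmixseg:::intensity_bins(m, c(0, 255), 64)
  rt <- ctmixseg:::tile_index(64, 4)
  for (tr in 1:4) for (tc in 1:4) {
    sel <- bins[rt == tr, rt == tc]
    h <- tabulate(sel, 64)
    clip <- 0.02 * length(sel)
    ch <- ctmixseg:::clip_histogram(h, clip)
    excess <- sum(pmax(h - clip, 0))
    expect_true(all(ch <= clip + excess / 64 + 1e-9))
    expect_equal(sum(ch), length(sel))       # mass preserved
  }
})

test_that("degenerate clahe equals independent global equalization", {
  set.seed(22)
  m <- matrix(runif(40 * 40, 0, 255), 40)
  out <- clahe(m, tiles = c(1, 1), clip_limit = 1e9, n_bins = 256,
               value_range = c(0, 255))
  expect_equal(out, oracle_global_he(m), tolerance = 1e-12)
})

test_that("constant images pass through clahe and wiener unchanged in kind", {
  const <- matrix(42, 16, 16)
  cc <- clahe(const, tiles = c(2, 2), value_range = c(0, 255))
  expect_lt(max(cc) - min(cc), 1e-9)         # still constant
  expect_identical(wiener_filter(const), const)
  expect_identical(resize_image(const, c(8, 8)), matrix(42, 8, 8))
  expect_equal(normalize01(const), matrix(0, 16, 16))
  expect_error(clahe(matrix(1, 4, 4), tiles = c(8, 8)), "larger")
})

test_that("wiener filter shrinks noise and reduces to the local mean", {
  set.seed(23)
  m <- matrix(rnorm(50 * 50), 50)
  out <- wiener_filter(m, window = 3, noise = "auto")
  expect_lte(var(as.vector(out)), var(as.vector(m)))
  # huge declared noise makes every pixel the local mean exactly
  flat <- wiener_filter(m, window = 3, noise = 1e9)
  expect_equal(flat, ctmixseg:::box_mean(m, 3), tolerance = 1e-12)
  # the box mean itself against a tiny brute-force oracle
  sm <- matrix(1:12, 3, 4)
  bf <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1) ii <- 1 + (1 - ii); if (ii > 3) ii <- 3 - (ii - 3)
      if (jj < 1) jj <- 1 + (1 - jj); if (jj > 4) jj <- 4 - (jj - 4)
      acc <- acc + sm[ii, jj]
    }
    bf[i, j] <- acc / 9
  }
  expect_equal(ctmixseg:::box_mean(sm, 3), bf, tolerance = 1e-12)
  expect_error(wiener_filter(m, window = 4), "odd")
})

test_that("resize is deterministic bilinear with exact identity", {
  set.seed(24)
  m <- matrix(runif(128 * 128, 0, 255), 128)
  out <- resize_image(m, c(32, 32))
  expect_identical(dim(out), c(32L, 32L))
  expect_identical(resize_image(m, c(128, 128)), m)
  expect_true(all(out >= min(m) & out <= max(m)))  # convex combinations
})

test_that("normalize01 hits its range contract", {
  m <- matrix(0:255, 16, 16)
  n <- normalize01(m)
  expect_equal(range(n), c(0, 1))
  expect_equal(n[2, 1] * 255, 1)
})

test_that("rotation augmentation yields 8 aligned copies", {
  set.seed(25)
  m <- matrix(runif(24 * 24), 24)
  mask <- matrix(sample(0:2, 24 * 24, TRUE), 24)
  rots <- augment_rotations(m, mask)
  expect_length(rots, 8)
  expect_equal(vapply(rots, `[[`, numeric(1), "angle"), seq(0, 315, by = 45))
  expect_identical(rots[[1]]$image, m)
  expect_identical(rots[[1]]$mask, mask)
  for (k in c(3, 5, 7)) {  # 90, 180, 270: exact grid permutations
    expect_identical(sort(as.vector(rots[[k]]$image)), sort(as.vector(m)))
    expect_identical(sort(unique(as.vector(rots[[k]]$mask))),
                     sort(unique(as.vector(mask))))
  }
  # oblique rotations keep the label alphabet (nearest-neighbour)
  expect_true(all(rots[[2]]$mask %in% 0:2))
  expect_error(augment_rotations(m, mask[1:10, 1:10]), "differ")
})

test_that("double 180-degree rotation is the identity", {
  m <- matrix(1:20, 4, 5)
  expect_identical(rotate_matrix(rotate_matrix(m, 180), 180), m)
})

test_that("the preprocessing pipeline composes stages in order", {
  set.seed(26)
  m <- matrix(runif(64 * 64, -1000, 400), 64)   # HU-like
  stages <- list("window",
                 list(stage = "clahe", tiles = c(4, 4)),
                 "wiener",
                 list(stage = "resize", target = c(32, 32)),
                 "normalize")
  out <- preprocess_pipeline(m, stages)
  manual <- normalize01(resize_image(wiener_filter(
    clahe(hounsfield_window(m), tiles = c(4, 4))), c(32, 32)))
  expect_equal(out, manual, tolerance = 1e-12)
  expect_identical(dim(out), c(32L, 32L))
  expect_identical(preprocess_pipeline(m, NULL), m)
  expect_identical(preprocess_pipeline(m, list()), m)
  expect_error(preprocess_pipeline(m, list("sharpen")), "unknown")
})

test_that("raster_image validates its declared range", {
  expect_error(raster_image(matrix(300, 2, 2), c(0, 255)), "outside")
  ri <- raster_image(matrix(runif(4), 2))
  expect_equal(ri$value_range, c(0, 1))
  expect_output(print(ri), "raster_image 2 x 2")
})
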