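# shared fixtures and independent oracles

# the printed two-component intensity regime used as simulation truth
table9_params <- function() {
  ltmix_params(weights = c(0.5, 0.5),
               locations = c(60.54, 121.98),
               scales = sqrt(c(94.2568, 128.784)),
               shape = 4)
}

draw_table9 <- function(n_per_comp, seed) {
  p <- table9_params()
  ctmixseg:::with_seed(seed, c(
    rltype(n_per_comp, p$locations[1], p$scales[1], p$shape),
    rltype(n_per_comp, p$locations[2], p$scales[2], p$shape)))
}

small_phantom_spec <- function(size = 32) {
  phantom_spec(size = c(size, size), n_nodules = c(1, 2),
               nodule_radius = c(2, 4))
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, next_max) {
    k <- length(labels)
    if (k == n) { out[[length(out) + 1]] <<- labels; return(invisible()) }
    for (l in seq_len(next_max + 1))
      grow(c(labels, l), max(next_max, l))
  }
  grow(integer(0), 0L)
  out
}

# brute-force partition metrics, written pair-by-pair / pixel-by-pixel,
# independent of the contingency-table implementations
oracle_rand <- function(a, b) {
  n <- length(a)
  if (n < 2) return(1)
  agree <- 0; total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1
  }
  agree / total
}

oracle_voi <- function(a, b) {
  n <- length(a)
  ent <- function(labs) {
    h <- 0
    for (l in unique(labs)) {
      p <- sum(labs == l) / n
      h <- h - p * log2(p)
    }
    h
  }
  joint <- paste(a, b)
  ent(a) + ent(b) - 2 * (ent(a) + ent(b) - ent(joint))
}

oracle_gce <- function(a, b) {
  n <- length(a)
  err_dir <- function(s, t_) {
    e <- 0
    for (x in seq_len(n)) {
      rs <- which(s == s[x])
      rt <- which(t_ == t_[x])
      e <- e + length(setdiff(rs, rt)) / length(rs)
    }
    e
  }
  min(err_dir(a, b), err_dir(b, a)) / n
}

# plain global histogram equalization (independent of the clahe code path)
oracle_global_he <- function(m, n_bins = 256, vr = c(0, 255)) {
  b <- pmin(pmax(floor((m - vr[1]) / (vr[2] - vr[1]) * n_bins) + 1, 1), n_bins)
  cdf <- cumsum(tabulate(b, n_bins)) / length(m)
  matrix(vr[1] + cdf[b] * (vr[2] - vr[1]), nrow(m), ncol(m))
}
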