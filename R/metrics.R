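#' Pixel-wise confusion counts
#'
#' Counts true/false positives/negatives between a predicted and a true
#' binary mask (nonzero = foreground = positive).
#'
#' @param pred,truth binary masks (logical or 0/1 numeric) of equal shape.
#' @return named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(pred, truth) {
  p <- as_binary(pred, "pred"); t_ <- as_binary(truth, "truth")
  check_same_shape(pred, truth)
  c(tp = sum(p & t_), fp = sum(p & !t_), fn = sum(!p & t_), tn = sum(!p & !t_))
}

as_binary <- function(m, what) {
  v <- as.logical(m != 0)
  if (any(is.na(v))) stop("'", what, "' contains NA", call. = FALSE)
  v
}

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a); db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop("mask shapes differ", call. = FALSE)
}

#' Confusion-derived statistics
#'
#' Accuracy, sensitivity (= recall), specificity, precision and F1 from
#' confusion counts. Ratios with zero denominator are reported as `NA`
#' (undefined), not errors.
#'
#' @param counts output of [confusion_counts()], or a predicted mask (with
#'   `truth` supplied).
#' @param truth optional true mask when `counts` is a mask.
#' @return named numeric vector
#'   `c(accuracy, sensitivity, specificity, precision, f1)`.
#' @export
basic_stats <- function(counts, truth = NULL) {
  if (!is.null(truth)) counts <- confusion_counts(counts, truth)
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  c(accuracy = sdiv(tp + tn, tp + fp + fn + tn),
    sensitivity = sdiv(tp, tp + fn),
    specificity = sdiv(tn, tn + fp),
    precision = sdiv(tp, tp + fp),
    f1 = sdiv(2 * tp, 2 * tp + fp + fn))
}

#' Dice coefficient and intersection-over-union
#'
#' Overlap ratios between binary masks: Dice `2|A∩B|/(|A|+|B|)` and
#' Jaccard/IoU `|A∩B|/|A∪B|`. Two empty masks count as perfect agreement
#' (1) by convention.
#'
#' @param pred,truth binary masks of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  check_same_shape(pred, truth)
  a <- as_binary(pred, "pred"); b <- as_binary(truth, "truth")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' @rdname dice_coefficient
#' @export
iou <- function(pred, truth) {
  check_same_shape(pred, truth)
  a <- as_binary(pred, "pred"); b <- as_binary(truth, "truth")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# shared contingency machinery for the partition metrics
partition_contingency <- function(seg, truth) {
  check_same_shape(seg, truth)
  s <- as.vector(seg); t_ <- as.vector(truth)
  table(factor(s), factor(t_))
}

#' Probabilistic Rand index
#'
#' With a single ground truth this is the Rand index: the fraction of pixel
#' pairs whose same-segment/different-segment relation agrees between the
#' two partitions. Invariant to relabeling; 1 for identical partitions.
#'
#' @param seg,truth label masks (any label alphabets) of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
pri <- function(seg, truth) {
  ct <- partition_contingency(seg, truth)
  n <- sum(ct)
  if (n < 2) return(1)
  pairs <- choose(n, 2)
  (pairs + sum(ct^2) - (sum(rowSums(ct)^2) + sum(colSums(ct)^2)) / 2) / pairs
}

#' Variation of information
#'
#' Meila's information-theoretic partition distance
#' `H(S) + H(T) - 2 I(S; T)` in bits; 0 iff the partitions are identical up
#' to relabeling, symmetric in its arguments.
#'
#' @inheritParams pri
#' @return non-negative scalar (bits).
#' @export
voi <- function(seg, truth) {
  ct <- partition_contingency(seg, truth)
  n <- sum(ct)
  p <- ct / n
  h <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hs <- h(rowSums(p)); ht <- h(colSums(p))
  mi <- hs + ht - h(as.vector(p))          # I = H(S) + H(T) - H(S,T)
  max(hs + ht - 2 * mi, 0)
}

#' Global consistency error
#'
#' Martin's refinement-tolerant segmentation error: the mean local
#' refinement error `|R(S,x) \ R(T,x)| / |R(S,x)|`, minimized over the two
#' directions, so any strict refinement scores 0.
#'
#' @inheritParams pri
#' @return scalar in `[0, 1]`.
#' @export
gce <- function(seg, truth) {
  ct <- partition_contingency(seg, truth)
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  e_st <- sum(ct * (a[row(ct)] - ct) / a[row(ct)])
  e_ts <- sum(ct * (b[col(ct)] - ct) / b[col(ct)])
  min(e_st, e_ts) / n
}

#' ROC curve and AUC for pixel scores
#'
#' Sweeps a threshold over the unique score values (ties move together),
#' accumulates true/false positive rates, and integrates the curve by the
#' trapezoidal rule. If the truth contains a single class the AUC is
#' undefined and returned as `NA`.
#'
#' @param scores numeric vector/matrix of per-pixel probabilities.
#' @param truth binary mask of the same shape.
#' @return list with `auc` and a data frame `curve` (`threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, truth) {
  check_same_shape(scores, truth)
  s <- as.vector(scores); y <- as_binary(truth, "truth")
  np <- sum(y); nn <- sum(!y)
  if (np == 0 || nn == 0)
    return(list(auc = NA_real_, curve = NULL))
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  keep <- c(diff(s) != 0, TRUE)            # last index of each tied block
  tpr <- cumsum(y)[keep] / np
  fpr <- cumsum(!y)[keep] / nn
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc,
       curve = data.frame(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr))
}

#' Evaluate a segmentation against ground truth
#'
#' Convenience wrapper computing the configured metrics for one sample.
#' Binary overlap metrics (`dice`, `iou`, and the confusion statistics)
#' treat nonzero labels as foreground; the partition metrics (`pri`, `voi`,
#' `gce`) use the full label alphabets. An optional region-of-interest mask
#' restricts every metric to the pixels inside it.
#'
#' @param pred predicted label mask.
#' @param truth true label mask.
#' @param metrics character vector from `c("dice", "iou", "accuracy",
#'   "sensitivity", "specificity", "precision", "f1", "pri", "voi", "gce")`.
#' @param roi optional binary mask; metrics are computed within it.
#' @return named numeric vector of metric values.
#' @export
evaluate_masks <- function(pred, truth,
                           metrics = c("dice", "iou", "pri", "voi", "gce"),
                           roi = NULL) {
  if (!is.null(roi)) {
    check_same_shape(pred, roi)
    keep <- as_binary(roi, "roi")
    pred <- as.vector(pred)[keep]
    truth <- as.vector(truth)[keep]
  }
  known <- c("dice", "iou", "accuracy", "sensitivity", "specificity",
             "precision", "f1", "pri", "voi", "gce")
  bad <- setdiff(metrics, known)
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  out <- numeric(0)
  if (any(metrics %in% known[1:7])) {
    bs <- basic_stats(confusion_counts(pred, truth))
    out <- c(out, dice = dice_coefficient(pred, truth), iou = iou(pred, truth),
             bs)
  }
  if ("pri" %in% metrics) out <- c(out, pri = pri(pred, truth))
  if ("voi" %in% metrics) out <- c(out, voi = voi(pred, truth))
  if ("gce" %in% metrics) out <- c(out, gce = gce(pred, truth))
  out[metrics]
}

#' Aggregate per-sample metric rows
#'
#' Mean and population standard deviation per metric across samples (a
#' single sample reports sd 0), in long form plus a rendered
#' `"mean +/- sd"` summary string, the conventional presentation of
#' segmentation benchmarks.
#'
#' @param per_sample data frame with columns `sample_id`, `metric`, `value`.
#' @param percent logical; render the summary in percent.
#' @return data frame with columns `metric`, `mean`, `sd`, `n`, `summary`.
#' @export
aggregate_report <- function(per_sample, percent = FALSE) {
  stopifnot(is.data.frame(per_sample),
            all(c("metric", "value") %in% names(per_sample)))
  if (!nrow(per_sample)) stop("no metric rows to aggregate", call. = FALSE)
  sp <- split(per_sample$value, per_sample$metric)
  scale <- if (percent) 100 else 1
  out <- do.call(rbind, lapply(names(sp), function(m) {
    v <- sp[[m]][!is.na(sp[[m]])]
    mu <- mean(v)
    sdv <- if (length(v) > 1) sqrt(mean((v - mu)^2)) else 0
    data.frame(metric = m, mean = mu, sd = sdv, n = length(v),
               summary = sprintf("%.2f ± %.2f%s", mu * scale, sdv * scale,
                                 if (percent) "%" else ""))
  }))
  rownames(out) <- NULL
  out[order(out$metric), , drop = FALSE]
}

#' Match predicted segment labels to ground truth
#'
#' Segmentation labels from a mixture fit are arbitrary up to permutation.
#' For K up to 8 this searches all label permutations for the one
#' maximizing pixel agreement with the truth; larger alphabets fall back to
#' greedy majority matching on the contingency table.
#'
#' @param pred predicted label mask.
#' @param truth true label mask.
#' @return `pred` relabeled into the truth's alphabet.
#' @export
relabel_to_truth <- function(pred, truth) {
  check_same_shape(pred, truth)
  ct <- partition_contingency(pred, truth)
  plabs <- rownames(ct); tlabs <- colnames(ct)
  if (length(plabs) <= 8 && length(plabs) <= length(tlabs)) {
    perms <- permutations_of(seq_along(tlabs), length(plabs))
    agree <- vapply(perms, function(pm) sum(ct[cbind(seq_along(plabs), pm)]),
                    numeric(1))
    map <- tlabs[perms[[which.max(agree)]]]
  } else {
    map <- tlabs[max.col(ct, ties.method = "first")]
  }
  out <- map[match(as.vector(as.character(pred)), plabs)]
  out <- utils::type.convert(out, as.is = TRUE)
  if (!is.null(dim(pred))) dim(out) <- dim(pred)
  out
}

# all injective maps of 1..k into 'from' (k-permutations)
permutations_of <- function(from, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(from)) {
    rest <- permutations_of(from[-i], k - 1)
    out <- c(out, lapply(rest, function(r) c(from[i], r)))
  }
  out
}
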