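# independent brute-force oracle: expand counts into per-sample outcomes and
# recompute every metric from first principles
oracle_from_counts <- function(tp, tn, fp, fn) {
  truth <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  pred <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  n <- length(truth)
  list(
    acc = sum(truth == pred) / n,
    sens = if (sum(truth == 1) > 0) {
      sum(truth == 1 & pred == 1) / sum(truth == 1)
    } else NA,
    spec = if (sum(truth == 0) > 0) {
      sum(truth == 0 & pred == 0) / sum(truth == 0)
    } else NA,
    f1_std = 2 * tp / (2 * tp + fp + fn),
    f1_threat = tp / (tp + fp + fn),
    mcc = {
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
    }
  )
}

# exhaustive concordant-pair counting with half-weight ties
pair_count_auc <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
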