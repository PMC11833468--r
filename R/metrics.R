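#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the marginal products. Accepts any pair of equal-length
#' categorical (or binary) vectors. In the degenerate case `p_e == 1` (both
#' raters confined to one identical category) kappa is returned as 1 for
#' perfect agreement and 0 otherwise, with a warning.
#'
#' @param x,y Equal-length vectors of labels.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 1) stop("empty vectors", call. = FALSE)
  lv <- sort(unique(c(x, y)))
  tab <- table(factor(x, lv), factor(y, lv)) / length(x)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (1 - pe < 1e-12) {
    warning("degenerate kappa: both raters constant", call. = FALSE)
    return(if (po >= 1 - 1e-12) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

# ROC AUC by the rank statistic (Mann-Whitney with tie midranks).
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores) # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics
#'
#' Standard confusion-matrix metrics of predicted presence against gold
#' presence, plus ROC AUC computed from a ranking score by the rank
#' statistic (tie midranks). When the gold vector is single-class the AUC is
#' undefined and reported as `NA`; the other metrics are still computed.
#' Accuracy and precision are included as supplementary metrics.
#'
#' @param pred,gold Equal-length 0/1 vectors.
#' @param scores Ranking score for AUC; defaults to `pred` itself. The
#'   pipeline uses the validated count as the score (higher count = stronger
#'   evidence of presence).
#' @return Named list: recall, precision, f1, accuracy, auc, kappa.
#' @export
binary_metrics <- function(pred, gold, scores = pred) {
  if (length(pred) != length(gold) || length(scores) != length(gold)) {
    stop("length mismatch", call. = FALSE)
  }
  tp <- sum(pred == 1 & gold == 1)
  fp <- sum(pred == 1 & gold == 0)
  fn <- sum(pred == 0 & gold == 1)
  tn <- sum(pred == 0 & gold == 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0) {
    2 * precision * recall / (precision + recall)
  } else if ((tp + fn > 0 || tp + fp > 0)) 0 else NA_real_
  list(
    recall = recall,
    precision = precision,
    f1 = f1,
    accuracy = (tp + tn) / length(gold),
    auc = auc_rank(scores, gold),
    kappa = suppressWarnings(cohen_kappa(pred, gold))
  )
}

#' Bin non-negative counts into ordinal labels
#'
#' Bins partition the non-negative integers; the default
#' `bins = c(0, 1, 2, 3)` yields the labels \{0\}, \{1\}, \{2\}, \{3+\}.
#'
#' @param x Non-negative integer vector.
#' @param bins Increasing vector of bin lower bounds starting at 0.
#' @return Integer bin labels.
#' @export
bin_counts <- function(x, bins = c(0, 1, 2, 3)) {
  stopifnot(bins[1] == 0, !is.unsorted(bins, strictly = TRUE))
  findInterval(x, bins)
}

#' Count-agreement metrics
#'
#' Spearman's rank correlation (midrank ties), Cohen's kappa on binned
#' counts (unweighted, via [cohen_kappa()] on the bin labels), and mean
#' absolute error. Spearman is `NA` when either vector is constant.
#'
#' @param pred_counts,gold_counts Equal-length non-negative integer vectors.
#' @param bins Bin spec for the binned kappa (see [bin_counts()]).
#' @return Named list: spearman_rho, kappa_binned, mae.
#' @export
count_metrics <- function(pred_counts, gold_counts, bins = c(0, 1, 2, 3)) {
  if (length(pred_counts) != length(gold_counts)) {
    stop("length mismatch", call. = FALSE)
  }
  rho <- if (stats::sd(pred_counts) == 0 || stats::sd(gold_counts) == 0) {
    NA_real_
  } else {
    stats::cor(pred_counts, gold_counts, method = "spearman")
  }
  list(
    spearman_rho = rho,
    kappa_binned = suppressWarnings(
      cohen_kappa(bin_counts(pred_counts, bins), bin_counts(gold_counts, bins))
    ),
    mae = mean(abs(pred_counts - gold_counts))
  )
}

#' Analytic kappa implied by planted error rates
#'
#' Closed-form expected Cohen's kappa of a binary extractor that, against a
#' gold standard with positive prevalence `prevalence`, produces false
#' positives at rate `fpr` and misses positives at rate `fnr`. Used to check
#' that measured kappa on simulated extractor errors converges to its
#' planted value.
#'
#' @param prevalence P(gold = 1).
#' @param fpr P(pred = 1 | gold = 0).
#' @param fnr P(pred = 0 | gold = 1).
#' @return Expected kappa.
#' @export
expected_kappa_from_error_rates <- function(prevalence, fpr, fnr) {
  p <- prevalence
  po <- p * (1 - fnr) + (1 - p) * (1 - fpr)
  q <- p * (1 - fnr) + (1 - p) * fpr # P(pred = 1)
  pe <- q * p + (1 - q) * (1 - p)
  (po - pe) / (1 - pe)
}
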