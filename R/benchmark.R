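# Confusion-count benchmarking of a subsampled set against the
# full-depth truth set, and the Welch test used for group comparisons.

#' Confusion counts of a set against a truth set
#'
#' TP = elements in both the subsample and the truth set, FP = only in
#' the subsample, FN = only in the truth set. No true-negative count is
#' defined (there is no closed universe of genes).
#'
#' @param subsample_set,truth_set Vectors of identifiers (duplicates
#'   ignored).
#' @return One-row tibble with `tp`, `fp`, `fn`.
#' @examples
#' confusion(c("a", "b", "c"), c("b", "c", "d"))
#' @export
confusion <- function(subsample_set, truth_set) {
  a <- unique(subsample_set)
  t <- unique(truth_set)
  tibble(
    tp = length(intersect(a, t)),
    fp = length(setdiff(a, t)),
    fn = length(setdiff(t, a))
  )
}

#' Precision, recall and F-score from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `f_score = TP / (TP + (FP + FN) / 2)` (equal to the harmonic mean
#' 2PR/(P+R) whenever both are defined and nonzero). Degenerate
#' denominators (an empty subsample or an empty truth set) yield `NA`
#' rather than 0, so "no calls" is distinguishable from "all wrong".
#'
#' @param counts One-row data frame with `tp`, `fp`, `fn` (e.g. from
#'   [confusion()]), or a numeric vector `c(tp, fp, fn)`.
#' @return One-row tibble with `precision`, `recall`, `f_score`.
#' @export
precision_recall_f <- function(counts) {
  if (is.numeric(counts) && length(counts) == 3) {
    counts <- tibble(tp = counts[1], fp = counts[2], fn = counts[3])
  }
  stopifnot(all(c("tp", "fp", "fn") %in% names(counts)))
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  stopifnot(all(c(tp, fp, fn) >= 0))
  tibble(
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    recall = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
    f_score = ifelse(tp + fp + fn > 0, tp / (tp + (fp + fn) / 2), NA_real_)
  )
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value (thin wrapper over [stats::t.test()]
#' returning a tidy row).
#'
#' @param x,y Numeric vectors, each of length >= 2, with nonzero
#'   variance in at least one.
#' @return One-row tibble with `t`, `df`, `p_value`, `mean_x`,
#'   `mean_y`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("Both groups need at least 2 observations.", class = "satseq_statistic_error")
  }
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      # degenerate but well-defined: identical constants differ by 0
      return(tibble(t = 0, df = NA_real_, p_value = 1, mean_x = mean(x), mean_y = mean(y)))
    }
    abort("Both groups are constant; Welch statistic undefined.", class = "satseq_statistic_error")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  tibble(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_x = mean(x),
    mean_y = mean(y)
  )
}
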