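# Expressed- and informative-gene definitions.
#
# "Expressed" is deliberately liberal — at least one mapped read in a
# sample. "Informative" is the conservative core set usable as
# population-level molecular phenotypes: at least `min_count` reads in
# at least `min_sample_fraction` of the samples (>= 10 reads in >= 50%
# of samples by default; the sample cutoff rounds up for odd n).

#' Expressed genes per sample
#'
#' @param counts Integer gene-by-sample matrix with dimnames.
#' @param min_count Minimum count for a gene to be called expressed in
#'   a sample (default 1, i.e. "at least a single read aligned").
#' @return Tibble with `sample_id`, `n_expressed`, and a list-column
#'   `genes` of expressed gene IDs.
#' @export
expressed_genes_per_sample <- function(counts, min_count = 1) {
  validate_counts(counts)
  stopifnot(min_count >= 1)
  hits <- counts >= min_count
  tibble(
    sample_id = colnames(counts),
    n_expressed = as.integer(colSums(hits)),
    genes = purrr::map(seq_len(ncol(counts)), function(j) rownames(counts)[hits[, j]])
  )
}

#' Dataset-level expressed genes (union over samples)
#'
#' Genes with `count >= min_count` in at least one sample.
#'
#' @inheritParams expressed_genes_per_sample
#' @return Character vector of gene IDs.
#' @export
expressed_genes_union <- function(counts, min_count = 1) {
  validate_counts(counts)
  rownames(counts)[rowSums(counts >= min_count) >= 1]
}

#' Informative genes
#'
#' Genes with at least `min_count` reads in at least
#' `ceiling(min_sample_fraction * n_samples)` samples.
#'
#' @inheritParams expressed_genes_per_sample
#' @param min_count Count threshold per sample (default 10).
#' @param min_sample_fraction Fraction of samples that must meet the
#'   count threshold (default 0.5); the required sample count is the
#'   ceiling of `min_sample_fraction * n_samples`.
#' @return Character vector of gene IDs.
#' @export
informative_genes <- function(counts, min_count = 10, min_sample_fraction = 0.5) {
  validate_counts(counts)
  stopifnot(min_count >= 1, min_sample_fraction > 0, min_sample_fraction <= 1)
  need <- ceiling(min_sample_fraction * ncol(counts))
  rownames(counts)[rowSums(counts >= min_count) >= need]
}

#' Prevalence distribution of detected genes
#'
#' For each k = 1..n_samples, the number of genes detected in exactly k
#' samples, under either the expressed rule (`count >= 1`) or the
#' informative count threshold (`count >= min_count`). The histogram
#' sums to the number of genes detected in at least one sample.
#'
#' @inheritParams expressed_genes_per_sample
#' @param rule `"expressed"` or `"informative"`.
#' @param min_count Per-sample detection threshold used when
#'   `rule = "informative"` (default 10).
#' @return Tibble with `n_samples_detected` (k) and `n_genes`.
#' @export
prevalence_distribution <- function(counts, rule = c("expressed", "informative"),
                                    min_count = 10) {
  rule <- match.arg(rule)
  validate_counts(counts)
  thr <- if (rule == "expressed") 1 else min_count
  k <- rowSums(counts >= thr)
  n <- ncol(counts)
  tibble(
    n_samples_detected = seq_len(n),
    n_genes = as.integer(tabulate(k[k >= 1], nbins = n))
  )
}

#' Per-sample detection summary
#'
#' One row per sample with its expressed- and informative-threshold
#' gene counts, plus dataset-level totals as an attribute — the
#' machine-readable version of a per-kit detection figure.
#'
#' @inheritParams informative_genes
#' @return Tibble with `sample_id`, `n_expressed`,
#'   `n_meeting_informative_count`; attribute `"dataset"` holds a
#'   one-row tibble with the union expressed count and the informative
#'   set size.
#' @export
detection_summary <- function(counts, min_count = 10, min_sample_fraction = 0.5) {
  validate_counts(counts)
  out <- tibble(
    sample_id = colnames(counts),
    n_expressed = as.integer(colSums(counts >= 1)),
    n_meeting_informative_count = as.integer(colSums(counts >= min_count))
  )
  attr(out, "dataset") <- tibble(
    n_expressed_union = length(expressed_genes_union(counts)),
    n_informative = length(informative_genes(counts, min_count, min_sample_fraction))
  )
  out
}

#' Prevalence histogram plot
#'
#' @param counts Integer gene-by-sample matrix.
#' @param rule,min_count Passed to [prevalence_distribution()].
#' @return A ggplot.
#' @export
plot_prevalence <- function(counts, rule = c("expressed", "informative"), min_count = 10) {
  rule <- match.arg(rule)
  pd <- prevalence_distribution(counts, rule, min_count)
  ggplot2::ggplot(pd, ggplot2::aes(.data$n_samples_detected, .data$n_genes)) +
    ggplot2::geom_col(fill = if (rule == "expressed") "#5B9BD5" else "#ED7D31") +
    ggplot2::labs(
      x = "Number of samples in which the gene is detected",
      y = "Number of genes",
      title = sprintf("Prevalence of %s genes", rule)
    )
}
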