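# Seeded depth downsampling of count matrices.
#
# Subsampling reads without replacement induces a multivariate
# hypergeometric distribution on per-gene counts, so thinning counts
# hypergeometrically is the exact count-level equivalent of read-level
# subsampling (seqtk-style). Draws use the sequential conditional
# decomposition: gene g receives Hyper(c_g, remaining_total - c_g,
# remaining_draw), which is vectorized across samples.

# Joint hypergeometric thinning of all columns; `target` is a vector of
# per-sample draw sizes (must be <= column totals).
thin_matrix_hyper <- function(counts, target) {
  n_genes <- nrow(counts)
  n_samples <- ncol(counts)
  rem <- colSums(counts)
  k <- as.numeric(target)
  stopifnot(all(k <= rem), all(k >= 0))
  out <- matrix(0L, n_genes, n_samples, dimnames = dimnames(counts))
  for (g in seq_len(n_genes)) {
    if (!any(k > 0)) break
    cg <- counts[g, ]
    x <- rhyper(n_samples, m = cg, n = rem - cg, k = k)
    out[g, ] <- as.integer(x)
    k <- k - x
    rem <- rem - cg
  }
  out
}

#' Downsample one sample's counts to a target depth
#'
#' `without_replacement` (the default, and the faithful equivalent of
#' read subsampling) draws a multivariate hypergeometric sample: the
#' output sums exactly to `target_depth`. `with_replacement` draws a
#' multinomial with probabilities proportional to the counts.
#'
#' @param counts_column Non-negative integer vector (one sample's
#'   per-gene counts); names are preserved.
#' @param target_depth Target total (reads for this sample).
#' @param seed Integer seed; identical seeds give identical draws.
#' @param mode `"without_replacement"` or `"with_replacement"`.
#' @return Integer vector of thinned counts.
#' @examples
#' downsample_sample(c(a = 900, b = 100), 100, seed = 1)
#' @export
downsample_sample <- function(counts_column, target_depth, seed,
                              mode = c("without_replacement", "with_replacement")) {
  mode <- match.arg(mode)
  stopifnot(all(counts_column >= 0), target_depth >= 0)
  total <- sum(counts_column)
  if (mode == "without_replacement" && target_depth > total) {
    abort(
      sprintf("target_depth (%s) exceeds the column total (%s).", format(target_depth), format(total)),
      class = "satseq_depth_error"
    )
  }
  withr::with_seed(seed, {
    if (mode == "without_replacement") {
      m <- matrix(as.numeric(counts_column), ncol = 1)
      out <- thin_matrix_hyper(m, target_depth)[, 1]
    } else {
      if (total == 0) abort("Cannot resample from an all-zero column.", class = "satseq_depth_error")
      out <- as.integer(rmultinom(1, target_depth, prob = counts_column)[, 1])
    }
    names(out) <- names(counts_column)
    out
  })
}

#' Downsample a count matrix over a (depth x seed) replicate grid
#'
#' For every combination of `depths` and `seeds`, every sample is
#' thinned independently to the target depth. The random substream for
#' a grid cell is derived deterministically from `(seed, depth)`, so
#' results do not depend on the order in which cells are evaluated.
#'
#' @param counts Integer gene-by-sample matrix with dimnames.
#' @param depths Positive target depths (reads per sample).
#' @param seeds Unique integer replicate seeds.
#' @param mode Passed to the per-sample draw; see [downsample_sample()].
#' @param infeasible Policy when a depth exceeds a sample's total in
#'   `without_replacement` mode: `"error"` (default) or `"cap"` (thin
#'   that sample to its own total).
#' @return Tibble with one row per grid cell: `depth`, `seed`, and a
#'   list-column `counts` of thinned matrices.
#' @export
downsample_matrix <- function(counts, depths, seeds,
                              mode = c("without_replacement", "with_replacement"),
                              infeasible = c("error", "cap")) {
  mode <- match.arg(mode)
  infeasible <- match.arg(infeasible)
  validate_counts(counts)
  stopifnot(length(depths) >= 1, length(seeds) >= 1)
  if (anyDuplicated(seeds)) abort("`seeds` must be unique.")
  totals <- colSums(counts)

  grid <- tidyr::expand_grid(depth = as.numeric(depths), seed = as.integer(seeds))
  grid$counts <- purrr::map2(grid$depth, grid$seed, function(d, s) {
    target <- rep(d, ncol(counts))
    if (mode == "without_replacement" && any(target > totals)) {
      if (infeasible == "error") {
        abort(
          sprintf(
            "Depth %s infeasible for sample(s) %s (totals below target).",
            format(d), paste(colnames(counts)[target > totals], collapse = ", ")
          ),
          class = "satseq_depth_error"
        )
      }
      target <- pmin(target, totals)
    }
    withr::with_seed(derive_seed(s, d), {
      if (mode == "without_replacement") {
        thin_matrix_hyper(counts, target)
      } else {
        out <- vapply(seq_len(ncol(counts)), function(j) {
          as.integer(rmultinom(1, target[j], prob = counts[, j])[, 1])
        }, integer(nrow(counts)))
        dimnames(out) <- dimnames(counts)
        out
      }
    })
  })
  grid
}

#' Coupled (nested) downsampling of one sample across depths
#'
#' Draws a single random permutation of the sample's reads and takes the
#' first `d` slots for each depth, so smaller depths are exact subsets
#' of larger ones. Useful for monotonicity checks (a gene detected at
#' 0.5M coupled reads is always detected at 12M); marginally each depth
#' is still an exact hypergeometric thinning.
#'
#' @inheritParams downsample_sample
#' @param depths Increasing target depths, all `<= sum(counts_column)`.
#' @return Tibble with `depth` and list-column `counts` (named integer
#'   vectors).
#' @export
downsample_coupled <- function(counts_column, depths, seed) {
  total <- sum(counts_column)
  stopifnot(all(depths >= 0), all(depths <= total))
  gene_of_read <- rep(seq_along(counts_column), counts_column)
  withr::with_seed(seed, {
    ord <- sample.int(total)
  })
  shuffled <- gene_of_read[ord]
  tibble(
    depth = as.numeric(depths),
    counts = purrr::map(depths, function(d) {
      out <- tabulate(shuffled[seq_len(d)], nbins = length(counts_column))
      names(out) <- names(counts_column)
      out
    })
  )
}
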