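#' Simulate a 3' mRNA-Seq gene-by-sample count matrix with known DE truth
#'
#' Draws negative-binomial counts for a two-condition whole-blood-style
#' design. Gene baseline abundances are log-uniform (a long tail of rare
#' genes plus a core of highly expressed genes, so detection thresholds
#' have something to bite on); a designated subset of genes carries a
#' condition effect of `2^lfc_magnitude`, split between up- and
#' down-regulation by `de_balance`. Per-gene means are scaled so the
#' expected library size of every sample equals `depth_per_sample`.
#'
#' The defaults emulate the study design this package targets: ~27
#' samples in two groups, ~15,000 annotated genes with detectable
#' expression potential in blood, and full-depth libraries of ~12.5
#' million mapped reads per sample.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_condition Integer vector of length 1 or 2 giving
#'   group sizes (length 1 is recycled to both groups).
#' @param baseline_mean_log_range Range (natural-log scale) of relative
#'   gene abundances, drawn log-uniformly.
#' @param dispersion NB dispersion alpha; variance = mu + alpha * mu^2.
#' @param n_de_genes Number of genes given a true condition effect.
#' @param lfc_magnitude Absolute log2 fold change of true DE genes.
#' @param de_balance Fraction of DE genes that are up-regulated in the
#'   second condition.
#' @param depth_per_sample Expected total counts per sample.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A list of class `sim_counts`:
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples}
#'     \item{condition}{character vector of condition labels per sample}
#'     \item{de_genes}{character vector of true DE gene IDs}
#'     \item{truth}{tibble with `gene_id`, `true_log2_fc`, `baseline_mean`}
#'   }
#' @examples
#' sim <- simulate_counts(n_genes = 200, n_samples_per_condition = 3,
#'                        depth_per_sample = 1e4, seed = 1)
#' dim(sim$counts)
#' @export
simulate_counts <- function(n_genes = 15000,
                            n_samples_per_condition = c(14L, 13L),
                            baseline_mean_log_range = log(c(0.01, 1000)),
                            dispersion = 0.1,
                            n_de_genes = 1500,
                            lfc_magnitude = 1,
                            de_balance = 0.5,
                            depth_per_sample = 12.5e6,
                            seed = 1L) {
  if (n_genes < 1 || any(n_samples_per_condition < 1)) {
    abort("`n_genes` and `n_samples_per_condition` must be positive.")
  }
  if (dispersion <= 0) abort("`dispersion` must be > 0.")
  if (n_de_genes < 0 || n_de_genes > n_genes) {
    abort("`n_de_genes` must lie in [0, n_genes].")
  }
  if (depth_per_sample < 1) abort("`depth_per_sample` must be >= 1.")
  if (length(n_samples_per_condition) == 1) {
    n_samples_per_condition <- rep(n_samples_per_condition, 2)
  }

  n_a <- n_samples_per_condition[1]
  n_b <- n_samples_per_condition[2]
  n_samples <- n_a + n_b
  condition <- rep(c("A", "B"), c(n_a, n_b))
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  sample_ids <- sprintf("s%02d", seq_len(n_samples))

  withr::with_seed(seed, {
    w <- exp(runif(n_genes, baseline_mean_log_range[1], baseline_mean_log_range[2]))
    mu_base <- w / sum(w) * depth_per_sample

    lfc <- numeric(n_genes)
    de_idx <- integer(0)
    if (n_de_genes > 0) {
      de_idx <- sample.int(n_genes, n_de_genes)
      n_up <- round(n_de_genes * de_balance)
      sign <- rep(-1, n_de_genes)
      if (n_up > 0) sign[seq_len(n_up)] <- 1
      lfc[de_idx] <- sign * lfc_magnitude
    }

    mu_b <- mu_base * 2^lfc
    # rescale condition B so its expected depth also equals depth_per_sample
    mu_b <- mu_b / sum(mu_b) * depth_per_sample

    size <- 1 / dispersion
    counts_a <- matrix(
      rnbinom(n_genes * n_a, mu = rep(mu_base, n_a), size = size),
      nrow = n_genes
    )
    counts_b <- matrix(
      rnbinom(n_genes * n_b, mu = rep(mu_b, n_b), size = size),
      nrow = n_genes
    )
    counts <- cbind(counts_a, counts_b)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(gene_ids, sample_ids)

    structure(
      list(
        counts = counts,
        condition = condition,
        de_genes = gene_ids[sort(de_idx)],
        truth = tibble(
          gene_id = gene_ids,
          true_log2_fc = lfc,
          baseline_mean = mu_base,
          mean_condition_b = mu_b
        )
      ),
      class = "sim_counts"
    )
  })
}

#' @export
print.sim_counts <- function(x, ...) {
  cat(sprintf(
    "<sim_counts> %d genes x %d samples (%d true DE genes)\n",
    nrow(x$counts), ncol(x$counts), length(x$de_genes)
  ))
  invisible(x)
}
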