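# Two-group negative-binomial differential expression.
#
# A self-contained NB Wald stage: median-of-ratios normalization,
# method-of-moments dispersion estimation shrunk toward a fitted
# mean-dispersion trend, a per-gene NB GLM (log link, cell-means
# parameterization so label swaps are exactly antisymmetric), Wald
# p-values from the standard normal, and Benjamini-Hochberg adjustment.
# It is deliberately not a DESeq2 clone: no Cook's filtering, no
# independent filtering, no LFC shrinkage.

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's factor is the median over
#' genes of its counts divided by the per-gene geometric-mean
#' reference, rescaled so the factors have geometric mean 1. When no
#' gene is nonzero in every sample (sparse shallow libraries), a
#' positive-counts-only variant is used: geometric means are taken over
#' positive entries and medians over genes where the sample is nonzero.
#'
#' @param counts Integer gene-by-sample matrix.
#' @param fallback Use the positive-counts variant when no gene is
#'   ubiquitously nonzero (default `TRUE`); with `FALSE` that situation
#'   is an error.
#' @return Named positive numeric vector, geometric mean 1.
#' @export
size_factors <- function(counts, fallback = TRUE) {
  validate_counts(counts)
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  usable <- is.finite(loggeo)
  if (any(usable)) {
    ratios <- logc[usable, , drop = FALSE] - loggeo[usable]
    sf <- exp(apply(ratios, 2, median))
  } else {
    if (!fallback) {
      abort("No gene has nonzero counts in all samples.", class = "satseq_normalization_error")
    }
    pos <- counts > 0
    any_pos <- rowSums(pos) > 0
    loggeo <- rowSums(ifelse(pos, logc, 0)) / ncol(counts)
    sf <- vapply(seq_len(ncol(counts)), function(j) {
      ok <- any_pos & pos[, j]
      if (!any(ok)) {
        abort(sprintf("Sample %s has no positive counts.", colnames(counts)[j]),
          class = "satseq_normalization_error"
        )
      }
      exp(median(logc[ok, j] - loggeo[ok]))
    }, numeric(1))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Per-gene NB dispersion estimates
#'
#' Method-of-moments on normalized counts: pooled within-group sample
#' variance minus the Poisson component, divided by the squared mean
#' (`variance = mu + alpha * mu^2`). Raw estimates are floored and
#' shrunk toward a fitted mean-dispersion trend
#' `alpha(mu) = a0 + a1 / mu` by `shrink_weight` (the trend borrows
#' strength across genes, stabilizing the per-gene estimates the Wald
#' test plugs in).
#'
#' @param counts Integer gene-by-sample matrix.
#' @param sf Size factors from [size_factors()].
#' @param condition Two-level label vector, >= 2 samples per level.
#' @param shrink_weight Weight on the trend in the shrunk estimate,
#'   in `[0, 1]`.
#' @param floor Minimum dispersion.
#' @return Named numeric vector of dispersions (one per gene).
#' @export
estimate_dispersions <- function(counts, sf, condition,
                                 shrink_weight = 0.5, floor = 1e-8) {
  validate_counts(counts)
  lv <- sort(unique(condition))
  if (length(lv) != 2) abort("`condition` must have exactly two levels.", class = "satseq_design_error")
  if (any(table(condition) < 2)) {
    abort("Each group needs at least 2 samples for dispersion estimation.", class = "satseq_design_error")
  }
  q <- sweep(counts, 2, sf, "/")
  n <- ncol(counts)
  g1 <- condition == lv[1]
  g2 <- condition == lv[2]
  n1 <- sum(g1)
  n2 <- sum(g2)
  m1 <- rowMeans(q[, g1, drop = FALSE])
  m2 <- rowMeans(q[, g2, drop = FALSE])
  v1 <- apply(q[, g1, drop = FALSE], 1, var)
  v2 <- apply(q[, g2, drop = FALSE], 1, var)
  v_within <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)
  mu_bar <- (n1 * m1 + n2 * m2) / n
  xi <- mean(1 / sf) # Poisson component of Var(count/sf) is mu * E[1/sf]
  alpha_raw <- ifelse(mu_bar > 0, (v_within - mu_bar * xi) / mu_bar^2, NA_real_)

  # mean-dispersion trend alpha(mu) = a0 + a1/mu on moderately expressed genes
  ok <- is.finite(alpha_raw) & mu_bar >= 1
  trend <- rep(NA_real_, length(alpha_raw))
  if (sum(ok) >= 10) {
    fit <- lm(alpha_raw[ok] ~ I(1 / mu_bar[ok]))
    a0 <- max(coef(fit)[1], floor)
    a1 <- max(coef(fit)[2], 0)
    trend <- a0 + a1 / mu_bar
  } else if (any(ok)) {
    trend <- rep(max(median(alpha_raw[ok]), floor), length(alpha_raw))
  } else {
    trend <- rep(floor, length(alpha_raw))
  }

  alpha_raw <- pmax(alpha_raw, floor)
  alpha <- (1 - shrink_weight) * alpha_raw + shrink_weight * pmax(trend, floor)
  alpha[!is.finite(alpha)] <- floor
  setNames(pmax(alpha, floor), rownames(counts))
}

#' Per-gene NB Wald test for a two-group design
#'
#' Fits, per gene, an NB GLM with log link and a group indicator (via
#' an orthogonal cell-means parameterization: one log-mean per group,
#' size factors as offsets), with the supplied dispersions plugged in.
#' The group contrast is the natural-log fold change; the Wald
#' statistic is contrast / SE with SE from the Fisher information, and
#' the two-sided p-value uses a t reference with `n - 2` degrees of
#' freedom (the plug-in Wald statistic is t-like rather than normal at
#' realistic sample sizes; the t reference keeps the null rejection
#' rate at its nominal level). Genes with all
#' counts zero are reported untested; non-converged genes keep their
#' estimates but get `NA` p-values.
#'
#' Because the two group means are estimated independently, relabelling
#' the groups negates every log fold change exactly and leaves
#' p-values bit-identical.
#'
#' @param counts Integer gene-by-sample matrix.
#' @param sf Size factors.
#' @param dispersions Per-gene dispersion vector.
#' @param condition Two-level label vector; fold changes are level 2 vs
#'   level 1 in sorted level order.
#' @param max_iter,tol IRLS controls.
#' @return Tibble: `gene_id`, `base_mean`, `log2_fold_change`, `se`,
#'   `stat`, `p_value`, `status` (`"tested"`, `"zero"`,
#'   `"not_converged"`).
#' @export
nb_wald_test <- function(counts, sf, dispersions, condition,
                         max_iter = 50, tol = 1e-10) {
  validate_counts(counts)
  lv <- sort(unique(condition))
  if (length(lv) != 2) abort("`condition` must have exactly two levels.", class = "satseq_design_error")
  alpha <- dispersions[rownames(counts)]
  q <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(q)
  all_zero <- rowSums(counts) == 0

  # one intercept-only NB GLM per group, vectorized across genes
  fit_group <- function(y, s) {
    n_g <- nrow(y)
    mu0 <- pmax(rowMeans(sweep(y, 2, s, "/")), 1e-8)
    gamma <- log(mu0)
    info <- numeric(n_g)
    converged <- rep(FALSE, n_g)
    log_s <- log(s)
    for (it in seq_len(max_iter)) {
      eta <- outer(gamma, rep(1, ncol(y))) # G x n
      mu <- exp(sweep(eta, 2, log_s, "+"))
      mu <- pmin(pmax(mu, 1e-10), 1e12)
      w <- mu / (1 + alpha * mu)
      z <- eta + (y - mu) / mu
      sw <- rowSums(w)
      gamma_new <- rowSums(w * z) / sw
      gamma_new <- pmin(pmax(gamma_new, -30), 30)
      delta <- abs(gamma_new - gamma)
      done <- delta < tol * (1 + abs(gamma))
      converged <- converged | done
      gamma <- gamma_new
      info <- sw
      if (all(done)) break
    }
    list(gamma = gamma, info = info, converged = converged)
  }

  f1 <- fit_group(counts[, condition == lv[1], drop = FALSE], sf[condition == lv[1]])
  f2 <- fit_group(counts[, condition == lv[2], drop = FALSE], sf[condition == lv[2]])

  beta1 <- f2$gamma - f1$gamma # natural-log fold change, level 2 vs 1
  se <- sqrt(1 / f1$info + 1 / f2$info)
  stat <- beta1 / se
  df_resid <- max(ncol(counts) - 2, 1)
  p <- 2 * pt(-abs(stat), df = df_resid)
  status <- dplyr::case_when(
    all_zero ~ "zero",
    !(f1$converged & f2$converged) ~ "not_converged",
    TRUE ~ "tested"
  )
  p[status != "tested"] <- NA_real_

  tibble(
    gene_id = rownames(counts),
    base_mean = base_mean,
    log2_fold_change = ifelse(status == "zero", NA_real_, beta1 / log(2)),
    se = ifelse(status == "zero", NA_real_, se / log(2)),
    stat = ifelse(status == "zero", NA_real_, stat),
    p_value = p,
    status = status
  )
}

#' BH adjustment and DEG calling
#'
#' Benjamini-Hochberg adjustment over the tested genes (untested genes
#' are excluded from the adjustment denominator) and calling at
#' `adjusted_p < alpha` with no fold-change cutoff; direction follows
#' the sign of the log fold change.
#'
#' @param results Tibble from [nb_wald_test()].
#' @param alpha FDR threshold (default 0.05).
#' @return `results` with `adjusted_p`, `direction` (`"up"`, `"down"`,
#'   `"ns"`) and logical `de` columns added.
#' @export
adjust_and_call <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), all(c("p_value", "log2_fold_change") %in% names(results)))
  stopifnot(alpha > 0, alpha < 1)
  padj <- rep(NA_real_, nrow(results))
  ok <- !is.na(results$p_value)
  padj[ok] <- p.adjust(results$p_value[ok], method = "BH")
  de <- !is.na(padj) & padj < alpha
  results$adjusted_p <- padj
  results$direction <- dplyr::case_when(
    de & results$log2_fold_change > 0 ~ "up",
    de & results$log2_fold_change < 0 ~ "down",
    TRUE ~ "ns"
  )
  results$de <- de
  results
}

#' Two-group NB differential expression, end to end
#'
#' Convenience wrapper: [size_factors()] then [estimate_dispersions()]
#' then [nb_wald_test()] then [adjust_and_call()]. All expressed genes
#' are tested (no pre-filtering beyond dropping all-zero genes from the
#' test).
#'
#' @inheritParams estimate_dispersions
#' @param alpha FDR threshold.
#' @param shrink_weight Dispersion shrinkage weight.
#' @return Object of class `nb_de`: list with `results` (tibble),
#'   `size_factors`, `alpha`, `levels`, `n_untested`.
#' @examples
#' sim <- simulate_counts(n_genes = 300, n_samples_per_condition = 5,
#'                        depth_per_sample = 5e4, n_de_genes = 30, seed = 4)
#' fit <- nb_de(sim$counts, sim$condition)
#' glance(fit)
#' @export
nb_de <- function(counts, condition, alpha = 0.05, shrink_weight = 0.5) {
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, sf, condition, shrink_weight = shrink_weight)
  res <- nb_wald_test(counts, sf, disp, condition)
  res <- adjust_and_call(res, alpha = alpha)
  structure(
    list(
      results = res,
      size_factors = sf,
      alpha = alpha,
      levels = sort(unique(condition)),
      n_untested = sum(res$status != "tested")
    ),
    class = "nb_de"
  )
}

#' Differentially expressed gene IDs from an `nb_de` fit
#'
#' @param object An [nb_de()] result.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return Character vector of gene IDs.
#' @export
de_genes <- function(object, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(object, "nb_de"))
  r <- object$results
  keep <- r$de & (direction == "both" | r$direction == direction)
  r$gene_id[keep]
}

#' @export
print.nb_de <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<nb_de> %d tested genes: %d DE at FDR %.3g (%d up, %d down); %d untested\n",
    g$n_tested, g$n_de, x$alpha, g$n_up, g$n_down, x$n_untested
  ))
  invisible(x)
}

#' @export
tidy.nb_de <- function(x, ...) x$results

#' @export
glance.nb_de <- function(x, ...) {
  r <- x$results
  tibble(
    n_tested = sum(r$status == "tested"),
    n_de = sum(r$de),
    n_up = sum(r$direction == "up"),
    n_down = sum(r$direction == "down"),
    n_untested = x$n_untested,
    alpha = x$alpha
  )
}

#' Volcano plot of an `nb_de` fit
#'
#' @param object An [nb_de()] result.
#' @param lfc_line Vertical reference lines at `+/- lfc_line` (log2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nb_de <- function(object, lfc_line = 1, ...) {
  r <- dplyr::filter(object$results, .data$status == "tested")
  ggplot2::ggplot(r, ggplot2::aes(.data$log2_fold_change, -log10(.data$adjusted_p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$direction), size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "#D7263D", down = "#1B6CA8", ns = "grey70")) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-lfc_line, lfc_line), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p")
}
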