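# Orchestration: the full saturation experiment and the two-kit
# comparison report.

#' Binomially thin per-sample AD/DP of variant records
#'
#' Approximates re-calling variants at a lower depth by thinning every
#' allele-depth entry (and the non-allele remainder of DP)
#' binomially at `ratio`. This is an explicit approximation of the
#' full re-call — it cannot lose or gain sites for reasons other than
#' read support.
#'
#' @param variants Variant tibble.
#' @param ratio Retention probability in `(0, 1]`.
#' @param seed Integer seed.
#' @return Variant tibble with thinned `ad` and `dp`.
#' @export
thin_variants <- function(variants, ratio, seed) {
  stopifnot(ratio > 0, ratio <= 1)
  withr::with_seed(seed, {
    out <- variants
    for (i in seq_len(nrow(variants))) {
      m <- variants$ad[[i]]
      d <- variants$dp[[i]]
      m2 <- m
      ok <- !is.na(m)
      m2[ok] <- rbinom(sum(ok), m[ok], ratio)
      other <- pmax(d - rowSums(m, na.rm = TRUE), 0)
      ok_d <- !is.na(d)
      d2 <- d
      d2[ok_d] <- rowSums(m2, na.rm = TRUE)[ok_d] +
        rbinom(sum(ok_d), other[ok_d], ratio)
      out$ad[[i]] <- m2
      out$dp[[i]] <- as.integer(d2)
    }
    out
  })
}

# Stringent-filter survivor keys for a variant set (used as the
# saturation metric and for confusion against the full-depth truth).
stringent_survivor_keys <- function(variants, ...) {
  surv <- filter_stringent(variants, ...)
  if (!nrow(surv)) {
    return(character(0))
  }
  paste(surv$chrom, surv$pos, surv$ref,
    vapply(seq_len(nrow(surv)), function(i) {
      paste(surv$alt[[i]][surv$kept_alts[[i]]], collapse = ",")
    }, character(1)),
    sep = ":"
  )
}

#' Run the sequencing-depth saturation experiment
#'
#' For every (depth, seed) cell of the replicate grid, the full-depth
#' count matrix is thinned without replacement, the expressed-gene
#' union, the informative-gene set and (when `condition` is given) the
#' DEG set are recomputed, and each is benchmarked against the
#' full-depth truth set with precision/recall/F. When `variants` is
#' given, per-sample AD/DP are binomially thinned at `depth /
#' full_depth` and the stringent filter survivors are benchmarked the
#' same way (SNPs and INDELs separately). Each metric's set sizes are
#' then fitted with [fit_asymptotic()] and the plateau depth computed
#' at `slope_threshold`.
#'
#' The default grid is the seven-depth, ten-seed design used for
#' benchmarking 3' mRNA-Seq libraries (0.5M-12M reads/sample; replicate
#' seeds 127, 2, 5, 7, 9, 11, 12, 81, 21, 47). Everything downstream is
#' a pure function of the inputs and `master_seed`.
#'
#' @param counts Full-depth gene-by-sample integer matrix.
#' @param condition Optional two-level label vector enabling the DEG
#'   metric.
#' @param variants Optional full-depth variant tibble enabling the
#'   SNP/INDEL metrics.
#' @param depths,seeds Replicate grid.
#' @param informative_min_count,informative_min_sample_fraction
#'   Informative-gene rule.
#' @param de_alpha FDR threshold for the DEG sets.
#' @param slope_threshold Plateau slope threshold (responses/read).
#' @param infeasible Depth-infeasibility policy, see
#'   [downsample_matrix()].
#' @param master_seed Seed combined with each grid seed.
#' @return Object of class `saturation_report`: list with `values`
#'   (tibble: metric, depth, seed, value, tp, fp, fn, precision,
#'   recall, f_score), `fits` (tibble: per-metric parameters, SSE and
#'   plateau coordinates), `truth` (named truth-set sizes) and
#'   `config`.
#' @export
run_saturation <- function(counts,
                           condition = NULL,
                           variants = NULL,
                           depths = c(0.5, 1, 2, 5, 7.5, 10, 12) * 1e6,
                           seeds = c(127L, 2L, 5L, 7L, 9L, 11L, 12L, 81L, 21L, 47L),
                           informative_min_count = 10,
                           informative_min_sample_fraction = 0.5,
                           de_alpha = 0.05,
                           slope_threshold = 1e-4,
                           infeasible = c("error", "cap"),
                           master_seed = 1L) {
  infeasible <- match.arg(infeasible)
  validate_counts(counts)
  if (anyDuplicated(seeds)) abort("`seeds` must be unique.")

  # full-depth truth sets
  truth <- list(
    expressed = expressed_genes_union(counts),
    informative = informative_genes(counts, informative_min_count, informative_min_sample_fraction)
  )
  if (!is.null(condition)) {
    truth$degs <- de_genes(nb_de(counts, condition, alpha = de_alpha))
  }
  full_depth <- max(colSums(counts))
  if (!is.null(variants)) {
    v <- variant_type(variants)
    truth$snps <- stringent_survivor_keys(v[v$type == "SNP", ])
    truth$indels <- stringent_survivor_keys(v[v$type == "INDEL", ])
  }

  grid <- tidyr::expand_grid(depth = as.numeric(depths), seed = as.integer(seeds))
  rows <- purrr::map2(grid$depth, grid$seed, function(d, s) {
    cell_seed <- derive_seed(master_seed, s, d)
    thin <- downsample_matrix(counts,
      depths = d, seeds = derive_seed(master_seed, s),
      infeasible = infeasible
    )$counts[[1]]
    sets <- list(
      expressed = expressed_genes_union(thin),
      informative = informative_genes(thin, informative_min_count, informative_min_sample_fraction)
    )
    if (!is.null(condition)) {
      sets$degs <- de_genes(nb_de(thin, condition, alpha = de_alpha))
    }
    if (!is.null(variants)) {
      tv <- thin_variants(v, ratio = min(d / full_depth, 1), seed = cell_seed)
      sets$snps <- stringent_survivor_keys(tv[tv$type == "SNP", ])
      sets$indels <- stringent_survivor_keys(tv[tv$type == "INDEL", ])
    }
    purrr::imap(sets, function(set, metric) {
      cm <- confusion(set, truth[[metric]])
      dplyr::bind_cols(
        tibble(metric = metric, depth = d, seed = s, value = length(set)),
        cm, precision_recall_f(cm)
      )
    }) |> dplyr::bind_rows()
  })
  values <- dplyr::bind_rows(rows)

  fits <- values |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_map(function(df, key) {
      fit <- tryCatch(
        fit_asymptotic(df, x = "depth", y = "value"),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(tibble(
          metric = key$metric, y0 = NA_real_, ymax = NA_real_, lrc = NA_real_,
          residual_sse = NA_real_, saturating = NA, x_plateau = NA_real_,
          y_at_plateau = NA_real_, extrapolated = NA
        ))
      }
      pl <- tryCatch(plateau(fit, slope_threshold), error = function(e) NULL)
      tibble(
        metric = key$metric, y0 = fit$y0, ymax = fit$ymax, lrc = fit$lrc,
        residual_sse = fit$residual_sse, saturating = fit$saturating,
        x_plateau = pl$x_plateau %||% NA_real_,
        y_at_plateau = pl$y_at_plateau %||% NA_real_,
        extrapolated = pl$extrapolated %||% NA
      )
    }) |>
    dplyr::bind_rows()

  structure(
    list(
      values = values,
      fits = fits,
      truth = vapply(truth, length, integer(1)),
      config = list(
        depths = as.numeric(depths), seeds = as.integer(seeds),
        informative_min_count = informative_min_count,
        informative_min_sample_fraction = informative_min_sample_fraction,
        de_alpha = de_alpha, slope_threshold = slope_threshold,
        master_seed = master_seed,
        n_genes = nrow(counts), n_samples = ncol(counts)
      )
    ),
    class = "saturation_report"
  )
}

#' @export
print.saturation_report <- function(x, ...) {
  cat(sprintf(
    "<saturation_report> %d metrics x %d depths x %d seeds\n",
    length(unique(x$values$metric)), length(x$config$depths), length(x$config$seeds)
  ))
  print(x$fits)
  invisible(x)
}

#' @export
tidy.saturation_report <- function(x, ...) x$values

#' @export
glance.saturation_report <- function(x, ...) x$fits

#' @export
autoplot.saturation_report <- function(object, ...) {
  pl <- dplyr::filter(object$fits, !is.na(.data$x_plateau))
  curves <- object$fits |>
    dplyr::filter(!is.na(.data$ymax)) |>
    dplyr::group_by(.data$metric) |>
    dplyr::reframe(
      depth = seq(0, max(object$config$depths), length.out = 200),
      value = model_predict(
        list(y0 = .data$y0[1], ymax = .data$ymax[1], lrc = .data$lrc[1]),
        seq(0, max(object$config$depths), length.out = 200)
      )
    )
  ggplot2::ggplot(object$values, ggplot2::aes(.data$depth, .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = curves, colour = "#C8A2C8") +
    ggplot2::geom_point(
      data = dplyr::rename(pl, depth = "x_plateau", value = "y_at_plateau"),
      colour = "#40E0D0", size = 3
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Reads per sample", y = "Set size")
}

#' Write a saturation report to disk
#'
#' `values.tsv` (per metric/depth/seed rows), `fits.tsv` (per-metric
#' fit + plateau), and `report.json` (config, truth sizes, fits) —
#' diff-able, language-neutral outputs.
#'
#' @param report A [run_saturation()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_saturation_report <- function(report, dir) {
  stopifnot(inherits(report, "saturation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$values, file.path(dir, "values.tsv"), progress = FALSE)
  readr::write_tsv(report$fits, file.path(dir, "fits.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(config = report$config, truth = as.list(report$truth), fits = report$fits),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Compare two library groups on per-sample detection metrics
#'
#' Welch two-sample t-tests on per-sample expressed-gene counts and
#' per-sample informative-threshold gene counts between two count
#' matrices (e.g. two library preparation kits run on the same
#' samples), with significance stars at the conventional thresholds
#' (`****` for p <= 1e-4).
#'
#' @param counts_a,counts_b Gene-by-sample matrices (>= 2 samples
#'   each).
#' @param informative_min_count Per-sample informative count threshold.
#' @return Tibble with one row per metric: group means, medians, `t`,
#'   `df`, `p_value`, `stars`.
#' @export
compare_groups <- function(counts_a, counts_b, informative_min_count = 10) {
  validate_counts(counts_a)
  validate_counts(counts_b)
  if (ncol(counts_a) < 2 || ncol(counts_b) < 2) {
    abort("Each group needs at least 2 samples.", class = "satseq_design_error")
  }
  per_sample <- function(m) {
    list(
      expressed = as.numeric(colSums(m >= 1)),
      informative_count = as.numeric(colSums(m >= informative_min_count))
    )
  }
  a <- per_sample(counts_a)
  b <- per_sample(counts_b)
  purrr::map2(a, b, function(x, y) {
    wt <- welch_t(x, y)
    tibble(
      mean_a = mean(x), mean_b = mean(y),
      median_a = median(x), median_b = median(y),
      t = wt$t, df = wt$df, p_value = wt$p_value,
      stars = signif_stars(wt$p_value)
    )
  }) |>
    dplyr::bind_rows(.id = "metric")
}
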