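#' Simulate saturation-curve observations
#'
#' Generates replicate (depth, response) observations from the
#' asymptotic regression model
#' `y = ymax + (y0 - ymax) * exp(-exp(lrc) * x)` plus i.i.d. Gaussian
#' noise — the data-generating process assumed by [fit_asymptotic()].
#' Defaults mirror a gene-detection saturation experiment: seven depths
#' between 0.5M and 12M reads per sample, ten replicates per depth, and
#' a curve rising from a few hundred genes at zero depth to an
#' asymptote of ~23,000 genes.
#'
#' @param y0 Response at zero depth.
#' @param ymax Asymptote; must exceed `y0`.
#' @param lrc Natural log of the rate constant.
#' @param depths Positive depths at which to observe.
#' @param replicates_per_depth Replicates per depth.
#' @param noise_sd Gaussian noise standard deviation (0 for exact
#'   points on the curve).
#' @param seed Integer seed.
#' @return Tibble with columns `depth`, `replicate`, `response`.
#' @export
simulate_saturation_observations <- function(y0 = 500,
                                             ymax = 23000,
                                             lrc = -15,
                                             depths = c(0.5, 1, 2, 5, 7.5, 10, 12) * 1e6,
                                             replicates_per_depth = 10,
                                             noise_sd = 200,
                                             seed = 1L) {
  if (!(ymax > y0)) abort("`ymax` must exceed `y0`.")
  if (any(depths <= 0)) abort("`depths` must be strictly positive.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (replicates_per_depth < 1) abort("`replicates_per_depth` must be >= 1.")

  params <- list(y0 = y0, ymax = ymax, lrc = lrc)
  withr::with_seed(seed, {
    out <- tidyr::expand_grid(depth = depths, replicate = seq_len(replicates_per_depth))
    mu <- model_predict(params, out$depth)
    out$response <- mu + if (noise_sd > 0) rnorm(nrow(out), 0, noise_sd) else 0
    out
  })
}
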