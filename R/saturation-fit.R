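#' Asymptotic regression for sequencing-depth saturation
#'
#' Fits the three-parameter asymptotic regression model
#' \deqn{y = y_{max} + (y_0 - y_{max}) e^{-e^{lrc} x}}
#' to (depth, response) observations, where `ymax` is the asymptote,
#' `y0` the response at zero depth, and `lrc` the natural log of the
#' exponential rate constant. This is the classical self-starting
#' asymptotic regression form; fitting uses Levenberg–Marquardt
#' nonlinear least squares seeded by a self-start heuristic
#' (`ymax0 = 1.05 max(y)`, `y00 = min(y)`, `lrc0` from an OLS fit of
#' `log(ymax0 - y)` on `x`), with `stats::SSasymp` as a fallback
#' initializer.
#'
#' All replicate points are fitted jointly (pooled, not averaged).
#'
#' @param data Data frame with the observations.
#' @param x,y Column names (strings) holding depth and response;
#'   defaults `"depth"` and `"response"`.
#'
#' @return An object of class `asymp_fit`: a list with elements `y0`,
#'   `ymax`, `lrc`, `residual_sse`, `n_obs`, `saturating` (logical,
#'   `ymax > y0`), `max_x` and the pooled `data`.
#' @seealso [plateau()], [model_predict()], [model_derivative()]
#' @examples
#' obs <- simulate_saturation_observations(noise_sd = 0, seed = 1)
#' fit <- fit_asymptotic(obs)
#' glance(fit)
#' @export
fit_asymptotic <- function(data, x = "depth", y = "response") {
  stopifnot(is.data.frame(data), x %in% names(data), y %in% names(data))
  xs <- as.numeric(data[[x]])
  ys <- as.numeric(data[[y]])
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]
  ys <- ys[keep]
  if (length(unique(xs)) < 3) {
    abort("Need at least 3 distinct depths to fit the saturation model.", class = "satseq_data_error")
  }
  if (length(unique(ys)) < 2) {
    abort("Responses are all equal; saturation model is unidentifiable.", class = "satseq_data_error")
  }

  df <- data.frame(x = xs, y = ys)
  start <- asymp_selfstart(xs, ys)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ ymax + (y0 - ymax) * exp(-exp(lrc) * x),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12, ptol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(
      nls(y ~ SSasymp(x, ymax, y0, lrc), data = df),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    abort(
      sprintf(
        "Asymptotic fit failed to converge (start: y0=%.4g, ymax=%.4g, lrc=%.4g).",
        start$y0, start$ymax, start$lrc
      ),
      class = "satseq_fit_error"
    )
  }

  cf <- coef(fit)
  res <- ys - (cf[["ymax"]] + (cf[["y0"]] - cf[["ymax"]]) * exp(-exp(cf[["lrc"]]) * xs))
  out <- structure(
    list(
      y0 = unname(cf[["y0"]]),
      ymax = unname(cf[["ymax"]]),
      lrc = unname(cf[["lrc"]]),
      residual_sse = sum(res^2),
      n_obs = length(xs),
      saturating = cf[["ymax"]] > cf[["y0"]],
      max_x = max(xs),
      data = tibble(depth = xs, response = ys)
    ),
    class = "asymp_fit"
  )
  if (!out$saturating) {
    warn("Fitted curve is non-saturating (ymax <= y0); plateau estimation will refuse it.")
  }
  out
}

# Self-start heuristic for asymptotic regression.
asymp_selfstart <- function(x, y) {
  ymax0 <- max(y) * 1.05
  if (ymax0 == 0) ymax0 <- max(y) + 1
  y00 <- min(y)
  resid <- pmax(ymax0 - y, ymax0 * 1e-9 + 1e-9)
  sl <- coef(lm(log(resid) ~ x))[[2]]
  lrc0 <- log(max(-sl, 1e-12))
  list(y0 = y00, ymax = ymax0, lrc = lrc0)
}

as_asymp_params <- function(fit) {
  if (inherits(fit, "asymp_fit") ||
    (is.list(fit) && all(c("y0", "ymax", "lrc") %in% names(fit)))) {
    list(y0 = fit$y0, ymax = fit$ymax, lrc = fit$lrc)
  } else {
    abort("Expected an `asymp_fit` or a list with y0, ymax, lrc.")
  }
}

#' Evaluate the fitted saturation curve
#'
#' @param fit An [fit_asymptotic()] result, or any list with `y0`,
#'   `ymax`, `lrc`.
#' @param x Depths (non-negative numeric vector).
#' @return Predicted responses.
#' @export
model_predict <- function(fit, x) {
  p <- as_asymp_params(fit)
  stopifnot(all(x >= 0))
  p$ymax + (p$y0 - p$ymax) * exp(-exp(p$lrc) * x)
}

#' Slope of the fitted saturation curve
#'
#' Closed-form derivative `(ymax - y0) * exp(lrc) * exp(-exp(lrc) * x)`;
#' strictly positive and decreasing in `x` for a saturating fit.
#'
#' @inheritParams model_predict
#' @return Slopes (response units per read).
#' @export
model_derivative <- function(fit, x) {
  p <- as_asymp_params(fit)
  stopifnot(all(x >= 0))
  (p$ymax - p$y0) * exp(p$lrc) * exp(-exp(p$lrc) * x)
}

#' Saturation depth: where the curve flattens to a slope threshold
#'
#' Solves analytically for the depth at which the fitted curve's slope
#' equals `slope_threshold`:
#' \deqn{x_{plateau} = -\frac{\ln(-t / (y_0 - y_{max})) - lrc}{e^{lrc}}}
#' The default threshold, 1e-4 responses per read, reads as "one more
#' gene per 10,000 extra reads per sample" — the marginal-gain cutoff
#' used to declare a library saturated.
#'
#' @param fit A saturating [fit_asymptotic()] result.
#' @param slope_threshold Positive slope (responses per read) defining
#'   the plateau.
#' @return A one-row tibble of class `plateau_result`: `x_plateau`,
#'   `y_at_plateau`, `slope_threshold`, `extrapolated` (`TRUE` when the
#'   plateau lies beyond the largest observed depth).
#' @export
plateau <- function(fit, slope_threshold = 1e-4) {
  p <- as_asymp_params(fit)
  stopifnot(slope_threshold > 0)
  if (!(p$ymax > p$y0)) {
    abort("Fit is non-saturating (ymax <= y0); no plateau exists.", class = "satseq_fit_error")
  }
  slope0 <- model_derivative(p, 0)
  if (slope_threshold > slope0) {
    abort(
      sprintf(
        "Slope threshold %.3g exceeds the curve's initial slope %.3g; the curve is flatter than the threshold everywhere.",
        slope_threshold, slope0
      ),
      class = "satseq_fit_error"
    )
  }
  x_p <- -(log(-slope_threshold / (p$y0 - p$ymax)) - p$lrc) / exp(p$lrc)
  extrap <- if (!is.null(fit$max_x)) x_p > fit$max_x else NA
  out <- tibble(
    x_plateau = x_p,
    y_at_plateau = model_predict(p, x_p),
    slope_threshold = slope_threshold,
    extrapolated = extrap
  )
  class(out) <- c("plateau_result", class(out))
  out
}

#' Predicted gain in response between two depths
#'
#' @param fit An [fit_asymptotic()] result.
#' @param x_from,x_to Depths with `0 <= x_from <= x_to` (`x_to` may be
#'   `Inf` for the total remaining gain).
#' @return `model_predict(x_to) - model_predict(x_from)`.
#' @export
marginal_gain <- function(fit, x_from, x_to) {
  stopifnot(all(x_from >= 0), all(x_to >= x_from))
  p <- as_asymp_params(fit)
  to <- ifelse(is.infinite(x_to), p$ymax, model_predict(p, x_to))
  to - model_predict(p, x_from)
}

#' @export
print.asymp_fit <- function(x, ...) {
  cat(sprintf(
    "<asymp_fit> y0 = %.4g, ymax = %.4g, lrc = %.4g (SSE %.4g, n = %d)%s\n",
    x$y0, x$ymax, x$lrc, x$residual_sse, x$n_obs,
    if (x$saturating) "" else " [non-saturating]"
  ))
  invisible(x)
}

#' @export
tidy.asymp_fit <- function(x, ...) {
  tibble(
    term = c("y0", "ymax", "lrc"),
    estimate = c(x$y0, x$ymax, x$lrc)
  )
}

#' @export
glance.asymp_fit <- function(x, ...) {
  tibble(
    y0 = x$y0, ymax = x$ymax, lrc = x$lrc,
    residual_sse = x$residual_sse, n_obs = x$n_obs,
    saturating = x$saturating
  )
}

#' @export
autoplot.asymp_fit <- function(object, slope_threshold = 1e-4, ...) {
  grid <- tibble(
    depth = seq(0, max(object$data$depth), length.out = 200),
    response = model_predict(object, seq(0, max(object$data$depth), length.out = 200))
  )
  p <- ggplot2::ggplot(object$data, ggplot2::aes(.data$depth, .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#C8A2C8", linewidth = 1) +
    ggplot2::labs(x = "Reads per sample", y = "Response")
  if (object$saturating && slope_threshold <= model_derivative(object, 0)) {
    pl <- plateau(object, slope_threshold)
    p <- p + ggplot2::geom_point(
      data = tibble(depth = pl$x_plateau, response = pl$y_at_plateau),
      colour = "#40E0D0", size = 3
    )
  }
  p
}
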