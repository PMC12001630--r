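test_that("model prediction and derivative closed forms", {
  p <- list(y0 = 0, ymax = 100, lrc = log(log(2)))
  expect_equal(model_predict(p, 0), 0)
  expect_equal(model_predict(p, 1), 50) # half-life identity
  expect_equal(model_predict(p, 1e9), 100, tolerance = 1e-9)
  expect_equal(model_derivative(p, 0), 100 * log(2))
  flat <- list(y0 = 5, ymax = 5, lrc = -1)
  expect_equal(model_derivative(flat, c(0, 10, 100)), rep(0, 3))
})

test_that("derivative matches a central finite difference", {
  withr::with_seed(3, {
    for (i in 1:20) {
      p <- list(y0 = runif(1, 0, 100), ymax = runif(1, 200, 1e4), lrc = runif(1, -16, -1))
      x <- runif(1, 0, 2 / exp(p$lrc))
      h <- max(x, 1) * 1e-6
      fd <- (model_predict(p, x + h) - model_predict(p, x - h)) / (2 * h)
      expect_equal(model_derivative(p, x), fd, tolerance = 1e-5)
    }
  })
})

test_that("noise-free fits recover the generating parameters", {
  obs <- simulate_saturation_observations(
    y0 = 500, ymax = 23000, lrc = -15,
    replicates_per_depth = 1, noise_sd = 0, seed = 1
  )
  fit <- fit_asymptotic(obs)
  expect_equal(fit$y0, 500, tolerance = 1e-4)
  expect_equal(fit$ymax, 23000, tolerance = 1e-4)
  expect_equal(fit$lrc, -15, tolerance = 1e-4)
  expect_lt(fit$residual_sse, 1e-6)
  expect_true(fit$saturating)
})

test_that("degenerate and decreasing data are refused or flagged", {
  expect_error(
    fit_asymptotic(tibble::tibble(depth = c(1, 2), response = c(1, 2))),
    class = "satseq_data_error"
  )
  expect_error(
    fit_asymptotic(tibble::tibble(depth = 1:5, response = rep(3, 5))),
    class = "satseq_data_error"
  )
  dec <- tibble::tibble(
    depth = c(1e5, 1e6, 5e6, 1e7),
    response = c(1000, 800, 400, 200)
  )
  fit <- tryCatch(
    suppressWarnings(fit_asymptotic(dec)),
    error = function(e) e
  )
  if (inherits(fit, "asymp_fit")) {
    expect_false(fit$saturating)
    expect_error(plateau(fit), class = "satseq_fit_error")
  } else {
    expect_s3_class(fit, "satseq_fit_error")
  }
})

test_that("plateau is self-consistent with the derivative and monotone in the threshold", {
  obs <- simulate_saturation_observations(noise_sd = 0, seed = 2)
  fit <- fit_asymptotic(obs)
  pl <- plateau(fit, 1e-4)
  expect_equal(model_derivative(fit, pl$x_plateau) / 1e-4, 1, tolerance = 1e-9)
  expect_equal(pl$y_at_plateau, model_predict(fit, pl$x_plateau))
  # threshold equal to the initial slope puts the plateau at the origin
  s0 <- model_derivative(fit, 0)
  expect_equal(plateau(fit, s0)$x_plateau, 0, tolerance = 1e-9)
  # doubling the threshold strictly decreases the plateau depth
  expect_lt(plateau(fit, 2e-4)$x_plateau, pl$x_plateau)
  expect_error(plateau(fit, s0 * 2), class = "satseq_fit_error")
})

test_that("marginal gain is additive and bounded by the total range", {
  fit <- fit_asymptotic(simulate_saturation_observations(noise_sd = 0, seed = 4))
  expect_equal(marginal_gain(fit, 2e6, 2e6), 0)
  expect_equal(marginal_gain(fit, 0, Inf), fit$ymax - fit$y0)
  a <- 1e6
  b <- 4e6
  cc <- 9e6
  expect_equal(
    marginal_gain(fit, a, b) + marginal_gain(fit, b, cc),
    marginal_gain(fit, a, cc),
    tolerance = 1e-12
  )
})

test_that("x-rescaling shifts lrc and the plateau equivariantly", {
  obs <- simulate_saturation_observations(noise_sd = 0, seed = 6)
  fit1 <- fit_asymptotic(obs)
  c_scale <- 1e-6 # reads -> millions of reads
  obs2 <- dplyr::mutate(obs, depth = depth * c_scale)
  fit2 <- fit_asymptotic(obs2)
  expect_equal(fit2$lrc, fit1$lrc - log(c_scale), tolerance = 1e-4)
  p1 <- plateau(fit1, 1e-4)
  p2 <- plateau(fit2, 1e-4 / c_scale)
  expect_equal(p2$x_plateau, p1$x_plateau * c_scale, tolerance = 1e-4)
})

test_that("noisy fits are close to unbiased at the replicate design scale", {
  true <- list(y0 = 500, ymax = 23000, lrc = -15)
  errs <- vapply(1:30, function(s) {
    obs <- simulate_saturation_observations(
      y0 = true$y0, ymax = true$ymax, lrc = true$lrc,
      noise_sd = 200, seed = 1000 + s
    )
    abs(fit_asymptotic(obs)$ymax - true$ymax) / true$ymax
  }, numeric(1))
  expect_lte(median(errs), 0.02)
})

test_that("tidy/glance/autoplot methods work on fits", {
  fit <- fit_asymptotic(simulate_saturation_observations(seed = 8))
  td <- tidy(fit)
  expect_equal(td$term, c("y0", "ymax", "lrc"))
  g <- glance(fit)
  expect_true(g$saturating)
  expect_s3_class(autoplot(fit), "ggplot")
})
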