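test_that("size factors match closed-form median-of-ratios cases", {
  m <- toy_counts(cbind(c(4, 8, 12), c(4, 8, 12)))
  expect_equal(unname(size_factors(m)), c(1, 1))

  a <- c(5L, 10L, 20L, 40L)
  m2 <- toy_counts(cbind(a, 2L * a))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  single <- toy_counts(matrix(c(4L, 16L), nrow = 1))
  expect_equal(unname(size_factors(single)), c(0.5, 2))
})

test_that("size-factor fallback handles sparse matrices", {
  # no gene nonzero in every sample
  m <- toy_counts(rbind(c(10, 0), c(0, 10), c(5, 0)))
  expect_error(size_factors(m, fallback = FALSE), class = "satseq_normalization_error")
  sf <- size_factors(m)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  expect_true(all(sf > 0))
})

test_that("dispersion estimation recovers the generating dispersion", {
  cond <- rep(c("A", "B"), each = 20)
  withr::with_seed(21, {
    mu <- exp(runif(400, log(50), log(1000)))
    pois <- matrix(rpois(400 * 40, rep(mu, 40)), nrow = 400)
    dimnames(pois) <- list(sprintf("g%d", 1:400), sprintf("s%d", 1:40))
    sf <- size_factors(pois)
    d_pois <- estimate_dispersions(pois, sf, cond, shrink_weight = 0)
    expect_lte(median(d_pois), 0.01)

    nb <- matrix(rnbinom(400 * 40, mu = rep(mu, 40), size = 10), nrow = 400)
    dimnames(nb) <- dimnames(pois)
    d_nb <- estimate_dispersions(nb, size_factors(nb), cond, shrink_weight = 0)
    expect_gte(median(d_nb), 0.05)
    expect_lte(median(d_nb), 0.2)
  })
  # constant gene: zero sample variance floors the estimate
  flat <- toy_counts(matrix(7L, 1, 8))
  d <- estimate_dispersions(flat, setNames(rep(1, 8), colnames(flat)),
    rep(c("A", "B"), each = 4),
    shrink_weight = 0
  )
  expect_equal(unname(d), 1e-8)
  expect_error(
    estimate_dispersions(flat, setNames(rep(1, 8), colnames(flat)), c("A", rep("B", 7))),
    class = "satseq_design_error"
  )
})

test_that("the Wald stage recovers known fold changes and flags zero genes", {
  withr::with_seed(33, {
    n1 <- 14
    n2 <- 15
    G <- 300
    mu <- rep(500, G)
    # a minority of DE genes so median-of-ratios normalization holds
    lfc2 <- rep(0, G)
    lfc2[seq(10, G, by = 10)] <- 2
    y <- cbind(
      matrix(rnbinom(G * n1, mu = mu, size = 10), nrow = G),
      matrix(rnbinom(G * n2, mu = mu * 2^lfc2, size = 10), nrow = G)
    )
    y[1, ] <- 0L # an all-zero gene
    dimnames(y) <- list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:(n1 + n2)))
    cond <- rep(c("A", "B"), c(n1, n2))
    fit <- nb_de(y, cond)
    res <- tidy(fit)
    expect_equal(res$status[1], "zero")
    expect_true(is.na(res$p_value[1]))
    est <- res$log2_fold_change[res$status == "tested" & lfc2 == 2]
    expect_lt(abs(median(est) - 2), 0.5)
    null_est <- res$log2_fold_change[res$status == "tested" & lfc2 == 0 & seq_len(G) > 1]
    expect_lt(abs(median(null_est)), 0.3)
  })
})

test_that("label swap negates LFC exactly and leaves p-values unchanged", {
  sim <- simulate_counts(400, 5, depth_per_sample = 5e4, n_de_genes = 40, seed = 17)
  cond <- sim$condition
  swapped <- ifelse(cond == "A", "B", "A")
  f1 <- nb_de(sim$counts, cond)
  f2 <- nb_de(sim$counts, swapped)
  r1 <- tidy(f1)
  r2 <- tidy(f2)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$log2_fold_change, -r2$log2_fold_change)
})

test_that("normalization consistency: scaling a sample is absorbed by its size factor", {
  sim <- simulate_counts(300, 4, depth_per_sample = 2e4, n_de_genes = 30, seed = 23)
  m <- sim$counts
  sf <- size_factors(m)
  disp <- estimate_dispersions(m, sf, sim$condition)
  r1 <- nb_wald_test(m, sf, disp, sim$condition)
  m2 <- m
  m2[, 3] <- m2[, 3] * 4L
  sf2 <- sf
  sf2[3] <- sf2[3] * 4
  r2 <- nb_wald_test(m2, sf2, disp, sim$condition)
  # the NB likelihood is not exactly scale-invariant (only its Poisson
  # part is), so the statistics agree approximately, tightly so for
  # well-expressed genes
  ok <- r1$status == "tested" & r1$base_mean > 20 & abs(r1$log2_fold_change) < 10
  expect_equal(r1$log2_fold_change[ok], r2$log2_fold_change[ok], tolerance = 0.02)
  expect_gt(cor(r1$p_value[ok], r2$p_value[ok]), 0.99)
})

test_that("BH adjustment and calling match hand computation", {
  res <- tibble::tibble(
    gene_id = sprintf("g%d", 1:4),
    log2_fold_change = c(1, -1, 2, -2),
    p_value = c(0.01, 0.02, 0.03, 0.04),
    status = "tested"
  )
  out <- adjust_and_call(res, alpha = 0.05)
  expect_equal(out$adjusted_p, rep(0.04, 4))
  expect_true(all(out$de))
  expect_equal(out$direction, c("up", "down", "up", "down"))

  none <- adjust_and_call(dplyr::mutate(res, p_value = 1), alpha = 0.05)
  expect_false(any(none$de))

  one <- adjust_and_call(res[1, ], alpha = 0.05)
  expect_equal(one$adjusted_p, 0.01)
  expect_true(one$de)

  # untested genes are excluded from the BH denominator
  with_na <- dplyr::bind_rows(res, tibble::tibble(
    gene_id = "g5", log2_fold_change = NA_real_, p_value = NA_real_, status = "zero"
  ))
  out_na <- adjust_and_call(with_na, alpha = 0.05)
  expect_equal(out_na$adjusted_p[1:4], rep(0.04, 4))
  expect_true(is.na(out_na$adjusted_p[5]))
})

test_that("de_genes extracts the called set with direction filters", {
  sim <- simulate_counts(500, c(6, 6),
    depth_per_sample = 1e5, n_de_genes = 60,
    lfc_magnitude = 2, seed = 31
  )
  fit <- nb_de(sim$counts, sim$condition)
  degs <- de_genes(fit)
  expect_setequal(degs, union(de_genes(fit, "up"), de_genes(fit, "down")))
  # strong effects at decent depth: most calls are true
  if (length(degs) > 10) {
    expect_gt(mean(degs %in% sim$de_genes), 0.8)
  }
  g <- glance(fit)
  expect_equal(g$n_de, length(degs))
})
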