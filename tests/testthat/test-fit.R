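test_that("pinball loss matches hand-computed values", {
  expect_equal(pinball_loss(1.0, 10, C = 10, alpha = 2, tau = 0.3), 0)
  expect_equal(pinball_loss(c(1, 1), c(12, 8), C = 10, alpha = 2, tau = 0.9),
               0.9 * 2 + 0.1 * 2)
  expect_equal(pinball_loss(c(1, 1), c(12, 8), C = 10, alpha = 2, tau = 0.5),
               0.5 * 4)  # half the absolute residual sum
  expect_error(pinball_loss(1, 10, C = -1, alpha = 2, tau = 0.5), "positive")
})

test_that("pinball loss is invariant under record reordering", {
  co <- noisy_cohort(n = 25)
  h <- co$height_cm / 100
  w <- co$weight_kg
  p <- sample(25)
  expect_equal(pinball_loss(h, w, 14, 2.2, 0.9),
               pinball_loss(h[p], w[p], 14, 2.2, 0.9), tolerance = 1e-12)
})

test_that("noise-free power-law cohorts are recovered exactly at any centile", {
  co <- exact_cohort(15, 2.73)
  for (q in c(2, 50, 98)) {
    f <- fit_powerlaw_quantile(co, q)
    expect_lt(abs(f$alpha - 2.73), 1e-3)
    expect_lt(abs(f$C - 15) / 15, 1e-3)
    expect_lt(f$loss, 1e-6)
    expect_equal(f$tau, q / 100)
  }
})

test_that("the simplex fit attains the brute-force grid minimum", {
  co <- noisy_cohort(n = 20, seed = 1)
  f <- fit_powerlaw_quantile(co, 50)
  oracle <- grid_pinball_min(co$height_cm / 100, co$weight_kg, 0.5,
                             alphas = seq(1, 4, length.out = 400),
                             logCs = seq(log(5), log(30), length.out = 400))
  expect_lte(f$loss, oracle + 1e-6)
})

test_that("fitted parameters are scale-equivariant", {
  co <- noisy_cohort(n = 80, seed = 6)
  f <- fit_powerlaw_quantile(co, 50)
  kw <- cohort(co$height_cm, co$weight_kg * 2, 8, "F")
  fw <- fit_powerlaw_quantile(kw, 50)
  expect_equal(fw$alpha, f$alpha, tolerance = 1e-4)
  expect_equal(fw$C, 2 * f$C, tolerance = 1e-4)
  kh <- cohort(co$height_cm * 1.5, co$weight_kg, 8, "F")
  fh <- fit_powerlaw_quantile(kh, 50)
  expect_equal(fh$alpha, f$alpha, tolerance = 1e-4)
  expect_equal(fh$C, f$C * 1.5^(-f$alpha), tolerance = 1e-3)
})

test_that("quantile coverage at the optimum brackets tau", {
  m <- uni_model_3anchor(round = FALSE)
  co <- sample_cohort(m, 300, seed = 12)
  n <- nrow(co)
  for (q in c(10, 50, 90)) {
    f <- fit_powerlaw_quantile(co, q)
    below <- mean(co$weight_kg < predict(f, co$height_cm / 100))
    expect_gte(below, q / 100 - 2 / n)
    expect_lte(below, q / 100 + 2 / n)
  }
})

test_that("power-law fit equals the exponentiated log-log linear fit on clean data", {
  co <- exact_cohort(12, 1.85)
  lf <- fit_linear_quantile(log(co$height_cm / 100), log(co$weight_kg), 0.5)
  pf <- fit_powerlaw_quantile(co, 50)
  expect_equal(pf$alpha, lf$slope, tolerance = 1e-3)
  expect_equal(log(pf$C), lf$intercept, tolerance = 1e-3)
  # and agrees within 0.02 on a large continuous sample
  m <- uni_model_3anchor(round = FALSE)
  big <- sample_cohort(m, 20000, seed = 15)
  lf2 <- fit_linear_quantile(log(big$height_cm / 100), log(big$weight_kg), 0.5)
  pf2 <- fit_powerlaw_quantile(big, 50)
  expect_lt(abs(pf2$alpha - lf2$slope), 0.02)
})

test_that("degenerate fitting inputs raise errors", {
  expect_error(fit_powerlaw_quantile(cohort(c(130, 130, 130), c(20, 22, 24), 8, "F"), 50),
               "unidentifiable")
  expect_error(fit_powerlaw_quantile(cohort(c(130, 131), c(20, 22), 8, "F"), 50),
               "at least 3")
  expect_error(fit_linear_quantile(c(1, 1, 1), c(2, 3, 4), 0.5), "unidentifiable")
})

test_that("linear quantile regression solves exact and constant cases", {
  xs <- 1:10
  for (tau in c(0.1, 0.5, 0.9)) {
    f <- fit_linear_quantile(xs, 3 + 2 * xs, tau)
    expect_equal(f$intercept, 3, tolerance = 1e-5)
    expect_equal(f$slope, 2, tolerance = 1e-5)
    g <- fit_linear_quantile(xs, rep(4.5, 10), tau)
    expect_equal(g$slope, 0, tolerance = 1e-6)
    expect_equal(g$intercept, 4.5, tolerance = 1e-6)
  }
})

test_that("linear quantile fit matches a dense grid-search oracle", {
  set.seed(30)
  xs <- runif(30, 1, 2)
  ys <- 5 + 3 * xs + rnorm(30, 0, 0.5)
  f <- fit_linear_quantile(xs, ys, 0.9)
  grid_a <- seq(2, 9, length.out = 500)
  grid_b <- seq(0, 6, length.out = 500)
  best <- Inf
  for (b in grid_b) {
    r <- matrix(ys - b * xs, nrow = 500, ncol = 30, byrow = TRUE) - grid_a
    loss <- rowSums(ifelse(r >= 0, 0.9 * r, -0.1 * r))
    best <- min(best, min(loss))
  }
  expect_lte(f$loss, best + 1e-6)
})

test_that("fit_profile summarises bootstrap medians per centile deterministically", {
  m <- uni_model_3anchor(round = TRUE)
  co <- sample_cohort(m, 1500, seed = 20)
  bs <- bootstrap_config(B = 5, seed = 21)
  p1 <- fit_profile(co, centiles = c(10, 50, 90), bootstrap = bs)
  p2 <- fit_profile(co, centiles = c(10, 50, 90), bootstrap = bs)
  expect_equal(p1$entries, p2$entries)
  expect_equal(p1$entries$q, c(10, 50, 90))
  expect_true(all(p1$entries$alpha_lo <= p1$entries$alpha))
  expect_true(all(p1$entries$alpha <= p1$entries$alpha_hi))
  expect_equal(p1$B, 5)
})

test_that("a single-centile profile is trivially uni-scaling", {
  co <- exact_cohort(15, 2, n = 50)
  p <- fit_profile(co, centiles = 50, bootstrap = NULL)
  expect_equal(nrow(p$entries), 1)
  expect_equal(p$scaling_class, "uni")
})
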