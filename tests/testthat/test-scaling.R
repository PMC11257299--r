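# build a profile object through the public fitting path on exact data
exact_profile <- function(alphas, qs = c(2, 50, 98), intervals = NULL) {
  stopifnot(length(alphas) == length(qs))
  # one exact fit per centile, then assemble entries as fit_profile would
  entries <- do.call(rbind, lapply(seq_along(qs), function(i) {
    co <- exact_cohort(15, alphas[i], n = 40)
    f <- fit_powerlaw_quantile(co, qs[i])
    data.frame(q = qs[i], alpha = f$alpha,
               alpha_lo = if (is.null(intervals)) NA_real_ else intervals[[i]][1],
               alpha_hi = if (is.null(intervals)) NA_real_ else intervals[[i]][2],
               C = f$C, C_lo = NA_real_, C_hi = NA_real_)
  }))
  co <- exact_cohort(15, 2, n = 40)
  p <- fit_profile(co, centiles = 50, bootstrap = NULL)  # skeleton
  p$entries <- entries
  p
}

test_that("scaling classification follows the spread-and-interval rule", {
  uni <- classify_scaling(exact_profile(c(2, 2, 2)), epsilon = 0.1)
  expect_equal(uni$scaling_class, "uni")
  expect_lt(uni$spread, 0.01)

  multi <- classify_scaling(
    exact_profile(c(2.4, 2.73, 4.0),
                  intervals = list(c(2.38, 2.42), c(2.70, 2.76), c(3.95, 4.05))),
    epsilon = 0.1)
  expect_equal(multi$scaling_class, "multi")
  expect_gt(multi$spread, 1.0)

  # spread above epsilon but overlapping intervals: refuse to over-claim
  und <- classify_scaling(
    exact_profile(c(2.0, 2.1, 2.25),
                  intervals = list(c(1.8, 2.3), c(1.9, 2.4), c(2.0, 2.5))),
    epsilon = 0.1)
  expect_equal(und$scaling_class, "undetermined")
})

test_that("a spread exactly at epsilon is classified uni", {
  p <- exact_profile(c(2, 2, 2),
                     intervals = list(c(1.9, 2.3), c(2.0, 2.4), c(2.05, 2.45)))
  p$entries$alpha <- c(2.0, 2.125, 2.25)  # spread 0.25, exact in binary
  expect_equal(classify_scaling(p, epsilon = 0.25)$scaling_class, "uni")
  # just under the boundary: spread exceeds epsilon but intervals all overlap
  expect_equal(classify_scaling(p, epsilon = 0.2499)$scaling_class,
               "undetermined")
})

test_that("classification ignores centile order and duplicated entries", {
  p <- exact_profile(c(2.4, 2.73, 4.0),
                     intervals = list(c(2.38, 2.42), c(2.70, 2.76), c(3.95, 4.05)))
  shuffled <- p
  shuffled$entries <- p$entries[c(3, 1, 2), ]
  dup <- p
  dup$entries <- p$entries[c(1, 2, 3, 2), ]
  base <- classify_scaling(p, 0.1)
  expect_equal(classify_scaling(shuffled, 0.1)$scaling_class, base$scaling_class)
  expect_equal(classify_scaling(shuffled, 0.1)$spread, base$spread)
  expect_equal(classify_scaling(dup, 0.1)$scaling_class, base$scaling_class)
})

test_that("single-centile profiles cannot be classified", {
  p <- exact_profile(2, qs = 50)
  expect_error(classify_scaling(p), "at least two")
})

test_that("crossing heights match the closed form and the defining identity", {
  # parallel curves never cross
  expect_null(crossing_height(list(alpha = 2, C = 12), list(alpha = 2, C = 15)))
  expect_error(crossing_height(list(alpha = 2, C = 12), list(alpha = 2, C = 12)),
               "degenerate")
  # published 8-year male 2nd/98th centile parameters: short-height crossing
  a <- list(alpha = 2.39, C = 12.19)
  b <- list(alpha = 4.05, C = 13.41)
  cr <- crossing_height(a, b, range = c(1.10, 1.45))
  expect_equal(cr$h, (12.19 / 13.41)^(1 / (4.05 - 2.39)), tolerance = 1e-12)
  expect_lt(cr$h, 1.0)
  expect_false(cr$inside_range)
  # symmetry and the defining identity C_a h*^a_a = C_b h*^a_b
  expect_equal(crossing_height(b, a)$h, cr$h, tolerance = 1e-12)
  expect_lt(abs(a$C * cr$h^a$alpha / (b$C * cr$h^b$alpha) - 1), 1e-10)
})

test_that("the age table stacks cells long-format with classifications", {
  profiles <- list()
  for (sex in c("M", "F")) {
    for (age in 5:17) {
      co <- cohort(seq(100 + 4 * (age - 5), 130 + 4 * (age - 5), length.out = 40),
                   15 * seq(1.0 + 0.04 * (age - 5), 1.3 + 0.04 * (age - 5),
                            length.out = 40)^2,
                   age, sex)
      profiles[[length(profiles) + 1]] <-
        fit_profile(co, centiles = c(2, 10, 50, 90, 98), bootstrap = NULL)
    }
  }
  tab <- exponent_age_table(profiles)
  expect_equal(nrow(tab$params), 13 * 2 * 5)
  expect_equal(nrow(tab$classes), 26)
  expect_true(all(tab$classes$scaling_class == "uni"))
  # single profile also works
  one <- exponent_age_table(profiles[1])
  expect_equal(nrow(one$params), 5)
  # inconsistent grids rejected
  bad <- fit_profile(exact_cohort(15, 2), centiles = c(2, 50), bootstrap = NULL)
  expect_error(exponent_age_table(c(profiles[1], list(bad))), "schema")
})

test_that("age-varying exponents are recovered across cells", {
  alphas <- c(2.2, 3.0, 2.4)  # rise then fall with age
  profiles <- lapply(seq_along(alphas), function(i) {
    m <- reference_model(alphas = c(alphas[i], alphas[i], alphas[i]),
                         round_to_integers = FALSE)
    co <- sample_cohort(m, 20000, seed = 100 + i, age = 7 + i, sex = "F")
    fit_profile(co, centiles = c(2, 50, 98), bootstrap = NULL)
  })
  tab <- exponent_age_table(profiles)$params
  got <- tab$alpha[tab$q == 50]
  expect_true(all(abs(got - alphas) < 0.05))
})
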