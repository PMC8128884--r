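test_that("population doublings follow log2 of the fold expansion", {
  expect_equal(population_doublings(culture_count(1e5, 2e5, 2)), 1)
  expect_equal(population_doublings(culture_count(1e5, 1e5, 2)), 0)
  expect_equal(population_doublings(culture_count(1.25e5, 5e5, 4)), 2)
  expect_lt(population_doublings(culture_count(1e5, 5e4, 2)), 0)
  expect_error(culture_count(0, 1e5, 2), "n0")
})

test_that("population doublings are additive over culture intervals", {
  for (k in c(1.5, 2, 3.7)) {
    n0 <- 1e5
    pd_total <- population_doublings(n0 * k^2, n0)
    pd_steps <- population_doublings(n0 * k, n0) +
      population_doublings(n0 * k^2, n0 * k)
    expect_equal(pd_steps, pd_total)
  }
})

test_that("doubling time is days per doubling, undefined without growth", {
  expect_equal(doubling_time(2, 2), 1)
  expect_equal(doubling_time(1, 3), 3)
  expect_equal(doubling_time(log2(4), 4), 2)
  expect_warning(pdt <- doubling_time(0, 2), "did not grow")
  expect_true(is.na(pdt))
  expect_warning(pdt2 <- doubling_time(-0.5, 2), "did not grow")
  expect_true(is.na(pdt2))
  expect_error(doubling_time(1, 0), "days_in_culture")
})

test_that("the screening verdict flips strictly at the threshold", {
  expect_equal(classify_culture(39.9)$verdict, "SUBSTANDARD")
  expect_equal(classify_culture(40.0)$verdict, "ACCEPTABLE")
  expect_equal(classify_culture(55, threshold = 60)$verdict, "SUBSTANDARD")
  # grid scan: the verdict changes exactly at the threshold and nowhere else
  grid <- seq(0, 80, by = 0.1)
  verdicts <- classify_culture(grid, threshold = 40)$verdict
  expect_true(all(verdicts[grid < 40] == "SUBSTANDARD"))
  expect_true(all(verdicts[grid >= 40] == "ACCEPTABLE"))
  expect_equal(sum(verdicts[-1] != verdicts[-length(verdicts)]), 1)
  expect_error(classify_culture(30, threshold = -1), "non-negative")
  expect_error(classify_culture(-5), "non-negative")
})

test_that("Spearman rho matches the brute-force rank formula", {
  expect_equal(spearman_correlation(1:5, 5:1)$rho, -1)
  # worked example: d = (-1, 1, -1, 1, 0), so 1 - 6 * 4 / (5 * 24) = 0.8
  expect_equal(spearman_correlation(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  # exhaustive check over every permutation at n = 5 (no ties)
  x <- c(3.2, 1.1, 4.8, 2.5, 0.7)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (y in perms(c(10, 20, 30, 40, 50))) {
    expect_equal(spearman_correlation(x, y)$rho, spearman_formula(x, y))
  }
})

test_that("Spearman estimate agrees with the stats reference", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(12); y <- 0.5 * x + rnorm(12)
    ours <- spearman_correlation(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(ours$rho, unname(ref$estimate))
  }
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(7)
  x <- runif(15); y <- runif(15)
  base <- spearman_correlation(x, y)$rho
  expect_equal(spearman_correlation(exp(3 * x), y)$rho, base)
  expect_equal(spearman_correlation(x, y^3 + 2 * y)$rho, base)
  expect_equal(spearman_correlation(rank(x), rank(y))$rho, base)
})

test_that("Spearman rho is centred at zero under independence", {
  set.seed(123)
  rhos <- replicate(1000, {
    spearman_correlation(rnorm(32), rnorm(32))$rho
  })
  expect_lt(abs(mean(rhos)), 0.02)
})

test_that("the Fisher-z interval brackets rho and validates input", {
  # Fisher z with sd 1.03/sqrt(n-3) reproduces the conventional
  # printed interval style for a cohort of n = 32
  res <- spearman_correlation(1:32, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9,
                                      12, 11, 14, 13, 16, 15, 18, 17,
                                      20, 19, 22, 21, 24, 23, 26, 25,
                                      28, 27, 30, 29, 32, 31))
  z <- atanh(res$rho); se <- 1.03 / sqrt(32 - 3)
  expect_equal(res$ci_lower, tanh(z - qnorm(0.975) * se))
  expect_equal(res$ci_upper, tanh(z + qnorm(0.975) * se))
  expect_true(res$ci_lower < res$rho && res$rho < res$ci_upper)
  expect_lt(res$p_value, 0.001)
  expect_error(spearman_correlation(1:5, 1:6), "lengths differ")
  expect_error(spearman_correlation(1:3, 3:1), "at least 4")
  expect_error(spearman_correlation(rep(1, 6), 1:6), "constant")
})

test_that("scatter report tabulates cohorts with verdicts and groups", {
  set.seed(9)
  std <- data.frame(mms = runif(32, 40, 80), pdt = runif(32, 1.5, 3),
                    protocol = "standard")
  chal <- data.frame(mms = runif(16, 10, 40 - 1e-9),
                     pdt = runif(16, 1.8, 3.5), protocol = "challenge")
  rep48 <- scatter_report(rbind(std, chal))
  expect_equal(nrow(rep48), 48)
  expect_true(all(rep48$verdict[rep48$protocol == "challenge"] ==
                    "SUBSTANDARD"))
  expect_equal(attr(rep48, "threshold"), 40)
  low <- scatter_report(data.frame(mms = c(10, 20), pdt = c(3, 4)))
  expect_true(all(low$verdict == "SUBSTANDARD"))
  expect_true(all(low$protocol == "unlabelled"))
  expect_error(scatter_report(data.frame(mms = numeric(0),
                                         pdt = numeric(0))), "at least one")
})
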