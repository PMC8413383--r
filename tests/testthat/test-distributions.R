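# Method-of-moments fitting, chi-squared family selection, perturbation.

test_that("normal fit solves the population-moment equations by hand", {
  f <- fit_distribution(c(1, 2, 3, 1, 2, 3, 1, 2, 3), "normal")
  # population moments of {1,2,3}: mean 2, variance 2/3
  expect_equal(f$parameters$mean, 2, tolerance = 1e-12)
  expect_equal(f$parameters$sd, sqrt(2 / 3), tolerance = 1e-12)
})

test_that("exponential matches the mean with rate 1/mean", {
  x <- c(2, 6, 2, 6, 2, 6, 2, 6)  # mean 4
  f <- fit_distribution(x, "exponential")
  expect_equal(f$parameters$rate, 1 / 4, tolerance = 1e-12)
  expect_equal(f$mean, 4, tolerance = 1e-12)
})

test_that("fitted moments equal the sample's population moments", {
  with_seed(71, x <- rgamma(200, shape = 4, scale = 1.5))
  m <- mean(x)
  v <- mean((x - m)^2)
  for (fam in c("normal", "lognormal", "gamma", "uniform")) {
    f <- fit_distribution(x, fam)
    expect_equal(f$mean, m, tolerance = 1e-10, label = fam)
    expect_equal(f$sd^2, v, tolerance = 1e-10, label = fam)
  }
  # one-parameter exponential: mean only
  f <- fit_distribution(x, "exponential")
  expect_equal(f$mean, m, tolerance = 1e-10)
})

test_that("gamma parameters are recovered from seeded draws", {
  with_seed(73, x <- rgamma(10000, shape = 3, scale = 2))
  f <- fit_distribution(x, "gamma")
  expect_gt(f$parameters$shape, 2.7)
  expect_lt(f$parameters$shape, 3.3)
  expect_gt(f$parameters$scale, 1.8)
  expect_lt(f$parameters$scale, 2.2)
  # independent cross-check: fitdistrplus moment matching
  alt <- fitdistrplus::fitdist(x, "gamma", method = "mme")
  expect_equal(f$parameters$shape, unname(alt$estimate["shape"]),
               tolerance = 1e-6)
  expect_equal(f$parameters$scale, 1 / unname(alt$estimate["rate"]),
               tolerance = 1e-6)
})

test_that("support violations skip the family with a reason", {
  x <- c(-1, 2, 3, 4, 5, 6, 7, 8)
  expect_error(fit_distribution(x, "lognormal"), "family skipped.*support")
  expect_error(fit_distribution(x, "gamma"), "family skipped")
  expect_error(fit_distribution(rep(1:4, 2), "normal", bins = 10),
               NA)  # in-support fit works
  expect_error(fit_distribution(c(1, 2, 3), "normal"), "at least 8")
})

test_that("chi-squared selection separates normal from uniform", {
  with_seed(75, xn <- rnorm(5000))
  f <- select_family(xn, candidates = c("normal", "uniform"))
  expect_equal(f$family, "normal")

  with_seed(76, xu <- runif(5000))
  f <- select_family(xu, candidates = c("normal", "uniform"))
  expect_equal(f$family, "uniform")
})

test_that("selection falls through to the only feasible candidate", {
  with_seed(77, x <- rnorm(50))  # has negatives: lognormal/gamma infeasible
  f <- select_family(x, candidates = c("lognormal", "gamma", "normal"))
  expect_equal(f$family, "normal")
  expect_match(attr(f, "skipped")[["lognormal"]], "support")
  expect_error(select_family(x, candidates = c("lognormal", "gamma")),
               "no feasible candidate")
})

test_that("GOF bins merge on small samples and df is floored", {
  with_seed(78, x <- rnorm(12, 10, 2))
  f <- fit_distribution(x, "normal", bins = 10)
  expect_equal(f$bins_used, 2L)  # floor(12/5) = 2 equiprobable bins
  expect_equal(f$df, 1L)
  big <- fit_distribution(with_seed(79, rnorm(500)), "normal", bins = 10)
  expect_equal(big$bins_used, 10L)
  expect_equal(big$df, 7L)  # 10 - 1 - 2 parameters
})

test_that("perturb shifts the mean by one SD and keeps the SD", {
  f <- fit_distribution(with_seed(80, rnorm(100, 10, 2)), "normal")
  up <- perturb(f, +1)
  expect_equal(up$parameters$mean, f$mean + f$sd, tolerance = 1e-12)
  expect_equal(up$parameters$sd, f$sd, tolerance = 1e-12)
  expect_identical(perturb(f, 0), f)  # bit-exact identity
})

test_that("a textbook shift: Normal(10, 2) + 1 sigma -> Normal(12, 2)", {
  f <- structure(list(family = "normal",
                      parameters = list(mean = 10, sd = 2),
                      mean = 10, sd = 2, gof_statistic = 0, gof_pvalue = 1,
                      df = 1L, bins_used = 10L, n = 100,
                      group = NA, variable = NA, shift = 0),
                 class = "distribution_fit")
  up <- perturb(f, +1)
  expect_equal(up$parameters$mean, 12)
  expect_equal(up$parameters$sd, 2)
})

test_that("gamma re-solves from the shifted moment pair", {
  # mean 6, SD 2 -> shape 9, scale 2/3; down 1 SD -> mean 4, SD 2 ->
  # shape*scale = 4 and shape*scale^2 = 4, i.e. shape 4, scale 1
  f <- structure(list(family = "gamma",
                      parameters = list(shape = 9, scale = 2 / 3),
                      mean = 6, sd = 2, gof_statistic = 0, gof_pvalue = 1,
                      df = 1L, bins_used = 10L, n = 100,
                      group = NA, variable = NA, shift = 0),
                 class = "distribution_fit")
  dn <- perturb(f, -1)
  expect_equal(dn$parameters$shape, 4, tolerance = 1e-10)
  expect_equal(dn$parameters$scale, 1, tolerance = 1e-10)
  expect_equal(dn$mean, 4, tolerance = 1e-10)
  expect_equal(dn$sd, 2, tolerance = 1e-10)
})

test_that("shifts outside the family support suggest the normal fallback", {
  with_seed(81, x <- rexp(100, rate = 1))
  f <- fit_distribution(x, "exponential")
  expect_error(perturb(f, -1), "fall back to the normal family")
  g <- fit_distribution(with_seed(82, rgamma(100, 2, 2)), "gamma")
  expect_error(perturb(g, -3), "fall back to the normal family")
})

test_that("quantile coupling is monotone and hits the fitted moments", {
  with_seed(83, x <- rlnorm(500, 1, 0.4))
  f <- fit_distribution(x, "lognormal")
  u <- seq(0.01, 0.99, by = 0.01)
  q <- dist_quantile(f, u)
  expect_false(is.unsorted(q))
  # analytic mean of the fitted family equals the sample mean
  expect_equal(f$mean, mean(x), tolerance = 1e-10)
})
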