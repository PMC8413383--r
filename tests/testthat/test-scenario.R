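# The scenario engine: coupled resampling, Delta K / Delta kappa,
# adjudication.

# grouped table, K = intercept + beta * x exactly, x ~ N(mu_g, sigma_g)
linear_scenario_setup <- function(beta = 0.1, intercept = 8, seed = 91,
                                  n_per_group = 40) {
  tb <- linear_table(n_per_group = n_per_group, beta = beta,
                     intercept = intercept, noise = 0, seed = seed)
  fit <- fit_model(model_spec("glm"), tb)
  fits <- fit_group_distributions(tb, "x", candidates = "normal")
  list(tb = tb, fit = fit, fits = fits)
}

test_that("a zero shift under common random numbers changes nothing", {
  su <- linear_scenario_setup()
  spec0 <- scenario_spec("S0", c(x = 0), "increase", n_draws = 200)
  res <- run_scenario(su$fit, su$tb, spec0, su$fits, master_seed = 5)
  expect_true(all(res$delta_K == 0))
  expect_true(all(res$delta_kappa == 0))
  expect_equal(attr(res, "classification"), "best-case")
})

test_that("linear model: Delta K = beta * sigma_g, antisymmetric in the shift", {
  su <- linear_scenario_setup(beta = 0.1)
  up <- scenario_spec("up", c(x = +1), "increase", n_draws = 300)
  dn <- scenario_spec("dn", c(x = -1), "decrease", n_draws = 300)
  r_up <- run_scenario(su$fit, su$tb, up, su$fits, master_seed = 5)
  r_dn <- run_scenario(su$fit, su$tb, dn, su$fits, master_seed = 5)
  for (g in r_up$group) {
    sigma_g <- su$fits[[g]][["x"]]$sd
    expect_lt(abs(r_up$delta_K[r_up$group == g] - 0.1 * sigma_g), 1e-8)
    expect_lt(abs(r_up$delta_K[r_up$group == g] +
                    r_dn$delta_K[r_dn$group == g]), 1e-8)
  }
})

test_that("the Delta kappa identity holds to numerical precision", {
  su <- linear_scenario_setup(seed = 93)
  sp <- scenario_spec("up", c(x = +1), "increase", n_draws = 100)
  res <- run_scenario(su$fit, su$tb, sp, su$fits, master_seed = 7)
  expect_lt(max(abs(res$delta_kappa * res$K_base / 100 - res$delta_K)),
            1e-12)
  # direct arithmetic spot check of the formula
  expect_equal((13.0 - 13.4) / 13.4 * 100, -2.985075, tolerance = 1e-6)
})

test_that("non-perturbed columns do not contribute to Delta K", {
  # model reads ONLY column z; perturbing x must leave predictions
  # identical, proving substitution locality
  with_seed(95, {
    df <- do.call(rbind, lapply(c("A", "B"), function(g) {
      data.frame(state = g, x = rnorm(30, 20, 3), z = rnorm(30, 5, 1))
    }))
    df$K <- 10 + 0.5 * df$z
  })
  tb <- mk_table(df[, c("K", "state", "x", "z")])
  fit <- fit_model(model_spec("glm"), tb)
  fits <- fit_group_distributions(tb, "x", candidates = "normal")
  sp <- scenario_spec("sx", c(x = +1), "increase", n_draws = 150)
  res <- run_scenario(fit, tb, sp, fits, master_seed = 9)
  expect_true(all(abs(res$delta_K) < 1e-10))
  # K_base equals the group mean of the untouched z contribution
  for (g in res$group) {
    zbar <- mean(df$z[df$state == g])
    expect_equal(res$K_base[res$group == g], 10 + 0.5 * zbar,
                 tolerance = 1e-10)
  }
})

test_that("declared bounds clip sampled values and report the rate", {
  with_seed(97, {
    df <- do.call(rbind, lapply(c("A", "B"), function(g) {
      data.frame(state = g, x = pmax(rnorm(30, 1.5, 2), 0))
    }))
    df$K <- 12 + 0.1 * df$x
  })
  tb <- mk_table(df[, c("K", "state", "x")],
                 bounds = list(x = c(0, 100)))
  fit <- fit_model(model_spec("glm"), tb)
  fits <- fit_group_distributions(tb, "x", candidates = "normal")
  sp <- scenario_spec("sx", c(x = -1), "decrease", n_draws = 200)
  res <- run_scenario(fit, tb, sp, fits, master_seed = 11)
  expect_true(all(res$clip_rate > 0))  # mean near 0: many draws below 0
  expect_true(all(res$clip_rate <= 1))
})

test_that("scenario draws are reproducible and seed-sensitive", {
  su <- linear_scenario_setup(seed = 99)
  sp <- scenario_spec("up", c(x = +1), "increase", n_draws = 100)
  a <- run_scenario(su$fit, su$tb, sp, su$fits, master_seed = 1)
  b <- run_scenario(su$fit, su$tb, sp, su$fits, master_seed = 1)
  c <- run_scenario(su$fit, su$tb, sp, su$fits, master_seed = 2)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$K_base, c$K_base))
})

test_that("missing fits and unknown variables are caught up front", {
  su <- linear_scenario_setup(seed = 101)
  sp_bad <- scenario_spec("bad", c(nope = 1), "increase", n_draws = 10)
  expect_error(run_scenario(su$fit, su$tb, sp_bad, su$fits),
               "unknown predictor")
  sp <- scenario_spec("up", c(x = 1), "increase", n_draws = 10)
  expect_error(run_scenario(su$fit, su$tb, sp,
                            list(A = list()), master_seed = 1),
               "no distribution fit")
})

mk_result <- function(dK, expected, K_base = 13) {
  df <- data.frame(group = paste0("G", seq_along(dK)),
                   n_communities = 10, K_base = K_base,
                   K_scenario = K_base + dK, delta_K = dK,
                   delta_kappa = dK / K_base * 100, clip_rate = 0)
  structure(df, id = "T", expected = expected,
            description = "synthetic verdict case",
            national_mean_delta_K = mean(dK),
            classification = if (mean(dK) > 0) "worst-case" else "best-case",
            class = c("scenario_result", "data.frame"))
}

test_that("adjudication follows the sign rules", {
  sp <- scenario_spec("T", c(x = 1), "increase", n_draws = 10)
  v <- adjudicate(mk_result(c(0.2, 0.1, 0.4), "increase"), sp)
  expect_true(v$hypothesis_supported)
  expect_equal(v$classification, "worst-case")
  expect_equal(v$n_supporting, 3)
  expect_length(v$nonconforming_groups, 0)

  # negative mean: best-case
  sp_dec <- scenario_spec("T", c(x = -1), "decrease", n_draws = 10)
  v2 <- adjudicate(mk_result(c(-0.3, -0.1), "decrease"), sp_dec)
  expect_equal(v2$classification, "best-case")
  expect_true(v2$hypothesis_supported)

  # mixed signs: support only where the sign conforms; stragglers listed
  v3 <- adjudicate(mk_result(c(0.5, -0.2, 0.3), "increase"), sp)
  expect_equal(v3$n_supporting, 2)
  expect_equal(v3$nonconforming_groups, "G2")
})

test_that("the default hypothesis suite encodes the ten scenarios", {
  vm <- list(poverty = "pov", unemployment = "unemp", income = "inc",
             no_insurance = "noins", public_private_ratio = "ratio",
             transport_cost = "tcost", vacancy = "vac")
  scen <- default_scenarios(vm)
  expect_named(scen, paste0("H", 1:10))
  h1 <- scen$H1
  expect_equal(h1$directions, c(pov = 1, unemp = 1, inc = -1))
  expect_equal(h1$expected, "increase")
  h2 <- scen$H2
  expect_equal(h2$directions, c(pov = -1, unemp = -1, inc = 1))
  expect_equal(h2$expected, "decrease")
  expect_equal(scen$H6$directions, c(ratio = 1))
  expect_equal(scen$H6$expected, "decrease")
  expect_equal(scen$H10$directions, c(vac = 1))
  expect_equal(scen$H10$expected, "increase")
  # scenarios degrade gracefully when a variable is unmapped
  scen_small <- default_scenarios(list(vacancy = "vac"))
  expect_named(scen_small, c("H9", "H10"))
})

test_that("scenario results export as tidy CSV", {
  su <- linear_scenario_setup(seed = 103)
  sp <- scenario_spec("H1", c(x = +1), "increase", n_draws = 50)
  res <- run_scenario(su$fit, su$tb, sp, su$fits, master_seed = 3)
  v <- adjudicate(res, sp)
  f <- withr::local_tempfile(fileext = ".csv")
  write_scenario_result(v, f)
  back <- utils::read.csv(f)
  expect_equal(names(back), c("hypothesis", "group", "K_base",
                              "K_scenario", "delta_K", "delta_kappa",
                              "supported"))
  expect_equal(nrow(back), nrow(res))
  expect_equal(back$delta_K, res$delta_K, tolerance = 1e-15)
})
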