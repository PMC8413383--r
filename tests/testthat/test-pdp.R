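# Partial dependence: oracle equivalence, closed forms, bands, ranking.

# independent brute-force oracle: loop over background rows, clone the
# row, overwrite the predictor, predict, accumulate
brute_pdp <- function(model, table, predictor, grid) {
  X <- predictor_matrix(table)
  acc <- numeric(length(grid))
  for (i in seq_len(nrow(X))) {
    Xi <- X[rep(i, length(grid)), , drop = FALSE]
    Xi[, predictor] <- grid
    acc <- acc + predict(model, Xi)
  }
  acc / nrow(X)
}

test_that("compute_pdp matches the brute-force row-clone oracle", {
  tb <- friedman_table(50, noise = 0.5, seed = 51)
  grid <- as.numeric(stats::quantile(tb$data$x1, c(0.1, 0.35, 0.6, 0.85)))
  for (fam in c("glm", "mars", "random_forest", "gbm", "bart")) {
    fit <- fit_model(fast_spec(fam, seed = 13), tb)
    got <- compute_pdp(fit, tb, "x1", grid = grid)
    want <- brute_pdp(fit, tb, "x1", grid)
    expect_lt(max(abs(got$effect - want)), 1e-10)
  }
})

test_that("additive models have the closed-form partial effect", {
  # f(x1, x2) = x1 + x2 exactly, so pdp(x1 = v) = v + mean(x2)
  df <- data.frame(K = NA, state = "a",
                   x1 = c(3, 4, 5, 6, 7, 8), x2 = c(0, 1, 2, 0, 1, 2))
  df$K <- df$x1 + df$x2
  tb <- mk_table(df)
  fit <- fit_model(model_spec("glm"), tb)
  p <- compute_pdp(fit, tb, "x1", grid = 5)
  expect_equal(p$effect, 5 + mean(df$x2), tolerance = 1e-8)
})

test_that("a single background row reduces the PDP to a point prediction", {
  tb <- friedman_table(30, noise = 0.5, seed = 53)
  one <- ft_subset(tb, 4L)
  fit <- fit_model(fast_spec("gbm", seed = 1), tb)
  v <- tb$data$x2[4]
  p <- compute_pdp(fit, one, "x2", grid = v)
  expect_equal(p$effect, predict(fit, one$data), tolerance = 1e-12)
  expect_equal(attr(p, "n_background"), 1L)
})

test_that("the PDP of an ignored predictor is flat", {
  with_seed(55, {
    x1 <- runif(80)
    df <- data.frame(K = 10 + 2 * x1, state = "a", x1 = x1,
                     ignored = runif(80))
  })
  tb <- mk_table(df)
  fit <- fit_model(model_spec("mars"), tb)  # never selects `ignored`
  p <- compute_pdp(fit, tb, "ignored")
  expect_lt(max(p$effect) - min(p$effect), 1e-10)
})

test_that("the PDP is invariant to permuting background rows", {
  tb <- friedman_table(60, noise = 0.5, seed = 57)
  fit <- fit_model(fast_spec("random_forest", seed = 3), tb)
  with_seed(58, perm <- sample(60))
  tb_perm <- feature_table(tb$data[perm, ], tb$meta)
  grid <- as.numeric(stats::quantile(tb$data$x3, c(0.2, 0.5, 0.8)))
  p1 <- compute_pdp(fit, tb, "x3", grid = grid)
  p2 <- compute_pdp(fit, tb_perm, "x3", grid = grid)
  expect_equal(p1$effect, p2$effect, tolerance = 1e-12)
})

test_that("grid hygiene: empty, unsorted and extrapolating grids", {
  tb <- friedman_table(30, noise = 0.5, seed = 59)
  fit <- fit_model(model_spec("glm"), tb)
  expect_error(compute_pdp(fit, tb, "x1", grid = numeric(0)), "empty")
  expect_error(compute_pdp(fit, tb, "x1", grid = c(0.5, 0.2)),
               "strictly increasing")
  expect_warning(compute_pdp(fit, tb, "x1", grid = c(0.5, 99)),
                 "extrapolation")
  expect_error(compute_pdp(fit, tb, "nope", grid = 1), "not a model")
  # default grid is strictly increasing within the observed range
  p <- compute_pdp(fit, tb, "x1")
  expect_false(is.unsorted(p$grid, strictly = TRUE))
})

test_that("a monotone positive driver yields a monotone PDP", {
  gen <- generate_communities(generator_config(
    n_groups = 25, communities_per_group = 20, seed = 61,
    preclinical = NULL))
  fit <- fit_model(fast_spec("gbm", seed = 7), gen$table)
  x <- gen$table$data$poverty
  grid <- as.numeric(unique(stats::quantile(x, seq(0.25, 0.75, by = 0.05))))
  p <- compute_pdp(fit, gen$table, "poverty", grid = grid)
  rho <- stats::cor(p$grid, p$effect, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("bands: constant model is width zero, B = 1 degenerates", {
  df <- data.frame(K = rep(12.5, 20), state = "a", x = runif(20))
  tb <- mk_table(df)
  fit <- fit_model(model_spec("glm"), tb)  # constant-response fast path
  p <- pdp_band(fit, tb, "x", B = 100)
  expect_equal(p$lower, p$effect, tolerance = 1e-12)
  expect_equal(p$upper, p$effect, tolerance = 1e-12)

  tb2 <- friedman_table(40, noise = 0.5, seed = 63)
  fit2 <- fit_model(fast_spec("gbm", seed = 2), tb2)
  p1 <- pdp_band(fit2, tb2, "x1", B = 1)
  expect_identical(p1$lower, p1$effect)
  expect_identical(p1$upper, p1$effect)
  # a real bootstrap band brackets the point estimate
  pB <- pdp_band(fit2, tb2, "x1", B = 50)
  expect_true(all(pB$lower <= pB$effect + 1e-12))
  expect_true(all(pB$upper >= pB$effect - 1e-12))
})

test_that("bart bands are the posterior percentiles of draw-wise PDPs", {
  tb <- friedman_table(40, noise = 0.5, seed = 65)
  fit <- fit_model(fast_spec("bart", seed = 11), tb)
  grid <- as.numeric(stats::quantile(tb$data$x4, c(0.25, 0.75)))
  p <- pdp_band(fit, tb, "x4", grid = grid)
  X <- predictor_matrix(tb)
  for (gi in seq_along(grid)) {
    Xv <- X
    Xv[, "x4"] <- grid[gi]
    draw_means <- rowMeans(predict_draws(fit, Xv))
    qs <- stats::quantile(draw_means, c(0.025, 0.975), names = FALSE)
    expect_equal(p$lower[gi], qs[1], tolerance = 1e-10)
    expect_equal(p$upper[gi], qs[2], tolerance = 1e-10)
    expect_equal(p$effect[gi], mean(draw_means), tolerance = 1e-10)
  }
  expect_equal(attr(p, "band"), "posterior")
})

test_that("rank_variables is ordered, normalized and reproducible", {
  with_seed(67, {
    df <- data.frame(K = NA, state = "a", a = runif(120), b = runif(120),
                     c = runif(120))
    df$K <- 10 + 3 * df$a + 1 * df$b
  })
  tb <- mk_table(df)
  fit <- fit_model(fast_spec("gbm", seed = 5), tb)
  r <- rank_variables(fit)
  expect_equal(r$predictor[1], "a")
  expect_equal(sum(r$score), 1, tolerance = 1e-12)
  expect_equal(r$rank, 1:3)
  expect_identical(rank_variables(fit), r)
})

test_that("pure-noise predictors score near-uniform importance", {
  with_seed(69, {
    df <- data.frame(K = NA, state = "a", n1 = runif(500), n2 = runif(500),
                     n3 = runif(500), n4 = runif(500))
    df$K <- 13 + rnorm(500, 0, 1)
  })
  tb <- mk_table(df)
  fit <- fit_model(fast_spec("random_forest", seed = 9), tb)
  r <- rank_variables(fit)
  expect_lt(max(r$score) - min(r$score), 0.15)
})
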