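# Repeated-holdout splits, scoring and best-model selection.

test_that("splits have the 80-20 shape and partition the rows", {
  plans <- make_splits(100, repeats = 30, seed = 7)
  expect_length(plans, 30)
  for (pl in plans) {
    expect_length(pl$train, 80)
    expect_length(pl$test, 20)
    expect_length(intersect(pl$train, pl$test), 0)
    expect_setequal(c(pl$train, pl$test), 1:100)
  }
  # every row appears in at least one training set
  expect_setequal(unique(unlist(lapply(plans, `[[`, "train"))), 1:100)

  small <- make_splits(10, repeats = 5, seed = 1)
  expect_length(small[[1]]$train, 8)
  expect_length(small[[1]]$test, 2)

  expect_error(make_splits(4, 3, 1), "too small")

  # too few repeats to cover every row: proceed with a warning
  expect_warning(one <- suppressMessages(make_splits(200, repeats = 1,
                                                     seed = 2)),
                 "coverage incomplete")
  expect_length(one, 1)
})

test_that("identical seeds reproduce identical plans", {
  a <- make_splits(60, repeats = 30, seed = 123)
  b <- make_splits(60, repeats = 30, seed = 123)
  expect_identical(a, b)
  c <- make_splits(60, repeats = 30, seed = 124)
  expect_false(identical(a, c))
})

test_that("score_predictions matches hand arithmetic", {
  s <- score_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s, list(r2 = 1, rmse = 0, mae = 0))

  expect_warning(s <- score_predictions(c(0, 0), c(1, 1)),
                 "zero-variance")  # constant y: R^2 undefined
  expect_equal(s$rmse, 1)
  expect_equal(s$mae, 1)

  # mean predictor: R^2 = 0 by construction
  s <- score_predictions(c(1, 2, 3), c(2, 2, 2))
  expect_equal(s$rmse, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(s$mae, 2 / 3, tolerance = 1e-12)
  expect_equal(s$r2, 0, tolerance = 1e-12)

  expect_warning(s <- score_predictions(c(5, 5, 5), c(4, 5, 6)),
                 "zero-variance")
  expect_true(is.na(s$r2))
  expect_equal(s$rmse, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(s$mae, 2 / 3, tolerance = 1e-12)
})

test_that("score_predictions agrees with a brute-force loop", {
  brute <- function(y, yhat) {
    sse <- 0; sae <- 0; sst <- 0
    m <- sum(y) / length(y)
    for (i in seq_along(y)) {
      sse <- sse + (y[i] - yhat[i])^2
      sae <- sae + abs(y[i] - yhat[i])
      sst <- sst + (y[i] - m)^2
    }
    list(r2 = 1 - sse / sst, rmse = sqrt(sse / length(y)),
         mae = sae / length(y))
  }
  with_seed(17, {
    for (rep in 1:20) {
      y <- rnorm(25)
      yhat <- y + rnorm(25, 0, 0.5)
      got <- score_predictions(y, yhat)
      want <- brute(y, yhat)
      expect_equal(got$r2, want$r2, tolerance = 1e-12)
      expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
      expect_equal(got$mae, want$mae, tolerance = 1e-12)
    }
  })
})

test_that("the null model's holdout RMSE approximates the response SD", {
  # mean predictor: expected RMSE equals the population SD of K
  with_seed(19, {
    df <- data.frame(K = rnorm(400, 13, 2), state = "a", x = runif(400))
  })
  tb <- mk_table(df)
  plans <- make_splits(400, repeats = 30, seed = 2)
  rep_cv <- run_cv(tb, list(model_spec("glm")), plans)
  null_rmse <- rep_cv$summary$mean_rmse_out[rep_cv$summary$model == "null"]
  expect_equal(null_rmse, 2, tolerance = 0.15)
})

test_that("glm on noiseless linear data is exact on every repeat", {
  tb <- linear_table(n_per_group = 20, noise = 0, seed = 23)
  plans <- make_splits(n_communities(tb), repeats = 10, seed = 3)
  rep_cv <- run_cv(tb, list(model_spec("glm")), plans)
  cells <- rep_cv$cells[rep_cv$cells$model == "glm", ]
  expect_true(all(cells$rmse_out < 1e-8))
  expect_true(all(is.na(cells$error)))
})

test_that("metric cells satisfy RMSE >= MAE and R^2 <= 1", {
  tb <- friedman_table(80, noise = 1, seed = 25)
  plans <- make_splits(80, repeats = 5, seed = 4)
  rep_cv <- run_cv(tb, list(model_spec("glm"), fast_spec("gbm")), plans)
  ok <- rep_cv$cells[is.na(rep_cv$cells$error), ]
  expect_true(all(ok$rmse_in >= ok$mae_in))
  expect_true(all(ok$rmse_out >= ok$mae_out))
  expect_true(all(ok$r2_in[ok$model != "null"] <= 1 + 1e-12))
})

test_that("single fit failures are recorded and the harness continues", {
  with_seed(27, {
    x1 <- rnorm(40)
    df <- data.frame(K = 12 + x1, state = "a", x1 = x1, x2 = 2 * x1)
  })
  tb <- mk_table(df)  # collinear pair: glm fails, ridge copes
  plans <- make_splits(40, repeats = 3, seed = 5)
  rep_cv <- run_cv(tb, list(model_spec("glm"),
                            model_spec("ridge", list(lambda = 0.01))),
                   plans)
  glm_cells <- rep_cv$cells[rep_cv$cells$model == "glm", ]
  expect_true(all(grepl("singular", glm_cells$error)))
  ridge_cells <- rep_cv$cells[rep_cv$cells$model == "ridge[lambda=0.01]", ]
  expect_true(all(is.na(ridge_cells$error)))
  best <- select_best(rep_cv)
  expect_equal(best$family, "ridge")
})

test_that("a flexible learner is selected over glm on a nonlinear truth", {
  tb <- friedman_table(300, noise = 0.6, seed = 29)
  plans <- make_splits(300, repeats = 6, seed = 6)
  rep_cv <- run_cv(tb, list(model_spec("glm"), fast_spec("gbm", seed = 2)),
                   plans)
  s <- rep_cv$summary
  expect_lt(s$mean_rmse_out[s$model == "gbm"],
            s$mean_rmse_out[s$model == "glm"])
  expect_equal(select_best(rep_cv)$family, "gbm")

  # the winner is stable under a row permutation of the input table
  with_seed(30, perm <- sample(n_communities(tb)))
  tb_perm <- feature_table(tb$data[perm, ], tb$meta)
  rep_cv2 <- run_cv(tb_perm, list(model_spec("glm"),
                                  fast_spec("gbm", seed = 2)), plans)
  expect_equal(select_best(rep_cv2)$family, "gbm")
})

test_that("exact ties break by registry order, logged", {
  tb <- linear_table(n_per_group = 20, noise = 0.1, seed = 31)
  plans <- make_splits(n_communities(tb), repeats = 3, seed = 7)
  # the same model registered twice: a perfect tie on every metric
  specs <- list(model_spec("glm", label = "glm"),
                model_spec("glm", label = "glm_again"))
  rep_cv <- run_cv(tb, specs, plans)
  expect_message(best <- select_best(rep_cv), "tie")
  expect_equal(best$label, "glm")
})

test_that("flexible in-sample RMSE does not exceed holdout RMSE on average", {
  tb <- friedman_table(150, noise = 1, seed = 33)
  plans <- make_splits(150, repeats = 8, seed = 8)
  rep_cv <- run_cv(tb, list(fast_spec("random_forest", seed = 3),
                            fast_spec("gbm", seed = 3)), plans)
  s <- rep_cv$summary
  for (m in c("random_forest", "gbm")) {
    expect_lt(s$mean_rmse_in[s$model == m], s$mean_rmse_out[s$model == m])
  }
})

test_that("the comparison table mirrors the report and writes to disk", {
  tb <- linear_table(noise = 0.2, seed = 35)
  plans <- make_splits(n_communities(tb), repeats = 3, seed = 9)
  rep_cv <- run_cv(tb, list(model_spec("glm")), plans)
  tab <- cv_table(rep_cv)
  expect_equal(tab$model, c("glm", "null"))
  expect_true(is.na(tab$r2[tab$model == "null"]))
  expect_equal(tab$r2[1], unname(rep_cv$full_r2["glm"]))
  f <- withr::local_tempfile(fileext = ".csv")
  fj <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rep_cv, f, fj)
  back <- utils::read.csv(f)
  expect_equal(back$rmse_out, tab$rmse_out, tolerance = 1e-15)
  expect_true(jsonlite::validate(paste(readLines(fj), collapse = "")))
})
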