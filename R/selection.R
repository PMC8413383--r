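# Repeated randomized percentage-holdout model selection.
#
# Each repeat draws a random 80% training subset and scores every
# registered learner on both the training rows (in-sample) and the 20%
# holdout (out-of-sample) by R^2, RMSE and MAE, alongside a null model
# that predicts the training-set mean. The best learner minimizes mean
# out-of-sample RMSE (ties: out-of-sample MAE, then in-sample RMSE, then
# registry order).

#' Plan repeated randomized holdout splits
#'
#' Draws `repeats` independent train/test partitions with
#' `round(train_fraction * n)` training rows (at least one row held out).
#' After drawing, coverage is checked: every row must appear in at least
#' one training set; if not, the whole plan is redrawn (logged). With 80%
#' draws repeated 30 times a coverage failure has probability about
#' `n * 0.2^30`, so redraws are essentially never needed; with very few
#' repeats coverage may be unattainable, in which case the last draw is
#' used with a warning.
#'
#' @param n number of rows (must be at least 5).
#' @param repeats number of holdout repeats (default 30).
#' @param seed integer seed; identical seeds give identical plans.
#' @param train_fraction training proportion (default 0.8).
#' @return list of `split_plan` objects with fields `repeat_index`,
#'   `train`, `test`, `seed`.
#' @export
make_splits <- function(n, repeats = 30L, seed = 1L, train_fraction = 0.8) {
  if (n < 5) stop("n too small for an 80-20 split (need n >= 5)",
                  call. = FALSE)
  stopifnot(repeats >= 1, train_fraction > 0, train_fraction < 1)
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)

  with_seed(seed, {
    plans <- NULL
    for (attempt in 1:50) {
      plans <- lapply(seq_len(repeats), function(r) {
        train <- sort(sample.int(n, n_train))
        structure(list(repeat_index = r, train = train,
                       test = setdiff(seq_len(n), train), seed = seed),
                  class = "split_plan")
      })
      covered <- unique(unlist(lapply(plans, `[[`, "train")))
      if (length(covered) == n) return(plans)
      if (attempt <= 3)
        stage_log("splits",
                  "coverage check failed (attempt %d): %d/%d rows in a training set; redrawing",
                  attempt, length(covered), n)
    }
    # with this few repeats full coverage may be unattainable; proceed on
    # the last draw rather than refuse the run
    warning(sprintf(
      "training coverage incomplete after 50 redraws (%d/%d rows); %d repeats are too few to cover every row",
      length(covered), n, repeats), call. = FALSE)
    plans
  })
}

#' Score predictions against observations
#'
#' `rmse` is the root mean squared error, `mae` the mean absolute error
#' and `r2 = 1 - SSE/SST` with SST about the mean of `y`. A zero-variance
#' `y` leaves R^2 undefined: `r2` is returned as `NA` with a warning
#' (RMSE and MAE are still valid).
#'
#' @param y observed response vector (length at least 2).
#' @param yhat predictions, same length.
#' @return list with elements `r2`, `rmse`, `mae`.
#' @export
score_predictions <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ",
                                      call. = FALSE)
  if (length(y) < 2) stop("need at least 2 observations", call. = FALSE)
  err <- y - yhat
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) {
    warning("zero-variance y: R^2 undefined", call. = FALSE)
    NA_real_
  } else 1 - sum(err^2) / sst
  list(r2 = r2, rmse = rmse, mae = mae)
}

#' Run the repeated-holdout comparison harness
#'
#' Fits every spec on every plan's training rows and scores in- and
#' out-of-sample. A null model predicting the training-set mean is always
#' included (its R^2 is reported as `NA`: not applicable). Individual fit
#' failures are recorded as missing cells with the error message; the
#' harness continues. Each family's single reported R^2 is the in-sample
#' R^2 of a full-data refit (the holdout cells retain their own per-repeat
#' R^2 detail).
#'
#' @param table a [feature_table()].
#' @param specs list of [model_spec()] (see [default_model_specs()]).
#' @param plans list of split plans from [make_splits()].
#' @return a `cv_report`: list with `cells` (one row per model x repeat x
#'   in/out), `summary` (per-model means and SDs), `full_r2` (full-data
#'   refit in-sample R^2) and `specs`.
#' @export
run_cv <- function(table, specs, plans) {
  stopifnot(inherits(table, "feature_table"), length(specs) >= 1)
  y <- response_values(table)
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate model labels", call. = FALSE)

  rows <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    for (pl in plans) {
      cell <- tryCatch({
        fit <- fit_model(spec, table, train_index = pl$train)
        sin <- score_predictions(y[pl$train],
                                 predict(fit, table$data[pl$train, ]))
        sout <- score_predictions(y[pl$test],
                                  predict(fit, table$data[pl$test, ]))
        data.frame(model = spec$label, family = spec$family,
                   repeat_index = pl$repeat_index,
                   r2_in = sin$r2, rmse_in = sin$rmse, mae_in = sin$mae,
                   r2_out = sout$r2, rmse_out = sout$rmse,
                   mae_out = sout$mae, error = NA_character_)
      }, error = function(e) {
        data.frame(model = spec$label, family = spec$family,
                   repeat_index = pl$repeat_index,
                   r2_in = NA_real_, rmse_in = NA_real_, mae_in = NA_real_,
                   r2_out = NA_real_, rmse_out = NA_real_,
                   mae_out = NA_real_, error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  # null baseline: training-mean predictor
  for (pl in plans) {
    mu <- mean(y[pl$train])
    rows[[length(rows) + 1L]] <- data.frame(
      model = "null", family = "null", repeat_index = pl$repeat_index,
      r2_in = NA_real_,
      rmse_in = sqrt(mean((y[pl$train] - mu)^2)),
      mae_in = mean(abs(y[pl$train] - mu)),
      r2_out = NA_real_,
      rmse_out = sqrt(mean((y[pl$test] - mu)^2)),
      mae_out = mean(abs(y[pl$test] - mu)),
      error = NA_character_)
  }
  cells <- do.call(rbind, rows)

  metric_cols <- c("r2_in", "rmse_in", "mae_in", "r2_out", "rmse_out",
                   "mae_out")
  model_order <- c(labels, "null")
  summ <- do.call(rbind, lapply(model_order, function(lb) {
    sub <- cells[cells$model == lb & is.na(cells$error), , drop = FALSE]
    means <- vapply(metric_cols, function(cc)
      if (nrow(sub)) mean(sub[[cc]]) else NA_real_, numeric(1))
    sds <- vapply(metric_cols, function(cc)
      if (nrow(sub)) stats::sd(sub[[cc]]) else NA_real_, numeric(1))
    out <- data.frame(model = lb, n_ok = nrow(sub))
    for (cc in metric_cols) out[[paste0("mean_", cc)]] <- means[[cc]]
    for (cc in metric_cols) out[[paste0("sd_", cc)]] <- sds[[cc]]
    out
  }))

  full_r2 <- vapply(specs, function(spec) {
    tryCatch({
      fit <- fit_model(spec, table)
      score_predictions(y, predict(fit, table$data))$r2
    }, error = function(e) NA_real_)
  }, numeric(1))
  names(full_r2) <- labels

  structure(list(cells = cells, summary = summ, full_r2 = full_r2,
                 specs = specs, n = n_communities(table),
                 repeats = length(plans)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d models x %d repeats on n=%d\n",
              length(x$specs), x$repeats, x$n))
  tab <- cv_table(x)
  print(format(tab, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Model-comparison table
#'
#' One row per model: full-data in-sample R^2 and mean in-/out-of-sample
#' RMSE and MAE over the holdout repeats (null baseline last, R^2 not
#' applicable).
#'
#' @param report a `cv_report`.
#' @return a data.frame.
#' @export
cv_table <- function(report) {
  s <- report$summary
  data.frame(model = s$model,
             r2 = c(unname(report$full_r2[s$model[s$model != "null"]]),
                    NA_real_)[seq_len(nrow(s))],
             rmse_in = s$mean_rmse_in, mae_in = s$mean_mae_in,
             rmse_out = s$mean_rmse_out, mae_out = s$mean_mae_out)
}

#' Write a CV report to disk
#'
#' `path` gets the model-comparison CSV ([cv_table()] layout);
#' `detail_path`, when given, gets the per-repeat cells as JSON.
#'
#' @param report a `cv_report`.
#' @param path CSV output path.
#' @param detail_path optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path, detail_path = NULL) {
  write_csv_precise(cv_table(report), path)
  if (!is.null(detail_path)) {
    jsonlite::write_json(report$cells, detail_path, dataframe = "rows",
                         na = "null", digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Select the best model from a CV report
#'
#' Minimizes mean out-of-sample RMSE; ties (within `tol`) are broken by
#' mean out-of-sample MAE, then mean in-sample RMSE, then registry order
#' (logged when invoked).
#'
#' @param report a `cv_report`.
#' @param tol tie tolerance on each criterion.
#' @return the winning [model_spec()].
#' @export
select_best <- function(report, tol = 1e-12) {
  stopifnot(inherits(report, "cv_report"))
  s <- report$summary[report$summary$model != "null", , drop = FALSE]
  s <- s[s$n_ok > 0, , drop = FALSE]
  if (!nrow(s)) stop("all model families failed", call. = FALSE)
  labels <- vapply(report$specs, `[[`, character(1), "label")
  s$registry_order <- match(s$model, labels)

  cand <- s[s$mean_rmse_out <= min(s$mean_rmse_out) + tol, , drop = FALSE]
  if (nrow(cand) > 1) {
    cand <- cand[cand$mean_mae_out <= min(cand$mean_mae_out) + tol, ,
                 drop = FALSE]
    if (nrow(cand) > 1)
      cand <- cand[cand$mean_rmse_in <= min(cand$mean_rmse_in) + tol, ,
                   drop = FALSE]
    if (nrow(cand) > 1) {
      stage_log("select", "tie among {%s}; broken by registry order",
                paste(cand$model, collapse = ", "))
      cand <- cand[order(cand$registry_order), , drop = FALSE]
    }
  }
  report$specs[[cand$registry_order[1]]]
}
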