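# End-to-end orchestration: load/generate -> reduce -> select -> interpret
# -> scenarios -> report.  Every artifact is a plain CSV/JSON file; one
# master seed fans out to every stage, so a rerun with the same config is
# byte-identical.

#' Configure an end-to-end run
#'
#' @param input `NULL` to generate synthetic data from `generator`, or a
#'   list `list(csv = ..., meta = ...)` of paths for
#'   [load_feature_table()].
#' @param generator a [generator_config()] (used when `input` is `NULL`).
#' @param model_labels which members of [default_model_specs()] to
#'   compare (default: all). Labels, e.g. `"glm"`, `"mars[degree=2]"`.
#' @param model_specs optional explicit list of [model_spec()] objects;
#'   overrides `model_labels` (use to resize stochastic samplers).
#' @param repeats holdout repeats (default 30).
#' @param train_fraction training share per split (default 0.8).
#' @param pca_threshold explained-variance threshold for the pre-clinical
#'   reduction; `NULL` skips the reduction.
#' @param pdp_predictors predictors to compute PDPs for; `"auto"` takes
#'   the `pdp_top_k` most important.
#' @param pdp_top_k how many top-ranked predictors `"auto"` selects.
#' @param pdp_band_B bootstrap resamples for non-Bayesian PDP bands.
#' @param variable_map conceptual-to-column map for
#'   [default_scenarios()]; `NULL` uses the synthetic generator's
#'   default column names.
#' @param scenarios list of [scenario_spec()]; default: the H1-H10 suite
#'   from `variable_map`.
#' @param n_draws scenario resample size per group.
#' @param seed master seed.
#' @param output_dir directory for artifacts.
#' @return a `run_config`.
#' @export
run_config <- function(input = NULL,
                       generator = generator_config(),
                       model_labels = NULL,
                       model_specs = NULL,
                       repeats = 30L,
                       train_fraction = 0.8,
                       pca_threshold = 0.92,
                       pdp_predictors = "auto",
                       pdp_top_k = 5L,
                       pdp_band_B = 200L,
                       variable_map = NULL,
                       scenarios = NULL,
                       n_draws = 1000L,
                       seed = 1L,
                       output_dir = "scenpred_run") {
  stopifnot(repeats >= 1, train_fraction > 0, train_fraction < 1)
  if (is.null(variable_map)) {
    variable_map <- list(poverty = "poverty",
                         unemployment = "unemployment_change",
                         income = "median_income",
                         no_insurance = "no_insurance",
                         public_private_ratio = "public_private_ratio",
                         transport_cost = "transport_cost",
                         vacancy = "vacancy")
  }
  structure(list(input = input, generator = generator,
                 model_labels = model_labels, model_specs = model_specs,
                 repeats = as.integer(repeats),
                 train_fraction = train_fraction,
                 pca_threshold = pca_threshold,
                 pdp_predictors = pdp_predictors,
                 pdp_top_k = as.integer(pdp_top_k),
                 pdp_band_B = as.integer(pdp_band_B),
                 variable_map = variable_map, scenarios = scenarios,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

validate_run_config <- function(config, table) {
  preds <- predictor_names(table)
  vm_cols <- unlist(config$variable_map)
  scen <- config$scenarios
  if (is.null(scen)) {
    # default suite adapts: scenarios whose mapped columns are absent are
    # dropped; explicitly supplied scenarios are validated strictly below
    vm <- config$variable_map[vm_cols %in% preds]
    scen <- if (length(vm)) default_scenarios(vm, n_draws = config$n_draws)
            else list()
  }
  scen_vars <- unique(unlist(lapply(scen, function(s) names(s$directions))))
  unknown <- setdiff(scen_vars, preds)
  if (length(unknown))
    stop("validation error: scenario variable(s) not in the table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!identical(config$pdp_predictors, "auto")) {
    unknown <- setdiff(config$pdp_predictors, preds)
    if (length(unknown))
      stop("validation error: PDP predictor(s) not in the table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  scen
}

#' Run the full pipeline
#'
#' Stages: (1) load or generate the community table; (2) PCA-reduce the
#' pre-clinical block; (3) repeated-holdout comparison of the model
#' library and best-model selection; (4) full-data refit, importance
#' ranking and PDPs with bands; (5) per-group distribution fitting and
#' the scenario suite with hypothesis adjudication; (6) artifacts + JSON
#' manifest. Fails fast with a stage-tagged error; artifacts written
#' before the failure are retained.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list of in-memory artifacts: `table`,
#'   `reduction`, `cv_report`, `best_spec`, `best_fit`, `importance`,
#'   `pdps`, `verdicts`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    el <- proc.time()[["elapsed"]] - t0
    stage_log(stage, "done (%.1fs elapsed)", el)
  }

  # 1. data
  truth <- NULL
  if (is.null(config$input)) {
    gen <- generate_communities(config$generator)
    table <- gen$table
    truth <- gen$truth
    stage_log("data", "generated %d communities in %d groups (SNR %.2f)",
              n_communities(table), length(unique(group_labels(table))),
              truth$snr)
  } else {
    table <- load_feature_table(config$input$csv, config$input$meta)
    stage_log("data", "loaded %d communities from %s",
              n_communities(table), config$input$csv)
  }
  scen_specs <- validate_run_config(config, table)
  tick("data")

  # 2. pre-clinical reduction
  reduction <- NULL
  if (!is.null(config$pca_threshold) &&
      length(predictor_names(table, "preclinical")) >= 2) {
    red <- reduce_preclinical(table, config$pca_threshold)
    table <- red$table
    reduction <- red$reduction
    stage_log("reduce", "%d pre-clinical columns -> %d components (%.1f%%)",
              length(reduction$source_columns), reduction$n_components,
              100 * reduction$variance_explained[reduction$n_components])
    write_pca_loadings(reduction, out("pca_loadings.csv"))
  }
  tick("reduce")

  # 3. selection
  specs <- config$model_specs %||% default_model_specs(seed = config$seed)
  if (is.null(config$model_specs) && !is.null(config$model_labels)) {
    labels <- vapply(specs, `[[`, character(1), "label")
    missing_lb <- setdiff(config$model_labels, labels)
    if (length(missing_lb))
      stop("validation error: unknown model label(s): ",
           paste(missing_lb, collapse = ", "), call. = FALSE)
    specs <- specs[labels %in% config$model_labels]
  }
  plans <- make_splits(n_communities(table), repeats = config$repeats,
                       seed = derive_seed(config$seed, "splits"),
                       train_fraction = config$train_fraction)
  report <- run_cv(table, specs, plans)
  write_cv_report(report, out("cv_report.csv"), out("cv_detail.json"))
  best_spec <- select_best(report)
  stage_log("select", "best model: %s (mean out-of-sample RMSE %.4g)",
            best_spec$label,
            report$summary$mean_rmse_out[report$summary$model ==
                                           best_spec$label])
  tick("select")

  # 4. interpretation
  best_fit <- fit_model(best_spec, table)
  importance <- rank_variables(best_fit)
  write_csv_precise(importance, out("importance.csv"))
  pdp_vars <- if (identical(config$pdp_predictors, "auto")) {
    utils::head(importance$predictor, config$pdp_top_k)
  } else config$pdp_predictors
  pdps <- lapply(pdp_vars, function(v) {
    p <- pdp_band(best_fit, table, v, B = config$pdp_band_B)
    write_pdp(p, out(sprintf("pdp_%s.csv", v)))
    p
  })
  names(pdps) <- pdp_vars
  tick("interpret")

  # 5. scenarios
  verdicts <- list()
  if (length(scen_specs)) {
    scen_vars <- unique(unlist(lapply(scen_specs,
                                      function(s) names(s$directions))))
    fits <- fit_group_distributions(table, scen_vars)
    for (s in scen_specs) {
      res <- run_scenario(best_fit, table, s, fits,
                          master_seed = config$seed)
      v <- adjudicate(res, s)
      write_scenario_result(v, out(sprintf("scenario_%s.csv", s$id)))
      verdicts[[s$id]] <- v
      stage_log("scenario", "%s: mean dK %+.4g -> %s (%d/%d groups)",
                s$id, v$national_mean_delta_K, v$classification,
                v$n_supporting, v$n_groups)
    }
    national <- lapply(verdicts, function(v)
      list(expected = v$expected,
           national_mean_delta_K = v$national_mean_delta_K,
           classification = v$classification,
           hypothesis_supported = v$hypothesis_supported,
           n_supporting = v$n_supporting, n_groups = v$n_groups,
           nonconforming_groups = as.list(v$nonconforming_groups)))
    jsonlite::write_json(national, out("national_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  tick("scenario")

  # 6. manifest
  manifest <- list(
    package_version = as.character(utils::packageVersion("scenpred")),
    config_hash = config_hash(unclass(config)),
    seed = config$seed,
    n_communities = n_communities(table),
    n_groups = length(unique(group_labels(table))),
    models_compared = vapply(report$specs, `[[`, character(1), "label"),
    best_model = best_spec$label,
    scenarios = names(verdicts),
    artifacts = basename(list.files(config$output_dir))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(table = table, truth = truth, reduction = reduction,
                 cv_report = report, best_spec = best_spec,
                 best_fit = best_fit, importance = importance, pdps = pdps,
                 verdicts = verdicts, manifest = manifest,
                 output_dir = config$output_dir))
}

#' Write a human-readable run summary
#'
#' Markdown report: the model-comparison table, top importances, PDP
#' tables and per-hypothesis national verdicts with nonconforming
#' groups. Sections for artifacts that are absent are omitted; failed CV
#' cells are marked, not fatal.
#'
#' @param artifacts the list returned by [run_pipeline()].
#' @param path output Markdown path.
#' @return `path`, invisibly.
#' @export
write_report <- function(artifacts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...), file = con)
  md_table <- function(df, digits = 4) {
    fmt_cell <- function(x) {
      if (is.numeric(x)) formatC(x, digits = digits, format = "g")
      else as.character(x)
    }
    body <- vapply(seq_len(nrow(df)), function(i)
      paste0("| ", paste(vapply(df[i, ], fmt_cell, character(1)),
                         collapse = " | "), " |"), character(1))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      body)
  }

  w("# Community mental-health scenario analysis: run summary")
  w("")
  w("- best model: **%s**", artifacts$best_spec$label)
  w("- communities: %d in %d groups", n_communities(artifacts$table),
    length(unique(group_labels(artifacts$table))))
  if (!is.null(artifacts$reduction))
    w("- pre-clinical reduction: %d columns -> %d components (%.1f%% variance)",
      length(artifacts$reduction$source_columns),
      artifacts$reduction$n_components,
      100 * artifacts$reduction$variance_explained[
        artifacts$reduction$n_components])
  w("")
  w("## Model comparison (repeated 80-20 holdout)")
  w("")
  tab <- cv_table(artifacts$cv_report)
  failed <- artifacts$cv_report$cells[!is.na(artifacts$cv_report$cells$error), ]
  writeLines(md_table(tab), con)
  if (nrow(failed))
    w("\n%d model x repeat cells failed and were skipped (e.g. %s).",
      nrow(failed), failed$error[1])
  w("")
  w("## Variable importance (top 10)")
  w("")
  writeLines(md_table(utils::head(artifacts$importance, 10)), con)
  if (length(artifacts$pdps)) {
    w("")
    w("## Partial dependence")
    for (nm in names(artifacts$pdps)) {
      p <- artifacts$pdps[[nm]]
      w("")
      w("### %s (band: %s)", nm, attr(p, "band"))
      w("")
      writeLines(md_table(as.data.frame(p)), con)
    }
  }
  if (length(artifacts$verdicts)) {
    w("")
    w("## Scenario hypotheses")
    w("")
    vt <- do.call(rbind, lapply(artifacts$verdicts, function(v)
      data.frame(hypothesis = v$id, expected = v$expected,
                 mean_delta_K = v$national_mean_delta_K,
                 classification = v$classification,
                 supported = v$hypothesis_supported,
                 conforming = sprintf("%d/%d", v$n_supporting, v$n_groups))))
    writeLines(md_table(vt), con)
    for (v in artifacts$verdicts) {
      if (length(v$nonconforming_groups))
        w("\n- %s nonconforming groups: %s", v$id,
          paste(v$nonconforming_groups, collapse = ", "))
    }
  }
  invisible(path)
}
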