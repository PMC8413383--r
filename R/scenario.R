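# Scenario-based sensitivity analysis.
#
# For each group (state), the perturbable predictors get per-group fitted
# distributions.  Base-case values are sampled from the *unperturbed*
# fitted distributions; scenario values come from the same distributions
# with their means shifted by the hypothesis's sign map (in SD units),
# coupled through common random numbers (shared uniforms pushed through
# both quantile functions) so a zero shift gives exactly zero change.
# Substituting the sampled values into copies of the group's rows (all
# other columns untouched) and predicting with the selected model yields
#
#   K_base,  K_scenario,  Delta K = K_scenario - K_base,
#   Delta kappa = Delta K / K_base * 100%.
#
# A hypothesis is supported in a group when the sign of Delta K matches
# the expected direction; nationally the scenario is classified
# worst-case when the mean Delta K over groups is positive, best-case
# otherwise.

#' Specify a perturbation scenario
#'
#' @param id scenario/hypothesis identifier (e.g. `"H1"`).
#' @param directions named numeric vector: shift in SD units per
#'   perturbed predictor (usually `+1` or `-1`; several variables may be
#'   perturbed jointly, as in the economic scenarios).
#' @param expected expected effect on the response: `"increase"` or
#'   `"decrease"`.
#' @param description free-text statement of the hypothesis.
#' @param n_draws resample size per group (default 1000).
#' @param seed optional seed; defaults to a seed derived from `id` at run
#'   time.
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(id, directions, expected = c("increase", "decrease"),
                          description = NULL, n_draws = 1000L, seed = NULL) {
  expected <- match.arg(expected)
  stopifnot(is.numeric(directions), length(directions) >= 1,
            !is.null(names(directions)), all(nzchar(names(directions))))
  structure(list(id = id, directions = directions, expected = expected,
                 description = description %||% id,
                 n_draws = as.integer(n_draws), seed = seed),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario_spec %s (expect %s in K): %s\n", x$id, x$expected,
              paste(sprintf("%s %+g sd", names(x$directions), x$directions),
                    collapse = ", ")))
  invisible(x)
}

#' The ten standard built-environment hypotheses
#'
#' Encodes the H1-H10 structure: joint economic degradation/improvement
#' (poverty and unemployment move together, income opposes them), health
#' insurance unavailability, public-vs-private insurance access, travel
#' cost and housing vacancy, each perturbed by one SD in both directions.
#' The sign map is built from `variable_map`, so the convention for any
#' variable (e.g. a change-in-unemployment-rate column) can be adjusted
#' by the caller rather than being hard-coded.
#'
#' @param variable_map named list mapping the conceptual variables
#'   `poverty`, `unemployment`, `income`, `no_insurance`,
#'   `public_private_ratio`, `transport_cost`, `vacancy` to column names.
#'   Entries may be omitted; scenarios whose variables are absent are
#'   dropped.
#' @param n_draws resample size per group for every scenario.
#' @return named list of [scenario_spec()] objects (`H1` ... `H10`).
#' @export
default_scenarios <- function(variable_map, n_draws = 1000L) {
  vm <- variable_map
  dir_of <- function(...) {
    d <- c(...)
    keep <- names(d) %in% names(vm)
    d <- d[keep]
    stats::setNames(as.numeric(d), unlist(vm[names(d)]))
  }
  defs <- list(
    H1 = list(dir_of(poverty = +1, unemployment = +1, income = -1),
              "increase",
              "economic degradation degrades community mental health"),
    H2 = list(dir_of(poverty = -1, unemployment = -1, income = +1),
              "decrease",
              "economic improvement improves community mental health"),
    H3 = list(dir_of(no_insurance = -1), "decrease",
              "fewer uninsured families improves community mental health"),
    H4 = list(dir_of(no_insurance = +1), "increase",
              "more uninsured families degrades community mental health"),
    H5 = list(dir_of(public_private_ratio = -1), "increase",
              "less access to public insurance degrades community mental health"),
    H6 = list(dir_of(public_private_ratio = +1), "decrease",
              "more access to public insurance improves community mental health"),
    H7 = list(dir_of(transport_cost = -1), "decrease",
              "cheaper travel improves community mental health"),
    H8 = list(dir_of(transport_cost = +1), "increase",
              "costlier travel degrades community mental health"),
    H9 = list(dir_of(vacancy = -1), "decrease",
              "decreasing vacancy improves community mental health"),
    H10 = list(dir_of(vacancy = +1), "increase",
               "increasing vacancy degrades community mental health")
  )
  defs <- Filter(function(d) length(d[[1]]) > 0, defs)
  out <- lapply(names(defs), function(id) {
    scenario_spec(id, defs[[id]][[1]], defs[[id]][[2]],
                  description = defs[[id]][[3]], n_draws = n_draws)
  })
  stats::setNames(out, names(defs))
}

#' Fit per-group distributions for a set of predictors
#'
#' Runs [select_family()] for every (group, variable) pair. Groups with
#' fewer than 8 communities cannot support the chi-squared GOF; they fall
#' back to a method-of-moments normal fit with `NA` GOF fields (warned
#' once).
#'
#' @param table a [feature_table()].
#' @param variables predictor names to fit.
#' @param candidates candidate family set.
#' @param bins equiprobable bin target for the GOF.
#' @return nested list `fits[[group]][[variable]]` of `distribution_fit`.
#' @export
fit_group_distributions <- function(table, variables,
                                    candidates = DIST_FAMILIES, bins = 10L) {
  stopifnot(all(variables %in% predictor_names(table)))
  grp <- group_labels(table)
  small <- character(0)
  fits <- lapply(unique(grp), function(g) {
    rows <- grp == g
    stats::setNames(lapply(variables, function(v) {
      x <- table$data[[v]][rows]
      if (length(x) >= 8) {
        select_family(x, candidates = candidates, bins = bins,
                      group = g, variable = v)
      } else {
        small <<- union(small, g)
        m <- mean(x)
        normal_moment_fit(mean = m, sd = sqrt(mean((x - m)^2)),
                          n = length(x), group = g, variable = v)
      }
    }), variables)
  })
  if (length(small))
    warning("group(s) with fewer than 8 communities use a normal ",
            "method-of-moments fallback (no GOF): ",
            paste(small, collapse = ", "), call. = FALSE)
  stats::setNames(fits, unique(grp))
}

#' Run one perturbation scenario
#'
#' See the module description above for the sampling scheme. Variables
#' with declared bounds in the table metadata are clipped to those bounds
#' after sampling; clip rates are reported per group.
#'
#' @param model a `scenpred_fit` trained on the table's predictors.
#' @param table a [feature_table()].
#' @param spec a [scenario_spec()].
#' @param fits per-group distribution fits from
#'   [fit_group_distributions()] covering every perturbed variable.
#' @param master_seed seed used (with the scenario id and group label)
#'   to derive per-group draw seeds when `spec$seed` is `NULL`.
#' @return a `scenario_result`: data.frame with one row per group
#'   (`group`, `n_communities`, `K_base`, `K_scenario`, `delta_K`,
#'   `delta_kappa`, `clip_rate`) and attributes `id`, `expected`,
#'   `national_mean_delta_K`, `classification`.
#' @export
run_scenario <- function(model, table, spec, fits, master_seed = 1L) {
  stopifnot(inherits(model, "scenpred_fit"),
            inherits(table, "feature_table"),
            inherits(spec, "scenario_spec"))
  vars <- names(spec$directions)
  missing_vars <- setdiff(vars, model$feature_names)
  if (length(missing_vars))
    stop("scenario '", spec$id, "' perturbs unknown predictor(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  grp <- group_labels(table)
  groups <- unique(grp)
  X <- predictor_matrix(table)
  base_seed <- spec$seed %||% derive_seed(master_seed, "scenario", spec$id)

  rows_out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    ridx <- which(grp == g)
    if (!length(ridx)) {
      warning("group '", g, "' has no rows; skipped", call. = FALSE)
      next
    }
    gfits <- fits[[g]]
    if (is.null(gfits) || !all(vars %in% names(gfits)))
      stop("no distribution fit for group '", g, "' / variable(s) ",
           paste(setdiff(vars, names(gfits)), collapse = ", "),
           call. = FALSE)

    nd <- spec$n_draws
    U <- with_seed(derive_seed(base_seed, "draws", g),
                   matrix(stats::runif(nd * length(vars)), nd,
                          length(vars), dimnames = list(NULL, vars)))
    clipped <- 0L
    total <- 0L
    base_vals <- scen_vals <- matrix(NA_real_, nd, length(vars),
                                     dimnames = list(NULL, vars))
    for (v in vars) {
      f0 <- gfits[[v]]
      f1 <- tryCatch(perturb(f0, spec$directions[[v]]), error = function(e) e)
      if (inherits(f1, "error")) {
        # the shifted mean left the fitted family's support (e.g. a -1 sd
        # shift of a lognormal whose SD exceeds its mean): fall back to a
        # normal distribution with the same moments for BOTH the base and
        # the scenario draws, so the coupling stays comparable
        warning("scenario '", spec$id, "', group '", g, "': ", v,
                " falls back to the normal family (",
                conditionMessage(f1), ")", call. = FALSE)
        f0 <- normal_moment_fit(f0)
        f1 <- perturb(f0, spec$directions[[v]])
      }
      bv <- dist_quantile(f0, U[, v])
      sv <- dist_quantile(f1, U[, v])
      b <- column_bounds(table, v)
      if (!is.null(b)) {
        nclip <- sum(bv < b[1] | bv > b[2]) + sum(sv < b[1] | sv > b[2])
        clipped <- clipped + nclip
        total <- total + 2L * nd
        bv <- pmin(pmax(bv, b[1]), b[2])
        sv <- pmin(pmax(sv, b[1]), b[2])
      }
      base_vals[, v] <- bv
      scen_vals[, v] <- sv
    }

    # stack the group's rows once per draw; substitute jointly
    ng <- length(ridx)
    Xg <- X[rep(ridx, times = nd), , drop = FALSE]
    drow <- rep(seq_len(nd), each = ng)
    Xs <- Xg
    for (v in vars) {
      Xg[, v] <- base_vals[drow, v]
      Xs[, v] <- scen_vals[drow, v]
    }
    K_base <- mean(predict(model, Xg))
    K_scen <- mean(predict(model, Xs))
    dK <- K_scen - K_base
    rows_out[[gi]] <- data.frame(
      group = g, n_communities = ng, K_base = K_base, K_scenario = K_scen,
      delta_K = dK, delta_kappa = dK / K_base * 100,
      clip_rate = if (total > 0) clipped / total else 0)
  }
  res <- do.call(rbind, rows_out[!vapply(rows_out, is.null, logical(1))])
  rownames(res) <- NULL
  mean_dK <- mean(res$delta_K)
  structure(res,
            id = spec$id, expected = spec$expected,
            description = spec$description,
            national_mean_delta_K = mean_dK,
            classification = if (mean_dK > 0) "worst-case" else "best-case",
            class = c("scenario_result", "data.frame"))
}

#' Adjudicate a scenario against its hypothesis
#'
#' Per group, the hypothesis is supported when the sign of `delta_K`
#' matches the expected direction; nationally the scenario is worst-case
#' iff the mean `delta_K` over groups is positive. Nonconforming groups
#' (sign opposite to expectation) are listed.
#'
#' @param result a `scenario_result` from [run_scenario()].
#' @param spec the matching [scenario_spec()].
#' @return a `scenario_verdict`: list with `id`, `expected`,
#'   `classification`, `national_mean_delta_K`, `hypothesis_supported`
#'   (national sign matches expectation), `n_supporting`,
#'   `nonconforming_groups`, and `per_group` (the result with a
#'   `supported` column appended).
#' @export
adjudicate <- function(result, spec) {
  stopifnot(inherits(result, "scenario_result"),
            inherits(spec, "scenario_spec"))
  sign_needed <- if (spec$expected == "increase") 1 else -1
  per_group <- as.data.frame(result)
  per_group$supported <- sign(per_group$delta_K) == sign_needed
  mean_dK <- attr(result, "national_mean_delta_K")
  structure(list(
    id = spec$id,
    description = spec$description,
    expected = spec$expected,
    national_mean_delta_K = mean_dK,
    classification = attr(result, "classification"),
    hypothesis_supported = sign(mean_dK) == sign_needed,
    n_supporting = sum(per_group$supported),
    n_groups = nrow(per_group),
    nonconforming_groups = per_group$group[!per_group$supported],
    per_group = per_group
  ), class = "scenario_verdict")
}

#' @export
print.scenario_verdict <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$id, x$description))
  cat(sprintf("  national mean delta K = %+.4g -> %s; hypothesis %s (%d/%d groups conform)\n",
              x$national_mean_delta_K, x$classification,
              if (x$hypothesis_supported) "supported" else "not supported",
              x$n_supporting, x$n_groups))
  if (length(x$nonconforming_groups))
    cat("  nonconforming:", paste(x$nonconforming_groups, collapse = ", "),
        "\n")
  invisible(x)
}

#' Write a scenario result as tidy CSV
#'
#' Columns: hypothesis, group, K_base, K_scenario, delta_K, delta_kappa,
#' supported.
#'
#' @param verdict a `scenario_verdict`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scenario_result <- function(verdict, path) {
  stopifnot(inherits(verdict, "scenario_verdict"))
  df <- data.frame(hypothesis = verdict$id, verdict$per_group)
  write_csv_precise(df[, c("hypothesis", "group", "K_base", "K_scenario",
                           "delta_K", "delta_kappa", "supported")], path)
}
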