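# Synthetic multilevel community data with known ground truth.
#
# Emulates the structure the framework assumes: ~50 groups (states) of
# metropolitan communities; per-group predictor distributions with
# group-level parameters drawn from configured ranges; a block of
# correlated pre-clinical variables generated from a small number of
# latent factors; and a known response surface (linear, smooth saturating
# and latent-factor terms) plus additive Gaussian noise, centered near a
# 13% outcome so magnitudes read like the real application.  The ground
# truth (per-group parameters, surface terms, signal-to-noise ratio,
# closed-form partial effects for additive terms) is returned alongside
# the table so every downstream stage can be tested against it.

#' Describe one synthetic predictor
#'
#' @param name column name.
#' @param category predictor category tag.
#' @param family marginal family per group: `"normal"`, `"gamma"`,
#'   `"lognormal"` or `"uniform"`.
#' @param mean_range range the group-level means are drawn from.
#' @param sd_range range the group-level SDs are drawn from.
#' @param bounds optional clip bounds recorded in the column metadata.
#' @param units free-text units.
#' @return a `predictor_spec` list.
#' @export
predictor_spec <- function(name, category, family, mean_range, sd_range,
                           bounds = NULL, units = NULL) {
  family <- match.arg(family, c("normal", "gamma", "lognormal", "uniform"))
  stopifnot(length(mean_range) == 2, length(sd_range) == 2,
            mean_range[1] <= mean_range[2], sd_range[1] <= sd_range[2],
            sd_range[1] > 0)
  if (family %in% c("gamma", "lognormal") && mean_range[1] <= 0)
    stop("config error: ", family, " family needs a positive mean range",
         call. = FALSE)
  structure(list(name = name, category = category, family = family,
                 mean_range = mean_range, sd_range = sd_range,
                 bounds = bounds, units = units),
            class = "predictor_spec")
}

default_predictor_specs <- function() {
  list(
    predictor_spec("poverty", "economic", "gamma", c(8, 25), c(3, 7),
                   bounds = c(0, 100), units = "% families below poverty"),
    predictor_spec("median_income", "economic", "normal",
                   c(45000, 90000), c(8000, 18000), units = "USD/yr"),
    predictor_spec("unemployment_change", "economic", "normal",
                   c(-2, 4), c(1, 3), units = "% change"),
    predictor_spec("no_insurance", "insurance_availability", "gamma",
                   c(8, 20), c(2.5, 6), bounds = c(0, 100),
                   units = "% families uninsured"),
    predictor_spec("public_private_ratio", "insurance_type", "lognormal",
                   c(0.5, 1.3), c(0.15, 0.45), units = "ratio"),
    predictor_spec("transport_cost", "transport_cost", "normal",
                   c(16, 30), c(3.5, 7), bounds = c(0, 100),
                   units = "% of income"),
    predictor_spec("vacancy", "housing_vacancy", "lognormal",
                   c(250, 900), c(120, 400), units = "vacant properties"),
    predictor_spec("smoking", "behavioral", "normal", c(14, 26),
                   c(2.5, 5), bounds = c(0, 100), units = "% adults smoking")
  )
}

default_surface <- function() {
  list(intercept = 11,
       terms = list(
         list(type = "linear", var = "poverty", coef = 0.08),
         list(type = "linear", var = "median_income", coef = -2e-05),
         list(type = "linear", var = "unemployment_change", coef = 0.06),
         list(type = "linear", var = "no_insurance", coef = 0.06),
         list(type = "linear", var = "public_private_ratio", coef = -0.35),
         list(type = "linear", var = "transport_cost", coef = 0.012),
         list(type = "saturating", var = "vacancy", scale = 0.9,
              rate = 400),
         list(type = "linear", var = "smoking", coef = 0.02),
         list(type = "factor", index = 1L, coef = 0.25)
       ))
}

#' Configure the synthetic community generator
#'
#' Defaults mirror a national metropolitan study: 50 state-like groups of
#' 5-50 communities, eight tagged built-environment/behavioral
#' predictors, a 12-column pre-clinical block driven by 3 latent factors,
#' and a response surface centered near K = 13%.
#'
#' @param n_groups number of groups (states).
#' @param communities_per_group a single count or a `c(lo, hi)` range
#'   sampled per group.
#' @param predictors list of [predictor_spec()].
#' @param preclinical `NULL` for none, or a list with `n_vars`,
#'   `n_factors`, `noise_sd`, `loading_range`.
#' @param surface list with `intercept` and `terms` (see
#'   [true_pdp()] for the supported term types).
#' @param noise_sd SD of the additive Gaussian response noise.
#' @param seed master seed.
#' @return a `generator_config`.
#' @export
generator_config <- function(n_groups = 50L,
                             communities_per_group = c(5L, 50L),
                             predictors = default_predictor_specs(),
                             preclinical = list(n_vars = 12L, n_factors = 3L,
                                                noise_sd = 0.3,
                                                loading_range = c(0.6, 1)),
                             surface = default_surface(),
                             noise_sd = 0.45,
                             seed = 1L) {
  stopifnot(n_groups >= 1, length(communities_per_group) %in% 1:2,
            all(communities_per_group >= 1), noise_sd >= 0)
  if (length(communities_per_group) == 2 &&
      communities_per_group[1] > communities_per_group[2])
    stop("config error: communities_per_group range inverted", call. = FALSE)
  pred_names <- vapply(predictors, `[[`, character(1), "name")
  surf_vars <- unlist(lapply(surface$terms, function(t)
    if (t$type %in% c("linear", "saturating")) t$var else NULL))
  unknown <- setdiff(surf_vars, pred_names)
  if (length(unknown))
    stop("config error: surface references unknown predictor(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(preclinical)) {
    stopifnot(preclinical$n_vars >= 1, preclinical$n_factors >= 1,
              preclinical$n_factors <= preclinical$n_vars)
  } else {
    # without a pre-clinical block there are no latent factors to load on
    surface$terms <- Filter(function(t) t$type != "factor", surface$terms)
  }
  structure(list(n_groups = as.integer(n_groups),
                 communities_per_group = as.integer(communities_per_group),
                 predictors = predictors, preclinical = preclinical,
                 surface = surface, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

surface_term_fun <- function(term) {
  switch(term$type,
    linear = function(x) term$coef * x,
    saturating = function(x) term$scale * (1 - exp(-x / term$rate)),
    factor = function(x) term$coef * x,
    stop("config error: unknown surface term type '", term$type, "'",
         call. = FALSE))
}

# draw n values from `family` with the given (mean, sd), method-of-moments
# parameterization
sample_family <- function(family, n, m, s) {
  switch(family,
    normal = stats::rnorm(n, m, s),
    gamma = stats::rgamma(n, shape = m^2 / s^2, scale = s^2 / m),
    lognormal = {
      sdlog2 <- log(1 + s^2 / m^2)
      stats::rlnorm(n, log(m) - sdlog2 / 2, sqrt(sdlog2))
    },
    uniform = stats::runif(n, m - sqrt(3) * s, m + sqrt(3) * s))
}

#' Generate a synthetic community dataset
#'
#' @param config a [generator_config()].
#' @return list with `table` (a validated [feature_table()]) and `truth`
#'   (group-level parameters, surface term functions, per-term
#'   contribution matrix, latent factors, realized signal-to-noise ratio
#'   and clip rates).
#' @export
generate_communities <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    cpg <- config$communities_per_group
    sizes <- if (length(cpg) == 1) rep(cpg, config$n_groups)
             else sample(cpg[1]:cpg[2], config$n_groups, replace = TRUE)
    groups <- sprintf("G%02d", seq_len(config$n_groups))
    grp <- rep(groups, times = sizes)
    n <- length(grp)

    # group-level parameters, then community draws
    data <- data.frame(state = grp, stringsAsFactors = FALSE)
    gp_rows <- list()
    clip_counts <- c(clipped = 0, total = 0)
    for (ps in config$predictors) {
      gm <- stats::runif(config$n_groups, ps$mean_range[1], ps$mean_range[2])
      gs <- stats::runif(config$n_groups, ps$sd_range[1], ps$sd_range[2])
      x <- numeric(n)
      for (gi in seq_len(config$n_groups)) {
        idx <- which(grp == groups[gi])
        x[idx] <- sample_family(ps$family, length(idx), gm[gi], gs[gi])
      }
      if (!is.null(ps$bounds)) {
        nclip <- sum(x < ps$bounds[1] | x > ps$bounds[2])
        clip_counts <- clip_counts + c(nclip, n)
        x <- pmin(pmax(x, ps$bounds[1]), ps$bounds[2])
      }
      data[[ps$name]] <- x
      gp_rows[[ps$name]] <- data.frame(group = groups, variable = ps$name,
                                       family = ps$family, mean = gm,
                                       sd = gs)
    }

    # correlated pre-clinical block from latent factors
    factors <- NULL
    loadings <- NULL
    if (!is.null(config$preclinical)) {
      pc <- config$preclinical
      factors <- matrix(stats::rnorm(n * pc$n_factors), n, pc$n_factors)
      loadings <- matrix(
        stats::runif(pc$n_vars * pc$n_factors, pc$loading_range[1],
                     pc$loading_range[2]) *
          sample(c(-1, 1), pc$n_vars * pc$n_factors, replace = TRUE),
        pc$n_vars, pc$n_factors)
      block <- factors %*% t(loadings) +
        pc$noise_sd * matrix(stats::rnorm(n * pc$n_vars), n, pc$n_vars)
      colnames(block) <- sprintf("preclinical_%02d", seq_len(pc$n_vars))
      data <- cbind(data, as.data.frame(block))
    }

    # response surface
    terms <- config$surface$terms
    contrib <- matrix(0, n, length(terms))
    for (ti in seq_along(terms)) {
      tm <- terms[[ti]]
      fun <- surface_term_fun(tm)
      xin <- if (tm$type == "factor") {
        if (is.null(factors)) stop("config error: factor term without a ",
                                   "pre-clinical block", call. = FALSE)
        factors[, tm$index]
      } else data[[tm$var]]
      contrib[, ti] <- fun(xin)
    }
    signal <- config$surface$intercept + rowSums(contrib)
    eps <- stats::rnorm(n, 0, config$noise_sd)
    K <- signal + eps
    k_clip <- sum(K < 0 | K > 100)
    K <- pmin(pmax(K, 0), 100)
    data <- cbind(data.frame(K = K), data)

    meta <- c(
      list(column_meta("K", "response", units = "% adults, >14 bad days"),
           column_meta("state", "group_key")),
      lapply(config$predictors, function(ps)
        column_meta(ps$name, "predictor", category = ps$category,
                    units = ps$units, bounds = ps$bounds)),
      if (!is.null(config$preclinical))
        lapply(sprintf("preclinical_%02d",
                       seq_len(config$preclinical$n_vars)),
               function(nm) column_meta(nm, "predictor",
                                        category = "preclinical"))
    )

    snr <- if (config$noise_sd > 0)
      stats::var(signal) / config$noise_sd^2 else Inf

    truth <- list(
      config = config,
      group_params = do.call(rbind, gp_rows),
      surface = config$surface,
      term_vars = vapply(terms, function(t)
        if (t$type == "factor") sprintf(".factor%d", t$index) else t$var,
        character(1)),
      contrib = contrib,
      factors = factors,
      loadings = loadings,
      signal = signal,
      snr = snr,
      response_clip_rate = k_clip / n,
      predictor_clip_rate = if (clip_counts["total"] > 0)
        unname(clip_counts["clipped"] / clip_counts["total"]) else 0
    )
    list(table = feature_table(data, meta), truth = truth)
  })
}

#' Closed-form partial dependence from the generator's ground truth
#'
#' Available for predictors whose contribution to the surface is additive
#' (`linear` or `saturating` terms): the true partial effect at grid
#' value `v` is the term evaluated at `v` plus the mean of all other
#' contributions (intercept included) over the generated rows. Asking
#' about a predictor tied to the latent pre-clinical factors (or any
#' non-additive construction) is an error: no closed form is declared.
#'
#' @param truth the `truth` element from [generate_communities()].
#' @param predictor predictor name.
#' @param grid numeric grid.
#' @return numeric vector of true partial effects on the grid.
#' @export
true_pdp <- function(truth, predictor, grid) {
  terms <- truth$surface$terms
  hit <- which(truth$term_vars == predictor)
  if (startsWith(predictor, "preclinical_"))
    stop("no closed-form partial effect: '", predictor,
         "' loads on latent factors", call. = FALSE)
  base <- truth$surface$intercept +
    if (length(hit)) mean(rowSums(truth$contrib[, -hit, drop = FALSE]))
    else mean(rowSums(truth$contrib))
  if (!length(hit)) return(rep(base, length(grid)))
  fun <- surface_term_fun(terms[[hit]])
  base + fun(grid)
}

#' Write a generated dataset as CSV + metadata + truth summary
#'
#' Emits `<prefix>.csv`, `<prefix>_meta.yaml` (consumable by
#' [load_feature_table()]) and `<prefix>_truth.json` (group-level
#' parameters, surface description, SNR).
#'
#' @param gen result of [generate_communities()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of the paths written.
#' @export
write_generated <- function(gen, dir, prefix = "communities") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, ".csv"))
  metaf <- file.path(dir, paste0(prefix, "_meta.yaml"))
  truthf <- file.path(dir, paste0(prefix, "_truth.json"))
  write_feature_table(gen$table, csv)
  write_column_meta(gen$table$meta, metaf)
  tr <- gen$truth
  jsonlite::write_json(
    list(group_params = tr$group_params,
         surface = tr$surface,
         snr = tr$snr,
         response_clip_rate = tr$response_clip_rate,
         predictor_clip_rate = tr$predictor_clip_rate,
         seed = tr$config$seed),
    truthf, dataframe = "rows", auto_unbox = TRUE, digits = NA,
    force = TRUE)
  c(csv = csv, meta = metaf, truth = truthf)
}
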