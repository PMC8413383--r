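# Model registry: every learner sits behind one fit/predict contract so the
# selection harness, the PDP engine and the scenario engine never care
# which family produced a prediction.

MODEL_FAMILIES <- c("glm", "ridge", "lasso", "gam", "mars",
                    "random_forest", "gbm", "bart")

# documented per-family default hyperparameters
family_defaults <- function(family) {
  switch(family,
    glm = list(),
    ridge = list(lambda = NULL),   # NULL -> 10-fold cv.glmnet lambda.min
    lasso = list(lambda = NULL),
    gam = list(k = 10),            # max basis dim per smooth, GCV penalty
    mars = list(degree = 1L, penalty = NULL, max_terms = 21L,
                max_knots = 15L),  # penalty NULL -> 2 if degree==1 else 3
    random_forest = list(ntree = 500L, mtry = NULL),
    gbm = list(nrounds = 200L, eta = 0.05, max_depth = 3L,
               min_child_weight = 5, subsample = 1),
    bart = list(ntree = 50L, ndpost = 500L, nskip = 250L, k = 2,
                alpha = 0.95, beta = 2, nu = 3, q = 0.9),
    stop("configuration error: unknown model family '", family, "'",
         call. = FALSE)
  )
}

#' Specify a regression learner
#'
#' @param family one of `"glm"`, `"ridge"`, `"lasso"`, `"gam"`, `"mars"`,
#'   `"random_forest"`, `"gbm"` (gradient boosting), `"bart"` (Bayesian
#'   additive regression trees).
#' @param params named list of family-specific hyperparameters; unknown
#'   names are rejected. Unset parameters take the documented defaults.
#' @param seed integer seed for stochastic families; every fit is
#'   deterministic given `(spec, data, seed)`.
#' @param label display label (defaults to the family plus any
#'   non-default parameters).
#' @return a `model_spec` object.
#' @export
model_spec <- function(family, params = list(), seed = 1L, label = NULL) {
  if (!family %in% MODEL_FAMILIES)
    stop("configuration error: unknown model family '", family,
         "'; registered: ", paste(MODEL_FAMILIES, collapse = ", "),
         call. = FALSE)
  defaults <- family_defaults(family)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("configuration error: unknown hyperparameter(s) for ", family,
         ": ", paste(unknown, collapse = ", "), call. = FALSE)
  full <- utils::modifyList(defaults, params)
  if (is.null(label)) {
    shown <- params[!vapply(params, is.null, logical(1))]
    label <- if (length(shown)) {
      sprintf("%s[%s]", family,
              paste(names(shown), unlist(shown), sep = "=", collapse = ";"))
    } else family
  }
  structure(list(family = family, params = full, seed = as.integer(seed),
                 label = label),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$label, "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Registered model families
#' @return character vector of family names in registry order.
#' @export
registered_families <- function() MODEL_FAMILIES

#' The default model library
#'
#' The standard comparison suite: generalized linear model, ridge, lasso,
#' generalized additive model, four adaptive-regression-splines variants
#' (degree 1; degree 2; degree 3; degree 3 with penalty 2), random forest,
#' gradient boosting and Bayesian additive regression trees.
#'
#' @param seed master seed; each member gets a derived child seed.
#' @return list of [model_spec()] objects.
#' @export
default_model_specs <- function(seed = 1L) {
  mk <- function(family, params = list(), label = NULL)
    model_spec(family, params, seed = derive_seed(seed, "fit", family,
                                                  label %||% ""),
               label = label)
  list(
    mk("glm"),
    mk("ridge"),
    mk("lasso"),
    mk("gam"),
    mk("mars", list(degree = 1L), "mars"),
    mk("mars", list(degree = 2L), "mars[degree=2]"),
    mk("mars", list(degree = 3L), "mars[degree=3]"),
    mk("mars", list(degree = 3L, penalty = 2), "mars[degree=3;penalty=2]"),
    mk("random_forest"),
    mk("gbm"),
    mk("bart")
  )
}
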