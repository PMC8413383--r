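# Uniform fit/predict/importance contract over the model registry.
#
# fit_model() returns a `scenpred_fit` whose predict() accepts any matrix
# or data.frame carrying the training predictor columns.  A constant
# response is handled uniformly (every family degenerates to the constant
# predictor), so downstream contracts hold for all families.

#' Fit a registered learner to a feature table
#'
#' @param spec a [model_spec()].
#' @param table a [feature_table()].
#' @param train_index optional integer row subset to train on (default:
#'   all rows).
#' @return a `scenpred_fit` with methods [predict.scenpred_fit()],
#'   [model_importance()] and, for the `bart` family,
#'   [predict_draws()].
#' @export
fit_model <- function(spec, table, train_index = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(table, "feature_table"))
  X <- predictor_matrix(table)
  y <- response_values(table)
  if (is.null(train_index)) train_index <- seq_len(nrow(X))
  if (!length(train_index)) stop("train_index must be non-empty", call. = FALSE)
  Xt <- X[train_index, , drop = FALSE]
  yt <- y[train_index]

  fit <- if (stats::sd(yt) < 1e-12) {
    list(kind = "constant", value = yt[1])
  } else {
    with_seed(spec$seed, switch(spec$family,
      glm = fit_glm(Xt, yt),
      ridge = fit_glmnet(Xt, yt, alpha = 0, spec$params),
      lasso = fit_glmnet(Xt, yt, alpha = 1, spec$params),
      gam = fit_gam(Xt, yt, spec$params),
      mars = fit_mars(Xt, yt, spec$params),
      random_forest = fit_rf(Xt, yt, spec$params),
      gbm = fit_gbm(Xt, yt, spec$params),
      bart = fit_bart(Xt, yt, spec$params)
    ))
  }

  structure(list(spec = spec, family = spec$family,
                 feature_names = colnames(X),
                 fit = fit, train_x = Xt, train_y = yt),
            class = "scenpred_fit")
}

#' @export
print.scenpred_fit <- function(x, ...) {
  cat(sprintf("scenpred_fit: %s on %d rows x %d predictors\n",
              x$spec$label, nrow(x$train_x), ncol(x$train_x)))
  invisible(x)
}

# coerce prediction input to the training column layout; schema errors here
as_model_matrix <- function(object, newdata) {
  if (inherits(newdata, "feature_table")) newdata <- newdata$data
  if (is.data.frame(newdata)) newdata <- as.matrix(
    newdata[, intersect(names(newdata), object$feature_names), drop = FALSE])
  if (!is.matrix(newdata)) stop("newdata must be a matrix, data.frame or feature_table",
                                call. = FALSE)
  missing_cols <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing_cols))
    stop("schema error: newdata lacks training column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  newdata[, object$feature_names, drop = FALSE]
}

#' Predict from a fitted learner
#'
#' @param object a `scenpred_fit`.
#' @param newdata matrix, data.frame or `feature_table` carrying the
#'   training predictor columns (extra columns ignored; missing columns
#'   are a schema error).
#' @param ... unused.
#' @return numeric vector of predictions, one per row.
#' @export
predict.scenpred_fit <- function(object, newdata, ...) {
  Xn <- as_model_matrix(object, newdata)
  fit <- object$fit
  out <- switch(fit$kind,
    constant = rep(fit$value, nrow(Xn)),
    glm = drop(cbind(1, Xn) %*% fit$coef),
    glmnet = drop(stats::predict(fit$object, newx = Xn, s = fit$lambda)),
    gam = as.numeric(mgcv::predict.gam(fit$object,
                                       newdata = as.data.frame(Xn))),
    mars = mars_predict(fit$object, Xn),
    rf = as.numeric(stats::predict(fit$object, newdata = Xn)),
    gbm = as.numeric(stats::predict(fit$object,
                                    xgboost::xgb.DMatrix(Xn, nthread = 1))),
    bart = bart_predict_mean(fit$object, Xn),
    stop("internal: unknown fit kind ", fit$kind)
  )
  if (any(!is.finite(out)))
    stop("non-finite prediction from family ", object$family, call. = FALSE)
  unname(out)
}

#' Posterior/ensemble predictive draws
#'
#' For the `bart` family, returns the kept posterior draws of the
#' regression function evaluated at `newdata` (draws in rows). Other
#' families return `NULL` — callers fall back to bootstrap uncertainty.
#'
#' @param object a `scenpred_fit`.
#' @param newdata prediction input as in [predict.scenpred_fit()].
#' @return a `ndpost x nrow(newdata)` matrix, or `NULL`.
#' @export
predict_draws <- function(object, newdata) {
  stopifnot(inherits(object, "scenpred_fit"))
  if (object$fit$kind != "bart") return(NULL)
  bart_predict_draws(object$fit$object, as_model_matrix(object, newdata))
}

# ---- per-family fits -------------------------------------------------------

fit_glm <- function(X, y) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste("`.y` ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  obj <- stats::lm(fml, data = df)
  cf <- stats::coef(obj)
  if (anyNA(cf)) {
    stop("fit error: singular design; collinear column(s): ",
         paste(gsub("`", "", names(cf)[is.na(cf)]), collapse = ", "),
         call. = FALSE)
  }
  list(kind = "glm", coef = unname(cf))
}

fit_glmnet <- function(X, y, alpha, params) {
  lambda <- params$lambda
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = 10,
                            standardize = TRUE)
    lambda <- cv$lambda.min
    obj <- cv$glmnet.fit
  } else {
    # supply a descending path ending at the requested lambda: glmnet's
    # coordinate descent is far more accurate warm-started down a path
    lam_max <- max(max(abs(crossprod(scale(X), scale(y)))) / length(y),
                   lambda * 10, 1e-6)
    path <- sort(unique(c(exp(seq(log(lam_max), log(lambda + 1e-12),
                                  length.out = 30)), lambda)),
                 decreasing = TRUE)
    obj <- glmnet::glmnet(X, y, alpha = alpha, lambda = path,
                          standardize = TRUE, thresh = 1e-12)
  }
  list(kind = "glmnet", object = obj, lambda = lambda)
}

fit_gam <- function(X, y, params) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  kmax <- params$k %||% 10
  terms <- vapply(colnames(X), function(nm) {
    u <- length(unique(X[, nm]))
    if (u >= 4) sprintf("s(`%s`, k = %d)", nm, max(3L, min(kmax, u - 1L)))
    else sprintf("`%s`", nm)
  }, character(1))
  fml <- stats::as.formula(paste("`.y` ~", paste(terms, collapse = " + ")))
  obj <- mgcv::gam(fml, data = df, method = "GCV.Cp")
  list(kind = "gam", object = obj)
}

fit_rf <- function(X, y, params) {
  mtry <- params$mtry %||% max(1L, floor(ncol(X) / 3))
  obj <- randomForest::randomForest(x = X, y = y, ntree = params$ntree,
                                    mtry = mtry, importance = FALSE)
  list(kind = "rf", object = obj)
}

fit_gbm <- function(X, y, params) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  obj <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = params$eta,
                  max_depth = params$max_depth,
                  min_child_weight = params$min_child_weight,
                  subsample = params$subsample, nthread = 1,
                  base_score = mean(y)),
    data = dtrain, nrounds = params$nrounds, verbose = 0)
  list(kind = "gbm", object = obj)
}

fit_mars <- function(X, y, params) {
  degree <- params$degree
  penalty <- fit_mars_penalty(degree, params$penalty)
  obj <- mars_fit(X, y, degree = degree, penalty = penalty,
                  max_terms = params$max_terms, max_knots = params$max_knots)
  list(kind = "mars", object = obj)
}

fit_bart <- function(X, y, params) {
  obj <- bart_fit(X, y, ntree = params$ntree, ndpost = params$ndpost,
                  nskip = params$nskip, k = params$k, alpha = params$alpha,
                  beta = params$beta, nu = params$nu, q = params$q)
  list(kind = "bart", object = obj)
}

# ---- importance ------------------------------------------------------------

#' Per-predictor importance scores
#'
#' Tree ensembles report native importance: split-improvement totals for
#' random forest and gradient boosting, and the split inclusion
#' proportion (the fraction of splitting rules using each predictor,
#' averaged over posterior draws) for `bart`. Families without a native
#' measure fall back, with a warning, to permutation importance — the
#' mean increase in training RMSE when a column is shuffled. Scores are
#' nonnegative and normalized to sum to 1; ties and ordering are stable.
#'
#' @param object a `scenpred_fit`.
#' @param n_perm shuffles per column for the permutation fallback.
#' @return named numeric vector, in training-column order, summing to 1.
#' @export
model_importance <- function(object, n_perm = 10) {
  stopifnot(inherits(object, "scenpred_fit"))
  p <- length(object$feature_names)
  raw <- switch(object$fit$kind,
    rf = {
      imp <- randomForest::importance(object$fit$object, type = 2)
      stats::setNames(imp[, 1], rownames(imp))
    },
    gbm = {
      tab <- xgboost::xgb.importance(model = object$fit$object)
      stats::setNames(tab$Gain, tab$Feature)
    },
    bart = bart_inclusion_proportions(object$fit$object),
    {
      if (object$fit$kind != "constant")
        warning("family '", object$family,
                "' has no native importance; using permutation importance",
                call. = FALSE)
      permutation_importance(object, n_perm)
    }
  )
  out <- stats::setNames(numeric(p), object$feature_names)
  raw <- raw[names(raw) %in% object$feature_names]
  out[names(raw)] <- pmax(as.numeric(raw), 0)
  if (sum(out) > 0) out <- out / sum(out)
  else out[] <- 1 / p  # constant model: no predictor informative
  out
}

permutation_importance <- function(object, n_perm = 10) {
  X <- object$train_x
  y <- object$train_y
  base_rmse <- sqrt(mean((y - predict(object, X))^2))
  with_seed(derive_seed(object$spec$seed, "perm_importance"), {
    vapply(seq_len(ncol(X)), function(j) {
      d <- vapply(seq_len(n_perm), function(b) {
        Xp <- X
        Xp[, j] <- X[sample(nrow(X)), j]
        sqrt(mean((y - predict(object, Xp))^2)) - base_rmse
      }, numeric(1))
      max(mean(d), 0)
    }, numeric(1)) -> imp
    stats::setNames(imp, colnames(X))
  })
}
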