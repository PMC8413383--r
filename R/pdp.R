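# Partial dependence and variable-importance ranking.
#
# The partial dependence of the response on predictor x_j is the model's
# prediction averaged over the empirical distribution of the remaining
# predictors:  p_j(v) = (1/n) * sum_i f(v, x_{-j,i}).  Uncertainty bands
# come from posterior draws when the model exposes them (bart) and from a
# nonparametric bootstrap over the background rows otherwise.

default_pdp_grid <- function(x, n_grid = 25L) {
  g <- unique(stats::quantile(x, probs = seq(0.01, 0.99,
                                             length.out = n_grid),
                              type = 7, names = FALSE))
  sort(g)
}

#' Compute a partial dependence curve
#'
#' For each grid value `v`, predictor `predictor` is forced to `v` in
#' every background row (all other columns untouched) and predictions are
#' averaged.
#'
#' @param model a `scenpred_fit`.
#' @param table the [feature_table()] providing background rows.
#' @param predictor name of a model predictor.
#' @param grid ordered numeric grid; default: 25 equally spaced quantiles
#'   between the 1st and 99th percentile of the observed predictor.
#'   Values beyond the observed range are allowed but flagged as
#'   extrapolation.
#' @param n_grid grid size when `grid` is `NULL`.
#' @return a `pdp_result`: data.frame with columns `grid`, `effect`,
#'   `lower`, `upper` and attributes `predictor`, `n_background`.
#' @export
compute_pdp <- function(model, table, predictor, grid = NULL, n_grid = 25L) {
  stopifnot(inherits(model, "scenpred_fit"),
            inherits(table, "feature_table"))
  if (!predictor %in% model$feature_names)
    stop("'", predictor, "' is not a model predictor", call. = FALSE)
  X <- predictor_matrix(table)
  xobs <- X[, predictor]
  if (is.null(grid)) grid <- default_pdp_grid(xobs, n_grid)
  grid <- as.numeric(grid)
  if (!length(grid)) stop("empty PDP grid", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("PDP grid must be strictly increasing", call. = FALSE)
  if (min(grid) < min(xobs) || max(grid) > max(xobs))
    warning("PDP grid extends beyond the observed range of '", predictor,
            "' (extrapolation)", call. = FALSE)

  effect <- vapply(grid, function(v) {
    Xv <- X
    Xv[, predictor] <- v
    mean(predict(model, Xv))
  }, numeric(1))

  structure(data.frame(grid = grid, effect = effect, lower = NA_real_,
                       upper = NA_real_),
            predictor = predictor, n_background = nrow(X),
            band = "none", class = c("pdp_result", "data.frame"))
}

#' Partial dependence with 95% bands
#'
#' Bands describe the uncertainty of the *averaged* partial effect, not a
#' prediction interval. For `bart` fits the band is the 2.5/97.5
#' percentile of the draw-wise partial dependence over the kept posterior
#' draws; for all other families it is a nonparametric bootstrap over the
#' background rows (`B` resamples of the averaging set; `B = 1`
#' degenerates to the point estimate).
#'
#' @inheritParams compute_pdp
#' @param level band coverage (default 0.95).
#' @param B bootstrap resamples for non-Bayesian fits (default 200).
#' @param seed seed for the bootstrap resampling (default: derived from
#'   the model's seed).
#' @return a `pdp_result` with `lower`/`upper` filled.
#' @export
pdp_band <- function(model, table, predictor, grid = NULL, level = 0.95,
                     B = 200L, n_grid = 25L, seed = NULL) {
  res <- compute_pdp(model, table, predictor, grid = grid, n_grid = n_grid)
  grid <- res$grid
  X <- predictor_matrix(table)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  if (model$fit$kind == "bart") {
    draw_pdp <- vapply(grid, function(v) {
      Xv <- X
      Xv[, predictor] <- v
      rowMeans(predict_draws(model, Xv))
    }, numeric(model$fit$object$ndpost))
    qs <- apply(draw_pdp, 2, stats::quantile, probs = probs, names = FALSE)
    res$lower <- qs[1, ]
    res$upper <- qs[2, ]
    attr(res, "band") <- "posterior"
    return(res)
  }

  if (B <= 1L) {
    res$lower <- res$effect
    res$upper <- res$effect
    attr(res, "band") <- "bootstrap(B=1, degenerate)"
    return(res)
  }
  # per-row prediction matrix, then cheap bootstrap over rows
  P <- vapply(grid, function(v) {
    Xv <- X
    Xv[, predictor] <- v
    predict(model, Xv)
  }, numeric(nrow(X)))
  seed <- seed %||% derive_seed(model$spec$seed, "pdp_boot", predictor)
  boot <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      idx <- sample.int(nrow(X), replace = TRUE)
      colMeans(P[idx, , drop = FALSE])
    }, numeric(length(grid))))
  })
  qs <- apply(boot, 2, stats::quantile, probs = probs, names = FALSE)
  res$lower <- qs[1, ]
  res$upper <- qs[2, ]
  attr(res, "band") <- sprintf("bootstrap(B=%d)", B)
  res
}

#' Write a PDP curve as CSV
#' @param pdp a `pdp_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdp <- function(pdp, path) {
  write_csv_precise(as.data.frame(pdp), path)
}

#' Plot a partial dependence curve
#'
#' Base-graphics rendering of the averaged effect with its band.
#'
#' @param x a `pdp_result`.
#' @param ... passed to [plot()].
#' @export
plot.pdp_result <- function(x, ...) {
  pred <- attr(x, "predictor")
  ylim <- range(c(x$effect, x$lower, x$upper), na.rm = TRUE)
  plot(x$grid, x$effect, type = "l", lwd = 2, xlab = pred,
       ylab = "partial effect on K", ylim = ylim, ...)
  if (!all(is.na(x$lower))) {
    graphics::lines(x$grid, x$lower, lty = 2, col = "blue")
    graphics::lines(x$grid, x$upper, lty = 2, col = "blue")
  }
  invisible(x)
}

#' Rank predictors by importance
#'
#' Descending stable sort of [model_importance()] scores; ties keep
#' training column order.
#'
#' @param model a `scenpred_fit`.
#' @param n_perm shuffles for the permutation fallback.
#' @return data.frame with columns `predictor`, `score`, `rank`.
#' @export
rank_variables <- function(model, n_perm = 10) {
  sc <- model_importance(model, n_perm = n_perm)
  ord <- order(-sc)  # stable: ties keep column order
  data.frame(predictor = names(sc)[ord], score = unname(sc[ord]),
             rank = seq_along(sc))
}
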