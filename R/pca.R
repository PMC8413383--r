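# PCA reduction of correlated pre-clinical covariates.
#
# Community-level pre-clinical health variables (obesity, diabetes,
# hypertension prevalence and the like) are strongly collinear.  Rather
# than dropping variables, they are replaced by the smallest number of
# principal components whose cumulative explained variance reaches a
# configurable threshold.  Columns are standardized (zero mean, unit
# variance) first: the variables carry mixed units, so correlation-matrix
# PCA is the defensible default.

#' Replace pre-clinical columns by principal components
#'
#' Runs PCA on the standardized `"preclinical"`-category predictors and
#' replaces them with the smallest set of leading components whose
#' cumulative explained variance is at least `variance_threshold`. All
#' other columns are left untouched.
#'
#' @param ft a [feature_table()].
#' @param variance_threshold cumulative explained-variance fraction to
#'   retain (default 0.92).
#' @return a list with elements `table` (the reduced `feature_table`) and
#'   `reduction` (a `pca_reduction` with loadings, centers/scales and the
#'   explained-variance profile), or `reduction = NULL` when fewer than
#'   two pre-clinical columns exist (the table is returned unchanged with
#'   a warning).
#' @export
reduce_preclinical <- function(ft, variance_threshold = 0.92) {
  stopifnot(inherits(ft, "feature_table"),
            is.numeric(variance_threshold),
            variance_threshold > 0, variance_threshold <= 1)
  pre <- predictor_names(ft, category = "preclinical")
  if (length(pre) < 2L) {
    warning("fewer than 2 pre-clinical columns; table returned unchanged",
            call. = FALSE)
    return(list(table = ft, reduction = NULL))
  }

  X <- as.matrix(ft$data[, pre, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) scl[scl == 0] <- 1  # constant column: center only
  Z <- scale(X, center = ctr, scale = scl)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)

  ev <- pc$sdev^2
  cumvar <- cumsum(ev) / sum(ev)
  k <- which(cumvar >= variance_threshold - 1e-12)[1]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  comp_names <- paste0("preclinical_pc", seq_len(k))
  colnames(scores) <- comp_names

  keep <- setdiff(names(ft$data), pre)
  data <- cbind(ft$data[, keep, drop = FALSE], as.data.frame(scores))
  meta <- Filter(function(m) !(m$name %in% pre), ft$meta)
  meta <- c(meta, lapply(comp_names, function(nm) {
    column_meta(nm, role = "predictor", category = "preclinical",
                units = "standardized score")
  }))

  reduction <- structure(
    list(source_columns = pre, center = ctr, scale = scl,
         loadings = pc$rotation, n_components = k,
         variance_explained = cumvar, eigenvalues = ev,
         threshold = variance_threshold, component_names = comp_names),
    class = "pca_reduction")

  list(table = feature_table(data, meta), reduction = reduction)
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat(sprintf(
    "pca_reduction: %d pre-clinical columns -> %d components (%.1f%% var, threshold %.0f%%)\n",
    length(x$source_columns), x$n_components,
    100 * x$variance_explained[x$n_components], 100 * x$threshold))
  invisible(x)
}

#' Write PCA loadings as CSV
#'
#' @param reduction a `pca_reduction` from [reduce_preclinical()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pca_loadings <- function(reduction, path) {
  stopifnot(inherits(reduction, "pca_reduction"))
  df <- data.frame(variable = rownames(reduction$loadings),
                   reduction$loadings, check.names = FALSE)
  write_csv_precise(df, path)
}

#' Apply a stored PCA reduction to new data
#'
#' Projects the pre-clinical columns of `newdata` onto the stored loadings
#' using the training centers and scales.
#'
#' @param reduction a `pca_reduction`.
#' @param newdata data.frame containing the source columns.
#' @return matrix of retained component scores.
#' @export
project_preclinical <- function(reduction, newdata) {
  X <- as.matrix(newdata[, reduction$source_columns, drop = FALSE])
  Z <- scale(X, center = reduction$center, scale = reduction$scale)
  scores <- Z %*% reduction$loadings[, seq_len(reduction$n_components),
                                     drop = FALSE]
  colnames(scores) <- reduction$component_names
  scores
}
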