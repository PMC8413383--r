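# Fixtures built in code: small grouped tables with known response
# surfaces, used across the unit tests.

# build column metadata for a plain data.frame: response K, group `state`,
# everything else a predictor (category "economic" unless overridden)
mk_meta <- function(df, categories = list(), bounds = list()) {
  lapply(names(df), function(nm) {
    if (nm == "K") {
      column_meta("K", "response", bounds = bounds[["K"]])
    } else if (nm == "state") {
      column_meta("state", "group_key")
    } else {
      column_meta(nm, "predictor",
                  category = categories[[nm]] %||% "economic",
                  bounds = bounds[[nm]])
    }
  })
}

mk_table <- function(df, ...) feature_table(df, mk_meta(df, ...))

# grouped table with K = intercept + beta * x (+ optional noise), x normal
# per group with distinct group means/sds
linear_table <- function(n_per_group = 30, groups = c("A", "B", "C"),
                         beta = 0.1, intercept = 8, noise = 0, seed = 1,
                         mu = NULL, sigma = NULL) {
  with_seed(seed, {
    mu <- mu %||% seq(10, 30, length.out = length(groups))
    sigma <- sigma %||% seq(2, 4, length.out = length(groups))
    df <- do.call(rbind, lapply(seq_along(groups), function(g) {
      x <- stats::rnorm(n_per_group, mu[g], sigma[g])
      data.frame(state = groups[g], x = x)
    }))
    df$K <- intercept + beta * df$x + stats::rnorm(nrow(df), 0, noise)
    mk_table(df[, c("K", "state", "x")])
  })
}

# Friedman's benchmark surface on 5 uniform predictors (+ optional spares)
friedman_data <- function(n, noise = 1, seed = 1, p = 5) {
  with_seed(seed, {
    X <- matrix(stats::runif(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    y <- 10 * sin(pi * X[, 1] * X[, 2]) + 20 * (X[, 3] - 0.5)^2 +
      10 * X[, 4] + 5 * X[, 5] + stats::rnorm(n, 0, noise)
    list(X = X, y = y)
  })
}

friedman_table <- function(n, noise = 1, seed = 1) {
  fd <- friedman_data(n, noise, seed)
  df <- data.frame(K = (fd$y - min(fd$y)) / (max(fd$y) - min(fd$y)) * 20 + 5,
                   state = rep(c("A", "B"), length.out = n), fd$X)
  mk_table(df)
}

# small spec variants so the stochastic families stay fast in tests
fast_spec <- function(family, seed = 1, ...) {
  params <- switch(family,
    random_forest = list(ntree = 150L),
    gbm = list(nrounds = 80L),
    bart = list(ntree = 20L, ndpost = 80L, nskip = 80L),
    list())
  model_spec(family, utils::modifyList(params, list(...)), seed = seed,
             label = family)
}
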