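# Per-group parametric distribution fitting for the scenario engine.
#
# Parameters are estimated by the method of moments using *population*
# moments (divide by n), the usual MoM convention: the fitted family's
# analytic mean and variance equal the sample's.  Family choice among the
# candidate set {normal, lognormal, gamma, exponential, uniform} is by the
# chi-squared goodness-of-fit statistic on equiprobable bins.
#
# The exponential family has a single parameter, so only the mean is
# matched (its SD necessarily equals its mean).

DIST_FAMILIES <- c("normal", "lognormal", "gamma", "exponential", "uniform")

dist_registry <- list(
  normal = list(
    npar = 2L,
    support = function(x) TRUE,
    mom = function(m, v) list(mean = m, sd = sqrt(v)),
    q = function(p, par) stats::qnorm(p, par$mean, par$sd),
    moments = function(par) c(mean = par$mean, var = par$sd^2),
    feasible = function(m, v) v >= 0
  ),
  lognormal = list(
    npar = 2L,
    support = function(x) all(x > 0),
    mom = function(m, v) {
      sdlog2 <- log(1 + v / m^2)
      list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
    },
    q = function(p, par) stats::qlnorm(p, par$meanlog, par$sdlog),
    moments = function(par) {
      mu <- exp(par$meanlog + par$sdlog^2 / 2)
      c(mean = mu, var = (exp(par$sdlog^2) - 1) * mu^2)
    },
    feasible = function(m, v) m > 0 && v > 0
  ),
  gamma = list(
    npar = 2L,
    support = function(x) all(x > 0),
    mom = function(m, v) list(shape = m^2 / v, scale = v / m),
    q = function(p, par) stats::qgamma(p, shape = par$shape,
                                       scale = par$scale),
    moments = function(par) c(mean = par$shape * par$scale,
                              var = par$shape * par$scale^2),
    feasible = function(m, v) m > 0 && v > 0
  ),
  exponential = list(
    npar = 1L,
    support = function(x) all(x >= 0),
    mom = function(m, v) list(rate = 1 / m),  # one moment: mean only
    q = function(p, par) stats::qexp(p, rate = par$rate),
    moments = function(par) c(mean = 1 / par$rate, var = 1 / par$rate^2),
    feasible = function(m, v) m > 0
  ),
  uniform = list(
    npar = 2L,
    support = function(x) TRUE,
    mom = function(m, v) list(min = m - sqrt(3 * v), max = m + sqrt(3 * v)),
    q = function(p, par) stats::qunif(p, par$min, par$max),
    moments = function(par) c(mean = (par$min + par$max) / 2,
                              var = (par$max - par$min)^2 / 12),
    feasible = function(m, v) v > 0
  )
)

#' Fit a parametric family by the method of moments
#'
#' Parameters solve the moment equations against the sample's population
#' moments (`mean(x)` and `mean((x - mean(x))^2)`). Goodness of fit is the
#' chi-squared statistic over equiprobable bins of the fitted
#' distribution: 10 bins by default, reduced until the expected count per
#' bin is at least 5, with degrees of freedom `bins - 1 - n_parameters`
#' (floored at 1).
#'
#' @param values numeric sample (at least 8 observations).
#' @param family one of `"normal"`, `"lognormal"`, `"gamma"`,
#'   `"exponential"`, `"uniform"`.
#' @param bins target number of equiprobable bins (default 10).
#' @param group,variable optional labels carried through to reports.
#' @return a `distribution_fit` with fields `family`, `parameters`,
#'   `mean`, `sd`, `gof_statistic`, `gof_pvalue`, `df`, `bins_used`, `n`.
#' @export
fit_distribution <- function(values, family, bins = 10L, group = NA_character_,
                             variable = NA_character_) {
  family <- match.arg(family, DIST_FAMILIES)
  reg <- dist_registry[[family]]
  values <- as.numeric(values)
  if (length(values) < 8)
    stop("need at least 8 observations to fit a distribution (got ",
         length(values), ")", call. = FALSE)
  if (!reg$support(values))
    stop("family skipped: values outside the support of the ", family,
         " family", call. = FALSE)
  m <- mean(values)
  v <- mean((values - m)^2)  # population moment
  if (!reg$feasible(m, v))
    stop("family skipped: moment equations infeasible for the ", family,
         " family (mean ", signif(m, 4), ", var ", signif(v, 4), ")",
         call. = FALSE)
  par <- reg$mom(m, v)

  n <- length(values)
  nb <- max(2L, min(as.integer(bins), floor(n / 5)))
  br <- reg$q(seq(0, 1, length.out = nb + 1), par)
  br[1] <- -Inf
  br[nb + 1] <- Inf
  if (any(diff(br) <= 0)) {
    gof <- Inf
    pval <- 0
    df <- 1L
  } else {
    obs <- as.numeric(table(cut(values, breaks = br, right = TRUE)))
    expd <- rep(n / nb, nb)
    gof <- sum((obs - expd)^2 / expd)
    df <- max(nb - 1L - reg$npar, 1L)
    pval <- stats::pchisq(gof, df, lower.tail = FALSE)
  }

  mom <- reg$moments(par)
  structure(list(family = family, parameters = par,
                 mean = unname(mom["mean"]), sd = sqrt(unname(mom["var"])),
                 gof_statistic = gof, gof_pvalue = pval, df = df,
                 bins_used = nb, n = n, group = group, variable = variable,
                 shift = 0),
            class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(sprintf("distribution_fit: %s(%s)  mean=%.4g sd=%.4g  chi2=%.3g (df=%d, p=%.3g) n=%d\n",
              x$family,
              paste(names(x$parameters), signif(unlist(x$parameters), 4),
                    sep = "=", collapse = ", "),
              x$mean, x$sd, x$gof_statistic, x$df, x$gof_pvalue, x$n))
  invisible(x)
}

#' Select the best-fitting family by chi-squared GOF
#'
#' Fits every feasible candidate and returns the one with the smallest
#' chi-squared statistic; infeasible candidates (support or moment
#' violations) are skipped with their reasons collected. Ties go to the
#' earlier candidate (logged).
#'
#' @param values numeric sample.
#' @param candidates families to try, in priority order.
#' @param bins target equiprobable bin count.
#' @param group,variable labels used in error messages and reports.
#' @return the winning `distribution_fit`; attribute `"skipped"` lists the
#'   infeasible candidates with reasons.
#' @export
select_family <- function(values, candidates = DIST_FAMILIES, bins = 10L,
                          group = NA_character_, variable = NA_character_) {
  fits <- list()
  skipped <- character(0)
  for (fam in candidates) {
    f <- tryCatch(fit_distribution(values, fam, bins = bins, group = group,
                                   variable = variable),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) skipped[fam] <- f else fits[[fam]] <- f
  }
  if (!length(fits))
    stop("no feasible candidate family for variable '", variable,
         "' in group '", group, "': ",
         paste(names(skipped), skipped, sep = ": ", collapse = "; "),
         call. = FALSE)
  stats_ <- vapply(fits, `[[`, numeric(1), "gof_statistic")
  best <- which(stats_ <= min(stats_) + 1e-12)
  if (length(best) > 1)
    stage_log("distfit", "GOF tie among {%s} for %s/%s; keeping '%s'",
              paste(names(fits)[best], collapse = ", "), group, variable,
              names(fits)[best[1]])
  out <- fits[[best[1]]]
  attr(out, "skipped") <- skipped
  out
}

#' Shift a fitted distribution's mean by a multiple of its SD
#'
#' Returns the same family re-solved from the pair
#' `(mean + shift * sd, sd^2)`: the mean moves, the variance is held
#' fixed (for the one-parameter exponential family only the mean can be
#' matched and the SD follows it). A shifted mean that leaves the
#' family's feasible region is an error suggesting the normal-family
#' fallback.
#'
#' @param fit a `distribution_fit`.
#' @param shift shift in SD units (e.g. `+1`, `-1`; `0` returns an
#'   identical distribution).
#' @return a new `distribution_fit` (GOF fields set to `NA`: the shifted
#'   distribution is a construction, not a fit to data).
#' @export
perturb <- function(fit, shift) {
  stopifnot(inherits(fit, "distribution_fit"), is.numeric(shift),
            length(shift) == 1L)
  if (shift == 0) return(fit)  # identity, bit-exact
  reg <- dist_registry[[fit$family]]
  new_mean <- fit$mean + shift * fit$sd
  new_var <- fit$sd^2
  if (!reg$feasible(new_mean, new_var))
    stop("shifted mean ", signif(new_mean, 4),
         " is outside the support of the ", fit$family,
         " family; fall back to the normal family for this variable",
         call. = FALSE)
  par <- reg$mom(new_mean, new_var)
  mom <- reg$moments(par)
  out <- fit
  out$parameters <- par
  out$mean <- unname(mom["mean"])
  out$sd <- sqrt(unname(mom["var"]))
  out$gof_statistic <- NA_real_
  out$gof_pvalue <- NA_real_
  out$shift <- fit$shift + shift
  out
}

# build a normal distribution_fit directly from moments (fallback path:
# small groups without a GOF, or shifts leaving a family's support)
normal_moment_fit <- function(fit = NULL, mean = fit$mean, sd = fit$sd,
                              n = fit$n %||% NA_integer_,
                              group = fit$group %||% NA_character_,
                              variable = fit$variable %||% NA_character_) {
  structure(list(family = "normal",
                 parameters = list(mean = mean, sd = sd),
                 mean = mean, sd = sd,
                 gof_statistic = NA_real_, gof_pvalue = NA_real_,
                 df = NA_integer_, bins_used = NA_integer_,
                 n = n, group = group, variable = variable, shift = 0),
            class = "distribution_fit")
}

#' Quantile function of a fitted distribution
#'
#' Used to couple base and scenario draws through common random numbers:
#' the same uniforms pushed through the base and the shifted quantile
#' functions.
#'
#' @param fit a `distribution_fit`.
#' @param p probabilities in `[0, 1]`.
#' @return quantiles.
#' @export
dist_quantile <- function(fit, p) {
  stopifnot(inherits(fit, "distribution_fit"))
  dist_registry[[fit$family]]$q(p, fit$parameters)
}
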