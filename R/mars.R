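# Multivariate adaptive regression splines.
#
# Classic two-stage procedure: a greedy forward pass that adds reflected
# pairs of hinge functions max(0, x - c) / max(0, c - x) (optionally in
# products with existing terms up to `degree`), then a backward pruning
# pass that deletes terms to minimize the generalized cross-validation
# (GCV) criterion
#
#   GCV = RSS/n / (1 - enp/n)^2,   enp = M + penalty * (M - 1) / 2
#
# with M basis functions. penalty = 2 is the usual additive-model charge,
# 3 the usual choice when interactions are allowed.

fit_mars_penalty <- function(degree, penalty) {
  penalty %||% (if (degree == 1L) 2 else 3)
}

mars_hinge <- function(x, cut, sign) {
  if (sign > 0) pmax(x - cut, 0) else pmax(cut - x, 0)
}

mars_basis_col <- function(X, comps) {
  col <- rep(1, nrow(X))
  for (cp in comps) col <- col * mars_hinge(X[, cp$var], cp$cut, cp$sign)
  col
}

mars_rss <- function(B, y) {
  fit <- stats::lm.fit(B, y)
  sum(fit$residuals^2)
}

mars_gcv <- function(rss, n, M, penalty) {
  enp <- M + penalty * (M - 1) / 2
  if (enp >= n) return(Inf)
  (rss / n) / (1 - enp / n)^2
}

mars_fit <- function(X, y, degree = 1L, penalty = 2, max_terms = 21L,
                     max_knots = 15L) {
  n <- nrow(X)
  p <- ncol(X)
  knots <- lapply(seq_len(p), function(j) {
    u <- sort(unique(X[, j]))
    if (length(u) <= 2) return(numeric(0))
    u <- u[-c(1, length(u))]  # boundary knots give a void side
    if (length(u) > max_knots)
      u <- unique(stats::quantile(u, probs = seq(0, 1, length.out = max_knots),
                                  type = 7, names = FALSE))
    u
  })

  terms <- list(list())  # intercept
  B <- matrix(1, n, 1)
  rss <- mars_rss(B, y)
  tol <- 1e-10 * max(rss, 1e-300)

  while (ncol(B) + 2 <= max_terms) {
    best <- NULL
    for (ti in seq_along(terms)) {
      parent <- terms[[ti]]
      if (length(parent) >= degree) next
      used <- vapply(parent, `[[`, numeric(1), "var")
      for (j in setdiff(seq_len(p), used)) {
        bt <- B[, ti]
        xj <- X[, j]
        for (cut in knots[[j]]) {
          b1 <- bt * pmax(xj - cut, 0)
          b2 <- bt * pmax(cut - xj, 0)
          cand_rss <- mars_rss(cbind(B, b1, b2), y)
          if (is.null(best) || cand_rss < best$rss - 1e-12) {
            best <- list(rss = cand_rss, parent = ti, var = j, cut = cut)
          }
        }
      }
    }
    if (is.null(best) || rss - best$rss < tol) break
    parent <- terms[[best$parent]]
    t1 <- c(parent, list(list(var = best$var, cut = best$cut, sign = 1)))
    t2 <- c(parent, list(list(var = best$var, cut = best$cut, sign = -1)))
    terms <- c(terms, list(t1), list(t2))
    B <- cbind(B, mars_basis_col(X, t1), mars_basis_col(X, t2))
    rss <- best$rss
    if (rss < tol) break
  }

  # backward pruning on GCV, keeping the best subset seen
  keep <- seq_along(terms)
  best_keep <- keep
  best_gcv <- mars_gcv(mars_rss(B[, keep, drop = FALSE], y), n,
                       length(keep), penalty)
  current <- keep
  while (length(current) > 1) {
    step_best <- NULL
    for (drop_i in current[-1]) {  # never the intercept
      sub <- setdiff(current, drop_i)
      g <- mars_gcv(mars_rss(B[, sub, drop = FALSE], y), n, length(sub),
                    penalty)
      if (is.null(step_best) || g < step_best$gcv) {
        step_best <- list(gcv = g, sub = sub)
      }
    }
    current <- step_best$sub
    if (step_best$gcv < best_gcv - 1e-12) {
      best_gcv <- step_best$gcv
      best_keep <- current
    }
  }

  Bk <- B[, best_keep, drop = FALSE]
  fit <- stats::lm.fit(Bk, y)
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  structure(list(terms = terms[best_keep], coef = unname(coef),
                 degree = degree, penalty = penalty, gcv = best_gcv,
                 feature_names = colnames(X)),
            class = "scenpred_mars")
}

mars_predict <- function(object, Xn) {
  B <- vapply(object$terms, function(tm) mars_basis_col(Xn, tm),
              numeric(nrow(Xn)))
  if (nrow(Xn) == 1L) B <- matrix(B, nrow = 1)
  drop(B %*% object$coef)
}
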