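# Bayesian additive regression trees: a minimal sum-of-trees sampler.
#
# The model is Y = sum_j g(X; T_j, M_j) + eps, eps ~ N(0, sigma^2), with m
# regression trees T_j whose leaf parameters M_j carry the fitted values.
# Priors follow the standard regularizing choices: a node at depth d
# splits with probability alpha * (1 + d)^-beta; leaf values are
# N(0, sigma_mu^2) with sigma_mu = 0.5 / (k * sqrt(m)) after the response
# is mapped to [-0.5, 0.5]; sigma^2 has a scaled-inverse-chi-squared prior
# calibrated so that a naive linear-model residual SD sits at the q-th
# prior quantile. Trees are updated one at a time by Metropolis-Hastings
# GROW/PRUNE proposals with the leaf values integrated out, then leaf
# values and sigma^2 are drawn from their conjugate full conditionals.

bart_loglik_leaf <- function(nl, sl, sigma2, sigma_mu2) {
  0.5 * log(sigma2 / (sigma2 + nl * sigma_mu2)) +
    sigma_mu2 * sl^2 / (2 * sigma2 * (sigma2 + nl * sigma_mu2))
}

bart_logprior_split <- function(depth, alpha, beta) {
  # log ratio: (split at depth d, both children terminal) vs (terminal at d)
  log(alpha) - beta * log1p(depth) +
    2 * log(1 - alpha * (2 + depth)^(-beta)) -
    log(1 - alpha * (1 + depth)^(-beta))
}

tree_new <- function() {
  list(var = NA_integer_, cut = NA_real_, left = NA_integer_,
       right = NA_integer_, parent = NA_integer_, depth = 0L,
       leaf = TRUE, mu = 0, active = TRUE)
}

# vars with at least one usable cutpoint for the rows in `idx`
tree_valid_vars <- function(X, idx, cuts) {
  ok <- integer(0)
  for (j in seq_along(cuts)) {
    if (!length(cuts[[j]])) next
    xr <- range(X[idx, j])
    if (any(cuts[[j]] >= xr[1] & cuts[[j]] < xr[2])) ok <- c(ok, j)
  }
  ok
}

tree_growable_leaves <- function(tr, assign, X, cuts) {
  leaves <- which(tr$leaf & tr$active)
  leaves[vapply(leaves, function(l) {
    idx <- which(assign == l)
    length(idx) >= 2 && length(tree_valid_vars(X, idx, cuts)) > 0
  }, logical(1))]
}

tree_nog_nodes <- function(tr) {
  internal <- which(!tr$leaf & tr$active)
  internal[vapply(internal, function(v) {
    tr$leaf[tr$left[v]] && tr$leaf[tr$right[v]]
  }, logical(1))]
}

tree_is_stump <- function(tr) tr$leaf[1] && sum(tr$active) == 1L

tree_add_node <- function(tr, parent) {
  free <- which(!tr$active)
  id <- if (length(free)) free[1] else length(tr$var) + 1L
  tr$var[id] <- NA_integer_; tr$cut[id] <- NA_real_
  tr$left[id] <- NA_integer_; tr$right[id] <- NA_integer_
  tr$parent[id] <- parent; tr$depth[id] <- tr$depth[parent] + 1L
  tr$leaf[id] <- TRUE; tr$mu[id] <- 0; tr$active[id] <- TRUE
  list(tr = tr, id = id)
}

# one MH structure step (grow or prune) for one tree; resid is the partial
# residual this tree must explain
bart_structure_step <- function(tr, assign, X, cuts, resid, sigma2,
                                sigma_mu2, alpha, beta) {
  stump <- tree_is_stump(tr)
  do_grow <- stump || stats::runif(1) < 0.5

  if (do_grow) {
    growable <- tree_growable_leaves(tr, assign, X, cuts)
    if (!length(growable)) return(list(tr = tr, assign = assign))
    b <- length(growable)
    leaf <- if (b == 1L) growable else growable[sample.int(b, 1)]
    idx <- which(assign == leaf)
    vars <- tree_valid_vars(X, idx, cuts)
    v <- if (length(vars) == 1L) vars else vars[sample.int(length(vars), 1)]
    xr <- range(X[idx, v])
    valid_cuts <- cuts[[v]][cuts[[v]] >= xr[1] & cuts[[v]] < xr[2]]
    cut <- if (length(valid_cuts) == 1L) valid_cuts
           else valid_cuts[sample.int(length(valid_cuts), 1)]

    left_rows <- idx[X[idx, v] <= cut]
    right_rows <- setdiff(idx, left_rows)
    sL <- sum(resid[left_rows]); sR <- sum(resid[right_rows])
    llr <- bart_loglik_leaf(length(left_rows), sL, sigma2, sigma_mu2) +
      bart_loglik_leaf(length(right_rows), sR, sigma2, sigma_mu2) -
      bart_loglik_leaf(length(idx), sL + sR, sigma2, sigma_mu2)
    lprior <- bart_logprior_split(tr$depth[leaf], alpha, beta)

    parent_was_nog <- !is.na(tr$parent[leaf]) && {
      pa <- tr$parent[leaf]
      sib <- if (tr$left[pa] == leaf) tr$right[pa] else tr$left[pa]
      tr$leaf[sib]
    }
    w2star <- length(tree_nog_nodes(tr)) + 1L - as.integer(parent_was_nog)
    pg <- if (stump) 1 else 0.5
    logA <- log(0.5) - log(pg) + log(b) - log(w2star) + lprior + llr

    if (log(stats::runif(1)) < logA) {
      res <- tree_add_node(tr, leaf); tr <- res$tr; lid <- res$id
      res <- tree_add_node(tr, leaf); tr <- res$tr; rid <- res$id
      tr$leaf[leaf] <- FALSE; tr$var[leaf] <- v; tr$cut[leaf] <- cut
      tr$left[leaf] <- lid; tr$right[leaf] <- rid
      assign[left_rows] <- lid
      assign[right_rows] <- rid
    }
    return(list(tr = tr, assign = assign))
  }

  # prune
  nog <- tree_nog_nodes(tr)
  if (!length(nog)) return(list(tr = tr, assign = assign))
  w2 <- length(nog)
  node <- if (w2 == 1L) nog else nog[sample.int(w2, 1)]
  lid <- tr$left[node]; rid <- tr$right[node]
  lrows <- which(assign == lid); rrows <- which(assign == rid)
  sL <- sum(resid[lrows]); sR <- sum(resid[rrows])
  llr <- bart_loglik_leaf(length(lrows), sL, sigma2, sigma_mu2) +
    bart_loglik_leaf(length(rrows), sR, sigma2, sigma_mu2) -
    bart_loglik_leaf(length(lrows) + length(rrows), sL + sR, sigma2,
                     sigma_mu2)
  lprior <- bart_logprior_split(tr$depth[node], alpha, beta)

  # growable-leaf count of the pruned tree
  tr2 <- tr
  tr2$leaf[node] <- TRUE; tr2$active[c(lid, rid)] <- FALSE
  tr2$var[node] <- NA_integer_
  assign2 <- assign
  assign2[c(lrows, rrows)] <- node
  bstar <- length(tree_growable_leaves(tr2, assign2, X, cuts))
  if (bstar == 0L) return(list(tr = tr, assign = assign))
  pgstar <- if (tree_is_stump(tr2)) 1 else 0.5
  logA <- log(pgstar) - log(0.5) - log(bstar) + log(w2) - lprior - llr

  if (log(stats::runif(1)) < logA) {
    tr2$left[node] <- NA_integer_; tr2$right[node] <- NA_integer_
    return(list(tr = tr2, assign = assign2))
  }
  list(tr = tr, assign = assign)
}

bart_draw_leaves <- function(tr, assign, resid, sigma2, sigma_mu2) {
  leaves <- which(tr$leaf & tr$active)
  for (l in leaves) {
    idx <- which(assign == l)
    nl <- length(idx)
    prec <- nl / sigma2 + 1 / sigma_mu2
    mean_l <- (sum(resid[idx]) / sigma2) / prec
    tr$mu[l] <- stats::rnorm(1, mean_l, sqrt(1 / prec))
  }
  tr
}

bart_fit <- function(X, y, ntree = 50L, ndpost = 500L, nskip = 250L,
                     k = 2, alpha = 0.95, beta = 2, nu = 3, q = 0.9,
                     numcut = 100L) {
  n <- nrow(X); p <- ncol(X)
  ymin <- min(y); ymax <- max(y)
  ys <- (y - ymin) / (ymax - ymin) - 0.5
  sigma_mu <- 0.5 / (k * sqrt(ntree))
  sigma_mu2 <- sigma_mu^2

  # sigma prior calibration from a crude linear fit
  sigma_hat <- if (p < n - 1) {
    r <- stats::lm.fit(cbind(1, X), ys)$residuals
    max(sqrt(sum(r^2) / max(n - p - 1, 1)), 1e-6)
  } else max(stats::sd(ys), 1e-6)
  lambda <- sigma_hat^2 * stats::qchisq(1 - q, nu) / nu

  cuts <- lapply(seq_len(p), function(j) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2) return(numeric(0))
    u <- u[-length(u)]
    if (length(u) > numcut)
      u <- unique(stats::quantile(u, probs = seq(0, 1, length.out = numcut),
                                  type = 7, names = FALSE))
    u
  })

  trees <- replicate(ntree, tree_new(), simplify = FALSE)
  assigns <- replicate(ntree, rep(1L, n), simplify = FALSE)
  tree_fits <- matrix(0, n, ntree)
  fit_total <- numeric(n)
  sigma2 <- sigma_hat^2

  kept_trees <- vector("list", ndpost)
  kept_sigma <- numeric(ndpost)
  kept_fit <- matrix(0, ndpost, n)
  incl_counts <- matrix(0, ndpost, p)

  niter <- nskip + ndpost
  for (it in seq_len(niter)) {
    for (j in seq_len(ntree)) {
      resid <- ys - (fit_total - tree_fits[, j])
      st <- bart_structure_step(trees[[j]], assigns[[j]], X, cuts, resid,
                                sigma2, sigma_mu2, alpha, beta)
      tr <- bart_draw_leaves(st$tr, st$assign, resid, sigma2, sigma_mu2)
      trees[[j]] <- tr
      assigns[[j]] <- st$assign
      newfit <- tr$mu[st$assign]
      fit_total <- fit_total + newfit - tree_fits[, j]
      tree_fits[, j] <- newfit
    }
    r <- ys - fit_total
    sigma2 <- (nu * lambda + sum(r^2)) / stats::rchisq(1, nu + n)

    d <- it - nskip
    if (d >= 1) {
      kept_trees[[d]] <- lapply(trees, function(tr) {
        list(var = tr$var, cut = tr$cut, left = tr$left, right = tr$right,
             leaf = tr$leaf, active = tr$active, mu = tr$mu)
      })
      kept_sigma[d] <- sqrt(sigma2)
      kept_fit[d, ] <- fit_total
      for (tr in trees) {
        splits <- tr$var[!tr$leaf & tr$active]
        if (length(splits))
          incl_counts[d, ] <- incl_counts[d, ] + tabulate(splits, p)
      }
    }
  }

  yscale <- ymax - ymin
  structure(list(
    kept_trees = kept_trees,
    sigma = kept_sigma * yscale,
    yhat_train_draws = (kept_fit + 0.5) * yscale + ymin,
    incl_counts = incl_counts,
    feature_names = colnames(X),
    ymin = ymin, ymax = ymax, ntree = ntree, ndpost = ndpost
  ), class = "scenpred_bart")
}

bart_route_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  stack <- list(list(node = 1L, idx = seq_len(nrow(X))))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (!length(top$idx)) next
    node <- top$node
    if (tree$leaf[node]) {
      out[top$idx] <- tree$mu[node]
    } else {
      le <- X[top$idx, tree$var[node]] <= tree$cut[node]
      stack[[length(stack) + 1L]] <- list(node = tree$left[node],
                                          idx = top$idx[le])
      stack[[length(stack) + 1L]] <- list(node = tree$right[node],
                                          idx = top$idx[!le])
    }
  }
  out
}

bart_predict_draws <- function(object, Xn) {
  ndpost <- object$ndpost
  yscale <- object$ymax - object$ymin
  out <- matrix(0, ndpost, nrow(Xn))
  for (d in seq_len(ndpost)) {
    fit <- numeric(nrow(Xn))
    for (tree in object$kept_trees[[d]]) {
      fit <- fit + bart_route_tree(tree, Xn)
    }
    out[d, ] <- (fit + 0.5) * yscale + object$ymin
  }
  out
}

bart_predict_mean <- function(object, Xn) {
  colMeans(bart_predict_draws(object, Xn))
}

bart_inclusion_proportions <- function(object) {
  tot <- rowSums(object$incl_counts)
  prop <- object$incl_counts / ifelse(tot > 0, tot, 1)
  stats::setNames(colMeans(prop), object$feature_names)
}
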