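# Full-covariance Gaussian mixture fitting by EM with k-means++
# initialisation. This is the clustering engine behind habitat definition;
# it is deliberately self-contained and deterministic under a seed.

# evaluate an expression with a temporarily seeded RNG, restoring the
# caller's random state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance from the nearest chosen centre
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        pick <- sample.int(n, 1)
      } else {
        pick <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

log_dmvnorm <- function(X, mu, Sigma) {
  d <- ncol(X)
  L <- chol(Sigma)
  Xc <- sweep(X, 2, mu)
  z <- backsolve(L, t(Xc), transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(L))) + colSums(z^2))
}

gmm_em_once <- function(X, k, tol, reg, max_iter) {
  n <- nrow(X); d <- ncol(X)
  centers <- kmeanspp_centers(X, k)
  assign0 <- if (k > 1) {
    km <- suppressWarnings(stats::kmeans(X, centers = centers,
                                         iter.max = 30))
    km$cluster
  } else rep(1L, n)
  weights <- numeric(k); means <- matrix(0, k, d)
  covs <- array(0, c(d, d, k))
  gvar <- diag(apply(X, 2, stats::var) + reg, d)
  for (j in seq_len(k)) {
    sel <- assign0 == j
    weights[j] <- max(sum(sel), 1) / n
    if (sum(sel) >= 2) {
      means[j, ] <- colMeans(X[sel, , drop = FALSE])
      covs[, , j] <- cov(X[sel, , drop = FALSE]) * (sum(sel) - 1) / sum(sel) +
        reg * diag(d)
    } else {
      means[j, ] <- centers[j, ]
      covs[, , j] <- gvar
    }
  }
  weights <- weights / sum(weights)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j)
      log(weights[j]) + log_dmvnorm(X, means[j, ], covs[, , j]), numeric(n))
    logd <- matrix(logd, n, k)
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    nj <- colSums(resp)
    if (any(nj < 1e-8)) stop("component collapsed")
    weights <- nj / n
    for (j in seq_len(k)) {
      means[j, ] <- colSums(resp[, j] * X) / nj[j]
      Xc <- sweep(X, 2, means[j, ])
      covs[, , j] <- crossprod(Xc * resp[, j], Xc) / nj[j] + reg * diag(d)
    }
  }
  list(weights = weights, means = means, covs = covs, loglik = ll)
}

# a fit is degenerate when a component has collapsed onto (near-)coincident
# points -- its covariance sits on the ridge floor -- or carries fewer
# effective observations than it has free parameters; such fits inflate the
# likelihood without describing real structure and are treated as EM failures
gmm_degenerate <- function(fit, n, reg) {
  d <- ncol(fit$means)
  for (j in seq_along(fit$weights)) {
    if (fit$weights[j] * n < d + 1) return(TRUE)
    ev <- eigen(fit$covs[, , j], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 10 * reg) return(TRUE)
  }
  FALSE
}

# best-of-restarts EM fit; deterministic under the caller-provided RNG state
gmm_em <- function(X, k, restarts = 5L, tol = 1e-4, reg = 1e-6,
                   max_iter = 100L) {
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- tryCatch(gmm_em_once(X, k, tol, reg, max_iter),
                    error = function(e) NULL)
    if (!is.null(fit) && gmm_degenerate(fit, nrow(X), reg))
      fit <- NULL
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best))
    stop(sprintf("EM failed for k = %d", k))
  best
}

gmm_log_resp <- function(weights, means, covs, X) {
  n <- nrow(X); k <- length(weights)
  logd <- vapply(seq_len(k), function(j)
    log(weights[j]) + log_dmvnorm(X, means[j, ], covs[, , j]), numeric(n))
  logd <- matrix(logd, n, k)
  mx <- apply(logd, 1, max)
  lse <- mx + log(rowSums(exp(logd - mx)))
  exp(logd - lse)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones.
#'
#' @param a,b integer/factor vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  nc2 <- choose2(length(a))
  expected <- sum_a * sum_b / nc2
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
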