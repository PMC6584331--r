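## Zero-truncated normal mixture model for pooled intra-hyphal particle
## speeds. Densities, random generation, and a maximum-likelihood EM fit.

#' Zero-truncated normal density
#'
#' Density of `N(mean, sd)` restricted to `x > 0`.
#'
#' @param x Quantiles (> 0 for nonzero density).
#' @param mean,sd Parameters of the parent normal.
#' @param log Return log density?
#' @return Density values.
#' @export
dtnorm0 <- function(x, mean, sd, log = FALSE) {
  ld <- stats::dnorm(x, mean, sd, log = TRUE) -
    stats::pnorm(mean / sd, log.p = TRUE)
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

#' Zero-truncated normal random deviates (rejection sampling)
#'
#' @param n Number of draws.
#' @param mean,sd Parent normal parameters; efficient when
#'   `pnorm(mean/sd)` is not tiny, which holds for all speed components used
#'   here (positive means).
#' @return Numeric vector of positive draws.
#' @export
rtnorm0 <- function(n, mean, sd) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > 0
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Mixture density / CDF of zero-truncated normals
#'
#' @param x Quantiles.
#' @param weights,means,sds Component parameters (weights sum to 1).
#' @return Density (`dtnorm0_mix`) or CDF (`ptnorm0_mix`) values.
#' @export
dtnorm0_mix <- function(x, weights, means, sds) {
  stopifnot(length(weights) == length(means), length(means) == length(sds))
  rowSums(vapply(seq_along(weights), function(j) {
    weights[j] * dtnorm0(x, means[j], sds[j])
  }, numeric(length(x))))
}

#' @rdname dtnorm0_mix
#' @export
ptnorm0_mix <- function(x, weights, means, sds) {
  stopifnot(length(weights) == length(means), length(means) == length(sds))
  rowSums(vapply(seq_along(weights), function(j) {
    p0 <- stats::pnorm(0, means[j], sds[j])
    weights[j] * pmax(stats::pnorm(x, means[j], sds[j]) - p0, 0) / (1 - p0)
  }, numeric(length(x))))
}

## Observed-data log-likelihood for parameter set th = list(w, mu, sigma)
tnorm0_mix_loglik <- function(x, w, mu, sigma) {
  k <- length(w)
  lmat <- vapply(seq_len(k), function(j) {
    log(w[j]) + dtnorm0(x, mu[j], sigma[j], log = TRUE)
  }, numeric(length(x)))
  m <- apply(lmat, 1L, max)
  sum(m + log(rowSums(exp(lmat - m))))
}

## One EM run from a given start. Generalized EM: the M-step for each
## component maximises the weighted truncated-normal log-likelihood
## numerically (Nelder-Mead warm-started at the current parameters), which
## guarantees a non-decreasing observed-data log-likelihood. The weighted
## normal part of the objective depends on the data only through three
## sufficient statistics, so each M-step objective evaluation is O(1).
tnorm0_mix_em_once <- function(x, w, mu, sigma, max_iter, tol) {
  n <- length(x)
  k <- length(w)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ## E-step
    lmat <- vapply(seq_len(k), function(j) {
      log(w[j]) + dtnorm0(x, mu[j], sigma[j], log = TRUE)
    }, numeric(n))
    m <- do.call(pmax, lapply(seq_len(k), function(j) lmat[, j]))
    lse <- m + log(rowSums(exp(lmat - m)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r <- exp(lmat - lse)
    ## M-step
    nk <- colSums(r)
    w <- nk / n
    for (j in seq_len(k)) {
      s0 <- nk[j]
      s1 <- sum(r[, j] * x)
      s2 <- sum(r[, j] * x^2)
      negq <- function(par) {
        mu_j <- par[1L]
        s_j <- exp(par[2L])
        s0 * (par[2L] + 0.5 * log(2 * pi)) +
          (s2 - 2 * mu_j * s1 + mu_j^2 * s0) / (2 * s_j^2) +
          s0 * stats::pnorm(mu_j / s_j, log.p = TRUE)
      }
      opt <- stats::optim(c(mu[j], log(sigma[j])), negq,
                          method = "Nelder-Mead",
                          control = list(maxit = 200, reltol = 1e-12))
      if (is.finite(opt$value) && opt$value <= negq(c(mu[j], log(sigma[j])))) {
        mu[j] <- opt$par[1L]
        sigma[j] <- max(exp(opt$par[2L]), 1e-6)
      }
    }
  }
  list(w = w, mu = mu, sigma = sigma,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       converged = converged, iterations = length(ll_trace))
}

#' Fit a zero-truncated normal mixture to pooled speeds by EM
#'
#' Maximum-likelihood fit of a `k`-component mixture of normals truncated at
#' zero, the model used to decompose pooled intra-hyphal particle speeds into
#' low-, intermediate- and high-mobility fractions. Initialisation is
#' moment-based from `k` quantile bins; additional restarts jitter the
#' initial means and sds, and the best log-likelihood wins (ties broken by
#' the first attained maximum). Components are reported in ascending order of
#' mean.
#'
#' @param speeds Positive speed observations (um/s), at least `10 * k`.
#' @param k Number of components (default 3).
#' @param n_restarts Number of EM starts (default 20).
#' @param max_iter Maximum EM iterations per start.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return A `speed_mixture_fit` with `weights`, `means`, `sds`, `loglik`,
#'   `loglik_trace` (best run), `converged`, `n` and `k`.
#' @export
fit_speed_mixture <- function(speeds, k = 3L, n_restarts = 20L,
                              max_iter = 500L, tol = 1e-8) {
  speeds <- as.numeric(speeds)
  if (any(!is.finite(speeds)) || any(speeds <= 0)) {
    stop("speeds must be finite and strictly positive")
  }
  if (length(speeds) < 10L * k) {
    stop("need at least ", 10L * k, " observations to fit ", k, " components")
  }
  xs <- sort(speeds)
  n <- length(xs)
  bins <- if (k == 1L) list(xs) else {
    split(xs, cut(seq_len(n), breaks = k, labels = FALSE))
  }
  mu0 <- vapply(bins, mean, numeric(1))
  s0 <- pmax(vapply(bins, stats::sd, numeric(1)), diff(range(xs)) / (10 * k))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    if (r == 1L) {
      mu <- mu0
      sg <- s0
    } else {
      mu <- abs(mu0 + stats::rnorm(k, sd = stats::sd(xs) / 2))
      sg <- s0 * exp(stats::rnorm(k, sd = 0.4))
    }
    fit <- tnorm0_mix_em_once(xs, rep(1 / k, k), mu, sg, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik + 1e-9) best <- fit
  }
  ord <- order(best$mu)
  structure(
    list(weights = best$w[ord], means = best$mu[ord], sds = best$sigma[ord],
         loglik = best$loglik, loglik_trace = best$loglik_trace,
         converged = best$converged, iterations = best$iterations,
         n = n, k = as.integer(k)),
    class = "speed_mixture_fit"
  )
}

#' @export
print.speed_mixture_fit <- function(x, ...) {
  cat("<speed_mixture_fit> ", x$k, " zero-truncated normal components, n = ",
      x$n, "\n", sep = "")
  tab <- data.frame(weight = round(x$weights, 3),
                    mean_um_s = round(x$means, 3),
                    sd_um_s = round(x$sds, 3))
  print(tab)
  cat(sprintf("  log-likelihood %.3f (%s after %d iterations)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}
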