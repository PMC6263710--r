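#' Fit a univariate Gaussian mixture by expectation-maximization
#'
#' The personalized baseline of the non-emotional face is, per AU, a
#' K-component Gaussian mixture over the intensities observed in a short
#' modeling window:
#' \deqn{P(X) = \sum_{i=1}^{K} w_i\, \eta(X; \mu_i, \Sigma_i)}
#' with \eqn{\eta} the normal density. K = 3 by default, enough to absorb a
#' drifting resting level plus recurring stereotyped activations, so that
#' only genuinely novel muscle configurations score as unexpected.
#'
#' The fit is a standard EM with k-means initialization seeded at the sample
#' quantiles (deterministic given the data), at most
#' `max_iter` iterations or a log-likelihood improvement below `tol`,
#' variances floored at `variance_floor` (keeping the density, and hence the
#' variation score, bounded), and empty components reseeded once then
#' dropped with weight renormalization. If the samples hold fewer distinct
#' values than `k`, the fit starts from those values and surplus components
#' are dropped.
#'
#' @param x Numeric intensity samples (at least `k`).
#' @param k Number of components (default 3).
#' @param seed Optional integer seed making the fit reproducible without
#'   disturbing the caller's RNG stream.
#' @param variance_floor Lower bound on component variances (default 1e-4).
#' @param max_iter Iteration cap (default 100).
#' @param tol Log-likelihood convergence tolerance (default 1e-6).
#' @return An object of class `"au_mixture"`: weights, means, variances,
#'   log-likelihood and iteration count. Supports [tidy()], [glance()] and
#'   [mixture_pdf()].
#' @examples
#' m <- fit_mixture(c(rnorm(100, 0.5, 0.05), rnorm(100, 2, 0.05)), k = 2, seed = 1)
#' tidy(m)
#' @export
fit_mixture <- function(x, k = 3, seed = NULL, variance_floor = 1e-4,
                        max_iter = 100, tol = 1e-6) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) abort_data("mixture samples must be finite")
  n <- length(x)
  if (n < k) {
    abort_model(sprintf("need at least k = %d samples to fit the mixture (got %d)", k, n))
  }
  with_seed(seed, em_mixture(x, k, variance_floor, max_iter, tol))
}

em_mixture <- function(x, k, variance_floor, max_iter, tol) {
  n <- length(x)
  ux <- unique(x)
  if (length(ux) < k) {
    mu <- sort(ux)
    k <- length(mu)
    w <- rep(1 / k, k)
    s2 <- rep(max(var(x), variance_floor), k)
    if (k == 1) {
      return(new_au_mixture(
        weights = 1, means = mu, variances = max(variance_floor, 0),
        loglik = sum(dnorm(x, mu, sqrt(variance_floor), log = TRUE)),
        n_iter = 0L, n_obs = n, converged = TRUE
      ))
    }
  } else {
    ## k-means-style seeding at the sample quantiles: assign each point to
    ## its nearest quantile center. Deterministic given the data, so nearby
    ## modeling windows get nearly identical initializations.
    centers <- unname(stats::quantile(x, (2 * seq_len(k) - 1) / (2 * k)))
    if (length(unique(centers)) < k) centers <- sort(sample(unique(x), k))
    cl <- findInterval(x, head(centers, -1) / 2 + centers[-1] / 2) + 1L
    cnt <- tabulate(cl, k)
    mu <- ifelse(cnt > 0, vapply(seq_len(k), function(j) mean(x[cl == j]),
                                 numeric(1)), centers)
    w <- pmax(cnt, 0.5) / sum(pmax(cnt, 0.5))
    s2 <- vapply(seq_len(k), function(j) {
      if (cnt[j] > 1) var(x[cl == j]) else var(x)
    }, numeric(1))
  }
  s2 <- pmax(s2, variance_floor)
  w <- pmax(w, 1e-12)
  w <- w / sum(w)

  loglik <- -Inf
  converged <- FALSE
  reseeded <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ## E-step in log space for numerical safety
    lp <- vapply(seq_len(k), function(j) {
      log(w[j]) + dnorm(x, mu[j], sqrt(s2[j]), log = TRUE)
    }, numeric(n))
    lp <- matrix(lp, n, k)
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    new_loglik <- sum(lse)
    resp <- exp(lp - lse)
    nk <- colSums(resp)

    empty <- nk < 1e-8
    if (any(empty)) {
      if (!reseeded) {
        reseeded <- TRUE
        for (j in which(empty)) {
          mu[j] <- x[sample.int(n, 1)]
          s2[j] <- max(var(x), variance_floor)
          w[j] <- 1 / k
        }
        w <- w / sum(w)
        next
      }
      keep <- !empty
      mu <- mu[keep]; s2 <- s2[keep]
      w <- nk[keep] / sum(nk[keep])
      k <- sum(keep)
      next
    }

    w <- nk / n
    mu <- colSums(resp * x) / nk
    s2 <- colSums(resp * (matrix(x, n, k) -
                            matrix(mu, n, k, byrow = TRUE))^2) / nk
    s2 <- pmax(s2, variance_floor)

    if (is.finite(loglik) && abs(new_loglik - loglik) < tol) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik
  }
  ord <- order(mu)
  new_au_mixture(
    weights = w[ord], means = mu[ord], variances = s2[ord],
    loglik = loglik, n_iter = iter, n_obs = n, converged = converged
  )
}

new_au_mixture <- function(weights, means, variances, loglik, n_iter, n_obs,
                           converged) {
  structure(
    list(
      weights = weights, means = means, variances = variances,
      k = length(weights), loglik = loglik, n_iter = n_iter,
      n_obs = n_obs, converged = converged
    ),
    class = "au_mixture"
  )
}

#' @export
print.au_mixture <- function(x, ...) {
  cat(sprintf("<au_mixture: %d component(s), n = %d, loglik = %.4g>\n",
              x$k, x$n_obs, x$loglik))
  print(tidy(x))
  invisible(x)
}

#' @method tidy au_mixture
#' @export
tidy.au_mixture <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$k),
    weight = x$weights,
    mean = x$means,
    variance = x$variances
  )
}

#' @method glance au_mixture
#' @export
glance.au_mixture <- function(x, ...) {
  tibble::tibble(
    k = x$k, loglik = x$loglik, n_iter = x$n_iter,
    converged = x$converged, n_obs = x$n_obs
  )
}

#' Mixture probability density
#'
#' Evaluates the fitted baseline density \eqn{P(X) = \sum_i w_i \eta(X;
#' \mu_i, \Sigma_i)} at the given intensities. Strictly positive everywhere.
#'
#' @param model An [fit_mixture()] object.
#' @param x Numeric vector of intensities.
#' @return Densities, same length as `x`.
#' @examples
#' m <- fit_mixture(rnorm(50), k = 1, seed = 1)
#' mixture_pdf(m, 0)
#' @export
mixture_pdf <- function(model, x) {
  sd <- sqrt(model$variances)
  out <- numeric(length(x))
  for (j in seq_len(model$k)) {
    out <- out + model$weights[j] * dnorm(x, model$means[j], sd[j])
  }
  out
}
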