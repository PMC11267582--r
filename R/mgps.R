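# Full DuMouchel empirical-Bayes gamma-Poisson shrinker (MGPS).
#
# Model: for each (drug, term) cell, the observed count a ~ Poisson(lambda*E)
# with E = (a+b)(a+c)/n the independence expectation, and the reporting
# ratio lambda drawn from a two-component gamma mixture prior
#   lambda ~ w * Gamma(alpha1, beta1) + (1-w) * Gamma(alpha2, beta2)
# (shape/rate parameterization). Marginally a follows a mixture of negative
# binomials; the five hyperparameters are fitted by maximizing the marginal
# likelihood over all tables. The posterior of lambda given a is again a
# two-gamma mixture, giving
#   EBGM = 2^{E[log2 lambda | a]}  and  EB05 = 5th posterior percentile.

#' @noRd
nb_mix_loglik <- function(theta, a, E) {
  # theta = (log a1, log b1, log a2, log b2, logit w)
  a1 <- exp(theta[1]); b1 <- exp(theta[2])
  a2 <- exp(theta[3]); b2 <- exp(theta[4])
  w <- stats::plogis(theta[5])
  l1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
  m <- pmax(l1, l2)
  sum(m + log(w * exp(l1 - m) + (1 - w) * exp(l2 - m)))
}

#' @noRd
posterior_mix <- function(theta, a, E) {
  a1 <- exp(theta[1]); b1 <- exp(theta[2])
  a2 <- exp(theta[3]); b2 <- exp(theta[4])
  w <- stats::plogis(theta[5])
  l1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE) +
    log(w)
  l2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE) +
    log(1 - w)
  m <- pmax(l1, l2)
  q <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  list(q = q, shape1 = a1 + a, rate1 = b1 + E,
       shape2 = a2 + a, rate2 = b2 + E)
}

#' Full empirical-Bayes gamma-Poisson shrinker across a table set
#'
#' Fits the five hyperparameters of DuMouchel's two-component gamma mixture
#' prior by maximum marginal likelihood over all supplied 2x2 tables, then
#' computes per-table shrinkage estimates: `EBGM = 2^{E[log2 lambda | a]}`
#' and `EB05`, the 5th percentile of the posterior gamma mixture. With few
#' tables the hyperparameter fit is unstable; 50 or more is recommended.
#'
#' @param tables `data.table` with columns `a, b, c, d` (one row per
#'   drug-term pair).
#' @param init Optional starting values
#'   `c(alpha1, beta1, alpha2, beta2, w)`; the default is DuMouchel's
#'   classic `(0.2, 0.1, 2, 4, 1/3)`.
#' @param theta Optional fixed hyperparameters (same layout as `init`);
#'   when given, the optimization is skipped and the posterior is computed
#'   under this prior.
#' @return Object of class `mgps_fit`: `hyperparams` (named vector), `w`,
#'   `loglik`, `loglik_init`, `converged`, and `results` (`data.table` with
#'   `a`, `E`, `ebgm`, `eb05`).
#' @export
mgps_full <- function(tables, init = c(0.2, 0.1, 2, 4, 1 / 3),
                      theta = NULL) {
  tables <- data.table::as.data.table(tables)
  a <- as.numeric(tables$a)
  E <- (tables$a + tables$b) * (tables$a + tables$c) / as.numeric(tables$n %||%
    (tables$a + tables$b + tables$c + tables$d))
  if (any(E <= 0)) stop("non-positive expected count in MGPS input",
                        call. = FALSE)
  to_theta <- function(p) c(log(p[1]), log(p[2]), log(p[3]), log(p[4]),
                            stats::qlogis(p[5]))
  if (is.null(theta)) {
    t0 <- to_theta(init)
    ll0 <- nb_mix_loglik(t0, a, E)
    opt <- stats::optim(t0, function(th) -nb_mix_loglik(th, a, E),
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (opt$value > -ll0 + 1e-6) {
      stop("MGPS hyperparameter fit failed to improve on its ",
           "initialization (loglik ", round(-opt$value, 2), " vs ",
           round(ll0, 2), ")", call. = FALSE)
    }
    th <- opt$par
    converged <- opt$convergence == 0L
    loglik <- -opt$value
    loglik_init <- ll0
  } else {
    th <- to_theta(theta)
    converged <- NA
    loglik <- nb_mix_loglik(th, a, E)
    loglik_init <- loglik
  }
  post <- posterior_mix(th, a, E)
  elog <- post$q * (digamma(post$shape1) - log(post$rate1)) +
    (1 - post$q) * (digamma(post$shape2) - log(post$rate2))
  ebgm <- exp(elog)
  eb05 <- vapply(seq_along(a), function(i) {
    mixture_quantile(0.05, post$q[i], post$shape1[i], post$rate1[i],
                     post$shape2[i], post$rate2[i])
  }, numeric(1))
  hp <- c(alpha1 = exp(th[1]), beta1 = exp(th[2]),
          alpha2 = exp(th[3]), beta2 = exp(th[4]),
          w = stats::plogis(th[5]))
  structure(list(hyperparams = hp, loglik = loglik,
                 loglik_init = loglik_init, converged = converged,
                 results = data.table::data.table(a = a, E = E, ebgm = ebgm,
                                                  eb05 = eb05)),
            class = "mgps_fit")
}

#' @noRd
mixture_quantile <- function(p, q, s1, r1, s2, r2) {
  cdf <- function(x) q * stats::pgamma(x, s1, r1) +
    (1 - q) * stats::pgamma(x, s2, r2)
  hi <- max(stats::qgamma(p, s1, r1), stats::qgamma(p, s2, r2), 1e-8)
  lo <- min(stats::qgamma(p, s1, r1), stats::qgamma(p, s2, r2))
  if (cdf(lo) > p) lo <- lo / 2
  stats::uniroot(function(x) cdf(x) - p, lower = max(lo, 1e-300),
                 upper = hi * 1.0000001, extendInt = "upX",
                 tol = 1e-10)$root
}

#' @export
print.mgps_fit <- function(x, ...) {
  cat("Empirical-Bayes gamma-Poisson shrinker fit\n")
  hp <- x$hyperparams
  cat(sprintf("  prior: %.3f * Gamma(%.3g, %.3g) + %.3f * Gamma(%.3g, %.3g)\n",
              hp["w"], hp["alpha1"], hp["beta1"], 1 - hp["w"],
              hp["alpha2"], hp["beta2"]))
  cat(sprintf("  prior mean reporting ratio: %.3f\n",
              hp["w"] * hp["alpha1"] / hp["beta1"] +
                (1 - hp["w"]) * hp["alpha2"] / hp["beta2"]))
  cat(sprintf("  marginal loglik: %.2f (initialization %.2f); %d tables\n",
              x$loglik, x$loglik_init, nrow(x$results)))
  invisible(x)
}
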