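# Multi-item gamma Poisson shrinker (MGPS / EBGM): empirical-Bayes shrinkage
# of the observed-to-expected reporting ratio. The observed count a for a
# drug-event pair is modelled as Poisson(lambda * E) with expected count
# E = (a+b)(a+c)/N; lambda carries a two-component gamma mixture prior. With
# gamma components the posterior is again a gamma mixture, so the geometric
# mean EBGM = 2^(E[log2 lambda | a]) and the 5th percentile EBGM05 have
# closed/semi-closed forms.

#' Gamma-mixture prior for the MGPS shrinker
#'
#' `lambda ~ w * Gamma(alpha1, rate beta1) + (1-w) * Gamma(alpha2, rate
#' beta2)`. The default is the canonical starting prior (alpha1 = 0.2,
#' beta1 = 0.1, alpha2 = 2, beta2 = 4, w = 1/3), used as a fixed prior unless
#' [fit_mgps_prior()] is invoked.
#'
#' @param alpha1,beta1 shape and rate of the first (diffuse) component.
#' @param alpha2,beta2 shape and rate of the second (null-centred) component.
#' @param w mixture weight of the first component, in (0, 1).
#' @return object of class `mgps_prior`.
#' @export
mgps_prior <- function(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                       w = 1 / 3) {
  p <- list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2,
            w = w)
  if (any(unlist(p[1:4]) <= 0) || w <= 0 || w >= 1) {
    stop("prior requires positive shapes/rates and w in (0, 1)")
  }
  structure(p, class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(
    "MGPS gamma-mixture prior: w=%.3f, Gamma(%.3g, rate %.3g) / Gamma(%.3g, rate %.3g)\n",
    x$w, x$alpha1, x$beta1, x$alpha2, x$beta2))
  if (!is.null(attr(x, "converged"))) {
    cat("fitted: converged =", attr(x, "converged"), "\n")
  }
  invisible(x)
}

# marginal (negative binomial) density of the observed count under one
# gamma component: a | E ~ NB(size = alpha, prob = beta/(beta+E))
nb_marginal <- function(a, alpha, beta, e, log = FALSE) {
  dnbinom(a, size = alpha, prob = beta / (beta + e), log = log)
}

# posterior mixture weight of component 1 and the component posteriors
ebgm_posterior <- function(a, e, prior) {
  l1 <- nb_marginal(a, prior$alpha1, prior$beta1, e, log = TRUE)
  l2 <- nb_marginal(a, prior$alpha2, prior$beta2, e, log = TRUE)
  # log-sum-exp for numerical stability on large counts
  m <- pmax(l1 + log(prior$w), l2 + log(1 - prior$w))
  q1 <- exp(l1 + log(prior$w) - m) /
    (exp(l1 + log(prior$w) - m) + exp(l2 + log(1 - prior$w) - m))
  list(q1 = q1,
       shape1 = prior$alpha1 + a, rate1 = prior$beta1 + e,
       shape2 = prior$alpha2 + a, rate2 = prior$beta2 + e)
}

#' Empirical-Bayes geometric mean (EBGM) and its 5th percentile
#'
#' Computes `EBGM = 2^(E[log2 lambda | a])`, the posterior geometric mean of
#' the reporting-rate ratio, and `EBGM05`, the 5th percentile of the posterior
#' gamma mixture found by monotone root-finding on the mixture CDF.
#'
#' @param t a [contingency_table()], or a list/data.frame with fields
#'   `a`, `b`, `c`, `d` (vectorized).
#' @param prior an [mgps_prior()].
#' @return data.frame with columns `ebgm`, `ebgm05`.
#' @export
#' @examples
#' ebgm_estimate(contingency_table(10, 90, 100, 9900))
ebgm_estimate <- function(t, prior = mgps_prior()) {
  stopifnot(inherits(prior, "mgps_prior"))
  k <- as_cells(t)
  n <- k$a + k$b + k$c + k$d
  e <- (k$a + k$b) * (k$a + k$c) / n
  if (any(e <= 0)) stop("expected count E must be positive")
  po <- ebgm_posterior(k$a, e, prior)
  elog <- po$q1 * (digamma(po$shape1) - log(po$rate1)) +
    (1 - po$q1) * (digamma(po$shape2) - log(po$rate2))
  ebgm <- exp(elog)
  if (any(!is.finite(ebgm))) {
    bad <- which(!is.finite(ebgm))[1L]
    stop(sprintf("non-finite posterior moment for cells a=%g b=%g c=%g d=%g",
                 k$a[bad], k$b[bad], k$c[bad], k$d[bad]))
  }
  ebgm05 <- vapply(seq_along(ebgm), function(i) {
    cdf <- function(x) {
      po$q1[i] * pgamma(x, po$shape1[i], rate = po$rate1[i]) +
        (1 - po$q1[i]) * pgamma(x, po$shape2[i], rate = po$rate2[i]) - 0.05
    }
    hi <- max(qgamma(0.5, po$shape1[i], rate = po$rate1[i]),
              qgamma(0.5, po$shape2[i], rate = po$rate2[i]), ebgm[i])
    lo <- min(qgamma(1e-8, po$shape1[i], rate = po$rate1[i]),
              qgamma(1e-8, po$shape2[i], rate = po$rate2[i]))
    uniroot(cdf, lower = max(lo, .Machine$double.xmin), upper = hi,
            extendInt = "upX", tol = 1e-10)$root
  }, numeric(1))
  data.frame(ebgm = ebgm, ebgm05 = ebgm05)
}

#' Fit the MGPS gamma-mixture hyperparameters
#'
#' Maximizes the marginal negative-binomial mixture likelihood of the observed
#' counts given their expected counts over (alpha1, beta1, alpha2, beta2, w),
#' by bounded quasi-Newton optimization on the log/logit scale from the
#' default starting prior. On non-convergence (or with too few tables) the
#' default prior is returned with `converged = FALSE`.
#'
#' @param tables list of [contingency_table()] objects (>= 50 recommended), a
#'   data.frame with columns `a`, `b`, `c`, `d`, or a data.frame with columns
#'   `a` and `e` (observed and expected counts directly).
#' @param start starting prior, default [mgps_prior()].
#' @return an [mgps_prior()] with attributes `converged` (logical) and
#'   `loglik`.
#' @export
fit_mgps_prior <- function(tables, start = mgps_prior()) {
  if (is.data.frame(tables) && all(c("a", "e") %in% names(tables)) &&
      !all(c("b", "c", "d") %in% names(tables))) {
    a <- as.numeric(tables$a)
    e <- as.numeric(tables$e)
    return(fit_mgps_prior_ae(a, e, start))
  }
  cells <- if (is.data.frame(tables)) as_cells(tables) else {
    ks <- lapply(tables, as_cells)
    list(a = vapply(ks, `[[`, numeric(1), "a"),
         b = vapply(ks, `[[`, numeric(1), "b"),
         c = vapply(ks, `[[`, numeric(1), "c"),
         d = vapply(ks, `[[`, numeric(1), "d"))
  }
  n <- cells$a + cells$b + cells$c + cells$d
  e <- (cells$a + cells$b) * (cells$a + cells$c) / n
  fit_mgps_prior_ae(cells$a, e, start)
}

fit_mgps_prior_ae <- function(a, e, start = mgps_prior()) {
  keep <- is.finite(e) & e > 0
  a <- a[keep]; e <- e[keep]
  default_out <- function() {
    out <- start
    attr(out, "converged") <- FALSE
    attr(out, "loglik") <- mix_loglik(a, e, start)
    out
  }
  if (length(a) < 2L) return(default_out())
  nll <- function(theta) {
    p <- theta_to_prior(theta)
    -mix_loglik(a, e, p)
  }
  theta0 <- c(log(start$alpha1), log(start$beta1),
              log(start$alpha2), log(start$beta2), qlogis(start$w))
  fit <- tryCatch(
    optim(theta0, nll, method = "L-BFGS-B",
          lower = rep(c(log(1e-4), -20), c(4, 1)),
          upper = rep(c(log(1e4), 20), c(4, 1)),
          control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0 || !is.finite(fit$value)) {
    return(default_out())
  }
  out <- theta_to_prior(fit$par)
  attr(out, "converged") <- TRUE
  attr(out, "loglik") <- -fit$value
  out
}

theta_to_prior <- function(theta) {
  mgps_prior(alpha1 = exp(theta[1]), beta1 = exp(theta[2]),
             alpha2 = exp(theta[3]), beta2 = exp(theta[4]),
             w = plogis(theta[5]))
}

# total log marginal likelihood of counts a with expectations e under prior p
mix_loglik <- function(a, e, p) {
  l1 <- nb_marginal(a, p$alpha1, p$beta1, e, log = TRUE)
  l2 <- nb_marginal(a, p$alpha2, p$beta2, e, log = TRUE)
  m <- pmax(l1 + log(p$w), l2 + log(1 - p$w))
  sum(m + log(exp(l1 + log(p$w) - m) + exp(l2 + log(1 - p$w) - m)))
}
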