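#' Pointwise discrepancy functions
#'
#' A discrepancy function `D(x, theta2)` measures, at a design point `x`, the
#' separation between the assumed true model and the rival model with
#' parameters `theta2`.  For homoscedastic normal errors it is the squared
#' mean difference (the T-criterion integrand); otherwise it is the
#' Kullback-Leibler divergence between the two response densities.  All
#' discrepancies are nonnegative and vanish when the two densities coincide.
#'
#' `discrepancy()` picks the canonical discrepancy for the pair's error
#' model.  The individual constructors are exported for explicit use (e.g.
#' `kl_normal()` to study the T/KL duality under normal errors).
#'
#' @param pair A [discrim_pair].
#' @return A function `(x, theta2) -> numeric`, vectorized over `x`, with a
#'   `tag` attribute naming the error model it encodes.
#' @export
discrepancy <- function(pair) {
  switch(pair$error$tag,
         normal    = squared_difference(pair),
         lognormal = kl_lognormal(pair),
         gamma     = kl_gamma(pair),
         binomial  = kl_binomial(pair),
         stop("unknown error tag"))
}

#' @rdname discrepancy
#' @export
squared_difference <- function(pair) {
  tr <- pair$true_model$fn; th <- pair$theta_tr; rv <- pair$rival$fn
  f <- function(x, theta2) (tr(x, th) - rv(x, theta2))^2
  attr(f, "tag") <- "normal"
  f
}

#' @rdname discrepancy
#' @export
kl_normal <- function(pair) {
  s2 <- pair$error$sigma2
  tr <- pair$true_model$fn; th <- pair$theta_tr; rv <- pair$rival$fn
  f <- function(x, theta2) (tr(x, th) - rv(x, theta2))^2 / (2 * s2)
  attr(f, "tag") <- "normal"
  f
}

#' @rdname discrepancy
#' @export
kl_lognormal <- function(pair) {
  sd2 <- pair$error$sdlog^2
  tr <- pair$true_model$fn; th <- pair$theta_tr; rv <- pair$rival$fn
  f <- function(x, theta2) {
    e1 <- tr(x, th); e2 <- rv(x, theta2)
    if (any(e1 <= 0) || any(e2 <= 0))
      stop("lognormal mean must be positive")
    (log(e1) - log(e2))^2 / (2 * sd2)
  }
  attr(f, "tag") <- "lognormal"
  f
}

#' @rdname discrepancy
#' @export
kl_gamma <- function(pair) {
  nu <- pair$error$shape
  tr <- pair$true_model$fn; th <- pair$theta_tr; rv <- pair$rival$fn
  f <- function(x, theta2) {
    e1 <- tr(x, th); e2 <- rv(x, theta2)
    if (any(e1 <= 0) || any(e2 <= 0))
      stop("gamma mean must be positive")
    nu * (log(e2 / e1) + e1 / e2 - 1)
  }
  attr(f, "tag") <- "gamma"
  f
}

#' @rdname discrepancy
#' @export
kl_binomial <- function(pair) {
  tr <- pair$true_model$fn; th <- pair$theta_tr; rv <- pair$rival$fn
  eps <- 1e-12
  warned <- FALSE
  f <- function(x, theta2) {
    p1 <- stats::plogis(tr(x, th))
    p2 <- stats::plogis(rv(x, theta2))
    if (any(p2 < eps | p2 > 1 - eps)) {
      if (!warned) {
        warned <<- TRUE
        warning("rival success probability clamped away from {0,1}",
                call. = FALSE)
      }
      p2 <- pmin(pmax(p2, eps), 1 - eps)
    }
    p1 <- pmin(pmax(p1, eps), 1 - eps)
    p1 * log(p1 / p2) + (1 - p1) * log((1 - p1) / (1 - p2))
  }
  attr(f, "tag") <- "binomial"
  f
}

#' Numeric-quadrature KL divergence (reference oracle)
#'
#' Computes the KL divergence between the true and rival response densities
#' by adaptive quadrature over the outcome space (a two-term sum for binomial
#' outcomes).  Slow but assumption-free; used to validate the closed-form
#' discrepancies, never in the search path.
#'
#' @param pair A [discrim_pair].
#' @param x A single design point.
#' @param theta2 Rival parameter vector.
#' @param rel.tol Quadrature relative tolerance.
#' @return The KL divergence at `x`.
#' @export
kl_quadrature <- function(pair, x, theta2, rel.tol = 1e-10) {
  stopifnot(length(x) == 1L)
  e1 <- true_mean(pair, x)
  e2 <- pair$rival$fn(x, theta2)
  em <- pair$error
  ldens <- switch(em$tag,
    normal = function(y, eta) stats::dnorm(y, eta, sqrt(em$sigma2),
                                           log = TRUE),
    lognormal = function(y, eta)
      stats::dlnorm(y, log(eta) - em$sdlog^2 / 2, em$sdlog, log = TRUE),
    gamma = function(y, eta)
      stats::dgamma(y, shape = em$shape, rate = em$shape / eta, log = TRUE),
    binomial = NULL)
  if (em$tag == "binomial") {
    p1 <- stats::plogis(e1); p2 <- stats::plogis(e2)
    return(p1 * log(p1 / p2) + (1 - p1) * log((1 - p1) / (1 - p2)))
  }
  # log-density difference avoids underflow where the rival density vanishes
  integrand <- function(y) {
    l1 <- ldens(y, e1)
    v <- exp(l1) * (l1 - ldens(y, e2))
    v[!is.finite(v)] <- 0   # only where the true density itself underflows
    v
  }
  lo <- if (em$tag == "normal") -Inf else 0
  stats::integrate(integrand, lo, Inf, rel.tol = rel.tol,
                   subdivisions = 500L)$value
}
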