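#' Parameter space with box bounds and a finite sampling box
#'
#' Each coordinate has a lower/upper bound (possibly infinite); the inner
#' quasi-Newton solver respects these bounds directly.  The sampling box is a
#' finite sub-box used to draw random initial points for multistart; it
#' defaults to the bounds truncated to `[-10, 10]` in unbounded directions.
#'
#' @param lower,upper Numeric vectors of box bounds (may be `-Inf`/`Inf`).
#' @param sample_lower,sample_upper Finite sampling box contained in the
#'   bounds; defaults derived from the bounds.
#' @return An object of class `param_space`.
#' @export
param_space <- function(lower, upper, sample_lower = NULL, sample_upper = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  p <- length(lower)
  stopifnot(length(upper) == p, p >= 1L)
  if (any(lower > upper)) stop("param_space requires lower <= upper")
  if (is.null(sample_lower))
    sample_lower <- ifelse(is.finite(lower), lower, -10)
  if (is.null(sample_upper))
    sample_upper <- ifelse(is.finite(upper), upper, 10)
  sample_lower <- as.numeric(sample_lower)
  sample_upper <- as.numeric(sample_upper)
  stopifnot(length(sample_lower) == p, length(sample_upper) == p)
  if (any(!is.finite(sample_lower)) || any(!is.finite(sample_upper)))
    stop("sampling box must be finite")
  if (any(sample_lower < lower - 1e-12) || any(sample_upper > upper + 1e-12))
    stop("sampling box must be contained in the bounds")
  if (any(sample_lower >= sample_upper))
    stop("sampling box must have positive volume")
  structure(list(lower = lower, upper = upper,
                 sample_lower = sample_lower, sample_upper = sample_upper,
                 p = p),
            class = "param_space")
}

#' Mean-response model
#'
#' Wraps a mean function `eta(x, theta)` (vectorized in `x`) together with its
#' parameter dimension and, for rival models, the parameter space over which
#' the inner minimization runs.
#'
#' @param fn Function of `(x, theta)` returning the mean response, vectorized
#'   over `x`.
#' @param npar Number of parameters.
#' @param pspace A [param_space] (required when the model is used as a rival).
#' @param name Optional label used in printing.
#' @return An object of class `mean_model`.
#' @export
mean_model <- function(fn, npar, pspace = NULL, name = "") {
  stopifnot(is.function(fn), npar >= 0)
  if (!is.null(pspace)) {
    stopifnot(inherits(pspace, "param_space"))
    if (pspace$p != npar) stop("pspace dimension must equal npar")
  }
  structure(list(fn = fn, npar = as.integer(npar), pspace = pspace,
                 name = name),
            class = "mean_model")
}

#' Error model
#'
#' Distributional assumption shared by the true and rival models:
#' \describe{
#'   \item{`normal`}{homoscedastic Gaussian with common variance `sigma2`
#'     (default 1); discrimination uses the squared mean difference, and the
#'     Gaussian KL divergence equals that difference divided by `2*sigma2`.}
#'   \item{`lognormal`}{multiplicative error: `log y` is Gaussian with mean
#'     `log eta` (up to a common shift) and common log-scale variance
#'     `sdlog^2` (default `sdlog = 1`), i.e. a constant coefficient of
#'     variation.  The KL divergence is `(log eta_tr - log eta_2)^2 /
#'     (2 sdlog^2)`.}
#'   \item{`gamma`}{constant coefficient of variation: shape `shape`
#'     (default 1) and rate `shape/eta`, so the variance is `eta^2/shape`.
#'     The KL divergence is `shape * (log(eta_2/eta_tr) + eta_tr/eta_2 - 1)`.}
#'   \item{`binomial`}{binary outcome with success probability
#'     `plogis(eta)`; `eta` is the linear predictor.  The KL divergence is
#'     the Bernoulli divergence.}
#' }
#' The lognormal and gamma defaults reproduce the classical
#' Michaelis-Menten discrimination benchmarks.
#'
#' @param tag One of `"normal"`, `"lognormal"`, `"gamma"`, `"binomial"`.
#'   The long aliases `"normal_homoscedastic"`, `"lognormal_meanvar"`,
#'   `"gamma_meanvar"` and `"binomial_logit"` are accepted.
#' @param sigma2 Gaussian variance (normal tag only).
#' @param sdlog Log-scale standard deviation (lognormal tag only).
#' @param shape Gamma shape parameter (gamma tag only).
#' @return An object of class `error_model`.
#' @export
error_model <- function(tag = c("normal", "lognormal", "gamma", "binomial",
                                "normal_homoscedastic", "lognormal_meanvar",
                                "gamma_meanvar", "binomial_logit"),
                        sigma2 = 1, sdlog = 1, shape = 1) {
  tag <- match.arg(tag)
  tag <- c(normal_homoscedastic = "normal", lognormal_meanvar = "lognormal",
           gamma_meanvar = "gamma", binomial_logit = "binomial")[tag] %|%
    tag
  stopifnot(sigma2 > 0, sdlog > 0, shape > 0)
  structure(list(tag = tag, sigma2 = sigma2, sdlog = sdlog, shape = shape),
            class = "error_model")
}

`%|%` <- function(a, b) if (is.na(a)) b else unname(a)

#' Two-model discrimination problem
#'
#' The assumed true model is fully specified (mean function plus nominal
#' parameter values `theta_tr`); the rival model has free parameters ranging
#' over its [param_space].  Both share one [design_space] and one
#' [error_model].
#'
#' @param true_model A [mean_model] for the assumed true mean.
#' @param theta_tr Nominal parameter values of the true model.
#' @param rival A [mean_model] with a `pspace`.
#' @param space A [design_space].
#' @param error An [error_model] (default homoscedastic normal).
#' @param name Optional label.
#' @return An object of class `discrim_pair`.
#' @export
discrim_pair <- function(true_model, theta_tr, rival, space,
                         error = error_model("normal"), name = "") {
  stopifnot(inherits(true_model, "mean_model"), inherits(rival, "mean_model"),
            inherits(space, "design_space"), inherits(error, "error_model"))
  if (is.null(rival$pspace)) stop("rival model needs a param_space")
  theta_tr <- as.numeric(theta_tr)
  if (length(theta_tr) != true_model$npar)
    stop("theta_tr length must equal the true model's npar")
  xs <- seq(space$x_lo, space$x_hi, length.out = 101)
  eta <- true_model$fn(xs, theta_tr)
  if (any(!is.finite(eta)))
    stop("true mean is not finite on the design space")
  if (error$tag %in% c("lognormal", "gamma") && any(eta <= 0))
    stop(sprintf("%s errors require a strictly positive true mean", error$tag))
  structure(list(true_model = true_model, theta_tr = theta_tr,
                 rival = rival, space = space, error = error, name = name),
            class = "discrim_pair")
}

#' Multi-model discrimination problem
#'
#' One fully specified true model against `K - 1 >= 2` rival models, all on a
#' common design space and error model.  Used with max-min efficiency
#' criteria.
#'
#' @inheritParams discrim_pair
#' @param rivals List of rival [mean_model]s, each with a `pspace`.
#' @return An object of class `discrim_set`.
#' @export
discrim_set <- function(true_model, theta_tr, rivals, space,
                        error = error_model("normal"), name = "") {
  stopifnot(is.list(rivals), length(rivals) >= 1L)
  pairs <- lapply(rivals, function(r)
    discrim_pair(true_model, theta_tr, r, space, error))
  structure(list(true_model = true_model, theta_tr = theta_tr,
                 rivals = rivals, pairs = pairs, space = space,
                 error = error, K = length(rivals) + 1L, name = name),
            class = "discrim_set")
}

#' Extract the i-th pairwise problem from a discrimination set
#'
#' @param set A [discrim_set].
#' @param i Rival index in `1..(K-1)`.
#' @return A [discrim_pair].
#' @export
pair_from_set <- function(set, i) {
  stopifnot(inherits(set, "discrim_set"), i >= 1, i <= length(set$rivals))
  set$pairs[[i]]
}

#' Evaluate the true mean of a discrimination problem
#'
#' @param problem A [discrim_pair] or [discrim_set].
#' @param x Points in the design space.
#' @export
true_mean <- function(problem, x) {
  problem$true_model$fn(x, problem$theta_tr)
}
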