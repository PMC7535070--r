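#' Dose-response discrimination problem from a developmental toxicology study
#'
#' Five nested dose-response models for a continuous endpoint (fetal weight
#' under butyl benzyl phthalate exposure), on the dose interval
#' `[0, 1250]` mg/kg/day:
#' \deqn{v1 = a, \quad v2 = a e^{-x/b}, \quad v3 = a e^{-(x/b)^d},}
#' \deqn{v4 = a(c - (c-1) e^{-x/b}), \quad v5 = a(c - (c-1) e^{-(x/b)^d}),}
#' with `a, b > 0`, `c` in `[0, 1]`, `d >= 1`.  The largest model `v5` is
#' taken as the true model with fitted nominal values
#' `(a, b, c, d) = (4.282, 835.571, 0.739, 3.515)`; the four submodels are
#' the rivals.  Sampling boxes for the rival multistarts: `a` in
#' `[0.1, 10]`, `b` in `[1, 5000]`, `c` in `[0, 1]`, `d` in `[1, 10]`.
#'
#' @param error `"normal"` (T-optimality) or `"lognormal"` (KL-optimality
#'   with constant coefficient of variation).
#' @return A [discrim_set] with four rivals.
#' @export
toxicology_set <- function(error = c("normal", "lognormal")) {
  error <- match.arg(error)
  v1 <- mean_model(function(x, th) rep(th[1], length(x)), 1,
                   param_space(1e-8, Inf, 0.1, 10), "v1: constant")
  v2 <- mean_model(function(x, th) th[1] * exp(-x / th[2]), 2,
                   param_space(c(1e-8, 1e-8), c(Inf, Inf),
                               c(0.1, 1), c(10, 5000)),
                   "v2: exponential decay")
  v3 <- mean_model(function(x, th) th[1] * exp(-(x / th[2])^th[3]), 3,
                   param_space(c(1e-8, 1e-8, 1), c(Inf, Inf, Inf),
                               c(0.1, 1, 1), c(10, 5000, 10)),
                   "v3: Weibull decay")
  v4 <- mean_model(function(x, th)
                     th[1] * (th[3] - (th[3] - 1) * exp(-x / th[2])), 3,
                   param_space(c(1e-8, 1e-8, 0), c(Inf, Inf, 1),
                               c(0.1, 1, 0), c(10, 5000, 1)),
                   "v4: plateau exponential")
  v5 <- mean_model(function(x, th)
                     th[1] * (th[3] - (th[3] - 1) * exp(-(x / th[2])^th[4])),
                   4, NULL, "v5: plateau Weibull")
  discrim_set(v5, c(4.282, 835.571, 0.739, 3.515),
              list(v1, v2, v3, v4), design_space(0, 1250),
              error_model(error), name = paste0("toxicology_", error))
}

#' Michaelis-Menten vs modified Michaelis-Menten discrimination
#'
#' The modified Michaelis-Menten model `V x / (K + x) + F x` with nominal
#' `(V, K, F) = (1, 1, 1)` is the assumed true model; the rival is the plain
#' Michaelis-Menten model `V x / (K + x)` with `V, K > 0`.  Substrate
#' concentration range `[0.1, 5]`.  Errors are lognormal or gamma with a
#' constant coefficient of variation.
#'
#' @param error `"lognormal"` or `"gamma"`.
#' @return A [discrim_pair].
#' @export
mm_mmm_pair <- function(error = c("lognormal", "gamma")) {
  error <- match.arg(error)
  mmm <- mean_model(function(x, th) th[1] * x / (th[2] + x) + th[3] * x,
                    3, NULL, "modified Michaelis-Menten")
  mm <- mean_model(function(x, th) th[1] * x / (th[2] + x), 2,
                   param_space(c(1e-8, 1e-8), c(Inf, Inf),
                               c(0.05, 0.05), c(10, 10)),
                   "Michaelis-Menten")
  discrim_pair(mmm, c(1, 1, 1), mm, design_space(0.1, 5),
               error_model(error), name = paste0("mm_mmm_", error))
}

#' Three-model discrimination with exponential, quadratic and
#' trigonometric means
#'
#' True model `theta10 + theta11 e^x + theta12 e^-x` with nominal
#' `(4.5, -1.5, -2)` on `[-1, 1]`, homoscedastic normal errors.  Rivals: a
#' quadratic polynomial and a trigonometric model
#' `b0 + b1 sin(pi x / 2) + b2 cos(pi x / 2) + b3 sin(pi x)`, both with
#' unbounded coefficients (sampling box `[-10, 10]` per coordinate).
#'
#' @return A [discrim_set] with two rivals.
#' @export
trig_poly_set <- function() {
  free <- function(p) param_space(rep(-Inf, p), rep(Inf, p),
                                  rep(-10, p), rep(10, p))
  e1 <- mean_model(function(x, th) th[1] + th[2] * exp(x) + th[3] * exp(-x),
                   3, NULL, "exponential")
  q2 <- mean_model(function(x, th) th[1] + th[2] * x + th[3] * x^2,
                   3, free(3), "quadratic")
  t3 <- mean_model(function(x, th)
                     th[1] + th[2] * sin(pi * x / 2) +
                       th[3] * cos(pi * x / 2) + th[4] * sin(pi * x),
                   4, free(4), "trigonometric")
  discrim_set(e1, c(4.5, -1.5, -2), list(q2, t3), design_space(-1, 1),
              error_model("normal"), name = "trig_poly")
}

#' Four logistic regression models for a binary outcome
#'
#' Linear predictors `theta10 x`, `theta20 + theta21 x`,
#' `theta30 x + theta31 x^2` as rivals of the true quadratic predictor
#' `1 + x + x^2`, all with logit link on the design space `[0, 1]` (the
#' interval consistent with the reported optimal supports; the original
#' source does not print it).  Binomial errors; KL-optimality.
#'
#' @return A [discrim_set] with three rivals.
#' @export
logistic4_set <- function() {
  free <- function(p) param_space(rep(-Inf, p), rep(Inf, p),
                                  rep(-10, p), rep(10, p))
  h1 <- mean_model(function(x, th) th[1] * x, 1, free(1),
                   "logit: slope only")
  h2 <- mean_model(function(x, th) th[1] + th[2] * x, 2, free(2),
                   "logit: linear")
  h3 <- mean_model(function(x, th) th[1] * x + th[2] * x^2, 2, free(2),
                   "logit: quadratic, no intercept")
  h4 <- mean_model(function(x, th) th[1] + th[2] * x + th[3] * x^2,
                   3, NULL, "logit: full quadratic")
  discrim_set(h4, c(1, 1, 1), list(h1, h2, h3), design_space(0, 1),
              error_model("binomial"), name = "logistic4")
}

#' Cubic-vs-linear discrimination (singular optimum)
#'
#' True cubic `1 + x + 0 x^2 + x^3` on `[-1, 1]` against a straight line
#' with free intercept and slope (sampling box `[-5, 5]^2`), normal errors.
#' The T-optimal design has only three support points — fewer than the four
#' cubic parameters — so its information matrix is singular; a best
#' four-point design also exists.
#'
#' @return A [discrim_pair].
#' @export
cubic_vs_linear_pair <- function() {
  cubic <- mean_model(function(x, th)
                        th[1] + th[2] * x + th[3] * x^2 + th[4] * x^3,
                      4, NULL, "cubic")
  line <- mean_model(function(x, th) th[1] + th[2] * x, 2,
                     param_space(c(-Inf, -Inf), c(Inf, Inf),
                                 c(-5, -5), c(5, 5)),
                     "line")
  discrim_pair(cubic, c(1, 1, 0, 1), line, design_space(-1, 1),
               error_model("normal"), name = "cubic_vs_linear")
}

#' Constant vs constrained quadratic discrimination
#'
#' True constant model (nominal 0) on `[-1, 1]` against the quadratic
#' `theta0 + theta1 x + theta2 x^2` subject to `theta1^2 + theta2^2 >= 1`.
#' The constraint is handled by the polar reparameterization
#' `theta1 = r cos(phi)`, `theta2 = r sin(phi)` with `r >= 1` (sampling
#' capped at `r = 100`) and `phi` in `[0, 2 pi]`, which turns the feasible
#' set into a box.  Normal errors.
#'
#' @return A [discrim_pair] whose rival parameters are `(theta0, r, phi)`.
#' @export
constrained_quadratic_pair <- function() {
  const <- mean_model(function(x, th) rep(th[1], length(x)), 1, NULL,
                      "constant")
  quad <- mean_model(function(x, th)
                       th[1] + th[2] * cos(th[3]) * x +
                         th[2] * sin(th[3]) * x^2,
                     3,
                     param_space(c(-Inf, 1, 0), c(Inf, Inf, 2 * pi),
                                 c(-5, 1, 0), c(5, 100, 2 * pi)),
                     "constrained quadratic (polar)")
  discrim_pair(const, 0, quad, design_space(-1, 1), error_model("normal"),
               name = "constrained_quadratic")
}

#' Polynomial family for standardized maximin T-optimal design
#'
#' Discriminating a degree-`m` polynomial from a degree-`(m - 2)` polynomial
#' on `[-1, 1]` reduces, after factoring out the leading coefficient, to
#' discriminating `eta_tr(x, theta_tr) = theta_tr x^{m-1} + x^m` (with
#' `theta_tr` the ratio of the two leading coefficients) from the free
#' degree-`(m - 2)` class.  With `theta_tr` only known to lie in `[-1, 1]`,
#' the standardized maximin criterion seeks the design with the best
#' worst-case T-efficiency over that interval.
#'
#' @param m Polynomial degree (>= 2).
#' @param tr_lower,tr_upper Interval of plausible `theta_tr`.
#' @param oracle If `TRUE`, attach the closed-form locally optimal value
#'   [dette_local_value] as the problem's oracle (fast); if `FALSE` local
#'   optima are searched by [pso_qn].
#' @return A [stdmaximin_problem].
#' @export
dette_family <- function(m, tr_lower = -1, tr_upper = 1, oracle = FALSE) {
  stopifnot(m >= 2)
  p <- m - 1L   # rival coefficients: degree m - 2 polynomial
  rival <- mean_model(function(x, th)
                        drop(outer(x, 0:(length(th) - 1L), `^`) %*% th),
                      p,
                      param_space(rep(-Inf, p), rep(Inf, p),
                                  rep(-5, p), rep(5, p)),
                      sprintf("degree-%d polynomial", m - 2L))
  truef <- mean_model(function(x, th) th[1] * x^(m - 1) + x^m, 1, NULL,
                      sprintf("x^%d + theta x^%d", m, m - 1L))
  make_pair <- function(theta_tr)
    discrim_pair(truef, theta_tr, rival, design_space(-1, 1),
                 error_model("normal"),
                 name = sprintf("dette_m%d", m))
  orc <- if (oracle) function(th) list(value = dette_local_value(m, th))
         else NULL
  stdmaximin_problem(make_pair, tr_lower, tr_upper, oracle = orc,
                     name = sprintf("dette_m%d", m))
}

#' Locally T-optimal criterion value for the polynomial family
#'
#' For a linear rival class, the locally T-optimal criterion value equals
#' the squared error of the best uniform (Chebyshev) approximation of the
#' true mean by the rival class.  For `m = 2` (approximation by constants)
#' this is the squared half-range of `theta_tr x + x^2`; for larger `m` the
#' best approximation is computed numerically on a fine grid.
#'
#' @param m Polynomial degree.
#' @param theta_tr True-model parameter.
#' @return The locally optimal criterion value.
#' @export
dette_local_value <- function(m, theta_tr) {
  xs <- seq(-1, 1, length.out = 8001)
  g <- theta_tr * xs^(m - 1) + xs^m
  if (m == 2) return(((max(g) - min(g)) / 2)^2)
  basis <- outer(xs, 0:(m - 2L), `^`)
  obj <- function(b) max(abs(g - drop(basis %*% b)))
  b0 <- qr.solve(basis, g)   # least squares start
  E <- stats::optim(b0, obj, method = "Nelder-Mead",
                    control = list(maxit = 20000L, reltol = 1e-13))$value
  E^2
}

#' Catalog of published reference designs
#'
#' Machine-readable catalog of the optimal (and benchmark) designs reported
#' for the shipped fixtures, keyed by example id, with their criterion
#' values and dual weight vectors where available.  Backed by a JSON file
#' under `inst/extdata`; each entry round-trips through [design].
#'
#' @param key Optional single key; omit to get the whole catalog.
#' @return A named list of entries `list(problem =, design =, value =,
#'   alpha =, note =)` (fields may be `NULL`), or a single entry.
#' @export
reference_designs <- function(key = NULL) {
  path <- system.file("extdata", "reference_designs.json",
                      package = "discrimdesign", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  cat_ <- lapply(raw, function(e) {
    e$design <- design(as.numeric(e$design$support),
                       as.numeric(e$design$weights))
    e
  })
  if (is.null(key)) return(cat_)
  if (!key %in% names(cat_)) stop("unknown reference design key: ", key)
  cat_[[key]]
}
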