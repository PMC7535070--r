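#' Fedorov-Wynn exchange algorithm for pairwise discrimination
#'
#' Classical vertex-exchange baseline.  At iteration `k`: compute the inner
#' minimizer `theta_hat` of the current design; locate the point `x*`
#' maximizing the discrepancy `D(x, theta_hat)` over a fine candidate grid
#' with a local polish; mix the current design with the point mass at `x*`
#' using the Wynn step `1/(k + 1)`; every `prune_every` iterations
#' canonicalize the design (merging drifted clusters and dropping tiny
#' weights).
#'
#' @param pair A [discrim_pair].
#' @param n_support Size of the random initial design.
#' @param iterations Number of exchange iterations.
#' @param prune_every Canonicalize every this many iterations.
#' @param seed Integer seed.
#' @param disc Optional discrepancy override.
#' @param restarts Inner multistarts.
#' @param grid_n Candidate grid resolution.
#' @param merge_tol,weight_floor Canonicalization settings.
#' @return List of class `pairwise_result` with `design` and `criterion`.
#' @export
fedorov_wynn <- function(pair, n_support = NULL, iterations = 200,
                         prune_every = 3, seed = NULL, disc = NULL,
                         restarts = 4, grid_n = 2001, merge_tol = 1e-3,
                         weight_floor = 1e-3) {
  stopifnot(inherits(pair, "discrim_pair"), iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(disc)) disc <- discrepancy(pair)
  if (is.null(n_support)) n_support <- default_n_support(pair)
  sp <- pair$space
  d <- design(stats::runif(n_support, sp$x_lo, sp$x_hi))
  grid <- seq(sp$x_lo, sp$x_hi, length.out = grid_n)
  step <- grid[2] - grid[1]
  warm <- NULL
  for (k in seq_len(iterations)) {
    cv <- inner_minimize(pair, d, disc = disc, restarts = restarts,
                         theta_init = warm)
    warm <- cv$theta_hat
    dv <- disc(grid, cv$theta_hat)
    i <- which.max(dv)
    lo <- max(sp$x_lo, grid[i] - step); hi <- min(sp$x_hi, grid[i] + step)
    xs <- stats::optimize(function(x) disc(x, cv$theta_hat),
                          c(lo, hi), maximum = TRUE)$maximum
    if (disc(xs, cv$theta_hat) < dv[i]) xs <- grid[i]
    gam <- 1 / (k + 1)
    d <- design(c(d$support, xs), c((1 - gam) * d$weights, gam))
    if (k %% prune_every == 0L)
      d <- canonicalize(d, sp, merge_tol, weight_floor)
  }
  d <- canonicalize(d, sp, merge_tol, weight_floor)
  crit <- inner_minimize(pair, d, disc = disc, restarts = restarts + 2,
                         theta_init = warm)
  structure(list(design = d, criterion = crit, certificate = NULL,
                 trace = NULL),
            class = "pairwise_result")
}

#' Remes exchange algorithm for T-optimal discriminating designs
#'
#' Uniform-approximation baseline for homoscedastic normal errors only.  It
#' exploits the equioscillation structure of T-optimal designs: the support
#' of the optimum sits at local extrema of the deviation `d(x) = eta_tr(x) -
#' eta_2(x, theta_hat)` between consecutive sign changes, with equal
#' absolute deviation at all support points.  Each iteration computes
#' `theta_hat` for the current design, moves every support point to the
#' nearest extremum of `|d|`, and re-optimizes the weights over the simplex
#' at fixed support (direct criterion maximization, which coincides with the
#' equivalence-theorem weight condition at the solution).  The algorithm
#' stops when the absolute deviations at the support points agree to
#' `stop_tol` relative.
#'
#' @param pair A [discrim_pair] with normal errors.
#' @param n_support Number of support points.
#' @param iterations Maximum iterations.
#' @param seed Integer seed.
#' @param restarts Inner multistarts.
#' @param grid_n Resolution for locating sign changes and extrema.
#' @param stop_tol Relative equioscillation tolerance.
#' @return List of class `pairwise_result`.
#' @export
remes <- function(pair, n_support = NULL, iterations = 200, seed = NULL,
                  restarts = 4, grid_n = 2001, stop_tol = 1e-6) {
  stopifnot(inherits(pair, "discrim_pair"))
  if (pair$error$tag != "normal")
    stop("the Remes exchange is implemented for T-optimality (normal errors) only")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_support)) n_support <- default_n_support(pair)
  n <- as.integer(n_support)
  sp <- pair$space
  tr <- function(x) true_mean(pair, x)
  rv <- pair$rival$fn
  disc <- squared_difference(pair)
  grid <- seq(sp$x_lo, sp$x_hi, length.out = grid_n)
  s <- sort(stats::runif(n, sp$x_lo, sp$x_hi))
  w <- rep(1 / n, n)
  warm <- NULL
  d <- design(s, w)
  for (it in seq_len(iterations)) {
    cv <- inner_minimize(pair, d, restarts = restarts, theta_init = warm)
    warm <- cv$theta_hat
    dev <- function(x) tr(x) - rv(x, cv$theta_hat)
    dg <- dev(grid)
    # segment the design space at sign changes of the deviation
    sgn <- sign(dg); sgn[sgn == 0] <- 1
    cuts <- which(diff(sgn) != 0)
    bounds <- c(sp$x_lo, (grid[cuts] + grid[cuts + 1]) / 2, sp$x_hi)
    extrema <- vapply(seq_len(length(bounds) - 1L), function(j) {
      lo <- bounds[j]; hi <- bounds[j + 1]
      cand <- c(lo, hi,
                stats::optimize(function(x) abs(dev(x)), c(lo, hi),
                                maximum = TRUE, tol = 1e-10)$maximum)
      cand[which.max(abs(dev(cand)))]   # |d| can peak at a segment end
    }, numeric(1))
    if (length(extrema) < n)
      stop("equioscillation structure not found; rerun with different n or initial points")
    s_new <- vapply(s, function(si)
      extrema[which.min(abs(extrema - si))], numeric(1))
    if (length(unique(s_new)) < n) {
      # collapsed assignment: fall back to the n largest-|d| extrema
      ord <- order(abs(dev(extrema)), decreasing = TRUE)
      s_new <- sort(extrema[ord[seq_len(n)]])
    }
    s <- sort(s_new)
    # weight step: maximize the criterion over the simplex at fixed support
    wobj <- function(fw) {
      ww <- project_simplex(c(fw, 1 - sum(fw)))
      dd <- design(s, ww)
      inner_minimize(pair, dd, restarts = 1, theta_init = warm)$value
    }
    if (n == 2L) {
      wopt <- stats::optimize(function(fw) wobj(fw), c(0, 1), maximum = TRUE,
                              tol = 1e-10)
      w <- c(wopt$maximum, 1 - wopt$maximum)
    } else if (n > 2L) {
      wopt <- stats::optim(w[-n], wobj, method = "Nelder-Mead",
                           control = list(fnscale = -1, maxit = 120L,
                                          reltol = 1e-10))
      w <- project_simplex(c(wopt$par, 1 - sum(wopt$par)))
    }
    d <- design(s, w)
    ds <- abs(dev(s))
    if ((max(ds) - min(ds)) <= stop_tol * max(ds)) break
  }
  crit <- inner_minimize(pair, d, restarts = restarts + 2, theta_init = warm)
  structure(list(design = d, criterion = crit, certificate = NULL,
                 trace = NULL),
            class = "pairwise_result")
}
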