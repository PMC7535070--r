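#' Particle swarm configuration
#'
#' Tuning parameters of the particle swarm optimizer.  Defaults follow the
#' standard recommendations: cognitive and social accelerations `c1 = c2 =
#' 2`, inertia decreasing linearly from 0.95 to 0.2 over the first 80% of
#' the iterations and held at 0.2 thereafter.
#'
#' @param swarm Number of particles (>= 2).
#' @param iters Number of iterations (>= 1).
#' @param c1,c2 Acceleration constants.
#' @param inertia_start,inertia_end Inertia schedule endpoints.
#' @param decay_frac Fraction of iterations over which inertia decays.
#' @param vmax_frac Velocity clamp, as a fraction of each box width.
#' @param seed Optional integer seed.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(swarm = 32, iters = 200, c1 = 2, c2 = 2,
                       inertia_start = 0.95, inertia_end = 0.2,
                       decay_frac = 0.8, vmax_frac = 0.5, seed = NULL) {
  stopifnot(swarm >= 2, iters >= 1, decay_frac > 0, decay_frac <= 1,
            vmax_frac > 0)
  structure(list(swarm = as.integer(swarm), iters = as.integer(iters),
                 c1 = c1, c2 = c2, inertia_start = inertia_start,
                 inertia_end = inertia_end, decay_frac = decay_frac,
                 vmax_frac = vmax_frac, seed = seed),
            class = "pso_config")
}

#' Inertia weight schedule
#'
#' Linear decay from `start` to `end` over the first `decay_frac` of the
#' iterations, constant at `end` afterwards.
#'
#' @param t Iteration index (1-based).
#' @param iters Total iterations.
#' @param start,end Schedule endpoints.
#' @param decay_frac Decay fraction.
#' @export
inertia_weight <- function(t, iters, start = 0.95, end = 0.2,
                           decay_frac = 0.8) {
  t0 <- max(1, floor(decay_frac * iters))
  ifelse(t >= t0, end, start + (end - start) * t / t0)
}

#' Euclidean projection onto the probability simplex
#'
#' Closed-form projection of an arbitrary vector onto
#' `{w : w_i >= 0, sum w_i = 1}`.
#'
#' @param v Numeric vector.
#' @return The projected vector.
#' @export
project_simplex <- function(v) {
  n <- length(v)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_len(n) > 0))
  tau <- (css[rho] - 1) / rho
  pmax(v - tau, 0)
}

#' Repair a design-encoded particle
#'
#' Particles encode an `n`-point design as `(s_1, ..., s_n, p_1, ...,
#' p_{n-1})` with the last weight implied.  Support coordinates are clipped
#' to the design space; the full weight vector (including the implied last
#' weight) is projected onto the probability simplex.
#'
#' @param raw Numeric vector of length `2n - 1`.
#' @param space A [design_space].
#' @return The repaired vector.
#' @export
repair_design_particle <- function(raw, space) {
  n <- (length(raw) + 1L) %/% 2L
  s <- pmin(pmax(raw[seq_len(n)], space$x_lo), space$x_hi)
  if (n == 1L) return(s)
  pfree <- raw[n + seq_len(n - 1L)]
  p <- project_simplex(c(pfree, 1 - sum(pfree)))
  c(s, p[seq_len(n - 1L)])
}

#' Particle swarm optimization over a box
#'
#' Maximizes `fn` over the box `[lower, upper]` with a standard global-best
#' particle swarm: fresh uniform random factors per particle, coordinate and
#' iteration; linear inertia decay; velocity clamped to `vmax_frac` of each
#' box width; zero initial velocities.  An optional `repair` function maps
#' each proposed position back to the feasible set (used for design
#' particles, whose weights must live on the simplex).  Non-finite objective
#' values are treated as `-Inf`; if the whole initial swarm is non-finite an
#' error is raised.  With a fixed seed the run is bit-reproducible.
#'
#' @param fn Objective to maximize.  Called as `fn(x)` or, if it accepts a
#'   second argument, `fn(x, i)` with the particle index (useful for
#'   per-particle caches such as inner-solver warm starts).
#' @param lower,upper Finite box bounds.
#' @param config A [pso_config].
#' @param repair Optional function mapping a position vector to the feasible
#'   set.
#' @param early_stop Optional function `(best_par, best_value, t)` returning
#'   `TRUE` to terminate early (e.g. an equivalence-theorem check).
#' @return List with `par`, `value`, `trace` (best value per iteration) and
#'   `evals`.
#' @export
pso_optimize <- function(fn, lower, upper, config = pso_config(),
                         repair = NULL, early_stop = NULL) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(lower <= upper))
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- length(lower)
  N <- config$swarm
  takes_index <- length(formals(fn)) >= 2L
  evalf <- function(x, i) {
    v <- if (takes_index) fn(x, i) else fn(x)
    if (!is.finite(v)) -Inf else v
  }
  vmax <- config$vmax_frac * (upper - lower)
  X <- matrix(stats::runif(N * d, rep(lower, each = N), rep(upper, each = N)),
              nrow = N)
  if (!is.null(repair))
    X <- t(apply(X, 1L, repair))
  if (d == 1L) X <- matrix(X, ncol = 1L)
  V <- matrix(0, N, d)
  f <- vapply(seq_len(N), function(i) evalf(X[i, ], i), numeric(1))
  if (all(f == -Inf)) stop("objective is non-finite for the whole swarm")
  P <- X; pf <- f
  g <- which.max(pf)
  gx <- P[g, ]; gf <- pf[g]
  trace <- numeric(config$iters)
  evals <- N
  for (t in seq_len(config$iters)) {
    w <- inertia_weight(t, config$iters, config$inertia_start,
                        config$inertia_end, config$decay_frac)
    R1 <- matrix(stats::runif(N * d), N, d)
    R2 <- matrix(stats::runif(N * d), N, d)
    V <- w * V + config$c1 * R1 * (P - X) +
      config$c2 * R2 * (matrix(gx, N, d, byrow = TRUE) - X)
    V <- pmin(pmax(V, matrix(-vmax, N, d, byrow = TRUE)),
              matrix(vmax, N, d, byrow = TRUE))
    X <- X + V
    if (!is.null(repair)) {
      X <- t(apply(X, 1L, repair))
      if (d == 1L) X <- matrix(X, ncol = 1L)
    } else {
      X <- pmin(pmax(X, matrix(lower, N, d, byrow = TRUE)),
                matrix(upper, N, d, byrow = TRUE))
    }
    f <- vapply(seq_len(N), function(i) evalf(X[i, ], i), numeric(1))
    evals <- evals + N
    imp <- f > pf
    if (any(imp)) {
      P[imp, ] <- X[imp, ]
      pf[imp] <- f[imp]
      b <- which.max(pf)        # ties resolve to the lowest index
      if (pf[b] > gf) { gf <- pf[b]; gx <- P[b, ] }
    }
    trace[t] <- gf
    if (!is.null(early_stop) && isTRUE(early_stop(gx, gf, t))) {
      trace <- trace[seq_len(t)]
      break
    }
  }
  list(par = gx, value = gf, trace = trace, evals = evals)
}
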