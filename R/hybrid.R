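#' @keywords internal
design_particle_box <- function(n, space) {
  list(lower = c(rep(space$x_lo, n), rep(0, n - 1L)),
       upper = c(rep(space$x_hi, n), rep(1, n - 1L)))
}

#' @keywords internal
decode_design_particle <- function(v, n) {
  if (n == 1L) return(design(v[1L], 1))
  w <- v[n + seq_len(n - 1L)]
  design(v[seq_len(n)], c(w, max(0, 1 - sum(w))))
}

#' @keywords internal
default_n_support <- function(pair) {
  max(pair$true_model$npar, pair$rival$npar)
}

#' PSO-QN: hybrid search for a pairwise optimal discriminating design
#'
#' Two-layer hybrid: an outer particle swarm explores the space of `n`-point
#' designs (support points plus free weights, repaired onto the feasible
#' set), while each particle's fitness — the discrimination criterion of the
#' design it encodes — is computed by the smooth inner quasi-Newton
#' minimization over the rival parameters ([inner_minimize]).  Each particle
#' keeps its last inner minimizer as a warm start.  The returned design is
#' canonicalized, re-evaluated with extra multistarts, and certified by the
#' equivalence theorem; the design is returned even when the certificate
#' fails (rerun with a larger `n_support` or budget in that case).
#'
#' @param pair A [discrim_pair].
#' @param n_support Number of support points; defaults to the larger of the
#'   two models' parameter counts.  Values below the rival's parameter count
#'   are allowed and can recover singular optimal designs.
#' @param pso A [pso_config]; 32 particles and 200 iterations by default.
#' @param restarts Inner multistarts per fitness evaluation.
#' @param seed Integer seed for the whole run.
#' @param disc Optional discrepancy override.
#' @param certify_tol,grid_size Equivalence certificate settings.
#' @param merge_tol,weight_floor Canonicalization settings.
#' @return List of class `pairwise_result` with `design`, `criterion`
#'   (a `criterion_value`), `certificate` and the swarm `trace`.
#' @export
pso_qn <- function(pair, n_support = NULL, pso = pso_config(),
                   restarts = 4, seed = NULL, disc = NULL,
                   certify_tol = 1e-3, grid_size = 1001,
                   merge_tol = 1e-3, weight_floor = 1e-3) {
  stopifnot(inherits(pair, "discrim_pair"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_support)) n_support <- default_n_support(pair)
  if (is.null(disc)) disc <- discrepancy(pair)
  n <- as.integer(n_support)
  box <- design_particle_box(n, pair$space)
  warm <- vector("list", pso$swarm)
  fit <- function(v, i) {
    d <- decode_design_particle(v, n)
    cv <- try(inner_minimize(pair, d, disc = disc, restarts = restarts,
                             theta_init = warm[[i]]), silent = TRUE)
    if (inherits(cv, "try-error")) return(-Inf)
    warm[[i]] <<- cv$theta_hat
    cv$value
  }
  run <- pso_optimize(fit, box$lower, box$upper, config = pso,
                      repair = function(v) repair_design_particle(v, pair$space))
  d <- canonicalize(decode_design_particle(run$par, n), pair$space,
                    merge_tol, weight_floor)
  inits <- do.call(rbind, Filter(Negate(is.null), warm))
  crit <- inner_minimize(pair, d, disc = disc, restarts = restarts + 4,
                         theta_init = inits)
  cert <- equivalence_check(pair, d, grid_size = grid_size,
                            tol = certify_tol, crit = crit, disc = disc)
  structure(list(design = d, criterion = crit, certificate = cert,
                 trace = run$trace),
            class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat("<PSO-QN result>\n")
  print(x$design)
  cat(sprintf("criterion: %.8g   certificate: %s\n", x$criterion$value,
              if (x$certificate$passed) "passed" else "FAILED"))
  invisible(x)
}

#' Normalize a reference list to designs plus criterion values
#' @keywords internal
resolve_references <- function(set, references, restarts = 4) {
  lapply(seq_along(references), function(i) {
    r <- references[[i]]
    if (inherits(r, "pairwise_result")) {
      if (!is.null(r$certificate) && !r$certificate$passed)
        warning("reference design for rival ", i, " is not certified",
                call. = FALSE)
      list(design = r$design, value = r$criterion$value)
    } else if (inherits(r, "design")) {
      list(design = r,
           value = inner_minimize(set$pairs[[i]], r,
                                  restarts = restarts)$value)
    } else {
      if (is.null(r$value))
        r$value <- inner_minimize(set$pairs[[i]], r$design,
                                  restarts = restarts)$value
      r
    }
  })
}

#' PSO-S-QN: max-min optimal design for three or more competing models
#'
#' Three-layer hybrid: the outer swarm maximizes the minimal per-rival
#' efficiency `min_j I_j(xi) / I_j(xi_j*)`, where each `I_j` is computed by
#' the inner quasi-Newton solver and the denominators come from the supplied
#' pairwise reference optima (normally [pso_qn] results).  After the search,
#' the dual weight vector `alpha` is recovered ([recover_alpha]) and the
#' design is certified with the generalized equivalence theorem.
#'
#' @param set A [discrim_set].
#' @param references One pairwise optimum per rival: `pairwise_result`s,
#'   designs, or `list(design =, value =)`.
#' @param n_support Points in the candidate designs; defaults to the maximal
#'   parameter count over all models.
#' @param pso A [pso_config]; 32 particles / 400 iterations by default.
#' @param restarts,seed,certify_tol,grid_size,merge_tol,weight_floor As in
#'   [pso_qn].
#' @param activity_tol Efficiency tolerance defining the active set.
#' @return List of class `maxmin_result` with `design`, `profile`
#'   (an `efficiency_profile`), `alpha`, `certificate`, `trace`.
#' @export
pso_s_qn <- function(set, references, n_support = NULL,
                     pso = pso_config(swarm = 32, iters = 400),
                     restarts = 4, seed = NULL, certify_tol = 1e-3,
                     grid_size = 1001, merge_tol = 1e-3, weight_floor = 1e-3,
                     activity_tol = 0.01) {
  stopifnot(inherits(set, "discrim_set"))
  if (!is.null(seed)) set.seed(seed)
  K1 <- length(set$rivals)
  refs <- resolve_references(set, references, restarts)
  refv <- vapply(refs, `[[`, numeric(1), "value")
  if (any(refv <= 0)) stop("degenerate reference")
  if (is.null(n_support))
    n_support <- max(set$true_model$npar,
                     vapply(set$rivals, `[[`, integer(1), "npar"))
  n <- as.integer(n_support)
  discs <- lapply(set$pairs, discrepancy)
  box <- design_particle_box(n, set$space)
  warm <- rep(list(vector("list", K1)), pso$swarm)
  fit <- function(v, i) {
    d <- decode_design_particle(v, n)
    worst <- Inf
    for (j in seq_len(K1)) {
      cv <- try(inner_minimize(set$pairs[[j]], d, disc = discs[[j]],
                               restarts = restarts,
                               theta_init = warm[[i]][[j]]), silent = TRUE)
      if (inherits(cv, "try-error")) return(-Inf)
      warm[[i]][[j]] <<- cv$theta_hat
      worst <- min(worst, cv$value / refv[j])
    }
    worst
  }
  run <- pso_optimize(fit, box$lower, box$upper, config = pso,
                      repair = function(v) repair_design_particle(v, set$space))
  d <- canonicalize(decode_design_particle(run$par, n), set$space,
                    merge_tol, weight_floor)
  profile <- min_efficiency(set, d, refs, restarts = restarts + 4,
                            activity_tol = activity_tol)
  alpha <- try(recover_alpha(set, d, refs, profile = profile), silent = TRUE)
  if (inherits(alpha, "try-error")) {
    warning("alpha recovery failed; returning result without certificate",
            call. = FALSE)
    alpha <- NULL; cert <- NULL
  } else {
    cert <- equivalence_check(set, d, grid_size = grid_size,
                              tol = certify_tol, alpha = alpha,
                              profile = profile)
  }
  structure(list(design = d, profile = profile, alpha = alpha,
                 certificate = cert, trace = run$trace),
            class = "maxmin_result")
}

#' @export
print.maxmin_result <- function(x, ...) {
  cat("<PSO-S-QN result>\n")
  print(x$design)
  print(x$profile)
  if (!is.null(x$alpha))
    cat("alpha:", sprintf("%.3f", x$alpha), "\n")
  if (!is.null(x$certificate))
    cat("certificate:", if (x$certificate$passed) "passed" else "FAILED", "\n")
  invisible(x)
}

#' Recover the dual weight vector of a max-min optimal design
#'
#' At a max-min optimal design there exists a weight vector `alpha` on the
#' active set such that the design is also optimal for the
#' `alpha`-weighted-sum criterion.  `recover_alpha` finds it by minimizing
#' the design-weighted squared deviation between the weighted normalized
#' discrepancies and the max-min value over the support points, using a
#' small particle swarm on the simplex (the objective is a tiny quadratic;
#' the swarm needs no derivatives and respects the simplex via projection).
#' Components off the active set are fixed at zero.  A large residual at the
#' optimum triggers a warning that the design may not be max-min optimal.
#'
#' @param set A [discrim_set].
#' @param d The candidate max-min optimal [design] (canonical).
#' @param references Pairwise references, as in [pso_s_qn].
#' @param profile Optional cached `efficiency_profile`.
#' @param pso A [pso_config] for the simplex search.
#' @param restarts,seed As in [inner_minimize].
#' @param activity_tol Efficiency tolerance defining the active set.
#' @param resid_tol Residual above which the optimality warning fires.
#' @return Numeric `alpha` of length `K - 1` (class `alpha_vector`), with
#'   the achieved objective in attribute `"objective"`.
#' @export
recover_alpha <- function(set, d, references, profile = NULL,
                          pso = pso_config(swarm = 64, iters = 300),
                          restarts = 4, seed = NULL, activity_tol = 0.01,
                          resid_tol = 1e-3) {
  stopifnot(inherits(set, "discrim_set"), inherits(d, "design"))
  if (!is.null(seed)) set.seed(seed)
  K1 <- length(set$rivals)
  if (is.null(profile)) {
    refs <- resolve_references(set, references, restarts)
    profile <- min_efficiency(set, d, refs, restarts = restarts,
                              activity_tol = activity_tol)
  }
  act <- profile$active_set
  m <- length(act)
  alpha <- rep(0, K1)
  if (m == 1L) {
    alpha[act] <- 1
    attr(alpha, "objective") <- 0
    class(alpha) <- "alpha_vector"
    return(alpha)
  }
  # M[k, j]: normalized discrepancy of active rival j at support point k
  M <- vapply(act, function(j) {
    disc_j <- discrepancy(set$pairs[[j]])
    disc_j(d$support, profile$theta_hat[[j]]) / profile$ref_values[j]
  }, numeric(length(d$support)))
  w <- d$weights; b <- profile$min_eff
  obj <- function(a) -sum(w * (as.numeric(M %*% a) - b)^2)
  run <- pso_optimize(obj, rep(0, m), rep(1, m), config = pso,
                      repair = project_simplex)
  alpha[act] <- project_simplex(run$par)
  resid <- -run$value
  if (resid > resid_tol * max(1, b^2))
    warning("design may not be max-min optimal (alpha residual ",
            signif(resid, 3), ")", call. = FALSE)
  attr(alpha, "objective") <- resid
  class(alpha) <- "alpha_vector"
  alpha
}

#' Standardized maximin discrimination problem
#'
#' A family of pairwise discrimination problems indexed by a scalar
#' true-model parameter `theta_tr` ranging over a compact interval.  The
#' standardized maximin criterion scores a design by its worst T-efficiency
#' over the interval, each efficiency being relative to the locally optimal
#' design at that `theta_tr`.
#'
#' @param make_pair Function `theta_tr -> discrim_pair`.
#' @param tr_lower,tr_upper Finite bounds of the true-parameter interval.
#' @param oracle Optional function `theta_tr -> list(value =, design =)`
#'   returning the locally optimal criterion value (and optionally design);
#'   when absent, local optima are found by [pso_qn] and memoized.
#' @param name Optional label.
#' @return An object of class `stdmaximin_problem`.
#' @export
stdmaximin_problem <- function(make_pair, tr_lower, tr_upper, oracle = NULL,
                               name = "") {
  stopifnot(is.function(make_pair), is.finite(tr_lower), is.finite(tr_upper),
            tr_lower <= tr_upper)
  probe <- make_pair((tr_lower + tr_upper) / 2)
  stopifnot(inherits(probe, "discrim_pair"))
  structure(list(make_pair = make_pair, tr_lower = tr_lower,
                 tr_upper = tr_upper, oracle = oracle, space = probe$space,
                 name = name),
            class = "stdmaximin_problem")
}

#' Locally optimal criterion values over a grid of true parameters
#' @keywords internal
local_optima_on_grid <- function(problem, grid, n_support, local_pso,
                                 restarts, warn_uncertified = TRUE) {
  vapply(grid, function(th) {
    pr <- problem$make_pair(th)
    if (!is.null(problem$oracle)) {
      v <- problem$oracle(th)$value
    } else {
      res <- pso_qn(pr, n_support = n_support, pso = local_pso,
                    restarts = restarts)
      if (warn_uncertified && !res$certificate$passed)
        warning(sprintf("local optimum at theta_tr = %g is not certified",
                        th), call. = FALSE)
      v <- res$criterion$value
    }
    if (v <= 0) stop("locally optimal criterion is zero at theta_tr = ", th)
    v
  }, numeric(1))
}

#' Worst-case efficiency of a design over the true-parameter interval
#'
#' Evaluates `min over theta_tr of T(design, theta_tr) / T*(theta_tr)` on an
#' equally spaced grid of the interval.  Denominators are the locally
#' optimal criterion values (from the problem's oracle, from [pso_qn], or
#' supplied precomputed via `local_values`).
#'
#' @param problem A [stdmaximin_problem].
#' @param d A [design].
#' @param grid_size Grid resolution over the interval.
#' @param n_support Support size for the local searches.
#' @param local_pso [pso_config] for the local searches.
#' @param restarts Inner multistarts.
#' @param local_values Optional precomputed locally optimal values on the
#'   same grid.
#' @return The minimal efficiency, with the per-grid-point efficiencies in
#'   attribute `"profile"` and the grid in `"grid"`.
#' @export
stdmaximin_efficiency <- function(problem, d, grid_size = 21,
                                  n_support = NULL,
                                  local_pso = pso_config(32, 100),
                                  restarts = 4, local_values = NULL) {
  stopifnot(inherits(problem, "stdmaximin_problem"), inherits(d, "design"))
  grid <- seq(problem$tr_lower, problem$tr_upper, length.out = grid_size)
  if (is.null(local_values))
    local_values <- local_optima_on_grid(problem, grid, n_support,
                                         local_pso, restarts)
  eff <- vapply(seq_along(grid), function(k) {
    pr <- problem$make_pair(grid[k])
    inner_minimize(pr, d, restarts = restarts)$value / local_values[k]
  }, numeric(1))
  out <- min(eff)
  attr(out, "profile") <- eff
  attr(out, "grid") <- grid
  out
}

#' Nested-PSO-QN: standardized maximin T-optimal design
#'
#' Four-layer hybrid for robust discrimination when the true model's
#' parameter is only known to lie in an interval.  The outer swarm searches
#' over designs; each design's fitness is its worst efficiency over the
#' true-parameter interval, evaluated on a fixed grid (the interval is
#' one-dimensional in all shipped problems, so a grid replaces the inner
#' swarm; the grid resolution is a tuning knob).  Numerators use the inner
#' quasi-Newton solver with per-particle warm starts; denominators — the
#' locally optimal criterion values — are computed once per grid point, by
#' the problem's oracle when available and otherwise by [pso_qn], and
#' memoized.
#'
#' @param problem A [stdmaximin_problem].
#' @param n_support Support size of candidate designs.
#' @param outer [pso_config] for the design swarm (64 particles / 200
#'   iterations by default).
#' @param grid_size Resolution of the true-parameter grid.
#' @param local_pso [pso_config] for the locally optimal design searches.
#' @param restarts,seed,merge_tol,weight_floor As in [pso_qn].
#' @return List of class `stdmaximin_result` with `design`, `value` (the
#'   worst-case efficiency), `grid`, `local_values`, `trace`.
#' @export
nested_pso_qn <- function(problem, n_support, outer = pso_config(64, 200),
                          grid_size = 21, local_pso = pso_config(32, 100),
                          restarts = 4, seed = NULL, merge_tol = 1e-3,
                          weight_floor = 1e-3) {
  stopifnot(inherits(problem, "stdmaximin_problem"))
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(problem$tr_lower, problem$tr_upper, length.out = grid_size)
  den <- local_optima_on_grid(problem, grid, n_support, local_pso, restarts)
  pairs <- lapply(grid, problem$make_pair)
  n <- as.integer(n_support)
  box <- design_particle_box(n, problem$space)
  warm <- rep(list(vector("list", length(grid))), outer$swarm)
  fit <- function(v, i) {
    d <- decode_design_particle(v, n)
    worst <- Inf
    for (k in seq_along(grid)) {
      cv <- try(inner_minimize(pairs[[k]], d, restarts = restarts,
                               theta_init = warm[[i]][[k]]), silent = TRUE)
      if (inherits(cv, "try-error")) return(-Inf)
      warm[[i]][[k]] <<- cv$theta_hat
      worst <- min(worst, cv$value / den[k])
    }
    worst
  }
  run <- pso_optimize(fit, box$lower, box$upper, config = outer,
                      repair = function(v)
                        repair_design_particle(v, problem$space))
  d <- canonicalize(decode_design_particle(run$par, n), problem$space,
                    merge_tol, weight_floor)
  val <- stdmaximin_efficiency(problem, d, grid_size = grid_size,
                               restarts = restarts + 2, local_values = den)
  structure(list(design = d, value = as.numeric(val),
                 profile = attr(val, "profile"), grid = grid,
                 local_values = den, trace = run$trace),
            class = "stdmaximin_result")
}

#' @export
print.stdmaximin_result <- function(x, ...) {
  cat("<Nested-PSO-QN result>\n")
  print(x$design)
  cat(sprintf("worst-case efficiency: %.4f\n", x$value))
  invisible(x)
}
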