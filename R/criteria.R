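#' Inner minimization over the rival parameters
#'
#' Evaluates the discrimination criterion of a fixed design: the
#' design-weighted discrepancy `sum_i p_i D(s_i, theta2)` minimized over the
#' rival's parameter space.  The objective is smooth in `theta2`, so a
#' box-constrained quasi-Newton search (`optim`, method `"L-BFGS-B"`) is run
#' from `restarts` random initial points drawn uniformly from the rival's
#' sampling box (plus the best of a cheap random screen, and any caller
#' supplied warm starts).  The reported value is the best over all starts;
#' the run is flagged converged when at least two starts agree to `1e-6`
#' relative.
#'
#' @param pair A [discrim_pair].
#' @param d A [design].
#' @param disc Discrepancy function; defaults to [discrepancy]`(pair)`.
#' @param restarts Number of random multistarts (>= 1).
#' @param seed Optional integer seed (consumed via `set.seed`).
#' @param theta_init Optional vector or matrix (rows) of extra warm starts.
#' @param maxit Iteration cap per quasi-Newton run.
#' @return An object of class `criterion_value`: a list with `value`,
#'   `theta_hat`, `restarts_used`, `converged`.
#' @export
inner_minimize <- function(pair, d, disc = NULL, restarts = 4, seed = NULL,
                           theta_init = NULL, maxit = 300L) {
  stopifnot(inherits(pair, "discrim_pair"), inherits(d, "design"),
            restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(disc)) disc <- discrepancy(pair)
  ps <- pair$rival$pspace
  p <- ps$p
  s <- d$support; w <- d$weights
  obj <- function(theta) {
    v <- tryCatch(sum(w * disc(s, theta)), error = function(e) Inf)
    if (!is.finite(v)) 1e12 else v
  }
  starts <- list()
  if (!is.null(theta_init)) {
    if (is.null(dim(theta_init))) theta_init <- matrix(theta_init, nrow = 1)
    for (k in seq_len(nrow(theta_init))) {
      th <- pmin(pmax(theta_init[k, ], ps$lower), ps$upper)
      if (all(is.finite(th))) starts[[length(starts) + 1L]] <- th
    }
  }
  # cheap random screen: best of 32 draws seeds one extra start
  scr <- matrix(stats::runif(32L * p, ps$sample_lower, ps$sample_upper),
                ncol = p, byrow = TRUE)
  sv <- apply(scr, 1L, obj)
  starts[[length(starts) + 1L]] <- scr[which.min(sv), ]
  for (k in seq_len(restarts))
    starts[[length(starts) + 1L]] <-
      stats::runif(p, ps$sample_lower, ps$sample_upper)
  vals <- rep(NA_real_, length(starts))
  best <- NULL; bestv <- Inf
  for (k in seq_along(starts)) {
    fit <- try(stats::optim(starts[[k]], obj, method = "L-BFGS-B",
                            lower = ps$lower, upper = ps$upper,
                            control = list(maxit = maxit, pgtol = 1e-10,
                                           factr = 1e2)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    vals[k] <- fit$value
    if (fit$value < bestv) { bestv <- fit$value; best <- fit$par }
  }
  ok <- vals[is.finite(vals)]
  if (length(ok) == 0L)
    stop("inner solver failed; enlarge sampling box")
  agree <- sum(ok <= bestv + 1e-6 * max(bestv, 1e-12))
  structure(list(value = bestv, theta_hat = best,
                 restarts_used = length(starts),
                 converged = agree >= min(2L, length(ok))),
            class = "criterion_value")
}

#' @export
print.criterion_value <- function(x, ...) {
  cat(sprintf("<criterion value %.8g (%sconverged, %d starts)>\n", x$value,
              if (x$converged) "" else "NOT ", x$restarts_used))
  cat("theta_hat:", signif(x$theta_hat, 6), "\n")
  invisible(x)
}

#' Discrimination criterion of a design
#'
#' The T-criterion (squared mean difference) or KL-criterion (divergence)
#' value of `d`, depending on `disc` / the pair's error model.  Thin wrapper
#' over [inner_minimize].
#'
#' @inheritParams inner_minimize
#' @param ... Passed to [inner_minimize].
#' @return A `criterion_value`.
#' @export
criterion <- function(pair, d, disc = NULL, ...) {
  inner_minimize(pair, d, disc = disc, ...)
}

#' Efficiency of a design relative to a reference design
#'
#' `criterion(d) / criterion(reference)`, where the reference is the (near-)
#' optimal design for the pair.  A ratio above 1 signals a suboptimal
#' reference and triggers a warning.
#'
#' @inheritParams inner_minimize
#' @param reference The reference (optimal) [design].
#' @param ref_value Optional precomputed reference criterion value.
#' @param ... Passed to [inner_minimize].
#' @return Efficiency in `[0, 1]` (slightly above 1 possible, with warning).
#' @export
efficiency <- function(pair, d, reference, disc = NULL, ref_value = NULL,
                       ...) {
  if (is.null(disc)) disc <- discrepancy(pair)
  if (is.null(ref_value))
    ref_value <- inner_minimize(pair, reference, disc = disc, ...)$value
  if (ref_value <= 0) stop("degenerate reference")
  v <- inner_minimize(pair, d, disc = disc, ...)$value
  eff <- v / ref_value
  if (eff > 1 + 1e-6)
    warning(sprintf("efficiency %.6f > 1: reference design looks suboptimal",
                    eff), call. = FALSE)
  eff
}

#' Per-rival efficiencies and their minimum
#'
#' For a multi-model problem, computes the efficiency of `d` relative to each
#' pairwise optimal reference, the minimal efficiency (the max-min criterion
#' value), and the active set: the rival indices whose efficiency is within
#' `activity_tol` of the minimum.
#'
#' @param set A [discrim_set].
#' @param d A [design].
#' @param references List of reference designs (one per rival), or a list of
#'   lists `list(design =, value =)` carrying precomputed criterion values.
#' @param restarts,seed,maxit Passed to [inner_minimize].
#' @param activity_tol Absolute efficiency tolerance defining the active set.
#' @return An object of class `efficiency_profile`: `eff`, `min_eff`,
#'   `active_set`, plus per-rival criterion values, reference values and
#'   inner minimizers.
#' @export
min_efficiency <- function(set, d, references, restarts = 4, seed = NULL,
                           maxit = 300L, activity_tol = 0.01) {
  stopifnot(inherits(set, "discrim_set"))
  K1 <- length(set$rivals)
  stopifnot(length(references) == K1)
  if (!is.null(seed)) set.seed(seed)
  eff <- num <- den <- rep(NA_real_, K1)
  th <- vector("list", K1)
  for (i in seq_len(K1)) {
    pr <- set$pairs[[i]]
    ref <- references[[i]]
    if (inherits(ref, "design")) {
      rd <- ref
      rv <- inner_minimize(pr, rd, restarts = restarts, maxit = maxit)$value
    } else {
      rd <- ref$design
      rv <- if (!is.null(ref$value)) ref$value
            else inner_minimize(pr, rd, restarts = restarts,
                                maxit = maxit)$value
    }
    if (rv <= 0) stop("degenerate reference for rival ", i)
    cv <- inner_minimize(pr, d, restarts = restarts, maxit = maxit)
    num[i] <- cv$value; den[i] <- rv; th[[i]] <- cv$theta_hat
    eff[i] <- cv$value / rv
  }
  m <- min(eff)
  structure(list(eff = eff, min_eff = m,
                 active_set = which(eff <= m + activity_tol),
                 values = num, ref_values = den, theta_hat = th),
            class = "efficiency_profile")
}

#' @export
print.efficiency_profile <- function(x, ...) {
  cat("<efficiency profile>\n")
  cat("eff:      ", paste(sprintf("%.4f", x$eff), collapse = "  "), "\n")
  cat(sprintf("min_eff:   %.4f\nactive set: {%s}\n", x$min_eff,
              paste(x$active_set, collapse = ", ")))
  invisible(x)
}

#' Directional derivative of a discrimination criterion
#'
#' For a two-model problem, the directional derivative of the criterion at
#' design `d` in the direction of the point mass at `x` is
#' `psi(x) = D(x, theta_hat) - criterion(d)`; the equivalence theorem states
#' that `d` is optimal iff `psi <= 0` everywhere, with equality at the
#' support points.  For a multi-model (max-min) problem the generalized form
#' is `psi(x) = sum_i alpha_i D_i(x, theta_hat_i) / I_i* - I_m(d)`, with
#' `alpha` a dual weight vector supported on the active set.
#'
#' @param problem A [discrim_pair] or [discrim_set].
#' @param d A [design].
#' @param x Points at which to evaluate `psi`.
#' @param ... Method-specific arguments: for pairs, `crit` (a cached
#'   `criterion_value`) and `disc`; for sets, `alpha`, `references` and an
#'   optional cached `profile`.
#' @return Numeric vector of `psi` values.
#' @export
directional_derivative <- function(problem, d, x, ...) {
  UseMethod("directional_derivative")
}

#' @rdname directional_derivative
#' @param crit Optional cached `criterion_value` for `d`.
#' @param disc Optional discrepancy function.
#' @export
directional_derivative.discrim_pair <- function(problem, d, x, crit = NULL,
                                                disc = NULL, ...) {
  if (is.null(disc)) disc <- discrepancy(problem)
  if (is.null(crit)) crit <- inner_minimize(problem, d, disc = disc, ...)
  disc(x, crit$theta_hat) - crit$value
}

#' @rdname directional_derivative
#' @param alpha Dual weight vector (length `K - 1`, sums to 1).
#' @param references Reference designs or `list(design =, value =)` per rival.
#' @param profile Optional cached `efficiency_profile` for `d`.
#' @export
directional_derivative.discrim_set <- function(problem, d, x, alpha = NULL,
                                               references = NULL,
                                               profile = NULL, ...) {
  if (is.null(alpha)) stop("alpha missing for multi-model form")
  if (is.null(profile)) {
    if (is.null(references))
      stop("references are required to evaluate the max-min derivative")
    profile <- min_efficiency(problem, d, references, ...)
  }
  K1 <- length(problem$rivals)
  stopifnot(length(alpha) == K1)
  psi <- rep(-profile$min_eff, length(x))
  for (i in seq_len(K1)) {
    if (alpha[i] <= 0) next
    disc_i <- discrepancy(problem$pairs[[i]])
    psi <- psi + alpha[i] * disc_i(x, profile$theta_hat[[i]]) /
      profile$ref_values[i]
  }
  psi
}

#' Equivalence-theorem certificate for a candidate optimal design
#'
#' Evaluates the directional derivative on an equally spaced verification
#' grid augmented with the design's support points.  The design passes when
#' `max psi <= tol * max(1, criterion)` everywhere and `|psi| <= tol *
#' max(1, criterion)` at every support point.
#'
#' @inheritParams directional_derivative
#' @param grid_size Number of equally spaced grid points.
#' @param tol Relative certification tolerance.
#' @param ... Passed to the `directional_derivative` method (e.g. `crit`,
#'   or `alpha`/`references`/`profile` for sets).
#' @return An object of class `equivalence_report` with the grid, `psi`
#'   values, `max_psi`, `argmax_x`, support-point residuals, and `passed`.
#' @export
equivalence_check <- function(problem, d, grid_size = 1001, tol = 1e-3, ...) {
  stopifnot(inherits(d, "design"))
  sp <- problem$space
  args <- list(...)
  if (inherits(problem, "discrim_pair")) {
    if (is.null(args$disc)) args$disc <- discrepancy(problem)
    if (is.null(args$crit))
      args$crit <- inner_minimize(problem, d, disc = args$disc)
    scale_val <- args$crit$value
  } else {
    if (is.null(args$profile)) {
      if (is.null(args$references))
        stop("references are required to certify a max-min design")
      args$profile <- min_efficiency(problem, d, args$references)
    }
    if (is.null(args$alpha)) stop("alpha missing for multi-model form")
    scale_val <- args$profile$min_eff
  }
  grid <- sort(unique(c(seq(sp$x_lo, sp$x_hi, length.out = grid_size),
                        d$support)))
  psi <- do.call(directional_derivative,
                 c(list(problem = problem, d = d, x = grid), args))
  spsi <- do.call(directional_derivative,
                  c(list(problem = problem, d = d, x = d$support), args))
  thr <- tol * max(1, scale_val)
  imax <- which.max(psi)
  structure(list(grid = grid, psi = psi, max_psi = psi[imax],
                 argmax_x = grid[imax], support_x = d$support,
                 support_psi = spsi, tol = tol, threshold = thr,
                 criterion = scale_val,
                 passed = psi[imax] <= thr && all(abs(spsi) <= thr)),
            class = "equivalence_report")
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat(sprintf("<equivalence report: %s>\n",
              if (x$passed) "PASSED" else "FAILED"))
  cat(sprintf("max psi %.3e at x = %.6g (threshold %.3e)\n",
              x$max_psi, x$argmax_x, x$threshold))
  cat("support psi:", sprintf("%.2e", x$support_psi), "\n")
  invisible(x)
}

#' @export
as.data.frame.equivalence_report <- function(x, ...) {
  data.frame(x = x$grid, psi = x$psi)
}

#' Export the verification grid of an equivalence report as CSV
#'
#' @param report An `equivalence_report`.
#' @param path File path.
#' @export
write_psi_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
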