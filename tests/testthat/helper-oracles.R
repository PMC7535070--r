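# Shared test helpers: small search budgets and brute-force oracles.

quick_pso <- function(swarm = 24, iters = 80, ...) {
  pso_config(swarm = swarm, iters = iters, ...)
}

# Iteratively refined grid search over the rival parameter box: an
# independent, derivative-free oracle for the inner minimization.
grid_inner_oracle <- function(pair, d, disc = NULL, n_grid = 51,
                              stages = 6) {
  if (is.null(disc)) disc <- discrepancy(pair)
  ps <- pair$rival$pspace
  lo <- ps$sample_lower; hi <- ps$sample_upper
  obj <- function(theta) {
    v <- tryCatch(sum(d$weights * disc(d$support, theta)),
                  error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }
  best <- NULL; bestv <- Inf
  for (st in seq_len(stages)) {
    axes <- lapply(seq_len(ps$p), function(j)
      seq(lo[j], hi[j], length.out = n_grid))
    G <- as.matrix(expand.grid(axes))
    vals <- apply(G, 1L, obj)
    i <- which.min(vals)
    if (vals[i] < bestv) { bestv <- vals[i]; best <- G[i, ] }
    span <- (hi - lo) / (n_grid - 1) * 3   # keep a margin around the best
    lo <- pmax(ps$lower, best - span)
    hi <- pmin(ps$upper, best + span)
  }
  list(value = bestv, theta = best)
}

# Restrict a pair's rival parameter space to its (compact) sampling box, so
# quasi-Newton and grid search optimize over the same set: some rivals (e.g.
# Michaelis-Menten under a near-interpolable design) have inner minimizers
# escaping to infinity along a parameter ridge, which no finite grid tracks.
box_restricted_pair <- function(pair) {
  ps <- pair$rival$pspace
  rv <- mean_model(pair$rival$fn, pair$rival$npar,
                   param_space(ps$sample_lower, ps$sample_upper),
                   pair$rival$name)
  discrim_pair(pair$true_model, pair$theta_tr, rv, pair$space, pair$error)
}

random_design <- function(space, n) {
  w <- stats::rexp(n)
  design(stats::runif(n, space$x_lo, space$x_hi), w / sum(w))
}
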