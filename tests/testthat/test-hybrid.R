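test_that("PSO-QN recovers the two-point dose-response optimum", {
  p1 <- pair_from_set(toxicology_set("normal"), 1)
  res <- pso_qn(p1, n_support = 2, pso = quick_pso(24, 80), restarts = 2,
                seed = 7)
  expect_equal(res$design$support, c(0, 1250), tolerance = 1e-4)
  expect_equal(res$design$weights, c(0.5, 0.5), tolerance = 1e-3)
  expect_true(res$certificate$passed)
  # global-best trace is monotone: a doubled budget can never do worse
  expect_true(all(diff(res$trace) >= 0))
  expect_gte(res$trace[length(res$trace)],
             res$trace[ceiling(length(res$trace) / 2)])
})

test_that("PSO-QN finds the singular three-point cubic design", {
  cb <- cubic_vs_linear_pair()
  res <- pso_qn(cb, n_support = 3, pso = quick_pso(32, 120), restarts = 2,
                seed = 3)
  expect_true(res$certificate$passed)
  expect_equal(res$design$support, c(-0.5, 0.5, 1), tolerance = 5e-3)
  expect_equal(res$design$weights, c(1/6, 1/2, 1/3), tolerance = 5e-3)
  # the 4-point optimum attains the same criterion value (optimum not unique)
  v4 <- inner_minimize(cb, reference_designs("cubic_4pt")$design,
                       restarts = 4, seed = 5)$value
  expect_equal(res$criterion$value, v4, tolerance = 2e-3)
})

test_that("polar reparameterization handles the constrained rival", {
  cq <- constrained_quadratic_pair()
  res <- pso_qn(cq, n_support = 3, pso = quick_pso(32, 120), restarts = 2,
                seed = 5)
  expect_true(res$certificate$passed)
  expect_equal(res$design$support, c(-1, 0, 1), tolerance = 5e-3)
  expect_equal(res$design$weights, c(0.25, 0.5, 0.25), tolerance = 0.01)
  # the inner minimizer sits on the constraint boundary r = 1
  expect_equal(res$criterion$theta_hat[2], 1, tolerance = 1e-4)
})

test_that("dual weights are recovered on the active set", {
  tp <- trig_poly_set()
  refs <- list(reference_designs("trig_T2")$design,
               reference_designs("trig_T3")$design)
  set.seed(11)
  prof <- min_efficiency(tp, reference_designs("trig_T23")$design, refs,
                         restarts = 4)
  a <- recover_alpha(tp, reference_designs("trig_T23")$design, refs,
                     profile = prof, seed = 2)
  expect_equal(as.numeric(a), c(0.688, 0.312), tolerance = 5e-3)
  expect_equal(sum(a), 1, tolerance = 1e-9)
  expect_lt(attr(a, "objective"), 1e-3)

  # K = 2: the simplex is a point
  p1 <- pair_from_set(toxicology_set("normal"), 1)
  solo <- discrim_set(p1$true_model, p1$theta_tr, list(p1$rival), p1$space,
                      p1$error)
  a1 <- recover_alpha(solo, reference_designs("tox_T_1")$design,
                      list(reference_designs("tox_T_1")$design), seed = 3)
  expect_equal(as.numeric(a1), 1)
})

test_that("PSO-S-QN approaches the printed three-model max-min optimum", {
  tp <- trig_poly_set()
  refs <- list(list(design = reference_designs("trig_T2")$design),
               list(design = reference_designs("trig_T3")$design))
  res <- pso_s_qn(tp, refs, n_support = 5, pso = quick_pso(20, 100),
                  restarts = 2, seed = 12)
  expect_gt(res$profile$min_eff, 0.79)   # printed optimum: 0.806
  expect_setequal(res$profile$active_set, c(1L, 2L))
})

test_that("standardized maximin machinery matches the analytic oracle", {
  fam <- dette_family(2)
  # swarm-found local optimum agrees with the Chebyshev closed form
  set.seed(4)
  for (th in c(-0.8, 0, 0.6)) {
    res <- pso_qn(fam$make_pair(th), n_support = 3,
                  pso = quick_pso(24, 60), restarts = 2)
    expect_equal(res$criterion$value, dette_local_value(2, th),
                 tolerance = 1e-4)
  }
  # a single-point parameter set reduces to the locally optimal design:
  # the local optimum has worst-case efficiency 1 over {theta_tr}
  point <- stdmaximin_problem(fam$make_pair, 0.4, 0.4,
                              oracle = function(th)
                                list(value = dette_local_value(2, th)))
  loc <- pso_qn(fam$make_pair(0.4), n_support = 3, pso = quick_pso(24, 60),
                restarts = 2, seed = 6)
  v <- stdmaximin_efficiency(point, loc$design, grid_size = 1, restarts = 2)
  expect_equal(as.numeric(v), 1, tolerance = 1e-3)
})

test_that("Nested-PSO-QN reaches the published worst-case efficiency", {
  fam <- dette_family(2, oracle = TRUE)
  res <- nested_pso_qn(fam, n_support = 3, outer = quick_pso(20, 50),
                       grid_size = 9, restarts = 2, seed = 9)
  # printed worst-case efficiency: 64.00%
  expect_gt(res$value, 0.625)
  fine <- stdmaximin_efficiency(fam, res$design, grid_size = 41,
                                restarts = 3)
  expect_equal(as.numeric(fine), 0.64, tolerance = 0.006)
})
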