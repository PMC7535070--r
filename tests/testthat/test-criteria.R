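test_that("an interpolating rival drives a one-point criterion to zero", {
  cb <- cubic_vs_linear_pair()
  d1 <- design(0.4, 1)
  cv <- inner_minimize(cb, d1, restarts = 3, seed = 1)
  expect_lt(cv$value, 1e-12)
  expect_true(cv$converged)
})

test_that("quasi-Newton inner minimum matches the grid-refinement oracle", {
  cb <- cubic_vs_linear_pair()
  d <- design(c(-0.8, -0.1, 0.6, 1), c(0.3, 0.3, 0.2, 0.2))
  qn <- inner_minimize(cb, d, restarts = 4, seed = 2)
  or <- grid_inner_oracle(cb, d)
  expect_lt(abs(qn$value - or$value), 1e-5)
  expect_lte(qn$value, or$value + 1e-10)   # QN at least as good as the grid

  # compact-box copy: the unconstrained inner minimizer of this rival can
  # drift along a (V, K) ridge that no finite grid tracks
  mmp <- box_restricted_pair(mm_mmm_pair("gamma"))
  d2 <- design(c(0.1, 1.6, 5), c(0.3, 0.5, 0.2))
  qn2 <- inner_minimize(mmp, d2, restarts = 4, seed = 3)
  or2 <- grid_inner_oracle(mmp, d2)
  expect_lt(abs(qn2$value - or2$value), 1e-5)
})

test_that("criterion values at published designs are reproduced", {
  # pharmacokinetic pair, lognormal and gamma errors
  lnv <- inner_minimize(mm_mmm_pair("lognormal"),
                        reference_designs("mm_mmm_lognormal")$design,
                        restarts = 4, seed = 4)
  expect_equal(lnv$value, 0.002565090, tolerance = 1e-5)
  gav <- inner_minimize(mm_mmm_pair("gamma"),
                        reference_designs("mm_mmm_gamma")$design,
                        restarts = 4, seed = 5)
  expect_equal(gav$value, 0.002564359, tolerance = 1e-5)

  # exponential-vs-quadratic and exponential-vs-trigonometric T-criteria
  tp <- trig_poly_set()
  c2 <- inner_minimize(pair_from_set(tp, 1),
                       reference_designs("trig_T2")$design,
                       restarts = 4, seed = 6)
  expect_equal(c2$value, 0.001087, tolerance = 5e-4)
  c3 <- inner_minimize(pair_from_set(tp, 2),
                       reference_designs("trig_T3")$design,
                       restarts = 4, seed = 7)
  expect_equal(c3$value, 0.005715, tolerance = 5e-4)
})

test_that("efficiency is 1 at the reference and drops under perturbation", {
  p1 <- pair_from_set(toxicology_set("normal"), 1)
  ref <- reference_designs("tox_T_1")$design
  expect_equal(efficiency(p1, ref, ref, seed = 8), 1, tolerance = 1e-10)
  pert <- design(ref$support, c(0.55, 0.45))
  expect_lt(efficiency(p1, pert, ref, seed = 9), 1)
  cbp <- cubic_vs_linear_pair()
  bad <- design(0.4, 1)   # interpolable one-point design: criterion zero
  expect_error(efficiency(cbp, ref, bad, ref_value = 0, seed = 10),
               "degenerate reference")
})

test_that("min_efficiency reproduces the three-model max-min value", {
  tp <- trig_poly_set()
  refs <- list(reference_designs("trig_T2")$design,
               reference_designs("trig_T3")$design)
  prof <- min_efficiency(tp, reference_designs("trig_T23")$design, refs,
                         restarts = 4, seed = 11)
  expect_equal(prof$min_eff, 0.806, tolerance = 2e-3)
  expect_setequal(prof$active_set, c(1L, 2L))
  expect_equal(prof$min_eff, min(prof$eff))

  # K = 2 reduces to plain efficiency
  p1 <- pair_from_set(toxicology_set("normal"), 1)
  solo <- discrim_set(p1$true_model, p1$theta_tr, list(p1$rival), p1$space,
                      p1$error)
  ref <- reference_designs("tox_T_1")$design
  d <- reference_designs("tox_P2000")$design
  prof2 <- min_efficiency(solo, d, list(ref), restarts = 4, seed = 12)
  expect_equal(prof2$min_eff,
               efficiency(p1, d, ref, seed = 12), tolerance = 1e-6)
})

test_that("the criterion is concave over design mixtures", {
  cb <- cubic_vs_linear_pair()
  set.seed(13)
  for (k in 1:8) {
    d1 <- random_design(cb$space, 3)
    d2 <- random_design(cb$space, 3)
    a <- stats::runif(1, 0.2, 0.8)
    mix <- design(c(d1$support, d2$support),
                  c(a * d1$weights, (1 - a) * d2$weights))
    v1 <- inner_minimize(cb, d1, restarts = 3)$value
    v2 <- inner_minimize(cb, d2, restarts = 3)$value
    vm <- inner_minimize(cb, mix, restarts = 3)$value
    expect_gte(vm, a * v1 + (1 - a) * v2 - 1e-8)
  }
})

test_that("T- and normal-KL efficiencies coincide for arbitrary designs", {
  p2 <- pair_from_set(toxicology_set("normal"), 2)
  p2kl <- discrim_pair(p2$true_model, p2$theta_tr, p2$rival, p2$space,
                       error_model("normal", sigma2 = 3.7))
  ref <- reference_designs("tox_T_2")$design
  set.seed(14)
  for (k in 1:3) {
    d <- random_design(p2$space, 3)
    effT <- efficiency(p2, d, ref, disc = squared_difference(p2), seed = 20 + k)
    effK <- efficiency(p2kl, d, ref, disc = kl_normal(p2kl), seed = 20 + k)
    expect_equal(effT, effK, tolerance = 1e-10)
  }
})

test_that("directional derivatives separate optimal from non-optimal designs", {
  cq <- constrained_quadratic_pair()
  dstar <- reference_designs("constrained_quad")$design
  crit <- inner_minimize(cq, dstar, restarts = 6, seed = 15)
  psi <- directional_derivative(cq, dstar, seq(-1, 1, length.out = 1001),
                                crit = crit)
  expect_lte(max(psi), 1e-6)
  # psi vanishes at the support points of the optimum
  expect_equal(directional_derivative(cq, dstar, dstar$support, crit = crit),
               rep(0, 3), tolerance = 1e-6)

  cb <- cubic_vs_linear_pair()
  unif5 <- design(seq(-1, 1, length.out = 5))
  crit5 <- inner_minimize(cb, unif5, restarts = 4, seed = 16)
  psi5 <- directional_derivative(cb, unif5, seq(-1, 1, length.out = 1001),
                                 crit = crit5)
  expect_gt(max(psi5), 0)
})

test_that("equivalence_check passes printed optima and flags others", {
  p1 <- pair_from_set(toxicology_set("normal"), 1)
  set.seed(17)
  ok <- equivalence_check(p1, reference_designs("tox_T_1")$design)
  expect_true(ok$passed)
  bad <- equivalence_check(p1, design(c(0, 600), c(0.5, 0.5)))
  expect_false(bad$passed)
  expect_true(is.finite(bad$argmax_x))
  expect_gt(bad$max_psi, bad$threshold)
  # report exports a (x, psi) table
  df <- as.data.frame(bad)
  expect_named(df, c("x", "psi"))
  expect_equal(nrow(df), length(bad$grid))
})
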