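test_that("Fedorov-Wynn reaches high but not exact efficiency", {
  p1 <- pair_from_set(toxicology_set("normal"), 1)
  ref <- reference_designs("tox_T_1")$design
  set.seed(31)
  refv <- inner_minimize(p1, ref, restarts = 4)$value
  effs <- vapply(1:6, function(s) {
    fw <- fedorov_wynn(p1, n_support = 2, iterations = 100, seed = 300 + s,
                       restarts = 2)
    fw$criterion$value / refv
  }, numeric(1))
  expect_true(all(effs >= 0.97))
  expect_true(all(effs <= 1 + 1e-6))
})

test_that("the exchange direction at an optimum carries zero gain", {
  p1 <- pair_from_set(toxicology_set("normal"), 1)
  ref <- reference_designs("tox_T_1")$design
  set.seed(32)
  cv <- inner_minimize(p1, ref, restarts = 4)
  disc <- discrepancy(p1)
  grid <- seq(0, 1250, length.out = 2001)
  xs <- grid[which.max(disc(grid, cv$theta_hat))]
  # the best exchange candidate is an existing support point, and its
  # discrepancy equals the criterion value (psi = 0): no direction improves
  expect_lt(min(abs(xs - ref$support)), 1250 * 1e-3)
  expect_equal(disc(xs, cv$theta_hat), cv$value, tolerance = 1e-6)
  # mixing toward it with a vanishing step stays near-optimal
  d <- design(c(ref$support, xs), c(0.98 * ref$weights, 0.02))
  d <- canonicalize(d, p1$space)
  v <- inner_minimize(p1, d, restarts = 3)$value
  expect_gte(v, cv$value * (1 - 5e-3))
})

test_that("Remes solves the equioscillating dose-response problem exactly", {
  p1 <- pair_from_set(toxicology_set("normal"), 1)
  for (s in 1:4) {
    rm_ <- remes(p1, n_support = 2, iterations = 60, seed = 400 + s,
                 restarts = 2)
    expect_equal(rm_$design$support, c(0, 1250), tolerance = 1e-3)
    expect_equal(rm_$design$weights, c(0.5, 0.5), tolerance = 1e-3)
  }
})

test_that("the deviation equioscillates at the exact cubic optimum", {
  cb <- cubic_vs_linear_pair()
  dstar <- design(c(-0.5, 0.5, 1), c(1/6, 1/2, 1/3))
  cv <- inner_minimize(cb, dstar, restarts = 6, seed = 41)
  dev <- abs(true_mean(cb, dstar$support) -
               cb$rival$fn(dstar$support, cv$theta_hat))
  expect_lt(max(dev) - min(dev), 1e-4)
})

test_that("Remes is restricted to T-optimality", {
  expect_error(remes(mm_mmm_pair("lognormal"), n_support = 3, seed = 1),
               "T-optimality")
})
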