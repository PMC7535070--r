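test_that("the swarm maximizes a smooth unimodal objective", {
  r <- pso_optimize(function(x) -(x - 0.3)^2, 0, 1,
                    pso_config(32, 200, seed = 1))
  expect_equal(as.numeric(r$par), 0.3, tolerance = 1e-6)
})

test_that("inertia decays linearly over the first 80% then stays constant", {
  iters <- 200
  w <- inertia_weight(seq_len(iters), iters)
  expect_lt(abs(w[1] - 0.95), 0.01)
  expect_equal(w[160], 0.2)                   # end of the decay window
  expect_true(all(w[160:200] == 0.2))
  expect_true(all(diff(w[1:159]) < 0))
  # slope is linear on the decay window
  expect_equal(diff(w[1:159]), rep(diff(w[1:2]), 158), tolerance = 1e-9)
})

test_that("simplex projection and particle repair behave as projections", {
  expect_equal(project_simplex(c(0.7, 0.6, -0.3)), c(0.55, 0.45, 0))
  v <- c(0.2, 0.5, 0.3)
  expect_equal(project_simplex(v), v)

  sp <- design_space(0, 1250)
  feas <- c(100, 600, 900, 0.4, 0.35)    # n = 3, implied p3 = 0.25
  expect_equal(repair_design_particle(feas, sp), feas)
  # weights (0.7, 0.6) imply p3 = -0.3: projected to (0.55, 0.45, 0)
  rep1 <- repair_design_particle(c(10, 20, 30, 0.7, 0.6), sp)
  expect_equal(rep1[4:5], c(0.55, 0.45))
  # out-of-space support is clipped
  expect_equal(repair_design_particle(c(-5, 2000, 0.5), sp)[1:2],
               c(0, 1250))
  # repair is idempotent
  raw <- c(-3, 600, 1300, 0.9, 0.4)
  once <- repair_design_particle(raw, sp)
  expect_equal(repair_design_particle(once, sp), once)
})

test_that("global best is monotone and runs are seed-reproducible", {
  fn <- function(x) sin(5 * x[1]) * cos(3 * x[2]) - 0.1 * sum(x^2)
  r1 <- pso_optimize(fn, c(-2, -2), c(2, 2), pso_config(20, 60, seed = 42))
  r2 <- pso_optimize(fn, c(-2, -2), c(2, 2), pso_config(20, 60, seed = 42))
  expect_identical(r1$par, r2$par)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace) >= 0))
})

test_that("a multimodal objective is solved in most seeded runs", {
  # five local maxima on [0, 4]; dense-grid oracle defines the truth
  fn <- function(x) sin(5 * x) + 0.3 * x
  xs <- seq(0, 4, length.out = 200001)
  truth <- max(fn(xs))
  hits <- 0L
  for (s in 1:10) {
    r <- pso_optimize(fn, 0, 4, pso_config(24, 120, seed = 1000 + s))
    if (abs(r$value - truth) < 1e-6) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("non-finite objectives are tolerated or rejected sensibly", {
  fn <- function(x) if (x[1] < 0.5) NaN else -(x[1] - 0.7)^2
  r <- pso_optimize(fn, 0, 1, pso_config(24, 80, seed = 3))
  expect_equal(as.numeric(r$par), 0.7, tolerance = 1e-4)
  expect_error(pso_optimize(function(x) NaN, 0, 1, pso_config(8, 5, seed = 4)),
               "non-finite")
})
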