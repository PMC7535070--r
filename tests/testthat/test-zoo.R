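test_that("fixture nominal values and spaces match their sources", {
  tox <- toxicology_set("normal")
  expect_equal(tox$theta_tr, c(4.282, 835.571, 0.739, 3.515))
  expect_length(tox$rivals, 4L)
  expect_equal(c(tox$space$x_lo, tox$space$x_hi), c(0, 1250))
  # plateau Weibull at dose 0 collapses to its amplitude
  expect_equal(true_mean(tox, 0), 4.282)

  mmp <- mm_mmm_pair("lognormal")
  expect_equal(mmp$theta_tr, c(1, 1, 1))
  expect_equal(c(mmp$space$x_lo, mmp$space$x_hi), c(0.1, 5))
  expect_equal(true_mean(mmp, 1), 1.5)   # 1/(1+1) + 1

  tp <- trig_poly_set()
  expect_equal(tp$theta_tr, c(4.5, -1.5, -2))
  expect_length(tp$rivals, 2L)
  expect_equal(true_mean(tp, 0), 1.0)    # 4.5 - 1.5 - 2

  lg <- logistic4_set()
  expect_equal(lg$K, 4L)
  expect_equal(lg$theta_tr, c(1, 1, 1))
  expect_equal(true_mean(lg, 1), 3)
  expect_identical(lg$error$tag, "binomial")

  cb <- cubic_vs_linear_pair()
  expect_equal(cb$theta_tr, c(1, 1, 0, 1))

  cq <- constrained_quadratic_pair()
  expect_gte(cq$rival$pspace$lower[2], 1)  # feasibility r >= 1

  fam <- dette_family(3)
  expect_equal(c(fam$tr_lower, fam$tr_upper), c(-1, 1))
  pr <- fam$make_pair(0.5)
  expect_equal(true_mean(pr, 2), 0.5 * 4 + 8)
})

test_that("the reference catalog is well-formed and round-trips", {
  cat_ <- reference_designs()
  expect_gt(length(cat_), 15L)
  for (e in cat_) {
    expect_s3_class(e$design, "design")
    expect_equal(sum(e$design$weights), 1, tolerance = 1e-9)
    txt <- design_to_json(e$design)
    d2 <- design_from_json(txt)
    expect_equal(d2$support, e$design$support, tolerance = 1e-15)
  }
  p2000 <- reference_designs("tox_P2000")$design
  expect_equal(p2000$support, c(0, 270, 350, 450, 580, 750, 970, 1250))
  expect_equal(p2000$weights, rep(1 / 8, 8))
  expect_error(reference_designs("no_such_key"), "unknown")
})

test_that("spot-checked catalog optima satisfy their certificates", {
  set.seed(55)
  for (k in c("tox_T_2", "mm_mmm_gamma", "cubic_4pt")) {
    e <- reference_designs(k)
    pr <- fixture_problem(e$problem)
    ec <- equivalence_check(pr, e$design,
                            crit = inner_minimize(pr, e$design, restarts = 5))
    expect_true(ec$passed, label = paste(k, "certificate"))
  }
})
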