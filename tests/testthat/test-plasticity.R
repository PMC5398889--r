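test_that("running average follows its closed-form recursion", {
  expect_equal(update_running_average(5, 2, 0), 2)
  # constant input: geometric convergence at rate alpha
  xbar <- 0
  for (k in 1:40) xbar <- update_running_average(xbar, 1, 0.8)
  expect_equal(1 - xbar, 0.8^40, tolerance = 1e-12)
  # unit impulse decays as alpha^k
  xbar <- update_running_average(0, 1, 0.6) # impulse absorbed: (1-a)
  for (k in 1:10) xbar <- update_running_average(xbar, 0, 0.6)
  expect_equal(xbar, (1 - 0.6) * 0.6^10, tolerance = 1e-12)
  expect_error(update_running_average(0, 1, 1), "alpha_avg")
})

test_that("supralinear kinds evaluate correctly and are odd", {
  expect_equal(supralinear(0.1, "cubic"), 1e-3)
  expect_equal(supralinear(-2, "signed_square"), -4)
  expect_equal(supralinear(4, "sqrt"), 2)
  expect_equal(supralinear(0.3, "identity"), 0.3)
  grid <- seq(-2, 2, by = 0.13)
  for (k in c("cubic", "signed_square", "identity", "sqrt")) {
    expect_equal(supralinear(0, k), 0)
    expect_equal(supralinear(-grid, k), -supralinear(grid, k))
  }
  expect_error(supralinear(1, "quartic"), "unknown s_kind")
})

test_that("eligibility accumulation matches a scalar loop oracle", {
  # printed single-step example
  e <- accumulate_eligibility(matrix(0, 1, 1), r_prev = 0.5,
                              x = 0.2, xbar = 0, s_kind = "cubic")
  expect_equal(e[1, 1], 1e-3)
  # x == xbar leaves e unchanged
  e0 <- matrix(stats::rnorm(9), 3, 3)
  expect_equal(accumulate_eligibility(e0, c(1, 2, 3), c(4, 5, 6),
                                      c(4, 5, 6)), e0)
  # T random steps equal the sum of single-step increments from an
  # independent scalar loop
  set.seed(8)
  n <- 4; T_steps <- 25
  rs <- matrix(stats::rnorm(T_steps * n), T_steps, n)
  xs <- matrix(stats::rnorm(T_steps * n), T_steps, n)
  xb <- matrix(stats::rnorm(T_steps * n), T_steps, n)
  for (kind in c("cubic", "signed_square", "identity", "sqrt")) {
    e <- matrix(0, n, n)
    for (t in seq_len(T_steps))
      e <- accumulate_eligibility(e, rs[t, ], xs[t, ], xb[t, ], kind)
    oracle <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) for (t in seq_len(T_steps))
      oracle[i, j] <- oracle[i, j] +
        supralinear(rs[t, j] * (xs[t, i] - xb[t, i]), kind)
    expect_equal(e, oracle, tolerance = 1e-12)
  }
})

test_that("the compiled trial accumulator agrees with the R reference", {
  p <- tiny_params(n = 8)
  spec <- blank_spec(120)
  spec$inputs[1:40, 1] <- 1
  for (kind in c("cubic", "signed_square", "identity", "sqrt")) {
    w <- init_canonical_weights(p, seed = 17)
    pl <- plasticity_params(s_kind = kind)
    set.seed(31)
    rec <- run_trial(w, spec, p, plast = pl, record = "full")
    expect_equal(rec$eligibility, reference_eligibility(rec, kind),
                 tolerance = 1e-10)
  }
})

test_that("reward baseline updates follow the per-type running average", {
  bl <- reward_baseline()
  # first trial of a type: baseline initialized at R, so R - rbar = 0
  u1 <- update_baseline(bl, "AA", -0.4)
  expect_equal(u1$rbar_used, -0.4)
  # stored 0, R = 1 -> new stored 0.67
  bl2 <- reward_baseline()
  bl2$rbar <- c(AA = 0); bl2$n_seen <- c(AA = 1L)
  u2 <- update_baseline(bl2, "AA", 1, alpha_trace = 0.33)
  expect_equal(u2$rbar_used, 0)
  expect_equal(unname(u2$baseline$rbar[["AA"]]), 0.67)
  # R equal to the stored value leaves it unchanged
  u3 <- update_baseline(u2$baseline, "AA", 0.67)
  expect_equal(unname(u3$baseline$rbar[["AA"]]), 0.67)
  # convergence for iid rewards: error halves every ~1.7 trials
  bl4 <- reward_baseline()
  bl4$rbar <- c(z = 1); bl4$n_seen <- c(z = 1L)
  for (k in 1:30) bl4 <- update_baseline(bl4, "z", 0)$baseline
  expect_equal(unname(bl4$rbar[["z"]]), 0.33^30, tolerance = 1e-12)
})

test_that("weight updates are clipped elementwise and Dale signs enforced", {
  p <- tiny_params(n = 8)
  pl <- plasticity_params(eta = 1)
  J <- matrix(0, 8, 8)
  e <- matrix(0, 8, 8); e[2, 3] <- 3e-4
  # R == rbar: no change
  expect_equal(unclass(apply_weight_update(J, e, -0.5, -0.5, pl, p)),
               J, ignore_attr = TRUE)
  # proposed change 3e-4 is clipped to exactly 1e-4
  J2 <- apply_weight_update(J, e, 1, 0, pl, p)
  expect_equal(J2[2, 3], 1e-4)
  expect_equal(attr(J2, "clipped_fraction"), 1 / 64)
  # Dale: small excitatory weight driven negative clamps at 0
  pd <- tiny_params(n = 8, variant = "dale")
  Jd <- matrix(0, 8, 8); Jd[1, 2] <- 5e-5
  ed <- matrix(0, 8, 8); ed[1, 2] <- -1e-4
  Jd2 <- apply_weight_update(Jd, ed, 1, 0, pl, pd)
  expect_equal(Jd2[1, 2], 0)
  # inhibitory column capped at 0 from above
  Ji <- matrix(0, 8, 8); ei <- matrix(0, 8, 8); ei[1, 6] <- 1e-4
  expect_equal(apply_weight_update(Ji, ei, 1, 0, pl, pd)[1, 6], 0)
  expect_error(apply_weight_update(J, e * NA, 1, 0, pl, p), "non-finite")
})

test_that("relaxation terms cancel over a long constant-input episode", {
  # a settled neuron receives one perturbation; the summed deviation from the
  # running average telescopes back to ~0 once the trace has relaxed
  tau <- 30; dt <- 1; alpha <- plasticity_params()$alpha_avg
  u <- 0.5
  x <- u; xbar <- x
  devs <- numeric(1000)
  for (t in 1:1000) {
    x <- x + (dt / tau) * (-x + u)
    if (t == 100) x <- x + 0.5
    xbar <- update_running_average(xbar, x, alpha)
    devs[t] <- x - xbar
  }
  peak <- max(abs(devs))
  expect_gt(peak, 0.1)                     # the perturbation was visible
  expect_lt(abs(sum(devs)), 0.01 * peak)   # ... and cancels in the sum
})

test_that("weights stay constant when learning is disabled", {
  fit0 <- train_rmhebb("dnms", n_trials = 3, seed = 4, eta = 0)
  expect_identical(fit0$weights$J, fit0$weights_init$J)
  # zero perturbations and matched reward baseline also freeze the weights
  p <- tiny_params(n = 8)
  w <- init_canonical_weights(p, seed = 2)
  spec <- blank_spec(100)
  rec <- run_trial(w, spec, p, perturbation_config(rate_hz = 0),
                   plast = plasticity_params())
  J2 <- apply_weight_update(w$J, rec$eligibility, -1, -1,
                            plasticity_params(), p)
  expect_equal(unclass(J2), w$J, ignore_attr = TRUE)
})
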