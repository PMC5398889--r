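# planted binary code: class +1/-1 along a fixed population direction
static_code_tensor <- function(n_trials = 24, n_time = 20, n_neurons = 30,
                               noise_sd = 0, seed = 1) {
  set.seed(seed)
  values <- rep(c(1, -1), length.out = n_trials)
  dir1 <- stats::rnorm(n_neurons); dir1 <- dir1 / sqrt(sum(dir1^2))
  tens <- planted_code_fixture(n_trials, n_time, n_neurons,
                               codes = list(list(name = "cls", values = values,
                                                 direction = dir1,
                                                 timecourse = rep(1, n_time))),
                               noise_sd = noise_sd)
  tens
}

test_that("activity sampling produces the expected tensor layout", {
  p <- network_params(n_neurons = 20)
  w <- init_canonical_weights(p, seed = 70)
  set.seed(70)
  recs <- lapply(1:4, function(i)
    run_trial(w, make_dnms_trial(dnms_config()), p, record = "full"))
  tens <- sample_activity(recs, period_ms = 10)
  expect_equal(dim(tens$data), c(4, 100, 20))
  expect_equal(nrow(tens$labels), 4)
  # row t is the response at time t * period
  expect_equal(tens$data[2, 7, ], recs[[2]]$activity[70, ])
  # constant traces sample to identical rows; a linear ramp stays arithmetic
  recs[[1]]$activity[] <- 1
  recs[[1]]$activity[, 3] <- seq_len(1000)
  tens2 <- sample_activity(recs[1], period_ms = 10)
  expect_equal(tens2$data[1, , 3], seq(10, 1000, by = 10))
  expect_true(all(tens2$data[1, , 1] == 1))
  # mixed durations are rejected
  short <- run_trial(w, blank_spec(500), p, record = "full")
  expect_error(sample_activity(list(recs[[1]], short)), "mixed durations")
})

test_that("cross-temporal decoding separates planted static codes", {
  tens <- static_code_tensor(noise_sd = 0.05)
  acc <- crosstemporal_decode(tens, category = function(lb) lb$cls,
                              n_iterations = 20)
  expect_true(all(acc >= 0 & acc <= 1))
  expect_gt(mean(acc), 0.97)      # separable static code decodes everywhere

  # permuted labels fall to chance
  set.seed(2)
  perm <- sample(tens$labels$cls)
  acc0 <- crosstemporal_decode(tens, category = perm, n_iterations = 20)
  # grand mean within the binomial 99% band around 0.5 (12 test trials x
  # 20 iterations, correlated across cells; use a generous 3 SE band on the
  # per-iteration mean)
  expect_lt(abs(mean(acc0) - 0.5), 0.15)
})

test_that("a code that switches direction mid-trial shows a bottleneck", {
  set.seed(3)
  n_time <- 20; n_neurons <- 40; n_trials <- 24
  values <- rep(c(1, -1), length.out = n_trials)
  dd <- qr.Q(qr(matrix(stats::rnorm(n_neurons * 2), n_neurons, 2)))
  d1 <- dd[, 1]; d2 <- dd[, 2]
  tens <- planted_code_fixture(n_trials, n_time, n_neurons,
    codes = list(
      list(name = "cls", values = values, direction = d1,
           timecourse = c(rep(1, 10), rep(0, 10))),
      list(name = "cls2", values = values, direction = d2,
           timecourse = c(rep(0, 10), rep(1, 10)))),
    noise_sd = 0.05)
  acc <- crosstemporal_decode(tens, category = function(lb) lb$cls,
                              n_iterations = 20)
  on_diag <- mean(c(diag(acc)[1:10], diag(acc)[11:20]))
  cross <- mean(c(acc[1:10, 11:20], acc[11:20, 1:10]))
  expect_gt(on_diag, 0.95)
  expect_lt(abs(cross - 0.5), 0.15)
  expect_gt(on_diag - cross, 0.3)
})

test_that("regression axes recover planted directions and orthonormalize", {
  set.seed(4)
  n_neurons <- 50; n_trials <- 60; n_time <- 15
  dirs <- qr.Q(qr(matrix(stats::rnorm(n_neurons * 3), n_neurons, 3)))
  vals <- list(stats::rnorm(n_trials), stats::rnorm(n_trials),
               stats::rnorm(n_trials))
  tens <- planted_code_fixture(n_trials, n_time, n_neurons,
    codes = list(
      list(name = "f1", values = vals[[1]], direction = dirs[, 1],
           timecourse = rep(1, n_time)),
      list(name = "f2", values = vals[[2]], direction = dirs[, 2],
           timecourse = seq(0, 1, length.out = n_time)),
      list(name = "f3", values = vals[[3]], direction = dirs[, 3],
           timecourse = rep(0.5, n_time))),
    noise_sd = 0.05)
  feats <- data.frame(f1 = vals[[1]], f2 = vals[[2]], f3 = vals[[3]])
  ax <- regression_axes(tens, feats)
  # orthonormal output
  expect_equal(crossprod(ax$ortho), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # recovered raw vectors align with the planted directions
  for (f in 1:3) {
    cosang <- abs(sum(ax$raw[, f] * dirs[, f])) /
      sqrt(sum(ax$raw[, f]^2))
    expect_gt(cosang, 0.9)
  }
  # first orthogonal axis is the normalized first raw vector
  v1 <- ax$raw[, 1] / sqrt(sum(ax$raw[, 1]^2))
  expect_equal(abs(sum(v1 * ax$ortho[, 1])), 1, tolerance = 1e-10)
  # zero-variance feature is rejected by name
  feats$f2 <- 0
  expect_error(regression_axes(tens, feats), "f2")
})

test_that("trajectory projection averages correct trials by group", {
  set.seed(5)
  n_trials <- 40; n_time <- 10; n_neurons <- 20
  ctx <- rep(1:2, each = 20)
  bias <- rep(c(-0.5, -0.1, 0.1, 0.5), 10)  # 4 levels: sign() not collinear
  choice <- ifelse(bias > 0, 1, -1)
  dirs <- qr.Q(qr(matrix(stats::rnorm(n_neurons * 2), n_neurons, 2)))
  tens <- planted_code_fixture(n_trials, n_time, n_neurons,
    codes = list(
      list(name = "choice", values = choice, direction = dirs[, 1],
           timecourse = seq(0, 1, length.out = n_time)),
      list(name = "bias", values = bias, direction = dirs[, 2],
           timecourse = rep(1, n_time))),
    noise_sd = 0.01,
    labels = data.frame(context = ctx, correct = rep(TRUE, n_trials)))
  ax <- regression_axes(tens, data.frame(choice = choice, bias = bias))
  traj <- project_trajectories(tens, ax, c("context", "bias", "choice"))
  # bias fully determines choice among correct trials: 2 contexts x 4 biases
  expect_equal(length(unique(interaction(traj$context, traj$bias,
                                         traj$choice, drop = TRUE))), 8)
  # projections recover the planted time courses (choice axis ramps)
  tr1 <- traj[traj$context == 1 & traj$bias == 0.5 &
                traj$feature == "choice", ]
  expect_equal(tr1$value, seq(0, 1, length.out = n_time) *
                 sum(dirs[, 1] * ax$ortho[, 1]), tolerance = 0.05)
  # a correctness filter removes groups: mark positive-bias trials of
  # context 1 incorrect and the corresponding groups disappear
  tens$labels$correct[ctx == 1 & bias > 0] <- FALSE
  traj2 <- project_trajectories(tens, ax, c("context", "bias", "choice"))
  expect_equal(length(unique(interaction(traj2$context, traj2$bias,
                                         traj2$choice, drop = TRUE))), 6)
  # projecting onto an extra zero axis gives zero coordinates
  ax0 <- ax
  ax0$ortho <- cbind(ax0$ortho, 0)
  ax0$features <- c(ax0$features, "null")
  traj0 <- project_trajectories(tens, ax0, c("context"))
  expect_true(all(traj0$value[traj0$feature == "null"] == 0))
})

test_that("noise-only fixtures decode at chance", {
  set.seed(6)
  tens <- planted_code_fixture(20, 10, 15, codes = list(), noise_sd = 1,
                               labels = data.frame(cls = rep(c("a", "b"), 10)))
  acc <- crosstemporal_decode(tens, category = function(lb) lb$cls,
                              n_iterations = 30)
  expect_lt(abs(mean(acc) - 0.5), 0.15)
})
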