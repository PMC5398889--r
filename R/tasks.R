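#' Delayed nonmatch-to-sample task configuration
#'
#' Two stimuli (A or B, coded on two one-hot input channels) are presented in
#' sequence with an intervening delay; the network must report whether they
#' differ. Variants:
#' \describe{
#'   \item{standard}{200 ms stimuli, 200 ms delay, 1000 ms trials,
#'     targets -1 (match) / +1 (nonmatch).}
#'   \item{long_delay}{400 ms stimuli, 1000 ms delay, 2000 ms trials.}
#'   \item{variable_delay}{300 ms stimuli, delay drawn uniformly from
#'     300--800 ms, 1600 ms trials.}
#'   \item{dale}{standard timing, targets 0 (match) / 5 (nonmatch) for the
#'     nonnegative-response network; the correctness threshold is 2.5.}
#' }
#' The response window is always the last 200 ms of the trial.
#'
#' @param variant One of `"standard"`, `"long_delay"`, `"variable_delay"`,
#'   `"dale"`.
#' @return An object of class `rmh_dnms_config`.
#' @export
dnms_config <- function(variant = c("standard", "long_delay",
                                    "variable_delay", "dale")) {
  variant <- match.arg(variant)
  cfg <- switch(variant,
    standard = list(stim_ms = 200, delay_ms = 200, duration_ms = 1000,
                    targets = c(match = -1, nonmatch = 1), err_thresh = 1),
    long_delay = list(stim_ms = 400, delay_ms = 1000, duration_ms = 2000,
                      targets = c(match = -1, nonmatch = 1), err_thresh = 1),
    variable_delay = list(stim_ms = 300, delay_range_ms = c(300, 800),
                          duration_ms = 1600,
                          targets = c(match = -1, nonmatch = 1),
                          err_thresh = 1),
    dale = list(stim_ms = 200, delay_ms = 200, duration_ms = 1000,
                targets = c(match = 0, nonmatch = 5), err_thresh = 2.5))
  cfg$variant <- variant
  cfg$response_ms <- 200
  structure(cfg, class = "rmh_dnms_config")
}

# step indices (1-based, half-open ms windows [start, end) on the dt grid)
window_steps <- function(start_ms, end_ms, dt_ms) {
  seq.int(start_ms / dt_ms + 1L, end_ms / dt_ms)
}

#' Generate one delayed nonmatch-to-sample trial
#'
#' Stimulus A activates input channel 1 (u = (1, 0)), stimulus B channel 2
#' (u = (0, 1)); channels are zero outside the two presentation windows.
#'
#' @param cfg A [dnms_config()].
#' @param stim1,stim2 `"A"` or `"B"`. Defaults draw each uniformly.
#' @param dt_ms Integration step in ms.
#' @return An object of class `rmh_trial_spec`: list with `inputs`
#'   (T x 2 matrix), `target`, `response_window_ms`, `duration_ms`,
#'   `trial_type` (`"AA"`, `"AB"`, `"BA"`, `"BB"`) and task metadata.
#' @export
make_dnms_trial <- function(cfg, stim1 = NULL, stim2 = NULL, dt_ms = 1) {
  if (is.null(stim1)) stim1 <- sample(c("A", "B"), 1)
  if (is.null(stim2)) stim2 <- sample(c("A", "B"), 1)
  stopifnot(stim1 %in% c("A", "B"), stim2 %in% c("A", "B"))
  delay <- if (cfg$variant == "variable_delay")
    stats::runif(1, cfg$delay_range_ms[1], cfg$delay_range_ms[2])
  else cfg$delay_ms
  delay <- round(delay / dt_ms) * dt_ms
  T_steps <- as.integer(cfg$duration_ms / dt_ms)
  inputs <- matrix(0, T_steps, 2)
  chan <- function(s) if (s == "A") 1L else 2L
  w1 <- window_steps(0, cfg$stim_ms, dt_ms)
  w2 <- window_steps(cfg$stim_ms + delay, 2 * cfg$stim_ms + delay, dt_ms)
  inputs[w1, chan(stim1)] <- 1
  inputs[w2, chan(stim2)] <- 1
  target <- unname(if (stim1 == stim2) cfg$targets["match"]
                   else cfg$targets["nonmatch"])
  structure(list(
    inputs = inputs, target = target,
    response_window_ms = c(cfg$duration_ms - cfg$response_ms,
                           cfg$duration_ms),
    duration_ms = cfg$duration_ms, dt_ms = dt_ms,
    trial_type = paste0(stim1, stim2),
    metadata = list(task = "dnms", variant = cfg$variant,
                    stim1 = stim1, stim2 = stim2, delay_ms = delay)),
    class = "rmh_trial_spec")
}

#' Selective-integration task configuration
#'
#' Two noisy sensory channels (Gaussian per-step samples with per-trial mean,
#' or bias) are shown for the first 500 ms; two binary context channels,
#' constant over the whole trial, cue which sensory modality is relevant. The
#' network must output +1 if the cued modality's bias is positive, -1
#' otherwise, over a 200 ms response period (700 ms trials). Training uses
#' biases of +/-0.5; psychometric testing sweeps an 11-point grid from -0.5
#' to 0.5 in steps of 0.1.
#'
#' @param stim_ms Sensory presentation duration (500).
#' @param response_ms Response period duration (200).
#' @param noise_sd Per-step Gaussian noise SD of the sensory channels (1).
#' @return An object of class `rmh_selint_config`.
#' @export
selint_config <- function(stim_ms = 500, response_ms = 200, noise_sd = 1) {
  structure(list(stim_ms = stim_ms, response_ms = response_ms,
                 duration_ms = stim_ms + response_ms,
                 train_bias_set = c(-0.5, 0.5),
                 test_bias_grid = seq(-0.5, 0.5, by = 0.1),
                 noise_sd = noise_sd, err_thresh = 1),
            class = "rmh_selint_config")
}

#' Generate one selective-integration trial
#'
#' @param cfg A [selint_config()].
#' @param context 1 or 2: which sensory modality is relevant. Default random.
#' @param bias1,bias2 Biases (means) of the two sensory channels in
#'   `[-0.5, 0.5]`. Defaults draw from the training set `{-0.5, +0.5}`.
#' @param dt_ms Integration step in ms.
#' @param strict If `TRUE` (default), a relevant-modality bias of exactly 0 is
#'   an error (the target is undefined); with `strict = FALSE` the trial is
#'   generated with `target = NA` (used for psychometric testing).
#' @return An `rmh_trial_spec` with 4 input channels (2 sensory, 2 context)
#'   and trial type `(context, sign bias1, sign bias2)`.
#' @export
make_selective_integration_trial <- function(cfg, context = NULL,
                                             bias1 = NULL, bias2 = NULL,
                                             dt_ms = 1, strict = TRUE) {
  if (is.null(context)) context <- sample(1:2, 1)
  if (is.null(bias1)) bias1 <- sample(cfg$train_bias_set, 1)
  if (is.null(bias2)) bias2 <- sample(cfg$train_bias_set, 1)
  stopifnot(context %in% 1:2)
  if (abs(bias1) > 0.5 || abs(bias2) > 0.5)
    stop("invalid parameter: biases must lie in [-0.5, 0.5]")
  rel_bias <- if (context == 1) bias1 else bias2
  if (rel_bias == 0 && strict)
    stop("invalid parameter: relevant-modality bias of 0 has no defined target")
  T_steps <- as.integer(cfg$duration_ms / dt_ms)
  stim_steps <- window_steps(0, cfg$stim_ms, dt_ms)
  inputs <- matrix(0, T_steps, 4)
  inputs[stim_steps, 1] <- stats::rnorm(length(stim_steps), bias1, cfg$noise_sd)
  inputs[stim_steps, 2] <- stats::rnorm(length(stim_steps), bias2, cfg$noise_sd)
  inputs[, 3] <- as.numeric(context == 1)
  inputs[, 4] <- as.numeric(context == 2)
  target <- if (rel_bias == 0) NA_real_ else if (rel_bias > 0) 1 else -1
  structure(list(
    inputs = inputs, target = target,
    response_window_ms = c(cfg$stim_ms, cfg$duration_ms),
    duration_ms = cfg$duration_ms, dt_ms = dt_ms,
    trial_type = paste0("ctx", context, ":", sign(bias1), ":", sign(bias2)),
    metadata = list(task = "selint", context = context,
                    bias1 = bias1, bias2 = bias2)),
    class = "rmh_trial_spec")
}

#' Generate one sign-discrimination episode (gradient-comparison task)
#'
#' A vector of `n_inputs` constant values, drawn i.i.d. uniform on
#' \eqn{[-1, 1]}, is presented for 100 ms; after a 100 ms delay the output
#' neuron must report the sign of the input mean over the final 100 ms
#' (300 ms episodes). The spec of a single scheduled perturbation -- random
#' sign, magnitude 0.5, at the midpoint of the response window -- is stored in
#' the metadata; [run_trial()] applies it when asked.
#'
#' @param n_inputs Number of constant input channels (default 10).
#' @param dt_ms Integration step in ms.
#' @param pert_neuron Neuron receiving the scheduled perturbation (default 1,
#'   the output neuron).
#' @return An `rmh_trial_spec`.
#' @export
make_sign_trial <- function(n_inputs = 10, dt_ms = 1, pert_neuron = 1L) {
  repeat {
    vals <- stats::runif(n_inputs, -1, 1)
    if (mean(vals) != 0) break
  }
  duration <- 300
  T_steps <- as.integer(duration / dt_ms)
  inputs <- matrix(0, T_steps, n_inputs)
  inputs[window_steps(0, 100, dt_ms), ] <-
    matrix(vals, nrow = 100 / dt_ms, ncol = n_inputs, byrow = TRUE)
  structure(list(
    inputs = inputs, target = sign(mean(vals)),
    response_window_ms = c(200, 300),
    duration_ms = duration, dt_ms = dt_ms,
    trial_type = if (mean(vals) > 0) "pos" else "neg",
    metadata = list(task = "sign", values = vals,
                    sched_pert = list(time_ms = 250, neuron = pert_neuron,
                                      amplitude = 0.5 * sample(c(-1, 1), 1)))),
    class = "rmh_trial_spec")
}

#' Trial error and reward
#'
#' The error of a trial is the mean absolute difference between the output
#' neuron's response and the target over the response window; the reward is
#' its negative.
#'
#' @param output_trace Numeric vector (or 1-column matrix) of the output
#'   neuron's response over the whole trial.
#' @param target Scalar target response.
#' @param window_steps Integer indices of the response window within the
#'   trace.
#' @return Scalar error (`trial_reward()` returns its negative).
#' @export
trial_error <- function(output_trace, target, window_steps) {
  output_trace <- as.numeric(output_trace)
  if (length(window_steps) == 0)
    stop("invalid parameter: empty response window")
  if (max(window_steps) > length(output_trace) || min(window_steps) < 1)
    stop("invalid parameter: response window outside trace")
  mean(abs(output_trace[window_steps] - target))
}

#' @rdname trial_error
#' @export
trial_reward <- function(output_trace, target, window_steps) {
  -trial_error(output_trace, target, window_steps)
}

#' Has the performance criterion been reached?
#'
#' TRUE iff at least `k` of the last `n` trial errors are below `err_thresh`
#' (95 of 100 below 1 for the canonical tasks; below 2.5 for the Dale
#' variant). Always FALSE while fewer than `n` trials have been seen.
#'
#' @param error_history Numeric vector of per-trial errors, oldest first.
#' @param err_thresh Correctness threshold (default 1).
#' @param k,n Criterion counts (default 95 of 100).
#' @return Logical scalar.
#' @export
criterion_reached <- function(error_history, err_thresh = 1, k = 95, n = 100) {
  if (length(error_history) < n) return(FALSE)
  last <- error_history[seq.int(length(error_history) - n + 1L,
                                length(error_history))]
  sum(last < err_thresh) >= k
}
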