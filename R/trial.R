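#' Simulate one trial
#'
#' Runs the network over a whole trial: activations are reset to uniform
#' \eqn{[-0.1, 0.1]} noise (bias neurons clamped to 1), the eligibility trace
#' is reset to zero, and every step applies the Euler update, random
#' perturbations, the bias clamp, the running-average update and (if `plast`
#' is given) the eligibility accumulation. Weights are never modified inside
#' a trial; learning happens between trials via [apply_weight_update()].
#'
#' @param weights An `rmh_weights` object.
#' @param spec An `rmh_trial_spec` (see [make_dnms_trial()] and friends).
#' @param params An [network_params()] object.
#' @param pert A [perturbation_config()]; use `rate_hz = 0` to disable random
#'   perturbations.
#' @param plast A [plasticity_params()] object, or `NULL` to skip eligibility
#'   accumulation. Its `alpha_avg` drives the running average in either case.
#' @param record `"output"` (default, output trace only) or `"full"` (also
#'   store activity, potentials and the running average at every step, as
#'   needed by the decoding and gradient analyses).
#' @param scheduled_pert Optional list(time_ms, neuron, amplitude): a single
#'   deterministic perturbation, as used in the gradient-comparison episodes.
#'   Defaults to `spec$metadata$sched_pert` only when `apply_sched = TRUE`.
#' @param apply_sched Apply the spec's scheduled perturbation (default FALSE).
#' @param x_init Optional initial activation vector overriding the random
#'   reset (used to replay an episode, e.g. for the unperturbed baseline run).
#' @param alpha_avg Running-average coefficient when `plast` is `NULL`.
#' @return An object of class `rmh_trial_record`: list with `output_trace`,
#'   `perturbations` (data.frame step/neuron/delta), `eligibility` (if
#'   `plast` given), `reward`, `error`, `trial_type`, `r_range`, `x0`, `r0`,
#'   and (if `record = "full"`) `activity`, `potentials`, `xbars` (T x N).
#' @export
run_trial <- function(weights, spec, params,
                      pert = perturbation_config(),
                      plast = NULL,
                      record = c("output", "full"),
                      scheduled_pert = NULL, apply_sched = FALSE,
                      x_init = NULL, alpha_avg = 0.33) {
  record <- match.arg(record)
  stopifnot(inherits(spec, "rmh_trial_spec"))
  if (spec$duration_ms %% params$dt_ms != 0)
    stop("invalid parameter: trial duration not divisible by dt")
  if (ncol(spec$inputs) != params$n_inputs)
    stop("invalid parameter: spec has ", ncol(spec$inputs),
         " input channels but params$n_inputs = ", params$n_inputs)
  p_step <- pert$rate_hz * params$dt_ms / 1000
  if (p_step > 1)
    stop("invalid parameter: per-step perturbation probability > 1")
  if (is.null(scheduled_pert) && apply_sched)
    scheduled_pert <- spec$metadata$sched_pert
  sched_step <- -1L; sched_neuron <- -1L; sched_amp <- 0
  if (!is.null(scheduled_pert)) {
    sched_step <- as.integer(scheduled_pert$time_ms / params$dt_ms) - 1L
    sched_neuron <- as.integer(scheduled_pert$neuron) - 1L
    sched_amp <- scheduled_pert$amplitude
  }
  d <- params$dale
  aavg <- if (is.null(plast)) alpha_avg else plast$alpha_avg
  res <- .sim_trial_cpp(
    weights$J, weights$B, spec$inputs,
    params$bias_indices - 1L,
    if (params$variant == "canonical") 0L else 1L,
    if (is.null(d)) 0 else d$m, if (is.null(d)) 0 else d$M_sat,
    params$dt_ms, params$tau_ms,
    p_step, pert$amplitude_low, pert$amplitude_high,
    !is.null(plast), if (is.null(plast)) 0L else s_kind_code(plast$s_kind),
    aavg, record == "full",
    sched_step, sched_neuron, sched_amp,
    x_init, params$output_indices - 1L)

  rec <- list(
    output_trace = res$output_trace,
    perturbations = data.frame(step = res$pert_step, neuron = res$pert_neuron,
                               delta = res$pert_amp),
    inputs = spec$inputs,
    eligibility = res$eligibility,
    trial_type = spec$trial_type,
    target = spec$target,
    response_steps = window_steps(spec$response_window_ms[1],
                                  spec$response_window_ms[2], params$dt_ms),
    duration_ms = spec$duration_ms, dt_ms = params$dt_ms,
    r_range = res$r_range,
    x0 = drop(res$x0), r0 = drop(res$r0),
    metadata = spec$metadata)
  if (record == "full") {
    rec$activity <- res$activity
    rec$potentials <- res$potentials
    rec$xbars <- res$xbars
  }
  if (!is.na(spec$target)) {
    rec$error <- trial_error(rec$output_trace[, 1], spec$target,
                             rec$response_steps)
    rec$reward <- -rec$error
  } else {
    rec$error <- NA_real_
    rec$reward <- NA_real_
  }
  class(rec) <- "rmh_trial_record"
  rec
}
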