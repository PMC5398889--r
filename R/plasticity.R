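#' Plasticity parameters for the reward-modulated Hebbian rule
#'
#' During a trial every synapse accumulates a potential Hebbian weight change
#' (eligibility trace)
#' \deqn{e_{ij}(t) = e_{ij}(t-1) + S\left(r_j(t-1)\,(x_i(t) - \bar{x}_i(t))\right),}
#' where S is a monotonic supralinear function (cubic by default) and
#' \eqn{\bar{x}} is a fast running average of the activation. At the end of
#' the trial the trace is converted into an actual change
#' \eqn{\Delta J_{ij} = \eta\, e_{ij}\,(R - \bar{R})}, elementwise clipped to
#' `clip_abs`, where \eqn{\bar{R}} is a per-trial-type running average of past
#' rewards.
#'
#' @param eta Learning rate \eqn{\eta} (default 0.5; long-delay and
#'   variable-delay task variants use smaller task-specific defaults).
#' @param clip_abs Elementwise cap on the per-trial |weight change|
#'   (default 1e-4).
#' @param alpha_trace Smoothing coefficient of the per-trial-type reward
#'   baseline (default 0.33).
#' @param s_kind Supralinear amplification: `"cubic"` (default),
#'   `"signed_square"`, `"identity"` (ablation, no amplification), or
#'   `"sqrt"` (sublinear ablation, signed square root).
#' @param alpha_avg Per-step coefficient of the running average \eqn{\bar{x}}
#'   (default 0.33 at dt = 1 ms, the same smoothing constant as the reward
#'   trace: an ~1.5 ms averaging window, much faster than the mean 333 ms
#'   inter-perturbation interval. This default also reproduces the expected
#'   clipped-update fraction of roughly 10 percent on the standard task; see
#'   the methods vignette.)
#' @return An object of class `rmh_plasticity_params`.
#' @export
plasticity_params <- function(eta = 0.5, clip_abs = 1e-4, alpha_trace = 0.33,
                              s_kind = c("cubic", "signed_square",
                                         "identity", "sqrt"),
                              alpha_avg = 0.33) {
  s_kind <- match.arg(s_kind)
  if (eta < 0) stop("invalid parameter: eta must be >= 0")
  if (clip_abs <= 0) stop("invalid parameter: clip_abs must be > 0")
  if (alpha_trace <= 0 || alpha_trace >= 1)
    stop("invalid parameter: alpha_trace must be in (0,1)")
  if (alpha_avg < 0 || alpha_avg >= 1)
    stop("invalid parameter: alpha_avg must be in [0,1)")
  structure(list(eta = eta, clip_abs = clip_abs, alpha_trace = alpha_trace,
                 s_kind = s_kind, alpha_avg = alpha_avg),
            class = "rmh_plasticity_params")
}

# integer code used by the compiled simulator
s_kind_code <- function(s_kind) {
  match(s_kind, c("cubic", "signed_square", "identity", "sqrt")) - 1L
}

#' Supralinear amplification function S
#'
#' `cubic`: \eqn{v^3}; `signed_square`: \eqn{v |v|}; `identity`: \eqn{v};
#' `sqrt`: \eqn{\mathrm{sign}(v)\sqrt{|v|}}. All are odd and monotonic; only
#' the first two are supralinear.
#'
#' @param v Numeric vector.
#' @param s_kind One of `"cubic"`, `"signed_square"`, `"identity"`, `"sqrt"`.
#' @return Numeric vector, S applied elementwise.
#' @export
supralinear <- function(v, s_kind = "cubic") {
  switch(s_kind,
         cubic = v^3,
         signed_square = v * abs(v),
         identity = v,
         sqrt = sign(v) * sqrt(abs(v)),
         stop("invalid parameter: unknown s_kind '", s_kind, "'"))
}

#' Update the running average of activations
#'
#' \eqn{\bar{x}' = \alpha \bar{x} + (1 - \alpha) x}, elementwise.
#'
#' @param xbar Current running average.
#' @param x Current activation vector.
#' @param alpha_avg Coefficient in `[0, 1)`.
#' @return Updated running average.
#' @export
update_running_average <- function(xbar, x, alpha_avg) {
  if (alpha_avg < 0 || alpha_avg >= 1)
    stop("invalid parameter: alpha_avg must be in [0,1)")
  alpha_avg * xbar + (1 - alpha_avg) * x
}

#' Accumulate the Hebbian eligibility trace for one step (reference)
#'
#' Adds \eqn{S(r_j(t-1)\,(x_i(t) - \bar{x}_i(t)))} to every entry
#' \eqn{e_{ij}}. This reference implementation evaluates the elementwise
#' definition directly; the compiled trial simulator uses an algebraically
#' equivalent rank-1 formulation, and the two are compared in the test suite.
#'
#' @param e Eligibility matrix (n x n), row i = synapses into neuron i.
#' @param r_prev Responses at the previous step (presynaptic inputs).
#' @param x Activations at the current step.
#' @param xbar Running average of activations at the current step.
#' @param s_kind Supralinear kind, see [supralinear()].
#' @return Updated eligibility matrix.
#' @export
accumulate_eligibility <- function(e, r_prev, x, xbar, s_kind = "cubic") {
  e + supralinear(outer(x - xbar, r_prev), s_kind)
}

#' Create an empty per-trial-type reward baseline
#'
#' The expected reward \eqn{\bar{R}} is tracked separately for every trial
#' type (combination of inputs), as an exponential running average of past
#' rewards of that type.
#'
#' @return An object of class `rmh_reward_baseline` (empty table).
#' @export
reward_baseline <- function() {
  structure(list(rbar = numeric(0), n_seen = integer(0)),
            class = "rmh_reward_baseline")
}

#' Update the reward baseline for one trial
#'
#' Returns the baseline used for this trial's weight update and the updated
#' baseline table. On the first trial of a type the baseline is initialized at
#' the observed reward (so \eqn{R - \bar{R} = 0} and no learning occurs on
#' that trial); afterwards the stored value is the pre-trial expectation and
#' is updated as
#' \eqn{\bar{R}(n) = \alpha_{trace}\bar{R}(n-1) + (1-\alpha_{trace})R(n)}.
#'
#' @param bl An `rmh_reward_baseline` object.
#' @param trial_type Character label of the trial type.
#' @param R Scalar reward for this trial.
#' @param alpha_trace Smoothing coefficient (default 0.33).
#' @return A list with `rbar_used` (scalar) and `baseline` (updated table).
#' @export
update_baseline <- function(bl, trial_type, R, alpha_trace = 0.33) {
  if (!is.finite(R)) stop("invalid parameter: reward must be finite")
  i <- match(trial_type, names(bl$rbar))
  if (is.na(i)) {
    bl$rbar <- c(bl$rbar, stats::setNames(R, trial_type))
    bl$n_seen <- c(bl$n_seen, stats::setNames(1L, trial_type))
    rbar_used <- R
  } else {
    rbar_used <- bl$rbar[[i]]
    bl$rbar[[i]] <- alpha_trace * bl$rbar[[i]] + (1 - alpha_trace) * R
    bl$n_seen[[i]] <- bl$n_seen[[i]] + 1L
  }
  list(rbar_used = rbar_used, baseline = bl)
}

#' Apply the end-of-trial weight update
#'
#' \eqn{\Delta J = \mathrm{clamp}(\eta\, e\, (R - \bar{R}),\ \pm clip_{abs})}
#' elementwise, added to J. For the Dale variant, columns from excitatory
#' neurons are then floored at 0 and columns from inhibitory neurons capped at
#' 0, preserving the sign structure at all times.
#'
#' @param J Recurrent weight matrix.
#' @param e Eligibility matrix (same shape).
#' @param R Trial reward.
#' @param rbar Baseline (expected) reward used for this trial.
#' @param plast A [plasticity_params()] object.
#' @param params An [network_params()] object (for the variant and, for Dale,
#'   the population split).
#' @return The updated weight matrix, with an attribute `clipped_fraction`
#'   giving the fraction of entries whose update hit the cap.
#' @export
apply_weight_update <- function(J, e, R, rbar, plast, params) {
  dJ <- plast$eta * e * (R - rbar)
  if (any(!is.finite(dJ)))
    stop("numerical failure: non-finite weight update")
  clipped <- mean(abs(dJ) > plast$clip_abs)
  dJ <- pmin(pmax(dJ, -plast$clip_abs), plast$clip_abs)
  J <- J + dJ
  if (params$variant == "dale") {
    d <- params$dale
    exc <- seq_len(d$n_exc)
    inh <- d$n_exc + seq_len(d$n_inh)
    J[, exc] <- pmax(J[, exc], 0)
    J[, inh] <- pmin(J[, inh], 0)
  }
  attr(J, "clipped_fraction") <- clipped
  J
}
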