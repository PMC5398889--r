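#' Node-perturbation gradient for one episode
#'
#' The node-perturbation (REINFORCE-style) weight update uses the injected
#' perturbations themselves as credit signals: the eligibility is
#' \eqn{e_{ij} = \sum_t \xi_i(t)\, r_j(t-1)} (the perturbation received by the
#' postsynaptic neuron times the presynaptic input at that step), and the
#' gradient is \eqn{\eta\, e\, (R - R_0)} where \eqn{R_0} is the expected
#' reward without perturbation. It is the ground truth against which the
#' Hebbian rule variants are compared.
#'
#' @param record A full `rmh_trial_record` (from `run_trial(..., record =
#'   "full")`) whose `perturbations` log holds the injected \eqn{\xi}.
#' @param reward Episode reward R.
#' @param rbar Baseline reward \eqn{R_0}.
#' @param eta Learning rate factor.
#' @return An n x n matrix of proposed weight changes.
#' @export
node_perturbation_gradient <- function(record, reward, rbar, eta = 0.5) {
  n <- length(record$x0)
  T_steps <- nrow(record$output_trace)
  e <- matrix(0, n, n)
  pl <- record$perturbations
  if (nrow(pl) > 0) {
    rprev <- rbind(record$r0, record$activity)  # row t = r(t-1)
    for (k in seq_len(nrow(pl))) {
      t <- pl$step[k]
      e[pl$neuron[k], ] <- e[pl$neuron[k], ] + pl$delta[k] * rprev[t, ]
    }
  }
  eta * (reward - rbar) * e
}

#' Gradient proposed by a Hebbian rule variant for one episode
#'
#' All Hebbian variants accumulate functions of the presynaptic input
#' \eqn{r_j(t-1)} and the postsynaptic fluctuation
#' \eqn{x_i(t) - \bar{x}_i(t)}:
#' \describe{
#'   \item{cubic / signed_square / sqrt / identity}{accumulate
#'     \eqn{S(r_j(t-1)(x_i - \bar{x}_i))} over the whole episode, then
#'     multiply by \eqn{\eta (R - R_0)}. `identity` (no supralinear
#'     amplification) is the delayed-reward Exploratory-Hebbian ablation.}
#'   \item{windowed}{like `identity` but accumulating only over
#'     `window_ms` ms starting at the scheduled perturbation (10 ms default;
#'     with a 1 ms window the result coincides with node perturbation).}
#'   \item{eh_realtime}{the full Exploratory-Hebbian rule with a real-time
#'     reward signal: accumulates
#'     \eqn{r_j(t-1)(x_i - \bar{x}_i)(R(t) - \bar{R}(t))} per step, where
#'     \eqn{R(t) = -|output(t) - target|} during the response window (0
#'     before) and \eqn{\bar{R}(t)} is its running average.}
#' }
#'
#' @param record A full `rmh_trial_record` of a sign-task episode.
#' @param variant One of `"cubic"`, `"signed_square"`, `"sqrt"`,
#'   `"identity"`, `"windowed"`, `"eh_realtime"`.
#' @param reward,rbar Episode reward and baseline (unused by `eh_realtime`).
#' @param eta Learning rate factor.
#' @param window_ms Accumulation window for `"windowed"` (default 10).
#' @param alpha_r Running-average coefficient of the real-time reward trace
#'   (default 0.8, matching the activation running average).
#' @return An n x n matrix of proposed weight changes.
#' @export
variant_gradient <- function(record, variant, reward, rbar, eta = 0.5,
                             window_ms = 10, alpha_r = 0.8) {
  T_steps <- nrow(record$output_trace)
  rprev <- rbind(record$r0, record$activity[-T_steps, , drop = FALSE])
  V <- record$potentials - record$xbars
  if (variant %in% c("cubic", "signed_square", "sqrt", "identity")) {
    e <- crossprod(supralinear(V, variant), supralinear(rprev, variant))
    return(eta * (reward - rbar) * e)
  }
  if (variant == "windowed") {
    pl <- record$perturbations
    if (nrow(pl) != 1)
      stop("invalid parameter: windowed variant needs exactly one perturbation")
    w <- as.integer(window_ms / record$dt_ms)
    idx <- pl$step[1]:min(T_steps, pl$step[1] + w - 1L)
    e <- crossprod(V[idx, , drop = FALSE], rprev[idx, , drop = FALSE])
    return(eta * (reward - rbar) * e)
  }
  if (variant == "eh_realtime") {
    # the reward signal exists only during the response window; its running
    # average starts at the first observed sample (the same first-observation
    # convention as the per-trial-type baseline), so w tracks within-window
    # reward fluctuations and is 0 where no reward signal exists
    rs <- record$response_steps
    Rt <- -abs(record$output_trace[rs, 1] - record$target)
    w <- numeric(T_steps)
    acc <- Rt[1]
    for (k in seq_along(rs)) {
      w[rs[k]] <- Rt[k] - acc     # pre-update expectation
      acc <- alpha_r * acc + (1 - alpha_r) * Rt[k]
    }
    e <- crossprod(V * w, rprev)
    return(eta * e)
  }
  stop("invalid parameter: unknown variant '", variant, "'")
}

#' Alignment between two gradient matrices
#'
#' Pearson product-moment correlation over the flattened entries.
#'
#' @param g1,g2 Matrices of the same shape.
#' @return Scalar correlation.
#' @export
gradient_alignment <- function(g1, g2) {
  if (!all(dim(g1) == dim(g2)))
    stop("invalid parameter: gradients must have the same shape")
  v1 <- as.vector(g1); v2 <- as.vector(g2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("undefined correlation: zero-variance gradient")
  stats::cor(v1, v2)
}

#' Compare rule variants against node-perturbation over many episodes
#'
#' For each episode: draw fresh random canonical weights, generate one
#' sign-discrimination trial, run it with a single scheduled perturbation
#' (random sign, magnitude 0.5, midpoint of the response window) and no other
#' noise, replay it unperturbed from the same initial state to obtain the
#' baseline reward \eqn{R_0}, and compute the gradients proposed by
#' node-perturbation and by every rule variant. No learning is applied.
#' Alignment with the node-perturbation ground truth is reported both pooled
#' (correlation over all entries of all episodes) and as the mean per-episode
#' correlation.
#'
#' @param n_episodes Number of episodes (>= 100).
#' @param seed Optional seed.
#' @param n_neurons Network size (default 200; smaller is useful for
#'   brute-force cross-checks).
#' @param variants Character vector of variant labels.
#' @param eta Learning rate factor (common scale; does not affect
#'   correlations).
#' @return A data.frame with columns `variant`, `pooled_cor`,
#'   `mean_episode_cor`.
#' @export
run_gradient_experiment <- function(n_episodes = 500, seed = NULL,
                                    n_neurons = 200,
                                    variants = c("cubic", "signed_square",
                                                 "sqrt", "identity",
                                                 "windowed", "eh_realtime"),
                                    eta = 0.5) {
  if (n_episodes < 100)
    stop("invalid parameter: n_episodes must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  params <- network_params(n_neurons = n_neurons, n_inputs = 10L)
  no_pert <- perturbation_config(rate_hz = 0)

  stats_acc <- lapply(variants, function(v)
    list(sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0, n = 0, ep_cor = numeric(0)))
  names(stats_acc) <- variants

  for (ep in seq_len(n_episodes)) {
    w <- init_weights(params)
    spec <- make_sign_trial(n_inputs = 10, dt_ms = params$dt_ms)
    rec <- run_trial(w, spec, params, no_pert, plast = NULL, record = "full",
                     apply_sched = TRUE)
    base <- run_trial(w, spec, params, no_pert, plast = NULL,
                      record = "output", x_init = rec$x0)
    R0 <- base$reward
    gnp <- node_perturbation_gradient(rec, rec$reward, R0, eta)
    x <- as.vector(gnp)
    for (v in variants) {
      g <- variant_gradient(rec, v, rec$reward, R0, eta)
      y <- as.vector(g)
      a <- stats_acc[[v]]
      a$sx <- a$sx + sum(x); a$sy <- a$sy + sum(y)
      a$sxx <- a$sxx + sum(x * x); a$syy <- a$syy + sum(y * y)
      a$sxy <- a$sxy + sum(x * y); a$n <- a$n + length(x)
      if (stats::sd(x) > 0 && stats::sd(y) > 0)
        a$ep_cor <- c(a$ep_cor, stats::cor(x, y))
      stats_acc[[v]] <- a
    }
  }
  pooled <- vapply(stats_acc, function(a) {
    num <- a$sxy - a$sx * a$sy / a$n
    den <- sqrt((a$sxx - a$sx^2 / a$n) * (a$syy - a$sy^2 / a$n))
    num / den
  }, numeric(1))
  data.frame(variant = variants,
             pooled_cor = unname(pooled),
             mean_episode_cor = vapply(stats_acc,
                                       function(a) mean(a$ep_cor), numeric(1)),
             row.names = NULL)
}
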