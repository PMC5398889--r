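#' Network parameters for a continuous-time recurrent rate network
#'
#' Constructs and validates the fixed constants of the network model
#' \deqn{\tau \frac{dx_i}{dt} = -x_i + \sum_j J_{ij} r_j + \sum_k B_{ik} u_k,}
#' where responses are \eqn{r = \tanh(x)} for the canonical signed variant, or
#' a nonnegative piecewise-linear function for the excitatory/inhibitory
#' (Dale's-law) variant. Four arbitrarily chosen neurons are clamped to
#' \eqn{x = 1} and serve as bias inputs to the rest of the network.
#'
#' @param n_neurons Number of neurons (default 200).
#' @param tau_ms Neural relaxation time constant in ms (default 30).
#' @param g Recurrent gain; 1.5 places the canonical network in the early
#'   chaotic regime.
#' @param dt_ms Euler integration step in ms (default 1).
#' @param n_inputs Number of external input channels M (task dependent).
#' @param variant `"canonical"` (signed tanh responses) or `"dale"`
#'   (nonnegative responses, separate excitatory/inhibitory populations).
#' @param bias_indices Indices of the 4 neurons clamped to x = 1.
#' @param output_indices Indices of the neuron(s) whose response is read out
#'   as the network output. Must be disjoint from `bias_indices`.
#' @param dale A [dale_params()] list; required (and defaulted) when
#'   `variant = "dale"`.
#' @return An object of class `rmh_network_params`.
#' @export
network_params <- function(n_neurons = 200L, tau_ms = 30, g = 1.5, dt_ms = 1,
                           n_inputs = 2L,
                           variant = c("canonical", "dale"),
                           bias_indices = 2:5, output_indices = 1L,
                           dale = NULL) {
  variant <- match.arg(variant)
  n_neurons <- as.integer(n_neurons)
  if (is.na(n_neurons) || n_neurons <= 0L)
    stop("invalid parameter: n_neurons must be a positive integer")
  if (!(tau_ms > dt_ms && dt_ms > 0))
    stop("invalid parameter: need tau_ms > dt_ms > 0")
  bias_indices <- as.integer(bias_indices)
  output_indices <- as.integer(output_indices)
  if (length(bias_indices) != 4L)
    stop("invalid parameter: exactly 4 bias neurons are required")
  if (length(intersect(bias_indices, output_indices)) > 0L)
    stop("invalid parameter: bias_indices and output_indices must be disjoint")
  if (any(c(bias_indices, output_indices) < 1L) ||
      any(c(bias_indices, output_indices) > n_neurons))
    stop("invalid parameter: neuron indices out of range")
  if (variant == "dale" && is.null(dale)) dale <- dale_params()
  if (variant == "dale" && dale$n_exc + dale$n_inh != n_neurons)
    stop("invalid parameter: n_exc + n_inh must equal n_neurons")
  structure(list(n_neurons = n_neurons, tau_ms = tau_ms, g = g, dt_ms = dt_ms,
                 n_inputs = as.integer(n_inputs), variant = variant,
                 bias_indices = bias_indices, output_indices = output_indices,
                 dale = dale),
            class = "rmh_network_params")
}

#' Parameters of the excitatory/inhibitory (Dale's-law) network variant
#'
#' The Dale variant splits the population into strictly excitatory and
#' strictly inhibitory neurons (first `n_exc` indices excitatory by
#' convention), initializes a semi-sparse connection matrix in which every
#' neuron receives `in_degree_exc` excitatory connections of weight
#' `w_exc_init` and `in_degree_inh` inhibitory connections of weight
#' `-g_inhib`, and uses the nonnegative piecewise-linear response
#' \eqn{r = \min(\max(x + m, 0), M_{sat})}.
#'
#' @param n_exc,n_inh Sizes of the excitatory and inhibitory populations.
#' @param in_degree_exc,in_degree_inh Per-neuron in-degrees from each
#'   population.
#' @param w_exc_init Initial weight of excitatory connections (1).
#' @param g_inhib Magnitude of initial inhibitory weights (1.2).
#' @param m Response offset (responses rise from 0 at x = -m).
#' @param M_sat Response ceiling (20; in practice responses stay well below).
#' @return An object of class `rmh_dale_params`.
#' @export
dale_params <- function(n_exc = 100L, n_inh = 100L,
                        in_degree_exc = 50L, in_degree_inh = 50L,
                        w_exc_init = 1.0, g_inhib = 1.2,
                        m = 2, M_sat = 20) {
  if (in_degree_exc <= 0 || in_degree_exc > n_exc ||
      in_degree_inh <= 0 || in_degree_inh > n_inh)
    stop("invalid parameter: in-degree exceeds population size")
  if (m <= 0 || M_sat <= 0)
    stop("invalid parameter: m and M_sat must be positive")
  structure(list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 in_degree_exc = as.integer(in_degree_exc),
                 in_degree_inh = as.integer(in_degree_inh),
                 w_exc_init = w_exc_init, g_inhib = g_inhib,
                 m = m, M_sat = M_sat),
            class = "rmh_dale_params")
}

#' Perturbation configuration
#'
#' Each neuron (except the clamped bias neurons) independently receives, at a
#' mean rate of `rate_hz` events per second, an additive perturbation to its
#' activation drawn uniformly from `amplitude`. These perturbations provide
#' the exploratory variation that drives learning and are applied both during
#' training and during testing/decoding.
#'
#' @param amplitude Length-2 numeric, the uniform draw bounds (default
#'   c(-0.5, 0.5)).
#' @param rate_hz Mean per-neuron event rate in Hz (default 3).
#' @return An object of class `rmh_pert_config`.
#' @export
perturbation_config <- function(amplitude = c(-0.5, 0.5), rate_hz = 3) {
  if (length(amplitude) != 2L || amplitude[1] >= amplitude[2])
    stop("invalid parameter: amplitude must be increasing bounds")
  if (rate_hz < 0) stop("invalid parameter: rate_hz must be >= 0")
  structure(list(amplitude_low = amplitude[1], amplitude_high = amplitude[2],
                 rate_hz = rate_hz),
            class = "rmh_pert_config")
}

#' Initialize weights for the canonical signed network
#'
#' Recurrent weights J are i.i.d. Gaussian with mean 0 and variance
#' \eqn{g^2/N}; input weights B are i.i.d. uniform on \eqn{[-1, 1]} and stay
#' fixed during learning.
#'
#' @param params An [network_params()] object with `variant = "canonical"`.
#' @param seed Optional integer seed (calls `set.seed` for reproducibility).
#' @return An object of class `rmh_weights` with elements `J` (N x N,
#'   row i = inputs to neuron i), `B` (N x M) and `variant`.
#' @export
init_canonical_weights <- function(params, seed = NULL) {
  if (params$variant != "canonical")
    stop("invalid parameter: params$variant must be 'canonical'")
  if (!is.null(seed)) set.seed(seed)
  N <- params$n_neurons
  J <- matrix(stats::rnorm(N * N, mean = 0, sd = params$g / sqrt(N)), N, N)
  B <- matrix(stats::runif(N * params$n_inputs, -1, 1), N, params$n_inputs)
  structure(list(J = J, B = B, variant = "canonical"), class = "rmh_weights")
}

#' Initialize semi-sparse weights for the Dale's-law network
#'
#' Every row (postsynaptic neuron) receives exactly `in_degree_exc`
#' connections of weight `w_exc_init` from randomly chosen excitatory columns
#' and `in_degree_inh` connections of weight `-g_inhib` from randomly chosen
#' inhibitory columns; all other entries are 0.
#'
#' @inheritParams init_canonical_weights
#' @return An `rmh_weights` object.
#' @export
init_dale_weights <- function(params, seed = NULL) {
  if (params$variant != "dale")
    stop("invalid parameter: params$variant must be 'dale'")
  if (!is.null(seed)) set.seed(seed)
  d <- params$dale
  N <- params$n_neurons
  J <- matrix(0, N, N)
  exc_cols <- seq_len(d$n_exc)
  inh_cols <- d$n_exc + seq_len(d$n_inh)
  for (i in seq_len(N)) {
    J[i, sample(exc_cols, d$in_degree_exc)] <- d$w_exc_init
    J[i, sample(inh_cols, d$in_degree_inh)] <- -d$g_inhib
  }
  B <- matrix(stats::runif(N * params$n_inputs, -1, 1), N, params$n_inputs)
  structure(list(J = J, B = B, variant = "dale"), class = "rmh_weights")
}

#' Initialize network weights
#'
#' Dispatches to [init_canonical_weights()] or [init_dale_weights()] according
#' to `params$variant`.
#' @inheritParams init_canonical_weights
#' @return An `rmh_weights` object.
#' @export
init_weights <- function(params, seed = NULL) {
  switch(params$variant,
         canonical = init_canonical_weights(params, seed),
         dale = init_dale_weights(params, seed))
}

#' Neuron response function
#'
#' Canonical variant: \eqn{r = \tanh(x)}. Dale variant: \eqn{r = 0} for
#' \eqn{x < -m}, \eqn{r = x + m} on \eqn{[-m, M_{sat} - m]}, and
#' \eqn{r = M_{sat}} above.
#'
#' @param x Numeric vector of activations.
#' @param params An [network_params()] object.
#' @return Numeric vector of responses, same length as `x`.
#' @export
neuron_response <- function(x, params) {
  if (params$variant == "canonical") return(tanh(x))
  d <- params$dale
  pmin(pmax(x + d$m, 0), d$M_sat)
}

#' Draw one step of exploratory perturbations
#'
#' Each neuron independently receives, with probability
#' `rate_hz * dt_ms / 1000`, an additive value drawn uniformly from the
#' configured amplitude range, and 0 otherwise. (Bias-neuron exemption is
#' applied by the trial simulator, not here.)
#'
#' @param n_neurons Number of neurons.
#' @param pert A [perturbation_config()].
#' @param dt_ms Step size in ms.
#' @return Numeric vector of perturbations (mostly zeros).
#' @export
draw_perturbations <- function(n_neurons, pert, dt_ms) {
  p <- pert$rate_hz * dt_ms / 1000
  if (p > 1) stop("invalid parameter: per-step perturbation probability > 1")
  delta <- numeric(n_neurons)
  hit <- stats::runif(n_neurons) < p
  if (any(hit))
    delta[hit] <- stats::runif(sum(hit), pert$amplitude_low, pert$amplitude_high)
  delta
}

#' Initialize a network state
#'
#' Activations are drawn uniformly from \eqn{[-0.1, 0.1]} (the per-trial reset
#' convention), bias neurons are clamped to 1, responses computed, and the
#' running average \eqn{\bar{x}} initialized at x.
#'
#' @param params An [network_params()] object.
#' @param x Optional explicit activation vector (bias clamp still applied).
#' @return A list with elements `x`, `r`, `xbar`, `t_ms`.
#' @export
init_state <- function(params, x = NULL) {
  if (is.null(x)) x <- stats::runif(params$n_neurons, -0.1, 0.1)
  x[params$bias_indices] <- 1
  list(x = x, r = neuron_response(x, params), xbar = x, t_ms = 0)
}

#' Advance the network by one Euler step (reference implementation)
#'
#' Applies the explicit Euler update
#' \eqn{x \leftarrow x + (dt/\tau)(-x + J r + B u)}, adds the perturbation
#' vector, clamps the bias neurons to x = 1, recomputes responses and the
#' running average of x, and advances the trial clock. This R-level stepper is
#' the reference against which the compiled trial simulator is tested; use
#' [run_trial()] for whole trials.
#'
#' @param state A state list as returned by [init_state()].
#' @param weights An `rmh_weights` object.
#' @param u_t Input vector at this step (length `n_inputs`).
#' @param delta_t Perturbation vector (length `n_neurons`).
#' @param params An [network_params()] object.
#' @param alpha_avg Running-average coefficient for xbar (default 0.8).
#' @return The updated state list.
#' @export
step_network <- function(state, weights, u_t, delta_t, params,
                         alpha_avg = 0.33) {
  a <- params$dt_ms / params$tau_ms
  x <- state$x + a * (-state$x + drop(weights$J %*% state$r) +
                        drop(weights$B %*% u_t))
  x <- x + delta_t
  x[params$bias_indices] <- 1
  if (any(!is.finite(x)))
    stop("numerical failure: non-finite activation at t = ", state$t_ms)
  r <- neuron_response(x, params)
  xbar <- alpha_avg * state$xbar + (1 - alpha_avg) * x
  list(x = x, r = r, xbar = xbar, t_ms = state$t_ms + params$dt_ms)
}
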