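# Small networks and hand-built trial specs used across the test files.

tiny_params <- function(n = 8L, n_inputs = 2L, variant = "canonical",
                        g = 1.5) {
  network_params(n_neurons = n, g = g, n_inputs = n_inputs,
                 variant = variant,
                 dale = if (variant == "dale")
                   dale_params(n_exc = n / 2, n_inh = n / 2,
                               in_degree_exc = n / 4, in_degree_inh = n / 4)
                 else NULL)
}

# a silent trial: no inputs, given duration
blank_spec <- function(duration_ms, n_inputs = 2L, dt_ms = 1) {
  T_steps <- as.integer(duration_ms / dt_ms)
  structure(list(inputs = matrix(0, T_steps, n_inputs), target = NA_real_,
                 response_window_ms = c(duration_ms - 100, duration_ms),
                 duration_ms = duration_ms, dt_ms = dt_ms,
                 trial_type = "blank", metadata = list(task = "blank")),
            class = "rmh_trial_spec")
}

# recompute a trial's eligibility trace with the R reference accumulator
reference_eligibility <- function(rec, s_kind) {
  n <- length(rec$x0)
  T_steps <- nrow(rec$potentials)
  e <- matrix(0, n, n)
  r_prev <- rec$r0
  for (t in seq_len(T_steps)) {
    e <- accumulate_eligibility(e, r_prev, rec$potentials[t, ],
                                rec$xbars[t, ], s_kind)
    r_prev <- rec$activity[t, ]
  }
  e
}
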