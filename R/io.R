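#' Save and load network weight snapshots
#'
#' Weights are written as plain text: `J.csv` and `B.csv` (no headers) plus a
#' `params.json` describing the network configuration, so snapshots are
#' portable and diffable.
#'
#' @param weights An `rmh_weights` object.
#' @param params The [network_params()] the weights belong to.
#' @param dir Directory to write to (created if needed).
#' @return `write_weights` returns `dir` invisibly; `read_weights` returns a
#'   list with `weights` and `params`.
#' @export
write_weights <- function(weights, params, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(weights$J, file.path(dir, "J.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(weights$B, file.path(dir, "B.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  p <- unclass(params)
  p$dale <- if (!is.null(p$dale)) unclass(p$dale) else NULL
  jsonlite::write_json(p, file.path(dir, "params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_weights
#' @export
read_weights <- function(dir) {
  J <- as.matrix(utils::read.table(file.path(dir, "J.csv"), sep = ","))
  B <- as.matrix(utils::read.table(file.path(dir, "B.csv"), sep = ","))
  dimnames(J) <- NULL; dimnames(B) <- NULL
  p <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  dale <- if (!is.null(p$dale))
    dale_params(p$dale$n_exc, p$dale$n_inh, p$dale$in_degree_exc,
                p$dale$in_degree_inh, p$dale$w_exc_init, p$dale$g_inhib,
                p$dale$m, p$dale$M_sat) else NULL
  params <- network_params(p$n_neurons, p$tau_ms, p$g, p$dt_ms, p$n_inputs,
                           p$variant, p$bias_indices, p$output_indices, dale)
  list(weights = structure(list(J = J, B = B, variant = p$variant),
                           class = "rmh_weights"),
       params = params)
}

#' Export a trial's inputs as CSV
#'
#' One row per timestep, one column per input channel; useful for
#' cross-implementation comparison of task fixtures.
#'
#' @param spec An `rmh_trial_spec`.
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_trial_csv <- function(spec, file) {
  df <- as.data.frame(spec$inputs)
  names(df) <- paste0("u", seq_len(ncol(df)))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
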