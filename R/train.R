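#' Train a recurrent network with reward-modulated Hebbian learning
#'
#' The main fitting function. Repeats: sample a trial of the chosen task, run
#' it with exploratory perturbations while accumulating the supralinear
#' Hebbian eligibility trace, compute the delayed reward \eqn{R = -}error,
#' update the per-trial-type reward baseline, and apply the clipped weight
#' update \eqn{\Delta J = \eta e (R - \bar{R})}. Weights only change between
#' trials. Fully reproducible from `(task, config, seed)`.
#'
#' Task-specific learning-rate defaults: 0.5 for `dnms`, `dnms_dale` and
#' `selint`; 0.03 for `dnms_long`; 0.003 for `dnms_vardelay`.
#'
#' @param task One of `"dnms"`, `"dnms_long"`, `"dnms_vardelay"`,
#'   `"dnms_dale"`, `"selint"`.
#' @param n_trials Maximum number of training trials.
#' @param seed Optional integer seed set before initialization and training.
#' @param eta Learning rate; `NULL` uses the task default.
#' @param params Optional [network_params()] override.
#' @param pert A [perturbation_config()].
#' @param plast Optional [plasticity_params()] override (its `eta` is
#'   replaced by the `eta` argument when that is given).
#' @param stop_after_criterion If non-negative, training stops this many
#'   trials after the criterion (95 of the last 100 errors below the task
#'   threshold) is first met; `Inf` (default) trains all `n_trials`.
#' @param verbose Print progress every 100 trials.
#' @return An object of class `rmhebb`: list with `weights` (final),
#'   `weights_init`, `curve` (data.frame: trial, trial_type, error, reward,
#'   rbar_used, clipped_fraction, r_min, r_max), `trials_to_criterion`
#'   (NA if never reached), `baseline`, `task`, `params`, `pert`, `plast`,
#'   `task_cfg`, `seed`, `call`.
#' @seealso [simulate.rmhebb()], [psychometric_table()], [learning_stats()]
#' @examples
#' fit <- train_rmhebb("dnms", n_trials = 5, seed = 1)
#' print(fit)
#' @export
train_rmhebb <- function(task = c("dnms", "dnms_long", "dnms_vardelay",
                                  "dnms_dale", "selint"),
                         n_trials = 10000, seed = NULL, eta = NULL,
                         params = NULL, pert = perturbation_config(),
                         plast = NULL, stop_after_criterion = Inf,
                         verbose = FALSE) {
  task <- match.arg(task)
  cl <- match.call()
  if (!is.null(seed)) set.seed(seed)

  task_cfg <- switch(task,
    dnms = dnms_config("standard"),
    dnms_long = dnms_config("long_delay"),
    dnms_vardelay = dnms_config("variable_delay"),
    dnms_dale = dnms_config("dale"),
    selint = selint_config())
  eta_default <- switch(task, dnms = 0.5, dnms_dale = 0.5, selint = 0.5,
                        dnms_long = 0.03, dnms_vardelay = 0.003)
  if (is.null(plast)) plast <- plasticity_params()
  if (!is.null(eta)) plast$eta <- eta else plast$eta <- eta_default
  if (is.null(params)) {
    params <- network_params(
      n_inputs = if (task == "selint") 4L else 2L,
      variant = if (task == "dnms_dale") "dale" else "canonical")
  }

  make_trial <- function() {
    if (task == "selint") make_selective_integration_trial(task_cfg,
                                                           dt_ms = params$dt_ms)
    else make_dnms_trial(task_cfg, dt_ms = params$dt_ms)
  }

  weights <- init_weights(params)
  weights_init <- weights
  bl <- reward_baseline()
  n_trials <- as.integer(n_trials)

  curve <- data.frame(trial = integer(n_trials),
                      trial_type = character(n_trials),
                      error = numeric(n_trials), reward = numeric(n_trials),
                      rbar_used = numeric(n_trials),
                      clipped_fraction = numeric(n_trials),
                      r_min = numeric(n_trials), r_max = numeric(n_trials))
  trials_to_criterion <- NA_integer_
  n_done <- 0L

  for (i in seq_len(n_trials)) {
    spec <- make_trial()
    rec <- run_trial(weights, spec, params, pert, plast)
    upd <- update_baseline(bl, rec$trial_type, rec$reward, plast$alpha_trace)
    bl <- upd$baseline
    weights$J <- apply_weight_update(weights$J, rec$eligibility, rec$reward,
                                     upd$rbar_used, plast, params)
    curve$trial[i] <- i
    curve$trial_type[i] <- rec$trial_type
    curve$error[i] <- rec$error
    curve$reward[i] <- rec$reward
    curve$rbar_used[i] <- upd$rbar_used
    curve$clipped_fraction[i] <- attr(weights$J, "clipped_fraction")
    curve$r_min[i] <- rec$r_range[1]
    curve$r_max[i] <- rec$r_range[2]
    n_done <- i
    if (is.na(trials_to_criterion) &&
        criterion_reached(curve$error[seq_len(i)], task_cfg$err_thresh)) {
      trials_to_criterion <- i
    }
    if (verbose && i %% 100 == 0)
      message(sprintf("trial %d: error %.3f (median last 100: %.3f)", i,
                      rec$error,
                      stats::median(curve$error[max(1, i - 99):i])))
    if (!is.na(trials_to_criterion) &&
        i >= trials_to_criterion + stop_after_criterion) break
  }
  attr(weights$J, "clipped_fraction") <- NULL
  curve <- curve[seq_len(n_done), , drop = FALSE]

  structure(list(weights = weights, weights_init = weights_init,
                 curve = curve, trials_to_criterion = trials_to_criterion,
                 baseline = bl, task = task, params = params, pert = pert,
                 plast = plast, task_cfg = task_cfg, seed = seed, call = cl),
            class = "rmhebb")
}

#' @export
print.rmhebb <- function(x, ...) {
  cat("Reward-modulated Hebbian learning fit\n")
  cat("  task:", x$task, " network:", x$params$variant,
      sprintf("(N = %d, tau = %g ms, g = %g)\n", x$params$n_neurons,
              x$params$tau_ms, x$params$g))
  cat(sprintf("  trials run: %d, eta = %g\n", nrow(x$curve), x$plast$eta))
  if (is.na(x$trials_to_criterion)) {
    cat("  criterion (95/100 correct) not reached\n")
  } else {
    cat(sprintf("  criterion (95/100 correct) reached at trial %d\n",
                x$trials_to_criterion))
  }
  invisible(x)
}

#' @export
summary.rmhebb <- function(object, ...) {
  cv <- object$curve
  n <- nrow(cv)
  last <- cv$error[max(1, n - 99):n]
  out <- list(task = object$task, n_trials = n,
              trials_to_criterion = object$trials_to_criterion,
              final_median_error = stats::median(last),
              final_correct_fraction = mean(last < object$task_cfg$err_thresh),
              mean_clipped_fraction = mean(cv$clipped_fraction),
              r_range = c(min(cv$r_min), max(cv$r_max)),
              eta = object$plast$eta)
  class(out) <- "summary.rmhebb"
  out
}

#' @export
print.summary.rmhebb <- function(x, ...) {
  cat(sprintf("task %s: %d trials, trials-to-criterion %s\n", x$task,
              x$n_trials, ifelse(is.na(x$trials_to_criterion), "not reached",
                                 x$trials_to_criterion)))
  cat(sprintf("  last-100 median error %.3f, correct fraction %.2f\n",
              x$final_median_error, x$final_correct_fraction))
  cat(sprintf("  mean clipped fraction %.3f, response range [%.3f, %.3f]\n",
              x$mean_clipped_fraction, x$r_range[1], x$r_range[2]))
  invisible(x)
}

#' @export
coef.rmhebb <- function(object, ...) object$weights$J

#' @export
residuals.rmhebb <- function(object, ...) object$curve$error

#' Plot a learning curve
#'
#' Per-trial error (grey) with a 100-trial running median (solid line) and
#' the trials-to-criterion marker, mirroring the usual learning-curve figure
#' for this family of experiments.
#'
#' @param x An `rmhebb` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rmhebb <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$trial, cv$error, col = "grey70", pch = ".",
                 xlab = "trial", ylab = "trial error", ...)
  if (nrow(cv) >= 100) {
    med <- stats::runmed(cv$error, 101)
    graphics::lines(cv$trial, med, lwd = 2)
  }
  if (!is.na(x$trials_to_criterion))
    graphics::abline(v = x$trials_to_criterion, lty = 2)
  invisible(x)
}

#' Simulate test trials from a trained network
#'
#' Runs `nsim` trials with the fitted (frozen) weights: perturbations stay on,
#' plasticity is off.
#'
#' @param object An `rmhebb` fit.
#' @param nsim Number of trials.
#' @param seed Optional seed.
#' @param record Passed to [run_trial()] (`"full"` needed for decoding).
#' @param trial_specs Optional list of `rmh_trial_spec` objects to use instead
#'   of freshly sampled task trials.
#' @param ... Unused.
#' @return A list of `rmh_trial_record` objects.
#' @export
simulate.rmhebb <- function(object, nsim = 1, seed = NULL,
                            record = "output", trial_specs = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trial_specs)) {
    trial_specs <- replicate(nsim, {
      if (object$task == "selint")
        make_selective_integration_trial(object$task_cfg,
                                         dt_ms = object$params$dt_ms)
      else make_dnms_trial(object$task_cfg, dt_ms = object$params$dt_ms)
    }, simplify = FALSE)
  }
  lapply(trial_specs, function(sp)
    run_trial(object$weights, sp, object$params, object$pert,
              plast = NULL, record = record,
              alpha_avg = object$plast$alpha_avg))
}

#' Summary statistics over a set of learning curves
#'
#' Pointwise median and quartiles of the per-trial error across runs
#' (truncated to the shortest run), plus the median and inter-quartile range
#' of trials-to-criterion; runs that never reached criterion are counted
#' separately.
#'
#' @param fits A list of `rmhebb` fits (or of learning-curve data.frames with
#'   an `error` column plus an optional `trials_to_criterion` attribute).
#' @return A list with `per_trial` (data.frame: trial, q25, median, q75),
#'   `trials_to_criterion` (vector), `ttc_median`, `ttc_iqr`, `n_unreached`.
#' @export
learning_stats <- function(fits) {
  if (length(fits) == 0) stop("invalid parameter: no curves given")
  curves <- lapply(fits, function(f) if (inherits(f, "rmhebb")) f$curve else f)
  ttc <- vapply(fits, function(f) {
    if (inherits(f, "rmhebb")) as.numeric(f$trials_to_criterion)
    else as.numeric(attr(f, "trials_to_criterion") %||% NA)
  }, numeric(1))
  n_min <- min(vapply(curves, nrow, integer(1)))
  errs <- vapply(curves, function(cv) cv$error[seq_len(n_min)],
                 numeric(n_min))
  errs <- matrix(errs, nrow = n_min)
  qs <- t(apply(errs, 1, stats::quantile, probs = c(0.25, 0.5, 0.75)))
  reached <- ttc[!is.na(ttc)]
  list(per_trial = data.frame(trial = seq_len(n_min), q25 = qs[, 1],
                              median = qs[, 2], q75 = qs[, 3]),
       trials_to_criterion = ttc,
       ttc_median = if (length(reached)) stats::median(reached) else NA_real_,
       ttc_iqr = if (length(reached))
         unname(stats::quantile(reached, c(0.25, 0.75))) else c(NA_real_, NA_real_),
       n_unreached = sum(is.na(ttc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Psychometric table for the selective-integration task
#'
#' Runs frozen-weight test trials (perturbations on, plasticity off) over the
#' full grid of bias combinations for each context, and aggregates the trial
#' response (mean output over the response window) by context, sorting
#' modality and the sorting modality's bias -- the two "sorted" views of the
#' psychometric data.
#'
#' @param object An `rmhebb` fit for the `selint` task, or (for testing) a
#'   function `f(context, bias1, bias2)` returning a scalar response.
#' @param cfg A [selint_config()].
#' @param n_per_cell Trials per (bias1, bias2, context) combination.
#' @param seed Optional seed.
#' @return A data.frame with columns `context`, `sort_modality`, `bias`,
#'   `relevant` (is the sorting modality the cued one), `n`, `mean_response`,
#'   `q25`, `q75`.
#' @export
psychometric_table <- function(object, cfg = selint_config(), n_per_cell = 2,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- cfg$test_bias_grid
  cells <- expand.grid(context = 1:2, bias1 = grid, bias2 = grid,
                       rep = seq_len(n_per_cell))
  resp <- numeric(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    ctx <- cells$context[k]; b1 <- cells$bias1[k]; b2 <- cells$bias2[k]
    if (is.function(object)) {
      resp[k] <- object(ctx, b1, b2)
    } else {
      sp <- make_selective_integration_trial(cfg, ctx, b1, b2,
                                             dt_ms = object$params$dt_ms,
                                             strict = FALSE)
      rec <- run_trial(object$weights, sp, object$params, object$pert,
                       plast = NULL, alpha_avg = object$plast$alpha_avg)
      resp[k] <- mean(rec$output_trace[rec$response_steps, 1])
    }
  }
  out <- list()
  for (ctx in 1:2) for (sm in 1:2) {
    sel <- cells$context == ctx
    b <- if (sm == 1) cells$bias1[sel] else cells$bias2[sel]
    r <- resp[sel]
    agg <- lapply(grid, function(bv) {
      ri <- r[abs(b - bv) < 1e-9]
      data.frame(context = ctx, sort_modality = sm, bias = bv,
                 relevant = (ctx == sm), n = length(ri),
                 mean_response = mean(ri),
                 q25 = unname(stats::quantile(ri, 0.25)),
                 q75 = unname(stats::quantile(ri, 0.75)))
    })
    out[[length(out) + 1L]] <- do.call(rbind, agg)
  }
  do.call(rbind, out)
}
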