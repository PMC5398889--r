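#' Sample population activity into a trials x timepoints x neurons tensor
#'
#' Samples each neuron's response every `period_ms` ms from a list of
#' fully-recorded trials (e.g. the 1000 ms nonmatch-to-sample trial sampled
#' every 10 ms gives 100 timepoints x 200 neurons per trial).
#'
#' @param records List of `rmh_trial_record` objects with `activity` (all of
#'   the same duration).
#' @param period_ms Sampling period in ms (default 10).
#' @return An object of class `rmh_activity_tensor`: list with `data`
#'   (array trials x timepoints x neurons), `labels` (data.frame of per-trial
#'   metadata: trial_type, target, error, plus task fields), and
#'   `sample_period_ms`.
#' @export
sample_activity <- function(records, period_ms = 10) {
  durs <- vapply(records, function(r) r$duration_ms, numeric(1))
  if (length(unique(durs)) != 1)
    stop("invalid parameter: trials have mixed durations")
  dt <- records[[1]]$dt_ms
  T_steps <- nrow(records[[1]]$activity)
  step <- as.integer(period_ms / dt)
  idx <- seq.int(step, T_steps, by = step)
  n_neurons <- ncol(records[[1]]$activity)
  data <- array(NA_real_, c(length(records), length(idx), n_neurons))
  for (k in seq_along(records))
    data[k, , ] <- records[[k]]$activity[idx, , drop = FALSE]
  labels <- do.call(rbind, lapply(records, function(r) {
    md <- r$metadata
    data.frame(trial_type = r$trial_type, target = r$target,
               error = r$error,
               stim1 = md$stim1 %||% NA, stim2 = md$stim2 %||% NA,
               context = md$context %||% NA,
               bias1 = md$bias1 %||% NA, bias2 = md$bias2 %||% NA,
               stringsAsFactors = FALSE)
  }))
  structure(list(data = data, labels = labels, sample_period_ms = period_ms),
            class = "rmh_activity_tensor")
}

# z-score the rows (timepoints) of a timepoints x neurons matrix; rows with
# zero variance become all-NA and are scored as incorrect by the decoder.
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2))
  z <- (m - mu) / s
  z[s == 0, ] <- NA_real_
  z
}

#' Cross-temporal maximal-correlation decoding
#'
#' For each of `n_iterations` random stratified half/half splits of the
#' trials: the training trials of each category are averaged pointwise into a
#' prototype (timepoints x neurons); each test trial's population vector at
#' time j is assigned the category whose prototype row i has the maximal
#' Pearson correlation with it, for every pair (i, j). The returned matrix
#' holds, at row i and column j, the proportion of test trials correctly
#' decoded at test time j by the classifier trained at time i, averaged over
#' iterations. High diagonal but low off-diagonal accuracy ("bottlenecks")
#' indicates a dynamic population code.
#'
#' @param tensor An `rmh_activity_tensor`.
#' @param category Factor/character vector (one per trial) of the class to
#'   decode, or a function applied to `tensor$labels`.
#' @param n_iterations Number of random splits (default 100).
#' @param condition Optional stratification factor (defaults to the task
#'   conditions in `tensor$labels$trial_type`); each condition is split
#'   half/half.
#' @return A timepoints x timepoints matrix of class `rmh_accuracy_matrix`.
#' @export
crosstemporal_decode <- function(tensor, category, n_iterations = 100,
                                 condition = NULL) {
  if (is.function(category)) category <- category(tensor$labels)
  category <- as.character(category)
  if (is.null(condition)) condition <- tensor$labels$trial_type
  condition <- as.character(condition)
  n_trials <- dim(tensor$data)[1]
  n_time <- dim(tensor$data)[2]
  classes <- sort(unique(category))
  if (any(table(category) < 2))
    stop("invalid parameter: every class needs at least 2 trials")

  ztest <- lapply(seq_len(n_trials),
                  function(k) zscore_rows(tensor$data[k, , ]))
  acc <- matrix(0, n_time, n_time)
  conds <- unique(condition)
  for (it in seq_len(n_iterations)) {
    train_idx <- unlist(lapply(conds, function(cn) {
      ids <- which(condition == cn)
      sample(ids, floor(length(ids) / 2))
    }))
    test_idx <- setdiff(seq_len(n_trials), train_idx)
    protos <- lapply(classes, function(cl) {
      ids <- intersect(train_idx, which(category == cl))
      zscore_rows(colMeans(tensor$data[ids, , , drop = FALSE], dims = 1))
    })
    # stacked prototype rows: (n_class * n_time) x neurons
    P <- do.call(rbind, protos)
    P[is.na(P)] <- 0   # zero-variance prototype rows never win
    it_acc <- matrix(0, n_time, n_time)
    for (k in test_idx) {
      Z <- ztest[[k]]
      bad <- is.na(Z[, 1])
      Z[is.na(Z)] <- 0
      S <- Z %*% t(P)                      # n_time x (n_class * n_time)
      M <- matrix(S, n_time * n_time, length(classes))
      dec <- max.col(M, ties.method = "first")   # (j, i) pairs, j fastest
      correct <- matrix(classes[dec] == category[k], n_time, n_time)
      correct[bad, ] <- FALSE              # zero-variance test rows: incorrect
      it_acc <- it_acc + t(correct)        # -> [i, j]
    }
    acc <- acc + it_acc / length(test_idx)
  }
  acc <- acc / n_iterations
  class(acc) <- c("rmh_accuracy_matrix", class(acc))
  attr(acc, "sample_period_ms") <- tensor$sample_period_ms
  acc
}

#' @export
plot.rmh_accuracy_matrix <- function(x, ...) {
  p <- attr(x, "sample_period_ms") %||% 1
  t_axis <- seq_len(nrow(x)) * p
  graphics::image(t_axis, t_axis, unclass(x), zlim = c(0, 1),
                  xlab = "training time (ms)", ylab = "testing time (ms)",
                  ...)
  invisible(x)
}

#' Orthogonal task-variable axes by per-feature regression and QR
#'
#' For each neuron and each sampled timepoint, the response across trials is
#' regressed (ordinary least squares, with intercept) on the task features.
#' Grouping the fitted coefficients by feature yields one population vector
#' per feature and timepoint; each feature keeps the vector at the timepoint
#' where its norm is maximal, and the resulting set is orthogonalized by QR
#' decomposition in the given feature order (the first feature's axis is
#' preserved up to normalization; later axes depend on the order, which is
#' therefore explicit).
#'
#' @param tensor An `rmh_activity_tensor`.
#' @param features A data.frame (one row per trial) of numeric feature
#'   values, e.g. choice, modality biases, context.
#' @param order Character vector giving the QR column order (default:
#'   the order of `features`' columns).
#' @return An object of class `rmh_feature_axes`: list with `features`
#'   (ordered names), `raw` (neurons x features matrix of regression
#'   vectors), `ortho` (orthonormal axes, same shape), `timepoints` (per
#'   feature, the max-norm timepoint).
#' @export
regression_axes <- function(tensor, features, order = names(features)) {
  stopifnot(is.data.frame(features))
  if (!all(order %in% names(features)))
    stop("invalid parameter: order names features that do not exist")
  features <- features[order]
  X <- cbind(`(Intercept)` = 1, as.matrix(features))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    zv <- names(features)[vapply(features, function(f) stats::var(f) == 0,
                                 logical(1))]
    stop("invalid parameter: rank-deficient feature design",
         if (length(zv)) paste0(" (zero-variance: ",
                                paste(zv, collapse = ", "), ")") else "")
  }
  n_time <- dim(tensor$data)[2]
  n_neurons <- dim(tensor$data)[3]
  n_feat <- length(order)
  W <- array(NA_real_, c(n_time, n_neurons, n_feat))
  for (t in seq_len(n_time)) {
    Y <- tensor$data[, t, ]                 # trials x neurons
    beta <- qr.coef(qx, Y)                  # (1 + n_feat) x neurons
    W[t, , ] <- t(beta[-1, , drop = FALSE])
  }
  raw <- matrix(NA_real_, n_neurons, n_feat,
                dimnames = list(NULL, order))
  tp <- integer(n_feat)
  for (f in seq_len(n_feat)) {
    norms <- sqrt(rowSums(W[, , f]^2))
    tp[f] <- which.max(norms)
    raw[, f] <- W[tp[f], , f]
  }
  qrd <- qr(raw)
  Q <- qr.Q(qrd)
  R <- qr.R(qrd)
  Q <- Q %*% diag(sign(diag(R)), n_feat)    # fix QR sign ambiguity
  colnames(Q) <- order
  structure(list(features = order, raw = raw, ortho = Q,
                 timepoints = tp),
            class = "rmh_feature_axes")
}

#' Project condition-averaged population activity onto feature axes
#'
#' Correct trials are grouped by the given label columns (typically context,
#' the averaging modality's bias, and final choice); the pointwise mean
#' activity of each group is projected onto the orthogonal feature axes,
#' giving one trajectory per group through the task-variable subspace.
#' Groups that contain no correct trials (impossible combinations) are
#' simply absent.
#'
#' @param tensor An `rmh_activity_tensor` whose labels include the grouping
#'   columns and a logical `correct` column (or `error` from which
#'   correctness is derived via `err_thresh`).
#' @param axes An `rmh_feature_axes` object.
#' @param grouping Character vector of label column names to group by.
#' @param err_thresh Error threshold defining a correct trial (default 1),
#'   used only when labels lack a `correct` column.
#' @return A long data.frame: grouping columns, `n_trials`, `time` (index),
#'   `feature`, `value`.
#' @export
project_trajectories <- function(tensor, axes, grouping, err_thresh = 1) {
  lb <- tensor$labels
  if (is.null(lb$correct)) lb$correct <- lb$error < err_thresh
  keep <- which(lb$correct)
  if (length(keep) == 0)
    stop("invalid parameter: no correct trials to project")
  key <- interaction(lb[keep, grouping, drop = FALSE], drop = TRUE)
  out <- list()
  for (g in levels(key)) {
    ids <- keep[key == g]
    avg <- apply(tensor$data[ids, , , drop = FALSE], c(2, 3), mean)
    proj <- avg %*% axes$ortho              # time x features
    gi <- lb[ids[1], grouping, drop = FALSE]
    for (f in seq_along(axes$features)) {
      out[[length(out) + 1L]] <- cbind(
        gi, n_trials = length(ids),
        data.frame(time = seq_len(nrow(proj)),
                   feature = axes$features[f], value = proj[, f]),
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Synthetic population-activity tensor with planted codes
#'
#' Builds an activity tensor in which each feature contributes
#' `value * direction * timecourse` to the population response, plus i.i.d.
#' Gaussian noise -- a ground-truth fixture for testing the decoders without
#' training any network.
#'
#' @param n_trials,n_timepoints,n_neurons Tensor dimensions.
#' @param codes A list of code specs: each a list with `name`, `values`
#'   (length `n_trials`), `direction` (length `n_neurons`), `timecourse`
#'   (length `n_timepoints`).
#' @param noise_sd SD of the additive Gaussian noise.
#' @param labels Optional extra data.frame of per-trial labels; the planted
#'   feature values are always included as columns.
#' @return An `rmh_activity_tensor`.
#' @export
planted_code_fixture <- function(n_trials, n_timepoints, n_neurons, codes,
                                 noise_sd = 0, labels = NULL) {
  data <- array(stats::rnorm(n_trials * n_timepoints * n_neurons,
                             sd = noise_sd),
                c(n_trials, n_timepoints, n_neurons))
  for (cd in codes) {
    stopifnot(length(cd$values) == n_trials,
              length(cd$direction) == n_neurons,
              length(cd$timecourse) == n_timepoints)
    pattern <- outer(cd$timecourse, cd$direction)  # time x neurons
    for (k in seq_len(n_trials))
      data[k, , ] <- data[k, , ] + cd$values[k] * pattern
  }
  lb <- if (length(codes) > 0)
    as.data.frame(lapply(codes, function(cd) cd$values),
                  col.names = vapply(codes, `[[`, "", "name"))
  else data.frame(row.names = seq_len(n_trials))
  if (!is.null(labels)) lb <- cbind(lb, labels)
  if (is.null(lb$trial_type)) lb$trial_type <- "all"
  structure(list(data = data, labels = lb, sample_period_ms = 10),
            class = "rmh_activity_tensor")
}
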