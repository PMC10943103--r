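#' Train a model on a replay buffer
#'
#' Sweeps the whole buffer `rounds` times in stored order, applying the
#' delta-rule plasticity step ([apply_plasticity()]) to every transition, and
#' records the mean squared next-state prediction error
#' \eqn{\|s_{t+1} - \hat s_{t+1}\|^2} of each sweep (errors measured just
#' before each update, so the first sweep reflects the initial map).
#'
#' @param model a [cml()] model whose dimensions match the buffer.
#' @param buffer a `replay_buffer` from [sample_exploration()].
#' @param rounds number of replay sweeps (>= 1).
#' @return list with `$model` (trained) and `$curve`, a data.frame with
#'   columns `sweep` and `mean_sq_prediction_error`.
#' @export
train_on_replay <- function(model, buffer, rounds = 10) {
  stopifnot(inherits(model, "cml"), inherits(buffer, "replay_buffer"))
  if (rounds < 1) stop("rounds must be >= 1")
  tr <- buffer$transitions
  if (is.null(tr) || nrow(tr) == 0) stop("empty replay buffer")
  if (buffer$n_obs != model$n_o || buffer$n_a != model$n_a)
    stop("buffer dimensions do not match the model")
  fit <- train_replay_onehot(model$Q, model$V, model$W,
                             as.integer(tr$from), as.integer(tr$action),
                             as.integer(tr$to), as.integer(rounds),
                             model$eta_q, model$eta_v, model$eta_w,
                             model$normalize_v,
                             identical(model$w_rule, "regression"))
  model$Q <- fit$Q; model$V <- fit$V; model$W <- fit$W
  list(model = model,
       curve = data.frame(sweep = seq_len(rounds),
                          mean_sq_prediction_error = as.numeric(fit$curve)))
}

#' Train a model on dense (continuous) transitions
#'
#' Same plasticity rules as [train_on_replay()] for environments whose
#' observations are real-valued feature vectors rather than one-hot codes.
#' Optionally regularizes `t(Q)` to reconstruct the observation
#' ([reconstruction_regularize()]), which keeps planning-relevant observation
#' components represented in the state code.
#'
#' @param model a [cml()] model.
#' @param obs `n_o x T` matrix of observations.
#' @param actions integer vector of T action indices.
#' @param obs_next `n_o x T` matrix of next observations.
#' @param rounds number of sweeps.
#' @param eta_recon reconstruction-regularizer learning rate (0 disables).
#' @return list with `$model` and `$curve` as in [train_on_replay()].
#' @export
train_on_dense <- function(model, obs, actions, obs_next, rounds = 1,
                           eta_recon = 0) {
  stopifnot(inherits(model, "cml"), nrow(obs) == model$n_o,
            nrow(obs_next) == model$n_o,
            ncol(obs) == length(actions), ncol(obs_next) == length(actions))
  if (rounds < 1) stop("rounds must be >= 1")
  fit <- train_replay_dense(model$Q, model$V, model$W,
                            obs, as.integer(actions), obs_next,
                            as.integer(rounds),
                            model$eta_q, model$eta_v, model$eta_w,
                            model$normalize_v,
                            identical(model$w_rule, "regression"), eta_recon)
  model$Q <- fit$Q; model$V <- fit$V; model$W <- fit$W
  list(model = model,
       curve = data.frame(sweep = seq_len(rounds),
                          mean_sq_prediction_error = as.numeric(fit$curve)))
}

#' Write a learning curve to CSV
#'
#' @param curve data.frame with columns `sweep`, `mean_sq_prediction_error`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_learning_curve <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
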