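#' Construct a cognitive map learner
#'
#' A cognitive map learner (CML) embeds observations and actions linearly into
#' a common high-dimensional state space and learns, by local delta-rule
#' plasticity, to predict the embedding of the next observation from the
#' current one plus the embedding of the executed action:
#' \deqn{Q o_{t+1} \approx Q o_t + V a_t.}
#' The learned geometry then supports online planning: the utility of an
#' action for reaching goal observation \eqn{o^*} is the scalar product of its
#' embedding with the goal direction \eqn{d_t = Q o^* - Q o_t}.
#'
#' Three maps are learned: `Q` (n_s x n_o) embeds observations, `V` (n_s x n_a)
#' embeds actions, and `W` (n_a x n_s) maps state differences back to action
#' space, substituting for `t(V)` when weight transport is not assumed.
#'
#' @param n_o number of observation components (number of nodes/cells for
#'   discrete environments, feature dimension for continuous ones).
#' @param n_a number of actions.
#' @param n_s state-space dimension. High dimensions (hundreds to thousands)
#'   make random action embeddings approximately orthogonal, which is what the
#'   planning heuristic relies on.
#' @param eta_q,eta_v,eta_w nonnegative learning rates for `Q`, `V`, `W`.
#' @param sigma_q,sigma_v,sigma_w standard deviations of the zero-mean
#'   Gaussian initialization of each matrix. Defaults follow the discrete
#'   (one-hot) setting; continuous observation models typically swap to a
#'   small `sigma_q` and `sigma_v = 1`.
#' @param normalize_v if `TRUE`, every column of `V` is renormalized to unit
#'   Euclidean norm after each plasticity step. Useful at small `n_s`; at
#'   `n_s >= 1000` the implicit normalization of high-dimensional random
#'   vectors makes it unnecessary, so the default is `FALSE`.
#' @param w_rule delta rule used to train `W` (see [apply_plasticity()]):
#'   `"transpose"` (default) makes each action's row of `W` track the
#'   observed state change of that action, so `W` converges to the role of
#'   `t(V)`; `"regression"` regresses the executed action on the observed
#'   state change. The transpose rule is unconditionally stable (its
#'   presynaptic input is the one-hot action) and reproduces `t(V)`-based
#'   utilities; the regression rule violates the LMS stability bound
#'   \eqn{\eta \|x\|^2 < 2} while the observation embeddings are still far
#'   apart, and its fixed point whitens the utility profile.
#' @param seed integer seed for the Gaussian initialization.
#'
#' @return an object of class `cml`: a list with matrices `Q`, `V`, `W`,
#'   the dimensions, learning rates, `normalize_v` flag and `seed`.
#' @examples
#' m <- cml(n_o = 4, n_a = 6, n_s = 100, seed = 1)
#' s <- embed_observation(m, onehot(2, 4))
#' @export
cml <- function(n_o, n_a, n_s,
                eta_q = 0.1, eta_v = 0.01, eta_w = 0.01,
                sigma_q = 1, sigma_v = 0.1, sigma_w = 0.1,
                normalize_v = FALSE, w_rule = c("transpose", "regression"),
                seed = 1L) {
  w_rule <- match.arg(w_rule)
  stopifnot(n_o >= 1, n_a >= 1, n_s >= 1,
            eta_q >= 0, eta_v >= 0, eta_w >= 0)
  local_seed(seed)
  model <- structure(list(
    Q = matrix(stats::rnorm(n_s * n_o, 0, sigma_q), n_s, n_o),
    V = matrix(stats::rnorm(n_s * n_a, 0, sigma_v), n_s, n_a),
    W = matrix(stats::rnorm(n_a * n_s, 0, sigma_w), n_a, n_s),
    n_o = as.integer(n_o), n_a = as.integer(n_a), n_s = as.integer(n_s),
    eta_q = eta_q, eta_v = eta_v, eta_w = eta_w,
    normalize_v = isTRUE(normalize_v),
    w_rule = w_rule,
    seed = as.integer(seed)
  ), class = "cml")
  if (model$normalize_v) model$V <- normalize_columns(model$V)
  model
}

#' @export
print.cml <- function(x, ...) {
  cat(sprintf("<cml> n_o=%d n_a=%d n_s=%d  eta_q=%g eta_v=%g eta_w=%g%s\n",
              x$n_o, x$n_a, x$n_s, x$eta_q, x$eta_v, x$eta_w,
              if (x$normalize_v) "  (V columns normalized)" else ""))
  invisible(x)
}

normalize_columns <- function(M) {
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  sweep(M, 2, nrm, "/")
}

#' One-hot code
#'
#' @param i hot index (1-based).
#' @param n code length.
#' @return numeric vector with a single 1 at position `i`.
#' @export
onehot <- function(i, n) {
  stopifnot(length(i) == 1, i >= 1, i <= n)
  v <- numeric(n)
  v[i] <- 1
  v
}

#' Embed an observation into state space
#'
#' Computes \eqn{s_t = Q o_t}; for a one-hot observation this selects the
#' corresponding column of `Q`.
#'
#' @param model a [cml()] model.
#' @param o observation code of length `n_o`.
#' @return state vector of length `n_s`.
#' @export
embed_observation <- function(model, o) {
  check_len(o, model$n_o, "observation")
  drop(model$Q %*% o)
}

#' Predict the next state
#'
#' The model's one-step prediction \eqn{\hat s_{t+1} = s_t + V a_t}.
#'
#' @param model a [cml()] model.
#' @param s_t current state vector (length `n_s`).
#' @param a_t action code of length `n_a`.
#' @return predicted state vector.
#' @export
predict_next_state <- function(model, s_t, a_t) {
  check_len(s_t, model$n_s, "state")
  check_len(a_t, model$n_a, "action")
  s_t + drop(model$V %*% a_t)
}

#' Apply one plasticity step
#'
#' Updates the model from a single transition (o_t, a_t, o_next) using the
#' local delta rules. Writing \eqn{e = s_{t+1} - \hat s_{t+1}} for the
#' prediction error (computed from the pre-update matrices):
#' \deqn{\Delta V = \eta_v \, e \, a_t^T, \qquad
#'       \Delta Q = -\eta_q \, e \, o_{t+1}^T,}
#' and `W` is trained by a separate delta rule so that it can substitute
#' `t(V)` in the utility computation. With the default
#' `w_rule = "transpose"` the row of `W` belonging to the executed action
#' tracks the observed state change \eqn{\Delta s = s_{t+1} - s_t}:
#' \deqn{\Delta W = \eta_w \, a_t (\Delta s - W^T a_t)^T;}
#' with `w_rule = "regression"` the executed action is regressed on the
#' state change: \eqn{\Delta W = \eta_w (a_t - W \Delta s) \Delta s^T}
#' (see [cml()] for the stability trade-off). If `normalize_v` is set, the
#' updated columns of `V` are renormalized to unit length.
#'
#' @param model a [cml()] model.
#' @param o_t,a_t,o_next the transition's observation, action and next
#'   observation codes.
#' @return the updated model.
#' @export
apply_plasticity <- function(model, o_t, a_t, o_next) {
  check_len(o_t, model$n_o, "observation")
  check_len(a_t, model$n_a, "action")
  check_len(o_next, model$n_o, "next observation")
  s_t <- embed_observation(model, o_t)
  s_next <- embed_observation(model, o_next)
  s_hat <- predict_next_state(model, s_t, a_t)
  err <- s_next - s_hat
  if (!all(is.finite(err)))
    stop("non-finite prediction error; check learning rates and inputs")
  ds <- s_next - s_t
  if (identical(model$w_rule, "regression")) {
    model$W <- model$W +
      model$eta_w * tcrossprod(a_t - drop(model$W %*% ds), ds)
  } else {
    a_idx <- which.max(a_t)
    model$W[a_idx, ] <- model$W[a_idx, ] +
      model$eta_w * a_t[a_idx] * (ds - model$W[a_idx, ])
  }
  model$V <- model$V + model$eta_v * tcrossprod(err, a_t)
  model$Q <- model$Q + model$eta_q * tcrossprod(-err, o_next)
  if (model$normalize_v) model$V <- normalize_columns(model$V)
  model
}

#' Compute action utilities for a goal direction
#'
#' The utility of each action is the scalar product of its embedding with the
#' goal direction \eqn{d_t = s^* - s_t}: \eqn{u_t = V^T d_t}, or, avoiding the
#' weight transport, \eqn{u_t = W d_t} with the separately learned map `W`.
#'
#' @param model a [cml()] model.
#' @param d_t goal direction vector of length `n_s`.
#' @param use_w if `TRUE` use `W d_t` (the default during planning on discrete
#'   worlds); if `FALSE` use `t(V) d_t`.
#' @return numeric utility vector of length `n_a`.
#' @export
compute_utilities <- function(model, d_t, use_w = TRUE) {
  check_len(d_t, model$n_s, "direction")
  if (use_w) drop(model$W %*% d_t) else drop(crossprod(model$V, d_t))
}

#' Winner-take-all action selection
#'
#' Selects the afforded action with the highest eligibility
#' \eqn{e_t = u_t \odot g_t}. Actions with affordance 0 are excluded from the
#' competition (they cannot be executed, whatever their utility). Ties are
#' broken deterministically in favor of the lowest action index.
#'
#' @param u_t utility vector of length `n_a`.
#' @param g_t affordance vector of length `n_a`, entries in `[0, 1]`
#'   (0 = unavailable).
#' @return one-hot action code.
#' @export
select_action <- function(u_t, g_t) {
  stopifnot(length(u_t) == length(g_t))
  if (!any(g_t > 0)) stop("no afforded action")
  e <- u_t * g_t
  e[g_t <= 0] <- -Inf
  onehot(which.max(e), length(u_t))
}

#' Quantize the model's weights
#'
#' Uniformly quantizes each of `Q`, `V`, `W` to `2^bits` levels spanning that
#' matrix's own `[min, max]` range, emulating limited weight precision of
#' in-memory-computing hardware.
#'
#' @param model a [cml()] model.
#' @param bits integer >= 1, number of bits per weight.
#' @return a new model with quantized matrices.
#' @export
quantize_weights <- function(model, bits) {
  stopifnot(length(bits) == 1, bits >= 1)
  levels <- 2^bits
  qmat <- function(M) {
    lo <- min(M); hi <- max(M)
    if (hi == lo) return(M)
    step <- (hi - lo) / (levels - 1)
    lo + round((M - lo) / step) * step
  }
  model$Q <- qmat(model$Q)
  model$V <- qmat(model$V)
  model$W <- qmat(model$W)
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the three matrices,
#' dimensions, learning rates, flags and seed; it round-trips bit-exactly.
#'
#' @param model a [cml()] model.
#' @param path file path.
#' @return `save_cml` returns `path` invisibly; `load_cml` returns the model.
#' @export
save_cml <- function(model, path) {
  stopifnot(inherits(model, "cml"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cml
#' @export
load_cml <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cml"))
  model
}

check_len <- function(x, n, what) {
  if (length(x) != n)
    stop(sprintf("%s has length %d, expected %d", what, length(x), n),
         call. = FALSE)
  invisible(TRUE)
}

# Temporarily seed the RNG, restoring the caller's RNG state on exit.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  withr::defer({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, envir = env)
  invisible(NULL)
}
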