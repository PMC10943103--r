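#' Quadruped observation schema
#'
#' Field names of the 29-component observation vector of the simulated
#' quadruped ("ant"): torso position (x, y, z), torso orientation quaternion,
#' the 8 joint angles, torso linear and angular velocities, and the 8 joint
#' angular velocities. Provided so a physics backend can be wired to the
#' model; the package itself exercises the continuous machinery on the
#' built-in point mass.
#'
#' @return character vector of length 29.
#' @export
ant_observation_schema <- function() {
  c("torso_x", "torso_y", "torso_z",
    "quat_x", "quat_y", "quat_z", "quat_w",
    "hip_front_left", "knee_front_left",
    "hip_front_right", "knee_front_right",
    "hip_back_left", "knee_back_left",
    "hip_back_right", "knee_back_right",
    "vel_x", "vel_y", "vel_z",
    "angvel_x", "angvel_y", "angvel_z",
    "angvel_hip_front_left", "angvel_knee_front_left",
    "angvel_hip_front_right", "angvel_knee_front_right",
    "angvel_hip_back_left", "angvel_knee_back_left",
    "angvel_hip_back_right", "angvel_knee_back_right")
}

#' Map a one-hot action index to per-joint torques
#'
#' With `n_joints` joints and torques restricted to two magnitudes per joint,
#' there are `2^n_joints` composite actions; the binary expansion of the
#' (0-based) index selects the sign of each joint's torque: bit `j` set means
#' `+tau` on joint `j + 1`, unset means `-tau`.
#'
#' @param index 0-based action index in `0 .. 2^n_joints - 1`.
#' @param n_joints number of joints.
#' @param tau torque magnitude.
#' @return numeric torque vector of length `n_joints`.
#' @export
remap_action <- function(index, n_joints, tau = 0.1) {
  stopifnot(length(index) == 1, index >= 0, index < 2^n_joints)
  bits <- as.integer(intToBits(index))[seq_len(n_joints)]
  tau * (2 * bits - 1)
}

#' Build a target observation from a partial assignment
#'
#' Copies the current observation and overwrites only the targeted fields
#' (by name, if the observation is named, or by index), so that planning
#' strives to change exactly those components — e.g. the torso (x, y) — and
#' leave everything else as it is.
#'
#' @param current current observation (optionally named).
#' @param target_fields named list / vector of desired values, or a list with
#'   integer names-as-indices.
#' @return the target observation.
#' @export
make_target_observation <- function(current, target_fields = list()) {
  target <- current
  if (!length(target_fields)) return(target)
  keys <- names(target_fields)
  if (is.null(keys)) stop("target_fields must be named")
  for (k in seq_along(target_fields)) {
    idx <- suppressWarnings(as.integer(keys[k]))
    if (is.na(idx)) {
      if (is.null(names(current)) || !(keys[k] %in% names(current)))
        stop(sprintf("unknown observation field '%s'", keys[k]))
      idx <- match(keys[k], names(current))
    }
    if (idx < 1 || idx > length(current)) stop("target field out of range")
    target[idx] <- target_fields[[k]]
  }
  target
}

#' Express an absolute target in the agent's heading frame
#'
#' Computes the vector from the agent to the absolute target in polar form,
#' subtracts the agent's heading angle from the polar angle, converts back to
#' Cartesian, and adds the offset to the agent position. With heading 0 this
#' is the identity; with heading `pi` a target ahead appears behind.
#'
#' @param agent_position length-2 (x, y).
#' @param agent_heading heading angle to the x-axis, radians.
#' @param absolute_target length-2 (x, y).
#' @return length-2 relative target coordinates.
#' @export
relative_target_transform <- function(agent_position, agent_heading,
                                      absolute_target) {
  stopifnot(length(agent_position) == 2, length(absolute_target) == 2,
            is.finite(agent_heading))
  v <- absolute_target - agent_position
  mag <- sqrt(sum(v^2))
  ang <- atan2(v[2], v[1]) - agent_heading
  agent_position + mag * c(cos(ang), sin(ang))
}

#' Reconstruction regularization of the observation embedding
#'
#' One delta-rule step driving \eqn{Q^T (Q o) \to o}: without it, training on
#' continuous observations can let easily predicted components dominate the
#' state code while planning-relevant ones (such as position) collapse out.
#'
#' @param model a [cml()] model.
#' @param o observation vector.
#' @param eta learning rate.
#' @return the updated model.
#' @export
reconstruction_regularize <- function(model, o, eta = 0.001) {
  check_len(o, model$n_o, "observation")
  s <- drop(model$Q %*% o)
  err <- o - drop(crossprod(model$Q, s))
  model$Q <- model$Q + eta * tcrossprod(s, err)
  model
}

#' Joint-limit affordances for composite torque actions
#'
#' Each joint contributes, per direction, a score that ramps linearly from 1
#' (far from the limit the direction approaches) down to 0 (at the limit),
#' over `ramp` times the joint's range. The affordance of a composite action
#' is the mean of its joints' directional scores.
#'
#' @param angles current joint angles.
#' @param limits_low,limits_high per-joint limits (`low < high`).
#' @param action_table `n_actions x n_joints` matrix of torque signs
#'   (+1/-1), e.g. rows of [remap_action()] divided by `tau`.
#' @param ramp fraction of the joint range over which the score ramps
#'   (default 0.1).
#' @return affordance vector of length `n_actions`, entries in `[0, 1]`.
#' @export
joint_limit_affordance <- function(angles, limits_low, limits_high,
                                   action_table, ramp = 0.1) {
  n_j <- length(angles)
  stopifnot(length(limits_low) == n_j, length(limits_high) == n_j,
            ncol(action_table) == n_j)
  if (any(limits_high <= limits_low)) stop("degenerate joint limits")
  if (any(angles < limits_low | angles > limits_high)) {
    warning("joint angle outside limits; clamping")
    angles <- pmin(pmax(angles, limits_low), limits_high)
  }
  range <- limits_high - limits_low
  up <- pmin((limits_high - angles) / (ramp * range), 1)    # score toward high
  down <- pmin((angles - limits_low) / (ramp * range), 1)   # score toward low
  score <- ifelse(action_table > 0, rep(up, each = nrow(action_table)),
                  rep(down, each = nrow(action_table)))
  score <- matrix(score, nrow(action_table), n_j)
  rowMeans(score)
}

#' A damped point-mass control environment
#'
#' A minimal continuous environment conforming to the planner interface:
#' observation `(x, y, vx, vy)`, 8 actions applying a constant force in one
#' of 8 compass directions for `n_repeat` integration substeps of a damped
#' point mass. Deterministic given the action sequence.
#'
#' @param mass point mass.
#' @param damping linear velocity damping coefficient.
#' @param dt integration step.
#' @param force force magnitude.
#' @param n_repeat substeps per action (each action is held for several
#'   integration steps so it produces an appreciable state change).
#' @return a list of class `pointmass_env` with `$n_o = 4`, `$n_a = 8`,
#'   `$reset(x, y)`, `$step(obs, action)` and `$affordances(obs)`.
#' @export
pointmass_env <- function(mass = 1, damping = 2, dt = 0.1, force = 1,
                          n_repeat = 5) {
  dirs <- seq(0, 2 * pi, length.out = 9)[1:8]
  F <- force * rbind(cos(dirs), sin(dirs))
  env <- list(
    n_o = 4L, n_a = 8L,
    schema = c("x", "y", "vx", "vy"),
    reset = function(x = 0, y = 0) c(x = x, y = y, vx = 0, vy = 0),
    step = function(obs, action) {
      stopifnot(action >= 1, action <= 8)
      p <- unname(obs[1:2]); v <- unname(obs[3:4])
      for (k in seq_len(n_repeat)) {
        v <- v + dt * (F[, action] / mass - damping * v)
        p <- p + dt * v
      }
      c(x = p[1], y = p[2], vx = v[1], vy = v[2])
    },
    affordances = function(obs) rep(1, 8)
  )
  structure(env, class = "pointmass_env")
}

#' Motor babbling on a continuous environment
#'
#' Collects transitions by executing uniformly random actions over
#' `n_episodes` episodes of `ep_len` steps (each from a fresh reset), the only
#' training signal the continuous controller gets.
#'
#' @param env a `pointmass_env` (or any object with the same protocol).
#' @param n_episodes,ep_len exploration budget.
#' @param seed integer seed.
#' @return list with matrices `$obs`, `$obs_next` (`n_o x T`) and `$actions`.
#' @export
babble <- function(env, n_episodes = 100, ep_len = 20, seed = 1L) {
  local_seed(seed)
  T_total <- n_episodes * ep_len
  O <- matrix(0, env$n_o, T_total)
  On <- matrix(0, env$n_o, T_total)
  acts <- integer(T_total)
  t <- 0L
  for (ep in seq_len(n_episodes)) {
    obs <- env$reset()
    for (k in seq_len(ep_len)) {
      a <- sample.int(env$n_a, 1L)
      nxt <- env$step(obs, a)
      t <- t + 1L
      O[, t] <- obs; On[, t] <- nxt; acts[t] <- a
      obs <- nxt
    }
  }
  list(obs = O, actions = acts, obs_next = On)
}

#' Goal-reaching episode on a continuous environment
#'
#' Closed-loop control: at every step the target observation is rebuilt from
#' the current one with the desired (x, y) substituted, the goal direction is
#' embedded, utilities \eqn{V^T d_t} are gated by the environment's
#' affordances, and the winner-take-all action is executed. Runs for
#' `max_steps` steps and logs the distance to goal.
#'
#' @param model a [cml()] model trained with [train_on_dense()].
#' @param env a `pointmass_env`.
#' @param goal_xy length-2 goal position.
#' @param max_steps episode length.
#' @param start_obs starting observation (default: `env$reset()`).
#' @return list with `$final_distance`, `$initial_distance`, `$trajectory`
#'   (data.frame `t`, `x`, `y`, `action_index`, `distance_to_goal`).
#' @export
reach_goal <- function(model, env, goal_xy, max_steps = 100,
                       start_obs = env$reset()) {
  obs <- start_obs
  d0 <- sqrt(sum((obs[1:2] - goal_xy)^2))
  log <- vector("list", max_steps)
  for (t in seq_len(max_steps)) {
    target <- make_target_observation(obs, list(x = goal_xy[1],
                                                y = goal_xy[2]))
    d <- drop(model$Q %*% (target - obs))
    u <- compute_utilities(model, d, use_w = FALSE)
    a <- which.max(ifelse(env$affordances(obs) > 0,
                          u * env$affordances(obs), -Inf))
    obs <- env$step(obs, a)
    log[[t]] <- data.frame(t = t, x = obs[1], y = obs[2], action_index = a,
                           distance_to_goal = sqrt(sum((obs[1:2] -
                                                          goal_xy)^2)))
  }
  traj <- do.call(rbind, log)
  list(final_distance = traj$distance_to_goal[max_steps],
       initial_distance = d0, trajectory = traj)
}
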