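# The Markov decision process: discrete 9-action space moving a virtual
# probe on the skin, ray-cast insonification, reward dispatch and
# termination. The environment object is a mutable R environment with
# reset/step semantics (standard episodic-RL interface).

#' Discrete action names
#'
#' Order: h+/-, theta+/-, phi+/-, psi+/-, switch.
#' @export
ACTIONS <- c("h+", "h-", "theta+", "theta-", "phi+", "phi-",
             "psi+", "psi-", "switch")

#' Create a scanning environment
#'
#' Step sizes follow the generic cylinder scale: 4 mm in height (mapped to
#' patient scale through the inverse size normalization), 3 degrees around
#' the axis, 2 degrees for each probe rotation.
#'
#' @param scene An [anatomy_scene()], or NULL when `phantom` is given.
#' @param phantom A [phantom_config()]; the base scene is generated from it
#'   and targets are re-placed at every reset.
#' @param probe A [probe_model()].
#' @param reward A [reward_config()].
#' @param randomize NULL for fixed targets, or a list with `n` (integer
#'   vector of admissible target counts) and `size_class`; a fresh
#'   placement is drawn at every reset.
#' @param init_theta_range Angular range (degrees) for the random initial
#'   probe position; defaults to the phantom's rib span or the full circle.
#' @param tilt_limit Tilt termination threshold in degrees (default 20).
#' @param h_step_generic Height step in generic-scale mm (default 4).
#' @param theta_step Angular step around the axis in degrees (default 3).
#' @param rot_step Probe rotation/tilt step in degrees (default 2).
#' @return An object of class `us_env`.
#' @export
us_env <- function(scene = NULL, phantom = NULL, probe = probe_model(),
                   reward = reward_config(), randomize = NULL,
                   init_theta_range = NULL, tilt_limit = 20,
                   h_step_generic = 4, theta_step = 3, rot_step = 2) {
  if (is.null(scene)) {
    stopifnot(inherits(phantom, "phantom_config"))
    scene <- generate_phantom(phantom)
    if (is.null(randomize))
      randomize <- list(n = phantom$n_targets,
                        size_class = phantom$size_class)
  }
  if (is.null(init_theta_range)) {
    cfg <- scene$provenance$config
    init_theta_range <- if (!is.null(cfg)) cfg$rib_span else c(-180, 180)
  }
  e <- new.env(parent = emptyenv())
  e$base_scene <- scene
  e$scene <- scene
  e$probe <- probe
  e$rcfg <- reward
  e$randomize <- randomize
  e$init_theta_range <- init_theta_range
  e$tilt_limit <- tilt_limit
  e$frame <- fit_cylinder(scene_bone_points(scene))
  e$h_step <- h_step_generic * diff(e$frame$h_range) / e$frame$generic_height
  e$theta_step <- theta_step
  e$rot_step <- rot_step
  e$terminal <- "unset"
  e$reset_count <- 0L
  class(e) <- "us_env"
  e
}

#' @export
print.us_env <- function(x, ...) {
  cat("<us_env> R_c =", round(x$frame$R_c, 1), "mm, targets:",
      length(x$scene$targets), "\n")
  invisible(x)
}

#' Reset the environment
#'
#' Re-places targets (when randomization is configured), voxelizes the
#' scene around the target centroid, and puts the probe at a uniformly
#' random valid (h, theta) with phi = psi = 0, examining mode. The state
#' history is filled with the initial grid (whose insonified channel shows
#' the initial imaging plane); the coverage ledger is cleared.
#'
#' @param env A `us_env`.
#' @param seed Integer seed for placement and initial pose.
#' @return The initial 9-channel state tensor, invisibly.
#' @export
env_reset <- function(env, seed = NULL) {
  env$reset_count <- env$reset_count + 1L
  if (is.null(seed)) seed <- env$reset_count
  with_seed(seed, {
    if (!is.null(env$randomize)) {
      n <- if (length(env$randomize$n) > 1L)
        sample(env$randomize$n, 1L) else env$randomize$n
      env$scene <- place_targets(env$base_scene, n,
                                 env$randomize$size_class,
                                 seed = sample.int(2^30, 1L))
    }
    env$centroid <- target_centroid(env$scene)
    grid <- voxelize(env$scene, env$centroid)
    if (grid$N == 0L) stop("no target voxels inside the state cube")
    env$grid <- grid
    env$centroid_g <- to_generic(env$frame, matrix(env$centroid, 1L, 3L))
    hr <- env$frame$h_range
    margin <- 0.05 * diff(hr)
    pose <- NULL
    for (i in 1:200) {
      h <- runif(1, hr[1L] + margin, hr[2L] - margin)
      th <- runif(1, env$init_theta_range[1L], env$init_theta_range[2L])
      pose <- build_pose(h, th, 0, 0, env$frame, env$scene$skin,
                         adj = FALSE, tilt_limit = env$tilt_limit)
      if (!is.null(pose) && !pose$terminal_tilt) break
      pose <- NULL
    }
    if (is.null(pose)) stop("could not sample a valid initial probe pose")
    env$pose <- pose
  })
  cr <- cast_rays(env$pose, env$grid, env$probe)
  g0 <- env$grid
  g0$ins <- cr$ins
  env$history <- list(g0, g0, g0)
  env$covered <- array(FALSE, env$grid$dims)
  env$steps <- 0L
  env$adj <- FALSE
  env$d_trace <- numeric(0)
  env$p_trace <- numeric(0)
  env$log <- list()
  env$terminal <- "none"
  invisible(state_tensor(env$history))
}

.generic_distance <- function(env, point) {
  pg <- to_generic(env$frame, matrix(point, 1L, 3L))
  sqrt(sum((pg - env$centroid_g)^2))
}

#' Advance the environment by one action
#'
#' Movement actions displace the probe on the cylinder surface or rotate
#' it, re-project onto the skin and re-cast rays; an off-surface move
#' leaves the pose unchanged and is rewarded as an ordinary step on the
#' unchanged state. The reward dispatch: mode switch gets the fixed switch
#' penalty; readjusting-mode motion gets 0 with no coverage or shadow
#' accounting; an examining step with shadow fraction below `T_th` earns
#' the composite step reward and accrues coverage; at or above `T_th` it
#' earns the shadow penalty and its coverage is discarded. Reaching the
#' success coverage fraction pays the terminal bonus; the step budget
#' truncates; tilting beyond the limit terminates without extra reward.
#'
#' @param env A `us_env` (after [env_reset()]).
#' @param action Integer 1-9 or an [ACTIONS] name.
#' @return List with `state` (the 3-grid history; materialize the
#'   9-channel tensor with [env_state()]), `reward`, `terminal`
#'   (one of "none", "success", "truncated", "tilt_violation") and
#'   `outcome` (per-step quantities: n_t, n_ins, N_t, n_shadow, p_t, d_t,
#'   component rewards, adj flag).
#' @export
env_step <- function(env, action) {
  if (env$terminal == "unset") stop("call env_reset() before env_step()")
  if (env$terminal != "none")
    stop("episode is terminal (", env$terminal, "); call env_reset()")
  if (is.character(action)) action <- match(action, ACTIONS)
  if (is.na(action) || action < 1L || action > 9L)
    stop("action index out of range: must be 1..9")
  env$steps <- env$steps + 1L
  rcfg <- env$rcfg
  outcome <- list(n_t = 0L, n_ins = 0L, N_t = 0L, n_shadow = 0L,
                  p_t = NA_real_, d_t = NA_real_, r_c = NA_real_,
                  r_a = NA_real_, r_s = NA_real_)

  if (action == 9L) {                       # switch: toggle mode, no motion
    env$adj <- !env$adj
    reward <- rcfg$switch_penalty
    g <- env$history[[3L]]                  # state unchanged
  } else {
    p <- env$pose
    h <- p$h; th <- p$theta; phi <- p$phi; psi <- p$psi
    delta <- switch(action,
                    `1` = {h <- h + env$h_step; NULL},
                    `2` = {h <- h - env$h_step; NULL},
                    `3` = {th <- th + env$theta_step; NULL},
                    `4` = {th <- th - env$theta_step; NULL},
                    `5` = {phi <- phi + env$rot_step; NULL},
                    `6` = {phi <- phi - env$rot_step; NULL},
                    `7` = {psi <- psi + env$rot_step; NULL},
                    `8` = {psi <- psi - env$rot_step; NULL})
    newpose <- build_pose(h, th, phi, psi, env$frame, env$scene$skin,
                          adj = env$adj, tilt_limit = env$tilt_limit)
    if (!is.null(newpose)) env$pose <- newpose    # off-surface: unchanged
    pose <- env$pose
    if (pose$terminal_tilt) env$terminal <- "tilt_violation"

    cr <- cast_rays(pose, env$grid, env$probe)
    d_t <- .generic_distance(env, pose$contact_point)
    outcome$n_ins <- cr$n_ins
    outcome$N_t <- cr$N_t
    outcome$n_shadow <- cr$n_shadow
    outcome$d_t <- d_t
    if (env$adj) {
      reward <- 0
    } else {
      sh <- reward_shadow(cr$n_shadow, cr$N_t)
      r_a <- reward_attenuation(d_t, env$frame$generic_radius)
      outcome$p_t <- sh$p_t
      outcome$r_s <- sh$r_s
      outcome$r_a <- r_a
      env$d_trace <- c(env$d_trace, d_t)
      env$p_trace <- c(env$p_trace, sh$p_t)
      if (sh$p_t < rcfg$T_th) {
        newly <- cr$covered & !env$covered
        n_t <- sum(newly)
        env$covered <- env$covered | newly
        outcome$n_t <- n_t
        outcome$r_c <- reward_coverage(n_t, env$grid$N)
        reward <- reward_step(list(r_c = outcome$r_c, r_a = r_a,
                                   r_s = sh$r_s), rcfg)
        if (sum(env$covered) >= rcfg$success_fraction * env$grid$N &&
            env$terminal == "none") {
          reward <- reward_terminal(env$d_trace, env$p_trace, rcfg,
                                    env$frame$generic_radius)
          env$terminal <- "success"
        }
      } else {
        reward <- rcfg$shadow_penalty      # coverage discarded
      }
    }
    g <- env$history[[3L]]
    g$ins <- cr$ins
  }

  if (env$terminal == "none" && env$steps >= rcfg$max_steps)
    env$terminal <- "truncated"
  env$history <- list(env$history[[2L]], env$history[[3L]], g)
  outcome$adj <- env$adj
  env$log[[length(env$log) + 1L]] <-
    c(list(step = env$steps, action = ACTIONS[action],
           h = env$pose$h, theta = env$pose$theta, phi = env$pose$phi,
           psi = env$pose$psi, reward = reward,
           terminal = env$terminal), outcome)
  list(state = env$history, reward = reward,
       terminal = env$terminal, outcome = outcome)
}

#' Current 9-channel state tensor
#' @param env A `us_env`.
#' @return Binary array 9 x 30 x 30 x 30.
#' @export
env_state <- function(env) state_tensor(env$history)

#' Cumulative coverage fraction of the target
#' @param env A `us_env`.
#' @return Fraction in `[0, 1]`.
#' @export
env_coverage <- function(env) sum(env$covered) / env$grid$N

#' Episode log as a data frame
#' @param env A `us_env`.
#' @return One row per step.
#' @export
episode_log <- function(env) {
  do.call(rbind, lapply(env$log, function(rec)
    as.data.frame(rec[!vapply(rec, is.null, logical(1))])))
}

#' Write the episode log as JSON lines
#' @param env A `us_env`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_episode_log <- function(env, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in env$log)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  invisible(path)
}
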