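# Evaluation protocols: greedy rollouts, success rate / step count /
# shadow / attenuation aggregates per target-size class, target-position
# heatmaps, and trajectory export back to patient scale.

#' Classify a target volume into the size classes
#'
#' Boundaries: small below 4 cm^3, medium from 4 to 13.5 cm^3 (closed
#' interval), large above 13.5 cm^3.
#'
#' @param volume_cm3 Target volume in cm^3 (> 0).
#' @return "small", "medium" or "large".
#' @export
classify_size <- function(volume_cm3) {
  if (any(volume_cm3 <= 0)) stop("target volume must be positive")
  ifelse(volume_cm3 < 4, "small",
         ifelse(volume_cm3 <= 13.5, "medium", "large"))
}

#' Greedy policy from a trained network
#' @param net A `qnet`.
#' @return Function `(env) -> action` taking the argmax action.
#' @export
greedy_policy <- function(net) {
  function(env) select_action(net, featurize(env$history, net$pool_f),
                              eps = 0)
}

#' Uniform random policy
#' @return Function `(env) -> action` drawing uniformly from the 9 actions.
#' @export
random_policy <- function() {
  function(env) sample.int(length(ACTIONS), 1L)
}

#' Run one episode under a policy
#'
#' @param env A `us_env`.
#' @param policy Function `(env) -> action`.
#' @param seed Reset seed.
#' @return An `episode_result`: `success` (95% coverage within the step
#'   budget), `steps`, `coverage`, `D` and `P` (episode means of
#'   d_t / R_c and 1 - p_t over examining steps, as percentages),
#'   `total_reward`, `size_class`, `trajectory` (pose records), `seed`.
#' @export
run_episode <- function(env, policy, seed = NULL) {
  env_reset(env, seed)
  total <- 0
  trajectory <- list()
  repeat {
    a <- policy(env)
    res <- env_step(env, a)
    total <- total + res$reward
    p <- env$pose
    trajectory[[length(trajectory) + 1L]] <-
      list(step = env$steps, h = p$h, theta = p$theta, phi = p$phi,
           psi = p$psi, adj = env$adj,
           contact = p$contact_point, centerline = p$centerline)
    if (res$terminal != "none") break
  }
  vol <- sum(vapply(env$scene$targets, shape_volume, numeric(1)))
  structure(list(success = env$terminal == "success",
                 terminal = env$terminal, steps = env$steps,
                 coverage = env_coverage(env),
                 D = if (length(env$d_trace))
                   100 * mean(env$d_trace / env$frame$generic_radius)
                 else NA_real_,
                 P = if (length(env$p_trace))
                   100 * mean(1 - env$p_trace) else NA_real_,
                 total_reward = total, volume_cm3 = vol,
                 size_class = classify_size(vol),
                 d_trace = env$d_trace, p_trace = env$p_trace,
                 trajectory = trajectory, seed = seed),
            class = "episode_result")
}

#' Evaluate a policy over repeated episodes
#'
#' Runs `n_episodes` greedy (or supplied-policy) episodes per environment
#' and aggregates success rate, steps, P and D per size class. Metrics are
#' reported over all episodes and, separately, over successful episodes
#' only.
#'
#' @param policy Function `(env) -> action`.
#' @param envs A `us_env` or list of them.
#' @param n_episodes Episodes per environment.
#' @param seed Master seed; episode seeds derive from it.
#' @return List with `episodes` (data frame, one row per episode) and
#'   `summary` (data frame per size class and scope).
#' @export
evaluate_policy <- function(policy, envs, n_episodes = 100L, seed = 1L) {
  if (inherits(envs, "us_env")) envs <- list(envs)
  seeds <- with_seed(seed, sample.int(2^30, n_episodes * length(envs)))
  rows <- list()
  k <- 0L
  for (env in envs) {
    for (i in seq_len(n_episodes)) {
      k <- k + 1L
      ep <- run_episode(env, policy, seed = seeds[k])
      rows[[k]] <- data.frame(env = match(TRUE, vapply(envs, identical,
                                                       logical(1), env)),
                              episode = i, seed = seeds[k],
                              success = ep$success, terminal = ep$terminal,
                              steps = ep$steps, coverage = ep$coverage,
                              P = ep$P, D = ep$D,
                              volume_cm3 = ep$volume_cm3,
                              size_class = ep$size_class)
    }
  }
  episodes <- do.call(rbind, rows)
  agg <- function(df, scope) {
    if (!nrow(df)) return(NULL)
    do.call(rbind, lapply(split(df, df$size_class), function(g)
      data.frame(size_class = g$size_class[1L], scope = scope,
                 n = nrow(g), success_rate = mean(g$success),
                 steps_mean = mean(g$steps), steps_sd = sd(g$steps),
                 P_mean = mean(g$P, na.rm = TRUE),
                 P_sd = sd(g$P, na.rm = TRUE),
                 D_mean = mean(g$D, na.rm = TRUE),
                 D_sd = sd(g$D, na.rm = TRUE))))
  }
  summary <- rbind(agg(episodes, "all"),
                   agg(episodes[episodes$success, , drop = FALSE],
                       "successful"))
  rownames(summary) <- NULL
  list(episodes = episodes, summary = summary)
}

#' Success-rate heatmap over target positions
#'
#' Places a reference target at every lattice position beneath the ribs
#' where it intersects no rib, runs episodes there, and averages success
#' over the depth axis, yielding a success-rate map over the (x, y) plane
#' (x = anterior axis index, y = lateral; the depth average runs along the
#' cylinder radius at fixed angle bands in this implementation's frame:
#' positions are gridded in Cartesian world coordinates).
#'
#' @param policy Function `(env) -> action`.
#' @param scene An [anatomy_scene()] (bones + skin; targets are replaced).
#' @param target Reference target shape (an [ellipsoid()]); it is
#'   translated to each grid position.
#' @param stride Grid stride in mm (default 4, one state voxel; coarser
#'   strides for desk-scale runs).
#' @param n_per Episodes per position.
#' @param seed Master seed.
#' @param reward,probe Environment configuration.
#' @return List with `xs`, `ys` (mm), `rate` (matrix of success rates,
#'   NA where no valid placement exists) and `counts`.
#' @export
position_heatmap <- function(policy, scene, target, stride = 4, n_per = 1L,
                             seed = 1L, reward = reward_config(),
                             probe = probe_model()) {
  stopifnot(inherits(target, "ellipsoid"))
  bb <- Reduce(function(a, b) rbind(pmin(a[1, ], b[1, ]),
                                    pmax(a[2, ], b[2, ])),
               lapply(scene$bones, shape_bbox))
  inner <- 0.85 * max(bb[2, 1:2] - colMeans(bb)[1:2])
  ctr <- colMeans(bb)
  xs <- seq(bb[1, 1], bb[2, 1], by = stride)
  ys <- seq(bb[1, 2], bb[2, 2], by = stride)
  zs <- seq(bb[1, 3] + 10, bb[2, 3] - 10, by = stride * 2)
  rate <- matrix(NA_real_, length(xs), length(ys),
                 dimnames = list(round(xs), round(ys)))
  counts <- matrix(0L, length(xs), length(ys))
  seeds <- with_seed(seed, sample.int(2^30, length(xs) * length(ys)))
  k <- 0L
  for (ix in seq_along(xs)) for (iy in seq_along(ys)) {
    k <- k + 1L
    if (sqrt((xs[ix] - ctr[1])^2 + (ys[iy] - ctr[2])^2) > inner) next
    succ <- integer(0)
    for (z in zs) {
      tgt <- ellipsoid(c(xs[ix], ys[iy], z), target$semi, target$rot)
      pts <- .ellipsoid_samples(tgt, 200L)
      if (any(.point_in_bones(scene$bones, pts))) next
      if (!all(shape_inside(scene$skin, pts))) next
      sc <- anatomy_scene(scene$skin, scene$bones, list(tgt),
                          scene$frame_id, scene$provenance)
      env <- us_env(scene = sc, probe = probe, reward = reward,
                    randomize = NULL)
      for (j in seq_len(n_per)) {
        ep <- run_episode(env, policy, seed = seeds[k] + j)
        succ <- c(succ, as.integer(ep$success))
      }
    }
    if (length(succ)) {
      rate[ix, iy] <- mean(succ)
      counts[ix, iy] <- length(succ)
    }
  }
  list(xs = xs, ys = ys, rate = rate, counts = counts)
}

#' Export an episode trajectory to patient scale
#'
#' Writes the pose sequence as CSV and JSON; contact points are recorded
#' in world (patient) coordinates together with the generic-scale pose
#' coordinates mapped back through the inverse size normalization.
#'
#' @param episode An `episode_result`.
#' @param frame The `cyl_frame` of the environment that produced it.
#' @param path Output path without extension; `.csv` and `.json` are
#'   appended.
#' @return Character vector of the two paths, invisibly.
#' @export
export_trajectory <- function(episode, frame, path) {
  rows <- do.call(rbind, lapply(episode$trajectory, function(tr)
    data.frame(step = tr$step, h = tr$h, theta = tr$theta, phi = tr$phi,
               psi = tr$psi, adj = tr$adj,
               contact_x = tr$contact[1L], contact_y = tr$contact[2L],
               contact_z = tr$contact[3L],
               centerline_x = tr$centerline[1L],
               centerline_y = tr$centerline[2L],
               centerline_z = tr$centerline[3L])))
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  write.csv(format(rows, digits = 17), csv, row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(list(frame = list(R_c = frame$R_c,
                                         h_range = frame$h_range,
                                         generic_radius =
                                           frame$generic_radius,
                                         generic_height =
                                           frame$generic_height),
                            poses = rows),
                       js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv, js))
}

#' Re-import an exported trajectory CSV
#' @param path Path written by [export_trajectory()] (with `.csv`).
#' @return Data frame of pose records.
#' @export
read_trajectory <- function(path) {
  read.csv(path)
}
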