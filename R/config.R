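# YAML configuration with a strict schema, run manifests, and the
# command entry points (phantom / train / eval). All randomness flows
# from one master seed via named substreams.

#' Default configuration
#'
#' Defaults are the published protocol where stated: learning rate 7e-5,
#' 80-step episodes, shadow threshold T_th 0.20, reward weights
#' alpha1 = 1, alpha2 = 0.5, step sizes 4 mm / 3 deg / 2 deg / 2 deg.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    phantom = list(n_ribs = 5L, rib_radius = 5, intercostal_gap = 20,
                   torso_radius = 80, torso_height = 170, skin_offset = 10,
                   rib_span = c(-80, 80), n_targets = 1L,
                   size_class = "medium"),
    probe = list(footprint_length = 40, ray_spacing = 2,
                 imaging_depth = 120),
    steps = list(h_mm = 4, theta_deg = 3, phi_deg = 2, psi_deg = 2),
    reward = list(alpha1 = 1, alpha2 = 0.5, T_th = 0.20, k_end = 10,
                  success_fraction = 0.95, switch_penalty = -1,
                  shadow_penalty = -0.1, max_steps = 80L),
    train = list(lr = 7e-5, total_steps = 5e6, target_update_period = 5e3,
                 eps_start = 1, eps_end = 0.05, eps_decay_steps = 3e6,
                 buffer_capacity = 5e4, batch_size = 32L, gamma = 0.99,
                 per_alpha = 0.6, per_beta0 = 0.4, priority_floor = 1e-6,
                 grad_clip = 10, warmup = 1000L, pool_f = 3L,
                 hidden = c(128L)),
    eval = list(n_episodes = 100L))
}

.check_keys <- function(user, defaults, path = "") {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop("unknown configuration key: ", paste0(path, extra[1L]))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      .check_keys(as.list(user[[nm]]), defaults[[nm]],
                  path = paste0(path, nm, "."))
  }
}

.merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]]))
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Load and resolve a YAML configuration
#'
#' Missing entries take the defaults; unknown keys are refused by name.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return Resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (length(user)) {
      .check_keys(user, cfg)
      cfg <- .merge_config(cfg, user)
    }
  }
  cfg
}

#' Write a run manifest
#'
#' Records the fully resolved configuration, master seed, package version
#' and input-file hashes — enough to re-execute the run.
#'
#' @param config Resolved configuration list.
#' @param path Output JSON path.
#' @param inputs Character vector of input files to hash.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, path, inputs = character()) {
  man <- list(config = config,
              master_seed = config$seed,
              package = "icuplan",
              version = as.character(utils::packageVersion("icuplan")),
              input_md5 = if (length(inputs))
                as.list(tools::md5sum(inputs)) else NULL,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.cfg_env <- function(config, scene = NULL) {
  ph <- config$phantom
  pc <- phantom_config(n_ribs = ph$n_ribs, rib_radius = ph$rib_radius,
                       intercostal_gap = ph$intercostal_gap,
                       torso_radius = ph$torso_radius,
                       torso_height = ph$torso_height,
                       skin_offset = ph$skin_offset,
                       rib_span = ph$rib_span, n_targets = ph$n_targets,
                       size_class = ph$size_class, seed = config$seed)
  rw <- do.call(reward_config, config$reward)
  pr <- do.call(probe_model, config$probe)
  st <- config$steps
  stopifnot(st$phi_deg == st$psi_deg)  # one rotation step drives both
  if (is.null(scene))
    us_env(phantom = pc, probe = pr, reward = rw,
           h_step_generic = st$h_mm, theta_step = st$theta_deg,
           rot_step = st$phi_deg)
  else us_env(scene = scene, probe = pr, reward = rw,
              h_step_generic = st$h_mm, theta_step = st$theta_deg,
              rot_step = st$phi_deg)
}

#' Generate a phantom from a configuration and write scene files
#'
#' @param config_path YAML path or NULL for defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master-seed override.
#' @return Output directory, invisibly.
#' @export
cmd_phantom <- function(config_path = NULL, out_dir = ".", seed = NULL) {
  config <- load_config(config_path)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- config$phantom
  pc <- phantom_config(n_ribs = ph$n_ribs, rib_radius = ph$rib_radius,
                       intercostal_gap = ph$intercostal_gap,
                       torso_radius = ph$torso_radius,
                       torso_height = ph$torso_height,
                       skin_offset = ph$skin_offset,
                       rib_span = ph$rib_span, n_targets = ph$n_targets,
                       size_class = ph$size_class, seed = config$seed)
  scene <- generate_phantom(pc)
  write_scene_manifest(scene, file.path(out_dir, "scene.json"))
  pts <- scene_bone_points(scene)
  write.csv(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3]),
            file.path(out_dir, "bone_points.csv"), row.names = FALSE)
  skin <- scene$skin
  if (inherits(skin, "cylinder_skin"))
    write_stl(cylinder_mesh(skin$cx, skin$cy, skin$radius, skin$z_range,
                            name = "skin"),
              file.path(out_dir, "skin.stl"))
  write_run_manifest(config, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Train a policy from a configuration
#'
#' @param config_path YAML path or NULL for defaults.
#' @param out_dir Output directory for checkpoint, learning curve and
#'   manifest.
#' @param seed Optional master-seed override.
#' @param total_steps Optional override of the training budget.
#' @return The [train()] result, invisibly.
#' @export
cmd_train <- function(config_path = NULL, out_dir = ".", seed = NULL,
                      total_steps = NULL) {
  config <- load_config(config_path)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(total_steps)) config$train$total_steps <- total_steps
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- .cfg_env(config)
  tc <- do.call(train_config,
                c(config$train,
                  list(seed = config$seed,
                       checkpoint_path = file.path(out_dir,
                                                   "checkpoint.rds"))))
  result <- train(env, tc)
  write_learning_curve(result, file.path(out_dir, "learning_curve.csv"))
  write_run_manifest(config, file.path(out_dir, "manifest.json"),
                     inputs = if (!is.null(config_path)) config_path
                     else character())
  invisible(result)
}

#' Evaluate a policy from a configuration
#'
#' Without a checkpoint a uniform random policy is evaluated (baseline).
#'
#' @param checkpoint Path to a training checkpoint, or NULL for the
#'   random baseline.
#' @param config_path YAML path or NULL for defaults.
#' @param out_dir Output directory for metric tables and manifest.
#' @param seed Optional master-seed override.
#' @return The [evaluate_policy()] result, invisibly.
#' @export
cmd_eval <- function(checkpoint = NULL, config_path = NULL, out_dir = ".",
                     seed = NULL) {
  config <- load_config(config_path)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  policy <- if (is.null(checkpoint)) random_policy()
  else {
    if (!file.exists(checkpoint)) stop("checkpoint not found: ", checkpoint)
    greedy_policy(readRDS(checkpoint)$net)
  }
  env <- .cfg_env(config)
  res <- evaluate_policy(policy, env, n_episodes = config$eval$n_episodes,
                         seed = config$seed)
  write.csv(res$summary, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(res$episodes, file.path(out_dir, "episodes.csv"),
            row.names = FALSE)
  write_run_manifest(config, file.path(out_dir, "manifest.json"))
  invisible(res)
}
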