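# Single-process training loop: epsilon-greedy rollouts fill the
# prioritized buffer; after warm-up, one importance-weighted Huber
# gradient step per environment step; the target network is hard-copied
# on a fixed period. Fully seeded and resumable from a checkpoint.

#' Training configuration
#'
#' Defaults follow the full-scale protocol (learning rate 7e-5, 5e6 steps,
#' target update every 5e3 steps, exploration 1 -> 0.05 over the first 3e6
#' steps, gamma 0.99, batch 32, priority exponent 0.6 with importance
#' weights annealed 0.4 -> 1); every entry scales down for CPU-sized runs.
#'
#' @param lr Learning rate.
#' @param total_steps Environment steps to train for.
#' @param target_update_period Steps between target-network copies.
#' @param eps_start,eps_end,eps_decay_steps Linear exploration schedule.
#' @param buffer_capacity Replay capacity.
#' @param batch_size Batch size.
#' @param gamma Discount factor.
#' @param per_alpha Priority exponent.
#' @param per_beta0 Initial importance-weight exponent (annealed to 1).
#' @param per_beta_steps Steps over which the importance-weight exponent
#'   anneals to 1 (defaults to the exploration decay horizon).
#' @param priority_floor Priority floor.
#' @param grad_clip Global gradient-norm clip.
#' @param warmup Transitions collected before learning starts.
#' @param pool_f State pooling factor (30 must be divisible by it).
#' @param hidden Trunk layer widths.
#' @param seed Master seed; placement, exploration and replay draw from it.
#' @param checkpoint_path Optional .rds path written every
#'   `checkpoint_every` steps and at the end.
#' @param checkpoint_every Steps between checkpoints.
#' @param eval_every Steps between greedy evaluation probes (0 = never).
#' @param eval_episodes Episodes per evaluation probe.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 7e-5, total_steps = 5e6,
                         target_update_period = 5e3,
                         eps_start = 1, eps_end = 0.05,
                         eps_decay_steps = 3e6,
                         buffer_capacity = 5e4, batch_size = 32L,
                         gamma = 0.99, per_alpha = 0.6, per_beta0 = 0.4,
                         per_beta_steps = eps_decay_steps,
                         priority_floor = 1e-6, grad_clip = 10,
                         warmup = 1000L, pool_f = 3L, hidden = c(128L),
                         seed = 1L, checkpoint_path = NULL,
                         checkpoint_every = Inf, eval_every = 0L,
                         eval_episodes = 10L) {
  stopifnot(eps_start >= eps_end, eps_end >= 0, 30 %% pool_f == 0)
  structure(as.list(environment()), class = "train_config")
}

.eps_at <- function(cfg, step) {
  max(cfg$eps_end,
      cfg$eps_start - (cfg$eps_start - cfg$eps_end) *
        step / cfg$eps_decay_steps)
}

.beta_at <- function(cfg, step) {
  min(1, cfg$per_beta0 + (1 - cfg$per_beta0) * step / cfg$per_beta_steps)
}

# full mutable-state snapshot of an environment (for exact resume)
env_snapshot <- function(env) as.list.environment(env)

env_restore <- function(env, snap) {
  for (f in names(snap)) assign(f, snap[[f]], envir = env)
  invisible(env)
}

#' Train a dueling double DQN on a scanning environment
#'
#' @param env A `us_env` (or a factory function returning one).
#' @param config A [train_config()].
#' @param resume_from Optional checkpoint path (as written by this
#'   function) to continue from; the run proceeds exactly as if
#'   uninterrupted.
#' @param verbose Print progress every 2000 steps.
#' @return List with `net` (trained `qnet`), `target_net`, `history`
#'   (data frame: step, eps, loss, episode return, eval success rate) and
#'   `config`.
#' @export
train <- function(env, config = train_config(), resume_from = NULL,
                  verbose = FALSE) {
  if (is.function(env)) env <- env()
  input_dim <- 9L * as.integer(30L / config$pool_f)^3L

  if (!is.null(resume_from)) {
    ck <- readRDS(resume_from)
    net <- ck$net; tnet <- ck$target_net; opt <- ck$opt
    buf <- rb_restore(ck$buffer)
    env_restore(env, ck$env_state)
    assign(".Random.seed", ck$random_seed, envir = globalenv())
    step0 <- ck$step
    phi <- ck$phi
    ep_return <- ck$ep_return
    history <- ck$history
  } else {
    set.seed(config$seed)
    net <- qnet_init(input_dim, config$hidden, pool_f = config$pool_f,
                     seed = config$seed + 1L)
    tnet <- net
    opt <- adam_init(length(.qnet_params(net)), lr = config$lr)
    buf <- replay_buffer(config$buffer_capacity, input_dim,
                         alpha = config$per_alpha,
                         priority_floor = config$priority_floor)
    env_reset(env, seed = sample.int(2^30, 1L))
    phi <- featurize(env$history, config$pool_f)
    step0 <- 0L
    ep_return <- 0
    history <- list()
  }

  save_ck <- function(step) {
    if (is.null(config$checkpoint_path)) return(invisible())
    saveRDS(list(net = net, target_net = tnet, opt = opt,
                 buffer = rb_snapshot(buf), env_state = env_snapshot(env),
                 random_seed = get(".Random.seed", envir = globalenv()),
                 step = step, phi = phi, ep_return = ep_return,
                 history = history, config = config),
            config$checkpoint_path)
  }

  for (step in (step0 + 1L):config$total_steps) {
    eps <- .eps_at(config, step)
    a <- select_action(net, phi, eps)
    res <- env_step(env, a)
    phi2 <- featurize(env$history, config$pool_f)
    rb_add(buf, phi, a, res$reward, phi2, res$terminal != "none")
    ep_return <- ep_return + res$reward
    loss <- NA_real_
    if (rb_size(buf) >= config$warmup) {
      batch <- rb_sample(buf, config$batch_size, beta = .beta_at(config, step))
      y <- td_target(batch, net, tnet, config$gamma)
      lr <- qnet_learn(net, opt, batch$S, batch$a, y, batch$weights,
                       grad_clip = config$grad_clip)
      if (!is.finite(lr$loss))
        stop("training aborted: non-finite loss at step ", step)
      net <- lr$net; opt <- lr$opt
      rb_update(buf, batch$idx, lr$td_errors)
      loss <- lr$loss
    }
    if (step %% config$target_update_period == 0L) tnet <- net
    if (res$terminal != "none") {
      history[[length(history) + 1L]] <-
        list(step = step, eps = eps, loss = loss, episode_return = ep_return,
             terminal = res$terminal)
      ep_return <- 0
      env_reset(env, seed = sample.int(2^30, 1L))
      phi <- featurize(env$history, config$pool_f)
    } else phi <- phi2
    if (is.finite(config$checkpoint_every) &&
        step %% config$checkpoint_every == 0L) save_ck(step)
    if (verbose && step %% 2000L == 0L)
      message("step ", step, " eps=", round(eps, 3),
              " loss=", signif(loss, 3))
  }
  save_ck(config$total_steps)
  hist_df <- if (length(history))
    do.call(rbind, lapply(history, as.data.frame)) else
      data.frame(step = integer(), eps = numeric(), loss = numeric(),
                 episode_return = numeric(), terminal = character())
  list(net = net, target_net = tnet, history = hist_df, config = config)
}

#' Write a learning-curve CSV
#' @param result Value of [train()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_learning_curve <- function(result, path) {
  write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}
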