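# Decomposed reward: coverage + attenuation + shadow avoidance, with a
# terminal bonus on success and fixed penalties for mode switching and
# over-shadowed acquisitions.

#' Reward configuration
#'
#' @param alpha1 Weight of the attenuation term (0-1, default 1).
#' @param alpha2 Weight of the shadow term (0-1, default 0.5).
#' @param T_th Maximum tolerated shadowed fraction of the imaging plane;
#'   at or above it the step is penalized and its coverage discarded
#'   (default 0.20).
#' @param k_end Scale of the terminal success bonus (default 10).
#' @param success_fraction Cumulative coverage fraction that ends the
#'   episode successfully (default 0.95).
#' @param switch_penalty Reward for the mode-switch action (default -1).
#' @param shadow_penalty Reward for an examining step with shadow fraction
#'   at or above `T_th` (default -0.1).
#' @param max_steps Episode truncation length (default 80).
#' @return An object of class `reward_config`.
#' @export
reward_config <- function(alpha1 = 1, alpha2 = 0.5, T_th = 0.20, k_end = 10,
                          success_fraction = 0.95, switch_penalty = -1,
                          shadow_penalty = -0.1, max_steps = 80L) {
  stopifnot(alpha1 >= 0, alpha1 <= 1, alpha2 >= 0, alpha2 <= 1,
            T_th > 0, T_th <= 1, success_fraction > 0, success_fraction <= 1,
            max_steps >= 1)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, T_th = T_th,
                 k_end = k_end, success_fraction = success_fraction,
                 switch_penalty = switch_penalty,
                 shadow_penalty = shadow_penalty,
                 max_steps = as.integer(max_steps)),
            class = "reward_config")
}

#' Coverage reward: fraction of target voxels newly covered this step
#'
#' Previously covered voxels are excluded from `n_t`, so re-scanning an
#' already covered region earns nothing.
#'
#' @param n_t Newly covered target voxels this step.
#' @param N Total target voxels.
#' @return `n_t / N` in `[0, 1]`.
#' @export
reward_coverage <- function(n_t, N) {
  if (N <= 0) stop("target has no voxels (N = 0); mis-configured reset")
  stopifnot(n_t >= 0, n_t <= N)
  n_t / N
}

#' Attenuation reward: exp(-d_t / R_c)
#'
#' Penalizes probe-target distance as a proxy for acoustic attenuation
#' along the travelled path.
#'
#' @param d_t Probe-target distance (mm, generic scale).
#' @param R_c Cylinder radius (mm, generic scale).
#' @return Reward in `(0, 1]`.
#' @export
reward_attenuation <- function(d_t, R_c) {
  stopifnot(d_t >= 0, R_c > 0)
  exp(-d_t / R_c)
}

#' Shadow reward: 1 - p_t
#'
#' `p_t` is the shadowed fraction of the total scanned volume (insonified
#' plus shadowed cells in the imaging plane); when nothing is scanned
#' (`N_t = 0`) the fraction is defined as 1, so an uninformative pose earns
#' the minimum.
#'
#' @param n_shadow Shadowed cells this step.
#' @param N_t Total scanned cells this step (insonified + shadowed).
#' @return List with `r_s` and `p_t`.
#' @export
reward_shadow <- function(n_shadow, N_t) {
  stopifnot(N_t >= 0, n_shadow >= 0, n_shadow <= N_t || N_t == 0)
  p_t <- if (N_t > 0) n_shadow / N_t else 1
  list(r_s = 1 - p_t, p_t = p_t)
}

#' Per-step reward: r_c + alpha1 * r_a + alpha2 * r_s
#'
#' The coverage coefficient is fixed at 1 (it is the fundamental term).
#'
#' @param outcome List with components `r_c`, `r_a`, `r_s`.
#' @param config A [reward_config()].
#' @return Scalar reward in `[0, 1 + alpha1 + alpha2]`.
#' @export
reward_step <- function(outcome, config) {
  outcome$r_c + config$alpha1 * outcome$r_a + config$alpha2 * outcome$r_s
}

#' Terminal success bonus
#'
#' `r_end = k_end * (1 + alpha1 / D + alpha2 * P)` with
#' `D = mean(d_t / R_c)` and `P = mean(1 - p_t)` over the episode's
#' examining-mode steps.
#'
#' @param d_trace Per-step probe-target distances (mm, generic scale),
#'   examining-mode steps only.
#' @param p_trace Per-step shadow fractions, same steps.
#' @param config A [reward_config()].
#' @param R_c Cylinder radius (mm, generic scale).
#' @return Scalar terminal reward.
#' @export
reward_terminal <- function(d_trace, p_trace, config, R_c) {
  stopifnot(length(d_trace) == length(p_trace), length(d_trace) >= 1)
  D <- mean(d_trace / R_c)
  if (D <= 0) stop("degenerate episode: all probe-target distances zero")
  P <- mean(1 - p_trace)
  config$k_end * (1 + config$alpha1 / D + config$alpha2 * P)
}
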