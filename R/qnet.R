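# Dueling Q-network. The 9-channel 30^3 binary state is downsampled by a
# 3D max-pool (binary max = any) and fed to a fully connected trunk with
# rectifier units; two heads estimate the state value V(s) and the action
# advantages A(s, .), combined as Q = V + (A - mean(A)). Forward and
# backward passes are plain BLAS matrix products, sized so training runs
# on a single CPU core.

#' Max-pool a binary 3D array by an integer factor
#'
#' @param a 3D array (logical or 0/1) whose dimensions are divisible by `f`.
#' @param f Pooling factor.
#' @return 3D 0/1 array of dimension `dim(a) / f`.
#' @export
pool3d_max <- function(a, f) {
  d <- dim(a)
  stopifnot(length(d) == 3L, all(d %% f == 0L))
  m <- d %/% f
  dim(a) <- c(f, m[1L], f, m[2L], f, m[3L])
  b <- aperm(a, c(2L, 4L, 6L, 1L, 3L, 5L))
  dim(b) <- c(prod(m), f^3)
  array(as.integer(rowSums(b) > 0), m)
}

#' Flatten a state history into the network input vector
#'
#' Concatenates the max-pooled channels of the three time slots (oldest
#' first; channel order target, bone, insonified).
#'
#' @param history List of 3 `voxel_grid`s (as kept by `us_env`), or a
#'   9 x 30 x 30 x 30 state tensor.
#' @param pool_f Pooling factor (default 3: 30^3 -> 10^3 per channel).
#' @return Numeric 0/1 vector of length `9 * (30 / pool_f)^3`.
#' @export
featurize <- function(history, pool_f = 3L) {
  if (is.list(history)) {
    d <- history[[1L]]$dims
    x <- unlist(lapply(history, function(g)
      c(g$target, g$bone, g$ins)), use.names = FALSE)
    pool_stack_cpp(as.integer(x), 9L, as.integer(d), as.integer(pool_f))
  } else {
    stopifnot(length(dim(history)) == 4L)
    d <- dim(history)[-1L]
    x <- unlist(lapply(seq_len(dim(history)[1L]),
                       function(i) history[i, , , ]), use.names = FALSE)
    pool_stack_cpp(as.integer(x), dim(history)[1L], as.integer(d),
                   as.integer(pool_f))
  }
}

#' Initialize a dueling Q-network
#'
#' @param input_dim Length of the feature vector.
#' @param hidden Integer vector of trunk layer widths.
#' @param n_actions Size of the discrete action space (default 9).
#' @param pool_f Pooling factor recorded for featurization.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `qnet` (list of weight matrices and biases).
#' @export
qnet_init <- function(input_dim, hidden = c(128L), n_actions = 9L,
                      pool_f = 3L, seed = 1L) {
  with_seed(seed, {
    sizes <- c(input_dim, hidden)
    W <- list(); b <- list()
    for (i in seq_along(hidden)) {
      W[[i]] <- matrix(rnorm(sizes[i] * sizes[i + 1L],
                             sd = sqrt(2 / sizes[i])),
                       sizes[i], sizes[i + 1L])
      b[[i]] <- numeric(sizes[i + 1L])
    }
    last <- tail(sizes, 1L)
    structure(list(W = W, b = b,
                   Wv = matrix(rnorm(last, sd = sqrt(2 / last)), last, 1L),
                   bv = 0,
                   Wa = matrix(rnorm(last * n_actions, sd = sqrt(2 / last)),
                               last, n_actions),
                   ba = numeric(n_actions),
                   input_dim = input_dim, hidden = hidden,
                   n_actions = n_actions, pool_f = pool_f),
              class = "qnet")
  })
}

# forward pass; X is batch x input_dim. Returns Q and the activation cache.
qnet_forward <- function(net, X) {
  H <- list()
  A <- X
  for (i in seq_along(net$W)) {
    Z <- A %*% net$W[[i]]
    Z <- sweep(Z, 2L, net$b[[i]], "+")
    A <- pmax(Z, 0)
    H[[i]] <- A
  }
  V <- as.numeric(A %*% net$Wv) + net$bv
  Adv <- sweep(A %*% net$Wa, 2L, net$ba, "+")
  Q <- V + Adv - rowMeans(Adv)
  list(Q = Q, V = V, Adv = Adv, H = H, X = X)
}

#' Action values for a state
#'
#' Applies the dueling combination `Q = V + (A - mean(A))`.
#'
#' @param net A `qnet`.
#' @param state A feature vector, a state history list, or a 9-channel
#'   state tensor.
#' @return Numeric vector of `n_actions` action values.
#' @export
q_values <- function(net, state) {
  x <- if (is.numeric(state) && is.null(dim(state))) state
  else featurize(state, net$pool_f)
  if (length(x) != net$input_dim)
    stop("state feature length ", length(x), " does not match network input ",
         net$input_dim)
  as.numeric(qnet_forward(net, matrix(x, 1L))$Q)
}

#' Value and mean-centered advantage decomposition for a state
#' @inheritParams q_values
#' @return List with `V` (scalar) and `A` (centered advantages).
#' @export
q_decompose <- function(net, state) {
  x <- if (is.numeric(state) && is.null(dim(state))) state
  else featurize(state, net$pool_f)
  fw <- qnet_forward(net, matrix(x, 1L))
  list(V = fw$V, A = as.numeric(fw$Adv - rowMeans(fw$Adv)))
}

#' Epsilon-greedy action selection
#'
#' With probability `eps` a uniform random action; otherwise the argmax of
#' the action values, ties broken by the lowest index. Uses R's global RNG.
#'
#' @param net A `qnet`.
#' @param state State (any form accepted by [q_values()]).
#' @param eps Exploration rate in `[0, 1]`.
#' @return Action index in 1..n_actions.
#' @export
select_action <- function(net, state, eps) {
  stopifnot(eps >= 0, eps <= 1)
  if (eps > 0 && runif(1) < eps) sample.int(net$n_actions, 1L)
  else which.max(q_values(net, state))
}

# backward pass: dQ is the gradient of the loss wrt Q (batch x n_actions).
# Returns gradients for every parameter.
qnet_backward <- function(net, fw, dQ) {
  dV <- rowSums(dQ)
  dAdv <- dQ - rowMeans(dQ)
  top <- if (length(fw$H)) fw$H[[length(fw$H)]] else fw$X
  grads <- list(Wv = crossprod(top, dV), bv = sum(dV),
                Wa = crossprod(top, dAdv), ba = colSums(dAdv))
  dH <- matrix(dV, ncol = 1L) %*% t(net$Wv) + dAdv %*% t(net$Wa)
  gW <- vector("list", length(net$W)); gb <- vector("list", length(net$W))
  for (i in rev(seq_along(net$W))) {
    dZ <- dH * (fw$H[[i]] > 0)
    below <- if (i > 1L) fw$H[[i - 1L]] else fw$X
    gW[[i]] <- crossprod(below, dZ)
    gb[[i]] <- colSums(dZ)
    if (i > 1L) dH <- dZ %*% t(net$W[[i]])
  }
  grads$W <- gW; grads$b <- gb
  grads
}

# flatten/unflatten helpers for the optimizer
.qnet_params <- function(net) {
  c(unlist(net$W), unlist(net$b), as.numeric(net$Wv), net$bv,
    as.numeric(net$Wa), net$ba)
}

.qnet_set_params <- function(net, p) {
  k <- 0L
  take <- function(n) { out <- p[(k + 1L):(k + n)]; k <<- k + n; out }
  for (i in seq_along(net$W)) {
    d <- dim(net$W[[i]]); net$W[[i]] <- matrix(take(prod(d)), d[1L], d[2L])
  }
  for (i in seq_along(net$b)) net$b[[i]] <- take(length(net$b[[i]]))
  d <- dim(net$Wv); net$Wv <- matrix(take(prod(d)), d[1L], d[2L])
  net$bv <- take(1L)
  d <- dim(net$Wa); net$Wa <- matrix(take(prod(d)), d[1L], d[2L])
  net$ba <- take(length(net$ba))
  net
}

.grads_flat <- function(net, grads) {
  c(unlist(grads$W), unlist(grads$b), as.numeric(grads$Wv), grads$bv,
    as.numeric(grads$Wa), grads$ba)
}

adam_init <- function(n_params, lr = 7e-5, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(m = numeric(n_params), v = numeric(n_params), t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  opt$m <- opt$beta1 * opt$m + (1 - opt$beta1) * grads
  opt$v <- opt$beta2 * opt$v + (1 - opt$beta2) * grads^2
  mh <- opt$m / (1 - opt$beta1^opt$t)
  vh <- opt$v / (1 - opt$beta2^opt$t)
  list(opt = opt, params = params - opt$lr * mh / (sqrt(vh) + opt$eps))
}

# one importance-weighted Huber gradient step; returns updated net/opt,
# the per-sample TD errors, and the scalar loss.
qnet_learn <- function(net, opt, S, actions, targets, weights,
                       grad_clip = 10) {
  n <- nrow(S)
  fw <- qnet_forward(net, S)
  qa <- fw$Q[cbind(seq_len(n), actions)]
  err <- qa - targets
  huber <- ifelse(abs(err) <= 1, 0.5 * err^2, abs(err) - 0.5)
  loss <- mean(weights * huber)
  dqa <- weights * pmax(pmin(err, 1), -1) / n
  dQ <- matrix(0, n, net$n_actions)
  dQ[cbind(seq_len(n), actions)] <- dqa
  grads <- qnet_backward(net, fw, dQ)
  g <- .grads_flat(net, grads)
  gn <- sqrt(sum(g^2))
  if (is.finite(grad_clip) && gn > grad_clip) g <- g * (grad_clip / gn)
  upd <- adam_step(opt, .qnet_params(net), g)
  list(net = .qnet_set_params(net, upd$params), opt = upd$opt,
       td_errors = err, loss = loss)
}

#' Double-Q TD targets for a batch
#'
#' Terminal transitions get `y = r`; otherwise
#' `y = r + gamma * Q_target(s', argmax_a Q_online(s', a))` — the online
#' network selects the action, the target network evaluates it.
#'
#' @param batch List with `S2` (next-state matrix), `r` (rewards) and
#'   `terminal` (logical).
#' @param online,target `qnet`s.
#' @param gamma Discount factor.
#' @return Numeric vector of targets.
#' @export
td_target <- function(batch, online, target, gamma) {
  y <- batch$r
  live <- !batch$terminal
  if (any(live)) {
    S2 <- batch$S2[live, , drop = FALSE]
    a_star <- max.col(qnet_forward(online, S2)$Q, ties.method = "first")
    qt <- qnet_forward(target, S2)$Q
    y[live] <- batch$r[live] +
      gamma * qt[cbind(seq_along(a_star), a_star)]
  }
  y
}
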