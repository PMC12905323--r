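# Prioritized experience replay. Transitions are stored with their states
# bit-packed (the features are binary), so a 50k-transition buffer stays
# small in memory. Sampling probability is priority^alpha; importance
# weights are (capacity_used * P(i))^-beta, normalized by the batch
# maximum; priorities are refreshed to |TD error| + floor after learning.

.pack_bits <- function(x) {
  n <- length(x)
  pad <- (-n) %% 8L
  packBits(c(as.logical(x), logical(pad)))
}

.unpack_bits <- function(r, n) {
  as.integer(rawToBits(r))[seq_len(n)]
}

#' Create a prioritized replay buffer
#'
#' @param capacity Maximum number of transitions (ring buffer).
#' @param state_dim Length of the (binary) state feature vector.
#' @param alpha Priority exponent (default 0.6).
#' @param priority_floor Added to |TD error| so priorities stay positive.
#' @return An object of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity = 5e4, state_dim, alpha = 0.6,
                          priority_floor = 1e-6) {
  b <- new.env(parent = emptyenv())
  b$capacity <- as.integer(capacity)
  b$state_dim <- as.integer(state_dim)
  b$alpha <- alpha
  b$floor <- priority_floor
  b$S <- vector("list", capacity)
  b$S2 <- vector("list", capacity)
  b$a <- integer(capacity)
  b$r <- numeric(capacity)
  b$terminal <- logical(capacity)
  b$priority <- numeric(capacity)
  b$size <- 0L
  b$head <- 0L
  b$max_priority <- 1
  class(b) <- "replay_buffer"
  b
}

#' Number of stored transitions
#' @param buf A `replay_buffer`.
#' @return Integer count.
#' @export
rb_size <- function(buf) buf$size

#' Add a transition
#'
#' New transitions receive the maximum priority seen so far, so each is
#' learned from at least once.
#'
#' @param buf A `replay_buffer`.
#' @param s,s2 State feature vectors (binary).
#' @param a Action index.
#' @param r Reward.
#' @param terminal Logical.
#' @return The buffer, invisibly.
#' @export
rb_add <- function(buf, s, a, r, s2, terminal) {
  buf$head <- (buf$head %% buf$capacity) + 1L
  i <- buf$head
  buf$S[[i]] <- .pack_bits(s)
  buf$S2[[i]] <- .pack_bits(s2)
  buf$a[i] <- as.integer(a)
  buf$r[i] <- r
  buf$terminal[i] <- terminal
  buf$priority[i] <- buf$max_priority
  buf$size <- min(buf$size + 1L, buf$capacity)
  invisible(buf)
}

#' Sample a prioritized batch
#'
#' @param buf A `replay_buffer`.
#' @param n Batch size.
#' @param beta Importance-weight exponent (annealed 0.4 -> 1 in training).
#' @return List with `idx`, unpacked state matrices `S`, `S2`, vectors
#'   `a`, `r`, `terminal`, and max-normalized importance `weights` (all
#'   at most 1).
#' @export
rb_sample <- function(buf, n, beta = 0.4) {
  if (buf$size == 0L) stop("replay buffer is empty")
  m <- buf$size
  pr <- buf$priority[seq_len(m)]^buf$alpha
  probs <- pr / sum(pr)
  idx <- sample.int(m, n, replace = TRUE, prob = probs)
  w <- (m * probs[idx])^(-beta)
  w <- w / max(w)
  unpack <- function(lst) t(vapply(idx, function(i)
    .unpack_bits(lst[[i]], buf$state_dim), integer(buf$state_dim)))
  list(idx = idx, S = unpack(buf$S), S2 = unpack(buf$S2),
       a = buf$a[idx], r = buf$r[idx], terminal = buf$terminal[idx],
       weights = w)
}

#' Update priorities after a learning step
#'
#' @param buf A `replay_buffer`.
#' @param idx Indices returned by [rb_sample()].
#' @param td_errors Per-sample TD errors.
#' @return The buffer, invisibly.
#' @export
rb_update <- function(buf, idx, td_errors) {
  p <- abs(td_errors) + buf$floor
  buf$priority[idx] <- p
  buf$max_priority <- max(buf$max_priority, p)
  invisible(buf)
}

# snapshot/restore for checkpointing
rb_snapshot <- function(buf) {
  as.list.environment(buf)[c("capacity", "state_dim", "alpha", "floor", "S", "S2",
                 "a", "r", "terminal", "priority", "size", "head",
                 "max_priority")]
}

rb_restore <- function(snap) {
  b <- replay_buffer(snap$capacity, snap$state_dim, snap$alpha, snap$floor)
  for (f in names(snap)) assign(f, snap[[f]], envir = b)
  b
}
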