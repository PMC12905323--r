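# Dueling network identity, action selection, double-Q targets,
# prioritized replay, and training-loop determinism.

# a network whose top activation is forced to 1 so head outputs are
# readable: W1 = 0, b1 = 1 -> hidden activation 1 for any input
readable_net <- function(bv = 1, ba = rep(0, 9)) {
  net <- qnet_init(4L, hidden = 1L, seed = 1)
  net$W[[1]][] <- 0
  net$b[[1]] <- 1
  net$Wv[] <- 0
  net$bv <- bv
  net$Wa[] <- 0
  net$ba <- ba
  net
}

test_that("dueling combination: advantages are mean-centered", {
  # worked example: V = 1, A = (0.5, -0.5, 0, ...) with mean 0
  net <- readable_net(bv = 1, ba = c(0.5, -0.5, rep(0, 7)))
  q <- q_values(net, c(1, 0, 1, 0))
  expect_equal(q, c(1.5, 0.5, rep(1, 7)))
  # constant advantage head collapses to Q = V for all actions
  cnet <- readable_net(bv = 2.5, ba = rep(7, 9))
  expect_equal(q_values(cnet, rep(0, 4)), rep(2.5, 9))
  # identity over random draws: sum_a (Q - V) = 0
  for (sd in 1:100) {
    net <- qnet_init(24L, hidden = c(8L, 6L), seed = sd)
    with_seed(sd, x <- as.numeric(runif(24) > 0.5))
    dec <- q_decompose(net, x)
    q <- q_values(net, x)
    expect_lt(abs(sum(q - dec$V)), 1e-5)
    expect_equal(q, dec$V + dec$A, tolerance = 1e-9)
  }
})

test_that("epsilon-greedy selection: uniform at 1, argmax with low-index
           ties at 0", {
  net <- qnet_init(6L, hidden = 4L, seed = 2)
  x <- c(1, 0, 0, 1, 1, 0)
  with_seed(10, {
    draws <- replicate(9000, select_action(net, x, eps = 1))
    tab <- tabulate(draws, 9)
    expect_gt(chisq.test(tab)$p.value, 0.01)
  })
  a0 <- replicate(20, select_action(net, x, eps = 0))
  expect_equal(length(unique(a0)), 1L)
  expect_equal(a0[1], which.max(q_values(net, x)))
  tie <- readable_net(bv = 0, ba = c(0, 3, 1, 3, 0, 0, 0, 0, 0))
  expect_equal(select_action(tie, c(1, 1, 0, 0), eps = 0), 2L)
})

test_that("double-Q targets: terminal, discount-free and hand-computed", {
  online <- readable_net(bv = 0, ba = c(0, 0, 5, rep(0, 6)))
  target <- readable_net(bv = 2, ba = 1:9)
  S2 <- matrix(runif(8), 2, 4)
  batch <- list(S2 = S2, r = c(3, -1), terminal = c(TRUE, FALSE))
  expect_equal(td_target(batch, online, target, 0.9)[1], 3)
  expect_equal(td_target(batch, online, target, 0)[2], -1)
  # online argmax is action 3; target evaluates it: Q_t(3) = 2 + (3 - 5)
  expect_equal(td_target(batch, online, target, 0.5)[2], -1 + 0.5 * 0)
  target2 <- readable_net(bv = 4, ba = c(9, rep(0, 8)))
  # Q_t2(a) = 4 + ba - mean(ba); a* = 3 -> 4 + 0 - 1 = 3
  expect_equal(td_target(batch, online, target2, 0.5)[2], -1 + 0.5 * 3)
})

test_that("prioritized sampling follows priority^alpha with bounded
           weights", {
  buf <- replay_buffer(16L, state_dim = 4L, alpha = 1)
  s <- c(1, 0, 1, 0)
  for (i in 1:2) rb_add(buf, s, 1L, 0, s, FALSE)
  rb_update(buf, 1:2, c(3, 1))           # priorities 3 and 1
  with_seed(3, {
    idx <- rb_sample(buf, 4000L, beta = 1)$idx
    k <- sum(idx == 1L)
    # binomial CI around 3/4
    expect_gt(k / 4000, 0.75 - 3 * sqrt(0.75 * 0.25 / 4000))
    expect_lt(k / 4000, 0.75 + 3 * sqrt(0.75 * 0.25 / 4000))
  })
  # equal priorities sample uniformly
  buf2 <- replay_buffer(8L, state_dim = 4L, alpha = 0.6)
  for (i in 1:8) rb_add(buf2, s, 1L, 0, s, FALSE)
  with_seed(4, {
    smp <- rb_sample(buf2, 8000L, beta = 0.5)
    expect_gt(chisq.test(tabulate(smp$idx, 8))$p.value, 0.01)
    expect_true(all(smp$weights <= 1 + 1e-12))
    expect_equal(max(smp$weights), 1)
  })
  expect_error(rb_sample(replay_buffer(4L, 4L), 2L), "empty")
})

test_that("replay round-trips packed states and refreshes priorities", {
  buf <- replay_buffer(4L, state_dim = 11L)
  s1 <- as.numeric(runif(11) > 0.4)
  s2 <- as.numeric(runif(11) > 0.6)
  rb_add(buf, s1, 5L, 2.5, s2, TRUE)
  smp <- rb_sample(buf, 3L, beta = 0.4)
  expect_equal(smp$S[1, ], as.integer(s1))
  expect_equal(smp$S2[1, ], as.integer(s2))
  expect_equal(smp$a[1], 5L)
  expect_true(smp$terminal[1])
  rb_update(buf, 1L, td_errors = -2)
  expect_equal(buf$priority[1], 2 + 1e-6)
  expect_gt(buf$max_priority, 2)
})

test_that("gradient steps reduce the Huber loss on a fixed batch", {
  with_seed(9, {
    net <- qnet_init(12L, hidden = 8L, seed = 9)
    opt <- icuplan:::adam_init(length(icuplan:::.qnet_params(net)),
                               lr = 1e-2)
    S <- matrix(as.numeric(runif(12 * 16) > 0.5), 16, 12)
    a <- sample.int(9, 16, replace = TRUE)
    y <- runif(16, -1, 1)
    w <- rep(1, 16)
    first <- NA
    for (i in 1:60) {
      st <- icuplan:::qnet_learn(net, opt, S, a, y, w)
      if (i == 1) first <- st$loss
      net <- st$net; opt <- st$opt
    }
    expect_lt(st$loss, first / 4)
  })
})

test_that("training is deterministic and resumable from a checkpoint", {
  mk_env <- function() us_env(scene = easy_scene(), randomize = NULL)
  base <- list(lr = 5e-3, target_update_period = 50L,
               eps_decay_steps = 100L, buffer_capacity = 400L,
               warmup = 40L, pool_f = 10L, hidden = 8L, seed = 77L,
               batch_size = 8L)
  run <- function(steps, ckpt = NULL, resume = NULL) {
    cfg <- do.call(train_config,
                   c(base, list(total_steps = steps,
                                checkpoint_path = ckpt)))
    train(mk_env(), cfg, resume_from = resume)
  }
  r1 <- run(120L)
  r2 <- run(120L)
  expect_identical(icuplan:::.qnet_params(r1$net),
                   icuplan:::.qnet_params(r2$net))
  expect_identical(r1$history, r2$history)
  # resume: 120 uninterrupted == 60 + checkpoint + 60 more
  ck <- tempfile(fileext = ".rds")
  run(60L, ckpt = ck)
  r3 <- run(120L, resume = ck)
  expect_identical(icuplan:::.qnet_params(r1$net),
                   icuplan:::.qnet_params(r3$net))
  expect_identical(r1$history, r3$history)
})
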