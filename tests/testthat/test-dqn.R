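# Double-DQN machinery: Q-network contract, epsilon-greedy statistics, the
# double-Q target, TD loss, replay buffer semantics, target sync, and
# convergence to the value-iteration optimum on a small chain MDP.

tiny_qcfg <- function() {
  dqn_config(capacity = 50, batch_size = 8, sync_period = 10, state_size = 15,
             channels = c(4, 6, 8, 10), stem_kernel = 3, stem_stride = 1,
             profile = "desk")
}

test_that("q_forward: 8 finite outputs, deterministic, seed-sensitive", {
  cfg <- tiny_qcfg()
  net <- q_network(cfg, seed = 1)
  s <- array(stats::runif(15 * 15 * 5, -1, 1), c(15, 15, 5))
  q <- q_forward(net, s)
  expect_length(q, 8)
  expect_true(all(is.finite(q)))
  expect_identical(q, q_forward(net, s))
  net2 <- q_network(cfg, seed = 2)
  expect_false(isTRUE(all.equal(q, q_forward(net2, s))))
  expect_error(q_forward(net, array(0, c(14, 15, 5, 1))))
})

test_that("select_action: greedy argmax and epsilon mixture frequencies", {
  q <- c(0, 1, 2, 9, 4, 5, 6, 7)
  set.seed(30)
  expect_true(all(replicate(50, select_action(q, 0)) == 3))
  # epsilon = 1: uniform over 8 actions, binomial CI on 80,000 draws
  set.seed(31)
  draws <- replicate(80000, select_action(q, 1))
  expect_equal(as.numeric(table(factor(draws, 0:7))) / 80000, rep(0.125, 8),
               tolerance = 0.005 / 0.125)
  # epsilon = 0.2: argmax frequency 0.8 + 0.2/8 = 0.825
  set.seed(32)
  draws <- replicate(100000, select_action(q, 0.2))
  expect_equal(mean(draws == 3), 0.825, tolerance = 0.01 / 0.825)
})

test_that("double-Q target: hand case, divergence from vanilla, terminals, gamma 0", {
  # eval picks argmax index 2 (value 2); target scores it 0 => target = 0
  qe <- matrix(c(1, 2), 2, 1)
  qt <- matrix(c(5, 0), 2, 1)
  expect_equal(double_q_target(qe, qt, r = 0, done = FALSE, gamma = 0.9), 0)
  vanilla <- 0 + 0.9 * max(qt)                  # 4.5: the overestimating form
  expect_false(double_q_target(qe, qt, 0, FALSE, 0.9) == vanilla)
  expect_equal(double_q_target(qe, qt, r = 1.5, done = TRUE, gamma = 0.9), 1.5)
  set.seed(33)
  qe2 <- matrix(rnorm(8 * 6), 8, 6); qt2 <- matrix(rnorm(8 * 6), 8, 6)
  r <- rnorm(6); done <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  expect_equal(double_q_target(qe2, qt2, r, done, gamma = 0), r)
  tg <- double_q_target(qe2, qt2, r, done, gamma = 0.9)
  expect_equal(tg[done], r[done])
})

test_that("td_loss: zero at fit, single-sample arithmetic, quadratic scaling", {
  cfg <- tiny_qcfg()
  net <- q_network(cfg, seed = 3)
  s <- array(stats::runif(15 * 15 * 5 * 4, -1, 1), c(15, 15, 5, 4))
  a <- c(0L, 3L, 7L, 2L)
  batch <- list(s = s, a = a, r = numeric(4), done = rep(FALSE, 4), s2 = s)
  q <- q_forward(net, s)
  fit <- q[cbind(a + 1L, 1:4)]
  expect_equal(td_loss(batch, fit, net), 0)
  expect_equal(td_loss(list(s = s[, , , 1, drop = FALSE], a = a[1], r = 0,
                            done = FALSE, s2 = NULL),
                       fit[1] + 2, net), 4)
  resid <- fit + c(1, -1, 2, 0.5)
  expect_equal(td_loss(batch, fit + 2 * (resid - fit), net),
               4 * td_loss(batch, resid, net))
  expect_error(td_loss(batch, fit[1:2], net), "mismatch")
})

test_that("replay buffer: FIFO overwrite, seeded reproducibility, uniformity", {
  buf <- replay_buffer(10, c(2, 2, 1))
  for (i in 1:11) {
    s <- array(i, c(2, 2, 1))
    buffer_push(buf, s, i %% 8L, i, FALSE, s)
  }
  expect_equal(buf$size, 10L)
  expect_false(any(buf$r == 1))                  # oldest overwritten
  expect_true(all(2:11 %in% buf$r))
  set.seed(40)
  b1 <- buffer_sample(buf, 4)
  set.seed(40)
  b2 <- buffer_sample(buf, 4)
  expect_identical(b1$idx, b2$idx)
  expect_identical(b1$s, b2$s)
  # uniformity of single-item samples
  set.seed(41)
  picks <- replicate(50000, buffer_sample(buf, 1)$r)
  freq <- unname(table(factor(picks, 2:11))) / 50000
  expect_equal(as.numeric(freq), rep(0.1, 10), tolerance = 0.01 / 0.1)
  # under-filled buffer refuses to sample
  buf2 <- replay_buffer(10, c(2, 2, 1))
  buffer_push(buf2, array(0, c(2, 2, 1)), 0L, 0, FALSE, array(0, c(2, 2, 1)))
  expect_error(buffer_sample(buf2, 1), "warm-up")
})

test_that("sync_target copies exactly and checks architecture", {
  cfg <- tiny_qcfg()
  net <- q_network(cfg, seed = 4)
  targ <- sync_target(net)
  s <- array(stats::runif(15 * 15 * 5, -1, 1), c(15, 15, 5))
  expect_identical(q_forward(net, s), q_forward(targ, s))
  # one gradient step moves the eval net but not the target copy
  opt <- nn_adam_init(net, lr = 1e-2)
  batch <- list(s = array(s, c(15, 15, 5, 1)), a = 0L, r = 1, done = TRUE,
                s2 = array(s, c(15, 15, 5, 1)))
  up <- dqn_update(net, targ, opt, batch, 0.9)
  expect_false(isTRUE(all.equal(q_forward(up$net_eval, s), q_forward(targ, s))))
  other <- q_network(dqn_config(state_size = 15, channels = c(2, 2, 2, 2),
                                stem_kernel = 3, stem_stride = 1,
                                capacity = 50, batch_size = 8,
                                profile = "desk"), seed = 1)
  expect_error(sync_target(net, other), "architecture mismatch")
})

test_that("repeated updates on a fixed batch reduce the TD loss", {
  cfg <- tiny_qcfg()
  set.seed(50)
  net <- q_network(cfg, seed = 5)
  targ <- sync_target(net)
  opt <- nn_adam_init(net, lr = 1e-3)
  s <- array(runif(15 * 15 * 5 * 8, -1, 1), c(15, 15, 5, 8))
  batch <- list(s = s, a = sample(0:7, 8, TRUE), r = runif(8, -1.5, 1.5),
                done = rep(TRUE, 8), s2 = s)
  losses <- numeric(60)
  for (i in 1:60) {
    up <- dqn_update(net, targ, opt, batch, 0.9)
    net <- up$net_eval; opt <- up$opt; losses[i] <- up$loss
  }
  expect_lt(losses[60], losses[1] / 10)
})

test_that("tabular-capacity training converges to value-iteration Q*", {
  mdp <- chain_mdp()
  qstar <- oracle_value_iteration(mdp$P, mdp$R, mdp$terminal, gamma = 0.9)
  # a single linear layer on one-hot states IS a Q table
  set.seed(60)
  net <- nn_seq(nn_dense(mdp$nS, mdp$nA, activation = "linear"))
  targ <- sync_target(net)
  # Adam's terminal oscillation is O(lr), so lr must sit well under the 1e-2
  # tolerance for the learned table to settle
  opt <- nn_adam_init(net, lr = 3e-3)
  buf <- replay_buffer(200, mdp$nS)
  s <- 1L
  for (step in 1:6000) {
    a <- if (runif(1) < 0.3) sample.int(2, 1) else
      which.max(q_forward(net, matrix(one_hot(s, mdp$nS))))
    s2 <- mdp$P[s, a]
    r <- mdp$R[s, a]
    done <- mdp$terminal[s2]
    buffer_push(buf, matrix(one_hot(s, mdp$nS)), a - 1L, r, done,
                matrix(one_hot(s2, mdp$nS)))
    if (buf$size >= buf$capacity) {
      up <- dqn_update(net, targ, opt, buffer_sample(buf, 32), 0.9)
      net <- up$net_eval; opt <- up$opt
      if (step %% 25 == 0) targ <- sync_target(net, targ)
    }
    s <- if (done) 1L else s2
  }
  q_learned <- t(sapply(1:mdp$nS, function(i)
    q_forward(net, matrix(one_hot(i, mdp$nS)))))
  # compare on non-terminal states (terminal Q is never trained)
  expect_lt(max(abs(q_learned[1:4, ] - qstar[1:4, ])), 1e-2)
})
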