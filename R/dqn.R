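# Double deep Q-network agent (the next-point network): reduced residual
# backbone + adaptive average pooling + linear head over the 8 actions, a FIFO
# replay buffer, epsilon-greedy behaviour, the double-Q target (action chosen
# by the evaluation network, scored by the target network) and the training
# loop: fill the buffer, then one gradient update per environment step with
# periodic target synchronisation.

#' DQN configuration
#'
#' "full" profile: 51 px states, buffer 21,000, batch 256, lr 1e-4, sync
#' every 2,000 updates, wide ResNet-18-like backbone \[1,1,1,1\] - GPU-scale,
#' not exercised by the tests. "desk" profile: 25 px states, buffer 2,000,
#' batch 8, lr 1e-3, sync every 200, narrow backbone; runs on one CPU.
#' Discount 0.9 and exploration 0.2 (used in both training and testing) are
#' shared by both profiles.
#'
#' @param gamma discount factor.
#' @param epsilon exploration probability (training and testing).
#' @param capacity replay buffer size (transitions).
#' @param batch_size gradient batch size.
#' @param lr Adam learning rate.
#' @param sync_period target-network synchronisation period (updates).
#' @param state_size state window side (px).
#' @param in_channels state channel count (5, or fewer under state ablation).
#' @param channels backbone stage widths.
#' @param pool_size adaptive-average-pool output side before the linear head:
#'   1 = global average (full-size default, where 512 channels carry the
#'   directional information); the desk profile pools to 2x2 so its narrow
#'   feature maps keep coarse location.
#' @param stem_kernel,stem_stride stem convolution geometry.
#' @param n_actions action count (8).
#' @param profile preset name.
#' @export
dqn_config <- function(gamma = 0.9, epsilon = 0.2, capacity = NULL,
                       batch_size = NULL, lr = NULL, sync_period = NULL,
                       state_size = NULL, in_channels = 5, channels = NULL,
                       pool_size = NULL, stem_kernel = NULL,
                       stem_stride = NULL, n_actions = 8,
                       profile = c("full", "desk")) {
  profile <- match.arg(profile)
  base <- if (profile == "full") {
    list(capacity = 21000, batch_size = 256, lr = 1e-4, sync_period = 2000,
         state_size = 51, channels = c(64, 128, 256, 512), pool_size = 1,
         stem_kernel = 7, stem_stride = 2)
  } else {
    list(capacity = 2000, batch_size = 8, lr = 1e-3, sync_period = 200,
         state_size = 25, channels = c(8, 12, 16, 24), pool_size = 2,
         stem_kernel = 3, stem_stride = 1)
  }
  given <- list(capacity = capacity, batch_size = batch_size, lr = lr,
                sync_period = sync_period, state_size = state_size,
                channels = channels, pool_size = pool_size,
                stem_kernel = stem_kernel, stem_stride = stem_stride)
  for (nm in names(given)) if (!is.null(given[[nm]])) base[[nm]] <- given[[nm]]
  stopifnot(gamma >= 0, gamma <= 1, epsilon >= 0, epsilon <= 1,
            base$capacity >= base$batch_size)
  base$gamma <- gamma
  base$epsilon <- epsilon
  base$in_channels <- in_channels
  base$n_actions <- n_actions
  base$profile <- profile
  structure(base, class = "dqn_config")
}

#' Build a Q-network
#'
#' Stem convolution, four residual stages (\[1,1,1,1\] blocks, strides
#' 1/2/2/2), adaptive average pooling (`pool_size`) and a linear head with
#' one output per action.
#'
#' @param cfg a [dqn_config()].
#' @param seed initialisation seed.
#' @return an `nn_layer` network.
#' @export
q_network <- function(cfg = dqn_config(profile = "desk"), seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ch <- cfg$channels
  head <- if (cfg$pool_size == 1) {
    list(nn_gap(), nn_dense(ch[4], cfg$n_actions, activation = "linear"))
  } else {
    list(nn_resize(cfg$pool_size, cfg$pool_size),   # block-average pooling
         nn_flatten(),
         nn_dense(ch[4] * cfg$pool_size^2, cfg$n_actions,
                  activation = "linear"))
  }
  net <- do.call(nn_seq, c(
    list(nn_conv(cfg$in_channels, ch[1], cfg$stem_kernel, cfg$stem_stride,
                 activation = "relu"),
         nn_res_block(ch[1], ch[1], 1),
         nn_res_block(ch[1], ch[2], 2),
         nn_res_block(ch[2], ch[3], 2),
         nn_res_block(ch[3], ch[4], 2)),
    head))
  attr(net, "state_size") <- cfg$state_size
  attr(net, "in_channels") <- cfg$in_channels
  net
}

state_array <- function(s) {
  if (inherits(s, "env_state")) s <- s$layers
  if (length(dim(s)) == 3) dim(s) <- c(dim(s), 1L)   # single conv state
  s                                                  # matrices pass through
}

#' Q-values of one or more states
#'
#' @param net a [q_network()].
#' @param s an `env_state`, a (w, w, k) array, or a (w, w, k, N) batch.
#' @return numeric vector of length `n_actions`, or a (n_actions, N) matrix.
#' @export
q_forward <- function(net, s) {
  x <- state_array(s)
  ss <- attr(net, "state_size")
  if (!is.null(ss)) {
    want <- c(ss, ss, attr(net, "in_channels"))
    if (length(dim(x)) != 4 || !identical(as.integer(dim(x)[1:3]),
                                          as.integer(want))) {
      stop(sprintf("state shape %s does not match the network's %s",
                   paste(dim(x), collapse = "x"), paste(want, collapse = "x")))
    }
  }
  q <- nn_forward(net, x)$out
  if (ncol(q) == 1) as.numeric(q) else q
}

#' Epsilon-greedy action selection from Q-values
#'
#' With probability `epsilon` a uniformly random action, otherwise the argmax
#' (smallest-index tie-break). Uses the current RNG stream.
#'
#' @param q numeric vector of action values.
#' @param epsilon exploration probability.
#' @return action index 0..(length(q) - 1).
#' @export
select_action <- function(q, epsilon) {
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    sample.int(length(q), 1) - 1L
  } else {
    which.max(q) - 1L
  }
}

#' Double-Q target from explicit Q matrices
#'
#' For non-terminal transitions `r + gamma * Q_targ(s', argmax_a Q_eval(s', a))`;
#' for terminal transitions just `r` (the closing step has no successor).
#'
#' @param q_eval_next,q_targ_next (n_actions, N) matrices of next-state values
#'   under the evaluation and target networks.
#' @param r rewards (length N).
#' @param done terminal flags (length N).
#' @param gamma discount factor.
#' @return numeric vector of N targets.
#' @export
double_q_target <- function(q_eval_next, q_targ_next, r, done, gamma) {
  q_eval_next <- as.matrix(q_eval_next)
  q_targ_next <- as.matrix(q_targ_next)
  n <- length(r)
  stopifnot(ncol(q_eval_next) == n, ncol(q_targ_next) == n, length(done) == n)
  a_star <- apply(q_eval_next, 2, which.max)
  boot <- q_targ_next[cbind(a_star, seq_len(n))]
  r + gamma * boot * as.numeric(!done)
}

#' Double-Q targets for a sampled batch
#'
#' @param batch a batch from [buffer_sample()].
#' @param net_eval,net_targ evaluation and target networks.
#' @param gamma discount factor.
#' @export
compute_double_q_target <- function(batch, net_eval, net_targ, gamma) {
  if (length(batch$r) == 0) stop("empty batch")
  qe <- q_forward(net_eval, batch$s2)
  qt <- q_forward(net_targ, batch$s2)
  if (is.null(dim(qe))) { qe <- matrix(qe); qt <- matrix(qt) }
  double_q_target(qe, qt, batch$r, batch$done, gamma)
}

#' Temporal-difference loss of a batch
#'
#' Mean squared error between the (detached) targets and the evaluation
#' network's value of the taken actions.
#'
#' @param batch a batch from [buffer_sample()].
#' @param targets per-sample targets (e.g. from [compute_double_q_target()]).
#' @param net_eval evaluation network.
#' @export
td_loss <- function(batch, targets, net_eval) {
  n <- length(batch$r)
  if (length(targets) != n) stop("batch/target size mismatch")
  q <- q_forward(net_eval, batch$s)
  if (is.null(dim(q))) q <- matrix(q)
  pred <- q[cbind(batch$a + 1L, seq_len(n))]
  mean((targets - pred)^2)
}

# ---- replay buffer ----------------------------------------------------------

#' Create a FIFO replay buffer
#'
#' Preallocated ring store; when full, the newest transition overwrites the
#' oldest.
#'
#' @param capacity maximum number of transitions.
#' @param state_dim state dimensions, e.g. `c(w, w, k)` for image states or a
#'   single feature count for vector states.
#' @return environment of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity, state_dim) {
  buf <- new.env(parent = emptyenv())
  buf$capacity <- as.integer(capacity)
  buf$state_dim <- state_dim
  # states live in lists: element assignment is pointer-sized, while writing
  # columns of one big preallocated matrix would copy it on every push
  buf$s <- vector("list", capacity)
  buf$s2 <- vector("list", capacity)
  buf$a <- integer(capacity)
  buf$r <- numeric(capacity)
  buf$done <- logical(capacity)
  buf$size <- 0L
  buf$cursor <- 1L
  class(buf) <- "replay_buffer"
  buf
}

#' Push a transition into the buffer
#'
#' @param buf a [replay_buffer()].
#' @param s,s2 states (env_state or array).
#' @param a action 0..7.
#' @param r reward.
#' @param done terminal flag.
#' @export
buffer_push <- function(buf, s, a, r, done, s2) {
  i <- buf$cursor
  buf$s[[i]] <- as.vector(state_array(s))
  buf$s2[[i]] <- as.vector(state_array(s2))
  buf$a[i] <- as.integer(a)
  buf$r[i] <- r
  buf$done[i] <- done
  buf$cursor <- if (i == buf$capacity) 1L else i + 1L
  buf$size <- min(buf$size + 1L, buf$capacity)
  invisible(buf)
}

#' Sample a batch uniformly without replacement
#'
#' Learning only starts once the buffer is full; sampling earlier is an error.
#'
#' @param buf a [replay_buffer()].
#' @param batch_size number of transitions.
#' @return list with `s`, `a`, `r`, `done`, `s2`, `idx`.
#' @export
buffer_sample <- function(buf, batch_size) {
  if (buf$size < buf$capacity) {
    stop(sprintf("replay buffer not yet full (%d / %d): warm-up incomplete",
                 buf$size, buf$capacity))
  }
  idx <- sample.int(buf$size, batch_size)
  d <- prod(buf$state_dim)
  gather <- function(lst) {
    array(vapply(idx, function(j) lst[[j]], numeric(d)),
          c(buf$state_dim, length(idx)))
  }
  list(s = gather(buf$s), a = buf$a[idx], r = buf$r[idx],
       done = buf$done[idx], s2 = gather(buf$s2), idx = idx)
}

#' Synchronise the target network with the evaluation network
#'
#' Returns an exact copy of the evaluation network; later evaluation updates
#' do not mutate it (copy semantics).
#'
#' @param net_eval evaluation network.
#' @param net_targ optional existing target network (architecture check).
#' @export
sync_target <- function(net_eval, net_targ = NULL) {
  if (!is.null(net_targ) &&
      length(nn_flat_params(net_eval)) != length(nn_flat_params(net_targ))) {
    stop("architecture mismatch between evaluation and target networks")
  }
  net_eval
}

#' One double-DQN gradient update
#'
#' Computes targets through the target network, backpropagates the TD loss
#' through the evaluation network only, and applies one Adam step.
#'
#' @param net_eval,net_targ networks.
#' @param opt optimizer state from [nn_adam_init()].
#' @param batch a batch from [buffer_sample()].
#' @param gamma discount factor.
#' @return list with updated `net_eval`, `opt`, and the scalar `loss`.
#' @export
dqn_update <- function(net_eval, net_targ, opt, batch, gamma) {
  targets <- compute_double_q_target(batch, net_eval, net_targ, gamma)
  n <- length(batch$r)
  fw <- nn_forward(net_eval, state_array(batch$s), keep_cache = TRUE)
  q <- fw$out
  sel <- cbind(batch$a + 1L, seq_len(n))
  pred <- q[sel]
  loss <- mean((targets - pred)^2)
  dq <- matrix(0, nrow(q), n)
  dq[sel] <- 2 * (pred - targets) / n
  bw <- nn_backward(net_eval, fw$cache, dq, need_dx = FALSE)
  st <- nn_adam_step(net_eval, bw$grads, opt)
  list(net_eval = st$layer, opt = st$opt, loss = loss)
}

# ---- training and inference loops -------------------------------------------

episode_from_sample <- function(sample, first_p, env_cfg, rcfg,
                                with_gt = TRUE) {
  pm <- first_p_forward(first_p, first_p_input(sample$image))
  fp <- select_first_point(pm, first_p$cfg$scale)
  fp[1] <- min(max(fp[1], 1), nrow(sample$image))
  fp[2] <- min(max(fp[2], 1), ncol(sample$image))
  env_init(sample$image, pm, fp, cfg = env_cfg, rcfg = rcfg,
           gt_mask = if (with_gt) sample$mask,
           gt_contour = if (with_gt) sample$contour)
}

#' Train the double-DQN agent
#'
#' Warm-up fills the replay buffer with epsilon-greedy experience; thereafter
#' one gradient update per environment step, with the target network
#' synchronised every `sync_period` updates. All randomness (exploration,
#' sampling, episode order) flows from `seed`.
#'
#' @param dataset list of samples, each with `image`, `mask`, `contour`.
#' @param first_p a trained (or stub) first-point network.
#' @param env_cfg an [env_config()] (its `state_layers` must match
#'   `dqn_cfg$in_channels`).
#' @param rcfg a [reward_config()].
#' @param dqn_cfg a [dqn_config()].
#' @param total_steps total environment steps (warm-up included).
#' @param seed master seed.
#' @param net_eval optionally continue training an existing network.
#' @param verbose print progress every 500 steps.
#' @return list with `net_eval`, `net_targ`, `log` (per-step data.frame:
#'   reward components, total reward, TD loss, episode metrics at episode
#'   ends), `opt`, and the configs.
#' @export
train_agent <- function(dataset, first_p, env_cfg = env_config(profile = "desk"),
                        rcfg = reward_config(),
                        dqn_cfg = dqn_config(profile = "desk"),
                        total_steps = 5000, seed = 1L, net_eval = NULL,
                        verbose = FALSE) {
  stopifnot(length(dataset) >= 1)
  k <- length(state_layer_channels(env_cfg$state_layers))
  if (k != dqn_cfg$in_channels) {
    stop(sprintf("state has %d channels but the network expects %d", k,
                 dqn_cfg$in_channels))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(net_eval)) net_eval <- q_network(dqn_cfg, seed = seed)
  net_targ <- sync_target(net_eval)
  opt <- nn_adam_init(net_eval, lr = dqn_cfg$lr)
  buf <- replay_buffer(dqn_cfg$capacity,
                       c(env_cfg$state_size, env_cfg$state_size, k))
  n_updates <- 0L
  ep_idx <- 0L
  ep <- NULL
  state <- NULL
  logs <- vector("list", total_steps)
  for (step in seq_len(total_steps)) {
    if (is.null(ep) || ep$done) {
      ep_idx <- ep_idx + 1L
      sample_i <- dataset[[(ep_idx - 1L) %% length(dataset) + 1L]]
      ep <- episode_from_sample(sample_i, first_p, env_cfg, rcfg)
      state <- extract_state(ep)
    }
    # warm-up acts uniformly at random: the untrained argmax policy would
    # pin the agent to a border and fill the buffer with degenerate data
    eps_now <- if (buf$size < buf$capacity) 1 else dqn_cfg$epsilon
    a <- if (stats::runif(1) < eps_now) {
      sample.int(dqn_cfg$n_actions, 1) - 1L
    } else {
      which.max(q_forward(net_eval, state)) - 1L
    }
    st <- env_step(ep, a)
    # a step-cap ending is truncation, not an MDP terminal: bootstrap through
    # it; only a closed contour is a true terminal (no successor)
    terminal <- st$done && identical(st$done_reason, "closed")
    buffer_push(buf, state, a, st$reward, terminal, st$state)
    loss <- NA_real_
    if (buf$size >= buf$capacity) {
      batch <- buffer_sample(buf, dqn_cfg$batch_size)
      up <- dqn_update(net_eval, net_targ, opt, batch, dqn_cfg$gamma)
      net_eval <- up$net_eval
      opt <- up$opt
      loss <- up$loss
      n_updates <- n_updates + 1L
      if (n_updates %% dqn_cfg$sync_period == 0L) {
        net_targ <- sync_target(net_eval, net_targ)
      }
    }
    f_ep <- NA_real_; apd_ep <- NA_real_
    if (st$done) {
      m <- rasterize_contour(contour(st$ep$trajectory, closed = TRUE),
                             dim(sample_i$mask))
      f_ep <- precision_recall_fmeasure(m, sample_i$mask)["f"]
      apd_ep <- average_perpendicular_distance(contour(st$ep$trajectory),
                                               sample_i$contour)
    }
    logs[[step]] <- c(step = step, episode = ep_idx,
                      rd = unname(st$components["rd"]),
                      re = unname(st$components["re"]),
                      rp = unname(st$components["rp"]),
                      reward = st$reward, loss = loss, done = as.numeric(st$done),
                      f = unname(f_ep), apd = unname(apd_ep))
    ep <- st$ep
    state <- st$state
    if (verbose && step %% 500 == 0) {
      recent <- do.call(rbind, logs[max(1, step - 499):step])
      message(sprintf("step %d | mean r %.3f | updates %d | loss %.4f",
                      step, mean(recent[, "reward"], na.rm = TRUE), n_updates,
                      loss))
    }
  }
  log_df <- as.data.frame(do.call(rbind, logs))
  list(net_eval = net_eval, net_targ = net_targ, log = log_df, opt = opt,
       env_cfg = env_cfg, rcfg = rcfg, dqn_cfg = dqn_cfg, seed = seed,
       n_updates = n_updates)
}

#' Segment an image with a trained agent
#'
#' Runs the first-point network, then traces the boundary with the agent's
#' epsilon-greedy policy (the method keeps epsilon at its training value at
#' test time; pass `epsilon = 0` for greedy inference) until closure or the
#' step cap. Rewards are not computed unless ground truth is supplied.
#'
#' @param gray grayscale image matrix.
#' @param first_p trained first-point network.
#' @param net_eval trained Q-network.
#' @param env_cfg an [env_config()].
#' @param epsilon exploration at inference.
#' @param seed seed for the inference policy's randomness.
#' @param gt optional list with `mask` and `contour` for step rewards.
#' @return list with `contour`, `mask`, `log`, `first_point`, `prob_map`.
#' @export
segment_image <- function(gray, first_p, net_eval,
                          env_cfg = env_config(profile = "desk"),
                          epsilon = 0.2, seed = 1L, gt = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ep <- episode_from_sample(list(image = gray,
                                 mask = gt$mask, contour = gt$contour),
                            first_p, env_cfg, reward_config(),
                            with_gt = !is.null(gt))
  policy <- function(state, i) select_action(q_forward(net_eval, state), epsilon)
  res <- run_episode(ep, policy)
  res$first_point <- ep$first_point
  res
}
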