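# Shared fixtures and memoized desk-scale training artifacts. Training is
# expensive (minutes), so the trained first-point network and agents are
# built once per test run and reused by every test that needs them. All
# seeds are fixed up front.

ew_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = ew_cache, inherits = FALSE)) {
    assign(key, builder(), envir = ew_cache)
  }
  get(key, envir = ew_cache, inherits = FALSE)
}

desk_train_set <- function() {
  memo("train_set", function() {
    lapply(1:40, function(i) generate_phantom(phantom_spec(seed = i)))
  })
}

desk_test_set <- function() {
  memo("test_set", function() {
    lapply(101:110, function(i) generate_phantom(phantom_spec(seed = i)))
  })
}

# first-point network trained for 6 epochs on the 20 training phantoms
desk_first_p <- function() {
  memo("first_p", function() {
    train_first_p(desk_train_set(), first_p_config(profile = "desk"),
                  epochs = 6, seed = 11)
  })
}

# full-reward desk agent (~5,000 environment steps, buffer 2,000, sync 200)
desk_agent_full <- function() {
  memo("agent_full", function() {
    train_agent(desk_train_set(), desk_first_p()$net,
                env_config(profile = "desk"), reward_config(),
                dqn_config(profile = "desk"), total_steps = 5000, seed = 11)
  })
}

# ablation agent: difference-IoU reward only (same state, same budget)
desk_agent_rd_only <- function() {
  memo("agent_rd", function() {
    train_agent(desk_train_set(), desk_first_p()$net,
                env_config(profile = "desk"),
                reward_config(enabled_terms = "diff_iou"),
                dqn_config(profile = "desk"), total_steps = 5000, seed = 11)
  })
}

heldout_fmeasure <- function(agent, epsilon = 0.2) {
  test <- desk_test_set()
  vapply(seq_along(test), function(i) {
    ph <- test[[i]]
    res <- segment_image(ph$image, desk_first_p()$net, agent$net_eval,
                         env_config(profile = "desk"), epsilon = epsilon,
                         seed = 100 + i)
    unname(precision_recall_fmeasure(res$mask, ph$mask)["f"])
  }, numeric(1))
}

# small deterministic 5-state chain MDP: actions 0 = left, 1 = right; reward
# 1 on entering the terminal right end, -0.05 per other move
chain_mdp <- function() {
  nS <- 5L
  P <- cbind(pmax(seq_len(nS) - 1L, 1L), pmin(seq_len(nS) + 1L, nS))
  R <- matrix(-0.05, nS, 2)
  R[nS - 1L, 2] <- 1
  terminal <- c(rep(FALSE, nS - 1L), TRUE)
  list(nS = nS, nA = 2L, P = P, R = R, terminal = terminal)
}

one_hot <- function(i, n) { v <- numeric(n); v[i] <- 1; v }
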