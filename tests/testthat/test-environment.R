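# MDP environment: state geometry, action map, transition/termination logic,
# reward assembly, determinism, ablation subsets.

toy_episode <- function(cfg = env_config(profile = "desk"),
                        rcfg = reward_config(), seed = 21, with_gt = TRUE) {
  ph <- generate_phantom(phantom_spec(seed = seed))
  pm <- matrix(0, cfg$image_size / 8, cfg$image_size / 8)
  pm[cbind(pmin((ph$contour$points[, 1] - 1) %/% 8 + 1, nrow(pm)),
           pmin((ph$contour$points[, 2] - 1) %/% 8 + 1, ncol(pm)))] <- 1
  start <- ph$contour$points[1, ]
  list(ep = env_init(ph$image, pm, start, cfg = cfg, rcfg = rcfg,
                     gt_mask = if (with_gt) ph$mask,
                     gt_contour = if (with_gt) ph$contour),
       ph = ph, pm = pm)
}

test_that("build_concatenated_image contract and upsample geometry", {
  gray <- matrix(0.5, 96, 96)
  pm <- matrix(0.1, 12, 12)
  ci <- build_concatenated_image(gray, pm)
  expect_equal(dim(ci), c(96, 96, 3))
  expect_equal(ci[, , 2], matrix(0, 96, 96))      # Sobel of a constant
  expect_error(build_concatenated_image(gray, matrix(0, 11, 12)), "1/8")
  # single-hot probability cell maps near 8x its position after upsampling
  pm2 <- matrix(0, 12, 12); pm2[5, 9] <- 1
  up <- build_concatenated_image(matrix(runif(96 * 96), 96), pm2)[, , 3]
  hot <- which(up == max(up), arr.ind = TRUE)[1, ]
  expect_lt(abs(hot[1] - 8 * 5), 8.1)
  expect_lt(abs(hot[2] - 8 * 9), 8.1)
})

test_that("state is exactly (w, w, 5) everywhere, including all corners", {
  t <- toy_episode()
  cfg <- t$ep$cfg
  w <- cfg$state_size
  corners <- rbind(c(1, 1), c(1, cfg$image_size), c(cfg$image_size, 1),
                   c(cfg$image_size, cfg$image_size),
                   c(cfg$image_size %/% 2, cfg$image_size %/% 2))
  for (i in seq_len(nrow(corners))) {
    st <- extract_state(t$ep, corners[i, ])
    expect_equal(dim(st$layers), c(w, w, 5))
    expect_true(all(st$layers[, , 4] %in% c(0, 1)))  # past layer stays binary
  }
  expect_error(extract_state(t$ep, c(0, 5)), "out of bounds")
})

test_that("a centered in-bounds state is a plain crop and sees past points", {
  # crop_size == state_size isolates the plain-crop path (the desk default
  # crops a wider window and resizes)
  t <- toy_episode(cfg = env_config(profile = "desk", crop_size = 25))
  cfg <- t$ep$cfg
  ctr <- c(48, 48)
  st <- extract_state(t$ep, ctr)
  half <- (cfg$state_size - 1) / 2
  expect_equal(st$layers[, , 1],
               t$ep$concat[(ctr[1] - half):(ctr[1] + half),
                           (ctr[2] - half):(ctr[2] + half), 1])
  # the first (visited) point is marked 1 in the past layer when in window
  fp <- t$ep$first_point
  st2 <- extract_state(t$ep, fp)
  expect_equal(st2$layers[half + 1, half + 1, 4], 1)
  # the global layer is identical across states of the episode
  expect_equal(st$layers[, , 5], st2$layers[, , 5])
})

test_that("action map: anchored directions, cancellation, clamping, errors", {
  expect_equal(apply_action(c(10, 10), 4, 5), c(15, 10))   # 4 = down
  expect_equal(apply_action(c(10, 10), 7, 5), c(5, 15))    # 7 = up-right
  p <- c(30, 30)
  for (a in 0:3) {
    q <- apply_action(apply_action(p, a, 6), a + 4L, 6)
    expect_equal(q, p)                                     # opposites cancel
  }
  expect_equal(apply_action(c(2, 2), 1, 5, shape = c(50, 50)), c(1, 1))
  expect_error(apply_action(c(5, 5), 8, 5), "invalid action")
  expect_error(apply_action(c(5, 5), -1, 5), "invalid action")
})

test_that("episodes cap at max_steps and finished episodes refuse to step", {
  t <- toy_episode()
  ep <- t$ep
  # walk away from the start, then oscillate in place: closure never fires
  n <- 0
  rewards <- c()
  while (!ep$done) {
    a <- if (n < 8) 4L else c(2L, 6L)[n %% 2L + 1L]
    st <- env_step(ep, a)
    ep <- st$ep; n <- n + 1
    rewards <- c(rewards, st$reward)
  }
  expect_gte(min(rewards), -1.5); expect_lte(max(rewards), 1.5)
  expect_equal(n, ep$cfg$max_steps)
  expect_equal(ep$done_reason, "max_steps")
  expect_equal(nrow(ep$trajectory), ep$cfg$max_steps + 1)
  expect_error(env_step(ep, 0), "already done")
})

test_that("skip schedule reduces 5 -> 3 only near closure after the step gate", {
  # full-size config; scripted walk anchored at (180, 100)
  cfg <- env_config()     # 368, n 5 -> 3, gate 100, distances 40 / 20
  gray <- matrix(runif(368 * 368), 368, 368)
  pm <- matrix(0, 46, 46)
  ep <- env_init(gray, pm, c(180, 100), cfg = cfg)
  # 60 steps right: far away (300 px), oscillate up/down to pass the gate
  for (i in 1:40) { s <- env_step(ep, 6); ep <- s$ep }
  expect_equal(ep$n_skip, 5)
  for (i in 1:56) { s <- env_step(ep, i %% 2L * 4L); ep <- s$ep }
  expect_equal(ep$step_count, 96)
  expect_equal(ep$n_skip, 5)          # distance 200: no reduction
  # walk back toward the start; n must reduce once within 40 px, after gate
  skips <- c()
  while (!ep$done && ep$step_count < 300) {
    s <- env_step(ep, 2)              # left, toward the start point
    ep <- s$ep
    skips <- c(skips, ep$n_skip)
  }
  expect_true(any(skips == 3))        # reduction happened
  expect_true(all(diff(skips) <= 0))  # and never reverted
  d_first <- sqrt(sum((ep$trajectory[nrow(ep$trajectory), ] - c(180, 100))^2))
  expect_equal(ep$done_reason, "closed")
  expect_lt(d_first, cfg$close_distance)
  # reduction must not have fired before the step gate
  first_reduced <- which(skips == 3)[1] + 96
  expect_gt(first_reduced, cfg$reduce_after_step)
})

test_that("identical action sequences give identical episodes (determinism)", {
  run <- function() {
    t <- toy_episode(seed = 33)
    ep <- t$ep
    rewards <- c()
    set.seed(99)
    while (!ep$done) {
      s <- env_step(ep, sample(0:7, 1))
      ep <- s$ep
      rewards <- c(rewards, s$reward)
    }
    list(tr = ep$trajectory, r = rewards, reason = ep$done_reason)
  }
  a <- run(); b <- run()
  expect_identical(a$tr, b$tr)
  expect_identical(a$r, b$r)
  expect_identical(a$reason, b$reason)
})

test_that("a perfect boundary step earns the componentwise maximum 1.5", {
  # square ground truth; scripted tracer walks exactly along it
  cfg <- env_config(image_size = 96, state_size = 25, n_skip = 4,
                    n_skip_reduced = 2, reduce_after_step = 30,
                    reduce_distance = 12, close_distance = 6, max_steps = 80,
                    profile = "desk")
  sq <- rbind(c(20, 20), c(20, 76), c(76, 76), c(76, 20))
  # dense square boundary as gt contour
  steps <- lapply(1:4, function(i) {
    a <- sq[i, ]; b <- sq[i %% 4 + 1, ]
    n <- max(abs(b - a))
    cbind(round(seq(a[1], b[1], length.out = n + 1)),
          round(seq(a[2], b[2], length.out = n + 1)))[-(n + 1), ]
  })
  gtc <- contour(do.call(rbind, steps), closed = TRUE)
  gtm <- rasterize_contour(gtc, c(96, 96))
  gray <- matrix(0.2, 96, 96); gray[gtm == 1] <- 0.9
  ep <- env_init(gray, matrix(0, 12, 12), c(20, 20), cfg = cfg,
                 gt_mask = gtm, gt_contour = gtc)
  # trace the square: right along the top edge, down the right edge, ...
  acts <- c(rep(c(6L, 4L, 2L, 0L), each = 14), rep(0L, 10))
  rewards <- c(); comps <- NULL
  for (a in acts) {
    if (ep$done) break
    s <- env_step(ep, a)
    ep <- s$ep
    rewards <- c(rewards, s$reward)
    comps <- rbind(comps, s$components)
  }
  expect_equal(max(rewards), 1.5)
  i <- which.max(rewards)
  expect_equal(unname(comps[i, ]), c(1, 0.5, 0))
})

test_that("state-layer ablation subsets change only the channel count", {
  for (sl in c("SCGP", "SP", "SCG")) {
    cfg <- env_config(profile = "desk", state_layers = sl)
    t <- toy_episode(cfg = cfg)
    st <- extract_state(t$ep)
    expect_equal(dim(st$layers)[3], length(state_layer_channels(sl)))
  }
  expect_equal(state_layer_channels("SP"), c(1L, 2L, 4L))
  expect_equal(state_layer_channels("SCG"), c(1L, 2L, 3L, 5L))
})

test_that("run_episode traces a scripted square into its exact mask", {
  cfg <- env_config(image_size = 96, state_size = 25, n_skip = 4,
                    n_skip_reduced = 4, reduce_after_step = 54,
                    reduce_distance = 8, close_distance = 5, max_steps = 80,
                    profile = "desk")
  gray <- matrix(runif(96 * 96), 96, 96)
  ep <- env_init(gray, matrix(0, 12, 12), c(20, 20), cfg = cfg)
  # 56 moves of 4 px trace a 56x56 square; padding never runs (closure first)
  acts <- c(rep(c(6L, 4L, 2L, 0L), each = 14), rep(0L, 10))
  res <- run_episode(ep, function(s, i) acts[i])
  expect_true(res$ep$done)
  expect_equal(res$ep$done_reason, "closed")
  expect_true(res$contour$closed)
  sq_mask <- matrix(0L, 96, 96); sq_mask[20:76, 20:76] <- 1L
  expect_equal(res$mask, sq_mask)
  expect_lte(nrow(res$contour$points), cfg$max_steps + 1)
})
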