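# The deterministic contour-tracing MDP. An episode wraps one image: the
# agent starts at the first edge point, moves through the 8-direction skip
# neighborhood (n px per move, reduced near closure), and each step is scored
# by the sum of difference-IoU, edge-distance and points-clustering rewards.
# The transition function is a point mass: same episode + same actions =>
# same trajectory, rewards and termination.

#' Environment configuration
#'
#' Full-size defaults: 368 px images, 51 px states, skip 5 -> 3, closure
#' thresholds 40/20 px active after step 100, 300-step cap. The desk profile
#' (`env_config(profile = "desk")`) scales the geometry to 96 px images:
#' 25 px states sourced from a 51 px crop, skip 5 -> 3 kept literally,
#' thresholds 12/6 after step 25, 100-step cap (~3 laps around a typical
#' phantom).
#'
#' @param image_size image side W = H (px).
#' @param state_size state window side w = h (px, odd).
#' @param crop_size side of the window cropped around the current point
#'   before resizing to `state_size` (default: equal to `state_size`, i.e. a
#'   plain crop). The desk profile crops 51 px and resizes to 25 so the
#'   agent's field of view in skip-moves matches the full-size design.
#' @param n_skip,n_skip_reduced skip-neighborhood distances (px).
#' @param reduce_after_step step count after which closure logic activates.
#' @param reduce_distance distance to the first point below which the skip
#'   distance is reduced.
#' @param close_distance distance to the first point below which the episode
#'   closes.
#' @param max_steps episode cap.
#' @param state_layers one of "SCGP" (all 5 layers), "SP" (gray/Sobel/past),
#'   "SCG" (gray/Sobel/prob/global) - the state ablation switch.
#' @param profile "full" or "desk"; presets overridden by explicit arguments.
#' @return list of class `env_config`.
#' @export
env_config <- function(image_size = NULL, state_size = NULL, crop_size = NULL,
                       n_skip = NULL, n_skip_reduced = NULL,
                       reduce_after_step = NULL, reduce_distance = NULL,
                       close_distance = NULL, max_steps = NULL,
                       state_layers = "SCGP", profile = c("full", "desk")) {
  profile <- match.arg(profile)
  base <- if (profile == "full") {
    list(image_size = 368, state_size = 51, crop_size = 51, n_skip = 5,
         n_skip_reduced = 3, reduce_after_step = 100, reduce_distance = 40,
         close_distance = 20, max_steps = 300)
  } else {
    list(image_size = 96, state_size = 25, crop_size = 51, n_skip = 5,
         n_skip_reduced = 3, reduce_after_step = 25, reduce_distance = 12,
         close_distance = 6, max_steps = 100)
  }
  given <- list(image_size = image_size, state_size = state_size,
                crop_size = crop_size, n_skip = n_skip,
                n_skip_reduced = n_skip_reduced,
                reduce_after_step = reduce_after_step,
                reduce_distance = reduce_distance,
                close_distance = close_distance, max_steps = max_steps)
  for (nm in names(given)) if (!is.null(given[[nm]])) base[[nm]] <- given[[nm]]
  stopifnot(base$state_size < base$image_size / 2,
            base$crop_size >= base$state_size,
            base$n_skip_reduced <= base$n_skip,
            base$close_distance < base$reduce_distance,
            state_layers %in% c("SCGP", "SP", "SCG"))
  base$state_layers <- state_layers
  base$profile <- profile
  structure(base, class = "env_config")
}

#' Channel indices selected by a state-layer subset
#' @param state_layers "SCGP", "SP" or "SCG".
#' @export
state_layer_channels <- function(state_layers) {
  switch(state_layers,
         SCGP = 1:5,    # gray, sobel, prob crop, past points, global prob
         SP   = c(1L, 2L, 4L),
         SCG  = c(1L, 2L, 3L, 5L),
         stop("unknown state layer subset: ", state_layers))
}

#' Build the 3-layer concatenated image
#'
#' Layers: normalized grayscale, normalized Sobel magnitude, bilinearly
#' 8x-upsampled edge-probability map - each min-max normalized to \[-1, 1\].
#'
#' @param gray (H, W) grayscale matrix.
#' @param prob_map (H/8, W/8) probability/score map.
#' @return array (H, W, 3).
#' @export
build_concatenated_image <- function(gray, prob_map) {
  H <- nrow(gray); W <- ncol(gray)
  if (!identical(dim(prob_map), c(H %/% 8L, W %/% 8L)) &&
      !identical(as.integer(dim(prob_map)), as.integer(c(H / 8, W / 8)))) {
    stop(sprintf("prob_map must be %dx%d (1/8 of %dx%d), got %s",
                 H %/% 8, W %/% 8, H, W, paste(dim(prob_map), collapse = "x")))
  }
  up <- bilinear_resize(prob_map, H, W)
  out <- array(0, c(H, W, 3))
  out[, , 1] <- normalize_pm1(gray)
  out[, , 2] <- normalize_pm1(sobel_edge_map(gray))
  out[, , 3] <- normalize_pm1(up)
  out
}

#' Initialise an episode
#'
#' @param gray (H, W) grayscale image (raw intensities; normalized internally).
#' @param prob_map (H/8, W/8) edge-probability map from the first-point network.
#' @param first_point length-2 (row, col) starting edge point.
#' @param cfg an [env_config()].
#' @param rcfg a [reward_config()].
#' @param gt_mask,gt_contour ground truth; both NULL for reward-free inference.
#' @return episode state list of class `lv_episode`.
#' @export
env_init <- function(gray, prob_map, first_point, cfg = env_config(),
                     rcfg = reward_config(), gt_mask = NULL, gt_contour = NULL) {
  H <- nrow(gray); W <- ncol(gray)
  stopifnot(H == cfg$image_size, W == cfg$image_size)
  first_point <- as.numeric(first_point)
  if (first_point[1] < 1 || first_point[1] > H ||
      first_point[2] < 1 || first_point[2] > W) {
    stop("first point out of bounds")
  }
  concat <- build_concatenated_image(gray, prob_map)
  global_prob <- normalize_pm1(bilinear_resize(prob_map, cfg$state_size,
                                               cfg$state_size))
  past <- matrix(0, H, W)
  past[first_point[1], first_point[2]] <- 1
  if (!is.null(gt_contour)) gt_contour <- as_contour(gt_contour)
  ep <- list(concat = concat, global_prob = global_prob, past = past,
             trajectory = matrix(first_point, 1, 2,
                                 dimnames = list(NULL, c("row", "col"))),
             first_point = first_point, step_count = 0L,
             n_skip = cfg$n_skip, done = FALSE, done_reason = NA_character_,
             mask_ring = vector("list", rcfg$mask_interval),
             cfg = cfg, rcfg = rcfg, gt_mask = gt_mask, gt_contour = gt_contour)
  class(ep) <- "lv_episode"
  ep
}

# action index (0-7) -> (drow, dcol) unit direction, counterclockwise from up;
# the two anchored directions: 4 = down ("the pixel under"), 7 = up-right.
.action_dirs <- matrix(c(-1L, 0L,   # 0 up
                         -1L, -1L,  # 1 up-left
                          0L, -1L,  # 2 left
                          1L, -1L,  # 3 down-left
                          1L, 0L,   # 4 down
                          1L, 1L,   # 5 down-right
                          0L, 1L,   # 6 right
                         -1L, 1L),  # 7 up-right
                       ncol = 2, byrow = TRUE)

#' Apply a skip-neighborhood action to a point
#'
#' @param p length-2 (row, col) point.
#' @param a action index in 0..7 (counterclockwise from up; 4 = down,
#'   7 = up-right).
#' @param n skip distance (px).
#' @param shape optional `c(H, W)`; the result is clamped to bounds.
#' @return displaced (row, col) point.
#' @export
apply_action <- function(p, a, n, shape = NULL) {
  if (length(a) != 1 || is.na(a) || !(a %in% 0:7)) {
    stop("invalid action index: ", a)
  }
  q <- as.numeric(p) + .action_dirs[a + 1L, ] * n
  if (!is.null(shape)) {
    q[1] <- min(max(q[1], 1), shape[1])
    q[2] <- min(max(q[2], 1), shape[2])
  }
  q
}

#' Extract the agent's state at a center point
#'
#' Layers 1-4 are `state_size` windows centered on `center`, cropped from the
#' concatenated image and the past-points map; windows exceeding the image are
#' cropped to bounds and bilinearly resized back to the exact state size
#' (crop-and-resize rule). Layer 5 is the episode's fixed resized global
#' probability map. The configured layer subset is applied last.
#'
#' @param ep an episode from [env_init()].
#' @param center length-2 (row, col) point inside the image.
#' @return list of class `env_state` with `layers` (w, w, k) and `center`.
#' @export
extract_state <- function(ep, center = NULL) {
  cfg <- ep$cfg
  if (is.null(center)) center <- ep$trajectory[nrow(ep$trajectory), ]
  H <- dim(ep$concat)[1]; W <- dim(ep$concat)[2]
  if (center[1] < 1 || center[1] > H || center[2] < 1 || center[2] > W) {
    stop("state center out of bounds")
  }
  w <- cfg$state_size
  half <- (cfg$crop_size - 1) %/% 2
  r0 <- round(center[1]) - half; r1 <- round(center[1]) + half
  c0 <- round(center[2]) - half; c1 <- round(center[2]) + half
  rr <- max(r0, 1):min(r1, H)
  cc <- max(c0, 1):min(c1, W)
  crop <- array(0, c(length(rr), length(cc), 3))
  crop[, , 1:3] <- ep$concat[rr, cc, , drop = FALSE]
  if (length(rr) != w || length(cc) != w) {
    crop <- resize_fwd(array(crop, c(dim(crop), 1L)), w, w)[, , , 1]
  }
  # the past-points layer is rebuilt from the trajectory so isolated visited
  # pixels survive downsampling (bilinear averaging would erase them)
  past <- matrix(0, w, w)
  tr <- ep$trajectory
  inside <- tr[, 1] >= rr[1] & tr[, 1] <= rr[length(rr)] &
            tr[, 2] >= cc[1] & tr[, 2] <= cc[length(cc)]
  if (any(inside)) {
    pr <- round((tr[inside, 1] - rr[1] + 0.5) * w / length(rr) + 0.5)
    pc <- round((tr[inside, 2] - cc[1] + 0.5) * w / length(cc) + 0.5)
    past[cbind(pmin(pmax(pr, 1), w), pmin(pmax(pc, 1), w))] <- 1
  }
  layers <- array(0, c(w, w, 5))
  layers[, , 1:3] <- crop
  layers[, , 4] <- past
  layers[, , 5] <- ep$global_prob
  keep <- state_layer_channels(cfg$state_layers)
  structure(list(layers = layers[, , keep, drop = FALSE],
                 center = as.numeric(center)),
            class = "env_state")
}

euclid <- function(p, q) sqrt(sum((as.numeric(p) - as.numeric(q))^2))

#' Take one environment step
#'
#' Moves the current point by the selected action, updates trajectory and
#' past-points map, computes the three reward components (when ground truth is
#' attached), applies the skip-reduction and closure rules, and returns the
#' next state.
#'
#' @param ep a live episode.
#' @param a action index 0..7.
#' @return list with updated `ep`, `state` (next state), `reward`,
#'   `components` (named rd/re/rp), `done`, `done_reason`.
#' @export
env_step <- function(ep, a) {
  if (ep$done) stop("episode is already done (", ep$done_reason, ")")
  cfg <- ep$cfg; rcfg <- ep$rcfg
  cur <- ep$trajectory[nrow(ep$trajectory), ]
  new_p <- apply_action(cur, a, ep$n_skip,
                        shape = c(cfg$image_size, cfg$image_size))
  new_p <- round(new_p)
  ep$trajectory <- rbind(ep$trajectory, new_p)
  ep$past[new_p[1], new_p[2]] <- 1
  ep$step_count <- ep$step_count + 1L

  comps <- c(rd = NA_real_, re = NA_real_, rp = NA_real_)
  reward <- NA_real_
  if (!is.null(ep$gt_mask)) {
    shape <- dim(ep$gt_mask)
    m_curr <- rasterize_contour(contour(ep$trajectory, closed = TRUE), shape)
    n_tr <- nrow(ep$trajectory)
    # Mprev (trajectory minus the last mask_interval points) is exactly the
    # Mcurr of mask_interval steps ago: reuse it from a small ring cache
    m_prev <- if (n_tr - rcfg$mask_interval >= 2) {
      ep$mask_ring[[(ep$step_count - rcfg$mask_interval) %%
                      rcfg$mask_interval + 1L]]
    } else {
      first_mask <- matrix(0L, shape[1], shape[2])
      first_mask[ep$first_point[1], ep$first_point[2]] <- 1L
      first_mask
    }
    ep$mask_ring[[ep$step_count %% rcfg$mask_interval + 1L]] <- m_curr
    comps["rd"] <- diff_iou_reward(m_curr, m_prev, ep$gt_mask)
    comps["re"] <- edge_distance_reward(min_edge_distance(new_p, ep$gt_contour),
                                        rcfg)
    tail_n <- min(rcfg$cluster_window, n_tr)
    recent <- ep$trajectory[seq(n_tr - tail_n + 1, n_tr), , drop = FALSE]
    comps["rp"] <- points_clustering_reward(recent, rcfg)
    reward <- total_reward(comps["rd"], comps["re"], comps["rp"], rcfg)
    names(reward) <- NULL
  }

  if (ep$step_count > cfg$reduce_after_step) {
    d_first <- euclid(new_p, ep$first_point)
    if (d_first < cfg$close_distance) {
      ep$done <- TRUE
      ep$done_reason <- "closed"
    } else if (d_first < cfg$reduce_distance) {
      ep$n_skip <- cfg$n_skip_reduced
    }
  }
  if (!ep$done && ep$step_count >= cfg$max_steps) {
    ep$done <- TRUE
    ep$done_reason <- "max_steps"
  }
  list(ep = ep, state = extract_state(ep, new_p), reward = reward,
       components = comps, done = ep$done, done_reason = ep$done_reason)
}

#' Run a full episode under a policy
#'
#' @param ep a fresh episode from [env_init()].
#' @param policy function(state, step_index) returning an action 0..7.
#' @param collect_transitions store (s, a, r, s', done) records.
#' @return list with the closed `contour`, its rasterized `mask`, the final
#'   `ep`, a per-step `log` data.frame and (optionally) `transitions`.
#' @export
run_episode <- function(ep, policy, collect_transitions = FALSE) {
  state <- extract_state(ep)
  transitions <- if (collect_transitions) vector("list", ep$cfg$max_steps)
  log_rows <- vector("list", ep$cfg$max_steps)
  i <- 0L
  while (!ep$done) {
    i <- i + 1L
    a <- policy(state, i)
    st <- env_step(ep, a)
    if (collect_transitions) {
      transitions[[i]] <- list(s = state, a = a, r = st$reward,
                               s2 = st$state, done = st$done)
    }
    p <- st$state$center
    log_rows[[i]] <- data.frame(step = i, row = p[1], col = p[2], action = a,
                                rd = st$components["rd"],
                                re = st$components["re"],
                                rp = st$components["rp"], reward = st$reward,
                                done = st$done, row.names = NULL)
    ep <- st$ep
    state <- st$state
  }
  final_contour <- contour(ep$trajectory, closed = TRUE)
  mask <- rasterize_contour(final_contour,
                            c(ep$cfg$image_size, ep$cfg$image_size))
  list(contour = final_contour, mask = mask, ep = ep,
       log = do.call(rbind, log_rows[seq_len(i)]),
       transitions = if (collect_transitions) transitions[seq_len(i)])
}

#' Write an episode log as a tab-separated file
#' @param log data.frame from [run_episode()].
#' @param path output file.
#' @export
write_episode_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
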