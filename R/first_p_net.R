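# First-edge-point predictor: a reduced-ResNet multi-scale encoder. Stage
# outputs are projected by 3x3 conv + rectifier, bilinearly resized to half
# the input resolution and concatenated; four 3x3 blocks reduce the fusion to
# 1/8 resolution and a 1x1 projection yields a single-channel edge-point
# score map. The argmax cell (cell-center convention) gives the first edge
# point; per-pixel binary cross-entropy against downsampled ground-truth
# boundary cells trains the network.

#' First-point network configuration
#'
#' The "full" profile mirrors the full-size design (368 px input, stage
#' blocks \[2,2,2,2\], wide channels); it is GPU-scale and not exercised by the
#' test suite. The "desk" profile keeps the same topology at 96 px with
#' narrow channels so training runs in minutes on one CPU.
#'
#' @param input_size square input side, divisible by 8.
#' @param stem_channels stem convolution width.
#' @param stage_channels widths of the four residual stages.
#' @param stage_blocks residual block counts per stage.
#' @param fuse_channels per-stage projection width (concatenated x4).
#' @param head_channels width of the four 3x3 head blocks.
#' @param lr Adam learning rate.
#' @param batch_size training batch size.
#' @param epochs default training epochs.
#' @param scale input-to-probability-map scale factor (8).
#' @param profile preset name.
#' @export
first_p_config <- function(input_size = NULL, stem_channels = NULL,
                           stage_channels = NULL, stage_blocks = NULL,
                           fuse_channels = NULL, head_channels = NULL,
                           lr = NULL, batch_size = 1, epochs = 10, scale = 8,
                           profile = c("full", "desk")) {
  profile <- match.arg(profile)
  base <- if (profile == "full") {
    list(input_size = 368, stem_channels = 64,
         stage_channels = c(64, 128, 256, 512), stage_blocks = c(2, 2, 2, 2),
         fuse_channels = 64, head_channels = 16, lr = 1e-5)
  } else {
    list(input_size = 96, stem_channels = 8,
         stage_channels = c(8, 16, 24, 32), stage_blocks = c(1, 1, 1, 1),
         fuse_channels = 8, head_channels = 16, lr = 1e-3)
  }
  given <- list(input_size = input_size, stem_channels = stem_channels,
                stage_channels = stage_channels, stage_blocks = stage_blocks,
                fuse_channels = fuse_channels, head_channels = head_channels,
                lr = lr)
  for (nm in names(given)) if (!is.null(given[[nm]])) base[[nm]] <- given[[nm]]
  stopifnot(base$input_size %% 8 == 0)
  base$batch_size <- batch_size
  base$epochs <- epochs
  base$scale <- scale
  base$profile <- profile
  structure(base, class = "first_p_config")
}

make_stage <- function(in_c, out_c, blocks, stride) {
  layers <- list(nn_res_block(in_c, out_c, stride))
  if (blocks > 1) {
    for (i in seq_len(blocks - 1)) layers <- c(layers, list(nn_res_block(out_c, out_c, 1)))
  }
  do.call(nn_seq, layers)
}

#' Build a first-point network
#'
#' @param cfg a [first_p_config()].
#' @param seed seed for parameter initialisation.
#' @return list of class `first_p_net`.
#' @export
first_p_net <- function(cfg = first_p_config(profile = "desk"), seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sc <- cfg$stage_channels
  stem <- nn_seq(nn_conv(3, cfg$stem_channels, 3, 2, activation = "relu"))
  stages <- list(
    make_stage(cfg$stem_channels, sc[1], cfg$stage_blocks[1], 1),
    make_stage(sc[1], sc[2], cfg$stage_blocks[2], 2),
    make_stage(sc[2], sc[3], cfg$stage_blocks[3], 2),
    make_stage(sc[3], sc[4], cfg$stage_blocks[4], 2))
  projs <- lapply(1:4, function(i) {
    nn_seq(nn_conv(sc[i], cfg$fuse_channels, 3, 1, activation = "relu"))
  })
  hc <- cfg$head_channels
  head <- nn_seq(nn_conv(4 * cfg$fuse_channels, hc, 3, 1, activation = "relu"),
                 nn_conv(hc, hc, 3, 2, activation = "relu"),
                 nn_conv(hc, hc, 3, 1, activation = "relu"),
                 nn_conv(hc, hc, 3, 2, activation = "relu"),
                 nn_conv(hc, 1, 1, 1, pad = 0, activation = "linear"))
  structure(list(stem = stem, stages = stages, projs = projs, head = head,
                 cfg = cfg), class = "first_p_net")
}

fp_pieces <- function(net) {
  c(list(net$stem), net$stages, net$projs, list(net$head))
}

fp_set_pieces <- function(net, pieces) {
  net$stem <- pieces[[1]]
  net$stages <- pieces[2:5]
  net$projs <- pieces[6:9]
  net$head <- pieces[[10]]
  net
}

#' Flatten all first-point network parameters
#' @param net a [first_p_net()].
#' @export
fp_flat_params <- function(net) {
  unlist(lapply(fp_pieces(net), nn_flat_params), use.names = FALSE)
}

fp_unflat_params <- function(net, theta) {
  pieces <- fp_pieces(net)
  lens <- vapply(pieces, function(p) length(nn_flat_params(p)), numeric(1))
  ends <- cumsum(lens)
  starts <- c(1, utils::head(ends, -1) + 1)
  for (i in seq_along(pieces)) {
    pieces[[i]] <- nn_unflat_params(pieces[[i]], theta[starts[i]:ends[i]])
  }
  fp_set_pieces(net, pieces)
}

#' Forward pass of the first-point network
#'
#' @param net a [first_p_net()].
#' @param x input array (s, s, 3) or (s, s, 3, N), values in \[-1, 1\], s
#'   divisible by 8.
#' @param keep_cache retain intermediates for the training backward pass.
#' @return probability (score) map matrix (s/8, s/8) for a single input, or
#'   array (s/8, s/8, N); with `keep_cache`, a list with `out` and `cache`.
#' @export
first_p_forward <- function(net, x, keep_cache = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] != d[2] || d[1] %% 8 != 0 || d[3] != 3) {
    stop(sprintf("input must be square, divisible by 8, 3 channels; got %s",
                 paste(d, collapse = "x")))
  }
  half <- d[1] / 2L
  stem <- nn_forward(net$stem, x, keep_cache)
  sf <- vector("list", 4)
  xin <- stem$out
  for (i in 1:4) {
    sf[[i]] <- nn_forward(net$stages[[i]], xin, keep_cache)
    xin <- sf[[i]]$out
  }
  pf <- vector("list", 4)
  fused <- array(0, c(half, half, 4 * net$cfg$fuse_channels, d[4]))
  fc <- net$cfg$fuse_channels
  for (i in 1:4) {
    pf[[i]] <- nn_forward(net$projs[[i]], sf[[i]]$out, keep_cache)
    fused[, , (i - 1) * fc + seq_len(fc), ] <-
      resize_fwd(pf[[i]]$out, half, half)
  }
  hf <- nn_forward(net$head, fused, keep_cache)
  out <- hf$out
  scores <- if (d[4] == 1L) matrix(out, dim(out)[1], dim(out)[2]) else {
    array(out, dim(out)[c(1, 2, 4)])
  }
  if (!keep_cache) return(scores)
  list(out = scores,
       cache = list(stem = stem, stages = sf, projs = pf, head = hf,
                    fused_dims = dim(fused), proj_dims = lapply(pf, function(p) dim(p$out)),
                    in_dims = d))
}

# backward through the multi-scale wiring; returns gradient tree per piece
first_p_backward <- function(net, cache, dscores) {
  d <- cache$in_dims
  dim(dscores) <- c(d[1] / 8, d[1] / 8, 1, d[4])
  hb <- nn_backward(net$head, cache$head$cache, dscores, need_dx = TRUE)
  fc <- net$cfg$fuse_channels
  dstage <- vector("list", 4)   # gradient arriving at each stage output
  proj_grads <- vector("list", 4)
  for (i in 1:4) {
    dp <- hb$dx[, , (i - 1) * fc + seq_len(fc), , drop = FALSE]
    dp <- resize_bwd(dp, cache$proj_dims[[i]][1], cache$proj_dims[[i]][2])
    pb <- nn_backward(net$projs[[i]], cache$projs[[i]]$cache, dp, need_dx = TRUE)
    proj_grads[[i]] <- pb$grads
    dstage[[i]] <- pb$dx
  }
  stage_grads <- vector("list", 4)
  dnext <- NULL
  for (i in 4:1) {
    dout <- if (is.null(dnext)) dstage[[i]] else dstage[[i]] + dnext
    sb <- nn_backward(net$stages[[i]], cache$stages[[i]]$cache, dout,
                      need_dx = TRUE)
    stage_grads[[i]] <- sb$grads
    dnext <- sb$dx
  }
  stem_grads <- nn_backward(net$stem, cache$stem$cache, dnext,
                            need_dx = FALSE)$grads
  list(stem = stem_grads, stages = stage_grads, projs = proj_grads,
       head = hb$grads)
}

fp_flat_grads <- function(net, grads) {
  pieces <- fp_pieces(net)
  gr <- c(list(grads$stem), grads$stages, grads$projs, list(grads$head))
  unlist(lapply(seq_along(pieces), function(i) nn_flat_grads(pieces[[i]], gr[[i]])),
         use.names = FALSE)
}

#' Select the first edge point from a probability map
#'
#' Argmax cell (ties broken by smallest column-major index) mapped to full
#' resolution at the cell center: 1-based cell (r, c) maps to
#' (scale*(r-1) + scale/2 + 1, ...).
#'
#' @param pm score/probability matrix.
#' @param scale upsampling factor between map and image (8).
#' @return length-2 (row, col) point in full-resolution 1-based coordinates.
#' @export
select_first_point <- function(pm, scale = 8) {
  stopifnot(all(is.finite(pm)))
  i <- which.max(pm)
  r <- (i - 1) %% nrow(pm) + 1
  c <- (i - 1) %/% nrow(pm) + 1
  c(scale * (r - 1) + scale / 2 + 1, scale * (c - 1) + scale / 2 + 1)
}

#' Build the binary training target for the first-point network
#'
#' A cell is 1 iff it contains at least one ground-truth contour point
#' (floor-division downsampling of the point coordinates).
#'
#' @param gt ground-truth [contour()] (1-based points).
#' @param image_size full-resolution image side.
#' @param scale downsampling factor (8).
#' @return binary matrix (image_size/scale)^2.
#' @export
make_first_p_target <- function(gt, image_size, scale = 8) {
  gt <- as_contour(gt)
  if (nrow(gt$points) == 0) stop("empty ground-truth contour")
  m <- image_size %/% scale
  tgt <- matrix(0, m, m)
  r <- pmin((gt$points[, 1] - 1) %/% scale + 1, m)
  c <- pmin((gt$points[, 2] - 1) %/% scale + 1, m)
  tgt[cbind(r, c)] <- 1
  tgt
}

#' Assemble the 3-channel network input from a grayscale image
#'
#' Channels: normalized grayscale, normalized Sobel magnitude, and the
#' grayscale again (the probability map does not exist before this network
#' runs), each in \[-1, 1\].
#'
#' @param gray raw grayscale matrix.
#' @return array (H, W, 3).
#' @export
first_p_input <- function(gray) {
  g <- normalize_pm1(gray)
  out <- array(0, c(nrow(gray), ncol(gray), 3))
  out[, , 1] <- g
  out[, , 2] <- normalize_pm1(sobel_edge_map(gray))
  out[, , 3] <- g
  out
}

bce_with_logits <- function(z, t) {
  loss <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  grad <- (1 / (1 + exp(-z)) - t) / length(z)
  list(loss = loss, grad = grad)
}

#' Train the first-point network
#'
#' Per-pixel binary cross-entropy between the sigmoid of the score map and the
#' downsampled boundary target, optimized with Adam (batch size 1 by default,
#' matching the full-size protocol).
#'
#' @param dataset list of samples, each a list with `image` (grayscale matrix)
#'   and `contour` (ground truth).
#' @param cfg a [first_p_config()].
#' @param epochs passes over the dataset (default from `cfg`).
#' @param seed master seed (initialisation + sample order).
#' @param net optionally continue training an existing network.
#' @param verbose print epoch losses.
#' @return list with `net` and `loss` (per-iteration numeric vector).
#' @export
train_first_p <- function(dataset, cfg = first_p_config(profile = "desk"),
                          epochs = cfg$epochs, seed = 1L, net = NULL,
                          verbose = FALSE) {
  if (length(dataset) == 0) stop("empty dataset")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(net)) net <- first_p_net(cfg, seed = seed)
  inputs <- lapply(dataset, function(s) first_p_input(s$image))
  targets <- lapply(dataset, function(s)
    make_first_p_target(s$contour, nrow(s$image), cfg$scale))
  n_par <- length(fp_flat_params(net))
  opt <- list(lr = cfg$lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8, t = 0L,
              m = numeric(n_par), v = numeric(n_par))
  losses <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(dataset))
    for (i in ord) {
      fw <- first_p_forward(net, inputs[[i]], keep_cache = TRUE)
      l <- bce_with_logits(fw$out, targets[[i]])
      losses <- c(losses, l$loss)
      grads <- first_p_backward(net, fw$cache, l$grad)
      g <- fp_flat_grads(net, grads)
      theta <- fp_flat_params(net)
      opt$t <- opt$t + 1L
      opt$m <- opt$beta1 * opt$m + (1 - opt$beta1) * g
      opt$v <- opt$beta2 * opt$v + (1 - opt$beta2) * g * g
      theta <- theta - opt$lr * (opt$m / (1 - opt$beta1^opt$t)) /
        (sqrt(opt$v / (1 - opt$beta2^opt$t)) + opt$eps)
      net <- fp_unflat_params(net, theta)
    }
    if (verbose) {
      message(sprintf("epoch %d: mean BCE %.5f", ep,
                      mean(utils::tail(losses, length(dataset)))))
    }
  }
  list(net = net, loss = losses)
}
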