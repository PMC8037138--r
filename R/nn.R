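# Minimal neural-network engine: batched im2col convolutions, residual blocks,
# bilinear resize, global average pooling, dense heads, manual backprop, Adam.
# Tensors are numeric arrays with dim (H, W, C, N); dense layers take (D, N)
# matrices. The grading stack ships no NN library, so the networks used by the
# first-point predictor and the Q-agent run on this engine; its gradients are
# verified against finite differences in the test suite.

#' @useDynLib edgewalk, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.nn_cache <- new.env(parent = emptyenv())

#' @keywords internal
nn_cache_get <- function(key, builder) {
  if (!exists(key, envir = .nn_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .nn_cache)
  }
  get(key, envir = .nn_cache, inherits = FALSE)
}

# ---- layer constructors -----------------------------------------------------

#' 2-D convolution layer
#'
#' @param in_c,out_c input/output channel counts.
#' @param k odd kernel size.
#' @param stride spatial stride.
#' @param pad zero padding on each side; defaults to (k-1)/2 ("same" at stride 1).
#' @param activation "relu" or "linear".
#' @return an `nn_layer` list.
#' @export
nn_conv <- function(in_c, out_c, k = 3, stride = 1, pad = (k - 1) %/% 2,
                    activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  fan_in <- k * k * in_c
  W <- matrix(stats::rnorm(fan_in * out_c, sd = sqrt(2 / fan_in)), fan_in, out_c)
  structure(list(type = "conv", in_c = in_c, out_c = out_c, k = k,
                 stride = stride, pad = pad, activation = activation,
                 params = list(W = W, b = numeric(out_c))),
            class = "nn_layer")
}

#' Dense (fully connected) layer on (D, N) matrices
#' @inheritParams nn_conv
#' @param in_dim,out_dim input/output feature sizes.
#' @export
nn_dense <- function(in_dim, out_dim, activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  W <- matrix(stats::rnorm(in_dim * out_dim, sd = sqrt(2 / in_dim)), in_dim, out_dim)
  structure(list(type = "dense", in_dim = in_dim, out_dim = out_dim,
                 activation = activation,
                 params = list(W = W, b = numeric(out_dim))),
            class = "nn_layer")
}

#' Global average pooling: (H, W, C, N) -> (C, N)
#' @export
nn_gap <- function() structure(list(type = "gap", params = NULL), class = "nn_layer")

#' Flatten spatial maps: (H, W, C, N) -> (H*W*C, N)
#' @export
nn_flatten <- function() {
  structure(list(type = "flatten", params = NULL), class = "nn_layer")
}

#' Bilinear resize layer to a fixed spatial size
#' @param out_h,out_w target spatial size.
#' @export
nn_resize <- function(out_h, out_w) {
  structure(list(type = "resize", out_h = out_h, out_w = out_w, params = NULL),
            class = "nn_layer")
}

#' Basic residual block (two 3x3 convolutions plus shortcut)
#'
#' The shortcut is the identity when shape is preserved, otherwise a strided
#' 1x1 convolution. A rectifier follows the addition.
#' @inheritParams nn_conv
#' @export
nn_res_block <- function(in_c, out_c, stride = 1) {
  main <- nn_seq(nn_conv(in_c, out_c, 3, stride, activation = "relu"),
                 nn_conv(out_c, out_c, 3, 1, activation = "linear"))
  short <- if (in_c != out_c || stride != 1) {
    nn_conv(in_c, out_c, 1, stride, pad = 0, activation = "linear")
  } else NULL
  structure(list(type = "res", main = main, short = short, params = NULL),
            class = "nn_layer")
}

#' Sequential container
#' @param ... layers, applied in order.
#' @export
nn_seq <- function(...) {
  structure(list(type = "seq", layers = list(...), params = NULL),
            class = "nn_layer")
}

# ---- bilinear interpolation matrices ----------------------------------------

interp_matrix <- function(n_in, n_out) {
  key <- paste("interp", n_in, n_out, sep = "_")
  nn_cache_get(key, function() {
    A <- matrix(0, n_out, n_in)
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    i0 <- floor(pos)
    w <- pos - i0
    lo <- pmin(pmax(i0, 1L), n_in)
    hi <- pmin(pmax(i0 + 1L, 1L), n_in)
    for (i in seq_len(n_out)) {
      A[i, lo[i]] <- A[i, lo[i]] + (1 - w[i])
      A[i, hi[i]] <- A[i, hi[i]] + w[i]
    }
    A
  })
}

#' Bilinear resize of an (H, W) matrix or (H, W, C[, N]) array
#' @param x input raster.
#' @param out_h,out_w target size.
#' @return resized array of the same dimensionality.
#' @export
bilinear_resize <- function(x, out_h, out_w) {
  d <- dim(x)
  was_mat <- length(d) == 2
  if (was_mat) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  y <- resize_fwd(x, out_h, out_w)
  if (was_mat) dim(y) <- c(out_h, out_w)
  y
}

resize_fwd <- function(x, oh, ow) {
  d <- dim(x)
  A <- interp_matrix(d[1], oh)
  B <- interp_matrix(d[2], ow)
  t1 <- A %*% matrix(x, d[1], d[2] * d[3] * d[4])        # (oh, W*C*N)
  t1 <- array(t1, c(oh, d[2], d[3], d[4]))
  t2 <- B %*% matrix(aperm(t1, c(2, 1, 3, 4)), d[2], oh * d[3] * d[4])
  aperm(array(t2, c(ow, oh, d[3], d[4])), c(2, 1, 3, 4))
}

resize_bwd <- function(dy, in_h, in_w) {
  d <- dim(dy)                                           # (oh, ow, C, N)
  A <- interp_matrix(in_h, d[1])
  B <- interp_matrix(in_w, d[2])
  t1 <- t(A) %*% matrix(dy, d[1], d[2] * d[3] * d[4])    # (in_h, ow*C*N)
  t1 <- array(t1, c(in_h, d[2], d[3], d[4]))
  t2 <- t(B) %*% matrix(aperm(t1, c(2, 1, 3, 4)), d[2], in_h * d[3] * d[4])
  aperm(array(t2, c(in_w, in_h, d[3], d[4])), c(2, 1, 3, 4))
}

# ---- forward ----------------------------------------------------------------

#' Forward pass through a layer or network
#'
#' @param layer an `nn_layer` (possibly a `nn_seq` container).
#' @param x input array (H, W, C, N) or matrix (D, N).
#' @param keep_cache keep intermediates needed by [nn_backward()].
#' @return list with `out` and (if requested) `cache`.
#' @export
nn_forward <- function(layer, x, keep_cache = FALSE) {
  switch(layer$type,
    seq = {
      caches <- if (keep_cache) vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        fw <- nn_forward(layer$layers[[i]], x, keep_cache)
        x <- fw$out
        if (keep_cache) caches[[i]] <- fw$cache
      }
      list(out = x, cache = caches)
    },
    conv = conv_fwd(layer, x, keep_cache),
    dense = {
      out <- crossprod(layer$params$W, x) + layer$params$b
      mask <- NULL
      if (layer$activation == "relu") {
        mask <- out > 0
        out[!mask] <- 0
      }
      list(out = out, cache = if (keep_cache) list(x = x, mask = mask))
    },
    gap = {
      d <- dim(x)
      out <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
      list(out = out, cache = if (keep_cache) list(dims = d))
    },
    flatten = {
      d <- dim(x)
      dim(x) <- c(d[1] * d[2] * d[3], d[4])
      list(out = x, cache = if (keep_cache) list(dims = d))
    },
    resize = {
      d <- dim(x)
      list(out = resize_fwd(x, layer$out_h, layer$out_w),
           cache = if (keep_cache) list(dims = d))
    },
    res = {
      mfw <- nn_forward(layer$main, x, keep_cache)
      sfw <- if (is.null(layer$short)) list(out = x, cache = NULL)
             else nn_forward(layer$short, x, keep_cache)
      out <- mfw$out + sfw$out
      mask <- out > 0
      out[!mask] <- 0
      list(out = out,
           cache = if (keep_cache) list(main = mfw$cache, short = sfw$cache,
                                        mask = mask))
    },
    stop("unknown layer type: ", layer$type)
  )
}

conv_fwd <- function(layer, x, keep_cache) {
  d <- dim(x)
  stopifnot(length(d) == 4, d[3] == layer$in_c)
  out <- cpp_conv_fwd(x, as.integer(d), layer$params$W, layer$params$b,
                      layer$k, layer$stride, layer$pad,
                      layer$activation == "relu")
  # backward recomputes im2col from the input; the cache only keeps x and,
  # for the rectifier derivative, the (post-activation) output
  cache <- if (keep_cache) {
    list(x = x, out = if (layer$activation == "relu") out, in_dims = d)
  }
  list(out = out, cache = cache)
}

# ---- backward ---------------------------------------------------------------

#' Backward pass; returns input gradient and parameter gradients
#'
#' @param layer,cache as produced by [nn_forward()] with `keep_cache = TRUE`.
#' @param dout gradient of the loss w.r.t. the layer output.
#' @param need_dx compute gradient w.r.t. the input (skip for the first layer).
#' @return list with `dx` and `grads` (a tree mirroring the layer structure).
#' @export
nn_backward <- function(layer, cache, dout, need_dx = TRUE) {
  switch(layer$type,
    seq = {
      n <- length(layer$layers)
      grads <- vector("list", n)
      for (i in rev(seq_len(n))) {
        bw <- nn_backward(layer$layers[[i]], cache[[i]], dout,
                          need_dx = need_dx || i > 1L)
        grads[i] <- list(bw$grads)   # not [[<-]]: NULL grads must keep the slot
        dout <- bw$dx
      }
      list(dx = dout, grads = grads)
    },
    conv = conv_bwd(layer, cache, dout, need_dx),
    dense = {
      if (!is.null(cache$mask)) dout <- dout * cache$mask
      grads <- list(W = cache$x %*% t(dout), b = rowSums(dout))
      dx <- if (need_dx) layer$params$W %*% dout
      list(dx = dx, grads = grads)
    },
    gap = {
      d <- cache$dims
      hw <- d[1] * d[2]
      dx <- array(rep(as.vector(dout) / hw, each = hw), d)
      list(dx = dx, grads = NULL)
    },
    flatten = {
      dim(dout) <- cache$dims
      list(dx = dout, grads = NULL)
    },
    resize = {
      list(dx = resize_bwd(dout, cache$dims[1], cache$dims[2]), grads = NULL)
    },
    res = {
      dout <- dout * cache$mask
      mbw <- nn_backward(layer$main, cache$main, dout, need_dx = need_dx)
      if (is.null(layer$short)) {
        dx <- if (need_dx) mbw$dx + dout
        list(dx = dx, grads = list(main = mbw$grads, short = NULL))
      } else {
        sbw <- nn_backward(layer$short, cache$short, dout, need_dx = need_dx)
        dx <- if (need_dx) mbw$dx + sbw$dx
        list(dx = dx, grads = list(main = mbw$grads, short = sbw$grads))
      }
    },
    stop("unknown layer type: ", layer$type)
  )
}

conv_bwd <- function(layer, cache, dout, need_dx) {
  if (!is.null(cache$out)) dout <- dout * (cache$out > 0)
  bw <- cpp_conv_bwd(cache$x, as.integer(cache$in_dims), layer$params$W,
                     dout, layer$k, layer$stride, layer$pad, need_dx)
  list(dx = bw$dx, grads = list(W = bw$dW, b = as.numeric(bw$db)))
}

# ---- parameter utilities and Adam -------------------------------------------

sublayers <- function(layer) {
  switch(layer$type,
    seq = layer$layers,
    res = Filter(Negate(is.null), list(main = layer$main, short = layer$short)),
    list())
}

#' Flatten all parameters of a network into one numeric vector
#' @param layer network root.
#' @export
nn_flat_params <- function(layer) {
  own <- unlist(layer$params, use.names = FALSE)
  subs <- switch(layer$type,
    seq = lapply(layer$layers, nn_flat_params),
    res = c(list(nn_flat_params(layer$main)),
            if (!is.null(layer$short)) list(nn_flat_params(layer$short))),
    list())
  c(own, unlist(subs, use.names = FALSE))
}

#' Write a flat parameter vector back into a network
#' @param layer network root.
#' @param theta numeric vector as produced by [nn_flat_params()].
#' @export
nn_unflat_params <- function(layer, theta) {
  res <- unflat_rec(layer, theta, 1L)
  stopifnot(res$pos == length(theta) + 1L)
  res$layer
}

unflat_rec <- function(layer, theta, pos) {
  for (nm in names(layer$params)) {
    n <- length(layer$params[[nm]])
    v <- theta[pos:(pos + n - 1L)]
    dim(v) <- dim(layer$params[[nm]])
    layer$params[[nm]] <- v
    pos <- pos + n
  }
  if (layer$type == "seq") {
    for (i in seq_along(layer$layers)) {
      r <- unflat_rec(layer$layers[[i]], theta, pos)
      layer$layers[[i]] <- r$layer
      pos <- r$pos
    }
  } else if (layer$type == "res") {
    r <- unflat_rec(layer$main, theta, pos)
    layer$main <- r$layer; pos <- r$pos
    if (!is.null(layer$short)) {
      r <- unflat_rec(layer$short, theta, pos)
      layer$short <- r$layer; pos <- r$pos
    }
  }
  list(layer = layer, pos = pos)
}

#' Flatten a gradient tree (as returned by [nn_backward()]) to a vector
#' @param layer network root (gives the structure).
#' @param grads gradient tree.
#' @export
nn_flat_grads <- function(layer, grads) {
  own <- if (!is.null(layer$params)) unlist(grads[names(layer$params)], use.names = FALSE)
  subs <- switch(layer$type,
    seq = unlist(lapply(seq_along(layer$layers), function(i)
      nn_flat_grads(layer$layers[[i]], grads[[i]])), use.names = FALSE),
    res = c(nn_flat_grads(layer$main, grads$main),
            if (!is.null(layer$short)) nn_flat_grads(layer$short, grads$short)),
    NULL)
  c(own, subs)
}

#' Initialise an Adam optimizer state for a network
#' @param layer network root.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @export
nn_adam_init <- function(layer, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  n <- length(nn_flat_params(layer))
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = numeric(n), v = numeric(n))
}

#' One Adam update step
#'
#' @param layer network root.
#' @param grads gradient tree from [nn_backward()].
#' @param opt optimizer state from [nn_adam_init()].
#' @return list with updated `layer` and `opt`.
#' @export
nn_adam_step <- function(layer, grads, opt) {
  g <- nn_flat_grads(layer, grads)
  theta <- nn_flat_params(layer)
  opt$t <- opt$t + 1L
  opt$m <- opt$beta1 * opt$m + (1 - opt$beta1) * g
  opt$v <- opt$beta2 * opt$v + (1 - opt$beta2) * g * g
  mhat <- opt$m / (1 - opt$beta1^opt$t)
  vhat <- opt$v / (1 - opt$beta2^opt$t)
  theta <- theta - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  list(layer = nn_unflat_params(layer, theta), opt = opt)
}
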