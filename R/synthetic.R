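# Synthetic left-ventricle phantoms with exact ground truth. The blood pool is
# a bright, roughly circular region (star-convex radial model r(theta) = R +
# sum_k a_k sin(k theta + phi_k)) on a darker background, wrapped by a darker
# myocardium-like ring, degraded by a smooth intensity-inhomogeneity field,
# Gaussian blur and additive noise. Optional boundary depressions (inward
# notches) mimic papillary muscles / trabeculations, which the ground-truth
# endocardial contour excludes in real data but which here deform the true
# boundary so the tracer must handle them.

#' Phantom specification
#'
#' Defaults describe the desk-scale world: 96 x 96 rasters (the full-size
#' profile uses 368) with a blood pool of radius ~0.29 * size, mild shape
#' harmonics, moderate blur/noise, and one papillary-muscle-like depression.
#'
#' @param size square image side (px).
#' @param center_jitter max uniform displacement of the pool center (px).
#' @param base_radius mean boundary radius (px).
#' @param harmonics amplitudes (px) of radial harmonics k = 2, 3, ... .
#' @param pool_intensity,ring_intensity,background_intensity mean intensities
#'   (arbitrary units in \[0, 1\]) of blood pool, myocardial ring, background.
#' @param ring_width radial thickness (px) of the dark ring.
#' @param inhomogeneity_amplitude amplitude of the smooth multiplicative-free
#'   additive bias field.
#' @param blur_sigma Gaussian blur scale (px).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param depression_count,depression_depth,depression_width number, radial
#'   depth (px) and angular width (radians) of boundary notches.
#' @param seed integer random seed for this phantom.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 96, center_jitter = 4,
                         base_radius = round(0.29 * size),
                         harmonics = c(0.05, 0.03) * base_radius,
                         pool_intensity = 0.85, ring_intensity = 0.30,
                         background_intensity = 0.10,
                         ring_width = round(0.1 * size),
                         inhomogeneity_amplitude = 0.10,
                         blur_sigma = 1.0, noise_sd = 0.03,
                         depression_count = 1, depression_depth = 0.12 * base_radius,
                         depression_width = 0.45, seed = 1L) {
  spec <- list(size = size, center_jitter = center_jitter,
               base_radius = base_radius, harmonics = harmonics,
               pool_intensity = pool_intensity, ring_intensity = ring_intensity,
               background_intensity = background_intensity,
               ring_width = ring_width,
               inhomogeneity_amplitude = inhomogeneity_amplitude,
               blur_sigma = blur_sigma, noise_sd = noise_sd,
               depression_count = depression_count,
               depression_depth = depression_depth,
               depression_width = depression_width, seed = as.integer(seed))
  if (spec$size < 16) stop("phantom size too small")
  if (spec$base_radius + sum(abs(spec$harmonics)) + spec$center_jitter >=
      spec$size / 2) {
    stop("radius plus perturbation must stay inside the half-image")
  }
  structure(spec, class = "phantom_spec")
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(img); W <- ncol(img)
  ri <- pmin(pmax(seq_len(H + 2 * rad) - rad, 1L), H)
  ci <- pmin(pmax(seq_len(W + 2 * rad) - rad, 1L), W)
  xp <- img[ri, , drop = FALSE]
  out <- matrix(0, H, W)
  for (j in seq_along(k)) out <- out + k[j] * xp[(j - 1) + seq_len(H), , drop = FALSE]
  xp <- out[, ci[seq_len(W + 2 * rad)], drop = FALSE]
  out <- matrix(0, H, W)
  for (j in seq_along(k)) out <- out + k[j] * xp[, (j - 1) + seq_len(W), drop = FALSE]
  out
}

# radius function r(theta) of a spec given drawn phases/depression centers
radius_fn <- function(spec, phases, notch_centers) {
  function(theta) {
    r <- rep(spec$base_radius, length(theta))
    for (k in seq_along(spec$harmonics)) {
      r <- r + spec$harmonics[k] * sin((k + 1) * theta + phases[k])
    }
    for (tc in notch_centers) {
      d <- atan2(sin(theta - tc), cos(theta - tc))   # wrapped angular distance
      r <- r - spec$depression_depth * exp(-(d / spec$depression_width)^2 / 2)
    }
    r
  }
}

#' Generate one phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (numeric matrix in \[0, 1\]), `mask` (0/1 matrix),
#'   `contour` (dense, ordered counterclockwise, closed), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  ctr <- spec$size / 2 + stats::runif(2, -spec$center_jitter, spec$center_jitter)
  phases <- stats::runif(max(1, length(spec$harmonics)), 0, 2 * pi)
  notch_centers <- if (spec$depression_count > 0) {
    stats::runif(spec$depression_count, 0, 2 * pi)
  } else numeric(0)
  rfun <- radius_fn(spec, phases, notch_centers)

  # dense ordered boundary, counterclockwise (row down, col right: theta
  # increasing with row = ctr - r sin(theta) walks counterclockwise on screen)
  npts <- max(256L, ceiling(4 * pi * spec$base_radius))
  theta <- seq(0, 2 * pi, length.out = npts + 1L)[-(npts + 1L)]
  rr <- rfun(theta)
  pts <- cbind(row = ctr[1] - rr * sin(theta), col = ctr[2] + rr * cos(theta))
  ipts <- round(pts)
  keep <- c(TRUE, rowSums(abs(diff(ipts))) > 0)
  ipts <- ipts[keep, , drop = FALSE]
  gt_contour <- contour(ipts, closed = TRUE)
  mask <- rasterize_contour(gt_contour, c(spec$size, spec$size))

  # intensity model from the same analytic boundary
  g <- expand.grid(row = seq_len(spec$size), col = seq_len(spec$size))
  dr <- g$row - ctr[1]; dc <- g$col - ctr[2]
  rad <- sqrt(dr^2 + dc^2)
  th <- atan2(-dr, dc)
  rb <- rfun(th)
  img <- ifelse(rad <= rb, spec$pool_intensity,
                ifelse(rad <= rb + spec$ring_width, spec$ring_intensity,
                       spec$background_intensity))
  img <- matrix(img, spec$size, spec$size)
  if (spec$inhomogeneity_amplitude > 0) {
    u <- (matrix(g$row, spec$size) - spec$size / 2) / spec$size
    v <- (matrix(g$col, spec$size) - spec$size / 2) / spec$size
    a <- stats::runif(3, -1, 1)
    img <- img + spec$inhomogeneity_amplitude * (a[1] * u + a[2] * v +
                                                 a[3] * sin(pi * u) * sin(pi * v))
  }
  img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(spec$size^2, sd = spec$noise_sd),
                        spec$size, spec$size)
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, contour = gt_contour, spec = spec)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a dataset of phantoms on disk
#'
#' Writes, for each phantom, an ASCII PGM image, an ASCII PGM mask (0/255) and
#' a contour text file ("x y" per line, 0-based, x = column), plus a manifest
#' of tab-separated relative paths (image, contour, mask). Per-item seeds are
#' derived from the master seed, so the same seed reproduces files byte for
#' byte.
#'
#' @param n number of phantoms.
#' @param dir output directory (created if needed).
#' @param spec template [phantom_spec()]; each item redraws only the seed.
#' @param seed master seed.
#' @return path to the manifest file.
#' @export
generate_dataset <- function(n, dir, spec = phantom_spec(), seed = 1L) {
  stopifnot(n >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  rows <- character(n)
  for (i in seq_len(n)) {
    s <- spec
    s$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    ph <- generate_phantom(s)
    img_f <- sprintf("phantom_%03d_image.pgm", i)
    msk_f <- sprintf("phantom_%03d_mask.pgm", i)
    ctr_f <- sprintf("phantom_%03d_contour.txt", i)
    write_pgm(ph$image, file.path(dir, img_f))
    write_pgm(ph$mask * 255, file.path(dir, msk_f), maxval = 255)
    write_contour_file(ph$contour, file.path(dir, ctr_f))
    rows[i] <- paste(img_f, ctr_f, msk_f, sep = "\t")
  }
  manifest <- file.path(dir, "manifest.tsv")
  writeLines(rows, manifest)
  manifest
}

#' Read a dataset manifest
#'
#' @param manifest path to a manifest written by [generate_dataset()].
#' @return data.frame with absolute `image`, `contour`, `mask` paths.
#' @export
read_manifest <- function(manifest) {
  rows <- strsplit(readLines(manifest), "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 3)
  if (length(bad)) stop("malformed manifest line(s): ", paste(bad, collapse = ", "))
  d <- do.call(rbind, rows)
  base <- dirname(manifest)
  data.frame(image = file.path(base, d[, 1]), contour = file.path(base, d[, 2]),
             mask = file.path(base, d[, 3]), stringsAsFactors = FALSE)
}

#' Perturb a contour with iid displacement noise
#'
#' @param gt a [contour()].
#' @param shift noise scale (px); 0 returns the contour unchanged.
#' @param seed random seed.
#' @param shape optional `c(H, W)` bounds for clamping.
#' @return perturbed contour.
#' @export
perturb_contour <- function(gt, shift, seed = 1L, shape = NULL) {
  stopifnot(shift >= 0)
  gt <- as_contour(gt)
  if (shift == 0) return(gt)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(gt$points)
  pts <- gt$points + matrix(stats::rnorm(2 * n, sd = shift), n, 2)
  pts <- round(pts)
  if (!is.null(shape)) {
    pts[, 1] <- pmin(pmax(pts[, 1], 1), shape[1])
    pts[, 2] <- pmin(pmax(pts[, 2], 1), shape[2])
  }
  contour(pts, closed = gt$closed)
}
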