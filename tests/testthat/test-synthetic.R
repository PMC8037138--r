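# Phantom generator: geometric fidelity, determinism, topology, file round
# trips, and the contour perturbation helper.

test_that("a clean disc phantom has area ~ pi R^2 and bimodal intensities", {
  # large radius so the boundary-inclusive fill (~ +pi*R px) sits inside the
  # 2% analytic-area band
  spec <- phantom_spec(size = 200, center_jitter = 0, base_radius = 80,
                       harmonics = 0, inhomogeneity_amplitude = 0,
                       blur_sigma = 0, noise_sd = 0, depression_count = 0,
                       seed = 5)
  ph <- generate_phantom(spec)
  expect_lt(abs(sum(ph$mask) - pi * spec$base_radius^2),
            0.02 * pi * spec$base_radius^2)
  # pool/background modes present and separated (no blur, no noise)
  expect_gt(mean(ph$image == spec$pool_intensity), 0.15)
  expect_gt(mean(ph$image == spec$background_intensity), 0.15)
})

test_that("same seed reproduces the phantom bit for bit; seeds differ", {
  a <- generate_phantom(phantom_spec(seed = 9))
  b <- generate_phantom(phantom_spec(seed = 9))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$contour$points, b$contour$points)
  c <- generate_phantom(phantom_spec(seed = 10))
  expect_false(identical(a$image, c$image))
})

test_that("depressions strictly shrink the mask", {
  base <- phantom_spec(seed = 4, depression_count = 0)
  dep <- phantom_spec(seed = 4, depression_count = 2,
                      depression_depth = 0.2 * base$base_radius)
  m0 <- generate_phantom(base)$mask
  m1 <- generate_phantom(dep)$mask
  expect_lt(compute_iou(m0, m1), 1)
  expect_lt(sum(m1), sum(m0))
})

test_that("masks are one 4-connected component without holes, contours CCW", {
  flood <- function(m, start) {
    H <- nrow(m); W <- ncol(m)
    seen <- matrix(FALSE, H, W)
    stack <- list(start); seen[start[1], start[2]] <- TRUE
    val <- m[start[1], start[2]]
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= H && q[2] >= 1 && q[2] <= W &&
            !seen[q[1], q[2]] && m[q[1], q[2]] == val) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    seen
  }
  for (seed in c(2, 7, 13)) {
    ph <- generate_phantom(phantom_spec(seed = seed))
    m <- ph$mask
    inside <- which(m == 1, arr.ind = TRUE)
    comp <- flood(m, inside[1, ])
    expect_equal(sum(comp), sum(m))                 # single component
    bg <- flood(m, c(1, 1))                         # background from border
    expect_equal(sum(bg) + sum(m), length(m))       # no holes
    # counterclockwise orientation: positive shoelace signed area in
    # (x = col, y = -row) screen coordinates
    p <- ph$contour$points
    x <- p[, 2]; y <- -p[, 1]
    a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
    expect_gt(a2, 0)
  }
})

test_that("generate_dataset round-trips and is byte-reproducible", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- generate_dataset(4, d1, phantom_spec(), seed = 3)
  m2 <- generate_dataset(4, d2, phantom_spec(), seed = 3)
  man <- read_manifest(m1)
  expect_equal(nrow(man), 4)
  for (i in 1:4) {
    expect_identical(readLines(man$image[i]),
                     readLines(read_manifest(m2)$image[i]))
    img <- read_pgm(man$image[i])
    msk <- (read_pgm(man$mask[i]) > 0.5) * 1L
    ctr <- load_contour_file(man$contour[i])
    expect_equal(dim(img), dim(msk))
    # re-rasterized contour reproduces the written mask
    expect_gte(compute_iou(rasterize_contour(ctr, dim(msk)), msk), 0.99)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("perturb_contour: identity at 0, unit rigid shift APD, monotone trend", {
  ph <- generate_phantom(phantom_spec(seed = 6))
  expect_identical(perturb_contour(ph$contour, 0)$points, ph$contour$points)
  # rigid +1 row shift of a straight segment has APD exactly 1
  seg <- contour(cbind(10, 5:40))
  shifted <- contour(cbind(11, 5:40))
  expect_equal(average_perpendicular_distance(shifted, seg), 1)
  apds <- sapply(c(0.5, 2, 5), function(s) {
    mean(sapply(1:3, function(k) {
      average_perpendicular_distance(
        perturb_contour(ph$contour, s, seed = k, shape = c(96, 96)),
        ph$contour)
    }))
  })
  expect_true(all(diff(apds) > 0))
})
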