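# Raster geometry and evaluation metrics for contour-based segmentation.
# Conventions: rasters are (H x W) matrices indexed [row, col], 1-based, row
# increasing downward. Contours are ordered (row, col) point lists.

#' Construct a contour
#'
#' @param points two-column matrix of (row, col) coordinates, ordered along the
#'   boundary. A single point may be given as a length-2 vector.
#' @param closed logical; a closed contour implies the segment last -> first.
#' @return object of class `contour`.
#' @export
contour <- function(points, closed = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 1)
  colnames(points) <- c("row", "col")
  structure(list(points = points, closed = isTRUE(closed)), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour: %d points, %s>\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

as_contour <- function(x) {
  if (inherits(x, "contour")) x else contour(x)
}

check_same_shape <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s have different shapes: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
}

#' Intersection over union of two binary masks
#'
#' Defined as 0 when both masks are empty (degenerate episode-start case).
#'
#' @param a,b binary matrices of identical shape.
#' @return scalar in \[0, 1\].
#' @export
compute_iou <- function(a, b) {
  check_same_shape(a, b)
  inter <- sum(a > 0 & b > 0)
  uni <- sum(a > 0 | b > 0)
  if (uni == 0) 0 else inter / uni
}

#' Pixel counts of mask intersection and union
#'
#' Integer counts used for exact difference-IoU comparisons.
#' @inheritParams compute_iou
#' @return named numeric vector `c(inter =, union =)`.
#' @export
mask_overlap_counts <- function(a, b) {
  check_same_shape(a, b)
  c(inter = sum(a > 0 & b > 0), union = sum(a > 0 | b > 0))
}

# Integer Bresenham line between two points; returns matrix of (row, col).
bresenham <- function(p, q) {
  r0 <- p[1]; c0 <- p[2]; r1 <- q[1]; c1 <- q[2]
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  out
}

#' Rasterize a contour into a filled binary mask
#'
#' Consecutive points are connected (and last to first to close the polygon);
#' interior pixels are filled by an even-odd scanline rule and boundary pixels
#' are always included. A single point yields a one-pixel mask; collinear
#' points yield just their line segment.
#'
#' @param c a [contour()] or a two-column (row, col) matrix.
#' @param shape target mask dimensions `c(H, W)`.
#' @return binary (0/1) integer matrix of dimension `shape`.
#' @export
rasterize_contour <- function(c, shape) {
  c <- as_contour(c)
  pts <- round(c$points)
  H <- shape[1]; W <- shape[2]
  if (any(pts[, 1] < 1 | pts[, 1] > H | pts[, 2] < 1 | pts[, 2] > W)) {
    stop("contour point out of bounds for shape ", H, "x", W)
  }
  mask <- matrix(0L, H, W)
  n <- nrow(pts)
  if (n == 1) {
    mask[pts[1, 1], pts[1, 2]] <- 1L
    return(mask)
  }
  verts <- rbind(pts, pts[1, , drop = FALSE])   # close last -> first
  # boundary pixels
  for (i in seq_len(n)) {
    seg <- bresenham(verts[i, ], verts[i + 1, ])
    mask[seg] <- 1L
  }
  # interior: even-odd scanline over polygon edges (vertex rule rmin <= y < rmax)
  r1 <- verts[seq_len(n), 1]; c1 <- verts[seq_len(n), 2]
  r2 <- verts[seq_len(n) + 1, 1]; c2 <- verts[seq_len(n) + 1, 2]
  keep <- r1 != r2
  r1 <- r1[keep]; c1 <- c1[keep]; r2 <- r2[keep]; c2 <- c2[keep]
  if (length(r1)) {
    lo <- pmin(r1, r2); hi <- pmax(r1, r2)
    for (y in seq(min(lo), max(hi) - 1L)) {
      act <- which(lo <= y & y < hi)
      if (length(act) < 2) next
      xs <- sort(c1[act] + (y - r1[act]) * (c2[act] - c1[act]) / (r2[act] - r1[act]))
      for (j in seq(1, length(xs) - 1, by = 2)) {
        a <- ceiling(xs[j] - 1e-9); b <- floor(xs[j + 1] + 1e-9)
        if (b >= a) mask[y, a:b] <- 1L
      }
    }
  }
  mask
}

#' Minimum Euclidean distance from a point to a contour's points
#'
#' @param p length-2 (row, col) point.
#' @param gt ground-truth [contour()] (nonempty).
#' @return distance in pixels.
#' @export
min_edge_distance <- function(p, gt) {
  gt <- as_contour(gt)
  if (nrow(gt$points) == 0) stop("empty ground-truth contour")
  sqrt(min((gt$points[, 1] - p[1])^2 + (gt$points[, 2] - p[2])^2))
}

#' Average perpendicular distance between contours
#'
#' Mean over predicted points of the distance to the nearest ground-truth
#' contour point. Ground-truth contours are assumed densely sampled, making
#' the point-to-point approximation sub-pixel accurate.
#'
#' @param pred,gt contours (nonempty).
#' @return mean distance in pixels.
#' @export
average_perpendicular_distance <- function(pred, gt) {
  pred <- as_contour(pred); gt <- as_contour(gt)
  if (nrow(pred$points) == 0 || nrow(gt$points) == 0) stop("empty contour")
  gr <- gt$points[, 1]; gc <- gt$points[, 2]
  d <- vapply(seq_len(nrow(pred$points)), function(i) {
    sqrt(min((gr - pred$points[i, 1])^2 + (gc - pred$points[i, 2])^2))
  }, numeric(1))
  mean(d)
}

#' Precision, recall and F-measure of a predicted mask
#'
#' Conventions for empty denominators: precision of an empty prediction is 0;
#' F is 0 when precision and recall are both 0.
#'
#' @param pred,gt binary masks of identical shape.
#' @return named numeric vector `c(precision =, recall =, f =)`.
#' @export
precision_recall_fmeasure <- function(pred, gt) {
  check_same_shape(pred, gt)
  tp <- sum(pred > 0 & gt > 0)
  fp <- sum(pred > 0 & gt <= 0)
  fn <- sum(pred <= 0 & gt > 0)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f = f)
}

#' Sobel gradient magnitude of a grayscale image
#'
#' 3x3 Sobel filters with reflect padding; magnitude sqrt(gx^2 + gy^2).
#'
#' @param img numeric matrix.
#' @return matrix of the same shape.
#' @export
sobel_edge_map <- function(img) {
  H <- nrow(img); W <- ncol(img)
  ri <- c(1L, seq_len(H), H)          # reflect border (edge replication)
  ci <- c(1L, seq_len(W), W)
  xp <- img[ri, ci, drop = FALSE]
  sh <- function(dr, dc) xp[seq_len(H) + 1L + dr, seq_len(W) + 1L + dc, drop = FALSE]
  # gx: horizontal (col) derivative; gy: vertical (row) derivative
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Min-max normalize a raster to \[-1, 1\]
#'
#' Constant rasters map to 0.
#' @param x numeric matrix or array.
#' @export
normalize_pm1 <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(x * 0)
  2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
}
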