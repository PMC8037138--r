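# Independent brute-force oracles. These deliberately use naive loops and
# never call the package implementations they check.

oracle_iou <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    pa <- a[i, j] > 0; pb <- b[i, j] > 0
    if (pa && pb) inter <- inter + 1
    if (pa || pb) uni <- uni + 1
  }
  if (uni == 0) 0 else inter / uni
}

oracle_prf <- function(pred, gt) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] > 0; g <- gt[i, j] > 0
    if (p && g) tp <- tp + 1
    if (p && !g) fp <- fp + 1
    if (!p && g) fn <- fn + 1
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(p, r, f)
}

oracle_dice <- function(a, b) {
  na <- sum(a > 0); nb <- sum(b > 0)
  if (na + nb == 0) 0 else 2 * sum(a > 0 & b > 0) / (na + nb)
}

oracle_min_dist <- function(p, pts) {
  best <- Inf
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((pts[i, 1] - p[1])^2 + (pts[i, 2] - p[2])^2)
    if (d < best) best <- d
  }
  best
}

oracle_apd <- function(pred_pts, gt_pts) {
  tot <- 0
  for (i in seq_len(nrow(pred_pts))) {
    tot <- tot + oracle_min_dist(pred_pts[i, ], gt_pts)
  }
  tot / nrow(pred_pts)
}

# direct 3x3 Sobel convolution with edge-replicated border
oracle_sobel <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      v <- img[min(max(i + di, 1), H), min(max(j + dj, 1), W)]
      gx <- gx + kx[di + 2, dj + 2] * v
      gy <- gy + ky[di + 2, dj + 2] * v
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# value iteration on an explicit finite MDP: P[s, a] = next state, R[s, a],
# terminal[s]; returns Q*
oracle_value_iteration <- function(P, R, terminal, gamma, tol = 1e-10) {
  nS <- nrow(P); nA <- ncol(P)
  Q <- matrix(0, nS, nA)
  repeat {
    V <- apply(Q, 1, max)
    V[terminal] <- 0
    Qn <- R + gamma * matrix(V[P], nS, nA)
    if (max(abs(Qn - Q)) < tol) break
    Q <- Qn
  }
  Q
}

random_mask <- function(h, w, p = 0.4) matrix(as.integer(stats::runif(h * w) < p), h, w)
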