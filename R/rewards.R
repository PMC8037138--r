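# Immediate reward components of the contour-tracing MDP. Three terms:
# difference-IoU (dominant, in {-1, 0, 1}), edge-distance (in [0, 0.5] with
# defaults), and points-clustering penalty (-0.5 when the recent trajectory
# window collapses onto one spot). With defaults the attainable per-step total
# lies in [-1.5, 1.5]. Each term can be toggled for ablation runs.

#' Reward configuration
#'
#' @param ratio scaling of the edge-distance term; with `dist_threshold` 10 it
#'   normalizes that term to \[0, 0.5\] so difference-IoU stays dominant.
#' @param dist_threshold distance (px) beyond which the edge term is 0.
#' @param std_threshold dispersion (px) below which the clustering penalty fires.
#' @param cluster_window number of recent points entering the dispersion.
#' @param cluster_penalty magnitude of the clustering penalty.
#' @param mask_interval points excluded from the previous mask in the
#'   difference-IoU term (the "last 5 points" interval).
#' @param enabled_terms subset of `c("diff_iou", "edge_dist", "points_clus")`;
#'   disabled terms contribute 0 (ablation switch).
#' @return list of class `reward_config`.
#' @export
reward_config <- function(ratio = 0.05, dist_threshold = 10, std_threshold = 10,
                          cluster_window = 20, cluster_penalty = 0.5,
                          mask_interval = 5,
                          enabled_terms = c("diff_iou", "edge_dist", "points_clus")) {
  stopifnot(ratio > 0, dist_threshold > 0, std_threshold > 0,
            cluster_window >= 2, mask_interval >= 1,
            all(enabled_terms %in% c("diff_iou", "edge_dist", "points_clus")))
  structure(list(ratio = ratio, dist_threshold = dist_threshold,
                 std_threshold = std_threshold, cluster_window = cluster_window,
                 cluster_penalty = cluster_penalty, mask_interval = mask_interval,
                 enabled_terms = enabled_terms),
            class = "reward_config")
}

#' Difference-IoU reward
#'
#' Sign of IoU(curr, gt) - IoU(prev, gt), in \{-1, 0, 1\}. Ties are decided by
#' exact integer cross-multiplication of pixel counts, never by float equality.
#'
#' @param curr,prev,gt binary masks of identical shape (current segmentation,
#'   segmentation without the last interval of points, ground truth).
#' @export
diff_iou_reward <- function(curr, prev, gt) {
  check_same_shape(curr, gt); check_same_shape(prev, gt)
  a <- mask_overlap_counts(curr, gt)
  b <- mask_overlap_counts(prev, gt)
  # IoU(curr) vs IoU(prev):  ia/ua ? ib/ub  <=>  ia*ub ? ib*ua (all counts >= 0)
  if (a["union"] == 0 && b["union"] == 0) return(0)
  lhs <- a["inter"] * max(b["union"], 1)
  rhs <- b["inter"] * max(a["union"], 1)
  unname(sign(lhs - rhs))
}

#' Edge-distance reward
#'
#' `ratio * (dist_threshold - dist)` when `dist < dist_threshold`, else 0.
#'
#' @param dist non-negative distance (px) from the new point to the nearest
#'   ground-truth contour point.
#' @param cfg a [reward_config()].
#' @export
edge_distance_reward <- function(dist, cfg = reward_config()) {
  if (any(dist < 0)) stop("negative distance")
  ifelse(dist < cfg$dist_threshold, cfg$ratio * (cfg$dist_threshold - dist), 0)
}

#' Coordinate dispersion of a point window
#'
#' Pooled standard deviation sqrt(var(rows) + var(cols)) (population variances):
#' zero iff all points coincide, grows with spatial spread.
#'
#' @param points two-column (row, col) matrix.
#' @export
point_dispersion <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  n <- nrow(points)
  vr <- sum((points[, 1] - mean(points[, 1]))^2) / n
  vc <- sum((points[, 2] - mean(points[, 2]))^2) / n
  sqrt(vr + vc)
}

#' Points-clustering reward
#'
#' `-cluster_penalty` when the dispersion of the last `cluster_window` located
#' points falls below `std_threshold`; 0 while the window is not yet full.
#'
#' @param recent_points two-column matrix of the most recent points (at most
#'   `cluster_window` rows).
#' @param cfg a [reward_config()].
#' @export
points_clustering_reward <- function(recent_points, cfg = reward_config()) {
  if (is.null(dim(recent_points))) {
    recent_points <- matrix(recent_points, ncol = 2, byrow = TRUE)
  }
  if (nrow(recent_points) == 0) stop("empty point window")
  if (nrow(recent_points) < cfg$cluster_window) return(0)
  if (point_dispersion(recent_points) < cfg$std_threshold) -cfg$cluster_penalty else 0
}

#' Total immediate reward
#'
#' Sum of the enabled components; with defaults the attainable range is
#' \[-1.5, 1.5\].
#'
#' @param diff_iou,edge_dist,points_clus component values (each computed by its
#'   own function; disabled components contribute 0 regardless of value).
#' @param cfg a [reward_config()].
#' @export
total_reward <- function(diff_iou, edge_dist, points_clus, cfg = reward_config()) {
  r <- 0
  if ("diff_iou" %in% cfg$enabled_terms) r <- r + diff_iou
  if ("edge_dist" %in% cfg$enabled_terms) r <- r + edge_dist
  if ("points_clus" %in% cfg$enabled_terms) r <- r + points_clus
  r
}

#' F-measure-difference reward (comparison toggle only)
#'
#' Sign of F(curr, gt) - F(prev, gt). Considered and rejected in favour of
#' difference-IoU by the method; provided only so the comparison property can
#' be tested, never tuned.
#'
#' @inheritParams diff_iou_reward
#' @export
diff_fmeasure_reward <- function(curr, prev, gt) {
  fa <- precision_recall_fmeasure(curr, gt)["f"]
  fb <- precision_recall_fmeasure(prev, gt)["f"]
  unname(sign(fa - fb))
}
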