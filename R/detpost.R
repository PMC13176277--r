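#' Detector post-processing parameters
#'
#' Defaults follow the detection-to-count conversion used throughout the
#' workflow: a 0.5 confidence threshold and a 0.7 IoU threshold for greedy
#' non-maximum suppression; ground-truth matching declares a detection
#' correct when it overlaps a ground-truth box by at least 50% IoU.
#'
#' @param conf_threshold minimum score kept by [filter_confidence()].
#' @param nms_iou IoU above which [nms()] suppresses an overlapping box.
#' @param match_iou minimum IoU for a true-positive match.
#' @return an object of class `detpost_params`.
#' @export
detpost_params <- function(conf_threshold = 0.5, nms_iou = 0.7,
                           match_iou = 0.5) {
  stopifnot(conf_threshold > 0, conf_threshold < 1,
            nms_iou > 0, nms_iou < 1, match_iou > 0, match_iou < 1)
  structure(list(conf_threshold = conf_threshold, nms_iou = nms_iou,
                 match_iou = match_iou), class = "detpost_params")
}

#' Construct a detection table
#'
#' Detections are plain data frames in the package-wide box convention
#' (0-based half-open corners) with a score in `[0, 1]` and an opaque
#' `source_id` naming the image the detection belongs to.
#'
#' @param x_min,y_min,x_max,y_max box corners (vectorized).
#' @param score detection confidence in `[0, 1]`.
#' @param source_id sample identifier (recycled).
#' @return data frame with columns `x_min`, `y_min`, `x_max`, `y_max`,
#'   `score`, `source_id`.
#' @export
detections <- function(x_min, y_min, x_max, y_max, score, source_id = "img1") {
  d <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                  x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                  score = as.numeric(score),
                  source_id = rep_len(as.character(source_id), length(x_min)))
  .check_boxes(d)
  if (any(d$score < 0 | d$score > 1)) stop("scores must lie in [0, 1]")
  d
}

.check_boxes <- function(b) {
  if (nrow(b) == 0) return(invisible(b))
  if (any(b$x_min >= b$x_max) || any(b$y_min >= b$y_max))
    stop("degenerate box: require x_min < x_max and y_min < y_max")
  invisible(b)
}

#' Intersection over union of two boxes
#'
#' Areas follow the half-open pixel convention, so `area = (x_max - x_min)
#' * (y_max - y_min)`. Symmetric in its arguments.
#'
#' @param a,b boxes as length-4 numeric vectors `(x_min, y_min, x_max,
#'   y_max)` or single-row data frames.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  a <- .as_box(a); b <- .as_box(b)
  .iou_vec(a[1], a[2], a[3], a[4], b[1], b[2], b[3], b[4])
}

.as_box <- function(b) {
  if (is.data.frame(b)) b <- unlist(b[1, c("x_min", "y_min", "x_max", "y_max")])
  b <- as.numeric(b)
  if (length(b) != 4) stop("a box is (x_min, y_min, x_max, y_max)")
  if (b[1] >= b[3] || b[2] >= b[4])
    stop("degenerate box: require x_min < x_max and y_min < y_max")
  b
}

# vectorized IoU of one box against many
.iou_vec <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  iw <- pmax(0, pmin(ax2, bx2) - pmax(ax1, bx1))
  ih <- pmax(0, pmin(ay2, by2) - pmax(ay1, by1))
  inter <- iw * ih
  union <- (ax2 - ax1) * (ay2 - ay1) + (bx2 - bx1) * (by2 - by1) - inter
  inter / union
}

#' Confidence filtering
#'
#' Keeps detections with `score >= thr` (inclusive), preserving input
#' order. Idempotent.
#'
#' @param dets detection data frame (see [detections()]).
#' @param thr confidence threshold in (0, 1).
#' @return filtered detection data frame.
#' @export
filter_confidence <- function(dets, thr = 0.5) {
  stopifnot(thr > 0, thr < 1)
  dets[dets$score >= thr, , drop = FALSE]
}

#' Greedy non-maximum suppression
#'
#' Repeatedly selects the highest-scoring remaining detection and
#' suppresses every remaining detection whose IoU with it is strictly
#' greater than `iou_thr`. Ties in score are broken by input order, so the
#' result is deterministic; returned rows are in selection (descending
#' score) order and any two of them have IoU <= `iou_thr`.
#'
#' @param dets detection data frame.
#' @param iou_thr suppression threshold in (0, 1).
#' @return surviving detections in selection order.
#' @export
nms <- function(dets, iou_thr = 0.7) {
  stopifnot(iou_thr > 0, iou_thr < 1)
  .check_boxes(dets)
  n <- nrow(dets)
  if (n == 0) return(dets)
  ord <- order(-dets$score)  # stable: ties keep input order
  d <- dets[ord, , drop = FALSE]
  alive <- rep(TRUE, n)
  keep <- integer(0)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep <- c(keep, i)
    rest <- which(alive & seq_len(n) > i)
    if (length(rest)) {
      ious <- .iou_vec(d$x_min[i], d$y_min[i], d$x_max[i], d$y_max[i],
                       d$x_min[rest], d$y_min[rest], d$x_max[rest], d$y_max[rest])
      alive[rest[ious > iou_thr]] <- FALSE
    }
  }
  d[keep, , drop = FALSE]
}

#' Convert raw detections to a count
#'
#' `|nms(filter_confidence(dets, conf_threshold), nms_iou)|` - the
#' detection-to-count conversion applied uniformly to every detector.
#'
#' @param dets detection data frame.
#' @param params a [detpost_params()] object.
#' @return integer count.
#' @export
detections_to_count <- function(dets, params = detpost_params()) {
  nrow(nms(filter_confidence(dets, params$conf_threshold), params$nms_iou))
}

#' Match detections to ground truth
#'
#' Detections are processed in descending score order; each one matches
#' the not-yet-matched ground-truth box of highest IoU, provided that IoU
#' is at least `match_iou` (then it is a true positive), otherwise it is a
#' false positive. Ground-truth boxes left unmatched are false negatives.
#' This greedy best-IoU assignment mirrors the COCO evaluator.
#'
#' @param dets detection data frame for a single image.
#' @param gts ground-truth box data frame (`x_min`, `y_min`, `x_max`,
#'   `y_max`) for the same image.
#' @param match_iou minimum IoU for a match.
#' @return list with `tp_pairs` (data frame `det_index`, `gt_index`, input
#'   row indices), `fp_indices`, `fn_indices`, `is_tp` (logical per
#'   detection in descending-score order), `order` (the descending-score
#'   permutation of detection rows).
#' @export
match_detections <- function(dets, gts, match_iou = 0.5) {
  .check_boxes(dets); .check_boxes(gts)
  nd <- nrow(dets); ng <- nrow(gts)
  ord <- if (nd) order(-dets$score) else integer(0)
  gt_taken <- rep(FALSE, ng)
  is_tp <- logical(nd)
  tp_det <- integer(0); tp_gt <- integer(0)
  for (k in seq_len(nd)) {
    i <- ord[k]
    if (ng == 0) next
    ious <- .iou_vec(dets$x_min[i], dets$y_min[i], dets$x_max[i], dets$y_max[i],
                     gts$x_min, gts$y_min, gts$x_max, gts$y_max)
    ious[gt_taken] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= match_iou) {
      gt_taken[j] <- TRUE
      is_tp[k] <- TRUE
      tp_det <- c(tp_det, i); tp_gt <- c(tp_gt, j)
    }
  }
  list(tp_pairs = data.frame(det_index = tp_det, gt_index = tp_gt),
       fp_indices = setdiff(ord, tp_det),
       fn_indices = which(!gt_taken),
       is_tp = is_tp,
       order = ord)
}

#' Average precision at a fixed IoU threshold
#'
#' Detections pooled over an image set (distinguished by `source_id`) are
#' matched per image, ranked by score globally, and the area under the
#' interpolated precision-recall curve is returned. With a single class
#' this equals mAP at the chosen IoU (mAP@50 at the default threshold).
#'
#' Two interpolation rules are provided: `"coco101"` (the COCO evaluator's
#' 101-point average of the precision envelope) and `"all_points"`
#' (exact area under the envelope).
#'
#' @param dets detection data frame with `source_id`.
#' @param gts ground-truth data frame with `source_id`.
#' @param match_iou IoU threshold for a true positive (default 0.5).
#' @param interpolation `"coco101"` or `"all_points"`.
#' @return AP in `[0, 1]`; `NaN` with a warning if there is no ground truth.
#' @examples
#' g <- detections(c(0, 40), c(0, 0), c(10, 50), c(10, 10), score = 1)
#' average_precision(g, g)  # perfect detections: AP = 1
#' @export
average_precision <- function(dets, gts, match_iou = 0.5,
                              interpolation = c("coco101", "all_points")) {
  interpolation <- match.arg(interpolation)
  .check_boxes(dets); .check_boxes(gts)
  ng <- nrow(gts)
  if (ng == 0) {
    warning("no ground-truth boxes: AP is undefined")
    return(NaN)
  }
  if (nrow(dets) == 0) return(0)
  if (is.null(dets$source_id)) dets$source_id <- "img1"
  if (is.null(gts$source_id)) gts$source_id <- "img1"
  scores <- numeric(0); tps <- logical(0)
  for (img in unique(dets$source_id)) {
    di <- dets[dets$source_id == img, , drop = FALSE]
    gi <- gts[gts$source_id == img, , drop = FALSE]
    m <- if (nrow(gi)) match_detections(di, gi, match_iou)
         else list(is_tp = logical(nrow(di)), order = order(-di$score))
    scores <- c(scores, di$score[m$order])
    tps <- c(tps, m$is_tp)
  }
  ord <- order(-scores)
  tp_cum <- cumsum(tps[ord])
  fp_cum <- cumsum(!tps[ord])
  recall <- tp_cum / ng
  precision <- tp_cum / (tp_cum + fp_cum)
  env <- rev(cummax(rev(precision)))  # precision envelope
  if (interpolation == "coco101") {
    rgrid <- seq(0, 1, by = 0.01)
    idx <- findInterval(rgrid, recall, left.open = TRUE) + 1L
    p <- ifelse(idx <= length(env), env[idx], 0)
    mean(p)
  } else {
    sum(diff(c(0, recall)) * env)
  }
}
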