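# Independent brute-force oracles used to validate the fast implementations.

# Greedy NMS by literal definition: repeatedly take the highest-scoring
# remaining detection (first on ties), drop every remaining detection whose
# IoU with it exceeds the threshold. O(n^2), no sorting shortcuts.
nms_oracle <- function(dets, thr) {
  remaining <- dets
  kept <- dets[0, , drop = FALSE]
  while (nrow(remaining) > 0) {
    i <- which.max(remaining$score)
    top <- remaining[i, , drop = FALSE]
    kept <- rbind(kept, top)
    remaining <- remaining[-i, , drop = FALSE]
    if (nrow(remaining)) {
      ok <- vapply(seq_len(nrow(remaining)), function(k)
        iou(top, remaining[k, ]) <= thr, TRUE)
      remaining <- remaining[ok, , drop = FALSE]
    }
  }
  kept
}

# Literal greedy matcher: walk detections in descending score, compare with
# every unmatched gt, take the best IoU if it clears the threshold.
match_oracle <- function(dets, gts, thr) {
  ord <- order(-dets$score)
  taken <- rep(FALSE, nrow(gts))
  is_tp <- logical(nrow(dets))
  for (k in seq_along(ord)) {
    i <- ord[k]
    best <- 0; best_j <- 0
    for (j in seq_len(nrow(gts))) {
      if (taken[j]) next
      v <- iou(dets[i, ], gts[j, ])
      if (v > best) { best <- v; best_j <- j }
    }
    if (best_j > 0 && best >= thr) { taken[best_j] <- TRUE; is_tp[k] <- TRUE }
  }
  is_tp
}

# Exhaustive PR-curve construction from ranked TP flags: precision and
# recall at every rank, envelope by literal suffix maximum, then either
# the literal 101-point average or the literal rectangle sum.
ap_oracle <- function(is_tp_ranked, n_gt, rule = c("coco101", "all_points")) {
  rule <- match.arg(rule)
  n <- length(is_tp_ranked)
  if (n == 0) return(0)
  prec <- numeric(n); rec <- numeric(n)
  for (k in 1:n) {
    tp <- sum(is_tp_ranked[1:k])
    prec[k] <- tp / k
    rec[k] <- tp / n_gt
  }
  env <- numeric(n)
  for (k in 1:n) env[k] <- max(prec[k:n])
  if (rule == "coco101") {
    vals <- numeric(101)
    for (i in 0:100) {
      r <- i / 100
      above <- which(rec >= r)
      vals[i + 1] <- if (length(above)) env[min(above)] else 0
    }
    mean(vals)
  } else {
    total <- 0
    prev_r <- 0
    for (k in 1:n) {
      total <- total + (rec[k] - prev_r) * env[k]
      prev_r <- rec[k]
    }
    total
  }
}

# Regression metrics from explicit sums (no lm()).
regress_oracle <- function(pred, manual) {
  n <- length(pred)
  sx <- sum(manual); sy <- sum(pred)
  sxx <- sum(manual^2); sxy <- sum(manual * pred)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  fitted <- intercept + slope * manual
  sse <- sum((pred - fitted)^2)
  sst <- sum((pred - sy / n)^2)
  err <- pred - manual
  rmse <- sqrt(sum(err^2) / n)
  rng <- max(manual) - min(manual)
  list(slope = slope, intercept = intercept,
       r2 = 1 - sse / sst,
       rmse = rmse,
       nrmse_pct = 100 * rmse / rng,
       mae = sum(abs(err)) / n,
       bias = sum(err) / n,
       mape_pct = 100 * sum(abs(err[manual > 0]) / manual[manual > 0]) /
         sum(manual > 0))
}

# Random small box/detection generators for property suites.
random_dets <- function(n, span = 60, source_id = "img1") {
  x <- runif(n, 0, span); y <- runif(n, 0, span)
  w <- runif(n, 2, 14); h <- runif(n, 2, 14)
  detections(x, y, x + w, y + h, score = round(runif(n), 3),
             source_id = source_id)
}

random_gts <- function(n, span = 60, source_id = "img1") {
  x <- runif(n, 0, span); y <- runif(n, 0, span)
  w <- runif(n, 2, 14); h <- runif(n, 2, 14)
  data.frame(x_min = x, y_min = y, x_max = x + w, y_max = y + h,
             source_id = source_id)
}
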