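test_that("IoU follows the half-open area convention", {
  b <- c(3, 4, 10, 12)
  expect_equal(iou(b, b), 1.0)
  expect_equal(iou(c(0, 0, 2, 2), c(5, 5, 7, 7)), 0.0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_equal(iou(c(1, 1, 3, 3), c(0, 0, 2, 2)), 1 / 7)  # symmetric
  expect_error(iou(c(0, 0, 0, 2), b), "degenerate")
})

test_that("confidence filtering is inclusive, order-preserving and idempotent", {
  d <- detections(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50), c(10, 10, 10),
                  score = c(0.9, 0.5, 0.49))
  f <- filter_confidence(d, 0.5)
  expect_equal(f$score, c(0.9, 0.5))
  expect_identical(filter_confidence(f, 0.5), f)
  expect_equal(nrow(filter_confidence(d[0, ], 0.5)), 0L)
})

test_that("greedy NMS matches its definition on the worked examples", {
  # two boxes with IoU 0.8: only the higher score survives at thr 0.7
  d <- detections(c(0, 0), c(0, 1), c(10, 10), c(10, 11), score = c(0.9, 0.8))
  expect_gt(iou(d[1, ], d[2, ]), 0.7)
  expect_equal(nms(d, 0.7)$score, 0.9)

  # IoU 0.6 <= thr: both survive
  d2 <- detections(c(0, 0), c(0, 2.5), c(10, 10), c(10, 12.5),
                   score = c(0.9, 0.8))
  expect_lt(iou(d2[1, ], d2[2, ]), 0.7)
  expect_equal(nrow(nms(d2, 0.7)), 2L)

  # non-overlapping boxes all survive, in descending score order
  d3 <- detections(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50), c(10, 10, 10),
                   score = c(0.3, 0.9, 0.6))
  expect_equal(nms(d3, 0.7)$score, c(0.9, 0.6, 0.3))
})

test_that("NMS equals the brute-force oracle on random instances", {
  set.seed(401)
  for (rep in 1:300) {
    n <- sample(0:12, 1)
    d <- random_dets(n, span = 40)
    thr <- runif(1, 0.2, 0.8)
    expect_equal(nms(d, thr), nms_oracle(d, thr), ignore_attr = TRUE)
  }
})

test_that("detection-to-count composes filter and NMS with the documented monotonicities", {
  expect_equal(detections_to_count(detections(numeric(0), numeric(0),
                                              numeric(0), numeric(0),
                                              numeric(0))), 0L)
  ten <- detections(seq(0, 180, by = 20), rep(0, 10),
                    seq(10, 190, by = 20), rep(10, 10), score = rep(0.9, 10))
  expect_equal(detections_to_count(ten), 10L)

  # three mutually overlapping boxes collapse to one
  tri <- detections(c(0, 0.2, 0.4), c(0, 0.2, 0.4), c(10, 10.2, 10.4),
                    c(10, 10.2, 10.4), score = c(0.9, 0.8, 0.7))
  expect_equal(detections_to_count(tri), 1L)

  set.seed(77)
  for (rep in 1:25) {
    d <- random_dets(sample(3:15, 1))
    counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(ct)
      detections_to_count(d, detpost_params(conf_threshold = ct)), 0L)
    expect_true(all(diff(counts) <= 0))  # non-increasing in conf threshold
    counts2 <- vapply(c(0.2, 0.4, 0.6, 0.8), function(it)
      detections_to_count(d, detpost_params(nms_iou = it)), 0L)
    expect_true(all(diff(counts2) >= 0))  # non-decreasing in NMS IoU
  }
})

test_that("greedy matching enforces one-to-one assignment and partitions detections", {
  g <- data.frame(x_min = c(0, 30), y_min = c(0, 0),
                  x_max = c(10, 40), y_max = c(10, 10))
  perfect <- detections(g$x_min, g$y_min, g$x_max, g$y_max, score = c(0.9, 0.8))
  m <- match_detections(perfect, g)
  expect_equal(nrow(m$tp_pairs), 2L)
  expect_equal(length(m$fp_indices), 0L)
  expect_equal(length(m$fn_indices), 0L)

  # one gt, two coincident detections: higher score wins, other is FP
  twin <- detections(c(0, 0), c(0, 0), c(10, 10), c(10, 10),
                     score = c(0.7, 0.95))
  m2 <- match_detections(twin, g[1, ])
  expect_equal(m2$tp_pairs$det_index, 2L)
  expect_equal(m2$fp_indices, 1L)

  # max IoU below the threshold is a false positive
  off <- detections(7, 7, 17, 17, score = 0.9)
  expect_lt(iou(off, g[1, ]), 0.5)
  m3 <- match_detections(off, g)
  expect_equal(nrow(m3$tp_pairs), 0L)
  expect_equal(length(m3$fp_indices), 1L)
  expect_equal(sort(m3$fn_indices), c(1L, 2L))

  # invariants on random inputs: tp + fp = |dets|, tp + fn = |gts|
  set.seed(88)
  for (rep in 1:50) {
    d <- random_dets(sample(1:8, 1)); gt <- random_gts(sample(1:8, 1))
    mm <- match_detections(d, gt)
    expect_equal(nrow(mm$tp_pairs) + length(mm$fp_indices), nrow(d))
    expect_equal(nrow(mm$tp_pairs) + length(mm$fn_indices), nrow(gt))
    expect_false(anyDuplicated(mm$tp_pairs$gt_index) > 0)
  }
})

test_that("average precision reproduces the enumerated PR curve", {
  g <- random_gts(3, source_id = "a")
  perfect <- detections(g$x_min, g$y_min, g$x_max, g$y_max,
                        score = rep(1, 3), source_id = "a")
  expect_equal(average_precision(perfect, g), 1.0)
  expect_equal(average_precision(perfect[0, ], g), 0.0)
  expect_warning(ap0 <- average_precision(perfect, g[0, ]), "undefined")
  expect_true(is.nan(ap0))

  # 2 gts; ranked detections TP(0.9), FP(0.8), TP(0.7): the precision
  # envelope is 1.0 to recall 0.5 then 2/3 to recall 1.0
  gt <- data.frame(x_min = c(0, 30), y_min = c(0, 0),
                   x_max = c(10, 40), y_max = c(10, 10), source_id = "a")
  d <- detections(c(0, 60, 30), c(0, 0, 0), c(10, 70, 40), c(10, 10, 10),
                  score = c(0.9, 0.8, 0.7), source_id = "a")
  expect_equal(ap_oracle(c(TRUE, FALSE, TRUE), 2, "all_points"), 5 / 6)
  expect_equal(average_precision(d, gt, interpolation = "all_points"), 5 / 6)
  expect_equal(average_precision(d, gt, interpolation = "coco101"),
               ap_oracle(c(TRUE, FALSE, TRUE), 2, "coco101"))
})

test_that("AP matches exhaustive enumeration on random multi-image instances", {
  set.seed(402)
  for (rep in 1:150) {
    imgs <- sample(1:2, 1)
    gt <- do.call(rbind, lapply(seq_len(imgs), function(i)
      random_gts(sample(1:3, 1), span = 30, source_id = paste0("im", i))))
    d <- do.call(rbind, lapply(seq_len(imgs), function(i)
      random_dets(sample(0:3, 1), span = 30, source_id = paste0("im", i))))
    if (nrow(d) == 0 || nrow(d) > 6) next
    # oracle ranking: per-image greedy match, then global score order
    flags <- scores <- NULL
    for (i in unique(d$source_id)) {
      di <- d[d$source_id == i, , drop = FALSE]
      gi <- gt[gt$source_id == i, , drop = FALSE]
      ordi <- order(-di$score)
      flags <- c(flags, match_oracle(di, gi, 0.5))
      scores <- c(scores, di$score[ordi])
    }
    ord <- order(-scores)
    for (rule in c("coco101", "all_points")) {
      expect_equal(average_precision(d, gt, 0.5, rule),
                   ap_oracle(flags[ord], nrow(gt), rule), tolerance = 1e-12)
    }
  }
})

test_that("feeding ground truth as detections is a fixed point", {
  set.seed(90)
  gx <- rep(seq(0, 90, by = 30), 3) + runif(12, 0, 5)
  gy <- rep(seq(0, 60, by = 30), each = 4) + runif(12, 0, 5)
  g <- data.frame(x_min = gx, y_min = gy, x_max = gx + runif(12, 5, 12),
                  y_max = gy + runif(12, 5, 12))
  asdet <- detections(g$x_min, g$y_min, g$x_max, g$y_max, score = rep(1, 12))
  expect_equal(detections_to_count(asdet), nrow(g))
  expect_equal(average_precision(asdet, g), 1.0)
})

test_that("COCO detection files round-trip", {
  d <- random_dets(5, source_id = "scene_001")
  tf <- tempfile(fileext = ".json")
  write_coco_detections(d, tf)
  d2 <- read_coco_detections(tf)
  expect_equal(d2, d, tolerance = 1e-12)
})
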