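scene_for_aug <- function(seed = 6, count = 5)
  render_scene(tiny_params(count = count, mode = "free", scale = 0.1,
                           debris = 1, seed = seed))

test_that("flips are involutions on image, boxes and pixel masks", {
  sc <- scene_for_aug()
  for (op in list(hflip, vflip)) {
    back <- op(op(sc))
    expect_identical(back$image, sc$image)
    expect_identical(back$instances, sc$instances)
    expect_identical(lapply(back$pixels, sort), lapply(sc$pixels, sort))
  }
})

test_that("flip box arithmetic follows the mirror rule", {
  sc <- scene_for_aug()
  W <- dim(sc$image)[2]; H <- dim(sc$image)[1]
  sc$instances <- data.frame(instance_id = 1L, x_min = 0, y_min = 0,
                             x_max = 10, y_max = 10, is_tiller = TRUE)
  sc$pixels <- list(1L)
  # analogue of a (0,0,10,10) box in a 100-wide image: (W-10, 0, W, 10)
  h <- hflip(sc)$instances
  expect_equal(unlist(h[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = W - 10, y_min = 0, x_max = W, y_max = 10))
  v <- vflip(sc)$instances
  expect_equal(unlist(v[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 0, y_min = H - 10, x_max = 10, y_max = H))

  # a centered box maps to itself under either flip
  sc$instances$x_min <- W / 2 - 5; sc$instances$x_max <- W / 2 + 5
  sc$instances$y_min <- H / 2 - 5; sc$instances$y_max <- H / 2 + 5
  expect_equal(hflip(sc)$instances, sc$instances)
  expect_equal(vflip(sc)$instances, sc$instances)
})

test_that("45-degree rotation expands the canvas and preserves instances", {
  sc <- scene_for_aug(seed = 13)
  W <- dim(sc$image)[2]; H <- dim(sc$image)[1]
  r <- rotate45(sc)
  expect_equal(dim(r$image)[2], ceiling((W + H) / sqrt(2)))
  expect_equal(dim(r$image)[1], ceiling((W + H) / sqrt(2)))
  expect_equal(nrow(r$instances), nrow(sc$instances))
  expect_equal(sum(r$instances$is_tiller), sc$true_count)
  b <- r$instances
  expect_true(all(b$x_min >= 0 & b$y_min >= 0 &
                    b$x_max <= dim(r$image)[2] & b$y_max <= dim(r$image)[1]))
})

test_that("a unit square at the rotation center maps to an AABB of side sqrt(2)", {
  sc <- scene_for_aug()
  W <- dim(sc$image)[2]; H <- dim(sc$image)[1]
  sc$instances <- data.frame(instance_id = 1L, x_min = W / 2 - 0.5,
                             y_min = H / 2 - 0.5, x_max = W / 2 + 0.5,
                             y_max = H / 2 + 0.5, is_tiller = TRUE)
  sc$pixels <- NULL
  b <- rotate45(sc)$instances
  # AABB of the rotated unit square has side exactly sqrt(2)
  expect_equal(b$x_max - b$x_min, sqrt(2))
  expect_equal(b$y_max - b$y_min, sqrt(2))
})

test_that("two successive rotations compose to a 90-degree rotation of box centroids", {
  sc <- scene_for_aug(seed = 23)
  r2 <- rotate45(rotate45(sc))
  d0 <- dim(sc$image); d2 <- dim(r2$image)
  c0 <- c(d0[2] / 2, d0[1] / 2); c2 <- c(d2[2] / 2, d2[1] / 2)
  b0 <- sc$instances; b2 <- r2$instances
  cx0 <- (b0$x_min + b0$x_max) / 2 - c0[1]
  cy0 <- (b0$y_min + b0$y_max) / 2 - c0[2]
  cx2 <- (b2$x_min + b2$x_max) / 2 - c2[1]
  cy2 <- (b2$y_min + b2$y_max) / 2 - c2[2]
  # 90-degree rotation: (x, y) -> (-y, x); corner snapping adds ~1 px noise
  expect_lt(max(abs(cx2 - (-cy0))), 1.5)
  expect_lt(max(abs(cy2 - cx0)), 1.5)
})

test_that("rotated boxes still bound their rotated instance pixels", {
  # the corner-transformed AABB must contain the instance's rotated pixels
  # (to raster tolerance); for thin diagonal strokes it is necessarily
  # loose, so only a weak IoU floor is meaningful alongside containment
  sc <- scene_for_aug(seed = 31, count = 6)
  r <- rotate45(sc)
  H2 <- dim(r$image)[1]
  for (i in seq_len(nrow(r$instances))) {
    lin <- r$pixels[[i]]
    rr <- ((lin - 1) %% H2) + 1
    cc <- ((lin - 1) %/% H2) + 1
    tight <- c(min(cc) - 1, min(rr) - 1, max(cc), max(rr))
    stored <- unlist(r$instances[i, c("x_min", "y_min", "x_max", "y_max")])
    expect_gte(tight[1], stored[1] - 1)
    expect_gte(tight[2], stored[2] - 1)
    expect_lte(tight[3], stored[3] + 1)
    expect_lte(tight[4], stored[4] + 1)
    expect_gte(iou(tight, stored), 0.2)
  }
})

test_that("HSV channel conversion is a geometric no-op with the expected encoding", {
  sc <- scene_for_aug()
  h <- hsv_channels(sc)
  expect_identical(h$instances, sc$instances)
  expect_identical(dim(h$image), dim(sc$image))

  img <- array(0, dim = c(1, 2, 3))
  img[1, 1, ] <- c(0, 255, 0)        # pure green
  img[1, 2, ] <- c(77, 77, 77)       # gray
  out <- hsv_channels(list(image = img,
                           instances = data.frame(), pixels = NULL))$image
  expect_equal(out[1, 1, 1], round(120 / 360 * 255))  # hue channel
  expect_equal(out[1, 2, 2], 0)                       # zero saturation
})

test_that("dataset expansion preserves counts and reports exact accounting", {
  set.seed(3)
  scenes <- scene_batch(3, tiny_params(count = 4, scale = 0.1, seed = NULL),
                        seed = 19)
  n0 <- sum(vapply(scenes, function(s) nrow(s$instances), 0L))

  idty <- expand_dataset(scenes, ops = character(0), include_original = TRUE)
  expect_equal(length(idty$scenes), 3L)
  expect_equal(idty$accounting$total_instances, n0)

  one <- expand_dataset(scenes, ops = "hflip")
  expect_equal(one$accounting$total_instances, 2 * n0)

  full <- expand_dataset(scenes)
  expect_equal(full$accounting$total_instances, 5 * n0)
  expect_equal(length(full$scenes), 15L)
  per_scene <- vapply(full$scenes, function(s) nrow(s$instances), 0L)
  expect_equal(per_scene, rep(vapply(scenes, function(s) nrow(s$instances), 0L), 5))

  expect_error(expand_dataset(scenes, ops = character(0),
                              include_original = FALSE), "nothing")
})
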