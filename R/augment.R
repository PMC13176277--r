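#' Label-preserving augmentation operators
#'
#' Four operators expand an annotated dataset while preserving per-scene
#' instance counts exactly: horizontal and vertical flips, a 45-degree
#' rotation onto an expanded canvas, and an RGB-to-HSV channel swap. Each
#' takes and returns a `tiller_scene` (image + boxes + instance pixel
#' masks) with exact bounding-box bookkeeping.
#'
#' @name augment-ops
#' @param scene a `tiller_scene` (from [render_scene()]) or any list with
#'   the same `image`/`instances`/`pixels` fields.
#' @return a transformed scene of the same class.
NULL

.scene_dims <- function(scene) dim(scene$image)[1:2]

#' @describeIn augment-ops mirror about the vertical axis; a box
#'   `(x_min, x_max)` maps to `(W - x_max, W - x_min)`.
#' @export
hflip <- function(scene) {
  d <- .scene_dims(scene); H <- d[1]; W <- d[2]
  scene$image <- scene$image[, W:1, , drop = FALSE]
  b <- scene$instances
  if (nrow(b)) {
    new_xmin <- W - b$x_max
    b$x_max <- W - b$x_min
    b$x_min <- new_xmin
    scene$instances <- b
  }
  if (!is.null(scene$pixels))
    scene$pixels <- lapply(scene$pixels, function(lin) {
      r <- ((lin - 1L) %% H) + 1L
      cc <- ((lin - 1L) %/% H) + 1L
      (W - cc) * H + r
    })
  scene
}

#' @describeIn augment-ops mirror about the horizontal axis (same rule on y).
#' @export
vflip <- function(scene) {
  d <- .scene_dims(scene); H <- d[1]
  scene$image <- scene$image[H:1, , , drop = FALSE]
  b <- scene$instances
  if (nrow(b)) {
    new_ymin <- H - b$y_max
    b$y_max <- H - b$y_min
    b$y_min <- new_ymin
    scene$instances <- b
  }
  if (!is.null(scene$pixels))
    scene$pixels <- lapply(scene$pixels, function(lin) {
      r <- ((lin - 1L) %% H) + 1L
      cc <- ((lin - 1L) %/% H) + 1L
      (cc - 1L) * H + (H - r + 1L)
    })
  scene
}

#' @describeIn augment-ops rotate the image 45 degrees about its center
#'   onto an expanded canvas (no instance is ever cropped); the canvas is
#'   background-filled and the image resampled bilinearly. Each box is
#'   replaced by the axis-aligned bounds of its four rotated corners, and
#'   instance pixel masks are rotated exactly (nearest-pixel).
#' @export
rotate45 <- function(scene) .rotate_scene(scene, pi / 4)

.rotate_scene <- function(scene, theta) {
  d <- .scene_dims(scene); H <- d[1]; W <- d[2]
  ct <- cos(theta); st <- sin(theta)
  W2 <- as.integer(ceiling(W * abs(ct) + H * abs(st)))
  H2 <- as.integer(ceiling(W * abs(st) + H * abs(ct)))
  cin <- c(W / 2, H / 2); cout <- c(W2 / 2, H2 / 2)
  bg <- if (!is.null(scene$params$background_level))
    scene$params$background_level else c(0, 0, 0)

  # inverse map output pixel centers into the source frame
  xo <- rep(seq_len(W2) - 0.5, each = H2) - cout[1]
  yo <- rep(seq_len(H2) - 0.5, times = W2) - cout[2]
  xi <- ct * xo + st * yo + cin[1]   # R(-theta)
  yi <- -st * xo + ct * yo + cin[2]
  x0 <- floor(xi - 0.5); y0 <- floor(yi - 0.5)
  fx <- xi - 0.5 - x0; fy <- yi - 0.5 - y0
  gx0 <- pmin(pmax(x0, 0), W - 1); gx1 <- pmin(pmax(x0 + 1, 0), W - 1)
  gy0 <- pmin(pmax(y0, 0), H - 1); gy1 <- pmin(pmax(y0 + 1, 0), H - 1)
  outside <- xi < 0 | xi > W | yi < 0 | yi > H
  out <- array(0, dim = c(H2, W2, 3))
  for (ch in 1:3) {
    src <- scene$image[, , ch]
    v <- (1 - fx) * (1 - fy) * src[cbind(gy0 + 1, gx0 + 1)] +
      fx * (1 - fy) * src[cbind(gy0 + 1, gx1 + 1)] +
      (1 - fx) * fy * src[cbind(gy1 + 1, gx0 + 1)] +
      fx * fy * src[cbind(gy1 + 1, gx1 + 1)]
    v[outside] <- bg[ch]
    out[, , ch] <- matrix(v, nrow = H2)
  }
  scene$image <- round(out)

  fwd <- function(x, y) {  # forward rotation of points
    xr <- ct * (x - cin[1]) - st * (y - cin[2]) + cout[1]
    yr <- st * (x - cin[1]) + ct * (y - cin[2]) + cout[2]
    cbind(xr, yr)
  }
  b <- scene$instances
  if (nrow(b)) {
    cx <- cbind(b$x_min, b$x_max, b$x_min, b$x_max)
    cy <- cbind(b$y_min, b$y_min, b$y_max, b$y_max)
    xr <- matrix(0, nrow(b), 4); yr <- xr
    for (k in 1:4) {
      p <- fwd(cx[, k], cy[, k])
      xr[, k] <- p[, 1]; yr[, k] <- p[, 2]
    }
    b$x_min <- pmax(0, apply(xr, 1, min))
    b$x_max <- pmin(W2, apply(xr, 1, max))
    b$y_min <- pmax(0, apply(yr, 1, min))
    b$y_max <- pmin(H2, apply(yr, 1, max))
    scene$instances <- b
  }
  if (!is.null(scene$pixels))
    scene$pixels <- lapply(scene$pixels, function(lin) {
      r <- ((lin - 1L) %% H) + 1L
      cc <- ((lin - 1L) %/% H) + 1L
      p <- fwd(cc - 0.5, r - 0.5)
      rr <- pmin(pmax(as.integer(ceiling(p[, 2])), 1L), H2)
      rc <- pmin(pmax(as.integer(ceiling(p[, 1])), 1L), W2)
      unique((rc - 1L) * H2 + rr)
    })
  scene
}

#' @describeIn augment-ops replace the three RGB channels by the HSV
#'   representation scaled to 8-bit (hue 0-360 mapped to 0-255); geometry,
#'   boxes and counts are untouched.
#' @export
hsv_channels <- function(scene) {
  d <- .scene_dims(scene); H <- d[1]; W <- d[2]
  hsv <- grDevices::rgb2hsv(rbind(as.vector(scene$image[, , 1]),
                                  as.vector(scene$image[, , 2]),
                                  as.vector(scene$image[, , 3])),
                            maxColorValue = 255)
  out <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) out[, , ch] <- matrix(round(hsv[ch, ] * 255), nrow = H)
  scene$image <- out
  scene
}

#' Expand an annotated dataset by augmentation
#'
#' Applies each requested operator to every scene and reports exact
#' instance accounting. Because every operator preserves per-scene
#' instance counts, the grand total equals
#' `originals x (include_original + number of ops)`.
#'
#' @param scenes list of scenes (see [augment-ops]).
#' @param ops character vector, ordered subset of
#'   `c("hflip", "vflip", "rotate45", "hsv_channels")`.
#' @param include_original keep the untransformed scenes in the output.
#' @return list with `scenes` (expanded list; each element carries an
#'   `augmentation` attribute naming its op or `"original"`) and
#'   `accounting` (list: `n_scenes`, `n_original_instances`, `per_op`
#'   named instance totals, `total_instances`).
#' @examples
#' b <- scene_batch(2, scene_params(count = 3, scale = 0.1), seed = 5)
#' expand_dataset(b, ops = c("hflip", "vflip"))$accounting$total_instances
#' @export
expand_dataset <- function(scenes,
                           ops = c("hflip", "vflip", "rotate45", "hsv_channels"),
                           include_original = TRUE) {
  if (length(ops) == 0) {
    if (!include_original)
      stop("no ops and originals excluded: nothing to produce")
  } else {
    ops <- match.arg(ops, c("hflip", "vflip", "rotate45", "hsv_channels"),
                     several.ok = TRUE)
  }
  n_orig <- vapply(scenes, function(s) nrow(s$instances), 0L)
  out <- list()
  if (include_original)
    out <- lapply(scenes, function(s) { attr(s, "augmentation") <- "original"; s })
  per_op <- stats::setNames(integer(length(ops)), ops)
  for (op in ops) {
    f <- switch(op, hflip = hflip, vflip = vflip, rotate45 = rotate45,
                hsv_channels = hsv_channels)
    aug <- lapply(scenes, function(s) {
      s2 <- f(s); attr(s2, "augmentation") <- op; s2
    })
    per_op[op] <- sum(vapply(aug, function(s) nrow(s$instances), 0L))
    out <- c(out, aug)
  }
  list(scenes = out,
       accounting = list(
         n_scenes = length(scenes),
         n_original_instances = sum(n_orig),
         per_op = as.list(per_op),
         total_instances = sum(n_orig) * include_original + sum(per_op)))
}
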