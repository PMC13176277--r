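#' Scene generation parameters
#'
#' Builds the parameter set for [render_scene()]. Defaults emulate the
#' bench-top imaging setup the package targets: a 3024 x 4032 px frame over
#' an approximately 30 x 40 cm field of view (about 100.8 px/cm), clipped
#' tillers of uniform 2.0 cm length spread on a near-black velvet background.
#'
#' The global `scale` factor shrinks the frame and all lengths
#' proportionally (areas by `scale^2`) so that test batches run quickly;
#' `scale = 1` reproduces the full imaging geometry. Stroke widths are
#' floored at 4 px after scaling so instances remain resolvable: a thinner
#' stroke would correspond to no physical tiller at the emulated optics.
#'
#' @param image_width_px,image_height_px frame size in pixels before scaling.
#' @param px_per_cm imaging resolution before scaling.
#' @param tiller_length_cm clipping length of each tiller segment.
#' @param tiller_width_px numeric length-2 range of stroke widths in px
#'   (at `scale = 1`).
#' @param count number of tillers, or `NULL` to draw from `count_range`.
#' @param count_range inclusive integer range to draw `count` from when
#'   `count` is `NULL`.
#' @param overlap_mode `"disjoint"` (instance masks are kept separated by at
#'   least `min_gap_px`) or `"free"` (instances may overlap and cross, as
#'   they do in real spread samples).
#' @param curvature_max maximum stroke curvature in radians per pixel of arc
#'   length; each tiller's curvature is drawn uniformly from
#'   `[0, curvature_max]` with random sign. 0 gives straight segments.
#' @param debris_rate expected number of non-tiller debris objects (pale
#'   seed-fragment/leaf-tip stubs) per scene; drawn Poisson.
#' @param background_level RGB triplet (0-255) of the dark background.
#' @param noise_sd standard deviation of additive Gaussian sensor noise.
#' @param min_gap_px minimum pixel separation enforced between instance
#'   masks in disjoint mode (at `scale = 1`); floored at 6 px after scaling
#'   so separated instances stay morphologically separable.
#' @param scale global geometry scale factor in (0, 1].
#' @param seed integer seed making the rendered scene reproducible.
#' @return an object of class `scene_params` (a list of resolved, scaled
#'   parameters).
#' @seealso [render_scene()], [scene_batch()]
#' @examples
#' p <- scene_params(count = 5, scale = 0.1, seed = 1)
#' p$px_per_cm
#' @export
scene_params <- function(image_width_px = 3024, image_height_px = 4032,
                         px_per_cm = 100.8, tiller_length_cm = 2.0,
                         tiller_width_px = c(8, 16),
                         count = NULL, count_range = NULL,
                         overlap_mode = c("disjoint", "free"),
                         curvature_max = 0.003, debris_rate = 3,
                         background_level = c(8, 8, 10), noise_sd = 2,
                         min_gap_px = 12, scale = 1, seed = NULL) {
  overlap_mode <- match.arg(overlap_mode)
  stopifnot(scale > 0, scale <= 1, px_per_cm > 0, tiller_length_cm > 0,
            length(tiller_width_px) == 2, all(tiller_width_px > 0),
            tiller_width_px[1] <= tiller_width_px[2],
            curvature_max >= 0, debris_rate >= 0,
            length(background_level) == 3, noise_sd >= 0)
  if (is.null(count) && is.null(count_range))
    stop("either `count` or `count_range` must be given")
  if (!is.null(count)) {
    count <- as.integer(count)
    if (is.na(count) || count < 0) stop("`count` must be a non-negative integer")
  } else {
    count_range <- as.integer(count_range)
    stopifnot(length(count_range) == 2, count_range[1] >= 0,
              count_range[1] <= count_range[2])
  }
  p <- list(
    image_width_px  = max(1L, as.integer(round(image_width_px * scale))),
    image_height_px = max(1L, as.integer(round(image_height_px * scale))),
    px_per_cm       = px_per_cm * scale,
    tiller_length_cm = tiller_length_cm,
    tiller_width_px = pmax(4, tiller_width_px * scale),
    count = count, count_range = count_range,
    overlap_mode = overlap_mode,
    curvature_max = curvature_max / scale,  # same bend per tiller at any scale
    debris_rate = debris_rate,
    background_level = as.numeric(background_level),
    noise_sd = noise_sd,
    # separation below ~6 px is not resolvable by any morphological
    # pipeline with 3x3 elements plus smoothing, so the disjoint-mode gap
    # is floored there: "disjoint" must keep meaning "separable" at any scale
    min_gap_px = max(6L, as.integer(round(min_gap_px * scale))),
    scale = scale, seed = seed)
  class(p) <- "scene_params"
  p
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf("Scene parameters: %d x %d px (%.1f px/cm), %s overlap\n",
              x$image_width_px, x$image_height_px, x$px_per_cm, x$overlap_mode))
  cnt <- if (!is.null(x$count)) as.character(x$count)
         else sprintf("U[%d, %d]", x$count_range[1], x$count_range[2])
  cat(sprintf("  tillers: %s, length %.1f cm (~%.0f px), width %.1f-%.1f px\n",
              cnt, x$tiller_length_cm, x$tiller_length_cm * x$px_per_cm,
              x$tiller_width_px[1], x$tiller_width_px[2]))
  cat(sprintf("  debris rate %.1f, scale %.2f, seed %s\n",
              x$debris_rate, x$scale,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

# odd brush size >= 3 for a stroke of width w
.odd_ge3 <- function(w) max(3L, 2L * as.integer(floor(w / 2)) + 1L)

.disc_brush_cache <- new.env(parent = emptyenv())
.disc_brush <- function(size) {
  key <- as.character(size)
  b <- .disc_brush_cache[[key]]
  if (is.null(b)) {
    b <- EBImage::makeBrush(size, shape = if (size >= 5) "disc" else "box")
    .disc_brush_cache[[key]] <- b
  }
  b
}

# Rasterize a constant-width stroke along a circular arc in local coordinates.
# Returns a small logical matrix plus the float extent used for placement.
.stroke_mask <- function(length_px, width_px, curvature, phi) {
  t <- seq(0, length_px, by = 0.4)
  if (abs(curvature) < 1e-8) {
    xs <- t * cos(phi); ys <- t * sin(phi)
  } else {
    k <- curvature
    xs <- (sin(phi + k * t) - sin(phi)) / k
    ys <- (cos(phi) - cos(phi + k * t)) / k
  }
  bw <- .odd_ge3(width_px)
  m <- as.integer(ceiling(bw / 2)) + 1L
  cx <- as.integer(round(xs - min(xs))) + m
  cy <- as.integer(round(ys - min(ys))) + m
  nr <- max(cy) + m; nc <- max(cx) + m
  mask <- matrix(0L, nr, nc)
  mask[cbind(cy, cx)] <- 1L
  mask <- EBImage::dilate(mask, .disc_brush(bw)) > 0
  mask
}

# Rasterize a rotated solid ellipse (debris) in local coordinates.
.ellipse_mask <- function(a, b, alpha) {
  m <- ceiling(max(a, b)) + 1
  g <- expand.grid(x = seq(-m, m), y = seq(-m, m))
  u <- g$x * cos(alpha) + g$y * sin(alpha)
  v <- -g$x * sin(alpha) + g$y * cos(alpha)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  matrix(inside, nrow = 2 * m + 1)
}

.hsv255 <- function(h_deg, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h_deg / 360, s, v)))
}

#' Render a synthetic clipping-sample scene
#'
#' Draws `count` green tiller strokes (slightly curved, constant width) and
#' optional pale debris stubs onto a noisy near-black background, and
#' records exact per-instance ground truth: tight axis-aligned bounding
#' boxes, instance pixel masks, and the true tiller count.
#'
#' Boxes use a single convention throughout the package: origin at the
#' top-left pixel corner, x rightward, y downward, 0-based half-open
#' intervals `[x_min, x_max) x [y_min, y_max)`.
#'
#' In `"disjoint"` mode instance placement is by rejection sampling with a
#' minimum mask separation of `min_gap_px`; if a placement cannot be found
#' within a bounded number of attempts an error is raised (the requested
#' density is infeasible for the frame). In `"free"` mode instances may
#' overlap arbitrarily; debris is drawn first so tiller masks stay exact.
#'
#' @param params a [scene_params()] object with a non-`NULL` seed.
#' @return an object of class `tiller_scene`: a list with `image`
#'   (H x W x 3 numeric array, 0-255), `instances` (data frame of boxes with
#'   `instance_id`, `x_min`, `y_min`, `x_max`, `y_max`, `is_tiller`),
#'   `pixels` (list of linear pixel indices per instance, the ground-truth
#'   segmentation masks), `true_count`, `regime`, `params`, `seed`.
#' @examples
#' sc <- render_scene(scene_params(count = 3, scale = 0.1, seed = 7))
#' sc$true_count
#' sc$instances
#' @export
render_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  if (is.null(params$seed)) stop("`params$seed` must be set for reproducibility")
  set.seed(params$seed)
  W <- params$image_width_px; H <- params$image_height_px
  n <- if (!is.null(params$count)) params$count
       else sample(params$count_range[1]:params$count_range[2], 1L)

  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3)
    img[, , ch] <- params$background_level[ch] +
      if (params$noise_sd > 0) stats::rnorm(H * W, 0, params$noise_sd) else 0

  disjoint <- params$overlap_mode == "disjoint"
  forbidden <- if (disjoint) matrix(FALSE, H, W) else NULL
  gap_brush <- if (disjoint) .disc_brush(2L * params$min_gap_px + 1L) else NULL

  pixels <- list(); rows_list <- list(); cols_list <- list()
  is_tiller <- logical(0)
  L <- params$tiller_length_cm * params$px_per_cm

  place_one <- function(maker) {
    # returns list(rows, cols) in frame coordinates or NULL after too many tries
    for (attempt in 1:200) {
      m <- maker()
      lh <- nrow(m); lw <- ncol(m)
      if (lh > H || lw > W) next
      r0 <- sample.int(H - lh + 1L, 1L) - 1L
      c0 <- sample.int(W - lw + 1L, 1L) - 1L
      idx <- which(m)
      rr <- ((idx - 1L) %% lh) + 1L + r0
      cc <- ((idx - 1L) %/% lh) + 1L + c0
      if (disjoint) {
        lin <- (cc - 1L) * H + rr
        if (any(forbidden[lin])) next
        # pad by the gap before dilating, or the exclusion zone would be
        # clipped at the local window edges
        g <- params$min_gap_px
        ph <- lh + 2L * g
        pm <- matrix(0L, ph, lw + 2L * g)
        pm[(g + 1L):(g + lh), (g + 1L):(g + lw)] <- m + 0L
        md <- EBImage::dilate(pm, gap_brush) > 0
        di <- which(md)
        dr <- ((di - 1L) %% ph) + 1L + r0 - g
        dc <- ((di - 1L) %/% ph) + 1L + c0 - g
        keep <- dr >= 1 & dr <= H & dc >= 1 & dc <= W
        forbidden[(dc[keep] - 1L) * H + dr[keep]] <<- TRUE
      }
      return(list(rows = rr, cols = cc))
    }
    NULL
  }

  paint <- function(rows, cols, rgb255) {
    npx <- H * W
    lin <- (cols - 1L) * H + rows
    img[lin] <<- rgb255[1]
    img[lin + npx] <<- rgb255[2]
    img[lin + 2L * npx] <<- rgb255[3]
  }

  add_instance <- function(rows, cols, tiller) {
    k <- length(pixels) + 1L
    pixels[[k]] <<- (cols - 1L) * H + rows
    rows_list[[k]] <<- range(rows); cols_list[[k]] <<- range(cols)
    is_tiller[k] <<- tiller
  }

  # debris first, so tillers rendered later keep exact masks in free mode
  n_debris <- if (params$debris_rate > 0) stats::rpois(1, params$debris_rate) else 0L
  if (n_debris > 0) {
    for (i in seq_len(n_debris)) {
      a <- stats::runif(1, 2, max(2.5, L / 8))
      b <- stats::runif(1, 1, a)
      alpha <- stats::runif(1, 0, pi)
      pl <- place_one(function() .ellipse_mask(a, b, alpha))
      if (is.null(pl)) next  # debris placement failure is not an error
      col <- .hsv255(stats::runif(1, 40, 60), stats::runif(1, 0.1, 0.3),
                     stats::runif(1, 0.5, 0.9))
      paint(pl$rows, pl$cols, col)
      add_instance(pl$rows, pl$cols, FALSE)
    }
  }

  if (n > 0) {
    for (i in seq_len(n)) {
      len <- L * stats::runif(1, 0.98, 1.02)
      w <- stats::runif(1, params$tiller_width_px[1], params$tiller_width_px[2])
      k <- stats::runif(1, 0, params$curvature_max) * sample(c(-1, 1), 1)
      phi <- stats::runif(1, 0, 2 * pi)
      pl <- place_one(function() .stroke_mask(len, w, k, phi))
      if (is.null(pl))
        stop(sprintf(paste0("disjoint placement failed for instance %d of %d: ",
                            "requested density is infeasible for this frame"),
                     i, n))
      col <- .hsv255(stats::runif(1, 85, 145), stats::runif(1, 0.5, 0.95),
                     stats::runif(1, 0.35, 0.9))
      paint(pl$rows, pl$cols, col)
      add_instance(pl$rows, pl$cols, TRUE)
    }
  }

  img[img < 0] <- 0; img[img > 255] <- 255
  img <- round(img)

  n_inst <- length(pixels)
  instances <- if (n_inst == 0) {
    data.frame(instance_id = integer(0), x_min = integer(0), y_min = integer(0),
               x_max = integer(0), y_max = integer(0), is_tiller = logical(0))
  } else {
    data.frame(
      instance_id = seq_len(n_inst),
      x_min = vapply(cols_list, `[`, 0, 1) - 1L,
      y_min = vapply(rows_list, `[`, 0, 1) - 1L,
      x_max = vapply(cols_list, `[`, 0, 2),
      y_max = vapply(rows_list, `[`, 0, 2),
      is_tiller = is_tiller)
  }

  structure(list(image = img, instances = instances, pixels = pixels,
                 true_count = sum(instances$is_tiller),
                 regime = regime_of(sum(instances$is_tiller)),
                 params = params, seed = params$seed),
            class = "tiller_scene")
}

#' @export
print.tiller_scene <- function(x, ...) {
  cat(sprintf("Synthetic tiller scene: %d x %d px, %d tillers (%s density), %d debris\n",
              dim(x$image)[2], dim(x$image)[1], x$true_count,
              as.character(x$regime), sum(!x$instances$is_tiller)))
  cat(sprintf("  overlap mode %s, seed %d\n", x$params$overlap_mode, x$seed))
  invisible(x)
}

#' Classify a tiller count into a density regime
#'
#' Samples are stratified by true count into low (< 150), medium (150-400,
#' inclusive on both ends) and high (> 400) density regimes; the three
#' strata partition the non-negative integers.
#'
#' @param count non-negative integer count (vectorized).
#' @return factor with levels `low`, `medium`, `high`.
#' @examples
#' regime_of(c(149, 150, 400, 401))
#' @export
regime_of <- function(count) {
  if (any(is.na(count)) || any(count < 0)) stop("`count` must be non-negative")
  factor(ifelse(count < 150, "low", ifelse(count <= 400, "medium", "high")),
         levels = c("low", "medium", "high"))
}

#' Generate a reproducible batch of synthetic scenes
#'
#' Per-scene seeds and counts are derived from a single master seed, so a
#' repeated call reproduces the batch exactly.
#'
#' @param n_scenes number of scenes (>= 1).
#' @param params_template a [scene_params()] object; its `count`/`seed` are
#'   overridden per scene.
#' @param count_sampler `NULL` to use the template's count settings, a
#'   single number for a fixed count, or a `function(n)` returning `n`
#'   counts (called under the master seed).
#' @param seed master seed.
#' @return list of `tiller_scene` objects.
#' @examples
#' b <- scene_batch(2, scene_params(count = 4, scale = 0.1), seed = 7)
#' vapply(b, `[[`, 0L, "true_count")
#' @export
scene_batch <- function(n_scenes, params_template, count_sampler = NULL, seed) {
  stopifnot(n_scenes >= 1, inherits(params_template, "scene_params"))
  set.seed(seed)
  counts <- if (is.null(count_sampler)) {
    if (!is.null(params_template$count)) rep(params_template$count, n_scenes)
    else sample(params_template$count_range[1]:params_template$count_range[2],
                n_scenes, replace = TRUE)
  } else if (is.function(count_sampler)) {
    as.integer(count_sampler(n_scenes))
  } else {
    rep(as.integer(count_sampler), n_scenes)
  }
  seeds <- sample.int(.Machine$integer.max, n_scenes)
  lapply(seq_len(n_scenes), function(i) {
    p <- params_template
    p$count <- counts[i]; p$count_range <- NULL; p$seed <- seeds[i]
    render_scene(p)
  })
}
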