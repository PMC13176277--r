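#' Edge-pipeline parameters
#'
#' Tunable parameters of the classical edge-based segmentation counter:
#' HSV hue threshold -> morphological erosion + Gaussian smoothing -> Canny
#' edge detection -> dilation -> hole filling and connected-component
#' counting. The hue window is expressed in degrees on the 0-360 hue circle
#' regardless of any library's internal encoding.
#'
#' Only `min_area_px` is geometry-dependent, so it is the only parameter
#' rescaled by `scale` (by `scale^2`, an area).
#'
#' @param hue_lo,hue_hi green hue window in degrees, `hue_lo < hue_hi`.
#' @param sat_min,val_min saturation/value guards in `[0, 1]`; they exclude
#'   near-black background pixels whose hue is undefined.
#' @param erosion_kernel_px odd side of the square erosion element.
#' @param blur_kernel_px,blur_sigma odd Gaussian kernel side and its sigma.
#' @param canny_lo,canny_hi Canny hysteresis thresholds on the gradient
#'   magnitude of the 0-255 mask raster, `canny_lo < canny_hi`.
#' @param dilation_kernel_px odd side of the square dilation element.
#' @param connectivity 4 or 8, pixel connectivity for component labeling.
#' @param min_area_px components smaller than this area (at `scale = 1`)
#'   are discarded before counting.
#' @param fill_holes fill enclosed holes before labeling, so each closed
#'   outline collapses to a single region.
#' @param scale global geometry scale factor, matching [scene_params()].
#' @return an object of class `edge_params`.
#' @examples
#' edge_params()
#' @export
edge_params <- function(hue_lo = 70, hue_hi = 170, sat_min = 0.25,
                        val_min = 0.15, erosion_kernel_px = 3,
                        blur_kernel_px = 5, blur_sigma = 1.0,
                        canny_lo = 50, canny_hi = 150,
                        dilation_kernel_px = 3, connectivity = 8,
                        min_area_px = 25, fill_holes = TRUE, scale = 1) {
  stopifnot(hue_lo < hue_hi, hue_lo >= 0, hue_hi <= 360,
            sat_min >= 0, sat_min <= 1, val_min >= 0, val_min <= 1,
            erosion_kernel_px %% 2 == 1, erosion_kernel_px >= 1,
            blur_kernel_px %% 2 == 1, blur_kernel_px >= 1, blur_sigma > 0,
            canny_lo < canny_hi, canny_lo > 0,
            dilation_kernel_px %% 2 == 1, dilation_kernel_px >= 1,
            connectivity %in% c(4, 8), min_area_px >= 0,
            is.logical(fill_holes), scale > 0, scale <= 1)
  structure(list(hue_lo = hue_lo, hue_hi = hue_hi, sat_min = sat_min,
                 val_min = val_min, erosion_kernel_px = as.integer(erosion_kernel_px),
                 blur_kernel_px = as.integer(blur_kernel_px), blur_sigma = blur_sigma,
                 canny_lo = canny_lo, canny_hi = canny_hi,
                 dilation_kernel_px = as.integer(dilation_kernel_px),
                 connectivity = as.integer(connectivity),
                 min_area_px = as.integer(round(min_area_px * scale^2)),
                 fill_holes = fill_holes, scale = scale),
            class = "edge_params")
}

#' @export
print.edge_params <- function(x, ...) {
  cat(sprintf(paste0("Edge-pipeline parameters: hue %g-%g deg (s>=%.2f, v>=%.2f), ",
                     "erode %dx%d, blur %dx%d s=%.1f,\n  Canny %g/%g, dilate %dx%d, ",
                     "%d-connectivity, min area %d px, fill holes %s\n"),
              x$hue_lo, x$hue_hi, x$sat_min, x$val_min,
              x$erosion_kernel_px, x$erosion_kernel_px,
              x$blur_kernel_px, x$blur_kernel_px, x$blur_sigma,
              x$canny_lo, x$canny_hi, x$dilation_kernel_px, x$dilation_kernel_px,
              x$connectivity, x$min_area_px, x$fill_holes))
  invisible(x)
}

.check_rgb <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("`image` must be an H x W x 3 RGB array")
  invisible(d)
}

#' HSV hue thresholding
#'
#' A pixel is foreground iff its hue lies in `[hue_lo, hue_hi]` (degrees)
#' and its saturation and value meet the `sat_min`/`val_min` guards; the
#' guards exclude dark background pixels whose hue is numerically undefined.
#'
#' @param image H x W x 3 numeric array, 8-bit scale (0-255).
#' @param params an [edge_params()] object.
#' @return logical H x W matrix, `TRUE` = foreground.
#' @export
hue_mask <- function(image, params = edge_params()) {
  d <- .check_rgb(image)
  hsv <- grDevices::rgb2hsv(rbind(as.vector(image[, , 1]),
                                  as.vector(image[, , 2]),
                                  as.vector(image[, , 3])),
                            maxColorValue = 255)
  h <- hsv[1, ] * 360
  m <- h >= params$hue_lo & h <= params$hue_hi &
    hsv[2, ] >= params$sat_min & hsv[3, ] >= params$val_min
  matrix(m, nrow = d[1], ncol = d[2])
}

#' Erosion and Gaussian smoothing of a binary mask
#'
#' Morphological erosion with a square element removes specks smaller than
#' the element; Gaussian smoothing of the 0/1 raster, re-binarized at 0.5,
#' regularizes the remaining silhouettes.
#'
#' @param mask logical H x W matrix.
#' @param params an [edge_params()] object.
#' @return logical H x W matrix.
#' @export
denoise <- function(mask, params = edge_params()) {
  stopifnot(is.matrix(mask))
  m <- mask + 0
  if (params$erosion_kernel_px > 1)
    m <- EBImage::erode(m, EBImage::makeBrush(params$erosion_kernel_px, "box"))
  g <- EBImage::makeBrush(params$blur_kernel_px, "Gaussian",
                          sigma = params$blur_sigma)
  m <- EBImage::filter2(m, g, boundary = 0)
  matrix(m >= 0.5, nrow = nrow(mask))
}

# 3x3 Sobel gradients with replicate padding; x = along columns, y = rows.
.sobel <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  p <- rbind(x[1, , drop = FALSE], x, x[nr, , drop = FALSE])
  p <- cbind(p[, 1, drop = FALSE], p, p[, nc, drop = FALSE])
  s <- function(dr, dc) p[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  gx <- (s(0, 2) + 2 * s(1, 2) + s(2, 2)) - (s(0, 0) + 2 * s(1, 0) + s(2, 0))
  gy <- (s(2, 0) + 2 * s(2, 1) + s(2, 2)) - (s(0, 0) + 2 * s(0, 1) + s(0, 2))
  list(gx = gx, gy = gy)
}

.shift0 <- function(x, dr, dc) {
  # shift matrix by (dr, dc), zero fill
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- x[rs - dr, cs - dc]
  out
}

# Canny edge detector on a single-channel raster: Sobel gradient,
# 4-sector non-maximum suppression (ties kept, so step edges yield a
# contiguous two-pixel band), hysteresis linking via 8-connectivity.
.canny <- function(x, lo, hi, connectivity = 8) {
  g <- .sobel(x)
  mag <- sqrt(g$gx^2 + g$gy^2)
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- floor(((ang + pi / 8) %% pi) / (pi / 4))  # 0 x, 1 diag, 2 y, 3 anti-diag
  n1 <- matrix(0, nrow(x), ncol(x)); n2 <- n1
  pick <- function(s, dr, dc) {
    w <- sector == s
    n1[w] <<- .shift0(mag, dr, dc)[w]
    n2[w] <<- .shift0(mag, -dr, -dc)[w]
  }
  pick(0, 0, 1); pick(1, 1, 1); pick(2, 1, 0); pick(3, 1, -1)
  ridge <- mag >= n1 & mag >= n2
  weak <- ridge & mag >= lo
  strong <- ridge & mag >= hi
  if (!any(strong)) return(matrix(FALSE, nrow(x), ncol(x)))
  lab <- .label_components(weak, connectivity = 8)
  keep <- unique(lab[strong])
  matrix(lab %in% keep[keep > 0], nrow(x))
}

# Connected-component labeling with 4- or 8-connectivity. EBImage's
# bwlabel is 4-connected; 8-connectivity is obtained by merging labels
# that touch diagonally (union-find over the label adjacency graph).
.label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(mask + 0)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  if (connectivity == 4) return(lab)
  L <- max(lab)
  if (L <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  sel <- a > 0 & b > 0 & a != b
  p1 <- cbind(a[sel], b[sel])
  a <- lab[-1, -nc]; b <- lab[-nr, -1]
  sel <- a > 0 & b > 0 & a != b
  pairs <- unique(rbind(p1, cbind(a[sel], b[sel])))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(L), find, 0L)
  map <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Canny edge map with dilation
#'
#' Canny edge detection on the 0/255 mask raster delineates object
#' boundaries; dilation with a square element strengthens edge continuity
#' so each outline stays a single connected curve.
#'
#' @param mask logical H x W matrix (typically the [denoise()] output).
#' @param params an [edge_params()] object.
#' @return logical H x W boundary map.
#' @export
edge_map <- function(mask, params = edge_params()) {
  stopifnot(is.matrix(mask))
  e <- .canny(mask * 255, params$canny_lo, params$canny_hi)
  if (params$dilation_kernel_px > 1)
    e <- EBImage::dilate(e + 0,
                         EBImage::makeBrush(params$dilation_kernel_px, "box")) > 0
  matrix(e, nrow = nrow(mask))
}

#' Count connected regions of a binary raster
#'
#' If `fill_holes` is set, interior holes (background not reachable from
#' the image border) are filled first, so a closed outline counts as one
#' region; components smaller than `min_area_px` are discarded.
#'
#' @param mask logical H x W matrix (edge map or segmentation mask).
#' @param params an [edge_params()] object.
#' @return integer count of surviving components.
#' @export
count_regions <- function(mask, params = edge_params()) {
  stopifnot(is.matrix(mask))
  m <- mask + 0
  if (params$fill_holes) m <- EBImage::fillHull(m)
  lab <- .label_components(m > 0, connectivity = params$connectivity)
  if (max(lab) == 0) return(0L)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  sum(areas >= max(1L, params$min_area_px))
}

#' Edge-based tiller counting
#'
#' The full classical baseline: hue thresholding, erosion + Gaussian
#' smoothing, Canny edge detection with dilation, hole filling and
#' connected-component counting. A pure function of `(image, params)`.
#'
#' On well-separated instances the count is exact; overlapping instances
#' merge into single regions, so crowded scenes are systematically
#' undercounted - the central failure mode this baseline is used to expose.
#'
#' @param image H x W x 3 numeric RGB array (0-255), e.g. a
#'   `tiller_scene$image` or a raster read from file.
#' @param params an [edge_params()] object; use `edge_params(scale =)` to
#'   match a scene generated at reduced scale.
#' @return integer predicted tiller count.
#' @examples
#' sc <- render_scene(scene_params(count = 4, scale = 0.15, debris_rate = 0,
#'                                 seed = 11))
#' count_tillers(sc$image, edge_params(scale = 0.15))
#' @export
count_tillers <- function(image, params = edge_params()) {
  .check_rgb(image)
  m <- hue_mask(image, params)
  m <- denoise(m, params)
  e <- edge_map(m, params)
  count_regions(e, params)
}

#' Intermediate rasters of the edge pipeline
#'
#' Returns the hue mask, denoised mask and dilated edge map alongside the
#' final count; useful for debugging and for writing panel figures.
#'
#' @inheritParams count_tillers
#' @return list with `mask`, `denoised`, `edges`, `count`.
#' @export
edge_pipeline_stages <- function(image, params = edge_params()) {
  .check_rgb(image)
  m <- hue_mask(image, params)
  d <- denoise(m, params)
  e <- edge_map(d, params)
  list(mask = m, denoised = d, edges = e, count = count_regions(e, params))
}
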