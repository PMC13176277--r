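#' Annotated image records
#'
#' The common currency of the annotation readers/writers: a list with
#' `image_path`, `width`, `height`, `boxes` (data frame `x_min`, `y_min`,
#' `x_max`, `y_max`, `is_tiller`) and a non-empty `sample_id` (the sample
#' barcode).
#'
#' @param scene a `tiller_scene`.
#' @param sample_id sample barcode string.
#' @param image_path path the image is (or will be) stored at.
#' @return an `annotated_record` list.
#' @export
as_annotated_record <- function(scene, sample_id, image_path = paste0(sample_id, ".png")) {
  stopifnot(nzchar(sample_id))
  d <- dim(scene$image)
  structure(list(image_path = image_path, width = d[2], height = d[1],
                 boxes = scene$instances, sample_id = sample_id),
            class = "annotated_record")
}

.check_record <- function(r) {
  stopifnot(!is.null(r$width), !is.null(r$height), r$width > 0, r$height > 0,
            nzchar(r$sample_id))
  b <- r$boxes
  if (nrow(b)) {
    .check_boxes(b)
    if (any(b$x_min < 0 | b$y_min < 0 | b$x_max > r$width | b$y_max > r$height))
      stop("box outside image bounds in record '", r$sample_id, "'")
  }
  invisible(r)
}

#' Read a LabelMe annotation file
#'
#' Reads rectangle shapes from LabelMe JSON. Rectangle corners may be
#' stored in any order; they are normalized to (min, max) corners on read.
#' Non-rectangle shapes are rejected with an error.
#'
#' @param path path to a LabelMe `.json` file.
#' @param sample_id sample barcode; defaults to the image file name without
#'   extension.
#' @return an `annotated_record`.
#' @export
read_labelme <- function(path, sample_id = NULL) {
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("malformed LabelMe JSON at '", path,
                                         "': ", conditionMessage(e)))
  if (is.null(j$imageWidth) || is.null(j$imageHeight))
    stop("LabelMe file lacks imageWidth/imageHeight: '", path, "'")
  shapes <- j$shapes
  boxes <- data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      is_tiller = logical(0))
  for (s in shapes) {
    if (!identical(s$shape_type, "rectangle"))
      stop("unsupported shape type '", s$shape_type,
           "' in '", path, "': only rectangles are read")
    p <- s$points
    if (length(p) != 2) stop("rectangle must have exactly two corner points")
    xs <- c(p[[1]][[1]], p[[2]][[1]]); ys <- c(p[[1]][[2]], p[[2]][[2]])
    boxes <- rbind(boxes, data.frame(
      x_min = min(xs), y_min = min(ys), x_max = max(xs), y_max = max(ys),
      is_tiller = !identical(s$label, "debris")))
  }
  ip <- if (is.null(j$imagePath)) "" else j$imagePath
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(if (nzchar(ip)) ip else path))
  r <- structure(list(image_path = ip, width = j$imageWidth,
                      height = j$imageHeight, boxes = boxes,
                      sample_id = sample_id),
                 class = "annotated_record")
  .check_record(r)
  r
}

#' Write a LabelMe annotation file
#'
#' Inverse of [read_labelme()]: `write_labelme(read_labelme(p), q)` then
#' `read_labelme(q)` preserves all boxes and image metadata.
#'
#' @param record an `annotated_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(record, path) {
  .check_record(record)
  b <- record$boxes
  shapes <- lapply(seq_len(nrow(b)), function(i) list(
    label = if (b$is_tiller[i]) "tiller" else "debris",
    points = list(list(b$x_min[i], b$y_min[i]), list(b$x_max[i], b$y_max[i])),
    group_id = NULL, shape_type = "rectangle", flags = stats::setNames(list(), character(0))))
  jsonlite::write_json(
    list(version = "5.0.1", flags = stats::setNames(list(), character(0)),
         shapes = shapes, imagePath = record$image_path,
         imageData = NULL, imageHeight = record$height,
         imageWidth = record$width),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Write YOLO text annotations
#'
#' One line per box: `class cx cy w h`, center/size normalized to `[0, 1]`
#' by the image dimensions. Class indices are 0 = tiller, 1 = debris.
#'
#' @param record an `annotated_record`.
#' @param path output `.txt` path.
#' @return `path`, invisibly.
#' @export
write_yolo <- function(record, path) {
  .check_record(record)
  if (record$width == 0 || record$height == 0) stop("zero image dimensions")
  b <- record$boxes
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   ifelse(b$is_tiller, 0L, 1L),
                   (b$x_min + b$x_max) / 2 / record$width,
                   (b$y_min + b$y_max) / 2 / record$height,
                   (b$x_max - b$x_min) / record$width,
                   (b$y_max - b$y_min) / record$height)
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO text annotations back into corner boxes
#'
#' @param path a YOLO `.txt` file.
#' @param width,height pixel dimensions of the corresponding image.
#' @param sample_id sample barcode; defaults to the file name.
#' @return an `annotated_record`; corners are recovered to within the
#'   format's quantization (0.5 px at 6 decimals for ordinary image sizes).
#' @export
read_yolo <- function(path, width, height, sample_id = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  v <- if (length(lines)) do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
       else matrix(numeric(0), 0, 5)
  boxes <- data.frame(
    x_min = (v[, 2] - v[, 4] / 2) * width,
    y_min = (v[, 3] - v[, 5] / 2) * height,
    x_max = (v[, 2] + v[, 4] / 2) * width,
    y_max = (v[, 3] + v[, 5] / 2) * height,
    is_tiller = v[, 1] == 0)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(image_path = "", width = width, height = height,
                 boxes = boxes, sample_id = sample_id),
            class = "annotated_record")
}

#' Write COCO instance annotations
#'
#' COCO boxes are `[x_min, y_min, width, height]` in pixels; category ids
#' start at 1 (1 = tiller, 2 = debris when present).
#'
#' @param records list of `annotated_record`s.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(records, path) {
  lapply(records, .check_record)
  images <- lapply(seq_along(records), function(i) list(
    id = i, file_name = records[[i]]$image_path,
    width = records[[i]]$width, height = records[[i]]$height,
    sample_id = records[[i]]$sample_id))
  anns <- list(); aid <- 0L; any_debris <- FALSE
  for (i in seq_along(records)) {
    b <- records[[i]]$boxes
    for (k in seq_len(nrow(b))) {
      aid <- aid + 1L
      any_debris <- any_debris || !b$is_tiller[k]
      anns[[aid]] <- list(
        id = aid, image_id = i,
        category_id = if (b$is_tiller[k]) 1L else 2L,
        bbox = c(b$x_min[k], b$y_min[k],
                 b$x_max[k] - b$x_min[k], b$y_max[k] - b$y_min[k]),
        area = (b$x_max[k] - b$x_min[k]) * (b$y_max[k] - b$y_min[k]),
        iscrowd = 0L)
    }
  }
  cats <- list(list(id = 1L, name = "tiller"))
  if (any_debris) cats <- c(cats, list(list(id = 2L, name = "debris")))
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO instance annotation file
#'
#' @param path a COCO `.json` file written by [write_coco()] or compatible.
#' @return list of `annotated_record`s, one per image.
#' @export
read_coco <- function(path) {
  j <- jsonlite::read_json(path)
  recs <- lapply(j$images, function(im) {
    boxes <- data.frame(x_min = numeric(0), y_min = numeric(0),
                        x_max = numeric(0), y_max = numeric(0),
                        is_tiller = logical(0))
    for (a in j$annotations) if (a$image_id == im$id) {
      bb <- as.numeric(unlist(a$bbox))
      boxes <- rbind(boxes, data.frame(
        x_min = bb[1], y_min = bb[2], x_max = bb[1] + bb[3],
        y_max = bb[2] + bb[4], is_tiller = a$category_id == 1))
    }
    sid <- if (!is.null(im$sample_id)) im$sample_id
           else sub("\\.[^.]*$", "", basename(im$file_name))
    structure(list(image_path = im$file_name, width = im$width,
                   height = im$height, boxes = boxes, sample_id = sid),
              class = "annotated_record")
  })
  recs
}

#' Read/write COCO detection results
#'
#' COCO results files are arrays of `{image_id, bbox [x, y, w, h], score,
#' category_id}`; this pair converts between that encoding and the
#' package's corner-box detection tables.
#'
#' @param dets detection data frame (see [detections()]); `source_id` is
#'   used as the COCO `image_id`.
#' @param path a `.json` path.
#' @return `read_coco_detections` returns a detection data frame.
#' @export
write_coco_detections <- function(dets, path) {
  .check_boxes(dets)
  out <- lapply(seq_len(nrow(dets)), function(i) list(
    image_id = dets$source_id[i],
    bbox = c(dets$x_min[i], dets$y_min[i],
             dets$x_max[i] - dets$x_min[i], dets$y_max[i] - dets$y_min[i]),
    score = dets$score[i], category_id = 1L))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco_detections
#' @export
read_coco_detections <- function(path) {
  j <- jsonlite::read_json(path)
  if (length(j) == 0)
    return(detections(numeric(0), numeric(0), numeric(0), numeric(0),
                      numeric(0), character(0)))
  bb <- do.call(rbind, lapply(j, function(a) as.numeric(unlist(a$bbox))))
  detections(bb[, 1], bb[, 2], bb[, 1] + bb[, 3], bb[, 2] + bb[, 4],
             score = vapply(j, function(a) as.numeric(a$score), 0),
             source_id = vapply(j, function(a) as.character(a$image_id), ""))
}

#' Stratified dataset split
#'
#' Assigns samples to train/validation/test subsets within each stratum by
#' shuffling and largest-remainder apportionment, so realized per-stratum
#' subset sizes deviate from the targets by less than one sample.
#'
#' @param sample_ids character vector of sample barcodes.
#' @param strata optional factor of the same length (e.g. density regimes);
#'   `NULL` treats all samples as one stratum.
#' @param fractions named numeric, must sum to 1.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return data frame `sample_id`, `stratum`, `subset`.
#' @examples
#' split_dataset(sprintf("s%02d", 1:40), seed = 1)
#' @export
split_dataset <- function(sample_ids, strata = NULL,
                          fractions = c(train = 0.85, val = 0.075, test = 0.075),
                          seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  if (is.null(strata)) strata <- rep("all", length(sample_ids))
  stopifnot(length(strata) == length(sample_ids))
  subsets <- names(fractions)
  set.seed(seed)
  out <- data.frame(sample_id = character(0), stratum = character(0),
                    subset = character(0))
  for (s in unique(as.character(strata))) {
    ids <- sample(sample_ids[as.character(strata) == s])
    n <- length(ids)
    if (n < sum(fractions > 0))
      warning("stratum '", s, "' has fewer records (", n,
              ") than nonzero splits; assignment is degenerate")
    ideal <- n * fractions
    base <- floor(ideal)
    rem <- ideal - base
    extra <- n - sum(base)
    if (extra > 0) {
      give <- order(-rem)[seq_len(extra)]
      base[give] <- base[give] + 1
    }
    assign <- rep(subsets, times = base)
    out <- rbind(out, data.frame(sample_id = ids, stratum = s,
                                 subset = assign))
  }
  rownames(out) <- NULL
  out
}

#' Read/write predicted-vs-manual count tables
#'
#' Plain CSV with the fixed header
#' `sample_id,predicted_count,manual_count,method`.
#'
#' @param records data frame with those four columns (see [count_records()]).
#' @param path a `.csv` path.
#' @return `read_counts` returns the count data frame.
#' @export
write_counts <- function(records, path) {
  stopifnot(all(c("sample_id", "predicted_count", "manual_count", "method")
                %in% names(records)))
  utils::write.csv(records[, c("sample_id", "predicted_count",
                               "manual_count", "method")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "predicted_count", "manual_count", "method")
                %in% names(x)))
  count_records(x$sample_id, x$predicted_count, x$manual_count, x$method)
}

#' Write a scene to disk as image plus annotations
#'
#' Writes the rendered image as PNG (requires the `png` package) together
#' with YOLO and LabelMe annotation files sharing the same stem.
#'
#' @param scene a `tiller_scene`.
#' @param stem output path without extension.
#' @return the image path, invisibly.
#' @export
write_scene <- function(scene, stem) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("writing PNG scenes requires the 'png' package")
  img_path <- paste0(stem, ".png")
  png::writePNG(scene$image / 255, img_path)
  rec <- as_annotated_record(scene, sample_id = basename(stem),
                             image_path = basename(img_path))
  write_labelme(rec, paste0(stem, ".json"))
  write_yolo(rec, paste0(stem, ".txt"))
  invisible(img_path)
}
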