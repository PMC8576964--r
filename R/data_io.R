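#' Annotation formats, resizing and augmentation
#'
#' A COCO dataset is held in memory as three data frames:
#' `images` (`id, file_name, width, height`), `annotations`
#' (`id, image_id, x, y, w, h, area, category_id` — bbox in COCO `xywh`) and
#' `categories` (`id, name, supercategory`). Category ids are the 1-based
#' counterparts of the package's 0-based class ids.
#'
#' @name data_io
NULL

#' An empty COCO dataset with the fixed 7-category table
#' @return A `coco_dataset` list (`images`, `annotations`, `categories`).
#' @export
coco_empty <- function() {
  ds <- list(
    images = data.frame(id = integer(), file_name = character(),
                        width = integer(), height = integer()),
    annotations = data.frame(id = integer(), image_id = integer(),
                             x = numeric(), y = numeric(),
                             w = numeric(), h = numeric(),
                             area = numeric(), category_id = integer()),
    categories = data.frame(id = seq_len(n_wbc_classes()),
                            name = wbc_classes(),
                            supercategory = "cell"))
  class(ds) <- "coco_dataset"
  ds
}

#' @export
print.coco_dataset <- function(x, ...) {
  cat(sprintf("COCO dataset: %d images, %d annotations, %d categories\n",
              nrow(x$images), nrow(x$annotations), nrow(x$categories)))
  if (nrow(x$annotations)) {
    tab <- table(factor(x$categories$name[x$annotations$category_id],
                        levels = x$categories$name))
    for (nm in names(tab)) cat(sprintf("  %-14s %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

validate_coco <- function(ds) {
  stopifnot(inherits(ds, "coco_dataset"))
  a <- ds$annotations
  if (nrow(a)) {
    stopifnot(all(a$image_id %in% ds$images$id),
              all(a$category_id %in% ds$categories$id),
              all(a$w > 0), all(a$h > 0))
  }
  invisible(TRUE)
}

#' Write a COCO dataset to JSON
#' @param ds A `coco_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(ds, path) {
  validate_coco(ds)
  img <- ds$images; ann <- ds$annotations
  obj <- list(
    images = lapply(seq_len(nrow(img)), function(i) list(
      id = img$id[i], file_name = img$file_name[i],
      width = img$width[i], height = img$height[i])),
    annotations = lapply(seq_len(nrow(ann)), function(i) list(
      id = ann$id[i], image_id = ann$image_id[i],
      bbox = c(ann$x[i], ann$y[i], ann$w[i], ann$h[i]),
      area = ann$area[i], category_id = ann$category_id[i], iscrowd = 0L)),
    categories = lapply(seq_len(nrow(ds$categories)), function(i) list(
      id = ds$categories$id[i], name = ds$categories$name[i],
      supercategory = ds$categories$supercategory[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO annotation JSON
#' @param path COCO JSON file.
#' @return A `coco_dataset`.
#' @export
read_coco <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ds <- coco_empty()
  if (!is.null(j$categories) && NROW(j$categories)) {
    ds$categories <- data.frame(id = as.integer(j$categories$id),
                                name = as.character(j$categories$name),
                                supercategory = if (is.null(j$categories$supercategory))
                                  "cell" else as.character(j$categories$supercategory))
  }
  if (!is.null(j$images) && NROW(j$images)) {
    ds$images <- data.frame(id = as.integer(j$images$id),
                            file_name = as.character(j$images$file_name),
                            width = as.integer(j$images$width),
                            height = as.integer(j$images$height))
  }
  if (!is.null(j$annotations) && NROW(j$annotations)) {
    bb <- do.call(rbind, j$annotations$bbox)
    ds$annotations <- data.frame(
      id = as.integer(j$annotations$id),
      image_id = as.integer(j$annotations$image_id),
      x = bb[, 1L], y = bb[, 2L], w = bb[, 3L], h = bb[, 4L],
      area = if (is.null(j$annotations$area)) bb[, 3L] * bb[, 4L]
             else as.numeric(j$annotations$area),
      category_id = as.integer(j$annotations$category_id))
  }
  validate_coco(ds)
  ds
}

#' Write detections as a COCO results JSON
#' @param dets Detection data frame with `image_id` column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coco_results <- function(dets, path) {
  obj <- lapply(seq_len(nrow(dets)), function(i) list(
    image_id = dets$image_id[i],
    category_id = dets$class_id[i] + 1L,
    bbox = c(dets$x1[i], dets$y1[i],
             dets$x2[i] - dets$x1[i], dets$y2[i] - dets$y1[i]),
    score = dets$score[i]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO results JSON into a detection data frame
#' @param path COCO results file.
#' @return Detection data frame (`x1,y1,x2,y2,class_id,score,image_id`).
#' @export
read_coco_results <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!NROW(j)) return(detections(image_id = integer()))
  bb <- do.call(rbind, j$bbox)
  detections(boxes(bb[, 1L], bb[, 2L], bb[, 1L] + bb[, 3L], bb[, 2L] + bb[, 4L]),
             class_id = j$category_id - 1L, score = j$score,
             image_id = j$image_id)
}

#' Convert a VGG Image Annotator (VIA) project to a COCO dataset
#'
#' Rectangle regions pass through; polygon regions are replaced by their
#' tight bounding rectangle. The region class is read from
#' `region_attributes[[class_attribute]]`; names outside the fixed 7-class
#' table map to `"Others"` with a warning. Image and annotation ids are
#' assigned deterministically in file order, then region order.
#'
#' @param via Path to a VIA project JSON, or the parsed list.
#' @param class_attribute Name of the region attribute holding the class.
#' @param default_size Fallback `c(width, height)` recorded for images whose
#'   size VIA did not store (VIA project files carry no pixel dimensions).
#' @return A `coco_dataset`.
#' @export
via_to_coco <- function(via, class_attribute = "class",
                        default_size = c(NA_integer_, NA_integer_)) {
  if (is.character(via)) {
    if (!file.exists(via)) stop("no such file: ", via, call. = FALSE)
    via <- jsonlite::fromJSON(via, simplifyVector = FALSE)
  }
  files <- if (!is.null(via[["_via_img_metadata"]])) via[["_via_img_metadata"]] else via
  ds <- coco_empty()
  cls_names <- wbc_classes()
  imgs <- list(); anns <- list(); ann_id <- 0L
  keys <- names(files)
  for (fi in seq_along(keys)) {
    entry <- files[[keys[fi]]]
    if (is.null(entry$filename)) next
    imgs[[length(imgs) + 1L]] <- data.frame(
      id = fi, file_name = entry$filename,
      width = as.integer(default_size[1L]), height = as.integer(default_size[2L]))
    regions <- entry$regions
    if (is.null(regions)) regions <- list()
    for (ri in seq_along(regions)) {
      r <- regions[[ri]]
      sa <- r$shape_attributes
      if (is.null(sa)) {
        stop(sprintf("VIA region without shape_attributes (file %s, region %d)",
                     entry$filename, ri), call. = FALSE)
      }
      cls <- r$region_attributes[[class_attribute]]
      if (is.null(cls)) {
        stop(sprintf("VIA region without a '%s' attribute (file %s, region %d)",
                     class_attribute, entry$filename, ri), call. = FALSE)
      }
      if (!cls %in% cls_names) {
        warning(sprintf("unknown class '%s' mapped to 'Others' (file %s, region %d)",
                        cls, entry$filename, ri), call. = FALSE)
        cls <- "Others"
      }
      if (identical(sa$name, "rect")) {
        bb <- c(sa$x, sa$y, sa$width, sa$height)
      } else if (identical(sa$name, "polygon")) {
        px <- unlist(sa$all_points_x); py <- unlist(sa$all_points_y)
        bb <- c(min(px), min(py), max(px) - min(px), max(py) - min(py))
      } else {
        stop(sprintf("unsupported VIA region shape '%s' (file %s, region %d)",
                     sa$name, entry$filename, ri), call. = FALSE)
      }
      if (bb[3L] <= 0 || bb[4L] <= 0) {
        stop(sprintf("degenerate VIA region (file %s, region %d)",
                     entry$filename, ri), call. = FALSE)
      }
      ann_id <- ann_id + 1L
      anns[[ann_id]] <- data.frame(
        id = ann_id, image_id = fi,
        x = bb[1L], y = bb[2L], w = bb[3L], h = bb[4L],
        area = bb[3L] * bb[4L],
        category_id = match(cls, cls_names))
    }
  }
  if (length(imgs)) ds$images <- do.call(rbind, imgs)
  if (length(anns)) ds$annotations <- do.call(rbind, anns)
  ds
}

#' Resize an image so its short edge matches a target, carrying boxes along
#'
#' One isotropic scale `s = target_short_edge / min(W, H)` is applied to both
#' axes (the long edge is reduced by the same ratio, preserving aspect), and
#' to every box coordinate exactly. Output dimensions are rounded to the
#' nearest integer. `mode = "square"` instead forces both edges to the
#' target with anisotropic scales.
#'
#' @param img `H x W x 3` numeric array (values in `[0, 1]`) or `NULL` to
#'   transform boxes only.
#' @param b Box data frame (may be empty).
#' @param target_short_edge Target size in pixels.
#' @param mode `"short_edge"` (default, aspect-preserving) or `"square"`.
#' @param size `c(height, width)` of the source; required when `img` is `NULL`.
#' @return List with `image` (or `NULL`), `boxes`, `scale` (`c(sx, sy)`) and
#'   `size` (`c(height, width)` of the output).
#' @export
resize_with_boxes <- function(img, b = boxes(), target_short_edge = 800,
                              mode = c("short_edge", "square"), size = NULL) {
  mode <- match.arg(mode)
  stopifnot(target_short_edge > 0)
  if (is.null(size)) size <- dim(img)[1:2]
  h <- size[1L]; w <- size[2L]
  if (mode == "short_edge") {
    s <- target_short_edge / min(w, h)
    sx <- s; sy <- s
  } else {
    sx <- target_short_edge / w; sy <- target_short_edge / h
  }
  out_h <- as.integer(round(h * sy)); out_w <- as.integer(round(w * sx))
  out_img <- NULL
  if (!is.null(img)) {
    # EBImage stores (first dim, second dim) = (our rows, our cols)
    out_img <- EBImage::imageData(EBImage::resize(
      EBImage::Image(img, colormode = "Color"), w = out_h, h = out_w))
    dim(out_img) <- c(out_h, out_w, dim(img)[3L])
  }
  nb <- boxes(b$x1 * sx, b$y1 * sy, b$x2 * sx, b$y2 * sy)
  list(image = out_img, boxes = nb, scale = c(sx = sx, sy = sy),
       size = c(height = out_h, width = out_w))
}

flip_image_px <- function(img, direction) {
  switch(direction,
         horizontal = img[, rev(seq_len(dim(img)[2L])), , drop = FALSE],
         vertical   = img[rev(seq_len(dim(img)[1L])), , , drop = FALSE],
         stop("direction must be 'horizontal' or 'vertical'", call. = FALSE))
}

#' Double a dataset by mirroring every image
#'
#' Appends a mirrored copy of each image and its annotations: for a
#' horizontal flip, each bbox becomes `x' = W - x - w` with `y` unchanged.
#' The output therefore has exactly twice the images and annotations, with
#' every per-class count doubled (augmentation keeps the class balance).
#' With `direction = "both"` the horizontal and vertical mirrors are both
#' appended (tripling the dataset).
#'
#' @param ds A `coco_dataset`.
#' @param direction `"horizontal"` (default), `"vertical"` or `"both"`.
#' @param image_dir,out_dir When both given, mirrored pixel files are written
#'   to `out_dir` (originals are read from `image_dir`); otherwise only the
#'   annotation tables are transformed.
#' @return The augmented `coco_dataset`.
#' @export
flip_augment <- function(ds, direction = c("horizontal", "vertical", "both"),
                         image_dir = NULL, out_dir = NULL) {
  direction <- match.arg(direction)
  validate_coco(ds)
  dirs <- if (direction == "both") c("horizontal", "vertical") else direction
  out <- ds
  next_img_id <- if (nrow(ds$images)) max(ds$images$id) else 0L
  next_ann_id <- if (nrow(ds$annotations)) max(ds$annotations$id) else 0L
  for (d in dirs) {
    imgs <- ds$images
    anns <- ds$annotations
    if (!nrow(imgs)) next
    id_map <- stats::setNames(next_img_id + seq_len(nrow(imgs)), imgs$id)
    prefix <- if (d == "horizontal") "fliph_" else "flipv_"
    new_imgs <- imgs
    new_imgs$id <- as.integer(id_map[as.character(imgs$id)])
    new_imgs$file_name <- paste0(prefix, imgs$file_name)
    new_anns <- anns
    if (nrow(anns)) {
      new_anns$id <- next_ann_id + seq_len(nrow(anns))
      new_anns$image_id <- as.integer(id_map[as.character(anns$image_id)])
      if (d == "horizontal") {
        W <- imgs$width[match(anns$image_id, imgs$id)]
        new_anns$x <- W - anns$x - anns$w
      } else {
        H <- imgs$height[match(anns$image_id, imgs$id)]
        new_anns$y <- H - anns$y - anns$h
      }
    }
    if (!is.null(image_dir) && !is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_len(nrow(imgs))) {
        src <- file.path(image_dir, imgs$file_name[i])
        if (!file.exists(src)) stop("missing image file: ", src, call. = FALSE)
        px <- png::readPNG(src)
        png::writePNG(flip_image_px(px, d),
                      file.path(out_dir, new_imgs$file_name[i]))
      }
    }
    out$images <- rbind(out$images, new_imgs)
    out$annotations <- rbind(out$annotations, new_anns)
    next_img_id <- max(out$images$id)
    next_ann_id <- if (nrow(out$annotations)) max(out$annotations$id) else 0L
  }
  rownames(out$images) <- rownames(out$annotations) <- NULL
  out
}

#' Rotate and shear an image about its center, carrying boxes along
#'
#' Training-time augmentation. The pixel warp is the affine map
#' `p' = c + S R (p - c)` with rotation `R` by `angle` degrees and shear
#' `S = [[1, shear], [0, 1]]` about the image center `c`; pixels are
#' bilinearly resampled on the same-size canvas (out-of-source pixels take
#' the `fill` value). Each box is replaced by the tight axis-aligned extent
#' of its four warped corners, clipped to the canvas; boxes falling entirely
#' outside are dropped (with their class labels).
#'
#' @param img `H x W x 3` array in `[0, 1]`, or `NULL` for boxes only.
#' @param b Box data frame.
#' @param angle Rotation in degrees (positive rotates image content
#'   clockwise on screen).
#' @param shear Shear coefficient (x displaced by `shear * y`).
#' @param class_id Optional class ids travelling with the boxes.
#' @param fill Fill value for pixels mapped from outside the source.
#' @param size `c(height, width)`; required when `img` is `NULL`.
#' @return List with `image`, `boxes`, `class_id` (if given) and `kept`
#'   (indices of surviving input boxes).
#' @export
rotate_shear_augment <- function(img, b = boxes(), angle = 0, shear = 0,
                                 class_id = NULL, fill = 0, size = NULL) {
  if (is.null(size)) size <- dim(img)[1:2]
  h <- size[1L]; w <- size[2L]
  th <- angle * pi / 180
  R <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  S <- rbind(c(1, shear), c(0, 1))
  A <- S %*% R
  cen <- c(w / 2, h / 2)
  out_img <- NULL
  if (!is.null(img)) {
    if (abs(angle) < 1e-12 && abs(shear) < 1e-12) {
      out_img <- img
    } else {
      # EBImage works in (first-dim, second-dim) coords; our map acts on
      # (x = col, y = row), so conjugate A with the axis swap.
      Aeb <- A[2:1, 2:1]
      off <- rev(cen) - Aeb %*% rev(cen)
      m <- rbind(t(Aeb), as.numeric(off))
      eb <- EBImage::affine(EBImage::Image(img, colormode = "Color"), m,
                            filter = "bilinear", bg.col = fill)
      out_img <- EBImage::imageData(eb)
      dim(out_img) <- dim(img)
    }
  }
  kept <- integer(); nb <- boxes()
  if (nrow(b)) {
    corners_x <- cbind(b$x1, b$x2, b$x1, b$x2)
    corners_y <- cbind(b$y1, b$y1, b$y2, b$y2)
    wx <- A[1L, 1L] * (corners_x - cen[1L]) + A[1L, 2L] * (corners_y - cen[2L]) + cen[1L]
    wy <- A[2L, 1L] * (corners_x - cen[1L]) + A[2L, 2L] * (corners_y - cen[2L]) + cen[2L]
    raw <- boxes(apply(wx, 1L, min), apply(wy, 1L, min),
                 apply(wx, 1L, max), apply(wy, 1L, max))
    cl <- clip_boxes(raw, w, h)
    kept <- which(!cl$degenerate)
    nb <- cl$boxes[kept, , drop = FALSE]
    rownames(nb) <- NULL
  }
  out <- list(image = out_img, boxes = nb, kept = kept)
  if (!is.null(class_id)) out$class_id <- class_id[kept]
  out
}

#' Split a COCO dataset into train and test partitions at image level
#'
#' Images are partitioned (each image's annotations travel with it);
#' `round(train_fraction * N)` images go to the training split. The split is
#' a deterministic function of `seed`.
#'
#' @param ds A `coco_dataset`.
#' @param train_fraction Fraction in `(0, 1)`.
#' @param seed Integer seed.
#' @return List of two `coco_dataset`s, `train` and `test`.
#' @export
split_dataset <- function(ds, train_fraction = 0.9, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  validate_coco(ds)
  n <- nrow(ds$images)
  take <- local_seed(seed, {
    n_train <- round(train_fraction * n)
    if (n) ds$images$id[sample.int(n, n_train)] else integer()
  })
  subset_ids <- function(ids) {
    part <- ds
    part$images <- ds$images[ds$images$id %in% ids, , drop = FALSE]
    part$annotations <- ds$annotations[ds$annotations$image_id %in% ids, , drop = FALSE]
    rownames(part$images) <- rownames(part$annotations) <- NULL
    part
  }
  list(train = subset_ids(take),
       test = subset_ids(setdiff(ds$images$id, take)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
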