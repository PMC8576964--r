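#' Synthetic bone-marrow-smear images with COCO ground truth
#'
#' A seeded generator that emulates dyed marrow-smear microscopy fields:
#' a smooth illumination gradient over a pale background with pixel noise,
#' and cells rendered as a nucleus ellipse (or lobes) over a cytoplasm
#' ellipse with class-conditional sizes and stain colors. The seven class
#' identities are synthetic conventions chosen to be class-separable by
#' color and size (e.g. the Megakaryocyte draws from the largest axis
#' distribution, the Erythrocyte is a small anuclear pink ellipse); they are
#' not histologically faithful. Ground-truth boxes are the tight axis-aligned
#' extent of each cell's rendered pixel support.
#'
#' @name synthetic_data
NULL

#' Default per-class appearance table
#'
#' One entry per class in [wbc_classes()] order; see [smear_spec()] for the
#' field meanings. Start from this table to customize cell counts, sizes or
#' stain colors.
#'
#' @param size_scale Multiplier applied to every axis distribution.
#' @return Named list of 7 class-appearance lists.
#' @export
default_cell_classes <- function(size_scale = 1) {
  s <- size_scale
  mk <- function(lambda, major, major_sd, ratio, cyto, cyto_sd, nucleus,
                 nuc_scale, nuc_style) {
    list(lambda = lambda, major = major * s, major_sd = major_sd * s,
         ratio = ratio, cyto = cyto, cyto_sd = cyto_sd, nucleus = nucleus,
         nuc_scale = nuc_scale, nuc_style = nuc_style)
  }
  list(
    Granulocyte   = mk(2.5, 40, 6, 0.80, c(0.95, 0.75, 0.78), 0.03,
                       c(0.45, 0.25, 0.55), 0.50, "lobed"),
    Erythrocyte   = mk(3.5, 22, 3, 0.90, c(0.93, 0.60, 0.58), 0.03,
                       NULL, 0, "none"),
    Lymphocyte    = mk(2.0, 34, 5, 0.95, c(0.72, 0.68, 0.90), 0.03,
                       c(0.35, 0.20, 0.50), 0.85, "round"),
    Megakaryocyte = mk(0.6, 130, 15, 0.85, c(0.90, 0.78, 0.85), 0.03,
                       c(0.40, 0.22, 0.50), 0.60, "lobed"),
    `Plasma cell` = mk(1.2, 36, 5, 0.75, c(0.55, 0.55, 0.85), 0.03,
                       c(0.35, 0.20, 0.50), 0.50, "eccentric"),
    Monocyte      = mk(1.2, 44, 6, 0.85, c(0.78, 0.78, 0.88), 0.03,
                       c(0.42, 0.28, 0.55), 0.65, "kidney"),
    Others        = mk(1.0, 30, 8, 0.80, c(0.85, 0.80, 0.70), 0.05,
                       c(0.45, 0.35, 0.45), 0.60, "round"))
}

#' Specify a synthetic smear image distribution
#'
#' @param width,height Canvas size in pixels.
#' @param classes Per-class appearance list; one entry per class in
#'   [wbc_classes()] order, each with `lambda` (Poisson mean cell count),
#'   `major`/`major_sd` (major axis, pixels), `ratio` (minor/major),
#'   `cyto`/`cyto_sd` (cytoplasm RGB mean and jitter), `nucleus` (RGB or
#'   `NULL` for anuclear), `nuc_scale`, `nuc_style` (`"round"`, `"lobed"`,
#'   `"kidney"`, `"eccentric"`, `"none"`). Defaults model a desk-scale
#'   256 x 256 field; `size_scale` shrinks all axis distributions together.
#' @param background Background RGB.
#' @param illumination Illumination-gradient amplitude (fraction of the
#'   dynamic range across the field).
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param max_overlap Maximum allowed pairwise IoU between placed cells
#'   (touching cells are deliberately allowed up to this cap).
#' @param max_tries Placement attempts per cell before a capacity error.
#' @param size_scale Multiplier on every class's axis distribution.
#' @param seed Integer; together with the image id it fully determines the
#'   generated pixels and annotations.
#' @return A `smear_spec` list.
#' @export
smear_spec <- function(width = 256, height = 256,
                       classes = default_cell_classes(size_scale),
                       background = c(0.93, 0.90, 0.92),
                       illumination = 0.10, noise_sd = 0.02,
                       max_overlap = 0.3, max_tries = 80L,
                       size_scale = 1, seed = 1L) {
  stopifnot(width >= 16, height >= 16, length(classes) == n_wbc_classes(),
            illumination >= 0, noise_sd >= 0,
            max_overlap >= 0, max_overlap < 1)
  spec <- list(width = as.integer(width), height = as.integer(height),
               classes = classes, background = background,
               illumination = illumination, noise_sd = noise_sd,
               max_overlap = max_overlap, max_tries = as.integer(max_tries),
               seed = as.integer(seed))
  class(spec) <- "smear_spec"
  spec
}

#' A small-field spec for quick experiments and training fixtures
#'
#' 128 x 128 canvas with axis distributions scaled so every class (including
#' the large Megakaryocyte) still fits, and fewer cells per field.
#'
#' @param ... Overrides passed to [smear_spec()].
#' @return A `smear_spec`.
#' @export
smear_spec_tiny <- function(...) {
  cls <- default_cell_classes(size_scale = 0.45)
  for (nm in names(cls)) cls[[nm]]$lambda <- cls[[nm]]$lambda * 0.55
  smear_spec(width = 128, height = 128, classes = cls, ...)
}

# Tight analytic x/y half-extents of an ellipse with half-axes (a, b)
# rotated by phi.
ellipse_extent <- function(a, b, phi) {
  ex <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
  ey <- sqrt((a * sin(phi))^2 + (b * cos(phi))^2)
  c(ex, ey)
}

# Logical membership of pixel centers in a rotated ellipse, evaluated on a
# window of 1-based pixel indices rows/cols. Pixel (i, j) has center
# (j - 0.5, i - 0.5) in continuous coordinates.
ellipse_mask <- function(rows, cols, cx, cy, a, b, phi) {
  px <- matrix(cols - 0.5, length(rows), length(cols), byrow = TRUE) - cx
  py <- matrix(rows - 0.5, length(rows), length(cols)) - cy
  u <- px * cos(phi) + py * sin(phi)
  v <- -px * sin(phi) + py * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Render one cell into img (H x W x 3); returns list(img, mask window).
render_cell <- function(img, cell, cls_def) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  ext <- ellipse_extent(cell$a, cell$b, cell$phi)
  rows <- max(1L, floor(cell$cy - ext[2L])):min(H, ceiling(cell$cy + ext[2L]))
  cols <- max(1L, floor(cell$cx - ext[1L])):min(W, ceiling(cell$cx + ext[1L]))
  mask <- ellipse_mask(rows, cols, cell$cx, cell$cy, cell$a, cell$b, cell$phi)
  # radial shading makes the rim slightly darker than the body
  px <- matrix(cols - 0.5, length(rows), length(cols), byrow = TRUE) - cell$cx
  py <- matrix(rows - 0.5, length(rows), length(cols)) - cell$cy
  u <- px * cos(cell$phi) + py * sin(cell$phi)
  v <- -px * sin(cell$phi) + py * cos(cell$phi)
  r2 <- (u / cell$a)^2 + (v / cell$b)^2
  shade <- 1 - 0.15 * r2
  for (ch in 1:3) {
    plane <- img[rows, cols, ch]
    plane[mask] <- clamp01(cell$cyto_col[ch] * shade[mask])
    img[rows, cols, ch] <- plane
  }
  nuc <- switch(cls_def$nuc_style,
    none = NULL,
    round = list(list(dx = 0, dy = 0, sa = cls_def$nuc_scale, sb = cls_def$nuc_scale)),
    eccentric = list(list(dx = 0.35, dy = 0, sa = cls_def$nuc_scale,
                          sb = cls_def$nuc_scale)),
    lobed = list(list(dx = -0.28, dy = -0.1, sa = cls_def$nuc_scale * 0.62,
                      sb = cls_def$nuc_scale * 0.7),
                 list(dx = 0.28, dy = 0.12, sa = cls_def$nuc_scale * 0.62,
                      sb = cls_def$nuc_scale * 0.7)),
    kidney = list(list(dx = 0, dy = 0, sa = cls_def$nuc_scale,
                       sb = cls_def$nuc_scale)))
  if (!is.null(nuc)) {
    for (lobe in nuc) {
      ncx <- cell$cx + lobe$dx * cell$a * cos(cell$phi) -
        lobe$dy * cell$b * sin(cell$phi)
      ncy <- cell$cy + lobe$dx * cell$a * sin(cell$phi) +
        lobe$dy * cell$b * cos(cell$phi)
      nmask <- ellipse_mask(rows, cols, ncx, ncy,
                            lobe$sa * cell$a, lobe$sb * cell$b, cell$phi) & mask
      for (ch in 1:3) {
        plane <- img[rows, cols, ch]
        plane[nmask] <- clamp01(cell$nuc_col[ch] * shade[nmask])
        img[rows, cols, ch] <- plane
      }
    }
    if (cls_def$nuc_style == "kidney") {
      # carve the indentation back to cytoplasm color
      bcx <- cell$cx + 0.45 * cell$a * cos(cell$phi)
      bcy <- cell$cy + 0.45 * cell$a * sin(cell$phi)
      bmask <- ellipse_mask(rows, cols, bcx, bcy,
                            0.45 * cell$a, 0.45 * cell$b, cell$phi) & mask
      for (ch in 1:3) {
        plane <- img[rows, cols, ch]
        plane[bmask] <- clamp01(cell$cyto_col[ch] * shade[bmask])
        img[rows, cols, ch] <- plane
      }
    }
  }
  list(img = img, rows = rows, cols = cols, mask = mask)
}

#' Generate one annotated synthetic smear image
#'
#' The background is a smooth illumination gradient plus Gaussian pixel
#' noise; cells are placed by rejection sampling under the pairwise-overlap
#' cap and rendered in placement order. Identical `(spec, image_id)` always
#' produce bit-identical output; the caller's RNG stream is left untouched.
#'
#' @param spec A [smear_spec()].
#' @param image_id Integer id (also seeds this image's randomness).
#' @param return_masks Also return each cell's rendered pixel-support mask
#'   (for verification).
#' @return A list (`annotated_image`) with `image` (`H x W x 3` array in
#'   `[0, 1]`), `boxes`, `class_id` (0-based), `image_id`, and optionally
#'   `masks` (per cell: `rows`, `cols`, logical `mask`).
#' @export
generate_smear_image <- function(spec, image_id = 1L, return_masks = FALSE) {
  stopifnot(inherits(spec, "smear_spec"))
  local_seed((spec$seed * 74093L + as.integer(image_id) * 131L) %% 2147483647L, {
    H <- spec$height; W <- spec$width
    img <- array(rep(spec$background, each = H * W), c(H, W, 3L))
    gdir <- stats::runif(1, 0, 2 * pi)
    gx <- cos(gdir); gy <- sin(gdir)
    xs <- matrix((seq_len(W) - 0.5) / W - 0.5, H, W, byrow = TRUE)
    ys <- matrix((seq_len(H) - 0.5) / H - 0.5, H, W)
    grad <- spec$illumination * (gx * xs + gy * ys)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + grad
    # place cells
    cells <- list(); placed <- boxes()
    cls_names <- wbc_classes()
    for (ci in seq_along(cls_names)) {
      def <- spec$classes[[ci]]
      n_cells <- stats::rpois(1L, def$lambda)
      for (k in seq_len(n_cells)) {
        ok <- FALSE
        for (try in seq_len(spec$max_tries)) {
          a <- max(2, stats::rnorm(1, def$major, def$major_sd)) / 2
          b <- a * def$ratio * stats::runif(1, 0.9, 1.1)
          phi <- stats::runif(1, 0, pi)
          ext <- ellipse_extent(a, b, phi)
          if (2 * ext[1L] >= W - 2 || 2 * ext[2L] >= H - 2) next
          cx <- stats::runif(1, ext[1L] + 1, W - ext[1L] - 1)
          cy <- stats::runif(1, ext[2L] + 1, H - ext[2L] - 1)
          cand <- boxes(cx - ext[1L], cy - ext[2L], cx + ext[1L], cy + ext[2L])
          if (nrow(placed) == 0L ||
              max(box_iou(cand, placed)) <= spec$max_overlap) {
            cyto <- clamp01(def$cyto + stats::rnorm(3, 0, def$cyto_sd))
            nuc <- if (is.null(def$nucleus)) NULL else
              clamp01(def$nucleus + stats::rnorm(3, 0, 0.02))
            cells[[length(cells) + 1L]] <- list(
              cx = cx, cy = cy, a = a, b = b, phi = phi,
              class_id = ci - 1L, cyto_col = cyto, nuc_col = nuc)
            placed <- rbind(placed, cand)
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop(structure(class = c("wbc_capacity_error", "error", "condition"),
                         list(message = sprintf(
                           "cannot place a '%s' cell under the overlap cap %.2f after %d tries",
                           cls_names[ci], spec$max_overlap, spec$max_tries),
                           call = NULL)))
        }
      }
    }
    # render and take ground truth from the rendered pixel support
    gt <- boxes(); class_id <- integer(); masks <- list()
    for (cell in cells) {
      r <- render_cell(img, cell, spec$classes[[cell$class_id + 1L]])
      img <- r$img
      ridx <- range(which(apply(r$mask, 1L, any)))
      cidx <- range(which(apply(r$mask, 2L, any)))
      gt <- rbind(gt, boxes(r$cols[cidx[1L]] - 1, r$rows[ridx[1L]] - 1,
                            r$cols[cidx[2L]], r$rows[ridx[2L]]))
      class_id <- c(class_id, cell$class_id)
      if (return_masks) masks[[length(masks) + 1L]] <-
          list(rows = r$rows, cols = r$cols, mask = r$mask)
    }
    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(H * W * 3L, 0, spec$noise_sd), c(H, W, 3L))
    }
    img <- clamp01(img)
    # 8-bit quantization so files round-trip exactly
    img <- round(img * 255) / 255
    out <- list(image = img, boxes = gt, class_id = class_id,
                image_id = as.integer(image_id))
    if (return_masks) out$masks <- masks
    class(out) <- "annotated_image"
    out
  })
}

#' Generate a synthetic dataset on disk in COCO layout
#'
#' Writes `n_images` PNG files plus one COCO annotation JSON with the fixed
#' 7-category table (background is never a category). At the default spec,
#' 50 or more images populate all three COCO area bins (small, medium,
#' large).
#'
#' @param spec A [smear_spec()].
#' @param n_images Number of images.
#' @param out_dir Output directory (created if needed); `NULL` keeps the
#'   dataset in memory only.
#' @param annotations_file Name of the JSON file inside `out_dir`.
#' @return A `coco_dataset` (invisibly when writing to disk).
#' @export
generate_smear_dataset <- function(spec, n_images, out_dir = NULL,
                                   annotations_file = "annotations.json") {
  stopifnot(n_images >= 0)
  ds <- coco_empty()
  write_px <- !is.null(out_dir)
  if (write_px) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  imgs <- list(); anns <- list(); ann_id <- 0L
  for (i in seq_len(n_images)) {
    ai <- generate_smear_image(spec, image_id = i)
    fn <- sprintf("img_%05d.png", i)
    imgs[[i]] <- data.frame(id = i, file_name = fn,
                            width = spec$width, height = spec$height)
    if (nrow(ai$boxes)) {
      b <- ai$boxes
      anns[[length(anns) + 1L]] <- data.frame(
        id = ann_id + seq_len(nrow(b)), image_id = i,
        x = b$x1, y = b$y1, w = b$x2 - b$x1, h = b$y2 - b$y1,
        area = (b$x2 - b$x1) * (b$y2 - b$y1),
        category_id = ai$class_id + 1L)
      ann_id <- ann_id + nrow(b)
    }
    if (write_px) png::writePNG(ai$image, file.path(out_dir, fn))
  }
  if (length(imgs)) ds$images <- do.call(rbind, imgs)
  if (length(anns)) ds$annotations <- do.call(rbind, anns)
  if (write_px) {
    write_coco(ds, file.path(out_dir, annotations_file))
    return(invisible(ds))
  }
  ds
}
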