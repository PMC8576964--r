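#' RoIAlign head: classification, box refinement, counting
#'
#' Regions of interest are cut from the pyramid without any coordinate
#' quantization (RoIAlign): the box is mapped to feature coordinates by
#' `1/stride`, each output cell averages a small grid of bilinear samples,
#' and the patch feeds a two-hidden-layer network with an 8-way softmax
#' (seven cell classes plus background) and one box-delta set per
#' foreground class. Post-processing applies the confidence threshold,
#' multi-class (class-aware) NMS and clipping; counting tallies the
#' surviving detections per class and image.
#'
#' @name detection_head
NULL

# Bilinear sample of `feature` (Hf x Wf x C) at continuous points (y, x)
# with values located at integer grid coordinates 0..Hf-1 (corner-aligned).
# Returns (n x C) values plus the gather indices/weights for backprop.
bilinear_gather <- function(feature, ys, xs) {
  Hf <- dim(feature)[1L]; Wf <- dim(feature)[2L]; C <- dim(feature)[3L]
  ys <- pmin(pmax(ys, 0), Hf - 1L)
  xs <- pmin(pmax(xs, 0), Wf - 1L)
  y0 <- pmin(floor(ys), Hf - 2L); y0 <- pmax(y0, 0)
  x0 <- pmin(floor(xs), Wf - 2L); x0 <- pmax(x0, 0)
  wy <- ys - y0; wx <- xs - x0
  fm <- matrix(feature, Hf * Wf, C)
  i00 <- (y0 + 1L) + x0 * Hf
  i10 <- i00 + 1L
  i01 <- i00 + Hf
  i11 <- i01 + 1L
  w00 <- (1 - wy) * (1 - wx); w10 <- wy * (1 - wx)
  w01 <- (1 - wy) * wx;       w11 <- wy * wx
  vals <- fm[i00, , drop = FALSE] * w00 + fm[i10, , drop = FALSE] * w10 +
          fm[i01, , drop = FALSE] * w01 + fm[i11, , drop = FALSE] * w11
  list(vals = vals,
       idx = cbind(i00, i10, i01, i11), w = cbind(w00, w10, w01, w11),
       Hf = Hf, Wf = Wf, C = C)
}

bilinear_scatter <- function(cache, dvals) {
  dfm <- matrix(0, cache$Hf * cache$Wf, cache$C)
  for (corner in 1:4) {
    contrib <- dvals * cache$w[, corner]
    # accumulate rows with possibly repeated indices
    agg <- rowsum(contrib, group = cache$idx[, corner])
    dfm[as.integer(rownames(agg)), ] <- dfm[as.integer(rownames(agg)), ] + agg
  }
  array(dfm, c(cache$Hf, cache$Wf, cache$C))
}

#' Extract a fixed-size RoI feature patch by bilinear sampling
#'
#' The box (pixel coordinates) is divided by `stride` without rounding;
#' each of the `output_size^2` cells averages `sampling^2` bilinear samples
#' at regular sub-positions inside the cell. No quantization occurs
#' anywhere, so sub-pixel box shifts move the output smoothly.
#'
#' @param feature `h x w x C` feature map.
#' @param b Single-row box data frame (pixel coordinates; must be valid).
#' @param output_size Side length of the square output patch.
#' @param stride Pixels per feature cell.
#' @param sampling Sub-samples per cell side (default 2, i.e. 4 per cell).
#' @return `output_size x output_size x C` array.
#' @export
roi_align <- function(feature, b, output_size = 7L, stride = 1, sampling = 2L) {
  r <- roi_align_fwd(feature, b, output_size, stride, sampling)
  r$y
}

roi_align_fwd <- function(feature, b, output_size = 7L, stride = 1,
                          sampling = 2L) {
  validate_boxes(b)
  stopifnot(output_size >= 1L, sampling >= 1L)
  x1 <- b$x1[1L] / stride; y1 <- b$y1[1L] / stride
  x2 <- b$x2[1L] / stride; y2 <- b$y2[1L] / stride
  bw <- (x2 - x1) / output_size; bh <- (y2 - y1) / output_size
  # sample grid: cell (i, j), sub-sample (p, q)
  g <- expand.grid(p = seq_len(sampling), i = seq_len(output_size))
  ys <- y1 + (g$i - 1) * bh + (g$p - 0.5) / sampling * bh
  gx <- expand.grid(q = seq_len(sampling), j = seq_len(output_size))
  xs <- x1 + (gx$j - 1) * bw + (gx$q - 0.5) / sampling * bw
  pts <- expand.grid(yi = seq_along(ys), xi = seq_along(xs))
  bl <- bilinear_gather(feature, ys[pts$yi], xs[pts$xi])
  C <- dim(feature)[3L]
  # average the sampling^2 sub-samples per cell
  cell_i <- g$i[pts$yi]; cell_j <- gx$j[pts$xi]
  cell_id <- cell_i + (cell_j - 1L) * output_size
  sums <- rowsum(bl$vals, group = cell_id)
  y <- array(sums / sampling^2, c(output_size, output_size, C))
  list(y = y, cache = list(bl = bl, cell_id = cell_id,
                           n = sampling^2, os = output_size, C = C))
}

roi_align_bwd <- function(cache, dy) {
  dcell <- matrix(dy, cache$os * cache$os, cache$C) / cache$n
  dvals <- dcell[cache$cell_id, , drop = FALSE]
  bilinear_scatter(cache$bl, dvals)
}

head_init <- function(d, output_size = 7L, hidden = 64L, n_classes = 8L) {
  din <- output_size * output_size * d
  # prediction layers start near zero so initial scores are near uniform
  # and initial boxes stay near their proposals
  list(fc1 = list(W = par_linear(din, hidden), b = par_const(hidden)),
       fc2 = list(W = par_linear(hidden, hidden), b = par_const(hidden)),
       cls = list(W = par_new(c(hidden, n_classes), sd = 0.01),
                  b = par_const(n_classes)),
       reg = list(W = par_new(c(hidden, 4L * (n_classes - 1L)), sd = 0.001),
                  b = par_const(4L * (n_classes - 1L))))
}

# roi_feats: n x din matrix (flattened patches)
head_net_fwd <- function(hp, roi_feats) {
  f1 <- linear_fwd(roi_feats, hp$fc1$W, hp$fc1$b)
  r1 <- relu_fwd(f1$y)
  f2 <- linear_fwd(r1$y, hp$fc2$W, hp$fc2$b)
  r2 <- relu_fwd(f2$y)
  cl <- linear_fwd(r2$y, hp$cls$W, hp$cls$b)
  rg <- linear_fwd(r2$y, hp$reg$W, hp$reg$b)
  list(cls_logits = cl$y, reg = rg$y,
       cache = list(f1 = f1$cache, m1 = r1$mask, f2 = f2$cache, m2 = r2$mask,
                    cl = cl$cache, rg = rg$cache))
}

head_net_bwd <- function(cache, dcls, dreg) {
  dr2 <- linear_bwd(cache$cl, dcls) + linear_bwd(cache$rg, dreg)
  df2 <- relu_bwd(cache$m2, dr2)
  dr1 <- linear_bwd(cache$f2, df2)
  df1 <- relu_bwd(cache$m1, dr1)
  linear_bwd(cache$f1, df1)
}

#' Classify RoI features
#'
#' @param model A detector model.
#' @param roi_feats Either one RoI patch (`s x s x d` array) or a matrix of
#'   flattened patches (one row per RoI).
#' @return List with `scores` (`n x 8` softmax over the 7 cell classes +
#'   background, rows summing to 1) and `deltas` (`n x 28`; one
#'   `(tx, ty, tw, th)` per foreground class, the argmax class's code is
#'   applied downstream).
#' @export
head_forward <- function(model, roi_feats) {
  if (is.array(roi_feats) && length(dim(roi_feats)) == 3L) {
    roi_feats <- matrix(as.numeric(roi_feats), 1L)
  }
  out <- head_net_fwd(model$params$head, roi_feats)
  list(scores = softmax_rows(out$cls_logits), deltas = out$reg)
}

# Route each RoI to a pyramid level by box scale (log2 rule).
assign_roi_levels <- function(b, n_levels = 4L, canonical_size = 32,
                              canonical_level = 2L) {
  s <- sqrt(box_area(b))
  lvl <- floor(canonical_level + log2(pmax(s, 1e-6) / canonical_size))
  as.integer(pmin(pmax(lvl, 1L), n_levels))
}

#' Threshold, suppress and tidy raw detections
#'
#' Drops the background class (never present in the input by convention),
#' keeps detections with `score > score_threshold` (the deployment default
#' follows the 0.7 confidence rule), clips to the image, removes boxes that
#' became degenerate, applies class-aware NMS and sorts score-descending.
#' The operation is idempotent.
#'
#' @param dets Detection data frame.
#' @param image_size `c(height, width)`; `NULL` skips clipping.
#' @param score_threshold Minimum confidence (exclusive).
#' @param nms_iou Class-aware NMS threshold.
#' @return Filtered detection data frame.
#' @export
postprocess_detections <- function(dets, image_size = NULL,
                                   score_threshold = 0.7, nms_iou = 0.5) {
  if (nrow(dets) == 0L) return(dets)
  dets <- dets[dets$score > score_threshold & is.finite(dets$score), , drop = FALSE]
  if (nrow(dets) && !is.null(image_size)) {
    cl <- clip_boxes(dets, image_size[2L], image_size[1L])
    dets[, c("x1", "y1", "x2", "y2")] <- cl$boxes
    dets <- dets[!cl$degenerate, , drop = FALSE]
  }
  if (nrow(dets)) dets <- dets[validate_boxes(dets, "flag"), , drop = FALSE]
  if (!nrow(dets)) { rownames(dets) <- NULL; return(dets) }
  if (!is.null(dets$image_id) && length(unique(dets$image_id)) > 1L) {
    parts <- lapply(split(dets, dets$image_id), nms,
                    iou_threshold = nms_iou, class_aware = TRUE)
    out <- do.call(rbind, parts)
    out <- out[order(-out$score, out$class_id, seq_len(nrow(out))), , drop = FALSE]
  } else {
    out <- nms(dets, iou_threshold = nms_iou, class_aware = TRUE)
  }
  rownames(out) <- NULL
  attr(out, "keep_idx") <- NULL
  out
}

#' Tally detections into a per-class count report
#'
#' @param dets Post-processed detection data frame (optionally with
#'   `image_id`).
#' @return A `count_report` list: `per_image` (one row per image, one
#'   column per class plus `total`), `totals` (named vector over the 7
#'   classes) and `total`. Counting conserves detections: the grand total
#'   equals `nrow(dets)`.
#' @export
count_cells <- function(dets) {
  cls <- wbc_classes()
  ids <- if (is.null(dets$image_id)) rep(0L, nrow(dets)) else dets$image_id
  img_levels <- sort(unique(ids))
  tab <- table(factor(ids, levels = img_levels),
               factor(dets$class_id, levels = 0:(length(cls) - 1L)))
  per_image <- as.data.frame.matrix(tab)
  colnames(per_image) <- cls
  per_image <- cbind(data.frame(image_id = img_levels), per_image)
  per_image$total <- rowSums(per_image[, cls, drop = FALSE])
  totals <- colSums(per_image[, cls, drop = FALSE])
  out <- list(per_image = per_image, totals = totals, total = sum(totals))
  class(out) <- "count_report"
  out
}

#' @export
print.count_report <- function(x, ...) {
  cat("Cell count report —", x$total, "cells in",
      nrow(x$per_image), "image(s)\n")
  for (nm in names(x$totals)) cat(sprintf("  %-14s %d\n", nm, x$totals[[nm]]))
  invisible(x)
}

#' Write a count report as CSV
#' @param report A `count_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_csv <- function(report, path) {
  utils::write.csv(report$per_image, path, row.names = FALSE)
  invisible(path)
}
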