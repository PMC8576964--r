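#' Box geometry: representation, overlap, delta coding, suppression
#'
#' Boxes are axis-aligned rectangles in continuous, 0-based, half-open pixel
#' coordinates: a box covers `[x1, x2) x [y1, y2)` so that its area is exactly
#' `(x2 - x1) * (y2 - y1)`. Every stage of the detector (anchors, proposals,
#' localizer state, detections, ground truth) uses this one convention; COCO's
#' `[x, y, w, h]` form is converted only at the I/O boundary.
#'
#' @name geometry
NULL

#' Construct a box data frame
#'
#' @param x1,y1,x2,y2 Numeric vectors of equal length; `x1 < x2`, `y1 < y2`.
#' @return A `data.frame` with columns `x1, y1, x2, y2`.
#' @examples
#' boxes(0, 0, 10, 10)
#' @export
boxes <- function(x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric()) {
  data.frame(x1 = as.numeric(x1), y1 = as.numeric(y1),
             x2 = as.numeric(x2), y2 = as.numeric(y2))
}

box_matrix <- function(b) {
  if (is.matrix(b)) return(b)
  as.matrix(b[, c("x1", "y1", "x2", "y2"), drop = FALSE])
}

#' Validate boxes
#'
#' Degenerate boxes (non-positive width or height, or non-finite coordinates)
#' are never processed silently: this either errors or returns a logical flag.
#'
#' @param b Box data frame.
#' @param action `"error"` to stop on any invalid box, `"flag"` to return a
#'   logical vector (`TRUE` = valid).
#' @return Invisibly `TRUE`, or a logical vector when `action = "flag"`.
#' @export
validate_boxes <- function(b, action = c("error", "flag")) {
  action <- match.arg(action)
  m <- box_matrix(b)
  ok <- apply(is.finite(m), 1L, all) & (m[, 3L] > m[, 1L]) & (m[, 4L] > m[, 2L])
  if (action == "flag") return(ok)
  if (!all(ok)) {
    stop("invalid (degenerate or non-finite) box at row(s): ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Box areas
#' @param b Box data frame.
#' @return Numeric vector of areas.
#' @export
box_area <- function(b) {
  m <- box_matrix(b)
  (m[, 3L] - m[, 1L]) * (m[, 4L] - m[, 2L])
}

#' Pairwise intersection-over-union
#'
#' @param a,b Box data frames (or 4-column matrices).
#' @return A `nrow(a) x nrow(b)` matrix of IoU ratios in `[0, 1]`.
#' @details IoU is symmetric, 1 for identical boxes and 0 for disjoint ones.
#'   Degenerate boxes are rejected.
#' @export
box_iou <- function(a, b) {
  validate_boxes(a); validate_boxes(b)
  ma <- box_matrix(a); mb <- box_matrix(b)
  na <- nrow(ma); nb <- nrow(mb)
  ix1 <- pmax(matrix(ma[, 1L], na, nb), matrix(mb[, 1L], na, nb, byrow = TRUE))
  iy1 <- pmax(matrix(ma[, 2L], na, nb), matrix(mb[, 2L], na, nb, byrow = TRUE))
  ix2 <- pmin(matrix(ma[, 3L], na, nb), matrix(mb[, 3L], na, nb, byrow = TRUE))
  iy2 <- pmin(matrix(ma[, 4L], na, nb), matrix(mb[, 4L], na, nb, byrow = TRUE))
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  aa <- (ma[, 3L] - ma[, 1L]) * (ma[, 4L] - ma[, 2L])
  ab <- (mb[, 3L] - mb[, 1L]) * (mb[, 4L] - mb[, 2L])
  un <- matrix(aa, na, nb) + matrix(ab, na, nb, byrow = TRUE) - inter
  inter / un
}

#' Scalar IoU of two single boxes
#' @param a,b Single-row box data frames.
#' @return IoU ratio in `[0, 1]`.
#' @export
iou <- function(a, b) as.numeric(box_iou(a, b))[1L]

#' Encode boxes as regression deltas relative to anchors
#'
#' The standard center/log parameterization of two-stage detectors:
#' `tx = (cx_t - cx_a) / w_a`, `ty = (cy_t - cy_a) / h_a`,
#' `tw = log(w_t / w_a)`, `th = log(h_t / h_a)`.
#'
#' @param anchors,targets Box data frames of equal length.
#' @return A `data.frame` with columns `tx, ty, tw, th`.
#' @export
encode_deltas <- function(anchors, targets) {
  validate_boxes(anchors); validate_boxes(targets)
  a <- box_matrix(anchors); g <- box_matrix(targets)
  wa <- a[, 3L] - a[, 1L]; ha <- a[, 4L] - a[, 2L]
  wg <- g[, 3L] - g[, 1L]; hg <- g[, 4L] - g[, 2L]
  cxa <- (a[, 1L] + a[, 3L]) / 2; cya <- (a[, 2L] + a[, 4L]) / 2
  cxg <- (g[, 1L] + g[, 3L]) / 2; cyg <- (g[, 2L] + g[, 4L]) / 2
  data.frame(tx = (cxg - cxa) / wa, ty = (cyg - cya) / ha,
             tw = log(wg / wa), th = log(hg / ha))
}

#' Decode regression deltas against anchors
#'
#' Inverse of [encode_deltas()]: `decode(a, encode(a, g))` reproduces `g` to
#' floating-point precision. Decoded boxes are *not* clipped here; callers
#' clip against image bounds.
#'
#' @param anchors Box data frame.
#' @param deltas `data.frame` (or matrix) with columns `tx, ty, tw, th`.
#' @param clamp Cap on `|tw|`, `|th|` (default `log(1000/16)`, the usual
#'   guard against overflowing sizes from untrained regressors); the
#'   round-trip identity holds whenever the size ratio stays within it.
#' @return Box data frame.
#' @export
decode_deltas <- function(anchors, deltas, clamp = log(1000 / 16)) {
  validate_boxes(anchors)
  a <- box_matrix(anchors)
  d <- if (is.matrix(deltas)) deltas else
    as.matrix(deltas[, c("tx", "ty", "tw", "th"), drop = FALSE])
  wa <- a[, 3L] - a[, 1L]; ha <- a[, 4L] - a[, 2L]
  cxa <- (a[, 1L] + a[, 3L]) / 2; cya <- (a[, 2L] + a[, 4L]) / 2
  cx <- cxa + d[, 1L] * wa; cy <- cya + d[, 2L] * ha
  w <- wa * exp(pmin(pmax(d[, 3L], -clamp), clamp))
  h <- ha * exp(pmin(pmax(d[, 4L], -clamp), clamp))
  boxes(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

#' Clip boxes to image bounds
#'
#' Coordinates are clamped to `[0, width] x [0, height]`. Boxes that become
#' degenerate after clamping (zero width or height inside the canvas) are
#' flagged for removal, never silently kept.
#'
#' @param b Box data frame.
#' @param width,height Image dimensions in pixels (positive).
#' @return A list with `boxes` (clipped data frame) and `degenerate`
#'   (logical vector, `TRUE` where the clipped box has no area).
#' @export
clip_boxes <- function(b, width, height) {
  stopifnot(width > 0, height > 0)
  m <- box_matrix(b)
  m[, c(1L, 3L)] <- pmin(pmax(m[, c(1L, 3L)], 0), width)
  m[, c(2L, 4L)] <- pmin(pmax(m[, c(2L, 4L)], 0), height)
  out <- boxes(m[, 1L], m[, 2L], m[, 3L], m[, 4L])
  list(boxes = out, degenerate = !(m[, 3L] > m[, 1L] & m[, 4L] > m[, 2L]))
}

#' Construct a detection data frame
#'
#' @param b Box data frame.
#' @param class_id Integer class ids, `0..6` over the seven foreground cell
#'   classes (see [wbc_classes()]); background is never emitted.
#' @param score Confidence in `[0, 1]`.
#' @param image_id Optional integer image ids.
#' @return A `data.frame` with columns `x1, y1, x2, y2, class_id, score`
#'   (plus `image_id` when given).
#' @export
detections <- function(b = boxes(), class_id = integer(), score = numeric(),
                       image_id = NULL) {
  d <- cbind(b, data.frame(class_id = as.integer(class_id),
                           score = as.numeric(score)))
  if (!is.null(image_id)) d$image_id <- as.integer(image_id)
  d
}

#' Randomly perturb boxes
#'
#' Applies Gaussian noise in the center/log delta parameterization — the
#' standard way to emulate imperfect region proposals around ground truth
#' (e.g. to exercise or train box-refinement stages).
#'
#' @param b Box data frame.
#' @param sd_center,sd_size Noise standard deviations on the center offsets
#'   (units of box size) and on the log width/height.
#' @return Box data frame of the same shape (uses the current RNG stream).
#' @export
perturb_boxes <- function(b, sd_center = 0.15, sd_size = 0.15) {
  n <- nrow(b)
  d <- matrix(c(stats::rnorm(n, 0, sd_center), stats::rnorm(n, 0, sd_center),
                stats::rnorm(n, 0, sd_size), stats::rnorm(n, 0, sd_size)), n)
  decode_deltas(b, d)
}

#' Greedy non-maximum suppression
#'
#' Detections are processed in descending score order; each kept detection
#' suppresses later ones whose IoU with it exceeds `iou_threshold`. With
#' `class_aware = TRUE` (multi-class NMS) suppression applies only between
#' detections of the same class. Ties in score are broken by lower
#' `class_id`, then input order, so results are reproducible.
#'
#' @param dets Detection data frame (see [detections()]).
#' @param iou_threshold Suppression threshold in `(0, 1)`.
#' @param class_aware Restrict suppression to within-class pairs.
#' @param max_keep Stop after this many survivors (the rest are discarded;
#'   useful when only a top-N budget is needed).
#' @return The surviving detections, sorted score-descending.
#' @export
nms <- function(dets, iou_threshold = 0.5, class_aware = TRUE,
                max_keep = Inf) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  if (nrow(dets) == 0L) return(dets)
  stopifnot(all(is.finite(dets$score)))
  validate_boxes(dets)
  ord <- order(-dets$score, dets$class_id, seq_len(nrow(dets)))
  m <- box_matrix(dets)[ord, , drop = FALSE]
  cls <- dets$class_id[ord]
  n <- nrow(m)
  alive <- rep(TRUE, n)
  keep <- integer()
  areas <- (m[, 3L] - m[, 1L]) * (m[, 4L] - m[, 2L])
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep <- c(keep, i)
    if (length(keep) >= max_keep) break
    if (i < n) {
      later <- (i + 1L):n
      later <- later[alive[later]]
      if (!length(later)) next
      iw <- pmin(m[later, 3L], m[i, 3L]) - pmax(m[later, 1L], m[i, 1L])
      ih <- pmin(m[later, 4L], m[i, 4L]) - pmax(m[later, 2L], m[i, 2L])
      inter <- pmax(iw, 0) * pmax(ih, 0)
      ov <- inter / (areas[later] + areas[i] - inter)
      sup <- ov > iou_threshold
      if (class_aware) sup <- sup & (cls[later] == cls[i])
      alive[later[sup]] <- FALSE
    }
  }
  out <- dets[ord[keep], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "keep_idx") <- ord[keep]   # rows of the input that survived
  out
}
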