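#' COCO-protocol detection metrics
#'
#' Average precision and average recall computed under the MS COCO
#' conventions: greedy score-ordered matching, 101-point interpolated AP,
#' the 0.50:0.05:0.95 IoU threshold grid, area strata (small < 32^2,
#' medium in \[32^2, 96^2\], large > 96^2) and a fixed per-image detection
#' budget for AR.
#'
#' @name evaluation
NULL

coco_area_ranges <- function() {
  list(all    = c(0, 1e10),
       small  = c(0, 32^2),
       medium = c(32^2, 96^2),
       large  = c(96^2, 1e10))
}

#' Match detections to ground truth at one IoU threshold
#'
#' Greedy matching in descending score order: each detection is matched to
#' the unmatched ground-truth box of its class with the highest IoU, provided
#' that IoU reaches `iou_threshold`; each ground-truth box is matched at most
#' once. Matching is performed independently per image.
#'
#' @param dets Detection data frame with columns `x1,y1,x2,y2,class_id,score`
#'   and optionally `image_id` (a single image is assumed otherwise).
#' @param gts Ground-truth data frame with `x1,y1,x2,y2,class_id` and
#'   optionally `image_id`.
#' @param iou_threshold Minimum IoU for a match.
#' @return A list with `tp` (logical per detection, in the order of `dets`
#'   sorted score-descending), `order` (the sort permutation applied),
#'   `scores` (sorted scores) and `n_missed` (unmatched ground-truth count).
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  if (is.null(dets$image_id)) dets$image_id <- 0L
  if (nrow(gts) > 0L && is.null(gts$image_id)) gts$image_id <- 0L
  ord <- order(-dets$score, seq_len(nrow(dets)))
  d <- dets[ord, , drop = FALSE]
  tp <- logical(nrow(d))
  gt_matched <- rep(FALSE, nrow(gts))
  if (nrow(d) > 0L && nrow(gts) > 0L) {
    iom <- box_iou(d, gts)
    for (i in seq_len(nrow(d))) {
      cand <- which(!gt_matched &
                    gts$image_id == d$image_id[i] &
                    gts$class_id == d$class_id[i])
      if (!length(cand)) next
      ious <- iom[i, cand]
      j <- cand[which.max(ious)]
      if (max(ious) >= iou_threshold) {
        tp[i] <- TRUE
        gt_matched[j] <- TRUE
      }
    }
  }
  list(tp = tp, order = ord, scores = d$score,
       n_missed = sum(!gt_matched))
}

#' 101-point interpolated average precision at one IoU threshold
#'
#' Precision-recall points are accumulated from cumulative true/false
#' positives in descending score order; AP is the mean, over the 101 recall
#' thresholds `0.00, 0.01, ..., 1.00`, of the highest precision attained at
#' recall at least the threshold (the COCO interpolation).
#'
#' @param tp Logical vector of per-detection true-positive flags.
#' @param n_gt Number of ground-truth instances.
#' @param scores Optional scores; when supplied, `tp` is re-sorted into
#'   descending score order first.
#' @return AP in `[0, 1]`, or `NA` when `n_gt` is 0 (undefined stratum).
#' @export
average_precision <- function(tp, n_gt, scores = NULL) {
  if (n_gt == 0L) return(NA_real_)
  if (!is.null(scores)) tp <- tp[order(-scores, seq_along(scores))]
  if (!length(tp)) return(0)
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  # monotone envelope from the right, then sample at the recall grid
  for (i in rev(seq_len(length(precision) - 1L))) {
    precision[i] <- max(precision[i], precision[i + 1L])
  }
  grid <- (0:100) / 100   # exact thresholds (seq() accumulates fp error)
  idx <- findInterval(grid, recall, left.open = TRUE) + 1L  # first recall >= t
  q <- ifelse(idx <= length(precision), precision[pmin(idx, length(precision))], 0)
  mean(q)
}

# Per-(class, threshold, area-range) matching with COCO ignore semantics:
# ground truth outside the area range is "ignore"; detections matched to an
# ignored GT, or unmatched with their own area outside the range, are dropped
# from both TP and FP counts.
eval_one_cell <- function(d_by_img, g_by_img, thr, arng, max_dets) {
  all_tp <- logical(); all_ig <- logical(); all_scores <- numeric()
  npig <- 0L
  # deterministic numeric image order so score ties across images break
  # identically everywhere
  img_ids <- union(names(d_by_img), names(g_by_img))
  img_ids <- img_ids[order(suppressWarnings(as.numeric(img_ids)), img_ids)]
  for (im in img_ids) {
    d <- d_by_img[[im]]
    g <- g_by_img[[im]]
    nd <- if (is.null(d)) 0L else nrow(d)
    ng <- if (is.null(g)) 0L else nrow(g)
    if (nd > max_dets) { d <- d[seq_len(max_dets), , drop = FALSE]; nd <- max_dets }
    g_ig <- if (ng) (g$area < arng[1L] | g$area > arng[2L]) else logical()
    npig <- npig + sum(!g_ig)
    if (!nd) next
    tp <- logical(nd); dt_ig <- logical(nd)
    if (ng) {
      gord <- order(g_ig)  # non-ignored ground truth first
      iom <- box_iou(d, g[gord, , drop = FALSE])
      g_ig_s <- g_ig[gord]
      matched <- rep(FALSE, ng)
      for (i in seq_len(nd)) {
        best <- min(thr, 1 - 1e-10); m <- -1L
        for (j in seq_len(ng)) {
          if (matched[j] && !g_ig_s[j]) next
          if (m > 0L && !g_ig_s[m] && g_ig_s[j]) break
          if (iom[i, j] < best) next
          best <- iom[i, j]; m <- j
        }
        if (m > 0L) {
          matched[m] <- TRUE
          tp[i] <- !g_ig_s[m]
          dt_ig[i] <- g_ig_s[m]
        }
      }
    }
    d_area <- box_area(d)
    dt_ig <- dt_ig | (!tp & !dt_ig & (d_area < arng[1L] | d_area > arng[2L]))
    all_tp <- c(all_tp, tp); all_ig <- c(all_ig, dt_ig)
    all_scores <- c(all_scores, d$score)
  }
  ord <- order(-all_scores, seq_along(all_scores))
  keep <- !all_ig[ord]
  tp_sorted <- all_tp[ord][keep]
  list(tp = tp_sorted, n_gt = npig,
       max_recall = if (npig > 0L) sum(tp_sorted) / npig else NA_real_)
}

#' Evaluate a detection set against ground truth (COCO protocol)
#'
#' @param dets Detection data frame (`x1,y1,x2,y2,class_id,score,image_id`).
#' @param gts Ground-truth data frame (`x1,y1,x2,y2,class_id,image_id`,
#'   optional `area`; the box area is used when absent).
#' @param iou_thresholds IoU grid for the headline AP (default COCO
#'   `0.50:0.05:0.95`).
#' @param max_dets Per-image, per-class detection budget (AR convention).
#' @param zero_fill Treat classes absent from the ground truth as AP 0
#'   instead of excluding them (undefined) from the means.
#' @return A one-row `data.frame` with `AP, AP50, AP75, APS, APM, APL, AR`
#'   plus `n_images, n_dets, n_gt`. Undefined strata are `NA`.
#' @details Per-class AP over an empty stratum is undefined and excluded from
#'   every mean, so absent classes never deflate the score; set `zero_fill`
#'   for the stricter convention. `AP <= AP50` always holds: averaging over
#'   stricter thresholds cannot exceed the loosest one.
#' @export
evaluate_dataset <- function(dets, gts,
                             iou_thresholds = seq(0.5, 0.95, by = 0.05),
                             max_dets = 100L, zero_fill = FALSE) {
  if (nrow(dets) > 0L) {
    stopifnot(all(dets$class_id %in% 0:(n_wbc_classes() - 1L)))
  }
  if (is.null(dets$image_id)) dets$image_id <- 0L
  if (nrow(gts) > 0L && is.null(gts$image_id)) gts$image_id <- 0L
  if (is.null(gts$area)) gts$area <- box_area(gts)
  classes <- 0:(n_wbc_classes() - 1L)
  arngs <- coco_area_ranges()
  # AP[class, threshold, area-range]; recall[class, threshold] at range "all"
  ap <- array(NA_real_, c(length(classes), length(iou_thresholds), length(arngs)),
              dimnames = list(NULL, NULL, names(arngs)))
  rec <- matrix(NA_real_, length(classes), length(iou_thresholds))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    d <- dets[dets$class_id == cl, , drop = FALSE]
    g <- gts[gts$class_id == cl, , drop = FALSE]
    d <- d[order(-d$score, seq_len(nrow(d))), , drop = FALSE]
    d_by <- split(d, as.character(d$image_id))
    g_by <- split(g, as.character(g$image_id))
    for (ti in seq_along(iou_thresholds)) {
      for (ai in seq_along(arngs)) {
        cell <- eval_one_cell(d_by, g_by, iou_thresholds[ti], arngs[[ai]], max_dets)
        ap[ci, ti, ai] <- average_precision(cell$tp, cell$n_gt)
        if (ai == 1L) rec[ci, ti] <- cell$max_recall
      }
    }
  }
  if (zero_fill) { ap[is.na(ap)] <- 0; rec[is.na(rec)] <- 0 }
  mean_def <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  res <- data.frame(
    AP   = mean_def(ap[, , "all"]),
    AP50 = mean_def(ap[, which.min(abs(iou_thresholds - 0.50)), "all"]),
    AP75 = mean_def(ap[, which.min(abs(iou_thresholds - 0.75)), "all"]),
    APS  = mean_def(ap[, , "small"]),
    APM  = mean_def(ap[, , "medium"]),
    APL  = mean_def(ap[, , "large"]),
    AR   = mean_def(rec),
    n_images = length(unique(c(dets$image_id, gts$image_id))),
    n_dets = nrow(dets), n_gt = nrow(gts))
  class(res) <- c("wbc_eval", class(res))
  res
}

#' @export
print.wbc_eval <- function(x, ...) {
  cat("COCO-protocol detection metrics\n")
  cols <- c("AP", "AP50", "AP75", "APS", "APM", "APL", "AR")
  v <- vapply(cols, function(k) {
    val <- x[[k]]
    if (is.na(val)) "  --" else sprintf("%0.3f", val)
  }, character(1L))
  cat(paste(sprintf("%5s", cols), collapse = " "), "\n")
  cat(paste(sprintf("%5s", v), collapse = " "), "\n")
  cat(sprintf("(%d images, %d detections, %d ground-truth boxes)\n",
              x$n_images, x$n_dets, x$n_gt))
  invisible(x)
}

#' Evaluate COCO annotation + results files
#'
#' Reads a COCO ground-truth JSON and a COCO detection-results JSON
#' (`[{image_id, category_id, bbox, score}, ...]`) and runs
#' [evaluate_dataset()].
#'
#' @param gt_json Path to COCO annotation JSON.
#' @param results_json Path to COCO results JSON.
#' @param ... Passed to [evaluate_dataset()].
#' @return See [evaluate_dataset()].
#' @export
evaluate_coco_files <- function(gt_json, results_json, ...) {
  ds <- read_coco(gt_json)
  dets <- read_coco_results(results_json)
  gt <- ds$annotations
  g <- boxes(gt$x, gt$y, gt$x + gt$w, gt$y + gt$h)
  g$class_id <- gt$category_id - 1L
  g$image_id <- gt$image_id
  g$area <- gt$area
  evaluate_dataset(dets, g, ...)
}
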