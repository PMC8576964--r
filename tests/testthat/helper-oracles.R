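# Independent reference implementations used as oracles. Deliberately
# written in plain-loop style, structured differently from the package's
# vectorized code paths.

# Exact IoU for integer-coordinate boxes by counting unit grid cells.
oracle_grid_iou <- function(a, b) {
  cells <- function(bx) {
    out <- matrix(0L, 0L, 2L)
    for (x in seq(bx$x1, bx$x2 - 1L)) {
      for (y in seq(bx$y1, bx$y2 - 1L)) {
        out <- rbind(out, c(x, y))
      }
    }
    out
  }
  ca <- cells(a); cb <- cells(b)
  key <- function(m) paste(m[, 1L], m[, 2L])
  inter <- sum(key(ca) %in% key(cb))
  union <- nrow(ca) + nrow(cb) - inter
  inter / union
}

oracle_iou_pair <- function(a, b) {
  ix <- max(0, min(a$x2, b$x2) - max(a$x1, b$x1))
  iy <- max(0, min(a$y2, b$y2) - max(a$y1, b$y1))
  inter <- ix * iy
  inter / ((a$x2 - a$x1) * (a$y2 - a$y1) + (b$x2 - b$x1) * (b$y2 - b$y1) - inter)
}

# O(n^2) greedy suppression honoring the package's documented tie rule.
oracle_nms <- function(dets, thr, class_aware = TRUE) {
  n <- nrow(dets)
  ord <- order(-dets$score, dets$class_id, seq_len(n))
  d <- dets[ord, , drop = FALSE]
  suppressed <- rep(FALSE, n)
  kept <- integer()
  for (i in seq_len(n)) {
    if (suppressed[i]) next
    kept <- c(kept, i)
    if (i == n) next
    for (j in (i + 1L):n) {
      if (suppressed[j]) next
      if (class_aware && d$class_id[j] != d$class_id[i]) next
      if (oracle_iou_pair(d[i, ], d[j, ]) > thr) suppressed[j] <- TRUE
    }
  }
  out <- d[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive greedy matcher: per image and class, detections in score
# order take the unmatched ground truth with the highest IoU above the
# threshold.
oracle_match <- function(dets, gts, thr) {
  if (is.null(dets$image_id)) dets$image_id <- 0L
  if (nrow(gts) > 0L && is.null(gts$image_id)) gts$image_id <- 0L
  ord <- order(-dets$score, seq_len(nrow(dets)))
  d <- dets[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(gts))
  tp <- rep(FALSE, nrow(d))
  for (i in seq_len(nrow(d))) {
    best <- -1; bj <- 0L
    for (j in seq_len(nrow(gts))) {
      if (used[j]) next
      if (gts$image_id[j] != d$image_id[i]) next
      if (gts$class_id[j] != d$class_id[i]) next
      ov <- oracle_iou_pair(d[i, ], gts[j, ])
      if (ov > best) { best <- ov; bj <- j }
    }
    if (bj > 0L && best >= thr) { tp[i] <- TRUE; used[bj] <- TRUE }
  }
  list(tp = tp, n_missed = sum(!used))
}

# Direct-definition COCO evaluation: per class / IoU threshold / area
# range, greedy matching with ignore semantics, then AP as the mean over
# the 101 recall thresholds of the best precision at recall >= t.
oracle_coco_eval <- function(dets, gts, iou_thrs = seq(0.5, 0.95, 0.05),
                             max_dets = 100L) {
  if (is.null(dets$image_id)) dets$image_id <- 0L
  if (nrow(gts) > 0L && is.null(gts$image_id)) gts$image_id <- 0L
  if (is.null(gts$area)) gts$area <- (gts$x2 - gts$x1) * (gts$y2 - gts$y1)
  rngs <- list(all = c(0, 1e10), small = c(0, 1024),
               medium = c(1024, 9216), large = c(9216, 1e10))
  classes <- 0:6
  ap_arr <- array(NA_real_, c(7, length(iou_thrs), 4))
  rec_arr <- matrix(NA_real_, 7, length(iou_thrs))
  for (ci in seq_along(classes)) {
    dc <- dets[dets$class_id == classes[ci], , drop = FALSE]
    gc <- gts[gts$class_id == classes[ci], , drop = FALSE]
    for (ti in seq_along(iou_thrs)) {
      thr <- iou_thrs[ti]
      for (ai in seq_along(rngs)) {
        rng <- rngs[[ai]]
        all_tp <- logical(); all_ig <- logical(); all_sc <- numeric()
        npig <- 0L
        for (im in sort(unique(c(dc$image_id, gc$image_id)))) {
          di <- dc[dc$image_id == im, , drop = FALSE]
          di <- di[order(-di$score, seq_len(nrow(di))), , drop = FALSE]
          if (nrow(di) > max_dets) di <- di[1:max_dets, , drop = FALSE]
          gi <- gc[gc$image_id == im, , drop = FALSE]
          g_ig <- gi$area < rng[1] | gi$area > rng[2]
          npig <- npig + sum(!g_ig)
          if (!nrow(di)) next
          # non-ignored ground truth considered first
          gord <- order(g_ig)
          gi <- gi[gord, , drop = FALSE]; g_ig <- g_ig[gord]
          used <- rep(FALSE, nrow(gi))
          for (i in seq_len(nrow(di))) {
            best <- min(thr, 1 - 1e-10); m <- 0L
            for (j in seq_len(nrow(gi))) {
              if (used[j] && !g_ig[j]) next
              if (m > 0L && !g_ig[m] && g_ig[j]) break
              ov <- oracle_iou_pair(di[i, ], gi[j, ])
              if (ov < best) next
              best <- ov; m <- j
            }
            is_tp <- FALSE; is_ig <- FALSE
            if (m > 0L) {
              used[m] <- TRUE
              if (g_ig[m]) is_ig <- TRUE else is_tp <- TRUE
            } else {
              da <- (di$x2[i] - di$x1[i]) * (di$y2[i] - di$y1[i])
              if (da < rng[1] || da > rng[2]) is_ig <- TRUE
            }
            all_tp <- c(all_tp, is_tp); all_ig <- c(all_ig, is_ig)
            all_sc <- c(all_sc, di$score[i])
          }
        }
        ord <- order(-all_sc, seq_along(all_sc))
        tp <- all_tp[ord][!all_ig[ord]]
        if (npig == 0L) next
        if (!length(tp)) {
          ap_arr[ci, ti, ai] <- 0
          if (ai == 1L) rec_arr[ci, ti] <- 0
          next
        }
        rec <- cumsum(tp) / npig
        prec <- cumsum(tp) / seq_along(tp)
        q <- numeric(101L)
        for (k in 0:100) {
          t0 <- k / 100
          sel <- which(rec >= t0)
          q[k + 1L] <- if (length(sel)) max(prec[sel]) else 0
        }
        ap_arr[ci, ti, ai] <- mean(q)
        if (ai == 1L) rec_arr[ci, ti] <- max(rec)
      }
    }
  }
  mn <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  c(AP = mn(ap_arr[, , 1]),
    AP50 = mn(ap_arr[, which.min(abs(iou_thrs - 0.5)), 1]),
    AP75 = mn(ap_arr[, which.min(abs(iou_thrs - 0.75)), 1]),
    APS = mn(ap_arr[, , 2]), APM = mn(ap_arr[, , 3]), APL = mn(ap_arr[, , 4]),
    AR = mn(rec_arr))
}

# ---- random fixture generators -------------------------------------------

random_boxes <- function(n, lim = 100, min_side = 2, max_side = 30,
                         integer = FALSE) {
  w <- stats::runif(n, min_side, max_side)
  h <- stats::runif(n, min_side, max_side)
  x1 <- stats::runif(n, 0, lim - w)
  y1 <- stats::runif(n, 0, lim - h)
  if (integer) {
    x1 <- floor(x1); y1 <- floor(y1); w <- ceiling(w); h <- ceiling(h)
  }
  boxes(x1, y1, x1 + w, y1 + h)
}

# jitter detection boxes while keeping classes; rescore randomly
perturb_boxes_det <- function(d, sd) {
  nb <- perturb_boxes(d[, c("x1", "y1", "x2", "y2")], sd, sd)
  d[, c("x1", "y1", "x2", "y2")] <- nb
  d$score <- round(stats::runif(nrow(d), 0.5, 1), 3)
  d
}

random_detections <- function(n, lim = 100, n_classes = 3, n_images = 1) {
  d <- detections(random_boxes(n, lim),
                  class_id = sample(0:(n_classes - 1L), n, replace = TRUE),
                  score = round(stats::runif(n), 3))
  if (n_images > 1) d$image_id <- sample.int(n_images, n, replace = TRUE)
  d
}
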