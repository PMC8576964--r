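#' Region proposal network: anchors, objectness, proposal selection
#'
#' A shared 3x3 convolution plus two 1x1 heads slides over every pyramid
#' level, scoring `k` anchors per feature position for objectness and
#' regressing them into proposals. Per level the top pre-NMS candidates are
#' decoded, clipped and merged across levels; class-agnostic NMS and a
#' top-N budget produce the proposal set.
#'
#' @name region_proposal
NULL

#' Anchor configuration
#'
#' @param scales Anchor side lengths in pixels (each paired with every
#'   ratio). For pyramid use, one scale is routed per level.
#' @param ratios Height/width aspect ratios; shapes preserve area
#'   (`w = s / sqrt(r)`, `h = s * sqrt(r)`).
#' @return An `anchor_config` with `k = length(scales) * length(ratios)`.
#' @export
anchor_config <- function(scales = c(32, 64, 128, 256), ratios = c(0.5, 1, 2)) {
  stopifnot(length(scales) >= 1L, all(scales > 0), length(ratios) >= 1L,
            all(ratios > 0))
  structure(list(scales = scales, ratios = ratios,
                 k = length(scales) * length(ratios)),
            class = "anchor_config")
}

#' Generate anchors for one feature map
#'
#' One anchor of every configured shape is centered at
#' `((j + 0.5) * stride, (i + 0.5) * stride)` for each of the `h x w`
#' feature positions (0-based `i, j`), giving `h * w * k` anchors. Anchors
#' may extend beyond the image; callers clip or filter.
#'
#' @param feature_shape `c(h, w)` of the feature map.
#' @param stride Pixels per feature cell at this level.
#' @param cfg An [anchor_config()].
#' @return Box data frame of `h * w * k` anchors, ordered position-major
#'   (row-major over positions, shapes innermost), with columns `cx, cy`
#'   retained as attributes-free extras dropped.
#' @export
generate_anchors <- function(feature_shape, stride, cfg) {
  h <- feature_shape[1L]; w <- feature_shape[2L]
  shapes <- expand.grid(ratio = cfg$ratios, scale = cfg$scales)
  ws <- shapes$scale / sqrt(shapes$ratio)
  hs <- shapes$scale * sqrt(shapes$ratio)
  k <- nrow(shapes)
  # row-major over positions: i (rows) outer, j (cols) middle, shape inner
  pos <- expand.grid(shape = seq_len(k), j = seq_len(w) - 1L, i = seq_len(h) - 1L)
  cx <- (pos$j + 0.5) * stride
  cy <- (pos$i + 0.5) * stride
  boxes(cx - ws[pos$shape] / 2, cy - hs[pos$shape] / 2,
        cx + ws[pos$shape] / 2, cy + hs[pos$shape] / 2)
}

rpn_init <- function(d, k) {
  # prediction convolutions start near zero (standard detector practice)
  list(conv = list(W = par_conv(3, 3, d, d), b = par_const(d)),
       obj = list(W = par_new(c(1, 1, d, k), sd = 0.01), b = par_const(k)),
       reg = list(W = par_new(c(1, 1, d, 4L * k), sd = 0.01),
                  b = par_const(4L * k)))
}

# Head forward on one level; returns objectness logits (h, w, k), deltas
# (h, w, 4k) and caches for training.
rpn_head_fwd <- function(rp, feat) {
  sh <- conv_relu_fwd(feat, rp$conv, 1L)
  ob <- conv2d_fwd(sh$y, rp$obj$W, rp$obj$b, 1L)
  rg <- conv2d_fwd(sh$y, rp$reg$W, rp$reg$b, 1L)
  list(obj = ob$y, reg = rg$y,
       cache = list(shared = sh$cache, obj = ob$cache, reg = rg$cache))
}

rpn_head_bwd <- function(cache, dobj, dreg) {
  dsh <- conv2d_bwd(cache$obj, dobj) + conv2d_bwd(cache$reg, dreg)
  conv_relu_bwd(cache$shared, dsh)
}

# Deltas (h, w, 4k) -> matrix (h*w*k, 4) in the anchor order of
# generate_anchors (position row-major, shape innermost).
rpn_reg_to_matrix <- function(reg, k) {
  h <- dim(reg)[1L]; w <- dim(reg)[2L]
  out <- matrix(0, h * w * k, 4L)
  # anchor index = shape + (j-1)*k + (i-1)*w*k ; array element (i, j, ch)
  for (a in seq_len(k)) {
    block <- matrix(reg[, , (a - 1L) * 4L + 1:4], h * w, 4L)  # (i fastest)
    # reorder to row-major positions: idx over (j, i) with j fastest
    rm <- as.vector(t(matrix(seq_len(h * w), h, w)))  # row-major position order
    out[a + (seq_len(h * w) - 1L) * k, ] <- block[rm, ]
  }
  out
}

rpn_obj_to_vector <- function(obj, k) {
  h <- dim(obj)[1L]; w <- dim(obj)[2L]
  out <- numeric(h * w * k)
  rm <- as.vector(t(matrix(seq_len(h * w), h, w)))
  for (a in seq_len(k)) {
    v <- as.vector(obj[, , a])
    out[a + (seq_len(h * w) - 1L) * k] <- v[rm]
  }
  out
}

# Scatter per-anchor gradients back into (h, w, k) / (h, w, 4k) arrays.
rpn_scatter_obj <- function(dvec, h, w, k) {
  arr <- array(0, c(h, w, k))
  rm <- as.vector(t(matrix(seq_len(h * w), h, w)))
  for (a in seq_len(k)) {
    v <- dvec[a + (seq_len(h * w) - 1L) * k]
    plane <- numeric(h * w); plane[rm] <- v
    arr[, , a] <- matrix(plane, h, w)
  }
  arr
}

rpn_scatter_reg <- function(dmat, h, w, k) {
  arr <- array(0, c(h, w, 4L * k))
  rm <- as.vector(t(matrix(seq_len(h * w), h, w)))
  for (a in seq_len(k)) {
    block <- dmat[a + (seq_len(h * w) - 1L) * k, , drop = FALSE]
    for (ch in 1:4) {
      plane <- numeric(h * w); plane[rm] <- block[, ch]
      arr[, , (a - 1L) * 4L + ch] <- matrix(plane, h, w)
    }
  }
  arr
}

#' Run the RPN over a feature pyramid and select proposals
#'
#' Per level: objectness and delta prediction on every anchor, decoding,
#' clipping to the image, dropping degenerate boxes and keeping the
#' per-level pre-NMS top-K; then a cross-level merge, class-agnostic NMS
#' and the top-N budget, score-descending with deterministic tie-breaking
#' (input order).
#'
#' @param model A detector model from [wbc_model()].
#' @param pyramid Named list of consumed levels (N or P) with a `strides`
#'   attribute, e.g. from [bottom_up_fusion()].
#' @param image_size `c(height, width)` in pixels.
#' @param train Use the training-time pre/post NMS budgets.
#' @return Proposal data frame: `x1, y1, x2, y2, score, level`, sorted
#'   score-descending, at most `top_n` rows.
#' @export
rpn_forward <- function(model, pyramid, image_size, train = FALSE) {
  cfg <- model$cfg
  strides <- attr(pyramid, "strides")
  if (is.null(strides)) strides <- level_strides()[seq_along(pyramid)]
  pre_k <- if (train) cfg$rpn$pre_nms_train else cfg$rpn$pre_nms_test
  top_n <- if (train) cfg$rpn$top_n_train else cfg$rpn$top_n_test
  cand <- list()
  for (li in seq_along(pyramid)) {
    feat <- pyramid[[li]]
    stride <- strides[[li]]
    acfg <- anchor_config(scales = cfg$anchors$scales[li], ratios = cfg$anchors$ratios)
    hd <- rpn_head_fwd(model$params$rpn, feat)
    logits <- rpn_obj_to_vector(hd$obj, acfg$k)
    deltas <- rpn_reg_to_matrix(hd$reg, acfg$k)
    anchors <- generate_anchors(dim(feat)[1:2], stride, acfg)
    take <- order(-logits, seq_along(logits))[seq_len(min(pre_k, length(logits)))]
    dec <- decode_deltas(anchors[take, , drop = FALSE],
                         `colnames<-`(deltas[take, , drop = FALSE],
                                      c("tx", "ty", "tw", "th")))
    cl <- clip_boxes(dec, image_size[2L], image_size[1L])
    keep <- !cl$degenerate
    if (!any(keep)) next
    df <- cl$boxes[keep, , drop = FALSE]
    df$score <- sigmoid(logits[take][keep])
    df$level <- names(pyramid)[li]
    cand[[length(cand) + 1L]] <- df
  }
  if (!length(cand)) {
    out <- boxes(); out$score <- numeric(); out$level <- character()
    return(out)
  }
  all <- do.call(rbind, cand)
  nms_in <- detections(all[, 1:4], class_id = rep(0L, nrow(all)), score = all$score)
  kept <- nms(nms_in, iou_threshold = cfg$rpn$nms_iou, class_aware = FALSE,
              max_keep = top_n)
  out <- all[attr(kept, "keep_idx"), , drop = FALSE]
  out <- out[seq_len(min(top_n, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label and subsample proposals for training
#'
#' Proposals with maximum IoU at least `pos_iou` against any ground-truth
#' box are positives; at most `neg_iou` negatives; the interval between is
#' ignored. Every ground-truth box's best-matching proposal is force-
#' included as a positive. Positives are capped at half the batch;
#' negatives fill the remainder (`balance = "strict"` caps them at the
#' positive count instead, the literal 1:1 reading).
#'
#' @param proposals Box data frame.
#' @param gt_boxes Ground-truth box data frame (at least one row).
#' @param batch_size Maximum sampled proposals.
#' @param pos_iou,neg_iou IoU thresholds (defaults 0.7 / 0.3).
#' @param balance `"fill"` or `"strict"` (see above).
#' @return A data.frame with columns `idx` (row in `proposals`), `label`
#'   (`"pos"`/`"neg"`) and `gt` (assigned ground-truth row, `NA` for
#'   negatives). Empty, with a warning, when nothing is labelable.
#' @export
sample_proposals_for_training <- function(proposals, gt_boxes, batch_size = 64L,
                                          pos_iou = 0.7, neg_iou = 0.3,
                                          balance = c("fill", "strict")) {
  balance <- match.arg(balance)
  stopifnot(nrow(gt_boxes) >= 1L)
  empty <- data.frame(idx = integer(), label = character(), gt = integer())
  if (nrow(proposals) == 0L) { warning("no proposals to sample"); return(empty) }
  iom <- box_iou(proposals, gt_boxes)
  max_iou <- apply(iom, 1L, max)
  best_gt <- apply(iom, 1L, which.max)
  pos <- which(max_iou >= pos_iou)
  forced <- vapply(seq_len(nrow(gt_boxes)),
                   function(g) which.max(iom[, g]), integer(1L))
  pos <- union(forced, pos)          # forced first, so they survive the cap
  neg <- setdiff(which(max_iou <= neg_iou), pos)
  if (!length(pos) && !length(neg)) {
    warning("no proposals labelable as positive or negative")
    return(empty)
  }
  half <- max(1L, batch_size %/% 2L)
  forced_u <- unique(forced)
  if (length(forced_u) >= half) {
    pos_take <- forced_u  # forced positives are always kept, even over the cap
  } else {
    rest <- setdiff(pos, forced_u)
    pos_take <- c(forced_u,
                  sample_vec(rest, min(length(rest), half - length(forced_u))))
  }
  n_neg_cap <- if (balance == "strict") length(pos_take) else batch_size - length(pos_take)
  n_neg <- min(length(neg), n_neg_cap)
  neg_take <- sample_vec(neg, n_neg)
  out <- data.frame(idx = pos_take, label = rep("pos", length(pos_take)),
                    gt = best_gt[pos_take])
  if (length(neg_take)) {
    out <- rbind(out, data.frame(idx = neg_take,
                                 label = rep("neg", length(neg_take)),
                                 gt = rep(NA_integer_, length(neg_take))))
  }
  out
}

# sample() without the length-1 surprise
sample_vec <- function(x, n) {
  if (n <= 0L || !length(x)) return(x[0])
  if (length(x) == 1L) return(x)
  x[sample.int(length(x), n)]
}
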