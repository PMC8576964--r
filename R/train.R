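#' Joint training and inference
#'
#' One SGD iteration processes a mini-batch of images end-to-end: the
#' pyramid forward pass, RPN objectness and box losses on sampled anchors,
#' RoIAlign head classification and box-refinement losses on sampled
#' proposals (gradients flow through RoIAlign into the pyramid and
#' backbone), and an actor-critic localizer episode per image (policy and
#' value losses on the localizer's own parameters, with the features
#' treated as fixed inputs). All loss terms carry configurable weights.
#'
#' @name training
NULL

# --- per-image forward/backward -------------------------------------------

train_step_image <- function(model, img, gt_boxes, gt_classes, run_localizer) {
  cfg <- model$cfg
  lw <- cfg$train$loss_weights
  H <- dim(img)[1L]; W <- dim(img)[2L]
  py <- pyramid_fwd(model$params, img)
  levels <- consumed_levels(model, py)
  strides <- level_strides()
  dlev <- zero_like_levels(levels)
  losses <- c(rpn_obj = 0, rpn_box = 0, head_cls = 0, head_box = 0,
              ac_policy = 0, ac_value = 0)

  # ---- RPN: heads on every level, loss on sampled anchors ----
  heads <- list(); anchors_all <- list(); logits_all <- list(); deltas_all <- list()
  for (li in seq_along(levels)) {
    acfg <- anchor_config(cfg$anchors$scales[li], cfg$anchors$ratios)
    hd <- rpn_head_fwd(model$params$rpn, levels[[li]])
    heads[[li]] <- hd
    anchors_all[[li]] <- generate_anchors(dim(levels[[li]])[1:2], strides[li], acfg)
    logits_all[[li]] <- rpn_obj_to_vector(hd$obj, acfg$k)
    deltas_all[[li]] <- rpn_reg_to_matrix(hd$reg, acfg$k)
  }
  n_per_level <- vapply(anchors_all, nrow, integer(1L))
  anchors_cat <- do.call(rbind, anchors_all)
  logits_cat <- unlist(logits_all)
  deltas_cat <- do.call(rbind, deltas_all)

  dlogits_cat <- numeric(length(logits_cat))
  ddeltas_cat <- matrix(0, nrow(deltas_cat), 4L)
  if (nrow(gt_boxes) > 0L) {
    smp <- suppressWarnings(sample_proposals_for_training(
      anchors_cat, gt_boxes, cfg$rpn$batch, cfg$rpn$pos_iou, cfg$rpn$neg_iou))
    if (nrow(smp)) {
      lab <- as.numeric(smp$label == "pos")
      bce <- sigmoid_bce(logits_cat[smp$idx], lab)
      losses["rpn_obj"] <- bce$loss
      dlogits_cat[smp$idx] <- dlogits_cat[smp$idx] + lw$rpn_obj * bce$dlogits
      pos <- smp[smp$label == "pos", , drop = FALSE]
      if (nrow(pos)) {
        tgt <- as.matrix(encode_deltas(anchors_cat[pos$idx, , drop = FALSE],
                                       gt_boxes[pos$gt, , drop = FALSE]))
        sl <- smooth_l1(deltas_cat[pos$idx, , drop = FALSE], tgt,
                        norm = 4L * nrow(pos))
        losses["rpn_box"] <- sl$loss
        ddeltas_cat[pos$idx, ] <- ddeltas_cat[pos$idx, ] + lw$rpn_box * sl$dpred
      }
    }
  }
  off <- 0L
  for (li in seq_along(levels)) {
    acfg_k <- length(cfg$anchors$ratios)
    hw <- dim(levels[[li]])[1:2]
    sel <- off + seq_len(n_per_level[li])
    dobj <- rpn_scatter_obj(dlogits_cat[sel], hw[1L], hw[2L], acfg_k)
    dreg <- rpn_scatter_reg(ddeltas_cat[sel, , drop = FALSE],
                            hw[1L], hw[2L], acfg_k)
    dlev[[li]] <- dlev[[li]] + rpn_head_bwd(heads[[li]]$cache, dobj, dreg)
    off <- off + n_per_level[li]
  }

  # ---- head: proposals -> RoIAlign -> classification + regression ----
  props <- rpn_forward(model, levels, c(H, W), train = TRUE)
  pboxes <- props[, c("x1", "y1", "x2", "y2"), drop = FALSE]
  if (isTRUE(cfg$head$add_gt_proposals) && nrow(gt_boxes) > 0L) {
    pboxes <- rbind(pboxes, gt_boxes[, c("x1", "y1", "x2", "y2"), drop = FALSE])
  }
  if (nrow(gt_boxes) > 0L && nrow(pboxes) > 0L) {
    smp <- suppressWarnings(sample_proposals_for_training(
      pboxes, gt_boxes, cfg$head$batch, cfg$head$pos_iou, cfg$head$neg_iou))
    if (nrow(smp)) {
      rois <- pboxes[smp$idx, , drop = FALSE]
      lvl <- assign_roi_levels(rois, length(levels), cfg$head$canonical_size)
      os <- cfg$head$output_size
      feats <- matrix(0, nrow(rois), os * os * cfg$backbone$d)
      rcaches <- vector("list", nrow(rois))
      for (i in seq_len(nrow(rois))) {
        ra <- roi_align_fwd(levels[[lvl[i]]], rois[i, , drop = FALSE],
                            os, level_strides()[lvl[i]], 2L)
        feats[i, ] <- as.numeric(ra$y)
        rcaches[[i]] <- ra$cache
      }
      hf <- head_net_fwd(model$params$head, feats)
      nfg <- n_wbc_classes()
      labels <- ifelse(smp$label == "pos",
                       gt_classes[smp$gt] + 1L, nfg + 1L)
      ce <- softmax_ce(hf$cls_logits, labels)
      losses["head_cls"] <- ce$loss
      dcls <- lw$head_cls * ce$dlogits
      dreg <- matrix(0, nrow(rois), 4L * nfg)
      posi <- which(smp$label == "pos")
      if (length(posi)) {
        tgt <- as.matrix(encode_deltas(rois[posi, , drop = FALSE],
                                       gt_boxes[smp$gt[posi], , drop = FALSE]))
        cols <- (gt_classes[smp$gt[posi]]) * 4L  # 0-based class offset
        pred <- t(vapply(seq_along(posi), function(ii)
          hf$reg[posi[ii], cols[ii] + 1:4], numeric(4L)))
        sl <- smooth_l1(pred, tgt, norm = 4L * length(posi))
        losses["head_box"] <- sl$loss
        for (ii in seq_along(posi)) {
          dreg[posi[ii], cols[ii] + 1:4] <- lw$head_box * sl$dpred[ii, ]
        }
      }
      dfeats <- head_net_bwd(hf$cache, dcls, dreg)
      for (i in seq_len(nrow(rois))) {
        dpatch <- array(dfeats[i, ], c(os, os, cfg$backbone$d))
        dlev[[lvl[i]]] <- dlev[[lvl[i]]] + roi_align_bwd(rcaches[[i]], dpatch)
      }
    }
  }

  # ---- actor-critic localizer episode on one ground-truth object ----
  if (run_localizer && nrow(gt_boxes) > 0L) {
    gi <- if (nrow(gt_boxes) == 1L) 1L else sample.int(nrow(gt_boxes), 1L)
    ep <- actor_critic_episode(
      levels[[1L]], gt_boxes[gi, , drop = FALSE], gt_classes[gi],
      model$params$localizer, model$attention_cfg,
      stride = level_strides()[1L], image_size = c(H, W),
      anchors = anchor_config(cfg$anchors$scales[1:2], cfg$anchors$ratios),
      train = TRUE)
    # the policy-gradient terms are far noisier than the supervised ones;
    # clip them at the same per-tensor norm the dedicated refinement
    # trainer uses, and damp them by their loss weight, so they cannot
    # swamp the shared update
    locp <- collect_params(model$params$localizer)
    clip_grads(locp, 2)
    for (p in locp) p$g <- p$g * lw$ac_policy
    losses["ac_policy"] <- -sum(ep$rewards)
    vals <- vapply(ep$steps, `[[`, numeric(1L), "value")
    losses["ac_value"] <- mean((vals - sum(ep$rewards))^2)
  }

  # ---- backbone/pyramid backward from the accumulated level gradients ----
  if (identical(cfg$backbone$use_levels, "P")) {
    pyramid_bwd(py$cache, dN = NULL, dP = dlev)
  } else {
    pyramid_bwd(py$cache, dN = dlev)
  }
  losses
}

read_image_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  px[, , 1:3, drop = FALSE]
}

# Ground truth of one image from a coco_dataset, in pixel box coordinates.
gt_for_image <- function(ds, image_id) {
  a <- ds$annotations[ds$annotations$image_id == image_id, , drop = FALSE]
  list(boxes = boxes(a$x, a$y, a$x + a$w, a$y + a$h),
       classes = a$category_id - 1L)
}

#' Train the detector
#'
#' Joint SGD-with-momentum training of all loss terms. The run is a
#' deterministic function of the configuration seed: identical seeds give
#' identical loss trajectories on CPU. Structured JSON-line logs
#' (iteration, loss terms) go to `<out_dir>/train_log.jsonl`; the final
#' checkpoint, a config snapshot and the seed are written alongside.
#' Periodic held-out evaluation runs every `train$eval_every` iterations
#' when an evaluation split is supplied.
#'
#' @param cfg Run configuration ([default_config()] / [load_config()]).
#' @param dataset A `coco_dataset` for training; alternatively set
#'   `image_dir` + in-dir `annotations.json`.
#' @param image_dir Directory holding the PNG files.
#' @param eval_dataset Optional held-out `coco_dataset` for periodic AP50
#'   snapshots (shares `image_dir`).
#' @param out_dir Output directory (checkpoint, logs); `NULL` disables
#'   writing.
#' @param iterations Override of `cfg$train$iterations`.
#' @param model Optionally continue training an existing model.
#' @return The trained `wbc_model`, with attribute `"history"` (data frame
#'   of per-iteration losses) and `"eval_history"`.
#' @export
train <- function(cfg = default_config(), dataset = NULL, image_dir = NULL,
                  eval_dataset = NULL, out_dir = NULL, iterations = NULL,
                  model = NULL) {
  if (is.null(dataset)) {
    stopifnot(!is.null(image_dir))
    dataset <- read_coco(file.path(image_dir, "annotations.json"))
  }
  if (nrow(dataset$images) == 0L) stop("empty training split", call. = FALSE)
  iterations <- if (is.null(iterations)) cfg$train$iterations else iterations
  if (is.null(model)) model <- wbc_model(cfg)
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
    log_con <- file(file.path(out_dir, "train_log.jsonl"), open = "w")
    on.exit(close(log_con), add = TRUE)
  }
  # image cache (tiny datasets fit comfortably in memory)
  imgs <- new.env(parent = emptyenv())
  get_img <- function(id) {
    key <- as.character(id)
    if (is.null(imgs[[key]])) {
      fn <- dataset$images$file_name[dataset$images$id == id]
      imgs[[key]] <- read_image_png(file.path(image_dir, fn))
    }
    imgs[[key]]
  }
  history <- vector("list", iterations)
  eval_history <- list()
  local_seed(cfg$seed, {
    for (it in seq_len(iterations)) {
      zero_grads(model$plist)
      ids <- dataset$images$id[sample.int(nrow(dataset$images),
                                          min(cfg$train$batch_images,
                                              nrow(dataset$images)))]
      acc <- NULL
      for (id in ids) {
        gt <- gt_for_image(dataset, id)
        ls <- train_step_image(model, get_img(id), gt$boxes, gt$classes,
                               run_localizer =
                                 (it %% cfg$train$localizer_every) == 0L)
        acc <- if (is.null(acc)) ls else acc + ls
      }
      acc <- acc / length(ids)
      if (!all(is.finite(acc))) {
        stop("non-finite loss at iteration ", it, ": ",
             paste(names(acc), signif(acc, 4), collapse = ", "), call. = FALSE)
      }
      sgd_step(model$plist, cfg$train$lr, cfg$train$momentum,
               cfg$train$weight_decay,
               clip = if (is.null(cfg$train$grad_clip)) Inf else
                 cfg$train$grad_clip)
      history[[it]] <- c(iteration = it, total = sum(acc), acc)
      if (!is.null(log_con) && (it %% cfg$train$log_every == 0L || it == 1L)) {
        writeLines(jsonlite::toJSON(as.list(history[[it]]), auto_unbox = TRUE),
                   log_con)
      }
      if (!is.null(eval_dataset) && cfg$train$eval_every > 0L &&
          it %% cfg$train$eval_every == 0L) {
        ev <- evaluate_model(model, eval_dataset, image_dir)
        eval_history[[length(eval_history) + 1L]] <-
          cbind(data.frame(iteration = it), ev)
        if (!is.null(log_con)) {
          writeLines(jsonlite::toJSON(list(iteration = it, AP50 = ev$AP50),
                                      auto_unbox = TRUE), log_con)
        }
      }
    }
  })
  if (!is.null(out_dir)) {
    save_checkpoint(model, file.path(out_dir, "checkpoint.rds"))
    writeLines(as.character(cfg$seed), file.path(out_dir, "seed.txt"))
  }
  attr(model, "history") <- do.call(rbind, lapply(history, function(h)
    as.data.frame(as.list(h))))
  attr(model, "eval_history") <- if (length(eval_history))
    do.call(rbind, eval_history) else NULL
  model
}

#' Detect cells in one image
#'
#' Pyramid forward pass, RPN proposals, RoIAlign head scoring, then
#' thresholding and multi-class NMS. Each proposal contributes one
#' candidate per foreground class (score = that class's softmax
#' probability, box = the class-specific refined box). Optionally the
#' attention localizer's greedily refined box is added to the candidate
#' pool before NMS.
#'
#' @param model A `wbc_model`.
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param score_threshold Confidence cut (default from config; the
#'   deployment default is 0.7).
#' @param use_localizer Union the localizer's refined box into the
#'   candidate pool (default from config).
#' @return Detection data frame.
#' @export
detect_image <- function(model, img,
                         score_threshold = model$cfg$detect$score_threshold,
                         use_localizer = model$cfg$detect$use_localizer) {
  cfg <- model$cfg
  H <- dim(img)[1L]; W <- dim(img)[2L]
  py <- pyramid_fwd(model$params, img)
  levels <- consumed_levels(model, py)
  props <- rpn_forward(model, levels, c(H, W), train = FALSE)
  raw <- detections()
  if (nrow(props)) {
    rois <- props[, c("x1", "y1", "x2", "y2"), drop = FALSE]
    lvl <- assign_roi_levels(rois, length(levels), cfg$head$canonical_size)
    os <- cfg$head$output_size
    feats <- matrix(0, nrow(rois), os * os * cfg$backbone$d)
    for (i in seq_len(nrow(rois))) {
      feats[i, ] <- as.numeric(roi_align(levels[[lvl[i]]],
                                         rois[i, , drop = FALSE],
                                         os, level_strides()[lvl[i]], 2L))
    }
    hf <- head_forward(model, feats)
    nfg <- n_wbc_classes()
    cand <- list()
    for (cl in seq_len(nfg)) {
      d <- matrix(hf$deltas[, (cl - 1L) * 4L + 1:4], ncol = 4L)
      colnames(d) <- c("tx", "ty", "tw", "th")
      bb <- decode_deltas(rois, d)
      cand[[cl]] <- detections(bb, class_id = rep(cl - 1L, nrow(bb)),
                               score = hf$scores[, cl])
    }
    raw <- do.call(rbind, cand)
  }
  if (isTRUE(use_localizer)) {
    lcand <- localizer_candidates(model, levels, c(H, W))
    if (!is.null(lcand)) raw <- rbind(raw, lcand)
  }
  postprocess_detections(raw, image_size = c(H, W),
                         score_threshold = score_threshold,
                         nms_iou = cfg$detect$nms_iou)
}

# Inference-time localizer refinement: greedy episode from the pinpoint
# proposal, classified by the localizer's own class head.
localizer_candidates <- function(model, levels, image_size) {
  cfg <- model$cfg
  lp <- model$params$localizer
  acfg <- attention_config_from(cfg)
  state <- attention_state_init(lp, acfg)
  state <- glimpse_step(state, levels[[1L]], lp, acfg)
  pp <- pinpoint_proposals(state$alpha, level_strides()[1L],
                           anchor_config(cfg$anchors$scales[1:2],
                                         cfg$anchors$ratios),
                           image_size)
  if (!nrow(pp)) return(NULL)
  peak <- attr(pp, "peak")
  b <- pp[1L, , drop = FALSE]
  for (t in seq_len(acfg$steps)) {
    if (t > 1L) state <- glimpse_step(state, levels[[1L]], lp, acfg)
    z <- policy_input(state$context, b, peak, image_size, levels[[1L]],
                      level_strides()[1L])
    pol <- policy_forward(lp, z, acfg)
    nb <- decode_deltas(b, matrix(pol$mean, 1L))
    cl <- clip_boxes(nb, image_size[2L], image_size[1L])
    if (!cl$degenerate[1L]) b <- cl$boxes
  }
  z <- policy_input(state$context, b, peak, image_size, levels[[1L]],
                    level_strides()[1L])
  logits <- as.numeric(matrix(z, 1L) %*% lp$cls$W$v) + as.numeric(lp$cls$b$v)
  p <- softmax_vec(logits)
  detections(b, class_id = which.max(p) - 1L, score = max(p))
}

#' Detect cells in a directory of images
#'
#' @param model A `wbc_model`.
#' @param image_dir Directory of PNG files (or a `coco_dataset` +
#'   `image_dir` to fix ids).
#' @param dataset Optional `coco_dataset` supplying image ids/file names;
#'   otherwise files are enumerated and ids assigned in name order.
#' @param ... Passed to [detect_image()].
#' @return Detection data frame with `image_id`.
#' @export
detect_images <- function(model, image_dir, dataset = NULL, ...) {
  if (is.null(dataset)) {
    files <- sort(list.files(image_dir, pattern = "\\.png$"))
    meta <- data.frame(id = seq_along(files), file_name = files)
  } else {
    meta <- dataset$images
  }
  out <- list()
  for (i in seq_len(nrow(meta))) {
    img <- read_image_png(file.path(image_dir, meta$file_name[i]))
    d <- detect_image(model, img, ...)
    if (nrow(d)) { d$image_id <- meta$id[i]; out[[length(out) + 1L]] <- d }
  }
  if (!length(out)) return(detections(image_id = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Evaluate a model on a COCO dataset
#'
#' Runs detection at the evaluation score threshold (low, as usual for AP
#' computation) and scores against the dataset's annotations.
#'
#' @param model A `wbc_model`.
#' @param dataset A `coco_dataset`.
#' @param image_dir Directory holding the dataset's PNGs.
#' @param ... Passed to [evaluate_dataset()].
#' @return See [evaluate_dataset()].
#' @export
evaluate_model <- function(model, dataset, image_dir, ...) {
  dets <- detect_images(model, image_dir, dataset,
                        score_threshold = model$cfg$detect$eval_score_threshold)
  a <- dataset$annotations
  gt <- boxes(a$x, a$y, a$x + a$w, a$y + a$h)
  gt$class_id <- a$category_id - 1L
  gt$image_id <- a$image_id
  gt$area <- a$area
  evaluate_dataset(dets, gt, ...)
}

#' Draw detections on an image
#'
#' Renders 2-pixel box outlines color-coded by class (no text; the legend
#' is the class order of [wbc_classes()]).
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param dets Detection data frame.
#' @return The annotated image array.
#' @export
draw_detections <- function(img, dets) {
  pal <- matrix(c(0.89, 0.10, 0.11,  0.22, 0.49, 0.72,  0.30, 0.69, 0.29,
                  0.60, 0.31, 0.64,  1.00, 0.50, 0.00,  0.65, 0.34, 0.16,
                  0.20, 0.20, 0.20), ncol = 3L, byrow = TRUE)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  for (i in seq_len(nrow(dets))) {
    col <- pal[dets$class_id[i] + 1L, ]
    x1 <- max(1L, round(dets$x1[i]) + 1L); x2 <- min(W, round(dets$x2[i]))
    y1 <- max(1L, round(dets$y1[i]) + 1L); y2 <- min(H, round(dets$y2[i]))
    if (x2 <= x1 || y2 <= y1) next
    for (ch in 1:3) {
      img[y1:min(y1 + 1L, y2), x1:x2, ch] <- col[ch]
      img[max(y2 - 1L, y1):y2, x1:x2, ch] <- col[ch]
      img[y1:y2, x1:min(x1 + 1L, x2), ch] <- col[ch]
      img[y1:y2, max(x2 - 1L, x1):x2, ch] <- col[ch]
    }
  }
  img
}
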