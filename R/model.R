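#' Detector model and run configuration
#'
#' A `wbc_model` bundles every parameter group (backbone, top-down and
#' bottom-up pyramid, RPN, RoI head, attention localizer) with the run
#' configuration. Two presets exist: the full mode mirrors the published
#' training settings (800-pixel short edge, mini-batches of two images,
#' 30,000 SGD iterations), while the tiny mode keeps the identical
#' five-stage / two-pathway topology at small channel widths and image
#' sizes so training and tests run in minutes on one CPU.
#'
#' @name app
NULL

#' Default run configuration
#'
#' @param tiny Use the CPU-scale preset (small widths, 128-px images,
#'   2,000-iteration default budget); otherwise the full preset
#'   (30,000 iterations, 800-px short edge).
#' @param seed Integer seed; fixed and logged by every entry point.
#' @return Nested configuration list.
#' @export
default_config <- function(tiny = TRUE, seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    tiny = tiny,
    image = list(target_short_edge = if (tiny) 128L else 800L,
                 resize = FALSE),
    backbone = list(widths = if (tiny) c(8L, 8L, 16L, 16L, 32L)
                    else c(64L, 256L, 512L, 1024L, 2048L),
                    d = if (tiny) 16L else 256L,
                    use_levels = "N"),
    anchors = list(scales = if (tiny) c(12, 24, 48, 96) else c(32, 64, 128, 256),
                   ratios = c(0.5, 1, 2)),
    rpn = list(nms_iou = 0.7,
               pre_nms_train = if (tiny) 300L else 2000L,
               pre_nms_test = if (tiny) 200L else 1000L,
               top_n_train = if (tiny) 120L else 1000L,
               top_n_test = if (tiny) 80L else 300L,
               batch = 64L, pos_iou = 0.7, neg_iou = 0.3),
    head = list(output_size = 7L, hidden = 64L, batch = 32L,
                pos_iou = 0.7, neg_iou = 0.3, add_gt_proposals = TRUE,
                canonical_size = if (tiny) 24 else 224),
    detect = list(score_threshold = 0.7, nms_iou = 0.5,
                  eval_score_threshold = 0.05, use_localizer = FALSE),
    attention = list(d_k = if (tiny) 16L else 64L, d_v = 16L, d_h = 16L,
                     beta = 1, mode = "masked", steps = 8L, tau = 0.5,
                     eta = 1.0, policy_sd = 0.2, gamma = 0.9),
    train = list(iterations = if (tiny) 2000L else 30000L,
                 batch_images = 2L,
                 lr = 0.02 * 2 / 16,   # base 0.02 scaled by the mini-batch
                 momentum = 0.9, weight_decay = 1e-4, grad_clip = 5,
                 loss_weights = list(rpn_obj = 1, rpn_box = 1,
                                     head_cls = 1, head_box = 1,
                                     ac_policy = 0.2, ac_value = 0.2),
                 localizer_every = 1L,
                 eval_every = 0L,       # 0 = only at the end
                 log_every = 10L))
  cfg
}

# deep-merge override list into base config
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a YAML run configuration
#'
#' Keys present in the file override the [default_config()] preset chosen
#' by its `tiny` key (default `TRUE`).
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  ov <- yaml::read_yaml(path)
  tiny <- if (is.null(ov$tiny)) TRUE else isTRUE(ov$tiny)
  seed <- if (is.null(ov$seed)) 1L else as.integer(ov$seed)
  merge_config(default_config(tiny = tiny, seed = seed), ov)
}

attention_config_from <- function(cfg) {
  a <- cfg$attention
  attention_config(d_k = a$d_k, d_v = a$d_v, d_h = a$d_h, beta = a$beta,
                   mode = a$mode, steps = a$steps, tau = a$tau, eta = a$eta,
                   policy_sd = a$policy_sd, gamma = a$gamma)
}

#' Build a detector model
#'
#' All parameters are initialized from the configuration seed, so two
#' models built from the same configuration are identical.
#'
#' @param cfg Configuration list from [default_config()] or [load_config()].
#' @return A `wbc_model` list with `params`, `cfg` and the flattened
#'   parameter list used by the optimizer.
#' @export
wbc_model <- function(cfg = default_config()) {
  bcfg <- backbone_config(cfg$backbone$widths, cfg$backbone$d,
                          cfg$backbone$use_levels)
  acfg <- attention_config_from(cfg)
  params <- local_seed(cfg$seed, {
    list(backbone = backbone_init(bcfg),
         fpn = fpn_init(bcfg),
         bottom_up = bu_init(bcfg),
         rpn = rpn_init(cfg$backbone$d, length(cfg$anchors$ratios)),
         head = head_init(cfg$backbone$d, cfg$head$output_size,
                          cfg$head$hidden, n_wbc_classes() + 1L),
         localizer = localizer_init(cfg$backbone$d, acfg))
  })
  m <- list(params = params, cfg = cfg, attention_cfg = acfg,
            plist = collect_params(params))
  class(m) <- "wbc_model"
  m
}

#' @export
print.wbc_model <- function(x, ...) {
  n <- sum(vapply(x$plist, function(p) length(p$v), numeric(1L)))
  cat(sprintf("wbc_model: %d parameters in %d tensors (%s mode)\n",
              n, length(x$plist), if (isTRUE(x$cfg$tiny)) "tiny" else "full"))
  invisible(x)
}

#' Save / load model checkpoints
#'
#' Checkpoints store the configuration and every parameter value (plain R
#' lists, serialized with `saveRDS`).
#'
#' @param model A `wbc_model`.
#' @param path Checkpoint file.
#' @return `path` invisibly; `load_checkpoint` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  vals <- lapply(model$plist, function(p) p$v)
  saveRDS(list(cfg = model$cfg, values = vals, format = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path, call. = FALSE)
  ck <- readRDS(path)
  if (!is.list(ck) || is.null(ck$cfg) || is.null(ck$values)) {
    stop("incompatible checkpoint format: ", path, call. = FALSE)
  }
  model <- wbc_model(ck$cfg)
  if (!setequal(names(model$plist), names(ck$values))) {
    stop("incompatible checkpoint: parameter sets differ", call. = FALSE)
  }
  for (nm in names(ck$values)) model$plist[[nm]]$v <- ck$values[[nm]]
  model
}

consumed_levels <- function(model, py) {
  if (identical(model$cfg$backbone$use_levels, "P")) py$P else py$N
}

level_strides <- function() c(4, 8, 16, 32)
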