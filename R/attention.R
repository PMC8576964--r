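#' Soft-attention bounding-box localization with actor-critic refinement
#'
#' The localizer attends over one pyramid level: every feature position
#' (augmented with its normalized 2-d coordinates) is projected to a key and
#' a value; the query is the hidden state of a GRU. Scaled dot-product
#' attention produces weights `alpha` and a context vector; an LSTM consumes
#' the weighted-feature stream and the GRU updates the query from the LSTM
#' output. A proposal generator emits anchor-shaped boxes at the position of
#' the highest attention weight; the local search ranks candidate boxes by
#' IoU against ground truth, and an actor-critic agent then refines the
#' chosen box with a Gaussian policy over box deltas, rewarded by the IoU
#' improvement per step and a terminal bonus when the box is classified
#' correctly and overlaps ground truth beyond a threshold.
#'
#' @name attention_localizer
NULL

#' Attention localizer configuration
#'
#' @param d_k Query/key dimension.
#' @param d_v Value (context vector) dimension.
#' @param d_h LSTM hidden dimension.
#' @param beta Scalar scale factor applied to the attention logits.
#' @param mode `"masked"` (default): masked positions are excluded before a
#'   single softmax, receiving exactly zero weight. `"literal"`: the weights
#'   are `softmax(beta * softmax(QK'/sqrt(d_k)) * M)` — a second softmax
#'   over the mask-multiplied normalized weights, which never yields exact
#'   zeros (retained for fidelity to the printed equations).
#' @param steps Glimpse/refinement budget `T` per episode.
#' @param tau Termination IoU threshold.
#' @param eta Terminal bonus added to the reward on successful termination.
#' @param policy_sd Standard deviation of the Gaussian policy over the four
#'   box-delta parameters.
#' @param gamma Discount factor for the critic's TD target.
#' @param delta_cap Magnitude cap on the policy mean (via `cap * tanh`).
#' @return An `attention_config` list.
#' @export
attention_config <- function(d_k = 16L, d_v = 16L, d_h = 16L, beta = 1,
                             mode = c("masked", "literal"), steps = 8L,
                             tau = 0.5, eta = 1.0, policy_sd = 0.2,
                             gamma = 0.9, delta_cap = 0.5) {
  stopifnot(d_k >= 1L, beta > 0, tau > 0, tau < 1, steps >= 1L,
            policy_sd > 0)
  structure(list(d_k = as.integer(d_k), d_v = as.integer(d_v),
                 d_h = as.integer(d_h), beta = beta,
                 mode = match.arg(mode), steps = as.integer(steps),
                 tau = tau, eta = eta, policy_sd = policy_sd,
                 gamma = gamma, delta_cap = delta_cap),
            class = "attention_config")
}

softmax_masked <- function(logits, mask) {
  logits[!mask] <- -Inf
  m <- max(logits)
  e <- exp(logits - m)
  e[!mask] <- 0
  e / sum(e)
}

#' Scaled dot-product attention
#'
#' Masked mode: `alpha = softmax over unmasked positions of
#' beta * Q K' / sqrt(d_k)`; masked positions get exactly zero weight.
#' Literal mode: `beta_alpha = beta * softmax(Q K' / sqrt(d_k))` over all
#' positions, then `alpha = softmax(beta_alpha * M)`. In both modes the
#' context vector is `alpha' V`.
#'
#' @param Q Query vector of length `d_k`.
#' @param K `n x d_k` key matrix.
#' @param V `n x d_v` value matrix.
#' @param M Binary validity mask over the `n` positions (default all valid);
#'   at least one position must be unmasked.
#' @param beta Scalar logit scale.
#' @param mode `"masked"` or `"literal"`.
#' @return List with `alpha` (length `n`, summing to 1) and `context`
#'   (length `d_v`).
#' @export
scaled_attention <- function(Q, K, V, M = NULL, beta = 1,
                             mode = c("masked", "literal")) {
  mode <- match.arg(mode)
  r <- attention_fwd(Q, K, V, M, beta, mode)
  list(alpha = r$alpha, context = r$context)
}

attention_fwd <- function(Q, K, V, M = NULL, beta = 1, mode = "masked") {
  stopifnot(is.matrix(K), is.matrix(V), nrow(K) == nrow(V))
  d_k <- ncol(K)
  if (length(Q) != d_k) stop("Q must have the key dimension ", d_k, call. = FALSE)
  if (is.null(M)) M <- rep(1, nrow(K))
  if (length(M) != nrow(K)) stop("mask length must match the key count", call. = FALSE)
  mask <- M > 0
  if (!any(mask)) stop("all positions are masked", call. = FALSE)
  logits <- as.numeric(K %*% Q) / sqrt(d_k)
  if (mode == "masked") {
    alpha <- softmax_masked(beta * logits, mask)
    s1 <- NULL
  } else {
    s1 <- softmax_vec(logits)
    alpha <- softmax_vec(beta * s1 * M)
  }
  context <- as.numeric(crossprod(V, alpha))
  list(alpha = alpha, context = context,
       cache = list(Q = Q, K = K, V = V, M = M, mask = mask, beta = beta,
                    mode = mode, alpha = alpha, s1 = s1, d_k = d_k))
}

# Backward pass: given gradients on the context (and optionally on alpha),
# return gradients on Q, K, V.
attention_bwd <- function(cache, dcontext, dalpha = NULL) {
  with(cache, {
    da <- as.numeric(V %*% dcontext)
    if (!is.null(dalpha)) da <- da + dalpha
    dV <- outer(alpha, dcontext)
    softmax_jvp <- function(p, dp) p * (dp - sum(p * dp))
    if (mode == "masked") {
      ds <- softmax_jvp(alpha, da)   # exact zeros stay zero at masked entries
      dlogits <- beta * ds
    } else {
      dba <- softmax_jvp(alpha, da) * M        # grad on beta * s1 * M
      ds1 <- beta * dba
      dlogits <- softmax_jvp(s1, ds1)
    }
    dlogits <- dlogits / sqrt(d_k)
    dQ <- as.numeric(crossprod(K, dlogits))
    dK <- outer(dlogits, Q)
    list(dQ = dQ, dK = dK, dV = dV)
  })
}

localizer_init <- function(c_in, cfg) {
  din <- c_in + 2L  # features + normalized (x, y) position encoding
  # agent input: context + 2x2 RoI features of the current box +
  # box geometry (4) + attention-peak offset (2)
  zdim <- cfg$d_v + 4L * c_in + 6L
  # the policy head starts near zero so the initial greedy policy is a
  # no-op on the box; refinement is learned, never a random drift
  list(Wk = par_linear(din, cfg$d_k), Wv = par_linear(din, cfg$d_v),
       q0 = par_new(cfg$d_k, sd = 0.5),
       lstm = lstm_params(cfg$d_v, cfg$d_h),
       gru = gru_params(cfg$d_h, cfg$d_k),
       pol = list(W = par_new(c(zdim, 4L), sd = 0.01), b = par_const(4L)),
       val = list(W = par_new(c(zdim, 1L), sd = 0.05), b = par_const(1L)),
       cls = list(W = par_new(c(zdim, n_wbc_classes()), sd = 0.05),
                  b = par_const(n_wbc_classes())))
}

# Flatten a feature map into the attention input matrix X = [features, px, py]
# (column-major position order, i.e. index = i + (j-1) * h). Features are
# RMS-normalized per map so the attention logits stay in a stable range
# regardless of the backbone's activation scale.
attention_inputs <- function(feats) {
  h <- dim(feats)[1L]; w <- dim(feats)[2L]; C <- dim(feats)[3L]
  X <- matrix(feats, h * w, C)
  X <- X / (sqrt(mean(X^2)) + 1e-6)
  px <- rep((seq_len(w) - 0.5) / w, each = h)
  py <- rep((seq_len(h) - 0.5) / h, times = w)
  cbind(X, px, py)
}

#' Initialize the recurrent attention state
#'
#' @param lp Localizer parameter list (internal; from a [wbc_model()] as
#'   `model$params$localizer`).
#' @param cfg An [attention_config()].
#' @param box Optional starting box.
#' @return An `attention_state` list: query `q` (the GRU hidden state),
#'   LSTM `h`/`c`, attention map `alpha`, `context`, current `box`, step `t`.
#' @export
attention_state_init <- function(lp, cfg, box = NULL) {
  structure(list(q = as.numeric(lp$q0$v), h = rep(0, cfg$d_h),
                 c = rep(0, cfg$d_h), alpha = NULL, context = NULL,
                 box = box, t = 0L),
            class = "attention_state")
}

#' One glimpse: attend, then advance the recurrent stream
#'
#' Keys and values are projections of the flattened feature positions plus
#' their normalized coordinates; attention uses the current query; the LSTM
#' consumes the context vector and the GRU updates the query from the LSTM
#' output. Deterministic given parameters and state.
#'
#' @param state An `attention_state`.
#' @param feats One pyramid-level feature map (`h x w x C`).
#' @param lp Localizer parameters.
#' @param cfg An [attention_config()].
#' @param M Optional validity mask over the `h * w` positions.
#' @param keep_cache Retain caches for backpropagation.
#' @return The advanced `attention_state`; `alpha` is an `h x w` matrix
#'   summing to 1.
#' @export
glimpse_step <- function(state, feats, lp, cfg, M = NULL, keep_cache = FALSE) {
  h <- dim(feats)[1L]; w <- dim(feats)[2L]
  X <- attention_inputs(feats)
  K <- X %*% lp$Wk$v
  V <- X %*% lp$Wv$v
  at <- attention_fwd(state$q, K, V, M, cfg$beta, cfg$mode)
  ls <- lstm_fwd(at$context, state$h, state$c, lp$lstm)
  gr <- gru_fwd(ls$h, state$q, lp$gru)
  out <- state
  out$q <- gr$h
  out$h <- ls$h; out$c <- ls$c
  out$alpha <- matrix(at$alpha, h, w)
  out$context <- at$context
  out$t <- state$t + 1L
  if (keep_cache) {
    out$cache <- list(X = X, at = at$cache, lstm = ls$cache, gru = gr$cache,
                      q_in = state$q)
  }
  out
}

#' Anchor-shaped proposals at the attention peak
#'
#' The spatial argmax of `alpha` (ties broken row-major, top-left first) is
#' mapped to the pixel center `((j + 0.5) * stride, (i + 0.5) * stride)`
#' and one box per configured anchor shape is emitted there.
#'
#' @param alpha `h x w` attention-weight matrix.
#' @param stride Pixels per feature cell.
#' @param cfg An [anchor_config()].
#' @param image_size Optional `c(height, width)`; boxes are clipped when
#'   given (degenerate clips are dropped).
#' @return Box data frame with `k` rows (fewer if clipping drops some).
#' @export
pinpoint_proposals <- function(alpha, stride, cfg, image_size = NULL) {
  stopifnot(is.matrix(alpha))
  peak <- which(alpha == max(alpha), arr.ind = TRUE)
  peak <- peak[order(peak[, 1L], peak[, 2L]), , drop = FALSE][1L, ]  # row-major tie
  i <- peak[[1L]] - 1L; j <- peak[[2L]] - 1L
  cx <- (j + 0.5) * stride; cy <- (i + 0.5) * stride
  shapes <- expand.grid(ratio = cfg$ratios, scale = cfg$scales)
  ws <- shapes$scale / sqrt(shapes$ratio)
  hs <- shapes$scale * sqrt(shapes$ratio)
  b <- boxes(cx - ws / 2, cy - hs / 2, cx + ws / 2, cy + hs / 2)
  if (!is.null(image_size)) {
    cl <- clip_boxes(b, image_size[2L], image_size[1L])
    b <- cl$boxes[!cl$degenerate, , drop = FALSE]
    rownames(b) <- NULL
  }
  attr(b, "peak") <- c(x = cx, y = cy)
  b
}

#' Rank candidate boxes by IoU against ground truth
#'
#' Each RoI is assigned the ground-truth box it overlaps most; the list is
#' sorted by that IoU, descending, stable for ties (input order preserved).
#'
#' @param rois Nonempty box data frame.
#' @param gt_boxes Ground-truth box data frame (may be empty: all IoUs 0,
#'   original order kept).
#' @return `rois` with added columns `gt` (assigned row in `gt_boxes`, `NA`
#'   when empty) and `iou`, sorted by `iou` descending.
#' @export
rank_rois_by_iou <- function(rois, gt_boxes) {
  stopifnot(nrow(rois) >= 1L)
  out <- rois
  if (nrow(gt_boxes) == 0L) {
    out$gt <- NA_integer_
    out$iou <- 0
    return(out)
  }
  iom <- box_iou(rois, gt_boxes)
  out$gt <- apply(iom, 1L, which.max)
  out$iou <- apply(iom, 1L, max)
  out <- out[order(-out$iou, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

policy_forward <- function(lp, z, cfg) {
  u <- as.numeric(matrix(z, 1L) %*% lp$pol$W$v) + as.numeric(lp$pol$b$v)
  list(mean = cfg$delta_cap * tanh(u), u = u)
}

gaussian_logpdf <- function(x, mean, sd) {
  sum(stats::dnorm(x, mean, sd, log = TRUE))
}

# Build the policy/value/class input from the localizer state and the
# RoI-aligned features of the *current* box (the agent senses the box's own
# appearance, so its refinements are box-conditional rather than static).
# The context and RoI blocks are RMS-normalized so the heads see inputs of
# stable scale whatever the backbone's activation magnitude; the scales are
# treated as constants in the backward pass and returned for it.
policy_input <- function(context, b, peak, image_size, feats, stride) {
  H <- image_size[1L]; W <- image_size[2L]
  cx <- (b$x1 + b$x2) / 2; cy <- (b$y1 + b$y2) / 2
  bw <- b$x2 - b$x1; bh <- b$y2 - b$y1
  ctx_scale <- sqrt(mean(context^2)) + 1e-6
  roi <- as.numeric(roi_align(feats, b, output_size = 2L, stride = stride,
                              sampling = 1L))
  roi <- roi / (sqrt(mean(roi^2)) + 1e-6)
  z <- c(context / ctx_scale, roi, cx / W, cy / H, bw / W, bh / H,
         (peak[1L] - cx) / W, (peak[2L] - cy) / H)
  attr(z, "ctx_scale") <- ctx_scale
  z
}

#' Run one attention-localizer episode on a single ground-truth object
#'
#' The episode glimpses the feature map, generates pinpoint proposals at
#' the attention peak (merged with any caller-supplied `proposals`), ranks
#' them by IoU against the ground truth and starts from the top-ranked box.
#' At every step the actor samples a box-delta from a Gaussian policy
#' conditioned on the context vector, the current box geometry and the
#' attention-peak offset; the reward is the IoU improvement
#' `IoU(b_t) - IoU(b_{t-1})`. The episode terminates early when the
#' predicted class matches the ground truth and the IoU reaches `tau`
#' (adding the terminal bonus `eta`), or at the step budget. The critic is
#' a TD(0) value baseline; with `train = TRUE` the advantage-weighted
#' policy gradient, value gradient and (terminal-step only) classification
#' gradient are accumulated into the localizer parameters.
#'
#' @param feats One pyramid-level feature map.
#' @param gt_box Single-row ground-truth box data frame.
#' @param gt_class Ground-truth class id (0-based).
#' @param lp Localizer parameters (`model$params$localizer`).
#' @param cfg An [attention_config()].
#' @param stride Stride of `feats`.
#' @param image_size `c(height, width)` in pixels.
#' @param anchors An [anchor_config()] for the pinpoint proposals.
#' @param proposals Optional extra candidate start boxes.
#' @param init_box Optional explicit start box (skips proposal ranking).
#' @param train Accumulate gradients (requires `gt_box`).
#' @param greedy Use the policy mean instead of sampling.
#' @return List with `initial_box`, `final_box`, `initial_iou`, `final_iou`,
#'   `terminated`, `rewards`, `ious`, `steps` (per-step records) and
#'   `pred_class` at the last step.
#' @export
actor_critic_episode <- function(feats, gt_box, gt_class, lp, cfg, stride,
                                 image_size, anchors = anchor_config(16, c(0.5, 1, 2)),
                                 proposals = NULL, init_box = NULL,
                                 train = FALSE, greedy = FALSE) {
  state <- attention_state_init(lp, cfg)
  state <- glimpse_step(state, feats, lp, cfg, keep_cache = train)
  pp <- pinpoint_proposals(state$alpha, stride, anchors, image_size)
  peak <- attr(pp, "peak")
  if (is.null(init_box)) {
    cand <- if (is.null(proposals)) pp else rbind(pp, proposals[, c("x1", "y1", "x2", "y2")])
    ranked <- rank_rois_by_iou(cand, gt_box)
    init_box <- ranked[1L, c("x1", "y1", "x2", "y2")]
  }
  b <- init_box
  iou_prev <- iou(b, gt_box)
  initial_iou <- iou_prev
  rewards <- numeric(); ious <- numeric()
  steps <- list()
  terminated <- FALSE
  pred_class <- NA_integer_
  for (t in seq_len(cfg$steps)) {
    if (t > 1L) state <- glimpse_step(state, feats, lp, cfg, keep_cache = train)
    z <- policy_input(state$context, b, peak, image_size, feats, stride)
    pol <- policy_forward(lp, z, cfg)
    delta <- if (greedy) pol$mean else
      stats::rnorm(4L, pol$mean, cfg$policy_sd)
    value <- as.numeric(matrix(z, 1L) %*% lp$val$W$v) + as.numeric(lp$val$b$v)
    cls_logits <- as.numeric(matrix(z, 1L) %*% lp$cls$W$v) + as.numeric(lp$cls$b$v)
    pred_class <- which.max(cls_logits) - 1L
    nb <- decode_deltas(b, matrix(delta, 1L))
    cl <- clip_boxes(nb, image_size[2L], image_size[1L])
    if (!cl$degenerate[1L]) nb <- cl$boxes else nb <- b
    iou_new <- iou(nb, gt_box)
    r <- iou_new - iou_prev
    done <- (pred_class == gt_class) && (iou_new >= cfg$tau)
    if (done) r <- r + cfg$eta
    steps[[t]] <- list(z = z, delta = delta, pol = pol, value = value,
                       cls_logits = cls_logits, reward = r,
                       cache = state$cache, box = b)
    rewards <- c(rewards, r)
    ious <- c(ious, iou_new)
    b <- nb
    iou_prev <- iou_new
    if (done) { terminated <- TRUE; break }
  }
  if (train) localizer_backward(steps, gt_class, lp, cfg)
  list(initial_box = init_box, final_box = b,
       initial_iou = initial_iou, final_iou = iou_prev,
       terminated = terminated, rewards = rewards, ious = ious,
       pred_class = pred_class, steps = steps,
       alpha = state$alpha)
}

# Accumulate actor-critic gradients for one episode. The critic is trained
# toward its TD(0) target; the actor weights the score function by the
# baseline-subtracted discounted return (clipped for stability). Recurrence
# is truncated at one step: the query gradient propagates through the GRU
# and LSTM of its own step but not further back in time.
localizer_backward <- function(steps, gt_class, lp, cfg) {
  n <- length(steps)
  values <- vapply(steps, `[[`, numeric(1L), "value")
  rewards <- vapply(steps, `[[`, numeric(1L), "reward")
  returns <- numeric(n)
  acc <- 0
  for (t in rev(seq_len(n))) {
    acc <- rewards[t] + cfg$gamma * acc
    returns[t] <- acc
  }
  # episode-normalized advantages: zero mean, unit scale — keeps the score
  # function centered so the policy is attracted to relatively better
  # actions instead of repelled from everything
  adv_raw <- returns - values
  advs <- adv_raw - mean(adv_raw)
  s <- stats::sd(advs)
  if (is.finite(s) && s > 1e-8) advs <- advs / s
  advs <- pmax(pmin(advs, 2), -2)
  for (t in seq_len(n)) {
    st <- steps[[t]]
    target <- rewards[t] + if (t < n) cfg$gamma * values[t + 1L] else 0
    adv <- advs[t]
    dz <- numeric(length(st$z))
    # critic: 0.5 * (V - td_target)^2
    dV <- values[t] - target
    lp$val$W$g <- lp$val$W$g + outer(st$z, dV)
    lp$val$b$g <- lp$val$b$g + dV
    dz <- dz + as.numeric(lp$val$W$v) * dV
    # actor: -adv * log pi(delta | mean, sd)
    dmean <- -adv * (st$delta - st$pol$mean) / cfg$policy_sd^2
    du <- dmean * cfg$delta_cap * (1 - tanh(st$pol$u)^2)
    lp$pol$W$g <- lp$pol$W$g + outer(st$z, du)
    lp$pol$b$g <- lp$pol$b$g + du
    dz <- dz + as.numeric(lp$pol$W$v %*% du)
    # classification cross-entropy, terminal step only
    if (t == n) {
      p <- softmax_vec(st$cls_logits)
      dlog <- p
      dlog[gt_class + 1L] <- dlog[gt_class + 1L] - 1
      lp$cls$W$g <- lp$cls$W$g + outer(st$z, dlog)
      lp$cls$b$g <- lp$cls$b$g + dlog
      dz <- dz + as.numeric(lp$cls$W$v %*% dlog)
    }
    # context part of z flows back through attention and the recurrence
    dctx <- dz[seq_len(cfg$d_v)] / attr(st$z, "ctx_scale")
    cache <- st$cache
    if (is.null(cache)) next
    ab <- attention_bwd(cache$at, dctx)
    lp$Wk$g <- lp$Wk$g + crossprod(cache$X, ab$dK)
    lp$Wv$g <- lp$Wv$g + crossprod(cache$X, ab$dV)
    if (t == 1L) {
      lp$q0$g <- lp$q0$g + ab$dQ
    } else {
      # the query consumed at step t was produced by step t-1's GRU/LSTM
      gb <- gru_bwd(steps[[t - 1L]]$cache$gru, ab$dQ)
      lstm_bwd(steps[[t - 1L]]$cache$lstm, gb$dx)
      # truncated here: no further propagation back in time
    }
  }
  invisible(NULL)
}

#' Train the localizer with actor-critic episodes
#'
#' Iterates single-object episodes over the supplied (features, ground
#' truth) instances, accumulating gradients per episode and applying SGD
#' updates.
#'
#' @param lp Localizer parameters.
#' @param instances List of instances, each
#'   `list(feats, gt_box, gt_class, stride, image_size)`.
#' @param cfg An [attention_config()].
#' @param episodes Number of episodes.
#' @param lr,momentum SGD hyperparameters.
#' @param anchors Anchor shapes for pinpoint proposals.
#' @return Invisible data frame of per-episode summaries (`initial_iou`,
#'   `final_iou`, `terminated`, `return`).
#' @export
train_localizer <- function(lp, instances, cfg, episodes = 2000L,
                            lr = 3e-4, momentum = 0.9,
                            anchors = anchor_config(16, c(0.5, 1, 2))) {
  plist <- collect_params(lp)
  for (p in plist) p$m[] <- 0   # fresh momentum for the refinement phase
  log <- vector("list", episodes)
  for (e in seq_len(episodes)) {
    inst <- instances[[((e - 1L) %% length(instances)) + 1L]]
    zero_grads(plist)
    ep <- actor_critic_episode(inst$feats, inst$gt_box, inst$gt_class, lp, cfg,
                               stride = inst$stride,
                               image_size = inst$image_size,
                               anchors = anchors,
                               proposals = inst$proposals, train = TRUE)
    sgd_step(plist, lr, momentum, weight_decay = 1e-3, clip = 2)
    log[[e]] <- data.frame(initial_iou = ep$initial_iou,
                           final_iou = ep$final_iou,
                           terminated = ep$terminated,
                           return_ = sum(ep$rewards))
  }
  invisible(do.call(rbind, log))
}

#' Write episode traces as JSON lines (debugging aid)
#'
#' @param episode Result of [actor_critic_episode()].
#' @param path File to append one JSON line per step to.
#' @return `path`, invisibly.
#' @export
write_episode_trace <- function(episode, path) {
  con <- file(path, open = "a")
  on.exit(close(con))
  for (t in seq_along(episode$steps)) {
    st <- episode$steps[[t]]
    rec <- list(t = t, box = as.numeric(st$box),
                delta = as.numeric(st$delta), reward = st$reward,
                value = st$value, iou = episode$ious[t])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
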