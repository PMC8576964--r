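test_that("orthogonal query gives uniform weights and the mean of values", {
  set.seed(30)
  K <- matrix(0, 5, 4)           # all logits zero
  V <- matrix(rnorm(20), 5, 4)
  r <- scaled_attention(rnorm(4), K, V)
  expect_equal(r$alpha, rep(0.2, 5))
  expect_equal(r$context, colMeans(V), tolerance = 1e-12)
})

test_that("a one-hot mask selects exactly the unmasked value row", {
  set.seed(31)
  K <- matrix(rnorm(24), 6, 4); V <- matrix(rnorm(18), 6, 3)
  r <- scaled_attention(rnorm(4), K, V, M = c(0, 0, 1, 0, 0, 0))
  expect_equal(r$alpha, c(0, 0, 1, 0, 0, 0))
  expect_equal(r$context, V[3, ])
})

test_that("the two-key hand case reproduces alpha = (0.25, 0.75)", {
  d_k <- 4
  Q <- c(1, 0, 0, 0)
  # scaled logits (0, ln 3): K %*% Q / sqrt(d_k) must equal (0, log(3))
  K <- rbind(c(0, 0, 0, 0), c(log(3) * sqrt(d_k), 0, 0, 0))
  V <- rbind(c(1, 0), c(0, 1))
  r <- scaled_attention(Q, K, V, beta = 1, mode = "masked")
  expect_equal(r$alpha, c(0.25, 0.75))
  expect_equal(r$context, c(0.25, 0.75))
})

test_that("masked mode zeroes masked positions; literal mode never does", {
  set.seed(32)
  K <- matrix(rnorm(32), 8, 4); V <- matrix(rnorm(16), 8, 2); Q <- rnorm(4)
  M <- c(1, 1, 0, 1, 0, 1, 1, 1)
  rm_ <- scaled_attention(Q, K, V, M, mode = "masked")
  expect_identical(rm_$alpha[M == 0], c(0, 0))
  expect_equal(sum(rm_$alpha), 1, tolerance = 1e-6)
  rl <- scaled_attention(Q, K, V, M, mode = "literal")
  expect_true(all(rl$alpha > 0))
  expect_equal(sum(rl$alpha), 1, tolerance = 1e-6)
})

test_that("invalid attention inputs raise errors", {
  K <- matrix(rnorm(8), 2, 4); V <- matrix(rnorm(4), 2, 2)
  expect_error(scaled_attention(rnorm(4), K, V, M = c(0, 0)), "masked")
  expect_error(scaled_attention(rnorm(3), K, V), "dimension")
  expect_error(scaled_attention(rnorm(4), K, V, M = c(1, 1, 1)), "length")
})

test_that("attention gradients agree with finite differences", {
  set.seed(33)
  for (mode in c("masked", "literal")) {
    K <- matrix(rnorm(20), 5, 4); V <- matrix(rnorm(15), 5, 3); Q <- rnorm(4)
    M <- c(1, 1, 1, 0, 1)
    t_ <- rnorm(3)
    fw <- wbcdetect:::attention_fwd(Q, K, V, M, beta = 1.3, mode = mode)
    bw <- wbcdetect:::attention_bwd(fw$cache, t_)
    f <- function(Q2, K2, V2) {
      sum(wbcdetect:::attention_fwd(Q2, K2, V2, M, 1.3, mode)$context * t_)
    }
    eps <- 1e-6
    for (i in 1:4) {
      qp <- Q; qp[i] <- qp[i] + eps; qm <- Q; qm[i] <- qm[i] - eps
      expect_equal(bw$dQ[i], (f(qp, K, V) - f(qm, K, V)) / (2 * eps),
                   tolerance = 1e-5)
    }
    for (i in c(1, 7, 12)) {
      kp <- K; kp[i] <- kp[i] + eps; km <- K; km[i] <- km[i] - eps
      expect_equal(bw$dK[i], (f(Q, kp, V) - f(Q, km, V)) / (2 * eps),
                   tolerance = 1e-5)
      vp <- V; vp[i] <- vp[i] + eps; vm <- V; vm[i] <- vm[i] - eps
      expect_equal(bw$dV[i], (f(Q, K, vp) - f(Q, K, vm)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("glimpses are deterministic and keep alpha normalized", {
  m <- tiny_model()
  acfg <- m$attention_cfg
  lp <- m$params$localizer
  feats <- wbcdetect:::pyramid_fwd(m$params, tiny_image()$image)$N$N2
  s0 <- attention_state_init(lp, acfg)
  s1 <- glimpse_step(s0, feats, lp, acfg)
  s1b <- glimpse_step(s0, feats, lp, acfg)
  expect_identical(s1[c("q", "h", "c", "alpha", "context")],
                   s1b[c("q", "h", "c", "alpha", "context")])
  expect_equal(sum(s1$alpha), 1, tolerance = 1e-6)
  s2 <- glimpse_step(s1, feats, lp, acfg)
  expect_equal(sum(s2$alpha), 1, tolerance = 1e-6)
  expect_equal(s2$t, 2L)
  expect_false(identical(s1$q, s2$q))
})

test_that("pinpoint proposals center every shape at the attention peak", {
  alpha <- matrix(0, 6, 8)
  alpha[3, 5] <- 1   # 0-based (i, j) = (2, 4)
  pp <- pinpoint_proposals(alpha, stride = 4,
                           cfg = anchor_config(c(8, 16), c(0.5, 1, 2)))
  expect_equal(nrow(pp), 6L)
  expect_equal((pp$x1 + pp$x2) / 2, rep((4 + 0.5) * 4, 6))
  expect_equal((pp$y1 + pp$y2) / 2, rep((2 + 0.5) * 4, 6))
  # uniform alpha: row-major tie rule selects position (0, 0)
  pp0 <- pinpoint_proposals(matrix(1 / 12, 3, 4), stride = 4,
                            cfg = anchor_config(8, 1))
  expect_equal((pp0$x1 + pp0$x2) / 2, 2)
  expect_equal((pp0$y1 + pp0$y2) / 2, 2)
})

test_that("IoU ranking matches a brute-force sort and keeps tie order", {
  gt <- boxes(10, 10, 30, 30)
  rois <- rbind(boxes(20, 20, 40, 40), boxes(10, 10, 30, 29),
                boxes(80, 80, 90, 90))
  rk <- rank_rois_by_iou(rois, gt)
  expect_true(all(diff(rk$iou) <= 0))
  expect_equal(rk$iou[1], iou(boxes(10, 10, 30, 29), gt))
  set.seed(34)
  rois <- random_boxes(100)
  gts <- random_boxes(7)
  rk <- rank_rois_by_iou(rois, gts)
  iom <- box_iou(rois, gts)
  ref_iou <- apply(iom, 1, max)
  ord <- order(-ref_iou, seq_along(ref_iou))
  expect_equal(rk$iou, ref_iou[ord])
  expect_equal(rk$gt, apply(iom, 1, which.max)[ord])
  # empty ground truth: zeros, original order
  rk0 <- rank_rois_by_iou(rois, boxes())
  expect_equal(rk0$iou, rep(0, 100))
  expect_equal(as.matrix(rk0[, 1:4]), as.matrix(rois), ignore_attr = TRUE)
})

test_that("episode rewards telescope to the IoU difference plus the bonus", {
  m <- tiny_model()
  acfg <- m$attention_cfg
  lp <- m$params$localizer
  ai <- tiny_image()
  feats <- wbcdetect:::pyramid_fwd(m$params, ai$image)$N$N2
  set.seed(35)
  for (rep in 1:12) {
    gi <- sample.int(nrow(ai$boxes), 1)
    ep <- actor_critic_episode(feats, ai$boxes[gi, ], ai$class_id[gi],
                               lp, acfg, stride = 4, image_size = c(128, 128))
    bonus <- if (ep$terminated) acfg$eta else 0
    expect_equal(sum(ep$rewards) - bonus, ep$final_iou - ep$initial_iou,
                 tolerance = 1e-9)
    if (ep$terminated) {
      expect_gte(ep$final_iou, acfg$tau)
      expect_equal(ep$pred_class, ai$class_id[gi])
    } else {
      expect_length(ep$rewards, acfg$steps)
    }
  }
})

test_that("episode traces dump as JSON lines", {
  m <- tiny_model()
  ai <- tiny_image()
  feats <- wbcdetect:::pyramid_fwd(m$params, ai$image)$N$N2
  set.seed(36)
  ep <- actor_critic_episode(feats, ai$boxes[1, ], ai$class_id[1],
                             m$params$localizer, m$attention_cfg,
                             stride = 4, image_size = c(128, 128))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_episode_trace(ep, path)
  lines <- readLines(path)
  expect_length(lines, length(ep$steps))
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$t, 1)
  expect_length(rec$delta, 4L)
})
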