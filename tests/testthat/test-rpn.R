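test_that("anchors sit at half-stride centers with area-preserving shapes", {
  a <- generate_anchors(c(1, 1), 16, anchor_config(scales = 16, ratios = 1))
  expect_equal(nrow(a), 1L)
  expect_equal(unlist(a), c(x1 = 0, y1 = 0, x2 = 16, y2 = 16))
  a <- generate_anchors(c(50, 50), 8, anchor_config(scales = c(16, 32, 64),
                                                    ratios = c(0.5, 1, 2)))
  expect_equal(nrow(a), 22500L)
  a2 <- generate_anchors(c(1, 1), 16, anchor_config(scales = 20, ratios = 2))
  w <- a2$x2 - a2$x1; h <- a2$y2 - a2$y1
  expect_equal(w * h, 400, tolerance = 1e-6)
  expect_equal(h / w, 2, tolerance = 1e-6)
})

test_that("anchor counts follow h*w*k for random shapes", {
  set.seed(21)
  for (rep in 1:20) {
    h <- sample(1:12, 1); w <- sample(1:12, 1)
    ns <- sample(1:3, 1); nr <- sample(1:3, 1)
    cfg <- anchor_config(scales = runif(ns, 8, 64), ratios = runif(nr, 0.5, 2))
    expect_equal(nrow(generate_anchors(c(h, w), 4, cfg)), h * w * cfg$k)
  }
})

test_that("proposal selection clips, bounds and orders deterministically", {
  m <- tiny_model()
  py <- wbcdetect:::pyramid_fwd(m$params, tiny_image()$image)
  pr <- rpn_forward(m, py$N, c(128, 128), train = FALSE)
  expect_lte(nrow(pr), m$cfg$rpn$top_n_test)
  expect_true(all(pr$x1 >= 0 & pr$y1 >= 0 & pr$x2 <= 128 & pr$y2 <= 128))
  expect_true(all(diff(pr$score) <= 1e-12))
  expect_true(all(pr$x2 > pr$x1 & pr$y2 > pr$y1))
  pr2 <- rpn_forward(m, py$N, c(128, 128), train = FALSE)
  expect_identical(pr, pr2)
})

test_that("a top-N larger than the candidate pool returns every candidate", {
  cfg <- default_config(tiny = TRUE, seed = 2)
  cfg$rpn$pre_nms_test <- 5L
  cfg$rpn$top_n_test <- 10000L
  cfg$rpn$nms_iou <- 0.99
  m <- wbc_model(cfg)
  py <- wbcdetect:::pyramid_fwd(m$params, tiny_image()$image)
  pr <- rpn_forward(m, py$N, c(128, 128), train = FALSE)
  expect_lte(nrow(pr), 4L * 5L)
  expect_gt(nrow(pr), 0L)
})

test_that("training-time sampling follows the 0.7/0.3 interval rule", {
  gt <- boxes(10, 10, 30, 30)
  props <- rbind(
    boxes(10, 10, 30, 29),   # IoU 0.95 -> positive
    boxes(10, 16, 30, 36),   # IoU ~0.54 -> ignored
    boxes(60, 60, 80, 80))   # IoU 0 -> negative
  s <- sample_proposals_for_training(props, gt, batch_size = 8)
  expect_equal(s$label[s$idx == 1], "pos")
  expect_false(2 %in% s$idx)
  expect_equal(s$label[s$idx == 3], "neg")
  expect_equal(s$gt[s$idx == 1], 1L)
})

test_that("positives cap at half the batch and negatives fill 1:1", {
  set.seed(5)
  gt <- boxes(40, 40, 60, 60)
  pos <- perturb_boxes(gt[rep(1, 10), ], 0.01, 0.01)  # all IoU > 0.9
  neg <- random_boxes(50, lim = 30)                   # disjoint from gt
  props <- rbind(pos, neg)
  s <- sample_proposals_for_training(props, gt, batch_size = 20)
  expect_equal(sum(s$label == "pos"), 10L)
  expect_equal(sum(s$label == "neg"), 10L)
})

test_that("every ground truth's best proposal is force-included", {
  gt <- rbind(boxes(10, 10, 20, 20), boxes(70, 70, 90, 90))
  props <- rbind(boxes(11, 11, 21, 21),   # best for gt 1 (IoU < 0.7)
                 boxes(60, 60, 95, 95))   # best for gt 2 (IoU < 0.7)
  s <- sample_proposals_for_training(props, gt, batch_size = 4)
  expect_setequal(s$idx[s$label == "pos"], c(1L, 2L))
})

test_that("labels are exclusive and invariant to proposal order", {
  set.seed(6)
  gt <- rbind(boxes(20, 20, 45, 45), boxes(60, 10, 80, 35))
  props <- rbind(perturb_boxes(gt[c(1, 1, 2), ], 0.05, 0.05),
                 random_boxes(30, lim = 100))
  s1 <- sample_proposals_for_training(props, gt, batch_size = 1000)
  expect_false(any(duplicated(s1$idx)))
  perm <- sample(nrow(props))
  s2 <- sample_proposals_for_training(props[perm, , drop = FALSE], gt,
                                      batch_size = 1000)
  lab1 <- character(nrow(props)); lab1[s1$idx] <- s1$label
  lab2 <- character(nrow(props)); lab2[perm[s2$idx]] <- s2$label
  # positive/negative status per proposal does not depend on input order
  # (subsampling can drop different negatives, so compare positives and
  # the labeled status where both sampled)
  expect_identical(which(lab1 == "pos"), sort(which(lab2 == "pos")))
})

test_that("an unlabelable pool returns an empty sample with a warning", {
  gt <- boxes(10, 10, 30, 30)
  props <- boxes(10, 15, 30, 35)  # IoU ~0.54: ignored, but still forced
  # force-inclusion keeps the best match, so use two ignored proposals where
  # one is forced; drop to a case with empty proposals instead
  expect_warning(s <- sample_proposals_for_training(boxes(), gt, 8),
                 "no proposals")
  expect_equal(nrow(s), 0L)
})
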