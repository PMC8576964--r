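test_that("matching handles the canonical single-image cases", {
  gt <- detections(boxes(10, 10, 30, 30), 0L, 1)[, 1:5]
  gt$class_id <- 0L
  one <- detections(boxes(10, 10, 30, 30), 0L, 0.9)
  r <- match_detections(one, gt, 0.5)
  expect_equal(r$tp, TRUE)
  expect_equal(r$n_missed, 0L)
  two <- detections(rbind(boxes(10, 10, 30, 30), boxes(11, 11, 31, 31)),
                    c(0L, 0L), c(0.8, 0.9))
  r <- match_detections(two, gt, 0.5)
  expect_equal(r$tp, c(TRUE, FALSE))   # higher score matches first
  expect_equal(r$scores, c(0.9, 0.8))
})

test_that("matching agrees with the exhaustive reference on random instances", {
  set.seed(41)
  for (rep in 1:8) {
    dets <- random_detections(50, lim = 80, n_classes = 3, n_images = 2)
    gts <- random_detections(20, lim = 80, n_classes = 3, n_images = 2)[, -6]
    r <- match_detections(dets, gts, 0.4)
    ref <- oracle_match(dets, gts, 0.4)
    expect_identical(r$tp, ref$tp)
    expect_identical(r$n_missed, ref$n_missed)
  }
})

test_that("average precision hits the closed-form corner cases", {
  expect_equal(average_precision(c(TRUE, TRUE, TRUE), 3), 1.0)
  expect_equal(average_precision(logical(), 5), 0.0)
  expect_true(is.na(average_precision(logical(), 0)))
  # 2 ground truths, ranked detections (TP, FP): 101-point AP = 51/101
  expect_equal(average_precision(c(TRUE, FALSE), 2), 51 / 101)
})

test_that("perfect detections score 1.0 everywhere defined", {
  set.seed(42)
  gts <- random_detections(30, n_classes = 5, n_images = 3)[, -6]
  dets <- gts
  dets$score <- 1.0
  ev <- evaluate_dataset(dets, gts)
  expect_equal(ev$AP, 1.0)
  expect_equal(ev$AP50, 1.0)
  expect_equal(ev$AP75, 1.0)
  expect_equal(ev$AR, 1.0)
})

test_that("AP is monotone non-increasing in the IoU threshold", {
  set.seed(43)
  for (rep in 1:5) {
    gts <- random_detections(25, n_images = 2)[, -6]
    dets <- rbind(perturb_boxes_det(gts, 0.1), random_detections(15, n_images = 2))
    aps <- vapply(c(0.5, 0.75, 0.9), function(t)
      evaluate_dataset(dets, gts, iou_thresholds = t)$AP, numeric(1))
    expect_true(all(diff(aps) <= 1e-12))
    ev <- evaluate_dataset(dets, gts)
    expect_lte(ev$AP, ev$AP50 + 1e-12)
    expect_gte(ev$AP50, ev$AP75 - 1e-12)
  }
})

test_that("AR never decreases with a larger detection budget", {
  set.seed(44)
  gts <- random_detections(40, n_images = 2)[, -6]
  dets <- rbind(perturb_boxes_det(gts, 0.08), random_detections(60, n_images = 2))
  ar <- vapply(c(1L, 10L, 100L), function(k)
    evaluate_dataset(dets, gts, max_dets = k)$AR, numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
})

test_that("classes absent from ground truth stay undefined, not zero", {
  gts <- detections(boxes(10, 10, 30, 30), 0L, 1)[, 1:5]
  gts$class_id <- 0L
  dets <- detections(boxes(10, 10, 30, 30), 0L, 0.9)
  ev <- evaluate_dataset(dets, gts)
  expect_equal(ev$AP50, 1.0)   # a zero-filled absent class would deflate this
  ev0 <- evaluate_dataset(dets, gts, zero_fill = TRUE)
  expect_lt(ev0$AP50, 1.0)
})

test_that("full evaluation agrees with the reference implementation to 1e-6", {
  set.seed(45)
  for (rep in 1:3) {
    gts <- random_detections(30, lim = 150, n_classes = 4, n_images = 3)[, -6]
    gts$image_id <- sample.int(3, nrow(gts), replace = TRUE)
    dets <- rbind(perturb_boxes_det(gts, 0.12),
                  random_detections(40, lim = 150, n_classes = 4, n_images = 3))
    ev <- evaluate_dataset(dets, gts)
    ref <- oracle_coco_eval(dets, gts)
    for (k in c("AP", "AP50", "AP75", "APS", "APM", "APL", "AR")) {
      a <- ev[[k]]; b <- ref[[k]]
      if (is.na(b)) expect_true(is.na(a)) else expect_equal(a, b, tolerance = 1e-6)
    }
  }
})

test_that("evaluation reads COCO annotation and results files", {
  out <- withr::local_tempdir()
  ds <- generate_smear_dataset(fast_spec(seed = 11), 4L, out)
  a <- ds$annotations
  dets <- detections(boxes(a$x, a$y, a$x + a$w, a$y + a$h),
                     class_id = a$category_id - 1L,
                     score = rep(0.99, nrow(a)), image_id = a$image_id)
  res <- file.path(out, "results.json")
  write_coco_results(dets, res)
  ev <- evaluate_coco_files(file.path(out, "annotations.json"), res)
  expect_equal(ev$AP, 1.0)
})

test_that("unknown detection categories are rejected", {
  gts <- detections(boxes(0, 0, 5, 5), 0L, 1)[, 1:5]
  gts$class_id <- 0L
  bad <- detections(boxes(0, 0, 5, 5), 9L, 0.9)
  expect_error(evaluate_dataset(bad, gts))
})
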