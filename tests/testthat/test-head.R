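test_that("RoIAlign reproduces constants and the hand bilinear fixture", {
  fmap <- array(3.7, c(8, 8, 2))
  out <- roi_align(fmap, boxes(1.3, 2.1, 6.4, 7.2), output_size = 7, stride = 1)
  expect_equal(out, array(3.7, c(7, 7, 2)), tolerance = 1e-12)
  # bilinear sample of [[0,1],[2,3]] at (0.5, 0.5) is 1.5
  m <- array(c(0, 2, 1, 3), c(2, 2, 1))
  bl <- wbcdetect:::bilinear_gather(m, 0.5, 0.5)
  expect_equal(as.numeric(bl$vals), 1.5)
  expect_equal(as.numeric(wbcdetect:::bilinear_gather(m, 0, 1)$vals), 1)
})

test_that("a box on one aligned cell with single sampling returns that value", {
  fmap <- array(rnorm(36), c(6, 6, 1))
  # center of output cell = integer grid point (3, 4) (0-based x=3, y=4)
  out <- roi_align(fmap, boxes(2.5, 3.5, 3.5, 4.5), output_size = 1,
                   stride = 1, sampling = 1)
  expect_equal(as.numeric(out), fmap[5, 4, 1])
})

test_that("RoIAlign shifts smoothly with sub-pixel box movement", {
  fmap <- array(seq(0, 1, length.out = 64), c(8, 8, 1))
  a <- roi_align(fmap, boxes(2, 2, 5, 5), 2, 1)
  b <- roi_align(fmap, boxes(2.01, 2, 5.01, 5), 2, 1)
  expect_false(identical(a, b))
  expect_lt(max(abs(a - b)), 0.01)
})

test_that("RoIAlign rejects degenerate boxes", {
  fmap <- array(0, c(4, 4, 1))
  expect_error(roi_align(fmap, boxes(2, 2, 2, 5), 2, 1), "degenerate")
})

test_that("head scores are an 8-way softmax with per-class deltas", {
  m <- tiny_model()
  os <- m$cfg$head$output_size
  patch <- array(rnorm(os * os * m$cfg$backbone$d), c(os, os, m$cfg$backbone$d))
  out <- head_forward(m, patch)
  expect_equal(ncol(out$scores), 8L)
  expect_equal(sum(out$scores), 1, tolerance = 1e-6)
  expect_true(all(out$scores > 0))
  expect_equal(ncol(out$deltas), 28L)
})

test_that("a zero-weight head yields uniform scores of 1/8", {
  m <- tiny_model()
  hp <- m$params$head
  old <- list(W = hp$cls$W$v, b = hp$cls$b$v,
              f1 = hp$fc1$W$v, f2 = hp$fc2$W$v)
  hp$cls$W$v[] <- 0; hp$cls$b$v[] <- 0
  os <- m$cfg$head$output_size
  patch <- matrix(rnorm(os * os * m$cfg$backbone$d), 1)
  out <- head_forward(m, patch)
  expect_equal(as.numeric(out$scores), rep(0.125, 8), tolerance = 1e-12)
  hp$cls$W$v <- old$W; hp$cls$b$v <- old$b
})

test_that("post-processing enforces the confidence rule and class-aware NMS", {
  d <- detections(rbind(boxes(0, 0, 10, 10), boxes(0, 0, 10, 10)),
                  c(1L, 2L), c(0.65, 0.71))
  out <- postprocess_detections(d, image_size = c(50, 50))
  expect_equal(nrow(out), 1L)
  expect_equal(out$score, 0.71)
  same <- detections(rbind(boxes(0, 0, 10, 10), boxes(0, 1, 10, 11)),
                     c(1L, 1L), c(0.95, 0.8))
  expect_equal(nrow(postprocess_detections(same, c(50, 50))), 1L)
  diff <- detections(rbind(boxes(0, 0, 10, 10), boxes(0, 1, 10, 11)),
                     c(1L, 2L), c(0.95, 0.8))
  expect_equal(nrow(postprocess_detections(diff, c(50, 50))), 2L)
})

test_that("post-processing is idempotent", {
  set.seed(8)
  d <- random_detections(80)
  once <- postprocess_detections(d, c(100, 100), score_threshold = 0.3)
  twice <- postprocess_detections(once, c(100, 100), score_threshold = 0.3)
  expect_equal(once, twice)
})

test_that("counting tallies per class and conserves detections", {
  empty <- count_cells(detections())
  expect_equal(empty$total, 0)
  expect_true(all(empty$totals == 0))
  d <- detections(random_boxes(5), c(0L, 0L, 0L, 1L, 1L), rep(0.9, 5))
  rep_ <- count_cells(d)
  expect_equal(unname(rep_$totals[["Granulocyte"]]), 3)
  expect_equal(unname(rep_$totals[["Erythrocyte"]]), 2)
  expect_equal(rep_$total, 5)
  set.seed(9)
  d2 <- random_detections(40, n_classes = 7, n_images = 4)
  expect_equal(count_cells(d2)$total, nrow(d2))
})

test_that("count reports serialize to CSV with one row per image", {
  set.seed(10)
  d <- random_detections(20, n_classes = 7, n_images = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_csv(count_cells(d), path)
  csv <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(csv), length(unique(d$image_id)))
  expect_true(all(wbc_classes() %in% colnames(csv)))
  expect_equal(sum(csv$total), 20)
})

test_that("RoI level assignment is monotone in box size", {
  b <- rbind(boxes(0, 0, 8, 8), boxes(0, 0, 32, 32), boxes(0, 0, 120, 120))
  lvl <- wbcdetect:::assign_roi_levels(b, 4L, canonical_size = 24)
  expect_true(all(diff(lvl) >= 0))
  expect_equal(lvl[1], 1L)
  expect_equal(lvl[3], 4L)
})
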