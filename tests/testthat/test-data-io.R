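make_via <- function(regions_by_file) {
  files <- lapply(names(regions_by_file), function(fn) {
    list(filename = fn, size = 1L, regions = regions_by_file[[fn]])
  })
  names(files) <- paste0(names(regions_by_file), "1")
  list(`_via_img_metadata` = files)
}

test_that("an empty VIA project converts to an empty 7-category dataset", {
  ds <- via_to_coco(list(`_via_img_metadata` = list()))
  expect_equal(nrow(ds$images), 0L)
  expect_equal(nrow(ds$annotations), 0L)
  expect_equal(ds$categories$name, wbc_classes())
})

test_that("rect regions pass through and polygons take their tight bbox", {
  via <- make_via(list(
    "a.png" = list(
      list(shape_attributes = list(name = "rect", x = 10, y = 20,
                                   width = 30, height = 40),
           region_attributes = list(class = "Granulocyte")),
      list(shape_attributes = list(name = "polygon",
                                   all_points_x = list(0, 10, 0),
                                   all_points_y = list(0, 0, 20)),
           region_attributes = list(class = "Monocyte")))))
  ds <- via_to_coco(via)
  expect_equal(nrow(ds$images), 1L)
  a <- ds$annotations
  expect_equal(unlist(a[1, c("x", "y", "w", "h")]),
               c(x = 10, y = 20, w = 30, h = 40))
  expect_equal(a$category_id[1], match("Granulocyte", wbc_classes()))
  expect_equal(unlist(a[2, c("x", "y", "w", "h")]),
               c(x = 0, y = 0, w = 10, h = 20))
})

test_that("unknown class names map to Others with a warning; missing class errors", {
  via <- make_via(list(
    "a.png" = list(list(shape_attributes = list(name = "rect", x = 1, y = 1,
                                                width = 5, height = 5),
                        region_attributes = list(class = "Basophil")))))
  expect_warning(ds <- via_to_coco(via), "Others")
  expect_equal(ds$annotations$category_id, match("Others", wbc_classes()))
  via2 <- make_via(list(
    "b.png" = list(list(shape_attributes = list(name = "rect", x = 1, y = 1,
                                                width = 5, height = 5),
                        region_attributes = list()))))
  expect_error(via_to_coco(via2), "b.png")
})

test_that("VIA conversion then COCO write/read preserves annotations exactly", {
  via <- make_via(list(
    "a.png" = list(list(shape_attributes = list(name = "rect", x = 3, y = 7,
                                                width = 11, height = 13),
                        region_attributes = list(class = "Lymphocyte")))))
  ds <- via_to_coco(via)
  path <- withr::local_tempfile(fileext = ".json")
  write_coco(ds, path)
  rt <- read_coco(path)
  expect_equal(rt$annotations[, c("x", "y", "w", "h", "category_id")],
               ds$annotations[, c("x", "y", "w", "h", "category_id")])
})

test_that("short-edge resize preserves aspect and scales boxes isotropically", {
  r <- resize_with_boxes(NULL, boxes(0, 0, 10, 10), 800, size = c(800, 800))
  expect_equal(unname(r$size), c(800L, 800L))
  expect_equal(unname(r$scale), c(1, 1))
  r <- resize_with_boxes(NULL, boxes(), 800, size = c(1920, 2560))
  expect_equal(unname(r$size), c(800L, 1067L))
  expect_equal(unname(r$scale[1]), 800 / 1920)
  r <- resize_with_boxes(NULL, boxes(96, 96, 192, 192), 64, size = c(128, 128))
  expect_equal(unlist(r$boxes), c(x1 = 48, y1 = 48, x2 = 96, y2 = 96))
})

test_that("square mode forces both edges to the target", {
  r <- resize_with_boxes(NULL, boxes(0, 0, 100, 100), 100,
                         mode = "square", size = c(200, 400))
  expect_equal(unname(r$size), c(100L, 100L))
  expect_equal(unlist(r$boxes), c(x1 = 0, y1 = 0, x2 = 25, y2 = 50))
})

test_that("pixel resize halves dimensions correctly", {
  ai <- tiny_image()
  r <- resize_with_boxes(ai$image, ai$boxes, 64)
  expect_equal(dim(r$image), c(64L, 64L, 3L))
  expect_true(all(as.matrix(r$boxes) >= 0 & as.matrix(r$boxes) <= 64))
})

test_that("flip augmentation doubles everything and mirrors x coordinates", {
  ds <- tiny_dataset()
  fl <- flip_augment(ds)
  expect_equal(nrow(fl$images), 2L * nrow(ds$images))
  expect_equal(nrow(fl$annotations), 2L * nrow(ds$annotations))
  per_class <- table(factor(ds$annotations$category_id, levels = 1:7))
  per_class_fl <- table(factor(fl$annotations$category_id, levels = 1:7))
  expect_equal(as.integer(per_class_fl), 2L * as.integer(per_class))
  # x' = W - x - w, y unchanged
  n <- nrow(ds$annotations)
  orig <- ds$annotations; mirr <- fl$annotations[(n + 1):(2 * n), ]
  W <- ds$images$width[match(orig$image_id, ds$images$id)]
  expect_equal(mirr$x, W - orig$x - orig$w)
  expect_equal(mirr$y, orig$y)
})

test_that("flipping the flipped copy reproduces the original image and bbox", {
  ai <- tiny_image()
  once <- flip_image_px(ai$image, "horizontal")
  twice <- flip_image_px(once, "horizontal")
  expect_identical(twice, ai$image)
  W <- 128
  x1 <- ai$boxes$x1; w <- ai$boxes$x2 - ai$boxes$x1
  x1_back <- W - (W - x1 - w) - w
  expect_equal(x1_back, x1)
})

test_that("mirrored pixel files are written when image dirs are supplied", {
  out <- withr::local_tempdir()
  ds <- tiny_dataset()
  fl <- flip_augment(ds, image_dir = tiny_dataset_dir(), out_dir = out)
  f <- file.path(out, paste0("fliph_", ds$images$file_name[1]))
  expect_true(file.exists(f))
  orig <- png::readPNG(file.path(tiny_dataset_dir(), ds$images$file_name[1]))
  expect_equal(png::readPNG(f)[, rev(seq_len(128)), ], orig)
})

test_that("zero-angle zero-shear warp is the identity", {
  ai <- tiny_image()
  r <- rotate_shear_augment(ai$image, ai$boxes, 0, 0, class_id = ai$class_id)
  expect_identical(r$image, ai$image)
  expect_equal(r$boxes, ai$boxes, ignore_attr = TRUE)
  expect_equal(r$class_id, ai$class_id)
})

test_that("a 90-degree rotation maps the corner box as the matrix predicts", {
  r <- rotate_shear_augment(NULL, boxes(0, 0, 10, 10), angle = 90,
                            size = c(100, 100))
  expect_equal(unlist(r$boxes), c(x1 = 0, y1 = 90, x2 = 10, y2 = 100))
})

test_that("warped boxes always stay within the canvas", {
  ai <- tiny_image()
  set.seed(3)
  for (rep in 1:5) {
    r <- rotate_shear_augment(NULL, ai$boxes, angle = runif(1, -40, 40),
                              shear = runif(1, -0.3, 0.3), size = c(128, 128))
    if (nrow(r$boxes)) {
      expect_true(all(as.matrix(r$boxes) >= 0 & as.matrix(r$boxes) <= 128))
    }
  }
})

test_that("rotated pixels move where the forward map says", {
  img <- array(0, c(64, 64, 3))
  img[10, 40, ] <- 1   # row 10, col 40 -> (x, y) = (39.5, 9.5)
  r <- rotate_shear_augment(img, boxes(), angle = 90, size = c(64, 64))
  # forward map about (32, 32): (39.5, 9.5) -> (32 + (9.5-32)*? ) via A
  th <- pi / 2
  A <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  p <- c(39.5, 9.5); cen <- c(32, 32)
  q <- cen + as.numeric(A %*% (p - cen))
  hit <- which(r$image[, , 1] > 0.4, arr.ind = TRUE)
  expect_equal(unname(hit[1, ]), unname(c(ceiling(q[2]), ceiling(q[1]))))
})

test_that("image-level splitting partitions deterministically", {
  ds <- generate_smear_dataset(fast_spec(seed = 6), 10L, out_dir = NULL)
  sp <- split_dataset(ds, 0.9, seed = 4)
  expect_equal(nrow(sp$train$images), 9L)
  expect_equal(nrow(sp$test$images), 1L)
  expect_length(intersect(sp$train$images$id, sp$test$images$id), 0L)
  expect_setequal(c(sp$train$images$id, sp$test$images$id), ds$images$id)
  # annotations travel with their image
  expect_true(all(sp$train$annotations$image_id %in% sp$train$images$id))
  sp2 <- split_dataset(ds, 0.9, seed = 4)
  expect_identical(sp$train$images$id, sp2$train$images$id)
})

test_that("COCO results round-trip through the results JSON", {
  d <- random_detections(10, n_images = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_coco_results(d, path)
  rt <- read_coco_results(path)
  expect_equal(as.matrix(rt[, c("x1", "y1", "x2", "y2")]),
               as.matrix(d[, c("x1", "y1", "x2", "y2")]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rt$class_id, d$class_id)
  expect_equal(rt$image_id, d$image_id)
})
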