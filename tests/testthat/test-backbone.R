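test_that("backbone emits exactly four maps at strides 4/8/16/32", {
  m <- tiny_model()
  C <- forward_backbone(m, tiny_image()$image)
  expect_length(C, 4L)
  expect_named(C, c("C2", "C3", "C4", "C5"))
  expect_equal(unname(attr(C, "strides")), c(4, 8, 16, 32))
  sizes <- vapply(C, function(x) dim(x)[1L], integer(1L))
  expect_equal(unname(sizes), c(32L, 16L, 8L, 4L))  # 128 / stride
})

test_that("stride arithmetic follows ceil(input/stride) on odd sizes", {
  cfg <- default_config(tiny = TRUE, seed = 1)
  cfg$backbone$widths <- c(2L, 2L, 2L, 2L, 2L); cfg$backbone$d <- 2L
  m <- wbc_model(cfg)
  img <- array(0.5, c(100, 100, 3))
  C <- forward_backbone(m, img)
  expect_equal(unname(vapply(C, function(x) dim(x)[1L], integer(1L))),
               as.integer(ceiling(100 / c(4, 8, 16, 32))))
})

test_that("the five-stage config is enforced", {
  expect_error(backbone_config(widths = c(8, 8, 16)), "length")
})

test_that("top-down pyramid matches C shapes with a shared channel width", {
  m <- tiny_model()
  C <- forward_backbone(m, tiny_image()$image)
  P <- top_down_pyramid(m, C)
  expect_named(P, c("P2", "P3", "P4", "P5"))
  for (i in 1:4) {
    expect_equal(dim(P[[i]])[1:2], dim(C[[i]])[1:2])
    expect_equal(dim(P[[i]])[3L], m$cfg$backbone$d)
  }
})

test_that("nearest-neighbor upsampling duplicates each value into a 2x2 block", {
  x <- array(c(1, 3, 2, 4), c(2, 2, 1))  # [[1,2],[3,4]] in row terms
  up <- wbcdetect:::upsample2_fwd(x)
  expect_equal(dim(up), c(4L, 4L, 1L))
  expect_equal(up[1:2, 1:2, 1], matrix(1, 2, 2))
  expect_equal(up[1:2, 3:4, 1], matrix(2, 2, 2))
  expect_equal(up[3:4, 1:2, 1], matrix(3, 2, 2))
  expect_equal(up[3:4, 3:4, 1], matrix(4, 2, 2))
})

test_that("with zero laterals and identity smoothing P2 is the upsampled P5 path", {
  cfg <- default_config(tiny = TRUE, seed = 3)
  cfg$backbone$widths <- c(2L, 2L, 2L, 2L, 2L); cfg$backbone$d <- 2L
  m <- wbc_model(cfg)
  fp <- m$params$fpn
  id3 <- function(layer) {            # 3x3 conv = identity center tap
    layer$W$v[] <- 0
    for (c in seq_len(dim(layer$W$v)[3L])) layer$W$v[2, 2, c, c] <- 1
    layer$b$v[] <- 0
  }
  for (i in 2:5) id3(fp[[paste0("smooth", i)]])
  for (i in 2:4) { fp[[paste0("lat", i)]]$W$v[] <- 0; fp[[paste0("lat", i)]]$b$v[] <- 0 }
  C <- forward_backbone(m, array(runif(64 * 64 * 3), c(64, 64, 3)))
  P <- top_down_pyramid(m, C)
  up3 <- wbcdetect:::upsample2_fwd(
    wbcdetect:::upsample2_fwd(wbcdetect:::upsample2_fwd(P$P5)))
  expect_equal(P$P2, up3, tolerance = 1e-12)
})

test_that("bottom-up fusion mirrors shapes and N2 equals P2", {
  m <- tiny_model()
  C <- forward_backbone(m, tiny_image()$image)
  P <- top_down_pyramid(m, C)
  N <- bottom_up_fusion(m, P)
  expect_length(N, 4L)
  expect_identical(N$N2, P$P2)
  for (i in 1:4) expect_equal(dim(N[[i]]), dim(P[[i]]))
})

test_that("with degenerate fusion weights N_{i+1} reduces to P_{i+1}", {
  cfg <- default_config(tiny = TRUE, seed = 3)
  cfg$backbone$widths <- c(2L, 2L, 2L, 2L, 2L); cfg$backbone$d <- 2L
  m <- wbc_model(cfg)
  bu <- m$params$bottom_up
  for (i in 2:4) {
    bu[[paste0("down", i)]]$W$v[] <- 0; bu[[paste0("down", i)]]$b$v[] <- 0
    f <- bu[[paste0("fuse", i)]]
    f$W$v[] <- 0
    for (c in 1:2) f$W$v[2, 2, c, c] <- 1
    f$b$v[] <- 0
  }
  C <- forward_backbone(m, array(runif(64 * 64 * 3), c(64, 64, 3)))
  P <- top_down_pyramid(m, C)
  N <- bottom_up_fusion(m, P)
  for (i in 2:4) {
    expect_equal(N[[paste0("N", i + 1)]], P[[paste0("P", i + 1)]],
                 tolerance = 1e-12)
  }
})

test_that("forward passes are deterministic given fixed parameters", {
  m <- tiny_model()
  img <- tiny_image()$image
  a <- forward_backbone(m, img); b <- forward_backbone(m, img)
  expect_identical(a, b)
})

test_that("gradients reach the image and both fusion inputs (finite differences)", {
  set.seed(77)
  cfg <- backbone_config(widths = c(2L, 2L, 3L, 3L, 4L), d = 3L)
  params <- list(backbone = wbcdetect:::backbone_init(cfg),
                 fpn = wbcdetect:::fpn_init(cfg),
                 bottom_up = wbcdetect:::bu_init(cfg))
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  py <- wbcdetect:::pyramid_fwd(params, img)
  tN <- lapply(py$N, function(m) array(rnorm(length(m)), dim(m)))
  loss <- function(im) {
    p <- wbcdetect:::pyramid_fwd(params, im)
    sum(mapply(function(a, b) sum(a * b), p$N, tN))
  }
  dimg <- wbcdetect:::pyramid_bwd(py$cache, dN = tN)
  idx <- sample(length(img), 5)
  for (i in idx) {
    eps <- 1e-5
    ip <- img; ip[i] <- ip[i] + eps
    im2 <- img; im2[i] <- im2[i] - eps
    expect_equal(dimg[i], (loss(ip) - loss(im2)) / (2 * eps), tolerance = 1e-4)
  }
  # a loss on N5 reaches both the bottom-up predecessor path (via down/fuse
  # convolutions) and the top-down P path (lateral weights)
  pl <- wbcdetect:::collect_params(params)
  wbcdetect:::zero_grads(pl)
  dN5 <- wbcdetect:::zero_like_levels(py$N)
  dN5$N5 <- array(1, dim(py$N$N5))
  wbcdetect:::pyramid_bwd(py$cache, dN = dN5)
  expect_gt(sum(abs(pl[["bottom_up.down4.W"]]$g)), 0)
  expect_gt(sum(abs(pl[["fpn.lat5.W"]]$g)), 0)
  expect_gt(sum(abs(pl[["backbone.stem.W"]]$g)), 0)
})
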