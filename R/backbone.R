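#' Residual backbone and augmented feature pyramid
#'
#' A five-stage residual convolutional backbone exposes four feature maps
#' `C2..C5` at strides 4, 8, 16 and 32 (spatial sizes `ceil(input/stride)`).
#' The pyramid is built in two pathways: the classic top-down pathway with
#' lateral 1x1 connections and 3x3 anti-aliasing smoothing produces
#' `P2..P5`, and an added bottom-up fusion pathway — stride-2 3x3
#' convolution, elementwise addition with the same-resolution P level, then
#' a 3x3 convolution — produces `N2..N5`. Downstream stages (region
#' proposals, RoI head, attention localizer) consume the N levels by
#' default; a config switch routes them to the P levels instead.
#'
#' @name backbone_pyramid
NULL

#' Backbone / pyramid configuration
#'
#' @param widths Channel width per stage (length 5; tiny defaults keep the
#'   five-stage topology at CPU-friendly widths).
#' @param d Shared channel dimension of all P and N levels.
#' @param use_levels `"N"` (default) or `"P"`: which pyramid the detection
#'   stages consume.
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(widths = c(8L, 8L, 16L, 16L, 32L), d = 16L,
                            use_levels = c("N", "P")) {
  stopifnot(length(widths) == 5L, all(widths >= 1L), d >= 1L)
  structure(list(widths = as.integer(widths), d = as.integer(d),
                 use_levels = match.arg(use_levels)),
            class = "backbone_config")
}

backbone_init <- function(cfg) {
  w <- cfg$widths
  p <- list(stem = list(W = par_conv(3, 3, 3, w[1L]), b = par_const(w[1L])))
  for (i in 2:5) {
    p[[paste0("s", i)]] <- list(
      down = list(W = par_conv(3, 3, w[i - 1L], w[i]), b = par_const(w[i])),
      r1 = list(W = par_conv(3, 3, w[i], w[i]), b = par_const(w[i])),
      r2 = list(W = par_conv(3, 3, w[i], w[i]), b = par_const(w[i])))
  }
  p
}

fpn_init <- function(cfg) {
  w <- cfg$widths; d <- cfg$d
  p <- list()
  for (i in 2:5) {
    p[[paste0("lat", i)]] <- list(W = par_conv(1, 1, w[i], d), b = par_const(d))
    p[[paste0("smooth", i)]] <- list(W = par_conv(3, 3, d, d), b = par_const(d))
  }
  p
}

bu_init <- function(cfg) {
  d <- cfg$d
  p <- list()
  for (i in 2:4) {
    p[[paste0("down", i)]] <- list(W = par_conv(3, 3, d, d), b = par_const(d))
    p[[paste0("fuse", i)]] <- list(W = par_conv(3, 3, d, d), b = par_const(d))
  }
  p
}

# conv + relu helper returning combined cache
conv_relu_fwd <- function(x, layer, stride = 1L) {
  cv <- conv2d_fwd(x, layer$W, layer$b, stride)
  rl <- relu_fwd(cv$y)
  list(y = rl$y, cache = list(conv = cv$cache, mask = rl$mask))
}
conv_relu_bwd <- function(cache, dy) conv2d_bwd(cache$conv, relu_bwd(cache$mask, dy))

backbone_fwd <- function(bp, x) {
  caches <- list()
  s <- conv_relu_fwd(x, bp$stem, 2L)
  caches$stem <- s$cache
  h <- s$y
  C <- list()
  for (i in 2:5) {
    st <- bp[[paste0("s", i)]]
    dn <- conv_relu_fwd(h, st$down, 2L)
    r1 <- conv_relu_fwd(dn$y, st$r1, 1L)
    r2 <- conv2d_fwd(r1$y, st$r2$W, st$r2$b, 1L)
    sum_ <- r2$y + dn$y                      # residual connection
    rl <- relu_fwd(sum_)
    caches[[paste0("s", i)]] <- list(down = dn$cache, r1 = r1$cache,
                                     r2 = r2$cache, mask = rl$mask)
    h <- rl$y
    C[[paste0("C", i)]] <- h
  }
  list(C = C, cache = caches)
}

backbone_bwd <- function(cache, dC) {
  dh <- NULL
  for (i in 5:2) {
    ci <- cache[[paste0("s", i)]]
    d <- dC[[paste0("C", i)]]
    if (!is.null(dh)) d <- d + dh
    dsum <- relu_bwd(ci$mask, d)
    dr1 <- conv2d_bwd(ci$r2, dsum)
    ddn <- conv_relu_bwd(ci$r1, dr1) + dsum   # residual branch + skip
    dh <- conv_relu_bwd(ci$down, ddn)
  }
  invisible(conv_relu_bwd(cache$stem, dh))
}

fpn_fwd <- function(fp, C) {
  P <- list(); caches <- list()
  top <- NULL
  for (i in 5:2) {
    lat <- conv2d_fwd(C[[paste0("C", i)]],
                      fp[[paste0("lat", i)]]$W, fp[[paste0("lat", i)]]$b, 1L)
    merged <- lat$y
    up_dims <- NULL
    if (!is.null(top)) {
      up <- upsample2_fwd(top)
      up_dims <- dim(up)
      up <- crop_to(up, dim(merged)[1L], dim(merged)[2L])
      merged <- merged + up
    }
    sm <- conv2d_fwd(merged, fp[[paste0("smooth", i)]]$W,
                     fp[[paste0("smooth", i)]]$b, 1L)
    caches[[paste0("l", i)]] <- list(lat = lat$cache, smooth = sm$cache,
                                     up_dims = up_dims)
    P[[paste0("P", i)]] <- sm$y
    top <- merged
  }
  list(P = P[paste0("P", 2:5)], cache = caches)
}

fpn_bwd <- function(cache, dP) {
  dC <- list()
  dmerged_up <- NULL  # gradient flowing down the top-down pathway
  for (i in 2:5) {
    ci <- cache[[paste0("l", i)]]
    dmerged <- conv2d_bwd(ci$smooth, dP[[paste0("P", i)]])
    if (!is.null(dmerged_up)) dmerged <- dmerged + dmerged_up
    dC[[paste0("C", i)]] <- conv2d_bwd(ci$lat, dmerged)
    if (!is.null(ci$up_dims)) {
      dup <- array(0, ci$up_dims)
      dup[seq_len(dim(dmerged)[1L]), seq_len(dim(dmerged)[2L]), ] <- dmerged
      dmerged_up <- upsample2_bwd(dup)
    } else {
      dmerged_up <- NULL
    }
  }
  dC
}

bottom_up_fwd <- function(bu, P) {
  N <- list(N2 = P$P2)
  caches <- list()
  for (i in 2:4) {
    dn <- conv2d_fwd(N[[paste0("N", i)]],
                     bu[[paste0("down", i)]]$W, bu[[paste0("down", i)]]$b, 2L)
    s <- dn$y + P[[paste0("P", i + 1L)]]
    fu <- conv2d_fwd(s, bu[[paste0("fuse", i)]]$W, bu[[paste0("fuse", i)]]$b, 1L)
    caches[[paste0("l", i)]] <- list(down = dn$cache, fuse = fu$cache)
    N[[paste0("N", i + 1L)]] <- fu$y
  }
  list(N = N, cache = caches)
}

bottom_up_bwd <- function(cache, dN) {
  dP <- list()
  dn_carry <- NULL
  for (i in 4:2) {
    ci <- cache[[paste0("l", i)]]
    d_next <- dN[[paste0("N", i + 1L)]]
    if (!is.null(dn_carry)) d_next <- d_next + dn_carry
    ds <- conv2d_bwd(ci$fuse, d_next)
    dP[[paste0("P", i + 1L)]] <- ds
    dn_carry <- conv2d_bwd(ci$down, ds)
  }
  d2 <- dN$N2
  if (!is.null(dn_carry)) d2 <- d2 + dn_carry
  dP$P2 <- d2
  dP
}

#' Run the backbone on an image
#'
#' @param model A detector model from [wbc_model()].
#' @param image `H x W x 3` numeric array in `[0, 1]`. Dimensions need not
#'   be divisible by 32; sizes follow `ceil(input / stride)`.
#' @return Named list of four feature maps `C2, C3, C4, C5` (arrays
#'   `h x w x channels`) with a `strides` attribute `c(4, 8, 16, 32)`.
#' @export
forward_backbone <- function(model, image) {
  out <- backbone_fwd(model$params$backbone, image)$C
  attr(out, "strides") <- c(C2 = 4, C3 = 8, C4 = 16, C5 = 32)
  out
}

#' Build the top-down pyramid from backbone features
#'
#' `P5 = smooth(lateral(C5))`; `P_i = smooth(lateral(C_i) + upsample2(P_{i+1}))`
#' with nearest-neighbor upsampling; all levels share `d` channels.
#'
#' @param model A detector model.
#' @param C Output of [forward_backbone()].
#' @return Named list `P2..P5` with a `strides` attribute.
#' @export
top_down_pyramid <- function(model, C) {
  out <- fpn_fwd(model$params$fpn, C)$P
  attr(out, "strides") <- c(P2 = 4, P3 = 8, P4 = 16, P5 = 32)
  out
}

#' Add the bottom-up fusion pathway
#'
#' `N2 = P2`; `N_{i+1} = conv3x3(conv3x3_stride2(N_i) + P_{i+1})`.
#'
#' @param model A detector model.
#' @param P Output of [top_down_pyramid()].
#' @return Named list `N2..N5` with a `strides` attribute.
#' @export
bottom_up_fusion <- function(model, P) {
  out <- bottom_up_fwd(model$params$bottom_up, P)$N
  attr(out, "strides") <- c(N2 = 4, N3 = 8, N4 = 16, N5 = 32)
  out
}

# Full pyramid forward with caches kept for training.
pyramid_fwd <- function(params, image) {
  bb <- backbone_fwd(params$backbone, image)
  fp <- fpn_fwd(params$fpn, bb$C)
  bu <- bottom_up_fwd(params$bottom_up, fp$P)
  list(C = bb$C, P = fp$P, N = bu$N,
       cache = list(bb = bb$cache, fp = fp$cache, bu = bu$cache))
}

# Backward from gradients on the consumed levels (dN and/or dP).
pyramid_bwd <- function(cache, dN = NULL, dP = NULL) {
  if (!is.null(dN)) {
    dP_from_N <- bottom_up_bwd(cache$bu, dN)
    if (is.null(dP)) {
      dP <- dP_from_N
    } else {
      for (nm in names(dP_from_N)) {
        dP[[nm]] <- if (is.null(dP[[nm]])) dP_from_N[[nm]] else
          dP[[nm]] + dP_from_N[[nm]]
      }
    }
  }
  dC <- fpn_bwd(cache$fp, dP)
  backbone_bwd(cache$bb, dC)
}

# zero-filled gradient holders shaped like a pyramid level set
zero_like_levels <- function(lv) {
  lapply(lv, function(x) array(0, dim(x)))
}
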