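#' Neural-network primitives with explicit gradients
#'
#' The detector's layers — 2-D convolution (via im2col and BLAS matrix
#' multiplication), ReLU, linear maps, nearest-neighbor upsampling, GRU and
#' LSTM cells, softmax / sigmoid losses and smooth-L1 regression — are
#' implemented directly in R, each as a forward function returning its
#' output plus a cache, with a matching backward function implementing the
#' exact analytic gradient. Parameters live in environments so gradients
#' accumulate by reference; optimization is SGD with momentum. Everything is
#' deterministic given the RNG state, which is what makes seeded training
#' runs byte-reproducible on CPU.
#'
#' @name nn
#' @keywords internal
NULL

# ---- parameters -----------------------------------------------------------

par_new <- function(dims, sd = 0.05) {
  e <- new.env(parent = emptyenv())
  e$v <- array(stats::rnorm(prod(dims), 0, sd), dims)
  e$g <- array(0, dims)
  e$m <- array(0, dims)
  e
}

par_const <- function(dims, value = 0) {
  e <- new.env(parent = emptyenv())
  e$v <- array(value, dims)
  e$g <- array(0, dims)
  e$m <- array(0, dims)
  e
}

# Kaiming-style init for a conv kernel (kh, kw, cin, cout)
par_conv <- function(kh, kw, cin, cout) {
  par_new(c(kh, kw, cin, cout), sd = sqrt(2 / (kh * kw * cin)))
}

par_linear <- function(din, dout) par_new(c(din, dout), sd = sqrt(2 / din))

zero_grads <- function(params) {
  for (p in params) p$g[] <- 0
  invisible(NULL)
}

clip_grads <- function(params, clip) {
  for (p in params) {
    gn <- sqrt(sum(p$g^2))
    if (gn > clip) p$g <- p$g * (clip / gn)
  }
  invisible(NULL)
}

sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 0,
                     clip = Inf) {
  for (p in params) {
    g <- p$g
    if (is.finite(clip)) {
      gn <- sqrt(sum(g^2))
      if (gn > clip) g <- g * (clip / gn)
    }
    if (weight_decay > 0) g <- g + weight_decay * p$v
    p$m <- momentum * p$m - lr * g
    p$v <- p$v + p$m
  }
  invisible(NULL)
}

# Flatten a nested list of parameter environments into one named list.
collect_params <- function(x, prefix = "") {
  if (is.environment(x)) return(stats::setNames(list(x), prefix))
  out <- list()
  for (nm in names(x)) {
    out <- c(out, collect_params(x[[nm]],
                                 if (nzchar(prefix)) paste0(prefix, ".", nm) else nm))
  }
  out
}

# ---- convolution ----------------------------------------------------------

# x: (H, W, Cin) array. W: (kh, kw, Cin, Cout). "same"-style padding
# pad = (k - 1) / 2 keeps sizes at ceil(H / stride).
conv2d_fwd <- function(x, w_par, b_par, stride = 1L) {
  kh <- dim(w_par$v)[1L]; kw <- dim(w_par$v)[2L]
  cin <- dim(w_par$v)[3L]; cout <- dim(w_par$v)[4L]
  H <- dim(x)[1L]; W <- dim(x)[2L]
  stopifnot(dim(x)[3L] == cin)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  Ho <- as.integer(ceiling(H / stride)); Wo <- as.integer(ceiling(W / stride))
  Hp <- (Ho - 1L) * stride + kh; Wp <- (Wo - 1L) * stride + kw
  xpad <- array(0, c(Hp, Wp, cin))
  xpad[ph + seq_len(H), pw + seq_len(W), ] <- x
  cols <- matrix(0, Ho * Wo, kh * kw * cin)
  hsel0 <- (seq_len(Ho) - 1L) * stride
  wsel0 <- (seq_len(Wo) - 1L) * stride
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      slab <- xpad[ki + hsel0, kj + wsel0, , drop = FALSE]
      cols[, ki + (kj - 1L) * kh + (seq_len(cin) - 1L) * kh * kw] <-
        matrix(slab, Ho * Wo, cin)
    }
  }
  wmat <- matrix(w_par$v, kh * kw * cin, cout)
  ymat <- cols %*% wmat
  ymat <- sweep(ymat, 2L, as.numeric(b_par$v), `+`)
  y <- array(ymat, c(Ho, Wo, cout))
  list(y = y, cache = list(cols = cols, w_par = w_par, b_par = b_par,
                           dims = c(H, W, cin, Ho, Wo, cout),
                           pad = c(ph, pw, Hp, Wp), kh = kh, kw = kw,
                           stride = stride))
}

conv2d_bwd <- function(cache, dy) {
  d <- cache$dims
  H <- d[1L]; W <- d[2L]; cin <- d[3L]; Ho <- d[4L]; Wo <- d[5L]; cout <- d[6L]
  kh <- cache$kh; kw <- cache$kw; stride <- cache$stride
  ph <- cache$pad[1L]; pw <- cache$pad[2L]; Hp <- cache$pad[3L]; Wp <- cache$pad[4L]
  dymat <- matrix(dy, Ho * Wo, cout)
  wmat <- matrix(cache$w_par$v, kh * kw * cin, cout)
  cache$w_par$g <- cache$w_par$g +
    array(crossprod(cache$cols, dymat), dim(cache$w_par$v))
  cache$b_par$g <- cache$b_par$g + colSums(dymat)
  dcols <- tcrossprod(dymat, wmat)
  dxpad <- array(0, c(Hp, Wp, cin))
  hsel0 <- (seq_len(Ho) - 1L) * stride
  wsel0 <- (seq_len(Wo) - 1L) * stride
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      slab <- array(dcols[, ki + (kj - 1L) * kh + (seq_len(cin) - 1L) * kh * kw],
                    c(Ho, Wo, cin))
      dxpad[ki + hsel0, kj + wsel0, ] <- dxpad[ki + hsel0, kj + wsel0, ] + slab
    }
  }
  dxpad[ph + seq_len(H), pw + seq_len(W), , drop = FALSE]
}

# ---- pointwise and shape ops ----------------------------------------------

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}
relu_bwd <- function(mask, dy) dy * mask

# nearest-neighbor x2 upsampling
upsample2_fwd <- function(x) {
  H <- dim(x)[1L]; W <- dim(x)[2L]
  x[rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , drop = FALSE]
}
upsample2_bwd <- function(dy) {
  H2 <- dim(dy)[1L]; W2 <- dim(dy)[2L]; C <- dim(dy)[3L]
  H <- H2 %/% 2L; W <- W2 %/% 2L
  dx <- array(0, c(H, W, C))
  for (di in 0:1) for (dj in 0:1) {
    dx <- dx + dy[seq_len(H) * 2L - di, seq_len(W) * 2L - dj, , drop = FALSE]
  }
  dx
}

# crop (used when pyramid levels differ by one cell after ceil division)
crop_to <- function(x, H, W) x[seq_len(H), seq_len(W), , drop = FALSE]

linear_fwd <- function(x, w_par, b_par) {
  xm <- if (is.matrix(x)) x else matrix(x, 1L)
  y <- xm %*% w_par$v
  y <- sweep(y, 2L, as.numeric(b_par$v), `+`)
  list(y = y, cache = list(x = xm, w_par = w_par, b_par = b_par))
}

linear_bwd <- function(cache, dy) {
  dym <- if (is.matrix(dy)) dy else matrix(dy, 1L)
  cache$w_par$g <- cache$w_par$g + crossprod(cache$x, dym)
  cache$b_par$g <- cache$b_par$g + colSums(dym)
  tcrossprod(dym, cache$w_par$v)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# rows of a matrix
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- losses ---------------------------------------------------------------

# mean cross-entropy over rows of logits; labels are 1-based class indices
softmax_ce <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

# mean binary cross-entropy on logits
sigmoid_bce <- function(logits, targets) {
  p <- sigmoid(logits)
  loss <- -mean(targets * log(pmax(p, 1e-12)) +
                (1 - targets) * log(pmax(1 - p, 1e-12)))
  list(loss = loss, dlogits = (p - targets) / length(logits), probs = p)
}

# smooth-L1 (Huber), summed over elements then divided by `norm`
smooth_l1 <- function(pred, target, beta = 1, norm = length(pred)) {
  d <- pred - target
  a <- abs(d)
  l <- ifelse(a < beta, 0.5 * d^2 / beta, a - 0.5 * beta)
  dl <- ifelse(a < beta, d / beta, sign(d))
  list(loss = sum(l) / norm, dpred = dl / norm)
}

# ---- recurrent cells ------------------------------------------------------

gru_params <- function(din, dh) {
  list(Wz = par_linear(din, dh), Uz = par_linear(dh, dh), bz = par_const(dh),
       Wr = par_linear(din, dh), Ur = par_linear(dh, dh), br = par_const(dh),
       Wn = par_linear(din, dh), Un = par_linear(dh, dh), bn = par_const(dh))
}

gru_fwd <- function(x, h, p) {
  x <- matrix(x, 1L); h <- matrix(h, 1L)
  z <- sigmoid(x %*% p$Wz$v + h %*% p$Uz$v + matrix(p$bz$v, 1L))
  r <- sigmoid(x %*% p$Wr$v + h %*% p$Ur$v + matrix(p$br$v, 1L))
  n <- tanh(x %*% p$Wn$v + (r * h) %*% p$Un$v + matrix(p$bn$v, 1L))
  h2 <- (1 - z) * n + z * h
  list(h = as.numeric(h2),
       cache = list(x = x, h = h, z = z, r = r, n = n, p = p))
}

gru_bwd <- function(cache, dh2) {
  with(cache, {
    dh2 <- matrix(dh2, 1L)
    dn <- dh2 * (1 - z)
    dz <- dh2 * (h - n)
    dh <- dh2 * z
    da_n <- dn * (1 - n^2)
    p$Wn$g <- p$Wn$g + crossprod(x, da_n)
    p$Un$g <- p$Un$g + crossprod(r * h, da_n)
    p$bn$g <- p$bn$g + as.numeric(da_n)
    drh <- tcrossprod(da_n, p$Un$v)
    dr <- drh * h
    dh <- dh + drh * r
    dx <- tcrossprod(da_n, p$Wn$v)
    da_z <- dz * z * (1 - z)
    p$Wz$g <- p$Wz$g + crossprod(x, da_z)
    p$Uz$g <- p$Uz$g + crossprod(h, da_z)
    p$bz$g <- p$bz$g + as.numeric(da_z)
    dx <- dx + tcrossprod(da_z, p$Wz$v)
    dh <- dh + tcrossprod(da_z, p$Uz$v)
    da_r <- dr * r * (1 - r)
    p$Wr$g <- p$Wr$g + crossprod(x, da_r)
    p$Ur$g <- p$Ur$g + crossprod(h, da_r)
    p$br$g <- p$br$g + as.numeric(da_r)
    dx <- dx + tcrossprod(da_r, p$Wr$v)
    dh <- dh + tcrossprod(da_r, p$Ur$v)
    list(dx = as.numeric(dx), dh = as.numeric(dh))
  })
}

lstm_params <- function(din, dh) {
  list(W = par_linear(din, 4L * dh), U = par_linear(dh, 4L * dh),
       b = par_const(4L * dh))
}

lstm_fwd <- function(x, h, c, p) {
  x <- matrix(x, 1L); h <- matrix(h, 1L)
  dh <- length(c)
  a <- x %*% p$W$v + h %*% p$U$v + matrix(p$b$v, 1L)
  i <- sigmoid(a[, seq_len(dh)])
  f <- sigmoid(a[, dh + seq_len(dh)])
  o <- sigmoid(a[, 2L * dh + seq_len(dh)])
  g <- tanh(a[, 3L * dh + seq_len(dh)])
  c2 <- f * c + i * g
  h2 <- o * tanh(c2)
  list(h = as.numeric(h2), c = as.numeric(c2),
       cache = list(x = x, h = h, c = c, i = i, f = f, o = o, g = g,
                    c2 = c2, p = p, dh = dh))
}

lstm_bwd <- function(cache, dh2, dc2 = NULL) {
  with(cache, {
    if (is.null(dc2)) dc2 <- rep(0, dh)
    tc2 <- tanh(c2)
    do <- dh2 * tc2
    dc <- dh2 * o * (1 - tc2^2) + dc2
    di <- dc * g; dg <- dc * i; df <- dc * c
    dc_prev <- dc * f
    da <- cbind(matrix(di * i * (1 - i), 1L),
                matrix(df * f * (1 - f), 1L),
                matrix(do * o * (1 - o), 1L),
                matrix(dg * (1 - g^2), 1L))
    p$W$g <- p$W$g + crossprod(x, da)
    p$U$g <- p$U$g + crossprod(h, da)
    p$b$g <- p$b$g + as.numeric(da)
    list(dx = as.numeric(tcrossprod(da, p$W$v)),
         dh = as.numeric(tcrossprod(da, p$U$v)),
         dc = as.numeric(dc_prev))
  })
}
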