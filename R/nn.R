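# Minimal neural-network layer framework with manual backpropagation.
#
# No deep-learning runtime is available in this environment, so the layers
# needed by the variational network are implemented directly: zero-padded
# convolutions (im2col + BLAS matmul), non-overlapping transposed
# convolutions (kernel == stride), average pooling, instance normalisation
# and leaky ReLU. Tensors are single-batch arrays (nx, ny, nz, channels);
# 2D networks are the special case nz == 1 with unit z kernels/strides, which
# makes the 2D and 3D variants share one code path.
#
# Layers are stateless between calls: forward returns (y, cache) and backward
# consumes the cache, so one module instance can be applied several times per
# pass (the sensitivity U-Net runs once per coil). Gradients accumulate into
# per-layer parameter environments.

new_param_env <- function(wshape, bshape = NULL, init_weights = TRUE) {
  p <- new.env(parent = emptyenv())
  p$wshape <- wshape
  p$bshape <- bshape
  if (init_weights) {
    fan_in <- prod(wshape) / wshape[length(wshape)]
    bound <- 1 / sqrt(fan_in)
    p$W <- array(stats::runif(prod(wshape), -bound, bound), wshape)
    if (!is.null(bshape)) p$b <- stats::runif(bshape, -bound, bound)
  }
  p$gW <- NULL
  p$gb <- NULL
  p
}

nn_conv <- function(c_in, c_out, ksize, bias = FALSE, init_weights = TRUE) {
  ktot <- prod(ksize)
  list(type = "conv", ksize = ksize, c_in = c_in, c_out = c_out,
       p = new_param_env(c(ktot * c_in, c_out),
                         if (bias) c_out else NULL, init_weights))
}

nn_tconv <- function(c_in, c_out, stride, init_weights = TRUE) {
  list(type = "tconv", stride = stride, c_in = c_in, c_out = c_out,
       p = new_param_env(c(c_in, c_out, prod(stride)), NULL, init_weights))
}

nn_inorm <- function() list(type = "inorm", eps = 1e-5)
nn_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope)
nn_pool <- function(stride) list(type = "pool", stride = stride)

nn_seq <- function(...) list(type = "seq", children = list(...))

# standard refinement block: two (conv 3x3(x3) -> instance norm -> LeakyReLU)
nn_convblock <- function(c_in, c_out, ksize, init_weights = TRUE) {
  nn_seq(nn_conv(c_in, c_out, ksize, init_weights = init_weights),
         nn_inorm(), nn_lrelu(),
         nn_conv(c_out, c_out, ksize, init_weights = init_weights),
         nn_inorm(), nn_lrelu())
}

# ---- im2col convolution ------------------------------------------------------

# cached flat gather indices for im2col, keyed by (n, C, ksize)
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(n, C, ksize) {
  key <- paste(c(n, C, ksize), collapse = "x")
  idx <- .im2col_cache[[key]]
  if (!is.null(idx)) return(idx)
  np <- n + ksize - 1L
  # flat position of voxel (x, y, z) at kernel offset (1,1,1), channel 1
  base <- as.vector(outer(outer(seq_len(n[1]), np[1] * (seq_len(n[2]) - 1L),
                                `+`),
                          np[1] * np[2] * (seq_len(n[3]) - 1L), `+`))
  off <- as.matrix(expand.grid(o1 = seq_len(ksize[1]) - 1L,
                               o2 = seq_len(ksize[2]) - 1L,
                               o3 = seq_len(ksize[3]) - 1L))
  o_shift <- off[, 1] + np[1] * off[, 2] + np[1] * np[2] * off[, 3]
  c_shift <- np[1] * np[2] * np[3] * (seq_len(C) - 1L)
  # column order: offset-major, channel-minor -> shift[(o-1)*C + c]
  shifts <- as.vector(t(outer(o_shift, c_shift, `+`)))
  idx <- outer(base, shifts, `+`)
  storage.mode(idx) <- "integer" # integer gather avoids coercion every call
  dim(idx) <- NULL # flat vector: a matrix index would be read as coordinates
  .im2col_cache[[key]] <- idx
  idx
}

im2col <- function(x, ksize) {
  n <- dim(x)[1:3]; C <- dim(x)[4]
  pad <- (ksize - 1L) %/% 2L
  np <- n + ksize - 1L
  padded <- array(0, c(np, C))
  padded[pad[1] + seq_len(n[1]), pad[2] + seq_len(n[2]),
         pad[3] + seq_len(n[3]), ] <- x
  X <- padded[im2col_index(n, C, ksize)]
  dim(X) <- c(prod(n), prod(ksize) * C)
  X
}

# weight matrix of the adjoint convolution: spatially flipped kernel with
# input/output channels swapped, so dX = im2col(dY) %*% conv_adjoint_w(W)
conv_adjoint_w <- function(W, c_in, c_out, ktot) {
  W3 <- array(W, c(c_in, ktot, c_out))
  Wt3 <- aperm(W3[, ktot:1, , drop = FALSE], c(3, 2, 1))
  dim(Wt3) <- c(ktot * c_out, c_in)
  Wt3
}

fwd_conv <- function(mod, x) {
  n <- dim(x)[1:3]
  X <- im2col(x, mod$ksize)
  Y <- X %*% mod$p$W
  if (!is.null(mod$p$b)) Y <- sweep(Y, 2, mod$p$b, `+`)
  dim(Y) <- c(n, mod$c_out)
  list(y = Y, cache = list(x = x, n = n))
}

bwd_conv <- function(mod, cache, dy) {
  n <- cache$n
  dY <- dy
  dim(dY) <- c(prod(n), mod$c_out)
  X <- im2col(cache$x, mod$ksize)
  gW <- crossprod(X, dY)
  mod$p$gW <- if (is.null(mod$p$gW)) gW else mod$p$gW + gW
  if (!is.null(mod$p$b)) {
    gb <- colSums(dY)
    mod$p$gb <- if (is.null(mod$p$gb)) gb else mod$p$gb + gb
  }
  # input gradient = correlation with flipped kernel (zero-padded "same")
  ktot <- prod(mod$ksize)
  dX <- im2col(dy, mod$ksize) %*% conv_adjoint_w(mod$p$W, mod$c_in,
                                                 mod$c_out, ktot)
  dim(dX) <- c(n, mod$c_in)
  dX
}

# ---- transposed convolution (kernel == stride, non-overlapping) -------------

tconv_offsets <- function(stride) {
  as.matrix(expand.grid(seq_len(stride[1]), seq_len(stride[2]),
                        seq_len(stride[3])))
}

fwd_tconv <- function(mod, x) {
  n <- dim(x)[1:3]
  s <- mod$stride
  Xmat <- matrix(x, prod(n), mod$c_in)
  out <- array(0, c(n * s, mod$c_out))
  off <- tconv_offsets(s)
  for (o in seq_len(nrow(off))) {
    Yo <- array(Xmat %*% mod$p$W[, , o], c(n, mod$c_out))
    out[seq(off[o, 1], by = s[1], length.out = n[1]),
        seq(off[o, 2], by = s[2], length.out = n[2]),
        seq(off[o, 3], by = s[3], length.out = n[3]), ] <- Yo
  }
  list(y = out, cache = list(x = x, n = n))
}

bwd_tconv <- function(mod, cache, dy) {
  n <- cache$n
  s <- mod$stride
  Xmat <- matrix(cache$x, prod(n), mod$c_in)
  dXmat <- matrix(0, prod(n), mod$c_in)
  off <- tconv_offsets(s)
  gW <- array(0, dim(mod$p$W))
  for (o in seq_len(nrow(off))) {
    dYo <- matrix(dy[seq(off[o, 1], by = s[1], length.out = n[1]),
                     seq(off[o, 2], by = s[2], length.out = n[2]),
                     seq(off[o, 3], by = s[3], length.out = n[3]), ,
                     drop = FALSE],
                  prod(n), mod$c_out)
    gW[, , o] <- crossprod(Xmat, dYo)
    dXmat <- dXmat + dYo %*% t(mod$p$W[, , o])
  }
  mod$p$gW <- if (is.null(mod$p$gW)) gW else mod$p$gW + gW
  array(dXmat, c(n, mod$c_in))
}

# ---- pooling, normalisation, activation -------------------------------------

fwd_pool <- function(mod, x) {
  n <- dim(x)[1:3]; C <- dim(x)[4]
  s <- mod$stride
  m <- n %/% s
  out <- array(0, c(m, C))
  off <- tconv_offsets(s)
  for (o in seq_len(nrow(off))) {
    out <- out + x[seq(off[o, 1], by = s[1], length.out = m[1]),
                   seq(off[o, 2], by = s[2], length.out = m[2]),
                   seq(off[o, 3], by = s[3], length.out = m[3]), ,
                   drop = FALSE]
  }
  list(y = out / nrow(off), cache = list(n = n, C = C))
}

bwd_pool <- function(mod, cache, dy) {
  s <- mod$stride
  n <- cache$n
  m <- n %/% s
  dx <- array(0, c(n, cache$C))
  off <- tconv_offsets(s)
  g <- dy / nrow(off)
  for (o in seq_len(nrow(off))) {
    dx[seq(off[o, 1], by = s[1], length.out = m[1]),
       seq(off[o, 2], by = s[2], length.out = m[2]),
       seq(off[o, 3], by = s[3], length.out = m[3]), ] <- g
  }
  dx
}

fwd_inorm <- function(mod, x) {
  d <- dim(x)
  nvox <- prod(d[1:3])
  m <- matrix(x, nvox, d[4])
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  istd <- 1 / sqrt(colMeans(xc^2) + mod$eps)
  xhat <- sweep(xc, 2, istd, `*`)
  list(y = array(xhat, d), cache = list(xhat = xhat, istd = istd, d = d))
}

bwd_inorm <- function(mod, cache, dy) {
  d <- cache$d
  g <- matrix(dy, prod(d[1:3]), d[4])
  xhat <- cache$xhat
  gm <- colMeans(g)
  gxm <- colMeans(g * xhat)
  dx <- sweep(sweep(g, 2, gm) - sweep(xhat, 2, gxm, `*`), 2, cache$istd, `*`)
  array(dx, d)
}

fwd_lrelu <- function(mod, x) {
  scale <- mod$slope + (1 - mod$slope) * (x > 0)
  list(y = x * scale, cache = list(scale = scale))
}

bwd_lrelu <- function(mod, cache, dy) {
  dy * cache$scale
}

# ---- generic dispatch --------------------------------------------------------

nn_forward <- function(mod, x) {
  switch(mod$type,
    conv = fwd_conv(mod, x),
    tconv = fwd_tconv(mod, x),
    pool = fwd_pool(mod, x),
    inorm = fwd_inorm(mod, x),
    lrelu = fwd_lrelu(mod, x),
    seq = {
      caches <- vector("list", length(mod$children))
      for (i in seq_along(mod$children)) {
        r <- nn_forward(mod$children[[i]], x)
        x <- r$y
        caches[[i]] <- r$cache
      }
      list(y = x, cache = caches)
    },
    unet = fwd_unet(mod, x),
    stop("unknown layer type ", mod$type))
}

nn_backward <- function(mod, cache, dy) {
  switch(mod$type,
    conv = bwd_conv(mod, cache, dy),
    tconv = bwd_tconv(mod, cache, dy),
    pool = bwd_pool(mod, cache, dy),
    inorm = bwd_inorm(mod, cache, dy),
    lrelu = bwd_lrelu(mod, cache, dy),
    seq = {
      for (i in rev(seq_along(mod$children))) {
        dy <- nn_backward(mod$children[[i]], cache[[i]], dy)
      }
      dy
    },
    unet = bwd_unet(mod, cache, dy),
    stop("unknown layer type ", mod$type))
}

# ---- U-Net -------------------------------------------------------------------

#' @noRd
# Encoder/decoder with `length(strides)` pooling levels, channel doubling per
# level, skip concatenations, and a final 1x1 convolution. `strides` is a
# list of per-level pooling stride vectors, top level first; the decoder
# mirrors them in reverse.
nn_unet <- function(in_ch, out_ch, chans, strides, ksize,
                    init_weights = TRUE) {
  L <- length(strides)
  down <- list(); ch <- chans
  down[[1]] <- nn_convblock(in_ch, chans, ksize, init_weights)
  if (L > 1) {
    for (l in 2:L) {
      down[[l]] <- nn_convblock(ch, ch * 2, ksize, init_weights)
      ch <- ch * 2
    }
  }
  bottleneck <- nn_convblock(ch, ch * 2, ksize, init_weights)
  ups <- list(); upblocks <- list()
  for (l in seq_len(L)) {
    st <- strides[[L - l + 1]]
    ups[[l]] <- nn_tconv(ch * 2, ch, st, init_weights)
    if (l < L) {
      upblocks[[l]] <- nn_convblock(ch * 2, ch, ksize, init_weights)
      ch <- ch %/% 2
    } else {
      upblocks[[l]] <- nn_convblock(ch * 2, ch, ksize, init_weights)
    }
  }
  final <- nn_conv(chans, out_ch, c(1L, 1L, 1L), bias = TRUE, init_weights)
  list(type = "unet", L = L, strides = strides,
       children = list(down = down, bottleneck = bottleneck, ups = ups,
                       upblocks = upblocks, final = final))
}

fwd_unet <- function(mod, x) {
  ch <- mod$children
  skips <- list(); dcaches <- list(); pcaches <- list()
  for (l in seq_len(mod$L)) {
    r <- nn_forward(ch$down[[l]], x)
    dcaches[[l]] <- r$cache
    skips[[l]] <- r$y
    pl <- nn_pool(mod$strides[[l]])
    rp <- nn_forward(pl, r$y)
    pcaches[[l]] <- rp$cache
    x <- rp$y
  }
  rb <- nn_forward(ch$bottleneck, x)
  x <- rb$y
  ucaches <- list(); ubcaches <- list(); nskip <- integer(mod$L)
  for (l in seq_len(mod$L)) {
    ru <- nn_forward(ch$ups[[l]], x)
    ucaches[[l]] <- ru$cache
    sk <- skips[[mod$L - l + 1]]
    nskip[l] <- dim(sk)[4]
    x <- abind4(ru$y, sk)
    rub <- nn_forward(ch$upblocks[[l]], x)
    ubcaches[[l]] <- rub$cache
    x <- rub$y
  }
  rf <- nn_forward(ch$final, x)
  list(y = rf$y,
       cache = list(d = dcaches, p = pcaches, b = rb$cache, u = ucaches,
                    ub = ubcaches, f = rf$cache, nskip = nskip))
}

bwd_unet <- function(mod, cache, dy) {
  ch <- mod$children
  dy <- nn_backward(ch$final, cache$f, dy)
  dskips <- vector("list", mod$L)
  for (l in rev(seq_len(mod$L))) {
    dy <- nn_backward(ch$upblocks[[l]], cache$ub[[l]], dy)
    nc <- dim(dy)[4] - cache$nskip[l]
    dsk <- dy[, , , (nc + 1):dim(dy)[4], drop = FALSE]
    dy <- dy[, , , seq_len(nc), drop = FALSE]
    dskips[[mod$L - l + 1]] <- dsk
    dy <- nn_backward(ch$ups[[l]], cache$u[[l]], dy)
  }
  dy <- nn_backward(ch$bottleneck, cache$b, dy)
  for (l in rev(seq_len(mod$L))) {
    pl <- nn_pool(mod$strides[[l]])
    dy <- nn_backward(pl, cache$p[[l]], dy)
    dy <- dy + dskips[[l]]
    dy <- nn_backward(ch$down[[l]], cache$d[[l]], dy)
  }
  dy
}

# concatenate two (nx, ny, nz, C) arrays along channels
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# ---- parameter utilities -----------------------------------------------------

collect_param_envs <- function(mod) {
  if (is.environment(mod)) return(list())
  if (!is.list(mod)) return(list())
  out <- list()
  if (!is.null(mod$type) && mod$type %in% c("conv", "tconv")) {
    out <- c(out, list(mod$p))
  }
  if (!is.null(mod$children)) {
    kids <- mod$children
    if (!is.null(kids$down)) { # unet: children is a named list of lists
      for (grp in kids) {
        if (is.list(grp) && !is.null(grp$type)) {
          out <- c(out, collect_param_envs(grp))
        } else if (is.list(grp)) {
          for (g in grp) out <- c(out, collect_param_envs(g))
        }
      }
    } else {
      for (k in kids) out <- c(out, collect_param_envs(k))
    }
  }
  out
}

n_params_env <- function(p) {
  prod(p$wshape) + if (!is.null(p$bshape)) p$bshape else 0L
}

zero_grads <- function(envs) {
  for (p in envs) { p$gW <- NULL; p$gb <- NULL }
  invisible(NULL)
}
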