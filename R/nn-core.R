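# Minimal reverse-mode autodiff over 4-D feature maps, backed by BLAS.
#
# Feature maps are numeric arrays with dim (H, W, N, C): spatial dims first,
# then batch, then channels.  With channels last, the (H*W*N) x C matrix
# views needed by im2col/gemm convolutions, batch normalization, softmax and
# channel pooling are plain `dim<-` reshapes of contiguous memory — no
# permutation copies on the hot path.  Convolutions keep their im2col matrix
# for the backward pass only when it is modest in size (.cols_cache_limit),
# bounding peak RSS at large input sizes.

.cg_env <- new.env(parent = emptyenv())
.cg_env$id <- 0L

new_node <- function(value, parents = list(), backward = NULL) {
  # force argument promises BEFORE taking an id: any nodes created while
  # evaluating them must receive lower ids, so that creation order remains
  # a topological order of the graph
  force(value); force(parents); force(backward)
  .cg_env$id <- .cg_env$id + 1L
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  e$id <- .cg_env$id
  class(e) <- "cg_node"
  e
}

cg_param <- function(value) {
  n <- new_node(value)
  n$is_param <- TRUE
  n
}

cg_input <- function(value) new_node(value)

is_node <- function(x) inherits(x, "cg_node")

# Backpropagate from a scalar loss node.  Creation order is a topological
# order for a define-by-run graph, so nodes are processed by decreasing id.
cg_backward <- function(loss) {
  nodes <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ids <- vapply(nodes, function(n) n$id, integer(1))
  loss$grad <- 1
  for (nd in nodes[order(ids, decreasing = TRUE)]) {
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    nd$grad <- NULL   # release activation gradients as we go
    for (i in seq_along(nd$parents)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- nd$parents[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- numeric kernels -------------------------------------------------------

conv_out_dim <- function(n, k, stride, pad, dil) {
  (n + 2L * pad - dil * (k - 1L) - 1L) %/% stride + 1L
}

nn_pad <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

# (Hp,Wp,N,C) -> (Ho*Wo*N, k*k*C); block p of k*k holds the C channels of
# kernel tap p, so column order matches aperm(w, c(3,1,2,4)) row order.
# For shapes seen repeatedly a flat gather index is memoized, turning the
# whole extraction into one C-level subscript operation.
.im2col_memo <- new.env(parent = emptyenv())

im2col_index <- function(d, k, stride, dil, Ho, Wo) {
  Hp <- d[1]; Wp <- d[2]; N <- d[3]; C <- d[4]
  taps <- vector("list", k * k)
  for (p in seq_len(k * k)) {
    ki <- (p - 1L) %% k + 1L
    kj <- (p - 1L) %/% k + 1L
    si <- (seq_len(Ho) - 1L) * stride + (ki - 1L) * dil   # 0-based rows
    sj <- (seq_len(Wo) - 1L) * stride + (kj - 1L) * dil
    sp <- outer(si, sj * Hp, `+`)                          # Ho x Wo, 0-based
    taps[[p]] <- outer(as.vector(outer(as.vector(sp), (seq_len(N) - 1L) * (Hp * Wp), `+`)),
                       (seq_len(C) - 1L) * (Hp * Wp * N), `+`)
  }
  taps <- lapply(taps, function(t) {
    storage.mode(t) <- "integer"
    t <- t + 1L
    dim(t) <- NULL
    t
  })
  flat <- unlist(taps, use.names = FALSE)
  # flat: one gather for the whole im2col; taps: per-tap indices for the
  # col2im scatter in the backward pass
  list(flat = flat, taps = taps)
}

nn_im2col <- function(xp, k, stride, dil, Ho, Wo) {
  d <- dim(xp); N <- d[3]; C <- d[4]
  M <- Ho * Wo * N
  len <- M * k * k * C
  if (len <= .cols_cache_limit) {
    key <- paste(c(d, k, stride, dil), collapse = ".")
    idx <- .im2col_memo[[key]]
    if (is.null(idx)) {
      idx <- im2col_index(d, k, stride, dil, Ho, Wo)
      .im2col_memo[[key]] <- idx
    }
    cols <- xp[idx$flat]
    dim(cols) <- c(M, k * k * C)
    return(cols)
  }
  cols <- matrix(0, M, k * k * C)
  for (p in seq_len(k * k)) {
    ki <- (p - 1L) %% k + 1L
    kj <- (p - 1L) %/% k + 1L
    si <- (seq_len(Ho) - 1L) * stride + 1L + (ki - 1L) * dil
    sj <- (seq_len(Wo) - 1L) * stride + 1L + (kj - 1L) * dil
    sub <- xp[si, sj, , , drop = FALSE]
    dim(sub) <- c(M, C)
    cols[, ((p - 1L) * C + 1L):(p * C)] <- sub
  }
  cols
}

# x: (H,W,N,Cin); w: (k,k,Cin,Cout); b: length Cout or NULL.
# Returns list(y, cols); `cols` is the im2col matrix when it was built and is
# small enough to keep for the backward pass (NULL otherwise).
.cols_cache_limit <- 3e7   # elements; ~240 MB of doubles

nn_conv_fwd <- function(x, w, b, stride = 1L, pad = 0L, dil = 1L,
                        keep_cols = FALSE) {
  d <- dim(x); k <- dim(w)[1]; Cin <- dim(w)[3]; Cout <- dim(w)[4]
  stopifnot(d[4] == Cin)
  Ho <- conv_out_dim(d[1], k, stride, pad, dil)
  Wo <- conv_out_dim(d[2], k, stride, pad, dil)
  cols <- NULL
  if (k == 1L && stride == 1L && pad == 0L) {
    dim(x) <- c(d[1] * d[2] * d[3], Cin)
    y <- x %*% matrix(w, Cin, Cout)
  } else {
    cols <- nn_im2col(nn_pad(x, pad), k, stride, dil, Ho, Wo)
    y <- cols %*% matrix(aperm(w, c(3, 1, 2, 4)), k * k * Cin, Cout)
    if (!keep_cols || length(cols) > .cols_cache_limit) cols <- NULL
  }
  if (!is.null(b)) y <- y + rep(b, each = nrow(y))
  dim(y) <- c(Ho, Wo, d[3], Cout)
  list(y = y, cols = cols)
}

nn_conv_bwd <- function(x, w, gy, stride = 1L, pad = 0L, dil = 1L,
                        need_gx = TRUE, cols = NULL) {
  d <- dim(x); k <- dim(w)[1]; Cin <- dim(w)[3]; Cout <- dim(w)[4]
  dg <- dim(gy); Ho <- dg[1]; Wo <- dg[2]; N <- d[3]
  gmat <- gy
  dim(gmat) <- c(Ho * Wo * N, Cout)
  gb <- colSums(gmat)
  if (k == 1L && stride == 1L && pad == 0L) {
    xm <- x
    dim(xm) <- c(d[1] * d[2] * N, Cin)
    gw <- array(crossprod(xm, gmat), c(1, 1, Cin, Cout))
    gx <- NULL
    if (need_gx) {
      gx <- gmat %*% t(matrix(w, Cin, Cout))
      dim(gx) <- d
    }
    return(list(gx = gx, gw = gw, gb = gb))
  }
  if (is.null(cols)) {
    cols <- nn_im2col(nn_pad(x, pad), k, stride, dil, Ho, Wo)
  }
  wmat <- matrix(aperm(w, c(3, 1, 2, 4)), k * k * Cin, Cout)
  gwmat <- crossprod(cols, gmat)
  dim(gwmat) <- c(Cin, k, k, Cout)
  gw <- aperm(gwmat, c(2, 3, 1, 4))
  gx <- NULL
  if (need_gx) {
    gcols <- gmat %*% t(wmat)
    dp <- c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4])
    gxp <- array(0, dp)
    M <- Ho * Wo * N
    key <- paste(c(dp, k, stride, dil), collapse = ".")
    idx <- .im2col_memo[[key]]
    if (!is.null(idx)) {
      # flat scatter-add, one kernel tap at a time (indices within a tap are
      # unique, so vectorized `[<-` accumulation is exact)
      for (p in seq_len(k * k)) {
        blk <- gcols[, ((p - 1L) * Cin + 1L):(p * Cin)]
        dim(blk) <- NULL
        ip <- idx$taps[[p]]
        gxp[ip] <- gxp[ip] + blk
      }
    } else {
      for (p in seq_len(k * k)) {
        ki <- (p - 1L) %% k + 1L
        kj <- (p - 1L) %/% k + 1L
        si <- (seq_len(Ho) - 1L) * stride + 1L + (ki - 1L) * dil
        sj <- (seq_len(Wo) - 1L) * stride + 1L + (kj - 1L) * dil
        blk <- gcols[, ((p - 1L) * Cin + 1L):(p * Cin)]
        dim(blk) <- c(Ho, Wo, N, Cin)
        gxp[si, sj, , ] <- gxp[si, sj, , , drop = FALSE] + blk
      }
    }
    gx <- if (pad > 0) {
      gxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
    } else gxp
  }
  list(gx = gx, gw = gw, gb = gb)
}

## ---- autograd ops ----------------------------------------------------------

op_conv <- function(x, w, b, stride = 1L, pad = 0L, dil = 1L) {
  bval <- if (is.null(b)) NULL else b$value
  fw <- nn_conv_fwd(x$value, w$value, bval, stride, pad, dil, keep_cols = TRUE)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  nd <- new_node(fw$y, parents, function(g) {
    bw <- nn_conv_bwd(x$value, w$value, g, stride, pad, dil,
                      need_gx = !isTRUE(x$is_input_leaf), cols = fw$cols)
    if (is.null(b)) list(bw$gx, bw$gw) else list(bw$gx, bw$gw, bw$gb)
  })
  nd
}

op_relu <- function(x) {
  pos <- x$value > 0
  new_node(x$value * pos, list(x), function(g) list(g * pos))
}

op_sigmoid <- function(x) {
  val <- 1 / (1 + exp(-x$value))
  new_node(val, list(x), function(g) list(g * val * (1 - val)))
}

op_add <- function(a, b) {
  new_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

# concatenate along the channel axis (dim 4)
op_concat <- function(xs) {
  d1 <- dim(xs[[1]]$value)
  cs <- vapply(xs, function(x) dim(x$value)[4], numeric(1))
  out <- array(0, c(d1[1], d1[2], d1[3], sum(cs)))
  off <- 0L
  for (x in xs) {
    ci <- dim(x$value)[4]
    out[, , , off + seq_len(ci)] <- x$value
    off <- off + ci
  }
  new_node(out, xs, function(g) {
    off <- 0L
    lapply(xs, function(x) {
      ci <- dim(x$value)[4]
      gi <- g[, , , off + seq_len(ci), drop = FALSE]
      off <<- off + ci
      gi
    })
  })
}

op_batchnorm <- function(x, gamma, beta, state, momentum = 0.1, eps = 1e-5,
                         training = TRUE) {
  d <- dim(x$value)
  C <- d[4]; m <- d[1] * d[2] * d[3]
  if (training) {
    mu <- .colMeans(x$value, m, C)
    v <- pmax(.colMeans(x$value * x$value, m, C) - mu * mu, 0)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  # y = a * x + b0 with a, b0 per channel (fused affine form)
  a <- gamma$value * inv_sd
  ym <- x$value * rep(a, each = m) + rep(beta$value - mu * a, each = m)
  new_node(ym, list(x, gamma, beta), function(g) {
    xhat <- x$value * rep(inv_sd, each = m) - rep(mu * inv_sd, each = m)
    ggamma <- .colSums(g * xhat, m, C)
    gbeta <- .colSums(g, m, C)
    if (training) {
      # standard batch-norm backward, vectorized per channel
      gxm <- (g - rep(gbeta / m, each = m) - xhat * rep(ggamma / m, each = m)) *
        rep(gamma$value * inv_sd, each = m)
    } else {
      gxm <- g * rep(gamma$value * inv_sd, each = m)
    }
    list(gxm, ggamma, gbeta)
  })
}

op_maxpool2 <- function(x) {
  d <- dim(x$value)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  io <- seq(1L, d[1], 2L); ie <- seq(2L, d[1], 2L)
  jo <- seq(1L, d[2], 2L); je <- seq(2L, d[2], 2L)
  s1 <- x$value[io, jo, , , drop = FALSE]
  s2 <- x$value[ie, jo, , , drop = FALSE]
  s3 <- x$value[io, je, , , drop = FALSE]
  s4 <- x$value[ie, je, , , drop = FALSE]
  val <- pmax(s1, s2, s3, s4)
  new_node(val, list(x), function(g) {
    t1 <- s1 == val
    t2 <- (s2 == val) & !t1
    t3 <- (s3 == val) & !(t1 | t2)
    t4 <- !(t1 | t2 | t3)
    gx <- array(0, d)
    gx[io, jo, , ] <- g * t1
    gx[ie, jo, , ] <- g * t2
    gx[io, je, , ] <- g * t3
    gx[ie, je, , ] <- g * t4
    list(gx)
  })
}

.interp_memo <- new.env(parent = emptyenv())
interp_matrix_memo <- function(n_out, n_in) {
  key <- paste0(n_out, "x", n_in)
  m <- .interp_memo[[key]]
  if (is.null(m)) {
    m <- interp_matrix(n_out, n_in)
    .interp_memo[[key]] <- m
  }
  m
}

# apply separable row/col linear maps over the two spatial dims
nn_apply_interp <- function(x, Ah, Aw) {
  d <- dim(x)
  Ho <- nrow(Ah); Wo <- nrow(Aw)
  y <- Ah %*% matrix(x, d[1], d[2] * d[3] * d[4])
  dim(y) <- c(Ho, d[2], d[3], d[4])
  y <- aperm(y, c(2, 1, 3, 4))
  y <- Aw %*% matrix(y, d[2], Ho * d[3] * d[4])
  dim(y) <- c(Wo, Ho, d[3], d[4])
  aperm(y, c(2, 1, 3, 4))
}

op_resize_bilinear <- function(x, size) {
  d <- dim(x$value)
  size <- rep(size, length.out = 2)
  Ah <- interp_matrix_memo(size[1], d[1])
  Aw <- interp_matrix_memo(size[2], d[2])
  val <- nn_apply_interp(x$value, Ah, Aw)
  new_node(val, list(x), function(g) list(nn_apply_interp(g, t(Ah), t(Aw))))
}

op_global_avgpool <- function(x) {
  d <- dim(x$value)
  m <- matrix(x$value, d[1] * d[2], d[3] * d[4])
  val <- array(colMeans(m), c(1, 1, d[3], d[4]))
  new_node(val, list(x), function(g) {
    list(array(rep(as.vector(g) / (d[1] * d[2]), each = d[1] * d[2]), d))
  })
}

op_global_maxpool <- function(x) {
  d <- dim(x$value)
  m <- matrix(x$value, d[1] * d[2], d[3] * d[4])
  arg <- max.col(t(m), ties.method = "first")
  val <- array(m[cbind(arg, seq_len(d[3] * d[4]))], c(1, 1, d[3], d[4]))
  new_node(val, list(x), function(g) {
    gm <- matrix(0, d[1] * d[2], d[3] * d[4])
    gm[cbind(arg, seq_len(d[3] * d[4]))] <- as.vector(g)
    list(array(gm, d))
  })
}

# mean and max over the channel axis -> (H, W, N, 1)
op_channel_mean <- function(x) {
  d <- dim(x$value)
  xm <- x$value
  dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  val <- rowMeans(xm)
  dim(val) <- c(d[1], d[2], d[3], 1)
  new_node(val, list(x), function(g) {
    gxm <- matrix(as.vector(g) / d[4], d[1] * d[2] * d[3], d[4])
    dim(gxm) <- d
    list(gxm)
  })
}

op_channel_max <- function(x) {
  d <- dim(x$value)
  xm <- x$value
  dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  arg <- max.col(xm, ties.method = "first")
  val <- xm[cbind(seq_len(nrow(xm)), arg)]
  dim(val) <- c(d[1], d[2], d[3], 1)
  new_node(val, list(x), function(g) {
    gxm <- matrix(0, d[1] * d[2] * d[3], d[4])
    gxm[cbind(seq_len(nrow(gxm)), arg)] <- as.vector(g)
    dim(gxm) <- d
    list(gxm)
  })
}

# fully connected layer on a (1,1,N,C) tensor: y = W x + b per batch element
op_fc <- function(x, w, b) {
  d <- dim(x$value)
  xm <- t(matrix(x$value, d[3], d[4]))          # C x N
  ym <- w$value %*% xm + b$value
  new_node(array(t(ym), c(1, 1, d[3], nrow(w$value))), list(x, w, b),
           function(g) {
    gm <- t(matrix(g, d[3], nrow(w$value)))     # Cout x N
    list(array(t(crossprod(w$value, gm)), d), gm %*% t(xm), rowSums(gm))
  })
}

# x * s with s of shape (1,1,N,C) broadcast over the spatial dims
op_scale_channel <- function(x, s) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  sb <- rep(as.vector(s$value), each = hw)
  val <- x$value * array(sb, d)
  new_node(val, list(x, s), function(g) {
    gs <- colSums(matrix(g * x$value, hw, d[3] * d[4]))
    list(g * array(sb, d), array(gs, c(1, 1, d[3], d[4])))
  })
}

# x * s with s of shape (H,W,N,1) broadcast over channels
op_scale_spatial <- function(x, s) {
  d <- dim(x$value)
  big <- array(rep(as.vector(s$value), d[4]), d)
  val <- x$value * big
  new_node(val, list(x, s), function(g) {
    p <- g * x$value
    dim(p) <- c(d[1] * d[2] * d[3], d[4])
    gs <- rowSums(p)
    dim(gs) <- c(d[1], d[2], d[3], 1)
    list(g * big, gs)
  })
}

# per-pixel softmax over the channel axis (numerically stabilized)
nn_softmax <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  rmax <- xm[, 1]
  for (j in seq_len(d[4])[-1]) rmax <- pmax(rmax, xm[, j])
  e <- exp(xm - rmax)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}
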