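#' @title Reverse-mode automatic differentiation over dense arrays
#' @description Internal engine powering the network forward/backward pass.
#'   Tensors are plain numeric arrays in (batch, height, width, channel)
#'   layout; each differentiable operation appends a node to a global tape
#'   and `ad_backward()` walks the tape in reverse, accumulating gradients.
#' @name autodiff
#' @keywords internal
NULL

.ad <- new.env(parent = emptyenv())
.ad$recording <- FALSE
.ad$nodes <- NULL
.ad$n <- 0L

ad_begin <- function() {
  .ad$nodes <- vector("list", 256L)
  .ad$n <- 0L
  .ad$recording <- TRUE
  invisible(NULL)
}

ad_stop <- function() {
  .ad$recording <- FALSE
  .ad$nodes <- NULL
  .ad$n <- 0L
  invisible(NULL)
}

ad_push <- function(nd) {
  n <- .ad$n + 1L
  if (n > length(.ad$nodes)) length(.ad$nodes) <- 2L * length(.ad$nodes)
  .ad$nodes[[n]] <- nd
  .ad$n <- n
  nd
}

# A node holds a value, a gradient slot, and a backward closure that reads
# nd$grad and accumulates into its parents via ad_accum().
ad_node <- function(value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  if (isTRUE(.ad$recording)) ad_push(nd)
  nd
}

ad_leaf <- function(value) ad_node(value)

ad_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# Backward pass from a scalar loss node.
ad_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  if (.ad$n > 0L) {
    for (i in seq.int(.ad$n, 1L)) {
      nd <- .ad$nodes[[i]]
      if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
    }
  }
  invisible(NULL)
}

val <- function(x) if (is.environment(x)) x$value else x

# ---- shape helpers ---------------------------------------------------------

# zero- (or constant-) pad the two spatial dims of an (N,H,W,C) array
pad_hw <- function(x, p, fill = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4]))
  xp[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  xp
}

unpad_hw <- function(xp, p, H, W) {
  if (p == 0L) return(xp)
  xp[, p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

# im2col: patch matrix with rows indexed by (n, i, j) (n fastest) and column
# blocks ordered (dj outer, di inner), channels fastest within a block.  The
# convolution weight matrix uses the same row ordering:
#   row = ((dj - 1) * k + di - 1) * C_in + c_in
im2col <- function(xp, k, s, Ho, Wo) {
  d <- dim(xp)
  N <- d[1]; C <- d[4]
  M <- matrix(0, N * Ho * Wo, k * k * C)
  col <- 0L
  for (dj in seq_len(k)) {
    cj <- seq.int(dj, by = s, length.out = Wo)
    for (di in seq_len(k)) {
      ri <- seq.int(di, by = s, length.out = Ho)
      sl <- xp[, ri, cj, , drop = FALSE]
      M[, col + seq_len(C)] <- matrix(sl, N * Ho * Wo, C)
      col <- col + C
    }
  }
  M
}

col2im <- function(dM, N, Hp, Wp, C, k, s, Ho, Wo) {
  dxp <- array(0, c(N, Hp, Wp, C))
  col <- 0L
  for (dj in seq_len(k)) {
    cj <- seq.int(dj, by = s, length.out = Wo)
    for (di in seq_len(k)) {
      ri <- seq.int(di, by = s, length.out = Ho)
      blk <- array(dM[, col + seq_len(C)], c(N, Ho, Wo, C))
      dxp[, ri, cj, ] <- dxp[, ri, cj, , drop = FALSE] + blk
      col <- col + C
    }
  }
  dxp
}

conv_out_len <- function(H, k, s) {
  p <- (k - 1L) %/% 2L
  as.integer(floor((H + 2L * p - k) / s) + 1L)
}

# ---- elementwise and structural ops ---------------------------------------

op_add <- function(a, b) {
  ad_node(val(a) + val(b), backward = function(nd) {
    ad_accum(a, nd$grad)
    ad_accum(b, nd$grad)
  })
}

op_relu <- function(x) {
  v <- val(x)
  y <- v * (v > 0)
  ad_node(y, backward = function(nd) ad_accum(x, nd$grad * (v > 0)))
}

op_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-val(x)))
  ad_node(y, backward = function(nd) ad_accum(x, nd$grad * y * (1 - y)))
}

# broadcast multiply of an (N,H,W,C) tensor by an (N,1,1,C) channel gate
op_mul_gate <- function(x, g) {
  xv <- val(x); gv <- val(g)
  d <- dim(xv)
  gb <- aperm(array(aperm(gv, c(1, 4, 2, 3)), c(d[1], d[4], d[2], d[3])),
              c(1, 3, 4, 2))
  ad_node(xv * gb, backward = function(nd) {
    ad_accum(x, nd$grad * gb)
    dg <- apply(nd$grad * xv, c(1, 4), sum)
    ad_accum(g, array(dg, c(d[1], 1, 1, d[4])))
  })
}

op_concat_c <- function(a, b) {
  av <- val(a); bv <- val(b)
  da <- dim(av); db <- dim(bv)
  y <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- av
  y[, , , da[4] + seq_len(db[4])] <- bv
  ad_node(y, backward = function(nd) {
    ad_accum(a, nd$grad[, , , seq_len(da[4]), drop = FALSE])
    ad_accum(b, nd$grad[, , , da[4] + seq_len(db[4]), drop = FALSE])
  })
}

op_reshape <- function(x, dims) {
  v <- val(x)
  old <- dim(v)
  ad_node(array(v, dims),
          backward = function(nd) ad_accum(x, array(nd$grad, old)))
}

op_scale <- function(x, s) {
  ad_node(val(x) * s, backward = function(nd) ad_accum(x, nd$grad * s))
}

# ---- convolutions ----------------------------------------------------------

# standard 2-D convolution, same padding; w is a ((k*k*Cin) x Cout) matrix in
# im2col row order, b a length-Cout vector (or NULL)
op_conv2d <- function(x, w, b, k, stride = 1L) {
  xv <- val(x); wv <- val(w)
  d <- dim(xv)
  N <- d[1]; H <- d[2]; W <- d[3]; Cin <- d[4]
  Cout <- ncol(wv)
  p <- (k - 1L) %/% 2L
  Ho <- conv_out_len(H, k, stride)
  Wo <- conv_out_len(W, k, stride)
  xp <- pad_hw(xv, p)
  M <- im2col(xp, k, stride, Ho, Wo)
  Y <- M %*% wv
  if (!is.null(b)) Y <- Y + rep(val(b), each = nrow(Y))
  ad_node(array(Y, c(N, Ho, Wo, Cout)), backward = function(nd) {
    dY <- matrix(nd$grad, N * Ho * Wo, Cout)
    ad_accum(w, crossprod(M, dY))
    if (!is.null(b)) ad_accum(b, colSums(dY))
    dM <- dY %*% t(wv)
    dxp <- col2im(dM, N, H + 2L * p, W + 2L * p, Cin, k, stride, Ho, Wo)
    ad_accum(x, unpad_hw(dxp, p, H, W))
  })
}

# depthwise convolution: one k x k filter per channel; w is (k*k) x C,
# rows ordered (dj outer, di inner) to match im2col block order
op_dwconv2d <- function(x, w, k, stride = 1L) {
  xv <- val(x); wv <- val(w)
  d <- dim(xv)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  p <- (k - 1L) %/% 2L
  Ho <- conv_out_len(H, k, stride)
  Wo <- conv_out_len(W, k, stride)
  xp <- pad_hw(xv, p)
  y <- array(0, c(N, Ho, Wo, C))
  idx <- 0L
  per <- N * Ho * Wo
  for (dj in seq_len(k)) {
    cj <- seq.int(dj, by = stride, length.out = Wo)
    for (di in seq_len(k)) {
      ri <- seq.int(di, by = stride, length.out = Ho)
      idx <- idx + 1L
      sl <- xp[, ri, cj, , drop = FALSE]
      y <- y + sl * rep(wv[idx, ], each = per)
    }
  }
  ad_node(y, backward = function(nd) {
    dY <- nd$grad
    dW <- matrix(0, k * k, C)
    dxp <- array(0, dim(xp))
    idx <- 0L
    for (dj in seq_len(k)) {
      cj <- seq.int(dj, by = stride, length.out = Wo)
      for (di in seq_len(k)) {
        ri <- seq.int(di, by = stride, length.out = Ho)
        idx <- idx + 1L
        sl <- xp[, ri, cj, , drop = FALSE]
        dW[idx, ] <- apply(dY * sl, 4, sum)
        dxp[, ri, cj, ] <- dxp[, ri, cj, , drop = FALSE] +
          dY * rep(wv[idx, ], each = per)
      }
    }
    ad_accum(w, dW)
    ad_accum(x, unpad_hw(dxp, p, H, W))
  })
}

# ---- batch normalization ---------------------------------------------------

# Per-channel batch normalization.  `state` is an environment carrying
# running_mean / running_var / momentum / eps, updated in training mode.
op_batchnorm <- function(x, gamma, beta, state, training) {
  xv <- val(x)
  d <- dim(xv)
  m <- d[1] * d[2] * d[3]
  C <- d[4]
  xm <- matrix(xv, m, C)
  gv <- val(gamma); bv <- val(beta)
  eps <- state$eps
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    state$running_mean <- (1 - state$momentum) * state$running_mean +
      state$momentum * mu
    state$running_var <- (1 - state$momentum) * state$running_var +
      state$momentum * v
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  sd_ <- sqrt(v + eps)
  xhat <- (xm - rep(mu, each = m)) / rep(sd_, each = m)
  ym <- xhat * rep(gv, each = m) + rep(bv, each = m)
  ad_node(array(ym, d), backward = function(nd) {
    dY <- matrix(nd$grad, m, C)
    ad_accum(gamma, colSums(dY * xhat))
    ad_accum(beta, colSums(dY))
    if (training) {
      dxhat <- dY * rep(gv, each = m)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dxm <- (dxhat - rep(s1 / m, each = m) -
                xhat * rep(s2 / m, each = m)) / rep(sd_, each = m)
    } else {
      dxm <- dY * rep(gv / sd_, each = m)
    }
    ad_accum(x, array(dxm, d))
  })
}

# ---- pooling and upsampling ------------------------------------------------

op_avgpool3 <- function(x) {
  xv <- val(x)
  d <- dim(xv)
  xp <- pad_hw(xv, 1L)
  y <- array(0, d)
  for (dj in 1:3) for (di in 1:3) {
    y <- y + xp[, di + seq_len(d[2]) - 1L, dj + seq_len(d[3]) - 1L, ,
                drop = FALSE]
  }
  y <- y / 9
  ad_node(y, backward = function(nd) {
    dxp <- array(0, dim(xp))
    g <- nd$grad / 9
    for (dj in 1:3) for (di in 1:3) {
      ri <- di + seq_len(d[2]) - 1L
      cj <- dj + seq_len(d[3]) - 1L
      dxp[, ri, cj, ] <- dxp[, ri, cj, , drop = FALSE] + g
    }
    ad_accum(x, unpad_hw(dxp, 1L, d[2], d[3]))
  })
}

op_maxpool3 <- function(x) {
  xv <- val(x)
  d <- dim(xv)
  xp <- pad_hw(xv, 1L, fill = -Inf)
  y <- array(-Inf, d)
  for (dj in 1:3) for (di in 1:3) {
    y <- pmax(y, xp[, di + seq_len(d[2]) - 1L, dj + seq_len(d[3]) - 1L, ,
                    drop = FALSE])
  }
  ad_node(y, backward = function(nd) {
    dxp <- array(0, dim(xp))
    remaining <- array(TRUE, d)
    for (dj in 1:3) for (di in 1:3) {
      ri <- di + seq_len(d[2]) - 1L
      cj <- dj + seq_len(d[3]) - 1L
      sl <- xp[, ri, cj, , drop = FALSE]
      mk <- (sl == y) & remaining
      remaining <- remaining & !mk
      dxp[, ri, cj, ] <- dxp[, ri, cj, , drop = FALSE] + nd$grad * mk
    }
    ad_accum(x, unpad_hw(dxp, 1L, d[2], d[3]))
  })
}

op_gap <- function(x) {
  xv <- val(x)
  d <- dim(xv)
  y <- array(apply(xv, c(1, 4), mean), c(d[1], 1, 1, d[4]))
  ad_node(y, backward = function(nd) {
    g <- array(nd$grad, c(d[1], d[4]))
    gb <- aperm(array(g, c(d[1], d[4], d[2], d[3])), c(1, 3, 4, 2))
    ad_accum(x, gb / (d[2] * d[3]))
  })
}

# x2 upsampling as a pair of linear row/column operators (handles both
# nearest-neighbour and half-pixel bilinear interpolation)
upsample_operator <- function(H, mode) {
  U <- matrix(0, 2L * H, H)
  if (mode == "nearest") {
    for (i in seq_len(2L * H)) U[i, (i + 1L) %/% 2L] <- 1
  } else if (mode == "bilinear") {
    for (i in seq_len(2L * H)) {
      p <- i / 2 + 0.25
      lo <- floor(p); hi <- lo + 1
      whi <- p - lo
      lo <- min(max(lo, 1), H); hi <- min(max(hi, 1), H)
      U[i, lo] <- U[i, lo] + (1 - whi)
      U[i, hi] <- U[i, hi] + whi
    }
  } else {
    stop("unknown upsampling mode: ", mode)
  }
  U
}

apply_op_rows <- function(xv, A) {
  d <- dim(xv)
  xp <- aperm(xv, c(2, 1, 3, 4))
  y <- A %*% matrix(xp, d[2], d[1] * d[3] * d[4])
  aperm(array(y, c(nrow(A), d[1], d[3], d[4])), c(2, 1, 3, 4))
}

apply_op_cols <- function(xv, A) {
  d <- dim(xv)
  xp <- aperm(xv, c(3, 1, 2, 4))
  y <- A %*% matrix(xp, d[3], d[1] * d[2] * d[4])
  aperm(array(y, c(nrow(A), d[1], d[2], d[4])), c(2, 3, 1, 4))
}

op_upsample2 <- function(x, mode = "nearest") {
  xv <- val(x)
  d <- dim(xv)
  Uh <- upsample_operator(d[2], mode)
  Uw <- upsample_operator(d[3], mode)
  y <- apply_op_cols(apply_op_rows(xv, Uh), Uw)
  ad_node(y, backward = function(nd) {
    ad_accum(x, apply_op_cols(apply_op_rows(nd$grad, t(Uh)), t(Uw)))
  })
}

# ---- 2-D matrix ops (attention) --------------------------------------------

op_matmul <- function(a, b) {
  av <- val(a); bv <- val(b)
  ad_node(av %*% bv, backward = function(nd) {
    ad_accum(a, nd$grad %*% t(bv))
    ad_accum(b, crossprod(av, nd$grad))
  })
}

# a %*% t(b)
op_matmul_bt <- function(a, b) {
  av <- val(a); bv <- val(b)
  ad_node(tcrossprod(av, bv), backward = function(nd) {
    ad_accum(a, nd$grad %*% bv)
    ad_accum(b, crossprod(nd$grad, av))
  })
}

op_softmax_rows <- function(x) {
  v <- val(x)
  e <- exp(v - apply(v, 1, max))
  y <- e / rowSums(e)
  ad_node(y, backward = function(nd) {
    ad_accum(x, (nd$grad - rowSums(nd$grad * y)) * y)
  })
}

op_slice_sample <- function(x, n) {
  xv <- val(x)
  d <- dim(xv)
  ad_node(matrix(aperm(xv[n, , , , drop = FALSE], c(3, 2, 4, 1)),
                 d[2] * d[3], d[4]),
          backward = function(nd) {
            dx <- array(0, d)
            dx[n, , , ] <- aperm(array(nd$grad, c(d[3], d[2], d[4])),
                                 c(2, 1, 3))
            ad_accum(x, dx)
          })
}

# inverse of op_slice_sample over a list of (T x C) token matrices
op_stack_samples <- function(lst, h, w) {
  N <- length(lst)
  C <- ncol(val(lst[[1]]))
  y <- array(0, c(N, h, w, C))
  for (n in seq_len(N)) {
    y[n, , , ] <- aperm(array(val(lst[[n]]), c(w, h, C)), c(2, 1, 3))
  }
  ad_node(y, backward = function(nd) {
    for (n in seq_len(N)) {
      g <- matrix(aperm(nd$grad[n, , , , drop = FALSE], c(3, 2, 4, 1)),
                  h * w, C)
      ad_accum(lst[[n]], g)
    }
  })
}

op_cols <- function(x, idx) {
  v <- val(x)
  ad_node(v[, idx, drop = FALSE], backward = function(nd) {
    g <- matrix(0, nrow(v), ncol(v))
    g[, idx] <- nd$grad
    ad_accum(x, g)
  })
}

op_cbind <- function(lst) {
  vals <- lapply(lst, val)
  widths <- vapply(vals, ncol, integer(1))
  ad_node(do.call(cbind, vals), backward = function(nd) {
    off <- 0L
    for (i in seq_along(lst)) {
      ad_accum(lst[[i]], nd$grad[, off + seq_len(widths[i]), drop = FALSE])
      off <- off + widths[i]
    }
  })
}

op_add2d <- function(a, b) {
  ad_node(val(a) + val(b), backward = function(nd) {
    ad_accum(a, nd$grad)
    ad_accum(b, nd$grad)
  })
}

# ---- losses ----------------------------------------------------------------

op_bce <- function(p, t, eps = 1e-7) {
  pv <- pmin(pmax(val(p), eps), 1 - eps)
  tv <- val(t)
  n <- length(pv)
  ad_node(-sum(tv * log(pv) + (1 - tv) * log(1 - pv)) / n,
          backward = function(nd) {
            ad_accum(p, nd$grad * (pv - tv) / (pv * (1 - pv)) / n)
          })
}

op_soft_dice_loss <- function(p, t, smooth = 1) {
  pv <- val(p); tv <- val(t)
  num <- 2 * sum(pv * tv) + smooth
  den <- sum(pv) + sum(tv) + smooth
  ad_node(1 - num / den, backward = function(nd) {
    ad_accum(p, nd$grad * (-(2 * tv * den - num) / den^2))
  })
}

op_scalar_add <- function(a, b) {
  ad_node(val(a) + val(b), backward = function(nd) {
    ad_accum(a, nd$grad)
    ad_accum(b, nd$grad)
  })
}
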