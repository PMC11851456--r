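# Independent brute-force reference implementations used as oracles.
# Everything here is written with explicit loops over pixels so it shares no
# code path with the package's vectorized engine.

# reference same-padding 2-D convolution; w given as a k x k x cin x cout
# array indexed by (di, dj, cin, cout)
ref_conv2d <- function(x, w, b = NULL, stride = 1L) {
  d <- dim(x)  # N,H,W,C
  k <- dim(w)[1]
  cout <- dim(w)[4]
  p <- (k - 1) %/% 2
  Ho <- floor((d[2] + 2 * p - k) / stride) + 1
  Wo <- floor((d[3] + 2 * p - k) / stride) + 1
  y <- array(0, c(d[1], Ho, Wo, cout))
  for (n in seq_len(d[1])) for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) {
    for (co in seq_len(cout)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (di in seq_len(k)) for (dj in seq_len(k)) {
        ii <- (oi - 1) * stride + di - p
        jj <- (oj - 1) * stride + dj - p
        if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3]) {
          for (ci in seq_len(d[4])) {
            acc <- acc + x[n, ii, jj, ci] * w[di, dj, ci, co]
          }
        }
      }
      y[n, oi, oj, co] <- acc
    }
  }
  y
}

# reference depthwise convolution; w as k x k x c
ref_dwconv2d <- function(x, w, stride = 1L) {
  d <- dim(x)
  k <- dim(w)[1]
  p <- (k - 1) %/% 2
  Ho <- floor((d[2] + 2 * p - k) / stride) + 1
  Wo <- floor((d[3] + 2 * p - k) / stride) + 1
  y <- array(0, c(d[1], Ho, Wo, d[4]))
  for (n in seq_len(d[1])) for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) {
    for (c in seq_len(d[4])) {
      acc <- 0
      for (di in seq_len(k)) for (dj in seq_len(k)) {
        ii <- (oi - 1) * stride + di - p
        jj <- (oj - 1) * stride + dj - p
        if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3])
          acc <- acc + x[n, ii, jj, c] * w[di, dj, c]
      }
      y[n, oi, oj, c] <- acc
    }
  }
  y
}

# reference 3x3 stride-1 pooling (same padding; average counts padded zeros)
ref_pool3 <- function(x, type = c("avg", "max")) {
  type <- match.arg(type)
  d <- dim(x)
  y <- array(if (type == "max") -Inf else 0, d)
  for (n in seq_len(d[1])) for (oi in seq_len(d[2])) for (oj in seq_len(d[3])) {
    for (c in seq_len(d[4])) {
      vals <- numeric(0)
      for (di in -1:1) for (dj in -1:1) {
        ii <- oi + di; jj <- oj + dj
        vals <- c(vals, if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3])
          x[n, ii, jj, c] else if (type == "avg") 0 else -Inf)
      }
      y[n, oi, oj, c] <- if (type == "max") max(vals) else mean(vals)
    }
  }
  y
}

# pack a (di, dj, cin, cout)-indexed kernel into the engine's im2col weight
# matrix: row = ((dj-1)*k + di - 1)*cin + ci
pack_conv_weights <- function(w) {
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  m <- matrix(0, k * k * cin, cout)
  for (dj in seq_len(k)) for (di in seq_len(k)) for (ci in seq_len(cin)) {
    m[((dj - 1) * k + di - 1) * cin + ci, ] <- w[di, dj, ci, ]
  }
  m
}

pack_dw_weights <- function(w) {
  k <- dim(w)[1]; c <- dim(w)[3]
  m <- matrix(0, k * k, c)
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    m[(dj - 1) * k + di, ] <- w[di, dj, ]
  }
  m
}

# brute-force pixel counting for the metric oracle
ref_confusion <- function(p, t) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] == 1 && t[i, j] == 1) tp <- tp + 1
    else if (p[i, j] == 0 && t[i, j] == 0) tn <- tn + 1
    else if (p[i, j] == 1 && t[i, j] == 0) fp <- fp + 1
    else fn <- fn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# small helpers shared across tests
rand_fm <- function(h, w, c, seed = 1) {
  set.seed(seed)
  array(stats::runif(h * w * c), c(h, w, c))
}

tiny_model_config <- function(size = 16L, C = 2L, variant = "full",
                              backbone = "simple-conv", ...) {
  model_config(input_size = size, base_channels = C, variant = variant,
               backbone_name = backbone, ...)
}

# in-memory phantom training set shared by training/cli tests
phantom_pairs <- function(n = 4, size = 32, seed = 1) {
  generate_phantoms(phantom_spec(size = size, seed = seed), n)
}
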