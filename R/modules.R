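# The three architecture blocks and the encoder backbone registry.
#
# Each block comes as a pair: an `add_*` builder that registers parameters
# under a name prefix, and a `*_fwd` forward that wires the autodiff ops.
# Standalone `*_module()` constructors wrap a builder so the blocks can be
# exercised (and unit-tested) in isolation; the full network reuses the same
# builders and forwards.

# ---- spatial enhancement module (SEM) ---------------------------------------
#
# Skip-connection block: a 3x3 conv-BN-ReLU stem, parallel 3x3 average and max
# pooling (stride 1, same padding) concatenated and fused by a second
# conv-BN-ReLU, all multiplied by a sigmoid channel gate derived from a global
# average pool of the input, then added back onto the input (residual).

add_sem <- function(b, name, c) {
  add_conv(b, paste0(name, ".i1"), 3L, c, c)
  add_bn(b, paste0(name, ".i1bn"), c)
  add_conv(b, paste0(name, ".i2"), 3L, 2L * c, c)
  add_bn(b, paste0(name, ".i2bn"), c)
  add_conv(b, paste0(name, ".gate"), 1L, c, c)
  add_bn(b, paste0(name, ".gatebn"), c)
  invisible(b)
}

sem_fwd <- function(ctx, name, fin) {
  i1 <- op_relu(bn_fwd(ctx, paste0(name, ".i1bn"),
                       conv_fwd(ctx, paste0(name, ".i1"), fin, 3L)))
  pooled <- op_concat_c(op_avgpool3(i1), op_maxpool3(i1))
  i2 <- op_relu(bn_fwd(ctx, paste0(name, ".i2bn"),
                       conv_fwd(ctx, paste0(name, ".i2"), pooled, 3L)))
  g <- op_sigmoid(bn_fwd(ctx, paste0(name, ".gatebn"),
                         conv_fwd(ctx, paste0(name, ".gate"), op_gap(fin), 1L)))
  ctx$aux$sem_gate <- val(g)
  op_add(op_mul_gate(i2, g), fin)
}

#' Spatial enhancement module
#'
#' Builds a standalone spatial enhancement module (SEM): the skip-connection
#' block that fuses parallel 3x3 max/average pooling paths and re-weights them
#' with a global-average-pooled sigmoid channel gate before a residual
#' addition. Output shape always equals input shape.
#'
#' @param channels number of input (= output) channels.
#' @param seed integer seed for weight initialization.
#' @return an object of class `cxrseg_sem` with elements `params` and `state`.
#' @examples
#' m <- sem_module(4)
#' out <- sem_forward(m, array(stats::runif(8 * 8 * 4), c(8, 8, 4)))
#' dim(out)
#' @export
sem_module <- function(channels, seed = 1L) {
  set.seed(seed)
  b <- new_builder()
  add_sem(b, "sem", channels)
  structure(list(params = b$params, state = b$state, channels = channels),
            class = "cxrseg_sem")
}

#' Apply a spatial enhancement module to a feature map
#'
#' @param module a [sem_module()].
#' @param fin feature map, an `h x w x channels` array (all values finite).
#' @param training logical; use batch statistics in the normalization layers.
#' @param return_gate logical; also return the sigmoid gate activations.
#' @return an `h x w x channels` array, or a list with `out` and `gate` when
#'   `return_gate = TRUE`.
#' @export
sem_forward <- function(module, fin, training = FALSE, return_gate = FALSE) {
  fin <- as_batch(fin)
  check_finite(fin, "SEM input")
  if (dim(fin)[4] != module$channels)
    abort_shape("SEM input channel count does not match the module")
  ctx <- new_ctx(module$params, module$state, training)
  out <- sem_fwd(ctx, "sem", ad_leaf(fin))
  if (return_gate) list(out = unbatch(val(out)), gate = c(ctx$aux$sem_gate))
  else unbatch(val(out))
}

# ---- multi-scale feature fusion block (MS-FFB) ------------------------------
#
# Three parallel branches with kernel sizes 1, 3 and 5 (k = 2i - 1); each is a
# standard k x k convolution followed by a depthwise-separable k x k
# convolution, each followed by activation and batch normalization, and the
# branch outputs are summed elementwise.  `bn_after_relu` keeps the printed
# activation-then-normalization order; the conventional order is available as
# an option.

msffb_kernels <- function() c(1L, 3L, 5L)

add_msffb <- function(b, name, cin, cout) {
  for (i in 1:3) {
    k <- 2L * i - 1L
    pre <- sprintf("%s.b%d", name, i)
    add_conv(b, paste0(pre, ".conv"), k, cin, cout)
    add_bn(b, paste0(pre, ".bn1"), cout)
    add_dwconv(b, paste0(pre, ".dw"), k, cout)
    add_conv(b, paste0(pre, ".pw"), 1L, cout, cout)
    add_bn(b, paste0(pre, ".bn2"), cout)
  }
  invisible(b)
}

msffb_fwd <- function(ctx, name, xin, bn_after_relu = TRUE) {
  act_norm <- function(bn_name, t) {
    if (bn_after_relu) bn_fwd(ctx, bn_name, op_relu(t))
    else op_relu(bn_fwd(ctx, bn_name, t))
  }
  out <- NULL
  for (i in 1:3) {
    k <- 2L * i - 1L
    pre <- sprintf("%s.b%d", name, i)
    t <- conv_fwd(ctx, paste0(pre, ".conv"), xin, k)
    t <- act_norm(paste0(pre, ".bn1"), t)
    t <- dwconv_fwd(ctx, paste0(pre, ".dw"), t, k)
    t <- conv_fwd(ctx, paste0(pre, ".pw"), t, 1L)
    t <- act_norm(paste0(pre, ".bn2"), t)
    out <- if (is.null(out)) t else op_add(out, t)
  }
  out
}

#' Multi-scale feature fusion block
#'
#' Builds a standalone multi-scale feature fusion block (MS-FFB): three
#' parallel branches with kernel sizes 1, 3 and 5, each a standard
#' convolution followed by a depthwise-separable convolution (with activation
#' and batch normalization after each), summed elementwise. Spatial size is
#' preserved by same-padding; the channel count becomes `out_channels`.
#'
#' @param in_channels input channel count.
#' @param out_channels output channel count (shared by all branches).
#' @param seed integer seed for weight initialization.
#' @param bn_after_relu logical; normalize after the activation (default) or
#'   use the conventional conv-BN-ReLU order.
#' @return an object of class `cxrseg_msffb`.
#' @export
msffb_module <- function(in_channels, out_channels, seed = 1L,
                         bn_after_relu = TRUE) {
  if (out_channels < 1L) abort_config("out_channels must be >= 1")
  set.seed(seed)
  b <- new_builder()
  add_msffb(b, "msffb", in_channels, out_channels)
  structure(list(params = b$params, state = b$state,
                 in_channels = in_channels, out_channels = out_channels,
                 bn_after_relu = bn_after_relu),
            class = "cxrseg_msffb")
}

#' Apply a multi-scale feature fusion block to a feature map
#'
#' @param module a [msffb_module()].
#' @param xin feature map, an `h x w x in_channels` array.
#' @param training logical; use batch statistics in the normalization layers.
#' @return an `h x w x out_channels` array.
#' @export
msffb_forward <- function(module, xin, training = FALSE) {
  xin <- as_batch(xin)
  check_finite(xin, "MS-FFB input")
  if (dim(xin)[4] != module$in_channels)
    abort_shape("MS-FFB input channel count does not match the module")
  ctx <- new_ctx(module$params, module$state, training)
  out <- msffb_fwd(ctx, "msffb", ad_leaf(xin), module$bn_after_relu)
  unbatch(val(out))
}

# ---- transformer attention module (TAM) -------------------------------------
#
# Bottleneck block: feature map flattened to tokens, learned additive
# positional encoding, linear projections to queries/keys/values, scaled
# dot-product attention (softmax over the token axis, scale sqrt(d_k) with
# d_k the per-head channel count), value aggregation, reshape back, residual.

add_tam <- function(b, name, c, tokens, heads = 1L, posenc = TRUE) {
  add_mat(b, paste0(name, ".wq"), c, c)
  add_mat(b, paste0(name, ".wk"), c, c)
  add_mat(b, paste0(name, ".wv"), c, c)
  if (posenc) add_posenc(b, paste0(name, ".pos"), tokens, c)
  invisible(b)
}

tam_fwd <- function(ctx, name, fin, heads = 1L, posenc = TRUE,
                    residual = TRUE, collect_attention = FALSE) {
  d <- dim(val(fin))
  N <- d[1]; h <- d[2]; w <- d[3]; c <- d[4]
  ch <- c %/% heads
  scale <- 1 / sqrt(ch)
  outs <- vector("list", N)
  if (collect_attention) ctx$aux$attention <- list()
  for (n in seq_len(N)) {
    x_raw <- op_slice_sample(fin, n)
    xn <- if (posenc) op_add2d(x_raw, Pn(ctx, paste0(name, ".pos"))) else x_raw
    q <- op_matmul(xn, Pn(ctx, paste0(name, ".wq")))
    kk <- op_matmul(xn, Pn(ctx, paste0(name, ".wk")))
    v <- op_matmul(xn, Pn(ctx, paste0(name, ".wv")))
    head_out <- vector("list", heads)
    for (hd in seq_len(heads)) {
      cols <- (hd - 1L) * ch + seq_len(ch)
      qh <- op_cols(q, cols); kh <- op_cols(kk, cols); vh <- op_cols(v, cols)
      a <- op_softmax_rows(op_scale(op_matmul_bt(qh, kh), scale))
      if (collect_attention)
        ctx$aux$attention[[length(ctx$aux$attention) + 1L]] <- val(a)
      head_out[[hd]] <- op_matmul(a, vh)
    }
    o <- if (heads > 1L) op_cbind(head_out) else head_out[[1L]]
    outs[[n]] <- if (residual) op_add2d(o, x_raw) else o
  }
  op_stack_samples(outs, h, w)
}

#' Transformer attention module
#'
#' Builds a standalone transformer attention module (TAM): the bottleneck
#' block that flattens a feature map to tokens, adds a learned positional
#' encoding, projects tokens to queries/keys/values, applies scaled
#' dot-product self-attention (softmax-normalized token-by-token attention
#' map, scale `sqrt(d_k)`), aggregates values, and reshapes back to the input
#' shape with a residual connection.
#'
#' @param channels channel count `c` of the feature map.
#' @param height,width spatial size of the feature map (fixes the token count
#'   for the positional encoding).
#' @param heads number of attention heads; must divide `channels`.
#' @param posenc logical; learned additive positional encoding.
#' @param residual logical; residual connection from input to output.
#' @param seed integer seed for weight initialization.
#' @return an object of class `cxrseg_tam`.
#' @export
tam_module <- function(channels, height, width, heads = 1L, posenc = TRUE,
                       residual = TRUE, seed = 1L) {
  if (channels < heads || channels %% heads != 0L)
    abort_config("channels must be divisible by the number of heads")
  set.seed(seed)
  b <- new_builder()
  add_tam(b, "tam", channels, height * width, heads, posenc)
  structure(list(params = b$params, state = b$state, channels = channels,
                 height = height, width = width, heads = heads,
                 posenc = posenc, residual = residual),
            class = "cxrseg_tam")
}

#' Apply a transformer attention module to a feature map
#'
#' @param module a [tam_module()].
#' @param fin feature map, an `h x w x channels` array matching the module.
#' @param return_attention logical; also return the attention map(s), one
#'   `tokens x tokens` row-stochastic matrix per head.
#' @return an `h x w x channels` array, or a list with `out` and `attention`.
#' @export
tam_forward <- function(module, fin, return_attention = FALSE) {
  fin <- as_batch(fin)
  check_finite(fin, "TAM input")
  d <- dim(fin)
  if (d[4] != module$channels)
    abort_shape("TAM input channel count does not match the module")
  if (module$posenc && (d[2] != module$height || d[3] != module$width))
    abort_shape("TAM input spatial size does not match the positional encoding")
  ctx <- new_ctx(module$params, module$state, FALSE)
  out <- tam_fwd(ctx, "tam", ad_leaf(fin), module$heads, module$posenc,
                 module$residual, collect_attention = return_attention)
  if (return_attention) list(out = unbatch(val(out)), attention = ctx$aux$attention)
  else unbatch(val(out))
}

# ---- encoder backbone registry ----------------------------------------------
#
# Small offline stand-ins for the candidate backbone families, each truncated
# to three stages at strides 2/4/8 with channel widths (C, 2C, 4C).  The
# "simple-conv" backbone is a single conv-BN-ReLU per stage; the named
# families reproduce each family's characteristic block at miniature size.

#' Registered encoder backbone names
#'
#' @return character vector of the backbone families available offline.
#' @export
backbone_names <- function() {
  c("efficientnet", "resnet", "densenet", "mobilenet", "simple-conv")
}

add_backbone_stage <- function(b, name, kind, cin, cout) {
  switch(kind,
    "simple-conv" = add_cbr(b, paste0(name, ".c1"), 3L, cin, cout),
    "resnet" = {
      add_cbr(b, paste0(name, ".c1"), 3L, cin, cout)
      add_conv(b, paste0(name, ".r1"), 3L, cout, cout)
      add_bn(b, paste0(name, ".r1bn"), cout)
      add_conv(b, paste0(name, ".r2"), 3L, cout, cout)
      add_bn(b, paste0(name, ".r2bn"), cout)
    },
    "densenet" = {
      add_cbr(b, paste0(name, ".c1"), 3L, cin, cout)
      add_cbr(b, paste0(name, ".c2"), 3L, cout, cout)
      add_cbr(b, paste0(name, ".tr"), 1L, 2L * cout, cout)
    },
    "mobilenet" = {
      add_cbr(b, paste0(name, ".pw1"), 1L, cin, cout)
      add_dwconv(b, paste0(name, ".dw"), 3L, cout)
      add_bn(b, paste0(name, ".dwbn"), cout)
      add_cbr(b, paste0(name, ".pw2"), 1L, cout, cout)
    },
    "efficientnet" = {
      add_cbr(b, paste0(name, ".ex"), 1L, cin, 2L * cout)
      add_dwconv(b, paste0(name, ".dw"), 3L, 2L * cout)
      add_bn(b, paste0(name, ".dwbn"), 2L * cout)
      add_conv(b, paste0(name, ".se"), 1L, 2L * cout, 2L * cout)
      add_conv(b, paste0(name, ".pj"), 1L, 2L * cout, cout)
      add_bn(b, paste0(name, ".pjbn"), cout)
    },
    abort_config(paste0("unknown backbone: ", kind))
  )
  invisible(b)
}

backbone_stage_fwd <- function(ctx, name, kind, x) {
  switch(kind,
    "simple-conv" = cbr_fwd(ctx, paste0(name, ".c1"), x, 3L, 2L),
    "resnet" = {
      h <- cbr_fwd(ctx, paste0(name, ".c1"), x, 3L, 2L)
      r <- op_relu(bn_fwd(ctx, paste0(name, ".r1bn"),
                          conv_fwd(ctx, paste0(name, ".r1"), h, 3L)))
      r <- bn_fwd(ctx, paste0(name, ".r2bn"),
                  conv_fwd(ctx, paste0(name, ".r2"), r, 3L))
      op_relu(op_add(h, r))
    },
    "densenet" = {
      h1 <- cbr_fwd(ctx, paste0(name, ".c1"), x, 3L, 2L)
      h2 <- cbr_fwd(ctx, paste0(name, ".c2"), h1, 3L)
      cbr_fwd(ctx, paste0(name, ".tr"), op_concat_c(h1, h2), 1L)
    },
    "mobilenet" = {
      h <- cbr_fwd(ctx, paste0(name, ".pw1"), x, 1L)
      h <- op_relu(bn_fwd(ctx, paste0(name, ".dwbn"),
                          dwconv_fwd(ctx, paste0(name, ".dw"), h, 3L, 2L)))
      cbr_fwd(ctx, paste0(name, ".pw2"), h, 1L)
    },
    "efficientnet" = {
      h <- cbr_fwd(ctx, paste0(name, ".ex"), x, 1L)
      h <- op_relu(bn_fwd(ctx, paste0(name, ".dwbn"),
                          dwconv_fwd(ctx, paste0(name, ".dw"), h, 3L, 2L)))
      g <- op_sigmoid(conv_fwd(ctx, paste0(name, ".se"), op_gap(h), 1L))
      h <- op_mul_gate(h, g)
      bn_fwd(ctx, paste0(name, ".pjbn"),
             conv_fwd(ctx, paste0(name, ".pj"), h, 1L))
    },
    abort_config(paste0("unknown backbone: ", kind))
  )
}
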