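# Model configuration, network assembly, and the forward pass.

#' Model configuration
#'
#' Collects every architectural hyperparameter of the segmentation network.
#' The encoder produces three feature maps at strides 2/4/8 with channel
#' widths `base_channels * (1, 2, 4)`; the bottleneck (optionally refined by
#' the transformer attention module) sits at stride 8; the decoder fuses
#' skip connections (optionally enhanced by the spatial enhancement module)
#' with multi-scale feature fusion blocks and the prediction head upsamples
#' back to full resolution.
#'
#' @param input_size input spatial size in pixels (images are square).
#' @param base_channels channel width `C` of the first encoder stage; later
#'   stages use `2C` and `4C`.
#' @param stage_strides cumulative downsampling factors of the three encoder
#'   stages; must be strictly increasing.
#' @param backbone_name one of `"efficientnet"`, `"resnet"`, `"densenet"`,
#'   `"mobilenet"`, `"simple-conv"` (see [backbone_names()]).
#' @param use_pretrained logical; request pretrained backbone weights. No
#'   pretrained weights ship with this package, so `TRUE` is a configuration
#'   error unless a loader is registered externally.
#' @param attention_heads number of attention heads in the bottleneck; must
#'   divide `4 * base_channels`.
#' @param positional_encoding logical; learned additive positional encoding
#'   in the attention bottleneck.
#' @param msffb_out_channels optional length-3 integer vector overriding the
#'   output channels of the three decoder fusion blocks (deepest first);
#'   `NULL` keeps them equal to the matching skip widths `(4C, 2C, C)`.
#' @param variant ablation-ladder variant: `"BL"` (baseline, single-scale
#'   decoder, no attention, plain skips), `"MBL"` (+ multi-scale decoder),
#'   `"MBL+TAM"` (+ attention bottleneck), `"MBL+SEM"` (+ enhanced skips), or
#'   `"full"` (everything).
#' @param binarize_threshold probability threshold for the binary mask, in
#'   (0, 1); ties (probability exactly equal) go to foreground.
#' @param upsample one of `"nearest"` or `"bilinear"`; decoder upsampling.
#' @param bn_after_relu logical; in the fusion blocks, normalize after the
#'   activation (default) rather than the conventional conv-BN-ReLU order.
#' @param tam_residual logical; residual connection around the attention
#'   bottleneck.
#' @return an object of class `cxrseg_config` (a validated list).
#' @export
model_config <- function(input_size = 256L,
                         base_channels = 32L,
                         stage_strides = c(2L, 4L, 8L),
                         backbone_name = "efficientnet",
                         use_pretrained = FALSE,
                         attention_heads = 1L,
                         positional_encoding = TRUE,
                         msffb_out_channels = NULL,
                         variant = "full",
                         binarize_threshold = 0.5,
                         upsample = "nearest",
                         bn_after_relu = TRUE,
                         tam_residual = TRUE) {
  variants <- c("BL", "MBL", "MBL+TAM", "MBL+SEM", "full")
  if (!variant %in% variants)
    abort_config(paste0("variant must be one of: ", paste(variants, collapse = ", ")))
  if (!backbone_name %in% backbone_names())
    abort_config(paste0("unknown backbone '", backbone_name, "'; registered: ",
                        paste(backbone_names(), collapse = ", ")))
  if (length(stage_strides) != 3L || any(diff(stage_strides) <= 0))
    abort_config("stage_strides must be three strictly increasing factors")
  if (binarize_threshold <= 0 || binarize_threshold >= 1)
    abort_config("binarize_threshold must lie in (0, 1)")
  if (input_size %% max(stage_strides) != 0L)
    abort_shape("input_size must be divisible by the largest stage stride")
  if (base_channels < 1L) abort_config("base_channels must be >= 1")
  c_bott <- 4L * base_channels
  if (attention_heads < 1L || c_bott %% attention_heads != 0L)
    abort_config("attention_heads must divide the bottleneck channel count")
  if (!upsample %in% c("nearest", "bilinear"))
    abort_config("upsample must be 'nearest' or 'bilinear'")
  if (!is.null(msffb_out_channels) && length(msffb_out_channels) != 3L)
    abort_config("msffb_out_channels must be NULL or length 3")
  structure(list(
    input_size = as.integer(input_size),
    base_channels = as.integer(base_channels),
    stage_strides = as.integer(stage_strides),
    backbone_name = backbone_name,
    use_pretrained = isTRUE(use_pretrained),
    attention_heads = as.integer(attention_heads),
    positional_encoding = isTRUE(positional_encoding),
    msffb_out_channels = if (is.null(msffb_out_channels)) NULL
                         else as.integer(msffb_out_channels),
    variant = variant,
    binarize_threshold = binarize_threshold,
    upsample = upsample,
    bn_after_relu = isTRUE(bn_after_relu),
    tam_residual = isTRUE(tam_residual)
  ), class = "cxrseg_config")
}

variant_flags <- function(variant) {
  list(msffb = variant != "BL",
       tam = variant %in% c("MBL+TAM", "full"),
       sem = variant %in% c("MBL+SEM", "full"))
}

# decoder channel bookkeeping shared by the builder and the forward pass
model_plan <- function(config) {
  C <- config$base_channels
  enc <- c(C, 2L * C, 4L * C)
  out3 <- if (is.null(config$msffb_out_channels)) c(4L, 2L, 1L) * C
          else config$msffb_out_channels
  # the 1x1 convolutions after each upsampling harmonize the concatenated
  # width down to the next fusion block's input
  list(enc = enc,
       dec_in = c(4L * C, out3[2], out3[3]),
       dec_out = out3,
       head_in = enc[1] + out3[3])
}

#' Assemble a segmentation network
#'
#' Creates the network described by a [model_config()]: three encoder stages
#' joined by 1x1 channel-harmonizing convolutions, an (optional) attention
#' bottleneck, and a three-level decoder whose skip connections pass through
#' the spatial enhancement module and whose upsampled stream passes through
#' multi-scale feature fusion blocks, ending in a 1x1 sigmoid prediction head
#' at full resolution. Weights are seeded and deterministic.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `cxrseg_model`.
#' @export
cxrseg_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "cxrseg_config"))
  if (config$use_pretrained)
    abort_config("no pretrained weights are available for the built-in backbones")
  fl <- variant_flags(config$variant)
  plan <- model_plan(config)
  C <- config$base_channels
  set.seed(seed)
  b <- new_builder()
  # encoder
  add_backbone_stage(b, "enc1", config$backbone_name, 3L, plan$enc[1])
  add_conv(b, "harm1", 1L, plan$enc[1], plan$enc[1])
  add_backbone_stage(b, "enc2", config$backbone_name, plan$enc[1], plan$enc[2])
  add_conv(b, "harm2", 1L, plan$enc[2], plan$enc[2])
  add_backbone_stage(b, "enc3", config$backbone_name, plan$enc[2], plan$enc[3])
  # bottleneck
  add_conv(b, "bott", 1L, plan$enc[3], plan$enc[3])
  if (fl$tam) {
    tokens <- (config$input_size %/% config$stage_strides[3])^2
    add_tam(b, "tam", plan$enc[3], tokens, config$attention_heads,
            config$positional_encoding)
  }
  # skip connections
  if (fl$sem) {
    add_sem(b, "sem3", plan$enc[3])
    add_sem(b, "sem2", plan$enc[2])
    add_sem(b, "sem1", plan$enc[1])
  }
  # decoder fusion blocks (deepest first); BL uses a single-scale 3x3 block
  for (i in 1:3) {
    nm <- sprintf("dec%d", 4L - i)   # dec3, dec2, dec1
    if (fl$msffb) add_msffb(b, nm, plan$dec_in[i], plan$dec_out[i])
    else {
      add_conv(b, paste0(nm, ".conv"), 3L, plan$dec_in[i], plan$dec_out[i])
      add_bn(b, paste0(nm, ".bn"), plan$dec_out[i])
    }
    if (i < 3L) add_conv(b, sprintf("up%d", 4L - i), 1L,
                         plan$enc[4L - i] + plan$dec_out[i], plan$dec_in[i + 1L])
  }
  add_conv(b, "head", 1L, plan$head_in, 1L)
  structure(list(config = config, params = b$params, state = b$state,
                 seed = as.integer(seed)),
            class = "cxrseg_model")
}

# single decoder fusion step: MS-FFB (or the baseline single-scale block)
dec_block_fwd <- function(ctx, name, x, config, use_msffb) {
  if (use_msffb) msffb_fwd(ctx, name, x, config$bn_after_relu)
  else op_relu(bn_fwd(ctx, paste0(name, ".bn"),
                      conv_fwd(ctx, paste0(name, ".conv"), x, 3L)))
}

# full forward pass; returns the requested intermediate nodes
model_forward <- function(model, x, training = FALSE,
                          collect_attention = FALSE) {
  config <- model$config
  fl <- variant_flags(config$variant)
  ctx <- new_ctx(model$params, model$state, training)
  xin <- ad_leaf(x)
  s1 <- backbone_stage_fwd(ctx, "enc1", config$backbone_name, xin)
  s2 <- backbone_stage_fwd(ctx, "enc2", config$backbone_name,
                           conv_fwd(ctx, "harm1", s1, 1L))
  s3 <- backbone_stage_fwd(ctx, "enc3", config$backbone_name,
                           conv_fwd(ctx, "harm2", s2, 1L))
  bott <- conv_fwd(ctx, "bott", s3, 1L)
  if (fl$tam)
    bott <- tam_fwd(ctx, "tam", bott, config$attention_heads,
                    config$positional_encoding, config$tam_residual,
                    collect_attention = collect_attention)
  skip <- function(nm, s) if (fl$sem) sem_fwd(ctx, nm, s) else s
  f3 <- op_concat_c(skip("sem3", s3),
                    dec_block_fwd(ctx, "dec3", bott, config, fl$msffb))
  u3 <- conv_fwd(ctx, "up3", op_upsample2(f3, config$upsample), 1L)
  f2 <- op_concat_c(skip("sem2", s2),
                    dec_block_fwd(ctx, "dec2", u3, config, fl$msffb))
  u2 <- conv_fwd(ctx, "up2", op_upsample2(f2, config$upsample), 1L)
  f1 <- op_concat_c(skip("sem1", s1),
                    dec_block_fwd(ctx, "dec1", u2, config, fl$msffb))
  logits <- conv_fwd(ctx, "head", op_upsample2(f1, config$upsample), 1L)
  probs <- op_sigmoid(logits)
  list(ctx = ctx, s1 = s1, s2 = s2, s3 = s3, bottleneck = bott,
       f3 = f3, f2 = f2, f1 = f1, logits = logits, probs = probs)
}

# validate and batch an input image (h x w x 3, h x w, or n x h x w x 3)
prep_input <- function(image, config, require_input_size = FALSE) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  x <- as_batch(image)
  d <- dim(x)
  check_finite(x, "input image")
  if (d[4] != 3L) abort_shape("input must have 3 channels")
  s <- max(config$stage_strides)
  if (d[2] %% s != 0L || d[3] %% s != 0L)
    abort_shape("input spatial size must be divisible by the largest stride")
  fl <- variant_flags(config$variant)
  if (fl$tam && config$positional_encoding &&
      (d[2] != config$input_size || d[3] != config$input_size))
    abort_shape("input size must equal config$input_size when the attention positional encoding is enabled")
  if (require_input_size && (d[2] != config$input_size || d[3] != config$input_size))
    abort_shape("input spatial size must equal config$input_size")
  x
}

#' Run the encoder stages
#'
#' @param model a [cxrseg_model()].
#' @param image an `h x w x 3` array (grayscale `h x w` matrices are
#'   replicated to 3 channels).
#' @return a list of the three stage outputs `s1`, `s2`, `s3` as
#'   `h x w x c` arrays at strides `stage_strides` with channel widths
#'   `(C, 2C, 4C)`.
#' @export
encoder_forward <- function(model, image) {
  stopifnot(inherits(model, "cxrseg_model"))
  x <- prep_input(image, model$config, require_input_size = TRUE)
  config <- model$config
  ctx <- new_ctx(model$params, model$state, FALSE)
  xin <- ad_leaf(x)
  s1 <- backbone_stage_fwd(ctx, "enc1", config$backbone_name, xin)
  s2 <- backbone_stage_fwd(ctx, "enc2", config$backbone_name,
                           conv_fwd(ctx, "harm1", s1, 1L))
  s3 <- backbone_stage_fwd(ctx, "enc3", config$backbone_name,
                           conv_fwd(ctx, "harm2", s2, 1L))
  list(s1 = unbatch(val(s1)), s2 = unbatch(val(s2)), s3 = unbatch(val(s3)))
}

#' Run the decoder on encoder features
#'
#' Fuses the three skip feature maps with the bottleneck through the decoder:
#' at each level the (optionally SEM-enhanced) skip is concatenated with the
#' fusion block applied to the upsampled deeper stream, and the prediction
#' head upsamples once more to full resolution.
#'
#' @param model a [cxrseg_model()].
#' @param s1,s2,s3 encoder stage outputs as `h x w x c` arrays.
#' @param bottleneck bottleneck feature map at the spatial size of `s3`.
#' @return the full-resolution probability grid as an `H x W` matrix.
#' @export
decoder_forward <- function(model, s1, s2, s3, bottleneck) {
  stopifnot(inherits(model, "cxrseg_model"))
  config <- model$config
  fl <- variant_flags(config$variant)
  s1 <- as_batch(s1); s2 <- as_batch(s2); s3 <- as_batch(s3)
  bott <- as_batch(bottleneck)
  if (!all(dim(bott)[2:3] == dim(s3)[2:3]))
    abort_shape("bottleneck must match the spatial size of s3")
  if (!all(dim(s2)[2:3] == 2L * dim(s3)[2:3]) ||
      !all(dim(s1)[2:3] == 2L * dim(s2)[2:3]))
    abort_shape("skip features must halve in spatial size per stage")
  ctx <- new_ctx(model$params, model$state, FALSE)
  s1 <- ad_leaf(s1); s2 <- ad_leaf(s2); s3 <- ad_leaf(s3)
  bott <- ad_leaf(bott)
  skip <- function(nm, s) if (fl$sem) sem_fwd(ctx, nm, s) else s
  f3 <- op_concat_c(skip("sem3", s3),
                    dec_block_fwd(ctx, "dec3", bott, config, fl$msffb))
  u3 <- conv_fwd(ctx, "up3", op_upsample2(f3, config$upsample), 1L)
  f2 <- op_concat_c(skip("sem2", s2),
                    dec_block_fwd(ctx, "dec2", u3, config, fl$msffb))
  u2 <- conv_fwd(ctx, "up2", op_upsample2(f2, config$upsample), 1L)
  f1 <- op_concat_c(skip("sem1", s1),
                    dec_block_fwd(ctx, "dec1", u2, config, fl$msffb))
  logits <- conv_fwd(ctx, "head", op_upsample2(f1, config$upsample), 1L)
  probs <- val(op_sigmoid(logits))
  matrix(probs[1, , , 1], dim(probs)[2], dim(probs)[3])
}

#' Predict a lung mask for one image
#'
#' Runs the full forward pass and thresholds the sigmoid output. A pixel
#' whose probability equals the threshold exactly is foreground.
#'
#' @param object a [cxrseg_model()].
#' @param image an `h x w x 3` array (or `h x w` grayscale matrix) with
#'   finite values; spatial size must be divisible by the largest stride.
#' @param threshold binarization threshold; defaults to the configured one.
#' @param ... unused.
#' @return an object of class `cxrseg_mask`: a list with `probabilities`
#'   (an `h x w` matrix in `[0, 1]`), `binary` (an `h x w` 0/1 matrix) and
#'   `threshold`.
#' @export
predict.cxrseg_model <- function(object, image,
                                 threshold = object$config$binarize_threshold,
                                 ...) {
  x <- prep_input(image, object$config)
  fw <- model_forward(object, x, training = FALSE)
  p <- val(fw$probs)
  probs <- matrix(p[1, , , 1], dim(p)[2], dim(p)[3])
  structure(list(probabilities = probs,
                 binary = (probs >= threshold) * 1L,
                 threshold = threshold),
            class = "cxrseg_mask")
}

#' Count learnable parameters
#'
#' Total number of learnable scalars (convolution kernels and biases,
#' normalization scale/shift, attention projections and positional
#' encodings); running statistics are not learnable and are excluded.
#'
#' @param x a [cxrseg_model()] or a [model_config()].
#' @return integer parameter count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "cxrseg_config")) x <- cxrseg_model(x, seed = 1L)
  stopifnot(inherits(x, "cxrseg_model"))
  sum(vapply(x$params, length, numeric(1)))
}

#' Per-layer parameter table
#'
#' @param model a [cxrseg_model()].
#' @return a data.frame with one row per parameter array (`name`, `n`).
#' @export
parameter_table <- function(model) {
  stopifnot(inherits(model, "cxrseg_model"))
  data.frame(name = names(model$params),
             n = vapply(model$params, length, numeric(1)),
             row.names = NULL)
}

#' @export
print.cxrseg_config <- function(x, ...) {
  cat("Segmentation model configuration\n")
  cat(sprintf("  variant: %s   backbone: %s\n", x$variant, x$backbone_name))
  cat(sprintf("  input: %dx%dx3   base channels: %d   strides: %s\n",
              x$input_size, x$input_size, x$base_channels,
              paste(x$stage_strides, collapse = "/")))
  cat(sprintf("  attention heads: %d   positional encoding: %s   upsample: %s\n",
              x$attention_heads, x$positional_encoding, x$upsample))
  cat(sprintf("  binarize threshold: %g\n", x$binarize_threshold))
  invisible(x)
}

#' @export
print.cxrseg_model <- function(x, ...) {
  cat(sprintf("Segmentation network (%s variant, %s backbone)\n",
              x$config$variant, x$config$backbone_name))
  cat(sprintf("  %d parameter arrays, %d learnable parameters\n",
              length(x$params), count_parameters(x)))
  invisible(x)
}

#' @export
print.cxrseg_mask <- function(x, ...) {
  cat(sprintf("Predicted mask %dx%d, threshold %g, foreground fraction %.3f\n",
              nrow(x$binary), ncol(x$binary), x$threshold, mean(x$binary)))
  invisible(x)
}
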