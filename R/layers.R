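# Parameter registration and thin layer wrappers over the autodiff ops.
# A "builder" collects named parameter arrays and batch-norm state; forward
# functions address parameters by name through a per-pass context.

new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$params <- list()
  b$state <- list()
  b
}

badd <- function(b, name, value) {
  if (!is.null(b$params[[name]])) stop("duplicate parameter: ", name)
  b$params[[name]] <- value
  invisible(b)
}

# He-normal initialization for convolution weights
add_conv <- function(b, name, k, cin, cout, bias = TRUE) {
  sd <- sqrt(2 / (k * k * cin))
  badd(b, paste0(name, ".w"),
       matrix(stats::rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout))
  if (bias) badd(b, paste0(name, ".b"), numeric(cout))
  invisible(b)
}

add_dwconv <- function(b, name, k, c) {
  sd <- sqrt(2 / (k * k))
  badd(b, paste0(name, ".w"), matrix(stats::rnorm(k * k * c, sd = sd), k * k, c))
  invisible(b)
}

add_bn <- function(b, name, c, eps = 1e-5, momentum = 0.1) {
  badd(b, paste0(name, ".g"), rep(1, c))
  badd(b, paste0(name, ".b"), numeric(c))
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(c)
  st$running_var <- rep(1, c)
  st$eps <- eps
  st$momentum <- momentum
  b$state[[name]] <- st
  invisible(b)
}

add_mat <- function(b, name, nr, nc) {
  badd(b, name, matrix(stats::rnorm(nr * nc, sd = sqrt(1 / nr)), nr, nc))
  invisible(b)
}

add_posenc <- function(b, name, tokens, c) {
  badd(b, name, matrix(stats::rnorm(tokens * c, sd = 0.02), tokens, c))
  invisible(b)
}

# per-forward-pass context: caches a leaf node per parameter so the optimizer
# can read gradients back after ad_backward()
new_ctx <- function(params, state, training = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- params
  ctx$state <- state
  ctx$training <- isTRUE(training)
  ctx$leaves <- new.env(parent = emptyenv())
  ctx$aux <- list()
  ctx
}

Pn <- function(ctx, name) {
  nd <- ctx$leaves[[name]]
  if (is.null(nd)) {
    p <- ctx$params[[name]]
    if (is.null(p)) stop("unknown parameter: ", name)
    nd <- ad_leaf(p)
    ctx$leaves[[name]] <- nd
  }
  nd
}

conv_fwd <- function(ctx, name, x, k, stride = 1L, bias = TRUE) {
  op_conv2d(x, Pn(ctx, paste0(name, ".w")),
            if (bias) Pn(ctx, paste0(name, ".b")) else NULL, k, stride)
}

dwconv_fwd <- function(ctx, name, x, k, stride = 1L) {
  op_dwconv2d(x, Pn(ctx, paste0(name, ".w")), k, stride)
}

bn_fwd <- function(ctx, name, x) {
  op_batchnorm(x, Pn(ctx, paste0(name, ".g")), Pn(ctx, paste0(name, ".b")),
               ctx$state[[name]], ctx$training)
}

# conv -> BN -> ReLU (the conventional block used by the encoder stages)
cbr_fwd <- function(ctx, name, x, k, stride = 1L) {
  op_relu(bn_fwd(ctx, paste0(name, ".bn"),
                 conv_fwd(ctx, paste0(name, ".conv"), x, k, stride)))
}

add_cbr <- function(b, name, k, cin, cout) {
  add_conv(b, paste0(name, ".conv"), k, cin, cout)
  add_bn(b, paste0(name, ".bn"), cout)
  invisible(b)
}

# set every batch-norm layer of a parameter set to the identity map
# (gamma = 1, beta = 0, running stats frozen at mean 0 / var 1, eps = 0);
# useful for arithmetic checks against hand-computed values
bn_identity <- function(object) {
  for (nm in names(object$state)) {
    st <- object$state[[nm]]
    st$running_mean[] <- 0
    st$running_var[] <- 1
    st$eps <- 0
    object$params[[paste0(nm, ".g")]][] <- 1
    object$params[[paste0(nm, ".b")]][] <- 0
  }
  object
}

# coerce an h x w x c (or h x w) feature map to the internal N,H,W,C batch
as_batch <- function(fm) {
  if (is.matrix(fm)) fm <- array(fm, c(dim(fm), 1L))
  if (length(dim(fm)) == 3L) fm <- array(fm, c(1L, dim(fm)))
  if (length(dim(fm)) != 4L) abort_shape("feature map must be h x w x c")
  fm
}

unbatch <- function(x) array(x[1, , , ], dim(x)[2:4])
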