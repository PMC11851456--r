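# Training regimen: loss functions, Adam, reduce-on-plateau learning-rate
# schedule, early stopping, checkpointing of the best-monitor weights, and
# the top-level fitting function with its S3 methods.

#' Training configuration
#'
#' @param initial_lr initial Adam learning rate (default 0.001).
#' @param max_epochs maximum number of epochs (default 60).
#' @param plateau_patience epochs without monitor improvement before the
#'   learning rate is reduced (default 5).
#' @param lr_factor multiplicative learning-rate reduction on plateau
#'   (default 0.25, i.e. reduce to a quarter; set 0.75 for the
#'   reduce-by-a-quarter reading).
#' @param early_stop_patience epochs without monitor improvement before
#'   training stops (default 12).
#' @param batch_size minibatch size (default 8).
#' @param loss_name `"bce"` (binary cross-entropy) or `"bce+dice"`
#'   (equal-weight sum with one minus the soft Dice score).
#' @param seed integer seed for weight initialization and batch shuffling.
#' @param monitor `"val_jaccard"` (maximized) or `"val_loss"` (minimized);
#'   falls back to the training partition when no validation rows exist.
#' @param monitor_goal optional early-exit value: training stops once the
#'   monitor reaches it (useful for bounded overfitting checks).
#' @return an object of class `cxrseg_train_config`.
#' @export
train_config <- function(initial_lr = 0.001,
                         max_epochs = 60L,
                         plateau_patience = 5L,
                         lr_factor = 0.25,
                         early_stop_patience = 12L,
                         batch_size = 8L,
                         loss_name = "bce",
                         seed = 0L,
                         monitor = "val_jaccard",
                         monitor_goal = NULL) {
  if (lr_factor <= 0 || lr_factor >= 1)
    abort_config("lr_factor must lie in (0, 1)")
  if (plateau_patience < 1L) abort_config("plateau_patience must be >= 1")
  if (max_epochs < 0L) abort_config("max_epochs must be >= 0")
  if (!loss_name %in% c("bce", "bce+dice"))
    abort_config("loss_name must be 'bce' or 'bce+dice'")
  if (!monitor %in% c("val_jaccard", "val_loss"))
    abort_config("monitor must be 'val_jaccard' or 'val_loss'")
  structure(list(initial_lr = initial_lr, max_epochs = as.integer(max_epochs),
                 plateau_patience = as.integer(plateau_patience),
                 lr_factor = lr_factor,
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size), loss_name = loss_name,
                 seed = as.integer(seed), monitor = monitor,
                 monitor_goal = monitor_goal),
            class = "cxrseg_train_config")
}

#' Segmentation loss
#'
#' `"bce"` is the mean pixelwise binary cross-entropy (probabilities clamped
#' away from 0/1 so the loss is always finite); `"bce+dice"` adds one minus
#' the soft Dice score (smoothing constant 1) with equal weight.
#'
#' @param probabilities numeric array in `[0, 1]`.
#' @param truth_mask binary array of the same shape.
#' @param loss_name `"bce"` or `"bce+dice"`.
#' @return a non-negative scalar.
#' @export
seg_loss <- function(probabilities, truth_mask, loss_name = "bce") {
  if (!identical(dim(probabilities), dim(truth_mask)) &&
      length(probabilities) != length(truth_mask))
    abort_validation("probabilities and truth must have the same shape")
  p <- ad_leaf(probabilities)
  t <- truth_mask
  l <- op_bce(p, t)
  if (loss_name == "bce+dice") l <- op_scalar_add(l, op_soft_dice_loss(p, t))
  val(l)
}

loss_node <- function(probs_node, truth, loss_name) {
  l <- op_bce(probs_node, truth)
  if (loss_name == "bce+dice")
    l <- op_scalar_add(l, op_soft_dice_loss(probs_node, truth))
  l
}

#' Reduce-on-plateau learning-rate step
#'
#' Pure bookkeeping on a training state: if the monitor improved, the
#' stagnation counter resets; once `plateau_patience` epochs pass without
#' improvement, the learning rate is multiplied by `lr_factor` and the
#' counter resets.
#'
#' @param state a list with `current_lr`, `best_monitor_value`,
#'   `epochs_since_improvement` (see [new_train_state()]).
#' @param monitor_value monitor value of the completed epoch.
#' @param config a [train_config()].
#' @return the updated state; `$reduced` flags whether this step cut the rate.
#' @export
lr_step <- function(state, monitor_value, config) {
  better <- if (config$monitor == "val_loss")
    monitor_value < state$best_monitor_value else
    monitor_value > state$best_monitor_value
  state$reduced <- FALSE
  if (is.na(state$best_monitor_value) || better) {
    state$best_monitor_value <- monitor_value
    state$epochs_since_improvement <- 0L
  } else {
    state$epochs_since_improvement <- state$epochs_since_improvement + 1L
    if (state$epochs_since_improvement >= config$plateau_patience) {
      state$current_lr <- state$current_lr * config$lr_factor
      state$epochs_since_improvement <- 0L
      state$reduced <- TRUE
    }
  }
  state
}

#' Fresh training state
#'
#' @param config a [train_config()].
#' @return a list with `epoch`, `current_lr`, `best_monitor_value`,
#'   `epochs_since_improvement`, `stale_epochs`, and an empty `history`.
#' @export
new_train_state <- function(config) {
  list(epoch = 0L, current_lr = config$initial_lr,
       best_monitor_value = NA_real_, epochs_since_improvement = 0L,
       stale_epochs = 0L, reduced = FALSE,
       history = data.frame(epoch = integer(), lr = numeric(),
                            train_loss = numeric(), val_loss = numeric(),
                            val_jaccard = numeric()))
}

# ---- Adam -------------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}

# stack a list of pairs into batch arrays
make_batch <- function(pairs, idx) {
  d <- dim(pairs[[idx[1]]]$image)
  x <- array(0, c(length(idx), d))
  y <- array(0, c(length(idx), d[1], d[2], 1L))
  for (i in seq_along(idx)) {
    x[i, , , ] <- pairs[[idx[i]]]$image
    y[i, , , 1] <- pairs[[idx[i]]]$mask
  }
  list(x = x, y = y)
}

# mean loss and Jaccard of a model over a list of pairs (inference mode)
evaluate_pairs <- function(model, pairs, loss_name, threshold = 0.5) {
  tot_loss <- 0
  js <- numeric(length(pairs))
  ds <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    bt <- make_batch(pairs, i)
    fw <- model_forward(model, bt$x, training = FALSE)
    pv <- val(fw$probs)
    tot_loss <- tot_loss + val(loss_node(fw$probs, bt$y, loss_name))
    pm <- (matrix(pv[1, , , 1], dim(pv)[2], dim(pv)[3]) >= threshold) * 1
    m <- compute_metrics(confusion_counts(pm, pairs[[i]]$mask))
    js[i] <- m[["jaccard"]]; ds[i] <- m[["dice"]]
  }
  list(loss = tot_loss / length(pairs), jaccard = mean(js), dice = mean(ds))
}

#' Fit the segmentation network
#'
#' Trains with Adam under the reduce-on-plateau schedule: the monitor
#' (validation Jaccard by default) is tracked each epoch, the learning rate
#' is multiplied by `lr_factor` after `plateau_patience` stagnant epochs, and
#' training stops early after `early_stop_patience` stagnant epochs. The
#' weights achieving the best monitor value are checkpointed and restored.
#'
#' @param data either a manifest data.frame (from [build_manifest()]) or a
#'   list with elements `train` and optionally `val`, each a list of
#'   `list(image =, mask =)` pairs.
#' @param model a [cxrseg_model()] or a [model_config()] (a model is then
#'   initialized with the training seed).
#' @param config a [train_config()].
#' @param target_size image size used when loading from a manifest.
#' @param log_file optional JSONL path receiving one structured line per
#'   epoch.
#' @param verbose print per-epoch progress lines.
#' @return an object of class `cxrseg_fit` with elements `model` (best
#'   weights), `state` (including the per-epoch `history` data.frame),
#'   `config`, and `stopped` (one of `"max_epochs"`, `"early_stop"`,
#'   `"monitor_goal"`).
#' @export
cxrseg_fit <- function(data, model = model_config(), config = train_config(),
                       target_size = NULL, log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "cxrseg_train_config"))
  if (inherits(model, "cxrseg_config"))
    model <- cxrseg_model(model, seed = config$seed)
  stopifnot(inherits(model, "cxrseg_model"))
  if (is.data.frame(data)) {
    ts <- if (is.null(target_size)) model$config$input_size else target_size
    data <- list(train = load_partition(data, "train", ts),
                 val = load_partition(data, "val", ts))
  }
  train_pairs <- data$train
  val_pairs <- data$val
  if (length(train_pairs) == 0L) abort_validation("training partition is empty")
  has_val <- length(val_pairs) > 0L
  state <- new_train_state(config)
  opt <- adam_new(model$params)
  best_params <- model$params
  best_state_snapshot <- lapply(model$state, as.list)
  stopped <- "max_epochs"
  set.seed(config$seed)
  n <- length(train_pairs)
  thr <- model$config$binarize_threshold
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bidx in batches) {
      bt <- make_batch(train_pairs, bidx)
      ad_begin()
      fw <- model_forward(model, bt$x, training = TRUE)
      l <- loss_node(fw$probs, bt$y, config$loss_name)
      if (!is.finite(val(l)))
        abort_validation(sprintf("non-finite loss at epoch %d", epoch))
      ad_backward(l)
      grads <- list()
      leaves <- fw$ctx$leaves
      for (nm in names(model$params)) {
        nd <- leaves[[nm]]
        if (!is.null(nd) && !is.null(nd$grad)) grads[[nm]] <- nd$grad
      }
      ad_stop()
      upd <- adam_step(opt, model$params, grads, state$current_lr)
      opt <- upd$opt
      model$params <- upd$params
      ep_loss <- ep_loss + val(l) * length(bidx)
    }
    ep_loss <- ep_loss / n
    ev <- evaluate_pairs(model, if (has_val) val_pairs else train_pairs,
                         config$loss_name, thr)
    monitor_value <- if (config$monitor == "val_loss") ev$loss else ev$jaccard
    improved <- is.na(state$best_monitor_value) ||
      (if (config$monitor == "val_loss") monitor_value < state$best_monitor_value
       else monitor_value > state$best_monitor_value)
    if (improved) {
      best_params <- model$params
      best_state_snapshot <- lapply(model$state, as.list)
      state$stale_epochs <- 0L
    } else {
      state$stale_epochs <- state$stale_epochs + 1L
    }
    state <- lr_step(state, monitor_value, config)
    state$epoch <- epoch
    state$history <- rbind(state$history,
                           data.frame(epoch = epoch, lr = state$current_lr,
                                      train_loss = ep_loss, val_loss = ev$loss,
                                      val_jaccard = ev$jaccard))
    if (verbose)
      message(sprintf("epoch %3d lr %.2e train_loss %.4f val_loss %.4f val_J %.4f",
                      epoch, state$current_lr, ep_loss, ev$loss, ev$jaccard))
    if (!is.null(log_file))
      cat(jsonlite::toJSON(list(epoch = epoch, lr = state$current_lr,
                                train_loss = ep_loss, val_loss = ev$loss,
                                val_jaccard = ev$jaccard, val_dice = ev$dice),
                           auto_unbox = TRUE, digits = NA),
          "\n", file = log_file, append = TRUE, sep = "")
    if (!is.null(config$monitor_goal)) {
      goal_hit <- if (config$monitor == "val_loss")
        monitor_value <= config$monitor_goal else
        monitor_value >= config$monitor_goal
      if (goal_hit) { stopped <- "monitor_goal"; break }
    }
    if (state$stale_epochs >= config$early_stop_patience) {
      stopped <- "early_stop"
      break
    }
  }
  model$params <- best_params
  for (nm in names(best_state_snapshot)) {
    st <- model$state[[nm]]
    for (f in names(best_state_snapshot[[nm]]))
      st[[f]] <- best_state_snapshot[[nm]][[f]]
  }
  structure(list(model = model, state = state, config = config,
                 stopped = stopped),
            class = "cxrseg_fit")
}

#' @export
print.cxrseg_fit <- function(x, ...) {
  h <- x$state$history
  cat(sprintf("Fitted segmentation network (%s variant): %d epoch(s), stopped by %s\n",
              x$model$config$variant, nrow(h), x$stopped))
  if (nrow(h) > 0L)
    cat(sprintf("  best monitor (%s): %.4f   final lr: %.2e\n",
                x$config$monitor, x$state$best_monitor_value,
                x$state$current_lr))
  invisible(x)
}

#' @export
summary.cxrseg_fit <- function(object, ...) {
  print(object)
  h <- object$state$history
  if (nrow(h) > 0L) {
    cat("  history (last 5 epochs):\n")
    print(utils::tail(h, 5L), row.names = FALSE)
  }
  invisible(object$state$history)
}

#' @export
predict.cxrseg_fit <- function(object, image, ...) {
  predict(object$model, image, ...)
}

#' Plot training curves
#'
#' Loss (training and validation) and validation Jaccard index against epoch.
#'
#' @param x a [cxrseg_fit()] result.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cxrseg_fit <- function(x, ...) {
  h <- x$state$history
  if (nrow(h) == 0L) {
    warning("no training history to plot")
    return(invisible(NULL))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  graphics::plot(h$epoch, h$val_jaccard, type = "l", xlab = "epoch",
                 ylab = "validation Jaccard", ylim = c(0, 1))
  invisible(x)
}

# ---- checkpoints ------------------------------------------------------------

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Save model weights with a configuration sidecar
#'
#' Weights are serialized to RDS; a YAML sidecar (`<path>.yml`) records the
#' model configuration and its hash, validated on load.
#'
#' @param model a [cxrseg_model()].
#' @param path checkpoint file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(params = model$params,
               state = lapply(model$state, as.list),
               seed = model$seed), path)
  yaml::write_yaml(list(config = unclass(model$config),
                        config_hash = config_hash(model$config)),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Load model weights saved by [save_checkpoint()]
#'
#' @param path checkpoint file path (the `<path>.yml` sidecar must exist).
#' @param config a [model_config()] matching the checkpoint; its hash is
#'   validated against the sidecar.
#' @return a [cxrseg_model()] with restored weights.
#' @export
load_checkpoint <- function(path, config) {
  side <- paste0(path, ".yml")
  if (!file.exists(path) || !file.exists(side))
    abort_io(paste0("checkpoint or sidecar missing: ", path))
  meta <- yaml::read_yaml(side)
  if (!identical(meta$config_hash, config_hash(config)))
    abort_config("checkpoint was produced by a different model configuration")
  blob <- readRDS(path)
  model <- cxrseg_model(config, seed = blob$seed)
  if (!identical(names(model$params), names(blob$params)))
    abort_config("checkpoint parameter names do not match the configuration")
  model$params <- blob$params
  for (nm in names(blob$state)) {
    st <- model$state[[nm]]
    for (f in names(blob$state[[nm]])) st[[f]] <- blob$state[[nm]][[f]]
  }
  model
}
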