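# Segmentation evaluation: pixel confusion counts, the five overlap scores
# (Jaccard, Dice, accuracy, sensitivity, specificity), per-image and pooled
# aggregation, and colour-coded overlay rendering.

as_binary_mask <- function(m, what = "mask") {
  if (inherits(m, "cxrseg_mask")) m <- m$binary
  m <- as.matrix(m)
  if (is.logical(m)) m <- m * 1L
  if (!all(m %in% c(0, 1))) abort_validation(paste(what, "must be binary (0/1)"))
  m
}

#' Pixel confusion counts between two binary masks
#'
#' Foreground (value 1) is the lung field. Counts always satisfy
#' `tp + tn + fp + fn == length(truth)`.
#'
#' @param predicted,truth binary `h x w` matrices (0/1 or logical) of the
#'   same shape; `predicted` may also be a `cxrseg_mask`.
#' @return an object of class `cxrseg_counts`: a list with `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion_counts <- function(predicted, truth) {
  p <- as_binary_mask(predicted, "predicted mask")
  t <- as_binary_mask(truth, "truth mask")
  if (!identical(dim(p), dim(t)))
    abort_validation("predicted and truth masks must have the same shape")
  tp <- sum(p == 1 & t == 1)
  tn <- sum(p == 0 & t == 0)
  fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn), class = "cxrseg_counts")
}

#' Segmentation scores from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' Jaccard index `TP/(TP+FP+FN)`, Dice score `2TP/(2TP+FP+FN)` and
#' specificity `TN/(TN+FP)`. When both masks are empty (TP = FP = FN = 0)
#' the overlap scores J, D and Sn are defined as 1 (vacuous agreement);
#' an empty prediction against an empty truth likewise gives Sp and Acc
#' their ordinary values.
#'
#' @param counts a [confusion_counts()] result, or a list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @return a named numeric vector with elements `jaccard`, `dice`,
#'   `accuracy`, `sensitivity`, `specificity`, all in `[0, 1]`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, tn, fp, fn) < 0)) abort_validation("counts must be non-negative")
  ratio <- function(num, den, empty = 1) if (den == 0) empty else num / den
  c(jaccard = ratio(tp, tp + fp + fn),
    dice = ratio(2 * tp, 2 * tp + fp + fn),
    accuracy = ratio(tp + tn, tp + tn + fp + fn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp))
}

#' Aggregate per-image metric entries
#'
#' Two conventions are supported: `per-image-mean` averages each score over
#' images; `pooled` sums the confusion counts over images first and applies
#' the score formulas once.
#'
#' @param reports a list of per-image entries, each a list with `counts`
#'   (a [confusion_counts()]) and optionally `metrics`; the output of
#'   [evaluate_masks()] works directly.
#' @param mode `"per-image-mean"` (default) or `"pooled"`.
#' @return a named numeric vector of the five scores plus `n_images`.
#' @export
aggregate_metrics <- function(reports, mode = c("per-image-mean", "pooled")) {
  mode <- match.arg(mode)
  if (length(reports) < 1L) abort_validation("need at least one report entry")
  if (mode == "pooled") {
    tot <- list(tp = 0, tn = 0, fp = 0, fn = 0)
    for (r in reports) for (k in names(tot)) tot[[k]] <- tot[[k]] + r$counts[[k]]
    out <- compute_metrics(tot)
  } else {
    ms <- vapply(reports, function(r) {
      if (is.null(r$metrics)) compute_metrics(r$counts) else r$metrics
    }, numeric(5))
    out <- rowMeans(ms)
  }
  c(out, n_images = length(reports))
}

#' Evaluate a set of predicted masks against ground truth
#'
#' @param predicted,truth lists of binary masks (same length, same shapes).
#' @param names optional character vector of image identifiers.
#' @return a list of per-image entries, each with `name`, `counts` and
#'   `metrics`, of class `cxrseg_report`.
#' @export
evaluate_masks <- function(predicted, truth, names = NULL) {
  if (length(predicted) != length(truth))
    abort_validation("predicted and truth lists must have equal length")
  if (is.null(names)) names <- sprintf("image_%03d", seq_along(predicted))
  out <- Map(function(p, t, nm) {
    cc <- confusion_counts(p, t)
    list(name = nm, counts = cc, metrics = compute_metrics(cc))
  }, predicted, truth, names)
  class(out) <- "cxrseg_report"
  out
}

#' Write a metrics report as CSV
#'
#' One row per image (name, the four confusion counts, and the five scores as
#' percentages with two decimals), plus two aggregate rows (per-image mean
#' and pooled).
#'
#' @param report an [evaluate_masks()] result.
#' @param path output CSV path.
#' @return the written data.frame, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  pct <- function(x) round(100 * x, 2)
  rows <- lapply(report, function(r) {
    data.frame(name = r$name, tp = r$counts$tp, tn = r$counts$tn,
               fp = r$counts$fp, fn = r$counts$fn,
               J = pct(r$metrics[["jaccard"]]), D = pct(r$metrics[["dice"]]),
               Acc = pct(r$metrics[["accuracy"]]),
               Sn = pct(r$metrics[["sensitivity"]]),
               Sp = pct(r$metrics[["specificity"]]))
  })
  df <- do.call(rbind, rows)
  for (mode in c("per-image-mean", "pooled")) {
    ag <- aggregate_metrics(report, mode)
    df <- rbind(df, data.frame(name = paste0("aggregate:", mode),
                               tp = NA, tn = NA, fp = NA, fn = NA,
                               J = pct(ag[["jaccard"]]), D = pct(ag[["dice"]]),
                               Acc = pct(ag[["accuracy"]]),
                               Sn = pct(ag[["sensitivity"]]),
                               Sp = pct(ag[["specificity"]])))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Render a colour-coded prediction overlay
#'
#' Per-pixel colouring of the prediction/truth agreement: true positives
#' green, false positives red, false negatives blue, true negatives black.
#'
#' @param predicted,truth binary masks of the same shape.
#' @param path optional PNG output path; when supplied the overlay is written
#'   with [png::writePNG()].
#' @return an `h x w x 3` RGB array in `[0, 1]`, invisibly when written.
#' @export
render_overlay <- function(predicted, truth, path = NULL) {
  p <- as_binary_mask(predicted, "predicted mask")
  t <- as_binary_mask(truth, "truth mask")
  if (!identical(dim(p), dim(t)))
    abort_validation("predicted and truth masks must have the same shape")
  rgb <- array(0, c(dim(p), 3L))
  rgb[, , 2] <- (p == 1 & t == 1) * 1  # TP green
  rgb[, , 1] <- (p == 1 & t == 0) * 1  # FP red
  rgb[, , 3] <- (p == 0 & t == 1) * 1  # FN blue
  if (!is.null(path)) {
    png::writePNG(rgb, path)
    return(invisible(rgb))
  }
  rgb
}

#' @export
print.cxrseg_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP=%d TN=%d FP=%d FN=%d (total %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' @export
print.cxrseg_report <- function(x, ...) {
  ag <- aggregate_metrics(x, "per-image-mean")
  cat(sprintf("Segmentation report over %d image(s)\n", length(x)))
  cat(sprintf("  mean J=%.2f%% D=%.2f%% Acc=%.2f%% Sn=%.2f%% Sp=%.2f%%\n",
              100 * ag[["jaccard"]], 100 * ag[["dice"]],
              100 * ag[["accuracy"]], 100 * ag[["sensitivity"]],
              100 * ag[["specificity"]]))
  invisible(x)
}
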