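# Data pipeline: image/mask loading and resizing, deterministic dataset
# splitting, and the five-fold augmentation policy (contrast x0.9 / x1.1,
# horizontal flip, vertical flip).

#' The five-fold augmentation policy tags
#'
#' @return character vector: the original plus the four variants every
#'   training image receives.
#' @export
augmentation_tags <- function() {
  c("original", "contrast-0.9", "contrast-1.1", "hflip", "vflip")
}

# read an image file into an H x W (grayscale) or H x W x C array in [0, 1];
# EBImage stores width-first, so transpose into row-major image layout
read_image_array <- function(path) {
  if (!file.exists(path)) abort_io(paste0("cannot read file: ", path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) abort_io(paste0("failed to read ", path,
                                                      ": ", conditionMessage(e))))
  a <- as.array(img)
  if (length(dim(a)) == 2L) t(a)
  else aperm(a, c(2L, 1L, 3L))[, , seq_len(min(dim(a)[3], 3L)), drop = FALSE]
}

write_image_array <- function(x, path) {
  png::writePNG(x, path)
  invisible(path)
}

resize_array <- function(x, target, nearest = FALSE) {
  img <- if (is.matrix(x)) EBImage::Image(t(x))
         else EBImage::Image(aperm(x, c(2L, 1L, 3L)), colormode = "Color")
  out <- EBImage::resize(img, w = target, h = target,
                         filter = if (nearest) "none" else "bilinear")
  a <- as.array(out)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

#' Load and harmonize an image/mask pair
#'
#' The image is resized with bilinear interpolation to
#' `target_size x target_size`, scaled to `[0, 1]`, and replicated to three
#' channels if grayscale. The mask is resized with nearest-neighbour
#' interpolation and re-binarized, so no values outside `{0, 1}` can appear;
#' both 0/1 and 0/255 mask encodings are accepted.
#'
#' @param image_path,mask_path file paths (PNG or JPEG).
#' @param target_size output spatial size in pixels (default 256).
#' @return a list with `image` (`target_size x target_size x 3` array in
#'   `[0, 1]`) and `mask` (`target_size x target_size` 0/1 matrix).
#' @export
load_pair <- function(image_path, mask_path, target_size = 256L) {
  img <- read_image_array(image_path)
  msk <- read_image_array(mask_path)
  if (length(dim(msk)) == 3L) msk <- msk[, , 1]
  rng <- range(msk)
  mid <- mean(rng)
  if (rng[2] > rng[1]) {
    clusters <- unique(round(msk, 6))
    lo <- clusters[abs(clusters - rng[1]) <= 1e-3]
    hi <- clusters[abs(clusters - rng[2]) <= 1e-3]
    if (length(lo) + length(hi) < length(clusters))
      abort_validation(paste0("mask is not binary (",
                              length(clusters), " intensity clusters): ",
                              mask_path))
  }
  # constant masks (all background / all foreground) threshold at 0.5
  msk <- if (rng[2] > rng[1]) (msk > mid) * 1 else (msk >= 0.5) * 1
  img <- pmin(pmax(img, 0), 1)
  if (!identical(dim(img)[1:2], rep(as.integer(target_size), 2L)))
    img <- resize_array(img, target_size)
  if (!identical(dim(msk), rep(as.integer(target_size), 2L)))
    msk <- resize_array(msk, target_size, nearest = TRUE)
  msk <- (msk >= 0.5) * 1
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = msk)
}

#' Deterministic train/validation/test split
#'
#' Validation and test each receive the nearest integer to a tenth of the
#' dataset; training receives the remainder. Assignment is by a seeded
#' shuffle, so the same `(n_total, seed)` always yields the same partition.
#'
#' @param n_total number of image/mask pairs (at least 3).
#' @param seed integer seed for the shuffle.
#' @return an object of class `cxrseg_split`: a list with `n_total`,
#'   `n_train`, `n_val`, `n_test`, `seed` and `assignment` (a factor of
#'   length `n_total` with levels train/val/test, in original order).
#' @export
split_dataset <- function(n_total, seed = 0L) {
  n_total <- as.integer(n_total)
  if (is.na(n_total) || n_total < 3L)
    abort_validation("n_total must be at least 3")
  n_val <- as.integer(round(n_total / 10))
  n_test <- n_val
  n_train <- n_total - n_val - n_test
  set.seed(as.integer(seed))
  ord <- sample.int(n_total)
  part <- character(n_total)
  part[ord[seq_len(n_train)]] <- "train"
  part[ord[n_train + seq_len(n_val)]] <- "val"
  part[ord[n_train + n_val + seq_len(n_test)]] <- "test"
  structure(list(n_total = n_total, n_train = n_train, n_val = n_val,
                 n_test = n_test, seed = as.integer(seed),
                 assignment = factor(part, levels = c("train", "val", "test"))),
            class = "cxrseg_split")
}

#' @export
print.cxrseg_split <- function(x, ...) {
  cat(sprintf("Dataset split (seed %d): %d total -> %d train / %d val / %d test\n",
              x$seed, x$n_total, x$n_train, x$n_val, x$n_test))
  invisible(x)
}

#' Pair image and mask files under a dataset root
#'
#' Expects `<root>/images/*.png|jpg|jpeg` and `<root>/masks/*.png`, paired by
#' identical filename stem.
#'
#' @param root dataset directory.
#' @return a data.frame with `stem`, `image_path`, `mask_path`.
#' @export
pair_files <- function(root) {
  img_dir <- file.path(root, "images")
  msk_dir <- file.path(root, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    abort_data(paste0("expected images/ and masks/ under ", root))
  imgs <- list.files(img_dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
  if (length(imgs) == 0L) abort_data(paste0("no images found under ", img_dir))
  stems <- tools::file_path_sans_ext(imgs)
  masks <- file.path(msk_dir, paste0(stems, ".png"))
  missing <- !file.exists(masks)
  if (any(missing))
    abort_data(paste0("missing mask(s) for: ",
                      paste(utils::head(stems[missing], 5L), collapse = ", ")))
  o <- order(stems)
  data.frame(stem = stems[o],
             image_path = file.path(img_dir, imgs)[o],
             mask_path = masks[o],
             stringsAsFactors = FALSE)
}

#' Expand training records with the five-fold augmentation policy
#'
#' Each original yields itself plus four variants: contrast scaling by 0.9
#' and 1.1 (masks untouched) and horizontal and vertical flips (masks
#' transformed in lockstep). Augmenting already-augmented records is an
#' error.
#'
#' @param records a manifest data.frame with an `augmentation_tag` column
#'   (all `"original"`).
#' @return the expanded data.frame, five rows per input row.
#' @export
augment_partition <- function(records) {
  if (nrow(records) == 0L) return(records)
  if (!all(records$augmentation_tag == "original"))
    abort_validation("records are already augmented")
  out <- records[rep(seq_len(nrow(records)), each = 5L), , drop = FALSE]
  out$augmentation_tag <- rep(augmentation_tags(), nrow(records))
  rownames(out) <- NULL
  out
}

#' Apply an augmentation tag to a loaded image/mask pair
#'
#' Contrast tags scale image intensities multiplicatively and clip to
#' `[0, 1]`, leaving the mask untouched; flip tags mirror image and mask
#' together (horizontal = left/right, vertical = up/down).
#'
#' @param pair a [load_pair()] result.
#' @param tag one of `"original"`, `"contrast-0.9"`, `"contrast-1.1"`,
#'   `"hflip"`, `"vflip"` (see [augmentation_tags()]).
#' @return a transformed pair.
#' @export
apply_augmentation <- function(pair, tag) {
  img <- pair$image; msk <- pair$mask
  switch(tag,
    "original" = NULL,
    "contrast-0.9" = { img <- pmin(pmax(img * 0.9, 0), 1) },
    "contrast-1.1" = { img <- pmin(pmax(img * 1.1, 0), 1) },
    "hflip" = {
      img <- img[, rev(seq_len(ncol(msk))), , drop = FALSE]
      msk <- msk[, rev(seq_len(ncol(msk)))]
    },
    "vflip" = {
      img <- img[rev(seq_len(nrow(msk))), , , drop = FALSE]
      msk <- msk[rev(seq_len(nrow(msk))), ]
    },
    abort_validation(paste0("unknown augmentation tag: ", tag))
  )
  list(image = img, mask = msk)
}

#' Build a fully reproducible experiment manifest
#'
#' Pairs files under `root`, splits them deterministically, and expands the
#' training (and optionally validation) partition with the five-fold
#' augmentation policy. The manifest alone determines the experiment.
#'
#' @param root dataset directory with `images/` and `masks/`.
#' @param seed split seed.
#' @param augment_val logical; also augment the validation partition.
#' @param path optional CSV output path.
#' @return a data.frame with `stem`, `image_path`, `mask_path`, `partition`,
#'   `augmentation_tag`, `seed`.
#' @export
build_manifest <- function(root, seed = 0L, augment_val = FALSE, path = NULL) {
  pairs <- pair_files(root)
  sp <- split_dataset(nrow(pairs), seed)
  pairs$partition <- as.character(sp$assignment)
  pairs$augmentation_tag <- "original"
  pairs$seed <- as.integer(seed)
  parts <- split(pairs, pairs$partition)
  aug <- function(df, do) if (isTRUE(do) && !is.null(df)) augment_partition(df) else df
  out <- rbind(aug(parts$train, TRUE),
               aug(parts$val, augment_val),
               parts$test)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

# load every record of a manifest partition into memory as (image, mask)
# pairs with augmentations applied
load_partition <- function(manifest, partition, target_size = 256L) {
  rows <- manifest[manifest$partition == partition, , drop = FALSE]
  cache <- new.env(parent = emptyenv())
  lapply(seq_len(nrow(rows)), function(i) {
    key <- rows$image_path[i]
    base <- cache[[key]]
    if (is.null(base)) {
      base <- load_pair(rows$image_path[i], rows$mask_path[i], target_size)
      cache[[key]] <- base
    }
    p <- apply_augmentation(base, rows$augmentation_tag[i])
    p$name <- paste0(rows$stem[i],
                     ifelse(rows$augmentation_tag[i] == "original", "",
                            paste0("_", rows$augmentation_tag[i])))
    p
  })
}
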