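# Synthetic radiograph-like phantoms with exact ground-truth masks, so the
# whole pipeline is testable without external data.  Lung mode: two
# rotated-ellipse lobes (dark, as lung fields appear on a radiograph) over a
# textured thorax background with optional rib stripes and optional bright
# in-lung opacities mimicking pathology.  Lesion mode: a single irregular
# bright blob, a stand-in for tumour segmentation data.  Every sample is
# fully determined by (spec, seed, index).

#' Phantom generator specification
#'
#' @param size image size in pixels (square; default 256).
#' @param seed integer base seed; sample `i` derives its own stream from
#'   `(seed, i)`.
#' @param lobe_scale_range length-2 fraction range of the image height that
#'   a lobe semi-axis may span; must lie within (0, 0.5].
#' @param rotation_jitter maximal lobe rotation in degrees.
#' @param contrast_range length-2 range of per-image global contrast factors.
#' @param rib_stripes logical; overlay faint horizontal rib stripes.
#' @param opacity_probability probability that a bright pathology-like blob
#'   is placed inside the lung field (masks are never altered by it).
#' @param mode `"lung"` (two lobes) or `"lesion"` (single irregular blob).
#' @return an object of class `cxrseg_phantom_spec`.
#' @export
phantom_spec <- function(size = 256L,
                         seed = 0L,
                         lobe_scale_range = c(0.26, 0.34),
                         rotation_jitter = 8,
                         contrast_range = c(0.85, 1.15),
                         rib_stripes = TRUE,
                         opacity_probability = 0.3,
                         mode = c("lung", "lesion")) {
  mode <- match.arg(mode)
  if (any(lobe_scale_range <= 0) || any(lobe_scale_range > 0.5))
    abort_config("lobe_scale_range must lie within (0, 0.5]")
  if (opacity_probability < 0 || opacity_probability > 1)
    abort_config("opacity_probability must lie in [0, 1]")
  if (size %% 8L != 0L)
    abort_config("phantom size must be divisible by 8")
  structure(list(size = as.integer(size), seed = as.integer(seed),
                 lobe_scale_range = lobe_scale_range,
                 rotation_jitter = rotation_jitter,
                 contrast_range = contrast_range,
                 rib_stripes = isTRUE(rib_stripes),
                 opacity_probability = opacity_probability,
                 mode = mode),
            class = "cxrseg_phantom_spec")
}

# filled rotated ellipse as a logical matrix
ellipse_mask <- function(size, cx, cy, a, b, theta) {
  ii <- matrix(seq_len(size), size, size)        # row index
  jj <- matrix(seq_len(size), size, size, byrow = TRUE)
  dx <- (jj - cx); dy <- (ii - cy)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# cheap separable box blur, repeated for an approximately Gaussian kernel
smooth_matrix <- function(m, passes = 3L) {
  n <- nrow(m)
  for (p in seq_len(passes)) {
    m <- (m[c(1, 1:(n - 1)), ] + m + m[c(2:n, n), ]) / 3
    m <- (m[, c(1, 1:(n - 1))] + m + m[, c(2:n, n)]) / 3
  }
  m
}

gaussian_blob <- function(size, cx, cy, sd) {
  ii <- matrix(seq_len(size), size, size)
  jj <- matrix(seq_len(size), size, size, byrow = TRUE)
  exp(-(((jj - cx)^2 + (ii - cy)^2) / (2 * sd^2)))
}

# one deterministic phantom sample; RNG stream derived from (seed, index)
phantom_sample <- function(spec, index) {
  set.seed((spec$seed * 7919L + index) %% .Machine$integer.max)
  s <- spec$size
  # textured background: vertical intensity gradient + smoothed noise
  bg <- 0.55 + 0.15 * matrix(seq(-1, 1, length.out = s), s, s) +
    0.35 * smooth_matrix(matrix(stats::runif(s * s, -1, 1), s, s), 4L)
  if (spec$mode == "lesion") {
    # single irregular bright blob: ellipse with radial wobble
    cx <- s * stats::runif(1, 0.4, 0.6); cy <- s * stats::runif(1, 0.4, 0.6)
    a <- s * stats::runif(1, 0.10, 0.18); b <- s * stats::runif(1, 0.10, 0.18)
    th <- stats::runif(1, 0, pi)
    base <- ellipse_mask(s, cx, cy, a, b, th)
    wob <- smooth_matrix(matrix(stats::runif(s * s, -1, 1), s, s), 5L)
    mask <- (base | (smooth_matrix(base * 1, 2L) + 0.25 * wob > 0.6)) * 1L
    img <- bg * 0.5 + 0.45 * mask * (0.8 + 0.2 * wob)
  } else {
    scl <- stats::runif(2, spec$lobe_scale_range[1], spec$lobe_scale_range[2])
    rot <- stats::runif(2, -1, 1) * spec$rotation_jitter * pi / 180
    # two lobes, centres well separated so the components stay disjoint
    left <- ellipse_mask(s, 0.30 * s, 0.52 * s, 0.14 * s, scl[1] * s,
                         0.12 + rot[1])
    right <- ellipse_mask(s, 0.70 * s, 0.52 * s, 0.14 * s, scl[2] * s,
                          -0.12 + rot[2])
    mask <- (left | right) * 1L
    lung_shade <- smooth_matrix(mask * 1, 3L)
    img <- bg - 0.45 * lung_shade
    if (spec$rib_stripes) {
      ii <- matrix(seq_len(s), s, s)
      img <- img + 0.05 * sin(ii / s * 10 * pi)
    }
  }
  contrast <- stats::runif(1, spec$contrast_range[1], spec$contrast_range[2])
  img <- 0.5 + (img - 0.5) * contrast
  img <- pmin(pmax(img, 0), 1)
  pair <- list(image = array(rep(img, 3L), c(s, s, 3L)), mask = mask)
  if (spec$mode == "lung" && stats::runif(1) < spec$opacity_probability)
    pair <- perturb_with_opacity(pair, spec)
  pair
}

#' Add a pathology-like bright opacity inside the lung field
#'
#' Adds a bright Gaussian blob strictly inside the mask (diseased tissue is
#' still lung field, so the ground-truth mask is unchanged).
#'
#' @param pair a `list(image =, mask =)` lung-mode pair.
#' @param spec the [phantom_spec()] that produced it.
#' @return the pair with a brightened image and identical mask.
#' @export
perturb_with_opacity <- function(pair, spec) {
  inside <- which(pair$mask == 1, arr.ind = TRUE)
  if (nrow(inside) == 0L) return(pair)
  ctr <- inside[sample.int(nrow(inside), 1L), ]
  s <- nrow(pair$mask)
  blob <- gaussian_blob(s, ctr[2], ctr[1], s * stats::runif(1, 0.03, 0.07))
  bump <- 0.5 * blob * pair$mask   # confined to the lung field
  img <- pair$image
  for (ch in 1:3) img[, , ch] <- pmin(img[, , ch] + bump, 1)
  list(image = img, mask = pair$mask)
}

#' Generate phantom image/mask pairs on disk
#'
#' Writes `images/phantom_####.png` and `masks/phantom_####.png` under
#' `out_dir` plus a `manifest.csv`; the layout matches what the data pipeline
#' consumes. Deterministic: the same spec and seed always produce
#' byte-identical files.
#'
#' @param spec a [phantom_spec()].
#' @param n number of pairs (>= 0).
#' @param out_dir output directory (created if needed). `NULL` returns the
#'   pairs in memory without writing.
#' @return invisibly, a data.frame manifest with `stem`, `image_path`,
#'   `mask_path`; when `out_dir` is `NULL`, the list of pairs.
#' @export
generate_phantoms <- function(spec, n, out_dir = NULL) {
  stopifnot(inherits(spec, "cxrseg_phantom_spec"))
  if (n < 0L) abort_validation("n must be >= 0")
  if (is.null(out_dir)) {
    return(lapply(seq_len(n), function(i) phantom_sample(spec, i)))
  }
  img_dir <- file.path(out_dir, "images")
  msk_dir <- file.path(out_dir, "masks")
  ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE) |
    dir.exists(img_dir)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    abort_io(paste0("cannot create output directory: ", out_dir))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- phantom_sample(spec, i)
    stem <- sprintf("phantom_%04d", i)
    ip <- file.path(img_dir, paste0(stem, ".png"))
    mp <- file.path(msk_dir, paste0(stem, ".png"))
    write_image_array(p$image[, , 1], ip)
    write_image_array(p$mask + 0, mp)
    rows[[i]] <- data.frame(stem = stem, image_path = ip, mask_path = mp,
                            stringsAsFactors = FALSE)
  }
  manifest <- if (n > 0L) do.call(rbind, rows) else
    data.frame(stem = character(), image_path = character(),
               mask_path = character())
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
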