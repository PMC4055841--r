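# Deterministic two-class synthetic ROI generator: "mass-like" (bright,
# roughly isotropic central blob on textured background) vs
# "parenchyma-like" (oriented streak texture, no blob).
#
# Both classes share one low-pass background process; the class-specific
# component (blob / streaks) scales with `contrast`, so contrast = 0 makes
# the two generators distributionally identical.

SYNTH_BASE <- 25000   # mean intensity, 16-bit counts
SYNTH_BG_SD <- 1500   # background-texture standard deviation, counts
SYNTH_MIN_SIDE <- 64L # keeps 5x5 grids valid at scale (24, 3)

gaussian_brush <- function(sigma) {
  side <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  EBImage::makeBrush(side, shape = "gaussian", sigma = sigma)
}

oriented_brush <- function(sigma_long, sigma_short, angle) {
  half <- as.integer(ceiling(3 * sigma_long))
  ax <- seq(-half, half)
  u <- cos(angle) * matrix(ax, 2 * half + 1, 2 * half + 1) +
    sin(angle) * matrix(ax, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  v <- -sin(angle) * matrix(ax, 2 * half + 1, 2 * half + 1) +
    cos(angle) * matrix(ax, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  k <- exp(-0.5 * ((u / sigma_long)^2 + (v / sigma_short)^2))
  k / sum(k)
}

smooth_noise <- function(h, w, brush) {
  n <- matrix(rnorm(h * w), h, w)
  f <- EBImage::filter2(n, brush, boundary = "circular")
  (f - mean(f)) / sd(f)
}

roi_dims <- function(size) {
  size <- as.integer(round(size))
  if (length(size) == 1) size <- c(size, size)
  if (any(size < SYNTH_MIN_SIDE)) {
    abort(sprintf("ROI side below minimum of %d pixels", SYNTH_MIN_SIDE))
  }
  size
}

finalize_roi <- function(base_field, noise_model) {
  h <- nrow(base_field)
  w <- ncol(base_field)
  img <- switch(noise_model,
    gaussian = base_field + 0.2 * SYNTH_BG_SD * matrix(rnorm(h * w), h, w),
    speckle = base_field * (1 + 0.02 * matrix(rnorm(h * w), h, w)),
    abort(sprintf("unknown noise model '%s'", noise_model))
  )
  round(pmin(pmax(img, 0), 65535))
}

#' Generate a mass-like synthetic ROI
#'
#' Low-pass-filtered Gaussian noise (parenchyma-like background) plus a
#' centered, anisotropy-jittered Gaussian bright blob of radius
#' 0.2-0.4 times the image side and amplitude `contrast` background
#' standard deviations. 16-bit intensity range; bit-identical for identical
#' `(size, seed, ...)`.
#'
#' @param size Side length in pixels (scalar, or `c(height, width)`);
#'   minimum 64.
#' @param seed Integer seed; the image is a pure function of the arguments.
#' @param contrast Blob amplitude in units of the background standard
#'   deviation.
#' @param noise_model `"gaussian"` (additive) or `"speckle"`
#'   (multiplicative) pixel noise.
#' @return Intensity matrix (16-bit counts).
#' @export
make_mass_roi <- function(size, seed, contrast = 5, noise_model = "gaussian") {
  dims <- roi_dims(size)
  h <- dims[1]
  w <- dims[2]
  side <- min(h, w)
  with_seed(seed, {
    bg <- smooth_noise(h, w, gaussian_brush(max(2, side / 24)))
    r_frac <- runif(1, 0.2, 0.4)
    sig <- r_frac * side / 2
    aniso <- runif(1, 0.85, 1.2)
    phi <- runif(1, 0, pi)
    cy <- (h + 1) / 2 + runif(1, -0.05, 0.05) * h
    cx <- (w + 1) / 2 + runif(1, -0.05, 0.05) * w
    yy <- matrix(seq_len(h) - cy, h, w)
    xx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
    u <- cos(phi) * xx + sin(phi) * yy
    v <- -sin(phi) * xx + cos(phi) * yy
    blob <- exp(-0.5 * ((u / (sig * aniso))^2 + (v / (sig / aniso))^2))
    field <- SYNTH_BASE + SYNTH_BG_SD * bg + contrast * SYNTH_BG_SD * blob
    finalize_roi(field, noise_model)
  })
}

#' Generate a parenchyma-like synthetic ROI
#'
#' Same background process as [make_mass_roi()] but the class-specific
#' component is an oriented streak texture (directionally filtered noise at
#' a random orientation) with no central blob.
#'
#' @inheritParams make_mass_roi
#' @return Intensity matrix (16-bit counts).
#' @export
make_normal_roi <- function(size, seed, contrast = 5, noise_model = "gaussian") {
  dims <- roi_dims(size)
  h <- dims[1]
  w <- dims[2]
  side <- min(h, w)
  with_seed(seed, {
    bg <- smooth_noise(h, w, gaussian_brush(max(2, side / 24)))
    angle <- runif(1, 0, pi)
    streaks <- smooth_noise(h, w, oriented_brush(side / 8, 1.2, angle))
    field <- SYNTH_BASE + SYNTH_BG_SD * bg +
      0.5 * contrast * SYNTH_BG_SD * streaks
    finalize_roi(field, noise_model)
  })
}

#' Generate a labeled two-class set of synthetic ROIs
#'
#' Draws per-image sizes (uniform sides in `size_range`, with a +/-8%
#' aspect jitter) and independent child seeds from one master seed, then
#' generates `n_per_class` mass-like and `n_per_class` parenchyma-like
#' ROIs. Fully deterministic given `(arguments, seed)`.
#'
#' @param n_per_class ROIs per class.
#' @param size_range `c(min, max)` side length in pixels (minimum 64).
#' @param contrast Class-component amplitude in background-SD units.
#' @param noise_model `"gaussian"` or `"speckle"`.
#' @param seed Master integer seed.
#' @return Tibble with columns `id`, `label` ("mass"/"normal"), `height`,
#'   `width`, `seed`, and list-column `image`.
#' @examples
#' rois <- synth_rois(n_per_class = 3, size_range = c(64, 80), seed = 7)
#' table(rois$label)
#' @export
synth_rois <- function(n_per_class = 100L, size_range = c(64L, 256L),
                       contrast = 5, noise_model = "gaussian", seed = 1L) {
  if (!is_count(n_per_class) || n_per_class < 1) {
    abort("`n_per_class` must be a positive integer")
  }
  if (length(size_range) != 2 || size_range[1] < SYNTH_MIN_SIDE ||
        size_range[2] < size_range[1]) {
    abort(sprintf("`size_range` must be c(min, max) with min >= %d", SYNTH_MIN_SIDE))
  }
  n <- 2L * n_per_class
  geom <- with_seed(seed, {
    side <- round(runif(n, size_range[1], size_range[2]))
    other <- pmin(pmax(round(side * runif(n, 0.92, 1.08)),
                       size_range[1]), size_range[2])
    list(h = side, w = other, seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  label <- rep(c("mass", "normal"), each = n_per_class)
  images <- purrr::map(seq_len(n), function(i) {
    gen <- if (label[i] == "mass") make_mass_roi else make_normal_roi
    gen(c(geom$h[i], geom$w[i]), geom$seeds[i],
        contrast = contrast, noise_model = noise_model)
  })
  tibble(
    id = sprintf("%s_%03d", label, c(seq_len(n_per_class), seq_len(n_per_class))),
    label = label,
    height = as.integer(geom$h),
    width = as.integer(geom$w),
    seed = geom$seeds,
    image = images
  )
}

#' Write ROIs and a label manifest to disk
#'
#' Saves every image (16-bit PGM by default) and a `manifest.csv` with
#' columns `path,label`; paths are relative to the manifest's directory.
#' The written images round-trip losslessly through [read_roi()].
#'
#' @param rois Tibble from [synth_rois()] (columns `id`, `label`, `image`).
#' @param dir Output directory (created if needed).
#' @param format `"pgm"` (default) or `"tiff"` — both written as 16-bit.
#' @return Path of the manifest file, invisibly.
#' @export
write_roi_manifest <- function(rois, dir, format = c("pgm", "tiff")) {
  format <- match.arg(format)
  ext <- if (format == "pgm") "pgm" else "tif"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rel <- sprintf("%s.%s", rois$id, ext)
  for (i in seq_len(nrow(rois))) {
    path <- file.path(dir, rel[i])
    tryCatch(write_roi(rois$image[[i]], path),
             error = function(e) abort(sprintf("failed writing %s: %s",
                                               path, conditionMessage(e))))
  }
  manifest <- file.path(dir, "manifest.csv")
  write.csv(data.frame(path = rel, label = rois$label), manifest,
            row.names = FALSE)
  invisible(manifest)
}

#' Read a `path,label` manifest
#'
#' @param path Manifest CSV with columns `path` and `label`; relative image
#'   paths are resolved against the manifest's directory.
#' @return Tibble with absolute `path` and `label` columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(df))) {
    abort("manifest must have columns `path` and `label`")
  }
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                file.path(base, df$path))
  tibble(path = abs, label = df$label)
}
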