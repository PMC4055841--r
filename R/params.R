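#' Descriptor shape parameters
#'
#' Bundle the three histogram-shape parameters of the Weber local descriptor:
#' `T` dominant gradient orientations, `M` differential-excitation segments,
#' and `S` bins per segment. A single-scale descriptor has length
#' `T * M * S`; block partitioning and scale fusion multiply that length by
#' the number of blocks and scales.
#'
#' @param t_bins Number of dominant orientations `T` (even, at least 2).
#' @param m_segments Number of excitation segments `M` (at least 1).
#' @param s_bins Bins per segment `S` (at least 1).
#' @return An object of class `wld_params`.
#' @examples
#' wld_params(4, 4, 5)   # the operator shape used throughout: 80 bins/block
#' @export
wld_params <- function(t_bins = 4L, m_segments = 4L, s_bins = 5L) {
  if (!is_count(t_bins) || t_bins < 2 || t_bins %% 2 != 0) {
    abort("`t_bins` (T) must be an even integer >= 2")
  }
  if (!is_count(m_segments) || m_segments < 1) {
    abort("`m_segments` (M) must be an integer >= 1")
  }
  if (!is_count(s_bins) || s_bins < 1) {
    abort("`s_bins` (S) must be an integer >= 1")
  }
  structure(
    list(
      t_bins = as.integer(t_bins),
      m_segments = as.integer(m_segments),
      s_bins = as.integer(s_bins)
    ),
    class = "wld_params"
  )
}

#' @export
print.wld_params <- function(x, ...) {
  cat(sprintf(
    "WLD(T = %d, M = %d, S = %d): %d bins per block per scale\n",
    x$t_bins, x$m_segments, x$s_bins, x$t_bins * x$m_segments * x$s_bins
  ))
  invisible(x)
}

#' Square-ring neighborhood scale
#'
#' A descriptor scale is a symmetric square neighborhood `(P, R)` of side
#' `2R + 1` centered on the pixel, whose `P = 8R` neighbors are the pixels on
#' the sides of the square. Supported scales are (8, 1), (16, 2) and (24, 3).
#'
#' @param p Neighbor count `P` (8, 16 or 24).
#' @param r Radius `R` in pixels (1, 2 or 3); must satisfy `P = 8R`.
#' @return An object of class `wld_scale`.
#' @examples
#' wld_scale(24, 3)
#' @export
wld_scale <- function(p = 8L, r = 1L) {
  if (!is_count(p) || !is_count(r) || !(r %in% 1:3) || p != 8L * r) {
    abort("scale must be one of (P, R) = (8, 1), (16, 2), (24, 3)")
  }
  structure(list(p = as.integer(p), r = as.integer(r)), class = "wld_scale")
}

#' @export
print.wld_scale <- function(x, ...) {
  cat(sprintf("scale (P = %d, R = %d)\n", x$p, x$r))
  invisible(x)
}

#' Parse scales given as "P:R" strings
#'
#' Convenience for command-line style input such as `"8:1,16:2,24:3"`.
#'
#' @param x A character scalar/vector of `P:R` pairs, a `wld_scale`, or a
#'   list of `wld_scale` objects (returned unchanged).
#' @return A list of `wld_scale` objects.
#' @examples
#' parse_scales("8:1,24:3")
#' @export
parse_scales <- function(x) {
  if (inherits(x, "wld_scale")) {
    return(list(x))
  }
  if (is.list(x)) {
    if (!all(vapply(x, inherits, logical(1), "wld_scale"))) {
      abort("list elements must be `wld_scale` objects")
    }
    return(x)
  }
  if (!is.character(x)) {
    abort("`x` must be a character vector of P:R pairs or wld_scale objects")
  }
  parts <- unlist(strsplit(x, ",", fixed = TRUE))
  lapply(parts, function(s) {
    pr <- suppressWarnings(as.integer(strsplit(trimws(s), ":", fixed = TRUE)[[1]]))
    if (length(pr) != 2 || anyNA(pr)) abort(sprintf("cannot parse scale '%s'", s))
    wld_scale(pr[1], pr[2])
  })
}

#' Spatial block grid
#'
#' The spatial descriptor partitions the image into `rows x cols`
#' non-overlapping blocks; each block contributes its own normalized
#' histogram.
#'
#' @param rows,cols Block-row and block-column counts (at least 1).
#' @return An object of class `block_grid`.
#' @examples
#' block_grid(4, 4)
#' @export
block_grid <- function(rows, cols = rows) {
  if (!is_count(rows) || !is_count(cols) || rows < 1 || cols < 1) {
    abort("`rows` and `cols` must be integers >= 1")
  }
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols)),
    class = "block_grid"
  )
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("%d x %d block grid (%d blocks)\n", x$rows, x$cols, x$rows * x$cols))
  invisible(x)
}

#' Parse a grid given as "RxC"
#'
#' @param x A character scalar such as `"5x5"`, or a `block_grid`
#'   (returned unchanged).
#' @return A `block_grid`.
#' @export
parse_grid <- function(x) {
  if (inherits(x, "block_grid")) {
    return(x)
  }
  rc <- suppressWarnings(as.integer(strsplit(trimws(x), "x", fixed = TRUE)[[1]]))
  if (length(rc) != 2 || anyNA(rc)) abort(sprintf("cannot parse grid '%s'", x))
  block_grid(rc[1], rc[2])
}

#' Descriptor length for a parameter combination
#'
#' Analytic length of the multiscale spatial descriptor:
#' `rows * cols * length(scales) * T * M * S`.
#'
#' @inheritParams wld_params
#' @param params A [wld_params()] object.
#' @param grid A [block_grid()] (or "RxC" string).
#' @param scales List of [wld_scale()] objects (or "P:R,..." string).
#' @return Integer feature count.
#' @examples
#' descriptor_length(wld_params(4, 4, 5), "4x4", "24:3")  # 1280
#' descriptor_length(wld_params(4, 4, 5), "5x5", "24:3")  # 2000
#' @export
descriptor_length <- function(params, grid, scales) {
  stopifnot(inherits(params, "wld_params"))
  grid <- parse_grid(grid)
  scales <- parse_scales(scales)
  as.integer(grid$rows) * grid$cols * length(scales) *
    params$t_bins * params$m_segments * params$s_bins
}
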