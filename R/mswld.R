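# Spatial block partitioning and the (multiscale) spatial descriptor.

# Split `n` pixels into `k` contiguous runs; remainder pixels go one each to
# the leading runs.
split_lengths <- function(n, k) {
  base <- n %/% k
  lens <- rep(base, k)
  extra <- n %% k
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  lens
}

#' Partition an image into a block grid
#'
#' Tiles the image exactly (no overlap, no gap) into `rows x cols` blocks in
#' row-major order. When a dimension is not divisible the remainder pixels
#' are distributed one per block to the leading blocks.
#'
#' @param img Numeric intensity matrix.
#' @param grid A [block_grid()] or "RxC" string.
#' @return A list of matrices (the blocks), row-major, with a `layout`
#'   attribute giving each block's row/col extents.
#' @examples
#' length(block_partition(matrix(0, 100, 100), block_grid(4, 4)))  # 16
#' @export
block_partition <- function(img, grid) {
  assert_gray_image(img)
  grid <- parse_grid(grid)
  if (nrow(img) < grid$rows || ncol(img) < grid$cols) {
    abort("image smaller than the block grid")
  }
  hs <- split_lengths(nrow(img), grid$rows)
  ws <- split_lengths(ncol(img), grid$cols)
  row_end <- cumsum(hs)
  row_start <- row_end - hs + 1L
  col_end <- cumsum(ws)
  col_start <- col_end - ws + 1L
  blocks <- vector("list", grid$rows * grid$cols)
  layout <- vector("list", length(blocks))
  k <- 0L
  for (i in seq_len(grid$rows)) {
    for (j in seq_len(grid$cols)) {
      k <- k + 1L
      blocks[[k]] <- img[row_start[i]:row_end[i], col_start[j]:col_end[j], drop = FALSE]
      layout[[k]] <- c(
        block_row = i, block_col = j,
        row_start = row_start[i], row_end = row_end[i],
        col_start = col_start[j], col_end = col_end[j]
      )
    }
  }
  attr(blocks, "layout") <- do.call(rbind, layout)
  blocks
}

min_block_side <- function(scale) 2L * scale$r + 3L

#' Spatial WLD descriptor (one scale)
#'
#' Computes the basic WLD histogram independently inside each block of the
#' grid (each block excludes its own `R`-pixel border) and concatenates the
#' per-block histograms in row-major block order. Each block's span is
#' L1-normalized, which makes descriptors comparable across ROI sizes
#' without any resizing.
#'
#' @param img Numeric intensity matrix.
#' @param params A [wld_params()].
#' @param grid A [block_grid()] or "RxC" string.
#' @param scale A [wld_scale()].
#' @return Numeric vector of length `rows*cols*T*M*S` with a `layout`
#'   attribute (tibble: block, scale and bin-span bookkeeping).
#' @examples
#' img <- matrix(runif(96 * 96), 96, 96)
#' length(spatial_wld(img, wld_params(4, 4, 5), "4x4", wld_scale(24, 3)))  # 1280
#' @export
spatial_wld <- function(img, params = wld_params(), grid = block_grid(4, 4),
                        scale = wld_scale(8, 1)) {
  grid <- parse_grid(grid)
  blocks <- block_partition(img, grid)
  sides <- vapply(blocks, function(b) min(dim(b)), numeric(1))
  if (min(sides) < min_block_side(scale)) {
    abort(sprintf(
      "block too small: smallest block side %d < %d required at scale (P = %d, R = %d)",
      min(sides), min_block_side(scale), scale$p, scale$r
    ))
  }
  spans <- lapply(blocks, function(b) wld_descriptor(b, params, scale))
  out <- unlist(spans, use.names = FALSE)
  len <- params$t_bins * params$m_segments * params$s_bins
  bl <- attr(blocks, "layout")
  attr(out, "layout") <- tibble(
    block = seq_along(blocks),
    block_row = bl[, "block_row"],
    block_col = bl[, "block_col"],
    p = scale$p,
    r = scale$r,
    from = (seq_along(blocks) - 1L) * len + 1L,
    to = seq_along(blocks) * len
  )
  out
}

#' Multiscale spatial WLD descriptor
#'
#' Concatenates the per-scale spatial descriptors in the given scale order
#' (ascending radius by convention). With a single scale this is identical
#' to [spatial_wld()] at that scale; with several it is the scale-fusion
#' descriptor. Every per-block per-scale span remains individually
#' L1-normalized.
#'
#' @inheritParams spatial_wld
#' @param scales List of [wld_scale()] objects or a "P:R,P:R,..." string.
#' @return Numeric vector of length `rows*cols*n_scales*T*M*S` with a
#'   `layout` attribute.
#' @examples
#' img <- matrix(runif(96 * 96), 96, 96)
#' length(multiscale_spatial_wld(img, wld_params(4, 4, 5), "4x4", "8:1,16:2,24:3"))
#' @export
multiscale_spatial_wld <- function(img, params = wld_params(),
                                   grid = block_grid(4, 4),
                                   scales = list(wld_scale(24, 3))) {
  scales <- parse_scales(scales)
  if (length(scales) == 0) abort("no scales given")
  parts <- lapply(scales, function(sc) spatial_wld(img, params, grid, sc))
  out <- unlist(parts, use.names = FALSE)
  lens <- vapply(parts, length, numeric(1))
  shift <- cumsum(c(0, lens[-length(lens)]))
  layout <- purrr::map2(parts, shift, function(p, s) {
    l <- attr(p, "layout")
    l$from <- l$from + s
    l$to <- l$to + s
    l
  })
  attr(out, "layout") <- dplyr::bind_rows(layout)
  out
}
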