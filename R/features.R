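# Dataset-level feature extraction: manifest/image tables in, feature
# tibbles out.

feature_names <- function(n) sprintf("f%04d", seq_len(n))

#' Columns holding descriptor features
#'
#' @param data A feature tibble as returned by [mswld_features()].
#' @return Character vector of feature column names (those matching
#'   `^f\\d+$`).
#' @export
feature_cols <- function(data) {
  grep("^f[0-9]+$", names(data), value = TRUE)
}

#' Extract the numeric feature matrix from a feature tibble
#'
#' @inheritParams feature_cols
#' @return Numeric matrix, one row per image.
#' @export
feature_matrix <- function(data) {
  cols <- feature_cols(data)
  if (length(cols) == 0) abort("no feature columns (f0001, ...) found")
  as.matrix(data[, cols])
}

#' Compute MSWLD descriptors for a set of ROIs
#'
#' Takes a data frame describing the ROIs — either with an `image`
#' list-column of intensity matrices (as produced by [synth_rois()]) or with
#' a `path` column of image files (a manifest) — and returns one descriptor
#' row per ROI. All non-image columns (label, id, ...) are carried through.
#'
#' @param data Data frame with an `image` list-column or a `path` column.
#' @param params A [wld_params()].
#' @param grid A [block_grid()] or "RxC" string.
#' @param scales List of [wld_scale()] or "P:R,..." string.
#' @param base_dir Optional directory that relative `path`s are resolved
#'   against.
#' @return A tibble: the carried-through columns followed by feature columns
#'   `f0001 ...`; descriptor provenance (params, grid, scales, span layout)
#'   is stored in the `wld_layout` attribute.
#' @examples
#' rois <- synth_rois(n_per_class = 2, size_range = c(64, 72), seed = 1)
#' feats <- mswld_features(rois, wld_params(4, 4, 5), "2x2", "8:1")
#' dim(feature_matrix(feats))
#' @export
mswld_features <- function(data, params = wld_params(),
                           grid = block_grid(4, 4),
                           scales = list(wld_scale(24, 3)),
                           base_dir = NULL) {
  stopifnot(is.data.frame(data))
  grid <- parse_grid(grid)
  scales <- parse_scales(scales)
  imgs <- if ("image" %in% names(data)) {
    data$image
  } else if ("path" %in% names(data)) {
    paths <- data$path
    if (!is.null(base_dir)) paths <- file.path(base_dir, paths)
    lapply(paths, read_roi)
  } else {
    abort("`data` must have an `image` list-column or a `path` column")
  }
  descs <- lapply(imgs, multiscale_spatial_wld,
                  params = params, grid = grid, scales = scales)
  mat <- do.call(rbind, descs)
  colnames(mat) <- feature_names(ncol(mat))
  meta <- data[, setdiff(names(data), "image"), drop = FALSE]
  out <- dplyr::bind_cols(as_tibble(meta), as_tibble(mat))
  attr(out, "wld_layout") <- list(
    params = params, grid = grid, scales = scales,
    spans = attr(descs[[1]], "layout")
  )
  out
}

layout_json <- function(layout) {
  list(
    T = layout$params$t_bins,
    M = layout$params$m_segments,
    S = layout$params$s_bins,
    grid = c(layout$grid$rows, layout$grid$cols),
    scales = lapply(layout$scales, function(s) list(P = s$p, R = s$r))
  )
}

#' Write / read a feature table with provenance sidecar
#'
#' `write_features()` stores the feature tibble as plain CSV plus a sidecar
#' JSON (same path with `.json` appended) recording the descriptor
#' parameters (T, M, S), grid and scales. `read_features()` restores both.
#'
#' @param data Feature tibble from [mswld_features()].
#' @param path CSV output path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the feature tibble with its `wld_layout` attribute (if the
#'   sidecar is present).
#' @export
write_features <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  layout <- attr(data, "wld_layout")
  if (!is.null(layout)) {
    jsonlite::write_json(layout_json(layout), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- as_tibble(read.csv(path, check.names = FALSE))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    j <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "wld_layout") <- list(
      params = wld_params(j$T, j$M, j$S),
      grid = block_grid(j$grid[1], j$grid[2]),
      scales = apply(j$scales, 1, function(s) wld_scale(s[["P"]], s[["R"]]))
    )
  }
  out
}

# Encode text labels to the +1 (normal) / -1 (mass) convention.
encode_labels <- function(label) {
  if (is.numeric(label)) {
    if (!all(label %in% c(-1, 1))) abort("numeric labels must be +1/-1")
    return(as.integer(label))
  }
  lab <- tolower(as.character(label))
  if (!all(lab %in% c("mass", "normal"))) {
    abort("labels must be 'mass'/'normal' or +1/-1")
  }
  ifelse(lab == "normal", 1L, -1L)
}
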