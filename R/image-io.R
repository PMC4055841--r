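# Reading and writing single-channel ROI images (PNG, PGM, TIFF).

#' Read a grayscale ROI image
#'
#' Reads an 8- or 16-bit single-channel PNG, PGM (ASCII `P2` or binary `P5`)
#' or TIFF into an integer-valued intensity matrix (original bit-depth
#' counts, not rescaled to `[0, 1]`). Multi-channel images are rejected.
#'
#' @param path File path; format is chosen by extension
#'   (`.png`, `.pgm`, `.tif`/`.tiff`).
#' @return Numeric matrix of nonnegative integer intensities.
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      x <- png::readPNG(path, info = TRUE)
      if (length(dim(x)) != 2) {
        abort(sprintf("multi-channel image not supported: %s", path))
      }
      depth <- attr(x, "info")$bit.depth %||% 8
      round(unclass(x) * (2^depth - 1))
    },
    pgm = read_pgm(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("reading TIFF requires the 'tiff' package")
      }
      x <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(x)) != 2) {
        abort(sprintf("multi-channel image not supported: %s", path))
      }
      unclass(x)
    },
    abort(sprintf("unsupported image format '%s' (%s)", ext, path))
  )
  storage <- matrix(as.numeric(img), nrow(img), ncol(img))
  assert_gray_image(storage)
  storage
}

#' Write a grayscale ROI image
#'
#' Writes an intensity matrix as 16-bit binary PGM (default), 16-bit TIFF,
#' or 8-bit PNG. PGM needs no optional dependency and round-trips 16-bit
#' counts losslessly through [read_roi()].
#'
#' @param img Numeric matrix of intensities in `[0, 65535]`
#'   (`[0, 255]` for PNG).
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_roi <- function(img, path) {
  assert_gray_image(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = write_pgm(img, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("writing TIFF requires the 'tiff' package")
      }
      tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
    },
    png = png::writePNG(img / 255, path),
    abort(sprintf("unsupported image format '%s' (%s)", ext, path))
  )
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens: magic, width, height, maxval (comments allowed)
  tokens <- character(0)
  while (length(tokens) < 4) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0) abort(sprintf("truncated PGM header: %s", path))
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      # token separator
    } else {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || grepl("[[:space:]]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2])
  h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (!(magic %in% c("P2", "P5")) || anyNA(c(w, h, maxval))) {
    abort(sprintf("not a valid PGM file: %s", path))
  }
  n <- w * h
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (maxval > 255) {
    readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "big")
  } else {
    as.integer(readBin(con, "raw", n = n))
  }
  if (length(vals) != n) abort(sprintf("truncated PGM data: %s", path))
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path, maxval = 65535L) {
  v <- as.integer(round(t(img)))  # PGM is row-major (raster order)
  if (any(v < 0) || any(v > maxval)) {
    abort(sprintf("intensities outside [0, %d]: %s", maxval, path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(img), nrow(img), maxval),
            con, eos = NULL)
  if (maxval > 255) {
    bytes <- as.raw(rbind(v %/% 256L, v %% 256L))
  } else {
    bytes <- as.raw(v)
  }
  writeBin(bytes, con)
  invisible(path)
}
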