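# Per-pixel Weber-law primitives and the basic (T, M, S) histogram.
#
# Image convention: a numeric matrix with rows running top-to-bottom and
# columns left-to-right, so img[r, c - 1] is the left neighbor and
# img[r + 1, c] the one below. Maps computed on interior pixels carry an
# `offset` attribute: the number of border pixels excluded on each side.

ring_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[pmax(abs(g$dr), abs(g$dc)) == r, , drop = FALSE]
}

shift_crop <- function(img, dr, dc, off) {
  h <- nrow(img)
  w <- ncol(img)
  img[(1 + off + dr):(h - off + dr), (1 + off + dc):(w - off + dc), drop = FALSE]
}

#' Differential excitation map
#'
#' The Weber differential excitation of a pixel is the arctangent of the
#' summed relative intensity differences with its `P` square-ring neighbors,
#' `eps = arctan( sum_i (I_i - I_c) / I_c )`, bounded in `[-pi/2, pi/2]`.
#' Positive excitation means the pixel is darker than its surround. Pixels
#' with `I_c = 0` use denominator 1 (for integer intensities this equals
#' clamping the center to 1, and it preserves invariance under multiplicative
#' rescaling of strictly positive images).
#'
#' @param img Numeric matrix of nonnegative intensities.
#' @param scale A [wld_scale()]; the `R` border pixels on each side are
#'   excluded from the result.
#' @return Matrix of excitations of size `(nrow - 2R) x (ncol - 2R)` with
#'   attribute `offset = R`.
#' @examples
#' img <- matrix(100, 3, 3); img[2, 2] <- 100
#' img[c(1, 3), ] <- 110; img[, c(1, 3)] <- 110
#' differential_excitation(img, wld_scale(8, 1))  # atan(0.8)
#' @export
differential_excitation <- function(img, scale = wld_scale(8, 1)) {
  assert_gray_image(img)
  stopifnot(inherits(scale, "wld_scale"))
  r <- scale$r
  if (nrow(img) < 2 * r + 1 || ncol(img) < 2 * r + 1) {
    abort(sprintf("image too small for scale (P = %d, R = %d)", scale$p, r))
  }
  offs <- ring_offsets(r)
  nb_sum <- 0
  for (k in seq_len(nrow(offs))) {
    nb_sum <- nb_sum + shift_crop(img, offs$dr[k], offs$dc[k], r)
  }
  center <- shift_crop(img, 0L, 0L, r)
  denom <- ifelse(center == 0, 1, center)
  eps <- atan((nb_sum - scale$p * center) / denom)
  attr(eps, "offset") <- r
  eps
}

#' Gradient orientation map
#'
#' At each interior pixel the horizontal difference `I_73` (left minus right)
#' and vertical difference `I_51` (below minus above) of the radius-1 cross
#' give the gradient orientation `theta' = atan2(I_73, I_51) + pi`, mapped
#' into `[0, 2*pi]`. Flat crosses (both differences zero) map to `pi`
#' (the `atan2(0, 0) := 0` convention). The cross stays at radius 1 at every
#' descriptor scale; only the excitation neighborhood grows with `R`.
#'
#' @param img Numeric matrix of nonnegative intensities, at least 3x3.
#' @return Matrix of angles in `[0, 2*pi]` of size `(nrow-2) x (ncol-2)` with
#'   attribute `offset = 1`.
#' @export
gradient_orientation <- function(img) {
  assert_gray_image(img)
  h <- nrow(img)
  w <- ncol(img)
  if (h < 3 || w < 3) abort("image too small: gradient orientation needs at least 3x3")
  i73 <- img[2:(h - 1), 1:(w - 2), drop = FALSE] - img[2:(h - 1), 3:w, drop = FALSE]
  i51 <- img[3:h, 2:(w - 1), drop = FALSE] - img[1:(h - 2), 2:(w - 1), drop = FALSE]
  theta <- atan2(i73, i51) + pi  # R defines atan2(0, 0) = 0
  attr(theta, "offset") <- 1L
  theta
}

#' Quantize orientations into T dominant directions
#'
#' Maps each angle to the nearest of the `T` dominant orientations
#' `phi_t = 2*pi*t/T` via `t = mod(floor(theta'/(2*pi/T) + 1/2), T)`; angles
#' within half a sector of `phi_t` quantize to `t`, and `2*pi` wraps to 0.
#'
#' @param theta_prime Numeric matrix (or vector) of angles in `[0, 2*pi]`.
#' @param t_bins Number of dominant orientations `T` (>= 2).
#' @return Integer orientation indices in `0 ... T-1`, same shape as input,
#'   propagating any `offset` attribute.
#' @export
quantize_orientation <- function(theta_prime, t_bins) {
  if (!is_count(t_bins) || t_bins < 2) abort("`t_bins` must be an integer >= 2")
  tp <- unclass(theta_prime)
  if (any(tp < -1e-9 | tp > 2 * pi + 1e-9)) {
    abort("orientation out of range: angles must lie in [0, 2*pi]")
  }
  idx <- floor(tp / (2 * pi / t_bins) + 0.5) %% t_bins
  out <- array(as.integer(idx), dim = dim(tp) %||% length(tp))
  attr(out, "offset") <- attr(theta_prime, "offset")
  out
}

# Map excitations in [-pi/2, pi/2] to interval indices 0 .. M*S - 1
# (uniform bins, upper edge closed into the last bin).
excitation_interval <- function(eps, m_segments, s_bins) {
  n_int <- m_segments * s_bins
  idx <- floor((eps + pi / 2) / (pi / n_int))
  pmin(pmax(idx, 0), n_int - 1)
}

#' Basic WLD histogram at one scale
#'
#' Bins every valid pixel by its quantized orientation `t` and its
#' differential excitation, which is split uniformly over `[-pi/2, pi/2]`
#' into `M` segments of `S` bins each. Bin order is segment-major: the
#' histogram is the concatenation of rows `H_m = {H_{m,t} : t = 0..T-1}`,
#' each `H_{m,t}` holding `S` excitation bins, for `m = 0..M-1`. The two
#' maps are intersected on their common valid region and the result is
#' L1-normalized.
#'
#' @param exc Excitation map from [differential_excitation()].
#' @param ori Orientation index map from [quantize_orientation()], computed
#'   from the same image.
#' @param params A [wld_params()].
#' @return Numeric vector of length `T*M*S` summing to 1.
#' @export
wld_histogram <- function(exc, ori, params) {
  stopifnot(inherits(params, "wld_params"))
  off_e <- attr(exc, "offset") %||% 0L
  off_o <- attr(ori, "offset") %||% 0L
  off <- max(off_e, off_o)
  # both maps come from the same image, so equal original extents
  crop <- function(m, o) {
    d <- off - o
    if (d > 0) {
      m[(1 + d):(nrow(m) - d), (1 + d):(ncol(m) - d), drop = FALSE]
    } else {
      m
    }
  }
  e <- crop(unclass(exc), off_e)
  o <- crop(unclass(ori), off_o)
  if (!all(dim(e) == dim(o))) {
    abort("excitation and orientation maps do not cover the same image")
  }
  if (length(e) == 0 || any(dim(e) <= 0)) abort("empty region: no valid pixels")
  tt <- params$t_bins
  mm <- params$m_segments
  ss <- params$s_bins
  interval <- excitation_interval(e, mm, ss)
  m_idx <- interval %/% ss
  s_idx <- interval %% ss
  bin <- m_idx * (tt * ss) + as.integer(o) * ss + s_idx + 1
  counts <- tabulate(bin, nbins = tt * mm * ss)
  counts / sum(counts)
}

#' Single-block WLD descriptor of a whole image
#'
#' Convenience wrapper computing excitation and orientation maps and the
#' basic histogram at one scale.
#'
#' @inheritParams differential_excitation
#' @inheritParams wld_histogram
#' @return Numeric vector of length `T*M*S`.
#' @export
wld_descriptor <- function(img, params = wld_params(), scale = wld_scale(8, 1)) {
  exc <- differential_excitation(img, scale)
  ori <- quantize_orientation(gradient_orientation(img), params$t_bins)
  wld_histogram(exc, ori, params)
}
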