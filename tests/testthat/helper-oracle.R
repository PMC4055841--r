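# Independent scalar-loop oracle for the WLD descriptor: classifies every
# interior pixel one at a time with plain double loops. Shares no code with
# the vectorized implementation.

oracle_pixel_excitation <- function(img, r, c, radius) {
  ic <- img[r, c]
  total <- 0
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      if (max(abs(dr), abs(dc)) == radius) {
        total <- total + (img[r + dr, c + dc] - ic)
      }
    }
  }
  atan(total / if (ic == 0) 1 else ic)
}

oracle_pixel_theta <- function(img, r, c) {
  i73 <- img[r, c - 1] - img[r, c + 1]   # left minus right
  i51 <- img[r + 1, c] - img[r - 1, c]   # below minus above
  atan2(i73, i51) + pi
}

oracle_quantize <- function(theta, t_bins) {
  floor(theta / (2 * pi / t_bins) + 0.5) %% t_bins
}

# Basic WLD histogram of a whole image at one scale; per-pixel loop.
oracle_wld_hist <- function(img, t_bins, m_seg, s_bins, radius) {
  h <- nrow(img)
  w <- ncol(img)
  counts <- numeric(t_bins * m_seg * s_bins)
  n_int <- m_seg * s_bins
  for (r in (radius + 1):(h - radius)) {
    for (c in (radius + 1):(w - radius)) {
      eps <- oracle_pixel_excitation(img, r, c, radius)
      t_idx <- oracle_quantize(oracle_pixel_theta(img, r, c), t_bins)
      interval <- floor((eps + pi / 2) / (pi / n_int))
      interval <- min(max(interval, 0), n_int - 1)
      m_idx <- interval %/% s_bins
      s_idx <- interval %% s_bins
      bin <- m_idx * (t_bins * s_bins) + t_idx * s_bins + s_idx + 1
      counts[bin] <- counts[bin] + 1
    }
  }
  counts / sum(counts)
}

# Exhaustive pair-counting AUC oracle (ties count one half).
oracle_auc <- function(scores, y, positive = -1L) {
  pos <- which(y == positive)
  neg <- which(y != positive)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total +
        if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Leave-one-feature-out 1-NN accuracy drop (selector-relevance oracle).
oracle_loo_1nn_acc <- function(x, y) {
  n <- nrow(x)
  pred <- integer(n)
  for (i in seq_len(n)) {
    d <- colSums(abs(t(x[-i, , drop = FALSE]) - x[i, ]))
    pred[i] <- y[-i][which.min(d)]
  }
  mean(pred == y)
}

random_test_image <- function(side_h, side_w = side_h, max_val = 255) {
  matrix(sample.int(max_val, side_h * side_w, replace = TRUE), side_h, side_w)
}
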