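# Brute-force Otsu oracle: enumerate every cut between consecutive sorted
# unique values and maximise the between-class variance computed from the raw
# pixel values. Independent of the package's cumulative-moment implementation.
brute_otsu <- function(x) {
  u <- sort(unique(as.numeric(x)))
  if (length(u) == 1) return(u)
  best <- -Inf
  best_k <- 1L
  for (k in seq_len(length(u) - 1)) {
    cut <- (u[k] + u[k + 1]) / 2
    lo <- x < cut
    w <- mean(lo)
    sb <- w * (1 - w) * (mean(x[lo]) - mean(x[!lo]))^2
    if (sb > best) {
      best <- sb
      best_k <- k
    }
  }
  (u[best_k] + u[best_k + 1]) / 2
}

# Measurement table built directly, bypassing images, for filter/scoring
# tests. ck and her2 are per-tile means; validity defaults to TRUE.
make_measurements <- function(ck, her2 = ck * 0.5, valid = TRUE,
                              roi_area = 500L) {
  n <- length(ck)
  data.frame(
    tile_id = sprintf("%04d_%04d", seq_len(n) - 1L, 0L),
    row = seq_len(n) - 1L, col = 0L,
    ck_mean = ck, her2_mean = her2,
    roi_area = rep_len(roi_area, n),
    valid = rep_len(valid, n),
    stringsAsFactors = FALSE
  )
}

# A converged gaussian_fit object with chosen parameters, for QC and score
# identity tests.
make_fit <- function(mu, sigma, adj_r2 = 0.95, converged = TRUE,
                     reason = NA_character_) {
  structure(list(mu = mu, sigma = sigma, amplitude = 1, adj_r2 = adj_r2,
                 converged = converged, n_bins = 50L, reason = reason),
            class = "gaussian_fit")
}

# Small imaging geometry shared by image-level tests (64 px tiles keep the
# suite fast; the acceptance tests use the full 128 px geometry).
small_imaging <- function(...) imaging_params(tile_size = 64L, ...)

small_config <- function(...) default_config(min_tiles = 10L, ...)
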