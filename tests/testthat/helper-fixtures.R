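# builders for small in-code fixtures

# minimal well-formed event table from rating vectors; onsets follow the
# 25-s trial layout so rating periods land where the design expects them
make_events <- function(pain_ratings = numeric(0), tactile_ratings = numeric(0),
                        session = 1L) {
  n <- length(pain_ratings) + length(tactile_ratings)
  if (n == 0L) {
    return(tibble::tibble(
      onset = numeric(0), duration = numeric(0), trial_id = character(0),
      session = integer(0), modality = character(0),
      physical_level = character(0), rating = numeric(0),
      rating_onset = numeric(0), rating_duration = numeric(0)
    ))
  }
  t0 <- (seq_len(n) - 1L) * 25
  tibble::tibble(
    onset = t0 + 5,
    duration = 0,
    trial_id = sprintf("s%d_t%02d", session, seq_len(n)),
    session = as.integer(session),
    modality = c(rep("pain", length(pain_ratings)),
                 rep("tactile", length(tactile_ratings))),
    physical_level = "low",
    rating = c(pain_ratings, tactile_ratings),
    rating_onset = t0 + 15,
    rating_duration = 10
  )
}

# a small noiseless cohort configuration for recovery checks
noiseless_config <- function(n_subjects = 1, grid = c(4, 4, 4), n_regions = 4,
                             region_effects = NULL, rating_amp = 0.5,
                             seed = 1L, ...) {
  if (is.null(region_effects))
    region_effects <- region_effects_table(n_regions, 0, 0,
                                           intensity_slope = 0,
                                           peak_shift_s = 0, duration_s = 0)
  cohort_config(n_subjects = n_subjects, grid = grid, n_regions = n_regions,
                region_effects = region_effects,
                noise = noise_model(0, 0, numeric(0), 0),
                rating_amp = rating_amp, seed = seed, ...)
}

# brute-force separable-free 3-D Gaussian convolution with 'reflect'
# boundaries: the independent oracle for smooth_gaussian
brute_gaussian_3d <- function(vol3d, fwhm_mm, voxel_size = c(1, 1, 1)) {
  sigma <- fwhm_mm / sqrt(8 * log(2)) / voxel_size
  d <- dim(vol3d)
  rad <- pmax(1L, ceiling(4 * sigma))
  ks <- lapply(1:3, function(a) {
    t <- (-rad[a]):rad[a]
    k <- exp(-t^2 / (2 * sigma[a]^2))
    k / sum(k)
  })
  reflect <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  out <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    acc <- 0
    for (ix in seq_along(ks[[1]])) for (iy in seq_along(ks[[2]]))
      for (iz in seq_along(ks[[3]])) {
        xx <- reflect(x + ix - rad[1] - 1L, d[1])
        yy <- reflect(y + iy - rad[2] - 1L, d[2])
        zz <- reflect(z + iz - rad[3] - 1L, d[3])
        acc <- acc + ks[[1]][ix] * ks[[2]][iy] * ks[[3]][iz] * vol3d[xx, yy, zz]
      }
    out[x, y, z] <- acc
  }
  out
}
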