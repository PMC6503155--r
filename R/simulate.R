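# truncated-normal helpers on [lo, hi]
trunc_moments <- function(mu, sigma, lo = 0, hi = 10) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(v))
}

# parent (mu, sigma) whose truncated moments hit the target mean/sd
solve_trunc_parent <- function(mean, sd, lo = 0, hi = 10) {
  obj <- function(p) {
    mm <- trunc_moments(p[1], exp(p[2]), lo, hi)
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtrunc_norm <- function(n, mu, sigma, lo = 0, hi = 10) {
  pa <- stats::pnorm(lo, mu, sigma); pb <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mu, sigma)
}

#' Perceived-intensity rating model
#'
#' Ratings are truncated Gaussians on the 0-10 scale, one distribution per
#' (modality, physical level) cell. The default cell moments are the
#' observed perceived-intensity means and SDs of the study design this
#' package emulates (pain low 2.76 +/- 1.54, pain high 5.59 +/- 1.51,
#' tactile low 3.06 +/- 1.14, tactile high 5.65 +/- 1.26); the parent
#' parameters are solved so that the *truncated* distribution attains these
#' moments.
#'
#' @param moments Tibble with columns `modality`, `physical_level`, `mean`,
#'   `sd`.
#' @return A `rating_model` tibble with solved parent parameters attached.
#' @export
rating_model <- function(moments = NULL) {
  if (is.null(moments)) {
    moments <- tibble::tribble(
      ~modality, ~physical_level, ~mean, ~sd,
      "pain",    "low",  2.76, 1.54,
      "pain",    "high", 5.59, 1.51,
      "tactile", "low",  3.06, 1.14,
      "tactile", "high", 5.65, 1.26
    )
  }
  moments <- tibble::as_tibble(moments)
  stopifnot(all(c("modality", "physical_level", "mean", "sd") %in% names(moments)),
            all(moments$sd > 0))
  parents <- t(mapply(solve_trunc_parent, moments$mean, moments$sd))
  moments$mu <- parents[, 1]
  moments$sigma <- parents[, 2]
  structure(moments, class = c("rating_model", class(moments)))
}

draw_ratings <- function(model, modality, physical_level) {
  key <- paste(modality, physical_level)
  ref <- paste(model$modality, model$physical_level)
  row <- match(key, ref)
  if (any(is.na(row))) stop("rating model lacks a (modality, level) cell", call. = FALSE)
  rtrunc_norm(length(key), model$mu[row], model$sigma[row])
}

#' Region response-structure table
#'
#' One row per region: response amplitude at mid-scale rating for each
#' modality, amplitude gain per rating unit, the extra hemodynamic delay of
#' the pain response, and the pain neural-event duration (tactile events are
#' modelled as impulses; the duration and peak shift are the two knobs that
#' give pain its later, longer response). A region is pain-preferential iff
#' `amp_pain > amp_tactile`, and conversely.
#'
#' The defaults mark the first `n_pain_pref` regions pain-preferential
#' (amplitudes 1.0 vs 0.5 a.u.), the next `n_tactile_pref` regions
#' tactile-preferential (0.5 vs 1.0), and the rest modality-neutral
#' (0.7 vs 0.7), all with intensity slope 0.12 a.u. per rating unit. The
#' pain peak shift (0.8 s) and pain duration (1.5 s) are applied to the
#' pain-preferential regions, where later, longer pain responses were
#' observed; elsewhere they are 0 so that modality-neutral regions respond
#' identically to both modalities and are genuinely null.
#'
#' @param n_regions Number of regions.
#' @param n_pain_pref,n_tactile_pref Counts of modality-preferential regions.
#' @param amp_pref,amp_nonpref,amp_null Amplitudes (a.u.) for preferred,
#'   non-preferred and neutral responses.
#' @param intensity_slope Amplitude gain per rating unit (centred at
#'   rating 5).
#' @param peak_shift_s Extra pain response delay, seconds.
#' @param duration_s Pain neural-event duration, seconds.
#' @return Tibble with columns `region_id`, `amp_pain`, `amp_tactile`,
#'   `intensity_slope`, `peak_shift_s`, `duration_s`, `preference`.
#' @export
region_effects_table <- function(n_regions,
                                 n_pain_pref = if (n_regions >= 6) 3 else 0,
                                 n_tactile_pref = if (n_regions >= 6) 3 else 0,
                                 amp_pref = 1.0, amp_nonpref = 0.5,
                                 amp_null = 0.7, intensity_slope = 0.12,
                                 peak_shift_s = 0.8, duration_s = 1.5) {
  stopifnot(n_pain_pref + n_tactile_pref <= n_regions, duration_s >= 0)
  pref <- rep("none", n_regions)
  pref[seq_len(n_pain_pref)] <- "pain"
  pref[n_pain_pref + seq_len(n_tactile_pref)] <- "tactile"
  tibble::tibble(
    region_id = seq_len(n_regions),
    amp_pain = ifelse(pref == "pain", amp_pref,
                      ifelse(pref == "tactile", amp_nonpref, amp_null)),
    amp_tactile = ifelse(pref == "tactile", amp_pref,
                         ifelse(pref == "pain", amp_nonpref, amp_null)),
    intensity_slope = intensity_slope,
    peak_shift_s = ifelse(pref == "pain", peak_shift_s, 0),
    duration_s = ifelse(pref == "pain", duration_s, 0),
    preference = pref
  )
}

#' Noise model for synthetic BOLD
#'
#' @param sigma_white White-noise SD (a.u.) before AR(1) colouring.
#' @param ar1_rho AR(1) coefficient in `[0, 1)`.
#' @param drift_amplitudes SDs of random per-voxel coefficients on the first
#'   few high-pass DCT basis functions (slow drifts, removable by the 128 s
#'   filter).
#' @param motion_leak Scaling of the motion regressors leaking into the
#'   signal (default 0; the regressors are always generated so that the GLM
#'   covariate path is exercised).
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma_white = 1, ar1_rho = 0.3,
                        drift_amplitudes = c(2, 1, 0.5), motion_leak = 0) {
  stopifnot(is.finite(sigma_white), sigma_white >= 0,
            ar1_rho >= 0, ar1_rho < 1, all(is.finite(drift_amplitudes)),
            is.finite(motion_leak))
  structure(list(sigma_white = sigma_white, ar1_rho = ar1_rho,
                 drift_amplitudes = drift_amplitudes, motion_leak = motion_leak),
            class = "noise_model")
}

#' Full generative specification of a synthetic cohort
#'
#' Defaults reproduce the emulated study design: two sessions of 24 trials,
#' each trial 25 s long (2 s lead-in, 10 s stimulation window containing one
#' uniformly timed stimulus, 3 s gap, 10 s rating period), TR 0.8 s, six
#' alternating same-modality blocks of four trials per session with two low
#' and two high physical intensities in random order within each block.
#'
#' @param n_subjects Number of subjects.
#' @param grid Spatial grid dimensions (length 3).
#' @param n_regions Number of parcellation regions.
#' @param tr_s Repetition time, seconds.
#' @param sessions Sessions per subject.
#' @param trials_per_session Trials per session (multiple of 2 *
#'   `trials_per_block`).
#' @param lead_in_s,stim_window_s,gap_s,rating_s Trial layout constants,
#'   seconds.
#' @param rating_model A [rating_model()].
#' @param region_effects A [region_effects_table()].
#' @param noise A [noise_model()].
#' @param rating_amp Amplitude of the rating-period response, common to all
#'   regions (a.u.).
#' @param hrf An [hrf_spec()].
#' @param seed Integer master seed; per-subject streams are derived from
#'   (seed, subject index).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 8, grid = c(12, 12, 12), n_regions = 8,
                          tr_s = 0.8, sessions = 2, trials_per_session = 24,
                          lead_in_s = 2, stim_window_s = 10, gap_s = 3,
                          rating_s = 10, rating_model = isointense::rating_model(),
                          region_effects = region_effects_table(n_regions),
                          noise = noise_model(), rating_amp = 0.5,
                          hrf = hrf_spec(), seed = 1L) {
  stopifnot(n_subjects >= 1, length(grid) == 3, all(grid >= 1), n_regions >= 1,
            tr_s > 0, sessions >= 1, trials_per_session >= 1,
            lead_in_s >= 0, stim_window_s >= 0, gap_s >= 0, rating_s >= 0,
            nrow(region_effects) == n_regions)
  trial_len <- lead_in_s + stim_window_s + gap_s + rating_s
  structure(
    list(n_subjects = as.integer(n_subjects), grid = as.integer(grid),
         n_regions = as.integer(n_regions), tr_s = tr_s,
         sessions = as.integer(sessions),
         trials_per_session = as.integer(trials_per_session),
         lead_in_s = lead_in_s, stim_window_s = stim_window_s, gap_s = gap_s,
         rating_s = rating_s, trial_len_s = trial_len,
         n_scans = as.integer(round(trials_per_session * trial_len / tr_s)),
         rating_model = rating_model, region_effects = region_effects,
         noise = noise, rating_amp = rating_amp, hrf = hrf,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# deterministic per-(seed, subject, stage) stream seed below 2^31
subject_seed <- function(seed, subject_index, stage) {
  as.integer((as.double(seed %% 59999L) * 35051 +
                subject_index * 1009 + stage * 97) %% 2147483647)
}

#' Simulate one subject's event table
#'
#' Per session: six alternating same-modality blocks of four trials, two low
#' and two high physical intensities in random order within each block; the
#' starting modality alternates across sessions and subjects so it is
#' balanced. Trial t (0-based) occupies `[25 t, 25 (t+1))` s; its single
#' stimulus onset is uniform over the 10-s stimulation window and the rating
#' period starts 15 s into the trial. Ratings are drawn from the truncated
#' Gaussian rating model.
#'
#' @param config A [cohort_config()].
#' @param subject_index 1-based subject index.
#' @return A validated events tibble.
#' @export
simulate_events <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(subject_seed(config$seed, subject_index, 1L))
  trials_per_block <- 4L
  n_blocks <- config$trials_per_session %/% trials_per_block
  rows <- list()
  for (s in seq_len(config$sessions)) {
    start_pain <- (subject_index + s) %% 2L == 0L
    first_two <- if (start_pain) c("pain", "tactile") else c("tactile", "pain")
    block_mod <- rep(first_two, length.out = n_blocks)
    modality <- rep(block_mod, each = trials_per_block)
    level <- as.vector(vapply(seq_len(n_blocks),
                              function(b) sample(c("low", "low", "high", "high")),
                              character(trials_per_block)))
    t0 <- (seq_len(config$trials_per_session) - 1L) * config$trial_len_s
    onset <- t0 + config$lead_in_s + stats::runif(config$trials_per_session) *
      config$stim_window_s
    rating <- draw_ratings(config$rating_model, modality, level)
    rows[[s]] <- tibble::tibble(
      onset = onset, duration = 0,
      trial_id = sprintf("sub%02d_s%d_t%02d", subject_index, s,
                         seq_len(config$trials_per_session)),
      session = s, modality = modality, physical_level = level,
      rating = rating,
      rating_onset = t0 + config$lead_in_s + config$stim_window_s + config$gap_s,
      rating_duration = config$rating_s
    )
  }
  validate_events(dplyr::bind_rows(rows))
}

#' Simulate a parcellation tiling the grid
#'
#' Deterministic balanced recursive bisection of the in-mask voxels along
#' the longest coordinate extent, yielding contiguous, compact regions of
#' near-equal size.
#'
#' @param config A [cohort_config()].
#' @return A [parcellation()].
#' @export
simulate_parcellation <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_vox <- prod(config$grid)
  if (config$n_regions > n_vox %/% 8L)
    stop(sprintf("cannot fit %d regions of >= 8 voxels into %d voxels",
                 config$n_regions, n_vox), call. = FALSE)
  co <- arrayInd(seq_len(n_vox), config$grid)
  labels <- integer(n_vox)
  split_rec <- function(vox, k, next_label) {
    if (k == 1L) {
      labels[vox] <<- next_label
      return(next_label + 1L)
    }
    k1 <- k %/% 2L
    ext <- apply(co[vox, , drop = FALSE], 2L, function(x) diff(range(x)))
    ax <- which.max(ext)
    ord <- vox[order(co[vox, ax], co[vox, (ax %% 3L) + 1L], vox)]
    n1 <- round(length(vox) * k1 / k)
    nl <- split_rec(ord[seq_len(n1)], k1, next_label)
    split_rec(ord[(n1 + 1L):length(vox)], k - k1, nl)
  }
  split_rec(seq_len(n_vox), config$n_regions, 1L)
  parcellation(array(labels, config$grid))
}

ar1_noise <- function(n_t, n_v, sigma, rho) {
  w <- matrix(stats::rnorm(n_t * n_v), n_t, n_v)
  if (rho > 0) {
    w <- apply(w, 2L, function(x) as.numeric(stats::filter(x, rho, method = "recursive")))
    w <- w * sqrt(1 - rho^2)  # restore unit marginal variance (stationary)
  }
  w * sigma
}

smooth_random_walk <- function(n_t, scale = 0.02, span = 15L) {
  x <- cumsum(stats::rnorm(n_t, sd = scale))
  k <- rep(1 / span, span)
  pad <- c(rep(x[1], span), x, rep(x[n_t], span))
  as.numeric(stats::filter(pad, k, sides = 2L))[span + seq_len(n_t)]
}

#' Simulate a subject's BOLD data
#'
#' Every voxel of region g carries the region's trial-evoked signal: for
#' each stimulus, an HRF response (shifted by `peak_shift_s` and convolved
#' with a `duration_s` boxcar for pain; an impulse for tactile) with
#' amplitude `amp_modality(g) + intensity_slope(g) * (rating - 5)`, plus a
#' rating-period response of common amplitude (10-s boxcar), built with the
#' same microtime convolution the design builder uses. Slow DCT drifts,
#' AR(1)-coloured white noise and (optionally) leaked motion are added per
#' voxel. All randomness derives from the per-subject stream
#' (seed, subject index).
#'
#' @param config A [cohort_config()].
#' @param events Events from [simulate_events()] for the same subject.
#' @param parc A [parcellation()] from [simulate_parcellation()].
#' @param subject_index 1-based subject index.
#' @return A subject dataset: list with `bold` (list of per-session
#'   [bold_volume()]s), `events`, `motion` (list of T x 6 matrices),
#'   `subject`.
#' @export
simulate_bold <- function(config, events, parc, subject_index = 1L) {
  stopifnot(inherits(config, "cohort_config"), inherits(parc, "parcellation"))
  set.seed(subject_seed(config$seed, subject_index, 2L))
  re <- config$region_effects
  n_scans <- config$n_scans
  tr <- config$tr_s
  lab <- as.vector(parc$labels)
  n_vox <- length(lab)
  bold <- vector("list", config$sessions)
  motion <- vector("list", config$sessions)
  for (s in seq_len(config$sessions)) {
    ev <- events[events$session == s, , drop = FALSE]
    region_sig <- matrix(0, length(parc$region_ids), n_scans)
    for (gi in seq_along(parc$region_ids)) {
      g <- re[re$region_id == parc$region_ids[gi], , drop = FALSE]
      amp <- ifelse(ev$modality == "pain", g$amp_pain, g$amp_tactile) +
        g$intensity_slope * (ev$rating - 5)
      is_pain <- ev$modality == "pain"
      sig <- numeric(n_scans)
      if (any(is_pain))
        sig <- sig + convolve_events(ev$onset[is_pain],
                                     rep(g$duration_s, sum(is_pain)),
                                     amp[is_pain], n_scans, tr, config$hrf,
                                     shift_s = g$peak_shift_s)
      if (any(!is_pain))
        sig <- sig + convolve_events(ev$onset[!is_pain], 0, amp[!is_pain],
                                     n_scans, tr, config$hrf)
      sig <- sig + convolve_events(ev$rating_onset, ev$rating_duration,
                                   rep(config$rating_amp, nrow(ev)),
                                   n_scans, tr, config$hrf)
      region_sig[gi, ] <- sig
    }
    mot <- vapply(1:6, function(j) smooth_random_walk(n_scans), numeric(n_scans))
    motion[[s]] <- mot
    dat <- matrix(0, n_vox, n_scans)
    in_mask <- lab > 0L
    dat[in_mask, ] <- region_sig[match(lab[in_mask], parc$region_ids), , drop = FALSE]
    nm <- config$noise
    if (length(nm$drift_amplitudes)) {
      db <- dct_drift_basis(n_scans, tr)
      k <- min(length(nm$drift_amplitudes), ncol(db))
      if (k > 0) {
        coef <- matrix(stats::rnorm(n_vox * k), n_vox, k) *
          rep(nm$drift_amplitudes[seq_len(k)], each = n_vox)
        dat <- dat + coef %*% t(db[, seq_len(k), drop = FALSE])
      }
    }
    if (nm$sigma_white > 0)
      dat <- dat + t(ar1_noise(n_scans, n_vox, nm$sigma_white, nm$ar1_rho))
    if (nm$motion_leak != 0) {
      load <- matrix(stats::rnorm(n_vox * 6), n_vox, 6) * nm$motion_leak
      dat <- dat + load %*% t(mot)
    }
    bold[[s]] <- bold_volume(array(dat, c(config$grid, n_scans)), tr = tr,
                             voxel_size = c(3, 3, 3))
  }
  list(bold = bold, events = events, motion = motion, subject = subject_index)
}

#' Simulate a full subject or cohort
#'
#' @param config A [cohort_config()].
#' @param subject_index Subject to simulate.
#' @param parc Optional precomputed parcellation (rebuilt if `NULL`).
#' @return `simulate_subject`: one subject dataset. `simulate_cohort`: list
#'   with `subjects` (list of datasets), `parcellation`, `config`.
#' @export
simulate_subject <- function(config, subject_index = 1L, parc = NULL) {
  if (is.null(parc)) parc <- simulate_parcellation(config)
  events <- simulate_events(config, subject_index)
  simulate_bold(config, events, parc, subject_index)
}

#' @rdname simulate_subject
#' @export
simulate_cohort <- function(config) {
  parc <- simulate_parcellation(config)
  subjects <- purrr::map(seq_len(config$n_subjects), simulate_subject,
                         config = config, parc = parc)
  list(subjects = subjects, parcellation = parc, config = config)
}
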