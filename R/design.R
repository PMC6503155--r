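# Shared forward model: HRF-convolved regressor sampled at scan times.
#
# Events are represented on a microtime grid (dt = tr / bins). Zero-duration
# events are unit-area impulses (height amplitude / dt for one bin); positive
# durations are boxcars of the given amplitude. Convolution with the kernel is
# scaled by dt so both conventions converge to the continuous-time model. The
# scan value is read at the microtime onset bin of each TR. The synthetic
# generator composes signals with this same routine, so model-based fits are
# exact on noiseless data.
convolve_events <- function(onsets, durations, amplitudes, n_scans, tr,
                            spec = hrf_spec(), shift_s = 0, derivative = FALSE) {
  bins <- spec$microtime_bins_per_tr
  dt <- tr / bins
  n_micro <- n_scans * bins
  h <- canonical_hrf(spec, dt)
  if (derivative) h <- hrf_derivative(h, dt)
  lh <- length(h)
  hc <- cumsum(h) * dt  # running integral, for boxcar responses
  x <- numeric(n_micro)
  if (length(onsets)) {
    durations <- rep_len(durations, length(onsets))
    amplitudes <- rep_len(amplitudes, length(onsets))
    for (i in seq_along(onsets)) {
      s0 <- floor((onsets[i] + shift_s) / dt) + 1L
      if (s0 > n_micro || s0 < 1L) next
      if (durations[i] <= 0) {
        # unit-area impulse: a shifted copy of the kernel
        m <- s0:min(n_micro, s0 + lh - 1L)
        x[m] <- x[m] + amplitudes[i] * h[m - s0 + 1L]
      } else {
        # boxcar: difference of the kernel's running integral (support
        # ends nb + lh bins after onset)
        nb <- max(1L, round(durations[i] / dt))
        m <- s0:min(n_micro, s0 + nb + lh - 1L)
        r <- m - s0 + 1L
        k1 <- pmin(r, lh)
        k0 <- pmax(pmin(r - nb, lh), 0L)
        x[m] <- x[m] + amplitudes[i] * (hc[k1] - c(0, hc)[k0 + 1L])
      }
    }
  }
  idx <- (seq_len(n_scans) - 1L) * bins + spec$microtime_onset_bin
  x[idx]
}

#' Discrete cosine high-pass drift basis
#'
#' The standard fMRI high-pass filter implemented by regression: DCT basis
#' functions whose periods exceed the cut-off are included as drift columns.
#' The number of functions is `floor(2 * T * tr / cutoff)`.
#'
#' @param n_scans Number of scans in the session.
#' @param tr Repetition time, seconds.
#' @param cutoff_s High-pass cut-off period, seconds (default 128).
#' @return A `n_scans` x K matrix of orthonormal drift regressors (possibly
#'   zero columns when the session is shorter than the cut-off).
#' @export
dct_drift_basis <- function(n_scans, tr, cutoff_s = 128) {
  k_max <- floor(2 * n_scans * tr / cutoff_s)
  if (k_max < 1L) return(matrix(numeric(0), nrow = n_scans, ncol = 0L))
  t <- seq_len(n_scans) - 1L
  b <- vapply(
    seq_len(k_max),
    function(k) sqrt(2 / n_scans) * cos(pi * (2 * t + 1) * k / (2 * n_scans)),
    numeric(n_scans)
  )
  colnames(b) <- paste0("dct", seq_len(k_max))
  b
}

new_design_matrix <- function(mat, columns, row_session, tr) {
  stopifnot(nrow(columns) == ncol(mat), length(row_session) == nrow(mat))
  colnames(mat) <- columns$name
  structure(
    list(matrix = mat, columns = columns, row_session = row_session, tr = tr),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf(
    "<design_matrix> %d scans x %d columns (%s)\n",
    nrow(x$matrix), ncol(x$matrix),
    paste(sprintf("%d %s", table(x$columns$kind), names(table(x$columns$kind))),
          collapse = ", ")
  ))
  invisible(x)
}

# assemble the per-session nuisance block (motion, drift, session mean)
session_nuisance <- function(n_scans, tr, motion, hp_cutoff_s, session) {
  cols <- list(); meta <- list()
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_scans)
      stop(sprintf("motion rows (%d) must equal session scans (%d)", nrow(motion), n_scans),
           call. = FALSE)
    for (j in seq_len(ncol(motion))) {
      cols[[length(cols) + 1L]] <- motion[, j]
      meta[[length(meta) + 1L]] <-
        list(name = sprintf("s%d_motion%d", session, j), kind = "nuisance", condition = NA)
    }
  }
  drift <- dct_drift_basis(n_scans, tr, hp_cutoff_s)
  for (j in seq_len(ncol(drift))) {
    cols[[length(cols) + 1L]] <- drift[, j]
    meta[[length(meta) + 1L]] <-
      list(name = sprintf("s%d_drift%d", session, j), kind = "drift", condition = NA)
  }
  cols[[length(cols) + 1L]] <- rep(1, n_scans)
  meta[[length(meta) + 1L]] <-
    list(name = sprintf("s%d_mean", session), kind = "session_mean", condition = NA)
  list(cols = cols, meta = meta)
}

assemble_design <- function(per_session, tr) {
  sessions <- sort(unique(vapply(per_session, `[[`, 1L, "session")))
  mats <- list(); metas <- list(); row_session <- integer(0)
  # block-diagonal across sessions
  n_cols_total <- sum(vapply(per_session, function(s) length(s$cols), 1L))
  n_rows_total <- sum(vapply(per_session, function(s) s$n_scans, 1L))
  mat <- matrix(0, n_rows_total, n_cols_total)
  meta <- vector("list", n_cols_total)
  r0 <- 0L; c0 <- 0L
  for (s in per_session) {
    for (j in seq_along(s$cols)) {
      mat[r0 + seq_len(s$n_scans), c0 + j] <- s$cols[[j]]
      meta[[c0 + j]] <- c(s$meta[[j]], list(session = s$session))
    }
    row_session <- c(row_session, rep(s$session, s$n_scans))
    r0 <- r0 + s$n_scans; c0 <- c0 + length(s$cols)
  }
  columns <- dplyr::bind_rows(lapply(meta, function(m)
    tibble::tibble(name = m$name, kind = m$kind,
                   condition = as.character(m$condition), session = m$session)))
  new_design_matrix(mat, columns, row_session, tr)
}

condition_block <- function(onsets, durations, amplitudes, n_scans, tr, spec,
                            session, condition, with_derivative = TRUE) {
  cols <- list(); meta <- list()
  x <- convolve_events(onsets, durations, amplitudes, n_scans, tr, spec)
  cols[[1L]] <- x
  meta[[1L]] <- list(name = sprintf("s%d_%s", session, condition),
                     kind = "condition", condition = condition)
  if (with_derivative) {
    xd <- convolve_events(onsets, durations, amplitudes, n_scans, tr, spec,
                          derivative = TRUE)
    cols[[2L]] <- xd
    meta[[2L]] <- list(name = sprintf("s%d_%s_deriv", session, condition),
                       kind = "derivative", condition = condition)
  }
  list(cols = cols, meta = meta)
}

#' Build the five-condition first-level design matrix
#'
#' Per session: intensity-matched painful stimuli, intensity-matched tactile
#' stimuli, remaining painful stimuli, remaining tactile stimuli (all as
#' brief impulses) and the rating period (boxcars), each convolved with the
#' canonical HRF at microtime resolution, plus the temporal derivatives of
#' the five conditions, the six head-motion parameters, DCT drift regressors
#' for periods above the high-pass cut-off, and a session mean. Conditions
#' with zero events are omitted with a warning; the recorded column map makes
#' the omission explicit.
#'
#' @param events An events tibble covering the modelled sessions.
#' @param match A `match_result` from [match_trials()] defining the
#'   matched/remaining partition.
#' @param n_scans Integer vector, scans per session (recycled if length 1).
#' @param tr Repetition time, seconds.
#' @param motion List of per-session T x 6 motion-parameter matrices (or
#'   `NULL` to omit).
#' @param hp_cutoff_s High-pass cut-off, seconds (default 128).
#' @param hrf An [hrf_spec()].
#' @param stim_duration_s Modelled stimulus duration, seconds (default 0:
#'   impulses).
#' @return A `design_matrix`.
#' @export
build_design_5cond <- function(events, match, n_scans, tr, motion = NULL,
                               hp_cutoff_s = 128, hrf = hrf_spec(),
                               stim_duration_s = 0) {
  events <- label_matched(events, match)
  sessions <- sort(unique(events$session))
  n_scans <- rep_len(as.integer(n_scans), length(sessions))
  per_session <- vector("list", length(sessions))
  for (si in seq_along(sessions)) {
    s <- sessions[si]
    ev <- events[events$session == s, , drop = FALSE]
    spec5 <- list(
      matched_pain = ev$matched & ev$modality == "pain",
      matched_tactile = ev$matched & ev$modality == "tactile",
      other_pain = !ev$matched & ev$modality == "pain",
      other_tactile = !ev$matched & ev$modality == "tactile"
    )
    cols <- list(); meta <- list()
    for (cname in names(spec5)) {
      sel <- spec5[[cname]]
      if (!any(sel)) {
        warning(sprintf("condition '%s' has no events in session %d; column omitted",
                        cname, s), call. = FALSE)
        next
      }
      blk <- condition_block(ev$onset[sel], rep(stim_duration_s, sum(sel)),
                             rep(1, sum(sel)), n_scans[si], tr, hrf, s, cname)
      cols <- c(cols, blk$cols); meta <- c(meta, blk$meta)
    }
    blk <- condition_block(ev$rating_onset, ev$rating_duration, rep(1, nrow(ev)),
                           n_scans[si], tr, hrf, s, "rating")
    cols <- c(cols, blk$cols); meta <- c(meta, blk$meta)
    nui <- session_nuisance(n_scans[si], tr,
                            if (is.null(motion)) NULL else motion[[si]],
                            hp_cutoff_s, s)
    per_session[[si]] <- list(session = s, n_scans = n_scans[si],
                              cols = c(cols, nui$cols), meta = c(meta, nui$meta))
  }
  assemble_design(per_session, tr)
}

#' Build the parametric perceived-intensity design matrix
#'
#' Per session: one regressor collapsing all painful and tactile stimuli, one
#' parametric modulator whose impulse heights are the session-mean-centred
#' perceived-intensity ratings, one rating-period regressor, motion, drift
#' and session-mean columns. When all ratings in a session are identical the
#' modulator is identically zero and is omitted with a warning.
#'
#' @inheritParams build_design_5cond
#' @return A `design_matrix`.
#' @export
build_design_parametric <- function(events, n_scans, tr, motion = NULL,
                                    hp_cutoff_s = 128, hrf = hrf_spec(),
                                    stim_duration_s = 0) {
  events <- validate_events(events)
  sessions <- sort(unique(events$session))
  n_scans <- rep_len(as.integer(n_scans), length(sessions))
  per_session <- vector("list", length(sessions))
  for (si in seq_along(sessions)) {
    s <- sessions[si]
    ev <- events[events$session == s, , drop = FALSE]
    cols <- list(); meta <- list()
    blk <- condition_block(ev$onset, rep(stim_duration_s, nrow(ev)),
                           rep(1, nrow(ev)), n_scans[si], tr, hrf, s, "all_stim",
                           with_derivative = FALSE)
    cols <- c(cols, blk$cols); meta <- c(meta, blk$meta)
    centred <- ev$rating - mean(ev$rating)
    if (all(centred == 0)) {
      warning(sprintf("all ratings identical in session %d; modulator column omitted", s),
              call. = FALSE)
    } else {
      blk <- condition_block(ev$onset, rep(stim_duration_s, nrow(ev)), centred,
                             n_scans[si], tr, hrf, s, "rating_mod",
                             with_derivative = FALSE)
      cols <- c(cols, blk$cols); meta <- c(meta, blk$meta)
    }
    blk <- condition_block(ev$rating_onset, ev$rating_duration, rep(1, nrow(ev)),
                           n_scans[si], tr, hrf, s, "rating",
                           with_derivative = FALSE)
    cols <- c(cols, blk$cols); meta <- c(meta, blk$meta)
    nui <- session_nuisance(n_scans[si], tr,
                            if (is.null(motion)) NULL else motion[[si]],
                            hp_cutoff_s, s)
    per_session[[si]] <- list(session = s, n_scans = n_scans[si],
                              cols = c(cols, nui$cols), meta = c(meta, nui$meta))
  }
  assemble_design(per_session, tr)
}
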