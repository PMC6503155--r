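#' Trial time-course extraction window
#'
#' @param pre_s Seconds of pre-stimulus signal defining the baseline
#'   (default 1.6 s = 2 samples at TR 0.8).
#' @param post_s Seconds of post-stimulus signal (default 20 s, covering the
#'   hemodynamic return plus the prolonged pain response).
#' @return A `timecourse_window` list.
#' @export
timecourse_window <- function(pre_s = 1.6, post_s = 20) {
  stopifnot(pre_s >= 0, post_s > 0)
  structure(list(pre_s = pre_s, post_s = post_s), class = "timecourse_window")
}

window_offsets <- function(window, tr) {
  k <- seq.int(-round(window$pre_s / tr), round(window$post_s / tr))
  k * tr
}

# region-mean signal matrix (regions x T) for one session
region_means <- function(vol, parc) {
  lab <- as.vector(parc$labels)
  keep <- lab > 0L
  d <- dim(vol$data)
  m <- matrix(vol$data, nrow = prod(d[1:3]))[keep, , drop = FALSE]
  g <- factor(lab[keep], levels = parc$region_ids)
  if (any(table(g) == 0L))
    stop(sprintf("empty region: %s",
                 paste(parc$region_ids[table(g) == 0L], collapse = ", ")), call. = FALSE)
  rowsum(m, g) / as.integer(table(g))
}

#' Extract per-trial region time courses
#'
#' For every trial, the region-averaged BOLD signal is sampled at the
#' volumes nearest to `onset + offset` for offsets spanning the window (no
#' temporal interpolation), and the mean of the pre-stimulus samples is
#' subtracted as baseline. Trials whose window does not fit inside the
#' session are dropped and counted.
#'
#' @param bold A [bold_volume()] or a list of per-session volumes.
#' @param parc A [parcellation()] on the same grid.
#' @param events Events tibble; `onset`/`session` address the volumes. Set
#'   `lock = "rating"` to lock the window to the rating onsets instead.
#' @param window A [timecourse_window()].
#' @param lock `"stimulus"` (default) or `"rating"`.
#' @return A `trial_courses` object: `samples` array (region x trial x
#'   sample), `offsets` (seconds relative to lock), `region_ids`,
#'   `trial_meta` (tibble of retained trials), `n_dropped`.
#' @export
extract_region_courses <- function(bold, parc, events, window = timecourse_window(),
                                   lock = c("stimulus", "rating")) {
  lock <- match.arg(lock)
  if (inherits(bold, "bold_volume")) bold <- list(bold)
  events <- validate_events(events)
  tr <- bold[[1]]$tr
  offsets <- window_offsets(window, tr)
  k <- round(offsets / tr)
  n_pre <- sum(k < 0)
  sessions <- sort(unique(events$session))
  if (length(bold) < length(sessions))
    stop("one BOLD volume per session is required", call. = FALSE)
  keep_rows <- list(); course_rows <- list(); lock_idx <- integer(0); dropped <- 0L
  for (si in seq_along(sessions)) {
    s <- sessions[si]
    rm_mat <- region_means(bold[[si]], parc)
    t_n <- ncol(rm_mat)
    ev <- events[events$session == s, , drop = FALSE]
    lock_time <- if (lock == "stimulus") ev$onset else ev$rating_onset
    for (i in seq_len(nrow(ev))) {
      i0 <- round(lock_time[i] / tr) + 1L
      idx <- i0 + k
      if (any(idx < 1L | idx > t_n)) { dropped <- dropped + 1L; next }
      cs <- rm_mat[, idx, drop = FALSE]
      if (n_pre > 0)
        cs <- cs - rowMeans(cs[, seq_len(n_pre), drop = FALSE])
      keep_rows[[length(keep_rows) + 1L]] <- ev[i, , drop = FALSE]
      course_rows[[length(course_rows) + 1L]] <- cs
      lock_idx <- c(lock_idx, i0)
    }
  }
  n_trials <- length(course_rows)
  samples <- array(0, c(length(parc$region_ids), n_trials, length(offsets)))
  for (j in seq_len(n_trials)) samples[, j, ] <- course_rows[[j]]
  structure(
    list(samples = samples, offsets = offsets, region_ids = parc$region_ids,
         trial_meta = if (n_trials) dplyr::bind_rows(keep_rows) else events[0, ],
         lock_index = lock_idx, n_dropped = dropped, tr = tr, window = window,
         lock = lock),
    class = "trial_courses"
  )
}

#' @export
print.trial_courses <- function(x, ...) {
  cat(sprintf("<trial_courses> %d regions x %d trials x %d samples (%s-locked, %d dropped)\n",
              dim(x$samples)[1], dim(x$samples)[2], dim(x$samples)[3],
              x$lock, x$n_dropped))
  invisible(x)
}

#' @export
as_tibble.trial_courses <- function(x, ...) {
  tidyr::expand_grid(
    region_id = x$region_ids,
    trial_id = x$trial_meta$trial_id,
    offset_s = x$offsets
  ) |>
    dplyr::mutate(value = as.vector(x$samples))
}

#' Remove the rating-period response template from stimulus-locked courses
#'
#' The average rating-locked time course of each region (over all of the
#' subject's trials) estimates the response evoked by the rating act itself
#' (button presses, visual scale). Because trials recur at a fixed period,
#' every stimulus-locked sample sits at some phase of the rating-response
#' train: the template is taken as one trial period of the rating-locked
#' average and subtracted from each course at each sample's exact phase
#' relative to that trial's rating onset (jittered stimulus-to-rating lags
#' make the phases trial-specific; the template is linearly interpolated).
#' Courses are re-baselined afterwards, since the pre-stimulus baseline
#' itself contains rating-period signal from the preceding trial.
#'
#' @param courses Stimulus-locked `trial_courses` from
#'   [extract_region_courses()].
#' @param bold,parc,events The same inputs the courses were extracted from
#'   (used to build the rating-locked template).
#' @param window Window whose `pre_s` anchors the template support (defaults
#'   to the courses' window).
#' @return The corrected `trial_courses`, with the template matrix
#'   (region x sample) attached as `$template` and its offsets as
#'   `$template_offsets`.
#' @export
rating_template_removal <- function(courses, bold, parc, events, window = NULL) {
  stopifnot(inherits(courses, "trial_courses"))
  if (is.null(window)) window <- courses$window
  events <- validate_events(events)
  if (any(!is.finite(events$rating_onset)))
    stop("every trial needs a rating onset", call. = FALSE)
  tr <- courses$tr
  # trial period from the rating-onset train (Inf when aperiodic/single)
  gaps <- unlist(lapply(split(events$rating_onset, events$session),
                        function(x) diff(sort(x))))
  period <- if (length(gaps)) stats::median(gaps) else Inf
  post_tpl <- if (is.finite(period)) period - window$pre_s - tr else
    max(courses$offsets) - min(courses$offsets)
  rate <- extract_region_courses(bold, parc, events,
                                 timecourse_window(window$pre_s, post_tpl),
                                 lock = "rating")
  template <- apply(rate$samples, c(1, 3), mean)  # region x template sample
  toff <- rate$offsets
  # periodic linear interpolation of the template at arbitrary phase
  tpl_at <- function(phase) {
    if (is.finite(period)) {
      phase <- ((phase - toff[1]) %% period) + toff[1]
      xs <- c(toff, toff[1] + period)
      t(apply(template, 1L, function(v)
        stats::approx(xs, c(v, v[1]), xout = phase, rule = 2)$y))
    } else {
      t(apply(template, 1L, function(v)
        stats::approx(toff, v, xout = phase, yleft = 0, yright = 0)$y))
    }
  }
  meta <- courses$trial_meta
  k <- round(courses$offsets / tr)
  n_pre <- sum(k < 0)
  out <- courses$samples
  for (j in seq_len(nrow(meta))) {
    t_actual <- (courses$lock_index[j] + k - 1) * tr   # volume times, s
    phase <- t_actual - meta$rating_onset[j]
    sub <- tpl_at(phase)
    if (dim(out)[1] == 1L) sub <- matrix(sub, nrow = 1L)
    cs <- out[, j, , drop = TRUE]
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
    cs <- cs - sub
    if (n_pre > 0) cs <- cs - rowMeans(cs[, seq_len(n_pre), drop = FALSE])
    out[, j, ] <- cs
  }
  courses$samples <- out
  courses$template <- template
  courses$template_offsets <- toff
  courses
}

#' Trapezoidal area under a time course
#'
#' Signed trapezoidal integral of a baseline-subtracted course from offset 0
#' to the end of the window (negative dips subtract), in signal units x
#' seconds.
#'
#' @param values Numeric course samples.
#' @param offsets Their time offsets in seconds (same length).
#' @return The signed AUC.
#' @export
compute_auc <- function(values, offsets) {
  if (length(values) != length(offsets))
    stop("`values` and `offsets` lengths differ", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite samples in course", call. = FALSE)
  sel <- offsets >= 0
  v <- values[sel]; o <- offsets[sel]
  if (length(v) < 2L) return(0)
  sum(diff(o) * (v[-length(v)] + v[-1]) / 2)
}

# per-subject condition-mean courses: list(conditions, mean = array
# [region, condition, sample]); `labels` is one condition per trial (NA drops)
condition_mean_courses <- function(courses, labels, conditions = NULL) {
  stopifnot(inherits(courses, "trial_courses"))
  if (length(labels) != dim(courses$samples)[2])
    stop("`labels` must give one condition per retained trial", call. = FALSE)
  if (is.null(conditions)) conditions <- unique(stats::na.omit(labels))
  mean_arr <- array(NA_real_,
                    c(dim(courses$samples)[1], length(conditions),
                      dim(courses$samples)[3]))
  for (ci in seq_along(conditions)) {
    sel <- which(!is.na(labels) & labels == conditions[ci])
    if (!length(sel)) next
    mean_arr[, ci, ] <- apply(courses$samples[, sel, , drop = FALSE], c(1, 3), mean)
  }
  list(conditions = conditions, mean = mean_arr,
       offsets = courses$offsets, region_ids = courses$region_ids)
}

#' Across-subject condition-average time courses with per-timepoint tests
#'
#' Averages subject-level condition-mean courses across subjects and, for a
#' pair of conditions, reports the per-timepoint paired t statistic and
#' uncorrected p-value (descriptive annotation; inference rests on the AUC
#' permutation tests). Subjects lacking trials in a compared condition are
#' excluded pairwise and counted.
#'
#' @param subject_courses List (one element per subject) of `trial_courses`.
#' @param subject_labels List of per-trial condition labels (same order).
#' @param compare Character pair of condition names to test against each
#'   other.
#' @return A `timecourse_summary`: tibble (`region_id`, `offset_s`,
#'   `condition`, `mean`, `sem`) with the paired-test tibble in
#'   `attr(, "paired")` (`t` is `Inf` with `p = 0` when the paired SEM is
#'   exactly zero) and the number of excluded subjects in
#'   `attr(, "n_excluded")`.
#' @export
condition_average <- function(subject_courses, subject_labels,
                              compare = c("pain", "tactile")) {
  stopifnot(length(subject_courses) == length(subject_labels))
  conditions <- unique(stats::na.omit(unlist(subject_labels)))
  per_subj <- purrr::map2(subject_courses, subject_labels,
                          condition_mean_courses, conditions = conditions)
  offsets <- per_subj[[1]]$offsets
  region_ids <- per_subj[[1]]$region_ids
  complete <- vapply(per_subj, function(s) {
    ci <- match(compare, conditions)
    all(!is.na(s$mean[1, ci, 1]))
  }, TRUE)
  n_excluded <- sum(!complete)
  stack <- function(cond) {
    ci <- match(cond, conditions)
    arr <- vapply(per_subj, function(s) s$mean[, ci, ], per_subj[[1]]$mean[, 1, ])
    if (length(region_ids) == 1L) arr <- array(arr, c(1, dim(arr)))
    arr  # region x sample x subject
  }
  grand <- purrr::map(conditions, function(cond) {
    arr <- stack(cond)
    tibble::tibble(
      region_id = rep(region_ids, times = length(offsets)),
      offset_s = rep(offsets, each = length(region_ids)),
      condition = cond,
      mean = as.vector(apply(arr, c(1, 2), mean, na.rm = TRUE)),
      sem = as.vector(apply(arr, c(1, 2), stats::sd, na.rm = TRUE)) /
        sqrt(as.vector(apply(!is.na(arr), c(1, 2), sum)))
    )
  }) |> dplyr::bind_rows()
  a <- stack(compare[1])[, , complete, drop = FALSE]
  b <- stack(compare[2])[, , complete, drop = FALSE]
  d <- a - b
  n <- dim(d)[3]
  md <- apply(d, c(1, 2), mean)
  sdd <- apply(d, c(1, 2), stats::sd)
  tt <- ifelse(sdd > 0, md / (sdd / sqrt(n)),
               ifelse(md == 0, 0, sign(md) * Inf))
  pp <- ifelse(is.infinite(tt), 0, 2 * stats::pt(-abs(tt), df = n - 1))
  paired <- tibble::tibble(
    region_id = rep(region_ids, times = length(offsets)),
    offset_s = rep(offsets, each = length(region_ids)),
    t = as.vector(tt), p = as.vector(pp)
  )
  structure(grand, class = c("timecourse_summary", class(grand)),
            paired = paired, compare = compare, n_subjects = n,
            n_excluded = n_excluded)
}

#' AUC table for subject-level condition courses
#'
#' @param per_subject_means List of outputs of the internal condition-mean
#'   step, or built internally by [analysis3()]/[analysis4()].
#' @keywords internal
condition_auc_matrix <- function(per_subj, condition) {
  ci <- match(condition, per_subj[[1]]$conditions)
  offs <- per_subj[[1]]$offsets
  t(vapply(per_subj, function(s)
    vapply(seq_along(s$region_ids),
           function(g) {
             v <- s$mean[g, ci, ]
             if (any(is.na(v))) NA_real_ else compute_auc(v, offs)
           }, 1),
    numeric(length(per_subj[[1]]$region_ids))))
}

subject_matched_courses <- function(ds, parc, window, tolerance,
                                    remove_template = TRUE) {
  events <- label_matched(ds$events, match_trials(ds$events, tolerance))
  courses <- extract_region_courses(ds$bold, parc, events, window)
  if (remove_template)
    courses <- rating_template_removal(courses, ds$bold, parc, events, window)
  labels <- ifelse(courses$trial_meta$matched, courses$trial_meta$modality, NA)
  list(courses = courses, labels = labels, events = events)
}

#' Per-subject condition AUCs for matched trials
#'
#' Runs the full model-free chain for one subject — matching, extraction,
#' rating-template removal, condition-mean courses, AUC — and returns one
#' row per region and condition. [analysis3()] is the cohort-level wrapper.
#'
#' @inheritParams analysis3
#' @param ds One subject dataset (`bold` list, `events`).
#' @return Tibble with `region_id`, `condition`, `auc`.
#' @export
subject_condition_auc <- function(ds, parc, window = timecourse_window(),
                                  tolerance = 0.5, remove_template = TRUE) {
  sm <- subject_matched_courses(ds, parc, window, tolerance, remove_template)
  cm <- condition_mean_courses(sm$courses, sm$labels, c("pain", "tactile"))
  cm$region_ids <- sm$courses$region_ids
  auc <- vapply(seq_along(cm$conditions), function(ci)
    vapply(seq_along(cm$region_ids), function(g) {
      v <- cm$mean[g, ci, ]
      if (any(is.na(v))) NA_real_ else compute_auc(v, cm$offsets)
    }, 1), numeric(length(cm$region_ids)))
  tibble::tibble(
    region_id = rep(cm$region_ids, times = length(cm$conditions)),
    condition = rep(cm$conditions, each = length(cm$region_ids)),
    auc = as.vector(auc)
  )
}

#' Region-wise model-free comparison of matched painful and tactile responses
#'
#' For every subject, perceived-intensity-matched trials are selected, raw
#' region time courses are extracted, the rating-period template is removed,
#' condition-mean courses are formed and their AUCs computed. The
#' subject x region AUC matrices for the two modalities are then compared
#' with a paired sign-flip permutation test (both directions), FWE-corrected
#' across regions via the maximum statistic.
#'
#' @param cohort List of subject datasets (each with `bold` (list of
#'   per-session volumes), `events`, and optionally `motion`).
#' @param parc A [parcellation()].
#' @param cfg A [perm_config()].
#' @param window A [timecourse_window()].
#' @param tolerance Matching tolerance (default 0.5).
#' @param remove_template Remove the rating-period template (default TRUE).
#' @return A list: `auc` (long tibble: subject, region_id, condition, auc),
#'   `pain_gt_tactile` and `tactile_gt_pain` (`paired_perm` objects).
#' @export
analysis3 <- function(cohort, parc, cfg = perm_config(),
                      window = timecourse_window(), tolerance = 0.5,
                      remove_template = TRUE) {
  per_subj <- purrr::map(cohort, function(ds) {
    sm <- subject_matched_courses(ds, parc, window, tolerance, remove_template)
    cm <- condition_mean_courses(sm$courses, sm$labels, c("pain", "tactile"))
    cm$region_ids <- sm$courses$region_ids
    cm
  })
  a_pain <- condition_auc_matrix(per_subj, "pain")
  a_tact <- condition_auc_matrix(per_subj, "tactile")
  colnames(a_pain) <- colnames(a_tact) <- as.character(parc$region_ids)
  cfg_g <- cfg; cfg_g$tail <- "greater"
  auc_long <- dplyr::bind_rows(
    tibble::tibble(subject = rep(seq_along(cohort), each = ncol(a_pain)),
                   region_id = rep(parc$region_ids, length(cohort)),
                   condition = "pain", auc = as.vector(t(a_pain))),
    tibble::tibble(subject = rep(seq_along(cohort), each = ncol(a_tact)),
                   region_id = rep(parc$region_ids, length(cohort)),
                   condition = "tactile", auc = as.vector(t(a_tact)))
  )
  list(
    auc = auc_long,
    pain_gt_tactile = paired_signflip(a_pain, a_tact, cfg_g),
    tactile_gt_pain = paired_signflip(a_tact, a_pain, cfg_g)
  )
}

#' Intensity-mismatch comparison for modality-preferential regions
#'
#' The median-split comparison: all of a subject's stimuli are pooled and
#' split at the pooled median rating; counts in the two compared groups are
#' equalized by removing trials nearest the median from the larger group.
#' For pain-preferential regions, responses to low-perceived-intensity
#' painful stimuli are compared with responses to high-perceived-intensity
#' tactile stimuli; for tactile-preferential regions, low-intensity tactile
#' vs high-intensity painful. AUCs are compared with the paired sign-flip
#' permutation test across the tested regions.
#'
#' @inheritParams analysis3
#' @param preference Tibble with `region_id` and `preference`
#'   (`"pain"`/`"tactile"`) naming the regions to test (e.g. from
#'   [analysis3()] or the generator's ground truth).
#' @return A list with `pain_pref` and `tactile_pref` `paired_perm` results
#'   (differences are preferred-modality-low minus other-modality-high) and
#'   `n_excluded` per direction.
#' @export
analysis4 <- function(cohort, parc, preference, cfg = perm_config(),
                      window = timecourse_window(), remove_template = TRUE) {
  pain_regions <- preference$region_id[preference$preference == "pain"]
  tact_regions <- preference$region_id[preference$preference == "tactile"]
  subj_auc <- purrr::map(cohort, function(ds) {
    split_ev <- median_split(ds$events)
    med <- attr(split_ev, "pooled_median")
    courses <- extract_region_courses(ds$bold, parc, split_ev, window)
    if (remove_template)
      courses <- rating_template_removal(courses, ds$bold, parc, split_ev, window)
    meta <- courses$trial_meta
    group <- function(modality, level) {
      meta$trial_id[meta$modality == modality & meta$split == level]
    }
    pair_auc <- function(ids_a, ids_b) {
      ga <- meta[meta$trial_id %in% ids_a, , drop = FALSE]
      gb <- meta[meta$trial_id %in% ids_b, , drop = FALSE]
      eq <- equalize_counts(ga, gb, med)
      if (nrow(eq$a) == 0L || nrow(eq$b) == 0L) return(NULL)
      mean_auc <- function(ids) {
        sel <- which(meta$trial_id %in% ids)
        mc <- apply(courses$samples[, sel, , drop = FALSE], c(1, 3), mean)
        apply(mc, 1L, compute_auc, offsets = courses$offsets)
      }
      list(a = mean_auc(eq$a$trial_id), b = mean_auc(eq$b$trial_id))
    }
    list(
      pain_dir = pair_auc(group("pain", "low"), group("tactile", "high")),
      tact_dir = pair_auc(group("tactile", "low"), group("pain", "high"))
    )
  })
  run_direction <- function(dir, regions) {
    if (!length(regions)) return(NULL)
    keep <- !vapply(subj_auc, function(s) is.null(s[[dir]]), TRUE)
    ga <- t(vapply(subj_auc[keep], function(s) s[[dir]]$a, numeric(length(parc$region_ids))))
    gb <- t(vapply(subj_auc[keep], function(s) s[[dir]]$b, numeric(length(parc$region_ids))))
    colnames(ga) <- colnames(gb) <- as.character(parc$region_ids)
    sel <- as.character(regions)
    res <- paired_signflip(ga[, sel, drop = FALSE], gb[, sel, drop = FALSE], cfg)
    attr(res, "n_excluded") <- sum(!keep)
    res
  }
  list(
    pain_pref = run_direction("pain_dir", pain_regions),
    tactile_pref = run_direction("tact_dir", tact_regions)
  )
}
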