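#' Match painful and tactile trials by perceived intensity
#'
#' Greedy one-to-one pairing of painful trials with tactile trials of similar
#' perceived intensity. Painful trials are processed in chronological
#' (session, onset) order; for each, the not-yet-paired tactile trial whose
#' rating lies within `tolerance` of the painful trial's rating (closed
#' interval) and is closest in rating is selected. Ties on |rating
#' difference| are broken by the earliest tactile onset. Painful trials with
#' no candidate remain unmatched, mirroring how stimuli were labelled
#' unmatched when no electrical stimulus fell within the rating window.
#'
#' @param events An events tibble (see [validate_events()]).
#' @param tolerance Maximum absolute rating difference for a pair
#'   (default 0.5, i.e. the window `[r - 0.5, r + 0.5]`).
#' @return A `match_result`: list with `pairs` (tibble: `pain_trial_id`,
#'   `tactile_trial_id`, `delta_rating`), `unmatched_pain`,
#'   `unmatched_tactile` (character vectors) and `tolerance`.
#' @export
match_trials <- function(events, tolerance = 0.5) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || !is.finite(tolerance) ||
      tolerance < 0)
    stop("`tolerance` must be a single nonnegative number", call. = FALSE)
  events <- validate_events(events)
  pain <- dplyr::filter(events, .data$modality == "pain")
  tact <- dplyr::filter(events, .data$modality == "tactile")

  paired_t <- rep(FALSE, nrow(tact))
  out_p <- character(0); out_t <- character(0); out_d <- numeric(0)
  eps <- 1e-9  # guards the closed interval against floating-point wobble
  for (i in seq_len(nrow(pain))) {
    d <- abs(tact$rating - pain$rating[i])
    cand <- which(!paired_t & d <= tolerance + eps)
    if (!length(cand)) next
    best <- cand[order(d[cand], tact$session[cand], tact$onset[cand])][1]
    paired_t[best] <- TRUE
    out_p <- c(out_p, pain$trial_id[i])
    out_t <- c(out_t, tact$trial_id[best])
    out_d <- c(out_d, d[best])
  }
  structure(
    list(
      pairs = tibble::tibble(
        pain_trial_id = out_p, tactile_trial_id = out_t, delta_rating = out_d
      ),
      unmatched_pain = setdiff(pain$trial_id, out_p),
      unmatched_tactile = tact$trial_id[!paired_t],
      tolerance = tolerance
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d pairs (tolerance %.3g), %d painful and %d tactile trials unmatched\n",
    nrow(x$pairs), x$tolerance, length(x$unmatched_pain), length(x$unmatched_tactile)
  ))
  invisible(x)
}

#' @export
tidy.match_result <- function(x, ...) x$pairs

#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_unmatched_pain = length(x$unmatched_pain),
    n_unmatched_tactile = length(x$unmatched_tactile),
    tolerance = x$tolerance,
    mean_abs_delta = if (nrow(x$pairs)) mean(x$pairs$delta_rating) else NA_real_
  )
}

#' Annotate an events table with matching labels
#'
#' Adds a logical `matched` column and a `pair_id` column (shared between the
#' two members of a pair, `NA` for unmatched trials).
#'
#' @param events An events tibble.
#' @param match A `match_result` from [match_trials()].
#' @return The events tibble with `matched` and `pair_id` columns.
#' @export
label_matched <- function(events, match) {
  stopifnot(inherits(match, "match_result"))
  events <- validate_events(events)
  pid <- seq_len(nrow(match$pairs))
  lut <- c(
    stats::setNames(pid, match$pairs$pain_trial_id),
    stats::setNames(pid, match$pairs$tactile_trial_id)
  )
  events$pair_id <- unname(lut[events$trial_id])
  events$matched <- !is.na(events$pair_id)
  events
}

#' Median split of pooled perceived-intensity ratings
#'
#' All stimuli (painful and tactile pooled) are split at the pooled median
#' rating: strictly above the median is labelled `high`, strictly below
#' `low`, and ratings exactly at the median are `dropped` (the split defines
#' only strictly-higher and strictly-lower groups).
#'
#' @param events An events tibble with >= 2 rated stimuli.
#' @return A `split_labels` object: the events tibble with a `split` column
#'   plus attributes `pooled_median` and `counts` (tibble of counts per
#'   modality and label).
#' @export
median_split <- function(events) {
  events <- validate_events(events)
  if (nrow(events) < 2L)
    stop("median split requires at least two rated stimuli", call. = FALSE)
  med <- stats::median(events$rating)
  events$split <- dplyr::case_when(
    events$rating > med ~ "high",
    events$rating < med ~ "low",
    TRUE ~ "dropped"
  )
  counts <- dplyr::count(events, .data$modality, .data$split)
  structure(events, class = c("split_labels", class(events)),
            pooled_median = med, counts = counts)
}

#' Equalize trial counts between two split groups
#'
#' From the larger of two trial groups, removes the trials whose ratings lie
#' closest to the pooled median (ties broken by removing the earliest onset
#' first) until both groups have the same size. The smaller group is
#' untouched.
#'
#' @param group_a,group_b Events tibbles (rows of a split-labelled table).
#' @param median The pooled median rating the split was computed from.
#' @return A list with elements `a` and `b`, the (possibly trimmed) groups.
#' @export
equalize_counts <- function(group_a, group_b, median) {
  trim <- function(g, n_keep) {
    if (nrow(g) <= n_keep) return(g)
    ord <- order(abs(g$rating - median), g$session, g$onset)
    drop <- ord[seq_len(nrow(g) - n_keep)]
    g[-drop, , drop = FALSE]
  }
  n <- min(nrow(group_a), nrow(group_b))
  list(a = trim(group_a, n), b = trim(group_b, n))
}
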