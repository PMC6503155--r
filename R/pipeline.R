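#' First-level model of one subject
#'
#' Matches trials, builds the five-condition design, fits the GLM and forms
#' the three contrasts: matched-pain activation, matched-tactile activation,
#' and their difference.
#'
#' @param ds Subject dataset (`bold` list, `events`, optional `motion`).
#' @param tolerance Matching tolerance.
#' @param hp_cutoff_s High-pass cut-off, seconds.
#' @param hrf An [hrf_spec()].
#' @return List with `match`, `fit`, and `contrasts` (named `stat_map`s:
#'   `matched_pain`, `matched_tactile`, `pain_minus_tactile`).
#' @export
subject_first_level <- function(ds, tolerance = 0.5, hp_cutoff_s = 128,
                                hrf = hrf_spec()) {
  match <- match_trials(ds$events, tolerance)
  n_scans <- vapply(ds$bold, function(v) dim(v$data)[4], 1L)
  design <- build_design_5cond(ds$events, match, n_scans, ds$bold[[1]]$tr,
                               motion = ds$motion, hp_cutoff_s = hp_cutoff_s,
                               hrf = hrf)
  fit <- fit_glm(ds$bold, design)
  contrasts <- list(
    matched_pain = contrast_map(fit, contrast_weights(design, "matched_pain")),
    matched_tactile = contrast_map(fit, contrast_weights(design, "matched_tactile")),
    pain_minus_tactile = contrast_map(
      fit, contrast_weights(design, "matched_pain", "matched_tactile"))
  )
  list(match = match, fit = fit, design = design, contrasts = contrasts)
}

#' Group-level parametric perceived-intensity analysis
#'
#' Per subject, all stimuli are collapsed into one regressor with a
#' parametric modulator carrying the mean-centred ratings; the modulator
#' effect maps enter a second-level one-sample sign-flip test, identifying
#' voxels whose response amplitude scales with perceived intensity
#' regardless of modality.
#'
#' @param cohort List of subject datasets.
#' @param cfg A [perm_config()].
#' @param hp_cutoff_s High-pass cut-off, seconds.
#' @param correction `"voxel"` or `"cluster"`.
#' @return List with `maps` (per-subject modulator `stat_map`s) and `test`
#'   (a `voxel_fwe` or `cluster_fwe`).
#' @export
analysis1 <- function(cohort, cfg = perm_config(), hp_cutoff_s = 128,
                      correction = c("voxel", "cluster")) {
  correction <- match.arg(correction)
  maps <- purrr::map(cohort, function(ds) {
    n_scans <- vapply(ds$bold, function(v) dim(v$data)[4], 1L)
    design <- build_design_parametric(ds$events, n_scans, ds$bold[[1]]$tr,
                                      motion = ds$motion,
                                      hp_cutoff_s = hp_cutoff_s)
    fit <- fit_glm(ds$bold, design)
    contrast_map(fit, contrast_weights(design, "rating_mod"))
  })
  mask <- cohort[[1]]$bold[[1]]$mask
  test <- if (correction == "voxel") one_sample_signflip(maps, mask, cfg)
    else cluster_signflip(maps, mask, cfg)
  list(maps = maps, test = test)
}

#' Group-level GLM comparison of matched painful and tactile responses
#'
#' The voxelwise second-level pipeline: one-sample sign-flip tests of the
#' matched-pain and matched-tactile activation maps over the whole mask, a
#' union mask of the two thresholded activation maps, two one-tailed
#' difference tests (pain > tactile and tactile > pain) restricted to the
#' union mask, and the conjunction map.
#'
#' @inheritParams analysis1
#' @param tolerance Matching tolerance.
#' @return List with per-subject `contrasts`, activation tests `pain_act`
#'   and `tactile_act`, `union`, `conjunction`, and difference tests
#'   `pain_gt_tactile` / `tactile_gt_pain` (NULL when the union mask is
#'   empty).
#' @export
analysis2 <- function(cohort, cfg = perm_config(), tolerance = 0.5,
                      hp_cutoff_s = 128, correction = c("voxel", "cluster")) {
  correction <- match.arg(correction)
  firsts <- purrr::map(cohort, subject_first_level, tolerance = tolerance,
                       hp_cutoff_s = hp_cutoff_s)
  mask <- cohort[[1]]$bold[[1]]$mask
  act_cfg <- cfg; act_cfg$tail <- "greater"
  run_test <- function(maps, m, tcfg) {
    if (correction == "voxel") one_sample_signflip(maps, m, tcfg)
    else cluster_signflip(maps, m, tcfg)
  }
  sig_of <- function(test) {
    if (inherits(test, "voxel_fwe")) return(test$sig)
    keep <- test$clusters$cluster_id[test$clusters$p_fwe <= cfg$alpha]
    array(test$label_map %in% keep, dim(test$label_map))
  }
  pain_act <- run_test(purrr::map(firsts, ~ .x$contrasts$matched_pain), mask, act_cfg)
  tact_act <- run_test(purrr::map(firsts, ~ .x$contrasts$matched_tactile), mask, act_cfg)
  pain_sig <- array(sig_of(pain_act), dim(mask))
  tact_sig <- array(sig_of(tact_act), dim(mask))
  u <- union_mask(pain_sig, tact_sig)
  conj <- conjunction_mask(pain_sig, tact_sig)
  diff_maps <- purrr::map(firsts, ~ .x$contrasts$pain_minus_tactile)
  neg_maps <- purrr::map(diff_maps, function(m) { m$effect <- -m$effect; m })
  out <- list(firsts = firsts, pain_act = pain_act, tactile_act = tact_act,
              union = u, conjunction = conj,
              pain_gt_tactile = NULL, tactile_gt_pain = NULL)
  if (any(u)) {
    gcfg <- cfg; gcfg$tail <- "greater"
    out$pain_gt_tactile <- run_test(diff_maps, u, gcfg)
    out$tactile_gt_pain <- run_test(neg_maps, u, gcfg)
  }
  out
}

#' Region-aggregated GLM difference contrast
#'
#' The model-based counterpart of [analysis3()]: each subject's matched-pain
#' minus matched-tactile GLM effect map is averaged within parcellation
#' regions and the subject x region matrix is tested with one-sample
#' sign-flip max-statistic FWE, one tail per direction.
#'
#' @inheritParams analysis2
#' @param parc A [parcellation()].
#' @return List with `effects` (subject x region matrix),
#'   `pain_gt_tactile` and `tactile_gt_pain` (`voxel_fwe` objects over
#'   regions).
#' @export
analysis2_regions <- function(cohort, parc, cfg = perm_config(),
                              tolerance = 0.5, hp_cutoff_s = 128) {
  eff <- t(vapply(cohort, function(ds) {
    fl <- subject_first_level(ds, tolerance, hp_cutoff_s)
    region_effects(fl$contrasts$pain_minus_tactile, parc)$effect
  }, numeric(length(parc$region_ids))))
  colnames(eff) <- as.character(parc$region_ids)
  gcfg <- cfg; gcfg$tail <- "greater"
  list(effects = eff,
       pain_gt_tactile = one_sample_signflip(eff, NULL, gcfg),
       tactile_gt_pain = one_sample_signflip(-eff, NULL, gcfg))
}

read_subject_dataset <- function(spec) {
  bold <- purrr::map(spec$bold, read_bold)
  events <- read_events(spec$events)
  motion <- if (!is.null(spec$motion))
    purrr::map(spec$motion, function(p)
      as.matrix(readr::read_tsv(p, col_types = readr::cols(.default = "d"),
                                progress = FALSE)))
    else NULL
  list(bold = bold, events = events, motion = motion)
}

cohort_from_config <- function(config) {
  if (isTRUE(config$simulate)) {
    cc_args <- config$cohort %||% list()
    if (!is.null(config$seed)) cc_args$seed <- config$seed
    if (!is.null(cc_args$grid)) cc_args$grid <- as.integer(unlist(cc_args$grid))
    cc <- do.call(cohort_config, cc_args)
    sim <- simulate_cohort(cc)
    list(subjects = sim$subjects, parc = sim$parcellation, config = cc)
  } else {
    if (is.null(config$subjects) || !length(config$subjects))
      stop("config must list subject datasets or set simulate: true", call. = FALSE)
    subjects <- purrr::map(config$subjects, read_subject_dataset)
    grids <- purrr::map(subjects, ~ dim(.x$bold[[1]]$data)[1:3])
    if (length(unique(purrr::map_chr(grids, paste, collapse = "x"))) != 1L)
      stop("inconsistent grids across subjects", call. = FALSE)
    parc <- if (!is.null(config$parcellation)) read_parcellation(config$parcellation)
      else NULL
    list(subjects = subjects, parc = parc, config = NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline from a configuration
#'
#' Reads (or simulates) a cohort, then runs the enabled analyses and writes
#' their results: matched event tables, first-level contrast images,
#' second-level stat maps and cluster tables, time-course summaries, AUC
#' tables, the intensity-mismatch comparison, and a machine-readable run log
#' recording the seed and parameters. With a fixed seed the outputs are
#' bitwise reproducible.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognised fields: `simulate` + `cohort` (arguments of
#'   [cohort_config()]) or `subjects` (each with `bold`, `events`, `motion`
#'   paths) + `parcellation`; `analyses` (subset of `match`, `glm`,
#'   `permtest`, `timecourse`, `auc`, `analysis4`; default all); `seed`,
#'   `n_perm`, `alpha`, `cdt_p`, `tolerance`, `hp_cutoff_s`, `smooth_fwhm`.
#' @param out_dir Output directory (created if needed); overrides `config$out`.
#' @return Invisibly, the list of in-memory results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out %||% stop("no output directory given", call. = FALSE)
  analyses <- config$analyses %||%
    c("match", "glm", "permtest", "timecourse", "auc", "analysis4")
  seed <- as.integer(config$seed %||% 1L)
  tolerance <- config$tolerance %||% 0.5
  hp_cutoff_s <- config$hp_cutoff_s %||% 128
  cfg <- perm_config(n_perm = config$n_perm %||% 5000, seed = seed,
                     alpha = config$alpha %||% 0.05,
                     cdt_p = config$cdt_p %||% 0.001)
  # validate before any computation
  if (!isTRUE(config$simulate) && any(c("auc", "analysis4") %in% analyses) &&
      is.null(config$parcellation))
    stop("parcellation required for the region-wise analyses", call. = FALSE)
  set.seed(seed)
  ch <- cohort_from_config(config)
  subjects <- ch$subjects
  parc <- ch$parc
  if (!is.null(config$smooth_fwhm) && config$smooth_fwhm > 0)
    subjects <- purrr::map(subjects, function(ds) {
      ds$bold <- purrr::map(ds$bold, smooth_gaussian, fwhm_mm = config$smooth_fwhm)
      ds
    })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  if ("match" %in% analyses) {
    dir.create(file.path(out_dir, "events"), showWarnings = FALSE)
    res$matches <- purrr::imap(subjects, function(ds, i) {
      m <- match_trials(ds$events, tolerance)
      ev <- label_matched(ds$events, m)
      ev <- median_split(ev)
      write_events(tibble::as_tibble(ev),
                   file.path(out_dir, "events", sprintf("sub-%02d_events.tsv", i)))
      m
    })
  }

  if ("glm" %in% analyses) {
    dir.create(file.path(out_dir, "first_level"), showWarnings = FALSE)
    res$analysis2 <- analysis2(subjects, cfg, tolerance, hp_cutoff_s)
    purrr::iwalk(res$analysis2$firsts, function(fl, i) {
      for (cn in names(fl$contrasts)) {
        vol <- bold_volume(array(fl$contrasts[[cn]]$effect,
                                 c(dim(fl$contrasts[[cn]]$effect), 1L)),
                           tr = subjects[[1]]$bold[[1]]$tr)
        write_bold(vol, file.path(out_dir, "first_level",
                                  sprintf("sub-%02d_%s_effect.nii.gz", i, cn)))
      }
    })
  }

  if ("permtest" %in% analyses && !is.null(res$analysis2)) {
    dir.create(file.path(out_dir, "group"), showWarnings = FALSE)
    tr <- subjects[[1]]$bold[[1]]$tr
    wr <- function(arr, name) {
      write_bold(bold_volume(array(arr, c(dim(arr), 1L)), tr = tr),
                 file.path(out_dir, "group", name))
    }
    wr(res$analysis2$pain_act$t, "pain_act_t.nii.gz")
    wr(res$analysis2$pain_act$p_fwe, "pain_act_pfwe.nii.gz")
    wr(res$analysis2$tactile_act$t, "tactile_act_t.nii.gz")
    wr(res$analysis2$tactile_act$p_fwe, "tactile_act_pfwe.nii.gz")
    wr(res$analysis2$union + 0, "union_mask.nii.gz")
    wr(res$analysis2$conjunction + 0, "conjunction_mask.nii.gz")
    mask <- subjects[[1]]$bold[[1]]$mask
    cl <- cluster_signflip(
      purrr::map(res$analysis2$firsts, ~ .x$contrasts$pain_minus_tactile),
      res$analysis2$union %||% mask, cfg)
    readr::write_tsv(cl$clusters, file.path(out_dir, "group", "clusters.tsv"),
                     progress = FALSE)
    res$cluster <- cl
  }

  if (any(c("timecourse", "auc") %in% analyses) && !is.null(parc)) {
    dir.create(file.path(out_dir, "auc"), showWarnings = FALSE)
    res$analysis3 <- analysis3(subjects, parc, cfg, tolerance = tolerance)
    readr::write_tsv(res$analysis3$auc, file.path(out_dir, "auc", "auc.tsv"),
                     progress = FALSE)
    readr::write_tsv(tibble::as_tibble(res$analysis3$pain_gt_tactile),
                     file.path(out_dir, "auc", "analysis3_pain_gt_tactile.tsv"),
                     progress = FALSE)
    readr::write_tsv(tibble::as_tibble(res$analysis3$tactile_gt_pain),
                     file.path(out_dir, "auc", "analysis3_tactile_gt_pain.tsv"),
                     progress = FALSE)
    if ("timecourse" %in% analyses) {
      dir.create(file.path(out_dir, "timecourse"), showWarnings = FALSE)
      scs <- purrr::map(subjects, subject_matched_courses, parc = parc,
                        window = timecourse_window(), tolerance = tolerance)
      summ <- condition_average(purrr::map(scs, "courses"), purrr::map(scs, "labels"))
      readr::write_tsv(tibble::as_tibble(summ),
                       file.path(out_dir, "timecourse", "condition_means.tsv"),
                       progress = FALSE)
      res$timecourse <- summ
    }
  }

  if ("analysis4" %in% analyses && !is.null(parc)) {
    dir.create(file.path(out_dir, "analysis4"), showWarnings = FALSE)
    pref <- if (!is.null(ch$config))
      dplyr::filter(ch$config$region_effects, .data$preference != "none") |>
        dplyr::select("region_id", "preference")
      else if (!is.null(res$analysis3))
        dplyr::bind_rows(
          tibble::tibble(
            region_id = res$analysis3$pain_gt_tactile$region_id[
              res$analysis3$pain_gt_tactile$p_fwe <= cfg$alpha],
            preference = "pain"),
          tibble::tibble(
            region_id = res$analysis3$tactile_gt_pain$region_id[
              res$analysis3$tactile_gt_pain$p_fwe <= cfg$alpha],
            preference = "tactile"))
      else NULL
    if (!is.null(pref) && nrow(pref)) {
      pref$region_id <- as.integer(pref$region_id)
      res$analysis4 <- analysis4(subjects, parc, pref, cfg)
      for (dname in c("pain_pref", "tactile_pref")) {
        r <- res$analysis4[[dname]]
        if (!is.null(r))
          readr::write_tsv(tibble::as_tibble(r),
                           file.path(out_dir, "analysis4", paste0(dname, ".tsv")),
                           progress = FALSE)
      }
    }
  }

  log <- list(
    seed = seed, n_perm = cfg$n_perm, alpha = cfg$alpha, cdt_p = cfg$cdt_p,
    tolerance = tolerance, hp_cutoff_s = hp_cutoff_s,
    n_subjects = length(subjects), analyses = as.list(analyses),
    simulated = isTRUE(config$simulate)
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
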