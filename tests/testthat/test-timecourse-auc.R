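make_flat_dataset <- function(value = 3, n_scans = 250) {
  vol <- bold_volume(array(value, c(2, 2, 2, n_scans)), tr = 0.8)
  parc <- parcellation(array(1L, c(2, 2, 2)))
  list(bold = list(vol), parc = parc)
}

test_that("constant signals give identically zero baseline-corrected courses", {
  fx <- make_flat_dataset()
  ev <- make_events(c(3, 4), c(3.5, 4.5))
  tc <- extract_region_courses(fx$bold, fx$parc, ev)
  expect_true(all(tc$samples == 0))
  expect_equal(dim(tc$samples), c(1, 4, 28))  # 2 + 25 samples + lock sample
  expect_equal(tc$offsets[1], -1.6)
  expect_equal(tc$offsets[28], 20)
})

test_that("trials whose window leaves the session are dropped and counted", {
  fx <- make_flat_dataset(n_scans = 75)   # 60 s session
  ev <- make_events(c(3, 4, 5))           # onsets 5, 30, 55: third can't fit
  tc <- extract_region_courses(fx$bold, fx$parc, ev)
  expect_equal(dim(tc$samples)[2], 2)
  expect_equal(tc$n_dropped, 1)
})

test_that("noiseless extraction reproduces the generator's response", {
  re <- tibble::tibble(region_id = 1L, amp_pain = 1, amp_tactile = 0.5,
                       intensity_slope = 0, peak_shift_s = 0, duration_s = 0,
                       preference = "pain")
  cc <- noiseless_config(grid = c(2, 2, 2), n_regions = 1, region_effects = re,
                         rating_amp = 0, seed = 21)
  ev <- make_events(pain_ratings = 5)
  parc <- simulate_parcellation(cc)
  ds <- simulate_bold(cc, ev, parc, 1)
  tc <- extract_region_courses(ds$bold, parc, ev)
  # the forward model sampled on the volume grid, baseline-subtracted
  full <- isointense:::convolve_events(5, 0, 1, cc$n_scans, 0.8, cc$hrf)
  i0 <- round(5 / 0.8) + 1
  oracle <- full[i0 + round(tc$offsets / 0.8)]
  oracle <- oracle - mean(oracle[1:2])
  expect_equal(as.numeric(tc$samples[1, 1, ]), oracle, tolerance = 1e-9)
})

test_that("trapezoid AUC matches closed forms and is linear", {
  offs <- window_offsets <- seq(-1.6, 20, by = 0.8)
  expect_equal(compute_auc(rep(0, length(offs)), offs), 0)
  # triangle rising 0 to 1 over 5 s then back over 5 s, sampled at tr 0.8:
  # the trapezoid of the sampled polyline, computed independently
  tri <- function(t) ifelse(t < 0 | t > 10, 0, ifelse(t <= 5, t / 5, (10 - t) / 5))
  v <- tri(offs)
  sel <- offs >= 0
  oracle <- sum(diff(offs[sel]) * (utils::head(v[sel], -1) + utils::tail(v[sel], -1)) / 2)
  expect_equal(compute_auc(v, offs), oracle, tolerance = 1e-12)
  # scaling and additivity
  set.seed(30)
  u <- rnorm(length(offs)); w <- rnorm(length(offs))
  expect_equal(compute_auc(3 * u, offs), 3 * compute_auc(u, offs), tolerance = 1e-12)
  expect_equal(compute_auc(u + w, offs),
               compute_auc(u, offs) + compute_auc(w, offs), tolerance = 1e-12)
  expect_error(compute_auc(c(u, NA), c(offs, 21)), "non-finite")
})

test_that("AUC commutes with trial averaging", {
  set.seed(31)
  offs <- seq(-1.6, 20, by = 0.8)
  courses <- matrix(rnorm(12 * length(offs)), 12, length(offs))
  auc_each <- apply(courses, 1, compute_auc, offsets = offs)
  expect_equal(mean(auc_each), compute_auc(colMeans(courses), offs),
               tolerance = 1e-12)
})

test_that("a zero rating template leaves courses unchanged", {
  fx <- make_flat_dataset()                 # constant signal -> zero template
  ev <- make_events(c(3, 4), c(3.5, 4.5))
  tc <- extract_region_courses(fx$bold, fx$parc, ev)
  tc2 <- rating_template_removal(tc, fx$bold, fx$parc, ev)
  expect_equal(tc2$samples, tc$samples, tolerance = 1e-12)
  expect_true(all(tc2$template == 0))
})

test_that("rating-locked responses are removed from stimulus-locked courses", {
  re0 <- region_effects_table(2, 0, 0, amp_null = 0, intensity_slope = 0)
  cc0 <- noiseless_config(grid = c(4, 4, 4), n_regions = 2, region_effects = re0,
                          rating_amp = 1, seed = 13)
  ds0 <- simulate_subject(cc0, 1)
  p0 <- simulate_parcellation(cc0)
  raw <- extract_region_courses(ds0$bold, p0, ds0$events)
  corr <- rating_template_removal(raw, ds0$bold, p0, ds0$events)
  tpl_peak <- max(abs(corr$template))
  resid <- mean(apply(abs(corr$samples), 2, max))
  raw_resid <- mean(apply(abs(raw$samples), 2, max))
  expect_gt(raw_resid / tpl_peak, 0.5)   # before correction: large overlap
  expect_lt(resid / tpl_peak, 0.05)      # after: < 5% of the template peak
})

test_that("condition averages report per-timepoint paired statistics", {
  fx <- make_flat_dataset()
  ev <- make_events(c(3, 4), c(3.5, 4.5))
  tc <- extract_region_courses(fx$bold, fx$parc, ev)
  labels <- tc$trial_meta$modality
  # identical data in both conditions: zero t everywhere
  summ <- condition_average(list(tc, tc), list(labels, labels))
  paired <- attr(summ, "paired")
  expect_true(all(paired$t == 0))
  # constant offset between conditions with zero variance: t = Inf, p = 0
  tc_off <- tc
  tc_off$samples[, labels == "pain", ] <- tc_off$samples[, labels == "pain", ] + 1
  s2 <- condition_average(list(tc_off, tc_off), list(labels, labels))
  p2 <- attr(s2, "paired")
  late <- p2$offset_s >= 0
  expect_true(all(is.infinite(p2$t[late])))
  expect_true(all(p2$p[late] == 0))
})

test_that("region-wise AUC comparison recovers injected preferences", {
  cc <- cohort_config(n_subjects = 8, grid = c(6, 6, 6), n_regions = 8,
                      region_effects = region_effects_table(8, 2, 2),
                      noise = noise_model(0.5, 0.2, c(1, 0.5), 0), seed = 23)
  coh <- simulate_cohort(cc)
  suppressWarnings(
    a3 <- analysis3(coh$subjects, coh$parcellation,
                    perm_config(n_perm = 500, seed = 2)))
  sig_pain <- a3$pain_gt_tactile$region_id[a3$pain_gt_tactile$p_fwe <= 0.05]
  expect_setequal(sig_pain, c(1, 2))
  sig_tact <- a3$tactile_gt_pain$region_id[a3$tactile_gt_pain$p_fwe <= 0.05]
  expect_true(all(sig_tact %in% c(3, 4)))
  # results are invariant to region relabelling
  perm_ids <- c(5, 3, 8, 1, 7, 2, 6, 4)
  relab <- coh$parcellation
  relab$labels[] <- perm_ids[coh$parcellation$labels]
  relab <- parcellation(relab$labels)
  suppressWarnings(
    a3b <- analysis3(coh$subjects, relab, perm_config(n_perm = 500, seed = 2)))
  ord <- match(perm_ids, a3b$pain_gt_tactile$region_id)
  expect_equal(a3b$pain_gt_tactile$t[ord], a3$pain_gt_tactile$t,
               tolerance = 1e-10)
})

test_that("the intensity-mismatch comparison responds to the slope regime", {
  pref <- tibble::tibble(region_id = 1:2, preference = c("pain", "pain"))
  run_a4 <- function(slope, seed) {
    re <- region_effects_table(4, 2, 0, intensity_slope = slope)
    cc <- cohort_config(n_subjects = 6, grid = c(4, 4, 4), n_regions = 4,
                        region_effects = re,
                        noise = noise_model(0.3, 0, c(1), 0), seed = seed)
    coh <- simulate_cohort(cc)
    analysis4(coh$subjects, coh$parcellation, pref,
              perm_config(n_perm = 200, seed = 1))
  }
  # slope 0: the pain preference persists (pain_low > tactile_high)
  a4_flat <- run_a4(0, 41)
  expect_true(all(a4_flat$pain_pref$mean_diff > 0))
  # dominant slope: high-intensity tactile beats low-intensity pain
  a4_steep <- run_a4(0.8, 42)
  expect_true(all(a4_steep$pain_pref$mean_diff < 0))
})
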