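test_that("the canonical HRF has the expected shape", {
  h <- canonical_hrf(hrf_spec(), dt = 0.05)
  expect_equal(h[1], 0)           # gamma density with shape > 1 starts at 0
  expect_equal(max(h), 1)         # normalized to peak 1
  # argmax agrees with a dense numeric evaluation of the double gamma
  spec <- hrf_spec()
  tt <- seq(0, 32, by = 1e-3)
  dense <- dgamma(tt, spec$peak_delay_s, scale = 1) -
    spec$undershoot_ratio * dgamma(tt, spec$undershoot_delay_s, scale = 1)
  expect_lt(abs((which.max(h) - 1) * 0.05 - tt[which.max(dense)]), 0.05 + 1e-9)
  # halving dt doubles the sample count (+/- 1)
  expect_lt(abs(length(canonical_hrf(hrf_spec(), 0.025)) - 2 * length(h)), 2)
  expect_error(canonical_hrf(hrf_spec(), 0), "positive")
})

test_that("the DCT drift basis matches the period-count formula", {
  b <- dct_drift_basis(750, 0.8, 128)
  expect_equal(ncol(b), floor(2 * 750 * 0.8 / 128))  # 9 for a 600-s session
  expect_equal(crossprod(b), diag(9), tolerance = 1e-10, ignore_attr = TRUE)
  # independent construction: k-th function is a cosine with k half-cycles
  k <- 3
  oracle <- sqrt(2 / 750) * cos(pi * (2 * (0:749) + 1) * k / (2 * 750))
  expect_equal(b[, k], oracle, tolerance = 1e-12)
  expect_equal(ncol(dct_drift_basis(10, 0.8, 128)), 0)
})

test_that("the five-condition design has the documented structure", {
  cc <- cohort_config(seed = 1)
  ev <- simulate_events(cc, 1)
  m <- match_trials(ev, 0.5)
  motion <- list(matrix(rnorm(750 * 6), 750, 6), matrix(rnorm(750 * 6), 750, 6))
  d <- build_design_5cond(ev, m, 750, 0.8, motion)
  cols <- d$columns
  for (s in 1:2) {
    expect_equal(sum(cols$kind == "condition" & cols$session == s), 5)
    expect_equal(sum(cols$kind == "derivative" & cols$session == s), 5)
    expect_equal(sum(cols$kind == "nuisance" & cols$session == s), 6)
    expect_equal(sum(cols$kind == "drift" & cols$session == s), 9)
    expect_equal(sum(cols$kind == "session_mean" & cols$session == s), 1)
  }
  expect_equal(nrow(d$matrix), 1500)

  # empty conditions are omitted with a warning
  ev_all_matched <- ev
  m_all <- match_trials(ev_all_matched, 20)  # everything pairs
  w <- capture_warnings(
    d2 <- build_design_5cond(ev_all_matched, m_all, 750, 0.8, NULL))
  expect_true(all(grepl("no events", w)))
  expect_false(any(grepl("other_pain", d2$columns$name)))
})

test_that("the parametric design centres and scales its modulator", {
  ev <- make_events(c(4, 5, 6), c(4.5, 5.5, 6.5))
  d <- build_design_parametric(ev, 200, 0.8, NULL)
  mod <- d$matrix[, d$columns$kind == "condition" &
                    d$columns$condition == "rating_mod"]
  # doubling the centred ratings doubles the modulator column
  ev2 <- ev; ev2$rating <- mean(ev$rating) + 2 * (ev$rating - mean(ev$rating))
  d2 <- build_design_parametric(ev2, 200, 0.8, NULL)
  mod2 <- d2$matrix[, d2$columns$kind == "condition" &
                      d2$columns$condition == "rating_mod"]
  expect_equal(mod2, 2 * mod, tolerance = 1e-10)
  # identical ratings: modulator omitted with a warning
  ev3 <- ev; ev3$rating <- 5
  expect_warning(d3 <- build_design_parametric(ev3, 200, 0.8, NULL),
                 "modulator column omitted")
  expect_false(any(d3$columns$condition %in% "rating_mod"))
})

test_that("OLS fitting recovers exact coefficients and handles rank deficiency", {
  set.seed(8)
  x <- cbind(1, rnorm(80), rnorm(80))
  design <- isointense:::new_design_matrix(
    x, tibble::tibble(name = c("mean", "a", "b"), kind = c("session_mean", "condition", "condition"),
                      condition = c(NA, "a", "b"), session = 1L),
    rep(1L, 80), 0.8)
  beta0 <- matrix(c(2, -1, 0.5, 0, 3, 1), 3, 2)
  y <- x %*% beta0
  fit <- fit_glm(y, design)
  expect_equal(fit$beta, beta0, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$sigma2, c(0, 0), tolerance = 1e-12, ignore_attr = TRUE)

  # duplicated column: pseudoinverse keeps betas finite, with a warning
  x_dup <- cbind(x, x[, 3])
  design_dup <- isointense:::new_design_matrix(
    x_dup, tibble::tibble(name = c("mean", "a", "b", "b2"),
                          kind = c("session_mean", rep("condition", 3)),
                          condition = c(NA, "a", "b", "b2"), session = 1L),
    rep(1L, 80), 0.8)
  expect_warning(fit_dup <- fit_glm(y, design_dup), "rank deficient")
  expect_true(all(is.finite(fit_dup$beta)))
  expect_equal(fit_dup$dof, 80 - 3)
})

test_that("null t statistics follow the Student-t reference distribution", {
  set.seed(9)
  x <- cbind(1, scale(rnorm(40)))
  design <- isointense:::new_design_matrix(
    x, tibble::tibble(name = c("mean", "a"), kind = c("session_mean", "condition"),
                      condition = c(NA, "a"), session = 1L), rep(1L, 40), 0.8)
  y <- matrix(rnorm(40 * 10000), 40, 10000)
  fit <- fit_glm(y, design)
  sm <- contrast_map(fit, c(0, 1))
  ks <- ks.test(sm$t, pt, df = fit$dof)
  expect_gt(ks$p.value, 1e-3)
})

test_that("contrasts validate weights and scale as t statistics should", {
  re <- region_effects_table(2, 1, 1, intensity_slope = 0)
  cc <- noiseless_config(grid = c(4, 4, 2), n_regions = 2, region_effects = re,
                         seed = 12)
  ds <- simulate_subject(cc, 1)
  suppressWarnings(fl <- subject_first_level(ds))
  parc <- simulate_parcellation(cc)
  diffs <- region_effects(fl$contrasts$pain_minus_tactile, parc)
  pref <- re$preference[match(diffs$region_id, re$region_id)]
  # noiseless: positive difference exactly in the pain-preferential region
  expect_true(all(diffs$effect[pref == "pain"] > 0.4))
  expect_true(all(diffs$effect[pref == "tactile"] < -0.4))

  expect_error(contrast_map(fl$fit, rep(0, nrow(fl$fit$beta))), "all zero")
  expect_error(contrast_weights(fl$design, "nonexistent"), "no canonical column")

  w <- contrast_weights(fl$design, "matched_pain")
  m1 <- contrast_map(fl$fit, w)
  m2 <- contrast_map(fl$fit, 3 * w)
  expect_equal(m2$effect, 3 * m1$effect, tolerance = 1e-10)
  keep <- is.finite(m1$t) & is.finite(m2$t)
  expect_equal(m2$t[keep], m1$t[keep], tolerance = 1e-8)
})

test_that("drift-space components leave condition betas unchanged", {
  cc <- cohort_config(n_subjects = 1, grid = c(3, 3, 1), n_regions = 1,
                      region_effects = region_effects_table(1, 1, 0),
                      noise = noise_model(0.2, 0, numeric(0), 0), seed = 14)
  ds <- simulate_subject(cc, 1)
  suppressWarnings(fl1 <- subject_first_level(ds))
  # add an arbitrary combination of this design's drift columns to the data
  drift_cols <- fl1$design$matrix[, fl1$design$columns$kind == "drift"]
  set.seed(1)
  bump <- drift_cols %*% rnorm(ncol(drift_cols), sd = 5)
  n1 <- dim(ds$bold[[1]]$data)[4]
  for (s in 1:2) {
    rows <- if (s == 1) seq_len(n1) else n1 + seq_len(n1)
    add <- array(rep(bump[rows], each = prod(dim(ds$bold[[s]]$data)[1:3])),
                 dim(ds$bold[[s]]$data))
    ds$bold[[s]]$data <- ds$bold[[s]]$data + add
  }
  suppressWarnings(fl2 <- subject_first_level(ds))
  cond <- fl1$design$columns$kind == "condition"
  expect_equal(fl2$fit$beta[cond, ], fl1$fit$beta[cond, ], tolerance = 1e-8)
})
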