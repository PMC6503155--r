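test_that("greedy matching follows the closed-interval rule", {
  ev <- make_events(pain_ratings = c(3.0, 5.0), tactile_ratings = c(3.4, 5.6))
  m <- match_trials(ev, 0.5)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$pain_trial_id, "s1_t01")
  expect_equal(m$pairs$tactile_trial_id, "s1_t03")
  expect_equal(m$pairs$delta_rating, 0.4)
  # |5.6 - 5.0| = 0.6 > 0.5: second painful trial stays unmatched
  expect_equal(m$unmatched_pain, "s1_t02")
  expect_equal(m$unmatched_tactile, "s1_t04")

  # the interval bounds are inclusive
  m2 <- match_trials(make_events(4.0, 4.5), 0.5)
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(m2$pairs$delta_rating, 0.5)

  # no tactile trials: everything unmatched
  m3 <- match_trials(make_events(pain_ratings = c(2, 3)), 0.5)
  expect_equal(nrow(m3$pairs), 0)
  expect_equal(length(m3$unmatched_pain), 2)

  expect_error(match_trials(ev, -0.1), "nonnegative")
})

test_that("every matched pair respects the tolerance, on random tables", {
  skip_if_not_installed("igraph")
  set.seed(42)
  deficits <- integer(0)
  for (rep in 1:60) {
    np <- sample(0:12, 1); nt <- sample(0:12, 1)
    ev <- make_events(round(runif(np, 0, 10), 2), round(runif(nt, 0, 10), 2))
    tol <- sample(c(0.25, 0.5, 1), 1)
    m <- match_trials(ev, tol)
    if (nrow(m$pairs)) expect_true(all(m$pairs$delta_rating <= tol + 1e-9))
    # one-to-one: no id used twice
    expect_false(any(duplicated(c(m$pairs$pain_trial_id, m$pairs$tactile_trial_id))))
    # pairs + unmatched partition each modality
    expect_setequal(c(m$pairs$pain_trial_id, m$unmatched_pain),
                    ev$trial_id[ev$modality == "pain"])
    # exact maximum bipartite matching oracle: greedy is maximal, so it
    # finds at least half the optimum; record the actual deficit
    pain <- ev[ev$modality == "pain", ]; tact <- ev[ev$modality == "tactile", ]
    edges <- which(abs(outer(pain$rating, tact$rating, `-`)) <= tol + 1e-9,
                   arr.ind = TRUE)
    opt <- if (nrow(edges) == 0) 0 else {
      g <- igraph::graph_from_edgelist(
        cbind(paste0("p", edges[, 1]), paste0("t", edges[, 2])), directed = FALSE)
      igraph::V(g)$type <- startsWith(igraph::V(g)$name, "t")
      igraph::max_bipartite_match(g)$matching_size
    }
    expect_gte(nrow(m$pairs), ceiling(opt / 2))
    expect_lte(nrow(m$pairs), opt)
    deficits <- c(deficits, opt - nrow(m$pairs))
  }
  # the deficit is recorded, not asserted to be zero
  message(sprintf("greedy matching deficit vs optimum: mean %.3f, max %d",
                  mean(deficits), max(deficits)))
  expect_lt(mean(deficits), 1)
})

test_that("median split labels strictly above/below and drops ties", {
  ev <- make_events(c(1, 2, 3), c(4, 5, 6))
  sp <- median_split(ev)
  expect_equal(attr(sp, "pooled_median"), 3.5)
  expect_setequal(sp$rating[sp$split == "low"], c(1, 2, 3))
  expect_setequal(sp$rating[sp$split == "high"], c(4, 5, 6))

  ev2 <- make_events(c(2, 3), c(4, 4, 5))
  sp2 <- median_split(ev2)
  expect_equal(attr(sp2, "pooled_median"), 4)
  expect_setequal(sp2$rating[sp2$split == "low"], c(2, 3))
  expect_setequal(sp2$rating[sp2$split == "high"], 5)
  expect_equal(sum(sp2$split == "dropped"), 2)

  sp3 <- median_split(make_events(c(5, 5), c(5, 5)))
  expect_true(all(sp3$split == "dropped"))

  expect_error(median_split(make_events(5)), "at least two")
})

test_that("count equalization removes trials nearest the median", {
  ev <- make_events(c(1, 2, 3, 4.4, 4.6, 6, 7), c(1.5, 2.5, 3.5, 6.5, 7.5))
  a <- ev[ev$modality == "pain", ]; b <- ev[ev$modality == "tactile", ]
  eq <- equalize_counts(a, b, median = 4.5)
  expect_equal(nrow(eq$a), 5)
  expect_equal(nrow(eq$b), 5)
  # the two ratings nearest 4.5 were removed from the larger group
  expect_setequal(eq$a$rating, c(1, 2, 3, 6, 7))
  # equal sizes pass through unchanged
  eq2 <- equalize_counts(a[1:5, ], b, median = 4.5)
  expect_identical(eq2$a, a[1:5, ])
  # an empty group forces both empty
  eq3 <- equalize_counts(a, b[0, ], median = 4.5)
  expect_equal(nrow(eq3$a), 0)
})

test_that("matched groups have indistinguishable rating distributions", {
  cc <- cohort_config(n_subjects = 1, seed = 17)
  diffs <- vapply(1:20, function(i) {
    ev <- simulate_events(cc, i)
    m <- match_trials(ev, 0.5)
    lab <- label_matched(ev, m)
    mp <- lab$rating[lab$matched & lab$modality == "pain"]
    mt <- lab$rating[lab$matched & lab$modality == "tactile"]
    mean(mp) - mean(mt)
  }, 1)
  # paired differences are bounded by the tolerance...
  expect_true(all(abs(diffs) <= 0.5 + 1e-9))
  # ...and centred near zero across subjects
  expect_lt(abs(mean(diffs)), 0.1)
})
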