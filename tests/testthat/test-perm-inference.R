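test_that("sign-flip p-values are valid and handle degenerate input", {
  # identically zero maps: nothing can be significant
  z <- one_sample_signflip(matrix(0, 4, 6), NULL,
                           perm_config(n_perm = 64, exact = "always"))
  expect_true(all(z$p_fwe == 1))

  set.seed(5)
  x <- matrix(rnorm(6 * 30), 6, 30)
  r <- one_sample_signflip(x, NULL, perm_config(n_perm = 64, exact = "always"))
  expect_true(all(r$p_fwe >= 1 / 64 - 1e-12))
  expect_true(all(r$p_fwe <= 1))
  # exchangeability: permuting subject order changes nothing beyond
  # floating-point tie flips (one enumeration step at most)
  r2 <- one_sample_signflip(x[sample(6), ], NULL,
                            perm_config(n_perm = 64, exact = "always"))
  expect_lt(max(abs(r2$p_fwe - r$p_fwe)), 2 / 64 + 1e-12)

  expect_error(one_sample_signflip(x[1, , drop = FALSE], NULL, perm_config()),
               "at least 2 subjects")
})

test_that("sampled sign-flip p-values agree with exhaustive enumeration", {
  set.seed(6)
  x <- matrix(rnorm(8 * 64, mean = 0.3), 8, 64)
  pe <- one_sample_signflip(x, NULL,
                            perm_config(n_perm = 256, seed = 1, exact = "always"))
  ps <- one_sample_signflip(x, NULL,
                            perm_config(n_perm = 5000, seed = 2, exact = "never"))
  mcse <- sqrt(pe$p_fwe * (1 - pe$p_fwe) / 5000)
  expect_true(all(abs(ps$p_fwe - pe$p_fwe) <= 3 * mcse + 1e-12))
})

test_that("one-tailed p-values are monotone under positive shifts", {
  set.seed(7)
  x <- matrix(rnorm(8 * 20), 8, 20)
  cfg <- perm_config(n_perm = 256, tail = "greater", exact = "always")
  p0 <- one_sample_signflip(x, NULL, cfg)$p_fwe
  p1 <- one_sample_signflip(x + 0.5, NULL, cfg)$p_fwe
  expect_true(all(p1 <= p0 + 1e-12))
})

test_that("connected components respect the connectivity scheme", {
  # two blobs joined by a single diagonal voxel
  m <- array(FALSE, c(5, 5, 3))
  m[1:2, 1:2, 1] <- TRUE
  m[4:5, 4:5, 1] <- TRUE
  m[3, 3, 1] <- TRUE
  expect_equal(length(label_clusters(m, 26)$sizes), 1)
  expect_equal(length(label_clusters(m, 6)$sizes), 3)
  # 18-connectivity joins edge neighbours but not corner neighbours
  m2 <- array(FALSE, c(3, 3, 3))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 1] <- TRUE  # edge-diagonal in plane
  expect_equal(length(label_clusters(m2, 18)$sizes), 1)
  m3 <- array(FALSE, c(3, 3, 3))
  m3[1, 1, 1] <- TRUE; m3[2, 2, 2] <- TRUE  # full corner diagonal
  expect_equal(length(label_clusters(m3, 18)$sizes), 2)
  expect_equal(length(label_clusters(m3, 26)$sizes), 1)
  expect_equal(label_clusters(array(FALSE, c(2, 2, 2)))$sizes, integer(0))
  # sizes are conserved
  cl <- label_clusters(m, 6)
  expect_equal(sum(cl$sizes), sum(m))
})

test_that("cluster inference recovers an injected activation blob", {
  set.seed(11)
  dims <- c(8, 8, 8)
  mask <- array(TRUE, dims)
  blob <- array(FALSE, dims); blob[3:6, 3:6, 3:5] <- TRUE  # 48 voxels
  maps <- lapply(1:10, function(i) {
    m <- array(rnorm(prod(dims), sd = 0.5), dims)
    m[blob] <- m[blob] + 2
    m
  })
  res <- cluster_signflip(maps, mask, perm_config(n_perm = 500, seed = 3,
                                                  tail = "greater"))
  sig <- res$clusters[res$clusters$p_fwe <= 0.05, ]
  expect_equal(nrow(sig), 1)
  peak <- c(sig$peak_x, sig$peak_y, sig$peak_z)
  expect_true(blob[peak[1], peak[2], peak[3]])
  # no voxel above threshold: empty table
  null_maps <- lapply(1:6, function(i) array(rnorm(prod(dims), sd = 1e-3), dims))
  res0 <- cluster_signflip(null_maps, mask,
                           perm_config(n_perm = 64, seed = 4, cdt_p = 1e-6))
  expect_equal(nrow(res0$clusters), 0)
})

test_that("paired tests are antisymmetric and detect injected shifts", {
  set.seed(12)
  a <- matrix(rnorm(10 * 8), 10, 8)
  cfg <- perm_config(n_perm = 512, seed = 5, exact = "always")
  # b = a exactly: all t zero, all p = 1
  same <- paired_signflip(a, a, cfg)
  expect_true(all(same$t == 0))
  expect_true(all(same$p_fwe == 1))
  # swapping a and b negates t and preserves p (two-tailed)
  b <- a + matrix(rnorm(80, sd = 0.5), 10, 8)
  r1 <- paired_signflip(a, b, cfg)
  r2 <- paired_signflip(b, a, cfg)
  expect_equal(r2$t, -r1$t, tolerance = 1e-12)
  expect_equal(r2$p_fwe, r1$p_fwe, tolerance = 1e-12)
  expect_error(paired_signflip(a, b[1:5, ]), "identical dimensions")
})

test_that("a shifted region is flagged among null regions with high power", {
  set.seed(13)
  hits <- 0L
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    d <- matrix(rnorm(30 * 20), 30, 20)   # 19 null regions + 1 shifted
    d[, 1] <- d[, 1] + 1.5                # 1.5 pooled-SD shift
    r <- paired_signflip(d, matrix(0, 30, 20),
                         perm_config(n_perm = 500, seed = i))
    if (r$p_fwe[1] <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("union and conjunction masks obey set identities", {
  a <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1))
  b <- array(c(FALSE, TRUE, FALSE, FALSE), c(2, 2, 1))
  expect_equal(sum(conjunction_mask(a, b)), 0)
  expect_equal(sum(union_mask(a, b)), sum(a) + sum(b))
  expect_equal(union_mask(a, a), a)
  expect_equal(conjunction_mask(a, a), a)
  expect_true(all(conjunction_mask(a, b) <= union_mask(a, b)))
  expect_error(union_mask(a, array(TRUE, c(3, 2, 1))), "shapes differ")
})
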