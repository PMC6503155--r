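#' Permutation-test configuration
#'
#' @param n_perm Number of sign-flip permutations (default 5000).
#' @param seed Integer seed for the permutation stream.
#' @param alpha Family-wise significance level (default 0.05).
#' @param cdt_p Cluster-defining threshold as an uncorrected one-tailed
#'   p-value (default 0.001).
#' @param connectivity Voxel neighbourhood for cluster formation: 6 (faces),
#'   18 (faces + edges, default) or 26 (faces + edges + corners).
#' @param tail `"two"`, `"greater"` or `"less"`.
#' @param exact `"auto"` enumerates all `2^n` sign flips whenever
#'   `2^n <= n_perm`; `"always"`/`"never"` force the choice.
#' @return A `perm_config` list.
#' @export
perm_config <- function(n_perm = 5000, seed = 1L, alpha = 0.05, cdt_p = 0.001,
                        connectivity = 18, tail = c("two", "greater", "less"),
                        exact = c("auto", "always", "never")) {
  tail <- match.arg(tail)
  exact <- match.arg(exact)
  stopifnot(n_perm >= 1, alpha > 0, alpha < 1, cdt_p > 0, cdt_p < 1,
            connectivity %in% c(6, 18, 26))
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 alpha = alpha, cdt_p = cdt_p,
                 connectivity = as.integer(connectivity),
                 tail = tail, exact = exact),
            class = "perm_config")
}

# subject maps -> n x V matrix; maps may be a matrix, a list of 3-D arrays,
# or a list of stat_map objects (their effect images)
as_subject_matrix <- function(maps, mask = NULL) {
  if (is.matrix(maps)) return(maps)
  rows <- lapply(maps, function(m) {
    if (inherits(m, "stat_map")) m <- m$effect
    if (is.array(m) && !is.null(mask)) as.numeric(m[mask]) else as.numeric(m)
  })
  len <- unique(vapply(rows, length, 1L))
  if (length(len) != 1L) stop("subject maps differ in size", call. = FALSE)
  do.call(rbind, rows)
}

sign_matrix <- function(n_subj, cfg) {
  do_exact <- switch(cfg$exact,
    always = TRUE,
    never = FALSE,
    auto = n_subj <= 30 && 2^n_subj <= cfg$n_perm
  )
  if (do_exact) {
    s <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_subj), KEEP.OUT.ATTRS = FALSE))
    dimnames(s) <- NULL
    list(signs = s, exact = TRUE)
  } else {
    # draw from the configured stream without disturbing the caller's RNG
    rs <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(cfg$seed)
    s <- matrix(sample(c(-1, 1), cfg$n_perm * n_subj, replace = TRUE),
                nrow = cfg$n_perm)
    if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
    list(signs = s, exact = FALSE)
  }
}

# one-sample t statistics for every row of a sign matrix, exploiting that the
# per-subject sum of squares is sign-invariant
signflip_t <- function(signs, maps, ss) {
  n <- ncol(signs)
  m <- (signs %*% maps) / n
  v <- (rep(1, nrow(signs)) %o% ss - n * m^2) / (n - 1)
  tval <- m / sqrt(v / n)
  zero <- v <= 0
  if (any(zero)) tval[zero] <- ifelse(m[zero] == 0, 0, sign(m[zero]) * Inf)
  tval
}

tail_stat <- function(tval, tail) {
  switch(tail, two = abs(tval), greater = tval, less = -tval)
}

perm_pvalue <- function(stat_obs, null_max, exact) {
  # tie guard: the identity flip re-enters through the batched matrix path,
  # whose floating-point sum can differ from the observed statistic by an ulp
  counts <- vapply(stat_obs, function(s)
    sum(null_max >= s - 1e-12 * max(1, abs(s))), 1L)
  m <- length(null_max)
  if (exact) pmax(counts / m, 1 / m) else pmax((1L + counts) / (m + 1L), 1 / (m + 1L))
}

#' One-sample sign-flip permutation test with voxel-level FWE
#'
#' Second-level one-sample t-test whose null distribution is generated by
#' randomly negating each subject's whole effect map (one sign per subject
#' per permutation). Corrected p-values come from the permutation
#' distribution of the maximum statistic over the mask, so they control the
#' family-wise error rate. With few subjects all `2^n` flips are enumerated
#' exactly.
#'
#' @param maps Subject effect maps: an n x V matrix, a list of 3-D arrays, or
#'   a list of `stat_map`s.
#' @param mask Logical 3-D array restricting the tested voxels (`NULL` for
#'   all).
#' @param cfg A [perm_config()].
#' @return A `voxel_fwe` list: observed `t` (array if a mask was given),
#'   `p_fwe`, `threshold_t` (the alpha-quantile of the max-statistic null),
#'   `sig` mask, `null_max`, `exact`, `n_subjects`, `cfg`.
#' @export
one_sample_signflip <- function(maps, mask = NULL, cfg = perm_config()) {
  x <- as_subject_matrix(maps, mask)
  n <- nrow(x)
  if (n < 2L) stop("at least 2 subjects are required", call. = FALSE)
  if (!is.null(mask) && !any(mask)) stop("mask is empty", call. = FALSE)
  ss <- colSums(x^2)
  t_obs <- as.numeric(signflip_t(matrix(1, 1, n), x, ss))
  stat_obs <- tail_stat(t_obs, cfg$tail)

  sm <- sign_matrix(n, cfg)
  null_max <- numeric(0)
  for (start in seq(1L, nrow(sm$signs), by = 1024L)) {
    idx <- start:min(start + 1023L, nrow(sm$signs))
    tt <- signflip_t(sm$signs[idx, , drop = FALSE], x, ss)
    null_max <- c(null_max, apply(tail_stat(tt, cfg$tail), 1L, max))
  }
  p <- perm_pvalue(stat_obs, null_max, sm$exact)
  thr <- stats::quantile(null_max, 1 - cfg$alpha, type = 1, names = FALSE)
  out <- list(t = t_obs, p_fwe = p, threshold_t = thr, sig = p <= cfg$alpha,
              null_max = null_max, exact = sm$exact, n_subjects = n, cfg = cfg)
  if (!is.null(mask)) {
    out$t <- unmask(t_obs, mask)
    out$p_fwe <- unmask(p, mask, fill = 1)
    out$sig <- unmask(p <= cfg$alpha, mask, fill = FALSE) > 0
    out$mask <- mask
  }
  structure(out, class = "voxel_fwe")
}

#' @export
print.voxel_fwe <- function(x, ...) {
  cat(sprintf(
    "<voxel_fwe> n = %d subjects, %s permutations (%s), %d voxels significant at alpha %.3g\n",
    x$n_subjects, length(x$null_max), if (x$exact) "exhaustive" else "sampled",
    sum(x$sig), x$cfg$alpha))
  invisible(x)
}

connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  g <- g[keep, , drop = FALSE]
  # keep one offset per symmetric pair
  g[g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
      (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0), , drop = FALSE]
}

#' Label connected components of a 3-D logical array
#'
#' Union-find connected-component labelling under 6-, 18- or 26-neighbour
#' connectivity, the primitive behind cluster-extent inference.
#'
#' @param mask Logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return List with `labels` (integer array, 0 outside components) and
#'   `sizes` (voxel count per component, in label order).
#' @export
label_clusters <- function(mask, connectivity = 18) {
  d <- dim(mask)
  idx <- which(mask)
  nv <- length(idx)
  labels <- array(0L, d)
  if (nv == 0L) return(list(labels = labels, sizes = integer(0)))
  pos <- array(0L, d)
  pos[idx] <- seq_len(nv)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  co <- arrayInd(idx, d)
  offsets <- connectivity_offsets(connectivity)
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    nb <- sweep(co, 2L, off, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_rank <- pos[nb[ok, , drop = FALSE]]
    here <- which(ok)[nb_rank > 0L]
    there <- nb_rank[nb_rank > 0L]
    for (k in seq_along(here)) {
      ra <- find(here[k]); rb <- find(there[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(nv), find, 1L)
  lab <- match(roots, unique(roots))
  labels[idx] <- lab
  list(labels = labels, sizes = as.integer(table(lab)))
}

#' Cluster-extent sign-flip permutation test
#'
#' Voxels exceeding the cluster-defining threshold (the one-tailed Student-t
#' quantile at `1 - cdt_p` with `n - 1` dof, applied to the tail statistic)
#' are grouped into clusters by the configured connectivity. The null
#' distribution of the maximum cluster size is built by re-thresholding the
#' sign-flipped t maps, and each observed cluster receives a corrected
#' p-value from it.
#'
#' @inheritParams one_sample_signflip
#' @return A `cluster_fwe` list: `clusters` tibble (`cluster_id`, `size`,
#'   `peak_t`, `peak_x/y/z` voxel indices, `p_fwe`), `label_map`, `cdt_t`,
#'   `t`, `null_max_size`, `exact`, `cfg`.
#' @export
cluster_signflip <- function(maps, mask, cfg = perm_config()) {
  if (is.null(mask)) stop("cluster inference requires a 3-D mask", call. = FALSE)
  x <- as_subject_matrix(maps, mask)
  n <- nrow(x)
  if (n < 2L) stop("at least 2 subjects are required", call. = FALSE)
  ss <- colSums(x^2)
  cdt_t <- stats::qt(1 - cfg$cdt_p, df = n - 1)
  t_obs <- as.numeric(signflip_t(matrix(1, 1, n), x, ss))

  cluster_max <- function(stat_vec) {
    supra <- unmask(stat_vec >= cdt_t, mask, fill = FALSE) > 0
    cl <- label_clusters(supra, cfg$connectivity)
    if (length(cl$sizes)) max(cl$sizes) else 0L
  }

  sm <- sign_matrix(n, cfg)
  null_max <- numeric(0)
  for (start in seq(1L, nrow(sm$signs), by = 512L)) {
    idx <- start:min(start + 511L, nrow(sm$signs))
    tt <- tail_stat(signflip_t(sm$signs[idx, , drop = FALSE], x, ss), cfg$tail)
    null_max <- c(null_max, apply(tt, 1L, cluster_max))
  }

  supra <- unmask(tail_stat(t_obs, cfg$tail) >= cdt_t, mask, fill = FALSE) > 0
  cl <- label_clusters(supra, cfg$connectivity)
  t_arr <- unmask(t_obs, mask)
  rows <- lapply(seq_along(cl$sizes), function(id) {
    vox <- which(cl$labels == id)
    pk <- vox[which.max(abs(t_arr[vox]))]
    pc <- arrayInd(pk, dim(mask))
    tibble::tibble(cluster_id = id, size = cl$sizes[id], peak_t = t_arr[pk],
                   peak_x = pc[1], peak_y = pc[2], peak_z = pc[3])
  })
  clusters <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(cluster_id = integer(0), size = integer(0), peak_t = numeric(0),
                   peak_x = integer(0), peak_y = integer(0), peak_z = integer(0))
  clusters$p_fwe <- perm_pvalue(clusters$size, null_max, sm$exact)
  ord <- order(clusters$p_fwe, -clusters$size)
  clusters <- clusters[ord, , drop = FALSE]
  # relabel map in table order
  relabel <- array(0L, dim(mask))
  for (k in seq_len(nrow(clusters)))
    relabel[cl$labels == clusters$cluster_id[k]] <- k
  clusters$cluster_id <- seq_len(nrow(clusters))
  structure(
    list(clusters = clusters, label_map = relabel, cdt_t = cdt_t, t = t_arr,
         null_max_size = null_max, exact = sm$exact, n_subjects = n, cfg = cfg),
    class = "cluster_fwe"
  )
}

#' @export
print.cluster_fwe <- function(x, ...) {
  cat(sprintf("<cluster_fwe> cdt t = %.3g, %d clusters, %d significant at alpha %.3g\n",
              x$cdt_t, nrow(x$clusters), sum(x$clusters$p_fwe <= x$cfg$alpha),
              x$cfg$alpha))
  invisible(x)
}

#' @export
tidy.cluster_fwe <- function(x, ...) x$clusters

#' Paired sign-flip permutation test across regions
#'
#' Paired t-tests on per-subject differences `a - b` for every region, with
#' family-wise error control from the permutation distribution of the
#' maximum statistic across regions under subject-level sign flips of the
#' differences.
#'
#' @param values_a,values_b Subject x region matrices with matching rows and
#'   columns (e.g. AUCs per condition).
#' @param cfg A [perm_config()].
#' @return A `paired_perm` object: tibble with `region_id`, `mean_diff`, `t`,
#'   `p_fwe`; attributes carry `n_perm`, `tail`, `exact`, `n_subjects`.
#' @export
paired_signflip <- function(values_a, values_b, cfg = perm_config()) {
  a <- as.matrix(values_a); b <- as.matrix(values_b)
  if (!identical(dim(a), dim(b)))
    stop("`values_a` and `values_b` must have identical dimensions", call. = FALSE)
  n <- nrow(a)
  if (n < 2L) stop("at least 2 subjects are required", call. = FALSE)
  d <- a - b
  ss <- colSums(d^2)
  t_obs <- as.numeric(signflip_t(matrix(1, 1, n), d, ss))
  stat_obs <- tail_stat(t_obs, cfg$tail)
  sm <- sign_matrix(n, cfg)
  tt <- tail_stat(signflip_t(sm$signs, d, ss), cfg$tail)
  null_max <- apply(tt, 1L, max)
  p <- perm_pvalue(stat_obs, null_max, sm$exact)
  ids <- colnames(a)
  ids <- if (is.null(ids)) seq_len(ncol(a)) else ids
  res <- tibble::tibble(region_id = ids, mean_diff = colMeans(d), t = t_obs,
                        p_fwe = p)
  structure(res, class = c("paired_perm", class(res)),
            n_perm = length(null_max), tail = cfg$tail, exact = sm$exact,
            n_subjects = n, alpha = cfg$alpha)
}

#' @export
glance.paired_perm <- function(x, ...) {
  tibble::tibble(n_subjects = attr(x, "n_subjects"), n_regions = nrow(x),
                 n_perm = attr(x, "n_perm"), tail = attr(x, "tail"),
                 exact = attr(x, "exact"),
                 n_significant = sum(x$p_fwe <= attr(x, "alpha")))
}

#' Union and conjunction of significance masks
#'
#' Voxelwise OR (union) and AND (conjunction) of two thresholded maps: the
#' union constrains where modality-difference contrasts are evaluated, and
#' the conjunction identifies voxels activated by both modalities.
#'
#' @param map_a_sig,map_b_sig Logical arrays of identical shape.
#' @return Logical array.
#' @export
union_mask <- function(map_a_sig, map_b_sig) {
  if (!identical(dim(map_a_sig), dim(map_b_sig)))
    stop("mask shapes differ", call. = FALSE)
  map_a_sig | map_b_sig
}

#' @rdname union_mask
#' @export
conjunction_mask <- function(map_a_sig, map_b_sig) {
  if (!identical(dim(map_a_sig), dim(map_b_sig)))
    stop("mask shapes differ", call. = FALSE)
  map_a_sig & map_b_sig
}
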