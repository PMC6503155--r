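#' Fit a first-level GLM by ordinary least squares
#'
#' Per-voxel OLS of the (session-concatenated) BOLD time series on a design
#' matrix, via a rank-revealing decomposition. Rank-deficient designs are
#' solved with the Moore-Penrose pseudoinverse and the degrees of freedom are
#' reduced to `T - rank`.
#'
#' @param bold A [bold_volume()] or a list of per-session volumes sharing the
#'   grid, mask and TR (concatenated in time, matching the design's session
#'   row ranges). A plain T x V numeric matrix is also accepted.
#' @param design A `design_matrix` from [build_design_5cond()] or
#'   [build_design_parametric()].
#' @return A `glm_fit`: `beta` (K x V), `sigma2` (length V), `dof`, `rank`,
#'   `design`, plus the mask/grid needed to rebuild maps.
#' @export
fit_glm <- function(bold, design) {
  stopifnot(inherits(design, "design_matrix"))
  mask <- NULL; grid_dim <- NULL
  if (inherits(bold, "bold_volume")) bold <- list(bold)
  if (is.list(bold) && all(vapply(bold, inherits, TRUE, "bold_volume"))) {
    mask <- bold[[1]]$mask
    grid_dim <- dim(bold[[1]]$data)[1:3]
    if (!any(mask)) stop("mask is empty", call. = FALSE)
    y <- t(do.call(cbind, lapply(bold, vol_matrix)))  # T_total x V
  } else {
    y <- as.matrix(bold)
  }
  x <- design$matrix
  if (nrow(x) != nrow(y))
    stop(sprintf("design rows (%d) must equal total scans (%d)", nrow(x), nrow(y)),
         call. = FALSE)
  qx <- qr(x)
  rk <- qx$rank
  dof <- nrow(x) - rk
  if (dof <= 0) stop("non-positive residual degrees of freedom", call. = FALSE)
  if (rk == ncol(x)) {
    beta <- qr.coef(qx, y)
    xtx_pinv <- chol2inv(qr.R(qx))
  } else {
    warning(sprintf("design is rank deficient (rank %d of %d columns); using pseudoinverse",
                    rk, ncol(x)), call. = FALSE)
    sv <- svd(x)
    pos <- sv$d > max(sv$d) * 1e-10
    pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    beta <- pinv %*% y
    xtx_pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$v[, pos, drop = FALSE]) / sv$d[pos]^2)
  }
  res <- y - x %*% beta
  sigma2 <- colSums(res^2) / dof
  structure(
    list(beta = beta, sigma2 = sigma2, dof = dof, rank = rk, design = design,
         mask = mask, grid_dim = grid_dim),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d columns, %d voxels, %d residual dof\n",
              nrow(x$beta), ncol(x$beta), x$dof))
  invisible(x)
}

#' @export
glance.glm_fit <- function(x, ...) {
  tibble::tibble(n_columns = nrow(x$beta), n_voxels = ncol(x$beta),
                 dof = x$dof, rank = x$rank,
                 mean_sigma2 = mean(x$sigma2))
}

#' Contrast weights by condition name
#'
#' Builds a weight vector over design columns from condition names,
#' averaging the per-session canonical (non-derivative) columns of each named
#' condition so that sessions contribute equally.
#'
#' @param design A `design_matrix`.
#' @param plus Condition names entering with weight +1.
#' @param minus Condition names entering with weight -1.
#' @return Named numeric weight vector of length `ncol(design$matrix)`.
#' @export
contrast_weights <- function(design, plus, minus = character(0)) {
  w <- stats::setNames(numeric(nrow(design$columns)), design$columns$name)
  add <- function(w, conditions, sign) {
    for (cn in conditions) {
      sel <- design$columns$kind == "condition" &
        !is.na(design$columns$condition) & design$columns$condition == cn
      if (!any(sel))
        stop(sprintf("condition '%s' has no canonical column in this design (omitted or unknown)",
                     cn), call. = FALSE)
      w[sel] <- w[sel] + sign / sum(sel)
    }
    w
  }
  w <- add(w, plus, 1)
  w <- add(w, minus, -1)
  w
}

#' Contrast effect and t maps from a fitted GLM
#'
#' Computes the per-voxel contrast of parameter estimates `w' beta` and its
#' t statistic `w' beta / sqrt(sigma2 * w' (X'X)^- w)`.
#'
#' @param fit A `glm_fit`.
#' @param weights Numeric weight vector over design columns, or a named
#'   vector/list understood by [contrast_weights()] via `plus`/`minus`.
#' @return A `stat_map` list: `effect` and `t` 3-D arrays (or vectors when
#'   the fit was matrix-based), `weights`, `dof`, `mask`.
#' @export
contrast_map <- function(fit, weights) {
  stopifnot(inherits(fit, "glm_fit"))
  k <- nrow(fit$beta)
  if (length(weights) != k)
    stop(sprintf("weights length (%d) must equal design columns (%d)", length(weights), k),
         call. = FALSE)
  weights <- as.numeric(weights)
  if (all(weights == 0)) stop("contrast weights are all zero", call. = FALSE)
  effect <- as.numeric(crossprod(weights, fit$beta))
  design <- fit$design
  qx <- qr(design$matrix)
  var_w <- if (qx$rank == ncol(design$matrix)) {
    as.numeric(t(weights) %*% chol2inv(qr.R(qx)) %*% weights)
  } else {
    sv <- svd(design$matrix)
    pos <- sv$d > max(sv$d) * 1e-10
    xtx_pinv <- sv$v[, pos, drop = FALSE] %*% (t(sv$v[, pos, drop = FALSE]) / sv$d[pos]^2)
    as.numeric(t(weights) %*% xtx_pinv %*% weights)
  }
  tval <- effect / sqrt(fit$sigma2 * var_w)
  out <- list(effect = effect, t = tval, weights = weights, dof = fit$dof,
              mask = fit$mask, grid_dim = fit$grid_dim)
  if (!is.null(fit$mask)) {
    out$effect <- unmask(effect, fit$mask, fill = 0)
    out$t <- unmask(tval, fit$mask, fill = 0)
  }
  structure(out, class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s, dof %d, max |t| = %.3g\n",
              if (is.array(x$t)) paste(dim(x$t), collapse = " x ") else
                sprintf("%d voxels", length(x$t)),
              x$dof, max(abs(x$t), na.rm = TRUE)))
  invisible(x)
}

#' Average a stat map's effect within parcellation regions
#'
#' @param map A `stat_map` (array-backed).
#' @param parc A [parcellation()] on the same grid.
#' @return A tibble with `region_id`, `effect` (mean over region voxels),
#'   `n_voxels`.
#' @export
region_effects <- function(map, parc) {
  stopifnot(inherits(map, "stat_map"), inherits(parc, "parcellation"))
  lab <- as.vector(parc$labels)
  eff <- as.vector(map$effect)
  keep <- lab > 0L
  agg <- tapply(eff[keep], lab[keep], mean)
  cnt <- tapply(eff[keep], lab[keep], length)
  ids <- as.integer(names(agg))
  tibble::tibble(region_id = ids, effect = as.numeric(agg),
                 n_voxels = as.integer(cnt))[match(parc$region_ids, ids), ]
}
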