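#' Construct a 4-D BOLD volume
#'
#' A `bold_volume` bundles a 4-D numeric array (x, y, z, time) with its
#' repetition time, voxel size and an analysis mask. It is the container
#' every imaging operation in the package consumes and produces.
#'
#' @param data Numeric 4-D array, dimensions X x Y x Z x T.
#' @param tr Repetition time in seconds (time per volume), > 0.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @param mask Logical 3-D array matching the spatial grid; `NULL` means
#'   all voxels are in-mask.
#' @return An object of class `bold_volume`.
#' @export
bold_volume <- function(data, tr, voxel_size = c(3, 3, 3), mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4-D array (x, y, z, time)", call. = FALSE)
  if (dim(data)[4] < 1L) stop("time axis must have at least one volume", call. = FALSE)
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("`tr` must be a single positive number (seconds)", call. = FALSE)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive lengths in mm", call. = FALSE)
  sp <- dim(data)[1:3]
  if (is.null(mask)) {
    mask <- array(TRUE, sp)
  } else {
    if (!identical(dim(mask), as.integer(sp)))
      stop("`mask` shape must equal the spatial grid shape", call. = FALSE)
    mask <- array(as.logical(mask), sp)
  }
  # non-finite values are only tolerated outside the mask
  if (any(!is.finite(data[rep(mask, dim(data)[4])])))
    stop("non-finite voxel values inside the mask", call. = FALSE)
  structure(
    list(data = data, tr = tr, voxel_size = as.numeric(voxel_size), mask = mask),
    class = "bold_volume"
  )
}

#' @export
print.bold_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<bold_volume> %d x %d x %d voxels, %d volumes, TR %.3g s, %d in-mask voxels\n",
    d[1], d[2], d[3], d[4], x$tr, sum(x$mask)
  ))
  invisible(x)
}

#' @export
dim.bold_volume <- function(x) dim(x$data)

#' Construct a parcellation
#'
#' An integer-labelled 3-D grid assigning voxels to brain regions; label 0 is
#' background.
#'
#' @param labels Integer 3-D array; 0 means background.
#' @param region_ids Optional ordered integer vector of region labels; defaults
#'   to the sorted positive labels present.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, region_ids = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  present <- sort(unique(labels[labels > 0L]))
  if (is.null(region_ids)) region_ids <- present
  region_ids <- as.integer(region_ids)
  if (any(region_ids <= 0L)) stop("region ids must be positive integers", call. = FALSE)
  if (!all(present %in% region_ids))
    stop("labels contain values not listed in `region_ids`", call. = FALSE)
  structure(list(labels = labels, region_ids = region_ids), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf(
    "<parcellation> %s grid, %d regions, %d labelled voxels\n",
    paste(dim(x$labels), collapse = " x "), length(x$region_ids), sum(x$labels > 0L)
  ))
  invisible(x)
}

#' Read a 4-D BOLD NIfTI file
#'
#' The repetition time is taken from the time-axis pixel dimension of the
#' NIfTI-1 header.
#'
#' @param path Path to a NIfTI-1 file with 4 dimensions.
#' @param voxel_size Optional override of the spatial voxel size (mm).
#' @return A [bold_volume()].
#' @export
read_bold <- function(path, voxel_size = NULL) {
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != 4L)
    stop(sprintf("expected 4-D image, got %d dimensions in '%s'", length(dim(im)), path),
         call. = FALSE)
  pd <- RNifti::pixdim(im)
  tr <- if (length(pd) >= 4L) pd[4] else NA_real_
  if (!is.finite(tr) || tr <= 0)
    stop(sprintf("non-positive or missing tr (time-axis pixdim) in '%s'", path), call. = FALSE)
  vs <- if (is.null(voxel_size)) pd[1:3] else voxel_size
  bold_volume(array(as.numeric(im), dim(im)), tr = tr, voxel_size = vs)
}

#' Write a 4-D BOLD volume as NIfTI
#'
#' @param vol A [bold_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold <- function(vol, path) {
  stopifnot(inherits(vol, "bold_volume"))
  im <- RNifti::asNifti(vol$data)
  RNifti::pixdim(im) <- c(vol$voxel_size, vol$tr)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read / write an integer parcellation volume
#'
#' @param path NIfTI path.
#' @return [parcellation()] for `read_parcellation`; the path invisibly for
#'   `write_parcellation`.
#' @export
read_parcellation <- function(path) {
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != 3L)
    stop(sprintf("expected 3-D label image, got %d dimensions", length(dim(im))), call. = FALSE)
  parcellation(array(as.integer(round(im)), dim(im)))
}

#' @param parc A [parcellation()].
#' @rdname read_parcellation
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  im <- RNifti::asNifti(parc$labels)
  RNifti::writeNifti(im, path, datatype = "int32")
  invisible(path)
}

# 1-D convolution with reflective boundaries (scipy-style 'reflect':
# d c b a | a b c d | d c b a), kernel assumed odd-length and normalized.
conv1d_reflect <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(x * k)
  n <- length(x)
  idx <- c(pmin(r:1, n), 1:n, pmax(n - seq_len(r) + 1L, 1L))
  xp <- x[idx]
  out <- stats::filter(xp, k, method = "convolution", sides = 2L)
  as.numeric(out[(r + 1L):(r + n)])
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  t <- (-r):r
  k <- exp(-t^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Spatially smooth a BOLD volume with an isotropic Gaussian
#'
#' Separable Gaussian convolution with reflective boundary handling, applied
#' to every volume. The full-width at half-maximum is specified in mm and
#' converted per axis through the voxel size (sigma = fwhm / sqrt(8 ln 2)).
#' A FWHM of 0 returns the input unchanged.
#'
#' @param vol A [bold_volume()].
#' @param fwhm_mm Full-width at half-maximum of the kernel, mm, >= 0.
#' @return A smoothed [bold_volume()].
#' @export
smooth_gaussian <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "bold_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("`fwhm_mm` must be a single nonnegative number", call. = FALSE)
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / sqrt(8 * log(2))
  d <- dim(vol$data)
  out <- vol$data
  for (ax in 1:3) {
    sig_vox <- sigma_mm / vol$voxel_size[ax]
    k <- gaussian_kernel_1d(sig_vox)
    # fold axis `ax` to the first dimension, convolve columns, restore
    perm <- c(ax, setdiff(1:4, ax))
    a <- aperm(out, perm)
    m <- matrix(a, nrow = d[ax])
    m <- apply(m, 2L, conv1d_reflect, k = k)
    a <- array(m, dim(a))
    out <- aperm(a, order(perm))
  }
  bold_volume(out, tr = vol$tr, voxel_size = vol$voxel_size, mask = vol$mask)
}

# in-mask voxel x time matrix (rows follow which(mask) order)
vol_matrix <- function(vol) {
  d <- dim(vol$data)
  m <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4])
  m[as.vector(vol$mask), , drop = FALSE]
}

# place a per-voxel vector back into a 3-D array (NA outside mask -> fill)
unmask <- function(values, mask, fill = 0) {
  out <- array(fill, dim(mask))
  out[mask] <- values
  out
}
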