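#' Canonical double-gamma HRF specification
#'
#' Parameters of the canonical hemodynamic response function used for all
#' model-based regressors: a difference of two gamma densities (response peak
#' minus a scaled undershoot), sampled at microtime resolution and normalized
#' to peak 1.
#'
#' @param peak_delay_s Delay of the response gamma, seconds.
#' @param undershoot_delay_s Delay of the undershoot gamma, seconds.
#' @param peak_dispersion,undershoot_dispersion Dispersion (gamma scale) of
#'   the two components, seconds.
#' @param undershoot_ratio Amplitude ratio of undershoot to peak.
#' @param kernel_length_s Support of the sampled kernel, seconds.
#' @param microtime_bins_per_tr Microtime bins per TR used when building
#'   regressors.
#' @param microtime_onset_bin Bin at which the scan is sampled (middle-slice
#'   equivalent).
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     undershoot_ratio = 1 / 6, kernel_length_s = 32,
                     microtime_bins_per_tr = 16, microtime_onset_bin = 8) {
  vals <- c(peak_delay_s, undershoot_delay_s, peak_dispersion,
            undershoot_dispersion, kernel_length_s, microtime_bins_per_tr)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("HRF delays, dispersions, kernel length and bin count must be positive",
         call. = FALSE)
  structure(
    list(
      peak_delay_s = peak_delay_s, undershoot_delay_s = undershoot_delay_s,
      peak_dispersion = peak_dispersion,
      undershoot_dispersion = undershoot_dispersion,
      undershoot_ratio = undershoot_ratio, kernel_length_s = kernel_length_s,
      microtime_bins_per_tr = as.integer(microtime_bins_per_tr),
      microtime_onset_bin = as.integer(microtime_onset_bin)
    ),
    class = "hrf_spec"
  )
}

#' Sample the canonical double-gamma HRF
#'
#' @param spec An [hrf_spec()].
#' @param dt Sampling interval in seconds, > 0.
#' @return Numeric vector of kernel samples at `0, dt, 2 dt, ...` up to the
#'   kernel length, scaled to peak 1.
#' @export
canonical_hrf <- function(spec = hrf_spec(), dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number of seconds", call. = FALSE)
  t <- seq(0, spec$kernel_length_s, by = dt)
  h <- stats::dgamma(t, shape = spec$peak_delay_s / spec$peak_dispersion,
                     scale = spec$peak_dispersion) -
    spec$undershoot_ratio *
      stats::dgamma(t, shape = spec$undershoot_delay_s / spec$undershoot_dispersion,
                    scale = spec$undershoot_dispersion)
  h / max(h)
}

# finite-difference derivative of the sampled kernel (same length)
hrf_derivative <- function(h, dt) {
  c(diff(h), 0) / dt
}
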