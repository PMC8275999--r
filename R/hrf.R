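#' Specification of the canonical haemodynamic response basis
#'
#' The canonical HRF is the conventional difference of two gamma densities:
#' a positive response peaking a few seconds after stimulus onset followed by
#' a smaller, later undershoot. All timing parameters are in seconds.
#'
#' @param sampling_dt Sampling interval of the kernel (s). For design
#'   construction this should be the microtime resolution, i.e. `TR /
#'   microtime_bins`.
#' @param peak_delay Delay of the response peak (s).
#' @param undershoot_delay Delay of the undershoot (s).
#' @param peak_dispersion,undershoot_dispersion Dispersions (s) of the two
#'   gamma components.
#' @param peak_undershoot_ratio Ratio of peak to undershoot amplitude.
#' @param length Total kernel support (s).
#' @param include_time_derivative Should the temporal derivative be part of
#'   the basis set?
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(sampling_dt = 0.15625,
                     peak_delay = 6,
                     undershoot_delay = 16,
                     peak_dispersion = 1,
                     undershoot_dispersion = 1,
                     peak_undershoot_ratio = 6,
                     length = 32,
                     include_time_derivative = TRUE) {
  stopifnot(sampling_dt > 0, length > 0,
            peak_dispersion > 0, undershoot_dispersion > 0,
            peak_delay > 0, undershoot_delay > 0,
            peak_undershoot_ratio > 0)
  structure(list(sampling_dt = sampling_dt,
                 peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 length = length,
                 include_time_derivative = include_time_derivative),
            class = "hrf_spec")
}

#' Sample the canonical HRF (and its temporal derivative)
#'
#' Evaluates the double-gamma kernel on the grid `seq(0, length,
#' by = sampling_dt)`. The kernel is normalised to unit peak, so that (with
#' Riemann-sum convolution, as used in the design builder) a brief
#' unit-amplitude event of about a second produces a response of roughly
#' unit height, and a sustained unit boxcar plateaus at the kernel integral
#' `sum(hrf) * sampling_dt`. The temporal derivative is the backward finite
#' difference of the sampled kernel divided by the step (first element 0);
#' its integral is essentially zero because the kernel decays to zero.
#'
#' @param spec An [hrf_spec()].
#' @return A list with `time`, `hrf`, and (if requested) `dhrf` vectors.
#' @export
canonical_hrf <- function(spec = hrf_spec()) {
  stopifnot(inherits(spec, "hrf_spec"))
  tt <- seq(0, spec$length, by = spec$sampling_dt)
  peak <- stats::dgamma(tt, shape = spec$peak_delay / spec$peak_dispersion,
                        scale = spec$peak_dispersion)
  under <- stats::dgamma(tt, shape = spec$undershoot_delay / spec$undershoot_dispersion,
                         scale = spec$undershoot_dispersion)
  h <- peak - under / spec$peak_undershoot_ratio
  h <- h / max(h)
  out <- list(time = tt, hrf = h)
  if (isTRUE(spec$include_time_derivative)) {
    out$dhrf <- c(0, diff(h)) / spec$sampling_dt
  }
  out
}
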