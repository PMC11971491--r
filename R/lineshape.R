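#' Global lineshape envelope
#'
#' Time-domain envelope implementing the global (B0-inhomogeneity) lineshape
#' shared by all basis signals. At `asymmetry = 0` it is the pure Gaussian
#' `exp(-t^2 (pi * fwhm)^2 / (4 log 2))`, whose frequency-domain full width at
#' half maximum equals `fwhm_hz` exactly. For `asymmetry != 0` the lineshape
#' is a Gaussian whose width varies sigmoidally across the peak (the
#' asymmetric-Gaussian construction of Stancik-Brauns type): the kernel is
#' built in the frequency domain with width
#' `w(v) = 2 * fwhm / (1 + exp(-a * v))`, normalized to unit area (so the
#' time-domain envelope is 1 at t = 0) and converted to a time-domain
#' multiplier. As `a -> 0` this reduces continuously to the symmetric
#' Gaussian.
#'
#' @param fwhm_hz Frequency-domain FWHM in Hz (>= 0).
#' @param asymmetry Asymmetry parameter `a_g`; 0 gives a symmetric Gaussian.
#' @param acq An [acq_params()].
#' @return Complex vector of length `n_points` (real-valued for any
#'   `asymmetry`, returned complex for uniformity).
#' @export
lineshape_envelope <- function(fwhm_hz, asymmetry, acq) {
  stopifnot(fwhm_hz >= 0)
  tvec <- time_axis(acq)
  if (fwhm_hz == 0) return(as.complex(rep(1, acq$n_points)))
  if (asymmetry == 0) {
    return(as.complex(exp(-tvec^2 * (pi * fwhm_hz)^2 / (4 * log(2)))))
  }
  n <- acq$n_points
  # evaluate the kernel's continuous Fourier transform at the FID sample
  # times via an oversampled frequency grid (time axis stays k/fs for the
  # first n points of the length-m inverse transform; the periodic image is
  # pushed m/n FID durations away, so the envelope is effectively one-sided)
  m <- 8L * n
  f <- c(0:(m %/% 2 - 1), -(m %/% 2):-1) * acq$sampling_frequency_hz / m
  w <- 2 * fwhm_hz / (1 + exp(-asymmetry * f))
  K <- exp(-4 * log(2) * f^2 / w^2)
  K[w == 0] <- 0
  K <- K / sum(K)
  env <- stats::fft(K, inverse = TRUE)[seq_len(n)]  # env[1] = sum(K) = 1
  env
}

#' Apply per-signal and global modifications to a basis set
#'
#' Multiplies each basis FID in the time domain by the global lineshape
#' envelope and by `exp((2i pi (f0 + f_i) - pi d_i) t)`, where `f_i` is the
#' individual frequency shift (Hz), `d_i >= 0` the individual Lorentzian
#' damping (Hz), and `f0` a global frequency shift. The zero-order phase is
#' applied as a uniform complex rotation.
#'
#' @param basis A [basis_set()].
#' @param p A [fit_parameters()].
#' @return A modified [basis_set()].
#' @export
#' @examples
#' b <- default_basis(acq_params())
#' p <- fit_parameters(n_signals = length(b))
#' identical_b <- apply_modification(b, p)  # identity at the null parameters
apply_modification <- function(basis, p) {
  nb <- length(basis)
  stopifnot(length(p$shifts_hz) == nb, length(p$broadenings_hz) == nb)
  if (any(p$broadenings_hz < 0)) stop("broadenings_hz must be >= 0")
  acq <- basis$acq
  tvec <- time_axis(acq)
  env <- lineshape_envelope(p$lineshape_fwhm_hz, p$asymmetry, acq) *
    exp(1i * p$phase0_rad + 2i * pi * p$global_shift_hz * tvec)
  signals <- lapply(seq_len(nb), function(i) {
    s <- basis$signals[[i]]
    mod <- exp((2i * pi * p$shifts_hz[i] - pi * p$broadenings_hz[i]) * tvec)
    basis_signal(s$name, s$fid * env * mod, acq)
  })
  basis_set(signals)
}

#' Nonlinear fit parameters
#'
#' All nonlinear parameters of the spectral model: zero-order phase, global
#' frequency shift, per-signal frequency shifts and Lorentzian damping
#' factors, and the two global lineshape parameters (Gaussian FWHM and
#' asymmetry).
#'
#' @param phase0_rad Zero-order phase (radians).
#' @param global_shift_hz Global frequency shift `f0` (Hz).
#' @param shifts_hz Per-signal shifts `f_i` (Hz).
#' @param broadenings_hz Per-signal Lorentzian damping `d_i` (Hz, >= 0).
#' @param lineshape_fwhm_hz Global Gaussian FWHM (Hz).
#' @param asymmetry Global lineshape asymmetry `a_g`.
#' @param n_signals Convenience: build null parameters for this many signals.
#' @return An object of class `fit_parameters`.
#' @export
fit_parameters <- function(n_signals = NULL,
                           phase0_rad = 0, global_shift_hz = 0,
                           shifts_hz = NULL, broadenings_hz = NULL,
                           lineshape_fwhm_hz = 0, asymmetry = 0) {
  if (is.null(shifts_hz)) shifts_hz <- rep(0, n_signals)
  if (is.null(broadenings_hz)) broadenings_hz <- rep(0, length(shifts_hz))
  stopifnot(length(shifts_hz) == length(broadenings_hz))
  if (any(broadenings_hz < 0)) stop("broadenings_hz must be >= 0")
  structure(list(phase0_rad = phase0_rad, global_shift_hz = global_shift_hz,
                 shifts_hz = shifts_hz, broadenings_hz = broadenings_hz,
                 lineshape_fwhm_hz = lineshape_fwhm_hz,
                 asymmetry = asymmetry),
            class = "fit_parameters")
}
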