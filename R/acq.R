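#' Acquisition parameters
#'
#' Container for the acquisition metadata attached to every spectrum and basis
#' signal: transmitter (Larmor) frequency, sampling frequency, number of
#' complex time-domain points, the ppm value assigned to the spectral center
#' and the echo time.
#'
#' @param transmitter_frequency_hz Transmitter frequency F0 in Hz
#'   (e.g. 127.8e6 at 3 Tesla).
#' @param sampling_frequency_hz Temporal sampling frequency in Hz.
#' @param n_points Number of complex FID points.
#' @param ppm_reference Chemical shift (ppm) assigned to the zero-frequency
#'   bin of the spectrum. Defaults to 4.65, placing water on-center.
#' @param echo_time_s Echo time in seconds.
#'
#' @return An object of class `acq_params`.
#' @export
#' @examples
#' acq <- acq_params()
#' hzpppm(acq)  # Hz per ppm, F0 * 1e-6
acq_params <- function(transmitter_frequency_hz = 127.8e6,
                       sampling_frequency_hz = 2000,
                       n_points = 1024,
                       ppm_reference = 4.65,
                       echo_time_s = 0.028) {
  stopifnot(transmitter_frequency_hz > 0, sampling_frequency_hz > 0,
            n_points >= 2)
  structure(list(transmitter_frequency_hz = transmitter_frequency_hz,
                 sampling_frequency_hz = sampling_frequency_hz,
                 n_points = as.integer(n_points),
                 ppm_reference = ppm_reference,
                 echo_time_s = echo_time_s),
            class = "acq_params")
}

#' @rdname acq_params
#' @param acq An `acq_params` object.
#' @export
hzpppm <- function(acq) acq$transmitter_frequency_hz * 1e-6

#' Time axis of the FID
#'
#' First sample at t = 0 (the echo center for simulated data, so no
#' first-order phase is present).
#'
#' @param acq An `acq_params` object.
#' @return Numeric vector of length `n_points`, in seconds.
#' @export
time_axis <- function(acq) {
  (seq_len(acq$n_points) - 1) / acq$sampling_frequency_hz
}

#' Chemical-shift axis of the spectrum
#'
#' Returns the ppm value of each spectral bin in display order (high to low
#' ppm). Bin frequency offsets run from -fs/2 to +fs/2 - fs/N; the ppm value
#' of a bin at offset f is `ppm_reference - f / (F0 * 1e-6)`, so the
#' zero-frequency bin maps exactly to `ppm_reference`.
#'
#' @param acq An `acq_params` object.
#' @return Numeric vector of length `n_points`, strictly decreasing.
#' @export
#' @examples
#' ax <- ppm_axis(acq_params())
#' ax[513]  # zero-frequency bin -> 4.65
ppm_axis <- function(acq) {
  n <- acq$n_points
  f <- (seq_len(n) - 1 - n %/% 2) * acq$sampling_frequency_hz / n
  acq$ppm_reference - f / hzpppm(acq)
}

#' MRS spectrum
#'
#' A spectrum is stored canonically as a complex time-domain FID plus its
#' acquisition parameters; frequency-domain views are derived on demand with
#' [spec_fd()].
#'
#' @param fid Complex vector of length `acq$n_points`.
#' @param acq An `acq_params` object.
#' @param id Text label.
#' @return An object of class `mrs_spectrum`.
#' @export
mrs_spectrum <- function(fid, acq, id = "") {
  fid <- as.complex(fid)
  if (length(fid) != acq$n_points)
    stop("length(fid) must equal acq$n_points")
  structure(list(fid = fid, acq = acq, id = id), class = "mrs_spectrum")
}

#' Frequency-domain view of a spectrum
#'
#' Single discrete Fourier transform of the FID, reordered so bins match
#' [ppm_axis()] (zero frequency at the center).
#'
#' @param x An `mrs_spectrum` or a complex FID vector.
#' @param acq Required when `x` is a bare vector.
#' @return Complex vector in ppm-axis order.
#' @export
spec_fd <- function(x, acq = NULL) {
  fid <- if (inherits(x, "mrs_spectrum")) x$fid else as.complex(x)
  n <- length(fid)
  sp <- stats::fft(fid)
  # reorder: fft bin k holds offset k*fs/n (aliased); center the zero bin
  idx <- c((n %/% 2 + 1):n, 1:(n %/% 2))
  sp[idx]
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum '%s': %d pts, fs %.0f Hz, F0 %.4f MHz>\n",
              x$id, x$acq$n_points, x$acq$sampling_frequency_hz,
              x$acq$transmitter_frequency_hz / 1e6))
  invisible(x)
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("<acq_params: F0 %.4f MHz, fs %.0f Hz, %d pts, ref %.2f ppm, TE %.0f ms>\n",
              x$transmitter_frequency_hz / 1e6, x$sampling_frequency_hz,
              x$n_points, x$ppm_reference, x$echo_time_s * 1000))
  invisible(x)
}

# indices (in ppm-axis order) of bins whose ppm lies inside [lo, hi]
ppm_indices <- function(acq, range_ppm) {
  ax <- ppm_axis(acq)
  which(ax >= min(range_ppm) & ax <= max(range_ppm))
}
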