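#' Synthetic benchmark configuration
#'
#' Parameters of the synthetic MRS benchmark: per-signal random frequency
#' shifts (SD 0.004 ppm, zero mean) and Lorentzian broadenings (mean
#' 0.78 Hz, SD 0.156 Hz), drawn from a normal or a matched uniform
#' distribution (95 percent confidence-interval limits), a 4 Hz global
#' Gaussian broadening, and complex noise targeting the requested spectral
#' SNR values.
#'
#' @param n_spectra Spectra per SNR regime.
#' @param snr_targets Target SNR values.
#' @param distribution "normal" or "uniform" perturbation distribution.
#' @param shift_sd_ppm SD of per-signal frequency shifts (ppm).
#' @param broadening_mean_hz Mean per-signal Lorentzian broadening (Hz).
#' @param broadening_sd_hz SD of per-signal broadening (Hz).
#' @param global_gaussian_fwhm_hz Global Gaussian lineshape FWHM (Hz).
#' @param master_seed Integer master seed; per-spectrum seeds are derived
#'   deterministically from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_spectra = 1000,
                         snr_targets = c(10, 30, 60, 100),
                         distribution = c("normal", "uniform"),
                         shift_sd_ppm = 0.004,
                         broadening_mean_hz = 0.78,
                         broadening_sd_hz = 0.156,
                         global_gaussian_fwhm_hz = 4,
                         master_seed = 1) {
  distribution <- match.arg(distribution)
  stopifnot(n_spectra >= 1, shift_sd_ppm >= 0, broadening_sd_hz >= 0)
  structure(list(n_spectra = as.integer(n_spectra),
                 snr_targets = snr_targets, distribution = distribution,
                 shift_sd_ppm = shift_sd_ppm,
                 broadening_mean_hz = broadening_mean_hz,
                 broadening_sd_hz = broadening_sd_hz,
                 global_gaussian_fwhm_hz = global_gaussian_fwhm_hz,
                 master_seed = as.integer(master_seed)),
            class = "synth_config")
}

#' Convert an LCModel relaxation default to an expected broadening in Hz
#'
#' Scales the dimensionless LCModel relaxation defaults (DEEXT2 for the
#' expectation, DESDT2 for the SD) to a Lorentzian broadening in Hz at the
#' working field, using the square-root field scaling relative to the
#' 85.15 Hz/ppm reference field: `value * sqrt(hzpppm / 85.15) / pi`.
#'
#' @param value The LCModel default (e.g. 2.0 or 0.4).
#' @param hzpppm Working field in Hz/ppm (F0 x 1e-6), e.g. 127.8.
#' @return Broadening in Hz (0.78 for 2.0 at 127.8; 0.156 for 0.4).
#' @export
#' @examples
#' expected_broadening(2.0, 127.8)  # ~0.78
#' expected_broadening(0.4, 127.8)  # ~0.156
expected_broadening <- function(value, hzpppm) {
  stopifnot(value > 0, hzpppm > 0)
  value * sqrt(hzpppm / 85.15) / pi
}

#' Ground-truth record for one synthetic spectrum
#'
#' @param concentrations_mm Named concentrations (mM), keys = basis names.
#' @param shifts_hz Named per-signal shifts (Hz).
#' @param broadenings_hz Named per-signal broadenings (Hz, >= 0).
#' @param noise_sd Frequency-domain (real channel) noise SD.
#' @param seed Integer seed the random draws came from.
#' @param id Spectrum label.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(concentrations_mm, shifts_hz, broadenings_hz,
                         noise_sd = 0, seed = NA_integer_, id = "") {
  stopifnot(identical(sort(names(concentrations_mm)), sort(names(shifts_hz))),
            identical(sort(names(shifts_hz)), sort(names(broadenings_hz))),
            all(broadenings_hz >= 0))
  structure(list(concentrations_mm = concentrations_mm,
                 shifts_hz = shifts_hz, broadenings_hz = broadenings_hz,
                 noise_sd = noise_sd, seed = seed, id = id),
            class = "ground_truth")
}

#' Draw per-signal frequency and broadening perturbations
#'
#' Normal variant: shifts ~ N(0, (shift_sd_ppm x F0 x 1e-6)^2) Hz,
#' broadenings ~ N(mean, sd^2) truncated at zero. Uniform variant: both
#' uniform over the 95 percent confidence interval of the normal
#' (+/- 1.96 sd around the mean). One independent draw per basis signal;
#' reproducible from `seed`.
#'
#' @param cfg A [synth_config()].
#' @param basis_names Character vector of signal names.
#' @param seed Integer seed.
#' @param acq An [acq_params()] (for the ppm-to-Hz conversion).
#' @return List with named `shifts_hz` and `broadenings_hz`.
#' @export
draw_signal_perturbations <- function(cfg, basis_names, seed,
                                      acq = acq_params()) {
  set.seed(seed)
  n <- length(basis_names)
  sd_hz <- cfg$shift_sd_ppm * hzpppm(acq)
  if (cfg$distribution == "normal") {
    shifts <- stats::rnorm(n, 0, sd_hz)
    broad <- pmax(stats::rnorm(n, cfg$broadening_mean_hz,
                               cfg$broadening_sd_hz), 0)
  } else {
    shifts <- stats::runif(n, -1.96 * sd_hz, 1.96 * sd_hz)
    broad <- stats::runif(n,
                          cfg$broadening_mean_hz - 1.96 * cfg$broadening_sd_hz,
                          cfg$broadening_mean_hz + 1.96 * cfg$broadening_sd_hz)
    broad <- pmax(broad, 0)
  }
  list(shifts_hz = stats::setNames(shifts, basis_names),
       broadenings_hz = stats::setNames(broad, basis_names))
}

#' Synthesize one spectrum from a ground-truth record
#'
#' Applies the per-signal shifts and broadenings (same time-domain mechanics
#' as [apply_modification()]), scales by the concentrations, sums, applies
#' the global Gaussian envelope, and adds complex white Gaussian noise whose
#' frequency-domain real-channel SD equals `truth$noise_sd` (the noise draw
#' is seeded from `truth$seed` so the record reproduces the spectrum
#' exactly).
#'
#' @param basis A [basis_set()].
#' @param truth A [ground_truth()] whose keys match the basis names.
#' @param cfg A [synth_config()].
#' @return An [mrs_spectrum()].
#' @export
synthesize_spectrum <- function(basis, truth, cfg = synth_config()) {
  if (!setequal(names(truth$concentrations_mm), basis$names))
    stop("ground-truth keys must match basis names")
  acq <- basis$acq
  p <- fit_parameters(
    shifts_hz = unname(truth$shifts_hz[basis$names]),
    broadenings_hz = unname(truth$broadenings_hz[basis$names]),
    lineshape_fwhm_hz = cfg$global_gaussian_fwhm_hz)
  mod <- apply_modification(basis, p)
  amps <- truth$concentrations_mm[basis$names]
  fid <- Reduce(`+`, Map(function(s, a) a * s$fid, mod$signals, amps))
  if (truth$noise_sd > 0) {
    if (!is.na(truth$seed)) set.seed(noise_seed(truth$seed))
    n <- acq$n_points
    sd_t <- truth$noise_sd / sqrt(n)
    fid <- fid + complex(real = stats::rnorm(n, 0, sd_t),
                         imaginary = stats::rnorm(n, 0, sd_t))
  }
  mrs_spectrum(fid, acq, id = truth$id)
}

# derived noise-stream seed, kept below 2^31
noise_seed <- function(seed) (seed %% 2^29) + 2^29

#' Measure the spectral SNR
#'
#' Maximum of the real spectrum divided by the SD of the real spectrum over
#' a signal-free region.
#'
#' @param s An [mrs_spectrum()].
#' @param noise_region_ppm Signal-free interval (ppm).
#' @return SNR value (`Inf` for a noiseless spectrum).
#' @export
measure_snr <- function(s, noise_region_ppm = c(9.5, 10.5)) {
  re <- Re(spec_fd(s))
  idx <- ppm_indices(s$acq, noise_region_ppm)
  nsd <- stats::sd(re[idx])
  snr <- max(re) / nsd
  # on noise-free data the "noise" region holds only FID-truncation leakage;
  # ratios beyond any physical regime are flagged as infinite
  if (!is.finite(snr) || snr > 1e5) return(Inf)
  snr
}

#' Water reference spectrum
#'
#' A singlet at 4.65 ppm with a 4 Hz Gaussian lineshape and amplitude
#' `wconc * atth2o` (25116 at the defaults), matching the default
#' water-scaling assumptions so that unit basis amplitude maps to 1 mM.
#'
#' @param acq An [acq_params()].
#' @param wconc Assumed water concentration constant (mM).
#' @param atth2o Water attenuation factor.
#' @param fwhm_hz Gaussian FWHM (Hz).
#' @return An [mrs_spectrum()].
#' @export
water_reference <- function(acq = acq_params(), wconc = 35880, atth2o = 0.7,
                            fwhm_hz = 4) {
  sig <- parametric_signal("water", data.frame(
    ppm = acq$ppm_reference, amplitude = wconc * atth2o,
    fwhm_hz = fwhm_hz, shape = "gaussian"))
  mrs_spectrum(simulate_parametric(sig, acq)$fid, acq, id = "water")
}

#' Water amplitude of a reference spectrum
#'
#' The real part of the first FID point (the integral of the spectrum over
#' the full bandwidth), exact for the noiseless reference singlet.
#'
#' @param s An [mrs_spectrum()].
#' @return Amplitude estimate.
#' @export
water_amplitude <- function(s) Re(s$fid[1])

#' Generate a synthetic benchmark dataset
#'
#' `n_spectra` spectra per SNR regime with per-spectrum seeds derived
#' deterministically from the master seed, plus the water reference and the
#' ground-truth ledger.
#'
#' @param cfg A [synth_config()].
#' @param basis A [basis_set()]; defaults to [default_basis()].
#' @param concentrations Named concentration vector (mM); defaults to the
#'   benchmark values in [default_concentrations()].
#' @return List with `spectra` (list of [mrs_spectrum()]), `truths` (list of
#'   [ground_truth()]), `water` ([mrs_spectrum()]) and `snr` (numeric vector
#'   of the target SNR of each spectrum).
#' @export
generate_dataset <- function(cfg = synth_config(),
                             basis = default_basis(),
                             concentrations = default_concentrations()) {
  acq <- basis$acq
  conc <- concentrations[basis$names]
  if (anyNA(conc)) stop("concentrations must cover every basis name")
  base_seed <- cfg$master_seed %% 2^28
  spectra <- list(); truths <- list(); snr_of <- numeric(0)
  k <- 0L
  for (snr in cfg$snr_targets) {
    for (j in seq_len(cfg$n_spectra)) {
      k <- k + 1L
      seed <- base_seed + k
      pert <- draw_signal_perturbations(cfg, basis$names, seed, acq)
      # noiseless maximum determines the noise level for this spectrum
      truth0 <- ground_truth(conc, pert$shifts_hz, pert$broadenings_hz,
                             noise_sd = 0, seed = seed)
      clean <- synthesize_spectrum(basis, truth0, cfg)
      max_re <- max(Re(spec_fd(clean)))
      truth <- ground_truth(conc, pert$shifts_hz, pert$broadenings_hz,
                            noise_sd = max_re / snr, seed = seed,
                            id = sprintf("snr%g_%04d", snr, j))
      spectra[[k]] <- synthesize_spectrum(basis, truth, cfg)
      truths[[k]] <- truth
      snr_of[k] <- snr
    }
  }
  list(spectra = spectra, truths = truths,
       water = water_reference(acq), snr = snr_of)
}

#' Read or write the ground-truth ledger as CSV
#'
#' One row per spectrum x signal: id, name, concentration_mm, shift_hz,
#' broadening_hz, noise_sd, seed.
#'
#' @param truths List of [ground_truth()] records.
#' @param path CSV file path.
#' @return `write_truth_csv()` returns `path`; `read_truth_csv()` a list of
#'   [ground_truth()] records.
#' @export
write_truth_csv <- function(truths, path) {
  rows <- do.call(rbind, lapply(truths, function(tr) {
    nm <- names(tr$concentrations_mm)
    data.frame(id = tr$id, name = nm,
               concentration_mm = unname(tr$concentrations_mm),
               shift_hz = unname(tr$shifts_hz[nm]),
               broadening_hz = unname(tr$broadenings_hz[nm]),
               noise_sd = tr$noise_sd, seed = tr$seed)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, factor(df$id, levels = unique(df$id))), function(d) {
    ground_truth(stats::setNames(d$concentration_mm, d$name),
                 stats::setNames(d$shift_hz, d$name),
                 stats::setNames(d$broadening_hz, d$name),
                 noise_sd = d$noise_sd[1], seed = d$seed[1], id = d$id[1])
  })
}
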