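#' Read and write NIfTI-MRS files
#'
#' Stores spectra in the NIfTI-MRS layout: a single spatial voxel
#' (1 x 1 x 1), the complex FID along the fourth dimension (dwell time in
#' `pixdim[4]`), and repeated spectra (dynamics) along the fifth dimension.
#' Acquisition metadata travels in the standard JSON header extension
#' (ecode 44): `SpectrometerFrequency` (MHz), `ResonantNucleus`, `EchoTime`
#' (s), plus `ChemicalShiftReference` (ppm of the spectral center).
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_nifti_mrs()` returns a list of [mrs_spectrum()] objects (one
#'   per dynamic); `write_nifti_mrs()` returns `path` invisibly.
#' @export
read_nifti_mrs <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  dat <- as.array(img)
  if (!is.complex(dat))
    stop("NIfTI-MRS format error: data are not complex (field 'datatype')")
  dm <- dim(dat)
  if (length(dm) < 4 || any(dm[1:3] != 1))
    stop("NIfTI-MRS format error: expected a 1x1x1 spatial grid (field 'dim')")
  dwell <- hdr$pixdim[5]  # pixdim[4] in NIfTI numbering (element 5 incl. qfac)
  if (!is.finite(dwell) || dwell <= 0)
    stop("NIfTI-MRS format error: missing or non-positive dwell time (field 'pixdim[4]')")
  ext <- RNifti::extension(img, 44, "character")
  if (is.null(ext))
    stop("NIfTI-MRS format error: missing JSON header extension (field 'ecode 44')")
  meta <- jsonlite::fromJSON(ext)
  if (is.null(meta$SpectrometerFrequency))
    stop("NIfTI-MRS format error: missing field 'SpectrometerFrequency'")
  acq <- acq_params(
    transmitter_frequency_hz = meta$SpectrometerFrequency[[1]] * 1e6,
    sampling_frequency_hz = 1 / dwell,
    n_points = dm[4],
    ppm_reference = if (!is.null(meta$ChemicalShiftReference))
      meta$ChemicalShiftReference else 4.65,
    echo_time_s = if (!is.null(meta$EchoTime)) meta$EchoTime else 0)
  ndyn <- if (length(dm) >= 5) dm[5] else 1L
  ids <- meta$SpectrumIDs
  if (is.null(ids) || length(ids) != ndyn) ids <- sprintf("dyn%04d", seq_len(ndyn))
  lapply(seq_len(ndyn), function(k) {
    fid <- if (length(dm) >= 5) dat[1, 1, 1, , k] else dat[1, 1, 1, ]
    mrs_spectrum(fid, acq, id = ids[k])
  })
}

#' @rdname read_nifti_mrs
#' @param spectra A single [mrs_spectrum()] or a list of them sharing
#'   acquisition parameters.
#' @export
write_nifti_mrs <- function(spectra, path) {
  if (inherits(spectra, "mrs_spectrum")) spectra <- list(spectra)
  if (length(spectra) == 0) stop("no spectra to write")
  acq <- spectra[[1]]$acq
  for (s in spectra)
    if (!identical(unclass(s$acq)[1:4], unclass(acq)[1:4]))
      stop("mixed acquisition parameters across spectra")
  n <- acq$n_points
  ndyn <- length(spectra)
  dat <- array(complex(real = 0), dim = c(1, 1, 1, n, ndyn))
  for (k in seq_len(ndyn)) dat[1, 1, 1, , k] <- spectra[[k]]$fid
  if (ndyn == 1) dim(dat) <- c(1, 1, 1, n)
  dwell <- 1 / acq$sampling_frequency_hz
  img <- RNifti::asNifti(dat, RNifti::niftiHeader(
    list(pixdim = c(-1, 1, 1, 1, dwell, 1, 1, 1))))
  meta <- list(SpectrometerFrequency = acq$transmitter_frequency_hz / 1e6,
               ResonantNucleus = "1H",
               EchoTime = acq$echo_time_s,
               ChemicalShiftReference = acq$ppm_reference,
               SpectrumIDs = vapply(spectra, `[[`, character(1), "id"))
  RNifti::extension(img, 44) <- jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                 digits = NA)
  RNifti::writeNifti(img, path)
  invisible(path)
}
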