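#' Parametric (lineshape-model) basis signals
#'
#' Broad lipid and macromolecule resonances, and simple singlets, are modeled
#' as sums of damped complex exponentials rather than simulated spin systems.
#' Lorentzian components decay as `exp(-pi * fwhm * t)` (frequency-domain
#' FWHM = `fwhm_hz`); Gaussian components as
#' `exp(-t^2 * (pi * fwhm)^2 / (4 log 2))`, the same convention as the global
#' lineshape model.
#'
#' @param name Signal label.
#' @param components Data frame (or list coercible to one) with columns
#'   `ppm`, `amplitude`, `fwhm_hz`, `shape` ("lorentzian" or "gaussian").
#' @return `parametric_signal()` returns a `parametric_signal` object.
#' @export
parametric_signal <- function(name, components) {
  components <- as.data.frame(components)
  stopifnot(all(c("ppm", "amplitude", "fwhm_hz", "shape") %in%
                names(components)))
  if (any(components$fwhm_hz <= 0)) stop("fwhm_hz must be > 0")
  if (!all(components$shape %in% c("lorentzian", "gaussian")))
    stop("shape must be 'lorentzian' or 'gaussian'")
  structure(list(name = name, components = components),
            class = "parametric_signal")
}

#' @rdname parametric_signal
#' @param sig A `parametric_signal`.
#' @param acq An [acq_params()].
#' @return `simulate_parametric()` returns a [basis_signal()].
#' @export
simulate_parametric <- function(sig, acq) {
  tvec <- time_axis(acq)
  fid <- complex(acq$n_points)
  for (k in seq_len(nrow(sig$components))) {
    cmp <- sig$components[k, ]
    f <- (acq$ppm_reference - cmp$ppm) * hzpppm(acq)
    env <- if (cmp$shape == "lorentzian") exp(-pi * cmp$fwhm_hz * tvec)
           else exp(-tvec^2 * (pi * cmp$fwhm_hz)^2 / (4 * log(2)))
    fid <- fid + cmp$amplitude * exp(2i * pi * f * tvec) * env
  }
  basis_signal(sig$name, fid, acq)
}
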