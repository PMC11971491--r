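#' Basis signal and basis set containers
#'
#' A basis signal is a named reference FID sharing acquisition parameters with
#' the spectra it will be fitted to. A basis set is an ordered, uniquely named
#' collection of basis signals with consistent acquisition parameters.
#'
#' Amplitude convention: basis FIDs are normalized so that the first FID point
#' equals the number of contributing protons; under the water-scaling defaults
#' of the synthetic benchmark (water amplitude = WCONC * ATTH2O = 25116) a
#' unit fitted amplitude then corresponds to 1 mM.
#'
#' @param name Signal name (e.g. "NAA").
#' @param fid Complex FID vector.
#' @param acq An `acq_params` object.
#' @return `basis_signal()` returns a `basis_signal`; `basis_set()` a
#'   `basis_set`.
#' @export
basis_signal <- function(name, fid, acq) {
  fid <- as.complex(fid)
  if (length(fid) != acq$n_points)
    stop("length(fid) must equal acq$n_points")
  structure(list(name = name, fid = fid, acq = acq), class = "basis_signal")
}

#' @rdname basis_signal
#' @param signals List of `basis_signal` objects.
#' @export
basis_set <- function(signals) {
  stopifnot(length(signals) >= 1)
  nm <- vapply(signals, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("basis signal names must be unique")
  acq0 <- signals[[1]]$acq
  for (s in signals) {
    if (!identical(unclass(s$acq)[c(1, 2, 3)], unclass(acq0)[c(1, 2, 3)]))
      stop("inconsistent acquisition parameters across basis signals")
  }
  structure(list(signals = signals, names = nm, acq = acq0),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set: %d signals [%s%s]>\n", length(x$signals),
              paste(utils::head(x$names, 5), collapse = ", "),
              if (length(x$names) > 5) ", ..." else ""))
  invisible(x)
}

#' @export
length.basis_set <- function(x) length(x$signals)

# basis FIDs as an n_points x n_signals complex matrix
basis_matrix <- function(basis) {
  vapply(basis$signals, function(s) s$fid,
         complex(basis$acq$n_points))
}
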