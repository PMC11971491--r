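#' Default 29-signal brain basis set
#'
#' Builds the standard basis used by the synthetic benchmark: 19 metabolites
#' simulated as spin systems (ideal-pulse semi-LASER, TE1/TE2/TE3 =
#' 8/11/9 ms by default), plus the inverted -CrCH2 singlet, 4 lipid and
#' 5 macromolecule parametric signals. Spin and lineshape parameters are read
#' from editable JSON files shipped in `inst/extdata/`.
#'
#' @param acq An [acq_params()]; its `echo_time_s` is split into the three
#'   semi-LASER partitions via `te_partitions_s`.
#' @param te_partitions_s Echo-time partitions in seconds.
#' @return A [basis_set()] with 29 signals.
#' @export
#' @examples
#' b <- default_basis(acq_params())
#' length(b)          # 29
#' b$names[1:3]
default_basis <- function(acq = acq_params(),
                          te_partitions_s = c(0.008, 0.011, 0.009)) {
  key <- paste(acq$transmitter_frequency_hz, acq$sampling_frequency_hz,
               acq$n_points, acq$ppm_reference,
               paste(te_partitions_s, collapse = "-"), sep = "|")
  cached <- .regfit_cache[[key]]
  if (!is.null(cached)) return(cached)

  seq <- seq_spec("semi_laser_ideal", te_partitions_s)
  spin_file <- system.file("extdata", "spin_systems.json", package = "regfit",
                           mustWork = TRUE)
  para_file <- system.file("extdata", "parametric_signals.json",
                           package = "regfit", mustWork = TRUE)
  spin_db <- jsonlite::fromJSON(spin_file, simplifyVector = FALSE)
  para_db <- jsonlite::fromJSON(para_file, simplifyVector = FALSE)

  sim_metab <- function(rec) {
    fid <- complex(acq$n_points)
    for (m in rec$moieties) {
      shifts <- unlist(m$shifts_ppm)
      nsp <- length(shifts)
      J <- matrix(0, nsp, nsp)
      for (trip in m$j_hz) {
        i <- trip[[1]]; j <- trip[[2]]
        J[i, j] <- J[j, i] <- trip[[3]]
      }
      sys <- spin_system(rec$name, shifts, J)
      sig <- simulate_spin_system(sys, seq, acq, scale = m$scale)
      fid <- fid + sig$fid
    }
    basis_signal(rec$name, fid, acq)
  }
  metab <- lapply(spin_db$metabolites, sim_metab)

  para <- lapply(para_db$signals, function(rec) {
    comp <- do.call(rbind, lapply(rec$components, function(cc)
      data.frame(ppm = cc$ppm, amplitude = cc$amplitude,
                 fwhm_hz = cc$fwhm_hz, shape = cc$shape)))
    simulate_parametric(parametric_signal(rec$name, comp), acq)
  })
  para_names <- vapply(para, `[[`, character(1), "name")

  # assemble in the benchmark's canonical order
  metab_names <- vapply(metab, `[[`, character(1), "name")
  ordered <- c(metab[match(setdiff(basis_signal_order(), para_names),
                           metab_names)],
               para[match(intersect(basis_signal_order(), para_names),
                          para_names)])
  ordered <- ordered[order(match(vapply(ordered, `[[`, character(1), "name"),
                                 basis_signal_order()))]
  out <- basis_set(ordered)
  .regfit_cache[[key]] <- out
  out
}

#' Canonical basis signal order and benchmark concentrations
#'
#' The 29 signal names in their canonical order, and the nominal
#' healthy-brain concentrations (mM) used by the synthetic benchmark.
#' Lipid signals and -CrCH2 are present in the basis at zero concentration;
#' macromolecule signals at 4 mM each.
#'
#' @return `basis_signal_order()`: character vector of length 29.
#'   `default_concentrations()`: named numeric vector of length 29.
#' @export
basis_signal_order <- function() {
  c("Ala", "Asp", "Cr", "GABA", "Glc", "Glu", "Gln", "GSH", "GPC", "Gly",
    "Lac", "Ins", "NAA", "NAAG", "PCho", "PCr", "PEth", "sIns", "Tau",
    "-CrCH2", "Lip09", "Lip13a", "Lip13b", "Lip20",
    "MM09", "MM12", "MM14", "MM17", "MM20")
}

#' @rdname basis_signal_order
#' @export
default_concentrations <- function() {
  c(Ala = 0.2, Asp = 1.5, Cr = 5.0, GABA = 1.0, Glc = 1.0, Glu = 10.0,
    Gln = 3.0, GSH = 2.0, GPC = 1.2, Gly = 1.0, Lac = 0.5, Ins = 5.0,
    NAA = 10.0, NAAG = 2.0, PCho = 0.5, PCr = 4.5, PEth = 0.8, sIns = 0.4,
    Tau = 1.5, `-CrCH2` = 0, Lip09 = 0, Lip13a = 0, Lip13b = 0, Lip20 = 0,
    MM09 = 4.0, MM12 = 4.0, MM14 = 4.0, MM17 = 4.0, MM20 = 4.0)
}

#' @rdname basis_signal_order
#' @export
metabolite_names <- function() {
  basis_signal_order()[1:19]
}
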