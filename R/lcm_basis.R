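#' Read and write LCModel .basis files
#'
#' Supports the subset of the FORTRAN-namelist basis format needed for
#' interoperability: a `$SEQPAR` block (`HZPPPM`, `ECHOT`, `SEQ`), a
#' `$BASIS1` block (`BADELT` dwell time, `NDATAB` point count, `FMTBAS`),
#' and one `$BASIS` block per signal followed by the frequency-domain
#' values as "real imaginary" pairs. Signals are converted to the internal
#' time-domain convention on read.
#'
#' @param path File path.
#' @return `read_lcmodel_basis()` returns a [basis_set()];
#'   `write_lcmodel_basis()` returns `path` invisibly.
#' @export
read_lcmodel_basis <- function(path) {
  txt <- readLines(path, warn = FALSE)
  nl_starts <- grep("^\\s*\\$", txt)
  if (length(nl_starts) < 3)
    stop("LCModel basis format error: expected $SEQPAR, $BASIS1 and $BASIS blocks")

  parse_block <- function(lines) {
    body <- paste(lines, collapse = " ")
    body <- sub("^\\s*\\$\\w+", "", body)
    body <- sub("\\$END.*$", "", body)
    out <- list()
    pat <- "([A-Za-z0-9_]+)\\s*=\\s*('[^']*'|[-+0-9.eEdD]+)"
    m <- gregexpr(pat, body, perl = TRUE)[[1]]
    if (m[1] == -1) return(out)
    for (i in seq_along(m)) {
      kv <- regmatches(body, list(m))[[1]][i]
      key <- toupper(sub("\\s*=.*$", "", kv))
      val <- sub("^[^=]*=\\s*", "", kv)
      if (grepl("^'", val)) val <- gsub("'", "", val)
      else val <- as.numeric(gsub("[dD]", "e", val))
      out[[key]] <- val
    }
    out
  }

  # split file into blocks: each starts at $NAME, ends at $END
  ends <- grep("\\$END", txt)
  blocks <- list()
  starts <- setdiff(nl_starts, ends)
  for (s in starts) {
    e <- ends[ends >= s][1]
    if (is.na(e)) stop("LCModel basis format error: unterminated namelist block")
    nm <- toupper(sub("^\\s*\\$(\\w+).*$", "\\1", txt[s]))
    blocks[[length(blocks) + 1]] <- list(name = nm, first = s, last = e,
                                         fields = parse_block(txt[s:e]))
  }
  bn <- vapply(blocks, `[[`, character(1), "name")
  if (!"SEQPAR" %in% bn || !"BASIS1" %in% bn)
    stop("LCModel basis format error: missing $SEQPAR or $BASIS1 header block")
  seqpar <- blocks[[match("SEQPAR", bn)]]$fields
  basis1 <- blocks[[match("BASIS1", bn)]]$fields
  if (is.null(basis1$BADELT) || is.null(basis1$NDATAB) || is.null(seqpar$HZPPPM))
    stop("LCModel basis format error: missing BADELT, NDATAB or HZPPPM")
  n <- as.integer(basis1$NDATAB)
  acq <- acq_params(transmitter_frequency_hz = seqpar$HZPPPM * 1e6,
                    sampling_frequency_hz = 1 / basis1$BADELT,
                    n_points = n,
                    echo_time_s = if (!is.null(seqpar$ECHOT))
                      seqpar$ECHOT / 1000 else 0)

  sig_idx <- which(bn == "BASIS")
  if (length(sig_idx) == 0)
    stop("LCModel basis format error: no $BASIS signal blocks found")
  signals <- vector("list", length(sig_idx))
  for (j in seq_along(sig_idx)) {
    blk <- blocks[[sig_idx[j]]]
    id <- blk$fields$ID
    if (is.null(id)) stop("LCModel basis format error: $BASIS block without ID")
    first_data <- blk$last + 1
    last_data <- if (j < length(sig_idx)) blocks[[sig_idx[j + 1]]]$first - 1
                 else length(txt)
    vals <- suppressWarnings(as.numeric(unlist(
      strsplit(trimws(txt[first_data:last_data]), "\\s+"))))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2 * n)
      stop(sprintf("LCModel basis format error: signal '%s' truncated (%d of %d values)",
                   id, length(vals), 2 * n))
    fd <- complex(real = vals[seq(1, 2 * n, 2)], imaginary = vals[seq(2, 2 * n, 2)])
    # stored in frequency domain (fft of the FID); invert
    fid <- stats::fft(fd, inverse = TRUE) / n
    signals[[j]] <- basis_signal(id, fid, acq)
  }
  basis_set(signals)
}

#' @rdname read_lcmodel_basis
#' @param basis A [basis_set()].
#' @export
write_lcmodel_basis <- function(basis, path) {
  acq <- basis$acq
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w(" $SEQPAR")
  w(" FWHMBA = %.6f,", 0.1 / hzpppm(acq))
  w(" HZPPPM = %.6f,", hzpppm(acq))
  w(" ECHOT = %.2f,", acq$echo_time_s * 1000)
  w(" SEQ = 'SLASER'")
  w(" $END")
  w(" $BASIS1")
  w(" IDBASI = 'regfit',")
  w(" FMTBAS = '(2E15.6)',")
  w(" BADELT = %.9f,", 1 / acq$sampling_frequency_hz)
  w(" NDATAB = %d", acq$n_points)
  w(" $END")
  for (s in basis$signals) {
    w(" $BASIS")
    w(" ID = '%s',", s$name)
    w(" ISHIFT = 0")
    w(" $END")
    fd <- stats::fft(s$fid)
    writeLines(sprintf("%15.6E%15.6E", Re(fd), Im(fd)), con)
  }
  invisible(path)
}
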