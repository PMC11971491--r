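#' Metabolite accuracy record
#'
#' Squared concentration errors for the 19 metabolite signals (lipids,
#' macromolecules and -CrCH2 are excluded from the accuracy metric).
#'
#' @param est Named concentration estimates (mM).
#' @param truth Named true concentrations (mM).
#' @param spectrum_id Label.
#' @param method Fitting method label.
#' @return An object of class `accuracy_record` with elements
#'   `per_metabolite_error` (signed errors, mM) and `sse` (mM^2).
#' @export
sse_metabolites <- function(est, truth, spectrum_id = "", method = "") {
  m <- metabolite_names()
  missing_est <- setdiff(m, names(est))
  if (length(missing_est))
    stop("estimate is missing metabolite(s): ",
         paste(missing_est, collapse = ", "))
  missing_tr <- setdiff(m, names(truth))
  if (length(missing_tr))
    stop("truth is missing metabolite(s): ",
         paste(missing_tr, collapse = ", "))
  err <- est[m] - truth[m]
  structure(list(spectrum_id = spectrum_id, method = method,
                 per_metabolite_error = err, sse = sum(err^2)),
            class = "accuracy_record")
}

#' Compare two sets of accuracy records
#'
#' Relative reduction in the mean squared metabolite error of method b
#' versus method a, `100 * (mean_sse_a - mean_sse_b) / mean_sse_a`, with a
#' Welch two-sample t-test on the per-spectrum SSE distributions.
#'
#' @param a,b Lists of [sse_metabolites()] records, paired by
#'   `spectrum_id`.
#' @param snr Optional SNR label carried into the summary.
#' @return An object of class `comparison_summary`.
#' @export
compare_methods <- function(a, b, snr = NA_real_) {
  ids_a <- vapply(a, `[[`, character(1), "spectrum_id")
  ids_b <- vapply(b, `[[`, character(1), "spectrum_id")
  if (!identical(sort(ids_a), sort(ids_b)))
    stop("record lists are not paired by spectrum_id")
  b <- b[match(ids_a, ids_b)]
  sse_a <- vapply(a, `[[`, numeric(1), "sse")
  sse_b <- vapply(b, `[[`, numeric(1), "sse")
  pv <- if (isTRUE(all.equal(sse_a, sse_b))) 1
        else stats::t.test(sse_a, sse_b, var.equal = FALSE)$p.value
  structure(list(snr = snr,
                 method_a = a[[1]]$method, method_b = b[[1]]$method,
                 mean_sse_a = mean(sse_a), mean_sse_b = mean(sse_b),
                 relative_reduction_pct =
                   100 * (mean(sse_a) - mean(sse_b)) / mean(sse_a),
                 p_value = pv, n = length(sse_a),
                 sse_a = sse_a, sse_b = sse_b),
            class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf(
    "<comparison SNR %s: %s vs %s, mean SSE %.3f vs %.3f, reduction %.1f%%, p = %.3g>\n",
    format(x$snr), x$method_a, x$method_b, x$mean_sse_a, x$mean_sse_b,
    x$relative_reduction_pct, x$p_value))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Mean difference (bias) and 95 percent limits of agreement
#' (bias +/- 1.96 SD of the paired differences) between two sets of
#' concentration estimates.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @param metabolite Label.
#' @return An object of class `bland_altman` with `bias`, `loa_low`,
#'   `loa_high`, plus the per-pair `means` and `differences` for plotting.
#' @export
bland_altman <- function(x, y, metabolite = "") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(metabolite = metabolite, bias = bias,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 means = (x + y) / 2, differences = d),
            class = "bland_altman")
}

#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$means, x$differences, xlab = "Mean of methods (mM)",
       ylab = "Difference (mM)", main = x$metabolite, ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high), lty = 2)
  invisible(x)
}

#' Run the regularization benchmark
#'
#' Generates the synthetic datasets, fits every spectrum under every
#' requested mode, and summarizes accuracy per SNR regime. When both of a
#' mode pair are present, pairwise comparisons are emitted (method a = the
#' earlier mode in `modes`, method b = the later), giving the relative SSE
#' reduction and Welch t-test p-value per SNR.
#'
#' @param cfg A [synth_config()].
#' @param modes Character vector from c("reg", "noreg", "ff").
#' @param basis A [basis_set()].
#' @param verbose Print progress to stderr.
#' @return List with `records` (per mode, list of accuracy records),
#'   `summaries` (list of `comparison_summary`), `mean_sse` (data frame of
#'   mean SSE per mode x SNR) and `fits` (per mode, list of `fit_result`).
#' @export
run_benchmark <- function(cfg = synth_config(n_spectra = 50),
                          modes = c("noreg", "reg"),
                          basis = default_basis(), verbose = FALSE) {
  ds <- generate_dataset(cfg, basis)
  w_amp <- water_amplitude(ds$water)
  records <- stats::setNames(vector("list", length(modes)), modes)
  fits <- stats::setNames(vector("list", length(modes)), modes)
  for (mode in modes) {
    recs <- vector("list", length(ds$spectra))
    fts <- vector("list", length(ds$spectra))
    for (k in seq_along(ds$spectra)) {
      if (verbose && k %% 25 == 1)
        message(sprintf("[%s] fitting spectrum %d/%d", mode, k,
                        length(ds$spectra)))
      ft <- fit_spectrum(ds$spectra[[k]], basis, mode = mode,
                         water_amplitude = w_amp)
      recs[[k]] <- sse_metabolites(ft$concentrations_mm,
                                   ds$truths[[k]]$concentrations_mm,
                                   spectrum_id = ds$truths[[k]]$id,
                                   method = mode)
      fts[[k]] <- ft
    }
    records[[mode]] <- recs
    fits[[mode]] <- fts
  }
  snrs <- unique(ds$snr)
  mean_sse <- do.call(rbind, lapply(modes, function(mode) {
    data.frame(mode = mode, snr = snrs, mean_sse = vapply(snrs, function(s)
      mean(vapply(records[[mode]][ds$snr == s], `[[`, numeric(1), "sse")),
      numeric(1)))
  }))
  summaries <- list()
  if (length(modes) >= 2) {
    for (i in seq_len(length(modes) - 1)) for (j in (i + 1):length(modes)) {
      for (s in snrs) {
        sel <- ds$snr == s
        summaries[[length(summaries) + 1]] <-
          compare_methods(records[[modes[i]]][sel], records[[modes[j]]][sel],
                          snr = s)
      }
    }
  }
  list(records = records, summaries = summaries, mean_sse = mean_sse,
       fits = fits, snr = ds$snr, truths = ds$truths)
}
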