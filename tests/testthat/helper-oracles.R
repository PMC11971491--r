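# Independent oracles and measurement helpers used across the suite.

# Brute-force reference for the partially constrained penalized least-squares
# solve: enumerate every active set of the constrained block, solve the free
# subproblem, keep the best feasible solution.
ref_pnnls <- function(A, y, ncon, P) {
  ntot <- ncol(A); nfree <- ntot - ncon
  best <- NULL
  pen <- function(x) {
    if (nfree == 0) return(0)
    xs <- x[(ncon + 1):ntot]
    drop(t(xs) %*% P %*% xs)
  }
  for (mask in 0:(2^ncon - 1)) {
    on <- which(bitwAnd(mask, 2^(0:(ncon - 1))) > 0)
    cols <- c(on, if (nfree > 0) (ncon + 1):ntot)
    As <- A[, cols, drop = FALSE]
    G <- crossprod(As); b <- crossprod(As, y)
    ii <- which(cols > ncon)
    if (length(ii)) G[ii, ii] <- G[ii, ii] + P
    z <- tryCatch(solve(G, b), error = function(e) NULL)
    if (is.null(z)) next
    if (any(z[seq_along(on)] < -1e-9)) next
    x <- numeric(ntot); x[cols] <- z
    obj <- sum((y - A %*% x)^2) + pen(x)
    if (is.null(best) || obj < best$obj) best <- list(x = x, obj = obj)
  }
  best
}

# Closed-form AB (strongly coupled two-spin) pulse-acquire FID: four lines at
# center +/- (C +/- J)/2 with intensities (1 -/+ J/C)/2, C = sqrt(delta^2+J^2).
ab_fid <- function(delta_a_ppm, delta_b_ppm, j_hz, acq) {
  hz <- regfit::hzpppm(acq)
  va <- (acq$ppm_reference - delta_a_ppm) * hz
  vb <- (acq$ppm_reference - delta_b_ppm) * hz
  ctr <- (va + vb) / 2
  d <- va - vb
  C <- sqrt(d^2 + j_hz^2)
  freqs <- ctr + c((C + j_hz) / 2, (C - j_hz) / 2,
                   -(C - j_hz) / 2, -(C + j_hz) / 2)
  amps <- c(1 - j_hz / C, 1 + j_hz / C, 1 + j_hz / C, 1 - j_hz / C) / 2
  tvec <- regfit::time_axis(acq)
  drop(exp(2i * pi * tvec %o% freqs) %*% amps)
}

# zero-filled real spectrum and matching frequency/ppm axes
zf_spectrum <- function(fid, acq, zf = 16) {
  n <- length(fid); m <- n * zf
  sp <- fft(c(fid, rep(0 + 0i, m - n)))
  idx <- c((m %/% 2 + 1):m, 1:(m %/% 2))
  f <- (seq_len(m) - 1 - m %/% 2) * acq$sampling_frequency_hz / m
  list(re = Re(sp[idx]), f_hz = f,
       ppm = acq$ppm_reference - f / regfit::hzpppm(acq))
}

# location of the spectral maximum (ppm) with parabolic interpolation
peak_ppm <- function(fid, acq, zf = 16) {
  s <- zf_spectrum(fid, acq, zf)
  k <- which.max(s$re)
  if (k > 1 && k < length(s$re)) {
    y <- s$re[(k - 1):(k + 1)]
    sh <- 0.5 * (y[1] - y[3]) / (y[1] - 2 * y[2] + y[3])
  } else sh <- 0
  step <- s$ppm[2] - s$ppm[1]
  s$ppm[k] + sh * step
}

# measured full width at half maximum (Hz) of the dominant peak
measured_fwhm_hz <- function(fid, acq, zf = 16) {
  s <- zf_spectrum(fid, acq, zf)
  k <- which.max(s$re)
  half <- s$re[k] / 2
  iL <- k; while (iL > 1 && s$re[iL] > half) iL <- iL - 1
  iR <- k; while (iR < length(s$re) && s$re[iR] > half) iR <- iR + 1
  interp <- function(i1, i2) {
    s$f_hz[i1] + (half - s$re[i1]) * (s$f_hz[i2] - s$f_hz[i1]) /
      (s$re[i2] - s$re[i1])
  }
  abs(interp(iR - 1, iR) - interp(iL, iL + 1))
}

# shared small fixtures
test_acq <- function() acq_params()

# memoize the default basis across test files
shared_basis <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- default_basis()
    b
  }
})

# one noiseless, perturbation-free benchmark spectrum
clean_spectrum <- function(basis = shared_basis()) {
  conc <- default_concentrations()
  z <- stats::setNames(rep(0, length(basis)), basis$names)
  truth <- ground_truth(conc, z, z, noise_sd = 0, seed = 1, id = "clean")
  synthesize_spectrum(basis, truth, synth_config())
}
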