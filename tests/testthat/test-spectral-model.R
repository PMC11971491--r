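test_that("the null modification is the identity and commutes with scaling", {
  b <- shared_basis()
  p <- fit_parameters(n_signals = length(b))
  out <- apply_modification(b, p)
  for (k in c(1, 13, 29))
    expect_equal(out$signals[[k]]$fid, b$signals[[k]]$fid)
  # amplitude scaling commutes with modification
  p2 <- fit_parameters(n_signals = length(b),
                       shifts_hz = rep(0.7, length(b)),
                       broadenings_hz = rep(1.1, length(b)),
                       lineshape_fwhm_hz = 3)
  scaled <- b
  scaled$signals[[13]]$fid <- 2.5 * b$signals[[13]]$fid
  m1 <- apply_modification(scaled, p2)$signals[[13]]$fid
  m2 <- 2.5 * apply_modification(b, p2)$signals[[13]]$fid
  expect_equal(m1, m2)
})

test_that("individual shifts move peaks and damping broadens them as specified", {
  acq <- test_acq()
  sing <- simulate_parametric(parametric_signal("s", data.frame(
    ppm = 3.0, amplitude = 1, fwhm_hz = 2, shape = "lorentzian")), acq)
  bs <- basis_set(list(sing))
  hz <- hzpppm(acq)
  p <- fit_parameters(n_signals = 1, shifts_hz = 1)
  shifted <- apply_modification(bs, p)$signals[[1]]
  expect_equal((peak_ppm(sing$fid, acq) - peak_ppm(shifted$fid, acq)) * hz,
               1, tolerance = 0.02)
  p <- fit_parameters(n_signals = 1, broadenings_hz = 2)
  broadened <- apply_modification(bs, p)$signals[[1]]
  expect_equal(measured_fwhm_hz(broadened$fid, acq) -
                 measured_fwhm_hz(sing$fid, acq), 2, tolerance = 0.1)
  expect_error(apply_modification(bs, fit_parameters(n_signals = 1,
                                                     broadenings_hz = -1)),
               ">= 0")
})

test_that("cross-correlation recovers applied frequency shifts to 0.01 Hz", {
  acq <- test_acq()
  sing <- simulate_parametric(parametric_signal("s", data.frame(
    ppm = 2.5, amplitude = 1, fwhm_hz = 3, shape = "lorentzian")), acq)
  bs <- basis_set(list(sing))
  hz <- hzpppm(acq)
  for (f in c(-1.3, 0.21, 0.77)) {
    p <- fit_parameters(n_signals = 1, shifts_hz = f)
    shifted <- apply_modification(bs, p)$signals[[1]]
    est <- (peak_ppm(sing$fid, acq, zf = 64) -
              peak_ppm(shifted$fid, acq, zf = 64)) * hz
    expect_equal(est, f, tolerance = 0.01)
  }
})

test_that("the lineshape envelope obeys its width, symmetry and area contracts", {
  acq <- test_acq()
  expect_equal(lineshape_envelope(0, 0, acq), as.complex(rep(1, 1024)))
  env <- lineshape_envelope(4, 0, acq)
  expect_equal(Re(env), exp(-time_axis(acq)^2 * (pi * 4)^2 / (4 * log(2))))
  # measured spectral width of a narrow line broadened by the envelope
  sing <- exp(2i * pi * 100 * time_axis(acq))
  expect_equal(measured_fwhm_hz(sing * env, acq), 4, tolerance = 0.3)
  # asymmetric case: area (first envelope point) preserved to 1e-6
  enva <- lineshape_envelope(4, 0.3, acq)
  expect_lt(abs(enva[1] - 1), 1e-6)
  # a and -a give mirror-image lineshapes about the peak center
  envm <- lineshape_envelope(4, -0.3, acq)
  expect_lt(max(Mod(envm - Conj(enva))), 1e-12)
  # continuous reduction to the symmetric Gaussian as a -> 0
  expect_lt(max(Mod(lineshape_envelope(4, 1e-8, acq) - env)), 1e-6)
})

test_that("the spline basis partitions unity and its penalty kills straight lines", {
  acq <- test_acq()
  bl <- spline_baseline_basis(c(0.2, 4.0), 0.15, acq)
  expect_equal(rowSums(bl$matrix), rep(1, nrow(bl$matrix)))
  # projecting a constant onto the columns leaves ~no residual
  fit <- lm.fit(bl$matrix, rep(1, nrow(bl$matrix)))
  expect_lt(max(abs(fit$residuals)), 1e-10)
  # second-difference penalty vanishes on linear coefficient sequences
  co <- 2 + 0.3 * seq_len(ncol(bl$matrix))
  expect_lt(drop(t(co) %*% bl$penalty %*% co), 1e-10 * sum(co^2))
  # halving the knot spacing approximately doubles the column count
  bl2 <- spline_baseline_basis(c(0.2, 4.0), 0.075, acq)
  expect_equal(ncol(bl2$matrix) / ncol(bl$matrix), 2, tolerance = 0.15)
  expect_error(spline_baseline_basis(c(2, 2.05), 0.15, acq), "narrower")
  expect_error(spline_baseline_basis(c(-20, 4), 0.15, acq), "span")
})

test_that("the design matrix concatenates basis and spline blocks", {
  b <- shared_basis()
  acq <- b$acq
  bl <- spline_baseline_basis(c(0.2, 4.0), 0.15, acq)
  p <- fit_parameters(n_signals = length(b), lineshape_fwhm_hz = 4)
  d <- build_design(b, p, bl)
  expect_identical(ncol(d$columns), 29L + ncol(bl$matrix))
  # a zero basis signal yields a zero column
  b0 <- b
  b0$signals[[5]] <- basis_signal("Glc", complex(acq$n_points), acq)
  d0 <- build_design(b0, p, bl)
  expect_true(all(d0$columns[, 5] == 0))
})

test_that("the forward model reproduces a noiseless spectrum at the true parameters", {
  b <- shared_basis()
  acq <- b$acq
  y <- clean_spectrum(b)
  bl <- spline_baseline_basis(c(0.2, 4.0), 0.15, acq)
  p <- fit_parameters(n_signals = length(b), lineshape_fwhm_hz = 4)
  d <- build_design(b, p, bl)
  yv <- Re(spec_fd(y))[d$indices]
  a <- solve_amplitudes(d, yv)
  conc <- default_concentrations()[b$names]
  nz <- conc > 0
  expect_equal(a[seq_len(29)][nz], unname(conc[nz]), tolerance = 1e-3)
  # baseline stays near zero
  expect_lt(max(abs(d$columns[, -(1:29)] %*% a[-(1:29)])),
            1e-3 * max(abs(yv)))
  # and the reconstruction matches the data
  expect_lt(max(abs(yv - d$columns %*% a)), 1e-6 * max(abs(yv)))
})
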