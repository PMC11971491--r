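test_that("an uncoupled spin precesses freely at its chemical shift", {
  acq <- test_acq()
  sig <- simulate_spin_system(spin_system("s", 2.01),
                              seq_spec("pulse_acquire"), acq)
  expect_equal(peak_ppm(sig$fid, acq), 2.01, tolerance = 1e-3)
  # no relaxation: constant FID magnitude
  expect_lt(diff(range(Mod(sig$fid))), 1e-9)
  expect_equal(Re(sig$fid[1]), 1, tolerance = 1e-9)
})

test_that("weak coupling splits each resonance into a doublet separated by J", {
  acq <- test_acq()
  sys <- spin_system("ax", c(1.0, 4.0),
                     matrix(c(0, 7, 7, 0), 2))
  sig <- simulate_spin_system(sys, seq_spec("pulse_acquire"), acq)
  s <- zf_spectrum(sig$fid, acq, zf = 16)
  # examine the low-ppm resonance: two lines ~7 Hz apart
  win <- which(s$ppm > 0.8 & s$ppm < 1.2)
  re <- s$re[win]; f <- s$f_hz[win]
  k1 <- which.max(re)
  re2 <- re; re2[abs(f - f[k1]) < 3.5] <- -Inf
  k2 <- which.max(re2)
  expect_equal(abs(f[k2] - f[k1]), 7, tolerance = 0.15)
})

test_that("density-matrix propagation reproduces the closed-form AB spectrum", {
  acq <- test_acq()
  for (pars in list(c(2.0, 2.1, 10), c(3.0, 3.05, 7), c(1.5, 1.52, 5))) {
    sys <- spin_system("ab", pars[1:2],
                       matrix(c(0, pars[3], pars[3], 0), 2))
    sig <- simulate_spin_system(sys, seq_spec("pulse_acquire"), acq)
    oracle <- ab_fid(pars[1], pars[2], pars[3], acq)
    expect_lt(max(Mod(sig$fid - oracle)) / max(Mod(oracle)), 1e-6)
  }
})

test_that("spin-echo doublet components are J-modulated by +/- pi J TE", {
  acq <- test_acq()
  J <- 7
  hz <- hzpppm(acq)
  tvec <- time_axis(acq)
  sys <- spin_system("ax", c(1.0, 4.0), matrix(c(0, J, J, 0), 2))
  for (te in c(0.03, 0.05)) {
    sig <- simulate_spin_system(sys, seq_spec("spin_echo", te), acq)
    # least-squares extraction of the four line amplitudes
    vA <- (acq$ppm_reference - 1.0) * hz
    vX <- (acq$ppm_reference - 4.0) * hz
    M <- cbind(exp(2i * pi * (vA + J / 2) * tvec),
               exp(2i * pi * (vA - J / 2) * tvec),
               exp(2i * pi * (vX + J / 2) * tvec),
               exp(2i * pi * (vX - J / 2) * tvec))
    a <- qr.solve(M, sig$fid)
    expect_equal(Mod(a), rep(0.5, 4), tolerance = 0.04)
    # the +J/2 and -J/2 components of each doublet are phase-modulated by
    # +pi J TE and -pi J TE (weak-coupling corrections ~J/delta remain)
    expect_lt(abs(Arg(a[1]) - pi * J * te), 0.1)
    expect_lt(abs(Arg(a[2]) + pi * J * te), 0.1)
    # and the modulation difference across each doublet is 2 pi J TE
    expect_lt(abs(Arg(a[1] / a[2]) - 2 * pi * J * te), 0.15)
    expect_lt(abs(Arg(a[3] / a[4]) - 2 * pi * J * te), 0.15)
  }
})

test_that("ideal semi-LASER equals pulse-acquire for uncoupled spins", {
  acq <- test_acq()
  sys <- spin_system("s", 3.03)
  pa <- simulate_spin_system(sys, seq_spec("pulse_acquire"), acq)
  for (te in list(c(0.008, 0.011, 0.009), c(0.02, 0.03, 0.01))) {
    sl <- simulate_spin_system(sys, seq_spec("semi_laser_ideal", te), acq)
    expect_lt(max(Mod(sl$fid - pa$fid)), 1e-8)
  }
})

test_that("singlet amplitude is proportional to the proton count", {
  acq <- test_acq()
  s1 <- simulate_spin_system(spin_system("a", 3.0),
                             seq_spec("pulse_acquire"), acq, scale = 1)
  s3 <- simulate_spin_system(spin_system("a", 3.0),
                             seq_spec("pulse_acquire"), acq, scale = 3)
  expect_equal(s3$fid, 3 * s1$fid)
  expect_equal(Re(s3$fid[1]), 3)
})

test_that("oversized spin systems are rejected", {
  acq <- test_acq()
  expect_error(simulate_spin_system(spin_system("big", rep(1, 9)),
                                    seq_spec("pulse_acquire"), acq),
               "capacity")
})

test_that("parametric signals honor sign, width and shape conventions", {
  acq <- test_acq()
  inv <- simulate_parametric(parametric_signal("inv", data.frame(
    ppm = 3.913, amplitude = -1, fwhm_hz = 2, shape = "lorentzian")), acq)
  s <- zf_spectrum(inv$fid, acq)
  k <- which.min(s$re)
  expect_equal(s$ppm[k], 3.913, tolerance = 5e-3)
  expect_lt(s$re[k], 0)
  zero <- simulate_parametric(parametric_signal("z", data.frame(
    ppm = 2, amplitude = 0, fwhm_hz = 2, shape = "lorentzian")), acq)
  expect_true(all(zero$fid == 0))
  # width check at 4 Hz, where FID truncation over the 0.512 s acquisition
  # is negligible (a 2 Hz line is still ~7% wider than nominal)
  lor <- simulate_parametric(parametric_signal("l", data.frame(
    ppm = 3.0, amplitude = 1, fwhm_hz = 4, shape = "lorentzian")), acq)
  expect_equal(measured_fwhm_hz(lor$fid, acq), 4, tolerance = 0.02)
})

test_that("the default basis matches the benchmark structure", {
  b <- shared_basis()
  expect_length(b, 29)
  expect_identical(b$names, basis_signal_order())
  expect_true(all(c("NAA", "MM20", "Lip09", "-CrCH2") %in% b$names))
  for (s in b$signals) {
    expect_length(s$fid, 1024)
    expect_equal(s$acq$sampling_frequency_hz, 2000)
  }
  # the inverted singlet is negative in the real spectrum
  cr2 <- b$signals[[match("-CrCH2", b$names)]]
  s <- zf_spectrum(cr2$fid, b$acq)
  expect_lt(min(s$re), -0.5 * max(abs(s$re)))
})
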