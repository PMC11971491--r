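test_that("noise SD estimation matches the known level and guards its region", {
  acq <- test_acq()
  zero <- mrs_spectrum(complex(1024), acq)
  expect_equal(estimate_noise_sd(zero), 0)
  set.seed(3)
  sd_f <- 5
  reps <- replicate(20, {
    fid <- complex(real = rnorm(1024, 0, sd_f / sqrt(1024)),
                   imaginary = rnorm(1024, 0, sd_f / sqrt(1024)))
    estimate_noise_sd(mrs_spectrum(fid, acq))
  })
  expect_equal(mean(reps), sd_f, tolerance = 0.1)
  expect_error(estimate_noise_sd(zero, region_ppm = c(3, 5)), "overlaps")
})

test_that("the penalty vector is zero at the expectation point and scales per the model", {
  acq <- test_acq()
  nb <- 29
  cfg <- reg_config(noise_sd = 1)
  p0 <- fit_parameters(n_signals = nb, broadenings_hz = rep(0.78, nb))
  expect_equal(penalty_vector(p0, cfg, acq), rep(0, 2 * nb + 1))
  # a shift of 0.004 ppm at sigma = 1 gives a unit penalty entry
  p1 <- fit_parameters(n_signals = nb, broadenings_hz = rep(0.78, nb))
  p1$shifts_hz[1] <- 0.004 * hzpppm(acq)  # 0.5112 Hz
  expect_equal(penalty_vector(p1, cfg, acq)[1], 1.0)
  # sigma = 2, d = 0.936 vs d_exp 0.78 at d_reg 0.156 gives 2.0
  cfg2 <- reg_config(noise_sd = 2)
  p2 <- fit_parameters(n_signals = nb, broadenings_hz = rep(0.78, nb))
  p2$broadenings_hz[4] <- 0.936
  expect_equal(penalty_vector(p2, cfg2, acq)[nb + 4], 2.0)
  expect_error(penalty_vector(p0, reg_config(noise_sd = 0), acq), "sigma")
})

test_that("the amplitude solver matches a brute-force active-set oracle", {
  set.seed(11)
  for (trial in 1:20) {
    m <- 30; ncon <- 5; nfree <- 3
    A <- matrix(rnorm(m * (ncon + nfree)), m)
    y <- rnorm(m)
    P <- crossprod(diff(diag(nfree)))
    d <- structure(list(columns = A, n_basis = ncon, n_spline = nfree,
                        penalty = P, penalty_weight = 0.3),
                   class = "design_matrix")
    x <- solve_amplitudes(d, y)
    expect_true(all(x[1:ncon] >= 0))
    ref <- ref_pnnls(A, y, ncon, 0.3 * P)
    objx <- sum((y - A %*% x)^2) +
      drop(t(x[6:8]) %*% (0.3 * P) %*% x[6:8])
    expect_lt(objx, ref$obj + 1e-8 * (1 + ref$obj))
  }
})

test_that("orthogonal unconstrained columns recover their projections; negative data clamps", {
  A <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  d <- structure(list(columns = A, n_basis = 0, n_spline = 2,
                      penalty = matrix(0, 2, 2), penalty_weight = 0),
                 class = "design_matrix")
  expect_equal(solve_amplitudes(d, c(2, -3, 1, 1)), c(2, -3))
  # data equal to minus a constrained column clamps that amplitude at zero
  d2 <- structure(list(columns = A, n_basis = 2, n_spline = 0,
                       penalty = matrix(0, 0, 0), penalty_weight = 0),
                  class = "design_matrix")
  expect_equal(solve_amplitudes(d2, c(-1, 0.5, 0, 0)), c(0, 0.5))
})

test_that("variable-projection amplitudes are optimal against random perturbations", {
  set.seed(21)
  A <- matrix(rnorm(40 * 7), 40)
  y <- rnorm(40)
  P <- crossprod(diff(diag(2)))
  d <- structure(list(columns = A, n_basis = 5, n_spline = 2,
                      penalty = P, penalty_weight = 0.1),
                 class = "design_matrix")
  x <- solve_amplitudes(d, y)
  obj <- function(v) sum((y - A %*% v)^2) +
    drop(t(v[6:7]) %*% (0.1 * P) %*% v[6:7])
  o0 <- obj(x)
  for (k in 1:100) {
    v <- x + rnorm(7, 0, 0.05)
    v[1:5] <- pmax(v[1:5], 0)
    expect_gte(obj(v), o0 - 1e-10)
  }
})

test_that("the stacked objective vanishes for a perfect model and collapses to the unregularized form in the weak-penalty limit", {
  b <- shared_basis()
  acq <- b$acq
  nb <- length(b)
  bl <- spline_baseline_basis(c(0.2, 4.0), 0.15, acq)
  # data built from the model at the expectation point
  p0 <- fit_parameters(n_signals = nb, broadenings_hz = rep(0.78, nb),
                       lineshape_fwhm_hz = 4)
  conc <- default_concentrations()
  z <- stats::setNames(rep(0, nb), b$names)
  truth <- ground_truth(conc, z, stats::setNames(rep(0.78, nb), b$names),
                        noise_sd = 0, seed = 1)
  y <- synthesize_spectrum(b, truth, synth_config())
  off <- reg_config(enabled = FALSE)
  r_off <- objective(p0, y, b, bl, off)
  expect_lt(max(abs(r_off)), 1e-6 * max(abs(Re(spec_fd(y)))))
  r_on <- objective(p0, y, b, bl, reg_config(noise_sd = 3))
  expect_lt(max(abs(r_on)), 1e-6 * max(abs(Re(spec_fd(y)))))
  # weak-regularization limit reproduces the unregularized objective
  p1 <- fit_parameters(n_signals = nb, shifts_hz = rep(0.2, nb),
                       broadenings_hz = rep(1.0, nb),
                       lineshape_fwhm_hz = 4, asymmetry = 0.05)
  weak <- reg_config(f_reg_ppm = 1e12, d_reg_hz = 1e12, d_exp_hz = 0.78,
                     a_reg = 1e12, noise_sd = 3)
  expect_lt(abs(sum(objective(p1, y, b, bl, weak)^2) -
                sum(objective(p1, y, b, bl, off)^2)), 1e-10)
})

test_that("fitting the noiseless unperturbed spectrum recovers every benchmark concentration within 1 percent", {
  b <- shared_basis()
  y <- clean_spectrum(b)
  ft <- fit_spectrum(y, b, mode = "noreg")
  conc <- default_concentrations()[b$names]
  expect_true(all(abs(ft$concentrations_mm - conc) <=
                  pmax(0.01 * conc, 0.01)))
  expect_true(ft$converged)
})

test_that("fixed-frequency mode pins every individual shift and matches the strong-penalty limit", {
  b <- shared_basis()
  # noiseless spectrum with damping perturbations only: the effective
  # objective of the two formulations coincides and has a clean minimum
  cfg <- synth_config(shift_sd_ppm = 0)
  pert <- draw_signal_perturbations(cfg, b$names, seed = 3, acq = b$acq)
  truth <- ground_truth(default_concentrations(), pert$shifts_hz,
                        pert$broadenings_hz, noise_sd = 0, seed = 3)
  y <- synthesize_spectrum(b, truth, cfg)
  ff <- fit_spectrum(y, b, mode = "ff")
  expect_true(all(abs(ff$params$shifts_hz) <= 1e-6))
  strong <- fit_spectrum(y, b, mode = "reg",
                         cfg = reg_config(f_reg_ppm = 1e-9))
  expect_true(all(abs(strong$params$shifts_hz) < 1e-3))
  m <- metabolite_names()
  expect_true(all(abs(strong$concentrations_mm[m] - ff$concentrations_mm[m])
                  <= 1e-3 * pmax(ff$concentrations_mm[m], 1)))
})

test_that("fits are deterministic", {
  b <- shared_basis()
  cfg <- synth_config(n_spectra = 1, snr_targets = 60, master_seed = 9)
  ds <- generate_dataset(cfg, b)
  f1 <- fit_spectrum(ds$spectra[[1]], b, mode = "reg")
  f2 <- fit_spectrum(ds$spectra[[1]], b, mode = "reg")
  expect_identical(f1$amplitudes, f2$amplitudes)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$objective_value, f2$objective_value)
})

test_that("weakening any regularization never increases the converged data misfit", {
  b <- shared_basis()
  cfg <- synth_config(n_spectra = 1, snr_targets = 30, master_seed = 13)
  ds <- generate_dataset(cfg, b)
  y <- ds$spectra[[1]]
  misfit <- function(rc) {
    ft <- fit_spectrum(y, b, mode = "reg", cfg = rc)
    sum(ft$residual^2)
  }
  m_base <- misfit(reg_config())
  m_weak <- misfit(reg_config(f_reg_ppm = 0.008, d_reg_hz = 0.312,
                              a_reg = 0.2))
  m_weaker <- misfit(reg_config(f_reg_ppm = 0.04, d_reg_hz = 1.56,
                                a_reg = 1))
  expect_lte(m_weak, m_base * (1 + 1e-6))
  expect_lte(m_weaker, m_weak * (1 + 1e-6))
})

test_that("per-signal shifts and broadenings are recovered on noiseless data", {
  b <- shared_basis()
  cfg <- synth_config(n_spectra = 1, master_seed = 17)
  pert <- draw_signal_perturbations(cfg, b$names, seed = 170, acq = b$acq)
  truth <- ground_truth(default_concentrations(), pert$shifts_hz,
                        pert$broadenings_hz, noise_sd = 0, seed = 170)
  y <- synthesize_spectrum(b, truth, cfg)
  ft <- fit_spectrum(y, b, mode = "reg")
  strong <- c("NAA", "Cr", "PCr", "GPC", "PCho")
  i <- match(strong, b$names)
  f_err <- abs(ft$params$shifts_hz[i] + ft$params$global_shift_hz -
               unname(pert$shifts_hz[strong]))
  d_err <- abs(ft$params$broadenings_hz[i] -
               unname(pert$broadenings_hz[strong]))
  expect_true(all(f_err < 0.1))
  expect_true(all(d_err < 0.2))
})
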