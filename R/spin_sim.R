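#' Spin system definition
#'
#' A set of coupled spin-1/2 nuclei defined by their chemical shifts and
#' scalar (J) couplings. The full isotropic coupling Hamiltonian is used, so
#' strong-coupling effects are reproduced exactly.
#'
#' @param name Label.
#' @param chemical_shifts_ppm Numeric vector, one shift per spin.
#' @param j_couplings_hz Symmetric matrix (zero diagonal) of couplings in Hz.
#' @return An object of class `spin_system`.
#' @export
spin_system <- function(name, chemical_shifts_ppm, j_couplings_hz = NULL) {
  n <- length(chemical_shifts_ppm)
  if (is.null(j_couplings_hz)) j_couplings_hz <- matrix(0, n, n)
  j_couplings_hz <- as.matrix(j_couplings_hz)
  stopifnot(nrow(j_couplings_hz) == n, ncol(j_couplings_hz) == n)
  if (max(abs(j_couplings_hz - t(j_couplings_hz))) > 1e-9)
    stop("J-coupling matrix must be symmetric")
  if (any(diag(j_couplings_hz) != 0))
    stop("J-coupling matrix must have a zero diagonal")
  structure(list(name = name, chemical_shifts_ppm = chemical_shifts_ppm,
                 j_couplings_hz = j_couplings_hz, spin_count = n),
            class = "spin_system")
}

#' Pulse-sequence specification
#'
#' Ideal-pulse sequences supported by the simulator. `pulse_acquire` detects
#' immediately after excitation; `spin_echo` refocuses at TE with a single
#' 180; `semi_laser_ideal` uses four ideal 180 pulses with delays derived
#' from the three echo-time partitions (TE1, TE2, TE3), refocusing chemical
#' shift (but not J evolution) at the start of acquisition.
#'
#' @param kind One of "pulse_acquire", "spin_echo", "semi_laser_ideal".
#' @param te_partitions_s Echo-time partitions in seconds: none for
#'   pulse-acquire, `TE` for spin-echo, `c(TE1, TE2, TE3)` for semi-LASER.
#' @return An object of class `seq_spec`.
#' @export
seq_spec <- function(kind = c("pulse_acquire", "spin_echo", "semi_laser_ideal"),
                     te_partitions_s = numeric(0)) {
  kind <- match.arg(kind)
  nreq <- switch(kind, pulse_acquire = 0L, spin_echo = 1L,
                 semi_laser_ideal = 3L)
  if (length(te_partitions_s) != nreq)
    stop(sprintf("'%s' requires %d echo-time partition(s)", kind, nreq))
  structure(list(kind = kind, te_partitions_s = te_partitions_s,
                 echo_time_s = sum(te_partitions_s)), class = "seq_spec")
}

# Pauli-style single-spin operators (spin 1/2)
.Ix1 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
.Iy1 <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2)
.Iz1 <- matrix(c(0.5, 0, 0, -0.5), 2, 2)

# operator for spin i in an n-spin Hilbert space
spin_op <- function(op1, i, n) {
  out <- 1
  for (k in seq_len(n))
    out <- kronecker(out, if (k == i) op1 else diag(2))
  out
}

#' Simulate a spin system
#'
#' Density-matrix simulation with ideal (instantaneous, perfectly selective)
#' RF pulses and no relaxation. Chemical-shift offsets are taken relative to
#' `acq$ppm_reference`; the first FID point corresponds to the echo center.
#' The FID is normalized so its first point equals `scale * spin_count`
#' (one unit per proton).
#'
#' @param sys A [spin_system()].
#' @param seq A [seq_spec()].
#' @param acq An [acq_params()].
#' @param scale Amplitude multiplier (e.g. number of equivalent groups).
#' @param max_spins Capacity limit for the dense simulation.
#' @return A [basis_signal()].
#' @export
#' @examples
#' acq <- acq_params()
#' naa_ch3 <- spin_system("NAA-CH3", 2.008)
#' sig <- simulate_spin_system(naa_ch3, seq_spec("pulse_acquire"), acq, scale = 3)
simulate_spin_system <- function(sys, seq, acq, scale = 1, max_spins = 8) {
  n <- sys$spin_count
  if (n > max_spins)
    stop(sprintf("spin system '%s' has %d spins, above the capacity limit (%d)",
                 sys$name, n, max_spins))
  dimH <- 2^n
  offs <- (acq$ppm_reference - sys$chemical_shifts_ppm) * hzpppm(acq)

  Ix <- lapply(seq_len(n), function(i) spin_op(.Ix1, i, n))
  Iy <- lapply(seq_len(n), function(i) spin_op(.Iy1, i, n))
  Iz <- lapply(seq_len(n), function(i) spin_op(.Iz1, i, n))

  H <- matrix(0, dimH, dimH)
  for (i in seq_len(n)) H <- H + 2 * pi * offs[i] * Iz[[i]]
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j && sys$j_couplings_hz[i, j] != 0) {
    Jij <- sys$j_couplings_hz[i, j]
    H <- H + 2 * pi * Jij * Re(Ix[[i]] %*% Ix[[j]] + Iy[[i]] %*% Iy[[j]] +
                               Iz[[i]] %*% Iz[[j]])
  }
  eg <- eigen(H, symmetric = TRUE)
  V <- eg$vectors; lam <- eg$values

  evolve <- function(rho, t) {
    if (t == 0) return(rho)
    rt <- Conj(t(V)) %*% rho %*% V
    ph <- exp(-1i * lam * t)
    rt <- rt * (ph %o% Conj(ph))
    V %*% rt %*% Conj(t(V))
  }
  # ideal 180-degree pulses as products of single-spin rotations; the
  # spin-echo refocusing pulse is applied about x (so the echo of an
  # uncoupled spin is in phase with pulse-acquire); semi-LASER uses an even
  # number of 180y pulses, which preserves the sign as well
  mk180 <- function(r1) {
    R <- 1
    for (k in seq_len(n)) R <- kronecker(R, r1)
    R
  }
  R180y <- mk180(matrix(c(0, 1, -1, 0), 2, 2))
  R180x <- mk180(matrix(c(0, -1i, -1i, 0), 2, 2))
  pulse <- function(rho, R) R %*% rho %*% Conj(t(R))

  # 90-y excitation of thermal Iz magnetization -> Ix
  rho <- Reduce(`+`, Ix)

  if (seq$kind == "spin_echo") {
    te <- seq$te_partitions_s
    rho <- evolve(rho, te / 2)
    rho <- pulse(rho, R180x)
    rho <- evolve(rho, te / 2)
  } else if (seq$kind == "semi_laser_ideal") {
    p <- seq$te_partitions_s
    delays <- c(p[1] / 2, (p[1] + p[2]) / 2, p[2] / 2 + p[3] / 4,
                p[3] / 2, p[3] / 4)
    for (k in 1:4) {
      rho <- evolve(rho, delays[k])
      rho <- pulse(rho, R180y)
    }
    rho <- evolve(rho, delays[5])
  }

  # detection: s(t) = Tr(rho(t) F+) expanded over Hamiltonian eigenpairs
  Fp <- Reduce(`+`, Ix) + 1i * Reduce(`+`, Iy)
  rt <- Conj(t(V)) %*% rho %*% V
  Ft <- Conj(t(V)) %*% Fp %*% V
  C <- rt * t(Ft)                       # C[a,b] = rho~[a,b] * F~[b,a]
  W <- outer(lam, lam, function(a, b) b - a)
  keep <- which(Mod(C) > 1e-12 * max(Mod(C), 1e-300))
  # merge degenerate transitions (same frequency to ~1e-6 rad/s)
  key <- round(W[keep] * 1e6)
  agg <- rowsum(cbind(Re(C[keep]), Im(C[keep])), key)
  wu <- as.numeric(rownames(agg)) * 1e-6
  cu <- complex(real = agg[, 1], imaginary = agg[, 2])
  sel <- Mod(cu) > 1e-12 * max(Mod(cu))
  tvec <- time_axis(acq)
  fid <- drop(exp(1i * tvec %o% wu[sel]) %*% cu[sel])
  fid <- fid * scale / (dimH / 4)
  basis_signal(sys$name, fid, acq)
}
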