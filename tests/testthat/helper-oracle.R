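# Independent oracle: dense 4x4 complex density-matrix propagation for the
# two-spin-1/2 system, via eigendecomposition matrix exponentials. Used to
# cross-check the analytic product-operator engine; shares no code with it.

.o_s <- local({
  sx <- matrix(c(0, 1, 1, 0), 2, 2) / 2
  sy <- matrix(c(0, 1i, -1i, 0), 2, 2) / 2
  sz <- matrix(c(1, 0, 0, -1), 2, 2) / 2
  id <- diag(2)
  list(Ix = kronecker(sx, id), Iy = kronecker(sy, id), Iz = kronecker(sz, id),
       Sx = kronecker(id, sx), Sy = kronecker(id, sy), Sz = kronecker(id, sz))
})

# basis in the package's coefficient order; all operators have unit
# Frobenius norm so coefficients are plain trace inner products
.o_basis <- local({
  b <- list(E = diag(4) / 2)
  for (nm in c("Ix", "Iy", "Iz", "Sx", "Sy", "Sz")) b[[nm]] <- .o_s[[nm]]
  for (i in c("x", "y", "z")) for (s in c("x", "y", "z"))
    b[[paste0("I", i, "S", s)]] <-
      2 * .o_s[[paste0("I", i)]] %*% .o_s[[paste0("S", s)]]
  b[c("E", "Ix", "Iy", "Iz", "Sx", "Sy", "Sz",
      "IxSx", "IxSy", "IxSz", "IySx", "IySy", "IySz",
      "IzSx", "IzSy", "IzSz")]
})

oracle_coeffs_to_rho <- function(a) {
  rho <- matrix(0i, 4, 4)
  for (k in seq_along(.o_basis)) rho <- rho + a[[k]] * .o_basis[[k]]
  rho
}

oracle_rho_to_coeffs <- function(rho) {
  setNames(vapply(.o_basis, function(B)
    Re(sum(diag(Conj(t(B)) %*% rho))), numeric(1)), names(.o_basis))
}

.o_expmih <- function(H, t = 1) {   # exp(-i H t) for Hermitian H
  e <- eigen(H, symmetric = TRUE)
  V <- e$vectors
  V %*% diag(exp(-1i * e$values * t)) %*% Conj(t(V))
}

oracle_evolve <- function(a, sys, t, refocus_offsets = FALSE) {
  H <- 2 * pi * sys$J_IS * (.o_s$Iz %*% .o_s$Sz)
  if (!refocus_offsets)
    H <- H + 2 * pi * sys$offset_I * .o_s$Iz + 2 * pi * sys$offset_S * .o_s$Sz
  U <- .o_expmih(H, t)
  a2 <- oracle_rho_to_coeffs(U %*% oracle_coeffs_to_rho(a) %*% Conj(t(U)))
  # damping contract: transverse coefficients decay by exp(-t/T2')
  trans_I <- grepl("^Ix|^Iy", names(a2))
  trans_S <- grepl("Sx$|Sy$", names(a2))
  if (is.finite(sys$T2prime_I)) a2[trans_I] <- a2[trans_I] * exp(-t / sys$T2prime_I)
  if (is.finite(sys$T2prime_S)) a2[trans_S] <- a2[trans_S] * exp(-t / sys$T2prime_S)
  a2
}

oracle_pulse <- function(a, target, flip_deg, phase_deg,
                         attenuation = 1, leakage = 0) {
  ax <- function(spin, beta) {
    ph <- phase_deg * pi / 180
    beta * (cos(ph) * .o_s[[paste0(spin, "x")]] +
            sin(ph) * .o_s[[paste0(spin, "y")]])
  }
  beta <- flip_deg * pi / 180
  G <- matrix(0i, 4, 4)
  if (target %in% c("I", "both")) G <- G + ax("I", beta * attenuation)
  if (target %in% c("S", "both")) G <- G + ax("S", beta * attenuation)
  if (leakage > 0 && target == "I") G <- G + ax("S", beta * leakage)
  if (leakage > 0 && target == "S") G <- G + ax("I", beta * leakage)
  U <- .o_expmih(G)
  oracle_rho_to_coeffs(U %*% oracle_coeffs_to_rho(a) %*% Conj(t(U)))
}

oracle_zfilter <- function(a, keep_zz = FALSE) {
  keep <- c("E", "Iz", "Sz", if (keep_zz) "IzSz")
  a[setdiff(names(a), keep)] <- 0
  a
}

# mirrors the sequence definition of run_transfer_experiment() through the
# dense route; returns per-step and cycled complex signals
oracle_run_sequence <- function(sys, tau, cycle, variant,
                                attenuation = 1, leakage = 0,
                                cp = c(I = 1, S = 1), zfilter = TRUE) {
  n <- cycle$n_steps
  sig_I <- sig_S <- complex(n)
  for (k in seq_len(n)) {
    ph <- cycle$flipdown_phases[k]
    a <- setNames(numeric(16), names(.o_basis))
    a["Ix"] <- cp[["I"]]; a["Sx"] <- cp[["S"]]
    a <- oracle_pulse(a, "I", 90, 270, attenuation, leakage)
    if (zfilter) a <- oracle_zfilter(a)
    a <- oracle_pulse(a, "I", 90, ph, attenuation, leakage)
    blk <- if (variant == "dq_filter") ph else 0
    a <- oracle_evolve(a, sys, tau)
    a <- oracle_pulse(a, "both", 180, blk)
    a <- oracle_evolve(a, sys, tau)
    if (variant == "perfect_echo") {
      a <- oracle_pulse(a, "both", 90, 270)
    } else if (variant == "dq_filter") {
      a <- oracle_pulse(a, "both", 90, blk)
      a <- oracle_pulse(a, "both", 90, 90)
    }
    a <- oracle_evolve(a, sys, tau)
    a <- oracle_pulse(a, "both", 180, 0)
    a <- oracle_evolve(a, sys, tau)
    sig_I[k] <- a[["Ix"]] + 1i * a[["Iy"]]
    sig_S[k] <- a[["Sx"]] + 1i * a[["Sy"]]
  }
  rec <- exp(-1i * cycle$receiver_phases * pi / 180)
  list(signal_I = sig_I, signal_S = sig_S,
       cycled_I = mean(sig_I * rec), cycled_S = mean(sig_S * rec))
}
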