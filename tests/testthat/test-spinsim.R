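random_state <- function() {
  v <- rnorm(16)
  v[1] <- 0
  two_spin_state(v)
}

test_that("free evolution follows the analytic J-coupling rotation rules", {
  sys <- spin_system(J_IS = 0)
  st <- two_spin_state(Ix = 0.4, Iz = -0.3, IySz = 0.2)
  expect_equal(unclass(evolve_delay(st, sys, 0.013)), unclass(st),
               tolerance = 1e-14)

  # Ix under a J evolution of total time t_e
  J <- 52.7; t_e <- 6.3e-3
  out <- evolve_delay(two_spin_state(Ix = 1), spin_system(J_IS = J), t_e)
  expect_equal(unname(out["Ix"]), cos(pi * J * t_e), tolerance = 1e-12)
  expect_equal(unname(out["IySz"]), sin(pi * J * t_e), tolerance = 1e-12)
  expect_equal(sum(abs(unclass(out)[setdiff(names(out), c("Ix", "IySz"))])), 0)
})

test_that("T2' damping scales transverse coefficients by exp(-t/T2')", {
  sys <- spin_system(J_IS = 0, T2prime_I = 0.02, T2prime_S = 0.05)
  st <- two_spin_state(Ix = 1, Sy = 1, IxSy = 1, Iz = 1)
  out <- evolve_delay(st, sys, 0.01)
  expect_equal(unname(out["Ix"]), exp(-0.5), tolerance = 1e-12)
  expect_equal(unname(out["Sy"]), exp(-0.2), tolerance = 1e-12)
  expect_equal(unname(out["IxSy"]), exp(-0.5) * exp(-0.2), tolerance = 1e-12)
  expect_equal(unname(out["Iz"]), 1)
  expect_error(evolve_delay(st, sys, -1), ">= 0")
})

test_that("pulses rotate with the right-handed sign convention", {
  out <- apply_pulse(two_spin_state(Iz = 1), pulse_event("I", 90, 0))
  expect_equal(unname(out["Iy"]), -1, tolerance = 1e-12)
  expect_equal(po_norm(out), 1, tolerance = 1e-12)

  st <- random_state()
  out360 <- apply_pulse(st, pulse_event("both", 360, 37))
  expect_equal(unclass(out360), unclass(st), tolerance = 1e-12)

  # leakage rotates the non-target spin by the stated fraction
  out <- apply_pulse(two_spin_state(Sz = 1),
                     pulse_event("I", 90, 0, leakage = 0.1))
  expect_equal(unname(out["Sy"]), -sin(0.1 * pi / 2), tolerance = 1e-12)
})

test_that("z-filter retains only longitudinal terms, 2IzSz per flag", {
  st <- two_spin_state(Iz = 0.5, Sx = 0.3, IxSy = 0.2, IzSz = 0.4, Sz = -0.1)
  out <- apply_zfilter(st)
  expect_equal(unname(out["Iz"]), 0.5)
  expect_equal(unname(out["Sz"]), -0.1)
  expect_equal(sum(abs(unclass(out)[c("Sx", "IxSy", "IzSz")])), 0)
  expect_equal(unname(apply_zfilter(st, keep_zz = TRUE)["IzSz"]), 0.4)
  expect_equal(po_norm(apply_zfilter(two_spin_state(Sx = 1))), 0)
})

test_that("engine matches the dense density-matrix oracle on random operations", {
  set.seed(101)
  for (i in 1:60) {
    st <- random_state()
    a <- setNames(unclass(st), names(unclass(st)))
    sys <- spin_system(J_IS = runif(1, 0, 200),
                       offset_I = runif(1, -2000, 2000),
                       offset_S = runif(1, -2000, 2000),
                       T2prime_I = sample(c(Inf, runif(1, 0.005, 0.1)), 1),
                       T2prime_S = sample(c(Inf, runif(1, 0.005, 0.1)), 1))
    t <- runif(1, 0, 0.02)
    expect_equal(unclass(evolve_delay(st, sys, t)),
                 oracle_evolve(a, sys, t), tolerance = 1e-10)
    flip <- runif(1, 0, 360); ph <- runif(1, 0, 360)
    tgt <- sample(c("I", "S", "both"), 1)
    att <- runif(1); leak <- if (tgt == "both") 0 else runif(1)
    expect_equal(unclass(apply_pulse(st, pulse_event(tgt, flip, ph, att, leak))),
                 oracle_pulse(a, tgt, flip, ph, att, leak), tolerance = 1e-10)
  }
})

test_that("lossless composite sequences conserve the coefficient norm", {
  set.seed(202)
  for (i in 1:25) {
    st <- random_state()
    n0 <- po_norm(st)
    sys <- spin_system(J_IS = runif(1, 0, 120), offset_I = runif(1, -1000, 1000),
                       offset_S = runif(1, -1000, 1000))
    for (j in 1:6) {
      if (runif(1) < 0.5) st <- evolve_delay(st, sys, runif(1, 0, 0.01))
      else st <- apply_pulse(st, pulse_event(sample(c("I", "S", "both"), 1),
                                             runif(1, 0, 360), runif(1, 0, 360)))
    }
    expect_equal(po_norm(st), n0, tolerance = 1e-10)
  }
})

test_that("perfect echo transfers sin^2(pi J 2 tau) to C2 and retains C1", {
  sys <- spin_system(J_IS = 46)
  tau <- 4e-3
  theta <- 2 * pi * sys$J_IS * tau
  res <- run_transfer_experiment(sys, tau, variant = "perfect_echo")
  expect_equal(Re(res$cycled_S), sin(theta)^2, tolerance = 1e-12)
  expect_equal(Im(res$cycled_S), 0, tolerance = 1e-12)
  expect_equal(Re(res$cycled_I), cos(theta)^2, tolerance = 1e-12)

  # buildup: 4 ms exceeds 2 ms at J = 46 Hz
  res2 <- run_transfer_experiment(sys, 2e-3, variant = "perfect_echo")
  expect_gt(Re(res$cycled_S), Re(res2$cycled_S))

  # no coupling, no transfer; C1 signal maximal
  res0 <- run_transfer_experiment(spin_system(J_IS = 0), tau)
  expect_lt(abs(res0$cycled_S), 1e-12)
  expect_equal(Re(res0$cycled_I), 1, tolerance = 1e-12)
})

test_that("composite sequences agree with the oracle for all variants", {
  set.seed(303)
  for (variant in c("perfect_echo", "control_no_pi2", "dq_filter")) {
    for (i in 1:8) {
      sys <- spin_system(J_IS = runif(1, 10, 120),
                         offset_I = runif(1, -500, 500),
                         offset_S = runif(1, -500, 500))
      tau <- runif(1, 5e-4, 8e-3)
      att <- runif(1, 0.5, 1); leak <- runif(1, 0, 0.2)
      res <- run_transfer_experiment(sys, tau, variant = variant,
                                     selective = list(attenuation = att,
                                                      leakage = leak))
      orc <- oracle_run_sequence(sys, tau, res$cycle, variant,
                                 attenuation = att, leakage = leak)
      expect_equal(res$per_step$signal_S, orc$signal_S, tolerance = 1e-10)
      expect_equal(res$per_step$signal_I, orc$signal_I, tolerance = 1e-10)
      expect_equal(res$cycled_S, orc$cycled_S, tolerance = 1e-10)
    }
  }
})

test_that("control variant isolates the pure J-transfer term by subtraction", {
  sys <- spin_system(J_IS = 46)
  tau <- 3.5e-3
  pe <- run_transfer_experiment(sys, tau, variant = "perfect_echo")
  ct <- run_transfer_experiment(sys, tau, variant = "control_no_pi2")
  expect_lt(abs(ct$cycled_S), 1e-10)   # ideal pulses: no S signal in control
  theta <- 2 * pi * sys$J_IS * tau
  expect_equal(Re(pe$cycled_S) - Re(ct$cycled_S), sin(theta)^2,
               tolerance = 1e-10)
})

test_that("DQ cycle transfers in exactly half the scans at half the amplitude", {
  sys <- spin_system(J_IS = 46)
  tau <- 4e-3
  dq <- run_transfer_experiment(sys, tau, variant = "dq_filter")
  pe <- run_transfer_experiment(sys, tau, variant = "perfect_echo")
  expect_identical(dq$n_transfer_steps, 4L)
  expect_identical(nrow(dq$per_step), 8L)
  expect_equal(Re(dq$cycled_S) / Re(pe$cycled_S), 0.5, tolerance = 1e-12)
  # the DQ filter cancels uncoupled C1 magnetization over the cycle
  dq0 <- run_transfer_experiment(spin_system(J_IS = 0), tau,
                                 variant = "dq_filter")
  expect_lt(abs(dq0$cycled_I), 1e-12)
  expect_lt(abs(dq0$cycled_S), 1e-12)
})

test_that("pre-flip-down residuals cancel over the perfect-echo phase cycle", {
  sys <- spin_system(J_IS = 0)
  # a residual Sy coherence present before the flip-down survives each scan
  # but sums to zero because the receiver follows the flip-down phase
  res <- run_transfer_experiment(sys, 4e-3, variant = "perfect_echo",
                                 initial_state = two_spin_state(Sy = 1),
                                 zfilter = FALSE)
  expect_gt(max(abs(res$per_step$signal_S)), 0.99)
  expect_lt(abs(res$cycled_S), 1e-12)
  expect_lt(abs(res$cycled_I), 1e-12)
})

test_that("phase-cycled sum equals the receiver-weighted mean of the steps", {
  sys <- spin_system(J_IS = 33, offset_S = 150)
  res <- run_transfer_experiment(sys, 2e-3, variant = "perfect_echo",
                                 selective = list(attenuation = 0.7,
                                                  leakage = 0.05))
  rec <- exp(-1i * res$per_step$receiver_phase * pi / 180)
  expect_equal(res$cycled_S, mean(res$per_step$signal_S * rec),
               tolerance = 1e-14)
  expect_equal(res$cycled_I, mean(res$per_step$signal_I * rec),
               tolerance = 1e-14)
})

test_that("shaped-pulse profile is calibrated on resonance and selective off it", {
  pr <- shaped_pulse_profile(1e-3, 0.1, 90, c(0, 2300, 50000))
  expect_equal(pr$profile[1], 1, tolerance = 1e-3)
  expect_lt(abs(pr$profile[3]), 1e-3)          # far off-resonance: nothing
  expect_gt(abs(pr$profile[2]), 1e-4)          # C2 offset: small but nonzero
  expect_lt(abs(pr$profile[2]), 0.1)
  pr45 <- shaped_pulse_profile(1e-3, 0.1, 45, 0)
  expect_equal(pr45$profile, sin(45 * pi / 180), tolerance = 1e-3)
  expect_error(shaped_pulse_profile(-1), "duration")
  expect_error(shaped_pulse_profile(1e-3, 1.2), "truncation")
})

test_that("Bloch integration agrees with an independent ODE solution", {
  skip_if_not_installed("deSolve")
  dur <- 1e-3; tr <- 0.1; flip <- 90
  sigma <- (dur / 2) / sqrt(2 * log(1 / tr))
  for (off in c(500, 2300)) {
    shape_fun <- function(t) exp(-(t - dur / 2)^2 / (2 * sigma^2))
    amp <- (flip * pi / 180) / integrate(shape_fun, 0, dur)$value
    deriv <- function(t, M, parms) {
      w1 <- amp * shape_fun(t); wz <- 2 * pi * off
      list(c(-wz * M[2], wz * M[1] - w1 * M[3], w1 * M[2]))
    }
    sol <- deSolve::ode(c(0, 0, 1), seq(0, dur, length.out = 201), deriv,
                        NULL, method = "ode45")
    ref <- unname(-sol[nrow(sol), 3])
    got <- shaped_pulse_profile(dur, tr, flip, off, n_steps = 2000L)$profile
    expect_equal(got, ref, tolerance = 1e-4)
  }
})

test_that("selective imperfection defaults derive leakage from the profile", {
  imp <- selective_imperfections()
  expect_equal(imp$attenuation, sqrt(0.5))
  expect_gt(imp$leakage, 0)
  expect_lt(imp$leakage, 0.1)
  expect_equal(selective_imperfections(leakage = 0.03)$leakage, 0.03)
})
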