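## Product-operator engine for the C1 (I) / C2 (S) spin pair.
##
## The state is a real coefficient vector over the 16 Cartesian product
## operators {E/2, Ix, Iy, Iz, Sx, Sy, Sz, 2IaSb}. Internally it is held as a
## 4x4 array A[i, s] with i, s indexing {E, x, y, z} for the I and S factor
## respectively, so that single-spin rotations act as 3x3 rotation matrices on
## one index and weak-coupling evolution mixes four fixed coefficient pairs.
## Sign convention: rho' = U rho U+ with U = exp(-i * beta * I_phi), i.e.
## right-handed rotations; a 90(x) pulse takes Iz to -Iy.

.po_names <- c("E", "Ix", "Iy", "Iz", "Sx", "Sy", "Sz",
               "IxSx", "IxSy", "IxSz", "IySx", "IySy", "IySz",
               "IzSx", "IzSy", "IzSz")

# (row = I index, col = S index), 1-based over {E, x, y, z}
.po_idx <- matrix(c(1L,1L, 2L,1L, 3L,1L, 4L,1L, 1L,2L, 1L,3L, 1L,4L,
                    2L,2L, 2L,3L, 2L,4L, 3L,2L, 3L,3L, 3L,4L,
                    4L,2L, 4L,3L, 4L,4L), ncol = 2L, byrow = TRUE,
                  dimnames = list(.po_names, c("i", "s")))

#' State of the two-spin (C1/C2) system in the product-operator basis
#'
#' @param ... Named coefficients over the basis `E, Ix, Iy, Iz, Sx, Sy, Sz,
#'   IxSx, ..., IzSz`, where a bilinear name such as `IxSz` denotes the
#'   coefficient of the operator `2 Ix Sz`. Unnamed: a full numeric vector of
#'   length 16 in that order. Omitted coefficients are zero.
#' @return An object of class `two_spin_state`: a named numeric vector of
#'   length 16.
#' @examples
#' two_spin_state(Iz = 1)          # pure C1 longitudinal magnetization
#' two_spin_state(Ix = 1, Sx = 1)  # state after a nonselective CP transfer
#' @export
two_spin_state <- function(...) {
  args <- list(...)
  v <- stats::setNames(numeric(16L), .po_names)
  if (length(args) == 1L && is.null(names(args)) && length(args[[1L]]) == 16L) {
    v[] <- as.numeric(args[[1L]])
  } else if (length(args)) {
    if (is.null(names(args)) || any(!nzchar(names(args))))
      stop("two_spin_state: coefficients must be named (e.g. Iz = 1)")
    bad <- setdiff(names(args), .po_names)
    if (length(bad)) stop("two_spin_state: unknown operators: ",
                          paste(bad, collapse = ", "))
    for (nm in names(args)) v[nm] <- as.numeric(args[[nm]])
  }
  if (!all(is.finite(v))) stop("two_spin_state: coefficients must be finite")
  structure(v, class = "two_spin_state")
}

#' @export
print.two_spin_state <- function(x, digits = 4, ...) {
  nz <- which(abs(x) > 1e-12)
  if (!length(nz)) { cat("<two_spin_state> 0\n"); return(invisible(x)) }
  lab <- .po_names[nz]
  lab <- ifelse(nchar(lab) > 3, paste0("2", lab), lab)  # 2IaSb convention
  cat("<two_spin_state>",
      paste(sprintf("%+.*g %s", digits, unclass(x)[nz], lab), collapse = " "),
      "\n")
  invisible(x)
}

.po_to_mat <- function(state) {
  m <- matrix(0, 4L, 4L)
  m[.po_idx] <- unclass(state)
  m
}

.mat_to_po <- function(m) {
  structure(stats::setNames(m[.po_idx], .po_names), class = "two_spin_state")
}

#' Norm of the non-identity part of a state
#'
#' Euclidean norm over the 15 non-identity coefficients; conserved to
#' numerical precision under ideal (unitary, lossless) evolution.
#'
#' @param state A [two_spin_state()].
#' @return A scalar.
#' @export
po_norm <- function(state) sqrt(sum(unclass(state)[-1L]^2))

#' Two-spin system parameters
#'
#' @param J_IS One-bond scalar coupling between C1 and C2 in Hz (>= 0). The
#'   default 46 Hz is a typical glucose C1-C2 one-bond coupling.
#' @param offset_I,offset_S Resonance offsets of C1 / C2 in Hz.
#' @param T2prime_I,T2prime_S Refocused transverse decay constants in s
#'   (`Inf` disables the loss).
#' @return An object of class `spin_system`.
#' @export
spin_system <- function(J_IS = 46, offset_I = 0, offset_S = 0,
                        T2prime_I = Inf, T2prime_S = Inf) {
  stopifnot(J_IS >= 0, T2prime_I > 0, T2prime_S > 0)
  structure(list(J_IS = J_IS, offset_I = offset_I, offset_S = offset_S,
                 T2prime_I = T2prime_I, T2prime_S = T2prime_S),
            class = "spin_system")
}

#' A pulse applied to one or both spins
#'
#' Selective pulses are modeled as ideal spin-selective rotations with two
#' scalar imperfection parameters: `attenuation` (amplitude retention of the
#' nominal rotation on the target spin) and `leakage` (fraction of the nominal
#' rotation applied to the non-target spin), both defaultable from
#' [shaped_pulse_profile()].
#'
#' @param target `"I"` (C1 only), `"S"` (C2 only) or `"both"` (hard pulse).
#' @param flip_angle Nominal flip angle in degrees.
#' @param phase Pulse phase in degrees (0 = x, 90 = y, 180 = x-bar, ...).
#' @param attenuation Amplitude retention factor in `[0, 1]` on the target.
#' @param leakage Fraction in `[0, 1]` of the nominal rotation applied to the
#'   non-target spin (ignored for `target = "both"`).
#' @return An object of class `pulse_event`.
#' @export
pulse_event <- function(target = c("I", "S", "both"), flip_angle = 90,
                        phase = 0, attenuation = 1, leakage = 0) {
  target <- match.arg(target)
  stopifnot(attenuation >= 0, attenuation <= 1, leakage >= 0, leakage <= 1)
  structure(list(target = target, flip_angle = flip_angle, phase = phase,
                 attenuation = attenuation, leakage = leakage),
            class = "pulse_event")
}

# 3x3 coefficient rotation for a pulse of angle beta about an axis at `phase`
# in the xy-plane, in the spin convention above (beta, phase in radians).
.rot3 <- function(beta, phase) {
  cb <- cos(beta); sb <- sin(beta)
  mx <- matrix(c(1, 0, 0,
                 0, cb, -sb,
                 0, sb, cb), 3L, 3L, byrow = TRUE)
  cp <- cos(phase); sp <- sin(phase)
  z <- matrix(c(cp, -sp, 0,
                sp, cp, 0,
                0, 0, 1), 3L, 3L, byrow = TRUE)
  z %*% mx %*% t(z)
}

.rotate_I <- function(m, R) { m[2:4, ] <- R %*% m[2:4, ]; m }
.rotate_S <- function(m, R) { m[, 2:4] <- m[, 2:4] %*% t(R); m }

#' Apply a pulse to a two-spin state
#'
#' The targeted spin is rotated by `flip_angle * attenuation` about the
#' in-plane axis set by `phase`; for a selective pulse the other spin is
#' rotated by `flip_angle * leakage` about the same axis. The map is unitary
#' for `attenuation = 1`, `leakage = 0`.
#'
#' @param state A [two_spin_state()].
#' @param pulse A [pulse_event()].
#' @return The rotated [two_spin_state()].
#' @export
apply_pulse <- function(state, pulse) {
  stopifnot(inherits(state, "two_spin_state"), inherits(pulse, "pulse_event"))
  beta <- pulse$flip_angle * pi / 180
  phase <- pulse$phase * pi / 180
  m <- .po_to_mat(state)
  if (pulse$target %in% c("I", "both"))
    m <- .rotate_I(m, .rot3(beta * pulse$attenuation, phase))
  if (pulse$target %in% c("S", "both"))
    m <- .rotate_S(m, .rot3(beta * pulse$attenuation, phase))
  if (pulse$leakage > 0 && pulse$target != "both") {
    R <- .rot3(beta * pulse$leakage, phase)
    m <- if (pulse$target == "I") .rotate_S(m, R) else .rotate_I(m, R)
  }
  .mat_to_po(m)
}

#' Free evolution under offsets and weak J coupling
#'
#' Evolves the state under the weak-coupling Hamiltonian
#' `2*pi*J IzSz` (+ offset terms unless `refocus_offsets`) for a time `t`,
#' using the analytic product-operator rotation rules. If the spin system has
#' finite `T2prime`, transverse coefficients of the respective spin are damped
#' by `exp(-t / T2prime)` (doubly transverse terms receive both factors).
#'
#' @param state A [two_spin_state()].
#' @param sys A [spin_system()].
#' @param t Evolution time in s (>= 0).
#' @param refocus_offsets If `TRUE`, the offset terms are omitted, as in the
#'   middle of a spin echo; J evolution and damping still apply.
#' @return The evolved [two_spin_state()].
#' @export
evolve_delay <- function(state, sys, t, refocus_offsets = FALSE) {
  stopifnot(inherits(state, "two_spin_state"), inherits(sys, "spin_system"))
  if (t < 0) stop("evolve_delay: t must be >= 0")
  m <- .po_to_mat(state)

  phi <- pi * sys$J_IS * t
  c1 <- cos(phi); s1 <- sin(phi)
  n <- m
  # Ix <-> 2IySz ; Iy <-> 2IxSz ; Sx <-> 2IzSy ; Sy <-> 2IzSx
  n[2, 1] <- c1 * m[2, 1] - s1 * m[3, 4]
  n[3, 4] <- c1 * m[3, 4] + s1 * m[2, 1]
  n[3, 1] <- c1 * m[3, 1] + s1 * m[2, 4]
  n[2, 4] <- c1 * m[2, 4] - s1 * m[3, 1]
  n[1, 2] <- c1 * m[1, 2] - s1 * m[4, 3]
  n[4, 3] <- c1 * m[4, 3] + s1 * m[1, 2]
  n[1, 3] <- c1 * m[1, 3] + s1 * m[4, 2]
  n[4, 2] <- c1 * m[4, 2] - s1 * m[1, 3]
  m <- n

  if (!refocus_offsets) {
    zrot <- function(th) matrix(c(cos(th), -sin(th), 0,
                                  sin(th), cos(th), 0,
                                  0, 0, 1), 3L, 3L, byrow = TRUE)
    if (sys$offset_I != 0) m <- .rotate_I(m, zrot(2 * pi * sys$offset_I * t))
    if (sys$offset_S != 0) m <- .rotate_S(m, zrot(2 * pi * sys$offset_S * t))
  }

  if (is.finite(sys$T2prime_I)) m[2:3, ] <- m[2:3, ] * exp(-t / sys$T2prime_I)
  if (is.finite(sys$T2prime_S)) m[, 2:3] <- m[, 2:3] * exp(-t / sys$T2prime_S)
  .mat_to_po(m)
}

#' z-filter projection
#'
#' Retains the longitudinal coefficients `Iz` and `Sz` (and the identity) and
#' zeroes every other coefficient, modelling CW dephasing of all remaining
#' transverse 13C coherences. The two-spin longitudinal order `2IzSz` is also
#' zeroed by default (conservative projector); set `keep_zz = TRUE` to retain
#' it.
#'
#' @param state A [two_spin_state()].
#' @param keep_zz Retain the `2IzSz` coefficient.
#' @return The projected [two_spin_state()].
#' @export
apply_zfilter <- function(state, keep_zz = FALSE) {
  stopifnot(inherits(state, "two_spin_state"))
  keep <- c("E", "Iz", "Sz", if (keep_zz) "IzSz")
  v <- unclass(state)
  v[setdiff(.po_names, keep)] <- 0
  structure(v, class = "two_spin_state")
}

#' Phase cycle for the selective transfer experiment
#'
#' For the perfect-echo and control variants `flipdown_phases` is the per-step
#' phase of the selective flip-down pulse; for the double-quantum variant it
#' is the phase shift applied to the whole excitation block (flip-down, first
#' echo pi pulse and first pi/2), which is what a coherence-order-selective
#' cycle shifts. `receiver_phases` is applied to the detected signal as
#' `exp(-i * phase)`.
#'
#' @param flipdown_phases,receiver_phases Numeric vectors of equal length
#'   (degrees); the canonical cycles have 8 steps.
#' @return An object of class `phase_cycle`.
#' @export
phase_cycle <- function(flipdown_phases, receiver_phases) {
  if (length(flipdown_phases) != length(receiver_phases))
    stop("phase_cycle: phase lists must have equal length")
  if (!length(flipdown_phases)) stop("phase_cycle: empty cycle")
  structure(list(flipdown_phases = as.numeric(flipdown_phases),
                 receiver_phases = as.numeric(receiver_phases),
                 n_steps = length(flipdown_phases)),
            class = "phase_cycle")
}

#' Default 8-step phase cycles
#'
#' `perfect_echo` / `control_no_pi2`: flip-down x,x,x,x,xb,xb,xb,xb with
#' receiver yb,yb,yb,yb,y,y,y,y, so that any component created before the
#' flip-down pulse and not re-excited by it cancels over the cycle.
#' `dq_filter`: excitation-block phase 0,90,180,270 (twice) with receiver
#' `-2*phi`, the standard delta-p = +/-2 double-quantum selection.
#'
#' @param variant Sequence variant name.
#' @return A [phase_cycle()].
#' @export
default_phase_cycle <- function(variant = c("perfect_echo", "control_no_pi2",
                                            "dq_filter")) {
  variant <- match.arg(variant)
  if (variant == "dq_filter") {
    blk <- rep(c(0, 90, 180, 270), 2L)
    phase_cycle(blk, (-2 * blk) %% 360)
  } else {
    phase_cycle(rep(c(0, 180), each = 4L), rep(c(270, 90), each = 4L))
  }
}

#' Simulate the selective 1D C1-to-C2 J-transfer experiment
#'
#' Runs, for every phase-cycle step: nonselective CP (initial state
#' `cp_amplitude["I"] * Ix + cp_amplitude["S"] * Sx`), a selective flip-back
#' pulse on C1 (90 deg about -y, storing C1 along +z), the z-filter, the
#' selective flip-down with the per-step cycle phase, and then one of
#'
#' * `perfect_echo`: `tau - pi(x) - tau - pi/2(-y) - tau - pi(x) - tau`,
#' * `control_no_pi2`: the same echo train without the pi/2 transfer pulse,
#' * `dq_filter`: `tau - pi - tau - pi/2 - pi/2(y) - tau - pi(x) - tau`, with
#'   the flip-down, first pi and first pi/2 sharing the cycled block phase.
#'
#' Detection is the complex in-phase amplitude `a_x + i a_y` on each spin; the
#' receiver phase is applied as `exp(-i phase)` and the phase-cycled result is
#' the mean of the detected per-step signals.
#'
#' @param sys A [spin_system()].
#' @param tau Echo delay tau in s (each echo lasts `2 tau`); default 4 ms.
#' @param cycle A [phase_cycle()]; defaults to [default_phase_cycle()] for the
#'   chosen variant.
#' @param variant One of `"perfect_echo"`, `"control_no_pi2"`, `"dq_filter"`.
#' @param selective A list with `attenuation` and `leakage` in `[0, 1]`
#'   applied to the two selective C1 pulses (see [pulse_event()]).
#' @param cp_amplitude Named numeric `c(I = , S = )` initial transverse
#'   amplitudes after CP.
#' @param zfilter Apply the z-filter after flip-back (disable to study how the
#'   cycle handles unfiltered coherences).
#' @param keep_zz Passed to [apply_zfilter()].
#' @param initial_state Optional [two_spin_state()] replacing the CP state,
#'   e.g. a residual coherence injected to study what the phase cycle
#'   cancels; flip-back and z-filter still run unless disabled.
#' @param trace If `TRUE`, keep named [two_spin_state()] snapshots per step.
#' @return An object of class `sequence_result`: a list with `per_step` (data
#'   frame of per-step complex signals and detected values), `cycled_I`,
#'   `cycled_S` (receiver-weighted means), `n_transfer_steps` (steps with
#'   `|signal_S|` above 1e-9 times the largest per-step amplitude), and the
#'   call parameters.
#' @export
run_transfer_experiment <- function(sys, tau = 4e-3, cycle = NULL,
                                    variant = c("perfect_echo",
                                                "control_no_pi2", "dq_filter"),
                                    selective = list(attenuation = 1, leakage = 0),
                                    cp_amplitude = c(I = 1, S = 1),
                                    zfilter = TRUE, keep_zz = FALSE,
                                    initial_state = NULL, trace = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(sys, "spin_system"))
  if (tau <= 0) stop("run_transfer_experiment: tau must be > 0")
  if (is.null(cycle)) cycle <- default_phase_cycle(variant)
  stopifnot(inherits(cycle, "phase_cycle"))
  att <- selective$attenuation %||% 1
  leak <- selective$leakage %||% 0

  n <- cycle$n_steps
  sig_I <- sig_S <- complex(n)
  traces <- if (trace) vector("list", n) else NULL

  for (k in seq_len(n)) {
    ph <- cycle$flipdown_phases[k]
    snap <- list()
    st <- if (is.null(initial_state))
      two_spin_state(Ix = unname(cp_amplitude["I"]),
                     Sx = unname(cp_amplitude["S"]))
    else initial_state
    if (trace) snap$after_cp <- st
    st <- apply_pulse(st, pulse_event("I", 90, 270, att, leak))   # flip-back
    if (trace) snap$after_flipback <- st
    if (zfilter) st <- apply_zfilter(st, keep_zz)
    if (trace) snap$after_zfilter <- st
    st <- apply_pulse(st, pulse_event("I", 90, ph, att, leak))    # flip-down
    if (trace) snap$after_flipdown <- st

    blk <- if (variant == "dq_filter") ph else 0
    st <- evolve_delay(st, sys, tau)
    st <- apply_pulse(st, pulse_event("both", 180, blk))
    st <- evolve_delay(st, sys, tau)
    if (trace) snap$after_echo1 <- st

    if (variant == "perfect_echo") {
      st <- apply_pulse(st, pulse_event("both", 90, 270))         # pi/2(-y)
    } else if (variant == "dq_filter") {
      st <- apply_pulse(st, pulse_event("both", 90, blk))         # DQ excitation
      st <- apply_pulse(st, pulse_event("both", 90, 90))          # reconversion (y)
    }
    if (trace) snap$after_transfer_pulse <- st

    st <- evolve_delay(st, sys, tau)
    st <- apply_pulse(st, pulse_event("both", 180, 0))
    st <- evolve_delay(st, sys, tau)
    if (trace) { snap$after_echo2 <- st; traces[[k]] <- snap }

    sig_I[k] <- st["Ix"] + 1i * st["Iy"]
    sig_S[k] <- st["Sx"] + 1i * st["Sy"]
  }

  rec <- exp(-1i * cycle$receiver_phases * pi / 180)
  det_I <- sig_I * rec
  det_S <- sig_S * rec
  amax <- max(abs(sig_S), abs(sig_I), 1e-300)
  structure(list(
    variant = variant, tau = tau, sys = sys, cycle = cycle,
    per_step = data.frame(step = seq_len(n),
                          flipdown_phase = cycle$flipdown_phases,
                          receiver_phase = cycle$receiver_phases,
                          signal_I = sig_I, signal_S = sig_S,
                          detected_I = det_I, detected_S = det_S),
    cycled_I = mean(det_I), cycled_S = mean(det_S),
    n_transfer_steps = sum(abs(sig_S) > 1e-9 * amax),
    state_trace = traces), class = "sequence_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sequence_result <- function(x, ...) {
  cat(sprintf("<sequence_result> %s, tau = %.3g ms, J = %.3g Hz, %d steps\n",
              x$variant, 1e3 * x$tau, x$sys$J_IS, nrow(x$per_step)))
  cat(sprintf("  cycled I: %.6g%+.6gi   cycled S: %.6g%+.6gi   transfer steps: %d/%d\n",
              Re(x$cycled_I), Im(x$cycled_I), Re(x$cycled_S), Im(x$cycled_S),
              x$n_transfer_steps, nrow(x$per_step)))
  invisible(x)
}

#' Export a sequence result as JSON
#'
#' @param result A `sequence_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequence_result <- function(result, path) {
  stopifnot(inherits(result, "sequence_result"))
  ps <- result$per_step
  out <- list(
    variant = result$variant, tau_s = result$tau, J_Hz = result$sys$J_IS,
    per_step = data.frame(step = ps$step, flipdown_phase = ps$flipdown_phase,
                          receiver_phase = ps$receiver_phase,
                          signal_I_re = Re(ps$signal_I), signal_I_im = Im(ps$signal_I),
                          signal_S_re = Re(ps$signal_S), signal_S_im = Im(ps$signal_S),
                          detected_I_re = Re(ps$detected_I), detected_I_im = Im(ps$detected_I),
                          detected_S_re = Re(ps$detected_S), detected_S_im = Im(ps$detected_S)),
    cycled = list(I_re = Re(result$cycled_I), I_im = Im(result$cycled_I),
                  S_re = Re(result$cycled_S), S_im = Im(result$cycled_S)),
    n_transfer_steps = result$n_transfer_steps)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Excitation profile of a truncated Gaussian shaped pulse
#'
#' Integrates the Bloch equations (rotations only, no relaxation) for a
#' Gaussian-amplitude pulse of the given duration, truncated so the edge
#' amplitude is `truncation` times the peak, with the peak calibrated so the
#' on-resonance flip equals `flip_angle`. Returns the longitudinal-to-
#' transverse conversion (the component along the nominal pulse phase,
#' in `[-1, 1]`) at each offset; at zero offset it equals
#' `sin(flip_angle)` to better than 1e-3.
#'
#' @param duration Pulse length in s (> 0); default the 1-ms pulse used for
#'   C1 selection.
#' @param truncation Edge/peak amplitude ratio in (0, 1); default 0.1.
#' @param flip_angle Nominal on-resonance flip in degrees.
#' @param offsets Numeric vector of resonance offsets in Hz.
#' @param n_steps Number of piecewise-constant integration steps.
#' @return A data frame with columns `offset_hz` and `profile`.
#' @export
shaped_pulse_profile <- function(duration = 1e-3, truncation = 0.1,
                                 flip_angle = 90, offsets = 0,
                                 n_steps = 400L) {
  if (duration <= 0) stop("shaped_pulse_profile: duration must be > 0")
  if (truncation <= 0 || truncation >= 1)
    stop("shaped_pulse_profile: truncation must be in (0, 1)")
  dt <- duration / n_steps
  tmid <- (seq_len(n_steps) - 0.5) * dt - duration / 2
  sigma <- (duration / 2) / sqrt(2 * log(1 / truncation))
  shape <- exp(-tmid^2 / (2 * sigma^2))
  w1 <- shape * (flip_angle * pi / 180) / (sum(shape) * dt)  # rad/s, calibrated

  profile <- vapply(offsets, function(off) {
    omega <- 2 * pi * off
    M <- c(0, 0, 1)
    for (j in seq_len(n_steps)) {
      u <- c(w1[j], 0, omega)
      nu <- sqrt(sum(u^2))
      if (nu == 0) next
      a <- u / nu; th <- nu * dt
      K <- matrix(c(0, -a[3], a[2],
                    a[3], 0, -a[1],
                    -a[2], a[1], 0), 3L, 3L, byrow = TRUE)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
      M <- as.numeric(R %*% M)
    }
    -M[2]  # an x-phase pulse rotates z towards -y
  }, numeric(1L))
  data.frame(offset_hz = as.numeric(offsets), profile = profile)
}

#' Default selective-pulse imperfection parameters
#'
#' Packs the two scalar imperfections used by [run_transfer_experiment()]:
#' the per-pulse amplitude retention (default `sqrt(0.5)`, so the two
#' selective pulses of the z-filter together retain about half of the C1
#' signal) and the artifact leakage onto C2, computed from the Bloch
#' excitation profile at the C1-C2 offset unless given explicitly.
#'
#' @param attenuation Per-pulse amplitude retention in `[0, 1]`.
#' @param leakage Fraction of the nominal rotation leaking onto the non-target
#'   spin; if `NULL`, `|profile|` of the shaped pulse at `offset_hz`.
#' @param offset_hz C1-C2 frequency separation in Hz (about 23 ppm at
#'   100.6 MHz).
#' @param duration,truncation Shaped-pulse parameters.
#' @return A list with `attenuation` and `leakage`.
#' @export
selective_imperfections <- function(attenuation = sqrt(0.5), leakage = NULL,
                                    offset_hz = 23 * 100.6,
                                    duration = 1e-3, truncation = 0.1) {
  if (is.null(leakage)) {
    pr <- shaped_pulse_profile(duration, truncation, 90, offset_hz)
    leakage <- min(1, abs(pr$profile[1L]))
  }
  list(attenuation = attenuation, leakage = leakage)
}
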