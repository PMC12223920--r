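#' Integration window in ppm
#'
#' Windows follow the display convention and are (high ppm, low ppm) pairs.
#'
#' @param hi,lo Window edges in ppm, `hi > lo`.
#' @return An object of class `ppm_window`.
#' @export
ppm_window <- function(hi, lo) {
  stopifnot(is.numeric(hi), is.numeric(lo), length(hi) == 1L, length(lo) == 1L)
  if (!(hi > lo)) stop("ppm_window: hi must be > lo")
  structure(list(hi = hi, lo = lo), class = "ppm_window")
}

#' Baseline-correction specification
#'
#' A polynomial order plus the anchor regions (signal-free stretches, e.g.
#' between the large C1 peak and its first spinning sidebands) the polynomial
#' is fitted to.
#'
#' @param order Polynomial order (>= 0); default 5.
#' @param anchor_regions A list of [ppm_window()] objects, pairwise disjoint.
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(order = 5L, anchor_regions = list()) {
  stopifnot(order >= 0, is.list(anchor_regions))
  for (w in anchor_regions)
    if (!inherits(w, "ppm_window")) stop("baseline_spec: anchors must be ppm_window objects")
  if (length(anchor_regions) > 1L) {
    b <- do.call(rbind, lapply(anchor_regions, function(w) c(w$lo, w$hi)))
    b <- b[order(b[, 1L]), , drop = FALSE]
    if (any(b[-1L, 1L] < b[-nrow(b), 2L]))
      stop("baseline_spec: anchor regions must be pairwise disjoint")
  }
  structure(list(order = as.integer(order), anchor_regions = anchor_regions),
            class = "baseline_spec")
}

#' Default baseline anchor regions between C1 and its first sidebands
#'
#' Builds the two broad signal-free regions (190, 115) and (60, 10) ppm,
#' clipped to the spectrum axis, with the first-sideband positions of the C1
#' peak (`c1_ppm +/- mas_rate_kHz * 1000 / spectrometer_freq_MHz` ppm)
#' excluded with a configurable half-width.
#'
#' @param spec A [spectrum1d()]; its metadata supply MAS rate and frequency.
#' @param c1_ppm Chemical shift of the C1 peak (default 103 ppm).
#' @param exclusion_halfwidth Half-width in ppm removed around each sideband.
#' @return A list of [ppm_window()] objects.
#' @export
default_anchor_regions <- function(spec, c1_ppm = 103,
                                   exclusion_halfwidth = 4) {
  stopifnot(inherits(spec, "spectrum1d"))
  sb_off <- spec$meta$mas_rate * 1000 / spec$meta$spectrometer_freq_13C
  excl <- if (sb_off > 0)
    list(c(c1_ppm + sb_off - exclusion_halfwidth,
           c1_ppm + sb_off + exclusion_halfwidth),
         c(c1_ppm - sb_off - exclusion_halfwidth,
           c1_ppm - sb_off + exclusion_halfwidth)) else list()
  base <- list(c(115, 190), c(10, 60))  # (lo, hi)
  rng <- range(spec$ppm)
  out <- list()
  for (b in base) {
    segs <- list(b)
    for (e in excl) {
      segs <- unlist(lapply(segs, function(s) {
        if (e[2] <= s[1] || e[1] >= s[2]) return(list(s))
        keep <- list()
        if (e[1] > s[1]) keep <- c(keep, list(c(s[1], e[1])))
        if (e[2] < s[2]) keep <- c(keep, list(c(e[2], s[2])))
        keep
      }), recursive = FALSE)
    }
    for (s in segs) {
      lo <- max(s[1], rng[1]); hi <- min(s[2], rng[2])
      if (hi > lo) out <- c(out, list(ppm_window(hi, lo)))
    }
  }
  out
}

# discrete Hilbert transform: imaginary part of the analytic signal
.hilbert_imag <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  Im(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Zero- and first-order phase correction
#'
#' Applies the rotation `exp(i * (ph0 + ph1 * (ppm - pivot) / span))` to the
#' complex spectrum, where `span` is the full axis width, so `ph1` is the
#' phase ramp across the whole spectrum. For real-only data the imaginary
#' component is reconstructed by a discrete Hilbert transform before a
#' zero-order rotation; first-order phasing of real-only data is refused
#' because the reconstruction is not reliable far from the carrier. The
#' result carries its imaginary part, so phasing by `ph0` then `-ph0` is an
#' exact identity.
#'
#' @param spec A [spectrum1d()], complex (with `imag`) or real-only.
#' @param ph0 Zero-order phase in degrees.
#' @param ph1 First-order phase in degrees across the full spectral width.
#' @param pivot Pivot for the first-order term, in ppm (default: axis centre).
#' @return The phased [spectrum1d()] (always complex on output).
#' @export
phase_correct <- function(spec, ph0 = 0, ph1 = 0, pivot = NULL) {
  stopifnot(inherits(spec, "spectrum1d"))
  if (is.null(spec$imag)) {
    if (ph1 != 0)
      stop("phase_correct: first-order phasing requires complex data; ",
           "this spectrum is real-only")
    imag <- .hilbert_imag(spec$intensity)
  } else imag <- spec$imag
  if (is.null(pivot)) pivot <- mean(range(spec$ppm))
  span <- diff(range(spec$ppm))
  phi <- (ph0 + ph1 * (spec$ppm - pivot) / span) * pi / 180
  z <- complex(real = spec$intensity, imaginary = imag) * exp(1i * phi)
  spectrum1d(spec$ppm, Re(z), meta = spec$meta, imag = Im(z))
}

#' Anchored polynomial baseline correction
#'
#' Fits a polynomial of the given order to the spectrum intensity in the
#' anchor regions only (least squares, with the ppm axis affinely scaled to
#' `[-1, 1]` for conditioning) and subtracts it everywhere. At least
#' `2 * (order + 1)` anchor points are required.
#'
#' @param spec A [spectrum1d()].
#' @param bspec A [baseline_spec()]; anchors must lie within the axis range.
#' @return A list of class `baseline_fit` with `baseline` (fitted vector),
#'   `corrected` (the baseline-subtracted [spectrum1d()]), `anchor_index`
#'   (logical mask of anchor points) and `order`.
#' @export
fit_baseline <- function(spec, bspec) {
  stopifnot(inherits(spec, "spectrum1d"), inherits(bspec, "baseline_spec"))
  if (!length(bspec$anchor_regions))
    stop("fit_baseline: no anchor regions supplied")
  mask <- rep(FALSE, length(spec$ppm))
  rng <- range(spec$ppm)
  for (w in bspec$anchor_regions) {
    if (w$lo < rng[1] - 1e-9 || w$hi > rng[2] + 1e-9)
      stop(sprintf("fit_baseline: anchor region (%.4g, %.4g) outside axis range",
                   w$hi, w$lo))
    mask <- mask | (spec$ppm >= w$lo & spec$ppm <= w$hi)
  }
  need <- 2L * (bspec$order + 1L)
  if (sum(mask) <= need)
    stop("fit_baseline: ", sum(mask), " anchor points for order ",
         bspec$order, "; more than ", need, " are required")
  u <- 2 * (spec$ppm - rng[1]) / (rng[2] - rng[1]) - 1
  if (bspec$order == 0L) {
    bl <- rep(mean(spec$intensity[mask]), length(u))
  } else {
    fitdf <- data.frame(y = spec$intensity[mask], u = u[mask])
    fit <- stats::lm(y ~ stats::poly(u, degree = bspec$order, raw = TRUE),
                     data = fitdf)
    bl <- as.numeric(stats::predict(fit, newdata = data.frame(u = u)))
  }
  corrected <- spectrum1d(spec$ppm, spec$intensity - bl, meta = spec$meta,
                          imag = spec$imag)
  structure(list(baseline = bl, corrected = corrected,
                 anchor_index = mask, order = bspec$order),
            class = "baseline_fit")
}

#' Subtract the control spectrum from the transfer spectrum
#'
#' Difference spectroscopy: `transfer - scale * control`. By default the
#' control is normalized per scan (scaled by the ratio of scan counts) and
#' otherwise subtracted 1:1. If the two axes differ the control is resampled
#' onto the transfer axis by linear interpolation; axes whose ranges do not
#' cover each other beyond a small tolerance are rejected. Optionally the
#' scale can be refined by least squares over an artifact-only window.
#'
#' @param transfer,control Baseline-corrected [spectrum1d()] objects.
#' @param scale Scale factor for the control; `NULL` (default) uses the scan
#'   count ratio `n_scans(transfer) / n_scans(control)`.
#' @param lsq_window Optional [ppm_window()]: refine `scale` by least squares
#'   of `transfer - s * control` over this window (off by default; the
#'   reference procedure subtracts 1:1 per scan).
#' @return The difference [spectrum1d()] (metadata from `transfer`).
#' @export
subtract_control <- function(transfer, control, scale = NULL,
                             lsq_window = NULL) {
  stopifnot(inherits(transfer, "spectrum1d"), inherits(control, "spectrum1d"))
  tol <- 1e-6 * diff(range(transfer$ppm))
  ctrl_y <- if (length(control$ppm) == length(transfer$ppm) &&
                max(abs(control$ppm - transfer$ppm)) <= tol) {
    control$intensity
  } else {
    if (min(control$ppm) > min(transfer$ppm) + tol ||
        max(control$ppm) < max(transfer$ppm) - tol)
      stop("subtract_control: control axis does not cover the transfer axis")
    stats::approx(control$ppm, control$intensity, xout = transfer$ppm,
                  rule = 1)$y
  }
  if (is.null(scale))
    scale <- transfer$meta$n_scans / control$meta$n_scans
  if (!is.null(lsq_window)) {
    stopifnot(inherits(lsq_window, "ppm_window"))
    idx <- transfer$ppm >= lsq_window$lo & transfer$ppm <= lsq_window$hi
    if (sum(ctrl_y[idx]^2) == 0)
      stop("subtract_control: control is zero in the least-squares window")
    scale <- sum(transfer$intensity[idx] * ctrl_y[idx]) / sum(ctrl_y[idx]^2)
  }
  spectrum1d(transfer$ppm, transfer$intensity - scale * ctrl_y,
             meta = transfer$meta)
}

#' Trapezoidal integral over a ppm window
#'
#' Integrates the intensity over `[lo, hi)` with respect to ppm, interpolating
#' the intensity at the exact window edges, so the integral is additive over
#' adjacent windows sharing a boundary: the shared edge contributes to each
#' side exactly once.
#'
#' @param spec A [spectrum1d()].
#' @param window A [ppm_window()] inside the axis range.
#' @return The integral in (intensity units) * ppm.
#' @export
integrate_window <- function(spec, window) {
  stopifnot(inherits(spec, "spectrum1d"), inherits(window, "ppm_window"))
  rng <- range(spec$ppm)
  if (window$lo < rng[1] || window$hi > rng[2])
    stop(sprintf("integrate_window: window (%.4g, %.4g) outside axis range [%.4g, %.4g]",
                 window$hi, window$lo, rng[1], rng[2]))
  inside <- which(spec$ppm < window$hi & spec$ppm > window$lo)
  y_hi <- stats::approx(spec$ppm, spec$intensity, xout = window$hi)$y
  y_lo <- stats::approx(spec$ppm, spec$intensity, xout = window$lo)$y
  x <- c(window$hi, spec$ppm[inside], window$lo)      # descending
  y <- c(y_hi, spec$intensity[inside], y_lo)
  sum((y[-1L] + y[-length(y)]) / 2 * (x[-length(x)] - x[-1L]))
}

#' Percent C2 substitution from a difference spectrum
#'
#' Integrates the baseline-corrected difference spectrum over the substituted
#' (default 90.1-80.4 ppm) and free (default 80.4-71.9 ppm) C2 windows and
#' reports `100 * I_sub / (I_sub + I_free)`. The windows are adjacent and the
#' shared 80.4 ppm boundary is counted once on each side (half-open
#' convention). Negative integrals, which occur at low signal-to-noise, are
#' reported as-is with a warning; the percentage is clamped to `[0, 100]`
#' only in [summary.quant_result()], never in the stored values.
#'
#' @param diff_spec A baseline-corrected difference [spectrum1d()].
#' @param window_sub Window assigned to substituted C2.
#' @param window_free Window assigned to free (non-substituted) C2.
#' @param provenance Character vector of processing steps already applied;
#'   extended and stored in the result.
#' @return An object of class `quant_result` with fields `integral_sub`,
#'   `integral_free`, `pct_substituted`, `uncertainty_pct` (`NA` until set by
#'   [estimate_uncertainty()]), `window_sub`, `window_free`, `provenance`.
#' @export
c2_fraction <- function(diff_spec,
                        window_sub = ppm_window(90.1, 80.4),
                        window_free = ppm_window(80.4, 71.9),
                        provenance = character()) {
  i_sub <- integrate_window(diff_spec, window_sub)
  i_free <- integrate_window(diff_spec, window_free)
  if (i_sub <= 0 && i_free <= 0)
    stop("c2_fraction: both window integrals are <= 0; no signal to quantify")
  if (i_sub < 0 || i_free < 0)
    warning("c2_fraction: a window integral is negative (low signal-to-noise); ",
            "reported as-is")
  pct <- 100 * i_sub / (i_sub + i_free)
  prov <- c(provenance,
            sprintf("integrate: sub (%.4g, %.4g) = %.6g; free (%.4g, %.4g) = %.6g",
                    window_sub$hi, window_sub$lo, i_sub,
                    window_free$hi, window_free$lo, i_free),
            sprintf("pct_substituted = %.6g", pct))
  structure(list(integral_sub = i_sub, integral_free = i_free,
                 pct_substituted = pct, uncertainty_pct = NA_real_,
                 window_sub = window_sub, window_free = window_free,
                 provenance = prov),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  unc <- if (is.na(x$uncertainty_pct)) "" else sprintf(" +/- %.3g", x$uncertainty_pct)
  cat(sprintf("<quant_result> %% C2 substituted (%.4g-%.4g ppm): %.3g%s\n",
              x$window_sub$hi, x$window_sub$lo, x$pct_substituted, unc))
  cat(sprintf("  integrals: substituted %.6g, free %.6g\n",
              x$integral_sub, x$integral_free))
  invisible(x)
}

#' @export
summary.quant_result <- function(object, ...) {
  data.frame(pct_substituted = min(100, max(0, object$pct_substituted)),
             uncertainty_pct = object$uncertainty_pct,
             integral_sub = object$integral_sub,
             integral_free = object$integral_free)
}

#' Full transfer/control quantification pipeline
#'
#' Phase correction (if requested), anchored polynomial baseline correction of
#' transfer and control, control subtraction (per-scan 1:1 by default), and
#' windowed integration, with every step appended to the provenance log.
#'
#' @param transfer,control [spectrum1d()] objects (raw or pre-phased).
#' @param ph0,ph1 Phase correction applied to both spectra (degrees).
#' @param bspec A [baseline_spec()]; `NULL` uses order 5 with
#'   [default_anchor_regions()].
#' @param window_sub,window_free Integration windows, as in [c2_fraction()].
#' @param scale,lsq_window Passed to [subtract_control()].
#' @return A `quant_result` (see [c2_fraction()]).
#' @export
quantify_c2 <- function(transfer, control, ph0 = 0, ph1 = 0, bspec = NULL,
                        window_sub = ppm_window(90.1, 80.4),
                        window_free = ppm_window(80.4, 71.9),
                        scale = NULL, lsq_window = NULL) {
  prov <- character()
  if (ph0 != 0 || ph1 != 0) {
    transfer <- phase_correct(transfer, ph0, ph1)
    control <- phase_correct(control, ph0, ph1)
    prov <- c(prov, sprintf("phase: ph0 = %.4g, ph1 = %.4g", ph0, ph1))
  }
  if (is.null(bspec))
    bspec <- baseline_spec(5L, default_anchor_regions(transfer))
  transfer_c <- fit_baseline(transfer, bspec)$corrected
  control_c <- fit_baseline(control, bspec)$corrected
  prov <- c(prov, sprintf("baseline: order %d, %d anchor regions",
                          bspec$order, length(bspec$anchor_regions)))
  eff_scale <- if (is.null(scale))
    transfer$meta$n_scans / control$meta$n_scans else scale
  diff_spec <- subtract_control(transfer_c, control_c, scale = scale,
                                lsq_window = lsq_window)
  prov <- c(prov, sprintf("subtract control: scale = %.6g%s", eff_scale,
                          if (is.null(lsq_window)) "" else " (least-squares)"))
  c2_fraction(diff_spec, window_sub, window_free, provenance = prov)
}

#' Uncertainty of the percent-substitution estimate
#'
#' Three estimators:
#' * `replicate_sd`: sample standard deviation of `pct_substituted` across
#'   two or more replicate `quant_result`s.
#' * `noise_propagation`: seeded Monte-Carlo resampling - Gaussian noise of
#'   amplitude `noise_sigma` is added to the difference spectrum and the
#'   integration repeated `n_mc` times; the sd of the resulting percentages
#'   is returned.
#' * `anchor_perturbation`: the quantification is repeated with every anchor
#'   region boundary jittered uniformly within `+/- jitter` ppm (seeded); the
#'   spread quantifies the subjectivity of the baseline choice.
#'
#' The relative uncertainty of a reference sample can be transferred to
#' another with [transfer_relative_uncertainty()].
#'
#' @param results A list of `quant_result`s (`replicate_sd`) or a single one.
#' @param mode Estimator, see above.
#' @param diff_spec Difference spectrum (`noise_propagation`).
#' @param noise_sigma Noise amplitude for resampling (required for
#'   `noise_propagation`); estimate it from a signal-free region.
#' @param n_mc Number of Monte-Carlo draws.
#' @param transfer,control,bspec Pipeline inputs (`anchor_perturbation`).
#' @param jitter Anchor-boundary jitter half-width in ppm.
#' @param n_perturb Number of jittered re-runs.
#' @param seed Integer seed controlling both stochastic modes.
#' @param ... Extra arguments passed to [c2_fraction()] / [quantify_c2()].
#' @return Uncertainty in percentage points (one standard deviation).
#' @export
estimate_uncertainty <- function(results = NULL,
                                 mode = c("replicate_sd", "noise_propagation",
                                          "anchor_perturbation"),
                                 diff_spec = NULL, noise_sigma = NULL,
                                 n_mc = 100L, transfer = NULL, control = NULL,
                                 bspec = NULL, jitter = 2, n_perturb = 20L,
                                 seed = 1L, ...) {
  mode <- match.arg(mode)
  if (mode == "replicate_sd") {
    if (!is.list(results) || length(results) < 2L)
      stop("estimate_uncertainty: replicate_sd requires at least 2 results")
    pct <- vapply(results, function(r) r$pct_substituted, numeric(1L))
    return(stats::sd(pct))
  }
  if (mode == "noise_propagation") {
    if (is.null(diff_spec) || is.null(noise_sigma))
      stop("estimate_uncertainty: noise_propagation needs diff_spec and noise_sigma")
    pct <- withr::with_seed(seed, vapply(seq_len(n_mc), function(i) {
      noisy <- spectrum1d(diff_spec$ppm,
                          diff_spec$intensity +
                            stats::rnorm(length(diff_spec$ppm), 0, noise_sigma),
                          meta = diff_spec$meta)
      c2_fraction(noisy, ...)$pct_substituted
    }, numeric(1L)))
    return(stats::sd(pct))
  }
  # anchor_perturbation
  if (is.null(transfer) || is.null(control))
    stop("estimate_uncertainty: anchor_perturbation needs transfer and control")
  if (is.null(bspec))
    bspec <- baseline_spec(5L, default_anchor_regions(transfer))
  pct <- withr::with_seed(seed, vapply(seq_len(n_perturb), function(i) {
    regions <- lapply(bspec$anchor_regions, function(w) {
      repeat {
        hi <- w$hi + stats::runif(1, -jitter, jitter)
        lo <- w$lo + stats::runif(1, -jitter, jitter)
        hi <- min(hi, max(transfer$ppm)); lo <- max(lo, min(transfer$ppm))
        if (hi > lo) return(ppm_window(hi, lo))
      }
    })
    bs <- tryCatch(baseline_spec(bspec$order, regions),
                   error = function(e) bspec)  # jitter made regions overlap
    quantify_c2(transfer, control, bspec = bs, ...)$pct_substituted
  }, numeric(1L)))
  stats::sd(pct)
}

#' Transfer a reference sample's relative uncertainty
#'
#' When only one sample has replicate measurements, its relative standard
#' deviation can be carried over: `target_pct * ref_sd / ref_pct`.
#'
#' @param ref_pct,ref_sd Reference percentage and its sd.
#' @param target_pct Percentage of the sample the uncertainty is applied to.
#' @return Uncertainty in percentage points.
#' @export
transfer_relative_uncertainty <- function(ref_pct, ref_sd, target_pct) {
  stopifnot(ref_pct > 0, ref_sd >= 0)
  target_pct * ref_sd / ref_pct
}
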