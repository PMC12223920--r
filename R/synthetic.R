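#' Analytic peak specification
#'
#' @param center Peak position in ppm.
#' @param area Integrated area in a.u. * ppm.
#' @param fwhm Full width at half maximum in ppm (> 0); default 1.5 ppm,
#'   matching the broad lines of highly amorphous cellulose ethers.
#' @param shape `"lorentzian"`, `"gaussian"` or `"pseudo_voigt"`.
#' @param eta Lorentzian mixing fraction for `pseudo_voigt` (in `[0, 1]`).
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(center, area, fwhm = 1.5,
                      shape = c("lorentzian", "gaussian", "pseudo_voigt"),
                      eta = 0.5) {
  shape <- match.arg(shape)
  stopifnot(fwhm > 0, is.finite(area), eta >= 0, eta <= 1)
  structure(list(center = center, area = area, fwhm = fwhm, shape = shape,
                 eta = eta), class = "peak_spec")
}

# area-normalized lineshapes evaluated on an x grid
.lineshape <- function(x, pk) {
  lor <- function(x) {
    g <- pk$fwhm / 2
    (1 / pi) * g / ((x - pk$center)^2 + g^2)
  }
  gau <- function(x) {
    s <- pk$fwhm / (2 * sqrt(2 * log(2)))
    exp(-(x - pk$center)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  }
  base <- switch(pk$shape,
                 lorentzian = lor(x),
                 gaussian = gau(x),
                 pseudo_voigt = pk$eta * lor(x) + (1 - pk$eta) * gau(x))
  pk$area * base
}

#' Synthetic scene specification
#'
#' Everything needed to generate one synthetic 1D spectrum bit-reproducibly:
#' the analytic peaks, optional spinning sidebands of one parent peak,
#' polynomial baseline drift, the noise level and the RNG seed.
#'
#' @param peaks A list of [peak_spec()] objects.
#' @param sideband_parent Optional `list(index =, rel_amp =)`: the peak whose
#'   first spinning sidebands (at `center +/- mas_rate_kHz * 1000 /
#'   spectrometer_freq_MHz` ppm) are added with area `rel_amp` times the
#'   parent area.
#' @param baseline_poly Coefficients (constant first) of a polynomial in the
#'   axis scaled to `[-1, 1]`, added as baseline drift.
#' @param noise_sigma Standard deviation of the additive white Gaussian noise
#'   (a.u., amplitude-independent).
#' @param seed Integer RNG seed; generation is bit-reproducible for a fixed
#'   seed and leaves the global RNG state untouched.
#' @param axis `c(hi, lo, n)`: ppm range (descending) and number of points
#'   (>= 64).
#' @param meta An [acquisition_meta()]; supplies the MAS rate and frequency
#'   for sideband placement and is carried into the spectrum.
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(peaks, sideband_parent = NULL,
                            baseline_poly = 0, noise_sigma = 0, seed = 1L,
                            axis = c(hi = 220, lo = -20, n = 4096),
                            meta = acquisition_meta()) {
  stopifnot(is.list(peaks), noise_sigma >= 0)
  for (p in peaks) if (!inherits(p, "peak_spec"))
    stop("synthetic_scene: peaks must be peak_spec objects")
  if (axis[[3L]] < 64L) stop("synthetic_scene: axis must have >= 64 points")
  if (axis[[1L]] <= axis[[2L]]) stop("synthetic_scene: axis hi must exceed lo")
  structure(list(peaks = peaks, sideband_parent = sideband_parent,
                 baseline_poly = as.numeric(baseline_poly),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 axis = c(hi = axis[[1L]], lo = axis[[2L]], n = axis[[3L]]),
                 meta = meta),
            class = "synthetic_scene")
}

#' Render a synthetic scene into a spectrum
#'
#' Sums the analytic lineshapes, adds first-order spinning sidebands of the
#' designated parent peak, the baseline polynomial and seeded Gaussian noise.
#' Peaks whose centre falls outside the axis are kept (truncated tails) with
#' a warning.
#'
#' @param scene A [synthetic_scene()].
#' @return A [spectrum1d()] whose metadata label records the seed.
#' @export
make_spectrum <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  n <- as.integer(scene$axis[["n"]])
  x <- seq(scene$axis[["hi"]], scene$axis[["lo"]], length.out = n)
  y <- numeric(n)
  all_peaks <- scene$peaks
  if (!is.null(scene$sideband_parent)) {
    par_pk <- scene$peaks[[scene$sideband_parent$index]]
    sb_off <- scene$meta$mas_rate * 1000 / scene$meta$spectrometer_freq_13C
    for (s in c(-1, 1)) {
      sb <- par_pk
      sb$center <- par_pk$center + s * sb_off
      sb$area <- par_pk$area * scene$sideband_parent$rel_amp
      all_peaks <- c(all_peaks, list(sb))
    }
  }
  outside <- vapply(all_peaks, function(p)
    p$center > x[1L] || p$center < x[n], logical(1L))
  if (any(outside))
    warning("make_spectrum: ", sum(outside),
            " peak(s) outside the axis; tails truncated")
  for (p in all_peaks) y <- y + .lineshape(x, p)
  if (any(scene$baseline_poly != 0)) {
    u <- 2 * (x - x[n]) / (x[1L] - x[n]) - 1
    y <- y + as.numeric(outer(u, seq_along(scene$baseline_poly) - 1L, `^`) %*%
                          scene$baseline_poly)
  }
  if (scene$noise_sigma > 0)
    y <- y + withr::with_seed(scene$seed,
                              stats::rnorm(n, 0, scene$noise_sigma))
  meta <- scene$meta
  meta$label <- sprintf("%s [synthetic seed=%d]", meta$label, scene$seed)
  spectrum1d(x, y, meta = meta)
}

#' Synthetic transfer/control spectrum pair with known ground truth
#'
#' Emulates the output of the selective 1D J-transfer experiment and its
#' control: the transfer spectrum contains substituted-C2 (84 ppm) and free-C2
#' (75 ppm) peaks with area ratio `p : (1 - p)`, a residual C1 peak (103 ppm)
#' with first spinning sidebands, a broad z-filter artifact near 80 ppm, a
#' polynomial baseline drift and white noise; the control contains everything
#' except the C2 transfer peaks. The C1/C2 lines are Gaussian by default,
#' reflecting the inhomogeneous broadening of these highly amorphous
#' polymers (Gaussian tails are also negligible at the integration-window
#' edges, unlike Lorentzian ones); the artifact is a broad pseudo-Voigt. The
#' signal-to-noise ratio is defined as the larger noiseless C2 peak height
#' divided by the noise sigma. The transfer and control noise realizations
#' are independent (derived seeds).
#'
#' @param p_substituted True fraction of substituted C2 in `[0, 1]`.
#' @param snr Signal-to-noise ratio (> 0); `Inf` disables noise.
#' @param artifact_amp Artifact area as a fraction of the total C2 area.
#' @param seed Integer seed recorded in the truth record.
#' @param c2_area Total C2 area (a.u. * ppm).
#' @param c1_area Residual C1 area.
#' @param fwhm Line width of the C1/C2 peaks in ppm.
#' @param shape Lineshape of the C1/C2 peaks.
#' @param baseline_poly Baseline drift coefficients (scaled-axis polynomial).
#' @param axis `c(hi, lo, n)` axis specification.
#' @param meta An [acquisition_meta()].
#' @return A list with `transfer`, `control` ([spectrum1d()]s) and `truth`,
#'   a record of every generation parameter needed to score a downstream
#'   estimate (`p_substituted`, `pct_substituted`, `snr`, `noise_sigma`,
#'   `artifact_amp`, areas, centres, `seed`).
#' @export
make_transfer_pair <- function(p_substituted, snr = 20, artifact_amp = 0.1,
                               seed = 1L, c2_area = 10, c1_area = 40,
                               fwhm = 1.5, shape = "gaussian",
                               baseline_poly = c(0.05, 0.08, -0.06,
                                                 0.04, 0.03, -0.02),
                               axis = c(hi = 220, lo = -20, n = 8192),
                               meta = acquisition_meta(n_scans = 2048L)) {
  if (p_substituted < 0 || p_substituted > 1)
    stop("make_transfer_pair: p_substituted must be in [0, 1]")
  if (snr <= 0) stop("make_transfer_pair: snr must be > 0")
  if (artifact_amp < 0) stop("make_transfer_pair: artifact_amp must be >= 0")

  centers <- c(c1 = 103, c2_sub = 84, artifact = 80, c2_free = 75)
  c2_peaks <- list()
  if (p_substituted > 0)
    c2_peaks <- c(c2_peaks, list(peak_spec(centers[["c2_sub"]],
                                           p_substituted * c2_area, fwhm,
                                           shape = shape)))
  if (p_substituted < 1)
    c2_peaks <- c(c2_peaks, list(peak_spec(centers[["c2_free"]],
                                           (1 - p_substituted) * c2_area, fwhm,
                                           shape = shape)))
  common <- list(peak_spec(centers[["c1"]], c1_area, fwhm, shape = shape))
  if (artifact_amp > 0)
    common <- c(common, list(peak_spec(centers[["artifact"]],
                                       artifact_amp * c2_area, fwhm = 3,
                                       shape = "pseudo_voigt", eta = 0.5)))
  # SNR reference: larger noiseless C2 peak height
  a_big <- max(p_substituted, 1 - p_substituted) * c2_area
  height <- if (shape == "gaussian") {
    a_big / (fwhm / (2 * sqrt(2 * log(2))) * sqrt(2 * pi))
  } else a_big * 2 / (pi * fwhm)
  sigma <- if (is.finite(snr)) height / snr else 0

  scene_t <- synthetic_scene(c(common, c2_peaks),
                             sideband_parent = list(index = 1L, rel_amp = 0.15),
                             baseline_poly = baseline_poly,
                             noise_sigma = sigma, seed = seed,
                             axis = axis, meta = meta)
  scene_c <- synthetic_scene(common,
                             sideband_parent = list(index = 1L, rel_amp = 0.15),
                             baseline_poly = baseline_poly,
                             noise_sigma = sigma,
                             seed = seed + 1000003L,
                             axis = axis, meta = meta)
  list(transfer = make_spectrum(scene_t),
       control = make_spectrum(scene_c),
       truth = list(p_substituted = p_substituted,
                    pct_substituted = 100 * p_substituted,
                    snr = snr, noise_sigma = sigma,
                    artifact_amp = artifact_amp,
                    c2_area = c2_area, c1_area = c1_area, fwhm = fwhm,
                    shape = shape,
                    centers = as.list(centers), seed = seed,
                    control_seed = seed + 1000003L))
}

#' Generate noisy recovery curves from a set of swelling models
#'
#' One seeded noisy [relaxation_curve()] per model; paired microwave on/off
#' models at the same position in `models` share the underlying geometry by
#' construction of the caller.
#'
#' @param models A list of [swelling_model()] objects.
#' @param delays Recovery delay grid (s).
#' @param noise_sigma Additive Gaussian noise sd (amplitude-independent).
#' @param seed Integer seed; curve `i` uses `seed + i - 1`.
#' @return A list of [relaxation_curve()] objects.
#' @export
make_recovery_set <- function(models, delays, noise_sigma = 0, seed = 1L) {
  stopifnot(is.list(models))
  lapply(seq_along(models), function(i) {
    cv <- simulate_swelling_curve(models[[i]], delays)
    if (noise_sigma > 0)
      cv$amplitudes <- cv$amplitudes +
        withr::with_seed(seed + i - 1L,
                         stats::rnorm(length(delays), 0, noise_sigma))
    cv
  })
}

#' Place simulated sequence amplitudes on a ppm axis
#'
#' Bridges the pulse-sequence simulator and the spectrum domain: the real
#' parts of the phase-cycled detected I and S amplitudes become areas of
#' lineshapes at the configured C1 and C2 chemical shifts, so tau-dependence
#' studies of the transfer can be rendered and integrated like measured
#' spectra.
#'
#' @param result A `sequence_result` from [run_transfer_experiment()].
#' @param shift_I,shift_S Chemical shifts (ppm) at which to place the C1 and
#'   C2 amplitudes.
#' @param area_scale Area corresponding to unit detected amplitude.
#' @param fwhm Line width in ppm.
#' @param axis `c(hi, lo, n)` axis specification.
#' @param meta An [acquisition_meta()].
#' @return A [spectrum1d()] (zero spectrum if both amplitudes vanish).
#' @export
spinsim_to_spectrum <- function(result, shift_I = 103, shift_S = 84,
                                area_scale = 1, fwhm = 1.5,
                                axis = c(hi = 220, lo = -20, n = 4096),
                                meta = acquisition_meta()) {
  stopifnot(inherits(result, "sequence_result"))
  n <- as.integer(axis[[3L]])
  x <- seq(axis[[1L]], axis[[2L]], length.out = n)
  y <- numeric(n)
  amps <- c(Re(result$cycled_I), Re(result$cycled_S))
  shifts <- c(shift_I, shift_S)
  for (j in 1:2) {
    if (amps[j] == 0) next
    y <- y + .lineshape(x, peak_spec(shifts[j], amps[j] * area_scale, fwhm))
  }
  spectrum1d(x, y, meta = meta)
}
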