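lorentz <- function(x, x0, fwhm, area = 1) {
  g <- fwhm / 2
  area * (1 / pi) * g / ((x - x0)^2 + g^2)
}

dispersive_lorentz <- function(x, x0, fwhm, area = 1) {
  g <- fwhm / 2
  -area * (1 / pi) * (x - x0) / ((x - x0)^2 + g^2)
}

test_that("phase rotation recovers an absorptive line from a dispersive one", {
  x <- seq(120, 40, length.out = 4096)
  s <- spectrum1d(x, dispersive_lorentz(x, 80, 2))
  expect_equal(phase_correct(s, 0, 0)$intensity, s$intensity, tolerance = 1e-12)
  ph <- phase_correct(s, 90)
  expect_equal(ph$ppm[which.max(ph$intensity)], 80, tolerance = 0.05)
  expect_gt(max(ph$intensity), 0.9 * lorentz(80, 80, 2))
})

test_that("phasing by a then -a is an exact identity on complex data", {
  x <- seq(120, 40, length.out = 1024)
  s <- spectrum1d(x, lorentz(x, 80, 2), imag = dispersive_lorentz(x, 80, 2))
  back <- phase_correct(phase_correct(s, 37.5, 12), -37.5, -12)
  expect_equal(back$intensity, s$intensity, tolerance = 1e-10)
  expect_equal(back$imag, s$imag, tolerance = 1e-10)
})

test_that("first-order phasing of real-only data is refused", {
  s <- spectrum1d(seq(10, 0, length.out = 128), rnorm(128))
  expect_error(phase_correct(s, 0, 15), "real-only")
})

test_that("anchored polynomial baseline removal is exact on the model class", {
  x <- seq(220, -20, length.out = 4096)
  u <- 2 * (x - min(x)) / diff(range(x)) - 1
  drift <- 3 + 0.5 * u - 2 * u^2 + u^3 + 0.2 * u^4 - 0.7 * u^5
  s <- spectrum1d(x, drift)
  bs <- baseline_spec(5L, list(ppm_window(190, 115), ppm_window(60, 10)))
  fit <- fit_baseline(s, bs)
  expect_lt(max(abs(fit$corrected$intensity)), 1e-8 * max(abs(drift)))

  # flat zero input -> zero baseline
  z <- fit_baseline(spectrum1d(x, rep(0, length(x))), bs)
  expect_lt(max(abs(z$baseline)), 1e-12)

  # peaks + known drift + noise: anchor residuals below the noise level
  sigma <- 0.02
  y <- drift + lorentz(x, 84, 1.5, 5) + lorentz(x, 75, 1.5, 5) +
    withr::with_seed(5, rnorm(length(x), 0, sigma))
  fit2 <- fit_baseline(spectrum1d(x, y), bs)
  anchor_resid <- fit2$corrected$intensity[fit2$anchor_index]
  expect_lt(sd(anchor_resid), 1.1 * sigma)
  expect_lt(abs(mean(anchor_resid)), sigma)
})

test_that("baseline correction is idempotent and validates its inputs", {
  x <- seq(220, -20, length.out = 2048)
  y <- 2 + x / 100 + lorentz(x, 84, 1.5, 5) +
    withr::with_seed(6, rnorm(length(x), 0, 0.01))
  bs <- baseline_spec(5L, list(ppm_window(190, 115), ppm_window(60, 10)))
  once <- fit_baseline(spectrum1d(x, y), bs)$corrected
  twice <- fit_baseline(once, bs)$corrected
  expect_lt(max(abs(twice$intensity - once$intensity)),
            1e-8 * max(abs(once$intensity)))

  expect_error(baseline_spec(5L, list(ppm_window(100, 50), ppm_window(60, 10))),
               "disjoint")
  tiny <- spectrum1d(seq(100, 0, length.out = 64), rnorm(64))
  expect_error(fit_baseline(tiny, baseline_spec(5L, list(ppm_window(9, 8)))),
               "anchor points")
  expect_error(fit_baseline(tiny, baseline_spec(5L, list(ppm_window(150, 90)))),
               "outside axis range")
})

test_that("control subtraction removes shared artifacts and respects scaling", {
  x <- seq(220, -20, length.out = 4096)
  art <- lorentz(x, 80, 3, 2)
  j_peaks <- lorentz(x, 84, 1.5, 6) + lorentz(x, 75, 1.5, 4)
  transfer <- spectrum1d(x, j_peaks + art)
  control <- spectrum1d(x, art)
  d <- subtract_control(transfer, control)
  expect_equal(d$intensity, j_peaks, tolerance = 1e-12)
  w80 <- ppm_window(81, 79)
  expect_lt(abs(integrate_window(d, w80) -
                  integrate_window(spectrum1d(x, j_peaks), w80)),
            0.05 * integrate_window(spectrum1d(x, art), w80))

  expect_equal(subtract_control(transfer, transfer)$intensity,
               rep(0, length(x)))
  zero <- spectrum1d(x, rep(0, length(x)))
  expect_equal(subtract_control(transfer, zero)$intensity, transfer$intensity)

  # per-scan normalization via metadata
  t2 <- spectrum1d(x, 2 * art, meta = acquisition_meta(n_scans = 2048L))
  c2 <- spectrum1d(x, art, meta = acquisition_meta(n_scans = 1024L))
  expect_lt(max(abs(subtract_control(t2, c2)$intensity)), 1e-12)

  # least-squares scale over an artifact-dominated window; tail-free
  # (Gaussian) C2 peaks so the window sees the artifact only
  gauss <- function(x, x0, fwhm, area) {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    area * exp(-(x - x0)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  }
  jg <- gauss(x, 84, 1.5, 6) + gauss(x, 75, 1.5, 4)
  t3 <- spectrum1d(x, jg + 1.37 * art)
  d3 <- subtract_control(t3, control, lsq_window = ppm_window(81, 79))
  expect_lt(abs(integrate_window(d3, w80) -
                  integrate_window(spectrum1d(x, jg), w80)), 0.02)
})

test_that("control subtraction resamples compatible axes and rejects others", {
  x1 <- seq(200, 0, length.out = 2048)
  x2 <- seq(210, -5, length.out = 3000)
  f <- function(x) lorentz(x, 80, 3, 2)
  d <- subtract_control(spectrum1d(x1, f(x1)), spectrum1d(x2, f(x2)))
  expect_lt(max(abs(d$intensity)), 1e-3)  # linear-resampling error only
  short <- spectrum1d(seq(150, 50, length.out = 512),
                      f(seq(150, 50, length.out = 512)))
  expect_error(subtract_control(spectrum1d(x1, f(x1)), short), "cover")
})

test_that("windowed integration is exact, additive and range-checked", {
  x <- seq(220, -20, length.out = 8192)
  zero <- spectrum1d(x, rep(0, length(x)))
  expect_equal(integrate_window(zero, ppm_window(90.1, 80.4)), 0)

  rect <- spectrum1d(x, as.numeric(x < 90.1 & x > 80.4))
  expect_equal(integrate_window(rect, ppm_window(90.1, 80.4)), 90.1 - 80.4,
               tolerance = 0.01)

  # Lorentzian tails beyond +/- L carry area fwhm/(pi*L); +/- 80 fwhm
  # leaves 0.4%, inside the 0.5% band
  lor <- spectrum1d(x, lorentz(x, 84, 0.8, 3.7))
  expect_equal(integrate_window(lor, ppm_window(84 + 64, 84 - 64)), 3.7,
               tolerance = 0.005)

  s <- spectrum1d(x, withr::with_seed(8, rnorm(length(x))))
  total <- integrate_window(s, ppm_window(90.1, 71.9))
  parts <- integrate_window(s, ppm_window(90.1, 80.4)) +
    integrate_window(s, ppm_window(80.4, 71.9))
  expect_equal(total, parts, tolerance = 1e-10)

  expect_error(integrate_window(s, ppm_window(300, 200)), "outside axis range")
})

test_that("percent substitution reflects the window areas", {
  x <- seq(220, -20, length.out = 8192)
  only_sub <- spectrum1d(x, lorentz(x, 84, 1.5, 5))
  expect_equal(c2_fraction(only_sub)$pct_substituted, 100, tolerance = 0.5)

  equal <- spectrum1d(x, lorentz(x, 84, 1.5, 5) + lorentz(x, 75, 1.5, 5))
  expect_equal(c2_fraction(equal)$pct_substituted, 50, tolerance = 0.5)

  neg <- spectrum1d(x, lorentz(x, 84, 1.5, 5) - lorentz(x, 75, 0.8, 0.5))
  expect_warning(r <- c2_fraction(neg), "negative")
  expect_gt(r$pct_substituted, 100)              # stored unclamped
  expect_equal(summary(r)$pct_substituted, 100)  # clamped in the summary only
  expect_error(c2_fraction(spectrum1d(x, rep(0, length(x)) - 1e-9)), "no signal")
  expect_true(length(r$provenance) > 0)
})

test_that("quantification is invariant to a common intensity scale", {
  pair <- make_transfer_pair(0.42, snr = 30, artifact_amp = 0.1, seed = 4)
  q1 <- quantify_c2(pair$transfer, pair$control)
  scale_spec <- function(s, c) spectrum1d(s$ppm, c * s$intensity, meta = s$meta)
  q2 <- quantify_c2(scale_spec(pair$transfer, 731.2),
                    scale_spec(pair$control, 731.2))
  expect_equal(q1$pct_substituted, q2$pct_substituted, tolerance = 1e-10)
})

test_that("uncertainty estimators: replicates, noise Monte-Carlo, anchors", {
  r <- function(p) structure(list(pct_substituted = p), class = "quant_result")
  expect_equal(estimate_uncertainty(list(r(50), r(50), r(50))), 0)
  expect_equal(estimate_uncertainty(list(r(41), r(65))), sd(c(41, 65)))
  expect_error(estimate_uncertainty(list(r(50))), "at least 2")

  x <- seq(220, -20, length.out = 4096)
  d <- spectrum1d(x, lorentz(x, 84, 1.5, 6) + lorentz(x, 75, 1.5, 4))
  u1 <- estimate_uncertainty(mode = "noise_propagation", diff_spec = d,
                             noise_sigma = 0.05, n_mc = 50L, seed = 3L)
  u2 <- estimate_uncertainty(mode = "noise_propagation", diff_spec = d,
                             noise_sigma = 0.05, n_mc = 50L, seed = 3L)
  expect_identical(u1, u2)     # bit-reproducible for a fixed seed
  expect_gt(u1, 0)

  pair <- make_transfer_pair(0.59, snr = 10, artifact_amp = 0.15, seed = 2)
  ua <- estimate_uncertainty(mode = "anchor_perturbation",
                             transfer = pair$transfer, control = pair$control,
                             n_perturb = 8L, seed = 11L)
  expect_gt(ua, 0)
  expect_lt(ua, 10)
})

test_that("a reference sample's relative spread transfers to other samples", {
  # triplicate reference at 53 +/- 12 carried to a 59% sample gives +/- 13
  expect_equal(round(transfer_relative_uncertainty(53, 12, 59)), 13)
  expect_equal(transfer_relative_uncertainty(50, 5, 50), 5)
})

test_that("pipeline recovers the true substitution on synthetic pairs", {
  for (p in c(30, 50, 70)) {
    est <- mean(vapply(1:5, function(s) {
      pair <- make_transfer_pair(p / 100, snr = 20, artifact_amp = 0.1,
                                 seed = s)
      quantify_c2(pair$transfer, pair$control)$pct_substituted
    }, numeric(1)))
    expect_lt(abs(est - p), 3)
  }
})
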