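#' Acquisition metadata for a 1D spectrum
#'
#' Container for the acquisition parameters the analysis actually consumes:
#' the 13C Larmor frequency (needed to convert the MAS rate into a spinning
#' sideband offset in ppm), the MAS rate, the scan count (needed for per-scan
#' normalization when comparing or subtracting spectra), and the microwave
#' state (on/off) that distinguishes DNP-enhanced from unenhanced data.
#'
#' @param spectrometer_freq_13C 13C Larmor frequency in MHz. Must be > 0.
#' @param mas_rate Magic-angle spinning rate in kHz (>= 0; 0 for static).
#' @param temperature Sample temperature in K.
#' @param n_scans Number of co-added scans (>= 1).
#' @param microwaves_on Logical, whether the gyrotron microwaves were on.
#' @param relaxation_delay Recycle delay between scans, in s.
#' @param label Free-text sample/experiment label.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(spectrometer_freq_13C = 100.6, mas_rate = 10,
                             temperature = 104, n_scans = 1L,
                             microwaves_on = TRUE, relaxation_delay = 4.3,
                             label = "") {
  stopifnot(is.numeric(spectrometer_freq_13C), spectrometer_freq_13C > 0,
            is.numeric(mas_rate), mas_rate >= 0,
            is.numeric(n_scans), n_scans >= 1,
            is.logical(microwaves_on), length(microwaves_on) == 1L)
  structure(list(spectrometer_freq_13C = as.numeric(spectrometer_freq_13C),
                 mas_rate = as.numeric(mas_rate),
                 temperature = as.numeric(temperature),
                 n_scans = as.integer(n_scans),
                 microwaves_on = isTRUE(microwaves_on),
                 relaxation_delay = as.numeric(relaxation_delay),
                 label = as.character(label)[1L]),
            class = "acquisition_meta")
}

#' One-dimensional NMR spectrum
#'
#' A calibrated 1D spectrum: a strictly decreasing ppm axis (the NMR display
#' convention, downfield left), a real intensity vector of the same length,
#' and optionally the imaginary (dispersive) component needed for phase
#' correction. All window specifications elsewhere in the package follow the
#' same convention and are given as (high ppm, low ppm) pairs.
#'
#' @param ppm Numeric vector of chemical shifts in ppm, strictly decreasing,
#'   length >= 2.
#' @param intensity Real intensity vector, same length as `ppm`, all finite.
#' @param meta An [acquisition_meta()] object.
#' @param imag Optional imaginary component (same length), kept when the data
#'   originate from complex processing and required for first-order phasing.
#' @return An object of class `spectrum1d` with fields `ppm`, `intensity`,
#'   `meta` and optionally `imag`.
#' @export
spectrum1d <- function(ppm, intensity, meta = acquisition_meta(), imag = NULL) {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) < 2L) stop("spectrum1d: ppm axis must have at least 2 points")
  if (length(ppm) != length(intensity))
    stop("spectrum1d: ppm and intensity lengths differ (",
         length(ppm), " vs ", length(intensity), ")")
  if (any(diff(ppm) >= 0))
    stop("spectrum1d: ppm axis must be strictly decreasing")
  if (!all(is.finite(intensity)))
    stop("spectrum1d: intensity must be finite everywhere")
  if (!inherits(meta, "acquisition_meta"))
    stop("spectrum1d: meta must be an acquisition_meta object")
  obj <- list(ppm = ppm, intensity = intensity, meta = meta)
  if (!is.null(imag)) {
    imag <- as.numeric(imag)
    if (length(imag) != length(ppm))
      stop("spectrum1d: imag length differs from ppm axis")
    obj$imag <- imag
  }
  structure(obj, class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %d points, %.2f .. %.2f ppm%s\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)],
              if (!is.null(x$imag)) " (complex)" else ""))
  cat(sprintf("  %s | %.1f MHz, MAS %.1f kHz, %d scans, microwaves %s\n",
              if (nzchar(x$meta$label)) x$meta$label else "(unlabelled)",
              x$meta$spectrometer_freq_13C, x$meta$mas_rate, x$meta$n_scans,
              if (x$meta$microwaves_on) "on" else "off"))
  invisible(x)
}

#' Saturation-recovery series for one resonance
#'
#' Recovery delays and the integrated signal amplitude of one resonance at
#' each delay, as produced by a saturation-recovery experiment. Fitting
#' ([fit_saturation_recovery()]) requires at least 4 points.
#'
#' @param delays Recovery delays in s, strictly increasing, all >= 0.
#' @param amplitudes Integrated amplitudes (a.u.), same length as `delays`.
#' @param resonance_label Which resonance was integrated (e.g. `"C1"`, `"CO"`).
#' @param microwaves_on Logical microwave state during the measurement.
#' @return An object of class `relaxation_curve`.
#' @export
relaxation_curve <- function(delays, amplitudes, resonance_label = "C1",
                             microwaves_on = TRUE) {
  delays <- as.numeric(delays); amplitudes <- as.numeric(amplitudes)
  if (length(delays) != length(amplitudes))
    stop("relaxation_curve: delays and amplitudes lengths differ")
  if (any(delays < 0)) stop("relaxation_curve: delays must be >= 0")
  if (any(diff(delays) <= 0))
    stop("relaxation_curve: delays must be strictly increasing")
  structure(list(delays = delays, amplitudes = amplitudes,
                 resonance_label = as.character(resonance_label)[1L],
                 microwaves_on = isTRUE(microwaves_on)),
            class = "relaxation_curve")
}

#' @export
print.relaxation_curve <- function(x, ...) {
  cat(sprintf("<relaxation_curve> %s, %d delays (%.3g .. %.3g s), microwaves %s\n",
              x$resonance_label, length(x$delays), min(x$delays),
              max(x$delays), if (x$microwaves_on) "on" else "off"))
  invisible(x)
}

## ---- internal tabular interchange format ------------------------------------

.meta_fields <- c("spectrometer_freq_13C", "mas_rate", "temperature",
                  "n_scans", "microwaves_on", "relaxation_delay", "label")

.format_num <- function(x) sprintf("%.17g", x)

.write_header <- function(con, kind, meta_list) {
  writeLines(sprintf("# c2quant %s v1", kind), con)
  for (k in names(meta_list)) {
    v <- meta_list[[k]]
    v <- if (is.logical(v)) ifelse(v, "true", "false")
         else if (is.numeric(v)) .format_num(v) else as.character(v)
    writeLines(sprintf("# %s: %s", k, v), con)
  }
}

.parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in hdr[-1]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

.meta_from_header <- function(h) {
  to_num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  acquisition_meta(
    spectrometer_freq_13C = to_num(h$spectrometer_freq_13C, 100.6),
    mas_rate = to_num(h$mas_rate, 10),
    temperature = to_num(h$temperature, 104),
    n_scans = as.integer(to_num(h$n_scans, 1)),
    microwaves_on = is.null(h$microwaves_on) || identical(h$microwaves_on, "true"),
    relaxation_delay = to_num(h$relaxation_delay, 4.3),
    label = if (is.null(h$label)) "" else h$label)
}

#' Write / read the internal tabular spectrum format
#'
#' The interchange format is plain text: `# key: value` header lines carrying
#' the acquisition metadata, followed by two (or, for complex data, three)
#' whitespace-separated columns: ppm, intensity and optionally the imaginary
#' component. Values are written with 17 significant digits so the round trip
#' is lossless for doubles.
#'
#' @param spec A [spectrum1d()] object.
#' @param path File path to write to / read from.
#' @return `write_internal()` returns `path` invisibly; `read_internal()`
#'   returns a [spectrum1d()].
#' @export
write_internal <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum1d"))
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, "spectrum", spec$meta)
  writeLines(paste("# columns:",
                   if (is.null(spec$imag)) "ppm intensity"
                   else "ppm intensity imag"), con)
  if (is.null(spec$imag)) {
    writeLines(paste(.format_num(spec$ppm), .format_num(spec$intensity)), con)
  } else {
    writeLines(paste(.format_num(spec$ppm), .format_num(spec$intensity),
                     .format_num(spec$imag)), con)
  }
  invisible(path)
}

#' @rdname write_internal
#' @export
read_internal <- function(path) {
  if (!file.exists(path)) stop("read_internal: no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# c2quant spectrum", lines[1]))
    stop("read_internal: not a c2quant spectrum file: ", path)
  h <- .parse_header(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("read_internal: file has no data rows: ", path)
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  spectrum1d(m[, 1], m[, 2], meta = .meta_from_header(h),
             imag = if (ncol(m) >= 3L) m[, 3] else NULL)
}

#' Write / read a relaxation curve as two-column text
#'
#' Same header convention as [write_internal()]; the body holds delay (s) and
#' integrated amplitude columns.
#'
#' @param curve A [relaxation_curve()].
#' @param path File path.
#' @return `write_relaxation()` returns `path` invisibly; `read_relaxation()`
#'   a [relaxation_curve()].
#' @export
write_relaxation <- function(curve, path) {
  stopifnot(inherits(curve, "relaxation_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, "relaxation", list(resonance_label = curve$resonance_label,
                                        microwaves_on = curve$microwaves_on))
  writeLines("# columns: delay_s amplitude", con)
  writeLines(paste(.format_num(curve$delays), .format_num(curve$amplitudes)), con)
  invisible(path)
}

#' @rdname write_relaxation
#' @export
read_relaxation <- function(path) {
  if (!file.exists(path)) stop("read_relaxation: no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# c2quant relaxation", lines[1]))
    stop("read_relaxation: not a c2quant relaxation file: ", path)
  h <- .parse_header(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  relaxation_curve(m[, 1], m[, 2],
                   resonance_label = if (is.null(h$resonance_label)) "C1"
                                     else h$resonance_label,
                   microwaves_on = is.null(h$microwaves_on) ||
                     identical(h$microwaves_on, "true"))
}

## ---- Bruker TopSpin processed data ------------------------------------------

.read_jcamp_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hits <- regmatches(lines, regexec("^##\\$([A-Za-z0-9_]+)=\\s*(.*)$", lines))
  out <- list()
  for (m in hits) if (length(m) == 3L) out[[m[2]]] <- trimws(m[3])
  out
}

.require_param <- function(params, name, file) {
  v <- params[[name]]
  if (is.null(v) || !nzchar(v))
    stop("read_bruker_processed: parameter file '", file,
         "' is missing required field ", name)
  v
}

#' Read a Bruker TopSpin processed 1D dataset
#'
#' Reads the real part of a processed 1D spectrum (`1r`) from a TopSpin-style
#' directory and reconstructs the ppm axis from the `procs` parameters:
#' `ppm[i] = OFFSET - (i-1) * (SW_p/SF) / SI`, i.e. the first point sits at
#' the offset (left edge) and the axis spans the processed spectral width.
#' Both integer (`DTYPP = 0`, scaled by `2^NC_proc`) and double (`DTYPP = 2`)
#' typed arrays are supported, in either byte order. Raw FIDs and imaginary
#' parts are out of scope.
#'
#' @param path Either a directory containing `procs` and `1r` directly (a
#'   `pdata/<n>` directory) or a dataset root containing `pdata/`; in the
#'   latter case the lowest-numbered procno is used. Metadata are filled from
#'   `procs`/`acqus` where available and defaulted otherwise.
#' @return A [spectrum1d()].
#' @export
read_bruker_processed <- function(path) {
  if (!dir.exists(path)) stop("read_bruker_processed: no such directory: ", path)
  pdir <- path
  if (!file.exists(file.path(pdir, "procs"))) {
    cands <- sort(list.dirs(file.path(path, "pdata"), recursive = FALSE))
    cands <- cands[file.exists(file.path(cands, "procs"))]
    if (!length(cands))
      stop("read_bruker_processed: no procs file found under ", path)
    pdir <- cands[1L]
  }
  procs_file <- file.path(pdir, "procs")
  p <- .read_jcamp_params(procs_file)
  si <- as.integer(.require_param(p, "SI", procs_file))
  sf <- as.numeric(.require_param(p, "SF", procs_file))
  swp <- as.numeric(.require_param(p, "SW_p", procs_file))
  offset <- as.numeric(.require_param(p, "OFFSET", procs_file))
  if (!is.finite(si) || si < 2L)
    stop("read_bruker_processed: invalid SI in ", procs_file)
  bytordp <- as.integer(if (is.null(p$BYTORDP)) 0L else p$BYTORDP)
  dtypp <- as.integer(if (is.null(p$DTYPP)) 0L else p$DTYPP)
  nc_proc <- as.numeric(if (is.null(p$NC_proc)) 0 else p$NC_proc)

  rfile <- file.path(pdir, "1r")
  if (!file.exists(rfile))
    stop("read_bruker_processed: missing processed data file ", rfile)
  endian <- if (bytordp == 1L) "big" else "little"
  con <- file(rfile, "rb")
  on.exit(close(con))
  y <- if (dtypp == 2L) {
    readBin(con, what = "double", n = si, size = 8L, endian = endian)
  } else {
    as.numeric(readBin(con, what = "integer", n = si, size = 4L,
                       endian = endian)) * 2^nc_proc
  }
  if (length(y) < si)
    stop("read_bruker_processed: data file ", rfile, " is truncated (",
         length(y), " of ", si, " points)")

  sw_ppm <- swp / sf
  ppm <- offset - (seq_len(si) - 1L) * sw_ppm / si

  acqus_file <- file.path(dirname(dirname(pdir)), "acqus")
  ns <- 1L; masr <- 0
  if (file.exists(acqus_file)) {
    a <- .read_jcamp_params(acqus_file)
    if (!is.null(a$NS)) ns <- as.integer(a$NS)
    if (!is.null(a$MASR)) masr <- as.numeric(a$MASR) / 1000  # Hz -> kHz
  }
  spectrum1d(ppm, y,
             meta = acquisition_meta(spectrometer_freq_13C = sf,
                                     mas_rate = masr, n_scans = max(1L, ns),
                                     label = path))
}

#' Index of the axis point nearest to a chemical shift
#'
#' Ties (a shift exactly midway between two grid points) are broken toward
#' the lower index, i.e. the downfield point.
#'
#' @param spec A [spectrum1d()].
#' @param ppm A chemical shift within the axis range.
#' @return Integer index into `spec$ppm`.
#' @export
ppm_to_index <- function(spec, ppm) {
  stopifnot(inherits(spec, "spectrum1d"), is.numeric(ppm), length(ppm) == 1L)
  rng <- range(spec$ppm)
  if (ppm < rng[1] || ppm > rng[2])
    stop(sprintf("ppm_to_index: %.4g ppm outside axis range [%.4g, %.4g]",
                 ppm, rng[1], rng[2]))
  d <- abs(spec$ppm - ppm)
  which(d == min(d))[1L]
}
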