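#' Estimate lung input impedance from a pressure-flow record
#'
#' The default estimator is a single-window DFT evaluated at the exact
#' protocol bins: because every forcing component is bin-aligned in the
#' rectangular analysis window, Z(f_k) = P(f_k)/Q(f_k) is unbiased and exact
#' for a linear time-invariant lung. The alternative `"welch"` method averages
#' cross-spectra over 50%-overlapping full-window segments and reports per-bin
#' coherence; it needs at least two protocol windows of data and is intended
#' for imported records longer than one window. Bins whose coherence falls
#' below `coherence_threshold` are flagged, never dropped.
#'
#' @param record a `pf_record` (columns `t`, `flow`, `pressure`).
#' @param protocol the `multisine_protocol` used to generate the record.
#' @param method `"dft"` (default) or `"welch"`.
#' @param coherence_threshold flag bins with coherence below this (default 0.9).
#' @param detrend remove a linear trend from pressure and flow first
#'   (default `FALSE`; meant for drifting imported data).
#' @return A data frame of class `impedance_spectrum` with columns `freq_hz`,
#'   `Re_Z`, `Im_Z`, `coherence` (NA for the DFT method), `flagged`, and
#'   attributes `peep_cmH2O`, `method`.
#' @export
estimate_impedance <- function(record, protocol,
                               method = c("dft", "welch"),
                               coherence_threshold = 0.9, detrend = FALSE) {
  method <- match.arg(method)
  fs <- attr(record, "fs_hz")
  stopifnot(!is.null(fs), fs == protocol$fs_hz)
  nwin <- as.integer(round(protocol$window_s * protocol$fs_hz))
  q <- record$flow; p <- record$pressure
  if (length(q) < nwin)
    abort_lungfot("record shorter than one protocol window",
                  "lungfot_estimation_error")
  if (detrend) {
    tt <- seq_along(q)
    q <- stats::resid(stats::lm(q ~ tt))
    p <- stats::resid(stats::lm(p ~ tt))
  }

  if (method == "dft") {
    # exact-bin DFT over the longest whole number of windows
    nw <- length(q) %/% nwin
    n <- nw * nwin
    Qf <- stats::fft(q[seq_len(n)])
    Pf <- stats::fft(p[seq_len(n)])
    idx <- protocol$k_indices * nw + 1L
    if (max(Mod(Qf)) == 0 || any(Mod(Qf[idx]) < 1e-12 * max(Mod(Qf))))
      abort_lungfot("no excitation at a protocol bin", "lungfot_estimation_error")
    Z <- Pf[idx] / Qf[idx]
    coh <- rep(NA_real_, length(idx))
  } else {
    step <- nwin %/% 2L
    n_seg <- (length(q) - nwin) %/% step + 1L
    if (n_seg < 2L)
      abort_lungfot("welch method needs at least two protocol windows of data",
                    "lungfot_estimation_error")
    idx <- protocol$k_indices + 1L
    Sqq <- Spp <- numeric(length(idx))
    Sqp <- complex(length(idx))
    for (s in seq_len(n_seg)) {
      sel <- (s - 1L) * step + seq_len(nwin)
      Qf <- stats::fft(q[sel])[idx]
      Pf <- stats::fft(p[sel])[idx]
      Sqq <- Sqq + Mod(Qf)^2
      Spp <- Spp + Mod(Pf)^2
      Sqp <- Sqp + Conj(Qf) * Pf
    }
    if (max(Sqq) == 0 || any(Sqq < 1e-24 * max(Sqq)))
      abort_lungfot("no excitation at a protocol bin", "lungfot_estimation_error")
    Z <- Sqp / Sqq
    coh <- Mod(Sqp)^2 / (Sqq * Spp)
  }

  structure(data.frame(freq_hz = protocol$freqs_hz,
                       Re_Z = Re(Z), Im_Z = Im(Z),
                       coherence = coh,
                       flagged = !is.na(coh) & coh < coherence_threshold),
            class = c("impedance_spectrum", "data.frame"),
            peep_cmH2O = attr(record, "peep_cmH2O"),
            grade_label = attr(record, "grade_label"),
            method = method)
}

#' Derive resistance, reactance and dynamic elastance spectra
#'
#' R_L = Re(Z), X_L = Im(Z) and E_L = -omega X_L with omega = 2 pi f,
#' elementwise over the measured bins.
#'
#' @param spectrum an `impedance_spectrum`.
#' @return A data frame of class `mechanics_spectra` with columns `freq_hz`,
#'   `R_L` (cmH2O.s/mL), `X_L` (cmH2O.s/mL), `E_L` (cmH2O/mL); PEEP and grade
#'   attributes are carried over.
#' @export
to_mechanics <- function(spectrum) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  w <- 2 * pi * spectrum$freq_hz
  structure(data.frame(freq_hz = spectrum$freq_hz,
                       R_L = spectrum$Re_Z,
                       X_L = spectrum$Im_Z,
                       E_L = -w * spectrum$Im_Z),
            class = c("mechanics_spectra", "data.frame"),
            peep_cmH2O = attr(spectrum, "peep_cmH2O"),
            grade_label = attr(spectrum, "grade_label"))
}

#' Write an impedance/mechanics spectrum as CSV
#' @param spectrum an `impedance_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  m <- to_mechanics(spectrum)
  out <- data.frame(freq_hz = spectrum$freq_hz,
                    Re_Z = spectrum$Re_Z, Im_Z = spectrum$Im_Z,
                    R_L = m$R_L, X_L = m$X_L, E_L = m$E_L,
                    coherence = spectrum$coherence)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
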