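#' Build a multi-sine forced-oscillation protocol
#'
#' Constructs the forcing design used for input-impedance measurement during a
#' pause of regular ventilation: a sum of sinusoids whose frequencies are
#' integer multiples of the window's frequency resolution (so every component
#' falls exactly on a DFT bin) and mutually non-harmonic (no component
#' frequency is an integer multiple of another), which keeps harmonic
#' distortion products of one component from landing on another component's
#' bin.
#'
#' Component selection is deterministic: integer multipliers k of the base
#' resolution 1/window_s are scanned in ascending order, force-including the
#' multipliers of `f_min_hz`, 0.75 Hz (when at least three components are
#' requested and 0.75 Hz lies inside the band) and `f_max_hz`, and accepting a
#' candidate only if it is neither a multiple nor a divisor of any accepted
#' multiplier, until `n_components` are found.
#'
#' @param window_s oscillation window length, seconds (default 8).
#' @param fs_hz sampling rate, Hz; must exceed twice `f_max_hz` (default 256).
#' @param n_components number of sinusoidal components (default 19).
#' @param f_min_hz,f_max_hz band edges, Hz; each must be an integer multiple
#'   of `1/window_s` (defaults 0.5 and 19.625).
#' @param vt_peak_to_peak_ml peak-to-peak volume excursion of the synthesized
#'   forcing, mL (default 0.9 = 3 mL/kg for a 0.3 kg rat).
#' @param phases `"schroeder"` (default; low crest factor) or `"random"`.
#' @param seed integer seed, used only when `phases = "random"`.
#'
#' @return An object of class `multisine_protocol`: a list with fields
#'   `window_s`, `fs_hz`, `base_df_hz`, `k_indices`, `freqs_hz`, `phases_rad`,
#'   `vt_peak_to_peak_ml`.
#' @export
#' @examples
#' pr <- build_protocol()
#' range(pr$freqs_hz)  # 0.5 .. 19.625 Hz
build_protocol <- function(window_s = 8, fs_hz = 256, n_components = 19,
                           f_min_hz = 0.5, f_max_hz = 19.625,
                           vt_peak_to_peak_ml = 0.9,
                           phases = c("schroeder", "random"), seed = NULL) {
  phases <- match.arg(phases)
  stopifnot(is_scalar_number(window_s), window_s > 0,
            is_scalar_number(fs_hz), is_scalar_number(vt_peak_to_peak_ml),
            vt_peak_to_peak_ml > 0,
            n_components >= 2, f_min_hz > 0, f_min_hz < f_max_hz)
  if (fs_hz <= 2 * f_max_hz)
    abort_lungfot("sampling rate must exceed twice the maximum frequency",
                  "lungfot_protocol_error")
  df <- 1 / window_s
  k_min <- f_min_hz / df
  k_max <- f_max_hz / df
  if (abs(k_min - round(k_min)) > 1e-9 || abs(k_max - round(k_max)) > 1e-9)
    abort_lungfot("band edges must be integer multiples of 1/window_s (bin-aligned)",
                  "lungfot_protocol_error")
  k_min <- as.integer(round(k_min)); k_max <- as.integer(round(k_max))

  forced <- c(k_min, k_max)
  k_075 <- 0.75 / df
  if (n_components >= 3 && abs(k_075 - round(k_075)) < 1e-9 &&
      round(k_075) > k_min && round(k_075) < k_max)
    forced <- sort(unique(c(forced, as.integer(round(k_075)))))
  compatible <- function(k, set)
    all(k %% set != 0L) && all(set %% k != 0L)
  for (i in seq_along(forced)) {
    others <- forced[-i]
    if (length(others) && !compatible(forced[i], others))
      abort_lungfot("forced components are harmonically related; adjust band edges",
                    "lungfot_protocol_error")
  }
  if (length(forced) > n_components)
    abort_lungfot("n_components smaller than the number of forced components",
                  "lungfot_protocol_error")

  accepted <- forced
  for (k in seq.int(k_min, k_max)) {
    if (length(accepted) >= n_components) break
    if (k %in% accepted) next
    if (compatible(k, accepted)) accepted <- c(accepted, k)
  }
  if (length(accepted) < n_components)
    abort_lungfot(sprintf(
      "cannot place %d mutually non-harmonic components in [%g, %g] Hz (found %d)",
      n_components, f_min_hz, f_max_hz, length(accepted)),
      "lungfot_protocol_error")
  k_idx <- sort(accepted)

  n <- length(k_idx)
  ph <- switch(phases,
    schroeder = -pi * (seq_len(n)) * (seq_len(n) - 1) / n,
    random = { if (!is.null(seed)) set.seed(seed)
               stats::runif(n, 0, 2 * pi) })

  structure(list(window_s = window_s, fs_hz = fs_hz, base_df_hz = df,
                 k_indices = k_idx, freqs_hz = k_idx * df, phases_rad = ph,
                 vt_peak_to_peak_ml = vt_peak_to_peak_ml),
            class = "multisine_protocol")
}

#' Validate a multi-sine protocol
#'
#' Checks every structural invariant of the design and reports each one
#' individually rather than failing on the first violation.
#'
#' @param protocol a `multisine_protocol`.
#' @return A data frame with columns `check`, `pass`, `detail`.
#' @export
validate_protocol <- function(protocol) {
  p <- protocol
  k <- p$k_indices
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  binal <- abs(p$freqs_hz / p$base_df_hz - round(p$freqs_hz / p$base_df_hz))
  add("bin_aligned", all(binal < 1e-9),
      if (any(binal >= 1e-9)) sprintf("off-bin freqs: %s",
        paste(p$freqs_hz[binal >= 1e-9], collapse = ", ")) else "")
  harm <- FALSE
  for (i in seq_along(k)) for (j in seq_along(k))
    if (i != j && k[i] %% k[j] == 0) harm <- TRUE
  add("non_harmonic", !harm,
      if (harm) "some component is an integer multiple of another" else "")
  add("distinct_ascending", !is.unsorted(k, strictly = TRUE))
  add("phases_length", length(p$phases_rad) == length(k))
  add("nyquist", p$fs_hz > 2 * max(p$freqs_hz))
  add("positive_vt", p$vt_peak_to_peak_ml > 0)
  do.call(rbind, checks)
}

#' Synthesize the multi-sine volume and flow forcing
#'
#' Volume is an equal-amplitude sum of sinusoids rescaled so its peak-to-peak
#' excursion equals the protocol tidal volume exactly; flow is the analytic
#' time derivative (a sum of cosines), not a numerical difference.
#'
#' @param protocol a `multisine_protocol`.
#' @param n_windows number of contiguous protocol windows to synthesize
#'   (the forcing is periodic with period `window_s`); default 1.
#' @return A data frame with columns `t` (s), `volume` (mL), `flow` (mL/s).
#' @export
synthesize_forcing <- function(protocol, n_windows = 1) {
  p <- protocol
  stopifnot(inherits(p, "multisine_protocol"), n_windows >= 1)
  n <- as.integer(round(p$window_s * p$fs_hz * n_windows))
  t <- (seq_len(n) - 1) / p$fs_hz
  w <- 2 * pi * p$freqs_hz
  arg <- outer(t, w) + matrix(p$phases_rad, n, length(w), byrow = TRUE)
  v0 <- rowSums(sin(arg))
  amp <- p$vt_peak_to_peak_ml / (max(v0) - min(v0))
  q0 <- cos(arg) %*% w
  data.frame(t = t, volume = amp * v0, flow = amp * as.numeric(q0))
}

#' Write / read a protocol as JSON
#'
#' @param protocol a `multisine_protocol`.
#' @param path file path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol` returns
#'   the reconstructed `multisine_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$k_indices <- as.integer(x$k_indices)
  structure(x, class = "multisine_protocol")
}
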