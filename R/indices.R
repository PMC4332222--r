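#' Reduce a mechanics spectrum to the four rejection-sensitive indices
#'
#' * `E_low`  - dynamic elastance at the lowest protocol frequency (0.5 Hz),
#'   sensitive to tissue stiffening and derecruitment;
#' * `E_max`  - the highest absolute value of E_L over the measured bins;
#' * `E_het`  - `E_max - E_low`, an index of mechanical heterogeneity via the
#'   frequency dependence of elastance;
#' * `R_high` - resistance averaged over the top `n_high` frequencies
#'   (default 1, i.e. R_L at 19.625 Hz), dominated by airway resistance.
#'
#' @param spectra a `mechanics_spectra` data frame (see [to_mechanics()]).
#' @param n_high number of top frequencies averaged for `R_high` (default 1).
#' @param f_low_hz the frequency defining `E_low` (default 0.5).
#' @return A one-row data frame of class `index_set` with columns `R_high`,
#'   `E_low`, `E_max`, `E_het`, `peep_cmH2O`, `grade_label`.
#' @export
#' @examples
#' pr <- build_protocol()
#' m <- lung_model(compartments = list(cp_compartment(G = 3.611, H = 3.611)),
#'                 grade_label = "A0_native")
#' rec <- simulate_record(m, pr)
#' extract_indices(to_mechanics(estimate_impedance(rec, pr)))
extract_indices <- function(spectra, n_high = 1, f_low_hz = 0.5) {
  stopifnot(inherits(spectra, "mechanics_spectra"))
  if (n_high < 1 || n_high > nrow(spectra))
    abort_lungfot("n_high must be between 1 and the number of bins",
                  "lungfot_index_error")
  i_low <- which(abs(spectra$freq_hz - f_low_hz) < 1e-9)
  if (length(i_low) != 1)
    abort_lungfot(sprintf("spectrum has no %g Hz bin", f_low_hz),
                  "lungfot_index_error")
  e_low <- spectra$E_L[i_low]
  e_max <- max(abs(spectra$E_L))
  top <- order(spectra$freq_hz, decreasing = TRUE)[seq_len(n_high)]
  r_high <- mean(spectra$R_L[top])
  peep <- attr(spectra, "peep_cmH2O")
  structure(data.frame(R_high = r_high, E_low = e_low, E_max = e_max,
                       E_het = e_max - e_low,
                       peep_cmH2O = if (is.null(peep)) NA_real_ else peep,
                       grade_label = attr(spectra, "grade_label") %||% NA_character_,
                       stringsAsFactors = FALSE),
            class = c("index_set", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Index table for a whole cohort
#'
#' Runs estimate -> mechanics -> indices over every record of a cohort and
#' returns one tidy row per animal and PEEP.
#'
#' @param cohort an `fot_cohort` from [generate_cohort()].
#' @param n_high passed to [extract_indices()].
#' @param method impedance estimator, see [estimate_impedance()].
#' @return A data frame with columns `animal_id`, `group`, `grade`,
#'   `grade_num`, `tf_target`, `peep_cmH2O`, `R_high`, `E_low`, `E_max`,
#'   `E_het`.
#' @export
index_table <- function(cohort, n_high = 1, method = "dft") {
  stopifnot(inherits(cohort, "fot_cohort"))
  rows <- lapply(names(cohort$records), function(key) {
    rec <- cohort$records[[key]]
    idx <- extract_indices(to_mechanics(
      estimate_impedance(rec, cohort$protocol, method = method)),
      n_high = n_high)
    id <- sub("_peep[0-9.]+$", "", key)
    meta <- cohort$animals[cohort$animals$animal_id == id, ]
    cbind(meta[, c("animal_id", "group", "grade", "grade_num", "tf_target")],
          idx[, c("peep_cmH2O", "R_high", "E_low", "E_max", "E_het")],
          row.names = NULL)
  })
  do.call(rbind, rows)
}
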