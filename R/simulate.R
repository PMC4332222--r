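#' Simulate a pressure-flow record under multi-sine forcing
#'
#' Flow comes from [synthesize_forcing()]; pressure is built in the frequency
#' domain as P(f_k) = Z_L(f_k) Q(f_k) at the protocol bins (the model is
#' linear and time-invariant and the forcing is bin-aligned, so this is
#' exact), inverse-transformed, and optionally corrupted with additive white
#' Gaussian noise at a stated signal-to-noise ratio.
#'
#' @param model a `lung_model`.
#' @param protocol a `multisine_protocol`.
#' @param peep operating PEEP, cmH2O.
#' @param snr_db pressure signal-to-noise ratio in dB; `Inf` (default) means
#'   noiseless.
#' @param seed integer seed for the noise; ignored when `snr_db = Inf`.
#' @param n_windows number of contiguous protocol windows (default 1); noise
#'   is independent across the whole record.
#' @return A data frame of class `pf_record` with columns `t` (s), `flow`
#'   (mL/s), `pressure` (cmH2O) and attributes `fs_hz`, `window_s`,
#'   `peep_cmH2O`, `grade_label`, `snr_db`, `seed`, `n_windows`.
#' @export
simulate_record <- function(model, protocol, peep = 0, snr_db = Inf,
                            seed = NULL, n_windows = 1) {
  stopifnot(inherits(model, "lung_model"),
            inherits(protocol, "multisine_protocol"))
  Z <- lung_impedance(model, protocol$freqs_hz, peep)  # errors if unmeasurable
  forc <- synthesize_forcing(protocol, n_windows = n_windows)
  q <- forc$flow
  n <- length(q)
  Qf <- stats::fft(q)
  Pf <- complex(n)
  # bin of f_k in the full record: k * n_windows (0-based), +1 for R indexing
  idx <- protocol$k_indices * n_windows + 1L
  Pf[idx] <- Z * Qf[idx]
  Pf[n - idx + 2L] <- Conj(Pf[idx])
  p <- Re(stats::fft(Pf, inverse = TRUE)) / n
  if (is.finite(snr_db)) {
    if (!is.null(seed)) set.seed(seed)
    noise_sd <- sqrt(mean(p^2)) / 10^(snr_db / 20)
    p <- p + stats::rnorm(n, 0, noise_sd)
  }
  structure(data.frame(t = forc$t, flow = q, pressure = p),
            class = c("pf_record", "data.frame"),
            fs_hz = protocol$fs_hz, window_s = protocol$window_s,
            peep_cmH2O = peep, grade_label = model$grade_label,
            snr_db = snr_db, seed = seed, n_windows = n_windows)
}

#' Default cohort design
#'
#' Group sizes mirror the emulated study: native control and isograft (both
#' grade A0, n = 6 each) and allografts split into A1 (n = 4), A2 (n = 7) and
#' A3 (n = 6); five PEEP levels 0-8 cmH2O; pressure SNR 40 dB.
#'
#' @param snr_db pressure SNR in dB.
#' @param peep_cmH2O PEEP levels.
#' @return A list with elements `groups` (data frame), `peep_cmH2O`, `snr_db`.
#' @export
default_design <- function(snr_db = 40, peep_cmH2O = c(0, 2, 4, 6, 8)) {
  list(groups = data.frame(
         group = c("native", "isograft", "A1", "A2", "A3"),
         grade = grade_levels(),
         n = c(6L, 6L, 4L, 7L, 6L),
         stringsAsFactors = FALSE),
       peep_cmH2O = peep_cmH2O, snr_db = snr_db)
}

#' Generate a synthetic cohort of pressure-flow records
#'
#' For every animal one lung model is drawn from its grade preset, and one
#' record is simulated per PEEP level. All randomness derives hierarchically
#' from `seed`, so the same seed reproduces the cohort exactly.
#'
#' @param design a design list as returned by [default_design()].
#' @param preset a `grade_presets` object.
#' @param seed master integer seed.
#' @param protocol a `multisine_protocol`; default [build_protocol()].
#' @return A list of class `fot_cohort` with elements `animals` (metadata data
#'   frame: `animal_id`, `group`, `grade`, `grade_num`, `tf_target`, `seed`),
#'   `records` (list keyed `"<animal_id>_peep<p>"`), `models` (list keyed by
#'   animal id), `design`, `protocol`.
#' @export
generate_cohort <- function(design = default_design(),
                            preset = default_presets(), seed = 1,
                            protocol = build_protocol()) {
  animals <- list(); records <- list(); models <- list()
  a <- 0L
  for (gi in seq_len(nrow(design$groups))) {
    grp <- design$groups[gi, ]
    for (k in seq_len(grp$n)) {
      a <- a + 1L
      id <- sprintf("%s_%02d", grp$group, k)
      s_animal <- child_seed(seed, a)
      model <- sample_lung(preset, grp$grade, s_animal)
      models[[id]] <- model
      animals[[a]] <- data.frame(
        animal_id = id, group = grp$group, grade = grp$grade,
        grade_num = grade_number(grp$grade),
        tf_target = attr(model, "tf_target"), seed = s_animal,
        stringsAsFactors = FALSE)
      for (p in design$peep_cmH2O) {
        key <- sprintf("%s_peep%g", id, p)
        records[[key]] <- simulate_record(
          model, protocol, peep = p, snr_db = design$snr_db,
          seed = child_seed(s_animal, match(p, design$peep_cmH2O)))
      }
    }
  }
  structure(list(animals = do.call(rbind, animals), records = records,
                 models = models, design = design, protocol = protocol),
            class = "fot_cohort")
}

#' Write a pressure-flow record as CSV
#'
#' Metadata attributes are preserved in a commented header.
#' @param record a `pf_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  meta <- sprintf("# fs_hz=%g window_s=%g peep_cmH2O=%g grade=%s snr_db=%g",
                  attr(record, "fs_hz"), attr(record, "window_s"),
                  attr(record, "peep_cmH2O"), attr(record, "grade_label"),
                  attr(record, "snr_db"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(record), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]]
  kv <- strsplit(kv, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  d <- utils::read.csv(path, comment.char = "#")
  structure(d, class = c("pf_record", "data.frame"),
            fs_hz = as.numeric(vals["fs_hz"]),
            window_s = as.numeric(vals["window_s"]),
            peep_cmH2O = as.numeric(vals["peep_cmH2O"]),
            grade_label = unname(vals["grade"]),
            snr_db = as.numeric(vals["snr_db"]))
}
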