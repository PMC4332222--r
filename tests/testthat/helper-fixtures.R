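# Shared fixtures built in code.

default_proto <- build_protocol()

# single constant-phase compartment behind zero central impedance
single_cp_model <- function(G, H, Raw = 0, Iaw = 0, Pc = -Inf) {
  lung_model(Rc = 0, Ic = 0,
             compartments = list(cp_compartment(Raw = Raw, Iaw = Iaw,
                                                G = G, H = H, Pc = Pc)),
             grade_label = "A0_native")
}

# full synthesize -> estimate -> extract pipeline for one model
pipeline_indices <- function(model, protocol = default_proto, peep = 0,
                             snr_db = Inf, seed = NULL, n_high = 1) {
  rec <- simulate_record(model, protocol, peep = peep, snr_db = snr_db,
                         seed = seed)
  extract_indices(to_mechanics(estimate_impedance(rec, protocol)),
                  n_high = n_high)
}

# mechanics spectra straight from a closed-form impedance (bypasses the
# record pipeline; used as the independent oracle path)
mechanics_from_Z <- function(f_hz, Z, peep = 0, grade = "A0_native") {
  structure(data.frame(freq_hz = f_hz, R_L = Re(Z), X_L = Im(Z),
                       E_L = -2 * pi * f_hz * Im(Z)),
            class = c("mechanics_spectra", "data.frame"),
            peep_cmH2O = peep, grade_label = grade)
}

small_design <- function(n = 1, snr_db = Inf)
  list(groups = data.frame(group = c("native", "isograft", "A1", "A2", "A3"),
                           grade = c("A0_native", "A0_iso", "A1", "A2", "A3"),
                           n = rep(as.integer(n), 5)),
       peep_cmH2O = c(0, 2, 4, 6, 8), snr_db = snr_db)
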