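test_that("constant-phase compartment impedance matches the closed form", {
  cmp <- cp_compartment(Raw = 0.3, Iaw = 0, G = 3.611, H = 3.611)
  expect_equal(cmp$alpha, 0.5)  # atan(1) = pi/4
  Z <- compartment_impedance(cmp, 0.5)
  expect_equal(Re(Z), 0.3 + 3.611 / sqrt(pi), tolerance = 1e-12)
  expect_equal(-pi * Im(Z), 3.611 * sqrt(pi), tolerance = 1e-12)  # E at 0.5 Hz
  expect_error(compartment_impedance(cmp, 0), class = "lungfot_domain_error")
  # alpha consistent with G, H for unequal values
  cmp2 <- cp_compartment(G = 2, H = 6)
  expect_equal(cmp2$alpha, (2 / pi) * atan(3), tolerance = 1e-12)
  # high-frequency limit: tissue term vanishes
  Zhf <- compartment_impedance(cmp, 1e6)
  expect_equal(Re(Zhf), 0.3, tolerance = 1e-2)
  expect_lt(abs(Im(Zhf)), 1e-2)
})

test_that("parallel identical compartments combine as Z1/N behind the central airway", {
  cmp <- cp_compartment(Raw = 0.2, G = 4, H = 8, Pc = -1)
  m <- lung_model(Rc = 0.05, Ic = 1e-4,
                  compartments = rep(list(cmp), 5), grade_label = "A0_native")
  f <- default_proto$freqs_hz
  Z1 <- compartment_impedance(cmp, f)
  expect_equal(lung_impedance(m, f, peep = 0),
               0.05 + 1i * 2 * pi * f * 1e-4 + Z1 / 5, tolerance = 1e-12)
  # single compartment, no central airway: identity
  m1 <- single_cp_model(G = 4, H = 8, Raw = 0.2)
  expect_equal(lung_impedance(m1, f), compartment_impedance(m1$compartments[[1]], f),
               tolerance = 1e-15)
})

test_that("unequal peripheral resistances create positive frequency dependence of E_L", {
  f <- seq(0.5, 19.625, by = 0.125)
  mk <- function(raws) lung_model(compartments = lapply(raws, function(r)
    cp_compartment(Raw = r, G = 3, H = 20)), grade_label = "A0_native")
  E_het_of <- function(m) {
    E <- -2 * pi * f * Im(lung_impedance(m, f))
    max(abs(E)) - E[1]
  }
  hom <- E_het_of(mk(c(0.5, 0.5)))
  het <- E_het_of(mk(c(0.05, 2.0)))
  expect_gt(het, hom)  # dispersion strictly increases E_het
  # and E rises with f for the heterogeneous pair
  Ehet_spec <- -2 * pi * f * Im(lung_impedance(mk(c(0.05, 2.0)), f))
  expect_gt(Ehet_spec[length(f)], Ehet_spec[1])
})

test_that("derecruited lungs error as unmeasurable; recruitment is monotone in PEEP", {
  m <- lung_model(compartments = list(cp_compartment(G = 3, H = 9, Pc = 5),
                                      cp_compartment(G = 3, H = 9, Pc = 7)),
                  grade_label = "A3")
  expect_error(lung_impedance(m, 1, peep = 0), class = "lungfot_unmeasurable")
  expect_error(simulate_record(m, default_proto, peep = 0),
               class = "lungfot_unmeasurable")
  expect_silent(lung_impedance(m, 1, peep = 6))
  pre <- default_presets()
  lungs <- lapply(c(11, 12, 13), function(s) sample_lung(pre, "A2", s))
  for (lg in lungs) {
    n_open <- sapply(c(0, 2, 4, 6, 8), function(p)
      sum(sapply(lg$compartments, function(cmp) p >= cmp$Pc)))
    expect_true(all(diff(n_open) >= 0))
  }
})

test_that("grade presets produce the documented draw properties", {
  pre <- default_presets()
  iso <- sample_lung(pre, "A0_iso", seed = 1)
  expect_true(all(sapply(iso$compartments, function(cmp) cmp$Pc < 0)))
  cv <- function(m) {
    H <- sapply(m$compartments, `[[`, "H"); sd(H) / mean(H)
  }
  expect_gt(cv(sample_lung(pre, "A3", seed = 1)),
            cv(sample_lung(pre, "A1", seed = 1)))
  expect_identical(sample_lung(pre, "A2", seed = 9),
                   sample_lung(pre, "A2", seed = 9))
  expect_error(sample_lung(pre, "A4", seed = 1), class = "lungfot_preset_error")
})

test_that("simulated records reproduce the closed-form impedance and noise contract", {
  m <- single_cp_model(G = 5, H = 15, Raw = 0.4)
  rec <- simulate_record(m, default_proto)
  Zhat <- estimate_impedance(rec, default_proto)
  Z <- lung_impedance(m, default_proto$freqs_hz)
  rel <- Mod(complex(real = Zhat$Re_Z, imaginary = Zhat$Im_Z) - Z) / Mod(Z)
  expect_lt(max(rel), 1e-6)
  # resistive limit: nearly pure resistor gives p ~ Rc * q pointwise
  mr <- lung_model(Rc = 0.8, compartments = list(
    cp_compartment(G = 1e-9, H = 1e-9)), grade_label = "A0_native")
  rr <- simulate_record(mr, default_proto)
  expect_equal(rr$pressure, 0.8 * rr$flow, tolerance = 1e-6)
  # same seed, same noise; different seeds differ only in pressure
  r1 <- simulate_record(m, default_proto, snr_db = 40, seed = 5)
  r2 <- simulate_record(m, default_proto, snr_db = 40, seed = 5)
  r3 <- simulate_record(m, default_proto, snr_db = 40, seed = 6)
  expect_identical(r1$pressure, r2$pressure)
  expect_identical(r1$flow, r3$flow)
  expect_false(identical(r1$pressure, r3$pressure))
})

test_that("cohort generation is deterministic with the documented size", {
  co <- generate_cohort(seed = 3)
  expect_equal(nrow(co$animals), 29)          # 6 + 6 + 4 + 7 + 6
  expect_length(co$records, 29 * 5)
  co2 <- generate_cohort(seed = 3)
  expect_identical(co$animals, co2$animals)
  expect_identical(co$records[[17]]$pressure, co2$records[[17]]$pressure)
  sm <- generate_cohort(small_design(1), seed = 1)
  expect_equal(nrow(sm$animals), 5)
  expect_length(sm$records, 25)
})

test_that("record CSV round-trips with metadata", {
  m <- single_cp_model(G = 5, H = 15, Raw = 0.4)
  rec <- simulate_record(m, default_proto, peep = 4, snr_db = 40, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_record(rec, path)
  back <- read_record(path)
  expect_equal(back$pressure, rec$pressure, tolerance = 1e-12)
  expect_equal(attr(back, "peep_cmH2O"), 4)
  expect_equal(attr(back, "fs_hz"), 256)
})
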