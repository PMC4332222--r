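#' Constant-phase compartment
#'
#' A peripheral lung unit: an airway resistance and inertance in series with a
#' constant-phase viscoelastic tissue element (G - jH)/omega^alpha, with
#' alpha = (2/pi) atan(H/G). G is tissue damping, H tissue elastance
#' (cmH2O/mL); Raw and Iaw are the compartmental airway resistance
#' (cmH2O.s/mL) and inertance (cmH2O.s^2/mL). Pc is the closing pressure
#' (cmH2O): the compartment participates only when PEEP >= Pc.
#'
#' @param Raw,Iaw,G,H,Pc scalar parameters (see description); `G`, `H` > 0.
#' @return An object of class `cp_compartment`.
#' @export
#' @examples
#' cp_compartment(Raw = 0.3, G = 3.611, H = 3.611)
cp_compartment <- function(Raw = 0, Iaw = 0, G, H, Pc = -Inf) {
  stopifnot(is_scalar_number(G), G > 0, is_scalar_number(H), H > 0,
            is_scalar_number(Raw), is_scalar_number(Iaw))
  alpha <- (2 / pi) * atan(H / G)
  structure(list(Raw = Raw, Iaw = Iaw, G = G, H = H, alpha = alpha, Pc = Pc),
            class = "cp_compartment")
}

#' Input impedance of one constant-phase compartment
#'
#' Z(f) = Raw + j*omega*Iaw + (G - jH)/omega^alpha, omega = 2*pi*f.
#'
#' @param params a `cp_compartment`.
#' @param f_hz vector of positive frequencies, Hz.
#' @return Complex impedance, cmH2O.s/mL, one value per frequency.
#' @export
compartment_impedance <- function(params, f_hz) {
  stopifnot(inherits(params, "cp_compartment"))
  if (any(f_hz <= 0)) abort_lungfot("frequencies must be positive",
                                    "lungfot_domain_error")
  w <- 2 * pi * f_hz
  params$Raw + 1i * w * params$Iaw +
    (params$G - 1i * params$H) / w^params$alpha
}

#' Heterogeneous constant-phase lung model
#'
#' A central airway (resistance `Rc`, inertance `Ic`) in series with parallel
#' constant-phase compartments. Compartments with closing pressure above the
#' operating PEEP are derecruited and drop out of the parallel combination,
#' which is how the model expresses PEEP-dependent recruitment.
#'
#' @param Rc,Ic central airway resistance (cmH2O.s/mL) and inertance
#'   (cmH2O.s^2/mL).
#' @param compartments list of `cp_compartment` objects (at least one).
#' @param grade_label rejection-grade label, one of
#'   `"A0_native"`, `"A0_iso"`, `"A1"`, `"A2"`, `"A3"`.
#' @return An object of class `lung_model`.
#' @export
lung_model <- function(Rc = 0, Ic = 0, compartments,
                       grade_label = c("A0_native", "A0_iso", "A1", "A2", "A3")) {
  grade_label <- match.arg(grade_label)
  stopifnot(length(compartments) >= 1,
            all(vapply(compartments, inherits, TRUE, "cp_compartment")))
  structure(list(Rc = Rc, Ic = Ic, compartments = compartments,
                 grade_label = grade_label),
            class = "lung_model")
}

open_compartments <- function(model, peep) {
  vapply(model$compartments, function(cmp) peep >= cmp$Pc, TRUE)
}

#' Closed-form lung input impedance
#'
#' Z_L(f) = Rc + j*omega*Ic + [ sum over open compartments of 1/Z_i ]^-1,
#' where a compartment is open iff PEEP >= its closing pressure. With no open
#' compartment the lung is unmeasurable (condition class
#' `lungfot_unmeasurable`), mirroring grades so severe that oscillometry
#' cannot be applied.
#'
#' @param model a `lung_model`.
#' @param f_hz positive frequencies, Hz.
#' @param peep operating PEEP, cmH2O.
#' @return Complex impedance vector, cmH2O.s/mL.
#' @export
lung_impedance <- function(model, f_hz, peep = 0) {
  stopifnot(inherits(model, "lung_model"))
  open <- open_compartments(model, peep)
  if (!any(open))
    abort_lungfot(sprintf("no open compartment at PEEP %g: lung unmeasurable", peep),
                  "lungfot_unmeasurable")
  Y <- 0
  for (cmp in model$compartments[open])
    Y <- Y + 1 / compartment_impedance(cmp, f_hz)
  model$Rc + 1i * 2 * pi * f_hz * model$Ic + 1 / Y
}
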