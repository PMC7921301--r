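#' Rubisco kinetic constants
#'
#' Bundle the temperature-dependent Rubisco kinetics used by the FvCB model:
#' the Michaelis constants for CO2 (`Kc`) and O2 (`Ko`), the photorespiratory
#' CO2 compensation point (`gamma_star`), and the chloroplastic O2 mole
#' fraction (`O`). All gas quantities are mole fractions (equivalent to
#' partial pressures at 1 atm): `Kc` and `gamma_star` in umol mol^-1, `Ko`
#' and `O` in mmol mol^-1.
#'
#' Defaults are the widely used tobacco-based values at 25 C
#' (Kc = 404.9 umol mol^-1, Ko = 278.4 mmol mol^-1, Gamma* = 42.75
#' umol mol^-1) with O at its atmospheric value for 21% O2 growth
#' atmospheres (210 mmol mol^-1). All defaults live in this one place and
#' are overridable per call.
#'
#' @param Kc Michaelis constant for CO2 \[umol mol^-1\].
#' @param Ko Michaelis constant for O2 \[mmol mol^-1\].
#' @param gamma_star Photorespiratory CO2 compensation point \[umol mol^-1\].
#' @param O Chloroplastic O2 mole fraction \[mmol mol^-1\].
#' @param T_ref Reference temperature of the constants \[C\].
#' @return An object of class `kinetic_constants` (a named list).
#' @export
#' @examples
#' kin <- kinetic_constants()
#' kin$Kc * (1 + kin$O / kin$Ko)  # effective Michaelis term of the Ac branch
kinetic_constants <- function(Kc = 404.9, Ko = 278.4, gamma_star = 42.75,
                              O = 210, T_ref = 25) {
  vals <- c(Kc = Kc, Ko = Ko, gamma_star = gamma_star, O = O)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("kinetic constants must all be strictly positive and finite",
         call. = FALSE)
  }
  if (gamma_star >= Kc) {
    stop("gamma_star must be smaller than Kc", call. = FALSE)
  }
  structure(list(Kc = Kc, Ko = Ko, gamma_star = gamma_star, O = O,
                 T_ref = T_ref),
            class = "kinetic_constants")
}

#' FvCB parameter set
#'
#' The three leaf-level parameters estimated from an A-Ci curve: the maximum
#' Rubisco carboxylation rate `Vcmax`, the maximum RuBP-regeneration rate
#' `Jmax`, and respiration in the light `Rd` (all umol m^-2 s^-1), together
#' with the leaf temperature they refer to. `Jmax/Vcmax` outside (1, 3)
#' triggers a warning: fitted C3 curves rarely leave that band.
#'
#' @param Vcmax Maximum Rubisco carboxylation rate \[umol m^-2 s^-1\].
#' @param Jmax Maximum RuBP regeneration rate \[umol m^-2 s^-1\].
#' @param Rd Respiration in the light \[umol m^-2 s^-1\].
#' @param at_temperature Leaf temperature of the values \[C\].
#' @param warn Warn when Jmax/Vcmax is atypical (default TRUE).
#' @return An object of class `fvcb_params`.
#' @export
fvcb_params <- function(Vcmax, Jmax, Rd, at_temperature = 25, warn = TRUE) {
  if (!is.finite(Vcmax) || Vcmax <= 0) stop("Vcmax must be > 0", call. = FALSE)
  if (!is.finite(Jmax) || Jmax <= 0) stop("Jmax must be > 0", call. = FALSE)
  if (!is.finite(Rd) || Rd < 0) stop("Rd must be >= 0", call. = FALSE)
  ratio <- Jmax / Vcmax
  if (warn && (ratio <= 1 || ratio >= 3)) {
    warning(sprintf("Jmax/Vcmax = %.2f lies outside the typical (1, 3) band",
                    ratio), call. = FALSE)
  }
  structure(list(Vcmax = Vcmax, Jmax = Jmax, Rd = Rd,
                 at_temperature = at_temperature),
            class = "fvcb_params")
}

#' @export
print.fvcb_params <- function(x, ...) {
  cat(sprintf(
    "FvCB parameters at %.1f C: Vcmax = %.2f, Jmax = %.2f, Rd = %.3f umol m-2 s-1\n",
    x$at_temperature, x$Vcmax, x$Jmax, x$Rd))
  invisible(x)
}

#' Arrhenius temperature-response specification
#'
#' A single-exponential Arrhenius response: a quantity known at one
#' temperature is scaled to another by
#' `exp(dHa * (Tt - Tr) / (R * Tt * Tr))` with temperatures in kelvin and
#' R = 8.314 J mol^-1 K^-1. The dimensionless pre-exponential `c` of the
#' absolute form is retained for reference but cancels in scaling.
#'
#' @param dHa Activation energy \[J mol^-1\].
#' @param c Optional dimensionless scaling constant of the absolute form.
#' @return An object of class `arrhenius_spec`.
#' @export
arrhenius_spec <- function(dHa, c = NA_real_) {
  if (!is.finite(dHa) || dHa <= 0) stop("dHa must be > 0", call. = FALSE)
  structure(list(c = c, dHa = dHa), class = "arrhenius_spec")
}

#' Default Arrhenius parameter set
#'
#' Activation energies (J mol^-1) for the Rubisco kinetics and the fitted
#' FvCB parameters, from the same tobacco-based temperature-response
#' literature as [kinetic_constants()]: Kc 79 430, Ko 36 380, Gamma* 37 830,
#' Vcmax 65 330, Jmax 43 900, Rd 46 390. One editable block; override any
#' entry by name.
#'
#' @param ... Named overrides, e.g. `Jmax = arrhenius_spec(50000)`.
#' @return Named list of [arrhenius_spec()] objects
#'   (`Kc`, `Ko`, `gamma_star`, `Vcmax`, `Jmax`, `Rd`).
#' @export
default_arrhenius <- function(...) {
  spec <- list(
    Kc         = arrhenius_spec(79430),
    Ko         = arrhenius_spec(36380),
    gamma_star = arrhenius_spec(37830),
    Vcmax      = arrhenius_spec(65330),
    Jmax       = arrhenius_spec(43900),
    Rd         = arrhenius_spec(46390)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    stopifnot(inherits(dots[[nm]], "arrhenius_spec"))
    spec[[nm]] <- dots[[nm]]
  }
  spec
}

#' Scale a quantity between temperatures with an Arrhenius response
#'
#' @param value Quantity at `T_ref`.
#' @param spec An [arrhenius_spec()].
#' @param T_target Target temperature \[C\].
#' @param T_ref Temperature the value refers to \[C\].
#' @return The quantity at `T_target`.
#' @export
#' @examples
#' arrhenius_scale(404.9, arrhenius_spec(79430), T_target = 30, T_ref = 25)
arrhenius_scale <- function(value, spec, T_target, T_ref) {
  stopifnot(inherits(spec, "arrhenius_spec"))
  if (T_target < 0 || T_target > 50 || T_ref < 0 || T_ref > 50) {
    stop("temperatures must lie in the physiological range 0-50 C",
         call. = FALSE)
  }
  R <- 8.314
  Tt <- T_target + 273.15
  Tr <- T_ref + 273.15
  value * exp(spec$dHa * (Tt - Tr) / (R * Tt * Tr))
}

#' Kinetic constants at a leaf temperature
#'
#' Scales `Kc`, `Ko` and `gamma_star` from their reference temperature to a
#' leaf temperature using the Arrhenius set; `O` is temperature independent.
#'
#' @param kin A [kinetic_constants()] object.
#' @param T_leaf Leaf temperature \[C\].
#' @param arrhenius Named list of Arrhenius specs, see [default_arrhenius()].
#' @return A `kinetic_constants` object with `T_ref = T_leaf`.
#' @export
kinetics_at <- function(kin, T_leaf, arrhenius = default_arrhenius()) {
  stopifnot(inherits(kin, "kinetic_constants"))
  kinetic_constants(
    Kc = arrhenius_scale(kin$Kc, arrhenius$Kc, T_leaf, kin$T_ref),
    Ko = arrhenius_scale(kin$Ko, arrhenius$Ko, T_leaf, kin$T_ref),
    gamma_star = arrhenius_scale(kin$gamma_star, arrhenius$gamma_star,
                                 T_leaf, kin$T_ref),
    O = kin$O, T_ref = T_leaf)
}

#' Rubisco-limited net assimilation (Ac)
#'
#' The carboxylation-limited branch of the FvCB model:
#' `Ac = Vcmax * (Ci - Gamma*) / (Ci + Kc * (1 + O/Ko)) - Rd`.
#' Strictly increasing and concave in `Ci`, approaching `Vcmax - Rd` as
#' `Ci -> Inf`, and equal to `-Rd` at `Ci = Gamma*`.
#'
#' @param Ci Intercellular CO2 \[umol mol^-1\], vectorized, each >= 0.
#' @param params An [fvcb_params()] object.
#' @param kin A [kinetic_constants()] object.
#' @return Net assimilation \[umol m^-2 s^-1\].
#' @export
#' @examples
#' p <- fvcb_params(Vcmax = 71.1, Jmax = 134.3, Rd = 0.89)
#' ac_assimilation(300, p, kinetic_constants())  # ~17.2
ac_assimilation <- function(Ci, params, kin) {
  stopifnot(inherits(params, "fvcb_params"), inherits(kin, "kinetic_constants"))
  if (any(Ci < 0)) stop("Ci must be >= 0", call. = FALSE)
  Km <- kin$Kc * (1 + kin$O / kin$Ko)
  params$Vcmax * (Ci - kin$gamma_star) / (Ci + Km) - params$Rd
}

#' RuBP-regeneration-limited net assimilation (Aj)
#'
#' The light-saturated RuBP-regeneration branch of the FvCB model:
#' `Aj = Jmax * (Ci - Gamma*) / (4 Ci + 8 Gamma*) - Rd`.
#' Approaches `Jmax/4 - Rd` as `Ci -> Inf` and equals `-Rd` at
#' `Ci = Gamma*`.
#'
#' @param Ci Intercellular CO2 \[umol mol^-1\], vectorized, each >= 0.
#' @param params An [fvcb_params()] object.
#' @param gamma_star Photorespiratory compensation point \[umol mol^-1\].
#' @return Net assimilation \[umol m^-2 s^-1\].
#' @export
aj_assimilation <- function(Ci, params, gamma_star) {
  stopifnot(inherits(params, "fvcb_params"))
  if (!is.finite(gamma_star) || gamma_star <= 0) {
    stop("gamma_star must be strictly positive", call. = FALSE)
  }
  if (any(Ci < 0)) stop("Ci must be >= 0", call. = FALSE)
  params$Jmax * (Ci - gamma_star) / (4 * Ci + 8 * gamma_star) - params$Rd
}

#' FvCB envelope prediction with limitation labels
#'
#' Net assimilation as the pointwise minimum of the Rubisco-limited and
#' RuBP-regeneration-limited branches, with a per-point label saying which
#' branch is active. Ties are labelled `"RUBISCO"`.
#'
#' @param Ci_values Non-empty vector of intercellular CO2 \[umol mol^-1\].
#' @param params An [fvcb_params()] object.
#' @param kin A [kinetic_constants()] object.
#' @return A tibble with columns `Ci`, `A`, `limitation`
#'   (`"RUBISCO"` or `"RUBP"`).
#' @export
#' @examples
#' p <- fvcb_params(71.1, 134.3, 0.89)
#' predict_envelope(c(300, 800), p, kinetic_constants())
predict_envelope <- function(Ci_values, params, kin) {
  if (length(Ci_values) == 0) stop("Ci_values must be non-empty", call. = FALSE)
  ac <- ac_assimilation(Ci_values, params, kin)
  aj <- aj_assimilation(Ci_values, params, kin$gamma_star)
  tibble::tibble(
    Ci = Ci_values,
    A = pmin(ac, aj),
    limitation = ifelse(ac <= aj, "RUBISCO", "RUBP")
  )
}
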