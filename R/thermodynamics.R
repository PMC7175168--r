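# Gas constant in kcal mol^-1 K^-1; energies are kcal/mol throughout.
R_KCAL <- 1.987204e-3

#' Thermodynamic parameters of bond formation
#'
#' Bundles the Gibbs free energy of bond formation `dG` (kcal/mol) at
#' temperature `T` (K), optionally decomposed into enthalpy `dH` and
#' entropy `dS` via `dG = dH - T dS`. The gas constant is fixed at
#' 1.987204e-3 kcal/(mol K).
#'
#' @param dG Gibbs free energy of bond formation, kcal/mol (optional if
#'   `dH` and `dS` are given).
#' @param T Absolute temperature, K.
#' @param dH Enthalpy of bond formation, kcal/mol (optional).
#' @param dS Entropy of bond formation, kcal/(mol K) (optional).
#' @return An object of class `thermo_parameters`.
#' @export
thermo_parameters <- function(dG = NULL, T, dH = NULL, dS = NULL) {
  check_scalar(T, "T")
  if (T <= 0) stop_domain("`T` must be positive (kelvin), got %g", T)
  if (!is.null(dH) && !is.null(dS)) {
    check_scalar(dH, "dH"); check_scalar(dS, "dS")
    implied <- dH - T * dS
    if (is.null(dG)) {
      dG <- implied
    } else if (abs(dG - implied) >
               1e-9 * max(abs(dG), abs(implied), 1e-300)) {
      stop_domain("dG = %g inconsistent with dH - T*dS = %g", dG, implied)
    }
  }
  if (is.null(dG)) stop_usage("need `dG`, or both `dH` and `dS`")
  check_scalar(dG, "dG")
  structure(list(dG = dG, T = T, dH = dH, dS = dS, R = R_KCAL),
            class = "thermo_parameters")
}

#' Bonding probability from bond free energy
#'
#' Each bond site is a two-state system, so at equilibrium the occupation
#' follows Boltzmann statistics:
#' `Pb = exp(-dG/RT) / (1 + exp(-dG/RT))`. Evaluated in a numerically
#' stable form for large `|dG/RT|` (the logistic saturates; for
#' `dG/RT < -30` the complement `1 - exp(dG/RT)` is returned directly).
#'
#' @param dG Gibbs free energy of bond formation, kcal/mol. Negative
#'   values favor bonding (`Pb > 1/2`).
#' @param T Absolute temperature, K.
#' @return Bonding probability in `(0, 1)`.
#' @examples
#' prob_from_energy(-1.5, 358.15)  # ~0.89 at 85 degrees C
#' @export
prob_from_energy <- function(dG, T) {
  check_scalar(dG, "dG")
  check_scalar(T, "T")
  if (T <= 0) stop_domain("`T` must be positive (kelvin), got %g", T)
  z <- dG / (R_KCAL * T)
  if (z < -30) return(1 - exp(z))
  if (z > 30) return(exp(-z))
  1 / (1 + exp(z))
}

#' Bond free energy from bonding probability
#'
#' Inverse of [prob_from_energy()]: `dG = -RT log(Pb / (1 - Pb))`.
#'
#' @param Pb Bonding probability, strictly inside `(0, 1)`.
#' @param T Absolute temperature, K.
#' @return Free energy in kcal/mol.
#' @export
energy_from_prob <- function(Pb, T) {
  check_scalar(Pb, "Pb")
  check_scalar(T, "T")
  if (T <= 0) stop_domain("`T` must be positive (kelvin), got %g", T)
  if (Pb <= 0 || Pb >= 1)
    stop_domain("`Pb` must be strictly inside (0,1); got %g (dG infinite)", Pb)
  -R_KCAL * T * log(Pb / (1 - Pb))
}

#' Dimensional equilibrium constant from thermodynamics
#'
#' The equilibrium constant of terminus bonding must carry units of
#' concentration; the dimensionless `exp(dG/RT)` is made dimensional by
#' the total monomer-unit concentration:
#' `kappa = U exp(dG/RT) / (1 + exp(-dG/RT))`, algebraically equal to
#' `(1 - Pb)^2 U / Pb` with `Pb = prob_from_energy(dG, T)`.
#'
#' @inheritParams prob_from_energy
#' @param U Total monomer-unit concentration, mol/L.
#' @return Equilibrium constant `kappa = kminus/kplus` in mol/L.
#' @export
kappa_from_energy <- function(dG, T, U) {
  check_scalar(U, "U")
  if (U <= 0) stop_domain("`U` must be positive, got %g", U)
  Pb <- prob_from_energy(dG, T)
  (1 - Pb)^2 * U / Pb
}

#' Split free energy into enthalpy and entropy from two temperatures
#'
#' Given the bond free energy measured (or inferred) at two temperatures,
#' the linear relation `dG = dH - T dS` is solved exactly:
#' `dS = -(dG2 - dG1)/(T2 - T1)`, `dH = dG1 + T1 dS`.
#'
#' @param dG1,dG2 Free energies, kcal/mol.
#' @param T1,T2 The corresponding temperatures, K; must differ.
#' @return List with `dH` (kcal/mol) and `dS` (kcal/(mol K)).
#' @export
decompose_enthalpy_entropy <- function(dG1, T1, dG2, T2) {
  check_scalar(dG1, "dG1"); check_scalar(dG2, "dG2")
  check_scalar(T1, "T1"); check_scalar(T2, "T2")
  if (T1 <= 0 || T2 <= 0) stop_domain("temperatures must be positive")
  if (T1 == T2)
    stop_domain("T1 == T2: cannot separate enthalpy and entropy")
  dS <- -(dG2 - dG1) / (T2 - T1)
  dH <- dG1 + T1 * dS
  list(dH = dH, dS = dS)
}

#' Temperature-dependence regime of bond formation
#'
#' The signs of `dH` and `dS` determine how favorability changes with
#' temperature. When the signs match there is a critical temperature
#' `Tc = dH / dS` at which `dG = 0` (so `Pb = 1/2`):
#' * `+,+` — favorable above `Tc` (entropy-driven);
#' * `+,-` — unfavorable at all temperatures;
#' * `-,+` — favorable at all temperatures;
#' * `-,-` — favorable below `Tc` (enthalpy-driven, the usual
#'   polymerization case: bonds order the chain).
#'
#' @param dH Enthalpy, kcal/mol.
#' @param dS Entropy, kcal/(mol K).
#' @return List with `regime` (character label) and `Tc_K` (kelvin, or
#'   `NA` when the signs differ or `dS = 0`).
#' @export
classify_regime <- function(dH, dS) {
  check_scalar(dH, "dH"); check_scalar(dS, "dS")
  if (dH == 0 && dS == 0)
    stop_domain("dH and dS both zero: no thermodynamic drive")
  if (dS == 0) {
    return(list(regime = if (dH < 0) "favorable at all T"
                         else "unfavorable at all T",
                Tc_K = NA_real_))
  }
  if (dH == 0) {
    return(list(regime = if (dS > 0) "favorable at all T"
                         else "unfavorable at all T",
                Tc_K = NA_real_))
  }
  if (dH > 0 && dS > 0) {
    list(regime = "favorable above Tc", Tc_K = dH / dS)
  } else if (dH > 0 && dS < 0) {
    list(regime = "unfavorable at all T", Tc_K = NA_real_)
  } else if (dH < 0 && dS > 0) {
    list(regime = "favorable at all T", Tc_K = NA_real_)
  } else {
    list(regime = "favorable below Tc", Tc_K = dH / dS)
  }
}

#' Celsius/kelvin helpers
#'
#' @param x Temperature in degrees Celsius (`celsius_to_kelvin`) or
#'   kelvin (`kelvin_to_celsius`).
#' @return Converted temperature.
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15
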