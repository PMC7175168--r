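#' Rate constants of terminus bonding
#'
#' Association/dissociation rates of the single bond-forming reaction
#' between a free chain-end pair. `kplus` carries units L/(mol s) (the
#' reaction is bimolecular), `kminus` 1/s. Their ratio
#' `kappa = kminus/kplus` is the equilibrium constant, which in this
#' model has units of concentration and equals the critical monomer
#' concentration.
#'
#' @param kplus Bonding rate constant, L/(mol s), `> 0`.
#' @param kminus Unbonding rate, 1/s, `>= 0` (0 = irreversible bonding).
#' @return Object of class `rate_constants` with the derived `kappa`.
#' @export
rate_constants <- function(kplus, kminus) {
  check_scalar(kplus, "kplus"); check_scalar(kminus, "kminus")
  if (kplus <= 0) stop_domain("`kplus` must be positive, got %g", kplus)
  if (kminus < 0) stop_domain("`kminus` must be nonnegative, got %g", kminus)
  structure(list(kplus = kplus, kminus = kminus, kappa = kminus / kplus),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constants: k+ =", format(x$kplus), "L/(mol s); k- =",
      format(x$kminus), "1/s; kappa =", format(x$kappa), "mol/L\n")
  invisible(x)
}

# Dimensionless groups controlling the steady state at total
# concentration U: kbar = kappa / (2U), Delta = sqrt(kbar (2 + kbar)).
reduced_constants <- function(rates, U) {
  stopifnot(inherits(rates, "rate_constants"))
  check_scalar(U, "U")
  if (U <= 0) stop_domain("`U` must be positive, got %g", U)
  kbar <- rates$kappa / (2 * U)
  list(kbar = kbar, Delta = sqrt(kbar * (2 + kbar)))
}

#' Steady-state bonding probability
#'
#' The Hill-Langmuir fixed point `Pb = (1-Pb)U / ((1-Pb)U + kappa)`
#' is a quadratic in `Pb`; the root inside `[0, 1]` is
#' `Pb = 1 + kbar - sqrt(kbar (2 + kbar))` with `kbar = kappa/(2U)`
#' (the other root, `1 + kbar + Delta`, always exceeds 1).
#'
#' @param rates A [rate_constants()] object.
#' @param U Total monomer-unit concentration, mol/L.
#' @return Steady-state bonding probability in `(0, 1]`; exactly 1 when
#'   `kminus = 0`.
#' @examples
#' steady_state_probability(rate_constants(7.4e-5, 1e-6), U = 1)  # ~0.89
#' @export
steady_state_probability <- function(rates, U) {
  rc <- reduced_constants(rates, U)
  1 + rc$kbar - rc$Delta
}

#' Instantaneous rate of change of the bonding probability
#'
#' In a well-mixed solution the length distribution stays Flory-Schulz
#' while its parameter evolves by mass action on the single bond
#' reaction: `dp/dt = U kplus (1-p)^2 - kminus p`. Zero exactly at the
#' steady state.
#'
#' @param p Current bonding probability in `[0, 1]`.
#' @param rates A [rate_constants()] object.
#' @param U Total monomer-unit concentration, mol/L.
#' @return Rate `dp/dt` in 1/s.
#' @export
dp_dt <- function(p, rates, U) {
  stopifnot(inherits(rates, "rate_constants"))
  check_probability(p, "p", allow_one = TRUE)
  check_scalar(U, "U")
  U * rates$kplus * (1 - p)^2 - rates$kminus * p
}

#' Closed-form time evolution of the bonding probability
#'
#' The Riccati equation `dp/dt = U kplus (1-p)^2 - kminus p` is separable
#' and solves in hyperbolic functions. With `kbar = kappa/(2U)`,
#' `Delta = sqrt(kbar (2+kbar))` and rate scale `Delta kplus U`:
#' * `p0 > Pb`: `p(t) = 1 + kbar - Delta tanh(s t + atanh((1+kbar-p0)/Delta))`;
#' * `p0 < Pb`: the `atanh` argument exceeds 1 and the solution continues
#'   analytically on the `coth` branch,
#'   `p(t) = 1 + kbar - Delta coth(s t + acoth((1+kbar-p0)/Delta))`;
#' * `p0 = Pb` (within 1e-12): constant;
#' * `kminus = 0`: irreversible limit
#'   `p(t) = 1 - 1/(1/(1-p0) + kplus U t)`.
#'
#' All branches are monotone, stay between `p0` and `Pb`, and approach
#' `Pb` as `t -> Inf`. Hyperbolic arguments are clamped at 350; past
#' that, the asymptote `Pb` is returned exactly.
#'
#' @param t Time(s) in seconds, `>= 0`; vectorized.
#' @param p0 Initial bonding probability in `[0, 1)`.
#' @param rates A [rate_constants()] object.
#' @param U Total monomer-unit concentration, mol/L.
#' @return `p(t)`, same length as `t`.
#' @examples
#' r <- rate_constants(7.4e-5, 1e-6)
#' p_closed_form(c(0, 1e5, 1e7), p0 = 0, rates = r, U = 1)
#' @export
p_closed_form <- function(t, p0, rates, U) {
  check_probability(p0, "p0")
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop_domain("`t` must be nonnegative finite time(s)")
  rc <- reduced_constants(rates, U)
  kbar <- rc$kbar; Delta <- rc$Delta
  Pb <- 1 + kbar - Delta

  if (rates$kminus == 0) {
    # irreversible: 1/(1-p) grows linearly
    return(1 - 1 / (1 / (1 - p0) + rates$kplus * U * t))
  }
  if (abs(p0 - Pb) <= 1e-12) return(rep(Pb, length(t)))

  s <- Delta * rates$kplus * U        # 1/s
  arg0 <- (1 + kbar - p0) / Delta
  if (p0 > Pb) {
    # arg0 < 1: tanh branch
    c0 <- atanh(arg0)
    z <- s * t + c0
    out <- ifelse(z > 350, Pb, 1 + kbar - Delta * tanh(pmin(z, 350)))
  } else {
    # arg0 > 1: coth branch (acoth(x) = atanh(1/x))
    c0 <- atanh(1 / arg0)
    z <- s * t + c0
    out <- ifelse(z > 350, Pb,
                  1 + kbar - Delta / tanh(pmin(z, 350)))
  }
  out
}

#' Critical concentration
#'
#' As total material `U -> Inf`, the steady-state free-monomer
#' concentration `n(1) = (1 - Pb)^2 U` saturates at
#' `Cc = kappa = kminus/kplus`. Measuring the plateau monomer
#' concentration therefore gives one rate constant from the other.
#'
#' @param rates A [rate_constants()] object.
#' @return Critical concentration in mol/L.
#' @export
critical_concentration <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  rates$kappa
}

#' Rate of change of the number-average degree of polymerization
#'
#' With `Xn = 1/(1 - p)` (Carothers) and the chain rule on the bonding
#' dynamics, `dXn/dt = kplus U - kminus Xn (Xn - 1)`. Growth is linear
#' in time while bonds are scarce and slows as unbonding catches up.
#'
#' @param Xn Current number-average degree of polymerization, `>= 1`.
#' @param rates A [rate_constants()] object.
#' @param U Total monomer-unit concentration, mol/L.
#' @return `dXn/dt` in 1/s.
#' @export
dXn_dt <- function(Xn, rates, U) {
  stopifnot(inherits(rates, "rate_constants"))
  check_scalar(Xn, "Xn")
  if (Xn < 1) stop_domain("`Xn` must be >= 1, got %g", Xn)
  check_scalar(U, "U")
  rates$kplus * U - rates$kminus * Xn * (Xn - 1)
}

#' Rate constants from thermodynamics
#'
#' Given the unbonding rate (e.g. a measured hydrolysis rate) and the
#' bond free energy at temperature `T`, the bonding rate follows from
#' `kplus = kminus / kappa` with `kappa = kappa_from_energy(dG, T, U)`.
#' The resulting steady-state bonding probability reproduces
#' `prob_from_energy(dG, T)`.
#'
#' @param kminus Unbonding rate, 1/s, strictly positive.
#' @param dG Bond free energy, kcal/mol.
#' @param T Absolute temperature, K.
#' @param U Total monomer-unit concentration, mol/L.
#' @return A [rate_constants()] object.
#' @export
rate_from_thermo <- function(kminus, dG, T, U) {
  check_scalar(kminus, "kminus")
  if (kminus <= 0)
    stop_domain("`kminus` must be positive to infer `kplus`")
  kappa <- kappa_from_energy(dG, T, U)
  rate_constants(kplus = kminus / kappa, kminus = kminus)
}

#' Closed-form dynamics summary
#'
#' Packages the constants of the closed-form solution for reporting: the
#' steady state `Pb`, the dimensionless groups, the solution branch, the
#' integration constant, and the relaxation rate scale `Delta kplus U`.
#'
#' @inheritParams p_closed_form
#' @return List with `Pb`, `kbar`, `Delta`, `branch` (one of `"tanh"`,
#'   `"coth"`, `"constant"`, `"irreversible"`), `c` (integration
#'   constant; `NA` for constant/irreversible), and `rate_scale` (1/s).
#' @export
closed_form_solution <- function(p0, rates, U) {
  check_probability(p0, "p0")
  rc <- reduced_constants(rates, U)
  Pb <- 1 + rc$kbar - rc$Delta
  if (rates$kminus == 0) {
    branch <- "irreversible"; c0 <- NA_real_
  } else if (abs(p0 - Pb) <= 1e-12) {
    branch <- "constant"; c0 <- NA_real_
  } else if (p0 > Pb) {
    branch <- "tanh"; c0 <- atanh((1 + rc$kbar - p0) / rc$Delta)
  } else {
    branch <- "coth"; c0 <- atanh(rc$Delta / (1 + rc$kbar - p0))
  }
  list(Pb = Pb, kbar = rc$kbar, Delta = rc$Delta, branch = branch,
       c = c0, rate_scale = rc$Delta * rates$kplus * U)
}
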