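#' Length-truncated mass-action polymerization system
#'
#' The infinite family of aggregation/scission reactions
#' `P_i + P_j <-> P_(i+j)` is truncated by excluding, a priori, every
#' reaction whose product would exceed length `d` (`i + j <= d`). This
#' keeps the system closed and mass-conserving — truncation never deletes
#' material, it only forbids growth past `d`.
#'
#' @param d Maximum chain length carried by the state vector, `>= 1`.
#'   Capped at 2000 by default (the right-hand side costs O(d^2));
#'   pass `allow_large = TRUE` to override.
#' @param rates A [rate_constants()] object.
#' @param x0 Initial concentrations, mol/L, indexed by length `1..d`;
#'   all entries `>= 0` with positive total mass.
#' @param allow_large Permit `d > 2000`.
#' @return Object of class `truncated_system` with the conserved total
#'   monomer-unit concentration `U = sum(k * x0)`.
#' @seealso [monomer_start()], [flory_schulz_start()] for initial
#'   conditions; [integrate_system()], [steady_state()].
#' @export
truncated_system <- function(d, rates, x0, allow_large = FALSE) {
  d <- check_count(d, "d")[1L]
  if (d > 2000 && !allow_large)
    stop_usage("d = %d exceeds the default cap of 2000; set allow_large = TRUE",
               d)
  stopifnot(inherits(rates, "rate_constants"))
  if (!is.numeric(x0) || length(x0) != d || any(!is.finite(x0)))
    stop_domain("`x0` must be a finite numeric vector of length d = %d", d)
  if (any(x0 < 0)) stop_domain("`x0` must be nonnegative")
  U <- sum(seq_len(d) * x0)
  if (U <= 0) stop_domain("`x0` must carry positive total mass")
  structure(list(d = d, rates = rates, x0 = x0, U = U),
            class = "truncated_system")
}

#' All-monomer initial condition
#'
#' @param U Total monomer-unit concentration, mol/L.
#' @param d Truncation length.
#' @return Concentration vector `(U, 0, ..., 0)` of length `d`.
#' @export
monomer_start <- function(U, d) {
  check_scalar(U, "U")
  if (U <= 0) stop_domain("`U` must be positive, got %g", U)
  d <- check_count(d, "d")[1L]
  c(U, rep(0, d - 1L))
}

#' Flory-Schulz initial condition on a finite length grid
#'
#' The infinite Flory-Schulz distribution at parameter `p` is truncated
#' at `d` and then rescaled proportionally (all components by the same
#' factor) so the grid carries total monomer-unit mass exactly `U`.
#'
#' @param p Bonding probability in `[0, 1)`.
#' @param U Total monomer-unit concentration, mol/L.
#' @param d Truncation length.
#' @return Concentration vector of length `d` with `sum(k * x) == U`.
#' @export
flory_schulz_start <- function(p, U, d) {
  d <- check_count(d, "d")[1L]
  x <- concentrations(flory_schulz_state(p, U), kmax = d)
  x * (U / sum(seq_len(d) * x))
}

#' Mass-action right-hand side of the truncated system
#'
#' Component k of the time derivative collects every truncated reaction
#' in which a k-mer takes part:
#' `sum_{l=1}^{d-k} (2 kminus x[k+l] - 2 kplus x[k] x[l])`
#' (growth of/scission back to a k-mer, doubled because the k-mer can be
#' either partner) plus
#' `sum_{l=1}^{k-1} (kplus x[l] x[k-l] - kminus x[k])`
#' (formation of a k-mer from two shorter chains and its scission at any
#' of its k-1 internal bonds). Every reaction conserves monomer units,
#' so `sum(k * rhs) = 0` identically.
#'
#' @param x Concentration vector over lengths `1..d`, nonnegative.
#' @param rates A [rate_constants()] object.
#' @return Rate vector, mol/(L s), same length as `x`.
#' @export
polymerization_rhs <- function(x, rates) {
  stopifnot(inherits(rates, "rate_constants"))
  if (any(x < 0)) stop_domain("negative concentrations in `x`")
  rhs_raw(x, rates$kplus, rates$kminus)
}

# Unchecked RHS used inside the integrator (solvers probe slightly
# negative states near zero; the dynamics remain well-defined).
rhs_raw <- function(x, kplus, kminus) {
  d <- length(x)
  if (d == 1L) return(0)
  k <- seq_len(d)
  cs <- cumsum(x)
  tail_sum <- cs[d] - cs            # sum_{j>k} x_j
  shead <- c(cs[(d - 1L):1L], 0)    # sum_{l=1}^{d-k} x_l
  conv <- numeric(d)                # sum_{l=1}^{k-1} x_l x_{k-l}
  for (kk in 2:d)
    conv[kk] <- sum(x[1:(kk - 1L)] * x[(kk - 1L):1L])
  2 * kminus * tail_sum - 2 * kplus * x * shead +
    kplus * conv - (k - 1) * kminus * x
}

# Analytic Jacobian of rhs_raw; handed to lsoda to avoid O(d) numeric
# differencing per Jacobian evaluation.
rhs_jacobian <- function(x, kplus, kminus) {
  d <- length(x)
  K <- matrix(seq_len(d), d, d)      # row index k
  M <- t(K)                          # column index m
  cs <- cumsum(x)
  shead <- c(cs[(d - 1L):1L], 0)
  J <- 2 * kminus * (M > K) - 2 * kplus * x * (M + K <= d)
  idx <- K - M
  sel <- idx >= 1L
  J[sel] <- J[sel] + 2 * kplus * x[idx[sel]]
  diag(J) <- diag(J) - 2 * kplus * shead - (seq_len(d) - 1) * kminus
  J
}

#' Integrate the truncated polymerization dynamics
#'
#' Solves the mass-action system with `deSolve::ode` (lsoda: adaptive,
#' switches to an implicit method when stiff) using the analytic
#' Jacobian. Output times default to a logarithmic grid — the dynamics
#' relax on the scale `1/(Delta kplus U)`, typically spanning decades.
#'
#' @param system A [truncated_system()].
#' @param t_end Final time, s.
#' @param rtol,atol Solver tolerances; `atol` defaults to `1e-12 * U`.
#' @param times Output time grid (must start at 0); overrides the
#'   default logarithmic grid.
#' @param n_points Number of points in the default grid.
#' @return Object of class `polymer_trajectory`: `times`, `states`
#'   (matrix, one row per time, one column per length), `U`, `d`,
#'   `rates`, and `mass_drift` (max relative deviation of total mass).
#' @export
integrate_system <- function(system, t_end, rtol = 1e-8,
                             atol = 1e-12 * system$U, times = NULL,
                             n_points = 200L) {
  stopifnot(inherits(system, "truncated_system"))
  check_scalar(t_end, "t_end")
  if (t_end <= 0) stop_domain("`t_end` must be positive, got %g", t_end)
  if (is.null(times)) {
    times <- c(0, exp(seq(log(t_end) - log(1e6), log(t_end),
                          length.out = n_points)))
  }
  if (times[1] != 0) stop_domain("`times` must start at 0")
  kp <- system$rates$kplus; km <- system$rates$kminus
  func <- function(t, y, parms) list(rhs_raw(y, kp, km))
  jac <- function(t, y, parms) rhs_jacobian(y, kp, km)
  sol <- deSolve::ode(y = system$x0, times = times, func = func,
                      parms = NULL, method = "lsoda",
                      jacfunc = jac, jactype = "fullusr",
                      rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop_numerical("ODE integration failed (istate = %d)", diagn[1])
  states <- unname(sol[, -1, drop = FALSE])
  mass <- states %*% seq_len(system$d)
  structure(list(times = sol[, 1], states = states, U = system$U,
                 d = system$d, rates = system$rates,
                 mass_drift = max(abs(mass - system$U)) / system$U),
            class = "polymer_trajectory")
}

#' @export
print.polymer_trajectory <- function(x, ...) {
  cat("Polymer trajectory: d =", x$d, ",", length(x$times),
      "time points to t =", format(max(x$times)), "s\n")
  cat("  U =", format(x$U), "mol/L; max relative mass drift",
      format(x$mass_drift, digits = 3), "\n")
  invisible(x)
}

#' Bonding probability of a concentration state
#'
#' Every molecule, regardless of length, carries exactly one free A
#' terminus, so the bond concentration is `[AB] = U - sum(x)` and the
#' bonding probability is `(U - sum(x)) / U`.
#'
#' @param x Concentration vector over lengths `1..d`.
#' @param U Total monomer-unit concentration the state should carry.
#' @return Bonding probability in `[0, 1]`.
#' @export
bonding_probability_of_state <- function(x, U) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_domain("`x` must be finite numeric")
  check_scalar(U, "U")
  mass <- sum(seq_along(x) * x)
  if (abs(mass - U) / U > 1e-3)
    stop_numerical("state mass %g inconsistent with U = %g", mass, U)
  min(max((U - sum(x)) / U, 0), 1)
}

#' Integrate to steady state
#'
#' Integrates in expanding time chunks until the residual satisfies
#' `||rhs|| <= tol * kplus * U * ||x||` or the elapsed model time
#' exceeds `100 / (Delta kplus U)` (100 relaxation times; `kplus U`
#' alone sets the scale in the irreversible case where `Delta = 0`).
#'
#' @param system A [truncated_system()].
#' @param tol Relative residual tolerance.
#' @param rtol,atol Solver tolerances (tighter than [integrate_system()]
#'   defaults, since the target is the fixed point itself).
#' @return List with `x` (the steady state), `residual` (achieved
#'   relative residual), `t_elapsed` (model seconds integrated), and
#'   `converged`. Warns if the time cap is hit first.
#' @export
steady_state <- function(system, tol = 1e-10, rtol = 1e-10,
                         atol = 1e-14 * system$U) {
  stopifnot(inherits(system, "truncated_system"))
  kp <- system$rates$kplus; km <- system$rates$kminus
  rc <- reduced_constants(system$rates, system$U)
  scale <- if (rc$Delta > 0) rc$Delta * kp * system$U else kp * system$U
  t_cap <- 100 / scale
  resid_rel <- function(x) {
    nx <- sqrt(sum(x^2))
    sqrt(sum(rhs_raw(x, kp, km)^2)) / (kp * system$U * nx)
  }
  x <- system$x0
  if (system$d == 1L || resid_rel(x) <= tol)
    return(list(x = x, residual = resid_rel(x), t_elapsed = 0,
                converged = TRUE))
  t_now <- 0
  t_next <- 0.01 / scale
  while (t_now < t_cap) {
    t_next <- min(t_next, t_cap)
    sys_chunk <- system
    sys_chunk$x0 <- pmax(x, 0)
    traj <- integrate_system(sys_chunk, t_end = t_next - t_now,
                             rtol = rtol, atol = atol,
                             times = c(0, t_next - t_now))
    x <- traj$states[nrow(traj$states), ]
    t_now <- t_next
    if (resid_rel(x) <= tol) {
      return(list(x = x, residual = resid_rel(x), t_elapsed = t_now,
                  converged = TRUE))
    }
    t_next <- t_now * 4
  }
  warning(sprintf(
    "steady_state: residual %.3g above tol %.3g at the time cap %.3g s",
    resid_rel(x), tol, t_cap))
  list(x = x, residual = resid_rel(x), t_elapsed = t_now,
       converged = FALSE)
}

#' Write a trajectory to long-format CSV
#'
#' Columns `t,k,concentration`, one row per (time, length) pair, with a
#' JSON sidecar recording the run parameters.
#'
#' @param traj A `polymer_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "polymer_trajectory"))
  long <- data.frame(
    t = format(rep(traj$times, each = traj$d), digits = 17),
    k = rep(seq_len(traj$d), times = length(traj$times)),
    concentration = format(as.vector(t(traj$states)), digits = 17))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  final_p <- bonding_probability_of_state(
    traj$states[nrow(traj$states), ], traj$U)
  jsonlite::write_json(
    list(U = traj$U, d = traj$d, kplus = traj$rates$kplus,
         kminus = traj$rates$kminus, final_p = final_p,
         mass_drift = traj$mass_drift),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
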