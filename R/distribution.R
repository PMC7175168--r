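#' Flory-Schulz state of a polymerizing solution
#'
#' A Flory-Schulz (geometric) length distribution is fully described by the
#' bonding probability `p` — the fraction of potential inter-monomer bonds
#' that are formed — together with the total concentration `U` of monomer
#' units (mol/L). Every chain of length k carries k - 1 internal bonds, so
#' when all bond sites are independently occupied with probability `p` the
#' chain-length distribution is geometric with success probability 1 - p.
#'
#' @param p Bonding probability, in `[0, 1)`. `p = 1` is rejected: it
#'   implies infinite mean chain length.
#' @param U Total monomer-unit concentration, mol/L; must be positive.
#' @param m0 Monomer molar mass in g/mol; optional, only needed for mass
#'   distributions (e.g. 324.2 for an RNA nucleotide residue).
#'
#' @return An object of class `flory_schulz_state` with fields `p`, `U`,
#'   `m0`, plus the derived total molecule concentration `n_star = (1-p)*U`
#'   and bond concentration `AB = p*U` (their sum is exactly `U`: each
#'   monomer unit is either chain-starting or preceded by a bond).
#' @examples
#' st <- flory_schulz_state(p = 0.5, U = 1)
#' st$n_star + st$AB  # == U
#' @export
flory_schulz_state <- function(p, U, m0 = NULL) {
  check_probability(p, "p")
  check_scalar(U, "U")
  if (U <= 0) stop_domain("`U` must be positive, got %g", U)
  if (!is.null(m0)) {
    check_scalar(m0, "m0")
    if (m0 <= 0) stop_domain("`m0` must be positive, got %g", m0)
  }
  structure(list(p = p, U = U, m0 = m0,
                 n_star = (1 - p) * U, AB = p * U),
            class = "flory_schulz_state")
}

#' @export
print.flory_schulz_state <- function(x, ...) {
  cat("Flory-Schulz state: p =", format(x$p), " U =", format(x$U), "mol/L\n")
  cat("  molecules n* =", format(x$n_star), "mol/L; bonds [AB] =",
      format(x$AB), "mol/L\n")
  if (!is.null(x$m0)) cat("  monomer molar mass m0 =", format(x$m0), "g/mol\n")
  invisible(x)
}

#' Probability mass function of chain length
#'
#' `rho(k) = (1 - p) p^(k-1)`: the probability that a molecule drawn at
#' random from the solution is a k-mer. Lengths are 1-based; k = 1 is the
#' monomer.
#'
#' @param p Bonding probability in `[0, 1)`.
#' @param k Integer chain length(s), `k >= 1`; vectorized.
#' @return Probability (vector), summing to 1 over k = 1, 2, ...
#' @examples
#' length_pmf(0.5, 1:5)
#' @export
length_pmf <- function(p, k) {
  check_probability(p, "p")
  k <- check_count(k, "k")
  (1 - p) * p^(k - 1)
}

#' Equilibrium concentrations of each chain length
#'
#' `n(k) = (1 - p)^2 p^(k-1) [U]`, the molar concentration of k-mers in a
#' Flory-Schulz solution. The monomer-unit mass balance
#' `sum_k k n(k) = [U]` holds exactly in the infinite sum.
#'
#' @param state A [flory_schulz_state()].
#' @param kmax Largest length to report. Defaults to the smallest K whose
#'   tail mass beyond K is below `1e-12 * U`, capped at `1e6`.
#' @return Numeric vector of length `kmax`; entry k is the k-mer
#'   concentration in mol/L.
#' @export
concentrations <- function(state, kmax = default_kmax(state$p)) {
  stopifnot(inherits(state, "flory_schulz_state"))
  kmax <- check_count(kmax, "kmax")[1L]
  k <- seq_len(kmax)
  (1 - state$p)^2 * state$p^(k - 1) * state$U
}

#' Default reporting length for distribution vectors
#'
#' Smallest K such that the monomer-unit mass in chains longer than K is
#' below `tol` relative to the total, capped at 1e6. Uses the closed-form
#' tail mass `(1 + K(1-p)) p^K`.
#'
#' @param p Bonding probability in `[0, 1)`.
#' @param tol Relative tail-mass tolerance.
#' @return Integer K >= 1.
#' @export
default_kmax <- function(p, tol = 1e-12) {
  check_probability(p, "p")
  if (p == 0) return(1L)
  # tail mass fraction (1 + K(1-p)) p^K <= tol; bracket then bisect
  f <- function(K) (1 + K * (1 - p)) * p^K - tol
  K <- 1
  while (f(K) > 0 && K < 1e6) K <- K * 2
  if (K >= 1e6) return(1000000L)
  lo <- K %/% 2; hi <- K
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  as.integer(hi)
}

#' Equilibrium polymer yield
#'
#' Mass fraction of monomer units converted to polymers (chains of length
#' at least 2) at bonding probability `Pb`:
#' `eta = 1 - (1 - Pb)^2 = Pb (2 - Pb)`.
#'
#' @param Pb Bonding probability in `[0, 1]`.
#' @return Yield fraction in `[0, 1]`.
#' @examples
#' polymer_yield(exp(-1 / 2))  # ~0.845 for a mass-spectrum mode at 2
#' @export
polymer_yield <- function(Pb) {
  check_probability(Pb, "Pb", allow_one = TRUE)
  1 - (1 - Pb)^2
}

#' Mass distribution over chain length
#'
#' `m(k) = k m0 n(k)`: the mass (g/L) carried by k-mers. This is what a
#' chromatographic "spectrum" approximates — signal proportional to total
#' mass at each length. Total mass over all k equals `m0 * U`.
#'
#' @inheritParams concentrations
#' @return Numeric vector of length `kmax`, g/L per length.
#' @export
mass_distribution <- function(state, kmax = default_kmax(state$p)) {
  stopifnot(inherits(state, "flory_schulz_state"))
  if (is.null(state$m0))
    stop_domain("`m0` (monomer molar mass) is required for mass distributions")
  n <- concentrations(state, kmax)
  seq_along(n) * state$m0 * n
}

#' Continuous mode of the mass distribution
#'
#' The mass distribution m(k) has a single interior peak at
#' `k* = -1 / ln(p)`. Matching this to the peak of an experimental
#' spectrum gives a one-line estimate of the bonding probability.
#'
#' @param p Bonding probability in `(0, 1)`. `p = 0` is an error: the
#'   solution is monomer-dominated and the mode is undefined.
#' @return Real modal length `k* > 0`.
#' @seealso [mode_to_p()] for the inverse.
#' @export
mass_mode <- function(p) {
  check_probability(p, "p")
  if (p == 0)
    stop_domain("mass mode undefined at p = 0 (monomer-dominated solution)")
  -1 / log(p)
}

#' Bonding probability from a modal length
#'
#' Inverse of [mass_mode()]: `p = exp(-1 / k*)`.
#'
#' @param kstar Modal length of the mass distribution, `> 0`.
#' @return Bonding probability in `(0, 1)`.
#' @examples
#' mode_to_p(2)  # ~0.607: a mode of 2 implies ~60\% bonding
#' @export
mode_to_p <- function(kstar) {
  check_scalar(kstar, "kstar")
  if (kstar <= 0) stop_domain("`kstar` must be positive, got %g", kstar)
  exp(-1 / kstar)
}

#' Number-average degree of polymerization
#'
#' Carothers relation: the mean chain length is `Xn = 1 / (1 - p)`.
#'
#' @param p Bonding probability in `[0, 1)`.
#' @return Mean chain length, `>= 1`.
#' @export
number_average_dp <- function(p) {
  check_probability(p, "p")
  1 / (1 - p)
}

#' Write a length-distribution vector to CSV with a JSON sidecar
#'
#' One row per length with header `k,concentration` (or `k,mass`), plus a
#' `<path>.json` sidecar recording `{p, U, m0, kmax}` so the vector can be
#' regenerated from parameters alone.
#'
#' @param state A [flory_schulz_state()].
#' @param path Output CSV path.
#' @param what `"concentration"` (mol/L) or `"mass"` (g/L).
#' @param kmax Number of lengths to write.
#' @return `path`, invisibly.
#' @export
write_distribution_csv <- function(state, path,
                                   what = c("concentration", "mass"),
                                   kmax = default_kmax(state$p)) {
  what <- match.arg(what)
  v <- if (what == "mass") mass_distribution(state, kmax)
       else concentrations(state, kmax)
  df <- data.frame(k = seq_along(v), value = format(v, digits = 17))
  names(df)[2] <- what
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(p = state$p, U = state$U, m0 = state$m0,
                  kmax = length(v))
  jsonlite::write_json(sidecar[!vapply(sidecar, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
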