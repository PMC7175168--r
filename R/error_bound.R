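#' Monomer-unit mass beyond a truncation length
#'
#' Closed form of the tail of the mass balance:
#' `My = sum_{k > d} k n(k) = U (1 + d (1 - p)) p^d`.
#' This is exactly the mass a length-`d` grid cannot represent, and the
#' mass any conservative truncation must relocate into lengths `<= d`.
#'
#' @param p Bonding probability in `[0, 1)`.
#' @param U Total monomer-unit concentration, mol/L.
#' @param d Truncation length, `>= 1`.
#' @return Tail mass, mol/L.
#' @export
tail_mass <- function(p, U, d) {
  check_probability(p, "p")
  check_scalar(U, "U")
  d <- check_count(d, "d")[1L]
  U * (1 + d * (1 - p)) * p^d
}

# Closed-form series used by the bound (all geometric):
#   ||y||^2   = sum_{k>d} n(k)^2 = (1-p)^4 U^2 p^(2d) / (1-p^2)
#   ||n||^2   = sum_{k>=1} n(k)^2 = (1-p)^4 U^2 / (1-p^2)
#   Md Md^T   = sum_{k=1}^d k^2 = d(d+1)(2d+1)/6
tail_norm_sq <- function(p, U, d) (1 - p)^4 * U^2 * p^(2 * d) / (1 - p^2)
dist_norm_sq <- function(p, U) (1 - p)^4 * U^2 / (1 - p^2)
sum_k_sq <- function(d) d * (d + 1) * (2 * d + 1) / 6

#' Lower bound on the relative error of any mass-conserving truncation
#'
#' A finite simulation of maximum length `d` cannot represent the tail
#' of the Flory-Schulz distribution, and if it conserves mass it must
#' also misplace the tail's mass among lengths `<= d`. The l2 distance
#' between the true distribution and its closest mass-correct truncation
#' is therefore a floor under the error of *any* such simulation:
#' `E(p, d) = p^d sqrt(1 + 6 (1 + d(1-p))^2 (1-p^2) /
#'                         (d (d+1) (2d+1) (1-p)^4))`,
#' strictly greater than, but asymptotically equal to, `p^d`. `E` is the
#' ratio of (unsquared) l2 norms and is independent of `U`.
#'
#' @param p Bonding probability in `[0, 1)`.
#' @param d Truncation length, `>= 1`; vectorized.
#' @return Dimensionless relative-error lower bound; 0 at `p = 0`.
#' @export
relative_error_bound <- function(p, d) {
  check_probability(p, "p")
  d <- check_count(d, "d")
  if (p == 0) return(rep(0, length(d)))
  p^d * sqrt(1 + (1 + d * (1 - p))^2 * (1 - p^2) /
                 (sum_k_sq(d) * (1 - p)^4))
}

#' Minimum-norm mass-restoring projection onto a finite grid
#'
#' Truncating a length-distribution vector at `d` loses the tail mass
#' `My`. The least-squares correction `dx` with `sum(k dx[k]) = My` and
#' minimal `||dx||` is `dx[k] = k My / S`, `S = d(d+1)(2d+1)/6` (the
#' normal-equations solution for the 1 x d mass operator `Md = (1..d)`).
#'
#' @param n_vec Concentration vector over lengths `1..K`, `K > d`.
#' @param d Truncation length.
#' @param U Total monomer-unit mass the projection must carry; defaults
#'   to the mass of `n_vec` itself.
#' @return Vector of length `d`: the head of `n_vec` plus the mass
#'   correction; its total mass is exactly `U`.
#' @export
project_truncation <- function(n_vec, d, U = sum(seq_along(n_vec) * n_vec)) {
  if (!is.numeric(n_vec) || any(!is.finite(n_vec)))
    stop_domain("`n_vec` must be finite numeric")
  d <- check_count(d, "d")[1L]
  K <- length(n_vec)
  if (K <= d) stop_domain("length(n_vec) = %d must exceed d = %d", K, d)
  x <- n_vec[seq_len(d)]
  k <- seq_len(d)
  My <- U - sum(k * x)
  x + k * My / sum_k_sq(d)
}

#' Full truncation-error report
#'
#' Collects the tail statistics, projection norms, the relative-error
#' lower bound `E`, and the lax bound `p^d` for one `(p, U, d)`.
#' The decomposition `E^2 ||n||^2 = ||dx||^2 + ||y||^2` holds by
#' construction (tail error plus in-grid mass correction are
#' orthogonal).
#'
#' @inheritParams tail_mass
#' @return Object of class `truncation_error_report`: fields `p`, `U`,
#'   `d`, `tail_mass`, `tail_norm_sq`, `correction_norm_sq`, `E`, `lax`.
#' @export
truncation_error_report <- function(p, U, d) {
  check_probability(p, "p")
  check_scalar(U, "U")
  d <- check_count(d, "d")[1L]
  My <- tail_mass(p, U, d)
  structure(list(
    p = p, U = U, d = d,
    tail_mass = My,
    tail_norm_sq = if (p > 0) tail_norm_sq(p, U, d) else 0,
    correction_norm_sq = My^2 / sum_k_sq(d),
    E = relative_error_bound(p, d),
    lax = p^d), class = "truncation_error_report")
}

#' @export
print.truncation_error_report <- function(x, ...) {
  cat("Truncation error bound at p =", format(x$p), ", d =", x$d, "\n")
  cat("  tail mass", format(x$tail_mass), "mol/L;  E >=",
      format(x$E, digits = 6), " (lax bound p^d =",
      format(x$lax, digits = 6), ")\n")
  invisible(x)
}

#' Truncation lengths ruled out by the lax bound
#'
#' From `E > p^d`, any `d < log(E*) / log(Pb)` must exceed the error
#' target `E*`. The threshold is reported rounded to the nearest
#' integer; the unrounded real value is returned alongside.
#'
#' @param Pb Bonding probability in `(0, 1)`.
#' @param target_E Relative error target in `(0, 1)`.
#' @return List with `d` (integer threshold) and `d_real` (unrounded).
#' @export
min_d_lax <- function(Pb, target_E) {
  check_scalar(Pb, "Pb"); check_scalar(target_E, "target_E")
  if (Pb <= 0 || Pb >= 1)
    stop_domain("`Pb` must be strictly inside (0,1), got %g", Pb)
  if (target_E <= 0 || target_E >= 1)
    stop_domain("`target_E` must be strictly inside (0,1), got %g", target_E)
  d_real <- log(target_E) / log(Pb)
  list(d = as.integer(round(d_real)), d_real = d_real)
}

#' Smallest truncation length not excluded by the full bound
#'
#' Inverts [relative_error_bound()] numerically (doubling to bracket,
#' then bisection — `E` is strictly decreasing in `d`): the smallest
#' integer `d` with `E(Pb, d) < target_E`. Every simulation shorter
#' than this must exceed the error target.
#'
#' @inheritParams min_d_lax
#' @return Integer truncation length.
#' @export
min_d_full <- function(Pb, target_E) {
  check_scalar(Pb, "Pb"); check_scalar(target_E, "target_E")
  if (Pb <= 0 || Pb >= 1)
    stop_domain("`Pb` must be strictly inside (0,1), got %g", Pb)
  if (target_E <= 0 || target_E >= 1)
    stop_domain("`target_E` must be strictly inside (0,1), got %g", target_E)
  if (relative_error_bound(Pb, 1L) < target_E) return(1L)
  hi <- 2L
  while (relative_error_bound(Pb, hi) >= target_E) {
    hi <- hi * 2L
    if (hi > .Machine$integer.max %/% 2L)
      stop_numerical("no attainable truncation length below integer range")
  }
  lo <- hi %/% 2L  # E(lo) >= target, E(hi) < target
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (relative_error_bound(Pb, mid) >= target_E) lo <- mid else hi <- mid
  }
  hi
}
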