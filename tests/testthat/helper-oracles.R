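# Independent oracles used across the suite. Each recomputes a quantity
# by a different route than the package (enumeration, brute-force
# summation, generic solvers) so agreement is evidence, not tautology.

table2_rates <- function() rate_constants(kplus = 7.4e-5, kminus = 1e-6)

# RHS by explicit enumeration over every truncated reaction
# P_i + P_j <-> P_(i+j), i + j <= d, applying stoichiometry reaction by
# reaction. The forward flux of the (i, j) channel is kplus*x_i*x_j and
# its reverse kminus*x_(i+j); enumerating ordered pairs (i, j) counts
# each unordered collision twice, which is exactly the doubled
# bookkeeping the rate law requires for terminus pairings.
rhs_enumeration <- function(x, rates) {
  d <- length(x)
  dx <- numeric(d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (i + j > d) next
    fwd <- rates$kplus * x[i] * x[j]
    rev <- rates$kminus * x[i + j]
    dx[i] <- dx[i] - fwd + rev
    dx[j] <- dx[j] - fwd + rev
    dx[i + j] <- dx[i + j] + fwd - rev
  }
  dx
}

# Naive truncation of the infinite system: keep the untruncated sums but
# zero all lengths > d. Deletes mass whenever a chain grows past d.
rhs_deletion <- function(x, rates, big = 4L * length(x)) {
  d <- length(x)
  xe <- c(x, numeric(big - d))
  dx <- numeric(big)
  for (i in seq_len(big)) for (j in seq_len(big)) {
    if (i + j > big) next
    fwd <- rates$kplus * xe[i] * xe[j]
    rev <- rates$kminus * xe[i + j]
    dx[i] <- dx[i] - fwd + rev
    dx[j] <- dx[j] - fwd + rev
    dx[i + j] <- dx[i + j] + fwd - rev
  }
  out <- dx[seq_len(d)]
  out  # caller re-zeroes lengths > d after each step
}

# Detailed-balance steady state of the truncated system: every channel
# balances individually, forcing x_k = x_1 (x_1 / kappa)^(k-1); the
# free constant x_1 is fixed by the mass constraint sum(k x_k) = U.
detailed_balance_state <- function(rates, U, d) {
  kappa <- rates$kappa
  mass <- function(x1) sum(seq_len(d) * x1 * (x1 / kappa)^(seq_len(d) - 1)) - U
  x1 <- uniroot(mass, c(1e-300, U), tol = 1e-15)$root
  x1 * (x1 / kappa)^(seq_len(d) - 1)
}

# Generic equality-constrained least squares: minimize ||z - x_head||
# s.t. sum(k z_k) = U, via the KKT system solved with base solve().
constrained_ls_projection <- function(n_vec, d, U = sum(seq_along(n_vec) * n_vec)) {
  x <- n_vec[seq_len(d)]
  k <- seq_len(d)
  kkt <- rbind(cbind(2 * diag(d), k), c(k, 0))
  sol <- solve(kkt, c(2 * x, U))
  unname(sol[seq_len(d)])
}

# Brute-force tail mass by direct summation of k n(k) for k > d.
tail_mass_brute <- function(p, U, d, kmax = 5000L) {
  k <- (d + 1L):kmax
  sum(k * (1 - p)^2 * p^(k - 1) * U)
}

# Relative l2 error of a finite state vs the Flory-Schulz distribution
# at parameter p, both embedded in a common length range.
rel_l2_error <- function(x, p, U, kmax = max(length(x) * 4L, 2000L)) {
  n <- (1 - p)^2 * p^(seq_len(kmax) - 1) * U
  xe <- c(x, numeric(kmax - length(x)))
  sqrt(sum((xe - n)^2) / sum(n^2))
}
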