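test_that("steady-state probability is the fixed point of the bond balance", {
  expect_equal(steady_state_probability(rate_constants(1e-4, 0), 1), 1)
  expect_equal(round(steady_state_probability(table2_rates(), 1), 2), 0.89)
  # bisection oracle on Pb = (1-Pb)U / ((1-Pb)U + kappa)
  set.seed(7)
  for (i in 1:15) {
    kplus <- 10^runif(1, -6, -2); kminus <- 10^runif(1, -9, -4)
    U <- 10^runif(1, -2, 1)
    r <- rate_constants(kplus, kminus)
    f <- function(Pb) Pb - (1 - Pb) * U / ((1 - Pb) * U + r$kappa)
    oracle <- uniroot(f, c(0, 1 - 1e-15), tol = 1e-15)$root
    expect_equal(steady_state_probability(r, U), oracle,
                 tolerance = 1e-10)
  }
  # the discarded quadratic root 1 + kbar + Delta always exceeds 1
  for (kbar in 10^seq(-6, 2)) {
    expect_gt(1 + kbar + sqrt(kbar * (2 + kbar)), 1)
  }
})

test_that("dp/dt is the mass-action bond balance", {
  r <- table2_rates()
  expect_equal(dp_dt(0, r, 1), r$kplus)
  expect_equal(dp_dt(0.5, r, 1), 1.8e-5)
  Pb <- steady_state_probability(r, 1)
  expect_lt(abs(dp_dt(Pb, r, 1)), 1e-14 * r$kplus)
})

test_that("closed-form p(t) agrees with adaptive integration over 5 decades", {
  r <- table2_rates()
  U <- 1
  rk_oracle <- function(p0, ts) {
    sol <- deSolve::ode(y = c(p = p0), times = c(0, ts),
                        func = function(t, y, parms)
                          list(U * r$kplus * (1 - y)^2 - r$kminus * y),
                        parms = NULL,
                        rtol = 1e-12, atol = 1e-14, method = "ode45")
    sol[-1, "p"]
  }
  ts <- 10^(2:7)  # surrounds the relaxation time ~1.2e5 s
  expect_equal(p_closed_form(ts, 0, r, U), rk_oracle(0, ts),
               tolerance = 1e-8)
  # coth branch (start below Pb), tanh branch (start above Pb)
  expect_equal(p_closed_form(ts, 0.3, r, U), rk_oracle(0.3, ts),
               tolerance = 1e-8)
  expect_equal(p_closed_form(ts, 0.99, r, U), rk_oracle(0.99, ts),
               tolerance = 1e-8)
})

test_that("closed-form branches honor initial value, monotonicity, limits", {
  r <- table2_rates()
  Pb <- steady_state_probability(r, 1)
  for (p0 in c(0, 0.3, Pb, 0.95)) {
    expect_equal(p_closed_form(0, p0, r, 1), p0, tolerance = 1e-14)
    ts <- 10^seq(1, 8, by = 0.25)
    pt <- p_closed_form(ts, p0, r, 1)
    expect_true(all(diff(pt) * sign(Pb - p0 + 1e-300) >= -1e-15))
    expect_true(all(pt >= min(p0, Pb) - 1e-12 &
                    pt <= max(p0, Pb) + 1e-12))
    expect_equal(p_closed_form(1e12, p0, r, 1), Pb, tolerance = 1e-10)
  }
  sol <- closed_form_solution(0, r, 1)
  expect_identical(sol$branch, "coth")
  expect_identical(closed_form_solution(0.95, r, 1)$branch, "tanh")
  expect_identical(closed_form_solution(Pb, r, 1)$branch, "constant")
  # irreversible limit: hyperbolic algebra degenerates to 1/(1-p) growth
  ri <- rate_constants(1e-4, 0)
  expect_identical(closed_form_solution(0, ri, 1)$branch, "irreversible")
  ts <- c(0, 1e3, 1e5)
  expect_equal(p_closed_form(ts, 0.2, ri, 1),
               1 - 1 / (1 / 0.8 + 1e-4 * ts), tolerance = 1e-14)
  expect_error(p_closed_form(10, 1, r, 1), class = "polyadd_domain_error")
})

test_that("nondimensional form: dp/dtau = (1-p)^2/2 - kbar p", {
  r <- table2_rates()
  U <- 1
  kbar <- r$kappa / (2 * U)
  for (p in c(0, 0.25, 0.7, 0.95)) {
    # dp/dt divided by 2 kplus U must equal the dimensionless RHS
    expect_equal(dp_dt(p, r, U) / (2 * r$kplus * U),
                 0.5 * (1 - p)^2 - kbar * p, tolerance = 1e-14)
  }
})

test_that("critical concentration is kappa and n(1) saturates toward it", {
  expect_equal(critical_concentration(rate_constants(1e-4, 0)), 0)
  r <- table2_rates()
  expect_equal(critical_concentration(r), 0.0135135135135135,
               tolerance = 1e-12)
  n1 <- vapply(r$kappa * c(1e2, 1e4, 1e6), function(U) {
    (1 - steady_state_probability(r, U))^2 * U
  }, 0)
  expect_true(all(diff(n1) > 0))
  expect_true(all(n1 < r$kappa))
  expect_equal(n1[3], r$kappa, tolerance = 1e-2)
})

test_that("degree-of-polymerization rate matches the chain rule on p", {
  r <- table2_rates()
  Pb <- steady_state_probability(r, 1)
  expect_equal(dXn_dt(1 / (1 - Pb), r, 1), 0, tolerance = 1e-18)
  # irreversible: constant slope kplus U regardless of Xn
  ri <- rate_constants(2e-4, 0)
  for (Xn in c(1, 3, 50)) expect_equal(dXn_dt(Xn, ri, 1), 2e-4)
  # finite differences of Xn(t) = 1/(1 - p(t)) from the closed form
  for (t in c(1e3, 1e5, 5e5)) {
    h <- max(t * 1e-6, 1)
    Xn <- function(t) 1 / (1 - p_closed_form(t, 0, r, 1))
    expect_equal((Xn(t + h) - Xn(t - h)) / (2 * h),
                 dXn_dt(Xn(t), r, 1),
                 tolerance = 1e-6)
  }
  expect_error(dXn_dt(0.5, r, 1), class = "polyadd_domain_error")
})

test_that("rate constants are recoverable from thermodynamics", {
  # reference route: kminus = 1e-6/s with Pb rounded to 0.89 at 1 M
  kappa89 <- (1 - 0.89)^2 * 1 / 0.89
  expect_equal(signif(1e-6 / kappa89, 2), 7.4e-5)
  # full roundtrip through energy_from_prob / rate_from_thermo
  set.seed(11)
  for (i in 1:10) {
    r <- rate_constants(10^runif(1, -6, -3), 10^runif(1, -8, -5))
    U <- 10^runif(1, -1, 1)
    Pb <- steady_state_probability(r, U)
    dG <- energy_from_prob(Pb, 358.15)
    r2 <- rate_from_thermo(r$kminus, dG, 358.15, U)
    expect_equal(r2$kplus, r$kplus, tolerance = 1e-10)
    expect_equal(steady_state_probability(r2, U),
                 prob_from_energy(dG, 358.15), tolerance = 1e-10)
  }
  # symmetric case dG = 0
  r0 <- rate_from_thermo(1e-6, 0, 300, U = 2)
  expect_equal(steady_state_probability(r0, 2), 0.5, tolerance = 1e-12)
  expect_equal(r0$kplus, 2 * 1e-6 / 2, tolerance = 1e-12)
  expect_error(rate_from_thermo(0, -1, 300, 1),
               class = "polyadd_domain_error")
})
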