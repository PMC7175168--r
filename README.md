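# polyadd

Kinetics and equilibrium of reversible linear step-growth
(polyaddition) polymerization of functionally identical monomers — the
setting of nonenzymatic RNA oligomerization in well-mixed aqueous
solution, and of any polymer that grows by reversible end-to-end
addition without removal of a condensate.

The package is aimed at modelers and experimentalists who want to move
between four descriptions of the same chemical system:

1. **Equilibrium length statistics.** When every potential
   inter-monomer bond is independently occupied with probability *p*,
   the chain-length distribution is the Flory–Schulz (geometric) law
   ρ(k) = (1−p) p^(k−1), with k-mer concentrations
   n(k) = (1−p)² p^(k−1) [U] for total monomer-unit concentration [U].
   Summary statistics follow in closed form: polymer yield
   η = 1 − (1−p)² = p(2−p), number-average degree of polymerization
   X̄n = 1/(1−p) (Carothers), the mode of the mass distribution
   k\* = −1/ln p, and the critical concentration
   C_c = κ = k₋/k₊.
2. **Thermodynamics.** Each bond site is a two-state system, so the
   steady-state bonding probability obeys Boltzmann statistics,
   P_b = (1 + e^{ΔG_b/RT})⁻¹, with ΔG_b = ΔH_b − TΔS_b; two
   measurements at different temperatures separate enthalpy from
   entropy and locate the critical temperature T_c = ΔH_b/ΔS_b.
3. **Dynamics.** The bonding probability evolves by mass action,
   dp/dt = k₊[U](1−p)² − k₋p, a Riccati equation solved exactly in
   tanh/coth form (`p_closed_form()`); the full length distribution
   inherits this motion because a well-mixed step-growth system stays
   Flory–Schulz at all times.
4. **Finite simulation and its limits.** The infinite reaction family
   P_i + P_j ⇌ P_{i+j} is truncated at a maximum length d by excluding
   reactions whose product would exceed d (mass stays conserved), and
   integrated as a d-dimensional stiff ODE system (`integrate_system()`,
   via deSolve). Because the true distribution has an infinite tail, any
   mass-conserving truncation incurs a relative ℓ₂ error of at least
   E(p, d) = p^d · sqrt(1 + (1 + d(1−p))²(1−p²) / (S_d (1−p)⁴)),
   S_d = d(d+1)(2d+1)/6 — strictly greater than, and asymptotically
   equal to, p^d. `min_d_full()` inverts this bound to the smallest
   truncation length a target error permits.

An `experiment_analysis` layer interprets HPLC-style oligomer mass
spectra (`fit_p_from_spectrum()`, `interpret_probability()`,
`two_temperature_analysis()`) and generates synthetic populations and
spectra with known ground truth.

## Worked example

Hot-spring-like reference conditions: 1 M monomer units, hydrolysis
rate k₋ = 10⁻⁶ s⁻¹, bonding rate k₊ = 7.4×10⁻⁵ L mol⁻¹ s⁻¹
(equivalently ΔG_b ≈ −1.5 kcal/mol at 85 °C).

```r
library(polyadd)
r <- rate_constants(kplus = 7.4e-5, kminus = 1e-6)

steady_state_probability(r, U = 1)
#> [1] 0.8903129
critical_concentration(r)
#> [1] 0.01351351
p_closed_form(c(1e4, 1e5, 1e6), p0 = 0, rates = r, U = 1)
#> [1] 0.4234684 0.8519402 0.8903129
number_average_dp(0.8903129)
#> [1] 9.116844
truncation_error_report(0.8903129, U = 1, d = 25)
#> Truncation error bound at p = 0.8903129 , d = 25
#>   tail mass 0.2049704 mol/L;  E >= 0.117866  (lax bound p^d = 0.054773 )
```

Read: 89% of bond sites are occupied at steady state, free monomer
saturates at 13.5 mM however much material is supplied, the solution
relaxes over ~10⁵ s, mean chains are ~9 units long — and a simulation
truncated at d = 25 under these conditions must misstate the length
distribution by at least 12% in relative ℓ₂ norm, however good the
solver.

A command-line front end mirrors the R API for shell pipelines:

```sh
exec/polyadd steady-state --kplus 7.4e-5 --kminus 1e-6 --u 1 --out-dir out/
exec/polyadd bound --dg -3.5 --temp-c 85 --target-e 0.01 --out-dir out/
exec/polyadd simulate --d 100 --t-end 1e7 --out-dir out/
```

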