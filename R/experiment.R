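#' Oligomer mass spectrum
#'
#' A binned, length-indexed "spectrum" as produced by HPLC-style
#' analysis of an oligomerization product: a signal proportional to the
#' total mass at each chain length.
#'
#' @param lengths Strictly increasing positive integer lengths.
#' @param signal Nonnegative signal values (arbitrary units), same
#'   length as `lengths`; at least 2 entries are needed for mode
#'   fitting.
#' @param T Measurement temperature in kelvin (optional; carried for
#'   downstream thermodynamic interpretation).
#' @return Object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(lengths, signal, T = NULL) {
  lengths <- check_count(lengths, "lengths")
  if (length(lengths) < 2L)
    stop_domain("need at least 2 spectrum entries")
  if (any(diff(lengths) <= 0))
    stop_domain("`lengths` must be strictly increasing")
  if (!is.numeric(signal) || length(signal) != length(lengths) ||
      any(!is.finite(signal)) || any(signal < 0))
    stop_domain("`signal` must be nonnegative, same length as `lengths`")
  if (!is.null(T)) {
    check_scalar(T, "T")
    if (T <= 0) stop_domain("`T` must be positive (kelvin)")
  }
  structure(list(lengths = lengths, signal = signal, T = T),
            class = "mass_spectrum")
}

#' Read/write a spectrum as CSV (`k,signal`)
#'
#' @param path CSV path with header `k,signal`.
#' @param T Optional measurement temperature (K) to attach.
#' @return A [mass_spectrum()] (`read_spectrum_csv`) or `path`
#'   invisibly (`write_spectrum_csv`).
#' @export
read_spectrum_csv <- function(path, T = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("k", "signal") %in% names(df)))
    stop_usage("spectrum CSV must have columns `k` and `signal`")
  mass_spectrum(df$k, df$signal, T = T)
}

#' @rdname read_spectrum_csv
#' @param spec A [mass_spectrum()].
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "mass_spectrum"))
  utils::write.csv(
    data.frame(k = spec$lengths,
               signal = format(spec$signal, digits = 17)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate the bonding probability from a mass spectrum
#'
#' Two estimators:
#' * `"argmax"` (default): locate the spectrum peak `k*` (ties break
#'   toward the smaller length) and invert the mode relation
#'   `p = exp(-1/k*)`. Simple and robust, but quantizes `p` to
#'   `exp(-1/k)` for integer `k`.
#' * `"wls"`: the model mass distribution obeys
#'   `log(m(k)/k) = const + (k-1) log(p)`, so a signal-weighted linear
#'   regression of `log(signal/k)` on `k` estimates `log p` as its
#'   slope. Nonpositive signals are dropped with a warning.
#'
#' @param spec A [mass_spectrum()].
#' @param method `"argmax"` or `"wls"`.
#' @return List with `p`, `method`, and diagnostics: `kstar` (argmax)
#'   or `slope`, `intercept`, `residual_se`, `n_used` (wls).
#' @export
fit_p_from_spectrum <- function(spec, method = c("argmax", "wls")) {
  stopifnot(inherits(spec, "mass_spectrum"))
  method <- match.arg(method)
  if (diff(range(spec$signal)) == 0)
    stop_domain("flat spectrum: no mode to locate")
  if (method == "argmax") {
    kstar <- spec$lengths[which.max(spec$signal)]  # first max: smaller k
    list(p = mode_to_p(kstar), method = method, kstar = kstar)
  } else {
    keep <- spec$signal > 0
    if (any(!keep))
      warning(sprintf("dropping %d nonpositive signal(s) from wls fit",
                      sum(!keep)))
    k <- spec$lengths[keep]; s <- spec$signal[keep]
    if (length(k) < 2L) stop_domain("fewer than 2 positive signals")
    fit <- stats::lm(log(s / k) ~ k, weights = s)
    slope <- unname(stats::coef(fit)[2])
    p <- exp(slope)
    if (!(p > 0 && p < 1))
      stop_numerical("wls slope %g implies p outside (0,1)", slope)
    list(p = p, method = method, slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         residual_se = suppressWarnings(summary(fit)$sigma),
         n_used = length(k))
  }
}

#' Thermodynamic and distributional interpretation of a bonding probability
#'
#' At equilibrium the fitted `p` is the steady-state bonding
#' probability, which pins down the bond free energy at the measurement
#' temperature plus all equilibrium summary statistics.
#'
#' @param p Bonding probability in `(0, 1)`.
#' @param T Measurement temperature, K.
#' @param U Total monomer-unit concentration, mol/L (optional; enables
#'   the dimensional equilibrium constant `kappa`).
#' @return List with `dG` (kcal/mol), `eta` (polymer yield), `Xn`
#'   (number-average degree of polymerization), `kstar` (mass-mode
#'   length), and `kappa` (mol/L, if `U` given).
#' @export
interpret_probability <- function(p, T, U = NULL) {
  dG <- energy_from_prob(p, T)
  out <- list(dG = dG, eta = polymer_yield(p),
              Xn = number_average_dp(p), kstar = mass_mode(p))
  if (!is.null(U)) out$kappa <- kappa_from_energy(dG, T, U)
  out
}

#' Two-temperature enthalpy/entropy analysis
#'
#' Combines a bonding probability inferred at one temperature with a
#' reference bond free energy at another (e.g. a standard-state
#' literature value) to separate enthalpy from entropy and locate the
#' critical temperature.
#'
#' @param p1 Bonding probability at temperature `T1`, in `(0, 1)`.
#' @param T1 Temperature of the measurement, K.
#' @param dG2 Reference free energy, kcal/mol, at `T2`.
#' @param T2 Reference temperature, K; must differ from `T1`.
#' @return List with `dG1`, `dH`, `dS`, `Tc_K` (possibly `NA`),
#'   `Tc_C`, and `regime`.
#' @export
two_temperature_analysis <- function(p1, T1, dG2, T2) {
  dG1 <- energy_from_prob(p1, T1)
  de <- decompose_enthalpy_entropy(dG1, T1, dG2, T2)
  cls <- classify_regime(de$dH, de$dS)
  list(dG1 = dG1, dH = de$dH, dS = de$dS,
       Tc_K = cls$Tc_K,
       Tc_C = if (is.na(cls$Tc_K)) NA_real_ else kelvin_to_celsius(cls$Tc_K),
       regime = cls$regime)
}

#' Sample chain lengths from a Flory-Schulz population
#'
#' i.i.d. geometric draws on support 1, 2, ... with success probability
#' `1 - p` (mean length `1/(1-p)`); reproducible for a fixed seed.
#'
#' @param p Bonding probability in `[0, 1)`.
#' @param n_molecules Number of molecules to draw.
#' @param seed Integer RNG seed.
#' @return Integer vector of sampled lengths.
#' @export
generate_population <- function(p, n_molecules, seed) {
  check_probability(p, "p")
  n_molecules <- check_count(n_molecules, "n_molecules")[1L]
  check_scalar(seed, "seed")
  withr_seed(seed, stats::rgeom(n_molecules, prob = 1 - p) + 1L)
}

#' Synthesize a noisy mass spectrum with known ground truth
#'
#' Forward model of an HPLC-style measurement: the exact mass
#' distribution `m(k)` for lengths `1..kmax`, perturbed by multiplicative
#' Gaussian noise `signal[k] = m(k) (1 + eps_k)` with
#' `eps_k ~ N(0, noise_cv)`, truncated at -0.99 so signals stay
#' positive. Chromatographic peak-area noise scales with the signal,
#' hence the multiplicative form.
#'
#' @param p True bonding probability in `(0, 1)`.
#' @param m0 Monomer molar mass, g/mol.
#' @param kmax Largest length in the spectrum.
#' @param noise_cv Coefficient of variation of the noise (0 = exact).
#' @param seed Integer RNG seed.
#' @param U Total monomer-unit concentration, mol/L.
#' @return A [mass_spectrum()] over lengths `1..kmax`.
#' @export
generate_spectrum <- function(p, m0, kmax, noise_cv = 0, seed = 1L,
                              U = 1) {
  check_probability(p, "p")
  if (p == 0) stop_domain("`p` must be positive for a polymer spectrum")
  check_scalar(noise_cv, "noise_cv")
  if (noise_cv < 0) stop_domain("`noise_cv` must be nonnegative")
  kmax <- check_count(kmax, "kmax")[1L]
  m <- mass_distribution(flory_schulz_state(p, U, m0), kmax = kmax)
  eps <- if (noise_cv > 0)
    withr_seed(seed, pmax(stats::rnorm(kmax, 0, noise_cv), -0.99))
  else rep(0, kmax)
  mass_spectrum(seq_len(kmax), m * (1 + eps))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG
# stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
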