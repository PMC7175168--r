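# Command-line interface: git-style subcommands over the package
# functions. `parse_config()` and `run_command()` are exported so the
# pipeline is fully testable in-process; exec/polyadd is a thin wrapper.

CLI_SUBCOMMANDS <- c("steady-state", "dynamics", "simulate", "bound",
                     "analyze", "thermo", "fixtures")

# Reference defaults for the forward problem: 1 M of monomer units,
# hydrolysis rate 1e-6/s, bond free energy -1.5 kcal/mol at 85 C.
CLI_DEFAULTS <- list(u = 1, kminus = 1e-6, dg = -1.5, `temp-c` = 85)

cli_log <- function(level, cfg, msg, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(msg, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --key value pairs -> named list (values kept as strings here).
parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop_usage("unexpected argument `%s` (flags are --key value)", a)
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[[i + 1L]], "--"))
      stop_usage("flag `--%s` is missing a value", key)
    out[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  out
}

as_num <- function(raw, key) {
  v <- suppressWarnings(as.numeric(raw))
  if (is.na(v)) stop_usage("flag `--%s` expects a number, got `%s`", key, raw)
  v
}

#' Parse CLI arguments into a resolved run configuration
#'
#' First argument is the subcommand; the rest are `--key value` flags.
#' A YAML config file (`--config`) supplies values with precedence
#' CLI flag > config file > built-in default (`U` = 1 mol/L,
#' `kminus` = 1e-6/s, `dG` = -1.5 kcal/mol, `T` = 85 C). The forward
#' rate is parameterized by exactly one of `--kplus` or `--dg`; passing
#' both is a usage error.
#'
#' @param args Character vector of command-line arguments.
#' @return Object of class `run_config`: `command`, `params` (named
#'   list of strings), `out_dir`, `seed`, `log_level`.
#' @export
parse_config <- function(args) {
  if (length(args) < 1L)
    stop_usage("no subcommand; expected one of: %s",
               paste(CLI_SUBCOMMANDS, collapse = ", "))
  command <- args[[1L]]
  if (!command %in% CLI_SUBCOMMANDS)
    stop_usage("unknown subcommand `%s`; expected one of: %s", command,
               paste(CLI_SUBCOMMANDS, collapse = ", "))
  flags <- parse_flags(args[-1L])
  if (!is.null(flags$config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_usage("`--config` requires the yaml package")
    filed <- yaml::read_yaml(flags$config)
    if (!is.list(filed)) stop_usage("config file must be a YAML mapping")
    names(filed) <- gsub("_", "-", names(filed))
    for (k in names(filed))
      if (is.null(flags[[k]])) flags[[k]] <- as.character(filed[[k]])
    flags$config <- NULL
  }
  if (!is.null(flags$kplus) && !is.null(flags$dg))
    stop_usage(paste("`--kplus` and `--dg` both given: the forward rate",
                     "must be parameterized by exactly one of them"))
  if (!is.null(flags[["temp-c"]]) && !is.null(flags[["temp-k"]]))
    stop_usage("give either `--temp-c` or `--temp-k`, not both")
  structure(list(
    command = command,
    params = flags[setdiff(names(flags),
                           c("out-dir", "seed", "log-level"))],
    out_dir = flags[["out-dir"]] %||% ".",
    seed = as.integer(as_num(flags$seed %||% "1", "seed")),
    log_level = flags[["log-level"]] %||% "info"), class = "run_config")
}

# Temperature in kelvin from flags (defaults to 85 C when `needed`).
resolve_temp <- function(p, default_c = CLI_DEFAULTS[["temp-c"]]) {
  if (!is.null(p[["temp-k"]])) return(as_num(p[["temp-k"]], "temp-k"))
  celsius_to_kelvin(as_num(p[["temp-c"]] %||% as.character(default_c),
                           "temp-c"))
}

# Rate constants from flags: either --kplus directly or via --dg.
resolve_rates <- function(p, U) {
  kminus <- as_num(p$kminus %||% as.character(CLI_DEFAULTS$kminus),
                   "kminus")
  if (!is.null(p$kplus))
    return(rate_constants(as_num(p$kplus, "kplus"), kminus))
  dG <- as_num(p$dg %||% as.character(CLI_DEFAULTS$dg), "dg")
  rate_from_thermo(kminus, dG, resolve_temp(p), U)
}

write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Execute a parsed run configuration
#'
#' Dispatches to the subcommand, writes its CSV/JSON artifacts under
#' `out_dir`, logs parameters and timing to standard error, and returns
#' the report. Every JSON artifact embeds the resolved parameters and
#' the seed, so outputs are regenerable from their sidecars alone.
#'
#' @param config A [parse_config()] result.
#' @return The report list, invisibly.
#' @export
run_command <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  set.seed(config$seed)
  p <- config$params
  report <- switch(config$command,
    "steady-state" = cmd_steady_state(p, config),
    "thermo"       = cmd_thermo(p, config),
    "dynamics"     = cmd_dynamics(p, config),
    "simulate"     = cmd_simulate(p, config),
    "bound"        = cmd_bound(p, config),
    "analyze"      = cmd_analyze(p, config),
    "fixtures"     = cmd_fixtures(p, config))
  report$seed <- config$seed
  report$command <- config$command
  path <- file.path(config$out_dir,
                    paste0(gsub("-", "_", config$command), ".json"))
  write_report_json(report, path)
  cli_log("info", config, "%s finished in %.2f s -> %s", config$command,
          proc.time()[["elapsed"]] - t0, path)
  invisible(report)
}

cmd_steady_state <- function(p, config) {
  U <- as_num(p$u %||% "1", "u")
  rates <- resolve_rates(p, U)
  rc <- reduced_constants(rates, U)
  Pb <- steady_state_probability(rates, U)
  list(kplus = rates$kplus, kminus = rates$kminus, U = U,
       kappa = rates$kappa, kappa_bar = rc$kbar, Delta = rc$Delta,
       Pb = Pb, Cc = critical_concentration(rates),
       eta = polymer_yield(Pb), Xn = number_average_dp(Pb))
}

cmd_thermo <- function(p, config) {
  U <- as_num(p$u %||% "1", "u")
  T <- resolve_temp(p)
  dH <- if (!is.null(p$dh)) as_num(p$dh, "dh")
  dS <- if (!is.null(p$ds)) as_num(p$ds, "ds")
  dG <- if (!is.null(p$dg)) as_num(p$dg, "dg")
  tp <- thermo_parameters(dG = dG %||% if (is.null(dH)) CLI_DEFAULTS$dg,
                          T = T, dH = dH, dS = dS)
  Pb <- prob_from_energy(tp$dG, T)
  out <- list(dG = tp$dG, T_K = T, Pb = Pb,
              kappa = kappa_from_energy(tp$dG, T, U), U = U)
  if (!is.null(dH) && !is.null(dS)) {
    cls <- classify_regime(dH, dS)
    out$regime <- cls$regime
    out$Tc_K <- cls$Tc_K
    out$Tc_C <- if (is.na(cls$Tc_K)) NA_real_
                else kelvin_to_celsius(cls$Tc_K)
  }
  out
}

cmd_dynamics <- function(p, config) {
  U <- as_num(p$u %||% "1", "u")
  rates <- resolve_rates(p, U)
  p0 <- as_num(p$p0 %||% "0", "p0")
  sol <- closed_form_solution(p0, rates, U)
  t_end <- as_num(p[["t-end"]] %||%
                  as.character(20 / max(sol$rate_scale,
                                        rates$kplus * U)), "t-end")
  n <- as.integer(as_num(p[["n-points"]] %||% "200", "n-points"))
  times <- c(0, exp(seq(log(t_end) - log(1e6), log(t_end),
                        length.out = n - 1L)))
  pt <- p_closed_form(times, p0, rates, U)
  df <- data.frame(t = format(times, digits = 17),
                   p = format(pt, digits = 17),
                   Xn = format(1 / (1 - pt), digits = 17))
  csv <- file.path(config$out_dir, "dynamics.csv")
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  list(kplus = rates$kplus, kminus = rates$kminus, U = U, p0 = p0,
       t_end = t_end, Pb = sol$Pb, kappa_bar = sol$kbar,
       Delta = sol$Delta, branch = sol$branch,
       rate_scale = sol$rate_scale, csv = csv)
}

cmd_simulate <- function(p, config) {
  U <- as_num(p$u %||% "1", "u")
  rates <- resolve_rates(p, U)
  d <- as.integer(as_num(p$d %||% "100", "d"))
  init <- p$init %||% "monomers"
  x0 <- if (init == "monomers") {
    monomer_start(U, d)
  } else if (startsWith(init, "flory:")) {
    flory_schulz_start(as_num(substring(init, 7L), "init"), U, d)
  } else stop_usage("`--init` must be `monomers` or `flory:<p>`")
  sys <- truncated_system(d, rates, x0)
  rc <- reduced_constants(rates, U)
  t_end <- as_num(p[["t-end"]] %||%
                  as.character(100 / max(rc$Delta, 1e-3) /
                               (rates$kplus * U)), "t-end")
  traj <- integrate_system(sys, t_end,
                           rtol = as_num(p$rtol %||% "1e-8", "rtol"),
                           atol = as_num(p$atol %||%
                                         as.character(1e-12 * U), "atol"))
  csv <- file.path(config$out_dir, p$out %||% "trajectory.csv")
  write_trajectory_csv(traj, csv)
  final <- traj$states[nrow(traj$states), ]
  list(d = d, kplus = rates$kplus, kminus = rates$kminus, U = U,
       t_end = t_end, init = init,
       final_p = bonding_probability_of_state(final, U),
       residual = sqrt(sum(polymerization_rhs(pmax(final, 0),
                                              rates)^2)),
       mass_drift = traj$mass_drift, csv = csv)
}

cmd_bound <- function(p, config) {
  prob <- if (!is.null(p$p)) {
    as_num(p$p, "p")
  } else {
    prob_from_energy(as_num(p$dg %||% as.character(CLI_DEFAULTS$dg),
                            "dg"), resolve_temp(p))
  }
  if (!is.null(p[["target-e"]])) {
    target <- as_num(p[["target-e"]], "target-e")
    lax <- min_d_lax(prob, target)
    list(p = prob, target_E = target, min_d_full = min_d_full(prob, target),
         min_d_lax = lax$d, min_d_lax_real = lax$d_real)
  } else if (!is.null(p$d)) {
    rep_ <- truncation_error_report(prob, as_num(p$u %||% "1", "u"),
                                    as.integer(as_num(p$d, "d")))
    unclass(rep_)
  } else stop_usage("`bound` needs `--d` (report) or `--target-e` (invert)")
}

cmd_analyze <- function(p, config) {
  if (is.null(p$spectrum)) stop_usage("`analyze` needs `--spectrum <csv>`")
  T1 <- resolve_temp(p)
  spec <- read_spectrum_csv(p$spectrum, T = T1)
  fit <- fit_p_from_spectrum(spec, method = p$method %||% "argmax")
  interp <- interpret_probability(fit$p, T1)
  out <- list(p = fit$p, method = fit$method, kstar = interp$kstar,
              dG = interp$dG, eta = interp$eta, Xn = interp$Xn, T_K = T1)
  if (!is.null(p[["dg-ref"]])) {
    T2 <- celsius_to_kelvin(as_num(p[["temp-ref-c"]] %||% "25",
                                   "temp-ref-c"))
    tta <- two_temperature_analysis(fit$p, T1,
                                    as_num(p[["dg-ref"]], "dg-ref"), T2)
    out <- c(out, tta[c("dH", "dS", "Tc_K", "Tc_C", "regime")])
  }
  out
}

cmd_fixtures <- function(p, config) {
  prob <- as_num(p$p %||% "0.7", "p")
  spec <- generate_spectrum(prob, m0 = as_num(p$m0 %||% "324.2", "m0"),
                            kmax = as.integer(as_num(p$kmax %||% "50",
                                                     "kmax")),
                            noise_cv = as_num(p[["noise-cv"]] %||% "0.05",
                                              "noise-cv"),
                            seed = config$seed)
  csv <- file.path(config$out_dir, p$out %||% "spectrum.csv")
  write_spectrum_csv(spec, csv)
  list(p = prob, kmax = length(spec$lengths), csv = csv)
}

#' CLI entry point
#'
#' Parses, runs, and maps failures to exit codes: 0 success, 2 usage
#' error, 3 domain error, 4 numerical error.
#'
#' @param args Command-line arguments (defaults to the process's).
#' @return Integer exit status (invisibly); the `exec/polyadd` script
#'   passes it to `quit()`.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    run_command(parse_config(args))
    0L
  },
  polyadd_usage_error = function(e) { message("usage error: ",
                                              conditionMessage(e)); 2L },
  polyadd_domain_error = function(e) { message("domain error: ",
                                               conditionMessage(e)); 3L },
  polyadd_numerical_error = function(e) { message("numerical error: ",
                                                  conditionMessage(e)); 4L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
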