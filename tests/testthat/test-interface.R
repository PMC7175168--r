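test_that("parse_config applies defaults, precedence, and conflicts", {
  cfg <- parse_config(c("steady-state"))
  expect_identical(cfg$command, "steady-state")
  expect_identical(cfg$seed, 1L)
  expect_error(parse_config(character(0)), class = "polyadd_usage_error")
  expect_error(parse_config("transmute"), class = "polyadd_usage_error")
  expect_error(parse_config(c("steady-state", "--kplus", "1e-4",
                              "--dg", "-1.5")),
               class = "polyadd_usage_error")
  expect_error(parse_config(c("thermo", "--temp-c", "85",
                              "--temp-k", "358.15")),
               class = "polyadd_usage_error")
  expect_error(parse_config(c("bound", "--p")),
               class = "polyadd_usage_error")
  skip_if_not_installed("yaml")
  # config file supplies values; CLI flags win
  conf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("kminus: 2e-6", "u: 3"), conf)
  cfg2 <- parse_config(c("steady-state", "--config", conf, "--u", "4"))
  expect_identical(cfg2$params$kminus, "2e-6")
  expect_identical(cfg2$params$u, "4")
})

test_that("steady-state subcommand reports the reference equilibrium", {
  out_dir <- withr::local_tempdir()
  rep_ <- run_command(parse_config(c("steady-state", "--kplus", "7.4e-5",
                                     "--out-dir", out_dir)))
  expect_equal(round(rep_$Pb, 2), 0.89)
  expect_equal(rep_$Cc, 1e-6 / 7.4e-5)
  disk <- jsonlite::read_json(file.path(out_dir, "steady_state.json"))
  expect_equal(disk$Pb, rep_$Pb, tolerance = 1e-12)
  expect_equal(disk$seed, 1L)
  # default thermodynamic parameterization (dG = -1.5 at 85 C) is close
  rep_dg <- run_command(parse_config(c("steady-state",
                                       "--out-dir", out_dir)))
  expect_equal(round(rep_dg$Pb, 2), 0.89)
})

test_that("dynamics subcommand writes t,p,Xn consistent with closed form", {
  out_dir <- withr::local_tempdir()
  rep_ <- run_command(parse_config(c("dynamics", "--kplus", "7.4e-5",
                                     "--kminus", "1e-6", "--u", "1",
                                     "--p0", "0", "--t-end", "1e7",
                                     "--n-points", "40",
                                     "--out-dir", out_dir)))
  expect_identical(rep_$branch, "coth")
  df <- read.csv(file.path(out_dir, "dynamics.csv"))
  expect_named(df, c("t", "p", "Xn"))
  r <- table2_rates()
  expect_equal(df$p, p_closed_form(df$t, 0, r, 1), tolerance = 1e-12)
  expect_equal(df$Xn, 1 / (1 - df$p), tolerance = 1e-12)
})

test_that("simulate then bound: measured error dominates reported bound", {
  out_dir <- withr::local_tempdir()
  sim <- run_command(parse_config(c("simulate", "--d", "10",
                                    "--kplus", "7.4e-5",
                                    "--t-end", "5e7",
                                    "--out-dir", out_dir)))
  expect_lt(sim$mass_drift, 1e-6)
  bnd <- run_command(parse_config(c("bound", "--p",
                                    as.character(sim$final_p),
                                    "--d", "10", "--out-dir", out_dir)))
  df <- read.csv(file.path(out_dir, "trajectory.csv"))
  final <- df$concentration[df$t == max(df$t)]
  actual <- rel_l2_error(final, sim$final_p, 1)
  expect_gte(actual, bnd$E)
})

test_that("bound inversion mirrors the worked free-energy example", {
  out_dir <- withr::local_tempdir()
  rep_ <- run_command(parse_config(c("bound", "--dg", "-3.5",
                                     "--temp-c", "85",
                                     "--target-e", "0.01",
                                     "--out-dir", out_dir)))
  expect_identical(rep_$min_d_full, 700L)
  expect_identical(rep_$min_d_lax, 632L)
})

test_that("fixtures then analyze recovers the planted spectrum truth", {
  out_dir <- withr::local_tempdir()
  fix <- run_command(parse_config(c("fixtures", "--p",
                                    as.character(exp(-1 / 2)),
                                    "--noise-cv", "0",
                                    "--out-dir", out_dir)))
  rep_ <- run_command(parse_config(c("analyze", "--spectrum", fix$csv,
                                     "--temp-c", "-18",
                                     "--method", "argmax",
                                     "--dg-ref", "3.3",
                                     "--temp-ref-c", "25",
                                     "--out-dir", out_dir)))
  expect_equal(rep_$kstar, 2)
  expect_equal(rep_$p, exp(-1 / 2), tolerance = 1e-12)
  expect_equal(round(rep_$dG, 1), -0.2)
  expect_equal(round(rep_$Tc_C), -15)
})

test_that("reruns with the same seed produce byte-identical artifacts", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (dd in c(d1, d2)) {
    run_command(parse_config(c("fixtures", "--p", "0.7", "--seed", "9",
                               "--noise-cv", "0.05", "--out-dir", dd)))
  }
  expect_identical(readLines(file.path(d1, "spectrum.csv")),
                   readLines(file.path(d2, "spectrum.csv")))
})

test_that("cli_main maps condition classes to exit codes", {
  out_dir <- withr::local_tempdir()
  expect_identical(suppressMessages(cli_main(c("steady-state",
                                               "--out-dir", out_dir))), 0L)
  expect_identical(suppressMessages(cli_main("no-such-command")), 2L)
  expect_identical(suppressMessages(
    cli_main(c("bound", "--p", "1.5", "--d", "10",
               "--out-dir", out_dir))), 3L)
})
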