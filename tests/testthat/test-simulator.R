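test_that("with reactions off, uniform input chemistry passes through unchanged", {
  net <- tracer_net()
  f <- constant_forcing(800, precip = 4, temp = 10, pet = 0,
                        chem = c(Tr = 5e-5))
  cfg <- sim_config(net, forcing = f, hbv = hbv_params(),
                    initial = list(SF = c(Tr = 5e-5), SZ = c(Tr = 5e-5),
                                   DZ = c(Tr = 5e-5)),
                    spinup_days = 365)
  out <- run_simulation(cfg)
  expect_true(all(abs(out$stream$Tr - 5e-5) / 5e-5 < 1e-6))
})

test_that("identical configuration and seed replay identically", {
  net <- tracer_net()
  mk <- function() sim_config(net,
    forcing = list(source = "synthetic", years = 1),
    hbv = hbv_params(), initial = list(SF = c(Tr = 1e-4), SZ = c(Tr = 1e-4),
                                       DZ = c(Tr = 1e-4)),
    precip_chem = c(Tr = 1e-4), spinup_days = 0, seed = 77)
  o1 <- run_simulation(mk())
  o2 <- run_simulation(mk())
  expect_identical(o1$stream, o2$stream)
  expect_identical(o1$zones, o2$zones)
})

test_that("conservative stream response is linear in input chemistry", {
  net <- tracer_net()
  run_scaled <- function(s) {
    cfg <- sim_config(net, forcing = list(source = "synthetic", years = 1),
                      hbv = hbv_params(),
                      initial = list(SF = c(Tr = s * 1e-4),
                                     SZ = c(Tr = s * 1e-4),
                                     DZ = c(Tr = s * 1e-4)),
                      precip_chem = c(Tr = s * 1e-4), spinup_days = 0,
                      seed = 31)
    run_simulation(cfg)$stream$Tr
  }
  base <- run_scaled(1)
  tripled <- run_scaled(3)
  ok <- is.finite(base)
  expect_equal(tripled[ok], 3 * base[ok], tolerance = 1e-10)
})

test_that("output tables round-trip and their derived columns recompute", {
  out <- carbon_run()
  dir <- withr::local_tempdir()
  export_tables(out, dir)
  got <- read_sim_tables(dir)
  expect_equal(as.data.frame(got$stream), as.data.frame(out$stream),
               tolerance = 1e-12)
  expect_equal(as.data.frame(got$rates), as.data.frame(out$rates),
               tolerance = 1e-12)
  expect_equal(as.data.frame(got$exports), as.data.frame(out$exports),
               tolerance = 1e-12)
})

test_that("DIC aggregate equals the sum of its member species everywhere", {
  out <- carbon_run()
  z <- tidyr::pivot_wider(out$zones, names_from = "species",
                          values_from = "conc")
  # free bicarbonate = total component minus the secondaries it carries
  free_hco3 <- z$`HCO3-` - z$`CO2(aq)` - z$`CO3--`
  expect_equal(z$DIC, z$`CO2(aq)` + free_hco3 + z$`CO3--`, tolerance = 1e-12)
  # and, because sorbed DOC carries no inorganic carbon, DIC equals the
  # bicarbonate component total
  expect_equal(z$DIC, z$`HCO3-`, tolerance = 1e-12)
})

test_that("C-Q summaries recover constructed power laws and flag constants", {
  d <- tibble::tibble(date = 1:200, q = exp(seq(log(0.1), log(20),
                                                length.out = 200)))
  d$c1 <- 3 * d$q^0.5
  d$c2 <- 2
  expect_equal(cq_summary(d, "c1")$slope, 0.5, tolerance = 1e-10)
  expect_equal(cq_summary(d, "c1")$rho, 1)
  s2 <- cq_summary(d, "c2")
  expect_equal(s2$slope, 0)
  expect_equal(s2$rho, 0)
  expect_equal(s2$flag, "constant")
  expect_error(cq_summary(d[1:10, ], "c1"), ">= 30")
})

test_that("export flux columns are Q x C x 1000", {
  out <- carbon_run()
  sz <- out$exports[out$exports$zone == "SZ" &
                      out$exports$species == "Ca++", ]
  # reconstruct from the recorded end-of-step concentrations via the stream
  # mix on a day dominated by a single pathway is involved; instead check
  # dimensional consistency against the budget: total export equals the
  # flux-integrated concentration
  b <- out$budget
  tot_exp <- sum(out$exports$flux_mmol_m2_day[out$exports$species == "Ca++"]) / 1000
  expect_equal(tot_exp, unname(b$export[b$species == "Ca++"]),
               tolerance = 1e-6)
})

test_that("simulation rejects inconsistent series lengths", {
  net <- tracer_net()
  f <- constant_forcing(100, chem = c(Tr = 1e-4))
  cfg <- sim_config(net, forcing = f, hbv = hbv_params(),
                    initial = list(SF = c(Tr = 0), SZ = c(Tr = 0),
                                   DZ = c(Tr = 0)), spinup_days = 0)
  # corrupt: hydrology read from a shorter series
  h <- run_hbv(f[1:50, ], hbv_params())
  rf <- withr::local_tempfile(); pf <- withr::local_tempfile()
  write_hbv_light(h, hbv_params(), rf, pf)
  cfg$hbv <- list(results = rf, params = pf)
  expect_error(run_simulation(cfg), "lengths differ")
})

test_that("the command line interface runs, errors and replays deterministically", {
  dir <- withr::local_tempdir()
  cfgf <- file.path(dir, "cfg.yml")
  netf <- file.path(dir, "net.yml")
  writeLines(c("species:", "  primary: [Tr]"), netf)
  writeLines(c("dt: 1", "spinup_days: 0", "seed: 5",
               "forcing: {years: 1, spec: {}}",
               "network: net.yml",
               "precip_chem: {Tr: 1.0e-4}",
               "initial:",
               "  SF: {Tr: 1.0e-4}", "  SZ: {Tr: 1.0e-4}",
               "  DZ: {Tr: 1.0e-4}"), cfgf)
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  expect_equal(cli_main(c("run", "--config", cfgf, "--out", out1)), 0L)
  expect_true(file.exists(file.path(out1, "stream.tsv")))
  expect_true(file.exists(file.path(out1, "rates.tsv")))
  expect_true(file.exists(file.path(out1, "exports.tsv")))
  expect_equal(cli_main(c("run", "--config", cfgf, "--out", out2)), 0L)
  expect_identical(readLines(file.path(out1, "stream.tsv")),
                   readLines(file.path(out2, "stream.tsv")))
  # missing config and bad flags exit 2 / nonzero
  expect_equal(cli_main(c("run", "--out", out1)), 2L)
  expect_equal(cli_main(c("frobnicate")), 2L)
  expect_equal(cli_main(c("run", "--bogus", "x")), 2L)
  expect_equal(cli_main(c("run", "--config", file.path(dir, "nope.yml"),
                          "--out", out1)), 1L)
  # synth writes a forcing file
  expect_equal(cli_main(c("synth", "--out", dir, "--years", "1",
                          "--seed", "3")), 0L)
  expect_true(file.exists(file.path(dir, "forcing.tsv")))
})
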