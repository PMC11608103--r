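test_that("infiltration concentration is the flux-weighted rain/melt mix", {
  expect_equal(infiltration_concentration(2, 3e-4, 0, 9e-9), 3e-4)
  expect_equal(infiltration_concentration(1.5, 2e-4, 1.5, 0), 1e-4)
  expect_equal(infiltration_concentration(3, 1, 1, 5), 2)
  expect_equal(infiltration_concentration(0, 1, 0, 5), 0)
  expect_error(infiltration_concentration(-1, 1, 1, 1), "negative")
})

test_that("snowpack chemistry conserves mass through accumulation and melt", {
  s <- snow_chem_state(10, c(Tr = 2e-4))
  # no melt: pack is the mass-weighted mix of old pack and snowfall
  r <- step_snow_chemistry(s, p_snow = 5, c_ppt = c(Tr = 8e-4), q_melt = 0)
  expect_equal(r$state$swe, 15)
  expect_equal(r$state$conc[["Tr"]], (10 * 2e-4 + 5 * 8e-4) / 15)  # = 4e-4
  expect_equal(r$state$conc[["Tr"]], 4e-4)
  # pure partial melt: concentration unchanged, swe reduced
  r2 <- step_snow_chemistry(s, 0, c(Tr = 0), q_melt = 4)
  expect_equal(r2$state$swe, 6)
  expect_equal(r2$state$conc[["Tr"]], 2e-4)
  expect_equal(r2$c_melt[["Tr"]], 2e-4)
  # complete melt exports the whole pack plus the day's snowfall
  r3 <- step_snow_chemistry(s, 5, c(Tr = 8e-4), q_melt = 15)
  expect_equal(r3$state$swe, 0)
  exported <- r3$c_melt[["Tr"]] * 15
  expect_equal(exported, 10 * 2e-4 + 5 * 8e-4)
  # melt beyond the pack is an error
  expect_error(step_snow_chemistry(s, 0, c(Tr = 0), q_melt = 11), "exceeds")
})

test_that("snow mass bookkeeping is exact over random sequences", {
  set.seed(42)
  s <- snow_chem_state(0, c(Tr = 0))
  in_mass <- 0; out_mass <- 0
  for (i in 1:200) {
    p <- stats::rexp(1, 1 / 3)
    cp <- stats::runif(1, 1e-5, 1e-3)
    melt <- stats::runif(1) * (s$swe + p)
    r <- step_snow_chemistry(s, p, c(Tr = cp), melt)
    in_mass <- in_mass + p * cp
    out_mass <- out_mass + melt * r$c_melt[["Tr"]]
    s <- r$state
  }
  expect_equal(in_mass - out_mass, s$swe * s$conc[["Tr"]], tolerance = 1e-12)
})

test_that("a single advection step equals the closed-form backward-Euler update", {
  net <- tracer_net()
  states <- list(snow = snow_chem_state(0, c(Tr = 0)),
                 SF = zone_chem_state("SF", 5, c(Tr = 1e-4), net$eqsys),
                 SZ = zone_chem_state("SZ", 300, c(Tr = 2e-4), net$eqsys),
                 DZ = zone_chem_state("DZ", 600, c(Tr = 5e-5), net$eqsys))
  hy <- list(p_snow = 0, rain = 6, snowmelt = 0, q_sf = 1, q_infil = 5,
             q_sz = 2, q_perc = 2, q_dz = 3, v_sf = 5, v_sz = 305, v_dz = 599)
  c_rain <- c(Tr = 1e-3)
  out <- step_zone_advection(states, hy, c_rain, dt = 1)
  # SF: infiltration passes through at the rain concentration
  c_sf <- (5 * 1e-4 + (6 * 1e-3 - 5 * 1e-3)) / (5 + 1)
  expect_equal(out$exports$SF[["Tr"]], c_sf)
  c_sz <- (300 * 2e-4 + 5 * 1e-3) / (305 + 4)
  expect_equal(out$exports$SZ[["Tr"]], c_sz)
  c_dz <- (600 * 5e-5 + 2 * c_sz) / (599 + 3)
  expect_equal(out$exports$DZ[["Tr"]], c_dz)
})

test_that("stream mixing is flux-weighted and degenerates correctly", {
  expect_equal(stream_concentration(1, 2, 3, 5, 5, 5), 5)
  expect_equal(stream_concentration(0, 0, 2, 9, 9, 4), 4)
  expect_equal(stream_concentration(0.01, 0.35, 0.64, 1, 4, 2), 2.69)
  expect_true(is.na(stream_concentration(0, 0, 0, 1, 1, 1)))
  expect_error(stream_concentration(-1, 0, 1, 1, 1, 1), "negative")
})

test_that("conservative tracer matches an independent explicit mixing-cell oracle", {
  # 2 years of stochastic forcing, constant input chemistry, reactions off
  net <- tracer_net()
  c0 <- 1e-4
  cfg <- sim_config(net, forcing = list(source = "synthetic", years = 2),
                    hbv = hbv_params(),
                    initial = list(SF = c(Tr = c0), SZ = c(Tr = 3e-4),
                                   DZ = c(Tr = 2e-5)),
                    precip_chem = c(Tr = c0), spinup_days = 0, seed = 19)
  out <- run_simulation(cfg)
  h <- out$hydro
  zc <- cfg$zones
  # oracle: continuous mixing cells integrated by explicit Euler with 100
  # substeps per day, written directly from the mass-balance ODEs
  nsub <- 100; hh <- 1 / nsub
  v_sz_series <- h$uz + h$sm + zc$sz_passive
  v_dz_series <- h$lz + zc$dz_passive
  # pre-simulation storages from the day-1 balances (model convention)
  v0_sz <- v_sz_series[1] - (h$q_infil[1] - h$aet[1] - h$q_sz[1] - h$q_perc[1])
  v0_dz <- v_dz_series[1] - (h$q_perc[1] - h$q_dz[1])
  m_sf <- c0 * zc$sf_storage
  m_sz <- 3e-4 * v0_sz
  m_dz <- 2e-5 * v0_dz
  swe <- 0; m_snow <- 0
  v_sz_prev <- v0_sz; v_dz_prev <- v0_dz
  ora <- matrix(NA_real_, nrow(h), 3)
  for (t in seq_len(nrow(h))) {
    # snow: exact discrete bookkeeping (same contract as the model)
    swe_in <- swe + h$p_snow[t]
    m_in <- m_snow + h$p_snow[t] * c0
    c_pack <- if (swe_in > 0) m_in / swe_in else 0
    swe <- swe_in - h$snowmelt[t]
    m_snow <- m_in - h$snowmelt[t] * c_pack
    c_infil <- if (h$rain[t] + h$snowmelt[t] > 0)
      (h$rain[t] * c0 + h$snowmelt[t] * c_pack) / (h$rain[t] + h$snowmelt[t])
    else 0
    for (k in seq_len(nsub)) {
      fr0 <- (k - 1) / nsub; fr1 <- k / nsub
      v_sz0 <- v_sz_prev + fr0 * (v_sz_series[t] - v_sz_prev)
      v_dz0 <- v_dz_prev + fr0 * (v_dz_series[t] - v_dz_prev)
      c_sf <- m_sf / zc$sf_storage
      c_sz <- m_sz / v_sz0
      c_dz <- m_dz / v_dz0
      m_sf <- m_sf + hh * (h$rain[t] * c0 + h$snowmelt[t] * c_pack -
                             h$q_infil[t] * c_infil - h$q_sf[t] * c_sf)
      m_sz <- m_sz + hh * (h$q_infil[t] * c_infil -
                             (h$q_sz[t] + h$q_perc[t]) * c_sz)
      m_dz <- m_dz + hh * (h$q_perc[t] * c_sz - h$q_dz[t] * c_dz)
    }
    v_sz_prev <- v_sz_series[t]; v_dz_prev <- v_dz_series[t]
    qt <- h$q[t]
    ora[t, ] <- c(m_sf / zc$sf_storage, m_sz / v_sz_series[t],
                  m_dz / v_dz_series[t])
    ora[t, 1] <- if (qt > 0)
      (h$q_sf[t] * ora[t, 1] + h$q_sz[t] * ora[t, 2] + h$q_dz[t] * ora[t, 3]) / qt
    else NA
  }
  ok <- is.finite(out$stream$Tr) & is.finite(ora[, 1])
  rel <- abs(out$stream$Tr[ok] - ora[ok, 1]) / ora[ok, 1]
  expect_lt(max(rel), 0.005)
})

test_that("global conservative budget closes within 0.1%", {
  net <- tracer_net()
  cfg <- sim_config(net, forcing = list(source = "synthetic", years = 2),
                    hbv = hbv_params(),
                    initial = list(SF = c(Tr = 1e-4), SZ = c(Tr = 1e-4),
                                   DZ = c(Tr = 1e-4)),
                    precip_chem = c(Tr = 1e-4), spinup_days = 0, seed = 23)
  out <- run_simulation(cfg)
  b <- budget_closure(out)
  expect_lt(abs(b$rel_residual[b$species == "Tr"]), 1e-3)
})

test_that("steady uniform input converges to the input concentration", {
  # constant rain, no ET (ET removes water only, so any ET would
  # evapo-concentrate above the input concentration)
  net <- tracer_net()
  f <- constant_forcing(2500, precip = 4, temp = 10, pet = 0,
                        chem = c(Tr = 1e-4))
  cfg <- sim_config(net, forcing = f, hbv = hbv_params(),
                    initial = list(SF = c(Tr = 1e-4), SZ = c(Tr = 0),
                                   DZ = c(Tr = 0)),
                    spinup_days = 0)
  out <- run_simulation(cfg)
  tail_c <- out$stream$Tr[2450:2500]
  expect_true(all(abs(tail_c - 1e-4) / 1e-4 < 0.01))
  z <- out$zones[out$zones$species == "Tr" & out$zones$date == 2500, ]
  expect_true(all(abs(z$conc - 1e-4) / 1e-4 < 0.01))
})
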