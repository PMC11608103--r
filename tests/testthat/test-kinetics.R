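test_that("temperature factor obeys its analytic identities", {
  expect_equal(env_factor_T(c(5, 15, 25), q10 = 1), c(1, 1, 1))
  expect_equal(env_factor_T(20, q10 = 3.7), 1)
  expect_equal(env_factor_T(30, q10 = 2.3), 2.3)
  # printed absolute-value form rises on both sides of 20 degC
  expect_equal(env_factor_T(10, 2), env_factor_T(30, 2))
  # signed variant falls below 20 degC
  expect_equal(env_factor_T(10, 2, signed = TRUE), 0.5)
  expect_error(env_factor_T(10, q10 = 0), "q10")
})

test_that("soil moisture factor peaks at the critical saturation", {
  expect_equal(env_factor_Sw(0.7, 0.7, 0.8), 1)
  expect_equal(env_factor_Sw(c(0, 0.3, 0.9, 1), 0.6, 0), rep(1, 4))
  expect_equal(env_factor_Sw(0.35, 0.7, 0.8), 0.5^0.8)
  # swc above 1 stays on the rising branch over the whole range
  sw <- seq(0, 1, 0.1)
  expect_equal(env_factor_Sw(sw, 1.7, 1), sw / 1.7)
  # swc = 0 stays on the falling branch
  expect_equal(env_factor_Sw(sw[-1], 0, 1), 1 - sw[-1])
  f <- env_factor_Sw(sw, 0.6, 1.2)
  expect_equal(which.max(f), which.min(abs(sw - 0.6)))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("water-table factor is exponential in depth", {
  expect_equal(env_factor_Zw(c(0, 1, 5), 0), c(1, 1, 1))
  expect_equal(env_factor_Zw(0, 3.2), 1)
  zw <- seq(0, 5, 0.5)
  f <- env_factor_Zw(zw, 0.8)
  expect_true(all(diff(f) < 0))
  expect_equal(f, exp(-0.8 * zw))
  # negative product reverses the direction
  expect_true(all(diff(env_factor_Zw(zw, -0.8)) > 0))
})

test_that("TST rates vanish at equilibrium and reverse beyond it", {
  rxn <- rt_reaction("diss", "kinetic-tst", "M(s) -> S",
                     log10_keq = -3.2, log10_k = -13.1, ssa = 0.01,
                     substrate_mass = 1e5)
  ctx <- rate_context(temp = 20, sw = 1, zw = 0, water_volume = 100)
  r_eq <- kinetic_rate(rxn, tst_state_at(-3.2), ctx)
  expect_equal(r_eq, 0)
  expect_lt(kinetic_rate(rxn, tst_state_at(-2.5), ctx), 0)  # supersaturated
  expect_gt(kinetic_rate(rxn, tst_state_at(-4.0), ctx), 0)  # undersaturated
  # a TST reaction cannot be declared without its equilibrium constant
  expect_error(rt_reaction("x", "kinetic-tst", "M(s) -> S", log10_k = -10),
               "log10_keq")
})

test_that("Monod rate halves at the half-saturation constant", {
  net <- build_network(list(species = list(primary = list("S"),
                                           solid = list("M(s)"))),
                       default_database())
  rxn <- rt_reaction("up", "kinetic-monod", "S -> M(s)", log10_k = -10,
                     ssa = 1, substrate_mass = 1000, monod = c(S = 1e-4))
  ctx <- rate_context(temp = 20, sw = 1, zw = 0, water_volume = 100)
  st <- speciate(c(S = 1e-4), net$eqsys)
  kA <- 10^-10 * 86400 * 1000
  expect_equal(kinetic_rate(rxn, st, ctx), kA / 2)
  # inhibition halves again at C = KI
  rxn2 <- rt_reaction("up2", "kinetic-monod", "S -> M(s)", log10_k = -10,
                      ssa = 1, substrate_mass = 1000, monod = c(S = 1e-4),
                      inhibition = c(S = 1e-4))
  expect_equal(kinetic_rate(rxn2, st, ctx), kA / 4)
})

test_that("rates scale linearly in surface area and rate constant", {
  ctx <- rate_context(temp = 14, sw = 0.6, zw = 0.5, water_volume = 100)
  st <- tst_state_at(-4)
  mk <- function(k, mass) rt_reaction("d", "kinetic-tst", "M(s) -> S",
                                      log10_keq = -3.2, log10_k = k, ssa = 1,
                                      substrate_mass = mass, q10 = 2, n = 1,
                                      swc = 0.8, alpha_beta = 0.4)
  r1 <- kinetic_rate(mk(-13, 10), st, ctx)
  expect_equal(kinetic_rate(mk(-13, 30), st, ctx), 3 * r1)
  expect_equal(kinetic_rate(mk(-12, 10), st, ctx), 10 * r1)
})

test_that("factor breakdown multiplies to the rate", {
  rxn <- rt_reaction("d", "kinetic-tst", "M(s) -> S", log10_keq = -3.2,
                     log10_k = -13, ssa = 0.5, substrate_mass = 100,
                     q10 = 2.3, n = 0.8, swc = 0.7, alpha_beta = 0.2)
  ctx <- rate_context(temp = 8, sw = 0.4, zw = 1.2, water_volume = 50)
  b <- rate_breakdown(rxn, tst_state_at(-4), ctx)
  expect_equal(b$rate,
               10^-13 * 86400 * 50 * b$f_t * b$f_sw * b$f_zw * b$saturation)
  expect_equal(b$f_t, 2.3^(abs(8 - 20) / 10))
  expect_equal(b$f_sw, (0.4 / 0.7)^0.8)
  expect_equal(b$f_zw, exp(-0.2 * 1.2))
})

test_that("irreversible decomposition conserves the printed stoichiometric ratio", {
  # DOC consumed, 0.7 DIC produced: delta(DIC) = -0.7 * delta(DOC) exactly
  net <- build_network(list(species = list(
    primary = list("DOC", "HCO3-"), solid = list("OC_DZ(s)"))),
    default_database())
  rxn <- rt_reaction("resp", "kinetic-monod", "OC_DZ(s) + DOC -> 0.7 HCO3-",
                     log10_k = -9.2, ssa = 0.07, substrate_mass = 3.5e4,
                     monod = c(DOC = 5e-3))
  st0 <- zone_chem_state("DZ", 500, c(DOC = 2e-4, "HCO3-" = 1e-4), net$eqsys)
  ctx <- rate_context(temp = 10, sw = 0.8, zw = 0, dt = 1, water_volume = 500)
  res <- integrate_zone_reactions(st0, list(rxn), ctx)
  d_doc <- res$state$totals[["DOC"]] - 2e-4
  d_dic <- res$state$totals[["HCO3-"]] - 1e-4
  expect_lt(d_doc, 0)
  expect_equal(d_dic, -0.7 * d_doc, tolerance = 1e-12)
  # bookkeeping: delta totals = stoich x mean rate x dt / V
  expect_equal(d_doc, -res$rates[["resp"]] * 1 / 500, tolerance = 1e-12)
})

test_that("no reactions leave the state untouched with zero rates", {
  net <- tracer_net()
  st <- zone_chem_state("SZ", 300, c(Tr = 1e-4), net$eqsys)
  ctx <- rate_context(temp = 10, sw = 0.5, water_volume = 300)
  res <- integrate_zone_reactions(st, list(), ctx)
  expect_identical(res$state$totals, st$totals)
  expect_length(res$rates, 0)
})

test_that("stiff Monod consumption matches a fine-step explicit reference", {
  net <- build_network(list(species = list(primary = list("S"),
                                           solid = list("M(s)"))),
                       default_database())
  # fast: consumes most of the pool within the day
  rxn <- rt_reaction("fast", "kinetic-monod", "S -> M(s)", log10_k = -8.5,
                     ssa = 1, substrate_mass = 1e4, monod = c(S = 5e-5))
  V <- 200; C0 <- 3e-4
  ctx <- rate_context(temp = 20, sw = 1, zw = 0, dt = 1, water_volume = V)
  res <- integrate_zone_reactions(
    zone_chem_state("SZ", V, c(S = C0), net$eqsys), list(rxn), ctx)
  # independent reference: explicit Euler with 10,000 substeps
  kA <- 10^-8.5 * 86400 * 1e4
  cc <- C0
  h <- 1 / 10000
  for (i in 1:10000) cc <- cc - h * kA * cc / (cc + 5e-5) / V
  expect_equal(res$state$totals[["S"]], cc, tolerance = 1e-3)
})

test_that("the trapezoidal reaction step converges at second order", {
  net <- build_network(list(species = list(primary = list("S"),
                                           solid = list("M(s)"))),
                       default_database())
  rxn <- rt_reaction("m", "kinetic-monod", "S -> M(s)", log10_k = -10.3,
                     ssa = 1, substrate_mass = 1e4, monod = c(S = 2e-4))
  V <- 200; C0 <- 3e-4
  run_with <- function(dt, n) {
    st <- zone_chem_state("SZ", V, c(S = C0), net$eqsys)
    ctx <- rate_context(temp = 20, sw = 1, zw = 0, dt = dt, water_volume = V)
    for (i in seq_len(n)) st <- integrate_zone_reactions(st, list(rxn), ctx)$state
    st$totals[["S"]]
  }
  ref <- run_with(1 / 64, 64)
  e1 <- abs(run_with(1, 1) - ref)
  e2 <- abs(run_with(1 / 2, 2) - ref)
  e4 <- abs(run_with(1 / 4, 4) - ref)
  expect_gt(e1 / e2, 3); expect_lt(e1 / e2, 5.5)
  expect_gt(e2 / e4, 3); expect_lt(e2 / e4, 5.5)
})
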