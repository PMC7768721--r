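test_that("standard Gibbs energy at 25 C equals the summation oracle", {
  th <- thermo_state(temperature_C = 25, pressure_bar = 1)
  tab <- thermo_constants()
  g_of <- function(sp) tab$dG0f_kJ_mol[tab$species == sp]

  # empty reaction
  expect_equal(standard_gibbs(c(NH4 = 0, NO2 = 0), th), 0)

  # reference-state identity: independent hand summation over the table
  rx <- anammox_stoichiometry("nitrite_canonical")
  oracle <- g_of("N2") + 2 * g_of("H2O") - g_of("NH4") - g_of("NO2")
  expect_equal(standard_gibbs(rx, th), oracle)
  # frozen value of the oracle itself
  expect_equal(oracle, -344.51)

  expect_error(standard_gibbs(c(XX = 1), th), "XX")
})

test_that("temperature and pressure corrections behave as stated", {
  rx <- anammox_stoichiometry("nitrite_canonical")
  th25 <- thermo_state(25, 1)
  th2 <- thermo_state(2, 1)
  tab <- thermo_constants()
  pick <- function(col, sp) tab[[col]][tab$species == sp]
  dH <- pick("dH0f_kJ_mol", "N2") + 2 * pick("dH0f_kJ_mol", "H2O") -
    pick("dH0f_kJ_mol", "NH4") - pick("dH0f_kJ_mol", "NO2")
  dG25 <- standard_gibbs(rx, th25)
  # integrated van 't Hoff, computed independently
  T0 <- 298.15; T1 <- 275.15
  expect_equal(standard_gibbs(rx, th2),
               dH * (1 - T1 / T0) + dG25 * T1 / T0)
  # pressure term: dV * (P - 1) * 1e-4 kJ
  th_p <- thermo_state(25, 251)
  expect_equal(standard_gibbs(rx, th_p, dV_cm3_mol = 10) - dG25,
               10 * 250 * 1e-4)
})

test_that("in-situ Gibbs energy honours standard-state and equilibrium identities", {
  rx <- anammox_stoichiometry("nitrite_canonical")
  th <- thermo_state(25, 1, activity_model = "unit")
  dG0 <- standard_gibbs(rx, th)

  # Q = 1: all activities 1 (= 1e6 uM at unit coefficients)
  conc1 <- list(NH4 = 1e6, NO2 = 1e6, N2 = 1e6)
  expect_equal(in_situ_gibbs(rx, th, conc1, per = "reaction"), dG0)

  # equilibrium: choose reactant activities so RT ln Q = -dG0
  RT <- 8.314e-3 * 298.15
  x <- exp(dG0 / (2 * RT))            # a_NH4 = a_NO2 = x, a_N2 = 1
  conc_eq <- list(NH4 = x * 1e6, NO2 = x * 1e6, N2 = 1e6)
  expect_equal(in_situ_gibbs(rx, th, conc_eq, per = "reaction"), 0,
               tolerance = 1e-9)
})

test_that("NATZ porewater conditions give a strongly exergonic anammox", {
  rx <- anammox_stoichiometry("nitrite_canonical")
  th <- thermo_state(2, 250, ionic_strength = 0.7,
                     activity_model = "davies")
  dG <- in_situ_gibbs(rx, th, list(NH4 = 50, NO2 = 0.1, N2 = 500))

  # independent quotient oracle: Davies coefficients and quotient by hand
  gam1 <- 10^(-0.509 * (sqrt(0.7) / (1 + sqrt(0.7)) - 0.3 * 0.7))
  tab <- thermo_constants()
  pick <- function(col, sp) tab[[col]][tab$species == sp]
  dG25 <- pick("dG0f_kJ_mol", "N2") + 2 * pick("dG0f_kJ_mol", "H2O") -
    pick("dG0f_kJ_mol", "NH4") - pick("dG0f_kJ_mol", "NO2")
  dH <- pick("dH0f_kJ_mol", "N2") + 2 * pick("dH0f_kJ_mol", "H2O") -
    pick("dH0f_kJ_mol", "NH4") - pick("dH0f_kJ_mol", "NO2")
  T1 <- 275.15; T0 <- 298.15
  dG0T <- dH * (1 - T1 / T0) + dG25 * T1 / T0
  lnQ <- log(500e-6) - log(gam1 * 50e-6) - log(gam1 * 0.1e-6)
  oracle <- dG0T + 8.314e-3 * T1 * lnQ
  expect_equal(dG, oracle, tolerance = 1e-12)
  expect_lt(dG, -280)   # strongly exergonic
})

test_that("Gibbs energy is monotone in the reaction quotient and Davies
           collapses to unit coefficients at zero ionic strength", {
  rx <- anammox_stoichiometry("nitrite_canonical")
  th <- thermo_state(2, 250, activity_model = "unit")
  n2 <- 10^seq(0, 4, length.out = 12)       # product grid -> Q increasing
  dg <- in_situ_gibbs(rx, th, list(NH4 = 50, NO2 = 1, N2 = n2))
  expect_true(all(diff(dg) > 0))

  th_d0 <- thermo_state(2, 250, ionic_strength = 0,
                        activity_model = "davies")
  th_u <- thermo_state(2, 250, ionic_strength = 0, activity_model = "unit")
  cc <- list(NH4 = 50, NO2 = 1, N2 = 500)
  expect_equal(in_situ_gibbs(rx, th_d0, cc), in_situ_gibbs(rx, th_u, cc))
})

test_that("per-N normalisation is consistent with per-NH4", {
  rx <- anammox_stoichiometry("nitrate_coupled")
  th <- thermo_state(2, 250, activity_model = "unit")
  cc <- list(NH4 = 50, NO3 = 10, N2 = 500)
  per_nh4 <- in_situ_gibbs(rx, th, cc, per = "NH4")
  per_n <- in_situ_gibbs(rx, th, cc, per = "N")
  # 1 mol NH4 consumed produces 0.8 mol N2 = 1.6 mol N converted
  expect_equal(per_n * 1.6, per_nh4)
})

test_that("power supply is the rate-energy product with correct units", {
  expect_equal(power_supply(0, -100)$power_J_cm3_yr, 0)
  # 1 umol cm-3 yr-1 at -100 kJ/mol is 0.1 J cm-3 yr-1
  p <- power_supply(1, -100)
  expect_equal(p$power_J_cm3_yr, 0.1)
  expect_equal(p$power_W_cm3, 0.1 / 3.154e7)

  # linear rescaling of rate rescales power exactly
  r <- c(0, 0.3, 1.2, 0.7); g <- c(-90, -95, -100, -105)
  expect_equal(power_supply(3 * r, g)$power_J_cm3_yr,
               3 * power_supply(r, g)$power_J_cm3_yr)
  expect_equal(power_supply(r, g)$power_J_cm3_yr[r == 0], 0)
  expect_error(power_supply(1:3, c(-1, -2)), "grids|grid")
})

test_that("cell-specific rate conversion is scale-invariant and guarded", {
  expect_equal(cell_specific_rate(0, 1e6), 0)
  r1 <- cell_specific_rate(0.01, 1e7)
  expect_equal(cell_specific_rate(0.1, 1e8), r1)
  expect_error(cell_specific_rate(0.01, 0), "division guard")

  # hand chain on three fixtures: bulk rate -> per-cell -> protons/s
  set.seed(7)
  for (i in 1:3) {
    rate <- runif(1, 1e-4, 0.1); ab <- 10^runif(1, 5, 9)
    phi <- runif(1, 0.6, 0.9); rho <- 2.5; nH <- sample(2:6, 1)
    cells <- ab * rho * (1 - phi)
    hand <- (rate / cells * 1e9 / 365.25) * 1e-15 * 6.022e23 * nH / 86400
    got <- proton_pumping_rate(
      cell_specific_rate(rate, ab, rho_dry = rho, porosity = phi), nH)
    expect_equal(got, hand, tolerance = 1e-12)
  }
})

test_that("cell-specific rates in the synthetic NATZ match the field regime", {
  core <- reference_core()
  sol <- core$truth$solution
  r6 <- sol$reaction_rates[, "R6"]
  # abundance bump with a 1e7 cells/g peak, inside the span of qPCR peaks
  # observed in these zones
  ab <- make_abundance_profile(core$truth$natz,
                               sol$concentrations$depth_cm,
                               peak = 1e7, seed = 1)
  act <- r6 > 0.1 * max(r6)
  csr <- cell_specific_rate(r6[act], ab$true_cells_g[act],
                            porosity = sol$grid$porosity[act])
  expect_true(all(csr > 1e-3 & csr < 1e-1))
})

test_that("proton pumping converts the printed rate bounds", {
  expect_equal(signif(proton_pumping_rate(1e-1, n_H = 4), 2), 2800)
  expect_equal(signif(proton_pumping_rate(1e-3, n_H = 4), 2), 28)
  expect_equal(proton_pumping_rate(0), 0)
  expect_error(proton_pumping_rate(-1), ">= 0")
})
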