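test_that("QC gates on datapoint count and nitrate depletion", {
  # 5 datapoints: too few
  p5 <- suppressMessages(porewater_profile(
    "A", 1:5 * 10, list(NO3 = c(30, 20, 10, 4, 1), NH4 = rep(0, 5))))
  q <- qc_filter(p5)
  expect_false(q$pass)
  expect_true("too_few_points" %in% q$reasons)

  # 10 points but nitrate never below 2 uM
  p10 <- suppressMessages(porewater_profile(
    "B", 1:10 * 10, list(NO3 = seq(40, 10, length.out = 10))))
  q2 <- qc_filter(p10)
  expect_false(q2$pass)
  expect_identical(q2$reasons, "no_depletion")

  # both gates satisfied
  p_ok <- suppressMessages(porewater_profile(
    "C", 1:10 * 10, list(NO3 = seq(40, 0, length.out = 10))))
  expect_true(qc_filter(p_ok)$pass)

  expect_error(qc_filter(suppressMessages(porewater_profile(
    "D", 1:6, list(NH4 = rep(1, 6))))), "NO3")
})

test_that("QC is insensitive to input row order", {
  set.seed(3)
  z <- 1:10 * 10
  no3 <- seq(40, 0, length.out = 10)
  ord <- sample(10)
  p1 <- suppressMessages(porewater_profile("A", z, list(NO3 = no3)))
  p2 <- suppressMessages(porewater_profile("A", z[ord],
                                           list(NO3 = no3[ord])))
  expect_identical(qc_filter(p1), qc_filter(p2))
  expect_identical(p1$depths, p2$depths)
})

test_that("NATZ detection interpolates the two threshold crossings", {
  # NO3 40 -> 0 over 0-100 cm crosses 2 uM at 95; NH4 0 -> 40 over
  # 100-200 cm has its shallowest detectable extent at 105
  prof <- linear_natz_profile()
  iv <- detect_natz(prof)
  expect_equal(iv$top, 95)
  expect_equal(iv$bottom, 105)

  # unit-rescaling invariance: depths in metres scale the interval by 1/100
  prof_m <- suppressMessages(porewater_profile(
    "LINm", prof$depths / 100, prof$concentrations))
  iv_m <- detect_natz(prof_m, check_qc = FALSE)
  expect_equal(c(iv_m$top, iv_m$bottom), c(iv$top, iv$bottom) / 100)

  # degenerate overlap: both crossings at the same interpolated depth
  z <- seq(0, 200, by = 10)
  zd <- 100 / (1 - 2 / 40)             # makes both crossings land at 100
  no3 <- pmax(40 * (1 - z / zd), 0)
  nh4 <- pmax(40 * (1 - (200 - z) / zd), 0)
  deg <- detect_natz(suppressMessages(porewater_profile(
    "DEG", z, list(NO3 = no3, NH4 = nh4))), check_qc = FALSE)
  expect_equal(deg$top, 100, tolerance = 1e-9)
  expect_equal(deg$bottom, 100, tolerance = 1e-9)

  # ammonium never detectable: distinct no-NATZ condition
  flat <- suppressMessages(porewater_profile(
    "F", z, list(NO3 = pmax(40 - z, 0), NH4 = rep(0.5, length(z)))))
  expect_error(detect_natz(flat), class = "natzamx_no_natz")
})

test_that("detected interval on the forward-model core contains peak anammox", {
  core <- dense_noiseless_core()
  iv <- suppressMessages(detect_natz(core$profile))
  expect_gte(core$truth$depth_R6_max, iv$top)
  expect_lte(core$truth$depth_R6_max, iv$bottom)
})

test_that("diffusive flux applies Fick's law to a least-squares gradient", {
  # exact linear profile: C = 100 - 10 z over the fit window, phi = 0.8
  z <- seq(0, 9)
  p <- suppressMessages(porewater_profile(
    "L", z, list(NO3 = 100 - 10 * z, NH4 = c(rep(0, 9), 5)),
    porosity = 0.8))
  iv <- list(top = 9, bottom = 9)
  # choose D0 so Ds is exactly 300
  D0 <- 300 * (1 - 2 * log(0.8))
  J <- diffusive_flux(p, "NO3", iv, "above_natz", D0 = D0)
  expect_equal(J, -0.8 * 300 * (-10) * 1e-3)   # +2.4, downward

  # constant concentration: zero flux
  pc <- suppressMessages(porewater_profile(
    "C", z, list(NO3 = rep(50, 10)), porosity = 0.8))
  expect_equal(diffusive_flux(pc, "NO3", iv, "above_natz", D0 = D0), 0)

  # linearity: doubling concentrations doubles the flux
  p2 <- suppressMessages(porewater_profile(
    "L2", z, list(NO3 = 2 * (100 - 10 * z)), porosity = 0.8))
  expect_equal(diffusive_flux(p2, "NO3", iv, "above_natz", D0 = D0), 2 * J)

  expect_error(diffusive_flux(p, "NO3", list(top = 0.5, bottom = 0.5),
                              "above_natz", D0 = D0),
               "insufficient data")
})

test_that("noisy linear profiles recover the true flux within 3 SE", {
  set.seed(11)
  phi <- 0.8; D0 <- 350; slope <- -5
  Ds <- tortuosity_corrected_diffusivity(D0, phi)
  true_J <- -phi * Ds * slope * 1e-3
  z <- 0:9
  n_hit <- 0
  for (i in 1:20) {
    noisy <- 100 + slope * z + rnorm(10, 0, 1)
    p <- suppressMessages(porewater_profile(
      "N", z, list(NO3 = noisy), porosity = phi))
    J <- diffusive_flux(p, "NO3", list(top = 9, bottom = 9), "above_natz",
                        D0 = D0, n_fit_points = 10)
    # SE of the regression slope with sigma = 1 over 10 unit-spaced points
    se_slope <- 1 / sqrt(sum((z - mean(z))^2))
    se_J <- phi * Ds * se_slope * 1e-3
    if (abs(J - true_J) < 3 * se_J) n_hit <- n_hit + 1
  }
  expect_gte(n_hit, 19)   # ~99.7% nominal coverage
})

test_that("model-consistent fluxes: signs and magnitudes on the dense core", {
  core <- dense_noiseless_core()
  sol <- core$truth$solution
  iv <- suppressMessages(detect_natz(core$profile))
  sp <- species_table(); d0 <- setNames(sp$D0, sp$name)
  f_no3 <- diffusive_flux(core$profile, "NO3", iv, "above_natz",
                          D0 = d0[["NO3"]])
  f_nh4 <- diffusive_flux(core$profile, "NH4", iv, "below_natz",
                          D0 = d0[["NH4"]])
  expect_gt(f_no3, 0)     # nitrate moves down into the zone
  expect_lt(f_nh4, 0)     # ammonium moves up into the zone
  i_top <- which.min(abs(sol$face_depths - iv$top))
  i_bot <- which.min(abs(sol$face_depths - iv$bottom))
  expect_lt(abs(f_no3 - sol$face_fluxes[i_top, "NO3"]),
            0.2 * abs(sol$face_fluxes[i_top, "NO3"]))
  expect_lt(abs(f_nh4 - sol$face_fluxes[i_bot, "NH4"]),
            0.2 * abs(sol$face_fluxes[i_bot, "NH4"]))
})

test_that("efflux classification thresholds ammonium above the zone", {
  z <- seq(0, 200, by = 10)
  iv <- list(top = 95, bottom = 105)
  base <- list(NO3 = pmax(40 * (1 - z / 100), 0),
               NH4 = pmax(40 * (z - 100) / 100, 0))
  p0 <- suppressMessages(porewater_profile("A", z, base))
  expect_false(classify_efflux(p0, iv))

  leaky <- base
  leaky$NH4[z == 50] <- 15
  p1 <- suppressMessages(porewater_profile("B", z, leaky))
  expect_true(classify_efflux(p1, iv))

  # no measurements above the zone: indeterminate
  deep <- suppressMessages(porewater_profile(
    "C", z + 100, list(NH4 = base$NH4)))
  expect_true(is.na(suppressMessages(classify_efflux(deep, iv))))
})

test_that("site summaries compute the no-efflux percentage", {
  stub <- function(n_sites, n_pass, n_no_efflux) {
    structure(list(sites = list(), n_sites = n_sites, n_pass = n_pass,
                   n_no_efflux = n_no_efflux),
              class = "site_compilation")
  }
  summarize_counts <- function(s) summarize_sites(s)$counts$pct_no_efflux
  expect_equal(summarize_counts(stub(67, 67, 56)), 84)
  expect_equal(summarize_counts(stub(10, 10, 0)), 0)
  expect_equal(summarize_counts(stub(67, 67, 67)), 100)
  expect_warning(summarize_sites(stub(3, 0, 0)), "empty")
})

test_that("sediment age is depth over sedimentation rate", {
  expect_equal(sediment_age(160, 2), 80000)
  expect_equal(sediment_age(0, 2), 0)
  expect_equal(sediment_age(100, 4), 25000)
  expect_error(sediment_age(10, 0), "invalid input")
})
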