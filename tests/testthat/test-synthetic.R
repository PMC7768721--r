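test_that("noiseless cores equal the forward model at the sample depths", {
  core <- dense_noiseless_core()
  sol <- core$truth$solution
  z <- core$profile$depths
  for (sp in c("O2", "NO3", "NH4")) {
    expect_equal(core$profile$concentrations[[sp]],
                 approx(sol$grid$depths, sol$concentrations[[sp]],
                        xout = z, rule = 2)$y)
  }
})

test_that("core generation is deterministic given the seed", {
  spec <- default_core_spec(n_cells = 100, seed = 42)
  a <- suppressMessages(make_core(spec))
  b <- suppressMessages(make_core(spec))
  expect_identical(a$profile$concentrations, b$profile$concentrations)
  c2 <- suppressMessages(make_core(default_core_spec(n_cells = 100,
                                                     seed = 43)))
  expect_false(identical(a$profile$concentrations,
                         c2$profile$concentrations))
})

test_that("the default core has the reference geochemical structure", {
  core <- reference_core()
  sol <- core$truth$solution
  cc <- sol$concentrations
  # oxygen depletion between 0.4 and 1.2 m below seafloor
  o2_depl <- cc$depth_cm[which(cc$O2 < 2)[1]]
  expect_gt(o2_depl, 40); expect_lt(o2_depl, 120)
  # nitrate depleted below the oxygen depletion depth
  no3_depl <- cc$depth_cm[which(cc$NO3 < 2)[1]]
  expect_gt(no3_depl, o2_depl)
  # deep ammonium source
  expect_gt(cc$NH4[nrow(cc)], 100)

  # observed (noisy) profile passes QC and its NATZ brackets peak anammox
  expect_true(qc_filter(core$profile)$pass)
  iv <- suppressMessages(detect_natz(core$profile))
  expect_gte(core$truth$depth_R6_max, iv$top)
  expect_lte(core$truth$depth_R6_max, iv$bottom)
})

test_that("truth objects accompany every generator output", {
  core <- reference_core()
  expect_true(all(c("solution", "profiles", "R6", "natz",
                    "boundary_fluxes", "parameters") %in%
                    names(core$truth)))
  cov <- make_coverage(ori_ter_ratio = 1.4, seed = 2)
  expect_equal(cov$truth$ori_ter_ratio, 1.4)
  coll <- suppressMessages(make_site_collection(n_sites = 10, seed = 2))
  expect_identical(nrow(coll$truth), 10L)
})

test_that("abundance bumps span four orders of magnitude over background", {
  iv <- list(top = 90, bottom = 100)
  z <- c(seq(5, 50, 5), seq(75, 300, 25))

  # flat when peak equals background (truth curve exactly flat)
  flat <- make_abundance_profile(iv, z, background = 1e5, peak = 1e5,
                                 seed = 1)
  expect_true(all(flat$true_cells_g == 1e5))

  # determinism
  a <- make_abundance_profile(iv, z, seed = 9)
  b <- make_abundance_profile(iv, z, seed = 9)
  expect_identical(a, b)

  # defaults: truth ratio is exactly 1e4 when the bump centre is sampled
  zc <- sort(c(z, 95))
  d <- make_abundance_profile(iv, zc, seed = 1)
  expect_equal(max(d$true_cells_g) / min(d$true_cells_g), 1e4,
               tolerance = 1e-6)
  expect_equal(d$depth_cm[which.max(d$true_cells_g)], 95)

  # observed max/min ratio: median across seeds inside the 1e3.5-1e4.5 band
  r <- vapply(1:15, function(s) {
    x <- make_abundance_profile(iv, z, seed = s)$abundance_cells_g
    log10(max(x) / min(x))
  }, numeric(1))
  expect_gt(median(r), 3.5)
  expect_lt(median(r), 4.5)

  expect_error(make_abundance_profile(iv, z, background = 10, peak = 1),
               "invalid configuration")
  expect_error(make_abundance_profile(iv, z, width = -1),
               "invalid configuration")
})

test_that("site collections encode the designed efflux fraction and QC failures", {
  coll <- suppressMessages(make_site_collection(n_sites = 30,
                                                no_efflux_fraction = 1,
                                                qc_fail_fraction = 0,
                                                seed = 4))
  comp <- suppressMessages(compile_sites(coll$profiles))
  eff <- vapply(comp$sites, function(s) s$efflux, NA)
  pass <- vapply(comp$sites, function(s) isTRUE(s$qc$pass), logical(1))
  expect_true(all(!eff[pass & !is.na(eff)]))

  # sparse sites fail QC with too_few_points
  coll2 <- suppressMessages(make_site_collection(n_sites = 40,
                                                 qc_fail_fraction = 0.5,
                                                 seed = 6))
  comp2 <- suppressMessages(compile_sites(coll2$profiles))
  designed <- coll2$truth$designed_qc_fail
  reasons <- lapply(comp2$sites, function(s) s$qc$reasons)
  expect_true(all(vapply(which(designed), function(i)
    "too_few_points" %in% reasons[[i]], logical(1))))

  expect_error(make_site_collection(no_efflux_fraction = 2), "fraction")
  expect_error(make_site_collection(sparsity = 1), "sparsity")
})

test_that("no-efflux percentage is recovered within the binomial interval", {
  coll <- suppressMessages(make_site_collection(n_sites = 67,
                                                no_efflux_fraction = 0.84,
                                                seed = 1))
  s <- suppressMessages(summarize_sites(compile_sites(coll$profiles)))
  pct <- s$counts$pct_no_efflux
  # binomial 95% interval around 84% at the QC-passing site count
  half <- 196 * sqrt(0.84 * 0.16 / s$counts$n_pass)
  expect_gt(pct, 84 - half)
  expect_lt(pct, 84 + half)
})

test_that("coverage generator honours its contracts", {
  # ratio 1, no noise: exactly uniform
  u <- make_coverage(ori_ter_ratio = 1, noise_model = "none")
  expect_equal(diff(range(u$track$windows$coverage)), 0)

  # deterministic under a fixed seed
  a <- make_coverage(ori_ter_ratio = 1.3, noise_model = "poisson", seed = 8)
  b <- make_coverage(ori_ter_ratio = 1.3, noise_model = "poisson", seed = 8)
  expect_identical(a$track$windows, b$track$windows)

  expect_error(make_coverage(ori_ter_ratio = 0.5), "invalid configuration")
  expect_error(make_coverage(mean_depth = 0), "invalid configuration")
})
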