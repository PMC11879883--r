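test_that("occupancy follows the flyability-corrected area ratio", {
  expect_equal(computeStoichiometry(I_pP = 0, I_P = 100, k = 3.7), 0)
  expect_equal(computeStoichiometry(I_pP = 50, I_P = 50, k = 1), 50)
  expect_equal(computeStoichiometry(I_pP = 30, I_P = 40, k = 2), 60)
  expect_error(computeStoichiometry(0, 0, 1), "no signal")
  expect_error(computeStoichiometry(10, 10, 0), "positive")
  expect_error(computeStoichiometry(10, 10, -2), "positive")
})

test_that("occupancy is bounded and monotone in each argument", {
  set.seed(1)
  IpP <- runif(500, 0, 1e6); IP <- runif(500, 0, 1e6)
  k <- runif(500, 0.1, 15)
  occ <- computeStoichiometry(IpP, IP, k)
  expect_true(all(occ >= 0 & occ <= 100))
  # strictly increasing in I_pP and k, decreasing in I_P
  expect_true(all(computeStoichiometry(IpP * 1.1, IP, k) > occ))
  expect_true(all(computeStoichiometry(IpP, IP * 1.1, k) < occ))
  expect_true(all(computeStoichiometry(IpP, IP, k * 1.1) > occ))
  # k = 1 reduces to the uncorrected area fraction
  expect_equal(computeStoichiometry(IpP, IP, 1), 100 * IpP / (IpP + IP))
})

test_that("mean/SEM summaries follow the n-1 sample convention", {
  s <- summarizeMeanSem(5)
  expect_equal(s$mean, 5); expect_true(is.na(s$sem)); expect_equal(s$n, 1L)
  s2 <- summarizeMeanSem(c(2, 4))
  expect_equal(s2$mean, 3); expect_equal(s2$sem, 1)
  expect_equal(summarizeMeanSem(c(7, 7, 7))$sem, 0)
  expect_equal(summarizeMeanSem(c(1, 2, 3))$sem, 0.57735, tolerance = 1e-5)
  expect_error(summarizeMeanSem(numeric()), "no values")
})

test_that("the stoichiometry table summarises per-replicate occupancies", {
  paired <- data.frame(site_label = "S1", sample = "basal",
                       replicate = 1:3, I_P = c(70, 60, 50),
                       I_pP = c(30, 40, 50))
  tab <- siteStoichiometryTable(paired, c(S1 = 1))
  expect_equal(tab$n, 3L)
  expect_equal(tab$replicate_pct[[1]], c(30, 40, 50))
  expect_equal(tab$mean_pct, 40)
  expect_equal(tab$sem_pct, sd(c(30, 40, 50)) / sqrt(3))
  expect_equal(tab$k_used, 1)

  # identical areas across replicates give sem 0
  paired0 <- transform(paired, I_P = 60, I_pP = 40)
  expect_equal(siteStoichiometryTable(paired0, c(S1 = 1))$sem_pct, 0)

  expect_error(siteStoichiometryTable(paired, c(other = 1)),
               "no flyability ratio.*S1")
})

test_that("a calibrated panel supplies k to the stoichiometry table", {
  paired <- data.frame(site_label = "S1", sample = "basal",
                       replicate = 1L, I_P = 40, I_pP = 30)
  tab <- siteStoichiometryTable(paired, tinyPanel(k = 2))
  expect_equal(tab$mean_pct, 60)
  expect_error(siteStoichiometryTable(paired, tinyPanel()),
               "no flyability")
})

test_that("occupancy survives the full calibration round trip under noise", {
  # flyability re-estimated from simulated A/B pairs (3 technical
  # injections) before computing occupancy at CV 10%.  Sites with very low
  # occupancy can fail the calibration's direction-of-change validity
  # check (the untreated calibration sample carries almost no phospho
  # signal); those raise the prescribed error and are necessarily left
  # uncalibrated here.
  rp <- randomSitePanel(120, seed = 88, theta_range = c(0.05, 0.95),
                        fly_range = c(0.5, 12))
  cfg <- simulationConfig(rp$panel, rp$theta, flyability = rp$flyability,
                          noise_cv = 0.1, n_bio = 3, n_tech = 3, seed = 88)
  sim <- simulatePeakReport(cfg)
  khat <- vapply(seq_along(rp$flyability), function(i) {
    site <- names(rp$flyability)[i]
    t1 <- panelTargets(rp$panel)[i, , drop = FALSE]
    mini <- targetPanel(site, t1$dephos, t1$phos,
                        charges = list(t1$charges[[1]]))
    cp <- simulateCalibrationPair(cfg, site, seed = 60000 + i)
    tryCatch(calibrateFlyability(cp$report, mini, "calib_A",
                                 "calib_B")$calibrations[[site]]@k,
             error = function(e) NA_real_)
  }, numeric(1))
  names(khat) <- names(rp$flyability)
  ok <- !is.na(khat)
  expect_gte(sum(ok), 108L)  # >= 90% of sites calibrable
  # failures, if any, confined to low-occupancy sites
  expect_true(all(rp$theta[!ok] < 0.35))
  paired <- pairCognates(sim$report, rp$panel)
  tab <- siteStoichiometryTable(paired[paired$site_label %in%
                                         names(khat)[ok], ], khat[ok])
  err <- abs(tab$mean_pct - 100 * rp$theta[tab$site_label])
  expect_lte(median(err), 3)
})

test_that("noiseless simulation yields the configured occupancy in every replicate", {
  cfg <- simulationConfig(tinyPanel(), c(S1 = 0.6),
                          flyability = c(S1 = 2.5), noise_cv = 0,
                          n_bio = 3, seed = 9)
  sim <- simulatePeakReport(cfg)
  paired <- pairCognates(sim$report, tinyPanel())
  tab <- siteStoichiometryTable(paired, c(S1 = 2.5))
  expect_equal(tab$replicate_pct[[1]], rep(60, 3), tolerance = 1e-9)
  expect_equal(tab$sem_pct, 0, tolerance = 1e-9)
})
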