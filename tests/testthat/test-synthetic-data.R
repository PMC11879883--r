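test_that("simulation config validation catches inconsistent worlds", {
  expect_error(simulationConfig(tinyPanel(), c(S1 = 1.2),
                                flyability = c(S1 = 1)), "\\[0, 1\\]")
  expect_error(simulationConfig(tinyPanel(), c(S1 = 0.5)),
               "no flyability")
  expect_error(simulationConfig(tinyPanel(), c(S1 = 0.5),
                                flyability = c(S1 = -1)), "positive")
  expect_error(simulationConfig(tinyPanel(), c(S1 = 0.5),
                                flyability = c(S1 = 1),
                                charge_fractions = list(S1 = c(0.5, 0.4))),
               "sum to 1")
})

test_that("identical seed and config give byte-identical reports", {
  cfg <- defaultSimulationConfig(seed = 123)
  s1 <- simulatePeakReport(cfg)
  s2 <- simulatePeakReport(cfg)
  expect_identical(s1$report, s2$report)
  expect_identical(s1$ledger, s2$ledger)
  # a different seed changes the noise draw
  s3 <- simulatePeakReport(defaultSimulationConfig(seed = 124))
  expect_false(identical(s1$report$area, s3$report$area))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulatePeakReport(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noise-free areas satisfy the generative occupancy identity", {
  cfg <- simulationConfig(tinyPanel(), c(S1 = 0.37),
                          flyability = c(S1 = 3.3), amount = 2e6,
                          noise_cv = 0, n_bio = 2, seed = 1)
  sim <- simulatePeakReport(cfg)
  expect_equal(sim$report$area, sim$ledger$areas$area_true)
  led <- sim$ledger$areas
  IP <- sum(led$area_true[led$species == "SGTATPQR" & led$replicate == 1])
  IpP <- sum(led$area_true[led$species == "S[+80]GTATPQR" &
                           led$replicate == 1])
  expect_equal(IP, 2e6 * (1 - 0.37))
  expect_equal(IpP, 2e6 * 0.37 / 3.3)
  expect_equal(computeStoichiometry(IpP, IP, 3.3), 37, tolerance = 1e-12)
})

test_that("theta = 0 sites emit zero phospho signal", {
  cfg <- simulationConfig(tinyPanel(), c(S1 = 0), flyability = c(S1 = 1),
                          noise_cv = 0.2, seed = 8)
  sim <- simulatePeakReport(cfg)
  ph <- sim$report$species == "S[+80]GTATPQR"
  expect_true(all(sim$report$area[ph] == 0))
  expect_true(all(sim$report$area[!ph] > 0))
})

test_that("empirical area CV matches the configured noise level", {
  cfg <- simulationConfig(tinyPanel(), c(S1 = 0.5), flyability = c(S1 = 1),
                          noise_cv = 0.1, n_bio = 10000L, seed = 31)
  sim <- simulatePeakReport(cfg)
  a <- sim$report$area[sim$report$species == "SGTATPQR"]
  cv <- sd(a) / mean(a)
  expect_equal(cv, 0.1, tolerance = 0.1)
})

test_that("calibration pair simulation honours theta_A and replication", {
  cfg <- simulationConfig(tinyPanel(), c(S1 = 0.8), flyability = c(S1 = 2),
                          noise_cv = 0, n_tech = 4, seed = 6)
  cp <- simulateCalibrationPair(cfg, "S1", theta_A = 0.1)
  expect_equal(sort(unique(cp$report$sample)), c("calib_A", "calib_B"))
  expect_equal(max(cp$report$replicate), 4L)
  A <- cp$report[cp$report$sample == "calib_A" &
                 cp$report$species == "S[+80]GTATPQR", "area"]
  expect_equal(unique(A), cfg@amount[["S1"]] * 0.1 / 2)
  expect_error(simulateCalibrationPair(cfg, "nope"), "not in the")
  # an A/B pair with no phosphorylation difference is uninformative
  cp0 <- simulateCalibrationPair(cfg, "S1", theta_A = 0.8)
  expect_error(calibrateFlyability(cp0$report, tinyPanel(),
                                   "calib_A", "calib_B"),
               "uninformative")
})

test_that("time-course occupancies decay exponentially to the plateau", {
  cfg <- simulationConfig(tinyPanel(), c(S1 = 0.25),
                          flyability = c(S1 = 1), noise_cv = 0, seed = 2)
  # rate 0 keeps the baseline at every time point
  flat <- simulateTimecourse(cfg, data.frame(site_label = "S1",
                                             plateau = 0.03, rate = 0))
  expect_equal(unique(flat$ledger$truth$theta), 0.25)
  # emulation of a strongly inhibitor-sensitive site: ~25% basal dropping
  # to ~11% by 1 h and ~3% by 4 h
  tc <- simulateTimecourse(cfg, data.frame(site_label = "S1",
                                           plateau = 0.03, rate = 1.01),
                           times = c(0, 1, 4))
  th <- tc$ledger$truth
  expect_equal(th$theta[th$sample == "t0h"], 0.25)
  expect_equal(th$theta[th$sample == "t1h"], 0.110, tolerance = 0.01)
  expect_equal(th$theta[th$sample == "t4h"], 0.034, tolerance = 0.02)
  expect_error(
    simulateTimecourse(cfg, data.frame(site_label = "S1", plateau = 0.5,
                                       rate = 1)),
    "plateau")
})

test_that("standards generation is deterministic and exact at CV = 0", {
  truth <- c(a0 = 1, a1 = 2, a2 = 0.3)
  s1 <- simulateStandards(truth, c(1, 10, 100, 1000), noise_cv = 0.05,
                          seed = 5)
  s2 <- simulateStandards(truth, c(1, 10, 100, 1000), noise_cv = 0.05,
                          seed = 5)
  expect_identical(s1, s2)
  s0 <- simulateStandards(truth, c(1, 10, 100, 1000))
  expect_equal(s0$area, exp(0.3 * log(s0$conc)^2 + 2 * log(s0$conc) + 1))
  expect_error(simulateStandards(truth, c(0, 1)), "positive")
})
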