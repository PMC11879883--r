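test_that("peak report IO round-trips a 50-row synthetic report byte for byte", {
  cfg <- simulationConfig(isomerPanel(), c(S1 = 0.3, T5 = 0.2),
                          flyability = c(S1 = 1.3, T5 = 1.1),
                          noise_cv = 0.1, n_bio = 5, seed = 11)
  sim <- simulatePeakReport(cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writePeakReport(sim$report, f1)
  writePeakReport(readPeakReport(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("invalid peak reports are rejected", {
  good <- peakRow("SGTATPQR", 2L, "basal", 1L, 1e6)
  f <- tempfile(fileext = ".csv")
  write.csv(good[, -5], f, row.names = FALSE)
  expect_error(readPeakReport(f), "missing column")
  expect_error(writePeakReport(transform(good, area = -1), tempfile()),
               "non-negative")
  expect_error(writePeakReport(rbind(good, good), tempfile()),
               "duplicate")
})

test_that("charge aggregation sums areas over the charges used", {
  pair <- targetPanel("S1", "SGTATPQR", "S[+80]GTATPQR", charges = "2;3")
  m <- rbind(peakRow("SGTATPQR", 2L, "s", 1L, 100),
             peakRow("SGTATPQR", 3L, "s", 1L, 50),
             peakRow("S[+80]GTATPQR", 2L, "s", 1L, 10),
             peakRow("S[+80]GTATPQR", 3L, "s", 1L, 5))
  out <- aggregateChargeAreas(m, pair, "s", 1L)
  expect_equal(out, c(I_P = 150, I_pP = 15))

  # single observed charge passes through with a warning, contributing 0
  # for the unobserved one
  m2 <- m[m$charge == 2L, ]
  w <- capture_warnings(out2 <- aggregateChargeAreas(m2, pair, "s", 1L))
  expect_match(w, "not observed", all = TRUE)
  expect_length(w, 2L)  # one per species missing its 3+ charge
  expect_equal(unname(out2["I_P"]), 100)

  # no observed charge at all for a species is an error naming it
  m3 <- m[m$species == "SGTATPQR", ]
  expect_error(suppressWarnings(aggregateChargeAreas(m3, pair, "s", 1L)),
               "no signal.*S\\[\\+80\\]GTATPQR")

  # permutation invariance and additivity
  out3 <- aggregateChargeAreas(m[sample(nrow(m)), ], pair, "s", 1L)
  expect_equal(out3, out)
})

test_that("di-phospho screening applies the 10% rule", {
  sp <- function(areas)
    data.frame(species = names(areas), area = unname(areas),
               stringsAsFactors = FALSE)
  # scarce di-phospho species is excluded as unquantifiable
  scr <- screenPhosphospecies(sp(c("S[+80]GTAT[+80]PQR" = 8,
                                   "S[+80]GTATPQR" = 100)))
  expect_equal(scr$status[1], "excluded")
  expect_match(scr$reason[1], "10%")
  expect_equal(scr$status[2], "retained")

  # mono-phospho positional isomers are all retained
  scr2 <- screenPhosphospecies(sp(c("S[+80]GTATPQR" = 100,
                                    "SGTAT[+80]PQR" = 40)))
  expect_true(all(scr2$status == "retained"))

  # a di-phospho at/above threshold is kept but flagged
  scr3 <- screenPhosphospecies(sp(c("S[+80]GTAT[+80]PQR" = 15,
                                    "S[+80]GTATPQR" = 100)))
  expect_equal(scr3$status[1], "needs_review")

  # exclusion is monotone in the threshold
  areas <- sp(c("S[+80]GTAT[+80]PQR" = 15, "S[+80]GTATPQR" = 100))
  excl <- vapply(c(0.05, 0.10, 0.20, 0.50), function(th)
    sum(screenPhosphospecies(areas, th)$status == "excluded"), numeric(1))
  expect_true(all(diff(excl) >= 0))

  expect_error(screenPhosphospecies(sp(c("S[+80]GTAT[+80]PQR" = 8))),
               "mono-phospho")
})

test_that("cognate pairing gives one row per site/sample/replicate", {
  # positional isomers share the dephospho area
  m <- rbind(peakRow("SGTATPQR", 2L, "basal", 1L, 200),
             peakRow("S[+80]GTATPQR", 2L, "basal", 1L, 30),
             peakRow("SGTAT[+80]PQR", 2L, "basal", 1L, 10))
  paired <- pairCognates(m, isomerPanel())
  expect_equal(nrow(paired), 2L)
  expect_equal(paired$I_P, c(200, 200))
  expect_equal(sort(paired$I_pP), c(10, 30))

  # replicates each get a row
  m3 <- do.call(rbind, lapply(1:3, function(r)
    rbind(peakRow("SGTATPQR", 2L, "basal", r, 100),
          peakRow("S[+80]GTATPQR", 2L, "basal", r, 50))))
  expect_equal(nrow(pairCognates(m3, tinyPanel())), 3L)

  # all-zero site is a hard error
  m0 <- rbind(peakRow("SGTATPQR", 2L, "basal", 1L, 0),
              peakRow("S[+80]GTATPQR", 2L, "basal", 1L, 0))
  expect_error(pairCognates(m0, tinyPanel()), "no signal")
})

test_that("pairing reproduces the generator's ledger areas", {
  cfg <- simulationConfig(isomerPanel(), c(S1 = 0.4, T5 = 0.1),
                          flyability = c(S1 = 2, T5 = 0.7),
                          noise_cv = 0, n_bio = 2, seed = 5)
  sim <- simulatePeakReport(cfg)
  paired <- pairCognates(sim$report, isomerPanel())
  led <- sim$ledger$areas
  for (i in seq_len(nrow(paired))) {
    sub <- led[led$site_label == paired$site_label[i] &
               led$replicate == paired$replicate[i], ]
    np <- vapply(sub$species, function(s)
      countPhospho(parsePeptide(sub("#.*$", "", s))), integer(1))
    expect_equal(paired$I_P[i], sum(sub$area_true[np == 0]))
    expect_equal(paired$I_pP[i], sum(sub$area_true[np == 1]))
  }
})
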