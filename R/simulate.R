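# Synthetic peak-area generator.  Generates long-format reports in the exact
# schema the quantification layer consumes, together with a ground-truth
# ledger, so parameter recovery can be verified end to end without any raw
# MS data.
#
# Generative convention: a site with true occupancy theta, flyability f and
# total peptide amount T produces noise-free charge-summed areas
#   I_P  = T * (1 - theta)        (dephospho cognate)
#   I_pP = T * theta / f          (phosphopeptide "flies" 1/f as well)
# so that the occupancy model with k = f returns exactly 100 * theta.  Each
# site's cognate pool is generated independently; where two sites share a
# dephospho peptide string the generated species are disambiguated with a
# "#<site_label>" tag (a simplification relative to a genuinely shared
# peptide pool; see the methods vignette).

.lnSd <- function(cv) sqrt(log(1 + cv^2))

.applyNoise <- function(x, cv) {
  if (cv == 0) return(x)
  x * exp(rnorm(length(x), 0, .lnSd(cv)))
}

# run code with a private, restored RNG state
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old))
        rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Build a simulation configuration
#'
#' @param panel a [TargetPanel-class] naming the sites to simulate.
#' @param theta true occupancies in \[0, 1\]: a matrix (rows = sites,
#'   columns = samples, both named) or a named vector for a single sample
#'   called `"basal"`.
#' @param flyability true flyability per site (named); defaults to the
#'   panel's `flyability` column.
#' @param amount total peptide amount per site in area units (named or
#'   scalar; default `1e6`).
#' @param charge_fractions per-site numeric vectors of the signal fraction
#'   in each used charge state (must sum to 1); default: equal split.
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal area noise (natural scale; default 0.1, a typical
#'   label-free EIC precision).
#' @param n_tech technical injections per calibration sample (default 3).
#' @param n_bio biological replicates per sample (default 3).
#' @param seed integer seed; identical seed and config give byte-identical
#'   output.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(panel, theta, flyability = NULL, amount = 1e6,
                             charge_fractions = NULL, noise_cv = 0.1,
                             n_tech = 3L, n_bio = 3L, seed = 1L) {
  stopifnot(is(panel, "TargetPanel"))
  t <- panel@targets
  sites <- t$site_label
  if (!is.matrix(theta)) {
    theta <- matrix(theta, ncol = 1,
                    dimnames = list(names(theta), "basal"))
  }
  theta <- theta[sites, , drop = FALSE]
  if (is.null(flyability)) {
    flyability <- setNames(t$flyability, sites)
    if (anyNA(flyability))
      stop("panel has no flyability for site(s): ",
           paste(sites[is.na(flyability)], collapse = ", "))
  } else flyability <- flyability[sites]
  if (length(amount) == 1L && is.null(names(amount)))
    amount <- setNames(rep(amount, length(sites)), sites)
  else amount <- amount[sites]
  if (is.null(charge_fractions)) {
    charge_fractions <- lapply(setNames(seq_along(sites), sites), function(i) {
      nch <- length(t$charges[[i]])
      rep(1 / nch, nch)
    })
  } else charge_fractions <- charge_fractions[sites]
  new("SimulationConfig", panel = panel, theta = theta,
      flyability = flyability, amount = amount,
      charge_fractions = charge_fractions, noise_cv = as.numeric(noise_cv),
      n_tech = as.integer(n_tech), n_bio = as.integer(n_bio),
      seed = as.integer(seed))
}

#' Default simulation world modelled on the shipped AMPK panel
#'
#' One `"basal"` sample over the 19-site AMPK panel, with flyabilities as
#' calibrated on the original platform (0.58--12.22), true occupancies
#' spread evenly over the observed basal span of roughly 4--96\%, total
#' amount 1e6 area units per site, log-normal noise CV 10\%, 3 technical
#' injections and 3 biological replicates.
#'
#' @param seed integer seed.
#' @param noise_cv override the noise level.
#' @return A [SimulationConfig-class].
#' @export
defaultSimulationConfig <- function(seed = 1L, noise_cv = 0.1) {
  panel <- defaultTargetPanel()
  sites <- siteLabels(panel)
  theta <- setNames(seq(0.04, 0.96, length.out = length(sites)), sites)
  simulationConfig(panel, theta, noise_cv = noise_cv, seed = seed)
}

# species string for one site's form, tagging where a peptide string is
# shared between sites of the panel
.speciesName <- function(pep, site, shared) {
  if (pep %in% shared) paste0(pep, "#", site) else pep
}

#' Simulate a long-format peak-area report
#'
#' Generates one report row per (species, charge, sample, biological
#' replicate) under the configuration's ground truth, with multiplicative
#' log-normal noise, plus a ledger recording every noise-free area and the
#' per-site truth.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `report` (peak report data.frame, schema of
#'   [readPeakReport()]) and `ledger` (list with `truth`: per site/sample
#'   data.frame of `theta`, `flyability`, `amount`; and `areas`: the report
#'   with noise-free `area_true` instead of noisy areas).
#' @export
simulatePeakReport <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  t <- config@panel@targets
  shared <- unique(c(t$dephos[duplicated(t$dephos)],
                     t$phos[duplicated(t$phos)]))
  samples <- colnames(config@theta)
  rows <- list()
  .withSeed(config@seed, {
    for (i in seq_len(nrow(t))) {
      site <- t$site_label[i]
      charges <- t$charges[[i]]
      fr <- config@charge_fractions[[site]]
      T_amt <- config@amount[[site]]
      f <- config@flyability[[site]]
      for (smp in samples) {
        th <- config@theta[site, smp]
        for (rep_i in seq_len(config@n_bio)) {
          for (form in c("dephos", "phos")) {
            pep <- if (form == "dephos") t$dephos[i] else t$phos[i]
            free <- if (form == "dephos") T_amt * (1 - th) else T_amt * th / f
            for (ci in seq_along(charges)) {
              a_true <- free * fr[ci]
              rows[[length(rows) + 1L]] <- data.frame(
                species = .speciesName(pep, site, shared),
                charge = charges[ci], sample = smp, replicate = rep_i,
                area_true = a_true, site_label = site,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    areas <- do.call(rbind, rows)
    areas$area <- .applyNoise(areas$area_true, config@noise_cv)
  })
  report <- areas[, c("species", "charge", "sample", "replicate", "area")]
  truth <- expand.grid(site_label = t$site_label, sample = samples,
                       stringsAsFactors = FALSE)
  truth$theta <- config@theta[cbind(truth$site_label, truth$sample)]
  truth$flyability <- config@flyability[truth$site_label]
  truth$amount <- config@amount[truth$site_label]
  list(report = .validatePeakReport(report),
       ledger = list(truth = truth,
                     areas = areas[, c("species", "charge", "sample",
                                       "replicate", "site_label",
                                       "area_true")]))
}

#' Simulate a flyability calibration sample pair
#'
#' Emulates the calibration experiment for one site: sample `B` (high
#' phosphorylation, untreated) at the site's configured occupancy and
#' sample `A` (low phosphorylation) after a phosphatase treatment driving
#' occupancy to `theta_A` (default 0, complete dephosphorylation), both at
#' identical total peptide amount, each injected `n_tech` times.
#'
#' @param config a [SimulationConfig-class].
#' @param site site label in the config's panel.
#' @param theta_A residual occupancy of the treated sample (default 0).
#' @param sample_names labels for the pair in the emitted report.
#' @param seed RNG seed for the noise draw (defaults to the config's seed;
#'   pass distinct seeds to generate independent pairs).
#' @return list with `report` (peak report data.frame with samples A and B
#'   and `replicate` = injection number) and `ledger` (`theta_A`,
#'   `theta_B`, `flyability`, `amount`, and the noise-free areas).
#' @export
simulateCalibrationPair <- function(config, site, theta_A = 0,
                                    sample_names = c(A = "calib_A",
                                                     B = "calib_B"),
                                    seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  t <- config@panel@targets
  i <- match(site, t$site_label)
  if (is.na(i)) stop("site ", site, " not in the configuration's panel")
  stopifnot(theta_A >= 0, theta_A <= 1)
  theta_B <- config@theta[site, 1L]
  charges <- t$charges[[i]]
  fr <- config@charge_fractions[[site]]
  T_amt <- config@amount[[site]]
  f <- config@flyability[[site]]
  rows <- list()
  for (smp in c("A", "B")) {
    th <- if (smp == "A") theta_A else theta_B
    for (rep_i in seq_len(config@n_tech)) {
      for (form in c("dephos", "phos")) {
        pep <- if (form == "dephos") t$dephos[i] else t$phos[i]
        free <- if (form == "dephos") T_amt * (1 - th) else T_amt * th / f
        for (ci in seq_along(charges)) {
          rows[[length(rows) + 1L]] <- data.frame(
            species = pep, charge = charges[ci],
            sample = unname(sample_names[smp]), replicate = rep_i,
            area_true = free * fr[ci], stringsAsFactors = FALSE)
        }
      }
    }
  }
  areas <- do.call(rbind, rows)
  .withSeed(seed, {
    areas$area <- .applyNoise(areas$area_true, config@noise_cv)
  })
  report <- areas[, c("species", "charge", "sample", "replicate", "area")]
  list(report = .validatePeakReport(report),
       ledger = list(theta_A = theta_A, theta_B = theta_B, flyability = f,
                     amount = T_amt, areas = areas))
}

#' Simulate a treatment time course of occupancies
#'
#' Occupancy relaxes exponentially from its baseline towards a plateau,
#' \eqn{\theta(t) = plateau + (\theta_0 - plateau) e^{-rate\,t}}, emulating
#' the decay of a kinase-inhibitor-sensitive phosphosite after treatment.
#' The resulting per-time-point occupancies are passed through
#' [simulatePeakReport()].
#'
#' @param config a [SimulationConfig-class]; the first theta column is the
#'   baseline \eqn{\theta_0}.
#' @param decay data.frame with columns `site_label`, `plateau`, `rate`
#'   (per hour, `>= 0`); sites not listed keep their baseline at all times.
#' @param times time points in hours (samples are labelled `"t<h>h"`).
#' @return As [simulatePeakReport()].
#' @export
simulateTimecourse <- function(config, decay, times = c(0, 1, 4)) {
  stopifnot(is(config, "SimulationConfig"),
            all(c("site_label", "plateau", "rate") %in% names(decay)))
  if (any(decay$rate < 0)) stop("decay rates must be >= 0")
  theta0 <- setNames(config@theta[, 1L], rownames(config@theta))
  bad <- decay$site_label[decay$plateau < 0 |
                          decay$plateau > theta0[decay$site_label]]
  if (length(bad))
    stop("plateau outside [0, theta0] for site(s): ",
         paste(bad, collapse = ", "))
  theta <- vapply(times, function(tt) {
    th <- theta0
    idx <- match(decay$site_label, names(theta0))
    th[idx] <- decay$plateau +
      (theta0[idx] - decay$plateau) * exp(-decay$rate * tt)
    th
  }, numeric(length(theta0)))
  theta <- matrix(theta, nrow = length(theta0),
                  dimnames = list(names(theta0), paste0("t", times, "h")))
  cfg <- config
  cfg@theta <- theta
  simulatePeakReport(cfg)
}

#' Simulate calibration standards for the Wagner curve
#'
#' Generates (concentration, area) standards from a known log-quadratic
#' truth, \eqn{y = \exp(a_2 (\ln x)^2 + a_1 \ln x + a_0)}, with optional
#' multiplicative log-normal noise.
#'
#' @param coeffs named numeric `c(a0, a1, a2)`.
#' @param x positive concentration grid.
#' @param noise_cv multiplicative noise CV (0 = exact).
#' @param seed integer seed (optional).
#' @return data.frame with columns `conc` and `area`.
#' @export
simulateStandards <- function(coeffs, x, noise_cv = 0, seed = NULL) {
  stopifnot(all(c("a0", "a1", "a2") %in% names(coeffs)))
  if (any(x <= 0)) stop("concentration grid must be positive")
  lx <- log(x)
  y <- exp(coeffs[["a2"]] * lx^2 + coeffs[["a1"]] * lx + coeffs[["a0"]])
  .withSeed(seed, {
    y <- .applyNoise(y, noise_cv)
  })
  data.frame(conc = x, area = y)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", nrow(object@theta), "site(s) x",
      ncol(object@theta), "sample(s)\n")
  cat(sprintf("  noise CV %.3g; %d technical, %d biological replicates; seed %d\n",
              object@noise_cv, object@n_tech, object@n_bio, object@seed))
})
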