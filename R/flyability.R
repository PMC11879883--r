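#' Average technical replicates of charge-aggregated areas
#'
#' Sequential injections of one sample are technical replicates; their
#' charge-aggregated areas are averaged (arithmetic mean) before entering
#' the flyability calculation.
#'
#' @param areas data.frame or matrix with columns `I_P` and `I_pP`, one row
#'   per injection.
#' @return Named numeric `c(I_P = , I_pP = )`.
#' @examples
#' averageTechnicalReplicates(data.frame(I_P = c(90, 100, 110),
#'                                       I_pP = c(9, 10, 11)))
#' @export
averageTechnicalReplicates <- function(areas) {
  areas <- as.data.frame(areas)
  stopifnot(all(c("I_P", "I_pP") %in% names(areas)), nrow(areas) >= 1L)
  c(I_P = mean(areas$I_P), I_pP = mean(areas$I_pP))
}

#' Compute the flyability ratio of a cognate peptide pair
#'
#' The flyability ratio \eqn{k} normalises the different ionization and
#' detection efficiencies of a phosphopeptide and its dephosphorylated
#' cognate.  It is calibrated from two samples of identical peptide amount:
#' sample A with low phosphorylation (phosphatase treated) and sample B with
#' high phosphorylation (untreated),
#' \deqn{k = \frac{|I_{P,A} - I_{P,B}|}{|I_{pP,A} - I_{pP,B}|}.}
#' The magnitude of the area differences is used; the physically expected
#' direction (the dephospho area rises while the phospho area falls on
#' dephosphorylation) is verified separately, and a pair violating it is
#' rejected as not a valid dephosphorylation pair.
#'
#' @param A,B either a named numeric `c(I_P = , I_pP = )` of
#'   replicate-averaged areas, or a data.frame of technical-replicate areas
#'   (columns `I_P`, `I_pP`) which is averaged with
#'   [averageTechnicalReplicates()]; A is the low-, B the
#'   high-phosphorylation sample.
#' @param site_label label carried onto the result.
#' @param tol relative tolerance on the denominator: the phospho-area
#'   difference must exceed `tol * max(I_pP_A, I_pP_B)`, otherwise the
#'   calibration is uninformative.
#' @return A [FlyabilityCalibration-class].
#' @examples
#' computeFlyability(c(I_P = 58, I_pP = 0), c(I_P = 0, I_pP = 100))  # k = 0.58
#' @export
computeFlyability <- function(A, B, site_label = "", tol = 1e-6) {
  spread <- NA_real_
  n_tech <- c(A = 1L, B = 1L)
  norm <- function(x, which) {
    if (is.data.frame(x) || is.matrix(x)) {
      x <- as.data.frame(x)
      n_tech[[which]] <<- nrow(x)
      cv <- function(v) if (mean(v) > 0 && nrow(x) > 1L) sd(v) / mean(v) else 0
      spread <<- max(spread, cv(x$I_P), cv(x$I_pP), na.rm = TRUE)
      averageTechnicalReplicates(x)
    } else {
      stopifnot(all(c("I_P", "I_pP") %in% names(x)))
      x[c("I_P", "I_pP")]
    }
  }
  A <- norm(A, "A"); B <- norm(B, "B")
  dP  <- A[["I_P"]]  - B[["I_P"]]
  dpP <- A[["I_pP"]] - B[["I_pP"]]
  if (abs(dpP) <= tol * max(A[["I_pP"]], B[["I_pP"]], tol))
    stop(site_label, ": no phospho-signal change between samples -- ",
         "calibration uninformative")
  sign_ok <- dP > 0 && dpP < 0
  if (!sign_ok)
    stop(site_label, ": area differences do not have the expected opposite ",
         "signs -- A/B samples are not a valid dephosphorylation pair")
  k <- abs(dP) / abs(dpP)
  if (!is.finite(k) || k <= 0)
    stop(site_label, ": non-positive or non-finite flyability ratio")
  new("FlyabilityCalibration", site_label = site_label, k = unname(k),
      inputs = list(A = A, B = B),
      diagnostics = list(sign_consistent = sign_ok, rel_spread = spread,
                         n_tech = n_tech))
}

#' Calibrate flyability ratios for a whole panel from an A/B sample pair
#'
#' Runs [computeFlyability()] for every site of the panel using a peak
#' report that contains a matched low-phosphorylation (A) and
#' high-phosphorylation (B) sample, each typically injected several times
#' (technical replicates, averaged).  Returns the panel with its
#' `flyability` column filled in.
#'
#' @param measurements peak report data.frame covering samples `sample_A`
#'   and `sample_B`.
#' @param panel a [TargetPanel-class].
#' @param sample_A,sample_B sample labels of the low- and
#'   high-phosphorylation calibration samples.
#' @param mode charge combination mode, see [aggregateChargeAreas()].
#' @return A list with elements `panel` (the calibrated
#'   [TargetPanel-class]) and `calibrations` (named list of
#'   [FlyabilityCalibration-class] objects).
#' @export
calibrateFlyability <- function(measurements, panel, sample_A, sample_B,
                                mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  measurements <- .validatePeakReport(measurements)
  stopifnot(is(panel, "TargetPanel"))
  t <- panel@targets
  calibs <- list()
  for (i in seq_len(nrow(t))) {
    techTable <- function(sample_id) {
      sel <- .selectSpecies(measurements$species, t$dephos[i],
                            t$site_label[i]) |
             .selectSpecies(measurements$species, t$phos[i], t$site_label[i])
      reps <- sort(unique(measurements$replicate[
        measurements$sample == sample_id & sel]))
      if (!length(reps))
        stop("site ", t$site_label[i], ": no measurements for calibration ",
             "sample ", sample_id)
      do.call(rbind, lapply(reps, function(r)
        as.data.frame(as.list(aggregateChargeAreas(
          measurements, t[i, , drop = FALSE], sample_id, r, mode = mode)))))
    }
    calibs[[t$site_label[i]]] <-
      computeFlyability(techTable(sample_A), techTable(sample_B),
                        site_label = t$site_label[i])
  }
  t$flyability <- vapply(calibs[t$site_label], function(x) x@k, numeric(1))
  list(panel = new("TargetPanel", targets = t), calibrations = calibs)
}

#' Flyability ratio of a calibration
#' @param x a [FlyabilityCalibration-class].
#' @return The ratio `k`.
#' @export
flyabilityK <- function(x) {
  stopifnot(is(x, "FlyabilityCalibration"))
  x@k
}

setMethod("show", "FlyabilityCalibration", function(object) {
  cat("FlyabilityCalibration", object@site_label,
      sprintf(": k = %.4f\n", object@k))
  cat(sprintf("  A (low):  I_P = %.4g, I_pP = %.4g\n",
              object@inputs$A[["I_P"]], object@inputs$A[["I_pP"]]))
  cat(sprintf("  B (high): I_P = %.4g, I_pP = %.4g\n",
              object@inputs$B[["I_P"]], object@inputs$B[["I_pP"]]))
  d <- object@diagnostics
  cat(sprintf("  sign consistent: %s; technical spread (max CV): %s\n",
              d$sign_consistent,
              ifelse(is.na(d$rel_spread), "NA",
                     sprintf("%.3f", d$rel_spread))))
})
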