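#' Fit a Wagner log-quadratic calibration curve
#'
#' Least-squares fit of \eqn{\ln y = a_2 (\ln x)^2 + a_1 \ln x + a_0} to
#' calibration standards, the model of choice for LC-MS metabolite
#' calibration over wide concentration ranges.  The coefficient of
#' determination is computed on the log-transformed regression; a curve
#' with \eqn{R^2 \le 0.99} is flagged unusable (it can still be inspected,
#' but [invertWagner()] refuses it).
#'
#' @param standards data.frame with columns `conc` (x, concentration) and
#'   `area` (y, peak area), or two numeric vectors via `conc`/`area`.
#' @param conc,area alternative vector interface.
#' @return A [WagnerCurve-class].
#' @examples
#' x <- c(1, 10, 100, 1000)
#' y <- exp(3 + 1.2 * log(x) + 0.1 * log(x)^2)
#' fitWagner(conc = x, area = y)
#' @export
fitWagner <- function(standards = NULL, conc = NULL, area = NULL) {
  if (!is.null(standards)) {
    stopifnot(all(c("conc", "area") %in% names(standards)))
    conc <- standards$conc; area <- standards$area
  }
  if (length(unique(conc[conc > 0])) < 3L)
    stop("need at least 3 standards with distinct positive concentrations")
  if (any(conc <= 0) || any(area <= 0))
    stop("concentrations and areas must be positive")
  lx <- log(conc); ly <- log(area)
  fit <- lm(ly ~ lx + I(lx^2))
  cf <- coef(fit)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(fit$residuals^2) / sst
  new("WagnerCurve",
      coefficients = c(a0 = unname(cf[1]), a1 = unname(cf[2]),
                       a2 = unname(cf[3])),
      r_squared = r2, range = range(conc), usable = r2 > 0.99,
      n = length(conc))
}

#' Predicted peak area on a Wagner curve
#'
#' @param object a [WagnerCurve-class].
#' @param x concentrations (vectorised, positive).
#' @param ... unused.
#' @return Predicted areas \eqn{y = \exp(a_2 (\ln x)^2 + a_1 \ln x + a_0)}.
#' @export
setMethod("predict", "WagnerCurve", function(object, x, ...) {
  stopifnot(all(x > 0))
  cf <- object@coefficients
  lx <- log(x)
  exp(cf[["a2"]] * lx^2 + cf[["a1"]] * lx + cf[["a0"]])
})

#' Invert a Wagner calibration curve
#'
#' Solves \eqn{a_2 u^2 + a_1 u + (a_0 - \ln y) = 0} for \eqn{u = \ln x} and
#' returns \eqn{x = e^u} for the unique root inside the calibration range.
#' A near-zero quadratic term (|a2| < 1e-12) falls back to exact log-linear
#' inversion.  Extrapolation beyond the standards and ambiguous
#' (non-monotone) calibrations are errors.
#'
#' @param curve a usable [WagnerCurve-class].
#' @param y observed peak area (positive scalar).
#' @return Concentration `x`.
#' @export
invertWagner <- function(curve, y) {
  stopifnot(is(curve, "WagnerCurve"))
  if (!curve@usable)
    stop("calibration curve is unusable (R^2 <= 0.99)")
  if (length(y) != 1L || !is.finite(y) || y <= 0)
    stop("area y must be a single positive number")
  cf <- curve@coefficients
  lo <- log(curve@range[1]) - 1e-9
  hi <- log(curve@range[2]) + 1e-9
  if (abs(cf[["a2"]]) < 1e-12) {
    if (cf[["a1"]] == 0) stop("degenerate flat calibration curve")
    u <- (log(y) - cf[["a0"]]) / cf[["a1"]]
    if (u < lo || u > hi)
      stop("area outside the calibration range (no root in range)")
    return(exp(u))
  }
  disc <- cf[["a1"]]^2 - 4 * cf[["a2"]] * (cf[["a0"]] - log(y))
  if (disc < 0) stop("negative discriminant: area unreachable by the curve")
  roots <- (-cf[["a1"]] + c(-1, 1) * sqrt(disc)) / (2 * cf[["a2"]])
  inside <- roots[roots >= lo & roots <= hi]
  if (!length(inside))
    stop("no root inside the calibration range")
  if (length(unique(round(inside, 12))) > 1L)
    stop("ambiguous calibration: both roots inside the calibration range")
  exp(inside[1])
}

#' AMP/ATP and ADP/ATP ratios from a nucleotide panel
#'
#' @param conc named numeric with elements `AMP`, `ADP`, `ATP`
#'   (concentrations, same units).
#' @return Named numeric `c(AMP_ATP = , ADP_ATP = )`.
#' @examples
#' nucleotideRatios(c(AMP = 1, ADP = 2, ATP = 10))
#' @export
nucleotideRatios <- function(conc) {
  stopifnot(all(c("AMP", "ADP", "ATP") %in% names(conc)))
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (conc[["ATP"]] == 0) stop("ATP concentration is zero: ratios undefined")
  c(AMP_ATP = conc[["AMP"]] / conc[["ATP"]],
    ADP_ATP = conc[["ADP"]] / conc[["ATP"]])
}

#' Quantify adenine nucleotides in samples against calibration standards
#'
#' Fits one Wagner curve per nucleotide from the standards table, inverts
#' each sample's peak area on its nucleotide's curve, and reports
#' concentrations plus AMP/ATP and ADP/ATP ratios.
#'
#' @param standards data.frame `nucleotide,conc,area`.
#' @param samples data.frame `nucleotide,sample,area`.
#' @return data.frame with one row per sample: `sample`, `AMP`, `ADP`,
#'   `ATP`, `AMP_ATP`, `ADP_ATP`; the fitted curves are attached as
#'   attribute `curves` (named list of [WagnerCurve-class]).
#' @export
quantifyNucleotides <- function(standards, samples) {
  stopifnot(all(c("nucleotide", "conc", "area") %in% names(standards)),
            all(c("nucleotide", "sample", "area") %in% names(samples)))
  nts <- c("AMP", "ADP", "ATP")
  curves <- lapply(setNames(nts, nts), function(nt) {
    st <- standards[standards$nucleotide == nt, , drop = FALSE]
    if (!nrow(st)) stop("no standards for ", nt)
    fitWagner(st)
  })
  out <- list()
  for (smp in unique(samples$sample)) {
    conc <- vapply(nts, function(nt) {
      row <- samples[samples$sample == smp & samples$nucleotide == nt, ,
                     drop = FALSE]
      if (nrow(row) != 1L)
        stop("sample ", smp, ": expected exactly one ", nt, " area")
      invertWagner(curves[[nt]], row$area)
    }, numeric(1))
    r <- nucleotideRatios(conc)
    out[[length(out) + 1L]] <-
      data.frame(sample = smp, AMP = conc[["AMP"]], ADP = conc[["ADP"]],
                 ATP = conc[["ATP"]], AMP_ATP = r[["AMP_ATP"]],
                 ADP_ATP = r[["ADP_ATP"]], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "curves") <- curves
  res
}

setMethod("show", "WagnerCurve", function(object) {
  cf <- object@coefficients
  cat(sprintf("WagnerCurve: ln y = %.6g (ln x)^2 + %.6g ln x + %.6g\n",
              cf[["a2"]], cf[["a1"]], cf[["a0"]]))
  cat(sprintf("  R^2 = %.6f (%s), %d standards, range [%g, %g]\n",
              object@r_squared,
              if (object@usable) "usable" else "UNUSABLE: R^2 <= 0.99",
              object@n, object@range[1], object@range[2]))
})
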