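#' ModifiedPeptide: a peptide sequence with positioned mass modifications
#'
#' The analyte identity layer.  A peptide is an ordered string of one-letter
#' codes for the 20 standard amino acids; modifications are bracket groups
#' attached to the residue immediately preceding them in the source string
#' (e.g. `"S[+80]GTATPQR"` carries a phospho group on residue 1).  The
#' original bracket text is retained so that serialisation reproduces the
#' input byte for byte.
#'
#' @slot sequence single string of one-letter residue codes (no brackets).
#' @slot mods data.frame with columns `position` (1-based residue index),
#'   `delta` (mass shift, Da) and `label` (original bracket text).
#'
#' @seealso [parsePeptide()], [peptideString()], [monoisotopicMass()],
#'   [precursorMz()]
#' @export
setClass("ModifiedPeptide",
  representation(sequence = "character", mods = "data.frame"),
  prototype(sequence = "",
            mods = data.frame(position = integer(), delta = numeric(),
                              label = character())))

setValidity("ModifiedPeptide", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || is.na(object@sequence) ||
      !nzchar(object@sequence))
    msg <- c(msg, "sequence must be a single non-empty string")
  else {
    res <- strsplit(object@sequence, "", fixed = TRUE)[[1L]]
    bad <- setdiff(res, names(.AA_MONO))
    if (length(bad))
      msg <- c(msg, paste0("non-standard residue code(s): ",
                           paste(unique(bad), collapse = ", ")))
    m <- object@mods
    if (!all(c("position", "delta", "label") %in% names(m)))
      msg <- c(msg, "mods must have columns position, delta, label")
    else if (nrow(m) &&
             (any(m$position < 1L) || any(m$position > length(res))))
      msg <- c(msg, "mod position outside [1, peptide length]")
  }
  if (length(msg)) msg else TRUE
})

#' TargetPanel: the set of cognate phospho/dephospho peptide pairs to quantify
#'
#' One row per phosphosite.  Each phosphopeptide is paired with its cognate
#' dephosphorylated peptide (identical residue sequence, exactly one fewer
#' phospho group); positional isomers may share a dephospho peptide.  The
#' charges listed per site are the charge states whose EIC areas are combined
#' for quantification.  An optional flyability ratio `k` can be carried on
#' the panel (e.g. from a previous calibration on the same LC-MS platform).
#'
#' @slot targets data.frame with columns `site_label`, `isoform`, `dephos`,
#'   `phos` (peptide strings in the bracket dialect), `charges` (list column
#'   of integer vectors) and `flyability` (numeric, `NA` when uncalibrated).
#'
#' @seealso [targetPanel()], [readTargetPanel()], [defaultTargetPanel()]
#' @export
setClass("TargetPanel", representation(targets = "data.frame"))

setValidity("TargetPanel", function(object) {
  t <- object@targets
  need <- c("site_label", "isoform", "dephos", "phos", "charges", "flyability")
  if (!all(need %in% names(t)))
    return(paste("targets must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(t$site_label))
    return("duplicate site_label")
  for (i in seq_len(nrow(t))) {
    de <- tryCatch(parsePeptide(t$dephos[i]), error = function(e) e)
    ph <- tryCatch(parsePeptide(t$phos[i]), error = function(e) e)
    if (inherits(de, "error") || inherits(ph, "error"))
      return(paste0(t$site_label[i], ": unparseable peptide string"))
    if (de@sequence != ph@sequence)
      return(paste0(t$site_label[i],
                    ": phospho and dephospho sequences differ"))
    if (countPhospho(ph) != countPhospho(de) + 1L)
      return(paste0(t$site_label[i],
                    ": phospho form must carry exactly one more phospho group"))
    ch <- t$charges[[i]]
    if (!length(ch) || any(ch < 1L))
      return(paste0(t$site_label[i], ": charges must be positive and non-empty"))
    k <- t$flyability[i]
    if (!is.na(k) && (!is.finite(k) || k <= 0))
      return(paste0(t$site_label[i], ": flyability must be positive and finite"))
  }
  TRUE
})

#' FlyabilityCalibration: a calibrated flyability ratio with its inputs
#'
#' Result of calibrating the relative ionization/detection efficiency of a
#' cognate peptide pair from a low-phosphorylation (A, phosphatase-treated)
#' and a high-phosphorylation (B, untreated) sample of identical peptide
#' amount.  Holds the technical-replicate-averaged areas used and diagnostic
#' information.
#'
#' @slot site_label site identifier.
#' @slot k flyability ratio (positive, finite).
#' @slot inputs named list with elements `A` and `B`, each a named numeric
#'   vector `c(I_P = , I_pP = )` of replicate-averaged charge-aggregated
#'   areas.
#' @slot diagnostics named list: `sign_consistent` (logical; the dephospho
#'   area rose while the phospho area fell from B to A), `rel_spread`
#'   (largest coefficient of variation across technical replicates, `NA`
#'   when replicate-level areas were not supplied), `n_tech` (named integer,
#'   injections per sample).
#'
#' @seealso [computeFlyability()], [calibrateFlyability()]
#' @export
setClass("FlyabilityCalibration",
  representation(site_label = "character", k = "numeric",
                 inputs = "list", diagnostics = "list"))

setValidity("FlyabilityCalibration", function(object) {
  if (length(object@k) != 1L || !is.finite(object@k) || object@k <= 0)
    return("k must be a single positive finite number")
  if (!all(c("A", "B") %in% names(object@inputs)))
    return("inputs must contain elements A and B")
  for (s in c("A", "B")) {
    v <- object@inputs[[s]]
    if (!all(c("I_P", "I_pP") %in% names(v)))
      return(paste0("inputs$", s, " must be named c(I_P=, I_pP=)"))
  }
  TRUE
})

#' WagnerCurve: a log-quadratic calibration curve for LC-MS quantification
#'
#' Model \eqn{\ln y = a_2 (\ln x)^2 + a_1 \ln x + a_0} relating analyte
#' concentration \eqn{x} to peak area \eqn{y}, fitted to calibration
#' standards by least squares in log space.  A curve is usable only when the
#' coefficient of determination of that regression exceeds 0.99; inversion
#' is restricted to the concentration range spanned by the standards.
#'
#' @slot coefficients named numeric `c(a0, a1, a2)`.
#' @slot r_squared coefficient of determination of the log-space fit.
#' @slot range numeric length 2, `c(min, max)` concentration of standards.
#' @slot usable logical; `TRUE` iff `r_squared > 0.99`.
#' @slot n number of standards fitted.
#'
#' @seealso [fitWagner()], [invertWagner()]
#' @export
setClass("WagnerCurve",
  representation(coefficients = "numeric", r_squared = "numeric",
                 range = "numeric", usable = "logical", n = "integer"))

setValidity("WagnerCurve", function(object) {
  if (!all(c("a0", "a1", "a2") %in% names(object@coefficients)))
    return("coefficients must be named c(a0=, a1=, a2=)")
  if (length(object@range) != 2L || object@range[1] > object@range[2])
    return("range must be c(min, max) with min <= max")
  if (object@r_squared > 1 + 1e-12)
    return("r_squared cannot exceed 1")
  TRUE
})

#' SimulationConfig: the stated world for the synthetic peak-area generator
#'
#' Defines the ground truth from which synthetic peak-area reports are
#' generated: the target panel, true occupancy per site and sample, true
#' flyability per site, total peptide amount per site, how each species'
#' signal splits across its charge states, a multiplicative log-normal noise
#' level, and the replicate structure.
#'
#' @slot panel a [TargetPanel-class].
#' @slot theta numeric matrix of true occupancies in \[0, 1\]; rows = sites
#'   (named by `site_label`), columns = samples.
#' @slot flyability named positive numeric, true flyability per site.
#' @slot amount named positive numeric, total peptide amount per site
#'   (arbitrary area units).
#' @slot charge_fractions named list; per site, a numeric vector of fractions
#'   (one per charge in the panel's `charges`) summing to 1.
#' @slot noise_cv coefficient of variation of the multiplicative log-normal
#'   area noise, on the natural scale (0 = noiseless).
#' @slot n_tech technical injections per calibration sample.
#' @slot n_bio biological replicates per sample in the main report.
#' @slot seed integer RNG seed; identical seed and config give byte-identical
#'   output.
#'
#' @seealso [simulationConfig()], [simulatePeakReport()]
#' @export
setClass("SimulationConfig",
  representation(panel = "TargetPanel", theta = "matrix",
                 flyability = "numeric", amount = "numeric",
                 charge_fractions = "list", noise_cv = "numeric",
                 n_tech = "integer", n_bio = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  sites <- object@panel@targets$site_label
  th <- object@theta
  if (is.null(rownames(th)) || !setequal(rownames(th), sites))
    return("theta rows must be named by the panel's site labels")
  if (any(th < 0 | th > 1)) return("theta values must lie in [0, 1]")
  if (is.null(colnames(th)) || !length(colnames(th)))
    return("theta columns must be named by sample labels")
  if (!setequal(names(object@flyability), sites) ||
      any(object@flyability <= 0))
    return("flyability must be positive and named by site label")
  if (!setequal(names(object@amount), sites) || any(object@amount <= 0))
    return("amount must be positive and named by site label")
  for (s in sites) {
    fr <- object@charge_fractions[[s]]
    nch <- length(object@panel@targets$charges[[match(s, sites)]])
    if (length(fr) != nch || abs(sum(fr) - 1) > 1e-9 || any(fr < 0))
      return(paste0(s, ": charge fractions must be non-negative, one per ",
                    "charge, and sum to 1"))
  }
  if (object@noise_cv < 0) return("noise_cv must be >= 0")
  if (object@n_tech < 1L || object@n_bio < 1L)
    return("replicate counts must be >= 1")
  TRUE
})
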