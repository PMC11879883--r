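#' Construct a target panel of cognate peptide pairs
#'
#' @param site_label character, unique phosphosite labels (e.g.
#'   `"a1_S477"`).
#' @param dephos,phos peptide strings in the bracket dialect of
#'   [parsePeptide()]; `phos` must carry exactly one more phospho group than
#'   `dephos` on the identical residue sequence.
#' @param charges the charge states whose areas are combined per site:
#'   either a list of integer vectors or a character vector of `";"`-joined
#'   charges (e.g. `"2;3"`).
#' @param isoform optional protein/isoform annotation.
#' @param flyability optional flyability ratio per site (`NA` when
#'   uncalibrated).
#' @return A [TargetPanel-class].
#' @examples
#' targetPanel("S477", "SGTATPQR", "S[+80]GTATPQR", charges = "2")
#' @export
targetPanel <- function(site_label, dephos, phos, charges,
                        isoform = NA_character_, flyability = NA_real_) {
  if (is.character(charges))
    charges <- lapply(strsplit(charges, ";", fixed = TRUE),
                      function(x) as.integer(trimws(x)))
  if (!is.list(charges)) charges <- list(as.integer(charges))
  n <- length(site_label)
  t <- data.frame(site_label = as.character(site_label),
                  isoform = rep_len(as.character(isoform), n),
                  dephos = as.character(dephos),
                  phos = as.character(phos),
                  flyability = rep_len(as.numeric(flyability), n),
                  stringsAsFactors = FALSE)
  t$charges <- rep_len(charges, n)
  new("TargetPanel", targets = t[, c("site_label", "isoform", "dephos",
                                     "phos", "charges", "flyability")])
}

#' Read a target-definition table from CSV
#'
#' Expected columns: `site_label`, `dephos_peptide`, `phos_peptide`,
#' `charges_used` (`";"`-joined charge states), and optionally
#' `protein_isoform` and `flyability_k`.
#'
#' @param path CSV file path.
#' @return A [TargetPanel-class].
#' @seealso [writeTargetPanel()], [defaultTargetPanel()]
#' @export
readTargetPanel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("site_label", "dephos_peptide", "phos_peptide", "charges_used")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("target table is missing column(s): ", paste(miss, collapse = ", "))
  targetPanel(site_label = df$site_label,
              dephos = df$dephos_peptide,
              phos = df$phos_peptide,
              charges = df$charges_used,
              isoform = if ("protein_isoform" %in% names(df))
                df$protein_isoform else NA_character_,
              flyability = if ("flyability_k" %in% names(df))
                as.numeric(df$flyability_k) else NA_real_)
}

#' Write a target panel to CSV
#'
#' Emits the same schema read by [readTargetPanel()], including the
#' `flyability_k` column, so a panel augmented by [calibrateFlyability()]
#' round-trips.
#'
#' @param panel a [TargetPanel-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTargetPanel <- function(panel, path) {
  stopifnot(is(panel, "TargetPanel"))
  t <- panel@targets
  out <- data.frame(site_label = t$site_label,
                    protein_isoform = t$isoform,
                    dephos_peptide = t$dephos,
                    phos_peptide = t$phos,
                    charges_used = vapply(t$charges, paste,
                                          character(1), collapse = ";"),
                    flyability_k = t$flyability,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The AMPK phosphosite target panel shipped with the package
#'
#' The 19-site panel of cognate tryptic peptide pairs covering regulatory
#' phosphosites across the AMPK alpha1/alpha2, beta1/beta2 and gamma2/gamma3
#' subunit isoforms, with the charge states used for quantification, the
#' published precursor m/z of the dominant charge state for each form, and
#' platform-specific flyability ratios determined on the original LC-MS
#' system.  Positional isomers (alpha1 S477/T481, alpha2 S481/T485) share a
#' dephospho peptide.
#'
#' @param full if `TRUE`, return the underlying data.frame (including the
#'   published reference m/z columns) instead of a [TargetPanel-class].
#' @return A [TargetPanel-class], or a data.frame when `full = TRUE`.
#' @examples
#' defaultTargetPanel()
#' @export
defaultTargetPanel <- function(full = FALSE) {
  path <- system.file("extdata", "ampk_targets.csv", package = "phosFly",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (full) return(df)
  targetPanel(site_label = df$site_label,
              dephos = df$dephos_peptide,
              phos = df$phos_peptide,
              charges = df$charges_used,
              isoform = df$protein_isoform,
              flyability = df$flyability_k)
}

#' Site labels of a target panel
#' @param panel a [TargetPanel-class].
#' @return Character vector of site labels.
#' @export
siteLabels <- function(panel) {
  stopifnot(is(panel, "TargetPanel"))
  panel@targets$site_label
}

#' Target table of a panel
#' @param panel a [TargetPanel-class].
#' @return The underlying data.frame (one row per site; `charges` is a list
#'   column).
#' @export
panelTargets <- function(panel) {
  stopifnot(is(panel, "TargetPanel"))
  panel@targets
}

setMethod("show", "TargetPanel", function(object) {
  t <- object@targets
  cat("TargetPanel with", nrow(t), "site(s)\n")
  nk <- sum(!is.na(t$flyability))
  cat("  flyability calibrated for", nk, "site(s)\n")
  utils::head(t[, c("site_label", "isoform", "dephos", "phos")], 5) |> print()
  if (nrow(t) > 5) cat("  ...\n")
})
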