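# Long-format peak-area reports.  One row = one EIC peak area for a
# (species, charge, sample, replicate) combination, as exported from vendor
# quantification tools.  Kept as a validated plain data.frame (the natural
# container for a long report); the S4 layer sits on the identity and result
# objects.

.PEAK_COLS <- c("species", "charge", "sample", "replicate", "area")

.validatePeakReport <- function(df) {
  miss <- setdiff(.PEAK_COLS, names(df))
  if (length(miss))
    stop("peak report is missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(df$area)) || any(df$area < 0))
    stop("peak areas must be non-negative and non-missing")
  if (any(df$charge < 1))
    stop("charges must be positive integers")
  key <- paste(df$species, df$charge, df$sample, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate peak report key: species=", d$species, " charge=",
         d$charge, " sample=", d$sample, " replicate=", d$replicate)
  }
  df$charge <- as.integer(df$charge)
  df$replicate <- as.integer(df$replicate)
  df
}

#' Read a long-format peak-area report
#'
#' CSV schema: `species,charge,sample,replicate,area[,rt_min]`.  `species`
#' is a peptide string in the bracket dialect, optionally suffixed with
#' `"#tag"` to disambiguate co-eluting positional isomers; `rt_min` is an
#' optional retention time in minutes.  The (species, charge, sample,
#' replicate) key must be unique and all areas non-negative.
#'
#' @param path CSV file path.
#' @return A validated data.frame with the columns above.
#' @seealso [writePeakReport()], [simulatePeakReport()]
#' @export
readPeakReport <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .validatePeakReport(df)
}

#' Write a peak-area report to CSV
#'
#' @param report a peak report data.frame (see [readPeakReport()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePeakReport <- function(report, path) {
  report <- .validatePeakReport(report)
  write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# species string helpers: an optional "#tag" suffix disambiguates species
# with identical peptide strings
.speciesPeptide <- function(species) sub("#.*$", "", species)
.speciesTag <- function(species) {
  tag <- rep("", length(species))
  has <- grepl("#", species, fixed = TRUE)
  tag[has] <- sub("^[^#]*#", "", species[has])
  tag
}

# Select the report rows measuring `target` for a given site.  A target with
# an explicit tag matches only that tag; otherwise rows tagged with the site
# label are preferred, then untagged rows, then a single unambiguous foreign
# tag.
.selectSpecies <- function(species, target, site_label = "") {
  same <- .speciesPeptide(species) == .speciesPeptide(target)
  tags <- .speciesTag(species)
  tt <- .speciesTag(target)
  if (nzchar(tt)) return(same & tags == tt)
  if (any(same & tags == site_label) && nzchar(site_label))
    return(same & tags == site_label)
  if (any(same & tags == "")) return(same & tags == "")
  utags <- unique(tags[same])
  if (length(utags) == 1L) return(same)
  same & FALSE
}

.phosphoCount <- function(species) {
  vapply(.speciesPeptide(species),
         function(s) countPhospho(parsePeptide(s, permissive = TRUE)),
         integer(1), USE.NAMES = FALSE)
}

#' Aggregate EIC areas across the charge states used for quantification
#'
#' For one cognate pair, one sample and one replicate, combines the areas of
#' the charge states listed on the panel into a single dephospho area
#' \eqn{I_P} and phospho area \eqn{I_{pP}}.  The default combination is the
#' sum across charges, which uses all collected signal; `"mean"` is
#' available as an alternative convention.  A charge listed but not observed
#' contributes 0 and raises a warning; a species with no observed charge at
#' all is an error.
#'
#' @param measurements peak report data.frame.
#' @param pair one-row subset of a panel's target table (see
#'   [panelTargets()]), or a [TargetPanel-class] with a single site.
#' @param sample_id,replicate which sample/replicate to aggregate.
#' @param mode `"sum"` (default) or `"mean"` across observed charges.
#' @return Named numeric `c(I_P = , I_pP = )`.
#' @export
aggregateChargeAreas <- function(measurements, pair, sample_id, replicate,
                                 mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (is(pair, "TargetPanel")) {
    stopifnot(nrow(pair@targets) == 1L)
    pair <- pair@targets
  }
  charges <- pair$charges[[1L]]
  site <- if ("site_label" %in% names(pair)) pair$site_label[1L] else ""
  one <- function(species) {
    m <- measurements[.selectSpecies(measurements$species, species, site) &
                      measurements$sample == sample_id &
                      measurements$replicate == replicate, , drop = FALSE]
    obs <- m$charge[m$charge %in% charges]
    if (!length(obs))
      stop("no signal for species ", species, " (sample ", sample_id,
           ", replicate ", replicate, ") at any used charge")
    missing_z <- setdiff(charges, obs)
    if (length(missing_z))
      warning("species ", species, ": charge(s) ",
              paste(missing_z, collapse = ","),
              " not observed in sample ", sample_id, " replicate ",
              replicate, "; contributing 0", call. = FALSE)
    areas <- m$area[m$charge %in% charges]
    if (mode == "sum") sum(areas) else mean(c(areas, rep(0, length(missing_z))))
  }
  c(I_P = one(pair$dephos), I_pP = one(pair$phos))
}

#' Screen detected phosphospecies of one base peptide
#'
#' Applies the multi-species rules to all phosphorylated species sharing one
#' base peptide: mono-phosphorylated positional isomers (distinguishable by
#' retention time in the underlying data) are all retained as independently
#' quantifiable species; a di- (or higher) phosphopeptide whose total area
#' is below `threshold` (default 10\%) of the largest mono-phospho species
#' is too scarce to quantify and is excluded; one at or above the threshold
#' is retained but flagged for review.
#'
#' @param species_areas data.frame with columns `species` (bracket-dialect
#'   strings sharing a residue sequence) and `area` (summed area per
#'   species).
#' @param threshold di-phospho exclusion threshold relative to the largest
#'   mono-phospho species' area.
#' @return A data.frame (the screen report) with columns `species`,
#'   `n_phospho`, `area`, `status` (`"retained"`, `"excluded"` or
#'   `"needs_review"`) and `reason`.
#' @export
screenPhosphospecies <- function(species_areas, threshold = 0.10) {
  stopifnot(is.data.frame(species_areas),
            all(c("species", "area") %in% names(species_areas)),
            threshold > 0, threshold < 1)
  np <- .phosphoCount(species_areas$species)
  if (!any(np == 1L))
    stop("no mono-phospho species present; nothing to screen against")
  ref <- max(species_areas$area[np == 1L])
  status <- rep("retained", nrow(species_areas))
  reason <- rep("", nrow(species_areas))
  multi <- which(np >= 2L)
  for (i in multi) {
    if (species_areas$area[i] < threshold * ref) {
      status[i] <- "excluded"
      reason[i] <- sprintf("<%d%% of mono-phospho signal",
                           round(100 * threshold))
    } else {
      status[i] <- "needs_review"
      reason[i] <- sprintf(">=%d%% of mono-phospho signal: check identity",
                           round(100 * threshold))
    }
  }
  data.frame(species = species_areas$species, n_phospho = np,
             area = species_areas$area, status = status, reason = reason,
             stringsAsFactors = FALSE)
}

#' Assemble cognate phospho/dephospho area pairs
#'
#' Builds the quantification table: one row per (site, sample, replicate)
#' with the charge-aggregated dephospho area \eqn{I_P} and phospho area
#' \eqn{I_{pP}}.  Positional isomers that share a dephospho peptide (e.g.
#' two phosphosites on one tryptic peptide) each get their own row reusing
#' the same \eqn{I_P}.
#'
#' @param measurements peak report data.frame.
#' @param panel a [TargetPanel-class] (only sites whose species appear in
#'   the report are paired; a site entirely absent is skipped with a
#'   warning).
#' @param mode charge combination mode, see [aggregateChargeAreas()].
#' @return data.frame with columns `site_label`, `sample`, `replicate`,
#'   `I_P`, `I_pP`.
#' @export
pairCognates <- function(measurements, panel, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  measurements <- .validatePeakReport(measurements)
  stopifnot(is(panel, "TargetPanel"))
  t <- panel@targets
  out <- list()
  for (i in seq_len(nrow(t))) {
    sel <- .selectSpecies(measurements$species, t$dephos[i],
                          t$site_label[i]) |
           .selectSpecies(measurements$species, t$phos[i], t$site_label[i])
    sub <- measurements[sel, , drop = FALSE]
    if (!nrow(sub)) {
      warning("site ", t$site_label[i], ": no species in report; skipped",
              call. = FALSE)
      next
    }
    if (sum(sub$area) == 0)
      stop("no signal for site ", t$site_label[i],
           ": all cognate areas are zero")
    combos <- unique(sub[, c("sample", "replicate")])
    combos <- combos[order(combos$sample, combos$replicate), , drop = FALSE]
    for (j in seq_len(nrow(combos))) {
      areas <- aggregateChargeAreas(sub, t[i, , drop = FALSE],
                                    combos$sample[j], combos$replicate[j],
                                    mode = mode)
      out[[length(out) + 1L]] <-
        data.frame(site_label = t$site_label[i],
                   sample = combos$sample[j],
                   replicate = combos$replicate[j],
                   I_P = unname(areas["I_P"]), I_pP = unname(areas["I_pP"]),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    stop("no panel species found in the peak report")
  do.call(rbind, out)
}
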