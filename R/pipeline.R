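#' Run the full occupancy pipeline
#'
#' Orchestrates the stages: validate the peak report, screen multiply
#' phosphorylated species, obtain flyability ratios (by calibrating from a
#' matched A/B sample pair when one is given, otherwise from the panel),
#' assemble cognate area pairs, compute per-replicate occupancies with
#' replicate summaries, and, when a control sample is designated, run
#' Dunnett many-to-one comparisons of every treatment against it.
#'
#' @param report peak report data.frame or CSV path (see
#'   [readPeakReport()]).
#' @param panel [TargetPanel-class] or target-table CSV path.
#' @param calibration_report optional peak report (or CSV path) holding the
#'   flyability calibration samples.
#' @param sample_A,sample_B labels of the low-/high-phosphorylation
#'   calibration samples inside `calibration_report` (both required when a
#'   calibration report is given).
#' @param control optional control sample label for treatment comparisons.
#' @param threshold di-phospho screening threshold (see
#'   [screenPhosphospecies()]).
#' @param charge_mode charge combination mode, see
#'   [aggregateChargeAreas()].
#' @param out_dir optional directory; when given, writes
#'   `stoichiometry.csv`, `comparisons.csv` (if computed),
#'   `calibration.csv` (the calibrated panel) and `run.log` into it.
#' @return list with `stoichiometry` (per site/sample table), `comparisons`
#'   (or `NULL`), `panel` (with flyability filled in), `screen` (species
#'   screening reports) and `log` (character vector of all messages and
#'   warnings).
#' @examples
#' cfg <- defaultSimulationConfig(seed = 7, noise_cv = 0)
#' sim <- simulatePeakReport(cfg)
#' res <- runPipeline(sim$report, defaultTargetPanel())
#' head(res$stoichiometry)
#' @export
runPipeline <- function(report, panel, calibration_report = NULL,
                        sample_A = NULL, sample_B = NULL, control = NULL,
                        threshold = 0.10, charge_mode = c("sum", "mean"),
                        out_dir = NULL) {
  charge_mode <- match.arg(charge_mode)
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  if (is.character(report)) report <- readPeakReport(report)
  report <- .validatePeakReport(report)
  if (is.character(panel)) panel <- readTargetPanel(panel)
  stopifnot(is(panel, "TargetPanel"))

  # --- screening: multiply phosphorylated species per base peptide -------
  screens <- list()
  baseSeq <- vapply(.speciesPeptide(unique(report$species)), function(s)
    parsePeptide(s, permissive = TRUE)@sequence, character(1))
  speciesSeq <- setNames(baseSeq, unique(report$species))
  for (bs in unique(baseSeq)) {
    sp <- names(speciesSeq)[speciesSeq == bs]
    np <- .phosphoCount(sp)
    if (!any(np >= 1L)) next
    if (!any(np == 1L)) {
      note("screen ", bs, ": phosphospecies present but no mono-phospho ",
           "species; site not quantifiable")
      next
    }
    areas <- vapply(sp, function(s)
      sum(report$area[report$species == s]), numeric(1))
    scr <- screenPhosphospecies(
      data.frame(species = sp, area = unname(areas),
                 stringsAsFactors = FALSE), threshold = threshold)
    screens[[bs]] <- scr
    for (i in which(scr$status != "retained"))
      note("screen ", bs, ": species ", scr$species[i], " ",
           scr$status[i], " (", scr$reason[i], ")")
    drop <- scr$species[scr$status == "excluded"]
    if (length(drop))
      report <- report[!(report$species %in% drop), , drop = FALSE]
  }

  # --- flyability --------------------------------------------------------
  calibrations <- NULL
  if (!is.null(calibration_report)) {
    if (is.null(sample_A) || is.null(sample_B))
      stop("calibration requires both sample_A (low) and sample_B (high)")
    if (is.character(calibration_report))
      calibration_report <- readPeakReport(calibration_report)
    cal <- calibrateFlyability(calibration_report, panel, sample_A,
                               sample_B, mode = charge_mode)
    panel <- cal$panel
    calibrations <- cal$calibrations
    note("calibrated flyability for ", length(calibrations), " site(s)")
  }
  kvec <- setNames(panel@targets$flyability, panel@targets$site_label)

  # --- pairing and occupancy --------------------------------------------
  paired <- withCallingHandlers(
    pairCognates(report, panel, mode = charge_mode),
    warning = function(w) {
      log <<- c(log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  present <- unique(paired$site_label)
  missing_k <- present[is.na(kvec[present])]
  if (length(missing_k))
    stop("no flyability ratio for site(s) ",
         paste(missing_k, collapse = ", "),
         ": supply calibration samples or a panel flyability_k column")
  stoich <- siteStoichiometryTable(paired, kvec)
  note("computed occupancies for ", length(present), " site(s), ",
       length(unique(stoich$sample)), " sample(s)")

  # --- comparisons -------------------------------------------------------
  comparisons <- NULL
  if (!is.null(control)) {
    if (!control %in% stoich$sample)
      stop("control sample \"", control, "\" absent from the report")
    comparisons <- compareToControl(stoich, control)
    note("Dunnett comparisons vs ", control, ": ",
         nrow(comparisons), " comparison(s)")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeStoichiometryTable(stoich, file.path(out_dir, "stoichiometry.csv"))
    writeTargetPanel(panel, file.path(out_dir, "calibration.csv"))
    if (!is.null(comparisons))
      write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                row.names = FALSE, quote = FALSE)
    writeLines(log, file.path(out_dir, "run.log"))
  }
  list(stoichiometry = stoich, comparisons = comparisons, panel = panel,
       screen = screens, log = log)
}
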