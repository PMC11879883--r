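#' Flyability-corrected phosphosite occupancy
#'
#' The core occupancy model: given the charge-aggregated EIC areas of a
#' phosphopeptide (\eqn{I_{pP}}) and its dephosphorylated cognate
#' (\eqn{I_P}) and the pair's flyability ratio \eqn{k},
#' \deqn{Occupancy(\%) = 100 \cdot \frac{k\,I_{pP}}{k\,I_{pP} + I_P}.}
#' The result is intrinsically bounded in \[0, 100\]: no clipping is
#' applied, so an out-of-range value would indicate a bug upstream.
#'
#' @param I_pP,I_P non-negative areas (vectorised; not both zero).
#' @param k positive flyability ratio (scalar or vectorised).
#' @return Occupancy in percent.
#' @examples
#' computeStoichiometry(I_pP = 30, I_P = 40, k = 2)   # 60
#' computeStoichiometry(I_pP = 50, I_P = 50, k = 1)   # 50
#' @export
computeStoichiometry <- function(I_pP, I_P, k) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("k must be positive and finite")
  if (any(I_pP < 0) || any(I_P < 0)) stop("areas must be non-negative")
  if (any(I_pP + I_P == 0)) stop("no signal: both cognate areas are zero")
  100 * k * I_pP / (k * I_pP + I_P)
}

#' Mean, SEM and n of replicate values
#'
#' @param values numeric vector (biological replicate occupancies, or any
#'   replicate-level quantity).
#' @return list with `mean`, `sem` (sample SD over `sqrt(n)`; `NA` when a
#'   single value gives no spread estimate) and `n`.
#' @examples
#' summarizeMeanSem(c(2, 4))   # mean 3, sem 1
#' @export
summarizeMeanSem <- function(values) {
  if (!length(values)) stop("no values to summarise")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1L) sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Per-site, per-sample occupancy table with replicate summaries
#'
#' Applies the occupancy model independently to every biological replicate
#' (each replicate's areas give one occupancy; replicates are then
#' summarised as mean +/- SEM), using each site's flyability ratio from the
#' calibrated panel or a named vector.
#'
#' @param paired data.frame from [pairCognates()] (columns `site_label`,
#'   `sample`, `replicate`, `I_P`, `I_pP`).
#' @param k flyability ratios: a calibrated [TargetPanel-class] or a named
#'   numeric vector keyed by site label.  Every site in `paired` must have
#'   a positive ratio.
#' @return data.frame with one row per (site, sample): `site_label`,
#'   `sample`, `n`, `mean_pct`, `sem_pct`, `k_used`, and a list column
#'   `replicate_pct` of the per-replicate occupancies.
#' @export
siteStoichiometryTable <- function(paired, k) {
  stopifnot(all(c("site_label", "sample", "replicate", "I_P", "I_pP")
                %in% names(paired)))
  if (is(k, "TargetPanel"))
    k <- setNames(k@targets$flyability, k@targets$site_label)
  sites <- unique(paired$site_label)
  missing_k <- sites[!(sites %in% names(k)) | is.na(k[sites])]
  if (length(missing_k))
    stop("no flyability ratio for site(s): ",
         paste(missing_k, collapse = ", "))
  out <- list()
  for (s in sites) {
    for (smp in unique(paired$sample[paired$site_label == s])) {
      sub <- paired[paired$site_label == s & paired$sample == smp, ,
                    drop = FALSE]
      occ <- computeStoichiometry(sub$I_pP, sub$I_P, k[[s]])
      sm <- summarizeMeanSem(occ)
      row <- data.frame(site_label = s, sample = smp, n = sm$n,
                        mean_pct = sm$mean, sem_pct = sm$sem,
                        k_used = unname(k[[s]]), stringsAsFactors = FALSE)
      row$replicate_pct <- list(occ)
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Write a stoichiometry table to CSV
#'
#' Schema: `site,sample,n,mean_pct,sem_pct,replicate_values` with the
#' replicate occupancies `";"`-joined.
#'
#' @param tab output of [siteStoichiometryTable()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeStoichiometryTable <- function(tab, path) {
  out <- data.frame(site = tab$site_label, sample = tab$sample, n = tab$n,
                    mean_pct = tab$mean_pct, sem_pct = tab$sem_pct,
                    replicate_values = vapply(tab$replicate_pct, function(v)
                      paste(format(v, digits = 10, trim = TRUE),
                            collapse = ";"), character(1)),
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
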