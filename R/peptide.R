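#' Parse a bracket-annotated peptide string
#'
#' Parses the modification dialect used in targeted-proteomics panels:
#' one-letter residue codes, each optionally followed by a bracket group
#' `"[<sign><integer>]"` that modifies the residue immediately before it.
#' Recognised labels are `"+80"` (phospho, +79.96633 Da) and `"-1"` (loss of
#' one hydrogen atom, -1.0078250319 Da, as in a cysteine engaged in an
#' intramolecular disulfide).  Both the Unicode minus and the ASCII hyphen
#' are accepted in labels; the original text is retained so that
#' [peptideString()] reproduces the input exactly.
#'
#' @param s peptide string, e.g. `"S[+80]GTATPQR"`.
#' @param permissive if `TRUE`, an unrecognised bracket label is retained
#'   with its literal integer value (in Da) as the mass delta instead of
#'   raising an error.
#' @return A [ModifiedPeptide-class] object.
#' @examples
#' p <- parsePeptide("S[+80]GTATPQR")
#' peptideString(p)
#' monoisotopicMass(p)
#' @export
parsePeptide <- function(s, permissive = FALSE) {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop("peptide string must be a single character value")
  if (!nzchar(s)) stop("empty peptide string")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  residues <- character()
  pos <- integer(); delta <- numeric(); label <- character()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      if (!length(residues))
        stop("bracket modification before any residue at position ", i)
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket starting at position ", i)
      lab <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      norm <- gsub("−", "-", lab)
      if (!grepl("^[+-][0-9]+$", norm))
        stop("malformed bracket label \"", lab, "\" at position ", i)
      if (norm %in% names(.KNOWN_MODS)) {
        d <- unname(.KNOWN_MODS[norm])
      } else if (permissive) {
        d <- as.numeric(norm)
      } else {
        stop("unknown modification label \"", lab,
             "\" (use permissive = TRUE to accept its literal value)")
      }
      pos <- c(pos, length(residues))
      delta <- c(delta, d)
      label <- c(label, lab)
      i <- j + 1L
    } else if (ch %in% names(.AA_MONO)) {
      residues <- c(residues, ch)
      i <- i + 1L
    } else {
      stop("invalid character \"", ch, "\" at position ", i)
    }
  }
  if (!length(residues)) stop("no residues in peptide string")
  new("ModifiedPeptide",
      sequence = paste(residues, collapse = ""),
      mods = data.frame(position = pos, delta = delta, label = label,
                        stringsAsFactors = FALSE))
}

#' Serialise a ModifiedPeptide back to its bracket string
#'
#' Inverse of [parsePeptide()]: re-emits the residue sequence with each
#' modification's original bracket text after its residue, reproducing the
#' parsed input byte for byte.
#'
#' @param p a [ModifiedPeptide-class].
#' @return A single character string.
#' @export
peptideString <- function(p) {
  stopifnot(is(p, "ModifiedPeptide"))
  res <- strsplit(p@sequence, "", fixed = TRUE)[[1L]]
  out <- res
  m <- p@mods
  if (nrow(m)) {
    # several mods on one residue keep their original order
    for (i in seq_len(nrow(m)))
      out[m$position[i]] <- paste0(out[m$position[i]], "[", m$label[i], "]")
  }
  paste(out, collapse = "")
}

#' Monoisotopic mass of a (modified) peptide
#'
#' Sum of the standard residue monoisotopic masses, one water (the peptide
#' termini), and all modification deltas.
#'
#' @param p a [ModifiedPeptide-class] or a peptide string (parsed with the
#'   default, non-permissive settings).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopicMass("SGTATPQR")
#' @export
monoisotopicMass <- function(p) {
  if (is.character(p)) p <- parsePeptide(p)
  stopifnot(is(p, "ModifiedPeptide"))
  res <- strsplit(p@sequence, "", fixed = TRUE)[[1L]]
  sum(.AA_MONO[res]) + .MASS_WATER + sum(p@mods$delta)
}

#' Precursor m/z of a protonated peptide
#'
#' \eqn{m/z = (M + z \cdot m_{proton}) / z} with the bare proton mass
#' 1.00727646688 Da.
#'
#' @param p a [ModifiedPeptide-class] or a peptide string.
#' @param z positive integer charge.
#' @return Precursor m/z.
#' @examples
#' precursorMz("SGTATPQR", 2)       # 409.2118
#' precursorMz("S[+80]GTATPQR", 2)  # 449.1949
#' @export
precursorMz <- function(p, z) {
  if (length(z) != 1L || is.na(z) || z != as.integer(z) || z < 1)
    stop("charge z must be a positive integer")
  (monoisotopicMass(p) + z * .MASS_PROTON) / z
}

#' Number of phospho groups on a peptide
#'
#' Counts modifications whose delta equals the phospho monoisotopic delta.
#' Used to classify species as dephosphorylated (0), mono-phospho (1) or
#' multiply phosphorylated.
#'
#' @param p a [ModifiedPeptide-class] or a peptide string.
#' @return Integer count.
#' @export
countPhospho <- function(p) {
  if (is.character(p)) p <- parsePeptide(p)
  stopifnot(is(p, "ModifiedPeptide"))
  sum(abs(p@mods$delta - .MASS_PHOSPHO) < 1e-9)
}

setMethod("show", "ModifiedPeptide", function(object) {
  cat("ModifiedPeptide:", peptideString(object), "\n")
  cat("  residues:", nchar(object@sequence),
      " mods:", nrow(object@mods),
      sprintf(" monoisotopic mass: %.5f Da\n", monoisotopicMass(object)))
})
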