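# Shared fixtures, built in code.

# one site on a short tryptic peptide, single charge
tinyPanel <- function(k = NA_real_) {
  targetPanel("S1", "SGTATPQR", "S[+80]GTATPQR", charges = "2",
              flyability = k)
}

# two positional isomers sharing a dephospho peptide
isomerPanel <- function() {
  targetPanel(c("S1", "T5"), rep("SGTATPQR", 2),
              c("S[+80]GTATPQR", "SGTAT[+80]PQR"), charges = c("2", "2"))
}

# n random quantifiable sites: peptide of random residues with a phospho
# Ser, two charge states, flyability and occupancy drawn from the stated
# ranges
randomSitePanel <- function(n, seed, theta_range = c(0.05, 0.95),
                            fly_range = c(0.5, 12)) {
  set.seed(seed)
  aa <- c("A", "G", "L", "V", "P", "T", "E", "D", "Q", "N", "F", "Y")
  dephos <- phos <- character(n)
  for (i in seq_len(n)) {
    body <- paste(sample(aa, 7, replace = TRUE), collapse = "")
    dephos[i] <- paste0("S", body, "R")
    phos[i] <- paste0("S[+80]", body, "R")
  }
  # random bodies can collide; regenerate any duplicated peptide
  while (anyDuplicated(dephos)) {
    i <- which(duplicated(dephos))[1]
    body <- paste(sample(aa, 8, replace = TRUE), collapse = "")
    dephos[i] <- paste0("S", body, "R")
    phos[i] <- paste0("S[+80]", body, "R")
  }
  labels <- sprintf("site%03d", seq_len(n))
  panel <- targetPanel(labels, dephos, phos,
                       charges = rep("2;3", n))
  list(panel = panel,
       theta = setNames(runif(n, theta_range[1], theta_range[2]), labels),
       flyability = setNames(runif(n, fly_range[1], fly_range[2]), labels))
}

# a small literal peak report
peakRow <- function(species, charge, sample, replicate, area) {
  data.frame(species = species, charge = charge, sample = sample,
             replicate = replicate, area = area, stringsAsFactors = FALSE)
}
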