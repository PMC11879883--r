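---
title: "Flyability-corrected phosphosite occupancy: model, calibration and validation"
author: "phosFly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flyability-corrected phosphosite occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosFly)
```

## The problem

Phosphorylation stoichiometry — the fraction of a protein population that
carries a phosphate on a given residue at a moment in time — is the quantity
that separates a trace modification from a regulatory switch, yet most
signalling studies report only relative phospho-signal changes.  Targeted
label-free LC-MS makes absolute occupancy accessible: after tryptic
digestion, a phosphopeptide and its unmodified ("dephospho") cognate share a
residue sequence and differ by one phospho group, so the ratio of their
extracted-ion-chromatogram (EIC) peak areas carries the occupancy — if the
two forms ionised equally well.  They do not: the phosphate changes
ionisation and detection efficiency, often severalfold.  This package
implements the corrected estimator and everything needed to apply and
validate it.

## The occupancy model

For a site with charge-aggregated phosphopeptide area $I_{pP}$ and cognate
dephosphopeptide area $I_P$, and a pair-specific flyability ratio $k$,

$$\mathrm{Occupancy}(\%) \;=\; 100\cdot\frac{k\,I_{pP}}{k\,I_{pP} + I_P}.$$

$k$ rescales the phosphopeptide signal into dephosphopeptide-equivalent
units; the estimator is intrinsically bounded in $[0,100]$, strictly
increasing in $I_{pP}$ and $k$, strictly decreasing in $I_P$, and reduces to
the naive area fraction at $k=1$.  `computeStoichiometry()` refuses rather
than clips out-of-range input, because the algebra cannot produce an
out-of-range output — one would signal corrupted areas.

Occupancy is computed **per biological replicate** and then summarised as
mean ± SEM (sample SD over $\sqrt n$), rather than averaging areas before
the ratio.  The two orders differ only at second order in the noise, but the
per-replicate order yields a replicate-level spread on the scale the ratio
is reported on, which is what the SEM and the group comparisons need.  The
alternative order is available by summarising areas upstream.

## Flyability calibration

$k$ is calibrated from two samples of identical total peptide amount that
differ only in phosphorylation: A, treated with a broad phosphatase (low
phosphorylation), and B, untreated (high phosphorylation):

$$k \;=\; \frac{\lvert I_{P,A} - I_{P,B}\rvert}{\lvert I_{pP,A} - I_{pP,B}\rvert}.$$

Two deliberate choices:

* **Magnitudes, with a separate direction check.**  Written as a signed
  ratio the expression is negative whenever A is the dephosphorylated
  sample (the dephospho area rises while the phospho area falls).  Reported
  flyability ratios are positive, so the implementation uses magnitudes and
  independently verifies the physical direction of change; a pair violating
  it is rejected with an error, not a warning, because a same-direction
  change means the two samples are not a dephosphorylation pair at all.
* **The difference form is kept even though the phosphatase treatment is
  typically complete.**  Differences cancel any residual phosphorylation in
  A exactly (the test suite demonstrates exact recovery at
  $\theta_A = 0.2$), so completeness is not assumed.

Technical replicates (sequential injections of the same sample) are
averaged arithmetically before the ratio; the largest injection-level CV is
kept as a diagnostic.  The denominator must exceed a relative tolerance
($10^{-6}$ of the larger phospho area), otherwise the pair is
"uninformative" — e.g. when A and B have the same phosphorylation level.

A consequence users should expect: **sites with very low occupancy in the
untreated material are hard to calibrate.**  The contrast
$\lvert I_{P,A}-I_{P,B}\rvert = \theta_B T$ shrinks with $\theta_B$, and at
measurement CVs around 10% a site near 5% occupancy has an appreciable
chance of a noise-induced direction flip, which the validity check turns
into an error.  This is a property of the experiment, not of the
implementation; the round-trip tests tolerate (and bound) exactly these
failures.

## Targeting layer

Peptides are written in a bracket dialect: `S[+80]GTATPQR` is the
phosphopeptide, `[+80]` mapping to the phospho monoisotopic delta
79.96633 Da (not literal 80), and `[-1]` mapping to the loss of one
hydrogen atom (−1.0078250319 Da), as for cysteines engaged in an
intramolecular disulfide.  Both the Unicode minus and the ASCII hyphen are
accepted, and parsing–serialising round-trips byte for byte.  Monoisotopic
mass is the sum of the standard residue masses plus one water plus the
modification deltas, and precursor m/z uses the **bare proton mass**
1.00727646688 Da, $(M + z\,m_p)/z$.  These constants are validated by
reproducing every published precursor m/z of the shipped 19-site AMPK panel
to within 0.001 at the dominant charge (most agree to ~5×10⁻⁵).

Charge states listed per site are combined by **summation** of areas before
any ratio — the convention that uses all collected signal and is
noise-optimal for approximately Poisson-scaled areas.  Averaging is
available via `mode = "mean"` for comparison with pipelines that use it.  A
listed-but-unobserved charge contributes zero with a logged warning, so
partial observations remain usable; a species with no observed charge is an
error.

Multiply phosphorylated species are screened per base peptide: mono-phospho
positional isomers are all retained (they are chromatographically
resolvable species, each quantified against the shared dephospho peptide);
a di-phospho species below 10% of the largest mono-phospho species' area is
excluded as unquantifiable; one at or above 10% is retained but flagged
`needs_review`, a conservative stand-in for a situation the original
protocol never had to resolve.  The threshold is evaluated against the
largest mono-phospho species when several exist.

## What the synthetic generator emulates — and what it does not

The generator inverts the occupancy model: a site with occupancy $\theta$,
flyability $f$ and total amount $T$ yields noise-free charge-split areas
$I_P = T(1-\theta)\cdot c_z$ and $I_{pP} = (T\theta/f)\cdot c_z$, so the
estimator with $k=f$ returns exactly $100\,\theta$ — the generative
convention the equations imply.  Noise is multiplicative log-normal
($\varepsilon\sim N(0,\sigma)$ with $\sigma=\sqrt{\ln(1+\mathrm{CV}^2)}$,
CV on the natural scale), reflecting that areas are positive with errors
scaling with signal.  Defaults state the emulated world once: the 19-site
panel structure with flyabilities spanning 0.58–12.22 and occupancies
spread over 4–96%, amount $10^6$ area units, CV 10%, 3 technical
injections, 3 biological replicates; identical seed and configuration give
byte-identical output without disturbing the caller's RNG stream.

Known non-realisms, hence what a green test does *not* establish:

* **Independent cognate pools for positional isomers.**  Two sites sharing
  a dephospho peptide are generated as independently tagged species
  (`SGTATPQR#a1_S477`) so the per-site identity $I_P = T(1-\theta)$ holds
  exactly.  In real data the shared peptide is one pool whose dephospho
  fraction is $1-\sum_j\theta_j$, and the pairwise estimator then reads
  $\theta_j/(\theta_j + 1 - \sum_j\theta_j)$ — a small upward bias that
  grows with the *other* isomer's occupancy.  The quantification layer
  handles the real, untagged case (both isomers reuse the one $I_P$); the
  generator simply does not simulate that coupling.
* No chromatography: retention times, peak shapes, interference and
  integration errors are out of scope; species identity is given.
* Noise is i.i.d. across species and charges; real runs share injection-
  and ionisation-level fluctuations that partially cancel in ratios, so the
  simulation is, if anything, pessimistic about ratio noise.

The time-course simulator relaxes occupancy exponentially,
$\theta(t) = p + (\theta_0-p)e^{-rt}$, which reproduces the qualitative
shape of a kinase-inhibitor-sensitive site (e.g. ~25% basal falling to
~11% at 1 h and ~3% at 4 h with $p=0.03$, $r\approx1.0\,h^{-1}$).  This is
shape-level emulation only: measured per-site stoichiometries depend on raw
MS data that is not publicly deposited and are deliberately not treated as
recoverable truth.

## Statistics

Group summaries are mean ± SEM; a single replicate reports SEM as
undefined (`NA`) rather than zero.  Treatment-vs-control testing is
one-way ANOVA with Dunnett's many-to-one comparisons: per treatment a
pooled-variance t statistic against the control, adjusted by the joint
distribution of the correlated family ($\mathrm{corr}(T_j,T_k)=b_jb_k$,
$b_j=\sqrt{n_j/(n_j+n_0)}$).  No suitable multivariate-t implementation is
available in the dependency set, so the distribution is evaluated directly
by Gauss–Legendre quadrature over the one-factor representation (shared
normal factor × pooled $\chi$ scale), accurate to ~10⁻⁸; a Monte-Carlo
resampling mode serves as an internal cross-check.  Anchors: with one
comparison the adjusted p equals the pooled t-test p exactly, and the
adjusted p can never fall below the raw p.  Occupancies are compared across
treatments within a site; no adjustment is made across sites.

## Nucleotide calibration

Adenine nucleotide quantification uses the Wagner log-quadratic model
$\ln y = a_2(\ln x)^2 + a_1\ln x + a_0$, fitted by least squares in log
space.  $R^2$ is computed in the space of the fit (log space) — the natural
reading, though unstated in common protocols — and a curve with
$R^2 \le 0.99$ is flagged unusable rather than discarded, so diagnostics
remain inspectable; inversion refuses unusable curves.  Inversion solves
the quadratic in $\ln x$ and accepts only a unique root within the
standards' concentration range: extrapolation is an error (quantification
outside the calibrated range is unreliable), and two in-range roots mean
the calibration is non-monotone and ambiguous.  $|a_2|<10^{-12}$ falls back
to exact log-linear inversion.  One practical note from the validation
suite: on a 3-decade standards grid the log-space signal variance is so
large that even 20% multiplicative noise essentially never drops $R^2$
below 0.99 — the gate bites on narrow calibration ranges, which is where it
is needed.

## Numerical and degenerate-input choices

* Occupancy errors on zero total signal ($I_{pP}+I_P=0$) and on $k\le 0$.
* Pooled t test: both groups constant and equal → $p=1$; constant and
  different → $p=0$.
* Dunnett quadrature: 96 nodes per dimension, normal factor truncated at
  ±9σ, scale integrated over the central $1-2\times10^{-14}$ mass of
  $\sqrt{\chi^2_\nu/\nu}$; `adj_p` is clamped to `[raw_p, 1]` so quadrature
  round-off can never violate the dominance property.
* Flyability denominator tolerance is relative ($10^{-6}$), so the test is
  scale-invariant, matching the scale-invariance of $k$ itself.
* Random-seed handling saves and restores the global RNG state.

## A worked example

```{r example, eval = FALSE}
panel <- defaultTargetPanel()
cfg <- defaultSimulationConfig(seed = 11)      # CV 10%
sim <- simulatePeakReport(cfg)
calib <- simulateCalibrationPair(cfg, "g3_S65")
res <- runPipeline(sim$report, panel)
head(res$stoichiometry[, c("site_label", "sample", "mean_pct", "sem_pct")])
```

## Limitations

Flyability ratios are platform-specific: a $k$ calibrated on one LC-MS
system does not transfer to another, so shipped panel values are usable
only as structural defaults for simulation, not for quantifying new data.
The pipeline starts at peak areas — peak picking, identification and
validation happen upstream.  Measured study values (per-site
stoichiometries, measured flyabilities, inhibitor effect sizes) are not
recoverable without the raw data and are covered here only by
property-based tests and structure-matched synthetic fixtures.
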