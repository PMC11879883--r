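# Treatment-vs-control statistics: pooled-variance unpaired t test and
# one-way ANOVA with Dunnett's many-to-one multiple-comparisons adjustment.
# Dunnett's multivariate-t distribution is evaluated by direct quadrature
# over its one-factor representation (no external dependency), with a
# resampling approximation available as a cross-check.

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method
.gaussLegendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1L, ]^2))
}

#' Distribution function of Dunnett's two-sided max-|t| statistic
#'
#' Probability that all of `m` jointly distributed t statistics comparing
#' treatment groups to a shared control stay within `[-q, q]` under the
#' null.  The statistics share the control mean and the pooled variance
#' estimate, giving the one-factor correlation structure
#' \eqn{corr(T_j, T_k) = b_j b_k} with
#' \eqn{b_j = \sqrt{n_j / (n_j + n_0)}}; the probability is evaluated by
#' Gauss-Legendre quadrature over the shared normal factor and the pooled
#' scale.
#'
#' @param q non-negative quantile.
#' @param b vector of factor loadings, one per comparison (all in (0, 1);
#'   balanced designs give `b = sqrt(1/2)` for every comparison).
#' @param df pooled error degrees of freedom.
#' @param nodes quadrature nodes per dimension.
#' @return `P(max_j |T_j| <= q)`.
#' @seealso [dunnettVsControl()]
#' @export
pDunnett <- function(q, b, df, nodes = 96L) {
  if (q <= 0) return(0)
  stopifnot(all(b > 0), all(b < 1), df >= 1)
  gl <- .gaussLegendre(nodes)
  # z: shared standard-normal factor on [-9, 9]
  z <- 9 * gl$nodes
  wz <- 9 * gl$weights * dnorm(z)
  # s: pooled scale sqrt(chi^2_df / df), integrated against its density on
  # the interval carrying all but ~1e-14 of its mass
  s_lo <- sqrt(qchisq(1e-14, df) / df)
  s_hi <- sqrt(qchisq(1e-14, df, lower.tail = FALSE) / df)
  half <- (s_hi - s_lo) / 2
  s <- s_lo + half * (gl$nodes + 1)
  ws <- half * gl$weights * 2 * df * s * stats::dchisq(df * s^2, df)
  sq <- sqrt(1 - b^2)
  inner <- vapply(s, function(si) {
    prod_j <- rep(1, length(z))
    for (j in seq_along(b)) {
      prod_j <- prod_j * (pnorm((q * si - b[j] * z) / sq[j]) -
                          pnorm((-q * si - b[j] * z) / sq[j]))
    }
    sum(wz * prod_j)
  }, numeric(1))
  min(1, max(0, sum(ws * inner)))
}

#' Two-sided critical value of Dunnett's max-|t| statistic
#'
#' @inheritParams pDunnett
#' @param alpha family-wise error rate.
#' @return The critical value `c` with `P(max_j |T_j| > c) = alpha`.
#' @export
qDunnett <- function(alpha, b, df, nodes = 96L) {
  uniroot(function(q) pDunnett(q, b, df, nodes) - (1 - alpha),
          lower = 1e-6, upper = 50, tol = 1e-8)$root
}

#' Unpaired two-sample t test (pooled variance)
#'
#' Classic two-sided unpaired t test with pooled variance.  Degenerate
#' inputs follow the conventions: both groups constant with equal means
#' gives `p = 1`; both constant with different means gives `p = 0`.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @return list with `t`, `df`, `p`.
#' @examples
#' unpairedT(c(1, 2, 3), c(4, 5, 6))
#' @export
unpairedT <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  diff <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (diff == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(diff) * Inf, df = df, p = 0))
  }
  t <- diff / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Compares each treatment group against a designated control: a one-way
#' ANOVA (pooled within-group variance) plus, per treatment, a two-sided t
#' statistic against the control and its Dunnett-adjusted p value, which
#' accounts for the family of correlated comparisons sharing the control
#' group.  The adjusted p is always at least the raw (unadjusted,
#' pooled-variance) p; with exactly two groups the adjustment degenerates
#' to the ordinary pooled t test.
#'
#' @param groups named list of numeric vectors (replicate values per
#'   sample); each group needs `n >= 2`.
#' @param control name of the control group in `groups`.
#' @param method `"integration"` evaluates the multivariate-t probability
#'   by quadrature (exact to quadrature accuracy); `"resampling"`
#'   approximates it by Monte-Carlo simulation of the null max-|t|
#'   distribution.
#' @param nboot resamples for `method = "resampling"`.
#' @return data.frame with one row per treatment: `treatment`,
#'   `mean_diff` (treatment minus control), `t`, `raw_p`, `adj_p`; ANOVA
#'   `F`, `df` and `p` are attached as attributes `anova_F`, `anova_df`,
#'   `anova_p`.
#' @examples
#' g <- list(ctrl = c(10, 11, 9), trtA = c(7, 8, 6), trtB = c(10, 10, 11))
#' dunnettVsControl(g, "ctrl")
#' @export
dunnettVsControl <- function(groups, control,
                             method = c("integration", "resampling"),
                             nboot = 100000L) {
  method <- match.arg(method)
  if (!control %in% names(groups))
    stop("control group \"", control, "\" not found")
  if (length(groups) < 2L) stop("need at least 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L))
    stop("every group needs n >= 2 (offending: ",
         paste(names(groups)[n < 2L], collapse = ", "), ")")
  k <- length(groups)
  N <- sum(n)
  df <- N - k
  means <- vapply(groups, mean, numeric(1))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  sp2 <- ss_within / df
  grand <- sum(n * means) / N
  ss_between <- sum(n * (means - grand)^2)
  Fstat <- (ss_between / (k - 1)) / sp2
  anova_p <- pf(Fstat, k - 1, df, lower.tail = FALSE)

  trt <- setdiff(names(groups), control)
  n0 <- n[[control]]
  tstat <- vapply(trt, function(g)
    (means[[g]] - means[[control]]) /
      sqrt(sp2 * (1 / n[[g]] + 1 / n0)), numeric(1))
  raw_p <- 2 * pt(-abs(tstat), df)
  bvec <- sqrt(n[trt] / (n[trt] + n0))
  adj_p <- if (method == "integration") {
    vapply(abs(tstat), function(q) 1 - pDunnett(q, bvec, df), numeric(1))
  } else {
    maxT <- .simulateMaxAbsT(bvec, df, nboot)
    vapply(abs(tstat), function(q) mean(maxT >= q), numeric(1))
  }
  adj_p <- pmin(1, pmax(adj_p, raw_p))
  out <- data.frame(treatment = trt,
                    mean_diff = means[trt] - means[[control]],
                    t = tstat, raw_p = raw_p, adj_p = adj_p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "anova_F") <- Fstat
  attr(out, "anova_df") <- c(k - 1, df)
  attr(out, "anova_p") <- anova_p
  out
}

# null draws of max_j |T_j| under the one-factor structure
.simulateMaxAbsT <- function(b, df, nboot) {
  z0 <- rnorm(nboot)
  s <- sqrt(rchisq(nboot, df) / df)
  maxT <- rep(-Inf, nboot)
  for (j in seq_along(b)) {
    Tj <- (b[j] * z0 + sqrt(1 - b[j]^2) * rnorm(nboot)) / s
    maxT <- pmax(maxT, abs(Tj))
  }
  maxT
}

#' Dunnett comparisons for every site of a stoichiometry table
#'
#' Convenience wrapper running [dunnettVsControl()] per site on the
#' replicate occupancies of a [siteStoichiometryTable()] result.
#'
#' @param tab stoichiometry table with `replicate_pct` list column.
#' @param control control sample label.
#' @param ... passed to [dunnettVsControl()].
#' @return data.frame with columns `site_label`, `control`, `treatment`,
#'   `mean_diff_pct`, `raw_p`, `adj_p`.
#' @export
compareToControl <- function(tab, control, ...) {
  out <- list()
  for (s in unique(tab$site_label)) {
    sub <- tab[tab$site_label == s, , drop = FALSE]
    groups <- setNames(sub$replicate_pct, sub$sample)
    if (!control %in% names(groups))
      stop("site ", s, ": control sample \"", control, "\" absent")
    d <- dunnettVsControl(groups, control, ...)
    out[[length(out) + 1L]] <-
      data.frame(site_label = s, control = control,
                 treatment = d$treatment, mean_diff_pct = d$mean_diff,
                 raw_p = d$raw_p, adj_p = d$adj_p,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
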