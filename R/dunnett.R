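# Monte-Carlo Dunnett machinery: critical values for the max statistic of
# many-to-one comparisons, simulated from the exact null (shared pooled
# variance), cached per design so repeated classifications are cheap.

.dunnett_cache <- new.env(parent = emptyenv())

# Null distribution of max_i t_i for k = length(n) - 1 comparisons against
# the control (first element of n), df error degrees of freedom.
dunnett_null_draws <- function(n, df, ndraws = 50000, seed = 1) {
  key <- paste(c(n, df, ndraws, seed), collapse = "_")
  if (!is.null(.dunnett_cache[[key]])) return(.dunnett_cache[[key]])
  draws <- with_seed(seed, {
    g <- length(n)
    z <- matrix(stats::rnorm(ndraws * g), ndraws, g)
    s <- sqrt(stats::rchisq(ndraws, df) / df)
    t_stats <- sapply(2:g, function(i) {
      (z[, i] / sqrt(n[i]) - z[, 1] / sqrt(n[1])) /
        (s * sqrt(1 / n[i] + 1 / n[1]))
    })
    if (is.null(dim(t_stats))) t_stats <- matrix(t_stats, ncol = 1)
    apply(t_stats, 1, max)
  })
  .dunnett_cache[[key]] <- draws
  draws
}

#' Monte-Carlo Dunnett critical value
#'
#' One-sided critical value for the maximum of the many-to-one comparison
#' statistics under the one-way ANOVA null, computed by seeded Monte Carlo
#' from the exact null (independent group means, shared chi-square pooled
#' variance) rather than by multivariate-t quadrature. Deterministic for a
#' given design, draw count and seed; cached.
#'
#' @param n Integer vector of group sizes, control first.
#' @param df Error degrees of freedom (total N minus number of groups).
#' @param alpha Family-wise one-sided error rate (default 0.05).
#' @param ndraws Monte-Carlo draws (default 50000).
#' @param seed RNG seed for the draws.
#' @return Critical value (numeric scalar).
#' @export
dunnett_critical <- function(n, df, alpha = 0.05, ndraws = 50000, seed = 1) {
  stopifnot(length(n) >= 2L, all(n >= 2L), df >= 1)
  assert_proportion(alpha, "alpha")
  stats::quantile(dunnett_null_draws(n, df, ndraws, seed), 1 - alpha,
                  names = FALSE)
}

#' Classify mutant constructs against wild type
#'
#' Reproduces the two-stage decision rule used to color mutant panels:
#'
#' 1. Response stage (needs raw amplitudes): per construct, two-sided
#'    one-sample t-tests of the test- and saturating-concentration response
#'    amplitudes against zero. If neither differs from zero the construct is
#'    `no_response`.
#' 2. Potency stage: the remaining constructs' paired potency ratios enter a
#'    one-way ANOVA frame with the wild type as control; each mutant is
#'    compared with Dunnett's many-to-one adjustment, one-sided for a
#'    decrease (both "not different" and "greater" map to the same label).
#'    Significantly less than wild type gives `reduced`, otherwise
#'    `unchanged_or_greater`. Critical values come from the seeded
#'    Monte-Carlo null of [dunnett_critical()].
#'
#' @param ratios Data frame with columns `construct` and `ratio`, one row per
#'   recording; must include the wild-type construct.
#' @param amplitudes Optional data frame with columns `construct`, `peak_a`,
#'   `peak_b` (signed uA, one row per recording) for the response stage;
#'   omitted, every construct is treated as responding.
#' @param wt Name of the wild-type construct (default `"WT"`).
#' @param alpha Significance level (default 0.05).
#' @param ndraws Monte-Carlo draws for the Dunnett null (default 50000).
#' @param seed Seed for the Monte-Carlo null.
#' @return Data frame `construct`, `label`
#'   (`no_response`/`reduced`/`unchanged_or_greater`; wild type is labeled
#'   `reference`), `n`, `mean_ratio`, `p_zero_a`, `p_zero_b`, `p_vs_wt`.
#' @export
classify_mutants <- function(ratios, amplitudes = NULL, wt = "WT",
                             alpha = 0.05, ndraws = 50000, seed = 1) {
  stopifnot(all(c("construct", "ratio") %in% names(ratios)))
  constructs <- unique(ratios$construct)
  if (!wt %in% constructs) stop("wild-type group missing from `ratios`", call. = FALSE)
  mutants <- setdiff(constructs, wt)

  counts <- table(ratios$construct)
  if (any(counts < 3L)) {
    stop("every construct needs >= 3 replicates", call. = FALSE)
  }

  p_zero <- function(x) {
    # one-sample two-sided t-test vs zero, robust to degenerate input
    if (stats::sd(x) < .Machine$double.eps^0.5) {
      return(if (abs(mean(x)) < .Machine$double.eps^0.5) 1 else 0)
    }
    stats::t.test(x)$p.value
  }

  zero_a <- zero_b <- stats::setNames(rep(NA_real_, length(constructs)), constructs)
  responding <- stats::setNames(rep(TRUE, length(constructs)), constructs)
  if (!is.null(amplitudes)) {
    stopifnot(all(c("construct", "peak_a", "peak_b") %in% names(amplitudes)))
    for (cc in mutants) {
      a <- amplitudes[amplitudes$construct == cc, , drop = FALSE]
      if (nrow(a) == 0L) next
      zero_a[cc] <- p_zero(a$peak_a)
      zero_b[cc] <- p_zero(a$peak_b)
      responding[cc] <- zero_a[cc] < alpha || zero_b[cc] < alpha
    }
  }

  test_set <- c(wt, mutants[responding[mutants]])
  p_wt <- stats::setNames(rep(NA_real_, length(constructs)), constructs)
  label <- stats::setNames(rep("no_response", length(constructs)), constructs)
  label[wt] <- "reference"

  if (length(test_set) > 1L) {
    grp <- split(ratios$ratio[ratios$construct %in% test_set],
                 ratios$construct[ratios$construct %in% test_set])
    grp <- grp[c(wt, setdiff(test_set, wt))]
    ns <- lengths(grp)
    means <- vapply(grp, mean, numeric(1))
    df_err <- sum(ns) - length(ns)
    pooled <- sum(vapply(grp, function(x) sum((x - mean(x))^2), numeric(1))) / df_err
    draws <- dunnett_null_draws(ns, df_err, ndraws, seed)
    crit <- stats::quantile(draws, 1 - alpha, names = FALSE)
    for (i in 2:length(grp)) {
      cc <- names(grp)[i]
      d <- (means[i] - means[1]) / sqrt(pooled * (1 / ns[i] + 1 / ns[1]))
      # one-sided "less than control": by symmetry of the null,
      # P(min_j T_j <= d) = P(max_j T_j >= -d)
      p_wt[cc] <- mean(draws >= -d)
      label[cc] <- if (-d > crit) "reduced" else "unchanged_or_greater"
    }
  }

  mean_ratio <- vapply(constructs, function(cc)
    mean(ratios$ratio[ratios$construct == cc]), numeric(1))
  out <- data.frame(
    construct = constructs,
    label = unname(label[constructs]),
    n = as.integer(counts[constructs]),
    mean_ratio = unname(mean_ratio),
    p_zero_a = unname(zero_a[constructs]),
    p_zero_b = unname(zero_b[constructs]),
    p_vs_wt = unname(p_wt[constructs]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
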