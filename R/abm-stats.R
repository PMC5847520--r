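# Rank-based comparison of simulated survival across areas and life stages.
# Wilcoxon and Kruskal-Wallis delegate to the standard base-R tests; Dunn's
# post hoc (pairwise mean-rank z tests after a Kruskal-Wallis rejection) is
# implemented here with tie-corrected pooled variance and p.adjust-based
# multiplicity control.

#' Wilcoxon rank-sum comparison of two survival samples
#'
#' Two-sided rank-sum test (Mann-Whitney). Small samples without ties use
#' the exact null distribution; larger or tied samples the tie-corrected
#' normal approximation, as in [stats::wilcox.test()].
#'
#' @param a,b numeric samples (e.g. survival percentages for two areas).
#' @param exact forwarded to [stats::wilcox.test()]; default lets it decide
#'   (exact below 50 per group when tie-free).
#' @return list of class `rank_test` with `statistic` (W), `p_value`,
#'   `method` and the comparison sizes.
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    warning("all pooled values identical; rank test is degenerate")
    return(structure(list(statistic = length(a) * length(b) / 2,
                          p_value = 1, method = "degenerate",
                          n = c(length(a), length(b))),
                     class = "rank_test"))
  }
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0L
  small <- length(pooled) <= 16L
  if (ties && small && !isFALSE(exact)) {
    # exact permutation distribution with midranks: enumerate every
    # assignment of pooled values to the first sample
    r <- rank(pooled)
    n1 <- length(a)
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    idx <- utils::combn(length(pooled), n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    mu <- n1 * (length(pooled) + 1) / 2
    obs <- sum(r[seq_len(n1)])
    p <- mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
    return(structure(list(statistic = W, p_value = p,
                          method = "Exact rank-sum test (midranks)",
                          n = c(length(a), length(b))),
                     class = "rank_test"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = wt$method, n = c(length(a), length(b))),
            class = "rank_test")
}

#' Kruskal-Wallis test across life stages
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees
#' of freedom, via [stats::kruskal.test()].
#'
#' @param values numeric vector of survival values.
#' @param groups group labels (factor or character), at least two groups.
#' @return list of class `rank_test` with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need at least two groups")
  if (length(unique(values)) == 1L) {
    # one giant tie: every mean rank is equal, H is 0 by construction
    return(structure(list(statistic = 0, df = nlevels(droplevels(groups)) - 1L,
                          p_value = 1,
                          method = "Kruskal-Wallis rank sum test (degenerate)"),
                     class = "rank_test"))
  }
  kt <- stats::kruskal.test(values, droplevels(groups))
  structure(list(statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p_value = kt$p.value,
                 method = kt$method), class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4f%s, p = %.4g\n", x$statistic,
              if (!is.null(x$df)) sprintf(", df = %d", x$df) else "",
              x$p_value))
  invisible(x)
}

#' Dunn's post hoc pairwise comparisons
#'
#' After a Kruskal-Wallis rejection, compares each pair of groups by the
#' difference in mean ranks of the pooled sample, standardized with the
#' tie-corrected pooled variance
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))`,
#' where `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Two-sided
#' p-values from the standard normal, adjusted for multiplicity.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param method multiplicity adjustment for [stats::p.adjust()]; default
#'   `"holm"` (also sensible: `"bonferroni"`, `"BH"`).
#' @return data frame of class `dunn_test` with columns `comparison`, `z`,
#'   `p_unadjusted`, `p_adjusted`.
#' @examples
#' set.seed(1)
#' v <- c(rnorm(10), rnorm(10), rnorm(10, 3))
#' g <- rep(c("a", "b", "c"), each = 10)
#' dunn_posthoc(v, g)
#' @export
dunn_posthoc <- function(values, groups, method = "holm") {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  cmb <- utils::combn(levels(groups), 2L)
  z <- p <- numeric(ncol(cmb))
  for (i in seq_len(ncol(cmb))) {
    g1 <- cmb[1L, i]; g2 <- cmb[2L, i]
    se <- sqrt(v0 * (1 / n[[g1]] + 1 / n[[g2]]))
    z[i] <- if (se > 0) (rbar[[g1]] - rbar[[g2]]) / se else 0
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  out <- data.frame(comparison = paste(cmb[1L, ], cmb[2L, ], sep = "-"),
                    z = z, p_unadjusted = p,
                    p_adjusted = stats::p.adjust(p, method = method),
                    stringsAsFactors = FALSE)
  attr(out, "adjust_method") <- method
  class(out) <- c("dunn_test", "data.frame")
  out
}

#' @export
print.dunn_test <- function(x, ...) {
  cat("Dunn's post hoc test (", attr(x, "adjust_method"),
      "-adjusted p-values)\n", sep = "")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Stage-survival comparison of an ABM experiment
#'
#' Convenience wrapper applying the Kruskal-Wallis test and Dunn's post hoc
#' to an [run_abm_experiment()] result.
#'
#' @param experiment an `abm_experiment` data frame.
#' @param method multiplicity adjustment for the post hoc comparisons.
#' @return list with `kruskal` (a `rank_test`) and `dunn` (a `dunn_test`).
#' @export
compare_stage_survival <- function(experiment, method = "holm") {
  stopifnot(inherits(experiment, "abm_experiment"))
  list(kruskal = kruskal_wallis(experiment$survival_pct, experiment$stage),
       dunn = dunn_posthoc(experiment$survival_pct, experiment$stage,
                           method = method))
}
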