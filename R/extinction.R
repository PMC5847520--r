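# Quasi-extinction probability under Bernoulli catastrophe years.
#
# The only stochastic element is the yearly catastrophe indicator: in a
# catastrophe year the Kruger subadult and adult survival rates (s2, s3) are
# replaced by their KZN equivalents; otherwise projection is deterministic
# multiplication by the metapopulation matrix.

#' Initial stage-structured metapopulation vector
#'
#' Distributes regional female totals over the five single-year stages using
#' a population composition given as fractions of birds under 2 years old,
#' 3-5 years old and over 5. The young fraction maps to stage 1, the middle
#' fraction splits equally over stages 2-4, and the adult fraction is
#' stage 5.
#'
#' @param n_kruger,n_kzn total females per region (defaults: the published
#'   1200 and 425).
#' @param composition fractions `c(young, mid, adult)`; default
#'   `c(0.09, 0.24, 0.67)`.
#' @return numeric vector of length 10 (stages 1-5 Kruger, 6-10 KZN).
#' @export
initial_population <- function(n_kruger = 1200, n_kzn = 425,
                               composition = c(0.09, 0.24, 0.67)) {
  if (length(composition) != 3L || any(composition < 0)) {
    stop("composition must be 3 non-negative fractions")
  }
  comp <- composition / sum(composition)
  split5 <- c(comp[1], rep(comp[2] / 3, 3), comp[3])
  c(n_kruger * split5, n_kzn * split5)
}

#' Quasi-extinction probability under catastrophic poisoning years
#'
#' Projects the two-region metapopulation yearly for `horizon` years. Each
#' year is a catastrophe with probability `1 / interval_years`
#' (Bernoulli); in catastrophe years the Kruger s2 and s3 are replaced by
#' the KZN values, reverting afterwards. A replicate goes quasi-extinct when
#' total females fall below `threshold` — by default at any year
#' (first passage); `when = "endpoint"` checks only the final year.
#'
#' @param v_kruger,v_kzn [vital_rates()] for the two regions (defaults:
#'   [awbv_vital_rates()]).
#' @param interval_years mean catastrophe recurrence in years (e.g. 5, 10,
#'   15); `Inf` disables catastrophes.
#' @param horizon years to project (default 100).
#' @param threshold quasi-extinction threshold in females (default 10).
#' @param n0 initial stage vector, see [initial_population()].
#' @param gb,bg,gb0,bg0 dispersal fractions, as in [metapop_matrix()].
#' @param replicates Monte Carlo replicates (default 10000).
#' @param seed RNG seed (mandatory).
#' @param when `"any"` (first passage, default) or `"endpoint"`.
#' @return object of class `extinction_sim`: list with
#'   `extinction_probability`, `n_extinct`, `replicates`, and the scenario
#'   settings.
#' @examples
#' v <- awbv_vital_rates()
#' simulate_quasi_extinction(v$Kruger, v$KZN, interval_years = 5,
#'                           replicates = 500, seed = 1)
#' @export
simulate_quasi_extinction <- function(v_kruger = awbv_vital_rates()$Kruger,
                                      v_kzn = awbv_vital_rates()$KZN,
                                      interval_years,
                                      horizon = 100,
                                      threshold = 10,
                                      n0 = initial_population(),
                                      gb = 0.02, bg = 0.02,
                                      gb0 = 0.05, bg0 = 0.05,
                                      replicates = 10000,
                                      seed,
                                      when = c("any", "endpoint")) {
  when <- match.arg(when)
  if (missing(seed)) stop("seed is mandatory")
  if (replicates < 1) stop("need at least one replicate")
  if (threshold <= 0) stop("threshold must be positive")
  if (interval_years <= 0) stop("interval_years must be positive")
  if (length(n0) != 10L || any(n0 < 0)) stop("n0 must be 10 non-negative")
  set.seed(as.integer(seed))
  p_cat <- 1 / interval_years
  M <- metapop_matrix(v_kruger, v_kzn, gb, bg, gb0, bg0)
  v_cat <- vital_rates(v_kruger$s1, v_kzn$s2, v_kzn$s3, v_kruger$f,
                       region = "Kruger(catastrophe)")
  Mc <- metapop_matrix(v_cat, v_kzn, gb, bg, gb0, bg0)
  M <- unclass(M); Mc <- unclass(Mc)

  N <- matrix(n0, nrow = 10L, ncol = replicates)
  below <- rep(FALSE, replicates)
  for (yr in seq_len(horizon)) {
    cat_year <- stats::runif(replicates) < p_cat
    if (any(cat_year)) N[, cat_year] <- Mc %*% N[, cat_year, drop = FALSE]
    if (!all(cat_year)) N[, !cat_year] <- M %*% N[, !cat_year, drop = FALSE]
    if (when == "any") below <- below | colSums(N) < threshold
  }
  if (when == "endpoint") below <- colSums(N) < threshold
  structure(list(extinction_probability = mean(below),
                 n_extinct = sum(below), replicates = replicates,
                 interval_years = interval_years, horizon = horizon,
                 threshold = threshold, when = when, seed = seed),
            class = "extinction_sim")
}

#' @export
print.extinction_sim <- function(x, ...) {
  cat(sprintf(
    "Quasi-extinction simulation: interval %s yr, horizon %d yr, threshold %g females\n",
    format(x$interval_years), x$horizon, x$threshold))
  cat(sprintf("  P(extinction, %s) = %.4f  (%d / %d replicates)\n",
              if (x$when == "any") "first passage" else "endpoint",
              x$extinction_probability, x$n_extinct, x$replicates))
  invisible(x)
}

#' Extinction probabilities across catastrophe scenarios
#'
#' Runs [simulate_quasi_extinction()] for several mean recurrence intervals
#' (default the 15 / 10 / 5 year scenarios) and tabulates the results.
#'
#' @param intervals numeric vector of mean recurrence intervals in years.
#' @param seed RNG seed; each scenario uses a sub-seed derived from it.
#' @param ... further arguments to [simulate_quasi_extinction()].
#' @return data frame with `interval_years` and `extinction_probability`.
#' @export
extinction_scenarios <- function(intervals = c(15, 10, 5), seed, ...) {
  if (missing(seed)) stop("seed is mandatory")
  out <- lapply(seq_along(intervals), function(i) {
    sim <- simulate_quasi_extinction(interval_years = intervals[i],
                                     seed = as.integer(seed) + i, ...)
    data.frame(interval_years = intervals[i],
               extinction_probability = sim$extinction_probability)
  })
  do.call(rbind, out)
}
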