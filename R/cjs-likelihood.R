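# Cormack-Jolly-Seber likelihood machinery.
#
# The likelihood conditions on first capture. For bird i released at occasion
# r with last detection at occasion L, the contribution is
#   prod_{t=r}^{L-1} phi_it * p_{i,t+1}^{y} (1-p_{i,t+1})^{1-y}  *  chi_iL
# where chi_it is the probability of never being seen after occasion t:
#   chi_iK = 1,  chi_it = (1 - phi_it) + phi_it (1 - p_{i,t+1}) chi_{i,t+1}.
# Survival phi_it is indexed by the bird's region and *current* age class
# (classes advance annually), detection p by region and occasion.

#' Cormack-Jolly-Seber log-likelihood for explicit probability matrices
#'
#' Computes the CJS log-likelihood of a capture-history set given per-bird,
#' per-interval survival and detection probabilities. This is the numerical
#' core used by [fit_cjs()]; exposing it makes the likelihood testable
#' against brute-force enumeration.
#'
#' @param data a [capture_histories()] object.
#' @param phi survival probabilities: scalar, or matrix `[n, K-1]` where
#'   `phi[i, t]` is survival of bird `i` over interval `t -> t+1`.
#' @param p detection probabilities: scalar, or matrix `[n, K-1]` where
#'   `p[i, t]` is detection of bird `i` at occasion `t + 1`.
#' @return The summed log-likelihood (may be `-Inf` for impossible data).
#' @export
cjs_loglik <- function(data, phi, p) {
  stopifnot(inherits(data, "capture_histories"))
  n <- nrow(data$ch); K <- ncol(data$ch)
  if (K < 2L) stop("need at least two occasions")
  PHI <- if (length(phi) == 1L) matrix(phi, n, K - 1L) else as.matrix(phi)
  P <- if (length(p) == 1L) matrix(p, n, K - 1L) else as.matrix(p)
  if (!all(dim(PHI) == c(n, K - 1L)) || !all(dim(P) == c(n, K - 1L))) {
    stop("phi and p must be n x (K-1)")
  }
  if (any(!is.finite(PHI)) || any(!is.finite(P)) ||
      any(PHI < 0 | PHI > 1) || any(P < 0 | P > 1)) {
    stop("phi and p must be finite probabilities")
  }
  ch <- data$ch
  release <- data$release
  last <- apply(ch == 1L, 1L, function(z) max(which(z)))

  # chi[, t]: never seen after occasion t (t = 1..K)
  chi <- matrix(1, n, K)
  for (t in (K - 1L):1L) {
    chi[, t] <- (1 - PHI[, t]) + PHI[, t] * (1 - P[, t]) * chi[, t + 1L]
  }

  tmat <- matrix(seq_len(K - 1L), n, K - 1L, byrow = TRUE)
  act <- tmat >= release & tmat <= last - 1L  # intervals inside (release, last)
  y <- ch[, -1L, drop = FALSE]                # detection at occasion t+1
  term <- matrix(0, n, K - 1L)
  idx <- which(act)
  # 0*log(0) never arises: within the active window survival is certain in
  # the observed path only up to 'last', and log() of a true-zero probability
  # correctly yields -Inf for impossible data
  term[idx] <- log(PHI[idx]) +
    ifelse(y[idx] == 1L, log(P[idx]), log1p(-P[idx]))
  sum(term) + sum(log(chi[cbind(seq_len(n), last)]))
}

# -- design construction -----------------------------------------------------

parse_cjs_terms <- function(f, allowed, what) {
  if (inherits(f, "formula")) {
    tl <- attr(stats::terms(f), "term.labels")
  } else {
    tl <- as.character(f)
    tl <- tl[nzchar(tl)]
  }
  tl[tl == "t"] <- "time"
  if (!all(tl %in% allowed)) {
    stop(sprintf("%s terms must be a subset of {%s}", what,
                 paste(allowed, collapse = ", ")))
  }
  unique(tl)
}

# Design matrices for the stacked (bird x interval) phi rows and
# (bird x occasion 2..K) p rows. Treatment contrasts, intercept always
# present; 'site' = KZN indicator, 'age' = subadult/adult indicators of the
# bird's class during the interval, 'time' = interval (or occasion) factor.
cjs_design <- function(data, phi_terms, p_terms) {
  n <- nrow(data$ch); K <- ncol(data$ch)
  ni <- K - 1L
  tvec <- rep(seq_len(ni), each = n)
  region <- rep(as.character(data$region), ni)
  yrs <- pmax(tvec - rep(data$release, ni), 0L)
  cls <- age_class_at(rep(as.character(data$age_at_release), ni), yrs)

  build <- function(terms, time_levels) {
    X <- matrix(1, n * ni, 1L, dimnames = list(NULL, "(Intercept)"))
    if ("site" %in% terms) {
      X <- cbind(X, siteKZN = as.numeric(region == "KZN"))
    }
    if ("age" %in% terms) {
      X <- cbind(X, agesubadult = as.numeric(cls == "subadult"),
                 ageadult = as.numeric(cls == "adult"))
    }
    if ("time" %in% terms) {
      for (lv in time_levels[-1L]) {
        X <- cbind(X, as.numeric(tvec == lv))
        colnames(X)[ncol(X)] <- sprintf("time%d", lv)
      }
    }
    X
  }
  list(X_phi = build(phi_terms, seq_len(ni)),
       X_p = build(p_terms, seq_len(ni)),
       n = n, n_intervals = ni)
}

model_label <- function(phi_terms, p_terms) {
  lab <- function(terms) {
    if (length(terms) == 0L) return(".")
    paste(sub("^time$", "t", terms), collapse = " + ")
  }
  sprintf("Phi(%s), p(%s)", lab(phi_terms), lab(p_terms))
}
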