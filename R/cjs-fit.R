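# Maximum-likelihood fitting of CJS models with additive logit-scale
# structures over region ("site"), age class ("age") and occasion ("time").

#' Fit a Cormack-Jolly-Seber survival model
#'
#' Maximizes the CJS likelihood with survival and resighting modelled
#' additively on the logit scale. Allowed terms are `site` (region of
#' tagging), `age` (current age class, advancing annually) and `time`
#' (occasion effects) for survival, and `site` / `time` for resighting, in
#' the usual mark-recapture notation: `Phi(site + age), p(site + t)`.
#'
#' Optimization is multi-start BFGS on the logit-scale coefficients;
#' standard errors come from the observed information (numerical Hessian at
#' the optimum). AICc uses `aicc = -2 logL + 2k + 2k(k+1)/(n_ess - k - 1)`
#' with the effective sample size `n_ess` taken, by default, as the total
#' number of post-release detection opportunities.
#'
#' @param data a [capture_histories()] object.
#' @param phi formula or character vector of survival terms, e.g.
#'   `~ site + age` (use `~ 1` for constant survival).
#' @param p formula or character vector of resighting terms, e.g.
#'   `~ site + time` (alias `t`).
#' @param ess effective-sample-size convention for AICc:
#'   `"opportunities"` (default; sum over birds of occasions after release)
#'   or `"released"` (number of birds).
#' @param n_starts number of optimizer starts (the first is the null start).
#' @param control passed to [stats::optim()] (BFGS).
#' @return An object of class `cjs_fit` with components `coefficients`,
#'   `vcov`, `logLik`, `k`, `ess`, `aicc`, `model` (label), `phi_terms`,
#'   `p_terms`, `data`, `convergence` and `boundary`.
#' @seealso [cjs_loglik()], [rank_models()], [combined_survival()]
#' @examples
#' ch <- simulate_capture_histories(sim_spec(), seed = 42)
#' fit <- fit_cjs(ch, phi = ~ site + age, p = ~ site)
#' summary(fit)
#' @export
fit_cjs <- function(data, phi = ~1, p = ~1,
                    ess = c("opportunities", "released"),
                    n_starts = 4, control = list()) {
  stopifnot(inherits(data, "capture_histories"))
  ess <- match.arg(ess)
  phi_terms <- parse_cjs_terms(phi, c("site", "age", "time"), "phi")
  p_terms <- parse_cjs_terms(p, c("site", "time"), "p")
  if ("time" %in% phi_terms && "time" %in% p_terms) {
    warning("phi(time) with p(time): the final phi and p are confounded; ",
            "only their product is identifiable")
  }
  des <- cjs_design(data, phi_terms, p_terms)
  k_phi <- ncol(des$X_phi); k_p <- ncol(des$X_p)
  k <- k_phi + k_p
  n <- des$n; ni <- des$n_intervals

  nll <- function(beta) {
    PHI <- matrix(stats::plogis(des$X_phi %*% beta[seq_len(k_phi)]), n, ni)
    P <- matrix(stats::plogis(des$X_p %*% beta[k_phi + seq_len(k_p)]), n, ni)
    ll <- cjs_loglik(data, PHI, P)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  starts <- vector("list", max(1L, n_starts))
  starts[[1L]] <- rep(0, k)
  if (n_starts > 1L) {
    # deterministic spread of starts, independent of the global RNG
    for (s in 2L:n_starts) {
      starts[[s]] <- 1.5 * sin(seq_len(k) * s * 0.7) # bounded, reproducible
    }
  }
  ctl <- utils::modifyList(list(maxit = 1000L, reltol = 1e-10), control)
  best <- NULL
  for (st in starts) {
    op <- try(stats::optim(st, nll, method = "BFGS", control = ctl),
              silent = TRUE)
    if (inherits(op, "try-error")) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("CJS optimization failed from every start")
  op <- stats::optim(best$par, nll, method = "BFGS", control = ctl,
                     hessian = TRUE)
  if (op$value > best$value + 1e-6) op <- best  # keep best; no Hessian then
  beta <- op$par
  names(beta) <- c(paste0("phi:", colnames(des$X_phi)),
                   paste0("p:", colnames(des$X_p)))
  V <- matrix(NA_real_, k, k, dimnames = list(names(beta), names(beta)))
  if (!is.null(op$hessian)) {
    Vt <- try(solve(op$hessian), silent = TRUE)
    if (!inherits(Vt, "try-error")) {
      dimnames(Vt) <- dimnames(V)
      V <- Vt
    }
  }
  boundary <- any(abs(beta) > 8)
  if (boundary) {
    warning("estimates at or near the boundary of the parameter space ",
            "(|logit| > 8); probabilities ~0 or ~1")
  }
  ess_n <- switch(ess,
                  opportunities = sum(ncol(data$ch) - data$release),
                  released = nrow(data$ch))
  ll <- -op$value
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (ess_n - k - 1)
  structure(
    list(coefficients = beta, vcov = V, logLik = ll, k = k, ess = ess_n,
         aicc = aicc, model = model_label(phi_terms, p_terms),
         phi_terms = phi_terms, p_terms = p_terms, data = data,
         convergence = op$convergence, boundary = boundary),
    class = "cjs_fit")
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat("CJS model:", x$model, "\n")
  cat(sprintf("  logLik %.4f  k %d  ess %d  AICc %.4f\n",
              x$logLik, x$k, x$ess, x$aicc))
  if (x$convergence != 0L) cat("  WARNING: optimizer convergence code",
                               x$convergence, "\n")
  if (x$boundary) cat("  NOTE: boundary estimates\n")
  invisible(x)
}

#' @export
coef.cjs_fit <- function(object, ...) object$coefficients

#' @export
vcov.cjs_fit <- function(object, ...) object$vcov

#' @export
logLik.cjs_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$ess,
            class = "logLik")
}

#' Small-sample Akaike information criterion
#' @param object a fitted model with an AICc notion (here a `cjs_fit`).
#' @param ... unused.
#' @export
AICc <- function(object, ...) UseMethod("AICc")

#' @rdname AICc
#' @export
AICc.cjs_fit <- function(object, ...) object$aicc

#' @export
summary.cjs_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               z = object$coefficients / se)
  out <- list(fit = object, coef_table = tab,
              phi = predict(object, type = "phi"),
              p = predict(object, type = "p"))
  class(out) <- "summary.cjs_fit"
  out
}

#' @export
print.summary.cjs_fit <- function(x, ...) {
  print(x$fit)
  cat("\nLogit-scale coefficients:\n")
  stats::printCoefmat(x$coef_table)
  cat("\nSurvival (phi) by covariate combination:\n")
  print(x$phi, digits = 4)
  cat("\nResighting (p) by covariate combination:\n")
  print(x$p, digits = 4)
  invisible(x)
}

#' Back-transformed survival and resighting estimates
#'
#' Returns the estimated probabilities on the response scale for every
#' covariate combination the model distinguishes, with delta-method standard
#' errors.
#'
#' @param object a `cjs_fit`.
#' @param type `"phi"` (survival) or `"p"` (resighting).
#' @param ... unused.
#' @return data frame of estimates with columns for the covariates in the
#'   model, `estimate` and `se`.
#' @export
predict.cjs_fit <- function(object, type = c("phi", "p"), ...) {
  type <- match.arg(type)
  terms <- if (type == "phi") object$phi_terms else object$p_terms
  K <- ncol(object$data$ch)
  grid <- list()
  if ("site" %in% terms) grid$region <- REGIONS
  if ("age" %in% terms) grid$age <- AGE_CLASSES
  if ("time" %in% terms) grid$time <- seq_len(K - 1L)
  g <- if (length(grid)) expand.grid(grid, stringsAsFactors = FALSE)
       else data.frame(row.names = 1L)
  m <- max(1L, nrow(g))
  pre <- if (type == "phi") "phi:" else "p:"
  cf <- object$coefficients
  sel <- startsWith(names(cf), pre)
  bn <- sub(pre, "", names(cf)[sel])
  X <- matrix(0, m, sum(sel), dimnames = list(NULL, bn))
  X[, "(Intercept)"] <- 1
  if ("site" %in% terms) X[, "siteKZN"] <- as.numeric(g$region == "KZN")
  if ("age" %in% terms) {
    X[, "agesubadult"] <- as.numeric(g$age == "subadult")
    X[, "ageadult"] <- as.numeric(g$age == "adult")
  }
  if ("time" %in% terms) {
    for (lv in 2:(K - 1L)) X[, sprintf("time%d", lv)] <-
        as.numeric(g$time == lv)
  }
  eta <- drop(X %*% cf[sel])
  est <- stats::plogis(eta)
  V <- object$vcov[sel, sel, drop = FALSE]
  se_eta <- sqrt(rowSums((X %*% V) * X))
  out <- g
  out$estimate <- est
  out$se <- est * (1 - est) * se_eta  # delta method through the logit link
  rownames(out) <- NULL
  out
}

#' Simulate capture histories from a fitted CJS model
#'
#' Parametric-bootstrap generator: keeps the data's release design (regions,
#' age classes, release occasions) and draws survival and detection from
#' the fitted probabilities. Useful for goodness-of-fit and power checks.
#'
#' @param object a `cjs_fit`.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed (mandatory, for reproducibility).
#' @param ... unused.
#' @return list of `nsim` [capture_histories()] objects.
#' @export
simulate.cjs_fit <- function(object, nsim = 1, seed, ...) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  data <- object$data
  n <- nrow(data$ch); K <- ncol(data$ch)
  des <- cjs_design(data, object$phi_terms, object$p_terms)
  cf <- object$coefficients
  k_phi <- sum(startsWith(names(cf), "phi:"))
  PHI <- matrix(stats::plogis(des$X_phi %*% cf[seq_len(k_phi)]), n, K - 1L)
  P <- matrix(stats::plogis(des$X_p %*% cf[-seq_len(k_phi)]), n, K - 1L)
  lapply(seq_len(nsim), function(s) {
    ch <- matrix(0L, n, K)
    ch[cbind(seq_len(n), data$release)] <- 1L
    alive <- rep(TRUE, n)
    for (t in seq_len(K - 1L)) {
      at_risk <- alive & data$release <= t
      alive[at_risk] <- stats::runif(sum(at_risk)) < PHI[at_risk, t]
      seen <- alive & data$release <= t &
        stats::runif(n) < P[, t]
      ch[seen, t + 1L] <- 1L
    }
    capture_histories(ch, data$region, data$age_at_release, data$release,
                      bird_id = data$bird_id)
  })
}

#' Survival combined across age classes for one region
#'
#' Weights the fitted age-class survival probabilities of a region by that
#' region's released-bird age composition (or user weights) and propagates
#' the uncertainty by the delta method.
#'
#' @param fit a `cjs_fit` whose survival structure includes `site` (or is
#'   constant over site, in which case the region merely selects weights).
#' @param region `"Kruger"` or `"KZN"`.
#' @param weights optional numeric weights over
#'   `c(juvenile, subadult, adult)`; defaults to the composition of released
#'   birds in `region`. Normalized internally.
#' @return named numeric vector `c(estimate, se)`.
#' @export
combined_survival <- function(fit, region, weights = NULL) {
  stopifnot(inherits(fit, "cjs_fit"))
  region <- match.arg(region, REGIONS)
  if ("time" %in% fit$phi_terms) {
    stop("combined survival is defined for time-constant phi structures")
  }
  if (!region %in% fit$data$region) stop("region absent from the data")
  if (is.null(weights)) {
    sel <- fit$data$region == region
    weights <- as.numeric(table(fit$data$age_at_release[sel]))
  }
  if (length(weights) != 3L || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be 3 non-negative values over the age classes")
  }
  w <- weights / sum(weights)
  cf <- fit$coefficients
  sel <- startsWith(names(cf), "phi:")
  bn <- sub("phi:", "", names(cf)[sel])
  X <- matrix(0, 3L, sum(sel), dimnames = list(AGE_CLASSES, bn))
  X[, "(Intercept)"] <- 1
  if ("site" %in% fit$phi_terms) {
    X[, "siteKZN"] <- as.numeric(region == "KZN")
  }
  if ("age" %in% fit$phi_terms) {
    X["subadult", "agesubadult"] <- 1
    X["adult", "ageadult"] <- 1
  }
  eta <- drop(X %*% cf[sel])
  phi <- stats::plogis(eta)
  grad <- drop(t(X) %*% (w * phi * (1 - phi)))   # d(sum w phi)/d beta
  V <- fit$vcov[sel, sel, drop = FALSE]
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  c(estimate = sum(w * phi), se = se)
}
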