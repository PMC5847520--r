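test_that("likelihood of certain paths matches closed forms", {
  h11 <- one_history(c(1, 1))
  expect_equal(cjs_loglik(h11, phi = 1, p = 1), 0)
  expect_equal(cjs_loglik(h11, phi = 0.5, p = 1), log(0.5))
  # seen, gap, seen: phi^2 * p(miss) * p(seen)
  h101 <- one_history(c(1, 0, 1))
  expect_equal(cjs_loglik(h101, phi = 0.9, p = 0.7),
               2 * log(0.9) + log(0.3) + log(0.7))
  # impossible data under certain detection
  expect_equal(cjs_loglik(h101, phi = 1, p = 1), -Inf)
})

test_that("history probabilities sum to one over all possible histories", {
  for (K in 3:4) {
    for (pars in list(c(0.8, 0.6), c(0.3, 0.9), c(0.55, 0.15))) {
      total <- sum(vapply(all_histories(K), function(h) {
        exp(cjs_loglik(one_history(h), phi = pars[1], p = pars[2]))
      }, 0))
      expect_equal(total, 1, tolerance = 1e-12)
    }
  }
  # heterogeneous per-interval parameters, still a probability distribution
  set.seed(21)
  K <- 4
  phi <- runif(K - 1); p <- runif(K - 1)
  total <- sum(vapply(all_histories(K), function(h) {
    exp(cjs_loglik(one_history(h), phi = matrix(phi, 1), p = matrix(p, 1)))
  }, 0))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("adding terms never decreases the maximized log-likelihood", {
  ch <- simulate_capture_histories(sim_spec(), seed = 31)
  f0 <- fit_cjs(ch, phi = ~1, p = ~1)
  f1 <- fit_cjs(ch, phi = ~site, p = ~1)
  f2 <- fit_cjs(ch, phi = ~site + age, p = ~1)
  f3 <- fit_cjs(ch, phi = ~site + age, p = ~site)
  ll <- c(f0$logLik, f1$logLik, f2$logLik, f3$logLik)
  expect_true(all(diff(ll) > -1e-6))
  expect_equal(f3$k, 4 + 2)
  # AICc identity
  expect_equal(f3$aicc,
               -2 * f3$logLik + 2 * f3$k +
                 2 * f3$k * (f3$k + 1) / (f3$ess - f3$k - 1))
})

test_that("estimates recover additive logit-scale truth within 3 SE", {
  # additive truth so the fitted structure is correctly specified
  b0 <- qlogis(0.75); b_site <- -0.6; b_sub <- 0.45; b_ad <- 0.95
  phi_true <- rbind(
    Kruger = plogis(b0 + c(0, b_sub, b_ad)),
    KZN = plogis(b0 + b_site + c(0, b_sub, b_ad)))
  colnames(phi_true) <- c("juvenile", "subadult", "adult")
  p_true <- matrix(c(0.55, 0.45), 2, 6, dimnames = list(c("Kruger", "KZN")))
  cohorts <- expand.grid(region = c("Kruger", "KZN"),
                         age_at_release = c("juvenile", "subadult", "adult"),
                         release = 1, stringsAsFactors = FALSE)
  cohorts$n <- 600
  sp <- sim_spec(n_occasions = 6, cohorts = cohorts, phi = phi_true,
                 p = p_true)
  ch <- simulate_capture_histories(sp, seed = 41)
  fit <- fit_cjs(ch, phi = ~site + age, p = ~site)
  est <- predict(fit, type = "phi")
  for (i in seq_len(nrow(est))) {
    truth <- phi_true[est$region[i], est$age[i]]
    expect_lt(abs(est$estimate[i] - truth), 3 * est$se[i])
  }
})

test_that("perfect detection histories hit the boundary and are flagged", {
  ch <- capture_histories(matrix(1L, 30, 4), rep("Kruger", 30),
                          rep("adult", 30), rep(1L, 30))
  expect_warning(fit <- fit_cjs(ch, phi = ~1, p = ~1), "boundary")
  est <- predict(fit, type = "phi")$estimate
  expect_gt(est, 0.999)
  expect_true(fit$boundary)
})

test_that("phi(time) with p(time) warns about final-parameter confounding", {
  ch <- simulate_capture_histories(sim_spec(n_occasions = 4), seed = 51)
  expect_warning(fit_cjs(ch, phi = ~time, p = ~time), "confounded")
})

test_that("parametric-bootstrap simulation preserves the release design", {
  ch <- simulate_capture_histories(sim_spec(), seed = 71)
  fit <- fit_cjs(ch, phi = ~site, p = ~1)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  for (s in sims) {
    expect_equal(dim(s), dim(ch))
    expect_equal(s$release, ch$release)
    expect_equal(s$region, ch$region)
  }
  expect_identical(simulate(fit, seed = 5)[[1]]$ch, sims[[1]]$ch)
})

test_that("combined survival is a delta-method weighted mean", {
  # invariance: a constant-phi fit combines to itself under any weights
  ch <- simulate_capture_histories(sim_spec(), seed = 61)
  f <- fit_cjs(ch, phi = ~1, p = ~site)
  phi_hat <- predict(f, type = "phi")$estimate
  for (w in list(c(1, 1, 1), c(0.25, 0.25, 0.5), c(1, 0, 0))) {
    expect_equal(unname(combined_survival(f, "Kruger", w)["estimate"]),
                 phi_hat, tolerance = 1e-10)
  }
  # weighted-mean arithmetic on a fit with known age effects
  fake <- f
  fake$phi_terms <- "age"
  cf <- c("phi:(Intercept)" = qlogis(0.9),
          "phi:agesubadult" = qlogis(0.8) - qlogis(0.9),
          "phi:ageadult" = qlogis(0.7) - qlogis(0.9),
          "p:(Intercept)" = 0)
  fake$coefficients <- cf
  fake$vcov <- matrix(0, 4, 4, dimnames = list(names(cf), names(cf)))
  out <- combined_survival(fake, "Kruger", weights = c(0.25, 0.25, 0.5))
  expect_equal(unname(out["estimate"]), 0.775, tolerance = 1e-12)
  expect_error(combined_survival(f, "Oz"), "arg")
})
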