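make_world <- function(...) {
  cfg <- abm_config(...)
  set.seed(99)
  vulturedyn:::init_world(cfg)
}

# keep only agent 1 active, at a chosen position and heading
solo_agent <- function(world, x = 0, y = 0, heading = 0) {
  world$alive[-1] <- FALSE
  world$x[1] <- x; world$y[1] <- y; world$heading[1] <- heading
  world$has_mem[1] <- FALSE
  world
}

set_carcasses <- function(world, x, y, mass = 500, poisoned = FALSE,
                          large = mass > world$cfg$large_threshold) {
  n <- length(x)
  world$cx <- x; world$cy <- y
  world$cmass <- rep_len(mass, n)
  world$cpois <- rep_len(poisoned, n)
  world$clarge <- rep_len(large, n)
  world$cage <- rep(0L, n)
  world
}

test_that("configuration derives the published caps, counts and geometry", {
  cfg <- abm_config()
  expect_equal(cfg$cap_protected, 3000)
  expect_equal(cfg$cap_nonprotected, 6000)
  expect_equal(cfg$n_adults, 26)
  expect_equal(pi * cfg$region_radius^2, 20000)
  expect_equal(cfg$ticks_per_day, 54)
  expect_equal(cfg$step_km, 4)
  expect_error(abm_config(rate_protected = 0), "positive")
  expect_error(abm_config(n_roosts = 0), "roost")
  expect_error(abm_config(colony_radius = 60, forage_radius = 50), "within")
})

test_that("flipping the focus swaps habitat labels pointwise", {
  ck <- abm_config(focus = "Kruger"); cz <- abm_config(focus = "KZN")
  set.seed(1)
  x <- runif(500, -100, 100); y <- runif(500, -100, 100)
  hk <- vulturedyn:::habitat_of(x, y, ck)
  hz <- vulturedyn:::habitat_of(x, y, cz)
  expect_true(all(hk != hz))
  inside <- x^2 + y^2 <= ck$region_radius^2
  expect_true(all(hk[inside] == "protected"))
  expect_true(all(hz[inside] == "nonprotected"))
})

test_that("the world starts with the stated agents in the right places", {
  w <- make_world()
  expect_equal(as.numeric(table(w$stage)), c(26, 13, 13))
  ad <- w$stage == "adult"
  expect_true(all(w$x[ad]^2 + w$y[ad]^2 <= w$cfg$colony_radius^2 + 1e-9))
  expect_true(all(abs(w$x) <= 100 & abs(w$y) <= 100))
  expect_equal(nrow(w$roosts), 10)
  expect_true(all(w$alive))
})

test_that("carcass masses follow the stated habitat distributions", {
  set.seed(2)
  cfg <- abm_config()
  g <- draw_carcass_mass(1e5, "protected", cfg)
  expect_lt(abs(mean(g) - 300), 3)  # shape/rate = 1.2/0.004, rate form
  expect_lt(abs(mean(g > 1000) - 0.02745), 3 * sqrt(0.0275 * 0.9725 / 1e5))
  nm <- draw_carcass_mass(1e5, "nonprotected", cfg)
  expect_lt(abs(mean(nm) - 500), 1)
  expect_true(all(nm > 0))
  expect_equal(large_carcass_prob(cfg), 0.02745, tolerance = 5e-5 / 0.02745)
})

test_that("carcass replenishment fills each habitat to its cap", {
  w <- make_world()
  w <- vulturedyn:::spawn_carcasses(w)
  hab <- vulturedyn:::habitat_of(w$cx, w$cy, w$cfg)
  for (h in c("protected", "nonprotected")) {
    cap <- if (h == "protected") 3000 else 6000
    standing <- sum(w$cmass[hab == h])
    expect_gte(standing, cap)
    expect_lt(standing, cap + max(w$cmass[hab == h]) + 1e-9)
  }
  # large carcasses persist one extra day, small ones are removed at dawn
  large_before <- sum(w$clarge)
  w2 <- vulturedyn:::spawn_carcasses(w)
  expect_equal(sum(w2$cage == 1L), large_before)
  w3 <- vulturedyn:::spawn_carcasses(w2)
  expect_true(all(w3$cage < 2L))
})

test_that("degenerate poisoning rate 1 poisons every carcass", {
  w <- make_world(rate_protected = 1, rate_nonprotected = 1)
  w <- vulturedyn:::spawn_carcasses(w)
  expect_true(all(w$cpois))
  w2 <- make_world(rate_protected = Inf, rate_nonprotected = Inf)
  w2 <- vulturedyn:::spawn_carcasses(w2)
  expect_false(any(w2$cpois))
})

test_that("carcass detection respects the 6 km radius", {
  w <- solo_agent(make_world())
  w <- set_carcasses(w, x = 5, y = 0)
  w1 <- vulturedyn:::step_tick(w, day = 1)
  expect_equal(w1$x[1], 4)  # stepped straight at the carcass
  expect_equal(w1$y[1], 0)
  # 6.5 km away, unoccupied and small: not detected; the bird walks its own
  # way (heading pi points away from the carcass)
  w <- solo_agent(make_world(), heading = pi)
  w <- set_carcasses(w, x = 6.5, y = 0)
  w1 <- vulturedyn:::step_tick(w, day = 1)
  d <- sqrt((w1$x[1] - 6.5)^2 + w1$y[1]^2)
  expect_gt(d, 6.5)
})

test_that("occupied and large carcasses are visible from 7 km", {
  # a feeding bird on the carcass extends detection to 7 km
  w <- solo_agent(make_world(), heading = pi)
  w <- set_carcasses(w, x = 6.5, y = 0)
  w$alive[2] <- TRUE; w$feeding[2] <- TRUE; w$feed_target[2] <- 1L
  w$x[2] <- 6.5; w$y[2] <- 0
  w1 <- vulturedyn:::step_tick(w, day = 1)
  expect_equal(sqrt((w1$x[1] - 6.5)^2 + w1$y[1]^2), 2.5)
  # a lone large carcass likewise
  w <- solo_agent(make_world(), heading = pi)
  w <- set_carcasses(w, x = 6.5, y = 0, mass = 1500)
  w1 <- vulturedyn:::step_tick(w, day = 1)
  expect_equal(sqrt((w1$x[1] - 6.5)^2 + w1$y[1]^2), 2.5)
})

test_that("landing on a poisoned carcass kills instantly", {
  w <- solo_agent(make_world())
  w <- set_carcasses(w, x = 3, y = 0, poisoned = TRUE)
  w1 <- vulturedyn:::step_tick(w, day = 5)
  expect_false(w1$alive[1])
  expect_equal(w1$deaths_by_day, 5L)
  # unpoisoned: the bird lands, feeds and remembers the patch
  w <- solo_agent(make_world())
  w <- set_carcasses(w, x = 3, y = 0, poisoned = FALSE)
  w1 <- vulturedyn:::step_tick(w, day = 5)
  expect_true(w1$feeding[1])
  expect_equal(c(w1$mem_x[1], w1$mem_y[1]), c(3, 0))
  expect_true(w1$fed_today[1])
})

test_that("pre-release adults stay inside the foraging circle", {
  cfg <- abm_config(days = 30)
  set.seed(4)
  w <- vulturedyn:::init_world(cfg)
  for (day in 1:3) {
    w <- vulturedyn:::spawn_carcasses(w)
    for (k in 1:cfg$ticks_per_day) {
      w <- vulturedyn:::step_tick(w, day)
      ad <- w$stage == "adult" & w$alive
      expect_true(all(w$x[ad]^2 + w$y[ad]^2 <= cfg$forage_radius^2 + 1e-6))
    }
    w <- vulturedyn:::night_phase(w, day)
  }
})

test_that("without poisoning every bird survives the year", {
  r <- run_abm_year(abm_config(rate_protected = Inf,
                               rate_nonprotected = Inf, days = 40),
                    seed = 6)
  expect_equal(unname(r$survival_pct), c(100, 100, 100))
  expect_equal(length(r$deaths_by_day), 0L)
})

test_that("runs are deterministic and conserve birds", {
  cfg <- abm_config(days = 25)
  a <- run_abm_year(cfg, seed = 17)
  b <- run_abm_year(cfg, seed = 17)
  expect_identical(a$survival_pct, b$survival_pct)
  expect_identical(a$deaths_by_day, b$deaths_by_day)
  # every death is logged: alive + logged deaths = initial
  expect_equal(length(a$deaths_by_day), sum(a$n_initial) - sum(a$n_alive))
  expect_true(all(a$n_alive >= 0 & a$n_alive <= a$n_initial))
  c2 <- run_abm_year(cfg, seed = 18)
  expect_false(identical(a$survival_pct, c2$survival_pct) &&
                 identical(a$deaths_by_day, c2$deaths_by_day))
})

test_that("experiments aggregate replicate survival by stage", {
  ex <- run_abm_experiment(abm_config(days = 12), replicates = 3, seed = 30)
  expect_equal(nrow(ex), 9)
  expect_true(all(ex$survival_pct >= 0 & ex$survival_pct <= 100))
  s <- summary(ex)
  expect_equal(s$n, rep(3, 3))
  expect_equal(s$stage, c("adult", "subadult", "juvenile"))
  expect_true(all(c("mean", "sd", "focus", "n_roosts") %in% names(s)))
})
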