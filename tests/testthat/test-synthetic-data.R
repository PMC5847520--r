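test_that("certain survival and detection yield all-ones histories", {
  ch <- simulate_capture_histories(const_spec(1, 1, n = 3, K = 4), seed = 1)
  expect_true(all(ch$ch == 1L))
  expect_equal(dim(ch), c(3L, 4L))
})

test_that("certain death yields release-only histories", {
  ch <- simulate_capture_histories(const_spec(0, 1, n = 5, K = 5), seed = 2)
  expect_equal(rowSums(ch$ch), rep(1, 5))
  expect_true(all(ch$ch[, 1] == 1L))
})

test_that("history count and length are conserved", {
  sp <- sim_spec()
  ch <- simulate_capture_histories(sp, seed = 3)
  expect_equal(nrow(ch$ch), sum(sp$cohorts$n))
  expect_equal(ncol(ch$ch), sp$n_occasions)
  expect_true(all(ch$ch[cbind(seq_len(nrow(ch$ch)), ch$release)] == 1L))
})

test_that("re-sighting fraction at occasion 2 matches phi * p", {
  n <- 5000
  ch <- simulate_capture_histories(
    const_spec(0.8, 0.6, n = n, K = 7), seed = 11)
  frac <- mean(ch$ch[, 2])
  se <- sqrt(0.48 * 0.52 / n)
  expect_lt(abs(frac - 0.48), 3 * se)
})

test_that("invalid simulation designs are rejected", {
  expect_error(const_spec(1.2, 1), "probabilities")
  expect_error(sim_spec(cohorts = data.frame(
    region = "Kruger", age_at_release = "adult", release = 1, n = -3)),
    "negative")
  expect_error(sim_spec(cohorts = data.frame(
    region = "Kruger", age_at_release = "adult", release = 9, n = 3)),
    "release")
  expect_error(simulate_capture_histories(sim_spec()), "seed")
})

test_that("capture histories survive a CSV round trip", {
  ch <- simulate_capture_histories(sim_spec(), seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_capture_histories(ch, f)
  back <- read_capture_histories(f)
  expect_equal(back$ch, ch$ch, ignore_attr = TRUE)
  expect_equal(back$region, ch$region)
  expect_equal(back$age_at_release, ch$age_at_release)
  expect_equal(back$release, ch$release)
})

test_that("age classes advance deterministically with elapsed years", {
  expect_equal(age_class_at("juvenile", 0:6),
               c("juvenile", "juvenile", "subadult", "subadult", "subadult",
                 "adult", "adult"))
  expect_equal(age_class_at("subadult", 0:3),
               c("subadult", "subadult", "subadult", "adult"))
  expect_equal(age_class_at("adult", 0:2), rep("adult", 3))
})

test_that("annualization collapses within-year sightings to a single 1", {
  tagging <- data.frame(bird_id = "b1", region = "Kruger",
                        age_at_release = "adult",
                        tag_date = as.Date("2010-03-01"))
  records <- data.frame(bird_id = "b1",
                        date = as.Date(c("2011-02-01", "2011-04-10",
                                         "2011-09-30")))
  b <- as.Date(c("2010-01-01", "2011-01-01", "2012-01-01", "2013-01-01"))
  out <- annualize_sightings(records, tagging, b)
  expect_equal(out$histories$ch[1, ], c(1L, 1L, 0L), ignore_attr = TRUE)
  expect_equal(out$n_unique_annual, 1L)
  expect_equal(out$n_reseen, 1L)
})

test_that("never-resighted birds are excluded from the re-seen count", {
  tagging <- data.frame(bird_id = c("b1", "b2"), region = "KZN",
                        age_at_release = "juvenile",
                        tag_date = as.Date("2010-06-01"))
  records <- data.frame(bird_id = "b1", date = as.Date("2011-06-01"))
  b <- as.Date(c("2010-01-01", "2011-01-01", "2012-01-01"))
  out <- annualize_sightings(records, tagging, b)
  expect_equal(out$n_reseen, 1L)
  expect_equal(rowSums(out$histories$ch), c(2, 1), ignore_attr = TRUE)
})

test_that("annual re-sighting counts match a per-(bird, year) set oracle", {
  set.seed(8)
  years <- as.Date(c("2010-01-01", "2011-01-01", "2012-01-01",
                     "2013-01-01"))
  tagging <- data.frame(bird_id = sprintf("b%02d", 1:10),
                        region = sample(c("Kruger", "KZN"), 10, TRUE),
                        age_at_release = sample(c("juvenile", "adult"), 10,
                                                TRUE),
                        tag_date = as.Date("2010-02-01") +
                          sample(0:200, 10))
  records <- data.frame(
    bird_id = sample(tagging$bird_id, 25, TRUE),
    date = as.Date("2011-01-15") + sample(0:700, 25, TRUE))
  records$date <- pmax(records$date,
                       tagging$tag_date[match(records$bird_id,
                                              tagging$bird_id)])
  out <- annualize_sightings(records, tagging, years)

  # oracle: unique (bird, calendar year) pairs strictly after release year
  yr <- as.integer(format(records$date, "%Y"))
  tag_yr <- as.integer(format(tagging$tag_date, "%Y"))
  pairs <- unique(paste(records$bird_id, yr))
  post <- vapply(strsplit(pairs, " "), function(z) {
    as.integer(z[2]) > tag_yr[match(z[1], tagging$bird_id)]
  }, TRUE)
  expect_equal(out$n_unique_annual, sum(post))
  expect_equal(out$n_sightings, 25L)
})

test_that("records outside the occasion boundaries are rejected", {
  tagging <- data.frame(bird_id = "b1", region = "Kruger",
                        age_at_release = "adult",
                        tag_date = as.Date("2010-03-01"))
  records <- data.frame(bird_id = "b1", date = as.Date("2031-01-01"))
  b <- as.Date(c("2010-01-01", "2011-01-01", "2012-01-01"))
  expect_error(annualize_sightings(records, tagging, b), "outside")
  expect_error(
    annualize_sightings(data.frame(bird_id = "zz",
                                   date = as.Date("2011-06-01")),
                        tagging, b), "absent")
})
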