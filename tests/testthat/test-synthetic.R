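test_that("weather simulation is deterministic and calendar-complete", {
  w1 <- simulate_weather("X", "2010-01-01", "2010-12-31", seed = 4)
  w2 <- simulate_weather("X", "2010-01-01", "2010-12-31", seed = 4)
  expect_identical(w1, w2)
  expect_equal(nrow(w1), 365)
  w3 <- simulate_weather("X", "2010-01-01", "2010-12-31", seed = 5)
  expect_false(identical(w1$t_mean, w3$t_mean))
  expect_error(simulate_weather("X", "2010-01-02", "2010-01-01"), "empty")
})

test_that("a temperate city occupies all 10 bins over 30 years", {
  w <- simulate_weather("X", "1990-01-01", "2019-12-31", seed = 8)
  bins <- assign_temp_bin(w$t_mean)
  expect_equal(nlevels(droplevels(bins)), 10)
  # the dew point never exceeds air temperature, so rh stays <= 100
  expect_true(all(w$t_dew <= w$t_mean))
  expect_true(all(w$precip >= 0))
})

test_that("panel simulation is seed-reproducible and decomposes exactly", {
  cfg <- sim_config(n_politicians = 15, cities = c("C1", "C2"),
                    start_date = "2010-01-01", end_date = "2010-12-31",
                    speeches_per_sitting_day = 2, seed = 12)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$speeches, p2$speeches)
  expect_identical(p1$weather, p2$weather)
  expect_equal(reconstruct_outcome(p1), p1$speeches$flesch_kincaid,
               tolerance = 1e-12)
  # speeches only on simulated sitting days, weekday-biased
  dow <- as.integer(format(as.Date(p1$speeches$date), "%u"))
  expect_gt(mean(dow <= 5), 0.9)
})

test_that("zero noise and zero FE variance give the pure structural outcome", {
  cfg <- sim_config(n_politicians = 10, cities = "C1",
                    start_date = "2010-01-01", end_date = "2010-06-30",
                    speeches_per_sitting_day = 2, noise_sd = 0,
                    fe_sd = c(politician = 0, month_city = 0,
                              day_of_week = 0), seed = 3)
  p <- simulate_panel(cfg)
  w <- p$weather
  j <- match(paste(p$speeches$city, p$speeches$date), paste(w$city, w$date))
  expected <- cfg$baseline_fk +
    cfg$true_bin_effects[as.character(w$temp_bin[j])] +
    cfg$control_effects[["precip"]] * w$precip[j] +
    cfg$control_effects[["rh"]] * w$rh[j] +
    cfg$control_effects[["wind_speed"]] * w$wind_speed[j]
  expect_equal(p$speeches$flesch_kincaid, as.numeric(expected),
               tolerance = 1e-12)
})

test_that("the empirical intra-cluster correlation matches the configured rho", {
  cfg <- sim_config(n_politicians = 40, cities = c("C1", "C2"),
                    start_date = "2006-01-01", end_date = "2015-12-31",
                    speeches_per_sitting_day = 8,
                    intra_cluster_rho = 0.25, noise_sd = 2, seed = 44)
  p <- simulate_panel(cfg)
  eps <- p$truth$idiosyncratic[p$speeches$speech_id] +
    p$truth$cluster_draws[paste(p$speeches$city,
                                format(as.Date(p$speeches$date), "%Y-%m"),
                                sep = ":")]
  cl <- paste(p$speeches$city, format(as.Date(p$speeches$date), "%Y-%m"))
  # one-way ANOVA intraclass-correlation estimator
  n_g <- tapply(eps, cl, length)
  cm <- tapply(eps, cl, mean)
  big_n <- length(eps)
  g <- length(n_g)
  ssw <- sum((eps - ave(eps, cl))^2)
  ssb <- sum(n_g * (cm - mean(eps))^2)
  msw <- ssw / (big_n - g)
  msb <- ssb / (g - 1)
  n0 <- (big_n - sum(n_g^2) / big_n) / (g - 1)
  icc <- (msb - msw) / (msb + (n0 - 1) * msw)
  expect_lt(abs(icc - 0.25), 0.06)
})

test_that("demographics cover all age quartiles and honour proportions", {
  dem <- assign_demographics(sprintf("P%03d", 1:400), seed = 6)
  age <- 2012 - dem$birth_year
  q <- assign_age_quartile(age)
  expect_equal(nlevels(droplevels(q)), 4)
  expect_lt(abs(mean(dem$gender == "female") - 0.3), 0.06)
  dem2 <- assign_demographics(sprintf("P%03d", 1:400), seed = 6)
  expect_identical(dem, dem2)
  none <- assign_demographics("P1", rules = list(p_female = 0,
                                                 age_range = c(30, 60)),
                              seed = 2)
  expect_equal(none$gender, "male")
})

test_that("generated text re-scores to its targets", {
  txt <- generate_text(20, 1.5, 100, seed = 7)
  tc <- tokenize_and_count(txt)
  sc <- complexity_scores(tc)
  expect_equal(sc$avg_sentence_length, 20)       # exact by construction
  expect_lte(abs(sc$avg_word_syllables - 1.5), 0.05)
  expect_lte(abs(sc$flesch_kincaid - 9.91), 11.8 * 0.05)
  # minimal one-word one-syllable sentences
  txt1 <- generate_text(1, 1, 12, seed = 3)
  sc1 <- complexity_scores(tokenize_and_count(txt1))
  expect_equal(sc1$flesch, 121.22, tolerance = 1e-10)
  # determinism
  expect_identical(generate_text(15, 1.4, 90, seed = 9),
                   generate_text(15, 1.4, 90, seed = 9))
  expect_error(generate_text(20, 8, 100), "unreachable")
  expect_error(generate_text(12, 1.5, 100), "unreachable")
})

test_that("attach_speech_text yields scoreable text tracking the outcome", {
  cfg <- sim_config(n_politicians = 10, cities = "C1",
                    start_date = "2010-01-01", end_date = "2010-03-31",
                    speeches_per_sitting_day = 2, seed = 21)
  p <- simulate_panel(cfg)
  sp <- attach_speech_text(p$speeches, seed = 22)
  out <- score_speeches(sp)
  expect_equal(nrow(out$scored), nrow(sp))
  expect_true(all(out$scored$total_words >= 25))
})
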