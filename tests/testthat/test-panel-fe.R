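test_that("single-dimension demeaning subtracts group means exactly", {
  out <- demean_multiway(c(1, 2, 3, 5), list(c("A", "A", "B", "B")))
  expect_equal(as.numeric(out), c(-0.5, 0.5, -1, 1))
  expect_equal(attr(out, "iterations"), 1L)
  expect_true(attr(out, "converged"))
})

test_that("nested dimensions demean like the finer dimension alone", {
  set.seed(11)
  fine <- factor(sample(1:12, 300, replace = TRUE))
  coarse <- factor((as.integer(fine) - 1) %/% 3)  # fine nested in coarse
  m <- matrix(rnorm(600), 300)
  both <- demean_multiway(m, list(coarse, fine))
  fine_only <- demean_multiway(m, list(fine))
  expect_equal(unclass(both), unclass(fine_only), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("demeaned output has near-zero group means in every dimension", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 200
    gs <- list(factor(sample(1:15, n, TRUE)), factor(sample(1:6, n, TRUE)),
               factor(sample(1:4, n, TRUE)))
    out <- demean_multiway(matrix(rnorm(2 * n), n), gs, tol = 1e-10)
    for (g in gs) {
      gm <- rowsum(out, g) / as.vector(table(g))
      expect_lt(max(abs(gm)), 1e-10)
    }
  }
})

test_that("FE-OLS matches the dense dummy-variable oracle", {
  set.seed(21)
  for (rep in 1:10) {
    pn <- random_panel(n = 350)
    ours <- fit_raw(pn$y, pn$x, pn$fe, pn$cluster)
    dense <- lm(pn$y ~ pn$x + pn$fe$f1 + pn$fe$f2 + pn$fe$f3)
    ref <- coef(dense)[2:4]
    expect_equal(as.numeric(ours$beta), as.numeric(ref), tolerance = 1e-8)
    expect_equal(ours$k, dense$rank)
  }
})

test_that("CR1 vcov matches sandwich::vcovCL on the dense model", {
  skip_if_not_installed("sandwich")
  set.seed(22)
  pn <- random_panel(n = 500)
  ours <- fit_raw(pn$y, pn$x, pn$fe, pn$cluster)
  dense <- lm(pn$y ~ pn$x + pn$fe$f1 + pn$fe$f2 + pn$fe$f3)
  ref <- sandwich::vcovCL(dense, cluster = pn$cluster, type = "HC1",
                          cadjust = TRUE)[2:4, 2:4]
  expect_equal(unname(ours$vcov), unname(ref), tolerance = 1e-7)
})

test_that("with singleton clusters CR1 reduces to the HC1 form", {
  set.seed(23)
  pn <- random_panel(n = 300)
  ours <- fit_raw(pn$y, pn$x, pn$fe, factor(seq_along(pn$y)))
  # HC1: N/(N-K) * bread %*% (X' diag(e^2) X) %*% bread
  xd <- ours$xd
  bread <- solve(crossprod(xd))
  meat <- crossprod(xd * ours$resid)
  n <- nrow(xd)
  hc1 <- n / (n - ours$k) * bread %*% meat %*% bread
  expect_equal(unname(ours$vcov), unname(hc1), tolerance = 1e-10)
  expect_error(cluster_robust_vcov(xd, ours$resid, rep(1, n), k = ours$k),
               "2 clusters")
})

test_that("with iid errors and many clusters, clustered and iid SEs agree", {
  set.seed(24)
  n <- 6000
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
  y <- 0.5 * x[, 1] + rnorm(n)
  fe <- list(factor(sample(1:4, n, TRUE)))
  ours <- fit_raw(y, x, fe, factor(sample(1:300, n, TRUE)))
  iid_se <- sqrt(sum(ours$resid^2) / (n - ours$k) /
                   sum((ours$xd - mean(ours$xd))^2))
  expect_equal(sqrt(ours$vcov[1, 1]), iid_se, tolerance = 0.08)
})

test_that("clustered CIs attain nominal coverage where iid CIs undercover", {
  set.seed(25)
  reps <- 600
  n_cl <- 40
  m <- 10                       # cluster size
  n <- n_cl * m
  cl <- factor(rep(seq_len(n_cl), each = m))
  beta <- 0.5
  cover_cl <- cover_iid <- logical(reps)
  for (r in seq_len(reps)) {
    x <- rep(rnorm(n_cl), each = m)           # cluster-level regressor
    rho <- 0.5
    e <- sqrt(rho) * rep(rnorm(n_cl), each = m) + sqrt(1 - rho) * rnorm(n)
    y <- beta * x + e
    xm <- matrix(x - mean(x), n, 1, dimnames = list(NULL, "x"))
    ym <- y - mean(y)
    b <- sum(xm * ym) / sum(xm^2)
    res <- ym - b * xm[, 1]
    v_cl <- cluster_robust_vcov(xm, res, cl, k = 2)[1, 1]
    v_iid <- sum(res^2) / (n - 2) / sum(xm^2)
    cover_cl[r] <- abs(b - beta) <= qnorm(0.975) * sqrt(v_cl)
    cover_iid[r] <- abs(b - beta) <= qnorm(0.975) * sqrt(v_iid)
  }
  expect_gte(mean(cover_cl), 0.90)
  expect_lte(mean(cover_cl), 0.98)
  expect_lt(mean(cover_iid), 0.90)  # naive CIs undercover
})

test_that("Frisch-Waugh: demeaning only y equals demeaning both", {
  set.seed(26)
  pn <- random_panel(n = 300)
  dm <- demean_multiway(cbind(pn$y, pn$x), pn$fe)
  b_both <- qr.coef(qr(dm[, -1]), dm[, 1])
  yd_only <- demean_multiway(pn$y, pn$fe)
  xd <- demean_multiway(pn$x, pn$fe)
  b_fw <- qr.coef(qr(xd), as.numeric(yd_only))
  expect_equal(as.numeric(b_both), as.numeric(b_fw), tolerance = 1e-10)
})

test_that("zero-noise panels are recovered to numerical precision", {
  cfg <- sim_config(n_politicians = 20, cities = c("C1", "C2"),
                    start_date = "2010-01-01", end_date = "2011-12-31",
                    speeches_per_sitting_day = 3, noise_sd = 0,
                    fe_sd = c(politician = 1, month_city = 0.3,
                              day_of_week = 0.05),
                    seed = 7)
  p <- simulate_panel(cfg)
  f <- fit_fe_ols(build_design(p$speeches, p$weather))
  truth <- cfg$true_bin_effects
  for (b in names(f$beta)[grepl("^bin_", names(f$beta))]) {
    expect_equal(f$beta[[b]], truth[[sub("^bin_", "", b)]], tolerance = 1e-8)
  }
  ctrl_truth <- cfg$control_effects
  expect_equal(f$beta[["precip"]], ctrl_truth[["precip"]], tolerance = 1e-8)
  expect_equal(f$beta[["wind_speed"]], ctrl_truth[["wind_speed"]],
               tolerance = 1e-8)
})

test_that("collinear columns are pruned and reported", {
  set.seed(27)
  pn <- random_panel(n = 200)
  x <- cbind(pn$x, dup = pn$x[, 1] * 2)
  d <- demean_multiway(cbind(pn$y, x), pn$fe)
  # exercised through the design/fit surface
  sp <- data.frame(speech_id = as.character(1:200),
                   speaker_id = rep(c("p1", "p2"), 100),
                   city = "A",
                   date = as.Date("2010-06-01") + rep(0:49, 4),
                   flesch_kincaid = pn$y)
  w <- data.frame(city = "A", date = as.Date("2010-06-01") + 0:49,
                  t_mean = runif(50, -5, 35), t_dew = 5, precip = 0,
                  u_wind = 1, v_wind = 1)
  w <- derive_weather(w)
  des <- build_design(sp, w, controls = c("precip", "rh", "wind_speed"))
  f <- fit_fe_ols(des)
  # precip and wind_speed are constants here -> demean to zero -> pruned
  expect_true(all(c("precip", "wind_speed") %in% f$dropped_terms))
  expect_false("precip" %in% names(f$beta))
})

test_that("permuting bins within city-month drives coefficients to zero", {
  labels <- bin_scheme("full")$labels
  cfg0 <- sim_config(n_politicians = 30, cities = c("C1", "C2"),
                     start_date = "2008-01-01", end_date = "2010-12-31",
                     speeches_per_sitting_day = 2, seed = 1)
  rejections <- c()
  set.seed(28)
  for (panel_i in 1:3) {
    cfg <- cfg0
    cfg$seed <- 300L + panel_i
    p <- simulate_panel(cfg)
    w <- p$weather
    ym <- paste(w$city, format(w$date, "%Y-%m"))
    for (perm in 1:25) {
      w$temp_bin <- ave(as.character(w$temp_bin), ym,
                        FUN = function(v) sample(v))
      w$temp_bin <- factor(w$temp_bin, levels = labels)
      f <- fit_fe_ols(build_design(p$speeches, w))
      z <- f$beta[grepl("^bin_", names(f$beta))] /
        f$se[grepl("^bin_", names(f$beta))]
      rejections <- c(rejections, abs(z) > qnorm(0.975))
    }
  }
  rate <- mean(rejections)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("age quartiles follow the study's cut points", {
  expect_equal(as.character(assign_age_quartile(c(19, 44, 45, 50, 51, 56, 57, 80))),
               c("19-44", "19-44", "45-50", "45-50", "51-56", "51-56",
                 "57+", "57+"))
  expect_true(is.na(assign_age_quartile(NA)))
  expect_error(assign_age_quartile(15), "out of range")
})

test_that("study periods use closed year ranges", {
  expect_equal(as.character(assign_period(c(1950, 1967, 1968, 1985, 1986,
                                            2003, 2004, 2019))),
               c("1950-1967", "1950-1967", "1968-1985", "1968-1985",
                 "1986-2003", "1986-2003", "2004-2019", "2004-2019"))
  expect_error(assign_period(1949), "study span")
  expect_error(assign_period(2020), "study span")
})

test_that("interaction fit recovers level-specific effects exactly at zero noise", {
  cfg <- sim_config(n_politicians = 24, cities = c("C1", "C2"),
                    start_date = "2010-01-01", end_date = "2011-12-31",
                    speeches_per_sitting_day = 3, noise_sd = 0, seed = 17)
  p <- simulate_panel(cfg)
  sp <- p$speeches
  dem <- p$politicians
  sp$gender <- dem$gender[match(sp$speaker_id, dem$speaker_id)]
  # inject a gender-specific extra heat effect
  hot <- as.character(p$weather$temp_bin[
    match(paste(sp$city, sp$date), paste(p$weather$city, p$weather$date))])
  shift <- ifelse(sp$gender == "male" & hot == ">27", -0.10, 0)
  sp$flesch_kincaid <- sp$flesch_kincaid + shift
  des <- build_design(sp, p$weather, demographic = "gender")
  out <- fit_interaction(des)
  me <- out$marginal_effects
  male_hot <- me[me$bin == ">27" & me$level == "male", ]
  female_hot <- me[me$bin == ">27" & me$level == "female", ]
  expect_equal(male_hot$estimate, -0.05 - 0.10, tolerance = 1e-7)
  expect_equal(female_hot$estimate, -0.05, tolerance = 1e-7)
})

test_that("a one-level demographic degenerates to the plain fit", {
  cfg <- sim_config(n_politicians = 12, cities = "C1",
                    start_date = "2010-01-01", end_date = "2010-12-31",
                    speeches_per_sitting_day = 3, seed = 5)
  p <- simulate_panel(cfg)
  des <- build_design(p$speeches, p$weather)
  plain <- fit_fe_ols(des)
  one <- fit_interaction(des, demographic = rep("all", length(des$outcome)))
  bins <- names(plain$beta)[grepl("^bin_", names(plain$beta))]
  expect_equal(one$marginal_effects$estimate,
               as.numeric(plain$beta[paste0("bin_", one$marginal_effects$bin)]))
})

test_that("minority demographic levels get wider confidence intervals", {
  cfg <- sim_config(n_politicians = 60, cities = c("C1", "C2"),
                    start_date = "2008-01-01", end_date = "2011-12-31",
                    speeches_per_sitting_day = 4, seed = 31)
  p <- simulate_panel(cfg)
  sp <- p$speeches
  sp$gender <- p$politicians$gender[match(sp$speaker_id,
                                          p$politicians$speaker_id)]
  des <- build_design(sp, p$weather, cluster = "politician",
                      demographic = "gender")
  me <- fit_interaction(des)$marginal_effects
  mean_se <- tapply(me$se, me$level, mean, na.rm = TRUE)
  expect_gt(mean_se[["female"]], mean_se[["male"]])
})

test_that("empty exposure-by-level cells are reported as missing", {
  cfg <- sim_config(n_politicians = 20, cities = "C1",
                    start_date = "2010-01-01", end_date = "2010-12-31",
                    speeches_per_sitting_day = 3,
                    demographics = list(p_female = 0, age_range = c(25, 70)),
                    seed = 9)
  p <- simulate_panel(cfg)
  sp <- p$speeches
  sp$gender <- p$politicians$gender[match(sp$speaker_id,
                                          p$politicians$speaker_id)]
  # add a single female speech so the level exists but most cells are empty
  sp$gender[1] <- "female"
  des <- build_design(sp, p$weather, demographic = "gender")
  me <- fit_interaction(des)$marginal_effects
  fem <- me[me$level == "female", ]
  expect_true(any(is.na(fem$estimate)))
  expect_true(all(fem$n_cell[is.na(fem$estimate)] == 0))
})
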