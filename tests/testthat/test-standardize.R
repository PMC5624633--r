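test_that("area assignment follows latitude, the boundary convention, and port", {
  expect_equal(assign_area(lat = c(25, 23)), c("north", "south"))
  expect_equal(assign_area(lat = 24.3), "north") # >= cutoff is north
  expect_equal(assign_area(port = c("Suao", "Singang", "Tungkang")),
               c("north", "south", "south"))
  expect_equal(assign_area(lat = c(NA, 25), port = c("Suao", "Tungkang")),
               c("north", "north"))
  expect_error(assign_area(lat = NA_real_, port = NA_character_), "neither")
})

test_that("trip aggregation sums events, filters season, and reports rejects", {
  effort <- data.frame(trip_id = c("T1", "T2"),
                       year = 2005, month = c(6, 4), area = "south",
                       vessel_class = "CT2", fishing_days = c(5, 7))
  events <- data.frame(trip_id = c("T1", "T1", "T1", "T2", "TX"))
  out <- aggregate_trips(events, effort)
  expect_equal(nrow(out), 1L)            # T2 is April; TX is orphan
  expect_equal(out$catch_n, 3)
  expect_equal(out$cpue, 0.6)
  expect_equal(unname(attr(out, "n_excluded")["out_of_season"]), 1L)
  expect_equal(nrow(attr(out, "rejects")), 1L)
  expect_error(aggregate_trips(events,
                               transform(effort, fishing_days = c(0, 7))),
               "positive")
})

test_that("deterministic delta data recover the generating year effects", {
  cfg <- sim_config(seed = 71, n_trips = 3000, p_zero = 0, pcm_logsd = 0)
  cp <- gen_cpue(cfg)
  fits <- fit_delta_models(
    cp, spec_zpm = list(fixed = c("year", "month", "area")),
    spec_pcm = list(fixed = c("year", "month", "area")))
  ls_p <- suppressWarnings(lsmeans_year(fits$pcm)) # deterministic: perfect fit
  # PCM year LSmeans reproduce log year effects up to a constant
  truth <- log(cfg$year_effects[ls_p$year])
  expect_lt(max(abs((ls_p$estimate - truth) -
                    mean(ls_p$estimate - truth))), 1e-6)
  # all-positive data sit on the separation boundary of the binomial fit,
  # so check the fitted probabilities directly
  p_hat <- tapply(stats::fitted(fits$zpm$fit), fits$zpm$data$year, mean)
  expect_true(all(p_hat > 0.99))
})

test_that("single-year data and positive-free years are rejected with diagnostics", {
  cfg <- sim_config(seed = 72, n_trips = 200,
                    year_effects = c(`2001` = 1))
  expect_error(fit_delta_component(gen_cpue(cfg), "PCM"),
               "two year levels")
  cfg2 <- sim_config(seed = 73, n_trips = 400,
                     year_effects = c(`2001` = 1, `2002` = 1),
                     p_zero = data.frame(year = c("2001", "2002"),
                                         p_zero = c(0, 1)))
  expect_error(fit_delta_component(gen_cpue(cfg2), "PCM"), "2002")
})

test_that("stepwise selection drops absent effects and keeps real interactions", {
  # no vessel-class effect in the generator -> class eliminated
  cfg <- sim_config(seed = 74, n_trips = 5000)
  cp <- gen_cpue(cfg)
  sel <- suppressMessages(stepwise_select(cp, "PCM", "BIC"))
  expect_false("vessel_class" %in% sel$fixed)
  expect_true("year" %in% sel$fixed)
  expect_lte(sel$bic,
             fit_delta_component(cp, "PCM",
                                 fixed = c("year", "month", "vessel_class"))$bic)
  # a single candidate comes back unchanged
  one <- suppressMessages(stepwise_select(cp, "PCM", "AIC",
                                          candidates_fixed = character(0),
                                          candidates_random = character(0)))
  expect_equal(one$fixed, "year")
})

test_that("a strong year-month interaction is retained as a random term", {
  # amplify month effects differently per year via a year-varying p of
  # positive CPUE magnitude: build records directly with an interaction
  set.seed(75)
  n <- 6000
  year <- sample(as.character(2001:2004), n, replace = TRUE)
  month <- sample(5:7, n, replace = TRUE)
  dev <- matrix(rnorm(12, 0, 0.8), nrow = 4,
                dimnames = list(2001:2004, 5:7))
  mu <- log(2) + as.numeric(dev[cbind(year, as.character(month))])
  cp <- data.frame(trip_id = as.character(1:n), year = as.integer(year),
                   month = month, area = "south", vessel_class = "CT2",
                   fishing_days = 10,
                   catch_n = 10 * exp(mu + rnorm(n, 0, 0.3)))
  sel <- suppressMessages(
    stepwise_select(cp, "PCM", "AIC", candidates_fixed = "month",
                    candidates_random = "year:month"))
  expect_true("year:month" %in% sel$random)
})

test_that("LSmeans weighting follows observation counts with fixed margins", {
  # two months weighted 3:1 -> LSmean = 0.75 cell(m5) + 0.25 cell(m6)
  set.seed(76)
  d <- expand.grid(year = c(2001, 2002), month = c(5, 6))
  d <- d[rep(1:4, times = c(30, 30, 10, 10)), ]
  cell_mu <- c(`2001.5` = 1, `2002.5` = 2, `2001.6` = 4, `2002.6` = 3)
  mu <- cell_mu[paste(d$year, d$month, sep = ".")]
  cp <- data.frame(trip_id = as.character(seq_len(nrow(d))),
                   year = d$year, month = d$month, area = "south",
                   vessel_class = "CT2", fishing_days = 1,
                   catch_n = exp(mu))
  # saturated fixed model reproduces the cells exactly
  fit <- fit_delta_component(cp, "PCM", fixed = c("year", "month"))
  fit$fit <- stats::lm(log_cpue ~ year * month, data = fit$data)
  ls <- suppressWarnings(lsmeans_year(fit)) # saturated exact fit
  expect_equal(ls$estimate, c(0.75 * 1 + 0.25 * 4, 0.75 * 2 + 0.25 * 3),
               tolerance = 1e-8)
  ls_eq <- suppressWarnings(lsmeans_year(fit, weights = "equal"))
  expect_equal(ls_eq$estimate, c(2.5, 2.5), tolerance = 1e-8)
})

test_that("bias-corrected index: closed forms, scaling, and CI behaviour", {
  idx <- bias_corrected_index(p_pos = 1, mu = 0, sigma2 = 0)
  expect_equal(idx$index, 1)
  idx2 <- bias_corrected_index(p_pos = 1, mu = 0, sigma2 = 2)
  expect_equal(idx2$index, exp(1))
  expect_error(bias_corrected_index(1, 0, -1), "nonnegative")
  # relative index averages one and is invariant to a constant log shift
  idx3 <- bias_corrected_index(p_pos = c(0.5, 0.8), mu = c(0, 1),
                               sigma2 = 0.4, se_mu = c(0.1, 0.1),
                               se_p = c(0.05, 0.05))
  expect_equal(mean(idx3$relative_index), 1)
  idx4 <- bias_corrected_index(p_pos = c(0.5, 0.8), mu = c(0, 1) + 3,
                               sigma2 = 0.4)
  expect_equal(idx4$relative_index, idx3$relative_index)
  expect_true(all(idx3$lo <= idx3$index & idx3$index <= idx3$hi))
})

test_that("a doubled year effect doubles the relative index within noise", {
  cfg <- sim_config(seed = 77, n_trips = 6000,
                    year_effects = c(`2001` = 0.5, `2002` = 1.0),
                    p_zero = 0.2, pcm_logsd = 0.5)
  cp <- gen_cpue(cfg)
  std <- suppressMessages(standardize_cpue(
    cp, specs = list(zpm = list(fixed = c("year", "month")),
                     pcm = list(fixed = c("year", "month")))))
  ratio <- std$index$index[2] / std$index$index[1]
  expect_lt(abs(ratio - 2), 0.25)
})

test_that("residual diagnostics accept normal PCM residuals and flag degeneracy", {
  cfg <- sim_config(seed = 78, n_trips = 3000)
  std <- suppressMessages(standardize_cpue(
    gen_cpue(cfg),
    specs = list(zpm = list(fixed = c("year", "month")),
                 pcm = list(fixed = c("year", "month")))))
  diag <- residual_diagnostics(std$pcm, seed = 5)
  expect_false(diag$degenerate)
  expect_gt(diag$ks$p_value, 0.10) # lognormal generator: normal log residuals
  # degenerate: zero residuals
  cfg0 <- sim_config(seed = 79, n_trips = 500, p_zero = 0, pcm_logsd = 0,
                     month_effects = c(`5` = 1), area_effects = c(south = 1))
  fit0 <- fit_delta_component(gen_cpue(cfg0), "PCM", fixed = "year")
  expect_true(residual_diagnostics(fit0)$degenerate)
})
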