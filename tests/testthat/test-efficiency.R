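test_that("Abbott efficiency arithmetic and scale invariance", {
  expect_equal(abbott_efficiency(24, 24), 0)
  expect_equal(abbott_efficiency(20, 0), 100)
  expect_equal(abbott_efficiency(23, 14), 100 * 9 / 23)
  # treatment survival above control: legitimately negative
  expect_lt(abbott_efficiency(20, 22), 0)
  # scale-free: multiplying both counts by k changes nothing
  expect_equal(abbott_efficiency(5 * 23, 5 * 14), abbott_efficiency(23, 14))
  expect_error(abbott_efficiency(0, 3), "alive_control")
})

test_that("treatment-control pairing respects temperature and seed", {
  cfg <- simulation_config(seed = 77)
  gen <- generate_efficiency_dataset(cfg)
  rec <- pair_treatments_controls(gen$trials, seed = 5)
  # 16 treatments per temperature, each matched within its temperature
  expect_equal(as.integer(table(rec$temperature_C)), rep(16L, 3))
  expect_equal(nrow(rec), 48L)
  expect_true(all(!is.na(rec$copepod_mass_mg)))
  # each of the 8 controls serves exactly two treatments
  for (temp in c(15, 20, 25)) {
    ctl_used <- sub(".*\\|", "", rec$pair_id[rec$temperature_C == temp])
    expect_true(all(table(ctl_used) == 2))
  }
  # determinism
  rec2 <- pair_treatments_controls(gen$trials, seed = 5)
  expect_identical(rec, rec2)
  expect_false(identical(rec$pair_id,
                         pair_treatments_controls(gen$trials, seed = 6)$pair_id))

  # minimal case and missing-control error
  mini <- gen$trials[gen$trials$trial_id %in%
                       c("PE_none_15_c1", "PE_M_albidus_15_r1"), ]
  expect_equal(nrow(pair_treatments_controls(mini, 1)), 1L)
  no_ctl <- gen$trials[gen$trials$predator_count == 1, ]
  expect_error(pair_treatments_controls(no_ctl, 1), "no controls")
})

test_that("OLS machinery: exact fits, orthogonality, nested AIC identity", {
  set.seed(8)
  d <- data.frame(
    efficiency_pct = NA, species = rep(c("M_albidus", "M_viridis"), 24),
    temperature_C = rep(c(15, 20, 25), 16),
    copepod_mass_mg = runif(48, 0.1, 0.8)
  )
  # exact linear data: perfect fit
  d$efficiency_pct <- 10 + 30 * d$copepod_mass_mg
  exact <- suppressWarnings(fit_ols(efficiency_pct ~ copepod_mass_mg, d))
  expect_equal(exact$r_squared, 1)
  expect_lt(max(abs(residuals(exact$lm))), 1e-10)

  # intercept-only model estimates the mean
  d$efficiency_pct <- d$efficiency_pct + rnorm(48, 0, 5)
  int_only <- fit_ols(efficiency_pct ~ 1, d)
  expect_equal(int_only$terms$estimate, mean(d$efficiency_pct))

  # residuals orthogonal to every design column
  full <- fit_ols(efficiency_pct ~ copepod_mass_mg + species + temperature_C, d)
  X <- model.matrix(full$lm)
  expect_lt(max(abs(crossprod(X, residuals(full$lm)))), 1e-8)

  # reference levels: coefficients are contrasts against albidus and 15 C
  expect_true(all(c("speciesM_viridis", "temperature_C20", "temperature_C25")
                  %in% full$terms$term))

  # adding a predictor never increases RSS; Gaussian AIC identity holds
  small <- fit_ols(efficiency_pct ~ copepod_mass_mg, d)
  rss_small <- sum(residuals(small$lm)^2)
  rss_full <- sum(residuals(full$lm)^2)
  expect_lte(rss_full, rss_small + 1e-10)
  dk <- length(coef(full$lm)) - length(coef(small$lm))
  expect_equal(small$AIC - full$AIC,
               small$n * log(rss_small / rss_full) - 2 * dk,
               tolerance = 1e-8)

  # rank deficiency is reported, not silently dropped
  d$dup <- d$copepod_mass_mg
  expect_error(fit_ols(efficiency_pct ~ copepod_mass_mg + dup, d), "aliased")
})

test_that("AIC-based selection applies the minimum-difference rule", {
  set.seed(9)
  d <- data.frame(copepod_mass_mg = runif(47, 0.1, 0.8),
                  species = rep(c("M_albidus", "M_viridis"), length.out = 47))
  d$efficiency_pct <- 10 + 34 * d$copepod_mass_mg + rnorm(47, 0, 10)
  fits <- list(mass = fit_ols(efficiency_pct ~ copepod_mass_mg, d),
               species = fit_ols(efficiency_pct ~ species, d),
               both = fit_ols(efficiency_pct ~ copepod_mass_mg + species, d))
  sel <- model_selection(fits)
  expect_equal(sel$AIC, sort(sel$AIC))
  expect_equal(sel$delta_AIC[1], 0)

  # the published-style gap: 358.5 vs 362.6 prefers the first (delta 4.1)
  fake <- fits
  fake$mass$AIC <- 358.5; fake$species$AIC <- 362.6; fake$both$AIC <- 400
  sel2 <- model_selection(fake)
  expect_equal(attr(sel2, "selected"), "mass")
  expect_equal(sel2$preferred, c(TRUE, FALSE, FALSE))

  # delta below 2: flagged tie, no selection
  fake$species$AIC <- 360.0
  sel3 <- model_selection(fake)
  expect_true(attr(sel3, "tie"))
  expect_true(is.na(attr(sel3, "selected")))
  expect_false(any(sel3$preferred))

  # mismatched response vectors are rejected
  d2 <- d; d2$efficiency_pct <- d2$efficiency_pct + 1
  expect_error(model_selection(list(a = fits$mass,
                                    b = fit_ols(efficiency_pct ~ species, d2))),
               "same response")
})

test_that("distribution summary uses moment skewness and plain kurtosis", {
  sym <- describe_distribution(c(-1, 0, 1))
  expect_equal(sym$skewness, 0)
  expect_equal(sym$median, 0)

  # convention check: large normal sample has kurtosis about 3 (not 0)
  set.seed(10)
  z <- rnorm(200000)
  dd <- describe_distribution(z)
  expect_equal(dd$kurtosis, 3, tolerance = 0.05)
  expect_equal(dd$skewness, 0, tolerance = 0.05)

  expect_error(describe_distribution(rep(2, 10)), "undefined")
  expect_error(describe_distribution(c(1, 2)), "n >= 3")
})
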