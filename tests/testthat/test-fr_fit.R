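test_that("depletion solution reproduces its closed-form limits", {
  # b = 0: pure exponential background mortality
  p <- fr_params(0, 0, 0.5, 0.04)
  expect_equal(predict_remaining(c(1, 8, 32), p, P = 1, T = 6),
               c(1, 8, 32) * exp(-0.04 * 6), tolerance = 1e-10)
  expect_equal(predict_remaining(32, p, P = 1, T = 6, method = "ode"),
               32 * exp(-0.24), tolerance = 1e-6)

  # h = 0, m = 0: exponential predation
  p2 <- fr_params(0.3, 0, 0, 0)
  expect_equal(predict_remaining(c(2, 16), p2, P = 1, T = 6),
               c(2, 16) * exp(-0.3 * 6), tolerance = 1e-10)
  expect_equal(predict_remaining(16, p2, P = 1, T = 6, method = "ode"),
               16 * exp(-1.8), tolerance = 1e-6)

  # h = 0 with mortality: hazards add
  p3 <- fr_params(0.3, 0, 0, 0.02)
  expect_equal(predict_remaining(24, p3), 24 * exp(-(0.3 + 0.02) * 6),
               tolerance = 1e-10)
})

test_that("Rogers closed form agrees with brute-force RK4 integration", {
  expect_equal(rogers_remaining(32, 1, 0.5, 1, 6),
               rk4_remaining(32, 1, 0, 0.5, 0, 1, 6),
               tolerance = 1e-6)
  # with background mortality the analytic implicit solution must match too
  expect_equal(predict_remaining(32, fr_params(0.8, 0, 0.5, 0.05)),
               rk4_remaining(32, 0.8, 0, 0.5, 0.05, 1, 6),
               tolerance = 1e-6)
  expect_equal(predict_remaining(8, fr_params(2, 0, 1, 0.02)),
               rk4_remaining(8, 2, 0, 1, 0.02, 1, 6),
               tolerance = 1e-6)
  # type III dynamics through the ODE path
  expect_equal(predict_remaining(16, fr_params(0.1, 1, 0.3, 0.01)),
               rk4_remaining(16, 0.1, 1, 0.3, 0.01, 1, 6),
               tolerance = 1e-5)
})

test_that("remaining prey is monotone in time and in each hazard input", {
  N0 <- 24
  base <- list(b = 0.6, h = 0.5, m = 0.02)
  rem_at <- function(b = base$b, h = base$h, m = base$m, P = 1, T = 6) {
    predict_remaining(N0, fr_params(b, 0, h, m), P = P, T = T)
  }
  Ts <- c(0.5, 1, 2, 4, 6, 12)
  expect_true(all(diff(vapply(Ts, function(T) rem_at(T = T),
                              numeric(1))) < 0))
  bs <- c(0.05, 0.2, 0.8, 3)
  expect_true(all(diff(vapply(bs, function(b) rem_at(b = b),
                              numeric(1))) < 0))
  ms <- c(0, 0.01, 0.05, 0.2)
  expect_true(all(diff(vapply(ms, function(m) rem_at(m = m),
                              numeric(1))) < 0))
  expect_lt(rem_at(P = 1), rem_at(P = 0))
  # bounds: always within (0, N0]
  for (b in c(0.1, 1, 10)) {
    r <- rem_at(b = b)
    expect_gt(r, 0); expect_lte(r, N0)
  }
})

test_that("the two likelihood variants agree at m = 0", {
  # with m = 0 and deathless controls, the pooled likelihood reduces to the
  # treatment-only zero-mortality likelihood (controls contribute ~0)
  trials <- make_group_trials(fr_params(1, 0, 0.5, 0), seed = 31)
  trt <- trials[trials$predator_count == 1, ]
  for (bh in list(c(0.7, 0.4), c(1, 0.5), c(2, 0.2))) {
    p <- fr_params(bh[1], 0, bh[2], 0)
    expect_equal(nll_no_mortality(p, trt), nll_with_mortality(p, trials),
                 tolerance = 1e-9)
  }
  # guards: the no-mortality variant rejects controls and nonzero m
  expect_error(nll_no_mortality(fr_params(1, 0, 0.5, 0), trials),
               "predator-present")
  expect_error(nll_no_mortality(fr_params(1, 0, 0.5, 0.01), trt), "m = 0")
  expect_error(nll_with_mortality(fr_params(1, 0, 0.5, 0.01), trt),
               "control")
})

test_that("likelihood structure: saturation bound and b-unidentifiability", {
  trials <- make_group_trials(fr_params(0.8, 0, 0.5, 0.01), seed = 33)
  dat_trt <- trials[trials$predator_count == 1, ]

  # NLL is never below the saturated binomial NLL
  D <- dat_trt$initial_count - dat_trt$survivors
  N0 <- dat_trt$initial_count
  p_hat <- pmin(pmax(D / N0, 1e-12), 1 - 1e-12)
  saturated <- -sum(dbinom(D, N0, p_hat, log = TRUE))
  for (b in c(0.2, 0.8, 3)) {
    expect_gte(nll_no_mortality(fr_params(b, 0, 0.5, 0), dat_trt),
               saturated - 1e-9)
  }

  # a single control dish whose mortality is matched exactly attains the
  # saturated minimum
  one <- make_toy_trials(2)[2, ]                # a control row
  one$initial_count <- 16
  one$survivors <- 12
  m_exact <- -log(12 / 16) / one$duration_h
  attained <- nll_with_mortality(fr_params(0, 0, 0.5, m_exact), one)
  expect_equal(attained, -dbinom(4, 16, 4 / 16, log = TRUE),
               tolerance = 1e-8)

  # controls only: likelihood does not depend on b
  ctl <- trials[trials$predator_count == 0, ]
  expect_equal(nll_with_mortality(fr_params(0.1, 0, 0.5, 0.01), ctl),
               nll_with_mortality(fr_params(5, 0, 0.5, 0.01), ctl))
})

test_that("controls-only mortality MLE equals its closed form", {
  trials <- make_group_trials(fr_params(0.8, 0, 0.5, 0.03), seed = 35)
  ctl <- trials[trials$predator_count == 0, ]
  # closed form: total deaths over total exposure, i.e.
  # m_hat solves mean survival fraction = exp(-m T) weighted by N0
  surv_frac <- sum(ctl$survivors) / sum(ctl$initial_count)
  m_closed <- -log(surv_frac) / ctl$duration_h[1]
  m_mle <- optimize(function(m)
    nll_with_mortality(fr_params(0, 0, 0.5, m), ctl),
    interval = c(1e-6, 1), tol = 1e-9)$minimum
  expect_equal(m_mle, m_closed, tolerance = 1e-5)
})

test_that("fit_group selects the mortality variant from the data", {
  # zero control deaths force the zero-mortality variant
  trials <- make_group_trials(fr_params(1, 0, 0.5, 0), seed = 41)
  expect_equal(sum(trials$initial_count[trials$predator_count == 0] -
                     trials$survivors[trials$predator_count == 0]), 0)
  set.seed(41)
  fit <- fit_group(trials, 0)
  expect_equal(fit$variant, "no_mortality")
  expect_equal(fit$params$m, 0)
  expect_equal(fit$deviance, 2 * fit$nll)

  # strong mortality is detected and retained
  trials2 <- make_group_trials(fr_params(1, 0, 0.5, 0.05), seed = 42)
  set.seed(42)
  fit2 <- fit_group(trials2, 0)
  expect_equal(fit2$variant, "with_mortality")
  expect_lt(fit2$mortality_p, 0.05)
  expect_true(fit2$converged)
})

test_that("data generated at the starting values are recovered", {
  # truth equals the optimizer's conventional starts (b = 1, m = 0.01)
  trials <- make_group_trials(fr_params(1, 0, 0.5, 0.01), seed = 43)
  set.seed(43)
  fit <- fit_group(trials, 0)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$b - 1), 3 * fit$wald_se["b"] + 1e-9)
  expect_lt(abs(fit$params$h - 0.5), 3 * fit$wald_se["h"] + 1e-9)
})

test_that("profile bounds reproduce the analytic Gaussian interval", {
  est <- 1.3; se <- 0.2; nll0 <- 5
  quad_nll <- function(theta) nll0 + (theta - est)^2 / (2 * se^2)
  ci <- profile_bounds(quad_nll, est, nll0, level = 0.95, tol = 1e-10)
  z <- qnorm(0.975)
  expect_equal(unname(ci["low"]), est - z * se, tolerance = 1e-6)
  expect_equal(unname(ci["high"]), est + z * se, tolerance = 1e-6)

  # a flat profile is reported unbounded
  flat <- profile_bounds(function(theta) nll0, est, nll0)
  expect_true(all(is.na(flat)))
  expect_false(any(attr(flat, "bounded")))
})

test_that("profile interval brackets the MLE on fitted data", {
  trials <- make_group_trials(fr_params(0.8, 0, 0.5, 0), seed = 45)
  set.seed(45)
  fit <- fit_group(trials, 0)
  for (par in c("b", "h")) {
    ci <- profile_ci(fit, par)
    expect_lt(ci["low"], fit$params[[par]])
    expect_gt(ci["high"], fit$params[[par]])
  }
})

test_that("group comparison calls significance only for disjoint intervals", {
  mk_fit <- function(lo, hi) {
    list(profile_ci = list(b = structure(
      c(low = lo, high = hi),
      bounded = c(low = !is.na(lo), high = !is.na(hi)), level = 0.95)))
  }
  fits <- list(g1 = mk_fit(1, 2), g2 = mk_fit(1.5, 2.5), g3 = mk_fit(3, 4),
               g4 = mk_fit(NA, NA))
  cmp <- compare_groups(fits, "b")
  expect_true(cmp$overlap["g1", "g2"])
  expect_false(cmp$overlap["g1", "g3"])
  expect_true(cmp$significant["g1", "g3"])
  # unbounded interval conservatively overlaps everything and is flagged
  expect_true(all(cmp$overlap["g4", ]))
  expect_true(cmp$unbounded["g4"])
  # identical fits never differ
  same <- compare_groups(list(a = mk_fit(1, 2), b = mk_fit(1, 2)), "b")
  expect_false(any(same$significant, na.rm = TRUE))
})

test_that("likelihood at the truth beats a doubled attack coefficient", {
  # KL ordering: on data generated at the truth, the expected NLL is lower
  # at the truth than at any other parameter value, so across replicates
  # the mean NLL advantage must be clearly positive and the truth should
  # win in a clear majority of single-group datasets
  truth <- fr_params(0.8, 0, 0.5, 0.01)
  wrong <- fr_params(1.6, 0, 0.5, 0.01)
  diffs <- vapply(1:100, function(s) {
    trials <- make_group_trials(truth, seed = 1200 + s)
    nll_with_mortality(wrong, trials) - nll_with_mortality(truth, trials)
  }, numeric(1))
  expect_gt(mean(diffs) / (sd(diffs) / sqrt(length(diffs))), 3)
  expect_gte(mean(diffs >= 0), 0.75)
})

test_that("groups sharing true parameters rarely differ significantly", {
  truth <- fr_params(1, 0, 0.5, 0)
  no_diff <- vapply(1:25, function(s) {
    fits <- lapply(c(7000 + s, 8000 + s), function(sd) {
      trials <- make_group_trials(truth, seed = sd)
      set.seed(sd)
      fit <- fit_group(trials, 0)
      fit$profile_ci <- list(b = profile_ci(fit, "b"),
                             h = profile_ci(fit, "h"))
      fit
    })
    names(fits) <- c("g1", "g2")
    !any(compare_groups(fits, "b")$significant, na.rm = TRUE) &&
      !any(compare_groups(fits, "h")$significant, na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(no_diff), 0.9)
})
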