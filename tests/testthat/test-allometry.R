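test_that("length-to-mass follows the allometric power law and is monotone", {
  expect_identical(length_to_mass(1), 0.055)
  expect_equal(length_to_mass(2), 0.055 * 2^2.73)
  expect_equal(length_to_mass(c(1.3, 2.5)), 0.055 * c(1.3, 2.5)^2.73)

  # limit: mass vanishes with length
  expect_lt(length_to_mass(1e-8), 1e-20)

  # strict monotonicity: mass ordering equals length ordering
  set.seed(1)
  lens <- runif(50, 0.5, 3.5)
  expect_equal(order(length_to_mass(lens)), order(lens))

  expect_error(length_to_mass(0), "positive")
  expect_error(length_to_mass(-1), "positive")
})

test_that("Shapiro-Wilk gate behaves on clean and skewed samples", {
  norm50 <- qnorm(ppoints(50))          # exact normal quantiles
  res <- shapiro_wilk(norm50)
  expect_gt(res$W, 0.98)
  expect_gt(res$p, 0.05)

  set.seed(42)
  rejections <- sum(vapply(1:20, function(i) {
    shapiro_wilk(rexp(50))$p < 0.05
  }, logical(1)))
  expect_gte(rejections, 16)            # large majority of skewed samples

  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})

test_that("rank-sum test matches exhaustive enumeration and symmetry", {
  # identical multisets: no evidence of a shift
  x <- c(1, 2, 3, 4)
  res <- wilcoxon_rank_sum(x, x)
  expect_gt(res$p_value, 0.9)

  # full separation gives the smallest attainable p for this n
  sep <- wilcoxon_rank_sum(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_lt(sep$p_value, 0.05)

  # normal approximation vs exact enumeration over all 70 assignments
  cases <- list(
    list(x = c(1.2, 3.4, 5.1, 2.2), y = c(4.0, 6.5, 7.1, 2.9)),
    list(x = c(10, 20, 30, 40), y = c(15, 25, 60, 70)),
    list(x = c(0.1, 0.15, 0.2, 0.7), y = c(0.35, 0.5, 0.9, 1.4))
  )
  for (cs in cases) {
    approx_p <- wilcoxon_rank_sum(cs$x, cs$y)$p_value
    exact_p <- exact_wilcoxon_p(cs$x, cs$y)
    expect_lt(abs(approx_p - exact_p), 0.02)
  }

  # statistic is invariant under strictly increasing transformations
  set.seed(3)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  expect_equal(wilcoxon_rank_sum(exp(a), exp(b))$statistic,
               wilcoxon_rank_sum(a, b)$statistic)

  expect_error(wilcoxon_rank_sum(1, c(1, 2)), "n >= 2")
})

test_that("Welch test reproduces the hand-computed statistic and df", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  res <- welch_t(x, y)
  # hand computation: t = (2 - 3)/sqrt(1/3 + 1/3), Satterthwaite df = 4
  expect_equal(res$statistic, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(attr(res, "df"), 4, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-1 / sqrt(2 / 3), 4), tolerance = 1e-12)

  # identical samples: t = 0, p = 1
  same <- welch_t(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # equal n and equal variances collapse df to n1 + n2 - 2
  x2 <- c(0, 1, 2, 3); y2 <- x2 + 10
  expect_equal(attr(welch_t(x2, y2), "df"), 6, tolerance = 1e-12)

  expect_error(welch_t(rep(1, 3), rep(1, 3)), "constant")
})

test_that("normality gate selects Welch for normal, Wilcoxon for skewed", {
  clean1 <- qnorm(ppoints(30), 1, 0.2)
  clean2 <- qnorm(ppoints(30), 1.4, 0.25)
  expect_equal(choose_and_run_test(clean1, clean2)$test_name, "welch_t")

  skewed <- qexp(ppoints(30))^3
  res <- choose_and_run_test(clean1, skewed)
  expect_equal(res$test_name, "wilcoxon_rank_sum")
  expect_lt(res$normality_gate$y$p, 0.05)

  # alpha = 0: the gate can never reject, so Welch always runs
  expect_equal(choose_and_run_test(clean1, skewed, alpha = 0)$test_name,
               "welch_t")
})

test_that("random pairing count, determinism and difference arithmetic", {
  mk <- function(n, len) data.frame(
    copepod_id = paste0("c", seq_len(n)), species = "x", experiment = "FR",
    length_mm = len, stringsAsFactors = FALSE)

  # equal groups pair everyone; unequal groups pair the minimum
  expect_equal(random_species_pairing(mk(80, 1.7), mk(80, 2.1), 1)$n_pairs, 80)
  expect_equal(random_species_pairing(mk(24, 1.8), mk(23, 2.2), 1)$n_pairs, 23)

  # 1 + 1 records: the single difference is the mass difference
  single <- random_species_pairing(mk(1, 1.5), mk(1, 2.5), 7)
  expect_equal(single$differences,
               length_to_mass(2.5) - length_to_mass(1.5))

  # same seed reproduces; different seeds keep the count
  set.seed(123)
  alb <- mk(30, runif(30, 1.3, 2.5)); vir <- mk(40, runif(40, 1.2, 3.0))
  p1 <- random_species_pairing(alb, vir, seed = 9)
  p2 <- random_species_pairing(alb, vir, seed = 9)
  p3 <- random_species_pairing(alb, vir, seed = 10)
  expect_identical(p1$differences, p2$differences)
  expect_equal(length(p3$differences), length(p1$differences))

  expect_error(random_species_pairing(mk(3, 1:3 / 2)[0, ], mk(3, 1:3 / 2), 1),
               "at least one")
})
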