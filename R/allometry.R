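# Length-to-mass conversion and body-size statistical comparisons.

.mass_coefficient <- 0.055
.mass_exponent <- 2.73

#' Convert copepod body length to estimated body mass
#'
#' Allometric power law for cyclopoid copepods: mass (mg) =
#' 0.055 x length (mm) ^ 2.73.  Strictly increasing in length, so mass
#' ordering always reproduces length ordering.
#'
#' @param length_mm body length in mm, measured from the front of the
#'   cephalosome to the end of the last urosomite; positive.
#' @return estimated body mass in mg.
#' @export
#' @examples
#' length_to_mass(1.0)   # 0.055 mg
#' length_to_mass(2.0)
length_to_mass <- function(length_mm) {
  if (any(is.na(length_mm)) || any(length_mm <= 0)) {
    stop("length_mm must be positive")
  }
  .mass_coefficient * length_mm^.mass_exponent
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper over \code{stats::shapiro.test} (Royston's approximation,
#' valid for 3 <= n <= 5000) returning just the pieces the test-selection
#' gate needs.
#'
#' @param values numeric sample, non-constant, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) stop("shapiro_wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("shapiro_wilk undefined for constant sample")
  res <- stats::shapiro.test(values)
  list(W = unname(res$statistic), p = unname(res$p.value))
}

.two_sample_result <- function(test_name, statistic, p_value, n1, n2,
                               normality_gate = NULL) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n1 = n1, n2 = n2,
                 normality_gate = normality_gate),
            class = "two_sample_result")
}

#' @export
print.two_sample_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Wilcoxon rank sum test (two-sided)
#'
#' Midranks are used for ties; the two-sided p-value comes from the normal
#' approximation with tie-corrected variance and continuity correction
#' (\code{stats::wilcox.test} with \code{exact = FALSE}), so tied synthetic
#' masses are handled uniformly.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return a `two_sample_result` with the rank-sum (Mann-Whitney U)
#'   statistic.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("wilcoxon_rank_sum requires n >= 2 in each sample")
  }
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  )
  .two_sample_result("wilcoxon_rank_sum", res$statistic, res$p.value,
                     length(x), length(y))
}

#' Welch two-sample t-test (two-sided)
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#'
#' @param x,y numeric samples, each of size >= 2, with positive variance in
#'   at least one sample.
#' @return a `two_sample_result`; the Satterthwaite df is attached as
#'   attribute `df`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("welch_t requires n >= 2 in each sample")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("welch_t undefined: both samples constant")
  }
  res <- stats::t.test(x, y, var.equal = FALSE)
  out <- .two_sample_result("welch_t", res$statistic, res$p.value,
                            length(x), length(y))
  attr(out, "df") <- unname(res$parameter)
  out
}

#' Normality-gated two-sample comparison
#'
#' Runs the Shapiro-Wilk check on each sample; when both look normal at the
#' `alpha` gate, the comparison is the Welch t-test, otherwise the Wilcoxon
#' rank sum test.  The gate results are recorded on the returned object so
#' the selection is reportable.
#'
#' @param x,y numeric samples.
#' @param alpha normality-gate significance level (default 0.05).
#' @return a `two_sample_result` whose `normality_gate` holds both
#'   Shapiro-Wilk results.
#' @export
choose_and_run_test <- function(x, y, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha < 1)
  gx <- shapiro_wilk(x)
  gy <- shapiro_wilk(y)
  gate <- list(x = gx, y = gy, alpha = alpha)
  res <- if (gx$p >= alpha && gy$p >= alpha) welch_t(x, y)
         else wilcoxon_rank_sum(x, y)
  res$normality_gate <- gate
  res
}

#' Randomly pair copepods across species and difference their masses
#'
#' Each copepod of one species is paired uniformly at random, without
#' replacement, with a copepod of the other; when group sizes differ the
#' surplus individuals of the larger group are dropped uniformly at random.
#' Each pair contributes mass(M. viridis) - mass(M. albidus) in mg.
#'
#' @param albidus,viridis data frames of copepod records with a `length_mm`
#'   column (see \code{\link{copepod_columns}}); at least one row each.
#' @param seed integer seed making the pairing reproducible.
#' @param experiment optional label ("FR" or "PE") recorded on the result.
#' @return object of class `paired_differences` with `differences` (mg),
#'   `n_pairs`, `experiment` and `seed`.
#' @export
random_species_pairing <- function(albidus, viridis, seed,
                                   experiment = NA_character_) {
  if (NROW(albidus) < 1L || NROW(viridis) < 1L) {
    stop("need at least one copepod record per species")
  }
  n_pairs <- min(NROW(albidus), NROW(viridis))
  ma <- length_to_mass(albidus$length_mm)
  mv <- length_to_mass(viridis$length_mm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ia <- sample.int(length(ma), n_pairs)
  iv <- sample.int(length(mv), n_pairs)
  structure(list(differences = mv[iv] - ma[ia], n_pairs = n_pairs,
                 experiment = experiment, seed = seed),
            class = "paired_differences")
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
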