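# Response-type classification (type II vs type III) from polynomial
# logistic regressions of proportional consumption against initial density.

#' Binomial GLM of proportional consumption on initial density
#'
#' Fits a logit-link binomial regression of (eaten, survived) counts on
#' initial larval density, optionally with a quadratic density term, by
#' iteratively reweighted least squares (\code{stats::glm}).  The sign and
#' significance of the polynomial terms carry the response-type information:
#' under a type II response the per-larva consumption probability declines
#' with density from the outset; under a type III response it first rises.
#'
#' @param eaten integer vector of larvae consumed per dish.
#' @param initial integer vector of initial larvae per dish.
#' @param degree polynomial degree in density, 1 or 2.
#' @return data frame with one row per term (`term`, `estimate`, `se`, `z`,
#'   `p`), with attributes `converged` (IRLS convergence and no boundary
#'   fit) and `deviance`.
#' @export
fit_binomial_glm <- function(eaten, initial, degree = 1) {
  stopifnot(length(eaten) == length(initial), degree %in% c(1, 2))
  if (any(eaten < 0) || any(eaten > initial)) {
    stop("eaten must lie in [0, initial]")
  }
  if (length(unique(initial)) < degree + 2L) {
    stop("need at least degree + 2 distinct density levels")
  }
  df <- data.frame(eaten = eaten, alive = initial - eaten, density = initial)
  form <- if (degree == 1) cbind(eaten, alive) ~ density
          else cbind(eaten, alive) ~ density + I(density^2)
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = df,
               control = stats::glm.control(maxit = 100, epsilon = 1e-10))
  )
  sm <- summary(fit)$coefficients
  out <- data.frame(
    term = c("intercept", "first_order", "second_order")[seq_len(nrow(sm))],
    estimate = sm[, 1], se = sm[, 2], z = sm[, 3], p = sm[, 4],
    row.names = NULL
  )
  # IRLS can report convergence while the fit has run to the boundary
  # (all-or-nothing consumption drives logit coefficients to +-Inf); treat
  # implausibly large logit-scale estimates as non-converged
  attr(out, "converged") <- fit$converged && !fit$boundary &&
    all(abs(out$estimate[out$term == "intercept"]) < 15)
  attr(out, "deviance") <- stats::deviance(fit)
  out
}

#' Classify the functional-response type of one experimental group
#'
#' Implements the polynomial logistic-regression decision tree: the
#' quadratic fit is examined first, and a positive, significant first-order
#' term together with a negative, significant second-order term yields a
#' type III call; otherwise the linear fit is examined, and a negative,
#' significant first-order term yields a type II call; anything else is
#' inconclusive.  Only predator-present, non-excluded trials enter the fit.
#'
#' @param trials trial data frame for one species-by-temperature group (see
#'   \code{\link{trial_columns}}), or a list with numeric vectors `eaten`
#'   and `initial`.
#' @param alpha significance level for both terms (default 0.05).
#' @return object of class `response_type_fit` with the `classification`
#'   (`"type_II"`, `"type_III"` or `"inconclusive"`), the coefficient table
#'   of the deciding fit (`coefficients`), both underlying fits
#'   (`fit_degree1`, `fit_degree2`), `n_trials` and `converged`.
#' @export
classify_response <- function(trials, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.data.frame(trials)) {
    validate_trials(trials)
    use <- trials$predator_count == 1 & !trials$excluded
    eaten <- trials$initial_count[use] - trials$survivors[use]
    initial <- trials$initial_count[use]
  } else {
    eaten <- trials$eaten
    initial <- trials$initial
  }
  mk <- function(classification, table, d1, d2, converged) {
    structure(list(classification = classification, coefficients = table,
                   fit_degree1 = d1, fit_degree2 = d2,
                   n_trials = length(eaten), alpha = alpha,
                   converged = converged),
              class = "response_type_fit")
  }
  d2 <- tryCatch(fit_binomial_glm(eaten, initial, degree = 2),
                 error = function(e) NULL)
  d1 <- tryCatch(fit_binomial_glm(eaten, initial, degree = 1),
                 error = function(e) NULL)
  if (is.null(d1) && is.null(d2)) {
    return(mk("inconclusive", NULL, d1, d2, FALSE))
  }
  if (!is.null(d2) && isTRUE(attr(d2, "converged"))) {
    b1 <- d2$estimate[d2$term == "first_order"]
    p1 <- d2$p[d2$term == "first_order"]
    b2 <- d2$estimate[d2$term == "second_order"]
    p2 <- d2$p[d2$term == "second_order"]
    if (b1 > 0 && p1 < alpha && b2 < 0 && p2 < alpha) {
      return(mk("type_III", d2, d1, d2, TRUE))
    }
  }
  if (!is.null(d1) && isTRUE(attr(d1, "converged"))) {
    b1 <- d1$estimate[d1$term == "first_order"]
    p1 <- d1$p[d1$term == "first_order"]
    if (b1 < 0 && p1 < alpha) {
      return(mk("type_II", d1, d1, d2, TRUE))
    }
    return(mk("inconclusive", d1, d1, d2, TRUE))
  }
  mk("inconclusive", d1 %||% d2, d1, d2, FALSE)
}

#' @export
print.response_type_fit <- function(x, ...) {
  cat("Functional response classification:", x$classification,
      sprintf("(n = %d trials, alpha = %g)\n", x$n_trials, x$alpha))
  if (!is.null(x$coefficients)) print(x$coefficients)
  invisible(x)
}
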