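# Abbott-corrected predation efficiency and the linear-model analysis.

#' Abbott's control-corrected predation efficiency
#'
#' efficiency (%) = 100 x (alive in control - alive in treatment) / alive in
#' control.  Negative values are legitimate: they occur when treatment
#' survival exceeds that of the matched control.
#'
#' @param alive_control larvae alive in the matched control dish, >= 1.
#' @param alive_treatment larvae alive in the treatment dish, >= 0.
#' @return efficiency in percent; vectorised.
#' @export
#' @examples
#' abbott_efficiency(23, 14)   # 100 * 9/23
abbott_efficiency <- function(alive_control, alive_treatment) {
  if (any(alive_control < 1)) {
    stop("abbott_efficiency undefined when alive_control < 1")
  }
  if (any(alive_treatment < 0)) stop("alive_treatment must be >= 0")
  100 * (alive_control - alive_treatment) / alive_control
}

#' Match predator treatments to same-temperature controls
#'
#' Every predator dish of the efficiency experiment is matched to a control
#' dish held at the same temperature.  When controls are shared (fewer
#' controls than treatments) each control serves an equal number of
#' treatments and the assignment is drawn uniformly at random under `seed`.
#' Copepod mass is derived from the recorded body length via
#' \code{\link{length_to_mass}}.
#'
#' @param trials predation-efficiency trial data frame (see
#'   \code{\link{trial_columns}}); excluded rows are ignored.
#' @param seed integer seed for the control assignment.
#' @return data frame of efficiency records: `pair_id`, `species`,
#'   `temperature_C`, `alive_control`, `alive_treatment`, `efficiency_pct`,
#'   `copepod_mass_mg`.
#' @export
pair_treatments_controls <- function(trials, seed = 1L) {
  validate_trials(trials)
  tr <- included_trials(trials)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- list()
  for (temp in sort(unique(tr$temperature_C))) {
    at <- tr[tr$temperature_C == temp, , drop = FALSE]
    ctl <- at[at$predator_count == 0, , drop = FALSE]
    trt <- at[at$predator_count == 1, , drop = FALSE]
    if (nrow(trt) == 0L) next
    if (nrow(ctl) == 0L) {
      stop("temperature ", temp, " has treatments but no controls")
    }
    # shuffle before recycling so shared / unused controls are chosen
    # uniformly, then shuffle the assignment itself
    assign_ctl <- sample(rep_len(sample(ctl$trial_id), nrow(trt)))
    ctl_alive <- ctl$survivors[match(assign_ctl, ctl$trial_id)]
    mass <- ifelse(is.na(trt$copepod_length_mm), NA_real_,
                   length_to_mass(pmax(trt$copepod_length_mm, 1e-9)))
    out[[length(out) + 1L]] <- data.frame(
      pair_id = paste(trt$trial_id, assign_ctl, sep = "|"),
      species = trt$species,
      temperature_C = trt$temperature_C,
      alive_control = ctl_alive,
      alive_treatment = trt$survivors,
      efficiency_pct = abbott_efficiency(ctl_alive, trt$survivors),
      copepod_mass_mg = mass,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) stop("no treatment dishes to pair")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ordinary-least-squares regression of predation efficiency
#'
#' Least-squares fit with treatment (dummy) coding; the reference levels are
#' M. albidus for species and 15 degC for temperature, so coefficient signs
#' read as differences from that baseline.  AIC is the full Gaussian
#' log-likelihood convention with the error variance counted as a parameter
#' (\code{stats::AIC}).
#'
#' @param formula model formula, e.g.
#'   `efficiency_pct ~ species + factor(temperature_C)`.
#' @param data data frame of efficiency records (see
#'   \code{\link{pair_treatments_controls}}).
#' @return object of class `efficiency_lm`: `terms` (term, estimate, se, t,
#'   p), `n`, `r_squared`, `adjusted_R2`, `AIC`, `df_residual`, `response`,
#'   and the underlying `lm` fit.
#' @export
fit_ols <- function(formula, data) {
  data <- as.data.frame(data)
  if ("species" %in% names(data)) {
    lev <- intersect(c("M_albidus", "M_viridis"), unique(data$species))
    data$species <- factor(data$species, levels = lev)
  }
  if ("temperature_C" %in% names(data)) {
    data$temperature_C <- factor(data$temperature_C,
                                 levels = sort(unique(data$temperature_C)))
  }
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  n <- stats::nobs(fit)
  k <- length(stats::coef(fit))
  if (n <= k) stop("need more observations than model terms")
  sm <- summary(fit)
  ct <- sm$coefficients
  structure(list(
    terms = data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                       t = ct[, 3], p = ct[, 4], row.names = NULL),
    n = n,
    r_squared = sm$r.squared,
    adjusted_R2 = sm$adj.r.squared,
    AIC = stats::AIC(fit),
    df_residual = fit$df.residual,
    response = unname(stats::model.response(stats::model.frame(fit))),
    formula = formula,
    lm = fit
  ), class = "efficiency_lm")
}

#' @export
print.efficiency_lm <- function(x, ...) {
  cat("OLS fit:", deparse(x$formula), "\n")
  print(x$terms, digits = 4)
  cat(sprintf("n = %d, adjusted R^2 = %.3f, AIC = %.1f\n",
              x$n, x$adjusted_R2, x$AIC))
  invisible(x)
}

#' Rank candidate efficiency models by AIC
#'
#' Sorts the candidate fits by AIC and applies the conventional
#' minimum-difference rule: one model is preferred over another only when
#' its AIC is lower by at least 2; smaller gaps are flagged as ties.
#'
#' @param fits named list of `efficiency_lm` objects fitted to the same
#'   response vector.
#' @return data frame ranked by AIC with `model`, `df` (residual),
#'   `adjusted_R2`, `AIC`, `delta_AIC` and `preferred`; the selected model
#'   name is attached as attribute `selected` (NA when the top two are
#'   within 2 AIC units, flagged by attribute `tie`).
#' @export
model_selection <- function(fits) {
  stopifnot(length(fits) >= 2L)
  labs <- names(fits) %||% paste0("model", seq_along(fits))
  resp <- fits[[1]]$response
  for (f in fits) {
    if (f$n != fits[[1]]$n || !isTRUE(all.equal(f$response, resp))) {
      stop("all models must be fitted to the same response vector")
    }
  }
  tab <- data.frame(
    model = labs,
    df = vapply(fits, function(f) f$df_residual, numeric(1)),
    adjusted_R2 = vapply(fits, function(f) f$adjusted_R2, numeric(1)),
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    row.names = NULL
  )
  tab <- tab[order(tab$AIC), ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  tie <- nrow(tab) >= 2 && tab$delta_AIC[2] < 2
  # the top model is preferred only when the runner-up trails by >= 2 AIC
  tab$preferred <- c(!tie, rep(FALSE, nrow(tab) - 1L))
  rownames(tab) <- NULL
  attr(tab, "selected") <- if (tie) NA_character_ else tab$model[1]
  attr(tab, "tie") <- tie
  tab
}

#' Summary statistics of an efficiency distribution
#'
#' Reports range, median, moment skewness and plain (non-excess) kurtosis —
#' the convention under which a normal population has kurtosis 3.
#'
#' @param values numeric vector, n >= 3, non-constant.
#' @return list with `min`, `max`, `median`, `skewness`, `kurtosis`, `n`.
#' @export
describe_distribution <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L) stop("describe_distribution requires n >= 3")
  m2 <- mean((values - mean(values))^2)
  if (m2 == 0) stop("skewness/kurtosis undefined for constant sample")
  m3 <- mean((values - mean(values))^3)
  m4 <- mean((values - mean(values))^4)
  list(min = min(values), max = max(values), median = stats::median(values),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2, n = n)
}
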