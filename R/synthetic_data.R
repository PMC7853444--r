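# Seeded generators reproducing the predation-trial experimental design:
# a density ladder (1, 2, 4, 8, 16, 24, 32 larvae per 20 mL arena) with four
# predator replicates and one control per density for each of six
# species-by-temperature combinations (functional-response arm), and
# fixed-density dishes of 24 larvae split 8/8/8 across the two predator
# species and a control at each temperature (efficiency arm).

#' Configuration of the synthetic predation-trial generator
#'
#' Collects everything the generators need: the true functional-response
#' parameters per group, the experimental design, truncated-normal copepod
#' length distributions per species (bounded by the published adult body
#' length ranges: M. albidus 1.3-2.5 mm, M. viridis 1.2-3 mm), the
#' efficiency-arm effect structure, per-temperature control mortality of the
#' efficiency arm, and the seed recorded in all outputs.
#'
#' @param true_params either a single \code{\link{fr_params}} shared by all
#'   groups or a named list keyed `"<species>_<temperature>"`.
#' @param design an \code{\link{experiment_design}}.
#' @param length_distributions named list per species with `mean`, `sd`
#'   (mm) and `bounds` (length-2 truncation interval in mm).
#' @param efficiency_effect list with `intercept` (percent), `slope`
#'   (percent per mg of copepod mass) and `residual_sd` (percent of
#'   dish-level Gaussian noise added on top of binomial sampling noise).
#' @param pe_control_mortality named numeric: per-temperature proportion of
#'   control larvae dying over a trial in the efficiency arm.
#' @param duration_h trial duration in hours.
#' @param arena_volume_mL arena volume (metadata only; the dynamics run on
#'   counts per arena).
#' @param seed integer seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(
    true_params = fr_params(b = 1, q = 0, h = 0.5, m = 0.01),
    design = experiment_design(),
    length_distributions = list(
      M_albidus = list(mean = 1.7, sd = 0.20, bounds = c(1.3, 2.5)),
      M_viridis = list(mean = 2.1, sd = 0.25, bounds = c(1.2, 3.0))
    ),
    efficiency_effect = list(intercept = 9.72, slope = 34.44,
                             residual_sd = 0),
    pe_control_mortality = c("15" = 0.05, "20" = 0.11, "25" = 0.03),
    duration_h = 6,
    arena_volume_mL = 20,
    seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  for (sp in design$species) {
    ld <- length_distributions[[sp]]
    if (is.null(ld)) stop("no length distribution for species ", sp)
    if (ld$bounds[1] > ld$bounds[2]) stop("truncation bounds inverted for ", sp)
    if (ld$sd < 0) stop("length sd must be >= 0")
  }
  if (efficiency_effect$residual_sd < 0) stop("residual_sd must be >= 0")
  structure(list(
    true_params = true_params, design = design,
    length_distributions = length_distributions,
    efficiency_effect = efficiency_effect,
    pe_control_mortality = pe_control_mortality,
    duration_h = duration_h, arena_volume_mL = arena_volume_mL,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

.group_params <- function(config, species, temperature) {
  tp <- config$true_params
  if (inherits(tp, "fr_params")) return(tp)
  key <- paste(species, temperature, sep = "_")
  p <- tp[[key]]
  if (is.null(p)) stop("no true parameters for group ", key)
  p
}

#' Draw trial survivors from the model-matched binomial generator
#'
#' Survivors = N0 minus a Binomial(N0, p_gone) draw where p_gone is the
#' per-larva loss probability implied by the depletion dynamics
#' (\code{\link{predict_remaining}}).  This generator matches the fitted
#' likelihood exactly in distribution, making fitting a proper
#' self-consistency check.
#'
#' @param N0 initial prey count(s).
#' @param params an \code{\link{fr_params}}.
#' @param P predator count.
#' @param T trial duration (h).
#' @return integer survivor count(s), drawn from the current RNG stream.
#' @export
simulate_trial_binomial <- function(N0, params, P = 1, T = 6) {
  rem <- predict_remaining(N0, params, P = P, T = T)
  p_gone <- pmin(pmax(1 - rem / N0, 0), 1)
  as.integer(N0 - stats::rbinom(length(N0), N0, p_gone))
}

#' Draw trial survivors from the event-driven (Gillespie) generator
#'
#' Exact sample path of the continuous-time Markov chain whose mean-field
#' limit is the depletion equation: with N prey alive the total hazard is
#' lambda(N) = P b N^(1+q) / (1 + b h N^(1+q)) + m N, and each event removes
#' one prey (eaten or dead).  Unlike the binomial generator, prey losses are
#' not conditionally independent, so this mode probes robustness to
#' demographic stochasticity beyond the fitted likelihood's assumption.
#'
#' @inheritParams simulate_trial_binomial
#' @return integer survivor count(s).
#' @export
simulate_trial_gillespie <- function(N0, params, P = 1, T = 6) {
  stopifnot(inherits(params, "fr_params"), all(N0 >= 1), T > 0)
  b <- params$b; q <- params$q; h <- params$h; m <- params$m
  one <- function(n0) {
    N <- n0
    t <- 0
    repeat {
      if (N == 0L) break
      Nq <- N^(1 + q)
      rate <- P * b * Nq / (1 + b * h * Nq) + m * N
      if (rate <= 0) break
      t <- t + stats::rexp(1, rate)
      if (t > T) break
      N <- N - 1L
    }
    N
  }
  vapply(as.integer(N0), one, integer(1))
}

#' Draw copepod body lengths for one species
#'
#' Truncated-normal lengths within the species' published adult range, drawn
#' by inverse-CDF so the draw is reproducible under the current RNG state.
#' The default configuration places the M. viridis mean above the
#' M. albidus mean, so the species mass ordering of the generated data
#' matches the observed ordering.
#'
#' @param species species name present in the configuration.
#' @param n number of copepods.
#' @param config a \code{\link{simulation_config}}.
#' @return numeric lengths in mm, all within the truncation bounds.
#' @export
generate_copepod_lengths <- function(species, n, config) {
  stopifnot(n >= 1)
  ld <- config$length_distributions[[species]]
  if (is.null(ld)) stop("no length distribution for species ", species)
  rtruncnorm_icdf(n, ld$mean, ld$sd, ld$bounds[1], ld$bounds[2])
}

#' Generate one full functional-response dataset
#'
#' Simulates the complete design: for every species-by-temperature
#' combination, `replicates_per_density` predator dishes and
#' `controls_per_density` control dishes at each density of the ladder.
#' Survivors come from the chosen simulator; predator dishes carry a drawn
#' copepod length.  Deterministic given `config$seed`.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param simulator `"binomial"` (model-matched, default) or `"gillespie"`.
#' @return trial data frame (see \code{\link{trial_columns}}) with
#'   attributes `copepods` (copepod record data frame) and `seed`.
#' @export
generate_fr_dataset <- function(config, simulator = c("binomial", "gillespie")) {
  stopifnot(inherits(config, "simulation_config"))
  simulator <- match.arg(simulator)
  sim <- switch(simulator, binomial = simulate_trial_binomial,
                gillespie = simulate_trial_gillespie)
  d <- config$design
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  rows <- list()
  cops <- list()
  for (sp in d$species) {
    for (temp in d$temperatures) {
      pars <- .group_params(config, sp, temp)
      n_pred <- length(d$densities) * d$replicates_per_density
      lens <- if (n_pred > 0) generate_copepod_lengths(sp, n_pred, config)
              else numeric(0)
      li <- 0L
      for (dens in d$densities) {
        for (r in seq_len(d$replicates_per_density)) {
          li <- li + 1L
          id <- sprintf("FR_%s_%d_d%02d_r%d", sp, temp, dens, r)
          surv <- sim(dens, pars, P = 1, T = config$duration_h)
          rows[[length(rows) + 1L]] <- data.frame(
            trial_id = id, experiment = "FR", species = sp,
            temperature_C = temp, initial_count = dens, survivors = surv,
            predator_count = 1, duration_h = config$duration_h,
            arena_volume_mL = config$arena_volume_mL,
            copepod_length_mm = lens[li], excluded = FALSE,
            exclusion_reason = NA_character_, stringsAsFactors = FALSE
          )
          cops[[length(cops) + 1L]] <- data.frame(
            copepod_id = id, species = sp, experiment = "FR",
            length_mm = lens[li], stringsAsFactors = FALSE
          )
        }
        for (cc in seq_len(d$controls_per_density)) {
          id <- sprintf("FR_%s_%d_d%02d_c%d", sp, temp, dens, cc)
          surv <- sim(dens, pars, P = 0, T = config$duration_h)
          rows[[length(rows) + 1L]] <- data.frame(
            trial_id = id, experiment = "FR", species = "none",
            temperature_C = temp, initial_count = dens, survivors = surv,
            predator_count = 0, duration_h = config$duration_h,
            arena_volume_mL = config$arena_volume_mL,
            copepod_length_mm = NA_real_, excluded = FALSE,
            exclusion_reason = NA_character_, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  trials <- do.call(rbind, rows)
  validate_trials(trials)
  attr(trials, "copepods") <- do.call(rbind, cops)
  attr(trials, "seed") <- config$seed
  trials
}

#' Generate one full predation-efficiency dataset
#'
#' Per temperature: `pe_dishes_per_group` control dishes whose survivors are
#' Binomial(larvae, 1 - control mortality), and `pe_dishes_per_group`
#' treatment dishes per predator species whose expected Abbott efficiency is
#' `intercept + slope x copepod mass` (linear-probability link on the
#' treatment survival scale), with survivors drawn binomially.
#' Deterministic given `config$seed`.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with `trials` (trial data frame) and `copepods` (copepod
#'   record data frame); the seed is attached to both as attribute `seed`.
#' @export
generate_efficiency_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  d <- config$design
  eff <- config$efficiency_effect
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n_per <- d$pe_larvae_per_dish
  rows <- list()
  cops <- list()
  for (temp in d$temperatures) {
    mort <- config$pe_control_mortality[[as.character(temp)]] %||% 0
    p_ctl <- 1 - mort
    for (cc in seq_len(d$pe_dishes_per_group)) {
      id <- sprintf("PE_none_%d_c%d", temp, cc)
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = id, experiment = "PE", species = "none",
        temperature_C = temp, initial_count = n_per,
        survivors = stats::rbinom(1, n_per, p_ctl), predator_count = 0,
        duration_h = config$duration_h,
        arena_volume_mL = config$arena_volume_mL,
        copepod_length_mm = NA_real_, excluded = FALSE,
        exclusion_reason = NA_character_, stringsAsFactors = FALSE
      )
    }
    for (sp in d$species) {
      lens <- generate_copepod_lengths(sp, d$pe_dishes_per_group, config)
      mass <- length_to_mass(lens)
      expected_eff <- eff$intercept + eff$slope * mass
      if (eff$residual_sd > 0) {
        expected_eff <- expected_eff +
          stats::rnorm(length(mass), 0, eff$residual_sd)
      }
      if (any(expected_eff < 0) || any(expected_eff > 100)) {
        stop("configured effect implies expected efficiency outside [0, 100]")
      }
      p_trt <- p_ctl * (1 - expected_eff / 100)
      for (i in seq_len(d$pe_dishes_per_group)) {
        id <- sprintf("PE_%s_%d_r%d", sp, temp, i)
        rows[[length(rows) + 1L]] <- data.frame(
          trial_id = id, experiment = "PE", species = sp,
          temperature_C = temp, initial_count = n_per,
          survivors = stats::rbinom(1, n_per, p_trt[i]), predator_count = 1,
          duration_h = config$duration_h,
          arena_volume_mL = config$arena_volume_mL,
          copepod_length_mm = lens[i], excluded = FALSE,
          exclusion_reason = NA_character_, stringsAsFactors = FALSE
        )
        cops[[length(cops) + 1L]] <- data.frame(
          copepod_id = id, species = sp, experiment = "PE",
          length_mm = lens[i], stringsAsFactors = FALSE
        )
      }
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  validate_trials(trials)
  copepods <- do.call(rbind, cops)
  rownames(copepods) <- NULL
  attr(trials, "seed") <- config$seed
  attr(copepods, "seed") <- config$seed
  list(trials = trials, copepods = copepods)
}
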