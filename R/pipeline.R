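# Orchestration: run the full analysis of either experimental arm from
# files or from the synthetic generator, and write the report tables.

#' Pipeline configuration
#'
#' @param out_dir output directory for report tables (created if missing);
#'   `NULL` suppresses writing.
#' @param seed integer seed governing simulation, pairing and restarts.
#' @param alpha significance level for response-type terms and the
#'   normality gate.
#' @param alpha_m significance level for retaining the mortality term.
#' @param ci_level profile confidence level.
#' @param simulator `"binomial"` or `"gillespie"`.
#' @param sim_config a \code{\link{simulation_config}} used when no input
#'   files are given.
#' @param fr_trials_path,pe_trials_path optional CSV paths; when set, data
#'   are read instead of simulated.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1L, alpha = 0.05,
                            alpha_m = 0.05, ci_level = 0.95,
                            simulator = c("binomial", "gillespie"),
                            sim_config = NULL,
                            fr_trials_path = NULL, pe_trials_path = NULL) {
  stopifnot(alpha > 0, alpha < 1, ci_level > 0, ci_level < 1)
  simulator <- match.arg(simulator)
  if (is.null(sim_config)) sim_config <- simulation_config(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), alpha = alpha,
                 alpha_m = alpha_m, ci_level = ci_level,
                 simulator = simulator, sim_config = sim_config,
                 fr_trials_path = fr_trials_path,
                 pe_trials_path = pe_trials_path),
            class = "pipeline_config")
}

.config_fingerprint <- function(config) {
  # the fingerprint covers the analysis-relevant settings, not the output
  # location, so identical analyses hash identically wherever they write
  cfg <- config[setdiff(names(config), "out_dir")]
  config_hash(utils::capture.output(utils::str(cfg)))
}

.write_report <- function(df, config, file, hash) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, file)
  df$seed <- config$seed
  df$config_hash <- hash
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

.write_metadata <- function(config, hash, extra = list()) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  meta <- c(list(seed = config$seed, config_hash = hash,
                 package_version = as.character(utils::packageVersion("copepodFR")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            extra)
  path <- file.path(config$out_dir, "run_metadata.json")
  json <- paste0(
    "{\n",
    paste(sprintf('  "%s": %s', names(meta), vapply(meta, function(v) {
      if (is.numeric(v)) as.character(v) else sprintf('"%s"', v)
    }, character(1))), collapse = ",\n"),
    "\n}\n")
  writeLines(json, path)
  invisible(path)
}

#' Run the functional-response analysis
#'
#' For every species-by-temperature group: classify the response type from
#' the predator-present trials, fit the depletion-equation likelihood with
#' the shape exponent fixed by the classification, compute profile intervals
#' for the attack coefficient and handling time, and compare groups by
#' interval overlap.  Groups with fewer than two density levels are skipped
#' with a logged reason.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param trials optional trial data frame; otherwise read from
#'   `config$fr_trials_path` or simulated from `config$sim_config`.
#' @return list with `classifications`, `fits` (each carrying
#'   `profile_ci`), `comparisons` (per parameter), `skipped`, and the report
#'   tables `response_type`, `fr_parameters`, `fr_comparisons`.
#' @export
run_fr_analysis <- function(config = pipeline_config(), trials = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- .config_fingerprint(config)
  if (is.null(trials)) {
    trials <- if (!is.null(config$fr_trials_path)) {
      read_trials(config$fr_trials_path, "FR")
    } else {
      generate_fr_dataset(config$sim_config, simulator = config$simulator)
    }
  }
  validate_trials(trials)
  tr <- included_trials(trials)
  pred <- tr[tr$predator_count == 1, , drop = FALSE]
  if (nrow(pred) == 0L) stop("no predator-present trials: nothing to fit")

  groups <- unique(pred[, c("species", "temperature_C")])
  fits <- list()
  classifications <- list()
  skipped <- list()
  rt_rows <- list()
  par_rows <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  for (i in seq_len(nrow(groups))) {
    sp <- groups$species[i]; temp <- groups$temperature_C[i]
    lab <- paste(sp, temp, sep = "_")
    # controls carry species "none"; when their trial ids are tagged with a
    # species token (the generator's convention) they are assigned to that
    # combination, otherwise all same-temperature controls are shared
    ctl_all <- tr[tr$predator_count == 0 & tr$temperature_C == temp, ,
                  drop = FALSE]
    tokens <- paste0("_", unique(groups$species), "_")
    tagged <- rep(FALSE, nrow(ctl_all))
    for (tok in tokens) {
      tagged <- tagged | grepl(tok, ctl_all$trial_id, fixed = TRUE)
    }
    ctl <- if (any(tagged)) {
      ctl_all[grepl(paste0("_", sp, "_"), ctl_all$trial_id, fixed = TRUE), ,
              drop = FALSE]
    } else ctl_all
    gtr <- rbind(tr[tr$species == sp & tr$temperature_C == temp, ,
                    drop = FALSE], ctl)
    gpred <- gtr[gtr$predator_count == 1, , drop = FALSE]
    if (length(unique(gpred$initial_count)) < 2L) {
      skipped[[lab]] <- "fewer than two density levels"
      next
    }
    cls <- classify_response(gtr, alpha = config$alpha)
    classifications[[lab]] <- cls
    q_fixed <- if (cls$classification == "type_III") 1 else 0
    fit <- fit_group(gtr, q_fixed = q_fixed, alpha_m = config$alpha_m)
    if (fit$converged) {
      fit$profile_ci <- list(
        b = profile_ci(fit, "b", level = config$ci_level),
        h = profile_ci(fit, "h", level = config$ci_level)
      )
    }
    fits[[lab]] <- fit
    co <- cls$coefficients
    rt_rows[[lab]] <- data.frame(
      group = lab, classification = cls$classification,
      first_order = co$estimate[co$term == "first_order"][1] %||% NA_real_,
      first_order_p = co$p[co$term == "first_order"][1] %||% NA_real_,
      n_trials = cls$n_trials, stringsAsFactors = FALSE
    )
    cib <- fit$profile_ci$b %||% c(low = NA_real_, high = NA_real_)
    cih <- fit$profile_ci$h %||% c(low = NA_real_, high = NA_real_)
    par_rows[[lab]] <- data.frame(
      group = lab, variant = fit$variant, q = fit$q,
      b = fit$params$b, b_low = unname(cib["low"]), b_high = unname(cib["high"]),
      h = fit$params$h, h_low = unname(cih["low"]), h_high = unname(cih["high"]),
      m = fit$params$m, mortality_p = fit$mortality_p,
      deviance = fit$deviance, converged = fit$converged,
      stringsAsFactors = FALSE
    )
  }
  if (length(fits) == 0L) {
    stop("no group could be fitted; skipped: ",
         paste(names(skipped), collapse = ", "))
  }
  comparisons <- list()
  cmp_rows <- list()
  profiled <- Filter(function(f) !is.null(f$profile_ci), fits)
  if (length(profiled) >= 2L) {
    for (par in c("b", "h")) {
      cm <- compare_groups(profiled, par)
      comparisons[[par]] <- cm
      idx <- which(upper.tri(cm$significant), arr.ind = TRUE)
      cmp_rows[[par]] <- data.frame(
        parameter = par,
        group1 = rownames(cm$significant)[idx[, 1]],
        group2 = colnames(cm$significant)[idx[, 2]],
        significant = cm$significant[idx], stringsAsFactors = FALSE
      )
    }
  }
  response_type <- do.call(rbind, rt_rows); rownames(response_type) <- NULL
  fr_parameters <- do.call(rbind, par_rows); rownames(fr_parameters) <- NULL
  fr_comparisons <- if (length(cmp_rows)) do.call(rbind, cmp_rows) else
    data.frame()
  rownames(fr_comparisons) <- NULL
  .write_report(response_type, config, "response_type.csv", hash)
  .write_report(fr_parameters, config, "fr_parameters.csv", hash)
  if (nrow(fr_comparisons)) {
    .write_report(fr_comparisons, config, "fr_comparisons.csv", hash)
  }
  .write_metadata(config, hash, list(stage = "fr_analysis"))
  list(classifications = classifications, fits = fits,
       comparisons = comparisons, skipped = skipped,
       response_type = response_type, fr_parameters = fr_parameters,
       fr_comparisons = fr_comparisons, config_hash = hash)
}

# the six candidate models of the efficiency analysis
.efficiency_model_set <- function() {
  list(
    species_temperature =
      efficiency_pct ~ species + temperature_C,
    species_x_temperature =
      efficiency_pct ~ species * temperature_C,
    species_only = efficiency_pct ~ species,
    mass_temperature =
      efficiency_pct ~ copepod_mass_mg + temperature_C,
    mass_x_temperature =
      efficiency_pct ~ copepod_mass_mg * temperature_C,
    mass_only = efficiency_pct ~ copepod_mass_mg
  )
}

#' Run the predation-efficiency and body-size analysis
#'
#' Computes Abbott-corrected efficiencies from matched treatment-control
#' pairs, fits the six candidate linear models (species or mass, with and
#' without temperature and its interaction), ranks them by AIC, summarises
#' the efficiency distribution, and runs the body-size test battery
#' (normality-gated species comparisons per experimental arm and, when
#' records from both arms are available, the paired-difference comparison
#' across arms).
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param pe_trials optional efficiency-arm trial data frame; otherwise read
#'   from `config$pe_trials_path` or simulated.
#' @param copepods optional copepod record data frame (both arms allowed).
#' @return list with `records`, `models`, `selection`, `distribution`,
#'   `body_size_tests` and the written report tables.
#' @export
run_efficiency_analysis <- function(config = pipeline_config(),
                                    pe_trials = NULL, copepods = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- .config_fingerprint(config)
  if (is.null(pe_trials)) {
    if (!is.null(config$pe_trials_path)) {
      pe_trials <- read_trials(config$pe_trials_path, "PE")
    } else {
      gen <- generate_efficiency_dataset(config$sim_config)
      pe_trials <- gen$trials
      copepods <- copepods %||% gen$copepods
    }
  }
  validate_trials(pe_trials)
  records <- pair_treatments_controls(pe_trials, seed = config$seed)

  have_mass <- !all(is.na(records$copepod_mass_mg))
  model_set <- .efficiency_model_set()
  if (!have_mass) {
    model_set <- model_set[!grepl("mass", names(model_set))]
  }
  fit_data <- records[stats::complete.cases(
    records[, c("efficiency_pct", "species", "temperature_C",
                if (have_mass) "copepod_mass_mg")]), , drop = FALSE]
  models <- lapply(model_set, fit_ols, data = fit_data)
  selection <- model_selection(models)
  distribution <- describe_distribution(fit_data$efficiency_pct)

  body_size_tests <- list()
  bst_rows <- list()
  if (!is.null(copepods)) {
    add_test <- function(label, res) {
      body_size_tests[[label]] <<- res
      gate <- res$normality_gate
      bst_rows[[label]] <<- data.frame(
        comparison = label, test_name = res$test_name,
        statistic = res$statistic, p_value = res$p_value,
        n1 = res$n1, n2 = res$n2,
        gate_W_x = gate$x$W %||% NA_real_, gate_p_x = gate$x$p %||% NA_real_,
        gate_W_y = gate$y$W %||% NA_real_, gate_p_y = gate$y$p %||% NA_real_,
        stringsAsFactors = FALSE
      )
    }
    diffs <- list()
    for (arm in intersect(c("FR", "PE"), unique(copepods$experiment))) {
      alb <- copepods[copepods$experiment == arm &
                        copepods$species == "M_albidus", , drop = FALSE]
      vir <- copepods[copepods$experiment == arm &
                        copepods$species == "M_viridis", , drop = FALSE]
      if (nrow(alb) >= 3L && nrow(vir) >= 3L) {
        add_test(paste0("species_mass_", arm),
                 choose_and_run_test(length_to_mass(alb$length_mm),
                                     length_to_mass(vir$length_mm),
                                     alpha = config$alpha))
        diffs[[arm]] <- random_species_pairing(alb, vir, seed = config$seed,
                                               experiment = arm)
      }
    }
    if (all(c("FR", "PE") %in% names(diffs))) {
      add_test("mass_difference_by_design",
               wilcoxon_rank_sum(diffs$FR$differences, diffs$PE$differences))
      body_size_tests$paired_differences <- diffs
    }
  }
  body_size_table <- if (length(bst_rows)) do.call(rbind, bst_rows) else
    data.frame()
  rownames(body_size_table) <- NULL

  model_rows <- do.call(rbind, lapply(names(models), function(nm) {
    t <- models[[nm]]$terms
    data.frame(model = nm, term = t$term, estimate = t$estimate, se = t$se,
               t = t$t, p = t$p, n = models[[nm]]$n,
               adjusted_R2 = models[[nm]]$adjusted_R2,
               AIC = models[[nm]]$AIC, stringsAsFactors = FALSE)
  }))
  rownames(model_rows) <- NULL

  .write_report(records, config, "efficiency_records.csv", hash)
  .write_report(model_rows, config, "efficiency_models.csv", hash)
  .write_report(as.data.frame(selection), config, "model_selection.csv", hash)
  if (nrow(body_size_table)) {
    .write_report(body_size_table, config, "body_size_tests.csv", hash)
  }
  .write_metadata(config, hash, list(stage = "efficiency_analysis"))
  list(records = records, models = models, selection = selection,
       distribution = distribution, body_size_tests = body_size_tests,
       efficiency_models = model_rows, body_size_table = body_size_table,
       config_hash = hash)
}
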