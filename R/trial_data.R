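# Predation-trial records, CSV interchange, design enumeration, exclusions.
#
# A trial is one Petri-dish observation.  Trials are kept in plain data
# frames with a fixed, documented column set so every analysis stage works
# from the same interchange format.

.trial_columns <- c(
  "trial_id", "experiment", "species", "temperature_C", "initial_count",
  "survivors", "predator_count", "duration_h", "arena_volume_mL",
  "copepod_length_mm", "excluded", "exclusion_reason"
)

.copepod_columns <- c("copepod_id", "species", "experiment", "length_mm")

.species_levels <- c("M_albidus", "M_viridis", "none")
.temperature_levels <- c(15, 20, 25)
.experiment_levels <- c("FR", "PE")

#' Validate a data frame of predation trials
#'
#' Checks the invariants every downstream stage relies on: survivor counts
#' bounded by initial counts, predator counts in \{0, 1\}, species `"none"`
#' exactly when no predator is present, temperatures restricted to the
#' experimental settings, positive durations and arena volumes.
#'
#' @param trials data frame with the columns listed in
#'   \code{\link{trial_columns}}.
#' @return `trials`, invisibly, if valid; otherwise an error naming the
#'   offending trial and invariant.
#' @export
validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trials are missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(trials) == 0L) return(invisible(trials))

  bad <- function(cond, what) {
    if (any(cond)) {
      stop(what, " for trial(s): ",
           paste(utils::head(trials$trial_id[cond], 5L), collapse = ", "))
    }
  }
  bad(!trials$experiment %in% .experiment_levels, "unknown experiment label")
  bad(!trials$species %in% .species_levels, "unknown species label")
  bad(!trials$temperature_C %in% .temperature_levels,
      "temperature outside experimental settings")
  bad(trials$initial_count < 1 | trials$initial_count != round(trials$initial_count),
      "initial_count must be a positive integer")
  bad(trials$survivors < 0 | trials$survivors > trials$initial_count,
      "survivors outside [0, initial_count]")
  bad(!trials$predator_count %in% c(0, 1), "predator_count must be 0 or 1")
  bad((trials$species == "none") != (trials$predator_count == 0),
      "species 'none' must coincide with predator_count 0")
  bad(trials$duration_h <= 0, "duration_h must be positive")
  bad(trials$arena_volume_mL <= 0, "arena_volume_mL must be positive")
  len <- trials$copepod_length_mm
  bad(!is.na(len) & len <= 0, "copepod_length_mm must be positive when present")
  bad(!is.logical(trials$excluded) | is.na(trials$excluded),
      "excluded must be TRUE/FALSE")
  invisible(trials)
}

#' Column names of the trial and copepod interchange tables
#'
#' @return Character vector of column names.
#' @export
trial_columns <- function() .trial_columns

#' @rdname trial_columns
#' @export
copepod_columns <- function() .copepod_columns

#' Read predation trials from CSV
#'
#' Reads a comma-separated, UTF-8, headered trial table and validates every
#' row.  Excluded rows are retained with their flag set so that exclusion
#' decisions remain auditable; use \code{\link{included_trials}} for the
#' analysis view.
#'
#' @param path path to a CSV file with the columns of
#'   \code{\link{trial_columns}}.
#' @param schema which experimental arm the file holds, `"FR"` (functional
#'   response) or `"PE"` (predation efficiency); all rows must match.
#' @return validated data frame of trials.
#' @export
read_trials <- function(path, schema = c("FR", "PE")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(trial_id = "character"))
  missing_cols <- setdiff(.trial_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[, .trial_columns]
  raw$excluded <- as.logical(raw$excluded)
  raw$copepod_length_mm <- as.numeric(raw$copepod_length_mm)
  raw$exclusion_reason <- as.character(raw$exclusion_reason)
  raw$exclusion_reason[!is.na(raw$exclusion_reason) &
                         raw$exclusion_reason == ""] <- NA_character_
  if (nrow(raw) > 0L && any(raw$experiment != schema)) {
    stop("schema mismatch: file contains rows with experiment != ", schema)
  }
  validate_trials(raw)
  raw
}

#' Write predation trials to CSV
#'
#' Writes the deterministic column order of \code{\link{trial_columns}};
#' \code{read_trials(write_trials(x))} reproduces `x` field-for-field.
#'
#' @param trials validated trial data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials[, .trial_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Describe the experimental design
#'
#' Captures the trial layout: a ladder of initial larval densities with a
#' fixed number of predator replicates and predator-absent controls per
#' density for each species-by-temperature combination (functional-response
#' arm), plus fixed-density dishes split into predator and control groups
#' (predation-efficiency arm).
#'
#' @param densities strictly increasing positive integer larval densities
#'   per arena.
#' @param replicates_per_density predator replicates at each density.
#' @param controls_per_density predator-absent controls at each density.
#' @param species character vector of predator species.
#' @param temperatures experimental temperature settings (deg C).
#' @param pe_larvae_per_dish larvae per dish in the efficiency arm.
#' @param pe_dishes_per_group dishes per group (each predator species and the
#'   control) per temperature in the efficiency arm.
#' @param pe_groups number of groups per temperature in the efficiency arm
#'   (predator species plus one control group).
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(densities = c(1, 2, 4, 8, 16, 24, 32),
                              replicates_per_density = 4,
                              controls_per_density = 1,
                              species = c("M_albidus", "M_viridis"),
                              temperatures = c(15, 20, 25),
                              pe_larvae_per_dish = 24,
                              pe_dishes_per_group = 8,
                              pe_groups = 3) {
  if (length(densities) == 0L) stop("densities must be non-empty")
  if (any(densities <= 0) || any(diff(densities) <= 0)) {
    stop("densities must be positive and strictly increasing")
  }
  counts <- c(replicates_per_density, controls_per_density, pe_larvae_per_dish,
              pe_dishes_per_group, pe_groups)
  if (any(counts < 0) || pe_larvae_per_dish < 1) stop("counts must be positive")
  structure(list(
    densities = as.integer(densities),
    replicates_per_density = as.integer(replicates_per_density),
    controls_per_density = as.integer(controls_per_density),
    species = species,
    temperatures = temperatures,
    pe_larvae_per_dish = as.integer(pe_larvae_per_dish),
    pe_dishes_per_group = as.integer(pe_dishes_per_group),
    pe_groups = as.integer(pe_groups)
  ), class = "experiment_design")
}

#' Enumerate larvae, dish and copepod totals implied by a design
#'
#' Pure design arithmetic: per-tub and per-combination larvae counts, dish
#' counts, grand totals for both experimental arms, and the number of
#' predator copepods each arm consumes.
#'
#' @param design an \code{\link{experiment_design}}.
#' @return a list of named totals (see Details).
#' @details The functional-response totals treat one "tub" as one full
#'   density ladder (its larvae are split across one dish per density).  The
#'   efficiency-arm totals assume one control group per temperature and the
#'   remaining groups assigned to predator species.
#' @export
enumerate_design <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  d <- design
  ladders_per_combination <- d$replicates_per_density + d$controls_per_density
  n_comb <- length(d$species) * length(d$temperatures)
  larvae_per_tub <- sum(d$densities)
  dishes_per_combination <- length(d$densities) * ladders_per_combination
  predator_dishes_per_combination <- length(d$densities) * d$replicates_per_density
  fr_larvae_per_combination <- larvae_per_tub * ladders_per_combination

  pe_predator_groups <- max(d$pe_groups - 1L, 0L)
  pe_dishes_per_temperature <- d$pe_dishes_per_group * d$pe_groups
  pe_larvae_total <- d$pe_larvae_per_dish * pe_dishes_per_temperature *
    length(d$temperatures)

  list(
    fr_larvae_per_tub = larvae_per_tub,
    fr_larvae_per_combination = fr_larvae_per_combination,
    fr_larvae_total = fr_larvae_per_combination * n_comb,
    fr_dishes_per_combination = dishes_per_combination,
    fr_dishes_total = dishes_per_combination * n_comb,
    fr_predator_dishes_per_combination = predator_dishes_per_combination,
    fr_copepods = predator_dishes_per_combination * n_comb,
    n_combinations = n_comb,
    pe_dishes_per_temperature = pe_dishes_per_temperature,
    pe_larvae_total = pe_larvae_total,
    pe_control_larvae_per_temperature =
      d$pe_larvae_per_dish * d$pe_dishes_per_group,
    pe_copepods = d$pe_dishes_per_group * pe_predator_groups *
      length(d$temperatures)
  )
}

#' Flag trials for exclusion from analysis
#'
#' Applies the exclusion rules used when screening predation trials:
#' predator deaths during the pre-trial starvation period, accidental double
#' predator introduction (both identified by trial id, since they are lab
#' events not encoded in the counts), and insufficient copepod body length
#' (suggesting a male or immature rather than an adult non-gravid female).
#' Trials are never removed: the `excluded` flag and `exclusion_reason` are
#' set so the decision stays auditable.
#'
#' @param trials validated trial data frame.
#' @param rules named list; recognised names are `predator_death` (character
#'   vector of trial ids), `double_predator` (character vector of trial ids)
#'   and `insufficient_length` (numeric length threshold in mm applied to
#'   predator trials with a recorded copepod length).
#' @return list with `trials` (flags set), and `log`, a data frame of
#'   exclusion counts per species-by-temperature group and reason.
#' @export
apply_exclusions <- function(trials, rules = list()) {
  validate_trials(trials)
  known <- c("predator_death", "double_predator", "insufficient_length")
  unknown <- setdiff(names(rules), known)
  if (length(unknown) > 0L) {
    stop("unknown exclusion rule(s): ", paste(unknown, collapse = ", "))
  }
  mark <- function(trials, idx, reason) {
    fresh <- idx & !trials$excluded
    trials$excluded[fresh] <- TRUE
    trials$exclusion_reason[fresh] <- reason
    trials
  }
  for (rule in c("predator_death", "double_predator")) {
    if (!is.null(rules[[rule]])) {
      trials <- mark(trials, trials$trial_id %in% rules[[rule]], rule)
    }
  }
  if (!is.null(rules$insufficient_length)) {
    thr <- rules$insufficient_length
    stopifnot(is.numeric(thr), length(thr) == 1L, thr > 0)
    short <- trials$predator_count == 1 & !is.na(trials$copepod_length_mm) &
      trials$copepod_length_mm < thr
    trials <- mark(trials, short, "insufficient_length")
  }
  excl <- trials[trials$excluded, , drop = FALSE]
  log <- if (nrow(excl) > 0L) {
    as.data.frame(table(
      species = excl$species, temperature_C = excl$temperature_C,
      reason = excl$exclusion_reason
    ), responseName = "n", stringsAsFactors = FALSE)
  } else {
    data.frame(species = character(), temperature_C = character(),
               reason = character(), n = integer())
  }
  log <- log[log$n > 0L, , drop = FALSE]
  rownames(log) <- NULL
  list(trials = trials, log = log)
}

#' Analysis view of a trial table
#'
#' @param trials validated trial data frame.
#' @return the non-excluded rows.
#' @export
included_trials <- function(trials) {
  trials[!trials$excluded, , drop = FALSE]
}
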