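# Independent oracles used across tests.  These deliberately avoid the
# package's own solution paths: the ODE oracle is a fixed-step RK4
# integrator, the rank-sum oracle enumerates assignments exhaustively.

# fixed-step classical RK4 integration of the prey-depletion equation
rk4_remaining <- function(N0, b, q, h, m, P, T, dt = 1e-4) {
  f <- function(N) {
    Nq <- max(N, 0)^(1 + q)
    -(b * Nq / (1 + b * h * Nq)) * P - m * max(N, 0)
  }
  n_steps <- ceiling(T / dt)
  dt <- T / n_steps
  N <- N0
  for (i in seq_len(n_steps)) {
    k1 <- f(N)
    k2 <- f(N + dt / 2 * k1)
    k3 <- f(N + dt / 2 * k2)
    k4 <- f(N + dt * k3)
    N <- N + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  N
}

# exact two-sided rank-sum p-value by enumerating all assignments of the
# pooled ranks to group 1 (no ties assumed); feasible for n1 + n2 <= 12
exact_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * (length(y)) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# one full functional-response group (35 dishes) simulated at given truth
make_group_trials <- function(params, seed, species = "M_albidus",
                              temperature = 15,
                              simulator = "binomial") {
  design <- experiment_design(species = species, temperatures = temperature)
  cfg <- simulation_config(true_params = params, design = design, seed = seed)
  generate_fr_dataset(cfg, simulator = simulator)
}

# minimal valid trial table for plumbing tests
make_toy_trials <- function(n = 3) {
  data.frame(
    trial_id = paste0("t", seq_len(n)),
    experiment = "FR",
    species = rep(c("M_albidus", "none"), length.out = n),
    temperature_C = 15,
    initial_count = 8,
    survivors = seq_len(n),
    predator_count = rep(c(1, 0), length.out = n),
    duration_h = 6,
    arena_volume_mL = 20,
    copepod_length_mm = ifelse(rep(c(TRUE, FALSE), length.out = n), 1.8,
                               NA_real_),
    excluded = FALSE,
    exclusion_reason = NA_character_,
    stringsAsFactors = FALSE
  )
}
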