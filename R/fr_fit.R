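# Maximum-likelihood estimation of the functional response around the
# prey-depletion differential equation
#
#   dN/dt = -b N^(1+q) / (1 + b h N^(1+q)) * P - m N
#
# where b is the attack coefficient, h the handling time (h per prey),
# q the shape exponent (0 = type II, 1 = type III), P the predator count
# and m the background prey mortality rate (h^-1).  Missing prey are
# binomially distributed around the depletion the equation predicts; the
# likelihood counts prey no longer alive in both treatments (eaten or dead)
# and controls (dead).

#' Functional response parameter set
#'
#' @param b attack coefficient (arena^q predator^-1 h^-1), > 0 (0 allowed
#'   for limiting cases).
#' @param q shape exponent, fixed at 0 (type II) or 1 (type III).
#' @param h handling time in hours per prey, >= 0 (0 is the no-saturation
#'   limit).
#' @param m background prey mortality rate (h^-1), >= 0.
#' @return an object of class `fr_params`.
#' @export
fr_params <- function(b, q = 0, h, m = 0) {
  stopifnot(length(b) == 1L, length(h) == 1L, length(m) == 1L,
            is.finite(b), is.finite(h), is.finite(m))
  if (!(q %in% c(0, 1))) stop("q must be 0 (type II) or 1 (type III)")
  if (b < 0 || h < 0 || m < 0) stop("b, h, m must be non-negative")
  structure(list(b = b, q = q, h = h, m = m), class = "fr_params")
}

#' Rogers random-predator solution (type II, no background mortality)
#'
#' Closed form for the prey remaining after time `T` under the type II
#' depletion dynamics with m = 0: the number eaten E satisfies
#' E = N0 (1 - exp(-b (P T - h E))), whose solution is expressed through the
#' principal branch of the Lambert W function,
#' remaining = W0(b h N0 exp(b h N0 - b P T)) / (b h).
#'
#' @param N0 initial prey count(s), >= 1.
#' @param b attack coefficient, >= 0.
#' @param h handling time (h), >= 0 (0 gives the exponential limit
#'   N0 exp(-b P T)).
#' @param P predator count.
#' @param T trial duration in hours.
#' @return expected prey remaining, same length as `N0`.
#' @export
rogers_remaining <- function(N0, b, h, P = 1, T = 6) {
  stopifnot(all(N0 > 0), b >= 0, h >= 0, T > 0, P >= 0)
  if (b == 0 || P == 0) return(N0 + 0)
  if (h == 0) return(N0 * exp(-b * P * T))
  logz <- log(b * h * N0) + b * h * N0 - b * P * T
  w <- lambert_w0_exp(logz)
  rem <- w / (b * h)
  if (any(!is.finite(rem))) {
    stop(sprintf(
      "Lambert-W solution out of range (b = %g, h = %g, P = %g, T = %g)",
      b, h, P, T))
  }
  # extreme-predation regimes underflow to 0 remaining; keep the result
  # strictly positive so downstream log-probabilities stay finite
  pmin(pmax(rem, .Machine$double.xmin), N0)
}

# Exact remaining prey for q = 0 with background mortality, from the
# implicit (separable) solution of the depletion equation:
#   T = (1/A) log(N0/N) + (bP/(A m)) log((A + B N0)/(A + B N)),
# with A = bP + m, B = m b h.  Solved for N by bracketed Newton iteration
# on u = log N (the implicit time G(u) is monotone decreasing in u);
# vectorised over N0.
.remaining_q0 <- function(N0, b, h, m, P, T) {
  if (P == 0 || b == 0) return(N0 * exp(-m * T))
  if (m == 0) return(rogers_remaining(N0, b, h, P, T))
  if (h == 0) return(N0 * exp(-(b * P + m) * T))
  A <- b * P + m
  B <- m * b * h
  cf <- b * P / (A * m)
  lgN0 <- log(N0)
  lAB0 <- log(A + B * N0)
  lo <- lgN0 - A * T - 1e-9   # per-capita hazard <= A, so N(T) >= N0 e^(-AT)
  hi <- lgN0
  # predation-only and mortality-only depletions each bound N(T) from above
  u <- pmax(lo + 1e-12, log(pmin(rogers_remaining(N0, b, h, P, T),
                                 N0 * exp(-m * T))))
  for (i in seq_len(60L)) {
    eu <- exp(u)
    g <- (lgN0 - u) / A + cf * (lAB0 - log(A + B * eu)) - T
    lo <- ifelse(g > 0, u, lo)  # G decreasing: G(u) > 0 means root above u
    hi <- ifelse(g > 0, hi, u)
    gp <- -1 / A - cf * B * eu / (A + B * eu)
    un <- u - g / gp
    bad <- !is.finite(un) | un <= lo | un >= hi
    un[bad] <- ((lo + hi) / 2)[bad]
    if (max(abs(un - u)) < 1e-12) { u <- un; break }
    u <- un
  }
  exp(u)
}

# Build a fast negative log-likelihood closure for one dataset: trials are
# grouped by (P, T) once and densities de-duplicated, so each evaluation
# solves the depletion dynamics only for the distinct initial counts.
.make_nll <- function(dat, q, clamp_eps = 1e-12) {
  groups <- split(seq_along(dat$N0), paste(dat$P, dat$T))
  pre <- lapply(groups, function(idx) {
    uN0 <- unique(dat$N0[idx])
    list(uN0 = uN0, map = match(dat$N0[idx], uN0),
         P = dat$P[idx[1L]], T = dat$T[idx[1L]],
         N0 = dat$N0[idx], D = dat$N0[idx] - dat$S[idx])
  })
  function(b, h, m) {
    if (!is.finite(b) || !is.finite(h) || !is.finite(m) ||
        b < 0 || h < 0 || m < 0) return(Inf)
    nll <- 0
    for (g in pre) {
      rem <- if (q == 0) {
        .remaining_q0(g$uN0, b, h, m, g$P, g$T)
      } else {
        predict_remaining(g$uN0, fr_params(b, q, h, m), g$P, g$T,
                          method = "ode")
      }
      p_gone <- pmin(pmax(1 - rem[g$map] / g$N0, clamp_eps), 1 - clamp_eps)
      nll <- nll - sum(stats::dbinom(g$D, g$N0, p_gone, log = TRUE))
    }
    nll
  }
}

#' Expected prey remaining under the depletion dynamics
#'
#' Solves the prey-depletion differential equation from N(0) = N0 to time
#' `T`.  For q = 0 the default method uses the exact separable solution
#' (Lambert W when m = 0, safeguarded root-finding on the implicit integral
#' otherwise); `method = "ode"` integrates the equation numerically with
#' an adaptive solver (\code{deSolve::ode}, lsoda), which is also the route
#' taken for q = 1 where no closed form is available.
#'
#' @param N0 initial prey count(s), >= 1.
#' @param params an \code{\link{fr_params}} object.
#' @param P predator count (0 or 1 in the experimental design).
#' @param T trial duration in hours.
#' @param method `"auto"` (analytic when q = 0, otherwise ODE),
#'   `"analytic"` or `"ode"`.
#' @param rtol,atol relative and absolute tolerances of the adaptive solver.
#' @return expected prey remaining, strictly positive, same length as `N0`.
#' @export
predict_remaining <- function(N0, params, P = 1, T = 6,
                              method = c("auto", "analytic", "ode"),
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "fr_params"), all(N0 >= 1), T > 0, P >= 0)
  method <- match.arg(method)
  if (method == "auto") method <- if (params$q == 0) "analytic" else "ode"
  if (method == "analytic") {
    if (params$q != 0) stop("analytic solution only available for q = 0")
    return(.remaining_q0(N0, params$b, params$h, params$m, P, T))
  }
  b <- params$b; q <- params$q; h <- params$h; m <- params$m
  deriv <- function(t, N, parms) {
    Nq <- pmax(N, 0)^(1 + q)
    list(-(b * Nq / (1 + b * h * Nq)) * P - m * pmax(N, 0))
  }
  sol <- deSolve::ode(y = as.numeric(N0), times = c(0, T), func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  out <- as.numeric(sol[nrow(sol), -1])
  if (any(!is.finite(out))) {
    stop(sprintf("ODE solver failed (b = %g, q = %g, h = %g, m = %g, P = %g)",
                 b, q, h, m, P))
  }
  pmin(pmax(out, .Machine$double.xmin), N0)
}

# extract the (N0, survivors, P, T) arrays the likelihood needs
.group_data <- function(trials) {
  validate_trials(trials)
  tr <- included_trials(trials)
  list(N0 = tr$initial_count, S = tr$survivors,
       P = tr$predator_count, T = tr$duration_h)
}

# negative log-likelihood core: binomial probability of the missing prey
# D = N0 - S with per-larva loss probability 1 - N(T)/N0
.nll_core <- function(b, h, m, q, dat, clamp_eps = 1e-12) {
  .make_nll(dat, q, clamp_eps)(b, h, m)
}

#' Negative log-likelihood with background mortality
#'
#' Pools predator treatments and predator-absent controls of one group in a
#' single binomial likelihood around the depletion dynamics: controls inform
#' the mortality rate m directly, treatments inform b, h and (through their
#' own death hazard) m.  Loss probabilities that round outside (0, 1) are
#' clamped to [1e-12, 1 - 1e-12].
#'
#' @param params an \code{\link{fr_params}} object (m may be 0).
#' @param trials trial data frame for one species-by-temperature group,
#'   containing at least one control (predator_count = 0) dish; excluded
#'   rows are ignored.
#' @return the summed negative log-likelihood (finite for valid parameters).
#' @export
nll_with_mortality <- function(params, trials) {
  stopifnot(inherits(params, "fr_params"))
  dat <- .group_data(trials)
  if (!any(dat$P == 0)) {
    stop("nll_with_mortality requires at least one control (P = 0) dish")
  }
  .nll_core(params$b, params$h, params$m, params$q, dat)
}

#' Negative log-likelihood assuming zero background mortality
#'
#' The m = 0 variant, fitted to predator-present trials only; for q = 0 the
#' expected depletion is the Rogers random-predator closed form.
#'
#' @param params an \code{\link{fr_params}} object; `params$m` must be 0.
#' @param trials predator-present (predator_count = 1) trials only.
#' @return the summed negative log-likelihood.
#' @export
nll_no_mortality <- function(params, trials) {
  stopifnot(inherits(params, "fr_params"))
  if (params$m != 0) stop("nll_no_mortality requires m = 0")
  dat <- .group_data(trials)
  if (any(dat$P == 0)) {
    stop("nll_no_mortality accepts predator-present trials only")
  }
  .nll_core(params$b, params$h, 0, params$q, dat)
}

#' Fit the functional response of one species-by-temperature group
#'
#' Maximum-likelihood estimation on log-transformed parameters with a
#' derivative-free simplex (Nelder-Mead) from the conventional starting
#' values: b = 1, h = 1 / maximum observed feeding rate, m = 0.01 h^-1;
#' jittered restarts guard against simplex stalls.  If any control deaths
#' were observed the with-mortality variant is fitted first and m tested by
#' a two-sided Wald test from the observed information; when m is
#' insignificant (p >= `alpha_m`) or no control deaths occurred, the
#' zero-mortality variant is (re)fitted to the predator trials alone.
#'
#' @param trials trial data frame for one group; excluded rows are ignored.
#' @param q_fixed shape exponent fixed by \code{\link{classify_response}}:
#'   0 (type II) or 1 (type III).
#' @param alpha_m significance level for retaining the mortality term.
#' @param n_restarts number of jittered simplex restarts after the first
#'   run.
#' @return an object of class `fr_fit`: `params` (estimates), `wald_se`
#'   (natural scale, delta method), `nll`, `deviance` (2 x nll), `variant`
#'   (`"with_mortality"` or `"no_mortality"`), `mortality_p`, `converged`,
#'   `n_trials`, `start` values and the data used.
#' @export
fit_group <- function(trials, q_fixed = 0, alpha_m = 0.05, n_restarts = 2) {
  stopifnot(q_fixed %in% c(0, 1))
  dat <- .group_data(trials)
  if (length(dat$N0) == 0L) stop("no usable trials")
  trt <- lapply(dat, function(v) v[dat$P >= 1])
  ctl <- lapply(dat, function(v) v[dat$P == 0])
  if (length(trt$N0) == 0L) stop("no predator-present trials to fit")
  control_deaths <- sum(ctl$N0 - ctl$S)

  eaten <- trt$N0 - trt$S
  max_rate <- max(eaten / trt$T)            # prey per hour
  h_start <- if (max_rate > 0) 1 / max_rate else 1
  b_start <- 1
  m_start <- 0.01

  run_optim <- function(fn, start) {
    best <- stats::optim(start, fn, method = "Nelder-Mead",
                         control = list(maxit = 1000, reltol = 1e-10))
    for (r in seq_len(n_restarts)) {
      jit <- best$par + stats::rnorm(length(start), 0, 0.3)
      cand <- stats::optim(jit, fn, method = "Nelder-Mead",
                           control = list(maxit = 1000, reltol = 1e-10))
      if (cand$value < best$value - 1e-9) best <- cand
    }
    best
  }

  wald_se_natural <- function(fn, par) {
    H <- tryCatch(stats::optimHess(par, fn), error = function(e) NULL)
    if (is.null(H)) return(rep(NA_real_, length(par)))
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V) || any(diag(V) <= 0)) return(rep(NA_real_, length(par)))
    exp(par) * sqrt(diag(V))                 # delta method from log scale
  }

  nll_all <- .make_nll(dat, q_fixed)
  nll_trt <- .make_nll(trt, q_fixed)

  mortality_p <- NA_real_
  fit_mort <- NULL
  if (control_deaths > 0) {
    fn_mort <- function(lp) nll_all(exp(lp[1]), exp(lp[2]), exp(lp[3]))
    fit_mort <- run_optim(fn_mort, c(log(b_start), log(h_start), log(m_start)))
    se_mort <- wald_se_natural(fn_mort, fit_mort$par)
    m_hat <- exp(fit_mort$par[3])
    if (is.finite(se_mort[3]) && se_mort[3] > 0) {
      mortality_p <- 2 * stats::pnorm(-abs(m_hat / se_mort[3]))
    }
  }

  use_mortality <- control_deaths > 0 && is.finite(mortality_p) &&
    mortality_p < alpha_m

  if (use_mortality) {
    est <- exp(fit_mort$par)
    se <- se_mort
    res <- list(params = fr_params(est[1], q_fixed, est[2], est[3]),
                wald_se = c(b = se[1], h = se[2], m = se[3]),
                nll = fit_mort$value, variant = "with_mortality",
                converged = fit_mort$convergence == 0,
                data = dat)
  } else {
    fn_nom <- function(lp) nll_trt(exp(lp[1]), exp(lp[2]), 0)
    fit_nom <- run_optim(fn_nom, c(log(b_start), log(h_start)))
    est <- exp(fit_nom$par)
    se <- wald_se_natural(fn_nom, fit_nom$par)
    res <- list(params = fr_params(est[1], q_fixed, est[2], 0),
                wald_se = c(b = se[1], h = se[2], m = NA_real_),
                nll = fit_nom$value, variant = "no_mortality",
                converged = fit_nom$convergence == 0,
                data = trt)
  }

  structure(c(res, list(
    deviance = 2 * res$nll, mortality_p = mortality_p,
    control_deaths = control_deaths, q = q_fixed,
    n_trials = length(dat$N0),
    start = c(b = b_start, h = h_start, m = m_start),
    alpha_m = alpha_m, profile_ci = NULL
  )), class = "fr_fit")
}

#' @export
print.fr_fit <- function(x, ...) {
  cat(sprintf(
    "Functional response fit (q = %d, %s variant)\n", x$q, x$variant))
  cat(sprintf("  b = %.4g (SE %.3g), h = %.4g h (SE %.3g), m = %.4g /h\n",
              x$params$b, x$wald_se["b"], x$params$h, x$wald_se["h"],
              x$params$m))
  cat(sprintf("  deviance (-2 log L) = %.2f over %d trials; converged: %s\n",
              x$deviance, x$n_trials, x$converged))
  if (is.finite(x$mortality_p)) {
    cat(sprintf("  mortality Wald p = %.4g\n", x$mortality_p))
  }
  invisible(x)
}

#' Locate the bounds of a profile-likelihood interval
#'
#' Generic one-parameter profile search: walks outward from the estimate on
#' the log scale until the profiled negative log-likelihood rises above
#' nll_min + qchisq(level, 1)/2, then bisects to the crossing.  A side on
#' which the profile never crosses within `estimate * [1/search_factor,
#' search_factor]` is reported unbounded (NA with attribute flag).
#'
#' @param nll_profile function of one positive scalar returning the profiled
#'   negative log-likelihood.
#' @param estimate the maximum-likelihood estimate of the profiled
#'   parameter.
#' @param nll_min the minimised negative log-likelihood.
#' @param level confidence level (default 0.95).
#' @param search_factor multiplicative half-width of the search window.
#' @param tol bisection tolerance on the log scale.
#' @return numeric `c(low, high)` (NA where unbounded), with attributes
#'   `bounded` (logical pair) and `level`.
#' @export
profile_bounds <- function(nll_profile, estimate, nll_min, level = 0.95,
                           search_factor = 1e4, tol = 1e-2) {
  stopifnot(estimate > 0, level > 0, level < 1)
  target <- nll_min + stats::qchisq(level, 1) / 2
  le <- log(estimate)
  lim <- log(search_factor)
  eval_p <- function(lt) {
    v <- tryCatch(nll_profile(exp(lt)), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }
  one_side <- function(dir) {        # dir = -1 lower, +1 upper
    step <- 0.25
    inside <- le
    repeat {
      cand <- inside + dir * step
      if (abs(cand - le) > lim) return(NA_real_)
      if (eval_p(cand) > target) { outside <- cand; break }
      inside <- cand
      step <- step * 2
    }
    for (i in seq_len(40L)) {
      mid <- (inside + outside) / 2
      if (eval_p(mid) > target) outside <- mid else inside <- mid
      if (abs(outside - inside) < tol) break
    }
    exp((inside + outside) / 2)
  }
  low <- one_side(-1)
  high <- one_side(+1)
  structure(c(low = low, high = high),
            bounded = c(low = !is.na(low), high = !is.na(high)),
            level = level)
}

#' Profile-likelihood confidence interval for an attack or handling
#' parameter
#'
#' Profiles the deviance over one parameter of a converged fit, re-optimising
#' the remaining free parameters at each profiled value, and finds where the
#' profile deviance rises by the chi-square(1) quantile (3.841 at 95%) above
#' its minimum.  A side on which the profile never crosses within the search
#' window (estimate x 10^4 each way) is flagged unbounded, mirroring the
#' extremely wide intervals that flat likelihoods produce.
#'
#' @param fit an `fr_fit` from \code{\link{fit_group}}.
#' @param parameter `"b"` or `"h"`.
#' @param trials optional trial data frame; defaults to the data stored in
#'   the fit.
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)` with attributes `bounded` and `level`.
#' @export
profile_ci <- function(fit, parameter = c("b", "h"), trials = NULL,
                       level = 0.95) {
  stopifnot(inherits(fit, "fr_fit"))
  if (!fit$converged) stop("profile_ci requires a converged fit")
  parameter <- match.arg(parameter)
  dat <- if (is.null(trials)) fit$data else {
    d <- .group_data(trials)
    if (fit$variant == "no_mortality") lapply(d, function(v) v[d$P >= 1])
    else d
  }
  q <- fit$q
  est <- fit$params[[parameter]]
  nll_fn <- .make_nll(dat, q)
  if (fit$variant == "with_mortality") {
    others <- setdiff(c("b", "h", "m"), parameter)
    warm <- log(c(fit$params[[others[1]]], fit$params[[others[2]]]))
    nll_at <- function(theta) {
      fn <- function(lp) {
        v <- stats::setNames(c(theta, exp(lp)), c(parameter, others))
        nll_fn(v[["b"]], v[["h"]], v[["m"]])
      }
      opt <- stats::optim(warm, fn, method = "Nelder-Mead",
                          control = list(maxit = 200, reltol = 1e-8))
      warm <<- opt$par
      opt$value
    }
  } else {
    other <- setdiff(c("b", "h"), parameter)
    warm <- log(fit$params[[other]])
    nll_at <- function(theta) {
      fn <- function(lt) {
        v <- stats::setNames(c(theta, exp(lt)), c(parameter, other))
        nll_fn(v[["b"]], v[["h"]], 0)
      }
      opt <- stats::optimize(fn, interval = c(warm - 6, warm + 6),
                             tol = 1e-5)
      warm <<- opt$minimum
      opt$objective
    }
  }
  ci <- profile_bounds(nll_at, est, fit$nll, level = level)
  if (!is.na(ci["low"]) && !is.na(ci["high"]) &&
      !(ci["low"] <= est && est <= ci["high"])) {
    warning("profile interval does not bracket the estimate; ",
            "fit may not be at the optimum")
  }
  ci
}

#' Compare parameter estimates across groups by confidence-interval overlap
#'
#' Pairwise comparison of profile intervals: a difference between two groups
#' is called significant only when their intervals are disjoint.  Unbounded
#' intervals (flat profiles) conservatively overlap everything and are
#' flagged.
#'
#' @param fits named list of `fr_fit` objects, each carrying a
#'   `profile_ci` element, a list with entries `b` and/or `h` as returned by
#'   \code{\link{profile_ci}}.
#' @param parameter `"b"` or `"h"`.
#' @return list with `intervals` (data frame), logical matrices `overlap`
#'   and `significant`, and `unbounded` flags.
#' @export
compare_groups <- function(fits, parameter = c("b", "h")) {
  parameter <- match.arg(parameter)
  if (length(fits) < 2L) stop("need at least two fits to compare")
  labs <- names(fits) %||% paste0("group", seq_along(fits))
  ints <- t(vapply(fits, function(f) {
    ci <- f$profile_ci[[parameter]]
    if (is.null(ci)) stop("fits must carry profile_ci for '", parameter, "'")
    c(ci["low"], ci["high"])
  }, numeric(2)))
  unbounded <- apply(ints, 1L, function(r) any(is.na(r)))
  lo <- ifelse(is.na(ints[, 1]), -Inf, ints[, 1])
  hi <- ifelse(is.na(ints[, 2]), Inf, ints[, 2])
  n <- length(fits)
  overlap <- outer(seq_len(n), seq_len(n),
                   function(i, j) lo[i] <= hi[j] & lo[j] <= hi[i])
  dimnames(overlap) <- list(labs, labs)
  significant <- !overlap
  diag(significant) <- NA
  list(
    intervals = data.frame(group = labs, low = ints[, 1], high = ints[, 2],
                           unbounded = unbounded, row.names = NULL),
    overlap = overlap, significant = significant,
    unbounded = stats::setNames(unbounded, labs)
  )
}
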