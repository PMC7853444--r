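# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal branch of the Lambert W function on the non-negative reals
#'
#' Solves w e^w = z for z >= 0 by Halley iteration with a bounded iteration
#' count, vectorised.  Only the non-negative domain is needed here (the
#' Rogers depletion argument is always positive), where W0 is smooth and the
#' iteration is globally convergent from the log1p starting guess.
#'
#' @param z non-negative numeric vector.
#' @return W0(z), non-negative, same length as `z`.
#' @keywords internal
#' @noRd
lambert_w0 <- function(z) {
  stopifnot(all(z >= 0))
  w <- log1p(z)                      # exact at 0, asymptotically sane
  big <- z > 3
  w[big] <- log(z[big]) - log(log(z[big]))
  for (i in seq_len(60L)) {
    ew <- exp(w)
    f <- w * ew - z
    # Halley step
    d <- f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
    w <- w - d
    if (all(abs(d) <= 1e-15 * (1 + abs(w)))) break
  }
  pmax(w, 0)
}

#' W0(exp(logx)) without forming exp(logx)
#'
#' For logx beyond double-precision overflow the asymptotic form
#' W ~ L - log L is refined by bounded Newton steps on
#' f(w) = w + log(w) - logx.
#'
#' @param logx log of the (positive) argument.
#' @return W0(exp(logx)), a non-negative numeric vector.
#' @keywords internal
#' @noRd
lambert_w0_exp <- function(logx) {
  out <- numeric(length(logx))
  small <- logx <= 30
  if (any(small)) out[small] <- lambert_w0(exp(logx[small]))
  if (any(!small)) {
    L <- logx[!small]
    w <- L - log(L)
    # Newton on f(w) = w + log(w) - L  (monotone, well-conditioned for w > 0)
    for (i in seq_len(8L)) w <- w - (w + log(w) - L) / (1 + 1 / w)
    out[!small] <- w
  }
  out
}

# truncated-normal draws by inverse-CDF so results are exactly reproducible
# under the current RNG state (sd = 0 collapses to the mean)
rtruncnorm_icdf <- function(n, mean, sd, lower, upper) {
  if (lower > upper) stop("truncation bounds inverted: lower > upper")
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# polynomial rolling hash (mod 2^31 - 1) of a character vector; used to stamp
# reports with a configuration fingerprint
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
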