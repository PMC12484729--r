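#' Inverse logit
#'
#' Maps log-odds to probabilities. Thin wrapper around [stats::plogis()] so the
#' link used throughout the package is named explicitly.
#'
#' @param x numeric vector of log-odds.
#' @return probabilities in (0, 1).
#' @export
invlogit <- function(x) stats::plogis(x)

#' Logit
#'
#' @param p probabilities in (0, 1).
#' @return log-odds.
#' @export
logit <- function(p) stats::qlogis(p)

# Numerically stable log(1 + exp(x)); avoids overflow for large |x|.
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 18
  out[big] <- x[big] + exp(-x[big])
  out[!big] <- log1p(exp(x[!big]))
  out
}

# Round half away from zero (commercial rounding), used for person counts.
# base::round() rounds half to even, which would break printed headcounts.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Posterior percentile summary
#'
#' Percentiles are computed by linear interpolation between order statistics
#' (the type-7 definition), fixed package-wide so credible intervals are
#' bit-reproducible across platforms.
#'
#' @param x numeric vector of draws.
#' @param probs percentile levels, default the 2.5th and 97.5th.
#' @return numeric vector of percentiles, one per `probs`.
#' @export
cri_percentile <- function(x, probs = c(0.025, 0.975)) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(
    class = c("prevsae_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
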