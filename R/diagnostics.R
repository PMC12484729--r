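#' Effective sample size of an MCMC chain
#'
#' ESS = n / (1 + 2 * sum of autocorrelations), with the autocorrelation sum
#' truncated by the initial-positive-sequence rule: lag autocorrelations are
#' taken in consecutive pairs (rho_1 + rho_2, rho_3 + rho_4, ...) and summed
#' until the first pair with a non-positive sum. The estimate is capped at
#' `n`. A constant chain has no information content and is reported as 0
#' (with attribute `constant = TRUE`).
#'
#' @param chain numeric vector of at least 10 draws.
#' @return scalar ESS estimate.
#' @export
effective_sample_size <- function(chain) {
  if (length(chain) < 10) stop("need at least 10 draws to estimate ESS")
  n <- length(chain)
  if (stats::var(chain) == 0) {
    return(structure(0, constant = TRUE))
  }
  # grow the autocorrelation window until the first non-positive pair is
  # found, so well-mixed chains never pay for an O(n^2) full acf
  lag_max <- min(n - 1L, 128L)
  repeat {
    rho <- as.numeric(stats::acf(chain, lag.max = lag_max, plot = FALSE,
                                 demean = TRUE)$acf)[-1]  # drop lag 0
    # pad with a zero so an odd trailing lag still forms a pair
    if (length(rho) %% 2 == 1) rho <- c(rho, 0)
    pair_sums <- rho[seq(1, length(rho), by = 2)] +
      rho[seq(2, length(rho), by = 2)]
    bad <- which(pair_sums <= 0)
    if (length(bad) || lag_max >= n - 1L) break
    lag_max <- min(n - 1L, lag_max * 4L)
  }
  keep_pairs <- if (length(bad)) bad[1] - 1L else length(pair_sums)
  acsum <- if (keep_pairs > 0) sum(rho[seq_len(2L * keep_pairs)]) else 0
  min(n, max(n / (1 + 2 * acsum), 0))
}

#' Flag parameters with low effective sample size
#'
#' Parameters whose ESS is strictly below the threshold are flagged (the
#' convention is that chains are acceptable when their ESS is *above* 250,
#' so an ESS of exactly 250 is not flagged).
#'
#' @param draws an [run_mcmc()] result, or a named numeric vector of ESS
#'   values.
#' @param threshold flagging threshold, default 250.
#' @return character vector of flagged parameter names (empty if none).
#' @export
flag_low_ess <- function(draws, threshold = 250) {
  ess <- if (inherits(draws, "sae_draws")) draws$ess else draws
  if (is.null(names(ess))) stop("ESS values must be named")
  names(ess)[ess < threshold]
}
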