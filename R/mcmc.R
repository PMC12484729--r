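#' MCMC configuration
#'
#' Sampler settings for [run_mcmc()]. Defaults follow common practice for
#' this model class: a 5,000-iteration chain with a 500-iteration burn-in,
#' no thinning, inverse-gamma(0.001, 0.001) priors on the variances with a
#' flat-normal prior on the intercept, proposal scales adapted during
#' burn-in towards a 44% acceptance rate for scalar random-walk updates and
#' frozen afterwards (so detailed balance holds for the retained draws), and
#' parameter expansion switched on for the cluster variance.
#'
#' @param burn_in burn-in iterations (>= 0).
#' @param chain_length total iterations (> burn_in).
#' @param thin keep every `thin`-th post-burn-in draw (>= 1).
#' @param seed integer RNG seed; fixed seed gives identical chains.
#' @param adapt_interval proposal scales are re-tuned every this many
#'   iterations during burn-in.
#' @param prior `"igamma"` (inverse-gamma(0.001, 0.001) on variances) or
#'   `"uniform_sd"` (uniform(0, 100) on standard deviations), the usual
#'   sensitivity alternative.
#' @param use_parameter_expansion sample the cluster effects under a
#'   redundant multiplicative reparameterization (u = alpha * u_raw) to
#'   improve mixing of the cluster variance. Default `TRUE`.
#' @param target_accept target acceptance rate for adapted scalar updates.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(burn_in = 500L, chain_length = 5000L, thin = 1L,
                        seed = 1L, adapt_interval = 50L,
                        prior = c("igamma", "uniform_sd"),
                        use_parameter_expansion = TRUE,
                        target_accept = 0.44) {
  prior <- match.arg(prior)
  if (chain_length < 1) stop_config("chain_length must be >= 1")
  if (burn_in < 0) stop_config("burn_in must be >= 0")
  if (chain_length <= burn_in) {
    stop_config("chain_length must exceed burn_in")
  }
  if (thin < 1) stop_config("thin must be >= 1")
  structure(list(burn_in = as.integer(burn_in),
                 chain_length = as.integer(chain_length),
                 thin = as.integer(thin), seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 prior = prior,
                 use_parameter_expansion = isTRUE(use_parameter_expansion),
                 target_accept = target_accept),
            class = "mcmc_config")
}

# cluster-level Bernoulli log likelihood from sufficient statistics
.cl_loglik <- function(eta, s, n) s * eta - n * log1pexp(eta)

# one conjugate variance draw given sum of squares SS over m effects
.draw_var <- function(m, SS, prior) {
  if (prior == "igamma") {
    1 / stats::rgamma(1, shape = 0.001 + m / 2, rate = 0.001 + SS / 2)
  } else {
    # uniform(0, 100) on the sd => IG((m-1)/2, SS/2) on the variance,
    # truncated at 100^2; rejection is essentially never triggered
    repeat {
      val <- 1 / stats::rgamma(1, shape = max((m - 1) / 2, 0.5), rate = SS / 2)
      if (val <= 1e4) return(val)
    }
  }
}

#' Fit the four-level logistic model by Metropolis-within-Gibbs MCMC
#'
#' Single-site random-walk Metropolis updates for the intercept and every
#' random effect (vectorized over the conditionally independent effects of a
#' level), conjugate inverse-gamma updates for each variance given its
#' effects, and — because a diffuse intercept makes the level means only
#' weakly identified — additional *translation* moves that shift mass
#' between a parameter and the mean of the effects nested under it without
#' changing the likelihood. When parameter expansion is on, the cluster
#' effects are sampled as `u = alpha * u_raw` with a standard-normal working
#' prior on `alpha`; the reported cluster variance is `alpha^2 *
#' var(u_raw)`, which markedly improves mixing when the cluster variance is
#' near zero.
#'
#' The model operates on cluster-level sufficient statistics (successes and
#' sizes), which is exact for a random-intercept model without covariates.
#'
#' @param data an [model_data()] object.
#' @param start an [sae_params()], typically from [fit_mql1()].
#' @param config an [mcmc_config()].
#' @return object of class `sae_draws`: `params` (matrix of retained draws
#'   of beta0 and the three variances), `f`, `v`, `u` (retained random
#'   effect draws, one column per unit, columns named by unit id), `ess`
#'   (named ESS for every parameter), `low_ess` (names with ESS < 250),
#'   `accept` (mean post-burn-in acceptance rates per update block),
#'   `active` (which levels carried a random effect), plus the id
#'   vocabularies and maps needed by [predict_cluster_probs()].
#' @export
run_mcmc <- function(data, start, config = mcmc_config()) {
  stopifnot(inherits(data, "sae_model_data"), inherits(start, "sae_params"),
            inherits(config, "mcmc_config"))
  if (!all(is.finite(unlist(start[c("beta0", "sigma2_f", "sigma2_v",
                                    "sigma2_u")])))) {
    stop("starting values must be finite")
  }
  set.seed(config$seed)
  act <- active_levels(data)
  px <- config$use_parameter_expansion && act[["cluster"]]
  prior <- config$prior

  s <- data$s; n <- data$n
  nC <- length(s)
  nA <- length(data$area_ids)
  nS <- length(data$state_ids)
  aoc <- data$area_of_cluster
  soc <- data$state_of_cluster
  soa <- data$state_of_area
  # clusters per area / states, for translation moves and prior sums
  nclus_area <- tabulate(aoc, nbins = nA)
  narea_state <- tabulate(soa, nbins = nS)

  # state
  beta0 <- start$beta0
  f <- numeric(nS)
  v <- numeric(nA)
  s2f <- if (act[["state"]]) max(start$sigma2_f, 1e-4) else 0
  s2v <- if (act[["area"]]) max(start$sigma2_v, 1e-4) else 0
  s2u_start <- if (act[["cluster"]]) max(start$sigma2_u, 1e-4) else 0
  if (px) {
    alpha <- sqrt(s2u_start)
    u_raw <- numeric(nC)
    s2raw <- 1
  } else {
    alpha <- 1
    u_raw <- numeric(nC)  # plays the role of u directly
    s2raw <- s2u_start
  }

  eta <- rep(beta0, nC)
  ll <- .cl_loglik(eta, s, n)

  # proposal scales (adapted during burn-in only)
  sd_b <- 0.1; sd_f <- rep(0.5, nS); sd_v <- rep(0.5, nA)
  sd_u <- rep(0.8, nC); sd_a <- 0.1
  sd_t0 <- sqrt(max(s2f, 0.01) / max(nS, 1))
  sd_t1 <- rep(sqrt(max(s2v, 0.01) / 2), nS)
  sd_t2 <- rep(sqrt(max(s2u_start, 0.01) / 2), nA)
  acc <- list(b = 0, f = numeric(nS), v = numeric(nA), u = numeric(nC),
              a = 0, t0 = 0, t1 = numeric(nS), t2 = numeric(nA))
  acc_post <- rapply(acc, function(x) x * 0, how = "replace")
  n_post_updates <- 0L

  n_keep <- (config$chain_length - config$burn_in) %/% config$thin
  P <- matrix(NA_real_, n_keep, 4,
              dimnames = list(NULL, c("beta0", "sigma2_f", "sigma2_v",
                                      "sigma2_u")))
  Fm <- matrix(NA_real_, n_keep, nS, dimnames = list(NULL, data$state_ids))
  Vm <- matrix(NA_real_, n_keep, nA, dimnames = list(NULL, data$area_ids))
  Um <- matrix(NA_real_, n_keep, nC, dimnames = list(NULL, data$cluster_ids))
  keep_row <- 0L

  target <- config$target_accept
  for (iter in seq_len(config$chain_length)) {
    in_burn <- iter <= config$burn_in

    # --- intercept ---
    prop <- beta0 + sd_b * stats::rnorm(1)
    eta_p <- eta + (prop - beta0)
    ll_p <- .cl_loglik(eta_p, s, n)
    lr <- sum(ll_p) - sum(ll) + (beta0^2 - prop^2) / (2 * 1e6)
    if (log(stats::runif(1)) < lr) {
      beta0 <- prop; eta <- eta_p; ll <- ll_p
      acc$b <- acc$b + 1; if (!in_burn) acc_post$b <- acc_post$b + 1
    }

    # --- state effects (conditionally independent given the rest) ---
    if (act[["state"]]) {
      prop <- f + sd_f * stats::rnorm(nS)
      delta <- (prop - f)[soc]
      ll_p <- .cl_loglik(eta + delta, s, n)
      lr_s <- rowsum(ll_p - ll, soc, reorder = TRUE)[, 1] +
        (f^2 - prop^2) / (2 * s2f)
      take <- log(stats::runif(nS)) < lr_s
      if (any(take)) {
        f[take] <- prop[take]
        upd <- take[soc]
        eta[upd] <- eta[upd] + delta[upd]
        ll[upd] <- ll_p[upd]
        acc$f <- acc$f + take
        if (!in_burn) acc_post$f <- acc_post$f + take
      }
    }

    # --- area effects ---
    if (act[["area"]]) {
      prop <- v + sd_v * stats::rnorm(nA)
      delta <- (prop - v)[aoc]
      ll_p <- .cl_loglik(eta + delta, s, n)
      lr_a <- rowsum(ll_p - ll, aoc, reorder = TRUE)[, 1] +
        (v^2 - prop^2) / (2 * s2v)
      take <- log(stats::runif(nA)) < lr_a
      if (any(take)) {
        v[take] <- prop[take]
        upd <- take[aoc]
        eta[upd] <- eta[upd] + delta[upd]
        ll[upd] <- ll_p[upd]
        acc$v <- acc$v + take
        if (!in_burn) acc_post$v <- acc_post$v + take
      }
    }

    # --- cluster effects ---
    if (act[["cluster"]]) {
      prop <- u_raw + sd_u * stats::rnorm(nC)
      delta <- alpha * (prop - u_raw)
      ll_p <- .cl_loglik(eta + delta, s, n)
      lr_u <- ll_p - ll + (u_raw^2 - prop^2) / (2 * s2raw)
      take <- log(stats::runif(nC)) < lr_u
      if (any(take)) {
        u_raw[take] <- prop[take]
        eta[take] <- eta[take] + delta[take]
        ll[take] <- ll_p[take]
        acc$u <- acc$u + take
        if (!in_burn) acc_post$u <- acc_post$u + take
      }

      # --- expansion scale alpha (working prior N(0, 1)) ---
      if (px) {
        prop_a <- alpha + sd_a * stats::rnorm(1)
        delta <- (prop_a - alpha) * u_raw
        ll_p <- .cl_loglik(eta + delta, s, n)
        lr <- sum(ll_p) - sum(ll) + (alpha^2 - prop_a^2) / 2
        if (log(stats::runif(1)) < lr) {
          alpha <- prop_a; eta <- eta + delta; ll <- ll_p
          acc$a <- acc$a + 1; if (!in_burn) acc_post$a <- acc_post$a + 1
        }
      }
    }

    # --- translation moves along likelihood-invariant directions ---
    if (act[["state"]]) {
      d0 <- sd_t0 * stats::rnorm(1)
      lr <- sum(f^2 - (f - d0)^2) / (2 * s2f) +
        (beta0^2 - (beta0 + d0)^2) / (2 * 1e6)
      if (log(stats::runif(1)) < lr) {
        beta0 <- beta0 + d0; f <- f - d0
        acc$t0 <- acc$t0 + 1; if (!in_burn) acc_post$t0 <- acc_post$t0 + 1
      }
    }
    if (act[["state"]] && act[["area"]]) {
      d1 <- sd_t1 * stats::rnorm(nS)
      sumv <- rowsum(v, soa, reorder = TRUE)[, 1]
      sumv2 <- rowsum(v^2, soa, reorder = TRUE)[, 1]
      # v_k -> v_k - d_l for areas in state l; f_l -> f_l + d_l
      lr_t <- (f^2 - (f + d1)^2) / (2 * s2f) +
        (sumv2 - (sumv2 - 2 * d1 * sumv + narea_state * d1^2)) / (2 * s2v)
      take <- log(stats::runif(nS)) < lr_t
      if (any(take)) {
        f[take] <- f[take] + d1[take]
        shift <- ifelse(take[soa], d1[soa], 0)
        v <- v - shift
        acc$t1 <- acc$t1 + take
        if (!in_burn) acc_post$t1 <- acc_post$t1 + take
      }
    }
    if (act[["area"]] && act[["cluster"]] && abs(alpha) > 1e-8) {
      d2 <- sd_t2 * stats::rnorm(nA)
      # u_raw_j -> u_raw_j - d_k/alpha for clusters in area k; v_k -> v_k + d_k
      dr <- d2 / alpha
      sumu <- rowsum(u_raw, aoc, reorder = TRUE)[, 1]
      lr_t <- (v^2 - (v + d2)^2) / (2 * s2v) +
        (2 * dr * sumu - nclus_area * dr^2) / (2 * s2raw)
      take <- log(stats::runif(nA)) < lr_t
      if (any(take)) {
        v[take] <- v[take] + d2[take]
        shift <- ifelse(take[aoc], dr[aoc], 0)
        u_raw <- u_raw - shift
        acc$t2 <- acc$t2 + take
        if (!in_burn) acc_post$t2 <- acc_post$t2 + take
      }
    }
    if (!in_burn) n_post_updates <- n_post_updates + 1L

    # --- conjugate variance updates ---
    if (act[["state"]]) s2f <- .draw_var(nS, sum(f^2), prior)
    if (act[["area"]]) s2v <- .draw_var(nA, sum(v^2), prior)
    if (act[["cluster"]]) s2raw <- .draw_var(nC, sum(u_raw^2), prior)

    if (!all(is.finite(eta)) || !all(is.finite(c(beta0, s2f, s2v, s2raw,
                                                 alpha)))) {
      stop("MCMC chain diverged (non-finite state) at iteration ", iter)
    }

    # --- adaptation (burn-in only) ---
    if (in_burn && iter %% config$adapt_interval == 0L) {
      k <- config$adapt_interval
      tune <- function(sd, a) pmin(pmax(sd * exp(a / k - target), 1e-5), 50)
      sd_b <- tune(sd_b, acc$b); sd_f <- tune(sd_f, acc$f)
      sd_v <- tune(sd_v, acc$v); sd_u <- tune(sd_u, acc$u)
      sd_a <- tune(sd_a, acc$a)
      sd_t0 <- tune(sd_t0, acc$t0); sd_t1 <- tune(sd_t1, acc$t1)
      sd_t2 <- tune(sd_t2, acc$t2)
      acc <- rapply(acc, function(x) x * 0, how = "replace")
    }

    # --- retain ---
    if (!in_burn && (iter - config$burn_in) %% config$thin == 0L) {
      keep_row <- keep_row + 1L
      s2u_now <- if (act[["cluster"]]) {
        if (px) alpha^2 * s2raw else s2raw
      } else 0
      P[keep_row, ] <- c(beta0, s2f, s2v, s2u_now)
      Fm[keep_row, ] <- f
      Vm[keep_row, ] <- v
      Um[keep_row, ] <- alpha * u_raw
    }
  }

  chains <- cbind(P, Fm, Vm, Um)
  colnames(chains) <- c(colnames(P),
                        paste0("f[", data$state_ids, "]"),
                        paste0("v[", data$area_ids, "]"),
                        paste0("u[", data$cluster_ids, "]"))
  ess <- vapply(seq_len(ncol(chains)),
                function(i) as.numeric(effective_sample_size(chains[, i])),
                numeric(1))
  names(ess) <- colnames(chains)
  # collapsed levels produce constant zero chains by construction, not by
  # poor mixing: exclude them from ESS bookkeeping
  if (!act[["state"]]) ess <- ess[!grepl("^(f\\[|sigma2_f)", names(ess))]
  if (!act[["area"]]) ess <- ess[!grepl("^(v\\[|sigma2_v)", names(ess))]
  if (!act[["cluster"]]) ess <- ess[!grepl("^(u\\[|sigma2_u)", names(ess))]

  rate <- function(x) x / max(n_post_updates, 1)
  out <- list(
    params = P, f = Fm, v = Vm, u = Um,
    ess = ess, low_ess = flag_low_ess(ess),
    accept = rapply(acc_post, rate, how = "replace"),
    active = act,
    cluster_ids = data$cluster_ids, area_ids = data$area_ids,
    state_ids = data$state_ids,
    area_of_cluster = data$area_of_cluster,
    state_of_cluster = data$state_of_cluster,
    config = config
  )
  class(out) <- "sae_draws"
  out
}

#' @export
print.sae_draws <- function(x, ...) {
  cat("sae_draws:", nrow(x$params), "retained draws,",
      length(x$cluster_ids), "clusters;",
      length(x$low_ess), "parameter(s) with ESS < 250\n")
  print(round(colMeans(x$params), 4))
  invisible(x)
}

#' Export retained chains as plain CSV
#'
#' One column per parameter (intercept, variances, then every state, area
#' and cluster effect), one row per retained draw — the layout external
#' diagnostics tools expect.
#'
#' @param draws an [run_mcmc()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_chains <- function(draws, path) {
  stopifnot(inherits(draws, "sae_draws"))
  chains <- cbind(draws$params, draws$f, draws$v, draws$u)
  colnames(chains) <- c(colnames(draws$params),
                        paste0("f[", colnames(draws$f), "]"),
                        paste0("v[", colnames(draws$v), "]"),
                        paste0("u[", colnames(draws$u), "]"))
  utils::write.csv(as.data.frame(chains), path, row.names = FALSE)
  invisible(path)
}

#' Export the diagnostic summary (ESS, acceptance, flags) as CSV
#'
#' @param draws an [run_mcmc()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_diagnostics <- function(draws, path) {
  stopifnot(inherits(draws, "sae_draws"))
  utils::write.csv(data.frame(parameter = names(draws$ess),
                              ess = as.numeric(draws$ess),
                              low_ess = names(draws$ess) %in% draws$low_ess),
                   path, row.names = FALSE)
  invisible(path)
}
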