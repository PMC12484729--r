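#' Model parameters container
#'
#' @param beta0 log-odds intercept.
#' @param sigma2_f,sigma2_v,sigma2_u nonnegative variances of the state,
#'   area (district/constituency) and cluster random intercepts.
#' @param converged logical, did the estimator converge.
#' @param iterations iterations used.
#' @return object of class `sae_params`.
#' @export
sae_params <- function(beta0, sigma2_f, sigma2_v, sigma2_u,
                       converged = TRUE, iterations = NA_integer_) {
  stopifnot(is.finite(beta0), sigma2_f >= 0, sigma2_v >= 0, sigma2_u >= 0)
  structure(list(beta0 = beta0, sigma2_f = sigma2_f, sigma2_v = sigma2_v,
                 sigma2_u = sigma2_u, converged = converged,
                 iterations = iterations),
            class = "sae_params")
}

#' @export
print.sae_params <- function(x, ...) {
  cat(sprintf(
    "sae_params: beta0 = %.4f, sigma2_f = %.4f, sigma2_v = %.4f, sigma2_u = %.4f%s\n",
    x$beta0, x$sigma2_f, x$sigma2_v, x$sigma2_u,
    if (isTRUE(x$converged)) "" else "  [NOT converged]"))
  invisible(x)
}

#' First-order marginal quasi-likelihood (MQL1) starting values
#'
#' Linearizes the logistic model around the *fixed-part* prediction (the
#' defining feature of first-order MQL: random effects enter the Taylor
#' expansion at zero) and fits the resulting Gaussian variance-components
#' model, iterating the linearization until the relative change in all
#' parameters falls below `tol`. Each linearized fit is a maximum-likelihood
#' Gaussian multilevel fit, the estimator that iterative generalized least
#' squares converges to. MQL1 is known to be biased towards zero for large
#' cluster variances, which is why it is used only to seed the MCMC.
#'
#' Degenerate levels (a single state, or one area per state, or one cluster
#' per area) are collapsed to zero variance with a warning, so two- and
#' three-level toy datasets fit cleanly.
#'
#' @param data an [model_data()] object.
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param max_iter maximum relinearization iterations (default 50); on
#'   non-convergence the last iterate is returned with a warning and
#'   `converged = FALSE`.
#' @param var_floor small positive floor for variance iterates (default
#'   1e-6).
#' @return an [sae_params()] with `converged` and `iterations` set.
#' @export
fit_mql1 <- function(data, tol = 1e-6, max_iter = 50L, var_floor = 1e-6) {
  stopifnot(inherits(data, "sae_model_data"))
  y <- data$y
  if (length(unique(y)) < 2) {
    stop("complete separation: all outcomes identical; cannot estimate")
  }
  act <- active_levels(data)
  if (!all(act)) {
    warning("degenerate level(s) collapsed to zero variance: ",
            paste(names(act)[!act], collapse = ", "))
  }

  # factors for the linearized mixed model
  fc <- factor(data$j)
  fa <- factor(data$area_of_cluster[data$j])
  fs <- factor(data$state_of_cluster[data$j])
  terms <- c(
    if (act[["state"]]) "(1 | fs)",
    if (act[["area"]]) "(1 | fa)",
    if (act[["cluster"]]) "(1 | fc)"
  )
  form <- stats::as.formula(paste("z ~ 1 +", paste(terms, collapse = " + ")))

  beta0 <- logit(min(max(mean(y), 1e-4), 1 - 1e-4))
  sig <- c(f = var_floor, v = var_floor, u = var_floor)
  converged <- FALSE
  it <- 0L
  theta_start <- NULL
  for (it in seq_len(max_iter)) {
    pi0 <- invlogit(beta0)           # fixed-part prediction only (MQL1)
    w <- pi0 * (1 - pi0)
    z <- beta0 + (y - pi0) / w
    df <- data.frame(z = z, fs = fs, fa = fa, fc = fc)
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = df, REML = FALSE, start = theta_start,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))
    ))
    theta_start <- lme4::getME(fit, "theta")  # warm-start the next fit
    vc <- lme4::VarCorr(fit)
    new_sig <- c(
      f = if (act[["state"]]) max(as.numeric(vc$fs), var_floor) else 0,
      v = if (act[["area"]]) max(as.numeric(vc$fa), var_floor) else 0,
      u = if (act[["cluster"]]) max(as.numeric(vc$fc), var_floor) else 0
    )
    new_beta0 <- unname(lme4::fixef(fit)[1])
    # convergence is judged on the relative change of the linearization
    # point beta0: the variance estimates are deterministic (up to optimizer
    # noise below tol) functions of the linearized model once beta0 is fixed
    delta <- abs(new_beta0 - beta0) / max(abs(beta0), 1e-3)
    beta0 <- new_beta0
    sig <- new_sig
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("MQL1 did not converge in ", max_iter,
            " iterations; returning last iterate")
  }
  sae_params(beta0, sig[["f"]], sig[["v"]], sig[["u"]],
             converged = converged, iterations = it)
}
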