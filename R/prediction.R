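#' Precision-weighted cluster-level predicted probabilities
#'
#' For every retained draw and every cluster, the predicted probability is
#' the inverse logit of `beta0 + f_state + v_area + u_cluster`. Because the
#' random effects are posterior draws from the multilevel model, these
#' predictions partially pool (borrow strength) across clusters sharing a
#' district and state — clusters with little data are shrunk towards their
#' area mean in proportion to their precision. Per-cluster summaries are the
#' posterior mean and the 2.5th/97.5th percentiles across draws.
#'
#' @param draws an [run_mcmc()] result.
#' @param data the [model_data()] the model was fitted to (clusters may be a
#'   subset of the draws' clusters, but every requested cluster must be
#'   present in the draws).
#' @return object of class `sae_cluster_pred`: `prob` (draws x clusters
#'   probability matrix, columns named by cluster id) and `summary`
#'   (data.frame `cluster_id, mean, lo95, hi95, n_individuals`).
#' @export
predict_cluster_probs <- function(draws, data) {
  stopifnot(inherits(draws, "sae_draws"), inherits(data, "sae_model_data"))
  missing <- setdiff(data$cluster_ids, draws$cluster_ids)
  if (length(missing)) {
    stop("cluster(s) missing from posterior draws: ",
         paste(missing, collapse = ", "))
  }
  idx <- match(data$cluster_ids, draws$cluster_ids)
  a_idx <- match(data$area_ids[data$area_of_cluster], draws$area_ids)
  s_idx <- match(data$state_ids[data$state_of_cluster], draws$state_ids)

  eta <- draws$params[, "beta0"] +
    draws$f[, s_idx, drop = FALSE] +
    draws$v[, a_idx, drop = FALSE] +
    draws$u[, idx, drop = FALSE]
  prob <- invlogit(eta)
  colnames(prob) <- data$cluster_ids

  qs <- apply(prob, 2, cri_percentile)
  summary <- data.frame(
    cluster_id = data$cluster_ids,
    mean = colMeans(prob),
    lo95 = qs[1, ],
    hi95 = qs[2, ],
    n_individuals = as.integer(data$n),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(prob = prob, summary = summary),
            class = "sae_cluster_pred")
}

#' Aggregate cluster probabilities to area prevalence
#'
#' For each retained draw an area's value is the *simple (unweighted) mean*
#' of its sampled clusters' probabilities; the area prevalence is the mean
#' of these per-draw values times 100, and the 95% credible interval is the
#' 2.5th/97.5th percentile of the per-draw values times 100. The unweighted
#' cluster average (rather than a design-weighted one) is deliberate and
#' mirrors how the published small-area prevalences are defined; see the
#' methods vignette. Areas with no sampled cluster are omitted.
#'
#' @param pred an [predict_cluster_probs()] result (or a bare draws x
#'   clusters probability matrix with column names).
#' @param membership data.frame `cluster_id, area_id` mapping every cluster
#'   to exactly one area.
#' @param round_label label for the survey round (e.g. `"2021"`).
#' @return data.frame of class `area_estimate`: `area_id, prevalence, lo95,
#'   hi95, n_clusters, round`, prevalence and bounds in percent.
#' @export
aggregate_area <- function(pred, membership, round_label = "2021") {
  prob <- if (inherits(pred, "sae_cluster_pred")) pred$prob else pred
  if (is.null(dim(prob)) || is.null(colnames(prob))) {
    stop("pred must be a draws x clusters matrix with cluster id columns")
  }
  if (!nrow(membership)) stop("membership is empty")
  if (anyDuplicated(membership$cluster_id)) {
    stop("membership maps a cluster to more than one area")
  }
  sampled <- intersect(membership$cluster_id, colnames(prob))
  mem <- membership[match(sampled, membership$cluster_id), ]
  if (!nrow(mem)) stop("no sampled clusters appear in membership")

  areas <- sort(unique(mem$area_id))
  a_idx <- match(mem$area_id, areas)
  # per-draw area means: indicator matrix divided by cluster counts
  counts <- tabulate(a_idx, nbins = length(areas))
  M <- matrix(0, length(sampled), length(areas))
  M[cbind(seq_along(a_idx), a_idx)] <- 1 / counts[a_idx]
  area_draws <- prob[, sampled, drop = FALSE] %*% M

  qs <- apply(area_draws, 2, cri_percentile)
  out <- data.frame(
    area_id = areas,
    prevalence = 100 * colMeans(area_draws),
    lo95 = 100 * qs[1, ],
    hi95 = 100 * qs[2, ],
    n_clusters = counts,
    round = round_label,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "area_draws") <- area_draws
  class(out) <- c("area_estimate", "data.frame")
  out
}

#' Drop areas with no sampled cluster
#'
#' Model-based prevalence cannot be produced for an area none of whose
#' clusters were sampled for the indicator; such areas are dropped and
#' reported.
#'
#' @param membership data.frame `cluster_id, area_id` over the full frame.
#' @param sampled_clusters character vector of cluster ids with data.
#' @return list with `retained` and `dropped` area id vectors.
#' @export
drop_unsampled_areas <- function(membership, sampled_clusters) {
  all_areas <- unique(membership$area_id)
  with_data <- unique(membership$area_id[membership$cluster_id %in%
                                           sampled_clusters])
  list(retained = all_areas[all_areas %in% with_data],
       dropped = all_areas[!all_areas %in% with_data])
}
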