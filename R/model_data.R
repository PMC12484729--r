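#' Assemble model data for the four-level logistic fit
#'
#' Encodes survey records into the nesting index arrays the sampler works
#' with: each individual maps to a cluster, each cluster to one area
#' (district or constituency — the interchangeable level-3 geography) and
#' one state. Cluster-level sufficient statistics (successes and sizes) are
#' precomputed because, with a random intercept per cluster and no
#' covariates, the likelihood depends on individuals only through them.
#'
#' @param records data.frame with columns `outcome`, `cluster_id`,
#'   `state_id`, and `district_id` and/or `pc_id`.
#' @param level which level-3 geography nests the clusters: `"district"`
#'   (default) or `"pc"`.
#' @return object of class `sae_model_data`: outcome vector `y`, individual
#'   cluster index `j`, cluster-level tallies `s` (successes) and `n`
#'   (sizes), maps `area_of_cluster`, `state_of_cluster`, `state_of_area`,
#'   and the id vocabularies `cluster_ids`, `area_ids`, `state_ids`.
#' @export
model_data <- function(records, level = c("district", "pc")) {
  level <- match.arg(level)
  area_col <- if (level == "district") "district_id" else "pc_id"
  need <- c("outcome", "cluster_id", "state_id", area_col)
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  y <- records$outcome
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcomes must be 0/1 with no missing values")
  }

  cluster <- as.character(records$cluster_id)
  area <- as.character(records[[area_col]])
  state <- as.character(records$state_id)

  # each cluster must sit in exactly one area and one state, each area in
  # exactly one state
  map <- unique(data.frame(cluster, area, state, stringsAsFactors = FALSE))
  if (anyDuplicated(map$cluster)) {
    bad <- map$cluster[duplicated(map$cluster)]
    stop("cluster(s) mapped to multiple areas/states: ",
         paste(unique(bad), collapse = ", "))
  }
  amap <- unique(map[, c("area", "state")])
  if (anyDuplicated(amap$area)) {
    stop("area(s) mapped to multiple states: ",
         paste(amap$area[duplicated(amap$area)], collapse = ", "))
  }

  cluster_ids <- sort(unique(cluster))
  area_ids <- sort(unique(area))
  state_ids <- sort(unique(state))
  j <- match(cluster, cluster_ids)

  ord <- match(cluster_ids, map$cluster)
  area_of_cluster <- match(map$area[ord], area_ids)
  state_of_cluster <- match(map$state[ord], state_ids)
  state_of_area <- match(amap$state[match(area_ids, amap$area)], state_ids)

  s <- as.numeric(tapply(y, factor(j, levels = seq_along(cluster_ids)), sum))
  n <- as.numeric(tabulate(j, nbins = length(cluster_ids)))

  structure(list(
    y = as.numeric(y), j = j, s = s, n = n,
    area_of_cluster = area_of_cluster,
    state_of_cluster = state_of_cluster,
    state_of_area = state_of_area,
    cluster_ids = cluster_ids, area_ids = area_ids, state_ids = state_ids,
    level = level
  ), class = "sae_model_data")
}

#' @export
print.sae_model_data <- function(x, ...) {
  cat("sae_model_data:", length(x$y), "individuals,",
      length(x$cluster_ids), "clusters,", length(x$area_ids), x$level,
      "areas,", length(x$state_ids), "states\n")
  invisible(x)
}

# Which random-effect levels are identifiable: a single state collapses the
# state effect; one area per state collapses the area effect (confounded with
# the state effect, or with the intercept when states are also collapsed);
# one cluster per area likewise collapses the cluster effect.
active_levels <- function(data) {
  n_state <- length(data$state_ids)
  state <- n_state >= 2
  area <- length(data$area_ids) >= 2 &&
    any(tabulate(data$state_of_area, nbins = n_state) >= 2)
  cluster <- length(data$cluster_ids) >= 2 &&
    any(tabulate(data$area_of_cluster, nbins = length(data$area_ids)) >= 2)
  c(state = state, area = area, cluster = cluster)
}
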