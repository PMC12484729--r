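#' Configuration for the synthetic multistage survey generator
#'
#' The generator emulates a multistage household survey: states contain
#' districts, districts contain clusters (primary sampling units), and
#' clusters contain individuals. A binary indicator is generated from the
#' four-level random-intercept logistic model
#' `logit(pi) = beta0 + f_state + v_district + u_cluster` with independent
#' zero-mean normal random effects.
#'
#' Defaults are the stated simulation world used throughout the test suite:
#' 15 states x 8 districts x 10 clusters x 25 individuals at
#' `beta0 = -0.5`, `sigma2_f = 0.2`, `sigma2_v = 0.1`, `sigma2_u = 0.3`,
#' and a national projected population of 114,273,000 persons (the published
#' denominator for under-five children used in the headcount worked example).
#'
#' @param n_states number of states (>= 1).
#' @param districts_per_state districts within each state (>= 1).
#' @param clusters_per_district clusters within each district (>= 1).
#' @param individuals_per_cluster target individuals per cluster (>= 1).
#' @param cluster_size_range nonnegative integer; realized cluster sizes are
#'   uniform on `individuals_per_cluster` plus or minus this range (floored
#'   at 1). Default 0: constant sizes.
#' @param beta0 intercept on the log-odds scale.
#' @param sigma2_f,sigma2_v,sigma2_u variances (>= 0) of the state, district
#'   and cluster random effects.
#' @param eligibility_rate probability in (0, 1] that an individual is
#'   eligible for the indicator; eligibility is independent thinning, which
#'   mimics indicator-specific target populations (e.g. children under five
#'   versus all adults).
#' @param weight_dispersion positive coefficient of variation of the design
#'   weights. Weights are log-normal with mean 1: the survey literature gives
#'   no canonical weight distribution and only relative weights matter
#'   downstream.
#' @param national_projected_pop projected national population used as the
#'   headcount multiplier (one per indicator, recycled).
#' @param indicators character vector of indicator ids to emulate.
#' @param seed integer RNG seed; a fixed seed makes every generated artifact
#'   byte-identical across runs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_states = 15L,
                       districts_per_state = 8L,
                       clusters_per_district = 10L,
                       individuals_per_cluster = 25L,
                       cluster_size_range = 0L,
                       beta0 = -0.5,
                       sigma2_f = 0.2,
                       sigma2_v = 0.1,
                       sigma2_u = 0.3,
                       eligibility_rate = 1,
                       weight_dispersion = 0.25,
                       national_projected_pop = 114273000,
                       indicators = "indicator_1",
                       seed = 1L) {
  counts <- c(n_states = n_states, districts_per_state = districts_per_state,
              clusters_per_district = clusters_per_district,
              individuals_per_cluster = individuals_per_cluster)
  if (any(counts < 1) || any(counts != floor(counts))) {
    stop_config("all hierarchy counts must be integers >= 1")
  }
  if (cluster_size_range < 0) stop_config("cluster_size_range must be >= 0")
  vars <- c(sigma2_f = sigma2_f, sigma2_v = sigma2_v, sigma2_u = sigma2_u)
  if (any(vars < 0)) stop_config("variances must be >= 0")
  if (eligibility_rate <= 0 || eligibility_rate > 1) {
    stop_config("eligibility_rate must be in (0, 1]")
  }
  if (weight_dispersion <= 0) stop_config("weight_dispersion must be > 0")
  if (any(national_projected_pop <= 0)) {
    stop_config("national_projected_pop must be > 0")
  }
  structure(list(
    n_states = as.integer(n_states),
    districts_per_state = as.integer(districts_per_state),
    clusters_per_district = as.integer(clusters_per_district),
    individuals_per_cluster = as.integer(individuals_per_cluster),
    cluster_size_range = as.integer(cluster_size_range),
    beta0 = beta0, sigma2_f = sigma2_f, sigma2_v = sigma2_v,
    sigma2_u = sigma2_u,
    eligibility_rate = eligibility_rate,
    weight_dispersion = weight_dispersion,
    national_projected_pop = national_projected_pop,
    indicators = indicators,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Zero-padded hierarchical ids: states S01..., districts S01D03, clusters
# S01D03C007. Ids are strings so accidental arithmetic on them fails loudly.
.sim_ids <- function(cfg) {
  ns <- cfg$n_states; nd <- cfg$districts_per_state; nc <- cfg$clusters_per_district
  state_id <- sprintf("S%02d", seq_len(ns))
  district_state <- rep(seq_len(ns), each = nd)
  district_id <- sprintf("%sD%02d", state_id[district_state],
                         rep(seq_len(nd), times = ns))
  cluster_district <- rep(seq_len(ns * nd), each = nc)
  cluster_id <- sprintf("%sC%03d", district_id[cluster_district],
                        rep(seq_len(nc), times = ns * nd))
  list(state_id = state_id, district_id = district_id, cluster_id = cluster_id,
       district_state = district_state, cluster_district = cluster_district,
       cluster_state = district_state[cluster_district])
}

# Parliamentary-constituency labels deliberately cross district lines: within
# a state the cluster sequence is cut into districts_per_state equal strips
# after a half-district offset (with wrap-around), so every PC except in
# degenerate layouts straddles two districts.
.sim_pc_of_cluster <- function(cfg, ids) {
  nd <- cfg$districts_per_state; nc <- cfg$clusters_per_district
  per_state <- nd * nc
  rank_in_state <- (seq_along(ids$cluster_id) - 1L) %% per_state
  if (nd == 1L) {
    pc_index <- rep(1L, length(rank_in_state))
  } else {
    shifted <- (rank_in_state + nc %/% 2L) %% per_state
    pc_index <- shifted %/% nc + 1L
  }
  sprintf("%sP%02d", ids$state_id[ids$cluster_state], pc_index)
}

#' Simulate a multistage binary-indicator survey
#'
#' Draws state, district and cluster random effects from their configured
#' normal distributions, forms each cluster's true probability by inverse
#' logit of the linear predictor, and generates Bernoulli outcomes and
#' log-normal design weights (mean 1) for every eligible individual.
#'
#' @param config a [sim_config()].
#' @return a list with components:
#'   \describe{
#'     \item{records}{data.frame, one row per eligible individual:
#'       `individual_id, cluster_id, district_id, pc_id, state_id, outcome,
#'       weight`.}
#'     \item{truth}{realized random effects and per-cluster true
#'       probabilities, kept only for parameter-recovery and calibration
#'       tests: data.frame `cluster_id, district_id, pc_id, state_id, f, v,
#'       u, eta, pi, n_target` plus attributes `f` and `v` (named vectors).}
#'   }
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- .sim_ids(config)
  ns <- config$n_states
  ndist <- length(ids$district_id)
  nclus <- length(ids$cluster_id)

  f <- stats::rnorm(ns, 0, sqrt(config$sigma2_f))
  v <- stats::rnorm(ndist, 0, sqrt(config$sigma2_v))
  u <- stats::rnorm(nclus, 0, sqrt(config$sigma2_u))
  names(f) <- ids$state_id; names(v) <- ids$district_id; names(u) <- ids$cluster_id

  eta <- config$beta0 + f[ids$cluster_state] + v[ids$cluster_district] + u
  pi_true <- invlogit(eta)
  pc_id <- .sim_pc_of_cluster(config, ids)

  sizes <- rep(config$individuals_per_cluster, nclus)
  if (config$cluster_size_range > 0) {
    r <- config$cluster_size_range
    sizes <- pmax(1L, sizes + sample.int(2L * r + 1L, nclus, replace = TRUE) - r - 1L)
  }

  cl_idx <- rep(seq_len(nclus), times = sizes)
  n_total <- length(cl_idx)
  outcome <- stats::rbinom(n_total, 1L, pi_true[cl_idx])
  # log-normal with mean exactly 1 and cv = weight_dispersion
  sdlog <- sqrt(log1p(config$weight_dispersion^2))
  weight <- stats::rlnorm(n_total, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  eligible <- stats::runif(n_total) <= config$eligibility_rate

  records <- data.frame(
    individual_id = sprintf("%sI%04d", ids$cluster_id[cl_idx],
                            stats::ave(cl_idx, cl_idx, FUN = seq_along)),
    cluster_id = ids$cluster_id[cl_idx],
    district_id = ids$district_id[ids$cluster_district][cl_idx],
    pc_id = pc_id[cl_idx],
    state_id = ids$state_id[ids$cluster_state][cl_idx],
    outcome = outcome,
    weight = weight,
    stringsAsFactors = FALSE
  )[eligible, , drop = FALSE]
  rownames(records) <- NULL

  truth <- data.frame(
    cluster_id = ids$cluster_id,
    district_id = ids$district_id[ids$cluster_district],
    pc_id = pc_id,
    state_id = ids$state_id[ids$cluster_state],
    f = unname(f[ids$cluster_state]),
    v = unname(v[ids$cluster_district]),
    u = unname(u),
    eta = unname(eta),
    pi = unname(pi_true),
    n_target = sizes,
    stringsAsFactors = FALSE
  )
  attr(truth, "f") <- f
  attr(truth, "v") <- v
  attr(truth, "config") <- config
  list(records = records, truth = truth)
}

#' Simulate planar survey geometry
#'
#' Builds an abstract planar fixture for the cluster-reassignment stage:
#' districts tile a rectangle as a grid (one row of cells per state), an
#' alternative constituency layer tiles the same rectangle as vertical strips
#' that cross district lines, and each cluster point is its true district's
#' centroid jittered uniformly by at most `displacement` in each coordinate.
#' With `displacement = 0` every point lies inside its true district; once
#' displacement exceeds the half-width of a grid cell some points escape
#' their polygon, which is exactly the situation the assignment bookkeeping
#' has to handle.
#'
#' Geometry is planar and unitless by design: the reassignment logic being
#' exercised is topological (point-in-polygon), not geodesic.
#'
#' @param config a [sim_config()].
#' @param displacement nonnegative maximum per-coordinate jitter.
#' @param n_pc number of constituency strips; default one fewer than the
#'   total number of districts (at least 1) so strip boundaries never
#'   coincide with district boundaries.
#' @return list with `districts` and `pcs` (polygon tables, see
#'   [polygon_table()]) and `cluster_points` (data.frame `cluster_id, x, y,
#'   microdata_state_id, microdata_area_id`).
#' @export
simulate_geometry <- function(config, displacement = 0, n_pc = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (displacement < 0) stop_config("displacement must be >= 0")
  ids <- .sim_ids(config)
  ns <- config$n_states; nd <- config$districts_per_state
  width <- nd; height <- ns

  # district cells: state l occupies row l, district k the k-th column
  rects <- lapply(seq_along(ids$district_id), function(i) {
    l <- ids$district_state[i]
    k <- (i - 1L) %% nd + 1L
    rect_coords(k - 1, l - 1, k, l)
  })
  districts <- polygon_table(ids$district_id,
                             ids$state_id[ids$district_state], rects)

  if (is.null(n_pc)) n_pc <- max(1L, ns * nd - 1L)
  pc_rects <- lapply(seq_len(n_pc), function(p) {
    rect_coords(width * (p - 1) / n_pc, 0, width * p / n_pc, height)
  })
  # strips span all states; tag each with the state of its centroid column
  pc_state <- ids$state_id[pmin(ns, floor(height / 2) + 1L)]
  pcs <- polygon_table(sprintf("PC%03d", seq_len(n_pc)),
                       rep(pc_state, n_pc), pc_rects)

  set.seed(config$seed + 1L)
  nclus <- length(ids$cluster_id)
  d_idx <- ids$cluster_district
  cx <- ((d_idx - 1L) %% nd) + 0.5
  cy <- (ids$district_state[d_idx] - 1L) + 0.5
  jx <- stats::runif(nclus, -displacement, displacement)
  jy <- stats::runif(nclus, -displacement, displacement)
  cluster_points <- data.frame(
    cluster_id = ids$cluster_id,
    x = cx + jx, y = cy + jy,
    microdata_state_id = ids$state_id[ids$cluster_state],
    microdata_area_id = ids$district_id[d_idx],
    stringsAsFactors = FALSE
  )
  list(districts = districts, pcs = pcs, cluster_points = cluster_points)
}

#' Simulate projected population totals
#'
#' Emits one national projected-population row per configured indicator;
#' downstream these totals play the role census projections play for real
#' data, as the multiplier turning weighted sample shares into headcount
#' denominators. A row is emitted for every indicator even if no individual
#' is eligible for it — the headcount stage decides what to do with it.
#'
#' @param config a [sim_config()].
#' @return data.frame `indicator_id, projected_pop`.
#' @export
simulate_projections <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  data.frame(
    indicator_id = config$indicators,
    projected_pop = rep_len(config$national_projected_pop,
                            length(config$indicators)),
    stringsAsFactors = FALSE
  )
}
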