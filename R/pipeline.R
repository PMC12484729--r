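#' Run configuration for the estimation pipeline
#'
#' A plain list validated into shape. Configs are read from JSON (the one
#' structured-config format whose parser ships with this package's
#' dependency set); every field has a default so `run_config()` alone gives
#' a small, fast demonstration run.
#'
#' @param seed master integer seed; every stage derives its own stream from
#'   it and it is recorded in all output metadata.
#' @param level level-3 geography: `"district"` or `"pc"`.
#' @param rounds character labels of the two survey rounds, earlier first.
#' @param sim named list of [sim_config()] overrides. `beta0` may be a
#'   vector with one value per round (to build in secular change).
#' @param mcmc named list of [mcmc_config()] overrides.
#' @param displacement cluster point jitter passed to
#'   [simulate_geometry()].
#' @param indicator named list: `id`, `label`, `category`, `direction`.
#' @param out output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, level = "district",
                       rounds = c("2016", "2021"),
                       sim = list(), mcmc = list(), displacement = 0,
                       indicator = list(), out = tempfile("prevsae_run_")) {
  if (!level %in% c("district", "pc")) {
    stop_config("unknown geography level: ", level,
                " (must be 'district' or 'pc')")
  }
  sim_defaults <- list(n_states = 6L, districts_per_state = 4L,
                       clusters_per_district = 6L,
                       individuals_per_cluster = 20L,
                       beta0 = c(-0.4, -0.6))
  sim <- utils::modifyList(sim_defaults, sim)
  mcmc <- utils::modifyList(list(burn_in = 300L, chain_length = 1800L), mcmc)
  ind_defaults <- list(id = "indicator_1", label = "Synthetic indicator",
                       category = "Synthetic", direction = "lower_is_better")
  indicator <- utils::modifyList(ind_defaults, indicator)
  structure(list(seed = as.integer(seed), level = level, rounds = rounds,
                 sim = sim, mcmc = mcmc, displacement = displacement,
                 indicator = indicator, out = out),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' @param path JSON file whose top-level fields match [run_config()]
#'   arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[names(raw) %in% names(formals(run_config))])
}

.stage <- function(name, log, expr) {
  t0 <- Sys.time()
  result <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  log$timings[[name]] <- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  result
}

# per-round seeds derived from the master seed; kept well under 2^31
.round_seed <- function(seed, i, offset = 0L) {
  (seed * 131L + i * 7919L + offset) %% 2000000011L
}

#' Rebuild posterior draws from an exported chain CSV
#'
#' Inverse of [export_chains()]: reconstructs an `sae_draws`-shaped object
#' (draws, unit vocabularies, ESS and low-ESS flags) from the one-column-
#' per-parameter CSV.
#'
#' @param path chain CSV written by [export_chains()].
#' @return object of class `sae_draws`.
#' @export
import_chains <- function(path) {
  chains <- as.matrix(utils::read.csv(path, check.names = FALSE))
  cols <- colnames(chains)
  pick <- function(prefix) {
    sel <- grepl(paste0("^", prefix, "\\["), cols)
    m <- chains[, sel, drop = FALSE]
    colnames(m) <- sub("^.\\[(.*)\\]$", "\\1", cols[sel])
    m
  }
  Fm <- pick("f"); Vm <- pick("v"); Um <- pick("u")
  P <- chains[, c("beta0", "sigma2_f", "sigma2_v", "sigma2_u"), drop = FALSE]
  ess <- vapply(seq_len(ncol(chains)),
                function(i) as.numeric(effective_sample_size(chains[, i])),
                numeric(1))
  names(ess) <- cols
  out <- list(params = P, f = Fm, v = Vm, u = Um, ess = ess,
              low_ess = flag_low_ess(ess), accept = NULL,
              active = c(state = ncol(Fm) > 0, area = ncol(Vm) > 0,
                         cluster = ncol(Um) > 0),
              cluster_ids = colnames(Um), area_ids = colnames(Vm),
              state_ids = colnames(Fm), config = NULL)
  class(out) <- "sae_draws"
  out
}

#' Run the full small-area estimation pipeline
#'
#' Executes simulate -> assign -> fit (MQL1 then MCMC) -> predict ->
#' aggregate -> indicators (direct estimates, headcounts, ranks, change)
#' -> export, writing every intermediate artifact as CSV/GeoJSON into the
#' output directory, plus the five-sheet results workbook and a JSON run
#' log with the seed, chain settings, stage timings and any low-ESS flags.
#' A stage failure propagates with the stage name; artifacts written by
#' earlier stages are left intact.
#'
#' @param config a [run_config()] (or path to a JSON config file).
#' @param upto run only the pipeline prefix ending at this stage (stages are
#'   re-derived deterministically from the seed, so any prefix is
#'   self-contained): one of `"simulate"`, `"assign"`, `"fit"`,
#'   `"predict"`, `"aggregate"`, `"rank"`, `"change"`, `"export"`, `"all"`.
#' @return the output directory path, invisibly; the run log is also
#'   returned as attribute `log`.
#' @export
run_pipeline <- function(config = run_config(), upto = "all") {
  stages <- c(simulate = 1, assign = 2, fit = 3, predict = 4,
              aggregate = 5, rank = 6, change = 7, export = 8, all = 8)
  if (!upto %in% names(stages)) {
    stop_config("unknown pipeline stage: ", upto)
  }
  level_upto <- stages[[upto]]
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- new.env()
  log$timings <- list()

  rounds <- config$rounds
  beta0s <- rep_len(config$sim$beta0 %||% -0.5, length(rounds))
  area_col <- if (config$level == "district") "district_id" else "pc_id"

  sims <- list(); assigns <- list(); est <- list(); preds <- list()
  draws_all <- list()
  meta <- indicator_meta(config$indicator$id, config$indicator$label,
                         config$indicator$category,
                         config$indicator$direction, rounds)

  for (i in seq_along(rounds)) {
    r <- rounds[i]
    sim_args <- config$sim
    sim_args$beta0 <- beta0s[i]
    sim_args$seed <- .round_seed(config$seed, i)
    sim_args$indicators <- config$indicator$id
    cfg <- do.call(sim_config, sim_args)

    sims[[r]] <- .stage(paste0("simulate_", r), log, {
      sv <- simulate_survey(cfg)
      utils::write.csv(sv$records,
                       file.path(out_dir, paste0("records_", r, ".csv")),
                       row.names = FALSE)
      geom <- simulate_geometry(cfg, displacement = config$displacement)
      write_geojson_polygons(geom$districts,
                             file.path(out_dir, paste0("districts_", r,
                                                       ".geojson")))
      write_geojson_points(geom$cluster_points,
                           file.path(out_dir, paste0("clusters_", r,
                                                     ".geojson")))
      utils::write.csv(simulate_projections(cfg),
                       file.path(out_dir, "projections.csv"),
                       row.names = FALSE)
      c(sv, list(geom = geom, cfg = cfg))
    })

    if (level_upto < 2) next
    assigns[[r]] <- .stage(paste0("assign_", r), log, {
      asg <- assign_clusters(sims[[r]]$geom$cluster_points,
                             sims[[r]]$geom$districts,
                             single_unit_states = config$single_unit_states)
      utils::write.csv(asg,
                       file.path(out_dir, paste0("assignments_", r, ".csv")),
                       row.names = FALSE)
      asg
    })

    if (level_upto < 3) next
    # reassignment feeds the model at district level; constituency labels
    # come from the records (the synthetic PC layer crosses states, so the
    # spatial fixture is exercised but not used to relabel PCs)
    records <- sims[[r]]$records
    if (config$level == "district") {
      asg <- assigns[[r]]
      keep <- asg$cluster_id[asg$status != "dropped"]
      new_area <- stats::setNames(asg$assigned_area_id, asg$cluster_id)
      records <- records[records$cluster_id %in% keep, ]
      records$district_id <- unname(new_area[records$cluster_id])
    }

    fitted <- .stage(paste0("fit_", r), log, {
      md <- model_data(records, level = config$level)
      start <- fit_mql1(md)
      mcfg_args <- config$mcmc
      mcfg_args$seed <- .round_seed(config$seed, i, offset = 17L)
      mcfg <- do.call(mcmc_config, mcfg_args)
      draws <- run_mcmc(md, start, mcfg)
      export_chains(draws, file.path(out_dir, paste0("chains_", r, ".csv")))
      export_diagnostics(draws,
                         file.path(out_dir, paste0("diagnostics_", r,
                                                   ".csv")))
      jsonlite::write_json(start[c("beta0", "sigma2_f", "sigma2_v",
                                   "sigma2_u")],
                           file.path(out_dir, paste0("params_mql1_", r,
                                                     ".json")),
                           auto_unbox = TRUE, digits = NA)
      list(md = md, draws = draws, records = records)
    })
    draws_all[[r]] <- fitted$draws

    if (level_upto < 4) next
    preds[[r]] <- .stage(paste0("predict_", r), log, {
      pred <- predict_cluster_probs(fitted$draws, fitted$md)
      utils::write.csv(pred$summary,
                       file.path(out_dir, paste0("cluster_pred_", r,
                                                 ".csv")),
                       row.names = FALSE)
      pred
    })

    if (level_upto < 5) next
    est[[r]] <- .stage(paste0("aggregate_", r), log, {
      membership <- unique(fitted$records[, c("cluster_id", area_col)])
      names(membership)[2] <- "area_id"
      ae <- aggregate_area(preds[[r]], membership, round_label = r)
      utils::write.csv(as.data.frame(ae),
                       file.path(out_dir, paste0("area_est_", r, ".csv")),
                       row.names = FALSE)
      ae
    })
  }

  ind <- if (level_upto >= 6) .stage("indicators", log, {
    last <- rounds[length(rounds)]
    nat <- do.call(rbind, lapply(rounds, function(r) data.frame(
      indicator_id = config$indicator$id, round = r,
      prevalence = direct_weighted_prevalence(sims[[r]]$records),
      stringsAsFactors = FALSE)))
    st <- do.call(rbind, lapply(rounds, function(r) {
      d <- direct_weighted_prevalence(sims[[r]]$records, by = "state_id")
      data.frame(indicator_id = config$indicator$id, state_id = d$group,
                 round = r, prevalence = d$prevalence,
                 stringsAsFactors = FALSE)
    }))
    shares <- weighted_sample_share(sims[[last]]$records, area_col)
    proj <- simulate_projections(sims[[last]]$cfg)
    shares$denominator <- compute_denominator(
      shares$share, proj$projected_pop[proj$indicator_id ==
                                         config$indicator$id][1])
    hc <- merge(est[[last]][, c("area_id", "prevalence")], shares,
                by = "area_id")
    hc$headcount <- compute_headcount(hc$prevalence, hc$denominator)
    utils::write.csv(hc, file.path(out_dir, "headcounts.csv"),
                     row.names = FALSE)

    ranked <- lapply(rounds, function(r) {
      rk <- rank_areas(est[[r]], meta)
      utils::write.csv(as.data.frame(rk),
                       file.path(out_dir, paste0("ranks_", r, ".csv")),
                       row.names = FALSE)
      rk
    })
    names(ranked) <- rounds
    chg <- NULL
    if (level_upto >= 7) {
      chg <- classify_change(est[[rounds[1]]],
                             est[[rounds[length(rounds)]]], meta)
      utils::write.csv(as.data.frame(chg),
                       file.path(out_dir, "changes.csv"), row.names = FALSE)
    }
    list(national = nat, state = st, headcounts = hc, ranked = ranked,
         change = chg)
  }) else NULL

  if (level_upto >= 8) .stage("export", log, {
    last <- rounds[length(rounds)]
    all_states <- sort(unique(ind$state$state_id))
    all_areas <- unique(do.call(rbind, lapply(est, function(e)
      e[, "area_id", drop = FALSE])))$area_id
    area_state <- unique(do.call(rbind, lapply(rounds, function(r)
      unique(sims[[r]]$records[, c(area_col, "state_id")]))))
    # a reassigned area can only belong to one state in the synthetic world
    area_state <- area_state[!duplicated(area_state[[area_col]]), ]
    layout <- workbook_layout(
      indicators = data.frame(indicator_id = config$indicator$id,
                              label = config$indicator$label,
                              category = config$indicator$category,
                              stringsAsFactors = FALSE),
      states = data.frame(state_id = all_states, label = all_states,
                          stringsAsFactors = FALSE),
      areas = data.frame(area_id = area_state[[area_col]],
                         state_id = area_state$state_id,
                         label = area_state[[area_col]],
                         stringsAsFactors = FALSE),
      level = config$level)

    area_est <- do.call(rbind, lapply(rounds, function(r) {
      e <- as.data.frame(ind$ranked[[r]])
      e$indicator_id <- config$indicator$id
      e$headcount <- if (r == last)
        ind$headcounts$headcount[match(e$area_id, ind$headcounts$area_id)]
      else NA
      chg <- ind$change
      e$change_pp <- chg$change_pp[match(e$area_id, chg$area_id)]
      e$change_category <- chg$category[match(e$area_id, chg$area_id)]
      e
    }))
    area_est <- area_est[area_est$area_id %in% layout$dictionary$code, ]
    export_workbook(ind$national, ind$state, area_est, layout,
                    file.path(out_dir, "results.xlsx"))
  })

  run_log <- list(seed = config$seed, level = config$level,
                  rounds = rounds, mcmc = config$mcmc,
                  timings = log$timings,
                  low_ess = lapply(draws_all, function(d) d$low_ess))
  jsonlite::write_json(run_log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, null = "list")
  invisible(structure(out_dir, log = run_log))
}
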