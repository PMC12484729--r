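#' Indicator metadata
#'
#' Every ranked indicator needs a normative direction: whether a higher
#' value is better (e.g. full vaccination) or worse (e.g. child
#' underweight). Ranks, deciles and change categories are all
#' direction-adjusted so that rank 1 and decile 1 are always "best".
#'
#' @param indicator_id short stable id.
#' @param label human-readable label.
#' @param category thematic domain the indicator belongs to.
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @param rounds survey rounds the indicator is available for.
#' @return object of class `indicator_meta`.
#' @export
indicator_meta <- function(indicator_id, label = indicator_id,
                           category = "General",
                           direction = c("lower_is_better",
                                         "higher_is_better"),
                           rounds = c("2016", "2021")) {
  direction <- match.arg(direction)
  structure(list(indicator_id = indicator_id, label = label,
                 category = category, direction = direction,
                 rounds = rounds),
            class = "indicator_meta")
}

#' Direct design-weighted prevalence
#'
#' The classical survey estimator `100 * sum(w * y) / sum(w)`, used for
#' large geographies (states, nation) where direct estimation is stable,
#' and as the cross-check against which model-based estimates are
#' validated.
#'
#' @param records survey records with `outcome` and `weight` columns.
#' @param by optional column name to group by (e.g. `"state_id"`); `NULL`
#'   gives the national estimate.
#' @return a scalar percentage, or a data.frame `group, prevalence` when
#'   `by` is given. Empty groups are omitted with a warning.
#' @export
direct_weighted_prevalence <- function(records, by = NULL) {
  stopifnot(all(c("outcome", "weight") %in% names(records)))
  if (is.null(by)) {
    if (!nrow(records)) stop("no records")
    return(100 * sum(records$weight * records$outcome) / sum(records$weight))
  }
  groups <- split(records, records[[by]], drop = FALSE)
  empty <- names(groups)[vapply(groups, nrow, integer(1)) == 0]
  if (length(empty)) {
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
    groups <- groups[vapply(groups, nrow, integer(1)) > 0]
  }
  data.frame(
    group = names(groups),
    prevalence = vapply(groups, function(g)
      100 * sum(g$weight * g$outcome) / sum(g$weight), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Weighted sample share of each area
#'
#' Each area's share of the total design weight for the indicator's
#' eligible sample; shares sum to one and are the sample-distribution proxy
#' that allocates the national projected population across areas.
#'
#' @param records survey records with a `weight` column.
#' @param area_col column naming the area partition (e.g. `"district_id"`).
#' @return data.frame `area_id, share`.
#' @export
weighted_sample_share <- function(records, area_col = "district_id") {
  total <- sum(records$weight)
  if (!(total > 0)) stop("total weight must be > 0")
  w <- tapply(records$weight, records[[area_col]], sum)
  data.frame(area_id = names(w), share = as.numeric(w) / total,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Projected denominator for an area
#'
#' `share * national_pop`, rounded half away from zero at the final step —
#' e.g. a 4.2% share of a 114,273,000-person national projection gives a
#' denominator of 4,799,466 persons.
#'
#' @param share area share(s) of the national sample, in `[0, 1]`.
#' @param national_pop projected national population.
#' @return integer-valued denominator(s) in persons.
#' @export
compute_denominator <- function(share, national_pop) {
  stopifnot(all(share >= 0 & share <= 1), national_pop >= 0)
  round_half_away(share * national_pop)
}

#' Headcount for an area
#'
#' `prevalence / 100 * denominator`, rounded half away from zero at the
#' final step only.
#'
#' @param prevalence prevalence(s) in percent, in `[0, 100]`.
#' @param denominator projected persons in the area.
#' @return headcount(s) in persons.
#' @export
compute_headcount <- function(prevalence, denominator) {
  stopifnot(all(prevalence >= 0 & prevalence <= 100), all(denominator >= 0))
  round_half_away(prevalence / 100 * denominator)
}

#' Direction-adjusted ranks and decile positions
#'
#' Areas are ordered best-to-worst after adjusting for the indicator's
#' normative direction (for a `lower_is_better` indicator ascending
#' prevalence is best), so a lower rank always indicates a better outcome.
#' Ties share the minimum rank; the decile position is
#' `ceiling(10 * rank / n)`, so decile 1 holds the best areas.
#'
#' @param estimates an area estimate table with `area_id` and `prevalence`.
#' @param meta an [indicator_meta()] (its `direction` must be defined).
#' @return `estimates` with `rank` and `decile` columns appended.
#' @export
rank_areas <- function(estimates, meta) {
  if (!inherits(meta, "indicator_meta") || is.null(meta$direction)) {
    stop("normative direction undefined for indicator ",
         if (is.list(meta)) meta$indicator_id else "<unknown>")
  }
  if (!nrow(estimates)) stop("no area estimates to rank")
  key <- if (meta$direction == "lower_is_better") estimates$prevalence
         else -estimates$prevalence
  rk <- rank(key, ties.method = "min")
  out <- estimates
  out$rank <- as.integer(rk)
  out$decile <- as.integer(ceiling(10 * rk / nrow(estimates)))
  out
}

#' Classify between-round change
#'
#' Change is the percentage-point difference `prevalence_2021 -
#' prevalence_2016`. A change in the normatively good direction counts as
#' improvement. Within the improving and worsening subsets separately, the
#' absolute change is split at that subset's median: strictly above the
#' median is a "large" change, at or below it "small". Areas with exactly
#' zero change are counted as `improved_small` by explicit convention (and
#' flagged in the `zero_change` column). Areas present in only one round
#' are excluded and listed in the `excluded` attribute.
#'
#' @param est2016,est2021 area estimate tables for the two rounds.
#' @param meta an [indicator_meta()].
#' @return data.frame of class `change_record`: `area_id, prev_2016,
#'   prev_2021, change_pp, improving, category, zero_change`, with
#'   attribute `excluded` listing areas in only one round.
#' @export
classify_change <- function(est2016, est2021, meta) {
  stopifnot(inherits(meta, "indicator_meta"))
  common <- intersect(est2016$area_id, est2021$area_id)
  excluded <- setdiff(union(est2016$area_id, est2021$area_id), common)
  if (!length(common)) stop("no areas present in both rounds")
  p16 <- est2016$prevalence[match(common, est2016$area_id)]
  p21 <- est2021$prevalence[match(common, est2021$area_id)]
  change <- p21 - p16
  good_sign <- if (meta$direction == "lower_is_better") -1 else 1
  improving <- change * good_sign > 0 | change == 0
  mag <- abs(change)

  category <- character(length(change))
  for (side in c(TRUE, FALSE)) {
    in_side <- improving == side
    if (!any(in_side)) next
    med <- stats::median(mag[in_side])
    big <- in_side & mag > med     # median itself goes to the "small" group
    lab <- if (side) c("improved_small", "improved_large")
           else c("worsened_small", "worsened_large")
    category[in_side & !big] <- lab[1]
    category[big] <- lab[2]
  }

  out <- data.frame(area_id = common, prev_2016 = p16, prev_2021 = p21,
                    change_pp = change, improving = improving,
                    category = category, zero_change = change == 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  class(out) <- c("change_record", "data.frame")
  out
}
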