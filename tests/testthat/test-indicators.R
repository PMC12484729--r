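test_that("direct weighted prevalence: hand arithmetic and loop oracle", {
  r <- data.frame(outcome = c(1, 0, 0, 1), weight = 1)
  expect_equal(direct_weighted_prevalence(r), 50.0)
  r2 <- data.frame(outcome = c(1, 0), weight = c(3, 1))
  expect_equal(direct_weighted_prevalence(r2), 75.0)

  cfg <- tiny_config(seed = 13, weight_dispersion = 0.5)
  recs <- simulate_survey(cfg)$records
  # brute-force loop oracle
  num <- 0; den <- 0
  for (i in seq_len(nrow(recs))) {
    num <- num + recs$weight[i] * recs$outcome[i]
    den <- den + recs$weight[i]
  }
  expect_equal(direct_weighted_prevalence(recs), 100 * num / den,
               tolerance = 1e-12)
  by_state <- direct_weighted_prevalence(recs, by = "state_id")
  expect_equal(sort(by_state$group), sort(unique(recs$state_id)))
})

test_that("weighted sample shares partition the total weight", {
  r <- data.frame(district_id = c("A", "A", "B"),
                  weight = c(1, 1, 2))
  sh <- weighted_sample_share(r)
  expect_equal(sh$share[sh$area_id == "A"], 0.5)
  expect_equal(sh$share[sh$area_id == "B"], 0.5)
  one <- weighted_sample_share(data.frame(district_id = "A", weight = 5))
  expect_equal(one$share, 1)

  cfg <- sim_config(n_states = 4L, districts_per_state = 5L,
                    clusters_per_district = 3L,
                    individuals_per_cluster = 10L, seed = 17)
  recs <- simulate_survey(cfg)$records
  sh20 <- weighted_sample_share(recs)
  expect_equal(nrow(sh20), 20L)
  expect_lt(abs(sum(sh20$share) - 1), 1e-12)
})

test_that("denominators and headcounts follow the published arithmetic", {
  # worked example: a 4.2% sample share of 114,273,000 children
  expect_equal(compute_denominator(0.042, 114273000), 4799466)
  expect_equal(compute_denominator(0, 114273000), 0)
  expect_equal(compute_denominator(1, 114273000), 114273000)
  expect_equal(compute_headcount(0, 4799466), 0)
  expect_equal(compute_headcount(100, 4799466), 4799466)
  expect_equal(compute_headcount(34.1, 1000000), 341000)
  # rounding happens half-away-from-zero at the final step only
  expect_equal(compute_headcount(50, 3), 2)  # 1.5 -> 2
})

test_that("headcounts sum to at most the national total", {
  set.seed(3)
  shares <- as.numeric(prop.table(runif(50)))
  den <- compute_denominator(shares, 1e7)
  prev <- runif(50, 0, 100)
  expect_lte(sum(compute_headcount(prev, den)), 1e7 + 25)  # rounding slack
  expect_equal(sum(compute_headcount(rep(100, 50), den)), sum(den))
})

test_that("ranks adjust for normative direction and ties share min rank", {
  est <- data.frame(area_id = c("a", "b", "c"),
                    prevalence = c(10, 20, 30))
  lo <- rank_areas(est, indicator_meta("x", direction = "lower_is_better"))
  expect_equal(lo$rank, c(1L, 2L, 3L))
  hi <- rank_areas(est, indicator_meta("x", direction = "higher_is_better"))
  expect_equal(hi$rank, c(3L, 2L, 1L))
  # reversing direction exactly reverses the ordering
  expect_equal(lo$rank, rev(hi$rank)[rank(est$prevalence)])
  tie <- rank_areas(data.frame(area_id = c("a", "b", "c"),
                               prevalence = c(5, 5, 9)),
                    indicator_meta("x", direction = "lower_is_better"))
  expect_equal(tie$rank, c(1L, 1L, 3L))
})

test_that("deciles partition 700 tie-free areas into 70 each", {
  set.seed(8)
  est <- data.frame(area_id = sprintf("A%03d", 1:700),
                    prevalence = sample(seq(1, 99, length.out = 700)))
  rk <- rank_areas(est, indicator_meta("x", direction = "lower_is_better"))
  expect_equal(sort(unique(rk$rank)), 1:700)
  expect_equal(unname(table(rk$decile)), rep(70L, 10L), ignore_attr = TRUE)
  # ranking is a permutation
  expect_equal(sort(rk$rank), 1:700)
})

test_that("change classification: direction, median split, conventions", {
  meta <- indicator_meta("x", direction = "lower_is_better")
  e16 <- data.frame(area_id = c("a", "b", "c", "d", "e"),
                    prevalence = c(40, 30, 20, 10, 25))
  e21 <- data.frame(area_id = c("a", "b", "c", "d", "e"),
                    prevalence = c(30, 28, 21, 14, 25))
  ch <- classify_change(e16, e21, meta)
  # a improved by 10pp, b by 2; c worsened by 1, d by 4; e unchanged
  expect_equal(ch$change_pp[ch$area_id == "a"], -10)
  expect_true(ch$improving[ch$area_id == "a"])
  expect_false(ch$improving[ch$area_id == "c"])
  expect_equal(ch$category[ch$area_id == "e"], "improved_small")
  expect_true(ch$zero_change[ch$area_id == "e"])
  # categories partition the common areas
  expect_true(all(nchar(ch$category) > 0))

  # median split oracle on the improving side: |changes| {2,4,6,8} -> median
  # 5 -> {small, small, large, large}
  e16b <- data.frame(area_id = letters[1:4], prevalence = c(10, 10, 10, 10))
  e21b <- data.frame(area_id = letters[1:4],
                     prevalence = c(8, 6, 4, 2))
  chb <- classify_change(e16b, e21b, meta)
  expect_equal(chb$category,
               c("improved_small", "improved_small", "improved_large",
                 "improved_large"))

  # identical rounds: all zero change, all improved_small by convention
  chz <- classify_change(e16, e16, meta)
  expect_true(all(chz$category == "improved_small"))
  expect_true(all(chz$zero_change))
})

test_that("swapping rounds maps improvement to worsening, magnitudes kept", {
  meta <- indicator_meta("x", direction = "lower_is_better")
  set.seed(12)
  e16 <- data.frame(area_id = sprintf("A%02d", 1:20),
                    prevalence = runif(20, 10, 60))
  e21 <- data.frame(area_id = e16$area_id,
                    prevalence = e16$prevalence + rnorm(20, 0, 6))
  fwd <- classify_change(e16, e21, meta)
  rev <- classify_change(e21, e16, meta)
  expect_equal(fwd$change_pp, -rev$change_pp)
  swap <- c(improved_small = "worsened_small",
            improved_large = "worsened_large",
            worsened_small = "improved_small",
            worsened_large = "improved_large")
  expect_equal(unname(swap[fwd$category]), rev$category)
})

test_that("areas missing from one round are excluded and reported", {
  meta <- indicator_meta("x", direction = "lower_is_better")
  e16 <- data.frame(area_id = c("a", "b"), prevalence = c(10, 20))
  e21 <- data.frame(area_id = c("b", "c"), prevalence = c(15, 30))
  ch <- classify_change(e16, e21, meta)
  expect_equal(ch$area_id, "b")
  expect_equal(sort(attr(ch, "excluded")), c("a", "c"))
})

test_that("undefined direction errors, empty groups warn", {
  est <- data.frame(area_id = "a", prevalence = 10)
  meta <- list(indicator_id = "x", direction = NULL)
  expect_error(rank_areas(est, meta), "direction")
  expect_error(direct_weighted_prevalence(
    data.frame(outcome = numeric(0), weight = numeric(0))), "no records")
})
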