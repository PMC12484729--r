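# a small fitted model reused across prediction tests
local_pred_fixture <- local({
  fix <- NULL
  function() {
    if (is.null(fix)) {
      cfg <- tiny_config(seed = 23)
      sv <- simulate_survey(cfg)
      md <- model_data(sv$records)
      dr <- run_mcmc(md, fit_mql1(md), fast_mcmc(seed = 5))
      fix <<- list(sv = sv, md = md, dr = dr,
                   pred = predict_cluster_probs(dr, md))
    }
    fix
  }
})

test_that("cluster probabilities are the inverse-logit of the draws", {
  f <- local_pred_fixture()
  # brute force for one cluster: recombine the chains by hand
  cl <- f$md$cluster_ids[7]
  l <- f$md$state_of_cluster[7]; k <- f$md$area_of_cluster[7]
  eta <- f$dr$params[, "beta0"] + f$dr$f[, l] + f$dr$v[, k] + f$dr$u[, 7]
  expect_equal(unname(f$pred$prob[, cl]), unname(invlogit(eta)))
  s <- f$pred$summary
  expect_true(all(s$lo95 <= s$mean & s$mean <= s$hi95))
  expect_true(all(s$mean > 0 & s$mean < 1))
})

test_that("an all-zero draw predicts probability one half", {
  dr <- structure(list(
    params = cbind(beta0 = c(0, 0), sigma2_f = c(1, 1), sigma2_v = c(1, 1),
                   sigma2_u = c(1, 1)),
    f = matrix(0, 2, 1, dimnames = list(NULL, "S1")),
    v = matrix(0, 2, 1, dimnames = list(NULL, "D1")),
    u = matrix(0, 2, 2, dimnames = list(NULL, c("C1", "C2"))),
    cluster_ids = c("C1", "C2"), area_ids = "D1", state_ids = "S1"),
    class = "sae_draws")
  recs <- data.frame(cluster_id = rep(c("C1", "C2"), each = 3),
                     district_id = "D1", state_id = "S1",
                     outcome = rep(c(0, 1), 3), weight = 1)
  md <- suppress_degenerate(model_data(recs))
  pred <- predict_cluster_probs(dr, md)
  expect_equal(pred$summary$mean, c(0.5, 0.5))
  # degenerate (identical) draws collapse the credible interval
  expect_equal(pred$summary$lo95, pred$summary$mean)
  expect_equal(pred$summary$hi95, pred$summary$mean)
})

test_that("missing clusters in the draws are reported by name", {
  f <- local_pred_fixture()
  recs <- f$sv$records
  recs$cluster_id[1] <- "GHOST"
  md2 <- suppressWarnings(model_data(recs[recs$cluster_id == "GHOST" |
                                            recs$cluster_id %in%
                                            f$md$cluster_ids[1:5], ]))
  expect_error(predict_cluster_probs(f$dr, md2), "GHOST")
})

test_that("stored credible intervals match an independent percentile oracle", {
  f <- local_pred_fixture()
  for (cl in sample(colnames(f$pred$prob), 5)) {
    x <- f$pred$prob[, cl]
    i <- match(cl, f$pred$summary$cluster_id)
    expect_equal(f$pred$summary$lo95[i], manual_percentile(x, 0.025),
                 tolerance = 1e-12)
    expect_equal(f$pred$summary$hi95[i], manual_percentile(x, 0.975),
                 tolerance = 1e-12)
  }
})

test_that("area aggregation equals the matrix-product oracle", {
  set.seed(71)
  prob <- matrix(runif(200 * 9), 200, 9,
                 dimnames = list(NULL, paste0("C", 1:9)))
  membership <- data.frame(cluster_id = paste0("C", 1:9),
                           area_id = rep(c("A1", "A2", "A3"), c(2, 3, 4)))
  est <- aggregate_area(prob, membership, round_label = "2021")
  # oracle: indicator matrix divided by cluster counts
  M <- sapply(c("A1", "A2", "A3"), function(a)
    as.numeric(membership$area_id == a) / sum(membership$area_id == a))
  oracle <- prob %*% M
  ad <- attr(est, "area_draws")
  expect_equal(unname(ad), unname(oracle), tolerance = 1e-12)
  expect_equal(est$prevalence, 100 * colMeans(oracle), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(est$n_clusters, c(2L, 3L, 4L))
  expect_true(all(est$lo95 <= est$prevalence & est$prevalence <= est$hi95))
})

test_that("aggregation arithmetic and single-cluster areas are exact", {
  prob <- matrix(rep(c(0.2, 0.4, 0.7), each = 50), 50, 3,
                 dimnames = list(NULL, c("Ca", "Cb", "Cc")))
  membership <- data.frame(cluster_id = c("Ca", "Cb", "Cc"),
                           area_id = c("A", "A", "B"))
  est <- aggregate_area(prob, membership)
  expect_equal(est$prevalence[est$area_id == "A"], 30.0)
  # single-cluster area equals that cluster's summary times 100
  expect_equal(est$prevalence[est$area_id == "B"], 70.0)
  expect_equal(est$lo95[est$area_id == "B"], 70.0)
})

test_that("aggregation is invariant to cluster and draw order", {
  f <- local_pred_fixture()
  membership <- unique(f$sv$records[, c("cluster_id", "district_id")])
  names(membership) <- c("cluster_id", "area_id")
  a <- aggregate_area(f$pred$prob, membership)
  perm <- sample(ncol(f$pred$prob))
  b <- aggregate_area(f$pred$prob[, perm], membership[sample(nrow(membership)), ])
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
})

test_that("area prevalence lies within its clusters' posterior means", {
  f <- local_pred_fixture()
  membership <- unique(f$sv$records[, c("cluster_id", "district_id")])
  names(membership) <- c("cluster_id", "area_id")
  est <- aggregate_area(f$pred$prob, membership)
  for (i in seq_len(nrow(est))) {
    cls <- membership$cluster_id[membership$area_id == est$area_id[i]]
    rng <- range(f$pred$summary$mean[f$pred$summary$cluster_id %in% cls])
    expect_gte(est$prevalence[i], 100 * rng[1] - 1e-9)
    expect_lte(est$prevalence[i], 100 * rng[2] + 1e-9)
  }
})

test_that("unsampled areas are dropped and reported", {
  membership <- data.frame(cluster_id = paste0("C", 1:720),
                           area_id = paste0("A", 1:720))
  sampled <- membership$cluster_id[-c(5, 100, 333, 600, 720)]
  d <- drop_unsampled_areas(membership, sampled)
  expect_length(d$retained, 715)
  expect_equal(d$dropped, paste0("A", c(5, 100, 333, 600, 720)))
  # all sampled -> empty report
  d2 <- drop_unsampled_areas(membership, membership$cluster_id)
  expect_length(d2$dropped, 0)
  # aggregation omits areas without sampled clusters
  prob <- matrix(0.5, 10, 3, dimnames = list(NULL, paste0("C", 1:3)))
  est <- aggregate_area(prob, membership)
  expect_equal(est$area_id, paste0("A", 1:3))
})

test_that("empty membership errors", {
  prob <- matrix(0.5, 10, 1, dimnames = list(NULL, "C1"))
  expect_error(aggregate_area(prob, data.frame(cluster_id = character(0),
                                               area_id = character(0))),
               "empty")
})
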