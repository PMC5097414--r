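base_set <- function() {
  trial_set(data.frame(
    study_id = c("s1", "s2", "s3", "s4"),
    year = c(2000L, 2002L, 2005L, 2008L),
    blinded = c(TRUE, TRUE, FALSE, TRUE),
    follow_up_weeks = 26,
    n_t = c(150, 60, 200, 140), r_t = c(4, 1, 6, 3),
    n_c = c(145, 62, 195, 138), r_c = c(2, 1, 3, 2)),
    ae_category = "serious/any")
}

test_that("event deltas edit exactly the targeted cells", {
  ts <- base_set()
  d <- data.frame(study_id = "s1", arm = "treatment", change = -4,
                  label = "remove cancer cases")
  out <- apply_deltas(ts, d)
  expect_identical(out$r_t, c(0, 1, 6, 3))
  expect_identical(out$r_c, ts$r_c)
  expect_identical(ts$r_t[1], 4)  # original untouched

  multi <- data.frame(
    study_id = c("s2", "s3", "s4"),
    arm = c("treatment", "control", "control"),
    change = c(4, 1, 1),
    label = c("severe knee swelling x4", "cerebral hemorrhage",
              "breast cancer"))
  out2 <- apply_deltas(ts, multi)
  expect_identical(out2$r_t, c(4, 5, 6, 3))
  expect_identical(out2$r_c, c(2, 1, 4, 3))
  expect_identical(apply_deltas(ts, NULL), ts)  # identity
})

test_that("deltas violating count bounds or targets are rejected", {
  ts <- base_set()
  expect_error(apply_deltas(ts, data.frame(study_id = "s2",
                                           arm = "treatment", change = -2,
                                           label = "too many")),
               "-1 events", class = "harmsynth_validation_error")
  expect_error(apply_deltas(ts, data.frame(study_id = "s2",
                                           arm = "treatment", change = 60,
                                           label = "overflow")),
               "> n", class = "harmsynth_validation_error")
  expect_error(apply_deltas(ts, data.frame(study_id = "nope",
                                           arm = "control", change = 1,
                                           label = "ghost")),
               "unknown study", class = "harmsynth_validation_error")
})

test_that("applying inverse deltas restores the base set exactly", {
  ts <- base_set()
  d <- data.frame(study_id = c("s1", "s3"), arm = c("treatment", "control"),
                  change = c(-2, 3), label = c("a", "b"))
  inv <- d; inv$change <- -d$change
  back <- apply_deltas(apply_deltas(ts, d), inv)
  expect_identical(as.data.frame(back), as.data.frame(ts))
})

test_that("subgroup predicates filter as declared", {
  ts <- base_set()
  lb <- subgroup_filter(ts, "large_blinded", list(min_total_n = 200))
  expect_identical(lb$study_id, c("s1", "s4"))  # s3 unblinded, s2 small
  expect_identical(subgroup_filter(ts, "all")$study_id, ts$study_id)
  expect_identical(subgroup_filter(ts, "blinded")$study_id,
                   c("s1", "s2", "s4"))
  expect_error(subgroup_filter(ts, "large_blinded",
                               list(min_total_n = 10000)),
               "empty subgroup", class = "harmsynth_validation_error")
  expect_error(subgroup_filter(ts, "biggest"), "unknown subgroup",
               class = "harmsynth_validation_error")
  # custom predicate function
  late <- subgroup_filter(ts, function(x) x$year >= 2005)
  expect_identical(late$study_id, c("s3", "s4"))
})

test_that("scenario composition applies exclusions, subgroup, then deltas", {
  ts <- base_set()
  sc <- scenario_spec("combo", exclude = "s4", subgroup = "blinded",
                      deltas = data.frame(
                        study_id = c("s1", "s4"), arm = "treatment",
                        change = c(1, 5), label = c("keep", "dropped")))
  out <- apply_scenario(ts, sc)
  # s4 excluded before its delta could apply; s3 removed by subgroup
  expect_identical(out$study_id, c("s1", "s2"))
  expect_identical(out$r_t, c(5, 1))
})

test_that("leave-one-out reduces to the other study at k = 2", {
  ts <- subgroup_filter(base_set(), function(x) x$study_id %in% c("s1", "s3"))
  loo <- leave_one_out(ts, method = "dl_random")
  expect_identical(nrow(loo), 2L)
  for (i in 1:2) {
    other <- harmsynth:::subset_trialset(ts, -i)
    pe <- pool_trialset(other, "dl_random")
    expect_equal(loo$estimate[i], exp(pe$theta), tolerance = 1e-12)
    expect_identical(loo$k[i], 1L)
  }
  full <- pool_trialset(ts, "dl_random")
  expect_equal(sum(loo$weight_full), sum(full$weights), tolerance = 1e-9)
  expect_equal(sum(loo$weight_full), 1, tolerance = 1e-9)
})

test_that("excluding an injected harm-inflating outlier removes its bias", {
  # outlier with ~3x the treatment-arm event rate biases the pooled RR
  # upward; dropping it should lower the pooled log-RR in nearly every
  # replicate, and on average bring it back to the generating RR of 1
  res <- vapply(1:500, function(s) {
    ts <- gen_binary_trialset(simulation_config(
      k = 6, n_range = c(150, 400), p0 = 0.025, true_rr = 1,
      outlier = list(multiplier = 3, arm = "treatment"), seed = 20000 + s))
    out_id <- attr(ts, "outlier_id")
    tryCatch({
      full <- pool_trialset(ts, "dl_random")
      rest <- pool_trialset(
        harmsynth:::subset_trialset(ts, ts$study_id != out_id), "dl_random")
      c(full = full$theta, rest = rest$theta)
    }, error = function(e) c(full = NA_real_, rest = NA_real_))
  }, numeric(2))
  ok <- !is.na(res["full", ])
  expect_gte(mean(res["rest", ok] < res["full", ok]), 0.9)
  # aggregate bias: with the outlier the pooled log-RR is well above the
  # truth of 0; without it, close to 0
  expect_gt(mean(res["full", ok]), 0.15)
  expect_lt(abs(mean(res["rest", ok])), 0.1)
})

test_that("ladder rows are labeled, composable and reproducible", {
  ts <- base_set()
  scen <- list(scenario_spec("all"),
               scenario_spec("no_s3", exclude = "s3"))
  ladder <- run_ladder(ts, scen, methods = c("dl_random", "mh"))
  expect_identical(nrow(ladder), 4L)
  expect_identical(ladder$scenario, c("all", "all", "no_s3", "no_s3"))
  expect_identical(ladder$k, c(4L, 4L, 3L, 3L))

  # no-change scenario equals direct pooling
  direct <- pool_trialset(ts, "dl_random")
  expect_equal(ladder$estimate[1], exp(direct$theta), tolerance = 1e-15)
  expect_equal(ladder$ci_low[1], exp(direct$ci_low), tolerance = 1e-15)

  # pure function of inputs: byte-identical on rerun
  expect_identical(ladder, run_ladder(ts, scen,
                                      methods = c("dl_random", "mh")))
})

test_that("significance flag flips exactly when the CI crosses 1", {
  ts <- base_set()
  ladder <- run_ladder(ts, scenario_spec("base"), methods = "dl_random")
  expect_identical(ladder$significant,
                   ladder$ci_low > 1 | ladder$ci_high < 1)
  # constructed boundary: big effect -> significant
  big <- trial_set(data.frame(study_id = c("a", "b"),
                              n_t = c(500, 400), r_t = c(40, 30),
                              n_c = c(500, 400), r_c = c(8, 6)))
  row <- run_ladder(big, scenario_spec("base"), methods = "dl_random")
  expect_true(row$significant)
  expect_gt(row$ci_low, 1)
})
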