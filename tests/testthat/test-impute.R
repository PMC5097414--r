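# helper: a small observed set plus one or more hidden studies whose true
# counts generate the target by forward pooling
make_problem <- function(seed, n_hidden = 1, hidden_n = 120, bound = 12,
                         method = "dl_random", weights = c(2, 1, 1),
                         k_obs = 4, true_rr = 1.4) {
  ts <- gen_binary_trialset(simulation_config(
    k = k_obs + n_hidden, n_range = c(100, 300), p0 = 0.03,
    true_rr = true_rr, seed = seed))
  full <- as.data.frame(ts)
  full$n_t[seq_len(n_hidden) + k_obs] <- hidden_n
  full$n_c[seq_len(n_hidden) + k_obs] <- hidden_n
  # replace hidden counts by a known truth within bounds
  set.seed(seed + 7)
  true_rt <- sample(1:bound, n_hidden, replace = TRUE)
  true_rc <- sample(1:bound, n_hidden, replace = TRUE)
  full$r_t[seq_len(n_hidden) + k_obs] <- true_rt
  full$r_c[seq_len(n_hidden) + k_obs] <- true_rc
  complete <- trial_set(full, ae_category = "serious/any")
  target_pe <- pool_trialset(complete, method)
  observed <- harmsynth:::subset_trialset(complete, seq_len(k_obs))
  hidden_ids <- full$study_id[seq_len(n_hidden) + k_obs]
  problem <- imputation_problem(
    observed,
    hidden = data.frame(study_id = hidden_ids, n_t = hidden_n,
                        n_c = hidden_n),
    target = list(point = exp(target_pe$theta),
                  ci_low = exp(target_pe$ci_low),
                  ci_high = exp(target_pe$ci_high)),
    method_tag = method,
    bounds = data.frame(study_id = hidden_ids, max_t = bound,
                        max_c = bound),
    weights = weights)
  list(problem = problem, truth = data.frame(study_id = hidden_ids,
                                             r_t = true_rt, r_c = true_rc))
}

test_that("imputation problems validate their invariants", {
  obs <- gen_binary_trialset(simulation_config(k = 3, seed = 2))
  hid <- data.frame(study_id = "h1", n_t = 100, n_c = 100)
  tgt <- list(point = 1.4, ci_low = 1.0, ci_high = 2.0)
  expect_s3_class(imputation_problem(obs, hid, tgt), "imputation_problem")
  expect_error(imputation_problem(obs, hid[0, ], tgt), "no hidden",
               class = "harmsynth_validation_error")
  expect_error(imputation_problem(obs, hid,
                                  list(point = 2.5, ci_low = 1, ci_high = 2)),
               "outside its CI", class = "harmsynth_validation_error")
  expect_error(imputation_problem(obs, hid, tgt,
                                  bounds = data.frame(study_id = "h1",
                                                      max_t = 500,
                                                      max_c = 10)),
               "exceed", class = "harmsynth_validation_error")
})

test_that("the discrepancy is zero at the generating truth and rises nearby", {
  mp <- make_problem(seed = 101)
  expect_equal(discrepancy(mp$truth, mp$problem), 0, tolerance = 1e-12)

  # perturbing one count by +/-1 strictly increases the objective
  for (dcol in c("r_t", "r_c")) for (dd in c(-1, 1)) {
    cand <- mp$truth
    cand[[dcol]] <- cand[[dcol]] + dd
    if (cand[[dcol]] >= 0 && cand[[dcol]] <= 12)
      expect_gt(discrepancy(cand, mp$problem), 1e-8)
  }
})

test_that("point-only weighting reduces to squared log-point error", {
  mp <- make_problem(seed = 103, weights = c(1, 0, 0))
  cand <- mp$truth
  cand$r_t <- cand$r_t + 1
  cnt <- harmsynth:::problem_counts(mp$problem, cand)
  triple <- harmsynth:::pool_triple_counts(
    cnt$r_t, cnt$n_t, cnt$r_c, cnt$n_c, "dl_random", 0.5, 0.95)
  expect_equal(discrepancy(cand, mp$problem),
               (triple[1] - log(mp$problem$target$point))^2,
               tolerance = 1e-12)
})

test_that("exhaustive inversion recovers forward-computed hidden counts", {
  mp <- make_problem(seed = 107)
  sol <- invert_counts(mp$problem, "exhaustive")
  expect_equal(sol$objective, 0, tolerance = 1e-12)
  expect_identical(sol$assignments$r_t, as.numeric(mp$truth$r_t))
  expect_identical(sol$assignments$r_c, as.numeric(mp$truth$r_c))
  expect_true(sol$attained)
})

test_that("symmetric hidden studies produce reported ties", {
  # two hidden studies with identical sizes: swapping their assignments
  # cannot change the pooled result, so any asymmetric optimum has a twin
  mp <- make_problem(seed = 113, n_hidden = 2, bound = 4)
  sol <- invert_counts(mp$problem, "exhaustive")
  expect_equal(sol$objective, 0, tolerance = 1e-12)
  truth_differs <- !identical(mp$truth$r_t[1], mp$truth$r_t[2]) ||
    !identical(mp$truth$r_c[1], mp$truth$r_c[2])
  if (truth_differs) {
    expect_false(sol$unique)
    expect_gte(length(sol$ties), 2L)
  }
  # ties are reported smallest-total-events first
  totals <- vapply(sol$ties, function(t) sum(t$r_t) + sum(t$r_c), numeric(1))
  expect_identical(totals, sort(totals))
})

test_that("unattainable targets are flagged with the best effort returned", {
  obs <- gen_binary_trialset(simulation_config(k = 4, p0 = 0.03,
                                               true_rr = 1, seed = 211))
  problem <- imputation_problem(
    obs, hidden = data.frame(study_id = "h1", n_t = 50, n_c = 50),
    target = list(point = 30, ci_low = 25, ci_high = 36),
    bounds = data.frame(study_id = "h1", max_t = 6, max_c = 6))
  sol <- invert_counts(problem, "exhaustive")
  expect_gt(sol$objective, 0.1)
  expect_false(sol$attained)
  expect_s3_class(sol$assignments, "data.frame")
})

test_that("exhaustive search refuses over-cap spaces with advice", {
  obs <- gen_binary_trialset(simulation_config(k = 3, seed = 5))
  problem <- imputation_problem(
    obs, hidden = data.frame(study_id = c("h1", "h2"), n_t = 400,
                             n_c = 400),
    target = list(point = 1.4, ci_low = 1.0, ci_high = 2.0))
  expect_error(invert_counts(problem, "exhaustive", cap = 1e4),
               "coordinate_descent", class = "harmsynth_validation_error")
})

test_that("coordinate descent agrees with exhaustive on small instances", {
  for (seed in c(301, 307, 311)) {
    mp <- make_problem(seed = seed, bound = 9)  # 100 candidates
    ex <- invert_counts(mp$problem, "exhaustive")
    cd <- invert_counts(mp$problem, "coordinate_descent", restarts = 4,
                        seed = seed)
    expect_equal(cd$objective, ex$objective, tolerance = 1e-10)
    expect_identical(cd$assignments, ex$assignments)
  }
})
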