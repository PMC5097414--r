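team_scheme <- function() {
  classification_scheme("team", data.frame(
    term = c("joint sprain", "cancer", "synovitis", "herpes zoster",
             "knee pain"),
    severity = c("non_serious", "not_an_AE", "serious", "serious",
                 "non_serious"),
    locality = c("joint", "n/a", "joint", "other", "joint")))
}

author_scheme <- function() {
  classification_scheme("author", data.frame(
    term = c("joint sprain", "cancer"),
    severity = c("serious", "serious"),
    locality = c("joint", "other")))
}

demo_events <- function() {
  ae_records(data.frame(
    study_id = c("s1", "s1", "s1", "s2", "s2"),
    arm = c("treatment", "treatment", "control", "treatment", "control"),
    term = c("Joint Sprain", "synovitis", "cancer", "synovitis",
             "herpes zoster"),
    count = c(2, 1, 1, 3, 1),
    author_serious = c(TRUE, TRUE, TRUE, TRUE, TRUE)))
}

demo_arms <- function() {
  data.frame(study_id = c("s1", "s2"), n_t = c(100, 120),
             n_c = c(95, 115), blinded = TRUE)
}

test_that("classification applies scheme labels and exclusions", {
  lab <- classify_events(demo_events(), team_scheme())
  expect_identical(lab$severity[lab$term == "Joint Sprain"], "non_serious")
  expect_identical(lab$locality[lab$term == "Joint Sprain"], "joint")
  expect_true(lab$excluded[lab$term == "cancer"])
  # same records under author-designation: sprain and cancer both serious
  # (terms the scheme does not rule fall back with a warning)
  expect_warning(lab2 <- classify_events(demo_events(), author_scheme()),
                 "no rule")
  expect_identical(lab2$severity[lab2$term == "Joint Sprain"], "serious")
  expect_identical(lab2$severity[lab2$term == "cancer"], "serious")
  expect_identical(lab2$locality[lab2$term == "cancer"], "other")
})

test_that("unknown terms follow the fallback policy", {
  ev <- ae_records(data.frame(study_id = "s1", arm = "treatment",
                              term = "vertigo", count = 1,
                              author_serious = TRUE))
  expect_warning(lab <- classify_events(ev, author_scheme()), "vertigo")
  expect_identical(lab$severity, "serious")
  expect_identical(lab$locality, "other")

  strict <- classification_scheme("strict", data.frame(
    term = "flare", severity = "non_serious", locality = "joint"),
    fallback = "error")
  expect_error(classify_events(ev, strict), "no rule",
               class = "harmsynth_validation_error")
})

test_that("aggregation sums person counts per cell and respects unions", {
  lab <- classify_events(demo_events(), team_scheme())
  arms <- demo_arms()

  joint <- aggregate_counts(lab, arms, "serious", "joint")
  expect_identical(joint$r_t, c(1, 3))   # synovitis only
  expect_identical(joint$r_c, c(0, 0))
  expect_identical(attr(joint, "ae_category"), "serious/joint")

  other <- aggregate_counts(lab, arms, "serious", "other")
  expect_identical(other$r_c, c(0, 1))   # herpes zoster

  # with no local_non_joint events, "all serious" = joint + other
  all_s <- aggregate_counts(lab, arms, "serious", "any")
  expect_identical(all_s$r_t, joint$r_t + other$r_t)
  expect_identical(all_s$r_c, joint$r_c + other$r_c)

  # the excluded cancer record contributes to no cell
  nsae <- aggregate_counts(lab, arms, "non_serious", "any")
  expect_identical(nsae$r_t, c(2, 0))    # joint sprain
  expect_identical(sum(all_s$r_c) + sum(nsae$r_c), 1)
})

test_that("additivity within an arm and order independence hold", {
  ev <- ae_records(data.frame(
    study_id = "s1", arm = "treatment",
    term = c("synovitis", "septic arthritis"),
    count = c(2, 3), author_serious = TRUE))
  sch <- classification_scheme("x", data.frame(
    term = c("synovitis", "septic arthritis"),
    severity = "serious", locality = "joint"))
  arms <- data.frame(study_id = "s1", n_t = 50, n_c = 50)
  agg <- aggregate_counts(classify_events(ev, sch), arms, "serious", "joint")
  expect_identical(agg$r_t, 5)

  shuffled <- classify_events(ev[c(2, 1), ], sch)
  expect_identical(
    aggregate_counts(shuffled, arms, "serious", "joint")$r_t, 5)
})

test_that("aggregated counts above arm size are rejected", {
  ev <- ae_records(data.frame(study_id = "s1", arm = "treatment",
                              term = c("synovitis", "knee pain"),
                              count = c(4, 5), author_serious = TRUE))
  sch <- classification_scheme("x", data.frame(
    term = c("synovitis", "knee pain"), severity = "serious",
    locality = "joint"))
  arms <- data.frame(study_id = "s1", n_t = 6, n_c = 6)
  expect_error(aggregate_counts(classify_events(ev, sch), arms,
                                "serious", "joint"),
               "exceed", class = "harmsynth_validation_error")
  expect_error(aggregate_counts(classify_events(ev, sch),
                                data.frame(study_id = "zz", n_t = 50,
                                           n_c = 50), "serious", "joint"),
               "unknown study", class = "harmsynth_validation_error")
})

test_that("reclassifying a term moves its counts and conserves totals", {
  ev <- demo_events()
  arms <- demo_arms()
  count_all <- function(scheme) {
    lab <- classify_events(ev, scheme)
    sae <- aggregate_counts(lab, arms, "serious", "any")
    nsae <- aggregate_counts(lab, arms, "non_serious", "any")
    excl <- sum(lab$count[lab$excluded])
    c(sae = sum(sae$r_t) + sum(sae$r_c),
      nsae = sum(nsae$r_t) + sum(nsae$r_c), excl = excl)
  }
  base <- count_all(team_scheme())
  # flip joint sprain from non-serious to serious
  flipped <- classification_scheme("team2", data.frame(
    term = c("joint sprain", "cancer", "synovitis", "herpes zoster",
             "knee pain"),
    severity = c("serious", "not_an_AE", "serious", "serious",
                 "non_serious"),
    locality = c("joint", "n/a", "joint", "other", "joint")))
  after <- count_all(flipped)
  sprain_n <- 2
  expect_identical(after["sae"] - base["sae"], c(sae = sprain_n))
  expect_identical(base["nsae"] - after["nsae"], c(nsae = sprain_n))
  expect_identical(sum(base), sum(after))  # person-events conserved
})

test_that("scheme_diff reports disagreements and coverage gaps", {
  d <- scheme_diff(team_scheme(), author_scheme())
  expect_identical(sort(d$term[d$status == "differs"]),
                   c("cancer", "joint sprain"))
  expect_true(all(c("synovitis", "herpes zoster", "knee pain") %in%
                    d$term[d$status == "missing_in_b"]))
  expect_identical(nrow(scheme_diff(team_scheme(), team_scheme())), 0L)
})
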