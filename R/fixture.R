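# Packaged end-to-end fixture. IMPORTANT: the per-study split below is
# SYNTHETIC. Published safety tables in this literature print only the
# aggregate margins (8 placebo-controlled studies with 27 serious events
# among 1056 HA patients vs 16 among 1017 placebo patients; 10 studies
# with 415/1645 vs 375/1564 non-serious events); the individual study
# rows here are invented to sum to exactly those margins, including one
# deliberately high-rate study in the influential-outlier role. The
# fixture exercises the full pipeline -- pooling, subgroups, deltas,
# ladders -- but its pooled values are NOT a reproduction of any published
# per-study analysis.

#' Synthetic end-to-end fixture with published aggregate margins
#'
#' Returns a serious-AE trial set (8 studies, totals 27/1056 treated vs
#' 16/1017 control), a non-serious-AE trial set (10 studies, totals
#' 415/1645 vs 375/1564), and a full scenario ladder covering the standard
#' sensitivity rows: all studies; excluding the high-rate outlier study;
#' restriction to large blinded trials; restoring omitted serious events
#' (two myocardial infarctions, four cases of severe knee swelling, one
#' cerebral hemorrhage, one breast cancer) to the arms where such events
#' went uncounted; removing four implausibly-attributed cancer cases; and
#' the combined variant (non-cancer omissions restored, cancers removed)
#' -- each crossed with outlier exclusion and the large-blinded subgroup.
#'
#' The per-study split is synthetic (see the source for the construction);
#' only the margins match published aggregates. Use it for pipeline and
#' shape tests, never as evidence about the real trials.
#'
#' @return List with elements `sae` (binary [trial_set()]), `nsae` (binary
#'   [trial_set()]) and `scenarios` (list of [scenario_spec()]).
#' @export
make_paper_fixture <- function() {
  sae <- trial_set(data.frame(
    study_id = c("syn01", "syn02", "syn03", "syn04", "syn05", "syn06",
                 "syn07", "syn08_highrate"),
    year = c(1998L, 2001L, 1999L, 2004L, 2006L, 2009L, 2011L, 2003L),
    blinded = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    follow_up_weeks = 26,
    n_t = c(110L, 220L, 60L, 180L, 140L, 120L, 106L, 120L),
    r_t = c(2L, 5L, 0L, 4L, 3L, 2L, 2L, 9L),
    n_c = c(105L, 210L, 58L, 170L, 135L, 115L, 104L, 120L),
    r_c = c(1L, 3L, 1L, 2L, 2L, 1L, 1L, 5L),
    stringsAsFactors = FALSE), ae_category = "serious/any")

  nsae <- trial_set(data.frame(
    study_id = sprintf("syn%02d", 11:20),
    year = 1996L + seq_len(10L),
    blinded = TRUE, follow_up_weeks = 26,
    n_t = c(200L, 180L, 160L, 150L, 170L, 140L, 155L, 165L, 175L, 150L),
    r_t = c(50L, 45L, 40L, 38L, 43L, 35L, 39L, 41L, 44L, 40L),
    n_c = c(190L, 175L, 150L, 145L, 160L, 135L, 150L, 160L, 170L, 129L),
    r_c = c(46L, 42L, 36L, 34L, 39L, 32L, 35L, 37L, 40L, 34L),
    stringsAsFactors = FALSE), ae_category = "non_serious/any")

  outlier <- "syn08_highrate"
  omitted_noncancer <- data.frame(
    study_id = c("syn04", "syn04", "syn05", "syn06"),
    arm = c("treatment", "treatment", "control", "control"),
    change = c(1L, 4L, 1L, 1L),
    label = c("myocardial infarction (treatment)",
              "severe knee swelling x4",
              "myocardial infarction (control)",
              "cerebral hemorrhage (control)"),
    stringsAsFactors = FALSE)
  omitted_all <- rbind(omitted_noncancer, data.frame(
    study_id = "syn05", arm = "control", change = 1L,
    label = "breast cancer (control)", stringsAsFactors = FALSE))
  cancer_removal <- data.frame(
    study_id = "syn02", arm = "treatment", change = -4L,
    label = "remove four cancer cases", stringsAsFactors = FALSE)

  variants <- list(
    list(tag = "all_saes", deltas = NULL),
    list(tag = "include_omitted_saes", deltas = omitted_all),
    list(tag = "exclude_cancers", deltas = cancer_removal),
    list(tag = "omitted_noncancer_excl_cancers",
         deltas = rbind(omitted_noncancer, cancer_removal)))

  scenarios <- list()
  for (v in variants)
    for (drop_out in c(FALSE, TRUE))
      for (sg in list(NULL, "large_blinded")) {
        nm <- paste0(v$tag,
                     if (drop_out) "+excl_outlier" else "",
                     if (!is.null(sg)) "+large_blinded" else "")
        scenarios[[length(scenarios) + 1L]] <-
          scenario_spec(nm,
                        exclude = if (drop_out) outlier else character(),
                        subgroup = sg, deltas = v$deltas)
      }

  list(sae = sae, nsae = nsae, scenarios = scenarios)
}
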