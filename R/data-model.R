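#' Construct a trial set
#'
#' A trial set is the basic analysis container: one row per randomized
#' comparison of a treatment arm (here, hyaluronic-acid injection) against a
#' control arm (sham/placebo injection), carrying either binary
#' adverse-event counts or continuous outcome summaries.
#'
#' Binary trial sets require columns `study_id`, `n_t`, `r_t`, `n_c`, `r_c`
#' (treated/control sample sizes and numbers of persons with at least one
#' event in the adverse-event category named by `ae_category`). Continuous
#' trial sets require `study_id`, `n_t`, `mean_t`, `sd_t`, `n_c`, `mean_c`,
#' `sd_c`. Optional metadata columns `year`, `blinded` and
#' `follow_up_weeks` are carried along but never used for weighting; they
#' feed subgroup predicates (see [subgroup_filter()]).
#'
#' @param studies data frame of per-study summaries (see Details).
#' @param type `"binary"` or `"continuous"`.
#' @param ae_category label of the severity-by-locality cell the binary
#'   counts summarise (e.g. `"serious/any"`); `NA` for continuous sets.
#' @return An object of class `trial_set`: the validated data frame with
#'   attributes `type` and `ae_category`.
#' @examples
#' ts <- trial_set(data.frame(study_id = "s1", n_t = 1056, r_t = 27,
#'                            n_c = 1017, r_c = 16), ae_category = "serious/any")
#' ts
#' @seealso [read_trialset()], [pool_trialset()]
#' @export
trial_set <- function(studies, type = c("binary", "continuous"),
                      ae_category = NA_character_) {
  type <- match.arg(type)
  if (!is.data.frame(studies) || nrow(studies) == 0L)
    stop_validation("trial set must be a nonempty data frame (no studies)")
  studies <- as.data.frame(studies, stringsAsFactors = FALSE)

  need <- if (type == "binary") c("study_id", "n_t", "r_t", "n_c", "r_c")
          else c("study_id", "n_t", "mean_t", "sd_t", "n_c", "mean_c", "sd_c")
  missing_cols <- setdiff(need, names(studies))
  if (length(missing_cols))
    stop_validation("missing required columns: %s",
                    paste(missing_cols, collapse = ", "))
  for (meta in c("year", "blinded", "follow_up_weeks"))
    if (is.null(studies[[meta]])) studies[[meta]] <- NA

  studies$study_id <- as.character(studies$study_id)
  if (anyDuplicated(studies$study_id))
    stop_validation("duplicate study_id: %s",
                    paste(unique(studies$study_id[duplicated(studies$study_id)]),
                          collapse = ", "))

  for (i in seq_len(nrow(studies))) {
    row <- studies[i, ]
    if (type == "binary") {
      for (arm in c("t", "c")) {
        n <- row[[paste0("n_", arm)]]; r <- row[[paste0("r_", arm)]]
        assert_count(n, sprintf("n_%s [row %d, %s]", arm, i, row$study_id),
                     lower = 1)
        assert_count(r, sprintf("r_%s [row %d, %s]", arm, i, row$study_id))
        if (r > n)
          stop_validation("row %d (%s): events %d > n %d in %s arm",
                          i, row$study_id, r, n,
                          if (arm == "t") "treatment" else "control")
      }
    } else {
      for (arm in c("t", "c")) {
        assert_count(row[[paste0("n_", arm)]],
                     sprintf("n_%s [row %d, %s]", arm, i, row$study_id),
                     lower = 2)
        assert_scalar_number(row[[paste0("mean_", arm)]],
                             sprintf("mean_%s [row %d]", arm, i))
        if (!is.finite(row[[paste0("sd_", arm)]]) ||
            row[[paste0("sd_", arm)]] <= 0)
          stop_validation("row %d (%s): sd_%s must be > 0", i, row$study_id, arm)
      }
    }
  }

  keep <- c("study_id", "year", "blinded", "follow_up_weeks",
            setdiff(need, "study_id"), setdiff(names(studies),
              c("study_id", "year", "blinded", "follow_up_weeks", need)))
  studies <- studies[, keep]
  rownames(studies) <- NULL
  structure(studies, class = c("trial_set", "data.frame"),
            type = type, ae_category = ae_category)
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %s, %d studies%s\n", attr(x, "type"), nrow(x),
              if (!is.na(attr(x, "ae_category")))
                paste0(", AE category: ", attr(x, "ae_category")) else ""))
  print(as.data.frame(x), ...)
  invisible(x)
}

trialset_type <- function(ts) attr(ts, "type")

# Drop/keep rows of a trial_set while preserving attributes.
subset_trialset <- function(ts, idx) {
  out <- as.data.frame(ts)[idx, , drop = FALSE]
  if (nrow(out) == 0L) stop_validation("subset leaves no studies")
  rownames(out) <- NULL
  structure(out, class = c("trial_set", "data.frame"),
            type = attr(ts, "type"), ae_category = attr(ts, "ae_category"))
}

#' Construct a single 2x2 harm table
#'
#' One stratum of a stratified rare-event analysis: persons with and without
#' at least one event in each arm of one study.
#'
#' @param r_t,n_t events and sample size in the treated arm.
#' @param r_c,n_c events and sample size in the control arm.
#' @return An object of class `two_by_two`.
#' @examples
#' two_by_two(27, 1056, 16, 1017)
#' @export
two_by_two <- function(r_t, n_t, r_c, n_c) {
  n_t <- assert_count(n_t, "n_t", lower = 1)
  n_c <- assert_count(n_c, "n_c", lower = 1)
  r_t <- assert_count(r_t, "r_t")
  r_c <- assert_count(r_c, "r_c")
  if (r_t > n_t) stop_validation("r_t %d > n_t %d", r_t, n_t)
  if (r_c > n_c) stop_validation("r_c %d > n_c %d", r_c, n_c)
  structure(list(r_t = r_t, n_t = n_t, r_c = r_c, n_c = n_c),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("<2x2> treated %d/%d, control %d/%d\n",
              x$r_t, x$n_t, x$r_c, x$n_c))
  invisible(x)
}

#' Extract the per-study 2x2 tables of a binary trial set
#'
#' @param ts a binary [trial_set()].
#' @return Named list of [two_by_two()] tables, one per study.
#' @export
as_tables <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  if (trialset_type(ts) != "binary")
    stop_validation("2x2 tables are only defined for binary trial sets")
  out <- lapply(seq_len(nrow(ts)), function(i)
    two_by_two(ts$r_t[i], ts$n_t[i], ts$r_c[i], ts$n_c[i]))
  names(out) <- ts$study_id
  out
}

#' Construct a table of reported adverse-event records
#'
#' Raw adverse events as trial reports give them: a free-text term, the
#' study and arm it occurred in, the number of persons affected, and whether
#' the original study authors designated it serious. Classification into
#' severity and locality is applied later by [classify_events()].
#'
#' @param records data frame with columns `study_id`, `arm`
#'   (`"treatment"`/`"control"`), `term`, `count` (persons, >= 1) and
#'   `author_serious` (logical).
#' @return Validated data frame of class `ae_records`.
#' @export
ae_records <- function(records) {
  need <- c("study_id", "arm", "term", "count", "author_serious")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop_validation("missing required columns: %s",
                    paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!all(records$arm %in% c("treatment", "control")))
    stop_validation("arm must be 'treatment' or 'control'")
  for (i in seq_len(nrow(records)))
    assert_count(records$count[i], sprintf("count [row %d]", i), lower = 1)
  records$author_serious <- as.logical(records$author_serious)
  if (anyNA(records$author_serious))
    stop_validation("author_serious must be TRUE/FALSE")
  structure(records[, need], class = c("ae_records", "data.frame"))
}

ae_severities <- c("serious", "non_serious", "not_an_AE")
ae_localities <- c("joint", "local_non_joint", "other", "n/a")

#' Construct an adverse-event classification scheme
#'
#' A scheme maps each adverse-event term to a severity (`serious`,
#' `non_serious`, or `not_an_AE` for events judged physiologically unrelated,
#' e.g. a cancer diagnosed during a 13-week trial) and a locality (`joint`,
#' `local_non_joint`, `other`; `n/a` for non-events). Two conventions are
#' representable: clinician team judgment (every term ruled explicitly) and
#' deference to the original study authors (`fallback = "use_author_flag"`,
#' in which unruled terms take their severity from the author's serious flag
#' and locality `"other"`).
#'
#' @param name scheme identifier.
#' @param rules data frame with columns `term`, `severity`, `locality`.
#'   Term matching is exact but case-insensitive.
#' @param fallback `"use_author_flag"` or `"error"`: what [classify_events()]
#'   does with terms the rules do not cover.
#' @return Object of class `classification_scheme`.
#' @examples
#' classification_scheme("team", data.frame(
#'   term = c("joint sprain", "cancer"),
#'   severity = c("non_serious", "not_an_AE"),
#'   locality = c("joint", "n/a")))
#' @export
classification_scheme <- function(name, rules,
                                  fallback = c("use_author_flag", "error")) {
  fallback <- match.arg(fallback)
  need <- c("term", "severity", "locality")
  missing_cols <- setdiff(need, names(rules))
  if (length(missing_cols))
    stop_validation("scheme rules missing columns: %s",
                    paste(missing_cols, collapse = ", "))
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)[, need]
  rules$term <- tolower(trimws(rules$term))
  bad_sev <- setdiff(unique(rules$severity), ae_severities)
  if (length(bad_sev))
    stop_validation("unknown severity value(s): %s", paste(bad_sev, collapse = ", "))
  bad_loc <- setdiff(unique(rules$locality), ae_localities)
  if (length(bad_loc))
    stop_validation("unknown locality value(s): %s", paste(bad_loc, collapse = ", "))
  # conflicting duplicates are an error; identical duplicates collapse
  rules <- unique(rules)
  if (anyDuplicated(rules$term))
    stop_validation("conflicting rules for term(s): %s",
                    paste(unique(rules$term[duplicated(rules$term)]),
                          collapse = ", "))
  if (any(rules$severity == "not_an_AE" & rules$locality != "n/a"))
    stop_validation("not_an_AE terms must have locality 'n/a'")
  if (any(rules$severity != "not_an_AE" & rules$locality == "n/a"))
    stop_validation("locality 'n/a' is reserved for not_an_AE terms")
  structure(list(name = name, fallback = fallback, rules = rules),
            class = "classification_scheme")
}

#' @export
print.classification_scheme <- function(x, ...) {
  cat(sprintf("<classification_scheme> '%s': %d rules, fallback = %s\n",
              x$name, nrow(x$rules), x$fallback))
  invisible(x)
}

#' Construct a sensitivity scenario
#'
#' A scenario is a named, reproducible transformation of a trial set used by
#' the sensitivity ladder: drop named studies, restrict to a subgroup, and
#' apply signed event deltas (e.g. "add the omitted myocardial infarction
#' back to this arm", "remove the four cancer cases"). Application order is
#' exclusions, then subgroup, then deltas.
#'
#' @param name scenario label, used in ladder reports.
#' @param exclude character vector of study ids to drop (may be empty).
#' @param subgroup `NULL` or the name of a subgroup predicate understood by
#'   [subgroup_filter()] (e.g. `"large_blinded"`).
#' @param deltas `NULL` or a data frame with columns `study_id`, `arm`,
#'   `change` (signed integer) and `label` (the provenance of the delta).
#' @param subgroup_params named list of parameters forwarded to the
#'   subgroup predicate.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, exclude = character(), subgroup = NULL,
                          deltas = NULL, subgroup_params = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_validation("scenario needs a nonempty name")
  exclude <- as.character(exclude %||% character())
  if (!is.null(deltas)) {
    need <- c("study_id", "arm", "change", "label")
    missing_cols <- setdiff(need, names(deltas))
    if (length(missing_cols))
      stop_validation("deltas missing columns: %s",
                      paste(missing_cols, collapse = ", "))
    deltas <- as.data.frame(deltas, stringsAsFactors = FALSE)[, need]
    if (!all(deltas$arm %in% c("treatment", "control")))
      stop_validation("delta arm must be 'treatment' or 'control'")
    if (any(deltas$change != round(deltas$change)))
      stop_validation("delta changes must be integers")
    deltas$change <- as.integer(deltas$change)
  }
  structure(list(name = name, exclude = exclude, subgroup = subgroup,
                 deltas = deltas, subgroup_params = subgroup_params),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> '%s': %d exclusion(s), subgroup = %s, %d delta(s)\n",
              x$name, length(x$exclude), x$subgroup %||% "none",
              if (is.null(x$deltas)) 0L else nrow(x$deltas)))
  invisible(x)
}
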