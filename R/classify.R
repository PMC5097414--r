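# Two-axis classification of reported adverse events and aggregation into
# per-study 2x2 tables. The severity axis (serious / non-serious / not an
# AE at all) and the locality axis (injected joint / local elsewhere /
# systemic "other") are where competing reviews of the same trials diverge,
# so both the labels and the scheme applied are kept explicit.

#' Classify raw adverse-event records under a scheme
#'
#' Each record gains `severity` and `locality` labels and an `excluded`
#' flag (TRUE for terms the scheme rules out as adverse events at all,
#' e.g. a cancer diagnosed during a short trial). Terms absent from the
#' rule map follow the scheme's fallback: `"use_author_flag"` takes
#' severity from the original authors' serious flag with locality
#' `"other"` and emits one warning naming the unruled terms;
#' `"error"` stops.
#'
#' @param events an [ae_records()] table.
#' @param scheme a [classification_scheme()].
#' @return The records with `severity`, `locality`, `excluded` and
#'   `scheme` columns appended (class `classified_events`).
#' @examples
#' sch <- classification_scheme("team", data.frame(
#'   term = "joint sprain", severity = "non_serious", locality = "joint"))
#' ev <- ae_records(data.frame(study_id = "s1", arm = "treatment",
#'   term = "Joint Sprain", count = 2, author_serious = TRUE))
#' classify_events(ev, sch)
#' @export
classify_events <- function(events, scheme) {
  stopifnot(inherits(events, "ae_records"),
            inherits(scheme, "classification_scheme"))
  key <- tolower(trimws(events$term))
  idx <- match(key, scheme$rules$term)
  severity <- scheme$rules$severity[idx]
  locality <- scheme$rules$locality[idx]
  unknown <- is.na(idx)
  if (any(unknown)) {
    terms <- sort(unique(events$term[unknown]))
    if (scheme$fallback == "error")
      stop_validation("scheme '%s' has no rule for term(s): %s",
                      scheme$name, paste(terms, collapse = ", "))
    warning(sprintf(
      "scheme '%s': no rule for %d term(s) (%s); using original authors' serious flag with locality 'other'",
      scheme$name, length(terms), paste(terms, collapse = ", ")),
      call. = FALSE)
    severity[unknown] <- ifelse(events$author_serious[unknown],
                                "serious", "non_serious")
    locality[unknown] <- "other"
  }
  out <- as.data.frame(events)
  out$severity <- severity
  out$locality <- locality
  out$excluded <- severity == "not_an_AE"
  out$scheme <- scheme$name
  structure(out, class = c("classified_events", "data.frame"))
}

#' Aggregate classified events into a per-study binary trial set
#'
#' Sums the person counts of all events falling in the requested
#' severity-by-locality cell, per study and arm, against the arm sizes in
#' `arms`. Studies with no matching events contribute zero counts (and are
#' later excluded by [zero_cell_filter()] if both arms are zero). Combined
#' cells are unions: `locality = "any"` pools all localities of a
#' severity, giving e.g. the "all serious AEs" row. Counts are
#' persons-with-event per reported term; distinct terms within an arm are
#' summed as reported, since trial reports rarely say whether the same
#' person had two different events.
#'
#' @param labeled a `classified_events` table from [classify_events()].
#' @param arms data frame with `study_id`, `n_t`, `n_c` (and optional
#'   `year`, `blinded`, `follow_up_weeks`) for every study to appear in
#'   the output -- a binary [trial_set()] works.
#' @param severity `"serious"` or `"non_serious"`.
#' @param locality one of `"joint"`, `"local_non_joint"`, `"other"`, or
#'   `"any"` for the union.
#' @return A binary [trial_set()] with `ae_category =
#'   "<severity>/<locality>"`.
#' @export
aggregate_counts <- function(labeled, arms, severity = "serious",
                             locality = "any") {
  stopifnot(inherits(labeled, "classified_events"))
  severity <- match.arg(severity, c("serious", "non_serious"))
  locality <- match.arg(locality, c("any", ae_localities))
  arms <- as.data.frame(arms)
  if (!all(c("study_id", "n_t", "n_c") %in% names(arms)))
    stop_validation("arms needs study_id, n_t, n_c columns")

  bad <- setdiff(unique(labeled$study_id), arms$study_id)
  if (length(bad))
    stop_validation("events reference unknown study id(s): %s",
                    paste(bad, collapse = ", "))
  keep <- !labeled$excluded & labeled$severity == severity &
    (locality == "any" | labeled$locality == locality)
  sub <- labeled[keep, , drop = FALSE]

  sum_cell <- function(sid, arm) {
    sum(sub$count[sub$study_id == sid & sub$arm == arm])
  }
  out <- data.frame(study_id = arms$study_id,
                    year = arms$year %||% NA,
                    blinded = arms$blinded %||% NA,
                    follow_up_weeks = arms$follow_up_weeks %||% NA,
                    n_t = arms$n_t,
                    r_t = vapply(arms$study_id, sum_cell, numeric(1),
                                 arm = "treatment"),
                    n_c = arms$n_c,
                    r_c = vapply(arms$study_id, sum_cell, numeric(1),
                                 arm = "control"),
                    stringsAsFactors = FALSE)
  over_t <- out$r_t > out$n_t
  over_c <- out$r_c > out$n_c
  if (any(over_t | over_c))
    stop_validation("aggregated events exceed arm size in study %s",
                    paste(out$study_id[over_t | over_c], collapse = ", "))
  trial_set(out, type = "binary",
            ae_category = paste(severity, locality, sep = "/"))
}

#' Tabulate disagreements between two classification schemes
#'
#' One row per term where the two schemes assign different severity or
#' locality, or where one scheme has no rule at all. This is the table
#' that explains why two reviews pooling the same trials can count
#' different events as serious.
#'
#' @param a,b [classification_scheme()] objects.
#' @param terms terms to compare (default: union of both rule maps).
#' @return Data frame with columns `term`, `severity_a`, `locality_a`,
#'   `severity_b`, `locality_b`, `status` (`"differs"`, `"missing_in_a"`,
#'   `"missing_in_b"`); zero rows when the schemes agree everywhere.
#' @export
scheme_diff <- function(a, b, terms = NULL) {
  stopifnot(inherits(a, "classification_scheme"),
            inherits(b, "classification_scheme"))
  terms <- tolower(trimws(terms %||% union(a$rules$term, b$rules$term)))
  ia <- match(terms, a$rules$term)
  ib <- match(terms, b$rules$term)
  out <- data.frame(term = terms,
                    severity_a = a$rules$severity[ia],
                    locality_a = a$rules$locality[ia],
                    severity_b = b$rules$severity[ib],
                    locality_b = b$rules$locality[ib],
                    stringsAsFactors = FALSE)
  out$status <- ifelse(is.na(ia), "missing_in_a",
                ifelse(is.na(ib), "missing_in_b",
                ifelse(out$severity_a != out$severity_b |
                       out$locality_a != out$locality_b,
                       "differs", "agrees")))
  out <- out[out$status != "agrees", , drop = FALSE]
  rownames(out) <- NULL
  out
}
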