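# CSV/JSON interchange. The on-disk study format is long (one row per
# study x arm) so the same dialect carries any adverse-event category or a
# continuous outcome; in memory trial sets are wide (one row per study).

#' Read a trial set from a long-format CSV file
#'
#' Expected columns: `study_id`, `arm` (`treatment`/`control`) and either
#' `n` + `events` (binary harms) or `n` + `mean` + `sd` (continuous
#' outcome); optional `year`, `blinded`, `follow_up_weeks`. Each study must
#' contribute exactly one treatment and one control row. Validation
#' failures name the offending CSV line.
#'
#' @param path CSV file path.
#' @param type `"binary"` or `"continuous"`; by default inferred from the
#'   columns present.
#' @param ae_category category label attached to a binary set.
#' @return A [trial_set()].
#' @export
read_trialset <- function(path, type = NULL, ae_category = NA_character_) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(long) == 0L) stop_validation("no studies in %s", path)
  if (is.null(type))
    type <- if ("events" %in% names(long)) "binary" else "continuous"
  value_cols <- if (type == "binary") c("n", "events") else c("n", "mean", "sd")
  missing_cols <- setdiff(c("study_id", "arm", value_cols), names(long))
  if (length(missing_cols))
    stop_validation("%s: missing required columns: %s", path,
                    paste(missing_cols, collapse = ", "))
  bad_arm <- which(!long$arm %in% c("treatment", "control"))
  if (length(bad_arm))
    stop_validation("%s: line %d: arm must be treatment/control, got '%s'",
                    path, bad_arm[1] + 1L, long$arm[bad_arm[1]])
  if (type == "binary") {
    bad <- which(long$events > long$n | long$events < 0)
    if (length(bad))
      stop_validation("%s: line %d (study %s): events %s > n %s",
                      path, bad[1] + 1L, long$study_id[bad[1]],
                      long$events[bad[1]], long$n[bad[1]])
  }

  wide_one <- function(chunk) {
    if (nrow(chunk) != 2L || !setequal(chunk$arm, c("treatment", "control")))
      stop_validation("study %s: need exactly one treatment and one control row",
                      chunk$study_id[1])
    tr <- chunk[chunk$arm == "treatment", ]
    ct <- chunk[chunk$arm == "control", ]
    out <- data.frame(study_id = tr$study_id,
                      year = tr$year %||% NA,
                      blinded = tr$blinded %||% NA,
                      follow_up_weeks = tr$follow_up_weeks %||% NA,
                      stringsAsFactors = FALSE)
    if (type == "binary") {
      out$n_t <- tr$n; out$r_t <- tr$events
      out$n_c <- ct$n; out$r_c <- ct$events
    } else {
      out$n_t <- tr$n; out$mean_t <- tr$mean; out$sd_t <- tr$sd
      out$n_c <- ct$n; out$mean_c <- ct$mean; out$sd_c <- ct$sd
    }
    out
  }
  chunks <- split(long, factor(long$study_id, levels = unique(long$study_id)))
  wide <- do.call(rbind, lapply(chunks, wide_one))
  if ("blinded" %in% names(wide)) wide$blinded <- as.logical(wide$blinded)
  trial_set(wide, type = type, ae_category = ae_category)
}

#' Write a trial set to long-format CSV
#'
#' Inverse of [read_trialset()]: `read_trialset(write_trialset(ts, f))`
#' reproduces `ts` exactly.
#'
#' @param ts a [trial_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "trial_set"))
  type <- trialset_type(ts)
  arm_row <- function(i, arm) {
    suffix <- if (arm == "treatment") "t" else "c"
    out <- data.frame(study_id = ts$study_id[i], year = ts$year[i],
                      blinded = ts$blinded[i],
                      follow_up_weeks = ts$follow_up_weeks[i],
                      arm = arm, n = ts[[paste0("n_", suffix)]][i],
                      stringsAsFactors = FALSE)
    if (type == "binary") {
      out$events <- ts[[paste0("r_", suffix)]][i]
    } else {
      out$mean <- ts[[paste0("mean_", suffix)]][i]
      out$sd <- ts[[paste0("sd_", suffix)]][i]
    }
    out
  }
  long <- do.call(rbind, lapply(seq_len(nrow(ts)), function(i)
    rbind(arm_row(i, "treatment"), arm_row(i, "control"))))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a classification scheme from JSON
#'
#' Format: `{"name": ..., "fallback": ..., "rules": [{"term": ...,
#' "severity": ..., "locality": ...}, ...]}`.
#'
#' @param path JSON file path.
#' @return A [classification_scheme()].
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(raw$name) || is.null(raw$rules))
    stop_validation("%s: scheme JSON needs 'name' and 'rules'", path)
  classification_scheme(raw$name, raw$rules,
                        fallback = raw$fallback %||% "use_author_flag")
}

#' Write a classification scheme to JSON
#' @param scheme a [classification_scheme()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "classification_scheme"))
  jsonlite::write_json(list(name = scheme$name, fallback = scheme$fallback,
                            rules = scheme$rules),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read sensitivity scenarios from JSON
#'
#' Accepts a single scenario object or an array of them. Format:
#' `{"name": ..., "exclude": [...], "subgroup": ...,
#' "deltas": [{"study_id": ..., "arm": ..., "change": -4, "label": ...}]}`.
#'
#' @param path JSON file path.
#' @return List of [scenario_spec()] objects.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.null(raw$name)) raw <- list(raw)  # single scenario
  lapply(raw, function(sc) {
    deltas <- NULL
    if (length(sc$deltas))
      deltas <- do.call(rbind, lapply(sc$deltas, function(d)
        data.frame(study_id = d$study_id, arm = d$arm,
                   change = d$change, label = d$label %||% "",
                   stringsAsFactors = FALSE)))
    scenario_spec(sc$name,
                  exclude = unlist(sc$exclude) %||% character(),
                  subgroup = sc$subgroup,
                  deltas = deltas,
                  subgroup_params = sc$subgroup_params %||% list())
  })
}

#' Read raw adverse-event records from CSV
#'
#' Expected columns: `study_id`, `arm`, `term`, `count`, `author_serious`.
#'
#' @param path CSV file path.
#' @return An [ae_records()] table.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  ae_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a ladder or forest report to CSV or JSON
#'
#' The JSON form round-trips losslessly through [read_report()]; undefined
#' confidence limits (e.g. from degenerate all-zero strata) are written as
#' empty cells in CSV and `null` in JSON, and flagged in the `defined`
#' column.
#'
#' @param results nonempty data frame, e.g. from [run_ladder()] or
#'   [leave_one_out()].
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop_validation("empty results: nothing to report")
  results <- as.data.frame(results)
  if (format == "csv") {
    utils::write.csv(results, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(results, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#' @param path JSON file path.
#' @return Data frame.
#' @export
read_report <- function(path) {
  out <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  as.data.frame(out, stringsAsFactors = FALSE)
}
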