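# Per-study effect measures: log risk ratios for rare binary harms and
# Hedges-corrected standardized mean differences for continuous outcomes.

#' Split 2x2 tables into informative and double-zero tables
#'
#' Rare-harm pooling convention: a study with zero events in one arm still
#' carries information about relative risk and is kept; a study with zero
#' events in both arms contributes nothing to a ratio measure and is
#' excluded from pooling (it is reported, not silently dropped).
#'
#' @param tables list of [two_by_two()] tables, or a binary [trial_set()].
#' @return List with elements `included` and `excluded` (same kind as the
#'   input; for a trial set, data frames of the kept/dropped rows).
#' @export
zero_cell_filter <- function(tables) {
  if (inherits(tables, "trial_set")) {
    if (trialset_type(tables) != "binary")
      stop_validation("zero-cell filtering applies to binary trial sets")
    both_zero <- tables$r_t == 0 & tables$r_c == 0
    df <- as.data.frame(tables)
    return(list(
      included = if (any(!both_zero)) subset_trialset(tables, !both_zero)
                 else df[0, , drop = FALSE],
      excluded = df[both_zero, , drop = FALSE]))
  }
  stopifnot(all(vapply(tables, inherits, logical(1), "two_by_two")))
  both_zero <- vapply(tables, function(tb) tb$r_t == 0 && tb$r_c == 0,
                      logical(1))
  list(included = tables[!both_zero], excluded = tables[both_zero])
}

#' Log risk ratio for one 2x2 table
#'
#' Computes `log((r_t/n_t) / (r_c/n_c))` with its delta-method variance
#' `1/r_t - 1/n_t + 1/r_c - 1/n_c`. If exactly one arm has zero events, the
#' continuity constant `cc` is added to all four cells before estimation
#' and the correction is flagged; tables with no zero cell are untouched by
#' `cc`. A double-zero table has no defined ratio and is an error -- run
#' [zero_cell_filter()] first.
#'
#' @param table a [two_by_two()].
#' @param cc continuity-correction constant (default 0.5).
#' @return List with `theta` (log RR), `var`, `scale_tag = "log_rr"`,
#'   `cc_applied`.
#' @examples
#' exp(rr_single(two_by_two(27, 1056, 16, 1017))$theta)  # ~1.63
#' @export
rr_single <- function(table, cc = 0.5) {
  stopifnot(inherits(table, "two_by_two"))
  assert_scalar_number(cc, "cc", lower = 0)
  r_t <- table$r_t; n_t <- table$n_t; r_c <- table$r_c; n_c <- table$n_c
  if (r_t == 0 && r_c == 0)
    stop_numerical("risk ratio undefined for a double-zero table; filter first")
  cc_applied <- xor(r_t == 0, r_c == 0)
  if (cc_applied) {
    r_t <- r_t + cc; n_t <- n_t + cc
    r_c <- r_c + cc; n_c <- n_c + cc
  }
  theta <- log((r_t / n_t) / (r_c / n_c))
  v <- 1 / r_t - 1 / n_t + 1 / r_c - 1 / n_c
  list(theta = theta, var = v, scale_tag = "log_rr", cc_applied = cc_applied)
}

#' Per-study log risk ratios for a binary trial set
#'
#' Applies [zero_cell_filter()], then [rr_single()] to every informative
#' study.
#'
#' @param ts binary [trial_set()].
#' @param cc continuity constant forwarded to [rr_single()].
#' @return Data frame of class `effect_estimates` with columns `study_id`,
#'   `theta`, `var`, `cc_applied`; attributes `scale` (`"log_rr"`) and
#'   `excluded` (ids of double-zero studies).
#' @export
effects_log_rr <- function(ts, cc = 0.5) {
  parts <- zero_cell_filter(ts)
  if (nrow(parts$included) == 0L)
    stop_numerical("all studies have zero events in both arms; no ratio estimable")
  inc <- parts$included
  est <- lapply(as_tables(inc), rr_single, cc = cc)
  out <- data.frame(study_id = inc$study_id,
                    theta = vapply(est, `[[`, numeric(1), "theta"),
                    var = vapply(est, `[[`, numeric(1), "var"),
                    cc_applied = vapply(est, `[[`, logical(1), "cc_applied"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("effect_estimates", "data.frame"),
            scale = "log_rr", excluded = parts$excluded$study_id)
}

#' Hedges-corrected standardized mean difference
#'
#' Pooled-SD standardized difference (treatment minus control) multiplied
#' by the Hedges small-sample factor `J = 1 - 3/(4*df - 1)`, `df = n_t +
#' n_c - 2`, with the usual large-sample variance `(n_t + n_c)/(n_t*n_c) +
#' g^2 / (2*(n_t + n_c))`. Sign convention throughout the package: on
#' function scales where lower scores mean better function, negative values
#' favor the treatment.
#'
#' @param mean_t,sd_t,n_t treatment-arm mean, SD (> 0) and size (>= 2).
#' @param mean_c,sd_c,n_c control-arm summaries.
#' @return List with `theta` (Hedges g), `var`, `scale_tag = "smd"`,
#'   `cc_applied = FALSE`.
#' @examples
#' smd_hedges(10, 2, 50, 12, 2, 50)$theta  # ~ -0.99
#' @export
smd_hedges <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c) {
  n_t <- assert_count(n_t, "n_t", lower = 2)
  n_c <- assert_count(n_c, "n_c", lower = 2)
  if (sd_t <= 0 || sd_c <= 0) stop_validation("arm SDs must be > 0")
  df <- n_t + n_c - 2
  s_pooled <- sqrt(((n_t - 1) * sd_t^2 + (n_c - 1) * sd_c^2) / df)
  if (s_pooled == 0) stop_numerical("zero pooled SD")
  j <- 1 - 3 / (4 * df - 1)
  g <- j * (mean_t - mean_c) / s_pooled
  v <- (n_t + n_c) / (n_t * n_c) + g^2 / (2 * (n_t + n_c))
  list(theta = g, var = v, scale_tag = "smd", cc_applied = FALSE)
}

#' Per-study standardized mean differences for a continuous trial set
#'
#' @param ts continuous [trial_set()].
#' @return `effect_estimates` data frame (scale `"smd"`).
#' @export
effects_smd <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  if (trialset_type(ts) != "continuous")
    stop_validation("SMDs require a continuous trial set")
  est <- lapply(seq_len(nrow(ts)), function(i)
    smd_hedges(ts$mean_t[i], ts$sd_t[i], ts$n_t[i],
               ts$mean_c[i], ts$sd_c[i], ts$n_c[i]))
  out <- data.frame(study_id = ts$study_id,
                    theta = vapply(est, `[[`, numeric(1), "theta"),
                    var = vapply(est, `[[`, numeric(1), "var"),
                    cc_applied = FALSE, stringsAsFactors = FALSE)
  structure(out, class = c("effect_estimates", "data.frame"),
            scale = "smd", excluded = character())
}

#' Clinically important difference thresholds for function SMDs
#'
#' Conventional thresholds against which a pooled function SMD is judged,
#' on the negative-favors-treatment scale: a minimum clinically important
#' difference of -0.37, and minimum clinically important improvements of
#' -0.12 and -0.20.
#' @format Named numeric vector.
#' @export
smd_thresholds <- c(mcid = -0.37, mcii_tubach = -0.12, mcii_bannuru = -0.20)

#' Does a pooled SMD exceed a clinical-importance threshold?
#'
#' TRUE when the pooled effect is at least as large in magnitude as the
#' threshold and points in the same direction (both on the
#' negative-favors-treatment convention).
#'
#' @param pooled_smd pooled standardized mean difference.
#' @param threshold threshold on the same scale, e.g. from
#'   [smd_thresholds].
#' @return Logical flag.
#' @examples
#' exceeds_threshold(-0.23, smd_thresholds["mcid"])          # FALSE
#' exceeds_threshold(-0.23, smd_thresholds["mcii_tubach"])   # TRUE
#' @export
exceeds_threshold <- function(pooled_smd, threshold) {
  assert_scalar_number(pooled_smd, "pooled_smd")
  assert_scalar_number(threshold, "threshold")
  unname(abs(pooled_smd) >= abs(threshold) &
           sign(pooled_smd) == sign(threshold))
}
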