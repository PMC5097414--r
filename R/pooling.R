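# Pooling engines. All analysis-scale arithmetic is on log-RR / log-OR /
# SMD; back-transformation and rounding happen only in the reporting layer.

new_pooled_estimate <- function(theta, ci_low, ci_high, method_tag, k,
                                weights, Q, tau2, I2, scale, level,
                                excluded = character()) {
  structure(list(theta = theta, ci_low = ci_low, ci_high = ci_high,
                 method_tag = method_tag, k = k, weights = weights,
                 Q = Q, tau2 = tau2, I2 = I2, scale = scale, level = level,
                 excluded = excluded),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  ratio <- x$scale %in% c("log_rr", "log_or")
  lab <- switch(x$scale, log_rr = "RR", log_or = "OR", smd = "SMD")
  tf <- if (ratio) exp else identity
  cat(sprintf("<pooled_estimate> %s, k = %d\n", x$method_tag, x$k))
  cat(sprintf("  %s = %.4f  (%g%% CI %.4f to %.4f)\n", lab, tf(x$theta),
              100 * x$level, tf(x$ci_low), tf(x$ci_high)))
  if (!is.na(x$Q))
    cat(sprintf("  Q = %.3f, tau^2 = %s, I^2 = %.1f%%\n", x$Q,
                if (is.na(x$tau2)) "-" else format(x$tau2, digits = 4), x$I2))
  if (length(x$excluded))
    cat("  double-zero studies excluded:", paste(x$excluded, collapse = ", "),
        "\n")
  invisible(x)
}

#' Does the pooled confidence interval exclude the null?
#'
#' The null is 0 on the SMD scale and 1 on ratio scales (0 on the log
#' scale, where the comparison is made).
#'
#' @param pe a `pooled_estimate`.
#' @return Logical; `NA` if an interval endpoint is undefined.
#' @export
is_significant <- function(pe) {
  stopifnot(inherits(pe, "pooled_estimate"))
  if (is.na(pe$ci_low) || is.na(pe$ci_high)) return(NA)
  pe$ci_low > 0 || pe$ci_high < 0
}

#' Cochran Q, DerSimonian-Laird tau-squared and I-squared
#'
#' Method-of-moments heterogeneity statistics: Q is the weighted sum of
#' squared deviations from the fixed-effect mean (weights 1/v_i), `tau2 =
#' max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)`, and `I2 =
#' max(0, (Q - df)/Q) * 100`.
#'
#' @param effects an `effect_estimates` data frame (see [effects_log_rr()])
#'   or any data frame with `theta` and `var` columns; k >= 2.
#' @return List with `Q`, `tau2`, `I2`, `df`.
#' @export
heterogeneity <- function(effects) {
  theta <- effects$theta; v <- effects$var
  k <- length(theta)
  if (k < 2L) stop_validation("heterogeneity needs k >= 2 studies")
  w <- 1 / v
  mu_f <- ksum(w * theta) / ksum(w)
  Q <- ksum(w * (theta - mu_f)^2)
  df <- k - 1
  C <- ksum(w) - ksum(w^2) / ksum(w)
  tau2 <- max(0, (Q - df) / C)
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(Q = Q, tau2 = tau2, I2 = I2, df = df)
}

# Shared IV / DL core on (theta, var) vectors; returns list used by both
# the user-facing pooler and the fast search path of invert_counts().
iv_dl_core <- function(theta, v, model, level) {
  k <- length(theta)
  if (model == "dl_random" && k >= 2L) {
    het <- heterogeneity(data.frame(theta = theta, var = v))
    tau2 <- het$tau2; Q <- het$Q; I2 <- het$I2
  } else {
    tau2 <- 0
    if (k >= 2L) {
      het <- heterogeneity(data.frame(theta = theta, var = v))
      Q <- het$Q; I2 <- het$I2
    } else {
      Q <- 0; I2 <- 0
    }
  }
  w <- 1 / (v + tau2)
  mu <- ksum(w * theta) / ksum(w)
  se <- sqrt(1 / ksum(w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(theta = mu, se = se, ci_low = mu - z * se, ci_high = mu + z * se,
       weights = w / ksum(w), Q = Q, tau2 = tau2, I2 = I2)
}

#' Inverse-variance pooling (fixed effect or DerSimonian-Laird)
#'
#' Fixed effect weights each study by 1/v_i; the random-effects model adds
#' the DL moment estimate of between-study variance, weighting by
#' 1/(v_i + tau2). Confidence intervals are Wald intervals on the analysis
#' scale. With a single study the pooled estimate and interval are that
#' study's own.
#'
#' @param effects `effect_estimates` data frame (all on one scale).
#' @param model `"fixed"` or `"dl_random"`.
#' @param level confidence level (default 0.95).
#' @return A `pooled_estimate`.
#' @export
pool_iv <- function(effects, model = c("dl_random", "fixed"), level = 0.95) {
  model <- match.arg(model)
  if (!is.data.frame(effects) || nrow(effects) == 0L)
    stop_validation("no effect estimates to pool")
  if (any(!is.finite(effects$var)) || any(effects$var <= 0))
    stop_validation("all sampling variances must be finite and > 0")
  scale <- attr(effects, "scale") %||% "smd"
  core <- iv_dl_core(effects$theta, effects$var, model, level)
  new_pooled_estimate(core$theta, core$ci_low, core$ci_high,
                      method_tag = if (model == "fixed") "iv_fixed" else "dl_random",
                      k = nrow(effects),
                      weights = stats::setNames(core$weights, effects$study_id),
                      Q = core$Q,
                      tau2 = if (model == "dl_random") core$tau2 else NA_real_,
                      I2 = core$I2, scale = scale, level = level,
                      excluded = attr(effects, "excluded") %||% character())
}

# MH core on count vectors: returns log RR, its Greenland-Robins SE and
# the normalized MH weights.
mh_core <- function(r_t, n_t, r_c, n_c) {
  N <- n_t + n_c
  R <- r_t * n_c / N
  S <- r_c * n_t / N
  if (ksum(S) == 0 || ksum(R) == 0)
    stop_numerical("Mantel-Haenszel RR undefined: no events in one arm overall")
  P <- (n_t * n_c * (r_t + r_c) - r_t * r_c * N) / N^2
  log_rr <- log(ksum(R) / ksum(S))
  se <- sqrt(ksum(P) / (ksum(R) * ksum(S)))
  list(log_rr = log_rr, se = se, weights = S / ksum(S))
}

#' Mantel-Haenszel pooled risk ratio
#'
#' Fixed-effect stratified risk ratio `sum(r_t * n_c / N) / sum(r_c * n_t /
#' N)` with the Greenland-Robins variance for its logarithm. No continuity
#' correction is applied: single-zero strata are handled natively, which is
#' why this estimator is the usual comparator in sparse harm data. With a
#' single stratum it reduces to the crude risk ratio. Reported study
#' weights are the normalized MH weights `S_i / sum(S_i)`,
#' `S_i = r_c * n_t / N`.
#'
#' @param tables list of [two_by_two()] tables or a binary [trial_set()];
#'   double-zero tables are excluded via [zero_cell_filter()].
#' @param level confidence level.
#' @return A `pooled_estimate` on the `log_rr` scale. Heterogeneity `Q` and
#'   `I2` are computed descriptively from the per-study (continuity-
#'   corrected where needed) log risk ratios; `tau2` is `NA` for this
#'   fixed-effect method.
#' @export
pool_mh_rr <- function(tables, level = 0.95) {
  if (inherits(tables, "trial_set")) tables <- as_tables(tables)
  if (length(tables) == 0L) stop_validation("no tables to pool")
  parts <- zero_cell_filter(tables)
  if (length(parts$included) == 0L)
    stop_numerical("no informative strata after double-zero exclusion")
  tb <- parts$included
  r_t <- vapply(tb, `[[`, numeric(1), "r_t")
  n_t <- vapply(tb, `[[`, numeric(1), "n_t")
  r_c <- vapply(tb, `[[`, numeric(1), "r_c")
  n_c <- vapply(tb, `[[`, numeric(1), "n_c")
  core <- mh_core(r_t, n_t, r_c, n_c)
  z <- stats::qnorm(1 - (1 - level) / 2)
  k <- length(tb)
  if (k >= 2L) {
    eff <- lapply(tb, rr_single)
    het <- heterogeneity(data.frame(
      theta = vapply(eff, `[[`, numeric(1), "theta"),
      var = vapply(eff, `[[`, numeric(1), "var")))
    Q <- het$Q; I2 <- het$I2
  } else {
    Q <- 0; I2 <- 0
  }
  new_pooled_estimate(core$log_rr, core$log_rr - z * core$se,
                      core$log_rr + z * core$se,
                      method_tag = "mh", k = k,
                      weights = stats::setNames(core$weights,
                        names(tb) %||% as.character(seq_len(k))),
                      Q = Q, tau2 = NA_real_, I2 = I2,
                      scale = "log_rr", level = level,
                      excluded = names(parts$excluded) %||% character())
}

#' Pool a trial set with a named method
#'
#' Single entry point used by the sensitivity ladder and the reporting
#' layer. Binary sets support `"dl_random"`, `"iv_fixed"` (both on log RR
#' with continuity-corrected single-zero studies), `"mh"` and
#' `"exact_conditional"` (common odds ratio, see [pool_exact()]).
#' Continuous sets support `"dl_random"` and `"iv_fixed"` on the Hedges-g
#' scale.
#'
#' @param ts a [trial_set()].
#' @param method method tag (see Details).
#' @param cc continuity constant for the log-RR paths.
#' @param level confidence level.
#' @return A `pooled_estimate`.
#' @examples
#' ts <- trial_set(data.frame(study_id = c("a", "b"),
#'                            n_t = c(100, 200), r_t = c(3, 5),
#'                            n_c = c(100, 200), r_c = c(2, 4)))
#' pool_trialset(ts, "dl_random")
#' @export
pool_trialset <- function(ts, method = c("dl_random", "iv_fixed", "mh",
                                         "exact_conditional"),
                          cc = 0.5, level = 0.95) {
  stopifnot(inherits(ts, "trial_set"))
  method <- match.arg(method)
  if (trialset_type(ts) == "continuous") {
    if (method %in% c("mh", "exact_conditional"))
      stop_validation("method '%s' applies only to binary trial sets", method)
    return(pool_iv(effects_smd(ts),
                   model = if (method == "iv_fixed") "fixed" else "dl_random",
                   level = level))
  }
  switch(method,
    dl_random = pool_iv(effects_log_rr(ts, cc = cc), "dl_random", level),
    iv_fixed = pool_iv(effects_log_rr(ts, cc = cc), "fixed", level),
    mh = pool_mh_rr(ts, level = level),
    exact_conditional = pool_exact(ts, level = level))
}
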