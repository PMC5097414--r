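# Synthetic trial-set generators. These emulate the statistical structure
# of the pooled HA/placebo safety and function literature: a handful to a
# dozen or so parallel-arm trials, serious-event risks of a few percent in
# the control arm, optionally one study with a conspicuously higher event
# rate in both arms (the influential-outlier pattern), and continuous
# function outcomes with a small standardized effect. Generation is a pure
# function of the config: each study draws from its own counter-derived
# substream, so adding studies never reshuffles earlier ones, and the
# caller's RNG state is left untouched.

#' Simulation configuration
#'
#' @param k number of studies (>= 1).
#' @param n_range inclusive range per-arm sample sizes are drawn from
#'   (default 100 to 600, the size range typical of these trials).
#' @param p0 control-arm event risk (default 0.025: serious adverse events
#'   in this literature run at roughly 2-3 percent).
#' @param true_rr generating relative risk treatment vs control
#'   (default 1).
#' @param outlier `NULL`, or a list with `multiplier` (default 3) and
#'   `arm` (`"both"` or `"treatment"`, default `"both"`): the last study
#'   multiplies `p0` by `multiplier` in the given arm(s). `"both"`
#'   emulates a trial reporting about 7 percent serious events in both
#'   arms against the others' 2-3 percent (high-rate but ratio-neutral);
#'   `"treatment"` emulates a harm-inflating outlier whose own relative
#'   risk is `multiplier` times the generating one.
#' @param continuous `NULL`, or a list with `true_smd` (default -0.23, a
#'   small function benefit, negative favors treatment) and `sd` (outcome
#'   scale SD, default 1).
#' @param seed root RNG seed (integer).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(k, n_range = c(100, 600), p0 = 0.025,
                              true_rr = 1, outlier = NULL,
                              continuous = NULL, seed = 1) {
  k <- assert_count(k, "k", lower = 1)
  stopifnot(length(n_range) == 2L, n_range[1] >= 2, n_range[2] >= n_range[1])
  assert_scalar_number(p0, "p0", lower = 1e-12, upper = 1 - 1e-12)
  assert_scalar_number(true_rr, "true_rr", lower = 0)
  if (p0 * true_rr >= 1)
    stop_validation("p0 * true_rr = %.3f is not a probability", p0 * true_rr)
  if (!is.null(outlier)) {
    outlier$multiplier <- outlier$multiplier %||% 3
    outlier$arm <- match.arg(outlier$arm %||% "both", c("both", "treatment"))
    if (p0 * outlier$multiplier * max(1, true_rr) >= 1)
      stop_validation("outlier multiplier pushes event risk above 1")
  }
  if (!is.null(continuous)) {
    continuous$true_smd <- continuous$true_smd %||% -0.23
    continuous$sd <- continuous$sd %||% 1
    stopifnot(continuous$sd > 0)
  }
  structure(list(k = k, n_range = n_range, p0 = p0, true_rr = true_rr,
                 outlier = outlier, continuous = continuous,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

with_preserved_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  expr
}

#' Generate a binary (harm-count) trial set
#'
#' Per study: arm sizes uniform on `n_range`; control events
#' `Binomial(n_c, p0)`; treatment events `Binomial(n_t, p0 * true_rr)`.
#' If an outlier is configured, the last study multiplies the baseline
#' risk in both arms (its relative risk stays `true_rr`), and its id is
#' recorded in the `outlier_id` attribute. All studies are flagged
#' blinded; "large" vs "small" variation comes from the size draw.
#'
#' @param cfg a [simulation_config()].
#' @return Binary [trial_set()] with `ae_category = "serious/any"`.
#' @examples
#' gen_binary_trialset(simulation_config(k = 5, seed = 42))
#' @export
gen_binary_trialset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_preserved_rng({
    rows <- lapply(seq_len(cfg$k), function(i) {
      set.seed(substream_seed(cfg$seed, i))
      is_outlier <- !is.null(cfg$outlier) && i == cfg$k
      mult_t <- if (is_outlier) cfg$outlier$multiplier else 1
      mult_c <- if (is_outlier && cfg$outlier$arm == "both")
        cfg$outlier$multiplier else 1
      n_t <- sample(cfg$n_range[1]:cfg$n_range[2], 1L)
      n_c <- sample(cfg$n_range[1]:cfg$n_range[2], 1L)
      p_c <- cfg$p0 * mult_c
      p_t <- min(cfg$p0 * cfg$true_rr * mult_t, 1 - 1e-12)
      data.frame(study_id = sprintf("sim%02d", i), year = 1994L + i,
                 blinded = TRUE, follow_up_weeks = 26,
                 n_t = n_t, r_t = stats::rbinom(1L, n_t, p_t),
                 n_c = n_c, r_c = stats::rbinom(1L, n_c, p_c),
                 stringsAsFactors = FALSE)
    })
    ts <- trial_set(do.call(rbind, rows), type = "binary",
                    ae_category = "serious/any")
    if (!is.null(cfg$outlier))
      attr(ts, "outlier_id") <- sprintf("sim%02d", cfg$k)
    ts
  })
}

#' Generate a continuous (function-outcome) trial set
#'
#' Simulates patient-level normal outcomes -- control mean 0, treatment
#' mean `true_smd * sd` (negative favors treatment), common SD -- and
#' summarises each arm to mean/SD/n, which is all a meta-analysis of
#' published summaries ever sees.
#'
#' @param cfg a [simulation_config()] with a `continuous` component.
#' @return Continuous [trial_set()].
#' @export
gen_continuous_trialset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(cfg$continuous))
    stop_validation("config has no continuous component")
  smd <- cfg$continuous$true_smd
  sdv <- cfg$continuous$sd
  with_preserved_rng({
    rows <- lapply(seq_len(cfg$k), function(i) {
      set.seed(substream_seed(cfg$seed, i))
      n_t <- sample(cfg$n_range[1]:cfg$n_range[2], 1L)
      n_c <- sample(cfg$n_range[1]:cfg$n_range[2], 1L)
      y_t <- stats::rnorm(n_t, mean = smd * sdv, sd = sdv)
      y_c <- stats::rnorm(n_c, mean = 0, sd = sdv)
      data.frame(study_id = sprintf("sim%02d", i), year = 1994L + i,
                 blinded = TRUE, follow_up_weeks = 26,
                 n_t = n_t, mean_t = mean(y_t), sd_t = stats::sd(y_t),
                 n_c = n_c, mean_c = mean(y_c), sd_c = stats::sd(y_c),
                 stringsAsFactors = FALSE)
    })
    trial_set(do.call(rbind, rows), type = "continuous")
  })
}
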