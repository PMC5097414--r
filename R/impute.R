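# Recovery of withheld per-study event counts. When a published pooled
# estimate includes studies whose event counts were withheld (e.g. as
# proprietary), but their sample sizes are known, the integer counts can be
# recovered by searching the bounded grid of candidate counts for the
# assignment whose completed pooling reproduces the published point
# estimate and confidence limits. This module formalizes that
# trial-and-error as a bounded integer program with an explicit weighted
# objective, so the search is reproducible and its uniqueness is reported
# rather than assumed.

#' Define a count-imputation problem
#'
#' @param observed binary [trial_set()] of studies with full counts.
#' @param hidden data frame with `study_id`, `n_t`, `n_c` for the studies
#'   whose event counts are unknown; nonempty.
#' @param target published pooled estimate to reproduce: list or numeric
#'   vector with `point`, `ci_low`, `ci_high` on the RR scale. `point`
#'   must lie inside the interval.
#' @param method_tag pooling method the published estimate used (to
#'   invert): one of the [pool_trialset()] binary tags.
#' @param bounds data frame with `study_id`, `max_t`, `max_c`: the largest
#'   admissible event count per hidden arm (defaults to the arm sizes;
#'   tight bounds keep exhaustive search feasible). Must not exceed arm
#'   sizes.
#' @param weights length-3 weights of the squared log-scale discrepancies
#'   in (point, ci_low, ci_high); default `c(2, 1, 1)` -- the point
#'   estimate counts double since it is the primary published quantity.
#'   Set the CI weights to 0 to match the point estimate alone.
#' @param cc,level forwarded to the pooling method.
#' @return Object of class `imputation_problem`.
#' @export
imputation_problem <- function(observed, hidden, target,
                               method_tag = "dl_random", bounds = NULL,
                               weights = c(2, 1, 1), cc = 0.5, level = 0.95) {
  stopifnot(inherits(observed, "trial_set"))
  if (trialset_type(observed) != "binary")
    stop_validation("imputation operates on binary trial sets")
  hidden <- as.data.frame(hidden, stringsAsFactors = FALSE)
  if (nrow(hidden) == 0L) stop_validation("no hidden studies")
  if (!all(c("study_id", "n_t", "n_c") %in% names(hidden)))
    stop_validation("hidden needs study_id, n_t, n_c")
  if (any(hidden$study_id %in% observed$study_id))
    stop_validation("hidden study ids overlap observed set")
  target <- as.list(target)
  for (f in c("point", "ci_low", "ci_high"))
    assert_scalar_number(target[[f]] %||% NA, f, lower = 0)
  if (target$point < target$ci_low || target$point > target$ci_high)
    stop_validation("target point %.3f outside its CI (%.3f, %.3f)",
                    target$point, target$ci_low, target$ci_high)
  if (is.null(bounds)) {
    bounds <- data.frame(study_id = hidden$study_id,
                         max_t = hidden$n_t, max_c = hidden$n_c,
                         stringsAsFactors = FALSE)
  }
  bounds <- as.data.frame(bounds)[match(hidden$study_id, bounds$study_id), ]
  if (anyNA(bounds$max_t) || anyNA(bounds$max_c))
    stop_validation("bounds must cover every hidden study")
  if (any(bounds$max_t > hidden$n_t) || any(bounds$max_c > hidden$n_c))
    stop_validation("bounds exceed hidden arm sizes")
  stopifnot(length(weights) == 3L, all(weights >= 0), sum(weights) > 0)
  structure(list(observed = observed, hidden = hidden,
                 target = target[c("point", "ci_low", "ci_high")],
                 method_tag = method_tag, bounds = bounds,
                 weights = weights, cc = cc, level = level),
            class = "imputation_problem")
}

# Pool completed counts to the (theta, ci_low, ci_high) log-scale triple,
# matching pool_trialset() output exactly (shares iv_dl_core / mh_core).
pool_triple_counts <- function(r_t, n_t, r_c, n_c, method, cc, level) {
  keep <- !(r_t == 0 & r_c == 0)
  if (!any(keep)) return(NULL)
  r_t <- r_t[keep]; n_t <- n_t[keep]; r_c <- r_c[keep]; n_c <- n_c[keep]
  if (method %in% c("dl_random", "iv_fixed")) {
    z <- xor(r_t == 0, r_c == 0)
    rt <- r_t + cc * z; nt <- n_t + cc * z
    rc <- r_c + cc * z; nc <- n_c + cc * z
    theta <- log((rt / nt) / (rc / nc))
    v <- 1 / rt - 1 / nt + 1 / rc - 1 / nc
    core <- iv_dl_core(theta, v,
                       if (method == "iv_fixed") "fixed" else "dl_random",
                       level)
    c(core$theta, core$ci_low, core$ci_high)
  } else if (method == "mh") {
    core <- tryCatch(mh_core(r_t, n_t, r_c, n_c),
                     harmsynth_numerical_error = function(e) NULL)
    if (is.null(core)) return(NULL)
    zq <- stats::qnorm(1 - (1 - level) / 2)
    c(core$log_rr, core$log_rr - zq * core$se, core$log_rr + zq * core$se)
  } else if (method == "exact_conditional") {
    tabs <- lapply(seq_along(r_t), function(i)
      two_by_two(r_t[i], n_t[i], r_c[i], n_c[i]))
    pe <- tryCatch(pool_exact(tabs, level = level),
                   harmsynth_numerical_error = function(e) NULL)
    if (is.null(pe)) return(NULL)
    c(pe$theta, pe$ci_low, pe$ci_high)
  } else {
    stop_validation("unknown method '%s'", method)
  }
}

problem_counts <- function(problem, assign) {
  obs <- problem$observed
  list(r_t = c(obs$r_t, assign$r_t), n_t = c(obs$n_t, problem$hidden$n_t),
       r_c = c(obs$r_c, assign$r_c), n_c = c(obs$n_c, problem$hidden$n_c))
}

#' Discrepancy between a candidate completion and the published target
#'
#' Pools the observed studies together with the candidate hidden counts
#' and returns the weighted squared distance, on the log scale, between
#' the pooled (point, ci_low, ci_high) and the target triple. A candidate
#' whose pooled estimate is undefined (e.g. all completed studies
#' double-zero) scores `Inf`.
#'
#' @param assign data frame with `study_id`, `r_t`, `r_c` for every hidden
#'   study (order matched by id).
#' @param problem an [imputation_problem()].
#' @return Nonnegative objective value.
#' @export
discrepancy <- function(assign, problem) {
  stopifnot(inherits(problem, "imputation_problem"))
  assign <- as.data.frame(assign)
  assign <- assign[match(problem$hidden$study_id, assign$study_id), ]
  if (anyNA(assign$r_t) || anyNA(assign$r_c))
    stop_validation("assignment must cover every hidden study")
  if (any(assign$r_t > problem$bounds$max_t) ||
      any(assign$r_c > problem$bounds$max_c) ||
      any(assign$r_t < 0) || any(assign$r_c < 0))
    stop_validation("assignment outside bounds")
  cnt <- problem_counts(problem, assign)
  triple <- pool_triple_counts(cnt$r_t, cnt$n_t, cnt$r_c, cnt$n_c,
                               problem$method_tag, problem$cc, problem$level)
  discrepancy_value(triple, problem)
}

discrepancy_value <- function(triple, problem) {
  if (is.null(triple) || any(!is.finite(triple))) return(Inf)
  tgt <- log(c(problem$target$point, problem$target$ci_low,
               problem$target$ci_high))
  sum(problem$weights * (triple - tgt)^2)
}

# TRUE when every pooled component matches the printed target within
# half a unit of its last printed decimal (targets printed to 2 decimals).
target_attained <- function(triple, problem, tol = 0.005) {
  if (is.null(triple) || any(!is.finite(triple))) return(FALSE)
  tgt <- c(problem$target$point, problem$target$ci_low, problem$target$ci_high)
  use <- problem$weights > 0
  all(abs(exp(triple)[use] - tgt[use]) <= tol + 1e-12)
}

# enumerate (r_t, r_c) grid of hidden study j
hidden_grid <- function(problem, j) {
  expand.grid(r_t = 0:problem$bounds$max_t[j],
              r_c = 0:problem$bounds$max_c[j])
}

#' Invert a published pooled estimate for hidden event counts
#'
#' Searches the bounded integer grid of hidden (treated, control) event
#' counts for the assignment minimizing [discrepancy()].
#'
#' * `"exhaustive"` enumerates every candidate (refused above
#'   `cap` candidates) and returns the global minimizer together with all
#'   assignments tied within `tie_tol` of it.
#' * `"coordinate_descent"` cycles over hidden studies, fully enumerating
#'   one study's grid while holding the others fixed, from `restarts`
#'   deterministic pseudo-random starting points; returns the best local
#'   minimizer found. Intended for problems whose grids are too large to
#'   enumerate.
#'
#' @param problem an [imputation_problem()].
#' @param strategy `"exhaustive"` or `"coordinate_descent"`.
#' @param cap maximum number of candidates for exhaustive search
#'   (default 1e7).
#' @param restarts number of coordinate-descent restarts.
#' @param seed integer seed controlling the restart points (default 1;
#'   the search is deterministic given the seed).
#' @param tie_tol objective tolerance within which assignments are
#'   reported as tied.
#' @return Object of class `imputation_solution`: list with `assignments`
#'   (best data frame of `study_id`, `r_t`, `r_c`), `objective`, `unique`,
#'   `ties` (all tied assignments, smallest total events first),
#'   `attained` (TRUE when every matched component agrees with the target
#'   to printed precision, 0.005 on the RR scale), `pooled` (the completed
#'   pooled triple, back-transformed), and `strategy`.
#' @export
invert_counts <- function(problem,
                          strategy = c("exhaustive", "coordinate_descent"),
                          cap = 1e7, restarts = 5, seed = 1,
                          tie_tol = 1e-9) {
  stopifnot(inherits(problem, "imputation_problem"))
  strategy <- match.arg(strategy)
  h <- nrow(problem$hidden)
  grids <- lapply(seq_len(h), hidden_grid, problem = problem)
  sizes <- vapply(grids, nrow, numeric(1))
  total <- prod(sizes)

  obj_of <- function(rt_vec, rc_vec) {
    cnt <- problem_counts(problem,
                          data.frame(study_id = problem$hidden$study_id,
                                     r_t = rt_vec, r_c = rc_vec))
    triple <- pool_triple_counts(cnt$r_t, cnt$n_t, cnt$r_c, cnt$n_c,
                                 problem$method_tag, problem$cc,
                                 problem$level)
    list(obj = discrepancy_value(triple, problem), triple = triple)
  }

  best <- Inf; ties <- list()
  record <- function(rt_vec, rc_vec, obj) {
    if (obj < best - tie_tol) {
      best <<- obj
      ties <<- list(list(r_t = rt_vec, r_c = rc_vec, objective = obj))
    } else if (obj <= best + tie_tol) {
      key_new <- paste(c(rt_vec, rc_vec), collapse = ",")
      have <- vapply(ties, function(t)
        paste(c(t$r_t, t$r_c), collapse = ","), character(1))
      if (!key_new %in% have) {
        if (obj < best) best <<- obj
        ties[[length(ties) + 1L]] <<- list(r_t = rt_vec, r_c = rc_vec,
                                           objective = obj)
      }
    }
  }

  if (strategy == "exhaustive") {
    if (total > cap)
      stop_validation(paste("exhaustive search space of %.3g candidates",
                            "exceeds cap %.3g; tighten bounds or use",
                            "strategy = 'coordinate_descent'"), total, cap)
    idx <- rep(1L, h)
    repeat {
      rt_vec <- vapply(seq_len(h), function(j) grids[[j]]$r_t[idx[j]],
                       numeric(1))
      rc_vec <- vapply(seq_len(h), function(j) grids[[j]]$r_c[idx[j]],
                       numeric(1))
      record(rt_vec, rc_vec, obj_of(rt_vec, rc_vec)$obj)
      j <- 1L
      while (j <= h) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= sizes[j]) break
        idx[j] <- 1L; j <- j + 1L
      }
      if (j > h) break
    }
  } else {
    rng <- function(counter, modulus)
      floor(substream_seed(seed, counter) %% modulus)
    counter <- 0L
    for (rs in seq_len(restarts)) {
      rt_vec <- vapply(seq_len(h), function(j) {
        counter <<- counter + 1L
        rng(counter, problem$bounds$max_t[j] + 1)
      }, numeric(1))
      rc_vec <- vapply(seq_len(h), function(j) {
        counter <<- counter + 1L
        rng(counter, problem$bounds$max_c[j] + 1)
      }, numeric(1))
      cur <- obj_of(rt_vec, rc_vec)$obj
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (j in seq_len(h)) {
          g <- grids[[j]]
          objs <- vapply(seq_len(nrow(g)), function(r) {
            rt2 <- rt_vec; rc2 <- rc_vec
            rt2[j] <- g$r_t[r]; rc2[j] <- g$r_c[r]
            obj_of(rt2, rc2)$obj
          }, numeric(1))
          r_best <- which.min(objs)
          if (objs[r_best] < cur - 1e-15) {
            rt_vec[j] <- g$r_t[r_best]; rc_vec[j] <- g$r_c[r_best]
            cur <- objs[r_best]
            improved <- TRUE
          }
        }
      }
      record(rt_vec, rc_vec, cur)
    }
  }

  # deterministic reporting order: smallest total events first
  totals <- vapply(ties, function(t) sum(t$r_t) + sum(t$r_c), numeric(1))
  keys <- vapply(ties, function(t) paste(c(t$r_t, t$r_c), collapse = ","),
                 character(1))
  ties <- ties[order(totals, keys)]
  top <- ties[[1L]]
  assignments <- data.frame(study_id = problem$hidden$study_id,
                            r_t = top$r_t, r_c = top$r_c,
                            stringsAsFactors = FALSE)
  triple <- obj_of(top$r_t, top$r_c)$triple
  structure(list(
    assignments = assignments,
    objective = best,
    unique = length(ties) == 1L,
    ties = lapply(ties, function(t)
      data.frame(study_id = problem$hidden$study_id, r_t = t$r_t,
                 r_c = t$r_c, objective = t$objective,
                 stringsAsFactors = FALSE)),
    attained = target_attained(triple, problem),
    pooled = if (is.null(triple)) NULL else
      stats::setNames(exp(triple), c("point", "ci_low", "ci_high")),
    strategy = strategy),
    class = "imputation_solution")
}

#' @export
print.imputation_solution <- function(x, ...) {
  cat(sprintf("<imputation_solution> %s: objective %.3g (%s, %s)\n",
              x$strategy, x$objective,
              if (x$unique) "unique" else
                sprintf("%d tied assignments", length(x$ties)),
              if (x$attained) "target attained to printed precision"
              else "target NOT attained"))
  print(x$assignments)
  if (!is.null(x$pooled))
    cat(sprintf("  completed pooling: %.3f (%.3f, %.3f)\n",
                x$pooled[1], x$pooled[2], x$pooled[3]))
  invisible(x)
}

#' Read an imputation problem from JSON
#'
#' Format: `{"observed_csv": path-or-relative, "hidden": [{"study_id":
#' ..., "n_t": ..., "n_c": ...}], "target": {"point": ..., "ci_low": ...,
#' "ci_high": ...}, "method_tag": ..., "bounds": [...], "weights": [...],
#' "strategy": ...}`. Relative `observed_csv` paths resolve against the
#' JSON file's directory.
#'
#' @param path JSON file path.
#' @return List with `problem` (an [imputation_problem()]) and `strategy`.
#' @export
read_problem <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  obs_path <- raw$observed_csv
  if (!file.exists(obs_path))
    obs_path <- file.path(dirname(path), raw$observed_csv)
  observed <- read_trialset(obs_path)
  problem <- imputation_problem(
    observed, raw$hidden, as.list(raw$target),
    method_tag = raw$method_tag %||% "dl_random",
    bounds = raw$bounds,
    weights = raw$weights %||% c(2, 1, 1),
    cc = raw$cc %||% 0.5, level = raw$level %||% 0.95)
  list(problem = problem, strategy = raw$strategy %||% "exhaustive")
}
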