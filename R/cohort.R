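# Decision tree expansion and Markov cohort propagation.
#
# Each diagnostic arm expands into weighted branches (true positives by
# stage; false negatives, who start treatment late and by default at
# advanced stage). Every branch then runs the same four-state Markov chain:
# on_treatment (first 3 months) -> post_treatment (to the end of the
# disease-risk window, with Weibull disease mortality) -> post_disease
# (background mortality and morbidity only) ; absorbing dead state.

#' Expand a diagnostic arm into decision-tree branches
#'
#' Pathology arm: true positives split by the presenting stage mix; false
#' negatives (probability `fn_prob_pathology`) are assumed to have
#' progressed to advanced stage by the time of eventual correct diagnosis
#' (or retain the presenting mix when `cfg$run$fn_stage == "retain"`).
#' Liquid-biopsy arm: true positives split by the earlier-diagnosis stage
#' mix; false negatives fall back to the full histopathology pathway (the
#' pathology subtree, including its own false negatives when
#' `cfg$run$fn_recursive` is `TRUE`), and their diagnostic cost includes
#' both the liquid-biopsy testing (with the NNT multiplier) and the
#' subsequent pathology test.
#'
#' @param arm `"pathology"` or `"liquid"`.
#' @param cfg a `bl_config` object.
#' @return data.frame of branches: `label`, `weight`, `stage`, `diag_cost`
#'   (TZS, incurred at time 0). Weights sum to 1.
#' @export
#' @examples
#' build_decision_tree("pathology", bl_default_config())
build_decision_tree <- function(arm, cfg) {
  arm <- match.arg(arm, c("pathology", "liquid"))
  d <- cfg$diag
  s <- cfg$stages
  retain <- identical(cfg$run$fn_stage, "retain")

  path_tree <- function(diag_cost, prefix = "path") {
    fn <- d$fn_prob_pathology
    tp <- data.frame(
      label = paste0(prefix, c("_tp_limited", "_tp_advanced")),
      weight = (1 - fn) * c(s$p_limited_pathology, 1 - s$p_limited_pathology),
      stage = c("limited", "advanced"),
      diag_cost = diag_cost
    )
    fnb <- if (retain) {
      data.frame(
        label = paste0(prefix, c("_fn_limited", "_fn_advanced")),
        weight = fn * c(s$p_limited_pathology, 1 - s$p_limited_pathology),
        stage = c("limited", "advanced"),
        diag_cost = diag_cost
      )
    } else {
      data.frame(label = paste0(prefix, "_fn_advanced"), weight = fn,
                 stage = "advanced", diag_cost = diag_cost)
    }
    rbind(tp, fnb)
  }

  tree <- if (arm == "pathology") {
    path_tree(d$pathology_unit_cost)
  } else {
    lb_cost <- d$nnt * liquid_unit_cost(d)
    fn <- d$fn_prob_liquid
    tp <- data.frame(
      label = c("liquid_tp_limited", "liquid_tp_advanced"),
      weight = (1 - fn) * c(s$p_limited_liquid, 1 - s$p_limited_liquid),
      stage = c("limited", "advanced"),
      diag_cost = lb_cost
    )
    sub <- if (cfg$run$fn_recursive) {
      path_tree(lb_cost + d$pathology_unit_cost, prefix = "liquid_fn")
    } else {
      # non-recursive mode: all liquid FNs are correctly diagnosed by
      # pathology, entering at the presenting stage mix
      data.frame(
        label = c("liquid_fn_limited", "liquid_fn_advanced"),
        weight = c(s$p_limited_pathology, 1 - s$p_limited_pathology),
        stage = c("limited", "advanced"),
        diag_cost = lb_cost + d$pathology_unit_cost
      )
    }
    sub$weight <- fn * sub$weight
    rbind(tp, sub)
  }
  tree <- tree[tree$weight > 0, , drop = FALSE]
  stopifnot(abs(sum(tree$weight) - 1) < 1e-12)
  rownames(tree) <- NULL
  tree
}

# Cycle boundary schedule in months: fine cycles over the disease-risk
# window (truncated at the horizon if needed), then post-disease cycles to
# the age cap.
cycle_schedule <- function(run) {
  horizon <- run$disease_risk_horizon_months
  b <- seq(0, horizon, by = run$cycle_length_months)
  if (horizon - b[length(b)] > 1e-9 * horizon) b <- c(b, horizon)
  total <- (run$max_age - run$cohort_entry_age) * 12
  if (total > horizon)
    b <- c(b, seq(horizon, total, by = run$post_cycle_length_months)[-1])
  b
}

#' Run the Markov cohort for one decision-tree branch
#'
#' Propagates a unit cohort through the health states. During the
#' disease-risk window, per-cycle death probabilities are the conditional
#' Weibull hazards for the branch stage and all deaths are attributed to
#' disease (the fitted survival curve is all-cause, and background
#' mortality at these ages is negligible by comparison); afterwards the
#' cohort is in the post-disease state and dies only at the age-specific
#' background rate. The trace conserves probability at every cycle.
#'
#' @param stage `"limited"` or `"advanced"` (stage at treatment).
#' @param cfg a `bl_config` object.
#' @return Object of class `bl_trace`: a list of aligned vectors `t_start`,
#'   `t_end` (months from model entry), `state` (state occupied by the
#'   live cohort that cycle), `alive_start`, `alive_end`, `d_disease`,
#'   `d_background` (incident deaths during the cycle), `age_mid` (years).
#' @export
run_markov_branch <- function(stage, cfg) {
  stage <- match.arg(stage, c("limited", "advanced"))
  run <- cfg$run
  b <- cycle_schedule(run)
  t_start <- b[-length(b)]
  t_end <- b[-1]
  horizon <- run$disease_risk_horizon_months
  in_window <- t_start < horizon - 1e-9

  q <- numeric(length(t_start))
  if (any(in_window)) {
    s_start <- survival_at(t_start[in_window], stage, cfg$survival)
    s_end <- survival_at(t_end[in_window], stage, cfg$survival)
    if (any(s_start == 0))
      stop("degenerate survival inside the disease-risk window", call. = FALSE)
    q[in_window] <- 1 - s_end / s_start
  }
  age_start <- run$cohort_entry_age + t_start / 12
  post <- !in_window
  q[post] <- background_cycle_prob(age_start[post],
                                   (t_end - t_start)[post], cfg$life_table)

  alive_start <- c(1, cumprod(1 - q))[seq_along(q)]
  deaths <- alive_start * q
  alive_end <- alive_start - deaths

  state <- ifelse(t_start < run$treatment_duration_months - 1e-9, "on_treatment",
                  ifelse(in_window, "post_treatment", "post_disease"))

  out <- list(
    t_start = t_start, t_end = t_end, state = state,
    alive_start = alive_start, alive_end = alive_end,
    d_disease = ifelse(in_window, deaths, 0),
    d_background = ifelse(in_window, 0, deaths),
    age_mid = run$cohort_entry_age + (t_start + t_end) / 24
  )
  class(out) <- "bl_trace"
  out
}

#' Half-cycle-corrected occupancy
#'
#' Effective person-time weight per cycle: the arithmetic mean of the
#' start-of-cycle and end-of-cycle live occupancy. Deaths are timed at the
#' cycle midpoint for discounting.
#'
#' @param trace a `bl_trace`.
#' @return Numeric vector of effective live occupancy per cycle.
#' @export
half_cycle_occupancy <- function(trace) {
  (trace$alive_start + trace$alive_end) / 2
}

#' @export
print.bl_trace <- function(x, ...) {
  n <- length(x$t_start)
  cat(sprintf("Markov cohort trace: %d cycles, %.0f months\n", n, x$t_end[n]))
  cat(sprintf("  disease deaths: %.4f, background deaths: %.4f, alive at end: %.2e\n",
              sum(x$d_disease), sum(x$d_background), x$alive_end[n]))
  invisible(x)
}

#' Convert a cohort trace to a tidy data.frame
#'
#' One row per cycle with start-of-cycle occupancy split over the four
#' health states and incident deaths by cause; suitable for CSV export.
#'
#' @param x a `bl_trace`.
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @return data.frame with columns `cycle`, `time_months`, `state`,
#'   `occ_on_treatment`, `occ_post_treatment`, `occ_post_disease`,
#'   `occ_dead`, `incident_disease_deaths`, `incident_background_deaths`.
#' @export
as.data.frame.bl_trace <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- length(x$t_start)
  dead_start <- 1 - x$alive_start
  data.frame(
    cycle = seq_len(n),
    time_months = x$t_start,
    state = x$state,
    occ_on_treatment = ifelse(x$state == "on_treatment", x$alive_start, 0),
    occ_post_treatment = ifelse(x$state == "post_treatment", x$alive_start, 0),
    occ_post_disease = ifelse(x$state == "post_disease", x$alive_start, 0),
    occ_dead = dead_start,
    incident_disease_deaths = x$d_disease,
    incident_background_deaths = x$d_background
  )
}
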