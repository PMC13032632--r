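# Cost accrual: diagnosis (NNT multiplier, throughput tiers), treatment
# (drugs, non-drug resources, expected adverse-event costs, all in the
# first cycle), follow-up schedule, end-of-life care, and facility
# overheads. All values in Tanzanian Shillings.

#' Expected treatment cost at the start of treatment
#'
#' Stage-specific chemotherapy drug and non-drug costs plus the expected
#' adverse-event cost, \eqn{\sum_i p_i(stage) \cdot c_i} over the
#' adverse-event table.
#'
#' @param stage `"limited"` or `"advanced"`.
#' @param costs cost inputs (`cfg$costs`).
#' @return list with `treatment` (drug + non-drug, TZS) and
#'   `adverse_events` (expected TZS).
#' @export
#' @examples
#' treatment_cost("limited", bl_default_config()$costs)
treatment_cost <- function(stage, costs) {
  stage <- match.arg(stage, c("limited", "advanced"))
  trt <- costs$chemo_drug[[stage]]$mean + costs$chemo_nondrug[[stage]]$mean
  ae <- 0
  if (nrow(costs$ae_table) > 0) {
    p <- if (stage == "limited") costs$ae_table$p_limited else costs$ae_table$p_advanced
    ae <- sum(p * costs$ae_table$unit_cost)
  }
  list(treatment = trt, adverse_events = ae)
}

# follow-up cost per quarter as a function of time since model entry
# (months): monthly consultations in year 1, half-yearly in year 2,
# annually in years 3-5, none afterwards; the tabulated inputs are already
# expressed per quarter.
followup_quarter_rate <- function(t_mid_months, fu) {
  ifelse(t_mid_months < 12, fu$year1$mean,
         ifelse(t_mid_months < 24, fu$year2$mean,
                ifelse(t_mid_months < 60, fu$years3_5$mean, 0)))
}

#' Accrue discounted costs over a cohort trace
#'
#' Diagnosis is incurred at time 0 (undiscounted). Treatment and expected
#' adverse-event costs apply to the cohort entering the first cycle,
#' discounted at the first cycle midpoint. Follow-up accrues per alive
#' (half-cycle-corrected) patient at the quarterly rate for the current
#' model year, scaled by the cycle length. End-of-life care is incurred by
#' each incident disease death (none for background deaths), discounted at
#' the cycle midpoint. Overheads apply at `cfg$econ$overhead_rate` to
#' treatment, adverse-event, follow-up and end-of-life costs; the
#' diagnostic unit costs are treated as fully loaded from the microcosting
#' and receive no additional overhead unless
#' `cfg$run$overhead_on_diagnosis` is `TRUE`.
#'
#' @param trace a `bl_trace` for the branch's stage.
#' @param branch one row of [build_decision_tree()] output (list or
#'   single-row data.frame with `stage` and `diag_cost`).
#' @param cfg a `bl_config`.
#' @param r annual discount rate; defaults to the configured rate.
#' @return Object of class `bl_cost` with components `diagnosis`,
#'   `treatment`, `adverse_events`, `followup`, `end_of_life`, `overheads`,
#'   `total` (TZS, discounted, per patient entering the branch).
#' @export
accrue_costs <- function(trace, branch, cfg, r = cfg$econ$annual_discount_rate) {
  t_mid <- (trace$t_start + trace$t_end) / 24
  df <- disc_factor(t_mid, r)
  eff <- half_cycle_occupancy(trace)

  tc <- treatment_cost(branch$stage, cfg$costs)
  treatment <- tc$treatment * trace$alive_start[1] * df[1]
  adverse_events <- tc$adverse_events * trace$alive_start[1] * df[1]

  cyc_quarters <- (trace$t_end - trace$t_start) / 3
  followup <- sum(followup_quarter_rate(trace$t_start,
                                        cfg$costs$followup_per_quarter) *
                    cyc_quarters * eff * df)

  end_of_life <- sum(trace$d_disease * cfg$costs$end_of_life$mean * df)

  diagnosis <- branch$diag_cost
  oh_base <- treatment + adverse_events + followup + end_of_life
  if (isTRUE(cfg$run$overhead_on_diagnosis)) oh_base <- oh_base + diagnosis
  overheads <- cfg$econ$overhead_rate * oh_base

  out <- list(diagnosis = diagnosis, treatment = treatment,
              adverse_events = adverse_events, followup = followup,
              end_of_life = end_of_life, overheads = overheads)
  out$total <- diagnosis + treatment + adverse_events + followup +
    end_of_life + overheads
  class(out) <- "bl_cost"
  out
}

#' @export
print.bl_cost <- function(x, ...) {
  cat("Discounted cost per patient (TZS)\n")
  for (nm in c("diagnosis", "treatment", "adverse_events", "followup",
               "end_of_life", "overheads", "total"))
    cat(sprintf("  %-15s %14s\n", nm, format(round(x[[nm]]), big.mark = ",")))
  invisible(x)
}
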