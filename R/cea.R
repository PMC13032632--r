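# Arm-level evaluation and incremental cost-effectiveness.

#' Evaluate one diagnostic arm
#'
#' Expands the arm into decision-tree branches, runs the Markov cohort for
#' each distinct stage, and returns the branch-weighted discounted cost and
#' DALY burden per patient with full decompositions.
#'
#' @param arm `"pathology"` or `"liquid"`.
#' @param cfg a `bl_config`.
#' @return Object of class `bl_arm`: `arm`, `cost_tzs`, `dalys`,
#'   `cost_components` (TZS by category), `daly_components`, `branches`
#'   (per-branch detail data.frame).
#' @export
#' @examples
#' cfg <- bl_default_config()
#' evaluate_arm("pathology", cfg)
evaluate_arm <- function(arm, cfg) {
  stop_if_invalid(cfg)
  tree <- build_decision_tree(arm, cfg)

  stages <- unique(tree$stage)
  traces <- lapply(stats::setNames(stages, stages), run_markov_branch, cfg = cfg)
  dalys_by_stage <- lapply(traces, total_dalys, cfg = cfg)

  cost_comp <- c(diagnosis = 0, treatment = 0, adverse_events = 0,
                 followup = 0, end_of_life = 0, overheads = 0)
  daly_comp <- c(yll_disease = 0, yll_background = 0,
                 yld_disease = 0, yld_background = 0)
  rows <- vector("list", nrow(tree))
  for (i in seq_len(nrow(tree))) {
    br <- tree[i, ]
    cost <- accrue_costs(traces[[br$stage]], br, cfg)
    daly <- dalys_by_stage[[br$stage]]
    for (nm in names(cost_comp))
      cost_comp[nm] <- cost_comp[nm] + br$weight * cost[[nm]]
    for (nm in names(daly_comp))
      daly_comp[nm] <- daly_comp[nm] + br$weight * daly[[nm]]
    rows[[i]] <- data.frame(label = br$label, weight = br$weight,
                            stage = br$stage, cost_tzs = cost$total,
                            dalys = daly$total)
  }
  out <- list(arm = arm,
              cost_tzs = sum(cost_comp),
              dalys = sum(daly_comp),
              cost_components = cost_comp,
              daly_components = daly_comp,
              branches = do.call(rbind, rows))
  class(out) <- "bl_arm"
  out
}

#' @export
print.bl_arm <- function(x, ...) {
  cat(sprintf("Arm: %s\n", x$arm))
  cat(sprintf("  discounted cost: TZS %s\n",
              format(round(x$cost_tzs), big.mark = ",")))
  cat(sprintf("  discounted DALY burden: %.3f per patient\n", x$dalys))
  invisible(x)
}

#' Incremental cost-effectiveness of one arm against another
#'
#' Computes the incremental cost (comparator minus reference), DALYs
#' averted (reference burden minus comparator burden), the ICER from the
#' unrounded values, and net monetary benefit at each configured
#' willingness-to-pay threshold. Dominance is flagged when one arm is both
#' cheaper and more effective; a zero effect difference yields an infinite
#' ICER sentinel.
#'
#' @param reference the standard-of-care `bl_arm` (here: pathology).
#' @param comparator the intervention `bl_arm` (here: liquid biopsy).
#' @param econ economic settings (`cfg$econ`).
#' @return Object of class `bl_cea`: `delta_cost_tzs`, `delta_cost_usd`,
#'   `delta_dalys_averted`, `icer_tzs`, `icer_usd`, `net_benefit`
#'   (data.frame over thresholds, USD), `dominance`, plus both arm results.
#' @export
compute_icer <- function(reference, comparator, econ) {
  dc <- comparator$cost_tzs - reference$cost_tzs
  de <- reference$dalys - comparator$dalys
  icer_tzs <- if (de == 0) Inf * sign(dc) else dc / de
  dominance <- if (dc < 0 && de > 0) "comparator_dominates"
               else if (dc > 0 && de < 0) "reference_dominates"
               else "none"
  lam <- econ$thresholds_usd
  nb <- data.frame(
    threshold_usd = unname(lam),
    label = if (is.null(names(lam))) as.character(lam) else names(lam),
    nmb_usd = unname(lam * de - dc / econ$exchange_rate)
  )
  out <- list(delta_cost_tzs = dc,
              delta_cost_usd = dc / econ$exchange_rate,
              delta_dalys_averted = de,
              icer_tzs = icer_tzs,
              icer_usd = icer_tzs / econ$exchange_rate,
              net_benefit = nb,
              dominance = dominance,
              reference = reference, comparator = comparator)
  class(out) <- "bl_cea"
  out
}

#' @export
print.bl_cea <- function(x, ...) {
  cat(sprintf("Incremental analysis: %s vs %s\n",
              x$comparator$arm, x$reference$arm))
  cat(sprintf("  incremental cost:  TZS %s ($%s)\n",
              format(round(x$delta_cost_tzs), big.mark = ","),
              format(round(x$delta_cost_usd), big.mark = ",")))
  cat(sprintf("  DALYs averted:     %.3f per patient\n", x$delta_dalys_averted))
  if (x$dominance != "none") {
    cat(sprintf("  dominance: %s\n", x$dominance))
  } else {
    cat(sprintf("  ICER:              TZS %s ($%s) per DALY averted\n",
                format(round(x$icer_tzs), big.mark = ","),
                format(round(x$icer_usd), big.mark = ",")))
  }
  invisible(x)
}

#' Run the full base-case cost-utility comparison
#'
#' Evaluates both diagnostic arms under one configuration and computes the
#' incremental analysis (liquid biopsy vs pathology).
#'
#' @param cfg a `bl_config`; default is the packaged base case.
#' @return A `bl_cea` object (see [compute_icer()]).
#' @export
#' @examples
#' res <- evaluate_cea(bl_default_config())
#' print(res)
#' summary(res)
evaluate_cea <- function(cfg = bl_default_config()) {
  stop_if_invalid(cfg)
  pathology <- evaluate_arm("pathology", cfg)
  liquid <- evaluate_arm("liquid", cfg)
  compute_icer(pathology, liquid, cfg$econ)
}

#' @export
summary.bl_cea <- function(object, ...) {
  arms <- data.frame(
    arm = c(object$comparator$arm, object$reference$arm),
    cost_tzs = c(object$comparator$cost_tzs, object$reference$cost_tzs),
    dalys = c(object$comparator$dalys, object$reference$dalys)
  )
  structure(list(arms = arms,
                 cost_components = rbind(
                   comparator = object$comparator$cost_components,
                   reference = object$reference$cost_components),
                 cea = object),
            class = "summary.bl_cea")
}

#' @export
print.summary.bl_cea <- function(x, ...) {
  cat("Per-arm discounted results (per patient)\n")
  arms <- x$arms
  arms$cost_tzs <- format(round(arms$cost_tzs), big.mark = ",")
  arms$dalys <- round(arms$dalys, 3)
  print(arms, row.names = FALSE)
  cat("\nCost components (TZS)\n")
  print(round(x$cost_components))
  cat("\n")
  print(x$cea)
  invisible(x)
}
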