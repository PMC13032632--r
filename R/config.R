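# Internal helper: a (mean, se) parameter node.
par_ms <- function(mean, se) list(mean = mean, se = se)

#' Base-case model configuration
#'
#' Builds the packaged base-case configuration of the cost-utility model:
#' diagnostic performance and unit costs, stage mix at diagnosis, disability
#' weights, Weibull survival coefficients, treatment/follow-up/end-of-life
#' costs, economic settings (5% annual discount rate, 20% overheads,
#' 2595 TZS/USD) and run settings (3-month cycles, 24-month disease-risk
#' window, cohort entry at age 10, horizon capped at age 100).
#'
#' Monetary values are Tanzanian Shillings (TZS); conversion to USD happens
#' only at reporting time. The background life table is a packaged synthetic
#' fixture calibrated so that remaining life expectancy at age 10 equals 65
#' years (see [make_life_table_fixture()]); it is a documented stand-in for
#' national all-cause mortality and age-specific background morbidity data
#' and can be replaced via the `life_table` argument or the config file.
#'
#' The adverse-event table defaults to empty (zero probability and cost).
#' Both model arms incur adverse-event costs through the same mechanism, so
#' its effect on incremental results is second order; a nominal illustrative
#' table for exercising the code path is available from [make_ae_stub()].
#'
#' @param life_table optional replacement life table (data.frame with columns
#'   `age_start`, `q_annual`, `disability_weight`); default is the packaged
#'   calibrated fixture.
#' @param ae_table optional adverse-event table (data.frame with columns
#'   `event`, `p_limited`, `p_advanced`, `unit_cost`); default empty.
#' @return A list of class `bl_config` with components `econ`, `diag`,
#'   `stages`, `weights`, `costs`, `survival`, `life_table`, `run`,
#'   `uncertainty`.
#' @export
#' @examples
#' cfg <- bl_default_config()
#' cfg$diag$nnt
#' validate_config(cfg)
bl_default_config <- function(life_table = NULL, ae_table = NULL) {
  if (is.null(life_table)) life_table <- bl_packaged_life_table()
  if (is.null(ae_table)) ae_table <- make_ae_stub("zero")
  cfg <- list(
    econ = list(
      annual_discount_rate = 0.05,
      overhead_rate = 0.20,
      exchange_rate = 2595,          # TZS per USD
      thresholds_usd = c(gdp3 = 3633, gdp1 = 1211, opp_cost = 411),
      psa_iterations = 1000L,
      psa_seed = 20260221L
    ),
    diag = list(
      fn_prob_pathology = 0.221,
      fn_prob_liquid = 0.187,
      nnt = 4L,
      pathology_unit_cost = 413933,
      # Liquid-biopsy cost per sample by annual sequencing throughput.
      # The 900-samples/year value comes from the published microcosting;
      # lower-throughput tiers are derived defaults reflecting reduced
      # economies of scale (see the methods vignette for the derivation).
      liquid_unit_cost_by_tier = data.frame(
        samples_per_year = c(180, 300, 720, 900),
        unit_cost = c(2161219, 1558645, 1437379, 1308450)
      ),
      throughput_samples_per_year = 900,
      availability = 1.0,
      annual_incident_cases = 171L
    ),
    stages = list(
      p_limited_pathology = 0.396,
      p_limited_liquid = 0.600
    ),
    weights = list(
      active_disease = par_ms(0.288, 0.0526),
      terminal_disease = par_ms(0.540, 0.0105),
      post_treatment = par_ms(0.049, 0.0791)
    ),
    costs = list(
      chemo_drug = list(
        limited = par_ms(2777813, 361404),
        advanced = par_ms(2146124, 300775)
      ),
      chemo_nondrug = list(
        limited = par_ms(1598578, 96678),
        advanced = par_ms(1474471, 82376)
      ),
      ae_table = ae_table,
      followup_per_quarter = list(
        year1 = par_ms(87581, 17516),
        year2 = par_ms(23790, 4758),
        years3_5 = par_ms(11895, 2379)
      ),
      end_of_life = par_ms(166380, 41766)
    ),
    survival = list(
      beta0 = par_ms(-2.702, 0.4186),
      beta_advanced = par_ms(0.951, 0.4101),
      gamma = par_ms(0.500, 0.0781),
      time_unit = "months"
    ),
    life_table = life_table,
    run = list(
      cycle_length_months = 3,
      post_cycle_length_months = 3,
      disease_risk_horizon_months = 24,
      treatment_duration_months = 3,
      cohort_entry_age = 10,
      max_age = 100,
      fn_stage = "advanced",          # or "retain": FN patients keep stage mix
      fn_recursive = TRUE,            # liquid FNs re-enter the pathology tree
      background_yld_mode = "all_alive",  # or "post_disease_only"
      yll_discount_form = "continuous",   # or "annuity"
      overhead_on_diagnosis = FALSE
    ),
    # Uncertainty hyper-parameters for proportions whose (mean, se) pairs are
    # not stored elsewhere: se from reported 95% CI / elicited range width
    # divided by 2 * 1.96; low/high are the one-way sensitivity ranges.
    uncertainty = list(
      fn_prob_pathology = list(se = (0.31 - 0.13) / (2 * qnorm(0.975)),
                               low = 0.13, high = 0.31),
      fn_prob_liquid = list(se = (0.22 - 0.08) / (2 * qnorm(0.975)),
                            low = 0.08, high = 0.22),
      p_limited_pathology = list(se = (0.50 - 0.30) / (2 * qnorm(0.975)),
                                 low = 0.30, high = 0.50),
      p_limited_liquid = list(se = (0.80 - 0.40) / (2 * qnorm(0.975)),
                              low = 0.40, high = 0.80),
      discount_rate = list(low = 0.035, high = 0.10),
      overhead_rate = list(low = 0.15, high = 0.25)
    )
  )
  class(cfg) <- "bl_config"
  cfg
}

#' @export
print.bl_config <- function(x, ...) {
  cat("Cost-utility model configuration\n")
  cat(sprintf("  discount rate: %.1f%%/yr, overheads: %.0f%%, exchange rate: %s TZS/USD\n",
              100 * x$econ$annual_discount_rate, 100 * x$econ$overhead_rate,
              format(x$econ$exchange_rate, big.mark = ",")))
  cat(sprintf("  NNT: %d, FN prob (pathology/liquid): %.3f / %.3f\n",
              x$diag$nnt, x$diag$fn_prob_pathology, x$diag$fn_prob_liquid))
  cat(sprintf("  limited-stage proportion (pathology/liquid): %.3f / %.3f\n",
              x$stages$p_limited_pathology, x$stages$p_limited_liquid))
  cat(sprintf("  cycle %g mo, disease-risk window %g mo, entry age %g, cap %g\n",
              x$run$cycle_length_months, x$run$disease_risk_horizon_months,
              x$run$cohort_entry_age, x$run$max_age))
  nviol <- length(validate_config(x))
  cat(sprintf("  validation: %s\n",
              if (nviol == 0) "OK" else paste(nviol, "violation(s)")))
  invisible(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

#' Validate a model configuration
#'
#' Checks every structural invariant of the configuration (probability
#' bounds, non-negative costs and standard errors, positive Weibull shape,
#' cycle/horizon divisibility, life-table ordering) and reports violations.
#'
#' @param cfg a `bl_config` object.
#' @return Character vector of violation messages; empty if the
#'   configuration is valid.
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  add <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)

  e <- cfg$econ
  add(is.numeric(e$annual_discount_rate) && e$annual_discount_rate >= 0 &&
        e$annual_discount_rate < 1,
      "econ.annual_discount_rate: must be in [0, 1)")
  add(is.numeric(e$overhead_rate) && e$overhead_rate >= 0 && e$overhead_rate < 1,
      "econ.overhead_rate: must be in [0, 1)")
  add(is.numeric(e$exchange_rate) && e$exchange_rate > 0,
      "econ.exchange_rate: must be > 0")
  add(is.numeric(e$thresholds_usd) && length(e$thresholds_usd) >= 1 &&
        !is.unsorted(rev(e$thresholds_usd)) || !is.unsorted(e$thresholds_usd),
      "econ.thresholds_usd: must be sorted consistently")
  add(e$psa_iterations >= 1, "econ.psa_iterations: must be >= 1")

  d <- cfg$diag
  add(is_prob(d$fn_prob_pathology), "diag.fn_prob_pathology: must be a probability in [0, 1]")
  add(is_prob(d$fn_prob_liquid), "diag.fn_prob_liquid: must be a probability in [0, 1]")
  add(d$nnt >= 1, "diag.nnt: must be >= 1")
  add(d$pathology_unit_cost >= 0, "diag.pathology_unit_cost: must be >= 0")
  add(all(d$liquid_unit_cost_by_tier$unit_cost >= 0),
      "diag.liquid_unit_cost_by_tier: costs must be >= 0")
  add(all(d$liquid_unit_cost_by_tier$samples_per_year > 0),
      "diag.liquid_unit_cost_by_tier: throughputs must be > 0")
  add(is.numeric(d$availability) && d$availability > 0 && d$availability <= 1,
      "diag.availability: must be in (0, 1]")

  s <- cfg$stages
  add(is_prob(s$p_limited_pathology), "stages.p_limited_pathology: must be in [0, 1]")
  add(is_prob(s$p_limited_liquid), "stages.p_limited_liquid: must be in [0, 1]")

  for (nm in names(cfg$weights)) {
    w <- cfg$weights[[nm]]
    add(is_prob(w$mean), sprintf("weights.%s: weight must be in [0, 1]", nm))
    add(w$se >= 0, sprintf("weights.%s: se must be >= 0", nm))
  }

  co <- cfg$costs
  for (blk in c("chemo_drug", "chemo_nondrug")) {
    for (st in c("limited", "advanced")) {
      p <- co[[blk]][[st]]
      add(p$mean >= 0 && p$se >= 0, sprintf("costs.%s.%s: must be >= 0", blk, st))
    }
  }
  for (nm in names(co$followup_per_quarter)) {
    p <- co$followup_per_quarter[[nm]]
    add(p$mean >= 0 && p$se >= 0, sprintf("costs.followup_per_quarter.%s: must be >= 0", nm))
  }
  add(co$end_of_life$mean >= 0 && co$end_of_life$se >= 0,
      "costs.end_of_life: must be >= 0")
  if (nrow(co$ae_table) > 0) {
    add(all(co$ae_table$p_limited >= 0 & co$ae_table$p_limited <= 1) &&
          all(co$ae_table$p_advanced >= 0 & co$ae_table$p_advanced <= 1),
        "costs.ae_table: probabilities must be in [0, 1]")
    add(all(co$ae_table$unit_cost >= 0), "costs.ae_table: costs must be >= 0")
  }

  sv <- cfg$survival
  add(sv$gamma$mean > 0, "survival.gamma: Weibull shape must be > 0")
  add(all(c(sv$beta0$se, sv$beta_advanced$se, sv$gamma$se) >= 0),
      "survival: standard errors must be >= 0")

  lt <- cfg$life_table
  add(is.data.frame(lt) && all(c("age_start", "q_annual", "disability_weight")
                               %in% names(lt)),
      "life_table: must have columns age_start, q_annual, disability_weight")
  if (is.data.frame(lt) && nrow(lt) > 1) {
    add(all(diff(lt$age_start) > 0), "life_table: age_start must be strictly increasing")
    add(all(lt$q_annual >= 0 & lt$q_annual <= 1),
        "life_table: q_annual must be in [0, 1]")
    add(all(lt$disability_weight >= 0 & lt$disability_weight <= 1),
        "life_table: disability_weight must be in [0, 1]")
  }

  r <- cfg$run
  n_cyc <- r$disease_risk_horizon_months / r$cycle_length_months
  add(abs(n_cyc - round(n_cyc)) < 1e-6 || r$cycle_length_months < 1,
      "run.cycle_length_months: must divide disease_risk_horizon_months evenly")
  add(r$cohort_entry_age < r$max_age, "run.cohort_entry_age: must be < max_age")
  add(r$fn_stage %in% c("advanced", "retain"),
      "run.fn_stage: must be 'advanced' or 'retain'")
  add(r$background_yld_mode %in% c("all_alive", "post_disease_only"),
      "run.background_yld_mode: must be 'all_alive' or 'post_disease_only'")
  add(r$yll_discount_form %in% c("continuous", "annuity"),
      "run.yll_discount_form: must be 'continuous' or 'annuity'")
  v
}

stop_if_invalid <- function(cfg) {
  v <- validate_config(cfg)
  if (length(v) > 0)
    stop("invalid configuration:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  invisible(cfg)
}

# ---- config file I/O -------------------------------------------------------

ms_to_list <- function(p) list(mean = p$mean, se = p$se)

#' Write a model configuration to a YAML file
#'
#' @param cfg a `bl_config` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_bl_config()]
#' @export
write_bl_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$diag$liquid_unit_cost_by_tier <- as.list(cfg$diag$liquid_unit_cost_by_tier)
  y$costs$ae_table <- if (nrow(cfg$costs$ae_table) == 0) NULL
                      else as.list(cfg$costs$ae_table)
  y$life_table <- as.list(cfg$life_table)
  y$econ$thresholds_usd <- as.list(cfg$econ$thresholds_usd)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Read a model configuration from a YAML file
#'
#' Reads the documented nested key-value schema, fills absent optional blocks
#' (`costs.ae_table`, `life_table`, `uncertainty`) with the packaged
#' defaults, and validates every invariant. Unknown top-level or unknown
#' required keys raise schema errors naming the key; out-of-range values
#' raise validation errors listing the violated invariants.
#'
#' @param path path to a YAML configuration file, e.g. the packaged
#'   `system.file("extdata", "basecase.yaml", package = "blcea")`.
#' @return A validated `bl_config` object.
#' @export
read_bl_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  def <- bl_default_config()
  required <- c("econ", "diag", "stages", "weights", "costs", "survival", "run")
  missing <- setdiff(required, names(y))
  if (length(missing) > 0)
    stop("config schema error: missing required block(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  cfg <- def
  optional_keys <- list(costs = "ae_table")
  for (blk in required) {
    for (key in names(y[[blk]])) {
      if (!key %in% names(def[[blk]]))
        stop(sprintf("config schema error: unknown key %s.%s", blk, key),
             call. = FALSE)
      cfg[[blk]][[key]] <- y[[blk]][[key]]
    }
    miss <- setdiff(setdiff(names(def[[blk]]), optional_keys[[blk]]),
                    names(y[[blk]]))
    if (length(miss) > 0)
      stop(sprintf("config schema error: missing key(s) in %s: %s",
                   blk, paste(miss, collapse = ", ")), call. = FALSE)
  }
  cfg$diag$liquid_unit_cost_by_tier <-
    as.data.frame(cfg$diag$liquid_unit_cost_by_tier)
  cfg$econ$thresholds_usd <- unlist(cfg$econ$thresholds_usd)
  cfg$costs$ae_table <- if (length(y$costs$ae_table) == 0) make_ae_stub("zero")
                        else as.data.frame(y$costs$ae_table)
  cfg$life_table <- if (is.null(y$life_table)) bl_packaged_life_table()
                    else as.data.frame(y$life_table)
  if (!is.null(y$uncertainty))
    cfg$uncertainty <- utils::modifyList(def$uncertainty, y$uncertainty)
  class(cfg) <- "bl_config"
  stop_if_invalid(cfg)
  cfg
}

# ---- parameter addressing --------------------------------------------------

#' Set a configuration parameter by dotted path
#'
#' Addresses parameters with dotted paths such as
#' `"econ.annual_discount_rate"` or `"costs.chemo_drug.limited"`. When the
#' addressed node is a `(mean, se)` pair, the mean is set and the standard
#' error preserved.
#'
#' @param cfg a `bl_config` object.
#' @param path dotted parameter path.
#' @param value new (numeric) value.
#' @return The modified configuration.
#' @export
set_param <- function(cfg, path, value) {
  if (path == "diag.liquid_unit_cost") {
    # pseudo-parameter: unit cost at the current throughput tier; scales the
    # whole tier table proportionally so scenario tiers stay consistent
    base <- liquid_unit_cost(cfg$diag)
    cfg$diag$liquid_unit_cost_by_tier$unit_cost <-
      cfg$diag$liquid_unit_cost_by_tier$unit_cost * value / base
    return(cfg)
  }
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (k in keys) {
    if (!k %in% names(node))
      stop("unknown parameter path: ", path, call. = FALSE)
    node <- node[[k]]
  }
  if (is.list(node) && !is.null(node$mean)) keys <- c(keys, "mean")
  cfg[[keys]] <- value
  cfg
}

#' Get a configuration parameter by dotted path
#' @inheritParams set_param
#' @return The parameter value (the mean, for `(mean, se)` nodes).
#' @export
get_param <- function(cfg, path) {
  if (path == "diag.liquid_unit_cost") return(liquid_unit_cost(cfg$diag))
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (k in keys) {
    if (!k %in% names(node))
      stop("unknown parameter path: ", path, call. = FALSE)
    node <- node[[k]]
  }
  if (is.list(node) && !is.null(node$mean)) node$mean else node
}

# Resolve the per-sample liquid-biopsy unit cost at a given annual
# throughput. Exact tier match preferred; otherwise linear interpolation
# between the surrounding tiers, clamped (with a warning) to the nearest
# tier outside the tabulated range.
liquid_unit_cost <- function(diag, samples_per_year = diag$throughput_samples_per_year) {
  tab <- diag$liquid_unit_cost_by_tier
  tab <- tab[order(tab$samples_per_year), ]
  x <- samples_per_year
  if (x <= min(tab$samples_per_year) || x >= max(tab$samples_per_year)) {
    if (x < min(tab$samples_per_year) || x > max(tab$samples_per_year))
      warning("throughput ", x, " outside tabulated tiers; using nearest tier")
    i <- which.min(abs(tab$samples_per_year - x))
    return(tab$unit_cost[i])
  }
  stats::approx(tab$samples_per_year, tab$unit_cost, xout = x)$y
}
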