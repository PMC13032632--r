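# Deterministic (one-way), probabilistic and scenario sensitivity analyses.

# ---- distribution draws (method of moments) --------------------------------

rbeta_ms <- function(n, mean, se) {
  if (se == 0) return(rep(mean, n))
  v <- se^2
  if (v >= mean * (1 - mean))
    stop("beta method-of-moments: se too large for mean ", mean, call. = FALSE)
  k <- mean * (1 - mean) / v - 1
  rbeta(n, mean * k, (1 - mean) * k)
}

rgamma_ms <- function(n, mean, se) {
  if (se == 0) return(rep(mean, n))
  rgamma(n, shape = (mean / se)^2, scale = se^2 / mean)
}

# Beta shape parameters implied by (mean, se); exposed for testing.
beta_shapes <- function(mean, se) {
  k <- mean * (1 - mean) / se^2 - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Returns a copy of the configuration with uncertain parameters replaced
#' by random draws from their assigned distributions: proportions and
#' disability weights from Beta distributions (shape parameters by method
#' of moments from the mean and standard error), costs from Gamma
#' distributions (shape \eqn{(\mu/\sigma)^2}, scale \eqn{\sigma^2/\mu};
#' diagnostic unit costs use a 20% coefficient of variation), and the
#' survival coefficients from independent Normal distributions (the shape
#' is redrawn if non-positive). Structural quantities (NNT, discount rate,
#' overhead rate, exchange rate) are held fixed; any parameter with a zero
#' standard error is held at its mean.
#'
#' Uses the current R random-number state: seed with `set.seed()` or via
#' [run_psa()].
#'
#' @param cfg a `bl_config`.
#' @return A new `bl_config` with drawn parameter values.
#' @export
draw_psa_params <- function(cfg) {
  u <- cfg$uncertainty
  cfg$diag$fn_prob_pathology <- rbeta_ms(1, cfg$diag$fn_prob_pathology,
                                         u$fn_prob_pathology$se)
  cfg$diag$fn_prob_liquid <- rbeta_ms(1, cfg$diag$fn_prob_liquid,
                                      u$fn_prob_liquid$se)
  cfg$stages$p_limited_pathology <- rbeta_ms(1, cfg$stages$p_limited_pathology,
                                             u$p_limited_pathology$se)
  cfg$stages$p_limited_liquid <- rbeta_ms(1, cfg$stages$p_limited_liquid,
                                          u$p_limited_liquid$se)
  for (nm in names(cfg$weights)) {
    w <- cfg$weights[[nm]]
    cfg$weights[[nm]]$mean <- rbeta_ms(1, w$mean, w$se)
  }
  for (nm in c("beta0", "beta_advanced")) {
    p <- cfg$survival[[nm]]
    cfg$survival[[nm]]$mean <- rnorm(1, p$mean, p$se)
  }
  g <- cfg$survival$gamma
  repeat {
    gd <- rnorm(1, g$mean, g$se)
    if (gd > 0) break
  }
  cfg$survival$gamma$mean <- gd

  for (blk in c("chemo_drug", "chemo_nondrug")) {
    for (st in c("limited", "advanced")) {
      p <- cfg$costs[[blk]][[st]]
      cfg$costs[[blk]][[st]]$mean <- rgamma_ms(1, p$mean, p$se)
    }
  }
  for (nm in names(cfg$costs$followup_per_quarter)) {
    p <- cfg$costs$followup_per_quarter[[nm]]
    cfg$costs$followup_per_quarter[[nm]]$mean <- rgamma_ms(1, p$mean, p$se)
  }
  p <- cfg$costs$end_of_life
  cfg$costs$end_of_life$mean <- rgamma_ms(1, p$mean, p$se)

  # diagnostic unit costs: 20% coefficient of variation (Gamma shape 25);
  # the liquid tier table is scaled by one common multiplier
  pc <- cfg$diag$pathology_unit_cost
  cfg$diag$pathology_unit_cost <- rgamma_ms(1, pc, 0.2 * pc)
  mult <- rgamma_ms(1, 1, 0.2)
  cfg$diag$liquid_unit_cost_by_tier$unit_cost <-
    cfg$diag$liquid_unit_cost_by_tier$unit_cost * mult
  cfg
}

# ---- one-way (tornado) analysis --------------------------------------------

#' Default one-way sensitivity ranges
#'
#' Discount and overhead rates use their configured alternative values;
#' false-negative probabilities and the presenting stage mix use their
#' reported confidence intervals; cost inputs, disability weights and
#' survival coefficients vary by +/-20% of the mean. The stage mix at the
#' earlier liquid-biopsy diagnosis is not varied here: it is an assumption
#' examined by the dedicated [stage_shift_sweep()] scenario (and the PSA),
#' not a sampled quantity.
#'
#' @param cfg a `bl_config`.
#' @return Named list of `c(low, high)` ranges keyed by parameter path.
#' @export
default_oneway_grid <- function(cfg) {
  u <- cfg$uncertainty
  pm20 <- function(x) c(0.8, 1.2) * x
  list(
    "econ.annual_discount_rate" = c(u$discount_rate$low, u$discount_rate$high),
    "econ.overhead_rate" = c(u$overhead_rate$low, u$overhead_rate$high),
    "diag.fn_prob_pathology" = c(u$fn_prob_pathology$low, u$fn_prob_pathology$high),
    "diag.fn_prob_liquid" = c(u$fn_prob_liquid$low, u$fn_prob_liquid$high),
    "stages.p_limited_pathology" = c(u$p_limited_pathology$low,
                                     u$p_limited_pathology$high),
    "diag.pathology_unit_cost" = pm20(cfg$diag$pathology_unit_cost),
    "diag.liquid_unit_cost" = pm20(liquid_unit_cost(cfg$diag)),
    "costs.chemo_drug.limited" = pm20(cfg$costs$chemo_drug$limited$mean),
    "costs.chemo_drug.advanced" = pm20(cfg$costs$chemo_drug$advanced$mean),
    "costs.chemo_nondrug.limited" = pm20(cfg$costs$chemo_nondrug$limited$mean),
    "costs.chemo_nondrug.advanced" = pm20(cfg$costs$chemo_nondrug$advanced$mean),
    "costs.followup_per_quarter.year1" = pm20(cfg$costs$followup_per_quarter$year1$mean),
    "costs.end_of_life" = pm20(cfg$costs$end_of_life$mean),
    "weights.active_disease" = pmin(pm20(cfg$weights$active_disease$mean), 1),
    "weights.post_treatment" = pmin(pm20(cfg$weights$post_treatment$mean), 1),
    "weights.terminal_disease" = pmin(pm20(cfg$weights$terminal_disease$mean), 1),
    "survival.beta0" = pm20(cfg$survival$beta0$mean),
    "survival.beta_advanced" = pm20(cfg$survival$beta_advanced$mean),
    "survival.gamma" = pm20(cfg$survival$gamma$mean)
  )
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the ICER with each parameter at its low and high value, all
#' others held at base case, and sorts parameters by the width of the
#' resulting ICER span.
#'
#' @param cfg a `bl_config`.
#' @param grid named list of `c(low, high)` ranges keyed by dotted
#'   parameter path; default [default_oneway_grid()].
#' @return Object of class `bl_tornado`: data.frame with `parameter`,
#'   `low`, `high`, `icer_usd_low`, `icer_usd_high`, `span_usd`, sorted by
#'   decreasing span; the base-case ICER is in `attr(, "icer_usd_base")`.
#' @export
one_way_sa <- function(cfg, grid = default_oneway_grid(cfg)) {
  base <- evaluate_cea(cfg)
  rows <- lapply(names(grid), function(path) {
    rng <- grid[[path]]
    # validates the path (errors list valid names for typos)
    get_param(cfg, path)
    icers <- vapply(rng, function(v)
      evaluate_cea(set_param(cfg, path, v))$icer_usd, numeric(1))
    data.frame(parameter = path, low = rng[1], high = rng[2],
               icer_usd_low = icers[1], icer_usd_high = icers[2],
               span_usd = abs(diff(icers)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span_usd), ]
  rownames(out) <- NULL
  attr(out, "icer_usd_base") <- base$icer_usd
  class(out) <- c("bl_tornado", "data.frame")
  out
}

#' @export
print.bl_tornado <- function(x, ...) {
  cat(sprintf("One-way sensitivity analysis (base ICER $%.0f/DALY averted)\n\n",
              attr(x, "icer_usd_base")))
  y <- as.data.frame(x)
  y$icer_usd_low <- round(y$icer_usd_low)
  y$icer_usd_high <- round(y$icer_usd_high)
  y$span_usd <- round(y$span_usd)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
plot.bl_tornado <- function(x, ...) {
  y <- x[order(x$span_usd), ]
  base <- attr(x, "icer_usd_base")
  lo <- pmin(y$icer_usd_low, y$icer_usd_high)
  hi <- pmax(y$icer_usd_low, y$icer_usd_high)
  n <- nrow(y)
  graphics::plot(NULL, xlim = range(lo, hi, base), ylim = c(0.5, n + 0.5),
                 yaxt = "n", xlab = "ICER ($ per DALY averted)", ylab = "",
                 main = "Tornado diagram", ...)
  graphics::axis(2, at = seq_len(n), labels = y$parameter, las = 1, cex.axis = 0.6)
  graphics::segments(lo, seq_len(n), hi, seq_len(n), lwd = 8, col = "steelblue")
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

# ---- probabilistic sensitivity analysis ------------------------------------

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: per iteration, draws a
#' parameter set ([draw_psa_params()]), evaluates both arms, and records
#' the paired incremental cost and DALYs averted. Confidence intervals are
#' percentile-based (2.5th/97.5th of the simulation distribution). A rare
#' failed iteration (e.g. a degenerate survival draw) is resampled and
#' counted. Results are reproducible under a fixed seed.
#'
#' @param cfg a `bl_config`.
#' @param iterations number of Monte-Carlo iterations; default
#'   `cfg$econ$psa_iterations`.
#' @param seed RNG seed; default `cfg$econ$psa_seed`.
#' @return Object of class `bl_psa`: `draws` (data.frame with per-iteration
#'   arm costs/DALYs, `delta_cost_tzs`, `delta_cost_usd`,
#'   `delta_dalys_averted`), `ci` (percentile CIs), `seed`, `iterations`,
#'   `n_resampled`, `exchange_rate`.
#' @export
run_psa <- function(cfg, iterations = cfg$econ$psa_iterations,
                    seed = cfg$econ$psa_seed) {
  stop_if_invalid(cfg)
  set.seed(seed)
  n_resampled <- 0L
  rows <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    repeat {
      res <- tryCatch({
        cfg_i <- draw_psa_params(cfg)
        p <- evaluate_arm("pathology", cfg_i)
        l <- evaluate_arm("liquid", cfg_i)
        data.frame(iteration = i,
                   cost_pathology = p$cost_tzs, cost_liquid = l$cost_tzs,
                   dalys_pathology = p$dalys, dalys_liquid = l$dalys)
      }, error = function(e) NULL)
      if (!is.null(res)) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > iterations)
        stop("PSA: too many failed iterations", call. = FALSE)
    }
    rows[[i]] <- res
  }
  draws <- do.call(rbind, rows)
  draws$delta_cost_tzs <- draws$cost_liquid - draws$cost_pathology
  draws$delta_cost_usd <- draws$delta_cost_tzs / cfg$econ$exchange_rate
  draws$delta_dalys_averted <- draws$dalys_pathology - draws$dalys_liquid
  ci <- list(
    delta_cost_usd = quantile(draws$delta_cost_usd, c(0.025, 0.975), names = FALSE),
    delta_cost_tzs = quantile(draws$delta_cost_tzs, c(0.025, 0.975), names = FALSE),
    delta_dalys_averted = quantile(draws$delta_dalys_averted, c(0.025, 0.975),
                                   names = FALSE)
  )
  out <- list(draws = draws, ci = ci, seed = seed, iterations = iterations,
              n_resampled = n_resampled, exchange_rate = cfg$econ$exchange_rate,
              thresholds_usd = cfg$econ$thresholds_usd)
  class(out) <- "bl_psa"
  out
}

#' @export
print.bl_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %s)\n",
              x$iterations, format(x$seed)))
  cat(sprintf("  incremental cost 95%% CI:  $%.0f to $%.0f\n",
              x$ci$delta_cost_usd[1], x$ci$delta_cost_usd[2]))
  cat(sprintf("  DALYs averted 95%% CI:     %.2f to %.2f\n",
              x$ci$delta_dalys_averted[1], x$ci$delta_dalys_averted[2]))
  cr <- ceac_crossing(ceac(x))
  if (is.na(cr)) cat("  CEAC never crosses 0.5 on the default grid\n")
  else cat(sprintf("  CEAC crosses 0.5 at:      $%.0f per DALY averted\n", cr))
  invisible(x)
}

#' @export
plot.bl_psa <- function(x, ...) {
  graphics::plot(x$draws$delta_dalys_averted, x$draws$delta_cost_usd,
                 pch = 16, cex = 0.4, col = grDevices::adjustcolor("navy", 0.4),
                 xlab = "DALYs averted", ylab = "Incremental cost ($)",
                 main = "Cost-effectiveness plane", ...)
  for (lam in x$thresholds_usd) graphics::abline(0, lam, lty = 3)
  graphics::abline(h = 0, v = 0, col = "grey")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA iterations in
#' which liquid biopsy has positive net monetary benefit
#' (\eqn{\lambda \Delta E - \Delta C > 0}).
#'
#' @param psa a `bl_psa`.
#' @param lambda_usd grid of thresholds in USD per DALY averted;
#'   default $0 to $5000 in $10 steps.
#' @return data.frame with `lambda_usd` and `prob_liquid` of class
#'   `bl_ceac`.
#' @export
ceac <- function(psa, lambda_usd = seq(0, 5000, by = 10)) {
  de <- psa$draws$delta_dalys_averted
  dc <- psa$draws$delta_cost_usd
  prob <- vapply(lambda_usd, function(l) mean(l * de - dc > 0), numeric(1))
  structure(data.frame(lambda_usd = lambda_usd, prob_liquid = prob),
            class = c("bl_ceac", "data.frame"))
}

#' Threshold at which the acceptability curve crosses 0.5
#'
#' @param curve a [ceac()] result.
#' @return Smallest threshold with acceptability probability above 0.5, or
#'   `NA` (with a message) if the curve never crosses.
#' @export
ceac_crossing <- function(curve) {
  i <- which(curve$prob_liquid > 0.5)
  if (length(i) == 0) {
    message("CEAC never exceeds 0.5 on the supplied threshold grid")
    return(NA_real_)
  }
  curve$lambda_usd[min(i)]
}

#' @export
plot.bl_ceac <- function(x, ...) {
  graphics::plot(x$lambda_usd, x$prob_liquid, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay ($ per DALY averted)",
                 ylab = "P(liquid biopsy cost-effective)",
                 main = "Cost-effectiveness acceptability curve", ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey")
  invisible(x)
}

# ---- scenario analyses -----------------------------------------------------

#' Scenario analyses
#'
#' Re-runs the incremental analysis under the structural scenarios:
#' \describe{
#'   \item{`nnt`}{number-needed-to-test multiplier `value` in 2..6; NNT of
#'     2 or 3 uses the (higher) 300-samples/year liquid unit cost tier.}
#'   \item{`availability`}{fraction `value` of incident cases with access
#'     to liquid biopsy; costs and outcomes are the availability-weighted
#'     mix of the two arms, with the liquid unit cost adjusted to the
#'     reduced annual throughput.}
#'   \item{`extended_risk`}{disease-risk window extended to `value` months
#'     (36/48/60); added deaths carry terminal weight and end-of-life cost.}
#'   \item{`fn_retain_stage`}{false negatives retain the presenting stage
#'     mix instead of being assigned advanced-stage prognosis.}
#'   \item{`cycle_length`}{cycle shortened to `value` months over the
#'     disease-risk window (default one week, 12 * 7/365.25 months).}
#'   \item{`stage_shift`}{proportion of limited-stage patients at the
#'     earlier liquid-biopsy diagnosis set to `value`.}
#'   \item{`rituximab_free`, `tanzania_only`}{hooks accepting re-estimated
#'     `survival_params` (same `(mean, se)` layout as `cfg$survival`) and
#'     optional `overrides` (named list of dotted parameter paths), for
#'     subgroup or treatment-variant analyses whose coefficients are
#'     supplied by the user.}
#' }
#'
#' @param cfg a `bl_config`.
#' @param kind scenario kind (see Details).
#' @param value scenario-specific numeric setting.
#' @param survival_params replacement survival parameters (hook scenarios).
#' @param overrides named list of parameter overrides (hook scenarios).
#' @return A `bl_cea` with attribute `scenario` describing the settings.
#' @export
#' @examples
#' cfg <- bl_default_config()
#' run_scenario(cfg, "nnt", 2)
run_scenario <- function(cfg, kind = c("nnt", "availability", "extended_risk",
                                       "fn_retain_stage", "cycle_length",
                                       "stage_shift", "rituximab_free",
                                       "tanzania_only"),
                         value = NULL, survival_params = NULL,
                         overrides = NULL) {
  kind <- match.arg(kind)
  res <- switch(kind,
    nnt = {
      stopifnot(is.numeric(value), value >= 1)
      cfg$diag$nnt <- as.integer(value)
      cfg$diag$throughput_samples_per_year <- if (value <= 3) 300 else 900
      evaluate_cea(cfg)
    },
    availability = {
      stopifnot(is.numeric(value), value > 0, value <= 1)
      a <- value
      cfg$diag$availability <- a
      cfg$diag$throughput_samples_per_year <- 900 * a
      pathology <- evaluate_arm("pathology", cfg)
      liquid <- evaluate_arm("liquid", cfg)
      mixed <- liquid
      mixed$arm <- sprintf("liquid (%.0f%% availability)", 100 * a)
      mixed$cost_tzs <- a * liquid$cost_tzs + (1 - a) * pathology$cost_tzs
      mixed$dalys <- a * liquid$dalys + (1 - a) * pathology$dalys
      mixed$cost_components <- a * liquid$cost_components +
        (1 - a) * pathology$cost_components
      mixed$daly_components <- a * liquid$daly_components +
        (1 - a) * pathology$daly_components
      compute_icer(pathology, mixed, cfg$econ)
    },
    extended_risk = {
      stopifnot(is.numeric(value), value >= cfg$run$disease_risk_horizon_months)
      cfg$run$disease_risk_horizon_months <- value
      evaluate_cea(cfg)
    },
    fn_retain_stage = {
      cfg$run$fn_stage <- "retain"
      evaluate_cea(cfg)
    },
    cycle_length = {
      if (is.null(value)) value <- 12 * 7 / 365.25  # one week in months
      cfg$run$cycle_length_months <- value
      evaluate_cea(cfg)
    },
    stage_shift = {
      stopifnot(is.numeric(value), value >= 0, value <= 1)
      cfg$stages$p_limited_liquid <- value
      evaluate_cea(cfg)
    },
    rituximab_free = ,
    tanzania_only = {
      if (is.null(survival_params))
        stop(kind, " scenario requires re-estimated survival_params",
             call. = FALSE)
      cfg$survival <- utils::modifyList(cfg$survival, survival_params)
      if (!is.null(overrides))
        for (p in names(overrides)) cfg <- set_param(cfg, p, overrides[[p]])
      evaluate_cea(cfg)
    }
  )
  attr(res, "scenario") <- list(kind = kind, value = value)
  res
}

#' Sweep of the stage-shift assumption
#'
#' Varies the proportion of limited-stage patients at the earlier
#' liquid-biopsy diagnosis and reports the ICER at each value.
#'
#' @param cfg a `bl_config`.
#' @param p_grid proportions to evaluate (default 0.40 to 0.80 in 0.05 steps).
#' @return data.frame with `p_limited_liquid`, `icer_tzs`, `icer_usd`,
#'   `delta_dalys_averted`.
#' @export
stage_shift_sweep <- function(cfg, p_grid = seq(0.40, 0.80, by = 0.05)) {
  rows <- lapply(p_grid, function(p) {
    r <- run_scenario(cfg, "stage_shift", p)
    data.frame(p_limited_liquid = p, icer_tzs = r$icer_tzs,
               icer_usd = r$icer_usd,
               delta_dalys_averted = r$delta_dalys_averted)
  })
  do.call(rbind, rows)
}
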