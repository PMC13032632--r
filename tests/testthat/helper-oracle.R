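# Independent brute-force re-derivation of the whole model as a per-cycle
# scalar loop over explicitly enumerated branches. Shares only the survival
# and life-expectancy primitives with the package; all cohort propagation,
# cost and DALY accounting is re-done with plain accumulators, so agreement
# with the vectorised engine checks the engine, not the formulas alone.

oracle_lt_lookup <- function(lt, age, col) {
  i <- 1L
  for (k in seq_len(nrow(lt))) if (lt$age_start[k] <= age) i <- k
  lt[[col]][i]
}

oracle_branches <- function(arm, cfg) {
  d <- cfg$diag
  s <- cfg$stages
  retain <- identical(cfg$run$fn_stage, "retain")
  lbc <- d$nnt * get_param(cfg, "diag.liquid_unit_cost")
  pc <- d$pathology_unit_cost
  path_br <- function(dc) {
    fn <- d$fn_prob_pathology
    out <- list(
      list(w = (1 - fn) * s$p_limited_pathology, stage = "limited", diag = dc),
      list(w = (1 - fn) * (1 - s$p_limited_pathology), stage = "advanced", diag = dc)
    )
    if (retain) {
      c(out, list(
        list(w = fn * s$p_limited_pathology, stage = "limited", diag = dc),
        list(w = fn * (1 - s$p_limited_pathology), stage = "advanced", diag = dc)))
    } else {
      c(out, list(list(w = fn, stage = "advanced", diag = dc)))
    }
  }
  if (arm == "pathology") return(path_br(pc))
  fn <- d$fn_prob_liquid
  tp <- list(
    list(w = (1 - fn) * s$p_limited_liquid, stage = "limited", diag = lbc),
    list(w = (1 - fn) * (1 - s$p_limited_liquid), stage = "advanced", diag = lbc)
  )
  sub <- if (isTRUE(cfg$run$fn_recursive)) {
    path_br(lbc + pc)
  } else {
    list(list(w = s$p_limited_pathology, stage = "limited", diag = lbc + pc),
         list(w = 1 - s$p_limited_pathology, stage = "advanced", diag = lbc + pc))
  }
  sub <- lapply(sub, function(b) { b$w <- fn * b$w; b })
  c(tp, sub)
}

# returns list(cost_tzs, dalys) for one arm
oracle_arm <- function(arm, cfg) {
  run <- cfg$run
  r <- cfg$econ$annual_discount_rate
  lt <- cfg$life_table
  horizon <- run$disease_risk_horizon_months
  total_months <- (run$max_age - run$cohort_entry_age) * 12
  fu <- cfg$costs$followup_per_quarter
  w <- cfg$weights
  cost_sum <- 0
  daly_sum <- 0
  for (b in oracle_branches(arm, cfg)) {
    tc <- treatment_cost(b$stage, cfg$costs)
    alive <- 1
    t0 <- 0
    first <- TRUE
    trt <- ae <- fuc <- eol <- yll <- yld <- 0
    while (t0 < total_months - 1e-9) {
      in_win <- t0 < horizon - 1e-9
      len <- if (in_win) min(run$cycle_length_months, horizon - t0)
             else run$post_cycle_length_months
      t1 <- t0 + len
      age0 <- run$cohort_entry_age + t0 / 12
      age_mid <- run$cohort_entry_age + (t0 + t1) / 24
      q <- if (in_win) {
        1 - survival_at(t1, b$stage, cfg$survival) /
          survival_at(t0, b$stage, cfg$survival)
      } else {
        1 - (1 - oracle_lt_lookup(lt, age0, "q_annual"))^(len / 12)
      }
      deaths <- alive * q
      alive1 <- alive - deaths
      eff <- (alive + alive1) / 2
      df <- (1 + r)^(-(t0 + t1) / 24)
      cyc_years <- len / 12
      w_state <- if (t0 < run$treatment_duration_months - 1e-9) w$active_disease$mean
                 else if (in_win) w$post_treatment$mean else 0
      yld <- yld + eff * cyc_years * w_state * df
      bg_ok <- if (identical(run$background_yld_mode, "post_disease_only")) !in_win else TRUE
      if (bg_ok)
        yld <- yld + eff * cyc_years *
          oracle_lt_lookup(lt, age_mid, "disability_weight") * df
      yll_unit <- discounted_yll(age_mid, r, lt, run$max_age,
                                 form = run$yll_discount_form)
      if (in_win) {
        yld <- yld + deaths * w$terminal_disease$mean * cyc_years * df
        yll <- yll + deaths * yll_unit * df
        eol <- eol + deaths * cfg$costs$end_of_life$mean * df
      } else {
        yll <- yll + deaths * yll_unit * df
      }
      rate <- if (t0 < 12) fu$year1$mean else if (t0 < 24) fu$year2$mean
              else if (t0 < 60) fu$years3_5$mean else 0
      fuc <- fuc + rate * (len / 3) * eff * df
      if (first) {
        trt <- tc$treatment * alive * df
        ae <- tc$adverse_events * alive * df
        first <- FALSE
      }
      alive <- alive1
      t0 <- t1
    }
    oh_base <- trt + ae + fuc + eol
    if (isTRUE(run$overhead_on_diagnosis)) oh_base <- oh_base + b$diag
    total_cost <- b$diag + trt + ae + fuc + eol +
      cfg$econ$overhead_rate * oh_base
    cost_sum <- cost_sum + b$w * total_cost
    daly_sum <- daly_sum + b$w * (yll + yld)
  }
  list(cost_tzs = cost_sum, dalys = daly_sum)
}
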