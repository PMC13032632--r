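cfg <- bl_default_config()

test_that("ICER arithmetic, dominance and sentinels behave", {
  ref <- structure(list(arm = "pathology", cost_tzs = 0, dalys = 10),
                   class = "bl_arm")
  cmp <- structure(list(arm = "liquid", cost_tzs = 100, dalys = 8),
                   class = "bl_arm")
  econ <- cfg$econ
  r <- compute_icer(ref, cmp, econ)
  expect_equal(r$delta_cost_tzs, 100)
  expect_equal(r$delta_dalys_averted, 2)
  expect_equal(r$icer_tzs, 50)
  expect_equal(r$icer_usd, 50 / 2595)
  expect_equal(r$dominance, "none")
  # net benefit is linear in the threshold
  nb <- r$net_benefit$nmb_usd
  lam <- r$net_benefit$threshold_usd
  expect_equal(nb, lam * 2 - 100 / 2595, tolerance = 1e-12)

  cmp$cost_tzs <- -1
  expect_equal(compute_icer(ref, cmp, econ)$dominance, "comparator_dominates")
  cmp$cost_tzs <- 100
  cmp$dalys <- 10
  expect_true(is.infinite(compute_icer(ref, cmp, econ)$icer_tzs))
})

test_that("arm evaluation is deterministic and currency-consistent", {
  a1 <- evaluate_arm("liquid", cfg)
  a2 <- evaluate_arm("liquid", cfg)
  expect_identical(a1, a2)
  res <- evaluate_cea(cfg)
  expect_equal(res$icer_usd, res$icer_tzs / cfg$econ$exchange_rate)
  expect_equal(res$delta_cost_usd, res$delta_cost_tzs / 2595)
})

test_that("scalar-loop oracle reproduces the vectorised engine", {
  for (arm in c("pathology", "liquid")) {
    eng <- evaluate_arm(arm, cfg)
    ora <- oracle_arm(arm, cfg)
    expect_equal(eng$cost_tzs, ora$cost_tzs, tolerance = 1e-9)
    expect_equal(eng$dalys, ora$dalys, tolerance = 1e-9)
  }
  # and under a structurally different configuration
  cfg2 <- cfg
  cfg2$run$fn_stage <- "retain"
  cfg2$econ$annual_discount_rate <- 0.035
  cfg2$costs$ae_table <- make_ae_stub("nominal")
  for (arm in c("pathology", "liquid")) {
    eng <- evaluate_arm(arm, cfg2)
    ora <- oracle_arm(arm, cfg2)
    expect_equal(eng$cost_tzs, ora$cost_tzs, tolerance = 1e-9)
    expect_equal(eng$dalys, ora$dalys, tolerance = 1e-9)
  }
})

test_that("one-way analysis orders spans and respects known directions", {
  grid <- list(
    "econ.annual_discount_rate" = c(0.035, 0.10),
    "diag.liquid_unit_cost" = c(0.8, 1.2) * 1308450,
    "weights.post_treatment" = c(0.049, 0.049)   # zero-width range
  )
  tor <- one_way_sa(cfg, grid)
  expect_s3_class(tor, "bl_tornado")
  expect_equal(tor$span_usd[nrow(tor)], 0)       # zero-width range -> span 0
  expect_true(all(diff(tor$span_usd) <= 0))      # sorted by span
  dr <- tor[tor$parameter == "econ.annual_discount_rate", ]
  expect_gt(dr$icer_usd_high, dr$icer_usd_low)   # less future benefit at 10%
  expect_error(one_way_sa(cfg, list("no.such.param" = c(0, 1))),
               "unknown parameter")
})

test_that("no default one-way range pushes the ICER above 3xGDP", {
  tor <- one_way_sa(cfg)
  expect_lt(max(tor$icer_usd_low, tor$icer_usd_high), 3633)
})

test_that("method-of-moments hyperparameters match algebra", {
  expect_equal(unname(blcea:::beta_shapes(0.288, 0.0526)),
               c(21.06, 52.06), tolerance = 1e-3)
  # gamma with se = 20% of mean has shape 25 whatever the mean
  expect_equal((1 / 0.2)^2, 25)
  set.seed(1)
  draws <- replicate(2000, blcea:::rgamma_ms(1, 1e6, 2e5))
  expect_equal(mean(draws), 1e6, tolerance = 0.02)
  expect_equal(stats::sd(draws), 2e5, tolerance = 0.06)
  # zero se holds the parameter fixed
  expect_equal(blcea:::rbeta_ms(5, 0.3, 0), rep(0.3, 5))
  expect_equal(blcea:::rgamma_ms(5, 10, 0), rep(10, 5))
})

test_that("PSA draws vary uncertain parameters and are seed-reproducible", {
  set.seed(99)
  d1 <- draw_psa_params(cfg)
  set.seed(99)
  d2 <- draw_psa_params(cfg)
  expect_identical(d1, d2)
  expect_false(d1$diag$fn_prob_pathology == cfg$diag$fn_prob_pathology)
  expect_false(d1$weights$active_disease$mean == cfg$weights$active_disease$mean)
  expect_false(d1$survival$beta0$mean == cfg$survival$beta0$mean)
  # structural quantities held fixed
  expect_identical(d1$diag$nnt, cfg$diag$nnt)
  expect_identical(d1$econ$annual_discount_rate, cfg$econ$annual_discount_rate)
  expect_identical(d1$econ$overhead_rate, cfg$econ$overhead_rate)
  expect_true(d1$survival$gamma$mean > 0)
  expect_length(validate_config(d1), 0)
})

test_that("a small PSA is bit-reproducible and summarised by percentiles", {
  p1 <- run_psa(cfg, iterations = 25, seed = 5)
  p2 <- run_psa(cfg, iterations = 25, seed = 5)
  expect_identical(p1$draws, p2$draws)
  expect_equal(nrow(p1$draws), 25)
  expect_equal(p1$ci$delta_dalys_averted,
               unname(quantile(p1$draws$delta_dalys_averted, c(0.025, 0.975))))
  expect_lt(p1$ci$delta_cost_usd[1], p1$ci$delta_cost_usd[2])
})

test_that("CEAC limits and monotonicity follow the draw signs", {
  psa <- list(draws = data.frame(
    delta_dalys_averted = c(1, 2, 0.5, 1.5),
    delta_cost_usd = c(-10, 500, 800, 2000)
  ))
  class(psa) <- "bl_psa"
  curve <- ceac(psa, lambda_usd = seq(0, 4000, by = 100))
  expect_equal(curve$prob_liquid[1], 0.25)      # lambda = 0: cost-saving share
  expect_equal(curve$prob_liquid[nrow(curve)], 1)  # all deltaE > 0
  expect_true(all(diff(curve$prob_liquid) >= 0))
  # 3 of 4 iterations have positive net benefit once lambda > 2000/1.5
  expect_equal(ceac_crossing(curve), 1400)
  flat <- ceac(psa, lambda_usd = 0)
  expect_message(expect_true(is.na(ceac_crossing(flat))), "never")
})

test_that("scenario machinery matches its defining arithmetic", {
  base <- evaluate_cea(cfg)
  # nnt = 4 with base tier reproduces the base case
  s4 <- run_scenario(cfg, "nnt", 4)
  expect_equal(s4$icer_usd, base$icer_usd, tolerance = 1e-12)
  # nnt 2 and 3 use the 300-samples/year tier
  s2 <- run_scenario(cfg, "nnt", 2)
  expect_equal(s2$comparator$cost_components[["diagnosis"]] -
                 base$comparator$cost_components[["diagnosis"]],
               2 * 1558645 - 4 * 1308450, tolerance = 1e-6)
  # availability: outcomes are the stated weighted mix
  a <- 0.2
  sa <- run_scenario(cfg, "availability", a)
  cfg_a <- cfg
  cfg_a$diag$throughput_samples_per_year <- 900 * a
  liq_a <- evaluate_arm("liquid", cfg_a)
  expect_equal(sa$comparator$dalys,
               a * liq_a$dalys + (1 - a) * base$reference$dalys,
               tolerance = 1e-12)
  expect_equal(sa$comparator$cost_tzs,
               a * liq_a$cost_tzs + (1 - a) * base$reference$cost_tzs,
               tolerance = 1e-9)
  # FN staging assumption and extended risk move the ICER as expected
  expect_gt(run_scenario(cfg, "fn_retain_stage")$icer_usd, base$icer_usd)
  expect_lt(run_scenario(cfg, "extended_risk", 36)$icer_usd, base$icer_usd)
  # stage shift sweep is monotone: more stage shift, lower ICER
  sw <- stage_shift_sweep(cfg, c(0.45, 0.60, 0.75))
  expect_true(all(diff(sw$icer_usd) < 0))
  expect_equal(sw$icer_usd[2], base$icer_usd, tolerance = 1e-12)
  # hooks demand re-estimated survival parameters
  expect_error(run_scenario(cfg, "rituximab_free"), "survival_params")
  alt <- cfg$survival
  alt$beta_advanced$mean <- 0.8
  sr <- run_scenario(cfg, "rituximab_free", survival_params = alt,
                     overrides = list("costs.chemo_drug.limited" = 2.5e6))
  expect_s3_class(sr, "bl_cea")
})

test_that("1-week cycles leave the ICER nearly unchanged", {
  base <- evaluate_cea(cfg)
  wk <- run_scenario(cfg, "cycle_length")
  expect_lt(abs(wk$icer_usd - base$icer_usd) / base$icer_usd, 0.05)
})
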