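cfg <- bl_default_config()

test_that("decision trees carry the expected branch weights", {
  tp <- build_decision_tree("pathology", cfg)
  expect_equal(sum(tp$weight), 1)
  expect_equal(tp$weight, c((1 - 0.221) * 0.396, (1 - 0.221) * 0.604, 0.221),
               tolerance = 1e-12)
  expect_equal(tp$stage, c("limited", "advanced", "advanced"))
  expect_true(all(tp$diag_cost == 413933))

  tl <- build_decision_tree("liquid", cfg)
  expect_equal(sum(tl$weight), 1)
  expect_equal(tl$weight[1:2], c((1 - 0.187) * 0.6, (1 - 0.187) * 0.4),
               tolerance = 1e-12)
  fn <- grepl("^liquid_fn", tl$label)
  expect_equal(sum(tl$weight[fn]), 0.187, tolerance = 1e-12)
  # recursive mode: doubly-missed mass fn_l * fn_p at advanced stage
  expect_equal(tl$weight[tl$label == "liquid_fn_fn_advanced"], 0.187 * 0.221,
               tolerance = 1e-12)
  # liquid FN branches pay both diagnostics
  expect_true(all(tl$diag_cost[fn] == 4 * 1308450 + 413933))
  expect_true(all(tl$diag_cost[!fn] == 4 * 1308450))
})

test_that("zero FN probabilities collapse each arm to its stage mix", {
  cfg0 <- cfg
  cfg0$diag$fn_prob_pathology <- 0
  cfg0$diag$fn_prob_liquid <- 0
  tp <- build_decision_tree("pathology", cfg0)
  expect_equal(nrow(tp), 2)
  expect_equal(tp$weight, c(0.396, 0.604))
  tl <- build_decision_tree("liquid", cfg0)
  expect_equal(nrow(tl), 2)
  expect_equal(tl$weight, c(0.6, 0.4))
})

test_that("FN-retain-stage and non-recursive modes reshape the tree", {
  cfgr <- cfg
  cfgr$run$fn_stage <- "retain"
  tp <- build_decision_tree("pathology", cfgr)
  expect_equal(nrow(tp), 4)
  expect_equal(sum(tp$weight[tp$stage == "limited"]), 0.396, tolerance = 1e-12)

  cfgn <- cfg
  cfgn$run$fn_recursive <- FALSE
  tl <- build_decision_tree("liquid", cfgn)
  fn <- grepl("^liquid_fn", tl$label)
  expect_equal(sum(fn), 2)
  expect_equal(sum(tl$weight[fn & tl$stage == "limited"]), 0.187 * 0.396,
               tolerance = 1e-12)
})

test_that("Markov trace reproduces the survival curve and conserves mass", {
  tr <- run_markov_branch("advanced", cfg)
  # start of cycle 9 = month 24: live occupancy equals S(24 | advanced)
  expect_equal(tr$t_start[9], 24)
  expect_equal(tr$alive_start[9], survival_at(24, "advanced", cfg$survival),
               tolerance = 1e-12)
  # conservation: alive + cumulative deaths = 1 at every cycle
  cum_dead <- cumsum(tr$d_disease + tr$d_background)
  expect_lt(max(abs(tr$alive_end + cum_dead - 1)), 1e-12)
  expect_true(all(diff(1 - tr$alive_start) >= 0))   # dead mass non-decreasing
  # first cycle on treatment, window cycles post-treatment, then post-disease
  expect_equal(tr$state[1], "on_treatment")
  expect_true(all(tr$state[2:8] == "post_treatment"))
  expect_true(all(tr$state[9:length(tr$state)] == "post_disease"))
  # no background deaths inside the window, none from disease after it
  expect_true(all(tr$d_background[1:8] == 0))
  expect_true(all(tr$d_disease[-(1:8)] == 0))
})

test_that("zero-hazard cohort stays fully alive to the horizon cap", {
  tr <- run_markov_branch("limited", immortal_config())
  expect_equal(tr$alive_end[length(tr$alive_end)], 1, tolerance = 1e-12)
  expect_equal(max(tr$t_end), (100 - 10) * 12)
})

test_that("1-week cycles reproduce 3-month cumulative disease deaths", {
  cfgw <- cfg
  cfgw$run$cycle_length_months <- 12 * 7 / 365.25
  for (st in c("limited", "advanced")) {
    d3 <- sum(run_markov_branch(st, cfg)$d_disease)
    dw <- sum(run_markov_branch(st, cfgw)$d_disease)
    expect_lt(abs(d3 - dw), 1e-6)
  }
})

test_that("half-cycle correction averages start and end occupancy", {
  tr <- fake_trace(t_start = c(0, 3), t_end = c(3, 6),
                   state = c("on_treatment", "post_treatment"),
                   alive_start = c(1, 1), alive_end = c(1, 0.8))
  expect_equal(half_cycle_occupancy(tr), c(1, 0.9))
})

test_that("discounted person-time under half-cycle correction is bracketed", {
  tr <- run_markov_branch("advanced", cfg)
  r <- cfg$econ$annual_discount_rate
  df <- (1 + r)^(-(tr$t_start + tr$t_end) / 24)
  yrs <- (tr$t_end - tr$t_start) / 12
  pt_start <- sum(tr$alive_start * yrs * df)
  pt_end <- sum(tr$alive_end * yrs * df)
  pt_half <- sum(half_cycle_occupancy(tr) * yrs * df)
  expect_gt(pt_half, pt_end)
  expect_lt(pt_half, pt_start)
})

test_that("trace exports as a tidy per-cycle data frame", {
  tr <- run_markov_branch("limited", cfg)
  df <- as.data.frame(tr)
  expect_named(df, c("cycle", "time_months", "state", "occ_on_treatment",
                     "occ_post_treatment", "occ_post_disease", "occ_dead",
                     "incident_disease_deaths", "incident_background_deaths"))
  occ <- df$occ_on_treatment + df$occ_post_treatment + df$occ_post_disease +
    df$occ_dead
  expect_equal(occ, rep(1, nrow(df)), tolerance = 1e-12)
})
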