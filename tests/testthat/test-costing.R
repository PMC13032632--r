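cfg <- bl_default_config()

test_that("diagnosis costs apply the NNT multiplier and FN fallback", {
  tl <- build_decision_tree("liquid", cfg)
  expect_equal(tl$diag_cost[tl$label == "liquid_tp_limited"], 4 * 1308450)
  expect_equal(tl$diag_cost[tl$label == "liquid_fn_tp_limited"],
               4 * 1308450 + 413933)
  tp <- build_decision_tree("pathology", cfg)
  expect_true(all(tp$diag_cost == 413933))
  cfg1 <- cfg
  cfg1$diag$nnt <- 1L
  tl1 <- build_decision_tree("liquid", cfg1)
  expect_equal(tl1$diag_cost[1], 1308450)
})

test_that("treatment cost sums stage components plus expected AE cost", {
  expect_equal(treatment_cost("limited", cfg$costs)$treatment,
               2777813 + 1598578)
  expect_equal(treatment_cost("advanced", cfg$costs)$treatment,
               2146124 + 1474471)
  expect_equal(treatment_cost("limited", cfg$costs)$adverse_events, 0)
  costs2 <- cfg$costs
  costs2$ae_table <- data.frame(event = "x", p_limited = 1, p_advanced = 0.5,
                                unit_cost = 100)
  expect_equal(treatment_cost("limited", costs2)$adverse_events, 100)
  expect_equal(treatment_cost("advanced", costs2)$adverse_events, 50)
})

test_that("undiscounted follow-up and end-of-life match the schedule", {
  # fully alive cohort, r = 0: per-protocol schedule over five years
  cfg0 <- immortal_config(r = 0)
  tr <- run_markov_branch("limited", cfg0)
  br <- list(stage = "limited", diag_cost = 0)
  cost <- accrue_costs(tr, br, cfg0)
  expect_equal(cost$followup, 4 * 87581 + 4 * 23790 + 12 * 11895,
               tolerance = 1e-9)
  expect_equal(cost$end_of_life, 0)

  # a single disease death, r = 0: one end-of-life payment
  trd <- fake_trace(0, 3, "on_treatment", 1, 0)
  cost_d <- accrue_costs(trd, br, cfg0)
  expect_equal(cost_d$end_of_life, 166380)

  # zero-occupancy trace accrues nothing anywhere
  tr0 <- fake_trace(c(0, 3), c(3, 6), c("on_treatment", "post_treatment"),
                    c(0, 0), c(0, 0))
  c0 <- accrue_costs(tr0, br, cfg0)
  expect_equal(c0$treatment + c0$adverse_events + c0$followup +
                 c0$end_of_life + c0$overheads, 0)
})

test_that("overheads load care costs but not diagnosis by default", {
  tr <- run_markov_branch("limited", cfg)
  br <- list(stage = "limited", diag_cost = 413933)
  cost <- accrue_costs(tr, br, cfg)
  expect_equal(cost$overheads,
               0.2 * (cost$treatment + cost$adverse_events + cost$followup +
                        cost$end_of_life), tolerance = 1e-9)
  expect_equal(cost$total,
               cost$diagnosis + cost$treatment + cost$adverse_events +
                 cost$followup + cost$end_of_life + cost$overheads,
               tolerance = 1e-6)
  cfg_oh <- cfg
  cfg_oh$run$overhead_on_diagnosis <- TRUE
  cost2 <- accrue_costs(tr, br, cfg_oh)
  expect_equal(cost2$overheads - cost$overheads, 0.2 * 413933, tolerance = 1e-9)
})

test_that("arm diagnosis components satisfy the incremental identity", {
  d <- cfg$diag
  pa <- evaluate_arm("pathology", cfg)
  li <- evaluate_arm("liquid", cfg)
  delta_diag <- li$cost_components["diagnosis"] - pa$cost_components["diagnosis"]
  expect_equal(unname(delta_diag),
               d$nnt * 1308450 - d$pathology_unit_cost +
                 d$fn_prob_liquid * d$pathology_unit_cost,
               tolerance = 1e-9)
})

test_that("non-diagnosis costs fall as the discount rate rises", {
  tr <- run_markov_branch("limited", cfg)
  br <- list(stage = "limited", diag_cost = 0)
  c_lo <- accrue_costs(tr, br, cfg, r = 0.035)
  c_hi <- accrue_costs(tr, br, cfg, r = 0.10)
  expect_gt(c_lo$total, c_hi$total)
})

test_that("costs are linear over branch mixing", {
  arm <- evaluate_arm("pathology", cfg)
  tree <- build_decision_tree("pathology", cfg)
  tot <- 0
  for (i in seq_len(nrow(tree))) {
    tr <- run_markov_branch(tree$stage[i], cfg)
    tot <- tot + tree$weight[i] * accrue_costs(tr, tree[i, ], cfg)$total
  }
  expect_equal(arm$cost_tzs, tot, tolerance = 1e-9)
})
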