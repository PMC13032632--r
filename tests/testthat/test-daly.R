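cfg <- bl_default_config()

test_that("discounted YLL matches closed form, quadrature and limits", {
  lt65 <- flat_life_table()                     # e(10) = 65 with cap 75
  expect_equal(remaining_life_expectancy(10, lt65, 75), 65)
  y <- discounted_yll(10, 0.05, lt65, max_age = 75)
  expect_equal(y, (1 - exp(-0.05 * 65)) / 0.05, tolerance = 1e-12)
  # quadrature oracle: integral of e^(-rt) over [0, L]
  quad <- integrate(function(t) exp(-0.05 * t), 0, 65, rel.tol = 1e-12)$value
  expect_equal(y, quad, tolerance = 1e-10)
  expect_equal(discounted_yll(10, 0, lt65, max_age = 75), 65)
  # annuity variant differs only slightly
  ya <- discounted_yll(10, 0.05, lt65, max_age = 75, form = "annuity")
  expect_equal(ya, (1 - 1.05^(-65)) / 0.05, tolerance = 1e-12)
  expect_lt(abs(ya - y) / y, 0.05)
  expect_error(discounted_yll(-1, 0.05, lt65), ">= 0")
})

test_that("YLD accrual matches closed-form single-cycle cases", {
  w <- cfg$weights
  run <- cfg$run
  lt0 <- flat_life_table()                      # zero background weight
  # one patient alive through one 3-month on-treatment cycle, r = 0
  tr <- fake_trace(0, 3, "on_treatment", 1, 1)
  y <- accrue_yld(tr, w, lt0, r = 0, run = run)
  expect_equal(y$yld_disease, 0.288 * 0.25, tolerance = 1e-12)
  expect_equal(y$yld_background, 0)
  # one disease death in cycle 1 adds the terminal weight for that cycle
  trd <- fake_trace(0, 3, "on_treatment", 1, 0)
  yd <- accrue_yld(trd, w, lt0, r = 0, run = run)
  expect_equal(yd$yld_disease, 0.288 * 0.25 * 0.5 + 0.540 * 0.25,
               tolerance = 1e-12)
  # all weights zero -> zero disease YLD
  w0 <- lapply(w, function(p) list(mean = 0, se = p$se))
  expect_equal(accrue_yld(trd, w0, lt0, r = 0, run = run)$yld_disease, 0)
})

test_that("background YLD mode restricts accrual to the post-disease state", {
  lt <- flat_life_table(dw = 0.1)
  tr <- fake_trace(c(0, 24), c(3, 27), c("on_treatment", "post_disease"),
                   c(1, 1), c(1, 1))
  run_all_alive <- cfg$run
  y1 <- accrue_yld(tr, cfg$weights, lt, r = 0, run = run_all_alive)
  run_post <- cfg$run
  run_post$background_yld_mode <- "post_disease_only"
  y2 <- accrue_yld(tr, cfg$weights, lt, r = 0, run = run_post)
  expect_equal(y1$yld_background, 0.1 * 0.25 * 2, tolerance = 1e-12)
  expect_equal(y2$yld_background, 0.1 * 0.25, tolerance = 1e-12)
})

test_that("total DALYs decompose consistently and respond to model inputs", {
  tr <- run_markov_branch("advanced", cfg)
  d <- total_dalys(tr, cfg)
  expect_equal(d$total,
               d$yll_disease + d$yll_background + d$yld_disease + d$yld_background,
               tolerance = 1e-12)
  expect_true(all(unlist(d) >= 0))

  # immortal cohort with zero weights and zero background -> zero burden
  cfg0 <- immortal_config()
  for (nm in names(cfg0$weights)) cfg0$weights[[nm]]$mean <- 0
  expect_equal(total_dalys(run_markov_branch("limited", cfg0), cfg0)$total, 0)

  # doubling disability weights doubles YLD (no change to YLL)
  cfg2 <- cfg
  for (nm in names(cfg2$weights)) cfg2$weights[[nm]]$mean <-
      2 * cfg$weights[[nm]]$mean
  d2 <- total_dalys(run_markov_branch("advanced", cfg), cfg2)
  expect_equal(d2$yld_disease, 2 * d$yld_disease - d$yld_background * 0,
               tolerance = 1e-9)
  expect_equal(d2$yll_disease, d$yll_disease)
})

test_that("total DALYs increase with disease mortality and decrease with r", {
  base <- total_dalys(run_markov_branch("advanced", cfg), cfg)
  # higher baseline hazard -> more deaths -> more DALYs on this fixture
  cfg_hi <- cfg
  cfg_hi$survival$beta0$mean <- cfg$survival$beta0$mean + 0.3
  hi <- total_dalys(run_markov_branch("advanced", cfg_hi), cfg_hi)
  expect_gt(hi$total, base$total)
  # discount monotonicity
  tr <- run_markov_branch("advanced", cfg)
  expect_gt(total_dalys(tr, cfg, r = 0.035)$total, base$total)
  expect_lt(total_dalys(tr, cfg, r = 0.10)$total, base$total)
})

test_that("DALYs are linear over branch mixtures", {
  tl <- total_dalys(run_markov_branch("limited", cfg), cfg)$total
  ta <- total_dalys(run_markov_branch("advanced", cfg), cfg)$total
  arm <- evaluate_arm("pathology", cfg)
  tree <- build_decision_tree("pathology", cfg)
  mix <- sum(tree$weight * ifelse(tree$stage == "limited", tl, ta))
  expect_equal(arm$dalys, mix, tolerance = 1e-12)
})
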