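test_that("constant-hazard cycle conversion is exact and round-trips", {
  expect_equal(round(prob_to_cycle(0.2544, 3, 1), 5), 0.09322)
  # round trip: three cycles recompose the 3-year probability
  p1 <- prob_to_cycle(0.2544, 3, 1)
  expect_equal(1 - (1 - p1)^3, 0.2544, tolerance = 1e-12)
  expect_equal(prob_to_cycle(0, 5, 1), 0)
  expect_equal(prob_to_cycle(0.37, 4, 4), 0.37)
  expect_error(prob_to_cycle(1, 3, 1), "hazard")
})

test_that("decision-tree branches carry the right probabilities", {
  params <- cea_parameters()
  tree <- build_decision_tree(params, "pet")
  expect_equal(sum(tree$probability), 1)
  fn <- tree[tree$branch == "fn", ]
  expect_equal(fn$probability, 0.691 * 0.040, tolerance = 1e-12)
  expect_identical(fn$treatment_arm, "upper_neck_only")
  expect_identical(fn$truth, "metastatic")
  # perfect test: only TP and TN branches remain
  perfect <- cea_parameters(pet_sens = 1, pet_spec = 1)
  tree_p <- build_decision_tree(perfect, "pet")
  expect_equal(
    tree_p$probability[tree_p$branch %in% c("fn", "fp")],
    c(0, 0)
  )
  expect_equal(
    tree_p$probability[tree_p$branch == "tp"],
    perfect$prevalence
  )
  # conservation under arbitrary parameters
  for (s in c(0.5, 0.8, 0.99)) {
    tr <- build_decision_tree(cea_parameters(mri_sens = s), "mri")
    expect_equal(sum(tr$probability), 1)
  }
})

test_that("Markov trace matches closed forms and conserves the cohort", {
  # zero transitions, utility 1, no discounting -> 10 QALYs
  p0 <- cea_parameters(
    p_recur_3yr_treated = 0, p_mort_bg = 0,
    p_mort_rec_excess = 0, p_mort_post_excess = 0,
    u_recurrence_free = 1, discount_rate = 0, half_cycle = FALSE
  )
  tp <- list(treatment_arm = "whole_neck", truth = "metastatic")
  expect_equal(run_markov_trace(tp, p0)$qaly, 10)

  # same with 3% discounting, end-of-cycle accrual: geometric series
  p3 <- cea_parameters(
    p_recur_3yr_treated = 0, p_mort_bg = 0,
    p_mort_rec_excess = 0, p_mort_post_excess = 0,
    u_recurrence_free = 1, discount_rate = 0.03, half_cycle = FALSE
  )
  expect_equal(run_markov_trace(tp, p3)$qaly, sum(1.03^-(1:10)),
    tolerance = 1e-12
  )
  expect_equal(round(run_markov_trace(tp, p3)$qaly, 4), 8.5302)

  # FN branch cumulative recurrence after 3 cycles, no competing risks
  pfn <- cea_parameters(
    horizon_years = 3, p_mort_bg = 0,
    p_mort_rec_excess = 0, p_mort_post_excess = 0
  )
  fn <- list(treatment_arm = "upper_neck_only", truth = "metastatic")
  expect_equal(run_markov_trace(fn, pfn)$cumulative_recurrence, 0.2544,
    tolerance = 1e-9
  )

  # occupancy conservation and monotone dead fraction on the base case
  base <- cea_parameters()
  for (branch in purrr::transpose(as.list(build_decision_tree(base, "pet")))) {
    tr <- run_markov_trace(branch, base)$trace
    occ <- as.matrix(tr[, -1])
    expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-12)
    expect_true(all(diff(tr$dead) >= -1e-15))
    expect_true(all(occ >= -1e-15))
  }
})

test_that("benign branches never recur and undertreatment elevates recurrence", {
  base <- cea_parameters()
  tn <- run_markov_trace(
    list(treatment_arm = "upper_neck_only", truth = "benign"), base
  )
  expect_equal(tn$cumulative_recurrence, 0)
  fn <- run_markov_trace(
    list(treatment_arm = "upper_neck_only", truth = "metastatic"), base
  )
  tp <- run_markov_trace(
    list(treatment_arm = "whole_neck", truth = "metastatic"), base
  )
  expect_gt(fn$cumulative_recurrence, tp$cumulative_recurrence)
  expect_lt(fn$qaly, tp$qaly)
})

test_that("strategy evaluation reports coherent incremental results", {
  params <- cea_parameters()
  res <- evaluate_strategies(params)
  # ICER equals hand-computed delta cost / delta QALY
  d_cost <- res$strategies$cost[1] - res$strategies$cost[2]
  d_qaly <- res$strategies$qaly[1] - res$strategies$qaly[2]
  expect_equal(res$incremental$icer, d_cost / d_qaly, tolerance = 1e-9)
  # QALYs bounded by the undiscounted horizon
  expect_true(all(res$strategies$qaly <= params$horizon_years))
  # identical accuracy and test cost: increments vanish, ICER undefined
  same <- cea_parameters(
    mri_sens = params$pet_sens, mri_spec = params$pet_spec,
    cost_mri_test = params$cost_pet_test
  )
  res_same <- evaluate_strategies(same)
  expect_equal(res_same$incremental$incremental_cost, 0, tolerance = 1e-9)
  expect_equal(res_same$incremental$incremental_qaly, 0, tolerance = 1e-12)
  expect_true(is.na(res_same$incremental$icer))
  expect_equal(res_same$incremental$nmb_difference, 0, tolerance = 1e-9)
})

test_that("published base-case pair gives the published ICER", {
  expect_equal(icer(27228, 5.329, 25596, 5.305), 68000)
  expect_true(is.na(icer(100, 2, 50, 2)))
})

test_that("raising PET sensitivity never lowers PET QALYs", {
  qalys <- vapply(seq(0.90, 0.99, by = 0.015), function(s) {
    evaluate_strategies(cea_parameters(pet_sens = s))$strategies$qaly[1]
  }, numeric(1))
  expect_true(all(diff(qalys) >= -1e-12))
})

test_that("with no undertreatment penalty the sensitivity advantage vanishes", {
  # equal recurrence under- vs correctly-treated, equal specificity and
  # test costs: the only channel left for a QALY difference is
  # sensitivity, and it must carry no benefit
  params <- cea_parameters(
    p_recur_3yr_fn = 0.0744, p_recur_3yr_treated = 0.0744,
    mri_spec = 0.640, cost_mri_test = 1000
  )
  res <- evaluate_strategies(params)
  expect_equal(res$incremental$incremental_qaly, 0, tolerance = 1e-12)
})

test_that("costs scale linearly under uniform cost scaling", {
  params <- cea_parameters()
  res <- evaluate_strategies(params)
  scaled <- cea_parameters(
    cost_mri_test = params$cost_mri_test * 2,
    cost_pet_test = params$cost_pet_test * 2,
    cost_upper_rt = params$cost_upper_rt * 2,
    cost_whole_rt = params$cost_whole_rt * 2,
    cost_recurrence = params$cost_recurrence * 2,
    cost_followup = params$cost_followup * 2
  )
  res2 <- evaluate_strategies(scaled)
  expect_equal(res2$strategies$cost, 2 * res$strategies$cost,
    tolerance = 1e-9
  )
  expect_equal(res2$strategies$qaly, res$strategies$qaly)
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(cea_parameters(prevalence = 1.2), "probabilities")
  expect_error(cea_parameters(u_recurrence = -0.1), "utilities")
  expect_error(cea_parameters(cost_pet_test = -5), "costs")
  expect_error(cea_parameters(horizon_years = 10, cycle_years = 3), "multiple")
  expect_error(cea_parameters(not_a_parameter = 1), "unknown")
})

test_that("tornado orders bars by swing and honours trivial cases", {
  params <- cea_parameters()
  tor <- tornado(params)
  expect_true(all(diff(tor$swing) <= 1e-9))
  # zero-width range gives a zero-width bar
  zw <- tornado(params, tibble::tibble(
    parameter = "prevalence",
    low = params$prevalence, high = params$prevalence
  ))
  expect_equal(zw$swing, 0)
  expect_equal(zw$icer_low, zw$icer_base)
  # a parameter outside the incremental comparison leaves the ICER flat
  wtp_bar <- tornado(params, tibble::tibble(
    parameter = "wtp", low = 5e4, high = 2e5
  ))
  expect_equal(wtp_bar$swing, 0)
  # prevalence swept over its reported range keeps the ICER below WTP
  prev_bar <- tornado(params, tibble::tibble(
    parameter = "prevalence", low = 0.632, high = 0.796
  ))
  expect_true(all(is.finite(c(prev_bar$icer_low, prev_bar$icer_high))))
  expect_lt(max(prev_bar$icer_low, prev_bar$icer_high), params$wtp)
  # ranges must bracket the base value; unknown parameters fail
  expect_error(
    tornado(params, tibble::tibble(parameter = "prevalence", low = 0.8, high = 0.9)),
    "bracket"
  )
  expect_error(
    tornado(params, tibble::tibble(parameter = "nope", low = 0, high = 1)),
    "unknown"
  )
})
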