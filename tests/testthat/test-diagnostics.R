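test_that("confusion counts partition the cohort and respect the cutoff", {
  nodes <- make_toy_nodes()
  conf <- confusion_at_cutoff(nodes, "pet", 2)
  expect_identical(
    unlist(conf[c("tp", "fn", "fp", "tn")]),
    c(tp = 2L, fn = 1L, fp = 1L, tn = 2L)
  )
  expect_error(confusion_at_cutoff(nodes, "pet", 5), "cutoff")
  expect_error(confusion_at_cutoff(nodes[0, ], "pet", 2), "empty")

  # raising the cutoff never increases tp and never decreases tn
  coh <- generate_fixture_cohort_a()
  prev <- confusion_at_cutoff(coh, "mri", 1)
  for (k in 2:4) {
    cur <- confusion_at_cutoff(coh, "mri", k)
    expect_lte(cur$tp, prev$tp)
    expect_gte(cur$tn, prev$tn)
    prev <- cur
  }
})

test_that("diagnostic metrics reproduce the published node-level table", {
  pet <- diagnostic_metrics(confusion_counts(533, 22, 50, 89))
  est <- function(m, name) {
    round(100 * m$estimate[m$metric == name], 1)
  }
  expect_equal(est(pet, "accuracy"), 89.6)
  expect_equal(est(pet, "sensitivity"), 96.0)
  expect_equal(est(pet, "specificity"), 64.0)
  expect_equal(est(pet, "ppv"), 91.4)
  expect_equal(est(pet, "npv"), 80.2)

  mri <- diagnostic_metrics(confusion_counts(514, 41, 57, 82))
  expect_equal(est(mri, "accuracy"), 85.9)
  expect_equal(est(mri, "sensitivity"), 92.6)
  expect_equal(est(mri, "specificity"), 59.0)
  expect_equal(est(mri, "ppv"), 90.0)
  expect_equal(est(mri, "npv"), 66.7)

  perfect <- diagnostic_metrics(confusion_counts(10, 0, 0, 10))
  expect_true(all(perfect$estimate == 1))

  # zero denominators are reported as missing, never as zero
  no_benign <- diagnostic_metrics(confusion_counts(5, 2, 0, 0))
  expect_true(is.na(no_benign$estimate[no_benign$metric == "specificity"]))
  no_negative_calls <- diagnostic_metrics(confusion_counts(5, 0, 3, 0))
  expect_true(is.na(
    no_negative_calls$estimate[no_negative_calls$metric == "npv"]
  ))
  # point estimates inside their intervals
  ok <- !is.na(pet$estimate)
  expect_true(all(pet$conf.low[ok] <= pet$estimate[ok] &
    pet$estimate[ok] <= pet$conf.high[ok]))
})

test_that("Wilson interval matches the closed form and prop.test", {
  ci <- wilson_ci(622, 694)
  expect_equal(round(100 * ci$conf.low, 1), 87.1)
  expect_equal(round(100 * ci$conf.high, 1), 91.7)
  # independent route: score-test inversion in stats::prop.test
  for (case in list(c(622, 694), c(89, 139), c(3, 10), c(533, 555))) {
    ours <- wilson_ci(case[1], case[2])
    ref <- prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(c(ours$conf.low, ours$conf.high), as.numeric(ref),
      tolerance = 1e-10
    )
  }
})

test_that("McNemar reproduces the published staging comparison", {
  res <- mcnemar_paired(40, 21)
  expect_equal(round(res$p.value, 3), 0.021)
  # agreement with the standard implementation on the same table
  ref <- mcnemar.test(matrix(c(0, 21, 40, 0), 2, 2), correct = TRUE)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)

  # clamped correction: equal discordant counts give p = 1
  expect_equal(mcnemar_paired(7, 7)$p.value, 1)
  expect_equal(mcnemar_paired(0, 0)$p.value, 1)

  # without correction the p-value is smaller, and the exact binomial
  # route agrees on the ordering (40 successes of 61 at p = 1/2)
  plain <- mcnemar_paired(40, 21, correction = FALSE)
  expect_lt(plain$p.value, res$p.value)
  exact <- binom.test(40, 61, 0.5)$p.value
  expect_lt(abs(plain$p.value - exact), 0.01)
  expect_error(mcnemar_paired(-1, 2), "non-negative")
})

test_that("predictive-value comparison is null on identical calls and detects separation", {
  nodes <- make_toy_nodes()
  same <- nodes
  same$mri_score <- same$pet_score
  for (w in c("ppv", "npv")) {
    res <- compare_predictive_values(same, w)
    expect_equal(res$estimate[["difference"]], 0)
    expect_equal(res$p.value, 1)
  }

  # forced NPV separation at large n: A's negatives are almost always
  # right, B's negatives are often wrong
  set.seed(42)
  n <- 2000
  diseased <- rep(c(TRUE, FALSE), each = n / 2)
  pet_pos <- ifelse(diseased, runif(n) < 0.98, runif(n) < 0.1)
  mri_pos <- ifelse(diseased, runif(n) < 0.55, runif(n) < 0.1)
  sep <- nodes_from_calls(diseased, pet_pos, mri_pos)
  res <- compare_predictive_values(sep, "npv")
  expect_lt(res$p.value, 0.001)
  expect_gt(res$estimate[["difference"]], 0)

  # degenerate: no positive calls on one modality
  none <- nodes
  none$pet_score <- 0L
  expect_error(compare_predictive_values(none, "ppv"), "undefined")
})

test_that("predictive-value test agrees with a cluster bootstrap oracle", {
  spec <- cohort_spec(
    n_pos = 120, n_neg = 80,
    sens = c(pet = 0.90, mri = 0.78), spec = c(pet = 0.70, mri = 0.60),
    agreement_rho = 0.4
  )
  nodes <- sample_paired_cohort(spec, 200, seed = 11)
  for (w in c("ppv", "npv")) {
    p_wgs <- compare_predictive_values(nodes, w)$p.value
    p_boot <- bootstrap_pv_p(nodes, w, n_boot = 10000, seed = 123)
    expect_lt(abs(p_wgs - p_boot), 0.02)
  }
})

test_that("DeLong AUC equals brute-force pair counting and handles ties", {
  # 6-node toy: diseased scores 3,4,2; benign 1,0,2 -> AUC 8.5/9
  toy <- tibble::tibble(
    node_id = paste0("t", 1:6), patient_id = paste0("tp", 1:6),
    level = "II",
    pathology = rep(c("metastatic", "benign"), each = 3),
    pet_score = c(3L, 4L, 2L, 1L, 0L, 2L),
    mri_score = c(3L, 4L, 2L, 1L, 0L, 2L)
  )
  res <- delong_paired_auc(toy)
  expect_equal(res$estimate[["auc_pet"]], 8.5 / 9)
  expect_equal(
    res$estimate[["auc_pet"]],
    brute_force_auc(c(3, 4, 2), c(1, 0, 2))
  )
  # identical scores: difference 0, p = 1
  expect_equal(res$estimate[["difference"]], 0)
  expect_equal(res$p.value, 1)

  # perfectly separating scores give AUC 1
  sep <- toy
  sep$pet_score <- c(4L, 4L, 3L, 1L, 0L, 0L)
  expect_equal(delong_paired_auc(sep)$estimate[["auc_pet"]], 1)

  # equality with brute force on generated cohorts, to 1e-12
  for (seed in c(3, 17)) {
    coh <- sample_paired_cohort(cohort_spec(agreement_rho = 0.5), 400,
      seed = seed
    )
    d <- coh$pathology == "metastatic"
    res <- delong_paired_auc(coh)
    expect_equal(
      res$estimate[["auc_pet"]],
      brute_force_auc(coh$pet_score[d], coh$pet_score[!d]),
      tolerance = 1e-12
    )
    expect_equal(
      res$estimate[["auc_mri"]],
      brute_force_auc(coh$mri_score[d], coh$mri_score[!d]),
      tolerance = 1e-12
    )
  }
  expect_error(delong_paired_auc(toy[toy$pathology == "benign", ]), "class")
})

test_that("DeLong variance route matches the reference implementation", {
  skip_if_not_installed("pROC")
  coh <- sample_paired_cohort(cohort_spec(agreement_rho = 0.4), 500, seed = 21)
  ours <- delong_paired_auc(coh)
  ref <- pROC::roc.test(
    response = coh$pathology == "metastatic",
    predictor1 = coh$pet_score, predictor2 = coh$mri_score,
    method = "delong", paired = TRUE, quiet = TRUE
  )
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
  expect_equal(ours$estimate[["auc_pet"]], as.numeric(ref$estimate[1]),
    tolerance = 1e-12
  )
})

test_that("predictive values satisfy Bayes' rule and NPV falls with prevalence", {
  # count-based PPV/NPV equal the Bayes form on the fixture
  conf <- confusion_at_cutoff(generate_fixture_cohort_a(), "pet", 2)
  m <- diagnostic_metrics(conf)
  g <- function(name) m$estimate[m$metric == name]
  prev <- (conf$tp + conf$fn) / (conf$tp + conf$fn + conf$fp + conf$tn)
  ppv_bayes <- g("sensitivity") * prev /
    (g("sensitivity") * prev + (1 - g("specificity")) * (1 - prev))
  npv_bayes <- g("specificity") * (1 - prev) /
    (g("specificity") * (1 - prev) + (1 - g("sensitivity")) * prev)
  expect_equal(g("ppv"), ppv_bayes, tolerance = 1e-12)
  expect_equal(g("npv"), npv_bayes, tolerance = 1e-12)

  # NPV strictly decreasing in prevalence at fixed sens/spec
  sens <- 0.96
  spec <- 0.64
  npv_at <- function(prev) {
    spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)
  }
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(npv_at(grid)) < 0))
})

test_that("paired tests are invariant to row order", {
  coh <- sample_paired_cohort(cohort_spec(agreement_rho = 0.5), 300, seed = 8)
  set.seed(1)
  perm <- coh[sample.int(nrow(coh)), ]
  expect_equal(
    compare_predictive_values(coh, "ppv")$p.value,
    compare_predictive_values(perm, "ppv")$p.value
  )
  expect_equal(
    delong_paired_auc(coh)$p.value,
    delong_paired_auc(perm)$p.value
  )
  a <- compare_modalities(coh)
  b <- compare_modalities(perm)
  expect_equal(a$p_value, b$p_value)
})

test_that("compare_modalities assembles a coherent summary table", {
  coh <- generate_fixture_cohort_a()
  tab <- compare_modalities(coh)
  expect_setequal(
    tab$metric,
    c("accuracy", "sensitivity", "specificity", "ppv", "npv", "auc")
  )
  expect_equal(
    round(100 * tab$estimate_a[tab$metric == "accuracy"], 1), 89.6
  )
  expect_equal(
    round(100 * tab$estimate_b[tab$metric == "npv"], 1), 66.7
  )
  expect_true(all(tab$p_value[!is.na(tab$p_value)] >= 0 &
    tab$p_value[!is.na(tab$p_value)] <= 1))
})
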