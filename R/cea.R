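## Decision-tree + Markov cohort cost-effectiveness engine comparing an
## MRI-first with a PET/CT-first nodal staging strategy.
##
## Four Markov states: recurrence_free, regional_recurrence (one cycle
## of salvage management), post_salvage, dead (absorbing). The decision
## tree splits the cohort into TP/FN/TN/FP branches; the false-negative
## branch (metastatic disease managed with upper-neck-only irradiation)
## runs the trace with an elevated recurrence probability.

#' Economic-model parameter set
#'
#' All inputs of the decision-tree + Markov model, as a flat named list.
#' Diagnostic accuracy defaults are the study's node-level estimates
#' (PET 0.960/0.640, MRI 0.926/0.590), the pre-test probability of
#' nodal metastasis defaults to 0.691 (plausible range 0.632-0.796),
#' and the 3-year regional recurrence probability of an undertreated
#' false-negative defaults to 0.2544. Cost, utility and mortality
#' defaults are an illustrative parameter set (documented in the
#' methods vignette); they are configurable and no published base-case
#' cost/QALY pair is claimed to be reproduced by them.
#'
#' Probabilities are per the stated period (3-year recurrence inputs
#' are converted to per-cycle values internally via [prob_to_cycle()]);
#' costs are US$; utilities are per cycle in \[0, 1\];
#' `u_tox_whole_neck` is the per-cycle utility decrement of unnecessary
#' whole-neck irradiation (false positives); `discount_rate` is per
#' year, applied to both costs and QALYs.
#'
#' @param ... Name-value overrides of any default listed below.
#' @return A `cea_parameters` list.
#' @export
cea_parameters <- function(...) {
  defaults <- list(
    prevalence = 0.691,
    pet_sens = 0.960, pet_spec = 0.640,
    mri_sens = 0.926, mri_spec = 0.590,
    p_recur_3yr_fn = 0.2544,
    p_recur_3yr_treated = 0.0744,
    p_mort_bg = 0.012,
    p_mort_rec_excess = 0.15,
    p_mort_post_excess = 0.05,
    u_recurrence_free = 0.85,
    u_recurrence = 0.55,
    u_post_salvage = 0.70,
    u_tox_whole_neck = 0.03,
    cost_mri_test = 400,
    cost_pet_test = 1000,
    cost_upper_rt = 14000,
    cost_whole_rt = 17000,
    cost_recurrence = 40000,
    cost_followup = 500,
    discount_rate = 0.03,
    horizon_years = 10,
    cycle_years = 1,
    wtp = 1e5,
    half_cycle = TRUE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf(
      "unknown parameter(s): %s",
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }
  params <- utils::modifyList(defaults, overrides)
  probs <- c(
    "prevalence", "pet_sens", "pet_spec", "mri_sens", "mri_spec",
    "p_recur_3yr_fn", "p_recur_3yr_treated", "p_mort_bg",
    "p_mort_rec_excess", "p_mort_post_excess"
  )
  utils_ <- c(
    "u_recurrence_free", "u_recurrence", "u_post_salvage",
    "u_tox_whole_neck"
  )
  costs <- grep("^cost_", names(defaults), value = TRUE)
  bad <- function(x, lo, hi) any(unlist(params[x]) < lo | unlist(params[x]) > hi)
  if (bad(probs, 0, 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (bad(utils_, 0, 1)) stop("utilities must lie in [0, 1]", call. = FALSE)
  if (any(unlist(params[costs]) < 0)) {
    stop("costs must be non-negative", call. = FALSE)
  }
  if (params$horizon_years <= 0 || params$cycle_years <= 0 ||
    params$horizon_years %% params$cycle_years != 0) {
    stop("horizon must be a positive multiple of the cycle length",
      call. = FALSE
    )
  }
  structure(params, class = "cea_parameters")
}

#' Constant-hazard conversion of a cumulative probability to one cycle
#'
#' Converts a probability cumulated over `years_cum` years into the
#' per-cycle probability with the same constant hazard:
#' `1 - (1 - p_cum)^(cycle_years / years_cum)`.
#'
#' @param p_cum Cumulative probability in \[0, 1).
#' @param years_cum Period over which `p_cum` accrues (years, > 0).
#' @param cycle_years Cycle length (years, > 0).
#' @return Per-cycle probability.
#' @examples
#' prob_to_cycle(0.2544, 3, 1) # 0.09322
#' @export
prob_to_cycle <- function(p_cum, years_cum, cycle_years) {
  stopifnot(years_cum > 0, cycle_years > 0, p_cum >= 0)
  if (any(p_cum >= 1)) {
    stop("cumulative probability of 1 implies an infinite hazard",
      call. = FALSE
    )
  }
  1 - (1 - p_cum)^(cycle_years / years_cum)
}

#' Decision-tree branches of a staging strategy
#'
#' Splits the cohort by test result and truth: TP (whole-neck,
#' diseased) with probability `p * sens`; FN (upper-neck-only,
#' diseased) `p * (1 - sens)`; TN (upper-neck-only, benign)
#' `(1 - p) * spec`; FP (whole-neck, benign) `(1 - p) * (1 - spec)`.
#' Probabilities sum to 1.
#'
#' @param params A [cea_parameters()] object.
#' @param strategy `"pet"` or `"mri"`.
#' @return Tibble with columns `branch`, `probability`,
#'   `treatment_arm`, `truth`.
#' @export
build_decision_tree <- function(params, strategy = c("pet", "mri")) {
  strategy <- match.arg(strategy)
  p <- params$prevalence
  sens <- params[[paste0(strategy, "_sens")]]
  spec <- params[[paste0(strategy, "_spec")]]
  tibble::tibble(
    branch = c("tp", "fn", "tn", "fp"),
    probability = c(
      p * sens, p * (1 - sens),
      (1 - p) * spec, (1 - p) * (1 - spec)
    ),
    treatment_arm = c(
      "whole_neck", "upper_neck_only",
      "upper_neck_only", "whole_neck"
    ),
    truth = c("metastatic", "metastatic", "benign", "benign")
  )
}

markov_transition_matrix <- function(p_recur, p_mort_bg, p_mort_rec,
                                     p_mort_post) {
  states <- c("recurrence_free", "regional_recurrence", "post_salvage", "dead")
  m <- matrix(0, 4, 4, dimnames = list(states, states))
  m[1, 4] <- p_mort_bg
  m[1, 2] <- (1 - p_mort_bg) * p_recur
  m[1, 1] <- 1 - m[1, 2] - m[1, 4]
  m[2, 4] <- min(p_mort_bg + p_mort_rec, 1)
  m[2, 3] <- 1 - m[2, 4] # salvage completes within one cycle
  m[3, 4] <- min(p_mort_bg + p_mort_post, 1)
  m[3, 3] <- 1 - m[3, 4]
  m[4, 4] <- 1
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12)) {
    stop("transition matrix rows must be probabilities summing to 1",
      call. = FALSE
    )
  }
  m
}

#' Markov cohort trace for one decision-tree branch
#'
#' Advances a cohort that starts fully recurrence-free through
#' `horizon_years / cycle_years` cycles. The recurrence probability per
#' cycle comes from the branch: false negatives (metastatic, managed
#' upper-neck-only) use the elevated 3-year probability, other
#' metastatic branches the baseline treated probability, benign
#' branches zero. Per-cycle utilities and costs are accrued at cycle
#' end, discounted by `(1 + discount_rate)^(-t)`; with the half-cycle
#' correction (the default) occupancy is averaged over cycle start and
#' end. The up-front treatment cost (upper-neck vs whole-neck
#' radiotherapy) is incurred undiscounted at time zero; the utility
#' decrement of unnecessary whole-neck irradiation applies to benign
#' nodes treated whole-neck (false positives).
#'
#' @param branch One row of [build_decision_tree()] (list or one-row
#'   data frame with `treatment_arm` and `truth`).
#' @param params A [cea_parameters()] object.
#' @return A list: `trace` (tibble of per-cycle state occupancy),
#'   `cost` and `qaly` (discounted totals for this branch),
#'   `cumulative_recurrence` (1 minus final recurrence-free share,
#'   ignoring death competition when mortality is zero).
#' @export
run_markov_trace <- function(branch, params) {
  branch <- as.list(branch)
  diseased <- branch$truth == "metastatic"
  undertreated <- diseased && branch$treatment_arm == "upper_neck_only"
  p3 <- if (!diseased) {
    0
  } else if (undertreated) {
    params$p_recur_3yr_fn
  } else {
    params$p_recur_3yr_treated
  }
  p_recur <- if (p3 == 0) {
    0
  } else {
    prob_to_cycle(p3, 3, params$cycle_years)
  }
  m <- markov_transition_matrix(
    p_recur, params$p_mort_bg,
    params$p_mort_rec_excess, params$p_mort_post_excess
  )
  n_cycles <- as.integer(round(params$horizon_years / params$cycle_years))
  occ <- matrix(0, n_cycles + 1, 4, dimnames = list(NULL, colnames(m)))
  occ[1, ] <- c(1, 0, 0, 0)
  for (t in seq_len(n_cycles)) occ[t + 1, ] <- occ[t, , drop = FALSE] %*% m

  overtreated <- !diseased && branch$treatment_arm == "whole_neck"
  u_rf <- params$u_recurrence_free -
    if (overtreated) params$u_tox_whole_neck else 0
  state_utility <- c(u_rf, params$u_recurrence, params$u_post_salvage, 0)
  state_cost <- c(
    params$cost_followup, params$cost_recurrence,
    params$cost_followup, 0
  )
  disc <- (1 + params$discount_rate)^(-seq_len(n_cycles) * params$cycle_years)
  eff_occ <- if (isTRUE(params$half_cycle)) {
    (occ[-1, , drop = FALSE] + occ[-nrow(occ), , drop = FALSE]) / 2
  } else {
    occ[-1, , drop = FALSE]
  }
  qaly <- sum(disc * (eff_occ %*% state_utility) * params$cycle_years)
  cost_rt <- if (branch$treatment_arm == "whole_neck") {
    params$cost_whole_rt
  } else {
    params$cost_upper_rt
  }
  cost <- cost_rt + sum(disc * (eff_occ %*% state_cost))
  list(
    trace = tibble::as_tibble(cbind(cycle = 0:n_cycles, occ)),
    cost = cost,
    qaly = qaly,
    cumulative_recurrence = unname(
      1 - occ[n_cycles + 1, "recurrence_free"] -
        cumulative_dead_never_recurred(occ, m)
    )
  )
}

## Share of the dead who never recurred, so cumulative recurrence can be
## reported as "ever entered the recurrence state". Tracks an auxiliary
## never-recurred compartment through the same chain.
cumulative_dead_never_recurred <- function(occ, m) {
  n_cycles <- nrow(occ) - 1
  alive_nr <- 1
  dead_nr <- 0
  for (t in seq_len(n_cycles)) {
    dead_nr <- dead_nr + alive_nr * m[1, 4]
    alive_nr <- alive_nr * m[1, 1]
  }
  dead_nr
}

#' Expected costs, QALYs and the ICER of the two strategies
#'
#' Weights each decision-tree branch's Markov trace by its branch
#' probability, adds the strategy's test cost, and reports expected
#' discounted cost and QALYs per strategy plus the incremental
#' comparison of PET/CT versus MRI: incremental cost, incremental
#' QALYs, ICER = incremental cost / incremental QALYs, and a dominance
#' flag when one strategy is both cheaper and more effective. The ICER
#' is undefined (NA) when the incremental QALYs are zero; net monetary
#' benefit at `wtp` is always reported.
#'
#' @param params A [cea_parameters()] object.
#' @return A `cea_result` list with `strategies` (tibble) and
#'   `incremental` (tibble).
#' @export
evaluate_strategies <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  eval_one <- function(strategy) {
    tree <- build_decision_tree(params, strategy)
    res <- purrr::pmap(tree, function(...) {
      run_markov_trace(list(...), params)
    })
    test_cost <- params[[paste0("cost_", strategy, "_test")]]
    tibble::tibble(
      strategy = strategy,
      cost = test_cost +
        sum(tree$probability * purrr::map_dbl(res, "cost")),
      qaly = sum(tree$probability * purrr::map_dbl(res, "qaly"))
    )
  }
  strategies <- dplyr::bind_rows(eval_one("pet"), eval_one("mri"))
  d_cost <- strategies$cost[1] - strategies$cost[2]
  d_qaly <- strategies$qaly[1] - strategies$qaly[2]
  icer <- if (d_qaly == 0) NA_real_ else d_cost / d_qaly
  dominant <- if (d_qaly > 0 && d_cost < 0) {
    "pet"
  } else if (d_qaly < 0 && d_cost > 0) {
    "mri"
  } else {
    "none"
  }
  strategies$nmb <- params$wtp * strategies$qaly - strategies$cost
  incremental <- tibble::tibble(
    comparison = "pet_vs_mri",
    incremental_cost = d_cost,
    incremental_qaly = d_qaly,
    icer = icer,
    dominant = dominant,
    nmb_difference = strategies$nmb[1] - strategies$nmb[2]
  )
  structure(
    list(
      strategies = strategies, incremental = incremental,
      params = params
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness (PET/CT-first vs MRI-first)\n")
  print(x$strategies)
  cat("\n")
  print(x$incremental)
  invisible(x)
}

#' ICER from externally supplied cost/QALY pairs
#'
#' The incremental arithmetic on its own, for checking reported
#' strategy pairs: `(cost_a - cost_b) / (qaly_a - qaly_b)`.
#'
#' @param cost_a,qaly_a,cost_b,qaly_b Strategy totals (a vs b).
#' @return The ICER (NA if the QALYs are equal).
#' @examples
#' icer(27228, 5.329, 25596, 5.305) # 68000
#' @export
icer <- function(cost_a, qaly_a, cost_b, qaly_b) {
  d_qaly <- qaly_a - qaly_b
  if (d_qaly == 0) {
    return(NA_real_)
  }
  (cost_a - cost_b) / d_qaly
}

#' One-way deterministic (tornado) sensitivity analysis
#'
#' Re-evaluates the ICER with each parameter set to its lower and upper
#' bound, all else at base, and sorts the bars by ICER swing.
#'
#' @param params A [cea_parameters()] object (the base case).
#' @param param_ranges Tibble/data frame with columns `parameter`,
#'   `low`, `high`; each range must bracket the base value.
#' @return A tibble (class `tornado_result`): `parameter`, `low`,
#'   `high`, `icer_base`, `icer_low`, `icer_high`, `swing`, sorted by
#'   decreasing `swing`.
#' @export
tornado <- function(params, param_ranges = default_tornado_ranges(params)) {
  stopifnot(all(c("parameter", "low", "high") %in% names(param_ranges)))
  base_icer <- evaluate_strategies(params)$incremental$icer
  eval_at <- function(name, value) {
    if (!name %in% names(params)) {
      stop(sprintf("unknown parameter '%s'", name), call. = FALSE)
    }
    args <- stats::setNames(list(value), name)
    p2 <- do.call(cea_parameters, utils::modifyList(unclass(params), args))
    evaluate_strategies(p2)$incremental$icer
  }
  out <- purrr::pmap_dfr(param_ranges, function(parameter, low, high, ...) {
    base_val <- params[[parameter]]
    if (is.null(base_val)) {
      stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
    }
    if (low > base_val || high < base_val) {
      stop(sprintf(
        "range for '%s' must bracket the base value %.4g",
        parameter, base_val
      ), call. = FALSE)
    }
    tibble::tibble(
      parameter = parameter, low = low, high = high,
      icer_base = base_icer,
      icer_low = eval_at(parameter, low),
      icer_high = eval_at(parameter, high)
    )
  })
  out$swing <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$swing), ]
  class(out) <- c("tornado_result", class(out))
  out
}

#' Default one-way ranges for the tornado analysis
#'
#' Accuracy parameters vary over their study 95\% confidence intervals,
#' the pre-test probability over its reported plausible range
#' (0.632-0.796), the undertreated recurrence probability over a wide
#' plausible band, and costs/utilities by +/-25\% (utilities capped at
#' 1).
#'
#' @param params Base-case [cea_parameters()].
#' @return Tibble with columns `parameter`, `low`, `high`.
#' @export
default_tornado_ranges <- function(params = cea_parameters()) {
  rel <- function(name, f_lo = 0.75, f_hi = 1.25, cap = Inf) {
    tibble::tibble(
      parameter = name,
      low = params[[name]] * f_lo,
      high = min(params[[name]] * f_hi, cap)
    )
  }
  dplyr::bind_rows(
    tibble::tibble(parameter = "prevalence", low = 0.632, high = 0.796),
    tibble::tibble(parameter = "pet_sens", low = 0.941, high = 0.974),
    tibble::tibble(parameter = "pet_spec", low = 0.558, high = 0.715),
    tibble::tibble(parameter = "mri_sens", low = 0.901, high = 0.945),
    tibble::tibble(parameter = "mri_spec", low = 0.507, high = 0.668),
    tibble::tibble(parameter = "p_recur_3yr_fn", low = 0.15, high = 0.35),
    rel("p_recur_3yr_treated"),
    rel("cost_pet_test"),
    rel("cost_mri_test"),
    rel("cost_whole_rt"),
    rel("cost_upper_rt"),
    rel("cost_recurrence"),
    rel("u_recurrence_free", cap = 1),
    rel("u_recurrence", cap = 1)
  )
}
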