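## Probabilistic sensitivity analysis: joint parameter draws (beta for
## probabilities and utilities, gamma for costs), per-iteration strategy
## evaluation, CE-plane points and the cost-effectiveness acceptability
## curve.

#' Beta distribution matched to a mean and 95% range
#'
#' Finds the beta distribution with the given mean whose central 95%
#' interval width equals `high - low` (moment matching on the mean,
#' one-dimensional search on the concentration). A zero-width range
#' gives a degenerate (point-mass) distribution.
#'
#' @param mean Mean in (0, 1) (0 or 1 allowed only with zero width).
#' @param low,high Target 95% interval bounds (within \[0, 1\]).
#' @return A list distribution spec (`type`, `mean`, and shape
#'   parameters) consumed by [draw_parameter()].
#' @export
beta_from_mean_range <- function(mean, low, high) {
  stopifnot(mean >= 0, mean <= 1, low <= mean, mean <= high, low >= 0, high <= 1)
  width <- high - low
  if (width <= 0 || mean %in% c(0, 1)) {
    return(list(type = "point", mean = mean))
  }
  ## qbeta warns at the extreme lower bracket (near-Bernoulli shapes);
  ## those evaluations only serve the root search
  width_at <- function(log_kappa) {
    k <- exp(log_kappa)
    suppressWarnings(
      stats::qbeta(0.975, mean * k, (1 - mean) * k) -
        stats::qbeta(0.025, mean * k, (1 - mean) * k)
    )
  }
  root <- stats::uniroot(function(lk) width_at(lk) - width,
    lower = log(1e-2), upper = log(1e6), tol = 1e-10
  )
  k <- exp(root$root)
  list(type = "beta", mean = mean, shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Gamma distribution matched to a mean and 95% range
#'
#' As [beta_from_mean_range()] but for non-negative quantities (costs):
#' the shape is found so the central 95% interval width matches, and
#' the rate then fixes the mean.
#'
#' @param mean Positive mean (0 allowed only with zero width).
#' @param low,high Target 95% interval bounds (non-negative).
#' @return A distribution spec list.
#' @export
gamma_from_mean_range <- function(mean, low, high) {
  stopifnot(mean >= 0, low <= mean, mean <= high, low >= 0)
  width <- high - low
  if (width <= 0 || mean == 0) {
    return(list(type = "point", mean = mean))
  }
  width_at <- function(log_shape) {
    k <- exp(log_shape)
    (stats::qgamma(0.975, shape = k, rate = k / mean) -
      stats::qgamma(0.025, shape = k, rate = k / mean))
  }
  ## width is monotone decreasing in the shape only for shape >~ 0.5
  ## (below that the central mass collapses towards zero), so search the
  ## monotone branch and fail loudly on unattainably wide requests
  if (width_at(log(0.5)) < width) {
    stop("requested 95% range too wide for a gamma with this mean",
      call. = FALSE
    )
  }
  root <- stats::uniroot(function(lk) width_at(lk) - width,
    lower = log(0.5), upper = log(1e8), tol = 1e-10
  )
  k <- exp(root$root)
  list(type = "gamma", mean = mean, shape = k, rate = k / mean)
}

draw_parameter <- function(dist, n) {
  switch(dist$type,
    point = rep(dist$mean, n),
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    gamma = stats::rgamma(n, shape = dist$shape, rate = dist$rate),
    stop(sprintf("unknown distribution type '%s'", dist$type), call. = FALSE)
  )
}

#' Default PSA distributions for the model parameters
#'
#' Accuracy parameters get beta distributions matched to their study
#' 95% confidence intervals; the pre-test probability to its reported
#' plausible range; the undertreated recurrence probability to a wide
#' band; utilities to +/-0.05 absolute (capped in \[0, 1\]); costs to
#' gamma distributions matched to +/-25%. Mortality and structural
#' parameters (discounting, horizon, WTP) are held fixed.
#'
#' @param params Base-case [cea_parameters()].
#' @return Named list of distribution specs.
#' @export
default_psa_distributions <- function(params = cea_parameters()) {
  b <- function(name, low, high) {
    stats::setNames(list(beta_from_mean_range(params[[name]], low, high)), name)
  }
  b_abs <- function(name, delta) {
    m <- params[[name]]
    b(name, max(0, m - delta), min(1, m + delta))
  }
  g <- function(name, f = 0.25) {
    m <- params[[name]]
    stats::setNames(
      list(gamma_from_mean_range(m, m * (1 - f), m * (1 + f))), name
    )
  }
  c(
    b("prevalence", 0.632, 0.796),
    b("pet_sens", 0.941, 0.974),
    b("pet_spec", 0.558, 0.715),
    b("mri_sens", 0.901, 0.945),
    b("mri_spec", 0.507, 0.668),
    b("p_recur_3yr_fn", 0.15, 0.35),
    b_abs("p_recur_3yr_treated", 0.03),
    b_abs("u_recurrence_free", 0.05),
    b_abs("u_recurrence", 0.05),
    b_abs("u_post_salvage", 0.05),
    g("cost_pet_test"), g("cost_mri_test"),
    g("cost_upper_rt"), g("cost_whole_rt"),
    g("cost_recurrence"), g("cost_followup")
  )
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_iter` joint parameter sets from the supplied distributions
#' (all other parameters at base), evaluates both strategies per
#' iteration, and computes the cost-effectiveness acceptability curve:
#' at each willingness-to-pay grid point, the proportion of iterations
#' in which the PET/CT-first strategy has the higher net monetary
#' benefit. Fully reproducible given the seed.
#'
#' @param params Base-case [cea_parameters()].
#' @param distributions Named list of distribution specs, default
#'   [default_psa_distributions()].
#' @param n_iter Number of Monte Carlo iterations (>= 1), default 1000.
#' @param seed Integer seed.
#' @param wtp_grid WTP grid (US$/QALY) for the acceptability curve.
#' @return A `psa_result` list: `draws` (per-iteration parameters),
#'   `results` (per-iteration costs/QALYs/increments), `ceac` (tibble
#'   `wtp`, `prob_pet_cost_effective`), `seed`.
#' @export
psa <- function(params, distributions = default_psa_distributions(params),
                n_iter = 1000, seed = 1L,
                wtp_grid = seq(0, 2e5, by = 1e4)) {
  stopifnot(inherits(params, "cea_parameters"), n_iter >= 1)
  unknown <- setdiff(names(distributions), names(params))
  if (length(unknown) > 0) {
    stop(sprintf(
      "distribution(s) for unknown parameter(s): %s",
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }
  probs_and_utils <- c(
    "prevalence", "pet_sens", "pet_spec", "mri_sens", "mri_spec",
    "p_recur_3yr_fn", "p_recur_3yr_treated", "p_mort_bg",
    "p_mort_rec_excess", "p_mort_post_excess", "u_recurrence_free",
    "u_recurrence", "u_post_salvage", "u_tox_whole_neck"
  )
  set.seed(seed)
  draws <- tibble::as_tibble(purrr::map(distributions, draw_parameter, n = n_iter))
  for (nm in intersect(names(draws), probs_and_utils)) {
    if (any(draws[[nm]] < 0 | draws[[nm]] > 1)) {
      stop(sprintf("distribution support for '%s' leaves [0, 1]", nm),
        call. = FALSE
      )
    }
  }
  results <- purrr::map_dfr(seq_len(n_iter), function(i) {
    p_i <- do.call(
      cea_parameters,
      utils::modifyList(unclass(params), as.list(draws[i, ]))
    )
    res <- evaluate_strategies(p_i)
    tibble::tibble(
      iteration = i,
      cost_pet = res$strategies$cost[1], qaly_pet = res$strategies$qaly[1],
      cost_mri = res$strategies$cost[2], qaly_mri = res$strategies$qaly[2],
      incremental_cost = res$incremental$incremental_cost,
      incremental_qaly = res$incremental$incremental_qaly
    )
  })
  ceac <- tibble::tibble(
    wtp = wtp_grid,
    prob_pet_cost_effective = vapply(wtp_grid, function(w) {
      mean(w * results$incremental_qaly - results$incremental_cost > 0)
    }, numeric(1))
  )
  structure(
    list(draws = draws, results = results, ceac = ceac, seed = seed),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  n <- nrow(x$results)
  cat(sprintf("PSA with %d iterations (seed %d)\n", n, x$seed))
  cat(sprintf(
    "  mean incremental cost %0.0f, mean incremental QALY %0.4f\n",
    mean(x$results$incremental_cost), mean(x$results$incremental_qaly)
  ))
  at_1e5 <- x$ceac$prob_pet_cost_effective[x$ceac$wtp == 1e5]
  if (length(at_1e5) == 1) {
    cat(sprintf(
      "  P(PET/CT cost-effective at $100,000/QALY) = %.1f%%\n",
      100 * at_1e5
    ))
  }
  invisible(x)
}
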