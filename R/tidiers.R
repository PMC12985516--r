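## broom-style tidy()/glance() methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble::tibble(
    truth = c("metastatic", "metastatic", "benign", "benign"),
    call = c("positive", "negative", "positive", "negative"),
    n = c(x$tp, x$fn, x$fp, x$tn)
  )
}

#' @export
tidy.paired_test <- function(x, ...) {
  out <- tibble::tibble(
    statistic = x$statistic, p.value = x$p.value,
    method = x$method
  )
  if (!is.null(x$estimate)) {
    est <- tibble::as_tibble(as.list(x$estimate))
    out <- dplyr::bind_cols(est, out)
  }
  out
}

#' @export
tidy.diag_metrics <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
tidy.paired_correctness <- function(x, ...) {
  tibble::tibble(
    cell = c(
      "both_correct", paste0(x$modality_a, "_only_correct"),
      paste0(x$modality_b, "_only_correct"), "both_incorrect"
    ),
    n = c(
      x$both_correct, x$a_only_correct, x$b_only_correct,
      x$both_incorrect
    ),
    proportion = .data$n / x$n
  )
}

#' @export
glance.paired_correctness <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_excluded = x$n_excluded,
    both_correct = x$both_correct,
    a_only_correct = x$a_only_correct,
    b_only_correct = x$b_only_correct,
    both_incorrect = x$both_incorrect,
    mcnemar_statistic = x$mcnemar$statistic,
    mcnemar_p = x$mcnemar$p.value
  )
}

#' @export
tidy.cea_result <- function(x, ...) x$strategies

#' @export
glance.cea_result <- function(x, ...) x$incremental

#' @export
tidy.psa_result <- function(x, ...) x$results

#' @export
glance.psa_result <- function(x, ...) {
  at_wtp <- x$ceac$prob_pet_cost_effective[
    which.min(abs(x$ceac$wtp - 1e5))
  ]
  tibble::tibble(
    n_iter = nrow(x$results),
    seed = x$seed,
    mean_incremental_cost = mean(x$results$incremental_cost),
    mean_incremental_qaly = mean(x$results$incremental_qaly),
    prob_pet_cost_effective_at_100k = at_wtp
  )
}

#' @export
tidy.decision_impact <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$dose_transitions, decision = "dose", .before = 1),
    dplyr::mutate(x$field_transitions,
      decision = "field",
      node_pathology = NA_character_, .before = 1
    )
  )
}

#' @export
glance.decision_impact <- function(x, ...) {
  dplyr::full_join(
    dplyr::select(
      x$dose_rates, "oncologist_id", "node_pathology",
      "escalation_rate", "deescalation_rate"
    ),
    dplyr::select(x$field_rates, "oncologist_id", "expansion_rate"),
    by = "oncologist_id"
  )
}
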