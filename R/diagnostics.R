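## Node-level diagnostic evaluation: confusion matrices at an ordinal
## score cutoff, accuracy metrics with Wilson CIs, and the three paired
## comparisons (McNemar, weighted generalized score, DeLong).

score_column <- function(nodes, modality) {
  col <- paste0(modality, "_score")
  if (!col %in% names(nodes)) {
    stop(sprintf("no score column '%s' in node table", col), call. = FALSE)
  }
  nodes[[col]]
}

#' Confusion counts at a score cutoff
#'
#' Binarizes an ordinal 0-4 confidence score: a node is called positive
#' iff its score is greater than or equal to `cutoff` (primary analysis
#' cutoff 2, i.e. scores 2-4 positive), and cross-tabulates the call
#' against the pathology reference standard.
#'
#' @param nodes Node table (see [validate_node_table()]).
#' @param modality `"pet"` or `"mri"` (names the `<modality>_score` column).
#' @param cutoff Integer in 1..4.
#' @return A `confusion_counts` object with fields `tp`, `fn`, `fp`, `tn`.
#' @examples
#' coh <- generate_fixture_cohort_a()
#' confusion_at_cutoff(coh, "pet", 2)
#' @export
confusion_at_cutoff <- function(nodes, modality = c("pet", "mri"), cutoff = 2) {
  modality <- match.arg(modality)
  if (nrow(nodes) == 0) stop("empty cohort", call. = FALSE)
  if (!(length(cutoff) == 1 && cutoff %in% 1:4)) {
    stop("cutoff must be a single integer in 1..4", call. = FALSE)
  }
  pos_call <- score_column(nodes, modality) >= cutoff
  diseased <- nodes$pathology == "metastatic"
  confusion_counts(
    tp = sum(diseased & pos_call),
    fn = sum(diseased & !pos_call),
    fp = sum(!diseased & pos_call),
    tn = sum(!diseased & !pos_call)
  )
}

#' @rdname confusion_at_cutoff
#' @param tp,fn,fp,tn Non-negative integer cell counts.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      truth = c("metastatic", "benign"),
      call = c("positive", "negative")
    )
  )
  m["benign", ] <- c(x$fp, x$tn)
  print(m)
  invisible(x)
}

#' Accuracy metrics with Wilson confidence intervals
#'
#' Computes accuracy, sensitivity, specificity, PPV and NPV from a 2x2
#' confusion table, each with a two-sided Wilson score interval. A metric
#' whose denominator is zero is reported as missing (NA), never as 0.
#'
#' @param conf A `confusion_counts` object.
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble (class `diag_metrics`) with columns `metric`,
#'   `numerator`, `denominator`, `estimate`, `conf.low`, `conf.high`.
#' @examples
#' diagnostic_metrics(confusion_counts(533, 22, 50, 89))
#' @export
diagnostic_metrics <- function(conf, conf_level = 0.95) {
  stopifnot(inherits(conf, "confusion_counts"))
  defs <- tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity", "ppv", "npv"),
    numerator = c(conf$tp + conf$tn, conf$tp, conf$tn, conf$tp, conf$tn),
    denominator = c(
      conf$tp + conf$fn + conf$fp + conf$tn,
      conf$tp + conf$fn, conf$fp + conf$tn,
      conf$tp + conf$fp, conf$tn + conf$fn
    )
  )
  ci <- purrr::map2(defs$numerator, defs$denominator, function(x, n) {
    if (n == 0) {
      tibble::tibble(
        estimate = NA_real_, conf.low = NA_real_,
        conf.high = NA_real_
      )
    } else {
      wilson_ci(x, n, conf_level)
    }
  })
  out <- dplyr::bind_cols(defs, dplyr::bind_rows(ci))
  class(out) <- c("diag_metrics", class(out))
  out
}

#' McNemar test on paired discordant counts
#'
#' Paired comparison of two classifiers on the same subjects, using only
#' the discordant cells b (first-only correct/positive) and c
#' (second-only). With the continuity correction (the default) the
#' statistic is `(max(|b - c| - 1, 0))^2 / (b + c)`, referred to a
#' chi-square distribution with 1 df; the correction term is clamped at
#' zero so `b == c` gives p = 1. Without correction the statistic is
#' `(b - c)^2 / (b + c)`. When `b + c == 0` the test is degenerate and
#' p = 1.
#'
#' @param n_a_only,n_b_only Non-negative discordant counts.
#' @param correction Apply the continuity correction (default TRUE).
#' @return A `paired_test` object (statistic, p.value, estimate, method).
#' @examples
#' mcnemar_paired(40, 21) # p = 0.021
#' @export
mcnemar_paired <- function(n_a_only, n_b_only, correction = TRUE) {
  if (n_a_only < 0 || n_b_only < 0) {
    stop("discordant counts must be non-negative", call. = FALSE)
  }
  b <- n_a_only
  c_ <- n_b_only
  if (b + c_ == 0) {
    stat <- 0
    p <- 1
  } else {
    num <- if (correction) max(abs(b - c_) - 1, 0) else abs(b - c_)
    stat <- num^2 / (b + c_)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  paired_test(
    statistic = stat, p_value = p,
    method = if (correction) "mcnemar_cc" else "mcnemar_plain",
    estimate = c(n_a_only = b, n_b_only = c_)
  )
}

paired_test <- function(statistic, p_value, method, estimate = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(
      statistic = statistic, p.value = p_value, method = method,
      estimate = estimate
    ),
    class = "paired_test"
  )
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired test (%s): statistic = %.4g, p = %.4g\n",
    x$method, x$statistic, x$p.value
  ))
  if (!is.null(x$estimate)) {
    cat(
      "  ",
      paste(names(x$estimate), signif(unlist(x$estimate), 4),
        sep = " = ", collapse = ", "
      ), "\n"
    )
  }
  invisible(x)
}

#' Weighted generalized score test for paired predictive values
#'
#' Compares the positive (or negative) predictive value of two binary
#' tests applied to the same subjects. The statistic is the generalized
#' score statistic of the identity-link marginal model for
#' `P(diseased | positive call)` with test identity as covariate, where
#' the common predictive value under the null is the positives-weighted
#' pooled estimate and the variance is cluster-robust (subjects are the
#' clusters, contributing one record per positive call). The NPV
#' comparison applies the same construction to negative calls and benign
#' outcome. Referred to chi-square with 1 df, two-sided.
#'
#' Subjects positive on neither test (for PPV; negative on neither, for
#' NPV) contribute nothing; with identical calls on every node the
#' statistic is 0 and p = 1.
#'
#' @param nodes Node table with pathology and both score columns.
#' @param which `"ppv"` or `"npv"`.
#' @param modality_a,modality_b Score-column prefixes, default pet/mri.
#' @param cutoff Positivity cutoff in 1..4, default 2.
#' @return A `paired_test` object; `estimate` carries both predictive
#'   values and their difference (a minus b).
#' @export
compare_predictive_values <- function(nodes, which = c("ppv", "npv"),
                                      modality_a = "pet", modality_b = "mri",
                                      cutoff = 2) {
  which <- match.arg(which)
  d <- nodes$pathology == "metastatic"
  ya <- score_column(nodes, modality_a) >= cutoff
  yb <- score_column(nodes, modality_b) >= cutoff
  if (which == "npv") {
    d <- !d
    ya <- !ya
    yb <- !yb
  }
  n_a <- sum(ya)
  n_b <- sum(yb)
  if (n_a == 0 || n_b == 0) {
    stop(sprintf(
      "undefined comparison: a modality has no %s calls",
      if (which == "ppv") "positive" else "negative"
    ), call. = FALSE)
  }
  pv_a <- sum(d & ya) / n_a
  pv_b <- sum(d & yb) / n_b
  ## Null (weighted pooled) predictive value and score for the test-b term.
  p0 <- (sum(d & ya) + sum(d & yb)) / (n_a + n_b)
  w <- n_b / (n_a + n_b)
  u <- sum(yb * (d - p0))
  ## Cluster-robust variance of the efficient score: each subject's
  ## contribution after projecting out the estimated common value.
  e <- (d - p0) * (yb - w * (ya + yb))
  v <- sum(e^2)
  if (v == 0) {
    stat <- 0
    p <- 1
  } else {
    stat <- u^2 / v
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  est <- c(pv_a, pv_b, pv_a - pv_b)
  names(est) <- c(
    paste0(which, "_", modality_a), paste0(which, "_", modality_b),
    "difference"
  )
  paired_test(
    statistic = stat, p_value = p,
    method = paste0("weighted_gs_", which), estimate = est
  )
}

## Mann-Whitney structural components: for each diseased score, the
## fraction of benign scores it exceeds (ties count 1/2), and vice versa.
delong_components <- function(pos, neg) {
  v10 <- vapply(
    pos,
    function(x) mean((neg < x) + 0.5 * (neg == x)),
    numeric(1)
  )
  v01 <- vapply(
    neg,
    function(y) mean((pos > y) + 0.5 * (pos == y)),
    numeric(1)
  )
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' DeLong comparison of two correlated AUCs
#'
#' AUC for each modality via the Mann-Whitney estimator on the ordinal
#' 0-4 scores (ties count one half), with the variance and covariance of
#' the paired AUCs estimated from DeLong structural components, and a
#' two-sided z test on the AUC difference.
#'
#' @param nodes Node table with pathology and both score columns.
#' @param modality_a,modality_b Score-column prefixes, default pet/mri.
#' @return A `paired_test` object; `estimate` carries both AUCs and the
#'   difference (a minus b).
#' @export
delong_paired_auc <- function(nodes, modality_a = "pet", modality_b = "mri") {
  diseased <- nodes$pathology == "metastatic"
  if (!any(diseased) || all(diseased)) {
    stop("both pathology classes must be present", call. = FALSE)
  }
  sa <- score_column(nodes, modality_a)
  sb <- score_column(nodes, modality_b)
  ca <- delong_components(sa[diseased], sa[!diseased])
  cb <- delong_components(sb[diseased], sb[!diseased])
  m <- sum(diseased)
  n <- sum(!diseased)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- ca$auc - cb$auc
  if (var_diff <= 0) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  p <- 2 * stats::pnorm(-abs(z))
  est <- c(ca$auc, cb$auc, diff)
  names(est) <- c(
    paste0("auc_", modality_a), paste0("auc_", modality_b),
    "difference"
  )
  paired_test(statistic = z, p_value = p, method = "delong", estimate = est)
}

#' Table-2-shaped paired comparison of two modalities
#'
#' Convenience wrapper running the full node-level comparison at one
#' cutoff: per-modality accuracy metrics with Wilson CIs, McNemar tests
#' for sensitivity and specificity (discordant calls within each
#' pathology class), weighted generalized score tests for PPV and NPV,
#' and the DeLong AUC comparison.
#'
#' @inheritParams compare_predictive_values
#' @param correction Continuity correction for the McNemar tests.
#' @return A tibble with one row per metric: point estimates and CI
#'   bounds for both modalities and the paired p-value.
#' @export
compare_modalities <- function(nodes, modality_a = "pet", modality_b = "mri",
                               cutoff = 2, correction = TRUE) {
  conf_a <- confusion_at_cutoff(nodes, modality_a, cutoff)
  conf_b <- confusion_at_cutoff(nodes, modality_b, cutoff)
  met_a <- diagnostic_metrics(conf_a)
  met_b <- diagnostic_metrics(conf_b)

  diseased <- nodes$pathology == "metastatic"
  pos_a <- score_column(nodes, modality_a) >= cutoff
  pos_b <- score_column(nodes, modality_b) >= cutoff
  ## Sensitivity: discordance among diseased; specificity: among benign.
  p_sens <- mcnemar_paired(
    sum(diseased & pos_a & !pos_b), sum(diseased & !pos_a & pos_b),
    correction
  )$p.value
  p_spec <- mcnemar_paired(
    sum(!diseased & !pos_a & pos_b), sum(!diseased & pos_a & !pos_b),
    correction
  )$p.value
  p_ppv <- compare_predictive_values(
    nodes, "ppv", modality_a, modality_b,
    cutoff
  )$p.value
  p_npv <- compare_predictive_values(
    nodes, "npv", modality_a, modality_b,
    cutoff
  )$p.value
  auc <- delong_paired_auc(nodes, modality_a, modality_b)

  metrics <- c(
    "accuracy", "sensitivity", "specificity", "ppv", "npv",
    "auc"
  )
  join <- function(m, suffix) {
    out <- m[, c("metric", "estimate", "conf.low", "conf.high")]
    names(out)[-1] <- paste0(names(out)[-1], suffix)
    out
  }
  tab <- dplyr::left_join(join(met_a, "_a"), join(met_b, "_b"), by = "metric")
  tab <- dplyr::bind_rows(
    tab,
    tibble::tibble(
      metric = "auc",
      estimate_a = auc$estimate[[1]], conf.low_a = NA_real_,
      conf.high_a = NA_real_,
      estimate_b = auc$estimate[[2]], conf.low_b = NA_real_,
      conf.high_b = NA_real_
    )
  )
  tab$p_value <- c(NA_real_, p_sens, p_spec, p_ppv, p_npv, auc$p.value)
  tab$modality_a <- modality_a
  tab$modality_b <- modality_b
  tab
}
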