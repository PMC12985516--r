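#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Controlled vocabularies shared across the pipeline.
NODE_LEVELS <- c("I", "II", "III", "IV", "Va", "Vb", "VII", "VIII")
PATHOLOGY_LEVELS <- c("metastatic", "benign")
N_STAGES <- c("N0", "N1", "N2", "N3")
LATERALITY_LEVELS <- c("left", "right", "unknown")
DOSE_LEVELS <- c("low", "intermediate", "radical") # <60 / 60-66 / >=66 Gy
FIELD_LEVELS <- c("upper_neck_only", "whole_neck")
MODALITIES <- c("pet", "mri")

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form interval obtained by inverting the score test, without
#' continuity correction. This is the interval used for all accuracy
#' metrics reported by [diagnostic_metrics()].
#'
#' @param x Number of successes (non-negative integer).
#' @param n Number of trials (positive integer).
#' @param conf_level Two-sided confidence level, default 0.95.
#' @return A tibble with columns `estimate`, `conf.low`, `conf.high`.
#' @examples
#' wilson_ci(622, 694) # 0.871 - 0.917
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(length(x) == length(n), all(x >= 0), all(n > 0), all(x <= n))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  tibble::tibble(
    estimate = p,
    conf.low = (centre - half) / denom,
    conf.high = (centre + half) / denom
  )
}

#' Largest-remainder apportionment of a total into integer counts
#'
#' Distributes `total` units over categories proportionally to `weights`,
#' assigning leftover units to the largest fractional remainders (ties
#' broken by category order). Guarantees the counts sum exactly to `total`.
#'
#' @param weights Non-negative numeric vector (need not sum to 1).
#' @param total Non-negative integer to apportion.
#' @return Integer vector of counts, same length and names as `weights`.
#' @export
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0, sum(weights) > 0 || total == 0)
  if (total == 0) {
    return(stats::setNames(integer(length(weights)), names(weights)))
  }
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

## Stable short hash of an arbitrary configuration object, stamped into
## every output artifact so runs are attributable.
config_hash <- function(x) rlang::hash(x)

## Repeat each row of `df` according to an integer count column, then drop it.
expand_counts <- function(df, count_col = "n") {
  idx <- rep.int(seq_len(nrow(df)), df[[count_col]])
  out <- df[idx, setdiff(names(df), count_col), drop = FALSE]
  tibble::as_tibble(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
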