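## Patient-level N-stage assignment (table-driven TNM rules), biopsy
## adjudication of the two modalities' stages, upper-neck-only
## eligibility, and tabulation of radiotherapy decision changes.

#' Anatomic class of each nodal level for TNM staging
#'
#' Maps the 8 nodal levels onto the classes the staging rules use:
#' retropharyngeal nodes (level VII) never trigger bilaterality-based
#' upstaging, all other levels count as cervical. Table-driven so an
#' alternative staging edition can be swapped in.
#'
#' @return Named character vector level -> class
#'   (`"cervical"`/`"retropharyngeal"`).
#' @export
tnm_level_classes <- function() {
  stats::setNames(
    c(
      "cervical", "cervical", "cervical", "cervical", "cervical",
      "cervical", "retropharyngeal", "cervical"
    ),
    NODE_LEVELS
  )
}

#' Assign a TNM N category from positive-node descriptors
#'
#' Implements the nodal staging rules of the 8th-edition TNM system for
#' nasopharyngeal carcinoma on one patient's positive nodes:
#'
#' * no positive nodes: N0;
#' * any node with short axis > 60 mm, or any positive node below the
#'   caudal border of the cricoid cartilage: N3;
#' * otherwise bilateral cervical involvement: N2;
#' * otherwise (unilateral cervical and/or retropharyngeal): N1.
#'
#' Retropharyngeal involvement (level VII) is N1 regardless of
#' laterality. A positive cervical node with unknown laterality is an
#' error: the stage is not guessable.
#'
#' @param positive_nodes Data frame of this patient's positive nodes
#'   with columns `level`, `laterality`, `short_axis_mm` (NA allowed)
#'   and optionally `below_caudal_cricoid` (logical, default FALSE).
#'   Zero rows stage as N0.
#' @param level_classes Level -> class map, default [tnm_level_classes()].
#' @return A single string `"N0"`..`"N3"`.
#' @examples
#' assign_n_stage(data.frame(
#'   level = "II", laterality = "right",
#'   short_axis_mm = 20
#' )) # "N1"
#' @export
assign_n_stage <- function(positive_nodes, level_classes = tnm_level_classes()) {
  if (is.null(positive_nodes) || nrow(positive_nodes) == 0) {
    return("N0")
  }
  check_vocab(positive_nodes$level, names(level_classes), "level")
  below <- if ("below_caudal_cricoid" %in% names(positive_nodes)) {
    positive_nodes[["below_caudal_cricoid"]]
  } else {
    rep(FALSE, nrow(positive_nodes))
  }
  below[is.na(below)] <- FALSE
  size <- if ("short_axis_mm" %in% names(positive_nodes)) {
    positive_nodes[["short_axis_mm"]]
  } else {
    rep(NA_real_, nrow(positive_nodes))
  }
  if (any(size > 60, na.rm = TRUE) || any(below)) {
    return("N3")
  }
  cls <- level_classes[positive_nodes$level]
  cerv <- cls == "cervical"
  if (any(cerv)) {
    lat <- positive_nodes$laterality[cerv]
    if (any(is.na(lat) | lat == "unknown")) {
      stop("positive cervical node with unknown laterality: N stage not determinable",
        call. = FALSE
      )
    }
    if (all(c("left", "right") %in% lat)) {
      return("N2")
    }
  }
  "N1"
}

#' Upper-neck-only irradiation eligibility from the N category
#'
#' Elective sparing of the lower neck is recommended for N0-N1 disease
#' only; N2-N3 patients receive whole-neck irradiation. Vectorized.
#'
#' @param n_stage Character vector of N categories (`"N0"`..`"N3"`).
#' @return Character vector, `"upper_neck_only"` or `"whole_neck"`.
#' @examples
#' eligibility_upper_neck(c("N0", "N1", "N2", "N3"))
#' @export
eligibility_upper_neck <- function(n_stage) {
  check_vocab(n_stage, N_STAGES, "n_stage")
  ifelse(n_stage %in% c("N0", "N1"), "upper_neck_only", "whole_neck")
}

#' Adjudicate paired N stages against the biopsy reference
#'
#' Per patient, a modality is "correct" iff its N category equals the
#' biopsy-adjudicated truth (exact category equality, not the binned
#' N0-1 vs N2-3 comparison, which is a separate derived output). Records
#' with missing truth are excluded and counted.
#'
#' @param records Staging table (see [validate_staging_table()]).
#' @param modality_a,modality_b N-stage columns to compare, default
#'   `pet_n` and `mri_n`.
#' @return A `paired_correctness` object with the four cell counts
#'   (`both_correct`, `a_only_correct`, `b_only_correct`,
#'   `both_incorrect`), `n_excluded`, and the McNemar test on the
#'   discordant cells.
#' @export
adjudicate_staging <- function(records, modality_a = "pet_n",
                               modality_b = "mri_n") {
  records <- validate_staging_table(records)
  keep <- !is.na(records$true_n)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf(
      "adjudicate_staging: excluded %d record(s) with missing true_n",
      n_excluded
    ))
  }
  rec <- records[keep, ]
  a_ok <- rec[[modality_a]] == rec$true_n
  b_ok <- rec[[modality_b]] == rec$true_n
  out <- list(
    both_correct = sum(a_ok & b_ok),
    a_only_correct = sum(a_ok & !b_ok),
    b_only_correct = sum(!a_ok & b_ok),
    both_incorrect = sum(!a_ok & !b_ok),
    n = nrow(rec),
    n_excluded = n_excluded,
    modality_a = modality_a,
    modality_b = modality_b
  )
  out$mcnemar <- mcnemar_paired(out$a_only_correct, out$b_only_correct)
  structure(out, class = "paired_correctness")
}

#' @export
print.paired_correctness <- function(x, ...) {
  cat(sprintf(
    "Paired correctness (%s vs %s), n = %d:\n", x$modality_a,
    x$modality_b, x$n
  ))
  cat(sprintf(
    "  both correct %d | %s only %d | %s only %d | both incorrect %d\n",
    x$both_correct, x$modality_a, x$a_only_correct, x$modality_b,
    x$b_only_correct, x$both_incorrect
  ))
  cat(sprintf("  McNemar (cc) p = %.4g\n", x$mcnemar$p.value))
  invisible(x)
}

#' Accuracy of upper-neck-only recommendations per modality
#'
#' A modality's recommendation is correct when its eligibility call
#' (from its N category, via [eligibility_upper_neck()]) matches the
#' eligibility implied by the adjudicated true N category, i.e. the
#' binned N0-1 vs N2-3 comparison.
#'
#' @inheritParams adjudicate_staging
#' @return A tibble with one row per modality: `n_correct`, `n`,
#'   `proportion`, plus the McNemar p-value comparing the two modalities'
#'   recommendation correctness as an attribute-free extra row-wise
#'   column `p_value` (same value on both rows).
#' @export
recommendation_accuracy <- function(records, modality_a = "pet_n",
                                    modality_b = "mri_n") {
  records <- records[!is.na(records$true_n), ]
  truth <- eligibility_upper_neck(records$true_n)
  a_ok <- eligibility_upper_neck(records[[modality_a]]) == truth
  b_ok <- eligibility_upper_neck(records[[modality_b]]) == truth
  p <- mcnemar_paired(sum(a_ok & !b_ok), sum(!a_ok & b_ok))$p.value
  tibble::tibble(
    modality = c(modality_a, modality_b),
    n_correct = c(sum(a_ok), sum(b_ok)),
    n = nrow(records),
    proportion = c(mean(a_ok), mean(b_ok)),
    p_value = p
  )
}

dose_rank <- function(x) match(x, DOSE_LEVELS)

#' Tabulate radiotherapy decision changes before/after modality review
#'
#' Summarizes per-oncologist transition matrices for the dose category
#' (3x3, within each pathology class, per node) and the irradiation
#' field (2x2, per patient), together with the derived rates:
#' dose escalation / de-escalation (proportion of nodes in a pathology
#' class whose dose category moved up / down the ordinal scale low <
#' intermediate < radical) and field expansion (proportion of patients
#' switching upper-neck-only to whole-neck).
#'
#' @param decision_records Decision table (see
#'   [validate_decision_table()]). Duplicate (patient, oncologist,
#'   node) rows are an error.
#' @return A `decision_impact` list: `dose_transitions` (long tibble),
#'   `field_transitions` (long tibble), `dose_rates`, `field_rates`.
#' @export
decision_impact <- function(decision_records) {
  rec <- validate_decision_table(decision_records)
  key_cols <- intersect(
    c("patient_id", "oncologist_id", "node_id"),
    names(rec)
  )
  if (anyDuplicated(rec[key_cols])) {
    stop("duplicate (patient, oncologist, node) decision records",
      call. = FALSE
    )
  }

  dose_transitions <- rec |>
    dplyr::count(
      .data$oncologist_id, .data$node_pathology,
      from = factor(.data$dose_before, DOSE_LEVELS),
      to = factor(.data$dose_after, DOSE_LEVELS),
      .drop = FALSE
    ) |>
    dplyr::mutate(from = as.character(from), to = as.character(to))

  dose_rates <- rec |>
    dplyr::group_by(.data$oncologist_id, .data$node_pathology) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_escalated = sum(dose_rank(.data$dose_after) >
        dose_rank(.data$dose_before)),
      n_deescalated = sum(dose_rank(.data$dose_after) <
        dose_rank(.data$dose_before)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      escalation_rate = .data$n_escalated / .data$n,
      deescalation_rate = .data$n_deescalated / .data$n
    )

  ## Field decisions are per patient: collapse duplicate node rows
  ## (a patient's field call is common to their nodes).
  fld <- rec |>
    dplyr::distinct(
      .data$patient_id, .data$oncologist_id,
      .data$field_before, .data$field_after
    )
  if (anyDuplicated(fld[c("patient_id", "oncologist_id")])) {
    stop("conflicting field decisions within a (patient, oncologist) pair",
      call. = FALSE
    )
  }
  field_transitions <- fld |>
    dplyr::count(
      .data$oncologist_id,
      from = factor(.data$field_before, FIELD_LEVELS),
      to = factor(.data$field_after, FIELD_LEVELS),
      .drop = FALSE
    ) |>
    dplyr::mutate(from = as.character(from), to = as.character(to))

  field_rates <- fld |>
    dplyr::group_by(.data$oncologist_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_expanded = sum(.data$field_before == "upper_neck_only" &
        .data$field_after == "whole_neck"),
      .groups = "drop"
    ) |>
    dplyr::mutate(expansion_rate = .data$n_expanded / .data$n)

  structure(
    list(
      dose_transitions = dose_transitions,
      dose_rates = dose_rates,
      field_transitions = field_transitions,
      field_rates = field_rates
    ),
    class = "decision_impact"
  )
}

#' @export
print.decision_impact <- function(x, ...) {
  cat("Radiotherapy decision impact\n\nDose escalation/de-escalation:\n")
  print(x$dose_rates)
  cat("\nField expansion (upper-neck-only -> whole-neck):\n")
  print(x$field_rates)
  invisible(x)
}

#' Stage every patient in a node table
#'
#' Groups positive calls of one modality (score >= cutoff) by patient
#' and applies [assign_n_stage()]. Patients with no positive nodes
#' stage as N0.
#'
#' @param nodes Node table including `laterality` (and optionally
#'   `short_axis_mm`, `below_caudal_cricoid`).
#' @param modality `"pet"` or `"mri"`.
#' @param cutoff Positivity cutoff, default 2.
#' @return Tibble with `patient_id` and `n_stage`.
#' @export
stage_patients <- function(nodes, modality = c("pet", "mri"), cutoff = 2) {
  modality <- match.arg(modality)
  pos <- nodes[score_column(nodes, modality) >= cutoff, , drop = FALSE]
  ids <- unique(nodes$patient_id)
  staged <- pos |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(n_stage = assign_n_stage(df))
    }) |>
    dplyr::ungroup()
  dplyr::left_join(tibble::tibble(patient_id = ids), staged,
    by = "patient_id"
  ) |>
    dplyr::mutate(n_stage = dplyr::coalesce(.data$n_stage, "N0"))
}
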