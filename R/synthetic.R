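## Synthetic cohorts. Two kinds:
##   * exact fixture generators that reproduce requested summary counts
##     cell-for-cell (diagnostic cohort, staging cohort, decision cohort);
##   * a stochastic paired-cohort simulator with a Gaussian-copula joint
##     model for the two modalities' latent suspicion.

#' Published level distribution of biopsied nodes, by pathology class
#'
#' Proportions of nodal levels among 555 metastatic and 139 benign
#' biopsied nodes in the diagnostic cohort; used as the default level
#' distribution of the fixture generator.
#'
#' @return Named list with numeric vectors `metastatic` and `benign`
#'   (each summing to 1 over the 8 levels).
#' @export
cohort_a_level_distribution <- function() {
  list(
    metastatic = stats::setNames(
      c(13, 474, 22, 4, 17, 4, 2, 19) / 555, NODE_LEVELS
    ),
    benign = stats::setNames(
      c(11, 92, 7, 4, 1, 0, 0, 24) / 139, NODE_LEVELS
    )
  )
}

#' Specification of a paired diagnostic cohort
#'
#' Collects everything the generators need: class sizes, per-modality
#' operating characteristics, the latent agreement correlation, the
#' per-class level distributions, and the cutpoints that band a latent
#' suspicion percentile into the 0-4 confidence score. The defaults
#' describe the study conditions of the diagnostic cohort: 555
#' metastatic / 139 benign nodes, PET sensitivity/specificity
#' 0.960/0.640 and MRI 0.926/0.590 at cutoff >= 2.
#'
#' `score_band_cutpoints` are proportions splitting the positive band
#' into scores 2/3/4 (and the negative band into 0/1): given a call, the
#' latent percentile within the band selects the score, so cutoff >= 2
#' always reproduces the binary call.
#'
#' @param n_pos,n_neg Class sizes.
#' @param sens,spec Named probability vectors (`pet`, `mri`).
#' @param agreement_rho Latent Gaussian-copula correlation in \[-1, 1\].
#' @param level_distribution As [cohort_a_level_distribution()].
#' @param positive_band,negative_band Score proportions within the
#'   positive (scores 2,3,4) and negative (scores 0,1) bands; each must
#'   sum to 1.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_pos = 555, n_neg = 139,
                        sens = c(pet = 0.960, mri = 0.926),
                        spec = c(pet = 0.640, mri = 0.590),
                        agreement_rho = 0.5,
                        level_distribution = cohort_a_level_distribution(),
                        positive_band = c(`2` = 0.2, `3` = 0.3, `4` = 0.5),
                        negative_band = c(`0` = 0.5, `1` = 0.5),
                        seed = 1L) {
  stopifnot(
    n_pos >= 0, n_neg >= 0,
    all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1),
    all(MODALITIES %in% names(sens)), all(MODALITIES %in% names(spec)),
    abs(agreement_rho) <= 1,
    abs(sum(positive_band) - 1) < 1e-8, abs(sum(negative_band) - 1) < 1e-8,
    abs(sum(level_distribution$metastatic) - 1) < 1e-6,
    abs(sum(level_distribution$benign) - 1) < 1e-6
  )
  structure(
    list(
      n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
      sens = sens, spec = spec, agreement_rho = agreement_rho,
      level_distribution = level_distribution,
      positive_band = positive_band, negative_band = negative_band,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

## Deterministic score assignment: within a call band, allocate scores
## in fixed proportions by largest remainder; a seeded permutation
## decides which node gets which score.
band_scores <- function(n, positive, band_pos, band_neg) {
  band <- if (positive) band_pos else band_neg
  counts <- largest_remainder(band, n)
  scores <- rep(as.integer(names(counts)), counts)
  scores[sample.int(n, n)] # rng state already seeded by caller
}

## Joint correct/incorrect allocation for one pathology class given the
## two modalities' correct-call counts and a both-correct overlap.
joint_cells <- function(n, correct_a, correct_b, both_correct) {
  a_only <- correct_a - both_correct
  b_only <- correct_b - both_correct
  neither <- n - both_correct - a_only - b_only
  if (a_only < 0 || b_only < 0 || neither < 0 || both_correct < 0) {
    stop("infeasible joint allocation: requested overlap inconsistent with marginals",
      call. = FALSE
    )
  }
  c(both = both_correct, a_only = a_only, b_only = b_only, neither = neither)
}

#' Exact fixture: paired diagnostic cohort with requested confusion counts
#'
#' Builds a node table whose recomputed per-modality 2x2 confusion
#' counts at cutoff >= 2 match the request cell-for-cell. The defaults
#' reconstruct the published diagnostic cohort: PET
#' (TP,FN,FP,TN) = (533, 22, 50, 89) and MRI (514, 41, 57, 82) on
#' 555 metastatic / 139 benign nodes (confusion counts obtained by
#' rounding the printed sensitivities/specificities times the class
#' totals; they reproduce the printed 622/694 and 596/694 correctly
#' classified nodes exactly).
#'
#' The joint (PET x MRI) cells are unpublished, so the
#' both-correct overlap per class is a free parameter; the default is
#' the maximum-agreement allocation. Scores within a call band and
#' level labels (largest-remainder apportionment of the class level
#' distribution) are assigned deterministically given the seed.
#'
#' @param pet_counts,mri_counts `confusion_counts` for each modality.
#' @param both_correct_pos,both_correct_neg Both-modalities-correct
#'   counts among metastatic / benign nodes; `NULL` = maximum feasible.
#' @param spec A [cohort_spec()] supplying level distribution, score
#'   bands and seed.
#' @param n_patients Number of distinct patients to spread nodes over
#'   (some patients contribute two nodes), default 649.
#' @return A validated node tibble.
#' @export
generate_fixture_cohort_a <- function(pet_counts = confusion_counts(533, 22, 50, 89),
                                      mri_counts = confusion_counts(514, 41, 57, 82),
                                      both_correct_pos = NULL,
                                      both_correct_neg = NULL,
                                      spec = cohort_spec(),
                                      n_patients = 649) {
  n_pos <- pet_counts$tp + pet_counts$fn
  n_neg <- pet_counts$fp + pet_counts$tn
  if (n_pos != mri_counts$tp + mri_counts$fn ||
    n_neg != mri_counts$fp + mri_counts$tn) {
    stop("modalities disagree on class totals", call. = FALSE)
  }
  both_correct_pos <- both_correct_pos %||% min(pet_counts$tp, mri_counts$tp)
  both_correct_neg <- both_correct_neg %||% min(pet_counts$tn, mri_counts$tn)
  cells_pos <- joint_cells(n_pos, pet_counts$tp, mri_counts$tp, both_correct_pos)
  cells_neg <- joint_cells(n_neg, pet_counts$tn, mri_counts$tn, both_correct_neg)

  set.seed(spec$seed)
  ## correct call = positive for metastatic nodes, negative for benign
  build_class <- function(cells, pathology) {
    correct_a <- rep(c(TRUE, TRUE, FALSE, FALSE), cells)
    correct_b <- rep(c(TRUE, FALSE, TRUE, FALSE), cells)
    pos_a <- if (pathology == "metastatic") correct_a else !correct_a
    pos_b <- if (pathology == "metastatic") correct_b else !correct_b
    n <- length(pos_a)
    pet_score <- integer(n)
    mri_score <- integer(n)
    for (positive in c(TRUE, FALSE)) {
      ia <- which(pos_a == positive)
      if (length(ia)) {
        pet_score[ia] <- band_scores(
          length(ia), positive,
          spec$positive_band, spec$negative_band
        )
      }
      ib <- which(pos_b == positive)
      if (length(ib)) {
        mri_score[ib] <- band_scores(
          length(ib), positive,
          spec$positive_band, spec$negative_band
        )
      }
    }
    levels_n <- largest_remainder(
      spec$level_distribution[[pathology]], n
    )
    tibble::tibble(
      level = sample(rep(names(levels_n), levels_n)),
      pathology = pathology,
      mri_score = mri_score,
      pet_score = pet_score
    )
  }
  nodes <- dplyr::bind_rows(
    build_class(cells_pos, "metastatic"),
    build_class(cells_neg, "benign")
  )
  n <- nrow(nodes)
  n_patients <- min(n_patients, n)
  ## first (n - n_patients) patients contribute two nodes each
  patient_of_node <- c(
    seq_len(n - n_patients),
    seq_len(n_patients)
  )
  nodes <- nodes |>
    dplyr::mutate(
      node_id = sprintf("node_%04d", seq_len(n)),
      patient_id = sprintf("pt_%04d", patient_of_node),
      laterality = sample(c("left", "right"), n, replace = TRUE),
      .before = 1
    )
  validate_node_table(nodes)
}

#' Stochastic paired cohort from a Gaussian-copula latent model
#'
#' Samples `n` nodes: pathology with prevalence
#' `n_pos / (n_pos + n_neg)`; per node, a bivariate standard-normal
#' latent suspicion pair with correlation `agreement_rho`, thresholded
#' so each modality's marginal positive-call probability equals its
#' sensitivity (metastatic nodes) or one minus its specificity (benign
#' nodes); latent percentiles are then banded into 0-4 scores by the
#' spec's score-band proportions. Identical seeds give identical
#' cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param n Number of nodes, >= 1.
#' @param seed Integer seed (defaults to the spec's seed).
#' @return A validated node tibble.
#' @export
sample_paired_cohort <- function(spec, n, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"), n >= 1)
  if (abs(spec$agreement_rho) > 1) {
    stop("agreement_rho must lie in [-1, 1]", call. = FALSE)
  }
  set.seed(seed)
  prevalence <- spec$n_pos / (spec$n_pos + spec$n_neg)
  diseased <- stats::runif(n) < prevalence
  rho <- spec$agreement_rho
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  ## marginal positive-call probability per node and modality
  p_pos <- function(modality) {
    ifelse(diseased, spec$sens[[modality]], 1 - spec$spec[[modality]])
  }
  ## positive call iff latent percentile falls in the top p_pos mass
  u_pet <- stats::pnorm(z1)
  u_mri <- stats::pnorm(z2)
  score_from_u <- function(u, p) {
    pos <- u > 1 - p
    ## percentile within the band, mapped through the band proportions
    within <- ifelse(pos, (u - (1 - p)) / pmax(p, 1e-12),
      u / pmax(1 - p, 1e-12)
    )
    brk_pos <- cumsum(spec$positive_band)
    brk_neg <- cumsum(spec$negative_band)
    ifelse(pos,
      2L + findInterval(within, brk_pos[-length(brk_pos)] + 1e-15),
      0L + findInterval(within, brk_neg[-length(brk_neg)] + 1e-15)
    )
  }
  pet_score <- score_from_u(u_pet, p_pos("pet"))
  mri_score <- score_from_u(u_mri, p_pos("mri"))
  pathology <- ifelse(diseased, "metastatic", "benign")
  level <- character(n)
  for (cls in PATHOLOGY_LEVELS) {
    idx <- pathology == cls
    if (any(idx)) {
      level[idx] <- sample(NODE_LEVELS, sum(idx),
        replace = TRUE,
        prob = spec$level_distribution[[cls]]
      )
    }
  }
  validate_node_table(tibble::tibble(
    node_id = sprintf("sim_%06d", seq_len(n)),
    patient_id = sprintf("simpt_%06d", seq_len(n)),
    level = level,
    pathology = pathology,
    mri_score = as.integer(mri_score),
    pet_score = as.integer(pet_score),
    laterality = sample(c("left", "right"), n, replace = TRUE)
  ))
}

#' Default stage layout of the staging-cohort fixture
#'
#' A joint allocation of (true, PET, MRI) N categories over 503
#' patients that simultaneously reproduces every printed patient-level
#' summary: the paired-correctness table (423 both correct / 40 PET
#' only / 21 MRI only / 19 both incorrect) and its McNemar p = 0.021,
#' the upper-neck-only recommendation accuracies (PET 472/503, MRI
#' 447/503 under the N0-1 vs N2-3 binning) and their McNemar p = 0.003
#' (which pins the binned discordant cells to 45 vs 20), and the
#' printed N0/N1 margins (PET 21/179, MRI 19/170). The N2/N3 split is
#' not published and is fixed here by choice.
#'
#' @return Tibble with columns `true_n`, `pet_n`, `mri_n`, `n`.
#' @export
cohort_b_layout <- function() {
  tibble::tribble(
    ~true_n, ~pet_n, ~mri_n, ~n,
    "N0", "N0", "N0", 17,
    "N1", "N1", "N1", 139,
    "N2", "N2", "N2", 237,
    "N3", "N3", "N3", 30,
    "N1", "N1", "N2", 28, # PET-only correct
    "N2", "N2", "N1", 12, # PET-only correct
    "N1", "N0", "N1", 4, # MRI-only correct, PET bin-correct
    "N1", "N2", "N1", 10, # MRI-only correct
    "N2", "N1", "N2", 7, # MRI-only correct
    "N2", "N3", "N1", 5, # both incorrect, PET bin-correct
    "N2", "N1", "N3", 3, # both incorrect, MRI bin-correct
    "N1", "N2", "N2", 9, # both incorrect
    "N2", "N1", "N0", 2 # both incorrect
  )
}

#' Exact fixture: patient-level staging cohort
#'
#' Emits one record per patient whose (PET correct?, MRI correct?)
#' pattern reproduces the requested paired-correctness counts exactly.
#' With `stage_detail = cohort_b_layout()` (the default when the
#' requested counts are the published 423/40/21/19) the fixture also
#' reproduces the printed N0/N1 margins and binned recommendation
#' accuracies. For other counts, a minimal generic layout is used
#' (correct = N1; a wrong stage = N2 against truth N1, or N1 against
#' truth N2).
#'
#' @param both_correct,a_only,b_only,both_incorrect Cell counts
#'   (a = PET, b = MRI).
#' @param stage_detail Optional layout tibble (`true_n`, `pet_n`,
#'   `mri_n`, `n`) overriding the built-in choice; its cells must be
#'   consistent with the four counts.
#' @param seed Seed for the record-order permutation.
#' @return A validated staging tibble with 503 (or the requested
#'   total) rows.
#' @export
generate_staging_fixture_b <- function(both_correct = 423, a_only = 40,
                                       b_only = 21, both_incorrect = 19,
                                       stage_detail = NULL, seed = 1L) {
  counts <- c(both_correct, a_only, b_only, both_incorrect)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(stage_detail)) {
    if (identical(as.integer(counts), c(423L, 40L, 21L, 19L))) {
      stage_detail <- cohort_b_layout()
    } else {
      stage_detail <- tibble::tribble(
        ~true_n, ~pet_n, ~mri_n, ~n,
        "N1", "N1", "N1", both_correct,
        "N1", "N1", "N2", a_only,
        "N1", "N2", "N1", b_only,
        "N1", "N2", "N2", both_incorrect
      )
    }
  }
  cell_of <- function(pet_ok, mri_ok) {
    dplyr::case_when(
      pet_ok & mri_ok ~ "both_correct",
      pet_ok ~ "a_only",
      mri_ok ~ "b_only",
      .default = "both_incorrect"
    )
  }
  got <- stage_detail |>
    dplyr::mutate(cell = cell_of(
      .data$pet_n == .data$true_n,
      .data$mri_n == .data$true_n
    )) |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(n = sum(.data$n))
  want <- stats::setNames(
    counts, c("both_correct", "a_only", "b_only", "both_incorrect")
  )
  for (cell in names(want)) {
    have <- got$n[got$cell == cell]
    have <- if (length(have)) have else 0L
    if (have != want[[cell]]) {
      stop(sprintf(
        "stage_detail inconsistent with counts: %s has %d, expected %d",
        cell, have, want[[cell]]
      ), call. = FALSE)
    }
  }
  set.seed(seed)
  out <- expand_counts(stage_detail)
  out <- out[sample.int(nrow(out)), ]
  out$patient_id <- sprintf("stg_%04d", seq_len(nrow(out)))
  validate_staging_table(out[, c("patient_id", "mri_n", "pet_n", "true_n")])
}

#' Default decision-cohort transition specification
#'
#' Before/after transition counts for the three radiation oncologists in
#' the decision cohort (24 metastatic and 43 benign nodes from 62
#' patients), chosen to reproduce every printed rate: metastatic dose
#' escalation up to 16.7\% (4/24), benign de-escalation 4.7\% (2/43) for
#' each oncologist, benign escalation 7.0\%/0\%/11.6\%, and field
#' expansion (upper-neck-only to whole-neck) 6.4\%, 8.0\% and 11.3\%
#' (4, 5 and 7 of 62 patients). Unpublished cells (the
#' before-distributions and identity diagonals) are fixed here by
#' choice.
#'
#' @return A list with `dose` (tibble: oncologist_id, node_pathology,
#'   from, to, n) and `field` (tibble: oncologist_id, from, to, n).
#' @export
cohort_c_spec <- function() {
  dose <- tibble::tribble(
    ~oncologist_id, ~node_pathology, ~from, ~to, ~n,
    # metastatic, n = 24 per oncologist
    1L, "metastatic", "low", "low", 2,
    1L, "metastatic", "intermediate", "intermediate", 5,
    1L, "metastatic", "intermediate", "radical", 2,
    1L, "metastatic", "radical", "radical", 15,
    2L, "metastatic", "low", "low", 3,
    2L, "metastatic", "intermediate", "intermediate", 5,
    2L, "metastatic", "intermediate", "radical", 3,
    2L, "metastatic", "radical", "radical", 13,
    3L, "metastatic", "low", "intermediate", 1,
    3L, "metastatic", "intermediate", "intermediate", 4,
    3L, "metastatic", "intermediate", "radical", 3,
    3L, "metastatic", "radical", "radical", 16,
    # benign, n = 43 per oncologist
    1L, "benign", "low", "low", 2,
    1L, "benign", "low", "intermediate", 1,
    1L, "benign", "intermediate", "intermediate", 10,
    1L, "benign", "intermediate", "radical", 2,
    1L, "benign", "radical", "intermediate", 2,
    1L, "benign", "radical", "radical", 26,
    2L, "benign", "low", "low", 4,
    2L, "benign", "intermediate", "intermediate", 12,
    2L, "benign", "radical", "intermediate", 2,
    2L, "benign", "radical", "radical", 25,
    3L, "benign", "low", "low", 3,
    3L, "benign", "low", "intermediate", 2,
    3L, "benign", "intermediate", "intermediate", 9,
    3L, "benign", "intermediate", "radical", 3,
    3L, "benign", "radical", "intermediate", 2,
    3L, "benign", "radical", "radical", 24
  )
  field <- tibble::tribble(
    ~oncologist_id, ~from, ~to, ~n,
    1L, "upper_neck_only", "upper_neck_only", 5,
    1L, "upper_neck_only", "whole_neck", 4,
    1L, "whole_neck", "whole_neck", 53,
    2L, "upper_neck_only", "upper_neck_only", 15,
    2L, "upper_neck_only", "whole_neck", 5,
    2L, "whole_neck", "whole_neck", 42,
    3L, "upper_neck_only", "upper_neck_only", 45,
    3L, "upper_neck_only", "whole_neck", 7,
    3L, "whole_neck", "whole_neck", 10
  )
  list(dose = dose, field = field)
}

#' Exact fixture: radiotherapy decision cohort
#'
#' Emits decision records whose recomputed per-oncologist dose and field
#' transition matrices match the requested counts exactly. Dose
#' transitions are per node; field transitions are per patient (each
#' patient's nodes share the field decision).
#'
#' @param transition_specs As returned by [cohort_c_spec()].
#' @return A validated decision tibble (one row per node x oncologist,
#'   with a `node_id` column).
#' @export
generate_decision_fixture_c <- function(transition_specs = cohort_c_spec()) {
  dose <- transition_specs$dose
  field <- transition_specs$field
  if (any(dose$n < 0) || any(field$n < 0)) {
    stop("transition counts must be non-negative", call. = FALSE)
  }
  check_vocab(dose$from, DOSE_LEVELS, "dose from")
  check_vocab(dose$to, DOSE_LEVELS, "dose to")
  check_vocab(field$from, FIELD_LEVELS, "field from")
  check_vocab(field$to, FIELD_LEVELS, "field to")

  per_onc <- lapply(split(dose, dose$oncologist_id), function(d) {
    rows <- expand_counts(d)
    n_nodes <- nrow(rows)
    f <- expand_counts(field[field$oncologist_id == d$oncologist_id[1], ])
    n_pat <- nrow(f)
    ## map nodes onto patients: first patients carry the extra nodes
    node_patient <- c(
      seq_len(n_nodes - n_pat),
      seq_len(n_pat)
    )
    tibble::tibble(
      patient_id = sprintf("dec_pt_%02d", node_patient),
      oncologist_id = rows$oncologist_id,
      node_id = sprintf("dec_node_%02d", seq_len(n_nodes)),
      node_pathology = rows$node_pathology,
      dose_before = rows$from,
      dose_after = rows$to,
      field_before = f$from[node_patient],
      field_after = f$to[node_patient]
    )
  })
  validate_decision_table(dplyr::bind_rows(per_onc))
}
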