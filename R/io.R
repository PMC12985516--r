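## Delimited-text readers/writers and run configuration.
##
## All tables are comma-separated with a header; tab-separated input is
## accepted transparently. Required fields are validated against the
## controlled vocabularies; unknown extra columns pass through untouched.

read_delimited <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE
  )
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
}

## Report the first offending row in error messages so bad input is
## locatable without re-opening the file.
check_vocab <- function(values, vocab, field, allow_na = FALSE) {
  bad <- !(values %in% vocab)
  if (allow_na) bad <- bad & !is.na(values)
  if (any(bad)) {
    row <- which(bad)[1]
    stop(sprintf(
      "invalid %s '%s' in row %d (allowed: %s)",
      field, values[row], row, paste(vocab, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(values)
}

check_score <- function(values, field) {
  bad <- is.na(values) | values < 0 | values > 4 | values != floor(values)
  if (any(bad)) {
    row <- which(bad)[1]
    stop(sprintf(
      "invalid %s '%s' in row %d (scores are integers 0-4)",
      field, values[row], row
    ), call. = FALSE)
  }
  invisible(values)
}

#' Validate a node-level table
#'
#' Checks the invariants of the node record: confidence scores are
#' integers 0-4 for both modalities, nodal level comes from the 8-level
#' vocabulary (I, II, III, IV, Va, Vb, VII, VIII) and every node carries
#' exactly one pathology label. Optional columns (`laterality`,
#' `short_axis_mm`) are validated when present; extra columns are kept.
#'
#' @param nodes Data frame with columns `node_id`, `patient_id`, `level`,
#'   `pathology`, `mri_score`, `pet_score`.
#' @return The validated table as a tibble, row order preserved.
#' @export
validate_node_table <- function(nodes) {
  require_columns(
    nodes,
    c("node_id", "patient_id", "level", "pathology", "mri_score", "pet_score"),
    "node table"
  )
  check_vocab(nodes$level, NODE_LEVELS, "level")
  check_vocab(nodes$pathology, PATHOLOGY_LEVELS, "pathology")
  check_score(nodes$mri_score, "mri_score")
  check_score(nodes$pet_score, "pet_score")
  nodes$mri_score <- as.integer(nodes$mri_score)
  nodes$pet_score <- as.integer(nodes$pet_score)
  if ("laterality" %in% names(nodes)) {
    check_vocab(nodes$laterality, LATERALITY_LEVELS, "laterality")
  }
  if ("short_axis_mm" %in% names(nodes)) {
    bad <- !is.na(nodes$short_axis_mm) & nodes$short_axis_mm < 0
    if (any(bad)) {
      stop(sprintf("negative short_axis_mm in row %d", which(bad)[1]),
        call. = FALSE
      )
    }
  }
  tibble::as_tibble(nodes)
}

#' Read a node-level table from delimited text
#'
#' @param path Path to a CSV (or TSV) file with a header naming the node
#'   record fields.
#' @return A validated tibble of node records (see [validate_node_table()]).
#' @export
read_node_table <- function(path) validate_node_table(read_delimited(path))

#' Validate / read a patient-level staging table
#'
#' Each row carries the per-modality N stage and the biopsy-adjudicated
#' truth, all from the vocabulary N0-N3. `true_n` may be missing (NA);
#' such rows are excluded (with a logged count) by [adjudicate_staging()].
#'
#' @param records Data frame with columns `patient_id`, `mri_n`, `pet_n`,
#'   `true_n`.
#' @return Validated tibble.
#' @export
validate_staging_table <- function(records) {
  require_columns(
    records, c("patient_id", "mri_n", "pet_n", "true_n"),
    "staging table"
  )
  check_vocab(records$mri_n, N_STAGES, "mri_n")
  check_vocab(records$pet_n, N_STAGES, "pet_n")
  check_vocab(records$true_n, N_STAGES, "true_n", allow_na = TRUE)
  if ("t_stage" %in% names(records)) {
    check_vocab(records$t_stage, paste0("T", 1:4), "t_stage", allow_na = TRUE)
  }
  tibble::as_tibble(records)
}

#' @rdname validate_staging_table
#' @param path Path to a CSV/TSV staging table.
#' @export
read_staging_table <- function(path) validate_staging_table(read_delimited(path))

#' Validate / read a radiotherapy decision table
#'
#' One row per (patient, oncologist, node) with the dose category
#' (low <60 Gy, intermediate 60-66 Gy, radical >=66 Gy) and irradiation
#' field (upper_neck_only / whole_neck) recommended before and after
#' review of the second modality.
#'
#' @param records Data frame with columns `patient_id`, `oncologist_id`,
#'   `node_pathology`, `dose_before`, `dose_after`, `field_before`,
#'   `field_after`.
#' @return Validated tibble.
#' @export
validate_decision_table <- function(records) {
  require_columns(
    records,
    c(
      "patient_id", "oncologist_id", "node_pathology",
      "dose_before", "dose_after", "field_before", "field_after"
    ),
    "decision table"
  )
  check_vocab(records$node_pathology, PATHOLOGY_LEVELS, "node_pathology")
  check_vocab(records$dose_before, DOSE_LEVELS, "dose_before")
  check_vocab(records$dose_after, DOSE_LEVELS, "dose_after")
  check_vocab(records$field_before, FIELD_LEVELS, "field_before")
  check_vocab(records$field_after, FIELD_LEVELS, "field_after")
  tibble::as_tibble(records)
}

#' @rdname validate_decision_table
#' @param path Path to a CSV/TSV decision table.
#' @export
read_decision_table <- function(path) validate_decision_table(read_delimited(path))

#' Read a structured run configuration
#'
#' The configuration is a YAML file with top-level keys (`cutoff`,
#' `continuity_correction`, `ci_method`, `seed`, `output_dir`) and a
#' nested `cea` section holding economic-model parameters, which is
#' passed to [cea_parameters()].
#'
#' @param path Path to a YAML configuration file. `NULL` returns defaults.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  cea_args <- raw$cea %||% list()
  cfg <- list(
    cutoff = as.integer(raw$cutoff %||% 2L),
    continuity_correction = isTRUE(raw$continuity_correction %||% TRUE),
    ci_method = raw$ci_method %||% "wilson",
    seed = as.integer(raw$seed %||% 1L),
    output_dir = raw$output_dir %||% NULL,
    cea = do.call(cea_parameters, cea_args)
  )
  if (!cfg$cutoff %in% 1:4) stop("cutoff must be in 1..4", call. = FALSE)
  if (!identical(cfg$ci_method, "wilson")) {
    stop("only the Wilson score CI method is supported", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Write result tables and a run-metadata manifest
#'
#' Writes every element of `results` (each a data frame) as
#' `<name>.csv` in `output_dir` with a deterministic column order (the
#' order present in the data frame), plus a `run_metadata.json` record
#' embedding the seed, configuration hash, package version and the file
#' list, so every artifact is attributable to the run that produced it.
#'
#' @param results Named list of data frames (may be empty).
#' @param output_dir Directory to create/write into.
#' @param seed Integer seed the run used.
#' @param config Configuration object to hash into the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_result_tables <- function(results, output_dir, seed = NA_integer_,
                                config = NULL) {
  if (length(results) > 0 && is.null(names(results))) {
    stop("results must be a named list of data frames", call. = FALSE)
  }
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(output_dir)) {
      stop(sprintf("cannot create output directory '%s'", output_dir),
        call. = FALSE
      )
    }
  }
  files <- character(0)
  for (nm in names(results)) {
    path <- file.path(output_dir, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(results[[nm]]), path, progress = FALSE)
    files <- c(files, basename(path))
  }
  manifest <- list(
    seed = seed,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("npcnodes")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "run_metadata.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
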