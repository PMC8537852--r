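#' Read a protein x sample intensity matrix from TSV
#'
#' First column = protein accession, remaining columns = samples; empty cells
#' are missing values. Duplicate accessions, negative values and ragged rows
#' are rejected.
#'
#' @param path TSV file path.
#' @return Numeric matrix with protein rownames and sample colnames.
#' @export
read_intensity_matrix <- function(path) {
  df <- readr::read_tsv(path, na = "", col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs)) {
    stop("parse error in ", path, " at line(s) ",
         paste(utils::head(unique(probs$row), 5) + 1L, collapse = ", "),
         call. = FALSE)
  }
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate protein accession(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  mat <- suppressWarnings(
    matrix(as.numeric(raw), nrow(raw), ncol(raw),
           dimnames = list(ids, colnames(raw))))
  bad <- which(is.na(mat) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric intensity at line ", bad[1, 1] + 1L, " (protein ",
         ids[bad[1, 1]], ")", call. = FALSE)
  }
  if (any(mat < 0, na.rm = TRUE)) {
    badp <- which(rowSums(mat < 0, na.rm = TRUE) > 0)[1]
    stop("negative intensity at line ", badp + 1L, " (protein ", ids[badp],
         ")", call. = FALSE)
  }
  mat
}

#' Write a protein x sample intensity matrix as TSV
#'
#' Inverse of [read_intensity_matrix()]; missing values become empty cells.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_intensity_matrix <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "protein_id")
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' @rdname sample_table_io
#' @export
read_sample_table <- function(path) {
  readr::read_tsv(path, na = "", col_types = readr::cols(
    sample_id = readr::col_character(),
    subject_id = readr::col_character(),
    group = readr::col_character(),
    timepoint = readr::col_character()
  ), progress = FALSE)
}

#' Sample table TSV round-trip
#'
#' Columns: `sample_id`, `subject_id`, `group` (`case`/`control`),
#' `timepoint` (empty for cross-sectional designs).
#'
#' @param samples Sample tibble.
#' @param path File path.
#' @name sample_table_io
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(samples, path, na = "")
  invisible(path)
}

#' @rdname chromatogram_io
#' @export
read_chromatograms <- function(path) {
  readr::read_tsv(path, na = "", col_types = readr::cols(
    sample_id = readr::col_character(),
    peptide_id = readr::col_character(),
    transition_id = readr::col_character(),
    rt_min = readr::col_double(),
    intensity = readr::col_double()
  ), progress = FALSE)
}

#' Chromatogram long-format TSV round-trip
#'
#' Columns: `sample_id`, `peptide_id`, `transition_id`, `rt_min`,
#' `intensity`.
#'
#' @param chromatograms Long tibble.
#' @param path File path.
#' @name chromatogram_io
#' @export
write_chromatograms <- function(chromatograms, path) {
  readr::write_tsv(chromatograms, path, na = "")
  invisible(path)
}

#' @rdname target_io
#' @export
read_targets <- function(path) {
  readr::read_tsv(path, na = "", col_types = readr::cols(
    protein_id = readr::col_character(),
    gene = readr::col_character(),
    peptide_id = readr::col_character(),
    is_irt = readr::col_logical(),
    is_reference = readr::col_logical(),
    transitions = readr::col_character(),
    expected_rt_min = readr::col_double()
  ), progress = FALSE)
}

#' Target list TSV round-trip
#'
#' Columns as in [default_prm_targets()]; `transitions` is
#' semicolon-separated.
#'
#' @param targets Target tibble.
#' @param path File path.
#' @name target_io
#' @export
write_targets <- function(targets, path) {
  readr::write_tsv(targets, path, na = "")
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' The YAML maps 1:1 to [cohort_config()] fields under `discovery:` and
#' `longitudinal:`, plus `selection:` (`z_abs_threshold`, `q_threshold`),
#' `fpr_target`, `ci_method` and `seed`. Missing keys fall back to package
#' defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param seed Optional seed overriding the file's.
#' @return A run-config list.
#' @export
read_run_config <- function(path = NULL, seed = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- default_run_config(seed = if (!is.null(seed)) seed
                            else user$seed %||% 1L)
  for (blk in c("discovery", "longitudinal")) {
    if (!is.null(user[[blk]])) {
      base <- unclass(cfg[[blk]])  # keeps the derived per-stage sub-seed
      base[names(user[[blk]])] <- user[[blk]]
      cfg[[blk]] <- do.call(cohort_config, base)
    }
  }
  if (!is.null(user$selection)) {
    cfg$selection <- do.call(selection_criteria, user$selection)
  }
  cfg$fpr_target <- user$fpr_target %||% cfg$fpr_target
  cfg$ci_method <- user$ci_method %||% cfg$ci_method
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default run configuration at study scale
#'
#' Discovery: 1108 proteins, 12 vs 12, 53 up / 9 down planted. Validation:
#' the 21-target panel with planted upregulation. Longitudinal: 10 cases vs
#' 20 controls at 2 timepoints, 2 markers planted at both timepoints and 4
#' late-only.
#'
#' @param seed Global seed; per-stage sub-seeds are derived from it.
#' @return A run-config list.
#' @export
default_run_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    discovery = cohort_config(seed = derive_seed(seed, 1L)),
    longitudinal = cohort_config(
      n_case = 10L, n_control = 20L, n_proteins = 22L,
      n_de_up = 0L, n_de_down = 0L,
      baseline_log2_mean = 10, baseline_log2_sd = 1.5,
      tech_noise_log2_sd = 0.5,
      proteinuria_log2_mean = 0, proteinuria_log2_sd = 0,
      missing_midpoint_log2 = -30, missing_slope = 1,
      subject_log2_sd = 0.3,
      seed = derive_seed(seed, 3L)
    ),
    selection = selection_criteria(),
    n_candidates = 21L,
    validation_log2fc_range = c(1, 3),
    longitudinal_markers = c(
      both = "P05543", both2 = "P00450",
      late = "P43652", late2 = "P19823", late3 = "P02787", late4 = "P04217"
    ),
    longitudinal_effect = 1.5,
    fpr_target = 0.10,
    ci_method = "hanley"
  )
}

# expand one global seed into per-stage substreams (kept well below 2^31)
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% 2000000000L
}
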