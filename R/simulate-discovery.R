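#' Simulate a discovery-stage label-free quantification cohort
#'
#' Draws a protein x sample intensity matrix under the additive log2 model
#' described in [cohort_config()], together with the sample metadata table and
#' the planted ground truth needed for parameter-recovery testing. The
#' proteinuria confounder is a single multiplicative factor per case sample
#' applied to every protein — the minimal mechanism producing the global
#' fold-change shift that z-score centering corrects.
#'
#' @param config A [cohort_config()].
#' @return A list with components:
#'   \describe{
#'     \item{matrix}{numeric protein x sample matrix of raw-scale intensities,
#'       `NA` = not detected (left-censored).}
#'     \item{samples}{tibble with `sample_id`, `subject_id`, `group`
#'       (`"case"`/`"control"`) and `timepoint` (`NA` for cross-sectional).}
#'     \item{truth}{list with `de_proteins` (named planted log2 effects),
#'       `sample_global_factor` (named multiplicative proteinuria factors,
#'       1 for controls) and the log2 matrix before censoring.}
#'   }
#' @export
#' @examples
#' sim <- generate_discovery_cohort(cohort_config(n_proteins = 40, seed = 3))
#' dim(sim$matrix)
generate_discovery_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed)

  n_s <- config$n_case + config$n_control
  protein_ids <- sprintf("PROT%04d", seq_len(config$n_proteins))
  sample_ids <- c(sprintf("case_%02d", seq_len(config$n_case)),
                  sprintf("ctrl_%02d", seq_len(config$n_control)))
  is_case <- rep(c(TRUE, FALSE), c(config$n_case, config$n_control))

  baseline <- stats::rnorm(config$n_proteins, config$baseline_log2_mean,
                           config$baseline_log2_sd)

  effect <- numeric(config$n_proteins)
  n_de <- config$n_de_up + config$n_de_down
  de_idx <- if (n_de > 0) sample.int(config$n_proteins, n_de) else integer(0)
  if (config$n_de_up > 0) {
    up_idx <- de_idx[seq_len(config$n_de_up)]
    effect[up_idx] <- stats::runif(config$n_de_up, config$de_log2fc_range[1],
                                   config$de_log2fc_range[2])
  }
  if (config$n_de_down > 0) {
    dn_idx <- de_idx[config$n_de_up + seq_len(config$n_de_down)]
    effect[dn_idx] <- -stats::runif(config$n_de_down, config$de_log2fc_range[1],
                                    config$de_log2fc_range[2])
  }

  shift <- ifelse(is_case,
                  stats::rnorm(n_s, config$proteinuria_log2_mean,
                               config$proteinuria_log2_sd),
                  0)

  log2_mat <- outer(baseline, rep(1, n_s)) +
    outer(effect, as.numeric(is_case)) +
    outer(rep(1, config$n_proteins), shift) +
    matrix(stats::rnorm(config$n_proteins * n_s, 0, config$tech_noise_log2_sd),
           config$n_proteins, n_s)

  p_miss <- stats::plogis((config$missing_midpoint_log2 - log2_mat) /
                            config$missing_slope)
  missing <- matrix(stats::runif(length(p_miss)) < p_miss,
                    nrow(p_miss), ncol(p_miss))

  mat <- 2^log2_mat
  mat[missing] <- NA_real_
  dimnames(mat) <- list(protein_ids, sample_ids)
  dimnames(log2_mat) <- dimnames(mat)

  samples <- tibble::tibble(
    sample_id = sample_ids,
    subject_id = sample_ids,
    group = ifelse(is_case, "case", "control"),
    timepoint = NA_character_
  )

  truth <- list(
    de_proteins = stats::setNames(effect[de_idx], protein_ids[de_idx]),
    sample_global_factor = stats::setNames(2^shift, sample_ids),
    log2_complete = log2_mat
  )

  list(matrix = mat, samples = samples, truth = truth)
}

#' Simulate a two-timepoint (or longer) longitudinal cohort
#'
#' Each subject contributes one sample per timepoint and carries a random
#' intercept (sd `config$subject_log2_sd`, log2 units) shared across its
#' timepoints. Planted effects are supplied per protein and per timepoint via
#' `effect_schedule`, and apply to case subjects only. Intended for the
#' post-normalization targeted-assay scale, so the default proteinuria shift
#' should usually be set to 0 in `config` for this generator.
#'
#' @param config A [cohort_config()]; `n_proteins` is overridden when
#'   `protein_ids` is given.
#' @param n_timepoints Number of timepoints (>= 1).
#' @param effect_schedule Named list: protein id -> numeric vector of length
#'   `n_timepoints` of planted log2 effects in cases. Proteins absent from the
#'   schedule are null.
#' @param protein_ids Optional character vector of protein ids to simulate
#'   (e.g. a targeted panel); defaults to synthetic `PROT` accessions.
#' @return A list with `matrices` (named list of protein x sample matrices,
#'   one per timepoint), `samples` (tibble with one row per sample), and
#'   `truth` (planted schedule and subject intercepts).
#' @export
generate_longitudinal_cohort <- function(config, n_timepoints = 2L,
                                         effect_schedule = list(),
                                         protein_ids = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  n_timepoints <- as.integer(n_timepoints)
  if (is.na(n_timepoints) || n_timepoints < 1L) {
    stop("'n_timepoints' must be >= 1", call. = FALSE)
  }
  if (is.null(protein_ids)) {
    protein_ids <- sprintf("PROT%04d", seq_len(config$n_proteins))
  }
  bad <- setdiff(names(effect_schedule), protein_ids)
  if (length(bad)) {
    stop("effect_schedule names not among generated proteins: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed)

  n_p <- length(protein_ids)
  n_subj <- config$n_case + config$n_control
  subject_ids <- c(sprintf("caseS%02d", seq_len(config$n_case)),
                   sprintf("ctrlS%02d", seq_len(config$n_control)))
  is_case <- rep(c(TRUE, FALSE), c(config$n_case, config$n_control))
  intercept <- stats::rnorm(n_subj, 0, config$subject_log2_sd)

  baseline <- stats::rnorm(n_p, config$baseline_log2_mean, config$baseline_log2_sd)
  eff_mat <- matrix(0, n_p, n_timepoints, dimnames = list(protein_ids, NULL))
  for (p in names(effect_schedule)) {
    v <- effect_schedule[[p]]
    if (length(v) != n_timepoints) {
      stop("effect_schedule entry for ", p, " must have length n_timepoints",
           call. = FALSE)
    }
    eff_mat[p, ] <- as.numeric(v)
  }

  matrices <- vector("list", n_timepoints)
  names(matrices) <- sprintf("T%d", seq_len(n_timepoints))
  rows <- vector("list", n_timepoints)
  for (tp in seq_len(n_timepoints)) {
    sample_ids <- paste0(subject_ids, "_T", tp)
    shift <- ifelse(is_case,
                    stats::rnorm(n_subj, config$proteinuria_log2_mean,
                                 config$proteinuria_log2_sd),
                    0)
    log2_mat <- outer(baseline, rep(1, n_subj)) +
      outer(eff_mat[, tp], as.numeric(is_case)) +
      outer(rep(1, n_p), intercept + shift) +
      matrix(stats::rnorm(n_p * n_subj, 0, config$tech_noise_log2_sd), n_p, n_subj)
    p_miss <- stats::plogis((config$missing_midpoint_log2 - log2_mat) /
                              config$missing_slope)
    missing <- matrix(stats::runif(length(p_miss)) < p_miss, n_p, n_subj)
    mat <- 2^log2_mat
    mat[missing] <- NA_real_
    dimnames(mat) <- list(protein_ids, sample_ids)
    matrices[[tp]] <- mat
    rows[[tp]] <- tibble::tibble(
      sample_id = sample_ids,
      subject_id = subject_ids,
      group = ifelse(is_case, "case", "control"),
      timepoint = sprintf("T%d", tp)
    )
  }

  list(
    matrices = matrices,
    samples = dplyr::bind_rows(rows),
    truth = list(
      effect_schedule = eff_mat,
      subject_intercept = stats::setNames(intercept, subject_ids)
    )
  )
}

#' Simulate peptide-level evidence for candidate shortlisting
#'
#' Generates, for each protein, a set of tryptic-like peptide records carrying
#' the annotations the shortlisting filter acts on: oxidized-methionine flags
#' and missed-cleavage counts (both disqualify a peptide as a quantifier), and
#' a total MS1 intensity used to rank quantifier peptides.
#'
#' @param protein_ids Character vector of protein accessions.
#' @param peptides_per_protein Number of peptides drawn per protein.
#' @param oxmet_rate,missed_rate Per-peptide probability of carrying an
#'   oxidized Met / of having >= 1 missed cleavage.
#' @param seed Integer seed.
#' @return Tibble with `protein_id`, `peptide_id`, `peptide_sequence`,
#'   `has_oxidized_met`, `missed_cleavages`, `total_intensity`.
#' @export
generate_peptide_evidence <- function(protein_ids, peptides_per_protein = 6L,
                                      oxmet_rate = 0.15, missed_rate = 0.2,
                                      seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHILNPQSTVWY", "")[[1]]  # no K/R/M in the core
  n <- length(protein_ids) * peptides_per_protein
  len <- sample(7:18, n, replace = TRUE)
  core <- vapply(len, function(l) paste(sample(aa, l, replace = TRUE),
                                        collapse = ""), character(1))
  has_ox <- stats::runif(n) < oxmet_rate
  missed <- ifelse(stats::runif(n) < missed_rate,
                   sample(1:2, n, replace = TRUE), 0L)
  # oxidized Met shown as M(ox) inside the sequence; missed cleavage inserts
  # an internal K
  seqs <- core
  seqs[has_ox] <- paste0(substr(seqs[has_ox], 1, 3), "M(ox)",
                         substr(seqs[has_ox], 4, nchar(seqs[has_ox])))
  seqs[missed > 0] <- paste0(substr(seqs[missed > 0], 1, 5), "K",
                             substr(seqs[missed > 0], 6, nchar(seqs[missed > 0])))
  seqs <- paste0(seqs, sample(c("K", "R"), n, replace = TRUE))

  tibble::tibble(
    protein_id = rep(protein_ids, each = peptides_per_protein),
    peptide_id = paste0(rep(protein_ids, each = peptides_per_protein), "_pep",
                        rep(seq_len(peptides_per_protein), length(protein_ids))),
    peptide_sequence = seqs,
    has_oxidized_met = has_ox,
    missed_cleavages = as.integer(missed),
    total_intensity = 2^stats::rnorm(n, 22, 2)
  )
}
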