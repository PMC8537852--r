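#' Default targeted (PRM) assay panel
#'
#' The 21-protein urinary panel monitored in the validation and longitudinal
#' stages, with two quantifier peptides per protein, plus the biotinidase
#' (BTD, P43251) reference protein used to correct protein-loading (Bradford)
#' variation and the 11 spiked iRT standard peptides used to correct LC-MS/MS
#' drift. Peptide ids are synthetic; iRT peptide ids are the standard kit
#' sequences. Each peptide carries three fragment transitions `y1;y2;y3` with
#' decreasing response.
#'
#' @return Tibble with columns `protein_id`, `gene`, `peptide_id`, `is_irt`,
#'   `is_reference`, `transitions` (semicolon-separated ids) and
#'   `expected_rt_min`.
#' @export
default_prm_targets <- function() {
  genes <- c("A1BG", "ALB", "AFM", "TTR", "AZGP1", "C3", "CA1", "CP", "GC",
             "HBA1", "HBB", "ITIH2", "ORM1", "ORM2", "SERPINA1", "SERPINA3",
             "SERPINA6", "SERPINA7", "SERPINC1", "SHBG", "TF")
  acc <- c("P04217", "P02768", "P43652", "P02766", "P25311", "P01024",
           "P00915", "P00450", "P02774", "P69905", "P68871", "P19823",
           "P02763", "P19652", "P01009", "P01011", "P08185", "P05543",
           "P01008", "I3L145", "P02787")
  irt_seqs <- c("LGGNEQVTR", "GAGSSEPVTGLDAK", "VEATFGVDESNAK", "YILAGVENSK",
                "TPVISGGPYEYR", "TPVITGAPYEYR", "DGLDAASYYAPVR",
                "ADVTPADFSEWSK", "GTFIIDPGGVIR", "GTFIIDPAAVIR",
                "LFLQFGAQGSPFLK")

  quant <- tibble::tibble(
    protein_id = rep(c(acc, "P43251"), each = 2L),
    gene = rep(c(genes, "BTD"), each = 2L),
    peptide_id = paste0(rep(c(acc, "P43251"), each = 2L), "_pep",
                        rep(1:2, length(genes) + 1L)),
    is_irt = FALSE,
    is_reference = rep(c(rep(FALSE, length(genes)), TRUE), each = 2L)
  )
  irt <- tibble::tibble(
    protein_id = "iRT_kit",
    gene = "iRT",
    peptide_id = irt_seqs,
    is_irt = TRUE,
    is_reference = FALSE
  )
  out <- dplyr::bind_rows(quant, irt)
  out$transitions <- "y1;y2;y3"
  # spread elution deterministically across the gradient
  out$expected_rt_min <- round(seq(12, 65, length.out = nrow(out)), 2)
  out
}

#' Targeted acquisition design
#'
#' Describes a scheduled PRM run: the target peptides, the retention-time
#' sampling grid of each scheduled window (offsets in minutes around a
#' peptide's expected apex, strictly increasing), and the chromatographic peak
#' width.
#'
#' @param targets Target table as in [default_prm_targets()].
#' @param rt_grid Numeric vector of RT offsets (minutes) sampled around each
#'   peptide's expected retention time; strictly increasing.
#' @param peak_sigma Gaussian peak sd in minutes (default 0.08, ~11 s FWHM).
#' @return A list of class `prm_design`.
#' @export
prm_design <- function(targets = default_prm_targets(),
                       rt_grid = seq(-1.5, 1.5, by = 0.02),
                       peak_sigma = 0.08) {
  req <- c("protein_id", "gene", "peptide_id", "is_irt", "is_reference",
           "transitions", "expected_rt_min")
  miss <- setdiff(req, names(targets))
  if (length(miss)) {
    stop("targets table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(targets$is_irt & targets$is_reference)) {
    stop("a peptide cannot be both iRT and reference", call. = FALSE)
  }
  quant <- targets[!targets$is_irt, ]
  n_pep <- table(quant$protein_id)
  if (any(n_pep != 2L)) {
    stop("each target protein needs exactly two quantifier peptides; offending: ",
         paste(names(n_pep)[n_pep != 2L], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(targets$peptide_id)) {
    stop("duplicate peptide ids in targets", call. = FALSE)
  }
  if (any(diff(rt_grid) <= 0)) {
    stop("rt_grid must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(peak_sigma) || peak_sigma <= 0) {
    stop("peak_sigma must be > 0", call. = FALSE)
  }
  structure(list(targets = targets, rt_grid = as.numeric(rt_grid),
                 peak_sigma = peak_sigma),
            class = "prm_design")
}

# fixed relative response of the n-th transition of a peptide
transition_response <- function(n) c(1, 0.55, 0.25, 0.12, 0.06)[pmin(n, 5L)]

# fixed share of a protein's abundance carried by each of its two quantifier
# peptides (ionization efficiency differs between peptides)
peptide_share <- c(0.6, 0.4)

#' Simulate PRM transition chromatograms
#'
#' For every (sample, peptide, transition) triple, draws a Gaussian
#' chromatographic peak on the scheduled RT grid. Peak area is proportional to
#' peptide abundance x per-sample loading factor x per-sample instrument
#' drift; spiked iRT peptides are added after digestion at a fixed amount and
#' therefore carry the drift factor only. Optional nonnegative baseline noise
#' (truncated normal) and a small per-sample RT jitter are applied.
#' Deterministic under `seed`.
#'
#' @param design A [prm_design()].
#' @param samples Sample table (needs `sample_id`).
#' @param abundances Numeric protein x sample matrix covering every non-iRT
#'   target protein and every sample (arbitrary linear units).
#' @param loading_factor,drift_factor Optional named per-sample multiplicative
#'   factors; when `NULL` they are drawn log-normally (sd 0.25 / 0.2 log2
#'   units).
#' @param noise_sd Baseline noise sd in intensity units (0 = noiseless).
#' @param rt_jitter_sd Per-sample apex jitter sd in minutes.
#' @param irt_abundance Common scale of the spiked iRT peptides.
#' @param seed Integer seed.
#' @return List with `chromatograms` (long tibble: `sample_id`, `peptide_id`,
#'   `transition_id`, `rt_min`, `intensity`) and `truth` (the per-sample
#'   `loading_factor` and `drift_factor` actually used).
#' @export
generate_prm_dataset <- function(design, samples, abundances,
                                 loading_factor = NULL, drift_factor = NULL,
                                 noise_sd = 0, rt_jitter_sd = 0.02,
                                 irt_abundance = 5e4, seed = 1L) {
  stopifnot(inherits(design, "prm_design"))
  set.seed(seed)
  sample_ids <- samples$sample_id
  targets <- design$targets

  need <- unique(targets$protein_id[!targets$is_irt])
  miss_p <- setdiff(need, rownames(abundances))
  if (length(miss_p)) {
    stop("abundance matrix lacks target protein(s): ",
         paste(miss_p, collapse = ", "), call. = FALSE)
  }
  miss_s <- setdiff(sample_ids, colnames(abundances))
  if (length(miss_s)) {
    stop("abundance matrix lacks sample(s): ",
         paste(miss_s, collapse = ", "), call. = FALSE)
  }

  if (is.null(loading_factor)) {
    loading_factor <- stats::setNames(
      2^stats::rnorm(length(sample_ids), 0, 0.25), sample_ids)
  }
  if (is.null(drift_factor)) {
    drift_factor <- stats::setNames(
      2^stats::rnorm(length(sample_ids), 0, 0.20), sample_ids)
  }
  if (length(miss <- setdiff(sample_ids, names(loading_factor)))) {
    stop("loading_factor lacks sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(miss <- setdiff(sample_ids, names(drift_factor)))) {
    stop("drift_factor lacks sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  jitter <- stats::setNames(stats::rnorm(length(sample_ids), 0, rt_jitter_sd),
                            sample_ids)

  # iRT peptides differ in response; fixed geometric spread, deterministic
  irt_ids <- targets$peptide_id[targets$is_irt]
  irt_scale <- stats::setNames(
    2^seq(-0.7, 0.7, length.out = max(length(irt_ids), 1L)), irt_ids)

  # per-peptide quantifier share (pep1 = 0.6, pep2 = 0.4 of the protein)
  pep_no <- stats::ave(seq_len(nrow(targets)), targets$protein_id,
                       FUN = seq_along)

  trans_list <- strsplit(targets$transitions, ";", fixed = TRUE)
  grid <- design$rt_grid
  ng <- length(grid)
  sig <- design$peak_sigma

  out <- vector("list", length(sample_ids))
  for (si in seq_along(sample_ids)) {
    s <- sample_ids[si]
    blocks <- vector("list", nrow(targets))
    for (pi in seq_len(nrow(targets))) {
      pep <- targets$peptide_id[pi]
      trs <- trans_list[[pi]]
      if (targets$is_irt[pi]) {
        base_amp <- irt_abundance * irt_scale[[pep]] * drift_factor[[s]]
      } else {
        prot <- targets$protein_id[pi]
        base_amp <- abundances[prot, s] * peptide_share[pep_no[pi]] *
          loading_factor[[s]] * drift_factor[[s]]
      }
      rt_apex <- targets$expected_rt_min[pi] + jitter[[s]]
      rt <- targets$expected_rt_min[pi] + grid
      shape <- exp(-(rt - rt_apex)^2 / (2 * sig^2))
      amp <- base_amp * transition_response(seq_along(trs))
      intensity <- as.vector(outer(shape, amp))
      if (noise_sd > 0) {
        intensity <- intensity + abs(stats::rnorm(length(intensity), 0, noise_sd))
      }
      blocks[[pi]] <- tibble::tibble(
        sample_id = s,
        peptide_id = pep,
        transition_id = rep(trs, each = ng),
        rt_min = rep(rt, length(trs)),
        intensity = intensity
      )
    }
    out[[si]] <- dplyr::bind_rows(blocks)
  }

  list(
    chromatograms = dplyr::bind_rows(out),
    truth = list(loading_factor = loading_factor, drift_factor = drift_factor)
  )
}
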