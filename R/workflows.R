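#' @keywords internal
write_manifest <- function(out_dir, config, files, stage) {
  manifest <- list(
    stage = stage,
    package = "urinomics",
    version = as.character(utils::packageVersion("urinomics")),
    seed = config$seed,
    config = config_echo(config),
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- if (!is.null(names(files))) names(files)
                               else basename(files)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  # timestamps live in a side log so manifests stay reproducible
  cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), stage, "done\n",
      file = file.path(out_dir, "run.log"), append = TRUE)
  path
}

# strip classes so the config echoes as plain JSON-able lists
config_echo <- function(x) {
  if (is.list(x)) lapply(unclass(x), config_echo) else x
}

#' Run the discovery workflow
#'
#' Simulates (or ingests) a discovery cohort, then runs the full chain:
#' quantification filter, log2 fold changes, z-score centering, moderated
#' t-test, BH adjustment, dual-rule selection, candidate shortlisting, PCA
#' and complete-linkage clustering. All artifacts are written under
#' `out_dir` together with a reproducible manifest.
#'
#' @param config Run configuration from [default_run_config()] /
#'   [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @param matrix,samples Optional user-supplied data; simulated from
#'   `config$discovery` when `NULL`.
#' @return Invisibly, a list with the results table, candidate shortlist,
#'   selection, PCA scores, dendrogram, simulation truth and manifest path.
#' @export
run_discovery_workflow <- function(config = default_run_config(),
                                   out_dir = tempfile("discovery_"),
                                   matrix = NULL, samples = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (is.null(matrix)) {
    sim <- generate_discovery_cohort(config$discovery)
    matrix <- sim$matrix
    samples <- sim$samples
    truth <- sim$truth
  }
  filt <- filter_quantified(matrix, samples, min_fraction = 0.5)
  res <- discovery_results(filt, samples, criteria = config$selection)
  evidence <- generate_peptide_evidence(
    res$protein_id, seed = derive_seed(config$seed, 2L))
  shortlist <- shortlist_candidates(res, evidence,
                                    n_select = config$n_candidates)
  pca <- pca_scores(filt)
  hc <- cluster_samples(filt)

  files <- c(
    matrix = file.path(out_dir, "matrix.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    results = file.path(out_dir, "results.tsv"),
    candidates = file.path(out_dir, "candidates.tsv"),
    pca = file.path(out_dir, "pca_scores.tsv"),
    dendrogram = file.path(out_dir, "dendrogram.nwk")
  )
  write_intensity_matrix(matrix, files[["matrix"]])
  write_sample_table(samples, files[["samples"]])
  readr::write_tsv(res, files[["results"]], na = "")
  readr::write_tsv(shortlist, files[["candidates"]], na = "")
  readr::write_tsv(pca, files[["pca"]], na = "")
  dendrogram_newick(hc, files[["dendrogram"]])
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(de_proteins = as.list(truth$de_proteins),
           sample_global_factor = as.list(truth$sample_global_factor)),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, truth = file.path(out_dir, "ground_truth.json"))
  }
  manifest <- write_manifest(out_dir, config, files, "discovery")
  invisible(list(results = res, shortlist = shortlist, pca = pca,
                 dendrogram = hc, matrix = matrix, samples = samples,
                 truth = truth, manifest = manifest))
}

# build a target-panel abundance matrix with planted case effects
validation_abundances <- function(design, samples, log2fc_range, seed,
                                  base_log2_mean = 14, base_log2_sd = 1,
                                  noise_log2_sd = 0.5) {
  set.seed(seed)
  prots <- unique(design$targets$protein_id[!design$targets$is_irt])
  is_ref <- prots %in%
    design$targets$protein_id[design$targets$is_reference]
  n_s <- nrow(samples)
  is_case <- samples$group == "case"
  base <- stats::rnorm(length(prots), base_log2_mean, base_log2_sd)
  eff <- ifelse(is_ref, 0,
                stats::runif(length(prots), log2fc_range[1], log2fc_range[2]))
  lg <- outer(base, rep(1, n_s)) + outer(eff, as.numeric(is_case)) +
    matrix(stats::rnorm(length(prots) * n_s, 0, noise_log2_sd),
           length(prots), n_s)
  ab <- 2^lg
  dimnames(ab) <- list(prots, samples$sample_id)
  list(abundances = ab, planted_log2fc = stats::setNames(eff, prots))
}

#' Run the targeted validation workflow
#'
#' Simulates (or ingests) PRM chromatograms for the target panel, quantifies
#' by best-transition peak integration, applies the dual iRT / reference
#' normalization, rolls peptides up to proteins and writes the case vs
#' control comparison table (PE/CTL ratio, Welch p, stars).
#'
#' @inheritParams run_discovery_workflow
#' @param design A [prm_design()]; default panel when `NULL`.
#' @param chromatograms Optional user-supplied chromatogram table; simulated
#'   when `NULL`.
#' @param samples Sample table (12 vs 12 simulated when `NULL`).
#' @return Invisibly: comparison table, protein intensity table, peak areas,
#'   normalization factors, planted truth and manifest path.
#' @export
run_validation_workflow <- function(config = default_run_config(),
                                    out_dir = tempfile("validation_"),
                                    design = NULL, chromatograms = NULL,
                                    samples = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(design)) design <- prm_design()
  truth <- NULL
  if (is.null(samples)) {
    samples <- tibble::tibble(
      sample_id = c(sprintf("case_%02d", 1:12), sprintf("ctrl_%02d", 1:12)),
      subject_id = c(sprintf("case_%02d", 1:12), sprintf("ctrl_%02d", 1:12)),
      group = rep(c("case", "control"), each = 12),
      timepoint = NA_character_
    )
  }
  if (is.null(chromatograms)) {
    ab <- validation_abundances(design, samples,
                                config$validation_log2fc_range,
                                seed = derive_seed(config$seed, 4L))
    prm <- generate_prm_dataset(design, samples, ab$abundances,
                                noise_sd = 20,
                                seed = derive_seed(config$seed, 5L))
    chromatograms <- prm$chromatograms
    truth <- c(prm$truth, list(planted_log2fc = ab$planted_log2fc))
  }
  areas <- quantify_chromatograms(chromatograms, design)
  factors <- compute_normalization(areas, design)
  normalized <- apply_normalization(areas, factors)
  proteins <- rollup_protein(normalized, design)
  # the reference protein is a normalizer, not an analyte
  ref_ids <- unique(design$targets$protein_id[design$targets$is_reference])
  comparison <- compare_groups(proteins[!proteins$protein_id %in% ref_ids, ],
                               samples)

  files <- c(
    samples = file.path(out_dir, "samples.tsv"),
    targets = file.path(out_dir, "targets.tsv"),
    areas = file.path(out_dir, "peak_areas.tsv"),
    intensities = file.path(out_dir, "protein_intensities.tsv"),
    comparison = file.path(out_dir, "comparison.tsv")
  )
  write_sample_table(samples, files[["samples"]])
  write_targets(design$targets, files[["targets"]])
  readr::write_tsv(areas, files[["areas"]], na = "")
  readr::write_tsv(proteins, files[["intensities"]], na = "")
  readr::write_tsv(comparison, files[["comparison"]], na = "")
  manifest <- write_manifest(out_dir, config, files, "validation")
  invisible(list(comparison = comparison, proteins = proteins,
                 areas = areas, factors = factors, truth = truth,
                 manifest = manifest))
}

#' Run the longitudinal screening workflow
#'
#' Simulates (or ingests) a two-timepoint cohort on the targeted panel,
#' writes the per-timepoint comparison table, and computes ROC summaries
#' (AUC, Hanley-McNeil CI, p vs 0.5, detection rate at the configured FPR)
#' for the designated marker proteins at each timepoint.
#'
#' @inheritParams run_discovery_workflow
#' @param tables Optional named list of per-timepoint protein intensity
#'   tibbles; simulated when `NULL`.
#' @param samples Sample table covering both timepoints.
#' @return Invisibly: longitudinal table, both-timepoint marker set, ROC
#'   summaries, truth and manifest path.
#' @export
run_longitudinal_workflow <- function(config = default_run_config(),
                                      out_dir = tempfile("longitudinal_"),
                                      tables = NULL, samples = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- prm_design()
  panel <- unique(design$targets$protein_id[!design$targets$is_irt])
  genes <- design$targets$gene[match(panel, design$targets$protein_id)]
  truth <- NULL
  if (is.null(tables)) {
    mk <- config$longitudinal_markers
    eff <- config$longitudinal_effect
    schedule <- list()
    for (p in mk[startsWith(names(mk), "both")]) schedule[[p]] <- c(eff, eff)
    for (p in mk[startsWith(names(mk), "late")]) schedule[[p]] <- c(0, eff)
    sim <- generate_longitudinal_cohort(config$longitudinal,
                                        n_timepoints = 2L,
                                        effect_schedule = schedule,
                                        protein_ids = panel)
    tables <- lapply(names(sim$matrices), function(tp) {
      m <- sim$matrices[[tp]]
      tibble::tibble(
        sample_id = rep(colnames(m), each = nrow(m)),
        protein_id = rep(rownames(m), ncol(m)),
        gene = rep(genes, ncol(m)),
        intensity = as.vector(m)
      )
    })
    names(tables) <- names(sim$matrices)
    samples <- sim$samples
    truth <- sim$truth
  }
  # the reference protein is excluded from the marker table
  ref_ids <- unique(design$targets$protein_id[design$targets$is_reference])
  tables <- lapply(tables, function(t) t[!t$protein_id %in% ref_ids, ])
  lt <- longitudinal_table(tables, samples)

  marker_ids <- unname(config$longitudinal_markers[
    startsWith(names(config$longitudinal_markers), "both")])
  roc_rows <- list()
  for (tp in names(tables)) {
    tab <- tables[[tp]]
    smp <- samples[samples$timepoint == tp, ]
    for (m in marker_ids) {
      sc <- tab[tab$protein_id == m, ]
      sc <- sc[match(smp$sample_id, sc$sample_id), ]
      rs <- roc_summary(sc$intensity, smp$group,
                        fpr_target = config$fpr_target,
                        ci_method = config$ci_method)
      rs$protein_id <- m
      rs$timepoint <- tp
      roc_rows[[paste(tp, m)]] <- rs
    }
  }
  rocs <- dplyr::bind_rows(roc_rows)

  files <- c(
    samples = file.path(out_dir, "samples.tsv"),
    table = file.path(out_dir, "longitudinal_table.tsv"),
    rocs = file.path(out_dir, "roc_summaries.tsv")
  )
  write_sample_table(samples, files[["samples"]])
  readr::write_tsv(lt, files[["table"]], na = "")
  readr::write_tsv(rocs, files[["rocs"]], na = "")
  manifest <- write_manifest(out_dir, config, files, "longitudinal")
  invisible(list(table = lt,
                 both_timepoints = attr(lt, "both_timepoints"),
                 rocs = rocs, samples = samples, tables = tables,
                 truth = truth, manifest = manifest))
}

#' Run the full study-mirroring pipeline
#'
#' Discovery, validation and longitudinal workflows in order, each in its own
#' subdirectory, plus a master manifest checksumming the three stage
#' manifests. Fully deterministic under `config$seed`.
#'
#' @inheritParams run_discovery_workflow
#' @return Invisibly, the three stage results and the master manifest path.
#' @export
run_all <- function(config = default_run_config(), out_dir = tempfile("run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  disc <- run_discovery_workflow(config, file.path(out_dir, "discovery"))
  val <- run_validation_workflow(config, file.path(out_dir, "validation"))
  long <- run_longitudinal_workflow(config, file.path(out_dir, "longitudinal"))
  files <- c(
    discovery = disc$manifest,
    validation = val$manifest,
    longitudinal = long$manifest
  )
  manifest <- write_manifest(out_dir, config, files, "run_all")
  invisible(list(discovery = disc, validation = val, longitudinal = long,
                 manifest = manifest))
}
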