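#' Filter to reliably quantified proteins
#'
#' Retains proteins observed (non-missing) in at least `min_fraction` of the
#' samples of at least one group, and with at least 2 observed values in each
#' group (so that a per-group mean and variance exist). Row order is
#' preserved.
#'
#' @param mat Protein x sample intensity matrix, `NA` = missing.
#' @param samples Sample table with `sample_id` and `group`.
#' @param min_fraction Required observation fraction within a group (0, 1].
#' @return The filtered matrix.
#' @export
filter_quantified <- function(mat, samples, min_fraction = 0.5) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("'min_fraction' must be in (0, 1]", call. = FALSE)
  }
  grp <- group_columns(mat, samples)
  n_case <- rowSums(!is.na(mat[, grp$case, drop = FALSE]))
  n_ctrl <- rowSums(!is.na(mat[, grp$control, drop = FALSE]))
  keep <- (n_case / length(grp$case) >= min_fraction |
             n_ctrl / length(grp$control) >= min_fraction) &
    n_case >= 2 & n_ctrl >= 2
  if (!any(keep)) {
    warning("no protein passes the quantification filter", call. = FALSE)
  }
  mat[keep, , drop = FALSE]
}

# match sample table groups to matrix columns
group_columns <- function(mat, samples) {
  idx <- match(colnames(mat), samples$sample_id)
  if (anyNA(idx)) {
    stop("matrix columns missing from sample table: ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  grp <- samples$group[idx]
  if (!all(grp %in% c("case", "control"))) {
    stop("sample groups must be 'case' or 'control'", call. = FALSE)
  }
  if (!any(grp == "case") || !any(grp == "control")) {
    stop("both groups must be represented among the matrix columns",
         call. = FALSE)
  }
  list(case = which(grp == "case"), control = which(grp == "control"))
}

#' Per-protein log2 fold change (case over control)
#'
#' `log2fc = mean(log2 case values observed) - mean(log2 control values
#' observed)`, available-case: missing values are simply excluded. Proteins
#' with an empty group are dropped with a message.
#'
#' @inheritParams filter_quantified
#' @return Tibble with `protein_id`, `log2fc`, `n_case_obs`, `n_control_obs`.
#' @export
compute_log2fc <- function(mat, samples) {
  grp <- group_columns(mat, samples)
  lg <- log2(mat)
  mc <- rowMeans(lg[, grp$case, drop = FALSE], na.rm = TRUE)
  mx <- rowMeans(lg[, grp$control, drop = FALSE], na.rm = TRUE)
  n_case <- rowSums(!is.na(lg[, grp$case, drop = FALSE]))
  n_ctrl <- rowSums(!is.na(lg[, grp$control, drop = FALSE]))
  empty <- n_case == 0 | n_ctrl == 0
  if (any(empty)) {
    message(sum(empty), " protein(s) dropped from fold-change computation ",
            "(no observed value in one group)")
  }
  tibble::tibble(
    protein_id = rownames(mat)[!empty],
    log2fc = unname((mc - mx)[!empty]),
    n_case_obs = unname(as.integer(n_case[!empty])),
    n_control_obs = unname(as.integer(n_ctrl[!empty]))
  )
}

#' Center fold changes into z-scores
#'
#' `z = (FC - mean(FC)) / sd(FC)` across proteins (sd with the n-1
#' denominator). Centering removes any shift common to all proteins — in
#' particular the global proteinuria-driven intensity shift of case urine —
#' so that z measures regulation relative to the bulk of the proteome. The
#' output has mean 0 and sd 1.
#'
#' @param log2fc Numeric vector of per-protein log2 fold changes (length >= 2).
#' @return Numeric vector of z-scores, same order.
#' @export
center_fold_changes <- function(log2fc) {
  if (length(log2fc) < 2L) {
    stop("need at least 2 fold changes to center", call. = FALSE)
  }
  if (anyNA(log2fc)) stop("fold changes contain NA", call. = FALSE)
  s <- stats::sd(log2fc)
  if (s == 0) {
    stop("degenerate input: all fold changes identical (sd = 0)", call. = FALSE)
  }
  (log2fc - mean(log2fc)) / s
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment producing q-values:
#' `q_(i) = min over j >= i of m * p_(j) / j`, clipped at 1, mapped back to
#' the input order (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Apply the dual selection rule
#'
#' A protein is regulated when `|z| > z_abs_threshold` AND `q < q_threshold`
#' (both strict); the direction is the sign of z.
#'
#' @param records Tibble with at least `protein_id`, `z`, `q`.
#' @param criteria A [selection_criteria()].
#' @return List with `up` and `down` (character id vectors) and `records`
#'   (the input with a `direction` column: `"up"`, `"down"` or `"none"`).
#' @export
select_regulated <- function(records, criteria = selection_criteria()) {
  stopifnot(all(c("protein_id", "z", "q") %in% names(records)))
  sel <- abs(records$z) > criteria$z_abs_threshold &
    records$q < criteria$q_threshold
  direction <- rep("none", nrow(records))
  direction[sel & records$z > 0] <- "up"
  direction[sel & records$z < 0] <- "down"
  records$direction <- direction
  list(up = records$protein_id[direction == "up"],
       down = records$protein_id[direction == "down"],
       records = records)
}

#' Shortlist validation candidates with quantifier peptides
#'
#' From the upregulated set, peptides carrying oxidized methionine or missed
#' tryptic cleavages are excluded as quantifiers; proteins left with fewer
#' than two eligible peptides are dropped (a targeted assay needs two
#' precursors per protein). Survivors are ranked by log2 fold change, ties by
#' total protein signal intensity, and the top `n_select` are returned with
#' their two highest-intensity eligible peptides.
#'
#' @param records Tibble with `protein_id`, `log2fc` and a `direction`
#'   column; only rows with `direction == "up"` are considered.
#' @param evidence Peptide evidence tibble as from
#'   [generate_peptide_evidence()].
#' @param n_select Number of candidates wanted.
#' @return Tibble with `protein_id`, `rank`, `peptide_1`, `peptide_2`.
#' @export
shortlist_candidates <- function(records, evidence, n_select = 21L) {
  stopifnot(all(c("protein_id", "log2fc", "direction") %in% names(records)))
  up <- records[records$direction == "up", ]
  ok <- evidence[!evidence$has_oxidized_met & evidence$missed_cleavages == 0 &
                   evidence$protein_id %in% up$protein_id, ]
  counts <- table(ok$protein_id)
  eligible <- names(counts)[counts >= 2L]
  up <- up[up$protein_id %in% eligible, ]
  if (nrow(up) < n_select) {
    warning("only ", nrow(up), " proteins have >= 2 eligible peptides; ",
            "returning all of them", call. = FALSE)
  }
  prot_int <- tapply(ok$total_intensity, ok$protein_id, sum)
  up$total_intensity <- as.numeric(prot_int[up$protein_id])
  ord <- order(-up$log2fc, -up$total_intensity, up$protein_id)
  top <- up[ord, ][seq_len(min(n_select, nrow(up))), ]

  pep <- vapply(top$protein_id, function(p) {
    e <- ok[ok$protein_id == p, ]
    e <- e[order(-e$total_intensity, e$peptide_id), ]
    c(e$peptide_id[1], e$peptide_id[2])
  }, character(2), USE.NAMES = FALSE)

  tibble::tibble(
    protein_id = top$protein_id,
    rank = seq_len(nrow(top)),
    log2fc = top$log2fc,
    peptide_1 = pep[1, ],
    peptide_2 = pep[2, ]
  )
}

# impute left-censored missing values at half the per-sample observed minimum
# (raw scale); only used by the complete-matrix methods (PCA, clustering)
impute_halfmin <- function(mat) {
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (any(miss)) {
      obs <- mat[!miss, j]
      if (!length(obs)) stop("sample ", colnames(mat)[j], " entirely missing",
                             call. = FALSE)
      mat[miss, j] <- min(obs) / 2
    }
  }
  mat
}

#' PCA of samples on the log2 intensity matrix
#'
#' Missing values are imputed at half the per-sample observed minimum (a
#' left-censoring-consistent choice), intensities are log2 transformed,
#' proteins are centered, and sample scores are computed by singular value
#' decomposition.
#'
#' @inheritParams filter_quantified
#' @param n_components Number of components to keep.
#' @return Tibble of sample scores (`sample_id`, `PC1`, ...) with the
#'   per-component variance shares in attribute `"variance_share"`.
#' @export
pca_scores <- function(mat, n_components = 5L) {
  if (ncol(mat) < 3L) stop("PCA needs at least 3 samples", call. = FALSE)
  lg <- log2(impute_halfmin(mat))
  lg <- lg - rowMeans(lg)
  fit <- stats::prcomp(t(lg), center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  scores <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE])
  out <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(mat)), scores)
  attr(out, "variance_share") <- (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)]
  out
}

#' Complete-linkage clustering of samples
#'
#' Euclidean distance on centered log2 intensities (missing values imputed at
#' half the per-sample observed minimum), agglomerated with complete linkage.
#'
#' @inheritParams filter_quantified
#' @return An [stats::hclust] object over samples.
#' @export
cluster_samples <- function(mat) {
  if (ncol(mat) < 2L) stop("clustering needs at least 2 samples", call. = FALSE)
  lg <- log2(impute_halfmin(mat))
  lg <- lg - rowMeans(lg)
  stats::hclust(stats::dist(t(lg), method = "euclidean"), method = "complete")
}

#' Export a sample dendrogram as Newick text
#'
#' @param hc An [stats::hclust] object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Full discovery-stage differential abundance table
#'
#' Runs the complete discovery chain on a filtered matrix: log2 fold changes,
#' z-score centering, moderated t-test, BH adjustment and the dual selection
#' rule.
#'
#' @inheritParams filter_quantified
#' @param criteria A [selection_criteria()].
#' @param params Optional [moderated_params()]; estimated from the data when
#'   `NULL`.
#' @return Tibble with `protein_id`, `log2fc`, `z`, `t_mod`, `df_total`,
#'   `p_raw`, `q`, `direction`, `n_case_obs`, `n_control_obs`.
#' @export
discovery_results <- function(mat, samples, criteria = selection_criteria(),
                              params = NULL) {
  fc <- compute_log2fc(mat, samples)
  mt <- moderated_t_test(mat[fc$protein_id, , drop = FALSE], samples, params)
  res <- dplyr::inner_join(fc, mt, by = "protein_id")
  res$z <- center_fold_changes(res$log2fc)
  res$q <- adjust_bh(res$p_raw)
  res <- select_regulated(res, criteria)$records
  res[, c("protein_id", "log2fc", "z", "t_mod", "df_total", "p_raw", "q",
          "direction", "n_case_obs", "n_control_obs")]
}
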