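#' Integrate a chromatographic peak
#'
#' Finds the apex as the intensity maximum within `window` minutes of
#' `expected_rt`, extends the peak boundaries from the apex outward to the
#' first local minimum falling below 1% of the apex intensity (or to the
#' window edge), subtracts a linear baseline drawn between the two boundary
#' points, and integrates by the trapezoidal rule. The area is floored at 0.
#'
#' @param rt Strictly increasing retention times (minutes).
#' @param intensity Nonnegative trace intensities, same length.
#' @param expected_rt Scheduled apex retention time (minutes).
#' @param window Half-width (minutes) of the search window around
#'   `expected_rt`.
#' @return List with `area`, `rt_start`, `rt_apex`, `rt_end` and `zero_area`
#'   (flag: no signal in the window).
#' @export
integrate_peak <- function(rt, intensity, expected_rt, window) {
  if (window <= 0) stop("'window' must be > 0", call. = FALSE)
  if (length(rt) != length(intensity)) {
    stop("rt and intensity lengths differ", call. = FALSE)
  }
  idx <- which(rt >= expected_rt - window & rt <= expected_rt + window)
  if (!length(idx)) {
    return(list(area = 0, rt_start = NA_real_, rt_apex = NA_real_,
                rt_end = NA_real_, zero_area = TRUE))
  }
  seg_i <- intensity[idx]
  apex_rel <- which.max(seg_i)
  apex_val <- seg_i[apex_rel]
  if (apex_val <= 0) {
    return(list(area = 0, rt_start = rt[idx[1]], rt_apex = rt[idx[apex_rel]],
                rt_end = rt[idx[length(idx)]], zero_area = TRUE))
  }
  floor_val <- 0.01 * apex_val

  left <- apex_rel
  while (left > 1) {
    below <- seg_i[left] < floor_val
    is_min <- left < apex_rel &&
      seg_i[left] <= seg_i[left + 1] &&
      (left == 1 || seg_i[left] <= seg_i[left - 1])
    if (below && is_min) break
    left <- left - 1
  }
  right <- apex_rel
  n <- length(seg_i)
  while (right < n) {
    below <- seg_i[right] < floor_val
    is_min <- right > apex_rel &&
      seg_i[right] <= seg_i[right - 1] &&
      (right == n || seg_i[right] <= seg_i[right + 1])
    if (below && is_min) break
    right <- right + 1
  }

  span <- idx[left:right]
  x <- rt[span]
  y <- intensity[span]
  base <- y[1] + (y[length(y)] - y[1]) * (x - x[1]) / (x[length(x)] - x[1])
  if (length(x) < 2L) {
    area <- 0
  } else {
    area <- max(pracma::trapz(x, y - base), 0)
  }
  list(area = area, rt_start = x[1], rt_apex = rt[idx[apex_rel]],
       rt_end = x[length(x)], zero_area = area <= 0)
}

#' Pick the best transition of a peptide in one sample
#'
#' Each transition is scored by its integrated peak area divided by a
#' baseline-noise estimate (the median absolute deviation of the signal
#' outside the integrated peak). Noiseless traces with signal get infinite
#' score. Ties are broken by lexicographic transition id; all-zero traces
#' return the first transition with a zero-area flag.
#'
#' @param traces Tibble of one sample x peptide: `transition_id`, `rt_min`,
#'   `intensity`.
#' @param expected_rt,window Passed to [integrate_peak()].
#' @return List with `transition_id`, `peak` (the winning [integrate_peak()]
#'   result) and `snr`.
#' @export
pick_best_transition <- function(traces, expected_rt, window) {
  ids <- sort(unique(traces$transition_id))
  if (!length(ids)) stop("no transitions supplied", call. = FALSE)
  best <- NULL
  best_score <- -Inf
  best_id <- ids[1]
  for (tid in ids) {
    tr <- traces[traces$transition_id == tid, ]
    ord <- order(tr$rt_min)
    rt <- tr$rt_min[ord]
    y <- tr$intensity[ord]
    pk <- integrate_peak(rt, y, expected_rt, window)
    off <- y[is.na(pk$rt_start) | rt < pk$rt_start | rt > pk$rt_end]
    noise <- if (length(off)) stats::mad(off, center = 0) else 0
    score <- if (pk$area <= 0) 0 else if (noise <= 0) Inf else pk$area / noise
    if (is.null(best) || score > best_score) {
      best <- pk
      best_score <- score
      best_id <- tid
    }
  }
  list(transition_id = best_id, peak = best, snr = best_score)
}

#' Quantify every sample x peptide from transition chromatograms
#'
#' Applies best-transition selection and peak integration to a long
#' chromatogram table.
#'
#' @param chromatograms Long tibble: `sample_id`, `peptide_id`,
#'   `transition_id`, `rt_min`, `intensity`.
#' @param design A [prm_design()] supplying expected retention times.
#' @param window Integration search half-window in minutes; defaults to half
#'   the scheduled grid span.
#' @return Peak-area tibble: `sample_id`, `peptide_id`, `best_transition_id`,
#'   `area`, `rt_start`, `rt_apex`, `rt_end`, `zero_area`.
#' @export
quantify_chromatograms <- function(chromatograms, design, window = NULL) {
  stopifnot(inherits(design, "prm_design"))
  if (is.null(window)) {
    window <- diff(range(design$rt_grid)) / 2
  }
  exp_rt <- stats::setNames(design$targets$expected_rt_min,
                            design$targets$peptide_id)
  unknown <- setdiff(unique(chromatograms$peptide_id), names(exp_rt))
  if (length(unknown)) {
    stop("chromatograms contain peptides absent from the design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  groups <- dplyr::group_split(
    dplyr::group_by(chromatograms, .data$sample_id, .data$peptide_id))
  rows <- lapply(groups, function(g) {
    pep <- g$peptide_id[1]
    res <- pick_best_transition(g, exp_rt[[pep]], window)
    tibble::tibble(
      sample_id = g$sample_id[1],
      peptide_id = pep,
      best_transition_id = res$transition_id,
      area = res$peak$area,
      rt_start = res$peak$rt_start,
      rt_apex = res$peak$rt_apex,
      rt_end = res$peak$rt_end,
      zero_area = res$peak$zero_area
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-sample normalization factors
#'
#' Stage 1: `irt_median`, the median of the sample's iRT standard peptide
#' areas, corrects LC-MS/MS drift. Stage 2: `reference_signal`, the summed
#' iRT-normalized areas of the reference-protein (BTD) quantifier peptides,
#' corrects protein-loading (Bradford) variation.
#'
#' @param areas Peak-area tibble from [quantify_chromatograms()].
#' @param design A [prm_design()].
#' @return Tibble: `sample_id`, `irt_median`, `reference_signal`.
#' @export
compute_normalization <- function(areas, design) {
  t <- design$targets
  irt_ids <- t$peptide_id[t$is_irt]
  ref_ids <- t$peptide_id[t$is_reference]
  out <- lapply(split(areas, areas$sample_id), function(a) {
    s <- a$sample_id[1]
    irt <- a$area[a$peptide_id %in% irt_ids]
    if (!length(irt) || !any(irt > 0)) {
      stop("sample ", s, ": no positive iRT peptide area", call. = FALSE)
    }
    irt_median <- stats::median(irt)
    ref <- a$area[a$peptide_id %in% ref_ids]
    if (!length(ref) || sum(ref) <= 0) {
      stop("sample ", s, ": no positive reference (BTD) peptide area",
           call. = FALSE)
    }
    tibble::tibble(sample_id = s, irt_median = irt_median,
                   reference_signal = sum(ref) / irt_median)
  })
  dplyr::bind_rows(out)
}

#' Apply the dual normalization
#'
#' `normalized = (area / irt_median) / reference_signal`, iRT stage first,
#' reference-protein stage second. The reference peptides themselves
#' normalize to sample-independent constants, and any technical factor common
#' to all of a sample's traces cancels end to end.
#'
#' @param areas Peak-area tibble.
#' @param factors Output of [compute_normalization()].
#' @return `areas` with a `normalized` column.
#' @export
apply_normalization <- function(areas, factors) {
  miss <- setdiff(unique(areas$sample_id), factors$sample_id)
  if (length(miss)) {
    stop("normalization factors missing for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(areas, factors, by = "sample_id")
  out$normalized <- (out$area / out$irt_median) / out$reference_signal
  out
}

#' Roll peptides up to protein intensities
#'
#' A protein's value in a sample is the sum of its two quantifier peptides'
#' normalized areas. If one peptide is missing (zero-area flag), the
#' remaining one is used and the value flagged partial; if both are missing
#' the protein is `NA` for that sample.
#'
#' @param normalized Output of [apply_normalization()].
#' @param design A [prm_design()].
#' @return Tibble: `sample_id`, `protein_id`, `gene`, `intensity`,
#'   `n_peptides`, `partial`.
#' @export
rollup_protein <- function(normalized, design) {
  t <- design$targets[!design$targets$is_irt, ]
  x <- dplyr::inner_join(
    normalized, t[, c("peptide_id", "protein_id", "gene")], by = "peptide_id")
  x$value <- ifelse(x$zero_area, NA_real_, x$normalized)
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$sample_id, .data$protein_id, .data$gene),
    intensity = if (all(is.na(.data$value))) NA_real_
                else sum(.data$value, na.rm = TRUE),
    n_peptides = sum(!is.na(.data$value)),
    .groups = "drop"
  )
  out$partial <- !is.na(out$intensity) & out$n_peptides < 2L
  out
}

#' Welch two-sample t-test
#'
#' `t = (mean1 - mean2) / sqrt(v1/n1 + v2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. When both groups are constant:
#' equal means give `t = 0, p = 1`; unequal means give an infinite statistic
#' with `p = 0`.
#'
#' @param x,y Numeric vectors (case, control), each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs >= 2 observed values", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  delta <- mean(x) - mean(y)
  if (se2 == 0) {
    if (delta == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    return(list(t = sign(delta) * Inf, df = n1 + n2 - 2, p = 0))
  }
  t <- delta / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Group intensity ratio (case over control)
#'
#' Ratio of group means on the normalized linear intensity scale.
#'
#' @param x,y Numeric vectors (case, control).
#' @return `mean(x) / mean(y)`.
#' @export
group_ratio <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  my <- mean(y)
  if (!is.finite(my) || my <= 0) {
    stop("control group mean must be > 0", call. = FALSE)
  }
  mean(x) / my
}

# significance stars; thresholds ordered smallest-first with matching symbols
significance_stars <- function(p, thresholds = c(1e-4, 1e-3, 0.05),
                               symbols = c("***", "**", "*")) {
  out <- rep("", length(p))
  for (i in seq_along(thresholds)) {
    out[p < thresholds[i] & out == ""] <- symbols[i]
  }
  out
}

#' Case vs control comparison of a protein intensity table
#'
#' For each protein: PE/CTL ratio of group means, Welch test on the
#' normalized linear intensities, and significance stars
#' (`*`/`**`/`***` at p < 0.05 / 0.001 / 0.0001, the validation-table
#' convention; override via `star_thresholds`).
#'
#' @param protein_table Output of [rollup_protein()] (long), or any tibble
#'   with `sample_id`, `protein_id`, `gene`, `intensity`.
#' @param samples Sample table with `sample_id`, `group`.
#' @param log_scale Test on log2 intensities instead of linear (ratio is
#'   always on the linear scale).
#' @param star_thresholds,star_symbols Star legend (smallest threshold
#'   first).
#' @return Tibble: `protein_id`, `gene`, `ratio`, `t`, `df`, `p`,
#'   `significance`.
#' @export
compare_groups <- function(protein_table, samples, log_scale = FALSE,
                           star_thresholds = c(1e-4, 1e-3, 0.05),
                           star_symbols = c("***", "**", "*")) {
  x <- dplyr::left_join(protein_table,
                        samples[, c("sample_id", "group")], by = "sample_id")
  if (anyNA(x$group)) stop("samples table does not cover all samples",
                           call. = FALSE)
  rows <- lapply(split(x, x$protein_id), function(g) {
    cs <- g$intensity[g$group == "case"]
    ct <- g$intensity[g$group == "control"]
    tv <- if (log_scale) welch_test(log2(cs), log2(ct)) else welch_test(cs, ct)
    tibble::tibble(
      protein_id = g$protein_id[1],
      gene = g$gene[1],
      ratio = group_ratio(cs, ct),
      t = tv$t, df = tv$df, p = tv$p
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$p), ]
  out$significance <- significance_stars(out$p, star_thresholds, star_symbols)
  out
}
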