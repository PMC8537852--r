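#' Empirical ROC curve points
#'
#' Step curve over all distinct score thresholds with the classification rule
#' "positive if score >= threshold" (higher score = more case-like). The
#' curve starts at (0, 0) (threshold `Inf`) and ends at (1, 1).
#'
#' @param scores Numeric vector.
#' @param labels Character/factor vector, `"case"` or `"control"`.
#' @return Tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  check_scoreset(scores, labels)
  case <- scores[labels == "case"]
  ctrl <- scores[labels == "control"]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble::tibble(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(ctrl >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(case >= t), numeric(1))
  )
}

check_scoreset <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels lengths differ", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) stop("scoreset contains NA", call. = FALSE)
  if (!all(labels %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'", call. = FALSE)
  }
  if (!any(labels == "case") || !any(labels == "control")) {
    stop("scoreset needs at least one case and one control", call. = FALSE)
  }
  invisible(TRUE)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Mean over all case-control pairs of 1 if the case outscores the control,
#' 0.5 on ties, 0 otherwise.
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  check_scoreset(scores, labels)
  case <- scores[labels == "case"]
  ctrl <- scores[labels == "control"]
  cmp <- outer(case, ctrl, ">") + 0.5 * outer(case, ctrl, "==")
  mean(cmp)
}

#' Standard error, confidence interval and p-value for an AUC
#'
#' Hanley-McNeil standard error under the exponential approximation:
#' with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)},
#' \deqn{SE = \sqrt{\frac{A(1-A) + (n_1-1)(Q_1-A^2) + (n_2-1)(Q_2-A^2)}{n_1 n_2}}}
#' The 95% CI is \eqn{A \pm 1.96\,SE} clipped to \[0, 1\]; the p-value is a
#' two-sided normal test of A against 0.5.
#'
#' @param auc AUC estimate in \[0, 1\].
#' @param n_case,n_control Group sizes (>= 2).
#' @return List with `se`, `ci_low`, `ci_high`, `p_vs_half`.
#' @export
auc_inference <- function(auc, n_case, n_control) {
  if (!is.finite(auc) || auc < 0 || auc > 1) {
    stop("'auc' must be in [0, 1]", call. = FALSE)
  }
  if (n_case < 2 || n_control < 2) {
    stop("need at least 2 cases and 2 controls", call. = FALSE)
  }
  a <- auc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n_case - 1) * (q1 - a^2) +
                (n_control - 1) * (q2 - a^2)) / (n_case * n_control))
  if (se > 0) {
    p <- 2 * stats::pnorm(abs(a - 0.5) / se, lower.tail = FALSE)
  } else {
    p <- if (a == 0.5) 1 else 0
  }
  list(
    se = se,
    ci_low = max(0, a - 1.96 * se),
    ci_high = min(1, a + 1.96 * se),
    p_vs_half = p
  )
}

# DeLong variance of the AUC from placement values
delong_inference <- function(scores, labels) {
  case <- scores[labels == "case"]
  ctrl <- scores[labels == "control"]
  m <- length(case); n <- length(ctrl)
  cmp <- outer(case, ctrl, ">") + 0.5 * outer(case, ctrl, "==")
  a <- mean(cmp)
  v10 <- rowMeans(cmp)   # placement of each case among controls
  v01 <- colMeans(cmp)   # placement of each control among cases
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  if (se > 0) {
    p <- 2 * stats::pnorm(abs(a - 0.5) / se, lower.tail = FALSE)
  } else {
    p <- if (a == 0.5) 1 else 0
  }
  list(se = se, ci_low = max(0, a - 1.96 * se),
       ci_high = min(1, a + 1.96 * se), p_vs_half = p)
}

#' Sensitivity at a fixed false-positive rate
#'
#' The decision threshold is the `ceiling((1 - fpr_target) * n_control)`-th
#' order statistic of the control scores; a subject is called positive when
#' its score is strictly greater. With 20 controls and a 10% target this
#' admits exactly 2 control positives. No interpolation; the achieved FPR
#' (always <= the target) is reported alongside.
#'
#' @inheritParams roc_points
#' @param fpr_target Allowed control-positive fraction in \[0, 1\].
#' @return List with `sensitivity`, `threshold`, `achieved_fpr`.
#' @export
sensitivity_at_fpr <- function(scores, labels, fpr_target = 0.10) {
  check_scoreset(scores, labels)
  if (fpr_target < 0 || fpr_target > 1) {
    stop("'fpr_target' must be in [0, 1]", call. = FALSE)
  }
  case <- scores[labels == "case"]
  ctrl <- sort(scores[labels == "control"])
  k <- ceiling((1 - fpr_target) * length(ctrl))
  thr <- if (k < 1) -Inf else ctrl[k]
  list(
    sensitivity = mean(case > thr),
    threshold = thr,
    achieved_fpr = mean(ctrl > thr)
  )
}

#' One-stop ROC summary for a marker
#'
#' @inheritParams roc_points
#' @param fpr_target Fixed false-positive rate for the detection-rate readout.
#' @param ci_method `"hanley"` (default) or `"delong"`.
#' @return One-row tibble: `auc`, `se`, `ci_low`, `ci_high`, `p_vs_half`,
#'   `sens_at_fpr`, `achieved_fpr`, `fpr_target`, `n_case`, `n_control`.
#' @export
roc_summary <- function(scores, labels, fpr_target = 0.10,
                        ci_method = c("hanley", "delong")) {
  ci_method <- match.arg(ci_method)
  a <- auc(scores, labels)
  n1 <- sum(labels == "case")
  n2 <- sum(labels == "control")
  inf <- if (ci_method == "hanley") auc_inference(a, n1, n2)
         else delong_inference(scores, labels)
  sens <- sensitivity_at_fpr(scores, labels, fpr_target)
  tibble::tibble(
    auc = a, se = inf$se, ci_low = inf$ci_low, ci_high = inf$ci_high,
    p_vs_half = inf$p_vs_half, sens_at_fpr = sens$sensitivity,
    achieved_fpr = sens$achieved_fpr, fpr_target = fpr_target,
    n_case = n1, n_control = n2
  )
}

#' Two-timepoint longitudinal comparison table
#'
#' For every protein and timepoint: PE/CTL ratio of group means and Welch
#' p-value, with significance stars (`*`/`**` at p < 0.05 / 0.01, the
#' longitudinal-table convention). A protein is flagged as a both-timepoint
#' marker when it is significantly upregulated (p < 0.05 and ratio > 1) at
#' every timepoint.
#'
#' @param tables Named list (one per timepoint, in temporal order) of protein
#'   intensity tibbles with `sample_id`, `protein_id`, `gene`, `intensity`.
#' @param samples Sample table covering all timepoints (`sample_id`, `group`,
#'   `timepoint`).
#' @param p_threshold Per-timepoint significance level.
#' @return Tibble: `protein_id`, `gene`, `timepoint`, `ratio`, `p`,
#'   `significance`, `significant_up`; the both-timepoint marker ids are in
#'   attribute `"both_timepoints"`.
#' @export
longitudinal_table <- function(tables, samples, p_threshold = 0.05) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("'tables' must be a named list (timepoint labels)", call. = FALSE)
  }
  per_tp <- lapply(names(tables), function(tp) {
    cmp <- compare_groups(tables[[tp]],
                          samples[samples$timepoint == tp, ],
                          star_thresholds = c(0.01, 0.05),
                          star_symbols = c("**", "*"))
    cmp$timepoint <- tp
    cmp
  })
  out <- dplyr::bind_rows(per_tp)
  out$significant_up <- out$p < p_threshold & out$ratio > 1
  both <- Reduce(intersect, lapply(per_tp, function(x)
    x$protein_id[x$p < p_threshold & x$ratio > 1]))
  out <- out[, c("protein_id", "gene", "timepoint", "ratio", "p",
                 "significance", "significant_up")]
  attr(out, "both_timepoints") <- both
  out
}
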