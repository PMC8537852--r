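#' Cohort simulation configuration
#'
#' Bundles every parameter of the synthetic discovery / longitudinal cohort
#' generator. The generative model is additive on the log2 scale (log-normal on
#' the raw intensity scale): for protein \eqn{g} in sample \eqn{s},
#' \deqn{\log_2 I_{gs} = \mu_g + \beta_g \cdot \mathrm{case}(s) + \pi_s + \epsilon_{gs}}
#' where \eqn{\mu_g} is the protein baseline, \eqn{\beta_g} a planted
#' regulation effect (cases only), \eqn{\pi_s} a per-sample global proteinuria
#' shift applied to every protein of a case sample, and \eqn{\epsilon_{gs}}
#' technical noise. Values are then left-censored (missing-not-at-random)
#' with detection-failure probability
#' \eqn{\mathrm{logit}^{-1}((m_0 - \log_2 I)/k)} so that low-abundance
#' measurements go missing preferentially.
#'
#' Defaults mirror the scale of a two-arm urinary LFQ study: 1108 proteins,
#' 12 cases vs 12 controls, 53 planted up / 9 down with |log2 fold change| in
#' \[1.5, 3\], and a ~1 log2-unit case-wide proteinuria shift.
#'
#' @param n_case,n_control Number of case / control samples.
#' @param n_proteins Number of simulated proteins.
#' @param n_de_up,n_de_down Number of planted up-/down-regulated proteins.
#' @param de_log2fc_range Length-2 numeric; planted |log2FC| drawn uniformly
#'   from this range.
#' @param baseline_log2_mean,baseline_log2_sd Protein baseline abundance
#'   distribution (log2 LFQ-intensity scale).
#' @param tech_noise_log2_sd Technical noise sd (log2 units).
#' @param proteinuria_log2_mean,proteinuria_log2_sd Per-case-sample global
#'   shift distribution (log2 units); controls get no shift.
#' @param missing_midpoint_log2 Log2 intensity at which the detection-failure
#'   probability is 50%.
#' @param missing_slope Logistic scale of the censoring curve (log2 units,
#'   must be > 0); smaller = sharper censoring.
#' @param subject_log2_sd Between-subject random intercept sd (log2 units),
#'   used by the longitudinal generator; each subject keeps its intercept
#'   across timepoints.
#' @param seed Integer seed making generation deterministic.
#'
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_proteins = 50, seed = 7)
cohort_config <- function(n_case = 12L,
                          n_control = 12L,
                          n_proteins = 1108L,
                          n_de_up = 53L,
                          n_de_down = 9L,
                          de_log2fc_range = c(1.5, 3),
                          baseline_log2_mean = 23,
                          baseline_log2_sd = 2,
                          tech_noise_log2_sd = 0.5,
                          proteinuria_log2_mean = 1,
                          proteinuria_log2_sd = 0.3,
                          missing_midpoint_log2 = 18.5,
                          missing_slope = 1,
                          subject_log2_sd = 0.3,
                          seed = 1L) {
  cfg <- list(
    n_case = as.integer(n_case),
    n_control = as.integer(n_control),
    n_proteins = as.integer(n_proteins),
    n_de_up = as.integer(n_de_up),
    n_de_down = as.integer(n_de_down),
    de_log2fc_range = as.numeric(de_log2fc_range),
    baseline_log2_mean = as.numeric(baseline_log2_mean),
    baseline_log2_sd = as.numeric(baseline_log2_sd),
    tech_noise_log2_sd = as.numeric(tech_noise_log2_sd),
    proteinuria_log2_mean = as.numeric(proteinuria_log2_mean),
    proteinuria_log2_sd = as.numeric(proteinuria_log2_sd),
    missing_midpoint_log2 = as.numeric(missing_midpoint_log2),
    missing_slope = as.numeric(missing_slope),
    subject_log2_sd = as.numeric(subject_log2_sd),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  for (f in c("n_case", "n_control", "n_proteins")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("cohort_config field '", f, "' must be a positive count", call. = FALSE)
    }
  }
  for (f in c("n_de_up", "n_de_down")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0L) {
      stop("cohort_config field '", f, "' must be a non-negative count", call. = FALSE)
    }
  }
  if (cfg$n_de_up + cfg$n_de_down > cfg$n_proteins) {
    stop("cohort_config fields 'n_de_up' + 'n_de_down' exceed 'n_proteins'",
         call. = FALSE)
  }
  if (length(cfg$de_log2fc_range) != 2L || any(!is.finite(cfg$de_log2fc_range)) ||
      diff(cfg$de_log2fc_range) < 0) {
    stop("cohort_config field 'de_log2fc_range' must be an increasing pair",
         call. = FALSE)
  }
  for (f in c("baseline_log2_sd", "tech_noise_log2_sd", "proteinuria_log2_sd",
              "subject_log2_sd")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      stop("cohort_config field '", f, "' must be a non-negative sd", call. = FALSE)
    }
  }
  if (!is.finite(cfg$missing_slope) || cfg$missing_slope <= 0) {
    stop("cohort_config field 'missing_slope' must be > 0", call. = FALSE)
  }
  if (is.na(cfg$seed)) {
    stop("cohort_config field 'seed' must be an integer", call. = FALSE)
  }
  invisible(cfg)
}

#' Selection criteria for regulated proteins
#'
#' The discovery-stage dual rule: a protein is called regulated when
#' `|z| > z_abs_threshold` and `q < q_threshold`, both strict.
#'
#' @param z_abs_threshold Absolute centered-z cutoff (default 1.96).
#' @param q_threshold BH q-value cutoff (default 0.05).
#' @return A list of class `selection_criteria`.
#' @export
selection_criteria <- function(z_abs_threshold = 1.96, q_threshold = 0.05) {
  if (!is.finite(z_abs_threshold) || z_abs_threshold <= 0) {
    stop("'z_abs_threshold' must be > 0", call. = FALSE)
  }
  if (!is.finite(q_threshold) || q_threshold <= 0) {
    stop("'q_threshold' must be > 0", call. = FALSE)
  }
  structure(list(z_abs_threshold = z_abs_threshold, q_threshold = q_threshold),
            class = "selection_criteria")
}
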