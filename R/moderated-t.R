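#' Moderated-test prior parameters
#'
#' The empirical-Bayes prior on residual variances: an inverse-chi-square
#' prior with `d0` degrees of freedom and location `s0_sq`. `d0 = 0` gives
#' the classical pooled two-sample t-test; `d0 = Inf` replaces every
#' per-protein variance by `s0_sq`.
#'
#' @param d0 Prior degrees of freedom, >= 0, may be `Inf`.
#' @param s0_sq Prior variance, > 0.
#' @return A list of class `moderated_params`.
#' @export
moderated_params <- function(d0, s0_sq) {
  if (is.na(d0) || d0 < 0) stop("'d0' must be >= 0 (possibly Inf)", call. = FALSE)
  if (!is.finite(s0_sq) || s0_sq <= 0) stop("'s0_sq' must be > 0", call. = FALSE)
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderated_params")
}

# Newton inversion of the trigamma function (solve trigamma(x) = y)
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

# Method-of-moments fit of the variance prior from per-protein sample
# variances s2 on df degrees of freedom (log-variance moments of the scaled
# F distribution).
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L) stop("too few positive variances to fit the prior",
                         call. = FALSE)
  z <- log(s2[ok])
  d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- mean((e - emean)^2 * n / (n - 1) - trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond sampling noise: variances look exchangeable
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  }
  moderated_params(d0, s0_sq)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' For each protein, the pooled residual variance \eqn{s^2} on
#' \eqn{d = n_1 + n_2 - 2} degrees of freedom is shrunk toward a prior:
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}
#' and the moderated statistic is
#' \eqn{t = \mathrm{log2fc} / (\tilde s \sqrt{1/n_1 + 1/n_2})}, referred to a
#' t distribution on \eqn{d_0 + d} degrees of freedom, capped at the pooled
#' residual df of the dataset. Computed on log2 intensities, available-case.
#' When `params` is `NULL` the prior is estimated from the data by the
#' method of moments on log residual variances.
#'
#' @inheritParams filter_quantified
#' @param params A [moderated_params()], or `NULL` to estimate.
#' @return Tibble with `protein_id`, `t_mod`, `df_total`, `p_raw`, `s2`,
#'   `df_resid`, plus the prior used in attribute `"params"`.
#' @export
moderated_t_test <- function(mat, samples, params = NULL) {
  grp <- group_columns(mat, samples)
  lg <- log2(mat)
  case <- lg[, grp$case, drop = FALSE]
  ctrl <- lg[, grp$control, drop = FALSE]

  n1 <- rowSums(!is.na(case))
  n2 <- rowSums(!is.na(ctrl))
  m1 <- rowMeans(case, na.rm = TRUE)
  m2 <- rowMeans(ctrl, na.rm = TRUE)
  ss1 <- rowSums((case - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((ctrl - m2)^2, na.rm = TRUE)
  df_resid <- n1 + n2 - 2

  usable <- df_resid >= 1 & n1 >= 1 & n2 >= 1
  if (any(!usable)) {
    message(sum(!usable), " protein(s) excluded from the moderated test ",
            "(fewer than 3 observed values)")
  }
  n1 <- n1[usable]; n2 <- n2[usable]
  fc <- (m1 - m2)[usable]
  s2 <- ((ss1 + ss2) / df_resid)[usable]
  d <- df_resid[usable]

  if (is.null(params)) params <- estimate_variance_prior(s2, d)
  stopifnot(inherits(params, "moderated_params"))
  d0 <- params$d0
  s0 <- params$s0_sq

  # total df capped at the pooled residual df: the prior cannot contribute
  # more information than the whole dataset carries
  df_pooled <- sum(d)
  if (is.infinite(d0)) {
    s2_post <- rep(s0, length(s2))
    df_total <- rep(df_pooled, length(s2))
  } else {
    s2_post <- (d0 * s0 + d * s2) / (d0 + d)
    df_total <- pmin(d0 + d, df_pooled)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- fc / se
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)

  out <- tibble::tibble(
    protein_id = rownames(mat)[usable],
    t_mod = unname(t_mod),
    df_total = unname(df_total),
    p_raw = unname(p),
    s2 = unname(s2),
    df_resid = unname(d)
  )
  attr(out, "params") <- params
  out
}
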