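# Independent oracle implementations used to cross-check the package.
# These are deliberately naive and kept free of any package internals.

# literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j
bh_step_up_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(m * p[o] / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# tie-aware AUC by exhaustive pair counting (double loop)
auc_pairs_oracle <- function(case, ctrl) {
  s <- 0
  for (x in case) for (y in ctrl) {
    s <- s + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  s / (length(case) * length(ctrl))
}

# ROC by exhaustive threshold enumeration with the ">= threshold" rule
roc_enum_oracle <- function(case, ctrl) {
  thr <- c(Inf, sort(unique(c(case, ctrl)), decreasing = TRUE))
  data.frame(
    threshold = thr,
    fpr = sapply(thr, function(t) mean(ctrl >= t)),
    tpr = sapply(thr, function(t) mean(case >= t))
  )
}

# naive agglomerative complete linkage on a distance matrix; returns merge
# heights and the member sets created at each merge
complete_linkage_oracle <- function(dmat) {
  clusters <- as.list(seq_len(nrow(dmat)))
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        h <- max(dmat[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    members <- c(members, list(merged))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, members = members)
}

# member sets of an hclust merge sequence
hclust_members <- function(hc) {
  n <- length(hc$height)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    grab <- function(x) if (x < 0) -x else out[[x]]
    out[[k]] <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
  }
  out
}

# classical pooled two-sample t-test on log2 values (available-case)
pooled_t_oracle <- function(case, ctrl) {
  case <- case[!is.na(case)]
  ctrl <- ctrl[!is.na(ctrl)]
  n1 <- length(case); n2 <- length(ctrl)
  sp2 <- ((n1 - 1) * var(case) + (n2 - 1) * var(ctrl)) / (n1 + n2 - 2)
  t <- (mean(case) - mean(ctrl)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(abs(t), n1 + n2 - 2, lower.tail = FALSE))
}

# a clean Gaussian peak trace on a uniform grid
gaussian_trace <- function(amplitude, sigma, center, step = sigma / 10,
                           halfwidth = 6 * sigma) {
  rt <- seq(center - halfwidth, center + halfwidth, by = step)
  list(rt = rt, intensity = amplitude * exp(-(rt - center)^2 / (2 * sigma^2)))
}

# small cohort config for fast tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_case = 6L, n_control = 6L, n_proteins = 60L,
                   n_de_up = 5L, n_de_down = 2L,
                   missing_midpoint_log2 = 16, seed = 42L)
  defaults[names(args)] <- args
  do.call(cohort_config, defaults)
}

# a 2-transition, 2-protein + reference + iRT micro assay design
micro_design <- function(peak_sigma = 0.08) {
  targets <- tibble::tibble(
    protein_id = c(rep("P1", 2), rep("P2", 2), rep("REF", 2), rep("iRT_kit", 3)),
    gene = c(rep("G1", 2), rep("G2", 2), rep("BTD", 2), rep("iRT", 3)),
    peptide_id = c("P1_a", "P1_b", "P2_a", "P2_b", "REF_a", "REF_b",
                   "irt_1", "irt_2", "irt_3"),
    is_irt = c(rep(FALSE, 6), rep(TRUE, 3)),
    is_reference = c(rep(FALSE, 4), TRUE, TRUE, rep(FALSE, 3)),
    transitions = "y1;y2",
    expected_rt_min = seq(15, 55, length.out = 9)
  )
  prm_design(targets, rt_grid = seq(-1, 1, by = 0.02), peak_sigma = peak_sigma)
}

micro_samples <- function(n_case = 2, n_control = 2) {
  ids <- c(sprintf("case_%02d", seq_len(n_case)),
           sprintf("ctrl_%02d", seq_len(n_control)))
  tibble::tibble(sample_id = ids, subject_id = ids,
                 group = rep(c("case", "control"), c(n_case, n_control)),
                 timepoint = NA_character_)
}

micro_abundances <- function(samples, p1 = 4000, p2 = 1000, ref = 2000,
                             case_fold = 1) {
  is_case <- samples$group == "case"
  ab <- rbind(
    P1 = p1 * ifelse(is_case, case_fold, 1),
    P2 = p2 * ifelse(is_case, case_fold, 1),
    REF = rep(ref, nrow(samples))
  )
  colnames(ab) <- samples$sample_id
  ab
}
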