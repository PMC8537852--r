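test_that("peak integration recovers closed-form areas", {
  # Gaussian: area = A * sigma * sqrt(2*pi)
  g <- gaussian_trace(amplitude = 1000, sigma = 0.1, center = 30)
  pk <- integrate_peak(g$rt, g$intensity, expected_rt = 30, window = 0.6)
  expect_equal(pk$area, 1000 * 0.1 * sqrt(2 * pi), tolerance = 0.01)
  expect_false(pk$zero_area)
  expect_lte(pk$rt_start, pk$rt_apex)
  expect_lte(pk$rt_apex, pk$rt_end)

  # grid-refinement consistency: halving the step moves the area < 0.5%
  g2 <- gaussian_trace(1000, 0.1, 30, step = 0.1 / 20)
  pk2 <- integrate_peak(g2$rt, g2$intensity, 30, 0.6)
  expect_lt(abs(pk2$area - pk$area) / pk2$area, 0.005)

  # symmetric triangle, height h, half-width w: area = h * w
  rt <- seq(29, 31, by = 0.005)
  tri <- pmax(0, 500 * (1 - abs(rt - 30) / 0.2))
  pk3 <- integrate_peak(rt, tri, 30, 0.8)
  expect_equal(pk3$area, 500 * 0.2, tolerance = 0.01)

  # all-zero trace
  pk4 <- integrate_peak(rt, rep(0, length(rt)), 30, 0.5)
  expect_identical(pk4$area, 0)
  expect_true(pk4$zero_area)

  expect_error(integrate_peak(rt, tri, 30, 0), "window")
})

test_that("best-transition choice prefers signal over noise with documented tie-break", {
  g <- gaussian_trace(800, 0.08, 20, step = 0.01, halfwidth = 1)
  set.seed(6)
  traces <- dplyr::bind_rows(
    tibble::tibble(transition_id = "y2", rt_min = g$rt,
                   intensity = g$intensity + abs(rnorm(length(g$rt), 0, 5))),
    tibble::tibble(transition_id = "y1", rt_min = g$rt,
                   intensity = abs(rnorm(length(g$rt), 0, 5)))
  )
  expect_identical(pick_best_transition(traces, 20, 1)$transition_id, "y2")

  # single transition returns itself
  single <- traces[traces$transition_id == "y2", ]
  expect_identical(pick_best_transition(single, 20, 1)$transition_id, "y2")

  # exact tie -> lexicographically smallest id
  tie <- dplyr::bind_rows(
    tibble::tibble(transition_id = "yB", rt_min = g$rt, intensity = g$intensity),
    tibble::tibble(transition_id = "yA", rt_min = g$rt, intensity = g$intensity)
  )
  expect_identical(pick_best_transition(tie, 20, 1)$transition_id, "yA")

  # all-zero traces return the first transition flagged zero-area
  zero <- tibble::tibble(transition_id = rep(c("t1", "t2"), each = length(g$rt)),
                         rt_min = rep(g$rt, 2), intensity = 0)
  res <- pick_best_transition(zero, 20, 1)
  expect_identical(res$transition_id, "t1")
  expect_true(res$peak$zero_area)
})

test_that("normalization factors follow the iRT-median then reference-sum scheme", {
  des <- micro_design()
  areas <- tibble::tibble(
    sample_id = "s1",
    peptide_id = c("P1_a", "P1_b", "REF_a", "REF_b", "irt_1", "irt_2", "irt_3"),
    best_transition_id = "y1",
    area = c(1000, 500, 300, 100, 100, 200, 300),
    rt_start = 0, rt_apex = 0, rt_end = 0, zero_area = FALSE
  )
  f <- compute_normalization(areas, des)
  expect_equal(f$irt_median, 200)
  expect_equal(f$reference_signal, (300 + 100) / 200)
  norm <- apply_normalization(areas, f)
  expect_equal(norm$normalized[norm$peptide_id == "P1_a"],
               (1000 / 200) / 2)

  # missing iRT or reference signal names the sample
  bad <- areas[!grepl("irt", areas$peptide_id), ]
  expect_error(compute_normalization(bad, des), "s1")
  bad2 <- areas[!grepl("REF", areas$peptide_id), ]
  expect_error(compute_normalization(bad2, des), "s1")
})

test_that("dual normalization cancels per-sample technical scale end to end", {
  des <- micro_design()
  smp <- micro_samples()
  ab <- micro_abundances(smp)
  unit <- setNames(rep(1, nrow(smp)), smp$sample_id)
  prm <- generate_prm_dataset(des, smp, ab, loading_factor = unit,
                              drift_factor = unit, noise_sd = 0, seed = 9L)
  # multiply every trace of one sample by a constant
  chrom2 <- prm$chromatograms
  k <- chrom2$sample_id == "ctrl_01"
  chrom2$intensity[k] <- chrom2$intensity[k] * 7.3

  run <- function(ch) {
    a <- quantify_chromatograms(ch, des)
    rollup_protein(apply_normalization(a, compute_normalization(a, des)), des)
  }
  t1 <- run(prm$chromatograms)
  t2 <- run(chrom2)
  expect_equal(t1$intensity, t2$intensity, tolerance = 1e-9)

  # reference peptides normalize to a sample-independent constant
  a <- quantify_chromatograms(prm$chromatograms, des)
  norm <- apply_normalization(a, compute_normalization(a, des))
  ref <- norm[norm$peptide_id == "REF_a", ]
  expect_lt(diff(range(ref$normalized)) / mean(ref$normalized), 1e-9)
})

test_that("protein roll-up sums two peptides with partial flagging", {
  des <- micro_design()
  norm <- tibble::tibble(
    sample_id = rep("s1", 4),
    peptide_id = c("P1_a", "P1_b", "P2_a", "P2_b"),
    zero_area = c(FALSE, FALSE, TRUE, FALSE),
    normalized = c(3, 5, 0, 4)
  )
  out <- rollup_protein(norm, des)
  expect_equal(out$intensity[out$protein_id == "P1"], 8)
  expect_false(out$partial[out$protein_id == "P1"])
  expect_equal(out$intensity[out$protein_id == "P2"], 4)
  expect_true(out$partial[out$protein_id == "P2"])

  # both peptides missing -> NA
  norm$zero_area <- c(TRUE, TRUE, FALSE, FALSE)
  out2 <- rollup_protein(norm, des)
  expect_true(is.na(out2$intensity[out2$protein_id == "P1"]))

  # linearity
  norm$zero_area <- FALSE
  o1 <- rollup_protein(norm, des)
  norm2 <- norm
  norm2$normalized <- norm2$normalized * 2
  o2 <- rollup_protein(norm2, des)
  expect_equal(o2$intensity, o1$intensity * 2)
})

test_that("Welch test matches hand computation and the stats reference", {
  w <- welch_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(w$t, 1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$df, 4, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(w$t, 4, lower.tail = FALSE), tolerance = 1e-12)

  # identical groups
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # constant equal groups -> t = 0, p = 1
  expect_equal(welch_test(c(2, 2), c(2, 2)), list(t = 0, df = 2, p = 1))
  # equal variance and equal n -> df = 2n - 2
  expect_equal(welch_test(c(1, 2, 3, 4), c(2, 3, 4, 5))$df, 6, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:300) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    ref <- t.test(x, y)
    got <- welch_test(x, y)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("group ratio is the ratio of means and recovers planted fold changes", {
  expect_equal(group_ratio(c(6, 7), c(1, 1)), 6.5)
  expect_equal(group_ratio(c(2, 4), c(2, 4)), 1)
  expect_error(group_ratio(c(1, 2), c(0, 0)), "> 0")

  set.seed(12)
  case <- 2 * 2^rnorm(4000, 0, 0.3) # planted fold change 2
  ctrl <- 2^rnorm(4000, 0, 0.3)
  expect_equal(group_ratio(case, ctrl), 2, tolerance = 0.05)
})

test_that("normalization reduces the CV of null proteins under drift and loading", {
  des <- micro_design()
  smp <- micro_samples(4, 4)
  ab <- micro_abundances(smp)
  wins <- 0L
  for (s in 1:20) {
    set.seed(s)
    load <- setNames(2^rnorm(8, 0, 0.4), smp$sample_id)
    drift <- setNames(2^rnorm(8, 0, 0.3), smp$sample_id)
    prm <- generate_prm_dataset(des, smp, ab, loading_factor = load,
                                drift_factor = drift, noise_sd = 0, seed = s)
    a <- quantify_chromatograms(prm$chromatograms, des)
    norm <- rollup_protein(
      apply_normalization(a, compute_normalization(a, des)), des)
    raw <- dplyr::summarise(
      dplyr::group_by(dplyr::inner_join(
        a, des$targets[!des$targets$is_irt, c("peptide_id", "protein_id")],
        by = "peptide_id"), sample_id, protein_id),
      intensity = sum(area), .groups = "drop")
    cv <- function(x) sd(x) / mean(x)
    cv_raw <- cv(raw$intensity[raw$protein_id == "P1"])
    cv_norm <- cv(norm$intensity[norm$protein_id == "P1"])
    if (cv_norm < cv_raw) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})
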