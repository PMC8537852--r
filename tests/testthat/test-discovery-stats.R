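test_that("quantification filter matches a brute-force per-protein scan", {
  set.seed(5)
  mat <- matrix(2^rnorm(80, 20, 2), 10, 8,
                dimnames = list(sprintf("P%02d", 1:10), sprintf("S%d", 1:8)))
  mat[runif(80) < 0.4] <- NA
  samples <- tibble::tibble(sample_id = colnames(mat),
                            subject_id = colnames(mat),
                            group = rep(c("case", "control"), each = 4),
                            timepoint = NA_character_)
  got <- rownames(filter_quantified(mat, samples, 0.5))
  keep <- vapply(seq_len(nrow(mat)), function(i) {
    nc <- sum(!is.na(mat[i, 1:4])); nx <- sum(!is.na(mat[i, 5:8]))
    (nc / 4 >= 0.5 || nx / 4 >= 0.5) && nc >= 2 && nx >= 2
  }, logical(1))
  expect_identical(got, rownames(mat)[keep])

  # a fully observed protein survives; a 1-per-group protein does not
  mat2 <- mat
  mat2["P01", ] <- 100
  mat2["P02", ] <- c(100, NA, NA, NA, 100, NA, NA, NA)
  kept <- rownames(filter_quantified(mat2, samples, 0.5))
  expect_true("P01" %in% kept)
  expect_false("P02" %in% kept)
})

test_that("log2 fold change is the difference of observed group means of log2", {
  mat <- rbind(A = c(4, 4, 2, 2), B = c(8, 8, 8, 8))
  colnames(mat) <- c("c1", "c2", "x1", "x2")
  samples <- tibble::tibble(sample_id = colnames(mat),
                            subject_id = colnames(mat),
                            group = rep(c("case", "control"), each = 2),
                            timepoint = NA_character_)
  fc <- compute_log2fc(mat, samples)
  expect_equal(fc$log2fc[fc$protein_id == "A"], 1)
  expect_equal(fc$log2fc[fc$protein_id == "B"], 0)

  set.seed(9)
  mat3 <- matrix(2^rnorm(60, 20, 1), 10, 6,
                 dimnames = list(sprintf("Q%02d", 1:10), sprintf("S%d", 1:6)))
  mat3[sample(60, 10)] <- NA
  samples3 <- tibble::tibble(sample_id = colnames(mat3),
                             subject_id = colnames(mat3),
                             group = rep(c("case", "control"), each = 3),
                             timepoint = NA_character_)
  fc3 <- suppressMessages(compute_log2fc(mat3, samples3))
  for (p in fc3$protein_id) {
    cs <- log2(mat3[p, 1:3]); ct <- log2(mat3[p, 4:6])
    expect_equal(fc3$log2fc[fc3$protein_id == p],
                 mean(cs[!is.na(cs)]) - mean(ct[!is.na(ct)]))
  }
})

test_that("z-centering standardizes fold changes and ignores global shifts", {
  expect_equal(center_fold_changes(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  fc <- rnorm(200)
  z <- center_fold_changes(fc)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  # a constant shift (global proteinuria) leaves z untouched
  expect_equal(center_fold_changes(fc + 3.7), z, tolerance = 1e-10)
  expect_error(center_fold_changes(c(5, 5, 5)), "degenerate")
  expect_error(center_fold_changes(1), "at least 2")
})

test_that("BH adjustment reproduces hand-run examples and rejects bad input", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # q preserves the p ordering
  set.seed(3)
  p <- runif(300)
  q <- adjust_bh(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("moderated test matches limma's empirical-Bayes shrinkage", {
  skip_if_not_installed("limma")
  design <- model.matrix(~ rep(c(1, 0), each = 6))
  samples <- tibble::tibble(sample_id = sprintf("S%02d", 1:12),
                            subject_id = sprintf("S%02d", 1:12),
                            group = rep(c("case", "control"), each = 6),
                            timepoint = NA_character_)
  set.seed(21)
  # heteroscedastic proteins -> finite prior df
  sd_g <- exp(rnorm(200, log(0.6), 0.6))
  het <- matrix(2^(20 + rnorm(200 * 12) * rep(sd_g, 12)), 200, 12)
  # homoscedastic proteins -> infinite prior df (variances exchangeable)
  hom <- matrix(2^rnorm(200 * 12, 20, 2), 200, 12)
  for (mat in list(het, hom)) {
    dimnames(mat) <- list(sprintf("P%03d", 1:200), samples$sample_id)
    ours <- moderated_t_test(mat, samples)
    prm <- attr(ours, "params")
    fit <- limma::eBayes(limma::lmFit(log2(mat), design))
    expect_equal(prm$d0, fit$df.prior, tolerance = 1e-6)
    expect_equal(prm$s0_sq, fit$s2.prior, tolerance = 1e-6)
    expect_equal(ours$p_raw, unname(fit$p.value[, 2]), tolerance = 1e-8)
  }
})

test_that("dual selection applies strict thresholds with sign-consistent direction", {
  rec <- tibble::tibble(
    protein_id = c("a", "b", "c", "d"),
    z = c(2.5, 1.96, -2.2, 0.5),
    q = c(0.01, 0.001, 0.04, 0.2)
  )
  sel <- select_regulated(rec, selection_criteria())
  expect_identical(sel$up, "a")
  expect_identical(sel$down, "c")
  expect_identical(sel$records$direction, c("up", "none", "down", "none"))
})

test_that("candidate shortlisting excludes modified peptides and ranks by fold change", {
  rec <- tibble::tibble(
    protein_id = c("A", "B", "C", "D"),
    log2fc = c(3, 2.5, 2, 1.5),
    direction = c("up", "up", "up", "up")
  )
  ev <- tibble::tibble(
    protein_id = c("A", "A", "A", "B", "B", "C", "C", "D", "D"),
    peptide_id = paste0("pep", 1:9),
    peptide_sequence = "X",
    has_oxidized_met = c(FALSE, TRUE, FALSE, FALSE, FALSE,
                         FALSE, FALSE, FALSE, FALSE),
    missed_cleavages = c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
    total_intensity = c(10, 99, 5, 50, 40, 8, 9, 1, 2)
  )
  out <- shortlist_candidates(rec, ev, n_select = 2)
  # B has one eligible peptide left (missed cleavage kills the other) -> drop
  expect_identical(out$protein_id, c("A", "C"))
  # quantifiers are the two highest-intensity eligible peptides
  expect_identical(out$peptide_1[1], "pep1")  # pep2 is oxidized, pep1 > pep3
  expect_identical(out$peptide_2[1], "pep3")
  expect_warning(shortlist_candidates(rec, ev, n_select = 4), "eligible")

  # random instance against an explicit sort oracle
  set.seed(8)
  recs <- tibble::tibble(protein_id = sprintf("R%02d", 1:15),
                         log2fc = round(runif(15, 1, 3), 2),
                         direction = "up")
  ev2 <- generate_peptide_evidence(recs$protein_id, peptides_per_protein = 5,
                                   seed = 4)
  out2 <- shortlist_candidates(recs, ev2, n_select = 6)
  ok <- ev2[!ev2$has_oxidized_met & ev2$missed_cleavages == 0, ]
  elig <- names(which(table(ok$protein_id) >= 2))
  pool <- recs[recs$protein_id %in% elig, ]
  expect_identical(out2$protein_id,
                   pool$protein_id[order(-pool$log2fc)][1:6])
})

test_that("PCA scores separate planted groups and are orthogonal", {
  cfg <- cohort_config(n_case = 8L, n_control = 8L, n_proteins = 300L,
                       n_de_up = 80L, n_de_down = 0L,
                       de_log2fc_range = c(2, 3),
                       tech_noise_log2_sd = 0.5,
                       proteinuria_log2_mean = 0, proteinuria_log2_sd = 0,
                       missing_midpoint_log2 = 16, seed = 1L)
  hits <- 0L
  for (s in 1:20) {
    cfg$seed <- s
    sim <- generate_discovery_cohort(cfg)
    sc <- pca_scores(sim$matrix)
    case <- sc$PC1[sim$samples$group == "case"]
    ctrl <- sc$PC1[sim$samples$group == "control"]
    if (max(case) < min(ctrl) || max(ctrl) < min(case)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)

  sim <- generate_discovery_cohort(cfg)
  sc <- pca_scores(sim$matrix, n_components = 4)
  m <- as.matrix(sc[, -1])
  cross <- crossprod(m)
  expect_lt(max(abs(cross[upper.tri(cross)])), 1e-6)

  # a duplicated sample lands on identical coordinates
  mat <- sim$matrix
  mat <- cbind(mat, dup = mat[, 1])
  sc2 <- pca_scores(mat)
  expect_equal(unlist(sc2[sc2$sample_id == "dup", -1]),
               unlist(sc2[sc2$sample_id == colnames(mat)[1], -1]),
               ignore_attr = TRUE, tolerance = 1e-8)

  expect_error(pca_scores(sim$matrix[, 1:2]), "3 samples")
})

test_that("complete-linkage clustering matches an exhaustive oracle", {
  set.seed(14)
  mat <- matrix(2^rnorm(40 * 6, 20, 2), 40, 6,
                dimnames = list(sprintf("P%02d", 1:40), sprintf("S%d", 1:6)))
  hc <- cluster_samples(mat)
  lg <- log2(mat); lg <- lg - rowMeans(lg)
  oracle <- complete_linkage_oracle(as.matrix(dist(t(lg))))
  expect_equal(hc$height, oracle$heights, tolerance = 1e-10)
  expect_identical(hclust_members(hc), oracle$members)
  # heights are non-decreasing
  expect_true(all(diff(hc$height) >= -1e-12))

  # identical samples merge first at height 0
  mat2 <- mat
  mat2[, 2] <- mat2[, 1]
  hc2 <- cluster_samples(mat2)
  expect_equal(hc2$height[1], 0, tolerance = 1e-12)
  expect_identical(sort(hc2$merge[1, ]), c(-2L, -1L))

  # Newick export is a valid 6-leaf tree
  nwk <- dendrogram_newick(hc)
  phy <- ape::read.tree(text = nwk)
  expect_identical(sort(phy$tip.label), sort(colnames(mat)))
})
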