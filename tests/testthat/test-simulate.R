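test_that("methylome simulation is deterministic and honours degenerate settings", {
  spec <- sim_spec(genome_length = 5e4, n_hmrs = 2, seed = 7)
  a <- simulate_methylome(spec)
  b <- simulate_methylome(spec)
  expect_identical(a$methylome$sites, b$methylome$sites)
  expect_identical(a$hmr_truth, b$hmr_truth)

  # no HMRs, hyper level 1, infinite precision: every covered site fully
  # methylated
  spec1 <- sim_spec(genome_length = 2e4, n_hmrs = 0, hyper_level = 1,
                    betabin_precision = Inf, seed = 3)
  m <- simulate_methylome(spec1)$methylome
  expect_true(all(m$sites$meth == m$sites$total))

  expect_error(sim_spec(genome_length = -5), "positive")
  expect_error(sim_spec(coverage_mean = 0), "positive")
})

test_that("genome-wide methylation matches the planted mixture mean", {
  # 5,000 CpGs at density 10/kb over 500 kb, coverage 10, levels 0.1/0.85
  spec <- sim_spec(genome_length = 5e5, cpg_density = 10, coverage_mean = 10,
                   hypo_level = 0.1, hyper_level = 0.85, n_hmrs = 15,
                   seed = 21)
  sim <- simulate_methylome(spec)
  m <- sim$methylome
  # closed-form mixture mean from the planted-interval CpG fractions
  in_hmr <- rep(FALSE, nrow(m$sites))
  for (i in seq_len(nrow(sim$hmr_truth))) {
    in_hmr <- in_hmr | (m$sites$pos >= sim$hmr_truth$start[i] &
                          m$sites$pos < sim$hmr_truth$end[i])
  }
  expected <- mean(in_hmr) * 0.1 + (1 - mean(in_hmr)) * 0.85
  expect_equal(weighted_methylation(m), expected, tolerance = 0.02)
})

test_that("differentiation pair plants DMRs and the global methylation drop", {
  spec <- sim_spec(genome_length = 1e6, n_hmrs = 30,
                   dmr_spec = list(n_hypo_dmrs = 43, n_hyper_dmrs = 7,
                                   delta = 0.5, cpgs_per_dmr = 15),
                   global_loss = 0.04, seed = 13)
  pair <- simulate_differentiation_pair(spec)
  # bookkeeping: 50 truth rows, 43 losses
  expect_equal(nrow(pair$dmr_truth), 50L)
  expect_equal(sum(pair$dmr_truth$direction == "loss"), 43L)
  # the planted global drop is realised in the emitted counts
  drop <- weighted_methylation(pair$stem) - weighted_methylation(pair$villus)
  expect_lt(abs(as.numeric(drop) - 0.04), 0.01)
  # each planted DMR differs by ~delta in the recorded direction
  deltas <- vapply(seq_len(nrow(pair$dmr_truth)), function(i) {
    tr <- pair$dmr_truth[i, ]
    as.numeric(weighted_methylation(pair$stem, tr$chrom, tr$start, tr$end)) -
      as.numeric(weighted_methylation(pair$villus, tr$chrom, tr$start, tr$end))
  }, numeric(1))
  expect_true(all(deltas[pair$dmr_truth$direction == "loss"] > 0.25))
  expect_true(all(deltas[pair$dmr_truth$direction == "gain"] < -0.25))

  # null pair: no DMRs, no global loss -> conditions are exchangeable
  null_spec <- sim_spec(genome_length = 3e5, n_hmrs = 8,
                        dmr_spec = list(n_hypo_dmrs = 0, n_hyper_dmrs = 0,
                                        delta = 0.5, cpgs_per_dmr = 15),
                        global_loss = 0, seed = 17)
  null_pair <- simulate_differentiation_pair(null_spec)
  la <- null_pair$stem$sites$meth / pmax(null_pair$stem$sites$total, 1)
  lb <- null_pair$villus$sites$meth / pmax(null_pair$villus$sites$total, 1)
  expect_gt(wilcox.test(la, lb)$p.value, 0.01)

  # sub-noise-floor delta warns
  expect_warning(
    simulate_differentiation_pair(
      sim_spec(genome_length = 5e4, n_hmrs = 2, coverage_mean = 1.5,
               dmr_spec = list(n_hypo_dmrs = 1, n_hyper_dmrs = 0,
                               delta = 0.5, cpgs_per_dmr = 10),
               seed = 1)),
    "noise floor")
})

test_that("read-pattern simulation respects the co-methylation model", {
  m <- simulate_methylome(sim_spec(genome_length = 1e5, n_hmrs = 3,
                                   seed = 5))$methylome
  # rho = 1 on a fully methylated methylome: only mC,mC,mC
  full <- make_methylome(pos = (1:50) * 10, meth = rep(10, 50),
                         total = rep(10, 50))
  r1 <- simulate_read_patterns(full, rho = 1, n_reads = 200, seed = 2)
  expect_true(all(r1$m1 & r1$m2 & r1$m3))

  # rho = 1 generally: no intermediate classes
  rc <- simulate_read_patterns(m, rho = 1, n_reads = 2000, seed = 3)
  cls <- pattern_fractions(rc)$classes
  expect_equal(sum(cls$fraction[cls$n_meth %in% c(1, 2)]), 0)

  # rho = 0: fully methylated fraction equals the product of site levels
  lev <- c(0.8, 0.6, 0.7)
  m3 <- make_methylome(pos = c(10, 20, 30), meth = round(lev * 1000),
                       total = rep(1000, 3))
  r0 <- simulate_read_patterns(m3, rho = 0, n_reads = 20000, seed = 4)
  frac <- mean(r0$m1 & r0$m2 & r0$m3)
  p <- prod(lev)
  se <- sqrt(p * (1 - p) / 20000)
  expect_lt(abs(frac - p), 3 * se)

  # n_reads = 0 -> empty set, no error
  expect_equal(nrow(simulate_read_patterns(m3, 0.5, 0, seed = 1)), 0L)
  expect_error(simulate_read_patterns(m3, 1.2, 10), "rho")
  expect_error(simulate_read_patterns(make_methylome(10, 1, 2), 0.5, 10),
               ">= 3 CpGs")
})

test_that("4C track simulation plants detectable peaks and distinct classes", {
  sim <- simulate_4c_track(300, blind_fraction = 0.4, background_scale = 5,
                           peaks = list(list(position = 80, width = 20,
                                             enrichment = 10)),
                           seed = 6)
  f <- sim$track$fragments
  expect_true(all(diff(f$pos) > 0))
  # planted interval attains the maximal local mean count
  tt <- sim$peak_truth
  in_peak <- seq(tt$first, tt$last)
  peak_mean <- mean(f$count[in_peak])
  other <- setdiff(seq_len(300), in_peak)
  roll <- vapply(seq_len(280), function(i) mean(f$count[i:(i + 19)]),
                 numeric(1))
  expect_equal(which.max(roll) >= tt$first - 19 &&
                 which.max(roll) <= tt$last, TRUE)
  expect_gt(peak_mean, mean(f$count[other]))

  # blind_fraction = 0: all regular, normalization is the identity
  sim0 <- simulate_4c_track(100, blind_fraction = 0, seed = 8)
  expect_true(all(sim0$track$fragments$class == "regular"))
  n0 <- normalize_classes(sim0$track)
  expect_equal(n0$fragments$norm_count, as.numeric(sim0$track$fragments$count))

  expect_warning(simulate_4c_track(50, peaks = list(list(position = 10,
                                                         width = 5,
                                                         enrichment = 0.5)),
                                   seed = 1), "undetectable")
  expect_error(simulate_4c_track(50, peaks = list(list(position = 500,
                                                       width = 5,
                                                       enrichment = 5)),
                                 seed = 1), "outside")
  expect_identical(simulate_4c_track(100, seed = 3)$track$fragments,
                   simulate_4c_track(100, seed = 3)$track$fragments)
})

test_that("expression simulation plants recoverable fold changes", {
  ann <- simulate_annotations(genome_length = 1e6, n_genes = 50,
                              gene_length = c(3000, 10000), seed = 2)
  # strong effect, tiny noise: every planted gene passes the two-fold rule
  sim <- simulate_expression(ann$genes,
                             list(n_up = 5, n_down = 3, log2fc = 3,
                                  sigma = 0.1, n_replicates = 3), seed = 4)
  de <- de_genes(sim$expr, sim$groups, mode = "fold")
  planted <- sim$truth$gene_id[sim$truth$direction != "none"]
  expect_true(all(de$de[match(planted, de$gene_id)]))
  expect_equal(sum(de$de), 8L)
  up <- sim$truth$gene_id[sim$truth$direction == "up"]
  expect_true(all(de$log2fc[match(up, de$gene_id)] > 0))

  # sigma = 0: empirical fold change equals the planted value exactly
  exact <- simulate_expression(ann$genes,
                               list(n_up = 1, n_down = 0, log2fc = 2,
                                    sigma = 0, n_replicates = 2), seed = 5)
  de0 <- de_genes(exact$expr, exact$groups, mode = "fold")
  g <- exact$truth$gene_id[exact$truth$direction == "up"]
  expect_equal(de0$log2fc[match(g, de0$gene_id)], 2)

  # null spec: |log2FC| >= 1 count matches the analytic Gaussian tail
  nullsim <- simulate_expression(ann$genes,
                                 list(n_up = 0, n_down = 0, log2fc = 0,
                                      sigma = 0.6, n_replicates = 3),
                                 seed = 6)
  den <- de_genes(nullsim$expr, nullsim$groups, mode = "fold")
  p_fp <- 2 * pnorm(-1, sd = 0.6 * sqrt(2 / 3))
  se <- sqrt(50 * p_fp * (1 - p_fp))
  expect_lt(abs(sum(den$de) - 50 * p_fp), 3 * se + 1)

  expect_error(simulate_expression(ann$genes,
                                   list(n_up = 0, n_down = 0, log2fc = 0,
                                        sigma = 1, n_replicates = 1)),
               "replicates")
  expect_error(simulate_expression(ann$genes,
                                   list(n_up = 40, n_down = 20, log2fc = 1,
                                        sigma = 1, n_replicates = 3)),
               "more planted")
})

test_that("annotation simulation emits consistent genes, repeats and peaks", {
  ann <- simulate_annotations(genome_length = 1e6, n_genes = 10,
                              exons_per_gene = 3,
                              gene_length = c(3000, 10000), seed = 3)
  # 10 genes x 3 exons -> 20 introns
  n_introns <- sum(vapply(ann$genes$exon_starts, length, integer(1)) - 1L)
  expect_equal(n_introns, 20L)
  expect_true(all(ann$repeats$class %in% c("SINE", "LINE", "LTR")))

  # TSS-distance constraint honoured by every emitted peak
  ann2 <- simulate_annotations(genome_length = 1e6, n_genes = 10,
                               gene_length = c(3000, 10000),
                               n_tf_peaks = 15, min_tss_distance = 5000,
                               seed = 4)
  dmin <- vapply(ann2$tf_peaks$summit, function(p) {
    min(abs(p - ann2$genes$tss))
  }, numeric(1))
  expect_true(all(dmin >= 5000))

  # determinism
  again <- simulate_annotations(genome_length = 1e6, n_genes = 10,
                                exons_per_gene = 3,
                                gene_length = c(3000, 10000), seed = 3)
  expect_identical(ann$genes$tx_start, again$genes$tx_start)
  expect_identical(ann$repeats, again$repeats)

  expect_error(simulate_annotations(genome_length = 1e4, n_genes = 10,
                                    gene_length = c(3000, 10000)),
               "exceed genome length")
})
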