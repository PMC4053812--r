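test_that("class normalization maps both classes onto the rank-mean reference", {
  # 3-element oracle: blind {1,2,3} and regular {10,20,30} both map onto
  # the mean of sorted vectors {5.5, 11, 16.5}
  tr <- fragment_track(
    data.frame(chrom = "chr1", pos = c(10, 20, 30, 40, 50, 60),
               class = c("blind", "blind", "blind",
                         "regular", "regular", "regular"),
               count = c(1, 2, 3, 10, 20, 30)),
    viewpoint = list(chrom = "chr1", pos = 30, name = "vp"))
  norm <- normalize_classes(tr)$fragments$norm_count
  expect_equal(norm, c(5.5, 11, 16.5, 5.5, 11, 16.5))

  # equal-size tie-free case matches the independent sorted-mean oracle
  # and limma's quantile normalization
  set.seed(73)
  x <- rgamma(40, 3); y <- rgamma(40, 8)
  tr2 <- fragment_track(
    data.frame(chrom = "chr1", pos = seq_len(80) * 10,
               class = rep(c("blind", "regular"), each = 40),
               count = c(x, y)),
    viewpoint = list(chrom = "chr1", pos = 400, name = "vp"))
  n2 <- normalize_classes(tr2)$fragments$norm_count
  oracle <- oracle_qnorm_equal(x, y)
  expect_equal(n2[1:40], oracle$x, tolerance = 1e-12)
  expect_equal(n2[41:80], oracle$y, tolerance = 1e-12)
  if (requireNamespace("limma", quietly = TRUE)) {
    lim <- limma::normalizeQuantiles(cbind(x, y))
    expect_equal(n2[1:40], lim[, 1], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }

  # KS distance between normalized class distributions: 0 for equal
  # tie-free classes, <= 1/min(n) for unequal sizes
  ks <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(g) - ecdf(b)(g)))
  }
  expect_equal(ks(n2[1:40], n2[41:80]), 0)
  x3 <- rgamma(25, 3); y3 <- rgamma(70, 9)
  tr3 <- fragment_track(
    data.frame(chrom = "chr1", pos = seq_len(95) * 10,
               class = rep(c("blind", "regular"), c(25, 70)),
               count = c(x3, y3)),
    viewpoint = list(chrom = "chr1", pos = 400, name = "vp"))
  n3 <- normalize_classes(tr3)$fragments$norm_count
  expect_lte(ks(n3[1:25], n3[26:95]), 1 / 25)

  # tied raw counts within a class receive equal normalized values
  xt <- c(2, 2, 2, 5, 7); yt <- c(1, 3, 3, 6, 9)
  trt <- fragment_track(
    data.frame(chrom = "chr1", pos = seq_len(10) * 10,
               class = rep(c("blind", "regular"), each = 5),
               count = c(xt, yt)),
    viewpoint = list(chrom = "chr1", pos = 10, name = "vp"))
  nt <- normalize_classes(trt)$fragments$norm_count
  expect_equal(length(unique(nt[1:3])), 1L)
  expect_equal(length(unique(nt[c(7, 8)])), 1L)
  # and ranking within each class is preserved
  expect_true(all(diff(order(nt[1:5])) > 0))
  expect_equal(order(nt[6:10]), order(yt))

  # one class empty: identity
  tr4 <- fragment_track(
    data.frame(chrom = "chr1", pos = c(10, 20), class = "regular",
               count = c(4, 7)),
    viewpoint = list(chrom = "chr1", pos = 10, name = "vp"))
  expect_equal(normalize_classes(tr4)$fragments$norm_count, c(4, 7))
})

test_that("window test handles boundaries, ties and exact enumeration", {
  # all values equal: all-ties convention p = 1
  expect_equal(window_test(rep(5, 30), 11, 5)$p, 1)

  # w = 2, window strictly above all four flank values: p = 1/C(6,2)
  v <- c(1, 2, 10, 11, 3, 4)
  r <- window_test(v, 3, 2)
  expect_equal(r$p, 1 / 15)

  # left flank incomplete -> untestable, not an error
  expect_false(window_test(v, 2, 2)$testable)
  expect_true(is.na(window_test(v, 2, 2)$p))
  expect_false(window_test(v, 4, 2)$testable)

  # exact enumeration oracle over no-tie cases with 3w <= 12
  set.seed(79)
  for (w in c(2, 3, 4)) {
    vals <- sample(1000, 3 * w)
    p <- window_test(vals, w + 1, w)$p
    x <- vals[(w + 1):(2 * w)]
    y <- vals[c(1:w, (2 * w + 1):(3 * w))]
    expect_equal(p, oracle_ranksum_p(x, y, "greater"), tolerance = 1e-12)
  }
})

test_that("domainograms localise planted peaks and respect symmetry", {
  sim <- simulate_4c_track(300, background_scale = 5,
                           peaks = list(list(position = 100, width = 20,
                                             enrichment = 10)),
                           seed = 83)
  tr <- normalize_classes(sim$track)
  d <- build_domainogram(tr, window_sizes = c(5, 10, 20))
  tt <- sim$peak_truth
  for (r in 1:3) {
    w <- d$window_sizes[r]
    best <- which.max(d$neglog10p[r, ])
    # the window achieving the matrix maximum overlaps the planted peak
    expect_lte(best, tt$last)
    expect_gte(best + w - 1, tt$first)
  }

  # constant track: all testable entries are exactly 0
  trc <- fragment_track(
    data.frame(chrom = "chr1", pos = seq_len(60) * 10, class = "regular",
               count = rep(4, 60)),
    viewpoint = list(chrom = "chr1", pos = 300, name = "vp"))
  trc <- normalize_classes(trc)
  dc <- build_domainogram(trc, window_sizes = c(5))
  expect_true(all(dc$neglog10p[1, !is.na(dc$neglog10p[1, ])] == 0))

  # reversing the track reverses each row (up to boundary cells)
  vals <- rpois(90, 5) + seq(0.01, 0.9, length.out = 90)
  mk <- function(v) {
    t <- fragment_track(
      data.frame(chrom = "chr1", pos = seq_along(v) * 10, class = "regular",
                 count = v),
      viewpoint = list(chrom = "chr1", pos = 10, name = "vp"))
    normalize_classes(t)
  }
  d1 <- build_domainogram(mk(vals), window_sizes = 5)$neglog10p[1, ]
  d2 <- build_domainogram(mk(rev(vals)), window_sizes = 5)$neglog10p[1, ]
  # cell starting at i in the reversed track covers the same fragments as
  # the cell ending at n - i + 1 forward
  n <- 90; w <- 5
  for (i in c(10, 37, 60)) {
    expect_equal(d2[n - i - w + 2], d1[i], tolerance = 1e-9)
  }

  expect_error(build_domainogram(mk(rpois(5, 5)), window_sizes = 2),
               "shorter")
  raw <- fragment_track(
    data.frame(chrom = "chr1", pos = 1:60 * 10, class = "regular",
               count = rpois(60, 4)),
    viewpoint = list(chrom = "chr1", pos = 1, name = "vp"))
  expect_error(build_domainogram(raw, window_sizes = 5), "not normalized")
})

test_that("interaction calling merges cells and separates distant peaks", {
  sim <- simulate_4c_track(400, background_scale = 5,
                           peaks = list(list(position = 100, width = 20,
                                             enrichment = 10)),
                           seed = 89)
  tr <- normalize_classes(sim$track)
  d <- build_domainogram(tr, window_sizes = c(2, 5, 10, 20))
  calls <- call_interactions(d, p_threshold = 1e-3)
  tt <- sim$peak_truth
  hit <- overlap_bp(tt$start, tt$end, calls$start, calls$end) > 0
  expect_equal(sum(hit), 1L)  # exactly one merged call overlaps truth

  sim2 <- simulate_4c_track(500, background_scale = 5,
                            peaks = list(list(position = 100, width = 15,
                                              enrichment = 10),
                                         list(position = 400, width = 15,
                                              enrichment = 10)),
                            seed = 97)
  tr2 <- normalize_classes(sim2$track)
  d2 <- build_domainogram(tr2, window_sizes = c(2, 5, 10, 20))
  calls2 <- call_interactions(d2, p_threshold = 1e-3)
  t2 <- sim2$peak_truth
  expect_gte(nrow(calls2), 2L)
  expect_true(any(overlap_bp(t2$start[1], t2$end[1], calls2$start,
                             calls2$end) > 0))
  expect_true(any(overlap_bp(t2$start[2], t2$end[2], calls2$start,
                             calls2$end) > 0))

  empty <- call_interactions(d, p_threshold = 1e-300)
  expect_equal(nrow(empty), 0L)
})

test_that("viewpoint linking enforces the 750 kb and 5 kb rules exactly", {
  vp <- list(chrom = "chr1", pos = 1000000, name = "vp")
  genes <- gene_table(data.frame(
    gene_id = c("near", "far"), chrom = "chr1", strand = "+",
    tx_start = c(1254999, 1500000), tx_end = c(1300000, 1600000),
    exon_starts = I(list(1254999, 1500000)),
    exon_ends = I(list(1300000, 1600000))))
  # calls at 749,900 bp (kept) and 750,100 bp (dropped) from the viewpoint
  calls <- data.frame(chrom = "chr1",
                      start = c(1749900, 1750100, 1250000),
                      end = c(1749950, 1750150, 1250050),
                      best_p = 1e-5, window_sizes = "5", n_cells = 3)
  linked <- link_viewpoint(calls, vp, genes)
  expect_equal(nrow(linked), 2L)
  expect_true(all(linked$vp_distance <= 750000))

  # TSS-distance boundary: 4,999 bp links, 5,001 bp does not
  # call [1250000, 1250050): distance to TSS 1254999 is 4949
  near_call <- linked[linked$start == 1250000, ]
  expect_equal(near_call$linked_gene, "near")
  calls2 <- data.frame(chrom = "chr1",
                       start = c(1249948, 1249948 - 2),
                       end = c(1250000, 1249998),
                       best_p = 1e-5, window_sizes = "5", n_cells = 1)
  # distances: 1254999 - 1250000 = 4999 (kept); 1254999 - 1249998 = 5001
  l2 <- link_viewpoint(calls2, vp, genes)
  expect_equal(l2$tss_distance[1], 4999)
  expect_equal(l2$linked_gene[1], "near")
  expect_true(is.na(l2$linked_gene[2]))
  # distance exactly 5000 links ("within 5 kb")
  calls3 <- data.frame(chrom = "chr1", start = 1249947, end = 1249999,
                       best_p = 1e-5, window_sizes = "5", n_cells = 1)
  expect_equal(link_viewpoint(calls3, vp, genes)$tss_distance, 5000)
  expect_equal(link_viewpoint(calls3, vp, genes)$linked_gene, "near")

  # expression annotation travels with the link
  de <- data.frame(gene_id = c("near", "far"), log2fc = c(2.5, 0),
                   p.value = c(0.001, 0.9))
  l3 <- link_viewpoint(calls2[1, ], vp, genes, de_table = de)
  expect_equal(l3$log2fc, 2.5)

  # no calls -> empty output
  none <- call_interactions(
    structure(list(neglog10p = matrix(0, 1, 10), window_sizes = 2,
                   pos = 1:10, chrom = "chr1", viewpoint = vp),
              class = "domainogram"))
  expect_equal(nrow(link_viewpoint(none, vp, genes)), 0L)
})

test_that("fragment-track TSV round-trips through the header format", {
  sim <- simulate_4c_track(50, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_track(sim$track, path)
  back <- read_fragment_track(path)
  expect_equal(back$viewpoint, sim$track$viewpoint)
  expect_equal(back$fragments$count, sim$track$fragments$count)
  expect_equal(back$fragments$class, sim$track$fragments$class)
})
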