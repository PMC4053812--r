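# Genomic-element methylation dynamics and the rank-sum test shared with
# the 4C window statistic.

#' Wilcoxon/Mann-Whitney rank-sum test
#'
#' Two-sample rank-sum test with the branch structure the pipeline relies
#' on: an exact p-value (null distribution of the Mann-Whitney U statistic)
#' when the pooled sample has at most 12 observations and no ties, and a
#' normal approximation with midranks, tie correction and continuity
#' correction otherwise. If every pooled value is identical the p-value is
#' 1 by convention.
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return list with `statistic` (U, number of (x, y) pairs with x > y,
#'   ties counted 1/2) and `p.value`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1L)
  if (!has_ties && nx + ny <= 12L) {
    p <- switch(alternative,
      greater = stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE),
      less = stats::pwilcox(u, nx, ny),
      two.sided = {
        if (u > nx * ny / 2) {
          min(1, 2 * stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE))
        } else {
          min(1, 2 * stats::pwilcox(u, nx, ny))
        }
      })
    return(list(statistic = u, p.value = p))
  }
  n <- nx + ny
  tie_term <- sum(ties^3 - ties)
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    # all pooled values identical: no evidence either way
    return(list(statistic = u, p.value = 1))
  }
  mu <- nx * ny / 2
  sd_u <- sqrt(sigma2)
  p <- switch(alternative,
    greater = stats::pnorm((u - mu - 0.5) / sd_u, lower.tail = FALSE),
    less = stats::pnorm((u - mu + 0.5) / sd_u),
    two.sided = {
      z <- u - mu
      min(1, 2 * stats::pnorm((abs(z) - 0.5) / sd_u, lower.tail = FALSE))
    })
  list(statistic = u, p.value = min(max(p, 0), 1))
}

#' Build a genomic-element set from gene and repeat annotation
#'
#' Derives the element classes used in per-element methylation dynamics:
#' TSS windows (`tss +/- tss_flank`), exons, introns (gaps between exons),
#' 5'/3' UTRs when the gene table carries a CDS, and repeat classes
#' (SINE/LINE/LTR) passed through. An address may appear under several
#' classes; each interval carries exactly one class label.
#'
#' @param genes a [gene_table].
#' @param repeats optional BED-like data.frame (`chrom`, `start`, `end`,
#'   `class`).
#' @param tss_flank half-width of the TSS window (default 1000).
#' @return data.frame: `chrom`, `start`, `end`, `class`, `gene_id` (NA for
#'   repeats).
#' @export
build_elements <- function(genes, repeats = NULL, tss_flank = 1000) {
  stopifnot(inherits(genes, "gene_table"))
  out <- list()
  has_cds <- all(c("cds_start", "cds_end") %in% names(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    id <- g$gene_id
    ch <- g$chrom
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = max(0L, g$tss - tss_flank),
      end = g$tss + tss_flank, class = "TSS", gene_id = id)
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = es, end = ee, class = "exon", gene_id = id)
    if (length(es) > 1L) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = ee[-length(ee)], end = es[-1L],
        class = "intron", gene_id = id)
    }
    if (has_cds && !is.na(g$cds_start) && g$cds_start >= 0) {
      left <- c(g$tx_start, g$cds_start)   # upstream-of-CDS transcript part
      right <- c(g$cds_end, g$tx_end)
      utr5 <- if (g$strand == "+") left else right
      utr3 <- if (g$strand == "+") right else left
      if (utr5[1L] < utr5[2L]) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = utr5[1L], end = utr5[2L],
          class = "5'UTR", gene_id = id)
      }
      if (utr3[1L] < utr3[2L]) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = utr3[1L], end = utr3[2L],
          class = "3'UTR", gene_id = id)
      }
    }
  }
  if (!is.null(repeats) && nrow(repeats) > 0L) {
    out[[length(out) + 1L]] <- data.frame(
      chrom = repeats$chrom, start = repeats$start, end = repeats$end,
      class = repeats$class, gene_id = NA_character_)
  }
  el <- do.call(rbind, out)
  rownames(el) <- NULL
  el
}

#' Per-element methylation change between two methylomes
#'
#' For every element, the change is `100 * (level_b - level_a)` in
#' percentage points, using weighted (count-based) levels. The per-class
#' summary is the unweighted mean over elements with data in both
#' methylomes (each element gets one vote). Swapping `a` and `b` negates
#' every value.
#'
#' @param a,b [methylome]s on the same manifest.
#' @param elements element set from [build_elements()].
#' @return list with `per_element` (elements plus `level_a`, `level_b`,
#'   `change_pct`) and `per_class` (`class`, `n`, `mean_change_pct`;
#'   `NA` for classes with no covered element).
#' @export
element_change <- function(a, b, elements) {
  if (!same_manifest(a, b)) {
    stop("methylomes are on different genome manifests", call. = FALSE)
  }
  lev <- function(m, i) {
    as.numeric(weighted_methylation(m, elements$chrom[i],
                                    elements$start[i], elements$end[i]))
  }
  n <- nrow(elements)
  level_a <- vapply(seq_len(n), function(i) lev(a, i), numeric(1))
  level_b <- vapply(seq_len(n), function(i) lev(b, i), numeric(1))
  per_element <- cbind(elements,
                       data.frame(level_a = level_a, level_b = level_b,
                                  change_pct = 100 * (level_b - level_a)))
  classes <- unique(elements$class)
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    v <- per_element$change_pct[per_element$class == cl]
    v <- v[!is.na(v)]
    data.frame(class = cl, n = length(v),
               mean_change_pct = if (length(v)) mean(v) else NA_real_)
  }))
  list(per_element = per_element, per_class = per_class)
}

#' Compare expressed versus silent elements
#'
#' Two-sided rank-sum test of a per-element quantity (e.g. methylation
#' change) between elements of expressed and silent host genes, per
#' element class.
#'
#' @param per_element data.frame with `class` and a value column.
#' @param expressed logical vector, one entry per row of `per_element`.
#' @param value name of the value column (default `"change_pct"`).
#' @return data.frame: `class`, `n_expressed`, `n_silent`, `statistic`,
#'   `p.value` (`NA` = "no data" when either group is empty).
#' @export
expressed_vs_silent <- function(per_element, expressed,
                                value = "change_pct") {
  stopifnot(nrow(per_element) == length(expressed))
  v <- per_element[[value]]
  keep <- !is.na(v)
  classes <- unique(per_element$class)
  do.call(rbind, lapply(classes, function(cl) {
    sel <- keep & per_element$class == cl
    x <- v[sel & expressed]
    y <- v[sel & !expressed]
    if (length(x) == 0L || length(y) == 0L) {
      return(data.frame(class = cl, n_expressed = length(x),
                        n_silent = length(y), statistic = NA_real_,
                        p.value = NA_real_))
    }
    r <- rank_sum_test(x, y, "two.sided")
    data.frame(class = cl, n_expressed = length(x), n_silent = length(y),
               statistic = r$statistic, p.value = r$p.value)
  }))
}
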