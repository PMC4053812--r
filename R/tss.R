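# TSS-window methylation, differential-expression calls, and the
# DMR-expression permutation enrichment test.

#' TSS-window methylation table
#'
#' For every gene, summarises the methylome over the window
#' `[tss - flank, tss + flank)`: weighted methylation level and the number
#' of CpG data-points (total read observations over window CpGs, i.e.
#' summed coverage, by default; set `datapoint_mode = "cpgs"` to count
#' distinct covered CpGs instead). Genes below `min_datapoints` are
#' flagged, not dropped.
#'
#' @param m a [methylome].
#' @param genes a [gene_table].
#' @param flank window half-width in bp (default 1000).
#' @param min_datapoints coverage filter; a gene passes when
#'   `n_datapoints >= min_datapoints` (boundary inclusive). Cross-methylome
#'   comparisons require the pass flag in every compared methylome.
#' @param datapoint_mode `"coverage"` (sum of read counts) or `"cpgs"`
#'   (distinct covered CpGs).
#' @return data.frame: `gene_id`, `level` (NA = no data), `n_datapoints`,
#'   `pass`.
#' @export
tss_methylation <- function(m, genes, flank = 1000, min_datapoints = 80,
                            datapoint_mode = c("coverage", "cpgs")) {
  stopifnot(inherits(genes, "gene_table"), nrow(genes) > 0L)
  datapoint_mode <- match.arg(datapoint_mode)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    s <- sites_in_region(m, genes$chrom[i],
                         max(0L, genes$tss[i] - flank),
                         genes$tss[i] + flank)
    tot <- sum(s$total)
    ndp <- if (datapoint_mode == "coverage") tot else sum(s$total > 0L)
    data.frame(gene_id = genes$gene_id[i],
               level = if (tot > 0) sum(s$meth) / tot else NA_real_,
               n_datapoints = ndp,
               pass = ndp >= min_datapoints)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Differentially methylated TSSs between two methylomes
#'
#' Among genes passing the data-point filter in both methylomes, selects
#' those with an absolute TSS methylation difference strictly greater
#' than `min_diff` (a difference of exactly `min_diff` is excluded).
#'
#' @param table_a,table_b [tss_methylation()] tables sharing a gene
#'   universe.
#' @param min_diff difference threshold (default 0.50).
#' @return data.frame: `gene_id`, `level_a`, `level_b`, `diff`
#'   (`level_a - level_b`), `direction` (`"higher_in_a"`/`"higher_in_b"`).
#' @export
differential_tss <- function(table_a, table_b, min_diff = 0.50) {
  common <- intersect(table_a$gene_id, table_b$gene_id)
  if (length(common) == 0L) {
    stop("tables share no genes", call. = FALSE)
  }
  ia <- match(common, table_a$gene_id)
  ib <- match(common, table_b$gene_id)
  ok <- table_a$pass[ia] & table_b$pass[ib] &
    !is.na(table_a$level[ia]) & !is.na(table_b$level[ib])
  diff <- table_a$level[ia] - table_b$level[ib]
  sel <- ok & abs(diff) > min_diff
  out <- data.frame(gene_id = common[sel],
                    level_a = table_a$level[ia][sel],
                    level_b = table_b$level[ib][sel],
                    diff = diff[sel])
  out$direction <- ifelse(out$diff > 0, "higher_in_a", "higher_in_b")
  rownames(out) <- NULL
  out
}

#' Differential-expression calls on a replicate expression matrix
#'
#' Per-gene log2 fold change (`mean(groupB) - mean(groupA)`, values on
#' log2 scale) and equal-variance two-sample Student t-test. The DE flag
#' follows the chosen mode: `"fold"` flags `|log2FC| >= fold_log2`
#' (two-fold by default), `"ttest"` flags `p < alpha`, `"both"` requires
#' both. When both groups have zero variance and identical means the
#' p-value is 1 by convention (0 if the means differ).
#'
#' @param expr gene x sample numeric matrix (log2 scale, rownames =
#'   gene ids).
#' @param groups factor/character of length `ncol(expr)`.
#' @param group_a,group_b group labels to compare.
#' @param fold_log2 absolute log2 fold-change threshold (default 1).
#' @param alpha t-test significance level (default 0.01).
#' @param mode `"fold"`, `"ttest"` or `"both"`.
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, mirroring per-gene use of raw p-values).
#' @return data.frame: `gene_id`, `mean_a`, `mean_b`, `log2fc`,
#'   `p.value`, `de`.
#' @export
de_genes <- function(expr, groups, group_a = "A", group_b = "B",
                     fold_log2 = 1, alpha = 0.01,
                     mode = c("fold", "ttest", "both"), adjust = "none") {
  mode <- match.arg(mode)
  stopifnot(is.matrix(expr), ncol(expr) == length(groups))
  a <- expr[, groups == group_a, drop = FALSE]
  b <- expr[, groups == group_b, drop = FALSE]
  if (mode != "fold" && (ncol(a) < 2L || ncol(b) < 2L)) {
    stop("need >= 2 replicates per group for the t-test", call. = FALSE)
  }
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  log2fc <- mean_b - mean_a
  if (ncol(a) >= 2L && ncol(b) >= 2L) {
    p <- vapply(seq_len(nrow(expr)), function(i) {
      xa <- a[i, ]; xb <- b[i, ]
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        return(if (mean(xa) == mean(xb)) 1 else 0)
      }
      stats::t.test(xb, xa, var.equal = TRUE)$p.value
    }, numeric(1))
    p <- stats::p.adjust(p, method = adjust)
  } else {
    p <- rep(NA_real_, nrow(expr))
  }
  de <- switch(mode,
    fold = abs(log2fc) >= fold_log2,
    ttest = p < alpha,
    both = abs(log2fc) >= fold_log2 & p < alpha)
  data.frame(gene_id = rownames(expr) %||% as.character(seq_len(nrow(expr))),
             mean_a = mean_a, mean_b = mean_b, log2fc = log2fc,
             p.value = p, de = de, row.names = NULL)
}

#' Permutation test for DMR-gene enrichment in differential expression
#'
#' Compares the number of differentially expressed genes among
#' DMR-associated genes against the null of `n_perm` uniformly drawn gene
#' sets of the same size. The empirical p-value uses the add-one
#' correction `p = (1 + #(perm >= observed)) / (n_perm + 1)` and is never
#' zero.
#'
#' @param dmr_genes character vector of DMR-associated gene ids (subset of
#'   the universe; must be non-empty).
#' @param de_flags named logical vector over the gene universe.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `observed` (DE count among `dmr_genes`), `n` (set
#'   size), `p.value`, `null_mean`.
#' @export
dmr_expression_enrichment <- function(dmr_genes, de_flags, n_perm = 10000,
                                      seed = NULL) {
  if (length(dmr_genes) == 0L) {
    stop("dmr_genes is empty", call. = FALSE)
  }
  if (is.null(names(de_flags))) {
    stop("de_flags must be named by gene id", call. = FALSE)
  }
  if (!all(dmr_genes %in% names(de_flags))) {
    stop("dmr_genes must be a subset of the gene universe", call. = FALSE)
  }
  k <- length(dmr_genes)
  observed <- sum(de_flags[dmr_genes])
  with_seed(seed, {
    null_counts <- vapply(seq_len(n_perm), function(j) {
      sum(de_flags[sample.int(length(de_flags), k)])
    }, numeric(1))
    list(observed = observed, n = k,
         p.value = (1 + sum(null_counts >= observed)) / (n_perm + 1),
         null_mean = mean(null_counts))
  })
}
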