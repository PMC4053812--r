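#' Construct a gene table
#'
#' Per-gene annotation used for TSS windows, genomic-element construction
#' and interaction linking: transcript interval, strand, exon structure and
#' (optionally) a CDS from which UTRs can be derived. All coordinates are
#' 0-based half-open. The TSS is the transcript start on the plus strand
#' and the last transcript base (`tx_end - 1`) on the minus strand.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tx_start`, `tx_end`, list columns `exon_starts`,
#'   `exon_ends`, and optional `cds_start`, `cds_end`.
#' @return A `gene_table` (data.frame subclass with a computed `tss`
#'   column).
#' @export
gene_table <- function(genes) {
  req <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
           "exon_starts", "exon_ends")
  if (!is.data.frame(genes) || !all(req %in% names(genes))) {
    stop("gene table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  genes <- as.data.frame(genes)
  stopifnot(all(genes$strand %in% c("+", "-")),
            all(genes$tx_start < genes$tx_end))
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) != length(ee) || any(es >= ee)) {
      stop(sprintf("gene %s: malformed exons", genes$gene_id[i]), call. = FALSE)
    }
    o <- order(es)
    es <- es[o]; ee <- ee[o]
    if (any(es[-1L] < ee[-length(ee)])) {
      stop(sprintf("gene %s: overlapping exons", genes$gene_id[i]),
           call. = FALSE)
    }
    if (es[1L] < genes$tx_start[i] || ee[length(ee)] > genes$tx_end[i]) {
      stop(sprintf("gene %s: exon outside transcript", genes$gene_id[i]),
           call. = FALSE)
    }
    genes$exon_starts[[i]] <- es
    genes$exon_ends[[i]] <- ee
  }
  genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
  class(genes) <- c("gene_table", "data.frame")
  genes
}

#' Write / read a gene table as refFlat-like TSV
#'
#' Columns: gene_id, chrom, strand, tx_start, tx_end, cds_start, cds_end,
#' exon_count, comma-separated exon_starts, comma-separated exon_ends.
#' `read_gene_table(write_gene_table(x, p))` is the identity.
#'
#' @param genes a [gene_table].
#' @param path file path.
#' @return `write_gene_table` returns `path` invisibly; `read_gene_table`
#'   a [gene_table].
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tx_start = genes$tx_start, tx_end = genes$tx_end,
    cds_start = if ("cds_start" %in% names(genes)) genes$cds_start else -1L,
    cds_end = if ("cds_end" %in% names(genes)) genes$cds_end else -1L,
    exon_count = vapply(genes$exon_starts, length, integer(1)),
    exon_starts = vapply(genes$exon_starts,
                         function(x) paste(x, collapse = ","), character(1)),
    exon_ends = vapply(genes$exon_ends,
                       function(x) paste(x, collapse = ","), character(1))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  cols <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "exon_count", "exon_starts", "exon_ends")
  dat <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = cols,
                           colClasses = c("character", "character",
                                          "character", "integer", "integer",
                                          "integer", "integer", "integer",
                                          "character", "character"))
  dat$exon_starts <- lapply(strsplit(dat$exon_starts, ","), as.integer)
  dat$exon_ends <- lapply(strsplit(dat$exon_ends, ","), as.integer)
  dat$exon_count <- NULL
  if (all(dat$cds_start < 0L)) {
    dat$cds_start <- NULL
    dat$cds_end <- NULL
  }
  gene_table(dat)
}
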