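# Genomic-context annotation of DMRs, proximity to TF peaks, and
# methylation metaprofiles around TF binding sites.

#' Annotate DMRs with genomic context
#'
#' Labels every DMR with context categories: `TSS` if within `tss_dist` bp
#' of any annotated TSS, `exon`/`intron` by overlap with the gene's exon
#' structure, and `intergenic` if farther than `gene_dist` bp from every
#' gene interval. A DMR overlapping several categories is counted in each
#' of them; `TSS` and `intergenic` are mutually exclusive by construction.
#' A DMR near a gene body that overlaps no genic feature and no TSS window
#' would otherwise be unlabelled and falls back to `intergenic`, so every
#' DMR carries at least one label. Distances are edge-to-edge.
#'
#' @param dmrs data.frame from [call_dmrs()].
#' @param genes a [gene_table].
#' @param tss_dist TSS proximity threshold in bp (default 2000).
#' @param gene_dist gene proximity threshold for the intergenic label
#'   (default 2000).
#' @return list with `context` (per DMR: labels, nearest gene, distance to
#'   nearest TSS, one row per DMR) and `counts` (label x direction counts;
#'   multi-label DMRs counted in every label).
#' @export
annotate_dmrs <- function(dmrs, genes, tss_dist = 2000, gene_dist = 2000) {
  stopifnot(inherits(genes, "gene_table"))
  n <- nrow(dmrs)
  labels <- vector("list", n)
  nearest_gene <- character(n)
  tss_distance <- numeric(n)
  for (i in seq_len(n)) {
    same <- genes$chrom == dmrs$chrom[i]
    lab <- character(0)
    if (any(same)) {
      g <- genes[same, , drop = FALSE]
      d_tss <- iv_point_gap(dmrs$start[i], dmrs$end[i], g$tss)
      d_gene <- iv_gap(dmrs$start[i], dmrs$end[i], g$tx_start, g$tx_end)
      tss_distance[i] <- min(d_tss)
      nearest_gene[i] <- g$gene_id[which.min(d_gene)]
      if (min(d_tss) <= tss_dist) lab <- c(lab, "TSS")
      for (j in which(d_gene == 0)) {
        es <- g$exon_starts[[j]]; ee <- g$exon_ends[[j]]
        if (any(iv_gap(dmrs$start[i], dmrs$end[i], es, ee) == 0 &
                  pmin(dmrs$end[i], ee) > pmax(dmrs$start[i], es))) {
          lab <- c(lab, "exon")
        }
        if (length(es) > 1L) {
          is_ <- ee[-length(ee)]; ie <- es[-1L]
          if (any(pmin(dmrs$end[i], ie) > pmax(dmrs$start[i], is_))) {
            lab <- c(lab, "intron")
          }
        }
      }
      if (min(d_gene) > gene_dist) lab <- c(lab, "intergenic")
    } else {
      nearest_gene[i] <- NA_character_
      tss_distance[i] <- Inf
      lab <- "intergenic"
    }
    lab <- unique(lab)
    if (length(lab) == 0L) lab <- "intergenic"  # fallback: never unlabelled
    labels[[i]] <- lab
  }
  context <- data.frame(chrom = dmrs$chrom, start = dmrs$start,
                        end = dmrs$end, direction = dmrs$direction,
                        labels = vapply(labels, paste, character(1),
                                        collapse = ","),
                        nearest_gene = nearest_gene,
                        tss_distance = tss_distance)
  all_labels <- c("TSS", "exon", "intron", "intergenic")
  counts <- do.call(rbind, lapply(all_labels, function(l) {
    has <- vapply(labels, function(x) l %in% x, logical(1))
    data.frame(label = l,
               loss = sum(has & dmrs$direction == "loss"),
               gain = sum(has & dmrs$direction == "gain"))
  }))
  list(context = context, counts = counts)
}

#' TF peaks near DMRs
#'
#' All (DMR, peak) pairs whose edge-to-edge distance is at most
#' `max_dist` bp (0 for overlap). The relation is symmetric in the pair.
#'
#' @param dmrs data.frame with `chrom`, `start`, `end`.
#' @param peaks data.frame with `chrom`, `start`, `end` and optional
#'   `name`.
#' @param max_dist distance threshold in bp (default 1000).
#' @return data.frame: `dmr_idx`, `peak_idx`, `peak_name`, `distance`.
#' @export
peaks_near_dmrs <- function(dmrs, peaks, max_dist = 1000) {
  empty <- data.frame(dmr_idx = integer(), peak_idx = integer(),
                      peak_name = character(), distance = numeric())
  if (nrow(dmrs) == 0L || is.null(peaks) || nrow(peaks) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(dmrs))) {
    same <- which(peaks$chrom == dmrs$chrom[i])
    if (!length(same)) next
    d <- iv_gap(dmrs$start[i], dmrs$end[i],
                peaks$start[same], peaks$end[same])
    hit <- which(d <= max_dist)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        dmr_idx = i, peak_idx = same[hit],
        peak_name = if ("name" %in% names(peaks))
          peaks$name[same[hit]] else NA_character_,
        distance = d[hit])
    }
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Methylation metaprofile around TF binding sites
#'
#' Average methylation as a function of distance from TF peak summits,
#' restricted to peaks at least `min_tss_dist` bp from every TSS (peaks
#' closer than that are excluded; a peak at exactly `min_tss_dist` is
#' kept). Windows of `+/- flank` bp around each surviving summit are
#' binned at `bin_bp` resolution; by default the per-bin value pools read
#' counts across peaks (weighted methylation), `pooling = "mean"` averages
#' per-peak levels instead. The profile is invariant to peak order and
#' strand.
#'
#' @param m a [methylome].
#' @param peaks data.frame with `chrom`, `start`, `end` and `summit`
#'   (defaults to the interval midpoint when absent).
#' @param genes a [gene_table] supplying TSS positions.
#' @param min_tss_dist TSS exclusion radius in bp (default 5000).
#' @param flank profile half-width in bp (default 2000).
#' @param bin_bp bin width in bp (default 50).
#' @param pooling `"counts"` (pooled reads) or `"mean"` (mean of per-peak
#'   levels).
#' @return data.frame with `offset` (bin midpoint relative to summit) and
#'   `level`, with attribute `n_peaks`; a zero-row frame (n_peaks 0)
#'   signals "no data" when no peak survives the TSS filter.
#' @export
tf_metaprofile <- function(m, peaks, genes, min_tss_dist = 5000,
                           flank = 2000, bin_bp = 50,
                           pooling = c("counts", "mean")) {
  pooling <- match.arg(pooling)
  stopifnot(flank > 0, bin_bp > 0, flank %% bin_bp == 0)
  if (!"summit" %in% names(peaks)) {
    peaks$summit <- as.integer((peaks$start + peaks$end) %/% 2L)
  }
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    same <- genes$chrom == peaks$chrom[i]
    if (!any(same)) return(TRUE)
    min(iv_point_gap(peaks$start[i], peaks$end[i],
                     genes$tss[same])) >= min_tss_dist
  }, logical(1))
  peaks <- peaks[keep, , drop = FALSE]
  n_bins <- as.integer(2L * flank / bin_bp)
  breaks <- seq(-flank, flank, by = bin_bp)
  empty <- data.frame(offset = numeric(0), level = numeric(0))
  attr(empty, "n_peaks") <- 0L
  if (nrow(peaks) == 0L) return(empty)
  meth <- matrix(0, nrow(peaks), n_bins)
  total <- matrix(0, nrow(peaks), n_bins)
  for (i in seq_len(nrow(peaks))) {
    s <- sites_in_region(m, peaks$chrom[i],
                         peaks$summit[i] - flank, peaks$summit[i] + flank)
    if (nrow(s) == 0L) next
    off <- s$pos - peaks$summit[i]
    bin <- pmin(findInterval(off, breaks, rightmost.closed = TRUE), n_bins)
    for (b in unique(bin)) {
      sel <- bin == b
      meth[i, b] <- sum(s$meth[sel])
      total[i, b] <- sum(s$total[sel])
    }
  }
  level <- if (pooling == "counts") {
    tm <- colSums(meth); tt <- colSums(total)
    ifelse(tt > 0, tm / tt, NA_real_)
  } else {
    vapply(seq_len(n_bins), function(b) {
      lv <- ifelse(total[, b] > 0, meth[, b] / total[, b], NA_real_)
      if (all(is.na(lv))) NA_real_ else mean(lv, na.rm = TRUE)
    }, numeric(1))
  }
  out <- data.frame(offset = (breaks[-length(breaks)] + breaks[-1L]) / 2,
                    level = level)
  attr(out, "n_peaks") <- nrow(peaks)
  out
}
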