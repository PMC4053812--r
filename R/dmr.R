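# DMR calling between two methylomes: candidate regions are the symmetric
# difference of the two HMR interval sets (hypo in exactly one methylome),
# filtered on CpG count and weighted methylation difference.

# Symmetric difference of two interval data.frames (chrom/start/end,
# 0-based half-open), per chromosome, via IRanges set algebra. Fragments
# separated by at most merge_gap bp are fused: a differential region
# interrupted by a short ambiguous stretch is one candidate, not several.
interval_symdiff <- function(a, b, merge_gap = 0) {
  chroms <- union(unique(a$chrom), unique(b$chrom))
  out <- lapply(chroms, function(ch) {
    ra <- iv_to_ir(a$start[a$chrom == ch], a$end[a$chrom == ch])
    rb <- iv_to_ir(b$start[b$chrom == ch], b$end[b$chrom == ch])
    ra <- IRanges::reduce(ra)
    rb <- IRanges::reduce(rb)
    sd <- IRanges::union(IRanges::setdiff(ra, rb), IRanges::setdiff(rb, ra))
    if (length(sd) == 0L) return(NULL)
    if (merge_gap > 0) {
      sd <- IRanges::reduce(sd, min.gapwidth = merge_gap + 1L)
    }
    cbind(chrom = ch, ir_to_iv(sd))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer())
  }
  out
}

empty_dmr_frame <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             n_cpgs = integer(), level_a = numeric(), level_b = numeric(),
             delta = numeric(), direction = character(),
             min_p = numeric(), frac_sig = numeric())
}

#' Call differentially methylated regions (DMRs)
#'
#' Candidate regions are taken as the symmetric difference of the HMR sets
#' of the two methylomes (regions hypo-methylated in exactly one
#' population). Each candidate is summarised by its weighted methylation
#' in both methylomes; per-CpG Fisher exact tests on the
#' (methylated, unmethylated) read counts across conditions are summarised
#' per candidate but not used as a filter. Emitted DMRs must contain at
#' least `min_cpgs` CpGs covered in both methylomes and show an absolute
#' weighted methylation difference of at least `min_delta` (defaults: 10
#' CpGs and a 40% difference).
#'
#' Sign convention: `delta = level_a - level_b` with `a` the earlier
#' (stem) population, so `direction == "loss"` means methylation is lost
#' upon differentiation (`delta > 0`) and `"gain"` the reverse. Calling
#' with the methylomes swapped yields the same intervals with directions
#' flipped.
#'
#' @param a,b [methylome]s on the same genome manifest (`a` = condition
#'   before differentiation).
#' @param hmrs_a,hmrs_b HMR tables from [call_hmrs()] for `a` and `b`.
#' @param min_cpgs minimum CpGs covered in both methylomes (boundary
#'   inclusive: exactly `min_cpgs` passes).
#' @param min_delta minimum `|delta|` (boundary inclusive: exactly
#'   `min_delta` passes).
#' @param merge_gap candidate fragments separated by at most this many bp
#'   are fused into one candidate before filtering (default 1000, matching
#'   the desert size within which consecutive CpGs are treated as
#'   dependent).
#' @param sig_alpha per-CpG Fisher significance level used only for the
#'   reported `frac_sig` summary.
#' @return data.frame: `chrom`, `start`, `end`, `n_cpgs`, `level_a`,
#'   `level_b`, `delta`, `direction`, `min_p`, `frac_sig`.
#' @export
call_dmrs <- function(a, b, hmrs_a, hmrs_b, min_cpgs = 10, min_delta = 0.40,
                      merge_gap = 1000, sig_alpha = 0.05) {
  if (!same_manifest(a, b)) {
    stop("methylomes are on different genome manifests", call. = FALSE)
  }
  cand <- interval_symdiff(hmrs_a, hmrs_b, merge_gap = merge_gap)
  if (nrow(cand) == 0L) return(empty_dmr_frame())
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    ch <- cand$chrom[i]; s <- cand$start[i]; e <- cand$end[i]
    sa <- sites_in_region(a, ch, s, e)
    sb <- sites_in_region(b, ch, s, e)
    shared <- intersect(sa$pos[sa$total > 0L], sb$pos[sb$total > 0L])
    n_cpgs <- length(shared)
    tot_a <- sum(sa$total); tot_b <- sum(sb$total)
    level_a <- if (tot_a > 0) sum(sa$meth) / tot_a else NA_real_
    level_b <- if (tot_b > 0) sum(sb$meth) / tot_b else NA_real_
    delta <- level_a - level_b
    if (is.na(delta) || n_cpgs < min_cpgs || abs(delta) < min_delta - 1e-9) {
      return(NULL)
    }
    ka <- sa$meth[match(shared, sa$pos)]; na <- sa$total[match(shared, sa$pos)]
    kb <- sb$meth[match(shared, sb$pos)]; nb <- sb$total[match(shared, sb$pos)]
    p <- vapply(seq_along(shared), function(j) {
      stats::fisher.test(matrix(c(ka[j], na[j] - ka[j],
                                  kb[j], nb[j] - kb[j]), 2L, 2L))$p.value
    }, numeric(1))
    data.frame(chrom = ch, start = s, end = e, n_cpgs = n_cpgs,
               level_a = level_a, level_b = level_b, delta = delta,
               direction = if (delta > 0) "loss" else "gain",
               min_p = min(p), frac_sig = mean(p < sig_alpha))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_dmr_frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise DMR directions and methylation trajectories
#'
#' Counts DMRs by direction and tabulates each DMR's weighted methylation
#' across a set of methylomes (e.g. stem, progenitor, villus), mirroring a
#' per-DMR methylation-dynamics overview.
#'
#' @param dmrs non-empty data.frame from [call_dmrs()].
#' @param methylomes named list of [methylome]s to profile across
#'   (optional).
#' @return list with `counts` (named vector, loss/gain) and `trajectory`
#'   (data.frame DMR x methylome weighted level; `NULL` if no methylomes
#'   given).
#' @export
dmr_direction_summary <- function(dmrs, methylomes = NULL) {
  if (is.null(dmrs) || nrow(dmrs) == 0L) {
    stop("no DMRs to summarise", call. = FALSE)
  }
  counts <- c(loss = sum(dmrs$direction == "loss"),
              gain = sum(dmrs$direction == "gain"))
  trajectory <- NULL
  if (!is.null(methylomes) && length(methylomes) > 0L) {
    trajectory <- dmrs[c("chrom", "start", "end", "direction")]
    for (nm in names(methylomes)) {
      trajectory[[nm]] <- vapply(seq_len(nrow(dmrs)), function(i) {
        as.numeric(weighted_methylation(methylomes[[nm]], dmrs$chrom[i],
                                        dmrs$start[i], dmrs$end[i]))
      }, numeric(1))
    }
  }
  list(counts = counts, trajectory = trajectory)
}

#' Write intervals as BED6+
#'
#' Writes HMR or DMR tables as BED with name, score (`round(1000 * |delta|)`
#' for DMRs, `round(1000 * score)` for HMRs) and the remaining columns
#' appended after the first six.
#'
#' @param x data.frame from [call_hmrs()] or [call_dmrs()].
#' @param path output path.
#' @param prefix feature-name prefix.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path, prefix = "region") {
  score <- if ("delta" %in% names(x)) round(1000 * abs(x$delta)) else
    round(1000 * (x$score %||% rep(0, nrow(x))))
  extra <- setdiff(names(x), c("chrom", "start", "end"))
  bed <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    name = sprintf("%s_%d", prefix, seq_len(nrow(x))),
                    score = score, strand = ".")
  bed <- cbind(bed, x[extra])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
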