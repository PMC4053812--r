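# Generators for the non-methylome inputs: 4C fragment tracks, replicate
# expression matrices, and genome annotation (genes, repeats, TF peaks).

#' Simulate a 4C fragment-end track with planted interaction peaks
#'
#' Fragment ends are laid out with jittered spacing around a central
#' viewpoint. Regular fragments draw geometric (heavy-tailed) counts whose
#' mean decays from the viewpoint as a power law
#' `background_scale * (1 + d / decay_scale)^(-decay_exponent)`; blind
#' fragments (flanked by two primary-cutter sites without a secondary
#' site) draw from a systematically shifted distribution (`blind_shift`
#' times the regular mean), emulating their different frequency
#' distribution. Counts inside planted peaks are scaled by the peak's
#' enrichment. Setting `decay_exponent = 0` gives a homogeneous
#' (exchangeable) background, the appropriate null for calibrating the
#' window statistic.
#'
#' @param n_fragments number of fragment ends.
#' @param blind_fraction fraction of blind fragments in `[0, 1]`.
#' @param background_scale mean background count at the viewpoint.
#' @param peaks list of `list(position, width, enrichment)`: centre
#'   fragment index, width in fragments, count multiplier. Enrichment <= 1
#'   triggers a warning (undetectable).
#' @param seed RNG seed.
#' @param fragment_spacing mean bp between fragment ends.
#' @param decay_exponent,decay_scale power-law distance decay parameters.
#' @param blind_shift multiplier applied to blind-fragment means.
#' @param chrom,viewpoint_name track chromosome and viewpoint label.
#' @return list with `track` (a `fragment_track`: viewpoint plus fragment
#'   data.frame `chrom`, `pos`, `class`, `count`, `norm_count`) and
#'   `peak_truth` (chrom, start, end, first, last fragment indices,
#'   enrichment).
#' @export
simulate_4c_track <- function(n_fragments, blind_fraction = 0.35,
                              background_scale = 5, peaks = list(),
                              seed = NULL, fragment_spacing = 500,
                              decay_exponent = 0.85, decay_scale = 1e5,
                              blind_shift = 0.4, chrom = "chr1",
                              viewpoint_name = "vp") {
  stopifnot(n_fragments >= 3, background_scale > 0)
  stop_if_not_scalar_prob(blind_fraction, "blind_fraction")
  for (pk in peaks) {
    ctr <- pk$position
    if (ctr < 1 || ctr > n_fragments) {
      stop("peak position outside the track", call. = FALSE)
    }
    if (pk$enrichment <= 1) {
      warning("peak enrichment <= 1 is undetectable")
    }
  }
  with_seed(seed, {
    gaps <- round(fragment_spacing * stats::runif(n_fragments, 0.5, 1.5))
    pos <- cumsum(pmax(gaps, 1))
    vp_idx <- ceiling(n_fragments / 2)
    vp_pos <- pos[vp_idx]
    d <- abs(pos - vp_pos)
    mu <- background_scale * (1 + d / decay_scale)^(-decay_exponent)
    cls <- ifelse(stats::runif(n_fragments) < blind_fraction,
                  "blind", "regular")
    mu[cls == "blind"] <- mu[cls == "blind"] * blind_shift
    truth <- NULL
    for (pk in peaks) {
      first <- max(1L, as.integer(pk$position - floor(pk$width / 2)))
      last <- min(n_fragments, first + as.integer(pk$width) - 1L)
      mu[first:last] <- mu[first:last] * pk$enrichment
      truth <- rbind(truth, data.frame(
        chrom = chrom, start = pos[first], end = pos[last] + 1L,
        first = first, last = last, enrichment = pk$enrichment))
    }
    if (is.null(truth)) {
      truth <- data.frame(chrom = character(), start = integer(),
                          end = integer(), first = integer(),
                          last = integer(), enrichment = numeric())
    }
    count <- stats::rgeom(n_fragments, prob = 1 / (1 + mu))
    track <- fragment_track(
      data.frame(chrom = chrom, pos = pos, class = cls, count = count),
      viewpoint = list(chrom = chrom, pos = vp_pos, name = viewpoint_name)
    )
    list(track = track, peak_truth = truth)
  })
}

#' Simulate a replicate expression matrix with planted fold changes
#'
#' Per-gene log2 baseline intensities are uniform on `[4, 12]`; replicate
#' values are Normal(gene mean, sigma). The first `n_up` planted genes are
#' shifted up by `log2fc` in condition B, the next `n_down` shifted down.
#'
#' @param genes a [gene_table].
#' @param de_spec list with `n_up`, `n_down`, `log2fc`, `sigma`,
#'   `n_replicates` (>= 2).
#' @param seed RNG seed.
#' @return list with `expr` (gene x sample matrix, columns `A_1..A_r`,
#'   `B_1..B_r`), `groups` (factor), `truth` (gene_id, direction
#'   up/down/none).
#' @export
simulate_expression <- function(genes, de_spec, seed = NULL) {
  stopifnot(inherits(genes, "gene_table"))
  ds <- de_spec
  if (ds$n_replicates < 2) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  ng <- nrow(genes)
  if (ds$n_up + ds$n_down > ng) {
    stop("more planted DE genes than genes", call. = FALSE)
  }
  with_seed(seed, {
    ids <- genes$gene_id
    base <- stats::runif(ng, 4, 12)
    r <- ds$n_replicates
    shift <- rep(0, ng)
    planted <- sample.int(ng, ds$n_up + ds$n_down)
    up <- planted[seq_len(ds$n_up)]
    down <- planted[setdiff(seq_along(planted), seq_len(ds$n_up))]
    shift[up] <- ds$log2fc
    shift[down] <- -ds$log2fc
    a <- matrix(stats::rnorm(ng * r, base, ds$sigma), ng, r)
    b <- matrix(stats::rnorm(ng * r, base + shift, ds$sigma), ng, r)
    expr <- cbind(a, b)
    rownames(expr) <- ids
    colnames(expr) <- c(paste0("A_", seq_len(r)), paste0("B_", seq_len(r)))
    direction <- rep("none", ng)
    direction[up] <- "up"
    direction[down] <- "down"
    list(expr = expr,
         groups = factor(rep(c("A", "B"), each = r)),
         truth = data.frame(gene_id = ids, direction = direction))
  })
}

#' Simulate genome annotation: genes, repeats and TF peaks
#'
#' Genes occupy non-overlapping slots along the chromosome, each with the
#' requested number of exons (first exon starts at the transcript start,
#' last ends at the transcript end) and a CDS spanning the interior so
#' UTRs are derivable. Repeats are random intervals labelled
#' SINE/LINE/LTR. TF peaks are centred either at supplied positions
#' (e.g. planted methylation dips) or at random positions, optionally
#' constrained to lie at least `min_tss_distance` bp from every TSS.
#'
#' @param genome_length chromosome length (bp).
#' @param n_genes,exons_per_gene gene count and exons per gene.
#' @param gene_length min/max transcript length (bp).
#' @param n_repeats,repeat_length repeat count and length range.
#' @param n_tf_peaks,peak_width TF peak count and width (bp).
#' @param peak_centers optional bp positions for peak centres (overrides
#'   `n_tf_peaks` placement).
#' @param min_tss_distance minimum bp between any peak centre and any TSS.
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return list with `genes` ([gene_table]), `repeats` (BED-like
#'   data.frame with `class`), `tf_peaks` (data.frame `chrom`, `start`,
#'   `end`, `summit`, `name`).
#' @export
simulate_annotations <- function(genome_length = 2e6, n_genes = 60,
                                 exons_per_gene = 3,
                                 gene_length = c(5000, 20000),
                                 n_repeats = 100,
                                 repeat_length = c(200, 600),
                                 n_tf_peaks = 30, peak_width = 300,
                                 peak_centers = NULL,
                                 min_tss_distance = 0,
                                 chrom = "chr1", seed = NULL) {
  stopifnot(exons_per_gene >= 1, gene_length[1] >= 200)
  slot <- floor(genome_length / max(n_genes, 1))
  if (n_genes > 0 && slot < gene_length[2] + 2) {
    stop("requested genes exceed genome length", call. = FALSE)
  }
  if (n_repeats > 0 && n_repeats * repeat_length[2] > genome_length) {
    stop("requested repeats exceed genome length", call. = FALSE)
  }
  with_seed(seed, {
    glen <- round(stats::runif(n_genes, gene_length[1], gene_length[2]))
    tx_start <- vapply(seq_len(n_genes), function(i) {
      lo <- (i - 1) * slot
      as.integer(lo + floor(stats::runif(1) * (slot - glen[i] - 1)))
    }, integer(1))
    tx_end <- tx_start + glen
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    exon_starts <- vector("list", n_genes)
    exon_ends <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      if (exons_per_gene == 1L) {
        exon_starts[[i]] <- tx_start[i]
        exon_ends[[i]] <- tx_end[i]
        next
      }
      # 2*(k-1) interior breakpoints alternate exon/intron boundaries
      nb <- 2L * (exons_per_gene - 1L)
      bp <- sort(sample(seq(tx_start[i] + 50L, tx_end[i] - 50L), nb))
      es <- c(tx_start[i], bp[seq(2, nb, by = 2)])
      ee <- c(bp[seq(1, nb, by = 2)], tx_end[i])
      exon_starts[[i]] <- as.integer(es)
      exon_ends[[i]] <- as.integer(ee)
    }
    genes <- gene_table(data.frame(
      gene_id = sprintf("gene_%03d", seq_len(n_genes)),
      chrom = chrom, strand = strand,
      tx_start = tx_start, tx_end = tx_end,
      cds_start = as.integer(tx_start + round(glen * 0.1)),
      cds_end = as.integer(tx_end - round(glen * 0.1)),
      exon_starts = I(exon_starts), exon_ends = I(exon_ends)
    ))
    if (n_repeats > 0) {
      rlen <- round(stats::runif(n_repeats, repeat_length[1],
                                 repeat_length[2]))
      rstart <- floor(stats::runif(n_repeats) * (genome_length - rlen))
      repeats <- data.frame(chrom = chrom, start = as.integer(rstart),
                            end = as.integer(rstart + rlen),
                            class = sample(c("SINE", "LINE", "LTR"),
                                           n_repeats, replace = TRUE))
    } else {
      repeats <- data.frame(chrom = character(), start = integer(),
                            end = integer(), class = character())
    }
    if (is.null(peak_centers)) {
      centers <- integer(0)
      tries <- 0L
      while (length(centers) < n_tf_peaks && tries < 200L) {
        tries <- tries + 1L
        cand <- floor(stats::runif(n_tf_peaks) *
                        (genome_length - peak_width)) + peak_width %/% 2L
        if (min_tss_distance > 0 && nrow(genes) > 0) {
          dmin <- vapply(cand, function(p) min(abs(p - genes$tss)),
                         numeric(1))
          cand <- cand[dmin >= min_tss_distance]
        }
        centers <- utils::head(unique(c(centers, cand)), n_tf_peaks)
      }
      if (length(centers) < n_tf_peaks) {
        stop("could not place TF peaks respecting min_tss_distance",
             call. = FALSE)
      }
    } else {
      centers <- as.integer(peak_centers)
      if (min_tss_distance > 0 && nrow(genes) > 0) {
        dmin <- vapply(centers, function(p) min(abs(p - genes$tss)),
                       numeric(1))
        centers <- centers[dmin >= min_tss_distance]
      }
    }
    tf_peaks <- if (length(centers) > 0) {
      data.frame(
        chrom = chrom,
        start = as.integer(centers - peak_width %/% 2L),
        end = as.integer(centers + (peak_width + 1L) %/% 2L),
        summit = as.integer(centers),
        name = sprintf("peak_%03d", seq_along(centers))
      )
    } else {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 summit = integer(), name = character())
    }
    list(genes = genes, repeats = repeats, tf_peaks = tf_peaks)
  })
}
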