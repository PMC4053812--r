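#' Simulation specification for synthetic methylomes
#'
#' Bundles the parameters of the synthetic methylome generator. The defaults
#' describe the small-intestinal differentiation setting the pipeline
#' targets: ~10x coverage beta-binomial CpG counts over a two-state
#' (hypo/hyper) methylation landscape, planted hypo-methylated regions
#' occupying enough CpGs that the genome-wide weighted methylation of the
#' "stem" condition sits near 78%, and a differentiation pair with 43
#' methylation-loss and 7 methylation-gain DMRs plus a 4-point global
#' methylation drop (78% to 74%).
#'
#' @param genome_length simulated chromosome length in bp.
#' @param cpg_density expected CpGs per kb.
#' @param coverage_mean Poisson mean of per-CpG read coverage.
#' @param hypo_level,hyper_level mean methylation of the two states, with
#'   `0 <= hypo_level < hyper_level <= 1`.
#' @param betabin_precision precision of the beta-binomial emission
#'   (`alpha = mean * precision`; `Inf` gives binomial draws).
#' @param n_hmrs number of planted hypo-methylated regions shared by both
#'   conditions.
#' @param hmr_cpg_range integer range of CpGs per planted HMR.
#' @param dmr_spec list with `n_hypo_dmrs` (regions losing methylation upon
#'   differentiation), `n_hyper_dmrs` (gaining), `delta` (methylation
#'   difference in (0, 1]) and `cpgs_per_dmr`.
#' @param global_loss target drop in genome-wide weighted methylation
#'   between the two conditions (default 0.04).
#' @param seed integer seed; identical seeds give identical output.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(genome_length = 2e6, cpg_density = 10,
                     coverage_mean = 10, hypo_level = 0.10,
                     hyper_level = 0.85, betabin_precision = 15,
                     n_hmrs = 60, hmr_cpg_range = c(20, 40),
                     dmr_spec = list(n_hypo_dmrs = 43, n_hyper_dmrs = 7,
                                     delta = 0.5, cpgs_per_dmr = 15),
                     global_loss = 0.04, seed = 1) {
  if (!is.numeric(genome_length) || genome_length <= 0) {
    stop("genome_length must be positive", call. = FALSE)
  }
  if (!is.numeric(coverage_mean) || coverage_mean <= 0) {
    stop("coverage_mean must be positive", call. = FALSE)
  }
  stop_if_not_scalar_prob(hypo_level, "hypo_level")
  stop_if_not_scalar_prob(hyper_level, "hyper_level")
  if (hypo_level >= hyper_level) {
    stop("require hypo_level < hyper_level", call. = FALSE)
  }
  stopifnot(cpg_density > 0, betabin_precision > 0, n_hmrs >= 0,
            length(hmr_cpg_range) == 2L, hmr_cpg_range[1] >= 1,
            hmr_cpg_range[2] >= hmr_cpg_range[1], global_loss >= 0)
  dd <- dmr_spec
  stopifnot(dd$n_hypo_dmrs >= 0, dd$n_hyper_dmrs >= 0,
            dd$delta > 0, dd$delta <= 1, dd$cpgs_per_dmr >= 1)
  structure(
    list(genome_length = genome_length, cpg_density = cpg_density,
         coverage_mean = coverage_mean, hypo_level = hypo_level,
         hyper_level = hyper_level, betabin_precision = betabin_precision,
         n_hmrs = as.integer(n_hmrs), hmr_cpg_range = as.integer(hmr_cpg_range),
         dmr_spec = dd, global_loss = global_loss, seed = seed),
    class = "sim_spec"
  )
}

# Place `length(lens)` non-overlapping CpG-index runs across `n_sites` sites:
# one run per equal-width slot, uniformly jittered within the slot. Keeps
# runs well separated without rejection sampling.
place_runs <- function(n_sites, lens) {
  n_runs <- length(lens)
  if (n_runs == 0L) return(data.frame(first = integer(), last = integer()))
  slot <- floor(n_sites / n_runs)
  if (slot < max(lens) + 2L) {
    stop("too many planted regions for the number of CpGs", call. = FALSE)
  }
  first <- vapply(seq_len(n_runs), function(i) {
    lo <- (i - 1L) * slot + 1L
    hi <- i * slot - lens[i]
    as.integer(lo + floor(stats::runif(1) * (hi - lo)))
  }, integer(1))
  data.frame(first = first, last = first + lens - 1L)
}

# Beta-binomial count draws for a vector of site means.
draw_site_counts <- function(means, coverage_mean, precision) {
  n <- length(means)
  cov <- stats::rpois(n, coverage_mean)
  if (is.infinite(precision)) {
    p <- means
  } else {
    p <- stats::rbeta(n, means * precision, (1 - means) * precision)
    p[means <= 0] <- 0
    p[means >= 1] <- 1
  }
  meth <- stats::rbinom(n, cov, p)
  data.frame(meth = meth, total = cov)
}

# Shared genome layout: CpG positions plus planted run indices.
sim_layout <- function(spec) {
  n <- round(spec$genome_length * spec$cpg_density / 1000)
  if (n < 3L) stop("genome too short for the requested CpG density", call. = FALSE)
  pos <- sort(sample.int(spec$genome_length, n)) - 1L
  dd <- spec$dmr_spec
  lens <- c(
    if (spec$n_hmrs > 0)
      sample(seq(spec$hmr_cpg_range[1], spec$hmr_cpg_range[2]),
             spec$n_hmrs, replace = TRUE),
    rep(dd$cpgs_per_dmr, dd$n_hypo_dmrs + dd$n_hyper_dmrs)
  )
  kind <- c(rep("hmr", spec$n_hmrs),
            rep("loss", dd$n_hypo_dmrs), rep("gain", dd$n_hyper_dmrs))
  # interleave region kinds along the genome
  ord <- sample.int(length(lens))
  runs <- place_runs(n, lens[ord])
  runs$kind <- kind[ord]
  runs$n_cpgs <- lens[ord]
  list(pos = pos, runs = runs, n = n)
}

run_truth <- function(runs, pos, kinds, chrom = "chr1") {
  sel <- runs[runs$kind %in% kinds, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      direction = character()))
  }
  data.frame(chrom = chrom, start = pos[sel$first],
             end = pos[sel$last] + 1L, n_cpgs = sel$n_cpgs,
             direction = sel$kind)
}

#' Simulate a single methylome with planted hypo-methylated regions
#'
#' Draws strictly increasing CpG positions on one synthetic chromosome,
#' plants `n_hmrs` hypo-methylated runs, and emits beta-binomial read
#' counts: sites inside planted HMRs use `hypo_level`, all others
#' `hyper_level`. Pure function of the spec (and its seed).
#'
#' @param spec a [sim_spec]. DMR settings are ignored here (see
#'   [simulate_differentiation_pair()]).
#' @param sample_name label for the emitted methylome.
#' @return list with `methylome` (a [methylome]) and `hmr_truth`
#'   (data.frame of planted intervals: chrom, start, end, n_cpgs).
#' @export
simulate_methylome <- function(spec, sample_name = "sim") {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    spec0 <- spec
    spec0$dmr_spec <- list(n_hypo_dmrs = 0L, n_hyper_dmrs = 0L,
                           delta = spec$dmr_spec$delta,
                           cpgs_per_dmr = spec$dmr_spec$cpgs_per_dmr)
    lay <- sim_layout(spec0)
    means <- rep(spec$hyper_level, lay$n)
    for (i in seq_len(nrow(lay$runs))) {
      means[lay$runs$first[i]:lay$runs$last[i]] <- spec$hypo_level
    }
    counts <- draw_site_counts(means, spec$coverage_mean,
                               spec$betabin_precision)
    m <- methylome(
      data.frame(chrom = "chr1", pos = lay$pos,
                 meth = counts$meth, total = counts$total),
      sample_name = sample_name,
      manifest = c(chr1 = spec$genome_length)
    )
    truth <- run_truth(lay$runs, lay$pos, "hmr")
    list(methylome = m, hmr_truth = truth[setdiff(names(truth), "direction")])
  })
}

#' Simulate a stem/villus differentiation pair with planted DMRs
#'
#' Generates two methylomes over one shared CpG landscape. Both carry the
#' same planted HMRs. The "villus" condition differs from "stem" at the
#' planted DMRs by exactly `delta` (loss DMRs: hyper level dropping by
#' `delta`; gain DMRs: hypo blocks rising by `delta`) and at all remaining
#' sites by a uniform downward shift calibrated so that the genome-wide
#' weighted methylation drops by `global_loss` between the conditions
#' (DMR contributions included in the calibration; the shift is clamped at
#' zero if the DMRs alone exceed the target).
#'
#' @param spec a [sim_spec].
#' @return list with `stem`, `villus` ([methylome]s), `dmr_truth`
#'   (chrom, start, end, n_cpgs, direction, delta) and `hmr_truth`.
#' @export
simulate_differentiation_pair <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  dd <- spec$dmr_spec
  if (dd$delta * spec$coverage_mean < 1) {
    warning("planted delta is below the sampling noise floor ",
            "(delta * coverage < 1)")
  }
  with_seed(spec$seed, {
    lay <- sim_layout(spec)
    stem_means <- rep(spec$hyper_level, lay$n)
    for (i in seq_len(nrow(lay$runs))) {
      idx <- lay$runs$first[i]:lay$runs$last[i]
      if (lay$runs$kind[i] %in% c("hmr", "gain")) {
        stem_means[idx] <- spec$hypo_level
      }
    }
    # villus: DMRs shifted by exactly delta; everything else by a uniform
    # shift u chosen so the expected genome-wide drop equals global_loss
    in_dmr <- rep(FALSE, lay$n)
    villus_means <- stem_means
    for (i in seq_len(nrow(lay$runs))) {
      idx <- lay$runs$first[i]:lay$runs$last[i]
      if (lay$runs$kind[i] == "loss") {
        villus_means[idx] <- spec$hyper_level - dd$delta
        in_dmr[idx] <- TRUE
      } else if (lay$runs$kind[i] == "gain") {
        villus_means[idx] <- spec$hypo_level + dd$delta
        in_dmr[idx] <- TRUE
      }
    }
    dmr_net <- sum(stem_means[in_dmr] - villus_means[in_dmr]) / lay$n
    u <- (spec$global_loss - dmr_net) / (1 - mean(in_dmr))
    if (u < 0) {
      warning("planted DMRs alone exceed global_loss; uniform shift clamped at 0")
      u <- 0
    }
    villus_means[!in_dmr] <- pmax(0, villus_means[!in_dmr] - u)
    stem_counts <- draw_site_counts(stem_means, spec$coverage_mean,
                                    spec$betabin_precision)
    villus_counts <- draw_site_counts(villus_means, spec$coverage_mean,
                                      spec$betabin_precision)
    manifest <- c(chr1 = spec$genome_length)
    stem <- methylome(data.frame(chrom = "chr1", pos = lay$pos,
                                 meth = stem_counts$meth,
                                 total = stem_counts$total),
                      sample_name = "stem", manifest = manifest)
    villus <- methylome(data.frame(chrom = "chr1", pos = lay$pos,
                                   meth = villus_counts$meth,
                                   total = villus_counts$total),
                        sample_name = "villus", manifest = manifest)
    dmr_truth <- run_truth(lay$runs, lay$pos, c("loss", "gain"))
    dmr_truth$delta <- if (nrow(dmr_truth)) dd$delta else numeric(0)
    hmr_truth <- run_truth(lay$runs, lay$pos, "hmr")
    list(stem = stem, villus = villus, dmr_truth = dmr_truth,
         hmr_truth = hmr_truth[setdiff(names(hmr_truth), "direction")])
  })
}

#' Simulate per-read CpG methylation patterns
#'
#' Emits reads covering three consecutive CpGs each, with tunable
#' co-methylation: with probability `rho` a read is "coherent" (one
#' Bernoulli draw at the mean of the three site levels decides all three
#' calls), otherwise the three calls are independent Bernoullis at the
#' per-site levels. `rho = 1` therefore produces only fully methylated or
#' fully unmethylated reads; `rho = 0` gives exact independence.
#'
#' @param m a [methylome] with at least 3 CpGs.
#' @param rho co-methylation probability in `[0, 1]`.
#' @param n_reads number of reads (0 allowed).
#' @param seed RNG seed.
#' @return A `read_patterns` data.frame: `anchor_pos`, logical `m1`, `m2`,
#'   `m3`.
#' @export
simulate_read_patterns <- function(m, rho, n_reads, seed = NULL) {
  stop_if_not_scalar_prob(rho, "rho")
  stopifnot(n_reads >= 0)
  s <- m$sites
  if (nrow(s) < 3L) stop("methylome must have >= 3 CpGs", call. = FALSE)
  lev <- site_levels(m)
  # anchors: consecutive triples on one chromosome with defined levels
  n <- nrow(s)
  ok <- s$chrom[seq_len(n - 2L)] == s$chrom[seq_len(n - 2L) + 2L] &
    !is.na(lev[seq_len(n - 2L)]) & !is.na(lev[seq_len(n - 2L) + 1L]) &
    !is.na(lev[seq_len(n - 2L) + 2L])
  anchors <- which(ok)
  if (length(anchors) == 0L) {
    stop("no CpG triple with defined levels", call. = FALSE)
  }
  empty <- data.frame(anchor_pos = integer(), m1 = logical(),
                      m2 = logical(), m3 = logical())
  class(empty) <- c("read_patterns", "data.frame")
  if (n_reads == 0L) return(empty)
  with_seed(seed, {
    a <- sample(anchors, n_reads, replace = TRUE)
    L <- cbind(lev[a], lev[a + 1L], lev[a + 2L])
    coherent <- stats::runif(n_reads) < rho
    calls <- matrix(stats::runif(3L * n_reads) < as.vector(L),
                    nrow = n_reads)
    joint <- stats::runif(n_reads) < rowMeans(L)
    calls[coherent, ] <- joint[coherent]
    out <- data.frame(anchor_pos = s$pos[a], m1 = calls[, 1L],
                      m2 = calls[, 2L], m3 = calls[, 3L])
    class(out) <- c("read_patterns", "data.frame")
    out
  })
}
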