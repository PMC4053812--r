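#' Construct a methylome
#'
#' A methylome is an ordered table of single-CpG methylation counts for one
#' cell population: for each CpG the number of methylated read observations
#' and the total number of read observations. CpGs are indexed by the 0-based
#' position of the C on the plus strand, with both strands collapsed into one
#' count pair; all genomic intervals in the package are 0-based half-open.
#'
#' @param sites data.frame with columns `chrom` (character), `pos`
#'   (0-based integer), `meth` (methylated read count) and `total`
#'   (total read count). Must be strictly sorted by (chrom, pos) with no
#'   duplicate positions.
#' @param sample_name single character label for the cell population.
#' @param manifest named numeric vector of chromosome lengths (bp). Defaults
#'   to `max(pos) + 1` per chromosome present.
#' @return An object of class `methylome`.
#' @examples
#' m <- methylome(
#'   data.frame(chrom = "chr1", pos = c(100L, 150L), meth = c(5L, 9L),
#'              total = c(10L, 10L)),
#'   sample_name = "stem"
#' )
#' weighted_methylation(m)
#' @export
methylome <- function(sites, sample_name = "sample", manifest = NULL) {
  required <- c("chrom", "pos", "meth", "total")
  if (!is.data.frame(sites) || !all(required %in% names(sites))) {
    stop("`sites` must be a data.frame with columns chrom, pos, meth, total",
         call. = FALSE)
  }
  sites <- as.data.frame(sites)[required]
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$meth <- as.integer(sites$meth)
  sites$total <- as.integer(sites$total)
  if (nrow(sites) > 0L) {
    if (any(sites$total < 0L)) stop("negative total read count", call. = FALSE)
    if (any(sites$meth < 0L) || any(sites$meth > sites$total)) {
      stop("meth counts must satisfy 0 <= meth <= total", call. = FALSE)
    }
    o <- order(sites$chrom, sites$pos)
    if (!identical(o, seq_len(nrow(sites)))) sites <- sites[o, , drop = FALSE]
    dup <- duplicated(sites[c("chrom", "pos")])
    if (any(dup)) {
      d <- sites[which(dup)[1L], ]
      stop(sprintf("duplicate CpG position %s:%d", d$chrom, d$pos), call. = FALSE)
    }
    rownames(sites) <- NULL
  }
  if (is.null(manifest)) {
    if (nrow(sites) > 0L) {
      manifest <- tapply(sites$pos, sites$chrom, function(p) max(p) + 1)
      manifest <- stats::setNames(as.numeric(manifest), names(manifest))
    } else {
      manifest <- stats::setNames(numeric(0), character(0))
    }
  }
  structure(
    list(sample_name = as.character(sample_name)[1L],
         sites = sites, manifest = manifest),
    class = "methylome"
  )
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome> %s: %d CpGs on %d chromosome(s)\n",
              x$sample_name, nrow(x$sites), length(x$manifest)))
  wm <- weighted_methylation(x)
  if (!is.na(wm)) cat(sprintf("  genome-wide weighted methylation: %.3f\n", wm))
  invisible(x)
}

n_sites <- function(m) nrow(m$sites)

# Per-site methylation level; NA where total == 0 (level is undefined, not 0).
site_levels <- function(m) {
  with(m$sites, ifelse(total > 0L, meth / total, NA_real_))
}

# Subset of site rows falling in [start, end) on chrom.
sites_in_region <- function(m, chrom, start, end) {
  s <- m$sites
  s[s$chrom == chrom & s$pos >= start & s$pos < end, , drop = FALSE]
}

same_manifest <- function(a, b) {
  identical(sort(names(a$manifest)), sort(names(b$manifest))) &&
    all(a$manifest[sort(names(a$manifest))] == b$manifest[sort(names(a$manifest))])
}

#' Read a methcounts-style methylation table
#'
#' Parses a 6-column TSV (chrom, pos, strand, context, level, coverage) into
#' a [methylome]. Methylated read counts are reconstructed as
#' `round(level * coverage)`; this is exact when the file was written from
#' integer counts. Rows whose context is not `CpG`/`CpG-like` (`CpG`, `CG`,
#' case-insensitive) are skipped with a message.
#'
#' @param path file path.
#' @param sample_name label for the methylome (default: file base name).
#' @param manifest optional named chromosome-length vector.
#' @return A [methylome].
#' @export
read_methcounts <- function(path, sample_name = NULL, manifest = NULL) {
  sample_name <- sample_name %||% sub("\\.[^.]*$", "", basename(path))
  cols <- c("chrom", "pos", "strand", "context", "level", "coverage")
  dat <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = cols,
                           colClasses = c("character", "integer", "character",
                                          "character", "numeric", "integer"),
                           quote = "", comment.char = "#")
  if (nrow(dat) == 0L) {
    return(methylome(data.frame(chrom = character(), pos = integer(),
                                meth = integer(), total = integer()),
                     sample_name = sample_name, manifest = manifest))
  }
  keep <- toupper(dat$context) %in% c("CPG", "CG")
  if (any(!keep)) {
    message(sprintf("read_methcounts: skipped %d non-CpG row(s)", sum(!keep)))
    dat <- dat[keep, , drop = FALSE]
  }
  if (any(dat$coverage < 0L)) {
    stop(sprintf("negative coverage at line %d",
                 which(dat$coverage < 0L)[1L]), call. = FALSE)
  }
  n <- nrow(dat)
  if (n > 1L) {
    same <- dat$chrom[-1L] == dat$chrom[-n]
    dpos <- dat$pos[-1L] - dat$pos[-n]
    dup_adj <- same & dpos == 0L
    if (any(dup_adj)) {
      i <- which(dup_adj)[1L] + 1L
      stop(sprintf("duplicate CpG position %s:%d", dat$chrom[i], dat$pos[i]),
           call. = FALSE)
    }
    unsorted <- same & dpos < 0L
    if (any(unsorted)) {
      stop(sprintf("input not sorted by position: first offending line %d",
                   which(unsorted)[1L] + 1L), call. = FALSE)
    }
  }
  blocks <- rle(dat$chrom)$values
  if (anyDuplicated(blocks)) {
    stop("input not sorted: chromosome blocks are interleaved", call. = FALSE)
  }
  dup <- duplicated(dat[c("chrom", "pos")])
  if (any(dup)) {
    d <- dat[which(dup)[1L], ]
    stop(sprintf("duplicate CpG position %s:%d", d$chrom, d$pos), call. = FALSE)
  }
  sites <- data.frame(chrom = dat$chrom, pos = dat$pos,
                      meth = as.integer(round(dat$level * dat$coverage)),
                      total = dat$coverage)
  methylome(sites, sample_name = sample_name, manifest = manifest)
}

#' Write a methylome as a methcounts-style table
#'
#' Inverse of [read_methcounts()] (round-trip identity on valid methylomes).
#' Zero-coverage sites are written with level 0; their counts survive the
#' round trip because `round(0 * 0) == 0`.
#'
#' @param m a [methylome].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_methcounts <- function(m, path) {
  s <- m$sites
  lev <- ifelse(s$total > 0L, s$meth / s$total, 0)
  out <- data.frame(chrom = s$chrom, pos = s$pos, strand = "+",
                    context = "CpG", level = lev, coverage = s$total)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Weighted methylation of a region
#'
#' The weighted methylation level is the count-based summary
#' `sum(meth) / sum(total)` over all covered CpGs in the region -- not the
#' mean of per-CpG levels. It is invariant under splitting a region into
#' adjacent subregions and recombining the counts.
#'
#' @param m a [methylome].
#' @param chrom,start,end optional region (0-based half-open). Omit all three
#'   for the genome-wide value.
#' @return Fraction in `[0, 1]`, or `NA` ("no data") when the region contains
#'   no covered CpG.
#' @export
weighted_methylation <- function(m, chrom = NULL, start = NULL, end = NULL) {
  s <- if (is.null(chrom)) m$sites else {
    stopifnot(!is.null(start), !is.null(end))
    sites_in_region(m, chrom, start, end)
  }
  tot <- sum(as.numeric(s$total))
  if (tot <= 0) return(no_data())
  sum(as.numeric(s$meth)) / tot
}

#' Histogram of per-CpG methylation levels
#'
#' Bins per-site methylation levels of sufficiently covered CpGs into
#' `n_bins` equal-width bins over `[0, 1]`; the last bin is closed so fully
#' methylated sites are counted.
#'
#' @param m a [methylome].
#' @param n_bins number of bins (>= 2).
#' @param min_coverage minimum total read count for a site to be binned
#'   (default 1; no per-site floor).
#' @return data.frame with `bin_low`, `bin_high`, `fraction` (fractions sum
#'   to 1). All-`NA` fractions signal "no data".
#' @export
level_histogram <- function(m, n_bins = 10, min_coverage = 1) {
  stopifnot(n_bins >= 2)
  lev <- site_levels(m)
  lev <- lev[!is.na(lev) & m$sites$total >= min_coverage]
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  out <- data.frame(bin_low = breaks[-(n_bins + 1L)], bin_high = breaks[-1L])
  if (length(lev) == 0L) {
    out$fraction <- NA_real_
    return(out)
  }
  idx <- pmin(findInterval(lev, breaks, rightmost.closed = TRUE), n_bins)
  out$fraction <- tabulate(idx, nbins = n_bins) / length(lev)
  out
}

#' Pattern fractions of per-read CpG triples
#'
#' Summarises a read-pattern set (methylation calls of the first three CpGs
#' of each read) into the fraction of reads per ordered 8-pattern and per
#' methylated-CpG count class (0-3 mC). Fully co-methylated DNA yields only
#' the two extreme classes.
#'
#' @param r a `read_patterns` object (see [simulate_read_patterns()]): a
#'   data.frame with logical columns `m1`, `m2`, `m3`.
#' @return list with `patterns` (8 rows, ordered mC,mC,mC ... C,C,C) and
#'   `classes` (4 rows, n_meth 3:0), each with a `fraction` column summing
#'   to 1. Returns `NA` ("no data") for an empty set.
#' @export
pattern_fractions <- function(r) {
  stopifnot(is.data.frame(r), all(c("m1", "m2", "m3") %in% names(r)))
  if (nrow(r) == 0L) return(no_data())
  code <- 4L * r$m1 + 2L * r$m2 + r$m3  # 7 = mC,mC,mC ... 0 = C,C,C
  lab <- vapply(7:0, function(k) {
    paste(ifelse(bitwAnd(k, c(4L, 2L, 1L)) > 0L, "mC", "C"), collapse = ",")
  }, character(1))
  counts <- tabulate(8L - code, nbins = 8L)  # index 1 = pattern 7
  patterns <- data.frame(pattern = lab, fraction = counts / nrow(r))
  nm <- r$m1 + r$m2 + r$m3
  classes <- data.frame(
    n_meth = 3:0,
    fraction = vapply(3:0, function(k) mean(nm == k), numeric(1))
  )
  list(patterns = patterns, classes = classes)
}
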