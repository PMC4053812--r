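# 4C-seq interaction analysis: blind/regular fragment-end normalization,
# multiscale window-vs-flanks rank-sum domainogram, interaction calling and
# viewpoint-to-gene linking.

#' Construct a 4C fragment-end track
#'
#' @param fragments data.frame with `chrom`, `pos` (strictly increasing per
#'   chromosome), `class` (`"blind"` or `"regular"`), `count` (>= 0) and
#'   optional `norm_count`.
#' @param viewpoint list with `chrom`, `pos`, `name`: the anchored locus
#'   from which contacts are profiled.
#' @return An object of class `fragment_track`.
#' @export
fragment_track <- function(fragments, viewpoint) {
  req <- c("chrom", "pos", "class", "count")
  stopifnot(is.data.frame(fragments), all(req %in% names(fragments)),
            all(fragments$class %in% c("blind", "regular")),
            all(fragments$count >= 0),
            is.list(viewpoint),
            all(c("chrom", "pos", "name") %in% names(viewpoint)))
  for (ch in unique(fragments$chrom)) {
    p <- fragments$pos[fragments$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("fragment positions must be strictly increasing per chromosome",
           call. = FALSE)
    }
  }
  if (!"norm_count" %in% names(fragments)) {
    fragments$norm_count <- NA_real_
  }
  structure(list(viewpoint = viewpoint,
                 fragments = as.data.frame(fragments)),
            class = "fragment_track")
}

#' @export
print.fragment_track <- function(x, ...) {
  f <- x$fragments
  cat(sprintf("<fragment_track> viewpoint %s (%s:%d): %d fragments (%d blind, %d regular)%s\n",
              x$viewpoint$name, x$viewpoint$chrom, x$viewpoint$pos, nrow(f),
              sum(f$class == "blind"), sum(f$class == "regular"),
              if (all(is.na(f$norm_count))) "" else ", normalized"))
  invisible(x)
}

# Two-sample quantile normalization: map each class onto the rank-wise mean
# reference of the two class quantile functions. Works for unequal sizes;
# for equal sizes it coincides with column-wise quantile normalization of
# the two sorted vectors (mean of order statistics). Ties share midranks
# and thus receive equal normalized values.
quantile_normalize_two <- function(x, y) {
  qs <- function(v, p) {
    # linear interpolation of the empirical quantile function at midpoints
    stats::approx(x = (seq_along(v) - 0.5) / length(v), y = sort(v),
                  xout = p, rule = 2)$y
  }
  ref <- function(p) (qs(x, p) + qs(y, p)) / 2
  px <- (rank(x, ties.method = "average") - 0.5) / length(x)
  py <- (rank(y, ties.method = "average") - 0.5) / length(y)
  list(x = ref(px), y = ref(py))
}

#' Quantile-normalize blind and regular fragment classes
#'
#' Blind fragment ends (flanked by two primary-cutter sites) follow a
#' systematically different count distribution than regular ones; this
#' maps both classes onto a common reference (the rank-wise mean of the
#' two class distributions) so they are exchangeable in the window
#' statistic. Within each class the ranking is preserved and tied raw
#' counts receive equal normalized values. If one class is empty the
#' normalization is the identity.
#'
#' @param track a [fragment_track].
#' @return The track with `norm_count` filled in.
#' @export
normalize_classes <- function(track) {
  stopifnot(inherits(track, "fragment_track"))
  f <- track$fragments
  ib <- which(f$class == "blind")
  ir <- which(f$class == "regular")
  if (length(ib) == 0L || length(ir) == 0L) {
    track$fragments$norm_count <- as.numeric(f$count)
    return(track)
  }
  qn <- quantile_normalize_two(f$count[ib], f$count[ir])
  norm <- numeric(nrow(f))
  norm[ib] <- qn$x
  norm[ir] <- qn$y
  track$fragments$norm_count <- norm
  track
}

#' Window-versus-flanks enrichment test
#'
#' The core 4C statistic: the window of `w` consecutive fragment-end
#' values starting at index `i` is compared against its two directly
#' flanking windows of the same size (`2w` values pooled) with a one-sided
#' rank-sum test ("window greater"). Indices are 1-based along the track;
#' a window whose flanks are not both fully inside the track is
#' untestable.
#'
#' @param values numeric vector of (normalized) fragment counts.
#' @param i 1-based start index of the window.
#' @param w window size in fragments (>= 2).
#' @param alternative test direction (default `"greater"`).
#' @return list with `p` (NA if untestable), `testable` (logical).
#' @export
window_test <- function(values, i, w, alternative = "greater") {
  stopifnot(w >= 2)
  n <- length(values)
  if (i - w < 1L || i + 2L * w - 1L > n) {
    return(list(p = NA_real_, testable = FALSE))
  }
  win <- values[i:(i + w - 1L)]
  flanks <- values[c((i - w):(i - 1L), (i + w):(i + 2L * w - 1L))]
  list(p = rank_sum_test(win, flanks, alternative)$p.value, testable = TRUE)
}

#' Build a multiscale 4C domainogram
#'
#' Slides the window-versus-flanks test along the normalized track for a
#' range of window sizes and assembles the `-log10` p-value matrix
#' (window size x start index): a multiscale representation of 4C
#' enrichment along the chromosome. P-values are floored at `p_floor`;
#' untestable cells are `NA`.
#'
#' @param track a normalized [fragment_track] (run [normalize_classes()]
#'   first).
#' @param window_sizes integer window sizes in fragments (default
#'   `c(2, 5, 10, 20, 50, 100)`); sizes too large for the track are
#'   dropped with a warning.
#' @param p_floor lower bound on p-values (default 1e-16).
#' @return An object of class `domainogram`: list with `neglog10p`
#'   (matrix, rows = window sizes), `window_sizes`, `pos`, `chrom`,
#'   `viewpoint`.
#' @export
build_domainogram <- function(track, window_sizes = c(2, 5, 10, 20, 50, 100),
                              p_floor = 1e-16) {
  stopifnot(inherits(track, "fragment_track"))
  f <- track$fragments
  if (all(is.na(f$norm_count))) {
    stop("track is not normalized; run normalize_classes() first",
         call. = FALSE)
  }
  window_sizes <- sort(unique(as.integer(window_sizes)))
  stopifnot(all(window_sizes >= 2L))
  n <- nrow(f)
  if (n < 3L * min(window_sizes)) {
    stop("track shorter than three times the smallest window", call. = FALSE)
  }
  drop <- window_sizes[3L * window_sizes > n]
  if (length(drop)) {
    warning("dropping window sizes too large for the track: ",
            paste(drop, collapse = ", "))
    window_sizes <- setdiff(window_sizes, drop)
  }
  v <- f$norm_count
  mat <- matrix(NA_real_, length(window_sizes), n,
                dimnames = list(paste0("w", window_sizes), NULL))
  for (r in seq_along(window_sizes)) {
    w <- window_sizes[r]
    for (i in (w + 1L):(n - 2L * w + 1L)) {
      p <- window_test(v, i, w)$p
      mat[r, i] <- -log10(max(p, p_floor))
    }
  }
  structure(list(neglog10p = mat, window_sizes = window_sizes,
                 pos = f$pos, chrom = f$chrom[1L],
                 viewpoint = track$viewpoint),
            class = "domainogram")
}

#' Call significant interactions from a domainogram
#'
#' Cells with p below `p_threshold` are expanded to the fragment span they
#' cover and merged across adjacent indices and window scales into maximal
#' genomic intervals. Each call keeps its best p-value and the window
#' sizes supporting it.
#'
#' @param d a [build_domainogram()] result.
#' @param p_threshold calling threshold (default 1e-3).
#' @return data.frame: `chrom`, `start`, `end`, `best_p`,
#'   `window_sizes` (comma-separated supporting scales), `n_cells`.
#' @export
call_interactions <- function(d, p_threshold = 1e-3) {
  stopifnot(inherits(d, "domainogram"))
  thr <- -log10(p_threshold)
  hits <- which(!is.na(d$neglog10p) & d$neglog10p > thr, arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), best_p = numeric(),
                      window_sizes = character(), n_cells = integer()))
  }
  w <- d$window_sizes[hits[, 1L]]
  i <- hits[, 2L]
  frag_first <- i
  frag_last <- i + w - 1L
  start <- d$pos[frag_first]
  end <- d$pos[frag_last] + 1L
  ir <- iv_to_ir(start, end)
  merged <- IRanges::reduce(ir)
  ov <- IRanges::findOverlaps(ir, merged)
  grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  miv <- ir_to_iv(merged)
  p <- 10^(-d$neglog10p[hits])
  out <- do.call(rbind, lapply(seq_len(length(merged)), function(g) {
    sel <- grp == g
    data.frame(chrom = d$chrom, start = miv$start[g], end = miv$end[g],
               best_p = min(p[sel]),
               window_sizes = paste(sort(unique(w[sel])), collapse = ","),
               n_cells = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

#' Link interaction calls to genes and expression
#'
#' Restricts calls to within `range_bp` of the viewpoint (calls farther
#' away are discarded), then links every retained call that comes within
#' `tss_window` bp of a TSS to the nearest such gene and annotates it with
#' the gene's expression change (log2 fold change and p-value from a
#' [de_genes()] table, if supplied).
#'
#' @param calls data.frame from [call_interactions()].
#' @param viewpoint list with `chrom`, `pos` (e.g. `track$viewpoint`).
#' @param genes a [gene_table].
#' @param de_table optional per-gene data.frame from [de_genes()].
#' @param range_bp maximum distance from the viewpoint (default 750000,
#'   i.e. 750 kb up- and downstream).
#' @param tss_window maximum call-to-TSS distance for linking (default
#'   5000 bp).
#' @return `calls` filtered to range, with `vp_distance`, `linked_gene`,
#'   `tss_distance`, and (if `de_table` given) `log2fc`, `de_p` columns.
#' @export
link_viewpoint <- function(calls, viewpoint, genes, de_table = NULL,
                           range_bp = 750000, tss_window = 5000) {
  if (nrow(calls) == 0L) {
    out <- cbind(calls, data.frame(vp_distance = numeric(0),
                                   linked_gene = character(0),
                                   tss_distance = numeric(0)))
    return(out)
  }
  vp_dist <- iv_point_gap(calls$start, calls$end, viewpoint$pos)
  keep <- calls$chrom == viewpoint$chrom & vp_dist <= range_bp
  calls <- calls[keep, , drop = FALSE]
  vp_dist <- vp_dist[keep]
  if (nrow(calls) == 0L) {
    calls$vp_distance <- numeric(0)
    calls$linked_gene <- character(0)
    calls$tss_distance <- numeric(0)
    return(calls)
  }
  linked <- character(nrow(calls))
  tssd <- rep(NA_real_, nrow(calls))
  for (j in seq_len(nrow(calls))) {
    same <- genes$chrom == calls$chrom[j]
    if (!any(same)) { linked[j] <- NA_character_; next }
    dd <- iv_point_gap(calls$start[j], calls$end[j], genes$tss[same])
    k <- which.min(dd)
    if (dd[k] <= tss_window) {
      linked[j] <- genes$gene_id[same][k]
      tssd[j] <- dd[k]
    } else {
      linked[j] <- NA_character_
    }
  }
  calls$vp_distance <- vp_dist
  calls$linked_gene <- linked
  calls$tss_distance <- tssd
  if (!is.null(de_table)) {
    idx <- match(calls$linked_gene, de_table$gene_id)
    calls$log2fc <- de_table$log2fc[idx]
    calls$de_p <- de_table$p.value[idx]
  }
  rownames(calls) <- NULL
  calls
}

#' Write / read a 4C fragment track TSV
#'
#' Four columns (chrom, pos, class, count) with the viewpoint stored on a
#' `#viewpoint=chrom:pos:name` header line.
#'
#' @param track a [fragment_track].
#' @param path file path.
#' @return `write_fragment_track` returns `path` invisibly;
#'   `read_fragment_track` a [fragment_track].
#' @export
write_fragment_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#viewpoint=%s:%d:%s", track$viewpoint$chrom,
                     track$viewpoint$pos, track$viewpoint$name), con)
  utils::write.table(track$fragments[c("chrom", "pos", "class", "count")],
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_track
#' @export
read_fragment_track <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#viewpoint=", first)) {
    stop("missing #viewpoint header line", call. = FALSE)
  }
  parts <- strsplit(sub("^#viewpoint=", "", first), ":")[[1L]]
  vp <- list(chrom = parts[1L], pos = as.integer(parts[2L]),
             name = parts[3L])
  dat <- utils::read.table(path, sep = "\t", header = FALSE, skip = 1L,
                           col.names = c("chrom", "pos", "class", "count"),
                           colClasses = c("character", "integer",
                                          "character", "numeric"))
  fragment_track(dat, vp)
}
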