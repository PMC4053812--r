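# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (forward-backward, pwilcox, interpolation) so
# each test compares two independent routes to the same quantity.

# Per-site posterior of state 1 by exhaustive enumeration over all 2^n
# state paths of a two-state HMM with beta-binomial emissions.
oracle_hmm_posterior <- function(k, n, model) {
  m <- length(k)
  ab1 <- c(model$means[1] * model$precisions[1],
           (1 - model$means[1]) * model$precisions[1])
  ab2 <- c(model$means[2] * model$precisions[2],
           (1 - model$means[2]) * model$precisions[2])
  em <- cbind(betabin_logpmf(k, n, ab1[1], ab1[2]),
              betabin_logpmf(k, n, ab2[1], ab2[2]))
  total <- 0
  post <- numeric(m)
  for (code in 0:(2^m - 1)) {
    states <- as.integer(intToBits(code))[seq_len(m)] + 1L  # 1 or 2
    lp <- log(model$init[states[1]]) + em[1, states[1]]
    if (m > 1) {
      for (t in 2:m) {
        lp <- lp + log(model$trans[states[t - 1], states[t]]) + em[t, states[t]]
      }
    }
    w <- exp(lp)
    total <- total + w
    post <- post + w * (states == 1L)
  }
  post / total
}

# Rank-sum p-value by brute-force enumeration over all C(n+m, n)
# assignments of the pooled values to the x sample.
oracle_ranksum_p <- function(x, y, alternative = "greater") {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  obs <- u_of(seq_len(nx))
  combs <- utils::combn(length(pooled), nx)
  us <- apply(combs, 2, u_of)
  switch(alternative,
         greater = mean(us >= obs),
         less = mean(us <= obs),
         two.sided = min(1, 2 * min(mean(us >= obs), mean(us <= obs))))
}

# Equal-length two-vector quantile normalization: both vectors map onto the
# mean of their sorted values, by rank.
oracle_qnorm_equal <- function(x, y) {
  ref <- (sort(x) + sort(y)) / 2
  list(x = ref[rank(x)], y = ref[rank(y)])
}

# Overlap width between interval sets (0-based half-open).
overlap_bp <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

# Did any called interval overlap this truth interval?
any_overlap <- function(truth_start, truth_end, starts, ends) {
  length(starts) > 0 && any(overlap_bp(truth_start, truth_end, starts, ends) > 0)
}

# Small deterministic methylome built from explicit counts.
make_methylome <- function(pos, meth, total, chrom = "chr1",
                           sample_name = "test", manifest = NULL) {
  methylome(data.frame(chrom = chrom, pos = pos, meth = meth, total = total),
            sample_name = sample_name,
            manifest = manifest %||% c(chr1 = max(pos) + 1000))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
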