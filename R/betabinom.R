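#' Beta-binomial log probability mass
#'
#' Log PMF of the beta-binomial distribution: the number of methylated reads
#' among `n` at a CpG whose underlying methylation probability is drawn from
#' Beta(alpha, beta). This is the emission density of the segmentation HMM;
#' it models the overdispersion of bisulfite read counts relative to a plain
#' binomial.
#'
#' `log P(k | n, a, b) = log C(n, k) + log B(k + a, n - k + b) - log B(a, b)`
#'
#' Vectorised over `k` and `n`. For `n = 0` the PMF is 1 (log 0).
#'
#' @param k methylated read count(s), `0 <= k <= n`.
#' @param n total read count(s), `>= 0`.
#' @param alpha,beta positive shape parameters.
#' @return Log probabilities, same length as `k`.
#' @examples
#' betabin_logpmf(2, 4, 1, 1)  # log(1/5): uniform over k when alpha=beta=1
#' @export
betabin_logpmf <- function(k, n, alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("alpha and beta must be positive", call. = FALSE)
  }
  if (any(k < 0) || any(n < 0) || any(k > n)) {
    stop("require 0 <= k <= n", call. = FALSE)
  }
  lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
}

# Mean/precision parameterisation: alpha = mu * prec, beta = (1 - mu) * prec.
# Orthogonal knobs: mu is the state's mean methylation, prec its precision
# (prec -> Inf recovers the binomial).
betabin_ab <- function(mean, precision) {
  c(alpha = mean * precision, beta = (1 - mean) * precision)
}
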