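#' Two-state segmentation model
#'
#' Parameters of the hidden Markov model used to segment a methylome into
#' hypo- and hyper-methylated states: beta-binomial emission parameters per
#' state, a 2x2 transition matrix over consecutive CpGs, initial state
#' probabilities, and a desert size beyond which the chain is reset (distant
#' CpGs carry no dependence).
#'
#' States are identifiable by ordering: state 1 ("hypo") always has the lower
#' emission mean.
#'
#' @param hypo_mean,hyper_mean emission means of the two states, with
#'   `hypo_mean < hyper_mean`.
#' @param hypo_precision,hyper_precision beta-binomial precisions
#'   (`alpha = mean * precision`, `beta = (1 - mean) * precision`).
#' @param trans 2x2 transition matrix, rows summing to 1 (row/col 1 = hypo).
#' @param init initial state probabilities, summing to 1.
#' @param desert_size bp gap between consecutive CpGs beyond which the chain
#'   is restarted (default 1000).
#' @return An object of class `segmentation_model`.
#' @export
segmentation_model <- function(hypo_mean = 0.1, hyper_mean = 0.8,
                               hypo_precision = 10, hyper_precision = 10,
                               trans = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2,
                                              byrow = TRUE),
                               init = c(0.5, 0.5),
                               desert_size = 1000) {
  stopifnot(hypo_mean >= 0, hyper_mean <= 1, hypo_mean < hyper_mean,
            hypo_precision > 0, hyper_precision > 0,
            is.matrix(trans), dim(trans) == c(2L, 2L), all(trans >= 0),
            length(init) == 2L, all(init >= 0), desert_size > 0)
  if (any(abs(rowSums(trans) - 1) > 1e-8)) {
    stop("transition matrix rows must sum to 1", call. = FALSE)
  }
  init <- init / sum(init)
  structure(
    list(means = c(hypo_mean, hyper_mean),
         precisions = c(hypo_precision, hyper_precision),
         trans = trans, init = init, desert_size = desert_size,
         fitted = FALSE),
    class = "segmentation_model"
  )
}

#' @export
print.segmentation_model <- function(x, ...) {
  cat(sprintf(
    "<segmentation_model>%s hypo mean %.3f (prec %.2f), hyper mean %.3f (prec %.2f)\n",
    if (isTRUE(x$fitted)) " [fitted]" else "",
    x$means[1], x$precisions[1], x$means[2], x$precisions[2]))
  cat(sprintf("  stay probabilities: hypo %.4f, hyper %.4f; desert %d bp\n",
              x$trans[1, 1], x$trans[2, 2], as.integer(x$desert_size)))
  invisible(x)
}

# Split site indices into desert-delimited blocks (chrom change or inter-CpG
# gap > desert_size starts a new block).
desert_blocks <- function(sites, desert_size) {
  n <- nrow(sites)
  if (n == 0L) return(list())
  new_block <- c(TRUE,
                 sites$chrom[-1L] != sites$chrom[-n] |
                   (sites$pos[-1L] - sites$pos[-n]) > desert_size)
  split(seq_len(n), cumsum(new_block))
}

# Log emission matrix (n x 2) for the model's two states.
emission_logmat <- function(k, n, model) {
  out <- vapply(1:2, function(s) {
    ab <- betabin_ab(model$means[s], model$precisions[s])
    betabin_logpmf(k, n, ab[["alpha"]], ab[["beta"]])
  }, numeric(length(k)))
  matrix(out, ncol = 2L)
}

# One forward-backward sweep over all blocks: total loglik, site posteriors,
# pooled transition counts, block-start posteriors.
fb_sweep <- function(sites, model) {
  k <- sites$meth; n <- sites$total
  logem <- emission_logmat(k, n, model)
  blocks <- desert_blocks(sites, model$desert_size)
  gamma <- matrix(NA_real_, nrow(sites), 2)
  xi <- matrix(0, 2, 2)
  starts <- matrix(0, 0, 2)
  loglik <- 0
  for (idx in blocks) {
    if (length(idx) == 1L) {
      # single-site block: posterior from init and emission only
      w <- model$init * exp(logem[idx, ] - max(logem[idx, ]))
      loglik <- loglik + log(sum(model$init * exp(logem[idx, ] - max(logem[idx, ])))) +
        max(logem[idx, ])
      gamma[idx, ] <- w / sum(w)
      starts <- rbind(starts, gamma[idx, ])
      next
    }
    r <- .fb_block(logem[idx, , drop = FALSE], model$trans, model$init)
    gamma[idx, ] <- r$gamma
    xi <- xi + r$xi
    starts <- rbind(starts, r$gamma[1L, ])
    loglik <- loglik + r$loglik
  }
  list(loglik = loglik, gamma = gamma, xi = xi, starts = starts)
}

# Weighted beta-binomial ML in (mean, precision) for one state's M-step.
# Starting from the current parameters keeps the EM generalized-monotone.
mstep_emission <- function(k, n, w, mean0, prec0) {
  use <- n > 0L & w > 1e-12
  if (!any(use)) return(c(mean0, prec0))
  k <- k[use]; n <- n[use]; w <- w[use]
  obj <- function(par) {
    mu <- stats::plogis(par[1L])
    prec <- exp(par[2L])
    mu <- min(max(mu, 1e-6), 1 - 1e-6)
    prec <- min(max(prec, 1e-3), 1e6)
    -sum(w * betabin_logpmf(k, n, mu * prec, (1 - mu) * prec))
  }
  p0 <- c(stats::qlogis(min(max(mean0, 1e-6), 1 - 1e-6)), log(prec0))
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-10))
  # never move uphill in the penalised objective
  if (fit$value > obj(p0)) fit$par <- p0
  c(min(max(stats::plogis(fit$par[1L]), 1e-6), 1 - 1e-6),
    min(max(exp(fit$par[2L]), 1e-3), 1e6))
}

#' Fit the segmentation model by Baum-Welch EM
#'
#' Expectation-maximisation over the CpG sequence of a methylome: the E-step
#' is a scaled forward-backward pass restarted at coverage deserts, the
#' M-step refits transition probabilities in closed form and the
#' beta-binomial emission parameters numerically (a generalised M-step that
#' never decreases the expected complete-data log-likelihood, so the
#' observed-data log-likelihood is non-decreasing across iterations).
#' After fitting, states are relabelled so state 1 is the lower-mean (hypo)
#' state.
#'
#' @param m a [methylome] with at least 50 covered CpGs.
#' @param init a [segmentation_model] used as the starting point.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations; non-convergence yields a warning
#'   and the best parameters found.
#' @param seed reserved for randomised initialisation strategies; the
#'   default fit is deterministic given `init` and ignores it.
#' @return list with `model` (fitted [segmentation_model]), `loglik`
#'   (final value), `trace` (per-iteration log-likelihoods), `converged`,
#'   `iterations`.
#' @export
fit_segmentation <- function(m, init = segmentation_model(), tol = 1e-5,
                             max_iter = 50, seed = NULL) {
  sites <- m$sites
  covered <- sum(sites$total > 0L)
  if (covered == 0L) stop("all sites have zero coverage", call. = FALSE)
  if (covered < 50L) stop("need >= 50 covered CpGs to fit", call. = FALSE)
  model <- init
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    e <- fb_sweep(sites, model)
    trace <- c(trace, e$loglik)
    if (is.finite(prev) && abs(e$loglik - prev) <= tol * (abs(prev) + 1)) {
      converged <- TRUE
      break
    }
    prev <- e$loglik
    # M-step
    trans <- e$xi / pmax(rowSums(e$xi), .Machine$double.eps)
    trans[rowSums(e$xi) == 0, ] <- model$trans[rowSums(e$xi) == 0, ]
    init_p <- colMeans(e$starts)
    for (s in 1:2) {
      par <- mstep_emission(sites$meth, sites$total, e$gamma[, s],
                            model$means[s], model$precisions[s])
      model$means[s] <- par[1L]
      model$precisions[s] <- par[2L]
    }
    model$trans <- trans
    model$init <- init_p / sum(init_p)
  }
  if (!converged) {
    # evaluate the final parameter set so the reported loglik matches it
    trace <- c(trace, fb_sweep(sites, model)$loglik)
    warning("EM did not converge within max_iter; returning best parameters")
  }
  # enforce identifiability: state 1 = lower mean
  if (model$means[1L] > model$means[2L]) {
    model$means <- rev(model$means)
    model$precisions <- rev(model$precisions)
    model$trans <- model$trans[2:1, 2:1]
    model$init <- rev(model$init)
  }
  model$fitted <- TRUE
  list(model = model, loglik = trace[length(trace)], trace = trace,
       converged = converged, iterations = it)
}

# Posterior probability of the hypo state per site (posterior decoding).
hypo_posterior <- function(m, model) {
  fb_sweep(m$sites, model)$gamma[, 1L]
}

#' Call hypo-methylated regions (HMRs)
#'
#' Posterior decoding of the fitted segmentation model: HMRs are maximal
#' runs of CpGs whose posterior probability of the hypo state exceeds 0.5
#' (a posterior of exactly 0.5 is assigned to the hyper state), broken at
#' coverage deserts. Each HMR spans its first to last member CpG and
#' carries the weighted methylation level, CpG count and mean posterior.
#'
#' @param m a [methylome].
#' @param model a fitted [segmentation_model].
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `n_cpgs`, `level`, `score` (mean hypo posterior).
#' @export
call_hmrs <- function(m, model) {
  sites <- m$sites
  if (nrow(sites) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), level = numeric(), score = numeric()))
  }
  post <- hypo_posterior(m, model)
  hypo <- post > 0.5
  blocks <- desert_blocks(sites, model$desert_size)
  out <- list()
  for (idx in blocks) {
    r <- rle(hypo[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run <- idx[starts[j]:ends[j]]
      tot <- sum(sites$total[run])
      out[[length(out) + 1L]] <- data.frame(
        chrom = sites$chrom[run[1L]],
        start = sites$pos[run[1L]],
        end = sites$pos[run[length(run)]] + 1L,
        n_cpgs = length(run),
        level = if (tot > 0) sum(sites$meth[run]) / tot else NA_real_,
        score = mean(post[run])
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), level = numeric(), score = numeric()))
  }
  do.call(rbind, out)
}
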