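# Internal helpers: interval arithmetic on 0-based half-open coordinates,
# seeded evaluation, and small assertions.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @useDynLib methylodyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# 0-based half-open [start, end) -> IRanges (1-based closed [start+1, end]).
iv_to_ir <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

ir_to_iv <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Edge-to-edge gap in bp between half-open intervals; 0 on overlap or
# abutment. Vectorised over both pairs of endpoints.
iv_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

# Gap between an interval and a point position (the point occupies [p, p+1)).
iv_point_gap <- function(s, e, p) {
  iv_gap(s, e, p, p + 1L)
}

no_data <- function() {
  structure(NA_real_, class = c("methylodyn_no_data", "numeric"))
}

is_no_data <- function(x) inherits(x, "methylodyn_no_data") || (length(x) == 1L && is.na(x))

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
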