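# Internal helpers: classed error conditions, unit constants, seeded RNG
# substreams.

#' @useDynLib icasflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 1 mmHg in pascals
MMHG_TO_PA <- 133.322

icas_stop <- function(class, message, ..., call = sys.call(-1)) {
  stop(errorCondition(message, ..., class = c(class, "icasflow_error"),
                      call = call))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         class = "icasflow_input_error") {
  if (!is_scalar_number(x)) {
    icas_stop(class, sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    icas_stop(class, sprintf("`%s` must be strictly positive (got %g)", name, x))
  }
  if (nonneg && x < 0) {
    icas_stop(class, sprintf("`%s` must be non-negative (got %g)", name, x))
  }
  invisible(x)
}

#' Derive a reproducible substream seed from a root seed
#'
#' All randomness in the package flows from one root seed split into named
#' substreams, so that adding a pipeline stage never perturbs another stage's
#' draws. The derivation is a small deterministic integer hash of the stream
#' name folded into the root seed, kept inside the 32-bit signed range.
#'
#' @param seed integer root seed.
#' @param stream character stream name (e.g. "cohort").
#' @return an integer seed usable with [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  check_scalar(seed, "seed")
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% 1000000007
  as.integer((abs(seed) %% 1048573) * 2039 + h %% 1048573) %% 2147483647L
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

# rnorm truncated by rejection to [lo, hi]; vectorised, cheap at cohort sizes
rnorm_clipped <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Convert a pressure in mmHg to pascals
#' @param p_mmhg pressure in millimetres of mercury.
#' @return pressure in Pa (1 mmHg = 133.322 Pa).
#' @export
mmhg_to_pa <- function(p_mmhg) p_mmhg * MMHG_TO_PA
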