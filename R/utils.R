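## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Channels modeled by the trajectory stage, in canonical order.
VITAL_CHANNELS <- c("HR", "RR", "SBP", "DBP", "MAP", "SpO2")

# Blood gas parameters carried on the cohort table.
GAS_PARAMS <- c("ph", "po2", "pco2", "lactate", "base_excess", "total_co2")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive per-stage seeds from one root seed
#'
#' All randomness in the pipeline flows from a single root seed; each stage
#' receives its own reproducible sub-seed so that re-running one stage does not
#' perturb the stream of another. Sub-seeds are drawn from a seeded integer
#' stream and kept within the 32-bit range.
#'
#' @param seed Integer root seed.
#' @param n Number of stage seeds to derive.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Numerically safe log(sum(exp(x))) along rows of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

stop_input <- function(...) stop(..., call. = FALSE)

# Format a half-open interval the way clinical tables print ranges.
format_range <- function(lo, hi, digits = 2) {
  sprintf(paste0("%.", digits, "f–%.", digits, "f"), lo, hi)
}
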