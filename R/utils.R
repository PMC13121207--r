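#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Distance from a position to a 1-based inclusive interval
#'
#' Zero when the position lies inside `[start, end]`; otherwise the gap to the
#' nearer end. All coordinates are 1-based and inclusive, matching VCF.
#'
#' @param pos integer vector of positions.
#' @param start,end interval bounds, 1-based inclusive (`start <= end`).
#' @return integer vector of distances, `>= 0`.
#' @export
interval_distance <- function(pos, start, end) {
  stopifnot(all(start <= end))
  pmax(start - pos, pos - end, 0)
}

#' Percent of reference implied by a log2 fold-change
#'
#' Converts a log2 fold-change to the linear-scale percentage of the
#' reference arm: `100 * 2^lfc`. A log2FC of -1.9 corresponds to 26.8% of
#' the reference.
#'
#' @param lfc numeric vector of log2 fold-changes.
#' @return numeric vector of percentages.
#' @export
percent_of_control <- function(lfc) 100 * 2^lfc

# stop() with sprintf formatting and no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Logging goes to stderr so stdout stays clean for piped table output.
log_msg <- function(level, fmt, ...) {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}
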