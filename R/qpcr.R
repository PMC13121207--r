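# Relative transcript quantification: normalisation of target Ct values to
# the geometric mean of reference genes (efficiency-scaled, Delta-Delta-Ct
# style) and expression relative to the control group.

#' Normalised quantity per sample
#'
#' Technical replicates are averaged on the Ct scale first (a warning is
#' issued when the replicate spread exceeds 0.5 cycles). The normalised
#' quantity for sample s is
#' `NQ_s = E^(-Ct_target,s) / geomean_r(E^(-Ct_r,s))`,
#' which with perfect amplification efficiency `E = 2` equals
#' `2^(mean_r(Ct_r,s) - Ct_target,s)`. A global per-sample pipetting offset
#' added to every Ct therefore cancels out.
#'
#' @param ct a [read_ct()] table.
#' @param target target assay id.
#' @param refs character vector of reference assay ids (e.g. GAPDH, HPRT1,
#'   RPLP0).
#' @param efficiency amplification efficiency, must exceed 1 (default 2).
#' @return data frame `sample`, `group`, `NQ`.
#' @export
normalised_quantity <- function(ct, target, refs, efficiency = 2) {
  if (efficiency <= 1) abort("amplification efficiency must be > 1")
  samples <- unique(ct$sample)
  mean_ct <- function(s, assay) {
    x <- ct$ct[ct$sample == s & ct$assay == assay]
    if (!length(x)) abort("sample '%s' is missing assay '%s'", s, assay)
    if (diff(range(x)) > 0.5) {
      warnf("sample '%s', assay '%s': technical replicate spread %.2f cycles",
            s, assay, diff(range(x)))
    }
    mean(x)
  }
  nq <- vapply(samples, function(s) {
    ct_t <- mean_ct(s, target)
    ct_r <- vapply(refs, mean_ct, 0, s = s)
    efficiency^(mean(ct_r) - ct_t)
  }, 0)
  grp <- ct$group[match(samples, ct$sample)]
  data.frame(sample = samples, group = grp, NQ = unname(nq),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expression relative to the control group
#'
#' Scales normalised quantities so the mean over control samples is exactly
#' 100 percent.
#'
#' @param nq a [normalised_quantity()] data frame (`sample`, `group`, `NQ`).
#' @return `nq` with an added `percent_of_control` column.
#' @export
relative_to_control <- function(nq) {
  ctrl <- nq$NQ[nq$group == "control"]
  if (!length(ctrl)) abort("no control samples")
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0) abort("control mean is zero or undefined")
  nq$percent_of_control <- 100 * nq$NQ / m
  nq
}

#' Relative expression in one step
#'
#' Convenience wrapper composing [normalised_quantity()] and
#' [relative_to_control()].
#'
#' @inheritParams normalised_quantity
#' @return data frame `sample`, `group`, `NQ`, `percent_of_control`.
#' @export
relative_expression <- function(ct, target, refs, efficiency = 2) {
  relative_to_control(normalised_quantity(ct, target, refs, efficiency))
}
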