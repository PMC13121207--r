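# Classification of the "ASO-T Rescue Set": features significantly altered
# in proband cells, significantly changed by the targeting ASO, shifted back
# toward control z-score levels, and not altered by the targeting ASO in
# control cells (off-target exclusion). A restoration fraction r summarises
# how far each feature moved back toward control.

#' Configuration of the rescue classifier
#'
#' Three threshold sets drive the classifier: `primary` for the
#' disease-altered filter (proband vs control arms), `rescue` for the
#' treatment-responsive filter (proband ASO-T vs ASO-S; kept separately
#' configurable so a more permissive fold-change can capture partially
#' restored features), and `off_target` for the control ASO-T vs ASO-S
#' exclusion (defaults to the rescue thresholds). The restoration-fraction
#' cutoffs labelling full/partial/overshoot restoration are an artifact
#' convention, not taken from any published definition.
#'
#' @param primary,rescue,off_target [thresholds()] objects.
#' @param partial_min minimum positive r for the `partial` label.
#' @param full_min minimum r for the `full` label.
#' @param overshoot_min r strictly above this is labelled `overshoot`.
#' @param method test statistic passed to [run_contrast()].
#' @return list with class `rescue_config`.
#' @export
rescue_config <- function(primary = thresholds(),
                          rescue = thresholds(),
                          off_target = rescue,
                          partial_min = 1e-9, full_min = 0.8,
                          overshoot_min = 1.2, method = "welch") {
  stopifnot(partial_min > 0, partial_min <= full_min,
            full_min <= overshoot_min)
  structure(list(primary = primary, rescue = rescue, off_target = off_target,
                 partial_min = partial_min, full_min = full_min,
                 overshoot_min = overshoot_min, method = method),
            class = "rescue_config")
}

check_same_universe <- function(a, b) {
  if (!identical(a$feature, b$feature)) {
    d <- c(setdiff(a$feature, b$feature), setdiff(b$feature, a$feature))
    abort("comparison results cover different feature universes: %s",
          paste(utils::head(d, 10), collapse = ", "))
  }
}

#' Disease-altered flag from the two proband-vs-control contrasts
#'
#' A feature is disease-altered if it is significant (at the primary
#' thresholds) in either proband-vs-control comparison; which contrast(s)
#' qualified is recorded.
#'
#' @param res_cs,res_ct [run_contrast()] results for control-ASO-S vs
#'   proband-ASO-S and control-ASO-T vs proband-ASO-S, on the same feature
#'   universe.
#' @return data frame `feature`, `disease_altered`, `qualifying` (one of
#'   `""`, `"vs C_S"`, `"vs C_T"`, `"vs C_S; vs C_T"`).
#' @export
disease_altered <- function(res_cs, res_ct) {
  check_same_universe(res_cs, res_ct)
  f1 <- res_cs$significant
  f2 <- res_ct$significant
  qual <- ifelse(f1 & f2, "vs C_S; vs C_T",
                 ifelse(f1, "vs C_S", ifelse(f2, "vs C_T", NA)))
  data.frame(feature = res_cs$feature, disease_altered = f1 | f2,
             qualifying = qual, stringsAsFactors = FALSE)
}

#' Restoration fraction and z-shift toward control
#'
#' Using per-arm means of the z-score matrix (`mPS`, `mPT`, `mCS`, `mCT` for
#' proband/control x ASO-S/ASO-T), the restoration fraction toward control
#' arm c is `r_c = (mPT - mPS) / (m_c - mPS)`, defined when the denominator
#' exceeds `eps` in magnitude. The shift flag is true when `r_c > 0` for at
#' least one control arm; the reported r is taken from the control arm with
#' the larger baseline separation `|m_c - mPS|`. When both denominators are
#' below `eps` the flag is false and r is undefined.
#'
#' @param z a z-score matrix from [z_scores()].
#' @param design a [sample_design()] containing all four ASO arms.
#' @param eps numeric tolerance for the denominator.
#' @return data frame `feature`, `shift_toward_control`, `target_arm`, `r`.
#' @export
shift_toward_control <- function(z, design, eps = 1e-9) {
  arms <- list(PS = c("proband", "ASO_S"), PT = c("proband", "ASO_T"),
               CS = c("control", "ASO_S"), CT = c("control", "ASO_T"))
  m <- lapply(arms, function(a) {
    s <- arm_samples(design, a)
    if (!length(s)) abort("design is missing the (%s, %s) arm", a[1], a[2])
    rowMeans(z[, s, drop = FALSE], na.rm = TRUE)
  })
  num <- m$PT - m$PS
  den_cs <- m$CS - m$PS
  den_ct <- m$CT - m$PS
  r_cs <- ifelse(abs(den_cs) > eps, num / den_cs, NA_real_)
  r_ct <- ifelse(abs(den_ct) > eps, num / den_ct, NA_real_)
  flag <- (!is.na(r_cs) & r_cs > 0) | (!is.na(r_ct) & r_ct > 0)
  use_cs <- abs(den_cs) >= abs(den_ct) & !is.na(r_cs)
  use_cs[is.na(r_cs)] <- FALSE
  use_cs[is.na(r_ct) & !is.na(r_cs)] <- TRUE
  r <- ifelse(use_cs, r_cs, r_ct)
  target <- ifelse(is.na(r), NA_character_, ifelse(use_cs, "C_S", "C_T"))
  data.frame(feature = rownames(z), shift_toward_control = flag,
             target_arm = target, r = r, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Off-target flag from the control ASO-T vs ASO-S contrast
#'
#' Features significantly altered by the targeting ASO in control cells are
#' off-target effects and are excluded from the rescue set.
#'
#' @param res_ctcs [run_contrast()] result for control-ASO-T vs
#'   control-ASO-S.
#' @return data frame `feature`, `off_target`.
#' @export
off_target_flags <- function(res_ctcs) {
  data.frame(feature = res_ctcs$feature, off_target = res_ctcs$significant,
             stringsAsFactors = FALSE)
}

label_restoration <- function(in_set, r, config) {
  lab <- rep("none", length(r))
  ok <- in_set & !is.na(r)
  lab[ok & r >= config$partial_min] <- "partial"
  lab[ok & r >= config$full_min] <- "full"
  lab[ok & r > config$overshoot_min] <- "overshoot"
  lab
}

#' Classify every feature of a four-arm ASO experiment
#'
#' Runs the four two-arm contrasts (control-S vs proband-S, control-T vs
#' proband-S, proband-T vs proband-S, control-T vs control-S), the z-score
#' standardisation, and combines the criteria: a feature enters the rescue
#' set iff it is disease-altered AND treatment-responsive AND shifted toward
#' a control arm AND not off-target. Deterministic given its inputs.
#'
#' @param table an [abundance_table()] with four (genotype, treatment) arms.
#' @param design a [sample_design()] with at least two replicates per arm.
#' @param config a [rescue_config()].
#' @return list of class `rescue_result` with elements `calls` (one row per
#'   feature: all flags, qualifying contrast, target arm, restoration
#'   fraction `r` and label), `summary` (counts per label plus the rescue-set
#'   size) and `contrasts` (the four underlying comparison results).
#' @export
classify_rescue <- function(table, design, config = rescue_config()) {
  c_cs <- contrast(c("control", "ASO_S"), c("proband", "ASO_S"), "C_S vs P_S")
  c_ct <- contrast(c("control", "ASO_T"), c("proband", "ASO_S"), "C_T vs P_S")
  c_resp <- contrast(c("proband", "ASO_T"), c("proband", "ASO_S"), "P_T vs P_S")
  c_off <- contrast(c("control", "ASO_T"), c("control", "ASO_S"), "C_T vs C_S")
  res_cs <- run_contrast(table, design, c_cs, config$primary,
                         method = config$method,
                         lfc_min = config$primary$lfc_min_primary)
  res_ct <- run_contrast(table, design, c_ct, config$primary,
                         method = config$method,
                         lfc_min = config$primary$lfc_min_primary)
  res_resp <- run_contrast(table, design, c_resp, config$rescue,
                           method = config$method)
  res_off <- run_contrast(table, design, c_off, config$off_target,
                          method = config$method)
  dis <- disease_altered(res_cs, res_ct)
  z <- z_scores(table)
  shift <- shift_toward_control(z, design)
  off <- off_target_flags(res_off)
  calls <- data.frame(feature = dis$feature,
                      disease_altered = dis$disease_altered,
                      qualifying = dis$qualifying,
                      treatment_responsive = res_resp$significant,
                      shift_toward_control = shift$shift_toward_control,
                      target_arm = shift$target_arm,
                      off_target = off$off_target,
                      r = shift$r, stringsAsFactors = FALSE)
  calls$in_rescue_set <- calls$disease_altered & calls$treatment_responsive &
    calls$shift_toward_control & !calls$off_target
  calls$label <- label_restoration(calls$in_rescue_set, calls$r, config)
  summary <- c(table(factor(calls$label,
                            levels = c("full", "partial", "overshoot", "none"))))
  summary <- c(summary, rescue_set = sum(calls$in_rescue_set))
  structure(list(calls = calls, summary = summary,
                 contrasts = list(C_S_vs_P_S = res_cs, C_T_vs_P_S = res_ct,
                                  P_T_vs_P_S = res_resp, C_T_vs_C_S = res_off)),
            class = "rescue_result")
}
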