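# Synthetic-data generators with planted, machine-readable ground truth.
# Every generator mirrors the study design it exercises: a 2-genotype x
# 2-ASO-treatment amniocyte experiment with 4 replicates per arm, two
# unrelated trios sharing a founder haplotype around a focal variant, Ct
# tables normalised to three reference genes, and a candidate-variant table
# in which each decoy violates exactly one prioritisation filter.

#' Configuration for the omics simulator
#'
#' Defaults reproduce the study conditions exercised throughout the test
#' suite: 2000 features of which 100 are fully rescued, 50 partially
#' rescued, 50 disease-altered but not rescued and 20 ASO off-target, with a
#' disease effect of 1 log2 unit, replicate noise sd 0.25 and 4 replicates
#' per arm.
#'
#' @param n_null,n_rescued_full,n_rescued_partial,n_rescued_not,n_off_target
#'   feature counts per planted category.
#' @param delta disease effect size in log2 units.
#' @param partial_r restoration fraction of partially rescued features, in
#'   (0, 1).
#' @param off_target_effect log2 effect applied to both ASO-T arms of
#'   off-target features.
#' @param n_rep replicates per (genotype, treatment) arm.
#' @param sigma replicate noise sd (log2 units).
#' @param baseline_mean,baseline_sd distribution of per-feature baseline
#'   log2 intensities.
#' @param seed RNG seed.
#' @return list with class `omics_sim_config`.
#' @export
omics_sim_config <- function(n_null = 1780, n_rescued_full = 100,
                             n_rescued_partial = 50, n_rescued_not = 50,
                             n_off_target = 20, delta = 1.0, partial_r = 0.5,
                             off_target_effect = 0.6, n_rep = 4, sigma = 0.25,
                             baseline_mean = 20, baseline_sd = 2, seed = 1) {
  counts <- c(null = n_null, rescued_full = n_rescued_full,
              rescued_partial = n_rescued_partial,
              rescued_not = n_rescued_not, off_target = n_off_target)
  if (any(counts < 0)) abort("category counts must be non-negative")
  if (sigma <= 0) abort("sigma must be positive")
  if (partial_r <= 0 || partial_r >= 1) abort("partial_r must lie in (0, 1)")
  if (delta == 0 && sum(counts[-1]) > 0) {
    abort("delta = 0 with non-null categories planted")
  }
  structure(list(counts = counts, delta = delta, partial_r = partial_r,
                 off_target_effect = off_target_effect, n_rep = n_rep,
                 sigma = sigma, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, seed = seed),
            class = "omics_sim_config")
}

sim_design <- function(n_rep) {
  arms <- expand.grid(genotype = c("proband", "control"),
                      treatment = c("ASO_S", "ASO_T"),
                      stringsAsFactors = FALSE)
  des <- arms[rep(seq_len(nrow(arms)), each = n_rep), ]
  des$replicate <- rep(seq_len(n_rep), times = nrow(arms))
  des$sample <- sprintf("%s_%s_%d",
                        ifelse(des$genotype == "proband", "P", "C"),
                        ifelse(des$treatment == "ASO_S", "S", "T"),
                        des$replicate)
  rownames(des) <- NULL
  sample_design(des[c("sample", "genotype", "treatment", "replicate")])
}

#' Simulate a four-arm ASO rescue proteomics experiment
#'
#' Each feature's log2 abundance is `baseline + arm effect + N(0, sigma)`.
#' Arm effects by planted category (relative to the control baseline, with a
#' random sign s per feature): `null` has none; `rescued_full` is shifted by
#' `delta * s` in proband-ASO-S and back to 0 under proband-ASO-T;
#' `rescued_partial` retains `(1 - partial_r) * delta * s` under ASO-T;
#' `rescued_not` is shifted in both proband arms; `off_target` is shifted by
#' `off_target_effect * s` in both ASO-T arms (control and proband alike, so
#' the off-target exclusion — not the genotype — is what must remove it).
#'
#' @param config an [omics_sim_config()].
#' @return list with `table` ([abundance_table()]), `design`
#'   ([sample_design()]) and `truth` (data frame `feature`, `category`,
#'   `sign`, `effect_PS`, `effect_PT`, `effect_CS`, `effect_CT`).
#' @export
simulate_omics <- function(config = omics_sim_config()) {
  stopifnot(inherits(config, "omics_sim_config"))
  n <- sum(config$counts)
  category <- rep(names(config$counts), config$counts)
  features <- sprintf("F%04d", seq_len(n))
  design <- sim_design(config$n_rep)
  with_seed(config$seed, {
    s <- sample(c(-1, 1), n, replace = TRUE)
    d <- config$delta * s
    eff <- matrix(0, n, 4, dimnames = list(features, c("PS", "PT", "CS", "CT")))
    eff[category == "rescued_full", "PS"] <- d[category == "rescued_full"]
    eff[category == "rescued_partial", "PS"] <- d[category == "rescued_partial"]
    eff[category == "rescued_partial", "PT"] <-
      (1 - config$partial_r) * d[category == "rescued_partial"]
    eff[category == "rescued_not", c("PS", "PT")] <-
      d[category == "rescued_not"]
    off <- category == "off_target"
    eff[off, c("PT", "CT")] <- config$off_target_effect * s[off]
    baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    arm_key <- paste0(ifelse(design$genotype == "proband", "P", "C"),
                      ifelse(design$treatment == "ASO_S", "S", "T"))
    vals <- sapply(seq_len(nrow(design)), function(j) {
      baseline + eff[, arm_key[j]] +
        stats::rnorm(n, 0, config$sigma)
    })
    colnames(vals) <- design$sample
    rownames(vals) <- features
    truth <- data.frame(feature = features, category = category, sign = s,
                        effect_PS = eff[, "PS"], effect_PT = eff[, "PT"],
                        effect_CS = eff[, "CS"], effect_CT = eff[, "CT"],
                        stringsAsFactors = FALSE, row.names = NULL)
    list(table = abundance_table(vals), design = design, truth = truth)
  })
}

#' Simulate a phosphoproteomic experiment with a planted active kinase
#'
#' Sites are grouped into proteins (`GENE_S<pos>` ids) and kinases are
#' mapped to random substrate sites; the substrates of one planted kinase
#' share a common log2 shift in both proband arms, emulating constitutively
#' altered kinase activity in the disease state.
#'
#' @param n_proteins number of proteins.
#' @param sites_per_protein phosphosites per protein.
#' @param n_kinases number of kinases.
#' @param substrates_per_kinase substrate sites annotated per kinase.
#' @param kinase_shift log2 shift shared by the planted kinase's substrates
#'   (0 plants no kinase).
#' @param sigma replicate noise sd.
#' @param n_rep replicates per arm.
#' @param baseline_mean,baseline_sd baseline distribution.
#' @param seed RNG seed.
#' @return list with `table`, `design`, `kinase_map` (data frame `kinase`,
#'   `site`) and `truth` (list with `active_kinase` and the per-site shift).
#' @export
simulate_phospho <- function(n_proteins = 100, sites_per_protein = 5,
                             n_kinases = 20, substrates_per_kinase = 10,
                             kinase_shift = 1.0, sigma = 0.25, n_rep = 4,
                             baseline_mean = 20, baseline_sd = 2, seed = 1) {
  sites <- as.vector(vapply(seq_len(n_proteins), function(i) {
    sprintf("GENE%03d_S%d", i, seq_len(sites_per_protein) * 7)
  }, character(sites_per_protein)))
  n <- length(sites)
  design <- sim_design(n_rep)
  with_seed(seed, {
    kinase_map <- do.call(rbind, lapply(seq_len(n_kinases), function(k) {
      data.frame(kinase = sprintf("KIN%02d", k),
                 site = sample(sites, substrates_per_kinase),
                 stringsAsFactors = FALSE)
    }))
    active <- if (kinase_shift != 0) "KIN01" else NA_character_
    shift <- stats::setNames(rep(0, n), sites)
    if (!is.na(active)) {
      shift[kinase_map$site[kinase_map$kinase == active]] <- kinase_shift
    }
    baseline <- stats::rnorm(n, baseline_mean, baseline_sd)
    proband <- design$genotype == "proband"
    vals <- sapply(seq_len(nrow(design)), function(j) {
      baseline + (if (proband[j]) shift else 0) + stats::rnorm(n, 0, sigma)
    })
    dimnames(vals) <- list(sites, design$sample)
    list(table = abundance_table(vals), design = design,
         kinase_map = kinase_map,
         truth = list(active_kinase = active, site_shift = shift))
  })
}

#' Simulate two trios sharing a founder haplotype
#'
#' Two unrelated trios whose founders each carry one copy of a shared
#' ancestral haplotype spanning the planted segment; both probands inherit
#' it from both parents and are therefore homozygous across the segment,
#' with the focal variant homozygous alternate in the probands and
#' heterozygous in all four parents. Background genotypes are drawn from
#' per-marker allele frequencies under Hardy-Weinberg equilibrium with
#' Mendelian transmission. The markers immediately flanking the planted
#' segment are forced heterozygous in both probands so the segment boundary
#' is identifiable exactly at marker resolution. A configurable fraction of
#' genotype-quality values is drawn below the usual filtering cutoff.
#'
#' @param n_markers total marker count.
#' @param segment integer vector `c(first, last)` marker indices of the
#'   planted founder segment.
#' @param focal_marker marker index of the focal variant (inside `segment`).
#' @param chrom chromosome label.
#' @param start_pos position of the first marker.
#' @param maf_range range of background minor-allele frequencies.
#' @param gq_mean,gq_sd distribution of genotype qualities.
#' @param low_gq_fraction fraction of calls assigned a low GQ (uniform on
#'   10–35).
#' @param seed RNG seed.
#' @return list with `genotypes` ([genotype_matrix()]), `pedigree`, and
#'   `truth` (planted segment marker indices and positions, focal position,
#'   founder haplotype).
#' @export
simulate_pedigrees <- function(n_markers = 1000, segment = c(200, 400),
                               focal_marker = 300, chrom = "chr17",
                               start_pos = 45e6, maf_range = c(0.1, 0.5),
                               gq_mean = 60, gq_sd = 10,
                               low_gq_fraction = 0.1, seed = 1) {
  stopifnot(segment[1] >= 2, segment[2] <= n_markers - 1,
            focal_marker >= segment[1], focal_marker <= segment[2])
  inds <- c("AI-1", "AI-2", "AII-1", "BI-1", "BI-2", "BII-1")
  ped <- data.frame(
    family = c("A", "A", "A", "B", "B", "B"),
    id = inds,
    father = c(NA, NA, "AI-1", NA, NA, "BI-1"),
    mother = c(NA, NA, "AI-2", NA, NA, "BI-2"),
    sex = c(1, 2, 1, 1, 2, 1),
    affected = c("no", "no", "yes", "no", "no", "yes"),
    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  with_seed(seed, {
    pos <- start_pos + cumsum(sample(500:5000, n_markers, replace = TRUE))
    maf <- stats::runif(n_markers, maf_range[1], maf_range[2])
    in_seg <- seq(segment[1], segment[2])
    founder <- stats::rbinom(n_markers, 1, maf)  # shared ancestral haplotype
    founder[focal_marker] <- 1                   # focal alt rides on it
    maf[focal_marker] <- 0                       # absent from background
    draw_hap <- function() stats::rbinom(n_markers, 1, maf)
    # each parent: one founder-derived haplotype over the segment, one random
    parent_haps <- lapply(inds[c(1, 2, 4, 5)], function(i) {
      h1 <- draw_hap(); h2 <- draw_hap()
      h1[in_seg] <- founder[in_seg]
      list(h1 = h1, h2 = h2)
    })
    names(parent_haps) <- inds[c(1, 2, 4, 5)]
    transmit <- function(haps) {
      pick <- stats::rbinom(n_markers, 1, 0.5)
      hap <- ifelse(pick == 1, haps$h1, haps$h2)
      hap[in_seg] <- founder[in_seg]  # probands inherit the founder segment
      hap
    }
    child_hap <- list(
      `AII-1` = list(h1 = transmit(parent_haps[["AI-1"]]),
                     h2 = transmit(parent_haps[["AI-2"]])),
      `BII-1` = list(h1 = transmit(parent_haps[["BI-1"]]),
                     h2 = transmit(parent_haps[["BI-2"]])))
    haps <- c(parent_haps, child_hap)
    geno <- vapply(inds, function(i) haps[[i]]$h1 + haps[[i]]$h2,
                   numeric(n_markers))
    # obligate het flanks in the probands: the planted span ends exactly here
    flank <- c(segment[1] - 1, segment[2] + 1)
    for (pr in c("AII-1", "BII-1")) geno[flank, pr] <- 1L
    for (pa in inds[c(1, 2, 4, 5)]) geno[flank, pa] <- pmax(geno[flank, pa], 1L)
    gq <- matrix(pmax(stats::rnorm(n_markers * 6, gq_mean, gq_sd), 1),
                 n_markers, 6, dimnames = list(NULL, inds))
    low <- matrix(stats::runif(n_markers * 6) < low_gq_fraction, n_markers, 6)
    gq[low] <- stats::runif(sum(low), 10, 35)
    markers <- data.frame(chrom = chrom, pos = pos,
                          ref = "G", alt = "A", stringsAsFactors = FALSE)
    gm <- genotype_matrix(markers, geno, gq)
    truth <- list(segment_markers = segment,
                  segment_pos = c(pos[segment[1]], pos[segment[2]]),
                  focal_pos = pos[focal_marker],
                  founder_haplotype = founder)
    list(genotypes = gm, pedigree = ped, truth = truth)
  })
}

#' Simulate a qPCR Ct table with known relative expression
#'
#' Reference gene Ct values get a per-sample pipetting offset plus
#' N(0, sigma_ct) technical noise; the target Ct additionally encodes each
#' sample's true expressed fraction as `-log2(fraction)` extra cycles, so
#' recovered percent-of-control estimates can be compared against the truth.
#'
#' @param true_fractions named numeric vector of true expression fractions
#'   per sample (controls should be 1).
#' @param groups named character vector (`proband`/`control`) per sample.
#' @param sigma_ct technical noise sd in cycles.
#' @param n_tech technical replicates per assay.
#' @param seed RNG seed.
#' @return list with `ct` (a `ct_table`) and `truth` (data frame `sample`,
#'   `fraction`, `percent`).
#' @export
simulate_ct <- function(true_fractions,
                        groups = stats::setNames(
                          ifelse(true_fractions < 1, "proband", "control"),
                          names(true_fractions)),
                        sigma_ct = 0.05, n_tech = 3, seed = 1) {
  stopifnot(!is.null(names(true_fractions)), all(true_fractions > 0))
  refs <- c(GAPDH = 20, HPRT1 = 24, RPLP0 = 22)
  target_base <- 24
  with_seed(seed, {
    rows <- list()
    for (s in names(true_fractions)) {
      offset <- stats::rnorm(1, 0, 0.3)
      for (a in names(refs)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample = s, assay = a, role = "reference", rep = seq_len(n_tech),
          ct = refs[[a]] + offset + stats::rnorm(n_tech, 0, sigma_ct),
          group = groups[[s]], stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, assay = "CDK5RAP3", role = "target", rep = seq_len(n_tech),
        ct = target_base + offset - log2(true_fractions[[s]]) +
          stats::rnorm(n_tech, 0, sigma_ct),
        group = groups[[s]], stringsAsFactors = FALSE)
    }
    ct <- validate_ct(do.call(rbind, rows))
    truth <- data.frame(sample = names(true_fractions),
                        fraction = unname(true_fractions),
                        percent = 100 * unname(true_fractions),
                        stringsAsFactors = FALSE)
    list(ct = ct, truth = truth)
  })
}

#' Simulate a candidate-variant table with designed decoys
#'
#' Plants one causal deep-intronic variant (population MAF 0, maximum
#' SpliceAI delta per `causal_spec`, recessive trio genotypes 2/1/1) among
#' decoys each violating exactly one prioritisation filter: common MAF,
#' sub-threshold delta, or failed segregation. Decoys cycle through the
#' three violation types.
#'
#' @param n_decoys number of decoy variants.
#' @param causal_spec list with `chrom`, `pos`, `gene`, `delta` (defaults
#'   mirror a deep-intronic donor-gain candidate on chr17 with delta 0.42).
#' @param seed RNG seed.
#' @return list with `variants` (data frame ready for
#'   [prioritise_variants()]), `pedigree` (one trio) and `truth` (data frame
#'   `id`, `role`: `causal` or the violated filter).
#' @export
simulate_variant_table <- function(n_decoys = 9,
                                   causal_spec = list(chrom = "chr17",
                                                      pos = 47974691,
                                                      gene = "CDK5RAP3",
                                                      delta = 0.42),
                                   seed = 1) {
  ped <- data.frame(family = "A", id = c("father", "mother", "proband"),
                    father = c(NA, NA, "father"),
                    mother = c(NA, NA, "mother"),
                    sex = c(1, 2, 1), affected = c("no", "no", "yes"),
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  with_seed(seed, {
    mk_row <- function(id, pos, gene, maf, delta, gt) {
      data.frame(id = id, chrom = causal_spec$chrom, pos = pos, ref = "G",
                 alt = "A", gene = gene, maf = maf,
                 ds_ag = 0, ds_al = 0, ds_dg = delta, ds_dl = 0,
                 father = gt[1], mother = gt[2], proband = gt[3],
                 stringsAsFactors = FALSE)
    }
    causal <- mk_row("causal", causal_spec$pos, causal_spec$gene, 0,
                     causal_spec$delta, c(1, 1, 2))
    roles <- rep(c("common_maf", "low_delta", "fails_segregation"),
                 length.out = n_decoys)
    decoys <- lapply(seq_len(n_decoys), function(i) {
      pos <- causal_spec$pos + i * 1000L
      gene <- sprintf("DECOY%02d", i)
      switch(roles[i],
             common_maf = mk_row(sprintf("decoy%02d", i), pos, gene,
                                 0.02, 0.42, c(1, 1, 2)),
             low_delta = mk_row(sprintf("decoy%02d", i), pos, gene,
                                0, 0.09, c(1, 1, 2)),
             fails_segregation = mk_row(sprintf("decoy%02d", i), pos, gene,
                                        0, 0.42, c(1, 1, 1)))
    })
    variants <- do.call(rbind, c(list(causal), decoys))
    truth <- data.frame(id = variants$id,
                        role = c("causal", roles[seq_len(n_decoys)]),
                        stringsAsFactors = FALSE)
    list(variants = variants, pedigree = ped, truth = truth)
  })
}
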