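# ROH detection around a focal variant, cross-family minimal shared region,
# GQ-filtered haplotype concordance, a Somalier-style relatedness screen and
# the splice-variant prioritisation filter.
#
# Boundary conventions, taken verbatim from the study design: population MAF
# strictly < the cutoff, SpliceAI delta inclusive >=, genotype quality
# strictly >, outlier proximity inclusive <=.

#' Detect the run of homozygosity containing a focal position
#'
#' Starting from the marker at `focal_pos`, the run extends greedily in both
#' directions over consecutive homozygous calls (alternate-allele count 0 or
#' 2), consuming at most `max_het` heterozygous calls in total; a
#' heterozygous marker only joins the segment when a further homozygous
#' marker extends past it, so boundaries always sit on homozygous markers.
#' Markers with missing calls, or with GQ not exceeding `gq_min` when
#' `gq_min > 0`, are ignored (neither consumed nor boundary-setting).
#'
#' @param gm a [genotype_matrix()].
#' @param individual column name in the genotype matrix.
#' @param focal_pos 1-based position of the focal variant (must be a marker
#'   with a homozygous call in this individual).
#' @param max_het heterozygous interruptions allowed (default 0).
#' @param gq_min genotype-quality floor (strict `>`; 0 disables).
#' @return list of class `roh_segment`: `individual`, `chrom`, `start`,
#'   `end`, `n_markers` (markers of this scan inside the segment),
#'   `het_interruptions`.
#' @export
detect_roh <- function(gm, individual, focal_pos, max_het = 0, gq_min = 0) {
  if (!individual %in% colnames(gm$geno)) abort("unknown individual '%s'", individual)
  idx <- which(gm$markers$pos == focal_pos)
  if (!length(idx)) abort("no marker at focal position %d", focal_pos)
  idx <- idx[1]
  chrom <- gm$markers$chrom[idx]
  on_chrom <- which(gm$markers$chrom == chrom)
  calls <- gm$geno[on_chrom, individual]
  gq <- gm$gq[on_chrom, individual]
  pos <- gm$markers$pos[on_chrom]
  usable <- !is.na(calls) & (gq_min <= 0 | gq > gq_min)
  i0 <- match(idx, on_chrom)
  if (!usable[i0]) abort("focal call is missing or below the GQ floor")
  if (calls[i0] == 1) abort("focal call is heterozygous: no ROH by definition")
  scan <- function(step) {
    bound <- i0
    het_used <- 0
    pending_het <- 0
    i <- i0 + step
    while (i >= 1 && i <= length(calls)) {
      if (usable[i]) {
        if (calls[i] == 1) {
          if (het_used + pending_het + 1 > max_het) break
          pending_het <- pending_het + 1
        } else {
          bound <- i
          het_used <- het_used + pending_het
          pending_het <- 0
        }
      }
      i <- i + step
    }
    list(bound = bound, het = het_used)
  }
  left <- scan(-1)
  right <- scan(1)
  inside <- seq(left$bound, right$bound)
  structure(list(individual = individual, chrom = chrom,
                 start = pos[left$bound], end = pos[right$bound],
                 n_markers = sum(usable[inside]),
                 het_interruptions = left$het + right$het),
            class = "roh_segment")
}

#' Minimal region shared by a set of ROH segments
#'
#' The intersection of segments that all contain the focal variant —
#' equivalently the interval bounded by the smallest ROH.
#'
#' @param segments list of [detect_roh()] results on one chromosome.
#' @return list `chrom`, `start`, `end`.
#' @export
minimal_shared_region <- function(segments) {
  if (!length(segments)) abort("no segments supplied")
  chrom <- unique(vapply(segments, `[[`, "", "chrom"))
  if (length(chrom) != 1) abort("segments lie on different chromosomes")
  start <- max(vapply(segments, `[[`, 0, "start"))
  end <- min(vapply(segments, `[[`, 0, "end"))
  if (start > end) abort("segments are disjoint")
  list(chrom = chrom, start = start, end = end)
}

#' Haplotype concordance matrix over a shared region
#'
#' Restricts markers to those inside `region`, called in all `individuals`
#' and with genotype quality strictly above `gq_min` in every individual,
#' then renders allele states (`ref`/`het`/`alt`). The concordant
#' sub-interval is the maximal run of retained markers around `focal_pos`
#' where all `carriers` (the homozygous affected individuals) have identical
#' allele counts. A marker-funnel of the filtering is attached.
#'
#' @param gm a [genotype_matrix()].
#' @param region list or vector with `chrom`, `start`, `end`.
#' @param individuals individuals that must all be called.
#' @param gq_min genotype-quality cutoff (strict `>`, default 35).
#' @param carriers individuals whose allele counts must agree (default: all
#'   `individuals`).
#' @param focal_pos focal variant position (defaults to the region centre
#'   marker).
#' @return list of class `haplotype_matrix`: `states` (character matrix
#'   markers x individuals), `markers`, `concordant` (`start`/`end`),
#'   `funnel` (named counts: total, dropped_by_call, dropped_by_gq, kept).
#' @export
haplotype_matrix <- function(gm, region, individuals, gq_min = 35,
                             carriers = individuals, focal_pos = NULL) {
  stopifnot(all(individuals %in% colnames(gm$geno)))
  sel <- gm$markers$chrom == region$chrom &
    gm$markers$pos >= region$start & gm$markers$pos <= region$end
  total <- sum(sel)
  geno <- gm$geno[sel, individuals, drop = FALSE]
  gq <- gm$gq[sel, individuals, drop = FALSE]
  markers <- gm$markers[sel, , drop = FALSE]
  called <- rowSums(is.na(geno)) == 0
  good_gq <- rowSums(gq > gq_min) == length(individuals)
  keep <- called & good_gq
  funnel <- c(total = total,
              dropped_by_call = sum(!called),
              dropped_by_gq = sum(called & !good_gq),
              kept = sum(keep))
  if (!any(keep)) {
    abort("no markers survive filtering (total %d, dropped_by_call %d, dropped_by_gq %d)",
          funnel["total"], funnel["dropped_by_call"], funnel["dropped_by_gq"])
  }
  geno <- geno[keep, , drop = FALSE]
  markers <- markers[keep, , drop = FALSE]
  states <- matrix(c("ref", "het", "alt")[geno + 1], nrow = nrow(geno),
                   dimnames = list(markers$pos, individuals))
  if (is.null(focal_pos)) {
    focal_pos <- markers$pos[ceiling(nrow(markers) / 2)]
  }
  i0 <- which.min(abs(markers$pos - focal_pos))
  agree <- apply(geno[, carriers, drop = FALSE], 1,
                 function(g) length(unique(g)) == 1)
  lo <- i0
  while (lo > 1 && agree[lo - 1]) lo <- lo - 1
  hi <- i0
  while (hi < nrow(markers) && agree[hi + 1]) hi <- hi + 1
  if (!agree[i0]) abort("carriers disagree at the focal marker")
  structure(list(states = states, markers = markers,
                 concordant = list(chrom = region$chrom,
                                   start = markers$pos[lo],
                                   end = markers$pos[hi]),
                 funnel = funnel),
            class = "haplotype_matrix")
}

#' Pairwise relatedness score
#'
#' A Somalier-style genotype-concordance statistic over markers called in
#' both individuals:
#' `(N_both_het - 2 * N_opposite_hom) / min(N_het_i, N_het_j)`.
#' Unrelated pairs score near 0; the conventional cutoff calls a pair
#' unrelated when the score is below 0.05.
#'
#' @param gm a [genotype_matrix()].
#' @param ind_i,ind_j individual ids.
#' @param min_markers minimum overlapping called markers (default 200).
#' @return list `score`, `n_markers`, `unrelated` (score < 0.05).
#' @export
relatedness <- function(gm, ind_i, ind_j, min_markers = 200) {
  gi <- gm$geno[, ind_i]
  gj <- gm$geno[, ind_j]
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < min_markers) {
    abort("only %d overlapping called markers (need >= %d)", sum(ok), min_markers)
  }
  gi <- gi[ok]; gj <- gj[ok]
  both_het <- sum(gi == 1 & gj == 1)
  opp_hom <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
  denom <- min(sum(gi == 1), sum(gj == 1))
  if (denom == 0) abort("no heterozygous calls in one individual: score undefined")
  score <- (both_het - 2 * opp_hom) / denom
  list(score = score, n_markers = sum(ok), unrelated = score < 0.05)
}

seg_recessive_hom <- function(v, ped) {
  status <- "segregating"
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (!id %in% names(v)) next
    g <- v[[id]]
    if (is.na(g)) { status <- "unknown"; next }
    if (ped$affected[i] == "yes") {
      if (g != 2) return("fails")
    } else {
      has_affected_child <- any(ped$affected == "yes" &
                                  (ped$father == id | ped$mother == id),
                                na.rm = TRUE)
      if (has_affected_child) {
        if (g != 1) return("fails")
      } else if (!g %in% c(0, 1)) {
        return("fails")
      }
    }
  }
  status
}

seg_comp_het <- function(v, ped) {
  status <- "segregating"
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (!id %in% names(v)) next
    g <- v[[id]]
    if (is.na(g)) { status <- "unknown"; next }
    if (ped$affected[i] == "yes") {
      if (g != 1) return("fails")
    } else if (g == 2) {
      return("fails")
    }
  }
  status
}

seg_de_novo <- function(v, ped) {
  status <- "segregating"
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (!id %in% names(v)) next
    g <- v[[id]]
    if (is.na(g)) { status <- "unknown"; next }
    if (ped$affected[i] == "yes") {
      if (g < 1) return("fails")
    } else if (g != 0) {
      return("fails")
    }
  }
  status
}

#' Prioritise candidate splice variants
#'
#' Retains variants that are rare (population MAF strictly below `maf_max`),
#' splice-relevant (maximum of the four SpliceAI delta scores at or above
#' `delta_min`) and consistent with the inheritance `mode`:
#' `recessive_hom` requires affected individuals homozygous alternate,
#' parents of affected individuals heterozygous and unaffected siblings
#' carrying at most one allele; `de_novo` requires the variant absent from
#' unaffected individuals; `comp_het` additionally requires at least two
#' retained variants in the same gene, one inherited from each parent.
#' A missing genotype degrades segregation to `"unknown"` (the variant is
#' retained and flagged) rather than dropping the candidate silently.
#' Output is sorted by tier, then descending maximum delta.
#'
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `maf`, the four SpliceAI deltas `ds_ag`, `ds_al`, `ds_dg`,
#'   `ds_dl`, optionally `tier`, plus one allele-count column per pedigree
#'   member.
#' @param pedigree a [read_pedigree()] data frame.
#' @param mode `"recessive_hom"`, `"comp_het"` or `"de_novo"`.
#' @param maf_max MAF cutoff (strict `<`, default 0.01).
#' @param delta_min SpliceAI delta cutoff (inclusive `>=`, default 0.10).
#' @return the retained rows with added columns `max_delta` and
#'   `segregation` (`"segregating"` or `"unknown"`).
#' @export
prioritise_variants <- function(variants, pedigree, mode = "recessive_hom",
                                maf_max = 0.01, delta_min = 0.10) {
  if (!mode %in% c("recessive_hom", "comp_het", "de_novo")) {
    abort("unknown mode '%s'", mode)
  }
  dcols <- c("ds_ag", "ds_al", "ds_dg", "ds_dl")
  stopifnot(all(c("maf", "gene", dcols) %in% names(variants)))
  v <- variants
  v$max_delta <- do.call(pmax, c(unname(v[dcols]), list(na.rm = TRUE)))
  keep <- v$maf < maf_max & v$max_delta >= delta_min
  v <- v[keep, , drop = FALSE]
  if (!nrow(v)) return(v[order(v$max_delta), , drop = FALSE])
  seg_fun <- switch(mode, de_novo = seg_de_novo, comp_het = seg_comp_het,
                    recessive_hom = seg_recessive_hom)
  v$segregation <- vapply(seq_len(nrow(v)), function(i) {
    seg_fun(as.list(v[i, , drop = FALSE]), pedigree)
  }, "")
  v <- v[v$segregation != "fails", , drop = FALSE]
  if (mode == "comp_het" && nrow(v)) {
    affected <- pedigree$id[pedigree$affected == "yes"]
    fathers <- unique(stats::na.omit(pedigree$father[pedigree$id %in% affected]))
    mothers <- unique(stats::na.omit(pedigree$mother[pedigree$id %in% affected]))
    from_parent <- function(row, parents) {
      any(vapply(parents, function(p) {
        p %in% names(row) && !is.na(row[[p]]) && row[[p]] >= 1
      }, TRUE))
    }
    keep_gene <- vapply(split(seq_len(nrow(v)), v$gene), function(idx) {
      if (length(idx) < 2) return(FALSE)
      pat <- vapply(idx, function(i) from_parent(as.list(v[i, ]), fathers), TRUE)
      mat <- vapply(idx, function(i) from_parent(as.list(v[i, ]), mothers), TRUE)
      any(pat) && any(mat)
    }, TRUE)
    v <- v[v$gene %in% names(keep_gene)[keep_gene], , drop = FALSE]
  }
  if (!"tier" %in% names(v)) v$tier <- rep(4L, nrow(v))
  v[order(v$tier, -v$max_delta), , drop = FALSE]
}

#' Flag variants near splice-outlier intervals
#'
#' A variant is proximal when its distance to an interval (see
#' [interval_distance()]; 0 inside, 1-based inclusive coordinates) is at
#' most `window` base pairs. The distance to the nearest interval on the
#' same chromosome is recorded.
#'
#' @param variants data frame with `chrom` and `pos`.
#' @param outliers data frame with `chrom`, `start`, `end` (may be empty).
#' @param window proximity window in bp (inclusive `<=`, default 250).
#' @return `variants` with added `outlier_proximal` and `outlier_distance`.
#' @export
outlier_proximity <- function(variants, outliers, window = 250) {
  variants$outlier_distance <- NA_real_
  variants$outlier_proximal <- FALSE
  if (is.null(outliers) || !nrow(outliers)) return(variants)
  for (i in seq_len(nrow(variants))) {
    same <- outliers[outliers$chrom == variants$chrom[i], , drop = FALSE]
    if (!nrow(same)) next
    d <- min(interval_distance(variants$pos[i], same$start, same$end))
    variants$outlier_distance[i] <- d
    variants$outlier_proximal[i] <- d <= window
  }
  variants
}

#' Assign gene-list tiers to variants
#'
#' Tier 1–3 are the first matching gene list (e.g. neuromuscular /
#' neurological genes, other clinically relevant Mendelian genes, murine
#' essential genes); tier 4 is all remaining genes. Matching is
#' case-insensitive; a variant without a gene symbol gets tier 4 with a
#' warning.
#'
#' @param variants data frame with a `gene` column.
#' @param list1,list2,list3 character vectors of gene symbols.
#' @return `variants` with an integer `tier` column.
#' @export
assign_tiers <- function(variants, list1, list2 = character(),
                         list3 = character()) {
  lists <- lapply(list(list1, list2, list3), toupper)
  gene <- toupper(variants$gene)
  tier <- rep(4L, nrow(variants))
  for (t in 3:1) tier[gene %in% lists[[t]]] <- t
  if (any(is.na(variants$gene) | variants$gene == "")) {
    warnf("variant(s) without gene symbol assigned tier 4")
    tier[is.na(variants$gene) | variants$gene == ""] <- 4L
  }
  variants$tier <- tier
  variants
}
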