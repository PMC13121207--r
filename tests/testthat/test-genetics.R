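test_that("ROH extends greedily from the focal call with het allowance", {
  gm <- gm_from(P = c(2L, 2L, 0L, 2L, 1L, 2L))
  seg <- detect_roh(gm, "P", focal_pos = 400)
  expect_equal(c(seg$start, seg$end), c(100, 400))
  expect_equal(seg$n_markers, 4)
  expect_equal(seg$het_interruptions, 0)

  seg1 <- detect_roh(gm, "P", focal_pos = 400, max_het = 1)
  expect_equal(c(seg1$start, seg1$end), c(100, 600))
  expect_equal(seg1$het_interruptions, 1)

  all_hom <- gm_from(P = c(0L, 2L, 2L, 0L))
  seg2 <- detect_roh(all_hom, "P", focal_pos = 200)
  expect_equal(c(seg2$start, seg2$end), c(100, 400))

  # a trailing het never becomes a boundary
  trail <- gm_from(P = c(2L, 2L, 1L))
  seg3 <- detect_roh(trail, "P", focal_pos = 100, max_het = 5)
  expect_equal(seg3$end, 200)

  het_focal <- gm_from(P = c(2L, 1L, 2L))
  expect_error(detect_roh(het_focal, "P", focal_pos = 200), "heterozygous")
})

test_that("raising the het allowance never shrinks an ROH", {
  set.seed(21)
  for (i in 1:20) {
    calls <- sample(c(0L, 1L, 2L, NA), 60, replace = TRUE,
                    prob = c(0.4, 0.2, 0.35, 0.05))
    focal <- sample(which(!is.na(calls) & calls != 1), 1)
    gm <- gm_from(P = calls)
    prev <- NULL
    for (mh in 0:3) {
      seg <- detect_roh(gm, "P", focal_pos = focal * 100, max_het = mh)
      expect_true(seg$start <= focal * 100 && seg$end >= focal * 100)
      if (!is.null(prev)) {
        expect_lte(seg$start, prev$start)
        expect_gte(seg$end, prev$end)
      }
      prev <- seg
    }
  }
})

test_that("the minimal shared region is the intersection of the segments", {
  seg <- function(s, e) structure(list(chrom = "chr1", start = s, end = e),
                                  class = "roh_segment")
  expect_equal(minimal_shared_region(list(seg(100, 900), seg(200, 700))),
               list(chrom = "chr1", start = 200, end = 700))
  expect_equal(minimal_shared_region(list(seg(100, 900))),
               list(chrom = "chr1", start = 100, end = 900))
  expect_equal(minimal_shared_region(list(seg(1, 1000), seg(50, 500),
                                          seg(100, 300)))[c("start", "end")],
               list(start = 100, end = 300))
  expect_error(minimal_shared_region(list(seg(1, 10), seg(20, 30))), "disjoint")
})

test_that("haplotype matrix applies the strict GQ and called-in-all filters", {
  gq <- cbind(P1 = c(99, 35, 99, 36, 99), P2 = c(99, 99, 99, 99, 99))
  gm <- gm_from(P1 = c(2L, 2L, NA, 2L, 2L), P2 = c(2L, 2L, 2L, 2L, 2L),
                gq = gq)
  hm <- haplotype_matrix(gm, list(chrom = "chr1", start = 100, end = 500),
                         c("P1", "P2"), gq_min = 35, focal_pos = 100)
  # marker 2 dropped by GQ == 35 (strict >), marker 3 by missing call
  expect_equal(unname(hm$funnel),
               c(5, 1, 1, 3))
  expect_equal(as.integer(rownames(hm$states)), c(100, 400, 500))
  expect_equal(sum(hm$funnel[c("dropped_by_call", "dropped_by_gq", "kept")]),
               unname(hm$funnel["total"]))
})

test_that("the concordant sub-interval stops where carriers diverge", {
  gm <- gm_from(A = c(2L, 2L, 2L, 2L, 2L), B = c(0L, 2L, 2L, 2L, 2L))
  hm <- haplotype_matrix(gm, list(chrom = "chr1", start = 100, end = 500),
                         c("A", "B"), gq_min = 0, carriers = c("A", "B"),
                         focal_pos = 300)
  expect_equal(hm$concordant$start, 200)
  expect_equal(hm$concordant$end, 500)

  same <- gm_from(A = rep(2L, 5), B = rep(2L, 5))
  hm2 <- haplotype_matrix(same, list(chrom = "chr1", start = 100, end = 500),
                          c("A", "B"), gq_min = 0, focal_pos = 300)
  expect_equal(c(hm2$concordant$start, hm2$concordant$end), c(100, 500))
})

test_that("relatedness scores identical, related and unrelated pairs sensibly", {
  n <- 300
  set.seed(13)
  g <- sample(c(0L, 1L, 2L), n, replace = TRUE)
  gm <- gm_from(A = g, B = g)
  got <- relatedness(gm, "A", "B")
  expect_equal(got$score, 1.0)
  expect_false(got$unrelated)

  # 1 shared het + 10 opposite homozygotes, one het each -> (1 - 20)/1
  a <- c(1L, rep(0L, 10), rep(2L, 250))
  b <- c(1L, rep(2L, 10), rep(2L, 250))
  gm2 <- gm_from(A = a, B = b)
  expect_equal(relatedness(gm2, "A", "B", min_markers = 100)$score, -19)

  nohet <- gm_from(A = rep(0L, 250), B = rep(2L, 250))
  expect_error(relatedness(gm2, "A", "B", min_markers = 500), "overlapping")
  expect_error(relatedness(nohet, "A", "B", min_markers = 100), "undefined")

  # unrelated pair drawn from Hardy-Weinberg frequencies
  set.seed(2)
  p <- runif(2000, 0.1, 0.5)
  gm3 <- gm_from(A = rbinom(2000, 2, p), B = rbinom(2000, 2, p))
  expect_true(relatedness(gm3, "A", "B")$unrelated)
})

test_that("variant prioritisation applies the strict MAF/delta boundaries", {
  vs <- simulate_variant_table(n_decoys = 0)
  mk <- function(maf, delta, gt = c(1, 1, 2), gene = "GENEX") {
    v <- vs$variants[1, ]
    v$id <- "v"; v$gene <- gene; v$maf <- maf; v$ds_dg <- delta
    v$father <- gt[1]; v$mother <- gt[2]; v$proband <- gt[3]
    v
  }
  ped <- vs$pedigree
  expect_equal(nrow(prioritise_variants(mk(0, 0.10), ped)), 1)   # inclusive >=
  expect_equal(nrow(prioritise_variants(mk(0, 0.09), ped)), 0)
  expect_equal(nrow(prioritise_variants(mk(0.0099, 0.42), ped)), 1)
  expect_equal(nrow(prioritise_variants(mk(0.01, 0.42), ped)), 0)  # strict <
  expect_equal(nrow(prioritise_variants(mk(0.02, 0.42), ped)), 0)

  # recessive segregation: proband must be hom-alt, parents het
  expect_equal(nrow(prioritise_variants(mk(0, 0.42, c(1, 1, 1)), ped)), 0)
  expect_equal(nrow(prioritise_variants(mk(0, 0.42, c(0, 1, 2)), ped)), 0)

  # a missing parental genotype degrades to a flag, never a silent drop
  got <- prioritise_variants(mk(0, 0.42, c(NA, 1, 2)), ped)
  expect_equal(nrow(got), 1)
  expect_identical(got$segregation, "unknown")

  expect_error(prioritise_variants(mk(0, 0.42), ped, mode = "dominant"),
               "unknown mode")
})

test_that("the planted causal variant is the unique survivor among decoys", {
  vs <- simulate_variant_table(n_decoys = 9)
  got <- prioritise_variants(vs$variants, vs$pedigree, "recessive_hom")
  expect_identical(got$id, "causal")
  expect_equal(got$max_delta, 0.42)
  # idempotent and order-independent
  again <- prioritise_variants(got, vs$pedigree, "recessive_hom")
  expect_identical(again$id, "causal")
  shuf <- vs$variants[sample(nrow(vs$variants)), ]
  expect_identical(prioritise_variants(shuf, vs$pedigree, "recessive_hom")$id,
                   "causal")
})

test_that("compound-heterozygous mode needs one retained variant per parent", {
  vs <- simulate_variant_table(n_decoys = 0)
  ped <- vs$pedigree
  two <- rbind(vs$variants[1, ], vs$variants[1, ])
  two$id <- c("vA", "vB"); two$pos <- c(100, 200); two$gene <- "G1"
  two$proband <- 1
  two$father <- c(1, 0); two$mother <- c(0, 1)
  got <- prioritise_variants(two, ped, mode = "comp_het")
  expect_setequal(got$id, c("vA", "vB"))

  # both inherited from the same parent: not compound het
  same_parent <- two
  same_parent$father <- c(1, 1); same_parent$mother <- 0
  expect_equal(nrow(prioritise_variants(same_parent, ped, "comp_het")), 0)

  # a lone variant in a gene cannot be compound het
  expect_equal(nrow(prioritise_variants(two[1, ], ped, "comp_het")), 0)
})

test_that("outlier proximity uses an inclusive 250-bp window", {
  vars <- data.frame(chrom = "chr17",
                     pos = c(47974691, 47974938, 47974939, 47980000),
                     stringsAsFactors = FALSE)
  outs <- data.frame(chrom = "chr17", start = 47974600, end = 47974688)
  got <- outlier_proximity(vars, outs, window = 250)
  expect_equal(got$outlier_distance, c(3, 250, 251, 5312))
  expect_identical(got$outlier_proximal, c(TRUE, TRUE, FALSE, FALSE))

  none <- outlier_proximity(vars, outs[0, ])
  expect_false(any(none$outlier_proximal))
  expect_true(all(is.na(none$outlier_distance)))

  other_chrom <- outlier_proximity(vars,
                                   data.frame(chrom = "chr1", start = 1,
                                              end = 1e9))
  expect_false(any(other_chrom$outlier_proximal))
})

test_that("gene-list tiers follow first-match precedence, case-insensitively", {
  vars <- data.frame(gene = c("CDK5RAP3", "cdk5rap3", "TTN", "NOVEL", ""),
                     stringsAsFactors = FALSE)
  got <- suppressWarnings(
    assign_tiers(vars, list1 = c("CDK5RAP3"), list2 = c("CDK5RAP3", "TTN")))
  expect_equal(got$tier, c(1L, 1L, 2L, 4L, 4L))
  expect_warning(assign_tiers(vars, list1 = "X"), "without gene symbol")
})
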