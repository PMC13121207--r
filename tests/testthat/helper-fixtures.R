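# Fixture builders shared across the suite. Everything is generated in code;
# no binary files.

# a tiny four-arm design: 2 genotypes x 2 ASO treatments x n replicates
tiny_design <- function(n_rep = 2) {
  arms <- expand.grid(genotype = c("proband", "control"),
                      treatment = c("ASO_S", "ASO_T"),
                      stringsAsFactors = FALSE)
  des <- arms[rep(seq_len(4), each = n_rep), ]
  des$replicate <- rep(seq_len(n_rep), 4)
  des$sample <- sprintf("%s%s%d",
                        ifelse(des$genotype == "proband", "P", "C"),
                        ifelse(des$treatment == "ASO_S", "S", "T"),
                        des$replicate)
  rownames(des) <- NULL
  sample_design(des[c("sample", "genotype", "treatment", "replicate")])
}

# abundance matrix with per-arm means given as a features x 4 matrix
# (columns PS, PT, CS, CT), zero noise unless sd > 0
tiny_table <- function(arm_means, n_rep = 2, sd = 0, seed = 1) {
  des <- tiny_design(n_rep)
  key <- paste0(ifelse(des$genotype == "proband", "P", "C"),
                ifelse(des$treatment == "ASO_S", "S", "T"))
  set.seed(seed)
  vals <- sapply(seq_len(nrow(des)), function(j) {
    arm_means[, key[j]] + if (sd > 0) rnorm(nrow(arm_means), 0, sd) else 0
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(arm_means))
  if (is.null(rownames(arm_means))) {
    rownames(arm_means) <- sprintf("f%d", seq_len(nrow(arm_means)))
  }
  dimnames(vals) <- list(rownames(arm_means), des$sample)
  list(table = abundance_table(vals), design = des)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal VCF with GT:GQ genotypes; `geno` is a data frame with chrom, pos,
# ref, alt and one "GT:GQ" string column per individual
write_vcf <- function(geno, path) {
  inds <- setdiff(names(geno), c("chrom", "pos", "ref", "alt"))
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", inds), collapse = "\t"))
  body <- vapply(seq_len(nrow(geno)), function(i) {
    paste(c(geno$chrom[i], geno$pos[i], ".", geno$ref[i], geno$alt[i], ".",
            "PASS", ".", "GT:GQ", unlist(geno[i, inds])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

write_ped <- function(ids, fathers, mothers, affected, path, family = "FAM") {
  df <- data.frame(family = family, id = ids,
                   father = ifelse(is.na(fathers), "0", fathers),
                   mother = ifelse(is.na(mothers), "0", mothers),
                   sex = 1, affected = ifelse(affected == "yes", 2, 1))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# genotype matrix straight from vectors, one chromosome, positions 100,200,...
gm_from <- function(..., gq = NULL, chrom = "chr1") {
  cols <- list(...)
  geno <- do.call(cbind, cols)
  n <- nrow(geno)
  if (is.null(gq)) gq <- matrix(99, n, ncol(geno), dimnames = dimnames(geno))
  markers <- data.frame(chrom = chrom, pos = seq_len(n) * 100,
                        ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(markers, geno, gq)
}

# independent Benjamini-Hochberg step-up: sort, scale, cumulative min from
# the largest rank (oracle; intentionally naive)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m / seq_len(m) * p[o]
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# hypergeometric upper tail by exact combinatorial summation (oracle)
hyper_brute <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
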