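# Readers, validators and writers for every external table the pipeline
# touches. Coordinates are 1-based inclusive throughout (VCF convention);
# abundance matrices are log2-scale with missing values allowed.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Construct and validate an abundance table
#'
#' An abundance table is a numeric matrix of log2 intensities with unique
#' feature row names (protein accessions or `GENE_SiteResiduePosition`
#' phosphosite ids such as `UFL1_S462`) and unique sample column names.
#' Missing values are allowed; present values must be finite.
#'
#' @param values numeric matrix with rownames (features) and colnames
#'   (samples).
#' @return the validated matrix with class `abundance_table`.
#' @export
abundance_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("abundance values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("abundance matrix needs feature rownames and sample colnames")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) abort("duplicated feature id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) abort("duplicated sample id(s): %s", paste(unique(dup), collapse = ", "))
  if (any(is.infinite(values))) abort("abundance values must be finite where present")
  structure(values, class = c("abundance_table", class(values)))
}

#' Construct and validate a sample design table
#'
#' @param df data frame with columns `sample`, `genotype`
#'   (`proband`/`control`), `treatment` (`ASO_S`/`ASO_T`/`untreated`) and
#'   `replicate`; an optional `batch` column is kept if present.
#' @return validated data frame with class `sample_design`.
#' @export
sample_design <- function(df) {
  need <- c("sample", "genotype", "treatment", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("design is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample)) {
    abort("duplicated sample(s) in design: %s",
          paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$genotype), c("proband", "control"))
  if (length(bad)) abort("unknown genotype value(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$treatment), c("ASO_S", "ASO_T", "untreated"))
  if (length(bad)) abort("unknown treatment value(s): %s", paste(bad, collapse = ", "))
  if (any(!is.finite(df$replicate)) || any(df$replicate < 1)) {
    abort("replicate must be a positive integer")
  }
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Read an abundance matrix together with its sample design
#'
#' The matrix file is delimited text whose first column holds feature ids and
#' whose remaining columns are samples; the design file maps each sample to a
#' genotype, treatment and replicate. Every sample present in the matrix must
#' appear in the design.
#'
#' @param path path to the matrix file (TSV, or CSV by extension).
#' @param design_path path to the design file.
#' @param log2_transform if `TRUE` the matrix is on raw intensity scale and is
#'   log2-transformed on read (zeros and negatives become missing).
#' @return list with elements `table` (an [abundance_table()]) and `design`
#'   (a [sample_design()]), design rows ordered to match the matrix columns.
#' @export
read_abundance <- function(path, design_path, log2_transform = FALSE) {
  raw <- utils::read.delim(path, sep = delim_for(path), check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) abort("abundance file needs a feature column plus samples")
  ids <- as.character(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) abort("duplicated feature id(s): %s", paste(dup, collapse = ", "))
  vals <- raw[-1]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & col != "" & is.na(num))
      if (length(bad)) {
        abort("non-numeric value '%s' at row %d (feature %s), column %s",
              col[bad[1]], bad[1], ids[bad[1]], names(vals)[j])
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (log2_transform) {
    m[!is.na(m) & m <= 0] <- NA
    m <- log2(m)
  }
  des <- utils::read.delim(design_path, sep = delim_for(design_path),
                           stringsAsFactors = FALSE)
  des <- sample_design(des)
  missing_samples <- setdiff(colnames(m), des$sample)
  if (length(missing_samples)) {
    abort("sample(s) in matrix but absent from design: %s",
          paste(missing_samples, collapse = ", "))
  }
  des <- des[match(colnames(m), des$sample), , drop = FALSE]
  rownames(des) <- NULL
  list(table = abundance_table(m), design = sample_design(des))
}

#' Read a GMT gene-set collection
#'
#' Each line is `term<TAB>description<TAB>member1<TAB>member2...`. Duplicate
#' members within a term are collapsed with a warning; terms with no members
#' are rejected with a warning.
#'
#' @param path path to a GMT file.
#' @return named list of terms; each element is a list with `description` and
#'   `members` (unique character vector). Class `gene_set_collection`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) abort("unreadable GMT line %d", i)
    term <- parts[1]
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) {
      warnf("GMT term '%s' (line %d) has no members; skipped", term, i)
      next
    }
    if (anyDuplicated(members)) {
      warnf("GMT term '%s' has duplicated members; collapsed", term)
      members <- unique(members)
    }
    out[[term]] <- list(description = parts[2], members = members)
  }
  structure(out, class = "gene_set_collection")
}

gt_to_count <- function(gt) {
  gt <- sub(":.*", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  ifelse(gt %in% c("0/0"), 0L,
         ifelse(gt %in% c("0/1", "1/0"), 1L,
                ifelse(gt == "1/1", 2L, NA_integer_)))
}

#' Construct a genotype matrix object
#'
#' @param markers data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, strictly increasing by (chrom, pos), biallelic only.
#' @param geno integer matrix (markers x individuals) of alternate-allele
#'   counts in 0/1/2 with `NA` for missing.
#' @param gq numeric matrix of genotype qualities, same shape as `geno`.
#' @return list with class `genotype_matrix`.
#' @export
genotype_matrix <- function(markers, geno, gq) {
  stopifnot(nrow(markers) == nrow(geno), all(dim(geno) == dim(gq)))
  ord <- order(markers$chrom, markers$pos)
  if (any(ord != seq_len(nrow(markers)))) abort("markers must be sorted by (chrom, pos)")
  if (anyDuplicated(markers[c("chrom", "pos")])) abort("duplicated marker positions")
  if (any(!geno[!is.na(geno)] %in% 0:2)) abort("allele counts must be 0, 1 or 2")
  if (any(gq[!is.na(gq)] < 0)) abort("GQ must be non-negative")
  structure(list(markers = markers, geno = geno, gq = gq),
            class = "genotype_matrix")
}

#' Read a pedigree file
#'
#' PED-like, six whitespace- or tab-separated columns: family, individual id,
#' father id, mother id, sex, affected status (`1` unaffected / `2` affected /
#' `0` unknown, or the words `yes`/`no`/`unknown`). `0` or `.` mean "no
#' parent".
#'
#' @param path path to the pedigree file.
#' @return data frame with columns `family`, `id`, `father`, `mother`, `sex`,
#'   `affected` (one of `"yes"`, `"no"`, `"unknown"`), class `pedigree`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "affected"))
  ped$father[ped$father %in% c("0", ".", "")] <- NA
  ped$mother[ped$mother %in% c("0", ".", "")] <- NA
  aff <- as.character(ped$affected)
  ped$affected <- ifelse(aff %in% c("2", "yes"), "yes",
                         ifelse(aff %in% c("1", "no"), "no", "unknown"))
  for (col in c("father", "mother")) {
    ref <- ped[[col]]
    bad <- setdiff(ref[!is.na(ref)], ped$id)
    if (length(bad)) abort("pedigree %s id(s) not in file: %s", col,
                           paste(bad, collapse = ", "))
  }
  # no individual may be its own ancestor
  for (id in ped$id) {
    seen <- character(); frontier <- id
    while (length(frontier)) {
      rows <- ped[ped$id %in% frontier, , drop = FALSE]
      frontier <- stats::na.omit(c(rows$father, rows$mother))
      if (id %in% frontier) abort("pedigree cycle involving '%s'", id)
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
    }
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read genotypes from VCF or a genotype-matrix TSV
#'
#' VCF input uses the `GT` and `GQ` FORMAT fields (via the vcfR package);
#' multiallelic records are skipped with a logged count. The TSV dialect has
#' columns `chrom`, `pos`, `ref`, `alt` followed by one `GT:GQ` column per
#' individual. Every individual in the genotype file must appear in the
#' pedigree.
#'
#' @param path VCF (`.vcf`) or TSV path.
#' @param pedigree_path path to the pedigree file (see [read_pedigree()]).
#' @return list with `genotypes` (a [genotype_matrix()]) and `pedigree`.
#' @export
read_genotypes <- function(path, pedigree_path) {
  ped <- read_pedigree(pedigree_path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT, fixed = TRUE)
    if (any(multi)) {
      log_msg("INFO", "skipped %d multiallelic record(s)", sum(multi))
      vcf <- vcf[!multi, ]
      fix <- fix[!multi, , drop = FALSE]
    }
    markers <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT,
                          stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
    geno <- apply(gt, 2, gt_to_count)
    if (is.null(dim(geno))) geno <- matrix(geno, nrow = nrow(markers),
                                           dimnames = dimnames(gt))
    gq[is.na(gq)] <- 0
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(tab))) {
      abort("genotype TSV needs columns: %s", paste(need, collapse = ", "))
    }
    multi <- grepl(",", tab$alt, fixed = TRUE)
    if (any(multi)) {
      log_msg("INFO", "skipped %d multiallelic record(s)", sum(multi))
      tab <- tab[!multi, , drop = FALSE]
    }
    markers <- data.frame(chrom = tab$chrom, pos = as.integer(tab$pos),
                          ref = tab$ref, alt = tab$alt, stringsAsFactors = FALSE)
    inds <- setdiff(names(tab), need)
    geno <- sapply(inds, function(i) gt_to_count(tab[[i]]))
    gq <- sapply(inds, function(i) {
      q <- suppressWarnings(as.numeric(sub(".*:", "", tab[[i]])))
      ifelse(is.na(q), 0, q)
    })
    if (is.null(dim(geno))) {
      geno <- matrix(geno, nrow = nrow(markers), dimnames = list(NULL, inds))
      gq <- matrix(gq, nrow = nrow(markers), dimnames = list(NULL, inds))
    }
  }
  extra <- setdiff(colnames(geno), ped$id)
  if (length(extra)) {
    abort("individual(s) in genotype file absent from pedigree: %s",
          paste(extra, collapse = ", "))
  }
  gm <- genotype_matrix(markers, geno, gq)
  list(genotypes = gm, pedigree = ped)
}

#' Read a qPCR Ct table
#'
#' Long format with columns `sample`, `assay`, `role` (`target` or
#' `reference`), `rep` (technical replicate index), `ct` (cycles, `> 0`) and
#' `group` (`proband`/`control`); an optional `treatment` column is kept.
#' Every sample must be measured for every reference assay.
#'
#' @param path path to the Ct file.
#' @return data frame with class `ct_table`.
#' @export
read_ct <- function(path) {
  ct <- utils::read.delim(path, sep = delim_for(path), stringsAsFactors = FALSE)
  need <- c("sample", "assay", "role", "rep", "ct", "group")
  miss <- setdiff(need, names(ct))
  if (length(miss)) abort("Ct table is missing column(s): %s", paste(miss, collapse = ", "))
  validate_ct(ct)
}

validate_ct <- function(ct) {
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) abort("Ct values must be > 0")
  bad <- setdiff(unique(ct$role), c("target", "reference"))
  if (length(bad)) abort("unknown assay role(s): %s", paste(bad, collapse = ", "))
  refs <- unique(ct$assay[ct$role == "reference"])
  for (s in unique(ct$sample)) {
    have <- unique(ct$assay[ct$sample == s & ct$role == "reference"])
    missing_refs <- setdiff(refs, have)
    if (length(missing_refs)) {
      abort("sample '%s' is missing reference assay '%s'", s, missing_refs[1])
    }
  }
  class(ct) <- c("ct_table", "data.frame")
  ct
}

#' Read splice-outlier intervals
#'
#' Delimited text with columns `chrom`, `start`, `end` (1-based inclusive)
#' and optionally `kind` and `score`.
#'
#' @param path path to the interval table.
#' @return data frame with class `outlier_intervals`.
#' @export
read_outliers <- function(path) {
  x <- utils::read.delim(path, sep = delim_for(path), stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss)) abort("outlier table is missing column(s): %s", paste(miss, collapse = ", "))
  if (any(x$start > x$end)) abort("outlier intervals must have start <= end")
  class(x) <- c("outlier_intervals", "data.frame")
  x
}

#' Write a result table as byte-stable TSV
#'
#' Rows are sorted by all columns, numeric columns are formatted with six
#' significant digits, and a header line is always written, so identical
#' inputs produce identical files.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  x <- as.data.frame(x)
  if (nrow(x)) {
    x <- x[do.call(order, unname(as.list(x))), , drop = FALSE]
  }
  for (j in seq_along(x)) {
    if (is.numeric(x[[j]]) && !is.integer(x[[j]])) {
      x[[j]] <- ifelse(is.na(x[[j]]), NA, formatC(signif(x[[j]], 6),
                                                  format = "g", digits = 6))
    }
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
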