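# Over-representation analysis with RichFactor/InTerm reporting, and
# KSEA-style inferred kinase activity from phosphosite log2 fold-changes.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least `k` members of a size-`K` term in a size-`n` selection from a
#' universe of `N`.
#'
#' @param k observed overlap.
#' @param K term size within the universe.
#' @param n selection size.
#' @param N universe size.
#' @return upper-tail probability in `(0, 1]`.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(k < 0) || any(k > pmin(K, n)) || any(K > N) || any(n > N)) {
    abort("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a feature selection
#'
#' One row per term overlapping the selection, with the InTerm count `k`
#' (selected features in the term), term size `K` (term members in the
#' universe), `RichFactor = k / K`, hypergeometric upper-tail p and BH q
#' across the tested terms. Terms are intersected with the universe before
#' `K` is computed; terms disjoint from the selection are not reported.
#'
#' @param selection character vector of selected features (must lie in
#'   `universe`).
#' @param gene_sets a [read_gene_sets()] collection (or named list of
#'   character vectors).
#' @param universe character vector: all features that could have been
#'   selected.
#' @return data frame `term`, `description`, `InTerm`, `K`, `n`, `N`,
#'   `RichFactor`, `p`, `q`, ordered by p.
#' @export
ora <- function(selection, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) abort("empty universe")
  selection <- unique(selection)
  outside <- setdiff(selection, universe)
  if (length(outside)) {
    abort("selection member(s) outside universe: %s",
          paste(utils::head(outside, 10), collapse = ", "))
  }
  N <- length(universe)
  n <- length(selection)
  rows <- lapply(names(gene_sets), function(term) {
    gs <- gene_sets[[term]]
    members <- if (is.list(gs)) gs$members else gs
    desc <- if (is.list(gs) && !is.null(gs$description)) gs$description else ""
    members <- intersect(members, universe)
    K <- length(members)
    k <- length(intersect(members, selection))
    if (k < 1) return(NULL)
    data.frame(term = term, description = desc, InTerm = k, K = K, n = n,
               N = N, RichFactor = k / K,
               p = hypergeom_upper(k, K, n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), description = character(),
                      InTerm = integer(), K = integer(), n = integer(),
                      N = integer(), RichFactor = numeric(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  out$q <- bh_adjust(out$p)
  out[order(out$p, out$term), , drop = FALSE]
}

#' KSEA-style inferred kinase activity
#'
#' For each kinase with at least `m_min` annotated substrate sites present in
#' the fold-change vector, the activity score is
#' `z = (mean(substrate lfc) - mean(all lfc)) * sqrt(m) / sd(all lfc)`.
#' Significance comes from a two-sided permutation test drawing `n_perm`
#' random size-`m` site sets, with add-one correction
#' `p = (b + 1) / (n_perm + 1)`. This is an approximation of published
#' kinase-substrate enrichment scoring, not a reimplementation of any
#' specific tool.
#'
#' @param site_lfc named numeric vector of phosphosite log2 fold-changes
#'   (names are site ids such as `UFL1_S462`).
#' @param kinase_map data frame with columns `kinase` and `site`.
#' @param m_min minimum substrate count (kinases below it are skipped with a
#'   warning).
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation draws (deterministic given seed).
#' @return data frame `kinase`, `m`, `z`, `p`, `direction` (`up`/`down`),
#'   ordered by p then |z| descending.
#' @export
kinase_activity <- function(site_lfc, kinase_map, m_min = 3, n_perm = 1e4,
                            seed = 1) {
  stopifnot(all(c("kinase", "site") %in% names(kinase_map)))
  absent <- setdiff(unique(kinase_map$site), names(site_lfc))
  if (length(absent)) {
    warnf("%d mapped substrate site(s) absent from fold-changes; dropped",
          length(absent))
    kinase_map <- kinase_map[kinase_map$site %in% names(site_lfc), , drop = FALSE]
  }
  lfc <- site_lfc[!is.na(site_lfc)]
  mu <- mean(lfc)
  sdv <- stats::sd(lfc)
  ksea_z <- function(sites) {
    s <- intersect(sites, names(lfc))
    (mean(lfc[s]) - mu) * sqrt(length(s)) / sdv
  }
  kinases <- split(kinase_map$site, kinase_map$kinase)
  kinases <- lapply(kinases, function(s) intersect(unique(s), names(lfc)))
  small <- names(kinases)[lengths(kinases) < m_min]
  if (length(small)) {
    warnf("kinase(s) with fewer than %d mapped sites skipped: %s", m_min,
          paste(small, collapse = ", "))
    kinases <- kinases[lengths(kinases) >= m_min]
  }
  if (!length(kinases)) {
    return(data.frame(kinase = character(), m = integer(), z = numeric(),
                      p = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    rows <- lapply(names(kinases), function(kin) {
      m <- length(kinases[[kin]])
      z_obs <- ksea_z(kinases[[kin]])
      z_perm <- replicate(n_perm, {
        s <- sample(names(lfc), m)
        (mean(lfc[s]) - mu) * sqrt(m) / sdv
      })
      b <- sum(abs(z_perm) >= abs(z_obs))
      data.frame(kinase = kin, m = m, z = z_obs,
                 p = (b + 1) / (n_perm + 1),
                 direction = if (z_obs >= 0) "up" else "down",
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[order(out$p, -abs(out$z)), , drop = FALSE]
  })
}
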