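#' Median-of-ratios size factors
#'
#' Per-well scaling factors computed as the median, over genes, of the
#' ratio of a well's count to the gene's geometric mean across wells,
#' normalized so the factors themselves have geometric mean 1. Only genes
#' with nonzero counts in every well enter the reference; if no such gene
#' exists the reference falls back to geometric means over each gene's
#' positive counts, with a warning.
#'
#' @param counts nonnegative integer matrix, genes x wells.
#' @return numeric vector of size factors, one per well.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  lc <- log(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    ref <- rowMeans(lc[all_pos, , drop = FALSE])
    lr <- lc[all_pos, , drop = FALSE] - ref
  } else {
    warning("no gene has nonzero counts in all wells; ",
            "using positive-count geometric means", call. = FALSE)
    ref <- apply(lc, 1, function(v) mean(v[is.finite(v)]))
    keep <- is.finite(ref)
    lr <- lc[keep, , drop = FALSE] - ref[keep]
  }
  f <- apply(lr, 2, function(v) stats::median(v[is.finite(v)]))
  sf <- exp(f - mean(f))
  names(sf) <- colnames(counts)
  sf
}

#' Negative-binomial Wald test of one compound against DMSO
#'
#' Per-gene differential-expression test on size-factor-normalized counts.
#' The gene-wise dispersion is a pooled method-of-moments estimate
#' `(var_within - mean) / mean^2` floored at 1e-8; the log2 fold-change is
#' the ratio of normalized group means with a pseudocount; the Wald
#' statistic `log(mu1/mu2) / SE`, with
#' `SE^2 = (1/mu1 + a)/n1 + (1/mu2 + a)/n2`, is referred to a t
#' distribution on `n1 + n2 - 2` degrees of freedom (the dispersion is
#' estimated from those same wells, and a normal reference is
#' anticonservative at plate-scale replication). Genes with all-zero
#' counts get p = 1 and log2FC = 0.
#'
#' @param counts genes x wells count matrix with column names.
#' @param compound_wells,dmso_wells disjoint character vectors of column
#'   names (>= 2 wells each).
#' @param sf optional precomputed size factors for all columns of
#'   `counts`; by default computed from the selected wells only.
#' @param pseudocount added to normalized group means for the fold-change
#'   and the Wald standard error.
#' @return data.frame with one row per gene: `gene`, `mean_expression`
#'   (pooled normalized mean), `log2_fold_change` (compound vs DMSO),
#'   `p_value`, `adjusted_p` (Benjamini-Hochberg).
#' @export
nb_test <- function(counts, compound_wells, dmso_wells, sf = NULL,
                    pseudocount = 0.5) {
  if (length(intersect(compound_wells, dmso_wells)) > 0L)
    stop("compound and DMSO well sets overlap", call. = FALSE)
  if (length(compound_wells) < 2L || length(dmso_wells) < 2L)
    stop("nb_test requires >= 2 wells per group", call. = FALSE)
  counts <- as.matrix(counts)
  sel <- c(compound_wells, dmso_wells)
  if (!all(sel %in% colnames(counts)))
    stop("unknown well(s): ",
         paste(setdiff(sel, colnames(counts)), collapse = ", "),
         call. = FALSE)
  if (is.null(sf)) {
    sf <- size_factors(counts[, sel, drop = FALSE])
  } else {
    sf <- sf[match(sel, colnames(counts))]
  }
  q <- sweep(counts[, sel, drop = FALSE], 2, sf, "/")
  n1 <- length(compound_wells); n2 <- length(dmso_wells)
  q1 <- q[, seq_len(n1), drop = FALSE]
  q2 <- q[, n1 + seq_len(n2), drop = FALSE]
  m1 <- rowMeans(q1); m2 <- rowMeans(q2)
  mbar <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ss <- rowSums((q1 - m1)^2) + rowSums((q2 - m2)^2)
  v_within <- ss / (n1 + n2 - 2)
  alpha <- pmax((v_within - mbar) / pmax(mbar, 1e-12)^2, 1e-8)
  lfc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  se2 <- (1 / (m1 + pseudocount) + alpha) / n1 +
    (1 / (m2 + pseudocount) + alpha) / n2
  w <- (log(m1 + pseudocount) - log(m2 + pseudocount)) / sqrt(se2)
  p <- 2 * stats::pt(-abs(w), df = n1 + n2 - 2)
  zero <- mbar == 0
  p[zero] <- 1
  lfc[zero] <- 0
  genes <- rownames(counts)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(counts)))
  data.frame(gene = genes,
             mean_expression = mbar,
             log2_fold_change = lfc,
             p_value = p,
             adjusted_p = bh_adjust(p),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: `p * n / rank`, made monotone
#' from the largest p downwards and capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * n / seq.int(n, 1)))
  adj[order(o)]
}

#' Count differentially expressed genes
#'
#' Number of genes passing `adjusted_p < padj_max` and
#' `|log2_fold_change| > lfc_min` (both strict).
#'
#' @param de data.frame from [nb_test()].
#' @param padj_max adjusted-p cutoff (default 0.1).
#' @param lfc_min absolute log2 fold-change cutoff (default 1).
#' @return integer DEG count.
#' @export
count_deg <- function(de, padj_max = 0.1, lfc_min = 1) {
  if (nrow(de) == 0L) return(0L)
  sum(de$adjusted_p < padj_max & abs(de$log2_fold_change) > lfc_min)
}

#' Empirical DMSO-vs-DMSO null of the DEG count
#'
#' Repeatedly splits the DMSO wells into two disjoint random groups of
#' `group_size`, runs [nb_test()] + [count_deg()] on each split, and
#' returns the null DEG counts with their 95th percentile (nearest-rank
#' convention). Deterministic given the seed.
#'
#' @param counts genes x wells count matrix.
#' @param dmso_wells character vector of DMSO column names (at least
#'   `2 * group_size`).
#' @param group_size wells per side of each split.
#' @param n_draws number of random splits.
#' @param seed integer seed.
#' @param sf optional precomputed size factors for `counts`.
#' @param padj_max,lfc_min DEG thresholds (see [count_deg()]).
#' @return list with `null_deg_counts`, `null_95th_percentile`,
#'   `group_size`, `n_draws`.
#' @export
dmso_null <- function(counts, dmso_wells, group_size, n_draws = 100,
                      seed = 1, sf = NULL, padj_max = 0.1, lfc_min = 1) {
  if (length(dmso_wells) < 2L * group_size)
    stop("need at least 2 * group_size DMSO wells", call. = FALSE)
  set.seed(seed)
  degs <- integer(n_draws)
  for (i in seq_len(n_draws)) {
    pick <- sample(dmso_wells, 2L * group_size)
    de <- nb_test(counts, pick[seq_len(group_size)],
                  pick[group_size + seq_len(group_size)], sf = sf)
    degs[i] <- count_deg(de, padj_max, lfc_min)
  }
  list(null_deg_counts = degs,
       null_95th_percentile = nearest_rank_percentile(degs, 0.95),
       group_size = group_size, n_draws = n_draws)
}

## nearest-rank percentile: value at rank ceiling(p * n) of the sorted data
nearest_rank_percentile <- function(x, p) {
  sort(x)[ceiling(p * length(x))]
}

#' Call a compound RNA-active
#'
#' A compound is RNA-active when its DEG count is strictly greater than the
#' 95th percentile of the DMSO-vs-DMSO null (more DEG than 95% of the null
#' comparisons).
#'
#' @param compound compound id.
#' @param deg_count the compound's DEG count.
#' @param null a [dmso_null()] result.
#' @return one-row data.frame: `compound`, `deg_count`,
#'   `null_95th_percentile`, `active`.
#' @export
call_rna_active <- function(compound, deg_count, null) {
  data.frame(compound = compound,
             deg_count = as.integer(deg_count),
             null_95th_percentile = null$null_95th_percentile,
             active = deg_count > null$null_95th_percentile,
             stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation of a gene set
#'
#' Upper-tail hypergeometric p-value of the overlap between a DEG set and
#' an annotated gene set within a gene universe.
#'
#' @param deg_genes,annotated_genes character vectors, subsets of
#'   `universe`.
#' @param universe character vector of all testable genes.
#' @return list with `p`, `overlap`, `n_deg`, `n_annotated`, `n_universe`.
#' @export
ora_enrichment <- function(deg_genes, annotated_genes, universe) {
  if (length(universe) == 0L)
    stop("empty gene universe", call. = FALSE)
  deg_genes <- unique(deg_genes)
  annotated_genes <- unique(annotated_genes)
  universe <- unique(universe)
  if (!all(deg_genes %in% universe) || !all(annotated_genes %in% universe))
    stop("gene sets must be subsets of the universe", call. = FALSE)
  k <- length(intersect(deg_genes, annotated_genes))
  p <- stats::phyper(k - 1, length(annotated_genes),
                     length(universe) - length(annotated_genes),
                     length(deg_genes), lower.tail = FALSE)
  list(p = p, overlap = k, n_deg = length(deg_genes),
       n_annotated = length(annotated_genes),
       n_universe = length(universe))
}

#' Full RNA-activity pipeline over a screen's count matrix
#'
#' Computes screen-wide size factors, builds the DMSO-vs-DMSO null of the
#' DEG count, tests every compound (all of its replicate wells against a
#' random draw of DMSO wells of matching size, per the study design), and
#' calls RNA-activity.
#'
#' @param counts genes x wells count matrix.
#' @param meta well metadata data.frame with columns `well`, `compound`,
#'   `role` (`"dmso"` or `"compound"`).
#' @param group_size wells per side of the null splits; defaults to the
#'   per-compound replicate count.
#' @param n_draws null splits (default 100).
#' @param seed integer seed for the null splits and DMSO draws.
#' @param padj_max,lfc_min DEG thresholds.
#' @return list with `calls` (per-compound data.frame), `null`, `de`
#'   (named list of per-compound [nb_test()] tables).
#' @export
rna_activity_pipeline <- function(counts, meta, group_size = NULL,
                                  n_draws = 100, seed = 1,
                                  padj_max = 0.1, lfc_min = 1) {
  counts <- as.matrix(counts)
  dmso_wells <- meta$well[meta$role == "dmso"]
  compounds <- sort(unique(meta$compound[meta$role == "compound"]))
  wells_of <- lapply(compounds,
                     function(cp) meta$well[!is.na(meta$compound) &
                                              meta$compound == cp])
  names(wells_of) <- compounds
  if (is.null(group_size))
    group_size <- max(2L, round(stats::median(lengths(wells_of))))
  sf <- size_factors(counts)
  null <- dmso_null(counts, dmso_wells, group_size, n_draws = n_draws,
                    seed = seed, sf = sf,
                    padj_max = padj_max, lfc_min = lfc_min)
  de <- list()
  calls <- list()
  for (cp in compounds) {
    cw <- wells_of[[cp]]
    ref <- sample(dmso_wells, min(length(cw), length(dmso_wells) - 1L))
    de[[cp]] <- nb_test(counts, cw, ref, sf = sf)
    calls[[cp]] <- call_rna_active(cp, count_deg(de[[cp]], padj_max,
                                                 lfc_min), null)
  }
  list(calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
       null = null, de = de, group_size = group_size,
       size_factors = sf)
}
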