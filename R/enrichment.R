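# Gene Ontology over-representation among top scan windows, with
# significance by resampling windows (not genes), which preserves the
# clustering of genes into windows.

#' Genes overlapping each window
#'
#' A gene is assigned to every window it overlaps by at least 1 bp.
#'
#' @param windows a [partition_windows()] table.
#' @param genes data.frame `chrom`, `start`, `end`, `gene` (1-based
#'   inclusive intervals).
#' @return list of character vectors, one per window.
#' @export
window_gene_sets <- function(windows, genes) {
  lapply(seq_len(nrow(windows)), function(i) {
    hit <- genes$chrom == windows$chrom[i] &
      genes$start <= windows$end[i] & genes$end >= windows$start[i]
    unique(genes$gene[hit])
  })
}

#' Read a two-column (term, gene) map into a term list
#' @param path tab-delimited file, one row per term-gene pair.
#' @return named list: term -> character vector of genes.
#' @export
read_term_map <- function(path) {
  tm <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  split(tm[[2]], tm[[1]])
}

#' GO over-representation by window resampling
#'
#' For each term, the observed statistic is the number of distinct genes
#' carrying the term among the top windows; the null draws the same
#' number of windows without replacement from all windows.  `p = (1 +
#' #\{null >= observed\}) / (1 + replicates)`; q-values are
#' Benjamini-Hochberg across the tested terms.
#'
#' @param top_windows indices of the top windows.
#' @param gene_sets [window_gene_sets()] output for ALL windows.
#' @param term_genes named list: term -> character vector of genes.
#' @param replicates resampling replicates.
#' @param seed RNG seed.
#' @return data.frame `term`, `observed`, `p`, `q`, `genes`.
#' @export
go_resampling_test <- function(top_windows, gene_sets, term_genes,
                               replicates = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(top_windows) > length(gene_sets))
    stop("more top windows than windows")
  n_term <- length(term_genes)
  if (n_term == 0) stop("no terms supplied")
  count_terms <- function(widx) {
    genes <- unique(unlist(gene_sets[widx]))
    vapply(term_genes, function(tg) sum(genes %in% tg), numeric(1))
  }
  obs <- count_terms(top_windows)
  ge <- numeric(n_term)
  for (r in seq_len(replicates)) {
    smp <- sample(seq_along(gene_sets), length(top_windows))
    ge <- ge + (count_terms(smp) >= obs)
  }
  p <- (1 + ge) / (1 + replicates)
  data.frame(term = names(term_genes), observed = obs, p = p,
             q = fdr_qvalues(p),
             genes = vapply(names(term_genes), function(tm) {
               g <- unique(unlist(gene_sets[top_windows]))
               paste(sort(g[g %in% term_genes[[tm]]]), collapse = ",")
             }, character(1)),
             row.names = NULL)
}
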