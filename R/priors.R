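#' Gene x regulator prior matrix
#'
#' Binary (or non-negatively weighted) membership matrix linking regulators
#' (transcription factors or pathways) to their target genes; the design
#' matrix of the activity regression.
#'
#' @param M gene x regulator matrix with unique row (gene) and column
#'   (regulator) names; entries `>= 0`.
#' @param kind `"tf"` or `"pathway"`.
#' @return Object of class `prior_mat`.
#' @export
prior_mat <- function(M, kind = c("tf", "pathway")) {
  kind <- match.arg(kind)
  M <- as_dense(M)
  if (is.null(rownames(M)) || is.null(colnames(M))) {
    stopf("prior matrix needs gene row names and regulator column names")
  }
  check_no_duplicates(rownames(M), "gene ids")
  check_no_duplicates(colnames(M), "regulator ids")
  if (any(M < 0)) stopf("prior entries must be non-negative")
  structure(list(M = M, kind = kind), class = "prior_mat")
}

#' @export
print.prior_mat <- function(x, ...) {
  cat(sprintf("<prior_mat> %d genes x %d %s regulators, %d nonzeros\n",
              nrow(x$M), ncol(x$M), x$kind, sum(x$M != 0)))
  invisible(x)
}

#' @export
dim.prior_mat <- function(x) dim(x$M)

#' TF prior matrix from a TF-target edge list
#'
#' Restricts candidate target genes to those expressed in more than
#' `min_gene_proportion` of spots, builds the binary gene x TF membership
#' matrix, and then alternately drops genes regulated by fewer than
#' `min_regulators_per_gene` TFs and TFs with fewer than
#' `min_genes_per_regulator` target genes until a joint fixed point. The
#' shipped defaults (0.1, 10, 5) are the standard TF-prior configuration.
#'
#' @param edges data frame with columns `regulator`, `target` (extra columns,
#'   e.g. a weight, are ignored unless `use_weights = TRUE`).
#' @param expr post-QC [expr_mat] defining the expressed-gene universe.
#' @param min_gene_proportion coverage threshold for candidate targets
#'   (strictly greater than; default 0.1).
#' @param min_regulators_per_gene minimum TFs per retained gene (default 10).
#' @param min_genes_per_regulator minimum target genes per retained TF
#'   (default 5).
#' @param use_weights keep the numeric `weight` column as matrix entries
#'   instead of a binary membership.
#' @return A [prior_mat] of kind `"tf"` with genes and regulators in sorted
#'   order.
#' @export
tf_prior <- function(edges, expr, min_gene_proportion = 0.1,
                     min_regulators_per_gene = 10, min_genes_per_regulator = 5,
                     use_weights = FALSE) {
  if (!all(c("regulator", "target") %in% names(edges))) {
    stopf("`edges` must have columns regulator, target")
  }
  expressed <- coverage_filter(expr, min_gene_proportion)
  edges <- edges[edges$target %in% expressed, , drop = FALSE]
  if (nrow(edges) == 0) {
    stopf("prior is empty after the expressed-gene (coverage %g) filter",
          min_gene_proportion)
  }
  genes <- sort(unique(edges$target))
  regs <- sort(unique(edges$regulator))
  M <- matrix(0, length(genes), length(regs), dimnames = list(genes, regs))
  w <- if (use_weights && "weight" %in% names(edges)) as.numeric(edges$weight) else 1
  M[cbind(match(edges$target, genes), match(edges$regulator, regs))] <- w
  M <- prune_prior(M, min_regulators_per_gene, min_genes_per_regulator)
  prior_mat(M, kind = "tf")
}

# Alternate gene-row / regulator-column pruning to a fixed point.
prune_prior <- function(M, min_regs_per_gene, min_genes_per_reg) {
  repeat {
    keep_g <- rowSums(M != 0) >= min_regs_per_gene
    if (!any(keep_g)) {
      stopf("prior emptied by the minimum-regulators-per-gene filter (%d)",
            min_regs_per_gene)
    }
    M <- M[keep_g, , drop = FALSE]
    keep_r <- colSums(M != 0) >= min_genes_per_reg
    if (!any(keep_r)) {
      stopf("prior emptied by the minimum-genes-per-regulator filter (%d)",
            min_genes_per_reg)
    }
    M <- M[, keep_r, drop = FALSE]
    if (all(keep_g) && all(keep_r)) return(M)
  }
}

#' Pathway prior matrix from gene sets
#'
#' Membership matrix over the genes that pass the 10% coverage filter and are
#' present in both the expression matrix and the gene-set collection; sets
#' falling below `min_genes_per_regulator` retained genes are dropped with a
#' warning. Unlike the TF prior, no minimum-regulators-per-gene rule is
#' applied.
#'
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()]).
#' @param expr post-QC [expr_mat].
#' @param min_genes_per_regulator minimum retained genes per set (default 5).
#' @param min_gene_proportion coverage threshold for the gene universe
#'   (default 0.10).
#' @return A [prior_mat] of kind `"pathway"`.
#' @export
pathway_prior <- function(gene_sets, expr, min_genes_per_regulator = 5,
                          min_gene_proportion = 0.10) {
  if (length(gene_sets) == 0 || is.null(names(gene_sets))) {
    stopf("`gene_sets` must be a non-empty named list")
  }
  expressed <- coverage_filter(expr, min_gene_proportion)
  gene_sets <- lapply(gene_sets, function(g) sort(unique(intersect(g, expressed))))
  sizes <- lengths(gene_sets)
  if (any(sizes < min_genes_per_regulator)) {
    warnf("dropping %d gene set(s) below %d retained genes",
          sum(sizes < min_genes_per_regulator), min_genes_per_regulator)
    gene_sets <- gene_sets[sizes >= min_genes_per_regulator]
  }
  if (length(gene_sets) == 0) stopf("prior is empty after the minimum-set-size filter")
  genes <- sort(unique(unlist(gene_sets)))
  regs <- sort(names(gene_sets))
  M <- matrix(0, length(genes), length(regs), dimnames = list(genes, regs))
  for (r in regs) M[gene_sets[[r]], r] <- 1
  prior_mat(M, kind = "pathway")
}
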