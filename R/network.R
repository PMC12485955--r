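#' Spearman's rank correlation
#'
#' Pearson correlation of midranks. Constant input yields 0 with a `"tie"`
#' attribute instead of `NA`.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return Correlation in `[-1, 1]`; attribute `"tie"` is `TRUE` when either
#'   vector is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (pop_sd(rx) == 0 || pop_sd(ry) == 0) {
    return(structure(0, tie = TRUE))
  }
  structure(stats::cor(rx, ry), tie = FALSE)
}

#' Spatial k-nearest-neighbor smoothing of expression
#'
#' Replaces each spot's expression by the unweighted mean over itself (when
#' `include_self`) and its `k` nearest spatial neighbors (Euclidean distance
#' on the coordinates). Distance ties are broken deterministically by spot id
#' order. `k = 6` matches the hexagonal Visium neighborhood.
#'
#' @param expr an [expr_mat].
#' @param positions data frame with `spot_id`, `x`, `y` covering the spots of
#'   `expr`.
#' @param k_neighbors number of neighbors (default 6; must be `< n_spots`).
#' @param include_self include the spot itself in the mean (default TRUE).
#' @return An [expr_mat] of smoothed values in the same layer.
#' @export
smooth_expression <- function(expr, positions, k_neighbors = 6,
                              include_self = TRUE) {
  stopifnot(inherits(expr, "expr_mat"))
  V <- as_dense(expr$values)
  n <- nrow(V)
  if (k_neighbors >= n) stopf("k_neighbors (%d) must be smaller than the number of spots (%d)",
                              k_neighbors, n)
  idx <- match(rownames(V), positions$spot_id)
  if (anyNA(idx)) stopf("positions are missing %d spot(s)", sum(is.na(idx)))
  xy <- cbind(as.numeric(positions$x[idx]), as.numeric(positions$y[idx]))
  if (k_neighbors == 0) {
    if (!include_self) stopf("k_neighbors = 0 with include_self = FALSE leaves nothing to average")
    return(structure(list(values = V, layer = expr$layer), class = "expr_mat"))
  }
  D <- as.matrix(stats::dist(xy))
  out <- matrix(0, n, ncol(V), dimnames = dimnames(V))
  ids <- rownames(V)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(D[i, others], ids[others])]
    nb <- ord[seq_len(k_neighbors)]
    sel <- if (include_self) c(i, nb) else nb
    out[i, ] <- colMeans(V[sel, , drop = FALSE])
  }
  structure(list(values = out, layer = expr$layer), class = "expr_mat")
}

#' Focal-regulator multi-layer association network
#'
#' Correlates one focal regulator's activity, per sample, with partner vectors
#' across six molecular layers: ligands (L) and receptors (R) — spatially
#' averaged expression of genes annotated in a ligand-receptor pair table;
#' target genes (TG) — spatially averaged expression of all genes passing the
#' coverage filter; pathways (P) and TFs (TF) — inferred activities; drugs
#' (D) — per-spot drug scores. Genes must be expressed in more than
#' `min_expr_fraction` of spots; the focal regulator is excluded from its own
#' TF layer; a (focal, partner, layer) triple is retained when `|rho| >=
#' retain_abs_rho` in at least one sample.
#'
#' @param focal regulator id; must be a row of every sample's `tf` (or
#'   `pathway`, if that is where it lives) activity matrix.
#' @param samples named list; each element a list with components
#'   `tf` (regulator x spot matrix containing the focal row), and optionally
#'   `pathway` (matrix), `expr` ([expr_mat], sqrt layer), `positions`
#'   (data frame), `drugs` (spot x drug matrix).
#' @param lr_pairs optional data frame `ligand_gene`, `receptor_gene`.
#' @param retain_abs_rho retention threshold (default 0.3).
#' @param min_expr_fraction coverage threshold for gene layers (default 0.05).
#' @param k_neighbors,include_self smoothing parameters passed to
#'   [smooth_expression()].
#' @return Long data frame `sample_id`, `focal_id`, `partner_id`, `layer`,
#'   `rho`, `tie`, `n_spots`, `retained`, sorted deterministically.
#' @export
focal_network <- function(focal, samples, lr_pairs = NULL,
                          retain_abs_rho = 0.3, min_expr_fraction = 0.05,
                          k_neighbors = 6, include_self = TRUE) {
  if (is.null(names(samples))) names(samples) <- paste0("sample", seq_along(samples))
  rows <- list()
  for (sn in names(samples)) {
    sm <- samples[[sn]]
    if (is.null(sm$tf) || !(focal %in% rownames(sm$tf))) {
      stopf("focal regulator '%s' absent from the activities of sample '%s'",
            focal, sn)
    }
    fvec <- sm$tf[focal, ]
    spots <- names(fvec) %||% colnames(sm$tf)
    add <- function(partner, layer, values) {
      rho <- spearman_rho(fvec, values)
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sn, focal_id = focal, partner_id = partner, layer = layer,
        rho = as.numeric(rho), tie = isTRUE(attr(rho, "tie")),
        n_spots = length(values), stringsAsFactors = FALSE)
    }
    # gene layers (L / R / TG) on spatially averaged expression
    if (!is.null(sm$expr)) {
      keep_genes <- coverage_filter(sm$expr, min_expr_fraction)
      sme <- smooth_expression(sm$expr, sm$positions, k_neighbors, include_self)
      Vs <- as_dense(sme$values)[spots, , drop = FALSE]
      for (g in intersect(keep_genes, colnames(Vs))) {
        add(g, "TG", Vs[, g])
      }
      if (!is.null(lr_pairs)) {
        lig <- intersect(unique(lr_pairs$ligand_gene), intersect(keep_genes, colnames(Vs)))
        rec <- intersect(unique(lr_pairs$receptor_gene), intersect(keep_genes, colnames(Vs)))
        for (g in lig) add(g, "L", Vs[, g])
        for (g in rec) add(g, "R", Vs[, g])
      }
    }
    # activity layers
    for (tf in setdiff(rownames(sm$tf), focal)) add(tf, "TF", sm$tf[tf, spots])
    if (!is.null(sm$pathway)) {
      for (pw in setdiff(rownames(sm$pathway), focal)) {
        add(pw, "P", sm$pathway[pw, spots])
      }
    }
    if (!is.null(sm$drugs)) {
      Ds <- as_dense(sm$drugs)[spots, , drop = FALSE]
      for (dr in colnames(Ds)) add(dr, "D", Ds[, dr])
    }
  }
  out <- do.call(rbind, rows)
  key <- paste(out$partner_id, out$layer, sep = "\r")
  hit <- tapply(abs(out$rho) >= retain_abs_rho, key, any)
  out$retained <- as.logical(hit[key])
  out <- out[order(out$layer, out$partner_id, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Display shortlist of network partners
#'
#' Within each layer, partners are ranked by their mean absolute correlation
#' across samples and the top `top_n` kept (`top_n_pathways` for the P
#' layer); a partner additionally needs `|rho| > strong_rho` in at least
#' `strong_min_samples` samples.
#'
#' @param assoc a [focal_network()] table.
#' @param top_n overall per-layer cut (default 20).
#' @param top_n_pathways cut for the pathway layer (default 8).
#' @param strong_rho strong-correlation threshold (default 0.5, strict).
#' @param strong_min_samples minimum samples above `strong_rho` (default 5).
#' @return data frame `layer`, `partner_id`, `mean_abs_rho`, `n_strong`.
#' @export
display_select <- function(assoc, top_n = 20, top_n_pathways = 8,
                           strong_rho = 0.5, strong_min_samples = 5) {
  out <- list()
  for (ly in sort(unique(assoc$layer))) {
    sub <- assoc[assoc$layer == ly, , drop = FALSE]
    mean_abs <- tapply(abs(sub$rho), sub$partner_id, mean)
    n_strong <- tapply(abs(sub$rho) > strong_rho, sub$partner_id, sum)
    tab <- data.frame(layer = ly, partner_id = names(mean_abs),
                      mean_abs_rho = as.numeric(mean_abs),
                      n_strong = as.integer(n_strong), stringsAsFactors = FALSE)
    tab <- tab[order(-tab$mean_abs_rho, tab$partner_id), , drop = FALSE]
    tab <- utils::head(tab, if (ly == "P") top_n_pathways else top_n)
    tab <- tab[tab$n_strong >= strong_min_samples, , drop = FALSE]
    out[[length(out) + 1L]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
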