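#' Quality-control filter for spot-level counts
#'
#' Removes genes detected in too few spots and spots with too small a total
#' count. The two filters are applied in a single pass, genes first, then
#' spots (spot totals are evaluated after gene removal). A spot is removed
#' when its total is strictly below `min_counts_per_spot`; a gene is kept when
#' it has a nonzero count in at least `min_spots_per_gene` spots of the input
#' matrix. With `iterate = TRUE` the pass is repeated until a joint fixed
#' point, which also makes the filter idempotent.
#'
#' @param x an [expr_mat] in the `"raw"` layer.
#' @param min_spots_per_gene minimum number of spots with a nonzero count for
#'   a gene to be retained (default 5).
#' @param min_counts_per_spot minimum spot total count (default 1000; spots at
#'   exactly the threshold are kept).
#' @param iterate repeat the gene/spot pass until nothing changes.
#' @return The filtered [expr_mat]; the removal report (a data frame with
#'   columns `id`, `axis`, `value`, `threshold`) is attached as attribute
#'   `"qc_report"` and retrievable with [qc_report()].
#' @examples
#' m <- matrix(c(500, 400, 200, 300, 300, 300, 800, 150, 100, 900, 100, 0),
#'             4, 3, byrow = TRUE,
#'             dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
#' f <- filter_qc(expr_mat(m), min_spots_per_gene = 2, min_counts_per_spot = 1000)
#' dim(f)         # 3 x 3: spot s2 (total 900) removed
#' qc_report(f)
#' @export
filter_qc <- function(x, min_spots_per_gene = 5, min_counts_per_spot = 1000,
                      iterate = FALSE) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$layer != "raw") stopf("filter_qc expects the raw counts layer, got '%s'", x$layer)
  if (min_spots_per_gene < 0 || min_counts_per_spot < 0) {
    stopf("thresholds must be >= 0")
  }
  removed <- data.frame(id = character(), axis = character(),
                        value = numeric(), threshold = numeric(),
                        stringsAsFactors = FALSE)
  cur <- x$values
  repeat {
    nz_spots <- Matrix::colSums(cur > 0)
    keep_gene <- nz_spots >= min_spots_per_gene & nz_spots >= 1
    if (any(!keep_gene)) {
      removed <- rbind(removed, data.frame(
        id = colnames(cur)[!keep_gene], axis = "gene",
        value = as.numeric(nz_spots[!keep_gene]),
        threshold = min_spots_per_gene, stringsAsFactors = FALSE))
      cur <- cur[, keep_gene, drop = FALSE]
    }
    totals <- Matrix::rowSums(cur)
    keep_spot <- totals >= min_counts_per_spot
    if (!any(keep_spot)) {
      stopf("all spots removed: every spot total is below min_counts_per_spot = %g",
            min_counts_per_spot)
    }
    if (any(!keep_spot)) {
      removed <- rbind(removed, data.frame(
        id = rownames(cur)[!keep_spot], axis = "spot",
        value = as.numeric(totals[!keep_spot]),
        threshold = min_counts_per_spot, stringsAsFactors = FALSE))
      cur <- cur[keep_spot, , drop = FALSE]
    }
    if (!iterate || (all(keep_gene) && all(keep_spot))) break
  }
  out <- structure(list(values = cur, layer = "raw"), class = "expr_mat")
  attr(out, "qc_report") <- removed
  out
}

#' @rdname filter_qc
#' @export
qc_report <- function(x) attr(x, "qc_report")

#' Total-count normalization of spot profiles
#'
#' Rescales every spot row so its total equals a common target sum, removing
#' sequencing-depth differences between spots.
#'
#' @param x an [expr_mat] in the `"raw"` layer with no zero-total spot.
#' @param target_sum a positive number, or `"median"` (the default) for the
#'   median of the pre-normalization spot totals.
#' @return An [expr_mat] in the `"normalized"` layer. The target used is
#'   attached as attribute `"target_sum"`.
#' @export
normalize_total <- function(x, target_sum = "median") {
  stopifnot(inherits(x, "expr_mat"))
  if (x$layer != "raw") stopf("normalize_total expects the raw layer, got '%s'", x$layer)
  totals <- Matrix::rowSums(x$values)
  if (any(totals == 0)) {
    stopf("zero-total spot(s) present (e.g. '%s'); run filter_qc first",
          rownames(x$values)[which(totals == 0)[1]])
  }
  if (identical(target_sum, "median")) {
    target <- stats::median(totals)
  } else {
    if (!is.numeric(target_sum) || length(target_sum) != 1 || target_sum <= 0) {
      stopf("`target_sum` must be a positive number or \"median\"")
    }
    target <- target_sum
  }
  scaled <- if (inherits(x$values, "Matrix")) {
    Matrix::Diagonal(x = target / totals) %*% x$values
  } else {
    sweep(x$values, 1, target / totals, `*`)
  }
  dimnames(scaled) <- dimnames(x$values)
  out <- structure(list(values = scaled, layer = "normalized"), class = "expr_mat")
  attr(out, "target_sum") <- target
  out
}

#' Square-root variance-stabilizing transform
#'
#' Element-wise square root of the normalized layer. Monotone, so the order of
#' any two entries is preserved.
#'
#' @param x an [expr_mat] in the `"normalized"` layer, all entries `>= 0`.
#' @return An [expr_mat] in the `"sqrt"` layer.
#' @export
sqrt_transform <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$layer != "normalized") {
    stopf("sqrt_transform expects the normalized layer, got '%s'", x$layer)
  }
  v <- if (inherits(x$values, "Matrix")) x$values@x else x$values
  if (any(v < 0)) stopf("negative entries cannot be square-root transformed")
  out_v <- sqrt(x$values)
  dimnames(out_v) <- dimnames(x$values)
  structure(list(values = out_v, layer = "sqrt"), class = "expr_mat")
}

#' Gene coverage filter
#'
#' Returns the genes expressed (value strictly greater than 0) in strictly
#' more than `min_spot_fraction` of spots. Used with the default 0.10 to pick
#' the gene universe for activity inference, and with 0.05 for association
#' analyses.
#'
#' @param x an [expr_mat] with at least one spot.
#' @param min_spot_fraction fraction in `[0, 1]` (default 0.10); retention is
#'   strict (`fraction > min_spot_fraction`).
#' @return Character vector of retained gene ids (possibly empty, with a
#'   warning).
#' @export
coverage_filter <- function(x, min_spot_fraction = 0.10) {
  stopifnot(inherits(x, "expr_mat"))
  if (nrow(x$values) < 1) stopf("expression matrix has no spots")
  if (min_spot_fraction < 0 || min_spot_fraction > 1) {
    stopf("`min_spot_fraction` must be in [0, 1]")
  }
  frac <- Matrix::colSums(x$values > 0) / nrow(x$values)
  keep <- colnames(x$values)[frac > min_spot_fraction]
  if (length(keep) == 0) warnf("coverage_filter retained no genes at fraction %g",
                               min_spot_fraction)
  keep
}
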