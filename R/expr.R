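#' Spot-level expression matrix
#'
#' Light container for a spot x gene expression matrix together with a layer
#' tag recording where the values sit in the preprocessing chain: `"raw"`
#' (non-negative integer counts), `"normalized"` (spot totals rescaled to a
#' common target sum) or `"sqrt"` (element-wise square root of the normalized
#' layer, the variance-stabilized values all downstream inference consumes).
#'
#' Both dense base matrices and sparse [Matrix::Matrix-class] matrices are
#' accepted; operations preserve the representation of their input. Rows are
#' spots, columns are genes, and both dimensions must carry unique names.
#'
#' @param values spot x gene numeric matrix (dense or sparse) with unique
#'   row (spot) and column (gene) names; all entries finite and `>= 0`.
#' @param layer one of `"raw"`, `"normalized"`, `"sqrt"`.
#' @return An object of class `expr_mat`.
#' @examples
#' m <- matrix(rpois(12, 5), 4, 3,
#'             dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
#' e <- expr_mat(m)
#' dim(e)
#' @export
expr_mat <- function(values, layer = c("raw", "normalized", "sqrt")) {
  layer <- match.arg(layer)
  if (!(is.matrix(values) || inherits(values, "Matrix"))) {
    stopf("`values` must be a matrix or Matrix, got %s", class(values)[1])
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("`values` must have spot row names and gene column names")
  }
  check_no_duplicates(rownames(values), "spot ids")
  check_no_duplicates(colnames(values), "gene ids")
  v <- if (inherits(values, "Matrix")) values@x else values
  if (any(!is.finite(v))) stopf("expression values must be finite")
  if (any(v < 0)) stopf("expression values must be non-negative")
  if (layer == "raw" && any(v != floor(v))) {
    stopf("raw layer must contain integer counts")
  }
  structure(list(values = values, layer = layer), class = "expr_mat")
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Spot and gene identifiers of an expression matrix
#' @param x an [expr_mat] object.
#' @return Character vector of ids.
#' @export
spot_ids <- function(x) rownames(x$values)

#' @rdname spot_ids
#' @export
gene_ids <- function(x) colnames(x$values)

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d spots x %d genes, layer = %s (%s)\n",
              nrow(x$values), ncol(x$values), x$layer,
              if (inherits(x$values, "Matrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
as.matrix.expr_mat <- function(x, ...) as_dense(x$values)

# Subset helper preserving class and layer.
subset_expr <- function(x, spots = NULL, genes = NULL) {
  v <- x$values
  if (!is.null(spots)) v <- v[spots, , drop = FALSE]
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  structure(list(values = v, layer = x$layer), class = "expr_mat")
}
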