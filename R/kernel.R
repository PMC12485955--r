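#' Per-spot feature vectors: coordinates plus local mean histology RGB
#'
#' Builds the 5-dimensional feature vector used by the spot-similarity kernel:
#' the two spatial coordinates and, when morphology is available, the mean
#' red/green/blue pixel intensity of a local crop of the histology image.
#' Morphology can come either from an image raster (crops of side
#' `2 * crop_radius_px + 1` centered at each spot's pixel coordinate, clipped
#' at the borders) or from a precomputed per-spot RGB table. Without either,
#' the features are coordinates only.
#'
#' @param positions data frame with columns `spot_id`, `x`, `y` and, if an
#'   image is supplied, `px_row`, `px_col` (pixel coordinates in the raster).
#' @param image optional `H x W x 3` numeric array (any consistent intensity
#'   scale).
#' @param rgb optional data frame `spot_id, r, g, b` (used when `image` is
#'   absent).
#' @param crop_radius_px half-width of the square crop in pixels (default 25).
#' @return data frame of class `spot_features` with columns
#'   `spot_id, x, y, r, g, b` and attribute `has_morphology`.
#' @export
spot_features <- function(positions, image = NULL, rgb = NULL, crop_radius_px = 25) {
  req <- c("spot_id", "x", "y")
  if (!all(req %in% names(positions))) {
    stopf("`positions` must have columns %s", paste(req, collapse = ", "))
  }
  check_no_duplicates(positions$spot_id, "spot ids")
  n <- nrow(positions)
  out <- data.frame(spot_id = as.character(positions$spot_id),
                    x = as.numeric(positions$x), y = as.numeric(positions$y),
                    r = 0, g = 0, b = 0, stringsAsFactors = FALSE)
  has_morph <- FALSE
  if (!is.null(image)) {
    if (length(dim(image)) != 3 || dim(image)[3] != 3) {
      stopf("`image` must be an H x W x 3 array")
    }
    if (!all(c("px_row", "px_col") %in% names(positions))) {
      stopf("`positions` needs px_row/px_col columns to crop an image")
    }
    H <- dim(image)[1]; W <- dim(image)[2]
    r <- crop_radius_px
    if (r < 0) stopf("`crop_radius_px` must be >= 0")
    oob <- positions$px_row < 1 | positions$px_row > H |
           positions$px_col < 1 | positions$px_col > W
    if (any(oob)) warnf("%d spot pixel coordinate(s) outside the raster; crops clipped",
                        sum(oob))
    for (i in seq_len(n)) {
      ri <- max(1, min(H, round(positions$px_row[i])))
      ci <- max(1, min(W, round(positions$px_col[i])))
      rows <- max(1, ri - r):min(H, ri + r)
      cols <- max(1, ci - r):min(W, ci + r)
      out$r[i] <- mean(image[rows, cols, 1])
      out$g[i] <- mean(image[rows, cols, 2])
      out$b[i] <- mean(image[rows, cols, 3])
    }
    has_morph <- TRUE
  } else if (!is.null(rgb)) {
    if (!all(c("spot_id", "r", "g", "b") %in% names(rgb))) {
      stopf("`rgb` must have columns spot_id, r, g, b")
    }
    idx <- match(out$spot_id, rgb$spot_id)
    if (anyNA(idx)) stopf("RGB table is missing %d spot(s)", sum(is.na(idx)))
    out$r <- as.numeric(rgb$r[idx])
    out$g <- as.numeric(rgb$g[idx])
    out$b <- as.numeric(rgb$b[idx])
    has_morph <- TRUE
  }
  attr(out, "has_morphology") <- has_morph
  class(out) <- c("spot_features", "data.frame")
  out
}

#' Standardize and weight spot features
#'
#' Z-scores every included feature column across spots (population-sd
#' convention, dividing by n; constant columns become 0) and then multiplies
#' the morphology columns by `morph_weight`, giving the spatial:morphological
#' weighting of the kernel (default 1:0.05). When the features carry no
#' morphology the RGB columns are dropped entirely.
#'
#' @param features a [spot_features] data frame.
#' @param morph_weight non-negative weight on the RGB columns (default 0.05).
#' @return Numeric spot x d matrix (d = 2 or 5) with spot ids as row names.
#' @export
standardize_features <- function(features, morph_weight = 0.05) {
  stopifnot(inherits(features, "spot_features"))
  if (nrow(features) < 2) stopf("standardization needs at least 2 spots")
  if (morph_weight < 0) stopf("`morph_weight` must be >= 0")
  has_morph <- isTRUE(attr(features, "has_morphology"))
  cols <- if (has_morph) c("x", "y", "r", "g", "b") else c("x", "y")
  F <- as.matrix(features[, cols, drop = FALSE])
  rownames(F) <- features$spot_id
  F <- zscore_cols(F)
  if (has_morph) F[, c("r", "g", "b")] <- F[, c("r", "g", "b")] * morph_weight
  F
}

# Squared Euclidean cross-distances between row sets.
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

# Median of the nonzero pairwise distances, subsampled deterministically to
# at most 2000 rows for large n.
median_bandwidth <- function(F, max_n = 2000) {
  n <- nrow(F)
  if (n > max_n) {
    idx <- with_seed(1L, sort(sample.int(n, max_n)))
    F <- F[idx, , drop = FALSE]
  }
  d <- as.numeric(stats::dist(F))
  d <- d[d > 0]
  if (length(d) == 0) return(0)
  stats::median(d)
}

#' Gaussian RBF spot-similarity kernel
#'
#' Builds the symmetric positive semi-definite kernel
#' `K[i, j] = exp(-||F_i - F_j||^2 / (2 * sigma^2))` over standardized,
#' weighted spot features, together with its (possibly truncated)
#' eigendecomposition. The bandwidth defaults to the median of the nonzero
#' pairwise Euclidean distances (computed on a deterministic subsample of at
#' most 2000 spots when n is large).
#'
#' @param F spot x d numeric matrix (rows named by spot id), typically from
#'   [standardize_features()].
#' @param bandwidth positive number, or `"median"` for the median heuristic.
#' @param rank number of leading eigenpairs to keep, or `"full"`; default
#'   `min(n, 512)`.
#' @param tol eigenvalues are clipped at 0; clipping beyond `tol` (default
#'   1e-8) indicates a non-PSD input and errors.
#' @return Object of class `spatial_kernel`: list with elements `K`, `sigma`,
#'   `values` (non-increasing, `>= 0`), `vectors` (orthonormal columns),
#'   `rank`, `features` (the input `F`).
#' @export
rbf_kernel <- function(F, bandwidth = "median", rank = NULL, tol = 1e-8) {
  F <- as.matrix(F)
  if (nrow(F) < 2) stopf("kernel needs at least 2 spots")
  if (any(!is.finite(F))) stopf("features must be finite")
  if (identical(bandwidth, "median")) {
    sigma <- median_bandwidth(F)
    if (sigma == 0) {
      warnf("all spot features identical; kernel is all ones")
      sigma <- 1
    }
  } else {
    sigma <- bandwidth
    if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
      stopf("bandwidth sigma must be a positive number")
    }
  }
  D2 <- cross_dist2(F, F)
  K <- exp(-D2 / (2 * sigma^2))
  diag(K) <- 1
  dimnames(K) <- list(rownames(F), rownames(F))
  n <- nrow(K)
  if (is.null(rank)) rank <- min(n, 512L)
  eig <- kernel_eigen(K, rank = rank, tol = tol)
  structure(list(K = K, sigma = sigma, values = eig$values,
                 vectors = eig$vectors, rank = length(eig$values),
                 features = F),
            class = "spatial_kernel")
}

#' Eigendecomposition of a symmetric kernel
#'
#' Leading eigenpairs of a symmetric matrix, eigenvalues clipped at zero and
#' sorted non-increasing.
#'
#' @param K symmetric matrix.
#' @param rank integer number of leading pairs, or `"full"`.
#' @param tol maximum allowed negative excursion of an eigenvalue before
#'   clipping is treated as an error (default 1e-8).
#' @return list with `values` and `vectors`.
#' @export
kernel_eigen <- function(K, rank = "full", tol = 1e-8) {
  n <- nrow(K)
  if (!isTRUE(all.equal(K, t(K), tolerance = 1e-10))) stopf("K must be symmetric")
  if (identical(rank, "full")) rank <- n
  if (rank > n) stopf("rank (%d) exceeds matrix size (%d)", rank, n)
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) < -tol) {
    stopf("matrix is not PSD within tolerance (min eigenvalue %.3e)", min(e$values))
  }
  vals <- pmax(e$values, 0)
  idx <- seq_len(rank)
  list(values = vals[idx], vectors = e$vectors[, idx, drop = FALSE])
}

#' RBF cross-kernel block between two feature sets
#'
#' `K_cross[i, j] = exp(-||F1_i - F2_j||^2 / (2 * sigma^2))`, used to extend
#' fitted spatial components to held-out spots. Both feature sets must come
#' from the same standardization pipeline and share `sigma`.
#'
#' @param F1,F2 feature matrices (rows = spots).
#' @param sigma positive bandwidth.
#' @return `nrow(F1) x nrow(F2)` matrix.
#' @export
rbf_cross <- function(F1, F2, sigma) {
  if (sigma <= 0) stopf("sigma must be positive")
  exp(-cross_dist2(as.matrix(F1), as.matrix(F2)) / (2 * sigma^2))
}

#' @export
print.spatial_kernel <- function(x, ...) {
  cat(sprintf("<spatial_kernel> %d spots, sigma = %.4g, rank = %d/%d\n",
              nrow(x$K), x$sigma, x$rank, nrow(x$K)))
  invisible(x)
}
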