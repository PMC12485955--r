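#' Cross-validated hyperparameter search
#'
#' 10-fold cross-validation grid search over `(lambda1, lambda2)`. Spots are
#' shuffled into near-equal folds by a seeded permutation; for every fold the
#' kernel is rebuilt on the training spots (with the bandwidth fixed from the
#' full data), the model is fit for every grid cell, held-out expression is
#' predicted through the held-out-spot extension (see [predict.spotact()]),
#' and the score is the mean over held-out spots of the Pearson correlation
#' between predicted and observed expression across genes. The best cell
#' attains the maximal mean score; ties are broken toward the larger
#' `lambda1 + lambda2`.
#'
#' @param Y gene x spot matrix or [expr_mat] (`"sqrt"`/`"normalized"` layer).
#' @param prior a [prior_mat].
#' @param features spot x d standardized, weighted feature matrix (rows named
#'   by spot id) from [standardize_features()].
#' @param grid_lambda1,grid_lambda2 candidate values (default
#'   `10^(-2:2)` each).
#' @param n_folds number of folds (default 10, minimum 2).
#' @param seed integer seed for the fold shuffle (required).
#' @param mode `"kernel-span"` (default) or `"literal"`.
#' @param bandwidth kernel bandwidth, `"median"` (computed once on the full
#'   features) or a positive number.
#' @return Object of class `spotact_cv`: data frame `grid` with columns
#'   `lambda1`, `lambda2`, `mean_pcc`, `sd_pcc`; the `best` row; `sigma`;
#'   `n_folds`; `seed`; `mode`.
#' @export
spotact_cv <- function(Y, prior, features, grid_lambda1 = 10^(-2:2),
                       grid_lambda2 = 10^(-2:2), n_folds = 10, seed,
                       mode = c("kernel-span", "literal"),
                       bandwidth = "median") {
  mode <- match.arg(mode)
  if (missing(seed)) stopf("`seed` is required for reproducible folds")
  if (n_folds < 2) stopf("`n_folds` must be >= 2")
  if (inherits(Y, "expr_mat")) {
    if (Y$layer == "raw") stopf("normalize and sqrt-transform the counts before CV")
    Y <- t(as_dense(Y$values))
  }
  Y <- as_dense(Y)
  P <- prior$M
  if (!is.null(rownames(Y))) {
    genes <- intersect(rownames(P), rownames(Y))
    if (length(genes) == 0) stopf("no genes shared between Y and the prior")
    P <- P[genes, , drop = FALSE]
    Y <- Y[genes, , drop = FALSE]
  }
  F <- as.matrix(features)
  if (!is.null(colnames(Y)) && !is.null(rownames(F))) {
    if (!setequal(colnames(Y), rownames(F))) stopf("Y and features cover different spots")
    Y <- Y[, rownames(F), drop = FALSE]
  } else if (ncol(Y) != nrow(F)) {
    stopf("Y has %d spots but features have %d rows", ncol(Y), nrow(F))
  }
  n <- nrow(F)
  if (n_folds > n) stopf("more folds than spots")
  sigma <- if (identical(bandwidth, "median")) median_bandwidth(F) else bandwidth
  if (!is.numeric(sigma) || sigma <= 0) stopf("bandwidth sigma must be positive")

  perm <- with_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(n_folds), length.out = n)[order(perm)]

  grid <- expand.grid(lambda1 = grid_lambda1, lambda2 = grid_lambda2,
                      KEEP.OUT.ATTRS = FALSE)
  scores <- matrix(NA_real_, nrow(grid), n_folds)
  zero_var_seen <- FALSE
  PtP_e <- eigen(crossprod(P), symmetric = TRUE)
  V <- PtP_e$vectors
  d <- pmax(PtP_e$values, 0)

  for (f in seq_len(n_folds)) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    Ftr <- F[tr, , drop = FALSE]
    Ktr <- exp(-cross_dist2(Ftr, Ftr) / (2 * sigma^2))
    diag(Ktr) <- 1
    e <- eigen(Ktr, symmetric = TRUE)
    s <- pmax(e$values, 0)
    U <- e$vectors
    Kc <- rbf_cross(Ftr, F[te, , drop = FALSE], sigma)
    Ytr <- Y[, tr, drop = FALSE]
    Yte <- Y[, te, drop = FALSE]
    # fold-level precomputation shared across the grid
    Z <- crossprod(V, crossprod(P, Ytr)) %*% U     # R x ntr
    G_span <- crossprod(U, Kc)                     # ntr x nte (kernel-span path)
    cs <- colSums(Kc); cs[cs == 0] <- 1
    H_smooth <- crossprod(U, sweep(Kc, 2, cs, `/`))
    sd_te <- apply(Yte, 2, pop_sd)
    if (any(sd_te == 0)) zero_var_seen <- TRUE
    for (g in seq_len(nrow(grid))) {
      l1 <- grid$lambda1[g]; l2 <- grid$lambda2[g]
      omega <- penalty_spectrum(s, l1, l2, mode)
      Atl <- V %*% (Z / outer(d, omega, `+`))
      fsi <- si_fraction(s, l1, l2, mode)
      Asd_tl <- sweep(Atl, 2, 1 - fsi, `*`)
      A_te <- if (mode == "kernel-span") {
        inv_s <- ifelse(s > 1e-12, 1 / s, 0)
        sweep(Asd_tl, 2, inv_s, `*`) %*% G_span
      } else {
        Asd_tl %*% H_smooth
      }
      Yhat <- P %*% A_te
      pcc <- vapply(seq_along(te), function(j) {
        if (sd_te[j] == 0 || pop_sd(Yhat[, j]) == 0) return(NA_real_)
        stats::cor(Yhat[, j], Yte[, j])
      }, numeric(1))
      scores[g, f] <- mean(pcc, na.rm = TRUE)
    }
  }
  if (zero_var_seen) warnf("held-out spot(s) with zero expression variance excluded from fold means")
  grid$mean_pcc <- rowMeans(scores)
  grid$sd_pcc <- apply(scores, 1, stats::sd)
  ord <- order(-grid$mean_pcc, -(grid$lambda1 + grid$lambda2))
  best <- grid[ord[1], , drop = FALSE]
  structure(list(grid = grid, best = best, sigma = sigma, n_folds = n_folds,
                 seed = seed, mode = mode, fold_scores = scores),
            class = "spotact_cv")
}

#' @export
print.spotact_cv <- function(x, ...) {
  cat(sprintf("<spotact_cv> %d-fold CV over %d cells (%s mode, seed %d)\n",
              x$n_folds, nrow(x$grid), x$mode, x$seed))
  cat(sprintf("  best: lambda1 = %.4g, lambda2 = %.4g, mean held-out PCC = %.4f\n",
              x$best$lambda1, x$best$lambda2, x$best$mean_pcc))
  invisible(x)
}
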