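# Shared fixture builders and independent oracles.

# Small named count matrix.
toy_counts <- function(rows, spot_ids = NULL, gene_ids = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- spot_ids %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- gene_ids %||% paste0("g", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small regression instance with a well-conditioned RBF kernel.
random_instance <- function(n_genes = 20, n_regs = 6, n_spots = 30,
                            bandwidth = 0.4, seed = 1) {
  set.seed(seed)
  P <- matrix(rbinom(n_genes * n_regs, 1, 0.3), n_genes, n_regs,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("r%02d", seq_len(n_regs))))
  F <- matrix(rnorm(n_spots * 2), n_spots, 2,
              dimnames = list(sprintf("s%02d", seq_len(n_spots)), c("x", "y")))
  ker <- rbf_kernel(F, bandwidth = bandwidth, rank = "full")
  Y <- matrix(rnorm(n_genes * n_spots), n_genes, n_spots,
              dimnames = list(rownames(P), rownames(F)))
  list(P = P, F = F, kernel = ker, Y = Y, prior = prior_mat(P, "tf"))
}

# Raw decomposition objective, parameterized by (A_sd, A_si) in literal mode
# and (B, A_si) in kernel-span mode. Used by the generic-minimizer oracle.
raw_objective <- function(par, Y, P, K, l1, l2, mode) {
  R <- ncol(P); S <- ncol(Y)
  M1 <- matrix(par[seq_len(R * S)], R, S)
  Asi <- matrix(par[R * S + seq_len(R * S)], R, S)
  if (mode == "literal") {
    A <- M1 + Asi
    0.5 * sum((P %*% A - Y)^2) + 0.5 * l1 * sum((M1 %*% K)^2) +
      0.5 * l2 * sum(Asi^2)
  } else {
    A <- M1 %*% K + Asi
    0.5 * sum((P %*% A - Y)^2) + 0.5 * l1 * sum(M1^2) + 0.5 * l2 * sum(Asi^2)
  }
}

raw_gradient <- function(par, Y, P, K, l1, l2, mode) {
  R <- ncol(P); S <- ncol(Y)
  M1 <- matrix(par[seq_len(R * S)], R, S)
  Asi <- matrix(par[R * S + seq_len(R * S)], R, S)
  if (mode == "literal") {
    Gfit <- crossprod(P, P %*% (M1 + Asi) - Y)
    g1 <- Gfit + l1 * (M1 %*% K) %*% K
  } else {
    Gfit <- crossprod(P, P %*% (M1 %*% K + Asi) - Y)
    g1 <- Gfit %*% K + l1 * M1
  }
  g2 <- Gfit + l2 * Asi
  c(as.numeric(g1), as.numeric(g2))
}

# Generic iterative convex minimizer of the raw objective.
oracle_minimum <- function(Y, P, K, l1, l2, mode, maxit = 5000) {
  R <- ncol(P); S <- ncol(Y)
  o <- stats::optim(rep(0, 2 * R * S), raw_objective, raw_gradient,
                    Y = Y, P = P, K = K, l1 = l1, l2 = l2, mode = mode,
                    method = "L-BFGS-B",
                    control = list(maxit = maxit, factr = 10))
  o$value
}

# Reference BH step-up, written independently of stats::p.adjust.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive rank-sum enumeration oracle (midranks).
wilcox_enum <- function(x, y, alternative = "greater") {
  nx <- length(x); N <- nx + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  sums <- colSums(matrix(r[utils::combn(N, nx)], nrow = nx))
  if (alternative == "greater") mean(sums >= W) else mean(sums <= W)
}

# Spearman via explicit midrank Pearson formula.
spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# An identity-kernel spatial_kernel over given spot ids (for closed forms).
identity_kernel <- function(spot_ids) {
  n <- length(spot_ids)
  K <- diag(n)
  dimnames(K) <- list(spot_ids, spot_ids)
  structure(list(K = K, sigma = 1, values = rep(1, n), vectors = diag(n),
                 rank = n,
                 features = matrix(0, n, 2, dimnames = list(spot_ids, c("x", "y")))),
            class = "spatial_kernel")
}
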