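#' Hexagonal Visium-like spot grid
#'
#' Generates a hexagonal lattice of spot positions: alternate rows are offset
#' by half the spacing and the row pitch is `spacing * sqrt(3) / 2`, so
#' nearest-neighbor distances are constant across interior spots (the Visium
#' geometry).
#'
#' @param n_rows,n_cols grid dimensions (`>= 1`).
#' @param spacing center-to-center distance (default 1).
#' @param px_per_unit pixel scale for the synthetic full-resolution image
#'   coordinates (default 100).
#' @return data frame `spot_id`, `in_tissue`, `array_row`, `array_col`,
#'   `x`, `y`, `px_row`, `px_col`.
#' @export
sim_grid <- function(n_rows, n_cols, spacing = 1, px_per_unit = 100) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  g <- expand.grid(array_col = seq_len(n_cols), array_row = seq_len(n_rows),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$array_row, g$array_col), ]
  x <- spacing * (g$array_col - 1) + (spacing / 2) * ((g$array_row - 1) %% 2)
  y <- spacing * sqrt(3) / 2 * (g$array_row - 1)
  data.frame(
    spot_id = sprintf("spot_r%02d_c%02d", g$array_row, g$array_col),
    in_tissue = 1L, array_row = g$array_row, array_col = g$array_col,
    x = x, y = y,
    px_row = round(y * px_per_unit) + 1, px_col = round(x * px_per_unit) + 1,
    stringsAsFactors = FALSE)
}

#' Plant smooth + independent regulator activities
#'
#' Draws, for each regulator, a spatially smooth field `U sqrt(s) z` in the
#' kernel eigenbasis plus an iid normal field, each standardized and then
#' scaled so the smooth component contributes `sd_fraction` of the total
#' variance (and the independent component the remainder).
#'
#' @param kernel a [spatial_kernel] (full rank recommended).
#' @param n_regulators number of activity rows.
#' @param sd_fraction fraction of variance carried by the smooth component,
#'   in `[0, 1]` (default 0.7).
#' @param scale total per-regulator activity standard deviation (default 1).
#' @param seed integer seed.
#' @return list with regulator x spot matrices `A_sd`, `A_si` and
#'   `A = A_sd + A_si`.
#' @export
sim_activities <- function(kernel, n_regulators, sd_fraction = 0.7, scale = 1,
                           seed = 1) {
  stopifnot(inherits(kernel, "spatial_kernel"))
  if (sd_fraction < 0 || sd_fraction > 1) stopf("sd_fraction must be in [0, 1]")
  n <- nrow(kernel$K)
  U <- kernel$vectors
  sq <- sqrt(kernel$values)
  regs <- sprintf("reg%02d", seq_len(n_regulators))
  out <- with_seed(seed, {
    A_sd <- matrix(0, n_regulators, n)
    A_si <- matrix(0, n_regulators, n)
    for (r in seq_len(n_regulators)) {
      smooth <- as.numeric(U %*% (sq * stats::rnorm(length(sq))))
      s_sd <- pop_sd(smooth)
      if (s_sd > 0) smooth <- (smooth - mean(smooth)) / s_sd
      indep <- stats::rnorm(n)
      indep <- (indep - mean(indep)) / pop_sd(indep)
      A_sd[r, ] <- sqrt(sd_fraction) * scale * smooth
      A_si[r, ] <- sqrt(1 - sd_fraction) * scale * indep
    }
    list(A_sd = A_sd, A_si = A_si)
  })
  spots <- rownames(kernel$K)
  dimnames(out$A_sd) <- dimnames(out$A_si) <- list(regs, spots)
  out$A <- out$A_sd + out$A_si
  out
}

#' Random gene x regulator ground-truth prior
#'
#' @param n_genes size of the gene universe (ids `g0001`, ...).
#' @param n_regulators number of regulators.
#' @param targets_per_regulator targets sampled per regulator (default 25).
#' @param seed integer seed.
#' @return A [prior_mat] of kind `"tf"` over the full gene universe (rows with
#'   no regulator included, so the matrix aligns with simulated counts).
#' @export
sim_prior <- function(n_genes, n_regulators, targets_per_regulator = 25,
                      seed = 1) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  regs <- sprintf("reg%02d", seq_len(n_regulators))
  M <- matrix(0, n_genes, n_regulators, dimnames = list(genes, regs))
  with_seed(seed, {
    for (r in seq_len(n_regulators)) {
      M[sample.int(n_genes, targets_per_regulator), r] <- 1
    }
  })
  prior_mat(M, kind = "tf")
}

#' Simulate spot-level counts from planted activities
#'
#' Linear predictor `eta = baseline + P A + eps` with iid normal noise of sd
#' `noise_sd`; per-spot Poisson rates `depth * softplus(eta) / rowsum`, so the
#' expected total count of every spot equals `depth`. With
#' `family = "gaussian"` the predictor is returned directly as observed
#' values (no count noise), a convenient oracle mode for solver tests.
#'
#' @param prior a [prior_mat] (ground truth `P`).
#' @param A regulator x spot activity matrix (ground truth).
#' @param depth expected total counts per spot (default 5000).
#' @param noise_sd sd of the gene-level predictor noise (default 0.25).
#' @param seed integer seed.
#' @param family `"poisson"` (default, raw counts) or `"gaussian"`.
#' @param baseline constant added to the predictor (default 0).
#' @return An [expr_mat]: raw counts (`poisson`) or a `"sqrt"`-layer matrix of
#'   direct observations (`gaussian`).
#' @export
sim_counts <- function(prior, A, depth = 5000, noise_sd = 0.25, seed = 1,
                       family = c("poisson", "gaussian"), baseline = 0) {
  family <- match.arg(family)
  P <- prior$M
  if (ncol(P) != nrow(A)) stopf("prior has %d regulators but A has %d rows",
                                ncol(P), nrow(A))
  eta <- with_seed(seed, {
    baseline + P %*% A + matrix(stats::rnorm(nrow(P) * ncol(A), sd = noise_sd),
                                nrow(P), ncol(A))
  })
  dimnames(eta) <- list(rownames(P), colnames(A))
  if (family == "gaussian") {
    v <- t(eta) - min(eta)  # shift to >= 0 so the container invariant holds
    return(structure(list(values = v, layer = "sqrt"), class = "expr_mat"))
  }
  if (depth == 0) {
    counts <- matrix(0L, ncol(eta), nrow(eta),
                     dimnames = list(colnames(eta), rownames(eta)))
    return(expr_mat(counts, layer = "raw"))
  }
  u <- softplus(eta)                           # gene x spot, > 0
  rate <- t(u) * (depth / colSums(u))          # spot x gene; spot totals = depth
  counts <- with_seed(seed + 1, {
    matrix(stats::rpois(length(rate), lambda = rate), nrow(rate), ncol(rate))
  })
  dimnames(counts) <- dimnames(rate)
  expr_mat(counts, layer = "raw")
}

#' Spatial metaprogram labels by Voronoi partition
#'
#' Samples `n_programs` centroid spots and assigns every spot to its nearest
#' centroid (ties broken by centroid index), yielding contiguous spatial
#' niches that mimic metaprogram annotations.
#'
#' @param positions data frame with `spot_id`, `x`, `y`.
#' @param n_programs number of programs (`<= n_spots`).
#' @param seed integer seed.
#' @return data frame `spot_id`, `mp_label` (labels `MP1`, ...).
#' @export
sim_mp_labels <- function(positions, n_programs, seed = 1) {
  n <- nrow(positions)
  if (n_programs > n) stopf("more programs than spots")
  cent <- with_seed(seed, sample.int(n, n_programs))
  # plain squared distances (no expanded-product shortcut) so nearest-centroid
  # ties resolve identically to a brute-force recomputation
  d2 <- sapply(cent, function(j) {
    (positions$x - positions$x[j])^2 + (positions$y - positions$y[j])^2
  })
  lab <- apply(d2, 1, which.min)
  data.frame(spot_id = positions$spot_id, mp_label = paste0("MP", lab),
             stringsAsFactors = FALSE)
}

#' Shift a regulator's activity inside a metaprogram
#'
#' Adds `delta` to one activity row at the spots carrying a given label —
#' planted ground truth for metaprogram-differential tests.
#'
#' @param A regulator x spot matrix.
#' @param labels data frame `spot_id`, `mp_label`.
#' @param mp target metaprogram label.
#' @param regulator target activity row.
#' @param delta shift (default 1).
#' @return The shifted matrix.
#' @export
plant_mp_shift <- function(A, labels, mp, regulator, delta = 1) {
  if (!regulator %in% rownames(A)) stopf("unknown regulator '%s'", regulator)
  spots <- labels$spot_id[labels$mp_label == mp]
  spots <- intersect(spots, colnames(A))
  if (length(spots) == 0) stopf("no spots carry label '%s'", mp)
  A[regulator, spots] <- A[regulator, spots] + delta
  A
}

#' Random drug-target and ligand-receptor annotations
#'
#' Draws `n_drugs` drugs with 1-8 target genes each, and `n_lr_pairs`
#' ligand-receptor pairs from disjoint gene subsets, all from the supplied
#' gene universe.
#'
#' @param genes character vector of gene ids.
#' @param n_drugs number of drugs.
#' @param n_lr_pairs number of ligand-receptor pairs.
#' @param seed integer seed.
#' @return list with `drug_map` (`drug_id`, `drug_name`, `target_gene`) and
#'   `lr_pairs` (`ligand_gene`, `receptor_gene`).
#' @export
sim_annotations <- function(genes, n_drugs, n_lr_pairs, seed = 1) {
  if (length(genes) == 0) stopf("gene universe is empty")
  with_seed(seed, {
    drug_rows <- list()
    for (i in seq_len(n_drugs)) {
      k <- sample.int(8, 1)
      tg <- sample(genes, min(k, length(genes)))
      drug_rows[[i]] <- data.frame(
        drug_id = sprintf("DRUG%04d", i),
        drug_name = sprintf("compound_%04d", i),
        target_gene = tg, stringsAsFactors = FALSE)
    }
    drug_map <- if (n_drugs > 0) do.call(rbind, drug_rows) else
      data.frame(drug_id = character(), drug_name = character(),
                 target_gene = character(), stringsAsFactors = FALSE)
    lr <- data.frame(ligand_gene = character(), receptor_gene = character(),
                     stringsAsFactors = FALSE)
    if (n_lr_pairs > 0) {
      if (2 * n_lr_pairs > length(genes)) stopf("not enough genes for %d LR pairs", n_lr_pairs)
      pool <- sample(genes, 2 * n_lr_pairs)
      lr <- data.frame(ligand_gene = pool[seq_len(n_lr_pairs)],
                       receptor_gene = pool[n_lr_pairs + seq_len(n_lr_pairs)],
                       stringsAsFactors = FALSE)
    }
    list(drug_map = drug_map, lr_pairs = lr)
  })
}

#' Complete synthetic Visium-like sample with ground truth
#'
#' Assembles the full fixture: hexagonal grid, smooth synthetic RGB fields,
#' spatial kernel, planted smooth + independent activities, Poisson counts,
#' Voronoi metaprogram labels (optionally with a planted activity shift), and
#' drug / ligand-receptor annotations. Everything is reproducible from
#' `seed`. The default scale (20 x 20 spots, 300 genes, 12 regulators, 5
#' metaprograms, smooth-variance fraction 0.7, predictor noise sd 0.25,
#' expected depth 5000) is the shipped study condition for all simulation
#' tests.
#'
#' @param n_rows,n_cols grid size (default 20 x 20 = 400 spots).
#' @param n_genes gene universe size (default 300).
#' @param n_regulators number of regulators (default 12).
#' @param n_programs number of metaprograms (default 5).
#' @param sd_fraction smooth variance fraction (default 0.7).
#' @param noise_sd predictor noise sd (default 0.25).
#' @param depth expected counts per spot (default 5000).
#' @param targets_per_regulator prior targets per regulator (default 25).
#' @param n_drugs,n_lr_pairs annotation sizes (defaults 20 and 15).
#' @param shift optional list `list(mp =, regulator =, delta =)` planting an
#'   activity shift inside one metaprogram.
#' @param seed integer master seed.
#' @return list with `positions`, `rgb`, `counts` ([expr_mat], raw),
#'   `prior` ([prior_mat] over the full universe), `truth` (list `A`, `A_sd`,
#'   `A_si`), `labels`, `drug_map`, `lr_pairs`, `kernel_sim` (the
#'   spatial-only kernel used for planting), `params`.
#' @export
sim_sample <- function(n_rows = 20, n_cols = 20, n_genes = 300,
                       n_regulators = 12, n_programs = 5, sd_fraction = 0.7,
                       noise_sd = 0.25, depth = 5000,
                       targets_per_regulator = 25, n_drugs = 20,
                       n_lr_pairs = 15, shift = NULL, seed = 1) {
  positions <- sim_grid(n_rows, n_cols)
  # spatial-only kernel used to plant fields (the analysis kernel later adds RGB)
  feat0 <- spot_features(positions)
  F0 <- standardize_features(feat0)
  ker <- rbf_kernel(F0, rank = "full")
  # smooth RGB fields from the same kernel
  rgb <- with_seed(seed + 11, {
    ch <- sapply(1:3, function(i) {
      f <- as.numeric(ker$vectors %*% (sqrt(ker$values) * stats::rnorm(ker$rank)))
      s <- pop_sd(f)
      if (s > 0) f <- (f - mean(f)) / s
      pmin(255, pmax(0, 127 + 40 * f))
    })
    data.frame(spot_id = positions$spot_id, r = ch[, 1], g = ch[, 2], b = ch[, 3],
               stringsAsFactors = FALSE)
  })
  act <- sim_activities(ker, n_regulators, sd_fraction, scale = 1, seed = seed + 1)
  A <- act$A
  labels <- sim_mp_labels(positions, n_programs, seed = seed + 2)
  if (!is.null(shift)) {
    A <- plant_mp_shift(A, labels, shift$mp, shift$regulator,
                        shift$delta %||% 1)
  }
  prior <- sim_prior(n_genes, n_regulators, targets_per_regulator, seed = seed + 3)
  counts <- sim_counts(prior, A, depth = depth, noise_sd = noise_sd,
                       seed = seed + 4)
  ann <- sim_annotations(rownames(prior$M), n_drugs, n_lr_pairs, seed = seed + 5)
  list(positions = positions, rgb = rgb, counts = counts, prior = prior,
       truth = list(A = A, A_sd = act$A_sd, A_si = act$A_si),
       labels = labels, drug_map = ann$drug_map, lr_pairs = ann$lr_pairs,
       kernel_sim = ker,
       params = list(n_rows = n_rows, n_cols = n_cols, n_genes = n_genes,
                     n_regulators = n_regulators, n_programs = n_programs,
                     sd_fraction = sd_fraction, noise_sd = noise_sd,
                     depth = depth, seed = seed, shift = shift))
}
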