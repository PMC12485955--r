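#' Row-wise scaling of an activity matrix
#'
#' Scales each regulator row to zero mean and unit variance across spots
#' (population-sd convention). Constant rows become all-zero with a warning.
#'
#' @param A regulator x spot numeric matrix, `>= 2` spots.
#' @return Scaled matrix of the same shape.
#' @export
scale_activities <- function(A) {
  A <- as_dense(A)
  if (ncol(A) < 2) stopf("scaling needs at least 2 spots")
  mu <- rowMeans(A)
  sdv <- sqrt(rowMeans(A^2) - mu^2)
  sdv <- pmax(sdv, 0)  # guard tiny negatives from cancellation
  sdv[!is.finite(sdv)] <- 0
  const <- sdv < .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  if (any(const)) warnf("%d constant row(s) set to zero", sum(const))
  out <- (A - mu) / ifelse(const, 1, sdv)
  out[const, ] <- 0
  out
}

#' One-sided Wilcoxon rank-sum test
#'
#' Rank-sum test with midranks for ties. When the pooled size
#' `length(x) + length(y)` is at most 12 the p-value is computed by exhaustive
#' enumeration of all group assignments (valid under ties); otherwise a normal
#' approximation with tie-corrected variance and a 0.5 continuity correction
#' is used. The statistic is the rank sum of `x`.
#'
#' @param x,y non-empty numeric vectors (in-group and out-group values).
#' @param alternative `"greater"` (x shifted up) or `"less"`.
#' @param exact_max pooled size up to which the exact path is used
#'   (default 12).
#' @return list with `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, alternative = c("greater", "less"),
                          exact_max = 12) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stopf("both groups must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))  # midranks
  W <- sum(r[seq_len(nx)])
  if (N <= exact_max) {
    combs <- utils::combn(N, nx)
    sums <- colSums(matrix(r[combs], nrow = nx))
    p <- if (alternative == "greater") mean(sums >= W) else mean(sums <= W)
    return(list(statistic = W, p_value = p, method = "exact"))
  }
  mu <- nx * (N + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- nx * ny / 12 * ((N + 1) - tie_term)
  if (v <= 0) {
    # all values tied: no evidence of shift in either direction
    return(list(statistic = W, p_value = 1, method = "normal"))
  }
  z <- if (alternative == "greater") (W - mu - 0.5) / sqrt(v) else (W - mu + 0.5) / sqrt(v)
  p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
       else stats::pnorm(z)
  list(statistic = W, p_value = p, method = "normal")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment of a family of p-values; input order is
#' preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Metaprogram-differential statistics
#'
#' For every (metaprogram, feature) pair, compares the feature's values at
#' spots inside the metaprogram against all other spots with a Wilcoxon
#' rank-sum test, and reports the difference of means (inside minus outside)
#' on the supplied (scaled) matrix. P-values are BH-adjusted across all
#' (metaprogram, feature) pairs of the sample and feature kind — one family
#' per call.
#'
#' @param A feature x spot matrix; activities should be passed through
#'   [scale_activities()] first.
#' @param labels data frame with columns `spot_id`, `mp_label` covering the
#'   columns of `A`.
#' @param feature_kind `"tf"`, `"pathway"` or `"drug"` (recorded in the
#'   output).
#' @param sample_id sample identifier recorded in the output.
#' @param alternative `"greater"` (one-sided enrichment, the default) or
#'   `"two-one-sided"` (twice the smaller one-sided p, capped at 1, so that
#'   depleted features can also reach significance).
#' @param min_spots metaprograms with fewer spots are skipped with a warning
#'   (default 3).
#' @return data frame with columns `sample_id`, `mp_label`, `feature_id`,
#'   `feature_kind`, `mean_diff`, `statistic`, `p_value`, `adj_p`.
#' @export
mp_differential <- function(A, labels, feature_kind = c("tf", "pathway", "drug"),
                            sample_id = "sample1",
                            alternative = c("greater", "two-one-sided"),
                            min_spots = 3) {
  feature_kind <- match.arg(feature_kind)
  alternative <- match.arg(alternative)
  A <- as_dense(A)
  if (!all(c("spot_id", "mp_label") %in% names(labels))) {
    stopf("`labels` must have columns spot_id, mp_label")
  }
  idx <- match(colnames(A), labels$spot_id)
  if (anyNA(idx)) stopf("%d spot(s) of A missing from labels", sum(is.na(idx)))
  lab <- as.character(labels$mp_label[idx])
  mps <- sort(unique(lab))
  rows <- list()
  for (mp in mps) {
    inside <- lab == mp
    if (sum(inside) < min_spots) {
      warnf("metaprogram '%s' has fewer than %d spots; skipped", mp, min_spots)
      next
    }
    if (sum(!inside) == 0) next
    for (feat in rownames(A)) {
      xi <- A[feat, inside]; yo <- A[feat, !inside]
      tg <- rank_sum_test(xi, yo, "greater")
      p <- if (alternative == "greater") {
        tg$p_value
      } else {
        tl <- rank_sum_test(xi, yo, "less")
        min(1, 2 * min(tg$p_value, tl$p_value))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, mp_label = mp, feature_id = feat,
        feature_kind = feature_kind, mean_diff = mean(xi) - mean(yo),
        statistic = tg$statistic, p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stopf("no (metaprogram, feature) pair was testable")
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Cross-sample consensus feature selection
#'
#' A feature qualifies for a metaprogram when it is both significant
#' (`adj_p < p_thresh`) and differential (`|mean_diff| > diff_thresh`) in at
#' least `min_samples` samples. Qualifiers are ranked by the cross-sample
#' mean of `mean_diff`; the `top_k` most positive and, unless
#' `positive_only`, the `top_k` most negative are returned per metaprogram.
#' Rank ties are broken by feature id.
#'
#' @param results row-bound [mp_differential()] output across samples.
#' @param p_thresh adjusted-p threshold (default 0.001).
#' @param diff_thresh absolute mean-difference threshold (default 0.3).
#' @param min_samples minimum qualifying samples (default 15).
#' @param top_k shortlist size per direction (default 5).
#' @param positive_only keep only positive-mean-difference features (the drug
#'   rule).
#' @return data frame `mp_label`, `feature_id`, `direction`, `mean_mean_diff`,
#'   `n_qualifying`.
#' @export
consensus_select <- function(results, p_thresh = 0.001, diff_thresh = 0.3,
                             min_samples = 15, top_k = 5, positive_only = FALSE) {
  n_samples <- length(unique(results$sample_id))
  if (min_samples > n_samples) {
    stopf("min_samples = %d exceeds the %d available sample(s)",
          min_samples, n_samples)
  }
  key <- paste(results$mp_label, results$feature_id, sep = "\r")
  qual <- results$adj_p < p_thresh & abs(results$mean_diff) > diff_thresh
  n_q <- tapply(qual, key, sum)
  mean_md <- tapply(results$mean_diff, key, mean)
  info <- do.call(rbind, strsplit(names(n_q), "\r", fixed = TRUE))
  tab <- data.frame(mp_label = info[, 1], feature_id = info[, 2],
                    mean_mean_diff = as.numeric(mean_md),
                    n_qualifying = as.integer(n_q), stringsAsFactors = FALSE)
  tab <- tab[tab$n_qualifying >= min_samples, , drop = FALSE]
  out <- list()
  for (mp in sort(unique(tab$mp_label))) {
    sub <- tab[tab$mp_label == mp, , drop = FALSE]
    pos <- sub[sub$mean_mean_diff > 0, , drop = FALSE]
    pos <- pos[order(-pos$mean_mean_diff, pos$feature_id), , drop = FALSE]
    pos <- utils::head(pos, top_k)
    if (nrow(pos)) pos$direction <- "positive"
    out[[length(out) + 1L]] <- pos
    if (!positive_only) {
      neg <- sub[sub$mean_mean_diff < 0, , drop = FALSE]
      neg <- neg[order(neg$mean_mean_diff, neg$feature_id), , drop = FALSE]
      neg <- utils::head(neg, top_k)
      if (nrow(neg)) neg$direction <- "negative"
      out[[length(out) + 1L]] <- neg
    }
  }
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (length(out) == 0) {
    return(data.frame(mp_label = character(), feature_id = character(),
                      direction = character(), mean_mean_diff = numeric(),
                      n_qualifying = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("mp_label", "feature_id", "direction", "mean_mean_diff", "n_qualifying")]
}

#' Per-spot drug scores
#'
#' Scores each drug at each spot as the arithmetic mean expression of the
#' drug's target genes present in the matrix (the drug2cell-style score).
#' Drugs with no present target are dropped with a warning; per-drug target
#' coverage is attached as attribute `"coverage"`.
#'
#' @param expr an [expr_mat]; the normalized + sqrt layer is the conventional
#'   input (raw is accepted).
#' @param drug_map data frame `drug_id`, `drug_name`, `target_gene` (one row
#'   per drug-target pair).
#' @return spot x drug numeric matrix.
#' @export
drug_scores <- function(expr, drug_map) {
  stopifnot(inherits(expr, "expr_mat"))
  if (is.null(drug_map) || nrow(drug_map) == 0) stopf("drug-target map is empty")
  if (!all(c("drug_id", "target_gene") %in% names(drug_map))) {
    stopf("`drug_map` needs columns drug_id, target_gene")
  }
  V <- as_dense(expr$values)
  drugs <- unique(drug_map$drug_id)
  out <- matrix(NA_real_, nrow(V), length(drugs),
                dimnames = list(rownames(V), drugs))
  coverage <- data.frame(drug_id = drugs, n_targets = NA_integer_,
                         n_present = NA_integer_, stringsAsFactors = FALSE)
  keep <- logical(length(drugs))
  for (i in seq_along(drugs)) {
    tg <- unique(drug_map$target_gene[drug_map$drug_id == drugs[i]])
    present <- intersect(tg, colnames(V))
    coverage$n_targets[i] <- length(tg)
    coverage$n_present[i] <- length(present)
    if (length(present) == 0) next
    keep[i] <- TRUE
    out[, i] <- if (length(present) == 1) V[, present] else rowMeans(V[, present])
  }
  if (!all(keep)) {
    warnf("dropping %d drug(s) with no target in the expression matrix", sum(!keep))
  }
  out <- out[, keep, drop = FALSE]
  attr(out, "coverage") <- coverage
  out
}

#' Spearman correlations between regulator activities and drug scores
#'
#' Per sample, Spearman's rho between every regulator activity row and every
#' drug score column; a (regulator, drug) pair is retained when its absolute
#' rho reaches `retain_abs_rho` in at least one sample.
#'
#' @param activities regulator x spot matrix, or named list of them (one per
#'   sample).
#' @param scores spot x drug matrix, or named list matching `activities`.
#' @param retain_abs_rho retention threshold on `|rho|` (default 0.3).
#' @return Long data frame `sample_id`, `regulator`, `drug`, `rho`, `tie`,
#'   `n_spots`, `retained`.
#' @export
regulator_drug_correlation <- function(activities, scores, retain_abs_rho = 0.3) {
  if (!is.list(activities)) activities <- list(sample1 = activities)
  if (!is.list(scores)) scores <- list(sample1 = scores)
  stopifnot(length(activities) == length(scores))
  samples <- names(activities) %||% paste0("sample", seq_along(activities))
  rows <- list()
  for (si in seq_along(samples)) {
    A <- as_dense(activities[[si]])
    D <- as_dense(scores[[si]])
    spots <- intersect(colnames(A), rownames(D))
    if (length(spots) < 3) stopf("sample '%s' has fewer than 3 shared spots", samples[si])
    A <- A[, spots, drop = FALSE]
    D <- D[spots, , drop = FALSE]
    for (rg in rownames(A)) {
      for (dr in colnames(D)) {
        rho <- spearman_rho(A[rg, ], D[, dr])
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = samples[si], regulator = rg, drug = dr,
          rho = as.numeric(rho), tie = isTRUE(attr(rho, "tie")),
          n_spots = length(spots), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  key <- paste(out$regulator, out$drug, sep = "\r")
  hit <- tapply(abs(out$rho) >= retain_abs_rho, key, any)
  out$retained <- as.logical(hit[key])
  rownames(out) <- NULL
  out
}

#' Metaprogram proportions per sample
#'
#' @param labels data frame with columns `sample_id` (optional; a single
#'   sample is assumed when absent), `mp_label`.
#' @return sample x metaprogram matrix of proportions; rows sum to 1.
#' @export
mp_proportions <- function(labels) {
  if (nrow(labels) == 0) stopf("labels are empty")
  if (!"mp_label" %in% names(labels)) stopf("`labels` needs an mp_label column")
  sid <- if ("sample_id" %in% names(labels)) labels$sample_id else "sample1"
  tab <- table(sid, labels$mp_label)
  prop <- sweep(unclass(tab), 1, rowSums(tab), `/`)
  prop <- matrix(prop, nrow(tab), ncol(tab), dimnames = dimnames(tab))
  names(dimnames(prop)) <- NULL
  prop
}
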