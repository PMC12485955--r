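# Default parameter block mirroring the shipped thresholds of every stage.
default_params <- function() {
  list(
    min_spots_per_gene = 5, min_counts_per_spot = 1000,
    target_sum = "median",
    coverage_fraction = 0.10, assoc_coverage_fraction = 0.05,
    morph_weight = 0.05, bandwidth = "median", kernel_rank = 512,
    crop_radius_px = 25,
    min_gene_proportion = 0.1, min_regulators_per_gene = 10,
    min_genes_per_regulator = 5,
    mode = "kernel-span", lambda1 = NULL, lambda2 = NULL,
    grid_lambda1 = 10^(-2:2), grid_lambda2 = 10^(-2:2), n_folds = 10,
    p_thresh = 0.001, diff_thresh = 0.3, min_samples = 15, top_k = 5,
    retain_abs_rho = 0.3, strong_rho = 0.5, strong_min_samples = 5,
    top_n = 20, top_n_pathways = 8, k_neighbors = 6
  )
}

known_config_keys <- c("samples", "prior", "prior_kind", "gmt", "drug_targets",
                       "lr_pairs", "focal", "out", "seed", "params")

#' Resolve and validate a pipeline configuration
#'
#' A configuration is a YAML file or list with keys: `samples` (list of
#' `name`, `counts`, `positions`, optional `rgb`, optional `labels`),
#' `prior` (edge TSV) or `gmt` (gene sets), `prior_kind`, optional
#' `drug_targets`, `lr_pairs`, `focal` (regulator id for the network stage),
#' `out` (output directory), `seed`, and `params` overriding any shipped
#' default threshold. Unknown keys are rejected.
#'
#' @param config path to a YAML file or a list.
#' @return Validated config list with all defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(config$samples) || length(config$samples) == 0) {
    stopf("config needs at least one entry under `samples`")
  }
  if (is.null(config$out)) stopf("config needs an `out` directory")
  if (is.null(config$seed)) stopf("config needs a `seed`")
  for (s in config$samples) {
    for (k in c("name", "counts", "positions")) {
      if (is.null(s[[k]])) stopf("every sample needs `%s`", k)
    }
    for (k in intersect(c("counts", "positions", "rgb", "labels"), names(s))) {
      if (!file.exists(s[[k]])) stopf("sample '%s': missing file %s", s$name, s[[k]])
    }
  }
  if (is.null(config$prior) && is.null(config$gmt)) {
    stopf("config needs a `prior` edge list or a `gmt` collection")
  }
  for (k in intersect(c("prior", "gmt", "drug_targets", "lr_pairs"), names(config))) {
    if (!file.exists(config[[k]])) stopf("missing file for `%s`: %s", k, config[[k]])
  }
  config$prior_kind <- config$prior_kind %||% (if (is.null(config$gmt)) "tf" else "pathway")
  p <- default_params()
  extra <- setdiff(names(config$params), names(p))
  if (length(extra)) stopf("unknown params key(s): %s", paste(extra, collapse = ", "))
  p[names(config$params)] <- config$params
  config$params <- p
  config
}

log_stage <- function(stage, fmt = "", ...) {
  msg <- if (nzchar(fmt)) sprintf(fmt, ...) else ""
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full per-sample pipeline plus cross-sample consensus
#'
#' Orchestrates, per sample: read counts/positions (and RGB), QC filter,
#' total-count normalization, sqrt transform, feature/kernel construction,
#' prior construction, hyperparameter CV (skipped when `lambda1`/`lambda2`
#' are fixed in `params`), the activity fit, scaled activities,
#' metaprogram-differential statistics and drug scores (when labels and a
#' drug-target table are supplied), and the focal-regulator network (when
#' `focal` is set). With more than one sample, a consensus shortlist across
#' samples is written as well. Every output directory carries a JSON manifest
#' of the resolved configuration, seed and selected hyperparameters; outputs
#' are byte-identical across reruns with the same config and seed.
#'
#' @param config YAML path or list; see [read_run_config()].
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  p <- cfg$params
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  per_sample <- list()
  for (si in seq_along(cfg$samples)) {
    sc <- cfg$samples[[si]]
    sdir <- file.path(cfg$out, sc$name)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(nm, expr) {
      log_stage(paste0(sc$name, ":", nm))
      tryCatch(expr, error = function(e) {
        stopf("stage '%s' failed for sample '%s' (%s): %s",
              nm, sc$name, sc$counts, conditionMessage(e))
      })
    }
    raw <- stage("read", read_counts(sc$counts))
    positions <- stage("read", read_positions(sc$positions))
    qc <- stage("preprocess", filter_qc(raw, p$min_spots_per_gene, p$min_counts_per_spot))
    expr <- sqrt_transform(normalize_total(qc, p$target_sum))
    positions <- positions[positions$spot_id %in% spot_ids(expr), , drop = FALSE]
    expr <- subset_expr(expr, spots = positions$spot_id)
    rgb <- if (!is.null(sc$rgb)) utils::read.delim(sc$rgb, stringsAsFactors = FALSE) else NULL
    feats <- stage("kernel", spot_features(positions, rgb = rgb))
    F <- standardize_features(feats, p$morph_weight)
    prior <- stage("prior", {
      if (!is.null(cfg$prior)) {
        tf_prior(read_edge_tsv(cfg$prior), expr, p$min_gene_proportion,
                 p$min_regulators_per_gene, p$min_genes_per_regulator)
      } else {
        pathway_prior(read_gmt(cfg$gmt), expr, p$min_genes_per_regulator,
                      p$coverage_fraction)
      }
    })
    genes <- intersect(coverage_filter(expr, p$coverage_fraction), rownames(prior$M))
    Y <- t(as_dense(expr$values))[genes, , drop = FALSE]
    l1 <- p$lambda1; l2 <- p$lambda2
    if (is.null(l1) || is.null(l2)) {
      cv <- stage("cv", spotact_cv(Y, prior, F, p$grid_lambda1, p$grid_lambda2,
                                   p$n_folds, seed = cfg$seed + si,
                                   mode = p$mode, bandwidth = p$bandwidth))
      l1 <- cv$best$lambda1; l2 <- cv$best$lambda2
      utils::write.table(cv$grid, file.path(sdir, "cv_table.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    ker <- stage("kernel", rbf_kernel(F, p$bandwidth,
                                      rank = min(nrow(F), p$kernel_rank)))
    fit <- stage("fit", spotact(Y, prior, ker, l1, l2, p$mode))
    write_matrix_tsv(fit$A, file.path(sdir, "activity_total.tsv"), "regulator")
    write_matrix_tsv(fit$A_sd, file.path(sdir, "activity_spatial.tsv"), "regulator")
    write_matrix_tsv(fit$A_si, file.path(sdir, "activity_independent.tsv"), "regulator")
    scaled <- scale_activities(fit$A)
    labels <- if (!is.null(sc$labels)) read_mp_labels(sc$labels) else NULL
    diff_tab <- NULL
    if (!is.null(labels)) {
      diff_tab <- stage("mp-stats", mp_differential(
        scaled, labels, feature_kind = if (prior$kind == "tf") "tf" else "pathway",
        sample_id = sc$name))
      utils::write.table(diff_tab, file.path(sdir, "mp_differential.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    dsc <- NULL
    if (!is.null(cfg$drug_targets)) {
      dsc <- stage("drug-scores", drug_scores(expr, read_drug_targets(cfg$drug_targets)))
      write_matrix_tsv(dsc, file.path(sdir, "drug_scores.tsv"), "spot_id")
    }
    manifest <- list(sample = sc$name, seed = cfg$seed, mode = p$mode,
                     lambda1 = l1, lambda2 = l2, sigma = fit$sigma,
                     objective = fit$objective,
                     n_spots = ncol(fit$A), n_genes = nrow(Y),
                     n_regulators = nrow(fit$A),
                     package_version = as.character(utils::packageVersion("spotact")))
    jsonlite::write_json(manifest, file.path(sdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    per_sample[[sc$name]] <- list(fit = fit, scaled = scaled, expr = expr,
                                  positions = positions, labels = labels,
                                  diff = diff_tab, drugs = dsc)
  }
  # cross-sample consensus + focal network
  diffs <- Filter(Negate(is.null), lapply(per_sample, `[[`, "diff"))
  if (length(diffs) > 0) {
    all_diff <- do.call(rbind, diffs)
    cons <- consensus_select(all_diff, p$p_thresh, p$diff_thresh,
                             min(p$min_samples, length(diffs)), p$top_k)
    utils::write.table(cons, file.path(cfg$out, "consensus.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cfg$focal)) {
    log_stage("network", "focal regulator %s", cfg$focal)
    lr <- if (!is.null(cfg$lr_pairs)) read_lr_pairs(cfg$lr_pairs) else NULL
    net_samples <- lapply(per_sample, function(ps) {
      list(tf = ps$fit$A, expr = ps$expr, positions = ps$positions,
           drugs = ps$drugs)
    })
    net <- focal_network(cfg$focal, net_samples, lr_pairs = lr,
                         retain_abs_rho = p$retain_abs_rho,
                         min_expr_fraction = p$assoc_coverage_fraction,
                         k_neighbors = p$k_neighbors)
    utils::write.table(net, file.path(cfg$out, "focal_network.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    short <- display_select(net, p$top_n, p$top_n_pathways, p$strong_rho,
                            min(p$strong_min_samples, length(per_sample)))
    utils::write.table(short, file.path(cfg$out, "network_shortlist.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  resolved <- cfg
  jsonlite::write_json(resolved, file.path(cfg$out, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(cfg$out)
}
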