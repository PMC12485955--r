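#' Read a spot x gene count matrix
#'
#' Accepts either a Matrix Market triplet with sidecar id files (10x
#' convention: the `.mtx` stores genes x spots and is transposed on load;
#' `features.tsv`/`genes.tsv` holds gene ids in its first column,
#' `barcodes.tsv` the spot ids) or a dense TSV with a header row of gene ids
#' and a first column of spot ids. Gzipped files are accepted. A directory
#' path is treated as a 10x-style bundle.
#'
#' @param path path to a directory, a `.mtx`/`.mtx.gz` file, or a dense
#'   TSV/TSV.gz.
#' @return An [expr_mat] in the `"raw"` layer (sparse for MTX input, dense for
#'   TSV).
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    mtx <- first_existing(file.path(path, c("matrix.mtx", "matrix.mtx.gz")))
    if (is.null(mtx)) stopf("no matrix.mtx[.gz] under %s", path)
    return(read_counts_mtx(mtx))
  }
  if (grepl("\\.mtx(\\.gz)?$", path)) return(read_counts_mtx(path))
  read_counts_tsv(path)
}

first_existing <- function(paths) {
  hit <- paths[file.exists(paths)]
  if (length(hit)) hit[1] else NULL
}

read_counts_mtx <- function(mtx_path) {
  dir <- dirname(mtx_path)
  feat <- first_existing(file.path(dir, c("features.tsv", "features.tsv.gz",
                                          "genes.tsv", "genes.tsv.gz")))
  barc <- first_existing(file.path(dir, c("barcodes.tsv", "barcodes.tsv.gz")))
  if (is.null(feat) || is.null(barc)) {
    stopf("sidecar features/barcodes TSVs not found next to %s", mtx_path)
  }
  M <- Matrix::readMM(mtx_path)
  genes <- utils::read.delim(feat, header = FALSE, stringsAsFactors = FALSE)[[1]]
  spots <- utils::read.delim(barc, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (nrow(M) != length(genes) || ncol(M) != length(spots)) {
    stopf("MTX is %d x %d but sidecars list %d genes and %d spots",
          nrow(M), ncol(M), length(genes), length(spots))
  }
  M <- Matrix::t(M)  # 10x stores genes x spots; normalize to spot x gene
  dimnames(M) <- list(spots, genes)
  expr_mat(methods::as(M, "CsparseMatrix"), layer = "raw")
}

read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("dense counts TSV needs a spot id column plus genes")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  expr_mat(m, layer = "raw")
}

#' Write a count matrix
#'
#' `format = "mtx"` writes a 10x-style bundle (genes x spots `matrix.mtx`
#' with `features.tsv` and `barcodes.tsv`) into the directory `path`;
#' `format = "tsv"` writes a dense TSV (first column `spot_id`).
#'
#' @param x an [expr_mat].
#' @param path output directory (mtx) or file (tsv).
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expr_mat"))
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    M <- Matrix::t(methods::as(methods::as(x$values, "CsparseMatrix"), "generalMatrix"))
    Matrix::writeMM(M, file.path(path, "matrix.mtx"))
    writeLines(gene_ids(x), file.path(path, "features.tsv"))
    writeLines(spot_ids(x), file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(spot_id = spot_ids(x), as_dense(x$values),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read Visium spot positions
#'
#' Understands both Visium dialects: the headerless 6-column
#' `tissue_positions_list.csv` (`barcode, in_tissue, array_row, array_col,
#' pxl_row_in_fullres, pxl_col_in_fullres`) and the headered
#' `tissue_positions.csv`. Pixel coordinates are mapped to the generic
#' `x`/`y` columns used throughout the package (`x` = pixel column,
#' `y` = pixel row).
#'
#' @param path CSV path.
#' @param in_tissue_only drop spots with `in_tissue == 0` (default TRUE).
#' @return data frame `spot_id`, `in_tissue`, `array_row`, `array_col`, `x`,
#'   `y`, `px_row`, `px_col`.
#' @export
read_positions <- function(path, in_tissue_only = TRUE) {
  first <- readLines(path, n = 1)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) != 6) stopf("positions file has %d columns; expected 6", ncol(df))
  names(df) <- c("spot_id", "in_tissue", "array_row", "array_col",
                 "px_row", "px_col")
  if (in_tissue_only && any(df$in_tissue == 0)) df <- df[df$in_tissue == 1, ]
  df$x <- as.numeric(df$px_col)
  df$y <- as.numeric(df$px_row)
  rownames(df) <- NULL
  df[, c("spot_id", "in_tissue", "array_row", "array_col", "x", "y",
         "px_row", "px_col")]
}

#' Write spot positions in the headerless Visium dialect
#' @param positions data frame as produced by [sim_grid()] or
#'   [read_positions()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_positions <- function(positions, path) {
  df <- data.frame(positions$spot_id, positions$in_tissue %||% 1L,
                   positions$array_row, positions$array_col,
                   positions$px_row, positions$px_col)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines `name<TAB>description<TAB>gene1<TAB>gene2...`; CRLF
#' endings tolerated; duplicate genes within a set counted once.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stopf("GMT file %s is empty", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line %d: fewer than 3 fields", i)
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  sets
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a regulator-target edge list
#'
#' TSV with columns `regulator`/`tf` and `target` (an optional `weight`
#' column is kept). Duplicate edges are dropped with a warning.
#'
#' @param path TSV path.
#' @return data frame `regulator`, `target` (and `weight` when present).
#' @export
read_edge_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stopf("edge list %s is empty", path)
  names(df) <- tolower(names(df))
  if ("tf" %in% names(df) && !"regulator" %in% names(df)) {
    names(df)[names(df) == "tf"] <- "regulator"
  }
  if (!all(c("regulator", "target") %in% names(df))) {
    stopf("edge list needs columns regulator (or tf) and target")
  }
  dup <- duplicated(df[, c("regulator", "target")])
  if (any(dup)) {
    warnf("dropping %d duplicate edge(s)", sum(dup))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a ligand-receptor pair table
#'
#' Accepts the package's own `ligand_gene`/`receptor_gene` columns and the
#' CellTalkDB-style `ligand_gene_symbol`/`receptor_gene_symbol`.
#'
#' @param path TSV path.
#' @return data frame `ligand_gene`, `receptor_gene`.
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stopf("ligand-receptor table %s is empty", path)
  names(df) <- sub("_symbol$", "", tolower(names(df)))
  if (!all(c("ligand_gene", "receptor_gene") %in% names(df))) {
    stopf("ligand-receptor table needs ligand_gene and receptor_gene columns")
  }
  df[, c("ligand_gene", "receptor_gene")]
}

#' Read a drug-target table
#'
#' TSV with one row per drug-target pair: `drug_id`, `drug_name`,
#' `target_gene`.
#'
#' @param path TSV path.
#' @return data frame with those columns.
#' @export
read_drug_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stopf("drug-target table %s is empty", path)
  names(df) <- tolower(names(df))
  if (!all(c("drug_id", "target_gene") %in% names(df))) {
    stopf("drug-target table needs drug_id and target_gene columns")
  }
  if (!"drug_name" %in% names(df)) df$drug_name <- df$drug_id
  df[, c("drug_id", "drug_name", "target_gene")]
}

#' Read a spot-to-metaprogram label table
#'
#' TSV with columns `spot_id`, `mp_label` (optional `sample_id`).
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_mp_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("spot_id", "mp_label") %in% names(df))) {
    stopf("label table needs spot_id and mp_label columns")
  }
  df
}

#' Write a named matrix as TSV with an explicit id column
#' @param m matrix with row names.
#' @param path output path.
#' @param id_col name of the id column (default `"id"`).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), as_dense(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a complete synthetic sample directory
#'
#' Serializes a [sim_sample()] fixture as the plain-text inputs the pipeline
#' reads back: counts MTX bundle, positions CSV (headerless Visium dialect),
#' RGB TSV, TF-target edge TSV derived from the ground-truth prior, labels,
#' drug-target and ligand-receptor TSVs, and a ground-truth JSON.
#'
#' @param sample a [sim_sample()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sample$counts, file.path(dir, "counts"), format = "mtx")
  write_positions(sample$positions, file.path(dir, "tissue_positions_list.csv"))
  utils::write.table(sample$rgb, file.path(dir, "spot_rgb.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  M <- sample$prior$M
  idx <- which(M != 0, arr.ind = TRUE)
  edges <- data.frame(regulator = colnames(M)[idx[, 2]],
                      target = rownames(M)[idx[, 1]], stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$target), ]
  utils::write.table(edges, file.path(dir, "tf_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sample$labels, file.path(dir, "mp_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sample$drug_map, file.path(dir, "drug_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sample$lr_pairs, file.path(dir, "lr_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(A = sample$truth$A, A_sd = sample$truth$A_sd,
                A_si = sample$truth$A_si, params = sample$params)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(dir)
}
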