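# Domain containers and file I/O shared by every analysis stage.
#
# Expression is held as a plain numeric matrix (genes x samples) wrapped in a
# light S3 object carrying its scale ("linear", "log2" or "standardized").
# Missing values are NA in memory and empty cells on disk.

.EM_SCALES <- c("linear", "log2", "standardized")
.PAIR_NAMES <- c("R_T", "SI_IM1")

#' Construct an expression matrix
#'
#' Wraps a numeric genes x samples matrix together with the scale its values
#' live on. Gene and sample identifiers are taken from the dimnames and are
#' treated as opaque, case-sensitive strings; both must be unique.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   complete dimnames. `NA` marks a missing measurement.
#' @param scale One of `"linear"` (FPKM-like counts), `"log2"`, or
#'   `"standardized"` (after sample/gene standardization).
#' @return An object of class `ExpressionMatrix` with fields `values` and
#'   `scale`.
#' @export
expression_matrix <- function(values, scale = c("linear", "log2", "standardized")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicated gene identifiers: ", paste(utils::head(dup_g, 5), collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicated sample identifiers: ", paste(utils::head(dup_s, 5), collapse = ", "))
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s scale], %.2f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Construct a gene-weight map for a program pair
#'
#' Holds the predefined per-gene weights of a program of interest (R or SI)
#' and its confounder (T or IM1). These weight vectors are external inputs;
#' the package never re-derives them.
#'
#' @param gene_ids Character vector of unique gene identifiers.
#' @param confounder_weights Numeric weights of the confounder program
#'   (V_T for the R_T pair, V_IM1 for the SI_IM1 pair).
#' @param program_weights Numeric weights of the program of interest
#'   (V_R or V_SI).
#' @param pair_name `"R_T"` or `"SI_IM1"`.
#' @param min_genes Minimum number of genes required (default 50); inference
#'   with fewer genes would be unstable.
#' @return A `GeneWeightMap` object.
#' @export
gene_weight_map <- function(gene_ids, confounder_weights, program_weights,
                            pair_name = c("R_T", "SI_IM1"), min_genes = 50L) {
  pair_name <- match.arg(pair_name)
  gene_ids <- as.character(gene_ids)
  n <- length(gene_ids)
  if (n < min_genes)
    stop(sprintf("too few genes: %d < %d", n, min_genes))
  if (anyDuplicated(gene_ids))
    stop("duplicated genes in weight map: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5), collapse = ", "))
  if (length(confounder_weights) != n || length(program_weights) != n)
    stop("weight vectors must match the number of genes")
  if (!all(is.finite(confounder_weights)) || !all(is.finite(program_weights)))
    stop("non-finite weights in weight map")
  structure(list(gene_ids = gene_ids,
                 confounder_weights = as.numeric(confounder_weights),
                 program_weights = as.numeric(program_weights),
                 pair_name = pair_name),
            class = "GeneWeightMap")
}

#' @export
print.GeneWeightMap <- function(x, ...) {
  cat(sprintf("GeneWeightMap [%s]: %d genes\n", x$pair_name, length(x$gene_ids)))
  invisible(x)
}

#' Validate a sample metadata table
#'
#' @param df Data frame with at least `sample_id` and `condition` columns;
#'   condition must be one of healthy, moderate_infection, sepsis, other.
#'   Optional columns: `dataset_id`, `age`, `sex`, `timepoint`.
#' @return The validated data frame (class `SampleTable` prepended).
#' @export
sample_table <- function(df) {
  df <- as.data.frame(df)
  if (!all(c("sample_id", "condition") %in% names(df)))
    stop("sample table needs `sample_id` and `condition` columns")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in sample table")
  ok <- c("healthy", "moderate_infection", "sepsis", "other")
  bad <- setdiff(unique(df$condition), ok)
  if (length(bad))
    stop("unknown condition labels: ", paste(bad, collapse = ", "))
  if (anyNA(df$condition))
    stop("condition missing for some samples")
  class(df) <- c("SampleTable", class(df))
  df
}

#' Construct a one-to-one homolog map
#'
#' @param source_gene,target_gene Equal-length character vectors; no source or
#'   target may appear twice (strict one-to-one mapping, as for MGI one-to-one
#'   mouse-human homolog lists).
#' @return A `HomologMap` data frame.
#' @export
homolog_map <- function(source_gene, target_gene) {
  source_gene <- as.character(source_gene)
  target_gene <- as.character(target_gene)
  if (length(source_gene) != length(target_gene))
    stop("source and target vectors differ in length")
  if (anyDuplicated(source_gene))
    stop("homolog map is not one-to-one: duplicated source gene")
  if (anyDuplicated(target_gene))
    stop("homolog map is not one-to-one: duplicated target gene")
  structure(data.frame(source_gene = source_gene, target_gene = target_gene,
                       stringsAsFactors = FALSE),
            class = c("HomologMap", "data.frame"))
}

#' Bundle the tables of one cohort
#'
#' @param expression An `ExpressionMatrix`.
#' @param samples A `SampleTable` covering the expression samples.
#' @param proteins Optional samples x proteins numeric matrix (NPX-like log2
#'   scale), rownames = sample ids.
#' @param survival Optional data frame with `sample_id`, `time_days`, `event`
#'   and optionally `age`, `sex`.
#' @return A `CohortBundle` list.
#' @export
cohort_bundle <- function(expression, samples, proteins = NULL, survival = NULL) {
  stopifnot(inherits(expression, "ExpressionMatrix"))
  samples <- sample_table(samples)
  sid <- sample_ids(expression)
  if (!all(sid %in% samples$sample_id))
    stop("expression samples missing from sample table")
  if (!is.null(proteins)) {
    if (is.null(rownames(proteins)) || !all(rownames(proteins) %in% samples$sample_id))
      stop("protein table rows must be sample ids present in the sample table")
  }
  if (!is.null(survival)) {
    if (!all(c("sample_id", "time_days", "event") %in% names(survival)))
      stop("survival table needs sample_id, time_days, event")
    if (!all(survival$sample_id %in% samples$sample_id))
      stop("survival table contains unknown sample ids")
  }
  structure(list(expression = expression, samples = samples,
                 proteins = proteins, survival = survival),
            class = "CohortBundle")
}

# ---- readers / writers -----------------------------------------------------

.read_table <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          na.strings = c("NA", ""))
  df
}

#' Read an expression matrix from disk
#'
#' TSV/CSV layout: first column gene id, header row sample ids, empty cells
#' are missing. MTX triplet layout: MatrixMarket matrix plus `features.tsv`
#' and `barcodes.tsv` companions (cells become columns). For linear-scale
#' input, zeros are converted to missing values, matching the bulk
#' preprocessing policy; pass `scale_hint = "log2"` for already-log
#' microarray data, where zeros are meaningful and kept.
#'
#' @param path File path (for `mtx_triplet`, the `.mtx` file).
#' @param format `"tsv"`, `"csv"`, or `"mtx_triplet"`.
#' @param scale_hint Scale of the stored values, `"linear"` or `"log2"`.
#' @param features,barcodes Companion files for `mtx_triplet`; default to
#'   `features.tsv` / `barcodes.tsv` next to the matrix.
#' @param zero_as_missing Whether zeros become `NA`; defaults to `TRUE` only
#'   for linear scale. Single-cell counts should keep zeros
#'   (`zero_as_missing = FALSE`).
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, format = c("tsv", "csv", "mtx_triplet"),
                            scale_hint = c("linear", "log2"),
                            features = NULL, barcodes = NULL,
                            zero_as_missing = NULL) {
  format <- match.arg(format)
  scale_hint <- match.arg(scale_hint)
  if (is.null(zero_as_missing))
    zero_as_missing <- (scale_hint == "linear" && format != "mtx_triplet")
  if (!file.exists(path)) stop("file not found: ", path)

  if (format == "mtx_triplet") {
    dirn <- dirname(path)
    if (is.null(features)) features <- file.path(dirn, "features.tsv")
    if (is.null(barcodes)) barcodes <- file.path(dirn, "barcodes.tsv")
    if (!file.exists(features) || !file.exists(barcodes))
      stop("mtx_triplet requires matrix, features and barcodes files")
    m <- as.matrix(Matrix::readMM(path))
    feat <- utils::read.table(features, header = FALSE, sep = "\t",
                              stringsAsFactors = FALSE)[[1]]
    bc <- utils::read.table(barcodes, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(feat) || ncol(m) != length(bc))
      stop("mtx dimensions do not match features/barcodes")
    dimnames(m) <- list(feat, bc)
    if (zero_as_missing) m[m == 0] <- NA_real_
    return(expression_matrix(m, scale = scale_hint))
  }

  sep <- if (format == "tsv") "\t" else ","
  df <- .read_table(path, sep)
  if (ncol(df) < 2) stop("malformed header: need gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicated gene row: ",
         paste(utils::head(unique(genes[duplicated(genes)]), 5), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad))
        stop(sprintf("non-numeric cell at gene '%s', column '%s'",
                     genes[bad[1]], names(vals)[j]))
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (zero_as_missing) m[!is.na(m) & m == 0] <- NA_real_
  expression_matrix(m, scale = scale_hint)
}

#' Write an expression matrix as TSV
#'
#' First column `gene_id`, then one column per sample; missing values become
#' empty cells. Uses a fixed decimal format so write/read round-trips are
#' exact.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @param digits Significant digits for formatting (default 17, enough for an
#'   exact double round-trip).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, digits = 17) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  chr <- formatC(x$values, digits = digits, format = "g")
  chr[is.na(x$values)] <- NA_character_
  dim(chr) <- dim(x$values)
  df <- data.frame(gene_id = gene_ids(x), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene_id", sample_ids(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  message(sprintf("wrote %s: %d genes x %d samples", path, nrow(x$values), ncol(x$values)))
  invisible(path)
}

#' Read a gene-weight table
#'
#' Expects three columns: gene id, confounder weight, program weight
#' (tab-separated, with header).
#'
#' @param path TSV path.
#' @param pair_name `"R_T"` or `"SI_IM1"`.
#' @return A `GeneWeightMap`.
#' @export
read_gene_weights <- function(path, pair_name = c("R_T", "SI_IM1")) {
  pair_name <- match.arg(pair_name)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- .read_table(path, "\t")
  if (ncol(df) < 3)
    stop("gene-weight table needs 3 columns: gene, confounder weight, program weight")
  gene_weight_map(df[[1]], df[[2]], df[[3]], pair_name = pair_name)
}

#' Write a gene-weight table
#' @param w A `GeneWeightMap`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_weights <- function(w, path) {
  stopifnot(inherits(w, "GeneWeightMap"))
  df <- data.frame(gene_id = w$gene_ids,
                   confounder_weight = w$confounder_weights,
                   program_weight = w$program_weights)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rename genes through a one-to-one homolog map
#'
#' Genes without a mapping are dropped; values of retained genes are kept
#' exactly. Used to carry mouse expression onto human gene-weight maps (or
#' vice versa).
#'
#' @param x An `ExpressionMatrix`.
#' @param hmap A `HomologMap`.
#' @return An `ExpressionMatrix` with target gene names.
#' @export
map_homologs <- function(x, hmap) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(hmap, "HomologMap"))
  idx <- match(gene_ids(x), hmap$source_gene)
  keep <- !is.na(idx)
  if (!any(keep)) {
    warning("no genes overlap the homolog map; result is empty")
    m <- x$values[keep, , drop = FALSE]
    rownames(m) <- character(0)
    out <- x
    out$values <- m
    return(out)
  }
  m <- x$values[keep, , drop = FALSE]
  rownames(m) <- hmap$target_gene[idx[keep]]
  expression_matrix(m, scale = x$scale)
}

#' Restrict an expression matrix and a weight map to their shared genes
#'
#' Both outputs are ordered identically. The usable gene count depends on
#' which weight-map genes were actually measured, so the intersection can be
#' smaller than either input.
#'
#' @param x An `ExpressionMatrix`.
#' @param w A `GeneWeightMap`.
#' @param min_overlap Minimum shared genes (default 50) below which program
#'   inference would be unstable.
#' @return List with `expression`, `weights` and `n_shared`.
#' @export
align_genes <- function(x, w, min_overlap = 50L) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(w, "GeneWeightMap"))
  shared <- intersect(gene_ids(x), w$gene_ids)
  if (length(shared) < min_overlap)
    stop(sprintf("gene overlap too small for inference: %d < %d",
                 length(shared), min_overlap))
  xi <- x
  xi$values <- x$values[shared, , drop = FALSE]
  wi <- match(shared, w$gene_ids)
  ws <- gene_weight_map(shared, w$confounder_weights[wi], w$program_weights[wi],
                        pair_name = w$pair_name, min_genes = min_overlap)
  list(expression = xi, weights = ws, n_shared = length(shared))
}
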