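# Benchmarking of candidate transcriptional programs: disease-response rank
# statistics per dataset, a local cross-dataset covariation ranking (a
# documented stand-in for the remote SEEK co-expression service -- the F1
# layer is agnostic to the ranking source), and the covariation-F1 score that
# measures how well a program's ranking retrieves a labelled dataset class.

#' Define a candidate program
#'
#' @param name Program name.
#' @param mode `"geneset"` (unweighted member list, >= 10 genes) or
#'   `"gene_weights"` (wraps a `GeneWeightMap`).
#' @param genes Character vector of member genes (geneset mode).
#' @param weights A `GeneWeightMap` (gene_weights mode).
#' @return A `ProgramDef` object.
#' @export
program_def <- function(name, mode = c("geneset", "gene_weights"),
                        genes = NULL, weights = NULL) {
  mode <- match.arg(mode)
  if (mode == "geneset") {
    genes <- unique(as.character(genes))
    if (length(genes) < 10) stop("geneset programs need >= 10 genes")
  } else {
    if (!inherits(weights, "GeneWeightMap"))
      stop("gene_weights mode needs a GeneWeightMap")
  }
  structure(list(name = name, mode = mode, genes = genes, weights = weights),
            class = "ProgramDef")
}

#' Top-weight geneset of a weighted program
#'
#' Converts a gene-weights program to a geneset by taking the `n` genes with
#' the largest program weights, the convention used when a continuous
#' weighting must serve as a co-expression query set.
#'
#' @param w A `GeneWeightMap`.
#' @param n Number of genes (default 100).
#' @return Character vector of gene ids.
#' @export
top_weight_geneset <- function(w, n = 100L) {
  stopifnot(inherits(w, "GeneWeightMap"))
  n <- min(n, length(w$gene_ids))
  w$gene_ids[order(w$program_weights, decreasing = TRUE)[seq_len(n)]]
}

#' Per-sample level of a candidate program
#'
#' Geneset programs are scored by averaging the member genes per sample
#' (over observed members); gene-weights programs delegate to
#' [infer_program_levels()].
#'
#' @param program A `ProgramDef`.
#' @param z Standardized `ExpressionMatrix`.
#' @param min_genes Minimum member genes that must be present (default 5,
#'   geneset mode).
#' @return Named numeric vector of per-sample levels.
#' @export
program_level_simple <- function(program, z, min_genes = 5L) {
  stopifnot(inherits(program, "ProgramDef"), inherits(z, "ExpressionMatrix"))
  if (program$mode == "gene_weights") {
    lv <- infer_program_levels(z, program$weights)
    return(stats::setNames(lv$s_program, lv$sample_id))
  }
  present <- intersect(program$genes, gene_ids(z))
  if (length(present) < min_genes)
    stop(sprintf("only %d program genes present (< %d)", length(present), min_genes))
  colMeans(z$values[present, , drop = FALSE], na.rm = TRUE)
}

#' Signed rank-based disease-response statistic
#'
#' Two-sample Mann-Whitney statistic comparing program levels between disease
#' and healthy samples, standardized to a z score (tie-corrected normal
#' approximation) and signed positive for upregulation in disease. The
#' comparison is between independent groups, so the two-sample rank-sum form
#' of the Wilcoxon family is the applicable one.
#'
#' @param levels Named numeric vector of per-sample program levels.
#' @param labels Character/logical vector aligned with `levels`; `TRUE` or
#'   `"disease"` marks disease samples, rest are healthy.
#' @param min_per_group Minimum samples per group (default 3).
#' @return Signed z statistic (attribute `"p_value"`: two-sided normal p).
#' @export
response_score <- function(levels, labels, min_per_group = 3L) {
  if (is.character(labels)) labels <- labels == "disease"
  d <- levels[labels]
  h <- levels[!labels]
  if (length(d) < min_per_group || length(h) < min_per_group)
    stop("need >= ", min_per_group, " samples in each group")
  n1 <- length(d); n2 <- length(h); n <- n1 + n2
  r <- rank(c(d, h))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 == 0) 0 else (U - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  structure(z, p_value = p)
}

#' Rank datasets by the covariation of a program's genes
#'
#' For each dataset the covariation statistic is the mean pairwise Pearson
#' correlation among the program's genes, z-scored against `n_random`
#' size-matched random gene sets drawn from the same dataset. Datasets are
#' ranked by decreasing z. This local statistic stands in for a remote
#' co-expression retrieval engine; externally computed rankings can be fed
#' to [covariation_f1()] directly.
#'
#' @param program A `ProgramDef` (gene_weights programs are converted to
#'   their [top_weight_geneset()]).
#' @param datasets Named list of `ExpressionMatrix` objects (>= 2).
#' @param n_random Random gene sets per dataset for the z-score (default 50).
#' @param seed RNG seed.
#' @param min_genes Minimum program genes a dataset must contain (default 5);
#'   datasets below it are ranked last with a missing statistic and a warning.
#' @return Data frame (class `DatasetRanking`) with `dataset_id`,
#'   `covariation_z`, `rank`, ordered by rank; ties keep input order and are
#'   flagged in the `tied` column.
#' @export
dataset_covariation_rank <- function(program, datasets, n_random = 50L,
                                     seed = 1L, min_genes = 5L) {
  stopifnot(inherits(program, "ProgramDef"))
  if (length(datasets) < 2) stop("need >= 2 datasets to rank")
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset_", seq_along(datasets))
  gset <- if (program$mode == "geneset") program$genes else
    top_weight_geneset(program$weights)
  mean_pair_cor <- function(m) {
    cc <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
    mean(cc[upper.tri(cc)], na.rm = TRUE)
  }
  set.seed(seed)
  zstat <- vapply(names(datasets), function(id) {
    z <- datasets[[id]]
    present <- intersect(gset, gene_ids(z))
    if (length(present) < min_genes) {
      warning(sprintf("dataset %s has %d program genes (< %d); ranked last",
                      id, length(present), min_genes))
      return(NA_real_)
    }
    real <- mean_pair_cor(z$values[present, , drop = FALSE])
    null <- vapply(seq_len(n_random), function(r) {
      rs <- sample(gene_ids(z), length(present))
      mean_pair_cor(z$values[rs, , drop = FALSE])
    }, numeric(1))
    sd0 <- stats::sd(null)
    if (is.na(sd0) || sd0 == 0) return(NA_real_)
    (real - mean(null)) / sd0
  }, numeric(1))
  ord <- order(-zstat, na.last = TRUE)  # stable for ties (input order)
  out <- data.frame(dataset_id = names(datasets)[ord],
                    covariation_z = zstat[ord],
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$tied <- duplicated(out$covariation_z) |
    duplicated(out$covariation_z, fromLast = TRUE)
  out$tied[is.na(out$covariation_z)] <- FALSE
  class(out) <- c("DatasetRanking", class(out))
  out
}

#' Covariation-F1 score of a dataset ranking
#'
#' For each positive dataset's rank c, predicted positives are the datasets
#' ranked at or above c; precision = TP / c, recall = TP / (number of actual
#' positives), F1 their harmonic mean. The score is the mean F1 across the
#' positives' cutoffs. A perfect ranking (all positives on top) scores 1.
#'
#' @param ranking A `DatasetRanking`, or a character vector of dataset ids in
#'   rank order (externally supplied rankings are accepted verbatim).
#' @param positives Character vector of dataset ids forming the positive
#'   class (e.g., the sepsis datasets).
#' @return The mean-F1 score in `[0, 1]`; attribute `"per_cutoff"` holds the
#'   per-positive cutoff table.
#' @export
covariation_f1 <- function(ranking, positives) {
  ids <- if (inherits(ranking, "DatasetRanking")) ranking$dataset_id else
    as.character(ranking)
  if (anyDuplicated(ids)) stop("ranking contains duplicated dataset ids")
  positives <- unique(as.character(positives))
  if (!length(positives)) stop("need >= 1 positive dataset")
  if (!all(positives %in% ids)) stop("positives missing from the ranking")
  pos_rank <- sort(match(positives, ids))
  n_pos <- length(positives)
  tab <- lapply(pos_rank, function(c0) {
    tp <- sum(pos_rank <= c0)
    prec <- tp / c0
    rec <- tp / n_pos
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(cutoff = c0, tp = tp, precision = prec, recall = rec, f1 = f1)
  })
  tab <- do.call(rbind, tab)
  structure(mean(tab$f1), per_cutoff = tab)
}

#' Benchmark a set of candidate programs
#'
#' Computes, per program: the signed response score in each labelled
#' response dataset, and the covariation-F1 scores for the sepsis and
#' infection dataset classes from a shared covariation ranking.
#'
#' @param programs List of `ProgramDef`s.
#' @param response_data Named list of lists, each with `z` (standardized
#'   `ExpressionMatrix`) and `disease` (logical per sample).
#' @param datasets Named list of `ExpressionMatrix` for covariation ranking.
#' @param sepsis_ids,infection_ids Dataset ids of the two positive classes.
#' @param seed RNG seed for the covariation null.
#' @return Data frame with one row per program: response scores (one column
#'   per response dataset) plus `covariation_sepsis_f1` and
#'   `covariation_infections_f1`.
#' @export
benchmark_programs <- function(programs, response_data, datasets,
                               sepsis_ids, infection_ids, seed = 1L) {
  rows <- lapply(programs, function(pr) {
    resp <- vapply(response_data, function(rd) {
      lv <- program_level_simple(pr, rd$z)
      as.numeric(response_score(lv, rd$disease))
    }, numeric(1))
    rk <- dataset_covariation_rank(pr, datasets, seed = seed)
    out <- data.frame(program_name = pr$name, t(resp),
                      covariation_sepsis_f1 = as.numeric(covariation_f1(rk, sepsis_ids)),
                      covariation_infections_f1 = as.numeric(covariation_f1(rk, infection_ids)),
                      stringsAsFactors = FALSE)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
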