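# Phenotype and protein association with the R and SI levels: permutation-
# tested explained variance, 2D correlation maps, cross-cohort balance-marker
# ranking, and hypergeometric gene-set enrichment with BH correction.

#' Variance in a phenotype explained by R and/or SI levels
#'
#' OLS of the phenotype on the selected level columns (SI-only, R-only, or
#' the joint linear combination), with an empirical p obtained by permuting
#' the phenotype across samples. Optional covariate columns are adjusted for
#' by including them in both real and permuted fits.
#'
#' @param phenotype Named numeric vector (names = sample ids) or unnamed
#'   vector aligned with `levels`.
#' @param levels `ProgramLevels` with `z_R`, `z_SI`.
#' @param model `"SI_only"`, `"R_only"` or `"joint"`.
#' @param n_perm Permutations (default 1000).
#' @param seed RNG seed.
#' @param covariates Optional numeric matrix of extra columns (default none).
#' @param min_n Minimum complete samples (default 20).
#' @return One-row data frame with `model`, `r2`, `empirical_p`, `n`.
#' @export
variance_explained <- function(phenotype, levels,
                               model = c("joint", "SI_only", "R_only"),
                               n_perm = 1000L, seed = 1L, covariates = NULL,
                               min_n = 20L) {
  model <- match.arg(model)
  stopifnot(all(c("z_R", "z_SI") %in% names(levels)))
  if (!is.null(names(phenotype))) {
    idx <- match(levels$sample_id, names(phenotype))
    phenotype <- phenotype[idx]
  } else if (length(phenotype) != nrow(levels)) {
    stop("unnamed phenotype must align with the levels table")
  }
  X <- switch(model,
              SI_only = cbind(z_SI = levels$z_SI),
              R_only  = cbind(z_R = levels$z_R),
              joint   = cbind(z_R = levels$z_R, z_SI = levels$z_SI))
  if (!is.null(covariates)) X <- cbind(X, covariates)
  ok <- stats::complete.cases(phenotype, X)
  y <- phenotype[ok]; X <- X[ok, , drop = FALSE]
  if (length(y) < min_n) stop("fewer than ", min_n, " complete samples")
  if (stats::sd(y) == 0) stop("constant phenotype")
  real <- .r2_p(y, X)["r2"]
  set.seed(seed)
  Yp <- vapply(seq_len(n_perm), function(p) y[sample.int(length(y))],
               numeric(length(y)))
  null <- .r2_many(Yp, X)
  data.frame(model = model, r2 = as.numeric(real),
             empirical_p = (1 + sum(null >= real)) / (1 + n_perm),
             n = length(y), stringsAsFactors = FALSE)
}

#' 2D correlation map of features against SI and R levels
#'
#' Per feature (protein or gene), Pearson correlation with the standardized
#' SI and R levels across samples. The (r_SI, r_R) pairs form the 2D map in
#' which, e.g., inflammation markers sit right of the diagonal (SI-dominant)
#' and immune-activation markers above it (R-dominant).
#'
#' @param feature_table Samples x features numeric matrix, rownames = sample
#'   ids matching `levels$sample_id`.
#' @param levels `ProgramLevels` with `z_R`, `z_SI`.
#' @param min_n Minimum pairwise-complete samples per feature (default 10);
#'   features below it are skipped with a message.
#' @return Data frame (class `CorrelationMap2D`) with `feature_id`, `r_SI`,
#'   `r_R`, `n_used`.
#' @export
correlation_map <- function(feature_table, levels, min_n = 10L) {
  stopifnot(all(c("z_R", "z_SI") %in% names(levels)))
  shared <- intersect(levels$sample_id, rownames(feature_table))
  ft <- feature_table[shared, , drop = FALSE]
  li <- match(shared, levels$sample_id)
  zr <- levels$z_R[li]; zs <- levels$z_SI[li]
  rows <- lapply(colnames(ft), function(f) {
    v <- ft[, f]
    obs <- !is.na(v)
    if (sum(obs) < min_n || stats::sd(v[obs]) == 0) {
      message("correlation_map: skipping feature ", f)
      return(NULL)
    }
    data.frame(feature_id = f,
               r_SI = stats::cor(v[obs], zs[obs]),
               r_R = stats::cor(v[obs], zr[obs]),
               n_used = sum(obs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("CorrelationMap2D", class(out))
  out
}

#' Rank genes as markers of the R/SI-balance score across cohorts
#'
#' Per cohort, every gene's Pearson correlation with the balance score across
#' individuals; the unweighted mean of these correlations across cohorts
#' ranks the genes. Genes with mean correlation above `good_thresh` mark a
#' good balance, below `impaired_thresh` an impaired balance (both
#' exclusive). Within each direction, the `top_n` markers are chosen by the
#' correlation in the designated monocyte cohort (descending for good,
#' ascending for impaired).
#'
#' @param cohorts Named list; each element a list with `expression`
#'   (standardized `ExpressionMatrix`) and `levels` (`ProgramLevels` with
#'   `balance`).
#' @param monocyte_cohort_id Name of the monocyte cohort (must be present).
#' @param good_thresh,impaired_thresh Mean-correlation thresholds (defaults
#'   0.6 and -0.45).
#' @param top_n Marker-set size cap per direction (default 300).
#' @return Data frame (class `MarkerRanking`) with `gene_id`,
#'   `mean_r_balance`, one `r_<cohort>` column per cohort, `n_cohorts_used`,
#'   `selected_good`, `selected_impaired`, `top_good`, `top_impaired`.
#' @export
rank_balance_markers <- function(cohorts, monocyte_cohort_id,
                                 good_thresh = 0.6, impaired_thresh = -0.45,
                                 top_n = 300L) {
  if (length(cohorts) < 2) stop("need >= 2 cohorts")
  if (!monocyte_cohort_id %in% names(cohorts))
    stop("monocyte cohort not among the cohorts: ", monocyte_cohort_id)
  per_cohort <- lapply(cohorts, function(co) {
    z <- co$expression; lev <- co$levels
    bal <- lev$balance[match(sample_ids(z), lev$sample_id)]
    vapply(gene_ids(z), function(g) {
      v <- z$values[g, ]
      obs <- !is.na(v) & !is.na(bal)
      if (sum(obs) < 3 || stats::sd(v[obs]) == 0) return(NA_real_)
      stats::cor(v[obs], bal[obs])
    }, numeric(1))
  })
  all_genes <- sort(unique(unlist(lapply(per_cohort, names))))
  rmat <- sapply(per_cohort, function(r) r[all_genes])
  rownames(rmat) <- all_genes
  mean_r <- rowMeans(rmat, na.rm = TRUE)
  n_used <- rowSums(!is.na(rmat))
  out <- data.frame(gene_id = all_genes, mean_r_balance = mean_r,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (cn in colnames(rmat)) out[[paste0("r_", cn)]] <- rmat[, cn]
  out$n_cohorts_used <- n_used
  out$selected_good <- !is.na(mean_r) & mean_r > good_thresh
  out$selected_impaired <- !is.na(mean_r) & mean_r < impaired_thresh
  mono <- rmat[, monocyte_cohort_id]
  pick_top <- function(sel, decreasing) {
    flag <- rep(FALSE, nrow(out))
    idx <- which(sel)
    if (!length(idx)) return(flag)
    ord <- idx[order(mono[idx], decreasing = decreasing, na.last = TRUE)]
    flag[ord[seq_len(min(top_n, length(ord)))]] <- TRUE
    flag
  }
  out$top_good <- pick_top(out$selected_good, decreasing = TRUE)
  out$top_impaired <- pick_top(out$selected_impaired, decreasing = FALSE)
  class(out) <- c("MarkerRanking", class(out))
  out
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' Upper-tail hypergeometric test of each collection set against the marker
#' set within the universe, with Benjamini-Hochberg q-values across all
#' tested sets.
#'
#' @param markers Character vector of marker genes (must lie in `universe`).
#' @param collections Named list of character vectors (gene sets, e.g., read
#'   with [read_gmt()]); each set is intersected with the universe.
#' @param universe Character vector of all candidate genes.
#' @return Data frame with `set_name`, `set_size`, `overlap`, `p`, `q_BH`.
#' @export
hypergeom_enrich <- function(markers, collections, universe) {
  universe <- unique(as.character(universe))
  markers <- unique(as.character(markers))
  if (!length(universe)) stop("empty universe")
  if (!length(markers)) stop("empty marker set")
  if (!all(markers %in% universe))
    stop("markers must be a subset of the universe")
  N <- length(universe); n <- length(markers)
  rows <- lapply(names(collections), function(nm) {
    set <- intersect(unique(collections[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, markers))
    # P(X >= k), X ~ Hypergeometric(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_BH <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Read gene-set collections in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}
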