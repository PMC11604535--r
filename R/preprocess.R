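# Four-step bulk preprocessing applied before program inference:
# 1) missing-data policy (regime by overall missing fraction, >75% gene drop,
#    KNN imputation with k = 5), 2) log2 transform, 3) per-sample
# standardization across genes, 4) per-gene standardization anchored on the
# healthy controls. All standard deviations are population SDs (divide by n).

#' Preprocessing configuration
#'
#' @param low_missing_frac Overall missing fraction below which any gene with
#'   a missing value is simply dropped (default 0.01).
#' @param mid_missing_frac Overall missing fraction below which genes with
#'   heavy missingness are dropped and the rest KNN-imputed (default 0.15);
#'   above it, heavy genes are dropped and no imputation is done.
#' @param gene_drop_frac Per-gene missing fraction above which the gene is
#'   dropped in the medium/high regimes (default 0.75).
#' @param knn_k Neighbours for KNN imputation (default 5).
#' @param treat_zero_as_missing Convert zeros to missing on linear scale
#'   (default TRUE).
#' @param already_log Input is already log scale: skip the log2 step and keep
#'   zeros as data (default FALSE).
#' @return A `PreprocessConfig` list.
#' @export
preprocess_config <- function(low_missing_frac = 0.01, mid_missing_frac = 0.15,
                              gene_drop_frac = 0.75, knn_k = 5L,
                              treat_zero_as_missing = TRUE, already_log = FALSE) {
  if (!(low_missing_frac > 0 && low_missing_frac < mid_missing_frac && mid_missing_frac < 1))
    stop("need 0 < low_missing_frac < mid_missing_frac < 1")
  if (!(gene_drop_frac > 0 && gene_drop_frac < 1)) stop("gene_drop_frac must be in (0,1)")
  if (knn_k < 1) stop("knn_k must be >= 1")
  structure(list(low_missing_frac = low_missing_frac,
                 mid_missing_frac = mid_missing_frac,
                 gene_drop_frac = gene_drop_frac,
                 knn_k = as.integer(knn_k),
                 treat_zero_as_missing = isTRUE(treat_zero_as_missing),
                 already_log = isTRUE(already_log)),
            class = "PreprocessConfig")
}

.pop_sd <- function(v) {
  v <- v[!is.na(v)]
  sqrt(mean((v - mean(v))^2))
}

#' Missing-data policy (preprocessing step 1)
#'
#' The regime is chosen by the overall missing fraction m of the matrix:
#' below `low_missing_frac`, any gene with at least one missing value is
#' removed; between `low_missing_frac` and `mid_missing_frac`, genes missing
#' in more than `gene_drop_frac` of samples are removed and the remaining
#' holes are KNN-imputed (k = `knn_k`); at or above `mid_missing_frac`, heavy
#' genes are removed and the remaining holes are left missing (they are
#' excluded pairwise downstream).
#'
#' @param x An `ExpressionMatrix` (zeros already converted to missing for
#'   linear data by the reader or [inject_missing()]).
#' @param cfg A [preprocess_config()].
#' @return An `ExpressionMatrix`; attribute `"dropped_genes"` lists removed
#'   genes and `"regime"` records the regime used.
#' @export
apply_missing_policy <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  m <- x$values
  miss_frac <- mean(is.na(m))
  if (miss_frac == 0) {
    attr(x, "regime") <- "none"
    attr(x, "dropped_genes") <- character(0)
    return(x)
  }
  gene_miss <- rowMeans(is.na(m))
  if (miss_frac < cfg$low_missing_frac) {
    regime <- "low"
    drop <- gene_miss > 0
  } else {
    regime <- if (miss_frac < cfg$mid_missing_frac) "medium" else "high"
    drop <- gene_miss > cfg$gene_drop_frac
  }
  if (all(drop)) stop("missing-data policy dropped all genes")
  out <- x
  out$values <- m[!drop, , drop = FALSE]
  if (regime == "medium" && anyNA(out$values))
    out <- knn_impute(out, k = cfg$knn_k)
  attr(out, "regime") <- regime
  attr(out, "dropped_genes") <- rownames(m)[drop]
  out
}

#' KNN imputation over genes
#'
#' Each missing cell (g, s) is replaced by the mean value at sample s of the
#' k genes nearest to g. Distance between two genes is the Euclidean distance
#' over samples where both are observed, normalized by the number of shared
#' samples (so genes with different missingness are comparable). Only genes
#' observed at sample s can serve as neighbours there. Observed values are
#' never altered.
#'
#' @param x An `ExpressionMatrix`.
#' @param k Number of neighbours (default 5).
#' @return An `ExpressionMatrix` with holes filled where neighbours exist; a
#'   gene with no co-observed neighbour at a sample is left missing with a
#'   warning.
#' @export
knn_impute <- function(x, k = 5L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  m <- x$values
  holes <- which(is.na(m), arr.ind = TRUE)
  if (nrow(holes) == 0) return(x)
  ng <- nrow(m)
  unresolved <- 0L
  for (g in unique(holes[, 1])) {
    target <- m[g, ]
    obs_t <- !is.na(target)
    # mean squared difference over co-observed samples, per candidate gene
    d2 <- rep(NA_real_, ng)
    for (h in seq_len(ng)) {
      if (h == g) next
      both <- obs_t & !is.na(m[h, ])
      nb <- sum(both)
      if (nb == 0) next
      d2[h] <- sum((target[both] - m[h, both])^2) / nb
    }
    ord <- order(d2, na.last = NA)
    for (s in holes[holes[, 1] == g, 2]) {
      cand <- ord[!is.na(m[ord, s])]
      if (length(cand) == 0) { unresolved <- unresolved + 1L; next }
      use <- cand[seq_len(min(k, length(cand)))]
      m[g, s] <- mean(m[use, s])
    }
  }
  if (unresolved > 0)
    warning(sprintf("%d missing cells had no co-observed neighbours and were left missing",
                    unresolved))
  out <- x
  out$values <- m
  out
}

#' Log2 transform (preprocessing step 2)
#'
#' @param x An `ExpressionMatrix` on linear scale; all observed values must be
#'   positive (zeros should already have been converted to missing).
#' @param already_log If TRUE the input is returned unchanged apart from the
#'   scale flag being promoted to `"log2"`.
#' @return An `ExpressionMatrix` on log2 scale.
#' @export
log2_transform <- function(x, already_log = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (already_log || x$scale == "log2") {
    message("log2_transform: input already on log scale, skipping")
    x$scale <- "log2"
    return(x)
  }
  if (x$scale != "linear") stop("log2_transform expects linear-scale input")
  if (any(x$values <= 0, na.rm = TRUE))
    stop("nonpositive observed values: zeros must be treated as missing before log2")
  x$values <- log2(x$values)
  x$scale <- "log2"
  x
}

#' Per-sample standardization (preprocessing step 3)
#'
#' Each sample is centred and divided by the population SD across its observed
#' genes.
#'
#' @param x An `ExpressionMatrix` (log2 scale expected).
#' @return An `ExpressionMatrix` with scale `"standardized"`.
#' @export
standardize_samples <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  m <- x$values
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    obs <- !is.na(v)
    if (sum(obs) < 2) stop("sample has fewer than 2 observed genes: ", colnames(m)[j])
    mu <- mean(v[obs])
    sd_ <- sqrt(mean((v[obs] - mu)^2))
    if (sd_ == 0) stop("zero-variance sample: ", colnames(m)[j])
    m[, j] <- (v - mu) / sd_
  }
  x$values <- m
  x$scale <- "standardized"
  x
}

#' Control-anchored per-gene standardization (preprocessing step 4)
#'
#' Each gene is centred and scaled using the mean and population SD computed
#' from the healthy-control samples only; the transformation is then applied
#' to all samples. Genes constant in controls are dropped with a warning.
#'
#' @param x An `ExpressionMatrix`.
#' @param control_sample_ids Sample ids of the healthy controls (>= 3, each
#'   gene observed in >= 3 of them).
#' @return An `ExpressionMatrix`, scale `"standardized"`.
#' @export
standardize_genes_by_controls <- function(x, control_sample_ids) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  ctrl <- intersect(control_sample_ids, sample_ids(x))
  if (length(ctrl) < 3)
    stop("control-anchored standardization impossible: fewer than 3 control samples")
  m <- x$values
  cm <- m[, ctrl, drop = FALSE]
  n_obs <- rowSums(!is.na(cm))
  if (any(n_obs < 3))
    stop("some genes observed in fewer than 3 controls: ",
         paste(utils::head(rownames(m)[n_obs < 3], 5), collapse = ", "))
  mu <- rowMeans(cm, na.rm = TRUE)
  sd_ <- apply(cm, 1, .pop_sd)
  zero <- sd_ == 0
  if (any(zero)) {
    warning(sprintf("%d genes constant in controls dropped", sum(zero)))
    m <- m[!zero, , drop = FALSE]
    mu <- mu[!zero]; sd_ <- sd_[!zero]
  }
  x$values <- (m - mu) / sd_
  x$scale <- "standardized"
  x
}

#' Run the full bulk preprocessing pipeline
#'
#' Steps: missing-data policy, log2 transform, per-sample standardization,
#' control-anchored per-gene standardization. For already-log input the log2
#' step is skipped and zeros are kept as data.
#'
#' @param x An `ExpressionMatrix` on linear (or already-log) scale.
#' @param control_sample_ids Healthy-control sample ids for step 4; if `NULL`,
#'   step 4 is skipped (then levels must be standardized against a cohort
#'   reference downstream).
#' @param cfg A [preprocess_config()].
#' @return A standardized `ExpressionMatrix`; attribute `"preprocess_log"`
#'   records genes dropped per step and the missing regime.
#' @export
preprocess_pipeline <- function(x, control_sample_ids = NULL,
                                cfg = preprocess_config()) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  x1 <- apply_missing_policy(x, cfg)
  log_rec <- list(regime = attr(x1, "regime"),
                  dropped_step1 = attr(x1, "dropped_genes"))
  x2 <- log2_transform(x1, already_log = cfg$already_log)
  x3 <- standardize_samples(x2)
  if (!is.null(control_sample_ids)) {
    before <- gene_ids(x3)
    x4 <- standardize_genes_by_controls(x3, control_sample_ids)
    log_rec$dropped_step4 <- setdiff(before, gene_ids(x4))
  } else {
    x4 <- x3
    log_rec$dropped_step4 <- character(0)
  }
  attr(x4, "preprocess_log") <- log_rec
  x4
}
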