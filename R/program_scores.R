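# Per-sample inference of latent program levels by ordinary least squares of
# each sample's standardized expression profile on [intercept, V_confounder,
# V_program], control-standardization of the R and SI levels, the R/SI-balance
# score, protein weight maps, and plasma biomarker proxies.

# OLS of y on cbind(1, X); returns coefficients. Errors on rank deficiency,
# reporting the condition number of the design.
.ols_fit <- function(y, X, label = "design") {
  Xd <- cbind(intercept = 1, X)
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd)) {
    sv <- svd(Xd, nu = 0, nv = 0)$d
    kappa <- if (min(sv) > 0) max(sv) / min(sv) else Inf
    stop(sprintf("rank-deficient %s (condition number %.3g): weight vectors collinear on the gene overlap",
                 label, kappa))
  }
  qr.coef(qrd, y)
}

#' Infer program levels for every sample by per-sample regression
#'
#' For each sample i the standardized expression profile Z_i over the genes
#' shared with the weight map is modelled as
#' `Z_i = b_i + s_conf_i * V_confounder + s_prog_i * V_program`,
#' fitted by ordinary least squares. Genes missing in a sample are excluded
#' from that sample's fit only (pairwise deletion). The R_T pair yields
#' (b, s_T, s_R); the SI_IM1 pair yields (b, s_IM1, s_SI).
#'
#' @param z A standardized `ExpressionMatrix`.
#' @param w A `GeneWeightMap`.
#' @param min_overlap Minimum shared (and per-sample observed) genes.
#' @return Data frame with columns `sample_id`, `b`, `s_confounder`,
#'   `s_program`, `n_genes_used`.
#' @export
infer_program_levels <- function(z, w, min_overlap = 50L) {
  stopifnot(inherits(z, "ExpressionMatrix"))
  if (z$scale != "standardized")
    stop("infer_program_levels expects a standardized matrix; run preprocess_pipeline first")
  al <- align_genes(z, w, min_overlap = min_overlap)
  m <- al$expression$values
  V <- cbind(conf = al$weights$confounder_weights,
             prog = al$weights$program_weights)
  n <- ncol(m)
  out <- data.frame(sample_id = colnames(m), b = NA_real_,
                    s_confounder = NA_real_, s_program = NA_real_,
                    n_genes_used = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    y <- m[, i]
    obs <- !is.na(y)
    if (sum(obs) < min_overlap)
      stop(sprintf("sample %s has %d observed weight-map genes (< %d)",
                   colnames(m)[i], sum(obs), min_overlap))
    cf <- .ols_fit(y[obs], V[obs, , drop = FALSE],
                   label = sprintf("design for pair %s", w$pair_name))
    out$b[i] <- cf[["intercept"]]
    out$s_confounder[i] <- cf[["conf"]]
    out$s_program[i] <- cf[["prog"]]
    out$n_genes_used[i] <- sum(obs)
  }
  out
}

#' Compute raw R/T and SI/IM1 levels for a cohort
#'
#' Fits the two program pairs as two separate two-predictor regressions per
#' sample and assembles a `ProgramLevels` data frame.
#'
#' @param z A standardized `ExpressionMatrix`.
#' @param w_rt `GeneWeightMap` for the R_T pair.
#' @param w_si `GeneWeightMap` for the SI_IM1 pair.
#' @param min_overlap Minimum gene overlap per pair.
#' @return Data frame (class `ProgramLevels`) with columns `sample_id`,
#'   `s_R`, `s_T`, `s_SI`, `s_IM1`, `b_R_pair`, `b_SI_pair`.
#' @export
program_levels <- function(z, w_rt, w_si, min_overlap = 50L) {
  if (w_rt$pair_name != "R_T" || w_si$pair_name != "SI_IM1")
    stop("expected weight maps for pairs R_T and SI_IM1, in that order")
  rt <- infer_program_levels(z, w_rt, min_overlap)
  si <- infer_program_levels(z, w_si, min_overlap)
  lev <- data.frame(sample_id = rt$sample_id,
                    s_R = rt$s_program, s_T = rt$s_confounder,
                    s_SI = si$s_program, s_IM1 = si$s_confounder,
                    b_R_pair = rt$b, b_SI_pair = si$b,
                    stringsAsFactors = FALSE)
  class(lev) <- c("ProgramLevels", class(lev))
  lev
}

#' Standardize R and SI levels against healthy controls
#'
#' `z = (s - mean(controls)) / SD(controls)` (population SD), applied
#' separately for R and SI. When no controls are available the cohort itself
#' is the reference, flagged via `reference_mode = "cohort"`.
#'
#' @param levels A `ProgramLevels` data frame.
#' @param control_sample_ids Healthy-control sample ids (>= 3) or `NULL` for
#'   the cohort-reference fallback.
#' @return `levels` with added columns `z_R`, `z_SI`, `balance`
#'   (`z_R - z_SI`) and `reference_mode`.
#' @export
standardize_levels <- function(levels, control_sample_ids = NULL) {
  stopifnot(is.data.frame(levels), all(c("s_R", "s_SI") %in% names(levels)))
  if (is.null(control_sample_ids)) {
    ref <- rep(TRUE, nrow(levels))
    mode <- "cohort"
  } else {
    ref <- levels$sample_id %in% control_sample_ids
    if (sum(ref) < 3) stop("fewer than 3 control samples with inferred levels")
    mode <- "controls"
  }
  zstd <- function(s) {
    mu <- mean(s[ref]); sd_ <- .pop_sd(s[ref])
    if (sd_ == 0) stop("zero control SD for program level standardization")
    (s - mu) / sd_
  }
  levels$z_R <- zstd(levels$s_R)
  levels$z_SI <- zstd(levels$s_SI)
  levels$balance <- levels$z_R - levels$z_SI
  levels$reference_mode <- mode
  levels
}

#' R/SI-balance score
#'
#' Standardized R level minus standardized SI level. Positive scores indicate
#' R above SI (a "good" balance, typical of moderate infection); negative
#' scores indicate R below SI (an "impaired" balance, typical of sepsis).
#'
#' @param levels A `ProgramLevels` data frame after [standardize_levels()].
#' @return Named numeric vector of balance scores.
#' @export
balance_score <- function(levels) {
  if (!all(c("z_R", "z_SI") %in% names(levels)))
    stop("levels must contain z_R and z_SI; run standardize_levels first")
  stats::setNames(levels$z_R - levels$z_SI, levels$sample_id)
}

#' Fit a 2D protein weight map from transcriptome-derived levels
#'
#' Per protein, the Pearson correlations with the standardized R and SI
#' levels across samples become the protein's weights (w_R, w_SI). The map
#' built on one cohort can then score protein-only cohorts via
#' [infer_levels_from_proteins()].
#'
#' @param levels `ProgramLevels` with `z_R`, `z_SI`.
#' @param protein_table Samples x proteins numeric matrix, rownames = sample
#'   ids; pairwise-complete handling of missing values.
#' @param min_n Minimum samples a protein must be observed in (default 10).
#' @return Data frame (class `ProteinWeightMap`) with `protein_id`, `w_R`,
#'   `w_SI`, `n_used`.
#' @export
fit_protein_weight_map <- function(levels, protein_table, min_n = 10L) {
  stopifnot(all(c("z_R", "z_SI") %in% names(levels)))
  shared <- intersect(levels$sample_id, rownames(protein_table))
  if (length(shared) < min_n)
    stop("fewer than ", min_n, " samples with both levels and proteins")
  li <- match(shared, levels$sample_id)
  pt <- protein_table[shared, , drop = FALSE]
  zr <- levels$z_R[li]; zs <- levels$z_SI[li]
  out <- data.frame(protein_id = colnames(pt), w_R = NA_real_, w_SI = NA_real_,
                    n_used = NA_integer_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pt))) {
    v <- pt[, j]
    obs <- !is.na(v)
    out$n_used[j] <- sum(obs)
    if (sum(obs) < min_n) {
      warning("protein observed in < ", min_n, " samples, weight left missing: ",
              colnames(pt)[j])
      next
    }
    if (stats::sd(v[obs]) == 0) {
      warning("constant protein, weight left missing: ", colnames(pt)[j])
      next
    }
    out$w_R[j] <- stats::cor(v[obs], zr[obs])
    out$w_SI[j] <- stats::cor(v[obs], zs[obs])
  }
  class(out) <- c("ProteinWeightMap", class(out))
  out
}

#' Infer R and SI levels from a plasma-protein profile
#'
#' OLS of the per-sample standardized protein profile on
#' [intercept, w_R, w_SI] jointly: the protein map is a single 2D map, so one
#' two-predictor model returns protein-based R and SI levels.
#'
#' @param protein_profile Named numeric vector (one sample's proteins) or a
#'   samples x proteins matrix, rownames = sample ids.
#' @param pmap A `ProteinWeightMap`.
#' @param standardize Centre/scale each profile across proteins first
#'   (default TRUE, mirroring the transcriptome pipeline's per-sample
#'   standardization).
#' @param min_overlap Minimum proteins shared with the map (default 10).
#' @return Data frame with `sample_id`, `b`, `s_R`, `s_SI`, `n_proteins_used`.
#' @export
infer_levels_from_proteins <- function(protein_profile, pmap,
                                       standardize = TRUE, min_overlap = 10L) {
  stopifnot(inherits(pmap, "ProteinWeightMap"))
  if (is.null(dim(protein_profile))) {
    protein_profile <- matrix(protein_profile, nrow = 1,
                              dimnames = list("sample_1", names(protein_profile)))
  }
  pm <- pmap[!is.na(pmap$w_R) & !is.na(pmap$w_SI), ]
  out <- data.frame(sample_id = rownames(protein_profile), b = NA_real_,
                    s_R = NA_real_, s_SI = NA_real_,
                    n_proteins_used = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(protein_profile))) {
    v <- protein_profile[i, ]
    shared <- intersect(pm$protein_id, colnames(protein_profile)[!is.na(v)])
    if (length(shared) < min_overlap)
      stop(sprintf("sample %s shares %d proteins with the map (< %d)",
                   rownames(protein_profile)[i], length(shared), min_overlap))
    y <- as.numeric(v[shared])
    if (standardize) {
      sd_ <- .pop_sd(y)
      if (sd_ == 0) stop("constant protein profile cannot be standardized")
      y <- (y - mean(y)) / sd_
    }
    mi <- match(shared, pm$protein_id)
    cf <- .ols_fit(y, cbind(wR = pm$w_R[mi], wSI = pm$w_SI[mi]),
                   label = "protein weight design")
    out$b[i] <- cf[["intercept"]]
    out$s_R[i] <- cf[["wR"]]
    out$s_SI[i] <- cf[["wSI"]]
    out$n_proteins_used[i] <- length(shared)
  }
  out
}

#' Plasma biomarker proxies for R, SI and the balance
#'
#' R proxy = mean of z-scored CXCL11 and IFN-gamma; SI proxy = mean of
#' z-scored IL-6 and IL-8; balance proxy = R proxy minus SI proxy. Each
#' protein is z-scored across the cohort before averaging so markers on
#' different dynamic ranges contribute equally (`mode = "raw"` averages the
#' raw values instead). If one marker of a pair is missing for a sample, the
#' proxy degrades to the available marker and the sample is flagged partial.
#'
#' @param protein_table Samples x proteins numeric matrix, rownames = sample
#'   ids.
#' @param aliases Named list mapping the four roles to column names, default
#'   `list(CXCL11 = "CXCL11", IFNg = "IFNg", IL6 = "IL6", IL8 = "IL8")`.
#' @param mode `"zscore"` (default) or `"raw"`.
#' @return Data frame with `sample_id`, `R_proxy`, `SI_proxy`,
#'   `balance_proxy`, `partial`.
#' @export
biomarker_proxies <- function(protein_table,
                              aliases = list(CXCL11 = "CXCL11", IFNg = "IFNg",
                                             IL6 = "IL6", IL8 = "IL8"),
                              mode = c("zscore", "raw")) {
  mode <- match.arg(mode)
  need <- unlist(aliases[c("CXCL11", "IFNg", "IL6", "IL8")])
  missing_cols <- setdiff(need, colnames(protein_table))
  if (length(missing_cols))
    stop("marker proteins absent from table: ", paste(missing_cols, collapse = ", "))
  z <- protein_table[, need, drop = FALSE]
  if (mode == "zscore") {
    for (j in seq_len(ncol(z))) {
      v <- z[, j]; obs <- !is.na(v)
      sd_ <- .pop_sd(v)
      if (is.na(sd_) || sd_ == 0) stop("constant marker protein: ", colnames(z)[j])
      z[, j] <- (v - mean(v[obs])) / sd_
    }
  }
  pair_mean <- function(a, b) rowMeans(cbind(z[, a], z[, b]), na.rm = TRUE)
  rp <- pair_mean(need[1], need[2])
  sp <- pair_mean(need[3], need[4])
  partial <- rowSums(is.na(z)) > 0
  data.frame(sample_id = rownames(protein_table),
             R_proxy = rp, SI_proxy = sp, balance_proxy = rp - sp,
             partial = partial, stringsAsFactors = FALSE, row.names = NULL)
}
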