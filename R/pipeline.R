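# End-to-end orchestration: preprocess -> score -> validate -> associate ->
# stratify -> survival, with every stage's outputs written to the run
# directory and a machine-readable manifest (file checksums, parameters,
# seed) for reproducibility checks. All randomness flows from one root seed
# through fixed per-stage offsets.

#' Area under the ROC curve for a score separating two classes
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores below a random negative is 1 - AUC; ties count half.
#'
#' @param score Numeric score per sample.
#' @param positive Logical; TRUE marks the positive class (here: the class
#'   expected to score *lower*, pass `score = -balance` or flip as needed).
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  ok <- !is.na(score) & !is.na(positive)
  score <- score[ok]; positive <- as.logical(positive[ok])
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute an AUC")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Validate a run configuration
#'
#' @param cfg Named list; must contain `seed`. Optional entries override the
#'   stage defaults: `preprocess` (a [preprocess_config()] or its argument
#'   list), `min_overlap`, `n_folds`, `n_perm_validation`, `balance_thresh`,
#'   `si_quantile`, `outdir`. A YAML file path is accepted and loaded.
#' @return The validated config list (class `RunConfig`).
#' @export
run_config <- function(cfg = list()) {
  if (is.character(cfg) && length(cfg) == 1) {
    if (!file.exists(cfg)) stop("config file not found: ", cfg)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    cfg <- yaml::read_yaml(cfg)
  }
  if (is.null(cfg$seed)) stop("config must set a seed")
  defaults <- list(min_overlap = 50L, n_folds = 10L, n_perm_validation = 50L,
                   balance_thresh = 0, si_quantile = 0.85, outdir = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$preprocess)) cfg$preprocess <- preprocess_config()
  else if (!inherits(cfg$preprocess, "PreprocessConfig"))
    cfg$preprocess <- do.call(preprocess_config, cfg$preprocess)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("RunConfig", "list"))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the full bulk analysis pipeline on one cohort
#'
#' Stages: preprocessing (4-step), program-level inference and
#' control-standardized balance scores, hold-out explained-variance
#' validation with a permutation null, protein variance-explained and 2D
#' correlation map (when proteins are present), endotype assignment, and
#' survival analysis (when survival records are present). Outputs are
#' returned and, when `cfg$outdir` is set, written as TSV/JSON-like text
#' files with an md5 manifest.
#'
#' @param bundle A `CohortBundle`.
#' @param w_rt,w_si Weight maps for the two program pairs.
#' @param cfg A [run_config()] (list form accepted).
#' @return List with `levels`, `validation` (`heldout`, `null`, `summary`,
#'   `tpr_fpr`), `association` (optional), `endotypes`, `survival`
#'   (optional), and `manifest`.
#' @export
run_bulk_analysis <- function(bundle, w_rt, w_si, cfg = list(seed = 1L)) {
  cfg <- run_config(cfg)
  stopifnot(inherits(bundle, "CohortBundle"))
  controls <- bundle$samples$sample_id[bundle$samples$condition == "healthy"]
  if (length(controls) < 3) controls <- NULL

  z <- preprocess_pipeline(bundle$expression, control_sample_ids = controls,
                           cfg = cfg$preprocess)
  lev <- program_levels(z, w_rt, w_si, min_overlap = cfg$min_overlap)
  lev <- standardize_levels(lev, control_sample_ids = controls)

  held <- heldout_variance(z, w_rt, w_si, n_folds = cfg$n_folds,
                           seed = cfg$seed + 100L, min_overlap = cfg$min_overlap)
  null <- permuted_null_heldout(z, w_rt, w_si, n_folds = cfg$n_folds,
                                n_perm = cfg$n_perm_validation,
                                seed = cfg$seed + 200L,
                                min_overlap = cfg$min_overlap)
  real_joint <- held$r2[held$model == "joint"]
  null_joint <- null$r2[null$model == "joint"]
  validation <- list(
    heldout = held, null_r2 = null,
    percent_significant = as.numeric(percent_significant(real_joint, null_joint)),
    tpr_fpr = tpr_fpr_f1(real_joint,
                         null_joint[seq_len(min(length(null_joint),
                                                length(real_joint)))]))

  association <- NULL
  if (!is.null(bundle$proteins)) {
    cmap <- correlation_map(bundle$proteins, lev)
    ve <- do.call(rbind, lapply(colnames(bundle$proteins), function(pr) {
      v <- stats::setNames(bundle$proteins[, pr], rownames(bundle$proteins))
      out <- tryCatch(
        cbind(phenotype_id = pr,
              variance_explained(v, lev, "joint", n_perm = 200L,
                                 seed = cfg$seed + 300L)),
        error = function(e) NULL)
      out
    }))
    association <- list(correlation_map = cmap, variance_explained = ve)
  }

  endo <- assign_endotypes(lev, balance_thresh = cfg$balance_thresh,
                           si_quantile = cfg$si_quantile)
  surv <- NULL
  if (!is.null(bundle$survival)) {
    km <- tryCatch(km_logrank(endo, bundle$survival), error = function(e) NULL)
    cox <- tryCatch(
      cox_ph(bundle$survival, lev[, c("sample_id", "balance")], "balance"),
      error = function(e) NULL)
    surv <- list(km = km, cox = cox)
  }

  result <- list(levels = lev, validation = validation,
                 association = association, endotypes = endo, survival = surv,
                 config = cfg)
  result$manifest <- .write_run_outputs(result, bundle, cfg)
  result
}

# Write stage outputs and build the manifest (parameters, seed, file md5s).
.write_run_outputs <- function(result, bundle, cfg) {
  manifest <- list(seed = cfg$seed,
                   n_genes = nrow(bundle$expression$values),
                   n_samples = ncol(bundle$expression$values),
                   balance_thresh = cfg$balance_thresh,
                   si_quantile = cfg$si_quantile)
  if (is.null(cfg$outdir)) return(manifest)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    levels = .write_tsv(result$levels, file.path(cfg$outdir, "levels.tsv")),
    heldout = .write_tsv(result$validation$heldout,
                         file.path(cfg$outdir, "validation_heldout.tsv")),
    tpr_fpr = .write_tsv(result$validation$tpr_fpr,
                         file.path(cfg$outdir, "validation_tpr_fpr.tsv")),
    endotypes = .write_tsv(as.data.frame(result$endotypes),
                           file.path(cfg$outdir, "endotypes.tsv")))
  if (!is.null(result$association))
    files["correlation_map"] <- .write_tsv(
      result$association$correlation_map,
      file.path(cfg$outdir, "protein_correlation_map.tsv"))
  if (!is.null(result$survival) && !is.null(result$survival$cox))
    files["cox"] <- .write_tsv(result$survival$cox,
                               file.path(cfg$outdir, "cox_coefficients.tsv"))
  manifest$files <- data.frame(stage = names(files), path = unname(files),
                               md5 = unname(tools::md5sum(files)),
                               stringsAsFactors = FALSE)
  mf <- file.path(cfg$outdir, "manifest.tsv")
  .write_tsv(data.frame(key = c("seed", "n_genes", "n_samples"),
                        value = c(manifest$seed, manifest$n_genes,
                                  manifest$n_samples)), mf)
  manifest$manifest_file <- mf
  manifest
}

#' Assemble figure data from a pipeline run
#'
#' Produces the plot-ready tables behind the standard figures: the R-vs-SI
#' scatter per sample with condition labels, the balance-score distribution
#' per condition, and Kaplan-Meier curves per endotype when survival was
#' analysed. If ggplot2 is installed, ggplot objects are attached; figure
#' data are also written as TSVs when `outdir` is set.
#'
#' @param result Output of [run_bulk_analysis()].
#' @param samples The cohort's `SampleTable`.
#' @param outdir Optional output directory for the figure-data TSVs.
#' @return List with `scatter`, `balance`, optionally `km`, and `plots`
#'   (ggplot objects or `NULL`).
#' @export
render_report <- function(result, samples, outdir = NULL) {
  lev <- result$levels
  scatter <- data.frame(sample_id = lev$sample_id, z_SI = lev$z_SI,
                        z_R = lev$z_R,
                        condition = samples$condition[
                          match(lev$sample_id, samples$sample_id)],
                        stringsAsFactors = FALSE)
  balance <- data.frame(sample_id = lev$sample_id, balance = lev$balance,
                        condition = scatter$condition,
                        stringsAsFactors = FALSE)
  km <- if (!is.null(result$survival) && !is.null(result$survival$km))
    result$survival$km$curves else NULL
  plots <- NULL
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    plots <- list(
      scatter = ggplot2::ggplot(scatter,
                 ggplot2::aes(x = z_SI, y = z_R, colour = condition)) +
        ggplot2::geom_point(alpha = 0.6) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
        ggplot2::labs(x = "SI level (standardized)", y = "R level (standardized)"),
      balance = ggplot2::ggplot(balance,
                 ggplot2::aes(x = balance, fill = condition)) +
        ggplot2::geom_density(alpha = 0.4) +
        ggplot2::labs(x = "R/SI-balance score"))
    if (!is.null(km))
      plots$km <- ggplot2::ggplot(km,
                   ggplot2::aes(x = time, y = survival, colour = group)) +
        ggplot2::geom_step() +
        ggplot2::labs(x = "days", y = "survival")
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(scatter, file.path(outdir, "fig_scatter.tsv"))
    .write_tsv(balance, file.path(outdir, "fig_balance.tsv"))
    if (!is.null(km)) .write_tsv(km, file.path(outdir, "fig_km.tsv"))
  }
  list(scatter = scatter, balance = balance, km = km, plots = plots)
}
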