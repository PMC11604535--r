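# Per-cell R/SI scoring and per-patient, per-subpopulation response
# statistics. Cells are preprocessed with the bulk pipeline's log and
# per-cell standardization steps only: dropout zeros are kept as zeros (after
# a counts-per-10k + log2(1 + x) transform for raw counts), and no missing
# policy or control-gene standardization is applied.

#' Validate a cell annotation table
#'
#' @param df Data frame with `cell_id`, `patient_id`, `group` (control,
#'   moderate_infection or sepsis) and `subpopulation`.
#' @param vocabulary Allowed subpopulation labels; default covers the
#'   monocyte (MS1-MS4), T (TS1-TS2), B (BS1-BS2) and NK (NS1-NS2)
#'   subpopulations.
#' @return The validated data frame (class `CellAnnotation`).
#' @export
cell_annotation <- function(df, vocabulary = c(paste0("MS", 1:4),
                                               paste0("TS", 1:2),
                                               paste0("BS", 1:2),
                                               paste0("NS", 1:2))) {
  df <- as.data.frame(df)
  need <- c("cell_id", "patient_id", "group", "subpopulation")
  if (!all(need %in% names(df)))
    stop("cell annotation needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$cell_id)) stop("duplicated cell_id")
  bad_g <- setdiff(unique(df$group), c("control", "moderate_infection", "sepsis"))
  if (length(bad_g)) stop("unknown group labels: ", paste(bad_g, collapse = ", "))
  bad_s <- setdiff(unique(df$subpopulation), vocabulary)
  if (length(bad_s))
    stop("subpopulation labels outside vocabulary: ", paste(bad_s, collapse = ", "))
  if (anyNA(df[need])) stop("cell annotation contains missing values")
  class(df) <- c("CellAnnotation", class(df))
  df
}

#' Per-cell R and SI levels
#'
#' Preprocesses the cell matrix (optional counts-per-10k normalization for
#' raw counts, log2(1 + x), per-cell standardization across genes) and runs
#' the per-sample program regression on every cell. Cells with too few
#' observed weight-map genes are dropped with a count logged.
#'
#' @param cells `ExpressionMatrix` of cells in columns (raw linear counts or
#'   already-log values).
#' @param w_rt,w_si Weight maps for the R_T and SI_IM1 pairs.
#' @param normalize Counts-per-10k library normalization before log
#'   (default TRUE, appropriate for raw counts; set FALSE for already
#'   normalized input).
#' @param min_overlap Minimum weight-map genes per cell (default 50).
#' @return Data frame with `cell_id`, `s_R`, `s_SI`.
#' @export
per_cell_levels <- function(cells, w_rt, w_si, normalize = TRUE,
                            min_overlap = 50L) {
  stopifnot(inherits(cells, "ExpressionMatrix"))
  m <- cells$values
  if (anyNA(m)) stop("single-cell input must not contain missing values; zeros are data")
  if (cells$scale == "linear") {
    if (normalize) {
      tot <- colSums(m)
      if (any(tot == 0)) stop("cells with zero total counts")
      m <- sweep(m, 2, tot / 1e4, "/")
    }
    m <- log2(1 + m)
  }
  # per-cell standardization (population SD across genes)
  mu <- colMeans(m)
  sd_ <- sqrt(colMeans(sweep(m, 2, mu)^2))
  keep <- sd_ > 0
  n_drop_var <- sum(!keep)
  m <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], "/")
  z <- expression_matrix(m, scale = "standardized")
  lev <- program_levels(z, w_rt, w_si, min_overlap = min_overlap)
  if (n_drop_var > 0)
    message(sprintf("per_cell_levels: dropped %d zero-variance cells", n_drop_var))
  data.frame(cell_id = lev$sample_id, s_R = lev$s_R, s_SI = lev$s_SI,
             stringsAsFactors = FALSE)
}

#' Patient-level molecular response score for one subpopulation and program
#'
#' Welch two-sample t test of the patient's per-cell program levels against
#' the pooled control cells of the same subpopulation. The score is
#' `-log10(p)` signed by the direction of the patient mean relative to the
#' control mean (positive = increase). p-values are floored at 1e-300, so
#' scores are capped at 300 in magnitude.
#'
#' @param cell_levels Output of [per_cell_levels()].
#' @param annotation A `CellAnnotation`.
#' @param patient_id Patient to score.
#' @param subpopulation Subpopulation label.
#' @param program `"R"` or `"SI"`.
#' @param min_cells Minimum cells required on each side (default 10).
#' @return One-row data frame with `patient_id`, `subpopulation`, `program`,
#'   `signed_log10_p`, `p_value`, `n_cells_patient`, `n_cells_controls`;
#'   `signed_log10_p` is `NA` with a `reason` when cells are too few.
#' @export
patient_response <- function(cell_levels, annotation, patient_id,
                             subpopulation, program = c("R", "SI"),
                             min_cells = 10L) {
  program <- match.arg(program)
  stopifnot(inherits(annotation, "CellAnnotation"))
  col <- if (program == "R") "s_R" else "s_SI"
  ann <- annotation[match(cell_levels$cell_id, annotation$cell_id), ]
  in_sub <- ann$subpopulation == subpopulation
  pat <- cell_levels[[col]][in_sub & ann$patient_id == patient_id]
  ctl <- cell_levels[[col]][in_sub & ann$group == "control" &
                              ann$patient_id != patient_id]
  base <- data.frame(patient_id = patient_id, subpopulation = subpopulation,
                     program = program, signed_log10_p = NA_real_,
                     p_value = NA_real_,
                     n_cells_patient = length(pat),
                     n_cells_controls = length(ctl),
                     reason = NA_character_, stringsAsFactors = FALSE)
  if (length(pat) < min_cells || length(ctl) < min_cells) {
    base$reason <- sprintf("too few cells (patient %d, controls %d, need %d)",
                           length(pat), length(ctl), min_cells)
    return(base)
  }
  tt <- stats::t.test(pat, ctl, var.equal = FALSE)
  p <- max(tt$p.value, 1e-300)
  base$p_value <- p
  base$signed_log10_p <- sign(mean(pat) - mean(ctl)) * (-log10(p))
  base
}

#' Score every patient x subpopulation x program combination
#'
#' @param cell_levels Output of [per_cell_levels()].
#' @param annotation A `CellAnnotation`.
#' @param min_cells Minimum cells per side (default 10).
#' @return Data frame of [patient_response()] rows for all non-control
#'   patients, every subpopulation they contribute cells to, and both
#'   programs.
#' @export
all_patient_responses <- function(cell_levels, annotation, min_cells = 10L) {
  stopifnot(inherits(annotation, "CellAnnotation"))
  pats <- unique(annotation$patient_id[annotation$group != "control"])
  rows <- list()
  for (p in pats) {
    subs <- unique(annotation$subpopulation[annotation$patient_id == p])
    for (s in subs) for (pg in c("R", "SI"))
      rows[[length(rows) + 1L]] <-
        patient_response(cell_levels, annotation, p, s, pg, min_cells)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentage of patients with a significant molecular response per cell type
#'
#' A patient counts as responsive for a cell type if any of its
#' subpopulation x program scores within that cell type has p below `alpha`.
#'
#' @param scores Data frame of [patient_response()] rows.
#' @param alpha Significance level (default 0.05).
#' @param cell_type_of Function mapping a subpopulation label to its cell
#'   type; default strips trailing digits (MS1..MS4 -> MS, TS1 -> TS, ...).
#' @return Data frame with `cell_type`, `n_patients`, `percent_responsive`.
#' @export
response_summary <- function(scores, alpha = 0.05,
                             cell_type_of = function(s) sub("[0-9]+$", "", s)) {
  if (is.null(scores) || nrow(scores) == 0) {
    warning("empty score list")
    return(data.frame(cell_type = character(0), n_patients = integer(0),
                      percent_responsive = numeric(0)))
  }
  scores$cell_type <- cell_type_of(scores$subpopulation)
  out <- lapply(split(scores, scores$cell_type), function(df) {
    resp <- tapply(df$p_value < alpha, df$patient_id,
                   function(v) any(v, na.rm = TRUE))
    data.frame(cell_type = df$cell_type[1], n_patients = length(resp),
               percent_responsive = 100 * mean(resp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
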