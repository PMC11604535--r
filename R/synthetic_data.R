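# Synthetic-cohort generator with retrievable ground truth. Samples carry
# latent (R, T, SI, IM1) levels whose group means differ by condition --
# sepsis has low R relative to SI, moderate infection the opposite -- genes
# are weighted sums of the latents plus noise (exponentiated to linear scale
# so the full preprocessing pipeline is exercised), proteins load linearly on
# the latents, per-cell latents scatter around patient means, and survival
# hazards increase with SI and decrease with R.

.LATENTS <- c("R", "T", "SI", "IM1")

#' Generator configuration
#'
#' Defaults encode the assumed study structure: healthy latents centred at
#' zero; moderate infection with R induced above SI (means R=2, T=0.5, SI=1,
#' IM1=0.3); sepsis with R low relative to SI (means R=0.5, T=0.5, SI=2.5,
#' IM1=0.5); unit latent SD; gene-level residual SD 1 on the log2 scale.
#'
#' @param n_genes Number of genes (default 2000, >= 200).
#' @param n_per_condition Named vector of sample counts (default 100 healthy,
#'   100 moderate_infection, 100 sepsis).
#' @param latent_means Named list of length-4 mean vectors (R, T, SI, IM1)
#'   per condition.
#' @param latent_cov 4x4 positive semi-definite latent covariance. The
#'   default has unit variances with cor(R, SI) = 0.5 and the other pairs
#'   uncorrelated: within a condition, individuals who mount a stronger
#'   response induce both programs together, so the two levels co-vary
#'   positively across individuals while the *balance* between them stays a
#'   condition-level trait.
#' @param weight_orthogonality Target max pairwise |correlation| between the
#'   four weight vectors (default 0.1).
#' @param noise_sd Gene-level residual SD on the log2 scale (default 1).
#' @param baseline_mean,baseline_sd Per-gene baseline (log2 scale; defaults
#'   6 and 1, FPKM-like magnitudes after exponentiation).
#' @param missing_rate Fraction of cells marked missing (default 0).
#' @param cells_per_patient Cells per patient for single-cell generation
#'   (default 200, >= 20).
#' @param cell_sd Per-cell latent scatter around the patient mean (default 0.5).
#' @param survival List with `beta_SI`, `beta_R` (log-hazard coefficients,
#'   defaults 0.7 and -0.7), `target_event_rate` (default 0.59) and
#'   `censor_days` (default 28).
#' @param seed Mandatory RNG seed.
#' @return A `GeneratorConfig` list.
#' @export
generator_config <- function(n_genes = 2000L,
                             n_per_condition = c(healthy = 100L,
                                                 moderate_infection = 100L,
                                                 sepsis = 100L),
                             latent_means = list(
                               healthy = c(R = 0, T = 0, SI = 0, IM1 = 0),
                               moderate_infection = c(R = 2, T = 0.5, SI = 1, IM1 = 0.3),
                               sepsis = c(R = 0.5, T = 0.5, SI = 2.5, IM1 = 0.5)),
                             latent_cov = default_latent_cov(),
                             weight_orthogonality = 0.1,
                             noise_sd = 1,
                             baseline_mean = 6, baseline_sd = 1,
                             missing_rate = 0,
                             cells_per_patient = 200L, cell_sd = 0.5,
                             survival = list(beta_SI = 0.7, beta_R = -0.7,
                                             target_event_rate = 0.59,
                                             censor_days = 28),
                             seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (n_genes < 200) stop("n_genes must be >= 200")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  ev <- eigen(latent_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("latent_cov must be positive semi-definite")
  if (!(missing_rate >= 0 && missing_rate < 1)) stop("missing_rate must be in [0,1)")
  if (cells_per_patient < 20) stop("cells_per_patient must be >= 20")
  stopifnot(all(names(n_per_condition) %in% names(latent_means)))
  structure(list(n_genes = as.integer(n_genes),
                 n_per_condition = n_per_condition,
                 latent_means = latent_means, latent_cov = latent_cov,
                 weight_orthogonality = weight_orthogonality,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, missing_rate = missing_rate,
                 cells_per_patient = as.integer(cells_per_patient),
                 cell_sd = cell_sd, survival = survival, seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Default latent covariance
#'
#' Unit variances; cor(R, SI) = `r_si_cor` (default 0.5), reflecting the
#' coordinated induction of the two programs across individuals within a
#' condition; all other latent pairs uncorrelated.
#'
#' @param r_si_cor Within-condition correlation between the R and SI latents.
#' @return A 4x4 covariance matrix (order R, T, SI, IM1).
#' @export
default_latent_cov <- function(r_si_cor = 0.5) {
  S <- diag(4)
  dimnames(S) <- list(.LATENTS, .LATENTS)
  S["R", "SI"] <- S["SI", "R"] <- r_si_cor
  S
}

#' Generate near-orthogonal gene-weight maps with ground truth
#'
#' Four weight vectors (R, T, SI, IM1) are drawn from a standard normal; if
#' any pairwise |correlation| exceeds the target, each vector is replaced by
#' its residual against the preceding ones (which zeroes the pairwise
#' correlations) and rescaled to unit SD.
#'
#' @param n_genes Number of genes (>= 200).
#' @param orthogonality Target max pairwise |correlation| (default 0.1; must
#'   be positive).
#' @param seed RNG seed.
#' @return List with `w_rt`, `w_si` (`GeneWeightMap`s), and `truth` (gene ids
#'   plus the full n_genes x 4 weight matrix).
#' @export
generate_weights <- function(n_genes = 2000L, orthogonality = 0.1, seed = 1L) {
  if (orthogonality <= 0) stop("infeasible orthogonality target (must be > 0)")
  if (n_genes < 200) stop("n_genes must be >= 200")
  set.seed(seed)
  V <- matrix(stats::rnorm(n_genes * 4), ncol = 4,
              dimnames = list(NULL, .LATENTS))
  max_cor <- max(abs(stats::cor(V)[upper.tri(diag(4))]))
  if (max_cor > orthogonality) {
    for (j in 2:4) {
      fit <- stats::lm.fit(cbind(1, V[, 1:(j - 1), drop = FALSE]), V[, j])
      V[, j] <- fit$residuals
    }
    V <- scale(V)[, ]  # unit SD, zero mean; correlations now ~0
    colnames(V) <- .LATENTS
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  rownames(V) <- genes
  list(w_rt = gene_weight_map(genes, V[, "T"], V[, "R"], pair_name = "R_T"),
       w_si = gene_weight_map(genes, V[, "IM1"], V[, "SI"], pair_name = "SI_IM1"),
       truth = list(gene_ids = genes, weights = V))
}

# Draw latent (R, T, SI, IM1) rows for each sample of each condition.
.draw_latents <- function(cfg) {
  ch <- chol(cfg$latent_cov + diag(1e-12, 4))
  rows <- list()
  conds <- names(cfg$n_per_condition)
  for (cd in conds) {
    n <- cfg$n_per_condition[[cd]]
    if (n == 0) next
    z <- matrix(stats::rnorm(n * 4), ncol = 4) %*% ch
    z <- sweep(z, 2, cfg$latent_means[[cd]][.LATENTS], "+")
    colnames(z) <- .LATENTS
    rownames(z) <- sprintf("%s_%03d", cd, seq_len(n))
    rows[[cd]] <- z
  }
  do.call(rbind, rows)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Latents are drawn per condition from its multivariate normal; log2-scale
#' expression is baseline + weights x latents + Gaussian noise, exponentiated
#' to linear scale so the preprocessing pipeline (zeros-to-missing, log2,
#' standardizations) is exercised end to end. Optionally injects missing
#' values, proteins and survival.
#'
#' @param cfg A [generator_config()].
#' @param proteins Also generate a default protein panel (default TRUE).
#' @param survival Also generate survival records for the sepsis samples
#'   (default TRUE).
#' @return List with `bundle` (a `CohortBundle`), `w_rt`, `w_si`, and
#'   `truth` (latents, weights, protein loadings).
#' @export
generate_cohort <- function(cfg, proteins = TRUE, survival = TRUE) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  wt <- generate_weights(cfg$n_genes, cfg$weight_orthogonality, seed = cfg$seed)
  set.seed(cfg$seed + 1L)
  lat <- .draw_latents(cfg)
  V <- wt$truth$weights
  b <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  logexpr <- b + V %*% t(lat) +
    matrix(stats::rnorm(cfg$n_genes * nrow(lat), 0, cfg$noise_sd),
           nrow = cfg$n_genes)
  rownames(logexpr) <- wt$truth$gene_ids
  colnames(logexpr) <- rownames(lat)
  expr <- expression_matrix(2^logexpr, scale = "linear")
  if (cfg$missing_rate > 0)
    expr <- inject_missing(expr, cfg$missing_rate, seed = cfg$seed + 2L)
  cond <- sub("_[0-9]+$", "", rownames(lat))
  samples <- sample_table(data.frame(sample_id = rownames(lat),
                                     condition = cond,
                                     dataset_id = "synthetic",
                                     stringsAsFactors = FALSE))
  prot <- NULL
  if (proteins) {
    pl <- default_protein_loadings()
    prot <- generate_proteins(lat, pl, noise_sd = 0.5, seed = cfg$seed + 3L)
  }
  surv <- NULL
  if (survival) {
    sep <- rownames(lat)[cond == "sepsis"]
    if (length(sep) > 0)
      surv <- generate_survival(lat[sep, , drop = FALSE], cfg,
                                seed = cfg$seed + 4L)
  }
  bundle <- cohort_bundle(expr, samples, proteins = prot, survival = surv)
  truth <- list(latents = lat, weights = V, baseline = b,
                protein_loadings = if (proteins) default_protein_loadings() else NULL)
  list(bundle = bundle, w_rt = wt$w_rt, w_si = wt$w_si, truth = truth)
}

#' Default protein loading matrix
#'
#' A small plasma panel: R-loaded markers (CXCL11, IFNg, CXCL10), SI-loaded
#' markers (IL6, IL8, IL18bp, ferritin analog FER), and two unloaded noise
#' proteins. Rows are proteins, columns the four latents.
#'
#' @return Numeric proteins x 4 matrix.
#' @export
default_protein_loadings <- function() {
  L <- rbind(CXCL11 = c(1, 0, 0.1, 0),
             IFNg   = c(1, 0, 0.1, 0),
             CXCL10 = c(0.9, 0, 0.2, 0),
             IL6    = c(0.1, 0, 1, 0),
             IL8    = c(0.1, 0, 1, 0),
             IL18bp = c(0, 0, 0.8, 0.1),
             FER    = c(-0.2, 0, 0.7, 0),
             NOISE1 = c(0, 0, 0, 0),
             NOISE2 = c(0, 0, 0, 0))
  colnames(L) <- .LATENTS
  L
}

#' Generate a plasma-protein table from latents
#'
#' Protein value = loadings x latents + Gaussian noise (NPX-like log2 scale).
#'
#' @param latents Samples x 4 latent matrix (columns R, T, SI, IM1).
#' @param loadings Proteins x 4 loading matrix.
#' @param noise_sd Residual SD (default 0.5).
#' @param seed RNG seed.
#' @return Samples x proteins numeric matrix.
#' @export
generate_proteins <- function(latents, loadings, noise_sd = 0.5, seed = 1L) {
  if (ncol(latents) != 4 || ncol(loadings) != 4)
    stop("latents and loadings must have 4 latent columns")
  set.seed(seed)
  P <- latents %*% t(loadings) +
    matrix(stats::rnorm(nrow(latents) * nrow(loadings), 0, noise_sd),
           nrow = nrow(latents))
  dimnames(P) <- list(rownames(latents), rownames(loadings))
  P
}

#' Generate a synthetic single-cell cohort
#'
#' Per patient, a latent mean is drawn from its group's condition means (with
#' patient-level scatter); per-cell latents scatter around the patient mean
#' with SD `cell_sd`; per-cell log2 expression is baseline + weights x
#' latents + noise, converted to counts by Poisson sampling of per-cell rates
#' normalized to a target library size (Poisson thinning).
#'
#' @param cfg A [generator_config()]; `n_per_condition` is read as patients
#'   per group (healthy maps to the control group).
#' @param n_genes Genes for the cell matrix (default `cfg$n_genes`; smaller
#'   values speed up per-cell regression).
#' @param subpopulations Labels cells are split across (default `"MS1"`).
#' @param patient_sd Patient-level latent scatter (default 0.3).
#' @param library_size Target counts per cell (default 5000).
#' @param sc_noise_sd Per-cell gene noise SD (default `1.5 * cfg$noise_sd`).
#' @return List with `cells` (`ExpressionMatrix` of counts), `annotation`
#'   (`CellAnnotation`), `w_rt`, `w_si`, and `truth` (patient and per-cell
#'   latents).
#' @export
generate_single_cell <- function(cfg, n_genes = cfg$n_genes,
                                 subpopulations = "MS1", patient_sd = 0.3,
                                 library_size = 5000, sc_noise_sd = 1.5 * cfg$noise_sd) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  wt <- generate_weights(n_genes, cfg$weight_orthogonality, seed = cfg$seed)
  set.seed(cfg$seed + 10L)
  V <- wt$truth$weights
  b <- stats::rnorm(n_genes, cfg$baseline_mean, cfg$baseline_sd)
  group_of <- c(healthy = "control", moderate_infection = "moderate_infection",
                sepsis = "sepsis")
  ann <- list(); counts <- list(); pat_lat <- list(); cell_lat <- list()
  for (cd in names(cfg$n_per_condition)) {
    np <- cfg$n_per_condition[[cd]]
    if (np == 0) next
    mu_g <- cfg$latent_means[[cd]][.LATENTS]
    for (p in seq_len(np)) {
      pid <- sprintf("%s_p%02d", group_of[[cd]], p)
      pm <- mu_g + stats::rnorm(4, 0, patient_sd)
      nc <- cfg$cells_per_patient
      cl <- matrix(stats::rnorm(nc * 4, 0, cfg$cell_sd), ncol = 4,
                   dimnames = list(NULL, .LATENTS))
      cl <- sweep(cl, 2, pm, "+")
      le <- b + V %*% t(cl) +
        matrix(stats::rnorm(n_genes * nc, 0, sc_noise_sd), nrow = n_genes)
      lam <- 2^le
      lam <- sweep(lam, 2, colSums(lam) / library_size, "/")
      cm <- matrix(stats::rpois(length(lam), lam), nrow = n_genes)
      cids <- sprintf("%s_c%04d", pid, seq_len(nc))
      dimnames(cm) <- list(wt$truth$gene_ids, cids)
      counts[[pid]] <- cm
      ann[[pid]] <- data.frame(cell_id = cids, patient_id = pid,
                               group = group_of[[cd]],
                               subpopulation = rep_len(subpopulations, nc),
                               stringsAsFactors = FALSE)
      pat_lat[[pid]] <- pm
      rownames(cl) <- cids
      cell_lat[[pid]] <- cl
    }
  }
  cells <- expression_matrix(do.call(cbind, counts), scale = "linear")
  annotation <- cell_annotation(do.call(rbind, ann))
  rownames(annotation) <- NULL
  list(cells = cells, annotation = annotation,
       w_rt = wt$w_rt, w_si = wt$w_si,
       truth = list(patient_latents = do.call(rbind, pat_lat),
                    cell_latents = do.call(rbind, cell_lat),
                    weights = V))
}

#' Generate survival records from latents
#'
#' Exponential event times with hazard
#' `lambda * exp(beta_SI * SI + beta_R * R)`, administratively censored at
#' `censor_days`. The baseline hazard `lambda` is calibrated by root finding
#' so the expected event fraction matches `target_event_rate` given the
#' latents. Age and sex are simulated independently.
#'
#' @param latents Samples x 4 latent matrix (columns R, T, SI, IM1).
#' @param cfg A [generator_config()] (its `survival` element is used).
#' @param seed RNG seed.
#' @return Data frame with `sample_id`, `time_days`, `event`, `age`, `sex`.
#' @export
generate_survival <- function(latents, cfg, seed = 1L) {
  sv <- cfg$survival
  lp <- sv$beta_SI * latents[, "SI"] + sv$beta_R * latents[, "R"]
  cd <- sv$censor_days
  target <- sv$target_event_rate
  # expected event fraction before day `cd` as a function of lambda
  ev_frac <- function(lam) mean(1 - exp(-lam * exp(lp) * cd))
  lam <- stats::uniroot(function(l) ev_frac(l) - target,
                        lower = 1e-10, upper = 1e3, tol = 1e-12)$root
  if (lam <= 0) stop("calibrated baseline hazard must be positive")
  set.seed(seed)
  t_raw <- stats::rexp(nrow(latents), rate = lam * exp(lp))
  event <- as.integer(t_raw <= cd)
  data.frame(sample_id = rownames(latents),
             time_days = pmin(t_raw, cd),
             event = event,
             age = round(stats::rnorm(nrow(latents), 65, 10)),
             sex = sample(c("F", "M"), nrow(latents), replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Inject missing values into an expression matrix
#'
#' @param x An `ExpressionMatrix`.
#' @param rate Target missing fraction in `[0, 1)`.
#' @param mode `"uniform"` marks cells missing uniformly at random;
#'   `"gene_biased"` concentrates the missingness in a random subset of genes
#'   (driving them past heavy-missingness drop rules).
#' @param seed RNG seed.
#' @param biased_gene_frac Fraction of genes carrying the biased missingness
#'   (default 0.05).
#' @param biased_cell_frac Within-gene missing fraction for biased genes
#'   (default 0.9).
#' @return An `ExpressionMatrix` with `NA`s injected.
#' @export
inject_missing <- function(x, rate, mode = c("uniform", "gene_biased"),
                           seed = 1L, biased_gene_frac = 0.05,
                           biased_cell_frac = 0.9) {
  mode <- match.arg(mode)
  if (!(rate >= 0 && rate < 1)) stop("rate must be in [0,1)")
  if (rate == 0 && mode == "uniform") return(x)
  set.seed(seed)
  m <- x$values
  if (mode == "uniform") {
    holes <- stats::runif(length(m)) < rate
    m[holes] <- NA_real_
  } else {
    gsel <- sample(nrow(m), max(1, round(biased_gene_frac * nrow(m))))
    for (g in gsel)
      m[g, stats::runif(ncol(m)) < biased_cell_frac] <- NA_real_
    if (rate > 0) m[stats::runif(length(m)) < rate] <- NA_real_
  }
  x$values <- m
  x
}
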