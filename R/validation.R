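# Program validity checks: (Approach 1) hold-out explained variance -- genes
# are partitioned into folds, program levels are re-inferred without the
# held-out genes, and each held-out gene is regressed on the inferred R and
# SI levels under joint / R-only / SI-only models; matched permutation runs
# give null R-squared distributions, empirical p-values and TPR/FPR/F1
# curves. (Approach 2) inter-gene variation -- per-sample R-squared of the
# expression profile on the predefined weights, against a weight-permutation
# null.

# R^2 and F-test p of OLS of y on predictor columns X (intercept added).
.r2_p <- function(y, X) {
  X <- as.matrix(X)
  fit <- stats::lm.fit(cbind(1, X), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  r2 <- min(max(r2, 0), 1)
  k <- ncol(X)
  df2 <- length(y) - k - 1
  p <- if (df2 <= 0 || r2 >= 1) 0 else
    stats::pf((r2 / k) / ((1 - r2) / df2), k, df2, lower.tail = FALSE)
  c(r2 = r2, p = p)
}

# Vectorized R^2 of many response columns on one shared design.
# Y: n x G (no missing values), X: n x k predictor columns.
.r2_many <- function(Y, X) {
  Q <- qr.Q(qr(cbind(1, as.matrix(X))))
  qy2 <- colSums(crossprod(Q, Y)^2)
  y2 <- colSums(Y^2)
  tss <- y2 - nrow(Y) * colMeans(Y)^2
  r2 <- ifelse(tss <= 0, 0, 1 - (y2 - qy2) / tss)
  pmin(pmax(r2, 0), 1)
}

# F-test p from R^2 (k predictors, n observations), vectorized.
.p_from_r2 <- function(r2, k, n) {
  df2 <- n - k - 1
  if (df2 <= 0) return(rep(0, length(r2)))
  p <- stats::pf((r2 / k) / ((1 - r2) / df2), k, df2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  p
}

# Partition gene indices into n_folds disjoint folds of near-equal size.
.make_folds <- function(n_genes, n_folds) {
  fold <- rep(seq_len(n_folds), length.out = n_genes)
  sample(fold)
}

# Infer S_R and S_SI with a gene subset excluded; returns n_samples x 2.
.levels_excluding <- function(z, w_rt, w_si, exclude_genes, min_overlap) {
  zx <- z
  keep <- setdiff(gene_ids(z), exclude_genes)
  zx$values <- z$values[keep, , drop = FALSE]
  lev <- program_levels(zx, w_rt, w_si, min_overlap = min_overlap)
  cbind(S_R = lev$s_R, S_SI = lev$s_SI)
}

#' Hold-out explained variance per gene (Approach 1)
#'
#' Genes are partitioned into `n_folds` disjoint folds (10% held out per
#' fold, without replacement). For each fold, R and SI levels are recomputed
#' from the remaining genes, then every held-out gene is regressed on the
#' inferred levels under three models: joint (R + SI), R-only and SI-only.
#' Each gene's R-squared and regression p are recorded for the one fold in
#' which it was held out.
#'
#' @param z Standardized `ExpressionMatrix`.
#' @param w_rt,w_si Weight maps for the R_T and SI_IM1 pairs.
#' @param n_folds Number of folds (default 10; a fraction 1/n_folds of genes
#'   is held out per fold).
#' @param seed RNG seed controlling the fold assignment.
#' @param min_overlap Minimum genes left for level inference per fold.
#' @return Data frame with `gene_id`, `model` (`joint`, `R_only`, `SI_only`),
#'   `r2`, `p_value`, `fold`.
#' @export
heldout_variance <- function(z, w_rt, w_si, n_folds = 10L, seed = 1L,
                             min_overlap = 50L) {
  stopifnot(inherits(z, "ExpressionMatrix"))
  genes <- gene_ids(z)
  set.seed(seed)
  fold <- .make_folds(length(genes), n_folds)
  res <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    held <- genes[fold == f]
    if (length(held) == 0) next
    S <- .levels_excluding(z, w_rt, w_si, held, min_overlap)
    Y <- t(z$values[held, , drop = FALSE])
    if (!anyNA(Y)) {
      n <- nrow(Y)
      r2j <- .r2_many(Y, S)
      r2r <- .r2_many(Y, S[, "S_R", drop = FALSE])
      r2s <- .r2_many(Y, S[, "S_SI", drop = FALSE])
      res[[f]] <- data.frame(
        gene_id = rep(held, each = 3),
        model = rep(c("joint", "R_only", "SI_only"), times = length(held)),
        r2 = as.numeric(rbind(r2j, r2r, r2s)),
        p_value = as.numeric(rbind(.p_from_r2(r2j, 2, n),
                                   .p_from_r2(r2r, 1, n),
                                   .p_from_r2(r2s, 1, n))),
        fold = f, stringsAsFactors = FALSE)
      next
    }
    rows <- lapply(held, function(g) {
      y <- z$values[g, ]
      obs <- !is.na(y)
      y <- y[obs]
      Sg <- S[obs, , drop = FALSE]
      rj <- .r2_p(y, Sg)
      rr <- .r2_p(y, Sg[, "S_R", drop = FALSE])
      rs <- .r2_p(y, Sg[, "S_SI", drop = FALSE])
      data.frame(gene_id = g,
                 model = c("joint", "R_only", "SI_only"),
                 r2 = c(rj["r2"], rr["r2"], rs["r2"]),
                 p_value = c(rj["p"], rr["p"], rs["p"]),
                 fold = f, stringsAsFactors = FALSE)
    })
    res[[f]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Permutation null for the hold-out explained variance
#'
#' Repeats the held-out regressions with the sample labels of the inferred
#' level vectors shuffled relative to each gene's expression, giving a null
#' R-squared distribution per model. The identity permutation is excluded so
#' no "null" draw reproduces the real statistic by construction.
#'
#' @param z,w_rt,w_si,n_folds,min_overlap As in [heldout_variance()].
#' @param n_perm Number of permutations (default 100; below 20 a warning is
#'   emitted because the empirical-p resolution becomes coarse).
#' @param seed RNG seed (folds and permutations).
#' @return Data frame with `model`, `r2`, `perm`, pooled across genes and
#'   permutations.
#' @export
permuted_null_heldout <- function(z, w_rt, w_si, n_folds = 10L, n_perm = 100L,
                                  seed = 1L, min_overlap = 50L) {
  stopifnot(inherits(z, "ExpressionMatrix"))
  if (n_perm < 20) warning("empirical p resolution too coarse: n_perm < 20")
  genes <- gene_ids(z)
  n <- ncol(z$values)
  set.seed(seed)
  fold <- .make_folds(length(genes), n_folds)
  out <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    held <- genes[fold == f]
    if (length(held) == 0) next
    S <- .levels_excluding(z, w_rt, w_si, held, min_overlap)
    perms <- lapply(seq_len(n_perm), function(p) {
      repeat {
        pr <- sample.int(n)
        if (!identical(pr, seq_len(n)) || n == 1) return(pr)
      }
    })
    Y <- t(z$values[held, , drop = FALSE])
    complete <- !anyNA(Y)
    chunk <- vector("list", n_perm)
    for (p in seq_len(n_perm)) {
      Sp <- S[perms[[p]], , drop = FALSE]
      if (complete) {
        r2s <- rbind(.r2_many(Y, Sp),
                     .r2_many(Y, Sp[, "S_R", drop = FALSE]),
                     .r2_many(Y, Sp[, "S_SI", drop = FALSE]))
      } else {
        r2s <- vapply(held, function(g) {
          y <- z$values[g, ]
          obs <- !is.na(y)
          y <- y[obs]
          Sg <- Sp[obs, , drop = FALSE]
          c(.r2_p(y, Sg)["r2"],
            .r2_p(y, Sg[, "S_R", drop = FALSE])["r2"],
            .r2_p(y, Sg[, "S_SI", drop = FALSE])["r2"])
        }, numeric(3))
      }
      chunk[[p]] <- data.frame(model = rep(c("joint", "R_only", "SI_only"),
                                           times = length(held)),
                               r2 = as.numeric(r2s), perm = p,
                               stringsAsFactors = FALSE)
    }
    out[[f]] <- do.call(rbind, chunk)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percentage of genes significant against a permutation null
#'
#' Empirical p for each real statistic r is `(1 + #{null >= r}) / (1 + N)`
#' (+1-corrected, never exactly zero). Returns 100 times the fraction of
#' statistics with empirical p below `alpha`.
#'
#' @param real Numeric vector of real statistics (e.g., per-gene R-squared).
#' @param null Numeric vector of pooled null statistics (nonempty).
#' @param alpha Significance level (default 0.05).
#' @return Percentage in `[0, 100]`; attribute `"empirical_p"` carries the
#'   per-entry empirical p-values.
#' @export
percent_significant <- function(real, null, alpha = 0.05) {
  if (length(null) == 0) stop("null distribution is empty")
  ns <- sort(null)
  n_null <- length(ns)
  # #{null >= r} via binary search on the sorted null
  ge <- n_null - findInterval(real, ns, left.open = TRUE)
  emp_p <- (1 + ge) / (1 + n_null)
  pct <- 100 * mean(emp_p < alpha)
  attr(pct, "empirical_p") <- emp_p
  pct
}

#' TPR/FPR/precision/recall/F1 curve over R-squared cutoffs
#'
#' TPR(c) is the fraction of real genes with R-squared above c (a lower bound
#' on the true positive rate); FPR(c) is the same fraction in matched
#' permuted data. Precision assumes equal real and permuted set sizes (one
#' permuted copy per real run): `precision = TPR / (TPR + FPR)`;
#' `recall = TPR`; F1 is their harmonic mean, defined as 0 when both rates
#' are 0.
#'
#' @param real_r2 Per-gene R-squared from real data.
#' @param perm_r2 Per-gene R-squared from matched permuted data.
#' @param cutoffs R-squared cutoffs (default `c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5)`).
#' @return Data frame with `cutoff`, `tpr`, `fpr`, `precision`, `recall`, `f1`.
#' @export
tpr_fpr_f1 <- function(real_r2, perm_r2,
                       cutoffs = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5)) {
  out <- lapply(cutoffs, function(c0) {
    tpr <- mean(real_r2 > c0)
    fpr <- mean(perm_r2 > c0)
    prec <- if (tpr + fpr == 0) 0 else tpr / (tpr + fpr)
    f1 <- if (prec + tpr == 0) 0 else 2 * prec * tpr / (prec + tpr)
    data.frame(cutoff = c0, tpr = tpr, fpr = fpr,
               precision = prec, recall = tpr, f1 = f1)
  })
  do.call(rbind, out)
}

#' Inter-gene variation explained by the predefined weights (Approach 2)
#'
#' Per sample, the R-squared of the expression profile regressed on
#' [intercept, V_confounder, V_program], with an empirical p against a null
#' obtained by jointly permuting the weight rows across genes.
#'
#' @param z Standardized `ExpressionMatrix`.
#' @param w A `GeneWeightMap` (one program pair).
#' @param n_perm Weight permutations (default 200).
#' @param seed RNG seed.
#' @param min_overlap Minimum genes per sample.
#' @return Data frame with `sample_id`, `r2`, `empirical_p`; attribute
#'   `"percent_significant"` gives the percentage of samples with empirical
#'   p < 0.05.
#' @export
intergene_variation <- function(z, w, n_perm = 200L, seed = 1L,
                                min_overlap = 50L) {
  stopifnot(inherits(z, "ExpressionMatrix"))
  al <- align_genes(z, w, min_overlap = min_overlap)
  m <- al$expression$values
  V <- cbind(al$weights$confounder_weights, al$weights$program_weights)
  ng <- nrow(m)
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(ng), simplify = FALSE)
  out <- data.frame(sample_id = colnames(m), r2 = NA_real_,
                    empirical_p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(m))) {
    y <- m[, i]
    obs <- !is.na(y)
    if (sum(obs) < min_overlap)
      stop("sample with too few observed genes: ", colnames(m)[i])
    real <- .r2_p(y[obs], V[obs, , drop = FALSE])["r2"]
    null <- vapply(perms, function(pr) {
      Vp <- V[pr, , drop = FALSE]
      .r2_p(y[obs], Vp[obs, , drop = FALSE])["r2"]
    }, numeric(1))
    out$r2[i] <- real
    out$empirical_p[i] <- (1 + sum(null >= real)) / (1 + n_perm)
  }
  attr(out, "percent_significant") <- 100 * mean(out$empirical_p < 0.05)
  out
}
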