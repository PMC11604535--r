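test_that("generators are pure functions of config and seed", {
  cfg <- generator_config(n_genes = 300,
                          n_per_condition = c(healthy = 10, sepsis = 10),
                          seed = 5L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$bundle$expression$values, b$bundle$expression$values)
  expect_identical(a$bundle$proteins, b$bundle$proteins)
  expect_identical(a$bundle$survival, b$bundle$survival)
  expect_identical(a$truth$latents, b$truth$latents)

  w1 <- generate_weights(400, seed = 3)
  w2 <- generate_weights(400, seed = 3)
  expect_identical(w1$truth$weights, w2$truth$weights)
  expect_error(generator_config(seed = NULL), "seed is mandatory")
})

test_that("weight vectors honour the orthogonality target", {
  w <- generate_weights(2000, orthogonality = 0.1, seed = 2)
  cc <- cor(w$truth$weights)
  expect_lte(max(abs(cc[upper.tri(cc)])), 0.1)
  # loose target: raw normal draws pass whp (corr null SD ~ 1/sqrt(n))
  w2 <- generate_weights(2000, orthogonality = 0.9, seed = 2)
  cc2 <- cor(w2$truth$weights)
  expect_lte(max(abs(cc2[upper.tri(cc2)])), 0.9)
  expect_error(generate_weights(400, orthogonality = 0), "infeasible")
})

test_that("noiseless cohorts recover latents almost perfectly", {
  cfg <- generator_config(n_genes = 500,
                          n_per_condition = c(healthy = 30, sepsis = 30),
                          noise_sd = 1e-6, seed = 8L)
  co <- generate_cohort(cfg, proteins = FALSE, survival = FALSE)
  # inference layer in isolation: feed the latent model directly (no
  # per-sample rescaling) -> essentially exact recovery
  direct <- co$truth$weights %*% t(co$truth$latents)
  zd <- expression_matrix(direct, scale = "standardized")
  levd <- program_levels(zd, co$w_rt, co$w_si)
  truth <- co$truth$latents[levd$sample_id, ]
  expect_gt(cor(levd$s_R, truth[, "R"]), 0.999)
  expect_gt(cor(levd$s_SI, truth[, "SI"]), 0.999)

  # full pipeline: the per-sample standardization step divides each profile
  # by its own dispersion, which compresses extreme latent states, so the
  # noiseless limit is near- but not exactly-perfect
  ctrl <- co$bundle$samples$sample_id[co$bundle$samples$condition == "healthy"]
  z <- preprocess_pipeline(co$bundle$expression, control_sample_ids = ctrl)
  lev <- program_levels(z, co$w_rt, co$w_si)
  truth2 <- co$truth$latents[lev$sample_id, ]
  expect_gt(cor(lev$s_R, truth2[, "R"]), 0.9)
  expect_gt(cor(lev$s_SI, truth2[, "SI"]), 0.9)
})

test_that("protein generation follows the loading structure", {
  set.seed(4)
  lat <- matrix(rnorm(150 * 4), ncol = 4,
                dimnames = list(paste0("s", 1:150), c("R", "T", "SI", "IM1")))
  P <- generate_proteins(lat, default_protein_loadings(), noise_sd = 0.5, seed = 9)
  # SI-loaded protein tracks SI more than R
  expect_gt(abs(cor(P[, "IL6"], lat[, "SI"])), abs(cor(P[, "IL6"], lat[, "R"])))
  expect_gt(abs(cor(P[, "CXCL11"], lat[, "R"])), abs(cor(P[, "CXCL11"], lat[, "SI"])))
  # unloaded proteins hover near zero correlation
  expect_lt(abs(cor(P[, "NOISE1"], lat[, "SI"])), 0.25)
  expect_identical(P, generate_proteins(lat, default_protein_loadings(),
                                        noise_sd = 0.5, seed = 9))
  expect_error(generate_proteins(lat[, 1:3], default_protein_loadings()),
               "4 latent")
})

test_that("survival calibration hits the target event rate and Cox recovers betas", {
  cfg <- generator_config(n_genes = 300,
                          n_per_condition = c(sepsis = 400),
                          seed = 12L)
  set.seed(12)
  ch <- chol(cfg$latent_cov + diag(1e-12, 4))
  lat <- matrix(rnorm(400 * 4), ncol = 4) %*% ch
  lat <- sweep(lat, 2, cfg$latent_means$sepsis, "+")
  colnames(lat) <- c("R", "T", "SI", "IM1")
  rownames(lat) <- paste0("s", 1:400)
  sv <- generate_survival(lat, cfg, seed = 1)
  expect_true(all(sv$time_days <= 28))
  expect_lt(abs(mean(sv$event) - 0.59), 0.06)

  # null betas: endotype-free log-rank p roughly uniform (no systematic signal)
  cfg0 <- cfg
  cfg0$survival$beta_SI <- 0; cfg0$survival$beta_R <- 0
  sv0 <- generate_survival(lat, cfg0, seed = 2)
  gr <- data.frame(sample_id = sv0$sample_id,
                   endotype = rep(c("A", "B"), 200))
  expect_gt(km_logrank(gr, sv0)$overall$p, 0.001)
})

test_that("missing injection achieves the requested pattern and drives the drop rule", {
  co <- small_cohort()
  x <- co$co$bundle$expression
  expect_identical(inject_missing(x, 0)$values, x$values)
  xm <- inject_missing(x, 0.05, seed = 3)
  expect_lt(abs(mean(is.na(xm$values)) - 0.05), 0.01)

  # gene-biased missingness sends exactly the biased genes past the 75% rule
  xb <- inject_missing(x, 0, mode = "gene_biased", seed = 4,
                       biased_gene_frac = 3 / nrow(x$values),
                       biased_cell_frac = 0.9)
  biased <- rownames(xb$values)[rowMeans(is.na(xb$values)) > 0.75]
  expect_length(biased, 3)
  out <- apply_missing_policy(xb)
  expect_setequal(attr(out, "dropped_genes"), biased)
})
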