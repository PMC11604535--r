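test_that("per-sample regression equals the normal-equations oracle", {
  # hand-specified 4-gene case
  V_T <- c(0, 1, 1, -1); V_R <- c(1, -1, 2, 0); Zi <- c(2, 0, 5, -1)
  z <- make_std_em(matrix(Zi, 4, 1))
  w <- gene_weight_map(gene_ids(z), V_T, V_R, "R_T", min_genes = 4L)
  lv <- infer_program_levels(z, w, min_overlap = 4L)
  oc <- oracle_ols(Zi, cbind(V_T, V_R))
  expect_equal(c(lv$b, lv$s_confounder, lv$s_program), oc, tolerance = 1e-10)

  # null profile -> all-zero coefficients
  z0 <- make_std_em(matrix(0, 4, 1))
  lv0 <- infer_program_levels(z0, w, min_overlap = 4L)
  expect_equal(c(lv0$b, lv0$s_confounder, lv0$s_program), c(0, 0, 0))

  # orthogonal projection: Z = 3 V_R with zero-mean orthogonal weights
  vr <- c(1, -1, 1, -1); vt <- c(1, 1, -1, -1)
  zo <- make_std_em(matrix(3 * vr, 4, 1))
  wo <- gene_weight_map(gene_ids(zo), vt, vr, "R_T", min_genes = 4L)
  lvo <- infer_program_levels(zo, wo, min_overlap = 4L)
  expect_equal(c(lvo$b, lvo$s_confounder, lvo$s_program), c(0, 0, 3),
               tolerance = 1e-10)

  # 100 random small instances against the oracle
  set.seed(99)
  for (i in 1:100) {
    ng <- sample(10:50, 1)
    y <- rnorm(ng); vc <- rnorm(ng); vp <- rnorm(ng)
    zi <- make_std_em(matrix(y, ng, 1))
    wi <- gene_weight_map(gene_ids(zi), vc, vp, "R_T", min_genes = ng)
    li <- infer_program_levels(zi, wi, min_overlap = ng)
    expect_equal(c(li$b, li$s_confounder, li$s_program),
                 oracle_ols(y, cbind(vc, vp)), tolerance = 1e-8)
  }
})

test_that("missing genes are deleted pairwise per sample and collinear designs error", {
  set.seed(3)
  ng <- 80
  vc <- rnorm(ng); vp <- rnorm(ng)
  y <- 1 + 2 * vc - 1.5 * vp + rnorm(ng, 0, 0.1)
  z <- make_std_em(cbind(y, y))
  z$values[1:10, 2] <- NA  # second sample misses 10 genes
  w <- gene_weight_map(gene_ids(z), vc, vp, "R_T")
  lv <- infer_program_levels(z, w)
  expect_equal(lv$n_genes_used, c(80L, 70L))
  expect_equal(lv$s_program[2], oracle_ols(y[-(1:10)], cbind(vc, vp)[-(1:10), ])[3],
               tolerance = 1e-10)

  wcol <- gene_weight_map(gene_ids(z), vc, 2 * vc, "R_T")
  expect_error(infer_program_levels(z, wcol), "condition number")
})

test_that("affine shift of one sample moves only its intercept", {
  set.seed(4)
  ng <- 100
  vc <- rnorm(ng); vp <- rnorm(ng); y <- rnorm(ng)
  z1 <- make_std_em(matrix(y, ng, 1))
  z2 <- make_std_em(matrix(y + 5, ng, 1))
  w <- gene_weight_map(gene_ids(z1), vc, vp, "R_T")
  l1 <- infer_program_levels(z1, w)
  l2 <- infer_program_levels(z2, w)
  expect_equal(l2$b, l1$b + 5, tolerance = 1e-10)
  expect_equal(l2$s_confounder, l1$s_confounder, tolerance = 1e-10)
  expect_equal(l2$s_program, l1$s_program, tolerance = 1e-10)
})

test_that("level standardization and balance follow the control reference", {
  lev <- data.frame(sample_id = c("c1", "c2", "c3", "p1"),
                    s_R = c(-1, 0, 1, 2), s_T = 0,
                    s_SI = c(0, 1, 2, 0), s_IM1 = 0,
                    b_R_pair = 0, b_SI_pair = 0)
  out <- standardize_levels(lev, c("c1", "c2", "c3"))
  # population SD of (-1,0,1) is 0.8165; patient 2 -> 2.449
  expect_equal(out$z_R[4], 2 / sqrt(2 / 3), tolerance = 1e-8)
  expect_equal(out$z_R[2], 0)  # control at the control mean
  expect_equal(out$balance, out$z_R - out$z_SI)
  expect_equal(balance_score(out), setNames(out$z_R - out$z_SI, out$sample_id))

  # balance is antisymmetric under swapping the two programs
  sw <- lev
  sw$s_R <- lev$s_SI; sw$s_SI <- lev$s_R
  out_sw <- standardize_levels(sw, c("c1", "c2", "c3"))
  expect_equal(out_sw$balance, -out$balance)

  expect_error(standardize_levels(lev, c("c1", "c2")), "fewer than 3")
  # cohort fallback flagged
  out_cohort <- standardize_levels(lev, NULL)
  expect_equal(unique(out_cohort$reference_mode), "cohort")
})

test_that("parameter recovery holds on a synthetic cohort", {
  co <- small_cohort()
  truth <- co$co$truth$latents[co$lev$sample_id, ]
  expect_gt(cor(co$lev$s_R, truth[, "R"]), 0.9)
  expect_gt(cor(co$lev$s_SI, truth[, "SI"]), 0.9)
})

test_that("protein weight map, protein-based levels and proxies behave as specified", {
  co <- small_cohort()
  prot <- co$co$bundle$proteins
  pmap <- fit_protein_weight_map(co$lev, prot)
  expect_true(all(abs(pmap$w_R) <= 1, na.rm = TRUE))
  # R-loaded markers correlate more with R, SI-loaded with SI
  expect_gt(pmap$w_R[pmap$protein_id == "CXCL11"],
            pmap$w_SI[pmap$protein_id == "CXCL11"])
  expect_gt(pmap$w_SI[pmap$protein_id == "IL6"],
            pmap$w_R[pmap$protein_id == "IL6"])

  # a protein equal to z_R has w_R = 1
  prot2 <- cbind(prot, ZRCOPY = co$lev$z_R[match(rownames(prot), co$lev$sample_id)])
  pmap2 <- fit_protein_weight_map(co$lev, prot2)
  expect_equal(pmap2$w_R[pmap2$protein_id == "ZRCOPY"], 1, tolerance = 1e-10)
  expect_equal(pmap2$w_SI[pmap2$protein_id == "ZRCOPY"],
               cor(co$lev$z_R, co$lev$z_SI), tolerance = 1e-10)

  # constant protein: missing weight plus warning
  prot3 <- cbind(prot, FLAT = 1)
  expect_warning(pmap3 <- fit_protein_weight_map(co$lev, prot3), "constant")
  expect_true(is.na(pmap3$w_R[pmap3$protein_id == "FLAT"]))

  # protein-based inference equals the normal-equations oracle
  pm <- pmap[!is.na(pmap$w_R), ]
  set.seed(8)
  prof <- setNames(rnorm(nrow(pm)), pm$protein_id)
  got <- infer_levels_from_proteins(prof, pmap, standardize = FALSE,
                                    min_overlap = nrow(pm))
  oc <- oracle_ols(as.numeric(prof), cbind(pm$w_R, pm$w_SI))
  expect_equal(c(got$b, got$s_R, got$s_SI), oc, tolerance = 1e-8)
  # zero profile -> zero coefficients
  got0 <- infer_levels_from_proteins(setNames(rep(0, nrow(pm)), pm$protein_id),
                                     pmap, standardize = FALSE,
                                     min_overlap = nrow(pm))
  expect_equal(c(got0$b, got0$s_R, got0$s_SI), c(0, 0, 0))

  # biomarker proxies: z-scored pair means and partial degradation
  px <- biomarker_proxies(prot)
  expect_equal(px$balance_proxy, px$R_proxy - px$SI_proxy)
  zs <- sweep(sweep(prot[, c("CXCL11", "IFNg")], 2, colMeans(prot[, c("CXCL11", "IFNg")])),
              2, apply(prot[, c("CXCL11", "IFNg")], 2,
                       function(v) sqrt(mean((v - mean(v))^2))), "/")
  expect_equal(px$R_proxy, rowMeans(zs), ignore_attr = TRUE, tolerance = 1e-10)
  protNA <- prot
  protNA[1, "IL8"] <- NA
  pxNA <- biomarker_proxies(protNA)
  expect_true(pxNA$partial[1])
  expect_error(biomarker_proxies(prot[, setdiff(colnames(prot), "IL8")]),
               "IL8")
})
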