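test_that("variance explained matches the generating decomposition and nests", {
  co <- small_cohort()
  lev <- co$lev
  set.seed(61)
  # phenotype = 0.8 z_SI + noise with SD 0.6 sd(z_SI): expected R^2 =
  # 0.64/(0.64+0.36) = 0.64
  ph <- 0.8 * lev$z_SI + rnorm(nrow(lev), 0, 0.6 * sd(lev$z_SI))
  names(ph) <- lev$sample_id
  ve <- variance_explained(ph, lev, "SI_only", n_perm = 200, seed = 2)
  expect_equal(ve$r2, 0.64, tolerance = 0.13)
  expect_equal(ve$empirical_p, 1 / 201)

  # phenotype exactly z_R: R-only R^2 = 1
  ph2 <- setNames(lev$z_R, lev$sample_id)
  ve2 <- variance_explained(ph2, lev, "R_only", n_perm = 50, seed = 2)
  expect_equal(ve2$r2, 1, tolerance = 1e-10)

  # joint model dominates both single models
  for (i in 1:5) {
    phr <- setNames(rnorm(nrow(lev)), lev$sample_id)
    r2s <- sapply(c("joint", "SI_only", "R_only"), function(mo)
      variance_explained(phr, lev, mo, n_perm = 20, seed = i)$r2)
    expect_gte(r2s["joint"], r2s["SI_only"] - 1e-12)
    expect_gte(r2s["joint"], r2s["R_only"] - 1e-12)
  }

  expect_error(variance_explained(setNames(rep(1, nrow(lev)), lev$sample_id),
                                  lev, "joint"), "constant phenotype")
})

test_that("correlation map separates R-loaded from SI-loaded features", {
  co <- small_cohort()
  cm <- correlation_map(co$co$bundle$proteins, co$lev)
  expect_true(all(abs(cm$r_SI) <= 1 & abs(cm$r_R) <= 1))
  r_row <- cm[cm$feature_id == "CXCL11", ]
  si_row <- cm[cm$feature_id == "IL6", ]
  expect_gt(r_row$r_R, r_row$r_SI)
  expect_gt(si_row$r_SI, si_row$r_R)

  # feature identical to z_R / negated z_SI
  ft <- cbind(co$co$bundle$proteins,
              ZR = co$lev$z_R[match(rownames(co$co$bundle$proteins),
                                    co$lev$sample_id)],
              NZSI = -co$lev$z_SI[match(rownames(co$co$bundle$proteins),
                                        co$lev$sample_id)])
  cm2 <- correlation_map(ft, co$lev)
  expect_equal(cm2$r_R[cm2$feature_id == "ZR"], 1, tolerance = 1e-10)
  expect_equal(cm2$r_SI[cm2$feature_id == "NZSI"], -1, tolerance = 1e-10)
})

test_that("balance-marker ranking selects planted markers with threshold and cap rules", {
  co <- small_cohort()
  lev <- co$lev
  # two cohorts sharing the gene space; plant markers of each direction
  mk <- function(seed) {
    set.seed(seed)
    z <- co$z
    bal <- lev$balance[match(sample_ids(z), lev$sample_id)]
    z$values["g0001", ] <- bal + rnorm(length(bal), 0, 0.2 * sd(bal))
    z$values["g0002", ] <- -bal + rnorm(length(bal), 0, 0.2 * sd(bal))
    list(expression = z, levels = lev)
  }
  cohorts <- list(monocytes = mk(1), pbmc = mk(2))
  mr <- rank_balance_markers(cohorts, "monocytes", top_n = 5)
  g1 <- mr[mr$gene_id == "g0001", ]
  g2 <- mr[mr$gene_id == "g0002", ]
  expect_gt(g1$mean_r_balance, 0.9)
  expect_true(g1$selected_good && g1$top_good)
  expect_lt(g2$mean_r_balance, -0.9)
  expect_true(g2$selected_impaired && g2$top_impaired)
  # marker directions are disjoint; top sets respect the cap
  expect_false(any(mr$selected_good & mr$selected_impaired))
  expect_lte(sum(mr$top_good), 5)
  expect_lte(sum(mr$top_impaired), 5)
  # thresholds are exclusive: mean r of 0.55 is not selected
  expect_false(any(mr$selected_good & mr$mean_r_balance <= 0.6))
  # invariant to cohort order
  mr2 <- rank_balance_markers(rev(cohorts), "monocytes", top_n = 5)
  expect_equal(mr$selected_good, mr2$selected_good[match(mr$gene_id, mr2$gene_id)])
})

test_that("hypergeometric enrichment matches exhaustive combinatorics and BH arithmetic", {
  # universe 10, set 4, markers 5, overlap 4 -> 6/252
  uni <- paste0("u", 1:10)
  res <- hypergeom_enrich(markers = uni[1:5],
                          collections = list(S = uni[c(1:4)]), universe = uni)
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)
  expect_equal(round(res$p, 5), 0.02381)

  # zero overlap boundary: P(X >= 0) = 1
  res0 <- hypergeom_enrich(uni[1:2], list(S = uni[9:10]), uni)
  expect_lte(res0$p, 1)
  resb <- hypergeom_enrich(uni[1:10], list(S = uni[1]), uni)
  expect_equal(resb$p, 1)

  # exhaustive enumeration for random cases on universes <= 15
  set.seed(77)
  for (i in 1:30) {
    N <- sample(6:15, 1); K <- sample(2:(N - 1), 1); n <- sample(2:(N - 1), 1)
    uni <- paste0("g", seq_len(N))
    markers <- sample(uni, n)
    set <- uni[seq_len(K)]
    k <- length(intersect(markers, set))
    got <- hypergeom_enrich(markers, list(S = set), uni)$p
    expect_equal(got, oracle_hypergeom(N, K, n, k), tolerance = 1e-10)
  }

  # BH q-values: (0.01, 0.02, 0.9) -> (0.03, 0.03, 0.9)
  fake <- data.frame(p = c(0.01, 0.02, 0.9))
  expect_equal(p.adjust(fake$p, "BH"), c(0.03, 0.03, 0.9))
  # and via the interface: q ordering preserved
  uni <- paste0("g", 1:12)
  res3 <- hypergeom_enrich(markers = uni[1:6],
                           collections = list(A = uni[1:5], B = uni[7:11],
                                              C = uni[c(1, 7:9)]),
                           universe = uni)
  expect_equal(res3$q_BH, p.adjust(res3$p, "BH"))
})
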