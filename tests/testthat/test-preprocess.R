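test_that("missing policy picks the regime from the overall missing fraction", {
  # m = 0.1% (< 1%): drop any gene with a missing cell, no imputation
  set.seed(5)
  m <- matrix(rexp(100 * 10) + 1, 100, 10)
  em <- make_em(m)
  em$values[7, 3] <- NA
  out <- apply_missing_policy(em)
  expect_equal(attr(out, "regime"), "low")
  expect_equal(nrow(out$values), 99)
  expect_false(anyNA(out$values))
  expect_equal(attr(out, "dropped_genes"), "g07")

  # m = 5% (medium): heavy gene dropped, the rest imputed
  em2 <- make_em(matrix(rexp(40 * 20) + 1, 40, 20))
  set.seed(6)
  holes <- sample(which(row(em2$values) > 1), round(0.05 * 800))
  em2$values[holes] <- NA
  em2$values[1, 1:16] <- NA  # 80% missing in gene g01
  out2 <- apply_missing_policy(em2)
  expect_equal(attr(out2, "regime"), "medium")
  expect_false("g01" %in% gene_ids(out2))
  expect_false(anyNA(out2$values))

  # no missing values: identity
  em3 <- make_em(matrix(rexp(20) + 1, 4, 5))
  out3 <- apply_missing_policy(em3)
  expect_identical(out3$values, em3$values)

  # high regime: heavy genes dropped, remaining holes left missing
  em4 <- make_em(matrix(rexp(40 * 10) + 1, 40, 10))
  set.seed(7)
  em4$values[sample(400, 100)] <- NA
  out4 <- apply_missing_policy(em4)
  expect_equal(attr(out4, "regime"), "high")
  expect_true(anyNA(out4$values))
})

test_that("knn imputation matches an exhaustive-neighbour oracle and never touches observed cells", {
  set.seed(42)
  m <- matrix(rnorm(8 * 6), 8, 6)
  em <- make_em(m, scale = "log2")
  em$values[3, 2] <- NA
  out <- knn_impute(em, k = 5)

  # oracle: enumerate all gene distances (mean squared difference over
  # co-observed samples), take the 5 nearest, average their values at s2
  target <- em$values[3, ]
  d <- sapply(seq_len(8), function(h) {
    if (h == 3) return(Inf)
    both <- !is.na(target) & !is.na(em$values[h, ])
    sum((target[both] - em$values[h, both])^2) / sum(both)
  })
  nn <- order(d)[1:5]
  expect_equal(out$values[3, 2], mean(em$values[nn, 2]))

  # observed cells unchanged; imputed value within neighbour range
  expect_identical(out$values[-3, ], em$values[-3, ])
  expect_gte(out$values[3, 2], min(em$values[nn, 2]))
  expect_lte(out$values[3, 2], max(em$values[nn, 2]))

  # no missing cells: identity
  em5 <- make_em(matrix(rnorm(30), 6, 5), scale = "log2")
  expect_identical(knn_impute(em5)$values, em5$values)
})

test_that("log2 transform validates scale and positivity", {
  em <- make_em(matrix(c(8, 1, 2, 4), 2, 2))
  out <- log2_transform(em)
  expect_equal(out$values[1, 1], 3)
  expect_equal(out$values[2, 1], 0)
  expect_equal(out$scale, "log2")
  em$values[1, 1] <- 0
  expect_error(log2_transform(em), "nonpositive")
  expect_message(log2_transform(make_em(matrix(1:4, 2, 2), scale = "log2")),
                 "skipping")
})

test_that("per-sample standardization gives population mean 0 / SD 1 and is idempotent", {
  em <- make_em(matrix(c(2, 4, 6), 3, 1), scale = "log2")
  out <- standardize_samples(em)
  expect_equal(as.numeric(out$values), c(-1.22474487, 0, 1.22474487),
               tolerance = 1e-8)
  again <- standardize_samples(out)
  expect_equal(again$values, out$values, tolerance = 1e-12)

  expect_error(standardize_samples(make_em(matrix(5, 3, 1), scale = "log2")),
               "zero-variance sample")
})

test_that("control-anchored gene standardization uses control mean and population SD", {
  m <- rbind(g1 = c(0, 2, 4, 6), g2 = c(1, 2, 3, 10))
  colnames(m) <- c("c1", "c2", "c3", "p1")
  em <- expression_matrix(m, scale = "log2")
  out <- standardize_genes_by_controls(em, c("c1", "c2", "c3"))
  # gene g1: control mean 2, population SD sqrt(8/3); sepsis value 6 -> 2.449
  expect_equal(out$values["g1", "p1"], (6 - 2) / sqrt(8 / 3), tolerance = 1e-8)
  # controls themselves: per-gene mean 0, population SD 1
  ctl <- out$values[, 1:3]
  expect_equal(rowMeans(ctl), c(g1 = 0, g2 = 0), tolerance = 1e-12)
  expect_equal(apply(ctl, 1, function(v) sqrt(mean((v - mean(v))^2))),
               c(g1 = 1, g2 = 1), tolerance = 1e-12)

  # gene constant in controls is dropped with warning
  m2 <- rbind(m, g3 = c(5, 5, 5, 9))
  em2 <- expression_matrix(m2, scale = "log2")
  expect_warning(out2 <- standardize_genes_by_controls(em2, c("c1", "c2", "c3")),
                 "constant in controls")
  expect_false("g3" %in% gene_ids(out2))

  expect_error(standardize_genes_by_controls(em, c("c1", "c2")),
               "impossible")
})

test_that("full pipeline output satisfies the stated invariants deterministically", {
  co <- small_cohort()
  z1 <- preprocess_pipeline(co$co$bundle$expression, control_sample_ids = co$ctrl)
  # step-4 output: control-restricted gene means 0, population SD 1
  ctl <- z1$values[, co$ctrl]
  expect_lt(max(abs(rowMeans(ctl))), 1e-9)
  sds <- apply(ctl, 1, function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(sds - 1)), 1e-9)
  # determinism: identical inputs give bit-identical outputs
  z2 <- preprocess_pipeline(co$co$bundle$expression, control_sample_ids = co$ctrl)
  expect_identical(z1$values, z2$values)
})
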