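test_that("endotype rules partition patients and match the stated thresholds", {
  lev <- data.frame(sample_id = paste0("p", 1:6),
                    balance = c(0.5, -2, -1, 0, -0.1, -3),
                    z_SI = c(0, 3, 0.2, 1, 0.1, 2.5))
  ea <- assign_endotypes(lev, balance_thresh = 0, si_quantile = 0.8)
  expect_equal(ea$endotype[1], "moderate_imbalance")  # balance +0.5
  expect_equal(ea$endotype[4], "moderate_imbalance")  # boundary: >= thresh
  si_cut <- attr(ea, "thresholds_used")[["si_cut"]]
  expect_equal(ea$endotype[2], "high_SI")             # balance -2, z_SI 3 >= cut
  expect_equal(ea$endotype[3], "severe_imbalance")
  # exactly one endotype per assigned patient; high_SI implies both rules
  expect_false(anyNA(ea$endotype))
  hs <- ea[ea$endotype == "high_SI", ]
  expect_true(all(hs$balance < 0 & hs$z_SI >= si_cut))
})

test_that("quantile calibration recovers engineered class proportions", {
  co <- small_cohort()
  sep <- co$lev[grepl("^sepsis", co$lev$sample_id), ]
  # engineer a cohort with known 20/62/16 shares by construction
  set.seed(5)
  n <- 500
  fake <- data.frame(sample_id = paste0("x", 1:n),
                     balance = rnorm(n, -1.5, 1), z_SI = rnorm(n, 2, 1))
  th <- calibrate_endotype_thresholds(fake, p_moderate = 0.20, p_high_si = 0.16)
  ea <- assign_endotypes(fake, balance_thresh = th$balance_thresh,
                         si_quantile = th$si_quantile)
  shares <- 100 * table(ea$endotype) / n
  expect_lt(abs(shares[["moderate_imbalance"]] - 20), 5)
  expect_lt(abs(shares[["severe_imbalance"]] - 62), 5)
  expect_lt(abs(shares[["high_SI"]] - 16), 5)
  # works on real inferred sepsis levels too (partition is complete)
  th2 <- calibrate_endotype_thresholds(sep)
  ea2 <- assign_endotypes(sep, th2$balance_thresh, th2$si_quantile)
  expect_equal(sort(unique(ea2$endotype)),
               sort(intersect(c("moderate_imbalance", "severe_imbalance", "high_SI"),
                              unique(ea2$endotype))))
})

test_that("KM estimate and log-rank statistic match hand-worked risk tables", {
  # 6-patient toy: events at 1,2,4,5; censored at 3 and 6
  surv6 <- data.frame(sample_id = paste0("p", 1:6),
                      time_days = 1:6, event = c(1, 1, 0, 1, 1, 0))
  asg <- data.frame(sample_id = paste0("p", 1:6),
                    endotype = rep(c("A", "B"), 3))
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = surv6)
  # hand product-limit: 5/6, 5/6*4/5, (censor), *2/3, *1/2
  expect_equal(summary(fit)$surv,
               c(5/6, 5/6 * 4/5, 5/6 * 4/5 * 2/3, 5/6 * 4/5 * 2/3 * 1/2),
               tolerance = 1e-12)

  # 3-vs-3 log-rank, hand-worked 2x2 risk tables:
  # group A dies at 1,2,3; group B at 4,5,6
  toy <- data.frame(sample_id = paste0("q", 1:6),
                    time_days = 1:6, event = 1)
  grp <- data.frame(sample_id = paste0("q", 1:6),
                    endotype = rep(c("A", "B"), each = 3))
  km <- km_logrank(grp, toy, min_group = 3)
  O <- 3
  E <- 3/6 + 2/5 + 1/4
  V <- (3*3*1*5) / (36*5) + (2*3*1*4) / (25*4) + (1*3*1*3) / (16*3)
  expect_equal(km$overall$chisq, (O - E)^2 / V, tolerance = 1e-8)
  expect_equal(km$overall$p, pchisq((O - E)^2 / V, 1, lower.tail = FALSE),
               tolerance = 1e-8)

  # identical survival in both groups: statistic ~ 0, p ~ 1
  same <- data.frame(sample_id = paste0("r", 1:10),
                     time_days = rep(1:5, 2), event = 1)
  gs <- data.frame(sample_id = paste0("r", 1:10),
                   endotype = rep(c("A", "B"), each = 5))
  km2 <- km_logrank(gs, same, min_group = 5)
  expect_lt(km2$overall$chisq, 1e-10)

  # small group exclusion warning
  gsm <- gs; gsm$endotype[1:5] <- c("A", "A", "A", "A", "C")
  expect_warning(km_logrank(gsm, same, min_group = 4), "excluded")

  # breslow variant runs and reports the test used
  km3 <- km_logrank(grp, toy, test = "breslow", min_group = 3)
  expect_equal(km3$test, "breslow")
  expect_gt(km3$overall$chisq, 0)
})

test_that("log-rank detects a hazard-ratio-3 difference with high power", {
  set.seed(13)
  hits <- 0
  for (i in 1:20) {
    t1 <- rexp(100, 1); t2 <- rexp(100, 3)
    df <- data.frame(sample_id = paste0("s", 1:200),
                     time_days = pmin(c(t1, t2), 5),
                     event = as.integer(c(t1, t2) <= 5))
    gr <- data.frame(sample_id = df$sample_id,
                     endotype = rep(c("A", "B"), each = 100))
    if (km_logrank(gr, df)$overall$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("Cox model recovers coefficients, respects scale invariance and guards", {
  co <- small_cohort()
  cfg <- co$cfg
  set.seed(99)
  # n = 500 latents from the sepsis condition; hazard from (SI, R)
  ch <- chol(cfg$latent_cov + diag(1e-12, 4))
  lat <- matrix(rnorm(500 * 4), ncol = 4) %*% ch
  lat <- sweep(lat, 2, cfg$latent_means$sepsis, "+")
  colnames(lat) <- c("R", "T", "SI", "IM1")
  rownames(lat) <- paste0("v", 1:500)
  sv <- generate_survival(lat, cfg, seed = 3)
  covs <- data.frame(sample_id = rownames(lat), SI = lat[, "SI"], R = lat[, "R"])
  fit <- cox_ph(sv, covs, c("SI", "R"))
  expect_lt(abs(fit$log_hr[fit$term == "SI"] - 0.7), 0.2)
  expect_lt(abs(fit$log_hr[fit$term == "R"] - (-0.7)), 0.2)
  expect_true(all(c("age", "sex") %in% fit$term))

  # doubling all times leaves hazard ratios unchanged
  sv2 <- sv; sv2$time_days <- sv$time_days * 2
  fit2 <- cox_ph(sv2, covs, c("SI", "R"))
  expect_equal(fit2$log_hr, fit$log_hr, tolerance = 1e-8)

  # null covariate: CI covers 0 (checked across replicates at ~95%)
  set.seed(7)
  cover <- mean(replicate(30, {
    svn <- sv
    covn <- data.frame(sample_id = rownames(lat), X = rnorm(500))
    f <- cox_ph(svn, covn, "X", use_age_sex = FALSE)
    log(f$ci_lower) <= 0 && log(f$ci_upper) >= 0
  }))
  expect_gt(cover, 0.8)

  # too few events is refused
  svf <- sv[1:40, ]
  svf$event <- 0; svf$event[1:5] <- 1
  expect_error(cox_ph(svf, covs, "SI"), "events")
})
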