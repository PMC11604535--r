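# R/SI-based endotype assignment and its prognostic evaluation. The survival
# machinery (Kaplan-Meier product-limit estimate, log-rank / generalized
# Wilcoxon tests, Cox proportional hazards with Efron tie handling) is
# delegated to the survival package behind a thin interface.

#' Assign R/SI endotypes
#'
#' Patients with a balance score at or above `balance_thresh` have a limited
#' reduction in R/SI balance ("moderate_imbalance"). Patients below it are
#' subdivided: those whose standardized SI level reaches the cohort
#' `si_quantile` are "high_SI", the rest "severe_imbalance". Thresholds are
#' explicit inputs; [calibrate_endotype_thresholds()] can derive them from
#' target class proportions.
#'
#' @param levels `ProgramLevels` with `balance` and `z_SI`.
#' @param balance_thresh Balance cutoff on the standardized scale (default 0:
#'   non-negative balance = limited reduction).
#' @param si_quantile Cohort quantile of `z_SI` defining "exceptionally high"
#'   SI (default 0.85).
#' @return Data frame (class `EndotypeAssignment`) with `sample_id`,
#'   `endotype`, `balance`, `z_SI`; attribute `"thresholds_used"` records the
#'   numeric cutoffs. Patients with missing levels are left unassigned
#'   (`NA`) and listed in attribute `"unassigned"`.
#' @export
assign_endotypes <- function(levels, balance_thresh = 0, si_quantile = 0.85) {
  stopifnot(all(c("balance", "z_SI") %in% names(levels)))
  si_cut <- stats::quantile(levels$z_SI, si_quantile, na.rm = TRUE, names = FALSE)
  endo <- ifelse(levels$balance >= balance_thresh, "moderate_imbalance",
                 ifelse(levels$z_SI >= si_cut, "high_SI", "severe_imbalance"))
  out <- data.frame(sample_id = levels$sample_id, endotype = endo,
                    balance = levels$balance, z_SI = levels$z_SI,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds_used") <- c(balance_thresh = balance_thresh,
                                    si_cut = si_cut, si_quantile = si_quantile)
  attr(out, "unassigned") <- out$sample_id[is.na(endo)]
  class(out) <- c("EndotypeAssignment", class(out))
  out
}

#' Calibrate endotype thresholds to target class proportions
#'
#' Chooses the balance cutoff as the quantile putting `p_moderate` of the
#' cohort at or above it, and the SI quantile so that among the remaining
#' patients a share `p_high_si` of the whole cohort exceeds it.
#'
#' @param levels `ProgramLevels` with `balance`, `z_SI`.
#' @param p_moderate,p_high_si Target shares of the moderate-imbalance and
#'   high-SI classes (the severe class takes the rest).
#' @return List with `balance_thresh` and `si_quantile` usable in
#'   [assign_endotypes()].
#' @export
calibrate_endotype_thresholds <- function(levels, p_moderate = 0.20,
                                          p_high_si = 0.16) {
  stopifnot(p_moderate > 0, p_high_si > 0, p_moderate + p_high_si < 1)
  bal <- levels$balance[!is.na(levels$balance)]
  bt <- stats::quantile(bal, 1 - p_moderate, names = FALSE)
  low <- levels$z_SI[levels$balance < bt & !is.na(levels$balance)]
  # si cut on the full-cohort z_SI scale such that ~p_high_si of all patients
  # fall in the high-SI class
  n_high <- round(p_high_si * length(bal))
  si_cut <- sort(low, decreasing = TRUE)[max(n_high, 1)]
  sq <- mean(levels$z_SI <= si_cut, na.rm = TRUE)
  list(balance_thresh = bt, si_quantile = sq)
}

#' Kaplan-Meier curves and log-rank / Breslow tests across endotypes
#'
#' Product-limit survival estimate per group plus the overall and pairwise
#' significance of survival differences. `test = "logrank"` uses the
#' standard log-rank statistic; `test = "breslow"` the generalized Wilcoxon
#' weighting (survdiff with rho = 1), which up-weights early differences.
#'
#' @param assignments `EndotypeAssignment` (or any data frame with
#'   `sample_id` and a `endotype`/`group` column).
#' @param survival_df Data frame with `sample_id`, `time_days`, `event`.
#' @param test `"logrank"` or `"breslow"`.
#' @param min_group Minimum patients per group (default 5); smaller groups
#'   are excluded with a warning.
#' @return List with `curves` (data frame: group, time, n_risk, n_event,
#'   survival, lower, upper), `overall` (chisq, df, p) and `pairwise`
#'   (data frame of group pairs with p).
#' @export
km_logrank <- function(assignments, survival_df, test = c("logrank", "breslow"),
                       min_group = 5L) {
  test <- match.arg(test)
  rho <- if (test == "logrank") 0 else 1
  grp_col <- if ("endotype" %in% names(assignments)) "endotype" else "group"
  df <- merge(assignments[, c("sample_id", grp_col)], survival_df,
              by = "sample_id")
  names(df)[names(df) == grp_col] <- "group"
  df <- df[!is.na(df$group) & !is.na(df$time_days) & !is.na(df$event), ]
  tab <- table(df$group)
  small <- names(tab)[tab < min_group]
  if (length(small)) {
    warning("groups below minimum size excluded: ", paste(small, collapse = ", "))
    df <- df[!df$group %in% small, ]
  }
  if (length(unique(df$group)) < 2) stop("need >= 2 groups of sufficient size")
  df$group <- factor(df$group)
  su <- survival::Surv(df$time_days, df$event)
  fit <- survival::survfit(su ~ group, data = df, conf.type = "log-log")
  sm <- summary(fit)
  strata <- if (!is.null(sm$strata)) sub("^group=", "", as.character(sm$strata))
            else rep(levels(df$group)[1], length(sm$time))
  curves <- data.frame(group = strata, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, survival = sm$surv,
                       lower = sm$lower, upper = sm$upper,
                       stringsAsFactors = FALSE)
  sd_all <- survival::survdiff(su ~ group, data = df, rho = rho)
  k <- length(sd_all$n)
  overall <- list(chisq = sd_all$chisq, df = k - 1,
                  p = stats::pchisq(sd_all$chisq, k - 1, lower.tail = FALSE))
  grps <- levels(df$group)
  pw <- list()
  for (i in seq_len(length(grps) - 1)) for (j in (i + 1):length(grps)) {
    sub <- df[df$group %in% c(grps[i], grps[j]), ]
    sdp <- survival::survdiff(survival::Surv(time_days, event) ~ group,
                              data = sub, rho = rho)
    pw[[length(pw) + 1L]] <- data.frame(
      group1 = grps[i], group2 = grps[j], chisq = sdp$chisq,
      p = stats::pchisq(sdp$chisq, 1, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  list(curves = curves, overall = overall, pairwise = do.call(rbind, pw),
       test = test)
}

#' Cox proportional-hazards model for 28-day mortality
#'
#' Partial-likelihood fit with Efron tie handling. Covariates are the
#' continuous balance score or endotype indicators, plus age and sex when
#' available in the survival table.
#'
#' @param survival_df Data frame with `sample_id`, `time_days`, `event` and
#'   optionally `age`, `sex`.
#' @param covariates Data frame (or named vector source) with `sample_id`
#'   plus the model covariates, e.g. `balance`, or a factor `endotype`.
#' @param covariate_names Columns of `covariates` to include.
#' @param use_age_sex Include `age` and `sex` from `survival_df` when present
#'   (default TRUE).
#' @param min_events Minimum number of events for a continuous-covariate
#'   model (default 30; configurable down for toy data).
#' @return Data frame with `term`, `log_hr`, `hr`, `se`, `ci_lower`,
#'   `ci_upper` (95% Wald, on the HR scale), `p`; attribute `"fit"` carries
#'   the `coxph` object.
#' @export
cox_ph <- function(survival_df, covariates, covariate_names,
                   use_age_sex = TRUE, min_events = 30L) {
  df <- merge(survival_df, covariates, by = "sample_id")
  terms <- covariate_names
  if (use_age_sex) {
    if ("age" %in% names(df) && !all(is.na(df$age))) terms <- c(terms, "age")
    if ("sex" %in% names(df) && !all(is.na(df$sex))) terms <- c(terms, "sex")
  }
  df <- df[stats::complete.cases(df[, c("time_days", "event", terms)]), ]
  if (sum(df$event) < min_events)
    stop(sprintf("only %d events (< %d): continuous-covariate Cox fit refused",
                 sum(df$event), min_events))
  if ("sex" %in% terms && !is.numeric(df$sex))
    df$sex <- as.integer(factor(df$sex)) - 1L
  fml <- stats::as.formula(paste("survival::Surv(time_days, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w)))
        stop("Cox fit did not converge (possible complete separation): ",
             conditionMessage(w))
      suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
    })
  s <- summary(fit)
  co <- s$coefficients
  data.frame(term = rownames(co), log_hr = co[, "coef"],
             hr = exp(co[, "coef"]), se = co[, "se(coef)"],
             ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
             ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
             p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE,
             row.names = NULL) -> out
  attr(out, "fit") <- fit
  out
}
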