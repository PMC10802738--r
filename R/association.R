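#' @importFrom survival Surv coxph survSplit
NULL

#' Covariate sets for the nested association models
#'
#' Model 1 adjusts for age and sex; model 2 adds APOE-e4 allele count
#' (or carrier status); model 3 adds cardiovascular/lifestyle/kidney covariates
#' (BMI, type-2 diabetes, education, hypertension, smoking, eGFR). The sets are
#' nested by construction.
#'
#' @param model 1, 2 or 3.
#' @param e4_carrier if `TRUE`, e4 enters as carrier status (0/1) instead of
#'   allele count (0/1/2).
#' @return character vector of phenotype-column terms.
#' @export
model_covariates <- function(model, e4_carrier = FALSE) {
  stopifnot(model %in% 1:3)
  e4_term <- if (e4_carrier) "I(apoe_e4 > 0)" else "apoe_e4"
  covs <- c("age", "sex")
  if (model >= 2) covs <- c(covs, e4_term)
  if (model >= 3) covs <- c(covs, "bmi", "diabetes", "education",
                            "hypertension", "smoking", "egfr")
  covs
}

# Apply a follow-up cutoff: events after `cutoff` are censored at the cutoff.
apply_followup_cutoff <- function(pheno, cutoff) {
  if (is.null(cutoff)) return(pheno)
  stopifnot(is.numeric(cutoff), cutoff > 0)
  over <- pheno$time > cutoff
  pheno$event[over] <- 0L
  pheno$time[over] <- cutoff
  pheno
}

#' Proteome-wide Cox proportional-hazards scan for incident LOAD
#'
#' Fits, per aptamer, a Cox model for incident events with the protein as a
#' single standardized linear term plus the covariates of the requested nested
#' model. Prevalent cases are excluded from the risk set; participants are
#' censored at death/non-AD dementia or the administrative horizon (already
#' encoded in `time`/`event`). Ties are handled with the Efron approximation.
#' Hazard ratios are per SD of protein level. BH-FDR is computed across
#' aptamers within the call (one family per model x outcome x follow-up
#' window).
#'
#' @param proteins samples x aptamers numeric matrix (standardized).
#' @param pheno phenotype data.frame with columns `time`, `event`,
#'   `prevalent`, `age`, `sex`, `apoe_e4` and, for model 3, the extra
#'   covariates.
#' @param model nested model id (1, 2 or 3).
#' @param followup_cutoff optional follow-up cutoff in years (e.g. 10).
#' @param min_events minimum number of events required to fit (default 10).
#' @param e4_carrier use carrier coding for e4 (default allele count).
#' @return data.frame of class `assoc_records`: `aptamer`, `model`, `outcome`,
#'   `followup`, `beta`, `hr`, `se`, `p`, `fdr`, `n`, `n_events`, `flag`.
#'   Degenerate or non-converged aptamers carry a flag and NA estimates; they
#'   are excluded from the FDR family.
#' @export
fit_cox_per_aptamer <- function(proteins, pheno, model = 1,
                                followup_cutoff = NULL, min_events = 10,
                                e4_carrier = FALSE) {
  proteins <- as.matrix(proteins)
  stopifnot(nrow(proteins) == nrow(pheno))
  covs <- model_covariates(model, e4_carrier)
  ph <- pheno[pheno$prevalent == 0, , drop = FALSE]
  pm <- proteins[pheno$prevalent == 0, , drop = FALSE]
  if (any(ph$time <= 0)) stop("non-positive follow-up time in risk set", call. = FALSE)
  ph <- apply_followup_cutoff(ph, followup_cutoff)

  records <- lapply(seq_len(ncol(pm)), function(j) {
    dat <- ph
    dat$.protein <- pm[, j]
    dat <- dat[!is.na(dat$.protein), , drop = FALSE]
    rec <- list(aptamer = colnames(pm)[j], model = model, outcome = "incident",
                followup = if (is.null(followup_cutoff)) Inf else followup_cutoff,
                beta = NA_real_, hr = NA_real_, se = NA_real_, p = NA_real_,
                n = nrow(dat), n_events = sum(dat$event), flag = "ok")
    if (stats::sd(dat$.protein) < 1e-12) { rec$flag <- "constant_protein"; return(rec) }
    if (rec$n_events < min_events) { rec$flag <- "too_few_events"; return(rec) }
    f <- stats::as.formula(paste("survival::Surv(time, event) ~ .protein +",
                                 paste(covs, collapse = " + ")))
    fit <- tryCatch(
      survival::coxph(f, data = dat, ties = "efron"),
      error = function(e) NULL, warning = function(w) {
        fit2 <- suppressWarnings(survival::coxph(f, data = dat, ties = "efron"))
        attr(fit2, "warned") <- conditionMessage(w)
        fit2
      })
    if (is.null(fit) || is.na(stats::coef(fit)[".protein"])) {
      rec$flag <- "no_convergence"; return(rec)
    }
    sm <- summary(fit)$coefficients
    rec$beta <- sm[".protein", "coef"]
    rec$se <- sm[".protein", "se(coef)"]
    rec$hr <- exp(rec$beta)
    rec$p <- sm[".protein", "Pr(>|z|)"]
    if (!is.null(attr(fit, "warned")) &&
        grepl("converge|infinite", attr(fit, "warned"))) rec$flag <- "no_convergence"
    rec
  })
  finalize_assoc(records)
}

#' Proteome-wide logistic scan for prevalent LOAD
#'
#' Cross-sectional baseline logistic regression of the prevalent flag on each
#' standardized protein plus the covariates of the requested nested model.
#' Complete separation is reported with a `separation` flag rather than a
#' silent drop.
#'
#' @inheritParams fit_cox_per_aptamer
#' @param min_cases minimum number of prevalent cases required (default 10).
#' @return data.frame of class `assoc_records` with `outcome = "prevalent"`;
#'   `hr` holds the odds ratio per SD protein.
#' @export
fit_logistic_prevalent <- function(proteins, pheno, model = 1,
                                   min_cases = 10, e4_carrier = FALSE) {
  proteins <- as.matrix(proteins)
  stopifnot(nrow(proteins) == nrow(pheno))
  if (is.null(pheno$prevalent)) stop("pheno lacks a 'prevalent' flag", call. = FALSE)
  covs <- model_covariates(model, e4_carrier)
  records <- lapply(seq_len(ncol(proteins)), function(j) {
    dat <- pheno
    dat$.protein <- proteins[, j]
    dat <- dat[!is.na(dat$.protein), , drop = FALSE]
    rec <- list(aptamer = colnames(proteins)[j], model = model,
                outcome = "prevalent", followup = NA_real_,
                beta = NA_real_, hr = NA_real_, se = NA_real_, p = NA_real_,
                n = nrow(dat), n_events = sum(dat$prevalent), flag = "ok")
    if (stats::sd(dat$.protein) < 1e-12) { rec$flag <- "constant_protein"; return(rec) }
    if (rec$n_events < min_cases) { rec$flag <- "too_few_cases"; return(rec) }
    f <- stats::as.formula(paste("prevalent ~ .protein +", paste(covs, collapse = " + ")))
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm(f, data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    rec$beta <- sm[".protein", "Estimate"]
    rec$se <- sm[".protein", "Std. Error"]
    rec$hr <- exp(rec$beta)
    rec$p <- sm[".protein", "Pr(>|z|)"]
    if (separated || abs(rec$beta) > 15) {
      rec$flag <- "separation"
      rec$beta <- rec$hr <- rec$se <- rec$p <- NA_real_
    }
    rec
  })
  finalize_assoc(records)
}

finalize_assoc <- function(records) {
  df <- do.call(rbind, lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  df$fdr <- NA_real_
  fit_ok <- !is.na(df$p)
  if (any(fit_ok)) df$fdr[fit_ok] <- bh_fdr(df$p[fit_ok])
  class(df) <- c("assoc_records", "data.frame")
  df
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values: `q_i = min_{j: p_(j) >= p_(i)} p_(j) * m / j`,
#' capped at 1, returned in the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("pvalues must be numeric", call. = FALSE)
  bad <- which(is.na(pvalues) | pvalues < 0 | pvalues > 1)
  if (length(bad))
    stop(sprintf("p-values outside [0, 1] at index: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Test time-dependence of per-aptamer protein effects
#'
#' Splits follow-up into episodes at `split_at` years, fits a Cox model with
#' period-specific protein coefficients, and compares it with the
#' constant-coefficient model by a likelihood-ratio test. A period without
#' events yields an undefined period estimate and the LRT is skipped for that
#' aptamer.
#'
#' @inheritParams fit_cox_per_aptamer
#' @param split_at split time in years.
#' @return data.frame: `aptamer`, `beta_early`, `beta_late`, `lrt_stat`,
#'   `lrt_df`, `lrt_p`, `flag`.
#' @export
time_dependence_check <- function(proteins, pheno, model = 1, split_at = 10,
                                  e4_carrier = FALSE) {
  proteins <- as.matrix(proteins)
  covs <- model_covariates(model, e4_carrier)
  ph <- pheno[pheno$prevalent == 0, , drop = FALSE]
  pm <- proteins[pheno$prevalent == 0, , drop = FALSE]
  if (split_at <= 0 || split_at >= Inf) stop("split_at must be a positive time", call. = FALSE)

  out <- lapply(seq_len(ncol(pm)), function(j) {
    dat <- ph
    dat$.protein <- pm[, j]
    dat <- dat[!is.na(dat$.protein), , drop = FALSE]
    rec <- list(aptamer = colnames(pm)[j], beta_early = NA_real_,
                beta_late = NA_real_, lrt_stat = NA_real_, lrt_df = NA_real_,
                lrt_p = NA_real_, flag = "ok")
    split <- survival::survSplit(Surv(time, event) ~ .,
                                 data = dat, cut = split_at, episode = "period")
    split$period <- factor(split$period)
    base_f <- stats::as.formula(
      paste("survival::Surv(tstart, time, event) ~ .protein +",
            paste(covs, collapse = " + ")))
    m0 <- survival::coxph(base_f, data = split, ties = "efron")
    if (nlevels(split$period) < 2) {
      # split beyond last follow-up time: single episode, nothing to compare
      rec$beta_early <- stats::coef(m0)[".protein"]
      rec$lrt_stat <- 0; rec$lrt_df <- 0; rec$lrt_p <- 1
      rec$flag <- "single_period"
      return(rec)
    }
    ev_by_period <- tapply(split$event, split$period, sum)
    if (any(ev_by_period == 0)) { rec$flag <- "no_events_in_period"; return(rec) }
    full_f <- stats::as.formula(
      paste("survival::Surv(tstart, time, event) ~ .protein:period +",
            paste(covs, collapse = " + ")))
    m1 <- survival::coxph(full_f, data = split, ties = "efron")
    cf <- stats::coef(m1)
    rec$beta_early <- cf[".protein:period1"]
    rec$beta_late <- cf[".protein:period2"]
    lrt <- 2 * (m1$loglik[2] - m0$loglik[2])
    df <- length(cf) - length(stats::coef(m0))
    rec$lrt_stat <- lrt
    rec$lrt_df <- df
    rec$lrt_p <- stats::pchisq(lrt, df = df, lower.tail = FALSE)
    rec
  })
  do.call(rbind, lapply(out, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
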