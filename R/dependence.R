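#' Classify LOAD-associated proteins as APOE-dependent or -independent
#'
#' A protein is APOE-dependent when it is FDR-significant in the age/sex model
#' (model 1) but its association is abolished (nominal P > `alpha_p`) or its
#' direction of effect inverts once APOE-e4 enters the model (model 2).
#' A protein is APOE-independent when it remains FDR-significant in model 2.
#' A protein meeting both the dependence flip clause and model-2 FDR
#' significance is labelled dependent (the flip signals an e4-driven primary
#' association). Everything else is "other". Sign inversion is judged on the
#' full-precision log-effect, never on rounded hazard ratios.
#'
#' @param records_model1,records_model2 `assoc_records` data.frames (or any
#'   data.frame with `aptamer`, `beta`, `p`, `fdr`) for the two nested models,
#'   matched one-to-one on `aptamer`.
#' @param alpha_fdr FDR threshold (default 0.05).
#' @param alpha_p nominal significance threshold in model 2 (default 0.05).
#' @return data.frame: `aptamer`, `label` (`dependent`/`independent`/`other`),
#'   `direction_flip`, `fdr_model1`, `p_model2`, `sign_model1`, `sign_model2`.
#' @export
classify_dependence <- function(records_model1, records_model2,
                                alpha_fdr = 0.05, alpha_p = 0.05) {
  need <- c("aptamer", "beta", "p", "fdr")
  stopifnot(all(need %in% names(records_model1)),
            all(need %in% names(records_model2)))
  extra1 <- setdiff(records_model1$aptamer, records_model2$aptamer)
  extra2 <- setdiff(records_model2$aptamer, records_model1$aptamer)
  if (length(extra1) || length(extra2))
    stop(sprintf("aptamers not matched across models: %s",
                 paste(c(extra1, extra2), collapse = ", ")), call. = FALSE)
  r2 <- records_model2[match(records_model1$aptamer, records_model2$aptamer), ]
  r1 <- records_model1

  flip <- sign(r1$beta) != sign(r2$beta)
  dependent <- !is.na(r1$fdr) & r1$fdr < alpha_fdr &
    ((!is.na(r2$p) & r2$p > alpha_p) | (!is.na(flip) & flip))
  independent <- !dependent & !is.na(r2$fdr) & r2$fdr < alpha_fdr
  label <- ifelse(dependent, "dependent", ifelse(independent, "independent", "other"))
  data.frame(aptamer = r1$aptamer,
             label = label,
             direction_flip = flip,
             fdr_model1 = r1$fdr,
             p_model2 = r2$p,
             sign_model1 = sign(r1$beta),
             sign_model2 = sign(r2$beta),
             stringsAsFactors = FALSE)
}

#' APOE-e4 hazard ratio before and after protein adjustment
#'
#' Mediation-by-adjustment: fits the base Cox model
#' `Surv(time, event) ~ apoe_e4 + age + sex` on the incident risk set, then
#' re-fits with each candidate protein added individually and with all of them
#' jointly, reporting the e4 hazard ratio from each fit. A mediator pulls the
#' e4 effect toward the null; an e4-suppressed protein with an opposing
#' LOAD association pushes it away (the "masking" pattern). The percentage
#' change is reported on the log-HR scale by default
#' (`100 * (log hr_adj - log hr_base) / log hr_base`); the HR-scale variant
#' `100 * (hr_adj - hr_base) / (hr_base - 1)` is available via `scale`.
#'
#' @param pheno phenotype data.frame (see [fit_cox_per_aptamer()]).
#' @param proteins samples x aptamers matrix.
#' @param protein_ids aptamer ids (columns of `proteins`) to adjust for.
#' @param scale `"log_hr"` (default) or `"hr"` for the pct-change definition.
#' @param e4_carrier use carrier coding for e4.
#' @return list of class `mediation_result`:
#'   \item{base}{e4 HR, se, p of the unadjusted base model.}
#'   \item{mediation}{data.frame `aptamer`, `hr_e4_base`, `hr_e4_adjusted`,
#'     `pct_change`.}
#'   \item{multivariable}{e4 HR, se, p with all proteins entered jointly.}
#' @export
e4_effect_with_adjustment <- function(pheno, proteins, protein_ids,
                                      scale = c("log_hr", "hr"),
                                      e4_carrier = FALSE) {
  scale <- match.arg(scale)
  proteins <- as.matrix(proteins)
  missing_ids <- setdiff(protein_ids, colnames(proteins))
  if (length(missing_ids))
    stop(sprintf("proteins not in matrix: %s", paste(missing_ids, collapse = ", ")),
         call. = FALSE)
  keep <- pheno$prevalent == 0
  ph <- pheno[keep, , drop = FALSE]
  pm <- proteins[keep, protein_ids, drop = FALSE]
  e4_term <- if (e4_carrier) "I(apoe_e4 > 0)" else "apoe_e4"

  fit_e4 <- function(extra_cols) {
    dat <- cbind(ph, extra_cols)
    rhs <- c(e4_term, "age", "sex", colnames(extra_cols))
    f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(rhs, collapse = " + ")))
    fit <- survival::coxph(f, data = dat, ties = "efron")
    sm <- summary(fit)$coefficients
    c(beta = sm[1, "coef"], se = sm[1, "se(coef)"], p = sm[1, "Pr(>|z|)"])
  }
  base <- fit_e4(ph[, 0, drop = FALSE])
  hr_base <- exp(base[["beta"]])

  pct <- function(hr_adj) {
    if (scale == "log_hr") 100 * (log(hr_adj) - log(hr_base)) / log(hr_base)
    else 100 * (hr_adj - hr_base) / (hr_base - 1)
  }
  med <- do.call(rbind, lapply(protein_ids, function(id) {
    col <- pm[, id, drop = FALSE]
    colnames(col) <- ".adj_protein"
    adj <- fit_e4(as.data.frame(col))
    data.frame(aptamer = id, hr_e4_base = hr_base,
               hr_e4_adjusted = exp(adj[["beta"]]),
               pct_change = pct(exp(adj[["beta"]])),
               stringsAsFactors = FALSE)
  }))

  block <- pm[stats::complete.cases(pm), , drop = FALSE]
  kappa_val <- tryCatch(kappa(stats::cor(block), exact = TRUE), error = function(e) NA)
  if (is.finite(kappa_val) && kappa_val > 1e4)
    warning(sprintf("protein adjustment block is near-collinear (condition number %.3g)",
                    kappa_val), call. = FALSE)
  all_cols <- as.data.frame(pm)
  colnames(all_cols) <- make.names(colnames(all_cols))
  multi <- fit_e4(all_cols)

  structure(list(
    base = list(hr = hr_base, se = base[["se"]], p = base[["p"]]),
    mediation = med,
    multivariable = list(hr = exp(multi[["beta"]]), se = multi[["se"]],
                         p = multi[["p"]])
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> base e4 HR = %.3f; multivariable e4 HR = %.3f (%d proteins)\n",
              x$base$hr, x$multivariable$hr, nrow(x$mediation)))
  print(x$mediation, row.names = FALSE)
  invisible(x)
}

#' Per-aptamer linear regression of protein level on APOE-e4 dose
#'
#' Fits `protein ~ apoe_e4 + age + sex` per aptamer; the beta is the change in
#' (standardized) protein level per e4 allele. BH-FDR across aptamers.
#'
#' @inheritParams fit_cox_per_aptamer
#' @return data.frame: `aptamer`, `beta`, `se`, `p`, `fdr`.
#' @export
protein_e4_regression <- function(proteins, pheno) {
  proteins <- as.matrix(proteins)
  stopifnot(nrow(proteins) == nrow(pheno))
  if (stats::var(pheno$apoe_e4) < 1e-12)
    stop("no variance in APOE-e4 exposure", call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(ncol(proteins)), function(j) {
    dat <- data.frame(y = proteins[, j], apoe_e4 = pheno$apoe_e4,
                      age = pheno$age, sex = pheno$sex)
    fit <- stats::lm(y ~ apoe_e4 + age + sex, data = dat)
    sm <- summary(fit)$coefficients
    data.frame(aptamer = colnames(proteins)[j],
               beta = sm["apoe_e4", "Estimate"], se = sm["apoe_e4", "Std. Error"],
               p = sm["apoe_e4", "Pr(>|t|)"], stringsAsFactors = FALSE)
  }))
  out$fdr <- bh_fdr(out$p)
  out
}

#' Protein x APOE-e4 interaction check
#'
#' Adds a protein-by-e4 product term to the model-2 Cox fit and reports the
#' interaction p-value per aptamer, leaving the main-effect records untouched.
#'
#' @inheritParams fit_cox_per_aptamer
#' @return data.frame: `aptamer`, `beta_interaction`, `se`, `p`.
#' @export
protein_e4_interaction <- function(proteins, pheno, e4_carrier = FALSE) {
  proteins <- as.matrix(proteins)
  keep <- pheno$prevalent == 0
  ph <- pheno[keep, , drop = FALSE]
  pm <- proteins[keep, , drop = FALSE]
  e4_term <- if (e4_carrier) "I(apoe_e4 > 0)" else "apoe_e4"
  do.call(rbind, lapply(seq_len(ncol(pm)), function(j) {
    dat <- ph
    dat$.protein <- pm[, j]
    f <- stats::as.formula(paste(
      "survival::Surv(time, event) ~ .protein *", e4_term, "+ age + sex"))
    fit <- survival::coxph(f, data = dat, ties = "efron")
    sm <- summary(fit)$coefficients
    ix <- grep("^\\.protein:", rownames(sm))
    data.frame(aptamer = colnames(pm)[j],
               beta_interaction = sm[ix, "coef"], se = sm[ix, "se(coef)"],
               p = sm[ix, "Pr(>|z|)"], stringsAsFactors = FALSE)
  }))
}
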