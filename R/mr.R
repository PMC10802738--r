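#' Instrument-selection parameters for Mendelian randomization
#'
#' Defaults follow the cis-pQTL instrument design: a 500 kb cis half-window
#' around the protein-coding gene, a window-wide Bonferroni threshold
#' `Pb = window_alpha / N` (N = variants in the window), greedy LD clumping at
#' r-squared 0.2 for the forward direction and 0.01 for the reverse direction,
#' proxy substitution above r-squared 0.8, genome-wide significance 5e-8 for
#' reverse instruments, and the APOE region chr19:45,048,858-45,733,201
#' (1-based inclusive) for the APOE-locus exclusion.
#'
#' @param cis_halfwidth cis window half-width in base pairs.
#' @param window_alpha numerator of the window-wide threshold.
#' @param clump_r2_forward,clump_r2_reverse r-squared clumping thresholds.
#' @param proxy_r2 minimum r-squared for proxy substitution.
#' @param gwas_alpha_reverse genome-wide significance threshold for reverse
#'   instruments.
#' @param apoe_region list with `chrom`, `start`, `end`.
#' @param tss_anchored anchor the cis window on the gene start (TSS) rather
#'   than the gene body.
#' @param keep_palindromic keep palindromic (A/T, C/G) variants at
#'   harmonization instead of dropping them.
#' @return list of class `mr_params`.
#' @export
mr_params <- function(cis_halfwidth = 500000,
                      window_alpha = 0.05,
                      clump_r2_forward = 0.2,
                      clump_r2_reverse = 0.01,
                      proxy_r2 = 0.8,
                      gwas_alpha_reverse = 5e-8,
                      apoe_region = list(chrom = "19", start = 45048858, end = 45733201),
                      tss_anchored = FALSE,
                      keep_palindromic = FALSE) {
  stopifnot(cis_halfwidth > 0,
            clump_r2_forward > 0, clump_r2_forward < 1,
            clump_r2_reverse > 0, clump_r2_reverse < 1,
            proxy_r2 > 0, proxy_r2 < 1)
  structure(list(cis_halfwidth = cis_halfwidth, window_alpha = window_alpha,
                 clump_r2_forward = clump_r2_forward,
                 clump_r2_reverse = clump_r2_reverse, proxy_r2 = proxy_r2,
                 gwas_alpha_reverse = gwas_alpha_reverse,
                 apoe_region = apoe_region, tss_anchored = isTRUE(tss_anchored),
                 keep_palindromic = isTRUE(keep_palindromic)),
            class = "mr_params")
}

# Greedy clumping: repeatedly keep the smallest-P variant and discard the
# rest with r2 >= threshold against it. Ties in P broken by position, then id,
# so the result does not depend on input row order.
clump_variants <- function(stats_df, ld, r2_threshold) {
  if (!nrow(stats_df)) return(stats_df)
  ord <- order(stats_df$p, stats_df$pos, stats_df$variant)
  df <- stats_df[ord, , drop = FALSE]
  kept <- integer(0)
  alive <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    kept <- c(kept, i)
    vi <- df$variant[i]
    r2 <- ld[vi, df$variant]^2
    alive <- alive & !(r2 >= r2_threshold)
    alive[kept] <- FALSE
  }
  df[kept, , drop = FALSE]
}

#' Select cis-pQTL instruments for a protein
#'
#' Takes all variants within the cis window around the protein-coding gene,
#' computes the window-wide threshold `Pb = window_alpha / N`, keeps variants
#' with `P < Pb`, and greedy-clumps the survivors at
#' `r2 >= clump_r2_forward`. An empty post-threshold set is returned (not an
#' error) with reason `"no significant cis-pQTL"`, mirroring proteins excluded
#' from the forward analysis for lack of usable instruments.
#'
#' @param exposure_stats summary-statistic data.frame (`variant`, `chrom`,
#'   `pos`, `ea`, `beta`, `se`, `p`, `n`).
#' @param gene_region list or vector with `chrom`, `start`, `end`
#'   (1-based inclusive gene body coordinates).
#' @param ld square LD *correlation* matrix with variant dimnames covering the
#'   candidates (r-squared is its elementwise square).
#' @param params an [mr_params()].
#' @return list of class `instrument_selection`: `variants` (selected rows in
#'   selection order), `pb`, `n_window`, `reason` (`NA` when non-empty).
#' @export
select_cis_instruments <- function(exposure_stats, gene_region, ld,
                                   params = mr_params()) {
  gr <- as.list(gene_region)
  stopifnot(!is.null(gr$chrom), !is.null(gr$start), !is.null(gr$end))
  anchor_end <- if (params$tss_anchored) as.numeric(gr$start) else as.numeric(gr$end)
  lo <- as.numeric(gr$start) - params$cis_halfwidth
  hi <- anchor_end + params$cis_halfwidth
  cand <- exposure_stats[exposure_stats$chrom == gr$chrom &
                           exposure_stats$pos >= lo &
                           exposure_stats$pos <= hi, , drop = FALSE]
  if (!nrow(cand))
    stop("empty cis candidate window for the gene region", call. = FALSE)
  pb <- params$window_alpha / nrow(cand)
  sig <- cand[cand$p < pb, , drop = FALSE]
  if (!nrow(sig)) {
    return(structure(list(variants = sig, pb = pb, n_window = nrow(cand),
                          reason = "no significant cis-pQTL"),
                     class = "instrument_selection"))
  }
  missing_ld <- setdiff(sig$variant, rownames(ld))
  if (length(missing_ld))
    stop(sprintf("LD matrix lacks variants: %s", paste(missing_ld, collapse = ", ")),
         call. = FALSE)
  kept <- clump_variants(sig, ld, params$clump_r2_forward)
  structure(list(variants = kept, pb = pb, n_window = nrow(cand),
                 reason = NA_character_),
            class = "instrument_selection")
}

#' Harmonize exposure and outcome summary statistics into an instrument set
#'
#' Aligns effect alleles (flipping the outcome beta when its effect allele is
#' the complement of the exposure's), substitutes missing outcome variants by
#' their highest-r2 proxy above `proxy_r2` when possible, drops palindromic
#' variants by default, and assembles the LD submatrix for the retained
#' instruments. Every flip, proxy substitution and drop is recorded in the
#' harmonization log.
#'
#' @param selection an [select_cis_instruments()] result, or a data.frame of
#'   exposure rows (`variant`, `ea`, `beta`, `se`, optionally `oa`).
#' @param outcome_stats outcome summary-statistic data.frame (same columns).
#' @param ld LD correlation matrix covering exposure variants and potential
#'   proxies.
#' @param params an [mr_params()].
#' @return object of class `instrument_set` with `variants`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `ld` and `log`
#'   (a data.frame of actions), or an empty set with a `reason`.
#' @export
harmonize_and_proxy <- function(selection, outcome_stats, ld,
                                params = mr_params()) {
  expo <- if (inherits(selection, "instrument_selection")) selection$variants else selection
  log <- list()
  note <- function(variant, action, detail = "") {
    log[[length(log) + 1L]] <<- data.frame(variant = variant, action = action,
                                           detail = detail, stringsAsFactors = FALSE)
  }
  palindromic <- function(ea, oa) {
    pairs <- paste0(toupper(ea), toupper(oa))
    pairs %in% c("AT", "TA", "CG", "GC")
  }
  rows <- list()
  for (i in seq_len(nrow(expo))) {
    v <- expo$variant[i]
    ex <- expo[i, ]
    if (!is.null(ex$oa) && !params$keep_palindromic &&
        isTRUE(palindromic(ex$ea, ex$oa))) {
      note(v, "dropped", "palindromic")
      next
    }
    oc <- outcome_stats[outcome_stats$variant == v, , drop = FALSE]
    used <- v
    if (!nrow(oc)) {
      # proxy lookup: best-r2 outcome variant above the threshold
      if (v %in% rownames(ld)) {
        cand <- intersect(colnames(ld), outcome_stats$variant)
        cand <- setdiff(cand, v)
        if (length(cand)) {
          r2 <- ld[v, cand]^2
          best <- cand[which.max(r2)]
          if (max(r2) > params$proxy_r2) {
            oc <- outcome_stats[outcome_stats$variant == best, , drop = FALSE]
            used <- best
            note(v, "proxy", sprintf("%s (r2=%.3f)", best, max(r2)))
          }
        }
      }
      if (!nrow(oc)) {
        note(v, "dropped", "absent from outcome, no proxy")
        next
      }
    }
    beta_out <- oc$beta[1]
    if (!identical(toupper(oc$ea[1]), toupper(ex$ea))) {
      beta_out <- -beta_out
      note(used, "allele_flip", sprintf("outcome ea %s vs exposure ea %s",
                                        oc$ea[1], ex$ea))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variant = v, ld_id = used,
      beta_exposure = ex$beta, se_exposure = ex$se,
      beta_outcome = beta_out, se_outcome = oc$se[1],
      stringsAsFactors = FALSE)
  }
  log_df <- if (length(log)) do.call(rbind, log)
            else data.frame(variant = character(0), action = character(0),
                            detail = character(0), stringsAsFactors = FALSE)
  if (!length(rows)) {
    return(structure(list(variants = character(0), beta_exposure = numeric(0),
                          se_exposure = numeric(0), beta_outcome = numeric(0),
                          se_outcome = numeric(0), ld = matrix(0, 0, 0),
                          log = log_df,
                          reason = "instrument set empty after harmonization"),
                     class = "instrument_set"))
  }
  h <- do.call(rbind, rows)
  ld_ids <- h$variant
  sub <- if (all(ld_ids %in% rownames(ld))) ld[ld_ids, ld_ids, drop = FALSE]
         else diag(nrow(h))
  dimnames(sub) <- list(h$variant, h$variant)
  instrument_set(h$variant, h$beta_exposure, h$se_exposure,
                 h$beta_outcome, h$se_outcome, sub, log = log_df)
}

#' Construct an instrument set
#'
#' @param variants variant ids.
#' @param beta_exposure,se_exposure exposure effects and standard errors.
#' @param beta_outcome,se_outcome outcome effects and standard errors.
#' @param ld LD correlation matrix (defaults to identity).
#' @param log optional harmonization log.
#' @return object of class `instrument_set`.
#' @export
instrument_set <- function(variants, beta_exposure, se_exposure,
                           beta_outcome, se_outcome, ld = NULL, log = NULL) {
  k <- length(variants)
  stopifnot(k >= 1,
            length(beta_exposure) == k, length(se_exposure) == k,
            length(beta_outcome) == k, length(se_outcome) == k,
            all(se_exposure > 0), all(se_outcome > 0))
  if (is.null(ld)) ld <- diag(k)
  ld <- as.matrix(ld)
  dimnames(ld) <- list(variants, variants)
  check_ld(ld, "instrument LD")
  structure(list(variants = variants,
                 beta_exposure = as.numeric(beta_exposure),
                 se_exposure = as.numeric(se_exposure),
                 beta_outcome = as.numeric(beta_outcome),
                 se_outcome = as.numeric(se_outcome),
                 ld = ld, log = log, reason = NA_character_),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %d instrument(s)\n", length(x$variants)))
  if (length(x$variants))
    print(data.frame(variant = x$variants, beta_exposure = x$beta_exposure,
                     beta_outcome = x$beta_outcome), row.names = FALSE)
  if (!is.na(x$reason)) cat("reason:", x$reason, "\n")
  invisible(x)
}

new_mr_estimate <- function(theta, se, method, n_instruments,
                            cochran_q = NA_real_, q_p = NA_real_,
                            egger_intercept = NA_real_,
                            egger_intercept_p = NA_real_, flags = character(0)) {
  structure(list(theta = theta, se = se,
                 p = 2 * stats::pnorm(-abs(theta / se)),
                 method = method, n_instruments = n_instruments,
                 cochran_q = cochran_q, q_p = q_p,
                 egger_intercept = egger_intercept,
                 egger_intercept_p = egger_intercept_p,
                 flags = flags),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> method = %s, k = %d\n", x$method, x$n_instruments))
  cat(sprintf("  theta = %.4g (se %.4g), OR = %.3f, p = %.3g\n",
              x$theta, x$se, exp(x$theta), x$p))
  if (!is.na(x$cochran_q))
    cat(sprintf("  Cochran Q = %.3g (p = %.3g)\n", x$cochran_q, x$q_p))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4g (p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_p))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Generalized weighted least squares (correlated-instrument) MR estimate
#'
#' Causal effect `theta = (bx' W bx)^-1 bx' W by` with `W = Omega^-1` and
#' `Omega[i, j] = se_y[i] * se_y[j] * rho[i, j]`, where rho is the instruments'
#' LD correlation; `se = sqrt((bx' W bx)^-1)`. With a single instrument this
#' reduces exactly to the Wald ratio `by/bx` with standard error `se_y/|bx|`.
#' A numerically singular Omega is ridge-regularized (1e-6 on the diagonal)
#' and flagged.
#'
#' @param inst an [instrument_set()].
#' @return an `mr_estimate` (method `"gwls"`, or `"wald"` for one instrument).
#' @export
estimate_gwls <- function(inst) {
  stopifnot(inherits(inst, "instrument_set"))
  k <- length(inst$variants)
  if (k < 1) stop("empty instrument set", call. = FALSE)
  bx <- inst$beta_exposure; by <- inst$beta_outcome; sy <- inst$se_outcome
  if (k == 1) {
    return(new_mr_estimate(by / bx, sy / abs(bx), "wald", 1L))
  }
  omega <- outer(sy, sy) * inst$ld
  flags <- character(0)
  w_bx <- tryCatch(solve(omega, bx), error = function(e) NULL)
  if (is.null(w_bx) || !all(is.finite(w_bx)) ||
      kappa(omega, exact = TRUE) > 1e12) {
    omega <- omega + diag(1e-6, k)
    w_bx <- solve(omega, bx)
    flags <- "ridge_regularized"
  }
  denom <- sum(bx * w_bx)
  theta <- sum(w_bx * by) / denom
  new_mr_estimate(theta, sqrt(1 / denom), "gwls", as.integer(k), flags = flags)
}

#' Inverse-variance-weighted MR estimate (independent instruments)
#'
#' `theta = sum(bx * by / se_y^2) / sum(bx^2 / se_y^2)`,
#' `se = sqrt(1 / sum(bx^2 / se_y^2))`; algebraically identical to
#' [estimate_gwls()] with an identity LD matrix. Requires at least two
#' instruments (use the Wald ratio otherwise).
#'
#' @param inst an [instrument_set()].
#' @return an `mr_estimate` with Cochran's Q attached.
#' @export
estimate_ivw <- function(inst) {
  stopifnot(inherits(inst, "instrument_set"))
  k <- length(inst$variants)
  if (k < 2)
    stop("IVW requires >= 2 instruments; use the Wald ratio (estimate_gwls) for one",
         call. = FALSE)
  bx <- inst$beta_exposure; by <- inst$beta_outcome; sy <- inst$se_outcome
  w <- bx^2 / sy^2
  theta <- sum(bx * by / sy^2) / sum(w)
  est <- new_mr_estimate(theta, sqrt(1 / sum(w)), "ivw", as.integer(k))
  q <- cochran_q(inst, theta)
  est$cochran_q <- q$q
  est$q_p <- q$q_p
  est
}

#' Cochran's Q heterogeneity statistic across instrument ratios
#'
#' `Q = sum w_i (theta_i - theta)^2` with `theta_i = by_i / bx_i` and
#' `w_i = bx_i^2 / se_y_i^2`; p-value from a chi-squared with k - 1 df.
#'
#' @param inst an [instrument_set()] with k >= 2.
#' @param theta the pooled (IVW) estimate.
#' @return list with `q` and `q_p`.
#' @export
cochran_q <- function(inst, theta) {
  stopifnot(inherits(inst, "instrument_set"))
  k <- length(inst$variants)
  if (k < 2) stop("Cochran's Q requires >= 2 instruments", call. = FALSE)
  if (any(inst$beta_exposure == 0))
    stop("per-instrument ratio undefined: exposure beta of 0", call. = FALSE)
  ratios <- inst$beta_outcome / inst$beta_exposure
  w <- inst$beta_exposure^2 / inst$se_outcome^2
  q <- sum(w * (ratios - theta)^2)
  list(q = q, q_p = stats::pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' MR-Egger regression for directional pleiotropy
#'
#' Weighted regression `by = alpha + theta * bx` with weights `1/se_y^2`,
#' after orienting instruments so every exposure beta is non-negative. The
#' intercept alpha estimates directional pleiotropy. Requires at least three
#' instruments; with fewer, a skipped estimate with a reason flag is returned.
#'
#' @param inst an [instrument_set()].
#' @return an `mr_estimate` (method `"egger"`) with intercept fields, or a
#'   flagged NA estimate when underdetermined.
#' @export
mr_egger <- function(inst) {
  stopifnot(inherits(inst, "instrument_set"))
  k <- length(inst$variants)
  if (k < 3) {
    est <- new_mr_estimate(NA_real_, NA_real_, "egger", as.integer(k),
                           flags = "skipped: fewer than 3 instruments")
    est$p <- NA_real_
    return(est)
  }
  flip <- sign(inst$beta_exposure) < 0
  bx <- abs(inst$beta_exposure)
  by <- ifelse(flip, -inst$beta_outcome, inst$beta_outcome)
  fit <- stats::lm(by ~ bx, weights = 1 / inst$se_outcome^2)
  sm <- summary(fit)$coefficients
  est <- new_mr_estimate(sm["bx", "Estimate"], sm["bx", "Std. Error"],
                         "egger", as.integer(k),
                         egger_intercept = sm["(Intercept)", "Estimate"],
                         egger_intercept_p = sm["(Intercept)", "Pr(>|t|)"])
  est
}

#' Forward MR for one protein: select, harmonize, estimate
#'
#' Convenience wrapper running [select_cis_instruments()],
#' [harmonize_and_proxy()] and the estimator appropriate to the instrument
#' count (Wald for one, GWLS otherwise), with Cochran's Q and MR-Egger
#' attached when defined.
#'
#' @inheritParams select_cis_instruments
#' @param outcome_stats outcome (LOAD GWAS) summary statistics.
#' @return an `mr_estimate`, or a reason-coded `NA` estimate when no usable
#'   instruments exist.
#' @export
forward_mr <- function(exposure_stats, outcome_stats, gene_region, ld,
                       params = mr_params()) {
  sel <- select_cis_instruments(exposure_stats, gene_region, ld, params)
  if (!nrow(sel$variants)) {
    est <- new_mr_estimate(NA_real_, NA_real_, "none", 0L, flags = sel$reason)
    est$p <- NA_real_
    return(est)
  }
  inst <- harmonize_and_proxy(sel, outcome_stats, ld, params)
  if (!length(inst$variants)) {
    est <- new_mr_estimate(NA_real_, NA_real_, "none", 0L, flags = inst$reason)
    est$p <- NA_real_
    return(est)
  }
  est <- estimate_gwls(inst)
  if (length(inst$variants) >= 2) {
    ivw <- estimate_ivw(inst)
    est$cochran_q <- ivw$cochran_q
    est$q_p <- ivw$q_p
  }
  if (length(inst$variants) >= 3) {
    eg <- mr_egger(inst)
    est$egger_intercept <- eg$egger_intercept
    est$egger_intercept_p <- eg$egger_intercept_p
  }
  est
}

#' Reverse MR: effect of LOAD genetic liability on a protein
#'
#' Instruments are genome-wide-significant LOAD variants
#' (`P < gwas_alpha_reverse`), greedy-clumped at the stringent
#' `clump_r2_reverse` threshold, with the protein's cis window (plus/minus
#' `cis_halfwidth`) excluded to avoid pleiotropic cis effects, and the APOE
#' region optionally excluded. The estimate is IVW (Wald for a single
#' surviving instrument). The protein summary statistics provide the outcome
#' side; `age_stratum` selects a stratum-specific outcome table when supplied.
#'
#' @param outcome_gwas LOAD GWAS summary statistics (exposure side here).
#' @param protein_stats variant effects on the protein (outcome side), or a
#'   named list of stratum tables when using `age_stratum`.
#' @param protein_gene_region list with `chrom`, `start`, `end` for the
#'   protein-coding gene (cis exclusion); `NULL` to skip.
#' @param ld LD correlation matrix over the LOAD instruments.
#' @param params an [mr_params()].
#' @param exclude_apoe drop instruments inside the APOE region (default TRUE).
#' @param age_stratum optional stratum label indexing `protein_stats`.
#' @return an `mr_estimate`, reason-coded `NA` when all instruments are
#'   excluded.
#' @export
reverse_mr <- function(outcome_gwas, protein_stats, protein_gene_region = NULL,
                       ld = NULL, params = mr_params(), exclude_apoe = TRUE,
                       age_stratum = NULL) {
  if (!is.null(age_stratum)) {
    stopifnot(is.list(protein_stats), age_stratum %in% names(protein_stats))
    protein_stats <- protein_stats[[age_stratum]]
  }
  gws <- outcome_gwas[outcome_gwas$p < params$gwas_alpha_reverse, , drop = FALSE]
  if (!is.null(protein_gene_region)) {
    gr <- as.list(protein_gene_region)
    cis <- gws$chrom == gr$chrom &
      gws$pos >= as.numeric(gr$start) - params$cis_halfwidth &
      gws$pos <= as.numeric(gr$end) + params$cis_halfwidth
    gws <- gws[!cis, , drop = FALSE]
  }
  if (exclude_apoe) {
    ap <- params$apoe_region
    inside <- gws$chrom == ap$chrom & gws$pos >= ap$start & gws$pos <= ap$end
    gws <- gws[!inside, , drop = FALSE]
  }
  reason_na <- function(reason) {
    est <- new_mr_estimate(NA_real_, NA_real_, "none", 0L, flags = reason)
    est$p <- NA_real_
    est
  }
  if (!nrow(gws)) return(reason_na("all instruments excluded"))
  if (is.null(ld)) {
    ld <- diag(nrow(gws))
    dimnames(ld) <- list(gws$variant, gws$variant)
  }
  kept <- clump_variants(gws, ld, params$clump_r2_reverse)
  inst <- harmonize_and_proxy(kept, protein_stats, ld, params)
  if (!length(inst$variants))
    return(reason_na(inst$reason))
  if (length(inst$variants) == 1) estimate_gwls(inst) else estimate_ivw(inst)
}

#' Tabulate MR estimates across proteins with a per-direction FDR
#'
#' @param estimates named list of `mr_estimate` objects (one per protein).
#' @param direction label recorded in the output (`"forward"`/`"reverse"`).
#' @return data.frame: `protein`, `direction`, `method`, `n_inst`, `theta`,
#'   `se`, `p`, `fdr`, `q`, `q_p`, `egger_intercept`, `egger_p`,
#'   `exclusion_reason`.
#' @export
mr_table <- function(estimates, direction = "forward") {
  df <- do.call(rbind, lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    data.frame(protein = nm, direction = direction, method = e$method,
               n_inst = e$n_instruments, theta = e$theta, se = e$se, p = e$p,
               q = e$cochran_q, q_p = e$q_p,
               egger_intercept = e$egger_intercept, egger_p = e$egger_intercept_p,
               exclusion_reason = if (length(e$flags)) paste(e$flags, collapse = ";")
                                  else NA_character_,
               stringsAsFactors = FALSE)
  }))
  df$fdr <- NA_real_
  ok <- !is.na(df$p)
  if (any(ok)) df$fdr[ok] <- bh_fdr(df$p[ok])
  df[, c("protein", "direction", "method", "n_inst", "theta", "se", "p", "fdr",
         "q", "q_p", "egger_intercept", "egger_p", "exclusion_reason")]
}
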