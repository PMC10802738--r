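#' Scenario configuration for the synthetic cohort generator
#'
#' Bundles and validates every parameter of the cohort simulator. Defaults
#' describe an elderly population-based cohort with an APOE-e4 per-allele
#' hazard ratio of 2.1 for incident late-onset Alzheimer's disease (LOAD),
#' roughly 13% incident events over a maximum 16-year follow-up, and censoring
#' by a competing death/non-AD-dementia process.
#'
#' Protein levels are generated on the standardized (SD) scale as
#' \code{beta_e4_protein * e4_dose + liability_beta_protein * liability + N(0,1)},
#' where \code{liability} is a standard-normal non-APOE disease liability
#' score. Survival times follow an exponential proportional-hazards model with
#' linear predictor
#' \code{log(hr_e4_load)*e4 + age_log_hr*(age - mean age) + sex_log_hr*female +
#' t(beta_protein_hazard) proteins + liability_log_hr*liability}.
#'
#' @param n_samples number of participants (>= 2).
#' @param n_proteins number of aptamers simulated.
#' @param e4_allele_freq APOE-e4 allele frequency in `[0, 1]`.
#' @param beta_e4_protein per-protein shift (protein-SD units) per e4 allele;
#'   scalar recycled across proteins or a length-`n_proteins` vector.
#' @param beta_protein_hazard per-protein log hazard ratio per protein SD;
#'   scalar or length-`n_proteins` vector.
#' @param hr_e4_load hazard ratio for incident LOAD per e4 allele (> 0).
#' @param baseline_hazard baseline event rate per year (> 0).
#' @param max_followup administrative censoring horizon in years (> 0).
#' @param censor_rate yearly rate of the competing censoring process
#'   (death or incident non-AD dementia), > 0.
#' @param prevalent_frac probability of being a prevalent (baseline) case.
#' @param liability_log_hr log hazard ratio per SD of the non-APOE liability
#'   score.
#' @param liability_beta_protein per-protein shift (SD units) per liability SD;
#'   scalar or vector.
#' @param age_mean,age_sd mean and SD of baseline age (years); draws are
#'   truncated to `[66, 96]`.
#' @param age_log_hr log hazard ratio per year of age (centered at `age_mean`).
#' @param sex_female_frac probability of female sex.
#' @param sex_log_hr log hazard ratio for female vs male sex.
#' @param extra_covariates if `TRUE`, the phenotype table additionally carries
#'   null-effect lifestyle/comorbidity covariates (BMI, type-2 diabetes,
#'   education, hypertension, smoking, eGFR) so that the fully adjusted
#'   association model can be exercised.
#' @param seed integer seed; all randomness in [generate_cohort()] is routed
#'   through it and recorded in the output.
#' @return An object of class `scenario_config` (a validated list).
#' @seealso [generate_cohort()], [scenario_opposing_effects()]
#' @export
scenario_config <- function(n_samples = 5000,
                            n_proteins = 1,
                            e4_allele_freq = 0.15,
                            beta_e4_protein = 0,
                            beta_protein_hazard = 0,
                            hr_e4_load = 2.1,
                            baseline_hazard = 0.009,
                            max_followup = 16,
                            censor_rate = 0.04,
                            prevalent_frac = 0,
                            liability_log_hr = 0,
                            liability_beta_protein = 0,
                            age_mean = 76,
                            age_sd = 5.5,
                            age_log_hr = 0.05,
                            sex_female_frac = 0.57,
                            sex_log_hr = 0,
                            extra_covariates = FALSE,
                            seed = NULL) {
  stopifnot(length(n_samples) == 1L, length(n_proteins) == 1L)
  if (!is.numeric(n_samples) || n_samples < 2)
    stop("n_samples must be >= 2", call. = FALSE)
  if (n_proteins < 0) stop("n_proteins must be non-negative", call. = FALSE)
  for (p in c(e4_allele_freq, prevalent_frac, sex_female_frac)) {
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (r in c(baseline_hazard, censor_rate, max_followup)) {
    if (!is.numeric(r) || r <= 0)
      stop("rates and follow-up horizon must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(hr_e4_load) || hr_e4_load <= 0)
    stop("hr_e4_load must be > 0", call. = FALSE)
  recycle <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n_proteins)
    if (n_proteins > 0 && length(x) != n_proteins)
      stop(sprintf("%s must have length 1 or n_proteins", what), call. = FALSE)
    x
  }
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_proteins = as.integer(n_proteins),
    e4_allele_freq = e4_allele_freq,
    beta_e4_protein = recycle(beta_e4_protein, "beta_e4_protein"),
    beta_protein_hazard = recycle(beta_protein_hazard, "beta_protein_hazard"),
    hr_e4_load = hr_e4_load,
    baseline_hazard = baseline_hazard,
    max_followup = max_followup,
    censor_rate = censor_rate,
    prevalent_frac = prevalent_frac,
    liability_log_hr = liability_log_hr,
    liability_beta_protein = recycle(liability_beta_protein, "liability_beta_protein"),
    age_mean = age_mean,
    age_sd = age_sd,
    age_log_hr = age_log_hr,
    sex_female_frac = sex_female_frac,
    sex_log_hr = sex_log_hr,
    extra_covariates = isTRUE(extra_covariates),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  n_samples: %d, n_proteins: %d, e4 freq: %.3f\n",
              x$n_samples, x$n_proteins, x$e4_allele_freq))
  cat(sprintf("  hr_e4_load: %.3g, baseline hazard: %.4g/y, censor: %.4g/y, horizon: %gy\n",
              x$hr_e4_load, x$baseline_hazard, x$censor_rate, x$max_followup))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

#' Genotype panel constructor
#'
#' A lightweight container for a set of variants with positions, allele
#' frequencies and an LD correlation matrix. LD defaults to block-exchangeable
#' correlation `rho` within a single block; a full square correlation matrix
#' may be supplied instead.
#'
#' @param n_variants number of variants (ignored when `ld` is a matrix).
#' @param maf minor/effect allele frequency, scalar or per-variant vector.
#' @param rho exchangeable LD correlation used when `ld` is `NULL`.
#' @param ld optional square correlation matrix (symmetric, unit diagonal,
#'   positive semidefinite).
#' @param chrom chromosome label.
#' @param pos 1-based positions (defaults to an evenly spaced grid).
#' @param ids variant identifiers.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(n_variants = 1, maf = 0.3, rho = 0, ld = NULL,
                           chrom = "1", pos = NULL, ids = NULL) {
  if (is.null(ld)) {
    ld <- matrix(rho, n_variants, n_variants)
    diag(ld) <- 1
  } else {
    ld <- as.matrix(ld)
    n_variants <- nrow(ld)
  }
  check_ld(ld, "ld")
  if (is.null(pos)) pos <- seq(1e6, by = 10000L, length.out = n_variants)
  if (is.null(ids)) ids <- paste0("rs", seq_len(n_variants))
  maf <- rep_len(maf, n_variants)
  stopifnot(all(maf > 0 & maf < 1))
  dimnames(ld) <- list(ids, ids)
  structure(list(ids = ids, chrom = rep_len(as.character(chrom), n_variants),
                 pos = as.numeric(pos), maf = maf, ld = ld, dosage = NULL),
            class = "genotype_panel")
}

# Symmetry / unit-diagonal / PSD validation shared by the MR and simulation code.
check_ld <- function(ld, name = "ld") {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld))
    stop(sprintf("%s must be a square matrix", name), call. = FALSE)
  if (max(abs(ld - t(ld))) > 1e-8)
    stop(sprintf("%s is not symmetric", name), call. = FALSE)
  if (max(abs(diag(ld) - 1)) > 1e-8)
    stop(sprintf("%s must have a unit diagonal", name), call. = FALSE)
  ev <- eigen(ld, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("%s is not positive semidefinite (min eigenvalue %.3g)",
                 name, min(ev)), call. = FALSE)
  invisible(TRUE)
}

# Dosages in {0,1,2} with the panel's LD, via a Gaussian copula on two
# haplotypes per individual. Preserves allele frequency exactly in
# expectation; haplotype-level correlation approximates the target LD.
simulate_dosages <- function(panel, n) {
  m <- length(panel$ids)
  ch <- chol(nearest_psd(panel$ld))
  hap <- function() {
    z <- matrix(stats::rnorm(n * m), n, m) %*% ch
    thr <- stats::qnorm(panel$maf)
    t(t(z) < thr) * 1L
  }
  d <- hap() + hap()
  colnames(d) <- panel$ids
  d
}

# Clip tiny negative eigenvalues so chol() succeeds on borderline-PSD input.
nearest_psd <- function(m, eps = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

#' Generate a synthetic cohort with protein levels and survival outcomes
#'
#' Draws baseline covariates, APOE-e4 dosage, standardized protein levels and
#' incident-event follow-up under an exponential proportional-hazards model
#' (see [scenario_config()] for the generative equations). Individuals are
#' censored by the earlier of a competing censoring event (death / non-AD
#' dementia, exponential with rate `censor_rate`) and the administrative
#' horizon `max_followup`. A `prevalent_frac` fraction is flagged as prevalent
#' baseline cases; these carry no follow-up information and are excluded from
#' incident risk sets downstream.
#'
#' @param config a [scenario_config()].
#' @return A list of class `load_cohort` with elements
#'   \item{pheno}{data.frame: `id`, `age`, `sex` (`"F"`/`"M"`), `apoe_e4`
#'     (0/1/2), `liability`, `time`, `event`, `prevalent`, plus optional extra
#'     covariates.}
#'   \item{proteins}{numeric matrix, samples x aptamers.}
#'   \item{genotypes}{a `genotype_panel` carrying the e4 variant dosage.}
#'   \item{config}{the generating configuration (seed recorded).}
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "scenario_config"))
    config <- do.call(scenario_config, as.list(config))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_proteins

  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  age <- pmin(pmax(age, 66), 96)
  female <- stats::rbinom(n, 1, config$sex_female_frac)
  e4 <- stats::rbinom(n, 2, config$e4_allele_freq)
  liability <- stats::rnorm(n)

  proteins <- NULL
  if (p > 0) {
    proteins <- matrix(stats::rnorm(n * p), n, p)
    proteins <- proteins +
      outer(e4, config$beta_e4_protein) +
      outer(liability, config$liability_beta_protein)
    colnames(proteins) <- sprintf("prot_%d", seq_len(p))
  }

  lp <- log(config$hr_e4_load) * e4 +
    config$age_log_hr * (age - config$age_mean) +
    config$sex_log_hr * female +
    config$liability_log_hr * liability
  if (p > 0) lp <- lp + drop(proteins %*% config$beta_protein_hazard)

  t_event <- stats::rexp(n, rate = config$baseline_hazard * exp(lp))
  t_censor <- stats::rexp(n, rate = config$censor_rate)
  horizon <- pmin(t_censor, config$max_followup)
  time <- pmin(t_event, horizon)
  event <- as.integer(t_event <= horizon)
  prevalent <- stats::rbinom(n, 1, config$prevalent_frac)
  time[prevalent == 1] <- 0
  event[prevalent == 1] <- 0L

  pheno <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    age = age,
    sex = factor(ifelse(female == 1, "F", "M"), levels = c("M", "F")),
    apoe_e4 = e4,
    liability = liability,
    time = time,
    event = event,
    prevalent = prevalent,
    stringsAsFactors = FALSE
  )
  if (config$extra_covariates) {
    pheno$bmi <- stats::rnorm(n, 27, 4)
    pheno$diabetes <- stats::rbinom(n, 1, 0.12)
    pheno$education <- factor(sample(c("primary", "secondary", "college", "university"),
                                     n, replace = TRUE, prob = c(0.25, 0.45, 0.2, 0.1)),
                              levels = c("primary", "secondary", "college", "university"))
    pheno$hypertension <- stats::rbinom(n, 1, 0.6)
    pheno$smoking <- factor(sample(c("never", "former", "current"), n, replace = TRUE,
                                   prob = c(0.45, 0.42, 0.13)),
                            levels = c("never", "former", "current"))
    pheno$egfr <- stats::rnorm(n, 65, 15)
  }
  if (p > 0) rownames(proteins) <- pheno$id

  panel <- genotype_panel(n_variants = 1, maf = config$e4_allele_freq,
                          chrom = "19", pos = 45411941, ids = "rs429358")
  panel$dosage <- matrix(e4, ncol = 1, dimnames = list(pheno$id, "rs429358"))

  structure(list(pheno = pheno, proteins = proteins, genotypes = panel,
                 config = config),
            class = "load_cohort")
}

#' @export
print.load_cohort <- function(x, ...) {
  cat(sprintf("<load_cohort> %d samples, %d proteins; %d incident events (%.1f%%), %d prevalent\n",
              nrow(x$pheno),
              if (is.null(x$proteins)) 0L else ncol(x$proteins),
              sum(x$pheno$event), 100 * mean(x$pheno$event),
              sum(x$pheno$prevalent)))
  invisible(x)
}

#' Generate two-sample GWAS summary statistics from an LD panel
#'
#' Emulates the two-sample Mendelian-randomization design: per-variant marginal
#' effects on the exposure are the LD-propagated joint effects `R b`
#' (standardized genotype and trait scale); the outcome's marginal effects are
#' `causal_theta * R b`. Estimation noise is drawn independently for the two
#' tables (the non-overlapping-samples assumption) with covariance
#' `R / n` matching the standard errors reported in each table.
#'
#' @param panel a [genotype_panel()] supplying the LD correlation.
#' @param true_pqtl_betas per-variant joint (conditional) effects on the
#'   exposure trait.
#' @param causal_theta causal effect of the exposure on the outcome.
#' @param n_exposure,n_outcome GWAS sample sizes (>= 100).
#' @param seed optional integer seed.
#' @return A list with two data.frames, `exposure` and `outcome`, each with
#'   columns `variant`, `chrom`, `pos`, `ea`, `beta`, `se`, `p`, `n`.
#' @export
generate_two_sample_sumstats <- function(panel, true_pqtl_betas, causal_theta,
                                         n_exposure, n_outcome, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (n_exposure < 100 || n_outcome < 100)
    stop("GWAS sample sizes must be >= 100", call. = FALSE)
  m <- length(panel$ids)
  b <- rep_len(true_pqtl_betas, m)
  check_ld(panel$ld, "panel$ld")
  if (!is.null(seed)) set.seed(seed)

  R <- panel$ld
  ch <- chol(nearest_psd(R))
  draw <- function(marg, n) {
    se <- rep(1 / sqrt(n), m)
    noise <- drop(stats::rnorm(m) %*% ch) * se
    beta <- marg + noise
    data.frame(variant = panel$ids, chrom = panel$chrom, pos = panel$pos,
               ea = "A", beta = beta, se = se,
               p = 2 * stats::pnorm(-abs(beta / se)), n = n,
               stringsAsFactors = FALSE)
  }
  marg <- drop(R %*% b)
  list(exposure = draw(marg, n_exposure),
       outcome = draw(causal_theta * marg, n_outcome))
}

#' Opposing-effects scenario: genotype down-regulates, liability up-regulates
#'
#' Builds the competing-mechanisms scenario in which the APOE-e4 allele lowers
#' a protein's serum level while raising LOAD hazard, and non-APOE disease
#' liability raises both the protein level and the hazard. The observational
#' signature is a direction flip: the protein's age/sex-adjusted hazard ratio
#' is below one, but turns above one once e4 dosage enters the model. The
#' genetic signature is a positive reverse-MR effect of liability on the
#' protein. The bundle carries a simulated cohort plus two-sample summary
#' statistics for the reverse MR (non-APOE liability instruments).
#'
#' @param config a [scenario_config()]; must specify `beta_e4_protein < 0`,
#'   `liability_beta_protein > 0` and `hr_e4_load > 1` (the defaults here do).
#'   `liability_log_hr` must be > 0.
#' @param n_liability_variants number of independent liability instruments in
#'   the simulated GWAS tables.
#' @param n_gwas sample size for both summary-statistic tables.
#' @return A list of class `opposing_scenario`: `cohort`, `exposure_stats`
#'   (variant -> liability), `outcome_stats` (variant -> protein), `panel`,
#'   `config`.
#' @export
scenario_opposing_effects <- function(config = NULL,
                                      n_liability_variants = 20,
                                      n_gwas = 50000) {
  if (is.null(config)) {
    config <- scenario_config(
      n_samples = 20000, n_proteins = 1,
      beta_e4_protein = -1.2, beta_protein_hazard = 0,
      hr_e4_load = 2.1,
      liability_log_hr = 0.3, liability_beta_protein = 0.3,
      seed = 1L
    )
  }
  if (any(config$beta_e4_protein >= 0) ||
      any(config$liability_beta_protein <= 0) ||
      config$hr_e4_load <= 1 || config$liability_log_hr <= 0)
    stop(paste("opposing-effects scenario requires beta_e4_protein < 0,",
               "liability_beta_protein > 0, liability_log_hr > 0 and hr_e4_load > 1"),
         call. = FALSE)
  cohort <- generate_cohort(config)
  panel <- genotype_panel(n_variants = n_liability_variants, maf = 0.3, rho = 0,
                          chrom = "2", ids = sprintf("load_rs%d", seq_len(n_liability_variants)))
  ss <- generate_two_sample_sumstats(
    panel,
    true_pqtl_betas = rep(0.08, n_liability_variants),
    causal_theta = config$liability_beta_protein[1],
    n_exposure = n_gwas, n_outcome = n_gwas,
    seed = if (is.null(config$seed)) NULL else config$seed + 1L
  )
  structure(list(cohort = cohort, exposure_stats = ss$exposure,
                 outcome_stats = ss$outcome, panel = panel, config = config),
            class = "opposing_scenario")
}

#' Write cohort outputs as TSV files
#'
#' @param cohort a `load_cohort`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "load_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(pheno = file.path(dir, "pheno.tsv"),
             proteins = file.path(dir, "proteins.tsv"))
  write_tsv_commented(cohort$pheno, paths["pheno"], seed = cohort$config$seed)
  pm <- data.frame(id = rownames(cohort$proteins), cohort$proteins,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_commented(pm, paths["proteins"], seed = cohort$config$seed)
  invisible(paths)
}

# TSV writer adding a '#' header line with the generating seed, so every
# artifact records its provenance.
write_tsv_commented <- function(df, path, seed = NULL, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# proteoload seed=%s%s",
                     if (is.null(seed)) "NA" else seed,
                     if (is.null(extra)) "" else paste0(" ", extra)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
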