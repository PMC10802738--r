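test_that("config validation rejects impossible scenarios", {
  expect_error(scenario_config(n_samples = 1), "n_samples")
  expect_error(scenario_config(baseline_hazard = 0), "positive")
  expect_error(scenario_config(censor_rate = -1), "positive")
  expect_error(scenario_config(e4_allele_freq = 1.2), "probabilities")
  expect_error(scenario_config(hr_e4_load = 0), "hr_e4_load")
})

test_that("fixed seed gives bit-identical cohorts and sumstats", {
  cfg <- scenario_config(n_samples = 200, n_proteins = 3, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$proteins, b$proteins)

  panel <- genotype_panel(4, maf = 0.3, rho = 0.4)
  s1 <- generate_two_sample_sumstats(panel, 0.3, 0.2, 1000, 1000, seed = 9)
  s2 <- generate_two_sample_sumstats(panel, 0.3, 0.2, 1000, 1000, seed = 9)
  expect_identical(s1, s2)
})

test_that("empirical allele frequency matches the configured value", {
  cfg <- scenario_config(n_samples = 5000, n_proteins = 0, seed = 11)
  co <- generate_cohort(cfg)
  f_hat <- mean(co$pheno$apoe_e4) / 2
  se <- sqrt(0.15 * 0.85 / (2 * 5000))
  expect_lt(abs(f_hat - 0.15), 3 * se)
  expect_true(all(co$pheno$apoe_e4 %in% 0:2))
})

test_that("null-effect survival matches the exponential baseline", {
  # with all effects off and no competing censoring pressure the event
  # fraction at the horizon is 1 - exp(-h0 * t)
  cfg <- scenario_config(n_samples = 20000, n_proteins = 0, hr_e4_load = 1,
                         age_log_hr = 0, baseline_hazard = 0.02,
                         censor_rate = 1e-9, max_followup = 10, seed = 3)
  co <- generate_cohort(cfg)
  expected <- 1 - exp(-0.02 * 10)
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(mean(co$pheno$event) - expected), 4 * se)
  expect_true(all(co$pheno$time <= 10 + 1e-12))
})

test_that("null cohort gives per-protein hazard ratios centred on 1", {
  cfg <- scenario_config(n_samples = 20000, n_proteins = 10,
                         beta_e4_protein = 0, beta_protein_hazard = 0, seed = 5)
  co <- generate_cohort(cfg)
  rec <- fit_cox_per_aptamer(co$proteins, co$pheno, model = 1)
  expect_lt(mean(abs(rec$beta)), 0.05)
})

test_that("e4 hazard ratio of 2.1 per allele is recovered at n = 20,000", {
  cfg <- scenario_config(n_samples = 20000, n_proteins = 0, seed = 7)
  co <- generate_cohort(cfg)
  fit <- survival::coxph(survival::Surv(time, event) ~ apoe_e4 + age + sex,
                         data = co$pheno)
  sm <- summary(fit)$coefficients["apoe_e4", ]
  expect_lt(abs(sm["coef"] - log(2.1)), 3 * sm["se(coef)"])
})

test_that("e4-regulated protein without hazard effect shows the confounding pattern", {
  cfg <- scenario_config(n_samples = 20000, n_proteins = 1,
                         beta_e4_protein = -1, beta_protein_hazard = 0,
                         hr_e4_load = 2.1, seed = 13)
  co <- generate_cohort(cfg)
  r1 <- fit_cox_per_aptamer(co$proteins, co$pheno, model = 1)
  r2 <- fit_cox_per_aptamer(co$proteins, co$pheno, model = 2)
  expect_lt(r1$hr, 1)                         # confounded by e4
  expect_lt(r1$p, 0.05)
  expect_lt(abs(r2$beta), 3 * r2$se)          # vanishes after adjustment
})

test_that("sumstat generator propagates LD and respects the two-sample design", {
  panel <- genotype_panel(3, maf = 0.3, rho = 0.5)
  b <- c(0.5, 0, 0)
  s <- generate_two_sample_sumstats(panel, b, 0.3, 50000, 50000, seed = 2)
  marg <- drop(panel$ld %*% b)
  expect_lt(max(abs(s$exposure$beta - marg)), 4 * s$exposure$se[1] * 2)
  # p consistent with beta/se
  expect_equal(s$exposure$p, 2 * pnorm(-abs(s$exposure$beta / s$exposure$se)))
  # replicate-level SE calibration: empirical SD of betas matches reported se
  reps <- sapply(1:200, function(i)
    generate_two_sample_sumstats(panel, b, 0, 5000, 5000, seed = 100 + i)$exposure$beta[1])
  expect_lt(abs(sd(reps) / (1 / sqrt(5000)) - 1), 0.1)
})

test_that("non-PSD LD is rejected with the matrix named", {
  ld <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3)
  expect_error(genotype_panel(ld = ld), "positive semidefinite")
})

test_that("single strong pQTL Wald ratio recovers the causal effect", {
  panel <- genotype_panel(1, maf = 0.3)
  s <- generate_two_sample_sumstats(panel, 0.5, 0.3, 5000, 5000, seed = 21)
  inst <- instrument_set("rs1", s$exposure$beta, s$exposure$se,
                         s$outcome$beta, s$outcome$se)
  est <- estimate_gwls(inst)
  expect_equal(est$method, "wald")
  expect_lt(abs(est$theta - 0.3), 3 * est$se)
})

test_that("null causal effect yields a null MR estimate", {
  panel <- genotype_panel(5, maf = 0.3, rho = 0)
  s <- generate_two_sample_sumstats(panel, 0.3, 0, 5000, 5000, seed = 31)
  inst <- instrument_set(panel$ids, s$exposure$beta, s$exposure$se,
                         s$outcome$beta, s$outcome$se)
  est <- estimate_ivw(inst)
  expect_lt(abs(est$theta), 3 * est$se)
})

test_that("correlated instruments: GWLS is calibrated where identity-rho IVW is not", {
  panel <- genotype_panel(3, maf = 0.3, rho = 0.5)
  theta0 <- 0.3
  reps <- 500
  cover_gwls <- cover_ivw <- logical(reps)
  for (i in seq_len(reps)) {
    s <- generate_two_sample_sumstats(panel, c(0.4, 0.4, 0.4), theta0,
                                      2000, 2000, seed = 1000 + i)
    inst_ld <- instrument_set(panel$ids, s$exposure$beta, s$exposure$se,
                              s$outcome$beta, s$outcome$se, ld = panel$ld)
    g <- estimate_gwls(inst_ld)
    v <- estimate_ivw(inst_ld)  # ignores rho by construction
    cover_gwls[i] <- abs(g$theta - theta0) < 1.96 * g$se
    cover_ivw[i] <- abs(v$theta - theta0) < 1.96 * v$se
  }
  expect_gt(mean(cover_gwls), 0.92)      # near-nominal 95%
  expect_lt(mean(cover_ivw), 0.92)       # understated SE under LD
  # GWLS point estimate unbiased
  s <- generate_two_sample_sumstats(panel, c(0.4, 0.4, 0.4), theta0,
                                    50000, 50000, seed = 77)
  g <- estimate_gwls(instrument_set(panel$ids, s$exposure$beta, s$exposure$se,
                                    s$outcome$beta, s$outcome$se, ld = panel$ld))
  expect_lt(abs(g$theta - theta0), 3 * g$se)
})

test_that("opposing-effects scenario produces the direction-flip triad", {
  sc <- scenario_opposing_effects()
  ph <- sc$cohort$pheno
  ph$prot <- sc$cohort$proteins[, 1]
  s1 <- summary(survival::coxph(survival::Surv(time, event) ~ prot + age + sex,
                                data = ph))$coefficients["prot", ]
  s2 <- summary(survival::coxph(survival::Surv(time, event) ~ prot + apoe_e4 + age + sex,
                                data = ph))$coefficients["prot", ]
  expect_lt(s1["coef"], 0)
  expect_gt(s2["coef"], 0)
  expect_gt(abs(s1["z"]), 2)
  expect_gt(abs(s2["z"]), 2)
  inst <- harmonize_and_proxy(sc$exposure_stats, sc$outcome_stats, sc$panel$ld)
  expect_gt(estimate_ivw(inst)$theta, 0)
})

test_that("removing either mechanism removes the flip", {
  # no liability->protein path: model-2 HR ~ 1
  cfg <- scenario_config(n_samples = 20000, n_proteins = 1,
                         beta_e4_protein = -1.2, liability_log_hr = 0.3,
                         liability_beta_protein = 0, seed = 8)
  co <- generate_cohort(cfg)
  r2 <- fit_cox_per_aptamer(co$proteins, co$pheno, model = 2)
  expect_lt(abs(r2$beta), 3 * r2$se)
  # no e4->protein path: models 1 and 2 agree
  cfg2 <- scenario_config(n_samples = 20000, n_proteins = 1,
                          beta_e4_protein = 0, liability_log_hr = 0.3,
                          liability_beta_protein = 0.3, seed = 9)
  co2 <- generate_cohort(cfg2)
  r1 <- fit_cox_per_aptamer(co2$proteins, co2$pheno, model = 1)
  r2b <- fit_cox_per_aptamer(co2$proteins, co2$pheno, model = 2)
  expect_lt(abs(r1$beta - r2b$beta), 3 * sqrt(r1$se^2 + r2b$se^2))
  # invalid sign pattern rejected
  bad <- scenario_config(beta_e4_protein = 0.5, liability_beta_protein = 0.3,
                         liability_log_hr = 0.3)
  expect_error(scenario_opposing_effects(bad), "requires")
})

test_that("cohort TSV round-trips through the writers", {
  cfg <- scenario_config(n_samples = 50, n_proteins = 2, seed = 4)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  m <- read_protein_matrix(paths[["proteins"]])
  expect_equal(unname(m), unname(co$proteins), tolerance = 1e-12)
  expect_equal(rownames(m), co$pheno$id)
})
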