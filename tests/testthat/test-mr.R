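test_that("greedy cis selection applies the window threshold then clumps", {
  stats <- data.frame(variant = paste0("v", 1:5), chrom = "1",
                      pos = c(1e6, 1.1e6, 1.2e6, 1.3e6, 1.4e6), ea = "A",
                      beta = 0.3, se = 0.05,
                      p = c(1e-9, 1e-8, 0.2, 1e-6, 0.5), n = 5000)
  ld <- diag(5)
  ld[1, 2] <- ld[2, 1] <- sqrt(0.5)  # r2 = 0.5 between v1 and v2
  dimnames(ld) <- list(stats$variant, stats$variant)
  sel <- select_cis_instruments(stats, list(chrom = "1", start = 1e6, end = 1.4e6), ld)
  expect_equal(sel$pb, 0.05 / 5)
  expect_equal(sel$variants$variant, c("v1", "v4"))  # v2 clumped, v3/v5 fail Pb
})

test_that("cis selection handles singleton and empty outcomes", {
  stats <- data.frame(variant = "v1", chrom = "1", pos = 1e6, ea = "A",
                      beta = 0.5, se = 0.05, p = 1e-10, n = 5000)
  ld <- matrix(1, 1, 1, dimnames = list("v1", "v1"))
  sel <- select_cis_instruments(stats, list(chrom = "1", start = 9e5, end = 1.1e6), ld)
  expect_equal(nrow(sel$variants), 1L)
  stats$p <- 0.5
  sel2 <- select_cis_instruments(stats, list(chrom = "1", start = 9e5, end = 1.1e6), ld)
  expect_equal(nrow(sel2$variants), 0L)
  expect_equal(sel2$reason, "no significant cis-pQTL")
  expect_error(select_cis_instruments(stats, list(chrom = "2", start = 1, end = 2), ld),
               "empty cis candidate window")
})

test_that("clumping output is independent of input row order", {
  set.seed(51)
  n <- 12
  stats <- data.frame(variant = paste0("v", 1:n), chrom = "1",
                      pos = seq(1e6, by = 1e4, length.out = n), ea = "A",
                      beta = 0.3, se = 0.05, p = runif(n, 1e-12, 1e-4), n = 5000)
  ld <- matrix(0.55, n, n); diag(ld) <- 1
  dimnames(ld) <- list(stats$variant, stats$variant)
  region <- list(chrom = "1", start = 1e6, end = 1.2e6)
  a <- select_cis_instruments(stats, region, ld)
  b <- select_cis_instruments(stats[sample(n), ], region, ld)
  expect_equal(a$variants$variant, b$variants$variant)
})

test_that("harmonization flips alleles, substitutes proxies, drops weak proxies", {
  expo <- data.frame(variant = c("v1", "v2", "v3"), ea = "A",
                     beta = c(0.4, 0.3, 0.2), se = 0.05, stringsAsFactors = FALSE)
  outc <- data.frame(variant = c("v1", "p2"), chrom = "1", pos = c(1, 2),
                     ea = c("C", "A"), beta = c(-0.1, 0.15), se = 0.04,
                     p = 0.001, n = 1e5, stringsAsFactors = FALSE)
  ld <- diag(4)
  ld[2, 4] <- ld[4, 2] <- 0.95          # v2 ~ p2, r2 = 0.9
  dimnames(ld) <- list(c("v1", "v2", "v3", "p2"), c("v1", "v2", "v3", "p2"))
  inst <- harmonize_and_proxy(expo, outc, ld)
  expect_equal(inst$variants, c("v1", "v2"))          # v3 dropped: no proxy
  expect_equal(inst$beta_outcome[1], 0.1)             # allele flip
  expect_equal(inst$beta_outcome[2], 0.15)            # proxy value
  expect_true(any(inst$log$action == "allele_flip"))
  expect_true(any(inst$log$action == "proxy"))
  expect_true(any(inst$log$action == "dropped"))
  # weak proxy (r2 = 0.5) is not used
  ld2 <- ld; ld2[2, 4] <- ld2[4, 2] <- sqrt(0.5)
  inst2 <- harmonize_and_proxy(expo, outc, ld2)
  expect_equal(inst2$variants, "v1")
})

test_that("palindromic variants are dropped by default but kept on request", {
  expo <- data.frame(variant = c("v1", "v2"), ea = c("A", "A"), oa = c("T", "G"),
                     beta = c(0.4, 0.3), se = 0.05, stringsAsFactors = FALSE)
  outc <- data.frame(variant = c("v1", "v2"), chrom = "1", pos = 1:2, ea = "A",
                     beta = c(0.2, 0.15), se = 0.04, p = 0.01, n = 1e5)
  ld <- diag(2); dimnames(ld) <- list(c("v1", "v2"), c("v1", "v2"))
  inst <- harmonize_and_proxy(expo, outc, ld)
  expect_equal(inst$variants, "v2")
  inst2 <- harmonize_and_proxy(expo, outc, ld, mr_params(keep_palindromic = TRUE))
  expect_equal(inst2$variants, c("v1", "v2"))
})

test_that("single-instrument GWLS is exactly the Wald ratio", {
  inst <- toy_instruments(0.4, 0.2, 0.1)
  est <- estimate_gwls(inst)
  expect_identical(est$method, "wald")
  expect_equal(est$theta, 0.5)
  expect_equal(est$se, 0.25)
})

test_that("GWLS with identity LD equals IVW to 1e-12 over random draws", {
  set.seed(61)
  for (i in 1:1000) {
    k <- sample(2:6, 1)
    bx <- rnorm(k, 0.3, 0.1)
    by <- rnorm(k, 0.1, 0.05)
    sy <- runif(k, 0.01, 0.2)
    inst <- toy_instruments(bx, by, sy)
    g <- estimate_gwls(inst)
    v <- estimate_ivw(inst)
    expect_lt(abs(g$theta - v$theta) / max(abs(v$theta), 1e-12), 1e-12)
    expect_lt(abs(g$se - v$se) / v$se, 1e-12)
  }
})

test_that("GWLS with correlated instruments matches a direct matrix-solve oracle", {
  set.seed(62)
  for (i in 1:50) {
    k <- 4
    rho <- runif(1, -0.2, 0.6)
    bx <- rnorm(k, 0.4, 0.1); by <- rnorm(k, 0.2, 0.1); sy <- runif(k, 0.05, 0.2)
    inst <- toy_instruments(bx, by, sy, rho = rho)
    omega <- outer(sy, sy) * inst$ld
    w <- solve(omega)
    theta_oracle <- drop(solve(t(bx) %*% w %*% bx) %*% t(bx) %*% w %*% by)
    se_oracle <- sqrt(drop(solve(t(bx) %*% w %*% bx)))
    est <- estimate_gwls(inst)
    expect_equal(est$theta, theta_oracle, tolerance = 1e-10)
    expect_equal(est$se, se_oracle, tolerance = 1e-10)
  }
})

test_that("IVW matches the hand-computed weighted average and gates on k", {
  inst <- toy_instruments(c(0.5, 0.4, 0.2), c(0.25, 0.1, 0.08), c(0.1, 0.08, 0.12))
  est <- estimate_ivw(inst)
  w <- inst$beta_exposure^2 / inst$se_outcome^2
  theta_hand <- sum(inst$beta_exposure * inst$beta_outcome / inst$se_outcome^2) / sum(w)
  expect_equal(est$theta, theta_hand, tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  # null outcome betas
  null_inst <- toy_instruments(c(0.5, 0.4), c(0, 0), c(0.1, 0.1))
  expect_equal(estimate_ivw(null_inst)$theta, 0)
  expect_error(estimate_ivw(toy_instruments(0.5, 0.2, 0.1)), "Wald")
})

test_that("estimates are equivariant in the exposure scale", {
  set.seed(63)
  inst <- toy_instruments(rnorm(4, 0.4, 0.1), rnorm(4, 0.2, 0.05),
                          runif(4, 0.05, 0.15), rho = 0.3)
  est <- estimate_gwls(inst)
  inst2 <- inst
  inst2$beta_exposure <- inst$beta_exposure * 2
  est2 <- estimate_gwls(inst2)
  expect_equal(est2$theta, est$theta / 2, tolerance = 1e-12)
})

test_that("Cochran's Q is zero for homogeneous ratios and matches the formula", {
  inst <- toy_instruments(c(0.5, 0.25), c(0.25, 0.125), c(0.1, 0.1))
  est <- estimate_ivw(inst)
  expect_equal(est$cochran_q, 0, tolerance = 1e-12)
  expect_equal(est$q_p, 1)
  het <- toy_instruments(c(0.5, 0.4, 0.3), c(0.3, 0.05, 0.2), c(0.1, 0.08, 0.09))
  ev <- estimate_ivw(het)
  ratios <- het$beta_outcome / het$beta_exposure
  w <- het$beta_exposure^2 / het$se_outcome^2
  q_hand <- sum(w * (ratios - ev$theta)^2)
  expect_equal(ev$cochran_q, q_hand, tolerance = 1e-12)
  expect_equal(ev$q_p, pchisq(q_hand, df = 2, lower.tail = FALSE))
  expect_error(cochran_q(toy_instruments(c(0, 0.2), c(0.1, 0.1), c(0.1, 0.1)), 0.5),
               "exposure beta of 0")
})

test_that("MR-Egger recovers slope and intercept, and skips when underdetermined", {
  bx <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  inst <- toy_instruments(bx, 0.3 * bx, rep(0.05, 5))
  est <- mr_egger(inst)
  expect_equal(est$theta, 0.3, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0, tolerance = 1e-10)
  # constant pleiotropy shows in the intercept (simulation)
  set.seed(64)
  ints <- replicate(200, {
    by <- 0.3 * bx + 0.05 + rnorm(5, 0, 0.02)
    mr_egger(toy_instruments(bx, by, rep(0.02, 5)))$egger_intercept
  })
  expect_lt(abs(mean(ints) - 0.05), 3 * sd(ints) / sqrt(200))
  skip_est <- mr_egger(toy_instruments(c(0.4, 0.3), c(0.2, 0.15), c(0.1, 0.1)))
  expect_true(grepl("skipped", skip_est$flags))
  expect_true(is.na(skip_est$theta))
})

test_that("forward MR null calibration: type-I error near 5%", {
  set.seed(65)
  panel <- genotype_panel(3, maf = 0.3, rho = 0.3)
  reps <- 500
  pvals <- vapply(seq_len(reps), function(i) {
    s <- generate_two_sample_sumstats(panel, c(0.4, 0.3, 0.3), 0,
                                      5000, 5000, seed = 2000 + i)
    inst <- instrument_set(panel$ids, s$exposure$beta, s$exposure$se,
                           s$outcome$beta, s$outcome$se, ld = panel$ld)
    estimate_gwls(inst)$p
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("reverse MR excludes the APOE locus and the cis window", {
  gwas <- data.frame(
    variant = c("apoe1", "apoe2", "cis1", "far1", "far2"),
    chrom = c("19", "19", "5", "2", "7"),
    pos = c(45300000, 45400000, 1e6, 5e7, 8e7),
    ea = "A",
    beta = c(0.4, 0.35, 0.2, 0.1, 0.12), se = 0.01,
    p = c(1e-50, 1e-40, 1e-12, 1e-9, 1e-10), n = 4e5)
  prot <- data.frame(variant = gwas$variant, chrom = gwas$chrom, pos = gwas$pos,
                     ea = "A", beta = 0.3 * gwas$beta, se = 0.02, p = 0.001, n = 5000)
  est <- reverse_mr(gwas, prot,
                    protein_gene_region = list(chrom = "5", start = 9e5, end = 1.1e6))
  expect_equal(est$n_instruments, 2L)          # far1, far2 only
  expect_lt(abs(est$theta - 0.3), 3 * est$se)
  # only-APOE instruments with exclusion -> reason-coded NA
  gwas_apoe <- gwas[1:2, ]
  est2 <- reverse_mr(gwas_apoe, prot)
  expect_true(is.na(est2$theta))
  expect_match(est2$flags, "all instruments excluded")
  # without the exclusion the APOE instruments are usable
  est3 <- reverse_mr(gwas_apoe, prot, exclude_apoe = FALSE)
  expect_equal(est3$n_instruments, 2L)
})

test_that("reverse MR recovers a simulated liability -> protein effect", {
  panel <- genotype_panel(20, maf = 0.3, rho = 0, chrom = "2")
  s <- generate_two_sample_sumstats(panel, rep(0.1, 20), 0.1,
                                    200000, 20000, seed = 66)
  gwas <- s$exposure          # variant -> LOAD, all genome-wide significant
  prot <- s$outcome
  est <- reverse_mr(gwas, prot, ld = panel$ld)
  expect_lt(abs(est$theta - 0.1), 3 * est$se)
})

test_that("age-stratified reverse MR selects the stratum table", {
  panel <- genotype_panel(10, maf = 0.3, rho = 0, chrom = "2")
  s_young <- generate_two_sample_sumstats(panel, rep(0.1, 10), 0.05,
                                          200000, 20000, seed = 67)
  s_old <- generate_two_sample_sumstats(panel, rep(0.1, 10), 0.4,
                                        200000, 20000, seed = 68)
  strata <- list(lt80 = s_young$outcome, ge80 = s_old$outcome)
  est_y <- reverse_mr(s_young$exposure, strata, ld = panel$ld, age_stratum = "lt80")
  est_o <- reverse_mr(s_young$exposure, strata, ld = panel$ld, age_stratum = "ge80")
  expect_gt(est_o$theta, est_y$theta)
})

test_that("mr_table assembles per-protein rows with a per-direction FDR", {
  ests <- list(p1 = estimate_gwls(toy_instruments(0.4, 0.2, 0.05)),
               p2 = estimate_gwls(toy_instruments(0.4, 0.01, 0.05)))
  tab <- mr_table(ests, direction = "forward")
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$fdr >= tab$p - 1e-12))
  expect_equal(tab$direction, c("forward", "forward"))
})
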