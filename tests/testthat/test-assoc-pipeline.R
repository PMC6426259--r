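make_table <- function(n_samples = 100, seed = 1) {
  tax <- build_taxonomy(c(2, 2, 3, 4, 6, 5), seed = seed)
  sample_abundance_table(tax, n_samples,
                         target_zero_fracs = seq(0, 0.9, length.out = 22),
                         seed = seed + 1)
}

test_that("prevalence filter splits taxa into a retained/dropped partition", {
  tt <- make_table(seed = 2)
  ft <- filter_taxa(tt, 0.20)
  expect_setequal(c(rownames(ft$abundance), ft$dropped$taxon),
                  rownames(tt$abundance))
  expect_true(all(rowMeans(ft$abundance > 0) >= 0.20))
  ## boundary: exactly 20% non-zero is retained (>= semantics)
  tt$abundance["s_001", ] <- c(rep(0.01, 20), rep(0, 80))
  ft2 <- filter_taxa(tt, 0.20)
  expect_true("s_001" %in% rownames(ft2$abundance))
  ## threshold 0 is the identity
  expect_equal(nrow(filter_taxa(tt, 0)$abundance), nrow(tt$abundance))
  ## everything dropped is an error
  expect_error(filter_taxa(tt, 1.5), "dropped")
})

test_that("rank-INT matches the Blom quantile oracle and is rank-invariant", {
  ## frozen oracle: qnorm((r - 3/8) / (n + 1/4)) at n = 3
  expect_equal(rank_int(c(1.2, 5.0, 3.3)),
               qnorm((c(1, 3, 2) - 3 / 8) / 3.25))
  expect_equal(round(rank_int(c(1.2, 5.0, 3.3)), 2), c(-0.87, 0.87, 0.00))
  set.seed(3)
  x <- rexp(100)
  expect_equal(rank_int(x), rank_int(log(x)))     # monotone invariance
  expect_equal(rank_int(x), rank_int(x * 100 + 7))
  expect_lt(abs(sum(rank_int(x))), 1e-10)         # symmetry
  ## ties (zero mass) share a mid-rank
  y <- c(0, 0, 0, 1, 2)
  expect_equal(rank_int(y)[1], rank_int(y)[2])
  expect_error(rank_int(rep(1, 10)), "constant")
  expect_error(rank_int(c(1, 2)), "3 finite")
  ## near-normality at the discovery sample size
  z <- rank_int(rexp(182))
  expect_gt(shapiro.test(z)$p.value, 0.01)
})

test_that("covariate selection admits noise-sharers and bars genotype proxies", {
  set.seed(4)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  shared <- rnorm(n)
  y <- -0.3 * g + shared + rnorm(n, 0, 0.5)
  cand <- cbind(noise1 = rnorm(n), noise2 = rnorm(n),
                sharer = shared + rnorm(n, 0, 0.3),
                gproxy = g + rnorm(n, 0, 0.2))
  ## independent noise alone is never admitted
  expect_length(select_level_covariates(y, cand[, 1:2], g), 0)
  sel <- select_level_covariates(y, cand, g)
  expect_true("sharer" %in% sel)
  expect_false("gproxy" %in% sel)
  ## adjusting for the sharer shrinks the genotype SE (power gain)
  fit0 <- fit_snp_taxon(y, g)
  fit1 <- fit_snp_taxon(y, g, C = cand[, sel, drop = FALSE])
  expect_lt(fit1$se, fit0$se)
  ## and leaves the estimate unbiased
  expect_lt(abs(fit1$beta - -0.3 / sd(y)), 3 * fit1$se)
})

test_that("SNP-taxon regression recovers effects on the declared scale", {
  set.seed(5)
  n <- 1000
  g <- rbinom(n, 2, 0.3)
  y <- -0.4 * g + rnorm(n)
  fit <- fit_snp_taxon(y, g, taxon = "t1", predictor = "L1")
  ## outcome standardized to unit variance, genotype untransformed
  expect_lt(abs(fit$beta - -0.4 / sd(y)), 3 * fit$se)
  expect_true(fit$p > 0 && fit$p <= 1)
  ## perfect fit
  fitp <- suppressWarnings(fit_snp_taxon(scale(g)[, 1], g))
  expect_lt(fitp$p, 1e-10)
  ## irrelevant covariate barely moves the estimate
  fitn <- fit_snp_taxon(y, g, C = cbind(z = rnorm(n)))
  expect_lt(abs(fitn$beta - fit$beta), fit$se)
  ## constant genotype is a flagged record, not a crash
  fitc <- fit_snp_taxon(y, rep(1, n))
  expect_true(is.na(fitc$beta))
  expect_match(fitc$note, "constant-genotype")
})

test_that("taxon-disease logistic regression is calibrated and unbiased", {
  set.seed(6)
  ## parameter recovery: protective taxon, log-OR -0.5 per SD
  n <- 2000
  b <- rnorm(n)
  d <- rbinom(n, 1, plogis(-0.5 + -0.5 * b))
  fit <- fit_taxon_disease(b, d)
  expect_lt(abs(fit$beta - -0.5), 3 * fit$se)
  ## null calibration: p roughly uniform over replicates
  ps <- replicate(300, {
    b <- rnorm(300); d <- rbinom(300, 1, 0.4)
    fit_taxon_disease(b, d)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_error(fit_taxon_disease(rnorm(10), rep(1, 10)), "both classes")
})

test_that("per-rank Bonferroni thresholds follow the rank test counts", {
  res <- data.frame(rank = c(rep("genus", 63), "species"),
                    p = c(runif(63, 0, 1e-4), 0.04))
  out <- per_level_bonferroni(res)
  expect_equal(out$threshold[out$rank == "genus"][1], 0.05 / 63)
  expect_equal(out$threshold[out$rank == "species"], 0.05)   # single test
  expect_true(out$candidate[out$rank == "species"])
  expect_equal(nrow(per_level_bonferroni(res[0, ])), 0)      # empty level
})

test_that("stratified analyses handle degenerate strata and recover heterogeneity", {
  set.seed(7)
  n <- 600
  subtype <- sample(c("CD", "UC"), n, replace = TRUE, prob = c(0.6, 0.4))
  ileal <- ifelse(subtype == "CD", rbinom(n, 1, 0.6), NA)
  g <- rbinom(n, 2, 0.3)
  ## effect only in CD
  y <- ifelse(subtype == "CD", -0.5 * g, 0) + rnorm(n)
  out <- stratified_analysis(y, g, subtype = subtype, ileal = ileal)
  expect_setequal(out$stratum, c("IBD", "CD", "CDil", "CDni", "UC"))
  expect_gt(abs(out$beta[out$stratum == "CD"]),
            abs(out$beta[out$stratum == "UC"]))
  ## CD strata partition: CDil + CDni sample sizes sum to CD
  expect_equal(out$n[out$stratum == "CDil"] + out$n[out$stratum == "CDni"],
               out$n[out$stratum == "CD"])
  ## constant genotype in a stratum gives a missing-result record
  g2 <- ifelse(subtype == "UC", 0, g)
  out2 <- stratified_analysis(y, g2, subtype = subtype, ileal = ileal)
  expect_true(is.na(out2$beta[out2$stratum == "UC"]))
  expect_match(out2$note[out2$stratum == "UC"], "constant-genotype")
})

test_that("the null SNP-taxon pipeline keeps its type-I error near nominal", {
  set.seed(8)
  ps <- replicate(400, {
    n <- 150
    g <- rbinom(n, 2, 0.3)
    Z <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 40, 12))
    b <- rexp(n) * rbinom(n, 1, 0.7)   # sparse, skewed, independent of g
    fit_snp_taxon(rank_int(b), g, Z = Z)$p
  })
  rej <- mean(ps < 0.05)
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.075)
})
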