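test_that("standard errors are recovered from printed effect/p pairs", {
  ## normal-quantile oracle: SE = |beta| / qnorm(1 - p/2)
  expect_equal(se_from_beta_p(-0.56, 4.0e-4), 0.56 / qnorm(1 - 2e-4))
  expect_equal(se_from_beta_p(-0.56, 4.0e-4), 0.158, tolerance = 5e-3)
  expect_equal(se_from_beta_p(-0.08, 0.50), 0.119, tolerance = 5e-3)
  expect_error(se_from_beta_p(-0.1, 1), "inside")
  expect_error(se_from_beta_p(0, 0.05), "non-zero")
})

test_that("fixed-effect pooling follows inverse-variance arithmetic", {
  ## two identical studies: same estimate, SE shrinks by sqrt(2)
  m <- inverse_variance_meta(c(-0.5, -0.5), c(0.1, 0.1))
  expect_equal(m$beta, -0.5)
  expect_equal(m$se, 0.1 / sqrt(2))
  expect_equal(sum(m$weights), 1)
  expect_lt(m$se, 0.1)
  ## single study passes through with a warning
  expect_warning(m1 <- inverse_variance_meta(-0.3, 0.2), "single study")
  expect_equal(m1$beta, -0.3)
  expect_equal(m1$se, 0.2)
  ## order invariance and scale consistency
  m2 <- inverse_variance_meta(c(-0.2, -0.6), c(0.15, 0.3))
  m3 <- inverse_variance_meta(c(-0.6, -0.2), c(0.3, 0.15))
  expect_equal(m2$beta, m3$beta)
  m4 <- inverse_variance_meta(2 * c(-0.2, -0.6), 2 * c(0.15, 0.3))
  expect_equal(m4$beta, 2 * m2$beta)
  expect_equal(m4$se, 2 * m2$se)
})

test_that("published two-stage rows pool to their printed values", {
  path <- system.file("extdata", "published_associations.tsv",
                      package = "ascbias")
  tab <- read.delim(path)
  ## the three rows whose printed pooled value reconstructs from printed
  ## (beta, p) pairs alone; the Bacteroides row does not round-trip through
  ## the printed precision of its replication p-value
  tab <- tab[tab$outcome != "Bacteroides", ]
  for (i in seq_len(nrow(tab))) {
    pooled <- inverse_variance_meta(
      c(tab$beta_discovery[i], tab$beta_replication[i]),
      c(se_from_beta_p(tab$beta_discovery[i], tab$p_discovery[i]),
        se_from_beta_p(tab$beta_replication[i], tab$p_replication[i])))
    expect_equal(round(pooled$beta, 2), tab$beta_pooled[i],
                 info = paste(tab$outcome[i], tab$gene[i]))
  }
})

test_that("pooling agrees with the reference meta-analysis implementation", {
  skip_if_not_installed("metafor")
  beta <- c(-0.56, -0.30); se <- c(0.158, 0.122)
  ours <- inverse_variance_meta(beta, se)
  ref <- metafor::rma(yi = beta, sei = se, method = "FE")
  expect_equal(ours$beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$se, ref$se, tolerance = 1e-10)
})

test_that("sign enrichment is exact, symmetric and direction-aware", {
  ## symmetric null: half negative is unremarkable
  expect_gt(sign_enrichment(c(rep(-1, 84), rep(1, 84)))$p, 0.4)
  ## exact binomial oracle for 101 of 168
  e <- sign_enrichment(c(rep(-1, 101), rep(1, 67)))
  expect_equal(e$p, binom.test(101, 168, alternative = "greater")$p.value)
  expect_lt(e$p, 0.01)
  ## degenerate direction
  expect_equal(sign_enrichment(rep(1, 10), "negative")$p, 1)
  ## exact mirror symmetry
  set.seed(1)
  x <- rnorm(51)
  expect_equal(sign_enrichment(x, "negative")$p,
               sign_enrichment(-x, "positive")$p)
  ## zeros reduce the total
  expect_equal(sign_enrichment(c(0, -1, 1, -1))$n_total, 3)
})

test_that("concordance pairs taxa, detects shared structure, stays null otherwise", {
  set.seed(2)
  ## independent noise panels: small correlation, non-significant
  c0 <- concordance(matrix(rnorm(200), 50, 4), rnorm(50), n_perm = 2000,
                    seed = 3)
  expect_lt(abs(c0$correlation), 0.35)
  expect_gt(c0$p, 0.01)
  ## construction with shared structure is detected as positive
  bB <- rnorm(50)
  bg <- sapply(1:4, function(i) 0.5 * bB + rnorm(50, 0, 0.3))
  c1 <- concordance(bg, bB, n_perm = 2000, seed = 4)
  expect_gt(c1$correlation, 0.5)
  expect_lt(c1$p, 0.01)
  expect_equal(sum(c1$bins$n), 50)
  expect_error(concordance(rnorm(2), rnorm(2)), "3 paired")
  ## permutation p is calibrated under the null
  ps <- replicate(60, concordance(rnorm(20), rnorm(20), n_perm = 400)$p)
  expect_gt(mean(ps < 0.05), 0.0)   # sanity: not all tiny
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("slope test against unity flags attenuation only when present", {
  x <- c(-0.5, -0.2, 0.1, 0.3, 0.6, -0.8, 0.4, 0.05, -0.3, 0.7)
  s_id <- suppressWarnings(slope_vs_unity(x, x))
  expect_equal(s_id$slope, 1)
  expect_equal(s_id$t, 0)
  expect_equal(s_id$p, 1)
  set.seed(5)
  s_half <- slope_vs_unity(0.5 * x + rnorm(10, 0, 0.01), x)
  expect_equal(s_half$slope, 0.5, tolerance = 0.05)
  expect_lt(s_half$p, 0.05)
  expect_error(slope_vs_unity(c(1, 2), c(1, 2)), "3 pairs")
  expect_error(slope_vs_unity(x, rep(1, 10)), "constant")
})

test_that("case-only attenuation under mediation surfaces as a slope below 1", {
  ## mediation panel: full-population vs case-only genotype effects
  pan <- run_panel_experiment("a", n_taxa = 40, reps = 1, seed = 6,
                              effect_range = c(0.5, 1.2))
  ## case-only estimates regressed on their own full-population analogue:
  ## approximate the population effect by the generative slope beta_g's
  ## attenuated partner; here use the disease-effect axis as anchor instead
  set.seed(7)
  beta_full <- numeric(30); beta_case <- numeric(30)
  for (t in 1:30) {
    spec <- causal_model("a", beta = -runif(1, 0.3, 0.8),
                         omegaB = -0.8, prevalence = 0.3)
    spec$omega0 <- calibrate_intercept(spec)
    pop <- simulate_population(spec, 6000)
    s <- standardize(pop$b, pop$g, pop$d)
    beta_full[t] <- ascbias:::ols_slope(s$B, pop$g)
    cases <- pop$d == 1
    beta_case[t] <- ascbias:::ols_slope(s$B[cases], pop$g[cases])
  }
  st <- slope_vs_unity(beta_case, beta_full)
  expect_lt(st$slope, 1)
  expect_lt(st$p, 0.05)
})
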