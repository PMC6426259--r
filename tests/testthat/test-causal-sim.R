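test_that("model constraints are enforced at construction", {
  expect_error(causal_model("a", omegaG = 0.3), "model a forces")
  expect_error(causal_model("b", omegaB = 0.3), "model b forces")
  expect_error(causal_model("c", beta = 0.3), "model c forces")
  expect_error(causal_model("d", omegaB = 0.3), "model d forces")
  expect_error(causal_model("a", maf = 0), "maf")
})

test_that("intercept calibration hits the target prevalence", {
  ## closed forms with all effects zero
  null_spec <- causal_model("c", prevalence = 0.3)
  expect_equal(calibrate_intercept(null_spec, 0.3), log(0.3 / 0.7),
               tolerance = 1e-6)
  expect_equal(calibrate_intercept(null_spec, 0.5), 0, tolerance = 1e-6)
  ## Monte-Carlo oracle: rare disease with both effects active
  spec <- causal_model("c", omegaB = 0.5, omegaG = 0.5, prevalence = 0.01)
  w0 <- calibrate_intercept(spec, 0.01)
  spec$omega0 <- w0
  pop <- simulate_population(spec, 2e5, seed = 1)
  expect_lt(abs(mean(pop$d) - 0.01), 0.001)
})

test_that("populations show the model-dictated associations", {
  ## null model: no B-d correlation
  null_a <- causal_model("a", beta = 0, omegaB = 0, prevalence = 0.3)
  pop0 <- simulate_population(null_a, 1e5, seed = 2)
  expect_lt(abs(cor(pop0$B, pop0$d)), 0.01)
  ## model c: B and G unassociated in the population
  popc <- simulate_population(canon_c(), 2e5, seed = 3)
  expect_lt(abs(cor(popc$B, popc$G)), 3 / sqrt(2e5))
  ## model d with gamma < 0, omegaG > 0: negative population corr(B, G)
  popd <- simulate_population(canon_d(), 2e5, seed = 4)
  expect_lt(cor(popd$B, popd$G), -3 / sqrt(2e5))
  ## standardized views
  for (v in list(popc$B, popc$G, popc$D)) {
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(mean(v^2) - 1), 1e-8)
  }
})

test_that("ascertainment reproduces the case-only association patterns", {
  expect_error(ascertain(simulate_population(canon_c(), 500, seed = 5),
                         n_cases = 10000), "available")
  ## model c cases: positive within-case association from biased selection
  popc <- simulate_population(canon_c(), 2e5, seed = 6)
  cc <- ascertain(popc)
  expect_gt(cor(cc$B, cc$G), 3 / sqrt(cc$n))
  ## model d cases: the indirect association is cancelled
  popd <- simulate_population(canon_d(), 2e5, seed = 7)
  cd <- ascertain(popd)
  expect_lt(abs(cor(cd$B, cd$G)), 3.5 / sqrt(cd$n))
  ## subsampling is uniform and seed-stable
  c200 <- ascertain(popc, n_cases = 200, seed = 8)
  expect_equal(c200$n, 200)
  expect_identical(ascertain(popc, 200, seed = 8)$g, c200$g)
})

test_that("bias replicates carry the predicted Delta signs per model", {
  r_a <- run_bias_experiment(canon_a(), reps = 60, n = 8000, seed = 9)
  expect_gt(median(r_a$delta), 0)            # -sign(beta), beta < 0
  expect_true(all(r_a$delta == r_a$beta_case - r_a$beta_pop))
  r_b <- run_bias_experiment(canon_b(), reps = 60, n = 8000, seed = 10)
  expect_lt(abs(median(r_b$delta)), 3 * sd(r_b$delta) / sqrt(60))
  r_c <- run_bias_experiment(canon_c(), reps = 60, n = 8000, seed = 11)
  expect_gt(median(r_c$delta), 0)            # -sign(omegaG * omegaB)
  r_d <- run_bias_experiment(canon_d(), reps = 60, n = 8000, seed = 12)
  expect_lt(abs(median(r_d$beta_case)), 0.02)
  ## error-distribution robustness: exponential and uniform share the signs
  for (ed in c("exponential", "uniform")) {
    r <- run_bias_experiment(canon_a(), reps = 40, n = 8000, seed = 13,
                             error_dists = ed)
    expect_gt(median(r$delta), 0)
  }
})

test_that("sparsity runs are deterministic and attenuate toward the null", {
  s1 <- run_sparsity_experiment("a", reps = 10, n = 2000, n_cases = 100,
                                seed = 14)
  s2 <- run_sparsity_experiment("a", reps = 10, n = 2000, n_cases = 100,
                                seed = 14)
  expect_identical(s1$sev_int, s2$sev_int)
  ## attenuation: dense vs very sparse bins (model b keeps a true effect)
  s <- run_sparsity_experiment("b", reps = 300, n = 4000, n_cases = 200,
                               seed = 15)
  dense <- abs(s$sev_int[s$zero_frac < 0.3])
  sparse <- abs(s$sev_int[s$zero_frac > 0.7])
  expect_gt(median(dense), median(sparse))
})

test_that("heterogeneity strata behave as designed", {
  ## models c and d: no association signal in any stratum (UC independent,
  ## CD bias diluted toward null at rare-disease literature magnitudes)
  h_c <- run_heterogeneity_experiment("c", reps = 200, n = 30000,
                                      n_cases = 200, seed = 30)
  for (p in list(h_c$p_IBD, h_c$p_CD, h_c$p_UC)) {
    rej <- mean(p < 0.05, na.rm = TRUE)
    expect_gt(rej, 0.01); expect_lt(rej, 0.11)
  }
  ## model a: the genotype-bacterium arrow is population-wide, so UC cases
  ## (sampled without selection on B) show the full effect while CD cases
  ## are attenuated by case-only selection
  h_a <- run_heterogeneity_experiment("a", reps = 200, n = 10000,
                                      n_cases = 150, seed = 16,
                                      prev_cd = 0.02, prev_uc = 0.02)
  expect_gt(nrow(h_a), 150)
  expect_lt(mean(h_a$beta_UC, na.rm = TRUE), 0)
  expect_lt(mean(h_a$beta_UC, na.rm = TRUE),
            mean(h_a$beta_CD, na.rm = TRUE))
})

test_that("severity acts as the buffering intermediate under reverse causation", {
  sv <- run_severity_experiment("d", reps = 3, n = 60000, seed = 17)
  expect_true(all(sv$p_unadj < 0.01))          # persists unadjusted
  expect_true(all(abs(sv$cor_adj) < 0.05))     # cancelled by adjustment
  ## mediation keeps its signal after adjustment for severity
  sa <- run_severity_experiment("a", reps = 2, n = 30000, seed = 18)
  expect_true(all(sa$cor_unadj < 0))
})

test_that("panel correlations discriminate the causal models", {
  pc <- run_panel_experiment("c", n_taxa = 30, reps = 4, seed = 19,
                             omegaG = 1.2, effect_range = c(0.6, 1.4))
  expect_lt(mean(attr(pc, "panel_cor")), -0.2)
  pa <- run_panel_experiment("a", n_taxa = 30, reps = 4, seed = 20)
  expect_gt(mean(attr(pa, "panel_cor")), 0.2)
  pd <- run_panel_experiment("d", n_taxa = 30, reps = 6, seed = 21)
  expect_lt(abs(mean(attr(pd, "panel_cor"))), 0.25)
})

test_that("polynomial approximation is nested and saturates appropriately", {
  ## common disease, modest effects: marginal terms already fit well
  pop1 <- simulate_population(
    causal_model("c", omegaB = 0.2, omegaG = 0.2, prevalence = 0.5),
    20000, seed = 22)
  f1 <- fit_polynomial_logit_approx(pop1)
  expect_true(all(diff(f1$fit_quality) >= -1e-12))
  expect_gt(f1$fit_quality["model0"], 0.98 * f1$fit_quality["model3"])
  ## rare disease, large effects: higher-order terms are needed
  pop2 <- simulate_population(
    causal_model("c", omegaB = 1.5, omegaG = 1.5, prevalence = 0.02),
    20000, seed = 23)
  f2 <- fit_polynomial_logit_approx(pop2)
  expect_gt(f2$fit_quality["model3"], f2$fit_quality["model0"] + 0.01)
  ## max_order = 1 reproduces model0 exactly
  f3 <- fit_polynomial_logit_approx(pop1, max_order = 1)
  expect_equal(f3$lambda$model0, f1$lambda$model0)
  expect_named(f3$lambda, "model0")
})
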