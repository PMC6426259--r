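test_that("standardization is idempotent, errors on constants, kills moments under independence", {
  set.seed(1)
  b <- rnorm(500); g <- rbinom(500, 2, 0.3); d <- rbinom(500, 1, 0.4)
  s <- standardize(b, g, d)
  s2 <- standardize(s$B, s$G, d)   # idempotence on already-standardized input
  expect_equal(s$B, s2$B, tolerance = 1e-12)
  expect_equal(s$G, s2$G, tolerance = 1e-12)
  expect_error(standardize(b, g, rep(1, 500)), "constant|binary")
  expect_error(standardize(b, rep(2, 500), d), "g")
  ## independence oracle: mixed moments with D vanish at root-n scale
  set.seed(2)
  n <- 1e6
  b <- rnorm(n); g <- rbinom(n, 2, 0.3); d <- rbinom(n, 1, 0.3)
  m <- standardize(b, g, d)$moments
  for (mm in c(m$E_BGD, m$E_BD, m$E_GD, m$E_G2D))
    expect_lt(abs(mm), 3 / sqrt(n) * 2)
})

test_that("conditional-moment identity is algebraically exact on finite samples", {
  for (seed in 1:5) {
    pop <- simulate_population(canon_c(), 2000, seed = seed)
    s <- standardize(pop$b, pop$g, pop$d)
    r <- s$moments$sigma_d / s$moments$mu_d
    cases <- pop$d == 1
    for (X in list(s$B, s$G, s$B * s$G, s$G^2)) {
      expect_lt(abs(mean(X[cases]) - (mean(X) + r * mean(X * s$D))), 1e-10)
    }
  }
})

test_that("the moment formula reproduces the two-regression difference exactly", {
  ## d independent of (B, G): Delta = 0 when the mixed moments vanish
  m0 <- structure(list(E_BG = 0.25, E_BD = 0, E_GD = 0, E_BGD = 0,
                       E_G2D = 0, mu_d = 0.3, sigma_d = sqrt(0.21), n = 100),
                  class = "moment_set")
  expect_equal(delta_exact(m0)$delta, 0)
  ## oracle equivalence across all four models, random parameter draws
  set.seed(3)
  specs <- list(
    causal_model("a", beta = runif(1, -0.5, 0.5), omegaB = runif(1, -1, 1),
                 prevalence = runif(1, 0.1, 0.5)),
    causal_model("b", beta = runif(1, -0.5, 0.5), omegaG = runif(1, -1, 1),
                 prevalence = runif(1, 0.1, 0.5)),
    causal_model("c", omegaB = runif(1, -1, 1), omegaG = runif(1, -1, 1),
                 prevalence = runif(1, 0.1, 0.5)),
    causal_model("d", gamma = runif(1, -0.5, 0.5), omegaG = runif(1, -1, 1),
                 prevalence = runif(1, 0.1, 0.5)))
  for (i in seq_along(specs)) {
    pop <- simulate_population(specs[[i]], 20000, seed = 100 + i)
    de <- delta_exact(standardize(pop$b, pop$g, pop$d)$moments)
    expect_lt(abs(de$delta - delta_brute(pop)), 1e-8)
    expect_equal(de$beta_case - de$beta, de$delta, tolerance = 1e-12)
  }
  ## model c at the reference parameterization: positive bias
  popc <- simulate_population(canon_c(), 2e5, seed = 42)
  expect_gt(delta_exact(standardize(popc$b, popc$g, popc$d)$moments)$delta, 0)
})

test_that("closed-form approximations carry the right magnitude and signs", {
  ## model b is exactly unbiased
  expect_equal(delta_approx(canon_b())$delta, 0)
  ## model a with beta < 0: positive approximation
  expect_gt(delta_approx(canon_a())$delta, 0)
  ## magnitude against the exact-formula oracle (small effects, mu_d = 0.3)
  sp_a <- causal_model("a", beta = -0.3, omegaB = -0.4, prevalence = 0.3)
  pop <- simulate_population(sp_a, 2e5, seed = 44)
  de <- delta_exact(standardize(pop$b, pop$g, pop$d)$moments)
  expect_equal(delta_approx(sp_a)$delta, de$delta, tolerance = 0.25)
  ## sign agreement with the exact estimator across random sweeps and all
  ## three additive error distributions
  set.seed(45)
  for (ed in c("normal", "exponential", "uniform")) {
    for (i in 1:8) {
      sgn <- sample(c(-1, 1), 3, replace = TRUE)
      spec <- switch(sample(c("a", "c", "d"), 1),
        a = causal_model("a", beta = sgn[1] * runif(1, 0.2, 0.4),
                         omegaB = sgn[2] * runif(1, 0.3, 0.7),
                         prevalence = 0.3, error_dist = ed),
        c = causal_model("c", omegaB = sgn[1] * runif(1, 0.3, 0.7),
                         omegaG = sgn[2] * runif(1, 0.3, 0.7),
                         prevalence = 0.3, error_dist = ed),
        d = causal_model("d", gamma = sgn[1] * runif(1, 0.2, 0.4),
                         omegaG = sgn[2] * runif(1, 0.3, 0.7),
                         prevalence = 0.3, error_dist = ed))
      pop <- simulate_population(spec, 1e5)
      de <- delta_exact(standardize(pop$b, pop$g, pop$d)$moments)
      ap <- delta_approx(spec)
      if (abs(de$delta) > 6 / sqrt(sum(pop$d)))  # resolvable above MC noise
        expect_equal(sign(de$delta), ap$sign)
    }
  }
})

test_that("rare diseases suffer less selection bias than common ones", {
  rare <- causal_model("c", omegaB = -0.5, omegaG = 0.5, prevalence = 0.01)
  common <- canon_c()
  pop_r <- simulate_population(rare, 5e5, seed = 46)
  pop_c <- simulate_population(common, 2e5, seed = 47)
  d_r <- delta_exact(standardize(pop_r$b, pop_r$g, pop_r$d)$moments)$delta
  d_c <- delta_exact(standardize(pop_c$b, pop_c$g, pop_c$d)$moments)$delta
  expect_lt(abs(d_r), abs(d_c))
})

test_that("sign-pattern predictions match the canonical table", {
  ## canonical signs: beta < 0 (or gamma < 0), omegaB < 0, omegaG > 0
  pa <- predict_sign_pattern("a")
  expect_equal(unclass(pa)[1:4],
               c(population = "-", case_only = "-", delta = "+",
                 panel_corr = "+"))
  pb <- predict_sign_pattern("b")
  expect_equal(pb[["case_only"]], "same-as-population")
  expect_equal(pb[["delta"]], "0")
  pc <- predict_sign_pattern("c")
  expect_equal(unclass(pc)[1:4],
               c(population = "0", case_only = "+", delta = "+",
                 panel_corr = "-"))
  pd <- predict_sign_pattern("d")
  expect_equal(unclass(pd)[1:4],
               c(population = "-", case_only = "0", delta = "+",
                 panel_corr = "0"))
  expect_error(predict_sign_pattern("c", omegaB_sign = 0), "contradictory")
})
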