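## fast intercept calibration on a realized linear predictor
calibrate_on_eta <- function(eta, target) {
  stats::uniroot(function(w) mean(stats::plogis(w + eta)) - target,
                 c(-40, 40), extendInt = "yes", tol = 1e-9)$root
}

## per-replicate child seeds derived from one master seed
replicate_seeds <- function(seed, reps) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2^31 - 2, reps)
}

## signed explained variance of a simple regression
signed_r2 <- function(y, x) {
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  r <- stats::cor(x, y)
  sign(r) * r^2
}

simple_p <- function(y, x) {
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor.test(x, y)$p.value
}

#' Replicate grid of the case-only bias under a generative model
#'
#' For each replicate, simulates a population, estimates the coefficient of
#' the standardized bacterial level on the standardized genotype by ordinary
#' least squares in the whole population and in cases only, and records
#' their difference Delta.  Repeats over the requested error distributions.
#'
#' @param spec a \code{\link{causal_model}} (its \code{error_dist} is
#'   overridden per grid cell).
#' @param reps replicates per error distribution.
#' @param n individuals per replicate.
#' @param seed master seed; replicate seeds are derived from it.
#' @param error_dists error distributions to cover.
#' @return an object of class \code{"experiment_result"}: a data frame with
#'   one row per replicate (model_id, error_dist, rep, beta_pop, beta_case,
#'   delta) where \code{delta = beta_case - beta_pop} exactly.
#' @examples
#' r <- run_bias_experiment(causal_model("b", beta = -0.3, omegaG = 0.4),
#'                          reps = 20, n = 5000, seed = 1)
#' median(r$delta)
#' @export
run_bias_experiment <- function(spec, reps = 200, n = 20000, seed = NULL,
                                error_dists = "normal") {
  stopifnot(inherits(spec, "causal_model"), reps >= 1)
  out <- list()
  for (ed in error_dists) {
    sp <- spec
    sp$error_dist <- ed
    sp$omega0 <- calibrate_intercept(sp)
    seeds <- replicate_seeds(seed, reps)
    rows <- lapply(seq_len(reps), function(i) {
      pop <- simulate_population(sp, n, seed = seeds[i])
      bp <- ols_slope(pop$B, pop$G)
      cases <- pop$d == 1
      bc <- ols_slope(pop$B[cases], pop$G[cases])
      data.frame(model_id = sp$model_id, error_dist = ed, rep = i,
                 beta_pop = bp, beta_case = bc, delta = bc - bp,
                 stringsAsFactors = FALSE)
    })
    out[[ed]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("experiment_result", "data.frame"),
            experiment = "bias", n = n, seed = seed)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result (%s): %d rows\n",
              attr(x, "experiment"), nrow(x)))
  NextMethod()
}

## one sparsity-style replicate: NB bacterium, logistic disease, case subsample
sparsity_replicate <- function(model_id, n, n_cases, maf, zero_frac,
                               beta, gamma, omegaB, omegaG, prevalence,
                               nb_mean = 50) {
  g <- stats::rbinom(n, 2, maf)
  if (stats::var(g) == 0) return(NULL)
  G <- standardize_vec(g, "g")
  size <- if (zero_frac <= exp(-nb_mean)) Inf else
    suppressWarnings(nb_size_for_zero(nb_mean, zero_frac))
  if (model_id == "d") {
    w0 <- calibrate_on_eta(omegaG * G, prevalence)
    d <- stats::rbinom(n, 1, stats::plogis(w0 + omegaG * G))
    if (stats::var(d) == 0) return(NULL)
    ## gamma acts as the per-case log-fold change of the bacterial mean:
    ## a standardized-status scaling would blow up for rare disease
    b <- as.numeric(rnbinom_mu(n, nb_mean * exp(gamma * d), size))
  } else {
    shift <- if (model_id %in% c("a", "b")) beta * G else 0
    b <- as.numeric(rnbinom_mu(n, nb_mean * exp(shift), size))
    if (stats::var(b) == 0) return(NULL)
    Bl <- standardize_vec(b, "b")
    eta <- switch(model_id,
                  a = omegaB * Bl,
                  b = omegaG * G,
                  c = omegaB * Bl + omegaG * G)
    w0 <- calibrate_on_eta(eta, prevalence)
    d <- stats::rbinom(n, 1, stats::plogis(w0 + eta))
  }
  list(g = g, b = b, d = d)
}

#' Sparsity experiment: effect recovery under increasing zero inflation
#'
#' Per replicate, draws an allele frequency uniformly, a negative-binomial
#' bacterial level whose dispersion is solved to hit a replicate-specific
#' zero fraction, and a disease status from the model's logistic; samples
#' cases; and estimates the genotype-bacterium association in the cases on
#' the raw and on the rank-transformed level.  Signed explained variance and
#' p-values are recorded with the replicate's zero fraction.
#'
#' @param model_id generative model, one of "a", "b", "c", "d".
#' @param reps number of replicates (the reference experiment uses 20000;
#'   scale down for quick runs).
#' @param n population size per replicate.
#' @param n_cases cases sampled per replicate.
#' @param seed master seed.
#' @param zero_range range of target zero fractions, default [0, 0.95].
#' @param maf_range range of allele frequencies, default [0.05, 0.95].
#' @param beta,gamma,omegaB,omegaG,prevalence generative effects.
#' @return an \code{"experiment_result"} data frame with columns zero_frac,
#'   maf, sev_raw, sev_int (signed explained variance), p_raw, p_int.
#' @export
run_sparsity_experiment <- function(model_id = "a", reps = 20000, n = 10000,
                                    n_cases = 200, seed = NULL,
                                    zero_range = c(0, 0.95),
                                    maf_range = c(0.05, 0.95),
                                    beta = -0.3, gamma = -0.3,
                                    omegaB = -0.5, omegaG = 0.5,
                                    prevalence = 0.3) {
  seeds <- replicate_seeds(seed, reps)
  rows <- vector("list", reps)
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    maf <- stats::runif(1, maf_range[1], maf_range[2])
    zf <- stats::runif(1, zero_range[1], zero_range[2])
    rep_i <- sparsity_replicate(model_id, n, n_cases, maf, zf,
                                beta, gamma, omegaB, omegaG, prevalence)
    if (is.null(rep_i) || sum(rep_i$d) < n_cases) next
    idx <- sample(which(rep_i$d == 1), n_cases)
    g <- rep_i$g[idx]; b <- rep_i$b[idx]
    if (stats::var(g) == 0) next
    raw_ok <- stats::var(b) > 0
    bint <- if (raw_ok && length(unique(b)) > 1) rank_int(b) else NULL
    rows[[i]] <- data.frame(
      model_id = model_id, rep = i, zero_frac = zf, maf = maf,
      sev_raw = if (raw_ok) signed_r2(b, g) else 0,
      sev_int = if (!is.null(bint)) signed_r2(bint, g) else 0,
      p_raw = if (raw_ok) simple_p(b, g) else NA_real_,
      p_int = if (!is.null(bint)) simple_p(bint, g) else NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  structure(res, class = c("experiment_result", "data.frame"),
            experiment = "sparsity", n = n, n_cases = n_cases, seed = seed)
}

#' Subtype-heterogeneity experiment
#'
#' Two disease labels are generated per replicate: one (CD) from the causal
#' model, one (UC) independent of everything; their union is the composite
#' diagnosis (IBD).  The genotype-bacterium association (after rank
#' transformation) is then tested among sampled IBD cases and within the
#' CD-only and UC-only strata, emulating effect heterogeneity treated as
#' misclassification.
#'
#' @param model_id generative model for the CD component.
#' @param reps number of replicates.
#' @param n population size per replicate.
#' @param n_cases IBD cases sampled per replicate.
#' @param seed master seed.
#' @param maf_range allele-frequency range, default [0.05, 0.2].
#' @param zero_range zero-fraction range, default [0, 0.8].
#' @param beta,gamma,omegaB,omegaG generative effects (magnitudes chosen to
#'   match reported genotype and bacterium effects; \code{gamma} is the
#'   per-case log-fold change of the bacterial mean under reverse
#'   causation).
#' @param prev_cd,prev_uc subtype prevalences.
#' @return an \code{"experiment_result"} data frame with per-replicate
#'   estimates and p-values in the IBD, CD and UC strata.
#' @export
run_heterogeneity_experiment <- function(model_id = "a", reps = 10000,
                                         n = 30000, n_cases = 200,
                                         seed = NULL,
                                         maf_range = c(0.05, 0.2),
                                         zero_range = c(0, 0.8),
                                         beta = -0.3, gamma = -0.4,
                                         omegaB = -0.4, omegaG = 0.4,
                                         prev_cd = 0.007, prev_uc = 0.007) {
  seeds <- replicate_seeds(seed, reps)
  rows <- vector("list", reps)
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    maf <- stats::runif(1, maf_range[1], maf_range[2])
    zf <- stats::runif(1, zero_range[1], zero_range[2])
    rep_i <- sparsity_replicate(model_id, n, n_cases, maf, zf,
                                beta, gamma, omegaB, omegaG, prev_cd)
    if (is.null(rep_i)) next
    uc <- stats::rbinom(n, 1, prev_uc)          # independent subtype
    ibd <- as.integer(rep_i$d == 1 | uc == 1)   # union; CD label wins ties
    is_cd <- rep_i$d == 1
    if (sum(ibd) < n_cases) next
    idx <- sample(which(ibd == 1), n_cases)
    g <- rep_i$g[idx]; b <- rep_i$b[idx]
    if (length(unique(b)) < 2 || stats::var(g) == 0) next
    y <- rank_int(b)
    strata <- list(IBD = rep(TRUE, n_cases),
                   CD = is_cd[idx], UC = !is_cd[idx])
    vals <- lapply(strata, function(s) {
      if (sum(s) < 10 || stats::var(g[s]) == 0 || stats::var(y[s]) == 0)
        return(c(NA_real_, NA_real_))
      c(ols_slope(y[s], g[s]), simple_p(y[s], g[s]))
    })
    rows[[i]] <- data.frame(
      model_id = model_id, rep = i, zero_frac = zf, maf = maf,
      beta_IBD = vals$IBD[1], p_IBD = vals$IBD[2],
      beta_CD = vals$CD[1], p_CD = vals$CD[2],
      beta_UC = vals$UC[1], p_UC = vals$UC[2],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  structure(res, class = c("experiment_result", "data.frame"),
            experiment = "heterogeneity", n = n, n_cases = n_cases,
            seed = seed)
}

#' Severity experiment: an intermediate variable between the model and diagnosis
#'
#' Replaces the binary status in the generative model with a severity score
#' drawn from Binomial(5, p) where p follows the model's logistic; diagnosis
#' is severity >= 1.  The case-only genotype-bacterium correlation is then
#' computed with and without adjusting the bacterial level for severity.
#' Under reverse causation the case-only correlation persists (severity
#' still varies within cases) but is cancelled by the adjustment.
#'
#' @param model_id generative model.
#' @param reps replicates.
#' @param n population size per replicate.
#' @param seed master seed.
#' @param beta,gamma,omegaB,omegaG,prevalence generative parameters;
#'   \code{prevalence} is the target P(severity >= 1).
#' @return an \code{"experiment_result"} data frame with per-replicate
#'   case-only correlations and p-values, unadjusted and severity-adjusted.
#' @export
run_severity_experiment <- function(model_id = "d", reps = 10, n = 100000,
                                    seed = NULL,
                                    beta = -0.3, gamma = -0.3,
                                    omegaB = -0.5, omegaG = 0.5,
                                    prevalence = 0.3) {
  seeds <- replicate_seeds(seed, reps)
  rows <- vector("list", reps)
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    g <- stats::rbinom(n, 2, 0.2)
    G <- standardize_vec(g, "g")
    if (model_id == "d") {
      ## severity trials driven by the genotype; bacterium follows severity
      w0 <- stats::uniroot(function(w)
        mean(1 - (1 - stats::plogis(w + omegaG * G))^5) - prevalence,
        c(-40, 40), extendInt = "yes", tol = 1e-9)$root
      sev <- stats::rbinom(n, 5, stats::plogis(w0 + omegaG * G))
      S <- standardize_vec(sev, "severity")
      b <- gamma * S + stats::rnorm(n)
    } else {
      b <- if (model_id %in% c("a", "b")) beta * G + stats::rnorm(n)
           else stats::rnorm(n)
      eta <- switch(model_id,
                    a = omegaB * b,
                    b = omegaG * G,
                    c = omegaB * b + omegaG * G)
      w0 <- stats::uniroot(function(w)
        mean(1 - (1 - stats::plogis(w + eta))^5) - prevalence,
        c(-40, 40), extendInt = "yes", tol = 1e-9)$root
      sev <- stats::rbinom(n, 5, stats::plogis(w0 + eta))
    }
    cases <- sev >= 1
    gc_ <- g[cases]; bc_ <- b[cases]; sc_ <- sev[cases]
    badj <- stats::resid(stats::lm(bc_ ~ sc_))
    rows[[i]] <- data.frame(
      model_id = model_id, rep = i, n_cases = sum(cases),
      cor_unadj = stats::cor(bc_, gc_), p_unadj = simple_p(bc_, gc_),
      cor_adj = stats::cor(badj, gc_), p_adj = simple_p(badj, gc_),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  structure(res, class = c("experiment_result", "data.frame"),
            experiment = "severity", n = n, seed = seed)
}

#' Panel experiment: paired genotype and disease effect estimates across taxa
#'
#' Simulates a panel of taxa sharing one risk variant.  Per taxon, the
#' genotype effect is estimated among cases only and the taxon-disease
#' effect by case-control logistic regression; the across-taxa correlation
#' of the two estimate sets is the summary of interest.  Effects are drawn
#' concordantly (bacteria depleted by the risk allele are protective), at
#' magnitudes comparable to replicated cohort estimates.
#'
#' @param model_id generative model shared by the panel's taxa.
#' @param n_taxa taxa per panel (>= 2).
#' @param reps number of panels.
#' @param n_cases,n_controls sizes of the case-only and case-control
#'   analysis samples.
#' @param seed master seed.
#' @param maf allele frequency.
#' @param prevalence disease prevalence.
#' @param effect_range magnitude range of the primary per-taxon effect.
#' @param omegaG genotype log-odds (models b, c, d).
#' @param n_pop population size simulated per taxon; default just large
#'   enough to yield the requested cases and controls.
#' @return an \code{"experiment_result"} data frame with one row per
#'   (panel, taxon): beta_g (case-only genotype effect), beta_B
#'   (case-control disease effect); attribute \code{panel_cor} holds the
#'   per-panel correlations.
#' @export
run_panel_experiment <- function(model_id = "a", n_taxa = 50, reps = 1,
                                 n_cases = 500, n_controls = 500,
                                 seed = NULL, maf = 0.3, prevalence = 0.3,
                                 effect_range = c(0.2, 0.8), omegaG = 0.5,
                                 n_pop = NULL) {
  stopifnot(n_taxa >= 2)
  seeds <- replicate_seeds(seed, reps)
  if (is.null(n_pop))
    n_pop <- ceiling(max(n_cases / (prevalence * 0.8),
                         n_controls / ((1 - prevalence) * 0.8)))
  all_rows <- vector("list", reps)
  panel_cor <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    rows <- vector("list", n_taxa)
    for (t in seq_len(n_taxa)) {
      mag <- stats::runif(1, effect_range[1], effect_range[2])
      spec <- switch(model_id,
        a = causal_model("a", beta = -0.6 * mag + stats::rnorm(1, 0, 0.05),
                         omegaB = -mag, maf = maf, prevalence = prevalence),
        b = causal_model("b", beta = -mag, omegaG = omegaG, maf = maf,
                         prevalence = prevalence),
        c = causal_model("c", omegaB = -mag, omegaG = omegaG, maf = maf,
                         prevalence = prevalence),
        d = causal_model("d", gamma = -mag, omegaG = omegaG, maf = maf,
                         prevalence = prevalence))
      spec$omega0 <- NULL
      pop <- simulate_population_fast(spec, n_pop)
      if (is.null(pop)) next
      case_idx <- which(pop$d == 1)
      ctrl_idx <- which(pop$d == 0)
      if (length(case_idx) < n_cases || length(ctrl_idx) < n_controls) next
      ci <- sample(case_idx, n_cases)
      beta_g <- ols_slope(standardize_vec(pop$b)[ci], pop$g[ci])
      cc <- c(ci, sample(ctrl_idx, n_controls))
      bstd <- standardize_vec(pop$b[cc])
      fit <- suppressWarnings(stats::glm(pop$d[cc] ~ bstd,
                                         family = stats::binomial()))
      rows[[t]] <- data.frame(panel = r, taxon = t,
                              beta_g = beta_g,
                              beta_B = stats::coef(fit)[["bstd"]],
                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    all_rows[[r]] <- df
    panel_cor[r] <- if (is.null(df) || nrow(df) < 3) NA_real_ else
      stats::cor(df$beta_g, df$beta_B)
  }
  res <- do.call(rbind, all_rows)
  structure(res, class = c("experiment_result", "data.frame"),
            experiment = "panel", panel_cor = panel_cor, seed = seed)
}

## simulate_population without the expensive external intercept calibration:
## calibrates on the replicate's own linear predictor
simulate_population_fast <- function(spec, n) {
  g <- stats::rbinom(n, 2, spec$maf)
  if (stats::var(g) == 0) return(NULL)
  G <- standardize_vec(g, "g")
  if (spec$model_id == "d") {
    eta <- spec$omegaG * G
    w0 <- calibrate_on_eta(eta, spec$prevalence)
    d <- stats::rbinom(n, 1, stats::plogis(w0 + eta))
    if (stats::var(d) == 0) return(NULL)
    D <- standardize_vec(d, "d")
    b <- spec$gamma * D + draw_error(n, spec$error_dist)
  } else {
    b <- simulate_bacteria(spec, G = G)
    eta <- spec$omegaB * logistic_scale(spec, b) + spec$omegaG * G
    w0 <- calibrate_on_eta(eta, spec$prevalence)
    d <- stats::rbinom(n, 1, stats::plogis(w0 + eta))
    if (stats::var(d) == 0) return(NULL)
  }
  list(g = g, b = b, d = d)
}

#' Polynomial least-squares approximation of the logistic disease surface
#'
#' Regresses the true generative disease probability on nested polynomial
#' expansions of the standardized bacterial level and genotype: model k
#' contains all monomials \code{B^i G^j} with \code{1 <= i + j <= k + 1}
#' (model0 holds the marginal terms only; model3 reaches power 4 with all
#' interactions).  Fit quality is the squared correlation between fitted and
#' true probabilities; collinear terms are dropped and reported.
#'
#' @param sample a \code{"population_sample"} (carries \code{p_true}).
#' @param max_order highest polynomial order, default 4 (models 0..3).
#' @return an object of class \code{"poly_approx"}: list with per-model
#'   coefficient vectors (\code{lambda}), \code{fit_quality}, and any
#'   dropped terms.
#' @export
fit_polynomial_logit_approx <- function(sample, max_order = 4) {
  stopifnot(inherits(sample, "population_sample"), max_order >= 1)
  B <- sample$B; G <- sample$G; p <- sample$p_true
  terms <- list(); orders <- integer(0)
  for (tot in seq_len(max_order))
    for (i in 0:tot) {
      j <- tot - i
      nm <- paste0(if (i) paste0("B", if (i > 1) i else "") else "",
                   if (j) paste0("G", if (j > 1) j else "") else "")
      terms[[nm]] <- B^i * G^j
      orders[[nm]] <- tot
    }
  X <- do.call(cbind, terms)
  colnames(X) <- names(terms)
  lambda <- list(); fq <- numeric(0); dropped <- list()
  for (k in seq_len(max_order)) {
    keep <- orders <= k
    fit <- stats::lm(p ~ X[, keep, drop = FALSE])
    cf <- stats::coef(fit)
    names(cf) <- sub("^X\\[, keep, drop = FALSE\\]", "", names(cf))
    mname <- paste0("model", k - 1)
    lambda[[mname]] <- cf[!is.na(cf)]
    dropped[[mname]] <- names(cf)[is.na(cf)]
    fq[mname] <- stats::cor(stats::fitted(fit), p)^2
  }
  structure(list(lambda = lambda, fit_quality = fq, dropped = dropped),
            class = "poly_approx")
}

#' @export
print.poly_approx <- function(x, ...) {
  cat("polynomial approximation of the disease probability surface\n")
  for (nm in names(x$fit_quality))
    cat(sprintf("  %s: %d terms, fit quality %.4f\n", nm,
                length(x$lambda[[nm]]) - 1, x$fit_quality[nm]))
  invisible(x)
}
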