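#' Specify a generative causal model linking genotype, bacterium and disease
#'
#' Four parsimonious models relate a biallelic risk variant \code{g}, a
#' bacterial level \code{b} and a binary disease status \code{d}:
#' \describe{
#'   \item{a (mediation)}{\code{B = beta*G + eps}; disease risk is logistic in
#'     \code{B} only (\code{omegaG = 0}).  The variant acts on disease through
#'     the bacterium.}
#'   \item{b (pleiotropy)}{\code{B = beta*G + eps}; disease risk is logistic in
#'     \code{G} only (\code{omegaB = 0}).  The variant acts on bacterium and
#'     disease independently.}
#'   \item{c (independent risk factors)}{\code{B = eps} (\code{beta = 0});
#'     disease risk is logistic in both \code{B} and \code{G}.  Bacterium and
#'     variant are unassociated in the population.}
#'   \item{d (reverse causation)}{disease is logistic in \code{G}; then
#'     \code{b = gamma*D + eps} with \code{D} the standardized status.  The
#'     disease alters the bacterium.}
#' }
#' \code{G} denotes the standardized genotype and \code{eps} a unit-variance
#' error drawn from \code{error_dist}.  Effects \code{beta} and \code{gamma}
#' are therefore on the per-SD scale; \code{omega0}, \code{omegaB},
#' \code{omegaG} are log-odds.  When \code{omega0} is \code{NULL} it is
#' calibrated to \code{prevalence} at simulation time (see
#' \code{\link{calibrate_intercept}}).
#'
#' @param model_id one of \code{"a"}, \code{"b"}, \code{"c"}, \code{"d"}.
#' @param beta effect of standardized genotype on bacterial level (models a, b).
#' @param gamma effect of standardized disease status on bacterial level
#'   (model d).
#' @param omega0 logistic intercept (log-odds); \code{NULL} to calibrate to
#'   \code{prevalence}.
#' @param omegaB,omegaG logistic coefficients of bacterial level and genotype.
#' @param maf allele frequency of the risk allele, strictly inside (0, 1).
#' @param prevalence target disease prevalence, strictly inside (0, 1).
#' @param error_dist distribution of the bacterial error term: one of
#'   \code{"normal"}, \code{"exponential"}, \code{"uniform"},
#'   \code{"negative-binomial"}.  The first three are standardized to mean 0,
#'   variance 1.  The negative-binomial option draws the bacterial level
#'   itself from a NB with a log-link shift in the mean (so the monotone link
#'   washes out under rank transformation) and a dispersion solved to hit
#'   \code{zero_frac}.
#' @param zero_frac target proportion of zero values for the
#'   negative-binomial error distribution, in [0, 0.95].
#' @param nb_mean baseline negative-binomial mean (counts).
#' @return an object of class \code{"causal_model"}.
#' @examples
#' m <- causal_model("c", omegaB = -0.4, omegaG = 0.4, prevalence = 0.3)
#' pop <- simulate_population(m, n = 5000, seed = 1)
#' mean(pop$d)
#' @export
causal_model <- function(model_id = c("a", "b", "c", "d"),
                         beta = 0, gamma = 0,
                         omega0 = NULL, omegaB = 0, omegaG = 0,
                         maf = 0.2, prevalence = 0.3,
                         error_dist = c("normal", "exponential", "uniform",
                                        "negative-binomial"),
                         zero_frac = 0.5, nb_mean = 50) {
  model_id <- match.arg(model_id)
  error_dist <- match.arg(error_dist)
  if (maf <= 0 || maf >= 1)
    stop("'maf' must be strictly inside (0, 1)")
  if (prevalence <= 0 || prevalence >= 1)
    stop("'prevalence' must be strictly inside (0, 1)")
  if (zero_frac < 0 || zero_frac > 0.95)
    stop("'zero_frac' must be in [0, 0.95]")
  ## per-model structural zeros
  switch(model_id,
    a = {
      if (gamma != 0 || omegaG != 0)
        stop("model a forces gamma = 0 and omegaG = 0")
    },
    b = {
      if (gamma != 0 || omegaB != 0)
        stop("model b forces gamma = 0 and omegaB = 0")
    },
    c = {
      if (beta != 0 || gamma != 0)
        stop("model c forces beta = 0 and gamma = 0")
    },
    d = {
      if (beta != 0 || omegaB != 0)
        stop("model d forces beta = 0 and omegaB = 0")
    })
  structure(
    list(model_id = model_id, beta = beta, gamma = gamma,
         omega0 = omega0, omegaB = omegaB, omegaG = omegaG,
         maf = maf, prevalence = prevalence,
         error_dist = error_dist, zero_frac = zero_frac, nb_mean = nb_mean),
    class = "causal_model")
}

#' @export
print.causal_model <- function(x, ...) {
  lab <- c(a = "mediation (g -> B -> d)",
           b = "pleiotropy (B <- g -> d)",
           c = "independent risk factors (B -> d <- g)",
           d = "reverse causation (g -> d -> B)")
  cat("Generative causal model", sQuote(x$model_id), "-", lab[[x$model_id]],
      "\n")
  cat(sprintf("  beta = %g, gamma = %g, omegaB = %g, omegaG = %g\n",
              x$beta, x$gamma, x$omegaB, x$omegaG))
  cat(sprintf("  maf = %g, target prevalence = %g, omega0 = %s\n",
              x$maf, x$prevalence,
              if (is.null(x$omega0)) "(calibrated at simulation)"
              else format(x$omega0)))
  cat(sprintf("  error distribution: %s%s\n", x$error_dist,
              if (x$error_dist == "negative-binomial")
                sprintf(" (zero fraction %g, mean %g)", x$zero_frac, x$nb_mean)
              else ""))
  invisible(x)
}

## standardize to mean 0, variance 1 using the population (divide-by-n)
## convention so that finite-sample moment identities are exact
standardize_vec <- function(x, what = deparse(substitute(x))) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0) stop("cannot standardize constant vector: ", what)
  (x - m) / sqrt(v)
}

## unit-variance, mean-zero error draws
draw_error <- function(n, dist) {
  switch(dist,
    normal      = stats::rnorm(n),
    exponential = stats::rexp(n) - 1,
    uniform     = stats::runif(n, -sqrt(3), sqrt(3)),
    stop("unsupported error distribution: ", dist))
}

## NB dispersion (size) giving P(X = 0) = p0 at mean mu:
## (size/(size+mu))^size = p0.  As size -> Inf, P(0) -> exp(-mu) (Poisson),
## so targets below exp(-mu) are unattainable and are clamped with a warning.
nb_size_for_zero <- function(mu, p0) {
  stopifnot(mu > 0, p0 >= 0, p0 < 1)
  if (p0 <= exp(-mu)) {
    if (p0 > 0)
      warning(sprintf(
        "zero-fraction target %.3g below Poisson floor exp(-mu) = %.3g; clamped",
        p0, exp(-mu)))
    return(Inf)
  }
  f <- function(ls) {
    s <- exp(ls)
    -s * log1p(mu / s) - log(p0)   # log1p avoids cancellation at large size
  }
  exp(stats::uniroot(f, c(-34, 34), tol = 1e-12)$root)
}

## draw NB counts with mean mu (vector allowed) and size; size = Inf -> Poisson
rnbinom_mu <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = size)
}

#' Calibrate the logistic intercept to a target disease prevalence
#'
#' Solves for the intercept \code{omega0} such that the marginal disease
#' probability under the model equals \code{target}.  The marginal expectation
#' is evaluated by Monte Carlo with common random numbers (a fixed internal
#' draw of the linear predictor's stochastic part), which makes the objective
#' smooth and the root deterministic given \code{seed}.
#'
#' @param spec a \code{\link{causal_model}}.
#' @param target target prevalence in (0, 1); defaults to
#'   \code{spec$prevalence}.
#' @param n Monte-Carlo size for the marginal expectation.
#' @param seed integer seed for the internal draw.
#' @return the intercept (log-odds) as a single number.
#' @examples
#' calibrate_intercept(causal_model("c", prevalence = 0.3))  # ~ log(0.3/0.7)
#' @export
calibrate_intercept <- function(spec, target = spec$prevalence,
                                n = 200000, seed = 20260923) {
  stopifnot(inherits(spec, "causal_model"))
  if (target <= 0 || target >= 1) stop("'target' must be in (0, 1)")
  eta <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    g <- stats::rbinom(n, 2, spec$maf)
    G <- standardize_vec(g, "g")
    if (spec$model_id == "d") {
      spec$omegaG * G
    } else {
      b <- simulate_bacteria(spec, G, D = NULL)
      spec$omegaB * logistic_scale(spec, b) + spec$omegaG * G
    }
  })
  f <- function(w0) mean(stats::plogis(w0 + eta)) - target
  r <- stats::uniroot(f, c(-40, 40), tol = 1e-10, extendInt = "yes")
  r$root
}

## bacterial level given standardized G (models a/b/c) or standardized D
## (model d).  For the additive error distributions B = beta*G (+ gamma*D) +
## eps; for the negative binomial the level itself is a count with a log-link
## mean shift exp(beta*G + gamma*D), centered/scaled downstream.
simulate_bacteria <- function(spec, G, D = NULL) {
  n <- length(if (is.null(G)) D else G)
  shift <- 0
  if (!is.null(G)) shift <- shift + spec$beta * G
  if (!is.null(D)) shift <- shift + spec$gamma * D
  if (spec$error_dist == "negative-binomial") {
    size <- nb_size_for_zero(spec$nb_mean, spec$zero_frac)
    counts <- rnbinom_mu(n, spec$nb_mean * exp(shift), size)
    as.numeric(counts)
  } else {
    shift + draw_error(n, spec$error_dist)
  }
}

## scale on which the bacterial level enters the generative logistic: raw for
## the additive unit-variance errors (B = beta*G + eps is already near-
## standardized), standardized for negative-binomial counts, whose raw scale
## is arbitrary (depth-dependent)
logistic_scale <- function(spec, b) {
  if (spec$error_dist == "negative-binomial") standardize_vec(b, "b") else b
}

#' Simulate a population under a generative causal model
#'
#' Draws genotype \code{g ~ Binomial(2, maf)}, the bacterial level and the
#' disease status in the order the model dictates: for models a/b/c the
#' bacterium is built from the genotype and disease is then drawn from the
#' model's logistic; for model d the disease is drawn first (logistic in
#' \code{G}) and the bacterium is built from the standardized status.
#'
#' @param spec a \code{\link{causal_model}}.
#' @param n number of individuals (>= 2).
#' @param seed optional integer seed.
#' @return an object of class \code{"population_sample"}: a list with raw
#'   vectors \code{g}, \code{b}, \code{d}, the true disease probabilities
#'   \code{p_true}, standardized views \code{G}, \code{B}, \code{D}, the
#'   realized intercept \code{omega0}, \code{n} and the \code{spec}.
#' @examples
#' pop <- simulate_population(causal_model("b", beta = -0.3, omegaG = 0.4),
#'                            n = 2000, seed = 7)
#' coef(lm(pop$B ~ pop$G))[2]  # close to -0.3/sqrt(1.09)
#' @export
simulate_population <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "causal_model"), n >= 2)
  if (!is.null(seed)) set.seed(seed)
  w0 <- spec$omega0
  if (is.null(w0)) w0 <- calibrate_intercept(spec)
  g <- stats::rbinom(n, 2, spec$maf)
  tries <- 0
  while (stats::var(g) == 0 && tries < 10) {   # degenerate at tiny n
    g <- stats::rbinom(n, 2, spec$maf); tries <- tries + 1
  }
  if (stats::var(g) == 0)
    stop("degenerate genotype draw: all individuals identical")
  G <- standardize_vec(g, "g")
  if (spec$model_id == "d") {
    p <- stats::plogis(w0 + spec$omegaG * G)
    d <- stats::rbinom(n, 1, p)
    if (stats::var(d) == 0) stop("degenerate disease draw")
    D <- standardize_vec(d, "d")
    b <- simulate_bacteria(spec, G = NULL, D = D)
  } else {
    b <- simulate_bacteria(spec, G = G)
    p <- stats::plogis(w0 + spec$omegaB * logistic_scale(spec, b) +
                         spec$omegaG * G)
    d <- stats::rbinom(n, 1, p)
    if (stats::var(d) == 0) stop("degenerate disease draw")
    D <- standardize_vec(d, "d")
  }
  structure(
    list(g = g, b = b, d = d, p_true = p,
         G = G, B = standardize_vec(b, "b"), D = D,
         omega0 = w0, n = n, spec = spec),
    class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("population_sample: n = %d, model %s, prevalence %.3f\n",
              x$n, x$spec$model_id, mean(x$d)))
  invisible(x)
}

#' Simulate method for causal models
#'
#' Thin wrapper around \code{\link{simulate_population}} following the
#' \code{stats::simulate} convention.
#'
#' @param object a \code{\link{causal_model}}.
#' @param nsim number of populations to draw.
#' @param seed optional seed.
#' @param n individuals per population.
#' @param ... unused.
#' @return a list of \code{nsim} \code{population_sample} objects.
#' @export
simulate.causal_model <- function(object, nsim = 1, seed = NULL, n = 10000,
                                  ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, nsim)
  lapply(seeds, function(s) simulate_population(object, n, seed = s))
}

#' Restrict a simulated population to ascertained cases
#'
#' Uniformly subsamples \code{n_cases} individuals with \code{d = 1} (all
#' cases when \code{n_cases} is \code{NULL}) and recomputes the standardized
#' views within the subsample, mirroring a case-only study design.
#'
#' @param sample a \code{population_sample}.
#' @param n_cases number of cases to keep; \code{NULL} keeps all.
#' @param seed optional seed for the subsample.
#' @return a \code{population_sample} containing cases only.  The element
#'   \code{D} is absent (status is constant within cases).
#' @export
ascertain <- function(sample, n_cases = NULL, seed = NULL) {
  stopifnot(inherits(sample, "population_sample"))
  idx <- which(sample$d == 1)
  if (!is.null(n_cases)) {
    if (length(idx) < n_cases)
      stop(sprintf("requested %d cases but only %d available",
                   n_cases, length(idx)))
    if (!is.null(seed)) set.seed(seed)
    idx <- sample(idx, n_cases)
  }
  out <- sample
  out$g <- sample$g[idx]; out$b <- sample$b[idx]; out$d <- sample$d[idx]
  out$p_true <- sample$p_true[idx]
  out$G <- standardize_vec(out$g, "g")
  out$B <- standardize_vec(out$b, "b")
  out$D <- NULL
  out$n <- length(idx)
  out
}

## OLS slope of y on x, population-variance convention (exact moment algebra)
ols_slope <- function(y, x) {
  mx <- mean(x); my <- mean(y)
  mean((x - mx) * (y - my)) / mean((x - mx)^2)
}
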