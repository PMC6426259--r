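#' Standardize raw vectors and compute the mixed moments of the bias formula
#'
#' Standardizes \code{b}, \code{g}, \code{d} to mean 0 and variance 1 using
#' the population-variance (divide-by-n) convention, and computes the sample
#' moments that enter the exact selection-bias formula:
#' E[BG], E[BD], E[GD], E[BGD], E[G^2 D], together with the prevalence
#' \code{mu_d} and \code{sigma_d = sqrt(mu_d (1 - mu_d))}.
#'
#' The population-variance convention matters: with it, the conditional-moment
#' identity E[X | d = 1] = E[X] + (sigma_d/mu_d) E[XD] is an algebraic
#' identity on any finite sample, not an approximation.
#'
#' @param b,g,d equal-length numeric vectors; \code{d} must be binary 0/1 with
#'   both classes present.
#' @return a list with standardized \code{B}, \code{G}, \code{D} and a
#'   \code{moments} element of class \code{"moment_set"}.
#' @examples
#' pop <- simulate_population(causal_model("c", omegaB = -0.4, omegaG = 0.4),
#'                            n = 5000, seed = 1)
#' s <- standardize(pop$b, pop$g, pop$d)
#' s$moments
#' @export
standardize <- function(b, g, d) {
  n <- length(d)
  if (length(b) != n || length(g) != n)
    stop("b, g, d must have equal lengths")
  if (!all(d %in% c(0, 1))) stop("d must be binary 0/1")
  B <- standardize_vec(b, "b")
  G <- standardize_vec(g, "g")
  D <- standardize_vec(d, "d")
  mu_d <- mean(d)
  moments <- structure(
    list(E_BG = mean(B * G), E_BD = mean(B * D), E_GD = mean(G * D),
         E_BGD = mean(B * G * D), E_G2D = mean(G * G * D),
         mu_d = mu_d, sigma_d = sqrt(mu_d * (1 - mu_d)), n = n),
    class = "moment_set")
  list(B = B, G = G, D = D, moments = moments)
}

#' @export
print.moment_set <- function(x, ...) {
  cat("moment_set (standardized variables, population-variance convention)\n")
  cat(sprintf("  E[BG] = %.6f   E[BD] = %.6f   E[GD] = %.6f\n",
              x$E_BG, x$E_BD, x$E_GD))
  cat(sprintf("  E[BGD] = %.6f  E[G2D] = %.6f\n", x$E_BGD, x$E_G2D))
  cat(sprintf("  mu_d = %.4f (n = %d)\n", x$mu_d, x$n))
  invisible(x)
}

#' Exact moment-based estimate of the case-only selection bias
#'
#' Computes Delta, the difference between the case-only and whole-population
#' regression coefficients of the standardized bacterial level on the
#' standardized genotype, from the mixed moments alone:
#' \deqn{\sigma^2_{G|d=1} = 1 + E[G^2 D]\,r - (E[GD]\,r)^2, \quad
#'       r = \sigma_d/\mu_d}
#' \deqn{\Delta = \frac{E[BGD]\,r - E[GD]E[BD]\,r^2}{\sigma^2_{G|d=1}}
#'       + E[BG]\,\frac{1 - \sigma^2_{G|d=1}}{\sigma^2_{G|d=1}}}
#' The derivation uses only the expansion of conditional moments of a binary
#' status, so it holds for any generating model and data distribution.  When
#' the moments are computed on a finite sample, \code{delta} equals the
#' difference between the two ordinary-least-squares coefficients computed on
#' that same sample up to floating-point error.
#'
#' @param moments a \code{"moment_set"} from \code{\link{standardize}}.
#' @return an object of class \code{"bias_estimate"} with elements
#'   \code{delta}, \code{var_G_case} (\eqn{\sigma^2_{G|d=1}}),
#'   \code{beta} (population coefficient, = E[BG]) and \code{beta_case}.
#' @examples
#' pop <- simulate_population(causal_model("c", omegaB = -0.4, omegaG = 0.4,
#'                                         prevalence = 0.3),
#'                            n = 20000, seed = 2)
#' delta_exact(standardize(pop$b, pop$g, pop$d)$moments)
#' @export
delta_exact <- function(moments) {
  stopifnot(inherits(moments, "moment_set"))
  r <- moments$sigma_d / moments$mu_d
  var_G_case <- 1 + moments$E_G2D * r - (moments$E_GD * r)^2
  if (var_G_case <= 0)
    stop("non-positive conditional variance of G among cases")
  delta <- (moments$E_BGD * r - moments$E_GD * moments$E_BD * r^2) /
    var_G_case + moments$E_BG * (1 - var_G_case) / var_G_case
  structure(
    list(delta = delta, var_G_case = var_G_case,
         beta = moments$E_BG, beta_case = moments$E_BG + delta,
         method = "exact moment formula"),
    class = "bias_estimate")
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat("Case-only selection bias (", x$method, ")\n", sep = "")
  cat(sprintf("  beta (population)  = % .6f\n", x$beta))
  cat(sprintf("  beta (cases only)  = % .6f\n", x$beta_case))
  cat(sprintf("  Delta              = % .6f\n", x$delta))
  if (!is.null(x$var_G_case))
    cat(sprintf("  var(G | d = 1)     = % .6f\n", x$var_G_case))
  if (!is.null(x$regime))
    cat("  validity: ", x$regime, "\n", sep = "")
  invisible(x)
}

#' @export
coef.bias_estimate <- function(object, ...) {
  c(beta = object$beta, beta_case = object$beta_case, delta = object$delta)
}

#' Closed-form approximation of the selection bias under each causal model
#'
#' Small-effect, common-disease approximations of Delta for the four
#' generative models, obtained from a second-order expansion of the logistic
#' around the prevalence \eqn{\mu_d} inside the exact moment formula
#' (\code{\link{delta_exact}}) under near-normal \code{B} and \code{G}:
#' \describe{
#'   \item{a}{\eqn{\Delta_a \approx -\tilde\beta(1-\tilde\beta^2)
#'     \tilde\omega_B^2\,\mu_d(1-\mu_d) / \sigma^2_{G|d=1}}}
#'   \item{b}{\eqn{\Delta_b \approx 0}}
#'   \item{c}{\eqn{\Delta_c \approx -\omega_G\tilde\omega_B\,\mu_d(1-\mu_d) /
#'     \sigma^2_{G|d=1}}}
#'   \item{d}{\eqn{\Delta_d \approx -\tilde\gamma\omega_G\sigma_d}}
#' }
#' Tildes denote the standardized-bacterium scale
#' (\eqn{\tilde\beta = \beta/\sqrt{1+\beta^2}},
#' \eqn{\tilde\omega_B = \omega_B\,\mathrm{sd}(b)}), and
#' \eqn{\sigma^2_{G|d=1}} defaults to 1 (its small-effect value) unless a
#' \code{moment_set} is supplied.  Outside the small-effect, common-disease,
#' near-normal regime only the sign is guaranteed:
#' sign(Delta_a) = -sign(beta), Delta_b = 0,
#' sign(Delta_c) = -sign(omegaG * omegaB), sign(Delta_d) = -sign(gamma * omegaG).
#'
#' @param spec a \code{\link{causal_model}}.
#' @param moments optional \code{"moment_set"} supplying
#'   \eqn{\sigma^2_{G|d=1}} and \eqn{\mu_d}; by default the model's target
#'   prevalence and \eqn{\sigma^2_{G|d=1} = 1} are used.
#' @return a \code{"bias_estimate"} whose \code{delta} is the approximation;
#'   \code{sign} gives the guaranteed sign as -1, 0 or +1.
#' @export
delta_approx <- function(spec, moments = NULL) {
  stopifnot(inherits(spec, "causal_model"))
  mu_d <- if (is.null(moments)) spec$prevalence else moments$mu_d
  var_G_case <- if (is.null(moments)) 1 else {
    r <- moments$sigma_d / moments$mu_d
    1 + moments$E_G2D * r - (moments$E_GD * r)^2
  }
  sigma_d <- sqrt(mu_d * (1 - mu_d))
  bs <- spec$beta / sqrt(1 + spec$beta^2)   # standardized-B scale
  gs <- spec$gamma / sqrt(1 + spec$gamma^2)
  wBs <- spec$omegaB * sqrt(1 + spec$beta^2)  # per SD of b
  delta <- switch(spec$model_id,
    a = -bs * (1 - bs^2) * wBs^2 * mu_d * (1 - mu_d) / var_G_case,
    b = 0,
    c = -spec$omegaG * wBs * mu_d * (1 - mu_d) / var_G_case,
    d = -gs * spec$omegaG * sigma_d)
  sgn <- switch(spec$model_id,
    a = -sign(spec$beta),
    b = 0,
    c = -sign(spec$omegaG * spec$omegaB),
    d = -sign(spec$gamma * spec$omegaG))
  structure(
    list(delta = delta, var_G_case = NULL, beta = NA_real_,
         beta_case = NA_real_, sign = sgn,
         method = sprintf("closed-form approximation, model %s",
                          spec$model_id),
         regime = "common disease, small effects, near-normal B and G; outside this regime only the sign is guaranteed"),
    class = "bias_estimate")
}

#' Expected association sign pattern under each causal model
#'
#' Tabulates, for the chosen model and effect signs, the expected sign of the
#' population genotype-bacterium association, of the case-only association,
#' of the selection bias Delta, and of the across-taxa correlation between
#' case-only genotype effects and case-control disease effects
#' (\code{panel_corr}).  Entries are \code{"-"}, \code{"0"}, \code{"+"};
#' \code{case_only} may also be \code{"same-as-population"} (model b, where
#' ascertainment leaves the coefficient unchanged).
#'
#' @param model_id one of \code{"a"}, \code{"b"}, \code{"c"}, \code{"d"}.
#' @param beta_sign sign of the genotype-to-bacterium effect (models a, b).
#' @param gamma_sign sign of the disease-to-bacterium effect (model d).
#' @param omegaB_sign,omegaG_sign signs of the logistic coefficients.
#' @return an object of class \code{"sign_pattern"}: a named character vector
#'   with entries \code{population}, \code{case_only}, \code{delta},
#'   \code{panel_corr}.
#' @examples
#' predict_sign_pattern("c", omegaB_sign = -1, omegaG_sign = 1)
#' @export
predict_sign_pattern <- function(model_id = c("a", "b", "c", "d"),
                                 beta_sign = -1, gamma_sign = -1,
                                 omegaB_sign = -1, omegaG_sign = 1) {
  model_id <- match.arg(model_id)
  as_chr <- function(s) if (s > 0) "+" else if (s < 0) "-" else "0"
  chk <- function(ok, msg) if (!ok) stop("contradictory sign input: ", msg)
  out <- switch(model_id,
    a = {
      chk(beta_sign != 0, "model a needs a non-zero beta")
      c(population = as_chr(beta_sign),
        case_only  = as_chr(beta_sign),          # attenuated, same sign
        delta      = as_chr(-beta_sign),
        panel_corr = "+")                        # concordant effect panels
    },
    b = c(population = as_chr(beta_sign),
          case_only  = "same-as-population",
          delta      = "0",
          panel_corr = "+"),
    c = {
      chk(omegaB_sign != 0 && omegaG_sign != 0,
          "model c needs non-zero omegaB and omegaG")
      c(population = "0",
        case_only  = as_chr(-omegaG_sign * omegaB_sign),
        delta      = as_chr(-omegaG_sign * omegaB_sign),
        panel_corr = as_chr(-omegaG_sign))
    },
    d = {
      chk(gamma_sign != 0 && omegaG_sign != 0,
          "model d needs non-zero gamma and omegaG")
      c(population = as_chr(gamma_sign * omegaG_sign),
        case_only  = "0",
        delta      = as_chr(-gamma_sign * omegaG_sign),
        panel_corr = "0")
    })
  structure(out, model_id = model_id, class = "sign_pattern")
}

#' @export
print.sign_pattern <- function(x, ...) {
  cat("Expected sign pattern, model", attr(x, "model_id"), "\n")
  for (nm in names(x)) cat(sprintf("  %-11s %s\n", nm, x[[nm]]))
  invisible(x)
}
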