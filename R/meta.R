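#' Recover a standard error from a printed effect and two-sided p-value
#'
#' Published association tables often print only the coefficient and its
#' p-value; the standard error is recovered as
#' \code{SE = |beta| / qnorm(1 - p/2)}, inverting the two-sided normal test.
#'
#' @param beta effect estimate (non-zero).
#' @param p two-sided p-value, strictly inside (0, 1).
#' @return the standard error.
#' @examples
#' se_from_beta_p(-0.56, 4.0e-4)   # ~0.158
#' @export
se_from_beta_p <- function(beta, p) {
  if (any(p <= 0 | p >= 1)) stop("'p' must be strictly inside (0, 1)")
  if (any(beta == 0)) stop("'beta' must be non-zero")
  ## upper-tail form keeps precision for very small p
  abs(beta) / stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools effect estimates with weights proportional to their inverse
#' squared standard errors: pooled beta is the weighted mean, pooled SE is
#' \code{1/sqrt(sum(1/SE^2))}, and the two-sided p-value uses the normal
#' reference.
#'
#' @param beta vector of study effect estimates.
#' @param se vector of study standard errors (> 0).
#' @return an object of class \code{"meta_result"}: list with \code{beta},
#'   \code{se}, \code{z}, \code{p}, and normalized per-study \code{weights}.
#' @examples
#' inverse_variance_meta(c(-0.5, -0.5), c(0.1, 0.1))  # beta -0.5, se ~0.0707
#' @export
inverse_variance_meta <- function(beta, se) {
  stopifnot(length(beta) == length(se), all(se > 0))
  if (length(beta) < 1) stop("no studies to pool")
  if (length(beta) == 1)
    warning("single study: pooled estimate is a pass-through")
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  pse <- 1 / sqrt(sum(w))
  z <- pooled / pse
  structure(
    list(beta = pooled, se = pse, z = z,
         p = 2 * stats::pnorm(-abs(z)), weights = w / sum(w),
         k = length(beta)),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("fixed-effect meta-analysis of %d studies\n", x$k))
  cat(sprintf("  pooled beta = % .4f (SE %.4f), z = % .3f, p = %.3g\n",
              x$beta, x$se, x$z, x$p))
  invisible(x)
}

#' Directional enrichment of effect signs
#'
#' One-sided exact binomial test of whether more coefficients than expected
#' under a fair coin point in the stated direction.  Zero coefficients are
#' counted to neither side (the total is reduced).  A normal approximation
#' (with or without continuity correction) is available for comparison with
#' published values computed that way.
#'
#' @param beta vector of effect estimates.
#' @param direction \code{"negative"} (default) or \code{"positive"}.
#' @param method \code{"exact"} (default), \code{"normal"} or
#'   \code{"normal-cc"}.
#' @return an object of class \code{"enrichment_result"}: list with
#'   \code{n_direction}, \code{n_total}, \code{direction}, \code{p}.
#' @examples
#' sign_enrichment(c(rep(-1, 101), rep(1, 67)))$p   # ~ 0.005
#' @export
sign_enrichment <- function(beta, direction = c("negative", "positive"),
                            method = c("exact", "normal", "normal-cc")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  beta <- beta[!is.na(beta)]
  n_total <- sum(beta != 0)
  if (n_total == 0) stop("no non-zero coefficients")
  k <- if (direction == "negative") sum(beta < 0) else sum(beta > 0)
  p <- switch(method,
    exact = stats::binom.test(k, n_total, 0.5,
                              alternative = "greater")$p.value,
    `normal` = stats::pnorm((k - n_total / 2) / sqrt(n_total / 4),
                            lower.tail = FALSE),
    `normal-cc` = stats::pnorm((k - 0.5 - n_total / 2) / sqrt(n_total / 4),
                               lower.tail = FALSE))
  structure(list(n_direction = k, n_total = n_total, direction = direction,
                 method = method, p = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("sign enrichment: %d of %d %s (%.1f%%), one-sided p = %.3g (%s)\n",
              x$n_direction, x$n_total, x$direction,
              100 * x$n_direction / x$n_total, x$p, x$method))
  invisible(x)
}

#' Concordance of per-taxon genotype and disease effects
#'
#' Sums, for each taxon, the genotype effect estimates across genes, pairs
#' the sums with the taxon's case-control disease effect, and measures their
#' Pearson correlation.  Significance comes from a taxon-label permutation
#' test.  Binned summaries of the summed genotype effects are returned for
#' display.
#'
#' @param beta_g matrix of genotype effects, taxa x genes (or a vector for a
#'   single gene).
#' @param beta_b vector of disease effects aligned to the same taxa.
#' @param n_perm number of permutations, default 10000.
#' @param n_bins number of display bins, default 6.
#' @param seed optional seed for the permutation draw.
#' @return an object of class \code{"concordance_result"}: list with
#'   \code{summed_beta_g}, \code{beta_b}, \code{correlation}, \code{p}
#'   (permutation, two-sided), and \code{bins} (per-bin mean disease
#'   effect).
#' @export
concordance <- function(beta_g, beta_b, n_perm = 10000, n_bins = 6,
                        seed = NULL) {
  bg <- if (is.matrix(beta_g)) rowSums(beta_g) else as.numeric(beta_g)
  if (length(bg) != length(beta_b)) stop("taxa not aligned across inputs")
  keep <- is.finite(bg) & is.finite(beta_b)
  bg <- bg[keep]; bb <- beta_b[keep]
  if (length(bg) < 3) stop("need at least 3 paired taxa")
  r <- stats::cor(bg, bb)
  if (!is.null(seed)) set.seed(seed)
  null_r <- replicate(n_perm, stats::cor(bg, sample(bb)))
  p <- (1 + sum(abs(null_r) >= abs(r))) / (n_perm + 1)
  breaks <- stats::quantile(bg, seq(0, 1, length.out = n_bins + 1))
  breaks[1] <- -Inf; breaks[n_bins + 1] <- Inf
  bin <- cut(bg, breaks, labels = FALSE)
  bins <- data.frame(bin = seq_len(n_bins),
                     mid = tapply(bg, bin, mean)[as.character(seq_len(n_bins))],
                     mean_beta_b = tapply(bb, bin, mean)[as.character(seq_len(n_bins))],
                     n = as.vector(table(factor(bin, seq_len(n_bins)))))
  structure(list(summed_beta_g = bg, beta_b = bb, correlation = r, p = p,
                 n_perm = n_perm, bins = bins),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("effect concordance over %d taxa: r = % .3f, permutation p = %.3g\n",
              length(x$beta_b), x$correlation, x$p))
  invisible(x)
}

#' Test a between-strata regression slope against unity
#'
#' Regresses subset-stratum effect estimates on full-sample estimates and
#' tests the slope against 1 with a t-test.  A slope below 1 indicates
#' attenuation of the subset estimates relative to the full sample, the
#' signature of case-only deflation under mediation.
#'
#' @param beta_subset effect estimates in the subset stratum.
#' @param beta_full effect estimates in the full sample, same taxa.
#' @return an object of class \code{"slope_test"}: list with \code{slope},
#'   \code{se}, \code{t} (against 1), \code{df}, \code{p} (two-sided).
#' @examples
#' x <- rnorm(50); slope_vs_unity(0.5 * x + rnorm(50, 0, 0.01), x)
#' @export
slope_vs_unity <- function(beta_subset, beta_full) {
  keep <- is.finite(beta_subset) & is.finite(beta_full)
  x <- beta_full[keep]; y <- beta_subset[keep]
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::var(x) == 0) stop("full-sample estimates are constant")
  fit <- summary(stats::lm(y ~ x))
  slope <- fit$coefficients["x", "Estimate"]
  se <- fit$coefficients["x", "Std. Error"]
  df <- fit$df[2]
  if (se < 1e-12) {           # exact fit: the test degenerates
    tt <- if (abs(slope - 1) < 1e-8) 0 else sign(slope - 1) * Inf
  } else tt <- (slope - 1) / se
  structure(list(slope = slope, se = se, t = tt, df = df,
                 p = 2 * stats::pt(-abs(tt), df)),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("slope vs 1: %.3f (SE %.3f), t(%d) = %.2f, p = %.3g\n",
              x$slope, x$se, x$df, x$t, x$p))
  invisible(x)
}
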