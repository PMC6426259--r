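#' Collect observed association signs into a comparable pattern
#'
#' Reduces the pipeline's outputs to the features the causal models make
#' predictions about: the sign and persistence of the case-only
#' genotype-bacterium association (discovery + replication/pooled), the sign
#' and significance of the across-taxa concordance, and whether the
#' subset-versus-full slope sits below 1.  Missing inputs leave the
#' corresponding slot uninformative.
#'
#' A case-only association is "persistent" when discovery and
#' replication/pooled estimates share a sign and the pooled p-value clears
#' \code{alpha / n_tests}; it is "null" when the pooled |z| < 1.28 and no
#' persistent replicated sign is present.
#'
#' @param discovery optional list(beta =, p =) for the discovery case-only
#'   association.
#' @param replication optional list(beta =, p =) for the replication or
#'   pooled association.
#' @param concordance optional \code{"concordance_result"}.
#' @param slope optional \code{"slope_test"}.
#' @param slope_informative is the slope feature applicable (the genetic
#'   effect is known to concentrate in the subset's subtype)?
#' @param alpha significance level, default 0.05.
#' @param n_tests multiplicity divisor for the persistence threshold.
#' @param conc_null_band half-width of the correlation band called null when
#'   the permutation test is non-significant; correlations outside the band
#'   that miss significance are left uninformative.
#' @return an object of class \code{"observed_signs"}: list with entries
#'   \code{case_only} ("-", "0", "+", or NA), \code{case_only_persistent}
#'   (logical), \code{concordance} ("-", "0", "+", or NA), \code{slope}
#'   ("<1", "=1", ">1", or NA), each with provenance notes.
#' @export
collect_observed <- function(discovery = NULL, replication = NULL,
                             concordance = NULL, slope = NULL,
                             slope_informative = !is.null(slope),
                             alpha = 0.05, n_tests = 1,
                             conc_null_band = 0.15) {
  case_sign <- NA_character_
  persistent <- NA
  if (!is.null(discovery)) {
    zs <- function(x) x$beta / se_from_beta_p(x$beta, max(x$p, 1e-300))
    if (!is.null(replication)) {
      pooled <- inverse_variance_meta(
        c(discovery$beta, replication$beta),
        c(se_from_beta_p(discovery$beta, max(discovery$p, 1e-300)),
          se_from_beta_p(replication$beta, max(replication$p, 1e-300))))
      same_sign <- sign(discovery$beta) == sign(replication$beta)
      persistent <- same_sign && pooled$p < alpha / n_tests
      ## null = weak pooled evidence without a persistent replicated sign;
      ## otherwise the pooled sign is reported
      case_sign <- if (!persistent && abs(pooled$z) < 1.28) "0"
        else if (pooled$beta < 0) "-" else "+"
    } else {
      z <- zs(discovery)
      persistent <- discovery$p < alpha / n_tests
      case_sign <- if (abs(z) < 1.28) "0" else if (discovery$beta < 0) "-" else "+"
    }
  }
  conc_sign <- NA_character_
  if (!is.null(concordance)) {
    conc_sign <- if (concordance$p < alpha) {
      if (concordance$correlation < 0) "-" else "+"
    } else if (abs(concordance$correlation) < conc_null_band) "0"
      else NA_character_   # neither significant nor near zero: ambiguous
  }
  slope_obs <- NA_character_
  if (!is.null(slope) && isTRUE(slope_informative)) {
    slope_obs <- if (slope$p >= alpha) "=1"
      else if (slope$slope < 1) "<1" else ">1"
  }
  structure(
    list(case_only = case_sign,
         case_only_persistent = persistent,
         concordance = conc_sign,
         slope = slope_obs,
         provenance = list(
           case_only = if (is.null(discovery)) "missing" else
             if (is.null(replication)) "discovery only" else
               "discovery + replication pooled",
           concordance = if (is.null(concordance)) "missing" else
             "permutation test on paired effect panels",
           slope = if (is.na(slope_obs)) "missing or uninformative" else
             "subset-vs-full regression slope")),
    class = "observed_signs")
}

#' @export
print.observed_signs <- function(x, ...) {
  cat("observed association pattern\n")
  cat(sprintf("  case-only sign : %s (%s)%s\n",
              ifelse(is.na(x$case_only), "uninformative", x$case_only),
              x$provenance$case_only,
              if (isTRUE(x$case_only_persistent)) ", persistent" else ""))
  cat(sprintf("  concordance    : %s (%s)\n",
              ifelse(is.na(x$concordance), "uninformative", x$concordance),
              x$provenance$concordance))
  cat(sprintf("  slope          : %s (%s)\n",
              ifelse(is.na(x$slope), "uninformative", x$slope),
              x$provenance$slope))
  invisible(x)
}

#' Score the four causal models against an observed sign pattern
#'
#' Compares the observed pattern with each model's predicted pattern
#' (\code{\link{predict_sign_pattern}}) feature by feature.  A model enters
#' the verdict set iff no informative feature contradicts it:
#' \itemize{
#'   \item a persistent negative case-only association is consistent with
#'     mediation (a) and pleiotropy (b) only; a positive case-only
#'     association under a negative population effect pattern points to
#'     independent risk factors (c); a null case-only association fits
#'     reverse causation (d);
#'   \item positive concordance fits a/b, negative fits c, null fits d;
#'   \item a subset-vs-full slope below 1 favors mediation (a) over
#'     pleiotropy (b) when the genetic effect concentrates in the subset's
#'     subtype; it never removes b from the verdict set on its own.
#' }
#'
#' @param observed an \code{"observed_signs"} object.
#' @param beta_sign,gamma_sign,omegaB_sign,omegaG_sign canonical effect
#'   signs used for the per-model predictions (defaults: risk allele
#'   depletes a protective bacterium).
#' @return an object of class \code{"model_fit_report"}: list with
#'   \code{matrix} (models x features, entries consistent / inconsistent /
#'   uninformative), \code{verdict} (models not rejected), \code{favored},
#'   and \code{notes} (narrative flags).
#' @examples
#' obs <- collect_observed(discovery = list(beta = -0.56, p = 4e-4),
#'                         replication = list(beta = -0.30, p = 0.014))
#' score_models(obs)
#' @export
score_models <- function(observed, beta_sign = -1, gamma_sign = -1,
                         omegaB_sign = -1, omegaG_sign = 1) {
  stopifnot(inherits(observed, "observed_signs"))
  models <- c("a", "b", "c", "d")
  feats <- c("case_only", "concordance", "slope")
  if (all(vapply(feats, function(f) is.na(observed[[f]]), logical(1))))
    stop("no informative observed feature")
  M <- matrix("uninformative", length(models), length(feats),
              dimnames = list(models, feats))
  for (m in models) {
    pred <- predict_sign_pattern(m, beta_sign, gamma_sign,
                                 omegaB_sign, omegaG_sign)
    ## case-only sign; a non-null sign that failed the persistence rule is
    ## ambiguous evidence and rejects nothing
    if (!is.na(observed$case_only)) {
      want <- pred[["case_only"]]
      if (want == "same-as-population") want <- pred[["population"]]
      M[m, "case_only"] <-
        if (observed$case_only == want) "consistent"
        else if (observed$case_only != "0" &&
                 !isTRUE(observed$case_only_persistent)) "uninformative"
        else "inconsistent"
    }
    ## concordance sign
    if (!is.na(observed$concordance)) {
      M[m, "concordance"] <-
        if (observed$concordance == pred[["panel_corr"]]) "consistent"
        else "inconsistent"
    }
    ## slope: informative only between a and b; never rejects alone
    if (!is.na(observed$slope)) {
      M[m, "slope"] <- switch(m,
        a = if (observed$slope == "<1") "consistent" else "uninformative",
        b = if (observed$slope == "=1") "consistent" else "uninformative",
        "uninformative")
    }
  }
  verdict <- models[apply(M != "inconsistent", 1, all)]
  favored <- NULL
  if (!is.na(observed$slope) && all(c("a", "b") %in% verdict))
    favored <- if (observed$slope == "<1") "a"
               else if (observed$slope == "=1") "b" else NULL
  notes <- character(0)
  if (identical(observed$case_only, "-") &&
      isTRUE(observed$case_only_persistent) &&
      !"c" %in% verdict)
    notes <- c(notes,
               "selection bias ruled out as sole explanation of the negative case-only association")
  structure(list(matrix = M, verdict = verdict, favored = favored,
                 notes = notes, observed = observed),
            class = "model_fit_report")
}

#' @export
print.model_fit_report <- function(x, ...) {
  cat("causal model fit report\n")
  print(x$matrix, quote = FALSE)
  cat("verdict (models not rejected):",
      if (length(x$verdict)) paste(x$verdict, collapse = ", ") else "none",
      "\n")
  if (!is.null(x$favored)) cat("favored by the slope feature:", x$favored, "\n")
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' @export
summary.model_fit_report <- function(object, ...) {
  cat(sprintf("%d of 4 causal models compatible with the observed pattern\n",
              length(object$verdict)))
  print(object)
  invisible(object)
}
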