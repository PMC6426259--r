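#' Filter taxa by detection prevalence and annotation quality
#'
#' Removes taxa detected (non-zero) in fewer than \code{min_nonzero_frac} of
#' samples, and optionally taxa whose lineage is incomplete at their own rank
#' (poorly annotated).  The boundary is inclusive: a taxon non-zero in
#' exactly the threshold fraction is retained.
#'
#' @param table a \code{"taxon_table"}.
#' @param min_nonzero_frac detection threshold, default 0.20.
#' @param drop_unannotated drop taxa whose name is empty/unknown in their
#'   lineage (only meaningful for tables read from files).
#' @return an object of class \code{"processed_table"}: list with
#'   \code{abundance} (retained taxa x samples), \code{taxonomy} subset, and
#'   \code{dropped} - a data frame ledger (taxon, reason).
#' @examples
#' tt <- sample_abundance_table(build_taxonomy(seed = 1), 50,
#'                              target_zero_fracs = runif(120, 0, 0.9),
#'                              seed = 2)
#' ft <- filter_taxa(tt)
#' nrow(ft$dropped) + nrow(ft$abundance) == nrow(tt$abundance)
#' @export
filter_taxa <- function(table, min_nonzero_frac = 0.20,
                        drop_unannotated = TRUE) {
  stopifnot(inherits(table, "taxon_table"))
  ab <- table$abundance
  if (!nrow(ab)) stop("empty table")
  nz <- rowMeans(ab > 0)
  unann <- if (drop_unannotated && !is.null(table$taxonomy$name))
    grepl("^(unknown|unclassified|)$", table$taxonomy$name[match(rownames(ab), table$taxonomy$id)])
  else rep(FALSE, nrow(ab))
  low <- nz < min_nonzero_frac
  dropped <- data.frame(
    taxon = rownames(ab)[low | unann],
    reason = ifelse(unann[low | unann], "unannotated", "low-prevalence"),
    stringsAsFactors = FALSE)
  keep <- !(low | unann)
  if (!any(keep)) stop("all taxa dropped by the prevalence filter")
  structure(
    list(abundance = ab[keep, , drop = FALSE],
         taxonomy = table$taxonomy[match(rownames(ab)[keep], table$taxonomy$id), ],
         dropped = dropped, min_nonzero_frac = min_nonzero_frac),
    class = "processed_table")
}

#' @export
print.processed_table <- function(x, ...) {
  cat(sprintf("processed_table: %d taxa retained, %d dropped (threshold %g)\n",
              nrow(x$abundance), nrow(x$dropped), x$min_nonzero_frac))
  if (nrow(x$dropped)) print(table(x$dropped$reason))
  invisible(x)
}

#' Rank-based inverse normal transformation
#'
#' Maps values through their mid-ranks to standard-normal quantiles using
#' the Blom offset: \code{qnorm((rank - 3/8) / (n + 1/4))}.  Ties (including
#' the zero mass typical of taxon abundances) share their mid-rank, and the
#' output is exactly invariant to any monotone increasing transformation of
#' the input.
#'
#' @param values numeric vector with at least 3 finite values, not all equal.
#' @param c_offset rank offset, default 3/8 (Blom).
#' @return transformed vector of the same length.
#' @examples
#' rank_int(c(1.2, 5.0, 3.3))   # -0.87, 0.87, 0.00
#' @export
rank_int <- function(values, c_offset = 3 / 8) {
  if (sum(is.finite(values)) < 3)
    stop("need at least 3 finite values")
  if (length(unique(values[is.finite(values)])) < 2)
    stop("constant input cannot be rank-transformed")
  n <- sum(is.finite(values))
  r <- rank(values, na.last = "keep", ties.method = "average")
  stats::qnorm((r - c_offset) / (n + 1 - 2 * c_offset))
}

#' Greedy within-rank covariate selection
#'
#' Stand-in for published covariate-selection approaches for multi-phenotype
#' studies: from candidate taxa of the same rank as the outcome, greedily
#' admits up to \code{max_k} covariates that (i) explain residual outcome
#' variance (nominal p < \code{p_in} given covariates already admitted and
#' the genotype) and (ii) are not themselves associated with the genotype
#' (nominal p > \code{p_geno}), which guards against collider adjustment.
#' Selection is deterministic given the data.
#'
#' @param y outcome vector (transformed taxon).
#' @param candidates matrix of candidate covariates (columns), same rank as
#'   the outcome and excluding it.
#' @param g genotype vector.
#' @param max_k maximum number of covariates, default 5.
#' @param p_in admission threshold for outcome association, default 0.05.
#' @param p_geno exclusion threshold for genotype association, default 0.05.
#' @return character vector of selected column names (possibly empty).
#' @export
select_level_covariates <- function(y, candidates, g, max_k = 5,
                                    p_in = 0.05, p_geno = 0.05) {
  if (is.null(candidates) || NCOL(candidates) == 0) return(character(0))
  candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates)))
    colnames(candidates) <- paste0("C", seq_len(ncol(candidates)))
  ## candidates associated with the genotype are ineligible
  ok <- vapply(seq_len(ncol(candidates)), function(j) {
    f <- summary(stats::lm(candidates[, j] ~ g))
    f$coefficients["g", "Pr(>|t|)"] > p_geno
  }, logical(1))
  pool <- colnames(candidates)[ok]
  chosen <- character(0)
  while (length(chosen) < max_k && length(pool)) {
    ps <- vapply(pool, function(nm) {
      X <- cbind(g, candidates[, c(chosen, nm), drop = FALSE])
      fit <- summary(stats::lm(y ~ X))
      cf <- fit$coefficients
      row <- paste0("X", nm)
      if (!row %in% rownames(cf)) return(1)  # collinear, skip
      cf[row, "Pr(>|t|)"]
    }, numeric(1))
    best <- names(which.min(ps))
    if (ps[best] >= p_in) break
    chosen <- c(chosen, best)
    pool <- setdiff(pool, best)
  }
  chosen
}

## assemble one association-result record
assoc_record <- function(taxon, predictor, stratum, fit_row, n, covariates,
                         note = "") {
  data.frame(taxon = taxon, predictor = predictor, stratum = stratum,
             beta = fit_row[1], se = fit_row[2], p = fit_row[4], n = n,
             covariates = paste(covariates, collapse = ","),
             note = note, stringsAsFactors = FALSE)
}

na_record <- function(taxon, predictor, stratum, note) {
  data.frame(taxon = taxon, predictor = predictor, stratum = stratum,
             beta = NA_real_, se = NA_real_, p = NA_real_, n = NA_integer_,
             covariates = "", note = note, stringsAsFactors = FALSE)
}

#' Linear SNP-taxon association test
#'
#' Ordinary least squares of the (standardized) transformed taxon level on
#' the genotype, adjusting for confounders \code{Z} and selected covariates
#' \code{C}.  The outcome is scaled to unit variance, the genotype is left
#' untransformed, so the coefficient is the change in outcome SD per
#' genotype unit.  Two-sided p-values use the t reference.
#'
#' @param y taxon outcome (transformed).
#' @param g genotype (dosage or carrier coding).
#' @param Z optional confounder data frame/matrix.
#' @param C optional covariate matrix (selected taxa).
#' @param stratum label recorded in the result.
#' @param taxon,predictor identifiers recorded in the result.
#' @return a one-row data frame of class \code{"assoc_result"}: taxon,
#'   predictor, stratum, beta, se, p, n, covariates, note.
#' @export
fit_snp_taxon <- function(y, g, Z = NULL, C = NULL, stratum = "IBD",
                          taxon = "taxon", predictor = "locus") {
  dat <- data.frame(y = as.numeric(y), g = as.numeric(g))
  if (!is.null(Z)) dat <- cbind(dat, as.data.frame(Z))
  if (!is.null(C)) dat <- cbind(dat, as.data.frame(C))
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) < ncol(dat) + 2)
    return(na_record(taxon, predictor, stratum, "insufficient-n"))
  if (stats::var(dat$g) == 0)
    return(na_record(taxon, predictor, stratum, "constant-genotype"))
  dat$y <- dat$y / stats::sd(dat$y)
  fit <- stats::lm(y ~ ., data = dat)
  cf <- summary(fit)$coefficients
  if (!"g" %in% rownames(cf))
    return(na_record(taxon, predictor, stratum, "collinear-design"))
  dropped <- setdiff(names(dat)[-1], rownames(cf))
  out <- assoc_record(taxon, predictor, stratum, cf["g", ],
                      n = nrow(dat),
                      covariates = setdiff(names(dat)[-(1:2)], dropped),
                      note = if (length(dropped))
                        paste("dropped:", paste(dropped, collapse = ","))
                      else "")
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Logistic taxon-disease association test
#'
#' Logistic regression of case/control status on the transformed taxon level
#' plus confounders; the coefficient is the log-odds of disease per SD of
#' taxon level.  Perfect separation is flagged (infinite-coefficient
#' sentinel) rather than returned as a spurious estimate.
#'
#' @param b transformed taxon level.
#' @param status 0/1 disease status (both classes required).
#' @param Z optional confounders.
#' @param taxon identifier recorded in the result.
#' @return a one-row \code{"assoc_result"} data frame (predictor =
#'   \code{"disease"}, stratum = \code{"case-control"}).
#' @export
fit_taxon_disease <- function(b, status, Z = NULL, taxon = "taxon") {
  dat <- data.frame(d = as.integer(status), b = as.numeric(b))
  if (!is.null(Z)) dat <- cbind(dat, as.data.frame(Z))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$d)) < 2)
    stop("both classes must be present in 'status'")
  dat$b <- dat$b / stats::sd(dat$b)
  fit <- suppressWarnings(stats::glm(d ~ ., data = dat, family = stats::binomial()))
  cf <- summary(fit)$coefficients
  sep <- !fit$converged || any(abs(cf[, "Estimate"]) > 15)
  out <- assoc_record(taxon, "disease", "case-control",
                      cf["b", c(1, 2, 3, 4)], n = nrow(dat),
                      covariates = names(dat)[-(1:2)],
                      note = if (sep) "separation" else "")
  if (sep) out$beta <- sign(out$beta) * Inf
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Per-rank Bonferroni candidate flagging
#'
#' Flags results whose p-value clears 0.05 divided by the number of tests
#' performed within the same taxonomic rank, mirroring within-level
#' multiplicity control across a hierarchy of correlated taxa.
#'
#' @param results data frame of association results carrying a \code{rank}
#'   column.
#' @param alpha family-wise level per rank, default 0.05.
#' @return the input with \code{threshold} and logical \code{candidate}
#'   columns added.
#' @export
per_level_bonferroni <- function(results, alpha = 0.05) {
  stopifnot("rank" %in% names(results))
  if (!nrow(results)) {
    results$threshold <- numeric(0); results$candidate <- logical(0)
    return(results)
  }
  ntest <- stats::ave(rep(1, nrow(results)), results$rank, FUN = sum)
  results$threshold <- alpha / ntest
  results$candidate <- !is.na(results$p) & results$p < results$threshold
  results
}

#' Subtype-stratified SNP-taxon associations
#'
#' Re-runs \code{\link{fit_snp_taxon}} within disease strata: all IBD cases,
#' CD, ileal CD, non-ileal CD and UC.  Strata without variant carriers or
#' with fewer than \code{min_n} usable samples produce a missing-result
#' record instead of an estimate.
#'
#' @param y,g,Z,C as in \code{\link{fit_snp_taxon}}, over all cases.
#' @param subtype character vector ("CD"/"UC") per case.
#' @param ileal 0/1 per case (\code{NA} for UC).
#' @param strata strata to run.
#' @param min_n minimal stratum size, default 10.
#' @param taxon,predictor identifiers.
#' @return an \code{"assoc_result"} data frame, one row per stratum.
#' @export
stratified_analysis <- function(y, g, Z = NULL, C = NULL, subtype, ileal,
                                strata = c("IBD", "CD", "CDil", "CDni", "UC"),
                                min_n = 10, taxon = "taxon",
                                predictor = "locus") {
  sel <- list(
    IBD  = rep(TRUE, length(y)),
    CD   = subtype %in% "CD",
    CDil = subtype %in% "CD" & ileal %in% 1,
    CDni = subtype %in% "CD" & ileal %in% 0,
    UC   = subtype %in% "UC")
  out <- lapply(strata, function(s) {
    i <- sel[[s]]
    if (sum(i) < min_n)
      return(na_record(taxon, predictor, s, "stratum-too-small"))
    r <- fit_snp_taxon(y[i], g[i],
                       Z = if (is.null(Z)) NULL else Z[i, , drop = FALSE],
                       C = if (is.null(C)) NULL else C[i, , drop = FALSE],
                       stratum = s, taxon = taxon, predictor = predictor)
    r
  })
  out <- do.call(rbind, out)
  class(out) <- c("assoc_result", "data.frame")
  out
}
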