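#' Default marginal frequencies of host covariates
#'
#' Marginal case-cohort characteristics used by \code{\link{sample_host_data}}:
#' female 57.7\%, Crohn's disease 63.2\% of cases (60\% of CD ileal), flare
#' 46.2\%, smoking 21.4\%, oral 5-ASA 38.5\%, corticosteroids 18.7\%,
#' anti-TNF 49.5\%, thiopurine/methotrexate 38.5\%; age mean 40.6 (SD 12,
#' truncated at 18).
#'
#' @return a named list of frequencies and age parameters.
#' @export
default_cohort_frequencies <- function() {
  list(female = 105 / 182, cd = 115 / 182, ileal_given_cd = 0.6,
       flare = 0.462, smoking = 0.214,
       asa = 0.385, corticosteroids = 0.187, anti_tnf = 0.495,
       thiopurine_mtx = 0.385,
       age_mean = 40.6, age_sd = 12, age_min = 18)
}

#' Default risk-locus panel
#'
#' Four IBD risk loci: three NOD2 variants (low-frequency, combined by
#' default into a carrier code) and one common variant per ATG16L1, CARD9
#' and LRRK2.
#'
#' @return a data frame with columns \code{locus}, \code{variant},
#'   \code{maf}.
#' @export
default_loci <- function() {
  data.frame(
    locus   = c("NOD2", "NOD2", "NOD2", "ATG16L1", "CARD9", "LRRK2"),
    variant = c("rsN1", "rsN2", "rsN3", "rsA1", "rsC1", "rsL1"),
    maf     = c(0.05, 0.02, 0.03, 0.45, 0.40, 0.02),
    stringsAsFactors = FALSE)
}

#' Generate host covariates, disease labels and genotypes
#'
#' Draws a synthetic cohort of IBD cases and healthy controls.  Binary
#' covariates are drawn independently at the requested marginal frequencies;
#' age is normal (truncated below) around its mean.  Disease subtype (CD/UC),
#' ileal involvement and flare are defined only for cases; treatment flags
#' are \code{NA} for controls.  Genotypes are allele-dosage draws
#' (Binomial(2, maf)) per variant; controls carry genotypes only when
#' \code{controls_genotyped} is \code{TRUE}.
#'
#' @param n_cases,n_controls cohort sizes (defaults 182 and 38).
#' @param frequencies marginal frequencies, see
#'   \code{\link{default_cohort_frequencies}}.
#' @param loci variant panel, see \code{\link{default_loci}}.
#' @param controls_genotyped draw genotypes for controls as well.
#' @param seed optional integer seed.
#' @return an object of class \code{"cohort_data"}: a list with
#'   \code{metadata} (data frame, one row per sample) and \code{genotypes}
#'   (samples x variants dosage matrix, \code{NA} rows for ungenotyped
#'   controls).
#' @examples
#' ch <- sample_host_data(50, 10, seed = 1)
#' colMeans(ch$metadata[ch$metadata$status == 1,
#'                      c("smoking", "anti_tnf")], na.rm = TRUE)
#' @export
sample_host_data <- function(n_cases = 182, n_controls = 38,
                             frequencies = default_cohort_frequencies(),
                             loci = default_loci(),
                             controls_genotyped = TRUE, seed = NULL) {
  stopifnot(n_cases >= 1, n_controls >= 0)
  fr <- frequencies
  bad <- vapply(fr[c("female", "cd", "ileal_given_cd", "flare", "smoking",
                     "asa", "corticosteroids", "anti_tnf",
                     "thiopurine_mtx")],
                function(x) x < 0 || x > 1, logical(1))
  if (any(bad)) stop("frequencies must be in [0, 1]: ",
                     paste(names(bad)[bad], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n <- n_cases + n_controls
  status <- rep(c(1L, 0L), c(n_cases, n_controls))
  rb <- function(p, m = n) stats::rbinom(m, 1, p)
  age <- pmax(fr$age_min, stats::rnorm(n, fr$age_mean, fr$age_sd))
  cd <- ifelse(status == 1, rb(fr$cd), NA)
  md <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    status = status,
    subtype = ifelse(status == 0, NA,
                     ifelse(cd == 1, "CD", "UC")),
    ileal = ifelse(status == 1 & cd == 1, rb(fr$ileal_given_cd), NA),
    flare = ifelse(status == 1, rb(fr$flare), NA),
    female = rb(fr$female), age = age, smoking = rb(fr$smoking),
    asa = ifelse(status == 1, rb(fr$asa), NA),
    corticosteroids = ifelse(status == 1, rb(fr$corticosteroids), NA),
    anti_tnf = ifelse(status == 1, rb(fr$anti_tnf), NA),
    thiopurine_mtx = ifelse(status == 1, rb(fr$thiopurine_mtx), NA),
    stringsAsFactors = FALSE)
  geno <- sapply(seq_len(nrow(loci)),
                 function(j) stats::rbinom(n, 2, loci$maf[j]))
  dimnames(geno) <- list(md$sample_id, loci$variant)
  if (!controls_genotyped && n_controls > 0) geno[status == 0, ] <- NA
  structure(list(metadata = md, genotypes = geno, loci = loci),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("cohort_data: %d samples (%d cases, %d controls), %d variants\n",
              nrow(x$metadata), sum(x$metadata$status == 1),
              sum(x$metadata$status == 0), ncol(x$genotypes)))
  invisible(x)
}

#' Combine variant dosages into a per-locus genotype coding
#'
#' \code{"carrier"} codes presence of at least one risk allele across the
#' locus's variants as 0/1; \code{"dosage"} sums the dosages.
#'
#' @param cohort a \code{"cohort_data"}.
#' @param locus locus name to extract (e.g. \code{"NOD2"}).
#' @param coding \code{"carrier"} (default) or \code{"dosage"}.
#' @return named numeric vector over samples (\code{NA} where ungenotyped).
#' @export
locus_genotype <- function(cohort, locus, coding = c("carrier", "dosage")) {
  coding <- match.arg(coding)
  stopifnot(inherits(cohort, "cohort_data"))
  vars <- cohort$loci$variant[cohort$loci$locus == locus]
  if (!length(vars)) stop("unknown locus: ", locus)
  x <- cohort$genotypes[, vars, drop = FALSE]
  s <- rowSums(x)
  if (coding == "carrier") as.numeric(s > 0) else as.numeric(s)
}

#' Embed a causal gene-bacterium-disease structure in a synthetic cohort
#'
#' Re-draws the disease status of every sample from the designated
#' generative model(s) and, for models with a genotype or disease effect on
#' the bacterium, re-draws the assigned taxon's leaf counts with a log-link
#' mean shift, then re-aggregates the hierarchy.  Taxa without an assignment
#' stay independent of disease and genotype.  When several taxa are
#' assigned, their logistic contributions add on the log-odds scale and the
#' intercept is re-calibrated to the first assignment's target prevalence.
#'
#' @param table a \code{"taxon_table"}.
#' @param cohort a \code{"cohort_data"} covering the same samples.
#' @param assignments named list: taxon id -> list(locus =, spec =
#'   \code{\link{causal_model}}); at most one model per taxon.
#' @param seed optional integer seed.
#' @return a list with the updated \code{table} (class \code{taxon_table})
#'   and \code{cohort} whose \code{metadata$status} is the generated disease
#'   status (subtype/flare/treatment columns are re-labelled accordingly).
#' @export
embed_causal_structure <- function(table, cohort, assignments, seed = NULL) {
  stopifnot(inherits(table, "taxon_table"), inherits(cohort, "cohort_data"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort$metadata)
  if (ncol(table$abundance) != n)
    stop("table and cohort sample counts differ")
  if (anyDuplicated(names(assignments)))
    stop("conflicting assignments: a taxon may carry at most one model")
  counts <- attr(table, "leaf_counts")
  eta <- rep(0, n)
  if (length(assignments)) {
    for (taxon in names(assignments)) {
      a <- assignments[[taxon]]
      if (!taxon %in% table$taxonomy$id) stop("unknown taxon: ", taxon)
      if (!a$locus %in% cohort$loci$locus) stop("unknown locus: ", a$locus)
      spec <- a$spec
      G <- standardize_vec(locus_genotype(cohort, a$locus,
                                          coding = a$coding %||% "dosage"),
                           a$locus)
      if (spec$model_id %in% c("a", "b")) {
        counts <- shift_taxon_counts(table, counts, taxon, spec$beta * G)
      }
      b_now <- taxon_value_from_counts(table, counts, taxon)
      eta <- eta + spec$omegaB * if (spec$omegaB != 0)
        standardize_vec(b_now, taxon) else 0
      eta <- eta + spec$omegaG * G
    }
    first <- assignments[[1]]$spec
    w0 <- stats::uniroot(function(w) mean(stats::plogis(w + eta)) -
                           first$prevalence,
                         c(-40, 40), extendInt = "yes", tol = 1e-10)$root
    d <- stats::rbinom(n, 1, stats::plogis(w0 + eta))
    ## reverse-causation assignments act after the disease draw
    if (stats::var(d) > 0) {
      D <- standardize_vec(d, "d")
      for (taxon in names(assignments)) {
        spec <- assignments[[taxon]]$spec
        if (spec$model_id == "d")
          counts <- shift_taxon_counts(table, counts, taxon, spec$gamma * D)
      }
    }
  } else {
    d <- stats::rbinom(n, 1, 0.5)   # disease independent of everything
  }
  new_table <- build_taxon_table(table$taxonomy, counts, table$depth)
  md <- cohort$metadata
  md$status <- d
  md$subtype[d == 0] <- NA
  new_cohort <- cohort
  new_cohort$metadata <- md
  list(table = new_table, cohort = new_cohort)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## value of a taxon recomputed from a leaf-count matrix (sum of its leaf
## descendants incl. pseudo-leaves)
taxon_value_from_counts <- function(table, counts, taxon) {
  ids <- descendant_leaf_rows(table$taxonomy, taxon, rownames(counts))
  colSums(counts[ids, , drop = FALSE])
}

descendant_leaf_rows <- function(tax, taxon, leaf_ids) {
  acc <- character(0)
  stack <- taxon
  while (length(stack)) {
    id <- stack[[1]]; stack <- stack[-1]
    if (id %in% leaf_ids) acc <- c(acc, id)
    ps <- paste0("unassigned@", id)
    if (ps %in% leaf_ids) acc <- c(acc, ps)
    stack <- c(stack, taxonomy_children(tax, id))
  }
  unique(acc)
}

## re-draw the leaf counts beneath `taxon` with a per-sample log-link shift,
## preserving each leaf's baseline mean and dispersion target
shift_taxon_counts <- function(table, counts, taxon, shift) {
  ids <- descendant_leaf_rows(table$taxonomy, taxon, rownames(counts))
  for (id in ids) {
    mu0 <- max(mean(counts[id, ]), 0.5)
    p0 <- mean(counts[id, ] == 0)
    size <- if (p0 <= exp(-mu0) || p0 >= 1) Inf else
      suppressWarnings(nb_size_for_zero(mu0, p0))
    counts[id, ] <- rnbinom_mu(ncol(counts), mu0 * exp(shift), size)
  }
  counts
}
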