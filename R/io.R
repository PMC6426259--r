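#' Write a taxon table and cohort to TSV files
#'
#' Emits three UTF-8 TSVs with deterministic column order and \code{NA} for
#' missing values: \code{abundance.tsv} (taxa as rows with \code{taxon_id},
#' \code{rank}, \code{lineage}, then one column per sample),
#' \code{genotypes.tsv} (samples x variants) and \code{metadata.tsv}
#' (samples x covariates).
#'
#' @param table a \code{"taxon_table"}.
#' @param cohort a \code{"cohort_data"} (optional; skip to write abundance
#'   only).
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort_tsv <- function(table, cohort = NULL, dir = ".") {
  stopifnot(inherits(table, "taxon_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tax <- table$taxonomy
  ab <- table$abundance
  lineages <- vapply(rownames(ab), function(id) taxonomy_lineage(tax, id),
                     character(1))
  ## %.17g keeps doubles bit-exact across a write/read round trip
  ab_chr <- apply(ab, 2, function(x) sprintf("%.17g", x))
  dimnames(ab_chr) <- dimnames(ab)
  df <- data.frame(taxon_id = rownames(ab),
                   rank = tax$rank[match(rownames(ab), tax$id)],
                   lineage = lineages,
                   ab_chr, check.names = FALSE, stringsAsFactors = FALSE)
  paths <- file.path(dir, "abundance.tsv")
  utils::write.table(df, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "cohort_data"))
    gpath <- file.path(dir, "genotypes.tsv")
    gdf <- data.frame(sample_id = rownames(cohort$genotypes),
                      cohort$genotypes, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(gdf, gpath, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    mpath <- file.path(dir, "metadata.tsv")
    md <- cohort$metadata
    num <- vapply(md, is.double, logical(1))
    md[num] <- lapply(md[num], function(x)
      ifelse(is.na(x), NA, sprintf("%.17g", x)))
    utils::write.table(md, mpath, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, gpath, mpath)
  }
  invisible(paths)
}

#' Read a taxon abundance table from TSV
#'
#' Expects columns \code{taxon_id}, \code{rank}, \code{lineage}, then one
#' column per sample.  Validates ids (unique), ranks (known labels) and
#' values (within [0, 1]); malformed rows are reported with their line
#' numbers.
#'
#' @param path TSV path.
#' @return a \code{"taxon_table"} (its taxonomy reconstructed from the
#'   lineage strings; leaf counts unavailable for tables read from disk).
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("taxon_id", "rank", "lineage")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon ids: ",
         paste(unique(df$taxon_id[duplicated(df$taxon_id)]), collapse = ", "))
  bad_rank <- !df$rank %in% TAXONOMIC_RANKS
  if (any(bad_rank))
    stop("unknown rank label(s) at line(s) ",
         paste(which(bad_rank) + 1, collapse = ", "), ": ",
         paste(unique(df$rank[bad_rank]), collapse = ", "))
  samp_cols <- setdiff(names(df), need)
  vals <- as.matrix(df[, samp_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  out_of_range <- which(vals < 0 | vals > 1, arr.ind = TRUE)
  if (nrow(out_of_range))
    stop(sprintf("abundance outside [0, 1] at line %d, column %s (value %g)",
                 out_of_range[1, 1] + 1, samp_cols[out_of_range[1, 2]],
                 vals[out_of_range[1, , drop = FALSE]]))
  rownames(vals) <- df$taxon_id
  tax <- taxonomy_from_lineage(df$taxon_id, df$rank, df$lineage)
  structure(list(abundance = vals, taxonomy = tax, depth = NA_real_),
            class = "taxon_table")
}

## rebuild a taxonomy object from lineage strings
taxonomy_from_lineage <- function(ids, ranks, lineages) {
  parts <- strsplit(lineages, ";", fixed = TRUE)
  name_of <- function(p) sub("^[a-z]__", "", p)
  rank_idx <- match(ranks, TAXONOMIC_RANKS)
  parent <- vapply(seq_along(ids), function(i) {
    k <- rank_idx[i]
    if (k == 1) return(NA_character_)
    up <- name_of(parts[[i]][k - 1])
    if (up == "") return(NA_character_)
    ## parent id = the taxon at rank k-1 whose name matches
    cand <- ids[ranks == TAXONOMIC_RANKS[k - 1] &
                  vapply(parts, function(p) name_of(p[k - 1]), character(1)) == up]
    if (length(cand)) cand[1] else NA_character_
  }, character(1))
  out <- data.frame(id = ids, rank = ranks, parent = parent,
                    name = vapply(seq_along(ids), function(i)
                      name_of(parts[[i]][rank_idx[i]]), character(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- out$id
  structure(out, ranks = TAXONOMIC_RANKS, class = c("taxonomy", "data.frame"))
}

#' Read genotype and metadata TSVs into a cohort object
#'
#' Joins the two files on \code{sample_id}; samples present in only one
#' file are dropped with a warning naming the count.  Composite loci are
#' built per the locus table (carrier or dosage coding via
#' \code{\link{locus_genotype}}).
#'
#' @param genotypes_path,metadata_path TSV paths.
#' @param loci locus definition table (\code{locus}, \code{variant},
#'   \code{maf}); defaults to \code{\link{default_loci}} restricted to the
#'   variants present.
#' @return a \code{"cohort_data"}.
#' @export
read_cohort <- function(genotypes_path, metadata_path,
                        loci = default_loci()) {
  g <- utils::read.delim(genotypes_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- utils::read.delim(metadata_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(g)) stop("genotypes need a sample_id column")
  if (!"sample_id" %in% names(m)) stop("metadata needs a sample_id column")
  common <- intersect(g$sample_id, m$sample_id)
  dropped <- length(union(g$sample_id, m$sample_id)) - length(common)
  if (dropped > 0)
    warning(dropped, " sample(s) present in only one file were dropped")
  g <- g[match(common, g$sample_id), , drop = FALSE]
  m <- m[match(common, m$sample_id), , drop = FALSE]
  geno <- as.matrix(g[, setdiff(names(g), "sample_id"), drop = FALSE])
  storage.mode(geno) <- "double"
  bad <- geno[!is.na(geno)]
  if (any(!bad %in% 0:2))
    stop("non-biallelic genotype codes found (expected dosages 0/1/2)")
  rownames(geno) <- common
  loci <- loci[loci$variant %in% colnames(geno), , drop = FALSE]
  structure(list(metadata = m, genotypes = geno, loci = loci),
            class = "cohort_data")
}

#' Run the full association-and-inference pipeline
#'
#' Executes, in order: prevalence filtering, rank-based inverse normal
#' transformation, per-taxon SNP association with confounders (and optional
#' within-rank covariate selection), per-rank Bonferroni flagging,
#' case-control taxon-disease associations (when controls are present),
#' sign enrichment, gene-bacteria/bacteria-disease concordance, and causal
#' model scoring.  All stages are deterministic given (inputs, config,
#' seed).
#'
#' @param table a \code{"taxon_table"}.
#' @param cohort a \code{"cohort_data"} aligned to the table's samples.
#' @param config list with optional entries: \code{loci} (names to test;
#'   default all in the cohort), \code{coding} ("carrier"/"dosage"),
#'   \code{confounders} (metadata columns; default the discovery set),
#'   \code{filter_threshold} (default 0.2), \code{select_covariates}
#'   (logical, default FALSE), \code{max_k} (default 5), \code{alpha}
#'   (default 0.05), \code{strata} (default IBD only), \code{seed}.
#' @param out_dir optional directory: when given, writes the association
#'   TSV and a JSON-like report (requires jsonlite) embedding the seed and
#'   a config checksum.
#' @return an object of class \code{"pipeline_result"}: list with
#'   \code{assoc} (per taxon/locus/stratum results with candidate flags),
#'   \code{disease_assoc}, \code{enrichment} (per locus),
#'   \code{concordance}, \code{report} (a \code{"model_fit_report"}), and
#'   \code{log} (stage-by-stage record counts).
#' @export
run_pipeline <- function(table, cohort, config = list(), out_dir = NULL) {
  stopifnot(inherits(table, "taxon_table"), inherits(cohort, "cohort_data"))
  cfg <- utils::modifyList(
    list(loci = unique(cohort$loci$locus), coding = "carrier",
         confounders = c("female", "age", "smoking", "asa",
                         "corticosteroids", "anti_tnf", "thiopurine_mtx"),
         filter_threshold = 0.2, select_covariates = FALSE, max_k = 5,
         alpha = 0.05, strata = "IBD", seed = 1L),
    config)
  miss_loci <- setdiff(cfg$loci, cohort$loci$locus)
  if (length(miss_loci))
    stop("config references absent locus/loci: ",
         paste(miss_loci, collapse = ", "))
  miss_conf <- setdiff(cfg$confounders, names(cohort$metadata))
  if (length(miss_conf))
    stop("config references absent confounder column(s): ",
         paste(miss_conf, collapse = ", "))
  set.seed(cfg$seed)
  log <- list(taxa_in = nrow(table$abundance),
              samples_in = ncol(table$abundance))

  ## 1. filter
  proc <- filter_taxa(table, cfg$filter_threshold)
  log$taxa_retained <- nrow(proc$abundance)
  log$taxa_dropped <- nrow(proc$dropped)

  md <- cohort$metadata
  is_case <- md$status == 1
  log$cases <- sum(is_case); log$controls <- sum(!is_case)

  ## 2. INT per taxon (cases for the SNP stage; all samples for case-control)
  Yc <- t(apply(proc$abundance[, is_case, drop = FALSE], 1, rank_int))
  Z <- md[is_case, cfg$confounders, drop = FALSE]
  Z <- Z[, vapply(Z, function(z) length(unique(z[!is.na(z)])) > 1,
                  logical(1)), drop = FALSE]

  ## 3. SNP-taxon associations in cases
  ranks <- proc$taxonomy$rank[match(rownames(Yc), proc$taxonomy$id)]
  assoc <- list()
  for (locus in cfg$loci) {
    gvec <- locus_genotype(cohort, locus, cfg$coding)[is_case]
    for (i in seq_len(nrow(Yc))) {
      Cmat <- NULL
      if (isTRUE(cfg$select_covariates)) {
        same <- which(ranks == ranks[i])
        cand <- t(Yc[setdiff(same, i), , drop = FALSE])
        sel <- select_level_covariates(Yc[i, ], cand, gvec, max_k = cfg$max_k)
        if (length(sel)) Cmat <- cand[, sel, drop = FALSE]
      }
      rows <- stratified_analysis(
        Yc[i, ], gvec, Z = Z, C = Cmat,
        subtype = md$subtype[is_case], ileal = md$ileal[is_case],
        strata = cfg$strata, taxon = rownames(Yc)[i], predictor = locus)
      assoc[[length(assoc) + 1]] <- rows
    }
  }
  assoc <- do.call(rbind, assoc)
  assoc$rank <- ranks[match(assoc$taxon, rownames(Yc))]
  assoc <- per_level_bonferroni(assoc[assoc$stratum %in% cfg$strata, ],
                                cfg$alpha)
  log$assoc_tests <- sum(!is.na(assoc$p))

  ## 4. taxon-disease case-control stage (needs controls)
  disease_assoc <- NULL
  if (any(!is_case)) {
    Zcc <- md[, intersect(c("female", "age", "smoking"), names(md)),
              drop = FALSE]
    disease_assoc <- do.call(rbind, lapply(seq_len(nrow(proc$abundance)),
      function(i) {
        b <- proc$abundance[i, ]
        if (length(unique(b)) < 3) return(NULL)
        fit_taxon_disease(rank_int(b), md$status, Z = Zcc,
                          taxon = rownames(proc$abundance)[i])
      }))
  }

  ## 5. enrichment per locus + concordance across loci
  ibd_rows <- assoc[assoc$stratum == "IBD" & !is.na(assoc$beta), ]
  enrichment <- lapply(split(ibd_rows$beta, ibd_rows$predictor),
                       sign_enrichment)
  conc <- NULL
  if (!is.null(disease_assoc) && length(cfg$loci)) {
    bg <- do.call(cbind, lapply(split(ibd_rows, ibd_rows$predictor),
      function(df) df$beta[match(rownames(proc$abundance), df$taxon)]))
    bb <- disease_assoc$beta[match(rownames(proc$abundance),
                                   disease_assoc$taxon)]
    ok <- rowSums(is.na(bg)) == 0 & !is.na(bb) & is.finite(bb)
    if (sum(ok) >= 3)
      conc <- concordance(bg[ok, , drop = FALSE], bb[ok],
                          n_perm = 2000, seed = cfg$seed)
  }

  ## 6. causal-model scoring from the top candidate association
  report <- NULL
  cand <- ibd_rows[order(ibd_rows$p), ]
  if (nrow(cand)) {
    obs <- collect_observed(
      discovery = list(beta = cand$beta[1], p = cand$p[1]),
      concordance = conc,
      alpha = cfg$alpha, n_tests = max(1, sum(!is.na(ibd_rows$p))))
    report <- score_models(obs)
  }

  out <- structure(
    list(assoc = assoc, disease_assoc = disease_assoc,
         enrichment = enrichment, concordance = conc, report = report,
         log = log, config = cfg),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- result$config
  tf <- tempfile(); on.exit(unlink(tf))
  dput(cfg, tf)
  checksum <- unname(tools::md5sum(tf))
  header <- sprintf("# seed=%s config_md5=%s", cfg$seed, checksum)
  apath <- file.path(out_dir, "assoc.tsv")
  writeLines(header, apath)
  suppressWarnings(utils::write.table(result$assoc, apath, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    rep <- list(seed = cfg$seed, config_md5 = checksum, log = result$log,
                verdict = if (!is.null(result$report)) result$report$verdict,
                enrichment = lapply(result$enrichment, function(e)
                  list(n = e$n_total, k = e$n_direction, p = e$p)),
                concordance = if (!is.null(result$concordance))
                  list(r = result$concordance$correlation,
                       p = result$concordance$p))
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  %d taxa in, %d retained; %d cases, %d controls; %d tests\n",
              x$log$taxa_in, x$log$taxa_retained, x$log$cases,
              x$log$controls, x$log$assoc_tests))
  ncand <- sum(x$assoc$candidate, na.rm = TRUE)
  cat(sprintf("  %d candidate association(s) after per-rank Bonferroni\n",
              ncand))
  if (!is.null(x$concordance))
    cat(sprintf("  concordance r = %.3f (p = %.3g)\n",
                x$concordance$correlation, x$concordance$p))
  if (!is.null(x$report))
    cat("  verdict:", paste(x$report$verdict, collapse = ", "), "\n")
  invisible(x)
}
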