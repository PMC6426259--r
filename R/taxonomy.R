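TAXONOMIC_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Build a random six-rank bacterial taxonomy
#'
#' Creates a nested hierarchy over the six ranks phylum, class, order,
#' family, genus and species.  Every non-phylum node is attached to exactly
#' one parent of the immediately higher rank, chosen uniformly at random (so
#' the tree is reproducible under \code{seed}).  Ranks need not have
#' non-decreasing node counts; in particular fewer species than genera means
#' some genera are leaves, as in real annotation where deeper levels are
#' often unresolved.
#'
#' @param level_counts integer vector of length 6: the number of named taxa
#'   at each rank, phylum through species.  The default reproduces a
#'   168-taxon hierarchy (6, 12, 17, 36, 63, 34).
#' @param seed optional integer seed for the random parent assignment.
#' @return an object of class \code{"taxonomy"}: a data frame with columns
#'   \code{id}, \code{rank}, \code{parent} (\code{NA} for phyla) and
#'   \code{name}, plus a \code{ranks} attribute.
#' @examples
#' tax <- build_taxonomy(seed = 1)
#' nrow(tax)          # 168
#' table(tax$rank)
#' @export
build_taxonomy <- function(level_counts = c(6, 12, 17, 36, 63, 34),
                           seed = NULL) {
  if (length(level_counts) != 6)
    stop("'level_counts' must have length 6 (phylum..species)")
  level_counts <- as.integer(level_counts)
  if (any(level_counts < 1)) stop("each rank needs at least one taxon")
  if (!is.null(seed)) set.seed(seed)
  prefix <- c("p", "c", "o", "f", "g", "s")
  nodes <- vector("list", 6)
  for (k in seq_len(6)) {
    ids <- sprintf("%s_%03d", prefix[k], seq_len(level_counts[k]))
    parent <- if (k == 1) NA_character_ else {
      up <- nodes[[k - 1]]$id
      ## every node gets a uniformly chosen parent at the rank above; sample()
      ## needs the resample guard when only one parent exists
      up[sample.int(length(up), level_counts[k], replace = TRUE)]
    }
    nodes[[k]] <- data.frame(id = ids, rank = TAXONOMIC_RANKS[k],
                             parent = parent,
                             name = sprintf("%s%03d",
                                            TAXONOMIC_RANKS[k], seq_len(level_counts[k])),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, nodes)
  rownames(out) <- out$id
  structure(out, ranks = TAXONOMIC_RANKS, class = c("taxonomy", "data.frame"))
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("taxonomy:", nrow(x), "taxa over", length(attr(x, "ranks")), "ranks\n")
  print(table(factor(x$rank, levels = attr(x, "ranks"))))
  invisible(x)
}

## full lineage string of a node, greengenes-like "p__x;c__y;..." down to the
## node's own rank (deeper fields left empty)
taxonomy_lineage <- function(tax, id) {
  stopifnot(inherits(tax, "taxonomy"))
  ranks <- attr(tax, "ranks")
  pieces <- setNames(rep("", length(ranks)), ranks)
  cur <- id
  while (!is.na(cur)) {
    row <- tax[cur, ]
    pieces[row$rank] <- row$name
    cur <- row$parent
  }
  paste(sprintf("%s__%s", substr(ranks, 1, 1), pieces), collapse = ";")
}

## children of a node (ids); internal
taxonomy_children <- function(tax, id) tax$id[!is.na(tax$parent) & tax$parent == id]

#' Simulate a hierarchical relative-abundance table
#'
#' Draws negative-binomial counts at the leaves of the taxonomy (named nodes
#' without children at any rank, plus one "unassigned" pseudo-leaf under each
#' internal node and at the top level, representing unknown/unmeasured mass),
#' aggregates counts up the hierarchy, and converts to per-sample relative
#' abundances by dividing by the per-sample total.  Per-leaf dispersions are
#' solved so the marginal zero probability matches \code{target_zero_fracs};
#' a target of exactly 0 is honored by zero-truncated sampling.  Baseline
#' leaf means are log-normal across taxa (heavy-tailed composition, as in
#' real communities) and scale with \code{depth}.
#'
#' By construction, for every sample the named children of a node sum to at
#' most the node's value, and within each rank the named taxa sum to at most
#' 1, the remainder being unassigned mass.
#'
#' @param taxonomy a \code{\link{build_taxonomy}} object.
#' @param n_samples number of samples.
#' @param target_zero_fracs per-taxon target zero fraction in [0, 0.95];
#'   recycled over named leaves.
#' @param dispersion fallback NB size parameter used for unassigned
#'   pseudo-leaves and when \code{target_zero_fracs} is \code{NULL}.
#' @param depth nominal sequencing depth (expected total counts per sample).
#' @param seed optional integer seed.
#' @param unassigned_share expected fraction of each internal node's mass
#'   that remains unassigned to named children.
#' @return an object of class \code{"taxon_table"}: a list with
#'   \code{abundance} (taxa x samples matrix of relative abundances over the
#'   named taxa), \code{taxonomy}, \code{depth}, and internal leaf counts
#'   (attribute \code{"leaf_counts"}) enabling causal re-generation.
#' @examples
#' tax <- build_taxonomy(c(2, 2, 2, 2, 2, 2), seed = 1)
#' tt <- sample_abundance_table(tax, n_samples = 5, seed = 2)
#' range(tt$abundance)
#' @export
sample_abundance_table <- function(taxonomy, n_samples,
                                   target_zero_fracs = 0.3,
                                   dispersion = 0.5,
                                   depth = 10000, seed = NULL,
                                   unassigned_share = 0.15) {
  stopifnot(inherits(taxonomy, "taxonomy"), n_samples >= 1, depth >= 1)
  if (!is.null(seed)) set.seed(seed)
  has_child <- taxonomy$id %in% taxonomy$parent
  leaves <- taxonomy$id[!has_child]
  internals <- taxonomy$id[has_child]
  if (!is.null(target_zero_fracs)) {
    if (any(target_zero_fracs < 0 | target_zero_fracs > 0.95))
      stop("'target_zero_fracs' must be in [0, 0.95]")
    target_zero_fracs <- rep_len(target_zero_fracs, length(leaves))
  }
  ## pseudo-leaves: one per internal node plus one top-level pool
  pseudo <- c(paste0("unassigned@", internals), "unassigned@top")
  all_leaves <- c(leaves, pseudo)
  ## log-normal composition over leaves; unassigned pools take a fixed share
  w <- stats::rlnorm(length(leaves), 0, 1.5)
  w <- w / sum(w) * (1 - unassigned_share)
  wp <- stats::rlnorm(length(pseudo), 0, 1)
  wp <- wp / sum(wp) * unassigned_share
  mu <- depth * c(w, wp)
  mu <- pmax(mu, 0.5)   # floor so dispersion targeting stays solvable
  counts <- matrix(0L, length(all_leaves), n_samples,
                   dimnames = list(all_leaves, NULL))
  for (i in seq_along(all_leaves)) {
    if (i <= length(leaves) && !is.null(target_zero_fracs)) {
      p0 <- target_zero_fracs[i]
      if (p0 == 0) {
        ## zero-truncated: the target IS the zero fraction, so none allowed
        x <- rnbinom_mu(n_samples, mu[i], Inf)
        while (any(x == 0)) x[x == 0] <- rnbinom_mu(sum(x == 0), mu[i], Inf)
      } else {
        size <- suppressWarnings(nb_size_for_zero(mu[i], p0))
        x <- rnbinom_mu(n_samples, mu[i], size)
      }
    } else {
      x <- rnbinom_mu(n_samples, mu[i], dispersion)
    }
    counts[i, ] <- x
  }
  build_taxon_table(taxonomy, counts, depth)
}

## aggregate leaf counts up the hierarchy and convert to proportions.
## counts: matrix (leaves + pseudo-leaves) x samples
build_taxon_table <- function(taxonomy, counts, depth) {
  n_samples <- ncol(counts)
  total <- colSums(counts)
  total[total == 0] <- 1
  value <- matrix(0, nrow(taxonomy), n_samples,
                  dimnames = list(taxonomy$id, colnames(counts)))
  ## accumulate each leaf (incl. pseudo) into all its ancestors
  own <- function(id) if (id %in% rownames(counts)) counts[id, ] else 0
  ranks <- attr(taxonomy, "ranks")
  for (k in rev(seq_along(ranks))) {
    ids <- taxonomy$id[taxonomy$rank == ranks[k]]
    for (id in ids) {
      kids <- taxonomy_children(taxonomy, id)
      base <- own(id) + own(paste0("unassigned@", id))
      value[id, ] <- base + if (length(kids)) colSums(value[kids, , drop = FALSE]) else 0
    }
  }
  colnames(value) <- colnames(counts) <- paste0("S", seq_len(n_samples))
  structure(
    list(abundance = sweep(value, 2, total, "/"),
         taxonomy = taxonomy, depth = depth),
    leaf_counts = counts,
    class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("taxon_table: %d taxa x %d samples (depth %g)\n",
              nrow(x$abundance), ncol(x$abundance), x$depth))
  cat(sprintf("  zero fraction: %.3f; max abundance: %.3f\n",
              mean(x$abundance == 0), max(x$abundance)))
  invisible(x)
}
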