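#' All-pairs Fisher enrichment scan over target x control genome pairs
#'
#' For every (target, control) genome pair and every Pfam in the screening
#' universe (present in at least one target genome), a 2x2 table contrasts
#' hits to the focal Pfam against hits to all other Pfams in the two
#' genomes. Two-sided Fisher p-values are Benjamini-Hochberg adjusted within
#' each pair's family of per-Pfam tests (`bh_family = "per_pair"`; set
#' `"global"` to adjust across all pair-by-Pfam tests at once). A pair
#' counts as significant for a Pfam when the adjusted p-value is below
#' `alpha` and the Pfam's proportion of hits is higher in the target genome
#' (the enriched direction; disable with `require_direction = FALSE`). A
#' Pfam is selected ("enriched") when it is significant in at least
#' `min_fraction` of all pairs.
#'
#' Raw counts are used without genome-size normalization; see
#' [normalization_diagnostic()] for the supporting check.
#'
#' @param matrix Pfam-by-genome integer count matrix.
#' @param genomes Genome metadata data.frame.
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @param min_fraction Minimum fraction of significant pairs for selection
#'   (default 0.25).
#' @param require_direction Require target proportion > control proportion
#'   in addition to significance (default TRUE).
#' @param bh_family `"per_pair"` (default) or `"global"`.
#' @return data.frame with one row per universe Pfam: `pfam_acc`,
#'   `n_pairs`, `n_significant`, `significant_fraction`, `selected`;
#'   ordered by decreasing `significant_fraction`, then accession. The BH
#'   family mode is recorded in the `bh_family` attribute.
#' @export
pairwise_enrichment <- function(matrix, genomes, alpha = 0.05,
                                min_fraction = 0.25,
                                require_direction = TRUE,
                                bh_family = c("per_pair", "global")) {
  bh_family <- match.arg(bh_family)
  genomes <- validate_genomes(genomes)
  sets <- genome_sets(genomes)
  if (length(sets$target) == 0L) stop("no TARGET genomes")
  if (length(sets$control) == 0L) stop("no CONTROL genomes")
  matrix <- align_matrix_to_genomes(validate_count_matrix(matrix), genomes)
  totals <- colSums(matrix)
  zero <- names(totals)[totals == 0L]
  if (length(zero) > 0L) {
    stop("genome(s) with zero total Pfam hits: ",
         paste(zero, collapse = ", "))
  }
  universe <- rowSums(matrix[, sets$target, drop = FALSE]) > 0L
  m <- matrix[universe, , drop = FALSE]
  n_pfam <- nrow(m)
  n_pairs <- length(sets$target) * length(sets$control)
  n_sig <- stats::setNames(integer(n_pfam), rownames(m))
  if (bh_family == "global") {
    praw <- matrix(NA_real_, nrow = n_pfam, ncol = n_pairs)
    dir_ok <- matrix(FALSE, nrow = n_pfam, ncol = n_pairs)
  }
  pair_i <- 0L
  for (tg in sets$target) {
    at <- m[, tg]
    n1 <- totals[[tg]]
    for (cg in sets$control) {
      pair_i <- pair_i + 1L
      ac <- m[, cg]
      n2 <- totals[[cg]]
      p <- fisher_vec_cached(at, ac, n1, n2)
      ok <- if (require_direction) at / n1 > ac / n2 else rep(TRUE, n_pfam)
      if (bh_family == "per_pair") {
        n_sig <- n_sig + (bh_adjust(p) < alpha & ok)
      } else {
        praw[, pair_i] <- p
        dir_ok[, pair_i] <- ok
      }
    }
  }
  if (bh_family == "global") {
    padj <- matrix(bh_adjust(as.vector(praw)), nrow = n_pfam)
    n_sig <- rowSums(padj < alpha & dir_ok)
  }
  out <- data.frame(
    pfam_acc = rownames(m),
    n_pairs = n_pairs,
    n_significant = as.integer(n_sig),
    significant_fraction = as.numeric(n_sig) / n_pairs,
    stringsAsFactors = FALSE
  )
  out$selected <- out$significant_fraction >= min_fraction
  out <- out[order(-out$significant_fraction, out$pfam_acc), ]
  rownames(out) <- NULL
  attr(out, "bh_family") <- bh_family
  out
}

# Fisher p for vectors of focal counts sharing fixed per-genome totals.
# Distinct (a, c) tables are computed once and mapped back: within one
# genome pair most Pfams share a handful of small tables.
fisher_vec_cached <- function(a, c, n1, n2) {
  key <- a * (max(c) + 1) + c
  u <- !duplicated(key)
  pu <- vapply(
    which(u),
    function(i) fisher_two_sided(a[i], n1 - a[i], c[i], n2 - c[i]),
    numeric(1L)
  )
  pu[match(key, key[u])]
}

#' Diagnostic for the no-normalization assumption
#'
#' Reports the Spearman rank correlation between each genome's total number
#' of Pfam hits and its total gene count, together with the per-genome
#' table, so the analyst can judge whether contrasting raw counts (without
#' genome-size normalization) is defensible. A degenerate case where either
#' variable is completely tied across genomes is reported as correlation 0
#' with a warning.
#'
#' @param matrix Pfam-by-genome integer count matrix.
#' @param genomes Genome metadata data.frame with `total_genes`.
#' @return List with `spearman_rho` and `table` (data.frame `genome_id`,
#'   `set_label`, `total_genes`, `pfam_hits`).
#' @export
normalization_diagnostic <- function(matrix, genomes) {
  genomes <- validate_genomes(genomes)
  if (nrow(genomes) < 3L) stop("need >= 3 genomes for the diagnostic")
  matrix <- align_matrix_to_genomes(validate_count_matrix(matrix), genomes)
  hits <- colSums(matrix)
  tab <- data.frame(
    genome_id = genomes$genome_id,
    set_label = genomes$set_label,
    total_genes = genomes$total_genes,
    pfam_hits = as.integer(hits),
    stringsAsFactors = FALSE
  )
  if (length(unique(tab$pfam_hits)) == 1L ||
      length(unique(tab$total_genes)) == 1L) {
    warning("all ranks tied on one variable; Spearman correlation defined as 0")
    rho <- 0
  } else {
    rho <- stats::cor(tab$total_genes, tab$pfam_hits, method = "spearman")
  }
  list(spearman_rho = rho, table = tab)
}

#' Overlap between the over-represented and enriched Pfam sets
#'
#' The quartile screen captures presence-absence contrasts while the
#' pairwise scan captures copy-number expansions, so the two selected sets
#' are typically near-disjoint; this summary makes the overlap explicit.
#'
#' @param screen Result of [quartile_screen()].
#' @param enrich Result of [pairwise_enrichment()].
#' @return List with accession vectors `overrepresented_only`,
#'   `enriched_only`, `both`, and integer `n_overrepresented`, `n_enriched`,
#'   `n_both`.
#' @export
overlap_report <- function(screen, enrich) {
  s <- screen$pfam_acc[screen$selected]
  e <- enrich$pfam_acc[enrich$selected]
  both <- sort(intersect(s, e))
  list(
    overrepresented_only = sort(setdiff(s, e)),
    enriched_only = sort(setdiff(e, s)),
    both = both,
    n_overrepresented = length(s),
    n_enriched = length(e),
    n_both = length(both)
  )
}

#' Write enrichment results to TSV
#' @param enrich Result of [pairwise_enrichment()].
#' @param path Output file path.
#' @param header Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_enrichment_results <- function(enrich, path, header = NULL) {
  write_tsv_plain(enrich, path, header = header)
}
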