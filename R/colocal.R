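#' Conserved co-localization scan for Pfam pairs
#'
#' For each candidate pair of Pfams, counts the genomes where genes of both
#' families co-occur and the subset where some gene of each lies on the same
#' replicon within `max_gene_gap` intervening genes (gene-rank distance
#' `<= max_gene_gap + 1`), on the same strand if required — an operon-style
#' arrangement. Replicons are treated as linear; circular wrap-around
#' adjacency is not considered. Genes lacking replicon or rank coordinates
#' are skipped (a message reports how many).
#'
#' `ordered_upstream_fraction` is the fraction of strand-resolved
#' co-localized instances in which the `pfam_a` gene precedes the `pfam_b`
#' gene on the shared coding strand (lower rank on `+`, higher on `-`);
#' per genome the closest qualifying gene pair is the scored instance.
#'
#' @param assignments Assignment data.frame with `replicon_id`,
#'   `gene_index`, `strand`.
#' @param pairs data.frame with columns `pfam_a`, `pfam_b` (distinct
#'   accessions).
#' @param max_gene_gap Maximum number of intervening genes (default 2).
#' @param require_same_strand Require a shared strand (default TRUE).
#' @return data.frame with one row per pair: `pfam_a`, `pfam_b`,
#'   `n_cooccurring_genomes`, `n_colocalized_genomes`,
#'   `colocalized_fraction` (NA when never co-occurring),
#'   `ordered_upstream_fraction` (NA when no strand-resolved instance).
#' @export
colocalization_scan <- function(assignments, pairs, max_gene_gap = 2L,
                                require_same_strand = TRUE) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- data.frame(
      pfam_a = vapply(pairs, `[[`, character(1L), 1L),
      pfam_b = vapply(pairs, `[[`, character(1L), 2L),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("pfam_a", "pfam_b") %in% names(pairs)))
  if (any(pairs$pfam_a == pairs$pfam_b)) {
    stop("co-localization pairs must have distinct accessions")
  }
  has_coord <- !is.na(assignments$replicon_id) &
    !is.na(assignments$gene_index)
  n_skipped <- sum(!has_coord)
  if (n_skipped > 0L) {
    message(n_skipped, " gene assignment(s) without coordinates skipped")
  }
  a <- assignments[has_coord, ]
  max_dist <- max_gene_gap + 1L
  out <- pairs[c("pfam_a", "pfam_b")]
  out$n_cooccurring_genomes <- 0L
  out$n_colocalized_genomes <- 0L
  out$ordered_upstream_fraction <- NA_real_
  for (r in seq_len(nrow(pairs))) {
    ga <- a[a$pfam_acc == pairs$pfam_a[r], ]
    gb <- a[a$pfam_acc == pairs$pfam_b[r], ]
    shared <- intersect(unique(ga$genome_id), unique(gb$genome_id))
    out$n_cooccurring_genomes[r] <- length(shared)
    n_up <- 0L
    n_resolved <- 0L
    n_coloc <- 0L
    for (g in shared) {
      xa <- ga[ga$genome_id == g, ]
      xb <- gb[gb$genome_id == g, ]
      cand <- merge(
        xa[c("replicon_id", "gene_index", "strand")],
        xb[c("replicon_id", "gene_index", "strand")],
        by = "replicon_id", suffixes = c("_a", "_b")
      )
      if (nrow(cand) == 0L) next
      cand$dist <- abs(cand$gene_index_a - cand$gene_index_b)
      ok <- cand$dist <= max_dist
      if (require_same_strand) {
        ok <- ok & !is.na(cand$strand_a) & !is.na(cand$strand_b) &
          cand$strand_a == cand$strand_b
      }
      if (!any(ok)) next
      n_coloc <- n_coloc + 1L
      hit <- cand[ok, ]
      hit <- hit[order(hit$dist, hit$gene_index_a), ][1L, ]
      resolved <- !is.na(hit$strand_a) && !is.na(hit$strand_b) &&
        hit$strand_a == hit$strand_b &&
        hit$gene_index_a != hit$gene_index_b
      if (resolved) {
        n_resolved <- n_resolved + 1L
        upstream <- if (hit$strand_a == "+") {
          hit$gene_index_a < hit$gene_index_b
        } else {
          hit$gene_index_a > hit$gene_index_b
        }
        n_up <- n_up + upstream
      }
    }
    out$n_colocalized_genomes[r] <- n_coloc
    if (n_resolved > 0L) {
      out$ordered_upstream_fraction[r] <- n_up / n_resolved
    }
  }
  out$colocalized_fraction <- ifelse(
    out$n_cooccurring_genomes > 0L,
    out$n_colocalized_genomes / out$n_cooccurring_genomes,
    NA_real_
  )
  out <- out[c("pfam_a", "pfam_b", "n_cooccurring_genomes",
               "n_colocalized_genomes", "colocalized_fraction",
               "ordered_upstream_fraction")]
  rownames(out) <- NULL
  out
}

#' Write co-localization results to TSV
#' @param colocal Result of [colocalization_scan()].
#' @param path Output file path.
#' @param header Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_colocal_results <- function(colocal, path, header = NULL) {
  write_tsv_plain(colocal, path, header = header)
}
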