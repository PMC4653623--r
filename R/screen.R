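#' Subtractive quartile screen for over-represented Pfams
#'
#' Contrasts per-genome gene counts for each Pfam between the target and
#' control genome sets. A Pfam is selected ("over-represented") when its
#' median (2nd quartile) count over all target genomes is at least
#' `target_median_min` and its median over all control genomes is at most
#' `control_median_max` — the defaults encode the target-median >= 1 /
#' control-median = 0 presence-absence rule. Quartiles use linear
#' interpolation between order statistics (R quantile type 7), so even-sized
#' sets can yield fractional medians; these are compared to the thresholds
#' as real numbers.
#'
#' The screening universe is the set of Pfams with at least one hit in at
#' least one target genome; control-only Pfams are excluded. Quartiles are
#' computed over every genome of each set, including zero counts.
#'
#' @param matrix Pfam-by-genome integer count matrix.
#' @param genomes Genome metadata data.frame with `set_label` in
#'   `TARGET`/`CONTROL`.
#' @param target_median_min Minimum target-set median count (default 1).
#' @param control_median_max Maximum control-set median count (default 0).
#' @return data.frame with one row per Pfam in the screening universe:
#'   `pfam_acc`, quartiles `target_q1/q2/q3`, `control_q1/q2/q3`, and
#'   logical `selected`; ordered by decreasing `target_q2`, then accession.
#' @export
quartile_screen <- function(matrix, genomes,
                            target_median_min = 1,
                            control_median_max = 0) {
  genomes <- validate_genomes(genomes)
  if (target_median_min < 0 || control_median_max < 0) {
    stop("quartile thresholds must be non-negative")
  }
  sets <- genome_sets(genomes)
  if (length(sets$target) == 0L) stop("no TARGET genomes")
  if (length(sets$control) == 0L) stop("no CONTROL genomes")
  matrix <- align_matrix_to_genomes(validate_count_matrix(matrix), genomes)
  tm <- matrix[, sets$target, drop = FALSE]
  cm <- matrix[, sets$control, drop = FALSE]
  universe <- rowSums(tm) > 0L
  tm <- tm[universe, , drop = FALSE]
  cm <- cm[universe, , drop = FALSE]
  qs <- function(m) {
    t(apply(m, 1L, stats::quantile, probs = c(0.25, 0.5, 0.75),
            names = FALSE, type = 7))
  }
  tq <- qs(tm)
  cq <- qs(cm)
  out <- data.frame(
    pfam_acc = rownames(tm),
    target_q1 = tq[, 1L], target_q2 = tq[, 2L], target_q3 = tq[, 3L],
    control_q1 = cq[, 1L], control_q2 = cq[, 2L], control_q3 = cq[, 3L],
    stringsAsFactors = FALSE
  )
  out$selected <- out$target_q2 >= target_median_min &
    out$control_q2 <= control_median_max
  out <- out[order(-out$target_q2, out$pfam_acc), ]
  rownames(out) <- NULL
  out
}

#' Write quartile-screen results to TSV
#' @param screen Result of [quartile_screen()].
#' @param path Output file path.
#' @param header Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_screen_results <- function(screen, path, header = NULL) {
  write_tsv_plain(screen, path, header = header)
}
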