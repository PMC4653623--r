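#' Build the Pfam-by-genome count matrix
#'
#' Tabulates, for every Pfam accession and genome, the number of distinct
#' genes carrying that Pfam. A gene carrying the same Pfam twice counts once;
#' a gene carrying two different Pfams counts once toward each (counting is
#' per gene, not per domain instance). Genomes with no assignments appear as
#' all-zero columns; rows and columns are ordered lexicographically so the
#' matrix is deterministic and invariant to input order.
#'
#' @param assignments Assignment data.frame (`gene_id`, `genome_id`,
#'   `pfam_acc`, ...).
#' @param genomes Genome metadata data.frame (`genome_id`, `set_label`, ...).
#' @return Integer matrix, Pfam accessions x genome ids.
#' @export
build_count_matrix <- function(assignments, genomes) {
  genomes <- validate_genomes(genomes)
  unknown <- setdiff(unique(assignments$genome_id), genomes$genome_id)
  if (length(unknown) > 0L) {
    stop("assignments reference unknown genome id(s): ",
         paste(sort(unknown), collapse = ", "))
  }
  gids <- sort(genomes$genome_id)
  a <- unique(assignments[c("gene_id", "genome_id", "pfam_acc")])
  pfams <- sort(unique(a$pfam_acc))
  m <- matrix(0L, nrow = length(pfams), ncol = length(gids),
              dimnames = list(pfams, gids))
  if (nrow(a) > 0L) {
    tab <- table(factor(a$pfam_acc, levels = pfams),
                 factor(a$genome_id, levels = gids))
    m[] <- as.integer(tab)
  }
  m
}

#' Split genome ids by set label
#' @param genomes Genome metadata data.frame.
#' @return List with character vectors `target` and `control`.
#' @export
genome_sets <- function(genomes) {
  list(
    target = genomes$genome_id[genomes$set_label == "TARGET"],
    control = genomes$genome_id[genomes$set_label == "CONTROL"]
  )
}

# Ensure the matrix has a column for every genome (all-zero where absent)
# and restrict columns to the given genomes, preserving matrix row order.
align_matrix_to_genomes <- function(matrix, genomes) {
  missing <- setdiff(genomes$genome_id, colnames(matrix))
  if (length(missing) > 0L) {
    pad <- matrix(0L, nrow = nrow(matrix), ncol = length(missing),
                  dimnames = list(rownames(matrix), missing))
    matrix <- cbind(matrix, pad)
  }
  matrix[, genomes$genome_id, drop = FALSE]
}
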