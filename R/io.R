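#' Read a HMMER3 per-domain table (domtblout)
#'
#' Parses the whitespace-delimited per-domain output of `hmmscan`/`hmmsearch`
#' (`--domtblout`) into gene-level domain assignments. The target name
#' (column 1) is taken as the gene id and the query accession (column 5) as
#' the Pfam accession; a version suffix (e.g. `PF02474.15`) is stripped.
#' Multiple domain hits of the same Pfam on one gene collapse to a single
#' assignment, because downstream counting is per gene, not per domain
#' instance.
#'
#' @param path Path to a domtblout file.
#' @param genome_id Genome identifier to attach to every assignment. HMMER
#'   output carries no genome column, so the caller supplies it (typically
#'   one file per genome).
#' @return A data.frame of assignments with columns `gene_id`, `genome_id`,
#'   `pfam_acc`, plus `replicon_id`, `gene_index`, `strand`,
#'   `signal_peptide` as `NA` (unknown, never silently `FALSE`).
#' @export
read_domtblout <- function(path, genome_id) {
  stopifnot(is.character(path), length(path) == 1L)
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(empty_assignments())
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 23L)
  if (length(bad) > 0L) {
    stop(sprintf(
      "malformed domtblout line %d in '%s': %d fields (>= 23 required)",
      idx[bad[1L]], path, nf[bad[1L]]
    ))
  }
  gene <- vapply(fields, `[[`, character(1L), 1L)
  acc <- vapply(fields, `[[`, character(1L), 5L)
  missing_acc <- acc == "-"
  if (any(missing_acc)) {
    warning(sprintf(
      "%d domtblout record(s) without a Pfam accession skipped in '%s'",
      sum(missing_acc), path
    ))
    gene <- gene[!missing_acc]
    acc <- acc[!missing_acc]
  }
  if (length(gene) == 0L) {
    return(empty_assignments())
  }
  acc <- strip_pfam_version(acc)
  out <- unique(data.frame(
    gene_id = gene, genome_id = genome_id, pfam_acc = acc,
    stringsAsFactors = FALSE
  ))
  out$replicon_id <- NA_character_
  out$gene_index <- NA_integer_
  out$strand <- NA_character_
  out$signal_peptide <- NA
  rownames(out) <- NULL
  out
}

strip_pfam_version <- function(acc) sub("\\.\\d+$", "", acc)

empty_assignments <- function() {
  data.frame(
    gene_id = character(0), genome_id = character(0),
    pfam_acc = character(0), replicon_id = character(0),
    gene_index = integer(0), strand = character(0),
    signal_peptide = logical(0), stringsAsFactors = FALSE
  )
}

assignment_columns <- c(
  "gene_id", "genome_id", "pfam_acc", "replicon_id",
  "gene_index", "strand", "signal_peptide"
)

#' Read a long-format assignment table
#'
#' Tab-separated with header; mandatory columns `gene_id`, `genome_id`,
#' `pfam_acc`; optional `replicon_id`, `gene_index` (0-based gene rank along
#' its replicon), `strand` (`+`/`-`) and `signal_peptide` (`TRUE`/`FALSE`,
#' empty = unknown). Missing optional columns are filled with `NA`.
#'
#' @param path Path to the TSV file.
#' @return Assignment data.frame (see [read_domtblout()] for columns).
#' @export
read_assignments <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "genome_id", "pfam_acc"))
  if (nrow(df) == 0L) return(empty_assignments())
  for (col in c("replicon_id", "strand")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  if (is.null(df$gene_index)) df$gene_index <- NA_integer_
  df$gene_index <- as.integer(df$gene_index)
  if (is.null(df$signal_peptide)) df$signal_peptide <- NA
  df$signal_peptide <- as_logical_flag(df$signal_peptide)
  df$pfam_acc <- strip_pfam_version(as.character(df$pfam_acc))
  df <- df[assignment_columns]
  df <- unique(df)
  rownames(df) <- NULL
  df
}

as_logical_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

#' Write assignments to the long-format TSV dialect
#' @param assignments Assignment data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  stopifnot(all(c("gene_id", "genome_id", "pfam_acc") %in% names(assignments)))
  for (col in setdiff(assignment_columns, names(assignments))) {
    assignments[[col]] <- NA
  }
  write_tsv_plain(assignments[assignment_columns], path)
}

#' Read a genome metadata table
#'
#' Tab-separated with header `genome_id`, `set_label`, `total_genes` and an
#' optional `lineage` column (semicolon-separated taxon names, most inclusive
#' first). Set labels `RNB`/`NC` are accepted as synonyms of
#' `TARGET`/`CONTROL`.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `genome_id`, `set_label`
#'   (`"TARGET"`/`"CONTROL"`), `total_genes`, `lineage`.
#' @export
read_genomes <- function(path) {
  df <- read_tsv_checked(path, c("genome_id", "set_label", "total_genes"))
  if (is.null(df$lineage)) df$lineage <- NA_character_
  validate_genomes(data.frame(
    genome_id = as.character(df$genome_id),
    set_label = normalize_set_label(df$set_label),
    total_genes = as.integer(df$total_genes),
    lineage = as.character(df$lineage),
    stringsAsFactors = FALSE
  ))
}

normalize_set_label <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x == "RNB"] <- "TARGET"
  x[x == "NC"] <- "CONTROL"
  bad <- setdiff(unique(x), c("TARGET", "CONTROL"))
  if (length(bad) > 0L) {
    stop("unknown set_label value(s): ", paste(bad, collapse = ", "))
  }
  x
}

validate_genomes <- function(genomes) {
  stopifnot(is.data.frame(genomes))
  if (anyDuplicated(genomes$genome_id)) {
    stop("duplicate genome_id: ",
         paste(unique(genomes$genome_id[duplicated(genomes$genome_id)]),
               collapse = ", "))
  }
  if (any(!is.na(genomes$total_genes) & genomes$total_genes < 0L)) {
    stop("total_genes must be >= 0")
  }
  genomes
}

#' Write a genome metadata table
#' @param genomes Genome data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(genomes, path) {
  write_tsv_plain(
    genomes[c("genome_id", "set_label", "total_genes", "lineage")], path
  )
}

#' Read a Pfam-by-genome count matrix from TSV
#'
#' First column `pfam_acc`, one integer column per genome id.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix, Pfam accessions as rownames, genome ids as
#'   colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "pfam_acc") {
    stop("count-matrix TSV must have 'pfam_acc' as its first column")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$pfam_acc
  validate_count_matrix(m)
}

#' Write a Pfam-by-genome count matrix to TSV
#' @param matrix Integer count matrix (Pfams x genomes).
#' @param path Output file path.
#' @param header Optional character vector of `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(matrix, path, header = NULL) {
  df <- data.frame(pfam_acc = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path, header = header)
}

validate_count_matrix <- function(m) {
  stopifnot(is.matrix(m))
  if (any(is.na(m)) || any(m < 0L)) stop("counts must be non-negative")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix needs Pfam rownames and genome colnames")
  }
  m
}

#' Read an expression table (`gene_id`, `study_id`, `log2fc`)
#' @param path Path to the TSV file.
#' @return data.frame of expression records.
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "study_id", "log2fc"))
  df$log2fc <- as.numeric(df$log2fc)
  if (any(!is.finite(df$log2fc))) stop("log2fc must be finite")
  df
}

#' Read a phylogenetic-distribution table
#'
#' Columns `pfam_acc`, `n_eukarya`, `n_bacteria`, `n_archaea`,
#' `prok_lineages` (semicolon-separated lineage names at a fixed rank).
#'
#' @param path Path to the TSV file.
#' @return data.frame with `prok_lineages` as a semicolon-joined string.
#' @export
read_phylo <- function(path) {
  df <- read_tsv_checked(
    path, c("pfam_acc", "n_eukarya", "n_bacteria", "n_archaea")
  )
  for (col in c("n_eukarya", "n_bacteria", "n_archaea")) {
    df[[col]] <- as.integer(df[[col]])
    if (any(is.na(df[[col]]) | df[[col]] < 0L)) {
      stop(col, " must be a non-negative integer")
    }
  }
  if (is.null(df$prok_lineages)) df$prok_lineages <- ""
  df$prok_lineages <- as.character(df$prok_lineages)
  df$prok_lineages[is.na(df$prok_lineages)] <- ""
  df
}

#' Read a one-column Pfam accession list (e.g. AntiSMASH reference Pfams)
#' @param path Path to a text file, one accession per line; `#` comments and
#'   blank lines ignored.
#' @return Character vector of accessions, version suffixes stripped.
#' @export
read_pfam_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(strip_pfam_version(lines))
}

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("'%s' lacks required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  df
}

write_tsv_plain <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
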