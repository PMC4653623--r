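#' Transcriptome-induction (EXP) evidence filter
#'
#' A candidate Pfam passes when at least one of its member genes shows a
#' log2 fold change of at least `min_log2fc` in at least one expression
#' study (default 1, i.e. 2-fold induction). Pfams whose member genes are
#' absent from every expression table are reported as `"untested"` — a
#' distinct state from a measured failure, never conflated with it — and do
#' not pass.
#'
#' @param candidates Character vector of Pfam accessions.
#' @param assignments Assignment data.frame defining Pfam membership of
#'   genes.
#' @param expression Expression data.frame (`gene_id`, `study_id`,
#'   `log2fc`).
#' @param min_log2fc Minimum log2 fold change (default 1).
#' @return data.frame `pfam_acc`, logical `exp`, `exp_status`
#'   (`"pass"`/`"fail"`/`"untested"`), `exp_best_log2fc` (NA when untested).
#' @export
exp_filter <- function(candidates, assignments, expression,
                       min_log2fc = 1.0) {
  best <- rep(NA_real_, length(candidates))
  if (nrow(expression) > 0L) {
    gene_best <- tapply(expression$log2fc, expression$gene_id, max)
    member <- assignments[assignments$pfam_acc %in% candidates &
                            assignments$gene_id %in% names(gene_best), ]
    if (nrow(member) > 0L) {
      fam_best <- tapply(gene_best[member$gene_id], member$pfam_acc, max)
      best <- as.numeric(fam_best[candidates])
    }
  }
  status <- ifelse(is.na(best), "untested",
                   ifelse(best >= min_log2fc, "pass", "fail"))
  data.frame(
    pfam_acc = candidates,
    exp = status == "pass",
    exp_status = status,
    exp_best_log2fc = best,
    stringsAsFactors = FALSE
  )
}

#' Limited-phylogenetic-distribution (LPD) evidence filter
#'
#' A candidate Pfam passes via mode "eukaryal" when the fraction of its
#' known sequences of eukaryal origin is at least `min_euk_fraction`, or via
#' mode "restricted" when its prokaryotic sequences outside the focal
#' lineages span at most `max_prok_lineages` lineages (capturing families
#' confined to, e.g., Rhizobiaceae plus a few intracellular pathogens).
#' Candidates without a distribution row, or with a zero total sequence
#' count, are `"unknown"` and do not pass.
#'
#' @param candidates Character vector of Pfam accessions.
#' @param phylo Phylogenetic-distribution data.frame (see [read_phylo()]).
#' @param min_euk_fraction Minimum eukaryal sequence fraction (default
#'   0.75).
#' @param max_prok_lineages Maximum number of non-focal prokaryotic
#'   lineages (default 5).
#' @param focal_lineages Lineages not counted against the restriction
#'   (default `"Rhizobiaceae"`).
#' @return data.frame `pfam_acc`, logical `lpd`, `lpd_status`, `lpd_mode`
#'   (`"eukaryal"`/`"restricted"`/NA), `euk_fraction`.
#' @export
lpd_filter <- function(candidates, phylo, min_euk_fraction = 0.75,
                       max_prok_lineages = 5L,
                       focal_lineages = "Rhizobiaceae") {
  i <- match(candidates, phylo$pfam_acc)
  total <- phylo$n_eukarya[i] + phylo$n_bacteria[i] + phylo$n_archaea[i]
  euk <- ifelse(!is.na(total) & total > 0L,
                phylo$n_eukarya[i] / total, NA_real_)
  n_nonfocal <- vapply(seq_along(candidates), function(j) {
    if (is.na(i[j])) return(NA_integer_)
    lin <- strsplit(phylo$prok_lineages[i[j]], ";", fixed = TRUE)[[1L]]
    lin <- trimws(lin)
    length(setdiff(lin[nzchar(lin)], focal_lineages))
  }, integer(1L))
  mode <- rep(NA_character_, length(candidates))
  mode[!is.na(euk) & euk >= min_euk_fraction] <- "eukaryal"
  restricted <- is.na(mode) & !is.na(total) & total > 0L &
    !is.na(n_nonfocal) & n_nonfocal <= max_prok_lineages
  mode[restricted] <- "restricted"
  status <- ifelse(is.na(total) | total == 0L, "unknown",
                   ifelse(is.na(mode), "fail", "pass"))
  data.frame(
    pfam_acc = candidates,
    lpd = status == "pass",
    lpd_status = status,
    lpd_mode = mode,
    euk_fraction = euk,
    stringsAsFactors = FALSE
  )
}

#' Signal-peptide (secretion) evidence filter
#'
#' A candidate Pfam passes when at least `min_fraction` (inclusive; default
#' 50%) of its member genes in the target genome set carry a predicted
#' signal-peptidase-I cleavage signal. Genes with an unknown flag are
#' excluded from the denominator; a Pfam whose target-set members all have
#' unknown flags is `"untested"`.
#'
#' @param candidates Character vector of Pfam accessions.
#' @param assignments Assignment data.frame carrying `signal_peptide` flags
#'   (logical, NA = unknown).
#' @param genomes Genome metadata data.frame; only `TARGET` genomes enter
#'   the denominator.
#' @param min_fraction Minimum flagged fraction (default 0.5).
#' @return data.frame `pfam_acc`, logical `secreted`, `secreted_status`,
#'   `secreted_fraction` (NA when untested).
#' @export
secretion_filter <- function(candidates, assignments, genomes,
                             min_fraction = 0.5) {
  genomes <- validate_genomes(genomes)
  target_ids <- genome_sets(genomes)$target
  a <- assignments[assignments$genome_id %in% target_ids &
                     assignments$pfam_acc %in% candidates &
                     !is.na(assignments$signal_peptide), ]
  frac <- rep(NA_real_, length(candidates))
  if (nrow(a) > 0L) {
    n_known <- tapply(a$signal_peptide, a$pfam_acc, length)
    n_flag <- tapply(a$signal_peptide, a$pfam_acc, sum)
    frac <- as.numeric((n_flag / n_known)[candidates])
  }
  status <- ifelse(is.na(frac), "untested",
                   ifelse(frac >= min_fraction, "pass", "fail"))
  data.frame(
    pfam_acc = candidates,
    secreted = status == "pass",
    secreted_status = status,
    secreted_fraction = frac,
    stringsAsFactors = FALSE
  )
}

#' Designate plant-interaction determinant (PID) families
#'
#' Combines the quartile screen with the three evidence filters. A Pfam is
#' a PID when it is over-represented and meets at least one of the EXP, LPD
#' and secretion criteria. Pfams in the screening universe that are not
#' over-represented are retained in the table with `is_pid = FALSE`.
#'
#' @param screen Result of [quartile_screen()].
#' @param exp Result of [exp_filter()] on the same universe.
#' @param lpd Result of [lpd_filter()] on the same universe.
#' @param secreted Result of [secretion_filter()] on the same universe.
#' @return data.frame with one row per universe Pfam: `pfam_acc`,
#'   `overrepresented`, the three criterion flags with their status and
#'   quantitative columns, `n_criteria` (0-3), `is_pid`, and
#'   `antismash_tagged` (all FALSE until [antismash_crossref()]).
#' @export
designate_pid <- function(screen, exp, lpd, secreted) {
  universe <- screen$pfam_acc
  for (nm in c("exp", "lpd", "secreted")) {
    tab <- get(nm)
    missing <- setdiff(universe, tab$pfam_acc)
    if (length(missing) > 0L) {
      stop(sprintf("%s filter output lacks accession(s): %s", nm,
                   paste(utils::head(sort(missing), 10L), collapse = ", ")))
    }
  }
  ei <- match(universe, exp$pfam_acc)
  li <- match(universe, lpd$pfam_acc)
  si <- match(universe, secreted$pfam_acc)
  out <- data.frame(
    pfam_acc = universe,
    overrepresented = screen$selected,
    exp = exp$exp[ei],
    lpd = lpd$lpd[li],
    secreted = secreted$secreted[si],
    stringsAsFactors = FALSE
  )
  out$n_criteria <- out$exp + out$lpd + out$secreted
  out$is_pid <- out$overrepresented & out$n_criteria >= 1L
  out$antismash_tagged <- FALSE
  out$exp_status <- exp$exp_status[ei]
  out$exp_best_log2fc <- exp$exp_best_log2fc[ei]
  out$lpd_status <- lpd$lpd_status[li]
  out$lpd_mode <- lpd$lpd_mode[li]
  out$euk_fraction <- lpd$euk_fraction[li]
  out$secreted_status <- secreted$secreted_status[si]
  out$secreted_fraction <- secreted$secreted_fraction[si]
  rownames(out) <- NULL
  out
}

#' Tag PID records against a reference Pfam list (e.g. AntiSMASH)
#'
#' Sets `antismash_tagged` by membership of the accession in a
#' user-supplied reference list, as used to flag candidate involvement in
#' secondary-metabolite synthesis or degradation.
#'
#' @param records Result of [designate_pid()].
#' @param reference_pfams Character vector of reference accessions.
#' @return `records` with `antismash_tagged` updated.
#' @export
antismash_crossref <- function(records, reference_pfams) {
  if (length(reference_pfams) == 0L) {
    warning("empty reference Pfam list; no records tagged")
    records$antismash_tagged <- FALSE
    return(records)
  }
  records$antismash_tagged <-
    records$pfam_acc %in% strip_pfam_version(reference_pfams)
  records
}

#' Summary counts for a PID table
#' @param records Result of [designate_pid()].
#' @return Named integer vector: universe size, over-represented, PIDs, and
#'   PIDs meeting >= 2 and all 3 criteria, and tagged PIDs.
#' @export
pid_summary <- function(records) {
  pid <- records[records$is_pid, ]
  c(
    universe = nrow(records),
    overrepresented = sum(records$overrepresented),
    pid = nrow(pid),
    pid_ge2 = sum(pid$n_criteria >= 2L),
    pid_eq3 = sum(pid$n_criteria == 3L),
    pid_antismash = sum(pid$antismash_tagged)
  )
}
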