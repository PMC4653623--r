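#' Configuration for the synthetic genome-annotation generator
#'
#' Defines a two-set genome collection with three planted Pfam classes:
#' `SPECIFIC` families present in most target genomes and absent from
#' controls (the presence-absence structure the quartile screen detects),
#' `EXPANDED` families present in both sets with a multiplied mean copy
#' number in the target set (the copy-number structure the pairwise Fisher
#' scan detects), and `NULL` families identically distributed across sets.
#' Conditional on presence in a genome, a family's gene count is
#' `1 + Poisson(lambda)`; presence is Bernoulli per genome. Evidence-layer
#' ground truth (induced, secreted, eukaryal-dominant families and operon
#' pairs) is planted on subsets of the `SPECIFIC` class.
#'
#' Default scales: null families average 4 genes per carrying genome
#' (small ordinary families); expanded families average 20 in controls and
#' `expansion_ratio` times that in targets, emulating large paralogous
#' transporter/regulator families, the class where lifestyle-specific
#' expansions occur; specific families average 2 (accessory
#' symbiosis-style genes).
#'
#' @param n_target,n_control Genomes per set (default 40 / 20).
#' @param n_pfams Total families (default 500).
#' @param n_specific,n_expanded,n_null Class sizes (default 20/20/460;
#'   must sum to `n_pfams`).
#' @param p_specific_target,p_specific_control,p_expanded,p_null
#'   Per-genome presence probabilities (defaults 0.9, 0, 0.9, 0.6).
#' @param mean_specific,mean_null Mean gene count per carrying genome for
#'   the specific and null classes (defaults 2 and 4; both >= 1).
#' @param mean_expanded_control Expanded-class mean count in control
#'   genomes (default 20).
#' @param expansion_ratio Target/control mean-count ratio for the expanded
#'   class (default 5).
#' @param n_induced,n_secreted,n_eukaryal Number of SPECIFIC families
#'   planted with each evidence flag (default 10 each; overlapping subsets
#'   drawn at random).
#' @param induced_log2fc_range Uniform range of log2 fold changes for
#'   member genes of induced families (default c(2, 8)).
#' @param background_log2fc_sd SD of the zero-centred normal log2fc noise
#'   for non-induced genes (default 0.3).
#' @param expression_coverage Fraction of non-induced target-set genes
#'   appearing in the expression tables (default 0.3).
#' @param n_studies Number of expression studies (default 4).
#' @param p_signal_planted,p_signal_background Per-gene signal-peptide flag
#'   probability for planted-secreted vs other families (defaults 0.8,
#'   0.1).
#' @param euk_frac_planted,euk_frac_background Uniform ranges for the
#'   eukaryal sequence fraction (defaults c(0.8, 0.95) and c(0, 0.3)).
#' @param prok_lineages_planted,prok_lineages_background Ranges (integer
#'   length-2) for the number of non-focal prokaryotic lineages (defaults
#'   c(0, 2) and c(15, 40)).
#' @param phylo_total Approximate total known sequences per family in the
#'   phylogenetic-distribution table (default 500).
#' @param n_operon_pairs Number of SPECIFIC-family pairs planted at
#'   adjacent gene ranks (default 2).
#' @param genes_per_genome Nominal genes per genome; gene ranks are drawn
#'   from a single replicon of this length (default 6000).
#' @param seed Integer seed; mandatory for reproducibility (default 42).
#' @return A `pid_sim_config` list.
#' @export
sim_config <- function(n_target = 40L, n_control = 20L, n_pfams = 500L,
                       n_specific = 20L, n_expanded = 20L,
                       n_null = n_pfams - n_specific - n_expanded,
                       p_specific_target = 0.9, p_specific_control = 0,
                       p_expanded = 0.9, p_null = 0.6,
                       mean_specific = 2, mean_null = 4,
                       mean_expanded_control = 20, expansion_ratio = 5,
                       n_induced = 10L, n_secreted = 10L, n_eukaryal = 10L,
                       induced_log2fc_range = c(2, 8),
                       background_log2fc_sd = 0.3,
                       expression_coverage = 0.3, n_studies = 4L,
                       p_signal_planted = 0.8, p_signal_background = 0.1,
                       euk_frac_planted = c(0.8, 0.95),
                       euk_frac_background = c(0, 0.3),
                       prok_lineages_planted = c(0L, 2L),
                       prok_lineages_background = c(15L, 40L),
                       phylo_total = 500L, n_operon_pairs = 2L,
                       genes_per_genome = 6000L, seed = 42L) {
  cfg <- as.list(environment())
  if (cfg$n_specific + cfg$n_expanded + cfg$n_null != cfg$n_pfams) {
    stop("class sizes must sum to n_pfams")
  }
  probs <- c(p_specific_target, p_specific_control, p_expanded, p_null)
  if (any(probs < 0 | probs > 1)) stop("presence probabilities must be in [0, 1]")
  if (any(c(mean_specific, mean_null, mean_expanded_control) < 1)) {
    stop("conditional mean counts must be >= 1 (counts are 1 + Poisson)")
  }
  if (expansion_ratio <= 1) stop("expansion_ratio must be > 1")
  if (max(c(n_induced, n_secreted, n_eukaryal, 2L * n_operon_pairs)) >
      n_specific) {
    stop("planted evidence classes must fit within the SPECIFIC families")
  }
  structure(cfg, class = "pid_sim_config")
}

#' Generate a synthetic input bundle with planted ground truth
#'
#' Draws a complete, reader-compatible input bundle — genome metadata, gene
#' assignments with coordinates and signal-peptide flags, expression
#' tables, phylogenetic distributions — together with the per-family ground
#' truth, deterministically for a given configuration and seed.
#'
#' @param config A [sim_config()] object.
#' @return List with data.frames `genomes`, `assignments`, `expression`,
#'   `phylo`, `ground_truth`, `operon_pairs`, plus the `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "pid_sim_config"))
  set.seed(config$seed)
  cfg <- config

  pfams <- sprintf("PF9%04d", seq_len(cfg$n_pfams))
  classes <- rep(c("SPECIFIC", "EXPANDED", "NULL"),
                 c(cfg$n_specific, cfg$n_expanded, cfg$n_null))
  specific <- pfams[classes == "SPECIFIC"]

  induced_fams <- sample(specific, cfg$n_induced)
  secreted_fams <- sample(specific, cfg$n_secreted)
  eukaryal_fams <- sample(specific, cfg$n_eukaryal)
  operon_members <- sample(specific, 2L * cfg$n_operon_pairs)
  operon_pairs <- if (cfg$n_operon_pairs > 0L) {
    data.frame(
      pfam_a = operon_members[seq_len(cfg$n_operon_pairs) * 2L - 1L],
      pfam_b = operon_members[seq_len(cfg$n_operon_pairs) * 2L],
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(pfam_a = character(0), pfam_b = character(0))
  }

  gids <- c(sprintf("T%03d", seq_len(cfg$n_target)),
            sprintf("C%03d", seq_len(cfg$n_control)))
  set_label <- rep(c("TARGET", "CONTROL"), c(cfg$n_target, cfg$n_control))
  genomes <- data.frame(
    genome_id = gids,
    set_label = set_label,
    total_genes = pmax(
      cfg$genes_per_genome,
      as.integer(round(stats::rnorm(length(gids), cfg$genes_per_genome * 1.1,
                                    cfg$genes_per_genome * 0.05)))
    ),
    lineage = ifelse(
      set_label == "TARGET",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Rhizobiaceae",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Other"
    ),
    stringsAsFactors = FALSE
  )

  # per-family presence probability and conditional Poisson mean, by set
  p_target <- c(SPECIFIC = cfg$p_specific_target, EXPANDED = cfg$p_expanded,
                "NULL" = cfg$p_null)[classes]
  p_control <- c(SPECIFIC = cfg$p_specific_control, EXPANDED = cfg$p_expanded,
                 "NULL" = cfg$p_null)[classes]
  mean_target <- c(SPECIFIC = cfg$mean_specific,
                   EXPANDED = cfg$mean_expanded_control * cfg$expansion_ratio,
                   "NULL" = cfg$mean_null)[classes]
  mean_control <- c(SPECIFIC = cfg$mean_specific,
                    EXPANDED = cfg$mean_expanded_control,
                    "NULL" = cfg$mean_null)[classes]

  draw_counts <- function(p, mu, n_genomes) {
    present <- matrix(
      stats::rbinom(length(p) * n_genomes, 1L, rep(p, n_genomes)),
      nrow = length(p)
    )
    counts <- matrix(
      1L + stats::rpois(length(p) * n_genomes, rep(mu - 1, n_genomes)),
      nrow = length(p)
    )
    present * counts
  }
  counts <- cbind(draw_counts(p_target, mean_target, cfg$n_target),
                  draw_counts(p_control, mean_control, cfg$n_control))
  dimnames(counts) <- list(pfams, gids)

  is_secreted_fam <- pfams %in% secreted_fams
  assignments <- vector("list", length(gids))
  for (gi in seq_along(gids)) {
    g <- gids[gi]
    k <- counts[, gi]
    fam <- rep(pfams, k)
    n_genes <- length(fam)
    if (n_genes == 0L) {
      assignments[[gi]] <- empty_assignments()
      next
    }
    if (n_genes > cfg$genes_per_genome) {
      stop("genome ", g, " drew more Pfam genes than genes_per_genome")
    }
    rank <- sample.int(cfg$genes_per_genome, n_genes) - 1L
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    df <- data.frame(
      gene_id = sprintf("%s_g%05d", g, seq_len(n_genes)),
      genome_id = g, pfam_acc = fam, replicon_id = "chr1",
      gene_index = rank, strand = strand,
      signal_peptide = stats::runif(n_genes) <
        ifelse(is_secreted_fam[match(fam, pfams)],
               cfg$p_signal_planted, cfg$p_signal_background),
      stringsAsFactors = FALSE
    )
    # pin one gene pair of each planted operon at adjacent ranks, shared
    # strand, pfam_a upstream of pfam_b on the coding strand
    for (r in seq_len(nrow(operon_pairs))) {
      ia <- which(df$pfam_acc == operon_pairs$pfam_a[r])
      ib <- which(df$pfam_acc == operon_pairs$pfam_b[r])
      if (length(ia) == 0L || length(ib) == 0L) next
      ia <- ia[1L]; ib <- ib[1L]
      repeat {
        start <- sample.int(cfg$genes_per_genome - 1L, 1L) - 1L
        taken <- df$gene_index[-c(ia, ib)]
        if (!(start %in% taken) && !((start + 1L) %in% taken)) break
      }
      s <- sample(c("+", "-"), 1L)
      df$strand[c(ia, ib)] <- s
      if (s == "+") {
        df$gene_index[ia] <- start
        df$gene_index[ib] <- start + 1L
      } else {
        df$gene_index[ia] <- start + 1L
        df$gene_index[ib] <- start
      }
    }
    assignments[[gi]] <- df
  }
  assignments <- do.call(rbind, assignments)
  rownames(assignments) <- NULL

  # expression: every member gene of an induced family (target set) is
  # measured induced in one study; a background sample of other target
  # genes carries zero-centred noise
  tgt <- assignments$genome_id %in% gids[set_label == "TARGET"]
  ind_gene <- tgt & assignments$pfam_acc %in% induced_fams
  bg_gene <- which(tgt & !ind_gene)
  bg_pick <- sort(sample(bg_gene,
                         round(cfg$expression_coverage * length(bg_gene))))
  studies <- sprintf("study%d", seq_len(cfg$n_studies))
  expression <- rbind(
    data.frame(
      gene_id = assignments$gene_id[ind_gene],
      study_id = sample(studies, sum(ind_gene), replace = TRUE),
      log2fc = stats::runif(sum(ind_gene), cfg$induced_log2fc_range[1L],
                            cfg$induced_log2fc_range[2L]),
      stringsAsFactors = FALSE
    ),
    data.frame(
      gene_id = assignments$gene_id[bg_pick],
      study_id = sample(studies, length(bg_pick), replace = TRUE),
      log2fc = stats::rnorm(length(bg_pick), 0, cfg$background_log2fc_sd),
      stringsAsFactors = FALSE
    )
  )
  rownames(expression) <- NULL

  lineage_pool <- sprintf("Lineage%02d", seq_len(50L))
  is_euk_fam <- pfams %in% eukaryal_fams
  euk_frac <- ifelse(
    is_euk_fam,
    stats::runif(cfg$n_pfams, cfg$euk_frac_planted[1L],
                 cfg$euk_frac_planted[2L]),
    stats::runif(cfg$n_pfams, cfg$euk_frac_background[1L],
                 cfg$euk_frac_background[2L])
  )
  n_lin <- ifelse(
    is_euk_fam,
    sample(cfg$prok_lineages_planted[1L]:cfg$prok_lineages_planted[2L],
           cfg$n_pfams, replace = TRUE),
    sample(cfg$prok_lineages_background[1L]:cfg$prok_lineages_background[2L],
           cfg$n_pfams, replace = TRUE)
  )
  prok_lineages <- vapply(seq_len(cfg$n_pfams), function(i) {
    paste(c("Rhizobiaceae", sample(lineage_pool, n_lin[i])), collapse = ";")
  }, character(1L))
  total_seqs <- stats::rpois(cfg$n_pfams, cfg$phylo_total)
  n_euk <- as.integer(round(euk_frac * total_seqs))
  n_arch <- stats::rbinom(cfg$n_pfams, total_seqs - n_euk, 0.05)
  phylo <- data.frame(
    pfam_acc = pfams,
    n_eukarya = n_euk,
    n_bacteria = total_seqs - n_euk - n_arch,
    n_archaea = n_arch,
    prok_lineages = prok_lineages,
    stringsAsFactors = FALSE
  )

  ground_truth <- data.frame(
    pfam_acc = pfams,
    class = classes,
    induced = pfams %in% induced_fams,
    secreted = pfams %in% secreted_fams,
    eukaryal = pfams %in% eukaryal_fams,
    operon_member = pfams %in% operon_members,
    stringsAsFactors = FALSE
  )

  list(
    config = cfg, genomes = genomes, assignments = assignments,
    expression = expression, phylo = phylo, ground_truth = ground_truth,
    operon_pairs = operon_pairs
  )
}

#' Write a synthetic bundle to the pipeline's TSV dialects
#' @param bundle Result of [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genomes(bundle$genomes, file.path(dir, "genomes.tsv"))
  write_assignments(bundle$assignments, file.path(dir, "assignments.tsv"))
  write_tsv_plain(bundle$expression, file.path(dir, "expression.tsv"))
  write_tsv_plain(bundle$phylo, file.path(dir, "phylo.tsv"))
  write_tsv_plain(bundle$ground_truth, file.path(dir, "ground_truth.tsv"))
  write_tsv_plain(bundle$operon_pairs, file.path(dir, "operon_pairs.tsv"))
  invisible(dir)
}
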