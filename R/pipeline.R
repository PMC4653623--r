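#' Default pipeline configuration
#'
#' All analysis thresholds live in one configuration object with the
#' published screen's values as defaults; a run can either name input files
#' (`inputs`) or request synthetic data (`simulate`, passed to
#' [sim_config()]).
#'
#' @param inputs Named list of input paths: `genomes`, `assignments`
#'   (mandatory unless simulating), optional `expression`, `phylo`,
#'   `antismash_pfams`, `operon_pairs`.
#' @param simulate `NULL`, or a named list of [sim_config()] overrides
#'   (e.g. `list(seed = 1)`).
#' @param params Named list of threshold overrides; see Details.
#' @details Threshold parameters and defaults: `target_median_min` (1),
#'   `control_median_max` (0), `alpha` (0.05), `min_fraction` (0.25),
#'   `bh_family` ("per_pair"), `require_direction` (TRUE), `min_log2fc`
#'   (1), `min_euk_fraction` (0.75), `max_prok_lineages` (5),
#'   `focal_lineages` ("Rhizobiaceae"), `secretion_min_fraction` (0.5),
#'   `max_gene_gap` (2), `require_same_strand` (TRUE), `filters_enabled`
#'   (TRUE).
#' @return A `pid_config` list.
#' @export
pipeline_config <- function(inputs = list(), simulate = NULL,
                            params = list()) {
  defaults <- list(
    target_median_min = 1, control_median_max = 0,
    alpha = 0.05, min_fraction = 0.25,
    bh_family = "per_pair", require_direction = TRUE,
    min_log2fc = 1, min_euk_fraction = 0.75, max_prok_lineages = 5L,
    focal_lineages = "Rhizobiaceae", secretion_min_fraction = 0.5,
    max_gene_gap = 2L, require_same_strand = TRUE, filters_enabled = TRUE
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(params)] <- params
  structure(list(inputs = inputs, simulate = simulate, params = defaults),
            class = "pid_config")
}

#' Read a pipeline configuration from YAML
#' @param path Path to a YAML file with optional `inputs`, `simulate` and
#'   `params` blocks.
#' @return A `pid_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    inputs = if (is.null(y$inputs)) list() else y$inputs,
    simulate = y$simulate,
    params = if (is.null(y$params)) list() else y$params
  )
}

# Polynomial rolling hash (mod 2^31 - 1) over a canonical JSON rendering;
# stamps every output so a results file can be traced to the exact
# configuration that produced it.
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                     force = TRUE))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full screening pipeline
#'
#' Wires the stages end to end: input reading (or synthetic generation),
#' count-matrix construction, quartile screen, normalization diagnostic,
#' pairwise Fisher enrichment, evidence filters and PID designation,
#' co-localization scan, overlap report, manifest and summary. Outputs are
#' deterministic: rerunning with an identical configuration (and seed, when
#' simulating) reproduces every file byte for byte.
#'
#' @param config A `pid_config` (see [pipeline_config()]) or the path to a
#'   YAML configuration file.
#' @param outdir Output directory, created if absent.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pid_config"))
  p <- config$params
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  hdr <- paste0("config_hash: ", hash)
  manifest <- list(
    tool = "pidscreen",
    version = as.character(utils::packageVersion("pidscreen")),
    config_hash = hash,
    config = config[c("inputs", "simulate", "params")],
    status = "running", failed_stage = NULL,
    input_checksums = list(), counts = list()
  )
  stage <- "inputs"
  fail <- function(e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    write_manifest(manifest, outdir)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (!is.null(config$simulate)) {
      sim <- do.call(sim_config, config$simulate)
      bundle <- generate_dataset(sim)
      write_dataset(bundle, file.path(outdir, "inputs"))
      genomes <- bundle$genomes
      assignments <- bundle$assignments
      expression <- bundle$expression
      phylo <- bundle$phylo
      antismash <- character(0)
      pairs <- bundle$operon_pairs
    } else {
      for (need in c("genomes", "assignments")) {
        path <- config$inputs[[need]]
        if (is.null(path) || !file.exists(path)) {
          stop("mandatory input '", need, "' missing")
        }
      }
      genomes <- read_genomes(config$inputs$genomes)
      assignments <- read_assignments(config$inputs$assignments)
      expression <- maybe_read(config$inputs$expression, read_expression)
      phylo <- maybe_read(config$inputs$phylo, read_phylo)
      antismash <- maybe_read(config$inputs$antismash_pfams, read_pfam_list)
      if (is.null(antismash)) antismash <- character(0)
      pairs <- maybe_read(config$inputs$operon_pairs, function(f) {
        read_tsv_checked(f, c("pfam_a", "pfam_b"))
      })
      manifest$input_checksums <- input_checksums(config$inputs)
    }
    log_stage("inputs", nrow(assignments), "assignments")

    stage <- "count_matrix"
    m <- build_count_matrix(assignments, genomes)
    write_count_matrix(m, file.path(outdir, "count_matrix.tsv"), header = hdr)
    manifest$counts$pfams_total <- nrow(m)
    manifest$counts$genomes <- ncol(m)
    log_stage(stage, nrow(m), "Pfams")

    stage <- "screen"
    screen <- quartile_screen(m, genomes,
                              target_median_min = p$target_median_min,
                              control_median_max = p$control_median_max)
    write_screen_results(screen, file.path(outdir, "screen_results.tsv"),
                         header = hdr)
    manifest$counts$universe <- nrow(screen)
    manifest$counts$overrepresented <- sum(screen$selected)
    log_stage(stage, sum(screen$selected), "over-represented Pfams")

    stage <- "normalization_diagnostic"
    nd <- normalization_diagnostic(m, genomes)
    write_tsv_plain(nd$table,
                    file.path(outdir, "normalization_diagnostic.tsv"),
                    header = c(hdr, sprintf("spearman_rho: %.6f",
                                            nd$spearman_rho)))
    manifest$counts$normalization_spearman_rho <- nd$spearman_rho
    log_stage(stage, sprintf("rho=%.3f", nd$spearman_rho), "")

    stage <- "enrichment"
    enrich <- pairwise_enrichment(
      m, genomes, alpha = p$alpha, min_fraction = p$min_fraction,
      require_direction = p$require_direction, bh_family = p$bh_family
    )
    write_enrichment_results(
      enrich, file.path(outdir, "enrichment_results.tsv"),
      header = c(hdr, paste0("bh_family: ", p$bh_family))
    )
    manifest$counts$enriched <- sum(enrich$selected)
    log_stage(stage, sum(enrich$selected), "enriched Pfams")

    stage <- "filters"
    universe <- screen$pfam_acc
    if (isTRUE(p$filters_enabled)) {
      exp_res <- exp_filter(
        universe, assignments,
        if (is.null(expression)) empty_expression() else expression,
        min_log2fc = p$min_log2fc
      )
      lpd_res <- lpd_filter(
        universe, if (is.null(phylo)) empty_phylo() else phylo,
        min_euk_fraction = p$min_euk_fraction,
        max_prok_lineages = p$max_prok_lineages,
        focal_lineages = p$focal_lineages
      )
      sec_res <- secretion_filter(universe, assignments, genomes,
                                  min_fraction = p$secretion_min_fraction)
    } else {
      exp_res <- exp_filter(universe, assignments, empty_expression())
      lpd_res <- lpd_filter(universe, empty_phylo())
      sec_res <- secretion_filter(universe, empty_assignments(), genomes)
    }
    pid <- designate_pid(screen, exp_res, lpd_res, sec_res)
    pid <- antismash_crossref_quiet(pid, antismash)
    write_tsv_plain(pid, file.path(outdir, "pid_results.tsv"), header = hdr)
    s <- pid_summary(pid)
    manifest$counts$pid <- unname(s[["pid"]])
    manifest$counts$pid_ge2 <- unname(s[["pid_ge2"]])
    manifest$counts$pid_eq3 <- unname(s[["pid_eq3"]])
    manifest$counts$pid_antismash <- unname(s[["pid_antismash"]])
    log_stage(stage, s[["pid"]], "PID Pfams")

    stage <- "colocalization"
    if (!is.null(pairs) && nrow(pairs) > 0L) {
      colocal <- suppressMessages(colocalization_scan(
        assignments, pairs, max_gene_gap = p$max_gene_gap,
        require_same_strand = p$require_same_strand
      ))
    } else {
      colocal <- colocalization_scan(empty_assignments(),
                                     data.frame(pfam_a = character(0),
                                                pfam_b = character(0)))
    }
    write_colocal_results(colocal,
                          file.path(outdir, "colocalization_results.tsv"),
                          header = hdr)
    manifest$counts$colocal_pairs <- nrow(colocal)
    log_stage(stage, nrow(colocal), "pairs scanned")

    stage <- "overlap"
    ov <- overlap_report(screen, enrich)
    manifest$counts$overlap_both <- ov$n_both
    jsonlite::write_json(ov, file.path(outdir, "overlap_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    stage <- "manifest"
    manifest$status <- "ok"
    write_manifest(manifest, outdir)
    summarize_run(outdir)
    invisible(list(matrix = m, screen = screen, enrichment = enrich,
                   pid = pid, colocal = colocal, overlap = ov,
                   normalization = nd, manifest = manifest))
  }, error = fail)
}

antismash_crossref_quiet <- function(pid, antismash) {
  if (length(antismash) == 0L) {
    pid$antismash_tagged <- FALSE
    pid
  } else {
    antismash_crossref(pid, antismash)
  }
}

maybe_read <- function(path, reader) {
  if (is.null(path)) return(NULL)
  if (!file.exists(path)) stop("input file not found: ", path)
  reader(path)
}

empty_expression <- function() {
  data.frame(gene_id = character(0), study_id = character(0),
             log2fc = numeric(0), stringsAsFactors = FALSE)
}

empty_phylo <- function() {
  data.frame(pfam_acc = character(0), n_eukarya = integer(0),
             n_bacteria = integer(0), n_archaea = integer(0),
             prok_lineages = character(0), stringsAsFactors = FALSE)
}

input_checksums <- function(inputs) {
  paths <- unlist(inputs[vapply(inputs, is.character, logical(1L))])
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) return(list())
  as.list(tools::md5sum(paths))
}

log_stage <- function(stage, n, what) {
  message(sprintf("[pidscreen] %-26s %s %s", stage, n, what))
}

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Summarize a completed run directory
#'
#' Renders a human-readable markdown report of the selection funnel, the
#' top candidates per criterion and the normalization diagnostic from the
#' TSVs a pipeline run wrote. Regeneration is idempotent.
#'
#' @param outdir A completed [run_pipeline()] output directory.
#' @return Invisibly, the path of the written `summary.md`.
#' @export
summarize_run <- function(outdir) {
  need <- c("run_manifest.json", "screen_results.tsv",
            "enrichment_results.tsv", "pid_results.tsv",
            "normalization_diagnostic.tsv")
  missing <- need[!file.exists(file.path(outdir, need))]
  if (length(missing) > 0L) {
    stop("incomplete run directory; missing: ",
         paste(missing, collapse = ", "))
  }
  man <- jsonlite::read_json(file.path(outdir, "run_manifest.json"))
  screen <- utils::read.delim(file.path(outdir, "screen_results.tsv"),
                              comment.char = "#")
  enrich <- utils::read.delim(file.path(outdir, "enrichment_results.tsv"),
                              comment.char = "#")
  pid <- utils::read.delim(file.path(outdir, "pid_results.tsv"),
                           comment.char = "#")
  cnt <- man$counts
  pid_sel <- pid[pid$is_pid, ]
  lines <- c(
    "# pidscreen run summary",
    "",
    paste0("Configuration hash: `", man$config_hash, "`"),
    "",
    "## Selection funnel",
    "",
    sprintf("- Pfams in screening universe: %d", cnt$universe),
    sprintf("- Over-represented (quartile screen): %d",
            cnt$overrepresented),
    sprintf("- Enriched (pairwise Fisher scan): %d", cnt$enriched),
    sprintf("- Overlap of the two selected sets: %d", cnt$overlap_both),
    sprintf("- PID (over-represented with >= 1 criterion): %d", cnt$pid),
    sprintf("  - meeting >= 2 criteria: %d; all 3 criteria: %d",
            cnt$pid_ge2, cnt$pid_eq3),
    "",
    "## Normalization diagnostic",
    "",
    sprintf(paste0("Spearman correlation between per-genome Pfam hits and",
                   " genome size: %.3f. Raw counts were contrasted without",
                   " genome-size normalization."),
            as.numeric(cnt$normalization_spearman_rho)),
    "",
    "## Top over-represented Pfams (by target median)",
    "",
    md_table(utils::head(
      screen[screen$selected,
             c("pfam_acc", "target_q2", "control_q2")], 10L)),
    "",
    "## Top enriched Pfams (by significant pair fraction)",
    "",
    md_table(utils::head(
      enrich[enrich$selected,
             c("pfam_acc", "n_significant", "significant_fraction")], 10L)),
    "",
    "## PID candidates",
    "",
    if (nrow(pid_sel) > 0L) {
      md_table(utils::head(
        pid_sel[c("pfam_acc", "exp", "lpd", "secreted", "n_criteria")], 20L))
    } else {
      "No Pfam met the PID designation in this run."
    }
  )
  path <- file.path(outdir, "summary.md")
  writeLines(lines, path)
  invisible(path)
}

md_table <- function(df) {
  if (nrow(df) == 0L) return("(none)")
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) formatC(x, digits = 4, format = "g")
    else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  paste(c(
    paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  ), collapse = "\n")
}
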