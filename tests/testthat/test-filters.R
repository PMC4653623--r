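mini_assignments <- function(pfam, genes, genome = "T01", sp = NA) {
  data.frame(gene_id = genes, genome_id = genome, pfam_acc = pfam,
             replicon_id = NA_character_, gene_index = NA_integer_,
             strand = NA_character_, signal_peptide = sp,
             stringsAsFactors = FALSE)
}

test_that("EXP filter distinguishes pass, fail and untested", {
  a <- rbind(mini_assignments("PF1", "g1"), mini_assignments("PF2", "g2"),
             mini_assignments("PF3", "g3"))
  ex <- data.frame(gene_id = c("g1", "g2"), study_id = "s1",
                   log2fc = c(6.0, 0.5))
  r <- exp_filter(c("PF1", "PF2", "PF3"), a, ex)
  expect_equal(r$exp_status, c("pass", "fail", "untested"))
  expect_equal(r$exp, c(TRUE, FALSE, FALSE))
  expect_equal(r$exp_best_log2fc, c(6.0, 0.5, NA))
  # best across studies is taken; stricter threshold is monotone
  ex2 <- rbind(ex, data.frame(gene_id = "g2", study_id = "s2", log2fc = 1.4))
  r2 <- exp_filter(c("PF1", "PF2", "PF3"), a, ex2)
  expect_true(r2$exp[2])
  r3 <- exp_filter(c("PF1", "PF2", "PF3"), a, ex2, min_log2fc = 2)
  expect_true(all(which(r3$exp) %in% which(r2$exp)))
})

test_that("LPD filter passes via eukaryal dominance or lineage restriction", {
  phylo <- data.frame(
    pfam_acc = c("PF1", "PF2", "PF3", "PF4"),
    n_eukarya = c(80L, 10L, 10L, 0L),
    n_bacteria = c(20L, 88L, 88L, 0L),
    n_archaea = c(0L, 2L, 2L, 0L),
    prok_lineages = c("Rhizobiaceae",
                      paste(sprintf("Lin%02d", 1:50), collapse = ";"),
                      "Rhizobiaceae;Brucellaceae;Bartonellaceae",
                      ""),
    stringsAsFactors = FALSE
  )
  r <- lpd_filter(c("PF1", "PF2", "PF3", "PF4", "PF5"), phylo)
  expect_equal(r$lpd_status,
               c("pass", "fail", "pass", "unknown", "unknown"))
  expect_equal(r$lpd_mode[1], "eukaryal")     # 80% eukaryal
  expect_equal(r$lpd_mode[3], "restricted")   # 2 non-focal lineages
  expect_equal(r$euk_fraction[1], 0.8)
  expect_false(any(r$lpd[4:5]))
  # stricter eukaryal threshold is monotone
  r2 <- lpd_filter(c("PF1", "PF2", "PF3"), phylo, min_euk_fraction = 0.9,
                   max_prok_lineages = 1)
  expect_true(all(which(r2$lpd) %in% which(r$lpd[1:3])))
})

test_that("secretion filter uses target-set genes and known flags only", {
  genomes <- make_genomes(1, 1)
  a <- rbind(
    mini_assignments("PF1", sprintf("g%d", 1:10), "T01",
                     sp = c(rep(TRUE, 6), rep(FALSE, 4))),
    mini_assignments("PF2", sprintf("h%d", 1:10), "T01",
                     sp = c(rep(TRUE, 5), rep(FALSE, 5))),
    mini_assignments("PF3", sprintf("i%d", 1:10), "T01", sp = FALSE),
    mini_assignments("PF4", sprintf("j%d", 1:4), "T01", sp = NA),
    # control-set genes are excluded from the denominator entirely
    mini_assignments("PF1", sprintf("k%d", 1:20), "C01", sp = FALSE)
  )
  r <- secretion_filter(c("PF1", "PF2", "PF3", "PF4"), a, genomes)
  expect_equal(r$secreted_fraction, c(0.6, 0.5, 0.0, NA))
  expect_equal(r$secreted, c(TRUE, TRUE, FALSE, FALSE))  # >= 50% inclusive
  expect_equal(r$secreted_status[4], "untested")
  # unknown flags excluded from the denominator, not counted as FALSE
  a2 <- rbind(mini_assignments("PF5", c("m1", "m2"), "T01", sp = c(TRUE, NA)))
  r2 <- secretion_filter("PF5", a2, genomes)
  expect_equal(r2$secreted_fraction, 1.0)
})

test_that("PID designation is overrepresented AND >= 1 criterion, exactly", {
  screen <- data.frame(
    pfam_acc = c("PF1", "PF2", "PF3", "PF4"),
    selected = c(TRUE, TRUE, FALSE, TRUE)
  )
  flags <- function(v) v
  exp <- data.frame(pfam_acc = screen$pfam_acc,
                    exp = c(TRUE, FALSE, TRUE, FALSE),
                    exp_status = "pass", exp_best_log2fc = NA)
  lpd <- data.frame(pfam_acc = screen$pfam_acc,
                    lpd = c(TRUE, FALSE, TRUE, FALSE),
                    lpd_status = "pass", lpd_mode = NA, euk_fraction = NA)
  sec <- data.frame(pfam_acc = screen$pfam_acc,
                    secreted = c(TRUE, FALSE, FALSE, FALSE),
                    secreted_status = "pass", secreted_fraction = NA)
  pid <- designate_pid(screen, exp, lpd, sec)
  expect_equal(pid$n_criteria, c(3L, 0L, 2L, 0L))
  expect_equal(pid$is_pid, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(pid$is_pid, pid$overrepresented & pid$n_criteria >= 1L)
  # key mismatch -> error listing missing accession
  expect_error(designate_pid(screen, exp[-2, ], lpd, sec), "PF2")
})

test_that("filters are order-independent in PID designation", {
  set.seed(41)
  b <- generate_dataset(sim_config(
    n_target = 6L, n_control = 4L, n_pfams = 30L, n_specific = 6L,
    n_expanded = 4L, n_induced = 3L, n_secreted = 3L, n_eukaryal = 3L,
    n_operon_pairs = 1L, genes_per_genome = 2000L, seed = 5L
  ))
  m <- build_count_matrix(b$assignments, b$genomes)
  s <- quartile_screen(m, b$genomes)
  u <- s$pfam_acc
  e <- exp_filter(u, b$assignments, b$expression)
  l <- lpd_filter(u, b$phylo)
  sc <- secretion_filter(u, b$assignments, b$genomes)
  p1 <- designate_pid(s, e, l, sc)
  # recompute filters on a shuffled universe: same records
  u2 <- sample(u)
  p2 <- designate_pid(s, exp_filter(u2, b$assignments, b$expression),
                      lpd_filter(u2, b$phylo),
                      secretion_filter(u2, b$assignments, b$genomes))
  expect_equal(p1, p2)
})

test_that("reference-list cross-tagging is exact set membership", {
  rec <- data.frame(pfam_acc = sprintf("PF%05d", 1:30),
                    antismash_tagged = FALSE)
  expect_warning(r0 <- antismash_crossref(rec, character(0)), "empty")
  expect_false(any(r0$antismash_tagged))
  set.seed(42)
  ref <- sample(sprintf("PF%05d", 1:60), 20)
  r <- antismash_crossref(rec, ref)
  expect_equal(sum(r$antismash_tagged),
               length(intersect(rec$pfam_acc, ref)))
  expect_setequal(r$pfam_acc[r$antismash_tagged],
                  intersect(rec$pfam_acc, ref))
})
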