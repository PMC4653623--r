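test_that("two-sided Fisher p matches enumeration oracle and fisher.test", {
  expect_equal(fisher_two_sided(0, 10, 0, 10), 1)
  # row swap symmetry
  expect_equal(fisher_two_sided(3, 7, 0, 10), fisher_two_sided(0, 10, 3, 7))
  # frozen from the enumeration oracle over margins (10,10)/(3,17)
  expect_equal(fisher_two_sided(3, 7, 0, 10),
               fisher_enum_oracle(3, 7, 0, 10), tolerance = 1e-12)
  expect_equal(fisher_two_sided(3, 7, 0, 10), 0.2105263, tolerance = 1e-6)
  set.seed(31)
  for (i in 1:200) {
    tb <- rpois(4, sample(c(2, 8, 25), 1))
    p <- fisher_two_sided(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, fisher_enum_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    if (sum(tb) > 0 && (tb[1] + tb[2]) > 0 && (tb[3] + tb[4]) > 0) {
      ft <- fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
      expect_equal(p, ft, tolerance = 1e-7)
    }
  }
  expect_error(fisher_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  set.seed(32)
  for (i in 1:50) {
    p <- runif(sample(500, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p & q <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise enrichment matches a direct per-pair recomputation", {
  set.seed(33)
  genomes <- make_genomes(3, 2)
  m <- matrix(rpois(8 * 5, 3) + 1L, nrow = 8,
              dimnames = list(sprintf("PF%05d", 1:8), genomes$genome_id))
  m[1, 1:3] <- m[1, 1:3] + 20L   # one clearly expanded family
  storage.mode(m) <- "integer"
  res <- pairwise_enrichment(m, genomes)

  # independent route: fisher.test + p.adjust per pair
  tcols <- genomes$genome_id[genomes$set_label == "TARGET"]
  ccols <- genomes$genome_id[genomes$set_label == "CONTROL"]
  tot <- colSums(m)
  n_sig <- setNames(integer(nrow(m)), rownames(m))
  for (tg in tcols) for (cg in ccols) {
    p <- sapply(rownames(m), function(pf) {
      fisher.test(matrix(c(m[pf, tg], tot[tg] - m[pf, tg],
                           m[pf, cg], tot[cg] - m[pf, cg]), 2,
                         byrow = TRUE))$p.value
    })
    sig <- p.adjust(p, "BH") < 0.05 &
      m[, tg] / tot[tg] > m[, cg] / tot[cg]
    n_sig <- n_sig + sig
  }
  expect_equal(res$n_significant[match(rownames(m), res$pfam_acc)],
               unname(n_sig))
  expect_true(all(res$n_pairs == length(tcols) * length(ccols)))
  expect_equal(res$significant_fraction, res$n_significant / res$n_pairs)
  expect_identical(res$selected, res$significant_fraction >= 0.25)
})

test_that("raising alpha or lowering min_fraction is monotone", {
  set.seed(34)
  genomes <- make_genomes(4, 3)
  m <- matrix(rpois(30 * 7, 2) + 1L, nrow = 30,
              dimnames = list(sprintf("PF%05d", 1:30), genomes$genome_id))
  m[1:3, 1:4] <- m[1:3, 1:4] * 6L
  storage.mode(m) <- "integer"
  lo <- pairwise_enrichment(m, genomes, alpha = 0.01)
  hi <- pairwise_enrichment(m, genomes, alpha = 0.10)
  key <- match(lo$pfam_acc, hi$pfam_acc)
  expect_true(all(hi$n_significant[key] >= lo$n_significant))
  strict <- pairwise_enrichment(m, genomes, min_fraction = 0.5)
  loose <- pairwise_enrichment(m, genomes, min_fraction = 0.1)
  expect_true(all(strict$pfam_acc[strict$selected] %in%
                    loose$pfam_acc[loose$selected]))
})

test_that("fully null data selects nothing in most replicates", {
  sizes <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    genomes <- make_genomes(8, 8)
    m <- matrix(rpois(100 * 16, 2) + 1L, nrow = 100,
                dimnames = list(sprintf("PF%05d", 1:100), genomes$genome_id))
    storage.mode(m) <- "integer"
    res <- pairwise_enrichment(m, genomes)
    sizes <- sizes + (sum(res$selected) > 0L)
  }
  expect_lte(sizes, 1L)   # 0 selected in >= 4 of 5 replicates
})

test_that("a zero-hit genome is reported by name", {
  genomes <- make_genomes(2, 1)
  m <- matrix(c(1L, 1L, 0L), nrow = 1,
              dimnames = list("PF00001", genomes$genome_id))
  expect_error(pairwise_enrichment(m, genomes), "C01")
})

test_that("normalization diagnostic reports Spearman rho and table", {
  genomes <- make_genomes(3, 2)
  genomes$total_genes <- c(1000L, 2000L, 3000L, 4000L, 5000L)
  # hits exactly proportional to genome size -> rho 1
  m <- matrix(rep(genomes$total_genes / 100, each = 2), nrow = 2,
              byrow = FALSE, dimnames = list(c("PF1", "PF2"),
                                             genomes$genome_id))
  storage.mode(m) <- "integer"
  nd <- normalization_diagnostic(m, genomes)
  expect_equal(nd$spearman_rho, 1)
  expect_equal(nd$table$pfam_hits, as.integer(colSums(m)))

  # identical hit totals across genomes of differing size -> defined as 0
  m2 <- matrix(5L, nrow = 2, ncol = 5,
               dimnames = list(c("PF1", "PF2"), genomes$genome_id))
  expect_warning(nd2 <- normalization_diagnostic(m2, genomes), "tied")
  expect_equal(nd2$spearman_rho, 0)

  # random genomes match a rank-then-Pearson oracle
  set.seed(35)
  g10 <- make_genomes(5, 5)
  g10$total_genes <- sample.int(9000L, 10L)
  m3 <- matrix(rpois(40 * 10, 3), nrow = 40,
               dimnames = list(sprintf("PF%05d", 1:40), g10$genome_id))
  storage.mode(m3) <- "integer"
  nd3 <- normalization_diagnostic(m3, g10)
  expect_equal(nd3$spearman_rho,
               cor(rank(g10$total_genes), rank(colSums(m3))),
               tolerance = 1e-12)
  expect_error(normalization_diagnostic(m3[, 1:2], g10[1:2, ]), ">= 3")
})

test_that("overlap report performs exact set algebra", {
  mk <- function(acc, sel) data.frame(pfam_acc = acc, selected = sel)
  ov <- overlap_report(mk(c("a", "b"), c(TRUE, TRUE)),
                       mk(c("c", "d"), c(TRUE, TRUE)))
  expect_equal(ov$n_both, 0L)
  ov2 <- overlap_report(mk(c("a", "b"), c(TRUE, TRUE)),
                        mk(c("a", "b"), c(TRUE, TRUE)))
  expect_equal(ov2$both, c("a", "b"))
  set.seed(36)
  acc <- sprintf("PF%05d", 1:50)
  s <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  e <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  ov3 <- overlap_report(mk(acc, s), mk(acc, e))
  expect_equal(ov3$n_both, sum(s & e))
  expect_setequal(ov3$overrepresented_only, acc[s & !e])
  expect_setequal(ov3$enriched_only, acc[!s & e])
})
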