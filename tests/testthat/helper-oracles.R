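# Independent oracles, kept deliberately separate from the package's own
# code paths: plain enumeration and direct formula transcriptions.

# Two-sided Fisher p by full enumeration over all tables with the observed
# margins; probabilities from log-binomial coefficients (not dhyper).
fisher_enum_oracle <- function(a, b, c, d, tie_tol = 1e-7) {
  n1 <- a + b
  n2 <- c + d
  k <- a + c
  if (k == 0 || k == n1 + n2 || n1 == 0 || n2 == 0) return(1)
  x <- max(0, k - n2):min(k, n1)
  logp <- lchoose(n1, x) + lchoose(n2, k - x) - lchoose(n1 + n2, k)
  prob <- exp(logp)
  obs <- prob[x == a]
  min(1, sum(prob[prob <= obs * (1 + tie_tol)]))
}

# Direct BH step-up: sort ascending, q_(i) = min_{j >= i} min(1, p_(j) m/j),
# returned in input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force (gene, Pfam) tally per genome, via loops over rows.
tally_oracle <- function(assignments, pfams, genomes) {
  m <- matrix(0L, length(pfams), length(genomes),
              dimnames = list(pfams, genomes))
  seen <- character(0)
  for (i in seq_len(nrow(assignments))) {
    key <- paste(assignments$gene_id[i], assignments$pfam_acc[i], sep = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    m[assignments$pfam_acc[i], assignments$genome_id[i]] <-
      m[assignments$pfam_acc[i], assignments$genome_id[i]] + 1L
  }
  m
}

# Sort-based median for the screen rule (linear-interpolation median of a
# sorted vector, written out directly).
median_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2L == 1L) x[(n + 1L) / 2L] else (x[n / 2L] + x[n / 2L + 1L]) / 2
}

# Random assignment table over given gene/genome/Pfam pools.
random_assignments <- function(n, genomes, pfams, genes_per_genome = 50L) {
  g <- sample(genomes, n, replace = TRUE)
  data.frame(
    gene_id = paste0(g, "_g", sample.int(genes_per_genome, n, replace = TRUE)),
    genome_id = g,
    pfam_acc = sample(pfams, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

make_genomes <- function(n_target, n_control, total_genes = 3000L) {
  data.frame(
    genome_id = c(sprintf("T%02d", seq_len(n_target)),
                  sprintf("C%02d", seq_len(n_control))),
    set_label = rep(c("TARGET", "CONTROL"), c(n_target, n_control)),
    total_genes = total_genes,
    lineage = NA_character_,
    stringsAsFactors = FALSE
  )
}
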