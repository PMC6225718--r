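# Generator contracts: determinism, degenerate configs, SFS shape,
# read-simulation error model, truth-table anchorability.

test_that("identical configs give byte-identical bundles", {
  cfg <- sim_config(seed = 7, n_genes = 15, n_accessions_A = 4,
                    n_accessions_B = 3)
  b1 <- simulate_dataset(cfg)
  b2 <- simulate_dataset(cfg)
  expect_identical(lapply(b1$transcripts, `[[`, "seq"),
                   lapply(b2$transcripts, `[[`, "seq"))
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$genomes$A$seq, b2$genomes$A$seq)
  r1 <- simulate_reads(b1$transcripts$A01, 5, 100, seed = 3)
  r2 <- simulate_reads(b2$transcripts$A01, 5, 100, seed = 3)
  expect_identical(r1, r2)
})

test_that("zero variant rates give identical accessions and empty truth", {
  cfg <- sim_config(seed = 2, n_genes = 8, n_accessions_A = 3,
                    n_accessions_B = 2, snp_rate_intra = 0,
                    indel_rate_intra = 0, divergence_AB = 0,
                    divergence_outgroup = 1e-9)
  b <- simulate_dataset(cfg)
  expect_equal(nrow(b$truth), 0)
  expect_identical(b$transcripts$A01$seq, b$transcripts$A02$seq)
  expect_identical(b$transcripts$A01$seq, b$transcripts$B01$seq)
})

test_that("config validation rejects bad panels and rate order", {
  expect_error(sim_config(n_accessions_A = 1), "at least 2")
  expect_error(sim_config(divergence_AB = 0.05, divergence_outgroup = 0.04),
               "must exceed")
  expect_error(sim_config(snp_rate_intra = 1.5), "0, 1")
  expect_error(sim_config(gene_length_range = c(100, 200)), "too short")
})

test_that("neutral SFS draws match the 1/i expectation", {
  n <- 10
  withr::with_seed(99, {
    draws <- sfs_sample(n, "neutral", 2000)
  })
  obs <- tabulate(draws, n - 1)
  p <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.01)
})

test_that("expansion and structured modes shift the singleton fraction", {
  n <- 10
  withr::with_seed(42, {
    neu <- mean(sfs_sample(n, "neutral", 1000) == 1)
    exps <- mean(sfs_sample(n, "expansion", 1000) == 1)
    str <- mean(sfs_sample(n, "structured", 1000) == 1)
  })
  expect_gt(exps, neu)
  expect_lt(str, neu)
})

test_that("error-free reads are exact substrings; depth 0 gives no reads", {
  seqs <- c(t1 = paste(rep("ACGTTGCAAC", 60), collapse = ""))
  reads <- simulate_reads(seqs, 3, 100, error_rate = 0, seed = 5)
  expect_gt(length(reads$r1), 0)
  expect_true(all(vapply(reads$r1, grepl, TRUE, x = seqs[["t1"]],
                         fixed = TRUE)))
  expect_true(all(vapply(revcomp(reads$r2), grepl, TRUE, x = seqs[["t1"]],
                         fixed = TRUE)))
  none <- simulate_reads(seqs, 0, 100, seed = 5)
  expect_length(none$r1, 0)
  expect_length(none$r2, 0)
})

test_that("read names encode the true transcript and offset", {
  b <- small_bundle()
  reads <- simulate_reads(b$transcripts$A01, 3, 100, seed = 8)
  parts <- strsplit(names(reads$r1), ":", fixed = TRUE)
  tid <- vapply(parts, `[[`, "", 1)
  start <- as.integer(vapply(parts, `[[`, "", 3))
  idx <- sample.int(length(reads$r1), 50)
  for (i in idx) {
    expect_identical(substr(b$transcripts$A01$seq[[tid[i]]], start[i],
                            start[i] + 99L), unname(reads$r1[i]))
  }
})

test_that("short transcripts are skipped with a warning", {
  expect_warning(r <- simulate_reads(c(short = "ACGTACGT"), 5, 100, seed = 1),
                 "skipped")
  expect_length(r$r1, 0)
})

test_that("observed read error rate matches the configured rate", {
  L <- 5000
  withr::with_seed(31, {
    tseq <- c(t1 = random_dna_test(L))
  })
  reads <- simulate_reads(tseq, 12, 100, error_rate = 0.01, seed = 17)
  emitted <- 0L
  wrong <- 0L
  for (i in seq_along(reads$r1)) {
    s <- as.integer(strsplit(names(reads$r1)[i], ":")[[1]][3])
    truth1 <- substr(tseq[[1]], s, s + 99L)
    truth2 <- substr(tseq[[1]], s + 120L, s + 219L)
    wrong <- wrong + mapply(function(a, b) sum(strsplit(a, "")[[1]] !=
                                                 strsplit(b, "")[[1]]),
                            reads$r1[i], truth1) +
      mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
             revcomp(reads$r2[i]), truth2)
    emitted <- emitted + 200L
  }
  expect_gt(emitted, 1e5)
  p_hat <- wrong / emitted
  tol <- 3 * sqrt(0.01 * 0.99 / emitted)
  expect_lt(abs(p_hat - 0.01), tol)
})

test_that("every truth record maps inside the bounds of present genomes", {
  b <- small_bundle()
  tr <- b$truth
  for (g in c("A", "B")) {
    chrom <- tr[[paste0("chrom", g)]]
    pos <- tr[[paste0("pos", g)]]
    present <- !is.na(chrom)
    lens <- nchar(b$genomes[[g]]$seq)
    expect_true(all(pos[present] >= 1))
    expect_true(all(pos[present] <= lens[chrom[present]]))
    # genes dropped from the genome yield no coordinates
    absent_genes <- setdiff(b$genes$gene, b$genomes[[g]]$genes$gene)
    expect_true(all(is.na(pos[tr$gene %in% absent_genes])))
  }
})

test_that("direct SFS panels are deterministic and outgroup-ancestral", {
  p1 <- simulate_panel(8, "neutral", n_sites = 50, seed = 4)
  p2 <- simulate_panel(8, "neutral", n_sites = 50, seed = 4)
  expect_identical(p1$alleles, p2$alleles)
  # the outgroup column carries the ancestral allele at every site
  expect_identical(unname(p1$alleles[, "OUT"]), p1$sites$ref)
})
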