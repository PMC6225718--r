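# Diversity estimators, SFS polarization, fixed differences, NJ trees.

test_that("diversity summary matches the brute-force oracle", {
  withr::with_seed(101, {
    for (rep in 1:12) {
      n <- sample(4:12, 1)
      S <- sample(1:100, 1)
      mode <- sample(c("neutral", "expansion", "structured"), 1)
      p <- simulate_panel(n, mode, n_sites = S, seed = sample.int(1e6, 1))
      cols <- sprintf("acc%02d", seq_len(n))
      ds <- diversity_summary(p, cols, L = S)
      or <- oracle_diversity(p$alleles[, cols, drop = FALSE])
      expect_equal(ds$S, or$S)
      expect_equal(ds$singletons, or$singletons)
      expect_equal(ds$theta_w, or$theta, tolerance = 1e-12)
      expect_equal(ds$pi, or$pi, tolerance = 1e-12)
      expect_equal(ds$tajima_d, or$D, tolerance = 1e-12)
      expect_equal(ds$singletons + ds$non_singletons, ds$S)
    }
  })
})

test_that("n = 2 makes Tajima's D identically zero; S = 0 undefined", {
  al <- matrix(c("A", "G", "A", "G", "C", "C"), 3, 2, byrow = TRUE,
               dimnames = list(NULL, c("x", "y")))
  m <- matrix_from_alleles(al, c(x = "ingroupA", y = "ingroupA"))
  ds <- diversity_summary(m, c("x", "y"))
  expect_equal(ds$S, 2)
  expect_equal(ds$pi, ds$S) # a1 = 1 at n = 2
  expect_equal(ds$tajima_d, 0)
  mono <- matrix_from_alleles(al[3, , drop = FALSE],
                              c(x = "ingroupA", y = "ingroupA"))
  ds0 <- diversity_summary(mono, c("x", "y"))
  expect_equal(ds0$S, 0)
  expect_equal(ds0$theta_w, 0)
  expect_true(is.na(ds0$tajima_d))
  expect_error(diversity_summary(mono, "x"), "at least 2")
})

test_that("tajima constants satisfy their defining identities", {
  for (n in c(2, 5, 10, 23)) {
    cst <- tajima_constants(n)
    expect_equal(cst$a1, sum(1 / seq_len(n - 1)))
    expect_equal(cst$e1, cst$c1 / cst$a1)
    expect_equal(cst$e2, cst$c2 / (cst$a1^2 + cst$a2))
  }
})

test_that("polarized SFS classes plus unpolarizable sum to S", {
  withr::with_seed(202, {
    for (mode in c("neutral", "expansion", "structured")) {
      p <- simulate_panel(9, mode, n_sites = 300, seed = sample.int(1e6, 1))
      sfs <- polarize_sfs(p, "ingroupA")
      expect_equal(sum(sfs$counts) + sfs$unpolarizable, sfs$S)
      ds <- diversity_summary(p, "ingroupA", L = 300)
      expect_equal(sfs$S, ds$S)
      # the outgroup is ancestral by construction, so classes match the
      # planted derived counts exactly and nothing is unpolarizable
      expect_equal(sfs$unpolarizable, 0)
    }
  })
})

test_that("polarization follows the outgroup allele site by site", {
  al <- rbind(c(rep("A", 9), "G", "A"),  # derived G singleton
              c(rep("A", 8), "G", "G", "G"), # derived count 2? outgroup G
              c(rep("A", 9), "G", "C"))  # outgroup carries a third allele
  colnames(al) <- c(sprintf("a%02d", 1:10), "OUT")
  sp <- stats::setNames(c(rep("ingroupA", 10), "outgroup"), colnames(al))
  m <- matrix_from_alleles(al, sp)
  sfs <- polarize_sfs(m, "ingroupA")
  expect_equal(unname(sfs$counts[1]), 1)  # row 1: singleton derived
  expect_equal(unname(sfs$counts[8]), 1)  # row 2: outgroup G, derived = A x 8
  expect_equal(sfs$unpolarizable, 1)      # row 3
  expect_equal(sfs$S, 3)
})

test_that("fixed differences require monomorphism for different alleles", {
  al <- rbind(c("A", "A", "G", "G"),  # fixed
              c("A", "G", "G", "G"),  # polymorphic in group 1
              c("C", "C", "C", "C"))  # shared
  colnames(al) <- c("x1", "x2", "y1", "y2")
  sp <- stats::setNames(c("ingroupA", "ingroupA", "ingroupB", "ingroupB"),
                        colnames(al))
  m <- matrix_from_alleles(al, sp)
  expect_equal(fixed_differences(m, "ingroupA", "ingroupB"), 1)
  expect_error(fixed_differences(m, character(0), "ingroupB"), "non-empty")
})

test_that("SNP distances are symmetric with zero diagonal", {
  p <- simulate_panel(6, "neutral", n_sites = 80, seed = 5)
  d <- snp_distance(p)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, ncol(d)))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("three-taxon NJ branch lengths match the closed form", {
  # d(A,B) = 2/5, d(A,C) = d(B,C) = 4/5 over 5 sites:
  # 3 sites A=B!=C, 1 site A!=B=C, 1 site A=C!=B
  al <- rbind(c("A", "A", "G"), c("A", "A", "G"), c("A", "A", "G"),
              c("A", "G", "G"), c("A", "G", "A"))
  colnames(al) <- c("A", "B", "C")
  sp <- stats::setNames(rep("ingroupA", 3), colnames(al))
  m <- matrix_from_alleles(al, sp)
  res <- nj_tree_with_bootstrap(m, replicates = 0)
  tr <- res$tree
  pend <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(pend[["A"]], 1 / 5)
  expect_equal(pend[["B"]], 1 / 5)
  expect_equal(pend[["C"]], 3 / 5)
})

test_that("duplicated accessions sit on a zero-length branch", {
  al <- cbind(rep(c("A", "G"), 10), rep(c("A", "G"), 10),
              rep("A", 20), rep(c("A", "C"), 10))
  colnames(al) <- c("d1", "d2", "x", "y")
  sp <- stats::setNames(rep("ingroupA", 4), colnames(al))
  m <- matrix_from_alleles(al, sp)
  res <- nj_tree_with_bootstrap(m, replicates = 0)
  tr <- res$tree
  pend <- stats::setNames(tr$edge.length[match(1:4, tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(pend[["d1"]] + pend[["d2"]], 0)
})

test_that("bootstrap support is reproducible and bounded", {
  p <- simulate_panel(6, "neutral", n_sites = 60, seed = 9)
  r1 <- nj_tree_with_bootstrap(p, replicates = 30, seed = 4, outgroup = "OUT")
  r2 <- nj_tree_with_bootstrap(p, replicates = 30, seed = 4, outgroup = "OUT")
  expect_identical(ape::write.tree(r1$tree), ape::write.tree(r2$tree))
  expect_true(all(r1$tree$node.label >= 0 & r1$tree$node.label <= 100))
  expect_error(nj_tree_with_bootstrap(
    matrix_from_alleles(matrix(character(0), 0, 3,
                               dimnames = list(NULL, c("a", "b", "c"))),
                        stats::setNames(rep("ingroupA", 3), c("a", "b", "c"))),
    replicates = 0), "comparable")
})

test_that("theta_by_transcript decomposes the group S", {
  b <- small_bundle()
  aln_calls <- lapply(c("A01", "A02", "A03", "A04", "A05"), function(a) {
    aln <- bundle_alignment(b, a)
    accession_consensus(pileup_alignments(aln, b$transcripts$A01))
  })
  names(aln_calls) <- c("A01", "A02", "A03", "A04", "A05")
  sp <- stats::setNames(rep("ingroupA", 5), names(aln_calls))
  m <- build_snp_matrix(aln_calls, sp, "A01")
  tt <- theta_by_transcript(m, names(aln_calls))
  ds <- diversity_summary(m, names(aln_calls))
  expect_equal(sum(tt$S), ds$S)
  expect_equal(sum(tt$L), m$L_total)
  expect_equal(sum(tt$theta), ds$theta_w, tolerance = 1e-12)
})

test_that("matrix consensus equals the planted genotypes", {
  b <- small_bundle()
  accs <- c("A01", "A02", "A03", "A04", "A05")
  cons <- lapply(accs, function(a) {
    aln <- bundle_alignment(b, a)
    accession_consensus(pileup_alignments(aln, b$transcripts$A01))
  })
  names(cons) <- accs
  sp <- stats::setNames(rep("ingroupA", length(accs)), accs)
  m <- build_snp_matrix(cons, sp, "A01")
  # every within-A planted SNP appears with the planted carrier pattern
  tr <- b$truth[b$truth$class == "SNP" & b$truth$species == "A", ]
  key_m <- paste(m$sites$transcript, m$sites$pos)
  for (r in seq_len(nrow(tr))) {
    i <- match(paste(tr$gene[r], tr$pos[r]), key_m)
    expect_false(is.na(i))
    carr <- strsplit(tr$carriers[r], ",")[[1]]
    want <- ifelse(accs %in% carr, tr$alt[r], tr$ancestral[r])
    expect_identical(unname(m$alleles[i, accs]), want)
  }
})
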