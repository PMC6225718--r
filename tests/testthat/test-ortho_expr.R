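# RBH orthology, FPKM quantification, rank correlations.

test_that("identical sets pair every transcript with its copy", {
  withr::with_seed(301, {
    seqs <- stats::setNames(replicate(8, random_dna_test(400)),
                            sprintf("t%02d", 1:8))
  })
  s1 <- transcript_set("X", seqs)
  s2 <- transcript_set("Y", seqs)
  pairs <- rbh_orthologs(s1, s2)
  expect_equal(nrow(pairs), 8)
  expect_identical(pairs$id1, pairs$id2)
  expect_true(all(pairs$coverage12 == 1 & pairs$coverage21 == 1))
})

test_that("RBH recovers shuffled orthologs at 2% divergence with no false pairs", {
  withr::with_seed(302, {
    seqs <- stats::setNames(replicate(20, random_dna_test(600)),
                            sprintf("t%02d", 1:20))
    mutate <- function(s, rate) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(ch)) < rate)
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      paste(ch, collapse = "")
    }
    div <- vapply(seqs, mutate, "", rate = 0.02)
    ord <- sample(20)
  })
  names(div) <- sprintf("u%02d", 1:20)
  s1 <- transcript_set("X", seqs)
  s2 <- transcript_set("Y", div[ord])
  pairs <- rbh_orthologs(s1, s2)
  expect_equal(nrow(pairs), 20)
  truth <- stats::setNames(names(div)[ord], names(seqs)[ord])
  expect_identical(pairs$id2, unname(truth[pairs$id1]))
})

test_that("RBH is symmetric under swapping the two sets", {
  b <- small_bundle()
  p12 <- rbh_orthologs(b$transcripts$A01, b$transcripts$B01)
  p21 <- rbh_orthologs(b$transcripts$B01, b$transcripts$A01)
  expect_setequal(paste(p12$id1, p12$id2), paste(p21$id2, p21$id1))
})

test_that("coverage exactly 0.80 is rejected", {
  withr::with_seed(303, {
    core <- random_dna_test(400)
    tail1 <- paste0("A", random_dna_test(99))
    tail2 <- paste0("C", random_dna_test(99)) # first tail base differs
  })
  # q1 shares exactly 400 of its 500 bases with q2: coverage 400/500 = 0.80
  s1 <- transcript_set("X", c(q = paste0(core, tail1)))
  s2 <- transcript_set("Y", c(r = paste0(core, tail2)))
  pairs <- rbh_orthologs(s1, s2, min_coverage = 0.80)
  expect_equal(nrow(pairs), 0)
  # the same pair passes a lower threshold, confirming the hit exists
  pairs2 <- rbh_orthologs(s1, s2, min_coverage = 0.75)
  expect_equal(nrow(pairs2), 1)
  expect_equal(pairs2$coverage12, 0.80)
})

test_that("FPKM follows the formula on a hand-built alignment table", {
  refs <- transcript_set("R", c(big = strrep("A", 2000),
                                other = strrep("C", 1000)))
  frag <- function(ref, n) {
    base <- data.frame(qname = paste0(ref, seq_len(n)), ref = ref,
                       mapped = TRUE, stringsAsFactors = FALSE)
    rbind(cbind(base, mate = 1L, strand = "+", pos = 1),
          cbind(base, mate = 2L, strand = "-", pos = 100))
  }
  aln <- rbind(frag("big", 100), frag("other", 900))
  out <- fpkm(aln, refs)
  expect_equal(attr(out, "total_fragments"), 1000)
  expect_equal(out$fpkm[out$transcript == "big"],
               100 * 1e9 / (2000 * 1000))
  # discordant mates (same strand) are not counted
  disc <- frag("big", 10)
  disc$qname <- paste0("d", disc$qname)
  disc$strand <- "+"
  out2 <- fpkm(rbind(frag("big", 100), disc), refs)
  expect_equal(out2$fragments[out2$transcript == "big"], 100)
  expect_error(fpkm(within(frag("big", 5), mate <- NA_integer_), refs),
               "unpaired")
})

test_that("zero counted fragments give zero FPKM", {
  refs <- transcript_set("R", c(t1 = strrep("A", 500)))
  aln <- data.frame(qname = "x", mate = 1L, ref = "t1", mapped = FALSE,
                    strand = NA, pos = NA)
  out <- fpkm(aln, refs)
  expect_equal(out$fpkm, 0)
  expect_equal(out$fragments, 0)
})

test_that("FPKM mass balance: sum(fpkm * L) / 1e9 * total = total", {
  b <- small_bundle()
  aln <- bundle_alignment(b, "A01", depth = 6)
  out <- fpkm(aln, b$transcripts$A01)
  total <- attr(out, "total_fragments")
  expect_equal(sum(out$fpkm * out$length) / 1e9 * total, total)
})

test_that("kendall tau matches exhaustive enumeration, with and without ties", {
  expect_equal(kendall_tau(1:10, 1:10)$tau, 1)
  expect_equal(kendall_tau(1:10, 10:1)$tau, -1)
  withr::with_seed(404, {
    for (rep in 1:8) {
      x <- sample(1:6, 20, replace = TRUE)   # heavy ties
      y <- x + sample(-2:2, 20, replace = TRUE)
      kt <- kendall_tau(x, y)
      expect_equal(kt$tau, oracle_kendall(x, y), tolerance = 1e-12)
    }
  })
  expect_true(is.na(kendall_tau(rep(1, 5), 1:5)$tau))
})

test_that("ortho theta scatter joins, filters and correlates", {
  pairs <- data.frame(id1 = c("a", "b", "c"), id2 = c("x", "y", "z"))
  th1 <- data.frame(transcript = c("a", "b", "c"), S = c(2, 0, 1),
                    theta = c(2, 0, 1), theta_per_site = c(.02, 0, .01))
  th2 <- data.frame(transcript = c("x", "y", "z"), S = c(1, 0, 3),
                    theta = c(2, 0, 1), theta_per_site = c(.02, 0, .01))
  sc <- ortho_theta_scatter(pairs, th1, th2)
  expect_equal(nrow(sc$table), 2) # the all-monomorphic pair b-y drops
  expect_equal(sc$tau, 1)
  expect_error(ortho_theta_scatter(data.frame(id1 = "q", id2 = "x"),
                                   th1, th2), "absent")
})

test_that("independent theta draws show no rank association", {
  withr::with_seed(505, {
    pairs <- data.frame(id1 = sprintf("a%03d", 1:500),
                        id2 = sprintf("b%03d", 1:500))
    th1 <- data.frame(transcript = pairs$id1, S = 1,
                      theta = stats::runif(500),
                      theta_per_site = stats::runif(500))
    th2 <- data.frame(transcript = pairs$id2, S = 1,
                      theta = stats::runif(500),
                      theta_per_site = stats::runif(500))
  })
  sc <- ortho_theta_scatter(pairs, th1, th2)
  expect_lt(abs(sc$tau), 0.1)
  expect_gt(sc$p, 0.01)
})
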