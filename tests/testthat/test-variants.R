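# Calling rule thresholds, artifact filter, non-redundant consolidation.

ref1 <- c(t1 = strrep("ACGTTGCAAC", 5))

counts_at <- function(pos, base, count, ref_base, ref_count) {
  data.frame(pos = c(pos, pos), base = c(base, ref_base),
             count = c(count, ref_count), stringsAsFactors = FALSE)
}

test_that("both calling thresholds are strict", {
  # ref base at position 11 is A
  cases <- list(
    list(alt = 12, ref = 0, called = TRUE, frac = 1.0),   # depth 12, all alt
    list(alt = 10, ref = 0, called = FALSE),              # depth 10 not > 10
    list(alt = 19, ref = 1, called = FALSE),              # 0.95 exactly
    list(alt = 20, ref = 1, called = TRUE, frac = 20 / 21),
    list(alt = 11, ref = 0, called = TRUE, frac = 1.0))
  for (cs in cases) {
    pile <- make_pileup(ref1, counts = list(
      t1 = counts_at(11, "G", cs$alt, "A", cs$ref)))
    calls <- call_variants(pile, read_accession = "X")
    if (cs$called) {
      expect_equal(nrow(calls), 1)
      expect_equal(calls$pos, 11)
      expect_equal(calls$ref, "A")
      expect_equal(calls$alt, "G")
      expect_equal(calls$class, "SNP")
      expect_equal(calls$non_ref_fraction, cs$frac)
    } else {
      expect_equal(nrow(calls), 0)
    }
  }
})

test_that("multi-allelic columns with no dominant allele yield nothing", {
  pile <- make_pileup(ref1, counts = list(
    t1 = data.frame(pos = c(11, 11, 11), base = c("G", "C", "T"),
                    count = c(8, 8, 8), stringsAsFactors = FALSE)))
  expect_equal(nrow(call_variants(pile)), 0)
})

test_that("indel calls apply the same thresholds at the anchor column", {
  pile <- make_pileup(
    ref1, counts = list(t1 = data.frame(pos = 8, base = "A", count = 12,
                                        stringsAsFactors = FALSE)),
    del = list(t1 = data.frame(pos = 8, seq = "AC", count = 12,
                               stringsAsFactors = FALSE)))
  calls <- call_variants(pile, read_accession = "X")
  d <- calls[calls$class == "deletion", ]
  expect_equal(nrow(d), 1)
  expect_equal(d$ref, "AC")
  expect_equal(d$alt, "-")
  expect_equal(d$non_ref_fraction, 1.0)
  # 19/20 at the anchor is not over 0.95
  pile2 <- make_pileup(
    ref1, counts = list(t1 = data.frame(pos = 8, base = "A", count = 20,
                                        stringsAsFactors = FALSE)),
    del = list(t1 = data.frame(pos = 8, seq = "AC", count = 19,
                               stringsAsFactors = FALSE)))
  expect_equal(nrow(call_variants(pile2)[
    call_variants(pile2)$class == "deletion", ]), 0)
})

test_that("an N majority never becomes a call", {
  pile <- make_pileup(ref1, counts = list(
    t1 = counts_at(11, "N", 15, "A", 0)))
  expect_equal(nrow(call_variants(pile)), 0)
})

test_that("filter_artifacts removes exactly the shared keys", {
  b <- small_bundle()
  calls <- bundle_calls(b, "A02")
  empty_self <- bundle_calls(b, "A01")
  expect_equal(nrow(empty_self), 0) # error-free self-comparison is clean
  kept <- filter_artifacts(calls, empty_self)
  expect_equal(attr(kept, "n_removed"), 0)
  attr(kept, "n_removed") <- NULL
  expect_equal(as.data.frame(kept), as.data.frame(calls))
  # planting one shared artifact removes it
  fake_self <- calls[1, , drop = FALSE]
  fake_self$read_accession <- fake_self$reference_accession
  filtered <- filter_artifacts(calls, fake_self)
  expect_equal(nrow(filtered), nrow(calls) - 1)
  expect_equal(attr(filtered, "n_removed"), 1)
  expect_false(any(filtered$pos == calls$pos[1] &
                     filtered$transcript == calls$transcript[1]))
})

test_that("filter_artifacts rejects mismatched reference accessions", {
  a <- data.frame(read_accession = "X", reference_accession = "R1",
                  transcript = "t", pos = 1, ref = "A", alt = "G",
                  class = "SNP", depth = 12, non_ref_fraction = 1)
  b <- a
  b$reference_accession <- "R2"
  b$read_accession <- "R2"
  expect_error(filter_artifacts(a, b), "different reference")
})

test_that("consolidation unions by key and tracks supporters", {
  mk <- function(acc, pos) {
    data.frame(read_accession = acc, reference_accession = "R",
               transcript = "t1", pos = pos, ref = "A", alt = "G",
               class = "SNP", depth = 12, non_ref_fraction = 1,
               stringsAsFactors = FALSE)
  }
  shared <- consolidate_nonredundant(list(mk("X", 5), mk("Y", 5), mk("Z", 5)))
  expect_equal(nrow(shared), 1)
  expect_equal(shared$n_supporters, 3)
  expect_equal(shared$supporters, "X,Y,Z")
  disjoint <- consolidate_nonredundant(list(mk("X", 1:5), mk("Y", 11:17)))
  expect_equal(nrow(disjoint), 12)
  # self-comparisons are excluded from the union
  self <- mk("R", 99)
  expect_equal(nrow(consolidate_nonredundant(list(mk("X", 5), self))), 1)
  expect_error(consolidate_nonredundant(list(
    mk("X", 1), within(mk("Y", 2), reference_accession <- "S"))),
    "one reference accession")
})

test_that("NR cardinality never exceeds the sum of pairwise cardinalities", {
  b <- small_bundle()
  calls <- lapply(c("A02", "A03", "A04"), function(a) bundle_calls(b, a))
  nr <- consolidate_nonredundant(calls)
  expect_lte(nrow(nr), sum(vapply(calls, nrow, 0L)))
  expect_gte(nrow(nr), max(vapply(calls, nrow, 0L)))
})

test_that("pairwise calls match the truth table exactly at depth 15", {
  b <- small_bundle()
  for (acc in c("A02", "A05")) {
    calls <- bundle_calls(b, acc)
    got <- paste(calls$transcript, calls$pos, calls$class)
    want <- truth_pairwise_keys(b, acc, "A01")
    expect_setequal(got, want)
  }
})

test_that("variant_count_table summarises pairwise sets", {
  b <- small_bundle()
  calls <- lapply(c("A02", "A03"), function(a) bundle_calls(b, a))
  tab <- variant_count_table(calls)
  expect_equal(tab$read_accession, c("A02", "A03"))
  expect_equal(tab$n_snp + tab$n_indel, vapply(calls, nrow, 0L))
})
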