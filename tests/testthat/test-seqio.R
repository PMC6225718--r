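# Format readers/writers: round-trip identity, validation, SAM pileup
# semantics, BED coordinate conventions, newick round-trip.

test_that("FASTA write/read round-trips ids and sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(a = "ACGTACGT", b = "GGGTTTAAACCC", c = "NNNACGT")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_identical(back, seqs)
})

test_that("empty FASTA reads as an empty set without error", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_length(read_fasta(f), 0)
})

test_that("FASTA validation names the offending record", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACGT", ">bad", "ACXT"), f)
  expect_error(read_fasta(f), "bad")
  writeLines(c(">dup", "ACGT", ">dup", "ACGT"), f)
  expect_error(read_fasta(f), "dup")
  expect_error(transcript_set("x", c(r1 = "ACGT", r1 = "ACGT")), "duplicate")
  expect_error(transcript_set("x", c(r1 = "ACXT")), "r1")
})

test_that("FASTQ pairs round-trip through write_fastq/read_fastq", {
  d <- withr::local_tempdir()
  reads <- structure(list(r1 = c("f1:1:1" = "ACGTACGTACGTACGTACGTA"),
                          r2 = c("f1:1:1" = "TTTTACGTACGTACGTACGTA")),
                     class = "read_pairs")
  write_fastq(reads, file.path(d, "x"))
  b1 <- read_fastq(file.path(d, "x_1.fastq"))
  b2 <- read_fastq(file.path(d, "x_2.fastq"))
  expect_identical(unname(b1), unname(reads$r1))
  expect_identical(names(b1), "f1:1:1/1")
  expect_identical(unname(b2), unname(reads$r2))
})

test_that("SAM write/read round-trips the alignment table", {
  b <- small_bundle()
  aln <- bundle_alignment(b, "A02", depth = 4)
  f <- withr::local_tempfile(fileext = ".sam")
  ref <- b$transcripts$A01
  write_sam(aln, ref, f)
  back <- read_sam(f, ref)
  m <- aln$mapped
  expect_identical(back$qname, aln$qname)
  expect_identical(back$mapped, aln$mapped)
  expect_identical(back$ref[m], aln$ref[m])
  expect_identical(back$pos[m], aln$pos[m])
  expect_identical(back$cigar[m], aln$cigar[m])
  expect_identical(back$strand[m], aln$strand[m])
  expect_identical(back$seq, aln$seq)
  expect_identical(back$mate, aln$mate)
})

test_that("read_sam rejects unknown reference names and bad CIGARs", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:t1\tLN:50",
               paste("r1", 0, "tX", 1, 60, "4M", "*", 0, 0, "ACGT", "IIII",
                     sep = "\t")), f)
  expect_error(read_sam(f, transcript_set("x", c(t1 = strrep("A", 50)))),
               "tX")
  writeLines(c("@SQ\tSN:t1\tLN:50",
               paste("r1", 0, "t1", 1, 60, "4Q", "*", 0, 0, "ACGT", "IIII",
                     sep = "\t")), f)
  expect_error(read_sam(f), "CIGAR.*line 2")
})

test_that("hand-written SAM with a 2-bp deletion in 3 of 5 reads piles up", {
  ref <- transcript_set("R", c(t1 = "ACGTACGTTGCAACGGTTAA"))
  f <- withr::local_tempfile(fileext = ".sam")
  # 3 reads delete ref[9:10] (anchor base 8), 2 reads are full matches
  del_read <- paste0(substr(ref$seq[[1]], 1, 8), substr(ref$seq[[1]], 11, 20))
  lines <- c("@HD\tVN:1.6", "@SQ\tSN:t1\tLN:20",
             vapply(1:3, function(i)
               paste(paste0("d", i), 0, "t1", 1, 60, "8M2D10M", "*", 0, 0,
                     del_read, strrep("I", 18), sep = "\t"), ""),
             vapply(1:2, function(i)
               paste(paste0("m", i), 0, "t1", 1, 60, "20M", "*", 0, 0,
                     ref$seq[[1]], strrep("I", 20), sep = "\t"), ""))
  writeLines(lines, f)
  pile <- read_sam_pileup(f, ref)
  del <- pile$transcripts$t1$del
  expect_equal(nrow(del), 1)
  expect_equal(del$pos, 8)
  expect_equal(del$seq, substr(ref$seq[[1]], 9, 10))
  expect_equal(del$count, 3)
  # deleted columns only get depth from the two full-match reads
  expect_equal(unname(colSums(pile$transcripts$t1$counts)[9]), 2)
  expect_equal(unname(colSums(pile$transcripts$t1$counts)[1]), 5)
})

test_that("a SAM with only unmapped reads yields empty pileup columns", {
  ref <- transcript_set("R", c(t1 = strrep("ACGT", 10)))
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:t1\tLN:40",
               paste("u1", 4, "*", 0, 0, "*", "*", 0, 0, "ACGTACGT",
                     strrep("I", 8), sep = "\t")), f)
  pile <- read_sam_pileup(f, ref)
  expect_equal(sum(pile$transcripts$t1$counts), 0)
  expect_null(pileup_columns(pile))
})

test_that("pileup depth equals a brute-force per-read interval scan", {
  b <- small_bundle()
  aln <- bundle_alignment(b, "A03", depth = 6)
  pile <- pileup_alignments(aln, b$transcripts$A01)
  for (id in names(pile$transcripts)[1:5]) {
    sub <- aln[aln$mapped & aln$ref == id, , drop = FALSE]
    expect_equal(unname(colSums(pile$transcripts[[id]]$counts)),
                 oracle_depth(sub, nchar(b$transcripts$A01$seq[[id]])))
  }
})

test_that("BED output follows 0-based half-open conventions", {
  d <- withr::local_tempfile(fileext = ".bed")
  anchored <- data.frame(
    transcript = c("t1", "t1"), pos = c(1050L, 99L),
    ref = c("A", "CAT"), alt = c("G", "-"),
    class = c("SNP", "deletion"), genome = "A", chrom = "chr1A",
    chrom_pos = c(1050L, 99L), strand = "+", anchored = TRUE,
    stringsAsFactors = FALSE)
  write_bed(anchored, d)
  bed <- read.table(d, sep = "\t")
  snp <- bed[grepl("SNP", bed$V4), ]
  expect_equal(c(snp$V2, snp$V3), c(1049L, 1050L))
  del <- bed[grepl("deletion", bed$V4), ]
  expect_equal(c(del$V2, del$V3), c(99L, 102L))
  # out-of-bounds coordinates are rejected
  expect_error(write_bed(anchored, d, chrom_lengths = c(chr1A = 500L)),
               "bounds")
})

test_that("newick write/read round-trips topology and branch lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  tr <- ape::read.tree(text = "((a:1,b:1):2,c:3);")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back))[1], 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length))
})

test_that("TSV tables round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(a = c("x", "y"), b = c(1.5, -2), c = c(NA, 7L))
  write_tsv(df, f)
  expect_equal(read_tsv(f), df)
})
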