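# Readers and writers for the formats the pipeline touches: FASTA, FASTQ,
# text SAM, BED, TSV and newick.  All coordinates are 1-based inclusive
# internally; BED output is 0-based half-open.

#' Construct a per-accession transcript set
#'
#' A transcript set is the reference unigene collection of one accession:
#' uniquely named uppercase A/C/G/T/N sequences.
#'
#' @param accession accession identifier.
#' @param seqs named character vector of sequences.
#' @param note free-text provenance note.
#' @return an object of class `transcript_set`.
#' @export
transcript_set <- function(accession, seqs, note = "") {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all transcripts must be named")
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop("duplicate transcript ids: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-IUPAC characters (outside A/C/G/T/N) in record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  structure(list(accession = accession, seq = seqs, note = note),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("<transcript_set> accession %s: %d transcripts, %d bp total\n",
              x$accession, length(x$seq), sum(nchar(x$seq))))
  invisible(x)
}

#' @export
length.transcript_set <- function(x) length(x$seq)

as_seq_vector <- function(x) {
  if (inherits(x, "transcript_set")) x$seq
  else if (is.character(x) && !is.null(names(x))) x
  else stop("expected a transcript_set or a named character vector")
}

#' Read / write FASTA
#'
#' Thin validating wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()].  Reading rejects duplicate ids and any
#' character outside A/C/G/T/N, naming the offending record; writing and
#' re-reading round-trips ids and sequences exactly.
#'
#' @param path file path.
#' @param seqs named character vector (or `transcript_set`) of sequences.
#' @return `read_fasta`: a named character vector (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-IUPAC characters (outside A/C/G/T/N) in record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_seq_vector(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write paired reads as FASTQ
#'
#' @param reads a list with named character vectors `r1` and `r2` as
#'   produced by [simulate_reads()].
#' @param prefix output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @export
write_fastq <- function(reads, prefix) {
  for (mate in 1:2) {
    rs <- reads[[paste0("r", mate)]]
    f <- paste0(prefix, "_", mate, ".fastq")
    if (length(rs) == 0) {
      file.create(f)
      next
    }
    dna <- Biostrings::DNAStringSet(rs)
    names(dna) <- paste0(names(rs), "/", mate)
    qual <- Biostrings::BStringSet(vapply(nchar(rs), function(n)
      strrep("I", n), ""))
    names(qual) <- names(dna)
    Biostrings::writeXStringSet(dna, f, format = "fastq", qualities = qual)
  }
  invisible(prefix)
}

#' Read FASTQ sequences
#'
#' @param path FASTQ file.
#' @return named character vector of read sequences (qualities dropped).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

# ---------------------------------------------------------------------------
# SAM
# ---------------------------------------------------------------------------

#' Write an alignment table as text SAM
#'
#' The alignment table is the in-memory format produced by [align_reads()]:
#' one row per read with columns `qname`, `mate` (1/2 or NA), `ref`, `pos`,
#' `strand`, `cigar`, `nm`, `mapped`, `ambiguous` and `seq` (the read as
#' sequenced).  SEQ is written in reference orientation per the SAM
#' convention; reading the file back restores the as-sequenced orientation.
#'
#' @param aln alignment data.frame.
#' @param reference a `transcript_set` (for `@SQ` header lines).
#' @param path output path.
#' @export
write_sam <- function(aln, reference, path) {
  refs <- as_seq_vector(reference)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)))
  n <- nrow(aln)
  mapped <- aln$mapped
  paired <- !is.na(aln$mate)
  # locate the mate row by qname for pairing flags
  mate_idx <- rep(NA_integer_, n)
  if (any(paired)) {
    key <- paste0(aln$qname, "/", ifelse(aln$mate == 1L, 2L, 1L))
    own <- paste0(aln$qname, "/", aln$mate)
    mate_idx <- match(key, own)
  }
  mate_mapped <- ifelse(is.na(mate_idx), FALSE, aln$mapped[mate_idx])
  mate_ref <- ifelse(is.na(mate_idx), NA, aln$ref[mate_idx])
  mate_pos <- ifelse(is.na(mate_idx), NA, aln$pos[mate_idx])
  mate_strand <- ifelse(is.na(mate_idx), NA, aln$strand[mate_idx])
  proper <- paired & mapped & mate_mapped & !is.na(mate_ref) &
    aln$ref == mate_ref & aln$strand != mate_strand
  flag <- ifelse(paired, 1L, 0L) +
    ifelse(proper, 2L, 0L) +
    ifelse(!mapped, 4L, 0L) +
    ifelse(paired & !mate_mapped, 8L, 0L) +
    ifelse(mapped & aln$strand == "-", 16L, 0L) +
    ifelse(paired & mate_mapped & mate_strand == "-", 32L, 0L) +
    ifelse(paired & aln$mate == 1L, 64L, 0L) +
    ifelse(paired & aln$mate == 2L, 128L, 0L)
  seq_out <- ifelse(mapped & aln$strand == "-", revcomp(aln$seq), aln$seq)
  tlen <- integer(n)
  pp <- which(proper)
  if (length(pp)) {
    lo <- pmin(aln$pos[pp], mate_pos[pp])
    hi <- pmax(aln$pos[pp] + nchar(aln$seq[pp]) - 1L,
               mate_pos[pp] + nchar(aln$seq[mate_idx[pp]]) - 1L)
    span <- hi - lo + 1L
    tlen[pp] <- ifelse(aln$pos[pp] <= mate_pos[pp], span, -span)
  }
  lines <- paste(aln$qname, flag,
                 ifelse(mapped, aln$ref, "*"),
                 ifelse(mapped, aln$pos, 0L),
                 ifelse(mapped, ifelse(aln$ambiguous, 0L, 60L), 0L),
                 ifelse(mapped, aln$cigar, "*"),
                 ifelse(proper, "=", "*"),
                 ifelse(proper, mate_pos, 0L),
                 tlen, seq_out, strrep("I", nchar(aln$seq)),
                 sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a text SAM file into an alignment table
#'
#' Secondary (0x100) and supplementary (0x800) records are dropped; unmapped
#' records are kept with `mapped = FALSE` (they are ignored downstream).
#' CIGAR strings are validated and reported with their line number on error.
#'
#' @param path SAM file path.
#' @param reference optional `transcript_set`; if given, reference names in
#'   the SAM must all be known transcript ids.
#' @return alignment data.frame (see [write_sam()]).
#' @export
read_sam <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  all_lines <- readLines(path)
  body_at <- which(!startsWith(all_lines, "@"))
  if (length(body_at) == 0) {
    return(data.frame(qname = character(0), mate = integer(0),
                      ref = character(0), pos = integer(0),
                      strand = character(0), cigar = character(0),
                      nm = integer(0), mapped = logical(0),
                      ambiguous = logical(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(all_lines[body_at], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("malformed SAM record (fewer than 11 fields) at line ",
         body_at[which(nf < 11)[1]])
  get <- function(i) vapply(fields, `[[`, "", i)
  flag <- as.integer(get(2))
  keep <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  flag <- flag[keep]
  lineno <- body_at[keep]
  qname <- get(1)[keep]
  rname <- get(3)[keep]
  pos <- as.integer(get(4)[keep])
  cigar <- get(6)[keep]
  seq <- toupper(get(10)[keep])
  mapped <- bitwAnd(flag, 4L) == 0L
  bad_cig <- mapped & !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(bad_cig))
    stop("malformed CIGAR '", cigar[which(bad_cig)[1]], "' at line ",
         lineno[which(bad_cig)[1]])
  if (!is.null(reference)) {
    ids <- names(as_seq_vector(reference))
    unknown <- mapped & !(rname %in% ids)
    if (any(unknown))
      stop("SAM reference name '", rname[which(unknown)[1]],
           "' not in the supplied transcript set (line ",
           lineno[which(unknown)[1]], ")")
  }
  strand <- ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")
  # restore as-sequenced orientation (SEQ is stored reference-oriented)
  rc <- mapped & strand == "-"
  seq[rc] <- revcomp(seq[rc])
  mate <- rep(NA_integer_, length(flag))
  mate[bitwAnd(flag, 64L) != 0L] <- 1L
  mate[bitwAnd(flag, 128L) != 0L] <- 2L
  mapq0 <- as.integer(get(5)[keep]) == 0L
  data.frame(qname = qname, mate = mate,
             ref = ifelse(mapped, rname, NA_character_),
             pos = ifelse(mapped, pos, NA_integer_),
             strand = ifelse(mapped, strand, NA_character_),
             cigar = ifelse(mapped, cigar, NA_character_),
             nm = NA_integer_, mapped = mapped,
             ambiguous = mapped & mapq0, seq = seq,
             stringsAsFactors = FALSE)
}

#' Pileup from a SAM file
#'
#' Streams a text SAM into per-transcript pileup columns: per-base counts,
#' insertion counts keyed by the inserted string at the anchor base, and
#' deletion counts keyed by the deleted span.  Unmapped, secondary and
#' supplementary records are ignored; base qualities and MAPQ are not
#' filtered (the calling rule uses depth and consensus fraction only).
#'
#' @param path SAM file path.
#' @param reference `transcript_set` the reads were aligned to.
#' @return a `pileup` object (see [pileup_alignments()]).
#' @export
read_sam_pileup <- function(path, reference) {
  aln <- read_sam(path, reference = reference)
  pileup_alignments(aln, reference)
}

# ---------------------------------------------------------------------------
# BED / TSV / newick
# ---------------------------------------------------------------------------

#' Write anchored variants as BED (0-based half-open)
#'
#' SNPs become single-base intervals `[pos-1, pos)`; deletions cover the
#' deleted span `[anchor, anchor+len)` (the anchor is the base before the
#' event); insertions are represented by their anchor base `[pos-1, pos)`.
#'
#' @param anchored anchored-variant data.frame from [lift_variants()].
#' @param path output path.
#' @param chrom_lengths optional named vector for bounds checking.
#' @export
write_bed <- function(anchored, path, chrom_lengths = NULL) {
  a <- anchored[anchored$anchored, , drop = FALSE]
  len <- ifelse(a$class == "deletion", nchar(a$ref), 0L)
  start0 <- ifelse(a$class == "deletion", a$chrom_pos, a$chrom_pos - 1L)
  end <- ifelse(a$class == "deletion", a$chrom_pos + len, a$chrom_pos)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[a$chrom]
    if (any(is.na(lim)) || any(start0 < 0) || any(end > lim))
      stop("variant coordinates outside chromosome bounds")
  }
  name <- paste(a$transcript, a$pos, a$class, sep = ":")
  df <- data.frame(chrom = a$chrom, start = start0, end = end, name = name,
                   score = 0L, strand = a$strand)
  df <- df[order(df$chrom, df$start, df$name), , drop = FALSE]
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' @param df data.frame to write.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE, na.strings = "NA")
}

#' Read / write trees in newick format
#'
#' Wrappers around [ape::read.tree()] / [ape::write.tree()]; topology and
#' branch lengths round-trip.
#'
#' @param tree a `phylo` object.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
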