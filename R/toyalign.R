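# Minimal k-mer seeded read aligner and transcript-to-genome mapper.
# Sufficient for low-divergence transcriptome data; not a splice-aware or
# genome-scale aligner (externally produced SAM / mapping tables can be
# imported through the seqio readers instead).

#' Align reads to a reference transcript set
#'
#' Seed-and-extend alignment: k-mer seeds vote for (transcript, diagonal)
#' candidates, each candidate is scored by mismatch count, and a gapped
#' extension permits a single indel of up to `max_indel` bp (charged
#' `indel_penalty` mismatch-equivalents, so an indel is only reported when
#' it saves at least that many mismatches).  The placement minimizing the
#' mismatch cost wins; ties are broken deterministically (ungapped first,
#' then '+' strand, smallest transcript, leftmost coordinate) and flagged
#' ambiguous.  Reads whose best placement still exceeds `max_mismatch_frac`
#' mismatches per base are reported unmapped.  Only the primary placement
#' is emitted.
#'
#' @param reads named character vector of read sequences, or a list with
#'   elements `r1`/`r2` as produced by [simulate_reads()] (mates are
#'   aligned independently and tagged 1/2).
#' @param reference a `transcript_set`.
#' @param k seed length (default 21).
#' @param max_mismatch_frac maximum mismatches per read base (default 0.10).
#' @param max_indel maximum indel length the gapped extension considers.
#' @param indel_penalty mismatch-equivalent cost of opening an indel.
#' @return alignment data.frame with one row per read: `qname`, `mate`,
#'   `ref`, `pos` (1-based), `strand`, `cigar`, `nm`, `mapped`,
#'   `ambiguous`, `seq`.
#' @export
align_reads <- function(reads, reference, k = 21, max_mismatch_frac = 0.10,
                        max_indel = 10, indel_penalty = 3) {
  refs <- as_seq_vector(reference)
  if (length(refs) == 0) stop("empty reference transcript set")
  if (is.list(reads) && !is.null(reads$r1)) {
    seqs <- c(reads$r1, reads$r2)
    mate <- rep(c(1L, 2L), c(length(reads$r1), length(reads$r2)))
  } else {
    seqs <- reads
    mate <- rep(NA_integer_, length(reads))
  }
  if (length(seqs) && any(nchar(seqs) < k))
    stop("k must not exceed the read length")
  res <- cpp_align_reads(unname(refs), unname(seqs), as.integer(k),
                         max_mismatch_frac, as.integer(max_indel),
                         as.integer(indel_penalty), TRUE)
  out <- data.frame(qname = names(seqs) %||% as.character(seq_along(seqs)),
                    mate = mate,
                    ref = names(refs)[res$ref],
                    pos = res$pos, strand = res$strand, cigar = res$cigar,
                    nm = res$nm, mapped = res$mapped,
                    ambiguous = res$ambiguous, seq = unname(seqs),
                    stringsAsFactors = FALSE)
  attr(out, "reference_accession") <-
    if (inherits(reference, "transcript_set")) reference$accession else NA
  out
}

#' Pileup columns from an alignment table
#'
#' Walks each mapped read's CIGAR and accumulates, per transcript position:
#' A/C/G/T/N counts, insertion counts keyed by the inserted string, and
#' deletion counts keyed by the deleted span.  Indels are left-normalized
#' against the reference and anchored at the base preceding the event.
#' Unmapped records are skipped; base quality and MAPQ are ignored.
#'
#' @param aln alignment data.frame ([align_reads()] or [read_sam()]).
#' @param reference the `transcript_set` the reads were aligned to.
#' @return object of class `pileup`: per-transcript `counts` (5 x L matrix,
#'   rows A/C/G/T/N), `ins` and `del` count tables, plus the reference.
#' @export
pileup_alignments <- function(aln, reference) {
  refs <- as_seq_vector(reference)
  m <- aln[aln$mapped, , drop = FALSE]
  unknown <- setdiff(unique(m$ref), names(refs))
  if (length(unknown))
    stop("alignments reference unknown transcript(s): ",
         paste(unknown, collapse = ", "))
  res <- cpp_pileup(unname(refs), match(m$ref, names(refs)), m$pos, m$cigar,
                    m$seq, m$strand)
  names(res) <- names(refs)
  for (i in seq_along(res))
    rownames(res[[i]]$counts) <- c("A", "C", "G", "T", "N")
  structure(list(transcripts = res, reference = refs,
                 reference_accession = attr(aln, "reference_accession")),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d transcripts, %d aligned bases\n",
              length(x$transcripts),
              sum(vapply(x$transcripts, function(t) sum(t$counts), 0))))
  invisible(x)
}

#' Flatten a pileup into per-position columns
#'
#' @param pile a `pileup` object.
#' @return data.frame with one row per covered position: transcript, pos,
#'   ref base, depth (sum of base counts) and per-base counts.
#' @export
pileup_columns <- function(pile) {
  out <- lapply(names(pile$transcripts), function(id) {
    cm <- pile$transcripts[[id]]$counts
    depth <- colSums(cm)
    keep <- which(depth > 0)
    if (!length(keep)) return(NULL)
    refchars <- strsplit(pile$reference[[id]], "")[[1]]
    data.frame(transcript = id, pos = keep, ref = refchars[keep],
               depth = depth[keep], A = cm[1, keep], C = cm[2, keep],
               G = cm[3, keep], T = cm[4, keep], N = cm[5, keep],
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map transcripts onto a genome
#'
#' Chains exact k-mer matches per (chromosome, strand) into colinear blocks
#' (one block per diagonal run; isolated mismatches are bridged within a
#' block, indels open a new block), extends block ends base-by-base, and
#' keeps the single best locus per transcript by alignment score
#' (match +1, mismatch -1, gap base -2).  Records failing `min_identity`
#' or `min_coverage` are omitted.
#'
#' @param transcripts a `transcript_set`.
#' @param genome named character vector of chromosome sequences, or a FASTA
#'   path.
#' @param genome_label label stored with each mapping (e.g. "A").
#' @param min_identity minimum fraction of matching bases over the aligned
#'   region (default 0.9).
#' @param min_coverage minimum fraction of the transcript aligned
#'   (default 0.5).
#' @param k seed length.
#' @return data.frame of mapping records: transcript, qlen, genome, chrom,
#'   start, end, strand, identity, coverage, score and a `blocks` list
#'   column of (qstart, qend, tstart, tend) matrices, 1-based inclusive,
#'   ordered by chromosome coordinate.
#' @export
map_transcripts <- function(transcripts, genome, genome_label = "genome",
                            min_identity = 0.9, min_coverage = 0.5, k = 21) {
  qs <- as_seq_vector(transcripts)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_fasta(genome)
  if (length(genome) == 0 || sum(nchar(genome)) == 0)
    stop("empty genome")
  res <- cpp_map_seqs(unname(qs), unname(genome), as.integer(k), 50L)
  rows <- list()
  blocks <- list()
  for (i in seq_along(qs)) {
    r <- res[[i]]
    if (is.null(r)) next
    if (r$identity < min_identity || r$coverage < min_coverage) next
    bm <- r$blocks
    colnames(bm) <- c("qstart", "qend", "tstart", "tend")
    rows[[length(rows) + 1]] <- data.frame(
      transcript = names(qs)[i], qlen = nchar(qs[[i]]),
      genome = genome_label, chrom = names(genome)[r$target],
      start = min(bm[, "tstart"]), end = max(bm[, "tend"]),
      strand = r$strand, identity = r$identity, coverage = r$coverage,
      score = r$score, stringsAsFactors = FALSE)
    blocks[[length(blocks) + 1]] <- bm
  }
  if (!length(rows)) {
    out <- data.frame(transcript = character(0), qlen = integer(0),
                      genome = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0),
                      coverage = numeric(0), score = numeric(0))
    out$blocks <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  out$blocks <- blocks
  out
}
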