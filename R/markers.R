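# Selection of anchored indels usable as PCR markers and a deterministic
# flanking-primer heuristic (Wallace-rule Tm; a dependency-free stand-in
# for thermodynamic primer design).

#' Select marker-eligible indels
#'
#' Retains non-redundant indels strictly longer than `min_length - 1` bp
#' (default: longer than 3 bp, i.e. >= 4) that are anchored to the chosen
#' genome.
#'
#' @param anchored anchored variants ([lift_variants()]) on the genome
#'   used for marker placement.
#' @param min_length minimum indel length in bp (default 4).
#' @return data.frame of eligible indels with an `indel_length` column.
#' @export
select_marker_indels <- function(anchored, min_length = 4) {
  len <- ifelse(anchored$class == "deletion", nchar(anchored$ref),
                ifelse(anchored$class == "insertion", nchar(anchored$alt), 0L))
  keep <- anchored$class %in% c("insertion", "deletion") &
    len >= min_length & anchored$anchored
  out <- anchored[keep, , drop = FALSE]
  out$indel_length <- len[keep]
  rownames(out) <- NULL
  out
}

wallace_tm <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

gc_frac <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  sum(b %in% c("G", "C")) / length(b)
}

has_long_run <- function(seq, max_run) {
  grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}", max_run + 1, max_run + 1,
                max_run + 1, max_run + 1), seq)
}

# enumerate qualifying primer windows in seq[lo..hi] (1-based inclusive)
primer_candidates <- function(seq, lo, hi, lengths, gc, max_run) {
  out <- list()
  for (len in lengths) {
    starts <- seq.int(lo, hi - len + 1L)
    starts <- starts[starts >= 1]
    for (s in starts) {
      w <- substr(seq, s, s + len - 1L)
      g <- gc_frac(w)
      if (g < gc[1] || g > gc[2]) next
      if (has_long_run(w, max_run)) next
      out[[length(out) + 1]] <- data.frame(start = s, end = s + len - 1L,
                                           seq = w, tm = wallace_tm(w),
                                           gc = g, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  cand <- do.call(rbind, out)
  cand[order(abs(cand$gc - 0.5), cand$start), , drop = FALSE]
}

#' Design flanking primers for an indel
#'
#' Deterministic heuristic: searches 18-24-mers within `flank` bp on each
#' side of the indel satisfying GC 40-60%, no mononucleotide run longer
#' than `max_run`, and Wallace-rule Tm (2(A+T) + 4(G+C)) within `tm_diff`
#' degrees between the pair, aiming for a reference-allele amplicon of
#' `amplicon[1]`-`amplicon[2]` bp.  The right primer is the reverse
#' complement of its transcript window.  When no window qualifies an
#' empty `primer_failure` value is returned, carrying the reason.
#'
#' @param transcript_seq reference transcript sequence containing the
#'   indel.
#' @param pos anchor position (base before the event, 1-based).
#' @param indel_length event length in bp.
#' @param class "insertion" or "deletion".
#' @param lengths candidate primer lengths.
#' @param flank search window on each side, bp.
#' @param gc GC-content bounds.
#' @param tm_diff maximum Tm difference between the two primers.
#' @param amplicon target reference-allele amplicon size range, bp.
#' @param max_run longest allowed mononucleotide run.
#' @return list with `left`, `right` (seq, start, end, tm, gc),
#'   `amplicon_ref`, `amplicon_alt`; or `NULL` with the failure reason in
#'   `attr(, "reason")` (attached via a classed `primer_failure` value).
#' @export
design_primers <- function(transcript_seq, pos, indel_length, class,
                           lengths = 18:24, flank = 150, gc = c(0.40, 0.60),
                           tm_diff = 3, amplicon = c(100, 300),
                           max_run = 4) {
  L <- nchar(transcript_seq)
  event_end <- if (class == "deletion") pos + indel_length else pos + 1L
  if (pos < min(lengths) + 10L || L - event_end < min(lengths) + 10L)
    return(primer_failure("indel too close to a transcript end"))
  left <- primer_candidates(transcript_seq, max(1L, pos - flank), pos,
                            lengths, gc, max_run)
  right_windows <- primer_candidates(transcript_seq, event_end,
                                     min(L, event_end + flank), lengths, gc,
                                     max_run)
  if (is.null(left) || is.null(right_windows))
    return(primer_failure("no primer window satisfies the GC/run constraints"))
  left <- utils::head(left, 60)
  right_windows <- utils::head(right_windows, 60)
  for (i in seq_len(nrow(left))) {
    for (j in seq_len(nrow(right_windows))) {
      size_ref <- right_windows$end[j] - left$start[i] + 1L
      if (size_ref < amplicon[1] || size_ref > amplicon[2]) next
      if (abs(left$tm[i] - right_windows$tm[j]) > tm_diff) next
      size_alt <- size_ref +
        if (class == "insertion") indel_length else -indel_length
      return(list(
        left = list(seq = left$seq[i], start = left$start[i],
                    end = left$end[i], tm = left$tm[i], gc = left$gc[i]),
        right = list(seq = revcomp(right_windows$seq[j]),
                     start = right_windows$start[j],
                     end = right_windows$end[j], tm = right_windows$tm[j],
                     gc = right_windows$gc[j]),
        amplicon_ref = size_ref, amplicon_alt = size_alt))
    }
  }
  primer_failure("no primer pair satisfies Tm/amplicon constraints")
}

# a "none" result that still carries why: NULL-like, tested with is.null()
# semantics via is_primer_failure() / marker_table()
primer_failure <- function(reason) {
  structure(list(), class = "primer_failure", reason = reason)
}

#' Did primer design fail?
#'
#' @param x result of [design_primers()].
#' @return `TRUE` for a failed design (the reason is in `attr(x, "reason")`).
#' @export
is_primer_failure <- function(x) inherits(x, "primer_failure")

#' Build a marker table for a set of eligible indels
#'
#' @param eligible output of [select_marker_indels()].
#' @param transcripts the reference `transcript_set` the indels were
#'   called on.
#' @param ... passed to [design_primers()].
#' @return data.frame, one row per indel with a designed primer pair:
#'   marker id, anchor coordinates, primer sequences, Tm, GC and expected
#'   amplicon sizes per allele.
#' @export
marker_table <- function(eligible, transcripts, ...) {
  seqs <- as_seq_vector(transcripts)
  rows <- list()
  for (i in seq_len(nrow(eligible))) {
    ts <- seqs[[eligible$transcript[i]]]
    pr <- design_primers(ts, eligible$pos[i], eligible$indel_length[i],
                         eligible$class[i], ...)
    if (is_primer_failure(pr)) next
    rows[[length(rows) + 1]] <- data.frame(
      marker = sprintf("M%04d", i), transcript = eligible$transcript[i],
      pos = eligible$pos[i], class = eligible$class[i],
      indel_length = eligible$indel_length[i],
      chrom = eligible$chrom[i], chrom_pos = eligible$chrom_pos[i],
      left_primer = pr$left$seq, right_primer = pr$right$seq,
      left_tm = pr$left$tm, right_tm = pr$right$tm,
      left_gc = pr$left$gc, right_gc = pr$right$gc,
      amplicon_ref = pr$amplicon_ref, amplicon_alt = pr$amplicon_alt,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(marker = character(0), transcript = character(0),
                      pos = integer(0), class = character(0),
                      indel_length = integer(0), chrom = character(0),
                      chrom_pos = integer(0), left_primer = character(0),
                      right_primer = character(0), left_tm = numeric(0),
                      right_tm = numeric(0), left_gc = numeric(0),
                      right_gc = numeric(0), amplicon_ref = integer(0),
                      amplicon_alt = integer(0)))
  do.call(rbind, rows)
}
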