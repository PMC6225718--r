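# Transfer transcript-coordinate variants onto pseudomolecule genomes via
# transcript mapping records, tally per chromosome, and integrate the two
# anchor sets.

#' Lift variants onto a genome through transcript mappings
#'
#' A variant whose transcript position falls inside an aligned block is
#' lifted by block offset arithmetic ('-'-strand mappings reverse the
#' within-block direction); positions in unaligned gaps between blocks are
#' left unanchored.  Indels are anchored by their anchor base; a deletion
#' whose span crosses a block edge (or an insertion whose anchor is the
#' last aligned base) is unanchored.  At most one mapping (the best locus)
#' exists per transcript, so anchoring is injective per genome.
#'
#' @param calls `nr_set` or `pairwise_calls` data.frame.
#' @param mappings mapping records from [map_transcripts()].
#' @return data.frame with the input columns plus `genome`, `chrom`,
#'   `chrom_pos`, `strand`, `anchored`.
#' @export
lift_variants <- function(calls, mappings) {
  n <- nrow(calls)
  genome <- rep(if (nrow(mappings)) mappings$genome[1] else NA_character_, n)
  chrom <- rep(NA_character_, n)
  cpos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  anchored <- rep(FALSE, n)
  midx <- match(calls$transcript, mappings$transcript)
  for (i in seq_len(n)) {
    m <- midx[i]
    if (is.na(m)) next
    p <- calls$pos[i]
    if (p < 1 || p > mappings$qlen[m])
      stop("variant position ", p, " outside transcript ",
           calls$transcript[i], " (length ", mappings$qlen[m], ")")
    span_end <- switch(calls$class[i],
                       deletion = p + nchar(calls$ref[i]),
                       insertion = p + 1L,
                       p)
    bm <- mappings$blocks[[m]]
    b <- which(bm[, "qstart"] <= p & p <= bm[, "qend"])
    if (!length(b)) next
    b <- b[1]
    if (span_end > bm[b, "qend"]) next # event crosses a block edge
    chrom[i] <- mappings$chrom[m]
    strand[i] <- mappings$strand[m]
    cpos[i] <- if (mappings$strand[m] == "+")
      bm[b, "tstart"] + (p - bm[b, "qstart"])
    else
      bm[b, "tstart"] + (bm[b, "qend"] - p)
    anchored[i] <- TRUE
  }
  out <- cbind(as.data.frame(calls)[
    setdiff(names(calls), "blocks")],
    genome = genome, chrom = chrom, chrom_pos = cpos, strand = strand,
    anchored = anchored, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Lift a single variant through its mapping record
#'
#' @param call one-row variant data.frame.
#' @param mapping one-row mapping record for the call's transcript.
#' @return a one-row anchored data.frame, or `NULL` when the position falls
#'   in an unaligned gap.
#' @export
lift_variant <- function(call, mapping) {
  if (call$transcript[1] != mapping$transcript[1])
    stop("mapping record does not belong to the call's transcript")
  out <- lift_variants(call[1, , drop = FALSE], mapping[1, , drop = FALSE])
  if (!out$anchored[1]) return(NULL)
  out
}

#' Per-chromosome tallies and binned densities of anchored variants
#'
#' @param anchored data.frame from [lift_variants()] (rows with
#'   `anchored = FALSE` are ignored).
#' @param bin_size density bin width in bp (default 1 kb, suited to
#'   synthetic genomes; use 1 Mb for real pseudomolecules).
#' @return list with `counts` (genome, chrom, n) and `density`
#'   (bedgraph-style genome, chrom, start, 0-based, end, count).
#' @export
tally_per_chromosome <- function(anchored, bin_size = 1000) {
  a <- anchored[anchored$anchored, , drop = FALSE]
  if (!nrow(a)) {
    return(list(counts = data.frame(genome = character(0),
                                    chrom = character(0), n = integer(0)),
                density = data.frame(genome = character(0),
                                     chrom = character(0), start = integer(0),
                                     end = integer(0), count = integer(0))))
  }
  cnt <- stats::aggregate(list(n = a$chrom), by = list(genome = a$genome,
                                                       chrom = a$chrom),
                          FUN = length)
  bin <- (a$chrom_pos - 1L) %/% bin_size
  dens <- stats::aggregate(list(count = bin),
                           by = list(genome = a$genome, chrom = a$chrom,
                                     bin = bin), FUN = length)
  dens <- data.frame(genome = dens$genome, chrom = dens$chrom,
                     start = dens$bin * bin_size,
                     end = (dens$bin + 1L) * bin_size, count = dens$count)
  list(counts = cnt[order(cnt$genome, cnt$chrom), , drop = FALSE],
       density = dens[order(dens$genome, dens$chrom, dens$start), ,
                      drop = FALSE])
}

#' Integrate anchor sets from two genomes over one non-redundant set
#'
#' Partitions the non-redundant variants into anchored-to-both, A-only,
#' B-only and neither (the four classes always sum to the NR cardinality),
#' and builds the union of placed variants, preferring the coordinates of
#' `prefer` when a variant is anchored to both genomes.
#'
#' @param anchors_A,anchors_B outputs of [lift_variants()] against the two
#'   genomes, derived from the same NR set.
#' @param nr the `nr_set` both anchor sets derive from.
#' @param prefer which genome's coordinates the union keeps for
#'   variants anchored to both ("A" or "B").
#' @return object of class `anchor_integration`: counts, fractions, the
#'   union data.frame, and the total.
#' @export
integrate_two_genomes <- function(anchors_A, anchors_B, nr, prefer = "A") {
  prefer <- match.arg(prefer, c("A", "B"))
  nrkey <- variant_key(nr)
  keyA <- variant_key(anchors_A)
  keyB <- variant_key(anchors_B)
  if (!all(keyA %in% nrkey) || !all(keyB %in% nrkey))
    stop("anchor sets contain variants absent from the NR set")
  inA <- nrkey %in% keyA[anchors_A$anchored]
  inB <- nrkey %in% keyB[anchors_B$anchored]
  classes <- ifelse(inA & inB, "both",
                    ifelse(inA, "A_only", ifelse(inB, "B_only", "neither")))
  counts <- c(both = sum(inA & inB), A_only = sum(inA & !inB),
              B_only = sum(!inA & inB), neither = sum(!inA & !inB))
  takeA <- if (prefer == "A") inA else (inA & !inB)
  rows <- list()
  if (any(takeA)) {
    ia <- match(nrkey[takeA], keyA)
    rows[[1]] <- anchors_A[ia, , drop = FALSE]
  }
  takeB <- inB & !(takeA)
  if (any(takeB)) {
    ib <- match(nrkey[takeB], keyB)
    rows[[length(rows) + 1]] <- anchors_B[ib, , drop = FALSE]
  }
  union <- if (length(rows)) do.call(rbind, rows) else
    anchors_A[0, , drop = FALSE]
  union$anchor_class <- classes[match(variant_key(union), nrkey)]
  rownames(union) <- NULL
  structure(list(counts = counts, fractions = counts / max(1, nrow(nr)),
                 union = union, total = nrow(nr)),
            class = "anchor_integration")
}

#' @export
print.anchor_integration <- function(x, ...) {
  cat("<anchor_integration>", x$total, "non-redundant variants\n")
  for (cl in names(x$counts))
    cat(sprintf("  %-8s %6d  (%.2f%%)\n", cl, x$counts[[cl]],
                100 * x$fractions[[cl]]))
  cat(sprintf("  placed on chromosomes: %d\n", nrow(x$union)))
  invisible(x)
}

#' Serialize an integration report as JSON
#'
#' @param x `anchor_integration`.
#' @param path output path.
#' @export
write_integration_json <- function(x, path) {
  jsonlite::write_json(list(total = x$total, counts = as.list(x$counts),
                            fractions = as.list(x$fractions)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
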