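# Reciprocal-best-hit orthology between two transcript sets, FPKM
# quantification from concordant fragments, and rank-correlation
# comparisons across ortholog pairs.

#' Reciprocal-best-hit orthologs between two transcript sets
#'
#' Each transcript's best hit in the other set is found with the in-package
#' seed-and-extend scorer (match +1, mismatch -1, gap base -2, the same
#' engine as [map_transcripts()]); a pair is emitted iff the two best hits
#' agree in both directions and query coverage (aligned query bases /
#' query length) strictly exceeds `min_coverage` in both directions.
#' A score tie for best hit disqualifies the query (logged).
#'
#' @param set1,set2 `transcript_set`s.
#' @param min_coverage strict coverage threshold, default 0.80.
#' @param k seed length.
#' @return data.frame: id1, id2, coverage12, coverage21, score12, score21.
#'   Tied queries are reported in `attr(, "n_ties")`.
#' @export
rbh_orthologs <- function(set1, set2, min_coverage = 0.80, k = 21) {
  s1 <- as_seq_vector(set1)
  s2 <- as_seq_vector(set2)
  if (!length(s1) || !length(s2)) stop("both transcript sets must be non-empty")
  fwd <- cpp_map_seqs(unname(s1), unname(s2), as.integer(k), 50L)
  rev <- cpp_map_seqs(unname(s2), unname(s1), as.integer(k), 50L)
  best <- function(res) {
    t(vapply(res, function(r) {
      if (is.null(r)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
      tie <- !is.na(r$second_score) && r$second_score == r$score
      c(if (tie) NA_real_ else r$target, r$score, r$coverage,
        as.numeric(tie))
    }, numeric(4)))
  }
  b1 <- best(fwd)
  b2 <- best(rev)
  n_ties <- sum(b1[, 4], b2[, 4])
  rows <- list()
  for (i in seq_along(s1)) {
    t2 <- b1[i, 1]
    if (is.na(t2)) next
    if (is.na(b2[t2, 1]) || b2[t2, 1] != i) next
    if (!strictly_over(b1[i, 3], 1, min_coverage)) next
    if (!strictly_over(b2[t2, 3], 1, min_coverage)) next
    rows[[length(rows) + 1]] <- data.frame(
      id1 = names(s1)[i], id2 = names(s2)[t2],
      coverage12 = b1[i, 3], coverage21 = b2[t2, 3],
      score12 = b1[i, 2], score21 = b2[t2, 2], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id1 = character(0), id2 = character(0),
               coverage12 = numeric(0), coverage21 = numeric(0),
               score12 = numeric(0), score21 = numeric(0))
  if (n_ties > 0)
    message(n_ties, " best-hit score tie(s); tied queries excluded")
  attr(out, "n_ties") <- n_ties
  out
}

#' FPKM from concordantly aligned fragments
#'
#' A fragment is counted iff both mates map to the same transcript on
#' opposite strands.  FPKM = fragments * 1e9 / (transcript length * total
#' counted fragments).
#'
#' @param aln paired alignment table ([align_reads()] on a `read_pairs`
#'   object, or [read_sam()] of a paired SAM); must carry mate flags.
#' @param transcripts the reference `transcript_set`.
#' @return data.frame: transcript, length, fragments, fpkm.  Total counted
#'   fragments in `attr(, "total_fragments")`.
#' @export
fpkm <- function(aln, transcripts) {
  refs <- as_seq_vector(transcripts)
  if (all(is.na(aln$mate)))
    stop("unpaired input: alignment table has no mate flags")
  m1 <- aln[!is.na(aln$mate) & aln$mate == 1L, , drop = FALSE]
  m2 <- aln[!is.na(aln$mate) & aln$mate == 2L, , drop = FALSE]
  j <- match(m1$qname, m2$qname)
  ok <- !is.na(j) & m1$mapped & m2$mapped[j] &
    !is.na(m1$ref) & m1$ref == m2$ref[j] & m1$strand != m2$strand[j]
  counts <- table(factor(m1$ref[ok], levels = names(refs)))
  total <- sum(counts)
  out <- data.frame(transcript = names(refs), length = unname(nchar(refs)),
                    fragments = as.integer(counts), stringsAsFactors = FALSE)
  out$fpkm <- if (total > 0)
    out$fragments * 1e9 / (out$length * total) else 0
  attr(out, "total_fragments") <- total
  out
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall's tau with a two-sided p-value (exact enumeration
#' over concordant/discordant pairs via [stats::cor.test()]; with ties the
#' p-value uses the normal approximation).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return list: `tau`, `p`, `n`.  A constant input vector gives
#'   `tau = NA` (undefined).
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(tau = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Ortholog-pair diversity comparison
#'
#' Joins per-transcript theta of the two species on ortholog pairs,
#' restricts to pairs where at least one species is polymorphic, and
#' reports Kendall's tau over the joined theta values.
#'
#' @param pairs output of [rbh_orthologs()].
#' @param theta1,theta2 outputs of [theta_by_transcript()] on each
#'   species' own reference set (theta1 keyed by `id1`, theta2 by `id2`).
#' @param value column to correlate ("theta_per_site" or "theta").
#' @return list: `table` (joined data.frame), `tau`, `p`, `n`.
#' @export
ortho_theta_scatter <- function(pairs, theta1, theta2,
                                value = "theta_per_site") {
  i1 <- match(pairs$id1, theta1$transcript)
  i2 <- match(pairs$id2, theta2$transcript)
  if (anyNA(i1) || anyNA(i2))
    stop("ortholog pair references a transcript absent from the theta tables")
  tab <- data.frame(id1 = pairs$id1, id2 = pairs$id2,
                    S1 = theta1$S[i1], S2 = theta2$S[i2],
                    theta1 = theta1[[value]][i1],
                    theta2 = theta2[[value]][i2], stringsAsFactors = FALSE)
  tab <- tab[tab$S1 > 0 | tab$S2 > 0, , drop = FALSE]
  kt <- if (nrow(tab) >= 2) kendall_tau(tab$theta1, tab$theta2)
        else list(tau = NA_real_, p = NA_real_, n = nrow(tab))
  list(table = tab, tau = kt$tau, p = kt$p, n = nrow(tab))
}
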