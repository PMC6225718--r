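# Pairwise SNP/indel calling with the strict depth / consensus-fraction
# rule, self-comparison artifact filtering, and non-redundant consolidation
# per reference transcript set.

variant_key <- function(df) {
  paste(df$transcript, df$pos, df$class, df$alt, sep = "\r")
}

#' Call SNPs and indels from a pileup
#'
#' A column yields a call iff its depth is strictly greater than
#' `min_depth` (default 10) AND a single non-reference allele accounts for
#' strictly more than `min_fraction` (default 0.95) of the depth.  The same
#' rule applies to insertion and deletion keys at their anchor column.
#' Multi-allelic columns where no single allele clears the fraction yield
#' nothing; zero-depth columns are skipped.  N never counts as a callable
#' allele (but does count towards depth).
#'
#' @param pile `pileup` of one read accession against one reference
#'   transcript set.
#' @param read_accession,reference_accession provenance labels (defaults
#'   from the pileup's alignment metadata where available).
#' @param min_depth depth must be `> min_depth` (strict).
#' @param min_fraction allele fraction must be `> min_fraction` (strict).
#' @return data.frame of class `pairwise_calls`: read_accession,
#'   reference_accession, transcript, pos, ref, alt, class, depth,
#'   non_ref_fraction.
#' @export
call_variants <- function(pile, read_accession = NA,
                          reference_accession = NULL,
                          min_depth = 10, min_fraction = 0.95) {
  stopifnot(inherits(pile, "pileup"))
  reference_accession <- reference_accession %||%
    (pile$reference_accession %||% NA)
  out <- list()
  bases <- c("A", "C", "G", "T")
  for (id in names(pile$transcripts)) {
    tr <- pile$transcripts[[id]]
    cm <- tr$counts
    depth <- colSums(cm)
    covered <- which(depth > min_depth)
    if (length(covered)) {
      refchars <- strsplit(pile$reference[[id]], "")[[1]]
      top <- max.col(t(cm[1:4, covered, drop = FALSE]), ties.method = "first")
      topc <- cm[1:4, covered, drop = FALSE][cbind(top, seq_along(covered))]
      alt <- bases[top]
      hit <- alt != refchars[covered] &
        strictly_over(topc, depth[covered], min_fraction)
      if (any(hit)) {
        out[[length(out) + 1]] <- data.frame(
          transcript = id, pos = covered[hit], ref = refchars[covered][hit],
          alt = alt[hit], class = "SNP", depth = unname(depth[covered][hit]),
          non_ref_fraction = unname(topc[hit] / depth[covered][hit]),
          stringsAsFactors = FALSE)
      }
    }
    for (kind in c("ins", "del")) {
      tab <- tr[[kind]]
      if (!nrow(tab)) next
      d <- depth[tab$pos]
      hit <- d > min_depth & strictly_over(tab$count, d, min_fraction)
      if (!any(hit)) next
      out[[length(out) + 1]] <- data.frame(
        transcript = id, pos = tab$pos[hit],
        ref = if (kind == "ins") "-" else tab$seq[hit],
        alt = if (kind == "ins") tab$seq[hit] else "-",
        class = if (kind == "ins") "insertion" else "deletion",
        depth = unname(d[hit]),
        non_ref_fraction = unname(tab$count[hit] / d[hit]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(transcript = character(0), pos = integer(0),
               ref = character(0), alt = character(0), class = character(0),
               depth = numeric(0), non_ref_fraction = numeric(0),
               stringsAsFactors = FALSE)
  res <- cbind(read_accession = rep(read_accession, nrow(res)),
               reference_accession = rep(reference_accession, nrow(res)),
               res, stringsAsFactors = FALSE)
  res <- res[order(res$transcript, res$pos, res$class), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("pairwise_calls", "data.frame")
  res
}

#' Remove self-comparison artifacts from a pairwise call set
#'
#' Variants also found when the reference accession's own reads are
#' compared against its own transcripts are systematic artifacts; every
#' call whose (transcript, position, class, alt) key appears in the
#' self-comparison set is removed.
#'
#' @param pairwise calls of one read accession vs the reference.
#' @param self_calls calls of the reference accession vs itself.
#' @return filtered `pairwise_calls`; the number of removed calls is in
#'   `attr(, "n_removed")`.
#' @export
filter_artifacts <- function(pairwise, self_calls) {
  ra <- unique(self_calls$reference_accession)
  rb <- unique(pairwise$reference_accession)
  if (length(ra) && length(rb) && !identical(ra, rb))
    stop("self_calls and pairwise calls use different reference accessions (",
         ra[1], " vs ", rb[1], ")")
  if (nrow(self_calls) &&
      !all(self_calls$read_accession == self_calls$reference_accession))
    stop("self_calls must come from the reference accession's own reads")
  drop <- variant_key(pairwise) %in% variant_key(self_calls)
  out <- pairwise[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  class(out) <- c("pairwise_calls", "data.frame")
  out
}

#' Consolidate pairwise call sets into a non-redundant set
#'
#' Union over read accessions against one fixed reference transcript set,
#' deduplicated by (transcript, position, class, alt allele); the
#' supporting read accessions of each non-redundant variant are retained.
#' Self-comparisons (read accession equal to the reference accession) are
#' excluded.
#'
#' @param call_list list of `pairwise_calls` sharing one reference
#'   accession.
#' @return data.frame of class `nr_set` with columns transcript, pos, ref,
#'   alt, class, supporters, n_supporters.
#' @export
consolidate_nonredundant <- function(call_list) {
  if (inherits(call_list, "data.frame")) call_list <- list(call_list)
  refs <- unique(unlist(lapply(call_list, function(x)
    unique(x$reference_accession))))
  refs <- refs[!is.na(refs)]
  if (length(refs) > 1)
    stop("all pairwise sets must share one reference accession; got: ",
         paste(refs, collapse = ", "))
  all <- do.call(rbind, lapply(call_list, as.data.frame))
  all <- all[is.na(all$read_accession) |
               all$read_accession != all$reference_accession, , drop = FALSE]
  if (!nrow(all)) {
    out <- data.frame(transcript = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      class = character(0), supporters = character(0),
                      n_supporters = integer(0), stringsAsFactors = FALSE)
    attr(out, "reference_accession") <- if (length(refs)) refs else NA
    class(out) <- c("nr_set", "data.frame")
    return(out)
  }
  key <- variant_key(all)
  first <- !duplicated(key)
  sup <- vapply(split(all$read_accession, key), function(s)
    paste(sort(unique(s)), collapse = ","), "")
  out <- all[first, c("transcript", "pos", "ref", "alt", "class"),
             drop = FALSE]
  out$supporters <- unname(sup[key[first]])
  out$n_supporters <- lengths(strsplit(out$supporters, ","))
  out <- out[order(out$transcript, out$pos, out$class, out$alt), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_accession") <- if (length(refs)) refs else NA
  class(out) <- c("nr_set", "data.frame")
  out
}

#' Pairwise variant count table
#'
#' Summarises a collection of pairwise call sets as a read-accession by
#' reference-accession count table of SNPs and indels (the layout of a
#' pairwise comparison matrix among accessions).
#'
#' @param call_list list of `pairwise_calls`.
#' @return data.frame: reference_accession, read_accession, n_snp, n_indel.
#' @export
variant_count_table <- function(call_list) {
  if (inherits(call_list, "data.frame")) call_list <- list(call_list)
  rows <- lapply(call_list, function(x) {
    data.frame(reference_accession = attr(x, "reference_accession") %||%
                 unique(x$reference_accession)[1],
               read_accession = unique(x$read_accession)[1],
               n_snp = sum(x$class == "SNP"),
               n_indel = sum(x$class != "SNP"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
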