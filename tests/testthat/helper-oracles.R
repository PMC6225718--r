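# Independent brute-force oracles, deliberately coded differently from the
# package implementations they check.

# diversity statistics by explicit pairwise comparison of sequences
oracle_diversity <- function(alleles) {
  n <- ncol(alleles)
  S <- 0L
  singles <- 0L
  for (s in seq_len(nrow(alleles))) {
    tab <- table(alleles[s, ])
    if (length(tab) > 1) {
      S <- S + 1L
      if (min(tab) == 1) singles <- singles + 1L
    }
  }
  # mean pairwise differences
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(alleles[, i] != alleles[, j])
      np <- np + 1
    }
  }
  pi <- tot / np
  a1 <- 0
  a2 <- 0
  for (i in 1:(n - 1)) {
    a1 <- a1 + 1 / i
    a2 <- a2 + 1 / i^2
  }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  theta <- S / a1
  D <- if (S > 0) (pi - theta) / sqrt(e1 * S + e2 * S * (S - 1)) else NA_real_
  list(S = S, singletons = singles, theta = theta, pi = pi, D = D)
}

# Kendall tau-b by exhaustive pair enumeration
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- 0
  disc <- 0
  tx <- 0
  ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) { tx <- tx + 1; next }
      if (dy == 0) { ty <- ty + 1; next }
      if (dx == dy) conc <- conc + 1 else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  xt <- table(x)
  yt <- table(y)
  n1 <- sum(xt * (xt - 1) / 2)
  n2 <- sum(yt * (yt - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# per-position coverage by scanning each read's aligned reference span
oracle_depth <- function(aln, ref_len) {
  depth <- integer(ref_len)
  m <- aln[aln$mapped, , drop = FALSE]
  for (r in seq_len(nrow(m))) {
    ops <- regmatches(m$cigar[r], gregexpr("[0-9]+[MIDNSHP=X]", m$cigar[r]))[[1]]
    at <- m$pos[r]
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        depth[at:(at + len - 1)] <- depth[at:(at + len - 1)] + 1L
        at <- at + len
      } else if (type %in% c("D", "N")) {
        at <- at + len
      }
    }
  }
  depth
}

# construct a pileup object directly from count specifications
make_pileup <- function(ref_seqs, counts = list(), ins = list(), del = list()) {
  empty_tab <- data.frame(pos = integer(0), seq = character(0),
                          count = integer(0), stringsAsFactors = FALSE)
  transcripts <- lapply(names(ref_seqs), function(id) {
    L <- nchar(ref_seqs[[id]])
    cm <- matrix(0L, 5, L, dimnames = list(c("A", "C", "G", "T", "N"), NULL))
    if (!is.null(counts[[id]])) {
      for (r in seq_len(nrow(counts[[id]]))) {
        row <- counts[[id]][r, ]
        cm[row$base, row$pos] <- row$count
      }
    }
    list(counts = cm, ins = ins[[id]] %||% empty_tab,
         del = del[[id]] %||% empty_tab)
  })
  names(transcripts) <- names(ref_seqs)
  structure(list(transcripts = transcripts, reference = ref_seqs,
                 reference_accession = "REF"), class = "pileup")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# truth-derived expected pairwise difference keys between two accessions
truth_pairwise_keys <- function(bundle, read_acc, ref_acc, species = "A") {
  tr <- bundle$truth[bundle$truth$species == species, , drop = FALSE]
  carr <- strsplit(tr$carriers, ",")
  has <- function(a) vapply(carr, function(x) a %in% x, logical(1))
  diff <- xor(has(read_acc), has(ref_acc))
  paste(tr$gene[diff], tr$pos[diff], tr$class[diff])
}

# truth-derived expected non-redundant keys for one reference accession
truth_nr_keys <- function(bundle, ref_acc, panel, species = "A") {
  tr <- bundle$truth[bundle$truth$species == species, , drop = FALSE]
  carr <- strsplit(tr$carriers, ",")
  has_ref <- vapply(carr, function(x) ref_acc %in% x, logical(1))
  n_carr <- lengths(carr)
  # polymorphic between the reference and at least one other panel member
  poly <- (has_ref & n_carr < length(panel)) | (!has_ref & n_carr >= 1)
  paste(tr$gene[poly], tr$pos[poly], tr$class[poly])
}
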