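# Cross-species high-confidence SNP matrix and population-genetic
# summaries: segregating sites, Watterson's theta, nucleotide diversity,
# Tajima's D, fixed differences, outgroup-polarized site-frequency
# spectra, and neighbor-joining trees with bootstrap support.

new_snp_matrix <- function(sites, alleles, species, L_total, L_by_transcript,
                           reference_accession, n_multiallelic) {
  structure(list(sites = sites, alleles = alleles, species = species,
                 L_total = L_total, L_by_transcript = L_by_transcript,
                 reference_accession = reference_accession,
                 n_multiallelic = n_multiallelic), class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf(paste0("<snp_matrix> %d biallelic sites x %d accessions, ",
                     "%d comparable sites, %d multi-allelic dropped\n"),
              nrow(x$alleles), ncol(x$alleles), x$L_total, x$n_multiallelic))
  invisible(x)
}

#' Per-accession consensus base calls from a pileup
#'
#' The consensus at a position is the base whose count strictly exceeds
#' `min_fraction` of the depth at a depth strictly greater than
#' `min_depth`; every other position is ambiguous ("N").
#'
#' @param pile a `pileup`.
#' @param min_depth,min_fraction strict thresholds (see [call_variants()]).
#' @return named list of per-transcript consensus character vectors.
#' @export
accession_consensus <- function(pile, min_depth = 10, min_fraction = 0.95) {
  stopifnot(inherits(pile, "pileup"))
  bases <- c("A", "C", "G", "T")
  out <- lapply(pile$transcripts, function(tr) {
    cm <- tr$counts
    depth <- colSums(cm)
    top <- max.col(t(cm[1:4, , drop = FALSE]), ties.method = "first")
    topc <- cm[1:4, , drop = FALSE][cbind(top, seq_along(depth))]
    cons <- ifelse(depth > min_depth & strictly_over(topc, depth, min_fraction),
                   bases[top], "N")
    cons
  })
  out
}

#' Build the high-confidence cross-species SNP matrix
#'
#' A site is retained iff every accession has an unambiguous consensus
#' allele there (depth strictly over `min_depth`, single allele strictly
#' over `min_fraction` of depth).  Retained polymorphic sites must be
#' biallelic across the full panel; sites with more than two alleles are
#' dropped and counted.  `L_total` counts all sites passing the coverage
#' filters in all accessions (monomorphic included), which is the
#' denominator for per-site statistics.
#'
#' @param consensus_list named list (per accession) of outputs of
#'   [accession_consensus()]; must include the reference accession (whose
#'   consensus, from its self-alignment, is its reference base wherever
#'   covered).
#' @param species named character vector mapping each accession to
#'   "ingroupA", "ingroupB" or "outgroup".
#' @param reference_accession id of the reference transcript set's
#'   accession.
#' @return a `snp_matrix`.
#' @export
build_snp_matrix <- function(consensus_list, species, reference_accession) {
  accs <- names(consensus_list)
  missing <- setdiff(accs, names(species))
  if (length(missing))
    stop("accession(s) missing from the species map: ",
         paste(missing, collapse = ", "))
  transcripts <- names(consensus_list[[1]])
  sites <- list()
  allele_rows <- list()
  L_total <- 0L
  n_multi <- 0L
  Lt <- integer(length(transcripts))
  names(Lt) <- transcripts
  for (id in transcripts) {
    m <- vapply(accs, function(a) consensus_list[[a]][[id]],
                consensus_list[[1]][[id]])
    ok <- rowSums(m == "N") == 0L
    L_total <- L_total + sum(ok)
    Lt[id] <- sum(ok)
    if (!any(ok)) next
    sub <- m[ok, , drop = FALSE]
    nall <- apply(sub, 1, function(r) length(unique(r)))
    n_multi <- n_multi + sum(nall > 2)
    poly <- which(nall == 2)
    if (!length(poly)) next
    pos_ok <- which(ok)[poly]
    sites[[length(sites) + 1]] <- data.frame(
      transcript = id, pos = pos_ok,
      ref = consensus_list[[reference_accession]][[id]][pos_ok],
      stringsAsFactors = FALSE)
    allele_rows[[length(allele_rows) + 1]] <- sub[poly, , drop = FALSE]
  }
  if (length(sites)) {
    sites <- do.call(rbind, sites)
    alleles <- do.call(rbind, allele_rows)
    colnames(alleles) <- accs
    rownames(sites) <- rownames(alleles) <- NULL
  } else {
    sites <- data.frame(transcript = character(0), pos = integer(0),
                        ref = character(0))
    alleles <- matrix(character(0), 0, length(accs),
                      dimnames = list(NULL, accs))
  }
  new_snp_matrix(sites, alleles, species[accs], L_total,
                 data.frame(transcript = transcripts, L = unname(Lt)),
                 reference_accession, n_multi)
}

group_columns <- function(m, group) {
  if (length(group) == 1 && group %in% m$species)
    names(m$species)[m$species == group]
  else {
    unknown <- setdiff(group, colnames(m$alleles))
    if (length(unknown))
      stop("unknown accession(s): ", paste(unknown, collapse = ", "))
    group
  }
}

#' Tajima's D constants
#'
#' The normalizing constants a1, a2, b1, b2, c1, c2, e1, e2 for a sample of
#' size n (Tajima 1989).
#'
#' @param n sample size (>= 2).
#' @return named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("n must be >= 2")
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1,
       e2 = e2)
}

# per-site derived quantities within a group: allele count k of one allele
group_site_counts <- function(m, cols) {
  sub <- m$alleles[, cols, drop = FALSE]
  if (!nrow(sub))
    return(data.frame(k = integer(0), n_allele = integer(0)))
  first <- sub[, 1]
  k <- rowSums(sub == first)
  n_allele <- apply(sub, 1, function(r) length(unique(r)))
  data.frame(k = k, n_allele = n_allele)
}

#' Within-group diversity summary
#'
#' Computes, over the matrix columns of one group: the number of
#' segregating sites S, singleton and non-singleton counts, Watterson's
#' theta (S / a1), nucleotide diversity pi = sum over sites of
#' 2 k (n - k) / (n (n - 1)), and Tajima's D
#' = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1)), with the constants of
#' [tajima_constants()].  Per-site values divide by the number of
#' comparable sites L.  With S = 0, theta and pi are 0 and D is undefined
#' (NA).
#'
#' @param m a `snp_matrix`.
#' @param group species label ("ingroupA"/"ingroupB") or a character
#'   vector of accession ids (>= 2).
#' @param L comparable-site denominator; defaults to the matrix's
#'   `L_total` (all sites passing the coverage filters).
#' @return object of class `diversity_summary`.
#' @export
diversity_summary <- function(m, group, L = NULL) {
  stopifnot(inherits(m, "snp_matrix"))
  cols <- group_columns(m, group)
  n <- length(cols)
  if (n < 2) stop("group must contain at least 2 accessions")
  L <- L %||% m$L_total
  cst <- tajima_constants(n)
  gc <- group_site_counts(m, cols)
  seg <- gc$n_allele == 2
  S <- sum(seg)
  k <- gc$k[seg]
  minor <- pmin(k, n - k)
  singletons <- sum(minor == 1)
  pi_total <- sum(2 * k * (n - k) / (n * (n - 1)))
  theta_w <- S / cst$a1
  D <- if (S == 0) NA_real_
  else if (pi_total == theta_w) 0 # numerator identically zero (e.g. n = 2)
  else (pi_total - theta_w) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  structure(list(group = paste(group, collapse = ","), n = n, S = S,
                 singletons = singletons, non_singletons = S - singletons,
                 theta_w = theta_w,
                 theta_w_per_site = if (L > 0) theta_w / L else NA_real_,
                 pi = pi_total,
                 pi_per_site = if (L > 0) pi_total / L else NA_real_,
                 tajima_d = D, L = L, constants = cst),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, digits = 4, ...) {
  cat(sprintf("<diversity_summary> group %s (n = %d, L = %d sites)\n",
              x$group, x$n, x$L))
  cat(sprintf("  segregating sites   %d  (singletons %d, non-singletons %d)\n",
              x$S, x$singletons, x$non_singletons))
  cat(sprintf("  Watterson theta     %.*g  (per site %.*g)\n", digits,
              x$theta_w, digits, x$theta_w_per_site))
  cat(sprintf("  pi                  %.*g  (per site %.*g)\n", digits,
              x$pi, digits, x$pi_per_site))
  cat(sprintf("  Tajima's D          %s\n",
              if (is.na(x$tajima_d)) "undefined (S = 0)" else
                formatC(x$tajima_d, digits = digits, format = "g")))
  invisible(x)
}

#' @export
as.data.frame.diversity_summary <- function(x, ...) {
  data.frame(group = x$group, n = x$n, L = x$L, S = x$S,
             singletons = x$singletons, non_singletons = x$non_singletons,
             theta_w = x$theta_w, theta_w_per_site = x$theta_w_per_site,
             pi = x$pi, pi_per_site = x$pi_per_site, tajima_d = x$tajima_d)
}

#' Per-transcript Watterson's theta for one group
#'
#' @param m a `snp_matrix`.
#' @param group species label or accession ids.
#' @return data.frame: transcript, L (comparable sites), S, theta
#'   (S / a1) and theta_per_site.
#' @export
theta_by_transcript <- function(m, group) {
  cols <- group_columns(m, group)
  n <- length(cols)
  cst <- tajima_constants(n)
  gc <- group_site_counts(m, cols)
  seg <- gc$n_allele == 2
  St <- table(factor(m$sites$transcript[seg],
                     levels = m$L_by_transcript$transcript))
  out <- data.frame(transcript = m$L_by_transcript$transcript,
                    L = m$L_by_transcript$L, S = as.integer(St),
                    stringsAsFactors = FALSE)
  out$theta <- out$S / cst$a1
  out$theta_per_site <- ifelse(out$L > 0, out$theta / out$L, NA_real_)
  out
}

#' Outgroup-polarized site-frequency spectrum
#'
#' For each site polymorphic within the group: when the outgroup allele
#' equals one of the two group alleles, the other allele is the derived
#' one and the site increments the class of its derived count; an outgroup
#' carrying a third allele makes the site unpolarizable.  Class counts plus
#' the unpolarizable count always sum to S.
#'
#' @param m a `snp_matrix`.
#' @param group ingroup species label or accession ids.
#' @param outgroup outgroup accession id (default: the accession mapped to
#'   "outgroup").
#' @return object of class `polarized_sfs`: `n`, `counts` (classes
#'   1..n-1), `unpolarizable`, `S`.
#' @export
polarize_sfs <- function(m, group, outgroup = NULL) {
  cols <- group_columns(m, group)
  outgroup <- outgroup %||% names(m$species)[m$species == "outgroup"][1]
  if (is.na(outgroup) || !outgroup %in% colnames(m$alleles))
    stop("outgroup accession not present in the matrix")
  n <- length(cols)
  sub <- m$alleles[, cols, drop = FALSE]
  out_al <- m$alleles[, outgroup]
  counts <- integer(n - 1)
  unpol <- 0L
  for (s in seq_len(nrow(sub))) {
    r <- sub[s, ]
    u <- unique(r)
    if (length(u) != 2) next # monomorphic within this group
    if (out_al[s] == u[1]) der <- u[2]
    else if (out_al[s] == u[2]) der <- u[1]
    else { unpol <- unpol + 1L; next }
    counts[sum(r == der)] <- counts[sum(r == der)] + 1L
  }
  structure(list(n = n, counts = stats::setNames(counts, seq_len(n - 1)),
                 unpolarizable = unpol, S = sum(counts) + unpol),
            class = "polarized_sfs")
}

#' @export
print.polarized_sfs <- function(x, ...) {
  cat(sprintf("<polarized_sfs> n = %d, S = %d (%d unpolarizable)\n",
              x$n, x$S, x$unpolarizable))
  print(x$counts)
  invisible(x)
}

#' @export
plot.polarized_sfs <- function(x, ...) {
  graphics::barplot(x$counts / max(1, sum(x$counts)),
                    xlab = "derived allele count",
                    ylab = "fraction of polarized sites", ...)
  invisible(x)
}

#' Fixed differences between two groups
#'
#' Counts sites monomorphic within each group for different alleles.
#'
#' @param m a `snp_matrix`.
#' @param group1,group2 species labels or accession id vectors.
#' @return integer count.
#' @export
fixed_differences <- function(m, group1, group2) {
  c1 <- group_columns(m, group1)
  c2 <- group_columns(m, group2)
  if (!length(c1) || !length(c2)) stop("both groups must be non-empty")
  s1 <- m$alleles[, c1, drop = FALSE]
  s2 <- m$alleles[, c2, drop = FALSE]
  mono1 <- rowSums(s1 == s1[, 1]) == length(c1)
  mono2 <- rowSums(s2 == s2[, 1]) == length(c2)
  sum(mono1 & mono2 & s1[, 1] != s2[, 1])
}

#' SNP distance matrix (proportion of differing columns)
#'
#' @param m a `snp_matrix`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
snp_distance <- function(m) {
  accs <- colnames(m$alleles)
  S <- nrow(m$alleles)
  if (S == 0)
    stop("no comparable polymorphic columns between accessions")
  d <- matrix(0, length(accs), length(accs), dimnames = list(accs, accs))
  for (i in seq_along(accs)) {
    for (j in seq_len(i - 1L)) {
      dij <- sum(m$alleles[, i] != m$alleles[, j]) / S
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree with bootstrap support
#'
#' Distance = proportion of matrix columns with differing alleles; NJ
#' agglomeration via [ape::nj()]; bootstrap resamples columns with
#' replacement and support is the fraction of replicates containing each
#' internal bipartition (counted with [ape::prop.clades()]).  When an
#' outgroup is given the returned tree is rooted on it.
#'
#' @param m a `snp_matrix` with at least 3 accessions.
#' @param replicates bootstrap replicates (0 = no support values).
#' @param seed RNG seed for the resampling.
#' @param outgroup optional accession id used for rooting.
#' @return object of class `nj_boot`: `tree` (a `phylo` whose node labels
#'   are percent support), `boot_trees`, `replicates`, `dist`.
#' @export
nj_tree_with_bootstrap <- function(m, replicates = 1000, seed = 1L,
                                   outgroup = NULL) {
  if (ncol(m$alleles) < 3) stop("need at least 3 accessions")
  d <- snp_distance(m)
  build <- function(mat) {
    tr <- ape::nj(mat)
    if (!is.null(outgroup)) tr <- ape::root(tr, outgroup,
                                            resolve.root = TRUE)
    tr
  }
  tree <- build(d)
  boots <- NULL
  if (replicates > 0) {
    S <- nrow(m$alleles)
    boots <- withr::with_seed(seed, lapply(seq_len(replicates), function(b) {
      mb <- m
      idx <- sample.int(S, S, replace = TRUE)
      mb$alleles <- m$alleles[idx, , drop = FALSE]
      build(snp_distance(mb))
    }))
    class(boots) <- "multiPhylo"
    support <- ape::prop.clades(tree, boots, rooted = FALSE)
    support[is.na(support)] <- 0L
    tree$node.label <- round(100 * support / replicates, 1)
  }
  structure(list(tree = tree, boot_trees = boots, replicates = replicates,
                 dist = d), class = "nj_boot")
}

#' @export
print.nj_boot <- function(x, ...) {
  cat(sprintf("<nj_boot> %d tips, %d bootstrap replicates\n",
              length(x$tree$tip.label), x$replicates))
  invisible(x)
}

#' @export
plot.nj_boot <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  if (!is.null(x$tree$node.label))
    ape::nodelabels(x$tree$node.label, frame = "none", adj = c(1.2, -0.3))
  invisible(x)
}

#' Bootstrap support for a given clade
#'
#' Fraction of bootstrap trees in which `tips` form a monophyletic group
#' (each tree rooted on `outgroup` before testing).
#'
#' @param x an `nj_boot`.
#' @param tips tip labels of the putative clade.
#' @param outgroup accession used to root each replicate.
#' @return proportion between 0 and 1.
#' @export
clade_support <- function(x, tips, outgroup) {
  if (is.null(x$boot_trees)) stop("tree was built without bootstrap")
  hits <- vapply(x$boot_trees, function(tr) {
    tr <- ape::root(tr, outgroup, resolve.root = TRUE)
    ape::is.monophyletic(tr, tips)
  }, logical(1))
  mean(hits)
}
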