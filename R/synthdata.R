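# Synthetic two-ingroup-species + outgroup dataset generator.
#
# The generator plants intra-species SNPs and indels (with site-frequency
# spectra controlled per species), substitution-only divergence between the
# two ingroup species and towards the outgroup, and emits two syntenic
# "virtual chromosome" genomes with order-preserving gene layout, so every
# planted variant carries known coordinates on both genomes.  Planted events
# are spaced, kept away from transcript ends, and indel junctions are made
# shift-invariant (non-repetitive context), so that error-free recovery is
# well-defined site by site.

.VARIANT_SPACING <- 24L   # min distance between planted events (bp)
.JUNCTION_MARGIN <- 12L   # read boundaries keep this distance from indel junctions
.FRAG_GAP <- 20L          # inner gap between mates; fragment = 2*read_length + gap
.INDEL_MAX <- 8L          # planted indel lengths are 1...INDEL_MAX bp
.SPACER_RANGE <- c(100L, 300L)

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_dataset()].  The
#' defaults are the study conditions the package's validation suite runs
#' under: a 12-accession panel for ingroup species A with an
#' expansion-shaped (singleton-rich) site-frequency spectrum, a
#' 10-accession panel for ingroup species B with a structure-shaped
#' (intermediate-frequency-rich) spectrum, one outgroup accession, and two
#' syntenic pseudomolecule genomes with unequal gene missingness.
#'
#' @param seed integer; fully determines every downstream draw.
#' @param n_genes number of ancestral genes (one transcript each).
#' @param gene_length_range bp interval for gene lengths.
#' @param n_accessions_A,n_accessions_B ingroup panel sizes (>= 2).
#' @param snp_rate_intra,indel_rate_intra per-bp probability that an
#'   interior site carries a planted intra-species SNP / indel.
#' @param divergence_AB per-bp substitution probability between the two
#'   ingroup lineages (substitution-only, so genome coordinate frames stay
#'   colinear).
#' @param divergence_outgroup per-bp substitution probability on the
#'   outgroup lineage; must exceed `divergence_AB`.
#' @param sfs_mode_A,sfs_mode_B one of "neutral", "expansion",
#'   "structured": the derived-allele-count sampler for each panel.
#' @param read_length bp.
#' @param fragment_depth guaranteed per-base read coverage floor: fragments
#'   are tiled quasi-uniformly to this coverage, with an
#'   expression-weighted Poisson component on top (see the methods
#'   vignette).
#' @param error_rate per-base substitution error probability in reads.
#' @param expression_dispersion sdlog of the log-normal per-gene expression
#'   weights.
#' @param missing_gene_fraction_per_genome probability that a gene is
#'   absent from each genome; scalar or length-2 vector `c(A=, B=)`.
#' @param theta_correlation correlation of per-gene mutation-rate
#'   multipliers between the two species (drives the ortholog theta-theta
#'   association).
#' @param expression_correlation correlation of per-gene expression
#'   weights between the two species.
#' @param minus_strand_fraction probability a gene lies on the minus strand
#'   of a genome.
#' @param n_chromosomes chromosomes per genome.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       gene_length_range = c(500L, 1500L),
                       n_accessions_A = 12L,
                       n_accessions_B = 10L,
                       snp_rate_intra = 0.005,
                       indel_rate_intra = 5e-4,
                       divergence_AB = 0.01,
                       divergence_outgroup = 0.03,
                       sfs_mode_A = "expansion",
                       sfs_mode_B = "structured",
                       read_length = 100L,
                       fragment_depth = 20,
                       error_rate = 0,
                       expression_dispersion = 2,
                       missing_gene_fraction_per_genome = c(A = 0.06, B = 0.25),
                       theta_correlation = 0.1,
                       expression_correlation = 0.9,
                       minus_strand_fraction = 0.25,
                       n_chromosomes = 7L) {
  sfs_modes <- c("neutral", "expansion", "structured")
  sfs_mode_A <- match.arg(sfs_mode_A, sfs_modes)
  sfs_mode_B <- match.arg(sfs_mode_B, sfs_modes)
  for (nm in c("snp_rate_intra", "indel_rate_intra", "divergence_AB",
               "divergence_outgroup", "error_rate", "theta_correlation",
               "expression_correlation", "minus_strand_fraction"))
    assert_prob(get(nm), nm)
  miss <- missing_gene_fraction_per_genome
  if (length(miss) == 1) miss <- c(A = unname(miss), B = unname(miss))
  if (length(miss) != 2) stop("missing_gene_fraction_per_genome must have length 1 or 2")
  names(miss) <- c("A", "B")
  assert_prob(miss, "missing_gene_fraction_per_genome")
  if (n_accessions_A < 2 || n_accessions_B < 2)
    stop("each ingroup panel needs at least 2 accessions")
  if (divergence_outgroup <= divergence_AB)
    stop("divergence_outgroup must exceed divergence_AB")
  if (n_genes < 1) stop("n_genes must be positive")
  margin <- 2L * read_length + .FRAG_GAP # one fragment length
  if (min(gene_length_range) < 2L * margin + 2L * .VARIANT_SPACING)
    stop("gene_length_range too short for read_length: genes need an ",
         "interior of at least ", 2L * .VARIANT_SPACING,
         " bp after end margins of one fragment length (2*read_length + ",
         .FRAG_GAP, ")")
  if (fragment_depth < 0) stop("fragment_depth must be >= 0")
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    n_accessions_A = as.integer(n_accessions_A),
    n_accessions_B = as.integer(n_accessions_B),
    snp_rate_intra = snp_rate_intra, indel_rate_intra = indel_rate_intra,
    divergence_AB = divergence_AB, divergence_outgroup = divergence_outgroup,
    sfs_mode_A = sfs_mode_A, sfs_mode_B = sfs_mode_B,
    read_length = as.integer(read_length), fragment_depth = fragment_depth,
    error_rate = error_rate, expression_dispersion = expression_dispersion,
    missing_gene_fraction_per_genome = miss,
    theta_correlation = theta_correlation,
    expression_correlation = expression_correlation,
    minus_strand_fraction = minus_strand_fraction,
    n_chromosomes = as.integer(n_chromosomes)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes (%d-%d bp), panels A=%d (%s) B=%d (%s) + outgroup\n",
              x$n_genes, x$gene_length_range[1], x$gene_length_range[2],
              x$n_accessions_A, x$sfs_mode_A, x$n_accessions_B, x$sfs_mode_B))
  cat(sprintf("  rates: snp %.2g, indel %.2g, div AB %.2g, div out %.2g\n",
              x$snp_rate_intra, x$indel_rate_intra, x$divergence_AB,
              x$divergence_outgroup))
  cat(sprintf("  reads: %d bp, coverage floor %g, error %.2g; seed %d\n",
              x$read_length, x$fragment_depth, x$error_rate, x$seed))
  invisible(x)
}

#' Sample derived-allele counts from a parameterized SFS
#'
#' Class probabilities over derived count i = 1..n-1: "neutral" uses
#' p(i) proportional to 1/i (the standard neutral expectation),
#' "expansion" 1/i^2 (singleton-rich, Tajima's D < 0), "structured"
#' i*(n-i) (intermediate-rich, Tajima's D > 0).
#'
#' @param n sample size.
#' @param mode SFS mode.
#' @param size number of draws.
#' @return integer vector of derived counts in 1..n-1.
#' @export
sfs_sample <- function(n, mode = c("neutral", "expansion", "structured"),
                       size = 1) {
  mode <- match.arg(mode)
  i <- seq_len(n - 1)
  w <- switch(mode, neutral = 1 / i, expansion = 1 / i^2,
              structured = i * (n - i))
  sample(i, size, replace = TRUE, prob = w)
}

# correlated standard-normal pair of length n
corr_normals <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  list(z1, z2)
}

#' Generate a synthetic two-species + outgroup dataset
#'
#' Produces the full study bundle: ancestral genes; per-accession transcript
#' sets for both ingroup panels and the outgroup (substitution-only
#' inter-lineage divergence, SFS-controlled intra-species SNPs and indels);
#' two syntenic genomes built as order-preserving gene concatenations with
#' random spacers, per-genome gene missingness and strand; a truth table
#' with every planted variant's alleles, carriers and coordinates on both
#' genomes; and per-gene expression weights.
#'
#' The reference accession of each species (A01 / B01) carries the
#' ancestral allele at every indel site, so its transcript coordinates
#' coincide with the ancestral gene frame used by the truth table.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, genomes, transcript sets, the
#'   truth table and a JSON copy of the configuration are written there.
#' @return object of class `sim_bundle`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config, dir))
}

simulate_dataset_impl <- function(config, dir) {
  G <- config$n_genes
  nA <- config$n_accessions_A
  nB <- config$n_accessions_B
  acc_A <- sprintf("A%02d", seq_len(nA))
  acc_B <- sprintf("B%02d", seq_len(nB))
  accs <- c(acc_A, acc_B, "OUT")
  margin <- 2L * config$read_length + .FRAG_GAP
  species <- stats::setNames(c(rep("ingroupA", nA), rep("ingroupB", nB),
                               "outgroup"), accs)
  genes <- sprintf("g%04d", seq_len(G))
  L <- sample(config$gene_length_range[1]:config$gene_length_range[2], G,
              replace = TRUE)

  zt <- corr_normals(G, config$theta_correlation)
  mA <- exp(0.8 * zt[[1]] - 0.32)
  mB <- exp(0.8 * zt[[2]] - 0.32)
  ze <- corr_normals(G, config$expression_correlation)
  s <- config$expression_dispersion
  wA <- stats::setNames(exp(s * ze[[1]] - s^2 / 2), genes)
  wB <- stats::setNames(exp(s * ze[[2]] - s^2 / 2), genes)

  bases <- c("A", "C", "G", "T")
  anc <- lapply(L, function(l) sample(bases, l, replace = TRUE))
  names(anc) <- genes

  truth <- list()
  # per-accession edits: snps[[acc]][[gene]] = data.frame(pos, base);
  # indels[[acc]][[gene]] = data.frame(pos, class, len, allele)
  snp_edit <- lapply(accs, function(a) list())
  names(snp_edit) <- accs
  ind_edit <- snp_edit
  ab_sites <- vector("list", G)
  out_sites <- vector("list", G)

  other_base <- function(b) sample(setdiff(bases, b), 1)

  for (g in seq_len(G)) {
    chars <- anc[[g]]
    l <- L[g]
    interior <- (margin + 1L):(l - margin)
    nI <- length(interior)
    n_ev <- c(ab   = stats::rbinom(1, nI, config$divergence_AB),
              out  = stats::rbinom(1, nI, min(1, config$divergence_outgroup)),
              snpA = stats::rbinom(1, nI, min(1, config$snp_rate_intra * mA[g])),
              snpB = stats::rbinom(1, nI, min(1, config$snp_rate_intra * mB[g])),
              indA = stats::rbinom(1, nI, min(1, config$indel_rate_intra * mA[g])),
              indB = stats::rbinom(1, nI, min(1, config$indel_rate_intra * mB[g])))
    tot <- sum(n_ev)
    if (tot == 0) next
    pos <- sort(sample(interior, min(tot, nI)))
    keep <- logical(length(pos))
    last <- -Inf
    for (j in seq_along(pos)) {
      if (pos[j] - last >= .VARIANT_SPACING) {
        keep[j] <- TRUE
        last <- pos[j]
      }
    }
    pos <- pos[keep]
    cats <- sample(rep(names(n_ev), n_ev))[seq_along(pos)]

    for (j in seq_along(pos)) {
      p <- pos[j]
      cat_j <- cats[j]
      if (cat_j == "out") {
        out_sites[[g]] <- rbind(out_sites[[g]],
                                data.frame(pos = p, base = other_base(chars[p])))
        next
      }
      if (cat_j == "ab") {
        alt <- other_base(chars[p])
        ab_sites[[g]] <- rbind(ab_sites[[g]], data.frame(pos = p, base = alt))
        truth[[length(truth) + 1]] <- data.frame(
          gene = genes[g], pos = p, class = "SNP", origin = "divergence_AB",
          species = "AB", ref = chars[p], alt = alt, ancestral = chars[p],
          carriers = paste(acc_B, collapse = ","),
          derived_count = nB, stringsAsFactors = FALSE)
        next
      }
      sp <- if (cat_j %in% c("snpA", "indA")) "A" else "B"
      n_sp <- if (sp == "A") nA else nB
      mode <- if (sp == "A") config$sfs_mode_A else config$sfs_mode_B
      panel <- if (sp == "A") acc_A else acc_B
      i <- sfs_sample(n_sp, mode, 1)
      if (cat_j %in% c("snpA", "snpB")) {
        alt <- other_base(chars[p])
        carriers <- panel[sample.int(n_sp, i)]
        for (a in carriers) {
          snp_edit[[a]][[genes[g]]] <- rbind(
            snp_edit[[a]][[genes[g]]], data.frame(pos = p, base = alt))
        }
        truth[[length(truth) + 1]] <- data.frame(
          gene = genes[g], pos = p, class = "SNP",
          origin = paste0("intra_", sp), species = sp, ref = chars[p],
          alt = alt, ancestral = chars[p],
          carriers = paste(sort(carriers), collapse = ","),
          derived_count = i, stringsAsFactors = FALSE)
      } else {
        len <- sample.int(.INDEL_MAX, 1)
        type <- sample(c("insertion", "deletion"), 1)
        if (type == "deletion") {
          # reject junctions that could shift left or right
          if (chars[p] == chars[p + len] || chars[p + 1] == chars[p + len + 1])
            next
          ref_al <- paste(chars[(p + 1):(p + len)], collapse = "")
          alt_al <- "-"
        } else {
          ok <- FALSE
          for (try in 1:25) {
            ins <- sample(bases, len, replace = TRUE)
            if (ins[len] != chars[p] && ins[1] != chars[p + 1]) {
              ok <- TRUE
              break
            }
          }
          if (!ok) next
          ref_al <- "-"
          alt_al <- paste(ins, collapse = "")
        }
        # reference accessions keep the ancestral state at indel sites so
        # the reference coordinate frame equals the ancestral frame
        i <- min(i, n_sp - 1L)
        carriers <- panel[1L + sample.int(n_sp - 1L, i)]
        for (a in carriers) {
          ind_edit[[a]][[genes[g]]] <- rbind(
            ind_edit[[a]][[genes[g]]],
            data.frame(pos = p, class = type, len = len,
                       allele = if (type == "insertion") alt_al else ref_al,
                       stringsAsFactors = FALSE))
        }
        truth[[length(truth) + 1]] <- data.frame(
          gene = genes[g], pos = p, class = type,
          origin = paste0("intra_", sp), species = sp, ref = ref_al,
          alt = alt_al, ancestral = ref_al,
          carriers = paste(sort(carriers), collapse = ","),
          derived_count = i, stringsAsFactors = FALSE)
      }
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene = character(0), pos = integer(0), class = character(0),
               origin = character(0), species = character(0),
               ref = character(0), alt = character(0),
               ancestral = character(0), carriers = character(0),
               derived_count = integer(0))

  # species base sequences
  apply_subs <- function(chars, sub) {
    if (!is.null(sub)) chars[sub$pos] <- sub$base
    chars
  }
  base_A <- anc
  base_B <- lapply(seq_len(G), function(g) apply_subs(anc[[g]], ab_sites[[g]]))
  base_O <- lapply(seq_len(G), function(g) apply_subs(anc[[g]], out_sites[[g]]))
  names(base_B) <- names(base_O) <- genes

  # accession transcripts + junction-avoidance zones
  build_accession <- function(base, snps, indels) {
    seqs <- character(G)
    names(seqs) <- genes
    zones <- list()
    for (g in seq_len(G)) {
      chars <- base[[g]]
      sn <- snps[[genes[g]]]
      if (!is.null(sn)) chars[sn$pos] <- sn$base
      id <- indels[[genes[g]]]
      if (!is.null(id) && nrow(id)) {
        id <- id[order(id$pos), , drop = FALSE]
        off <- 0L
        zl <- list()
        for (r in seq_len(nrow(id))) {
          la <- id$pos[r] + off
          if (id$class[r] == "deletion") {
            zl[[r]] <- c(la - .JUNCTION_MARGIN, la + .JUNCTION_MARGIN)
            off <- off - id$len[r]
          } else {
            zl[[r]] <- c(la - .JUNCTION_MARGIN, la + id$len[r] + .JUNCTION_MARGIN)
            off <- off + id$len[r]
          }
        }
        zones[[genes[g]]] <- do.call(rbind, zl)
        for (r in rev(seq_len(nrow(id)))) {
          p <- id$pos[r]
          if (id$class[r] == "deletion") {
            chars <- chars[-((p + 1L):(p + id$len[r]))]
          } else {
            chars <- append(chars, strsplit(id$allele[r], "")[[1]], after = p)
          }
        }
      }
      seqs[g] <- paste(chars, collapse = "")
    }
    list(seq = seqs, zones = zones)
  }

  transcripts <- list()
  zones <- list()
  for (a in accs) {
    base <- switch(species[[a]], ingroupA = base_A, ingroupB = base_B,
                   outgroup = base_O)
    built <- build_accession(base, snp_edit[[a]], ind_edit[[a]])
    transcripts[[a]] <- transcript_set(a, built$seq,
                                       note = "synthetic unigene set")
    zones[[a]] <- built$zones
  }

  # genomes: order-preserving concatenations with spacers
  nchrom <- min(config$n_chromosomes, G)
  chrom_idx <- sort(rep_len(seq_len(nchrom), G))
  build_genome <- function(label, base, miss_frac) {
    present <- stats::runif(G) >= miss_frac
    strand <- ifelse(stats::runif(G) < config$minus_strand_fraction, "-", "+")
    chrom_names <- sprintf("chr%d%s", seq_len(nchrom), label)
    seqs <- stats::setNames(character(nchrom), chrom_names)
    tab <- list()
    for (ci in seq_len(nchrom)) {
      parts <- character(0)
      at <- 0L
      for (g in which(chrom_idx == ci)) {
        if (!present[g]) next
        spacer <- random_dna(sample(.SPACER_RANGE[1]:.SPACER_RANGE[2], 1))
        gseq <- paste(base[[g]], collapse = "")
        if (strand[g] == "-") gseq <- revcomp(gseq)
        parts <- c(parts, spacer, gseq)
        start <- at + nchar(spacer) + 1L
        end <- start + nchar(gseq) - 1L
        at <- end
        tab[[length(tab) + 1]] <- data.frame(
          genome = label, gene = genes[g], chrom = chrom_names[ci],
          start = start, end = end, strand = strand[g],
          stringsAsFactors = FALSE)
      }
      parts <- c(parts, random_dna(sample(.SPACER_RANGE[1]:.SPACER_RANGE[2], 1)))
      seqs[ci] <- paste(parts, collapse = "")
    }
    list(seq = seqs, genes = do.call(rbind, tab), present = present)
  }
  genome_A <- build_genome("A", base_A,
                           config$missing_gene_fraction_per_genome[["A"]])
  genome_B <- build_genome("B", base_B,
                           config$missing_gene_fraction_per_genome[["B"]])

  # truth coordinates on each genome
  lift_truth <- function(gtab, pos, gene) {
    i <- match(gene, gtab$gene)
    chrom <- gtab$chrom[i]
    cp <- ifelse(gtab$strand[i] == "+", gtab$start[i] + pos - 1L,
                 gtab$end[i] - pos + 1L)
    list(chrom = chrom, pos = cp)
  }
  if (nrow(truth)) {
    la <- lift_truth(genome_A$genes, truth$pos, truth$gene)
    lb <- lift_truth(genome_B$genes, truth$pos, truth$gene)
    truth$chromA <- la$chrom
    truth$posA <- la$pos
    truth$chromB <- lb$chrom
    truth$posB <- lb$pos
  } else {
    truth$chromA <- character(0)
    truth$posA <- integer(0)
    truth$chromB <- character(0)
    truth$posB <- integer(0)
  }

  bundle <- structure(list(
    config = config,
    genes = data.frame(gene = genes, length = L, chrom = chrom_idx,
                       weight_A = unname(wA), weight_B = unname(wB),
                       rate_mult_A = mA, rate_mult_B = mB,
                       stringsAsFactors = FALSE),
    ancestral = stats::setNames(vapply(anc, paste, "", collapse = ""), genes),
    transcripts = transcripts,
    species = species,
    genomes = list(A = genome_A[c("seq", "genes")],
                   B = genome_B[c("seq", "genes")]),
    truth = truth,
    weights = list(A = wA, B = wB),
    zones = zones), class = "sim_bundle")

  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(paste0("<sim_bundle> %d genes, %d + %d + 1 accessions, ",
                     "%d planted variant records\n"),
              x$config$n_genes, x$config$n_accessions_A,
              x$config$n_accessions_B, nrow(x$truth)))
  invisible(x)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "transcripts"), showWarnings = FALSE)
  write_fasta(bundle$genomes$A$seq, file.path(dir, "genomeA.fasta"))
  write_fasta(bundle$genomes$B$seq, file.path(dir, "genomeB.fasta"))
  for (a in names(bundle$transcripts))
    write_fasta(bundle$transcripts[[a]],
                file.path(dir, "transcripts", paste0(a, ".fasta")))
  write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  write_tsv(bundle$genomes$A$genes, file.path(dir, "genesA.tsv"))
  write_tsv(bundle$genomes$B$genes, file.path(dir, "genesB.tsv"))
  cfg <- bundle$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Simulate paired reads from a transcript set
#'
#' Fragments are drawn per transcript in two layers: a quasi-uniform tiling
#' that guarantees an interior per-base coverage of about `depth`, plus a
#' Poisson number of uniformly placed fragments with mean proportional to
#' `2 * depth * weight`, carrying the expression signal.  Mates face
#' inward; mate 2 is the reverse complement of the fragment end.  Each read
#' name records its transcript, fragment index and true start offset.
#' Fragment boundaries are nudged away (+/- `r .JUNCTION_MARGIN` bp) from
#' supplied indel-junction zones so that every read overlapping an indel
#' spans it informatively.
#'
#' @param transcripts `transcript_set` or named character vector.
#' @param depth target uniform coverage floor (reads per base).
#' @param read_length bp; transcripts shorter than one fragment
#'   (`2*read_length + 20`) are skipped with a warning.
#' @param error_rate per-base substitution error probability.
#' @param seed RNG seed.
#' @param weights named per-transcript expression weights (default 1).
#' @param zones named list of two-column matrices of junction intervals,
#'   in the transcript's own coordinates.
#' @return list of class `read_pairs` with named character vectors `r1`
#'   and `r2`; names are `<transcript>:<fragment>:<start>`.
#' @export
simulate_reads <- function(transcripts, depth, read_length, error_rate = 0,
                           seed = 1L, weights = NULL, zones = NULL) {
  seqs <- as_seq_vector(transcripts)
  if (length(seqs) == 0) stop("no transcripts supplied")
  withr::with_seed(seed, {
    rl <- as.integer(read_length)
    flen <- 2L * rl + .FRAG_GAP
    r1 <- list()
    r2 <- list()
    skipped <- character(0)
    for (id in names(seqs)) {
      tl <- nchar(seqs[[id]])
      if (tl < flen) {
        skipped <- c(skipped, id)
        next
      }
      w <- if (is.null(weights)) 1 else unname(weights[[id]] %||% 1)
      span <- tl - flen + 1L
      # floor fragments scale with the full transcript length so the
      # coverage floor contributes a length-independent FPKM offset
      n_u <- if (depth <= 0) 0L else
        as.integer(ceiling(depth * tl / (2 * rl))) + 1L
      starts <- if (n_u > 0) as.integer(round(seq(1L, span, length.out = n_u)))
                else integer(0)
      n_w <- stats::rpois(1, 2 * depth * w * tl / (2 * rl))
      if (n_w > 0) starts <- c(starts, sample.int(span, n_w, replace = TRUE))
      if (!length(starts)) next
      zn <- if (!is.null(zones)) zones[[id]] else NULL
      if (!is.null(zn) && nrow(zn)) starts <- avoid_zones(starts, zn, rl, flen, span)
      s1 <- substring(seqs[[id]], starts, starts + rl - 1L)
      s2 <- revcomp(substring(seqs[[id]], starts + flen - rl, starts + flen - 1L))
      nm <- paste0(id, ":", seq_along(starts), ":", starts)
      names(s1) <- names(s2) <- nm
      r1[[id]] <- s1
      r2[[id]] <- s2
    }
    if (length(skipped))
      warning("transcript(s) shorter than one fragment skipped: ",
              paste(skipped, collapse = ", "))
    r1 <- if (length(r1)) unlist(r1, use.names = TRUE) else
      stats::setNames(character(0), character(0))
    r2 <- if (length(r2)) unlist(r2, use.names = TRUE) else
      stats::setNames(character(0), character(0))
    names(r1) <- sub("^[^.]*\\.", "", names(r1)) # drop unlist()'s list prefix
    names(r2) <- sub("^[^.]*\\.", "", names(r2))
    if (error_rate > 0) {
      r1[] <- cpp_add_errors(r1, error_rate)
      r2[] <- cpp_add_errors(r2, error_rate)
    }
    structure(list(r1 = r1, r2 = r2), class = "read_pairs")
  })
}

# shift fragment starts so no read boundary falls inside a junction zone
avoid_zones <- function(starts, zn, rl, flen, span) {
  in_zone <- function(x) {
    hit <- rep(FALSE, length(x))
    for (r in seq_len(nrow(zn)))
      hit <- hit | (x >= zn[r, 1] & x <= zn[r, 2])
    hit
  }
  bad_start <- function(s) {
    b <- c(s, s + rl - 1L, s + flen - rl, s + flen - 1L)
    any(in_zone(b))
  }
  deltas <- c(0L, as.integer(rbind(1:40, -(1:40))))
  vapply(starts, function(s) {
    for (d in deltas) {
      cand <- s + d
      if (cand >= 1L && cand <= span && !bad_start(cand)) return(cand)
    }
    s
  }, integer(1))
}

#' Simulate a high-confidence SNP panel directly from a parameterized SFS
#'
#' Bypasses sequencing: draws segregating sites for one ingroup panel of
#' size `n` (plus an outgroup accession fixed for the ancestral allele) and
#' returns them as a `snp_matrix`.  Used for calibration-style checks of
#' the diversity estimators where the quantity of interest is the
#' frequency-spectrum shape, not the read-level pipeline.
#'
#' @param n panel size.
#' @param sfs_mode see [sfs_sample()].
#' @param theta population mutation parameter per locus; the number of
#'   segregating sites is Poisson with mean `theta * a1` (so the Watterson
#'   estimator is unbiased for it).  Ignored when `n_sites` is given.
#' @param n_sites fixed number of segregating sites.
#' @param seed RNG seed.
#' @return a `snp_matrix` with accessions `acc01..accNN` plus `OUT`.
#' @export
simulate_panel <- function(n, sfs_mode = "neutral", theta = NULL,
                           n_sites = NULL, seed = 1L) {
  if (is.null(n_sites) && is.null(theta))
    stop("supply either theta or n_sites")
  withr::with_seed(seed, {
    a1 <- sum(1 / seq_len(n - 1))
    S <- if (!is.null(n_sites)) as.integer(n_sites) else
      stats::rpois(1, theta * a1)
    bases <- c("A", "C", "G", "T")
    accs <- c(sprintf("acc%02d", seq_len(n)), "OUT")
    if (S == 0) {
      alleles <- matrix(character(0), 0, n + 1, dimnames = list(NULL, accs))
      sites <- data.frame(transcript = character(0), pos = integer(0),
                          ref = character(0))
    } else {
      anc <- sample(bases, S, replace = TRUE)
      der <- vapply(anc, function(b) sample(setdiff(bases, b), 1), "")
      cnt <- sfs_sample(n, sfs_mode, S)
      alleles <- matrix(rep(anc, n + 1), S, n + 1,
                        dimnames = list(NULL, accs))
      for (s in seq_len(S))
        alleles[s, sample.int(n, cnt[s])] <- der[s]
      sites <- data.frame(transcript = "locus1", pos = seq_len(S), ref = anc,
                          stringsAsFactors = FALSE)
    }
    new_snp_matrix(sites, alleles,
                   species = stats::setNames(
                     c(rep("ingroupA", n), "outgroup"), accs),
                   L_total = S,
                   L_by_transcript = data.frame(transcript = "locus1", L = S),
                   reference_accession = NA_character_,
                   n_multiallelic = 0L)
  })
}
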