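# Fixtures shared across test files, built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small full bundle used by several module tests
small_bundle <- function() {
  fixture("small_bundle", function() {
    simulate_dataset(sim_config(seed = 11, n_genes = 40, n_accessions_A = 5,
                                n_accessions_B = 4, fragment_depth = 15,
                                indel_rate_intra = 2e-3))
  })
}

# align one accession of a bundle against a reference accession's set
bundle_alignment <- function(bundle, read_acc, ref_acc = "A01", depth = NULL,
                             error_rate = NULL, seed_offset = 500L) {
  cfg <- bundle$config
  sp <- bundle$species[[read_acc]]
  w <- switch(sp, ingroupA = bundle$weights$A, ingroupB = bundle$weights$B,
              bundle$weights$A)
  reads <- simulate_reads(bundle$transcripts[[read_acc]],
                          depth %||% cfg$fragment_depth, cfg$read_length,
                          error_rate %||% cfg$error_rate,
                          seed = cfg$seed + seed_offset +
                            match(read_acc, names(bundle$transcripts)),
                          weights = w, zones = bundle$zones[[read_acc]])
  align_reads(reads, bundle$transcripts[[ref_acc]])
}

bundle_calls <- function(bundle, read_acc, ref_acc = "A01", ...) {
  aln <- bundle_alignment(bundle, read_acc, ref_acc, ...)
  pile <- pileup_alignments(aln, bundle$transcripts[[ref_acc]])
  call_variants(pile, read_accession = read_acc,
                reference_accession = ref_acc)
}

# a crafted single-block mapping record for anchoring unit tests
fake_mapping <- function(transcript, qlen, chrom, tstart, strand = "+",
                         blocks = NULL, genome = "A") {
  if (is.null(blocks)) {
    blocks <- matrix(c(1L, qlen, tstart, tstart + qlen - 1L), 1, 4,
                     dimnames = list(NULL, c("qstart", "qend", "tstart",
                                             "tend")))
  }
  out <- data.frame(transcript = transcript, qlen = qlen, genome = genome,
                    chrom = chrom, start = min(blocks[, "tstart"]),
                    end = max(blocks[, "tend"]), strand = strand,
                    identity = 1, coverage = 1, score = qlen,
                    stringsAsFactors = FALSE)
  out$blocks <- list(blocks)
  out
}

# snp_matrix built directly from an allele matrix
matrix_from_alleles <- function(alleles, species, ref = NA_character_) {
  transpop:::new_snp_matrix(
    sites = data.frame(transcript = rep("locus1", nrow(alleles)),
                       pos = seq_len(nrow(alleles)),
                       ref = alleles[, 1], stringsAsFactors = FALSE),
    alleles = alleles, species = species, L_total = nrow(alleles),
    L_by_transcript = data.frame(transcript = "locus1", L = nrow(alleles)),
    reference_accession = ref, n_multiallelic = 0L)
}

random_dna_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
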