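# End-to-end orchestration of the synthetic-mode pipeline as idempotent,
# file-based stages: simulate | align | call | anchor | popgen | ortho |
# markers.  Every stage reads its inputs from the run directory and writes
# its outputs there, so stages can be re-run individually; a manifest with
# checksums and all thresholds actually used is written at the end.

stage_file <- function(outdir, ...) file.path(outdir, ...)

require_stage_file <- function(path, stage) {
  if (!file.exists(path))
    stop("missing input ", path, "; run stage '", stage, "' first",
         call. = FALSE)
  path
}

plog <- function(outdir, ...) {
  line <- paste0(...)
  cat(line, "\n", file = stage_file(outdir, "pipeline.log"), append = TRUE)
  message(line)
}

read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$missing_gene_fraction_per_genome <-
    unlist(x$missing_gene_fraction_per_genome)
  x$gene_length_range <- unlist(x$gene_length_range)
  do.call(sim_config, x)
}

load_transcripts <- function(outdir, acc) {
  f <- require_stage_file(
    stage_file(outdir, "transcripts", paste0(acc, ".fasta")), "simulate")
  transcript_set(acc, read_fasta(f))
}

panel_accessions <- function(config) {
  list(A = sprintf("A%02d", seq_len(config$n_accessions_A)),
       B = sprintf("B%02d", seq_len(config$n_accessions_B)),
       OUT = "OUT")
}

#' Run the synthetic-mode pipeline
#'
#' Chains the stages on one run directory: `simulate` (bundle + reads),
#' `align` (every accession's reads vs the reference transcript set),
#' `call` (pairwise calls, artifact filtering, non-redundant
#' consolidation, per-accession consensus), `anchor` (transcript mapping,
#' variant lifting, per-chromosome tallies, two-genome integration),
#' `popgen` (high-confidence SNP matrix, diversity summaries, polarized
#' SFS, fixed differences, NJ tree with bootstrap), `ortho` (RBH
#' orthologs, FPKM, theta-theta and expression comparisons) and `markers`
#' (anchored indel markers with primers).  Each stage is idempotent given
#' identical inputs and seed; a rerun with the same seed writes
#' byte-identical tables.
#'
#' @param config a [sim_config()]; when the `simulate` stage is skipped it
#'   is reloaded from the run directory's `config.json`.
#' @param outdir run directory.
#' @param stages character vector of stages, or "all".
#' @param reference_accession reference transcript set for calling
#'   (default "A01").
#' @param reference_accession_B the second species' own reference set,
#'   used by the ortho stage (default "B01").
#' @param min_depth,min_fraction calling thresholds (strict >).
#' @param min_identity,min_coverage transcript-to-genome mapping filters.
#' @param rbh_coverage strict RBH coverage threshold.
#' @param bootstrap_replicates NJ bootstrap replicates.
#' @param bin_size density bin width (bp).
#' @param k seed length for alignment and mapping.
#' @return (invisibly) the path of the manifest file.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         stages = "all",
                         reference_accession = "A01",
                         reference_accession_B = "B01",
                         min_depth = 10, min_fraction = 0.95,
                         min_identity = 0.9, min_coverage = 0.5,
                         rbh_coverage = 0.80,
                         bootstrap_replicates = 200,
                         bin_size = 1000, k = 21) {
  all_stages <- c("simulate", "align", "call", "anchor", "popgen", "ortho",
                  "markers")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(stage_file(outdir, "pipeline.log")))
    file.remove(stage_file(outdir, "pipeline.log"))
  opts <- list(reference_accession = reference_accession,
               reference_accession_B = reference_accession_B,
               min_depth = min_depth, min_fraction = min_fraction,
               min_identity = min_identity, min_coverage = min_coverage,
               rbh_coverage = rbh_coverage,
               bootstrap_replicates = bootstrap_replicates,
               bin_size = bin_size, k = k)
  if (!"simulate" %in% stages) {
    cfgf <- require_stage_file(stage_file(outdir, "config.json"), "simulate")
    config <- read_config_json(cfgf)
  }
  for (st in all_stages[all_stages %in% stages]) {
    plog(outdir, "== stage ", st, " ==")
    switch(st,
           simulate = stage_simulate(config, outdir),
           align = stage_align(config, outdir, opts),
           call = stage_call(config, outdir, opts),
           anchor = stage_anchor(config, outdir, opts),
           popgen = stage_popgen(config, outdir, opts),
           ortho = stage_ortho(config, outdir, opts),
           markers = stage_markers(config, outdir, opts))
  }
  write_manifest(outdir, opts, config)
}

stage_simulate <- function(config, outdir) {
  bundle <- simulate_dataset(config, dir = outdir)
  dir.create(stage_file(outdir, "reads"), showWarnings = FALSE)
  accs <- names(bundle$transcripts)
  for (i in seq_along(accs)) {
    a <- accs[i]
    w <- switch(bundle$species[[a]], ingroupA = bundle$weights$A,
                ingroupB = bundle$weights$B, bundle$weights$A)
    reads <- simulate_reads(bundle$transcripts[[a]], config$fragment_depth,
                            config$read_length, config$error_rate,
                            seed = config$seed + 1000L + i,
                            weights = w, zones = bundle$zones[[a]])
    write_fastq(reads, stage_file(outdir, "reads", a))
  }
  plog(outdir, "simulated ", config$n_genes, " genes, ",
       length(accs), " accessions, ", nrow(bundle$truth),
       " planted variant records")
}

load_reads <- function(outdir, acc) {
  f1 <- require_stage_file(stage_file(outdir, "reads", paste0(acc, "_1.fastq")),
                           "simulate")
  f2 <- require_stage_file(stage_file(outdir, "reads", paste0(acc, "_2.fastq")),
                           "simulate")
  r1 <- read_fastq(f1)
  r2 <- read_fastq(f2)
  names(r1) <- sub("/1$", "", names(r1))
  names(r2) <- sub("/2$", "", names(r2))
  structure(list(r1 = r1, r2 = r2), class = "read_pairs")
}

align_one <- function(outdir, acc, ref_set, opts) {
  reads <- load_reads(outdir, acc)
  aln <- align_reads(reads, ref_set, k = opts$k)
  dir.create(stage_file(outdir, "sam"), showWarnings = FALSE)
  samf <- stage_file(outdir, "sam",
                     paste0(acc, "_vs_", ref_set$accession, ".sam"))
  write_sam(aln, ref_set, samf)
  samf
}

stage_align <- function(config, outdir, opts) {
  ref_set <- load_transcripts(outdir, opts$reference_accession)
  panels <- panel_accessions(config)
  for (acc in c(panels$A, panels$B, panels$OUT)) {
    samf <- align_one(outdir, acc, ref_set, opts)
    plog(outdir, "aligned ", acc, " vs ", opts$reference_accession,
         " (k = ", opts$k, ") -> ", basename(samf))
  }
}

stage_call <- function(config, outdir, opts) {
  ref <- opts$reference_accession
  ref_set <- load_transcripts(outdir, ref)
  panels <- panel_accessions(config)
  dir.create(stage_file(outdir, "calls"), showWarnings = FALSE)
  calls <- list()
  for (acc in c(panels$A, panels$B, panels$OUT)) {
    samf <- require_stage_file(
      stage_file(outdir, "sam", paste0(acc, "_vs_", ref, ".sam")), "align")
    pile <- read_sam_pileup(samf, ref_set)
    cons <- accession_consensus(pile, opts$min_depth, opts$min_fraction)
    write_tsv(data.frame(transcript = names(cons),
                         consensus = vapply(cons, paste, "", collapse = ""),
                         stringsAsFactors = FALSE),
              stage_file(outdir, "calls", paste0("consensus_", acc, ".tsv")))
    if (acc %in% panels$A) {
      calls[[acc]] <- call_variants(pile, read_accession = acc,
                                    reference_accession = ref,
                                    min_depth = opts$min_depth,
                                    min_fraction = opts$min_fraction)
    }
  }
  self <- calls[[ref]]
  plog(outdir, "self-comparison calls (", ref, " vs itself): ", nrow(self))
  filtered <- lapply(calls[setdiff(names(calls), ref)], function(x) {
    y <- filter_artifacts(x, self)
    plog(outdir, "artifact filter removed ", attr(y, "n_removed"),
         " call(s) from ", x$read_accession[1] %||% "?")
    y
  })
  for (acc in names(filtered))
    write_tsv(as.data.frame(filtered[[acc]]),
              stage_file(outdir, "calls", paste0("pairwise_", acc, ".tsv")))
  nr <- consolidate_nonredundant(filtered)
  write_tsv(as.data.frame(nr), stage_file(outdir, "calls", "nr.tsv"))
  write_tsv(variant_count_table(filtered),
            stage_file(outdir, "calls", "pairwise_counts.tsv"))
  plog(outdir, "non-redundant set: ", nrow(nr), " variants (thresholds: ",
       "depth > ", opts$min_depth, ", fraction > ", opts$min_fraction, ")")
}

serialize_blocks <- function(blocks) {
  vapply(blocks, function(b)
    paste(apply(b, 1, paste, collapse = ":"), collapse = ";"), "")
}

deserialize_blocks <- function(s) {
  lapply(strsplit(s, ";", fixed = TRUE), function(parts) {
    m <- do.call(rbind, lapply(strsplit(parts, ":", fixed = TRUE),
                               as.integer))
    colnames(m) <- c("qstart", "qend", "tstart", "tend")
    m
  })
}

read_mappings <- function(path) {
  df <- read_tsv(path)
  df$blocks <- deserialize_blocks(df$blocks_enc)
  df$blocks_enc <- NULL
  df
}

load_nr <- function(outdir, ref) {
  f <- require_stage_file(stage_file(outdir, "calls", "nr.tsv"), "call")
  nr <- read_tsv(f)
  nr$ref <- as.character(nr$ref)
  nr$alt <- as.character(nr$alt)
  attr(nr, "reference_accession") <- ref
  class(nr) <- c("nr_set", "data.frame")
  nr
}

stage_anchor <- function(config, outdir, opts) {
  ref <- opts$reference_accession
  ref_set <- load_transcripts(outdir, ref)
  nr <- load_nr(outdir, ref)
  dir.create(stage_file(outdir, "anchor"), showWarnings = FALSE)
  anchors <- list()
  for (g in c("A", "B")) {
    gf <- require_stage_file(
      stage_file(outdir, paste0("genome", g, ".fasta")), "simulate")
    genome <- read_fasta(gf)
    mp <- map_transcripts(ref_set, genome, genome_label = g,
                          min_identity = opts$min_identity,
                          min_coverage = opts$min_coverage, k = opts$k)
    mp_out <- mp
    mp_out$blocks_enc <- serialize_blocks(mp_out$blocks)
    mp_out$blocks <- NULL
    write_tsv(mp_out, stage_file(outdir, "anchor",
                                 paste0("mappings_", g, ".tsv")))
    anc <- lift_variants(nr, mp)
    anchors[[g]] <- anc
    write_tsv(anc, stage_file(outdir, "anchor", paste0("anchored_", g, ".tsv")))
    write_bed(anc, stage_file(outdir, "anchor", paste0("anchored_", g, ".bed")),
              chrom_lengths = nchar(genome))
    tal <- tally_per_chromosome(anc, bin_size = opts$bin_size)
    write_tsv(tal$counts,
              stage_file(outdir, "anchor", paste0("chrom_counts_", g, ".tsv")))
    write_tsv(tal$density,
              stage_file(outdir, "anchor", paste0("density_", g, ".tsv")))
    plog(outdir, "genome ", g, ": mapped ", nrow(mp), "/",
         length(ref_set$seq), " transcripts (identity >= ",
         opts$min_identity, ", coverage >= ", opts$min_coverage,
         "); anchored ", sum(anc$anchored), "/", nrow(nr), " variants")
  }
  integ <- integrate_two_genomes(anchors$A, anchors$B, nr)
  write_integration_json(integ, stage_file(outdir, "anchor",
                                           "integration.json"))
  write_tsv(integ$union, stage_file(outdir, "anchor", "union.tsv"))
  plog(outdir, "integration: both ", integ$counts[["both"]], ", A only ",
       integ$counts[["A_only"]], ", B only ", integ$counts[["B_only"]],
       ", neither ", integ$counts[["neither"]])
}

load_consensus <- function(outdir, accs) {
  out <- list()
  for (a in accs) {
    f <- require_stage_file(
      stage_file(outdir, "calls", paste0("consensus_", a, ".tsv")), "call")
    df <- read_tsv(f)
    out[[a]] <- stats::setNames(
      lapply(df$consensus, function(s) strsplit(s, "")[[1]]), df$transcript)
  }
  out
}

stage_popgen <- function(config, outdir, opts) {
  panels <- panel_accessions(config)
  accs <- c(panels$A, panels$B, panels$OUT)
  cons <- load_consensus(outdir, accs)
  species <- stats::setNames(
    c(rep("ingroupA", length(panels$A)), rep("ingroupB", length(panels$B)),
      "outgroup"), accs)
  m <- build_snp_matrix(cons, species, opts$reference_accession)
  dir.create(stage_file(outdir, "popgen"), showWarnings = FALSE)
  write_tsv(cbind(m$sites, as.data.frame(m$alleles)),
            stage_file(outdir, "popgen", "snp_matrix.tsv"))
  div <- lapply(c("ingroupA", "ingroupB"), function(g)
    as.data.frame(diversity_summary(m, g)))
  div <- do.call(rbind, div)
  write_tsv(div, stage_file(outdir, "popgen", "diversity.tsv"))
  jsonlite::write_json(div, stage_file(outdir, "popgen", "diversity.json"),
                       dataframe = "rows", na = "null", digits = NA)
  for (g in c("ingroupA", "ingroupB")) {
    sfs <- polarize_sfs(m, g)
    write_tsv(data.frame(derived_count = names(sfs$counts),
                         sites = as.integer(sfs$counts)),
              stage_file(outdir, "popgen", paste0("sfs_", g, ".tsv")))
  }
  fd <- fixed_differences(m, "ingroupA", "ingroupB")
  write_tsv(data.frame(comparison = "ingroupA_vs_ingroupB", fixed = fd),
            stage_file(outdir, "popgen", "fixed_differences.tsv"))
  tr <- nj_tree_with_bootstrap(m, replicates = opts$bootstrap_replicates,
                               seed = config$seed, outgroup = panels$OUT)
  write_newick(tr$tree, stage_file(outdir, "popgen", "nj_tree.nwk"))
  write_tsv(theta_by_transcript(m, "ingroupA"),
            stage_file(outdir, "popgen", "theta_ingroupA.tsv"))
  plog(outdir, "matrix: ", nrow(m$alleles), " biallelic sites over ",
       m$L_total, " comparable sites; S_A = ", div$S[1], ", S_B = ",
       div$S[2], "; D_A = ", round(div$tajima_d[1], 3), ", D_B = ",
       round(div$tajima_d[2], 3), "; fixed differences = ", fd,
       "; NJ bootstrap = ", opts$bootstrap_replicates)
}

stage_ortho <- function(config, outdir, opts) {
  refA <- opts$reference_accession
  refB <- opts$reference_accession_B
  setA <- load_transcripts(outdir, refA)
  setB <- load_transcripts(outdir, refB)
  panels <- panel_accessions(config)
  dir.create(stage_file(outdir, "ortho"), showWarnings = FALSE)
  pairs <- rbh_orthologs(setA, setB, min_coverage = opts$rbh_coverage,
                         k = opts$k)
  write_tsv(pairs, stage_file(outdir, "ortho", "rbh_pairs.tsv"))
  plog(outdir, "RBH orthologs: ", nrow(pairs), " pairs (coverage > ",
       opts$rbh_coverage, " both ways)")
  # species B accessions against their own reference set
  consB <- list()
  for (acc in panels$B) {
    samf <- stage_file(outdir, "sam", paste0(acc, "_vs_", refB, ".sam"))
    if (!file.exists(samf)) align_one(outdir, acc, setB, opts)
    pile <- read_sam_pileup(samf, setB)
    consB[[acc]] <- accession_consensus(pile, opts$min_depth,
                                        opts$min_fraction)
  }
  speciesB <- stats::setNames(rep("ingroupB", length(panels$B)), panels$B)
  mB <- build_snp_matrix(consB, speciesB, refB)
  thetaB <- theta_by_transcript(mB, panels$B)
  write_tsv(thetaB, stage_file(outdir, "ortho", "theta_ingroupB.tsv"))
  thetaA <- read_tsv(require_stage_file(
    stage_file(outdir, "popgen", "theta_ingroupA.tsv"), "popgen"))
  sc <- ortho_theta_scatter(pairs, thetaA, thetaB)
  write_tsv(sc$table, stage_file(outdir, "ortho", "theta_scatter.tsv"))
  # FPKM of the two reference accessions on their own sets
  fp <- list()
  for (spec in list(c(refA, refA), c(refB, refB))) {
    samf <- stage_file(outdir, "sam", paste0(spec[1], "_vs_", spec[2], ".sam"))
    if (!file.exists(samf))
      align_one(outdir, spec[1], if (spec[2] == refA) setA else setB, opts)
    ref_set <- if (spec[2] == refA) setA else setB
    aln <- read_sam(samf, ref_set)
    fp[[spec[1]]] <- fpkm(aln, ref_set)
    write_tsv(fp[[spec[1]]],
              stage_file(outdir, "ortho", paste0("fpkm_", spec[1], ".tsv")))
  }
  iA <- match(pairs$id1, fp[[refA]]$transcript)
  iB <- match(pairs$id2, fp[[refB]]$transcript)
  expr_tau <- if (nrow(pairs) >= 2)
    kendall_tau(fp[[refA]]$fpkm[iA], fp[[refB]]$fpkm[iB])
  else list(tau = NA_real_, p = NA_real_, n = nrow(pairs))
  write_tsv(data.frame(comparison = c("theta_orthologs", "fpkm_orthologs"),
                       tau = c(sc$tau, expr_tau$tau),
                       p = c(sc$p, expr_tau$p), n = c(sc$n, expr_tau$n)),
            stage_file(outdir, "ortho", "rank_correlations.tsv"))
  plog(outdir, "Kendall tau: theta ", round(sc$tau %||% NA, 3), " (n = ",
       sc$n, "), FPKM ", round(expr_tau$tau %||% NA, 3), " (n = ",
       expr_tau$n, ")")
}

stage_markers <- function(config, outdir, opts) {
  ref <- opts$reference_accession
  ref_set <- load_transcripts(outdir, ref)
  ancB <- read_tsv(require_stage_file(
    stage_file(outdir, "anchor", "anchored_B.tsv"), "anchor"))
  ancB$ref <- as.character(ancB$ref)
  ancB$alt <- as.character(ancB$alt)
  eligible <- select_marker_indels(ancB)
  mk <- marker_table(eligible, ref_set)
  write_tsv(mk, stage_file(outdir, "markers.tsv"))
  plog(outdir, nrow(eligible), " marker-eligible indel(s), ",
       nrow(mk), " with designed primers")
}

write_manifest <- function(outdir, opts, config) {
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- list(
    tool = "transpop",
    version = as.character(utils::packageVersion("transpop")),
    seed = config$seed,
    thresholds = opts,
    config_hash = unname(tools::md5sum(stage_file(outdir, "config.json"))),
    files = lapply(seq_along(files), function(i)
      list(path = files[i], md5 = unname(sums[i]))))
  path <- stage_file(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
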