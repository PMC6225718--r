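---
title: "Methods: reference-free variant discovery, anchoring, and two-species diversity comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-free variant discovery, anchoring, and two-species diversity comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transpop)
```

## The problem

For a selfing diploid species without a genome assembly, genetic
diversity can still be surveyed from RNA-seq alone: assemble a unigene
set per accession, align every accession's reads to one accession's
unigenes, and call variants where the reads disagree with the
reference transcript.  Chromosomal context comes second-hand, by
mapping the unigenes onto the pseudomolecules of related, sequenced
species and lifting the variant coordinates through those mappings
("virtual chromosomes", justified by conserved gene order).  Finally,
aligning two species' accession panels plus an outgroup to one common
reference transcript set supports a classical population-genetics
comparison of the two species.

This package implements that workflow end to end, replacing the heavy
external machinery (assembler, short-read aligner, spliced mapper,
BLAST) with a compact built-in k-mer aligner adequate for
low-divergence transcriptome data, while keeping file-level import
paths (text SAM, FASTA, tabular mappings) open for externally produced
alignments at real scale.

## The calling rule and its consequences

A pileup column yields a call iff

* read depth **> 10** (strictly), and
* one single non-reference allele accounts for **> 95%** (strictly) of
  the depth.

Both inequalities are strict: depth 10 does not call, and 19 alternate
reads out of 20 (exactly 95%) do not call.  The same thresholds apply
to insertion and deletion keys at their anchor base (the base before
the event, after left-normalization against the reference).  Base
qualities and MAPQ are deliberately ignored — the rule filters on depth
and consensus fraction only, which is appropriate for essentially
homozygous selfing material, where a true variant site should be
near-fixed within an accession's reads and sequencing errors are
scattered and rare.  Diploid genotype likelihoods are out of scope.

Self-comparison (an accession's reads against its own transcripts)
should yield nothing; whatever it does yield marks positions that
mislead the aligner systematically (collapsed paralogs, repeats), and
any call sharing a (transcript, position, class, alt) key with the
self-comparison set is removed as an artifact.  The non-redundant (NR)
set is the deduplicated union of the filtered pairwise sets against one
fixed reference accession; the dedup key includes the alt allele, so two
different substitutions at one position stay distinct (alt-aware keys
preserve information and the choice is isolated in one helper).

## Anchoring

`map_transcripts()` chains exact k-mer matches (k = 21) per
(chromosome, strand) into colinear blocks — isolated mismatches are
bridged within a block, indels open a new block — extends block ends
base by base, and keeps one best locus per transcript by alignment
score (match +1, mismatch −1, gap base −2), with identity ≥ 0.9 and
coverage ≥ 0.5 as mapping filters.  "Mapped" is not defined precisely in
this literature, so the thresholds are explicit arguments and are
recorded in the pipeline log.  Only the best locus is kept because each
unigene is anchored to at most one position per genome; transcripts with
multiple plausible loci are therefore anchored to the strongest one.

`lift_variants()` places a variant by offset arithmetic inside its
block; minus-strand mappings reverse the within-block direction.
Positions in unaligned gaps stay unanchored, as do deletions whose span
crosses a block edge.  The two anchor sets are integrated into the
four-way partition both / A-only / B-only / neither, which always sums
to the NR cardinality; the union placement prefers genome A (the closer
relative in the motivating design), configurable.

## Population-genetic summaries

The high-confidence SNP matrix keeps a site iff every accession — both
ingroup panels and the outgroup — has depth > 10 and a > 95% consensus
allele there, and at most two alleles segregate across the whole panel.
The count of *all* sites passing the coverage filters (monomorphic
included), `L_total`, is the denominator for per-site statistics; the
matrix also records per-transcript comparable-site counts.  The number
of polymorphic columns alone is exposed as the alternative denominator
for users who want diversity relative to variable sites only; per-site
θ reported by `diversity_summary()` uses `L_total`.

Within a group of n accessions with S segregating sites:

* a₁ = Σᵢ₌₁ⁿ⁻¹ 1/i, θ_W = S/a₁;
* π = Σ_sites 2k(n−k)/(n(n−1)), k the within-group count of one allele;
* D = (π − S/a₁) / √(e₁S + e₂S(S−1)) with b₁ = (n+1)/(3(n−1)),
  b₂ = 2(n²+n+3)/(9n(n−1)), c₁ = b₁ − 1/a₁,
  c₂ = b₂ − (n+2)/(a₁n) + a₂/a₁², e₁ = c₁/a₁, e₂ = c₂/(a₁²+a₂).

With S = 0, D is undefined and reported as `NA`; when the numerator is
identically zero (as at n = 2, where π = S and a₁ = 1) D is 0.  π is
computed because D requires it, and both are reported.  Significance
annotation for D is out of scope; the statistic is reported unadorned.

Polarization: at a site polymorphic within an ingroup, the allele
disagreeing with the outgroup is the derived one; if the outgroup
carries a third allele the site is unpolarizable.  Class counts plus the
unpolarizable count always equal S.

Trees: pairwise distance is the proportion of differing matrix columns;
agglomeration is `ape::nj()`; bootstrap resamples matrix columns with
replacement, support being the fraction of replicates containing each
bipartition (`ape::prop.clades`), and the displayed tree is rooted on
the outgroup.

## Orthology and expression

RBH orthology runs the same seed-and-extend scorer in both directions
between two reference transcript sets; a pair requires agreement of the
two best hits and query coverage strictly over 0.80 in both directions
(coverage = aligned query bases / query length, per direction).  Score
ties disqualify a query and are logged.  The scorer's
match/mismatch/gap weights (+1/−1/−2) are explicit because nucleotide
search defaults differ between tools.

FPKM counts a fragment iff both mates map to the same transcript on
opposite strands: FPKM = fragments · 10⁹ / (length · total fragments).
Kendall's τ (tie-corrected τ-b, normal-approximation p-value with ties)
compares FPKM or per-transcript θ across ortholog pairs; the θ
comparison keeps pairs where at least one species is polymorphic.  Note
that this restriction induces a small negative dependence at low
per-transcript counts — a pair enters with S₁ = 0 only if S₂ > 0 — so
τ near zero (or slightly negative on small gene sets) is the expected
null behaviour, and a strong per-gene rate correlation is needed before
τ turns clearly positive.

## Markers

Anchored indels strictly longer than 3 bp (≥ 4, reading "longer than"
strictly, consistent with the strict thresholds elsewhere) are marker
candidates.  Primer design is a deterministic heuristic: 18–24-mers
within 150 bp flanks, GC 40–60%, no mononucleotide run over 4, Wallace
Tm (2(A+T) + 4(G+C)) within 3 °C between the pair, reference amplicon
100–300 bp.  The Wallace rule is a deliberate dependency-free stand-in
for thermodynamic design; amplicon sizes for the two alleles always
differ by exactly the indel length, which is the property genotyping
gels exploit.  Dimer/hairpin screening is out of scope.

## The synthetic-data generator

The generator is first-class, tested code.  It emulates:

* an ancestral gene set (uniform lengths 500–1500 bp by default);
* two ingroup lineages separated by substitution-only divergence
  (1%/bp default) and an outgroup at higher divergence (3%/bp),
  substitution-only so that all three coordinate frames stay colinear
  and every planted variant has exact coordinates on both genomes;
* per-species accession panels with intra-species SNPs and indels whose
  derived-allele counts are drawn from a parameterized site-frequency
  spectrum;
* two syntenic genomes as order-preserving gene concatenations with
  random spacers, per-gene random strand, and per-genome gene
  missingness (defaults 6% / 25%, chosen so the two-genome anchor
  partition resembles a closer and a more distant relative);
* reads with per-transcript expression weights and optional
  substitution errors.

### SFS modes

Derived counts i ∈ {1..n−1} are sampled with weights 1/i (neutral),
1/i² (expansion; singleton-rich), or i(n−i) (structured;
intermediate-rich).  The choice is analytic, not tuned: per segregating
site, E[π] under weights p(i) is Σ p(i)·2i(n−i)/(n(n−1)) while θ_W
contributes 1/a₁ per site.  For n = 10 these give E[π] − E[θ] per site
of exactly 0 (neutral), −0.075 (expansion) and +0.095 (structured), so
2000-site panels have expected Tajima's D of ≈ 0, ≈ −1.0 and ≈ +1.3
respectively — a clean qualitative reproduction of the
negative-vs-positive D contrast between a singleton-rich and a
structure-rich species that motivates the two default panel modes.
Genotype vectors are sampled directly from the SFS rather than from an
explicit coalescent: this gives exact control of the frequency classes
being contrasted.  For calibration, `simulate_panel()` draws S ~
Poisson(θ·a₁), which makes θ_W unbiased for the nominal θ by
construction; the neutral-mode mean D over replicate panels is then a
genuine check of the D implementation, not of a demographic model.

### Identifiability by construction

Error-free recovery of *every* planted variant is only a meaningful
target if each variant is unambiguously observable.  The generator
enforces this:

* planted events are ≥ 24 bp apart and at least one fragment length
  (2·read_length + 20 bp) from transcript ends, so every variant site
  lies in the fully covered interior;
* indels are re-drawn until their junction cannot shift left or right
  (non-repetitive context), making the left-normalized representation
  unique and shared between the caller and the truth table;
* fragment boundaries are nudged (deterministically, by up to ±40 bp)
  so that no read starts or ends within 12 bp of an indel junction:
  every read overlapping an indel spans it with enough anchor sequence
  to align unambiguously.  This implements the "reads unambiguous"
  proviso of the recovery contract rather than weakening the caller;
* the reference accession of each species carries the ancestral allele
  at every indel site, so the reference transcript coordinate frame
  equals the ancestral gene frame used by the truth table (SNP sites
  are unconstrained; indel derived-carrier draws are made from the
  remaining n−1 accessions, a small documented bias that does not touch
  the SNP-based spectra).

### Coverage model

`fragment_depth` is a guaranteed per-base coverage floor: fragments are
tiled quasi-uniformly with a count proportional to the full transcript
length, which (a) keeps interior coverage at ≥ the nominal depth so the
"> 10" filter passes everywhere at depth ≥ 15, and (b) makes the
floor's FPKM contribution length-independent, so expression ranks are
carried entirely by the second layer: a Poisson number of uniformly
placed fragments with mean proportional to 2 · depth · weight · length.
Expression weights are log-normal (sdlog 2 by default — several orders
of magnitude, as in transcriptome data) with a configurable between-
species correlation (0.9), and per-gene mutation-rate multipliers are
log-normal with their own between-species correlation (0.1), which is
the knob behind the ortholog θ–θ association.

### What the generator does not emulate

One transcript per gene (no isoforms — unigene sets collapse isoforms
anyway); no realistic error profiles (errors are uniform
substitutions); no spliced structure (genomes are intronless gene
concatenations, so transcript-to-genome mapping needs no splice model
and the anchoring contract stays exactly testable); no paralogy or
repeats; no explicit demography.  Passing the recovery tests therefore
demonstrates the correctness of the calling/anchoring/popgen machinery
under the stated rules, not robustness to assembly artifacts, paralog
collapse, or alignment ambiguity in real data — for real data the
import paths (SAM, mapping tables) and the artifact filter carry that
burden.

## Numerical choices

Strict threshold comparisons are made as `count/depth > 0.95 + 1e-9` so
that exact boundary fractions (19/20) are excluded regardless of binary
rounding.  The aligner charges an indel 3 mismatch-equivalents, so a
single terminal mismatch is never re-explained as an indel, and ties
between placements are broken deterministically (ungapped first, then
'+' strand, smallest transcript id, leftmost coordinate) and flagged
ambiguous.  Bootstrap and all generator draws flow from explicit seeds;
rerunning any stage with the same seed is byte-identical.

## Problem sizes used in the validation suite

The packaged checks run the full panel design at desk scale: variant
recovery on 500 genes × 12 accessions at coverage 20 (~3.5M reads);
the cross-species matrix, spectra, and trees on 100–120 genes with the
12 + 10 + 1 panel at coverage 15; estimator calibration on 200
replicate panels per SFS mode (n = 10, θ = 20); 200 bootstrap
replicates for tree support.  These sizes were chosen so the complete
suite exercises every stage in a few minutes on one core; all module
logic is size-independent.

## Known limitations

The built-in aligner handles one indel per read (up to 10 bp) and no
soft-clipping; at the planted densities multi-indel reads are vanishing
but real data should come through the SAM import path.  NR counts are
reference-accession-dependent (the pairwise matrix is not symmetric),
which is inherent to the design, and only the ≤-union bound is asserted.
The per-site θ denominator question (all comparable sites vs variable
sites) is exposed rather than resolved: both counts are available on the
matrix object.
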