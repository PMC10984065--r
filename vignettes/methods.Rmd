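---
title: "Methods: screening a single gene for exon-skipping transcripts and their genomic lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening a single gene for exon-skipping transcripts and their genomic lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skipscreen)
```

## The problem

Some disease-causing lesions in a gene act by removing exons from the mature
transcript — either a genomic multi-exon deletion or a splice-site variant
that makes the spliceosome skip one or more exons. When the removed stretch is
a multiple of 3 nt, the protein keeps its reading frame but loses a domain;
for genes with an autoinhibitory region this can produce a gain-of-function
disease. Such lesions are invisible to exome-style analyses that look for
coding point variants: the genomic change may be intronic or structural, and
its effect lives in the transcript.

`skipscreen` implements this screen as a reusable pipeline over a single
gene:

1. sequence a full-length cDNA amplicon of the gene per subject;
2. align reads to the canonical spliced transcript with a split-read aligner;
3. classify junctions against the exon model and quantify, per subject, the
   fraction of each exon-skip signature ("Δ19-22" = exons 19-22 absent);
4. flag subjects carrying novel, in-frame, regulatory-region skip transcripts
   not seen in healthy controls;
5. for flagged subjects, analyze trio genomic (WGS-style) reads to find the
   underlying lesion — a deletion (discordant pairs + split reads, with de
   novo status and parent of origin) or a splice-region SNV (annotated in
   HGVS c. notation);
6. classify a deletion's plausible mechanism by intersecting its breakpoints
   with a repeat-element track (Alu-mediated recombination vs none).

Because patient data are unavailable, the package ships a synthetic-data
module that builds a PLCG2-like locus and a preset 14-subject cohort whose
two causal probands carry, respectively, a heterozygous splice-donor SNV at
c.2298+5 and a de novo heterozygous 14,197 nt genomic deletion of exons
19-22. Everything is exercisable end to end without external data.

## Coordinates and gene model

A `gene_model()` stores exon intervals 0-based half-open in transcription
orientation (minus-strand genes are normalized at ingest with
`flip_gene_model()`); all user-facing positions are 1-based. HGVS c.
annotation follows the convention: exonic positions count coding bases,
intronic positions anchor to the nearest exon edge with a signed offset, the
5' half of an intron to the donor (`+k`) and the 3' half to the acceptor
(`-k`), with the exact midpoint of an odd-length intron going to the donor.
`genomic_to_cdna()` and `cdna_to_genomic()` are exact inverses over the gene
span — this is a tested property, not an aspiration.

```{r coords}
ref <- build_reference(sim_config(seed = 1))
m <- ref$model
genomic_to_cdna(m, m$exons$end[19] + 5L)
```

The preset locus has 33 exons whose lengths and intron structure are chosen
so the numbers match the anchors used throughout: coding sequence through
exon 19 ends at c.2298; the deletion removes 14,197 nt starting 1,000 nt into
intron 18 and ending in intron 22; and all four preset skip signatures
(Δ19: 162 nt, Δ18-19: 282 nt, Δ20-22: 360 nt, Δ19-22: 522 nt) are multiples
of 3, i.e. in frame.

## The split-read aligner

Reads are aligned by a purpose-built seed-and-chain aligner (C++ via Rcpp):

- **Anchoring.** Exact k-mer matches (default `k = 21`) against a 2-bit
  index of the reference, grouped by diagonal into ungapped anchors.
- **Chaining.** Dynamic programming selects the chain maximizing anchored
  k-mers; ties prefer the smaller total reference gap, and residual ties are
  reported as `ambiguous` rather than resolved arbitrarily.
- **Split resolution.** Between consecutive chain blocks the exact junction
  placement is chosen from the co-optimal set (all placements with minimal
  mismatches). In cDNA mode, if an annotated exon boundary lies within the
  microhomology window (default 8 nt), the junction **snaps to the boundary**
  (`exon_snap`); otherwise, and always in genomic mode, the junction is
  **left-aligned** — the standard convention for indel normalization, making
  placements deterministic under microhomology.
- **Soft clipping.** A terminal segment that would add more mismatches than
  matches (scored +1/−3) is clipped rather than forced into the alignment,
  so reads overhanging a junction by less than `k` stay mapped instead of
  polluting the mismatch statistics.
- **Filters.** `min_terminal = 12` nt per outer block, `max_mismatch_frac =
  0.05`, minimum aligned length `k`.

A junction in an alignment counts as *spanning* evidence when the read
overlaps both sides by at least `min_span = 12` nt. The stronger tested
guarantee — every error-free read recovers its junction — holds for reads
overhanging each side by at least `k` nt, the smallest overhang the k-mer
anchoring can attest exactly; reads with shorter overhangs are still mapped
(soft-clipped) but may not carry the junction.

## Quantification and cohort screen

Each mapped read is assigned by classifying its junctions against the model:
exact boundary pairs are `canonical_splice`, a pair joining the end of exon
a−1 to the start of exon b+1 is the skip `Δa-b`, anything else
`noncanonical`. For a signature, the reported fraction is

> supporting reads / informative reads,

where informative reads are those that span (with the aligner's minimum
flank) the canonical boundary replaced by the signature's first skip, either
canonically or via any junction starting there — i.e. exactly the reads that
could have revealed the event. The naive fraction over all mapped reads is
reported alongside (`fraction_total`).

The cohort screen (`flag_candidates()`) flags a (subject, signature) pair as
a candidate iff the fraction exceeds 10%, the skip is in frame, it touches
the regulatory exons (default 18-22), and the signature stays below 5% in
every healthy control ("not observed in healthy subjects", operationalized
with a noise floor rather than literal zero). Signatures at or above 5% are
reported; above 30% is labelled high-proportion. All thresholds are
configurable through `quant_config()`.

## Trio genomic analysis

For a flagged subject's trio, genomic-mode alignments feed two callers:

- **Deletion.** Split reads with a reference gap of at least 50 nt nominate
  exact breakpoints (modal consensus); pairs in proper orientation whose
  apparent insert exceeds mean + 4 sd corroborate them — a pair supports a
  specific deletion only if the interval implied between its mates contains
  both breakpoints, so chance-long fragments are not evidence. A member
  carries the deletion with ≥ 3 split reads, or ≥ 5 supporting pairs plus
  ≥ 1 split read. The call is **de novo** iff both parents have zero
  supporting reads *and* depth ≥ 10 at both breakpoints; insufficient
  parental depth yields `de_novo = NA` ("unevaluable"), never a false de
  novo. Parent of origin comes from junction-spanning child reads that also
  cover a Mendelian-informative flanking het site (majority vote, ≥ 3
  votes).
- **Splice-region SNV.** Pileups over ±8 nt of every donor/acceptor are
  screened (alt reads ≥ 4, alt fraction ≥ 0.2, depth ≥ 8; lower child depth
  marks the position unevaluable). Calls are annotated in HGVS c. notation
  and classified de novo / maternal / paternal / ambiguous from parental
  genotypes.

Deletion and SNV calls are written as VCF 4.2 (symbolic `<DEL>` with
`END`/`SVLEN`, per-member genotype columns).

## Mechanism classification

`breakpoint_repeat_intersect()` pads each breakpoint (default ±10 nt,
matching the caller's uncertainty) and intersects against a BED6 repeat
track. `classify_mechanism()` applies the decision table: `alu_mediated` iff
both ends overlap Alu elements sharing a strand (the aligned-repeat
configuration recombination requires); otherwise `repeat_both_ends`,
`repeat_one_end`, or `none`. Orientation matters: Alu at both ends on
opposite strands is *not* Alu-mediated. Sequence-level homology scoring is
deliberately out of scope — the classification operationalizes intersection
plus orientation.

## The synthetic cohort

`simulate_cohort()` builds the locus (GT/AG forced at every splice site),
plants the two causal lesions, and emits:

- per-subject paired amplicon reads from explicit isoform mixtures
  (proband 1: canonical 0.5 plus a mutant allele emitting Δ18-19 / Δ19 /
  Δ19-22 at 5:3:2; proband 2: canonical/Δ19-22 at 0.5/0.5; two positive
  controls at 0.5 Δ19 and 0.5 Δ20-22; everyone else canonical);
- trio genomic reads for both probands' families (Normal(350, 50) fragments,
  30× depth, per-base error 0.002), with Mendelian-informative marker sites
  planted so parent of origin is recoverable;
- a repeat track, machine-readable truth tables, and one seed driving
  everything deterministically.

One generator design choice deserves a note: the generator *blunts*
microhomology at the planted breakpoints (it edits deleted bases only, so
carriers and non-carriers see identical sequenced alleles). Without this, a
chance homology run at the breakpoint makes the left-aligned call differ from
the planted coordinate by the run length — a property of coordinates under
microhomology, not an aligner error. Blunting makes "breakpoints recovered
exactly" a well-posed assertion across seeds; the aligner itself handles
microhomologous junctions via the snap/left-align rules above, which are
tested separately against exhaustive placement oracles.

What the generator does **not** emulate: indels and structural errors in
reads, quality-score-correlated errors, PCR duplicates and amplification
bias, coverage waviness, multi-gene backgrounds, or paralogous sequence. The
error model is i.i.d. substitutions. These omissions are deliberate — the
pipeline's logic is exercised by the lesion geometry, mixtures and sampling
noise, which the generator does model.

## Problem sizes and runtime

The preset locus is ~31.5 kb, the canonical cDNA 4,428 nt. A cohort run at
2,000 read pairs/subject aligns ~56,000 reads in a few seconds; a trio at
30× is ~19,000 read pairs. The 20-seed acceptance sweeps (cohort recovery and
de novo caller) each run in a few minutes on one CPU.

## End-to-end example

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(list(outdir = "run1", seed = 1))
res <- run_all(cfg)
glance(res$screen)          # 2 candidate probands, 0 candidate controls
res$wgs$proband2$deletion   # exact breakpoints, de novo, maternal origin
```

## Limitations

- Single-gene scope: no genome-wide SV calling, no multi-mapping resolution
  across paralogs.
- The quantification denominator assumes amplicon-style coverage of the
  relevant boundary; very short exons (< 2 × min flank) would undercount
  informative reads.
- The de novo label is evidence-based (parents clean and covered), not a
  probabilistic genotype model; the VAF genotype bins (0.2 / 0.8) are
  heuristics appropriate for the simulated depths.
- Mechanism classification is intersection + orientation only; it does not
  align repeat copies to score recombination homology.
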