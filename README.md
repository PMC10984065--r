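# skipscreen

Detection of exon-skipping transcripts and their genomic lesions from
gene-specific cDNA sequencing.

## The scientific problem

Some disease-causing lesions remove whole exons from a gene's mature
transcript rather than changing its coding sequence — a genomic multi-exon
deletion, or a splice-region variant that makes the spliceosome skip exons.
If the removed stretch has length divisible by 3, the transcript stays in
frame and the protein simply loses a domain; when that domain is
autoinhibitory, the result can be a gain-of-function disease. Exome-centric
variant calling misses these lesions: the genomic change is intronic or
structural, and its consequence is only visible in the transcript.

`skipscreen` implements the transcript-first screen for a single gene:

1. **Quantify skips.** Per subject, align full-length cDNA amplicon reads to
   the canonical spliced transcript with a split-read aligner, classify every
   junction against the exon model, and estimate for each skip signature
   Δa–b (exons a through b absent) the fraction

   f(Δa–b) = supporting reads / informative reads,

   where the informative reads are those that span the boundary the skip
   replaces — with enough flank to have revealed it either way.
2. **Flag candidates.** A subject carries a candidate lesion if some skip
   has f > 10%, is in frame (skipped length ≡ 0 mod 3), touches the
   regulatory exon block (default exons 18–22), and stays below 5% in every
   healthy control. Fractions ≥ 5% are reported; > 30% is labelled
   high-proportion.
3. **Find the lesion.** For flagged subjects, trio genomic reads are
   screened for (a) a multi-exon deletion — split reads nominate exact
   breakpoints, discordant pairs whose implied interval contains both
   breakpoints corroborate them; the call carries genotype per family
   member, de novo status (parents clean *and* covered, depth ≥ 10), and
   parent of origin from phase-informative flanking het sites — and (b)
   splice-region SNVs within ±8 nt of any donor/acceptor, annotated in HGVS
   c. notation (e.g. `c.2298+5G>T`).
4. **Classify the mechanism.** Deletion breakpoints (±10 nt) are intersected
   with a repeat-element track: Alu elements on the same strand at both ends
   → `alu_mediated`, otherwise `repeat_both_ends` / `repeat_one_end` /
   `none`.

A synthetic-data module generates a PLCG2-like 31.5 kb locus and a preset
cohort (9 probands, 3 healthy controls, 2 positive controls) whose two
causal probands carry a heterozygous splice-donor SNV at c.2298+5 and a de
novo 14,197 nt deletion of exons 19–22, plus trio genomic reads and
machine-readable truth files — so the entire pipeline runs without patient
data. See the methods vignette (`vignettes/methods.Rmd`) for the model and
all numerical choices.

## Worked example

Simulate the preset cohort, screen it, and chase the flagged subjects down
to their genomic lesions:

```r
library(skipscreen)

co   <- simulate_cohort(sim_config(seed = 1, amplicon_depth = 2000L))
ref  <- co$reference
cdna <- make_isoform(ref$model, ref$seq)                 # canonical transcript
idx  <- index_reference(cdna, align_params()$k)

quants <- purrr::map(co$config$roster$subject_id, function(sid) {
  aln <- align_reads(co$amplicon[[sid]]$reads, idx, ref$model, mode = "cdna")
  quantify_subject(aln, ref$model, subject_id = sid)
}) |> purrr::list_rbind()

scr <- flag_candidates(quants, co$config$roster, ref$model)
scr
#> <cohort_screen> 14 subjects, 4 signatures, 6 candidate rows in 4 subjects
#> # A tibble: 6 × 5
#>   subject_id role             label  fraction frame
#>   <chr>      <chr>            <chr>     <dbl> <chr>
#> 1 proband1   proband          Δ18-19    0.235 in_frame
#> 2 proband1   proband          Δ19       0.188 in_frame
#> 3 proband1   proband          Δ19-22    0.120 in_frame
#> 4 proband2   proband          Δ19-22    0.504 in_frame
#> 5 positive1  positive_control Δ19       0.470 in_frame
#> 6 positive2  positive_control Δ20-22    0.533 in_frame

glance(scr)
#> # A tibble: 1 × 5
#>   n_subjects n_signatures n_candidate_subjects n_candidate_probands
#>        <int>        <int>                <int>                <int>
#> 1         14            4                    4                    2
#> # ℹ 1 more variable: n_candidate_controls <int>
```

Both causal probands are flagged (the two positive controls are supposed to
be, and no healthy control is). Proband 2's lesion is a genomic deletion:

```r
aln2 <- lapply(co$trios$proband2$members, function(r)
  align_reads(r, ref$seq, ref$model, mode = "genomic"))
del <- call_deletion(aln2, ref$model)
del
#> <deletion_call> PLCG2_locus.10287_24483del (14197 nt), exons 19-22; de novo: TRUE (de_novo)
#> # A tibble: 3 × 8
#>   member split_support discordant_support ref_support depth_left depth_right
#>   <chr>          <int>              <int>       <dbl>      <int>       <int>
#> 1 child             20                  5          11         16           9
#> 2 mother             0                  0          28         34          31
#> 3 father             0                  0          21         26          29
#> # ℹ 2 more variables: vaf <dbl>, genotype <chr>

classify_mechanism(breakpoint_repeat_intersect(del, co$repeat_track))
#> <mechanism_call> none (left: 0 element(s), right: 0 element(s))
```

Proband 1's lesion is a splice-donor SNV, annotated in HGVS c. notation:

```r
aln1 <- lapply(co$trios$proband1$members, function(r)
  align_reads(r, ref$seq, ref$model, mode = "genomic", keep_seq = TRUE))
snv <- splice_region_snv_screen(aln1, ref$seq, ref$model)
snv$calls[, c("pos", "ref", "alt", "label", "site", "inheritance")]
#> # A tibble: 1 × 6
#>     pos ref   alt   label       site         inheritance
#>   <int> <chr> <chr> <chr>       <chr>        <chr>
#> 1 11453 G     T     c.2298+5G>T donor_region maternal
```

The same analysis as one call, writing FASTA/FASTQ/TSV/VCF/JSON artifacts:

```r
res <- run_all(pipeline_config(list(outdir = "run1", seed = 1)))
```

Alignments, screens, deletion calls and mechanism calls all provide
`tidy()`, `glance()` and `autoplot()` methods.

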