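test_that("build_reference is seed-deterministic and splice-site consistent", {
  cfg <- sim_config(seed = 42)
  r1 <- build_reference(cfg)
  r2 <- build_reference(cfg)
  expect_identical(r1$seq, r2$seq)
  r3 <- build_reference(sim_config(seed = 43))
  expect_false(identical(r1$seq, r3$seq))
  # every intron starts GT and ends AG
  ex <- r1$model$exons
  for (i in 1:(nrow(ex) - 1L)) {
    don <- substring(r1$seq, ex$end[i] + 1L, ex$end[i] + 2L)
    acc <- substring(r1$seq, ex$start[i + 1L] - 1L, ex$start[i + 1L])
    expect_equal(don, "GT")
    expect_equal(acc, "AG")
  }
})

test_that("make_isoform matches exon-substring concatenation", {
  ref <- preset_ref()
  m <- ref$model
  ex <- m$exons
  # oracle: paste exon substrings (1-based coordinates from 0-based half-open)
  oracle <- paste(substring(ref$seq, ex$start + 1L, ex$end), collapse = "")
  expect_equal(make_isoform(m, ref$seq), oracle)
  # skipping exon 19 removes exactly that substring
  d19 <- make_isoform(m, ref$seq, 19L)
  e19 <- substring(ref$seq, ex$start[19] + 1L, ex$end[19])
  pre <- sum(ex$length[1:18])
  expect_equal(nchar(d19), spliced_length(m) - ex$length[19])
  expect_equal(d19, paste0(substr(oracle, 1, pre),
                           substr(oracle, pre + ex$length[19] + 1L,
                                  nchar(oracle))))
  expect_false(grepl(e19, d19, fixed = TRUE) &&
                 nchar(e19) > 30)  # the skipped exon is gone
  # multi-exon skip = sum of lengths removed
  d <- make_isoform(m, ref$seq, 19:22)
  expect_equal(nchar(d), spliced_length(m) - sum(ex$length[19:22]))
})

test_that("preset lesions reproduce the intended architecture", {
  ref <- preset_ref()
  m <- ref$model
  les <- preset_lesions(m)
  expect_equal(les$deletion$end - les$deletion$start + 1L, 14197L)
  expect_equal(deletion_to_exons(m, les$deletion$start, les$deletion$end)$exons,
               19:22)
  expect_equal(les$snv$pos, m$exons$end[19] + 5L)
  expect_equal(genomic_to_cdna(m, les$snv$pos)$label, "c.2298+5")
  # the assembled cohort reference guarantees the SNV ref base differs from
  # the alternate (the raw reference draw makes no such promise)
  co <- preset_cohort()
  expect_false(substring(co$reference$seq, les$snv$pos, les$snv$pos) ==
                 les$snv$alt)
  # all preset skip signatures are in frame
  for (sig in list(19L, 19:22, 18:19, 20:22)) {
    expect_equal(skip_frame(m, sig)$frame, "in_frame")
  }
})

test_that("amplicon reads are deterministic, paired, and faithful at zero error", {
  ref <- preset_ref()
  m <- ref$model
  iso <- c(canonical = make_isoform(m, ref$seq),
           "Δ19" = make_isoform(m, ref$seq, 19L))
  mix <- c(canonical = 0.7, "Δ19" = 0.3)
  s1 <- simulate_amplicon_reads(iso, mix, 300L, seed = 9, base_error_rate = 0)
  s2 <- simulate_amplicon_reads(iso, mix, 300L, seed = 9, base_error_rate = 0)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$reads), 600L)              # two mates per pair
  expect_setequal(s1$reads$mate, 1:2)
  expect_equal(nrow(s1$truth), 300L)
  expect_setequal(s1$truth$isoform, names(iso))
  # every error-free read is a substring of its isoform (mate 2 reverse strand)
  joined <- merge(s1$reads, s1$truth, by = "read_id")
  for (i in seq_len(nrow(joined))) {
    src <- iso[[joined$isoform[i]]]
    q <- if (joined$mate[i] == 2L) revcomp(joined$seq[i]) else joined$seq[i]
    expect_true(grepl(q, src, fixed = TRUE))
  }
})

test_that("isoform mixture fractions are recovered within binomial noise", {
  ref <- preset_ref()
  m <- ref$model
  iso <- c(canonical = make_isoform(m, ref$seq),
           "Δ19" = make_isoform(m, ref$seq, 19L))
  n <- 10000L
  s <- simulate_amplicon_reads(iso, c(canonical = 0.5, "Δ19" = 0.5), n,
                               seed = 4, base_error_rate = 0)
  phat <- mean(s$truth$isoform == "Δ19")
  expect_lt(abs(phat - 0.5), 4 * sqrt(0.25 / n))
})

test_that("mixtures must be valid", {
  ref <- preset_ref()
  iso <- c(canonical = make_isoform(ref$model, ref$seq))
  expect_error(simulate_amplicon_reads(iso, c(canonical = 0.4), 10L, seed = 1))
  expect_error(simulate_amplicon_reads(iso, c(missing = 1), 10L, seed = 1))
})

test_that("trio fragments and genotypes follow the requested zygosity", {
  ref <- preset_ref()
  m <- ref$model
  les <- preset_lesions(m)
  tr <- simulate_trio_wgs(
    ref$seq, m, deletion = les$deletion,
    genotypes = list(deletion = c(child = "0/1", mother = "0/0",
                                  father = "0/0")),
    depth = 10, seed = 31, base_error_rate = 0)
  expect_named(tr$members, c("child", "mother", "father"))
  expect_equal(tr$truth$genotypes$child[["deletion"]], "0/1")
  expect_equal(tr$truth$genotypes$mother[["deletion"]], "0/0")
  fr <- tr$truth$fragments
  # haplotype labels are 1/2 and roughly balanced
  expect_setequal(unique(fr$hap), 1:2)
  # fragment length >= 2x read length (both mates fit)
  expect_true(all(fr$frag_len >= 300L))
  # deterministic
  tr2 <- simulate_trio_wgs(
    ref$seq, m, deletion = les$deletion,
    genotypes = list(deletion = c(child = "0/1", mother = "0/0",
                                  father = "0/0")),
    depth = 10, seed = 31, base_error_rate = 0)
  expect_identical(tr, tr2)
})

test_that("child deletion-haplotype fragments spanning a breakpoint are enumerable", {
  ref <- preset_ref()
  m <- ref$model
  les <- preset_lesions(m)
  tr <- simulate_trio_wgs(
    ref$seq, m, deletion = les$deletion,
    genotypes = list(deletion = c(child = "0/1", mother = "0/0",
                                  father = "0/0")),
    depth = 20, seed = 13, base_error_rate = 0)
  fr <- tr$truth$fragments[tr$truth$fragments$member == "child", ]
  # on haplotype 2 (carries the deletion) the breakpoint sits at the 0-based
  # junction position start-1 of the deleted sequence
  bp_hap <- les$deletion$start - 1L
  span <- fr$hap == 2L & fr$frag_start <= bp_hap &
    fr$frag_start + fr$frag_len - 1L > bp_hap
  # each such fragment straddles the deletion: its two mates map > del length
  # apart on the reference, so at least those many discordant/split signals
  # must exist in the child's reads
  expect_gt(sum(span), 0)
  aln <- align_reads(tr$members$child, ref$seq, m, mode = "genomic")
  disc <- detect_discordant_pairs(aln, insert_mean = 350, insert_sd = 50)
  splits <- detect_split_reads(aln)
  evidence <- sum(disc$support) + sum(splits$support)
  # every spanning fragment contributes a discordant pair or a split read;
  # a few with the breakpoint within the minimum anchor of a read end are
  # soft-clipped instead, so allow a small deficit
  expect_gte(evidence, floor(0.8 * sum(span)))
})

test_that("simulate_cohort assembles the preset screen", {
  co <- preset_cohort()
  roster <- co$config$roster
  expect_equal(nrow(roster), 14L)
  expect_equal(sum(roster$role == "proband"), 9L)
  expect_equal(sum(roster$role == "healthy_control"), 3L)
  expect_equal(sum(roster$role == "positive_control"), 2L)
  expect_setequal(names(co$amplicon), roster$subject_id)
  expect_setequal(names(co$trios), c("proband1", "proband2"))
  # truth marks exactly the two causal probands
  expect_equal(sum(co$truth$roster$causal), 2L)
  expect_equal(co$truth$roster$lesion[co$truth$roster$subject_id == "proband1"],
               "splice_snv")
  expect_equal(co$truth$roster$lesion[co$truth$roster$subject_id == "proband2"],
               "genomic_deletion")
  # mixtures all sum to one
  for (mx in co$config$isoform_mixtures) expect_equal(sum(mx), 1)
  # proband1 carries the 5:3:2 mutant-allele mixture
  mx1 <- co$config$isoform_mixtures$proband1
  expect_equal(unname(mx1["canonical"]), 0.5)
  expect_equal(unname(mx1[c("Δ18-19", "Δ19", "Δ19-22")]),
               c(0.25, 0.15, 0.10))
})

test_that("repeat track respects exclusions and plants", {
  tr <- simulate_repeat_track(30000L, seed = 3, exclude = c(10000L, 24000L),
                              exclude_pad = 500L)
  expect_true(all(tr$start >= 1L & tr$end <= 30000L))
  expect_true(all(tr$family %in% c("Alu", "other_SINE", "LINE", "LTR",
                                   "other")))
  for (z in c(10000L, 24000L)) {
    expect_false(any(tr$start <= z + 500L & tr$end >= z - 500L))
  }
  tr2 <- simulate_repeat_track(30000L, seed = 3,
                               plant_alu = c(5000L, 20000L))
  hit1 <- tr2[tr2$start <= 5000L & tr2$end >= 5000L, ]
  hit2 <- tr2[tr2$start <= 20000L & tr2$end >= 20000L, ]
  expect_true(any(hit1$family == "Alu" & hit1$strand == "+"))
  expect_true(any(hit2$family == "Alu" & hit2$strand == "+"))
})
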