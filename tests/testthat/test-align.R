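test_that("the k-mer index finds every occurrence", {
  seq <- rand_dna(400L, seed = 1)
  k <- 11L
  idx <- index_reference(seq, k)
  for (i in withr::with_seed(2, sample(1:(400L - k + 1L), 60L))) {
    kmer <- substr(seq, i, i + k - 1L)
    # oracle: all start offsets of this k-mer (0-based)
    hits <- stringr::str_locate_all(
      seq, sprintf("(?=%s)", kmer))[[1]][, 1] - 1L
    expect_setequal(index_lookup(idx, kmer), hits)
  }
  expect_length(index_lookup(idx, paste(rep("N", k), collapse = "")), 0L)
})

test_that("exact substrings map at the planted offset on both strands", {
  seq <- rand_dna(1000L, seed = 3)
  starts <- withr::with_seed(4, sample(1:850, 40L))
  reads <- substring(seq, starts, starts + 120L)
  aln <- align_reads(reads, seq, mode = "genomic")
  expect_true(all(aln$status == "mapped"))
  expect_true(all(aln$strand == "+"))
  expect_true(all(aln$mismatches == 0L))
  first_r0 <- function(a) purrr::map_int(a$blocks, ~ parse_blocks(.x)$r0[1])
  expect_equal(first_r0(aln), starts - 1L)
  # reverse-complement reads map on the minus strand to the same blocks
  aln_rc <- align_reads(revcomp(reads), seq, mode = "genomic")
  expect_true(all(aln_rc$strand == "-"))
  expect_equal(first_r0(aln_rc), starts - 1L)
})

test_that("degenerate inputs behave: empty set, read == reference, short read", {
  seq <- rand_dna(100L, seed = 5)
  empty <- align_reads(character(0), seq, mode = "genomic")
  expect_equal(nrow(empty), 0L)
  # a read equal to a reference of exactly k nt maps off a single anchor
  tiny <- rand_dna(31L, seed = 55)
  whole <- align_reads(tiny, tiny, mode = "genomic",
                       params = align_params(k = 31L, min_terminal = 1L,
                                             min_span = 1L, min_aligned = 31L))
  expect_equal(whole$status, "mapped")
  expect_equal(whole$aligned, 31L)
  short <- align_reads(substr(seq, 10, 24), seq, mode = "genomic")  # 15 < k
  expect_equal(short$status, "unmapped")
})

test_that("reads with scattered errors still map; garbage does not", {
  seq <- rand_dna(2000L, seed = 6)
  clean <- substr(seq, 301, 450)
  noisy <- clean
  substr(noisy, 40, 40) <- "N"
  substr(noisy, 90, 90) <- "N"
  a <- align_reads(c(clean, noisy), seq, mode = "genomic")
  expect_equal(a$status, c("mapped", "mapped"))
  expect_equal(a$mismatches, c(0L, 2L))
  garbage <- rand_dna(150L, seed = 7)
  expect_equal(align_reads(garbage, seq, mode = "genomic")$status, "unmapped")
})

test_that("junk prefixes are soft-clipped, not forced into the alignment", {
  seq <- rand_dna(2000L, seed = 8)
  core <- substr(seq, 501, 640)
  read <- paste0("CCCCCCCCCC", core)       # 10 nt junk + 140 nt genuine
  a <- align_reads(read, seq, mode = "genomic")
  expect_equal(a$status, "mapped")
  expect_equal(a$clip_left, 10L)
  expect_equal(parse_blocks(a$blocks)$r0[1], 500L)
})

test_that("planted skip junctions are recovered at exact cDNA boundaries", {
  ref <- preset_ref()
  m <- ref$model
  cdna <- make_isoform(m, ref$seq)
  b <- cdna_boundaries(m)
  for (sig in list(19L, 19:22, 18:19, 20:22)) {
    iso <- make_isoform(m, ref$seq, sig)
    jpos <- sum(m$exons$length[1:(min(sig) - 1L)])  # junction in iso coords
    read <- substr(iso, jpos - 74L, jpos + 75L)      # centred on the junction
    a <- align_read(read, cdna, m, mode = "cdna")
    expect_equal(a$status, "mapped")
    expect_equal(nrow(a$junctions), 1L)
    expect_equal(a$junctions$left, b[min(sig) - 1L])
    expect_equal(a$junctions$right, b[max(sig)])
  }
})

test_that("100% of junction-spanning error-free reads recover the junction", {
  ref <- preset_ref()
  m <- ref$model
  cdna <- make_isoform(m, ref$seq)
  b <- cdna_boundaries(m)
  iso <- make_isoform(m, ref$seq, 19L)
  jpos <- sum(m$exons$length[1:18])
  k <- align_params()$k
  # every start offset that leaves >= k nt on both sides of the junction
  starts <- (jpos - 150L + k):(jpos - k)
  reads <- substring(iso, starts + 1L, starts + 150L)
  aln <- align_reads(reads, cdna, m, mode = "cdna")
  jt <- junction_table(aln)
  expect_equal(nrow(jt), 1L)
  expect_equal(jt$left, b[18])
  expect_equal(jt$right, b[19])
  expect_equal(jt$support, length(reads))
})

test_that("microhomology junctions snap to the exon boundary", {
  ref <- preset_ref()
  m <- ref$model
  ex <- m$exons
  b <- cdna_boundaries(m)
  # engineer 6 nt of microhomology: make the start of exon 20 equal the start
  # of exon 19, so a Δ19 junction read has ambiguous placement
  seq <- ref$seq
  hom <- substring(seq, ex$start[19] + 1L, ex$start[19] + 6L)
  substring(seq, ex$start[20] + 1L, ex$start[20] + 6L) <- hom
  cdna <- make_isoform(m, seq)
  iso <- make_isoform(m, seq, 19L)
  jpos <- sum(ex$length[1:18])
  read <- substr(iso, jpos - 70L, jpos + 71L)
  a <- align_read(read, cdna, m, mode = "cdna")
  expect_equal(nrow(a$junctions), 1L)
  # oracle: placements shifted right by 0..6 are all mismatch-free; the
  # aligner must pick the exon boundary among them
  for (shift in 0:6) {
    lft <- substr(iso, jpos - 70L, jpos + shift)
    rgt <- substr(iso, jpos + shift + 1L, jpos + 71L)
    expect_equal(paste0(lft, rgt), read)  # sanity: read unchanged by split
  }
  expect_equal(a$junctions$left, b[18])
  expect_equal(a$junctions$right, b[19])
  expect_equal(a$junctions$boundary_status, "exon_snap")
})

test_that("genomic-mode split placement matches the exhaustive one-gap oracle", {
  p <- align_params(k = 9L, min_terminal = 9L, min_span = 9L, min_aligned = 9L)
  n_checked <- 0L
  for (trial in 1:40) {
    ref <- rand_dna(300L, seed = 100 + trial)
    pieces <- withr::with_seed(200 + trial, {
      a <- sample(1:60, 1L)                 # prefix start (1-based)
      plen <- sample(15:30, 1L)
      gap <- sample(60:120, 1L)
      slen <- sample(15:30, 1L)
      c(a = a, plen = plen, gap = gap, slen = slen)
    })
    b0 <- pieces["a"] + pieces["plen"] + pieces["gap"]   # suffix start
    if (b0 + pieces["slen"] - 1L > 300L) next
    read <- paste0(
      substr(ref, pieces["a"], pieces["a"] + pieces["plen"] - 1L),
      substr(ref, b0, b0 + pieces["slen"] - 1L))
    a <- align_reads(read, ref, params = p, mode = "genomic")
    oracle <- one_gap_placements(read, ref, min_gap = 50L)
    if (a$status != "mapped" || !nzchar(a$junctions)) next
    n_checked <- n_checked + 1L
    ju <- parse_junctions(a$junctions)
    expect_equal(nrow(ju), 1L)
    # the aligner's placement is one of the mismatch-free placements...
    expect_true(any(oracle$left == ju$left & oracle$right == ju$right))
    # ...and is the left-aligned one: no mismatch-free placement with the
    # same gap length has a smaller left edge
    same_gap <- oracle[oracle$right - oracle$left == ju$right - ju$left, ]
    expect_equal(ju$left, min(same_gap$left))
  }
  expect_gt(n_checked, 20L)
})

test_that("alignment is deterministic and read-order invariant", {
  co <- preset_cohort()
  ref <- co$reference
  reads <- co$amplicon$proband1$reads[1:400, ]
  cdna <- make_isoform(ref$model, ref$seq)
  a1 <- align_reads(reads, cdna, ref$model, mode = "cdna")
  a2 <- align_reads(reads, cdna, ref$model, mode = "cdna")
  expect_identical(a1, a2)
  perm <- withr::with_seed(1, sample(nrow(reads)))
  a3 <- align_reads(reads[perm, ], cdna, ref$model, mode = "cdna")
  expect_identical(a1[perm, ], a3)
})

test_that("mismatch-saturated reads are rejected by max_mismatch_frac", {
  seq <- rand_dna(1000L, seed = 9)
  read <- substr(seq, 101, 250)
  mutated <- read
  for (i in seq(5, 150, by = 10)) {
    substr(mutated, i, i) <- "N"   # 15 mismatches in 150 nt = 10% > 5%
  }
  a <- align_reads(c(read, mutated), seq, mode = "genomic")
  expect_equal(a$status, c("mapped", "unmapped"))
})

test_that("SAM output round-trips through a standard parser", {
  ref <- preset_ref()
  m <- ref$model
  cdna <- make_isoform(m, ref$seq)
  iso <- make_isoform(m, ref$seq, 19L)
  jpos <- sum(m$exons$length[1:18])
  reads <- tibble::tibble(
    read_id = c("plain", "split", "clipped"),
    mate = 1L,
    seq = c(substr(cdna, 201, 350),
            substr(iso, jpos - 70L, jpos + 71L),
            paste0("CCCCCCCCCC", substr(cdna, 1001, 1140))))
  aln <- align_reads(reads, cdna, m, mode = "cdna", keep_seq = TRUE)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "t.sam")
  write_sam(aln, "cdna", nchar(cdna), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE)
  ga <- GenomicAlignments::readGAlignments(bam, use.names = TRUE)
  expect_setequal(names(ga), reads$read_id)
  # POS (1-based leftmost reference) matches the aligner's blocks
  ord <- match(aln$read_id, names(ga))
  expect_equal(GenomicAlignments::start(ga)[ord],
               purrr::map_int(aln$blocks, ~ parse_blocks(.x)$r0[1]) + 1L)
  # the split read's N gap reproduces the junction
  ju <- parse_junctions(aln$junctions[aln$read_id == "split"])
  gaps <- GenomicAlignments::junctions(ga)[["split"]]
  expect_equal(GenomicRanges::start(gaps), ju$left + 1L)
  expect_equal(GenomicRanges::end(gaps), ju$right)
  # the clipped read's CIGAR records the soft clip (the aligner may absorb a
  # junk base that happens to match the reference, so compare to clip_left)
  clip <- aln$clip_left[aln$read_id == "clipped"]
  expect_gte(clip, 9L)
  expect_match(GenomicAlignments::cigar(ga)[names(ga) == "clipped"],
               sprintf("^%dS", clip))
})

test_that("write_sam and parent_of_origin demand kept sequences", {
  ref <- preset_ref()
  a <- align_reads(substr(ref$seq, 3001, 3150), ref$seq, mode = "genomic")
  expect_error(write_sam(a, "x", nchar(ref$seq), tempfile()), "oseq")
})
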