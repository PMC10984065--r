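test_that("classify_junction covers its decision table", {
  m <- preset_ref()$model
  b <- cdna_boundaries(m)
  # single-exon and multi-exon skips
  expect_equal(classify_junction(b[18], b[19], m)$class, "exon_skip")
  expect_equal(classify_junction(b[18], b[19], m)$label, "Δ19")
  expect_equal(classify_junction(b[18], b[22], m)$label, "Δ19-22")
  expect_equal(classify_junction(b[17], b[19], m)$label, "Δ18-19")
  # canonical splice: zero-length gap at a boundary
  expect_equal(classify_junction(b[18], b[18], m)$class, "canonical_splice")
  # off-boundary edges are noncanonical
  expect_equal(classify_junction(b[18] + 3L, b[19], m)$class, "noncanonical")
  expect_equal(classify_junction(b[18], b[19] - 2L, m)$class, "noncanonical")
  expect_equal(classify_junction(100L, 100L, m)$class, "noncanonical")
  # reversed edges never classify
  expect_equal(classify_junction(b[19], b[18], m)$class, "noncanonical")
  # tolerance rescues near-boundary edges
  expect_equal(classify_junction(b[18] + 2L, b[19], m, tol = 2L)$class,
               "exon_skip")
  # vectorized
  got <- classify_junction(c(b[18], b[18]), c(b[19], b[22]), m)
  expect_equal(got$label, c("Δ19", "Δ19-22"))
})

test_that("assign_reads labels each read class correctly", {
  ref <- preset_ref()
  m <- ref$model
  cdna <- make_isoform(m, ref$seq)
  iso <- make_isoform(m, ref$seq, 19L)
  jpos <- sum(m$exons$length[1:18])
  ce <- cumsum(m$exons$length)
  reads <- tibble::tibble(
    read_id = c("skip", "canon", "inside", "junk"),
    mate = 1L,
    seq = c(substr(iso, jpos - 70L, jpos + 71L),     # spans the Δ19 junction
            substr(cdna, 1001, 1150),                 # spans boundaries
            substr(cdna, ce[32] + 10L, ce[32] + 109L),# inside terminal exon
            rand_dna(150L, seed = 77)))
  a <- assign_reads(align_reads(reads, cdna, m, mode = "cdna"), m)
  got <- setNames(a$assignment, a$read_id)
  expect_equal(unname(got["skip"]), "Δ19")
  expect_equal(unname(got["canon"]), "canonical_support")
  expect_equal(unname(got["inside"]), "uninformative")
  expect_equal(unname(got["junk"]), "unmapped")
})

test_that("quantify_subject matches a hand-counted fixture", {
  ref <- preset_ref()
  m <- ref$model
  cdna <- make_isoform(m, ref$seq)
  iso <- make_isoform(m, ref$seq, 19L)
  b <- cdna_boundaries(m)
  jpos <- sum(m$exons$length[1:18])          # = b[18]
  ce <- cumsum(m$exons$length)
  # 30 canonical reads spanning boundary 18, 10 Δ19 junction reads,
  # 20 reads inside the terminal exon (uninformative)
  canon <- substring(cdna, b[18] - 80L + seq_len(30L), b[18] + 70L + seq_len(30L))
  skip <- substring(iso, jpos - 80L + seq_len(10L), jpos + 70L + seq_len(10L))
  inert <- substring(cdna, ce[32] + seq_len(20L), ce[32] + 99L + seq_len(20L))
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:60), mate = 1L,
    seq = c(canon, skip, inert))
  aln <- align_reads(reads, cdna, m, mode = "cdna")
  q <- quantify_subject(aln, m, subject_id = "fx")
  expect_equal(nrow(q), 1L)
  expect_equal(q$label, "Δ19")
  expect_equal(q$supporting_reads, 10L)
  expect_equal(q$informative_reads, 40L)     # 30 spanning + 10 junction
  expect_equal(q$fraction, 0.25)
  expect_equal(q$fraction_total, 10 / 60)
  expect_equal(q$frame, "in_frame")
  expect_true(q$reported)
})

test_that("signatures below the report threshold are retained, not reported", {
  ref <- preset_ref()
  m <- ref$model
  cdna <- make_isoform(m, ref$seq)
  iso <- make_isoform(m, ref$seq, 19L)
  b <- cdna_boundaries(m)
  jpos <- sum(m$exons$length[1:18])
  offs <- rep(1:40, length.out = 97L)   # all spans keep >= 12 nt flanks
  canon <- substring(cdna, b[18] - 90L + offs, b[18] + 60L + offs)
  skip <- substring(iso, jpos - 80L + seq_len(3L), jpos + 70L + seq_len(3L))
  reads <- tibble::tibble(read_id = sprintf("r%03d", 1:100), mate = 1L,
                          seq = c(canon, skip))
  q <- quantify_subject(align_reads(reads, cdna, m, mode = "cdna"), m)
  expect_equal(q$fraction, 0.03)
  expect_false(q$reported)                   # 3% < 5% report threshold
  expect_equal(nrow(q), 1L)                  # but still in the full table
})

test_that("quantification is invariant to read order and duplication-consistent", {
  co <- preset_cohort()
  ref <- co$reference
  cdna <- make_isoform(ref$model, ref$seq)
  reads <- co$amplicon$positive1$reads
  aln <- align_reads(reads, cdna, ref$model, mode = "cdna")
  q1 <- quantify_subject(aln, ref$model)
  perm <- withr::with_seed(2, sample(nrow(reads)))
  q2 <- quantify_subject(align_reads(reads[perm, ], cdna, ref$model,
                                     mode = "cdna"), ref$model)
  expect_equal(dplyr::arrange(q1, label), dplyr::arrange(q2, label))
  # doubling every read doubles the counts and keeps fractions fixed
  doubled <- dplyr::bind_rows(
    reads, dplyr::mutate(reads, read_id = paste0(read_id, "_dup")))
  q3 <- quantify_subject(align_reads(doubled, cdna, ref$model, mode = "cdna"),
                         ref$model)
  expect_equal(q3$supporting_reads[order(q3$label)],
               2L * q1$supporting_reads[order(q1$label)])
  expect_equal(q3$fraction[order(q3$label)], q1$fraction[order(q1$label)])
})

test_that("a 50/50 mixture is recovered within 4 binomial sd at n = 10,000", {
  ref <- preset_ref()
  m <- ref$model
  iso <- c(canonical = make_isoform(m, ref$seq),
           "Δ19" = make_isoform(m, ref$seq, 19L))
  n <- 10000L
  s <- simulate_amplicon_reads(iso, c(canonical = 0.5, "Δ19" = 0.5), n,
                               seed = 8, base_error_rate = 0.002)
  aln <- align_reads(s$reads, iso[["canonical"]], m, mode = "cdna")
  q <- quantify_subject(aln, m)
  # the informative-read fraction estimates the mixture proportion; its
  # sampling noise is binomial in the informative count
  expect_false(q$undefined[q$label == "Δ19"])
  ninf <- q$informative_reads[q$label == "Δ19"]
  expect_lt(abs(q$fraction[q$label == "Δ19"] - 0.5), 4 * sqrt(0.25 / ninf))
})

test_that("flag_candidates applies every filter in its definition", {
  tm <- toy_model()
  cfg <- quant_config(regulatory_exons = 3L)
  mk <- function(sid, label, fraction) {
    fr <- skip_frame(tm, unclass(parse_skip_label(label)))
    tibble::tibble(subject_id = sid, label = label, frame = fr$frame,
                   skipped_nt = fr$skipped_nt,
                   supporting_reads = round(fraction * 100), informative_reads = 100L,
                   fraction = fraction, fraction_total = fraction,
                   undefined = FALSE, reported = fraction >= 0.05)
  }
  roster <- tibble::tibble(
    subject_id = c("p1", "p2", "p3", "p4", "p5", "hc1"),
    role = c(rep("proband", 5), "healthy_control"))
  quants <- dplyr::bind_rows(
    mk("p1", "Δ3", 0.20),   # in frame, regulatory, absent in controls -> YES
    mk("p2", "Δ2", 0.20),   # frameshift -> no
    mk("p3", "Δ3", 0.08),   # below flag threshold -> no
    mk("p4", "Δ4", 0.50),   # outside the regulatory exons -> no
    mk("p5", "Δ2-3", 0.20)) # regulatory but frameshift -> no
  scr <- flag_candidates(quants, roster, tm, cfg)
  expect_equal(scr$candidates$subject_id, "p1")
  # frame sanity of the toy fixtures
  expect_equal(unique(quants$frame[quants$label == "Δ3"]), "in_frame")
  expect_equal(unique(quants$frame[quants$label == "Δ2"]), "frameshift")
  # the same signature at >= 5% in a healthy control kills the candidate
  quants2 <- dplyr::bind_rows(quants, mk("hc1", "Δ3", 0.06))
  scr2 <- flag_candidates(quants2, roster, tm, cfg)
  expect_equal(nrow(scr2$candidates), 0L)
  # ... but a control fraction under the absence threshold does not
  quants3 <- dplyr::bind_rows(quants, mk("hc1", "Δ3", 0.03))
  scr3 <- flag_candidates(quants3, roster, tm, cfg)
  expect_equal(scr3$candidates$subject_id, "p1")
  # no healthy controls: novelty filter off, with a warning
  expect_warning(
    flag_candidates(quants, roster[roster$role == "proband", ], tm, cfg),
    "healthy controls")
})

test_that("raising the flag threshold never adds candidates", {
  co <- preset_cohort()
  ref <- co$reference
  cdna <- make_isoform(ref$model, ref$seq)
  quants <- purrr::map(co$config$roster$subject_id, function(sid) {
    aln <- align_reads(co$amplicon[[sid]]$reads, cdna, ref$model, mode = "cdna")
    quantify_subject(aln, ref$model, subject_id = sid)
  }) |> purrr::list_rbind()
  prev <- NULL
  for (thr in c(0.10, 0.20, 0.35, 0.60)) {
    cfg <- quant_config(flag_threshold = max(thr, 0.05),
                        high_proportion_threshold = max(thr, 0.30))
    scr <- flag_candidates(quants, co$config$roster, ref$model, cfg)
    keys <- paste(scr$candidates$subject_id, scr$candidates$label)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("cohort_screen tidiers and plot methods work", {
  co <- preset_cohort()
  ref <- co$reference
  cdna <- make_isoform(ref$model, ref$seq)
  quants <- purrr::map(co$config$roster$subject_id, function(sid) {
    aln <- align_reads(co$amplicon[[sid]]$reads, cdna, ref$model, mode = "cdna")
    quantify_subject(aln, ref$model, subject_id = sid)
  }) |> purrr::list_rbind()
  scr <- flag_candidates(quants, co$config$roster, ref$model)
  td <- tidy(scr)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("subject_id", "label", "fraction", "candidate") %in%
                    names(td)))
  gl <- glance(scr)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_subjects, 14L)
  expect_equal(gl$n_candidate_probands, 2L)
  expect_equal(gl$n_candidate_controls, 0L)
  p <- autoplot(scr)
  expect_s3_class(p, "ggplot")
  expect_output(print(scr), "cohort_screen")
})

test_that("quant_config rejects inconsistent thresholds", {
  expect_error(quant_config(report_threshold = 0.2, flag_threshold = 0.1),
               "report")
  expect_error(quant_config(high_proportion_threshold = 1.2), "report")
})

test_that("fraction bins follow the configured thresholds", {
  expect_equal(fraction_bin_labels(quant_config()),
               c("<5%", "5%-10%", "10%-30%", ">30%"))
  cfg <- quant_config(report_threshold = 0.02, flag_threshold = 0.15,
                      high_proportion_threshold = 0.4)
  expect_equal(fraction_bin_labels(cfg), c("<2%", "2%-15%", "15%-40%", ">40%"))
})
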