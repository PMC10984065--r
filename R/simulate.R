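#' Simulation configuration
#'
#' Bundles the locus geometry, sequencing parameters and cohort roster used
#' by the synthetic-data generator. Defaults emulate the study conditions of
#' a gene-specific cDNA screen: a PLCG2-like 33-exon locus, 150 bp paired-end
#' amplicon reads, and a cohort of nine probands, three healthy controls and
#' two positive controls.
#'
#' @param seed Integer seed controlling every random draw.
#' @param exon_lengths,intron_lengths Integer vectors of exon / intron
#'   lengths (nt); `length(intron_lengths) == length(exon_lengths) - 1`.
#' @param utr5_len,utr3_len 5'/3' UTR lengths (nt), contained in the first /
#'   last exon.
#' @param flank_len Genomic flank on each side of the gene (nt).
#' @param read_len Read length (nt); default 150.
#' @param paired Paired-end flag.
#' @param base_error_rate Per-base substitution error probability.
#' @param amplicon_depth Read pairs per subject for the cDNA screen.
#' @param wgs_depth Mean genomic coverage for trio sequencing.
#' @param insert_mean,insert_sd Fragment-length model (nt).
#' @param roster Tibble with columns `subject_id` and `role`
#'   (`proband` / `healthy_control` / `positive_control`).
#' @param isoform_mixtures Named list (by `subject_id`) of named numeric
#'   vectors: isoform label (`"canonical"` or a skip label such as
#'   `"Δ19-22"`) to mixture fraction; each vector must sum to 1.
#' @param background_skips Named numeric vector of low-level skip fractions
#'   added to every lesion-free subject (default none), reflecting common
#'   non-causal alternative splicing.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       exon_lengths = plcg2_like_exon_lengths(),
                       intron_lengths = plcg2_like_intron_lengths(),
                       utr5_len = 50L, utr3_len = 400L, flank_len = 2000L,
                       read_len = 150L, paired = TRUE,
                       base_error_rate = 0.002,
                       amplicon_depth = 2000L, wgs_depth = 30,
                       insert_mean = 350, insert_sd = 50,
                       roster = default_roster(),
                       isoform_mixtures = NULL,
                       background_skips = NULL) {
  seed <- assert_scalar_int(seed, "seed")
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  if (any(exon_lengths <= 0L)) abort("exon lengths must be positive")
  if (length(intron_lengths) != length(exon_lengths) - 1L) {
    abort("need exactly one intron length per internal junction")
  }
  if (any(intron_lengths < 4L)) abort("introns must be >= 4 nt")
  if (utr5_len >= exon_lengths[1] || utr3_len >= exon_lengths[length(exon_lengths)]) {
    abort("UTRs must fit inside the terminal exons")
  }
  cfg <- list(seed = seed, exon_lengths = exon_lengths,
              intron_lengths = intron_lengths,
              utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
              flank_len = as.integer(flank_len),
              read_len = as.integer(read_len), paired = isTRUE(paired),
              base_error_rate = base_error_rate,
              amplicon_depth = as.integer(amplicon_depth),
              wgs_depth = wgs_depth,
              insert_mean = insert_mean, insert_sd = insert_sd,
              roster = as_tibble(roster),
              isoform_mixtures = isoform_mixtures,
              background_skips = background_skips)
  if (is.null(cfg$isoform_mixtures)) {
    cfg$isoform_mixtures <- default_mixtures(cfg$roster, background_skips)
  }
  for (sid in names(cfg$isoform_mixtures)) {
    mx <- cfg$isoform_mixtures[[sid]]
    if (abs(sum(mx) - 1) > 1e-9) {
      abort(sprintf("mixture fractions for '%s' must sum to 1", sid))
    }
  }
  structure(cfg, class = "sim_config")
}

#' PLCG2-like locus geometry
#'
#' A synthetic 33-exon gene whose cumulative coding length through exon 19 is
#' 2298 nt (so a position 5 nt past the exon-19 donor annotates as c.2298+5)
#' and whose exons 18-22 give in-frame skips for Δ19, Δ18-19, Δ19-22 and
#' Δ20-22. Introns 18-22 are widened so a 14,197 nt deletion fits from
#' intron 18 to intron 22. The sequence content is random: the real gene's
#' sequence is not reproduced.
#'
#' @return Integer vector of lengths (nt).
#' @export
plcg2_like_exon_lengths <- function() {
  as.integer(c(146, rep(120, 17), 162, rep(120, 13), 520))
}

#' @rdname plcg2_like_exon_lengths
#' @export
plcg2_like_intron_lengths <- function() {
  as.integer(c(rep(300, 17), 2000, 3500, 3500, 3500, 2500, rep(300, 10)))
}

#' Default cohort roster: nine probands, three healthy controls, two positive
#' controls
#' @return Tibble with `subject_id` and `role`.
#' @export
default_roster <- function() {
  tibble(
    subject_id = c(paste0("proband", 1:9), paste0("control", 1:3),
                   paste0("positive", 1:2)),
    role = c(rep("proband", 9), rep("healthy_control", 3),
             rep("positive_control", 2)))
}

# Default per-subject isoform mixtures. Proband 1 carries a heterozygous
# splice-site SNV whose mutant allele emits Δ18-19 : Δ19 : Δ19-22 at 5:3:2
# (splicing-outcome ratios are model parameters, not measured quantities);
# proband 2 carries a heterozygous genomic Δ19-22 deletion with equal allelic
# expression. Positive controls carry the published Δ19 and Δ20-22 isoforms.
default_mixtures <- function(roster, background_skips = NULL) {
  base <- c(canonical = 1)
  if (!is.null(background_skips)) {
    stopifnot(sum(background_skips) < 1)
    base <- c(canonical = 1 - sum(background_skips), background_skips)
  }
  mx <- setNames(rep(list(base), nrow(roster)), roster$subject_id)
  mut <- 0.5 * c(0.5, 0.3, 0.2)
  mx[["proband1"]] <- c(canonical = 0.5,
                        setNames(mut, c("Δ18-19", "Δ19", "Δ19-22")))
  mx[["proband2"]] <- c(canonical = 0.5, "Δ19-22" = 0.5)
  mx[["positive1"]] <- c(canonical = 0.5, "Δ19" = 0.5)
  mx[["positive2"]] <- c(canonical = 0.5, "Δ20-22" = 0.5)
  mx
}

#' Build the synthetic genomic reference and gene model
#'
#' Deterministic for a fixed seed: random flank/exon/intron sequence with
#' canonical GT/AG dinucleotides written at every donor/acceptor.
#'
#' @param config A [sim_config()].
#' @return List with `seq` (character reference sequence) and `model`
#'   (a [gene_model()]).
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    el <- config$exon_lengths
    il <- config$intron_lengths
    n <- length(el)
    pieces <- character(2 * n + 1)
    pieces[1] <- random_dna(config$flank_len)
    for (i in seq_len(n)) {
      pieces[2 * i] <- random_dna(el[i])
      if (i < n) {
        intr <- random_dna(il[i])
        substr(intr, 1, 2) <- "GT"
        substr(intr, il[i] - 1, il[i]) <- "AG"
        pieces[2 * i + 1] <- intr
      }
    }
    pieces[2 * n + 1] <- random_dna(config$flank_len)
    seq <- paste(pieces, collapse = "")
    starts <- config$flank_len +
      c(0L, cumsum(el[-n] + il))
    model <- gene_model(
      tibble(start = starts, end = starts + el),
      chrom = "PLCG2_locus", strand = "+",
      cds_start_offset = config$utr5_len,
      cds_length = sum(el) - config$utr5_len - config$utr3_len,
      gene_id = "PLCG2_like", transcript_id = "TX_synthetic")
    list(seq = seq, model = model)
  })
}

#' Spliced isoform sequence for a skip signature
#'
#' Concatenates the retained exons; an empty (NULL) signature returns the
#' canonical spliced transcript.
#'
#' @param model A [gene_model()].
#' @param seq Genomic reference sequence (character scalar).
#' @param signature A [skip_signature()], integer vector of skipped exons, or
#'   `NULL` for the canonical transcript.
#' @return cDNA sequence (character scalar).
#' @export
make_isoform <- function(model, seq, signature = NULL) {
  ex <- model$exons
  keep <- ex$exon
  if (!is.null(signature)) {
    sk <- as.integer(unclass(signature))
    if (length(sk) == 0L || !all(sk %in% ex$exon)) {
      abort("invalid skip signature for this model")
    }
    keep <- setdiff(keep, sk)
  }
  paste(substring(seq, ex$start[keep] + 1L, ex$end[keep]), collapse = "")
}

# Isoform sequence for a mixture label ("canonical" or a skip label).
isoform_for_label <- function(model, seq, label) {
  if (identical(label, "canonical")) make_isoform(model, seq, NULL)
  else make_isoform(model, seq, parse_skip_label(label))
}

# Inject per-base substitution errors at `rate` into equal-length reads.
inject_errors <- function(seqs, rate, read_len) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  total <- length(seqs) * read_len
  nerr <- rbinom(1L, total, rate)
  if (nerr == 0L) return(seqs)
  idx <- sample.int(total, nerr)
  rd <- (idx - 1L) %/% read_len + 1L
  off <- (idx - 1L) %% read_len + 1L
  cur <- substring(seqs[rd], off, off)
  repl <- other_base(cur)
  for (t in seq_len(nerr)) {
    substr(seqs[rd[t]], off[t], off[t]) <- repl[t]
  }
  seqs
}

#' Simulate paired amplicon reads from an isoform mixture
#'
#' Emulates full-length cDNA amplicon sequencing: per read pair an isoform is
#' chosen by the mixture weights, a fragment is placed uniformly along it,
#' and 150 bp (by default) paired reads are taken from the fragment ends with
#' independent per-base substitution errors. Quality strings are constant
#' Q30.
#'
#' @param isoforms Named character vector: isoform label to cDNA sequence.
#' @param mixture Named numeric vector of mixture fractions (sum 1) over
#'   `names(isoforms)`.
#' @param n_pairs Number of read pairs (> 0).
#' @param seed Integer seed.
#' @param read_len,insert_mean,insert_sd,base_error_rate Sequencing model.
#' @param subject_id Label recorded in read ids and truth rows.
#' @return List with `reads` (tibble: `read_id`, `mate`, `seq`) and `truth`
#'   (tibble: `read_id`, `subject_id`, `isoform` of origin).
#' @export
simulate_amplicon_reads <- function(isoforms, mixture, n_pairs, seed,
                                    read_len = 150L, insert_mean = 350,
                                    insert_sd = 50, base_error_rate = 0.002,
                                    subject_id = "S1") {
  if (n_pairs <= 0) abort("n_pairs must be positive")
  if (abs(sum(mixture) - 1) > 1e-9) abort("mixture fractions must sum to 1")
  if (!all(names(mixture) %in% names(isoforms))) {
    abort("every mixture component needs an isoform sequence")
  }
  iso_len <- nchar(isoforms)
  if (read_len > min(iso_len[names(mixture)[mixture > 0]])) {
    abort("read_len exceeds the shortest isoform in the mixture")
  }
  withr::with_seed(seed, {
    lab <- sample(names(mixture), n_pairs, replace = TRUE, prob = mixture)
    len <- iso_len[lab]
    fl <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)), read_len), len)
    start <- floor(runif(n_pairs) * (len - fl + 1))  # 0-based
    src <- isoforms[lab]
    r1 <- substring(src, start + 1L, start + read_len)
    r2 <- revcomp(substring(src, start + fl - read_len + 1L, start + fl))
    r1 <- inject_errors(r1, base_error_rate, read_len)
    r2 <- inject_errors(r2, base_error_rate, read_len)
    ids <- sprintf("%s_read%06d", subject_id, seq_len(n_pairs))
    list(
      reads = tibble(
        read_id = rep(ids, 2L),
        mate = rep(c(1L, 2L), each = n_pairs),
        seq = c(r1, r2)),
      truth = tibble(read_id = ids, subject_id = subject_id, isoform = lab))
  })
}

#' Simulate trio genomic read pairs over a locus with planted lesions
#'
#' Each member's two haplotypes are built from the reference: a haplotype
#' carrying the deletion lacks the deleted interval; a haplotype carrying the
#' SNV has the alternate base. Heterozygous carriers draw fragments from both
#' haplotypes with equal probability; fragment lengths are
#' Normal(insert_mean, insert_sd) truncated below at 2 x read_len.
#'
#' @param seq Genomic reference sequence.
#' @param model A [gene_model()] (used for validation only).
#' @param deletion `NULL` or list/row with `start`, `end` (1-based inclusive).
#' @param snv `NULL` or list with `pos` (1-based) and `alt`.
#' @param genotypes List with elements `deletion` and/or `snv`, each a named
#'   character vector over members (`"0/0"`, `"0/1"`, `"1/1"`).
#' @param members Character vector of member names (default child, mother,
#'   father).
#' @param informative_sites `NULL` or tibble with `pos`, `allele`, `parent`:
#'   marker alleles planted on the child's lesion haplotype and on one
#'   haplotype of the named parent (used for parent-of-origin analysis).
#' @param depth Mean coverage per member.
#' @param seed Integer seed.
#' @param read_len,insert_mean,insert_sd,base_error_rate Sequencing model.
#' @return List with `members` (named list of read tibbles as in
#'   [simulate_amplicon_reads()]) and `truth` (lesion coordinates, genotypes,
#'   per-fragment haplotype of origin).
#' @export
simulate_trio_wgs <- function(seq, model, deletion = NULL, snv = NULL,
                              genotypes = list(),
                              members = c("child", "mother", "father"),
                              informative_sites = NULL,
                              depth = 30, seed = 1L, read_len = 150L,
                              insert_mean = 350, insert_sd = 50,
                              base_error_rate = 0.002) {
  L <- nchar(seq)
  if (!is.null(deletion)) {
    if (deletion$start < 1 || deletion$end > L || deletion$end <= deletion$start) {
      abort("deletion outside the reference")
    }
  }
  if (!is.null(snv) && (snv$pos < 1 || snv$pos > L)) abort("SNV outside the reference")
  gt_of <- function(what, m) {
    g <- genotypes[[what]]
    if (is.null(g) || is.na(g[m] %||% NA)) "0/0" else unname(g[m])
  }
  ok_gt <- c("0/0", "0/1", "1/1")
  for (w in names(genotypes)) {
    if (!all(genotypes[[w]] %in% ok_gt)) abort("genotypes must be 0/0, 0/1 or 1/1")
  }

  build_hap <- function(member, hap_idx) {
    # hap 2 carries a het lesion; both haps carry a hom lesion
    s <- seq
    carries <- function(what) {
      g <- gt_of(what, member)
      g == "1/1" || (g == "0/1" && hap_idx == 2L)
    }
    if (!is.null(informative_sites)) {
      for (r in seq_len(nrow(informative_sites))) {
        site <- informative_sites[r, ]
        plant <- (member == "child" && carries("deletion")) ||
          (member == site$parent && hap_idx == 2L)
        if (plant) s <- replace_bases(s, site$pos, site$allele)
      }
    }
    if (!is.null(snv) && carries("snv")) s <- replace_bases(s, snv$pos, snv$alt)
    if (!is.null(deletion) && carries("deletion")) {
      s <- paste0(substring(s, 1L, deletion$start - 1L),
                  substring(s, deletion$end + 1L, nchar(s)))
    }
    s
  }

  withr::with_seed(seed, {
    out <- list()
    truth_frag <- list()
    for (m in members) {
      haps <- c(build_hap(m, 1L), build_hap(m, 2L))
      n_frag <- round(depth * L / (2 * read_len))
      hap_idx <- sample(1:2, n_frag, replace = TRUE)
      hl <- nchar(haps)[hap_idx]
      fl <- pmax(round(rnorm(n_frag, insert_mean, insert_sd)), 2L * read_len)
      fl <- pmin(fl, hl)
      start <- floor(runif(n_frag) * (hl - fl + 1))
      src <- haps[hap_idx]
      r1 <- substring(src, start + 1L, start + read_len)
      r2 <- revcomp(substring(src, start + fl - read_len + 1L, start + fl))
      r1 <- inject_errors(r1, base_error_rate, read_len)
      r2 <- inject_errors(r2, base_error_rate, read_len)
      ids <- sprintf("%s_frag%06d", m, seq_len(n_frag))
      out[[m]] <- tibble(read_id = rep(ids, 2L),
                         mate = rep(c(1L, 2L), each = n_frag),
                         seq = c(r1, r2))
      truth_frag[[m]] <- tibble(member = m, read_id = ids,
                                hap = hap_idx, frag_start = start + 1L,
                                frag_len = fl)
    }
    list(
      members = out,
      truth = list(
        deletion = deletion, snv = snv,
        genotypes = lapply(setNames(members, members), function(m) {
          c(deletion = gt_of("deletion", m), snv = gt_of("snv", m))
        }),
        informative_sites = informative_sites,
        fragments = bind_rows(truth_frag)))
  })
}

#' Coordinates of the preset causal lesions on a built reference
#'
#' The deletion runs from 1,000 nt into intron 18 for 14,197 nt, ending in
#' intron 22 (so exons 19-22 are deleted); the splice SNV sits 5 nt past the
#' exon-19 donor (c.2298+5).
#'
#' @param model A [gene_model()] built from the preset geometry.
#' @return List with `deletion` (`start`, `end`, 1-based inclusive) and `snv`
#'   (`pos`, `alt`).
#' @export
preset_lesions <- function(model) {
  ex <- model$exons
  s0 <- ex$end[18] + 1000L            # 0-based first deleted base
  e0 <- s0 + 14197L                   # 0-based one-past-last deleted base
  list(deletion = list(start = s0 + 1L, end = e0),
       snv = list(pos = ex$end[19] + 5L, alt = "T"))
}

# Make the planted lesions unambiguous on the reference: remove breakpoint
# microhomology (so the deletion's left-aligned breakpoints equal the planted
# ones) and write the donor-consensus base 'G' at the SNV site so ref != alt.
enforce_lesion_context <- function(seq, lesions, window = 8L) {
  del <- lesions$deletion
  s0 <- del$start - 1L   # 0-based
  e0 <- del$end          # 0-based one-past-last
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  pick_diff <- function(avoid) setdiff(c("A", "C", "G", "T"), avoid)[1]
  for (i in 0:(window - 1L)) {
    if (v[s0 + 1L + i] == v[e0 + 1L + i]) {          # right-extension homology
      v[s0 + 1L + i] <- pick_diff(c(v[e0 + 1L + i], v[s0 + 1L + i]))
    }
    if (v[e0 - i] == v[s0 - i]) {                    # left-extension homology
      v[e0 - i] <- pick_diff(c(v[s0 - i], v[e0 - i]))
    }
  }
  v[lesions$snv$pos] <- "G"
  paste(v, collapse = "")
}

#' Simulate a repeat-element track
#'
#' Random background elements over the reference, optionally with Alu
#' elements planted at given positions (to reconstruct an Alu-mediated
#' deletion) or an exclusion zone around breakpoints (to reconstruct a
#' repeat-free case).
#'
#' @param ref_len Reference length (nt).
#' @param seed Integer seed.
#' @param n_background Number of random background elements.
#' @param plant_alu Optional integer vector of 1-based positions; a ~300 nt
#'   same-strand Alu element is centred on each.
#' @param exclude Optional 1-based positions; no element is placed within
#'   `exclude_pad` of them.
#' @param exclude_pad Exclusion half-width (nt).
#' @return Tibble with `start`, `end` (1-based inclusive), `family`, `strand`.
#' @export
simulate_repeat_track <- function(ref_len, seed = 1L, n_background = 25L,
                                  plant_alu = NULL, exclude = NULL,
                                  exclude_pad = 500L) {
  withr::with_seed(seed, {
    fam <- sample(c("Alu", "other_SINE", "LINE", "LTR", "other"),
                  n_background, replace = TRUE,
                  prob = c(.4, .15, .25, .1, .1))
    len <- ifelse(fam == "LINE", 1500L, 300L)
    start <- floor(runif(n_background) * (ref_len - len)) + 1L
    tr <- tibble(start = as.integer(start),
                 end = as.integer(start + len - 1L),
                 family = fam,
                 strand = sample(c("+", "-"), n_background, replace = TRUE))
    if (!is.null(exclude)) {
      keep <- rep(TRUE, nrow(tr))
      for (p in exclude) {
        keep <- keep & (tr$end < p - exclude_pad | tr$start > p + exclude_pad)
      }
      tr <- tr[keep, ]
    }
    if (!is.null(plant_alu)) {
      tr <- bind_rows(tr, tibble(
        start = as.integer(plant_alu - 150L),
        end = as.integer(plant_alu + 149L),
        family = "Alu", strand = "+"))
    }
    arrange(tr, .data$start)
  })
}

#' Simulate the full preset cohort
#'
#' Builds the reference, plants the two causal lesions (proband 1: an
#' inherited heterozygous splice-site SNV at c.2298+5 whose mutant allele
#' emits Δ18-19, Δ19 and Δ19-22 transcripts; proband 2: a de novo
#' heterozygous 14,197 nt genomic deletion of exons 19-22 on the maternally
#' transmitted chromosome), simulates amplicon reads for all 14 subjects and
#' trio genomic reads for both probands' families, and returns
#' machine-readable truth.
#'
#' @param config A [sim_config()]; `config$seed` drives everything.
#' @return List with `reference` (`seq`, `model`), `lesions`, `amplicon`
#'   (per-subject reads + truth), `trios` (per-proband
#'   [simulate_trio_wgs()] output), `repeat_track`, and `truth` (roster with
#'   planted mixtures and lesion assignments).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ref <- build_reference(config)
  lesions <- preset_lesions(ref$model)
  ref$seq <- enforce_lesion_context(ref$seq, lesions)

  labels <- unique(unlist(lapply(config$isoform_mixtures, names)))
  isoforms <- setNames(
    vapply(labels, function(l) isoform_for_label(ref$model, ref$seq, l), ""),
    labels)

  amplicon <- list()
  for (i in seq_len(nrow(config$roster))) {
    sid <- config$roster$subject_id[i]
    amplicon[[sid]] <- simulate_amplicon_reads(
      isoforms, config$isoform_mixtures[[sid]],
      n_pairs = config$amplicon_depth,
      seed = config$seed + 1000L + i,
      read_len = config$read_len, insert_mean = config$insert_mean,
      insert_sd = config$insert_sd,
      base_error_rate = config$base_error_rate, subject_id = sid)
  }

  # proband 1 trio: inherited splice SNV (multigenerational dominant family;
  # the transmitting parent is set to the mother as a simulation choice)
  trio1 <- simulate_trio_wgs(
    ref$seq, ref$model, deletion = NULL, snv = lesions$snv,
    genotypes = list(snv = c(child = "0/1", mother = "0/1", father = "0/0")),
    depth = config$wgs_depth, seed = config$seed + 211L,
    read_len = config$read_len, insert_mean = config$insert_mean,
    insert_sd = config$insert_sd, base_error_rate = config$base_error_rate)

  # proband 2 trio: de novo deletion on the maternal chromosome, with
  # Mendelian-informative flanking het sites for parent-of-origin analysis
  sites <- maternal_marker_sites(ref$seq, lesions$deletion,
                                 seed = config$seed + 97L)
  trio2 <- simulate_trio_wgs(
    ref$seq, ref$model, deletion = lesions$deletion, snv = NULL,
    genotypes = list(deletion = c(child = "0/1", mother = "0/0", father = "0/0")),
    informative_sites = sites,
    depth = config$wgs_depth, seed = config$seed + 409L,
    read_len = config$read_len, insert_mean = config$insert_mean,
    insert_sd = config$insert_sd, base_error_rate = config$base_error_rate)

  track <- simulate_repeat_track(
    nchar(ref$seq), seed = config$seed + 7L,
    exclude = c(lesions$deletion$start, lesions$deletion$end))

  truth <- config$roster
  truth$lesion <- dplyr::case_when(
    truth$subject_id == "proband1" ~ "splice_snv",
    truth$subject_id == "proband2" ~ "genomic_deletion",
    TRUE ~ "none")
  truth$causal <- truth$lesion != "none"

  list(reference = ref, lesions = lesions, isoforms = isoforms,
       amplicon = amplicon,
       trios = list(proband1 = trio1, proband2 = trio2),
       repeat_track = track,
       truth = list(roster = truth, mixtures = config$isoform_mixtures),
       config = config)
}

# Heterozygous marker sites flanking the deletion: mother 0/1, father 0/0,
# child's deletion haplotype carries the maternal alt allele.
maternal_marker_sites <- function(seq, deletion, n_per_side = 3L, seed = 1L,
                                  offsets = c(30L, 60L, 95L)) {
  pos <- c(deletion$start - offsets, deletion$end + offsets)
  ref_bases <- substring(seq, pos, pos)
  withr::with_seed(seed, {
    tibble(pos = as.integer(pos),
           allele = other_base(ref_bases),
           parent = "mother")
  })
}
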