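#' Pair up mate alignments and compute apparent insert sizes
#'
#' @param aln A genomic-mode [align_reads()] result containing both mates.
#' @return Tibble with one row per read pair mapped on both mates: outer
#'   span, inner interval (`gap_start`, `gap_end`, 0-based half-open between
#'   the mates), apparent insert size and orientation check (`proper`:
#'   forward-reverse with the forward mate leftmost).
#' @export
pair_table <- function(aln) {
  bl <- blocks_long(aln)
  if (nrow(bl) == 0) {
    return(tibble(read_id = character(0), insert = integer(0),
                  gap_start = integer(0), gap_end = integer(0),
                  proper = logical(0)))
  }
  per_mate <- bl |>
    group_by(.data$read_id, .data$mate) |>
    summarise(rs = min(.data$r0), re = max(.data$r1), .groups = "drop") |>
    left_join(dplyr::distinct(aln[aln$status == "mapped",
                                  c("read_id", "mate", "strand")]),
              by = c("read_id", "mate"))
  both <- per_mate |>
    group_by(.data$read_id) |>
    filter(dplyr::n() == 2L) |>
    arrange(.data$rs, .by_group = TRUE) |>
    summarise(insert = max(.data$re) - min(.data$rs),
              gap_start = .data$re[1], gap_end = .data$rs[2],
              proper = .data$strand[1] == "+" && .data$strand[2] == "-",
              .groups = "drop")
  both
}

#' Detect clusters of deletion-suggesting discordant read pairs
#'
#' Pairs in proper orientation whose apparent insert exceeds
#' `insert_mean + nsd * insert_sd` are clustered by overlap of the interval
#' implied between the mates; each cluster's interval is the intersection of
#' its members' implied intervals, which must contain the deletion.
#'
#' @param aln A genomic-mode [align_reads()] result (both mates).
#' @param insert_mean,insert_sd Fragment-length model used in sequencing.
#' @param nsd Discordance threshold in standard deviations (default 4).
#' @return Tibble with `cluster`, `start`, `end` (0-based half-open
#'   intersection interval) and `support` (pair count).
#' @export
detect_discordant_pairs <- function(aln, insert_mean, insert_sd, nsd = 4) {
  pt <- pair_table(aln)
  disc <- pt |>
    filter(.data$proper, .data$insert > insert_mean + nsd * insert_sd,
           .data$gap_end > .data$gap_start) |>
    arrange(.data$gap_start)
  if (nrow(disc) == 0) {
    return(tibble(cluster = integer(0), start = integer(0), end = integer(0),
                  support = integer(0)))
  }
  # single-pass overlap clustering on sorted implied intervals
  cl <- integer(nrow(disc))
  cur <- 1L; cur_end <- disc$gap_end[1]; cl[1] <- 1L
  for (i in seq_len(nrow(disc))[-1]) {
    if (disc$gap_start[i] < cur_end) {
      cl[i] <- cur
      cur_end <- min(cur_end, disc$gap_end[i])
    } else {
      cur <- cur + 1L; cl[i] <- cur; cur_end <- disc$gap_end[i]
    }
  }
  disc$cluster <- cl
  disc |>
    group_by(.data$cluster) |>
    summarise(start = max(.data$gap_start), end = min(.data$gap_end),
              support = dplyr::n(), .groups = "drop")
}

#' Breakpoint-resolved deletion candidates from split reads
#'
#' Reads aligned with a reference gap of at least `min_gap` nominate exact
#' (left, right) breakpoints (left-aligned by the genomic-mode aligner). The
#' consensus breakpoint is the modal pair; ties go to the smallest start,
#' then smallest end.
#'
#' @param aln A genomic-mode [align_reads()] result.
#' @param min_gap Smallest reference gap treated as a structural candidate
#'   rather than alignment noise (nt).
#' @return Tibble of candidates (`left`, `right`, `support`) sorted with the
#'   consensus first.
#' @export
detect_split_reads <- function(aln, min_gap = 50L) {
  jt <- junction_table(aln)
  jt <- jt[jt$right - jt$left >= min_gap, ]
  if (nrow(jt) == 0) {
    return(tibble(left = integer(0), right = integer(0), support = integer(0)))
  }
  jt |>
    select("left", "right", "support") |>
    arrange(desc(.data$support), .data$left, .data$right)
}

# reads with any block covering 1-based position `pos` (mapped only)
depth_at <- function(aln, pos) {
  bl <- blocks_long(aln)
  p0 <- pos - 1L
  if (nrow(bl) == 0) return(0L)
  length(unique(bl$read_id[bl$r0 <= p0 & p0 < bl$r1]))
}

# reads whose single contiguous block spans 1-based `pos` with >= flank nt on
# both sides (reference-allele support at a breakpoint)
ref_span_count <- function(aln, pos, flank = 12L) {
  bl <- blocks_long(aln)
  p0 <- pos - 1L
  sum(bl$r0 <= p0 - flank & bl$r1 >= p0 + flank)
}

# split-read support for a specific junction within +-tol
split_support_at <- function(aln, left, right, tol = 5L) {
  jt <- junction_table(aln)
  sum(jt$support[abs(jt$left - left) <= tol & abs(jt$right - right) <= tol])
}

#' Call a multi-exon deletion from trio evidence
#'
#' Breakpoints come from the child's split-read consensus. A member is called
#' as carrying the deletion if it has at least `min_split` split reads, or at
#' least `min_disc` discordant pairs together with at least one split read.
#' Genotypes follow the supporting-read fraction (0/1 in `[0.2, 0.8]`, 1/1
#' above 0.8). The call is de novo iff the child carries it and both parents
#' have zero supporting reads with depth >= `min_depth` at both breakpoints;
#' insufficient parental depth gives `de_novo = NA` ("unevaluable") rather
#' than a false de novo.
#'
#' @param trio_aln Named list of genomic-mode [align_reads()] results for
#'   `child`, `mother`, `father`.
#' @param model A [gene_model()].
#' @param insert_mean,insert_sd Fragment-length model.
#' @param min_split,min_disc,min_depth,tol Calling thresholds.
#' @param min_gap Smallest gap considered a structural candidate.
#' @return An object of class `deletion_call`, or `NULL` if the child has no
#'   consensus breakpoint: list with `chrom`, `start`, `end` (1-based
#'   inclusive), `length`, `members` (per-member support/genotype tibble),
#'   `de_novo` (logical, `NA` = unevaluable), `inheritance`,
#'   `affected_exons`, `breakpoints` (intron/exon labels), `label`.
#' @export
call_deletion <- function(trio_aln, model, insert_mean = 350, insert_sd = 50,
                          min_split = 3L, min_disc = 5L, min_depth = 10L,
                          tol = 5L, min_gap = 50L) {
  stopifnot(all(c("child", "mother", "father") %in% names(trio_aln)))
  cand <- detect_split_reads(trio_aln$child, min_gap)
  if (nrow(cand) == 0) return(NULL)
  left <- cand$left[1]; right <- cand$right[1]
  start1 <- left + 1L   # first deleted base, 1-based
  end1 <- right         # last deleted base, 1-based

  members <- purrr::imap(trio_aln, function(aln, m) {
    ss <- split_support_at(aln, left, right, tol)
    dc <- detect_discordant_pairs(aln, insert_mean, insert_sd)
    ds <- if (nrow(dc)) {
      # a pair supports THIS deletion only if the interval implied between
      # its mates contains both breakpoints; chance-long fragments that
      # merely overlap the interval are not evidence
      ov <- dc$start <= left + tol & dc$end >= right - tol
      if (any(ov)) sum(dc$support[ov]) else 0L
    } else 0L
    refs <- c(ref_span_count(aln, start1), ref_span_count(aln, end1 + 1L))
    alt <- ss
    vaf <- if (alt + mean(refs) > 0) alt / (alt + mean(refs)) else 0
    called <- ss >= min_split || (ds >= min_disc && ss >= 1L)
    gt <- if (!called || vaf < 0.2) "0/0" else if (vaf > 0.8) "1/1" else "0/1"
    tibble(member = m, split_support = ss, discordant_support = ds,
           ref_support = mean(refs),
           depth_left = depth_at(aln, start1), depth_right = depth_at(aln, end1),
           vaf = vaf, genotype = gt)
  }) |> bind_rows()

  child <- members[members$member == "child", ]
  if (child$genotype == "0/0") return(NULL)
  par <- members[members$member != "child", ]
  parents_covered <- all(par$depth_left >= min_depth & par$depth_right >= min_depth)
  parents_clean <- all(par$split_support == 0L & par$discordant_support == 0L)
  de_novo <- if (!parents_covered) NA else parents_clean
  inheritance <- dplyr::case_when(
    isTRUE(de_novo) ~ "de_novo",
    is.na(de_novo) ~ "unevaluable",
    par$genotype[par$member == "mother"] != "0/0" &
      par$genotype[par$member == "father"] == "0/0" ~ "maternal",
    par$genotype[par$member == "father"] != "0/0" &
      par$genotype[par$member == "mother"] == "0/0" ~ "paternal",
    TRUE ~ "ambiguous")
  dte <- deletion_to_exons(model, start1, end1)
  structure(
    list(chrom = model$chrom, start = start1, end = end1,
         length = end1 - start1 + 1L,
         members = members, de_novo = de_novo, inheritance = inheritance,
         affected_exons = dte$exons, breakpoints = dte$breakpoints,
         label = sprintf("%s.%d_%ddel", model$chrom, start1, end1)),
    class = "deletion_call")
}

#' @export
print.deletion_call <- function(x, ...) {
  cat(sprintf("<deletion_call> %s (%d nt), exons %s; de novo: %s (%s)\n",
              x$label, x$length,
              paste(range(x$affected_exons), collapse = "-"),
              ifelse(is.na(x$de_novo), "unevaluable", x$de_novo),
              x$inheritance))
  print(x$members)
  invisible(x)
}

#' Parent of origin of a de novo deletion
#'
#' Child reads spanning the deletion junction that also cover a
#' Mendelian-informative flanking het site vote for the parent whose allele
#' they carry; majority vote with at least `min_votes` informative reads,
#' otherwise `ambiguous`.
#'
#' @param del A [call_deletion()] result.
#' @param child_aln The child's genomic-mode alignments with `oseq`
#'   (`keep_seq = TRUE`).
#' @param sites Tibble with `pos` (1-based), `allele`, `parent`: alleles
#'   identifying the transmitting parent at sites near the breakpoints.
#' @param tol Junction matching tolerance (nt).
#' @param min_votes Minimum informative reads for a verdict.
#' @return List with `origin` (`maternal`/`paternal`/`ambiguous`) and
#'   `votes` (named integer vector).
#' @export
parent_of_origin <- function(del, child_aln, sites, tol = 5L, min_votes = 3L) {
  votes <- c(mother = 0L, father = 0L)
  if (!is.null(sites) && nrow(sites) > 0) {
    if (!"oseq" %in% names(child_aln)) {
      abort("parent_of_origin needs alignments with oseq (keep_seq = TRUE)")
    }
    left <- del$start - 1L; right <- del$end
    has_j <- child_aln$status == "mapped" & nzchar(child_aln$junctions)
    jr <- child_aln[has_j, ]
    for (i in seq_len(nrow(jr))) {
      ju <- parse_junctions(jr$junctions[i])
      if (!any(abs(ju$left - left) <= tol & abs(ju$right - right) <= tol)) next
      bl <- parse_blocks(jr$blocks[i])
      for (s in seq_len(nrow(sites))) {
        p0 <- sites$pos[s] - 1L
        hit <- which(bl$r0 <= p0 & p0 < bl$r1)
        if (length(hit) != 1L) next
        q <- bl$q0[hit] + (p0 - bl$r0[hit]) + 1L
        base <- substring(jr$oseq[i], q, q)
        if (base == sites$allele[s]) {
          votes[sites$parent[s]] <- votes[sites$parent[s]] + 1L
        }
      }
    }
  }
  total <- sum(votes)
  origin <- if (total < min_votes || votes["mother"] == votes["father"]) {
    "ambiguous"
  } else if (votes["mother"] > votes["father"]) "maternal" else "paternal"
  list(origin = origin, votes = votes)
}

# base pileup at given 1-based positions from alignments with oseq
pileup_bases <- function(aln, positions) {
  if (!"oseq" %in% names(aln)) abort("pileup needs alignments with oseq")
  bl <- blocks_long(aln)
  if (nrow(bl) == 0) {
    return(tibble(pos = integer(0), base = character(0), n = integer(0)))
  }
  oseq <- aln$oseq[bl$row]
  out <- purrr::map(positions, function(p1) {
    p0 <- p1 - 1L
    hit <- which(bl$r0 <= p0 & p0 < bl$r1)
    if (length(hit) == 0L) return(NULL)
    q <- bl$q0[hit] + (p0 - bl$r0[hit]) + 1L
    tab <- table(substring(oseq[hit], q, q))
    tibble(pos = p1, base = names(tab), n = as.integer(tab))
  })
  bind_rows(out)
}

#' Screen splice regions for single-nucleotide variants in a trio
#'
#' Every intronic position within `window` nt of a donor or acceptor is
#' piled up in the child; a variant is called where the alternate-allele
#' fraction is at least `min_frac` with at least `min_alt` alternate reads.
#' Calls are annotated in HGVS c. notation via the gene model and classified
#' by inheritance from the parents' pileups. Screened positions with child
#' depth below `min_depth` are reported as unevaluable.
#'
#' @param trio_aln Named list (`child`, `mother`, `father`) of genomic-mode
#'   [align_reads()] results with `oseq`.
#' @param ref_seq Reference sequence.
#' @param model A [gene_model()].
#' @param window Intronic window around each donor/acceptor (nt).
#' @param min_alt,min_frac,min_depth Calling thresholds.
#' @return List with `calls` (tibble: `pos`, `ref`, `alt`, `label`, `site`,
#'   `offset`, per-member genotypes, `inheritance`) and `unevaluable`
#'   (positions with insufficient child depth).
#' @export
splice_region_snv_screen <- function(trio_aln, ref_seq, model, window = 8L,
                                     min_alt = 4L, min_frac = 0.2,
                                     min_depth = 8L) {
  ex <- model$exons
  n <- nrow(ex)
  donor_pos <- unlist(lapply(seq_len(n - 1L), function(i) ex$end[i] + seq_len(window)))
  accept_pos <- unlist(lapply(seq_len(n - 1L) + 1L, function(i) ex$start[i] - (window:1) + 1L))
  positions <- sort(unique(c(donor_pos, accept_pos)))
  ref_bases <- substring(ref_seq, positions, positions)

  member_pile <- lapply(trio_aln, pileup_bases, positions = positions)
  gt_at <- function(pile, pos, ref, alt) {
    pb <- pile[pile$pos == pos, ]
    depth <- sum(pb$n)
    if (depth < min_depth) return(NA_character_)
    na <- sum(pb$n[pb$base == alt])
    if (na >= 2L && na / depth >= min_frac) {
      if (na / depth > 0.8) "1/1" else "0/1"
    } else "0/0"
  }

  child <- member_pile$child
  calls <- list(); uneval <- integer(0)
  for (t in seq_along(positions)) {
    p <- positions[t]; rb <- ref_bases[t]
    pb <- child[child$pos == p, ]
    depth <- sum(pb$n)
    if (depth < min_depth) { uneval <- c(uneval, p); next }
    nonref <- pb[pb$base != rb, ]
    if (nrow(nonref) == 0L) next
    alt <- nonref$base[which.max(nonref$n)]
    na <- max(nonref$n)
    if (na < min_alt || na / depth < min_frac) next
    cd <- genomic_to_cdna(model, p)
    gt_m <- gt_at(member_pile$mother, p, rb, alt)
    gt_f <- gt_at(member_pile$father, p, rb, alt)
    inheritance <- dplyr::case_when(
      is.na(gt_m) || is.na(gt_f) ~ "ambiguous",
      gt_m == "0/0" && gt_f == "0/0" ~ "de_novo",
      gt_m != "0/0" && gt_f == "0/0" ~ "maternal",
      gt_m == "0/0" && gt_f != "0/0" ~ "paternal",
      TRUE ~ "ambiguous")
    calls[[length(calls) + 1L]] <- tibble(
      pos = p, ref = rb, alt = alt,
      base = cd$base, offset = cd$intron_offset,
      label = sprintf("%s%s>%s", cd$label, rb, alt),
      site = if (cd$intron_offset > 0) "donor_region" else "acceptor_region",
      depth = depth, alt_reads = na,
      gt_child = if (na / depth > 0.8) "1/1" else "0/1",
      gt_mother = gt_m, gt_father = gt_f,
      inheritance = inheritance)
  }
  list(calls = if (length(calls)) bind_rows(calls) else
         tibble(pos = integer(0), ref = character(0), alt = character(0),
                base = integer(0), offset = integer(0), label = character(0),
                site = character(0), depth = integer(0), alt_reads = integer(0),
                gt_child = character(0), gt_mother = character(0),
                gt_father = character(0), inheritance = character(0)),
       unevaluable = uneval)
}

#' Write deletion and SNV calls as VCF 4.2
#'
#' The deletion is written as a symbolic `<DEL>` record with `END`/`SVLEN`
#' INFO fields (POS at the base before the deletion, per VCF convention);
#' SNVs as plain records. Per-member genotypes go in the sample columns.
#'
#' @param path Output file.
#' @param ref_seq Reference sequence (for anchor/REF bases).
#' @param chrom Contig name.
#' @param deletion A [call_deletion()] result or `NULL`.
#' @param snv_calls A [splice_region_snv_screen()] `calls` tibble or `NULL`.
#' @param members Sample column order.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(path, ref_seq, chrom, deletion = NULL,
                           snv_calls = NULL,
                           members = c("child", "mother", "father")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(ref_seq)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", members), collapse = "\t"))
  rows <- character(0)
  if (!is.null(deletion)) {
    pos <- deletion$start - 1L
    gts <- setNames(deletion$members$genotype, deletion$members$member)
    rows <- c(rows, paste(c(
      chrom, pos, deletion$label, substring(ref_seq, pos, pos), "<DEL>", ".",
      "PASS",
      sprintf("END=%d;SVLEN=-%d;SVTYPE=DEL", deletion$end, deletion$length),
      "GT", unname(gts[members])), collapse = "\t"))
  }
  if (!is.null(snv_calls) && nrow(snv_calls) > 0) {
    for (i in seq_len(nrow(snv_calls))) {
      r <- snv_calls[i, ]
      rows <- c(rows, paste(c(
        chrom, r$pos, r$label, r$ref, r$alt, ".", "PASS", ".",
        "GT", r$gt_child, r$gt_mother, r$gt_father), collapse = "\t"))
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
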