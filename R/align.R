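#' Build an exact-match k-mer index over a reference sequence
#'
#' @param seq Reference sequence (character scalar).
#' @param k K-mer size (default 21; 1-31).
#' @return An object of class `kmer_index`.
#' @export
index_reference <- function(seq, k = 21L) {
  k <- assert_scalar_int(k, "k")
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    abort("`seq` must be a non-empty character scalar")
  }
  structure(list(ptr = cpp_build_index(seq, k), k = k, seq = seq,
                 reflen = nchar(seq)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d over %d nt\n", x$k, x$reflen))
  invisible(x)
}

#' Look up the reference offsets of a k-mer
#'
#' @param index A [index_reference()] object.
#' @param kmer Character scalar of length `k`.
#' @return Integer vector of 0-based reference offsets (empty if absent).
#' @export
index_lookup <- function(index, kmer) {
  cpp_index_lookup(index$ptr, kmer)
}

#' Alignment parameters
#'
#' @param k Anchor k-mer size.
#' @param max_gap Largest reference gap (nt) a junction may span.
#' @param homology_window How far (nt) from the left-aligned placement a
#'   junction may be moved to land on annotated exon boundaries.
#' @param max_mismatch_frac Reads with a higher aligned mismatch fraction are
#'   reported unmapped.
#' @param min_terminal Minimum terminal block length (nt); junctions closer
#'   than this to a read end are not called from that read.
#' @param min_span Flank (nt) required on both sides for a block to count as
#'   spanning an annotated boundary.
#' @param min_aligned Minimum aligned length for a mapped read (defaults to `k`).
#' @param max_hits_per_kmer K-mers with more reference hits are ignored as
#'   repetitive.
#' @return A list of class `align_params`.
#' @export
align_params <- function(k = 21L, max_gap = 1e5, homology_window = 8L,
                         max_mismatch_frac = 0.05, min_terminal = 12L,
                         min_span = 12L, min_aligned = NULL,
                         max_hits_per_kmer = 64L) {
  structure(list(k = as.integer(k), max_gap = max_gap,
                 homology_window = as.integer(homology_window),
                 max_mismatch_frac = max_mismatch_frac,
                 min_terminal = as.integer(min_terminal),
                 min_span = as.integer(min_span),
                 min_aligned = as.integer(min_aligned %||% k),
                 max_hits_per_kmer = as.integer(max_hits_per_kmer)),
            class = "align_params")
}

#' Align reads to a single-gene reference with support for reference gaps
#'
#' The aligner chains exact k-mer anchors along diagonals (longest collinear
#' chain; ties broken towards the smaller total gap), turns inter-block
#' reference gaps into candidate junctions, extends block edges base-by-base,
#' and resolves junction microhomology by snapping to annotated exon
#' boundaries when a co-optimal placement within the homology window puts
#' both edges on annotated donor/acceptor positions, otherwise left-aligning.
#' Low-identity read tails are soft-clipped; reads above the mismatch
#' threshold, or with two equally good conflicting placements, are reported
#' `unmapped` / `ambiguous` rather than erroring.
#'
#' In `mode = "cdna"` the annotated boundaries are the cumulative exon ends
#' of `model` on the spliced transcript; in `mode = "genomic"` junctions are
#' always left-aligned (breakpoint snapping is a transcript concept) and the
#' allowed gap is large enough for multi-kb deletions.
#'
#' @param reads Tibble with columns `read_id`, `seq` (and optionally `mate`),
#'   or a character vector of sequences.
#' @param reference Reference sequence (character scalar) or a prebuilt
#'   [index_reference()].
#' @param model A [gene_model()] (required for `mode = "cdna"`).
#' @param params An [align_params()].
#' @param mode `"cdna"` (amplicon reads vs the spliced transcript) or
#'   `"genomic"`.
#' @param keep_seq Keep the reference-oriented read sequence in the output
#'   (needed for pileups).
#' @return A tibble with one row per read: `read_id`, `mate`, `status`
#'   (`mapped`/`unmapped`/`ambiguous`), `strand`, `n_blocks`, `mismatches`,
#'   `aligned`, `clip_left`, `clip_right`, `blocks` (encoded
#'   `"q0:q1:r0:r1;..."`, 0-based half-open), `junctions` (`"left:right;..."`,
#'   0-based: left exclusive end of the left block, right start of the right
#'   block), `junc_status` (`exon_snap`/`left_aligned`), `spans`
#'   (comma-separated indices of annotated boundaries spanned by
#'   junction-free blocks), and optionally `oseq`.
#' @export
align_reads <- function(reads, reference, model = NULL,
                        params = align_params(), mode = c("cdna", "genomic"),
                        keep_seq = FALSE) {
  mode <- match.arg(mode)
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read%d", seq_along(reads)),
                    mate = 1L, seq = reads)
  }
  reads <- as_tibble(reads)
  if (!"mate" %in% names(reads)) reads$mate <- 1L
  idx <- if (inherits(reference, "kmer_index")) reference
         else index_reference(reference, params$k)
  if (mode == "cdna") {
    if (is.null(model)) abort("cdna mode needs a gene model")
    b <- cdna_boundaries(model)
    donors <- acceptors <- span_points <- as.numeric(b)
  } else {
    donors <- acceptors <- numeric(0)
    span_points <- numeric(0)
  }
  res <- cpp_align_reads(idx$ptr, reads$seq, donors, acceptors, span_points,
                         params$max_gap, params$homology_window,
                         params$max_mismatch_frac, params$min_terminal,
                         params$min_span, params$min_aligned,
                         params$max_hits_per_kmer)
  out <- tibble(read_id = reads$read_id, mate = reads$mate,
                status = as.character(res$status),
                strand = as.character(res$strand),
                n_blocks = res$n_blocks, mismatches = res$mismatches,
                aligned = res$aligned, clip_left = res$clip_left,
                clip_right = res$clip_right,
                blocks = as.character(res$blocks),
                junctions = as.character(res$junctions),
                junc_status = as.character(res$junc_status),
                spans = as.character(res$spans))
  if (keep_seq) {
    out$oseq <- ifelse(out$strand == "-", revcomp(reads$seq), reads$seq)
  }
  out
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] returning decoded blocks and
#' junctions for one read.
#'
#' @inheritParams align_reads
#' @param read A single read sequence.
#' @return A list with `status`, `strand`, `blocks` (tibble `q0`, `q1`, `r0`,
#'   `r1`), `junctions` (tibble `left`, `right`, `boundary_status`),
#'   `mismatches`, `aligned`.
#' @export
align_read <- function(read, reference, model = NULL,
                       params = align_params(), mode = c("cdna", "genomic")) {
  aln <- align_reads(read, reference, model, params, mode)
  list(status = aln$status, strand = aln$strand,
       blocks = parse_blocks(aln$blocks),
       junctions = parse_junctions(aln$junctions, aln$junc_status),
       mismatches = aln$mismatches, aligned = aln$aligned)
}

#' Decode the encoded block column of an alignment row
#' @param blocks A single encoded block string (`"q0:q1:r0:r1;..."`).
#' @return Tibble with `q0`, `q1`, `r0`, `r1` (0-based half-open).
#' @export
parse_blocks <- function(blocks) {
  if (is.na(blocks) || !nzchar(blocks)) {
    return(tibble(q0 = integer(0), q1 = integer(0),
                  r0 = integer(0), r1 = integer(0)))
  }
  m <- do.call(rbind, lapply(strsplit(blocks, ";", fixed = TRUE)[[1]],
                             function(s) as.integer(strsplit(s, ":", fixed = TRUE)[[1]])))
  tibble(q0 = m[, 1], q1 = m[, 2], r0 = m[, 3], r1 = m[, 4])
}

#' @rdname parse_blocks
#' @param junctions Encoded junction string (`"left:right;..."`).
#' @param junc_status Encoded boundary-status string.
#' @export
parse_junctions <- function(junctions, junc_status = "") {
  if (is.na(junctions) || !nzchar(junctions)) {
    return(tibble(left = integer(0), right = integer(0),
                  boundary_status = character(0)))
  }
  m <- do.call(rbind, lapply(strsplit(junctions, ";", fixed = TRUE)[[1]],
                             function(s) as.integer(strsplit(s, ":", fixed = TRUE)[[1]])))
  st <- strsplit(junc_status, ";", fixed = TRUE)[[1]]
  if (length(st) != nrow(m)) st <- rep(NA_character_, nrow(m))
  tibble(left = m[, 1], right = m[, 2], boundary_status = st)
}

# Long-format blocks for a whole alignment tibble (mapped reads only).
blocks_long <- function(aln) {
  al <- aln[aln$status == "mapped" & nzchar(aln$blocks), ]
  if (nrow(al) == 0) {
    return(tibble(row = integer(0), read_id = character(0), mate = integer(0),
                  q0 = integer(0), q1 = integer(0), r0 = integer(0),
                  r1 = integer(0)))
  }
  parts <- strsplit(al$blocks, ";", fixed = TRUE)
  nb <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  m <- matrix(as.integer(unlist(strsplit(flat, ":", fixed = TRUE))),
              ncol = 4, byrow = TRUE)
  tibble(row = rep(which(aln$status == "mapped" & nzchar(aln$blocks)), nb),
         read_id = rep(al$read_id, nb), mate = rep(al$mate, nb),
         q0 = m[, 1], q1 = m[, 2], r0 = m[, 3], r1 = m[, 4])
}

#' Aggregate identical junctions across an alignment set
#'
#' @param aln An [align_reads()] result.
#' @return Tibble with `left`, `right` (0-based half-open reference gap),
#'   `support` (read count), `n_snap`, `n_left_aligned`.
#' @export
junction_table <- function(aln) {
  al <- aln[aln$status == "mapped" & nzchar(aln$junctions), ]
  if (nrow(al) == 0) {
    return(tibble(left = integer(0), right = integer(0), support = integer(0),
                  n_snap = integer(0), n_left_aligned = integer(0)))
  }
  ju <- strsplit(al$junctions, ";", fixed = TRUE)
  st <- strsplit(al$junc_status, ";", fixed = TRUE)
  flat <- unlist(ju, use.names = FALSE)
  m <- matrix(as.integer(unlist(strsplit(flat, ":", fixed = TRUE))),
              ncol = 2, byrow = TRUE)
  tibble(left = m[, 1], right = m[, 2],
         bstat = unlist(st, use.names = FALSE)) |>
    group_by(.data$left, .data$right) |>
    summarise(support = dplyr::n(),
              n_snap = sum(.data$bstat == "exon_snap"),
              n_left_aligned = sum(.data$bstat == "left_aligned"),
              .groups = "drop") |>
    arrange(desc(.data$support))
}

#' Write alignments as SAM
#'
#' Reference gaps (junctions) are encoded as `N` CIGAR operations;
#' soft-clipped tails as `S`. Reads aligned to the reverse strand are stored
#' in reference orientation with flag 16, following the SAM convention.
#'
#' @param aln An [align_reads()] result with `oseq` kept
#'   (`keep_seq = TRUE`).
#' @param ref_name Reference sequence name for the `@SQ` header.
#' @param ref_len Reference length.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref_name, ref_len, path) {
  if (!"oseq" %in% names(aln)) abort("write_sam needs alignments with oseq (keep_seq = TRUE)")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
  rows <- purrr::pmap_chr(
    aln[, c("read_id", "status", "strand", "blocks", "clip_left",
            "clip_right", "oseq")],
    function(read_id, status, strand, blocks, clip_left, clip_right, oseq) {
      if (status != "mapped") {
        return(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", read_id, oseq))
      }
      b <- parse_blocks(blocks)
      cig <- character(0)
      if (clip_left > 0) cig <- c(cig, sprintf("%dS", clip_left))
      for (i in seq_len(nrow(b))) {
        if (i > 1) cig <- c(cig, sprintf("%dN", b$r0[i] - b$r1[i - 1]))
        cig <- c(cig, sprintf("%dM", b$q1[i] - b$q0[i]))
      }
      if (clip_right > 0) cig <- c(cig, sprintf("%dS", clip_right))
      flag <- if (strand == "-") 16L else 0L
      sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
              read_id, flag, ref_name, b$r0[1] + 1L,
              paste(cig, collapse = ""), oseq)
    })
  writeLines(c(hdr, rows), path)
  invisible(path)
}
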