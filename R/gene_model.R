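#' Gene model for a single multi-exon gene
#'
#' Builds the coordinate backbone used by every stage of the pipeline: an
#' ordered exon/intron architecture together with the CDS offset needed for
#' HGVS c. annotation. Exon intervals are stored 0-based half-open in
#' transcription orientation; all user-facing positions (function arguments
#' and printed output) are 1-based inclusive.
#'
#' Minus-strand genes are normalized at ingest ([flip_gene_model()]): the
#' reference is reverse-complemented and the exons re-expressed on the
#' flipped sequence, so downstream logic always operates in transcription
#' orientation.
#'
#' @param exons Data frame with columns `start`, `end`: 0-based half-open
#'   exon intervals, ordered 1..n in transcription direction.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"` (recorded; coordinates must already be in
#'   transcription orientation — see [flip_gene_model()]).
#' @param cds_start_offset 0-based position of the first coding base within
#'   the spliced transcript (i.e. the 5' UTR length).
#' @param cds_length Coding sequence length in nt; defaults to everything
#'   downstream of the CDS start (no 3' UTR).
#' @param gene_id,transcript_id Identifiers carried through to reports.
#' @return An object of class `gene_model`.
#' @export
#' @examples
#' m <- gene_model(data.frame(start = c(0, 200), end = c(100, 350)),
#'                 cds_start_offset = 10)
#' spliced_length(m)
gene_model <- function(exons, chrom = "gene_locus", strand = "+",
                       cds_start_offset = 0, cds_length = NULL,
                       gene_id = "GENE", transcript_id = "TX") {
  exons <- as_tibble(exons)
  stopifnot(all(c("start", "end") %in% names(exons)))
  exons <- exons[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  n <- nrow(exons)
  if (n < 1L) abort("a gene model needs at least one exon")
  if (any(exons$end <= exons$start)) abort("exon intervals must be non-empty")
  if (n > 1L) {
    intron_len <- exons$start[-1] - exons$end[-n]
    if (any(intron_len < 4L)) {
      abort("exons must be strictly ordered and every intron must be >= 4 nt")
    }
  }
  if (!strand %in% c("+", "-")) abort('strand must be "+" or "-"')
  exons$exon <- seq_len(n)
  exons$length <- exons$end - exons$start
  spliced <- sum(exons$length)
  cds_start_offset <- as.integer(cds_start_offset)
  if (cds_start_offset < 0 || cds_start_offset >= spliced) {
    abort("cds_start_offset must lie within the spliced transcript")
  }
  cds_length <- as.integer(cds_length %||% (spliced - cds_start_offset))
  if (cds_length < 1 || cds_start_offset + cds_length > spliced) {
    abort("cds_length must fit within the spliced transcript")
  }
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, exons = exons[, c("exon", "start", "end", "length")],
         cds_start_offset = cds_start_offset, cds_length = cds_length),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s), %d exons on %s strand %s\n",
              x$gene_id, x$transcript_id, nrow(x$exons), x$chrom, x$strand))
  cat(sprintf("  span (1-based): %d-%d; spliced length %d nt; CDS offset %d, CDS %d nt\n",
              x$exons$start[1] + 1L, max(x$exons$end), spliced_length(x),
              x$cds_start_offset, x$cds_length))
  invisible(x)
}

#' Spliced transcript length of a gene model
#' @param model A [gene_model()].
#' @return Integer, nt.
#' @export
spliced_length <- function(model) sum(model$exons$length)

#' Genomic span of a gene model (1-based inclusive)
#' @param model A [gene_model()].
#' @return Integer vector `c(start, end)`.
#' @export
gene_span <- function(model) {
  c(model$exons$start[1] + 1L, max(model$exons$end))
}

# cumulative spliced positions of exon ends (0-based, exclusive), length n
cum_ends <- function(model) cumsum(model$exons$length)

#' Annotated exon-exon boundary positions in spliced (cDNA) coordinates
#'
#' Boundary j (j = 1..n-1) is the 0-based spliced position where exon j ends
#' and exon j+1 starts; this is where both a canonical splice and any skip
#' junction starting at exon j+1 sit on the cDNA reference.
#'
#' @param model A [gene_model()].
#' @return Integer vector of length n-1.
#' @export
cdna_boundaries <- function(model) {
  ce <- cum_ends(model)
  ce[-length(ce)]
}

#' Re-express a minus-strand gene model in transcription orientation
#'
#' Flips exon coordinates onto the reverse-complemented reference so that all
#' downstream logic runs in transcription orientation (a single code path).
#'
#' @param model A [gene_model()] whose coordinates are on the plus strand of
#'   a reference of length `ref_length`, with `strand = "-"`.
#' @param ref_length Length of the reference sequence.
#' @return A plus-orientation `gene_model` over the reverse-complemented
#'   reference.
#' @export
flip_gene_model <- function(model, ref_length) {
  if (model$strand != "-") return(model)
  ex <- model$exons
  new <- tibble(start = ref_length - rev(ex$end),
                end = ref_length - rev(ex$start))
  gene_model(new, chrom = model$chrom, strand = "+",
             cds_start_offset = model$cds_start_offset,
             cds_length = model$cds_length,
             gene_id = model$gene_id, transcript_id = model$transcript_id)
}

#' Convert genomic positions to HGVS c. coordinates
#'
#' Exonic positions map to their CDS-based c. position; intronic positions
#' anchor to the nearest exon edge with a signed offset (`+k` downstream of a
#' donor, `-k` upstream of an acceptor). A position in the 5' half of an
#' intron anchors to the donor, the 3' half to the acceptor; the exact
#' midpoint of an odd-length intron anchors to the donor, following HGVS
#' convention. 5' UTR positions get negative `base`, 3' UTR positions are
#' marked `region = "utr3"` and render as `c.*k`.
#'
#' @param model A [gene_model()].
#' @param pos Integer vector of 1-based genomic positions within the gene span.
#' @return A tibble with columns `pos`, `base`, `intron_offset`, `region`
#'   (one of `"cds"`, `"utr5"`, `"utr3"`) and `label` (e.g. `"c.2298+5"`).
#' @export
genomic_to_cdna <- function(model, pos) {
  pos <- as.integer(pos)
  span <- gene_span(model)
  if (any(pos < span[1] | pos > span[2])) {
    abort("position outside the gene span")
  }
  ex <- model$exons
  ce <- cum_ends(model)
  cum_before <- c(0L, ce[-length(ce)])
  out <- purrr::map(pos, function(p1) {
    p <- p1 - 1L  # 0-based
    i <- which(ex$start <= p & p < ex$end)
    if (length(i) == 1L) {
      sp <- cum_before[i] + (p - ex$start[i])
      c(spliced_to_c(model, sp), list(intron_offset = 0L))
    } else {
      # intron between exon i and i+1
      i <- max(which(ex$end <= p))
      intron_start <- ex$end[i]
      intron_len <- ex$start[i + 1L] - intron_start
      o <- p - intron_start           # 0-based offset into intron
      k_don <- o + 1L
      if (k_don <= ceiling(intron_len / 2)) {
        c(spliced_to_c(model, ce[i] - 1L), list(intron_offset = k_don))
      } else {
        c(spliced_to_c(model, ce[i]), list(intron_offset = -(intron_len - o)))
      }
    }
  })
  res <- tibble(
    pos = pos,
    base = purrr::map_int(out, "base"),
    intron_offset = purrr::map_int(out, "intron_offset"),
    region = purrr::map_chr(out, "region"))
  res$label <- format_cdna(res$base, res$intron_offset, res$region)
  res
}

# 0-based spliced position -> list(base, region)
spliced_to_c <- function(model, sp) {
  ci <- sp - model$cds_start_offset
  if (ci < 0L) {
    list(base = ci, region = "utr5")           # c.-k: ci = -k
  } else if (ci < model$cds_length) {
    list(base = ci + 1L, region = "cds")
  } else {
    list(base = ci - model$cds_length + 1L, region = "utr3")
  }
}

#' Render HGVS c. labels
#'
#' @param base Integer c. base (negative for 5' UTR).
#' @param intron_offset Signed intronic offset (0 if exonic).
#' @param region `"cds"`, `"utr5"` or `"utr3"`.
#' @return Character vector like `"c.2298+5"` or `"c.*12"`.
#' @export
format_cdna <- function(base, intron_offset = 0L, region = "cds") {
  core <- ifelse(region == "utr3", paste0("*", base), as.character(base))
  off <- ifelse(intron_offset == 0L, "",
                sprintf("%+d", intron_offset))
  paste0("c.", core, off)
}

#' Convert HGVS c. coordinates to genomic positions
#'
#' Exact inverse of [genomic_to_cdna()] on its image; additionally accepts
#' any intronic offset whose magnitude fits in the addressed intron.
#'
#' @param model A [gene_model()].
#' @param base Integer c. base (negative for 5' UTR positions).
#' @param intron_offset Signed intronic offset; `+k` requires `base` to be
#'   the last base of an exon, `-k` the first base of an exon.
#' @param region `"cds"`, `"utr5"` or `"utr3"`.
#' @return Integer vector of 1-based genomic positions.
#' @export
cdna_to_genomic <- function(model, base, intron_offset = 0L, region = "cds") {
  n <- max(length(base), length(intron_offset), length(region))
  base <- rep_len(as.integer(base), n)
  intron_offset <- rep_len(as.integer(intron_offset), n)
  region <- rep_len(region, n)
  ex <- model$exons
  ce <- cum_ends(model)
  cum_before <- c(0L, ce[-length(ce)])
  vapply(seq_len(n), function(t) {
    sp <- c_to_spliced(model, base[t], region[t])
    if (sp < 0L || sp >= spliced_length(model)) {
      abort("c. position outside the transcript")
    }
    i <- max(which(cum_before <= sp))
    g0 <- ex$start[i] + (sp - cum_before[i])
    k <- intron_offset[t]
    if (k == 0L) return(g0 + 1L)
    if (k > 0L) {
      if (sp != ce[i] - 1L || i == nrow(ex)) {
        abort("a +k offset requires the last base of a non-terminal exon")
      }
      intron_len <- ex$start[i + 1L] - ex$end[i]
      if (k > intron_len) abort("intron offset exceeds the intron length")
      return(ex$end[i] + k - 1L + 1L)
    }
    if (sp != cum_before[i] || i == 1L) {
      abort("a -k offset requires the first base of a non-initial exon")
    }
    intron_len <- ex$start[i] - ex$end[i - 1L]
    if (-k > intron_len) abort("intron offset exceeds the intron length")
    g0 + k + 1L
  }, integer(1))
}

c_to_spliced <- function(model, base, region) {
  switch(region,
    cds = model$cds_start_offset + base - 1L,
    utr5 = model$cds_start_offset + base,   # base is negative
    utr3 = model$cds_start_offset + model$cds_length + base - 1L,
    abort("region must be cds, utr5 or utr3"))
}

#' Reading-frame consequence of an exon skip
#'
#' A skip is in frame iff the total skipped exonic length is a multiple of 3,
#' in which case the downstream protein sequence is preserved apart from the
#' deleted segment.
#'
#' @param model A [gene_model()].
#' @param signature A [skip_signature()] or integer vector of skipped exon
#'   numbers.
#' @return A one-row tibble with columns `frame` (`"in_frame"` or
#'   `"frameshift"`) and `skipped_nt`.
#' @export
#' @examples
#' m <- gene_model(data.frame(start = c(0, 110, 250), end = c(100, 213, 350)))
#' skip_frame(m, 2)
skip_frame <- function(model, signature) {
  ex <- as.integer(unclass(signature))
  if (length(ex) == 0L) abort("empty skip signature")
  if (anyNA(ex) || !all(ex %in% model$exons$exon)) {
    abort("skip signature names exons absent from the model")
  }
  skipped_nt <- sum(model$exons$length[match(ex, model$exons$exon)])
  tibble(frame = if (skipped_nt %% 3L == 0L) "in_frame" else "frameshift",
         skipped_nt = as.integer(skipped_nt))
}

#' Exons removed by a genomic deletion
#'
#' Returns the exons fully contained in the deleted interval and, for each
#' breakpoint, the intron or exon containing it.
#'
#' @param model A [gene_model()].
#' @param start,end 1-based inclusive genomic interval of the deletion.
#' @return A list with `exons` (integer vector of fully deleted exon numbers)
#'   and `breakpoints`, a two-row tibble (`side`, `feature`, `number`) naming
#'   the intron/exon containing each breakpoint (`"flank"` if outside the
#'   gene body).
#' @export
deletion_to_exons <- function(model, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (end < start) abort("end must be >= start")
  span <- gene_span(model)
  if (end < span[1] || start > span[2]) {
    abort("deletion touches no exon or intron of the model")
  }
  ex <- model$exons
  s0 <- start - 1L  # 0-based half-open [s0, e0)
  e0 <- end
  fully <- ex$exon[ex$start >= s0 & ex$end <= e0]
  locate <- function(p0) {
    i <- which(ex$start <= p0 & p0 < ex$end)
    if (length(i) == 1L) return(list(feature = "exon", number = ex$exon[i]))
    if (p0 < ex$start[1] || p0 >= max(ex$end)) {
      return(list(feature = "flank", number = NA_integer_))
    }
    i <- max(which(ex$end <= p0))
    list(feature = "intron", number = ex$exon[i])
  }
  bl <- locate(s0)
  br <- locate(e0 - 1L)
  list(
    exons = as.integer(fully),
    breakpoints = tibble(
      side = c("left", "right"),
      feature = c(bl$feature, br$feature),
      number = c(bl$number, br$number)))
}

#' Write / read a gene model as a plain-text table
#'
#' The on-disk format is a TSV with one exon per row (`exon`, `start`, `end`;
#' 0-based half-open) preceded by `#key value` header lines carrying the
#' scalar fields.
#'
#' @param model A [gene_model()].
#' @param path File path.
#' @return `write_gene_model()` returns `path` invisibly;
#'   `read_gene_model()` returns a [gene_model()].
#' @export
write_gene_model <- function(model, path) {
  hdr <- c(
    sprintf("#gene_id\t%s", model$gene_id),
    sprintf("#transcript_id\t%s", model$transcript_id),
    sprintf("#chrom\t%s", model$chrom),
    sprintf("#strand\t%s", model$strand),
    sprintf("#cds_start_offset\t%d", model$cds_start_offset),
    sprintf("#cds_length\t%d", model$cds_length),
    "exon\tstart\tend")
  body <- sprintf("%d\t%d\t%d", model$exons$exon, model$exons$start, model$exons$end)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "\t"))
  vals <- setNames(kv[, 2], kv[, 1])
  body <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                     sep = "\t")
  gene_model(body[, c("start", "end")],
             chrom = vals[["chrom"]], strand = vals[["strand"]],
             cds_start_offset = as.integer(vals[["cds_start_offset"]]),
             cds_length = as.integer(vals[["cds_length"]]),
             gene_id = vals[["gene_id"]], transcript_id = vals[["transcript_id"]])
}
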