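#' Read and write FASTQ / FASTA via Biostrings
#'
#' Reads are written with constant Q30 quality strings, matching the
#' simulator's error model (errors are injected independently of quality).
#'
#' @param reads Tibble with `read_id`, `mate`, `seq`.
#' @param prefix Output prefix; mates go to `<prefix>_R1.fastq` /
#'   `<prefix>_R2.fastq`.
#' @return Character vector of written paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix) {
  paths <- character(0)
  for (m in sort(unique(reads$mate))) {
    sub <- reads[reads$mate == m, ]
    x <- Biostrings::DNAStringSet(sub$seq)
    names(x) <- paste0(sub$read_id, "/", m)
    q <- Biostrings::BStringSet(strrep("?", nchar(sub$seq)))
    path <- sprintf("%s_R%d.fastq", prefix, m)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_fastq_pair
#' @param paths FASTQ paths (one per mate, in mate order).
#' @return `read_fastq_pair()`: tibble with `read_id`, `mate`, `seq`.
#' @export
read_fastq_pair <- function(paths) {
  out <- purrr::imap(paths, function(p, m) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    tibble(read_id = sub("/[12]$", "", names(x)), mate = as.integer(m),
           seq = unname(as.character(x)))
  })
  bind_rows(out)
}

#' @rdname write_fastq_pair
#' @param seq Sequence(s) to write.
#' @param names Sequence names.
#' @param path FASTA path.
#' @export
write_fasta <- function(seq, names, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- names
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fastq_pair
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read a repeat track as BED6
#'
#' BED uses 0-based half-open coordinates; the in-memory track is 1-based
#' inclusive. The element family goes in the BED name column.
#'
#' @param track Tibble with `start`, `end`, `family`, `strand`.
#' @param path BED path.
#' @param chrom Contig name.
#' @return `path` / a track tibble.
#' @export
write_repeat_bed <- function(track, path, chrom = "PLCG2_locus") {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   chrom, track$start - 1L, track$end, track$family,
                   track$strand)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_repeat_bed
#' @export
read_repeat_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start0", "end", "family", "score",
                                 "strand"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "character", "character"))
  tibble(start = df$start0 + 1L, end = df$end, family = df$family,
         strand = df$strand)
}

#' Write a junction table as BED (0-based half-open gap intervals)
#'
#' @param jt A [junction_table()] result.
#' @param path BED path.
#' @param chrom Contig name.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(jt, path, chrom) {
  lines <- sprintf("%s\t%d\t%d\tjunction\t%d\t+",
                   chrom, jt$left, jt$right, jt$support)
  writeLines(lines, path)
  invisible(path)
}

# TSV with '#'-prefixed header line
write_report_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

read_report_tsv <- function(path) {
  lines <- readLines(path)
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  if (length(lines) == 1L) {
    return(as_tibble(setNames(rep(list(character(0)), length(header)), header)))
  }
  as_tibble(read.table(text = lines[-1], sep = "\t", header = FALSE,
                       col.names = header, stringsAsFactors = FALSE))
}
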