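# Shared fixtures, cached so expensive simulations run once per test session.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# preset reference locus (seed fixed; every test that only needs geometry or
# sequence shares this object)
preset_ref <- function() cached("preset_ref", build_reference(sim_config(seed = 101)))

# a full preset cohort at moderate depth, for tests of the screen machinery
preset_cohort <- function() {
  cached("preset_cohort", simulate_cohort(sim_config(seed = 101, amplicon_depth = 600)))
}

# genomic-mode alignments for the two preset trios of the cached cohort
preset_trio_aln <- function(trio) {
  key <- paste0("trio_aln_", trio)
  cached(key, {
    co <- preset_cohort()
    ref <- co$reference
    lapply(co$trios[[trio]]$members, function(r) {
      align_reads(r, ref$seq, ref$model, mode = "genomic", keep_seq = TRUE)
    })
  })
}

# small hand-made gene model: 4 exons on a 520 nt contig, exon lengths chosen
# so that some skips are in-frame (exon 3: 27 nt) and some frameshift
# (exon 2: 40 nt)
toy_model <- function() {
  gene_model(
    exons = tibble::tibble(start = c(20L, 120L, 220L, 320L),
                           end   = c(80L, 160L, 247L, 420L)),
    chrom = "toy", cds_start_offset = 10, cds_length = 150)
}

# random DNA string
rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# 0-based spliced coordinate of a c. position (independent re-derivation of
# the package's coordinate arithmetic, used as an oracle)
c_to_spliced_vec <- function(model, base, region) {
  as.integer(ifelse(region == "cds", model$cds_start_offset + base - 1L,
             ifelse(region == "utr5", model$cds_start_offset + base,
                    model$cds_start_offset + model$cds_length + base - 1L)))
}

# brute-force one-gap alignment oracle: best placement of `read` on `ref`
# as prefix + gap + suffix with gap >= min_gap, mismatch-free. Returns all
# zero-mismatch placements as a tibble(split, left, right): read[1..split]
# maps ending at 0-based ref offset `left`, remainder resumes at `right`.
one_gap_placements <- function(read, ref, min_gap = 50L) {
  n <- nchar(read); L <- nchar(ref)
  out <- list()
  for (split in seq_len(n - 1L)) {
    pre <- substr(read, 1L, split)
    suf <- substr(read, split + 1L, n)
    pre_hits <- stringr::str_locate_all(ref, stringr::fixed(pre))[[1]][, 1]
    suf_hits <- stringr::str_locate_all(ref, stringr::fixed(suf))[[1]][, 1]
    for (p in pre_hits) {
      left <- p - 1L + split              # 0-based end of prefix block
      for (s in suf_hits) {
        right <- s - 1L                   # 0-based start of suffix block
        if (right - left >= min_gap) {
          out[[length(out) + 1L]] <- tibble::tibble(
            split = split, left = left, right = right)
        }
      }
    }
  }
  dplyr::bind_rows(out)
}
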