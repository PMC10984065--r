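#' Quantification and candidate-flagging thresholds
#'
#' Defaults follow the screen's reporting conventions: skip transcripts are
#' reported at >= 5% of informative reads, flagged as potentially causal
#' above 10%, shaded as high-proportion above 30%, and called novel only when
#' below 5% in every healthy control.
#'
#' @param report_threshold Minimum fraction for a signature to appear in the
#'   per-subject report (the full table always retains everything).
#' @param flag_threshold Fraction above which a signature is a candidate.
#' @param high_proportion_threshold Fraction above which a signature is
#'   labelled high-proportion.
#' @param control_absence_threshold A candidate must stay below this fraction
#'   in every healthy control ("not observed in healthy subjects",
#'   operationalized with a noise floor rather than literal zero).
#' @param regulatory_exons Exons of the autoinhibitory/regulatory region
#'   (default 18-22, the span implicated by known and novel disease-causing
#'   deletions).
#' @param boundary_tolerance Coordinate tolerance (nt) when matching junction
#'   edges to annotated boundaries (default 0: the aligner already snaps).
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(report_threshold = 0.05, flag_threshold = 0.10,
                         high_proportion_threshold = 0.30,
                         control_absence_threshold = 0.05,
                         regulatory_exons = 18:22,
                         boundary_tolerance = 0L) {
  if (!(report_threshold > 0 && report_threshold <= flag_threshold &&
        flag_threshold <= high_proportion_threshold &&
        high_proportion_threshold <= 1)) {
    abort("need 0 < report <= flag <= high_proportion <= 1")
  }
  structure(list(report_threshold = report_threshold,
                 flag_threshold = flag_threshold,
                 high_proportion_threshold = high_proportion_threshold,
                 control_absence_threshold = control_absence_threshold,
                 regulatory_exons = as.integer(regulatory_exons),
                 boundary_tolerance = as.integer(boundary_tolerance)),
            class = "quant_config")
}

#' Classify a cDNA junction against the gene model
#'
#' A junction whose edges coincide (within `tol`) with the end of exon a-1
#' and the start of exon b+1 on the spliced transcript is an exon skip of
#' exons a..b; a zero-length gap at an annotated boundary is a canonical
#' splice; anything else is noncanonical.
#'
#' @param left,right Junction edges (0-based: exclusive end of the left
#'   block, start of the right block) on the cDNA reference; vectorized.
#' @param model A [gene_model()].
#' @param tol Matching tolerance in nt.
#' @return Tibble with `left`, `right`, `class`
#'   (`exon_skip`/`canonical_splice`/`noncanonical`) and `label` (skip label
#'   or `NA`).
#' @export
classify_junction <- function(left, right, model, tol = 0L) {
  b <- cdna_boundaries(model)  # boundary j at cum end of exon j
  match_b <- function(x) {
    hit <- which(abs(b - x) <= tol)
    if (length(hit) == 1L) hit else NA_integer_
  }
  n <- max(length(left), length(right))
  left <- rep_len(as.integer(left), n)
  right <- rep_len(as.integer(right), n)
  res <- purrr::map2(left, right, function(l, r) {
    if (r == l) {
      j <- match_b(l)
      if (!is.na(j)) return(list(class = "canonical_splice", label = NA_character_))
      return(list(class = "noncanonical", label = NA_character_))
    }
    if (r < l) return(list(class = "noncanonical", label = NA_character_))
    i <- match_b(l)   # end of exon i
    j <- match_b(r)   # start of exon j+1
    if (!is.na(i) && !is.na(j) && j > i) {
      sig <- skip_signature((i + 1L):j)
      return(list(class = "exon_skip", label = format(sig)))
    }
    list(class = "noncanonical", label = NA_character_)
  })
  tibble(left = left, right = right,
         class = purrr::map_chr(res, "class"),
         label = purrr::map_chr(res, "label"))
}

#' Assign each read to a skip signature or support class
#'
#' A mapped read's class is the union of the exon-skip classifications of its
#' junctions; a read with any noncanonical junction is `noncanonical`; a
#' junction-free read spanning at least one annotated exon-exon boundary is
#' `canonical_support`; a junction-free read inside one exon is
#' `uninformative`.
#'
#' @param aln An [align_reads()] result (cDNA mode).
#' @param model A [gene_model()].
#' @param tol Junction matching tolerance (nt).
#' @return `aln` with an added `assignment` column (a skip label,
#'   `canonical_support`, `uninformative`, `noncanonical`, or the read
#'   status for unmapped/ambiguous reads).
#' @export
assign_reads <- function(aln, model, tol = 0L) {
  jsets <- unique(aln$junctions[aln$status == "mapped" & nzchar(aln$junctions)])
  lut <- setNames(vapply(jsets, function(js) {
    j <- parse_junctions(js)
    cls <- classify_junction(j$left, j$right, model, tol)
    if (any(cls$class == "noncanonical")) return("noncanonical")
    skips <- cls$label[cls$class == "exon_skip"]
    if (length(skips) == 0L) return("canonical_support")  # canonical splice(s) seen
    ex <- sort(unique(unlist(lapply(skips, function(s) unclass(parse_skip_label(s))))))
    format(skip_signature(ex))
  }, ""), jsets)
  assignment <- dplyr::case_when(
    aln$status != "mapped" ~ aln$status,
    nzchar(aln$junctions) ~ unname(lut[aln$junctions]),
    nzchar(aln$spans) ~ "canonical_support",
    TRUE ~ "uninformative")
  aln$assignment <- assignment
  aln
}

# Junction left edges per read row as a list of integers (mapped reads with
# junctions only); used for informative-read denominators.
junction_lefts <- function(aln) {
  out <- vector("list", nrow(aln))
  has <- aln$status == "mapped" & nzchar(aln$junctions)
  if (any(has)) {
    out[has] <- lapply(strsplit(aln$junctions[has], ";", fixed = TRUE),
                       function(v) as.integer(sub(":.*$", "", v)))
  }
  out
}

#' Quantify per-subject isoform fractions
#'
#' For each observed skip signature the fraction is
#' `supporting / informative`, where supporting reads carry exactly that
#' signature and informative reads are those that could have revealed the
#' event: reads spanning (with the aligner's minimum flank) the canonical
#' boundary replaced by the signature's first skip, either canonically or
#' via any junction starting there. The naive fraction over all mapped reads
#' is reported alongside (`fraction_total`), since either denominator
#' convention may be wanted.
#'
#' @param aln An [align_reads()] result for one subject (cDNA mode).
#' @param model A [gene_model()].
#' @param config A [quant_config()].
#' @param subject_id Subject label for the output.
#' @return Tibble (full table) with `subject_id`, `label`, `frame`,
#'   `skipped_nt`, `supporting_reads`, `informative_reads`, `fraction`,
#'   `fraction_total`, `reported` (fraction >= report threshold),
#'   `undefined` (no informative reads). Signatures below the report
#'   threshold are retained with `reported = FALSE`.
#' @export
quantify_subject <- function(aln, model, config = quant_config(),
                             subject_id = "S1") {
  aln <- assign_reads(aln, model, config$boundary_tolerance)
  mapped <- aln[aln$status == "mapped", ]
  n_mapped <- nrow(mapped)
  b <- cdna_boundaries(model)

  # denominator pieces per boundary index
  span_counts <- integer(length(b))
  sp <- mapped$spans[nzchar(mapped$spans)]
  if (length(sp)) {
    tab <- table(as.integer(unlist(strsplit(sp, ",", fixed = TRUE))))
    span_counts[as.integer(names(tab))] <- as.integer(tab)
  }
  jl <- unlist(junction_lefts(mapped))
  jl_counts <- integer(length(b))
  if (length(jl)) {
    hit <- match(jl, b)
    tab <- table(hit[!is.na(hit)])
    jl_counts[as.integer(names(tab))] <- as.integer(tab)
  }
  informative_at <- span_counts + jl_counts

  sig_labels <- setdiff(unique(mapped$assignment),
                        c("canonical_support", "uninformative", "noncanonical"))
  if (length(sig_labels) == 0L) {
    return(tibble(subject_id = character(0), label = character(0),
                  frame = character(0), skipped_nt = integer(0),
                  supporting_reads = integer(0), informative_reads = integer(0),
                  fraction = numeric(0), fraction_total = numeric(0),
                  reported = logical(0), undefined = logical(0)))
  }
  rows <- purrr::map(sig_labels, function(lab) {
    sig <- parse_skip_label(lab)
    first_b <- min(unclass(sig)) - 1L  # boundary replaced by the first skip
    fr <- skip_frame(model, sig)
    supp <- sum(mapped$assignment == lab)
    info <- if (first_b >= 1L && first_b <= length(b)) informative_at[first_b] else 0L
    tibble(subject_id = subject_id, label = lab, frame = fr$frame,
           skipped_nt = fr$skipped_nt,
           supporting_reads = supp, informative_reads = info,
           fraction = if (info > 0L) supp / info else NA_real_,
           fraction_total = if (n_mapped > 0L) supp / n_mapped else NA_real_,
           undefined = info == 0L)
  })
  out <- bind_rows(rows)
  out$reported <- !out$undefined & out$fraction >= config$report_threshold
  arrange(out, desc(.data$fraction))
}

#' Display labels for the fraction bins of a quant configuration
#' @param config A [quant_config()].
#' @return Character vector of four bin labels.
#' @export
fraction_bin_labels <- function(config = quant_config()) {
  pct <- function(x) sprintf("%g%%", 100 * x)
  c(paste0("<", pct(config$report_threshold)),
    paste0(pct(config$report_threshold), "-", pct(config$flag_threshold)),
    paste0(pct(config$flag_threshold), "-", pct(config$high_proportion_threshold)),
    paste0(">", pct(config$high_proportion_threshold)))
}

#' Flag candidate causal transcripts across a cohort
#'
#' A (subject, signature) pair is a candidate iff its fraction exceeds the
#' flag threshold, the skip is in frame, it touches the regulatory-region
#' exons, and its fraction stays below the control-absence threshold in every
#' healthy control. High-proportion signatures are labelled for matrix-style
#' display. Without any healthy control the novelty filter is disabled with a
#' warning.
#'
#' @param quants Row-bound [quantify_subject()] tables for the whole cohort.
#' @param roster Tibble with `subject_id`, `role` (`proband`,
#'   `healthy_control`, `positive_control`).
#' @param model A [gene_model()].
#' @param config A [quant_config()].
#' @return An object of class `cohort_screen`: list with `candidates`
#'   (tibble), `quants` (annotated full table), `roster`, `config`.
#' @export
flag_candidates <- function(quants, roster, model, config = quant_config()) {
  roster <- as_tibble(roster)
  quants <- as_tibble(quants)
  hc <- roster$subject_id[roster$role == "healthy_control"]
  if (length(hc) == 0L) {
    warn("no healthy controls in the roster: novelty filter disabled")
  }
  # max fraction of each signature across healthy controls (0 if never seen)
  ctrl <- quants |>
    filter(.data$subject_id %in% hc) |>
    group_by(.data$label) |>
    summarise(control_max = max(.data$fraction, 0, na.rm = TRUE),
              .groups = "drop")
  q <- quants |>
    left_join(roster, by = "subject_id") |>
    left_join(ctrl, by = "label") |>
    mutate(
      control_max = dplyr::coalesce(.data$control_max, 0),
      regulatory = purrr::map_lgl(
        .data$label,
        function(l) length(intersect(unclass(parse_skip_label(l)),
                                     config$regulatory_exons)) > 0),
      in_frame = .data$frame == "in_frame",
      absent_in_controls = if (length(hc) == 0L) TRUE
                           else .data$control_max < config$control_absence_threshold,
      high_proportion = !is.na(.data$fraction) &
        .data$fraction > config$high_proportion_threshold,
      # not cut(): coinciding thresholds are a legal configuration and must
      # collapse bins rather than error on duplicate breaks
      bin = factor(dplyr::case_when(
        is.na(.data$fraction) ~ NA_character_,
        .data$fraction <= config$report_threshold ~ fraction_bin_labels(config)[1],
        .data$fraction <= config$flag_threshold ~ fraction_bin_labels(config)[2],
        .data$fraction <= config$high_proportion_threshold ~ fraction_bin_labels(config)[3],
        TRUE ~ fraction_bin_labels(config)[4]),
        levels = unique(fraction_bin_labels(config))),
      candidate = !is.na(.data$fraction) &
        .data$fraction > config$flag_threshold &
        .data$in_frame & .data$regulatory & .data$absent_in_controls)
  structure(
    list(candidates = filter(q, .data$candidate),
         quants = q, roster = roster, config = config, model = model),
    class = "cohort_screen")
}

#' @export
print.cohort_screen <- function(x, ...) {
  cat(sprintf("<cohort_screen> %d subjects, %d signatures, %d candidate rows in %d subjects\n",
              nrow(x$roster), length(unique(x$quants$label)),
              nrow(x$candidates), length(unique(x$candidates$subject_id))))
  if (nrow(x$candidates)) {
    print(x$candidates[, c("subject_id", "role", "label", "fraction", "frame")])
  }
  invisible(x)
}
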