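#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cohort screen
#'
#' @param x A [flag_candidates()] `cohort_screen`.
#' @param ... Unused.
#' @return The annotated per-(subject, signature) quantification tibble.
#' @export
tidy.cohort_screen <- function(x, ...) {
  as_tibble(x$quants)
}

#' @rdname tidy.cohort_screen
#' @return `glance()`: one-row summary (subjects, signatures, candidate
#'   subjects by role).
#' @export
glance.cohort_screen <- function(x, ...) {
  cand <- x$candidates |> dplyr::distinct(.data$subject_id, .data$role)
  tibble(
    n_subjects = nrow(x$roster),
    n_signatures = length(unique(x$quants$label)),
    n_candidate_subjects = nrow(cand),
    n_candidate_probands = sum(cand$role == "proband"),
    n_candidate_controls = sum(cand$role == "healthy_control"))
}

#' Tidy a deletion call
#'
#' @param x A [call_deletion()] result.
#' @param ... Unused.
#' @return Per-member support/genotype tibble with call coordinates attached.
#' @export
tidy.deletion_call <- function(x, ...) {
  x$members |>
    mutate(chrom = x$chrom, start = x$start, end = x$end, .before = 1)
}

#' @rdname tidy.deletion_call
#' @export
glance.deletion_call <- function(x, ...) {
  tibble(chrom = x$chrom, start = x$start, end = x$end, length = x$length,
         de_novo = x$de_novo, inheritance = x$inheritance,
         first_exon = min(x$affected_exons), last_exon = max(x$affected_exons))
}

#' Tidy a mechanism call
#'
#' @param x A [classify_mechanism()] result.
#' @param ... Unused.
#' @return Per-end overlapping elements with the classification attached.
#' @export
tidy.mechanism_call <- function(x, ...) {
  bind_rows(
    mutate(x$left, end_side = "left"),
    mutate(x$right, end_side = "right")) |>
    mutate(classification = x$classification)
}

#' @rdname tidy.mechanism_call
#' @export
glance.mechanism_call <- function(x, ...) {
  tibble(classification = x$classification,
         left_elements = nrow(x$left), right_elements = nrow(x$right))
}

#' Span of a deletion from its printed 1-based breakpoints
#'
#' Utility for reading published deletion coordinates of the form
#' `chr16.81944583_81958780del`: the span in nt is `end - start + 1`.
#'
#' @param start,end 1-based inclusive breakpoints, or `label` a string like
#'   `"chr16.81944583_81958780del"`.
#' @param label Optional label to parse instead of `start`/`end`.
#' @return List with `span_nt` and `span_kb` (rounded to the nearest kb).
#' @export
#' @examples
#' deletion_span(label = "chr16.81944583_81958780del")$span_kb
deletion_span <- function(start = NULL, end = NULL, label = NULL) {
  if (!is.null(label)) {
    m <- regmatches(label, regexec("(\\d+)_(\\d+)del", label))[[1]]
    if (length(m) != 3L) abort("cannot parse deletion label")
    start <- as.numeric(m[2]); end <- as.numeric(m[3])
  }
  span <- end - start + 1
  list(span_nt = span, span_kb = round(span / 1000))
}
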