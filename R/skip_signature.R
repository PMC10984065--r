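#' Exon-skip signature
#'
#' A skip signature names the set of exons absent from an alternative
#' transcript, e.g. \eqn{\Delta}19-22 for a transcript missing exons 19
#' through 22. Contiguous runs render as `"Δ19-22"`; non-contiguous sets
#' are comma-joined (`"Δ2,4-5"`).
#'
#' @param exons Integer vector of skipped exon numbers (non-empty).
#' @return An object of class `skip_signature` (sorted unique integer vector).
#' @export
#' @examples
#' format(skip_signature(19:22))
skip_signature <- function(exons) {
  ex <- sort(unique(as.integer(exons)))
  if (length(ex) == 0L || anyNA(ex) || any(ex < 1L)) {
    abort("a skip signature must name at least one positive exon number")
  }
  structure(ex, class = "skip_signature")
}

#' @export
format.skip_signature <- function(x, ...) {
  ex <- unclass(x)
  runs <- split(ex, cumsum(c(1L, diff(ex) != 1L)))
  parts <- vapply(runs, function(r) {
    if (length(r) == 1L) as.character(r) else sprintf("%d-%d", r[1], r[length(r)])
  }, "")
  paste0("Δ", paste(parts, collapse = ","))
}

#' @export
print.skip_signature <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a skip-signature label back to the exon set
#'
#' Inverse of `format.skip_signature()`; also accepts an ASCII `"del"` prefix.
#'
#' @param label Character vector of labels such as `"Δ19-22"`.
#' @return A list of [skip_signature()] objects (a single object if
#'   `length(label) == 1`).
#' @export
parse_skip_label <- function(label) {
  one <- function(lab) {
    body <- sub("^(Δ|del)", "", lab)
    if (!nzchar(body)) abort(sprintf("cannot parse skip label '%s'", lab))
    parts <- strsplit(body, ",", fixed = TRUE)[[1]]
    ex <- unlist(lapply(parts, function(p) {
      if (grepl("-", p, fixed = TRUE)) {
        ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
        seq(ab[1], ab[2])
      } else as.integer(p)
    }))
    if (anyNA(ex)) abort(sprintf("cannot parse skip label '%s'", lab))
    skip_signature(ex)
  }
  out <- lapply(label, one)
  if (length(out) == 1L) out[[1]] else out
}
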