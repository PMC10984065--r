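#' Intersect deletion breakpoints with a repeat-element track
#'
#' Each breakpoint, padded by `pad` nt on both sides, is intersected
#' (half-open interval overlap) against the repeat track. Deletions arising
#' from recombination between aligned repeat pairs (classically Alu-Alu)
#' leave a repeat element overlapping both breakpoints.
#'
#' @param del A [call_deletion()] result or list with `start`, `end`
#'   (1-based inclusive).
#' @param track Repeat track tibble (`start`, `end` 1-based inclusive,
#'   `family` in Alu/other_SINE/LINE/LTR/other, `strand`).
#' @param pad Breakpoint padding (nt); default 10, matching the caller's
#'   breakpoint uncertainty.
#' @return List with `left` and `right`: tibbles of overlapping elements.
#' @export
breakpoint_repeat_intersect <- function(del, track, pad = 10L) {
  if (pad < 0) abort("pad must be >= 0")
  track <- as_tibble(track)
  fam_ok <- c("Alu", "other_SINE", "LINE", "LTR", "other")
  if (nrow(track) > 0 && !all(track$family %in% fam_ok)) {
    abort("repeat families must be one of Alu/other_SINE/LINE/LTR/other")
  }
  hit <- function(p) {
    if (nrow(track) == 0) return(track)
    # breakpoint window [p - pad, p + pad] (1-based incl) vs element [s, e]
    track[track$start <= p + pad & track$end >= p - pad, ]
  }
  if (nrow(track) > 0 && (del$start > max(track$end) + pad ||
                          del$end < min(track$start) - pad)) {
    warn("deletion breakpoints lie outside the repeat track's coordinate space")
  }
  list(left = hit(del$start), right = hit(del$end))
}

#' Classify the deletional mechanism from breakpoint repeat overlaps
#'
#' Decision table: `alu_mediated` iff both breakpoints overlap Alu elements
#' sharing a common strand (the aligned-repeat configuration required for
#' recombination); otherwise `repeat_both_ends` if both ends overlap any
#' element, `repeat_one_end` if only one does, else `none`.
#'
#' @param overlaps Output of [breakpoint_repeat_intersect()].
#' @return An object of class `mechanism_call`: list with `classification`
#'   and the per-end overlap tibbles.
#' @export
classify_mechanism <- function(overlaps) {
  l <- overlaps$left; r <- overlaps$right
  alu_strands <- function(x) unique(x$strand[x$family == "Alu"])
  shared <- intersect(alu_strands(l), alu_strands(r))
  classification <- if (length(shared) > 0) {
    "alu_mediated"
  } else if (nrow(l) > 0 && nrow(r) > 0) {
    "repeat_both_ends"
  } else if (nrow(l) > 0 || nrow(r) > 0) {
    "repeat_one_end"
  } else "none"
  structure(list(classification = classification, left = l, right = r),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s (left: %d element(s), right: %d element(s))\n",
              x$classification, nrow(x$left), nrow(x$right)))
  invisible(x)
}
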