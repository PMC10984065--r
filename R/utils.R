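#' Random DNA sequence
#'
#' Draws an i.i.d. uniform A/C/G/T sequence using the current RNG state.
#'
#' @param n Sequence length in nucleotides.
#' @return A single character string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse-complement character sequences
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

# Replace bases of `seq` (single string) at 1-based positions `pos` with `base`.
replace_bases <- function(seq, pos, base) {
  if (length(pos) == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  v[pos] <- base
  paste(v, collapse = "")
}

# Draw a base different from each element of `ref`.
other_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
}

assert_scalar_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer", name))
  }
  as.integer(x)
}
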