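#' Reverse-complement a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert an RNA string to its DNA representation (U -> T)
#' @param x Character vector.
#' @return Character vector with U/u replaced by T/t.
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# collapse an integer/character vector to a comma string ("." if empty)
.collapse <- function(x) {
  if (length(x) == 0L) "." else paste(x, collapse = ",")
}

# inverse of .collapse for integers / characters
.uncollapse_int <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(v) {
    if (identical(v, ".") || length(v) == 0L) integer(0) else as.integer(v)
  })
}
.uncollapse_chr <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(v) {
    if (identical(v, ".") || length(v) == 0L) character(0) else v
  })
}

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}
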