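`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a nucleotide string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of nucleotide strings (ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# uniform random DNA string; composition realism is deliberately out of scope
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# pick a base different from every base in `avoid`
other_base <- function(avoid) {
  pool <- setdiff(c("A", "C", "G", "T"), toupper(avoid))
  pool[1L]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "", ...)
}
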