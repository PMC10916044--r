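# Internal sequence helpers. Probe/manifest sequences are plain uppercase
# character vectors; Biostrings is used where its primitives fit (FASTA IO,
# reverseComplement) but these small helpers avoid round-tripping through
# XString objects in hot inner loops.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                    R = "Y", Y = "R", N = "N")

assert_dna <- function(x, alphabet = c("A", "C", "G", "T"), what = "sequence") {
  bad <- !grepl(paste0("^[", paste(alphabet, collapse = ""), "]*$"), x)
  if (any(bad)) {
    abort(sprintf("invalid %s alphabet in: %s", what,
                  paste(head(x[bad], 3L), collapse = ", ")))
  }
  invisible(x)
}

#' Reverse-complement a DNA character vector
#'
#' Complements IUPAC codes A/C/G/T/R/Y/N (so the degenerate Type II body
#' code Y maps to R and back) and reverses each string. An involution:
#' `revcomp(revcomp(x)) == x`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGT")
#' revcomp("AYG") # Y complements to R
revcomp <- function(x) {
  assert_dna(x, names(DNA_COMPLEMENT), "DNA")
  comp <- chartr(paste(names(DNA_COMPLEMENT), collapse = ""),
                 paste(DNA_COMPLEMENT, collapse = ""), x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

complement_chr <- function(x) {
  chartr(paste(names(DNA_COMPLEMENT), collapse = ""),
         paste(DNA_COMPLEMENT, collapse = ""), x)
}

# substring by 0-based [start, end) interval
substr0 <- function(x, start0, end0) substr(x, start0 + 1L, end0)

`%+%` <- function(a, b) paste0(a, b)
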