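# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Sequences are held in the RNA alphabet
#' throughout the package; DNA input (FASTA/FASTQ) is converted on read.
#'
#' @param x character vector of sequences.
#' @return character vector in the RNA alphabet.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

# DNA view used for Biostrings matching
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement in the RNA alphabet
#' @param x character vector of RNA sequences.
#' @return reverse-complemented sequences.
#' @export
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("AUGC", "UACG", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Watson-Crick (+ optional GU wobble) pair test, vectorized
rna_pairs <- function(a, b, allow_gu = TRUE) {
  p <- paste0(a, b)
  wc <- p %in% c("AU", "UA", "GC", "CG")
  if (allow_gu) wc | p %in% c("GU", "UG") else wc
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# trapezoidal integral of y over x restricted to [a, b)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
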