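NUCS <- c("A", "C", "G", "T")

# A<->T, C<->G row permutation for 4 x k matrices ordered A,C,G,T
COMP_IDX <- c(4L, 3L, 2L, 1L)

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences over A/C/G/T/N (case kept upper).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- substring(a, seq_len(n), seq_len(n))
  bv <- substring(b, seq_len(n), seq_len(n))
  d <- which(av != bv)
  if (!length(d)) n else d[1L] - 1L
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

vg_log <- function(fmt, ...) {
  message(sprintf("[vgmotif %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}
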