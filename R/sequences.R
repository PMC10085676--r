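#' Coerce a character string to a validated RNA sequence
#'
#' Sequences are plain uppercase character scalars over `{A, C, G, U}`.
#' DNA input is accepted: `T` is silently transcribed to `U` (plasmid
#' sequences are DNA). Any other character is rejected with the 1-based
#' position of the first offender.
#'
#' @param x a character scalar (RNA or DNA).
#' @param what label used in error messages.
#' @return an uppercase RNA character scalar.
#' @examples
#' as_rna("acgt")  # "ACGU"
#' @export
as_rna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  if (nchar(x) == 0L) stop(what, " must be nonempty", call. = FALSE)
  bad <- regexpr("[^ACGU]", x)
  if (bad > 0L) {
    stop(
      sprintf("%s contains illegal character '%s' at position %d",
              what, substr(x, bad, bad), bad),
      call. = FALSE
    )
  }
  x
}

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Complement and reverse-complement of an RNA sequence
#'
#' @param x an RNA sequence (coerced with [as_rna()]).
#' @return an RNA character scalar.
#' @examples
#' rna_revcomp("GAUC")  # "GAUC"
#' @export
rna_revcomp <- function(x) {
  x <- as_rna(x)
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

#' @rdname rna_revcomp
#' @export
rna_complement <- function(x) {
  x <- as_rna(x)
  as.character(Biostrings::complement(Biostrings::RNAString(x)))
}

#' Read and write FASTA sequence files
#'
#' `load_fasta()` reads a FASTA file and returns a named character vector of
#' RNA sequences (ids preserved verbatim, `T` normalized to `U`); characters
#' outside the nucleotide alphabet raise an error naming the record and
#' position. `write_fasta()` writes a named character vector back out.
#' The two round-trip: `load_fasta(write_fasta(x)) == x`.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `load_fasta()`: a named character vector of RNA sequences.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (length(content) == 0L) stop("FASTA parse error: file is empty", call. = FALSE)
  if (!startsWith(trimws(lines[content[1L]]), ">")) {
    stop("FASTA parse error at line ", content[1L],
         ": expected a '>' header record", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  out <- vapply(
    seq_along(set),
    function(i) as_rna(as.character(set[[i]]), what = sprintf("record '%s'", names(set)[i])),
    character(1)
  )
  names(out) <- names(set)
  out
}

#' @rdname load_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
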