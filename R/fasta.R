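#' Read sequences from a FASTA file
#'
#' Sequences are returned as a named character vector of upper-case residue
#' strings, one element per FASTA record, in file order. The name is the
#' full header line (without the leading `>`); use [short_ids()] to trim
#' descriptions. Gap characters (`-`) and IUPAC ambiguity codes are kept
#' as-is.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
#' @examples
#' f <- system.file("extdata", "pbs_pair.fasta", package = "paleofoam")
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("FASTA format error: file is empty: ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("FASTA format error at line ", first,
         ": expected a '>' header, got: ", substr(lines[first], 1L, 40L))
  }
  set <- Biostrings::readBStringSet(path)
  if (any(!nzchar(names(set)))) stop("FASTA format error: empty header in ", path)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("FASTA format error: empty sequence for record '",
         names(seqs)[!nzchar(seqs)][1L], "'")
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), length(seqs) > 0L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Trim FASTA headers to their first whitespace-delimited token
#' @param seqs Named character vector.
#' @return The same vector with shortened names.
#' @export
short_ids <- function(seqs) {
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

# Character matrix view of an alignment (rows = sequences, cols = columns).
aln_matrix <- function(aln) {
  stopifnot(is.character(aln), length(aln) >= 1L)
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ", "))
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Reverse complement of a nucleotide string
#' @param x Single DNA string (IUPAC codes and gaps allowed).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Uniform random DNA string (internal helper shared by the simulator).
random_dna <- function(n, seed = NULL) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""))
}
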