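#' Annotate coding defects in an endogenous viral element
#'
#' Endogenous copies decay neutrally after germline integration, accumulating
#' in-frame stop codons and frameshifting indels that mark them as
#' functionally dead. This scans a declared reading frame for premature stop
#' codons (TAA/TAG/TGA; the terminal codon of the span is not counted) and,
#' when a pairwise alignment to an intact homolog is supplied, reports indels
#' whose length is not a multiple of 3 as frameshifts.
#'
#' @param seq Single named nucleotide string.
#' @param orf_start,orf_end 0-based half-open span of the reading frame on
#'   `seq`; the frame is frame 0 of the span on the given strand.
#' @param reference_aln Optional pairwise alignment (named character vector of
#'   length 2, equal lengths, gaps as `-`): the query copy first, an intact
#'   homolog second.
#' @param strand `"+"` or `"-"`; for `"-"` the span is reverse-complemented
#'   before scanning.
#' @return A list of class `defect_report`: `stop_positions` (0-based codon
#'   indices of premature stops), `stop_codons`, `frameshift_indels`
#'   (data.frame with 0-based alignment `position`, `length`, `type`
#'   ins/del relative to the query), `frame` (0), `strand`.
#' @export
#' @examples
#' annotate_defects(c(x = "ATGTAAAAATAG"), 0, 12)$stop_positions
annotate_defects <- function(seq, orf_start, orf_end, reference_aln = NULL,
                             strand = "+") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq[[1L]])
  L <- nchar(s)
  if (!(orf_start >= 0 && orf_start < orf_end && orf_end <= L))
    stop("ORF span [", orf_start, ", ", orf_end, ") invalid for sequence of length ", L)
  if (grepl("[^ACGTN-]", s)) stop("non-nucleotide alphabet in sequence")
  strand <- match.arg(strand, c("+", "-"))

  span <- substr(s, orf_start + 1L, orf_end)
  if (strand == "-") span <- revcomp(span)
  n_codon <- nchar(span) %/% 3L
  stops <- integer(0)
  codons <- character(0)
  if (n_codon >= 1L) {
    starts <- seq.int(1L, by = 3L, length.out = n_codon)
    cod <- substring(span, starts, starts + 2L)
    hit <- which(cod %in% c("TAA", "TAG", "TGA"))
    hit <- hit[hit < n_codon]          # terminal codon excluded
    stops <- hit - 1L                  # 0-based codon indices
    codons <- cod[hit]
  }

  fs <- data.frame(position = integer(0), length = integer(0),
                   type = character(0), stringsAsFactors = FALSE)
  if (!is.null(reference_aln)) {
    if (length(reference_aln) != 2L)
      stop("reference_aln must contain exactly 2 aligned sequences (query, reference)")
    m <- aln_matrix(reference_aln)
    indels <- rbind(gap_runs(m[1L, ], "del"),   # gaps in query = deletions
                    gap_runs(m[2L, ], "ins"))   # gaps in reference = insertions
    if (nrow(indels)) {
      fs <- indels[indels$length %% 3L != 0L, , drop = FALSE]
      fs <- fs[order(fs$position), , drop = FALSE]
      rownames(fs) <- NULL
    }
  }

  res <- list(stop_positions = stops, stop_codons = codons,
              frameshift_indels = fs, frame = 0L, strand = strand)
  class(res) <- "defect_report"
  res
}

# Runs of '-' in an aligned row, as 0-based alignment positions.
gap_runs <- function(row, type) {
  r <- rle(row == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  data.frame(position = starts[i] - 1L, length = r$lengths[i],
             type = rep(type, length(i)), stringsAsFactors = FALSE)
}

#' @export
print.defect_report <- function(x, ...) {
  cat("Defect report (frame ", x$frame, ", strand ", x$strand, "): ",
      length(x$stop_positions), " premature stop(s), ",
      nrow(x$frameshift_indels), " frameshift indel(s)\n", sep = "")
  invisible(x)
}

#' @export
format.defect_report <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}
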