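# IUPAC ambiguity code for a set of bases.
iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  out <- codes[[key]]
  if (is.null(out)) "N" else out
}

#' Build a consensus sequence from aligned element copies
#'
#' Reconstructs a single representative sequence from a multiple alignment of
#' degenerate germline copies, the way an endogenous-virus consensus genome is
#' assembled from fragmented insertions. Per column the plurality non-gap base
#' is called when its support (fraction of non-gap characters carrying it)
#' reaches `min_support`; tied or under-supported columns receive the IUPAC
#' ambiguity code of the observed bases. Columns that are gaps in a majority
#' of records are treated as insertion noise and dropped.
#'
#' @param aln Named character vector of equal-length aligned nucleotide
#'   sequences (>= 2 records).
#' @param min_support Minimum support in `[0, 1]` for an unambiguous call.
#' @param id Name given to the consensus record.
#' @return A list of class `paleofoam_consensus` with elements `seq` (named
#'   character vector of length 1), `support` (per emitted column, fraction of
#'   non-gap characters matching the called base or base set) and
#'   `kept_columns` (original column indices retained).
#' @export
#' @examples
#' aln <- c(a = "ACGT", b = "ACGT", c = "ACGA")
#' build_consensus(aln)$seq
build_consensus <- function(aln, min_support = 0.5, id = "consensus") {
  if (length(aln) < 2L) stop("consensus requires at least 2 aligned records")
  stopifnot(min_support >= 0, min_support <= 1)
  m <- aln_matrix(aln)
  m[m == "."] <- "-"
  n <- nrow(m)

  gap_count <- colSums(m == "-")
  if (any(gap_count == n))
    warning(sum(gap_count == n), " all-gap column(s) dropped from consensus")
  keep <- which(gap_count <= n / 2 & gap_count < n)
  if (length(keep) == 0L) stop("no columns left after dropping gap-majority columns")

  bases <- c("A", "C", "G", "T")
  out <- character(length(keep))
  support <- numeric(length(keep))
  for (i in seq_along(keep)) {
    col <- m[, keep[i]]
    nongap <- col[col != "-"]
    cnt <- tabulate(match(nongap, bases), nbins = 4L)
    names(cnt) <- bases
    if (sum(cnt) == 0L) {         # only N / other ambiguity present
      out[i] <- "N"
      support[i] <- 0
      next
    }
    top <- max(cnt)
    winners <- bases[cnt == top]
    supp <- top / length(nongap)
    if (length(winners) == 1L && supp >= min_support) {
      out[i] <- winners
      support[i] <- supp
    } else {
      seen <- bases[cnt > 0L]
      out[i] <- iupac_code(seen)
      support[i] <- sum(cnt[seen]) / length(nongap)
    }
  }
  res <- list(seq = setNames(paste(out, collapse = ""), id),
              support = support, kept_columns = keep)
  class(res) <- "paleofoam_consensus"
  res
}

#' @export
print.paleofoam_consensus <- function(x, ...) {
  cat("Consensus sequence '", names(x$seq), "': ", nchar(x$seq),
      " columns (mean support ", sprintf("%.3f", mean(x$support)), ")\n", sep = "")
  invisible(x)
}
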