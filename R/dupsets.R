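#' Best ungapped sliding identity between two sequences
#'
#' Slides one sequence against the other over all offsets whose overlap is at
#' least `min_overlap` and returns the maximum fraction of matching positions
#' in the overlap. Deterministic and gap-free; intended for comparing flanking
#' host sequence of candidate segmental duplicates.
#'
#' @param a,b Nucleotide strings.
#' @param min_overlap Minimum overlap (bp) for an offset to count.
#' @return Maximum identity in `[0, 1]`, or `NA` if no offset reaches
#'   `min_overlap`.
#' @export
sliding_identity <- function(a, b, min_overlap = 100L) {
  va <- strsplit(toupper(a), "")[[1L]]
  vb <- strsplit(toupper(b), "")[[1L]]
  la <- length(va); lb <- length(vb)
  if (min(la, lb) < min_overlap) return(NA_real_)
  best <- NA_real_
  for (s in seq.int(-(la - min_overlap), lb - min_overlap)) {
    ia <- max(1L, 1L - s):min(la, lb - s)
    if (length(ia) < min_overlap) next
    ident <- mean(va[ia] == vb[ia + s])
    if (is.na(best) || ident > best) best <- ident
  }
  best
}

#' Group element copies into segmental-duplication sets by shared flanks
#'
#' Copies of an endogenous element that arose by segmental duplication of one
#' locus carry nearly identical flanking host sequence, whereas independent
#' integrations sit in unrelated flanks. Contigs are single-linkage clustered:
#' two contigs fall in the same set when either their upstream or their
#' downstream flanks align (ungapped sliding comparison) with identity >=
#' `min_flank_identity` over at least `flank_window` bp.
#'
#' @param contigs Named character vector of contig sequences.
#' @param coords data.frame with columns `contig_id`, `element_start`,
#'   `element_end` (0-based half-open element span within the contig) and
#'   optionally `strand` (`"+"`/`"-"`, default `"+"`). Contigs without a row
#'   are excluded with a warning.
#' @param flank_window Minimum aligned flank overlap in bp.
#' @param min_flank_identity Identity threshold in `[0, 1]`.
#' @return A list of class `dupset_partition`: `sets` (list of character
#'   vectors of contig ids, singletons included), `membership` (named integer
#'   vector), `identity` (symmetric matrix of best flank identities).
#' @export
identify_duplicate_sets <- function(contigs, coords, flank_window = 100L,
                                    min_flank_identity = 0.90) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  req <- c("contig_id", "element_start", "element_end")
  if (!all(req %in% names(coords)))
    stop("coords must contain columns: ", paste(req, collapse = ", "))
  if (is.null(coords$strand)) coords$strand <- "+"

  ids <- names(contigs)
  missing <- setdiff(ids, coords$contig_id)
  if (length(missing)) {
    warning("no flank annotation for contig(s): ",
            paste(missing, collapse = ", "), " - excluded")
    ids <- setdiff(ids, missing)
  }
  if (length(ids) == 0L) stop("no annotated contigs to cluster")

  flanks <- lapply(ids, function(id) {
    row <- coords[coords$contig_id == id, ][1L, ]
    s <- contigs[[id]]
    L <- nchar(s)
    if (!(row$element_start >= 0 && row$element_start <= row$element_end &&
          row$element_end <= L))
      stop("element span out of range for contig ", id)
    if (identical(row$strand, "-")) {  # orient so the element reads 5'->3'
      s <- revcomp(s)
      es <- L - row$element_end; ee <- L - row$element_start
    } else {
      es <- row$element_start; ee <- row$element_end
    }
    list(left = substr(s, 1L, es), right = substr(s, ee + 1L, L))
  })
  names(flanks) <- ids

  n <- length(ids)
  idm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(idm) <- 1
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    cand <- c(sliding_identity(flanks[[i]]$left,  flanks[[j]]$left,  flank_window),
              sliding_identity(flanks[[i]]$right, flanks[[j]]$right, flank_window))
    best <- if (all(is.na(cand))) NA_real_ else max(cand, na.rm = TRUE)
    idm[i, j] <- idm[j, i] <- best
    if (!is.na(best) && best >= min_flank_identity) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  membership <- setNames(match(roots, unique(roots)), ids)
  sets <- split(ids, membership)
  names(sets) <- NULL

  res <- list(sets = sets, membership = membership, identity = idm)
  class(res) <- "dupset_partition"
  res
}

#' @export
print.dupset_partition <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("Segmental-duplication partition: ", length(x$sets), " set(s) of size ",
      paste(sort(sizes, decreasing = TRUE), collapse = ", "), "\n", sep = "")
  invisible(x)
}
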