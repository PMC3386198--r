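#' Count transitions and transversions between two aligned sequences
#'
#' Pairwise-deletion comparison: alignment columns where either sequence
#' carries a gap, an `N`, or any ambiguity code are excluded from the sites
#' compared. Transitions are the purine and pyrimidine exchanges A<->G and
#' C<->T; every other mismatch is a transversion.
#'
#' @param a,b Nucleotide strings (aligned: equal length).
#' @param aligned Must be `TRUE`; unaligned input is not supported — align
#'   the pair first.
#' @return List of class `subst_counts`: `transitions`, `transversions`,
#'   `sites_compared`.
#' @export
#' @examples
#' count_substitutions("ACGT", "GCGT")
count_substitutions <- function(a, b, aligned = TRUE) {
  if (!aligned) stop("unaligned input is not supported; align the pair first")
  va <- strsplit(toupper(a[[1L]]), "")[[1L]]
  vb <- strsplit(toupper(b[[1L]]), "")[[1L]]
  if (length(va) != length(vb))
    stop("aligned sequences differ in length (", length(va), " vs ", length(vb), ")")
  bases <- c("A", "C", "G", "T")
  ok <- va %in% bases & vb %in% bases   # pairwise deletion of gaps/N/ambiguity
  va <- va[ok]; vb <- vb[ok]
  mism <- va != vb
  ts <- sum(mism & ((va == "A" & vb == "G") | (va == "G" & vb == "A") |
                    (va == "C" & vb == "T") | (va == "T" & vb == "C")))
  res <- list(transitions = ts, transversions = sum(mism) - ts,
              sites_compared = length(va))
  class(res) <- "subst_counts"
  res
}

#' Kimura two-parameter distance
#'
#' Evolutionary distance under the two-parameter substitution model that
#' treats transitions and transversions separately:
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`, with `P` and `Q` the
#' observed transition and transversion proportions. The sampling variance is
#' the standard delta-method expression. Saturated comparisons (either
#' logarithm argument non-positive) raise an error rather than returning a
#' non-finite distance, so downstream dating cannot silently propagate
#' nonsense.
#'
#' @param counts A `subst_counts` object from [count_substitutions()], or the
#'   first of two raw sequences (then `b` must be given).
#' @param b Optional second sequence when `counts` is a raw sequence.
#' @return List of class `paleofoam_dist`: `d`, `P`, `Q`, `variance`,
#'   `sites_compared`, `model = "K2P"`.
#' @export
#' @examples
#' k2p_distance(count_substitutions("ACGTACGTAC", "ACGTACGTGC"))
k2p_distance <- function(counts, b = NULL) {
  if (!inherits(counts, "subst_counts")) {
    if (is.null(b)) stop("supply a subst_counts object or two sequences")
    counts <- count_substitutions(counts, b)
  }
  n <- counts$sites_compared
  if (n <= 0L) stop("no comparable sites (sites_compared = 0)")
  P <- counts$transitions / n
  Q <- counts$transversions / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance saturated: 1-2P-Q = ", signif(w1, 4),
         ", 1-2Q = ", signif(w2, 4))
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  c1 <- 1 / w1
  c2 <- 1 / w2
  c3 <- (c1 + c2) / 2
  variance <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n
  res <- list(d = d, P = P, Q = Q, variance = variance,
              sites_compared = n, model = "K2P")
  class(res) <- "paleofoam_dist"
  res
}

#' Proportion of differing sites (p-distance)
#'
#' @inheritParams count_substitutions
#' @return A `paleofoam_dist` with `model = "p"` (variance `p(1-p)/n`).
#' @export
p_distance <- function(a, b) {
  cnt <- count_substitutions(a, b)
  n <- cnt$sites_compared
  if (n <= 0L) stop("no comparable sites")
  p <- (cnt$transitions + cnt$transversions) / n
  res <- list(d = p, P = cnt$transitions / n, Q = cnt$transversions / n,
              variance = p * (1 - p) / n, sites_compared = n, model = "p")
  class(res) <- "paleofoam_dist"
  res
}

#' Hamming distance between two equal-length sequences
#'
#' Counts mismatching positions; gap characters count as mismatches against
#' any residue. Used e.g. to compare short conserved motifs such as the
#' retroviral primer-binding site between an endogenous element and an extant
#' virus.
#'
#' @param a,b Equal-length strings.
#' @return Integer mismatch count.
#' @export
#' @examples
#' hamming_distance("TGGCACCCAACGTGGGG", "TGGCGCCCAACGTGGGG")
hamming_distance <- function(a, b) {
  va <- strsplit(toupper(a[[1L]]), "")[[1L]]
  vb <- strsplit(toupper(b[[1L]]), "")[[1L]]
  if (length(va) != length(vb))
    stop("sequences differ in length (", length(va), " vs ", length(vb), ")")
  sum(va != vb)
}

#' @export
print.paleofoam_dist <- function(x, ...) {
  cat(x$model, " distance: d = ", signif(x$d, 6),
      " (P = ", signif(x$P, 4), ", Q = ", signif(x$Q, 4),
      ", var = ", signif(x$variance, 4), ", n = ", x$sites_compared, ")\n", sep = "")
  invisible(x)
}

#' @export
print.subst_counts <- function(x, ...) {
  cat("Substitutions over ", x$sites_compared, " sites: ",
      x$transitions, " transition(s), ", x$transversions,
      " transversion(s)\n", sep = "")
  invisible(x)
}
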