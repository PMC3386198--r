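#' Date a germline duplication (or invasion) from a pairwise divergence
#'
#' Under a strict neutral molecular clock two copies that duplicated `t`
#' years ago have accumulated an expected `2 r t` substitutions per site, so
#' `t = d / (2 r)`. The confidence interval propagates both the sampling
#' variance of the distance and the uncertainty of the neutral rate by the
#' delta method, `var(t) = t^2 (var(d)/d^2 + sd_r^2/r^2)`, as a 95% normal
#' interval truncated at zero.
#'
#' @param d A `paleofoam_dist` object (its `variance` is used) or a bare
#'   numeric divergence in substitutions/site.
#' @param rate_mean Neutral substitution rate in substitutions/site/year
#'   (e.g. the mammalian neutral rate 2.2e-9).
#' @param rate_sd Standard deviation of the rate (same units).
#' @param var_d Sampling variance of `d` when `d` is bare numeric.
#' @return List of class `age_estimate`: `t_years`, `interval` (length-2,
#'   years), `method = "pair_k2p"`, `rate` (list mean/sd), `d`.
#' @export
#' @examples
#' date_pair(0.041, rate_mean = 2.2e-9, rate_sd = 0.1e-9)
date_pair <- function(d, rate_mean, rate_sd = 0, var_d = 0) {
  if (inherits(d, "paleofoam_dist")) {
    var_d <- d$variance
    d <- d$d
  }
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d), d >= 0)
  if (rate_mean <= 0) stop("rate_mean must be positive")
  if (rate_sd < 0) stop("rate_sd must be non-negative")
  t <- d / (2 * rate_mean)
  if (d > 0) {
    var_t <- t^2 * (var_d / d^2 + rate_sd^2 / rate_mean^2)
    half <- 1.959964 * sqrt(var_t)
    interval <- c(max(0, t - half), t + half)
  } else {
    interval <- c(0, 0)
  }
  res <- list(t_years = t, interval = interval, method = "pair_k2p",
              rate = list(mean = rate_mean, sd = rate_sd), d = d)
  class(res) <- "age_estimate"
  res
}

#' UPGMA clustering of a distance matrix into an ultrametric tree
#'
#' Average-linkage agglomeration with node heights equal to half the merge
#' distance, so root-to-tip path lengths are identical for all leaves. Ties
#' between candidate merges are broken deterministically towards the pair of
#' clusters whose lexicographically smallest leaf labels sort first.
#'
#' @param dmat Symmetric numeric matrix with zero diagonal and dimnames.
#' @return List of class `upgma_fit`: `tree` (an [ape::phylo]) and
#'   `root_height` (half the final merge distance, in the units of `dmat`).
#' @export
#' @examples
#' m <- matrix(c(0, .02, .06, .02, 0, .06, .06, .06, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' upgma_tree(m)$root_height
upgma_tree <- function(dmat) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  if (n < 2L) stop("need at least 2 taxa")
  if (is.null(rownames(dmat))) rownames(dmat) <- colnames(dmat) <- paste0("t", seq_len(n))
  if (!isTRUE(all.equal(dmat, t(dmat), tolerance = 1e-12)))
    stop("distance matrix is not symmetric")
  if (any(dmat < 0)) stop("negative distances")
  if (any(!is.finite(dmat))) stop("non-finite distances")

  labels <- rownames(dmat)
  # active clusters: newick fragment, size, height, smallest member label
  cl <- lapply(labels, function(l) list(nwk = l, size = 1L, height = 0, rep = l))
  D <- dmat
  while (length(cl) > 1L) {
    m <- length(cl)
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      dij <- D[i, j]
      key <- paste(sort(c(cl[[i]]$rep, cl[[j]]$rep)), collapse = "\r")
      if (is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 && key < best$key)) {
        best <- list(i = i, j = j, d = dij, key = key)
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    a <- cl[[i]]; b <- cl[[j]]
    merged <- list(
      nwk = paste0("(", a$nwk, ":", format(h - a$height, digits = 15),
                   ",", b$nwk, ":", format(h - b$height, digits = 15), ")"),
      size = a$size + b$size, height = h, rep = min(a$rep, b$rep))
    others <- setdiff(seq_len(m), c(i, j))
    newD <- matrix(0, length(others) + 1L, length(others) + 1L)
    if (length(others)) {
      newD[1L, -1L] <- newD[-1L, 1L] <-
        (a$size * D[i, others] + b$size * D[j, others]) / merged$size
      newD[-1L, -1L] <- D[others, others, drop = FALSE]
    }
    cl <- c(list(merged), cl[others])
    D <- newD
  }
  root <- cl[[1L]]
  tree <- ape::read.tree(text = paste0(root$nwk, ";"))
  res <- list(tree = tree, root_height = root$height)
  class(res) <- "upgma_fit"
  res
}

# Per-pair per-column substitution codes for a set of aligned sequences:
# 0 identical, 1 transition, 2 transversion, NA excluded (gap/N/ambiguity).
# Returns a list of integer vectors indexed by pair, plus the pair index.
pair_codes <- function(aln) {
  m <- aln_matrix(aln)
  bases <- c("A", "C", "G", "T")
  code <- matrix(match(m, bases), nrow(m), ncol(m))  # NA for non-ACGT
  n <- nrow(m)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ts_partner <- c(3L, 4L, 1L, 2L)
  codes <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    x <- code[pairs[k, 1L], ]; y <- code[pairs[k, 2L], ]
    v <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & !is.na(y)
    v[ok] <- 0L
    mism <- which(ok & x != y)
    v[mism] <- ifelse(ts_partner[x[mism]] == y[mism], 1L, 2L)
    codes[[k]] <- v
  }
  list(pairs = pairs, codes = codes, labels = rownames(m), ncol = ncol(m))
}

# K2P d from a code vector (optionally restricted to resampled columns).
k2p_from_codes <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0L) stop("no comparable sites in pair")
  P <- sum(v == 1L) / n
  Q <- sum(v == 2L) / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("K2P distance saturated in duplication set")
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' @param aln Named character vector of aligned nucleotide sequences.
#' @return Symmetric numeric matrix of K2P distances (pairwise deletion).
#' @export
k2p_matrix <- function(aln) {
  pc <- pair_codes(aln)
  n <- length(pc$labels)
  D <- matrix(0, n, n, dimnames = list(pc$labels, pc$labels))
  for (k in seq_len(nrow(pc$pairs))) {
    d <- k2p_from_codes(pc$codes[[k]])
    D[pc$pairs[k, 1L], pc$pairs[k, 2L]] <- d
    D[pc$pairs[k, 2L], pc$pairs[k, 1L]] <- d
  }
  D
}

#' Date a multi-copy segmental-duplication set under a strict clock
#'
#' Builds a K2P distance matrix over the aligned copies, clusters it into an
#' ultrametric UPGMA tree, and converts the root height (per-lineage
#' substitutions/site back to the common ancestor) into years by dividing by
#' the neutral rate. Uncertainty combines alignment-column bootstrap
#' replicates with rate draws from Normal(`rate_mean`, `rate_sd`) truncated
#' at zero; the 2.5 and 97.5 percentiles of the replicate ages form the
#' interval.
#'
#' @param aln Named character vector of >= 3 aligned copies from one
#'   duplication set (for 2 copies use [date_pair()]).
#' @param rate_mean,rate_sd Neutral rate prior (substitutions/site/year).
#' @param n_bootstrap Number of bootstrap replicates.
#' @param seed Optional integer seed making the interval reproducible.
#' @return List of class `age_estimate` with `t_years`, `interval`,
#'   `method = "clock_set"`, `rate`, `tree` (the ultrametric [ape::phylo]
#'   with heights in substitutions/site) and `root_height`.
#' @export
date_duplication_set <- function(aln, rate_mean = 2.2e-9, rate_sd = 0.1e-9,
                                 n_bootstrap = 1000L, seed = NULL) {
  if (length(aln) < 3L)
    stop("need >= 3 sequences; for a pair use date_pair()")
  if (rate_mean <= 0) stop("rate_mean must be positive")
  pc <- pair_codes(aln)
  n <- length(pc$labels)

  dist_from_idx <- function(idx) {
    D <- matrix(0, n, n, dimnames = list(pc$labels, pc$labels))
    for (k in seq_len(nrow(pc$pairs))) {
      d <- k2p_from_codes(pc$codes[[k]][idx])
      D[pc$pairs[k, 1L], pc$pairs[k, 2L]] <- d
      D[pc$pairs[k, 2L], pc$pairs[k, 1L]] <- d
    }
    D
  }

  fit <- upgma_tree(dist_from_idx(seq_len(pc$ncol)))
  t_point <- fit$root_height / rate_mean

  boot <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(pc$ncol, pc$ncol, replace = TRUE)
      h <- upgma_tree(dist_from_idx(idx))$root_height
      r <- rnorm(1L, rate_mean, rate_sd)
      while (r <= 0) r <- rnorm(1L, rate_mean, rate_sd)
      h / r
    }, numeric(1))
  })
  interval <- unname(quantile(boot, c(0.025, 0.975)))

  res <- list(t_years = t_point, interval = interval, method = "clock_set",
              rate = list(mean = rate_mean, sd = rate_sd),
              tree = fit$tree, root_height = fit$root_height,
              n_bootstrap = n_bootstrap)
  class(res) <- "age_estimate"
  res
}

#' @export
print.age_estimate <- function(x, ...) {
  cat("Age estimate (", x$method, "): ", sprintf("%.2f", x$t_years / 1e6),
      " My [", sprintf("%.2f", x$interval[1] / 1e6), ", ",
      sprintf("%.2f", x$interval[2] / 1e6), "] at rate ",
      format(x$rate$mean, digits = 3), " subs/site/year\n", sep = "")
  invisible(x)
}
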