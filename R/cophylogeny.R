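#' Parse / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that add the
#' checks the downstream congruence machinery relies on: balanced
#' parentheses (reported with the character position of the first imbalance),
#' unique leaf labels, and branch-length round-tripping to at least 10
#' significant digits.
#'
#' @param text A Newick string.
#' @return `parse_newick`: an [ape::phylo]; `write_newick`: a Newick string.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:2):0.5,C:3);")
#' write_newick(tr)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("Newick parse error: unmatched ')' at position ", i)
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of string")
  if (!grepl(";\\s*$", text)) stop("Newick parse error: missing terminal ';'")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse error: unreadable tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tree
}

#' @rdname parse_newick
#' @param tree An [ape::phylo].
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 12)
}

#' Midpoint-root a phylogeny
#'
#' Places the root halfway along the longest leaf-to-leaf path, the standard
#' rooting when no outgroup is available (e.g. a virus family with no close
#' relative in the alignment). Total branch length and all leaf-to-leaf path
#' lengths are conserved.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @return A rooted [ape::phylo].
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("midpoint rooting requires branch lengths")
  if (length(tree$tip.label) < 2L) stop("need >= 2 leaves")
  phangorn::midpoint(tree)
}

# Clade key (sorted host-side labels below an edge) for every edge of a
# rooted tree, with tip labels first translated through `translate`.
edge_clades <- function(tree, translate = NULL) {
  ntip <- length(tree$tip.label)
  labs <- tree$tip.label
  if (!is.null(translate)) {
    miss <- setdiff(labs, names(translate))
    if (length(miss)) stop("tip(s) missing from tip map: ", paste(miss, collapse = ", "))
    labs <- unname(translate[labs])
  }
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- labs[i]
  # edges in postorder so children are filled before parents
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1L]; ch <- eo$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  child <- tree$edge[, 2L]
  keys <- vapply(child, function(ch) paste(sort(below[[ch]]), collapse = "|"),
                 character(1))
  data.frame(edge = seq_len(nrow(tree$edge)), clade = keys,
             is_external = child <= ntip, stringsAsFactors = FALSE)
}

#' Map branches between topologically congruent host and virus trees
#'
#' Codivergence analysis requires the virus tree, after translating its tips
#' to host names, to present exactly the same set of clades as the host
#' tree. When it does, every branch of one tree corresponds to exactly one
#' branch of the other and the bijection is returned; otherwise a failure
#' report lists the clades found in only one tree. Polytomies are congruent
#' only when both trees share the identical polytomy.
#'
#' @param host,virus Rooted [ape::phylo] trees.
#' @param tip_map Bijective map from virus tip labels to host tip labels:
#'   a named character vector (`names` = virus tips) or a data.frame with
#'   columns `virus_tip`, `host_tip`.
#' @return On success a data.frame of class `branch_mapping` with columns
#'   `clade`, `host_edge`, `virus_edge`, `is_external`; on failure an object
#'   of class `congruence_failure` with elements `host_only`, `virus_only`.
#' @export
map_congruent_branches <- function(host, virus, tip_map) {
  stopifnot(inherits(host, "phylo"), inherits(virus, "phylo"))
  if (is.data.frame(tip_map)) {
    stopifnot(all(c("virus_tip", "host_tip") %in% names(tip_map)))
    tip_map <- setNames(as.character(tip_map$host_tip),
                        as.character(tip_map$virus_tip))
  }
  if (anyDuplicated(names(tip_map)) || anyDuplicated(tip_map))
    stop("tip_map must be a bijection (duplicate entries found)")
  if (!setequal(tip_map, host$tip.label) ||
      !setequal(names(tip_map), virus$tip.label))
    stop("tip_map must cover exactly the host and virus tip sets")

  h <- edge_clades(host)
  v <- edge_clades(virus, translate = tip_map)
  host_only <- setdiff(h$clade, v$clade)
  virus_only <- setdiff(v$clade, h$clade)
  if (length(host_only) || length(virus_only)) {
    res <- list(host_only = host_only, virus_only = virus_only)
    class(res) <- "congruence_failure"
    return(res)
  }
  m <- merge(h, v, by = "clade", suffixes = c("_host", "_virus"))
  out <- data.frame(clade = m$clade, host_edge = m$edge_host,
                    virus_edge = m$edge_virus,
                    is_external = m$is_external_host,
                    stringsAsFactors = FALSE)
  out <- out[order(out$host_edge), ]
  rownames(out) <- NULL
  class(out) <- c("branch_mapping", "data.frame")
  out
}

#' Test whether a congruence mapping succeeded
#' @param x Result of [map_congruent_branches()].
#' @return `TRUE` for a branch mapping, `FALSE` for a failure report.
#' @export
is_congruent <- function(x) inherits(x, "branch_mapping")

#' @export
print.congruence_failure <- function(x, ...) {
  cat("Host and virus topologies are NOT congruent.\n")
  if (length(x$host_only))
    cat("  Clades only in host tree:\n    ", paste(x$host_only, collapse = "\n    "), "\n")
  if (length(x$virus_only))
    cat("  Clades only in virus tree:\n    ", paste(x$virus_only, collapse = "\n    "), "\n")
  invisible(x)
}

#' Extract paired host/virus branch lengths over a congruent topology
#'
#' @param mapping A `branch_mapping` from [map_congruent_branches()].
#' @param host Rooted host tree with branch lengths in millions of years.
#' @param virus Rooted virus tree with branch lengths in substitutions/site.
#' @return data.frame (class `branch_pair_table`): `branch_id` (clade key),
#'   `host_duration` (My), `virus_length` (subs/site), `is_external`.
#'   Zero-length root branches are excluded; an all-zero host axis is flagged
#'   with a warning.
#' @export
extract_branch_pairs <- function(mapping, host, virus) {
  if (!is_congruent(mapping)) stop("mapping is a congruence failure, not a bijection")
  if (max(mapping$host_edge) > nrow(host$edge) ||
      max(mapping$virus_edge) > nrow(virus$edge))
    stop("mapping is stale with respect to the supplied trees")
  if (is.null(host$edge.length) || is.null(virus$edge.length))
    stop("both trees need branch lengths")
  out <- data.frame(branch_id = mapping$clade,
                    host_duration = host$edge.length[mapping$host_edge],
                    virus_length = virus$edge.length[mapping$virus_edge],
                    is_external = mapping$is_external,
                    stringsAsFactors = FALSE)
  drop <- out$host_duration == 0 & out$virus_length == 0
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (all(out$host_duration == 0))
    warning("all host durations are zero - degenerate branch-pair table")
  class(out) <- c("branch_pair_table", "data.frame")
  out
}

#' Regression test of host-virus codivergence
#'
#' If a virus family codiverged with its hosts under roughly clock-like
#' evolution, virus branch lengths (substitutions/site) scale linearly with
#' the time spanned by the corresponding host branches (My). This fits
#' ordinary least squares of virus length on host duration, reports R², the
#' slope (substitutions/site per My), intercept, and the two-sided p-value of
#' the zero-slope F-test on 1 and n-2 df; optionally a permutation p-value
#' obtained by shuffling virus lengths across branches.
#'
#' @param pairs A `branch_pair_table` (or data.frame with `host_duration`,
#'   `virus_length`).
#' @param n_permutations Number of permutations (0 = skip).
#' @param seed Optional seed for the permutations.
#' @param through_origin Force the fit through the origin (no intercept).
#' @return List of class `codivergence_fit`: `r_squared`, `slope`,
#'   `intercept`, `p_value`, `n_branches`, `permutation_p` (or `NA`).
#' @export
codivergence_test <- function(pairs, n_permutations = 0L, seed = NULL,
                              through_origin = FALSE) {
  stopifnot(all(c("host_duration", "virus_length") %in% names(pairs)))
  x <- pairs$host_duration
  y <- pairs$virus_length
  n <- length(x)
  if (n < 3L) stop("need at least 3 branch pairs")
  if (var(x) == 0) stop("zero variance in host durations")

  fit <- if (through_origin) lm(y ~ x - 1) else lm(y ~ x)
  sm <- summary(fit)
  r2 <- sm$r.squared
  slope <- unname(coef(fit)[["x"]])
  intercept <- if (through_origin) 0 else unname(coef(fit)[[1L]])
  fstat <- sm$fstatistic
  p <- unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))

  perm_p <- NA_real_
  if (n_permutations > 0L) {
    r2_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        yp <- sample(y)
        summary(if (through_origin) lm(yp ~ x - 1) else lm(yp ~ x))$r.squared
      }, numeric(1))
    })
    perm_p <- (1 + sum(r2_perm >= r2)) / (n_permutations + 1)
  }

  res <- list(r_squared = r2, slope = slope, intercept = intercept,
              p_value = p, n_branches = n, permutation_p = perm_p)
  class(res) <- "codivergence_fit"
  res
}

#' @export
print.codivergence_fit <- function(x, ...) {
  cat("Codivergence fit over ", x$n_branches, " branch pairs: R² = ",
      sprintf("%.4f", x$r_squared), ", slope = ", format(x$slope, digits = 4),
      " subs/site per My, p = ", format(x$p_value, digits = 3), sep = "")
  if (!is.na(x$permutation_p))
    cat(", permutation p = ", format(x$permutation_p, digits = 3), sep = "")
  cat("\n")
  invisible(x)
}

#' Dated host phylogeny for the foamy-virus host set
#'
#' A rooted, dated (millions of years) phylogeny of the six hosts of known
#' foamy and foamy-like viruses: coelacanth, aye-aye, sloth, horse, cow and
#' cat. The coelacanth (lobe-finned fish) lineage split from the tetrapod
#' lineage at least 407 My ago (earliest coelacanth fossils); the placental
#' mammal radiation and the splits within Laurasiatheria follow commonly
#' cited molecular timetree estimates. Node ages are approximations intended
#' as a worked fixture for branch-length codivergence analysis, not a new
#' timetree.
#'
#' @param root_age Age (My) of the coelacanth-tetrapod split.
#' @return A rooted [ape::phylo] with branch lengths in My.
#' @export
host_tree_foamy <- function(root_age = 407) {
  stopifnot(root_age > 100)
  txt <- sprintf(
    "(coelacanth:%g,(sloth:100,(aye-aye:96,(horse:84,(cow:78,cat:78):6):12):4):%g);",
    root_age, root_age - 100)
  parse_newick(txt)
}
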