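# Shared fixture builders; everything is generated in code under fixed seeds.

rand_seq <- function(n, seed = NULL) paleofoam:::random_dna(n, seed = seed)

# Mutate `k` positions of a sequence to a different base (deterministic
# given the RNG state).
mutate_positions <- function(s, k) {
  v <- strsplit(s, "")[[1L]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}

# Contig = left flank + element + right flank, with a coords row.
make_contig <- function(id, left, element, right) {
  list(seq = setNames(paste0(left, element, right), id),
       coords = data.frame(contig_id = id, element_start = nchar(left),
                           element_end = nchar(left) + nchar(element),
                           strand = "+", stringsAsFactors = FALSE))
}

# Run code under a fixed seed (test-local convenience).
with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Independent per-column substitution classifier (brute force oracle).
count_subs_bruteforce <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1L]]
  vb <- strsplit(toupper(b), "")[[1L]]
  ts <- 0L; tv <- 0L; n <- 0L
  purine <- c("A", "G")
  for (i in seq_along(va)) {
    x <- va[i]; y <- vb[i]
    if (!(x %in% c("A", "C", "G", "T")) || !(y %in% c("A", "C", "G", "T"))) next
    n <- n + 1L
    if (x == y) next
    same_class <- (x %in% purine) == (y %in% purine)
    if (same_class) ts <- ts + 1L else tv <- tv + 1L
  }
  list(transitions = ts, transversions = tv, sites_compared = n)
}
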