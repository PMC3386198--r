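test_that("Newick parsing round-trips topology, labels and lengths", {
  txt <- "((A:1,B:2):0.5,C:3);"
  tr <- parse_newick(txt)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  back <- parse_newick(write_newick(tr))
  expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-10)
})

test_that("polytomies are preserved and malformed input errors with position", {
  poly <- parse_newick("(A:1,B:1,C:1);")
  expect_equal(poly$Nnode, 1L)                    # single node of out-degree 3
  expect_error(parse_newick("((A:1,B:2;"), "unclosed")
  expect_error(parse_newick("(A:1,B:2));"), "position 10")
  expect_error(parse_newick("((A:1,B:2):1,A:3);"), "duplicate")
})

test_that("midpoint rooting places the root halfway along the longest path", {
  mr <- midpoint_root(parse_newick("(A:1,B:3,C:1);"))
  depths <- setNames(ape::node.depth.edgelength(mr)[seq_along(mr$tip.label)],
                     mr$tip.label)
  expect_equal(depths[["A"]], 2)
  expect_equal(depths[["B"]], 2)
})

test_that("midpoint rooting is idempotent", {
  set.seed(51)
  tr <- ape::rtree(8)
  m1 <- midpoint_root(tr)
  m2 <- midpoint_root(m1)
  expect_equal(ape::cophenetic.phylo(m2)[m1$tip.label, m1$tip.label],
               ape::cophenetic.phylo(m1)[m1$tip.label, m1$tip.label],
               tolerance = 1e-10)
  d1 <- ape::node.depth.edgelength(m1)[seq_along(m1$tip.label)]
  d2 <- ape::node.depth.edgelength(m2)[seq_along(m2$tip.label)]
  expect_equal(max(d1), max(d2), tolerance = 1e-10)
})

test_that("midpoint rooting matches the all-pairs brute-force oracle", {
  set.seed(52)
  for (i in 1:20) {
    tr <- ape::unroot(ape::rtree(10))
    diameter <- max(ape::cophenetic.phylo(tr))   # brute force: all leaf pairs
    mr <- midpoint_root(tr)
    depths <- ape::node.depth.edgelength(mr)[seq_along(mr$tip.label)]
    expect_equal(max(depths), diameter / 2, tolerance = 1e-8)
    # total length and leaf path lengths conserved
    expect_equal(sum(mr$edge.length), sum(tr$edge.length), tolerance = 1e-8)
    expect_equal(ape::cophenetic.phylo(mr)[tr$tip.label, tr$tip.label],
                 ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-8)
  }
})

test_that("midpoint rooting requires branch lengths", {
  tr <- ape::rtree(5)
  tr$edge.length <- NULL
  expect_error(midpoint_root(tr), "branch lengths")
})

make_pair <- function(n = 5, seed = 61) {
  set.seed(seed)
  host <- ape::rtree(n)
  host$tip.label <- paste0("h", seq_len(n))
  virus <- host
  virus$tip.label <- paste0("v", seq_len(n))
  virus$edge.length <- host$edge.length * 0.001
  list(host = host, virus = virus,
       map = setNames(host$tip.label, virus$tip.label))
}

test_that("identical topologies map over all 2n-2 branches", {
  p <- make_pair(5)
  mp <- map_congruent_branches(p$host, p$virus, p$map)
  expect_true(is_congruent(mp))
  expect_equal(nrow(mp), 8L)                     # 2n-2 for rooted binary n=5
  expect_equal(sum(mp$is_external), 5L)
})

test_that("swapped tips yield a failure report naming discordant clades", {
  p <- make_pair(5, seed = 62)
  swapped <- p$map
  # swap the host assignments of two virus tips that are not sisters
  cl <- ape::cophenetic.phylo(p$virus)
  pick <- which(cl == max(cl), arr.ind = TRUE)[1, ]
  i <- rownames(cl)[pick[1]]; j <- colnames(cl)[pick[2]]
  swapped[c(i, j)] <- swapped[c(j, i)]
  mp <- map_congruent_branches(p$host, p$virus, swapped)
  expect_false(is_congruent(mp))
  expect_s3_class(mp, "congruence_failure")
  expect_gt(length(mp$virus_only), 0)
})

test_that("congruence is symmetric under the inverse tip map", {
  p <- make_pair(6, seed = 63)
  fwd <- map_congruent_branches(p$host, p$virus, p$map)
  inv <- setNames(names(p$map), p$map)
  bwd <- map_congruent_branches(p$virus, p$host, inv)
  expect_equal(is_congruent(fwd), is_congruent(bwd))
  expect_equal(nrow(fwd), nrow(bwd))
})

test_that("non-bijective tip maps are rejected", {
  p <- make_pair(4, seed = 64)
  bad <- p$map
  bad[2] <- bad[1]
  expect_error(map_congruent_branches(p$host, p$virus, bad), "bijection")
})

test_that("the six-host foamy tree pair maps congruently over 10 branches", {
  host <- host_tree_foamy()
  sim <- simulate_codivergence(host, viral_rate = 1e-9, seed = 65)
  mp <- map_congruent_branches(host, sim$virus_tree, sim$tip_map)
  expect_true(is_congruent(mp))
  expect_equal(nrow(mp), 10L)
  pairs <- extract_branch_pairs(mp, host, sim$virus_tree)
  expect_equal(nrow(pairs), 10L)
  expect_true(all(pairs$host_duration >= 0))
  expect_true(all(pairs$virus_length >= 0))
})

test_that("zero-noise codivergence simulation has virus_length = rate x duration", {
  host <- host_tree_foamy()
  sim <- simulate_codivergence(host, viral_rate = 2e-9, rate_noise_sd = 0)
  pairs <- extract_branch_pairs(
    map_congruent_branches(host, sim$virus_tree, sim$tip_map),
    host, sim$virus_tree)
  expect_equal(pairs$virus_length, pairs$host_duration * 1e6 * 2e-9,
               tolerance = 1e-12)
})

test_that("degenerate all-zero host durations are flagged", {
  p <- make_pair(4, seed = 66)
  p$host$edge.length[] <- 0
  p$virus$edge.length[] <- 0.01
  mp <- map_congruent_branches(p$host, p$virus, p$map)
  expect_warning(extract_branch_pairs(mp, p$host, p$virus), "degenerate")
})

test_that("exact linear branch pairs give R² = 1 and the expected slope", {
  pairs <- data.frame(host_duration = c(10, 20, 30),
                      virus_length = c(0.01, 0.02, 0.03))
  fit <- suppressWarnings(codivergence_test(pairs))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.001)
  expect_equal(fit$n_branches, 3L)
})

test_that("regression matches the normal-equations oracle on a hand table", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  fit <- codivergence_test(data.frame(host_duration = x, virus_length = y))
  # brute-force least squares via normal equations
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  n <- length(x)
  fstat <- (r2 / 1) / ((1 - r2) / (n - 2))
  p <- pf(fstat, 1, n - 2, lower.tail = FALSE)
  expect_lt(abs(fit$slope - beta[2, 1]), 1e-10)
  expect_lt(abs(fit$intercept - beta[1, 1]), 1e-10)
  expect_lt(abs(fit$r_squared - r2), 1e-10)
  expect_lt(abs(fit$p_value - p), 1e-10)
})

test_that("R² is scale-invariant and the slope rescales inversely", {
  set.seed(71)
  pairs <- data.frame(host_duration = runif(12, 1, 400),
                      virus_length = runif(12, 0, 0.5))
  f1 <- codivergence_test(pairs)
  pairs2 <- transform(pairs, host_duration = host_duration * 10,
                      virus_length = virus_length * 3)
  f2 <- codivergence_test(pairs2)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  expect_equal(f2$slope, f1$slope * 3 / 10, tolerance = 1e-12)
})

test_that("permutation p is calibrated on null data and tracks the analytic p", {
  set.seed(72)
  # null: virus lengths independent of host durations
  null_p <- vapply(1:10, function(i) {
    pairs <- data.frame(host_duration = 1:10,
                        virus_length = sample(seq(0.01, 0.1, length.out = 10)))
    codivergence_test(pairs, n_permutations = 200, seed = i)$permutation_p
  }, numeric(1))
  expect_gt(mean(null_p), 0.2)      # roughly uniform null, not concentrated at 0
  # rank agreement of analytic and permutation p across effect sizes
  fits <- lapply(c(2, 0.5, 0.05), function(noise) {
    set.seed(73)
    x <- 1:12
    y <- 0.01 * x + rnorm(12, 0, noise * 0.01 * mean(x))
    codivergence_test(data.frame(host_duration = x, virus_length = y),
                      n_permutations = 500, seed = 7)
  })
  ap <- vapply(fits, `[[`, numeric(1), "p_value")
  pp <- vapply(fits, `[[`, numeric(1), "permutation_p")
  expect_equal(order(ap), order(pp))
})

test_that("regression rejects degenerate input", {
  expect_error(codivergence_test(data.frame(host_duration = c(1, 1, 1),
                                            virus_length = c(1, 2, 3))),
               "zero variance")
  expect_error(codivergence_test(data.frame(host_duration = c(1, 2),
                                            virus_length = c(1, 2))),
               "at least 3")
})
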