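# K2P per-site change probabilities after expected d substitutions/site,
# with transition/transversion rate ratio kappa (alpha/beta, alpha+2beta=1):
#   P(transition)        = 1/4 + 1/4 e^{-4d/(k+2)} - 1/2 e^{-2d(k+1)/(k+2)}
#   P(each transversion) = 1/4 - 1/4 e^{-4d/(k+2)}
k2p_site_probs <- function(d, kappa) {
  e1 <- exp(-4 * d / (kappa + 2))
  e2 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv_each <- 0.25 - 0.25 * e1
  c(same = 1 - p_ts - 2 * p_tv_each, ts = p_ts, tv_each = p_tv_each)
}

# Evolve an integer-coded base vector (1=A,2=C,3=G,4=T; NA = non-ACGT kept
# as-is) by expected d substitutions/site under K2P. Draws on the current
# RNG stream.
evolve_codes <- function(x, d, kappa) {
  if (d == 0) return(x)
  pr <- k2p_site_probs(d, kappa)
  ts_partner <- c(3L, 4L, 1L, 2L)
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  ok <- which(!is.na(x))
  u <- runif(length(ok))
  out <- x
  i_ts <- ok[u >= pr["same"] & u < pr["same"] + pr["ts"]]
  i_tv1 <- ok[u >= pr["same"] + pr["ts"] & u < pr["same"] + pr["ts"] + pr["tv_each"]]
  i_tv2 <- ok[u >= pr["same"] + pr["ts"] + pr["tv_each"]]
  out[i_ts] <- ts_partner[x[i_ts]]
  out[i_tv1] <- tv1[x[i_tv1]]
  out[i_tv2] <- tv2[x[i_tv2]]
  out
}

seq_to_codes <- function(s) match(strsplit(toupper(s), "")[[1L]], c("A", "C", "G", "T"))
codes_to_seq <- function(x, original = NULL) {
  b <- c("A", "C", "G", "T")[x]
  if (!is.null(original)) b[is.na(x)] <- strsplit(original, "")[[1L]][is.na(x)]
  paste(b, collapse = "")
}

#' Evolve a nucleotide sequence under a neutral strict clock
#'
#' Site-independent continuous-time K2P substitution process: each site
#' changes with the closed-form change probabilities for an expected
#' `rate * duration` substitutions per site, with transition/transversion
#' rate ratio `kappa`. Non-ACGT characters (gaps, N) are carried through
#' unchanged.
#'
#' @param ancestor Single nucleotide string (optionally named).
#' @param duration Elapsed time in years (>= 0).
#' @param rate Substitution rate in substitutions/site/year (>= 0).
#' @param kappa Transition/transversion rate ratio (> 0), default 2.
#' @param seed Optional integer seed for reproducibility.
#' @return The evolved sequence as a character string (same name).
#' @export
#' @examples
#' anc <- paste(rep("ACGT", 5), collapse = "")
#' evolve_sequence(anc, duration = 9.3e6, rate = 2.2e-9, seed = 1)
evolve_sequence <- function(ancestor, duration, rate, kappa = 2, seed = NULL) {
  stopifnot(is.character(ancestor), length(ancestor) == 1L)
  if (duration < 0) stop("duration must be non-negative")
  if (rate < 0) stop("rate must be non-negative")
  if (kappa <= 0) stop("kappa must be positive")
  x <- seq_to_codes(ancestor[[1L]])
  y <- with_seed(seed, evolve_codes(x, d = rate * duration, kappa = kappa))
  setNames(codes_to_seq(y, original = toupper(ancestor[[1L]])), names(ancestor))
}

#' Simulate clock-like virus evolution along a dated host tree
#'
#' Produces a virus phylogeny whose topology mirrors the host tree exactly
#' and whose branch lengths are `viral_rate` substitutions/site/year times
#' the corresponding host branch duration, optionally perturbed by a
#' per-branch lognormal rate multiplier (mean 1) with log-scale standard
#' deviation `rate_noise_sd` — the relaxed-clock-style noise that degrades a
#' codivergence signal. With `root_seq_length` set, tip sequences are evolved
#' along the virus tree from a random root sequence.
#'
#' @param host_tree Rooted [ape::phylo] with branch lengths in My.
#' @param viral_rate Substitutions/site/year.
#' @param kappa Transition/transversion rate ratio for sequence evolution.
#' @param root_seq_length Optional root genome length (bp); `NULL` skips
#'   sequence simulation.
#' @param rate_noise_sd Log-scale SD of the per-branch rate multiplier
#'   (0 = strict clock, deterministic branch lengths).
#' @param seed Optional integer seed.
#' @return List of class `codivergence_sim`: `virus_tree` ([ape::phylo],
#'   subs/site), `tip_map` (named vector virus tip -> host tip), `tip_seqs`
#'   (named character vector or `NULL`), `true_rate`.
#' @export
simulate_codivergence <- function(host_tree, viral_rate, kappa = 2,
                                  root_seq_length = NULL, rate_noise_sd = 0,
                                  seed = NULL) {
  stopifnot(inherits(host_tree, "phylo"))
  if (is.null(host_tree$edge.length)) stop("host tree must be dated (branch lengths in My)")
  if (rate_noise_sd < 0) stop("rate_noise_sd must be non-negative")
  with_seed(seed, {
    virus <- host_tree
    mult <- if (rate_noise_sd > 0) {
      exp(rnorm(nrow(virus$edge), -rate_noise_sd^2 / 2, rate_noise_sd))
    } else rep(1, nrow(virus$edge))
    virus$edge.length <- host_tree$edge.length * 1e6 * viral_rate * mult
    virus$tip.label <- paste0("v_", host_tree$tip.label)
    tip_map <- setNames(host_tree$tip.label, virus$tip.label)

    tip_seqs <- NULL
    if (!is.null(root_seq_length)) {
      ntip <- length(virus$tip.label)
      root_codes <- sample.int(4L, root_seq_length, replace = TRUE)
      node_seq <- vector("list", ntip + virus$Nnode)
      node_seq[[ntip + 1L]] <- root_codes
      eo <- ape::reorder.phylo(virus, "cladewise")  # parents before children
      for (k in seq_len(nrow(eo$edge))) {
        p <- eo$edge[k, 1L]; ch <- eo$edge[k, 2L]
        node_seq[[ch]] <- evolve_codes(node_seq[[p]], eo$edge.length[k], kappa)
      }
      tip_seqs <- setNames(
        vapply(seq_len(ntip), function(i) codes_to_seq(node_seq[[i]]), character(1)),
        virus$tip.label)
    }
    res <- list(virus_tree = virus, tip_map = tip_map, tip_seqs = tip_seqs,
                true_rate = viral_rate)
    class(res) <- "codivergence_sim"
    res
  })
}

#' Configuration for an endogenization simulation
#'
#' Defaults reflect the textbook endogenous-retrovirus dating design: a
#' provirus fixed in the germline `endogenization_time` My ago, copied by
#' segmental duplication (default: four duplications 19.3 My ago, giving a
#' five-copy set), every copy decaying neutrally at the mammalian neutral
#' rate 2.2e-9 substitutions/site/year (SD 0.1e-9) with occasional indels.
#'
#' @param genome_length Element length in bp (default 5000).
#' @param flank_length Host flanking sequence per side in bp.
#' @param endogenization_time My before present of germline integration.
#' @param duplication_times My before present of each segmental duplication
#'   (each duplicates one extant copy; `k` times give `k+1` copies).
#' @param host_neutral_rate List `mean`/`sd` in substitutions/site/year.
#' @param kappa Transition/transversion rate ratio.
#' @param indel_rate Indel events per site per year (lengths geometric,
#'   capped at 10, so frameshifts arise naturally).
#' @param n_fragments Fragments per copy contig (1 = intact contigs).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(genome_length = 5000L, flank_length = 200L,
                       endogenization_time = 25,
                       duplication_times = rep(19.3, 4L),
                       host_neutral_rate = list(mean = 2.2e-9, sd = 0.1e-9),
                       kappa = 2, indel_rate = 1e-11, n_fragments = 1L,
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              flank_length = as.integer(flank_length),
              endogenization_time = endogenization_time,
              duplication_times = duplication_times,
              host_neutral_rate = host_neutral_rate,
              kappa = kappa, indel_rate = indel_rate,
              n_fragments = as.integer(n_fragments), seed = as.integer(seed))
  if (cfg$genome_length < 30L) stop("genome_length too short")
  if (any(cfg$duplication_times > cfg$endogenization_time))
    stop("duplication_times must not precede endogenization_time")
  if (cfg$host_neutral_rate$mean < 0 || cfg$host_neutral_rate$sd < 0 ||
      cfg$indel_rate < 0)
    stop("rates must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

# Ancestral element: ATG + random sense codons (no internal stops) + TAA.
ancestral_orf <- function(genome_length) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  n_codon <- genome_length %/% 3L
  body <- sample(sense, n_codon - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Simulate endogenization, segmental duplication and neutral decay
#'
#' Generates the data an invasion-dating analysis consumes, together with
#' truth for every stage: an ancestral provirus (single long ORF without
#' internal stops) flanked by random host sequence is fixed in the germline
#' `endogenization_time` My ago; at each duplication time one extant copy is
#' segmentally duplicated (copies inherit identical flanks); all lineages
#' decay neutrally under K2P at the host rate; indels (Poisson, geometric
#' lengths) are applied at the end while the true multiple alignment is
#' maintained, and each copy can be fragmented into overlapping contigs.
#'
#' @param config A [sim_config()].
#' @return List of class `endogenization_sim`: `contigs` (named character
#'   vector, flanks + element, indels applied), `fragments` (when
#'   `n_fragments > 1`), `alignment` (true MSA of the full loci, gaps as
#'   `-`), `element_alignment` (element columns only), and `truth` — ages,
#'   per-copy gained-stop codon indices, indel events, duplicate-set
#'   membership and a `coords` table (`contig_id`, `element_start`,
#'   `element_end`, `strand`) ready for [identify_duplicate_sets()].
#' @export
simulate_endogenization <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    elem <- ancestral_orf(cfg$genome_length)
    Le <- nchar(elem)
    fl <- cfg$flank_length
    locus <- paste0(random_dna(fl), elem, random_dna(fl))
    rate <- cfg$host_neutral_rate$mean

    # lineage evolution: list of code vectors; duplicate one lineage per event
    now <- cfg$endogenization_time
    lineages <- list(seq_to_codes(locus))
    births <- cfg$endogenization_time          # per-lineage origin (My)
    for (tdup in sort(cfg$duplication_times, decreasing = TRUE)) {
      dt_years <- (now - tdup) * 1e6
      lineages <- lapply(lineages, evolve_codes, d = rate * dt_years, kappa = cfg$kappa)
      src <- sample.int(length(lineages), 1L)
      lineages <- c(lineages, lineages[src])
      births <- c(births, tdup)
      now <- tdup
    }
    dt_years <- now * 1e6
    lineages <- lapply(lineages, evolve_codes, d = rate * dt_years, kappa = cfg$kappa)

    ncopy <- length(lineages)
    copy_ids <- sprintf("copy%02d", seq_len(ncopy))
    aln <- do.call(rbind, lapply(lineages, function(x) c("A", "C", "G", "T")[x]))
    rownames(aln) <- copy_ids
    col_class <- rep(c("L", "E", "R"), times = c(fl, Le, fl))

    # gained stops: in-frame stops in the decayed element (truth by direct scan)
    gained_stops <- lapply(seq_len(ncopy), function(i) {
      s <- paste(aln[i, col_class == "E"], collapse = "")
      starts <- seq.int(1L, by = 3L, length.out = nchar(s) %/% 3L)
      cod <- substring(s, starts, starts + 2L)
      idx <- which(cod %in% c("TAA", "TAG", "TGA"))
      idx[idx < length(cod)] - 1L
    })
    names(gained_stops) <- copy_ids

    # indels applied on the maintained alignment
    indel_events <- data.frame(copy = character(0), type = character(0),
                               column = integer(0), length = integer(0),
                               stringsAsFactors = FALSE)
    age_years <- cfg$endogenization_time * 1e6
    for (i in seq_len(ncopy)) {
      n_ev <- rpois(1L, cfg$indel_rate * ncol(aln) * age_years)
      for (e in seq_len(n_ev)) {
        len <- min(rgeom(1L, 0.5) + 1L, 10L)
        type <- sample(c("del", "ins"), 1L)
        pos <- sample.int(ncol(aln) - len, 1L)
        if (type == "del") {
          aln[i, pos:(pos + len - 1L)] <- "-"
        } else {
          block <- matrix("-", ncopy, len)
          block[i, ] <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
          aln <- cbind(aln[, seq_len(pos), drop = FALSE], block,
                       aln[, seq.int(pos + 1L, ncol(aln)), drop = FALSE])
          col_class <- c(col_class[seq_len(pos)], rep(col_class[pos], len),
                         col_class[seq.int(pos + 1L, length(col_class))])
        }
        indel_events <- rbind(indel_events,
          data.frame(copy = copy_ids[i], type = type, column = pos - 1L,
                     length = len, stringsAsFactors = FALSE))
      }
    }

    row_string <- function(i, cols) paste(aln[i, cols], collapse = "")
    degap <- function(s) gsub("-", "", s, fixed = TRUE)
    contigs <- setNames(vapply(seq_len(ncopy), function(i)
      degap(row_string(i, TRUE)), character(1)), copy_ids)
    coords <- data.frame(
      contig_id = copy_ids,
      element_start = vapply(seq_len(ncopy), function(i)
        sum(aln[i, col_class == "L"] != "-"), integer(1)),
      element_end = vapply(seq_len(ncopy), function(i)
        sum(aln[i, col_class %in% c("L", "E")] != "-"), integer(1)),
      strand = "+", stringsAsFactors = FALSE)

    alignment <- setNames(vapply(seq_len(ncopy), function(i)
      row_string(i, TRUE), character(1)), copy_ids)
    element_alignment <- setNames(vapply(seq_len(ncopy), function(i)
      row_string(i, col_class == "E"), character(1)), copy_ids)

    fragments <- NULL
    frag_coords <- NULL
    if (cfg$n_fragments > 1L) {
      fragments <- character(0)
      frag_coords <- data.frame(fragment_id = character(0), contig_id = character(0),
                                start = integer(0), end = integer(0),
                                stringsAsFactors = FALSE)
      overlap <- 100L
      for (i in seq_len(ncopy)) {
        s <- contigs[[i]]
        L <- nchar(s)
        nf <- cfg$n_fragments
        step <- max(300L, ceiling((L + (nf - 1L) * overlap) / nf))
        starts <- pmin(pmax(0L, (seq_len(nf) - 1L) * (step - overlap)), max(0L, L - 300L))
        for (f in seq_len(nf)) {
          a <- starts[f]; b <- min(L, a + step)
          fid <- sprintf("%s_frag%02d", copy_ids[i], f)
          fragments[fid] <- substr(s, a + 1L, b)
          frag_coords <- rbind(frag_coords,
            data.frame(fragment_id = fid, contig_id = copy_ids[i],
                       start = a, end = b, stringsAsFactors = FALSE))
        }
      }
    }

    truth <- list(endogenization_time = cfg$endogenization_time,
                  duplication_times = cfg$duplication_times,
                  copy_births = births,
                  duplicate_set = copy_ids,
                  gained_stops = gained_stops,
                  indel_events = indel_events,
                  coords = coords,
                  fragment_coords = frag_coords,
                  ancestral_element = elem)
    res <- list(contigs = contigs, fragments = fragments,
                alignment = alignment, element_alignment = element_alignment,
                truth = truth, config = cfg)
    class(res) <- "endogenization_sim"
    res
  })
}

#' @export
print.endogenization_sim <- function(x, ...) {
  cat("Endogenization simulation: ", length(x$contigs), " copies, element ",
      x$config$genome_length, " bp, endogenized ",
      x$config$endogenization_time, " My ago\n", sep = "")
  invisible(x)
}
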