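#' Run the paleovirology analysis pipeline from a single configuration
#'
#' Executes the requested stages in dependency order — `simulate`,
#' `consensus`, `defects`, `dupsets`, `date_pair`, `date_set`,
#' `codivergence` — each stage also being available as a standalone
#' function. Inputs referenced by path are validated before any stage runs
#' (fail fast); a stage failure aborts the run naming the stage. All numeric
#' results are written as JSON/TSV/FASTA/Newick under `out_dir` and a run
#' manifest (tool version, config hash, seeds, input digests, per-stage
#' outputs, timestamps) is written to `manifest.json`; re-running the same
#' config and seed reproduces the outputs byte-identically.
#'
#' @param config Path to a YAML or JSON configuration file, or an equivalent
#'   named list. Recognised top-level fields: `seed`, `out_dir`, and a
#'   `stages` list whose entries select and parameterise the stages (see the
#'   packaged demo in `system.file("extdata", "pipeline_demo.yaml",
#'   package = "paleofoam")`).
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list of class `run_manifest` with per-stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) {
    cfg <- config
  } else stop("config must be a file path or a list")

  if (is.null(cfg$stages) || !length(cfg$stages))
    stop("validation error: config has no stages")
  out_dir <- out_dir %||% cfg$out_dir %||% stop("validation error: no out_dir")
  seed <- cfg$seed %||% 1L

  known <- c("simulate", "consensus", "defects", "dupsets",
             "date_pair", "date_set", "codivergence")
  unknown <- setdiff(names(cfg$stages), known)
  if (length(unknown))
    stop("validation error: unknown stage(s): ", paste(unknown, collapse = ", "))
  order_run <- intersect(known, names(cfg$stages))

  # fail-fast: every file referenced by any stage must exist before stage 1
  for (st in order_run) {
    sc <- cfg$stages[[st]]
    for (f in c(sc$input, sc$alignment, sc$host_tree, sc$virus_tree, sc$tip_map)) {
      if (is.character(f) && !(f %in% c("simulate", "builtin")) && !file.exists(f))
        stop("validation error: stage '", st, "' input not found: ", f)
    }
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_norm <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_norm, tmp)
  manifest <- list(tool = "paleofoam",
                   version = as.character(packageVersion("paleofoam")),
                   config_hash = unname(tools::md5sum(tmp)),
                   seed = seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   input_digests = list(), stages = list())
  unlink(tmp)
  state <- new.env(parent = emptyenv())

  log_stage <- function(st, msg) message("[paleofoam] ", st, ": ", msg)
  digest_inputs <- function(paths) {
    paths <- unlist(Filter(function(f)
      is.character(f) && length(f) == 1L && file.exists(f), paths))
    if (!length(paths)) return(list())
    as.list(tools::md5sum(paths))
  }

  for (st in order_run) {
    sc <- cfg$stages[[st]]
    log_stage(st, "starting")
    res <- tryCatch(
      run_stage(st, sc, state, seed, out_dir),
      error = function(e) stop("stage '", st, "' failed: ", conditionMessage(e),
                               call. = FALSE))
    manifest$input_digests <- c(manifest$input_digests,
      digest_inputs(c(sc$input, sc$alignment, sc$host_tree, sc$virus_tree, sc$tip_map)))
    manifest$stages[[st]] <- res
    log_stage(st, "done")
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  man_out <- manifest
  man_out$started <- man_out$finished <- NULL  # timestamps kept in R object only,
  jsonlite::write_json(man_out, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Execute one stage; returns a small summary recorded in the manifest.
run_stage <- function(st, sc, state, seed, out_dir) {
  switch(st,
    simulate = {
      cfg <- sim_config(
        genome_length = sc$genome_length %||% 5000L,
        flank_length = sc$flank_length %||% 200L,
        endogenization_time = sc$endogenization_time %||% 25,
        duplication_times = sc$duplication_times %||% rep(19.3, 4L),
        host_neutral_rate = list(mean = sc$rate_mean %||% 2.2e-9,
                                 sd = sc$rate_sd %||% 0.1e-9),
        kappa = sc$kappa %||% 2, indel_rate = sc$indel_rate %||% 1e-11,
        n_fragments = sc$n_fragments %||% 1L, seed = sc$seed %||% seed)
      sim <- simulate_endogenization(cfg)
      state$sim <- sim
      write_fasta(sim$contigs, file.path(out_dir, "contigs.fasta"))
      write_fasta(sim$alignment, file.path(out_dir, "alignment.fasta"))
      jsonlite::write_json(
        sim$truth[c("endogenization_time", "duplication_times", "duplicate_set")],
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      list(n_copies = length(sim$contigs), outputs = c("contigs.fasta",
           "alignment.fasta", "truth.json"), seed = cfg$seed)
    },
    consensus = {
      aln <- stage_alignment(sc, state)
      cons <- build_consensus(aln, min_support = sc$min_support %||% 0.5)
      state$consensus <- cons
      write_fasta(cons$seq, file.path(out_dir, "consensus.fasta"))
      list(length = nchar(cons$seq), mean_support = mean(cons$support),
           outputs = "consensus.fasta")
    },
    defects = {
      aln <- stage_alignment(sc, state)
      target <- if (!is.null(state$consensus)) state$consensus$seq else aln[1L]
      orf_end <- sc$orf_end %||% (nchar(target) %/% 3L * 3L)
      rep_list <- annotate_defects(target, sc$orf_start %||% 0L, orf_end)
      writeLines(format(rep_list), file.path(out_dir, "defects.json"))
      list(n_stops = length(rep_list$stop_positions), outputs = "defects.json")
    },
    dupsets = {
      if (is.null(state$sim)) stop("dupsets stage needs the simulate stage (contigs + coords)")
      part <- identify_duplicate_sets(
        state$sim$contigs, state$sim$truth$coords,
        flank_window = sc$flank_window %||% 100L,
        min_flank_identity = sc$min_flank_identity %||% 0.90)
      jsonlite::write_json(part$sets, file.path(out_dir, "dupsets.json"),
                           auto_unbox = FALSE)
      list(n_sets = length(part$sets), outputs = "dupsets.json")
    },
    date_pair = {
      aln <- stage_alignment(sc, state)
      if (length(aln) < 2L) stop("date_pair needs two sequences")
      d <- k2p_distance(count_substitutions(aln[[1L]], aln[[2L]]))
      age <- date_pair(d, rate_mean = sc$rate_mean %||% 2.2e-9,
                       rate_sd = sc$rate_sd %||% 0.1e-9)
      jsonlite::write_json(
        list(d = d$d, t_my = age$t_years / 1e6,
             interval_my = age$interval / 1e6),
        file.path(out_dir, "date_pair.json"), auto_unbox = TRUE, digits = NA)
      list(d = d$d, t_my = age$t_years / 1e6, outputs = "date_pair.json")
    },
    date_set = {
      aln <- stage_alignment(sc, state)
      age <- date_duplication_set(
        aln, rate_mean = sc$rate_mean %||% 2.2e-9,
        rate_sd = sc$rate_sd %||% 0.1e-9,
        n_bootstrap = sc$n_bootstrap %||% 1000L, seed = sc$seed %||% seed)
      jsonlite::write_json(
        list(t_my = age$t_years / 1e6, interval_my = age$interval / 1e6,
             root_height = age$root_height),
        file.path(out_dir, "date_set.json"), auto_unbox = TRUE, digits = NA)
      writeLines(write_newick(age$tree), file.path(out_dir, "clock_tree.nwk"))
      list(t_my = age$t_years / 1e6, outputs = c("date_set.json", "clock_tree.nwk"))
    },
    codivergence = {
      host <- if (identical(sc$host_tree %||% "builtin", "builtin")) {
        host_tree_foamy()
      } else parse_newick(readLines(sc$host_tree, warn = FALSE)[1L])
      if (identical(sc$virus_tree %||% "simulate", "simulate")) {
        simc <- simulate_codivergence(
          host, viral_rate = sc$viral_rate %||% 1e-9,
          rate_noise_sd = sc$rate_noise_sd %||% 0, seed = sc$seed %||% seed)
        virus <- simc$virus_tree; tip_map <- simc$tip_map
      } else {
        virus <- parse_newick(readLines(sc$virus_tree, warn = FALSE)[1L])
        tm <- utils::read.delim(sc$tip_map, stringsAsFactors = FALSE)
        tip_map <- setNames(tm$host_tip, tm$virus_tip)
      }
      mp <- map_congruent_branches(host, virus, tip_map)
      if (!is_congruent(mp)) stop("host and virus topologies are not congruent")
      pairs <- extract_branch_pairs(mp, host, virus)
      fit <- codivergence_test(pairs,
                               n_permutations = sc$n_permutations %||% 0L,
                               seed = sc$seed %||% seed)
      utils::write.table(pairs, file.path(out_dir, "branch_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(unclass(fit), file.path(out_dir, "codivergence.json"),
                           auto_unbox = TRUE, digits = NA)
      list(r_squared = fit$r_squared, p_value = fit$p_value,
           outputs = c("branch_pairs.tsv", "codivergence.json"))
    },
    stop("unknown stage: ", st))
}

# Resolve the alignment a stage works on: explicit FASTA path, or the
# simulated duplicate-set alignment from an earlier simulate stage.
stage_alignment <- function(sc, state) {
  if (!is.null(sc$alignment) && !identical(sc$alignment, "simulate"))
    return(read_fasta(sc$alignment))
  if (!is.null(state$sim)) return(state$sim$alignment)
  stop("no alignment available: give 'alignment: <path>' or run the simulate stage")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("paleofoam run (v", x$version, "), seed ", x$seed, ", stages: ",
      paste(names(x$stages), collapse = " -> "), "\n", sep = "")
  invisible(x)
}
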