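#' Read a flat key=value pipeline configuration
#'
#' Lines of `key = value`; blank lines and `#` comments ignored. Recognized
#' keys: `assemblies` (directory of per-strain FASTA, or comma-separated
#' paths), `annotations` (directory of per-strain GFF3), `prophage_bed`,
#' `reads1`, `reads2`, `host_fasta`, `catalog` (repeat catalog TSV),
#' `out_dir`, `seed`, `verbosity` (0-2), `min_identity`, `pad`, `max_dist`,
#' `simulate` (true/false: generate the demo panel as input), `power`
#' (semicolon-separated `n1,n2,dist1,dist2,alpha` power requests).
#'
#' @param path config file path.
#' @return a named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) abort(sprintf("malformed config line: '%s'", lines[bad][1]))
  cfg <- setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, character(1), 1))
  pipeline_config(!!!cfg)
}

#' @rdname read_pipeline_config
#' @param ... configuration values (see keys above).
#' @export
pipeline_config <- function(...) {
  cfg <- rlang::list2(...)
  defaults <- list(out_dir = "crisprcomb_out", seed = 1L, verbosity = 1L,
                   min_identity = 0.80, pad = 32L, max_dist = 500L,
                   simulate = FALSE)
  cfg <- utils::modifyList(defaults, cfg)
  for (key in c("seed", "verbosity", "pad", "max_dist")) {
    cfg[[key]] <- as.integer(cfg[[key]])
  }
  cfg$min_identity <- as.numeric(cfg$min_identity)
  cfg$simulate <- isTRUE(cfg$simulate) || identical(tolower(as.character(cfg$simulate)), "true")
  structure(cfg, class = "pipeline_config")
}

pipe_log <- function(cfg, level, ...) {
  if (cfg$verbosity >= level) message("[crisprcomb] ", sprintf(...))
}

#' Demo strain plans
#'
#' A small three-strain panel: two related strains sharing two spacers,
#' canonical and orphan I-E arrays with different tetraloops, a small
#' canonical II-C array, and prophage regions (one intact, one incomplete)
#' donating protospacers.
#'
#' @return a list of [strain_plan()]s.
#' @export
default_demo_plans <- function() {
  list(
    strain_plan("strainA", contig_lengths = c(42000L, 26000L),
      arrays = list(
        array_plan("I-E", "canonical", n_spacers = 12, tetraloop = "TTCA",
                   spacer_sources = c(rep("random", 10),
                                      rep("prophage:phiA1", 2)),
                   contig = 1L),
        array_plan("I-E", "orphan", n_spacers = 9, tetraloop = "TTCG",
                   contig = 2L)
      ),
      prophages = list(prophage_plan("phiA1", 6000L, "intact", contig = 1L)),
      genes = 3L),
    strain_plan("strainB", contig_lengths = c(40000L, 24000L),
      arrays = list(
        array_plan("I-E", "canonical", n_spacers = 10, tetraloop = "TTCA",
                   spacer_sources = c("shared:strainA,1,1",
                                      "shared:strainA,1,2",
                                      rep("random", 8)),
                   contig = 1L),
        array_plan("II-C", "canonical", n_spacers = 7, contig = 2L)
      ),
      prophages = list(prophage_plan("phiB1", 5000L, "incomplete",
                                     contig = 1L)),
      genes = 3L),
    strain_plan("strainC", contig_lengths = c(38000L),
      arrays = list(
        array_plan("I-E", "orphan", n_spacers = 8, tetraloop = "TACA",
                   spacer_sources = c(rep("random", 6),
                                      rep("prophage:phiA1", 2)))
      ),
      genes = 2L)
  )
}

#' Run the whole pipeline
#'
#' Executes simulate (optional) -> detect -> type -> context ->
#' read-spacers -> match -> overlap -> stats, writing every stage's TSV and
#' FASTA artifacts plus a run manifest under `out_dir`. A stage failure
#' aborts with the stage name; artifacts of completed stages are retained.
#' Stages whose inputs are absent (e.g. no prophage BED, no reads) are
#' skipped with a logged notice.
#'
#' @param config a [pipeline_config()] (or path to a config file).
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, artifact) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, artifact = artifact, seed = cfg$seed,
      package_version = as.character(utils::packageVersion("crisprcomb")))
  }
  stage <- function(name, expr) {
    pipe_log(cfg, 1, "stage %s", name)
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  ## simulate ----------------------------------------------------------------
  if (cfg$simulate) {
    stage("simulate", {
      sim_dir <- file.path(cfg$out_dir, "sim")
      panel <- build_strain_panel(default_demo_plans(), seed = cfg$seed,
                                  out_dir = sim_dir)
      host <- synth_host_genome(30000L,
                                community = unlist(panel$sequences,
                                                   use.names = FALSE))
      reads <- simulate_reads(panel$sequences, host_genome = host,
                              host_fraction = 0.2, n_pairs = 2000L,
                              seed = cfg$seed)
      write_paired_fastq(reads, file.path(sim_dir, "reads_1.fastq"),
                         file.path(sim_dir, "reads_2.fastq"))
      writeLines(c(">host", host), file.path(sim_dir, "host.fasta"))
      cfg$assemblies <- sim_dir
      cfg$annotations <- sim_dir
      cfg$prophage_bed <- file.path(sim_dir, "prophages.bed")
      cfg$reads1 <- file.path(sim_dir, "reads_1.fastq")
      cfg$reads2 <- file.path(sim_dir, "reads_2.fastq")
      cfg$host_fasta <- file.path(sim_dir, "host.fasta")
      note("simulate", sim_dir)
    })
  }
  if (is.null(cfg$assemblies)) abort("config needs 'assemblies'")
  fasta <- if (dir.exists(cfg$assemblies)) {
    list.files(cfg$assemblies, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  } else strsplit(cfg$assemblies, ",")[[1]]
  strains <- sub("\\.(fa|fasta)$", "", basename(fasta))
  ## order-stable inputs
  ord <- order(strains); fasta <- fasta[ord]; strains <- strains[ord]
  catalog <- if (!is.null(cfg$catalog)) read_repeat_catalog(cfg$catalog) else
    default_repeat_catalog()

  ## detect + type + context -------------------------------------------------
  arrays <- stage("detect", {
    a <- bind_rows(lapply(seq_along(fasta), function(i) {
      strain_scan(read_assembly(fasta[i]), strain_id = strains[i])
    }))
    write_array_tsv(a, file.path(cfg$out_dir, "detect.arrays.tsv"))
    if (nrow(a)) {
      write_array_fasta(a, file.path(cfg$out_dir, "detect.spacers.fasta"),
                        "spacers")
      write_array_fasta(a, file.path(cfg$out_dir, "detect.repeats.fasta"),
                        "repeats")
    }
    note("detect", "detect.arrays.tsv")
    a
  })

  arrays <- stage("type", {
    cls <- classify_repeats(arrays$consensus_repeat, catalog)
    a <- bind_cols(arrays, select(cls, "type", "subtype", "edit_distance",
                                  "accepted"))
    readr::write_tsv(select(a, -"repeats", -"spacers"),
                     file.path(cfg$out_dir, "type.arrays.tsv"))
    census <- tetraloop_census(mutate(a, context = "unplaced"))
    readr::write_tsv(census, file.path(cfg$out_dir, "type.tetraloops.tsv"))
    note("type", "type.arrays.tsv")
    a
  })

  genes <- NULL
  arrays <- stage("context", {
    gff <- if (!is.null(cfg$annotations)) {
      vapply(strains, function(s) {
        f <- file.path(cfg$annotations, paste0(s, ".gff3"))
        if (file.exists(f)) f else NA_character_
      }, character(1))
    } else rep(NA_character_, length(strains))
    if (all(is.na(gff))) {
      pipe_log(cfg, 1, "context: no annotations; labels stay 'unplaced'")
      mutate(arrays, context = "unplaced", cas_gap = NA_integer_)
    } else {
      genes <- bind_rows(lapply(which(!is.na(gff)), function(i) {
        mutate(read_gene_annotations(gff[i]), strain_id = strains[i])
      }))
      a <- classify_context(arrays, genes, max_dist = cfg$max_dist)
      readr::write_tsv(select(a, -"repeats", -"spacers"),
                       file.path(cfg$out_dir, "context.arrays.tsv"))
      census <- tetraloop_census(a)
      readr::write_tsv(census, file.path(cfg$out_dir, "context.tetraloops.tsv"))
      note("context", "context.arrays.tsv")
      a
    }
  })

  ## read spacers ------------------------------------------------------------
  groups <- NULL
  if (!is.null(cfg$reads1)) {
    groups <- stage("read-spacers", {
      reads <- read_paired_fastq(cfg$reads1, cfg$reads2)
      if (!is.null(cfg$host_fasta)) {
        host <- read_assembly(cfg$host_fasta)
        n0 <- nrow(reads)
        reads <- host_filter(reads, unname(host))
        pipe_log(cfg, 2, "host filter kept %d/%d pairs", nrow(reads), n0)
      }
      g1 <- extract_read_spacers(reads$seq1, sample_id = "R1")
      g2 <- extract_read_spacers(reads$seq2, sample_id = "R2")
      resc <- if (nrow(arrays)) {
        rescue_known_repeats(c(reads$seq1, reads$seq2),
                             unique(arrays$consensus_repeat),
                             sample_id = "rescue")
      } else empty_groups()
      g <- merge_groups(g1, g2, resc)
      write_groups(g, file.path(cfg$out_dir, "readspacers.groups.tsv"),
                   file.path(cfg$out_dir, "readspacers.spacers.fasta"))
      note("read-spacers", "readspacers.groups.tsv")
      g
    })
  } else pipe_log(cfg, 1, "read-spacers: no reads configured; skipped")

  ## match -------------------------------------------------------------------
  matches <- stage("match", {
    sp <- array_spacer_table(arrays)
    if (nrow(sp) == 0) {
      pipe_log(cfg, 1, "match: no spacers detected")
      NULL
    } else {
      refs <- unlist(lapply(fasta, read_assembly))
      uniq <- dedupe_spacers(sp)
      m <- match_spacers_to_reference(uniq, refs,
                                      min_identity = cfg$min_identity)
      m <- left_join(m, select(uniq, "query_id", source_id = "strain_id"),
                     by = "query_id")
      readr::write_tsv(m, file.path(cfg$out_dir, "match.matches.tsv"))
      if (length(unique(sp$strain_id)) >= 2) {
        sh <- sharing_matrix(sp, min_identity = cfg$min_identity)
        write_sharing_tsv(sh, file.path(cfg$out_dir, "match.sharing.tsv"))
      }
      note("match", "match.matches.tsv")
      m
    }
  })

  ## overlap -----------------------------------------------------------------
  if (!is.null(cfg$prophage_bed) && !is.null(matches) && nrow(matches)) {
    stage("overlap", {
      bed <- read_prophage_bed(cfg$prophage_bed)
      bed$strain_id <- sub("_c[0-9]+$", "", bed$contig_id)
      att <- attribute_matches(matches, bed, arrays,
                               genes %||% tibble(contig_id = character(),
                                                 start = integer(),
                                                 end = integer(),
                                                 type = character()),
                               pad = cfg$pad)
      readr::write_tsv(att$matches,
                       file.path(cfg$out_dir, "overlap.categorized.tsv"))
      readr::write_tsv(att$per_region,
                       file.path(cfg$out_dir, "overlap.per_region.tsv"))
      readr::write_tsv(att$summary,
                       file.path(cfg$out_dir, "overlap.summary.tsv"))
      export_edges(att$edges, cfg$out_dir)
      note("overlap", "overlap.categorized.tsv")
    })
  } else {
    pipe_log(cfg, 1, "overlap: no prophage BED or no matches; skipped")
  }

  ## stats -------------------------------------------------------------------
  stage("stats", {
    out <- list()
    if (nrow(arrays)) {
      out$sizes <- array_size_summary(arrays)
      readr::write_tsv(out$sizes, file.path(cfg$out_dir, "stats.sizes.tsv"))
      ie <- filter(arrays, .data$subtype == "I-E")
      iic <- filter(arrays, .data$subtype == "II-C")
      tests <- list()
      if (nrow(ie) && nrow(iic)) {
        tests$`I-E_vs_II-C` <- tidy(wmw_test(ie$n_spacers, iic$n_spacers))
      }
      can <- filter(ie, .data$context == "canonical")
      orp <- filter(ie, .data$context == "orphan")
      if (nrow(can) && nrow(orp)) {
        tests$canonical_vs_orphan <- tidy(wmw_test(can$n_spacers,
                                                   orp$n_spacers))
      }
      if (length(tests)) {
        readr::write_tsv(bind_rows(tests, .id = "comparison"),
                         file.path(cfg$out_dir, "stats.tests.tsv"))
      }
    }
    if (!is.null(cfg$power)) {
      specs <- strsplit(cfg$power, ";")[[1]]
      pw <- bind_rows(lapply(specs, function(s) {
        tidy(parse_power_request(s, seed = cfg$seed))
      }))
      readr::write_tsv(pw, file.path(cfg$out_dir, "stats.power.tsv"))
    }
    note("stats", "stats.sizes.tsv")
  })

  readr::write_tsv(bind_rows(manifest), file.path(cfg$out_dir, "manifest.tsv"))
  pipe_log(cfg, 1, "done: %s", cfg$out_dir)
  invisible(cfg$out_dir)
}

#' Flatten detected arrays into a spacer table
#'
#' One row per spacer with its id, sequence and the source array interval
#' (used for self-hit removal during matching).
#'
#' @param arrays array tibble.
#' @return tibble `query_id`, `seq`, `strain_id`, `self_contig`,
#'   `self_start`, `self_end`.
#' @export
array_spacer_table <- function(arrays) {
  if (nrow(arrays) == 0) {
    return(tibble(query_id = character(), seq = character(),
                  strain_id = character(), self_contig = character(),
                  self_start = integer(), self_end = integer()))
  }
  bind_rows(lapply(seq_len(nrow(arrays)), function(i) {
    sp <- arrays$spacers[[i]]
    if (!length(sp)) return(NULL)
    tibble(
      query_id = sprintf("%s|%s|array%d|spacer%d", arrays$strain_id[i],
                         arrays$contig_id[i], arrays$array_idx[i],
                         seq_along(sp)),
      seq = sp, strain_id = arrays$strain_id[i],
      self_contig = arrays$contig_id[i],
      self_start = arrays$start[i], self_end = arrays$end[i]
    )
  }))
}

#' Parse a power request string
#'
#' Mirrors the printed call syntax:
#' `"13,18,lnorm(2.7365304,0.6243374),exp(0.0323741),0.05"`.
#'
#' @param x request string `n1,n2,dist1,dist2,alpha`.
#' @param reps,seed passed to [wmw_power()].
#' @return a `wmw_power` object.
#' @export
parse_power_request <- function(x, reps = 10000L, seed = 1L) {
  parts <- strsplit(x, ",(?![^(]*\\))", perl = TRUE)[[1]]
  if (length(parts) != 5) {
    abort("power request must be 'n1,n2,dist1,dist2,alpha'")
  }
  wmw_power(as.integer(parts[1]), as.integer(parts[2]), parts[3], parts[4],
            alpha = as.numeric(parts[5]), reps = reps, seed = seed)
}
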