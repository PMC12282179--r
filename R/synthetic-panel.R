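#' Plan a CRISPR array for a synthetic strain
#'
#' An array plan specifies one planted repeat-spacer array: its system type
#' (palindromic-repeat type I-E or short type II-C), whether it sits next to
#' a Cas operon (canonical) or far from any Cas gene (orphan), its spacer
#' count and where each spacer sequence comes from.
#'
#' @param system_type `"I-E"` or `"II-C"`.
#' @param context `"canonical"` or `"orphan"`.
#' @param n_spacers number of spacers (>= 1); the array carries
#'   `n_spacers + 1` repeat copies.
#' @param repeat_seq direct repeat (23-40 bp). Defaults to the catalog
#'   representative for the system type; for I-E the hairpin loop positions
#'   are overwritten with `tetraloop`.
#' @param tetraloop 4-nt loop planted into the I-E repeat hairpin (ignored
#'   for II-C).
#' @param spacer_len spacer length in bp (default 32).
#' @param spacer_sources character vector of length `n_spacers`; each entry
#'   one of `"random"`, `"prophage:<id>"`, or
#'   `"shared:<strain_id>,<array_idx>,<spacer_idx>"`. Defaults to all random.
#' @param mutation_rate per-base substitution rate applied to
#'   prophage-sourced spacers (0 = exact protospacer copies).
#' @param contig index of the contig to place the array on (`NA` =
#'   assign automatically).
#' @return a list of class `array_plan`.
#' @export
array_plan <- function(system_type = c("I-E", "II-C"),
                       context = c("canonical", "orphan"),
                       n_spacers = 10L,
                       repeat_seq = NULL, tetraloop = "TTCA",
                       spacer_len = 32L, spacer_sources = NULL,
                       mutation_rate = 0, contig = NA_integer_) {
  system_type <- match.arg(system_type)
  context <- match.arg(context)
  if (n_spacers < 1) abort("array plan needs n_spacers >= 1")
  if (is.null(repeat_seq)) {
    cat_ <- default_repeat_catalog()
    repeat_seq <- cat_$repeat_seq[match(if (system_type == "I-E") "I-E" else "II-C",
                                        cat_$subtype)]
    if (system_type == "I-E") {
      if (nchar(tetraloop) != 4) abort("tetraloop must be 4 nt")
      hp <- fold_hairpin(repeat_seq)
      loop_at <- hp$arm5_start + hp$stem_len  # 0-based loop start
      substr(repeat_seq, loop_at + 1, loop_at + 4) <- tetraloop
    }
  }
  if (nchar(repeat_seq) < 23 || nchar(repeat_seq) > 40) {
    abort("repeat length must be in [23, 40]")
  }
  if (system_type == "I-E") {
    hp <- fold_hairpin(repeat_seq)
    if (is.null(hp) || hp$loop_seq != tetraloop) {
      abort("I-E repeat must fold to a hairpin whose loop equals the tetraloop")
    }
  }
  if (is.null(spacer_sources)) spacer_sources <- rep("random", n_spacers)
  if (length(spacer_sources) != n_spacers) {
    abort("spacer_sources must have one entry per spacer")
  }
  structure(list(system_type = system_type, context = context,
                 n_spacers = as.integer(n_spacers), repeat_seq = repeat_seq,
                 tetraloop = if (system_type == "I-E") tetraloop else NA_character_,
                 spacer_len = as.integer(spacer_len),
                 spacer_sources = spacer_sources,
                 mutation_rate = mutation_rate, contig = contig),
            class = "array_plan")
}

#' Plan a prophage region for a synthetic strain
#'
#' @param prophage_id unique region id (panel-wide).
#' @param length region length in bp (>= 1000).
#' @param completeness `"intact"`, `"questionable"`, or `"incomplete"`.
#' @param contig contig index (`NA` = automatic).
#' @return a list of class `prophage_plan`.
#' @export
prophage_plan <- function(prophage_id, length = 8000L,
                          completeness = c("intact", "questionable", "incomplete"),
                          contig = NA_integer_) {
  completeness <- match.arg(completeness)
  if (length < 1000) abort("prophage regions must be >= 1 kb")
  structure(list(prophage_id = prophage_id, length = as.integer(length),
                 completeness = completeness, contig = contig),
            class = "prophage_plan")
}

#' Plan a synthetic strain
#'
#' @param strain_id strain name.
#' @param contig_lengths integer vector of contig lengths in bp.
#' @param arrays list of [array_plan()]s.
#' @param prophages list of [prophage_plan()]s.
#' @param genes number of decoy (non-Cas) gene annotations to scatter.
#' @return a list of class `strain_plan`.
#' @export
strain_plan <- function(strain_id, contig_lengths = c(40000L, 30000L),
                        arrays = list(), prophages = list(), genes = 4L) {
  structure(list(strain_id = strain_id,
                 contig_lengths = as.integer(contig_lengths),
                 arrays = arrays, prophages = prophages,
                 genes = as.integer(genes)),
            class = "strain_plan")
}

## composite feature builders -------------------------------------------------

# I-E and II-C operon gene names, in operon order
CAS_OPERON <- list(
  `I-E`  = c("cas3", "cas8e", "cas11", "cas7", "cas5", "cas6e", "cas1", "cas2"),
  `II-C` = c("cas9", "cas1", "cas2")
)

# Build the sequence and relative annotation of one planted feature.
# Returns list(seq, genes = tibble(rel_start, rel_end, strand, type, name),
#              array_rel = c(start, end) or NULL, ...)
build_array_feature <- function(plan, spacers) {
  rep_seq <- plan$repeat_seq
  units <- character(2L * plan$n_spacers + 1L)
  units[seq(1, length(units), by = 2)] <- rep_seq
  units[seq(2, length(units), by = 2)] <- spacers
  array_seq <- paste(units, collapse = "")

  genes <- tibble(rel_start = integer(), rel_end = integer(),
                  strand = character(), type = character(), name = character())
  seq_parts <- character(0)
  pos <- 0L
  add <- function(s) {
    seq_parts[[length(seq_parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  if (plan$context == "canonical") {
    if (plan$system_type == "II-C") {
      # tracrRNA-like element: reverse complement of 24 bp of the repeat,
      # upstream of the Cas operon
      anti <- revcomp(substr(rep_seq, 1, 24))
      genes <- bind_rows(genes, tibble(rel_start = pos, rel_end = pos + 24L,
                                       strand = "-", type = "ncRNA",
                                       name = "tracr_anti_repeat"))
      add(anti)
      add(random_dna(sample(50:200, 1)))
    }
    for (g in CAS_OPERON[[plan$system_type]]) {
      glen <- sample(600:1200, 1)
      genes <- bind_rows(genes, tibble(rel_start = pos, rel_end = pos + glen,
                                       strand = "+", type = "gene", name = g))
      add(random_dna(glen))
      add(random_dna(sample(20:80, 1)))
    }
    # leader gap between operon end and array start, within the 500 bp rule
    add(random_dna(sample(100L:400L, 1)))
  }
  array_rel <- c(pos, pos + nchar(array_seq))
  add(array_seq)
  list(seq = paste(seq_parts, collapse = ""), genes = genes,
       array_rel = array_rel)
}

resolve_spacers <- function(plans, prophage_seqs) {
  # returns nested list spacers[[strain]][[array_idx]] and a spacer truth tibble
  done <- list()
  truth <- list()
  for (sp in plans) {
    sid <- sp$strain_id
    done[[sid]] <- list()
    for (ai in seq_along(sp$arrays)) {
      ap <- sp$arrays[[ai]]
      seqs <- character(ap$n_spacers)
      rows <- vector("list", ap$n_spacers)
      for (si in seq_len(ap$n_spacers)) {
        src <- ap$spacer_sources[[si]]
        if (src == "random") {
          seqs[si] <- random_dna(ap$spacer_len)
          rows[[si]] <- tibble(source = "random", prophage_id = NA_character_,
                               src_start = NA_integer_, src_end = NA_integer_,
                               src_strand = NA_character_)
        } else if (startsWith(src, "prophage:")) {
          pid <- sub("^prophage:", "", src)
          pseq <- prophage_seqs[[pid]]
          if (is.null(pseq)) abort(sprintf("unknown prophage id '%s'", pid))
          if (nchar(pseq) < ap$spacer_len) abort("prophage shorter than spacer")
          s0 <- sample(0:(nchar(pseq) - ap$spacer_len), 1)
          proto <- sub0(pseq, s0, s0 + ap$spacer_len)
          strand <- sample(c("+", "-"), 1)
          spacer <- if (strand == "+") proto else revcomp(proto)
          seqs[si] <- mutate_seq(spacer, ap$mutation_rate)
          rows[[si]] <- tibble(source = src, prophage_id = pid,
                               src_start = s0,
                               src_end = s0 + ap$spacer_len,
                               src_strand = strand)
        } else if (startsWith(src, "shared:")) {
          ref <- strsplit(sub("^shared:", "", src), ",")[[1]]
          if (length(ref) != 3) abort("shared source must be strain,array,index")
          rs <- done[[ref[1]]][[as.integer(ref[2])]]
          if (is.null(rs)) {
            abort(sprintf("shared source %s not yet generated; order plans so donors come first", src))
          }
          seqs[si] <- rs[as.integer(ref[3])]
          rows[[si]] <- tibble(source = src, prophage_id = NA_character_,
                               src_start = NA_integer_, src_end = NA_integer_,
                               src_strand = NA_character_)
        } else {
          abort(sprintf("unknown spacer source '%s'", src))
        }
      }
      done[[sid]][[ai]] <- seqs
      truth[[length(truth) + 1L]] <- bind_rows(rows) |>
        mutate(strain_id = sid, array_idx = ai,
               spacer_idx = seq_len(ap$n_spacers), seq = seqs,
               .before = 1)
    }
  }
  list(spacers = done, truth = bind_rows(truth))
}

#' Build a synthetic strain panel with planted ground truth
#'
#' Generates multi-contig genomes carrying the planted CRISPR arrays,
#' Cas operons, prophage regions and decoy gene annotations described by the
#' plans, all placed without overlap and separated by at least 700 bp so the
#' canonical/orphan 500 bp rule is unambiguous. Canonical arrays sit
#' 100-400 bp downstream of their Cas operon; orphan arrays are placed away
#' from every Cas gene. Prophage-sourced spacers are exact copies of a
#' subinterval of the planted prophage (optionally mutated at the plan's
#' per-base rate). One seed controls every draw; the same plans and seed give
#' byte-identical output.
#'
#' @param plans list of [strain_plan()]s. Strains donating shared spacers
#'   must precede the recipients.
#' @param seed integer seed controlling all randomness.
#' @param out_dir optional directory; when given, per-strain FASTA + GFF3,
#'   a panel-wide prophage BED and truth TSVs are written there.
#' @return a list of class `crispr_panel` with elements `sequences` (named
#'   list of per-strain contig vectors), `genes`, `prophages`, `truth`
#'   (list of `arrays` and `spacers` tibbles), and `seed`.
#' @export
build_strain_panel <- function(plans, seed = 1L, out_dir = NULL) {
  if (!length(plans)) abort("no strain plans given")
  ids <- vapply(plans, `[[`, character(1), "strain_id")
  if (anyDuplicated(ids)) abort("duplicate strain ids")
  withr::with_seed(seed, {
    panel <- build_panel_impl(plans)
  })
  panel$seed <- seed
  panel$plans <- plans
  class(panel) <- "crispr_panel"
  if (!is.null(out_dir)) write_panel(panel, out_dir)
  panel
}

build_panel_impl <- function(plans) {
  # prophage sequences first (spacers may copy from them)
  prophage_seqs <- list()
  for (sp in plans) {
    for (pp in sp$prophages) {
      if (!is.null(prophage_seqs[[pp$prophage_id]])) {
        abort(sprintf("duplicate prophage id '%s'", pp$prophage_id))
      }
      prophage_seqs[[pp$prophage_id]] <- random_dna(pp$length)
    }
  }
  rs <- resolve_spacers(plans, prophage_seqs)

  MIN_GAP <- 700L
  sequences <- list()
  genes_out <- list(); proph_out <- list(); arrays_out <- list()

  for (sp in plans) {
    sid <- sp$strain_id
    n_contigs <- length(sp$contig_lengths)
    # features per contig: automatic round-robin for unassigned
    feats <- c(
      lapply(seq_along(sp$arrays), function(i) list(kind = "array", idx = i,
                                                    contig = sp$arrays[[i]]$contig)),
      lapply(seq_along(sp$prophages), function(i) list(kind = "prophage", idx = i,
                                                       contig = sp$prophages[[i]]$contig)),
      if (sp$genes > 0) lapply(seq_len(sp$genes), function(i) {
        list(kind = "decoy", idx = i, contig = NA_integer_)
      })
    )
    auto <- which(vapply(feats, function(f) is.na(f$contig), logical(1)))
    for (j in seq_along(auto)) feats[[auto[j]]]$contig <- ((j - 1L) %% n_contigs) + 1L

    contig_seqs <- character(n_contigs)
    for (ci in seq_len(n_contigs)) {
      clen <- sp$contig_lengths[ci]
      here <- feats[vapply(feats, function(f) f$contig == ci, logical(1))]
      built <- lapply(here, function(f) {
        switch(f$kind,
          array = {
            ap <- sp$arrays[[f$idx]]
            b <- build_array_feature(ap, rs$spacers[[sid]][[f$idx]])
            c(b, list(kind = "array", idx = f$idx))
          },
          prophage = {
            pp <- sp$prophages[[f$idx]]
            list(seq = prophage_seqs[[pp$prophage_id]],
                 genes = tibble(rel_start = integer(), rel_end = integer(),
                                strand = character(), type = character(),
                                name = character()),
                 array_rel = NULL, kind = "prophage", idx = f$idx)
          },
          decoy = {
            glen <- sample(600:1200, 1)
            list(seq = random_dna(glen),
                 genes = tibble(rel_start = 0L, rel_end = glen, strand = "+",
                                type = "gene",
                                name = sprintf("hyp_%s_%d", sid, f$idx)),
                 array_rel = NULL, kind = "decoy", idx = f$idx)
          })
      })
      lens <- vapply(built, function(b) nchar(b$seq), integer(1))
      need <- sum(lens) + MIN_GAP * (length(built) + 1L)
      if (length(built) && need > clen) {
        abort(sprintf(
          "strain %s contig %d: planted features (%d bp plus %d bp spacing) exceed contig length %d; features would overlap",
          sid, ci, sum(lens), MIN_GAP * (length(built) + 1L), clen))
      }
      # distribute slack over the gaps
      ngap <- length(built) + 1L
      slack <- clen - sum(lens) - MIN_GAP * ngap
      cuts <- sort(sample(0:slack, ngap - 1L, replace = TRUE))
      gaps <- MIN_GAP + diff(c(0L, cuts, slack))
      pos <- 0L
      parts <- character(0)
      cid <- sprintf("%s_c%d", sid, ci)
      for (bi in seq_along(built)) {
        parts <- c(parts, random_dna(gaps[bi]))
        pos <- pos + gaps[bi]
        b <- built[[bi]]
        parts <- c(parts, b$seq)
        if (nrow(b$genes)) {
          genes_out[[length(genes_out) + 1L]] <- b$genes |>
            mutate(strain_id = sid, contig_id = cid,
                   start = .data$rel_start + pos, end = .data$rel_end + pos) |>
            select("strain_id", "contig_id", "start", "end", "strand",
                   "type", "name")
        }
        if (b$kind == "array") {
          ap <- sp$arrays[[b$idx]]
          a0 <- pos + b$array_rel[1]
          arrays_out[[length(arrays_out) + 1L]] <- tibble(
            strain_id = sid, contig_id = cid, array_idx = b$idx,
            start = a0, end = pos + b$array_rel[2],
            system_type = ap$system_type, context = ap$context,
            repeat_seq = ap$repeat_seq, tetraloop = ap$tetraloop,
            n_spacers = ap$n_spacers,
            repeats = list(rep(ap$repeat_seq, ap$n_spacers + 1L)),
            spacers = list(rs$spacers[[sid]][[b$idx]])
          )
        } else if (b$kind == "prophage") {
          pp <- sp$prophages[[b$idx]]
          proph_out[[length(proph_out) + 1L]] <- tibble(
            strain_id = sid, contig_id = cid, start = pos,
            end = pos + nchar(b$seq), prophage_id = pp$prophage_id,
            completeness = pp$completeness
          )
        }
        pos <- pos + nchar(b$seq)
      }
      parts <- c(parts, random_dna(gaps[length(gaps)]))
      contig_seqs[ci] <- paste(parts, collapse = "")
      stopifnot(nchar(contig_seqs[ci]) == clen)
    }
    names(contig_seqs) <- sprintf("%s_c%d", sid, seq_len(n_contigs))
    sequences[[sid]] <- contig_seqs
  }

  list(sequences = sequences,
       genes = bind_rows(genes_out),
       prophages = bind_rows(proph_out),
       prophage_seqs = prophage_seqs,
       truth = list(arrays = bind_rows(arrays_out), spacers = rs$truth))
}

#' @rdname build_strain_panel
#' @param panel a `crispr_panel`.
#' @param dir output directory.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(panel$sequences)) {
    write_assembly(panel$sequences[[sid]], file.path(dir, paste0(sid, ".fasta")))
    g <- filter(panel$genes, .data$strain_id == sid)
    write_gene_annotations(select(g, -"strain_id"),
                           file.path(dir, paste0(sid, ".gff3")))
  }
  write_prophage_bed(panel$prophages, file.path(dir, "prophages.bed"))
  readr::write_tsv(select(panel$truth$arrays, -"repeats", -"spacers"),
                   file.path(dir, "truth_arrays.tsv"))
  readr::write_tsv(panel$truth$spacers, file.path(dir, "truth_spacers.tsv"))
  invisible(dir)
}

#' @export
print.crispr_panel <- function(x, ...) {
  cat(sprintf("<crispr_panel> %d strains, %d planted arrays, %d prophages (seed %d)\n",
              length(x$sequences), nrow(x$truth$arrays),
              nrow(x$prophages), x$seed))
  invisible(x)
}
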