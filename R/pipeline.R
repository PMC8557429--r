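#' Pipeline configuration
#'
#' Collects file paths, parameters and the seed for the pipeline drivers.
#' Any field can be overridden; \code{NULL} path fields disable the
#' corresponding input. A configuration can also be loaded from a YAML
#' file with \code{\link{read_pipeline_config}}.
#'
#' @param proteome_fasta path to a protein FASTA (or NULL).
#' @param transcripts_fasta path to a nucleotide FASTA to be translated
#'   (or NULL).
#' @param signal_tsv path to a signal annotation TSV; when NULL the
#'   built-in hydrophobicity heuristic is used.
#' @param seeds_fasta path to seed query sequences for the similarity arm
#'   (or NULL to run the motif arm alone).
#' @param ms_tsv path to an MS identification TSV.
#' @param gff3,genome_fasta,alignment_fasta gene-structure inputs.
#' @param outdir output directory (NULL = no files written).
#' @param pattern a \code{\link{pattern_params}} object.
#' @param search a \code{\link{search_params}} object.
#' @param ms_tol MS mass tolerance in Da.
#' @param intron_tolerance column tolerance for conserved-intron calls.
#' @param min_orf_len minimum ORF length for translation.
#' @param seed integer seed for any stochastic stage.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(proteome_fasta = NULL, transcripts_fasta = NULL,
                            signal_tsv = NULL, seeds_fasta = NULL,
                            ms_tsv = NULL, gff3 = NULL,
                            genome_fasta = NULL, alignment_fasta = NULL,
                            outdir = NULL, pattern = pattern_params(),
                            search = search_params(), ms_tol = 0.01,
                            intron_tolerance = 2L, min_orf_len = 60L,
                            seed = 1L) {
  structure(list(proteome_fasta = proteome_fasta,
                 transcripts_fasta = transcripts_fasta,
                 signal_tsv = signal_tsv, seeds_fasta = seeds_fasta,
                 ms_tsv = ms_tsv, gff3 = gff3,
                 genome_fasta = genome_fasta,
                 alignment_fasta = alignment_fasta, outdir = outdir,
                 pattern = pattern, search = search, ms_tol = ms_tol,
                 intron_tolerance = intron_tolerance,
                 min_orf_len = min_orf_len, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields override the \code{\link{pipeline_config}} defaults;
#' nested \code{pattern} and \code{search} blocks override the respective
#' parameter defaults.
#'
#' @param path path to a YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pat <- do.call(pattern_params, as.list(y$pattern))
  sea <- do.call(search_params, as.list(y$search))
  y$pattern <- NULL; y$search <- NULL
  do.call(pipeline_config, c(y, list(pattern = pat, search = sea)))
}

.write_stage <- function(outdir, name, writer) {
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writer(file.path(outdir, name))
}

#' Run the discovery pipeline
#'
#' Executes the discovery stages in protocol order: translate (when
#' transcripts are given), signal gate, motif scan in parallel with a
#' relaxed similarity pass, union, greedy dedup, length filter, stringent
#' second similarity pass, annotation and clustering. A run manifest
#' records parameters, seed and per-stage counts; reruns with the same
#' inputs and configuration are reproducible.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param proteome optional in-memory protein record data frame (replaces
#'   the FASTA inputs).
#' @param signals optional in-memory signal annotation data frame.
#' @param seeds optional in-memory seed record data frame.
#' @return list with \code{candidates} (record data frame with provenance
#'   columns), \code{representatives}, \code{members}, \code{annotated}
#'   (list of annotated precursors), \code{clusters}, \code{manifest}.
#' @export
run_discover <- function(config = pipeline_config(), proteome = NULL,
                         signals = NULL, seeds = NULL) {
  set.seed(config$seed)
  if (is.null(proteome)) {
    if (!is.null(config$transcripts_fasta)) {
      if (!file.exists(config$transcripts_fasta)) {
        stop("transcript input does not exist: ", config$transcripts_fasta)
      }
      tx <- read_fasta(config$transcripts_fasta, type = "nucleotide")
      proteome <- translate_orfs(tx, min_len = config$min_orf_len)
    } else if (!is.null(config$proteome_fasta)) {
      if (!file.exists(config$proteome_fasta)) {
        stop("proteome input does not exist: ", config$proteome_fasta)
      }
      proteome <- read_fasta(config$proteome_fasta)
    } else {
      stop("no proteome or transcript input configured")
    }
  }
  if (is.null(signals)) {
    signals <- if (!is.null(config$signal_tsv)) {
      read_signal_annotations(config$signal_tsv)
    } else {
      predict_signal(proteome)
    }
  }
  if (is.null(seeds) && !is.null(config$seeds_fasta)) {
    seeds <- read_fasta(config$seeds_fasta)
  }
  counts <- c(input = nrow(proteome))

  secretome <- gate_by_signal(proteome, signals, missing = "drop")
  counts["secretome"] <- nrow(secretome)

  hits <- scan_multicopy(secretome, config$pattern)
  counts["pattern_hits"] <- nrow(hits)

  pass1_ids <- character(0)
  if (!is.null(seeds) && nrow(proteome) > 0L) {
    aln <- align_all(proteome, seeds, config$search)
    best <- tapply(aln$evalue, aln$query_id, min)
    pass1_ids <- names(best)[best <= config$search$relaxed_evalue]
  }
  counts["relaxed_hits"] <- length(pass1_ids)

  cand_ids <- union(hits$protein_id, pass1_ids)
  candidates <- proteome[proteome$id %in% cand_ids, , drop = FALSE]
  counts["candidates"] <- nrow(candidates)

  dd <- dedup_greedy(candidates, identity = config$pattern$dedup_identity)
  counts["representatives"] <- nrow(dd$representatives)

  kept <- filter_length(dd$representatives,
                        max_len = config$pattern$max_precursor_len)
  counts["length_filtered"] <- nrow(kept)

  pass2_ids <- character(0)
  if (nrow(kept) > 0L && nrow(proteome) > 0L) {
    aln2 <- align_all(proteome, kept, config$search)
    best2 <- tapply(aln2$evalue, aln2$query_id, min)
    pass2_ids <- setdiff(
      names(best2)[best2 <= config$search$stringent_evalue], kept$id)
    pass2_ids <- setdiff(pass2_ids, dd$members$member)
  }
  counts["stringent_added"] <- length(pass2_ids)
  final <- rbind(kept[, c("id", "sequence")],
                 proteome[proteome$id %in% pass2_ids, c("id", "sequence"),
                          drop = FALSE])
  final$provenance <- c(
    rep("primary", nrow(kept)),
    rep("pass2", length(intersect(proteome$id, pass2_ids))))
  counts["final"] <- nrow(final)

  sig_by_id <- signals[match(final$id, signals$protein_id), , drop = FALSE]
  annotated <- lapply(seq_len(nrow(final)), function(i) {
    annotate_precursor(final[i, , drop = FALSE],
                       signal = sig_by_id[i, , drop = FALSE])
  })
  clusters <- if (nrow(final) > 0L) {
    graph_components(build_graph(final, config$search,
                                 threshold = config$search$cluster_evalue))
  } else list()
  counts["clusters"] <- length(clusters)

  manifest <- list(stage_counts = as.list(counts),
                   pattern = unclass(config$pattern),
                   search = unclass(config$search), seed = config$seed)
  .write_stage(config$outdir, "candidates.fasta",
               function(p) write_fasta(final, p))
  .write_stage(config$outdir, "hits.tsv", function(p)
    utils::write.table(hits, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  .write_stage(config$outdir, "peptides.fasta",
               function(p) write_peptides_fasta(annotated, p))
  .write_stage(config$outdir, "manifest.json", function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE))
  list(candidates = final, representatives = kept, members = dd$members,
       hits = hits, annotated = annotated, clusters = clusters,
       manifest = manifest)
}

#' Run the MS confirmation stage
#'
#' @param config a \code{\link{pipeline_config}} (supplies \code{ms_tsv},
#'   \code{ms_tol}, \code{outdir}).
#' @param annotated list of annotated precursors (e.g. from
#'   \code{\link{run_discover}}).
#' @param ids optional in-memory identification data frame (replaces
#'   \code{ms_tsv}).
#' @param proteome optional background records for novel-precursor
#'   detection.
#' @return list with \code{matches} and \code{summary}.
#' @export
run_ms <- function(config, annotated, ids = NULL, proteome = NULL) {
  if (is.null(ids)) {
    if (is.null(config$ms_tsv)) stop("no MS identification input configured")
    ids <- read_ms_identifications(config$ms_tsv)
  }
  matches <- match_identifications(ids, annotated, tol = config$ms_tol,
                                   proteome = proteome)
  summ <- confirmation_summary(matches)
  .write_stage(config$outdir, "ms_matches.tsv", function(p)
    utils::write.table(matches, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  list(matches = matches, summary = summ)
}

#' Run the gene-structure stage
#'
#' @param config a \code{\link{pipeline_config}} (supplies \code{gff3},
#'   \code{genome_fasta}, \code{alignment_fasta},
#'   \code{intron_tolerance}).
#' @param proteins protein record data frame for the modeled genes.
#' @return list with \code{introns} (per-gene annotations) and
#'   \code{conserved} (conservation report).
#' @export
run_genes <- function(config, proteins) {
  if (is.null(config$gff3) || is.null(config$genome_fasta)) {
    stop("gene-structure inputs not configured")
  }
  models <- read_gene_models(config$gff3)
  genome_set <- Biostrings::readDNAStringSet(config$genome_fasta)
  names(genome_set) <- vapply(strsplit(names(genome_set), "[ \t]"), `[`,
                              "", 1L)
  genome <- setNames(as.character(genome_set), names(genome_set))
  introns <- list()
  for (g in names(models)) {
    prot <- proteins[proteins$id == g, , drop = FALSE]
    if (nrow(prot) == 0L) stop("no protein supplied for gene ", g)
    introns[[g]] <- list(protein_id = g,
                         introns = protein_introns(models[[g]], prot,
                                                   genome))
  }
  conserved <- NULL
  if (!is.null(config$alignment_fasta)) {
    aln <- read_fasta(config$alignment_fasta)
    conserved <- conserved_introns(introns,
                                   setNames(aln$sequence, aln$id),
                                   tolerance = config$intron_tolerance)
  }
  list(introns = introns, conserved = conserved)
}

#' Generate the full synthetic study input set
#'
#' Runs the proteome, gene-model and MS generators with one seed and
#' (optionally) writes every file the other drivers consume. Held-out
#' families are written to a separate FASTA and excluded from the
#' discovery proteome.
#'
#' @param config a \code{\link{pipeline_config}} (supplies \code{seed} and
#'   \code{outdir}).
#' @param specs family specifications (default
#'   \code{\link{default_family_specs}}).
#' @param n_decoys number of decoys.
#' @return list with the generator outputs (\code{proteome},
#'   \code{ms}, \code{genes}) and the file paths written (when
#'   \code{outdir} is set).
#' @export
run_simulate <- function(config = pipeline_config(),
                         specs = default_family_specs(),
                         n_decoys = 1000L) {
  sim <- generate_proteome(specs = specs, n_decoys = n_decoys,
                           seed = config$seed)
  held_ids <- sim$truth$id[sim$truth$held_out]
  discovery <- sim$records[!sim$records$id %in% held_ids, , drop = FALSE]
  held <- sim$records[sim$records$id %in% held_ids, , drop = FALSE]

  sig_of <- function(id) {
    sim$signals[sim$signals$protein_id == id, , drop = FALSE]
  }
  planted <- sim$truth$id[sim$truth$label == "planted" &
                            !sim$truth$held_out]
  ann_planted <- lapply(planted, function(id) {
    r <- sim$records[sim$records$id == id, , drop = FALSE]
    annotate_precursor(r, signal = sig_of(id))
  })
  ann_held <- lapply(held$id, function(id) {
    r <- sim$records[sim$records$id == id, , drop = FALSE]
    annotate_precursor(r, signal = sig_of(id))
  })
  ms <- generate_ms_identifications(ann_planted, n = 200L,
                                    seed = config$seed, novel = ann_held)

  gwa_ids <- sim$truth$id[!is.na(sim$truth$family) &
                            sim$truth$family == "gwa"]
  genes <- NULL
  if (length(gwa_ids) >= 2L) {
    gwa <- sim$records[sim$records$id %in% gwa_ids, , drop = FALSE]
    first_seq <- gwa$sequence[1L]
    cys <- which(strsplit(first_seq, "")[[1L]] == "C")
    # phase-0 intron between the two C-terminal Cys codons
    plan <- data.frame(id = gwa$id,
                       protein_pos = cys[length(cys) - 1L] + 12L,
                       phase = 0L, stringsAsFactors = FALSE)
    genes <- generate_gene_models(gwa, plan, seed = config$seed)
  }

  paths <- list()
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$outdir, f)
    write_fasta(discovery, p("proteome.fasta"))
    if (nrow(held)) write_fasta(held, p("held_out.fasta"))
    write_signal_annotations(sim$signals, p("signals.tsv"))
    utils::write.table(sim$truth, p("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_ms_identifications(ms$identifications, p("ms_identifications.tsv"))
    utils::write.table(ms$truth, p("ms_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(genes)) {
      write_genome_fasta(genes$genome, p("genome.fasta"))
      write_gff3(genes$gff, p("genes.gff3"))
    }
    paths <- list(proteome = p("proteome.fasta"),
                  signals = p("signals.tsv"), truth = p("truth.tsv"),
                  ms = p("ms_identifications.tsv"))
  }
  list(proteome = sim, ms = ms, genes = genes,
       annotated_planted = ann_planted, annotated_held = ann_held,
       paths = paths)
}
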