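# residues used for spacers, mutations and decoy padding: no G (amidation
# donor), no K/R (cleavage sites), no C (Cys-domain bookkeeping), so that
# planted structure can never be created or destroyed by chance
.SPACER_ALPH <- strsplit("ADEFHILMNPQSTVWY", "")[[1L]]
.ALL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# the two published screening expressions, evaluated directly by a
# backtracking engine: the generator's acceptance oracle
.printed_patterns <- c(
  "((.{2,25}G[KR][KR])|(.{2,25}[KR](.{1}|.{3}|.{5})G[KR*])){3,}",
  "(.{5,25}[KR][KR]){5,}"
)

.oracle_accept <- function(seqs) {
  grepl(.printed_patterns[1L], seqs, perl = TRUE) |
    grepl(.printed_patterns[2L], seqs, perl = TRUE)
}

.rand_seq <- function(n, alphabet = .SPACER_ALPH) {
  if (n <= 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Specification of a synthetic precursor family
#'
#' Describes one planted family: its peptide motif (lower-case \code{x}
#' marks wildcard positions instantiated once per family), copy counts,
#' spacer lengths, architecture and ortholog divergence. Families marked
#' \code{discoverable} are verified against the published screening
#' expressions at generation time; \code{held_out} families are emitted
#' with the proteome truth but intended to be withheld from discovery
#' input, emulating precursors that only mass spectrometry reveals.
#'
#' @param family_id short family label.
#' @param architecture one of \code{multicopy},
#'   \code{single_copy_plus_cys_domain}, \code{cys8_peptide},
#'   \code{single_copy}.
#' @param copy_motif peptide motif, \code{x} = wildcard position.
#' @param copy_count_range length-2 integer range of copies per precursor.
#' @param spacer_len_range length-2 integer range of intersequence lengths
#'   (0,0 gives directly abutting copies).
#' @param amidated do copies end in an amidation glycine before the site?
#' @param cys_domain_len,cys_count size and cysteine count of a C-terminal
#'   Cys-rich domain (Cys-domain architectures only).
#' @param cys_tail append two C-terminal cysteines separated by 24 spacer
#'   residues (the RGWamide/APGWamide-style tail used for gene-structure
#'   comparisons).
#' @param n_members number of ortholog members (one per pseudo-species).
#' @param subs_rate per-site substitution rate applied to unprotected
#'   positions when deriving members from the family ancestor.
#' @param discoverable must members satisfy the screening thresholds?
#' @param held_out exclude from discovery input (novel-precursor truth).
#' @return a list of class \code{family_spec}.
#' @export
family_spec <- function(family_id, architecture = "multicopy", copy_motif,
                        copy_count_range = c(4L, 6L),
                        spacer_len_range = c(2L, 6L), amidated = TRUE,
                        cys_domain_len = 0L, cys_count = 0L,
                        cys_tail = FALSE, n_members = 8L, subs_rate = 0.1,
                        discoverable = TRUE, held_out = FALSE) {
  stopifnot(nzchar(family_id), nzchar(copy_motif),
            copy_count_range[1L] >= 1L,
            copy_count_range[1L] <= copy_count_range[2L],
            spacer_len_range[1L] >= 0L,
            spacer_len_range[1L] <= spacer_len_range[2L],
            n_members >= 1L, subs_rate >= 0, subs_rate < 1)
  structure(list(family_id = family_id, architecture = architecture,
                 copy_motif = copy_motif,
                 copy_count_range = as.integer(copy_count_range),
                 spacer_len_range = as.integer(spacer_len_range),
                 amidated = isTRUE(amidated),
                 cys_domain_len = as.integer(cys_domain_len),
                 cys_count = as.integer(cys_count),
                 cys_tail = isTRUE(cys_tail),
                 n_members = as.integer(n_members), subs_rate = subs_rate,
                 discoverable = isTRUE(discoverable),
                 held_out = isTRUE(held_out)),
            class = "family_spec")
}

#' Default synthetic family panel
#'
#' Emulates the precursor classes the pipeline targets: five multicopy
#' amidated families (one with directly abutting copies and a two-Cys
#' C-terminal tail, one with a monobasic-compatible copy), one
#' dibasic-only multicopy family, a vasotocin-like single-copy +
#' neurophysin-domain precursor, a CCWamide-like 8-Cys terminal peptide
#' precursor, and a held-out two-copy family that the screen cannot see
#' (novel-precursor truth for MS runs).
#'
#' @return list of \code{\link{family_spec}} objects.
#' @export
default_family_specs <- function() {
  list(
    family_spec("fmrf", copy_motif = "DPxFLRF", copy_count_range = c(5L, 7L),
                spacer_len_range = c(2L, 6L)),
    family_spec("pedal", copy_motif = "PSxLSx", copy_count_range = c(6L, 8L),
                spacer_len_range = c(5L, 12L), amidated = FALSE),
    family_spec("gwa", copy_motif = "ARGW", copy_count_range = c(4L, 6L),
                spacer_len_range = c(0L, 0L), cys_tail = TRUE),
    family_spec("asta", copy_motif = "xYSFGL", copy_count_range = c(4L, 6L),
                spacer_len_range = c(2L, 8L)),
    family_spec("mono", copy_motif = "KAADLRF", copy_count_range = c(4L, 6L),
                spacer_len_range = c(2L, 6L)),
    family_spec("qsg", copy_motif = "QSGFxE", copy_count_range = c(4L, 6L),
                spacer_len_range = c(2L, 8L)),
    family_spec("vaso", architecture = "single_copy_plus_cys_domain",
                copy_motif = "CYIQNCPRG", copy_count_range = c(1L, 1L),
                cys_domain_len = 80L, cys_count = 10L,
                discoverable = FALSE),
    family_spec("ccw", architecture = "cys8_peptide",
                copy_motif = "ccw", copy_count_range = c(1L, 1L),
                discoverable = FALSE),
    family_spec("wws", copy_motif = "WWSLPF", copy_count_range = c(2L, 2L),
                spacer_len_range = c(2L, 6L), discoverable = FALSE,
                held_out = TRUE)
  )
}

# canonical signal peptide: Met + charged n-region + 12-residue
# hydrophobic core + A-X-A cleavage motif; 18 residues, cleaved after 18
.make_signal <- function() {
  paste0("M", .rand_seq(2L, c("K", "R")),
         .rand_seq(12L, c("L", "V", "I", "F", "A")),
         "A", .rand_seq(1L, c("Q", "S", "T")), "A")
}

.instantiate_motif <- function(motif) {
  s <- strsplit(motif, "")[[1L]]
  s[s == "x"] <- sample(.SPACER_ALPH, sum(s == "x"), replace = TRUE)
  paste(s, collapse = "")
}

# assemble a family ancestor; returns sequence, per-position protection
# mask (TRUE = structural, never mutated) and the signal cleavage position
.build_ancestor <- function(spec) {
  sig <- .make_signal()
  parts <- list(list(seq = sig, prot = TRUE))
  add <- function(seq, prot) {
    if (nzchar(seq)) parts[[length(parts) + 1L]] <<- list(seq = seq,
                                                          prot = prot)
  }
  site <- function() sample(c("KR", "KR", "KR", "RR", "KK", "RK"), 1L)
  if (spec$architecture == "cys8_peptide") {
    add(.rand_seq(12L), FALSE)              # non-conserved lead peptide
    add(site(), TRUE)
    core <- strsplit(.rand_seq(25L), "")[[1L]]
    core[c(1L, 4L, 9L, 12L, 16L, 19L, 20L, 23L)] <- "C"
    core[25L] <- "W"                        # amidated aromatic C-terminus
    add(paste(core, collapse = ""), TRUE)
    add("G", TRUE)
  } else if (spec$architecture == "single_copy_plus_cys_domain") {
    copy <- .instantiate_motif(spec$copy_motif)
    add(copy, TRUE)
    if (spec$amidated) add("G", TRUE)
    add(site(), TRUE)
    dom <- strsplit(.rand_seq(spec$cys_domain_len), "")[[1L]]
    cys_at <- sort(sample(seq(3L, spec$cys_domain_len - 2L),
                          spec$cys_count))
    dom[cys_at] <- "C"
    add(paste(dom, collapse = ""), TRUE)
  } else {
    copy <- .instantiate_motif(spec$copy_motif)
    n_copies <- sample(seq(spec$copy_count_range[1L],
                           spec$copy_count_range[2L]), 1L)
    add(.rand_seq(sample(3:8, 1L)), FALSE)  # N-terminal pro-region
    for (i in seq_len(n_copies)) {
      add(copy, TRUE)
      if (spec$amidated) add("G", TRUE)
      add(site(), TRUE)
      if (i < n_copies) {
        add(.rand_seq(sample(seq(spec$spacer_len_range[1L],
                                 spec$spacer_len_range[2L]), 1L)), FALSE)
      }
    }
    if (spec$cys_tail) {
      add("C", TRUE)
      add(.rand_seq(24L), FALSE)
      add("C", TRUE)
      add(.rand_seq(3L), FALSE)
    } else {
      add(.rand_seq(sample(3:8, 1L)), FALSE)
    }
  }
  seqs <- vapply(parts, `[[`, "", "seq")
  prot <- rep(vapply(parts, `[[`, TRUE, "prot"), nchar(seqs))
  list(sequence = paste(seqs, collapse = ""), protected = prot,
       cleavage_after = nchar(sig))
}

.mutate_member <- function(ancestor, rate) {
  s <- strsplit(ancestor$sequence, "")[[1L]]
  idx <- which(!ancestor$protected)
  hit <- idx[stats::runif(length(idx)) < rate]
  if (length(hit)) s[hit] <- sample(.SPACER_ALPH, length(hit),
                                    replace = TRUE)
  paste(s, collapse = "")
}

# fail early on specs whose motif geometry cannot satisfy the screening
# thresholds
.check_discoverable_spec <- function(spec) {
  len <- nchar(spec$copy_motif)
  if (spec$amidated) {
    ok <- spec$copy_count_range[1L] >= 3L &&
      spec$spacer_len_range[2L] + len <= 25L &&
      spec$spacer_len_range[1L] + len >= 2L
  } else {
    ok <- spec$copy_count_range[1L] >= 5L &&
      spec$spacer_len_range[2L] + len <= 25L &&
      spec$spacer_len_range[1L] + len >= 5L
  }
  if (!ok) stop("family ", spec$family_id, " is marked discoverable but ",
                "its motif/spacer geometry cannot satisfy the screening ",
                "thresholds")
  invisible(TRUE)
}

#' Generate a synthetic proteome with ground truth
#'
#' Emits planted precursor families (orthologs derived from a family
#' ancestor by per-site substitution at unprotected positions), decoys
#' (random globular-like proteins, signal-bearing non-precursors and
#' glycine/basic-rich traps that can legitimately satisfy the screening
#' expressions), a signal-peptide annotation table, and a truth table.
#' Fully deterministic for a given seed. Every member of a
#' \code{discoverable} family is verified against direct evaluation of
#' the published screening expressions before emission.
#'
#' @param specs list of \code{\link{family_spec}} objects.
#' @param n_decoys number of decoy sequences (default 1000).
#' @param seed RNG seed.
#' @return list with \code{records} (id, sequence, species),
#'   \code{signals} (signal annotation data frame), \code{truth}
#'   (id, label, family, discoverable, held_out, species) and
#'   \code{specs}.
#' @export
generate_proteome <- function(specs = default_family_specs(),
                              n_decoys = 1000L, seed = 1L) {
  set.seed(seed)
  rec <- list(); sig <- list(); tru <- list()
  emit <- function(id, seqstr, species, has_sig, cleave, label, family,
                   disc, held) {
    rec[[length(rec) + 1L]] <<- data.frame(
      id = id, sequence = seqstr, species = species,
      stringsAsFactors = FALSE)
    sig[[length(sig) + 1L]] <<- data.frame(
      protein_id = id, has_signal = has_sig,
      cleavage_after = if (has_sig) cleave else NA_integer_,
      score = if (has_sig) 0.95 else 0.05, stringsAsFactors = FALSE)
    tru[[length(tru) + 1L]] <<- data.frame(
      id = id, label = label, family = family, discoverable = disc,
      held_out = held, species = species, stringsAsFactors = FALSE)
  }
  for (spec in specs) {
    if (spec$discoverable) .check_discoverable_spec(spec)
    anc <- .build_ancestor(spec)
    for (j in seq_len(spec$n_members)) {
      seqj <- .mutate_member(anc, spec$subs_rate)
      if (spec$discoverable && !.oracle_accept(seqj)) {
        stop("family ", spec$family_id, " member ", j,
             " failed oracle verification")
      }
      emit(sprintf("%s_m%02d", spec$family_id, j), seqj,
           sprintf("sp%02d", j), TRUE, anc$cleavage_after, "planted",
           spec$family_id, spec$discoverable, spec$held_out)
    }
  }
  if (n_decoys > 0L) {
    n_trap <- max(1L, round(0.1 * n_decoys))
    n_sig <- max(1L, round(0.1 * n_decoys))
    n_glob <- n_decoys - n_trap - n_sig
    k <- 0L
    for (i in seq_len(n_glob)) {
      k <- k + 1L
      emit(sprintf("decoy%04d", k),
           paste0("M", .rand_seq(sample(80:400, 1L), .ALL_AA)),
           "spXX", FALSE, NA_integer_, "decoy", NA_character_, FALSE,
           FALSE)
    }
    for (i in seq_len(n_sig)) {
      k <- k + 1L
      s <- .make_signal()
      emit(sprintf("decoy%04d", k),
           paste0(s, .rand_seq(sample(60:300, 1L), .ALL_AA)),
           "spXX", TRUE, nchar(s), "decoy", NA_character_, FALSE, FALSE)
    }
    trap_alph <- c(rep("G", 6L), rep("S", 3L), rep("K", 2L), rep("R", 2L),
                   rep("A", 3L), "P", "N", "Q")
    for (i in seq_len(n_trap)) {
      k <- k + 1L
      s <- .make_signal()
      emit(sprintf("decoy%04d", k),
           paste0(s, .rand_seq(sample(100:400, 1L), trap_alph)),
           "spXX", TRUE, nchar(s), "decoy_trap", NA_character_, FALSE,
           FALSE)
    }
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  list(records = bind(rec, data.frame(id = character(),
                                      sequence = character(),
                                      species = character())),
       signals = bind(sig, data.frame(protein_id = character(),
                                      has_signal = logical(),
                                      cleavage_after = integer(),
                                      score = numeric())),
       truth = bind(tru, data.frame(id = character(), label = character(),
                                    family = character(),
                                    discoverable = logical(),
                                    held_out = logical(),
                                    species = character())),
       specs = specs)
}

#' Generate gene models with planted introns
#'
#' Back-translates each precursor with random synonymous codons, inserts
#' GT..AG introns of random length at the planned protein positions and
#' phases, and emits a per-gene genomic scaffold plus GFF3 feature table.
#' Running \code{\link{protein_introns}} on the output recovers the plan
#' exactly, on either strand.
#'
#' @param precursors protein record data frame.
#' @param intron_plan data frame \code{id}, \code{protein_pos},
#'   \code{phase} (one row per planted intron).
#' @param seed RNG seed.
#' @param strands optional named character vector (\code{+}/\code{-}) per
#'   precursor id; default alternates starting with \code{+}.
#' @param intron_len_range intron length range in nt (default 60-500).
#' @return list with \code{genome} (named character, one scaffold per
#'   gene), \code{gff} (GFF3 data frame, see \code{\link{write_gff3}})
#'   and \code{truth} (the plan with strands).
#' @export
generate_gene_models <- function(precursors, intron_plan, seed = 1L,
                                 strands = NULL,
                                 intron_len_range = c(60L, 500L)) {
  set.seed(seed)
  inv_codon <- split(names(Biostrings::GENETIC_CODE),
                     Biostrings::GENETIC_CODE)
  if (is.null(strands)) {
    strands <- setNames(rep(c("+", "-"), length.out = nrow(precursors)),
                        precursors$id)
  }
  genome <- character(0)
  gff <- list()
  truth <- list()
  for (k in seq_len(nrow(precursors))) {
    id <- precursors$id[k]
    prot <- sub("\\*$", "", precursors$sequence[k])
    aa <- strsplit(prot, "")[[1L]]
    codons <- vapply(aa, function(a) {
      cand <- inv_codon[[a]]
      cand[sample.int(length(cand), 1L)]
    }, "")
    cds <- paste0(paste(codons, collapse = ""), "TAA")
    plan <- intron_plan[intron_plan$id == id, , drop = FALSE]
    if (nrow(plan) && any(plan$protein_pos > nchar(prot))) {
      stop("planned intron position beyond protein length for ", id)
    }
    brk <- integer(0)
    if (nrow(plan)) {
      brk <- ifelse(plan$phase == 0L, 3L * plan$protein_pos,
                    3L * (plan$protein_pos - 1L) + plan$phase)
      brk <- sort(unique(as.integer(brk)))
      if (any(brk <= 0L) || any(brk >= nchar(cds))) {
        stop("planned intron breakpoint outside CDS for ", id)
      }
    }
    bounds <- c(0L, brk, nchar(cds))
    exon_nt <- substring(cds, utils::head(bounds, -1L) + 1L,
                         bounds[-1L])
    introns <- vapply(seq_along(brk), function(i) {
      len <- sample(seq(intron_len_range[1L], intron_len_range[2L]), 1L)
      paste0("GT", .rand_seq(len - 4L, c("A", "C", "G", "T")), "AG")
    }, "")
    flank_l <- .rand_seq(sample(50:150, 1L), c("A", "C", "G", "T"))
    flank_r <- .rand_seq(sample(50:150, 1L), c("A", "C", "G", "T"))
    scaffold <- flank_l
    exon_coords <- matrix(0L, nrow = length(exon_nt), ncol = 2L)
    for (i in seq_along(exon_nt)) {
      exon_coords[i, 1L] <- nchar(scaffold) + 1L
      scaffold <- paste0(scaffold, exon_nt[i])
      exon_coords[i, 2L] <- nchar(scaffold)
      if (i <= length(introns)) scaffold <- paste0(scaffold, introns[i])
    }
    scaffold <- paste0(scaffold, flank_r)
    strand <- strands[[id]]
    chrom <- paste0("scf_", id)
    if (strand == "-") {
      L <- nchar(scaffold)
      scaffold <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(scaffold)))
      exon_coords <- cbind(L - exon_coords[, 2L] + 1L,
                           L - exon_coords[, 1L] + 1L)
    }
    genome[chrom] <- scaffold
    gstart <- min(exon_coords[, 1L]); gend <- max(exon_coords[, 2L])
    tid <- paste0(id, ".t1")
    rows <- list(
      data.frame(seqid = chrom, source = "pnpminer", type = "gene",
                 start = gstart, end = gend, score = ".", strand = strand,
                 phase = ".", attributes = paste0("ID=", id),
                 stringsAsFactors = FALSE),
      data.frame(seqid = chrom, source = "pnpminer", type = "mRNA",
                 start = gstart, end = gend, score = ".", strand = strand,
                 phase = ".",
                 attributes = paste0("ID=", tid, ";Parent=", id),
                 stringsAsFactors = FALSE)
    )
    # genomic order for GFF, transcription order for phase bookkeeping
    tr_order <- if (strand == "-") order(-exon_coords[, 1L])
                else order(exon_coords[, 1L])
    cum <- 0L
    cds_phase <- integer(nrow(exon_coords))
    for (i in tr_order) {
      cds_phase[i] <- (3L - cum %% 3L) %% 3L
      cum <- cum + exon_coords[i, 2L] - exon_coords[i, 1L] + 1L
    }
    for (i in seq_len(nrow(exon_coords))) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = chrom, source = "pnpminer", type = "exon",
        start = exon_coords[i, 1L], end = exon_coords[i, 2L], score = ".",
        strand = strand, phase = ".",
        attributes = paste0("ID=", tid, ".exon", i, ";Parent=", tid),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = chrom, source = "pnpminer", type = "CDS",
        start = exon_coords[i, 1L], end = exon_coords[i, 2L], score = ".",
        strand = strand, phase = as.character(cds_phase[i]),
        attributes = paste0("ID=", tid, ".cds;Parent=", tid),
        stringsAsFactors = FALSE)
    }
    gff[[length(gff) + 1L]] <- do.call(rbind, rows)
    if (nrow(plan)) {
      plan$strand <- strand
      truth[[length(truth) + 1L]] <- plan
    }
  }
  list(genome = genome,
       gff = do.call(rbind, gff),
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(id = character(), protein_pos = integer(),
                               phase = integer(), strand = character(),
                               stringsAsFactors = FALSE))
}

#' Write a GFF3 feature table
#'
#' @param gff data frame with the nine GFF3 columns (as produced by
#'   \code{\link{generate_gene_models}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(gff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write nucleotide records as FASTA
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 70L)
  invisible(path)
}

# eligibility pools for MS identification sampling; every emitted peptide
# string must occur exactly once across the context sequences so that the
# matcher's localization is unambiguous
.occurrences <- function(pep, context) {
  sum(vapply(context, function(s) {
    m <- gregexpr(pep, s, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }, 0L))
}

#' Generate synthetic MS identifications with ground truth
#'
#' Samples peptides from annotated precursors per category: full predicted
#' cores (with their modification lists), N-/C-/double truncations of 1-3
#' residues, monobasic-cleavage products honoring the 3-6 support rule,
#' internal fragments, peptides from held-out novel precursors, and
#' unmatchable sequences. All peptides are at least 4 residues long and
#' are constructed to be unambiguous (single occurrence, span not
#' colliding with another category's signature). Observed masses equal
#' the theoretical monoisotopic mass plus optional Gaussian error.
#'
#' @param annotated list of \code{\link{annotate_precursor}} objects (the
#'   discovered set).
#' @param category_mix named numeric vector of category proportions
#'   (summing to 1) over \code{full_dibasic}, \code{truncated_N},
#'   \code{truncated_C}, \code{truncated_both}, \code{internal},
#'   \code{monobasic_product}, \code{novel_precursor}, \code{unmatched}.
#' @param n number of identifications.
#' @param seed RNG seed.
#' @param novel list of annotated held-out precursors (required when the
#'   mix requests \code{novel_precursor}).
#' @param sigma standard deviation of Gaussian mass error in Da (default
#'   0).
#' @return list with \code{identifications} (data frame
#'   \code{source_id}, \code{peptide_sequence}, \code{modifications},
#'   \code{observed_mass}) and \code{truth} (\code{source_id},
#'   \code{category}, \code{precursor_id}, \code{start}, \code{end}).
#' @export
generate_ms_identifications <- function(annotated,
                                        category_mix = c(
                                          full_dibasic = 0.30,
                                          truncated_N = 0.12,
                                          truncated_C = 0.12,
                                          truncated_both = 0.08,
                                          internal = 0.08,
                                          monobasic_product = 0.10,
                                          novel_precursor = 0.15,
                                          unmatched = 0.05),
                                        n = 200L, seed = 1L, novel = NULL,
                                        sigma = 0) {
  stopifnot(abs(sum(category_mix) - 1) < 1e-8)
  set.seed(seed)
  context <- c(vapply(annotated, `[[`, "", "sequence"),
               vapply(novel, `[[`, "", "sequence"))
  unique_in_context <- function(pep) .occurrences(pep, context) == 1L

  pool <- list()
  push <- function(cat, ann, start, end, seqstr, mods) {
    pool[[cat]][[length(pool[[cat]]) + 1L]] <<- list(
      precursor_id = ann$id, start = start, end = end, sequence = seqstr,
      mods = mods)
  }
  for (cat in names(category_mix)) pool[[cat]] <- list()

  base_mods <- function(pep_row, c_term_intact, n_term_intact) {
    mods <- character(0)
    if (c_term_intact && pep_row$amidated) mods <- c(mods, "amidation")
    if (n_term_intact && pep_row$pyroglu) mods <- c(mods, "pyroglu_Q")
    mods
  }
  collides <- function(ann, start, end) {
    pep <- ann$peptides
    any(pep$start == start & pep$end == end) ||
      (nrow(ann$alternatives) &&
         any(ann$alternatives$start == start &
               ann$alternatives$end == end))
  }
  mono_pos <- function(ann) {
    ann$sites$position[ann$sites$site_type == "monobasic"]
  }

  for (ann in annotated) {
    pep <- ann$peptides
    mp <- mono_pos(ann)
    for (i in seq_len(nrow(pep))) {
      core <- pep$sequence[i]
      len <- nchar(core)
      st <- pep$start[i]; en <- pep$end[i]
      if (len >= 4L && unique_in_context(core)) {
        push("full_dibasic", ann, st, en, core,
             base_mods(pep[i, ], TRUE, TRUE))
      }
      for (k in 1:3) {
        # N-terminal truncation
        if (len - k >= 4L) {
          s2 <- st + k
          seq2 <- substr(core, k + 1L, len)
          if (!collides(ann, s2, en) && !any(mp + 2L == s2) &&
              !any(mp == en) && unique_in_context(seq2)) {
            push("truncated_N", ann, s2, en, seq2,
                 base_mods(pep[i, ], TRUE, FALSE))
          }
        }
        # C-terminal truncation
        if (len - k >= 4L) {
          e2 <- en - k
          seq2 <- substr(core, 1L, len - k)
          if (!collides(ann, st, e2) && !any(mp == e2) &&
              unique_in_context(seq2)) {
            push("truncated_C", ann, st, e2, seq2,
                 base_mods(pep[i, ], FALSE, TRUE))
          }
        }
      }
      # double truncation with a 1-residue cut on the N side
      if (len - 3L >= 4L) {
        s2 <- st + 1L; e2 <- en - sample(1:2, 1L)
        seq2 <- substr(core, 2L, e2 - st + 1L)
        if (!collides(ann, s2, e2) && !any(mp == e2) &&
            !any(mp + 2L == s2) && unique_in_context(seq2)) {
          push("truncated_both", ann, s2, e2, seq2, character(0))
        }
      }
      # internal fragment, both cuts at least 2 residues from boundaries
      if (len - 4L >= 4L) {
        s2 <- st + 2L; e2 <- en - 2L
        seq2 <- substr(core, 3L, len - 2L)
        near <- any(abs(c(pep$start, pep$end) - s2) <= 1L) ||
          any(abs(c(pep$start, pep$end) - e2) <= 1L)
        if (!near && !collides(ann, s2, e2) && !any(mp == e2) &&
            !any(mp + 2L == s2) && unique_in_context(seq2)) {
          push("internal", ann, s2, e2, seq2, character(0))
        }
      }
      # monobasic N-terminal product: ends right before the supported Arg
      for (p in mp[mp >= st + 3L & mp <= en - 1L]) {
        seq2 <- substr(core, 1L, p - st + 1L)
        if (nchar(seq2) >= 4L && unique_in_context(seq2)) {
          push("monobasic_product", ann, st, p, seq2,
               base_mods(pep[i, ], FALSE, TRUE))
        }
      }
    }
  }
  for (ann in if (is.null(novel)) list() else novel) {
    pep <- ann$peptides
    for (i in seq_len(nrow(pep))) {
      core <- pep$sequence[i]
      if (nchar(core) >= 4L && unique_in_context(core)) {
        push("novel_precursor", ann, pep$start[i], pep$end[i], core,
             base_mods(pep[i, ], TRUE, TRUE))
      }
    }
  }
  # decoy sequences occurring nowhere
  for (i in 1:50) {
    seq2 <- .rand_seq(sample(6:12, 1L), .ALL_AA)
    if (.occurrences(seq2, context) == 0L) {
      pool[["unmatched"]][[length(pool[["unmatched"]]) + 1L]] <- list(
        precursor_id = NA_character_, start = NA_integer_,
        end = NA_integer_, sequence = seq2, mods = character(0))
    }
  }

  counts <- floor(category_mix * n)
  rem <- n - sum(counts)
  if (rem > 0L) {
    extra <- order(category_mix * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  ids <- list(); truth <- list()
  k <- 0L
  for (cat in names(counts)) {
    need <- counts[[cat]]
    if (need == 0L) next
    avail <- pool[[cat]]
    if (length(avail) == 0L) {
      stop("category ", cat, " requested but no eligible peptide exists")
    }
    pick <- sample.int(length(avail), need, replace = TRUE)
    for (j in pick) {
      k <- k + 1L
      item <- avail[[j]]
      modstr <- if (length(item$mods)) paste(item$mods, collapse = ";")
                else "-"
      mass <- monoisotopic_mass(item$sequence, item$mods)
      if (sigma > 0) mass <- mass + stats::rnorm(1L, 0, sigma)
      ids[[k]] <- data.frame(
        source_id = sprintf("ms%04d", k), peptide_sequence = item$sequence,
        modifications = modstr, observed_mass = mass,
        stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(
        source_id = sprintf("ms%04d", k), category = cat,
        precursor_id = item$precursor_id, start = item$start,
        end = item$end, stringsAsFactors = FALSE)
    }
  }
  list(identifications = do.call(rbind, ids), truth = do.call(rbind, truth))
}
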