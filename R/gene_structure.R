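#' Read gene models from GFF3
#'
#' Imports gene/mRNA/CDS features and assembles one model per gene. When a
#' gene has several transcripts the longest complete CDS (total length
#' divisible by 3) is used; ties are broken by transcript id. CDS segments
#' are stored 1-based inclusive in transcription order (decreasing genomic
#' coordinate on the minus strand).
#'
#' @param gff_path path to a GFF3 file.
#' @return named list of gene models, each a list \code{gene_id},
#'   \code{transcript_id}, \code{chrom}, \code{strand}, \code{exons}
#'   (data frame \code{start}, \code{end}).
#' @export
read_gene_models <- function(gff_path) {
  gr <- rtracklayer::import(gff_path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, "")
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  models <- list()
  for (g in unique(mrna$Parent)) {
    tx <- mrna[mrna$Parent == g, , drop = FALSE]
    best <- NULL
    for (t in sort(tx$ID)) {
      seg <- cds[cds$Parent == t, , drop = FALSE]
      if (nrow(seg) == 0L) next
      tot <- sum(seg$end - seg$start + 1L)
      complete <- tot %% 3L == 0L
      if (is.null(best) || (complete && !best$complete) ||
          (complete == best$complete && tot > best$tot)) {
        best <- list(t = t, seg = seg, tot = tot, complete = complete)
      }
    }
    if (is.null(best)) next
    seg <- best$seg
    strand <- as.character(seg$strand[1L])
    ord <- if (strand == "-") order(-seg$start) else order(seg$start)
    seg <- seg[ord, , drop = FALSE]
    if (any(duplicated(unlist(mapply(seq, seg$start, seg$end,
                                     SIMPLIFY = FALSE))))) {
      stop("overlapping CDS segments in gene ", g)
    }
    models[[g]] <- list(gene_id = g, transcript_id = best$t,
                        chrom = as.character(seg$seqnames[1L]),
                        strand = strand,
                        exons = data.frame(start = seg$start, end = seg$end))
  }
  models
}

#' Extract the coding sequence of a gene model
#'
#' @param model a gene model (see \code{\link{read_gene_models}}).
#' @param genome named character vector or \code{DNAStringSet} of genomic
#'   sequences.
#' @return the spliced CDS as a character string (plus-strand orientation
#'   of the mRNA).
#' @export
cds_sequence <- function(model, genome) {
  gseq <- if (is.character(genome)) genome[[model$chrom]]
          else as.character(genome[[model$chrom]])
  pieces <- substring(gseq, model$exons$start, model$exons$end)
  if (model$strand == "-") {
    pieces <- vapply(pieces, function(p)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(p))),
      "")
  }
  paste(pieces, collapse = "")
}

#' Intron positions and phases in protein coordinates
#'
#' For each intron the phase is the cumulative CDS length before the
#' junction modulo 3. Phase 0 means the intron falls between codons, after
#' residue \code{protein_pos}; phases 1 and 2 interrupt the codon of
#' residue \code{protein_pos} (e.g. a phase-2 intron sits between the
#' second and third nucleotide of that residue's codon). The translated
#' CDS is validated against the supplied protein; the model is
#' strand-symmetric, so a gene and its reverse-complemented mirror yield
#' identical annotations.
#'
#' @param model gene model.
#' @param protein single-row protein record data frame (trailing \code{*}
#'   tolerated).
#' @param genome genomic sequences (named character or DNAStringSet).
#' @return data frame \code{intron_index}, \code{protein_pos},
#'   \code{phase}.
#' @export
protein_introns <- function(model, protein, genome) {
  cds <- cds_sequence(model, genome)
  prot_obs <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "solve"))
  prot_obs <- sub("\\*$", "", prot_obs)
  prot_exp <- sub("\\*$", "", protein$sequence[1L])
  if (prot_obs != prot_exp) {
    a <- strsplit(prot_obs, "")[[1L]]
    b <- strsplit(prot_exp, "")[[1L]]
    nmin <- min(length(a), length(b))
    diffpos <- which(a[seq_len(nmin)] != b[seq_len(nmin)])
    first <- if (length(diffpos)) diffpos[1L] else nmin + 1L
    stop("translated CDS does not match protein ", protein$id[1L],
         " (first difference at residue ", first, ")")
  }
  lens <- model$exons$end - model$exons$start + 1L
  n_introns <- length(lens) - 1L
  if (n_introns < 1L) {
    return(data.frame(intron_index = integer(), protein_pos = integer(),
                      phase = integer()))
  }
  cum <- cumsum(lens)[seq_len(n_introns)]
  phase <- as.integer(cum %% 3L)
  protein_pos <- ifelse(phase == 0L, cum %/% 3L, cum %/% 3L + 1L)
  data.frame(intron_index = seq_len(n_introns),
             protein_pos = as.integer(protein_pos), phase = phase)
}

# map a 1-based ungapped residue index to its column in an aligned row
.alignment_column <- function(aligned_row, pos) {
  chars <- strsplit(aligned_row, "")[[1L]]
  resno <- cumsum(chars != "-")
  which(resno == pos & chars != "-")[1L]
}

#' Call conserved introns across an ortholog alignment
#'
#' Each intron is projected onto the column of its \code{protein_pos} in
#' the given protein multiple alignment. Introns from different sequences
#' are grouped as conserved when their columns agree within
#' \code{tolerance} and their phases are identical (phase identity is a
#' hard requirement; the column tolerance absorbs small alignment
#' wobble). Groups of at least two members are reported.
#'
#' @param annotated list of lists, each with \code{protein_id} and
#'   \code{introns} (a \code{\link{protein_introns}} result).
#' @param alignment named character vector (or AAStringSet) of aligned,
#'   equal-length rows covering all proteins.
#' @param tolerance maximum column distance within a group (default 2).
#' @return data frame \code{group}, \code{protein_id},
#'   \code{intron_index}, \code{column}, \code{phase}.
#' @export
conserved_introns <- function(annotated, alignment, tolerance = 2L) {
  if (!is.character(alignment)) alignment <- as.character(alignment)
  rows <- list()
  for (a in annotated) {
    pid <- a$protein_id
    if (!pid %in% names(alignment)) {
      stop("protein absent from alignment: ", pid)
    }
    intr <- a$introns
    for (i in seq_len(nrow(intr))) {
      col <- .alignment_column(alignment[[pid]], intr$protein_pos[i])
      if (is.na(col)) stop("intron position beyond aligned residues: ", pid)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, intron_index = intr$intron_index[i],
        column = col, phase = intr$phase[i], stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(group = integer(), protein_id = character(),
                      intron_index = integer(), column = integer(),
                      phase = integer(), stringsAsFactors = FALSE)
  if (length(rows) == 0L) return(empty)
  tab <- do.call(rbind, rows)
  # single-linkage within phase on column distance
  tab <- tab[order(tab$phase, tab$column, tab$protein_id), , drop = FALSE]
  grp <- integer(nrow(tab))
  gid <- 0L
  for (i in seq_len(nrow(tab))) {
    if (i == 1L || tab$phase[i] != tab$phase[i - 1L] ||
        tab$column[i] - tab$column[i - 1L] > tolerance) {
      gid <- gid + 1L
    }
    grp[i] <- gid
  }
  tab$group <- grp
  sizes <- table(grp)
  keep <- grp %in% as.integer(names(sizes)[sizes >= 2L])
  out <- tab[keep, c("group", "protein_id", "intron_index", "column",
                     "phase"), drop = FALSE]
  if (nrow(out)) out$group <- as.integer(factor(out$group))
  rownames(out) <- NULL
  out
}
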