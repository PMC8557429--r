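#' Read a FASTA file into a record table
#'
#' Records are returned as a plain data frame with one row per sequence, the
#' container used throughout the package. Protein sequences may contain the
#' 20 standard residues plus \code{*} as a trailing stop; nucleotide
#' sequences are restricted to \code{ACGTN}.
#'
#' @param path path to a FASTA file.
#' @param type \code{"protein"} or \code{"nucleotide"}.
#' @return a data frame with columns \code{id} and \code{sequence}
#'   (upper-cased, whitespace stripped), in file order.
#' @export
read_fasta <- function(path, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file does not exist: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) > 0L && !startsWith(trimws(first), ">")) {
    stop("not a FASTA file (first line does not start with '>'): ", path)
  }
  set <- if (type == "protein") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a record table to FASTA
#'
#' Round-trip safe: \code{read_fasta(write_fasta(x))} reproduces ids and
#' sequences exactly.
#'
#' @param records data frame with columns \code{id} and \code{sequence}.
#' @param path output path.
#' @param wrap positive line width for the sequence lines.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(is.data.frame(records), wrap >= 1L)
  validate_records(records, allow_empty = TRUE)
  if (nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = as.integer(wrap))
  invisible(path)
}

# shared record-collection invariants: unique non-empty ids, non-empty
# sequences, '*' only as final character
validate_records <- function(records, allow_empty = FALSE) {
  if (!all(c("id", "sequence") %in% names(records))) {
    stop("records must have columns 'id' and 'sequence'")
  }
  if (nrow(records) == 0L) {
    if (allow_empty) return(invisible(records))
    stop("empty record collection")
  }
  if (any(!nzchar(records$id))) stop("empty record id")
  if (anyDuplicated(records$id)) {
    stop("duplicate record id: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  if (any(!nzchar(records$sequence))) {
    stop("empty sequence for id: ",
         paste(records$id[!nzchar(records$sequence)], collapse = ", "))
  }
  internal_stop <- grepl("\\*.", records$sequence)
  if (any(internal_stop)) {
    stop("internal stop '*' in sequence of: ",
         paste(records$id[internal_stop], collapse = ", "))
  }
  invisible(records)
}

#' Six-frame ORF translation
#'
#' Translates every transcript in all six reading frames under the standard
#' genetic code and emits each maximal stop-free stretch of at least
#' \code{min_len} residues. Both complete ORFs and stretches truncated by
#' the transcript ends are reported, because transcriptome fragments
#' frequently truncate precursors. Codons containing an \code{N} that still
#' translate unambiguously are translated; ambiguous codons become
#' \code{X}.
#'
#' Output ids are \code{<transcript>_f<frame>_<offset>} where frame is
#' \code{+1..+3} (forward) or \code{-1..-3} (reverse complement) and offset
#' is the 0-based nucleotide position of the first codon on the frame's
#' strand. Output order is deterministic: transcript order, then frame,
#' then position.
#'
#' @param transcripts data frame with columns \code{id}, \code{sequence}
#'   (nucleotide, \code{ACGTN}).
#' @param min_len minimum ORF length in residues (default 60).
#' @return data frame of protein records with columns \code{id},
#'   \code{sequence}, \code{source_transcript}, \code{frame},
#'   \code{frame_start}.
#' @export
translate_orfs <- function(transcripts, min_len = 60L) {
  stopifnot(is.data.frame(transcripts), min_len >= 1L)
  out <- list()
  for (k in seq_len(nrow(transcripts))) {
    tid <- transcripts$id[k]
    nt <- toupper(transcripts$sequence[k])
    bad <- regexpr("[^ACGTN]", nt)
    if (bad > 0L) {
      stop("invalid nucleotide '", substr(nt, bad, bad), "' at position ",
           bad, " in transcript ", tid)
    }
    fwd <- Biostrings::DNAString(nt)
    rev <- Biostrings::reverseComplement(fwd)
    for (fr in 1:6) {
      strand_seq <- if (fr <= 3L) fwd else rev
      off <- (fr - 1L) %% 3L            # 0-based offset of the frame
      n_cod <- (length(strand_seq) - off) %/% 3L
      if (n_cod < 1L) next
      frame_nt <- Biostrings::subseq(strand_seq, off + 1L, off + 3L * n_cod)
      prot <- as.character(
        Biostrings::translate(frame_nt, if.fuzzy.codon = "solve",
                              no.init.codon = TRUE)
      )
      m <- gregexpr("[^*]+", prot)[[1L]]
      if (m[1L] == -1L) next
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
      keep <- lens >= min_len
      if (!any(keep)) next
      frame_label <- if (fr <= 3L) paste0("+", fr) else paste0("-", fr - 3L)
      for (i in which(keep)) {
        aa_start <- starts[i]
        nt_off <- off + 3L * (aa_start - 1L)  # 0-based on this strand
        out[[length(out) + 1L]] <- data.frame(
          id = paste0(tid, "_f", frame_label, "_", nt_off),
          sequence = substr(prot, aa_start, aa_start + lens[i] - 1L),
          source_transcript = tid,
          frame = frame_label,
          frame_start = nt_off,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      source_transcript = character(), frame = character(),
                      frame_start = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  validate_records(res)
  res
}

#' Read signal-peptide annotations
#'
#' Tab-separated file with columns \code{protein_id}, \code{has_signal}
#' (\code{Y}/\code{N}), \code{cleavage_after} (1-based index of the last
#' signal-peptide residue, \code{-} when absent) and \code{score}. Lines
#' starting with \code{#} and an optional header line are ignored. Protein
#' ids unknown to the caller are tolerated here and validated at use time.
#'
#' @param path path to the TSV file.
#' @return data frame with columns \code{protein_id}, \code{has_signal}
#'   (logical), \code{cleavage_after} (integer, \code{NA} when no signal),
#'   \code{score}.
#' @export
read_signal_annotations <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) > 0L && grepl("^protein_id\\b", lines[1L])) {
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) {
    return(data.frame(protein_id = character(), has_signal = logical(),
                      cleavage_after = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 4L
  if (any(bad)) stop("malformed signal annotation line: ", lines[which(bad)[1L]])
  pid <- vapply(parts, `[`, "", 1L)
  hs_raw <- vapply(parts, `[`, "", 2L)
  if (!all(hs_raw %in% c("Y", "N"))) {
    stop("has_signal must be Y or N, got: ",
         paste(unique(setdiff(hs_raw, c("Y", "N"))), collapse = ", "))
  }
  has_signal <- hs_raw == "Y"
  cleav_raw <- vapply(parts, `[`, "", 3L)
  cleavage_after <- rep(NA_integer_, length(pid))
  for (i in which(has_signal)) {
    v <- suppressWarnings(as.integer(cleav_raw[i]))
    if (is.na(v) || v < 1L || cleav_raw[i] != as.character(v)) {
      stop("cleavage_after must be a positive integer when has_signal=Y ",
           "(protein ", pid[i], ", got '", cleav_raw[i], "')")
    }
    cleavage_after[i] <- v
  }
  score <- as.numeric(vapply(parts, `[`, "", 4L))
  data.frame(protein_id = pid, has_signal = has_signal,
             cleavage_after = cleavage_after, score = score,
             stringsAsFactors = FALSE)
}

#' Write signal-peptide annotations
#'
#' Inverse of \code{\link{read_signal_annotations}}; writes a header line.
#'
#' @param annotations data frame as returned by
#'   \code{\link{read_signal_annotations}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_signal_annotations <- function(annotations, path) {
  df <- data.frame(
    protein_id = annotations$protein_id,
    has_signal = ifelse(annotations$has_signal, "Y", "N"),
    cleavage_after = ifelse(is.na(annotations$cleavage_after), "-",
                            as.character(annotations$cleavage_after)),
    score = annotations$score,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Heuristic signal-peptide predictor
#'
#' A deliberately simple hydrophobicity heuristic usable when no external
#' signal-peptide annotation is available: a sequence is called secreted
#' when some 12-residue window within the first 30 residues has a mean
#' Kyte-Doolittle hydropathy above \code{cutoff}. The predicted cleavage
#' position is placed after the first small residue (A/G/S) that follows
#' the best-scoring window, or after the window otherwise. This is a
#' coarse stand-in for a dedicated predictor and is only intended to make
#' the pipeline self-contained.
#'
#' @param records protein record data frame.
#' @param cutoff mean hydropathy threshold (default 1.6).
#' @param window window width in residues (default 12).
#' @return signal annotation data frame (see
#'   \code{\link{read_signal_annotations}}).
#' @export
predict_signal <- function(records, cutoff = 1.6, window = 12L) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2, X = 0, `*` = 0)
  n <- nrow(records)
  has <- logical(n); cleave <- rep(NA_integer_, n); sc <- numeric(n)
  for (i in seq_len(n)) {
    s <- strsplit(records$sequence[i], "")[[1L]]
    head_len <- min(30L, length(s))
    if (head_len < window) next
    h <- kd[s[seq_len(head_len)]]
    means <- vapply(seq_len(head_len - window + 1L),
                    function(j) mean(h[j:(j + window - 1L)]), 0)
    best <- which.max(means)
    sc[i] <- max(0, min(1, means[best] / 4.5))
    if (means[best] > cutoff) {
      has[i] <- TRUE
      after <- best + window - 1L
      tail_idx <- which(s %in% c("A", "G", "S") &
                          seq_along(s) > after & seq_along(s) <= after + 8L)
      cleave[i] <- if (length(tail_idx)) tail_idx[1L] else after
      if (cleave[i] >= length(s)) cleave[i] <- length(s) - 1L
    }
  }
  data.frame(protein_id = records$id, has_signal = has,
             cleavage_after = cleave, score = sc, stringsAsFactors = FALSE)
}
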