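#' Parameters of the multicopy-precursor motif screen
#'
#' With the defaults, \code{\link{build_motif_patterns}} reproduces the two
#' published screening expressions verbatim: at least three repeats of
#' amidation sites separated by 2-25 residues, or at least five repeats of
#' dibasic cleavage sites separated by 5-25 residues; candidates longer
#' than 650 residues are discarded and redundancy is reduced at 0.95
#' identity.
#'
#' @param amid_min_repeats minimum number of amidation-site repeats.
#' @param amid_spacer length-2 integer range of spacer lengths between
#'   amidation sites (residues).
#' @param dibasic_min_repeats minimum number of dibasic-site repeats.
#' @param dibasic_spacer length-2 integer spacer range for the dibasic
#'   branch.
#' @param max_precursor_len maximum candidate length in residues.
#' @param dedup_identity identity threshold (over the shorter sequence) for
#'   greedy redundancy reduction.
#' @return a list of class \code{pattern_params}.
#' @export
pattern_params <- function(amid_min_repeats = 3L,
                           amid_spacer = c(2L, 25L),
                           dibasic_min_repeats = 5L,
                           dibasic_spacer = c(5L, 25L),
                           max_precursor_len = 650L,
                           dedup_identity = 0.95) {
  stopifnot(amid_min_repeats >= 1L, dibasic_min_repeats >= 1L,
            length(amid_spacer) == 2L, length(dibasic_spacer) == 2L,
            amid_spacer[1L] <= amid_spacer[2L],
            dibasic_spacer[1L] <= dibasic_spacer[2L],
            max_precursor_len >= 1L,
            dedup_identity > 0, dedup_identity <= 1)
  structure(list(amid_min_repeats = as.integer(amid_min_repeats),
                 amid_spacer = as.integer(amid_spacer),
                 dibasic_min_repeats = as.integer(dibasic_min_repeats),
                 dibasic_spacer = as.integer(dibasic_spacer),
                 max_precursor_len = as.integer(max_precursor_len),
                 dedup_identity = dedup_identity),
            class = "pattern_params")
}

#' Build the two screening regular expressions
#'
#' Generalizes the published POSIX-extended patterns by substituting the
#' repeat counts and spacer bounds from \code{params}. The literal \code{*}
#' inside \code{[KR*]} is kept: in translated output a stop symbol can
#' terminate an amidated C-terminal peptide.
#'
#' @param params a \code{\link{pattern_params}} object.
#' @return named character vector with elements \code{amidation} and
#'   \code{dibasic}.
#' @export
build_motif_patterns <- function(params = pattern_params()) {
  amid <- sprintf(
    "((.{%d,%d}G[KR][KR])|(.{%d,%d}[KR](.{1}|.{3}|.{5})G[KR*])){%d,}",
    params$amid_spacer[1L], params$amid_spacer[2L],
    params$amid_spacer[1L], params$amid_spacer[2L],
    params$amid_min_repeats
  )
  dib <- sprintf("(.{%d,%d}[KR][KR]){%d,}",
                 params$dibasic_spacer[1L], params$dibasic_spacer[2L],
                 params$dibasic_min_repeats)
  c(amidation = amid, dibasic = dib)
}

#' Screen sequences for multicopy-precursor motifs
#'
#' Applies the two screening patterns (amidation-repeat and dibasic-repeat
#' branches) unanchored anywhere in each sequence, with greedy POSIX
#' extended-regex semantics. A sequence is a hit iff at least one branch
#' matches; with default parameters the decision is identical to direct
#' evaluation of the two published expressions.
#'
#' @param records protein record data frame (columns \code{id},
#'   \code{sequence}).
#' @param params a \code{\link{pattern_params}} object.
#' @return data frame of hits with columns \code{protein_id},
#'   \code{matched_branch} (\code{amidation}, \code{dibasic} or
#'   \code{both}) and \code{match_spans} (1-based inclusive intervals,
#'   rendered \code{"start-end"} and semicolon-joined). Zero rows when
#'   nothing matches.
#' @export
scan_multicopy <- function(records, params = pattern_params()) {
  pats <- build_motif_patterns(params)
  empty <- data.frame(protein_id = character(), matched_branch = character(),
                      match_spans = character(), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)
  hit_a <- grepl(pats[["amidation"]], records$sequence)
  hit_d <- grepl(pats[["dibasic"]], records$sequence)
  any_hit <- hit_a | hit_d
  if (!any(any_hit)) return(empty)
  idx <- which(any_hit)
  spans <- character(length(idx))
  branch <- character(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    branch[j] <- if (hit_a[i] && hit_d[i]) "both"
                 else if (hit_a[i]) "amidation" else "dibasic"
    sp <- list()
    for (p in pats[c(hit_a[i], hit_d[i])]) {
      m <- gregexpr(p, records$sequence[i])[[1L]]
      sp[[length(sp) + 1L]] <- cbind(as.integer(m),
                                     as.integer(m) + attr(m, "match.length") - 1L)
    }
    sp <- unique(do.call(rbind, sp))
    sp <- sp[order(sp[, 1L], sp[, 2L]), , drop = FALSE]
    spans[j] <- paste(sprintf("%d-%d", sp[, 1L], sp[, 2L]), collapse = ";")
  }
  data.frame(protein_id = records$id[idx], matched_branch = branch,
             match_spans = spans, stringsAsFactors = FALSE)
}

#' Keep only sequences with an N-terminal signal peptide
#'
#' The motif screen is restricted to the secretome: records (or hits) whose
#' protein lacks a signal peptide are removed. In the pipeline driver the
#' gate is applied before pattern scanning.
#'
#' @param x data frame with an \code{id} or \code{protein_id} column.
#' @param annotations signal annotation data frame (see
#'   \code{\link{read_signal_annotations}}).
#' @param missing policy for ids without any annotation: \code{"drop"}
#'   (default, with a message), \code{"keep"}, or \code{"error"}.
#' @return the filtered data frame.
#' @export
gate_by_signal <- function(x, annotations, missing = c("drop", "keep", "error")) {
  missing <- match.arg(missing)
  idcol <- if ("protein_id" %in% names(x)) "protein_id" else "id"
  ids <- x[[idcol]]
  known <- ids %in% annotations$protein_id
  if (any(!known)) {
    if (missing == "error") {
      stop("unannotated protein id(s): ",
           paste(utils::head(ids[!known], 5L), collapse = ", "))
    }
    if (missing == "drop") {
      message(sum(!known), " record(s) without signal annotation dropped")
    }
  }
  has <- setNames(annotations$has_signal, annotations$protein_id)
  keep <- ifelse(known, has[ids], missing == "keep")
  x[which(keep), , drop = FALSE]
}

#' Remove over-long precursor candidates
#'
#' Candidates longer than \code{max_len} residues are removed (a candidate
#' of exactly \code{max_len} residues is kept).
#'
#' @param records protein record data frame.
#' @param max_len maximum length in residues (default 650).
#' @return the filtered record data frame.
#' @export
filter_length <- function(records, max_len = 650L) {
  drop <- nchar(records$sequence) > max_len
  if (any(drop)) message(sum(drop), " record(s) longer than ", max_len,
                         " residues removed")
  records[!drop, , drop = FALSE]
}

#' Global-alignment identity over the shorter sequence
#'
#' The shorter sequence is aligned end-to-end within the longer one
#' (affine gaps, BLOSUM62) and identity is the fraction of its residues
#' matched, the convention used by common redundancy-reduction tools.
#'
#' @param a,b amino-acid strings.
#' @return identity between 0 and 1.
#' @export
seq_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global-local",
    substitutionMatrix = blosum62_extended(), gapOpening = 11, gapExtension = 1
  )
  Biostrings::nmatch(aln) / nchar(a)
}

#' Greedy redundancy reduction
#'
#' Records are visited in order of decreasing length (ties broken by
#' lexicographic id). A record joins the first existing representative with
#' which its identity over the shorter sequence reaches \code{identity};
#' otherwise it becomes a new representative. Idempotent on its own
#' representatives.
#'
#' @param records protein record data frame.
#' @param identity identity threshold in (0, 1\] (default 0.95).
#' @return list with \code{representatives} (record data frame) and
#'   \code{members} (data frame \code{representative}, \code{member},
#'   \code{identity}; representatives themselves are not listed).
#' @export
dedup_greedy <- function(records, identity = 0.95) {
  stopifnot(identity > 0, identity <= 1)
  if (nrow(records) == 0L) {
    return(list(representatives = records,
                members = data.frame(representative = character(),
                                     member = character(),
                                     identity = numeric(),
                                     stringsAsFactors = FALSE)))
  }
  ord <- order(-nchar(records$sequence), records$id)
  recs <- records[ord, , drop = FALSE]
  rep_idx <- integer(0)
  members <- list()
  for (i in seq_len(nrow(recs))) {
    joined <- FALSE
    for (r in rep_idx) {
      pid <- seq_identity(recs$sequence[i], recs$sequence[r])
      if (pid >= identity) {
        members[[length(members) + 1L]] <- data.frame(
          representative = recs$id[r], member = recs$id[i],
          identity = pid, stringsAsFactors = FALSE)
        joined <- TRUE
        break
      }
    }
    if (!joined) rep_idx <- c(rep_idx, i)
  }
  list(
    representatives = recs[rep_idx, , drop = FALSE],
    members = if (length(members)) do.call(rbind, members)
              else data.frame(representative = character(),
                              member = character(), identity = numeric(),
                              stringsAsFactors = FALSE)
  )
}
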