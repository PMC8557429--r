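#' Predict prohormone-convertase cleavage sites
#'
#' Dibasic sites: within each maximal run of basic residues (K/R), dimers
#' are counted non-overlapping from the left and a site is placed after the
#' second residue of each dimer, so \code{"KRKR"} yields sites after
#' positions 2 and 4. Monobasic sites (alternative confidence): every
#' arginine that is not adjacent to another basic residue and that has a
#' supporting K/R 3-6 positions N-terminal yields a site cleaving
#' N-terminal to that arginine. Monobasic detection is off by default; it
#' is enabled for the interpretation of observed MS peptides, where such
#' sites occur as alternatives to the classic dibasic sites.
#'
#' A site's \code{position} is the 1-based index of the residue after which
#' cleavage occurs.
#'
#' @param seq amino-acid string.
#' @param include_monobasic also report monobasic sites (default FALSE).
#' @return data frame \code{position}, \code{site_type}, \code{motif},
#'   \code{confidence}, sorted by position.
#' @export
find_cleavage_sites <- function(seq, include_monobasic = FALSE) {
  s <- strsplit(seq, "")[[1L]]
  basic <- s %in% c("K", "R")
  n <- length(s)
  pos <- integer(0); typ <- character(0); mot <- character(0)
  conf <- character(0)
  # maximal basic runs, non-overlapping dimers from the left
  r <- rle(basic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= 2L)) {
    i <- starts[k]
    while (i + 1L <= ends[k]) {
      pos <- c(pos, i + 1L)
      typ <- c(typ, "dibasic")
      mot <- c(mot, paste0(s[i], s[i + 1L]))
      conf <- c(conf, "standard")
      i <- i + 2L
    }
  }
  if (include_monobasic) {
    for (p in which(s == "R")) {
      if ((p > 1L && basic[p - 1L]) || (p < n && basic[p + 1L])) next
      support <- (p - 6L):(p - 3L)
      support <- support[support >= 1L]
      if (length(support) && any(basic[support]) && p > 1L) {
        pos <- c(pos, p - 1L)
        typ <- c(typ, "monobasic")
        mot <- c(mot, "R")
        conf <- c(conf, "alternative")
      }
    }
  }
  df <- data.frame(position = pos, site_type = typ, motif = mot,
                   confidence = conf, stringsAsFactors = FALSE)
  df[order(df$position), , drop = FALSE]
}

# positions occupied by dibasic site residues (both basic residues of
# every counted dimer)
.site_mask <- function(n, sites) {
  mask <- logical(n)
  dib <- sites[sites$site_type == "dibasic", , drop = FALSE]
  for (p in dib$position) mask[c(p - 1L, p)] <- TRUE
  mask
}

#' Derive mature peptides from a precursor
#'
#' The region C-terminal to the signal peptide is segmented at dibasic
#' cleavage sites; both basic residues of each site belong to no peptide
#' (carboxypeptidase trimming is implicit). Within each segment a trailing
#' glycine immediately preceding a downstream site (or the sequence end)
#' marks C-terminal amidation and is removed from the mature core; a
#' leading glutamine flags potential pyroglutamate. Empty segments are
#' dropped but recorded, so that signal + peptide cores + removed glycines
#' + site residues always tile the precursor exactly.
#'
#' @param precursor a single-row protein record data frame, or a list with
#'   \code{id} and \code{sequence}.
#' @param sites cleavage sites from \code{\link{find_cleavage_sites}};
#'   computed on demand when NULL. Only dibasic sites segment the
#'   precursor.
#' @param signal signal annotation row for this protein (or NULL when no
#'   signal peptide is known).
#' @return data frame of mature peptides (\code{precursor_id},
#'   \code{start}, \code{end}, \code{sequence}, \code{amidated},
#'   \code{pyroglu}, \code{flanking}) with attribute \code{dropped_spans}
#'   (matrix of segments that vanished after processing).
#' @export
derive_peptides <- function(precursor, sites = NULL, signal = NULL) {
  id <- precursor$id[1L]
  seqstr <- precursor$sequence[1L]
  seqstr <- sub("\\*$", "", seqstr)
  n <- nchar(seqstr)
  if (is.null(sites)) sites <- find_cleavage_sites(seqstr)
  sig_end <- 0L
  if (!is.null(signal) && isTRUE(signal$has_signal[1L])) {
    sig_end <- as.integer(signal$cleavage_after[1L])
    if (sig_end >= n) stop("signal cleavage position beyond sequence: ", id)
  }
  mask <- .site_mask(n, sites)
  free <- !mask
  if (sig_end > 0L) free[seq_len(sig_end)] <- FALSE
  s <- strsplit(seqstr, "")[[1L]]

  runs <- rle(free)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg_i <- which(runs$values)
  peptides <- list()
  dropped <- NULL
  for (k in seg_i) {
    a <- starts[k]; b <- ends[k]
    amid <- FALSE
    core_end <- b
    # trailing G adjacent to a downstream site or the sequence end
    if (s[b] == "G" && (b == n || mask[b + 1L])) {
      amid <- TRUE
      core_end <- b - 1L
    }
    if (core_end < a) {
      dropped <- rbind(dropped, c(a, b))
      next
    }
    core <- substr(seqstr, a, core_end)
    upstream_sig <- (a == sig_end + 1L) && sig_end > 0L
    downstream_end <- (b == n)
    flanking <- if (upstream_sig && !downstream_end) "signal-dibasic"
                else if (downstream_end) "dibasic-end"
                else "dibasic-dibasic"
    peptides[[length(peptides) + 1L]] <- data.frame(
      precursor_id = id, start = a, end = core_end, sequence = core,
      amidated = amid, pyroglu = substr(core, 1L, 1L) == "Q",
      flanking = flanking, stringsAsFactors = FALSE)
  }
  res <- if (length(peptides)) do.call(rbind, peptides)
         else data.frame(precursor_id = character(), start = integer(),
                         end = integer(), sequence = character(),
                         amidated = logical(), pyroglu = logical(),
                         flanking = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "dropped_spans") <- dropped
  res
}

#' Reconstruct a precursor from its annotation (tiling check)
#'
#' Rebuilds the precursor string from signal peptide, peptide cores,
#' removed amidation glycines, cleavage-site residues and dropped
#' segments. Annotation is internally consistent iff the reconstruction
#' equals the input.
#'
#' @param annotation an \code{\link{annotate_precursor}} result.
#' @return TRUE when the tiling reconstructs the sequence exactly.
#' @export
check_tiling <- function(annotation) {
  seqstr <- sub("\\*$", "", annotation$sequence)
  n <- nchar(seqstr)
  covered <- logical(n)
  if (annotation$signal_end > 0L) covered[seq_len(annotation$signal_end)] <- TRUE
  dib <- annotation$sites[annotation$sites$site_type == "dibasic", ,
                          drop = FALSE]
  for (p in dib$position) covered[c(p - 1L, p)] <- TRUE
  pep <- annotation$peptides
  for (i in seq_len(nrow(pep))) {
    covered[pep$start[i]:pep$end[i]] <- TRUE
    if (pep$amidated[i]) covered[pep$end[i] + 1L] <- TRUE
  }
  ds <- attr(pep, "dropped_spans")
  if (!is.null(ds)) for (i in seq_len(nrow(ds))) {
    covered[ds[i, 1L]:ds[i, 2L]] <- TRUE
  }
  all(covered)
}

#' Flag consecutive peptide copies and their alternative products
#'
#' When two or more motif-matching peptide copies follow each other with no
#' intersequence (separated only by cleavage-site residues), processing can
#' produce a shorter product: the copy sequence after its last internal
#' basic residue (e.g. GWamide dipeptides from consecutive RGWamide
#' copies). Each such copy is flagged and its alternative product
#' reported.
#'
#' @param peptides data frame from \code{\link{derive_peptides}}.
#' @param motif regular expression a peptide core must match to count as a
#'   copy.
#' @param precursor_seq the precursor sequence (used to verify that the
#'   residues between abutting copies are all basic).
#' @return list with \code{peptides} (input plus logical
#'   \code{consecutive_copy}) and \code{alternatives} (data frame of
#'   alternative shorter products: \code{precursor_id},
#'   \code{parent_start}, \code{start}, \code{end}, \code{sequence},
#'   \code{amidated}).
#' @export
detect_consecutive_copies <- function(peptides, motif, precursor_seq) {
  peptides$consecutive_copy <- logical(nrow(peptides))
  alts <- list()
  if (nrow(peptides) >= 2L) {
    # the upstream member may carry a pro-region before its copy, so it
    # only needs to contain the motif; the downstream member must start
    # with it, otherwise its leading residues are intersequence and the
    # copies do not abut
    is_copy <- grepl(motif, peptides$sequence)
    starts_with <- grepl(paste0("^(", motif, ")"), peptides$sequence)
    seqstr <- sub("\\*$", "", precursor_seq)
    s <- strsplit(seqstr, "")[[1L]]
    for (i in seq_len(nrow(peptides) - 1L)) {
      if (!is_copy[i] || !starts_with[i + 1L]) next
      gap_from <- peptides$end[i] + 1L + peptides$amidated[i]
      gap_to <- peptides$start[i + 1L] - 1L
      between <- if (gap_from > gap_to) character(0) else s[gap_from:gap_to]
      if (all(between %in% c("K", "R"))) {
        peptides$consecutive_copy[c(i, i + 1L)] <- TRUE
      }
    }
    for (i in which(peptides$consecutive_copy)) {
      core <- peptides$sequence[i]
      m <- regexpr(".*[KR]", core)  # greedy: up to the last basic residue
      if (m > 0L) {
        cut <- attr(m, "match.length")
        if (cut < nchar(core)) {
          alts[[length(alts) + 1L]] <- data.frame(
            precursor_id = peptides$precursor_id[i],
            parent_start = peptides$start[i],
            start = peptides$start[i] + cut,
            end = peptides$end[i],
            sequence = substr(core, cut + 1L, nchar(core)),
            amidated = peptides$amidated[i],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(peptides = peptides,
       alternatives = if (length(alts)) do.call(rbind, alts)
                      else data.frame(precursor_id = character(),
                                      parent_start = integer(),
                                      start = integer(), end = integer(),
                                      sequence = character(),
                                      amidated = logical(),
                                      stringsAsFactors = FALSE))
}

#' Classify the architecture of an annotated precursor
#'
#' Deterministic precedence: \code{cys8_peptide} (terminal peptide with
#' exactly 8 cysteines, the hallmark of CCWamide/agatoxin-like peptides) >
#' \code{single_copy_plus_cys_domain} (a single non-Cys-rich peptide
#' followed by a Cys-rich region with at least 4 cysteines, the
#' vasotocin-neurophysin layout) > \code{multicopy} (at least 3 copies
#' with pairwise identity >= \code{copy_identity} over the shorter copy) >
#' \code{single_copy} > \code{other}. Peptides are sorted by position
#' first, so the call is invariant to input order.
#'
#' @param precursor single-row record data frame or list with
#'   \code{sequence}.
#' @param peptides data frame from \code{\link{derive_peptides}}.
#' @param copy_identity identity threshold for grouping peptide copies
#'   (default 0.5; a configuration knob, not a published constant).
#' @return list \code{class}, \code{cys_positions} (1-based precursor
#'   coordinates of the cysteines supporting the call), \code{copy_count}.
#' @export
classify_architecture <- function(precursor, peptides, copy_identity = 0.5) {
  seqstr <- sub("\\*$", "", precursor$sequence[1L])
  if (nrow(peptides) == 0L) {
    return(list(class = "other", cys_positions = integer(0), copy_count = 0L))
  }
  peptides <- peptides[order(peptides$start), , drop = FALSE]
  n_cys <- vapply(peptides$sequence,
                  function(x) sum(strsplit(x, "")[[1L]] == "C"), 0L)
  cys_at <- function(a, b) {
    if (b < a) return(integer(0))
    a - 1L + which(strsplit(substr(seqstr, a, b), "")[[1L]] == "C")
  }
  term <- nrow(peptides)
  if (n_cys[term] == 8L) {
    return(list(class = "cys8_peptide",
                cys_positions = cys_at(peptides$start[term],
                                       peptides$end[term]),
                copy_count = 1L))
  }
  cys_rich <- n_cys >= 4L
  if (sum(!cys_rich) == 1L) {
    lone <- which(!cys_rich)
    region_start <- peptides$end[lone] + 1L
    region_cys <- cys_at(region_start, nchar(seqstr))
    if (length(region_cys) >= 4L) {
      return(list(class = "single_copy_plus_cys_domain",
                  cys_positions = region_cys, copy_count = 1L))
    }
  }
  if (nrow(peptides) >= 3L) {
    cores <- peptides$sequence
    usable <- which(nchar(cores) >= 2L)
    if (length(usable) >= 3L) {
      m <- length(usable)
      adj <- matrix(FALSE, m, m)
      for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
        adj[i, j] <- adj[j, i] <-
          seq_identity(cores[usable[i]], cores[usable[j]]) >= copy_identity
      }
      # single-linkage groups
      grp <- seq_len(m)
      for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
        if (adj[i, j]) grp[grp == grp[j]] <- grp[i]
      }
      biggest <- max(table(grp))
      if (biggest >= 3L) {
        return(list(class = "multicopy", cys_positions = integer(0),
                    copy_count = as.integer(biggest)))
      }
    }
  }
  if (nrow(peptides) == 1L) {
    return(list(class = "single_copy", cys_positions = integer(0),
                copy_count = 1L))
  }
  list(class = "other", cys_positions = integer(0),
       copy_count = nrow(peptides))
}

#' Fully annotate a precursor
#'
#' Runs cleavage-site prediction, peptide derivation, consecutive-copy
#' detection and architecture classification for one protein record.
#' Monobasic sites are always computed for downstream MS interpretation
#' but never segment the precursor.
#'
#' @param record single-row protein record data frame.
#' @param signal signal annotation row for this protein, or NULL.
#' @param copy_motif optional regex for consecutive-copy detection; when
#'   NULL, abutting near-identical copies are detected with a permissive
#'   motif (any core).
#' @param copy_identity identity threshold for architecture copy grouping.
#' @return object of class \code{annotated_precursor}: a list with
#'   \code{id}, \code{sequence}, \code{signal_end}, \code{sites},
#'   \code{peptides}, \code{alternatives}, \code{architecture}.
#' @export
annotate_precursor <- function(record, signal = NULL, copy_motif = NULL,
                               copy_identity = 0.5) {
  seqstr <- sub("\\*$", "", record$sequence[1L])
  sites <- find_cleavage_sites(seqstr, include_monobasic = TRUE)
  pep <- derive_peptides(list(id = record$id[1L], sequence = seqstr),
                         sites = sites, signal = signal)
  cc <- detect_consecutive_copies(pep, motif = if (is.null(copy_motif)) ""
                                  else copy_motif, precursor_seq = seqstr)
  dropped <- attr(pep, "dropped_spans")
  pep <- cc$peptides
  attr(pep, "dropped_spans") <- dropped
  arch <- classify_architecture(list(sequence = seqstr), pep,
                                copy_identity = copy_identity)
  structure(list(
    id = record$id[1L],
    sequence = seqstr,
    signal_end = if (!is.null(signal) && isTRUE(signal$has_signal[1L]))
      as.integer(signal$cleavage_after[1L]) else 0L,
    sites = sites,
    peptides = pep,
    alternatives = cc$alternatives,
    architecture = arch
  ), class = "annotated_precursor")
}

#' @export
print.annotated_precursor <- function(x, ...) {
  cat(">", x$id, " [", x$architecture$class, "]\n", sep = "")
  s <- x$sequence
  marks <- rep(" ", nchar(s))
  if (x$signal_end > 0L) marks[seq_len(x$signal_end)] <- "s"
  dib <- x$sites[x$sites$site_type == "dibasic", , drop = FALSE]
  for (p in dib$position) marks[c(p - 1L, p)] <- "^"
  for (i in seq_len(nrow(x$peptides))) {
    if (x$peptides$amidated[i]) marks[x$peptides$end[i] + 1L] <- "a"
  }
  for (off in seq(1L, nchar(s), by = 60L)) {
    to <- min(off + 59L, nchar(s))
    cat(substr(s, off, to), "\n")
    cat(paste(marks[off:to], collapse = ""), "\n")
  }
  cat(nrow(x$peptides), "predicted peptide(s); s=signal, ^=cleavage site,",
      "a=amidation glycine\n")
  invisible(x)
}

#' Write predicted mature peptides as FASTA
#'
#' Headers carry the precursor id, coordinates and modification tags
#' (\code{amidated}, \code{pyroglu}).
#'
#' @param annotations list of \code{\link{annotate_precursor}} objects.
#' @param path output path.
#' @param min_len shortest peptide to write (default 2).
#' @return \code{path}, invisibly.
#' @export
write_peptides_fasta <- function(annotations, path, min_len = 2L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ann in annotations) {
    pep <- ann$peptides
    for (i in seq_len(nrow(pep))) {
      if (nchar(pep$sequence[i]) < min_len) next
      tags <- c(if (pep$amidated[i]) "amidated",
                if (pep$pyroglu[i]) "pyroglu")
      writeLines(c(
        sprintf(">%s_%d-%d%s", ann$id, pep$start[i], pep$end[i],
                if (length(tags)) paste0(" ", paste(tags, collapse = ";"))
                else ""),
        pep$sequence[i]), con)
    }
  }
  invisible(path)
}
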