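#' Read an MS identification table
#'
#' Tab-separated with header columns \code{peptide_sequence},
#' \code{modifications} (\code{"name@pos;..."}, \code{-} for none),
#' \code{observed_mass} (monoisotopic Da) and \code{source_id} - a
#' documented subset of the columns of a search-engine peptide table.
#'
#' @param path path to the TSV file.
#' @return data frame of identifications.
#' @export
read_ms_identifications <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(peptide_sequence = "character",
                                         modifications = "character",
                                         observed_mass = "numeric",
                                         source_id = "character"))
  need <- c("peptide_sequence", "modifications", "observed_mass", "source_id")
  if (!all(need %in% names(df))) {
    stop("identification table must have columns: ",
         paste(need, collapse = ", "))
  }
  short <- nchar(df$peptide_sequence) < 4L
  if (any(short)) stop("identification shorter than 4 residues: ",
                       paste(df$source_id[short], collapse = ", "))
  df
}

#' Write an MS identification table
#'
#' @param ids identification data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ms_identifications <- function(ids, path) {
  utils::write.table(ids, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ranking used to pick the primary match among ambiguous occurrences
.category_rank <- c(full_dibasic = 1, monobasic_product = 2, truncated_N = 3,
                    truncated_C = 4, truncated_both = 5, internal = 6,
                    novel_precursor = 7, unmatched = 8)

# categorize one occurrence (span on one annotated precursor)
.categorize_span <- function(ann, start, end) {
  pep <- ann$peptides
  exact <- which(pep$start == start & pep$end == end)
  if (length(exact)) return("full_dibasic")
  alt <- ann$alternatives
  if (nrow(alt) && any(alt$start == start & alt$end == end)) {
    return("monobasic_product")
  }
  mono <- ann$sites[ann$sites$site_type == "monobasic", , drop = FALSE]
  # N-terminal product ending before the monobasic arginine, or
  # C-terminal product starting after the removed arginine
  if (nrow(mono) && (any(mono$position == end) ||
                     any(mono$position + 2L == start))) {
    return("monobasic_product")
  }
  host <- which(pep$start <= start & pep$end >= end)
  if (length(host)) {
    h <- host[1L]
    share_n <- pep$start[h] == start
    share_c <- pep$end[h] == end
    if (share_n && !share_c) return("truncated_C")
    if (share_c && !share_n) return("truncated_N")
    bounds <- c(pep$start, pep$end)
    near <- any(abs(bounds - start) <= 1L) || any(abs(bounds - end) <= 1L)
    if (near) return("truncated_both")
    return("internal")
  }
  bounds <- c(pep$start, pep$end)
  near <- any(abs(bounds - start) <= 1L) || any(abs(bounds - end) <= 1L)
  if (near) "truncated_both" else "internal"
}

#' Match MS identifications to predicted precursor products
#'
#' Each identification is located as an exact substring of the annotated
#' precursors (all occurrences are reported) and classified by comparing
#' its span with the predicted peptide cores: \code{full_dibasic} (exact
#' core), \code{truncated_N}/\code{truncated_C}/\code{truncated_both}
#' (proper sub-spans sharing the C, N or neither boundary),
#' \code{monobasic_product} (span consistent with a supported monobasic
#' cleavage or a consecutive-copy alternative product), \code{internal}
#' (not within one residue of any predicted boundary),
#' \code{novel_precursor} (substring only of a background protein outside
#' the discovered set) or \code{unmatched}. The theoretical mass is
#' recomputed from sequence and modifications; a location match whose mass
#' error exceeds \code{tol} is demoted to \code{unmatched}.
#'
#' Among ambiguous occurrences a primary match is chosen by category rank,
#' then longest host sequence, then lexicographic id.
#'
#' @param ids identification data frame (see
#'   \code{\link{read_ms_identifications}}).
#' @param precursors list of \code{\link{annotate_precursor}} objects (the
#'   discovered set).
#' @param tol mass tolerance in Da (default 0.01, configurable; identifications
#'   carry sequences, so this is an internal consistency check).
#' @param proteome optional background protein record data frame searched
#'   for novel precursors.
#' @return data frame of matches: \code{source_id},
#'   \code{peptide_sequence}, \code{precursor_id}, \code{start},
#'   \code{end}, \code{category}, \code{mass_error}, \code{primary}.
#' @export
match_identifications <- function(ids, precursors, tol = 0.01,
                                  proteome = NULL) {
  if (tol <= 0) stop("tolerance must be positive")
  prec_ids <- vapply(precursors, `[[`, "", "id")
  prec_seqs <- vapply(precursors, `[[`, "", "sequence")
  bg <- NULL
  if (!is.null(proteome)) {
    bg <- proteome[!proteome$id %in% prec_ids, , drop = FALSE]
    bg$sequence <- sub("\\*$", "", bg$sequence)
  }
  rows <- list()
  for (k in seq_len(nrow(ids))) {
    pep <- ids$peptide_sequence[k]
    mods <- parse_modifications(ids$modifications[k])
    theo <- monoisotopic_mass(pep, mods)
    err <- ids$observed_mass[k] - theo
    found <- list()
    for (j in seq_along(precursors)) {
      m <- gregexpr(pep, prec_seqs[j], fixed = TRUE)[[1L]]
      if (m[1L] == -1L) next
      for (st in as.integer(m)) {
        cat_ <- .categorize_span(precursors[[j]], st, st + nchar(pep) - 1L)
        found[[length(found) + 1L]] <- data.frame(
          source_id = ids$source_id[k], peptide_sequence = pep,
          precursor_id = prec_ids[j], start = st,
          end = st + nchar(pep) - 1L, category = cat_, mass_error = err,
          host_len = nchar(prec_seqs[j]), stringsAsFactors = FALSE)
      }
    }
    if (length(found) == 0L && !is.null(bg) && nrow(bg) > 0L) {
      for (j in seq_len(nrow(bg))) {
        m <- gregexpr(pep, bg$sequence[j], fixed = TRUE)[[1L]]
        if (m[1L] == -1L) next
        for (st in as.integer(m)) {
          found[[length(found) + 1L]] <- data.frame(
            source_id = ids$source_id[k], peptide_sequence = pep,
            precursor_id = bg$id[j], start = st,
            end = st + nchar(pep) - 1L, category = "novel_precursor",
            mass_error = err, host_len = nchar(bg$sequence[j]),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(found) == 0L) {
      found[[1L]] <- data.frame(
        source_id = ids$source_id[k], peptide_sequence = pep,
        precursor_id = NA_character_, start = NA_integer_,
        end = NA_integer_, category = "unmatched", mass_error = err,
        host_len = 0L, stringsAsFactors = FALSE)
    }
    f <- do.call(rbind, found)
    if (abs(err) > tol) f$category <- "unmatched"
    ord <- order(.category_rank[f$category], -f$host_len, f$precursor_id)
    f$primary <- FALSE
    f$primary[ord[1L]] <- TRUE
    rows[[length(rows) + 1L]] <- f
  }
  res <- if (length(rows)) do.call(rbind, rows)
         else data.frame(source_id = character(),
                         peptide_sequence = character(),
                         precursor_id = character(), start = integer(),
                         end = integer(), category = character(),
                         mass_error = numeric(), host_len = integer(),
                         primary = logical(), stringsAsFactors = FALSE)
  res$host_len <- NULL
  rownames(res) <- NULL
  res
}

#' Summarize MS confirmation results
#'
#' Bookkeeping over the primary matches: per-precursor category counts and
#' pipeline totals, including the list of novel precursors (proteins
#' outside the discovered set supported by observed peptides) with their
#' supporting peptide counts.
#'
#' @param matches output of \code{\link{match_identifications}}.
#' @return list with \code{per_precursor} (data frame), \code{totals}
#'   (named integer vector: confirmed full peptides and precursors,
#'   truncated, monobasic, internal, novel peptides and precursors,
#'   unmatched) and \code{novel} (data frame \code{precursor_id},
#'   \code{n_peptides}).
#' @export
confirmation_summary <- function(matches) {
  pm <- matches[matches$primary, , drop = FALSE]
  cats <- names(.category_rank)
  per <- NULL
  real <- pm[!is.na(pm$precursor_id) & pm$category != "novel_precursor", ,
             drop = FALSE]
  if (nrow(real)) {
    tab <- table(real$precursor_id, factor(real$category, levels = cats))
    per <- as.data.frame.matrix(tab)
    per <- cbind(data.frame(precursor_id = rownames(per),
                            stringsAsFactors = FALSE), per)
    rownames(per) <- NULL
  } else {
    per <- data.frame(precursor_id = character(), stringsAsFactors = FALSE)
  }
  novel <- pm[pm$category == "novel_precursor", , drop = FALSE]
  novel_df <- if (nrow(novel)) {
    agg <- as.data.frame(table(novel$precursor_id),
                         stringsAsFactors = FALSE)
    names(agg) <- c("precursor_id", "n_peptides")
    agg
  } else {
    data.frame(precursor_id = character(), n_peptides = integer(),
               stringsAsFactors = FALSE)
  }
  full <- pm[pm$category == "full_dibasic", , drop = FALSE]
  totals <- c(
    full_peptides = nrow(full),
    full_precursors = length(unique(full$precursor_id)),
    truncated = sum(pm$category %in%
                      c("truncated_N", "truncated_C", "truncated_both")),
    monobasic = sum(pm$category == "monobasic_product"),
    internal = sum(pm$category == "internal"),
    novel_peptides = nrow(novel),
    novel_precursors = length(unique(novel$precursor_id)),
    unmatched = sum(pm$category == "unmatched")
  )
  list(per_precursor = per, totals = totals, novel = novel_df)
}
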