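#' Parameters of the similarity search
#'
#' Local alignment uses BLOSUM62 with affine gaps (a gap of length L costs
#' \code{gap_open + L * gap_extend}) and a Karlin-Altschul style E-value
#' \eqn{E = K m n e^{-\lambda S}} with the published gapped-BLOSUM62
#' constants. The threshold ladder mirrors the discovery protocol: a
#' relaxed first pass (1e-1), a stringent second pass and clustering pass
#' (1e-5), and a display/refinement threshold (1e-10).
#'
#' @param matrix substitution matrix name (only \code{"BLOSUM62"} is
#'   shipped).
#' @param gap_open,gap_extend affine gap parameters.
#' @param lambda,K Karlin-Altschul constants.
#' @param relaxed_evalue,stringent_evalue,cluster_evalue,display_evalue
#'   E-value thresholds.
#' @return a list of class \code{search_params}.
#' @export
search_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          lambda = 0.267, K = 0.041,
                          relaxed_evalue = 1e-1, stringent_evalue = 1e-5,
                          cluster_evalue = 1e-5, display_evalue = 1e-10) {
  stopifnot(relaxed_evalue > 0, stringent_evalue > 0, cluster_evalue > 0,
            display_evalue > 0, relaxed_evalue >= stringent_evalue)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 relaxed_evalue = relaxed_evalue,
                 stringent_evalue = stringent_evalue,
                 cluster_evalue = cluster_evalue,
                 display_evalue = display_evalue),
            class = "search_params")
}

# BLOSUM62 with 'X' and '*' forced to the matrix minimum, so unknown
# residues and stop symbols never contribute positive score
blosum62_extended <- function() {
  if (!is.null(.pnp_cache$blosum62x)) return(.pnp_cache$blosum62x)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  mn <- min(m)
  for (ch in c("X", "*")) {
    m[ch, ] <- mn
    m[, ch] <- mn
  }
  .pnp_cache$blosum62x <- m
  m
}

evalue_from_score <- function(score, m, n, params) {
  params$K * m * n * exp(-params$lambda * score)
}

#' Optimal local alignment score and E-value
#'
#' Smith-Waterman under affine gaps; a stand-in for a heuristic search
#' engine, exact at desk scale. \code{X} and \code{*} score the matrix
#' minimum.
#'
#' @param a,b amino-acid strings (non-empty).
#' @param params a \code{\link{search_params}} object.
#' @return list with \code{raw_score} and \code{evalue}.
#' @export
local_align <- function(a, b, params = search_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  s <- Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = blosum62_extended(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = FALSE
  ))
  list(raw_score = s, evalue = evalue_from_score(s, nchar(a), nchar(b), params))
}

# score every query against one subject in a single vectorized call
.align_scores_vs_subject <- function(query_seqs, subject_seq, params) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(query_seqs), Biostrings::AAString(subject_seq),
    type = "local", substitutionMatrix = blosum62_extended(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE
  )
}

#' All-vs-all local-alignment scores
#'
#' @param queries,subjects protein record data frames.
#' @param params a \code{\link{search_params}} object.
#' @return data frame \code{query_id}, \code{subject_id},
#'   \code{raw_score}, \code{evalue}.
#' @export
align_all <- function(queries, subjects, params = search_params()) {
  if (nrow(queries) == 0L || nrow(subjects) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      raw_score = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- vector("list", nrow(subjects))
  qlen <- nchar(queries$sequence)
  for (j in seq_len(nrow(subjects))) {
    sc <- .align_scores_vs_subject(queries$sequence, subjects$sequence[j],
                                   params)
    out[[j]] <- data.frame(
      query_id = queries$id, subject_id = subjects$id[j], raw_score = sc,
      evalue = evalue_from_score(sc, qlen, nchar(subjects$sequence[j]),
                                 params),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-pass (relaxed then stringent) similarity search
#'
#' Pass 1 retains every target with E-value at most
#' \code{params$relaxed_evalue} against any seed query. The union of pass-1
#' hits and externally supplied candidates (e.g. motif-screen hits), after
#' an optional curation hook, becomes the query set for a second pass at
#' \code{params$stringent_evalue}. This recycling of first-pass hits is
#' what recovers "hidden orthologs": targets similar to a first-pass hit
#' but not to any original seed.
#'
#' @param proteome protein record data frame to search.
#' @param seed_queries protein record data frame of seed sequences.
#' @param params a \code{\link{search_params}} object.
#' @param pattern_candidates optional character vector of proteome ids
#'   found by the motif screen, merged into the pass-2 query set.
#' @param keep optional curation hook: a character vector of ids to retain
#'   in the pass-2 query set, or a function applied to the candidate id
#'   vector.
#' @return data frame with one row per recovered proteome record:
#'   \code{protein_id} plus logical provenance columns \code{pass1},
#'   \code{pass2}, \code{pattern}.
#' @export
two_pass_search <- function(proteome, seed_queries, params = search_params(),
                            pattern_candidates = NULL, keep = NULL) {
  if (nrow(seed_queries) == 0L) stop("seed_queries must be non-empty")
  empty <- data.frame(protein_id = character(), pass1 = logical(),
                      pass2 = logical(), pattern = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(proteome) == 0L) return(empty)

  hits1 <- align_all(proteome, seed_queries, params)
  best1 <- tapply(hits1$evalue, hits1$query_id, min)
  pass1_ids <- names(best1)[best1 <= params$relaxed_evalue]

  query2_ids <- union(pass1_ids, intersect(pattern_candidates, proteome$id))
  if (!is.null(keep)) {
    query2_ids <- if (is.function(keep)) keep(query2_ids)
                  else intersect(query2_ids, keep)
  }
  pass2_ids <- character(0)
  if (length(query2_ids) > 0L) {
    q2 <- proteome[match(query2_ids, proteome$id), , drop = FALSE]
    hits2 <- align_all(proteome, q2, params)
    best2 <- tapply(hits2$evalue, hits2$query_id, min)
    pass2_ids <- names(best2)[best2 <= params$stringent_evalue]
  }

  all_ids <- union(union(pass1_ids, pass2_ids),
                   intersect(pattern_candidates, proteome$id))
  if (length(all_ids) == 0L) return(empty)
  all_ids <- proteome$id[proteome$id %in% all_ids]  # stable input order
  data.frame(protein_id = all_ids,
             pass1 = all_ids %in% pass1_ids,
             pass2 = all_ids %in% pass2_ids,
             pattern = all_ids %in% pattern_candidates,
             stringsAsFactors = FALSE)
}

#' All-vs-all similarity graph
#'
#' Undirected graph over the records with an edge wherever the pairwise
#' E-value is below \code{threshold}. Since the optimal local score is
#' symmetric, each unordered pair is scored once. Edge sets are nested
#' across thresholds: the graph at a stricter threshold is a subgraph of
#' the graph at a looser one.
#'
#' @param records protein record data frame.
#' @param params a \code{\link{search_params}} object.
#' @param threshold E-value cutoff (default \code{params$cluster_evalue}).
#' @return list of class \code{similarity_graph}: \code{nodes} (ids),
#'   \code{edges} (data frame \code{from}, \code{to}, \code{raw_score},
#'   \code{evalue}), \code{threshold}.
#' @export
build_graph <- function(records, params = search_params(),
                        threshold = params$cluster_evalue) {
  stopifnot(nrow(records) >= 1L)
  n <- nrow(records)
  edges <- list()
  lens <- nchar(records$sequence)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    sc <- .align_scores_vs_subject(records$sequence[rest],
                                   records$sequence[i], params)
    ev <- evalue_from_score(sc, lens[rest], lens[i], params)
    hit <- ev < threshold
    if (any(hit)) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = records$id[i], to = records$id[rest][hit],
        raw_score = sc[hit], evalue = ev[hit], stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = character(), to = character(),
                           raw_score = numeric(), evalue = numeric(),
                           stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = records$id, edges = edges, threshold = threshold),
            class = "similarity_graph")
}

#' Connected components of a similarity graph
#'
#' @param graph a \code{\link{build_graph}} result.
#' @return list of character vectors (sorted member ids), ordered by
#'   decreasing size, ties broken by the lexicographically smallest
#'   member.
#' @export
graph_components <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  clusters <- split(names(comp$membership), comp$membership)
  clusters <- lapply(clusters, sort)
  firsts <- vapply(clusters, `[`, "", 1L)
  ord <- order(-lengths(clusters), firsts)
  unname(clusters[ord])
}
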