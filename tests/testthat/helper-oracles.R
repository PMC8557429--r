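# Independent oracles used across the suite. These deliberately do not
# call the implementation paths they check.

# --- reference evaluation of the published screening expressions --------
# literal pattern strings, evaluated by the PCRE engine (the package
# builds its patterns programmatically and evaluates them with TRE)
ref_patterns <- c(
  "((.{2,25}G[KR][KR])|(.{2,25}[KR](.{1}|.{3}|.{5})G[KR*])){3,}",
  "(.{5,25}[KR][KR]){5,}"
)
ref_accept <- function(seqs) {
  grepl(ref_patterns[1L], seqs, perl = TRUE) |
    grepl(ref_patterns[2L], seqs, perl = TRUE)
}

rand_enriched_seqs <- function(n, len_range = c(50L, 700L)) {
  alph <- c(rep(c("K", "R", "G"), 6L),
            strsplit("ACDEFHILMNPQSTVWY", "")[[1L]])
  lens <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
  vapply(lens, function(L) paste(sample(alph, L, replace = TRUE),
                                 collapse = ""), "")
}

rand_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n,
               replace = TRUE), collapse = "")
}

# --- brute-force affine-gap Smith-Waterman ------------------------------
# O(mn) dynamic program, gap of length L costs gap_open + L * gap_ext
sw_dp_oracle <- function(a, b, mat, gap_open = 11, gap_ext = 1) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1L, m + 1L)
  Ix <- matrix(-Inf, n + 1L, m + 1L)
  Iy <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2L:(n + 1L)) for (j in 2L:(m + 1L)) {
    Ix[i, j] <- max(M[i - 1L, j] - gap_open - gap_ext,
                    Ix[i - 1L, j] - gap_ext)
    Iy[i, j] <- max(M[i, j - 1L] - gap_open - gap_ext,
                    Iy[i, j - 1L] - gap_ext)
    M[i, j] <- max(0, max(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L],
                          Iy[i - 1L, j - 1L]) + mat[A[i - 1L], B[j - 1L]])
    best <- max(best, M[i, j])
  }
  best
}

test_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  mn <- min(m)
  for (ch in c("X", "*")) {
    m[ch, ] <- mn
    m[, ch] <- mn
  }
  m
}

# --- peptide masses from elemental composition --------------------------
# residue formulas (residue = amino acid minus water) and monoisotopic
# atomic masses; fully independent of the implementation's residue table
.atoms <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
            O = 15.9949146196, S = 31.97207100)
.residue_formula <- list(
  G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2), K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)
.formula_mass <- function(f) sum(.atoms[names(f)] * f)
# modification deltas from elemental differences
oracle_mod_delta <- c(
  amidation = .formula_mass(c(N = 1, H = 1)) - .formula_mass(c(O = 1)),
  pyroglu_Q = -.formula_mass(c(N = 1, H = 3)),
  oxidation_M = .formula_mass(c(O = 1)),
  acetyl_Nterm = .formula_mass(c(C = 2, H = 2, O = 1)),
  sulfo_Y = .formula_mass(c(S = 1, O = 3)),
  carbamidomethyl_C = .formula_mass(c(C = 2, H = 3, N = 1, O = 1))
)
oracle_mass <- function(sequence, mods = character()) {
  s <- strsplit(sequence, "")[[1L]]
  res <- sum(vapply(s, function(a) .formula_mass(.residue_formula[[a]]), 0))
  water <- .formula_mass(c(H = 2, O = 1))
  # the fixed carbamidomethylation applies to every cysteine
  mult <- ifelse(mods == "carbamidomethyl_C", sum(s == "C"), 1)
  res + water + sum(oracle_mod_delta[mods] * mult)
}

# --- brute-force six-frame ORF scan -------------------------------------
revcomp_chr <- function(nt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(nt, "")[[1L]]]), collapse = "")
}
translate_codon_oracle <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  if (!grepl("N", codon)) return(unname(gc[[codon]]))
  subs <- c("A", "C", "G", "T")
  cand <- codon
  for (i in 1:3) {
    cand <- unlist(lapply(cand, function(cd) {
      if (substr(cd, i, i) == "N") {
        vapply(subs, function(x) {
          substr(cd, i, i) <- x
          cd
        }, "")
      } else cd
    }))
  }
  aas <- unique(unname(gc[cand]))
  if (length(aas) == 1L) aas else "X"
}
orf_oracle <- function(nt, min_len = 60L) {
  out <- character(0)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") nt else revcomp_chr(nt)
    for (off in 0:2) {
      n_cod <- (nchar(s) - off) %/% 3L
      if (n_cod < 1L) next
      prot <- paste(vapply(seq_len(n_cod), function(i) {
        translate_codon_oracle(substr(s, off + 3L * i - 2L, off + 3L * i))
      }, ""), collapse = "")
      for (piece in strsplit(prot, "*", fixed = TRUE)[[1L]]) {
        if (nchar(piece) >= min_len) out <- c(out, piece)
      }
    }
  }
  sort(out)
}

# --- shared acceptance-scale fixtures (built once per test run) ---------
.fixture_cache <- new.env(parent = emptyenv())
acceptance_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- generate_proteome(n_decoys = 1000L, seed = 101L)
  }
  .fixture_cache$sim
}
acceptance_annotated <- function() {
  if (is.null(.fixture_cache$ann)) {
    sim <- acceptance_sim()
    sig_of <- function(id) {
      sim$signals[sim$signals$protein_id == id, , drop = FALSE]
    }
    planted <- sim$truth$id[sim$truth$label == "planted"]
    anns <- lapply(planted, function(id) {
      annotate_precursor(sim$records[sim$records$id == id, , drop = FALSE],
                         signal = sig_of(id))
    })
    names(anns) <- planted
    .fixture_cache$ann <- anns
  }
  .fixture_cache$ann
}
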