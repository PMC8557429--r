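# Standard monoisotopic residue masses (Da) and the water mass added once
# per peptide chain. Leucine and isoleucine are distinct residues here
# (matching is sequence-level, not spectral).
AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)
WATER_MONO <- 18.010565

# Variable and fixed modification deltas (monoisotopic Da).
# amidation: C-terminal OH -> NH2; pyroglu_Q: N-terminal Gln cyclization
# (Gln only, not Glu, matching the search-space definition);
# carbamidomethyl_C is the only fixed modification and applies to every
# cysteine.
MOD_DELTAS <- c(
  amidation = -0.984016,
  pyroglu_Q = -17.026549,
  oxidation_M = 15.994915,
  acetyl_Nterm = 42.010565,
  sulfo_Y = 79.956815,
  carbamidomethyl_C = 57.021464
)

#' Modification table
#'
#' @return data frame of supported peptide modifications with their
#'   monoisotopic mass deltas and whether they are fixed.
#' @export
modification_table <- function() {
  data.frame(name = names(MOD_DELTAS), delta = unname(MOD_DELTAS),
             fixed = names(MOD_DELTAS) == "carbamidomethyl_C",
             stringsAsFactors = FALSE)
}

#' Parse a modification string
#'
#' Modifications are encoded \code{"name@pos"} joined by \code{";"}; the
#' position is optional for terminal modifications and for the fixed
#' carbamidomethylation (which then applies to every cysteine). An empty
#' string or \code{"-"} means no modification.
#'
#' @param x a single modification string.
#' @return data frame \code{name}, \code{pos} (NA when unpositioned).
#' @export
parse_modifications <- function(x) {
  if (is.na(x) || !nzchar(x) || x == "-") {
    return(data.frame(name = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  name <- sub("@.*$", "", parts)
  pos <- ifelse(grepl("@", parts),
                suppressWarnings(as.integer(sub("^.*@", "", parts))),
                NA_integer_)
  unknown <- setdiff(name, names(MOD_DELTAS))
  if (length(unknown)) stop("unknown modification: ",
                            paste(unknown, collapse = ", "))
  data.frame(name = name, pos = pos, stringsAsFactors = FALSE)
}

#' Monoisotopic peptide mass
#'
#' Sum of standard monoisotopic residue masses plus one water, plus the
#' deltas of the given modifications. Additive:
#' \code{mass(AB) = mass(A) + mass(B) - water}.
#'
#' @param sequence peptide string over the 20 standard residues.
#' @param modifications modification names (character vector), or a data
#'   frame from \code{\link{parse_modifications}}, or a modification
#'   string.
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(sequence, modifications = character()) {
  s <- strsplit(sequence, "")[[1L]]
  bad <- which(!s %in% names(AA_MONO))
  if (length(bad)) stop("unknown residue '", s[bad[1L]], "' at position ",
                        bad[1L], " in ", sequence)
  if (is.character(modifications) && length(modifications) == 1L &&
      grepl("@", modifications)) {
    modifications <- parse_modifications(modifications)
  }
  mods <- if (is.data.frame(modifications)) modifications
          else data.frame(name = as.character(modifications),
                          pos = rep(NA_integer_, length(modifications)),
                          stringsAsFactors = FALSE)
  unknown <- setdiff(mods$name, names(MOD_DELTAS))
  if (length(unknown)) stop("unknown modification: ",
                            paste(unknown, collapse = ", "))
  if (sum(mods$name == "amidation") > 1L) {
    stop("a peptide C-terminus is either amidated or a free acid, not both")
  }
  for (i in seq_len(nrow(mods))) {
    nm <- mods$name[i]; p <- mods$pos[i]
    ok <- switch(nm,
      amidation = TRUE,
      acetyl_Nterm = TRUE,
      pyroglu_Q = s[1L] == "Q",
      oxidation_M = if (is.na(p)) any(s == "M") else s[p] == "M",
      sulfo_Y = if (is.na(p)) any(s == "Y") else s[p] == "Y",
      carbamidomethyl_C = if (is.na(p)) TRUE else s[p] == "C"
    )
    if (!isTRUE(ok)) stop("modification ", nm, " invalid for peptide ",
                          sequence)
  }
  delta <- 0
  for (i in seq_len(nrow(mods))) {
    nm <- mods$name[i]
    mult <- if (nm == "carbamidomethyl_C" && is.na(mods$pos[i]))
      sum(s == "C") else 1L
    delta <- delta + MOD_DELTAS[[nm]] * mult
  }
  sum(AA_MONO[s]) + WATER_MONO + delta
}
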