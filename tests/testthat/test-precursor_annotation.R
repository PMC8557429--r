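test_that("dibasic sites are placed after non-overlapping dimers", {
  s1 <- find_cleavage_sites("AAKRAA")
  expect_equal(s1$position, 4L)
  expect_equal(s1$motif, "KR")
  expect_equal(nrow(find_cleavage_sites("AAAAAA")), 0L)
  # overlapping basic run: sites after positions 2 and 4
  s2 <- find_cleavage_sites("KRKR")
  expect_equal(s2$position, c(2L, 4L))
})

test_that("monobasic sites require an R with basic support at distance 3-6", {
  s <- find_cleavage_sites("KAAARA", include_monobasic = TRUE)
  mono <- s[s$site_type == "monobasic", ]
  expect_equal(mono$position, 4L)  # cleavage N-terminal to the R at 5
  expect_equal(mono$confidence, "alternative")

  # exhaustive position-by-position oracle on random sequences
  set.seed(11)
  for (i in 1:200) {
    seqstr <- paste(sample(c("K", "R", "A", "G", "L", "S"),
                           sample(10:60, 1L), replace = TRUE),
                    collapse = "")
    got <- find_cleavage_sites(seqstr, include_monobasic = TRUE)
    got_mono <- got$position[got$site_type == "monobasic"]
    ch <- strsplit(seqstr, "")[[1L]]
    basic <- ch %in% c("K", "R")
    want <- integer(0)
    for (p in which(ch == "R")) {
      adjacent <- (p > 1L && basic[p - 1L]) ||
        (p < length(ch) && basic[p + 1L])
      if (adjacent || p == 1L) next
      supported <- FALSE
      for (d in 3:6) if (p - d >= 1L && basic[p - d]) supported <- TRUE
      if (supported) want <- c(want, p - 1L)
    }
    expect_identical(got_mono, sort(want))
  }
})

test_that("peptides are derived between dibasic sites with modifications", {
  sig <- data.frame(protein_id = "p", has_signal = TRUE,
                    cleavage_after = 19L, score = 0.9)
  seqstr <- paste0("MKLLLLLLLLLLLLLLASA", "AFMRFG", "KR", "AYLRFG", "KR")
  pep <- derive_peptides(list(id = "p", sequence = seqstr), signal = sig)
  expect_equal(pep$sequence, c("AFMRF", "AYLRF"))
  expect_true(all(pep$amidated))
  expect_equal(pep$flanking, c("signal-dibasic", "dibasic-dibasic"))

  # leading Q flags potential pyroglutamate
  seq2 <- paste0("MKLLLLLLLLLLLLLLASA", "QSGAKG", "KR", "AFLG", "KR")
  pep2 <- derive_peptides(list(id = "p", sequence = seq2), signal = sig)
  expect_equal(pep2$sequence[1L], "QSGAK")
  expect_true(pep2$amidated[1L])
  expect_true(pep2$pyroglu[1L])

  # no internal sites, no signal: one peptide spanning the sequence
  pep3 <- derive_peptides(list(id = "p", sequence = "MAGAGAGAA"))
  expect_equal(pep3$sequence, "MAGAGAGAA")
  expect_equal(pep3$flanking, "dibasic-end")
  expect_false(pep3$amidated)
})

test_that("tiling reconstructs every annotated precursor exactly", {
  # handwritten edge cases: overlapping runs, lone-G segment, terminal G
  sig <- data.frame(protein_id = "p", has_signal = TRUE,
                    cleavage_after = 3L, score = 0.9)
  edge <- c("MAA" , "AFLRFG", "KRKR", "AYLG", "KR", "G", "KR", "APEW", "G")
  ann <- annotate_precursor(
    data.frame(id = "p", sequence = paste(edge, collapse = "")), sig)
  expect_true(check_tiling(ann))
  # terminal ...G amidates the last peptide
  last <- nrow(ann$peptides)
  expect_true(ann$peptides$amidated[last])
  expect_equal(ann$peptides$sequence[last], "APEW")

  # synthetic planted precursors
  sim <- generate_proteome(n_decoys = 0L, seed = 8L)
  for (id in sim$truth$id) {
    rec <- sim$records[sim$records$id == id, , drop = FALSE]
    sg <- sim$signals[sim$signals$protein_id == id, , drop = FALSE]
    expect_true(check_tiling(annotate_precursor(rec, sg)), info = id)
  }
})

test_that("amidation is flagged iff a glycine precedes a site or the end", {
  set.seed(13)
  sim <- generate_proteome(n_decoys = 0L, seed = 13L)
  ids <- sample(sim$truth$id, 20L)
  for (id in ids) {
    rec <- sim$records[sim$records$id == id, , drop = FALSE]
    sg <- sim$signals[sim$signals$protein_id == id, , drop = FALSE]
    ann <- annotate_precursor(rec, sg)
    s <- strsplit(ann$sequence, "")[[1L]]
    mask <- rep(FALSE, length(s))
    dib <- ann$sites[ann$sites$site_type == "dibasic", ]
    for (p in dib$position) mask[c(p - 1L, p)] <- TRUE
    for (i in seq_len(nrow(ann$peptides))) {
      e <- ann$peptides$end[i]
      g_next <- e < length(s) && s[e + 1L] == "G" &&
        (e + 1L == length(s) || mask[e + 2L])
      expect_equal(ann$peptides$amidated[i], g_next,
                   info = paste(id, i))
    }
  }
})

test_that("consecutive copies produce the alternative shorter amide product", {
  sig <- data.frame(protein_id = "p", has_signal = TRUE,
                    cleavage_after = 3L, score = 0.9)
  seqstr <- paste0("MAA", "ARGWG", "KR", "ARGWG", "KR", "TTEEF")
  ann <- annotate_precursor(data.frame(id = "p", sequence = seqstr), sig,
                            copy_motif = "ARGW")
  copies <- ann$peptides[grepl("ARGW", ann$peptides$sequence), ]
  expect_true(all(copies$consecutive_copy))
  expect_equal(unique(ann$alternatives$sequence), "GW")
  expect_true(all(ann$alternatives$amidated))

  # copies separated by an intersequence residue are not flagged
  seq2 <- paste0("MAA", "ARGWG", "KR", "T", "ARGWG", "KR")
  ann2 <- annotate_precursor(data.frame(id = "p", sequence = seq2), sig,
                             copy_motif = "ARGW")
  expect_false(any(ann2$peptides$consecutive_copy))

  cc <- detect_consecutive_copies(ann$peptides[0, ], "RGW", seqstr)
  expect_equal(nrow(cc$alternatives), 0L)
})

test_that("architecture classification follows the stated precedence", {
  sig <- data.frame(protein_id = "p", has_signal = TRUE,
                    cleavage_after = 3L, score = 0.9)
  mk <- function(body) annotate_precursor(
    data.frame(id = "p", sequence = paste0("MAA", body)), sig)

  multi <- mk(paste0("AA", strrep("DYPFLRFG" , 1L), "KR",
                     "TDYPFLRFG", "KR", "EDYPFLRFG", "KR", "SS"))
  expect_equal(multi$architecture$class, "multicopy")
  expect_gte(multi$architecture$copy_count, 3L)

  vaso <- mk(paste0("CYIQNCPRGG", "KR",
                    paste0("AE", strrep("LSC", 7L), "TT")))
  expect_equal(vaso$architecture$class, "single_copy_plus_cys_domain")
  expect_gte(length(vaso$architecture$cys_positions), 4L)

  cys8 <- mk(paste0("ALDEPTW", "KR", "CAACDDCAPACLLCWCCPCW"))
  expect_equal(cys8$architecture$class, "cys8_peptide")
  expect_length(cys8$architecture$cys_positions, 8L)

  single <- mk("QFDSWEPA")
  expect_equal(single$architecture$class, "single_copy")

  # order invariance of the classifier
  pep <- multi$peptides
  perm <- pep[sample(nrow(pep)), ]
  expect_equal(classify_architecture(list(sequence = multi$sequence),
                                     perm)$class, "multicopy")
})
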