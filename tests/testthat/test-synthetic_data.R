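test_that("proteome generation is deterministic and oracle-verified", {
  a <- generate_proteome(n_decoys = 60L, seed = 5L)
  b <- generate_proteome(n_decoys = 60L, seed = 5L)
  expect_identical(a, b)
  c2 <- generate_proteome(n_decoys = 60L, seed = 6L)
  expect_false(identical(a$records$sequence, c2$records$sequence))

  disc <- a$truth$id[a$truth$discoverable]
  expect_gte(length(unique(a$truth$family[a$truth$discoverable])), 5L)
  seqs <- a$records$sequence[match(disc, a$records$id)]
  expect_true(all(ref_accept(seqs)))

  # non-discoverable planted families must not leak into the screen
  nd <- a$truth$id[a$truth$label == "planted" & !a$truth$discoverable]
  nd_seqs <- a$records$sequence[match(nd, a$records$id)]
  expect_false(any(ref_accept(nd_seqs)))

  # every record labeled exactly once, signal table consistent
  expect_equal(anyDuplicated(a$truth$id), 0L)
  expect_setequal(a$truth$id, a$records$id)
  expect_setequal(a$signals$protein_id, a$records$id)

  # empty generation
  e <- generate_proteome(specs = list(), n_decoys = 0L, seed = 1L)
  expect_equal(nrow(e$records), 0L)
  expect_equal(nrow(e$truth), 0L)
})

test_that("impossible discoverable specs fail at generation", {
  bad <- family_spec("bad", copy_motif = "AFLRF",
                     spacer_len_range = c(26L, 30L))
  expect_error(generate_proteome(specs = list(bad), n_decoys = 0L,
                                 seed = 1L),
               "cannot satisfy")
})

test_that("gene-model generation recovers the planted plan end to end", {
  sim <- generate_proteome(n_decoys = 0L, seed = 9L)
  gwa <- sim$records[grepl("^gwa_", sim$records$id), , drop = FALSE][1:4, ]
  cys <- which(strsplit(gwa$sequence[1L], "")[[1L]] == "C")
  pos <- cys[length(cys) - 1L] + 12L
  plan <- data.frame(id = gwa$id, protein_pos = pos, phase = 0L,
                     stringsAsFactors = FALSE)
  gm <- generate_gene_models(gwa, plan, seed = 10L)
  expect_setequal(gm$truth$strand, c("+", "-"))
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_gff3(gm$gff, gff)
  write_genome_fasta(gm$genome, fa)
  genome <- setNames(as.character(Biostrings::readDNAStringSet(fa)),
                     names(gm$genome))
  models <- read_gene_models(gff)
  intr <- lapply(gwa$id, function(g) list(
    protein_id = g,
    introns = protein_introns(models[[g]],
                              gwa[gwa$id == g, , drop = FALSE], genome)))
  for (x in intr) {
    expect_equal(x$introns$protein_pos, pos)
    expect_equal(x$introns$phase, 0L)
  }
  # the members are generated pre-aligned (equal length, no indels)
  aln <- setNames(gwa$sequence, gwa$id)
  expect_length(unique(nchar(aln)), 1L)
  cons <- conserved_introns(intr, aln)
  expect_equal(length(unique(cons$group)), 1L)
  expect_equal(nrow(cons), 4L)
})

test_that("MS generator spans categories and errors on empty pools", {
  sim <- generate_proteome(n_decoys = 0L, seed = 12L)
  sig_of <- function(id) sim$signals[sim$signals$protein_id == id, ,
                                     drop = FALSE]
  planted <- sim$truth$id[sim$truth$label == "planted" &
                            !sim$truth$held_out]
  ann <- lapply(planted, function(id) annotate_precursor(
    sim$records[sim$records$id == id, , drop = FALSE], sig_of(id)))
  ms <- generate_ms_identifications(
    ann, n = 60L, seed = 2L,
    category_mix = c(full_dibasic = 0.5, truncated_N = 0.25,
                     monobasic_product = 0.25))
  expect_equal(nrow(ms$identifications), 60L)
  expect_setequal(unique(ms$truth$category),
                  c("full_dibasic", "truncated_N", "monobasic_product"))
  expect_true(all(nchar(ms$identifications$peptide_sequence) >= 4L))
  # masses are exactly theoretical at sigma = 0
  for (i in seq_len(10L)) {
    expect_equal(ms$identifications$observed_mass[i],
                 monoisotopic_mass(ms$identifications$peptide_sequence[i],
                                   parse_modifications(
                                     ms$identifications$modifications[i])))
  }
  expect_error(generate_ms_identifications(
    ann, n = 10L, seed = 2L,
    category_mix = c(full_dibasic = 0.5, novel_precursor = 0.5)),
    "novel_precursor")
})
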