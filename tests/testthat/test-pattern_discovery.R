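test_that("screen decisions match direct evaluation of the published patterns", {
  set.seed(1)
  seqs <- rand_enriched_seqs(2000L)
  recs <- data.frame(id = paste0("s", seq_along(seqs)), sequence = seqs,
                     stringsAsFactors = FALSE)
  hits <- scan_multicopy(recs)
  expect_identical(recs$id %in% hits$protein_id, unname(ref_accept(seqs)))
})

test_that("example sequences hit the correct pattern branch", {
  recs <- data.frame(
    id = c("none", "amid", "dib"),
    sequence = c("MAAAAAAAAAA",
                 paste0("M", strrep("AAGKR", 3L)),
                 paste0("M", strrep("AAAAAKR", 5L))),
    stringsAsFactors = FALSE)
  hits <- scan_multicopy(recs)
  expect_false("none" %in% hits$protein_id)
  expect_equal(hits$matched_branch[hits$protein_id == "amid"], "amidation")
  expect_equal(hits$matched_branch[hits$protein_id == "dib"], "dibasic")
  expect_match(hits$match_spans, "^\\d+-\\d+")
})

test_that("raising repeat thresholds never adds hits", {
  set.seed(2)
  recs <- data.frame(id = paste0("s", 1:500),
                     sequence = rand_enriched_seqs(500L, c(50L, 400L)),
                     stringsAsFactors = FALSE)
  base <- scan_multicopy(recs)$protein_id
  stricter_a <- scan_multicopy(recs, pattern_params(amid_min_repeats = 4L))
  stricter_d <- scan_multicopy(recs,
                               pattern_params(dibasic_min_repeats = 6L))
  expect_true(all(stricter_a$protein_id %in% base))
  expect_true(all(stricter_d$protein_id %in% base))
})

test_that("repeat-count, spacer and length boundaries follow the thresholds", {
  unit_hit <- function(s) nrow(scan_multicopy(
    data.frame(id = "x", sequence = s))) > 0L
  # 3 vs 2 amidation repeats
  expect_true(unit_hit(paste0("M", strrep("AAGKR", 3L))))
  expect_false(unit_hit(paste0("M", strrep("AAGKR", 2L))))
  # amidation spacer 25 vs 26
  expect_true(unit_hit(paste0("M", strrep(paste0(strrep("A", 25L), "GKR"),
                                          3L))))
  expect_false(unit_hit(paste0("M", strrep(paste0(strrep("A", 26L), "GKR"),
                                           3L))))
  # 5 vs 4 dibasic repeats
  expect_true(unit_hit(paste0("M", strrep("AAAAAKR", 5L))))
  expect_false(unit_hit(paste0("M", strrep("AAAAAKR", 4L))))
  # dibasic spacer 5 vs 4
  expect_true(unit_hit(paste0("M", strrep(paste0(strrep("A", 5L), "KR"),
                                          5L))))
  expect_false(unit_hit(paste0("M", strrep(paste0(strrep("A", 4L), "KR"),
                                           5L))))
  # length filter keeps 650 and drops 651
  recs <- data.frame(id = c("keep", "drop"),
                     sequence = c(rand_protein(650L), rand_protein(651L)),
                     stringsAsFactors = FALSE)
  expect_equal(suppressMessages(filter_length(recs))$id, "keep")
  expect_equal(nrow(filter_length(recs[0, ])), 0L)
})

test_that("signal gate keeps only annotated secreted proteins", {
  ann <- data.frame(protein_id = c("p1", "p2"),
                    has_signal = c(TRUE, FALSE),
                    cleavage_after = c(20L, NA), score = c(0.9, 0.1),
                    stringsAsFactors = FALSE)
  hits <- data.frame(protein_id = c("p1", "p2", "p3"),
                     stringsAsFactors = FALSE)
  expect_equal(suppressMessages(gate_by_signal(hits, ann))$protein_id, "p1")
  expect_equal(gate_by_signal(hits, ann, missing = "keep")$protein_id,
               c("p1", "p3"))
  expect_error(gate_by_signal(hits, ann, missing = "error"), "p3")
})

test_that("greedy dedup clusters by identity over the shorter sequence", {
  set.seed(3)
  s <- rand_protein(100L)
  recs <- data.frame(id = c("a", "b", "c", "d"),
                     sequence = c(s, s, rand_protein(100L),
                                  substr(s, 1L, 60L)),
                     stringsAsFactors = FALSE)
  dd <- dedup_greedy(recs)
  # identical pair collapses, the random 100-mer stays, the exact prefix
  # joins its parent (identity over shorter = 1)
  expect_setequal(dd$representatives$id, c("a", "c"))
  expect_setequal(dd$members$member, c("b", "d"))
  expect_equal(dd$members$representative[dd$members$member == "d"], "a")
  # idempotent on its own representatives
  dd2 <- dedup_greedy(dd$representatives)
  expect_equal(dd2$representatives$id, dd$representatives$id)
  expect_equal(nrow(dd2$members), 0L)
})
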