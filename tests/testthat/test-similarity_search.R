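test_that("self-alignment score is the sum of diagonal matrix values", {
  m <- test_blosum62()
  set.seed(21)
  for (i in 1:5) {
    s <- rand_protein(sample(10:40, 1L))
    expect_equal(local_align(s, s)$raw_score,
                 sum(diag(m[strsplit(s, "")[[1L]], strsplit(s, "")[[1L]]])))
  }
  # E-value strictly decreasing in score for fixed lengths
  p <- search_params()
  ev <- function(sc) p$K * 3600 * exp(-p$lambda * sc)
  expect_true(all(diff(ev(1:50)) < 0))
  expect_error(local_align("", "AAA"), "empty")
})

test_that("local alignment scores equal the brute-force DP oracle", {
  m <- test_blosum62()
  set.seed(22)
  for (i in 1:20) {
    a <- rand_protein(sample(10:60, 1L))
    b <- rand_protein(sample(10:60, 1L))
    expect_identical(local_align(a, b)$raw_score, sw_dp_oracle(a, b, m))
  }
})

test_that("the second pass recovers hidden orthologs through a chain", {
  set.seed(11)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  rs <- function(n) paste(sample(aa, n, TRUE), collapse = "")
  X1 <- rs(60); X2 <- rs(60); X3 <- rs(60); X4 <- rs(60)
  pro <- data.frame(id = c("A", "B", "C"),
                    sequence = c(paste0(X1, X2), paste0(X2, X3),
                                 paste0(X3, X4)),
                    stringsAsFactors = FALSE)
  seeds <- data.frame(id = "seedA", sequence = pro$sequence[1L],
                      stringsAsFactors = FALSE)
  p <- search_params()
  # construction check: C is dissimilar to the seed, similar to B
  expect_gt(local_align(seeds$sequence, pro$sequence[3L], p)$evalue,
            p$relaxed_evalue)
  expect_lt(local_align(pro$sequence[2L], pro$sequence[3L], p)$evalue,
            p$stringent_evalue)

  res <- two_pass_search(pro, seeds, p)
  expect_true("C" %in% res$protein_id)
  row_c <- res[res$protein_id == "C", ]
  expect_false(row_c$pass1)
  expect_true(row_c$pass2)

  # single stringent pass against the seeds alone misses C
  aln <- align_all(pro, seeds, p)
  best <- tapply(aln$evalue, aln$query_id, min)
  single <- names(best)[best <= p$stringent_evalue]
  expect_false("C" %in% single)
  # two-pass output is a superset of the single stringent pass
  expect_true(all(single %in% res$protein_id))

  expect_equal(nrow(two_pass_search(pro[0, ], seeds, p)), 0L)
  expect_error(two_pass_search(pro, seeds[0, ], p), "non-empty")
})

test_that("similarity graph components refine across thresholds", {
  set.seed(23)
  # two planted families of mutually similar members + random singletons
  base1 <- rand_protein(120L)
  base2 <- rand_protein(120L)
  mutate <- function(s) {
    ch <- strsplit(s, "")[[1L]]
    idx <- sample(length(ch), 10L)
    ch[idx] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], 10L,
                      replace = TRUE)
    paste(ch, collapse = "")
  }
  recs <- data.frame(
    id = c(paste0("f1_", 1:10), paste0("f2_", 1:10), paste0("r", 1:5)),
    sequence = c(vapply(1:10, function(i) mutate(base1), ""),
                 vapply(1:10, function(i) mutate(base2), ""),
                 vapply(1:5, function(i) rand_protein(120L), "")),
    stringsAsFactors = FALSE)
  p <- search_params()
  g5 <- build_graph(recs, p, threshold = 1e-5)
  comp5 <- graph_components(g5)
  multi <- comp5[lengths(comp5) > 1L]
  expect_length(multi, 2L)
  expect_setequal(multi[[1L]], paste0("f1_", 1:10))
  expect_setequal(multi[[2L]], paste0("f2_", 1:10))

  # edge subset and component refinement at the display threshold
  g10 <- build_graph(recs, p, threshold = 1e-10)
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(g10$edges) %in% key(g5$edges)))
  comp10 <- graph_components(g10)
  comp_of <- function(comps, id) which(vapply(comps, function(x)
    id %in% x, TRUE))
  for (cl in comp10) {
    hosts <- vapply(cl, function(id) comp_of(comp5, id), 1L)
    expect_length(unique(hosts), 1L)
  }

  # no edges: every record is a singleton
  none <- build_graph(recs[21:25, ], p, threshold = 1e-300)
  expect_true(all(lengths(graph_components(none)) == 1L))
})
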