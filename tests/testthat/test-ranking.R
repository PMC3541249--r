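test_that("relative entropy follows p1*log(p1/p2) with its conventions", {
  cfg <- ranking_config()
  # p1 == p2 exactly -> 0
  expect_equal(relative_entropy(list(n_sel = 1, N_sel = 2, n_ref = 0,
                                     N_ref = 1), cfg), 0)   # 1/2 vs (0+1)/(1+1)
  # unsmoothed worked example: 0.5 * ln(50)
  raw <- list(mode = "relative_entropy", proportion_mode = "proportions",
              pseudocount = 0)
  expect_equal(relative_entropy(list(n_sel = 5, N_sel = 10, n_ref = 10,
                                     N_ref = 1000), raw),
               0.5 * log(50), tolerance = 1e-12)
  expect_equal(round(relative_entropy(list(n_sel = 5, N_sel = 10, n_ref = 10,
                                           N_ref = 1000), raw), 4), 1.956)
  # absent from the selection -> 0 whatever the reference says
  expect_equal(relative_entropy(list(n_sel = 0, N_sel = 10, n_ref = 500,
                                     N_ref = 1000), cfg), 0)
  expect_error(relative_entropy(list(n_sel = 1, N_sel = 0, n_ref = 1,
                                     N_ref = 10), cfg), "domain")
  expect_error(ranking_config(pseudocount = 0), "pseudocount")
})

test_that("frequency ranking orders by count with lexicographic ties", {
  expect_equal(nrow(rank_by_frequency(data.frame(entry_id = character(),
                                                 doc_count = integer()))), 0)
  r <- rank_by_frequency(data.frame(entry_id = c("A", "B", "C"),
                                    doc_count = c(3, 7, 3)))
  expect_equal(r$entry_id, c("B", "A", "C"))
  expect_equal(r$rank, 1:3)
  expect_equal(r$score, c(7, 3, 3))

  set.seed(13)
  tab <- data.frame(entry_id = sprintf("e%02d", sample(50)),
                    doc_count = sample(0:9, 50, replace = TRUE))
  r <- rank_by_frequency(tab)
  o <- order(-tab$doc_count, tab$entry_id)            # reference sort oracle
  expect_equal(r$entry_id, tab$entry_id[o])
  expect_true(all(diff(r$score) <= 0))
})

test_that("entropy ranking promotes selection-specific entities over ubiquitous ones", {
  # U: 8 of 10 selected docs, rare in reference; C: 10 of 10, ubiquitous
  docs <- make_docs(sprintf("r%03d", 1:1000), rep("x", 1000))
  anns <- rbind(
    data.frame(doc_id = sprintf("r%03d", 1:12), entry_id = "U",
               stringsAsFactors = FALSE),
    data.frame(doc_id = sprintf("r%03d", 1:900), entry_id = "C",
               stringsAsFactors = FALSE))
  anns <- cbind(anns, field = "abstract", start = 0L, end = 1L,
                matched_text = "x", class_id = "Genes")
  ref <- build_index(docs, anns)
  tab <- data.frame(entry_id = c("C", "U"), doc_count = c(10L, 8L))
  ent <- rank_by_relative_entropy(tab, ref, sel_size = 10)
  freq <- rank_by_frequency(tab)
  expect_equal(ent$entry_id[1], "U")        # entropy: rare-in-reference wins
  expect_equal(freq$entry_id[1], "C")       # frequency: raw count wins

  expect_warning(
    rank_by_relative_entropy(data.frame(entry_id = "GHOST", doc_count = 2L),
                             ref, sel_size = 10),
    "absent from the reference")
})

test_that("entropy ranking equals the brute-force score-then-sort oracle", {
  set.seed(21)
  docs <- make_docs(sprintf("r%03d", 1:500), rep("x", 500))
  ents <- sprintf("e%02d", 1:20)
  anns <- do.call(rbind, lapply(ents, function(e) {
    n <- sample(1:400, 1)
    data.frame(doc_id = sprintf("r%03d", sample(500, n)), field = "abstract",
               start = 0L, end = 1L, matched_text = "x", entry_id = e,
               class_id = "Genes", stringsAsFactors = FALSE)
  }))
  ref <- build_index(docs, anns)
  tab <- data.frame(entry_id = ents,
                    doc_count = sample(1:30, 20, replace = TRUE))
  cfg <- ranking_config()
  r <- rank_by_relative_entropy(tab, ref, sel_size = 40, cfg)
  oracle_score <- vapply(seq_len(nrow(tab)), function(i) {
    p1 <- tab$doc_count[i] / 40
    n_ref <- length(ref$postings_entry[[tab$entry_id[i]]])
    p2 <- (n_ref + 1) / (ref$n_docs + 1)
    p1 * log(p1 / p2)
  }, numeric(1))
  o <- order(-oracle_score, -tab$doc_count, tab$entry_id)
  expect_equal(r$entry_id, tab$entry_id[o])
  expect_equal(r$score, oracle_score[o], tolerance = 1e-12)
  expect_equal(r$rank, seq_len(nrow(tab)))
  expect_true(all(diff(r$score) <= 1e-12))
})

test_that("rank order is invariant to the logarithm base", {
  set.seed(4)
  stats_list <- lapply(1:30, function(i)
    list(n_sel = sample(1:20, 1), N_sel = 20,
         n_ref = sample(0:500, 1), N_ref = 1000))
  cfg <- ranking_config()
  nat <- vapply(stats_list, relative_entropy, numeric(1), cfg = cfg)
  base2 <- nat / log(2)            # log2 rescales every score by 1/ln 2 > 0
  ids <- sprintf("s%02d", seq_along(nat))
  expect_equal(order(-nat, ids), order(-base2, ids))
})

test_that("score increases with n_sel whenever p1 >= p2", {
  cfg <- ranking_config()
  n_ref <- 50; N_ref <- 1000; N_sel <- 40
  p2 <- (n_ref + 1) / (N_ref + 1)
  ns <- seq_len(N_sel)
  sc <- vapply(ns, function(n) relative_entropy(
    list(n_sel = n, N_sel = N_sel, n_ref = n_ref, N_ref = N_ref), cfg),
    numeric(1))
  above <- which(ns / N_sel >= p2)
  expect_true(all(diff(sc[above]) > 0))
})

test_that("frequency and entropy ranking agree in the reference-uniform limit", {
  docs <- make_docs(sprintf("r%02d", 1:50), rep("x", 50))
  ents <- c("A", "B", "C", "D")
  anns <- do.call(rbind, lapply(ents, function(e)
    data.frame(doc_id = sprintf("r%02d", 1:10), field = "abstract", start = 0L,
               end = 1L, matched_text = "x", entry_id = e, class_id = "G",
               stringsAsFactors = FALSE)))
  ref <- build_index(docs, anns)          # identical n_ref for every entity
  tab <- data.frame(entry_id = ents, doc_count = c(9L, 2L, 5L, 7L))
  expect_equal(rank_by_relative_entropy(tab, ref, sel_size = 10)$entry_id,
               rank_by_frequency(tab)$entry_id)
})

test_that("raw-counts mode reads the score off the document counts", {
  raw <- ranking_config(proportion_mode = "raw_counts", pseudocount = 1)
  s <- list(n_sel = 5, N_sel = 10, n_ref = 9, N_ref = 1000)
  expect_equal(relative_entropy(s, raw), 5 * log(5 / 10), tolerance = 1e-12)
})

test_that("the minimum-document filter keeps the inclusive boundary", {
  tab <- data.frame(entry_id = c("A", "B", "C"), doc_count = c(4L, 5L, 12L))
  expect_equal(filter_min_docs(tab, 0), tab)
  expect_equal(filter_min_docs(tab, 5)$entry_id, c("B", "C"))
  set.seed(2)
  rt <- data.frame(entry_id = sprintf("e%02d", 1:40),
                   doc_count = sample(0:10, 40, replace = TRUE))
  k <- 4
  expect_equal(filter_min_docs(rt, k)$entry_id,
               rt$entry_id[rt$doc_count >= k])
})
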