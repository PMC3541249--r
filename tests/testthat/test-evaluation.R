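test_that("kappa matches hand-computed chance-corrected agreement", {
  expect_equal(cohens_kappa(diag(c(4, 6))), 1)
  # Pr(a)=0.8, Pr(e)=0.52 -> 0.28/0.48
  expect_equal(cohens_kappa(matrix(c(5, 1, 1, 3), 2, byrow = TRUE)),
               0.28 / 0.48, tolerance = 1e-12)
  expect_equal(round(cohens_kappa(matrix(c(5, 1, 1, 3), 2)), 4), 0.5833)
  expect_equal(cohens_kappa(matrix(1, 2, 2)), 0)     # exactly at chance
  expect_error(cohens_kappa(matrix(0, 2, 2)), "empty")
  expect_error(cohens_kappa(matrix(1, 2, 3)), "square")
  # both raters constant on the same category: chance agreement is 1
  expect_equal(cohens_kappa(matrix(c(7, 0, 0, 0), 2)), 1)
})

test_that("kappa is symmetric and invariant under category relabeling", {
  set.seed(19)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    tab <- matrix(rpois(k * k, 3) + 1, k, k)
    expect_equal(cohens_kappa(tab), cohens_kappa(t(tab)), tolerance = 1e-12)
    perm <- sample(k)
    expect_equal(cohens_kappa(tab[perm, perm]), cohens_kappa(tab),
                 tolerance = 1e-12)
  }
})

test_that("enrichment curves count gold hits along the ranked list", {
  L <- sprintf("g%d", 1:5)
  expect_equal(enrichment_curve(L, c("x", "y")), c(0, 0, 0, 0, 0))
  expect_equal(enrichment_curve(L, c("g2", "g4")), c(0, 1, 1, 2, 2))
  expect_equal(enrichment_curve(L, L), 1:5)
  expect_warning(curve <- enrichment_curve(L, character()), "empty gold")
  expect_equal(curve, rep(0L, 5))
  expect_error(enrichment_curve(character(), "g1"), "empty")

  expect_equal(enrichment_score(c(0, 1, 1, 2, 2)), 2)
  expect_equal(enrichment_score(rep(0L, 4)), 0)
  expect_equal(enrichment_score(1:9), 9)

  # final value equals |set(L) ∩ S| computed independently
  set.seed(6)
  for (i in 1:10) {
    L <- sample(sprintf("g%02d", 1:40), 25)
    S <- sample(sprintf("g%02d", 1:40), 12)
    cv <- enrichment_curve(L, S)
    expect_equal(cv[length(cv)], length(intersect(L, S)))
    expect_true(all(diff(cv) %in% c(0L, 1L)))
  }
})

test_that("the F-score is the harmonic mean with the stated edge case", {
  expect_equal(f_score(1, 1), 1)
  expect_equal(f_score(0, 0), 0)
  expect_equal(round_half_up(f_score(0.52, 0.67), 2), 0.59)
  expect_equal(round_half_up(f_score(0.59, 0.57), 2), 0.58)
  expect_error(f_score(1.2, 0.5), "domain")
  expect_error(f_score(0.5, -0.1), "domain")
})

test_that("round_half_up rounds ties away from zero at the printed precision", {
  expect_equal(round_half_up(0.585, 2), 0.59)
  expect_equal(round_half_up(0.584999, 2), 0.58)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-0.585, 2), -0.59)
})

test_that("precision/recall identities hold at every cutoff", {
  L <- sprintf("g%d", 1:5); S <- c("g2", "g4")
  tab <- precision_recall_table(L, S)
  expect_equal(tab$tp[3], 1)
  expect_equal(tab$precision[3], 1 / 3)
  expect_equal(tab$recall[3], 1 / 2)
  expect_equal(tab$recall[nrow(tab)], 1)       # S ⊆ L

  set.seed(8)
  for (i in 1:10) {
    L <- sample(sprintf("g%02d", 1:30), 20)
    S <- sample(sprintf("g%02d", 1:30), 7)
    tab <- precision_recall_table(L, S)
    expect_equal(tab$tp + tab$fp, tab$rank)
    expect_equal(tab$tp + tab$fn, rep(length(S), nrow(tab)))
    expect_true(all(diff(tab$recall) >= 0))
    miss <- which(diff(tab$tp) == 0) + 1       # rank added a miss
    expect_true(all(tab$precision[miss] < tab$precision[miss - 1] |
                      tab$precision[miss - 1] == 0))
    expect_equal(tab$f_score,
                 mapply(f_score, tab$precision, tab$recall))
  }
})

test_that("recall thresholds pick the first qualifying rank", {
  L <- sprintf("g%d", 1:5); S <- c("g2", "g4")
  tab <- precision_recall_table(L, S)
  at <- metrics_at_recall(tab, c(0.5, 1.0))
  expect_equal(at$rank[at$threshold == 0.5], 2)
  expect_equal(at$rank[at$threshold == 1.0], 4)
  none <- metrics_at_recall(precision_recall_table(L, c("zz1", "zz2")), 0.5)
  expect_true(is.na(none$rank))
  expect_error(metrics_at_recall(tab, 0), "thresholds")
})

test_that("the maximal F-score takes the earliest best cutoff", {
  L <- sprintf("g%d", 1:4)
  best <- max_f_score(precision_recall_table(L, L))
  expect_equal(best$rank, 4)
  expect_equal(best$f_score, 1)
  allmiss <- max_f_score(precision_recall_table(L, c("q1", "q2")))
  expect_equal(allmiss$rank, 1)
  expect_equal(allmiss$f_score, 0)
  set.seed(3)
  L <- sample(sprintf("g%02d", 1:30), 20)
  S <- sample(sprintf("g%02d", 1:30), 8)
  tab <- precision_recall_table(L, S)
  i <- which.max(tab$f_score)                 # exhaustive scan oracle
  expect_equal(max_f_score(tab), list(rank = tab$rank[i],
                                      f_score = tab$f_score[i]))
})

test_that("published reference rows are consistent within one printed digit", {
  tab <- ad_reference_metrics()
  expect_equal(nrow(tab), 32)
  recomputed <- mapply(f_score, tab$precision, tab$recall)
  # printed precision/recall are rounded to 2 dp, so F recomputed from them
  # can differ from the printed F by one unit in the last printed digit
  expect_true(all(abs(recomputed - tab$f_score) <= 0.0105))
  # and within each selection, ranks at the recall thresholds increase
  for (sel in unique(tab$selection)) {
    rows <- tab[tab$selection == sel & tab$row_type == "recall_threshold", ]
    expect_true(all(diff(rows$rank) > 0))
    expect_true(all(diff(rows$recall) > 0))
  }
})

test_that("gold standards read from text files drop comments", {
  p <- tempfile()
  writeLines(c("# curated markers", "APP", "APOE  ", "", "PSEN1 # inline"), p)
  g <- read_gold_standard(p)
  expect_equal(g$entity_ids, c("APOE", "APP", "PSEN1"))
})

test_that("top-abstract selection is newest first and truncated", {
  fx <- make_five_doc_fixture()
  all_docs <- fx$index$documents$doc_id
  got <- select_top_abstracts(fx$index, all_docs, "G1", n = 10)
  expect_equal(got$doc_id, c("d2", "d1"))               # 2004 before 2001
  got2 <- select_top_abstracts(fx$index, all_docs, "G2", n = 1)
  expect_equal(got2$doc_id, "d2")                       # 2004 beats 1999
  expect_equal(nrow(select_top_abstracts(fx$index, all_docs, "NOPE")), 0)
  # date tie broken by doc_id descending
  got3 <- select_top_abstracts(fx$index, all_docs, "EXPR", n = 10)
  expect_equal(got3$doc_id[1:2], c("d3", "d2"))         # both 2004-01-10
})
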