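test_that("an empty terminology yields a matcher that matches nothing", {
  expect_warning(m <- compile_matcher(terminology()), "match nothing")
  doc <- list(doc_id = "d1", title = "some title",
              abstract = "gene expression analysis")
  expect_equal(nrow(annotate_document(m, doc)), 0)
})

test_that("single-synonym matching reports exact 0-based spans", {
  term <- make_match_terminology()
  m <- compile_matcher(term)
  ann <- annotate_document(m, list(doc_id = "d1", title = "",
                                   abstract = "gene expression analysis"))
  exp_row <- ann[ann$entry_id == "EXPR", ]
  expect_equal(nrow(exp_row), 1)
  expect_equal(exp_row$start, 5)
  expect_equal(exp_row$end, 15)
  expect_equal(exp_row$matched_text, "expression")
})

test_that("case policy separates acronyms from long forms", {
  term <- make_match_terminology()
  m <- compile_matcher(term)
  ann <- annotate_document(m, list(
    doc_id = "d1", title = "", abstract = "ms patients with Multiple Sclerosis"))
  ann <- ann[ann$entry_id == "MS_DIS", ]
  expect_equal(nrow(ann), 1)                 # lowercase "ms" rejected (cs)
  expect_equal(ann$matched_text, "Multiple Sclerosis")
  ann2 <- annotate_document(m, list(doc_id = "d2", title = "",
                                    abstract = "MS patients and MSH2"))
  expect_equal(ann2$matched_text, "MS")      # boundary blocks MSH2
  expect_equal(nrow(ann2), 1)
})

test_that("leftmost-longest wins over nested shorter matches", {
  m <- compile_matcher(make_match_terminology())
  ann <- annotate_document(m, list(doc_id = "d1", title = "",
                                   abstract = "Kaplan-Meier Analysis was used"))
  expect_equal(nrow(ann), 1)
  expect_equal(ann$entry_id, "KMA")
  expect_equal(ann$matched_text, "Kaplan-Meier Analysis")
  # spelling variant: space for hyphen, collapsed separators
  ann2 <- annotate_document(m, list(doc_id = "d2", title = "",
                                    abstract = "the Kaplan  Meier Analysis"))
  expect_equal(ann2$entry_id, "KMA")
})

test_that("title and abstract are annotated independently", {
  term <- terminology(
    classes = data.frame(class_id = "P", name = "Prognosis",
                         parent_id = NA_character_, description = "",
                         stringsAsFactors = FALSE),
    entries = data.frame(entry_id = "BM", class_id = "P",
                         preferred_name = "biomarker", stringsAsFactors = FALSE),
    synonyms = data.frame(entry_id = "BM", text = "biomarker",
                          case_sensitive = FALSE, stringsAsFactors = FALSE))
  m <- compile_matcher(term)
  ann <- annotate_document(m, list(doc_id = "d1",
                                   title = "a biomarker study",
                                   abstract = "the biomarker was measured"))
  expect_equal(nrow(ann), 2)
  expect_equal(ann$field, c("title", "abstract"))
  expect_equal(ann$start, c(2, 4))
  for (i in 1:2) {
    text <- if (ann$field[i] == "title") "a biomarker study" else
      "the biomarker was measured"
    expect_equal(substr(text, ann$start[i] + 1, ann$end[i]), "biomarker")
  }
  expect_equal(nrow(annotate_document(m, list(doc_id = "d0", title = "",
                                              abstract = ""))), 0)
})

test_that("overlap resolution is greedy leftmost-longest with lexicographic ties", {
  base <- data.frame(doc_id = "d", field = "abstract",
                     matched_text = "x", class_id = "c",
                     stringsAsFactors = FALSE)
  disjoint <- cbind(base[rep(1, 2), ],
                    data.frame(start = c(0L, 10L), end = c(5L, 14L)))
  disjoint$entry_id <- c("A", "B")
  out <- resolve_overlaps(disjoint)
  expect_equal(out$start, c(0, 10))

  over <- cbind(base[rep(1, 2), ],
                data.frame(start = c(0L, 3L), end = c(5L, 9L)))
  over$entry_id <- c("A", "B")
  expect_equal(resolve_overlaps(over)$start, 0)

  tie <- cbind(base[rep(1, 2), ], data.frame(start = 0L, end = 5L))
  tie$entry_id <- c("APP", "APOE")
  expect_equal(resolve_overlaps(tie)$entry_id, "APOE")

  multi <- cbind(base[rep(1, 2), ], data.frame(start = 0L, end = 5L))
  multi$entry_id <- "A"
  multi$doc_id <- c("d1", "d2")
  expect_error(resolve_overlaps(multi), "multiple doc_ids")
})

test_that("annotations are invariant to terminology line order", {
  lines <- c("C\tEvidence\tEvidence marker\t-\t",
             "C\tStatistics\tStatistics\t-\t",
             "S\tEXPR\tEvidence\texpression\texpression\tci",
             "S\tKMA\tStatistics\tKaplan-Meier Analysis\tKaplan-Meier Analysis\tci",
             "S\tANA\tStatistics\tAnalysis\tAnalysis\tci")
  doc <- list(doc_id = "d", title = "expression study",
              abstract = "Kaplan-Meier Analysis of expression data")
  ref <- annotate_document(compile_matcher(load_terminology(
    write_tsv_fixture(lines))), doc)
  set.seed(5)
  for (i in 1:4) {
    alt <- annotate_document(compile_matcher(load_terminology(
      write_tsv_fixture(sample(lines)))), doc)
    expect_equal(alt, ref)
  }
})

test_that("matcher agrees with the naive per-synonym oracle on random documents", {
  term <- make_match_terminology()
  m <- compile_matcher(term)
  vocab <- c(term$synonyms$text, "Kaplan", "Meier", "Analysis", "expressions",
             "ms", "MSH2", "Multiple", "Sclerosis", "gene", "tumour",
             "patients", "apoptosis", "APPLE")
  set.seed(808)
  n_checked <- 0
  for (i in 1:110) {
    doc <- random_doc(sprintf("rd%03d", i), vocab,
                      n_tokens = sample(6:18, 1))
    got <- annotate_document(m, doc)
    want <- oracle_annotate(term, doc)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("doc", i, ":", doc$abstract))
    # offsets index the declared field
    if (nrow(got)) {
      for (r in seq_len(nrow(got))) {
        text <- doc[[got$field[r]]]
        expect_identical(substr(text, got$start[r] + 1, got$end[r]),
                         got$matched_text[r])
      }
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)
})
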