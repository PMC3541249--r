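# Fixture builders: everything is constructed in code at test time.

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path, useBytes = TRUE)
  path
}

# the six biomarker retrieval classes as roots, no entries
six_class_lines <- function() c(
  "# six biomarker retrieval classes",
  "C\tClinicalManagement\tClinical Management\t-\tClinical investigations on patients",
  "C\tDiagnostics\tDiagnostics\t-\tClinical and molecular diagnostics",
  "C\tPrognosis\tPrognosis\t-\tPrediction of outcome",
  "C\tStatistics\tStatistics\t-\tStatistical methods",
  "C\tEvidence\tEvidence marker\t-\tMolecular evidence of gene activity",
  "C\tAntecedent\tAntecedent\t-\tRisk factors")

# 3-level tree: 1 root, 2 children, 4 grandchildren; one entry per class
tree_lines <- function() c(
  "C\troot\tRoot\t-\t",
  "C\tkid1\tChild one\troot\t",
  "C\tkid2\tChild two\troot\t",
  "C\tgk1\tGrandchild 1\tkid1\t",
  "C\tgk2\tGrandchild 2\tkid1\t",
  "C\tgk3\tGrandchild 3\tkid2\t",
  "C\tgk4\tGrandchild 4\tkid2\t",
  "S\te_root\troot\troot term\troot term\tci",
  "S\te_gk1\tgk1\tleafy term\tleafy term\tci")

# terminology with exactly 6 classes, 10 entries, 25 synonyms
counted_lines <- function() {
  cl <- sprintf("C\tc%d\tClass %d\t-\t", 1:6, 1:6)
  syn <- character()
  # entries e1..e10 distributed over c1..c6; 25 synonym lines total
  sizes <- c(4, 3, 3, 3, 2, 2, 2, 2, 2, 2)      # sums to 25
  owner <- sprintf("c%d", rep(1:6, length.out = 10))
  for (i in 1:10) {
    for (s in seq_len(sizes[i])) {
      syn <- c(syn, sprintf("S\te%02d\t%s\tterm%02d\tsynonym%02dv%d\tci",
                            i, owner[i], i, i, s))
    }
  }
  c(cl, syn)
}

make_tree_terminology <- function() load_terminology(write_tsv_fixture(tree_lines()))
make_counted_terminology <- function() load_terminology(write_tsv_fixture(counted_lines()))

# small hand-made terminology for matching tests
make_match_terminology <- function() {
  terminology(
    classes = data.frame(
      class_id = c("Diseases", "Evidence", "Statistics", "Genes"),
      name = c("Diseases", "Evidence marker", "Statistics", "Genes"),
      parent_id = NA_character_, description = "",
      stringsAsFactors = FALSE),
    entries = data.frame(
      entry_id = c("MS_DIS", "EXPR", "KMA", "ANA", "APP", "APOE"),
      class_id = c("Diseases", "Evidence", "Statistics", "Statistics",
                   "Genes", "Genes"),
      preferred_name = c("multiple sclerosis", "expression",
                         "Kaplan-Meier Analysis", "Analysis", "APP", "APOE"),
      stringsAsFactors = FALSE),
    synonyms = data.frame(
      entry_id = c("MS_DIS", "MS_DIS", "EXPR", "KMA", "ANA", "APP", "APOE"),
      text = c("MS", "multiple sclerosis", "expression",
               "Kaplan-Meier Analysis", "Analysis", "APP", "APOE"),
      case_sensitive = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE),
    name = "match-fixture")
}

make_docs <- function(ids, abstracts, titles = NULL, dates = NULL) {
  data.frame(doc_id = ids,
             title = titles %||% rep("", length(ids)),
             abstract = abstracts,
             date = dates %||% rep(NA_character_, length(ids)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small terminology for merge/property tests
random_terminology <- function(n_classes = 3, n_entries = 4, prefix = "r") {
  cl <- data.frame(class_id = sprintf("%s_c%d", prefix, seq_len(n_classes)),
                   name = sprintf("%s class %d", prefix, seq_len(n_classes)),
                   parent_id = NA_character_, description = "",
                   stringsAsFactors = FALSE)
  if (n_classes > 1)          # chain some children under the first class
    cl$parent_id[-1] <- ifelse(stats::runif(n_classes - 1) < 0.5,
                               cl$class_id[1], NA_character_)
  en <- data.frame(entry_id = sprintf("%s_e%d", prefix, seq_len(n_entries)),
                   class_id = sample(cl$class_id, n_entries, replace = TRUE),
                   preferred_name = sprintf("%sterm%d", prefix, seq_len(n_entries)),
                   stringsAsFactors = FALSE)
  sy <- do.call(rbind, lapply(seq_len(n_entries), function(i) {
    k <- sample(1:3, 1)
    data.frame(entry_id = en$entry_id[i],
               text = sprintf("%sterm%dsyn%d", prefix, i, seq_len(k)),
               case_sensitive = FALSE, stringsAsFactors = FALSE)
  }))
  terminology(classes = cl, entries = en, synonyms = sy,
              name = paste0(prefix, "-random"))
}

# a tiny annotated 5-doc fixture used across index/query tests:
# docs 1,2 mention the disease; 2,3 mention an Evidence term; genes G1..G3
make_five_doc_fixture <- function() {
  term <- terminology(
    classes = data.frame(
      class_id = c("Diseases", "Evidence", "Genes"),
      name = c("Diseases", "Evidence marker", "Genes"),
      parent_id = NA_character_, description = "", stringsAsFactors = FALSE),
    entries = data.frame(
      entry_id = c("NSCLC", "EXPR", "G1", "G2", "G3"),
      class_id = c("Diseases", "Evidence", "Genes", "Genes", "Genes"),
      preferred_name = c("nsclc", "expression", "tp53", "egfr", "kras"),
      stringsAsFactors = FALSE),
    synonyms = data.frame(
      entry_id = c("NSCLC", "EXPR", "G1", "G2", "G3"),
      text = c("nsclc", "expression", "tp53", "egfr", "kras"),
      case_sensitive = FALSE, stringsAsFactors = FALSE),
    name = "five-doc-fixture")
  docs <- make_docs(
    sprintf("d%d", 1:5),
    c("nsclc tumours and tp53 in lung",
      "nsclc cohort shows expression of egfr and tp53",
      "expression of kras in cells",
      "unrelated filler text only",
      "egfr again without context"),
    dates = c("2001-05-01", "2004-01-10", "2004-01-10", "2011-07-23", "1999"))
  m <- compile_matcher(term)
  anns <- annotate_corpus(m, docs)
  list(term = term, docs = docs, anns = anns,
       index = build_index(docs, anns))
}
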