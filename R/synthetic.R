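# Seeded generator of synthetic terminologies, corpora with planted
# annotations, and marker gold standards. Documents are synthetic token
# sequences, not natural language: dictionary matching and Boolean set
# algebra are insensitive to grammar, and synthetic tokens keep the planted
# ground truth exact. Filler tokens always contain a digit while synonyms
# are purely alphabetic, so the filler vocabulary can never collide with a
# dictionary synonym.

#' Configuration of the synthetic corpus generator
#'
#' The generated corpus mimics the statistical structure that
#' terminology-filtered biomarker retrieval assumes: documents mention a
#' disease with some prevalence; biomarker-class terms (Clinical Management,
#' Diagnostics, Prognosis, Statistics, Evidence, Antecedent) appear
#' independently at per-class rates; gene mentions follow a Zipf-like
#' background frequency distribution; and a planted set of "true marker"
#' genes is mentioned more often (by `enrichment_factor`) inside documents
#' that contain both the disease and a Clinical Management or Evidence term.
#'
#' @param seed integer seed; every random choice derives from it.
#' @param n_docs number of documents.
#' @param n_genes size of the gene dictionary.
#' @param n_marker_genes number of planted marker genes.
#' @param background_gene_skew Zipf exponent of the background gene mention
#'   distribution (0 = uniform).
#' @param disease_prevalence fraction of documents mentioning the disease.
#' @param class_term_rates named per-document mention probability for each
#'   of the six biomarker classes.
#' @param enrichment_factor multiplier on marker-gene mention probability
#'   within disease documents that also carry a Clinical Management or
#'   Evidence term; 1 = null model (no signal).
#' @param genes_per_doc expected number of background gene mentions per
#'   document.
#' @param filler_range min/max filler tokens per abstract.
#' @param n_class_entries dictionary entries per biomarker class.
#' @param synonyms_per_entry synonyms per biomarker-class entry.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_docs = 2000L,
                             n_genes = 200L,
                             n_marker_genes = 20L,
                             background_gene_skew = 0.5,
                             disease_prevalence = 0.4,
                             class_term_rates = c(ClinicalManagement = 0.48,
                                                  Diagnostics = 0.42,
                                                  Prognosis = 0.44,
                                                  Statistics = 0.24,
                                                  Evidence = 0.41,
                                                  Antecedent = 0.10),
                             enrichment_factor = 5,
                             genes_per_doc = 3,
                             filler_range = c(20L, 40L),
                             n_class_entries = 6L,
                             synonyms_per_entry = 2L) {
  stopifnot(n_marker_genes <= n_genes, n_marker_genes >= 0,
            n_docs >= 1, n_genes >= 1,
            disease_prevalence >= 0, disease_prevalence <= 1,
            all(class_term_rates >= 0), all(class_term_rates <= 1),
            enrichment_factor >= 1, background_gene_skew >= 0,
            genes_per_doc > 0, length(filler_range) == 2,
            filler_range[1] <= filler_range[2])
  needed <- c("ClinicalManagement", "Diagnostics", "Prognosis", "Statistics",
              "Evidence", "Antecedent")
  if (!all(needed %in% names(class_term_rates)))
    stop("class_term_rates must name all six biomarker classes")
  expected_len <- mean(filler_range) + 1 + sum(class_term_rates) +
    genes_per_doc * enrichment_factor + 4
  if (expected_len > 500)
    stop("config error: rates imply an expected document length beyond the ",
         "hard cap of 500 tokens")
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 n_genes = as.integer(n_genes),
                 n_marker_genes = as.integer(n_marker_genes),
                 background_gene_skew = background_gene_skew,
                 disease_prevalence = disease_prevalence,
                 class_term_rates = class_term_rates[needed],
                 enrichment_factor = enrichment_factor,
                 genes_per_doc = genes_per_doc,
                 filler_range = as.integer(filler_range),
                 n_class_entries = as.integer(n_class_entries),
                 synonyms_per_entry = as.integer(synonyms_per_entry)),
            class = "synthetic_config")
}

BIOMARKER_CLASSES <- data.frame(
  class_id = c("ClinicalManagement", "Diagnostics", "Prognosis",
               "Statistics", "Evidence", "Antecedent"),
  name = c("Clinical Management", "Diagnostics", "Prognosis",
           "Statistics", "Evidence marker", "Antecedent"),
  description = c(
    "Terms indicating clinical investigations on patients",
    "Terms representing clinical as well as molecular diagnostics",
    "Terms indicating the prediction for a patient or outcome of therapies",
    "Statistical methods indicating the strength of the biomarker relationship",
    "Terms describing genetic or molecular evidence for activity of a gene",
    "Terms expressing exposure to hazardous agents and risk factors"),
  stringsAsFactors = FALSE)

# n unique purely-alphabetic words, lengths 6..10, drawn from the current stream
unique_words <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    lens <- sample(6:10, need, replace = TRUE)
    w <- vapply(lens, function(l)
      paste(sample(letters, l, replace = TRUE), collapse = ""), character(1))
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Generate a synthetic biomarker terminology
#'
#' Six biomarker retrieval classes with synthetic synonym sets, a `Genes`
#' class with `n_genes` single-synonym entries, and a `Diseases` class with
#' one disease entry. Deterministic for a fixed seed: two runs serialize to
#' byte-identical TSV; different seeds change the synonym strings but not
#' the class structure.
#'
#' @param cfg a [synthetic_config()].
#' @return a [terminology].
#' @export
generate_terminology <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n_bio <- nrow(BIOMARKER_CLASSES) * cfg$n_class_entries * cfg$synonyms_per_entry
  words <- unique_words(n_bio + cfg$n_genes + 2L)
  wi <- 0L
  take <- function(k) { w <- words[(wi + 1L):(wi + k)]; wi <<- wi + k; w }

  classes <- rbind(
    data.frame(class_id = BIOMARKER_CLASSES$class_id,
               name = BIOMARKER_CLASSES$name, parent_id = NA_character_,
               description = BIOMARKER_CLASSES$description,
               stringsAsFactors = FALSE),
    data.frame(class_id = c("Diseases", "Genes"),
               name = c("Diseases", "Human Genes/Proteins"),
               parent_id = NA_character_,
               description = c("Disease concepts",
                               "Gene and protein concepts"),
               stringsAsFactors = FALSE))

  en <- list(); sy <- list()
  for (cid in BIOMARKER_CLASSES$class_id) {
    for (i in seq_len(cfg$n_class_entries)) {
      eid <- sprintf("%s_t%02d", cid, i)
      syn <- take(cfg$synonyms_per_entry)
      en[[length(en) + 1L]] <- data.frame(
        entry_id = eid, class_id = cid, preferred_name = syn[1],
        stringsAsFactors = FALSE)
      sy[[length(sy) + 1L]] <- data.frame(
        entry_id = eid, text = syn, case_sensitive = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  gene_words <- take(cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    eid <- sprintf("G%03d", i)
    en[[length(en) + 1L]] <- data.frame(
      entry_id = eid, class_id = "Genes", preferred_name = gene_words[i],
      stringsAsFactors = FALSE)
    sy[[length(sy) + 1L]] <- data.frame(
      entry_id = eid, text = gene_words[i], case_sensitive = FALSE,
      stringsAsFactors = FALSE)
  }
  dis <- take(2L)
  en[[length(en) + 1L]] <- data.frame(
    entry_id = "DISEASE1", class_id = "Diseases", preferred_name = dis[1],
    stringsAsFactors = FALSE)
  sy[[length(sy) + 1L]] <- data.frame(
    entry_id = "DISEASE1", text = dis, case_sensitive = FALSE,
    stringsAsFactors = FALSE)

  en <- do.call(rbind, en); sy <- do.call(rbind, sy)
  classes <- classes[order(classes$class_id), , drop = FALSE]
  en <- en[order(en$entry_id), , drop = FALSE]
  sy <- sy[order(sy$entry_id, sy$text), , drop = FALSE]
  rownames(classes) <- rownames(en) <- rownames(sy) <- NULL
  terminology(classes = classes, entries = en, synonyms = sy,
              name = sprintf("synthetic-biomarker-seed%d", cfg$seed),
              version = "1")
}

#' Generate a synthetic corpus with planted annotations
#'
#' Assembles documents from a digit-bearing filler vocabulary with planted
#' synonym mentions: per document, the disease synonym appears with
#' probability `disease_prevalence`; one term of each biomarker class with
#' its class rate; each gene with its Zipf-skewed background probability.
#' Inside documents containing both the disease term and a Clinical
#' Management or Evidence term, marker-gene mention probabilities are
#' multiplied by `enrichment_factor` (capped at 0.95). Every planted mention
#' is recorded with its exact character offsets; the record is the matching
#' ground truth. Fully reproducible from the seed.
#'
#' @param cfg a [synthetic_config()].
#' @param term the matching [generate_terminology()] result.
#' @return object of class `synthetic_corpus`: list with `documents`,
#'   `true_annotations`, `marker_set` (a [gold_standard()]) and `config`.
#' @export
generate_corpus <- function(cfg, term) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(term, "terminology"))
  set.seed(cfg$seed + 1000003L)

  fillers <- sprintf("%s%03d",
                     vapply(sample(3:5, 300, replace = TRUE), function(l)
                       paste(sample(letters, l, replace = TRUE), collapse = ""),
                       character(1)),
                     seq_len(300))
  gene_ids <- sprintf("G%03d", seq_len(cfg$n_genes))
  markers <- if (cfg$n_marker_genes > 0)
    sort(sample(gene_ids, cfg$n_marker_genes)) else character()
  is_marker <- gene_ids %in% markers

  w <- seq_len(cfg$n_genes)^(-cfg$background_gene_skew)
  p_gene <- pmin(0.95, cfg$genes_per_doc * w / sum(w))

  syn_by_entry <- split(term$synonyms$text, term$synonyms$entry_id)
  class_entries <- split(term$entries$entry_id, term$entries$class_id)
  class_of <- stats::setNames(term$entries$class_id, term$entries$entry_id)
  six <- BIOMARKER_CLASSES$class_id
  rates <- cfg$class_term_rates

  docs <- vector("list", cfg$n_docs)
  anns <- vector("list", cfg$n_docs)
  for (d in seq_len(cfg$n_docs)) {
    doc_id <- sprintf("D%05d", d)
    disease <- stats::runif(1) < cfg$disease_prevalence
    class_present <- stats::runif(length(six)) < rates
    enriched <- disease && any(class_present[six %in% c("ClinicalManagement",
                                                        "Evidence")])
    p <- p_gene
    if (enriched && cfg$enrichment_factor > 1)
      p[is_marker] <- pmin(0.95, p[is_marker] * cfg$enrichment_factor)
    genes_here <- gene_ids[stats::runif(cfg$n_genes) < p]

    mention_entries <- character()
    if (disease) mention_entries <- "DISEASE1"
    for (ci in which(class_present)) {
      e <- class_entries[[six[ci]]]
      mention_entries <- c(mention_entries, e[sample.int(length(e), 1)])
    }
    mention_entries <- c(mention_entries, genes_here)
    mention_tokens <- vapply(mention_entries, function(e) {
      s <- syn_by_entry[[e]]
      s[sample.int(length(s), 1)]
    }, character(1))

    n_fill <- sample(cfg$filler_range[1]:cfg$filler_range[2], 1)
    fill_tokens <- sample(fillers, n_fill, replace = TRUE)
    n_tok <- n_fill + length(mention_tokens)
    slot <- sample.int(n_tok)                     # permutation of positions
    tokens <- character(n_tok)
    mention_pos <- slot[seq_along(mention_tokens)]
    tokens[mention_pos] <- mention_tokens
    tokens[slot[-seq_along(mention_tokens)]] <- fill_tokens
    starts <- c(0L, cumsum(stringi::stri_length(tokens) + 1L))
    abstract <- paste(tokens, collapse = " ")
    title <- paste(sample(fillers, 4), collapse = " ")
    date <- sprintf("%04d-%02d-%02d", sample(1995:2012, 1), sample(12, 1),
                    sample(28, 1))
    docs[[d]] <- data.frame(doc_id = doc_id, title = title,
                            abstract = abstract, date = date,
                            stringsAsFactors = FALSE)
    if (length(mention_entries)) {
      anns[[d]] <- data.frame(
        doc_id = doc_id, field = "abstract",
        start = starts[mention_pos],
        end = starts[mention_pos] + stringi::stri_length(mention_tokens),
        matched_text = unname(mention_tokens),
        entry_id = unname(mention_entries),
        class_id = unname(class_of[mention_entries]),
        stringsAsFactors = FALSE)
    }
  }
  documents <- do.call(rbind, docs)
  truth <- do.call(rbind, anns[!vapply(anns, is.null, logical(1))])
  if (is.null(truth)) truth <- empty_annotations()
  truth <- truth[order(truth$doc_id, truth$start), , drop = FALSE]
  rownames(documents) <- rownames(truth) <- NULL
  structure(list(documents = documents, true_annotations = truth,
                 marker_set = gold_standard(markers, "synthetic_markers"),
                 config = cfg),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus: %d documents, %d planted mentions, %d markers>\n",
              nrow(x$documents), nrow(x$true_annotations),
              length(x$marker_set$entity_ids)))
  invisible(x)
}

#' End-to-end marker recovery experiment
#'
#' Runs the full retrieval pipeline on a synthetic corpus: annotate with the
#' compiled matcher, build the index, evaluate the disease query restricted
#' to the gene class with and without the additional Clinical Management AND
#' Evidence class filters, rank the resulting gene tables, and compare the
#' enrichment curves of both rankings against the planted marker set. The
#' filtered query retrieves a subset of the unfiltered documents (AND
#' monotonicity); with `enrichment_factor > 1` its ranking should place the
#' planted markers higher.
#'
#' @param cfg a [synthetic_config()] with `n_marker_genes > 0` (a
#'   marker-free config yields a report flagged invalid).
#' @param ranking_mode `"frequency"` or `"relative_entropy"` (reference =
#'   the full synthetic corpus).
#' @param top_fraction the fraction of the gene dictionary regarded as "top
#'   ranks" when counting recovered markers (default: top decile).
#' @return object of class `recovery_report`: the two document sets, ranked
#'   lists, enrichment curves, enrichment scores, the fraction of markers in
#'   the top ranks of the filtered ranking, the minimum margin by which the
#'   filtered curve dominates the unfiltered one over the first
#'   `n_marker_genes` ranks, and `curve_gap_p_value`, a two-sided
#'   marker-label permutation p-value of the filtered-minus-unfiltered
#'   curve-difference statistic (exact under the null generator, where the
#'   marker labels are independent of both rankings).
#' @export
recovery_experiment <- function(cfg, ranking_mode = c("frequency",
                                                      "relative_entropy"),
                                top_fraction = 0.1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ranking_mode <- match.arg(ranking_mode)
  if (cfg$n_marker_genes == 0)
    return(structure(list(valid = FALSE,
                          reason = "degenerate config: no planted markers"),
                     class = "recovery_report"))
  term <- generate_terminology(cfg)
  corpus <- generate_corpus(cfg, term)
  matcher <- compile_matcher(term)
  anns <- annotate_corpus(matcher, corpus$documents)
  index <- build_index(corpus$documents, anns)
  disease_name <- term$entries$preferred_name[term$entries$entry_id == "DISEASE1"]
  q_unf <- sprintf('"%s" AND [Genes]', disease_name)
  q_fil <- sprintf('"%s" AND [Genes] AND [ClinicalManagement] AND [Evidence]',
                   disease_name)
  ds_unf <- evaluate_query(index, q_unf, term)
  ds_fil <- evaluate_query(index, q_fil, term)
  rank_table <- function(ds) {
    tab <- entity_table(index, ds, "Genes", term)
    if (ranking_mode == "frequency") rank_by_frequency(tab)
    else rank_by_relative_entropy(tab, index, max(1L, length(ds$doc_ids)))
  }
  r_unf <- rank_table(ds_unf)
  r_fil <- rank_table(ds_fil)
  markers <- corpus$marker_set$entity_ids
  curve_unf <- if (nrow(r_unf)) enrichment_curve(r_unf, markers) else integer()
  curve_fil <- if (nrow(r_fil)) enrichment_curve(r_fil, markers) else integer()

  at_rank <- function(curve, i) {   # curve value at rank i (constant beyond end)
    if (!length(curve)) return(0L)
    curve[pmin(i, length(curve))]
  }
  ranks_upto <- seq_len(cfg$n_marker_genes)
  dominance_min_margin <- min(at_rank(curve_fil, ranks_upto) -
                                at_rank(curve_unf, ranks_upto))
  top_k <- ceiling(cfg$n_genes * top_fraction)
  top_fil <- utils::head(r_fil$entry_id, top_k)
  top_decile_fraction <- mean(markers %in% top_fil)

  # Permutation test of the curve difference. With enrichment_factor = 1 the
  # corpus generator never consults the marker labels, so the marker set is a
  # uniform random gene subset independent of both rankings: resampling
  # same-size gene sets gives the exact null distribution of the statistic.
  all_genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  ids_fil <- r_fil$entry_id; ids_unf <- r_unf$entry_id
  gap_stat <- function(set) {
    cf <- cumsum(ids_fil %in% set)
    cu <- cumsum(ids_unf %in% set)
    sum(at_rank(cf, seq_len(cfg$n_genes)) - at_rank(cu, seq_len(cfg$n_genes)))
  }
  p_value <- if (length(ids_fil) && length(ids_unf)) {
    s_obs <- gap_stat(markers)
    s_perm <- replicate(199, gap_stat(sample(all_genes, length(markers))))
    (1 + sum(abs(s_perm) >= abs(s_obs))) / 200
  } else NA_real_

  structure(list(
    valid = TRUE, config = cfg, ranking_mode = ranking_mode,
    query_unfiltered = q_unf, query_filtered = q_fil,
    n_docs_unfiltered = length(ds_unf$doc_ids),
    n_docs_filtered = length(ds_fil$doc_ids),
    filtered_is_subset = all(ds_fil$doc_ids %in% ds_unf$doc_ids),
    ranked_unfiltered = r_unf, ranked_filtered = r_fil,
    curve_unfiltered = curve_unf, curve_filtered = curve_fil,
    es_unfiltered = enrichment_score(curve_unf),
    es_filtered = enrichment_score(curve_fil),
    top_k = top_k, top_decile_fraction = top_decile_fraction,
    dominance_min_margin = dominance_min_margin,
    curve_gap_p_value = p_value),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  if (!isTRUE(x$valid)) {
    cat("<recovery_report: INVALID -", x$reason, ">\n")
    return(invisible(x))
  }
  cat(sprintf(paste0(
    "<recovery_report (%s ranking)>\n",
    "  docs: %d unfiltered, %d filtered (subset: %s)\n",
    "  enrichment score: %d unfiltered, %d filtered (of %d markers)\n",
    "  markers in top %d ranks of filtered ranking: %.0f%%\n",
    "  min dominance margin over first %d ranks: %d\n"),
    x$ranking_mode, x$n_docs_unfiltered, x$n_docs_filtered,
    x$filtered_is_subset, x$es_unfiltered, x$es_filtered,
    x$config$n_marker_genes, x$top_k, 100 * x$top_decile_fraction,
    x$config$n_marker_genes, x$dominance_min_margin))
  invisible(x)
}

#' Write the fixture files of a synthetic corpus
#'
#' Emits the corpus as JSONL, the terminology as TSV, the planted
#' annotations as JSONL, the marker gold standard as plain text, and a JSON
#' echo of the configuration.
#'
#' @param corpus a [generate_corpus()] result.
#' @param term the matching [generate_terminology()] result.
#' @param dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
write_synthetic_fixtures <- function(corpus, term, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("corpus.jsonl", "terminology.tsv",
                            "true_annotations.jsonl", "gold_markers.txt",
                            "config.json"))
  docs <- corpus$documents
  writeLines(vapply(seq_len(nrow(docs)), function(i)
    jsonlite::toJSON(list(id = docs$doc_id[i], title = docs$title[i],
                          abstract = docs$abstract[i], date = docs$date[i]),
                     auto_unbox = TRUE), character(1)), paths[1])
  write_terminology(term, paths[2])
  tr <- corpus$true_annotations
  writeLines(vapply(seq_len(nrow(tr)), function(i)
    jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE), character(1)),
    paths[3])
  writeLines(c("# planted synthetic marker genes",
               corpus$marker_set$entity_ids), paths[4])
  cfg <- corpus$config
  jsonlite::write_json(unclass(cfg), paths[5], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
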