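# Evaluation battery: Cohen's kappa for inter-annotator agreement,
# GSEA-style enrichment curves of a ranked entity list against a curated
# gold standard, and ranked-retrieval precision/recall/F-score tables.

#' Round half up
#'
#' Decimal rounding with ties away from zero (0.585 -> 0.59 at 2 digits),
#' the convention used when comparing computed metrics against values
#' printed at fixed precision. Base R's `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}

#' Cohen's kappa from a square agreement table
#'
#' `kappa = (Pr(a) - Pr(e)) / (1 - Pr(e))` where `Pr(a)` is the observed
#' agreement (diagonal mass) and `Pr(e)` the agreement expected by chance
#' from the raters' marginal label distributions. Cell `(i, j)` counts items
#' labelled category `i` by rater 1 and `j` by rater 2. If chance agreement
#' is exactly 1 (both raters constant), kappa is defined as 1 when observed
#' agreement is also 1 and is a domain error otherwise.
#'
#' @param table square numeric matrix of nonnegative counts.
#' @return kappa, a number in `[-1, 1]`.
#' @export
cohens_kappa <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table))
    stop("domain error: agreement table must be square")
  if (any(table < 0) || any(table != round(table)))
    stop("domain error: counts must be nonnegative integers")
  n <- sum(table)
  if (n <= 0) stop("domain error: empty agreement table")
  pr_a <- sum(diag(table)) / n
  pr_e <- sum((rowSums(table) / n) * (colSums(table) / n))
  if (pr_e >= 1) {
    if (pr_a >= 1) return(1)
    stop("domain error: chance agreement is 1 but observed agreement is not")
  }
  (pr_a - pr_e) / (1 - pr_e)
}

#' Read a gold-standard entity list
#'
#' Plain text, one entity id per line; `#` starts a comment.
#'
#' @param path file path.
#' @param source label recorded with the set.
#' @return object of class `gold_standard`: list with `entity_ids`
#'   (character set) and `source`.
#' @export
read_gold_standard <- function(path, source = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- stringi::stri_replace_first_regex(lines, "#.*$", "")
  lines <- stringi::stri_trim_both(lines)
  gold_standard(lines[nzchar(lines)], source)
}

#' @rdname read_gold_standard
#' @param entity_ids character vector of entity ids.
#' @export
gold_standard <- function(entity_ids, source = "gold") {
  structure(list(entity_ids = sort(unique(as.character(entity_ids))),
                 source = source),
            class = "gold_standard")
}

gold_ids <- function(gold) {
  if (inherits(gold, "gold_standard")) gold$entity_ids
  else sort(unique(as.character(gold)))
}

ranked_ids <- function(ranked) {
  if (is.data.frame(ranked)) ranked$entry_id else as.character(ranked)
}

#' Enrichment curve of a ranked list against a gold standard
#'
#' Walking down the ranked entity list, the running sum is increased by 1
#' every time the entity at that rank belongs to the gold set S. Element `i`
#' of the curve is therefore `|top-i of L  intersect  S|`; the final value is
#' `|L intersect S|`. A gold set disjoint from the list yields an all-zero
#' curve.
#'
#' @param ranked a ranked entity list (data.frame with `entry_id`, e.g. from
#'   [rank_by_frequency()]) or a character vector of entity ids in rank
#'   order.
#' @param gold a [gold_standard()] or character vector of entity ids.
#' @return integer vector of length `N` (the running-sum curve).
#' @export
enrichment_curve <- function(ranked, gold) {
  ids <- ranked_ids(ranked)
  if (!length(ids)) stop("ranked list is empty")
  S <- gold_ids(gold)
  if (!length(S)) warning("empty gold standard: enrichment curve is all zero")
  cumsum(as.integer(ids %in% S))
}

#' Enrichment score of a curve
#'
#' The maximum of the running sum over all prefixes. Because every increment
#' of the curve is `+1`, this maximum coincides with the curve's final value
#' `|L intersect S|`; the full curve (what enrichment plots show) is the
#' richer object and is reported alongside by [enrichment_curve()].
#'
#' @param curve an [enrichment_curve()] result.
#' @return integer enrichment score.
#' @export
enrichment_score <- function(curve) {
  if (!length(curve)) return(0L)
  as.integer(max(curve))
}

#' F-score from precision and recall
#'
#' Harmonic mean, `2 P R / (P + R)`, defined as 0 when both are 0.
#'
#' @param precision,recall numbers in `[0, 1]`.
#' @return F-score in `[0, 1]`.
#' @export
f_score <- function(precision, recall) {
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1))
    stop("domain error: precision and recall must lie in [0, 1]")
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Ranked-retrieval metrics at every cutoff
#'
#' Treats the top-k of the ranked list as the retrieved positives, for every
#' k from 1 to N. At each k: `TP` is the number of gold entities in the
#' top-k, `FP = k - TP`, `FN = |S| - TP`; precision, recall and F-score
#' follow. No true-negative count is defined: the entity universe of ranked
#' retrieval is open.
#'
#' @inheritParams enrichment_curve
#' @return data.frame with columns `rank`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f_score`.
#' @export
precision_recall_table <- function(ranked, gold) {
  S <- gold_ids(gold)
  if (!length(S)) stop("domain error: gold standard is empty")
  curve <- enrichment_curve(ranked, S)
  k <- seq_along(curve)
  tp <- curve
  data.frame(rank = k, tp = tp, fp = k - tp, fn = length(S) - tp,
             precision = tp / k, recall = tp / length(S),
             f_score = ifelse(tp == 0, 0, 2 * (tp / k) * (tp / length(S)) /
                                (tp / k + tp / length(S))))
}

#' Metrics at recall thresholds
#'
#' For each threshold t, the first rank k at which recall reaches t, with
#' that row's precision and F-score — the row shape of a fixed-recall
#' performance table (e.g. recall 10%, 30%, 50%). A threshold the list never
#' reaches is reported with NA rank and metrics.
#'
#' @param table a [precision_recall_table()] result.
#' @param thresholds recall levels in `(0, 1]`.
#' @return data.frame with columns `threshold`, `rank`, `recall`,
#'   `precision`, `f_score`.
#' @export
metrics_at_recall <- function(table, thresholds = c(0.1, 0.3, 0.5)) {
  stopifnot(all(thresholds > 0 & thresholds <= 1))
  rows <- lapply(thresholds, function(t) {
    k <- which(table$recall >= t)
    if (!length(k))
      return(data.frame(threshold = t, rank = NA_integer_,
                        recall = NA_real_, precision = NA_real_,
                        f_score = NA_real_))
    k <- k[1]
    data.frame(threshold = t, rank = table$rank[k], recall = table$recall[k],
               precision = table$precision[k], f_score = table$f_score[k])
  })
  do.call(rbind, rows)
}

#' Maximal F-score of a ranked list
#'
#' The cutoff maximizing the F-score; the earliest rank wins ties.
#'
#' @param table a [precision_recall_table()] result.
#' @return list with `rank` and `f_score`.
#' @export
max_f_score <- function(table) {
  if (!nrow(table)) stop("domain error: empty metrics table")
  i <- which.max(table$f_score)    # which.max returns the first maximum
  list(rank = table$rank[i], f_score = table$f_score[i])
}

#' Most recent abstracts mentioning an entity
#'
#' The documents of `docset` containing `entry_id`, newest first (date
#' descending, then doc_id descending), truncated to `n`. Mirrors the manual
#' inspection protocol where a user reads only the first few (most recent)
#' retrieved abstracts per gene.
#'
#' @param index a `corpus_index`.
#' @param docset a `doc_set` or character vector of doc ids.
#' @param entry_id entity id.
#' @param n maximum number of documents.
#' @return data.frame of documents (possibly fewer than `n`).
#' @export
select_top_abstracts <- function(index, docset, entry_id, n = 10) {
  stopifnot(inherits(index, "corpus_index"), n > 0)
  ids <- if (inherits(docset, "doc_set")) docset$doc_ids else as.character(docset)
  hits <- intersect(index$postings_entry[[entry_id]] %||% character(), ids)
  docs <- index$documents[index$documents$doc_id %in% hits, , drop = FALSE]
  if (!nrow(docs)) return(empty_documents())
  o <- order(-date_sort_key(docs$date),
             -xtfrm(docs$doc_id))
  docs <- docs[utils::head(o, n), , drop = FALSE]
  rownames(docs) <- NULL
  docs
}

#' Published Alzheimer's disease retrieval-performance reference table
#'
#' A published evaluation of frequency-ranked gene retrieval for Alzheimer's
#' disease against a curated gold standard: for eight terminology-class
#' selections, the rank, recall and precision at recall 0.10/0.30/0.50 plus
#' the row attaining the maximal F-score, with all values printed at two
#' decimals. Bundled as fixture data for internal-consistency checks of the
#' F-score computation; the underlying corpus and gold standard are not
#' distributable, so only the printed summary values are included.
#'
#' @return data.frame with columns `selection`, `row_type`
#'   (`"recall_threshold"` or `"max_f"`), `rank`, `recall`, `precision`,
#'   `f_score`.
#' @export
ad_reference_metrics <- function() {
  rows <- rbind(
    c("genes",                         60, 0.10, 0.92, 0.17, "recall_threshold"),
    c("genes",                        230, 0.30, 0.73, 0.42, "recall_threshold"),
    c("genes",                        469, 0.50, 0.61, 0.55, "recall_threshold"),
    c("genes",                        728, 0.67, 0.52, 0.59, "max_f"),
    c("genes+clinical_management",     61, 0.10, 0.90, 0.17, "recall_threshold"),
    c("genes+clinical_management",    226, 0.30, 0.75, 0.42, "recall_threshold"),
    c("genes+clinical_management",    465, 0.50, 0.61, 0.55, "recall_threshold"),
    c("genes+clinical_management",    682, 0.65, 0.54, 0.59, "max_f"),
    c("genes+evidence",                62, 0.10, 0.89, 0.17, "recall_threshold"),
    c("genes+evidence",               225, 0.30, 0.75, 0.42, "recall_threshold"),
    c("genes+evidence",               464, 0.50, 0.61, 0.55, "recall_threshold"),
    c("genes+evidence",               654, 0.62, 0.54, 0.57, "max_f"),
    c("genes+prognosis",               63, 0.10, 0.87, 0.17, "recall_threshold"),
    c("genes+prognosis",              247, 0.30, 0.68, 0.41, "recall_threshold"),
    c("genes+prognosis",              541, 0.50, 0.52, 0.51, "recall_threshold"),
    c("genes+prognosis",              740, 0.61, 0.47, 0.53, "max_f"),
    c("genes+diagnostics",             64, 0.10, 0.86, 0.17, "recall_threshold"),
    c("genes+diagnostics",            237, 0.30, 0.71, 0.42, "recall_threshold"),
    c("genes+diagnostics",            494, 0.50, 0.57, 0.53, "recall_threshold"),
    c("genes+diagnostics",            520, 0.52, 0.57, 0.54, "max_f"),
    c("genes+statistics",              64, 0.10, 0.86, 0.17, "recall_threshold"),
    c("genes+statistics",             227, 0.30, 0.74, 0.42, "recall_threshold"),
    c("genes+statistics",             678, 0.50, 0.42, 0.45, "recall_threshold"),
    c("genes+statistics",             377, 0.41, 0.62, 0.49, "max_f"),
    c("genes+cm+evidence",             60, 0.10, 0.92, 0.17, "recall_threshold"),
    c("genes+cm+evidence",            224, 0.30, 0.75, 0.42, "recall_threshold"),
    c("genes+cm+evidence",            451, 0.50, 0.63, 0.56, "recall_threshold"),
    c("genes+cm+evidence",            555, 0.57, 0.59, 0.58, "max_f"),
    c("genes+cm+evidence+prognosis",   61, 0.10, 0.90, 0.17, "recall_threshold"),
    c("genes+cm+evidence+prognosis",  230, 0.30, 0.73, 0.42, "recall_threshold"),
    c("genes+cm+evidence+prognosis",  568, 0.50, 0.50, 0.50, "recall_threshold"),
    c("genes+cm+evidence+prognosis",  479, 0.47, 0.56, 0.51, "max_f"))
  data.frame(selection = rows[, 1],
             row_type = rows[, 6],
             rank = as.integer(rows[, 2]),
             recall = as.numeric(rows[, 3]),
             precision = as.numeric(rows[, 4]),
             f_score = as.numeric(rows[, 5]),
             stringsAsFactors = FALSE)
}
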