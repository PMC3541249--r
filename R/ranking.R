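# Entity ranking of a retrieved corpus: by document frequency, or by the
# entity's Kullback-Leibler (relative entropy / information gain)
# contribution against a reference corpus. The relative-entropy score
# promotes entities that are disproportionately frequent in the selection
# and demotes entities that are ubiquitous in the reference, e.g. cytokines
# that occur all over the literature.

#' Ranking configuration
#'
#' @param mode `"relative_entropy"` or `"frequency"`.
#' @param proportion_mode how the two quantities compared by the score are
#'   formed. `"proportions"` (default) uses corpus fractions
#'   `p1 = n_sel/N_sel` and `p2 = (n_ref + pseudocount)/(N_ref +
#'   pseudocount)`, the true KL information-gain term. `"raw_counts"` uses
#'   the document counts themselves, `p1 = n_sel`, `p2 = n_ref +
#'   pseudocount`, for a literal reading of the score as a function of
#'   "number of abstracts". Both orderings agree whenever all entities share
#'   the same corpus sizes.
#' @param pseudocount additive smoothing on the reference counts so entities
#'   absent from the reference stay finite; must be positive in
#'   `"proportions"` mode.
#' @param min_doc_count drop entities occurring in fewer than this many
#'   selected documents before ranking (see [filter_min_docs()]).
#' @return list of class `ranking_config`.
#' @export
ranking_config <- function(mode = c("relative_entropy", "frequency"),
                           proportion_mode = c("proportions", "raw_counts"),
                           pseudocount = 1, min_doc_count = 0L) {
  mode <- match.arg(mode)
  proportion_mode <- match.arg(proportion_mode)
  stopifnot(pseudocount >= 0, min_doc_count >= 0)
  if (proportion_mode == "proportions" && pseudocount <= 0)
    stop("pseudocount must be > 0 in proportions mode (guards n_ref = 0)")
  structure(list(mode = mode, proportion_mode = proportion_mode,
                 pseudocount = pseudocount,
                 min_doc_count = as.integer(min_doc_count),
                 log_base = "natural"),
            class = "ranking_config")
}

#' Relative-entropy score of one entity
#'
#' Computes `p1 * log(p1 / p2)` with the natural logarithm, where `p1`
#' measures the entity's prevalence in the selected corpus and `p2` its
#' prevalence in the reference corpus (see [ranking_config()] for how the
#' two are formed). An entity absent from the selection (`n_sel = 0`) scores
#' 0 by the `0 * log 0 = 0` convention. The logarithm base only rescales all
#' scores by a positive constant, so ranks are base-invariant.
#'
#' @param stats an [entity_stats()] result (any list with `n_sel`, `N_sel`,
#'   `n_ref`, `N_ref` works).
#' @param cfg a [ranking_config()] (or compatible list).
#' @return numeric score.
#' @export
relative_entropy <- function(stats, cfg = ranking_config()) {
  n_sel <- stats$n_sel; N_sel <- stats$N_sel
  n_ref <- stats$n_ref; N_ref <- stats$N_ref
  if (N_sel <= 0 || N_ref <= 0)
    stop("domain error: corpus sizes must be positive")
  if (n_sel == 0) return(0)
  if (identical(cfg$proportion_mode, "raw_counts")) {
    p1 <- n_sel
    p2 <- n_ref + cfg$pseudocount
  } else {
    p1 <- n_sel / N_sel
    p2 <- (n_ref + cfg$pseudocount) / (N_ref + cfg$pseudocount)
  }
  if (p2 <= 0)
    stop("domain error: reference probability is zero; use a positive pseudocount")
  p1 * log(p1 / p2)
}

ranked_entity_list <- function(entry_id, score, n_sel, n_ref) {
  o <- order(-score, -n_sel, entry_id)
  data.frame(rank = seq_along(o), entry_id = entry_id[o], score = score[o],
             n_sel = n_sel[o], n_ref = n_ref[o], stringsAsFactors = FALSE)
}

#' Rank entities by document frequency
#'
#' Descending document count; ties broken by lexicographic `entry_id`. The
#' `score` column equals the document count.
#'
#' @param table entity table (`entry_id`, `doc_count`), e.g. from
#'   [entity_table()].
#' @return data.frame with columns `rank`, `entry_id`, `score`, `n_sel`,
#'   `n_ref` (NA: no reference is consulted).
#' @export
rank_by_frequency <- function(table) {
  if (!nrow(table)) return(ranked_entity_list(character(), numeric(),
                                              integer(), integer()))
  stopifnot(all(table$doc_count >= 0))
  ranked_entity_list(table$entry_id, as.numeric(table$doc_count),
                     as.integer(table$doc_count),
                     rep(NA_integer_, nrow(table)))
}

#' Rank entities by relative entropy against a reference corpus
#'
#' Each entity's score is [relative_entropy()] of its selected-vs-reference
#' document counts. Entities missing from the reference are treated as
#' `n_ref = 0` (smoothed by the pseudocount) with a warning.
#'
#' @param table entity table (`entry_id`, `doc_count`) of the selection.
#' @param ref_index reference `corpus_index` (the stand-in for all of
#'   Medline).
#' @param sel_size number of documents in the selected corpus (`N_sel`).
#' @param cfg a [ranking_config()].
#' @return data.frame with columns `rank`, `entry_id`, `score`, `n_sel`,
#'   `n_ref`; scores non-increasing, ranks consecutive from 1, ties broken
#'   by higher `n_sel` then lexicographic `entry_id`.
#' @export
rank_by_relative_entropy <- function(table, ref_index, sel_size,
                                     cfg = ranking_config()) {
  stopifnot(inherits(ref_index, "corpus_index"), sel_size > 0)
  if (!nrow(table)) return(ranked_entity_list(character(), numeric(),
                                              integer(), integer()))
  n_ref <- vapply(table$entry_id, function(e)
    length(ref_index$postings_entry[[e]]), integer(1))
  missing <- table$entry_id[n_ref == 0L]
  if (length(missing))
    warning("entities absent from the reference corpus (smoothed): ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
  score <- vapply(seq_len(nrow(table)), function(i) {
    relative_entropy(list(n_sel = table$doc_count[i], N_sel = sel_size,
                          n_ref = n_ref[i], N_ref = ref_index$n_docs), cfg)
  }, numeric(1))
  ranked_entity_list(table$entry_id, score, as.integer(table$doc_count),
                     unname(n_ref))
}

#' Drop rarely-mentioned entities
#'
#' Keeps entities occurring in at least `k` documents of the selection. The
#' boundary is inclusive: with `k = 5`, an entity found in exactly 5
#' abstracts is kept. Used to cut the long tail of incidental gene mentions
#' before inspection.
#'
#' @param table entity table (`entry_id`, `doc_count`).
#' @param k minimum document count.
#' @return the filtered table.
#' @export
filter_min_docs <- function(table, k) {
  stopifnot(k >= 0)
  out <- table[table$doc_count >= k, , drop = FALSE]
  rownames(out) <- NULL
  out
}
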